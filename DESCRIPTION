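Package: pcpscore
Title: Positively Charged Surface Patch Scoring for Antibody Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies contiguous positively charged patches (PCPs) on the
    solvent-exposed surface of antibody antigen-binding domains (scFv) from
    PDB/mmCIF structures. Computes per-residue solvent accessibility
    (Shrake-Rupley), builds residue contact graphs, detects same-sign charged
    patches as connected components, and reports the PCP score (total residues
    in the three largest positive patches), a predictor of chimeric antigen
    receptor tonic signaling. Includes an in-silico charge-mutation scanner
    for framework-region engineering, a screened-Coulomb potential sampler
    for qualitative electrostatic maps, flow-cytometry index statistics
    (tonic signaling index, exhaustion score, Pearson association),
    four-parameter logistic EC50 fitting, and a synthetic fixture generator
    with planted patches of known size for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
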