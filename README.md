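# pcpscore

Quantifies **positively charged patches (PCPs)** on the solvent-exposed
surface of antibody antigen-binding domains (scFv), and computes the
**PCP score** — the total number of residues in the three largest
contiguous positive patches — a structural predictor of chimeric
antigen receptor (CAR) *tonic signaling*: the spontaneous,
antigen-independent receptor activation that drives CAR-T cell
exhaustion when too strong and limits persistence when too weak.

The package is for CAR/antibody engineers and structural
bioinformaticians who want to rank scFv designs by surface charge
clustering, scan framework-region charge mutations in silico, and
relate patch scores to flow-cytometry readouts.

## What it computes

Given a structure (PDB/mmCIF, e.g. a homology model):

1. per-residue integer formal charges at pH 7.5
   (Arg/Lys +1, Asp/Glu −1, His 0 by default);
2. per-residue solvent accessibility (Shrake–Rupley, probe 1.4 Å,
   960 points/atom) and a surface call at relative SASA ≥ 0.20;
3. a surface-residue contact graph (minimum heavy-atom distance
   ≤ 5 Å);
4. patches = connected components of same-sign charged surface
   residues; **PCP score = Σ sizes of the top 3 positive patches**.

Around that core: an in-silico charge-mutation scanner (ΔPCP per
mutation or per joint variant set, with CDR masking), a
screened-Coulomb potential sampler for qualitative electrostatic maps
(φ = Σ qᵢ e^(−κrᵢ)/(εrᵢ)), the flow-cytometry indexes
(tonic signaling index = MFI^CD69 / MFI^GFP; exhaustion score =
mean of GFP-normalised PD-1/Lag-3/Tim-3 MFIs), Pearson association
with two-tailed p, four-parameter-logistic EC50 fitting, and a
synthetic fixture generator that plants patches of known size so the
whole pipeline is testable without any external data.

## Worked example

```r
library(pcpscore)

# a fixture with planted patches of sizes 12, 9, 5
fix <- generate_shell_structure(patch_spec(sizes = c(12, 9, 5), seed = 7))
write_fixture(fix, "demo.pdb")

rep <- cmd_score("demo.pdb", run_config(max_asa = "sphere"))
rep$patches
#> <patch_set> 3 positive patch(es); PCP score 26
#>   #1 size 12: A:48 A:56 A:69 A:77 A:82 A:90 A:98 A:103 ...
#>   #2 size  9: A:374 A:395 A:408 A:416 A:429 A:437 A:442 A:450 ...
#>   #3 size  5: A:97 A:110 A:131 A:152 A:165
```

The detector recovers exactly the planted patch sizes; the PCP score
26 is their sum. (`max_asa = "sphere"` tells the surface classifier
that fixture residues are single spheres; real structures use the
default Tien max-ASA table.)

Sequence-level charge density of a 20-mer with three lysines and one
glutamate:

```r
charge_density("KKKEGGGGGGGGGGGGGGGG")
#> <charge_density> n=20 net=+2 e net/res=+0.1 pos/res=0.15 neg/res=-0.05
```

Assay side — indexes from a cohort and their association with patch
scores:

```r
co  <- generate_assay_cohort(10, true_r = 0.9, noise_cv = 0.1, seed = 7)
idx <- assay_indexes(co$assay)
head(idx, 3)
#>   sample_id  group tonic_index exhaustion_score
#> 1      S001 cohort    2.834413         3.238034
#> 2      S002 cohort    2.195236         1.998774
#> 3      S003 cohort    2.198085         2.211557

pearson_association(co$truth$pcp_score, idx$tonic_index)
#> <association> n=10 r=0.8358 r2=0.6986 p=0.002595  y = 1.107 + 0.03486 x
```

Here r² measures how much of the tonic-index variation the patch score
explains in this noisy 10-sample cohort; the two-tailed p tests
r = 0. Dose–response binding curves fit the 4PL model:

```r
conc <- 10^seq(-2, 2, length.out = 12)          # nM
resp <- 5 + 90 / (1 + (2.40 / conc))            # EC50 = 2.40 nM
fit_4pl(conc, resp)
#> <4PL fit> EC50 = 2.4 nM (95% CI 2.4-2.4), hill = 1, range [5, 95]
```

## Command line

```sh
pcpscore score     --structure model.pdb --out report        # PCP score + patch table
pcpscore scan      --structure model.pdb --mutations muts.txt --cdr-mask cdr.txt
pcpscore assay     --table assay.tsv --relative-to CONTROL
pcpscore correlate --table joined.tsv --x pcp_score --y tonic_index
pcpscore simulate  --out fixture --sizes 12,9,5 --seed 1
```

(`inst/exec/pcpscore`; run via
`Rscript $(Rscript -e 'cat(system.file("exec","pcpscore",package="pcpscore"))') ...`
or symlink it onto your PATH.) Mutation files take one
`chain:resnum:newtype` per line, with optional `group<TAB>spec` lines
for joint variant sets. Outputs are JSON/TSV plus Chimera `defattr`
and PyMOL selection scripts coloured by patch rank; identical
invocations produce byte-identical files.

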