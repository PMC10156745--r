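---
title: "Charge-patch scoring for scFv surfaces: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-patch scoring for scFv surfaces: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcpscore)
```

## The problem and the model

Chimeric antigen receptors (CARs) signal spontaneously in the absence of
antigen — *tonic signaling* — at strengths that vary widely between scFv
binding domains and that shape CAR-T cell fate: too much drives
exhaustion, too little limits persistence. A biophysical correlate of
this behaviour is the clustering of positively charged residues into
contiguous *positively charged patches* (PCPs) on the solvent-exposed
surface of the scFv, which promote antigen-independent receptor
self-association through electrostatic interactions.

`pcpscore` quantifies this property at residue level. The pipeline is:

1. **Charge assignment.** Each residue gets an integer formal charge at
   pH 7.5: Arg/Lys $+1$, Asp/Glu $-1$, His $0$, all others $0$
   (`charge_scheme()`). Integer charges make patch membership a binary,
   exactly testable predicate. His is the one genuinely ambiguous case
   at this pH; it is exposed as `histidine_mode`
   (`neutral`/`positive`/`fractional`) rather than silently fixed, with
   `neutral` as the default because the His side-chain pKa (~6.0) lies
   well below 7.5. A Henderson–Hasselbalch fractional mode (standard
   side-chain pKa table) is available for charge-density summaries.
   Terminal charges are ignored by default: the scFv is an internal
   fragment of a fusion receptor, not a free peptide.

2. **Solvent accessibility.** Shrake–Rupley quadrature
   (`compute_sasa()`) with a deterministic Fibonacci point lattice:
   default probe 1.4 Å (water) and 960 points per atom, which keeps the
   isolated-sphere error well under 1% and converges to <1% change at
   4000 points. Relative SASA divides by the Tien et al. theoretical
   maximum per residue type; residues at `rel_sasa >= 0.20` are called
   surface. The 0.20 threshold is the common rule-of-thumb boundary in
   the relative-accessibility literature; it is a parameter
   (`classify_surface()`), not a constant, because published patch
   tools do not document their exposure criterion.

3. **Contiguity.** Surface residues are nodes of a contact graph
   (`build_contact_graph()`); an edge joins residues whose minimum
   heavy-atom distance is ≤ 5.0 Å, the standard residue-contact
   convention. Patches are connected components of the subgraph induced
   by same-sign charged surface residues (`find_patches()`), ranked by
   size with ties broken by the smallest (chain, residue number) — the
   ranking is fully deterministic, and identical inputs serialize
   byte-identically.

4. **The score.** The PCP score is the total residue count of the top
   three largest positive patches (`pcp_score()`); with fewer than
   three patches the existing ones are summed, and no patches give 0.
   Concentrating on the largest three captures "few large patches"
   versus "many scattered charges", which is the distinction that
   tracks tonic signaling strength.

### A deliberate divergence: residue-level patches

Electrostatic-surface web tools segment patches on a continuum
potential map, so their patch residue lists can include neutral
residues that merely sit under a positive isosurface. `pcpscore`
instead defines a patch as a connected set of *charged* surface
residues. This residue-graph convention has exact semantics — every
membership decision is a distance comparison and a charge lookup — and
is therefore fully testable against brute-force oracles. The price is
that absolute scores are not numerically interchangeable with
potential-surface patch scores; comparisons should stay within one
convention. This is why the package validates against planted ground
truth and invariants rather than against any external tool's residue
lists.

### Electrostatic maps without a Poisson–Boltzmann solver

For qualitative field maps the package provides a screened-Coulomb
(Debye–Hückel) sampler (`coulomb_potential()`):
$\phi(\mathbf{x}) = \sum_i q_i\, e^{-\kappa r_i} / (\varepsilon r_i)$,
with a uniform dielectric (default $\varepsilon = 80$) and $\kappa$
from ionic strength via $\kappa = \sqrt{I}/3.04$ Å$^{-1}$ (0.127 Å$^{-1}$
at the 0.15 M culture-medium condition). Charges sit at side-chain
charge centers (Arg CZ, Lys NZ, Asp CG, Glu CD, His ND1/NE2 midpoint;
side-chain centroid, then CA, as fallbacks). This is a visualization
aid with closed-form testability — point-charge values, superposition,
monotone screening — and is *never* used in the PCP score. A grid
Poisson–Boltzmann solution with molecular boundary is explicitly out
of scope.

## Mutation scanning

`mutation_scan()` evaluates charge engineering the way framework-region
(FR) variants are designed: each mutation is a residue-type/charge
reassignment at fixed backbone — no remodeling, SASA and contacts are
retained — after which patches and score are recomputed. `direction =
"down"` mirrors neutralising lysines in or near patches of a
high-tonic-signaling CAR; `"up"` mirrors introducing lysines into a
low-tonic-signaling CAR. A user-supplied CDR mask rejects mutations in
antigen-contacting loops, and combinatorial mode applies a named set
jointly (multi-mutation variants, FR replacement). Fixed-backbone
reassignment is exact for the score's own semantics (the score depends
on coordinates only through contacts) but ignores any real structural
relaxation; ΔPCP rankings are design hypotheses, not affinity or
stability predictions.

Useful provable properties, all under test: neutralising a charged
surface residue never increases the score; charging a neutral surface
residue adjacent only to the largest patch increases it by exactly 1;
charging a residue adjacent to two patches merges them into one of size
$s_1 + s_2 + 1$; the score never exceeds the number of positive surface
residues.

## Assay statistics

- **Tonic signaling index** = MFI(CD69)/MFI(GFP): activation-marker
  upregulation normalised by receptor expression, on transduced
  reporter cells without antigen.
- **Exhaustion score** = mean of GFP-normalised MFIs of PD-1, Lag-3 and
  Tim-3.
- Both are ratios of pre-gated summary MFIs and thus invariant to
  instrument gain. Raw FCS event processing (gating, compensation) is
  out of scope: the formulas operate on per-sample MFIs, so the input
  format carries already-summarised values (wide or long tables).
- **Relative normalisation** divides by a designated reference sample
  (e.g. growth in regular medium), mapping the reference to 1.0.
- **Pearson association** uses the product-moment formula with the
  two-tailed $t$-based p-value on $n-2$ df, plus the least-squares line
  — the conventional reporting for index-versus-score panels. All
  p-values in the package are two-tailed.
- **Dose–response** uses the four-parameter logistic
  $y = b + (t - b)/(1 + (\mathrm{EC}_{50}/x)^{h})$, fitted by
  Levenberg–Marquardt least squares (via `minpack.lm`) on
  $\log \mathrm{EC}_{50}$ to enforce positivity. Initialisation:
  $b = \min y$, $t = \max y$, $h = 1$, EC50 at the geometric mean of
  the concentrations plus five log-spaced restarts across the tested
  range; the converged fit with the lowest RSS wins, and the 95% CI
  comes from the asymptotic covariance of $\log \mathrm{EC}_{50}$. The
  parameterisation guarantees the fitted curve at EC50 is exactly the
  half-maximum.

## What the synthetic generator emulates — and what it does not

`generate_shell_structure()` builds pseudo-structures whose ground
truth is exact by construction: single-atom (carbon-sized) residues on
a Fibonacci lattice over a 25 Å sphere (roughly scFv-sized), patches
planted as geodesic caps of lysines around greedily separated anchors,
all other shell residues glycine, and an optional dense interior ball
of glycines that are genuinely solvent-inaccessible. Defaults are
chosen so the pieces are mutually consistent: lattice spacing 4.2 Å
(below the 5 Å contact cutoff, so caps are contiguous; above the 4 Å
floor, so the lattice cannot alias patches together), minimum
inter-patch separation 8 Å (> cutoff, so planted patches can never
merge), and planted sizes (12, 9, 5) spanning the small-patch regime.
Because each pseudo-residue is one sphere, relative SASA is normalised
by the single-sphere area (`max_asa_sphere()`) rather than the
real-residue Tien table — the manifest records this along with every
parameter the fixture was designed for. Infeasible packings (patches
too large for the shell, separations unattainable) are refused with
advice rather than silently degraded.

What it does not emulate: real antibody fold geometry, side-chain
chemistry, backbone burial, or mixed-charge surfaces with negative
patches adjacent to positive ones. Passing the planted-patch checks
therefore demonstrates the correctness of the detection machinery, not
the biological accuracy of any particular scFv's score.

`generate_assay_cohort()` draws latent (patch score, tonic index)
pairs from a bivariate normal with a requested correlation (patch
score: mean 30, sd 10, covering the range observed across clinical
scFvs; tonic index: mean 2.0, sd 0.5), then converts the tonic latent
into positive marker MFIs with multiplicative lognormal noise around a
GFP scale of 1000. With zero noise the assay-derived index reproduces
the latent exactly, giving clean degenerate limits ($r^2 = 1$ at
$\rho = 1$); with noise it behaves like a gain-variable flow
experiment. Exhaustion markers are generated proportional to the tonic
latent, mirroring the empirical coupling of exhaustion to tonic
signaling. All generators run behind a single integer seed and never
consume the caller's RNG stream.

## Numerical choices and degenerate inputs

- Quadrature below 32 points per atom is refused rather than silently
  imprecise.
- Altloc records resolve to the highest occupancy, first-encountered on
  ties; hydrogens, HETATM and waters are dropped; insertion codes are
  preserved in residue keys.
- Multi-chain structures are one molecule (VH/VL may be separate
  chains in homology models); chain file order does not affect results.
- Zero qualifying residues give an empty patch set and score 0, not an
  error; empty structures and non-positive cutoffs are errors.
- Pearson needs $n \ge 3$ and nonzero variance in both variables;
  $|r| = 1$ reports $p = 0$.
- 4PL fitting needs ≥ 5 distinct positive concentrations; orientation
  is canonicalised so `top >= bottom` with the Hill sign flipped
  accordingly.
- Tabular outputs use a fixed column order, tab delimiter, `.` decimal
  separator and `%.6g` float format, written with LF endings — repeated
  runs are byte-identical, including patch ranking under size ties.

## Verification scale

The test suite validates the contact graph and patch partition against
brute-force oracles (an $O(n^2)$ distance scan and a breadth-first
flood fill) on 500 random fixtures of up to ~300 residues, planted
(12, 9, 5) recovery over 50 seeds, and score monotonicity over 1000
random neutralizations and 1000 adjacent charge-ups; statistical
operating characteristics use 1000 replicate cohorts (power and size
of the Pearson test at $n = 10$) and 200 noisy dose–response
simulations. These sizes give stable pass/fail behaviour at
sub-percent Monte-Carlo error while keeping the default run fast.

## Known limitations

- Residue-level patches are not numerically comparable to
  potential-surface patch scores; only orderings within one convention
  are meaningful.
- Fixed-backbone mutation scanning ignores structural relaxation and
  cannot flag stability- or affinity-destroying substitutions.
- The screened-Coulomb map assumes a uniform dielectric and no
  molecular boundary; it is qualitative by design.
- Formal charges ignore pKa shifts from local environment; the
  fractional mode uses model-compound pKa values only.
- Scores are computed on whatever structure is supplied; homology-model
  quality (template choice, linker conformation) propagates directly
  into the score and is outside the package's control.
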