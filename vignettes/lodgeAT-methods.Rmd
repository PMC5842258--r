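---
title: "Models and methods behind lodgeAT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lodgeAT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lodgeAT)
```

`lodgeAT` analyses stem lodging resistance in diversity panels of
*Brassica napus* and related species: it converts three-point bend tests
into stem strength traits, scans transcriptome-derived SNP and expression
markers for associations with those traits under population-structure and
kinship correction, validates candidate markers on independent panels, and
compares FTIR cell-wall spectra between genotypes. This vignette records
the models, the numerical choices, and the reasoning behind the design
decisions, in that order of importance.

## Stem mechanics

A bend test loads a stem section of span `L` (mm) at its midpoint and
records force against probe displacement. Two absolute strength traits are
read from the trace:

* `Fmax` — the maximum recorded force, the stem's absolute resistance to
  breaking;
* `F/V` — the slope of the initial elastic segment, its absolute
  resistance to elastic bending.

The material (geometry-independent) strength traits combine these with the
cross-section's second moment of area. The stem is modelled as an annular
beam: `I = pi (D2^4 - d1a^4) / 64`, where `D2` and `d1a` are the
equivalent-circle diameters `2 sqrt(area / pi)` of the whole-stem and
central-hollow cross-section areas. Diameters are always derived from
measured areas, never measured directly, because image-derived areas are
robust to non-circular sections. Then

* `MOR = Fmax * a * D2 / I` (modulus of rupture), and
* `MOE = (F/V) * (a^2 / 12) * (3L - 4a) / I` (modulus of elasticity),

with the loading point at midspan, `a = L/2`. In that case the MOE formula
reduces algebraically to the classical three-point-bend expression
`(F/V) L^3 / (48 I)`; the package enforces `a = L/2` by default and the
identity is verified to 1e-12 relative tolerance in the test suite.

**Units.** Forces are carried exactly as the instrument records them; no
gravity or probe-speed conversion is applied. Published stem-strength
tables mix force and stress conventions in ways that cannot be reconciled
by any single SI conversion, so the package is deliberately unit-agnostic:
its guarantees are about the formulas, and users who need SI stresses can
convert the inputs. Default spans: `L = 70` mm for the standard rig,
`L = 12` mm for the small-stem (Arabidopsis) rig.

**Elastic-slope window.** `F/V` is obtained by least squares over the
contiguous rising segment of the trace between the first crossings of 10%
and 40% of `Fmax`. The lower bound excludes the toe-in region where the
probe seats against the stem; the upper bound excludes pre-failure
curvature. The segment is selected by its displacement extent (crossing
points), not by testing each sample's force against the band: per-point
selection on a noisy ordinate truncates the residual distribution inside
the band and biases the slope downward by several percent at realistic
noise, while crossing-based selection leaves the fit unbiased. The window
is configurable.

**Peak reading under noise.** `Fmax` is the raw maximum of the trace. On a
trace that rises linearly to a corner, the raw maximum is exact in the
noise-free limit, which is the property the trait definition fixes; under
additive noise of standard deviation `s` it inherits an error on the order
of `s` at the corner (and slightly more with dense sampling, through the
maximum order statistic). Any smoother estimator would trade away the
noise-free exactness, so the package keeps the raw maximum and documents
the consequence: peak-force recovery degrades proportionally to the
instrument noise level, and at noise as large as 5% of `Fmax` the 5%
recovery band can no longer be met for most curves. Bend-test hardware
operates well below that noise level.

## Trait statistics

Accession-level variation is assessed by one-way ANOVA of each trait on
accession (Type-I sums of squares; a single factor, so balanced and
unbalanced designs are handled identically). Residual normality is checked
with a Shapiro–Wilk test at alpha = 0.05; on rejection the ANOVA is
recomputed on log10-transformed values and flagged. The alpha-level test
automates what is usually a visual residual check. When zeros or negative
values are present, a small positive offset (half the smallest positive
value, floored at 1e-6, plus any shift needed to clear negatives) is added
before the log and recorded in the output, since traits such as hollow
area can legitimately be zero.

The trait correlation panel reports pairwise Pearson coefficients over
accession means with pairwise-complete missing-value handling, two-sided
P-values against zero, and significance stars at 0.05/0.01/0.001. Both `r`
and `r^2` are reported explicitly because published trait-correlation
tables are frequently ambiguous about which of the two they print;
labelling both removes the ambiguity at the cost of one extra matrix.

## The association engine

**MAF filter.** Markers with minor allele frequency strictly below the
threshold (default 5%) over non-missing calls are removed; a marker at
exactly the threshold is retained, matching the usual "minor alleles
present at < 5%" phrasing. The filter is idempotent, and markers with all
calls missing are removed and counted separately.

**Kinship.** VanRaden's centred cross-product: genotypes are mean-imputed
per marker, centred at twice the allele frequency, and the cross-product
is scaled by `2 * sum(p(1-p))`. Imputation can introduce slightly negative
eigenvalues; when that happens the matrix is shifted by
`(|min eigenvalue| + 1e-10) I` and the shift recorded, so downstream
factorisations are safe.

**Null model and REML.** For each trait the polygenic null model
`y = Xb + u + e`, `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)` is fitted by REML,
with fixed effects an intercept plus the ancestry matrix Q (the last
ancestry column dropped: Q rows sum to one, so the full matrix is
collinear with the intercept). The variance ratio `delta = se2 / sg2` is
profiled out by the spectral decomposition of K restricted to the
orthogonal complement of X, and the restricted log-likelihood is maximised
in `log(delta)` over [1e-5, 1e5] — an 80-point grid followed by local
refinement, so a shoulder in the profile cannot capture the optimiser. The
test suite checks the optimum against a dense-matrix REML evaluation with
explicit determinants and inverses (1e-6 agreement) on panels where the
optimum is interior. When the trait carries no genetic signal relative to
a structured K, the profile pushes `delta` to the residual-dominated bound
and the fitted genetic variance collapses; with nearly unstructured K the
profile is nearly flat and the estimate is arbitrary — a property of REML,
not of the implementation.

**P3D scan.** `delta` is estimated once per trait and reused for every
marker; each marker's additive 0/1/2 code is appended to the fixed effects
and tested by generalised least squares under `V = sg2 (K + delta I)`,
using the rotation by `(K + delta I)^{-1/2}` and an F-test with
`n - p` residual degrees of freedom. This is the standard
approximation used by mixed-model association software; it makes the scan
a single rotation plus vectorised residual algebra. With `K = I` the
rotation is a scalar and the scan provably reduces to per-marker OLS
F-tests (asserted to 1e-8 in the tests); at `delta -> infinity` GLS
converges to OLS regardless of K. Missing genotypes are mean-imputed per
marker — the same convention as the kinship — and the imputation count is
reported per marker. Monomorphic markers are skipped and flagged. Raw P is
reported alongside Bonferroni and Benjamini–Hochberg columns; no
significance threshold is hard-wired, because thresholds in this field are
study-specific and often retrospective.

**Effect reporting.** Besides the GLS coefficient, each marker gets a
trait-effect percentage: the absolute difference between homozygote-class
means divided by the trait's range across accessions, times 100. This is
the field's convention for communicating effect sizes to breeders.

**GEM scan.** Each unigene's transcript abundance enters a fixed-effect
model `trait ~ intercept + Q + log2(RPKM + 1)` with an F-test on the
expression term; the coefficient's sign and the partial R^2 are reported.
The log2(x+1) transformation stabilises the heavy right tail of RPKM
values; the GEM model corrects for structure through Q only by default,
with kinship whitening available by passing K (the published precedent for
GEM analysis does not state that kinship was included, so Q-only is the
default and the choice is exposed).

**Expression as trait.** Highly associated GEMs are remapped by treating
the unigene's log2(RPKM+1) vector as the trait in a full kinship-corrected
SNP scan. This is literally a composition — the test suite asserts the
result is identical to calling the scan manually — and its scientific role
is to find the loci (cis regulators in the simplest case) controlling the
expression of trait-associated genes.

**Genomic inflation.** Scan calibration is summarised by
`lambda = median(chi2_obs) / median(chi2_null)` over the tested markers.

## Marker validation

Validation panels score one marker on accessions with replicate trait
values. The packaged test collapses replicates to accession means (the
genetically independent unit), excludes heterozygous calls from the
two-class comparison (reporting their count), and runs a Welch t-test by
default; the pooled-variance form is available by flag, since the
published analyses rarely state which was used and Welch is the safer
default under unequal class variances. A companion table cross-tabulates
allele classes against hard subpopulation assignments (argmax of Q) with a
chi-square independence test, no continuity correction — approximately
equal class frequencies across subpopulations are evidence that the
marker-trait association is not a structure artefact.

## FTIR

Spectra are truncated to the fingerprint region 800–1800 cm^-1; the
baseline is anchored by subtracting the absorbance at 1800 cm^-1 as a
constant offset (a single-point anchor, not a sloped two-point baseline —
the simplest reading of "anchored", and the one that leaves band shapes
untouched); and the curve is normalised to unit trapezoidal area over the
window. State flags make preprocessing idempotent. Group comparisons
average preprocessed spectra per group and subtract
(`mean(group_a) - mean(group_b)`, with the convention that group_a is the
wild type); because the published descriptions of such comparisons are
ambiguous about subtraction direction, the convention is recorded in the
result's metadata rather than guessed. Signed difference values are
reported at the marker bands — 1740 cm^-1 (ester carbonyl, high
methylesterification) and 1624 cm^-1 (carboxylate, de-esterified) — and a
band ratio (integral over band ± 8 cm^-1) summarises the esterification
state of a single spectrum. Area normalisation makes the ratio invariant
to global scaling of the raw spectrum.

## The synthetic panel generator

The generator exists so that every downstream stage can be tested against
a known truth; its defaults describe a realistic Associative
Transcriptomics panel.

* **Population structure.** Two ancestral subpopulations (K = 2, the
  structure typically detected in rapeseed panels); per-marker ancestral
  frequencies uniform on [0.1, 0.9]; subpopulation frequencies
  Balding–Nichols, `Beta(p(1-F)/F, (1-p)(1-F)/F)` at `Fst = 0.2` by
  default. Admixture proportions are Dirichlet with weight 10 on the home
  cluster and 0.4 elsewhere — median home ancestry around 0.96 with an
  admixed tail, matching the concentration seen in STRUCTURE plots of
  rapeseed diversity panels.
* **Genotypes.** Near-inbred: one allele draw doubled, with heterozygotes
  at rate 0.05; missing calls injected at 2%. A configurable 10% of
  markers are homoeologous duplicates of earlier markers — copies with 10%
  of calls redrawn — placed on the partner C-genome pseudochromosome, so
  association peaks can appear as paired A/C signals at desk scale without
  simulating whole subgenomes.
* **Expression.** log2 RPKM = gene baseline (uniform 2–8) + cis-marker
  genotype × cis effect + N(0, 0.5), exponentiated. In the noise-free
  limit the log2 difference between homozygote classes is exactly twice
  the cis effect, which the tests assert.
* **Traits.** Accession-mean Fmax = intercept (15, a mid-range value on
  the recorded-force scale of dried stem sections) + planted SNP effects +
  planted mediator effects (trait units per log2-RPKM) + a polygenic term
  drawn from `N(0, sd^2 K_realised)` with the panel's own kinship (default
  sd 1 — this is what makes kinship correction demonstrably necessary) +
  replicate-level environmental noise scaled so the accession-level
  heritability matches the configured value (default 0.7, a realistic
  value for stem strength traits). Companion traits (F/V, diameter, second
  moment, parenchyma, cortex, hollow area, height, weight, SLR) are
  generated around Fmax with fixed realistic correlations; the SLR–Fmax
  correlation is configurable (default 0.65, i.e. the square root of an
  R^2 of about 0.42 reported for field lodging scores against Fmax — the
  literature value is printed as R^2, so the generator plants its square
  root as r). MOR and MOE are computed from the generated mechanics
  quantities rather than drawn, so the trait table is internally
  consistent with the beam equations.
* **Bend curves.** Force rises linearly at the configured slope to Fmax,
  then decays exponentially; sampling step 0.004 mm, i.e. 500 samples/s at
  the standard 2 mm/s probe speed. Replicate curves in written panels get
  noise at 1% of Fmax.
* **Spectra.** 800–4000 cm^-1 on a 2 cm^-1 grid; fixed background bands
  (1050, 1160, 1515, 2925, 3350 cm^-1) plus the two esterification marker
  bands with amplitudes `0.45 * ester_level` at 1740 and
  `0.45 * (1 - ester_level)` at 1624; Gaussian noise per replicate.

**What the generator does not emulate.** Linkage disequilibrium beyond
the planted homoeologue correlation; family/pedigree relatedness beyond
two admixed clusters (K has a single dominant structure axis);
genotype-by-environment interaction and multi-year trial effects;
read-level expression noise; within-accession replicate variance
calibrated to any particular trial (no published variance components
exist to calibrate against, so the defaults are tunable). Consequently,
passing tests demonstrate correctness of the algorithms under a
structured, internally consistent model — not robustness to every
pathology of real field data.

One consequence of the single structure axis deserves emphasis: a
polygenic trait drawn from `N(0, K)` projects onto the population axis
with a chi-square(1) weight, so in roughly a quarter of simulated panels
the trait is effectively uncorrelated with structure and a naive
(no-kinship) scan is legitimately uninflated there. Across many panels
the naive scan's median inflation is far above 1 while the mixed model
stays calibrated — but "naive inflation exceeds a fixed bar in nearly
every panel" is not a property this trait model can deliver, and the
package does not pretend otherwise.

## Problem sizes and seeds

The shipped tests and the acceptance script run entirely on synthetic
panels at desk scale, chosen to make each property measurable in seconds:
60–79 accessions with 800–2000 markers for recovery studies (the 79 × 2000
recovery panels plant a causal effect of 1.0 trait units per allele copy,
which realises a trait-effect of about 25% of the accession range); 150
accessions × 1000 markers × 50 replicate panels for the structure-control
study (the larger panel makes confounding reliably expressed when the
polygenic draw aligns with structure); 5000 markers for null-uniformity
checks; 1000 random sections for the beam identities; 200 curves and 50
spectra-pair seeds for the instrument-level checks. All randomness flows
from explicit seeds, and identical configuration plus seed reproduces
every output byte-for-byte (the provenance header's timestamp aside).

## Known limitations

* The P3D approximation estimates `delta` once per trait; markers with
  very large effects would shift the variance components slightly, which
  exact per-marker REML would capture. This matches standard practice and
  the approximation error is negligible at the effect sizes of interest.
* Mean imputation of missing genotypes is simple and consistent between
  kinship and scan, but underestimates genotype variance at high
  missingness; the per-marker imputation count is reported so users can
  filter.
* The GEM model assumes an approximately linear trait–log-expression
  relationship; strongly nonlinear mediation would be attenuated.
* Hard subpopulation assignment (argmax of Q) in the validation-panel
  frequency table discards partial ancestry; with strongly admixed
  accessions the chi-square test is approximate.
* The unit-agnostic mechanics layer will happily mix units if the caller
  does; it reports exactly what it was given.
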