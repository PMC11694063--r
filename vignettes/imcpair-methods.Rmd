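---
title: "Methods: matched primary-metastasis compositional and spatial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched primary-metastasis compositional and spatial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`imcpair` analyses cohorts in which each patient contributes segmented
single-cell data from a primary breast tumor (PT) and at least one
distant metastasis, acquired on up to three antibody panels (tumor,
T cell, myeloid). This vignette is the package's own account of the
statistical machinery: the models, their assumptions, the tunable
parameters, and the design decisions taken where more than one
reasonable choice existed.

## Data model and quality control

A cohort is three tables: cells (one row per segmented cell, with
centroid coordinates in micrometers, area in pixels, marker intensities
as plain numeric columns, and a phenotype label), images (patient,
tissue site, annotated location, extent), and patients (molecular
subtype). QC removes cells with area below 7 or above 600 pixels
(inclusive retention bounds: `area >= 7 & area <= 600`; the bounds
themselves are kept, reading the exclusion rule as strict
inequalities), then removes images left with fewer than 100 cells. The
filter is idempotent and reports counts removed per panel and step.

Coordinates are continuous micrometers with the origin at the image's
top-left corner; masks are row-major label grids (0 background,
1 tumor, 2 stroma) and a cell is attributed to the pixel containing its
centroid (`floor(coord / pixel_size)`, ties to the lower index). The
signed border distance of a cell is the exact Euclidean distance from
its centroid pixel to the nearest pixel of the opposite compartment,
positive under the tumor mask and negative under stroma. This is a
pixel-level measurement by construction; no sub-pixel boundary
interpolation is attempted, matching how mask-based border distances
are produced by segmentation pipelines.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream test is validated.

The hierarchy is: patient *i* draws a latent phenotype composition
$p_i \sim \mathrm{Dirichlet}(\alpha_0)$; the PT sample draws its
realized composition from $\mathrm{Dirichlet}(\theta\, p_i)$; each
metastatic-site sample draws from
$\mathrm{Dirichlet}(\theta\, q_i)$ with
$q_i \propto p_i \odot \exp(\text{site effect} + \text{planted effect})$.
The concentration $\theta$ (`founder_strength`) is the founder effect:
large $\theta$ makes matched pairs nearly identical, $\theta = 0$ is
implemented as independent redraws of both sites from the base
Dirichlet — the exact no-linkage null for the matched-similarity test.
Site and planted effects act multiplicatively on the Dirichlet mean
(log-linear), mirroring the log link of the differential-abundance
model so that planted effects are recoverable in the model's own
parameterization.

Per image, a negative-binomial cell count is drawn, cells are placed
uniformly, categories are assigned multinomially from the sample
composition (or from niche compositions where a niche specification is
given: cells inside a blob redraw from the blob's composition,
overlaps resolve to the nearest center, background is niche 0), marker
expression is the category signature times log-normal noise, and a
tumor/stroma mask is built as a union of random tumor discs on a
stroma background.

Defaults were chosen once, as the conditions a cohort of this design
would present: 12 patients; 6 PT images per patient spread over the
three annotated locations and 2 intratumoral images per metastatic
site; 500 x 500 um images; a mean of 500 cells per image (real IMC
images of this size hold roughly one to three thousand cells;
500 already estimates a 20-category composition tightly and keeps a
full cohort compact); $\alpha_0 = 1$; $\theta = 50$, which produces a
clearly detectable founder effect with the wide patient-to-patient
spread such cohorts show; mask pixels of 4 um. A single global seed
drives every draw through a counter-based sub-seed stream, so the
order in which modules consume randomness cannot change results.

What the generator does *not* emulate: pixel-level images, spillover,
segmentation errors, spatially varying cell density, marker
correlations beyond the category signatures, or clinical covariates.
Tests passing on synthetic cohorts therefore validate the statistical
machinery (calibration, recovery, invariances), not robustness to
upstream imaging artifacts.

## Phenotyping

Two normalizations are provided: division by the per-marker 99th
percentile (linear-interpolation percentile) with clipping to [0, 1] —
the clipping realizes the outlier containment that motivates this
normalization, though whether the original analyses clipped values
above 1 is not documented — and arcsinh with per-marker z-scoring. The
arcsinh cofactor defaults to 1, the raw-count convention for this
modality, and is configurable.

Three clustering routes produce phenotype labels. The graph route
builds exact k-nearest-neighbor sets, weights edges by the Jaccard
index of neighbor sets, and applies Louvain modularity optimization
(single pass, fixed seed, default resolution). The SOM route trains a
batch self-organizing map (default 10 x 10 grid, a common default for
this family of tools; grid size is configurable) and Ward-D2 clusters
the codebook into the requested number of metaclusters — one
deterministic hierarchical pass rather than a consensus step, since
only the algorithm family is prescribed. The k-means route uses
k-means++ seeding under a fixed seed. All three are deterministic
given a seed and permutation-invariant up to label renaming; labels
are 1-based integers per R convention.

## Compositional analysis

Counts are closed with a pseudocount (default 1, added to counts
before closure, in that order) and transformed by the centered
log-ratio. The Aitchison distance is the Euclidean distance between
CLR vectors; it is a metric on zero-free compositions and invariant to
rescaling any sample by a positive constant. The Manhattan option is
the L1 distance between pseudocounted proportion vectors; note that L1
on proportions equals exactly twice the Bray-Curtis dissimilarity, and
the two scalings are often conflated — both are exposed
(`manhattan_scale = "l1"` default, `"bray"` = L1/2). The Jaccard
option binarizes at a strict 0.5 % presence threshold on raw
proportions.

The matched-similarity test statistic is the median over patients of
the matched-pair distance. The null permutes the patient labels of the
PT table and the metastasis table independently (a shared-permutation
mode exists for sensitivity analysis), re-pairs, and recomputes the
median; with 1,000 iterations the p-value is the plain fraction of
null medians strictly below the observed median. The plain fraction
(rather than the add-one estimator) follows the definition of the
statistic this test reproduces; an optional smoothed estimator is
available but off by default. With a single matched patient every
permutation is the identity and the test degenerates (warning). For
patients with several metastatic sites, sites are pooled into one
metastasis sample by default; immune-panel analyses restrict to
intratumoral images to avoid bias from the unequal location
distribution between PT and metastases.

Diversity is Shannon entropy in nats on positive-count categories (no
pseudocount). Compositional PCA is the SVD of the column-centered CLR
matrix; explained-variance fractions sum to one, and the embedding
preserves Aitchison geometry exactly. Patient grouping is Ward-D2 on
proportion vectors of metastasis samples. Dominant phenotypes break
ties by category axis order (documented, deterministic).

## Differential abundance

For each category, counts $y_{sc}$ are modelled as negative binomial
with $\log \mu_{sc} = \log N_s + x_s^\top \beta_c$, where $N_s$ is the
sample total — so the condition coefficient is a log fold change of
the category's *proportion*. The paired design enters as patient
fixed-effect blocks, accepting many parameters, as in the standard
design-matrix formulation; location or tissue covariates are added
where the sampling design is unbalanced. Dispersion is estimated per
category by Pearson moments from a Poisson fit,
$\hat\phi_c = \sum[(y-\hat\mu)^2 - \hat\mu] / \sum \hat\mu^2$, and
shrunk toward the across-category mean with a prior weight of 10
residual degrees of freedom. The condition effect is tested by a
quasi-likelihood F-test: the deviance difference between full and
reduced fits scaled by the Pearson dispersion of the full fit, against
$F(df_{\text{diff}}, df_{\text{resid}})$; a likelihood-ratio
chi-square option exists. This moment-plus-shrinkage scheme is a
deliberate simplification of empirical-Bayes dispersion moderation;
the package's validation targets are parameter recovery and error-rate
calibration, not coefficient-level equality with any particular
implementation (an independent quasi-likelihood implementation is used
as a cross-check in the test suite and agrees closely).

Categories observed in fewer than 3 samples are not tested (degenerate
fits); all-zero categories are excluded with a warning. BH adjustment
runs across the tested categories; FDR < 0.05 flags significance. A
numerical note: the NB2 score equations are not invariant to jointly
doubling counts and offsets (the IRLS weights $1/(1+\phi\mu)$ are not
scale-free), so exact offset invariance holds on the Poisson path
(`dispersion = "none"`) and approximately — to about the second
decimal of log2 fold change — on the moment path.

One-vs-rest comparisons fit each patient group against all remaining
samples with a tissue covariate, skipping singleton groups; a grouping
without a rest is a design error.

## PERMANOVA and beta dispersion

The pseudo-F statistic is computed from the Gower-centered squared
distance matrix: $SS_{\text{total}} = \sum_{i<j} d_{ij}^2 / n$,
within-group terms analogously per block, and
$F = (SS_B/(g-1)) / (SS_W/(n-g))$. When the number of distinct
labelings is at most 10,000 the null is enumerated exhaustively and
the p-value is the plain fraction including the observed labeling;
otherwise labels are sampled and the add-one convention
$(b+1)/(m+1)$ is used — the convention of the software family this
test belongs to, and distinct from the matched-similarity test, whose
plain-fraction definition is prescribed. Degenerate cases are defined
explicitly: all-identical samples give $F = 0, p = 1$; zero
within-group variation gives $F = +\infty$ with the p-value still
permutation-based. Only single-factor designs are supported, matching
the analyses this package implements (tissue site, subtype); pairwise
post-hoc contrasts can be run by subsetting, with Bonferroni left to
the caller.

Beta dispersion embeds samples by principal coordinates, keeping
negative-eigenvalue axes; squared distances are real-part minus
imaginary-part contributions, clamped at zero. Each group's center is
the spatial (geometric) median, found by Weiszfeld iteration to 1e-8;
per-sample distances to the own-group median are tested by a one-way F
with a label-permutation null. The dispersion test runs before
PERMANOVA in the pipeline and its result is attached to the PERMANOVA
report.

## Spatial analysis

Radius neighborhoods use centroid distance with a 60 um radius
(boundary inclusive); the cell itself is excluded by default so the
neighborhood describes the cell's surroundings, with `include_self`
preserving the alternative. Neighbor-composition vectors are
pseudocounted (CLR of raw neighbor counts needs one; default 1),
closed, CLR-transformed, and clustered by k-means for each k in
2..15. The average silhouette width — computed on one random subsample
(cap 10,000) shared across the sweep so the curve is comparable —
selects k; ties go to the smaller k. Isolated cells have
pseudocount-only neighborhoods (zero CLR vectors) and are assigned
like any other cell. Neighborhood detection is restricted to
intratumoral images in the pipeline, and a single-phenotype input is
an explicit error (the CLR is degenerate).

The interaction/avoidance test statistic is the mean count of type-B
neighbors per type-A cell on the radius graph; the null permutes
phenotype labels with positions fixed, and both one-sided p-values use
the add-one convention, with calls at 0.01. The radius graph stands in
for segmentation-mask touching neighbors, which synthetic data do not
have; this is a documented divergence from mask-based neighbor
definitions.

Tumor-vs-stroma enrichment of a subtype is the smoothed log2 ratio of
its share among tumor-compartment cells to its share among
stroma-compartment cells (pseudocount 1, with the subtype count `S`
entering the denominators), with compartments taken from the sign of
the border distance (zero counts as tumor). The formula is an
implementation definition — flagged as such in output metadata — and
is exactly antisymmetric under compartment swap. Cross-panel
correlations join image-level proportion tables on the physical core
and report Pearson coefficients per PT/metastasis stratum, leaving
zero-variance types unset.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/ingest, QC, clustering,
aggregation, similarity/diversity/PCA/grouping, differential abundance
(paired and one-vs-rest), beta dispersion + PERMANOVA, neighborhoods +
CN differential abundance, spatial analyses, and a report stage. Every
stage writes its own subdirectory only, checks its inputs and names
the missing artifact when invoked out of order, and logs cell/sample
counts after each filter. All randomness derives from the single
config seed via the counter-based stream, so a manifest (seed +
config) fully determines every output file.

Validation problem sizes were chosen to exercise each property at
meaningful resolution: 500 replicate cohorts for permutation-test
calibration (200 permutations each), 100 replicates of 40 paired
samples for differential-abundance recovery and null error rates,
2,000-cell images for clustering and niche recovery, and a 12-patient
three-panel cohort for the end-to-end determinism check.

## Known limitations

- The negative-binomial dispersion treatment is moment-based with a
  fixed prior weight; very small cohorts may under- or over-shrink.
- PERMANOVA is single-factor; stratified/multi-factor designs are out
  of scope.
- The interaction test permutes labels across the whole image, which
  conditions on composition but not on local density gradients.
- CLR handling of zeros relies on pseudocounts throughout; analyses of
  extremely sparse composition tables should interpret small distances
  cautiously.
- The silhouette-based choice of k inherits silhouette's bias toward
  compact, balanced clusters; rare niches may be merged.
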