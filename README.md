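# imcpair

Matched primary-tumor / distant-metastasis single-cell analysis for
imaging mass cytometry (IMC) cohorts.

## The problem

In studies of metastatic breast cancer, consecutive sections of tissue
microarray cores from a patient's primary tumor (PT) and from distant
metastases (bone, brain, liver, soft tissue) are imaged with several
antibody panels, segmented, and reduced to tables of single cells with
marker intensities. The scientific questions are compositional and
spatial: Which phenotypes are present, and in what proportions? Is a
metastasis compositionally more similar to *its own* primary tumor than
to other patients' tumors (a founder effect)? Which cell types shift in
abundance between sites? Do recurrent spatial niches (cellular
neighborhoods) form, and do they differ between PT and metastasis?

`imcpair` implements that full analysis as a tested, reusable pipeline
of tidyverse-style functions (data frames in, tibbles out), plus a
synthetic cohort generator that reproduces the data structure with
known ground truth, so that every statistical component can be
validated end to end.

## What is inside

- **Data model + QC** — cell/image/patient tables with schema and enum
  validation; area-based cell QC (retain 7-600 px) and minimum
  100-cell image QC; signed distance of each cell to the tumor-stroma
  mask border.
- **Phenotyping** — 99th-percentile and asinh/z-score marker
  normalization; shared nearest-neighbor (Jaccard) Louvain clustering,
  self-organizing-map metaclustering (Ward-D2 on the codebook), and
  k-means with k-means++ seeding.
- **Compositional analysis** — counts are closed with a pseudocount and
  mapped by the centered log-ratio (CLR) transform
  `clr(x)_i = log x_i - mean(log x)`. The Aitchison distance between two
  samples is the Euclidean distance of their CLR vectors; Manhattan and
  Jaccard (0.5 % presence) distances are provided alongside Shannon
  diversity, CLR-PCA, dominant-phenotype transition tables and Ward-D2
  patient grouping.
- **Matched-similarity permutation test** — observed statistic: median
  over patients of the matched PT-metastasis distance; null: patient
  labels permuted independently in both tables, 1,000 iterations;
  `p = #(null median < observed) / n_perm`.
- **Differential abundance** — per category a negative-binomial GLM with
  log link and `log(sample total)` offset, patient blocks for the paired
  design (plus location / tissue covariates where appropriate),
  moment-estimated dispersion shrunk toward the common value, a
  quasi-likelihood F-test, and Benjamini-Hochberg FDR across categories.
- **PERMANOVA and beta dispersion** — pseudo-F on Gower-centered
  squared distances with sampled or exhaustive permutation null;
  dispersion as distance to the group's spatial median in
  principal-coordinate space.
- **Spatial analysis** — 60 um radius neighbor graphs; cellular
  neighborhoods by k-means on CLR neighbor compositions with a
  silhouette sweep over k = 2..15; CN differential abundance;
  tumor-vs-stroma enrichment; interaction/avoidance permutation tests;
  cross-panel correlation on shared cores.
- **Pipeline** — `run_pipeline()` orchestrates all stages into a run
  directory with per-stage tables, JSON results, a manifest and a log;
  identical config + seed reproduces every file byte for byte.

## Worked example

```r
library(imcpair)

# a 6-patient matched cohort on the tumor panel with known ground truth
gen <- generate_cohort(synthetic_config(n_patients = 6, panels = "tumor",
                                        founder_strength = 200, seed = 42))
co  <- qc_filter(gen$cohort)$cohort

tab <- aggregate_counts(co$cells, co$images, panel = "tumor")
pt  <- tab[tab$tissue_class == "PT", ]
met <- tab[tab$tissue_class == "metastasis", ]

res <- matched_similarity_test(pt, met, n_perm = 1000, seed = 1)
res
#> <matched_perm_test>
#>   aitchison distance, 6 matched patients
#>   observed median = 3.5185 | null median mean = 8.0289
#>   p = 0 (1000 permutations, independent labels)
```

The matched median Aitchison distance (3.52) is far below the
permutation-null mean (8.03): at `founder_strength = 200` the generator
plants a strong patient-level founder composition, and the test detects
that matched pairs are more similar than random PT/metastasis pairings
(no null median fell below the observed median in 1,000 permutations,
hence p = 0 under the plain-fraction estimator). `autoplot(res)` draws
the null histogram with the observed median marked.

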