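test_that("CLR matches hand computations and sums to zero", {
  expect_equal(clr_transform(matrix(c(1, 1, 1, 1), 1), 1),
               matrix(0, 1, 4), ignore_attr = TRUE)
  # counts (4,1) + pseudocount -> proportions (5/7, 2/7)
  got <- clr_transform(matrix(c(4, 1), 1), 1)
  expect_equal(as.numeric(got), c(log(5 / 2) / 2, -log(5 / 2) / 2),
               tolerance = 1e-9)
  rnd <- withr::with_seed(1, matrix(rpois(60, 20), 6))
  expect_lt(max(abs(rowSums(clr_transform(rnd, 1)))), 1e-9)
  expect_error(clr_transform(matrix(c(0, 0), 1), 0),
               class = "imcpair_domain_error")
})

test_that("aggregation pools images additively and filters locations", {
  gen <- generate_cohort(synthetic_config(n_patients = 3, panels = "tumor",
                                          cells_per_image = 120, seed = 4))
  co <- gen$cohort
  tab <- aggregate_counts(co$cells, co$images, panel = "tumor")
  img <- aggregate_counts(co$cells, co$images, panel = "tumor", level = "image")
  # patient-level counts are sums of the image-level counts
  pooled <- dplyr::summarise(
    dplyr::group_by(dplyr::as_tibble(img), patient_id, tissue_class),
    dplyr::across(dplyr::all_of(categories(img)), sum), .groups = "drop")
  merged <- dplyr::inner_join(dplyr::as_tibble(tab), pooled,
                              by = c("patient_id", "tissue_class"),
                              suffix = c("", ".img"))
  for (ct in categories(tab)) {
    expect_equal(merged[[ct]], merged[[paste0(ct, ".img")]])
  }
  # location filter drops non-intratumoral images entirely
  it <- aggregate_counts(co$cells, co$images, panel = "tumor", level = "image",
                         location_filter = "intratumoral")
  expect_true(all(it$location == "intratumoral"))
  # pooled met sites give a single metastasis row per patient
  expect_equal(sum(tab$tissue_class == "metastasis"), 3)
})

test_that("patients with multiple met sites pool into one sample", {
  gen <- generate_cohort(synthetic_config(n_patients = 2, panels = "tumor",
                                          n_sites_per_patient = 2,
                                          cells_per_image = 100, seed = 6))
  tab <- aggregate_counts(gen$cohort$cells, gen$cohort$images, panel = "tumor",
                          pool_met_sites = TRUE)
  met <- tab[tab$tissue_class == "metastasis", ]
  expect_equal(nrow(met), 2)
  unpooled <- aggregate_counts(gen$cohort$cells, gen$cohort$images,
                               panel = "tumor", pool_met_sites = FALSE)
  expect_gt(nrow(unpooled[unpooled$tissue_class == "metastasis", ]), 2)
  per_site <- colSums(comp_counts(unpooled[unpooled$tissue_class == "metastasis", ]))
  expect_equal(colSums(comp_counts(met)), per_site)
})

test_that("distance methods match hand-computed examples", {
  # identical rows: zero for all three methods
  m <- matrix(c(3, 2, 5), 1, dimnames = list("P1_x", NULL))
  colnames(m) <- c("a", "b", "c")
  ta <- make_comp_table(m); tb <- make_comp_table(m, "metastasis")
  for (meth in c("aitchison", "manhattan", "jaccard")) {
    expect_equal(pairwise_distance(ta, tb, meth)$distance, 0, tolerance = 1e-12)
  }
  # manhattan on disjoint unit proportion vectors = 2 (no pseudocount)
  d <- imcpair:::cross_distance_matrix(matrix(c(1, 0), 1), matrix(c(0, 1), 1),
                                       "manhattan", pseudocount = 0)
  expect_equal(as.numeric(d), 2)
  expect_equal(as.numeric(imcpair:::cross_distance_matrix(
    matrix(c(1, 0), 1), matrix(c(0, 1), 1), "manhattan", pseudocount = 0,
    manhattan_scale = "bray")), 1)
  # jaccard presence threshold is strict at 0.5%
  a <- matrix(c(0.600, 0.004, 0.396), 1)
  b <- matrix(c(0.5, 0.5, 0), 1)
  expect_equal(as.numeric(imcpair:::cross_distance_matrix(a, b, "jaccard")),
               1 - 1 / 3)
  # aitchison on zero-free proportions, no pseudocount
  expect_equal(as.numeric(imcpair:::cross_distance_matrix(
    matrix(c(.8, .2), 1), matrix(c(.2, .8), 1), "aitchison", 0)),
    sqrt(2) * log(4), tolerance = 1e-9)
})

test_that("aitchison is a scale-invariant metric on zero-free compositions", {
  x <- withr::with_seed(3, matrix(rpois(30, 30) + 1, 3))
  d0 <- imcpair:::cross_distance_matrix(x, x, "aitchison", 0)
  for (cc in c(2, 10, 0.5)) {
    xs <- x; xs[1, ] <- xs[1, ] * cc
    ds <- imcpair:::cross_distance_matrix(xs, xs, "aitchison", 0)
    expect_equal(ds, d0, tolerance = 1e-9)
  }
  # metric axioms on random triples
  for (s in 1:20) {
    tr <- withr::with_seed(s, matrix(runif(9, 0.05, 1), 3))
    d <- imcpair:::cross_distance_matrix(tr, tr, "aitchison", 0)
    expect_equal(d, t(d), tolerance = 1e-8)
    expect_lt(max(abs(diag(d))), 1e-6)  # cross-product formula noise
    expect_lte(d[1, 3], d[1, 2] + d[2, 3] + 1e-8)
  }
})

test_that("jaccard distance is bounded with exact 0/1 endpoints", {
  ident <- matrix(c(10, 10, 0, 0), 1)
  disj <- matrix(c(0, 0, 10, 10), 1)
  expect_equal(as.numeric(imcpair:::cross_distance_matrix(ident, ident, "jaccard")), 0)
  expect_equal(as.numeric(imcpair:::cross_distance_matrix(ident, disj, "jaccard")), 1)
  rnd <- withr::with_seed(5, matrix(rpois(40, 5), 4))
  d <- imcpair:::cross_distance_matrix(rnd, rnd, "jaccard")
  expect_true(all(d >= 0 & d <= 1))
})

test_that("matched similarity test handles exact and degenerate cases", {
  # PT == met per patient, distinct across patients -> observed 0, p = 0
  m <- withr::with_seed(9, matrix(rpois(50, 20) + 1, 5,
                                  dimnames = list(paste0("P", 1:5), NULL)))
  colnames(m) <- paste0("c", 1:10)
  r <- matched_similarity_test(make_comp_table(m), make_comp_table(m, "metastasis"),
                               n_perm = 200, seed = 1)
  expect_equal(r$observed_median, 0)
  expect_equal(r$p_value, 0)
  # single patient: all null medians equal the observed, p = 0, warning
  one <- m[1, , drop = FALSE]
  expect_warning(
    r1 <- matched_similarity_test(make_comp_table(one),
                                  make_comp_table(one * 2, "metastasis"),
                                  n_perm = 50, seed = 1),
    regexp = "degenerate")
  expect_true(all(r1$null_medians == r1$observed_median))
  expect_equal(r1$p_value, 0)
  expect_error(matched_similarity_test(make_comp_table(m),
                                       make_comp_table(m, "metastasis"),
                                       n_perm = 0),
               class = "imcpair_parameter_error")
})

test_that("shannon diversity matches closed forms and vegan", {
  expect_equal(shannon_diversity(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon_diversity(c(5, 0, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  m <- withr::with_seed(2, matrix(rpois(40, 10), 4))
  expect_equal(shannon_diversity(m)$shannon,
               as.numeric(vegan::diversity(m, index = "shannon")),
               tolerance = 1e-12)
})

test_that("CLR-PCA variance fractions and 2-sample geometry are exact", {
  m <- withr::with_seed(4, matrix(rpois(50, 30) + 1, 5,
                                  dimnames = list(paste0("P", 1:5), paste0("c", 1:10))))
  p <- pca_clr(m, 1)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-9)
  # duplicated samples project to identical coordinates
  dup <- rbind(m, m[1, , drop = FALSE])
  rownames(dup) <- c(rownames(m), "P1b")
  pd <- pca_clr(dup, 1)
  cc <- as.matrix(pd$coords[, grep("^PC", names(pd$coords))])
  expect_equal(cc[1, ], cc[6, ], tolerance = 1e-9, ignore_attr = TRUE)
  # full-rank embedding preserves pairwise Aitchison distances exactly
  p3 <- pca_clr(m[1:3, ], 1)
  d_pca <- dist(as.matrix(p3$coords[, grep("^PC", names(p3$coords))]))
  d_ait <- dist(clr_transform(m[1:3, ], 1))
  expect_equal(as.numeric(d_pca), as.numeric(d_ait), tolerance = 1e-9)
})

test_that("dominant phenotypes, ties, and transition conservation", {
  m <- matrix(c(5, 3, 4, 4), 2, byrow = TRUE,
              dimnames = list(c("P1_PT", "P2_PT"), c("A", "B")))
  tab <- make_comp_table(m)
  dom <- dominant_phenotype(tab)
  expect_equal(dom$dominant, c("A", "A"))  # tie broken by axis order
  met <- make_comp_table(matrix(c(1, 9, 2, 1), 2, byrow = TRUE,
                                dimnames = list(c("P1_met", "P2_met"), c("A", "B"))),
                         "metastasis")
  met$patient_id <- c("P1", "P2"); tab$patient_id <- c("P1", "P2")
  tr <- dominant_transitions(tab, met)
  expect_equal(sum(tr$n_patients), 2)
})

test_that("patient grouping follows Ward-D2 on proportion vectors", {
  m <- rbind(c(10, 0, 0), c(10, 0, 0), c(0, 0, 10))
  rownames(m) <- paste0("P", 1:3); colnames(m) <- c("a", "b", "c")
  tab <- make_comp_table(m)
  g <- patient_grouping(tab, 2)
  expect_equal(g$group[1], g$group[2])
  expect_false(g$group[1] == g$group[3])
  expect_equal(dplyr::n_distinct(patient_grouping(tab, 1)$group), 1)
  expect_equal(dplyr::n_distinct(patient_grouping(tab, 3)$group), 3)
  expect_error(patient_grouping(tab, 4), class = "imcpair_parameter_error")
})

test_that("cell density arithmetic and scaling", {
  cells <- tibble::tibble(image_id = rep("i1", 250))
  img <- tibble::tibble(image_id = c("i1", "i2"), width_um = 500, height_um = 500)
  d <- cell_density(cells, img)
  expect_equal(d$density_per_mm2, c(1000, 0))
  img2 <- img; img2$width_um <- 1000; img2$height_um <- 1000
  expect_equal(cell_density(cells, img2)$density_per_mm2[1], 250)
})
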