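test_that("radius neighbors: adjacency cases and brute-force equality", {
  two <- tibble::tibble(x_um = c(0, 50), y_um = c(0, 0))
  e <- radius_neighbors(two, 60)
  expect_equal(nrow(e), 2)  # mutual
  far <- tibble::tibble(x_um = c(0, 70), y_um = c(0, 0))
  expect_equal(nrow(radius_neighbors(far, 60)), 0)

  cells <- withr::with_seed(13, tibble::tibble(x_um = runif(500, 0, 400),
                                               y_um = runif(500, 0, 400)))
  e <- radius_neighbors(cells, 60)
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  brute <- which(d <= 60 & d > 0, arr.ind = TRUE)
  expect_equal(nrow(e), nrow(brute))
  expect_setequal(paste(e$from, e$to), paste(brute[, 1], brute[, 2]))
  # symmetric edge list
  expect_setequal(paste(e$from, e$to), paste(e$to, e$from))
})

test_that("CN detection recovers planted niche count and labels", {
  for (k in 2:4) {
    img <- niche_image(k, n_cells = 1500, seed = k)
    m <- cn_detect(img, cn_params(seed = 5, silhouette_subsample = 1200))
    expect_equal(m$chosen_k, k)
    expect_gte(adjusted_rand(m$labels, img$true_niche), 0.8)
  }
})

test_that("CN detection is deterministic and rejects degenerate input", {
  img <- niche_image(2, n_cells = 600, seed = 9)
  p <- cn_params(seed = 3, k_range = 2:6, silhouette_subsample = 500)
  m1 <- cn_detect(img, p); m2 <- cn_detect(img, p)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$chosen_k, m2$chosen_k)
  mono <- img; mono$phenotype <- "c1"
  expect_error(cn_detect(mono, p), class = "imcpair_domain_error")
})

test_that("isolated cells get zero CLR neighborhoods but valid labels", {
  img <- niche_image(2, n_cells = 400, seed = 4)
  iso <- tibble::tibble(x_um = c(-1e6, 1e6) + 1e6 + 500, y_um = c(0, 0),
                        phenotype = c("c1", "c2"), image_id = "img1",
                        true_niche = 0L, true_category = c("c1", "c2"))
  # two far-away cells with no neighbors inside the radius
  aug <- dplyr::bind_rows(img, iso)
  m <- cn_detect(aug, cn_params(seed = 2, k_range = 2:4,
                                silhouette_subsample = 300))
  expect_equal(length(m$labels), nrow(aug))
  expect_false(anyNA(m$labels))
})

test_that("CN differential abundance flags a metastasis-only neighborhood", {
  # build a two-image-per-sample cohort where a second niche exists only
  # in metastasis images
  build <- function(pid, site, with_niche, seed) {
    sz <- 400
    spec <- list(list(composition = c(0.9, 0.05, 0.05), radius_um = 1000,
                      centers = matrix(c(sz / 2, sz / 2), 1)))
    if (with_niche) {
      spec[[2]] <- list(composition = c(0.05, 0.9, 0.05), radius_um = 120,
                        centers = matrix(c(100, 100), 1))
    }
    cells <- withr::with_seed(seed, tibble::tibble(x_um = runif(700, 0, sz),
                                                   y_um = runif(700, 0, sz)))
    out <- plant_niches(cells, c(1, 1, 1) / 3, paste0("c", 1:3), spec, sz,
                        seed = seed + 1)
    out$phenotype <- out$true_category
    out$image_id <- paste0(pid, "_", site)
    out$cell_id <- paste0(out$image_id, "_", seq_len(nrow(out)))
    out$panel <- "tumor"; out$area_px <- 50L
    out
  }
  pats <- paste0("P", 1:6)
  cells <- dplyr::bind_rows(
    purrr::imap(pats, function(p, i) build(p, "PT", FALSE, i * 10)),
    purrr::imap(pats, function(p, i) build(p, "bone", TRUE, i * 10 + 5)))
  images <- tibble::tibble(
    image_id = unique(cells$image_id),
    core_id = unique(cells$image_id),
    patient_id = sub("_.*", "", unique(cells$image_id)),
    tissue_site = ifelse(grepl("PT", unique(cells$image_id)), "PT", "bone"),
    location = "intratumoral", width_um = 400, height_um = 400)
  model <- cn_detect(cells, cn_params(seed = 6, k_range = 2:4,
                                      silhouette_subsample = 2000))
  res <- cn_differential_abundance(
    cells, model, images,
    da_design(contrast = "metastasis"), min_present = 3)
  expect_true(any(res$significant & res$log2fc > 0))
})

test_that("mask enrichment arithmetic, symmetry and antisymmetry", {
  # equal proportions in both compartments: enrichment ~ 0
  n <- 2000
  cells <- tibble::tibble(
    phenotype = rep(c("a", "b"), n / 2),
    border_distance_um = rep(c(5, -5), each = n / 2))
  enr <- mask_enrichment(cells)
  expect_lt(max(abs(enr$log2_enrichment)), 0.01)
  # worked example: subtype only in tumor (100/1000 vs 0/1000, S = 10)
  cells2 <- tibble::tibble(
    phenotype = c(rep("s", 100), rep(paste0("t", 1:9), length.out = 900),
                  rep(paste0("t", 1:9), length.out = 1000)),
    border_distance_um = c(rep(1, 1000), rep(-1, 1000)))
  e2 <- mask_enrichment(cells2)
  expect_equal(e2$log2_enrichment[e2$phenotype == "s"],
               log2((101 / 1010) / (1 / 1010)), tolerance = 1e-12)
  # swapping compartments negates every enrichment
  flipped <- cells2; flipped$border_distance_um <- -flipped$border_distance_um
  e3 <- mask_enrichment(flipped)
  expect_equal(e2$log2_enrichment, -e3$log2_enrichment, tolerance = 1e-12)
  expect_error(mask_enrichment(dplyr::mutate(cells, border_distance_um = 5)),
               class = "imcpair_domain_error")
})

test_that("interaction test calls co-placed types and stays calibrated", {
  # co-placed blobs of A and B in a background of C
  withr::with_seed(4, {
    n <- 600
    blob <- sample(1:3, n, replace = TRUE)
    cx <- c(100, 400, 250)[blob] + rnorm(n, 0, 15)
    cy <- c(100, 400, 100)[blob] + rnorm(n, 0, 15)
    ph <- ifelse(blob < 3, sample(c("A", "B"), n, replace = TRUE), "C")
  })
  ic <- tibble::tibble(x_um = pmin(pmax(cx, 0), 500),
                       y_um = pmin(pmax(cy, 0), 500), phenotype = ph)
  r <- interaction_test(ic, "A", "B", 60, n_perm = 200, seed = 1)
  expect_equal(r$call, "interaction")
  # null calibration: labels exchangeable
  ps <- vapply(1:100, function(s) {
    cells <- withr::with_seed(s, tibble::tibble(
      x_um = runif(200, 0, 300), y_um = runif(200, 0, 300),
      phenotype = sample(c("A", "B", "C"), 200, replace = TRUE)))
    interaction_test(cells, "A", "B", 60, n_perm = 100, seed = s + 7)$p_interaction
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # absent type: explicit no-call
  nc <- interaction_test(tibble::tibble(x_um = 1, y_um = 1, phenotype = "A"),
                         "A", "B", 60, n_perm = 100)
  expect_equal(nc$call, "no-call")
  # degenerate null: all cells isolated
  iso <- tibble::tibble(x_um = c(0, 1000, 2000, 3000), y_um = 0,
                        phenotype = c("A", "B", "A", "B"))
  rd <- interaction_test(iso, "A", "B", 60, n_perm = 100, seed = 1)
  expect_equal(rd$observed, 0)
  expect_equal(rd$p_avoidance, 1)
})

test_that("cross-panel correlation finds duplicated types and handles degenerate input", {
  withr::with_seed(31, {
    n_img <- 60
    base <- matrix(rpois(n_img * 3, 50), n_img)
  })
  mk_tab <- function(m, pn, extra) {
    counts <- cbind(m, extra)
    colnames(counts) <- paste0(pn, c("_t1", "_t2", "_t3", "_x"))
    df <- tibble::as_tibble(counts)
    df$sample_id <- paste0("img", seq_len(n_img), "_", pn)
    df$image_id <- df$sample_id
    df$core_id <- paste0("core", seq_len(n_img))
    df$patient_id <- "P1"
    df$tissue_class <- rep(c("PT", "metastasis"), each = n_img / 2)
    df$tissue_site <- "PT"; df$location <- "intratumoral"
    imcpair:::new_composition_table(df, colnames(counts))
  }
  # panel B duplicates panel A's counts, so proportions match exactly
  extra1 <- withr::with_seed(32, matrix(rpois(n_img, 30), n_img))
  ta <- mk_tab(base, "pa", extra1)
  tb <- mk_tab(base, "pb", extra1)
  corr <- cross_panel_correlation(list(pa = ta, pb = tb))
  dup <- corr[corr$type_a == "pa:pa_t1" & corr$type_b == "pb:pb_t1", ]
  expect_true(all(dup$r > 0.99))
  expect_setequal(unique(corr$stratum), c("PT", "metastasis"))
})

test_that("matched marker correlation hits the exact endpoints", {
  mk <- paste0("m", 1:6)
  mkcells <- function(pid, site, vals) {
    df <- tibble::tibble(cell_id = paste0(pid, site, 1:2),
                         image_id = paste0(pid, "_", site),
                         panel = "tumor", x_um = 1, y_um = 1, area_px = 10L)
    for (i in seq_along(mk)) df[[mk[i]]] <- vals[i]
    df
  }
  v <- c(1, 3, 2, 5, 4, 6)
  cells <- dplyr::bind_rows(
    mkcells("P1", "PT", v), mkcells("P1", "bone", v),          # identical: r = 1
    mkcells("P2", "PT", v), mkcells("P2", "bone", mean(v) - (v - mean(v))))
  images <- tibble::tibble(image_id = unique(cells$image_id),
                           core_id = unique(cells$image_id),
                           patient_id = rep(c("P1", "P2"), each = 2),
                           tissue_site = rep(c("PT", "bone"), 2),
                           location = "intratumoral",
                           width_um = 10, height_um = 10)
  r <- matched_marker_correlation(cells, images)
  expect_equal(r$r[r$patient_id == "P1"], 1)
  expect_equal(r$r[r$patient_id == "P2"], -1)
})

test_that("matched marker correlation rises as signature noise falls", {
  med_r <- vapply(c(1.2, 0.6, 0.2), function(noise) {
    gen <- generate_cohort(synthetic_config(
      n_patients = 6, panels = "tumor", cells_per_image = 120,
      images_per_pt = 2, marker_noise_sd = noise, seed = 17))
    median(matched_marker_correlation(gen$cohort$cells, gen$cohort$images)$r)
  }, numeric(1))
  expect_true(all(diff(med_r) > 0))
})
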