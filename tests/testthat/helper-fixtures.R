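# Shared fixture builders; everything is generated in code.

# wrap a patient x category count matrix as a composition table
make_comp_table <- function(m, tissue_class = "PT") {
  df <- tibble::as_tibble(m)
  df$sample_id <- rownames(m) %||% paste0("S", seq_len(nrow(m)))
  df$patient_id <- sub("_.*", "", df$sample_id)
  df$tissue_class <- tissue_class
  df$tissue_site <- if (tissue_class == "PT") "PT" else "bone"
  imcpair:::new_composition_table(df, colnames(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-image cohort for QC worked examples
toy_qc_cohort <- function() {
  mk <- function(image_id, areas) {
    tibble::tibble(
      cell_id = paste0(image_id, "_c", seq_along(areas)),
      image_id = image_id, panel = "tumor",
      x_um = seq_along(areas) %% 100, y_um = seq_along(areas) %% 100,
      area_px = areas, m1 = 1, phenotype = "ph1")
  }
  cells <- dplyr::bind_rows(mk("img1", rep(50L, 120)),
                            mk("img2", c(rep(5L, 60), rep(50L, 90))))
  images <- tibble::tibble(
    image_id = c("img1", "img2"), core_id = c("core1", "core2"),
    patient_id = "P1", tissue_site = c("PT", "PT"),
    location = "intratumoral", width_um = 100, height_um = 100)
  patients <- tibble::tibble(patient_id = "P1", molecular_subtype = "LumA")
  cohort(cells, images, patients)
}

# well-separated gaussian marker signatures for clustering recovery
gaussian_signature_data <- function(n_classes = 5, n_per_class = 400,
                                    n_markers = 10, sep = 8, seed = 42) {
  withr::with_seed(seed, {
    mu <- matrix(0, n_classes, n_markers)
    for (i in seq_len(n_classes)) mu[i, ((i - 1) %% n_markers) + 1] <- sep
    truth <- rep(seq_len(n_classes), each = n_per_class)
    x <- mu[truth, ] + matrix(rnorm(n_classes * n_per_class * n_markers),
                              n_classes * n_per_class)
    list(x = x, truth = truth)
  })
}

# one image with k planted one-hot Voronoi niches at fixed centers
niche_image <- function(k, n_cells = 2000, n_cat = 5, size = 500, seed = 1) {
  ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 7
  centers <- cbind(size / 2 + size * 0.3 * cos(ang),
                   size / 2 + size * 0.3 * sin(ang))
  spec <- lapply(seq_len(k), function(i) {
    p <- rep(0.02, n_cat); p[i] <- 1 - 0.02 * (n_cat - 1)
    list(composition = p / sum(p), radius_um = 2 * size,
         centers = centers[i, , drop = FALSE])
  })
  cells <- withr::with_seed(seed + 100,
                            tibble::tibble(x_um = runif(n_cells, 0, size),
                                           y_um = runif(n_cells, 0, size)))
  out <- plant_niches(cells, rep(1 / n_cat, n_cat), paste0("c", seq_len(n_cat)),
                      spec, size, seed = seed)
  out$phenotype <- out$true_category
  out$image_id <- "img1"
  out
}

# brute-force signed border distance oracle (nearest opposite-class pixel)
brute_border_distance <- function(cells, mask, px) {
  tum <- which(mask == 1L, arr.ind = TRUE)
  str <- which(mask == 2L, arr.ind = TRUE)
  vapply(seq_len(nrow(cells)), function(i) {
    col <- min(max(floor(cells$x_um[i] / px), 0), ncol(mask) - 1) + 1
    row <- min(max(floor(cells$y_um[i] / px), 0), nrow(mask) - 1) + 1
    lab <- mask[row, col]
    if (lab == 0L) return(NA_real_)
    opp <- if (lab == 1L) str else tum
    d <- sqrt(min((opp[, 1] - row)^2 + (opp[, 2] - col)^2))
    if (lab == 1L) d * px else -d * px
  }, numeric(1))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
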