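#' Radius neighbor graph of one image
#'
#' All pairs of cells whose centroid Euclidean distance is at most
#' `radius_um`; self-pairs excluded, symmetric.
#'
#' @param cells Cell table of a single image (`x_um`, `y_um`).
#' @param radius_um Neighborhood radius in micrometers (default 60).
#' @return Tibble edge list `from`, `to` (row indices into `cells`,
#'   both directions present) and `distance_um`.
#' @export
radius_neighbors <- function(cells, radius_um = 60) {
  assert_that(radius_um > 0, "radius_um must be > 0",
              class = "imcpair_validation_error")
  n <- nrow(cells)
  if (n < 2) return(tibble(from = integer(0), to = integer(0),
                           distance_um = numeric(0)))
  xy <- cbind(cells$x_um, cells$y_um)
  # grid binning keeps the candidate set local for large images
  cell_sz <- radius_um
  bx <- floor(xy[, 1] / cell_sz); by <- floor(xy[, 2] / cell_sz)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  from <- integer(0); to <- integer(0); dd <- numeric(0)
  for (b in names(buckets)) {
    ij <- as.integer(strsplit(b, " ")[[1]])
    cand <- unlist(buckets[paste(rep(ij[1] + (-1:1), each = 3),
                                 rep(ij[2] + (-1:1), times = 3))],
                   use.names = FALSE)
    rows <- buckets[[b]]
    d2 <- outer(rowSums(xy[rows, , drop = FALSE]^2),
                rowSums(xy[cand, , drop = FALSE]^2), `+`) -
      2 * tcrossprod(xy[rows, , drop = FALSE], xy[cand, , drop = FALSE])
    hit <- which(d2 <= radius_um^2 + 1e-9, arr.ind = TRUE)
    fi <- rows[hit[, 1]]; ti <- cand[hit[, 2]]
    keep <- fi != ti
    from <- c(from, fi[keep]); to <- c(to, ti[keep])
    dd <- c(dd, sqrt(pmax(d2[hit][keep], 0)))
  }
  ord <- order(from, to)
  tibble(from = from[ord], to = to[ord], distance_um = dd[ord])
}

# Per-cell neighbor composition count matrix (cells x categories).
neighborhood_counts <- function(cells, radius_um, categories,
                                include_self = FALSE) {
  n <- nrow(cells)
  y <- matrix(0L, n, length(categories),
              dimnames = list(NULL, categories))
  edges <- radius_neighbors(cells, radius_um)
  lab <- match(as.character(cells$phenotype), categories)
  if (nrow(edges) > 0) {
    tab <- table(factor(edges$from, levels = seq_len(n)),
                 factor(categories[lab[edges$to]], levels = categories))
    y <- y + as.integer(tab)
    dim(y) <- c(n, length(categories)); colnames(y) <- categories
  }
  if (include_self) y[cbind(seq_len(n), lab)] <- y[cbind(seq_len(n), lab)] + 1L
  y
}

#' Cellular-neighborhood parameters
#'
#' @param radius_um Neighborhood radius (default 60 um).
#' @param include_self Count the cell itself in its neighborhood.
#' @param clr_pseudocount Pseudocount before the CLR of neighbor counts.
#' @param k_range Candidate k values for the k-means sweep (default 2:15).
#' @param silhouette_subsample Maximum points used for silhouette
#'   evaluation (one shared subsample across the sweep).
#' @param seed RNG seed.
#' @return A list of class `cn_params`.
#' @export
cn_params <- function(radius_um = 60, include_self = FALSE,
                      clr_pseudocount = 1, k_range = 2:15,
                      silhouette_subsample = 10000L, seed = 1L) {
  assert_that(radius_um > 0, "radius_um must be > 0",
              class = "imcpair_validation_error")
  assert_that(length(k_range) > 0 && min(k_range) >= 2,
              "k_range must be non-empty with minimum >= 2",
              class = "imcpair_validation_error")
  structure(list(radius_um = radius_um, include_self = include_self,
                 clr_pseudocount = clr_pseudocount, k_range = sort(k_range),
                 silhouette_subsample = silhouette_subsample, seed = seed),
            class = "cn_params")
}

#' Detect cellular neighborhoods
#'
#' For every cell, the counts of each phenotype within its radius
#' neighborhood are collected (per image), pseudocounted, closed to
#' proportions and CLR-transformed; k-means is run for each k of the
#' sweep and the k maximizing the average silhouette width (computed on
#' one shared random subsample) is chosen. Isolated cells have a
#' pseudocount-only neighborhood, i.e. a zero CLR vector, and are
#' assigned to the nearest center like any other cell.
#'
#' @param cells Cell table with `phenotype` and `image_id` (may span
#'   many images; neighborhoods never cross image boundaries).
#' @param params A [cn_params()].
#' @return A `cn_model`: `chosen_k`, `centers`, `silhouette` tibble
#'   (`k`, `avg_width`), `labels` (per cell, 1-based), `categories`.
#' @export
cn_detect <- function(cells, params = cn_params()) {
  cells <- as_tibble(cells)
  cats <- sort(unique(as.character(cells$phenotype)))
  assert_that(length(cats) >= 2,
              "all cells share one phenotype; neighborhood composition is degenerate - skip CN analysis",
              class = "imcpair_domain_error")
  counts <- do.call(rbind, lapply(split(seq_len(nrow(cells)), cells$image_id),
                                  function(ix) {
                                    cbind(ix = ix,
                                          neighborhood_counts(cells[ix, ], params$radius_um,
                                                              cats, params$include_self))
                                  }))
  counts <- counts[order(counts[, "ix"]), , drop = FALSE]
  y <- counts[, cats, drop = FALSE]
  z <- clr_transform(y, params$clr_pseudocount)
  n <- nrow(z)
  sub <- with_seed(derive_seed(params$seed, "silhouette"),
                   sort(sample.int(n, min(n, params$silhouette_subsample))))
  dsub <- dist(z[sub, , drop = FALSE])
  sweep_tbl <- purrr::map(params$k_range, function(k) {
    lab <- kmeans_cluster(z, k, seed = derive_seed(params$seed, "kmeans", k))
    sl <- cluster::silhouette(lab[sub], dsub)
    avg <- if (is.matrix(sl)) mean(sl[, "sil_width"]) else NA_real_
    list(k = k, avg_width = avg, labels = lab)
  })
  sil <- tibble(k = vapply(sweep_tbl, `[[`, numeric(1), "k"),
                avg_width = vapply(sweep_tbl, `[[`, numeric(1), "avg_width"))
  best <- which.max(sil$avg_width)  # first maximum: ties go to smaller k
  labels <- sweep_tbl[[best]]$labels
  centers <- do.call(rbind, lapply(sort(unique(labels)), function(l)
    colMeans(z[labels == l, , drop = FALSE])))
  rownames(centers) <- paste0("CN", sort(unique(labels)))
  structure(list(chosen_k = sil$k[best], centers = centers,
                 silhouette = sil, labels = labels, categories = cats,
                 params = params),
            class = "cn_model")
}

#' @export
print.cn_model <- function(x, ...) {
  cat("<cn_model>\n")
  cat(sprintf("  chosen k = %d (avg silhouette %.3f) over k in [%d, %d]\n",
              x$chosen_k, max(x$silhouette$avg_width),
              min(x$silhouette$k), max(x$silhouette$k)))
  invisible(x)
}

#' Differential abundance of cellular neighborhoods
#'
#' Counts each cell's CN label per sample and delegates to [fit_da()]
#' with the paired PT/metastasis design.
#'
#' @param cells Cell table (same rows the model was fitted on).
#' @param model A `cn_model`.
#' @param images Image table.
#' @param design A [da_design()] (default: tissue class with patient blocks).
#' @param ... Passed to [fit_da()].
#' @return A `da_result` over CN labels.
#' @export
cn_differential_abundance <- function(cells, model, images,
                                      design = da_design(), ...) {
  cells <- as_tibble(cells)
  cells$phenotype <- paste0("CN", model$labels)
  tab <- aggregate_counts(cells, images, level = "patient")
  fit_da(tab, design = design, ...)
}

#' Tumor-versus-stroma enrichment of cell subtypes
#'
#' Smoothed log2 ratio of a subtype's share among tumor-compartment cells
#' to its share among stroma-compartment cells, pooled across the cohort:
#' `log2(((n_st + eps) / (n_t + eps * S)) / ((n_ss + eps) / (n_s + eps * S)))`
#' with `eps = 1` and `S` the number of subtypes. Compartments come from
#' the sign of `border_distance_um` (> 0 or 0 = tumor, < 0 = stroma);
#' cells with unset distance are excluded.
#'
#' @param cells Cell table with `border_distance_um` and `phenotype`.
#' @param eps Smoothing pseudocount (default 1).
#' @return Tibble `phenotype`, `n_tumor`, `n_stroma`, `log2_enrichment`.
#' @export
mask_enrichment <- function(cells, eps = 1) {
  cells <- filter(as_tibble(cells), !is.na(.data$border_distance_um))
  compartment <- ifelse(cells$border_distance_um >= 0, "tumor", "stroma")
  assert_that(any(compartment == "stroma") && any(compartment == "tumor"),
              "need cells in both tumor and stroma compartments",
              class = "imcpair_domain_error")
  subtypes <- sort(unique(as.character(cells$phenotype)))
  s <- length(subtypes)
  tab <- table(factor(cells$phenotype, levels = subtypes), compartment)
  n_t <- sum(tab[, "tumor"]); n_s <- sum(tab[, "stroma"])
  tibble(
    phenotype = subtypes,
    n_tumor = as.integer(tab[, "tumor"]),
    n_stroma = as.integer(tab[, "stroma"]),
    log2_enrichment = as.numeric(
      log2(((tab[, "tumor"] + eps) / (n_t + eps * s)) /
             ((tab[, "stroma"] + eps) / (n_s + eps * s))))
  )
}

#' Neighborhood interaction / avoidance test
#'
#' Statistic: mean number of type-B neighbors per type-A cell on the
#' radius graph of one image. The null keeps every cell in place and
#' permutes the phenotype labels across the image's cells;
#' `p_interaction = (#{null >= obs} + 1) / (n_perm + 1)` and
#' `p_avoidance` analogously with `<=`. A call is made at
#' `threshold` (default 0.01).
#'
#' @param cells Cell table of one image with `phenotype`.
#' @param type_a,type_b Phenotype labels (ordered pair: B around A).
#' @param radius_um Radius graph scale (default 60).
#' @param n_perm Number of label permutations (>= 100).
#' @param seed RNG seed.
#' @param threshold Call threshold on the p-values.
#' @return An `interaction_result`: `observed`, `null_mean`, `null_sd`,
#'   `p_interaction`, `p_avoidance`, `call`.
#' @export
interaction_test <- function(cells, type_a, type_b, radius_um = 60,
                             n_perm = 1000L, seed = 1L, threshold = 0.01) {
  assert_that(n_perm >= 100, "n_perm must be >= 100",
              class = "imcpair_parameter_error")
  cells <- as_tibble(cells)
  lab <- as.character(cells$phenotype)
  if (!type_a %in% lab || !type_b %in% lab) {
    return(structure(list(observed = NA_real_, null_mean = NA_real_,
                          null_sd = NA_real_, p_interaction = NA_real_,
                          p_avoidance = NA_real_, call = "no-call",
                          reason = "type absent from image"),
                     class = "interaction_result"))
  }
  edges <- radius_neighbors(cells, radius_um)
  stat <- function(l) {
    na <- sum(l == type_a)
    if (nrow(edges) == 0) return(0)
    sum(l[edges$from] == type_a & l[edges$to] == type_b) / na
  }
  obs <- stat(lab)
  null <- with_seed(seed, vapply(seq_len(n_perm),
                                 function(i) stat(sample(lab)), numeric(1)))
  p_int <- (sum(null >= obs - 1e-12) + 1) / (n_perm + 1)
  p_avd <- (sum(null <= obs + 1e-12) + 1) / (n_perm + 1)
  call <- if (p_int <= threshold) "interaction"
          else if (p_avd <= threshold) "avoidance" else "none"
  structure(list(observed = obs, null_mean = mean(null), null_sd = sd(null),
                 p_interaction = p_int, p_avoidance = p_avd, call = call,
                 n_perm = n_perm, seed = seed,
                 type_a = type_a, type_b = type_b),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  cat("<interaction_result>\n")
  if (x$call == "no-call") {
    cat("  no-call:", x$reason, "\n"); return(invisible(x))
  }
  cat(sprintf("  mean %s neighbors per %s cell = %.3f (null %.3f +/- %.3f)\n",
              x$type_b, x$type_a, x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  p_interaction = %.4g | p_avoidance = %.4g | call: %s\n",
              x$p_interaction, x$p_avoidance, x$call))
  invisible(x)
}

#' Cross-panel correlation of cell-type proportions
#'
#' Joins the per-image composition tables of the antibody panels on the
#' physical core (consecutive sections of one core share `core_id`),
#' keeps cores present in every panel, and computes Pearson correlations
#' between all pairs of cell-type proportion vectors across images,
#' stratified by tissue class (PT vs metastasis).
#'
#' @param tables Named list of image-level `composition_table`s, one per
#'   panel (from `aggregate_counts(..., level = "image")`).
#' @return Tibble `stratum`, `type_a`, `type_b`, `r`, `n_images`; types
#'   with zero variance get `NA` correlations. Strata with fewer than 3
#'   joined cores are skipped with a warning.
#' @export
cross_panel_correlation <- function(tables) {
  props <- purrr::imap(tables, function(tab, pn) {
    m <- comp_counts(tab)
    p <- m / rowSums(m)
    colnames(p) <- paste0(pn, ":", colnames(p))
    bind_cols(tab[c("core_id", "tissue_class")], as_tibble(p))
  })
  joined <- purrr::reduce(purrr::map(props, function(p)
    p |> select(-"tissue_class") |> dplyr::distinct(.data$core_id, .keep_all = TRUE)),
    ~ inner_join(.x, .y, by = "core_id"))
  strata <- props[[1]] |> dplyr::distinct(.data$core_id, .data$tissue_class)
  joined <- inner_join(joined, strata, by = "core_id")
  out <- list()
  for (st in unique(joined$tissue_class)) {
    sub <- filter(joined, .data$tissue_class == st)
    if (nrow(sub) < 3) {
      warn(sprintf("stratum %s has < 3 joined images; skipped", st))
      next
    }
    mat <- as.matrix(sub[setdiff(names(sub), c("core_id", "tissue_class"))])
    cm <- suppressWarnings(cor(mat))  # zero-variance columns -> NA
    pairs <- which(upper.tri(cm), arr.ind = TRUE)
    out[[st]] <- tibble(stratum = st,
                        type_a = rownames(cm)[pairs[, 1]],
                        type_b = colnames(cm)[pairs[, 2]],
                        r = cm[pairs], n_images = nrow(sub))
  }
  bind_rows(out)
}

#' Matched-pair marker correlation of tumor cells
#'
#' Per patient: the mean marker vector of PT tumor cells against that of
#' metastasis tumor cells, summarized as the Pearson correlation across
#' markers.
#'
#' @param cells Tumor-panel cell table.
#' @param images Image table.
#' @param markers Marker columns (default: all marker columns).
#' @return Tibble `patient_id`, `r` (`NA` when either vector is constant).
#' @export
matched_marker_correlation <- function(cells, images, markers = NULL) {
  cells <- as_tibble(cells)
  markers <- markers %||% marker_cols(cells)
  markers <- markers[colSums(!is.na(cells[markers])) == nrow(cells)]
  assert_that(length(markers) >= 3, "need >= 3 complete marker columns",
              class = "imcpair_validation_error")
  df <- cells |>
    left_join(select(images, "image_id", "patient_id", "tissue_site"),
              by = "image_id") |>
    mutate(tissue_class = ifelse(.data$tissue_site == "PT", "PT", "met"))
  means <- df |>
    group_by(.data$patient_id, .data$tissue_class) |>
    summarise(dplyr::across(dplyr::all_of(markers), mean), .groups = "drop")
  pts <- means |> count(.data$patient_id) |> filter(.data$n == 2) |>
    dplyr::pull("patient_id")
  purrr::map(pts, function(p) {
    a <- as.numeric(means[means$patient_id == p & means$tissue_class == "PT", markers])
    b <- as.numeric(means[means$patient_id == p & means$tissue_class == "met", markers])
    r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
    tibble(patient_id = p, r = r)
  }) |> bind_rows()
}
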