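#' Aggregate phenotype counts into a composition table
#'
#' Builds the sample x category count table used by every compositional
#' analysis. At `level = "patient"` a patient's PT images form one sample
#' and (by default) all of a patient's metastatic images are pooled into
#' one metastasis sample; with `pool_met_sites = FALSE` each metastatic
#' site is its own sample. At `level = "image"` every image is a sample.
#' Tumor-cell analyses use all locations; immune analyses pass
#' `location_filter = "intratumoral"` to avoid bias from the unequal
#' location distribution between PT and metastases.
#'
#' @param cells Cell table with `phenotype` labels.
#' @param images Image table (supplies patient, site, location).
#' @param panel Restrict to one antibody panel (or `NULL` for all cells).
#' @param level `"patient"` or `"image"`.
#' @param location_filter Locations to keep, or `NULL` for all.
#' @param pool_met_sites Pool a patient's metastatic sites into one sample.
#' @return A `composition_table`: tibble with metadata columns
#'   `sample_id`, `patient_id`, `tissue_class` (`"PT"`/`"metastasis"`),
#'   `tissue_site` (site, or `"pooled"`), for image level also `image_id`,
#'   `core_id` and `location`, plus one integer count column per category
#'   (attribute `"categories"`). Patients with zero qualifying images are
#'   omitted with a warning.
#' @export
aggregate_counts <- function(cells, images, panel = NULL,
                             level = c("patient", "image"),
                             location_filter = NULL,
                             pool_met_sites = TRUE) {
  level <- match.arg(level)
  cells <- as_tibble(cells)
  assert_that("phenotype" %in% names(cells) && !all(is.na(cells$phenotype)),
              "cells must carry phenotype labels",
              class = "imcpair_validation_error")
  if (!is.null(panel)) cells <- filter(cells, .data$panel == !!panel)
  meta_cols <- c("image_id", "core_id", "patient_id", "tissue_site", "location")
  df <- cells |>
    left_join(select(images, dplyr::all_of(meta_cols)), by = "image_id")
  if (!is.null(location_filter)) {
    df <- filter(df, .data$location %in% location_filter)
  }
  all_pat <- unique(cells |>
                      left_join(select(images, "image_id", "patient_id"),
                                by = "image_id") |>
                      dplyr::pull("patient_id"))
  df <- df |>
    mutate(tissue_class = ifelse(.data$tissue_site == "PT", "PT", "metastasis"))
  cats <- sort(unique(as.character(df$phenotype)))

  if (level == "image") {
    df$sample_id <- df$image_id
    grp <- df |> dplyr::distinct(.data$sample_id, .data$image_id, .data$core_id,
                                 .data$patient_id, .data$tissue_class,
                                 .data$tissue_site, .data$location)
  } else {
    df$sample_id <- ifelse(
      df$tissue_class == "PT", paste0(df$patient_id, "_PT"),
      if (pool_met_sites) paste0(df$patient_id, "_met")
      else paste0(df$patient_id, "_", df$tissue_site))
    grp <- df |>
      group_by(.data$sample_id, .data$patient_id, .data$tissue_class) |>
      summarise(tissue_site = if (dplyr::n_distinct(.data$tissue_site) == 1)
        .data$tissue_site[1] else "pooled", .groups = "drop")
  }
  counts <- df |>
    count(.data$sample_id, .data$phenotype) |>
    tidyr::pivot_wider(names_from = "phenotype", values_from = "n",
                       values_fill = 0L)
  for (ct in setdiff(cats, names(counts))) counts[[ct]] <- 0L
  out <- grp |> inner_join(counts, by = "sample_id") |>
    select(dplyr::all_of(c(setdiff(names(grp), cats), cats)))
  lost <- setdiff(all_pat, out$patient_id)
  if (length(lost) > 0) {
    warn(sprintf("patient(s) with zero qualifying images omitted: %s",
                 paste(lost, collapse = ", ")))
  }
  new_composition_table(out, cats)
}

new_composition_table <- function(df, categories) {
  structure(as_tibble(df), categories = categories,
            class = c("composition_table", class(as_tibble(df))))
}

#' Category names / count matrix of a composition table
#' @param x A `composition_table`.
#' @return `categories()`: character vector; `comp_counts()`: integer
#'   matrix with `sample_id` rownames.
#' @export
categories <- function(x) attr(x, "categories")

#' @rdname categories
#' @export
comp_counts <- function(x) {
  m <- as.matrix(x[categories(x)])
  rownames(m) <- x$sample_id
  m
}

# Preserve class/attributes through dplyr verbs used internally.
#' @export
`[.composition_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(categories(x) %in% names(out))) {
    new_composition_table(out, attr(x, "categories"))
  } else out
}

#' Centered log-ratio transform
#'
#' Adds a pseudocount to every count, converts each row to proportions,
#' and maps x to `log(x) - mean(log(x))`. Every output row sums to zero.
#'
#' @param counts Non-negative matrix (samples x categories) or a
#'   `composition_table`.
#' @param pseudocount Added to every count before closing (default 1).
#' @return Numeric matrix of CLR coordinates.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  m <- if (inherits(counts, "composition_table")) comp_counts(counts) else as.matrix(counts)
  assert_that(all(m >= 0), "counts must be non-negative",
              class = "imcpair_validation_error")
  assert_that(pseudocount >= 0, "pseudocount must be >= 0",
              class = "imcpair_validation_error")
  m <- m + pseudocount
  assert_that(all(rowSums(m) > 0),
              "all-zero row with pseudocount 0: CLR undefined",
              class = "imcpair_domain_error")
  assert_that(all(m > 0),
              "zero counts with pseudocount 0: CLR undefined",
              class = "imcpair_domain_error")
  p <- m / rowSums(m)
  lp <- log(p)
  sweep(lp, 1, rowMeans(lp), `-`)
}

close_props <- function(m, pseudocount) {
  m <- m + pseudocount
  m / rowSums(m)
}

# Cross-distance matrix between the rows of two count matrices.
cross_distance_matrix <- function(a, b, method = c("aitchison", "manhattan", "jaccard"),
                                  pseudocount = 1, presence_threshold = 0.005,
                                  manhattan_scale = c("l1", "bray")) {
  method <- match.arg(method)
  manhattan_scale <- match.arg(manhattan_scale)
  if (method == "aitchison") {
    ca <- clr_transform(a, pseudocount); cb <- clr_transform(b, pseudocount)
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
    sqrt(pmax(d2, 0))
  } else if (method == "manhattan") {
    pa <- close_props(as.matrix(a), pseudocount)
    pb <- close_props(as.matrix(b), pseudocount)
    d <- apply(pb, 1, function(r) rowSums(abs(sweep(pa, 2, r, `-`))))
    d <- matrix(d, nrow = nrow(pa))
    if (manhattan_scale == "bray") d / 2 else d
  } else {
    pa <- close_props(as.matrix(a), 0) > presence_threshold
    pb <- close_props(as.matrix(b), 0) > presence_threshold
    inter <- tcrossprod(pa * 1, pb * 1)
    uni <- outer(rowSums(pa), rowSums(pb), `+`) - inter
    d <- 1 - inter / uni
    d[uni == 0] <- 0  # two empty presence sets: identical
    d
  }
}

#' Pairwise compositional distances between matched samples
#'
#' Pairs the samples of two composition tables by `patient_id` and
#' returns one distance per pair. `"aitchison"` is Euclidean distance on
#' CLR-transformed counts; `"manhattan"` is the L1 distance between
#' pseudocounted proportion vectors (`manhattan_scale = "bray"` halves it
#' to the Bray-Curtis scale); `"jaccard"` is one minus the Jaccard index
#' of the presence sets, where a category is present when its raw
#' proportion strictly exceeds `presence_threshold` (default 0.5%).
#'
#' @param table_a,table_b `composition_table`s sharing the category axis
#'   (e.g. PT and metastasis samples).
#' @param method `"aitchison"`, `"manhattan"` or `"jaccard"`.
#' @param pseudocount Added to counts for CLR / proportions (default 1).
#' @param presence_threshold Strict presence cutoff for Jaccard.
#' @param manhattan_scale `"l1"` (default) or `"bray"` (L1 / 2).
#' @return Tibble `patient_id`, `distance`. Patients without a partner in
#'   both tables are excluded and reported via a warning.
#' @export
pairwise_distance <- function(table_a, table_b, method = "aitchison",
                              pseudocount = 1, presence_threshold = 0.005,
                              manhattan_scale = "l1") {
  assert_that(identical(categories(table_a), categories(table_b)),
              "tables must share an identical category axis",
              class = "imcpair_validation_error")
  common <- intersect(table_a$patient_id, table_b$patient_id)
  lost <- setdiff(union(table_a$patient_id, table_b$patient_id), common)
  if (length(lost) > 0) {
    warn(sprintf("unmatched patient(s) excluded: %s", paste(lost, collapse = ", ")))
  }
  a <- comp_counts(table_a)[match(common, table_a$patient_id), , drop = FALSE]
  b <- comp_counts(table_b)[match(common, table_b$patient_id), , drop = FALSE]
  d <- cross_distance_matrix(a, b, method, pseudocount, presence_threshold,
                             manhattan_scale)
  tibble(patient_id = common, distance = d[cbind(seq_along(common), seq_along(common))])
}

#' Matched-pair compositional similarity permutation test
#'
#' Tests whether matched PT/metastasis pairs are compositionally more
#' similar than random pairings. The observed statistic is the median
#' over patients of the matched-pair distance. For each permutation the
#' patient labels of the two tables are permuted independently
#' (`permutation = "shared"` applies one common permutation instead), the
#' pairing is re-formed, and the median recomputed. The p-value is the
#' plain fraction of null medians strictly below the observed median
#' (`smoothed = TRUE` uses (b + 1) / (n + 1) instead).
#'
#' @param pt_table,met_table `composition_table`s paired by `patient_id`.
#' @inheritParams pairwise_distance
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @param permutation `"independent"` (default) or `"shared"`.
#' @param smoothed Use the add-one p-value estimator (default `FALSE`).
#' @return `matched_perm_test` object: per-patient distances, observed
#'   median, null medians, `p_value`, `n_perm`, `seed`.
#' @export
matched_similarity_test <- function(pt_table, met_table, method = "aitchison",
                                    pseudocount = 1, presence_threshold = 0.005,
                                    manhattan_scale = "l1",
                                    n_perm = 1000L, seed = 1L,
                                    permutation = c("independent", "shared"),
                                    smoothed = FALSE) {
  permutation <- match.arg(permutation)
  assert_that(n_perm >= 1, "n_perm must be >= 1",
              class = "imcpair_parameter_error")
  common <- intersect(pt_table$patient_id, met_table$patient_id)
  n <- length(common)
  assert_that(n >= 1, "no matched patients", class = "imcpair_validation_error")
  if (n < 3) warn(sprintf("only %d matched patient(s): permutation null is degenerate", n))
  a <- comp_counts(pt_table)[match(common, pt_table$patient_id), , drop = FALSE]
  b <- comp_counts(met_table)[match(common, met_table$patient_id), , drop = FALSE]
  D <- cross_distance_matrix(a, b, method, pseudocount, presence_threshold,
                             manhattan_scale)
  per_patient <- D[cbind(seq_len(n), seq_len(n))]
  observed <- median(per_patient)
  null_medians <- with_seed(seed, vapply(seq_len(n_perm), function(it) {
    p1 <- sample.int(n)
    p2 <- if (permutation == "independent") sample.int(n) else p1
    median(D[cbind(p1, p2)])
  }, numeric(1)))
  b_lt <- sum(null_medians < observed)
  p <- if (smoothed) (b_lt + 1) / (n_perm + 1) else b_lt / n_perm
  structure(list(
    per_patient = tibble(patient_id = common, distance = per_patient),
    observed_median = observed, null_medians = null_medians,
    p_value = p, n_perm = n_perm, seed = seed, method = method,
    permutation = permutation, smoothed = smoothed
  ), class = "matched_perm_test")
}

#' @export
print.matched_perm_test <- function(x, ...) {
  cat("<matched_perm_test>\n")
  cat(sprintf("  %s distance, %d matched patients\n", x$method, nrow(x$per_patient)))
  cat(sprintf("  observed median = %.4f | null median mean = %.4f\n",
              x$observed_median, mean(x$null_medians)))
  cat(sprintf("  p = %.4g (%d permutations, %s labels)\n",
              x$p_value, x$n_perm, x$permutation))
  invisible(x)
}

#' Shannon diversity of compositions
#'
#' Shannon entropy H = -sum p_i log p_i in nats over the categories with
#' positive count (no pseudocount).
#'
#' @param x A `composition_table`, count matrix, or single count vector.
#' @return Tibble `sample_id`, `shannon` (or a single number for a vector).
#' @export
shannon_diversity <- function(x) {
  if (is.null(dim(x)) && !is.data.frame(x)) {
    assert_that(sum(x) > 0, "row sum must be > 0", class = "imcpair_validation_error")
    p <- x[x > 0] / sum(x)
    return(-sum(p * log(p)))
  }
  m <- if (inherits(x, "composition_table")) comp_counts(x) else as.matrix(x)
  assert_that(all(rowSums(m) > 0), "row sums must be > 0",
              class = "imcpair_validation_error")
  h <- apply(m, 1, function(r) { p <- r[r > 0] / sum(r); -sum(p * log(p)) })
  tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))), shannon = h)
}

#' Principal component analysis of CLR-transformed compositions
#'
#' Singular value decomposition of the column-centered CLR matrix;
#' sample coordinates and explained-variance fractions (summing to 1).
#'
#' @param x `composition_table` or count matrix (>= 3 samples).
#' @param pseudocount Passed to [clr_transform()].
#' @return `clr_pca` object: `coords` tibble (`sample_id`, `PC1`, ...),
#'   `var_explained`, plus the sample metadata columns of `x` when
#'   available.
#' @export
pca_clr <- function(x, pseudocount = 1) {
  m <- if (inherits(x, "composition_table")) comp_counts(x) else as.matrix(x)
  assert_that(nrow(m) >= 3, "need at least 3 samples",
              class = "imcpair_validation_error")
  cl <- clr_transform(m, pseudocount)
  cc <- sweep(cl, 2, colMeans(cl), `-`)
  sv <- svd(cc)
  keep <- sv$d > sv$d[1] * 1e-12
  if (!any(keep)) {  # rank 0: all samples identical
    coords <- matrix(0, nrow(m), 1, dimnames = list(rownames(m), "PC1"))
    ve <- 1
  } else {
    coords <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    rownames(coords) <- rownames(m)
    ve <- sv$d[keep]^2 / sum(sv$d[keep]^2)
  }
  meta <- if (inherits(x, "composition_table")) {
    x[setdiff(names(x), categories(x))]
  } else tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m))))
  structure(list(coords = bind_cols(as_tibble(meta), as_tibble(coords)),
                 var_explained = ve, loadings = if (any(keep)) sv$v[, keep, drop = FALSE] else NULL),
            class = "clr_pca")
}

#' @export
print.clr_pca <- function(x, ...) {
  cat("<clr_pca>\n")
  cat(sprintf("  %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$coords), length(x$var_explained),
              100 * x$var_explained[1],
              if (length(x$var_explained) > 1) 100 * x$var_explained[2] else 0))
  invisible(x)
}

#' Dominant phenotype per sample and PT-to-metastasis transitions
#'
#' `dominant_phenotype()` returns each sample's most abundant category
#' (ties broken by category axis order). `dominant_transitions()`
#' cross-tabulates the dominant PT vs metastasis category over matched
#' patients; row sums equal patient counts.
#'
#' @param x,pt_table,met_table `composition_table`s.
#' @return Tibble `sample_id`, `patient_id` (if present), `dominant`;
#'   transitions: tibble `pt_dominant`, `met_dominant`, `n_patients`.
#' @export
dominant_phenotype <- function(x) {
  m <- comp_counts(x)
  assert_that(all(rowSums(m) > 0), "row sums must be > 0",
              class = "imcpair_validation_error")
  dom <- categories(x)[apply(m[, categories(x), drop = FALSE], 1, which.max)]
  out <- tibble(sample_id = x$sample_id, dominant = dom)
  if ("patient_id" %in% names(x)) out <- bind_cols(out["sample_id"],
                                                   x["patient_id"], out["dominant"])
  out
}

#' @rdname dominant_phenotype
#' @export
dominant_transitions <- function(pt_table, met_table) {
  a <- dominant_phenotype(pt_table); b <- dominant_phenotype(met_table)
  inner_join(select(a, "patient_id", pt_dominant = "dominant"),
             select(b, "patient_id", met_dominant = "dominant"),
             by = "patient_id") |>
    count(.data$pt_dominant, .data$met_dominant, name = "n_patients")
}

#' Hierarchical patient grouping on metastasis composition
#'
#' Agglomerative clustering (Ward-D2 linkage, Euclidean distance) of the
#' per-patient phenotype proportion vectors, cut into `n_groups`.
#'
#' @param x `composition_table` of metastasis samples (one per patient).
#' @param n_groups Number of groups (<= number of patients).
#' @return Tibble `patient_id`, `group` (integer), plus the `hclust` tree
#'   as attribute `"tree"`.
#' @export
patient_grouping <- function(x, n_groups) {
  m <- comp_counts(x)
  assert_that(n_groups <= nrow(m), "n_groups must be <= number of patients",
              class = "imcpair_parameter_error")
  props <- m / rowSums(m)
  hc <- hclust(dist(props), method = "ward.D2")
  grp <- cutree(hc, k = n_groups)
  structure(tibble(patient_id = x$patient_id, group = as.integer(grp)),
            tree = hc)
}

#' Cell density per image
#'
#' Cells per square millimeter: `count / (width_um * height_um / 1e6)`.
#'
#' @param cells Cell table.
#' @param images Image table with extents.
#' @return Tibble `image_id`, `n_cells`, `density_per_mm2` (images with
#'   no cells get density 0).
#' @export
cell_density <- function(cells, images) {
  assert_that(all(images$width_um > 0) && all(images$height_um > 0),
              "zero-area image", class = "imcpair_validation_error")
  images |>
    select("image_id", "width_um", "height_um") |>
    left_join(count(cells, .data$image_id, name = "n_cells"), by = "image_id") |>
    mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L),
           density_per_mm2 = .data$n_cells / (.data$width_um * .data$height_um / 1e6)) |>
    select("image_id", "n_cells", "density_per_mm2")
}
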