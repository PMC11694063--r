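#' Marker normalization
#'
#' `normalize_percentile99()` range-normalizes each marker by its 99th
#' percentile across cells (linear-interpolation percentile), clipping to
#' \[0, 1\] to contain outliers; a marker whose 99th percentile is 0 maps
#' to all zeros. `transform_asinh_scale()` applies
#' `arcsinh(x / cofactor)` followed by a per-marker z-score; constant
#' markers map to all zeros.
#'
#' @param x Numeric matrix, cells x markers, values >= 0.
#' @param cofactor Positive arcsinh cofactor (default 1, the raw-count
#'   convention for this modality).
#' @return Numeric matrix of the same shape.
#' @export
normalize_percentile99 <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need at least 2 cells",
              class = "imcpair_validation_error")
  assert_that(all(x >= 0), "expression values must be >= 0",
              class = "imcpair_validation_error")
  q <- apply(x, 2, quantile, probs = 0.99, names = FALSE)  # type 7: linear interp
  out <- sweep(x, 2, ifelse(q > 0, q, 1), `/`)
  out[, q == 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' @rdname normalize_percentile99
#' @export
transform_asinh_scale <- function(x, cofactor = 1) {
  assert_that(cofactor > 0, "cofactor must be > 0",
              class = "imcpair_validation_error")
  x <- asinh(as.matrix(x) / cofactor)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  out <- sweep(sweep(x, 2, mu, `-`), 2, ifelse(s > 0, s, 1), `/`)
  out[, s == 0] <- 0
  out
}

# Exact k-nearest neighbours by chunked pairwise distances.
knn_index <- function(x, k) {
  n <- nrow(x)
  idx <- matrix(0L, n, k)
  chunk <- max(1L, floor(2e7 / n))
  sq <- rowSums(x^2)
  for (s in seq(1L, n, by = chunk)) {
    rows <- s:min(s + chunk - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) - 2 * tcrossprod(x[rows, , drop = FALSE], x)
    d2[cbind(seq_along(rows), rows)] <- Inf  # exclude self
    idx[rows, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  idx
}

#' Shared nearest-neighbor graph clustering (Louvain)
#'
#' Phenograph-style clustering: build the k-nearest-neighbor sets of each
#' cell (Euclidean), connect two cells by an edge weighted with the
#' Jaccard index of their neighbor sets (zero-weight pairs dropped), and
#' partition the weighted graph by Louvain modularity optimization.
#' Deterministic for a given seed.
#'
#' @param x Numeric matrix, cells x markers (normalized).
#' @param k_neighbors Neighborhood size (>= 1); must be < `nrow(x)`.
#' @param seed RNG seed for the Louvain pass.
#' @return Integer cluster labels (1-based), length `nrow(x)`.
#' @export
snn_louvain <- function(x, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  assert_that(k_neighbors >= 1, "k_neighbors must be >= 1",
              class = "imcpair_parameter_error")
  assert_that(n > k_neighbors,
              "need more rows than k_neighbors to build a neighbor graph",
              class = "imcpair_parameter_error")
  if (all(x == rep(x[1, ], each = n))) return(rep(1L, n))  # no structure
  nn <- knn_index(x, k_neighbors)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)            # |S_i  intersect  S_j|
  inter <- methods::as(inter, "TsparseMatrix")
  keep <- inter@i < inter@j & inter@x > 0
  i <- inter@i[keep] + 1L; j <- inter@j[keep] + 1L
  w <- inter@x[keep] / (2 * k_neighbors - inter@x[keep])  # Jaccard
  g <- igraph::graph_from_data_frame(
    data.frame(from = i, to = j, weight = w), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  memb <- with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  as.integer(memb[as.character(seq_len(n))])
}

# Batch self-organizing map. Deterministic: codebook initialized from a
# seeded sample of rows, Gaussian neighborhood shrinking linearly.
som_fit <- function(x, grid = c(10L, 10L), rlen = 15L, seed = 1L) {
  n_units <- prod(grid)
  gx <- rep(seq_len(grid[2]), each = grid[1])
  gy <- rep(seq_len(grid[1]), times = grid[2])
  grid_d2 <- outer(gx, gx, `-`)^2 + outer(gy, gy, `-`)^2
  code <- with_seed(seed, x[sample(nrow(x), n_units, replace = nrow(x) < n_units), , drop = FALSE])
  radii <- seq(max(grid) / 2, 0.5, length.out = rlen)
  sqx <- rowSums(x^2)
  for (it in seq_len(rlen)) {
    d2 <- outer(sqx, rowSums(code^2), `+`) - 2 * tcrossprod(x, code)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-grid_d2 / (2 * radii[it]^2))     # unit x unit neighborhood
    w <- h[bmu, , drop = FALSE]                # cell x unit weights
    denom <- colSums(w)
    upd <- crossprod(w, x) / ifelse(denom > 0, denom, 1)
    code[denom > 0, ] <- upd[denom > 0, ]
  }
  d2 <- outer(sqx, rowSums(code^2), `+`) - 2 * tcrossprod(x, code)
  list(codebook = code, bmu = max.col(-d2, ties.method = "first"))
}

#' Self-organizing-map metaclustering
#'
#' Trains a batch self-organizing map on the expression matrix, then
#' hierarchically clusters the codebook vectors (Ward-D2 linkage,
#' Euclidean) into `n_meta` metaclusters; each cell inherits the
#' metacluster of its best-matching unit. Deterministic for a given seed.
#'
#' @param x Numeric matrix, cells x markers (transformed).
#' @param som_grid SOM grid (rows, cols); default 10 x 10.
#' @param n_meta Number of metaclusters (<= number of grid units).
#' @param rlen Training epochs.
#' @param seed RNG seed.
#' @return Integer metacluster labels (1-based).
#' @export
som_metacluster <- function(x, som_grid = c(10L, 10L), n_meta = 20L,
                            rlen = 15L, seed = 1L) {
  x <- as.matrix(x)
  assert_that(n_meta >= 1 && n_meta <= prod(som_grid),
              "n_meta must be between 1 and the SOM grid size",
              class = "imcpair_parameter_error")
  assert_that(nrow(x) >= prod(som_grid),
              "need at least as many cells as SOM grid units",
              class = "imcpair_parameter_error")
  fit <- som_fit(x, grid = som_grid, rlen = rlen, seed = seed)
  hc <- hclust(dist(fit$codebook), method = "ward.D2")
  meta <- cutree(hc, k = n_meta)
  as.integer(meta[fit$bmu])
}

#' K-means phenotype clustering
#'
#' Standard k-means with k-means++ seeding of the initial centers (drawn
#' under `seed`), refined by `stats::kmeans` (Lloyd default engine,
#' `iter.max = 100`).
#'
#' @param x Numeric matrix, cells x markers.
#' @param k Number of clusters (<= `nrow(x)`).
#' @param seed RNG seed.
#' @param n_restart Seeded restarts; the lowest-inertia solution is kept.
#' @return Integer cluster labels (1-based).
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_restart = 5L) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= k, "need at least k rows",
              class = "imcpair_parameter_error")
  if (k == nrow(x)) return(seq_len(k))  # every point its own cluster
  best <- NULL
  for (r in seq_len(n_restart)) {
    centers <- with_seed(derive_seed(seed, "kmeanspp", r), kmeanspp_centers(x, k))
    km <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  as.integer(best$cluster)
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  ids <- integer(k)
  ids[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[ids[1], ], `-`)^2)
  for (i in seq_len(k - 1L)) {
    if (sum(d2) > 0) {
      ids[i + 1L] <- sample.int(n, 1, prob = d2 / sum(d2))
    } else {  # all remaining mass covered: pick an unchosen point
      ids[i + 1L] <- setdiff(seq_len(n), ids[seq_len(i)])[1]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[ids[i + 1L], ], `-`)^2))
  }
  x[ids, , drop = FALSE] + matrix(rnorm(k * ncol(x), 0, 1e-10), k)  # break exact ties
}

#' Per-cluster expression profiles
#'
#' Mean (or median) expression per cluster and marker, with cluster
#' sizes; the table that supports manual annotation of clusters.
#'
#' @param x Numeric matrix, cells x markers.
#' @param labels Cluster labels aligned with rows of `x`.
#' @param stat `"mean"` or `"median"`.
#' @return Tibble: `cluster`, `n_cells`, one column per marker.
#' @export
cluster_profiles <- function(x, labels, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  x <- as.matrix(x)
  assert_that(length(labels) == nrow(x), "labels must align with rows of x",
              class = "imcpair_validation_error")
  f <- if (stat == "mean") mean else median
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  df <- as_tibble(x)
  df$cluster <- labels
  df |>
    group_by(.data$cluster) |>
    summarise(n_cells = n(),
              dplyr::across(dplyr::all_of(colnames(x)), f),
              .groups = "drop") |>
    arrange(.data$cluster)
}
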