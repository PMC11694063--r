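as_dist_matrix <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  assert_that(nrow(m) == ncol(m) && max(abs(m - t(m))) < 1e-8 &&
                all(abs(diag(m)) < 1e-12),
              "need a square symmetric distance matrix with zero diagonal",
              class = "imcpair_validation_error")
  m
}

# sums of squares decomposition of a distance matrix under a grouping
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)  # = trace of the Gower-centered matrix
  ss_within <- 0
  for (g in unique(groups)) {
    sel <- groups == g
    ss_within <- ss_within + sum(d2[sel, sel]) / (2 * sum(sel))
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(d2, groups, n_groups, n) {
  ss <- permanova_ss(d2, groups)
  ss_between <- ss[["total"]] - ss[["within"]]
  if (ss[["total"]] <= 1e-12) return(c(0, 0))
  if (ss[["within"]] <= 1e-12) return(c(Inf, 1))
  c((ss_between / (n_groups - 1)) / (ss[["within"]] / (n - n_groups)),
    ss_between / ss[["total"]])
}

# all distinct assignments of a multiset of group labels (lexicographic)
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  uniq <- sort(unique(labels))
  counts <- table(factor(labels, levels = uniq))
  out <- list()
  rec <- function(remaining, acc) {
    if (sum(remaining) == 0) { out[[length(out) + 1L]] <<- acc; return(invisible()) }
    for (u in uniq) {
      if (remaining[[u]] > 0) {
        r2 <- remaining; r2[[u]] <- r2[[u]] - 1L
        rec(r2, c(acc, u))
      }
    }
  }
  rec(setNames(as.integer(counts), uniq), character(0))
  out
}

n_distinct_labelings <- function(groups) {
  tab <- table(groups)
  exp(lgamma(length(groups) + 1) - sum(lgamma(tab + 1)))
}

#' Permutational multivariate analysis of variance
#'
#' Tests whether group centroids in the space implied by a distance
#' matrix differ, via the pseudo-F statistic on the Gower-centered
#' squared distances. The p-value is obtained by permuting group labels:
#' sampled permutations with the add-one convention
#' `p = (#{F* >= F} + 1) / (n_perm + 1)`, or, when the number of distinct
#' labelings is at most `exact_limit`, by exhaustive enumeration
#' (`p = #{F* >= F} / total`, the observed labeling included).
#'
#' Degenerate inputs: all samples identical gives F = 0, p = 1; zero
#' within-group variation gives F = +Inf (p still from permutation).
#'
#' @param d Distance matrix (`dist` or square symmetric matrix).
#' @param groups Group labels (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of sampled permutations (999 for tumor-cell
#'   analyses, 9999 for immune analyses in the pipeline defaults).
#' @param seed RNG seed.
#' @param exact_limit Enumerate exhaustively when the distinct labelings
#'   are at most this many (default 10000); `0` disables.
#' @return A `permanova_result`: `pseudo_f`, `r_squared`, `p_value`,
#'   `n_perm` (or `n_labelings`), `exact`, `group_sizes`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = 1L,
                      exact_limit = 10000L) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  assert_that(length(groups) == n, "groups must align with the distance matrix",
              class = "imcpair_validation_error")
  sizes <- table(groups)
  assert_that(length(sizes) >= 2 && all(sizes >= 2),
              "need >= 2 groups with >= 2 samples each",
              class = "imcpair_validation_error")
  g <- length(sizes)
  d2 <- m^2
  obs <- permanova_f(d2, groups, g, n)
  exact <- exact_limit > 0 && n_distinct_labelings(groups) <= exact_limit
  if (exact) {
    perms <- multiset_permutations(groups)
    fs <- vapply(perms, function(lab) permanova_f(d2, lab, g, n)[1], numeric(1))
    p <- sum(fs >= obs[1] - 1e-12) / length(fs)
    n_eff <- length(fs)
  } else {
    fs <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      permanova_f(d2, sample(groups), g, n)[1], numeric(1)))
    p <- (sum(fs >= obs[1] - 1e-12) + 1) / (n_perm + 1)
    n_eff <- n_perm
  }
  structure(list(pseudo_f = obs[1], r_squared = obs[2], p_value = p,
                 exact = exact, n_perm = n_eff,
                 group_sizes = as.list(sizes), seed = seed,
                 null_f = fs),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("<permanova_result>\n")
  cat(sprintf("  pseudo-F = %.4g | R2 = %.3f | p = %.4g (%s, %d %s)\n",
              x$pseudo_f, x$r_squared, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_perm,
              if (x$exact) "labelings" else "permutations"))
  invisible(x)
}

# PCoA retaining negative-eigenvalue axes: list(pos=, neg=) coordinate blocks.
pcoa_axes <- function(m) {
  n <- nrow(m)
  a <- -0.5 * m^2
  centered <- a - outer(rowMeans(a), colMeans(a), `+`) + mean(a)
  e <- eigen(centered, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- e$values > tol; neg <- e$values < -tol
  list(pos = sweep(e$vectors[, pos, drop = FALSE], 2,
                   sqrt(e$values[pos]), `*`),
       neg = sweep(e$vectors[, neg, drop = FALSE], 2,
                   sqrt(abs(e$values[neg])), `*`))
}

# Weiszfeld iteration for the geometric (spatial) median with the
# imaginary-axis convention: squared distances are d_pos^2 - d_neg^2.
spatial_median <- function(pos, neg, tol = 1e-8, max_iter = 500L) {
  if (nrow(pos) == 1) return(list(pos = pos[1, ], neg = if (ncol(neg)) neg[1, ] else numeric(0)))
  mp <- colMeans(pos); mn <- if (ncol(neg)) colMeans(neg) else numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- rowSums(sweep(pos, 2, mp, `-`)^2)
    if (ncol(neg)) d2 <- d2 - rowSums(sweep(neg, 2, mn, `-`)^2)
    d <- sqrt(pmax(d2, 1e-12))
    w <- 1 / pmax(d, 1e-12)
    np <- colSums(pos * w) / sum(w)
    nn <- if (ncol(neg)) colSums(neg * w) / sum(w) else numeric(0)
    delta <- sqrt(sum((np - mp)^2) + sum((nn - mn)^2))
    mp <- np; mn <- nn
    if (delta < tol) break
  }
  list(pos = mp, neg = mn)
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the samples by principal-coordinate analysis (axes with
#' negative eigenvalues are kept; their squared distances enter with
#' opposite sign, per the standard convention), computes each group's
#' spatial median (geometric median, iteratively reweighted to tolerance
#' 1e-8), and tests the per-sample distances to the own-group median by a
#' one-way F whose null distribution comes from permuting group labels.
#'
#' @inheritParams permanova
#' @return A `beta_dispersion_result`: per-sample `distances` tibble,
#'   `f_statistic`, `p_value`, `n_perm`, `seed`.
#' @export
beta_dispersion <- function(d, groups, n_perm = 999L, seed = 1L) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  assert_that(length(groups) == n, "groups must align with the distance matrix",
              class = "imcpair_validation_error")
  if (any(table(groups) < 2)) {
    warn("group(s) of size 1: their dispersion distance is 0 by construction")
  }
  ax <- pcoa_axes(m)
  dist_to_median <- numeric(n)
  for (g in unique(groups)) {
    sel <- which(groups == g)
    med <- spatial_median(ax$pos[sel, , drop = FALSE],
                          ax$neg[sel, , drop = FALSE])
    d2 <- rowSums(sweep(ax$pos[sel, , drop = FALSE], 2, med$pos, `-`)^2)
    if (ncol(ax$neg)) {
      d2 <- d2 - rowSums(sweep(ax$neg[sel, , drop = FALSE], 2, med$neg, `-`)^2)
    }
    dist_to_median[sel] <- sqrt(pmax(d2, 0))
  }
  oneway_f <- function(z, lab) {
    mg <- tapply(z, lab, mean); ng <- table(lab)
    ssb <- sum(ng * (mg - mean(z))^2)
    ssw <- sum((z - mg[lab])^2)
    dfb <- length(mg) - 1; dfw <- length(z) - length(mg)
    if (ssw <= 1e-15) return(if (ssb <= 1e-15) 0 else Inf)
    (ssb / dfb) / (ssw / dfw)
  }
  f_obs <- oneway_f(dist_to_median, groups)
  f_null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    oneway_f(dist_to_median, sample(groups)), numeric(1)))
  p <- (sum(f_null >= f_obs - 1e-12) + 1) / (n_perm + 1)
  structure(list(
    distances = tibble(sample = rownames(m) %||% as.character(seq_len(n)),
                       group = groups, distance = dist_to_median),
    f_statistic = f_obs, p_value = p, n_perm = n_perm, seed = seed
  ), class = "beta_dispersion_result")
}

#' @export
print.beta_dispersion_result <- function(x, ...) {
  cat("<beta_dispersion_result>\n")
  cat(sprintf("  F = %.4g | p = %.4g (%d permutations)\n",
              x$f_statistic, x$p_value, x$n_perm))
  invisible(x)
}
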