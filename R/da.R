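#' Design specification for differential abundance
#'
#' @param condition Name of the condition column of the sample metadata
#'   (e.g. `tissue_class`), a factor with >= 2 levels.
#' @param covariates Character vector of adjustment columns
#'   (`patient_id` for the paired design, `location`, `tissue_site`).
#' @param contrast Condition level whose effect is reported (default: the
#'   second factor level).
#' @return A list of class `da_design`.
#' @export
da_design <- function(condition = "tissue_class",
                      covariates = "patient_id",
                      contrast = NULL) {
  structure(list(condition = condition, covariates = covariates,
                 contrast = contrast), class = "da_design")
}

# Moment (Pearson-style) estimate of the NB2 dispersion phi from a fitted
# mean: Var = mu + phi mu^2  =>  phi = sum((y-mu)^2 - mu) / sum(mu^2).
moment_dispersion <- function(y, mu) {
  max(0, sum((y - mu)^2 - mu) / sum(mu^2))
}

fit_nb_one <- function(y, X, Xr, offset, dispersion = c("moment", "none"),
                       common_phi = NULL, prior_df = 10,
                       test = c("qlf", "lrt")) {
  dispersion <- match.arg(dispersion); test <- match.arg(test)
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  pois <- suppressWarnings(stats::glm.fit(X, y, offset = offset,
                                          family = poisson(), control = ctl))
  phi <- 0
  if (dispersion == "moment") {
    phi_hat <- moment_dispersion(y, pois$fitted.values)
    df <- length(y) - ncol(X)
    phi <- if (is.null(common_phi)) phi_hat
           else (df * phi_hat + prior_df * common_phi) / (df + prior_df)
  }
  fam <- if (phi > 1e-8) MASS::negative.binomial(theta = 1 / phi) else poisson()
  full <- suppressWarnings(stats::glm.fit(X, y, offset = offset, family = fam,
                                          control = ctl))
  red <- suppressWarnings(stats::glm.fit(Xr, y, offset = offset, family = fam,
                                         control = ctl))
  df_diff <- ncol(X) - ncol(Xr)
  df_full <- length(y) - ncol(X)
  # deviance differences below numerical precision are zero (saturated or
  # exactly balanced fits would otherwise produce 0/0 noise in the F ratio)
  dd <- red$deviance - full$deviance
  if (dd < 1e-8 * (abs(full$deviance) + 1)) dd <- 0
  if (test == "qlf") {
    pearson <- sum((y - full$fitted.values)^2 /
                     fam$variance(full$fitted.values))
    s2 <- max(pearson / df_full, 1e-12)
    f <- dd / (df_diff * s2)
    p <- pf(f, df_diff, df_full, lower.tail = FALSE)
  } else {
    f <- dd
    p <- pchisq(f, df_diff, lower.tail = FALSE)
  }
  list(coef = full$coefficients, phi = phi, phi_raw = if (dispersion == "moment")
    moment_dispersion(y, pois$fitted.values) else 0, stat = f, p = p)
}

#' Negative-binomial differential abundance with paired design
#'
#' For each category, counts are modelled by a negative-binomial GLM with
#' log link and an offset of `log(sample total)`, so the condition
#' coefficient is a log fold change of the category's proportion. The
#' design matrix holds the covariates (e.g. patient blocks for the paired
#' design, sample location) plus the condition. Per-category dispersion
#' is estimated by Pearson moments and shrunk toward the across-category
#' common value (prior weight `prior_df` residual degrees of freedom);
#' the condition effect is tested by a quasi-likelihood F-test (deviance
#' difference of full vs reduced model scaled by the Pearson dispersion),
#' with a likelihood-ratio chi-square option. P-values are
#' Benjamini-Hochberg adjusted across categories; FDR < `fdr_threshold`
#' flags significance.
#'
#' @param x A `composition_table` (or sample x category count matrix with
#'   a `sample_meta` data frame supplied).
#' @param design A [da_design()].
#' @param sample_meta Optional metadata when `x` is a bare matrix.
#' @param dispersion `"moment"` (default) or `"none"` (Poisson fit).
#' @param test `"qlf"` (default) or `"lrt"`.
#' @param prior_df Shrinkage weight toward the common dispersion.
#' @param min_present Categories must have a nonzero count in at least
#'   this many samples to be tested (default 3); excluded categories are
#'   reported in the `excluded` attribute.
#' @param fdr_threshold Significance threshold on BH-adjusted p-values.
#' @return A `da_result`: tibble with `category`, `log2fc`, `dispersion`,
#'   `p_value`, `fdr`, `significant`.
#' @export
fit_da <- function(x, design = da_design(), sample_meta = NULL,
                   dispersion = "moment", test = "qlf", prior_df = 10,
                   min_present = 3L, fdr_threshold = 0.05) {
  if (inherits(x, "composition_table")) {
    counts <- comp_counts(x)
    meta <- as_tibble(x[setdiff(names(x), categories(x))])
  } else {
    counts <- as.matrix(x)
    assert_that(!is.null(sample_meta), "sample_meta required for matrix input",
                class = "imcpair_validation_error")
    meta <- as_tibble(sample_meta)
  }
  assert_that(all(rowSums(counts) > 0), "sample totals must be > 0",
              class = "imcpair_validation_error")
  cond <- factor(meta[[design$condition]])
  assert_that(nlevels(cond) >= 2, "condition must have >= 2 levels",
              class = "imcpair_design_error")
  assert_that(all(table(cond) >= 2), "need >= 2 samples per condition level",
              class = "imcpair_design_error")
  contrast <- design$contrast %||% levels(cond)[2]
  cond <- stats::relevel(cond, ref = setdiff(levels(cond), contrast)[1])

  covs <- design$covariates %||% character(0)
  fdat <- data.frame(..cond = cond)
  for (cv in covs) fdat[[cv]] <- factor(meta[[cv]])
  form_full <- stats::as.formula(paste(
    "~", paste(c(covs, "..cond"), collapse = " + ")))
  form_red <- if (length(covs) > 0)
    stats::as.formula(paste("~", paste(covs, collapse = " + "))) else ~1
  X <- model.matrix(form_full, fdat)
  Xr <- model.matrix(form_red, fdat)

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is not estimable; collinear term(s): %s",
                  paste(aliased, collapse = ", ")),
          class = "imcpair_design_error")
  }
  cond_col <- paste0("..cond", contrast)
  assert_that(cond_col %in% colnames(X), "contrast level not in design",
              class = "imcpair_design_error")

  offset <- log(rowSums(counts))
  present <- colSums(counts > 0)
  excluded <- colnames(counts)[present == 0]
  skipped <- colnames(counts)[present > 0 & present < min_present]
  keep <- colnames(counts)[present >= min_present]
  if (length(excluded) > 0) {
    warn(sprintf("all-zero category(ies) excluded: %s",
                 paste(excluded, collapse = ", ")))
  }
  assert_that(length(keep) > 0, "no categories left to test",
              class = "imcpair_validation_error")

  # common dispersion across categories (unshrunk moment estimates)
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 100)
  phis <- vapply(keep, function(ct) {
    fit <- suppressWarnings(stats::glm.fit(X, counts[, ct], offset = offset,
                                           family = poisson(), control = ctl))
    moment_dispersion(counts[, ct], fit$fitted.values)
  }, numeric(1))
  common_phi <- mean(phis)

  res <- purrr::map(keep, function(ct) {
    fit <- fit_nb_one(counts[, ct], X, Xr, offset, dispersion = dispersion,
                      common_phi = common_phi, prior_df = prior_df, test = test)
    tibble(category = ct,
           log2fc = unname(fit$coef[cond_col]) / log(2),
           dispersion = fit$phi, statistic = fit$stat, p_value = fit$p)
  }) |> bind_rows()
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  structure(res, class = c("da_result", class(res)),
            design = design, contrast = contrast, test = test,
            common_dispersion = common_phi,
            excluded = excluded, skipped = skipped,
            fdr_threshold = fdr_threshold)
}

#' One patient-group versus the rest of the cohort
#'
#' For each group with at least two samples, fits [fit_da()] with the
#' condition "sample belongs to the group" against all remaining samples,
#' adjusting for the tissue covariate; BH correction is applied across
#' categories within each group comparison. Singleton groups are skipped
#' with a warning; a grouping that leaves no "rest" is a design error.
#'
#' @param x A `composition_table`.
#' @param groups Vector (or column name in `x`) of group labels per sample.
#' @param tissue_covariate Metadata column to adjust for
#'   (default `"tissue_site"`); `NULL` for none.
#' @inheritParams fit_da
#' @return Tibble of stacked `da_result` rows with a `group` column.
#' @export
one_vs_rest_da <- function(x, groups, tissue_covariate = "tissue_site",
                           min_present = 3L, fdr_threshold = 0.05, ...) {
  meta <- as_tibble(x[setdiff(names(x), categories(x))])
  g <- if (length(groups) == 1 && is.character(groups)) meta[[groups]] else groups
  assert_that(length(g) == nrow(x), "groups must align with samples",
              class = "imcpair_validation_error")
  assert_that(length(unique(g)) >= 2,
              "grouping must leave a non-empty rest to compare against",
              class = "imcpair_design_error")
  out <- list()
  for (grp in sort(unique(g))) {
    if (sum(g == grp) < 2) {
      warn(sprintf("group %s has a single sample; skipped", grp))
      next
    }
    meta2 <- meta
    meta2$..group <- factor(ifelse(g == grp, "group", "rest"),
                            levels = c("rest", "group"))
    covs <- tissue_covariate
    if (!is.null(covs) && length(unique(meta2[[covs]])) < 2) covs <- NULL
    des <- da_design(condition = "..group", covariates = covs,
                     contrast = "group")
    fit <- fit_da(comp_counts(x), design = des, sample_meta = meta2,
                  min_present = min_present, fdr_threshold = fdr_threshold, ...)
    fit$group <- grp
    out[[length(out) + 1L]] <- as_tibble(fit)
  }
  bind_rows(out) |> select("group", dplyr::everything())
}

#' @export
print.da_result <- function(x, ...) {
  cat("<da_result>\n")
  cat(sprintf("  %d categories tested, %d significant at FDR < %g (contrast: %s)\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold"),
              attr(x, "contrast")))
  NextMethod()
}
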