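#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_vline
#'   geom_col geom_point geom_line labs theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Tidiers for imcpair result objects
#'
#' `tidy()` returns the per-unit table of a result (per-patient matched
#' distances, per-category differential-abundance rows, per-sample
#' dispersion distances, the silhouette sweep, PCA coordinates);
#' `glance()` returns a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name imcpair-tidiers
NULL

#' @rdname imcpair-tidiers
#' @export
tidy.matched_perm_test <- function(x, ...) x$per_patient

#' @rdname imcpair-tidiers
#' @export
glance.matched_perm_test <- function(x, ...) {
  tibble(observed_median = x$observed_median,
         null_median_mean = mean(x$null_medians),
         p_value = x$p_value, n_patients = nrow(x$per_patient),
         n_perm = x$n_perm, method = x$method)
}

#' @rdname imcpair-tidiers
#' @export
tidy.da_result <- function(x, ...) as_tibble(x)

#' @rdname imcpair-tidiers
#' @export
glance.da_result <- function(x, ...) {
  tibble(n_categories = nrow(x), n_significant = sum(x$significant),
         fdr_threshold = attr(x, "fdr_threshold"),
         contrast = attr(x, "contrast"),
         common_dispersion = attr(x, "common_dispersion"))
}

#' @rdname imcpair-tidiers
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(term = c("groups", "residual"),
         df = c(length(x$group_sizes) - 1,
                sum(unlist(x$group_sizes)) - length(x$group_sizes)),
         pseudo_f = c(x$pseudo_f, NA), r_squared = c(x$r_squared, NA),
         p_value = c(x$p_value, NA))
}

#' @rdname imcpair-tidiers
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared,
         p_value = x$p_value, exact = x$exact, n_perm = x$n_perm)
}

#' @rdname imcpair-tidiers
#' @export
tidy.beta_dispersion_result <- function(x, ...) x$distances

#' @rdname imcpair-tidiers
#' @export
glance.beta_dispersion_result <- function(x, ...) {
  tibble(f_statistic = x$f_statistic, p_value = x$p_value, n_perm = x$n_perm)
}

#' @rdname imcpair-tidiers
#' @export
tidy.cn_model <- function(x, ...) x$silhouette

#' @rdname imcpair-tidiers
#' @export
glance.cn_model <- function(x, ...) {
  tibble(chosen_k = x$chosen_k,
         best_silhouette = max(x$silhouette$avg_width, na.rm = TRUE),
         n_cells = length(x$labels), n_categories = length(x$categories))
}

#' @rdname imcpair-tidiers
#' @export
tidy.clr_pca <- function(x, ...) x$coords

#' @rdname imcpair-tidiers
#' @export
glance.clr_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         pc1_var = x$var_explained[1],
         pc2_var = if (length(x$var_explained) > 1) x$var_explained[2] else NA_real_)
}

#' Plots for imcpair result objects
#'
#' `autoplot()` draws the standard figure for each result type: the
#' permutation-null histogram with the observed matched median
#' (similarity test), a log2-fold-change bar chart (differential
#' abundance), the silhouette sweep with the chosen k (neighborhood
#' model), and the PC1/PC2 sample map (compositional PCA).
#'
#' @param object A result object.
#' @param colour_by Metadata column for coloring PCA points.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name imcpair-autoplot
NULL

#' @rdname imcpair-autoplot
#' @export
autoplot.matched_perm_test <- function(object, ...) {
  ggplot(tibble(null_median = object$null_medians), aes(x = .data$null_median)) +
    geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed_median, colour = "firebrick",
               linetype = "dashed") +
    geom_vline(xintercept = mean(object$null_medians), colour = "grey30",
               linetype = "dotted") +
    labs(x = sprintf("permutation median %s distance", object$method),
         y = "iterations",
         title = sprintf("matched median = %.3f, p = %.3g",
                         object$observed_median, object$p_value)) +
    theme_minimal()
}

#' @rdname imcpair-autoplot
#' @export
autoplot.da_result <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$log2fc) |>
    mutate(category = factor(.data$category, levels = .data$category))
  ggplot(df, aes(x = .data$log2fc, y = .data$category,
                 fill = .data$significant)) +
    geom_col() +
    scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70"),
                      name = sprintf("FDR < %g", attr(object, "fdr_threshold"))) +
    labs(x = sprintf("log2 fold change (%s vs rest)", attr(object, "contrast")),
         y = NULL) +
    theme_minimal()
}

#' @rdname imcpair-autoplot
#' @export
autoplot.cn_model <- function(object, ...) {
  ggplot(object$silhouette, aes(x = .data$k, y = .data$avg_width)) +
    geom_line(colour = "grey50") + geom_point() +
    geom_vline(xintercept = object$chosen_k, colour = "firebrick",
               linetype = "dashed") +
    labs(x = "k", y = "average silhouette width",
         title = sprintf("chosen k = %d", object$chosen_k)) +
    theme_minimal()
}

#' @rdname imcpair-autoplot
#' @export
autoplot.clr_pca <- function(object, colour_by = NULL, ...) {
  df <- object$coords
  p <- if (!is.null(colour_by) && colour_by %in% names(df)) {
    ggplot(df, aes(x = .data$PC1, y = .data$PC2,
                   colour = .data[[colour_by]]))
  } else {
    ggplot(df, aes(x = .data$PC1, y = .data$PC2))
  }
  p + geom_point(size = 2) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)",
                     100 * (if (length(object$var_explained) > 1)
                       object$var_explained[2] else 0))) +
    theme_minimal()
}
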