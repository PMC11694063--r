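#' Pipeline configuration
#'
#' Bundles the constants of the three analysis tracks (tumor, T cell,
#' myeloid): QC thresholds, clustering sizes, distance parameters,
#' permutation counts (1000 for matched similarity; 999 for the tumor
#' PERMANOVA and 9999 for the immune panels), neighborhood parameters,
#' the FDR threshold, and per-track location filters (the tumor track
#' uses all locations; the immune tracks restrict to intratumoral
#' images). A configuration can also be loaded from a YAML file.
#'
#' @param synthetic A [synthetic_config()] (simulated input), or `NULL`
#'   when `input_dir` points at an on-disk cohort.
#' @param input_dir Directory holding a cohort written by
#'   [write_cohort()] (used when `synthetic` is `NULL`).
#' @param qc A [qc_params()].
#' @param n_clusters Named vector: phenotype clusters per panel.
#' @param distance List: `method`, `pseudocount`, `presence_threshold`.
#' @param n_perm_similarity Permutations of the matched-similarity test.
#' @param n_perm_permanova Named vector of PERMANOVA permutations per panel.
#' @param cn A [cn_params()].
#' @param n_patient_groups Patient groups cut from the metastasis
#'   composition tree.
#' @param n_interaction_images Images sampled for interaction testing.
#' @param fdr_threshold Differential-abundance significance threshold.
#' @param location_filters Named list of location filters per panel.
#' @param seed Global seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            input_dir = NULL,
                            qc = qc_params(),
                            n_clusters = c(tumor = 20L, tcell = 10L, myeloid = 10L),
                            distance = list(method = "aitchison", pseudocount = 1,
                                            presence_threshold = 0.005),
                            n_perm_similarity = 1000L,
                            n_perm_permanova = c(tumor = 999L, tcell = 9999L,
                                                 myeloid = 9999L),
                            cn = cn_params(),
                            n_patient_groups = 4L,
                            n_interaction_images = 6L,
                            fdr_threshold = 0.05,
                            location_filters = list(tumor = NULL,
                                                    tcell = "intratumoral",
                                                    myeloid = "intratumoral"),
                            seed = 1L) {
  assert_that(!is.null(synthetic) || !is.null(input_dir),
              "provide a synthetic config or an input directory",
              class = "imcpair_validation_error")
  if (!is.null(input_dir)) {
    assert_that(dir.exists(input_dir),
                sprintf("input_dir does not exist: %s", input_dir),
                class = "imcpair_validation_error")
  }
  assert_that(seed >= 0, "seed must be non-negative",
              class = "imcpair_validation_error")
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with keys matching the `pipeline_config()`
#'   arguments (nested `synthetic`, `qc`, `cn` sections).
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synthetic)) args$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$qc)) args$qc <- do.call(qc_params, y$qc)
  if (!is.null(y$cn)) args$cn <- do.call(cn_params, y$cn)
  for (k in setdiff(names(y), c("synthetic", "qc", "cn"))) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

pipeline_stages <- function() {
  c("simulate", "qc", "cluster", "compose", "similarity", "da",
    "permanova", "neighborhoods", "spatial", "report")
}

require_artifact <- function(dir, file, produced_by) {
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    abort(sprintf("missing artifact '%s'; run the '%s' stage first",
                  file, produced_by),
          class = "imcpair_dependency_error")
  }
  path
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, na = "null")
}

log_line <- function(dir, ...) {
  cat(sprintf(...), "\n", sep = "", file = file.path(dir, "pipeline.log"),
      append = TRUE)
}

read_labelled_cells <- function(dir) {
  readr::read_csv(require_artifact(dir, "cluster/cells_labelled.csv", "cluster"),
                  show_col_types = FALSE, progress = FALSE)
}

read_comp <- function(dir, name) {
  f <- require_artifact(dir, file.path("compose", paste0(name, ".csv")), "compose")
  df <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  meta <- intersect(c("sample_id", "image_id", "core_id", "patient_id",
                      "tissue_class", "tissue_site", "location"), names(df))
  new_composition_table(df, setdiff(names(df), meta))
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order into a run directory: simulate/ingest,
#' QC, normalization + clustering, compositional aggregation, matched
#' similarity + diversity + PCA + patient grouping, differential
#' abundance (paired and one-vs-rest), PERMANOVA + beta dispersion,
#' cellular neighborhoods + CN differential abundance, and spatial
#' analyses (tumor/stroma enrichment, interaction tests, cross-panel
#' correlation, matched marker correlation), then a report stage. Every
#' intermediate table is written as delimited text, results also as
#' JSON, with a manifest and a log. Identical config + seed reproduces
#' every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created; existing stage outputs are
#'   overwritten only by their own stage).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "pipeline.log"))
  manifest <- list(seed = config$seed,
                   stages = pipeline_stages(),
                   config = rapply(unclass(config), unclass, how = "replace"))
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  for (st in pipeline_stages()) {
    run_stage(out_dir, st, config)
  }
  invisible(out_dir)
}

#' Run one pipeline stage
#'
#' Each stage reads the previous stages' outputs from the run directory
#' and overwrites only its own subdirectory; invoking a stage before its
#' inputs exist raises a dependency error naming the missing artifact.
#'
#' @param out_dir Run directory.
#' @param stage One of `simulate`, `qc`, `cluster`, `compose`,
#'   `similarity`, `da`, `permanova`, `neighborhoods`, `spatial`,
#'   `report`.
#' @param config A [pipeline_config()].
#' @return `out_dir`, invisibly.
#' @export
run_stage <- function(out_dir, stage, config) {
  stage <- match.arg(stage, pipeline_stages())
  fn <- get(paste0("stage_", stage), envir = asNamespace("imcpair"))
  sdir <- file.path(out_dir, stage)
  unlink(sdir, recursive = TRUE)
  dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
  withCallingHandlers(
    fn(out_dir, sdir, config),
    error = function(e) {
      log_line(out_dir, "stage %s FAILED: %s", stage, conditionMessage(e))
    })
  invisible(out_dir)
}

active_panels <- function(config) {
  if (!is.null(config$synthetic)) config$synthetic$panels else panels()
}

stage_simulate <- function(out_dir, sdir, config) {
  if (!is.null(config$input_dir)) {
    co <- read_cohort(config$input_dir)
    masks <- NULL
  } else {
    gen <- generate_cohort(config$synthetic)
    co <- gen$cohort
    masks <- gen$masks
    readr::write_csv(gen$truth$sample_compositions,
                     file.path(sdir, "truth_sample_compositions.csv"),
                     progress = FALSE)
  }
  write_cohort(co, file.path(sdir, "cohort"))
  if (!is.null(masks)) {
    mdir <- file.path(sdir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (nm in names(masks)) {
      write_mask(masks[[nm]], file.path(mdir, paste0(nm, ".png")))
    }
  }
  log_line(out_dir, "simulate: %d cells, %d images, %d patients",
           nrow(co$cells), nrow(co$images), nrow(co$patients))
}

stage_qc <- function(out_dir, sdir, config) {
  co <- read_cohort(require_artifact(out_dir, "simulate/cohort", "simulate"))
  res <- qc_filter(co, config$qc)
  write_cohort(res$cohort, file.path(sdir, "cohort"))
  readr::write_csv(res$report, file.path(sdir, "qc_report.csv"), progress = FALSE)
  log_line(out_dir, "qc: %d cells and %d images retained",
           nrow(res$cohort$cells), nrow(res$cohort$images))
}

stage_cluster <- function(out_dir, sdir, config) {
  co <- read_cohort(require_artifact(out_dir, "qc/cohort", "qc"))
  cells <- co$cells
  out <- list()
  for (pn in active_panels(config)) {
    sub <- filter(cells, .data$panel == pn)
    mk <- marker_cols(sub)
    mk <- mk[colSums(!is.na(sub[mk])) == nrow(sub)]  # other panels' markers are NA
    x <- normalize_percentile99(as.matrix(sub[mk]))
    lab <- som_metacluster(x, n_meta = config$n_clusters[[pn]],
                           seed = derive_seed(config$seed, "cluster", pn))
    sub$phenotype <- sprintf("%s_ph%02d", pn, lab)
    prof <- cluster_profiles(x, lab)
    readr::write_csv(prof, file.path(sdir, paste0("profiles_", pn, ".csv")),
                     progress = FALSE)
    out[[pn]] <- sub
    log_line(out_dir, "cluster[%s]: %d cells into %d phenotypes", pn,
             nrow(sub), length(unique(lab)))
  }
  readr::write_csv(bind_rows(out), file.path(sdir, "cells_labelled.csv"),
                   progress = FALSE)
}

stage_compose <- function(out_dir, sdir, config) {
  cells <- read_labelled_cells(out_dir)
  co <- read_cohort(require_artifact(out_dir, "qc/cohort", "qc"))
  for (pn in active_panels(config)) {
    lf <- config$location_filters[[pn]]
    tab <- aggregate_counts(cells, co$images, panel = pn, level = "patient",
                            location_filter = lf, pool_met_sites = TRUE)
    readr::write_csv(filter(tab, .data$tissue_class == "PT"),
                     file.path(sdir, paste0(pn, "_pt.csv")), progress = FALSE)
    readr::write_csv(filter(tab, .data$tissue_class == "metastasis"),
                     file.path(sdir, paste0(pn, "_met.csv")), progress = FALSE)
    img <- aggregate_counts(cells, co$images, panel = pn, level = "image",
                            location_filter = lf)
    readr::write_csv(img, file.path(sdir, paste0(pn, "_image.csv")),
                     progress = FALSE)
    log_line(out_dir, "compose[%s]: %d patient samples, %d image samples",
             pn, nrow(tab), nrow(img))
  }
}

stage_similarity <- function(out_dir, sdir, config) {
  for (pn in active_panels(config)) {
    pt <- read_comp(out_dir, paste0(pn, "_pt"))
    met <- read_comp(out_dir, paste0(pn, "_met"))
    res <- matched_similarity_test(
      pt, met, method = config$distance$method,
      pseudocount = config$distance$pseudocount,
      n_perm = config$n_perm_similarity,
      seed = derive_seed(config$seed, "similarity", pn))
    readr::write_csv(res$per_patient,
                     file.path(sdir, paste0(pn, "_matched_distances.csv")),
                     progress = FALSE)
    write_json_out(list(observed_median = res$observed_median,
                        p_value = res$p_value, n_perm = res$n_perm,
                        seed = res$seed, method = res$method),
                   file.path(sdir, paste0(pn, "_similarity.json")))
    log_line(out_dir, "similarity[%s]: median %.4f, p = %.4g", pn,
             res$observed_median, res$p_value)
  }
  # tumor-track extras: diversity, PCA, dominant flow, patient grouping
  pn <- active_panels(config)[1]
  pt <- read_comp(out_dir, paste0(pn, "_pt"))
  met <- read_comp(out_dir, paste0(pn, "_met"))
  readr::write_csv(bind_rows(shannon_diversity(pt), shannon_diversity(met)),
                   file.path(sdir, "shannon_diversity.csv"), progress = FALSE)
  both <- bind_rows(as_tibble(pt), as_tibble(met))
  pca <- pca_clr(new_composition_table(both, categories(pt)),
                 config$distance$pseudocount)
  readr::write_csv(pca$coords, file.path(sdir, "pca_coords.csv"),
                   progress = FALSE)
  readr::write_csv(tibble(component = seq_along(pca$var_explained),
                          var_explained = pca$var_explained),
                   file.path(sdir, "pca_variance.csv"), progress = FALSE)
  readr::write_csv(dominant_transitions(pt, met),
                   file.path(sdir, "dominant_transitions.csv"), progress = FALSE)
  grp <- patient_grouping(met, min(config$n_patient_groups, nrow(met)))
  readr::write_csv(grp, file.path(sdir, "patient_groups.csv"), progress = FALSE)
}

stage_da <- function(out_dir, sdir, config) {
  cells <- read_labelled_cells(out_dir)
  co <- read_cohort(require_artifact(out_dir, "qc/cohort", "qc"))
  pans <- active_panels(config)
  for (pn in pans) {
    lf <- config$location_filters[[pn]]
    if (is.null(lf)) {
      tab <- read_comp(out_dir, paste0(pn, "_pt")) |> as_tibble()
      tab2 <- read_comp(out_dir, paste0(pn, "_met")) |> as_tibble()
      full <- new_composition_table(bind_rows(tab, tab2),
                                    categories(read_comp(out_dir, paste0(pn, "_pt"))))
      des <- da_design(condition = "tissue_class", covariates = "patient_id",
                       contrast = "metastasis")
    } else {
      # image-level fit so the sample location can enter the model
      full <- aggregate_counts(cells, co$images, panel = pn, level = "image",
                               location_filter = NULL)
      keep_loc <- if (length(unique(full$location)) > 1) "location" else NULL
      des <- da_design(condition = "tissue_class",
                       covariates = c("patient_id", keep_loc),
                       contrast = "metastasis")
    }
    res <- fit_da(full, design = des, fdr_threshold = config$fdr_threshold)
    readr::write_csv(as_tibble(res), file.path(sdir, paste0(pn, "_paired_da.csv")),
                     progress = FALSE)
    write_json_out(list(panel = pn, design = unclass(des),
                        contrast = attr(res, "contrast"),
                        n_significant = sum(res$significant),
                        fdr_threshold = config$fdr_threshold),
                   file.path(sdir, paste0(pn, "_paired_da_manifest.json")))
    log_line(out_dir, "da[%s]: %d/%d significant at FDR < %g", pn,
             sum(res$significant), nrow(res), config$fdr_threshold)
  }
  # one patient group vs rest on the first panel's metastasis samples
  grp <- readr::read_csv(require_artifact(out_dir, "similarity/patient_groups.csv",
                                          "similarity"),
                         show_col_types = FALSE, progress = FALSE)
  met <- read_comp(out_dir, paste0(pans[1], "_met"))
  g <- grp$group[match(met$patient_id, grp$patient_id)]
  ovr <- tryCatch(
    one_vs_rest_da(met, g, tissue_covariate =
                     if (length(unique(met$tissue_site)) > 1) "tissue_site" else NULL,
                   fdr_threshold = config$fdr_threshold),
    error = function(e) tibble())
  readr::write_csv(ovr, file.path(sdir, "group_vs_rest_da.csv"), progress = FALSE)
}

stage_permanova <- function(out_dir, sdir, config) {
  for (pn in active_panels(config)) {
    met <- read_comp(out_dir, paste0(pn, "_met"))
    sizes <- table(met$tissue_site)
    keep <- names(sizes)[sizes >= 2]
    sub <- filter(met, .data$tissue_site %in% keep)
    res <- list(panel = pn)
    if (length(keep) >= 2) {
      d <- dist(clr_transform(comp_counts(sub), config$distance$pseudocount))
      np <- config$n_perm_permanova[[pn]]
      disp <- beta_dispersion(d, sub$tissue_site, n_perm = min(np, 999L),
                              seed = derive_seed(config$seed, "disp", pn))
      pv <- permanova(d, sub$tissue_site, n_perm = np,
                      seed = derive_seed(config$seed, "permanova", pn))
      res <- c(res, list(
        dispersion_f = disp$f_statistic, dispersion_p = disp$p_value,
        pseudo_f = pv$pseudo_f, r_squared = pv$r_squared,
        p_value = pv$p_value, exact = pv$exact, n_perm = pv$n_perm,
        group_sizes = pv$group_sizes))
      log_line(out_dir, "permanova[%s]: F = %.3f, p = %.4g (dispersion p = %.4g)",
               pn, pv$pseudo_f, pv$p_value, disp$p_value)
    } else {
      res$note <- "fewer than 2 tissue-site groups with >= 2 samples"
      log_line(out_dir, "permanova[%s]: skipped (%s)", pn, res$note)
    }
    write_json_out(res, file.path(sdir, paste0(pn, "_permanova.json")))
  }
}

stage_neighborhoods <- function(out_dir, sdir, config) {
  cells <- read_labelled_cells(out_dir)
  co <- read_cohort(require_artifact(out_dir, "qc/cohort", "qc"))
  intratumoral <- co$images$image_id[co$images$location == "intratumoral"]
  for (pn in active_panels(config)) {
    sub <- filter(cells, .data$panel == pn, .data$image_id %in% intratumoral)
    cn_cfg <- config$cn
    cn_cfg$seed <- derive_seed(config$seed, "cn", pn)
    model <- cn_detect(sub, cn_cfg)
    readr::write_csv(model$silhouette,
                     file.path(sdir, paste0(pn, "_silhouette.csv")),
                     progress = FALSE)
    readr::write_csv(tibble(cell_id = sub$cell_id, cn = model$labels),
                     file.path(sdir, paste0(pn, "_cn_labels.csv")),
                     progress = FALSE)
    res <- cn_differential_abundance(sub, model, co$images,
                                     fdr_threshold = config$fdr_threshold)
    readr::write_csv(as_tibble(res), file.path(sdir, paste0(pn, "_cn_da.csv")),
                     progress = FALSE)
    write_json_out(list(panel = pn, chosen_k = model$chosen_k,
                        n_cells = nrow(sub),
                        n_significant = sum(res$significant)),
                   file.path(sdir, paste0(pn, "_cn.json")))
    log_line(out_dir, "neighborhoods[%s]: k = %d over %d cells", pn,
             model$chosen_k, nrow(sub))
  }
}

stage_spatial <- function(out_dir, sdir, config) {
  cells <- read_labelled_cells(out_dir)
  co <- read_cohort(require_artifact(out_dir, "qc/cohort", "qc"))
  mdir <- file.path(out_dir, "simulate", "masks")
  pans <- active_panels(config)

  if (dir.exists(mdir)) {
    px <- config$synthetic$mask_pixel_um %||% 4
    withd <- purrr::map(split(cells, cells$image_id), function(ic) {
      mf <- file.path(mdir, paste0(ic$image_id[1], ".png"))
      if (!file.exists(mf)) return(NULL)
      suppressWarnings(signed_border_distance(ic, read_mask(mf), px))
    }) |> bind_rows()
    enr <- purrr::map(setdiff(pans, "tumor"), function(pn) {
      sub <- filter(withd, .data$panel == pn)
      tryCatch(mask_enrichment(sub) |> mutate(panel = pn),
               error = function(e) tibble())
    }) |> bind_rows()
    readr::write_csv(enr, file.path(sdir, "mask_enrichment.csv"),
                     progress = FALSE)
  }

  # interaction testing on the two most abundant phenotypes of each image
  tum <- filter(cells, .data$panel == pans[1])
  img_ids <- with_seed(derive_seed(config$seed, "interaction"),
                       sample(unique(tum$image_id),
                              min(config$n_interaction_images,
                                  length(unique(tum$image_id)))))
  inter <- purrr::map(sort(img_ids), function(im) {
    ic <- filter(tum, .data$image_id == im)
    top <- names(sort(table(ic$phenotype), decreasing = TRUE))[1:2]
    if (length(top) < 2 || anyNA(top)) return(NULL)
    r <- interaction_test(ic, top[1], top[2],
                          radius_um = config$cn$radius_um, n_perm = 200L,
                          seed = derive_seed(config$seed, "interaction", im))
    tibble(image_id = im, type_a = top[1], type_b = top[2],
           observed = r$observed, p_interaction = r$p_interaction,
           p_avoidance = r$p_avoidance, call = r$call)
  }) |> bind_rows()
  readr::write_csv(inter, file.path(sdir, "interaction_tests.csv"),
                   progress = FALSE)

  if (length(pans) > 1) {
    tabs <- lapply(stats::setNames(pans, pans), function(pn)
      read_comp(out_dir, paste0(pn, "_image")))
    corr <- cross_panel_correlation(tabs)
    readr::write_csv(corr, file.path(sdir, "cross_panel_correlation.csv"),
                     progress = FALSE)
  }
  mmc <- matched_marker_correlation(filter(cells, .data$panel == pans[1]),
                                    co$images)
  readr::write_csv(mmc, file.path(sdir, "matched_marker_correlation.csv"),
                   progress = FALSE)
  log_line(out_dir, "spatial: %d interaction tests, %d matched marker correlations",
           nrow(inter), nrow(mmc))
}

stage_report <- function(out_dir, sdir, config) {
  for (pn in active_panels(config)) {
    sim <- jsonlite::read_json(require_artifact(
      out_dir, file.path("similarity", paste0(pn, "_similarity.json")),
      "similarity"))
    pv <- jsonlite::read_json(require_artifact(
      out_dir, file.path("permanova", paste0(pn, "_permanova.json")),
      "permanova"))
    cn <- jsonlite::read_json(require_artifact(
      out_dir, file.path("neighborhoods", paste0(pn, "_cn.json")),
      "neighborhoods"))
    da <- readr::read_csv(require_artifact(
      out_dir, file.path("da", paste0(pn, "_paired_da.csv")), "da"),
      show_col_types = FALSE, progress = FALSE)
    write_json_out(list(panel = pn, matched_similarity = sim,
                        permanova = pv, neighborhoods = cn,
                        da_significant = sum(da$significant),
                        da_categories = nrow(da)),
                   file.path(sdir, paste0("summary_", pn, ".json")))
  }
  log_line(out_dir, "report: %d track summaries", length(active_panels(config)))
}
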