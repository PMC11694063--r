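#' Assemble a single-cell cohort
#'
#' A cohort bundles the three tables that describe a multiplexed-imaging
#' study: one row per segmented cell, one row per acquired image, and one
#' row per patient. Marker intensities are ordinary numeric columns of the
#' cell table; every column that is not one of the reserved schema columns
#' is treated as a marker.
#'
#' @param cells Data frame with columns `cell_id`, `image_id`, `panel`
#'   (one of `"tumor"`, `"tcell"`, `"myeloid"`), `x_um`, `y_um`, `area_px`,
#'   optionally `phenotype`, `border_distance_um`, `true_category`,
#'   `true_niche`, plus numeric marker columns.
#' @param images Data frame with columns `image_id`, `core_id`,
#'   `patient_id`, `tissue_site` (one of `"PT"`, `"bone"`, `"brain"`,
#'   `"liver"`, `"soft_tissue"`), `location` (one of `"intratumoral"`,
#'   `"stromal"`, `"margin"`), `width_um`, `height_um`.
#' @param patients Data frame with columns `patient_id`,
#'   `molecular_subtype` (one of `"LumA"`, `"LumB"`, `"HER2"`, `"TN"`).
#' @param validate Run [validate_cohort()] on the result (default `TRUE`).
#'
#' @return An object of class `imc_cohort`: a list with tibbles `cells`,
#'   `images`, `patients`.
#' @export
cohort <- function(cells, images, patients, validate = TRUE) {
  x <- structure(
    list(cells = as_tibble(cells), images = as_tibble(images),
         patients = as_tibble(patients)),
    class = "imc_cohort"
  )
  if (validate) validate_cohort(x)
  x
}

cell_schema_cols <- function() {
  c("cell_id", "image_id", "panel", "x_um", "y_um", "area_px",
    "phenotype", "border_distance_um", "true_category", "true_niche")
}

#' Marker columns of a cohort's cell table
#'
#' @param x An `imc_cohort` or a cell table.
#' @return Character vector of marker column names.
#' @export
marker_cols <- function(x) {
  cells <- if (inherits(x, "imc_cohort")) x$cells else x
  setdiff(names(cells), cell_schema_cols())
}

#' Validate cohort schema, enum domains, and referential integrity
#'
#' Checks the invariants every stage relies on: mandatory columns present,
#' categorical fields within the cohort design (the study covers primary
#' tumors and bone/brain/liver/soft-tissue metastases only), positive cell
#' areas, coordinates inside the owning image, finite non-negative marker
#' values, no duplicate identifiers, and that every cell references an
#' existing image and every image an existing patient.
#'
#' @param x An `imc_cohort`.
#' @return `x`, invisibly. Errors (class `imcpair_schema_error` or
#'   `imcpair_validation_error`) describe the first violated contract.
#' @export
validate_cohort <- function(x) {
  assert_that(inherits(x, "imc_cohort"), "`x` must be an `imc_cohort`.")
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      abort(sprintf("%s table is missing mandatory column(s): %s",
                    what, paste(miss, collapse = ", ")),
            class = "imcpair_schema_error")
    }
  }
  need(x$cells, c("cell_id", "image_id", "panel", "x_um", "y_um", "area_px"), "cells")
  need(x$images, c("image_id", "core_id", "patient_id", "tissue_site",
                   "location", "width_um", "height_um"), "images")
  need(x$patients, c("patient_id", "molecular_subtype"), "patients")

  check_enum <- function(vals, domain, field) {
    bad <- setdiff(unique(vals[!is.na(vals)]), domain)
    if (length(bad) > 0) {
      abort(sprintf("invalid %s value(s): %s (allowed: %s)",
                    field, paste(bad, collapse = ", "),
                    paste(domain, collapse = ", ")),
            class = "imcpair_validation_error")
    }
  }
  check_enum(x$cells$panel, panels(), "panel")
  check_enum(x$images$tissue_site, tissue_sites(), "tissue_site")
  check_enum(x$images$location, locations(), "location")
  check_enum(x$patients$molecular_subtype, subtypes(), "molecular_subtype")

  assert_that(!anyDuplicated(x$images$image_id), "duplicate image_id values",
              class = "imcpair_validation_error")
  assert_that(!anyDuplicated(x$patients$patient_id), "duplicate patient_id values",
              class = "imcpair_validation_error")
  assert_that(!anyDuplicated(paste(x$cells$panel, x$cells$cell_id)),
              "duplicate cell_id values within a panel",
              class = "imcpair_validation_error")

  assert_that(all(x$cells$image_id %in% x$images$image_id),
              "cells reference image_id values absent from the image table",
              class = "imcpair_validation_error")
  assert_that(all(x$images$patient_id %in% x$patients$patient_id),
              "images reference patient_id values absent from the patient table",
              class = "imcpair_validation_error")

  assert_that(all(x$cells$area_px > 0), "area_px must be > 0",
              class = "imcpair_validation_error")
  assert_that(all(x$images$width_um > 0) && all(x$images$height_um > 0),
              "image extents must be > 0", class = "imcpair_validation_error")

  ext <- x$cells |>
    left_join(select(x$images, "image_id", "width_um", "height_um"), by = "image_id")
  assert_that(all(ext$x_um >= 0 & ext$x_um <= ext$width_um &
                    ext$y_um >= 0 & ext$y_um <= ext$height_um),
              "cell centroids must lie within the owning image's bounds",
              class = "imcpair_validation_error")

  mk <- marker_cols(x)
  if (length(mk) > 0) {
    mv <- as.matrix(x$cells[mk])
    # markers of other panels are NA by construction in a stacked cell table
    assert_that(all(is.na(mv) | (is.finite(mv) & mv >= 0)),
                "marker expression values must be finite and >= 0",
                class = "imcpair_validation_error")
  }
  invisible(x)
}

#' @export
print.imc_cohort <- function(x, ...) {
  cat("<imc_cohort>\n")
  cat(sprintf("  %d cells | %d images | %d patients\n",
              nrow(x$cells), nrow(x$images), nrow(x$patients)))
  tab <- table(x$cells$panel)
  cat("  cells per panel:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat("  markers:", paste(head(marker_cols(x), 8), collapse = ", "),
      if (length(marker_cols(x)) > 8) "...", "\n")
  invisible(x)
}

#' Quality-control parameters
#'
#' Cells with an area of fewer than `min_area_px` or more than
#' `max_area_px` pixels, and images left with fewer than
#' `min_cells_per_image` cells, are excluded. Defaults follow the usual
#' IMC segmentation QC: 7 and 600 pixels (both bounds inclusive for
#' retention) and 100 cells.
#'
#' @param min_area_px,max_area_px Inclusive retention bounds on cell area.
#' @param min_cells_per_image Minimum surviving cells for an image to be kept.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_area_px = 7L, max_area_px = 600L,
                      min_cells_per_image = 100L) {
  assert_that(min_area_px > 0 && min_area_px <= max_area_px,
              "need 0 < min_area_px <= max_area_px",
              class = "imcpair_validation_error")
  assert_that(min_cells_per_image >= 1, "min_cells_per_image must be >= 1",
              class = "imcpair_validation_error")
  structure(list(min_area_px = as.integer(min_area_px),
                 max_area_px = as.integer(max_area_px),
                 min_cells_per_image = as.integer(min_cells_per_image)),
            class = "qc_params")
}

#' Cell- and image-level quality control
#'
#' Two-pass filter: first drop cells outside the area bounds, then drop
#' whole images whose remaining cell count falls below the minimum (with
#' all their cells). Patients are never dropped, so a patient can lose all
#' images on one panel but remain in the cohort. Idempotent.
#'
#' @param x An `imc_cohort`.
#' @param params A [qc_params()] object.
#' @return A list with `cohort` (filtered) and `report`, a tibble with one
#'   row per panel and step giving the numbers of cells and images removed.
#'   If nothing survives, the report carries the flag column `empty = TRUE`
#'   rather than erroring.
#' @export
qc_filter <- function(x, params = qc_params()) {
  assert_that(inherits(x, "imc_cohort"), "`x` must be an `imc_cohort`.")
  assert_that(nrow(x$cells) > 0, "cohort has no cells")
  cells <- x$cells
  keep_area <- cells$area_px >= params$min_area_px &
    cells$area_px <= params$max_area_px
  removed_area <- cells[!keep_area, , drop = FALSE]
  cells <- cells[keep_area, , drop = FALSE]

  # image filter is applied per panel: each panel is an independent dataset.
  # Count against the pre-area-filter image list so an image losing every
  # cell to the area filter is still reported at the image step.
  counts <- x$cells |>
    dplyr::distinct(.data$panel, .data$image_id) |>
    left_join(cells |> count(.data$panel, .data$image_id, name = "n_cells"),
              by = c("panel", "image_id")) |>
    mutate(n_cells = dplyr::coalesce(.data$n_cells, 0L))
  low <- counts |> filter(.data$n_cells < params$min_cells_per_image)
  cells2 <- cells |> anti_join(low, by = c("panel", "image_id"))
  removed_img_cells <- cells |> inner_join(low, by = c("panel", "image_id"))

  report <- bind_rows(
    removed_area |> count(.data$panel, name = "n") |>
      mutate(step = "cells_by_area", unit = "cells"),
    low |> count(.data$panel, name = "n") |>
      mutate(step = "images_below_min_cells", unit = "images"),
    removed_img_cells |> count(.data$panel, name = "n") |>
      mutate(step = "cells_with_removed_images", unit = "cells")
  ) |> select("panel", "step", "unit", "n")

  # drop images that no longer have cells on any panel they were acquired for
  kept_images <- x$images |>
    dplyr::semi_join(cells2 |> dplyr::distinct(.data$image_id), by = "image_id")
  out <- cohort(cells2, kept_images, x$patients, validate = FALSE)
  if (nrow(cells2) == 0) {
    warn("QC removed every cell in the cohort")
    report$empty <- TRUE
  }
  list(cohort = out, report = as_tibble(report))
}
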