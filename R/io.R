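#' Read and write cohort tables
#'
#' A cohort on disk is a directory holding `cells`, `images` and
#' `patients` tables, either as UTF-8 comma-separated text with a header
#' row (`format = "csv"`) or as Parquet columnar files
#' (`format = "parquet"`). Schema and enum domains are validated on read;
#' a missing mandatory column raises a schema error naming the column, an
#' out-of-domain categorical value (e.g. an unknown tissue site) raises a
#' validation error.
#'
#' @param path Directory to read from / write into (created if absent).
#' @param format `"csv"` or `"parquet"`.
#' @param x An `imc_cohort`.
#' @return `read_cohort()` returns a validated `imc_cohort`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  rd <- function(name) {
    f <- file.path(path, paste0(name, if (format == "csv") ".csv" else ".parquet"))
    assert_that(file.exists(f), sprintf("missing cohort table file: %s", f),
                class = "imcpair_io_error")
    if (format == "csv") {
      readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    } else {
      arrow::read_parquet(f)
    }
  }
  cohort(rd("cells"), rd("images"), rd("patients"))
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  assert_that(inherits(x, "imc_cohort"), "`x` must be an `imc_cohort`.")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    f <- file.path(path, paste0(name, if (format == "csv") ".csv" else ".parquet"))
    if (format == "csv") {
      readr::write_csv(df, f, progress = FALSE)
    } else {
      arrow::write_parquet(df, f)
    }
  }
  wr(x$cells, "cells"); wr(x$images, "images"); wr(x$patients, "patients")
  invisible(path)
}

#' Read or write a tumor-stroma label mask
#'
#' Masks are single-channel images with integer labels 0 = background,
#' 1 = tumor, 2 = stroma. TIFF and PNG are supported; values are stored
#' as label/255 in the image file and recovered by rounding.
#'
#' @param path File path ending in `.tiff`/`.tif` or `.png`.
#' @param mask Integer matrix (rows = y, columns = x) with values in 0:2.
#' @return `read_mask()` returns an integer label matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    abort("mask must be a .tiff/.tif or .png file", class = "imcpair_io_error")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  bad <- setdiff(unique(as.vector(m)), 0:2)
  assert_that(length(bad) == 0,
              sprintf("mask contains labels outside {0,1,2}: %s",
                      paste(bad, collapse = ", ")),
              class = "imcpair_validation_error")
  m
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  assert_that(is.matrix(mask) && all(mask %in% 0:2),
              "mask must be a matrix with labels in {0,1,2}",
              class = "imcpair_validation_error")
  ext <- tolower(tools::file_ext(path))
  img <- mask / 255
  switch(ext,
    "tif" = , "tiff" = tiff::writeTIFF(img, path),
    "png" = png::writePNG(img, path),
    abort("mask must be written as .tiff/.tif or .png", class = "imcpair_io_error")
  )
  invisible(path)
}
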