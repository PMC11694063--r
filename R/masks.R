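#' Signed distance of cells to the tumor-stroma border
#'
#' For each cell the distance (in micrometers) from its centroid pixel to
#' the nearest pixel of the opposite compartment is computed on a
#' tumor/stroma label mask; the sign is positive for cells under the tumor
#' mask and negative for cells under the stroma mask. Cells whose centroid
#' falls on background pixels get `NA`. The centroid is mapped to the
#' pixel containing it (`floor(coordinate / pixel_size)`, 0-based
#' row-major grid with origin at the image's top-left corner).
#'
#' The distance transform is the exact Euclidean distance map of
#' [EBImage::distmap()]; only the signed lookup is done here.
#'
#' @param cells Cell table of one image with `x_um`, `y_um`.
#' @param mask Integer matrix, rows = y, columns = x, labels
#'   0 = background, 1 = tumor, 2 = stroma.
#' @param pixel_size_um Edge length of one mask pixel in micrometers.
#' @return `cells` with a `border_distance_um` column. If the mask holds
#'   only one of the two compartments no interface exists: all distances
#'   are `NA` and a warning is emitted.
#' @export
signed_border_distance <- function(cells, mask, pixel_size_um) {
  assert_that(pixel_size_um > 0, "pixel_size_um must be > 0",
              class = "imcpair_validation_error")
  assert_that(is.matrix(mask), "mask must be a matrix",
              class = "imcpair_validation_error")
  cells <- as_tibble(cells)

  has_tumor <- any(mask == 1L)
  has_stroma <- any(mask == 2L)
  if (!has_tumor || !has_stroma) {
    warn("mask contains only one of {tumor, stroma}; no interface exists, distances unset")
    cells$border_distance_um <- NA_real_
    return(cells)
  }

  # distance from every pixel to the nearest tumor / stroma pixel:
  # distmap(x) gives, per pixel, the distance to the nearest zero pixel of x
  d_to_tumor <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(mask != 1L), nrow(mask)))))
  d_to_stroma <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(mask != 2L), nrow(mask)))))

  # centroid pixel: 0-based floor convention, clamped to the grid
  px_col <- pmin(pmax(floor(cells$x_um / pixel_size_um), 0), ncol(mask) - 1L) + 1L
  px_row <- pmin(pmax(floor(cells$y_um / pixel_size_um), 0), nrow(mask) - 1L) + 1L
  idx <- cbind(px_row, px_col)
  lab <- mask[idx]

  out <- rep(NA_real_, nrow(cells))
  out[lab == 1L] <- d_to_stroma[idx][lab == 1L] * pixel_size_um
  out[lab == 2L] <- -d_to_tumor[idx][lab == 2L] * pixel_size_um
  cells$border_distance_um <- out
  cells
}
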