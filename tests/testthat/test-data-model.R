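test_that("QC area thresholds are inclusive retention bounds", {
  areas <- c(3L, 7L, 100L, 600L, 601L)
  cells <- tibble::tibble(
    cell_id = paste0("c", 1:5), image_id = "img1", panel = "tumor",
    x_um = 1:5, y_um = 1:5, area_px = areas, m1 = 1)
  images <- tibble::tibble(image_id = "img1", core_id = "k1", patient_id = "P1",
                           tissue_site = "PT", location = "intratumoral",
                           width_um = 10, height_um = 10)
  patients <- tibble::tibble(patient_id = "P1", molecular_subtype = "TN")
  co <- cohort(cells, images, patients)
  res <- qc_filter(co, qc_params(min_cells_per_image = 1))
  expect_setequal(res$cohort$cells$area_px, c(7L, 100L, 600L))
})

test_that("image filter boundary sits at the minimum cell count", {
  mk <- function(id, n) tibble::tibble(
    cell_id = paste0(id, "_", seq_len(n)), image_id = id, panel = "tumor",
    x_um = 1, y_um = 1, area_px = 50L, m1 = 1)
  images <- tibble::tibble(
    image_id = c("a", "b"), core_id = c("k1", "k2"), patient_id = "P1",
    tissue_site = "PT", location = "intratumoral", width_um = 10, height_um = 10)
  patients <- tibble::tibble(patient_id = "P1", molecular_subtype = "TN")
  co <- cohort(dplyr::bind_rows(mk("a", 100), mk("b", 99)), images, patients)
  res <- qc_filter(co)
  expect_setequal(unique(res$cohort$cells$image_id), "a")
  expect_equal(sum(res$cohort$cells$image_id == "a"), 100)
})

test_that("two-image toy cohort QC report matches the hand count", {
  res <- qc_filter(toy_qc_cohort())
  # img2: 60 cells removed by area, remaining 90 < 100 -> image removed
  rep <- res$report
  expect_equal(rep$n[rep$step == "cells_by_area"], 60)
  expect_equal(rep$n[rep$step == "images_below_min_cells"], 1)
  expect_equal(rep$n[rep$step == "cells_with_removed_images"], 90)
  expect_equal(nrow(res$cohort$cells), 120)
  expect_equal(res$cohort$images$image_id, "img1")
})

test_that("qc_filter is idempotent", {
  once <- qc_filter(toy_qc_cohort())
  twice <- qc_filter(once$cohort)
  expect_identical(as.data.frame(once$cohort$cells),
                   as.data.frame(twice$cohort$cells))
  expect_equal(sum(twice$report$n), 0)
})

test_that("cohort IO round-trips identifiers exactly and reals to 1e-12", {
  gen <- generate_cohort(synthetic_config(n_patients = 2, panels = "tumor",
                                          cells_per_image = 60, seed = 5))
  for (fmt in c("csv", "parquet")) {
    d <- withr::local_tempdir()
    write_cohort(gen$cohort, d, format = fmt)
    back <- read_cohort(d, format = fmt)
    expect_identical(back$cells$cell_id, gen$cohort$cells$cell_id)
    expect_identical(back$images$tissue_site, gen$cohort$images$tissue_site)
    expect_equal(nrow(back$cells), nrow(gen$cohort$cells))
    expect_equal(as.data.frame(back$cells), as.data.frame(gen$cohort$cells),
                 tolerance = 1e-12)
  }
})

test_that("schema and enum violations raise typed errors", {
  gen <- generate_cohort(synthetic_config(n_patients = 2, panels = "tumor",
                                          cells_per_image = 60, seed = 5))
  co <- gen$cohort
  expect_error(cohort(dplyr::select(co$cells, -"image_id"), co$images, co$patients),
               class = "imcpair_schema_error", regexp = "image_id")
  img <- co$images; img$tissue_site[1] <- "lung"
  expect_error(cohort(co$cells, img, co$patients),
               class = "imcpair_validation_error", regexp = "lung")
})

test_that("signed border distance matches the worked 4x4 example", {
  mask <- cbind(matrix(1L, 4, 2), matrix(2L, 4, 2))
  cells <- tibble::tibble(x_um = c(0.5, 3.5, 1.5), y_um = c(1.5, 1.5, 2.5))
  d <- signed_border_distance(cells, mask, 1)$border_distance_um
  expect_equal(d, c(2, -2, 1))  # adjacency case: tumor pixel next to stroma
})

test_that("signed border distance equals brute force on random masks", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      nr <- sample(8:64, 1); nc <- sample(8:64, 1)
      mask <- matrix(sample(0:2, nr * nc, replace = TRUE, prob = c(.1, .45, .45)),
                     nr, nc)
      cells <- tibble::tibble(x_um = runif(50, 0, nc * 2), y_um = runif(50, 0, nr * 2))
    })
    got <- signed_border_distance(cells, mask, 2)$border_distance_um
    expect_equal(got, brute_border_distance(cells, mask, 2), tolerance = 1e-9)
  }
})

test_that("single-compartment masks yield unset distances with a warning", {
  cells <- tibble::tibble(x_um = 1, y_um = 1)
  expect_warning(out <- signed_border_distance(cells, matrix(1L, 4, 4), 1),
                 regexp = "interface")
  expect_true(is.na(out$border_distance_um))
})
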