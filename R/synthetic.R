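#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a matched primary-tumor (PT) /
#' distant-metastasis imaging cohort: per patient, ~6 PT images spread
#' over the three annotated locations and ~2 intratumoral metastasis
#' images per metastatic site, on up to three antibody panels; a shared
#' patient-level ("founder") phenotype composition from which both sites
#' are drawn; optional site-specific and planted differential-abundance
#' log-fold effects; spatially clustered cell niches inside 500x500 um
#' images; and a tumor/stroma disc mask per image.
#'
#' The hierarchical model: patient i draws a latent composition
#' p_i ~ Dirichlet(alpha0); the PT sample draws its realized composition
#' ~ Dirichlet(theta * p_i) and each metastatic-site sample draws
#' ~ Dirichlet(theta * q_i) with q_i proportional to
#' p_i * exp(site_effect + planted_da). `founder_strength = 0` is the
#' no-linkage null: PT and metastasis compositions are drawn
#' independently from Dirichlet(alpha0).
#'
#' @param n_patients Number of patients (all with a matched pair).
#' @param panels Which antibody panels to simulate.
#' @param n_categories Named integer vector: phenotype categories per panel.
#' @param subtype_probs Probabilities over the four molecular subtypes.
#' @param site_probs Probabilities over the four metastatic sites.
#' @param n_sites_per_patient Metastatic sites sampled per patient.
#' @param founder_strength Dirichlet concentration theta linking a
#'   patient's PT and metastasis compositions (>= 0; 0 = null).
#' @param alpha0 Base Dirichlet concentration for latent compositions
#'   (scalar, recycled per category).
#' @param site_effect Named list mapping a metastatic site to a log-fold
#'   vector over categories (per panel: list of lists), or `NULL`.
#' @param planted_da Named numeric vector (per panel: list) of log-fold
#'   PT-to-metastasis effects applied to every metastatic sample, or `NULL`.
#' @param images_per_pt PT images per patient, spread evenly over
#'   intratumoral / stromal / margin locations.
#' @param images_per_met Metastasis images per site (intratumoral).
#' @param cells_per_image Mean of the negative-binomial cell count.
#' @param cells_dispersion Negative-binomial size parameter.
#' @param image_size_um Image edge length (square images).
#' @param niche_spec Optional list of niches, each
#'   `list(composition =, radius_um =, count =)`, planted per image (see
#'   [plant_niches()]); or `NULL` for spatially unstructured images.
#' @param marker_signatures Named list per panel: category x marker mean
#'   matrix; `NULL` builds near one-hot default signatures.
#' @param marker_noise_sd Log-normal noise sd on marker means.
#' @param mask_pixel_um Mask resolution; tumor discs on stroma background.
#' @param mask_n_discs,mask_disc_radius_um Tumor-disc count and radius.
#' @param seed Single global seed; all sub-draws derive from it by a
#'   counter-based stream, so module order never changes results.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 12L,
                             panels = c("tumor", "tcell", "myeloid"),
                             n_categories = c(tumor = 20L, tcell = 10L, myeloid = 10L),
                             subtype_probs = c(LumA = 0.4, LumB = 0.25, HER2 = 0.15, TN = 0.2),
                             site_probs = c(bone = 0.4, brain = 0.2, liver = 0.25, soft_tissue = 0.15),
                             n_sites_per_patient = 1L,
                             founder_strength = 50,
                             alpha0 = 1,
                             site_effect = NULL,
                             planted_da = NULL,
                             images_per_pt = 6L,
                             images_per_met = 2L,
                             cells_per_image = 500,
                             cells_dispersion = 20,
                             image_size_um = 500,
                             niche_spec = NULL,
                             marker_signatures = NULL,
                             marker_noise_sd = 0.3,
                             mask_pixel_um = 4,
                             mask_n_discs = 4L,
                             mask_disc_radius_um = 90,
                             seed = 1L) {
  assert_prob_vector(subtype_probs, "subtype_probs")
  assert_prob_vector(site_probs, "site_probs")
  assert_that(founder_strength >= 0, "founder_strength must be >= 0",
              class = "imcpair_validation_error")
  assert_that(image_size_um > 0, "image_size_um must be > 0",
              class = "imcpair_validation_error")
  assert_that(all(panels %in% panels()), "unknown panel name",
              class = "imcpair_validation_error")
  structure(as.list(environment()), class = "synthetic_config")
}

default_signatures <- function(n_cat, prefix) {
  n_marker <- max(n_cat, 10L)
  sig <- matrix(0.5, n_cat, n_marker,
                dimnames = list(paste0(prefix, "_c", seq_len(n_cat)),
                                paste0(prefix, "_m", seq_len(n_marker))))
  for (i in seq_len(n_cat)) {
    sig[i, ((i - 1L) %% n_marker) + 1L] <- 5
    sig[i, (i %% n_marker) + 1L] <- 2.5
  }
  sig
}

#' Draw matched PT / metastasis composition count tables
#'
#' The composition layer of the generator, exposed on its own: for each
#' patient a latent composition, a PT and a metastasis realized
#' composition under the founder model, and multinomial counts at a given
#' sequencing depth of cells. Used directly for calibration studies where
#' per-cell spatial data are not needed.
#'
#' @param n_patients Number of matched patients.
#' @param n_categories Number of phenotype categories.
#' @param theta Founder strength (0 = independent null).
#' @param cells_per_sample Multinomial total per sample.
#' @param alpha0 Base Dirichlet concentration.
#' @param met_log_effect Optional log-fold vector applied to the
#'   metastasis Dirichlet mean (site effect and/or planted effect).
#' @param seed RNG seed.
#' @return List with integer matrices `pt` and `met`
#'   (patient x category, rownames = patient ids) and the latent and
#'   realized compositions.
#' @export
sample_paired_compositions <- function(n_patients, n_categories, theta,
                                       cells_per_sample = 1000L,
                                       alpha0 = 1, met_log_effect = NULL,
                                       seed = 1L) {
  k <- n_categories
  eff <- met_log_effect %||% rep(0, k)
  assert_that(length(eff) == k, "met_log_effect length must equal n_categories",
              class = "imcpair_validation_error")
  with_seed(seed, {
    latent <- rdirichlet(n_patients, rep(alpha0, k))
    if (theta == 0) {
      pt_comp <- rdirichlet(n_patients, rep(alpha0, k))
      met_comp <- rdirichlet(n_patients, rep(alpha0, k))
    } else {
      pt_comp <- t(vapply(seq_len(n_patients),
                          function(i) rdirichlet(1, theta * latent[i, ])[1, ],
                          numeric(k)))
      met_mean <- sweep(latent, 2, exp(eff), `*`)
      met_mean <- met_mean / rowSums(met_mean)
      met_comp <- t(vapply(seq_len(n_patients),
                           function(i) rdirichlet(1, theta * met_mean[i, ])[1, ],
                           numeric(k)))
    }
    draw <- function(comp) {
      m <- t(vapply(seq_len(n_patients),
                    function(i) rmultinom(1, cells_per_sample, comp[i, ])[, 1],
                    numeric(k)))
      storage.mode(m) <- "integer"
      dimnames(m) <- list(paste0("P", seq_len(n_patients)), paste0("c", seq_len(k)))
      m
    }
    list(pt = draw(pt_comp), met = draw(met_comp),
         latent = latent, pt_comp = pt_comp, met_comp = met_comp)
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config A [synthetic_config()].
#' @return A list with `cohort` (an `imc_cohort`), `truth` (list:
#'   `patient_latent`, `sample_compositions`, `planted_da`,
#'   per-cell truth is carried in the cell table columns `true_category`
#'   and `true_niche`), and `masks` (named list of label matrices, one per
#'   image).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  cf <- config
  seed <- cf$seed

  patients <- with_seed(derive_seed(seed, "patients"), {
    tibble(
      patient_id = sprintf("P%02d", seq_len(cf$n_patients)),
      molecular_subtype = sample(names(cf$subtype_probs), cf$n_patients,
                                 replace = TRUE, prob = cf$subtype_probs)
    )
  })
  pat_sites <- with_seed(derive_seed(seed, "sites"), {
    lapply(seq_len(cf$n_patients), function(i)
      sample(names(cf$site_probs), cf$n_sites_per_patient, prob = cf$site_probs))
  })

  images <- list(); cells <- list(); masks <- list()
  sample_comp <- list(); latents <- list()

  for (panel in cf$panels) {
    k <- cf$n_categories[[panel]]
    cats <- paste0(panel, "_c", seq_len(k))
    sig <- cf$marker_signatures[[panel]] %||% default_signatures(k, panel)
    rownames(sig) <- cats
    site_eff <- function(site) {
      e <- cf$site_effect[[panel]][[site]] %||% rep(0, k)
      e + (cf$planted_da[[panel]] %||% rep(0, k))
    }

    for (i in seq_len(cf$n_patients)) {
      pid <- patients$patient_id[i]
      latent <- with_seed(derive_seed(seed, "latent", panel, i),
                          rdirichlet(1, rep(cf$alpha0, k))[1, ])
      latents[[paste(panel, pid)]] <-
        tibble(panel = panel, patient_id = pid, category = cats, p = latent)

      draw_comp <- function(eff, key) {
        with_seed(derive_seed(seed, "comp", panel, i, key), {
          if (cf$founder_strength == 0) {
            rdirichlet(1, rep(cf$alpha0, k))[1, ]
          } else {
            m <- latent * exp(eff); m <- m / sum(m)
            rdirichlet(1, cf$founder_strength * m)[1, ]
          }
        })
      }

      # one PT sample; one sample per metastatic site
      samples <- c(list(list(site = "PT", comp = draw_comp(rep(0, k), "PT"),
                             locs = rep(locations(), length.out = cf$images_per_pt),
                             n_img = cf$images_per_pt)),
                   lapply(pat_sites[[i]], function(s)
                     list(site = s, comp = draw_comp(site_eff(s), s),
                          locs = rep("intratumoral", cf$images_per_met),
                          n_img = cf$images_per_met)))

      for (smp in samples) {
        sample_comp[[length(sample_comp) + 1L]] <-
          tibble(panel = panel, patient_id = pid, tissue_site = smp$site,
                 category = cats, p = smp$comp)
        for (j in seq_len(smp$n_img)) {
          core <- sprintf("%s_%s_core%d", pid, smp$site, j)
          img_id <- sprintf("%s_%s", core, panel)
          img_seed <- derive_seed(seed, "image", panel, i, smp$site, j)
          im <- generate_image(img_id, smp$comp, cats, sig, cf, img_seed)
          images[[img_id]] <- tibble(
            image_id = img_id, core_id = core, patient_id = pid,
            tissue_site = smp$site, location = smp$locs[j],
            width_um = cf$image_size_um, height_um = cf$image_size_um)
          cells[[img_id]] <- im$cells
          masks[[img_id]] <- im$mask
        }
      }
    }
  }

  co <- cohort(bind_rows(cells), bind_rows(images), patients)
  truth <- list(
    patient_latent = bind_rows(latents),
    sample_compositions = bind_rows(sample_comp),
    metastatic_sites = tibble(patient_id = patients$patient_id,
                              sites = vapply(pat_sites, paste, "", collapse = ",")),
    planted_da = cf$planted_da
  )
  list(cohort = co, truth = truth, masks = masks)
}

# One image: cell count, uniform positions, (niche-aware) categories,
# marker draws, areas, and a tumor-disc mask.
generate_image <- function(img_id, comp, cats, sig, cf, seed) {
  with_seed(seed, {
    n <- max(1L, rnbinom(1, size = cf$cells_dispersion, mu = cf$cells_per_image))
    sz <- cf$image_size_um
    cells <- tibble(
      cell_id = sprintf("%s_cell%05d", img_id, seq_len(n)),
      image_id = img_id,
      panel = sub(".*_", "", img_id),
      x_um = runif(n, 0, sz), y_um = runif(n, 0, sz),
      area_px = pmax(1L, as.integer(round(rlnorm(n, log(50), 0.6))))
    )
    if (is.null(cf$niche_spec)) {
      cells$true_category <- sample(cats, n, replace = TRUE, prob = comp)
      cells$true_niche <- 0L
    } else {
      cells <- plant_niches_(cells, comp, cats, cf$niche_spec, sz)
    }
    expr <- sig[cells$true_category, , drop = FALSE] *
      matrix(rlnorm(n * ncol(sig), 0, cf$marker_noise_sd), n)
    colnames(expr) <- colnames(sig)
    cells <- bind_cols(cells, as_tibble(expr))
    cells$phenotype <- cells$true_category

    npx <- max(2L, ceiling(sz / cf$mask_pixel_um))
    mask <- matrix(2L, npx, npx)  # stroma background
    cx <- runif(cf$mask_n_discs, 0, sz); cy <- runif(cf$mask_n_discs, 0, sz)
    gx <- (col(mask) - 0.5) * cf$mask_pixel_um
    gy <- (row(mask) - 0.5) * cf$mask_pixel_um
    for (d in seq_len(cf$mask_n_discs)) {
      mask[(gx - cx[d])^2 + (gy - cy[d])^2 <= cf$mask_disc_radius_um^2] <- 1L
    }
    list(cells = cells, mask = mask)
  })
}

# Internal: niche assignment for freshly placed cells (RNG state inherited).
plant_niches_ <- function(cells, comp, cats, niche_spec, image_size_um) {
  n <- nrow(cells)
  centers <- list()
  for (ni in seq_along(niche_spec)) {
    sp <- niche_spec[[ni]]
    if (!is.null(sp$centers)) {
      cmat <- matrix(sp$centers, ncol = 2)
    } else {
      cnt <- sp$count %||% 1L
      cmat <- cbind(runif(cnt, 0, image_size_um), runif(cnt, 0, image_size_um))
    }
    for (b in seq_len(nrow(cmat))) {
      centers[[length(centers) + 1L]] <-
        list(niche = ni, x = cmat[b, 1], y = cmat[b, 2], r = sp$radius_um,
             comp = sp$composition)
    }
  }
  niche <- integer(n)
  if (length(centers) > 0) {
    dmat <- vapply(centers, function(ce)
      sqrt((cells$x_um - ce$x)^2 + (cells$y_um - ce$y)^2), numeric(n))
    dmat <- matrix(dmat, nrow = n)
    nearest <- max.col(-dmat, ties.method = "first")
    inside <- dmat[cbind(seq_len(n), nearest)] <=
      vapply(centers, `[[`, numeric(1), "r")[nearest]
    niche[inside] <- vapply(centers, `[[`, integer(1), "niche")[nearest[inside]]
  }
  cells$true_niche <- niche
  cat_draw <- character(n)
  bg <- niche == 0L
  cat_draw[bg] <- sample(cats, sum(bg), replace = TRUE, prob = comp)
  for (ni in unique(niche[niche > 0L])) {
    sel <- niche == ni
    cat_draw[sel] <- sample(cats, sum(sel), replace = TRUE,
                            prob = niche_spec[[ni]]$composition)
  }
  cells$true_category <- cat_draw
  cells
}

#' Plant spatial niches into an existing image's cells
#'
#' Cells whose position falls inside a niche blob redraw their category
#' from the blob's composition; background cells redraw from the image
#' composition. A cell inside overlapping blobs takes the nearest
#' center's niche. `true_niche` 0 marks background.
#'
#' @param cells Cell table of one image (positions already set).
#' @param composition Image-level (background) composition over `categories`.
#' @param categories Category names.
#' @param niche_spec List of `list(composition =, radius_um =, count =)`;
#'   an optional `centers` matrix (one row per blob, in um) fixes blob
#'   placement instead of sampling `count` centers uniformly.
#' @param image_size_um Image edge length.
#' @param seed RNG seed.
#' @return `cells` with redrawn `true_category` and a `true_niche` column.
#' @export
plant_niches <- function(cells, composition, categories, niche_spec,
                         image_size_um, seed = 1L) {
  for (sp in niche_spec) assert_prob_vector(sp$composition, "niche composition")
  assert_prob_vector(composition, "composition")
  with_seed(seed,
            plant_niches_(as_tibble(cells), composition, categories,
                          niche_spec, image_size_um))
}
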