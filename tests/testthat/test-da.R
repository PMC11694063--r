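# shared generator for paired-count fits: fixed condition-level proportions,
# negative-binomial counts, patient effects on totals only
sim_paired_counts <- function(seed, n_pat = 20, n_cat = 20, fold = 1,
                              target = 1, phi = 0.05, mean_total = 1000) {
  withr::with_seed(seed, {
    p <- rep(1 / n_cat, n_cat)
    q <- p; q[target] <- q[target] * fold; q <- q / sum(q)
    tot <- rnbinom(2 * n_pat, mu = mean_total, size = 10) + 200
    pr <- rbind(matrix(p, n_pat, n_cat, byrow = TRUE),
                matrix(q, n_pat, n_cat, byrow = TRUE))
    y <- matrix(rnbinom(2 * n_pat * n_cat, mu = pr * tot, size = 1 / phi),
                2 * n_pat)
    colnames(y) <- paste0("c", seq_len(n_cat))
    list(y = y,
         meta = data.frame(tissue_class = rep(c("PT", "metastasis"), each = n_pat),
                           patient_id = rep(seq_len(n_pat), 2)),
         planted_log2 = log2(q[target] / p[target]))
  })
}

test_that("a no-effect category fits to zero fold change", {
  d <- sim_paired_counts(1, fold = 1)
  # identical counts in both conditions: exact no-effect fit
  y2 <- rbind(d$y[1:20, ], d$y[1:20, ])
  f2 <- fit_da(y2, da_design(contrast = "metastasis"), sample_meta = d$meta)
  expect_lt(max(abs(f2$log2fc)), 1e-6)
  expect_true(all(f2$p_value > 0.99))
})

test_that("planted fourfold enrichment is recovered with controlled FDR", {
  res <- vapply(1:25, function(s) {
    d <- sim_paired_counts(s, fold = 4)
    f <- fit_da(d$y, da_design(contrast = "metastasis"), sample_meta = d$meta)
    c(err = abs(f$log2fc[f$category == "c1"] - d$planted_log2),
      hit = f$fdr[f$category == "c1"] < 0.05)
  }, numeric(2))
  expect_gte(mean(res["hit", ]), 0.95)
  expect_gte(mean(res["err", ] <= 0.3), 0.95)
})

test_that("complete-null simulations rarely flag any category", {
  flags <- vapply(1:40, function(s) {
    d <- sim_paired_counts(100 + s, fold = 1)
    f <- fit_da(d$y, da_design(contrast = "metastasis"), sample_meta = d$meta)
    sum(f$significant) > 0
  }, logical(1))
  expect_lte(mean(flags), 0.10)
})

test_that("swapping condition levels negates fold changes, keeps p-values", {
  d <- sim_paired_counts(7, fold = 3)
  f1 <- fit_da(d$y, da_design(contrast = "metastasis"), sample_meta = d$meta)
  f2 <- fit_da(d$y, da_design(contrast = "PT"), sample_meta = d$meta)
  expect_equal(f1$log2fc, -f2$log2fc, tolerance = 1e-8)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-8)
})

test_that("doubling counts and totals leaves fold changes unchanged", {
  d <- sim_paired_counts(8, fold = 2)
  des <- da_design(contrast = "metastasis")
  # offset handling isolated from dispersion re-estimation: exact invariance
  f1 <- fit_da(d$y, des, sample_meta = d$meta, dispersion = "none")
  f2 <- fit_da(2 * d$y, des, sample_meta = d$meta, dispersion = "none")
  expect_equal(f1$log2fc, f2$log2fc, tolerance = 1e-6)
  # with moment dispersion the NB weights shift slightly; still close
  g1 <- fit_da(d$y, des, sample_meta = d$meta)
  g2 <- fit_da(2 * d$y, des, sample_meta = d$meta)
  expect_lt(max(abs(g1$log2fc - g2$log2fc)), 0.03)
})

test_that("BH adjustment matches the step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p); adj <- numeric(n)
    prev <- 1
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      adj[o[i]] <- prev
    }
    adj
  }
  for (s in 1:10) {
    p <- withr::with_seed(s, runif(sample(3:20, 1)))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("fit_da agrees directionally with edgeR quasi-likelihood", {
  d <- sim_paired_counts(12, fold = 4)
  f <- fit_da(d$y, da_design(contrast = "metastasis"), sample_meta = d$meta)
  grp <- factor(d$meta$tissue_class, levels = c("PT", "metastasis"))
  pat <- factor(d$meta$patient_id)
  design <- model.matrix(~ pat + grp)
  dge <- edgeR::DGEList(counts = t(d$y))
  dge <- edgeR::estimateDisp(dge, design)
  qf <- edgeR::glmQLFTest(edgeR::glmQLFit(dge, design), coef = ncol(design))
  tt <- edgeR::topTags(qf, n = Inf, sort.by = "none")$table
  expect_equal(f$log2fc, tt$logFC, tolerance = 0.05)
  expect_gt(cor(-log10(f$p_value), -log10(tt$PValue)), 0.95)
  expect_equal(which.min(f$p_value), which.min(tt$PValue))
})

test_that("design errors, zero categories and rare categories are handled", {
  d <- sim_paired_counts(3)
  y <- d$y; y[, 2] <- 0L
  expect_warning(f <- fit_da(y, da_design(contrast = "metastasis"),
                             sample_meta = d$meta), regexp = "c2")
  expect_false("c2" %in% f$category)
  # confounded design: covariate identical to condition
  meta2 <- d$meta; meta2$dup <- d$meta$tissue_class
  expect_error(fit_da(d$y, da_design(covariates = c("patient_id", "dup"),
                                     contrast = "metastasis"),
                      sample_meta = meta2),
               class = "imcpair_design_error")
})

test_that("one-vs-rest flags a planted group enrichment and needs a rest", {
  withr::with_seed(21, {
    n_g1 <- 6; n_g2 <- 10; n_cat <- 12
    p <- rep(1 / n_cat, n_cat); q <- p; q[3] <- q[3] * 3; q <- q / sum(q)
    y <- rbind(
      matrix(rnbinom(n_g1 * n_cat, mu = 800 * matrix(q, n_g1, n_cat, byrow = TRUE),
                     size = 20), n_g1),
      matrix(rnbinom(n_g2 * n_cat, mu = 800 * matrix(p, n_g2, n_cat, byrow = TRUE),
                     size = 20), n_g2))
    colnames(y) <- paste0("c", seq_len(n_cat))
  })
  tab <- make_comp_table(y, "metastasis")
  tab$patient_id <- paste0("P", seq_len(nrow(y)))
  g <- rep(c("g1", "g2"), c(6, 10))
  res <- one_vs_rest_da(tab, g, tissue_covariate = NULL)
  hit <- res[res$group == "g1" & res$category == "c3", ]
  expect_true(hit$significant)
  expect_gt(hit$log2fc, 0)
  expect_error(one_vs_rest_da(tab, rep("g1", nrow(y)), tissue_covariate = NULL),
               class = "imcpair_design_error")
})
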