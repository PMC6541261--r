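nb_fixture <- function(n_genes = 500, frac_de = 0, seed = 1, ...) {
  simulate_counts(n_genes, n_rep = 4, dispersion = 0.1, frac_de = frac_de,
                  interaction_lfc = 2, seed = seed, ...)
}

test_that("expression filter equals a brute-force row scan", {
  set.seed(5)
  m <- matrix(rnbinom(100 * 8, mu = 30, size = 5), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  kept <- filter_low_expression(m, min_cpm = 10, min_samples = 3)
  cutoff <- 10 * mean(colSums(m)) / 1e6
  manual <- rownames(m)[vapply(seq_len(nrow(m)), function(i) {
    sum(m[i, ] >= cutoff) >= 3
  }, logical(1))]
  expect_identical(rownames(kept), manual)

  # all-zero gene removed; boundary gene with exactly min_samples kept
  m2 <- rbind(m, zero = 0L)
  expect_false("zero" %in% rownames(filter_low_expression(m2)))
})

test_that("TMM factors behave on symmetric, scaled and shifted libraries", {
  set.seed(7)
  base <- matrix(rnbinom(400 * 2, mu = 50, size = 5), 400, 2,
                 dimnames = list(NULL, c("a", "b")))
  rownames(base) <- sprintf("g%d", 1:400)
  same <- cbind(a = base[, 1], b = base[, 1])
  rownames(same) <- rownames(base)
  f <- tmm_factors(same)
  expect_equal(f$norm_factor, c(1, 1))

  # pure 2x depth difference is absorbed by library size
  doub <- cbind(a = base[, 1], b = 2L * base[, 1])
  rownames(doub) <- rownames(base)
  expect_equal(tmm_factors(doub)$norm_factor, c(1, 1))

  # geometric mean exactly 1
  cs <- nb_fixture(seed = 2)
  f2 <- tmm_factors(cs$counts)
  expect_lt(abs(exp(mean(log(f2$norm_factor))) - 1), 1e-12)

  # one sample with an inflated gene block gets a factor < 1
  infl <- base
  infl[1:40, 2] <- infl[1:40, 2] * 20L
  f3 <- tmm_factors(infl)
  expect_lt(f3$norm_factor[2], f3$norm_factor[1])
})

test_that("TMM and voom agree with the edgeR / limma reference", {
  skip_if_not_installed("edgeR")
  skip_if_not_installed("limma")
  cs <- nb_fixture(n_genes = 800, seed = 3)
  m <- corexpr:::as_count_matrix(filter_low_expression(cs$counts))
  f <- tmm_factors(m)
  ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(f$norm_factor, unname(ref), tolerance = 1e-10)

  design <- design_group_means(cs$samples)
  v <- voom_transform(m, design, f)
  dge <- edgeR::DGEList(m)
  dge$samples$norm.factors <- unname(ref)
  vref <- limma::voom(dge, design, span = 0.5)
  expect_equal(v$E, vref$E, tolerance = 1e-10)
  expect_lt(max(abs(v$weights - vref$weights) / vref$weights), 1e-6)

  fit <- fit_and_moderate(v)
  lref <- limma::eBayes(limma::lmFit(vref))
  expect_equal(fit$d0, lref$df.prior, tolerance = 1e-6)
  expect_equal(fit$s02, lref$s2.prior, tolerance = 1e-6)
  ct <- contrast_interaction(design, 7)
  res <- apply_contrast(fit, ct)
  cref <- limma::eBayes(limma::contrasts.fit(limma::lmFit(vref), ct))
  expect_equal(res$t, unname(cref$t[, 1]), tolerance = 1e-8)
  expect_equal(res$p_value, unname(cref$p.value[, 1]), tolerance = 1e-8)
})

test_that("logCPM arithmetic and weight positivity hold", {
  # count 0 at effective library 1e6
  expect_equal(log2(0.5 / (1e6 + 1) * 1e6), -1.0000014, tolerance = 1e-6)

  # homoscedastic regime: large counts with a fixed dispersion have a flat
  # log-scale variance, so the trend is flat and weights near-equal
  set.seed(9)
  mu <- 2^runif(2000, 10, 17)
  m <- sapply(1:8, function(j) rnbinom(2000, mu = mu, size = 50))
  dimnames(m) <- list(sprintf("g%d", 1:2000), sprintf("s%d", 1:8))
  samples <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
                            species = rep(c("A", "B"), each = 4),
                            day = 0, replicate = rep(1:4, 2))
  v <- voom_transform(m, design_group_means(samples), tmm_factors(m))
  expect_true(all(v$weights > 0))
  expect_lt(max(v$weights) / min(v$weights), 1.1)

  bad_design <- cbind(1, 1)[rep(1, 8), ]
  expect_error(voom_transform(m, bad_design, NULL),
               class = "corexpr_validation_error")
})

test_that("empirical-Bayes moderation recovers the prior and its limits", {
  set.seed(11)
  g <- 5000; d0 <- 4; s02 <- 2; dg <- 18
  sigma2 <- s02 * d0 / rchisq(g, d0)
  sg2 <- sigma2 * rchisq(g, dg) / dg
  pr <- corexpr:::fit_variance_prior(sg2, dg)
  expect_lt(abs(pr$d0 - d0) / d0, 0.15)
  expect_lt(abs(pr$s02 - s02) / s02, 0.15)

  # equal variances: degenerate prior
  pr0 <- corexpr:::fit_variance_prior(rep(2, 100), dg)
  expect_identical(pr0$d0, Inf)

  cs <- nb_fixture(seed = 4)
  de <- run_de(cs$counts, cs$samples)
  design <- design_group_means(cs$samples)
  ct <- contrast_interaction(design, 7)

  # d0 -> 0: moderated t equals the ordinary t
  fit0 <- fit_and_moderate(de$voom, prior_df = 0)
  r0 <- apply_contrast(fit0, ct)
  ord <- r0$logFC / (sqrt(fit0$sigma2) *
    vapply(seq_len(nrow(fit0$coefficients)), function(g) {
      sqrt(drop(crossprod(ct, fit0$cov_unscaled[, , g] %*% ct)))
    }, numeric(1)))
  expect_lt(max(abs(r0$t - ord)), 1e-10)

  # d0 = Inf: every gene shares the prior variance
  fitI <- fit_and_moderate(de$voom, prior_df = Inf)
  expect_true(all(abs(fitI$s2_post - fitI$s02) < 1e-12))
})

test_that("contrast machinery produces difference-of-differences vectors", {
  samples <- tidyr::crossing(species = c("A", "B"), day = c(0, 7, 14),
                             replicate = 1:2) |>
    dplyr::mutate(sample_id = sprintf("%s%d_%d", species, day, replicate))
  design <- design_group_means(samples)
  ct <- contrast_interaction(design, 7)
  expect_equal(ct[c("A_d7", "A_d0", "B_d7", "B_d0", "A_d14", "B_d14")],
               c(A_d7 = 1, A_d0 = -1, B_d7 = -1, B_d0 = 1,
                 A_d14 = 0, B_d14 = 0))
  expect_error(apply_contrast(
    fit_and_moderate(voom_transform(
      corexpr:::as_count_matrix(nb_fixture(50, seed = 6)$counts),
      design_group_means(nb_fixture(50, seed = 6)$samples), NULL)),
    rep(0, 6)), class = "corexpr_validation_error")
})

test_that("null moderated t-statistics follow their reference distribution", {
  cs <- nb_fixture(n_genes = 2000, frac_de = 0, seed = 33)
  de <- run_de(cs$counts, cs$samples)
  res <- de$results[["interaction_d14"]]
  ks <- stats::ks.test(res$t, function(q) pt(q, attr(res, "df_total")))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted interaction effects rank above null genes", {
  cs <- nb_fixture(n_genes = 1000, frac_de = 0.1, seed = 12)
  de <- run_de(cs$counts, cs$samples)
  res <- de$results[["interaction_d7"]]
  truth <- cs$truth[match(res$gene, cs$truth$gene), ]
  expect_gt(rank_auc(abs(res$t), truth$lfc != 0), 0.95)
})

test_that("BH adjustment is exact on the worked example and monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(13)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "corexpr_validation_error")
})

test_that("DE tables carry signed fold changes and round-trip", {
  cs <- nb_fixture(200, frac_de = 0.2, seed = 14)
  de <- run_de(cs$counts, cs$samples)
  res <- de$results[["interaction_d7"]]
  tab <- de_table(res)
  expect_equal(tab$FC, sign(tab$logFC) * 2^abs(tab$logFC))
  expect_true(all(diff(tab$p) >= 0))
  p <- tempfile(fileext = ".tsv")
  de_table(res, path = p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  expect_equal(back$logFC, tab$logFC, tolerance = 1e-6)
  expect_equal(back$t, tab$t, tolerance = 1e-6)
})

test_that("a pure depth change leaves log fold changes unchanged", {
  # doubling every library is a depth-only change; equivariance is exact up
  # to the log-transform offsets, whose O(1/count) perturbation is
  # negligible at deep coverage
  set.seed(15)
  mu <- 2^runif(400, 26, 28)
  m <- sapply(1:24, function(j) rnbinom(400, mu = mu, size = 20))
  dimnames(m) <- list(sprintf("g%03d", 1:400),
                      sprintf("%s_d%d_r%d", rep(c("A", "B"), each = 12),
                              rep(rep(c(0, 7, 14), each = 4), 2),
                              rep(1:4, 6)))
  samples <- tibble::tibble(sample_id = colnames(m),
                            species = rep(c("A", "B"), each = 12),
                            day = rep(rep(c(0, 7, 14), each = 4), 2),
                            replicate = rep(1:4, 6))
  design <- design_group_means(samples)
  run <- function(mm) {
    v <- voom_transform(mm, design, tmm_factors(mm))
    apply_contrast(fit_and_moderate(v), contrast_interaction(design, 7))
  }
  r1 <- run(m)
  r2 <- run(2 * m)
  expect_lt(max(abs(r1$logFC - r2$logFC)), 1e-8)
  expect_equal(tmm_factors(2 * m)$norm_factor, tmm_factors(m)$norm_factor,
               tolerance = 1e-10)
})

test_that("tidy and glance methods summarize fits", {
  cs <- nb_fixture(120, seed = 16)
  de <- run_de(cs$counts, cs$samples)
  res <- de$results[[1]]
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(diff(td$p_value) >= 0))
  gl <- glance(de$fit)
  expect_equal(gl$n_genes, nrow(de$voom$E))
  expect_true(gl$d0 > 0)
})
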