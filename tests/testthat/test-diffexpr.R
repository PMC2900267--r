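# The three moderated statistics, FDR conversion and conglomerate ranking.

test_that("ANOVA components match stats::aov gene by gene", {
  em <- toy_expression(n_genes = 12, group_sizes = c(4, 6, 5, 8, 8),
                       seed = 21)
  aovc <- anova_decomposition(em)
  g <- group_factor(em)
  for (i in seq_len(nrow(em$values))) {
    fit <- stats::anova(stats::aov(em$values[i, ] ~ g))
    expect_equal(aovc$ss_between[i], fit$`Sum Sq`[1], tolerance = 1e-10)
    expect_equal(aovc$ss_within[i], fit$`Sum Sq`[2], tolerance = 1e-10)
    expect_equal(aovc$ms_between[i] / aovc$s2[i], fit$`F value`[1],
                 tolerance = 1e-10)
  }
  expect_identical(aovc$df_between, 4L)
  expect_identical(aovc$df_within, 31L - 5L)
})

test_that("degenerate ANOVA inputs are handled by the variance floor", {
  m <- rbind(g1 = c(1, 1, 3, 3),        # zero within-group variance
             g2 = c(2, 2, 2, 2),        # fully constant
             g3 = c(1, 2, 3, 4))
  des <- data.frame(array_id = paste0("a", 1:4),
                    group = c("x", "x", "y", "y"))
  colnames(m) <- paste0("a", 1:4)
  aovc <- anova_decomposition(expression_matrix(m, des))
  f <- aovc$ms_between / aovc$s2
  expect_true(all(is.finite(f)))
  expect_gt(f[1], 1e10)                  # enormous but finite
  expect_equal(aovc$ss_between[2], 0)
  des1 <- data.frame(array_id = paste0("a", 1:4),
                     group = c("x", "x", "x", "y"))
  expect_error(expression_matrix(m, des1))
})

test_that("moderated F reduces to classical F without shrinkage and shrinks otherwise", {
  em <- toy_expression(n_genes = 40, group_sizes = c(3, 3, 4), seed = 8)
  aovc <- anova_decomposition(em)
  classical <- aovc$ms_between / aovc$s2
  no_shrink <- limma_moderated_f(aovc, d0 = 0, s02 = 1)
  expect_equal(no_shrink$f, classical, tolerance = 1e-12)

  # identical variances: shrinkage toward the common value is a no-op
  aov2 <- aovc
  aov2$s2 <- rep(0.5, 40)
  mod2 <- limma_moderated_f(aov2, d0 = 4, s02 = 0.5)
  expect_equal(mod2$f, aov2$ms_between / 0.5, tolerance = 1e-12)
})

test_that("variance prior estimation agrees with limma's squeezeVar", {
  skip_if_not_installed("limma")
  set.seed(31)
  df <- 26
  s2 <- 0.04 * rchisq(500, df) / df * exp(rnorm(500, 0, 0.4))
  prior <- fit_variance_prior(s2, df)
  sq <- limma::squeezeVar(s2, df)
  expect_equal(prior$d0, sq$df.prior, tolerance = 0.05)
  expect_equal(prior$s02, sq$var.prior, tolerance = 0.05)
  shrunk <- (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  expect_equal(shrunk, sq$var.post, tolerance = 0.01)
})

test_that("moderated-F p-values are uniform on null data", {
  ks_ok <- vapply(1:20, function(s) {
    sim <- simulate_expression(specs = list(), n_null = 500,
                               group_sizes = c(4, 6, 5, 8, 8), seed = s)
    aovc <- anova_decomposition(sim$expression)
    p <- limma_moderated_f(aovc)$p
    # KS statistic below the 1% critical value 1.63/sqrt(n)
    suppressWarnings(stats::ks.test(p, "punif")$statistic) <
      1.63 / sqrt(500)
  }, NA)
  expect_gte(mean(ks_ok), 0.95)
})

test_that("windowed regularization matches a direct enumeration oracle", {
  em <- toy_expression(n_genes = 5, group_sizes = c(3, 3), seed = 14)
  aovc <- anova_decomposition(em)
  reg <- cybert_f(aovc, window_size = 3L, n0 = 10)
  ord <- order(aovc$mean_expr)
  s2o <- aovc$s2[ord]
  # brute-force truncated windows around each position
  expected_bg <- sapply(seq_len(5), function(i)
    mean(s2o[max(1, i - 1):min(5, i + 1)]))
  expect_equal(reg$sigma0_2[ord], expected_bg, ignore_attr = TRUE)
  expected_reg <- (10 * expected_bg + aovc$df_within * s2o) /
    (10 + aovc$df_within)
  expect_equal(reg$reg_s2[ord], expected_reg, ignore_attr = TRUE)
})

test_that("windowed regularization reduces to classical F at n0 = 0 and tempers outliers", {
  em <- toy_expression(n_genes = 30, group_sizes = c(4, 4), seed = 2)
  aovc <- anova_decomposition(em)
  reg0 <- cybert_f(aovc, window_size = 5L, n0 = 0)
  expect_equal(reg0$f, aovc$ms_between / aovc$s2, tolerance = 1e-12)

  # a single low-variance gene among noisier neighbours gets pulled up
  aov2 <- aovc
  aov2$s2 <- rep(1, 30); aov2$s2[15] <- 1e-4
  aov2$mean_expr <- seq_len(30)   # fixed ordering
  reg <- cybert_f(aov2, window_size = 5L, n0 = 10)
  expect_gt(reg$reg_s2[15], aov2$s2[15])
  expect_error(cybert_f(aovc, window_size = 4L), "odd")
  expect_error(cybert_f(aovc, window_size = 51L), "larger")
})

test_that("d statistic reduces to |t| for two groups at s0 = 0", {
  em <- toy_expression(n_genes = 15, group_sizes = c(4, 5), seed = 6)
  aovc <- anova_decomposition(em)
  d <- tempro:::sam_d_stat(aovc$ms_between, aovc$s2, 0)
  g <- group_factor(em)
  for (i in seq_len(15)) {
    tt <- stats::t.test(em$values[i, g == levels(g)[1]],
                        em$values[i, g == levels(g)[2]],
                        var.equal = TRUE)
    expect_equal(d[i], abs(tt$statistic), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("permutation FDR is near 1 on complete-null data and reproducible", {
  sim <- simulate_expression(specs = list(), n_null = 200,
                             group_sizes = c(4, 6, 5, 8, 8), seed = 17)
  sam1 <- sam_multiclass(sim$expression, n_perm = 100, seed = 5)
  sam2 <- sam_multiclass(sim$expression, n_perm = 100, seed = 5)
  expect_identical(sam1, sam2)
  expect_gte(median(sam1$fdr), 0.8)
  expect_error(sam_multiclass(sim$expression, n_perm = 10), ">= 100")
})

test_that("beta-uniform mixture fit recovers the null proportion", {
  lambdas <- vapply(1:10, function(s) {
    set.seed(s)
    fit <- attr(allison_fdr(runif(2000)), "fit")
    fit$lambda
  }, 0)
  expect_gte(mean(lambdas > 0.9), 0.9)

  # strong signal: FDR near 0 at the top of the list
  set.seed(3)
  p <- c(rbeta(600, 0.05, 10), runif(1400))
  fdr <- allison_fdr(p)
  expect_lt(min(fdr), 0.01)
  expect_true(all(diff(fdr[order(p)]) >= 0))   # monotone in p
})

test_that("the mixture fallback is Benjamini-Hochberg on unfittable inputs", {
  # four points cannot support a 3-parameter mixture fit reliably; the
  # documented fallback must reproduce the textbook BH values
  p <- c(0.01, 0.02, 0.5, 1.0)
  fdr <- suppressWarnings(withCallingHandlers(
    allison_fdr(p),
    warning = function(w) {
      expect_match(conditionMessage(w), "Benjamini-Hochberg")
      invokeRestart("muffleWarning")
    }))
  expect_equal(as.numeric(fdr), c(0.04, 0.04, 2 / 3, 1.0),
               tolerance = 1e-12)
})

test_that("conglomerate ranking follows the mean of per-test ranks", {
  ranks <- rbind(c(1, 2, 3), c(2, 1, 4), c(3, 3, 1), c(4, 5, 2),
                 c(5, 4, 5))
  fdrs <- matrix(0.01, 5, 3)
  ids <- paste0("g", 1:5)
  # hand computation: scores 2, 7/3, 7/3, 11/3, 14/3 -> order g1,(g2,g3),g4,g5
  res <- conglomerate_rank(ranks, fdrs, ids)
  expect_equal(res$score, c(2, 7 / 3, 7 / 3, 11 / 3, 14 / 3))
  expect_identical(res$gene_id[order(res$rank)],
                   c("g1", "g2", "g3", "g4", "g5"))  # tie broken by id
  expect_identical(res$rank[1], 1L)

  # agreement case: identical orderings pass through
  r2 <- cbind(1:5, 1:5, 1:5)
  res2 <- conglomerate_rank(r2, fdrs, ids)
  expect_identical(res2$rank, 1:5)
  expect_error(conglomerate_rank(ranks[, 1:2], fdrs, ids), "three")
})

test_that("conglomerate FDR is the running-maximum median of per-test FDRs", {
  ranks <- cbind(1:4, 1:4, 1:4)
  fdrs <- rbind(c(0.01, 0.02, 0.90),   # median 0.02
                c(0.30, 0.01, 0.02),   # median 0.02
                c(0.01, 0.50, 0.60),   # median 0.50
                c(0.10, 0.20, 0.30))   # median 0.20 -> raised to 0.50
  res <- conglomerate_rank(ranks, fdrs, paste0("g", 1:4), alpha = 0.05)
  expect_equal(res$fdr, c(0.02, 0.02, 0.50, 0.50))
  expect_identical(res$de, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("power increases with planted amplitude", {
  tp <- vapply(c(0.5, 1, 2), function(amp) {
    mean(vapply(1:3, function(s) {
      specs <- default_profile_specs(n_genes = 10, amplitude = amp)
      sim <- simulate_expression(specs, n_null = 400, seed = 1000 + s)
      de <- de_analysis(quantile_normalize(sim$expression),
                        n_perm = 100, seed = s)
      planted <- names(sim$truth$gene_cluster)[
        sim$truth$gene_cluster != "null"]
      sum(de_genes(de) %in% planted)
    }, 0))
  }, 0)
  expect_true(all(diff(tp) >= 0))
})
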