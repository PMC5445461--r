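# SNR / t scoring, dispersion estimation and the naive NB LRT.

test_that("SNR matches hand arithmetic and boundary rules", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 2, 2, 5, 5, 5),
             c = rep(7, 6))
  g <- rep(c("x", "y"), each = 3)
  sc <- snr_scores(m, g)
  expect_equal(sc$snr[1], -1.5)           # means 2,5; sds 1,1
  expect_equal(sc$mean_g1[1], 2); expect_equal(sc$sd_g2[1], 1)
  # zero total SD means undefined, even when the group means differ
  expect_true(is.na(sc$snr[2]))
  expect_true(is.na(sc$snr[3]))           # constant gene excluded
  expect_error(snr_scores(m, c("x", "y", "y", "y", "y", "y")), "at least 2")
  expect_error(snr_scores(m, rep("x", 6)), "two sample groups")
})

test_that("SNR is antisymmetric under group swap and scale-invariant", {
  fx <- sim_fixture(n_genes = 200, seed = 31)
  nm <- normalize_counts(fx$cm, size_factors(fx$cm))
  s1 <- snr_scores(nm, fx$cm$group)$snr
  s2 <- snr_scores(nm, factor(fx$cm$group,
                              levels = rev(levels(fx$cm$group))))$snr
  expect_equal(s1, -s2)
  s3 <- snr_scores(nm * 7.3, fx$cm$group)$snr
  expect_equal(s1, s3)
})

test_that("empirical SNR of heavy replication converges to the analytic value", {
  truth <- inject_de(100, 1, c(2, 2), dispersion = 0.1, seed = 5)
  truth$fold_change <- 2; truth$direction <- "down"  # mu2 = mu1/2
  cm <- simulate_counts(truth, c(2000, 2000), seed = 6)
  emp <- snr_scores(cm$counts, cm$group)$snr
  expect_lt(abs(emp - snr_analytic(100, 2, 0.1)) / snr_analytic(100, 2, 0.1),
            0.05)
  expect_lte(abs(emp), snr_upper_bound(100, 0.1) * 1.02)
})

test_that("Welch t matches hand arithmetic and is scaling-invariant", {
  m <- rbind(a = c(1, 2, 3, 4, 5, 6))
  g <- rep(c("x", "y"), each = 3)
  tt <- t_scores(m, g)
  expect_equal(tt$t_stat, -3 / sqrt(2 / 3))
  expect_equal(tt$t_stat, unname(t.test(1:3, 4:6)$statistic))
  expect_equal(t_scores(m * 11, g)$t_stat, tt$t_stat)
  expect_equal(t_scores(rbind(c(1, 2, 3, 1, 2, 3)), g)$t_stat, 0)
})

test_that("moment dispersion inverts the NB variance relation", {
  s <- sqrt(15)
  m <- rbind(a = c(10 - s, 10 + s, 10 - s, 10 + s),  # mean 10, var 30
             b = c(5, 5, 7, 7),                      # variance below mean
             c = c(0, 0, 3, 3))                      # one group all zero
  g <- c("x", "x", "y", "y")
  est <- dispersion_mom(m, g)$alpha_mom
  expect_equal(est[1], 0.2)                          # (30 - 10) / 100
  expect_equal(est[2], 0)                            # clamped
  expect_equal(est[3], 0)                            # only group y informs
  z <- dispersion_mom(rbind(c(0, 0, 0, 0)), g)$alpha_mom
  expect_true(is.na(z))
})

test_that("moment dispersion recovers the simulated value at scale", {
  bm <- sample_base_means(10000, seed = 41)
  truth <- inject_de(bm, 0, c(1.3, 4), dispersion = 0.1)
  cm <- simulate_counts(truth, c(50, 50))
  est <- dispersion_mom(cm$counts, cm$group)$alpha_mom
  expect_gt(median(est, na.rm = TRUE), 0.085)
  expect_lt(median(est, na.rm = TRUE), 0.115)
})

test_that("profile-ML dispersion sits at the floor for Poisson genes", {
  bm <- sample_base_means(2000, seed = 51)
  truth <- inject_de(bm, 0, c(1.3, 4), dispersion = 0)
  cm <- simulate_counts(truth, c(10, 10))
  est <- dispersion_mle(cm$counts, cm$group)
  expect_gte(mean(est$alpha_mle < 1e-3, na.rm = TRUE), 0.9)
  expect_true(all(est$alpha_mle >= 0, na.rm = TRUE))
  expect_error(dispersion_mle(cm$counts[, c(1, 11)], c("a", "b")),
               "at least 2")
})

test_that("profile-ML dispersion recovers a positive simulated value", {
  bm <- sample_base_means(2000, seed = 52)
  truth <- inject_de(bm, 0, c(1.3, 4), dispersion = 0.3)
  cm <- simulate_counts(truth, c(10, 10))
  est <- dispersion_mle(cm$counts, cm$group)$alpha_mle
  expect_lt(abs(median(est, na.rm = TRUE) - 0.3) / 0.3, 0.2)
})

test_that("LRT is null for identical groups and all-zero genes", {
  m <- rbind(a = c(3, 1, 4, 3, 1, 4),
             b = rep(0, 6),
             c = c(10, 60, 20, 10, 60, 20))
  g <- rep(c("x", "y"), each = 3)
  res <- nb_lrt(m, g)
  expect_lt(res$lrt_stat[1], 1e-6)
  expect_gt(res$p_value[1], 0.999)
  expect_equal(res$lrt_stat[2], 0)
  expect_equal(res$p_value[2], 1)
  expect_lt(res$lrt_stat[3], 1e-6)
  expect_true(all(res$lrt_stat >= 0))
})

test_that("LRT statistics agree with a MASS::glm.nb oracle", {
  fx <- sim_fixture(n_genes = 120, dispersion = 0.1, seed = 61)
  sf <- size_factors(fx$cm)
  mine <- nb_lrt(fx$cm, sf = sf)
  g <- fx$cm$group
  oracle <- vapply(seq_len(120), function(i) {
    x <- fx$cm$counts[i, ]
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(x ~ g + offset(log(sf)))),
      error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    null <- suppressWarnings(
      stats::glm(x ~ 1 + offset(log(sf)),
                 family = MASS::negative.binomial(fit$theta)))
    max(0, 2 * (stats::logLik(fit)[1] - stats::logLik(null)[1]))
  }, numeric(1))
  ok <- !is.na(oracle)
  expect_gt(sum(ok), 100)
  expect_gt(cor(mine$lrt_stat[ok], oracle[ok]), 0.999)
  expect_lt(median(abs(mine$lrt_stat[ok] - oracle[ok])), 0.05)
})

test_that("LRT at vanishing dispersion matches a Poisson GLM oracle", {
  bm <- sample_base_means(500, seed = 71)
  truth <- inject_de(bm, 0.3, c(1.3, 4), dispersion = 0)
  cm <- simulate_counts(truth, c(7, 7))
  mine <- nb_lrt(cm)
  g <- cm$group
  oracle <- vapply(seq_len(500), function(i) {
    x <- cm$counts[i, ]
    fit <- stats::glm(x ~ g, family = stats::poisson())
    fit$null.deviance - fit$deviance
  }, numeric(1))
  expect_gt(cor(mine$lrt_stat, oracle), 0.99)
})

test_that("LRT separates true DE genes from nulls at FDR 0.05", {
  bm <- sample_base_means(2000, seed = 81)
  truth <- inject_de(bm, 0.3, c(4, 4), dispersion = 0.01)
  cm <- simulate_counts(truth, c(7, 7))
  res <- nb_lrt(cm, sf = size_factors(cm))
  sig <- res$fdr_q < 0.05
  expect_gt(mean(sig[truth$is_de]), mean(sig[!truth$is_de]))
  expect_gt(mean(sig[truth$is_de]), 0.9)
})

test_that("LRT handles unequal size factors through offsets", {
  bm <- sample_base_means(1500, seed = 91)
  truth <- inject_de(bm, 0, c(1.3, 4), dispersion = 0.05)
  depth <- c(rep(1, 7), rep(2.5, 7))   # group 2 sequenced deeper
  cm <- simulate_counts(truth, c(7, 7), depth_factors = depth)
  sf <- size_factors(cm)
  res <- nb_lrt(cm, sf = sf)
  # no DE truth: with offsets in place the deeper group must not look DE
  expect_lt(mean(res$fdr_q < 0.05), 0.01)
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("BH q-values follow the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})
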