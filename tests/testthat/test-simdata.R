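# Synthetic count generation: base means, DE injection, NB sampling,
# binomial thinning and gene-set partitions.

test_that("base means honor the file support and are reproducible", {
  f <- withr::local_tempfile(lines = c("10", "100", "1000"))
  drawn <- sample_base_means(50, f, seed = 7)
  expect_true(all(drawn %in% c(10, 100, 1000)))
  expect_identical(sample_base_means(5000, seed = 1),
                   sample_base_means(5000, seed = 1))
  bad <- withr::local_tempfile(lines = c("10", "-3", "100"))
  expect_error(sample_base_means(5, bad), "line 2")
  expect_error(sample_base_means(5, "no_such_mode"), "mean_source")
})

test_that("parametric means are heavy-tailed with the configured median", {
  bm <- sample_base_means(10000, seed = 1)
  expect_true(all(bm >= 1))
  # closed-form median of the generating log-normal is exp(meanlog) = 500;
  # truncation at 1 barely moves it
  expect_gt(median(bm), 250)
  expect_lt(median(bm), 1000)
  expect_gt(max(bm), 1e4)  # heavy right tail spans orders of magnitude
})

test_that("DE injection flags the exact count with in-range fold changes", {
  bm <- sample_base_means(10000, seed = 3)
  truth <- inject_de(bm, 0.3, c(1.3, 4), seed = 11)
  expect_equal(sum(truth$is_de), 3000)
  expect_true(all(truth$fold_change[truth$is_de] >= 1.3 &
                    truth$fold_change[truth$is_de] <= 4))
  expect_true(all(truth$fold_change[!truth$is_de] == 1))
  expect_true(all(truth$direction[!truth$is_de] == "none"))
  # up/down split inside the exact 99% binomial interval
  n_up <- sum(truth$direction == "up")
  ci <- qbinom(c(0.005, 0.995), 3000, 0.5)
  expect_gte(n_up, ci[1]); expect_lte(n_up, ci[2])
})

test_that("DE injection boundary and error cases", {
  truth <- inject_de(c(10, 20, 30), 0, c(1.3, 4), seed = 1)
  expect_equal(sum(truth$is_de), 0)
  expect_true(all(truth$fold_change == 1))
  expect_error(inject_de(c(10, 20), 1.2, c(1.3, 4)), "de_fraction")
  expect_error(inject_de(c(10, 20), 0.5, c(0.5, 4)), "fc_range")
})

test_that("simulated counts have Poisson and NB moments", {
  truth <- inject_de(100, 0, c(1.3, 4), dispersion = 0, seed = 1)
  cm <- simulate_counts(truth, c(5000, 5000), seed = 2)
  x <- as.vector(cm$counts)
  expect_gt(var(x) / mean(x), 0.95)  # dispersion index of Poisson(100)
  expect_lt(var(x) / mean(x), 1.05)
  truth$dispersion <- 0.3
  cm <- simulate_counts(truth, c(5000, 5000), seed = 3)
  v <- var(as.vector(cm$counts))
  expect_lt(abs(v - 3100) / 3100, 0.10)  # mu + alpha mu^2 = 3100
})

test_that("count simulation is seed-deterministic and validates input", {
  fx1 <- sim_fixture(n_genes = 200, seed = 5)
  fx2 <- sim_fixture(n_genes = 200, seed = 5)
  expect_identical(fx1$cm$counts, fx2$cm$counts)
  truth <- fx1$truth
  truth$dispersion <- -1
  expect_error(simulate_counts(truth, c(5, 5)), "dispersion")
})

test_that("group-2 means move by the fold change in the right direction", {
  bm <- rep(1000, 2000)
  truth <- inject_de(bm, 0.5, c(2, 2), dispersion = 0, seed = 9)
  cm <- simulate_counts(truth, c(50, 50), seed = 10)
  m2 <- rowMeans(cm$counts[, cm$group == "g2"])
  up <- truth$direction == "up"; down <- truth$direction == "down"
  expect_lt(max(abs(m2[up] - 2000) / 2000), 0.1)
  expect_lt(max(abs(m2[down] - 500) / 500), 0.2)
})

test_that("moment regression across genes recovers the dispersion", {
  bm <- sample_base_means(10000, seed = 21)
  truth <- inject_de(bm, 0, c(1.3, 4), dispersion = 0.1, seed = 22)
  cm <- simulate_counts(truth, c(25, 25), seed = 23)
  m <- rowMeans(cm$counts)
  v <- apply(cm$counts, 1, var)
  # inverse-variance-style weights keep the heavy-tailed means from letting
  # a handful of huge genes dominate the fit
  fit <- lm(I(v - m) ~ 0 + I(m^2), weights = 1 / m^4)
  expect_lt(abs(coef(fit)[[1]] - 0.1) / 0.1, 0.15)
})

test_that("binomial thinning: identity, degenerate and moment behavior", {
  fx <- sim_fixture(n_genes = 300, seed = 8)
  expect_identical(downsample(fx$cm, 1, seed = 1)$counts, fx$cm$counts)
  expect_true(all(downsample(fx$cm, 0, seed = 1)$counts == 0))
  m <- matrix(rpois(100, 10000), 100, 1)
  thin <- downsample(m, 0.1, seed = 4)
  tot <- sum(m)
  expect_lt(abs(sum(thin) - 0.1 * tot), 3 * sqrt(tot * 0.1 * 0.9))
  expect_error(downsample(m, 1.5), "fraction")
})

test_that("thinning a Poisson matrix leaves Poisson marginals", {
  x <- matrix(rpois(20000, 100), ncol = 1)
  thin <- downsample(x, 0.1, seed = 6)
  # chi-square goodness of fit against Poisson(10), tails pooled so every
  # expected cell count is comfortably large
  cat_of <- pmax(pmin(thin, 20), 2) - 1          # categories 1..19
  obs <- tabulate(cat_of, 19)
  p <- c(ppois(2, 10), dpois(3:19, 10), ppois(19, 10, lower.tail = FALSE))
  expect_gt(chisq.test(obs, p = p)$p.value, 0.001)
})

test_that("gene-set partition is disjoint, exhaustive and near-equal", {
  ids <- sprintf("g%05d", 1:10000)
  sets <- make_gene_sets(ids, 100, seed = 2)
  expect_length(sets, 100)
  expect_true(all(lengths(sets) == 100))
  expect_identical(sort(unlist(sets, use.names = FALSE)), ids)
  singles <- make_gene_sets(letters[1:10], 10, seed = 3)
  expect_true(all(lengths(singles) == 1))
  uneven <- make_gene_sets(letters[1:10], 3, seed = 4)
  expect_equal(sort(unname(lengths(uneven))), c(3, 3, 4))
  expect_error(make_gene_sets(letters[1:5], 6), "n_sets")
})

test_that("count_matrix rejects malformed input", {
  expect_error(count_matrix(matrix(c(1, -2, 3, 4), 2), c("a", "b")),
               "non-negative")
  expect_error(count_matrix(matrix(c(1.5, 2, 3, 4), 2), c("a", "b")),
               "integer")
  expect_error(count_matrix(matrix(1:4, 2), "a"), "one label per sample")
  expect_error(count_matrix(matrix(1:4, 2, dimnames = list(c("g", "g"), NULL)),
                            c("a", "b")), "duplicate")
})
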