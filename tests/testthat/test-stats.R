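test_that("paired t matches the closed form and rejects degenerate input", {
  d <- c(1, 2, 3, 6)
  res <- paired_t(d)
  # hand oracle: mean 3, sd sqrt(14/3), t = 3 / (sd / 2)
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(4)), tolerance = 1e-12)
  expect_equal(res$t, 2.77746, tolerance = 1e-5)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * pt(-abs(res$t), 3), tolerance = 1e-12)
  # symmetric differences: t = 0, p = 1
  sym <- c(-2, -1, 1, 2)
  expect_equal(paired_t(sym)$t, 0)
  expect_equal(paired_t(sym)$p, 1)
  expect_error(paired_t(c(1, 1, 1)), "variance")
  expect_error(paired_t(3), "two participants")
})

test_that("J correction is exact, monotone, and approaches 1", {
  # independent log-gamma oracle
  expect_equal(j_correction(25),
               exp(lgamma(12.5) - lgamma(12)) / sqrt(12.5),
               tolerance = 1e-15)
  expect_equal(j_correction(25), 0.969646, tolerance = 1e-6)
  a <- 2:200
  j <- j_correction(a)
  expect_true(all(diff(j) > 0))
  expect_true(all(j < 1))
  expect_gt(j_correction(1e6), 1 - 1e-6)
  # distinct from the common approximation at small a
  expect_gt(abs(j_correction(4) - (1 - 3 / (4 * 4 - 1))), 1e-4)
  expect_error(j_correction(1), "a > 1")
})

test_that("|g| = J(n-1) |t| / sqrt(n) identity holds for fuzzed inputs", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    d <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.1, 3))
    g <- hedges_g(d)
    t <- paired_t(d)$t
    expect_equal(abs(g), j_correction(n - 1) * abs(t) / sqrt(n),
                 tolerance = 1e-12)
    expect_equal(sign(g), sign(mean(d)))
  }
  expect_error(hedges_g(rep(2, 5)), "variance")
})

test_that("printed t statistics convert to the printed effect sizes", {
  expect_equal(round(hedges_g_from_t(2.23, 26), 2), 0.42)
  expect_equal(round(hedges_g_from_t(1.58, 22), 2), 0.32)
  expect_lt(hedges_g_from_t(0.01, 26), 0.01)
})

test_that("BCa bootstrap brackets the estimate and matches boot::boot.ci", {
  set.seed(43)
  d <- rnorm(24, 0.8, 1)
  ci <- bootstrap_ci_g(d, n_boot = 4000, seed = 7)
  expect_lt(ci$lo, ci$g)
  expect_gt(ci$hi, ci$g)
  expect_equal(ci$g, hedges_g(d))
  # independent implementation: boot package BCa on the same statistic
  skip_if_not_installed("boot")
  b <- boot::boot(d, function(x, i) hedges_g(x[i]), R = 4000)
  bc <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(ci$lo, bc[1], tolerance = 0.1)
  expect_equal(ci$hi, bc[2], tolerance = 0.1)
  expect_error(bootstrap_ci_g(rep(1, 10)), "variance")
})

test_that("BCa interval covers the true g at close to nominal rate", {
  set.seed(44)
  n <- 35
  true_g <- j_correction(n - 1) * 0.6 # population effect after correction
  hits <- vapply(1:120, function(i) {
    d <- rnorm(n, 0.6, 1)
    ci <- bootstrap_ci_g(d, n_boot = 600, seed = i)
    ci$lo <= true_g && true_g <= ci$hi
  }, logical(1))
  expect_gt(mean(hits), 0.88)
  expect_lt(mean(hits), 1.0)
})

test_that("AIC-based log Bayes factors are zero at reference, (dAIC)/2 off it", {
  set.seed(45)
  n <- 20
  mk <- function(vals) tibble::tibble(
    participant = rep(sprintf("P%02d", 1:n), 2),
    condition = rep(c("CSplus_USminus", "CSminus"), each = n),
    value = vals)
  noise <- rnorm(2 * n)
  signal <- c(rnorm(n, 1, 0.3), rnorm(n, 0, 0.3))
  cands <- list(ref = mk(signal + noise * 2),
                same = mk(signal + noise * 2),
                clean = mk(signal + rnorm(2 * n, 0, 0.2)))
  cmp <- aic_lbf(cands, reference = "ref")
  expect_equal(cmp$lbf[cmp$candidate == "ref"], 0)
  # identical candidate: LBF exactly 0 as well
  expect_equal(cmp$lbf[cmp$candidate == "same"], 0)
  # LBF is (AIC - AIC_ref) / 2 by construction
  expect_equal(cmp$lbf, (cmp$aic - cmp$aic[cmp$candidate == "ref"]) / 2)
  # cleaner measure of the same effect wins (negative LBF)
  expect_lt(cmp$lbf[cmp$candidate == "clean"], 0)
  # mismatched participant sets are rejected
  bad <- cands
  bad$clean <- bad$clean[bad$clean$participant != "P01", ]
  expect_error(aic_lbf(bad, reference = "ref"), "participant")
})

test_that("sign-based classification accuracy counts agreement with group sign", {
  expect_equal(classification_accuracy(c(2, 3, 0.5)), 1)
  expect_equal(classification_accuracy(c(1, 1, 1, -1)), 0.75)
  expect_equal(classification_accuracy(c(-1, -2, -3, 1)), 0.75) # negative group mean
  # exact zero counts against accuracy
  expect_equal(classification_accuracy(c(1, 1, 0, 1)), 0.75)
  # invariant under positive rescaling
  d <- c(0.3, -0.1, 0.8, 0.2)
  expect_equal(classification_accuracy(d * 17), classification_accuracy(d))
  expect_error(classification_accuracy(c(-1, 1)), "zero")
})

test_that("split-half reliability is 1 for noise-free heterogeneous cohorts", {
  n <- 10
  trialwise <- tidyr::expand_grid(
    participant = sprintf("P%02d", 1:n),
    condition = c("CSplus_USminus", "CSminus"),
    trial_id = 1:8)
  # participant-specific true values, zero measurement noise
  truth <- setNames(seq(1, 4, length.out = n), sprintf("P%02d", 1:n))
  trialwise$length_deg <- truth[trialwise$participant] +
    2 * (trialwise$condition == "CSplus_USminus") *
    seq(1, 3, length.out = n)[match(trialwise$participant, names(truth))]
  rel <- split_half_reliability(trialwise, n_rep = 50, seed = 2)
  expect_equal(rel$mean_r, 1)
  expect_error(split_half_reliability(trialwise[trialwise$participant %in%
                                                  c("P01", "P02"), ],
                                      n_rep = 10, seed = 1), "three")
})

test_that("split-half reliability is near zero for homogeneous cohorts", {
  set.seed(47)
  n <- 12
  trialwise <- tidyr::expand_grid(
    participant = sprintf("P%02d", 1:n),
    condition = c("CSplus_USminus", "CSminus"),
    trial_id = 1:8)
  # identical true difference for everyone, plus measurement noise
  trialwise$length_deg <- 5 +
    2 * (trialwise$condition == "CSplus_USminus") +
    rnorm(nrow(trialwise))
  rs <- vapply(1:40, function(i) {
    trialwise$length_deg <- 5 +
      2 * (trialwise$condition == "CSplus_USminus") + rnorm(nrow(trialwise))
    split_half_reliability(trialwise, n_rep = 20, seed = i)$mean_r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("split-half reliability matches the analytic mixed-model value", {
  # trial value = mu_i(cond) + eps; true difference varies tau across
  # participants; half-set differences are di + noise with noise variance
  # 2 sigma^2 / (k/2), shared di across halves, independent noise:
  # rho = tau^2 / (tau^2 + 4 sigma^2 / k)
  set.seed(48)
  n <- 40; k <- 16; tau <- 1; sigma <- 1.2
  rho <- tau^2 / (tau^2 + 4 * sigma^2 / k)
  rs <- vapply(1:25, function(i) {
    di <- rnorm(n, 0, tau)
    trialwise <- tidyr::expand_grid(
      participant = sprintf("P%02d", 1:n),
      condition = c("CSplus_USminus", "CSminus"),
      trial_id = seq_len(k))
    trialwise$length_deg <-
      di[as.integer(factor(trialwise$participant))] *
      (trialwise$condition == "CSplus_USminus") +
      rnorm(nrow(trialwise), 0, sigma)
    split_half_reliability(trialwise, n_rep = 40, seed = i)$mean_r
  }, numeric(1))
  expect_equal(mean(rs), rho, tolerance = 0.07)
})

test_that("reliability is invariant in expectation to participant order", {
  set.seed(49)
  n <- 8
  trialwise <- tidyr::expand_grid(
    participant = sprintf("P%02d", 1:n),
    condition = c("CSplus_USminus", "CSminus"),
    trial_id = 1:6)
  trialwise$length_deg <- rnorm(nrow(trialwise)) +
    2 * runif(n)[as.integer(factor(trialwise$participant))] *
    (trialwise$condition == "CSplus_USminus")
  r1 <- split_half_reliability(trialwise, n_rep = 300, seed = 5)$mean_r
  perm <- trialwise[order(rev(trialwise$participant)), ]
  r2 <- split_half_reliability(perm, n_rep = 300, seed = 6)$mean_r
  expect_equal(r1, r2, tolerance = 0.12)
})

test_that("measure correlations form a symmetric correlation matrix", {
  set.seed(50)
  diffs <- list(scanpath = rnorm(20), scr = rnorm(20), hpr = rnorm(20))
  m <- measure_correlations(diffs)
  expect_equal(dim(m), c(3, 3))
  expect_equal(diag(m), c(scanpath = 1, scr = 1, hpr = 1))
  expect_equal(m, t(m))
})
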