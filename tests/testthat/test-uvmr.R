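test_that("Wald ratios follow their closed form", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$ratio_se, 0.1)
  neg <- wald_ratio(-0.1, 0.01, 0.05, 0.01)
  expect_equal(neg$ratio, -0.5)
  expect_equal(neg$ratio_se, 0.1)      # SE unaffected by sign
  # second-order SE reduces to first-order when the exposure is exact
  so <- wald_ratio(0.1, 0, 0.05, 0.01, second_order = TRUE)
  expect_equal(so$ratio_se, 0.1)
  so2 <- wald_ratio(0.1, 0.02, 0.05, 0.01, second_order = TRUE)
  expect_gt(so2$ratio_se, 0.1)
  expect_error(wald_ratio(0, 0.01, 0.05, 0.01), "nonzero")
})

test_that("IVW matches the closed-form weighted least squares oracle", {
  h <- harmonized_data(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10), c(0.01, 0.01))
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-14)
  expect_equal(est$scale_factor, 1)    # Q = 0, no inflation
  expect_equal(est$se, sqrt(1 / sum((1 / 0.01^2) * c(0.1, 0.2)^2)),
               tolerance = 1e-14)

  # consensus: identical ratios give that ratio for any weights
  set.seed(2)
  bx <- runif(6, 0.05, 0.3); sy <- runif(6, 0.005, 0.05)
  hc <- harmonized_data(bx, rep(0.01, 6), 0.7 * bx, sy)
  expect_equal(mr_ivw(hc)$beta, 0.7, tolerance = 1e-12)

  # scale equivariance: doubling every se_y doubles the SE, beta unchanged
  h1 <- random_harmonized(12, seed = 5)
  h2 <- h1; h2$se_y <- 2 * h1$se_y
  e1 <- mr_ivw(h1, random_effects = FALSE); e2 <- mr_ivw(h2, random_effects = FALSE)
  expect_equal(e2$beta, e1$beta, tolerance = 1e-12)
  expect_equal(e2$se, 2 * e1$se, tolerance = 1e-12)
})

test_that("IVW equals the inverse-variance weighted mean of Wald ratios", {
  for (s in 1:20) {
    h <- random_harmonized(sample(4:25, 1), seed = s)
    d <- list(bx = h$beta_x[, 1], by = h$beta_y, sy = h$se_y)
    ratios <- d$by / d$bx
    w <- (d$sy / d$bx)^-2
    oracle <- sum(w * ratios) / sum(w)
    expect_equal(mr_ivw(h)$beta, oracle, tolerance = 1e-10)
  }
})

test_that("random-effects IVW never reports a smaller SE than fixed-effect", {
  for (s in 1:15) {
    h <- random_harmonized(sample(3:20, 1), seed = 100 + s, theta = 0.2)
    mre <- mr_ivw(h, random_effects = TRUE)
    fe <- mr_ivw(h, random_effects = FALSE)
    expect_gte(mre$se, fe$se)
    expect_gte(mre$scale_factor, 1)
    expect_equal(mre$beta, fe$beta, tolerance = 1e-14)
  }
})

test_that("Egger regression matches the weighted OLS oracle and is orientation-invariant", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.02 + 0.5 * bx
  h <- harmonized_data(bx, rep(0.01, 3), by, rep(0.01, 3))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.5, tolerance = 1e-10)
  expect_equal(est$intercept, 0.02, tolerance = 1e-10)
  expect_equal(est$scale_factor, 1)    # zero residuals -> truncated at 1

  # oracle via lm on a heteroskedastic fixture
  set.seed(7)
  j <- 12
  bx <- runif(j, 0.05, 0.3); sy <- runif(j, 0.01, 0.05)
  by <- 0.01 + 0.4 * bx + rnorm(j, 0, sy)
  h2 <- harmonized_data(bx, rep(0.01, j), by, sy)
  fit <- lm(by ~ bx, weights = 1 / sy^2)
  est2 <- mr_egger(h2)
  expect_equal(est2$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(est2$intercept, unname(coef(fit)[1]), tolerance = 1e-10)
  sm <- summary(fit)
  # lm scales by sigma always; the estimator truncates the multiplier at 1
  expected_se <- unname(sm$coefficients[, 2]) / sm$sigma * max(1, sm$sigma)
  expect_equal(c(est2$intercept_se, est2$se), expected_se, tolerance = 1e-10)

  # flipping the sign of any (bx, by) pair changes nothing
  h3 <- h2
  flip <- c(2, 5, 9)
  h3$beta_x[flip, 1] <- -h3$beta_x[flip, 1]
  h3$beta_y[flip] <- -h3$beta_y[flip]
  est3 <- mr_egger(h3)
  expect_equal(est3$beta, est2$beta, tolerance = 1e-12)
  expect_equal(est3$intercept, est2$intercept, tolerance = 1e-12)
  expect_equal(est3$pvalue, est2$pvalue, tolerance = 1e-12)

  expect_error(mr_egger(harmonized_data(c(0.1, 0.2), c(0.01, 0.01),
                                        c(0.1, 0.1), c(0.01, 0.01))),
               "at least 3")
})

test_that("weighted median interpolates correctly and resists invalid instruments", {
  # symmetric case
  h <- harmonized_data(rep(0.1, 3), rep(0.01, 3), 0.1 * c(0.4, 0.5, 0.6),
                       rep(0.01, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 0.5,
               tolerance = 1e-10)

  # brute-force interpolation oracle on random fixtures
  for (s in 1:10) {
    hh <- random_harmonized(sample(5:15, 1), seed = 300 + s)
    ratios <- hh$beta_y / hh$beta_x[, 1]
    w <- (hh$se_y / abs(hh$beta_x[, 1]))^-2
    expect_equal(mr_weighted_median(hh, n_boot = 20, seed = s)$beta,
                 oracle_weighted_median(ratios, w), tolerance = 1e-10)
  }

  # single dominant weight pins the estimate to that SNP's ratio
  hd <- harmonized_data(rep(0.1, 5), rep(0.01, 5),
                        0.1 * c(0.1, 0.3, 0.52, 0.8, 0.9),
                        c(1, 1, 1e-4, 1, 1))
  expect_equal(mr_weighted_median(hd, n_boot = 20, seed = 2)$beta, 0.52,
               tolerance = 1e-3)

  # 40% of instruments with strong directional pleiotropy: the weighted
  # median stays near the truth while the naive mean does not
  set.seed(88)
  j <- 30
  bx <- runif(j, 0.05, 0.2); sy <- rep(0.005, j)
  alpha <- c(rep(0, 18), rep(0.05, 12))
  by <- 0.5 * bx + alpha + rnorm(j, 0, sy)
  hp <- harmonized_data(bx, rep(0.005, j), by, sy)
  wm <- mr_weighted_median(hp, n_boot = 200, seed = 3)
  naive <- mean(by / bx)
  expect_lt(abs(wm$beta - 0.5), 0.05)
  expect_gt(abs(naive - 0.5), 0.1)

  # order invariance
  hperm <- hp
  set.seed(4); perm <- sample(j)
  hperm$beta_x <- hp$beta_x[perm, , drop = FALSE]
  hperm$se_x <- hp$se_x[perm, , drop = FALSE]
  hperm$beta_y <- hp$beta_y[perm]; hperm$se_y <- hp$se_y[perm]
  hperm$snp_ids <- hp$snp_ids[perm]
  expect_equal(mr_weighted_median(hperm, n_boot = 50, seed = 9)$beta,
               mr_weighted_median(hp, n_boot = 50, seed = 9)$beta,
               tolerance = 1e-12)
})

test_that("the weighted-median bootstrap is reproducible from its seed", {
  h <- random_harmonized(10, seed = 44)
  a <- mr_weighted_median(h, n_boot = 200, seed = 7)
  b <- mr_weighted_median(h, n_boot = 200, seed = 7)
  c <- mr_weighted_median(h, n_boot = 200, seed = 8)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_identical(a$seed, 7L)
})

test_that("the estimator battery agrees on clean data and degrades gracefully", {
  # perfectly proportional data -> three identical betas
  bx <- c(0.1, 0.15, 0.2, 0.25)
  h <- harmonized_data(bx, rep(0.01, 4), 0.3 * bx, rep(0.01, 4))
  uv <- run_uvmr(h, seed = 1, n_boot = 50)
  expect_equal(uv$ivw_mre$beta, 0.3, tolerance = 1e-10)
  expect_equal(uv$egger$beta, 0.3, tolerance = 1e-8)
  expect_equal(uv$weighted_median$beta, 0.3, tolerance = 1e-10)
  expect_true(uv$consistent)

  # simulated truth theta = 0.3: all three CIs cover it
  d <- generate_dataset(simulation_truth(theta = 0.3, j_instruments = 50,
                                         seed = 123))
  iv <- build_instruments(d$exposure, d$ld)
  hh <- harmonize(d$exposure, d$outcome, iv)
  uv2 <- run_uvmr(hh, seed = 5, n_boot = 300)
  for (est in list(uv2$ivw_mre, uv2$egger, uv2$weighted_median)) {
    expect_lt(est$ci_low, 0.3)
    expect_gt(est$ci_high, 0.3)
  }

  # two instruments: IVW only, the others reported infeasible
  h2 <- harmonized_data(c(0.1, 0.2), c(0.01, 0.01), c(0.03, 0.06),
                        c(0.01, 0.01))
  uv3 <- run_uvmr(h2, seed = 1)
  expect_s3_class(uv3$ivw_mre, "mr_estimate")
  expect_null(uv3$egger)
  expect_null(uv3$weighted_median)
  expect_match(uv3$notes, "infeasible")
})
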