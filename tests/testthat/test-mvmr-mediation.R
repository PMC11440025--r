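test_that("multivariable IVW reduces to univariable IVW with one exposure", {
  for (s in 1:10) {
    h <- random_harmonized(sample(5:20, 1), seed = 500 + s)
    uv <- mr_ivw(h, random_effects = FALSE)
    mv <- mvmr_ivw(h)
    expect_equal(unname(mv$betas), uv$beta, tolerance = 1e-10)
  }
})

test_that("multivariable IVW solves the weighted normal equations exactly", {
  # exact linear structure: by = 0.3 x1 + 0.2 x2, zero residuals
  x <- cbind(c(0.1, 0.2, 0.15, 0.3, 0.25), c(0.05, 0.1, 0.2, 0.1, 0.15))
  by <- 0.3 * x[, 1] + 0.2 * x[, 2]
  h <- harmonized_data(x, matrix(0.01, 5, 2), by, rep(0.01, 5),
                       exposure_name = c("x1", "x2"))
  mv <- mvmr_ivw(h)
  expect_equal(unname(mv$betas), c(0.3, 0.2), tolerance = 1e-12)
  expect_equal(mv$scale_factor, 1)

  # random heteroskedastic fixture against lm
  set.seed(9)
  j <- 25
  x2 <- cbind(runif(j, 0.02, 0.3), runif(j, 0.02, 0.3), runif(j, 0.02, 0.3))
  sy <- runif(j, 0.005, 0.05)
  by2 <- x2 %*% c(0.3, 0.2, 0) + rnorm(j, 0, sy)
  h2 <- harmonized_data(x2, matrix(0.01, j, 3), drop(by2), sy,
                        exposure_name = c("a", "b", "c"))
  mv2 <- mvmr_ivw(h2)
  fit <- lm(drop(by2) ~ 0 + x2, weights = 1 / sy^2)
  expect_equal(unname(mv2$betas), unname(coef(fit)), tolerance = 1e-10)

  # a duplicated exposure column is a collinearity error
  x3 <- cbind(x2[, 1], x2[, 1])
  h3 <- harmonized_data(x3, matrix(0.01, j, 2), drop(by2), sy)
  expect_error(mvmr_ivw(h3), "rank deficient")
  # more exposures than SNPs is refused
  h4 <- harmonized_data(matrix(runif(4), 2, 2), matrix(0.01, 2, 2),
                        c(0.1, 0.2), c(0.01, 0.01))
  expect_error(mvmr_ivw(h4), "more SNPs than exposures")
})

test_that("MVMR separates direct effects from mediated total effects", {
  # three exposures, truth (0.3, 0.2, 0): mean absolute bias small
  errs <- sapply(1:50, function(s) {
    set.seed(700 + s)
    j <- 40
    x <- cbind(runif(j, 0.05, 0.25), runif(j, 0.05, 0.25), runif(j, 0.05, 0.25))
    sy <- rep(0.01, j)
    by <- drop(x %*% c(0.3, 0.2, 0)) + rnorm(j, 0, sy)
    mvmr_ivw(harmonized_data(x, matrix(0.005, j, 3), by, sy))$betas -
      c(0.3, 0.2, 0)
  })
  # signed bias per exposure over replicates (errs is 3 x reps)
  expect_lt(max(abs(rowMeans(errs))), 0.02)
})

test_that("merged instruments re-clump the union by the best p across exposures", {
  st <- generate_paper_shaped_study(seed = 23, j_instruments = 10,
                                    j_mediator = 4, n_null = 6)
  ivs <- lapply(st$exposures, build_instruments, ld = st$ld)
  merged <- merge_instruments(ivs, st$exposures, st$ld)
  union_ids <- unique(unlist(lapply(ivs, function(s) s$snps$snp_id)))
  expect_setequal(merged$snps$snp_id, union_ids)  # disjoint loci: no pruning

  # add a perfect duplicate pair across two exposures: one survives
  e1 <- as.data.frame(st$exposures[[1]])
  e2 <- as.data.frame(st$exposures[[2]])
  iv1 <- ivs[[1]]$snps$snp_id[1]
  iv2 <- ivs[[2]]$snps$snp_id[1]
  e2$chrom[e2$snp_id == iv2] <- e1$chrom[e1$snp_id == iv1]
  e2$pos[e2$snp_id == iv2] <- e1$pos[e1$snp_id == iv1] + 1000L
  exps <- list(sumstats(e1, "A", "continuous"), sumstats(e2, "B", "continuous"))
  ld2 <- ld_matrix(e1$snp_id, data.frame(snp_a = iv1, snp_b = iv2, r2 = 1))
  ivs2 <- lapply(exps, build_instruments, ld = ld2)
  merged2 <- merge_instruments(ivs2, exps, ld2)
  expect_equal(sum(merged2$snps$snp_id %in% c(iv1, iv2)), 1L)
})

test_that("the coefficient product and proportion mediated obey their identities", {
  mk <- function(beta, se, exposure = "E", outcome = "Y") {
    structure(list(method = "ivw_mre", exposure = exposure, outcome = outcome,
                   beta = beta, se = se), class = "mr_estimate")
  }
  total <- mk(1.0, 0.05); em <- mk(0.4, 0.04, outcome = "M")
  mo <- mk(0.25, 0.03, exposure = "M")
  med <- two_step_mediation(total, em, mo, n_draws = 5000, seed = 3)
  expect_equal(med$beta_indirect, 0.4 * 0.25, tolerance = 1e-15)
  expect_equal(med$se_indirect,
               sqrt(0.4^2 * 0.03^2 + 0.25^2 * 0.04^2), tolerance = 1e-15)
  # identity: PM * total = em * mo, exactly
  expect_equal(med$proportion_mediated * med$beta_total,
               med$beta_em * med$beta_mo, tolerance = 1e-15)
  expect_equal(med$beta_direct, 1.0 - 0.1, tolerance = 1e-15)
  expect_true(med$pm_ci[1] < med$proportion_mediated &
                med$proportion_mediated < med$pm_ci[2])

  # null mediator path
  med0 <- two_step_mediation(total, mk(0, 0.04, outcome = "M"), mo,
                             n_draws = 1000, seed = 1)
  expect_equal(med0$beta_indirect, 0)
  expect_equal(med0$proportion_mediated, 0)

  expect_error(two_step_mediation(mk(0, 0.05), em, mo), "zero")

  # delta-method SE agrees with Monte-Carlo at large draws (within 5%)
  set.seed(10)
  draws <- rnorm(1e5, 0.4, 0.04) * rnorm(1e5, 0.25, 0.03)
  expect_lt(abs(sd(draws) - med$se_indirect) / med$se_indirect, 0.05)
})

test_that("published-style odds ratios give the expected mediated proportion", {
  # products of printed-rounded ORs: total 2.943, em 2.593, mo 1.04
  mk <- function(or, se) structure(list(method = "ivw_mre", exposure = "E",
                                        outcome = "Y", beta = log(or), se = se),
                                   class = "mr_estimate")
  med <- two_step_mediation(mk(2.943, 0.15), mk(2.593, 0.42), mk(1.04, 0.012),
                            n_draws = 2000, seed = 8)
  expect_equal(med$proportion_mediated, log(2.593) * log(1.04) / log(2.943),
               tolerance = 1e-12)
  expect_equal(med$proportion_mediated, 0.0346, tolerance = 0.01)
})

test_that("mediation eligibility requires three significant undismissed links", {
  grid <- data.frame(
    exposure = c("E", "E", "M"),
    outcome = c("Y", "M", "Y"),
    pvalue = c(1e-5, 1e-4, 0.01),
    dismissed = FALSE, stringsAsFactors = FALSE
  )
  expect_equal(nrow(mediation_eligibility(grid, "M")), 1L)

  weak <- grid; weak$pvalue[3] <- 0.2          # mediator -> outcome n.s.
  expect_equal(nrow(mediation_eligibility(weak, "M")), 0L)

  dis <- grid; dis$dismissed[1] <- TRUE        # pleiotropy dismissal blocks it
  expect_equal(nrow(mediation_eligibility(dis, "M")), 0L)
})

test_that("the Bonferroni rule reproduces the grid-wide threshold", {
  b <- bonferroni(0.001, 30)
  expect_equal(b$threshold, 0.05 / 30, tolerance = 1e-15)
  expect_equal(round(b$threshold, 4), 0.0017)
  expect_true(b$significant)

  b2 <- bonferroni(0.01, 30)                   # nominal only
  expect_false(b2$significant)
  expect_true(b2$nominal)

  b3 <- bonferroni(0.04, 1)                    # m = 1: significant == nominal
  expect_identical(b3$significant, b3$nominal)
  expect_error(bonferroni(0.01, 0), "at least 1")
})
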