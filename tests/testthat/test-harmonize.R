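# build matched exposure/outcome single-SNP tables with chosen alleles
pair_tables <- function(ea_x, oa_x, ea_y, oa_y, eaf_x = 0.3, eaf_y = 0.3,
                        beta_x = 0.1, beta_y = 0.05) {
  exp_df <- data.frame(snp_id = "rs1", chrom = "1", pos = 1e6,
                       effect_allele = ea_x, other_allele = oa_x,
                       eaf = eaf_x, beta = beta_x, se = 0.01,
                       pvalue = 1e-10, n = 1e5, stringsAsFactors = FALSE)
  out_df <- exp_df
  out_df$effect_allele <- ea_y; out_df$other_allele <- oa_y
  out_df$eaf <- eaf_y; out_df$beta <- beta_y; out_df$pvalue <- 0.01
  list(exposure = sumstats(exp_df, "X", "continuous"),
       outcome = sumstats(out_df, "Y", "binary"))
}

harmonize_pair <- function(...) {
  tb <- pair_tables(...)
  iv <- build_instruments(tb$exposure, ld_matrix("rs1"))
  harmonize(tb$exposure, tb$outcome, iv)
}

test_that("allele alignment matches a hand-built truth table", {
  # exposure A/G; every outcome allele pair, expected action and sign
  cases <- list(
    list(c("A", "G"), "kept",            +1),  # identical
    list(c("G", "A"), "sign-flipped",    -1),  # swapped
    list(c("T", "C"), "strand-flipped",  +1),  # complement
    list(c("C", "T"), "strand-flipped",  -1),  # complement + swapped
    list(c("A", "C"), "dropped-unmatched", NA),
    list(c("A", "T"), "dropped-unmatched", NA),
    list(c("C", "G"), "dropped-unmatched", NA),
    list(c("T", "G"), "dropped-unmatched", NA),
    list(c("G", "C"), "dropped-unmatched", NA),
    list(c("G", "T"), "dropped-unmatched", NA),
    list(c("C", "A"), "dropped-unmatched", NA),
    list(c("T", "A"), "dropped-unmatched", NA)
  )
  for (cs in cases) {
    h <- harmonize_pair("A", "G", cs[[1]][1], cs[[1]][2], beta_y = -0.05)
    act <- h$harmonization_log$action
    expect_identical(act, cs[[2]])
    if (!is.na(cs[[3]])) {
      expect_equal(h$n_snp, 1L)
      expect_equal(h$beta_y, cs[[3]] * -0.05)
    } else {
      expect_equal(h$n_snp, 0L)
    }
  }
})

test_that("swapped outcome alleles flip the outcome beta and frequency", {
  h <- harmonize_pair("A", "G", "G", "A", eaf_x = 0.3, eaf_y = 0.7,
                      beta_y = -0.05)
  expect_equal(h$beta_y, 0.05)
  expect_equal(h$eaf_y, 0.3)
})

test_that("ambiguous palindromes are eliminated, informative ones aligned by frequency", {
  # in-band frequency in either dataset (or missing) drops the SNP
  h_mid <- harmonize_pair("A", "T", "A", "T", eaf_x = 0.50, eaf_y = 0.50)
  expect_identical(h_mid$harmonization_log$action, "dropped-palindromic")
  h_edge <- harmonize_pair("C", "G", "C", "G", eaf_x = 0.30, eaf_y = 0.45)
  expect_identical(h_edge$harmonization_log$action, "dropped-palindromic")
  h_na <- harmonize_pair("A", "T", "A", "T", eaf_x = NA, eaf_y = 0.2)
  expect_identical(h_na$harmonization_log$action, "dropped-palindromic")

  # out-of-band, same side of 0.5 -> same orientation
  h_same <- harmonize_pair("A", "T", "A", "T", eaf_x = 0.2, eaf_y = 0.25,
                           beta_y = 0.04)
  expect_identical(h_same$harmonization_log$action, "kept")
  expect_equal(h_same$beta_y, 0.04)
  # opposite sides -> the outcome record is on the other strand orientation
  h_opp <- harmonize_pair("A", "T", "A", "T", eaf_x = 0.2, eaf_y = 0.8,
                          beta_y = 0.04)
  expect_identical(h_opp$harmonization_log$action, "sign-flipped")
  expect_equal(h_opp$beta_y, -0.04)

  # band (0, 1) drops every palindrome regardless of frequency
  tb <- pair_tables("A", "T", "A", "T", eaf_x = 0.1, eaf_y = 0.1)
  iv <- build_instruments(tb$exposure, ld_matrix("rs1"))
  h_all <- harmonize(tb$exposure, tb$outcome, iv, palindrome_eaf_band = c(0, 1))
  expect_equal(h_all$n_snp, 0L)
})

test_that("palindrome drop count equals the in-band palindrome count", {
  d <- generate_dataset(simulation_truth(j_instruments = 40, seed = 13,
                                         palindrome_frac = 0.25))
  iv <- build_instruments(d$exposure, d$ld)
  h <- harmonize(d$exposure, d$outcome, iv)
  sel <- as.data.frame(d$exposure)[match(iv$snps$snp_id, d$exposure$snp_id), ]
  pal <- toupper(sel$other_allele) == chartr("ACGT", "TGCA", sel$effect_allele)
  in_band <- sel$eaf > 0.42 & sel$eaf < 0.58
  expect_equal(sum(h$harmonization_log$action == "dropped-palindromic"),
               sum(pal & in_band))
})

test_that("Wald ratios are invariant to how the raw files polarize alleles", {
  base <- generate_dataset(simulation_truth(j_instruments = 20, seed = 8))
  iv <- build_instruments(base$exposure, base$ld)
  h0 <- harmonize(base$exposure, base$outcome, iv)
  ratios0 <- h0$beta_y / h0$beta_x[, 1]

  # re-polarize a random subset of the outcome file (swap alleles, negate
  # beta, reflect eaf): harmonization must undo it exactly
  set.seed(99)
  od <- as.data.frame(base$outcome)
  flip <- runif(nrow(od)) < 0.5
  tmp <- od$effect_allele[flip]
  od$effect_allele[flip] <- od$other_allele[flip]
  od$other_allele[flip] <- tmp
  od$beta[flip] <- -od$beta[flip]
  od$eaf[flip] <- 1 - od$eaf[flip]
  out2 <- sumstats(od, "outcome", "binary")
  h1 <- harmonize(base$exposure, out2, iv)
  expect_identical(h1$snp_ids, h0$snp_ids)
  expect_equal(h1$beta_y / h1$beta_x[, 1], ratios0, tolerance = 1e-12)

  # strand-flip the exposure file wholesale: kept Wald ratios unchanged
  edf <- as.data.frame(base$exposure)
  edf$effect_allele <- chartr("ACGT", "TGCA", edf$effect_allele)
  edf$other_allele <- chartr("ACGT", "TGCA", edf$other_allele)
  exp2 <- sumstats(edf, "exposure", "continuous")
  iv2 <- build_instruments(exp2, base$ld)
  h2 <- harmonize(exp2, base$outcome, iv2)
  expect_equal(h2$beta_y / h2$beta_x[, 1], ratios0, tolerance = 1e-12)
})

test_that("harmonizing already-harmonized data is the identity", {
  d <- generate_dataset(simulation_truth(j_instruments = 15, seed = 31,
                                         palindrome_frac = 0.2))
  iv <- build_instruments(d$exposure, d$ld)
  h1 <- harmonize(d$exposure, d$outcome, iv)
  # rebuild aligned outcome/exposure tables from the kept SNPs and re-run
  keep <- match(h1$snp_ids, d$exposure$snp_id)
  exp_df <- as.data.frame(d$exposure)[keep, ]
  out_df <- as.data.frame(d$outcome)[keep, ]
  out_df$effect_allele <- exp_df$effect_allele
  out_df$other_allele <- exp_df$other_allele
  out_df$beta <- h1$beta_y
  out_df$eaf <- h1$eaf_y
  exp2 <- sumstats(exp_df, "exposure", "continuous")
  out2 <- sumstats(out_df, "outcome", "binary")
  iv2 <- build_instruments(exp2, d$ld)
  h2 <- harmonize(exp2, out2, iv2)
  expect_identical(h2$snp_ids, h1$snp_ids)
  expect_equal(h2$beta_y, h1$beta_y, tolerance = 1e-15)
  expect_equal(h2$beta_x[, 1], h1$beta_x[, 1], tolerance = 1e-15)
})

test_that("multi-exposure harmonization intersects and aligns all datasets", {
  st <- generate_paper_shaped_study(seed = 17, j_instruments = 15,
                                    j_mediator = 5, n_null = 10)
  ivs <- lapply(st$exposures, build_instruments, ld = st$ld)
  merged <- merge_instruments(ivs, st$exposures, st$ld)
  hm <- harmonize_multi(st$exposures, st$outcomes$PTSD, merged)
  expect_equal(ncol(hm$beta_x), 3L)
  expect_equal(nrow(hm$beta_x), hm$n_snp)
  expect_identical(colnames(hm$beta_x), names(st$exposures))
  expect_true(all(hm$se_y > 0))

  # dropping a SNP from one exposure drops the row everywhere
  short <- subset_sumstats_drop(st$exposures[[2]], merged$snps$snp_id[1])
  hm2 <- harmonize_multi(list(st$exposures[[1]], short, st$exposures[[3]]),
                         st$outcomes$PTSD, merged)
  expect_equal(hm2$n_snp, hm$n_snp - 1L)
  expect_false(merged$snps$snp_id[1] %in% hm2$snp_ids)

  # re-polarizing one exposure's file leaves its aligned column identical
  edf <- as.data.frame(st$exposures[[2]])
  tmp <- edf$effect_allele
  edf$effect_allele <- edf$other_allele
  edf$other_allele <- tmp
  edf$beta <- -edf$beta
  edf$eaf <- 1 - edf$eaf
  flipped <- sumstats(edf, names(st$exposures)[2], "continuous")
  hm3 <- harmonize_multi(list(st$exposures[[1]], flipped, st$exposures[[3]]),
                         st$outcomes$PTSD, merged)
  expect_identical(hm3$snp_ids, hm$snp_ids)
  expect_equal(hm3$beta_x[, 2], hm$beta_x[, 2], tolerance = 1e-15)

  # too few SNPs for the exposure count is an explicit infeasibility error
  tiny <- lapply(st$exposures, function(e)
    sumstats(as.data.frame(e)[1:3, ], attr(e, "trait_name"), "continuous"))
  iv_tiny <- build_instruments(tiny[[1]], st$ld)
  expect_error(harmonize_multi(tiny, st$outcomes$PTSD, iv_tiny), "infeasible")
})
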