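#' Multivariable IVW Mendelian randomization
#'
#' Weighted multiple regression of the outcome effects on the SNPs x
#' exposures matrix of exposure effects, no intercept, weights `1/se_y^2`.
#' Each coefficient is the direct effect of that exposure with the others
#' held fixed. Per-exposure SEs are inflated by `max(1, residual SD)`
#' (multiplicative overdispersion, truncated at 1) and tested against a
#' two-sided normal. With a single exposure this reduces exactly to the
#' univariable IVW point estimate.
#'
#' @param h a `harmonized` object, typically from [harmonize_multi]; needs
#'   `n_snp > ncol(beta_x)` and a full-column-rank effect matrix.
#' @return an object of class `mvmr_estimate`: list with `exposure_names`,
#'   `betas`, `ses`, `pvalues`, `ci_low`, `ci_high`, `or` (and bounds),
#'   `n_snp`, `scale_factor`.
#' @export
mvmr_ivw <- function(h) {
  x_mat <- h$beta_x
  k <- ncol(x_mat)
  j <- nrow(x_mat)
  if (j <= k) stop("mvmr_ivw: need more SNPs than exposures", call. = FALSE)
  w <- 1 / h$se_y^2
  xw <- x_mat * sqrt(w)
  if (qr(xw)$rank < k) {
    stop("mvmr_ivw: exposure effect matrix is rank deficient (collinear exposures)",
         call. = FALSE)
  }
  xtwx <- crossprod(xw)
  betas <- drop(solve(xtwx, crossprod(x_mat, w * h$beta_y)))
  resid <- h$beta_y - drop(x_mat %*% betas)
  dispersion <- sqrt(sum(w * resid^2) / (j - k))
  infl <- max(1, dispersion)
  ses <- sqrt(diag(solve(xtwx))) * infl
  pvalues <- 2 * stats::pnorm(-abs(betas / ses))
  z <- stats::qnorm(0.975)
  structure(list(
    exposure_names = colnames(x_mat),
    outcome_name = h$outcome_name,
    betas = stats::setNames(betas, colnames(x_mat)),
    ses = stats::setNames(ses, colnames(x_mat)),
    pvalues = stats::setNames(pvalues, colnames(x_mat)),
    ci_low = betas - z * ses,
    ci_high = betas + z * ses,
    or = exp(betas),
    or_low = exp(betas - z * ses),
    or_high = exp(betas + z * ses),
    n_snp = j,
    scale_factor = infl
  ), class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("Multivariable IVW on %s (%d SNPs):\n", x$outcome_name, x$n_snp))
  for (i in seq_along(x$betas)) {
    cat(sprintf("  %-20s beta %.4f (se %.4f), OR %.3f (%.3f, %.3f), p = %.3g\n",
                x$exposure_names[i], x$betas[i], x$ses[i],
                x$or[i], x$or_low[i], x$or_high[i], x$pvalues[i]))
  }
  invisible(x)
}

#' Merge per-exposure instrument sets for multivariable MR
#'
#' Union of the instrument SNPs of several exposures, re-clumped jointly with
#' each SNP ranked by its smallest p-value across exposures (ties broken by
#' snp_id), so correlated instruments contributed by different exposures
#' collapse to one representative.
#'
#' @param instrument_sets list of `instrument_set` objects.
#' @param exposures the matching list of exposure [sumstats] tables.
#' @param ld an [ld_matrix].
#' @param r2_max,window_kb clumping parameters.
#' @return an `instrument_set` over the merged SNPs (records taken from the
#'   first exposure carrying each SNP; `f_stats` from the ranking exposure).
#' @export
merge_instruments <- function(instrument_sets, exposures, ld,
                              r2_max = 0.001, window_kb = 10000) {
  all_ids <- unique(unlist(lapply(instrument_sets, function(s) s$snps$snp_id)))
  # per-SNP minimum p across exposures, plus a representative record
  rec_list <- lapply(instrument_sets, function(s) as.data.frame(s$snps))
  recs <- do.call(rbind, rec_list)
  min_p <- tapply(recs$pvalue, recs$snp_id, min)
  rep_rows <- recs[!duplicated(recs$snp_id), ]
  rep_rows$pvalue <- as.numeric(min_p[rep_rows$snp_id])
  merged <- sumstats(rep_rows, trait_name = paste(
    vapply(instrument_sets, function(s) s$exposure_name, ""), collapse = "+"),
    trait_type = "continuous")
  clumped <- ld_clump(merged, ld, r2_max = r2_max, window_kb = window_kb)
  f <- f_statistic(clumped$beta, clumped$se)
  structure(list(
    exposure_name = attr(merged, "trait_name"),
    snps = clumped,
    f_stats = stats::setNames(f, clumped$snp_id),
    r2_explained = stats::setNames(variance_explained(f, clumped$n), clumped$snp_id),
    p_threshold = min(vapply(instrument_sets, function(s) s$p_threshold, 0)),
    f_min = min(vapply(instrument_sets, function(s) s$f_min, 0)),
    selection_log = c(input = length(all_ids),
                      removed_overlap = 0L,
                      removed_pvalue = 0L,
                      removed_clump = length(all_ids) - nrow(clumped),
                      removed_weak = 0L,
                      retained = nrow(clumped))
  ), class = "instrument_set")
}

#' Two-step mediation MR by product of coefficients
#'
#' Combines three univariable MR estimates — exposure to outcome (total),
#' exposure to mediator, and mediator to outcome — into an indirect effect
#' `beta_em * beta_mo`, its delta-method SE
#' `sqrt(beta_em^2 se_mo^2 + beta_mo^2 se_em^2)`, and the proportion mediated
#' `indirect / total`. The proportion's interval comes from seeded
#' Monte-Carlo propagation (each of the three betas redrawn from its normal,
#' ratio recomputed, 2.5/97.5 percentiles taken) because the ratio is skewed
#' when the total effect is imprecise.
#'
#' @param beta_total,beta_em,beta_mo `mr_estimate` objects for the three
#'   links; `beta_total$beta` must be nonzero.
#' @param n_draws Monte-Carlo draws for the proportion CI (default 10000).
#' @param seed RNG seed, recorded in the result.
#' @return an object of class `mediation_result`: list with the three input
#'   betas, `beta_indirect`, `se_indirect`, `indirect_p`, `beta_direct`
#'   (difference-derived), `proportion_mediated`, `pm_ci`, `seed`.
#' @export
two_step_mediation <- function(beta_total, beta_em, beta_mo,
                               n_draws = 10000, seed = 1L) {
  if (beta_total$beta == 0) {
    stop("two_step_mediation: total effect is zero; proportion undefined",
         call. = FALSE)
  }
  beta_indirect <- beta_em$beta * beta_mo$beta
  se_indirect <- sqrt(beta_em$beta^2 * beta_mo$se^2 +
                        beta_mo$beta^2 * beta_em$se^2)
  indirect_p <- if (se_indirect > 0) {
    2 * stats::pnorm(-abs(beta_indirect / se_indirect))
  } else as.numeric(beta_indirect != 0)
  pm <- beta_indirect / beta_total$beta
  pm_draws <- with_seed(seed, {
    em <- stats::rnorm(n_draws, beta_em$beta, beta_em$se)
    mo <- stats::rnorm(n_draws, beta_mo$beta, beta_mo$se)
    tot <- stats::rnorm(n_draws, beta_total$beta, beta_total$se)
    em * mo / tot
  })
  pm_ci <- unname(stats::quantile(pm_draws, c(0.025, 0.975)))
  structure(list(
    exposure = beta_total$exposure,
    mediator = beta_em$outcome,
    outcome = beta_total$outcome,
    beta_total = beta_total$beta,
    se_total = beta_total$se,
    beta_em = beta_em$beta,
    beta_mo = beta_mo$beta,
    beta_indirect = beta_indirect,
    se_indirect = se_indirect,
    indirect_p = indirect_p,
    beta_direct = beta_total$beta - beta_indirect,
    proportion_mediated = pm,
    pm_ci = pm_ci,
    seed = as.integer(seed)
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total %.4f, indirect %.4f (se %.4f), direct %.4f\n",
              x$beta_total, x$beta_indirect, x$se_indirect, x$beta_direct))
  cat(sprintf("  proportion mediated %.2f%% (95%% CI %.2f%%, %.2f%%)\n",
              100 * x$proportion_mediated, 100 * x$pm_ci[1], 100 * x$pm_ci[2]))
  invisible(x)
}

#' Identify triples eligible for mediation analysis
#'
#' A triple (exposure, mediator, outcome) qualifies when the exposure-outcome,
#' exposure-mediator, and mediator-outcome IVW links are all significant at
#' `alpha` and none of the three was dismissed by the pleiotropy rule.
#'
#' @param grid data frame of IVW results with columns `exposure`, `outcome`,
#'   `pvalue`, and logical `dismissed`.
#' @param mediators character vector of trait names allowed as mediators.
#' @param alpha significance level per link (default 0.05).
#' @return data frame with columns `exposure`, `mediator`, `outcome` (zero
#'   rows when nothing qualifies).
#' @export
mediation_eligibility <- function(grid, mediators, alpha = 0.05) {
  stopifnot(all(c("exposure", "outcome", "pvalue", "dismissed") %in% names(grid)))
  ok <- function(e, o) {
    row <- grid[grid$exposure == e & grid$outcome == o, , drop = FALSE]
    nrow(row) > 0L && row$pvalue[1L] < alpha && !isTRUE(row$dismissed[1L])
  }
  exposures <- setdiff(unique(grid$exposure), mediators)
  outcomes <- setdiff(unique(grid$outcome), mediators)
  out <- list()
  for (e in exposures) for (m in mediators) for (y in outcomes) {
    if (ok(e, y) && ok(e, m) && ok(m, y)) {
      out[[length(out) + 1L]] <- data.frame(exposure = e, mediator = m,
                                            outcome = y,
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(exposure = character(0), mediator = character(0),
                      outcome = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Bonferroni multiplicity rule
#'
#' Threshold `0.05/m`; a p-value below it is study-wide significant, one
#' below 0.05 but not below the threshold is nominally significant.
#'
#' @param p p-value(s).
#' @param m number of comparisons (e.g. 30 for a 3-exposure x 10-outcome
#'   grid, giving threshold 0.0017 to two significant figures).
#' @return list with `threshold`, `significant`, `nominal` (vectorized over
#'   `p`).
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("bonferroni: m must be at least 1", call. = FALSE)
  threshold <- 0.05 / m
  list(threshold = threshold, significant = p < threshold, nominal = p < 0.05)
}
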