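#' Cochran's Q heterogeneity statistic
#'
#' Inverse-variance-weighted residual sum of squares around the fitted IVW
#' (through-origin) or Egger (with-intercept) regression:
#' `Q = sum(w_j (by_j - yhat_j)^2)` with `w_j = 1/se_y_j^2`, referred to a
#' chi-square with `n_snp - 1` (IVW) or `n_snp - 2` (Egger) degrees of
#' freedom. Large Q flags heterogeneity of the per-SNP causal estimates,
#' which under a multiplicative random-effects IVW widens the interval
#' rather than invalidating the estimate.
#'
#' @param h a `harmonized` object (single exposure).
#' @param model `"ivw"` (needs 2 SNPs) or `"egger"` (needs 3).
#' @return list with `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, model = c("ivw", "egger")) {
  model <- match.arg(model)
  d <- single_beta_x(h)
  j <- length(d$bx)
  w <- 1 / d$sy^2
  if (model == "ivw") {
    if (j < 2L) stop("cochran_q: IVW Q needs at least 2 instruments", call. = FALSE)
    beta <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
    resid <- d$by - beta * d$bx
    df <- j - 1L
  } else {
    if (j < 3L) stop("cochran_q: Egger Q needs at least 3 instruments", call. = FALSE)
    flip <- sign(d$bx); flip[flip == 0] <- 1
    bx <- d$bx * flip; by <- d$by * flip
    x_mat <- cbind(1, bx)
    coefs <- drop(solve(crossprod(x_mat * sqrt(w)), crossprod(x_mat, w * by)))
    resid <- by - drop(x_mat %*% coefs)
    df <- j - 2L
  }
  q <- sum(w * resid^2)
  list(Q = q, df = df, p = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the IVW (multiplicative random effects) causal effect with
#' each SNP excluded in turn; a single influential variant shows up as an
#' exclusion that moves the estimate or flips its sign.
#'
#' @param h a `harmonized` object with at least 2 SNPs.
#' @return list with `estimates` (data frame: snp_id, beta_excluding,
#'   se_excluding, p_excluding), `full_beta`, and `sign_stable` (TRUE when
#'   every leave-one-out beta keeps the full-set sign).
#' @export
leave_one_out <- function(h) {
  d <- single_beta_x(h)
  j <- length(d$bx)
  if (j < 2L) stop("leave_one_out: at least 2 instruments required", call. = FALSE)
  full <- mr_ivw(h)
  rows <- lapply(seq_len(j), function(k) {
    hk <- subset_harmonized(h, -k)
    est <- mr_ivw(hk)
    data.frame(snp_id = h$snp_ids[k], beta_excluding = est$beta,
               se_excluding = est$se, p_excluding = est$pvalue,
               stringsAsFactors = FALSE)
  })
  est <- do.call(rbind, rows)
  list(estimates = est, full_beta = full$beta,
       sign_stable = all(sign(est$beta_excluding) == sign(full$beta)))
}

# row-subset a harmonized object
subset_harmonized <- function(h, idx) {
  out <- h
  out$snp_ids <- h$snp_ids[idx]
  out$beta_x <- h$beta_x[idx, , drop = FALSE]
  out$se_x <- h$se_x[idx, , drop = FALSE]
  out$beta_y <- h$beta_y[idx]
  out$se_y <- h$se_y[idx]
  out$eaf_x <- h$eaf_x[idx]
  out$eaf_y <- h$eaf_y[idx]
  out$n_snp <- length(out$beta_y)
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (inverse first-order ratio
#' SE); asymmetry of the funnel suggests directional pleiotropy.
#'
#' @param h a `harmonized` object (single exposure).
#' @return data frame with `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  d <- single_beta_x(h)
  if (length(d$bx) < 1L) stop("funnel_data: no instruments", call. = FALSE)
  wr <- wald_ratio(d$bx, d$sx, d$by, d$sy)
  data.frame(snp_id = h$snp_ids, ratio = wr$ratio,
             precision = 1 / wr$ratio_se, stringsAsFactors = FALSE)
}

# leave-one-out fixed-effect IVW slopes for every SNP at once:
# beta_(-j) = (S1 - w_j bx_j by_j) / (S2 - w_j bx_j^2)
loo_ivw_beta <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-and-outlier test for horizontal pleiotropy. The observed
#' statistic is `RSS = sum_j w_j (by_j - beta_(-j) bx_j)^2` with `beta_(-j)`
#' the leave-one-out IVW slope and `w_j = 1/se_y_j^2`. Its null distribution
#' is simulated: in each of `n_sim` rounds, `bx*_j ~ N(bx_j, se_x_j)` and
#' `by*_j ~ N(beta_(-j) bx_j, se_y_j)` are drawn and the statistic recomputed
#' identically. The global p-value is the add-one empirical tail probability
#' (so never exactly 0). The per-SNP outlier test compares each observed
#' residual with its simulated counterparts as a plain empirical proportion
#' (the original formulation of the method), Bonferroni-multiplied by the
#' number of SNPs: with an add-one numerator the smallest attainable adjusted
#' p would be `n_snp/(n_sim+1)`, which for typical instrument counts exceeds
#' 0.05 and would make outliers undetectable at moderate `n_sim`. When
#' outliers are found, the IVW (multiplicative random effects) estimate is
#' recomputed without them.
#'
#' @param h a `harmonized` object with at least 4 SNPs.
#' @param n_sim simulated null datasets (default 1000).
#' @param outlier_alpha significance level for the Bonferroni-adjusted
#'   per-SNP outlier test (default 0.05).
#' @param seed RNG seed, recorded in the result.
#' @return an object of class `presso_result`: list with `rss_observed`,
#'   `global_p`, `n_sim`, `per_snp_p` (adjusted), `outliers`,
#'   `corrected_estimate` (`NULL` when no outliers), `seed`.
#' @export
mr_presso <- function(h, n_sim = 1000, outlier_alpha = 0.05, seed = 1L) {
  d <- single_beta_x(h)
  j <- length(d$bx)
  if (j < 4L) stop("mr_presso: at least 4 instruments required", call. = FALSE)
  w <- 1 / d$sy^2
  beta_loo <- loo_ivw_beta(d$bx, d$by, w)
  r_obs <- w * (d$by - beta_loo * d$bx)^2
  rss_obs <- sum(r_obs)

  sims <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(j * n_sim, d$bx, d$sx), nrow = j)
    by_star <- matrix(stats::rnorm(j * n_sim, beta_loo * d$bx, d$sy), nrow = j)
    # per-column leave-one-out slopes, vectorized over simulations
    s1 <- colSums(w * bx_star * by_star)
    s2 <- colSums(w * bx_star^2)
    beta_loo_star <- (rep(s1, each = j) - w * bx_star * by_star) /
      (rep(s2, each = j) - w * bx_star^2)
    r_star <- w * (by_star - beta_loo_star * bx_star)^2
    list(r_star = r_star, rss_star = colSums(r_star))
  })
  global_p <- (1 + sum(sims$rss_star >= rss_obs)) / (n_sim + 1)
  per_snp_raw <- rowSums(sims$r_star >= r_obs) / n_sim
  per_snp_adj <- pmin(1, per_snp_raw * j)
  outliers <- h$snp_ids[per_snp_adj < outlier_alpha]

  corrected <- NULL
  if (length(outliers) > 0L) {
    keep <- !(h$snp_ids %in% outliers)
    if (sum(keep) >= 1L) corrected <- mr_ivw(subset_harmonized(h, keep))
  }
  structure(list(
    rss_observed = rss_obs,
    global_p = global_p,
    n_sim = n_sim,
    per_snp_p = stats::setNames(per_snp_adj, h$snp_ids),
    outliers = outliers,
    corrected_estimate = corrected,
    seed = as.integer(seed)
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.3f, global p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_p, x$n_sim))
  if (length(x$outliers) > 0L) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected_estimate)) {
      cat("  outlier-corrected "); print(x$corrected_estimate)
    }
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Bundles Cochran's Q (IVW and, when feasible, Egger form), the Egger
#' intercept test, leave-one-out estimates, funnel data, and MR-PRESSO.
#' Each diagnostic is read against the conventional 0.05 level.
#'
#' @param h a `harmonized` object (single exposure).
#' @param n_sim MR-PRESSO simulation count.
#' @param seed RNG seed for MR-PRESSO.
#' @return an object of class `sensitivity_report`: list with `q_ivw`,
#'   `q_egger`, `egger_intercept` (list alpha/se/p), `loo`, `funnel`,
#'   `presso` (components `NULL` when instrument counts fall short).
#' @export
sensitivity_report <- function(h, n_sim = 1000, seed = 1L) {
  j <- h$n_snp
  q_ivw <- if (j >= 2L) cochran_q(h, "ivw") else NULL
  q_egger <- if (j >= 3L) cochran_q(h, "egger") else NULL
  intercept <- if (j >= 3L) {
    e <- mr_egger(h)
    list(alpha = e$intercept, se = e$intercept_se, p = e$intercept_p)
  } else NULL
  loo <- if (j >= 2L) leave_one_out(h) else NULL
  funnel <- if (j >= 1L) funnel_data(h) else NULL
  presso <- if (j >= 4L) mr_presso(h, n_sim = n_sim, seed = seed) else NULL
  structure(list(q_ivw = q_ivw, q_egger = q_egger,
                 egger_intercept = intercept, loo = loo,
                 funnel = funnel, presso = presso),
            class = "sensitivity_report")
}
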