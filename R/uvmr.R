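new_mr_estimate <- function(method, n_snp, beta, se, pvalue,
                            intercept = NULL, intercept_se = NULL,
                            intercept_p = NULL, scale_factor = 1,
                            ci_quantile = stats::qnorm(0.975),
                            exposure = NA_character_, outcome = NA_character_,
                            seed = NA_integer_) {
  ci_low <- beta - ci_quantile * se
  ci_high <- beta + ci_quantile * se
  structure(list(
    method = method,
    exposure = exposure,
    outcome = outcome,
    n_snp = n_snp,
    beta = beta,
    se = se,
    ci_low = ci_low,
    ci_high = ci_high,
    pvalue = pvalue,
    or = exp(beta),
    or_low = exp(ci_low),
    or_high = exp(ci_high),
    intercept = intercept,
    intercept_se = intercept_se,
    intercept_p = intercept_p,
    scale_factor = scale_factor,
    seed = seed
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (se %.4f), OR = %.3f (%.3f, %.3f), p = %.3g, nSNP = %d\n",
              x$method, x$beta, x$se, x$or, x$or_low, x$or_high, x$pvalue, x$n_snp))
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    exposure = x$exposure, outcome = x$outcome, method = x$method,
    n_snp = x$n_snp, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    or = x$or, or_low = x$or_low, or_high = x$or_high,
    egger_intercept = if (is.null(x$intercept)) NA_real_ else x$intercept,
    egger_intercept_p = if (is.null(x$intercept_p)) NA_real_ else x$intercept_p,
    scale_factor = x$scale_factor,
    stringsAsFactors = FALSE
  )
}

single_beta_x <- function(h) {
  if (ncol(h$beta_x) != 1L) {
    stop("univariable estimator applied to multi-exposure instruments", call. = FALSE)
  }
  list(bx = unname(h$beta_x[, 1L]), sx = unname(h$se_x[, 1L]),
       by = unname(h$beta_y), sy = unname(h$se_y))
}

#' Per-SNP Wald ratio
#'
#' The single-instrument causal estimate `beta_y / beta_x`. The first-order
#' standard error `se_y / |beta_x|` ignores exposure uncertainty (the
#' dominant convention, adequate for strong instruments); the second-order
#' form adds the `beta_y^2 se_x^2 / beta_x^4` term.
#'
#' @param beta_x,se_x exposure effect and SE; `beta_x` must be nonzero.
#' @param beta_y,se_y outcome effect and SE.
#' @param second_order include the exposure-uncertainty term in the SE.
#' @return list with `ratio` and `ratio_se` (vectorized).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE) {
  if (any(beta_x == 0)) {
    stop("wald_ratio: beta_x must be nonzero (degenerate instrument)", call. = FALSE)
  }
  ratio <- beta_y / beta_x
  ratio_se <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  list(ratio = ratio, ratio_se = ratio_se)
}

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome on exposure effects through the origin with
#' weights `1/se_y^2`:
#' `beta = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `se = 1 / sqrt(sum(w bx^2))`. With multiplicative random effects (the
#' default, and the primary model of the pipeline) the SE is inflated by
#' `max(1, sqrt(Q / (J - 1)))` where Q is Cochran's Q at the estimate, so
#' balanced heterogeneity widens the interval but never narrows it. P-values
#' are two-sided normal. A single SNP degrades to the Wald ratio.
#'
#' @param h a `harmonized` object (single exposure).
#' @param random_effects multiplicative random effects on/off.
#' @return an `mr_estimate` (`method` `"ivw_mre"` or `"ivw_fe"`).
#' @export
mr_ivw <- function(h, random_effects = TRUE) {
  d <- single_beta_x(h)
  j <- length(d$bx)
  if (j == 0L) stop("mr_ivw: no instruments", call. = FALSE)
  w <- 1 / d$sy^2
  sw_bx2 <- sum(w * d$bx^2)
  beta <- sum(w * d$bx * d$by) / sw_bx2
  se_fe <- sqrt(1 / sw_bx2)
  scale_factor <- 1
  if (random_effects && j >= 2L) {
    q <- sum(w * (d$by - beta * d$bx)^2)
    scale_factor <- max(1, sqrt(q / (j - 1)))
  }
  se <- se_fe * scale_factor
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (random_effects) "ivw_mre" else "ivw_fe",
                  j, beta, se, pvalue, scale_factor = scale_factor,
                  exposure = paste(h$exposure_names, collapse = "+"),
                  outcome = h$outcome_name)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an intercept
#' (weights `1/se_y^2`), after orienting every SNP so the exposure effect is
#' non-negative. The slope is the causal estimate under the InSIDE
#' assumption; an intercept deviating from zero indicates directional
#' horizontal pleiotropy. Slope and intercept SEs are inflated by
#' `max(1, residual SD)` and tested against a t distribution with
#' `n_snp - 2` degrees of freedom.
#'
#' @param h a `harmonized` object (single exposure) with at least 3 SNPs.
#' @return an `mr_estimate` with intercept fields (`method` `"egger"`).
#' @export
mr_egger <- function(h) {
  d <- single_beta_x(h)
  j <- length(d$bx)
  if (j < 3L) stop("mr_egger: at least 3 instruments required", call. = FALSE)
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  bx <- d$bx * flip
  by <- d$by * flip
  w <- 1 / d$sy^2
  x_mat <- cbind(1, bx)
  xtwx <- crossprod(x_mat * sqrt(w))
  coefs <- drop(solve(xtwx, crossprod(x_mat, w * by)))
  resid <- by - drop(x_mat %*% coefs)
  sigma <- sqrt(sum(w * resid^2) / (j - 2))
  # unscaled (sigma = 1) covariance, then the truncated dispersion multiplier
  se_unscaled <- sqrt(diag(solve(xtwx)))
  infl <- max(1, sigma)
  se <- se_unscaled * infl
  tstat <- coefs / se
  pvals <- 2 * stats::pt(-abs(tstat), df = j - 2)
  est <- new_mr_estimate("egger", j, unname(coefs[2L]), unname(se[2L]),
                         unname(pvals[2L]),
                         intercept = unname(coefs[1L]),
                         intercept_se = unname(se[1L]),
                         intercept_p = unname(pvals[1L]),
                         scale_factor = infl,
                         ci_quantile = stats::qt(0.975, df = j - 2),
                         exposure = paste(h$exposure_names, collapse = "+"),
                         outcome = h$outcome_name)
  est
}

# weighted median of values x with weights w: sort by x, find where the
# normalized cumulative weight (sum_{k<=j} w_k - w_j/2)/sum(w) crosses 1/2,
# linearly interpolating between bracketing order statistics
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (!any(s < 0.5)) return(x[1L])
  below <- max(which(s < 0.5))
  if (below == length(x)) return(x[length(x)])
  x[below] + (x[below + 1L] - x[below]) * (0.5 - s[below]) / (s[below + 1L] - s[below])
}

#' Weighted median estimator
#'
#' The weighted median of per-SNP Wald ratios with inverse-variance weights
#' on the ratio scale; consistent when at least half the weight comes from
#' valid instruments, so robust to up to 50% invalid weight. The SE comes
#' from a parametric bootstrap: exposure and outcome effects are redrawn from
#' normals centred at the observed values with the observed SEs, the weighted
#' median recomputed, and its standard deviation taken.
#'
#' @param h a `harmonized` object (single exposure) with at least 3 SNPs.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in the estimate.
#' @return an `mr_estimate` (`method` `"weighted_median"`).
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  d <- single_beta_x(h)
  j <- length(d$bx)
  if (j < 3L) stop("mr_weighted_median: at least 3 instruments required", call. = FALSE)
  wr <- wald_ratio(d$bx, d$sx, d$by, d$sy)
  w <- wr$ratio_se^-2
  beta <- weighted_median_point(wr$ratio, w)

  boot <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(j * n_boot, d$bx, d$sx), nrow = j)
    by_star <- matrix(stats::rnorm(j * n_boot, d$by, d$sy), nrow = j)
    vapply(seq_len(n_boot), function(k) {
      r <- by_star[, k] / bx_star[, k]
      weighted_median_point(r, (d$sy / abs(bx_star[, k]))^-2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pvalue <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", j, beta, se, pvalue,
                  exposure = paste(h$exposure_names, collapse = "+"),
                  outcome = h$outcome_name, seed = as.integer(seed))
}

#' Run the univariable estimator battery
#'
#' IVW with multiplicative random effects (primary), MR-Egger, and the
#' weighted median on the same harmonized instruments. Estimators whose
#' instrument-count requirements are not met (Egger and weighted median need
#' 3 SNPs) are reported as `NULL` with a note; the `consistent` flag says
#' whether all computed betas share a sign.
#'
#' @param h a `harmonized` object (single exposure).
#' @param seed RNG seed for the weighted-median bootstrap.
#' @param n_boot weighted-median bootstrap replicates.
#' @return list with elements `ivw_mre`, `egger`, `weighted_median` (each an
#'   `mr_estimate` or `NULL`), `consistent`, and `notes`.
#' @export
run_uvmr <- function(h, seed = 1L, n_boot = 1000) {
  notes <- character(0)
  ivw_est <- mr_ivw(h, random_effects = TRUE)
  egger_est <- NULL
  wm_est <- NULL
  if (h$n_snp >= 3L) {
    egger_est <- mr_egger(h)
    wm_est <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  } else {
    notes <- c(notes, sprintf(
      "egger and weighted_median infeasible with %d SNP(s); IVW only", h$n_snp))
  }
  betas <- c(ivw_est$beta,
             if (!is.null(egger_est)) egger_est$beta,
             if (!is.null(wm_est)) wm_est$beta)
  list(ivw_mre = ivw_est, egger = egger_est, weighted_median = wm_est,
       consistent = length(unique(sign(betas))) == 1L,
       notes = notes)
}
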