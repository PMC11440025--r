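#' Filter summary statistics by association p-value
#'
#' Retains rows with `pvalue` strictly below `threshold` (the conventional
#' genome-wide cut-off is 5e-8; mediator traits are often screened at a
#' relaxed 5e-6). Row order is preserved.
#'
#' @param table a [sumstats] table.
#' @param threshold p-value cut-off in (0, 1); strict inequality.
#' @return the filtered [sumstats] table (possibly empty).
#' @export
select_by_pvalue <- function(table, threshold) {
  stopifnot(inherits(table, "sumstats"))
  if (!(threshold > 0 && threshold < 1)) {
    stop("select_by_pvalue: threshold must be in (0, 1)", call. = FALSE)
  }
  keep <- table$pvalue < threshold
  subset_sumstats(table, keep)
}

# subset a sumstats table preserving class and attributes
subset_sumstats <- function(table, keep) {
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = attr(table, "trait_name"),
            trait_type = attr(table, "trait_type"),
            drop_log = attr(table, "drop_log"),
            class = c("sumstats", "data.frame"))
}

#' Greedy LD clumping
#'
#' Standard greedy pruning: SNPs are ranked by ascending p-value (ties broken
#' by `snp_id` lexicographic order, so the result does not depend on input row
#' order); the best remaining SNP becomes an index SNP, and every remaining
#' SNP on the same chromosome within `window_kb` of it with squared
#' correlation at or above `r2_max` is removed. SNP pairs absent from `ld`
#' are treated as uncorrelated (reference-panel dropout), with a warning when
#' whole SNPs are missing from the panel.
#'
#' @param table a [sumstats] table.
#' @param ld an [ld_matrix]; SNPs absent from it are treated as r2 = 0.
#' @param r2_max exclusion cut-off on squared correlation (default 0.001).
#' @param window_kb physical window around the index SNP in kilobases
#'   (default 10000); a SNP is in the window when
#'   `|pos_a - pos_b| <= window_kb * 1000` on the same chromosome.
#' @return the clumped [sumstats] table of retained index SNPs, in selection
#'   order.
#' @export
ld_clump <- function(table, ld, r2_max = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table) <= 1L) return(table)

  ids <- table$snp_id
  in_panel <- ids %in% colnames(ld)
  if (!all(in_panel)) {
    warning(sprintf("ld_clump: %d SNP(s) absent from LD panel, treated as uncorrelated",
                    sum(!in_panel)), call. = FALSE)
  }
  ord <- order(table$pvalue, ids)
  alive <- rep(TRUE, nrow(table))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    cand <- which(alive &
                    table$chrom == table$chrom[i] &
                    abs(table$pos - table$pos[i]) <= window_kb * 1000)
    if (length(cand) == 0L) next
    if (in_panel[i]) {
      cand_panel <- cand[in_panel[cand]]
      if (length(cand_panel) > 0L) {
        r2 <- unclass(ld)[ids[i], ids[cand_panel]]
        alive[cand_panel[r2 >= r2_max]] <- FALSE
      }
    }
  }
  # selection order (ascending p, ties by id) so the output is independent of
  # the input row order
  subset_sumstats(table, kept)
}

#' Per-SNP instrument-strength F statistic
#'
#' `F = beta^2 / se^2`, the square of the Wald z; values above 10 are the
#' conventional guard against weak-instrument bias.
#'
#' @param beta per-allele effect(s).
#' @param se standard error(s), > 0.
#' @return numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("f_statistic: se must be positive", call. = FALSE)
  (beta / se)^2
}

#' Variance in the exposure explained by a SNP
#'
#' Inverts the one-parameter relation `F = R2 (N - 2) / (1 - R2)` to
#' `R2 = F / (F + N - 2)`; monotone increasing in F at fixed N.
#'
#' @param f_stat per-SNP F statistic(s) (see [f_statistic]).
#' @param n total sample size(s), > 2.
#' @return R-squared value(s) in \[0, 1).
#' @export
variance_explained <- function(f_stat, n) {
  if (any(n <= 2)) stop("variance_explained: n must exceed 2", call. = FALSE)
  f_stat / (f_stat + n - 2)
}

#' Build an instrument set for an exposure
#'
#' Applies, in order: the p-value screen ([select_by_pvalue]), greedy LD
#' clumping ([ld_clump]), and the F-statistic filter (strictly `F > f_min`).
#' Per-stage removal counts are recorded in `selection_log`.
#'
#' @param table exposure [sumstats].
#' @param ld an [ld_matrix].
#' @param p_threshold association p-value cut-off (default 5e-8).
#' @param r2_max,window_kb clumping parameters (defaults 0.001 and 10000 kb).
#' @param f_min minimum F statistic, strict (default 10).
#' @param exclude_snps optional character vector of SNP ids removed before
#'   selection (used to keep mediator instruments non-overlapping with the
#'   exposure's instruments in mediation analysis).
#' @return an object of class `instrument_set`: list with `exposure_name`,
#'   `snps` (the retained [sumstats] rows), `f_stats`, `r2_explained`,
#'   `p_threshold`, and `selection_log`.
#' @export
build_instruments <- function(table, ld, p_threshold = 5e-8, r2_max = 0.001,
                              window_kb = 10000, f_min = 10,
                              exclude_snps = NULL) {
  stopifnot(inherits(table, "sumstats"))
  n0 <- nrow(table)
  if (!is.null(exclude_snps)) {
    table <- subset_sumstats(table, !(table$snp_id %in% exclude_snps))
  }
  n_excl <- n0 - nrow(table)
  sig <- select_by_pvalue(table, p_threshold)
  clumped <- ld_clump(sig, ld, r2_max = r2_max, window_kb = window_kb)
  f <- f_statistic(clumped$beta, clumped$se)
  strong <- f > f_min
  snps <- subset_sumstats(clumped, strong)
  f <- f[strong]
  log <- c(input = n0,
           removed_overlap = n_excl,
           removed_pvalue = nrow(table) - nrow(sig),
           removed_clump = nrow(sig) - nrow(clumped),
           removed_weak = nrow(clumped) - nrow(snps),
           retained = nrow(snps))
  out <- structure(list(
    exposure_name = attr(table, "trait_name"),
    snps = snps,
    f_stats = stats::setNames(f, snps$snp_id),
    r2_explained = stats::setNames(variance_explained(f, snps$n), snps$snp_id),
    p_threshold = p_threshold,
    f_min = f_min,
    selection_log = log
  ), class = "instrument_set")
  if (nrow(snps) == 0L) {
    attr(out, "empty") <- TRUE
  }
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d SNP(s) at p < %g (F > %g)\n",
              x$exposure_name, nrow(x$snps), x$p_threshold, x$f_min))
  log <- x$selection_log
  cat(sprintf("  input %d | overlap -%d | p-value -%d | clumping -%d | weak-F -%d\n",
              log[["input"]], log[["removed_overlap"]], log[["removed_pvalue"]],
              log[["removed_clump"]], log[["removed_weak"]]))
  if (nrow(x$snps) > 0L) {
    cat(sprintf("  F range %.1f - %.1f, sum R^2 = %.4g\n",
                min(x$f_stats), max(x$f_stats), sum(x$r2_explained)))
  }
  invisible(x)
}
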