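COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

# Align one outcome-side record to the exposure orientation (ea/oa).
# Returns list(action, flip) where action is one of kept / sign-flipped /
# strand-flipped / dropped-palindromic / dropped-unmatched, and flip says
# whether the outcome beta must be negated.
align_alleles <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y, band) {
  if (is_palindromic(ea_x, oa_x)) {
    # strand is unknowable from alleles; orientation must come from frequency
    if (!identical(sort(c(ea_y, oa_y)), sort(c(ea_x, oa_x)))) {
      return(list(action = "dropped-unmatched", flip = FALSE))
    }
    if (is.na(eaf_x) || is.na(eaf_y)) {
      return(list(action = "dropped-palindromic", flip = FALSE))
    }
    in_band <- function(f) f > band[1] && f < band[2]
    if (in_band(eaf_x) || in_band(eaf_y)) {
      return(list(action = "dropped-palindromic", flip = FALSE))
    }
    # align by frequency: an eaf_y reported for either strand label of the
    # same allele pair refers to the exposure effect allele iff it sits on
    # the same side of 0.5 as eaf_x
    eaf_y_for_ea <- if (ea_y == ea_x) eaf_y else 1 - eaf_y
    if ((eaf_x < 0.5) == (eaf_y_for_ea < 0.5)) {
      return(list(action = if (ea_y == ea_x) "kept" else "sign-flipped",
                  flip = ea_y != ea_x))
    }
    return(list(action = if (ea_y == ea_x) "sign-flipped" else "kept",
                flip = ea_y == ea_x))
  }
  if (ea_y == ea_x && oa_y == oa_x) {
    return(list(action = "kept", flip = FALSE))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(list(action = "sign-flipped", flip = TRUE))
  }
  cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
  if (cea == ea_x && coa == oa_x) {
    return(list(action = "strand-flipped", flip = FALSE))
  }
  if (cea == oa_x && coa == ea_x) {
    return(list(action = "strand-flipped", flip = TRUE))
  }
  list(action = "dropped-unmatched", flip = FALSE)
}

#' Harmonize exposure and outcome summary statistics over an instrument set
#'
#' Aligns the outcome's per-SNP effects to the exposure's effect allele:
#' matching allele pairs are kept; swapped pairs have the outcome beta negated
#' and `eaf_y` reflected; pairs that match after A/T, C/G strand
#' complementation are remapped and then treated the same way. Palindromic
#' SNPs (A/T or C/G pairs), whose strand cannot be resolved from alleles,
#' are aligned by allele frequency when the frequency is informative and
#' dropped when the effect-allele frequency lies in the open ambiguity band in
#' either dataset or is missing. Irreconcilable allele pairs are dropped and
#' logged, never silently kept.
#'
#' @param exposure,outcome [sumstats] tables.
#' @param instruments an `instrument_set` built from the exposure (see
#'   [build_instruments]); its SNPs must be present in the exposure table.
#' @param palindrome_eaf_band open frequency interval in which a palindromic
#'   SNP is considered ambiguous; default `c(0.42, 0.58)`, the de-facto
#'   convention of two-sample MR tooling. Use `c(0, 1)` to drop all
#'   palindromes.
#' @return an object of class `harmonized`: list with `exposure_names`,
#'   `outcome_name`, `snp_ids`, `beta_x` (SNPs x exposures matrix), `se_x`,
#'   `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `n_snp`, and a per-SNP
#'   `harmonization_log` data frame (snp_id, action, reason).
#' @export
harmonize <- function(exposure, outcome, instruments,
                      palindrome_eaf_band = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"),
            inherits(instruments, "instrument_set"))
  snps <- instruments$snps
  ex <- as.data.frame(exposure)[match(snps$snp_id, exposure$snp_id), ]
  oy <- as.data.frame(outcome)[match(snps$snp_id, outcome$snp_id), ]

  n <- nrow(ex)
  action <- character(n); flip <- logical(n); reason <- character(n)
  for (j in seq_len(n)) {
    if (is.na(ex$snp_id[j])) {
      action[j] <- "dropped-unmatched"; reason[j] <- "absent from exposure"
      next
    }
    if (is.na(oy$snp_id[j])) {
      action[j] <- "dropped-unmatched"; reason[j] <- "absent from outcome"
      next
    }
    a <- align_alleles(ex$effect_allele[j], ex$other_allele[j],
                       oy$effect_allele[j], oy$other_allele[j],
                       ex$eaf[j], oy$eaf[j], palindrome_eaf_band)
    action[j] <- a$action; flip[j] <- a$flip
    reason[j] <- switch(a$action,
                        "dropped-unmatched" = "irreconcilable alleles",
                        "dropped-palindromic" = "ambiguous palindrome",
                        "aligned")
  }
  keep <- !startsWith(action, "dropped")
  log <- data.frame(
    snp_id = snps$snp_id,
    action = action,
    reason = reason,
    stringsAsFactors = FALSE
  )

  beta_y <- ifelse(flip, -oy$beta, oy$beta)[keep]
  eaf_y <- ifelse(flip, 1 - oy$eaf, oy$eaf)[keep]
  structure(list(
    exposure_names = attr(exposure, "trait_name"),
    outcome_name = attr(outcome, "trait_name"),
    snp_ids = ex$snp_id[keep],
    beta_x = matrix(ex$beta[keep], ncol = 1,
                    dimnames = list(ex$snp_id[keep], attr(exposure, "trait_name"))),
    se_x = matrix(ex$se[keep], ncol = 1),
    beta_y = oy_num(beta_y),
    se_y = oy_num(oy$se[keep]),
    eaf_x = ex$eaf[keep],
    eaf_y = eaf_y,
    n_snp = sum(keep),
    harmonization_log = log
  ), class = "harmonized")
}

oy_num <- function(x) as.numeric(x)

#' Harmonize several exposures and one outcome to a common effect allele
#'
#' Multi-exposure analogue of [harmonize] for multivariable MR: a SNP is kept
#' only when it is present and alignable (same rules, including the
#' palindrome band) in every exposure and in the outcome. All effects are
#' oriented to the first exposure's effect allele.
#'
#' @param exposures list of two or more [sumstats] tables.
#' @param outcome [sumstats] table.
#' @param merged_instruments `instrument_set` over the merged instrument SNPs
#'   (see [merge_instruments]); SNPs must be present in the first exposure.
#' @param palindrome_eaf_band as in [harmonize].
#' @return a `harmonized` object whose `beta_x`/`se_x` are SNPs x exposures
#'   matrices.
#' @export
harmonize_multi <- function(exposures, outcome, merged_instruments,
                            palindrome_eaf_band = c(0.42, 0.58)) {
  stopifnot(length(exposures) >= 2L)
  ref <- exposures[[1L]]
  # harmonize outcome and every non-reference exposure against the reference
  h_y <- harmonize(ref, outcome, merged_instruments, palindrome_eaf_band)
  kept_ids <- h_y$snp_ids
  others <- lapply(exposures[-1L], function(exp_k) {
    harmonize(ref, exp_k, merged_instruments, palindrome_eaf_band)
  })
  for (h_k in others) kept_ids <- intersect(kept_ids, h_k$snp_ids)
  if (length(kept_ids) < length(exposures) + 1L) {
    stop("harmonize_multi: fewer harmonized SNPs than exposures + 1; MVMR infeasible",
         call. = FALSE)
  }
  ref_rows <- match(kept_ids, h_y$snp_ids)
  beta_x <- cbind(h_y$beta_x[ref_rows, 1L])
  se_x <- cbind(h_y$se_x[ref_rows, 1L])
  for (h_k in others) {
    rows_k <- match(kept_ids, h_k$snp_ids)
    beta_x <- cbind(beta_x, h_k$beta_y[rows_k])
    se_x <- cbind(se_x, h_k$se_y[rows_k])
  }
  exposure_names <- unname(vapply(exposures, attr, "", "trait_name"))
  dimnames(beta_x) <- list(kept_ids, exposure_names)
  structure(list(
    exposure_names = exposure_names,
    outcome_name = attr(outcome, "trait_name"),
    snp_ids = kept_ids,
    beta_x = beta_x,
    se_x = se_x,
    beta_y = h_y$beta_y[ref_rows],
    se_y = h_y$se_y[ref_rows],
    eaf_x = h_y$eaf_x[ref_rows],
    eaf_y = h_y$eaf_y[ref_rows],
    n_snp = length(kept_ids),
    harmonization_log = h_y$harmonization_log
  ), class = "harmonized")
}

#' Assemble already-aligned effect estimates into a harmonized object
#'
#' For data whose exposure and outcome effects are already expressed on a
#' common effect allele (e.g. extracted from a previous harmonization run, or
#' simulated directly on the aligned scale), bypassing allele reconciliation.
#'
#' @param beta_x exposure effects: vector, or SNPs x exposures matrix for
#'   multivariable use.
#' @param se_x exposure SEs, same shape as `beta_x`.
#' @param beta_y,se_y outcome effects and SEs (vectors).
#' @param snp_ids optional SNP identifiers (defaults to `snp_1`, ...).
#' @param exposure_name,outcome_name trait labels.
#' @param eaf_x,eaf_y optional effect-allele frequencies.
#' @return a `harmonized` object (see [harmonize]).
#' @export
harmonized_data <- function(beta_x, se_x, beta_y, se_y, snp_ids = NULL,
                            exposure_name = "exposure",
                            outcome_name = "outcome",
                            eaf_x = NULL, eaf_y = NULL) {
  if (!is.matrix(beta_x)) beta_x <- matrix(beta_x, ncol = 1)
  if (!is.matrix(se_x)) se_x <- matrix(se_x, ncol = 1)
  j <- nrow(beta_x)
  stopifnot(nrow(se_x) == j, length(beta_y) == j, length(se_y) == j,
            all(se_x > 0), all(se_y > 0))
  if (is.null(snp_ids)) snp_ids <- sprintf("snp_%d", seq_len(j))
  if (length(exposure_name) == ncol(beta_x)) colnames(beta_x) <- exposure_name
  rownames(beta_x) <- snp_ids
  structure(list(
    exposure_names = exposure_name,
    outcome_name = outcome_name,
    snp_ids = as.character(snp_ids),
    beta_x = beta_x,
    se_x = se_x,
    beta_y = as.numeric(beta_y),
    se_y = as.numeric(se_y),
    eaf_x = if (is.null(eaf_x)) rep(NA_real_, j) else eaf_x,
    eaf_y = if (is.null(eaf_y)) rep(NA_real_, j) else eaf_y,
    n_snp = j,
    harmonization_log = data.frame(snp_id = as.character(snp_ids),
                                   action = "kept", reason = "pre-aligned",
                                   stringsAsFactors = FALSE)
  ), class = "harmonized")
}

#' @export
print.harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %s -> %s, %d SNP(s)\n",
              paste(x$exposure_names, collapse = " + "), x$outcome_name, x$n_snp))
  tab <- table(x$harmonization_log$action)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write a harmonization log as TSV
#' @param h a `harmonized` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(h, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(h$harmonization_log, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
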