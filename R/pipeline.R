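#' Assemble a study configuration
#'
#' Collects traits and analysis parameters for [run_study]. Trait entries may
#' be [sumstats] objects or file paths (paths are read with
#' [read_sumstats] using `column_map`). The defaults are the conventional
#' two-sample MR parameter set: genome-wide instrument threshold 5e-8
#' (relaxed to 5e-6 for mediators left without enough instruments), clumping
#' at r2 < 0.001 in a 10,000 kb window, F > 10, palindrome ambiguity band
#' (0.42, 0.58), and Bonferroni correction over the full exposure-by-outcome
#' grid.
#'
#' @param exposures named list of exposure [sumstats] (or paths).
#' @param outcomes named list of outcome [sumstats] (or paths).
#' @param ld an [ld_matrix] (or a square-format path).
#' @param mediators names of outcomes that may act as mediators (their own
#'   summary statistics are reused as step-2 exposures).
#' @param p_primary,p_relaxed instrument p-value thresholds.
#' @param no_relax mediator trait names never given the relaxed threshold
#'   (default `"SCZ"`, which has ample genome-wide instruments).
#' @param r2_max,window_kb,f_min instrument-selection parameters.
#' @param palindrome_eaf_band ambiguity band for palindromic SNPs.
#' @param bonferroni_m comparisons for the Bonferroni rule; default
#'   `length(exposures) * length(outcomes)`.
#' @param presso_n_sim MR-PRESSO simulation count (default 1000).
#' @param wm_n_boot weighted-median bootstrap replicates (default 1000).
#' @param seed base seed; every stochastic step derives its own stream from
#'   it deterministically.
#' @param column_map used when traits are given as paths.
#' @return list of class `study_config`.
#' @export
study_config <- function(exposures, outcomes, ld, mediators = character(0),
                         p_primary = 5e-8, p_relaxed = 5e-6,
                         no_relax = "SCZ",
                         r2_max = 0.001, window_kb = 10000, f_min = 10,
                         palindrome_eaf_band = c(0.42, 0.58),
                         bonferroni_m = NULL,
                         presso_n_sim = 1000, wm_n_boot = 1000,
                         seed = 1L, column_map = canonical_column_map()) {
  load_trait <- function(x, name, type) {
    if (inherits(x, "sumstats")) return(x)
    read_sumstats(x, column_map, trait_type = type, trait_name = name)
  }
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  if (anyDuplicated(c(names(exposures), names(outcomes)))) {
    stop("study_config: trait names must be unique", call. = FALSE)
  }
  if (!all(mediators %in% names(outcomes))) {
    stop("study_config: mediators must be among the outcomes", call. = FALSE)
  }
  exposures <- mapply(load_trait, exposures, names(exposures),
                      MoreArgs = list(type = "continuous"), SIMPLIFY = FALSE)
  outcomes <- mapply(load_trait, outcomes, names(outcomes),
                     MoreArgs = list(type = "binary"), SIMPLIFY = FALSE)
  if (is.character(ld)) ld <- read_ld(ld, "square")
  if (is.null(bonferroni_m)) bonferroni_m <- length(exposures) * length(outcomes)
  structure(list(
    exposures = exposures, outcomes = outcomes, ld = ld,
    mediators = mediators,
    p_primary = p_primary, p_relaxed = p_relaxed, no_relax = no_relax,
    r2_max = r2_max, window_kb = window_kb, f_min = f_min,
    palindrome_eaf_band = palindrome_eaf_band,
    bonferroni_m = bonferroni_m,
    presso_n_sim = presso_n_sim, wm_n_boot = wm_n_boot,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Run the full MR study
#'
#' For every exposure-outcome pair: instrument selection, harmonization, the
#' univariable estimator battery (IVW with multiplicative random effects as
#' the primary method, MR-Egger, weighted median), the sensitivity battery,
#' and a significance tier — `bonferroni` (IVW p below 0.05/m), `nominal`
#' (below 0.05), `null`, or `dismissed` when MR-PRESSO's global test flags
#' pleiotropy (p < 0.05) for a pair that would otherwise be significant (the
#' Egger intercept p is carried alongside as a secondary flag). Outcomes with
#' two or more nominally significant exposures then get a multivariable IVW
#' fit on the jointly re-clumped union of instruments. Finally, every
#' eligible (exposure, mediator, outcome) triple — all three links nominally
#' significant and none dismissed — gets a two-step mediation analysis;
#' mediator instruments exclude SNPs already instrumenting any exposure (so
#' the two steps use non-overlapping variants) and fall back to the relaxed
#' threshold when fewer than three genome-wide instruments remain (never for
#' traits in `no_relax`).
#'
#' A failure in any one pair is caught, logged, and does not abort the grid.
#'
#' @param config a [study_config].
#' @return an object of class `mr_study`: list with `grid` (one row per
#'   exposure x outcome x method), `sensitivity` (per-pair
#'   `sensitivity_report`s), `instruments`, `mvmr`, `mediator_links`,
#'   `mediation`, `bonferroni_threshold`, `log` (character), and `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))
  note("bonferroni threshold: 0.05/%d = %.4f (p < %.2g study-wide)",
       config$bonferroni_m, 0.05 / config$bonferroni_m,
       signif(0.05 / config$bonferroni_m, 2))

  instruments <- lapply(names(config$exposures), function(e) {
    iv <- build_instruments(config$exposures[[e]], config$ld,
                            p_threshold = config$p_primary,
                            r2_max = config$r2_max,
                            window_kb = config$window_kb,
                            f_min = config$f_min)
    note("instruments[%s]: %d SNP(s) retained (p<%g, clump, F>%g)",
         e, nrow(iv$snps), config$p_primary, config$f_min)
    iv
  })
  names(instruments) <- names(config$exposures)

  grid_rows <- list(); sens <- list(); pair_idx <- 0L
  for (e in names(config$exposures)) {
    for (o in names(config$outcomes)) {
      pair_idx <- pair_idx + 1L
      pair <- paste(e, o, sep = "->")
      res <- tryCatch({
        h <- harmonize(config$exposures[[e]], config$outcomes[[o]],
                       instruments[[e]], config$palindrome_eaf_band)
        if (h$n_snp < 1L) stop("no harmonized instruments")
        uv <- run_uvmr(h, seed = child_seed(config$seed, pair_idx),
                       n_boot = config$wm_n_boot)
        sr <- sensitivity_report(h, n_sim = config$presso_n_sim,
                                 seed = child_seed(config$seed, 50000L + pair_idx))
        list(h = h, uv = uv, sr = sr)
      }, error = function(err) {
        note("pair %s failed: %s", pair, conditionMessage(err))
        NULL
      })
      if (is.null(res)) next
      sens[[pair]] <- res$sr
      presso_p <- if (!is.null(res$sr$presso)) res$sr$presso$global_p else NA_real_
      int_p <- if (!is.null(res$sr$egger_intercept)) res$sr$egger_intercept$p else NA_real_
      qp <- if (!is.null(res$sr$q_ivw)) res$sr$q_ivw$p else NA_real_
      bonf <- bonferroni(res$uv$ivw_mre$pvalue, config$bonferroni_m)
      tier <- if (bonf$significant) "bonferroni" else if (bonf$nominal) "nominal" else "null"
      dismissed <- !is.na(presso_p) && presso_p < 0.05 && tier != "null"
      if (dismissed) tier <- "dismissed"
      for (m in c("ivw_mre", "egger", "weighted_median")) {
        est <- res$uv[[m]]
        if (is.null(est)) next
        row <- as.data.frame(est)
        row$exposure <- e; row$outcome <- o
        row$presso_global_p <- presso_p
        row$q_p <- qp
        row$egger_intercept_p <- int_p
        row$tier <- tier
        row$dismissed <- dismissed
        grid_rows[[length(grid_rows) + 1L]] <- row
      }
    }
  }
  grid <- do.call(rbind, grid_rows)
  rownames(grid) <- NULL

  # --- multivariable MR on outcomes with >= 2 nominally significant exposures
  ivw_grid <- grid[grid$method == "ivw_mre", , drop = FALSE]
  mvmr <- list()
  for (o in names(config$outcomes)) {
    rows <- ivw_grid[ivw_grid$outcome == o & ivw_grid$pvalue < 0.05, , drop = FALSE]
    if (nrow(rows) < 2L) next
    exps <- rows$exposure
    fit <- tryCatch({
      merged <- merge_instruments(instruments[exps], config$exposures[exps],
                                  config$ld, r2_max = config$r2_max,
                                  window_kb = config$window_kb)
      hm <- harmonize_multi(config$exposures[exps], config$outcomes[[o]],
                            merged, config$palindrome_eaf_band)
      mvmr_ivw(hm)
    }, error = function(err) {
      note("mvmr[%s] failed: %s", o, conditionMessage(err))
      NULL
    })
    if (!is.null(fit)) {
      mvmr[[o]] <- fit
      note("mvmr[%s]: %s jointly modeled over %d SNP(s)",
           o, paste(exps, collapse = "+"), fit$n_snp)
    }
  }

  # --- mediator -> outcome links (step 2), instruments non-overlapping with
  #     every exposure's instrument set
  exposure_iv_ids <- unique(unlist(lapply(instruments, function(s) s$snps$snp_id)))
  med_rows <- list(); med_links <- list()
  for (m in config$mediators) {
    med_table <- config$outcomes[[m]]
    iv_m <- build_instruments(med_table, config$ld,
                              p_threshold = config$p_primary,
                              r2_max = config$r2_max,
                              window_kb = config$window_kb,
                              f_min = config$f_min,
                              exclude_snps = exposure_iv_ids)
    threshold_used <- config$p_primary
    if (nrow(iv_m$snps) < 3L && !(m %in% config$no_relax)) {
      iv_m <- build_instruments(med_table, config$ld,
                                p_threshold = config$p_relaxed,
                                r2_max = config$r2_max,
                                window_kb = config$window_kb,
                                f_min = config$f_min,
                                exclude_snps = exposure_iv_ids)
      threshold_used <- config$p_relaxed
    }
    note("mediator instruments[%s]: %d SNP(s) at p<%g (exposure-overlapping SNPs excluded)",
         m, nrow(iv_m$snps), threshold_used)
    for (o in setdiff(names(config$outcomes), m)) {
      est <- tryCatch({
        hm <- harmonize(med_table, config$outcomes[[o]], iv_m,
                        config$palindrome_eaf_band)
        if (hm$n_snp < 1L) stop("no harmonized instruments")
        mr_ivw(hm)
      }, error = function(err) {
        note("mediator link %s->%s failed: %s", m, o, conditionMessage(err))
        NULL
      })
      if (is.null(est)) next
      med_links[[paste(m, o, sep = "->")]] <- est
      med_rows[[length(med_rows) + 1L]] <- data.frame(
        exposure = m, outcome = o, pvalue = est$pvalue,
        threshold = threshold_used, dismissed = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  mediator_links <- if (length(med_rows) > 0L) do.call(rbind, med_rows) else
    data.frame(exposure = character(0), outcome = character(0),
               pvalue = numeric(0), threshold = numeric(0),
               dismissed = logical(0), stringsAsFactors = FALSE)

  # --- mediation over eligible triples
  elig_grid <- rbind(
    data.frame(exposure = ivw_grid$exposure, outcome = ivw_grid$outcome,
               pvalue = ivw_grid$pvalue, dismissed = ivw_grid$dismissed,
               stringsAsFactors = FALSE),
    mediator_links[, c("exposure", "outcome", "pvalue", "dismissed")]
  )
  triples <- mediation_eligibility(elig_grid, config$mediators)
  mediation <- list()
  if (nrow(triples) > 0L) {
    for (i in seq_len(nrow(triples))) {
      e <- triples$exposure[i]; m <- triples$mediator[i]; y <- triples$outcome[i]
      total <- grid_estimate(grid, e, y)
      em <- grid_estimate(grid, e, m)
      mo <- med_links[[paste(m, y, sep = "->")]]
      med <- tryCatch(
        two_step_mediation(total, em, mo,
                           seed = child_seed(config$seed, 90000L + i)),
        error = function(err) {
          note("mediation %s->%s->%s failed: %s", e, m, y, conditionMessage(err))
          NULL
        })
      if (!is.null(med)) {
        mediation[[paste(e, m, y, sep = "->")]] <- med
        note("mediation %s->%s->%s: proportion mediated %.2f%%",
             e, m, y, 100 * med$proportion_mediated)
      }
    }
  }

  structure(list(
    grid = grid,
    sensitivity = sens,
    instruments = instruments,
    mvmr = mvmr,
    mediator_links = mediator_links,
    mediation = mediation,
    bonferroni_threshold = 0.05 / config$bonferroni_m,
    log = log,
    config = config
  ), class = "mr_study")
}

# reconstruct a minimal mr_estimate from a grid IVW row
grid_estimate <- function(grid, e, o) {
  row <- grid[grid$exposure == e & grid$outcome == o & grid$method == "ivw_mre", ]
  if (nrow(row) == 0L) stop("no IVW row for ", e, " -> ", o, call. = FALSE)
  new_mr_estimate("ivw_mre", row$n_snp[1L], row$beta[1L], row$se[1L],
                  row$pvalue[1L], exposure = e, outcome = o)
}

#' @export
print.mr_study <- function(x, ...) {
  ivw <- x$grid[x$grid$method == "ivw_mre", ]
  cat(sprintf("MR study: %d pair(s), Bonferroni threshold %.4f\n",
              nrow(ivw), x$bonferroni_threshold))
  cat("  tiers:", paste(sprintf("%s %d", names(table(ivw$tier)), table(ivw$tier)),
                        collapse = ", "), "\n")
  if (length(x$mvmr) > 0L) {
    cat("  MVMR outcomes:", paste(names(x$mvmr), collapse = ", "), "\n")
  }
  for (med in x$mediation) {
    cat(sprintf("  mediation %s -> %s -> %s: PM %.2f%%\n",
                med$exposure, med$mediator, med$outcome,
                100 * med$proportion_mediated))
  }
  invisible(x)
}

#' Write study reports as TSV tables
#'
#' Emits `grid.tsv` (one row per pair and method, mirroring the usual
#' "exposure, outcome, method, nSNP, beta, se, OR, CI, p" result table plus
#' sensitivity columns and tier), `mvmr.tsv`, `mediation.tsv`,
#' `sensitivity.tsv` (per-pair Q, intercept and MR-PRESSO summaries) and
#' `run_log.txt`. Output is deterministic for a fixed config.
#'
#' @param study an `mr_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    df
  }
  write_tsv(fmt(study$grid), file.path(dir, "grid.tsv"))

  if (length(study$mvmr) > 0L) {
    mv <- do.call(rbind, lapply(study$mvmr, function(f) {
      data.frame(outcome = f$outcome_name, exposure = f$exposure_names,
                 n_snp = f$n_snp, beta = f$betas, se = f$ses,
                 or = f$or, or_low = f$or_low, or_high = f$or_high,
                 pvalue = f$pvalues, stringsAsFactors = FALSE)
    }))
    rownames(mv) <- NULL
    write_tsv(fmt(mv), file.path(dir, "mvmr.tsv"))
  }

  if (length(study$mediation) > 0L) {
    md <- do.call(rbind, lapply(study$mediation, function(m) {
      data.frame(exposure = m$exposure, mediator = m$mediator,
                 outcome = m$outcome, beta_total = m$beta_total,
                 or_total = exp(m$beta_total),
                 beta_indirect = m$beta_indirect, se_indirect = m$se_indirect,
                 proportion_mediated_pct = 100 * m$proportion_mediated,
                 pm_ci_low_pct = 100 * m$pm_ci[1], pm_ci_high_pct = 100 * m$pm_ci[2],
                 stringsAsFactors = FALSE)
    }))
    rownames(md) <- NULL
    write_tsv(fmt(md), file.path(dir, "mediation.tsv"))
  }

  sens_rows <- lapply(names(study$sensitivity), function(pair) {
    s <- study$sensitivity[[pair]]
    data.frame(
      pair = pair,
      q_ivw = if (!is.null(s$q_ivw)) s$q_ivw$Q else NA_real_,
      q_ivw_p = if (!is.null(s$q_ivw)) s$q_ivw$p else NA_real_,
      q_egger_p = if (!is.null(s$q_egger)) s$q_egger$p else NA_real_,
      egger_intercept = if (!is.null(s$egger_intercept)) s$egger_intercept$alpha else NA_real_,
      egger_intercept_p = if (!is.null(s$egger_intercept)) s$egger_intercept$p else NA_real_,
      presso_global_p = if (!is.null(s$presso)) s$presso$global_p else NA_real_,
      presso_outliers = if (!is.null(s$presso)) length(s$presso$outliers) else NA_integer_,
      loo_sign_stable = if (!is.null(s$loo)) s$loo$sign_stable else NA,
      stringsAsFactors = FALSE)
  })
  if (length(sens_rows) > 0L) {
    write_tsv(fmt(do.call(rbind, sens_rows)), file.path(dir, "sensitivity.tsv"))
  }

  con <- file(file.path(dir, "run_log.txt"), open = "wb")
  writeLines(study$log, con)
  close(con)
  invisible(dir)
}
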