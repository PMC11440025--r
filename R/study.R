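#' Generate a full synthetic study: 3 exposure clusters by 10 disorders
#'
#' Emits summary statistics shaped like a neuroticism-cluster/psychiatric-
#' disorder MR study: three exposure traits ("depressed_affect", "sesa",
#' "worry"), ten disorder outcomes, a shared SNP universe (per-exposure
#' instruments, mediator-specific instruments for the two disorders that act
#' as mediators, and null background SNPs), and a truth matrix mixing null
#' and non-null total effects. Two mediation chains are planted —
#' depressed_affect -> PD -> PTSD and sesa -> AN -> PTSD — with effect sizes
#' set to the log odds ratios such studies report (e.g. total effects around
#' OR 2.6-2.9 per SD of exposure, mediator-to-outcome effects around OR
#' 1.04-1.11), so the second chain is comfortably detectable while the first
#' is as marginal as it is in practice.
#'
#' @param seed RNG seed.
#' @param j_instruments instruments per exposure (default 40).
#' @param j_mediator mediator-specific instruments per mediator (default 30).
#' @param n_null null background SNPs (default 60).
#' @return an object of class `synthetic_study`: list with `exposures` and
#'   `outcomes` (named lists of [sumstats]), `mediators` (character), `ld`,
#'   and `truth` (list with `theta_total` 3 x 10 matrix and `chains` data
#'   frame giving em/mo/direct/total/proportion per planted chain).
#' @export
generate_paper_shaped_study <- function(seed = 1L, j_instruments = 40L,
                                        j_mediator = 30L, n_null = 60L) {
  exposure_names <- c("depressed_affect", "sesa", "worry")
  outcome_names <- c("ADHD", "AN", "ASD", "BIP", "MDD",
                     "OCD", "PD", "PTSD", "TS", "SCZ")
  mediators <- c("PD", "AN")

  theta_total <- matrix(0, 3, 10, dimnames = list(exposure_names, outcome_names))
  theta_total["depressed_affect", "ADHD"] <- log(2.145)
  theta_total["depressed_affect", "PD"]   <- log(2.593)
  theta_total["depressed_affect", "PTSD"] <- log(2.943)
  theta_total["sesa", "AN"]   <- log(2.77)
  theta_total["sesa", "PTSD"] <- log(2.69)
  theta_total["sesa", "SCZ"]  <- log(2.55)
  theta_total["worry", "MDD"]  <- log(2.58)
  theta_total["worry", "PTSD"] <- log(1.81)

  mo <- c(PD = log(1.04), AN = log(1.11))
  chains <- data.frame(
    exposure = c("depressed_affect", "sesa"),
    mediator = c("PD", "AN"),
    outcome = c("PTSD", "PTSD"),
    em = c(theta_total["depressed_affect", "PD"], theta_total["sesa", "AN"]),
    mo = unname(mo),
    stringsAsFactors = FALSE
  )
  chains$total <- c(theta_total["depressed_affect", "PTSD"],
                    theta_total["sesa", "PTSD"])
  chains$indirect <- chains$em * chains$mo
  chains$direct <- chains$total - chains$indirect
  chains$proportion_mediated <- chains$indirect / chains$total

  n_exposure <- 350000L
  n_outcome <- 200000L
  f_target <- 100

  with_seed(seed, {
    j <- j_instruments
    n_total <- 3L * j + 2L * j_mediator + n_null
    loc <- locus_positions(n_total)
    snp_id <- sprintf("rs%07d", seq_len(n_total))
    pair_idx <- sample(nrow(NON_PALINDROMIC_PAIRS), n_total, replace = TRUE)
    ea <- NON_PALINDROMIC_PAIRS[pair_idx, 1L]
    oa <- NON_PALINDROMIC_PAIRS[pair_idx, 2L]
    eaf <- stats::runif(n_total, 0.05, 0.95)
    se_x <- se_from_af(n_exposure, eaf)
    se_y <- se_from_af(n_outcome, eaf)

    # instrument layout over the shared universe
    idx_exp <- lapply(seq_len(3L), function(e) (e - 1L) * j + seq_len(j))
    idx_med <- list(PD = 3L * j + seq_len(j_mediator),
                    AN = 3L * j + j_mediator + seq_len(j_mediator))

    gamma <- matrix(0, n_total, 3L, dimnames = list(snp_id, exposure_names))
    for (e in seq_len(3L)) {
      rows <- idx_exp[[e]]
      gamma[rows, e] <- draw_gamma(se_x[rows], f_target)
    }
    delta <- matrix(0, n_total, 2L, dimnames = list(snp_id, mediators))
    for (m in seq_len(2L)) {
      rows <- idx_med[[m]]
      delta[rows, m] <- draw_gamma(se_y[rows], f_target)
    }

    # trait means: mediators combine their upstream exposure path and their
    # own instruments; PTSD adds the mediated paths on top of direct effects
    mu_med <- cbind(
      PD = theta_total["depressed_affect", "PD"] * gamma[, "depressed_affect"] +
        delta[, "PD"],
      AN = theta_total["sesa", "AN"] * gamma[, "sesa"] + delta[, "AN"]
    )
    mu_out <- matrix(0, n_total, 10L, dimnames = list(snp_id, outcome_names))
    for (o in outcome_names) {
      if (o %in% mediators) {
        mu_out[, o] <- mu_med[, o]
      } else if (o == "PTSD") {
        direct <- stats::setNames(chains$direct, chains$exposure)
        mu_out[, o] <-
          direct[["depressed_affect"]] * gamma[, "depressed_affect"] +
          direct[["sesa"]] * gamma[, "sesa"] +
          theta_total["worry", "PTSD"] * gamma[, "worry"] +
          mo[["PD"]] * mu_med[, "PD"] + mo[["AN"]] * mu_med[, "AN"]
      } else {
        mu_out[, o] <- drop(gamma %*% theta_total[, o])
      }
    }

    make_table <- function(mu, se, n, name, type) {
      beta <- stats::rnorm(n_total, mu, se)
      sumstats(data.frame(
        snp_id = snp_id, chrom = loc$chrom, pos = loc$pos,
        effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = beta, se = se,
        pvalue = 2 * stats::pnorm(-abs(beta / se)),
        n = n, stringsAsFactors = FALSE
      ), trait_name = name, trait_type = type)
    }
    exposures <- stats::setNames(lapply(seq_len(3L), function(e) {
      make_table(gamma[, e], se_x, n_exposure, exposure_names[e], "continuous")
    }), exposure_names)
    outcomes <- stats::setNames(lapply(outcome_names, function(o) {
      make_table(mu_out[, o], se_y, n_outcome, o, "binary")
    }), outcome_names)

    structure(list(
      exposures = exposures,
      outcomes = outcomes,
      mediators = mediators,
      ld = ld_matrix(snp_id),
      truth = list(theta_total = theta_total, chains = chains, seed = seed)
    ), class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic MR study (seed %d): %d exposures x %d outcomes, %d SNPs\n",
              x$truth$seed, length(x$exposures), length(x$outcomes),
              nrow(x$exposures[[1L]])))
  cat(sprintf("  %d non-null total effects, %d planted mediation chain(s)\n",
              sum(x$truth$theta_total != 0), nrow(x$truth$chains)))
  invisible(x)
}
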