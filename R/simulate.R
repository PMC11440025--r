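#' Specify the ground truth of a synthetic two-sample MR dataset
#'
#' Collects every parameter the generator needs; [generate_dataset] is a pure
#' function of this object, so the same truth always yields the same data.
#'
#' Effects are on standardized (per-allele, per-SD) scales; for binary
#' outcomes the same `1/(2 N p (1-p))` sampling-variance form is used on the
#' log-odds scale — adequate for testing the estimators, not a case-control
#' likelihood simulation. Exposure and outcome samples are non-overlapping by
#' construction, matching the two-sample design.
#'
#' @param theta true causal effect of the exposure on the outcome. In a
#'   mediation scenario (any of `theta_em`, `theta_mo`, `theta_direct` set)
#'   the total effect is `theta_direct + theta_em * theta_mo` and `theta` is
#'   ignored.
#' @param theta_em,theta_mo,theta_direct mediation-scenario effects:
#'   exposure to mediator, mediator to outcome, and the direct
#'   exposure-outcome path.
#' @param pleiotropy_frac fraction of exposure instruments carrying a
#'   horizontal pleiotropic effect on the outcome.
#' @param pleiotropy_mean,pleiotropy_sd pleiotropic effects are
#'   `N(pleiotropy_mean, pleiotropy_sd^2)`; mean 0 is balanced pleiotropy,
#'   nonzero is directional.
#' @param j_instruments number of true exposure instruments.
#' @param j_mediator number of mediator-specific instruments (mediation
#'   scenario only).
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param n_null number of null background SNPs (no effect anywhere).
#' @param ld_block_spec list of `c(size, r2)` pairs; each turns one
#'   instrument into an LD block of `size` SNPs with the given pairwise
#'   squared correlation.
#' @param palindrome_frac fraction of instruments assigned A/T or C/G allele
#'   pairs with allele frequency near 0.5 (so harmonization must drop them).
#' @param f_target expected per-instrument F statistic; instrument effect
#'   magnitudes are drawn uniformly within 30% of `se_x sqrt(f_target - 1)`,
#'   oriented to the exposure-increasing allele as in standard MR method
#'   simulations (so directional pleiotropy is directional relative to that
#'   orientation, and every true instrument stays genome-wide detectable at
#'   the default target).
#' @param seed RNG seed recorded in the truth and used by the generator.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(theta = 0.3,
                             theta_em = NULL, theta_mo = NULL,
                             theta_direct = NULL,
                             pleiotropy_frac = 0, pleiotropy_mean = 0,
                             pleiotropy_sd = 0,
                             j_instruments = 50L, j_mediator = 30L,
                             n_exposure = 350000L, n_outcome = 200000L,
                             n_mediator = 150000L, n_null = 0L,
                             ld_block_spec = list(),
                             palindrome_frac = 0,
                             f_target = 100, seed = 1L) {
  stopifnot(pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            palindrome_frac >= 0, palindrome_frac <= 1,
            j_instruments >= 1, f_target > 1,
            pleiotropy_sd >= 0)
  mediation <- !is.null(theta_em) || !is.null(theta_mo) || !is.null(theta_direct)
  if (mediation &&
      (is.null(theta_em) || is.null(theta_mo) || is.null(theta_direct))) {
    stop("simulation_truth: a mediation scenario needs theta_em, theta_mo and theta_direct",
         call. = FALSE)
  }
  if (mediation) theta <- theta_direct + theta_em * theta_mo
  structure(list(
    theta = theta, theta_em = theta_em, theta_mo = theta_mo,
    theta_direct = theta_direct, mediation = mediation,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    j_instruments = as.integer(j_instruments),
    j_mediator = as.integer(j_mediator),
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    n_mediator = as.integer(n_mediator), n_null = as.integer(n_null),
    ld_block_spec = ld_block_spec, palindrome_frac = palindrome_frac,
    f_target = f_target, seed = as.integer(seed)
  ), class = "simulation_truth")
}

NON_PALINDROMIC_PAIRS <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

# spread SNPs across chromosomes so that distinct loci never share a clumping
# window: successive same-chromosome loci sit 25 Mb apart (> 10 Mb window)
locus_positions <- function(n_loci) {
  chrom <- as.character(((seq_len(n_loci) - 1L) %% 22L) + 1L)
  pos <- 1000000L + ((seq_len(n_loci) - 1L) %/% 22L) * 25000000L
  list(chrom = chrom, pos = pos)
}

se_from_af <- function(n, p) 1 / sqrt(2 * n * p * (1 - p))

# true instrument effect magnitudes: scaled so E[F] ~ f_target while keeping
# every instrument genome-wide detectable at the default target (magnitude
# uniform within +/-10% of the target scale, oriented to the
# exposure-increasing allele)
draw_gamma <- function(se, f_target) {
  se * sqrt(f_target - 1) * stats::runif(length(se), 0.9, 1.1)
}

#' Generate a synthetic two-sample GWAS dataset
#'
#' Draws per-SNP summary statistics for an exposure, an outcome, and (in a
#' mediation scenario) a mediator, in non-overlapping samples, from a known
#' causal structure:
#' true instrument effects `gamma_j` with expected F near `f_target`,
#' per-SNP standard errors `1/sqrt(2 N p (1-p))` from the allele frequency,
#' observed effects drawn around their truth, horizontal pleiotropy added to
#' a configurable fraction of instruments, LD blocks realized as clusters of
#' near-duplicate SNPs, and a configurable fraction of ambiguous palindromic
#' variants. Everything is reproducible from `truth$seed`.
#'
#' @param truth a [simulation_truth].
#' @return an object of class `synthetic_dataset`: list with `exposure`,
#'   `outcome`, optional `mediator` ([sumstats] tables sharing one SNP
#'   universe), `ld` (an [ld_matrix]), and `truth`.
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  with_seed(truth$seed, generate_dataset_impl(truth))
}

generate_dataset_impl <- function(truth) {
  j <- truth$j_instruments
  jm <- if (truth$mediation) truth$j_mediator else 0L
  n_blocks <- length(truth$ld_block_spec)
  if (n_blocks > j) stop("generate_dataset: more LD blocks than instruments",
                         call. = FALSE)
  block_extra <- if (n_blocks > 0L) {
    sum(vapply(truth$ld_block_spec, function(b) b[1] - 1, 0))
  } else 0L
  n_total <- j + jm + truth$n_null + block_extra

  # --- loci: instruments first, then mediator instruments, then null SNPs;
  #     LD-block satellites share their index SNP's locus
  n_loci <- j + jm + truth$n_null
  loc <- locus_positions(n_loci)

  snp_id <- sprintf("rs%07d", seq_len(n_total))
  chrom <- character(n_total); pos <- integer(n_total)
  role <- character(n_total)       # instrument / mediator_iv / null / satellite
  parent <- integer(n_total)       # satellite's index-SNP row, else NA
  chrom[seq_len(n_loci)] <- loc$chrom
  pos[seq_len(n_loci)] <- loc$pos
  role[seq_len(j)] <- "instrument"
  if (jm > 0L) role[j + seq_len(jm)] <- "mediator_iv"
  if (truth$n_null > 0L) role[j + jm + seq_len(truth$n_null)] <- "null"
  parent[] <- NA_integer_

  row <- n_loci
  block_r2 <- rep(NA_real_, n_total)
  if (n_blocks > 0L) {
    for (b in seq_len(n_blocks)) {
      size <- truth$ld_block_spec[[b]][1]
      r2 <- truth$ld_block_spec[[b]][2]
      for (s in seq_len(size - 1L)) {
        row <- row + 1L
        chrom[row] <- chrom[b]
        pos[row] <- pos[b] + s * 1000L
        role[row] <- "satellite"
        parent[row] <- b
        block_r2[row] <- r2
      }
    }
  }

  # --- allele frequencies and alleles
  is_palin <- rep(FALSE, n_total)
  if (truth$palindrome_frac > 0 && j > 0L) {
    n_pal <- round(truth$palindrome_frac * j)
    if (n_pal > 0L) is_palin[sample(seq_len(j), n_pal)] <- TRUE
  }
  eaf <- stats::runif(n_total, 0.05, 0.95)
  eaf[is_palin] <- stats::runif(sum(is_palin), 0.45, 0.55)
  pal_pair <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  pair_idx <- sample(nrow(NON_PALINDROMIC_PAIRS), n_total, replace = TRUE)
  ea <- NON_PALINDROMIC_PAIRS[pair_idx, 1L]
  oa <- NON_PALINDROMIC_PAIRS[pair_idx, 2L]
  if (any(is_palin)) {
    pi2 <- sample(nrow(pal_pair), sum(is_palin), replace = TRUE)
    ea[is_palin] <- pal_pair[pi2, 1L]
    oa[is_palin] <- pal_pair[pi2, 2L]
  }
  # satellites inherit their index SNP's frequency
  sat <- role == "satellite"
  eaf[sat] <- eaf[parent[sat]]

  se_x <- se_from_af(truth$n_exposure, eaf)
  se_y <- se_from_af(truth$n_outcome, eaf)
  se_m <- se_from_af(truth$n_mediator, eaf)

  # --- true effects, oriented to the exposure-increasing allele
  gamma <- numeric(n_total)
  inst <- role == "instrument"
  gamma[inst] <- draw_gamma(se_x[inst], truth$f_target)
  gamma[sat] <- gamma[parent[sat]]
  delta <- numeric(n_total)        # mediator-specific instrument effects
  if (jm > 0L) {
    med_iv <- role == "mediator_iv"
    delta[med_iv] <- draw_gamma(se_m[med_iv], truth$f_target)
  }
  alpha <- numeric(n_total)        # horizontal pleiotropy on the outcome
  if (truth$pleiotropy_frac > 0 && j > 0L) {
    hit <- inst & (stats::runif(n_total) < truth$pleiotropy_frac)
    alpha[hit] <- stats::rnorm(sum(hit), truth$pleiotropy_mean, truth$pleiotropy_sd)
    alpha[sat] <- alpha[parent[sat]]
  }

  # --- trait means per SNP
  mu_x <- gamma
  if (truth$mediation) {
    mu_m <- truth$theta_em * gamma + delta
    mu_y <- truth$theta_direct * gamma + truth$theta_mo * mu_m + alpha
  } else {
    mu_m <- NULL
    mu_y <- truth$theta * gamma + alpha
  }

  draw_table <- function(mu, se, n, name, type = "binary") {
    beta <- stats::rnorm(n_total, mu, se)
    sumstats(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta, se = se,
      pvalue = 2 * stats::pnorm(-abs(beta / se)),
      n = n, stringsAsFactors = FALSE
    ), trait_name = name, trait_type = type)
  }
  exposure <- draw_table(mu_x, se_x, truth$n_exposure, "exposure", "continuous")
  outcome <- draw_table(mu_y, se_y, truth$n_outcome, "outcome", "binary")
  mediator <- if (truth$mediation) {
    draw_table(mu_m, se_m, truth$n_mediator, "mediator", "binary")
  } else NULL

  pairs <- NULL
  if (n_blocks > 0L) {
    # full pairwise within-block LD, not just satellite-to-index
    pair_list <- lapply(seq_len(n_blocks), function(b) {
      members <- c(b, which(parent == b & sat))
      if (length(members) < 2L) return(NULL)
      cmb <- utils::combn(members, 2L)
      data.frame(snp_a = snp_id[cmb[1L, ]], snp_b = snp_id[cmb[2L, ]],
                 r2 = truth$ld_block_spec[[b]][2], stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pair_list)
  }
  ld <- ld_matrix(snp_id, pairs)

  structure(list(exposure = exposure, outcome = outcome, mediator = mediator,
                 ld = ld, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic two-sample GWAS dataset (seed %d): %d SNPs, theta = %.3g\n",
              x$truth$seed, nrow(x$exposure), x$truth$theta))
  if (x$truth$mediation) {
    cat(sprintf("  mediation: em %.3g, mo %.3g, direct %.3g (total %.3g)\n",
                x$truth$theta_em, x$truth$theta_mo, x$truth$theta_direct,
                x$truth$theta))
  }
  invisible(x)
}

#' Write a synthetic dataset to disk in the canonical dialects
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(dataset$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(dataset$outcome, file.path(dir, "outcome.tsv"))
  if (!is.null(dataset$mediator)) {
    write_sumstats(dataset$mediator, file.path(dir, "mediator.tsv"))
  }
  write_ld(dataset$ld, file.path(dir, "ld.tsv"))
  invisible(dir)
}
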