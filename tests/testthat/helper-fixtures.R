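# fixture builders shared by the test files; everything is generated in code

make_snp_table <- function(n = 5, seed = 1, chrom = NULL, pos = NULL,
                           eaf = NULL, beta = NULL, se = NULL, pvalue = NULL,
                           effect_allele = NULL, other_allele = NULL,
                           n_sample = 100000L, trait_name = "trait",
                           trait_type = "continuous") {
  set.seed(seed)
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pick <- pairs[sample(4, n, replace = TRUE), , drop = FALSE]
  df <- data.frame(
    snp_id = sprintf("rs%04d", seq_len(n)),
    chrom = if (is.null(chrom)) as.character(((seq_len(n) - 1L) %% 22L) + 1L) else chrom,
    pos = if (is.null(pos)) 1000000L + ((seq_len(n) - 1L) %/% 22L) * 25000000L else pos,
    effect_allele = if (is.null(effect_allele)) pick[, 1] else effect_allele,
    other_allele = if (is.null(other_allele)) pick[, 2] else other_allele,
    eaf = if (is.null(eaf)) runif(n, 0.1, 0.9) else eaf,
    beta = if (is.null(beta)) rnorm(n, 0, 0.05) else beta,
    se = if (is.null(se)) rep(0.01, n) else se,
    pvalue = if (is.null(pvalue)) runif(n, 0.01, 0.99) else pvalue,
    n = n_sample,
    stringsAsFactors = FALSE
  )
  sumstats(df, trait_name = trait_name, trait_type = trait_type)
}

random_harmonized <- function(j = 10, seed = 1, theta = 0.3, k_exp = 1) {
  set.seed(seed)
  bx <- matrix(runif(j * k_exp, 0.02, 0.2) * sample(c(-1, 1), j * k_exp, TRUE),
               ncol = k_exp)
  sx <- matrix(runif(j * k_exp, 0.002, 0.02), ncol = k_exp)
  sy <- runif(j, 0.005, 0.05)
  by <- drop(bx %*% rep(theta, k_exp)) + rnorm(j, 0, sy)
  harmonized_data(bx, sx, by, sy)
}

# independent brute-force weighted median (grid-free, from the definition):
# smallest value at which the interpolated cumulative weight reaches 1/2
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(s, x, xout = 0.5, rule = 2)$y
}

subset_sumstats_drop <- function(ss, ids) {
  sumstats(as.data.frame(ss)[!(ss$snp_id %in% ids), ],
           attr(ss, "trait_name"), attr(ss, "trait_type"))
}

subset_harmonized_rows <- function(h, idx) {
  h$snp_ids <- h$snp_ids[idx]
  h$beta_x <- h$beta_x[idx, , drop = FALSE]
  h$se_x <- h$se_x[idx, , drop = FALSE]
  h$beta_y <- h$beta_y[idx]
  h$se_y <- h$se_y[idx]
  h$eaf_x <- h$eaf_x[idx]
  h$eaf_y <- h$eaf_y[idx]
  h$n_snp <- length(h$beta_y)
  h
}
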