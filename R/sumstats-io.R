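#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame of per-SNP association records for one
#' trait, with one row per variant and the columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' Binary-trait effects are stored on the log-odds scale throughout; odds
#' ratios appear only at the reporting boundary.
#'
#' Rows violating the record invariants (non-positive `se`, `pvalue` outside
#' (0, 1], alleles outside A/C/G/T, identical alleles, `eaf` outside \[0, 1\],
#' non-positive `n`) are dropped, and the number dropped per reason is kept in
#' the `drop_log` attribute.
#'
#' @param df data frame holding the columns named above (alleles are
#'   uppercased; `eaf` may be `NA`).
#' @param trait_name trait label, e.g. `"worry"` or `"PTSD"`.
#' @param trait_type `"binary"` or `"continuous"`; binary traits are expected
#'   on the log-odds scale.
#' @return a data frame of class `sumstats` with attributes `trait_name`,
#'   `trait_type` and `drop_log` (named integer vector of per-reason drops).
#' @export
sumstats <- function(df, trait_name, trait_type = c("binary", "continuous")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pvalue", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[required]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)

  valid_allele <- function(a) a %in% c("A", "C", "G", "T")
  checks <- list(
    bad_allele   = !(valid_allele(df$effect_allele) & valid_allele(df$other_allele)),
    same_alleles = df$effect_allele == df$other_allele,
    bad_se       = !is.finite(df$se) | df$se <= 0,
    bad_beta     = !is.finite(df$beta),
    bad_pvalue   = !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
    bad_eaf      = !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
    bad_n        = is.na(df$n) | df$n <= 0
  )
  # a row can fail several checks; attribute it to the first failing reason
  bad <- rep(NA_character_, nrow(df))
  for (reason in names(checks)) {
    hit <- checks[[reason]] & is.na(bad)
    hit[is.na(hit)] <- TRUE
    bad[hit & is.na(bad)] <- reason
  }
  drop_log <- table(factor(bad, levels = names(checks)))
  drop_log <- stats::setNames(as.integer(drop_log), names(checks))
  df <- df[is.na(bad), , drop = FALSE]

  if (anyDuplicated(df$snp_id)) {
    stop("sumstats: duplicate snp_id in table for trait '", trait_name, "'",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name,
            trait_type = trait_type,
            drop_log = drop_log,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  dropped <- sum(attr(x, "drop_log"))
  if (isTRUE(dropped > 0)) cat(sprintf("  %d row(s) dropped on read\n", dropped))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

trait_name <- function(x) attr(x, "trait_name")
trait_type <- function(x) attr(x, "trait_type")

#' Read GWAS summary statistics from a delimited file
#'
#' Column mapping is explicit, never sniffed: GWAS header dialects vary too
#' much for guessing to be safe. The file may be tab- or comma-delimited with
#' a header row; the separator is taken from whichever of tab/comma appears in
#' the header line.
#'
#' @param path path to the summary-statistics file.
#' @param column_map named character vector mapping the internal field names
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pvalue`, `n` to the file's column names. Supply `or` instead of
#'   `beta` when the file reports odds ratios; they are converted to log-odds
#'   (`beta = log(OR)`) on read. `eaf` may be omitted (stored as `NA`).
#' @param trait_type `"binary"` or `"continuous"`.
#' @param trait_name trait label; defaults to the file name without extension.
#' @return a [sumstats] table; invalid rows are dropped and counted in the
#'   `drop_log` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(rsid = c("rs1", "rs2"), chr = 1, bp = c(1e6, 2e6),
#'              ea = c("A", "C"), oa = c("G", "T"), freq = c(0.3, 0.4),
#'              b = c(0.02, -0.01), se = 0.005, p = c(1e-8, 0.04), n = 10000),
#'   tf, sep = "\t", quote = FALSE, row.names = FALSE)
#' ss <- read_sumstats(tf, c(snp_id = "rsid", chrom = "chr", pos = "bp",
#'                           effect_allele = "ea", other_allele = "oa",
#'                           eaf = "freq", beta = "b", se = "se",
#'                           pvalue = "p", n = "n"), "continuous", "toy")
#' nrow(ss)
read_sumstats <- function(path, column_map,
                          trait_type = c("binary", "continuous"),
                          trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (nrow(raw) == 0L) stop("read_sumstats: no data rows in ", path, call. = FALSE)

  effect_key <- if ("or" %in% names(column_map)) "or" else "beta"
  needed <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              effect_key, "se", "pvalue", "n")
  missing_map <- setdiff(needed, names(column_map))
  if (length(missing_map) > 0L) {
    stop("read_sumstats: column_map lacks field(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  missing_file <- setdiff(unname(column_map[c(needed, intersect("eaf", names(column_map)))]),
                          names(raw))
  if (length(missing_file) > 0L) {
    stop("read_sumstats: file lacks mapped column(s): ",
         paste(missing_file, collapse = ", "), call. = FALSE)
  }

  df <- data.frame(
    snp_id = raw[[column_map[["snp_id"]]]],
    chrom = raw[[column_map[["chrom"]]]],
    pos = raw[[column_map[["pos"]]]],
    effect_allele = raw[[column_map[["effect_allele"]]]],
    other_allele = raw[[column_map[["other_allele"]]]],
    eaf = if ("eaf" %in% names(column_map)) as.numeric(raw[[column_map[["eaf"]]]]) else NA_real_,
    beta = if (effect_key == "or") log(as.numeric(raw[[column_map[["or"]]]]))
           else as.numeric(raw[[column_map[["beta"]]]]),
    se = raw[[column_map[["se"]]]],
    pvalue = raw[[column_map[["pvalue"]]]],
    n = raw[[column_map[["n"]]]],
    stringsAsFactors = FALSE
  )
  out <- sumstats(df, trait_name = trait_name, trait_type = trait_type)
  if (nrow(out) == 0L) {
    stop("read_sumstats: zero valid rows after validation in ", path, call. = FALSE)
  }
  out
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-delimited dialect (`read_sumstats` with an
#' identity column map reads it back field-for-field), UTF-8 with LF endings.
#'
#' @param x a [sumstats] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", na = "NA")
  invisible(path)
}

#' Identity column map for files written by [write_sumstats]
#' @return named character vector usable as `column_map`.
#' @export
canonical_column_map <- function() {
  fields <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
              "eaf", "beta", "se", "pvalue", "n")
  stats::setNames(fields, fields)
}

#' Convert an odds ratio with confidence interval to log-odds beta and SE
#'
#' Inverts the usual "OR (95% CI)" reporting: `beta = log(OR)` and
#' `se = (log(hi) - log(lo)) / (2 z)` with `z` the standard-normal quantile
#' for the interval level.
#'
#' @param or_value odds ratio (> 0).
#' @param ci_low,ci_high confidence bounds, `ci_low < or_value < ci_high`.
#' @param level interval coverage, default 0.95.
#' @return list with elements `beta` and `se`.
#' @export
#' @examples
#' or_ci_to_beta_se(2.943, 2.210, 3.919)
or_ci_to_beta_se <- function(or_value, ci_low, ci_high, level = 0.95) {
  if (any(c(or_value, ci_low, ci_high) <= 0)) {
    stop("or_ci_to_beta_se: odds ratios and bounds must be positive", call. = FALSE)
  }
  if (!(ci_low < or_value && or_value < ci_high)) {
    stop("or_ci_to_beta_se: need ci_low < or_value < ci_high", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(beta = log(or_value), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Construct an LD matrix
#'
#' Squared-correlation (r-squared) matrix over a set of SNPs: symmetric, unit
#' diagonal, entries in \[0, 1\]. Pairs not supplied are taken as uncorrelated.
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param pairs optional data frame with columns `snp_a`, `snp_b`, `r2`.
#' @return matrix of class `ld_matrix` with `snp_ids` as dimnames.
#' @export
ld_matrix <- function(snp_ids, pairs = NULL) {
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(snp_ids)) stop("ld_matrix: duplicate snp_ids", call. = FALSE)
  m <- diag(1, length(snp_ids))
  dimnames(m) <- list(snp_ids, snp_ids)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    r2 <- as.numeric(pairs$r2)
    if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
      stop("ld_matrix: r2 outside [0, 1]", call. = FALSE)
    }
    a <- as.character(pairs$snp_a); b <- as.character(pairs$snp_b)
    known <- a %in% snp_ids & b %in% snp_ids
    m[cbind(a[known], b[known])] <- r2[known]
    m[cbind(b[known], a[known])] <- r2[known]
    diag(m) <- 1
  }
  class(m) <- c("ld_matrix", class(m))
  m
}

#' Read LD information
#'
#' @param path path to the LD file.
#' @param format `"pairwise"` (columns `snp_a`, `snp_b`, `r2`, whitespace- or
#'   tab-delimited with header) or `"square"` (header row of SNP ids, then the
#'   full matrix).
#' @param snp_ids for pairwise format, the full SNP universe (pairs involving
#'   other SNPs are ignored; missing pairs default to r2 = 0). Ignored for
#'   square format.
#' @return an [ld_matrix].
#' @export
read_ld <- function(path, format = c("pairwise", "square"), snp_ids = NULL) {
  format <- match.arg(format)
  if (format == "pairwise") {
    if (is.null(snp_ids)) stop("read_ld: pairwise format needs snp_ids", call. = FALSE)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L || !nzchar(first)) {
      return(ld_matrix(snp_ids))
    }
    pairs <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    names(pairs) <- tolower(names(pairs))
    if (!all(c("snp_a", "snp_b", "r2") %in% names(pairs))) {
      stop("read_ld: pairwise file needs columns snp_a, snp_b, r2", call. = FALSE)
    }
    ld_matrix(snp_ids, pairs)
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, check.names = FALSE,
                                     row.names = NULL))
    ids <- colnames(m)
    storage.mode(m) <- "double"
    if (any(!is.finite(m) | m < 0 | m > 1)) {
      stop("read_ld: r2 outside [0, 1]", call. = FALSE)
    }
    dimnames(m) <- list(ids, ids)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    class(m) <- c("ld_matrix", class(m))
    m
  }
}

#' Write an LD matrix in square format
#' @param ld an [ld_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  m <- unclass(ld)
  writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
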