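#' Column-name mapping for summary-statistics files
#'
#' GWAS summary statistics come with many header conventions. A dialect maps
#' the package's canonical field names to the column names found in a file.
#' The defaults follow GWAS-SSF-style headers.
#'
#' @param snp_id,chrom,pos,effect_allele,other_allele,eaf,beta,se,pvalue,n
#'   Column name in the file holding each canonical field.
#' @return A named character vector usable as the `dialect` argument of
#'   [read_sumstats()] and [write_sumstats()].
#' @examples
#' sumstats_dialect(snp_id = "SNP", pvalue = "P")
#' @export
sumstats_dialect <- function(snp_id = "rsid",
                             chrom = "chromosome",
                             pos = "base_pair_location",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             eaf = "effect_allele_frequency",
                             beta = "beta",
                             se = "standard_error",
                             pvalue = "p_value",
                             n = "n") {
  c(snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n)
}

.SUMSTAT_FIELDS <- names(sumstats_dialect())
.NUMERIC_FIELDS <- c("pos", "eaf", "beta", "se", "pvalue", "n")
.ALLELES <- c("A", "C", "G", "T")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header, maps columns through a
#' dialect, and validates every row against the per-SNP invariants (single
#' A/C/G/T alleles, effect allele distinct from the other allele, positive
#' standard error, allele frequency strictly inside (0, 1), p-value in (0, 1],
#' positive sample size). Rows violating an invariant are rejected
#' individually; the returned data frame carries them in the `"rejected"`
#' attribute with the file line number and a reason, and a warning summarizes
#' the count. Alleles are upper-cased on read; indels and multi-allelic
#' records are rejected.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector from [sumstats_dialect()].
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `data.frame` with canonical columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#'   one row per valid SNP, with attribute `"rejected"`.
#' @seealso [write_sumstats()], [harmonize()]
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(), sep = NULL) {
  if (!file.exists(path)) {
    mr_abort(sprintf("summary-statistics file not found: %s", path), "mr_input_error")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    mr_abort(sprintf("empty summary-statistics file: %s", path), "mr_input_error")
  }
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    mr_abort(sprintf("summary-statistics file has a header but no data rows: %s", path),
             "mr_input_error")
  }
  missing <- setdiff(.SUMSTAT_FIELDS, names(dialect))
  if (length(missing)) {
    mr_abort(sprintf("dialect does not map required field(s): %s",
                     paste(missing, collapse = ", ")), "mr_config_error")
  }
  absent <- setdiff(unname(dialect[.SUMSTAT_FIELDS]), names(raw))
  if (length(absent)) {
    mr_abort(sprintf("required column(s) missing from %s: %s", path,
                     paste(absent, collapse = ", ")), "mr_config_error")
  }
  df <- stats::setNames(raw[unname(dialect[.SUMSTAT_FIELDS])], .SUMSTAT_FIELDS)
  res <- .validate_sumstat_rows(df, line_offset = 1L)
  if (nrow(res$rejected)) {
    warning(sprintf("%d row(s) rejected while reading %s (see attr(, \"rejected\"))",
                    nrow(res$rejected), path), call. = FALSE)
  }
  out <- res$ok
  attr(out, "rejected") <- res$rejected
  out
}

# Row-level validation of a character-typed summary-statistics frame.
# Returns list(ok = typed data.frame, rejected = data.frame(line, snp_id, reason)).
.validate_sumstat_rows <- function(df, line_offset = 0L) {
  n <- nrow(df)
  out <- data.frame(
    snp_id = as.character(df$snp_id),
    chrom = as.character(df$chrom),
    pos = suppressWarnings(as.numeric(df$pos)),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    eaf = suppressWarnings(as.numeric(df$eaf)),
    beta = suppressWarnings(as.numeric(df$beta)),
    se = suppressWarnings(as.numeric(df$se)),
    pvalue = suppressWarnings(as.numeric(df$pvalue)),
    n = suppressWarnings(as.numeric(df$n)),
    stringsAsFactors = FALSE
  )
  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  for (f in .NUMERIC_FIELDS) {
    flag(is.na(out[[f]]) & !is.na(df[[f]]) & nzchar(as.character(df[[f]])),
         sprintf("unparseable %s", f))
    flag(is.na(out[[f]]), sprintf("missing %s", f))
  }
  flag(!is.na(out$se) & out$se <= 0, "nonpositive se")
  flag(!(out$effect_allele %in% .ALLELES) | !(out$other_allele %in% .ALLELES),
       "invalid allele (not a single A/C/G/T base)")
  flag(out$effect_allele == out$other_allele, "identical alleles")
  flag(!is.na(out$eaf) & (out$eaf <= 0 | out$eaf >= 1), "eaf outside (0,1)")
  flag(!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1), "pvalue outside (0,1]")
  flag(!is.na(out$n) & out$n <= 0, "nonpositive n")
  flag(!is.na(out$pos) & (out$pos < 1 | out$pos != round(out$pos)), "invalid position")
  bad <- !is.na(reason)
  rejected <- data.frame(line = which(bad) + line_offset,
                         snp_id = out$snp_id[bad],
                         reason = reason[bad],
                         stringsAsFactors = FALSE)
  ok <- out[!bad, , drop = FALSE]
  rownames(ok) <- NULL
  list(ok = ok, rejected = rejected)
}

# Strict validation for in-memory frames: aborts on the first violated
# invariant instead of rejecting rows. Used by harmonize() and the pipeline.
validate_sumstats_strict <- function(df, what = "summary statistics") {
  if (!is.data.frame(df)) {
    mr_abort(sprintf("%s must be a data.frame", what), "mr_input_error")
  }
  missing <- setdiff(.SUMSTAT_FIELDS, names(df))
  if (length(missing)) {
    mr_abort(sprintf("%s missing column(s): %s", what, paste(missing, collapse = ", ")),
             "mr_input_error")
  }
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  res <- .validate_sumstat_rows(df)
  if (nrow(res$rejected)) {
    mr_abort(sprintf("%s contain %d invalid row(s); first: snp %s (%s)",
                     what, nrow(res$rejected), res$rejected$snp_id[1],
                     res$rejected$reason[1]), "mr_input_error")
  }
  res$ok
}

#' Write GWAS summary statistics to a delimited text file
#'
#' Inverse of [read_sumstats()]: canonical columns are renamed through the
#' dialect and written with full double precision so that a write/read
#' round trip reproduces the records exactly.
#'
#' @param x Data frame of summary statistics with canonical columns.
#' @param path Output file path.
#' @inheritParams read_sumstats
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, dialect = sumstats_dialect(), sep = "\t") {
  x <- validate_sumstats_strict(x)
  out <- x[.SUMSTAT_FIELDS]
  for (f in .NUMERIC_FIELDS) out[[f]] <- sprintf("%.17g", out[[f]])
  names(out) <- unname(dialect[.SUMSTAT_FIELDS])
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the harmonization drop log
#'
#' @param x A [harmonize()] result (or any data frame with `snp_id` and
#'   `reason` columns).
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_droplog <- function(x, path, sep = "\t") {
  if (inherits(x, "harmonized_set")) x <- x$dropped
  utils::write.table(x[c("snp_id", "reason")], path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
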