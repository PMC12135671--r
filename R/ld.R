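#' Sparse pairwise-LD container
#'
#' Stores pairwise r-squared values as long-form triplets; pairs not listed
#' are taken as unlinked (r2 = 0) and the diagonal is implicitly 1. This is
#' the internal representation behind both accepted file layouts (square
#' matrix with a header of SNP ids, or long-form `snp_a`/`snp_b`/`r2`
#' triplets).
#'
#' @param pairs Data frame with columns `snp_a`, `snp_b`, `r2`, or `NULL`
#'   for an empty (fully unlinked) matrix.
#' @param snp_ids Character vector of SNP ids known to the matrix (used by
#'   strict-mode clumping to detect candidates with no LD information);
#'   ids appearing in `pairs` are added automatically.
#' @return An object of class `ld_matrix`.
#' @seealso [read_ld_matrix()], [clump()]
#' @export
ld_matrix <- function(pairs = NULL, snp_ids = character()) {
  if (is.null(pairs)) {
    pairs <- data.frame(snp_a = character(), snp_b = character(), r2 = numeric(),
                        stringsAsFactors = FALSE)
  }
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(pairs))) {
    mr_abort("LD pairs need columns snp_a, snp_b, r2", "mr_input_error")
  }
  r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(r2)) || any(r2 < 0 | r2 > 1)) {
    mr_abort("LD r2 values must lie in [0, 1]", "mr_input_error")
  }
  a <- as.character(pairs$snp_a); b <- as.character(pairs$snp_b)
  if (any(a == b & r2 != 1)) {
    mr_abort("diagonal LD entries must equal 1", "mr_input_error")
  }
  off <- a != b
  key <- paste(pmin(a[off], b[off]), pmax(a[off], b[off]), sep = "\036")
  dup <- duplicated(key)
  if (any(dup)) {
    # symmetric duplicates must agree (within fp noise)
    first <- match(key[dup], key)
    if (any(abs(r2[off][dup] - r2[off][first]) > 1e-12)) {
      mr_abort("asymmetric duplicate LD entries", "mr_input_error")
    }
  }
  structure(list(r2 = stats::setNames(r2[off][!dup], key[!dup]),
                 snp_ids = unique(c(snp_ids, a, b))),
            class = "ld_matrix")
}

#' Convert a dense symmetric r-squared matrix to an `ld_matrix`
#'
#' Validates unit diagonal, symmetry (within 1e-12) and the \[0, 1\] range.
#'
#' @param m Square numeric matrix with SNP ids as dimnames (row names may be
#'   omitted when columns are named).
#' @return An `ld_matrix`.
#' @export
as_ld_matrix <- function(m) {
  m <- as.matrix(m)
  ids <- colnames(m)
  if (is.null(ids)) mr_abort("dense LD matrix needs SNP ids as column names", "mr_input_error")
  if (nrow(m) != ncol(m)) mr_abort("LD matrix must be square", "mr_input_error")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0 | m > 1)) {
    mr_abort("LD r2 values must lie in [0, 1]", "mr_input_error")
  }
  if (any(abs(diag(m) - 1) > 1e-12)) {
    mr_abort("LD matrix must have a unit diagonal", "mr_input_error")
  }
  if (any(abs(m - t(m)) > 1e-12)) {
    mr_abort("LD matrix must be symmetric (within 1e-12)", "mr_input_error")
  }
  up <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  pairs <- data.frame(snp_a = ids[up[, 1]], snp_b = ids[up[, 2]],
                      r2 = m[up], stringsAsFactors = FALSE)
  ld_matrix(pairs, snp_ids = ids)
}

#' Read an LD matrix from a delimited file
#'
#' Accepts either a long-form triplet file (columns `snp_a`, `snp_b`, `r2`;
#' absent pairs imply r2 = 0) or a square matrix whose header row holds the
#' SNP ids (an optional leading id column is detected and used as row names).
#'
#' @param path Path to the file.
#' @param sep Field separator; `NULL` auto-detects tab vs comma.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, sep = NULL) {
  if (!file.exists(path)) mr_abort(sprintf("LD file not found: %s", path), "mr_input_error")
  header <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (all(c("snp_a", "snp_b", "r2") %in% names(df))) {
    return(ld_matrix(df))
  }
  first_num <- is.numeric(df[[1]])
  if (!first_num) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (is.null(rownames(m)) || first_num) rownames(m) <- colnames(m)
  as_ld_matrix(m)
}

#' Write an LD matrix as long-form triplets
#'
#' @param ld An `ld_matrix`.
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path, sep = "\t") {
  stopifnot(inherits(ld, "ld_matrix"))
  key <- names(ld$r2)
  ab <- if (length(key)) strsplit(key, "\036", fixed = TRUE) else list()
  df <- data.frame(snp_a = vapply(ab, `[`, "", 1),
                   snp_b = vapply(ab, `[`, "", 2),
                   r2 = sprintf("%.17g", unname(ld$r2)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise r-squared lookup
#'
#' @param ld An `ld_matrix` or `NULL` (everything unlinked).
#' @param a,b SNP id vectors (recycled to a common length).
#' @return Numeric vector of r2 values: 1 where `a == b`, 0 for pairs not in
#'   the matrix.
#' @export
ld_r2 <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_matrix"))
    key <- paste(pmin(a, b), pmax(a, b), sep = "\036")
    hit <- match(key, names(ld$r2))
    found <- !is.na(hit) & a != b
    out[found] <- unname(ld$r2[hit[found]])
  }
  out
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d SNPs, %d nonzero off-diagonal pairs\n",
              length(x$snp_ids), length(x$r2)))
  invisible(x)
}
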