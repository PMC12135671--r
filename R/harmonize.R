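.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Flip the orientation of selected rows in place: swap allele labels,
# negate beta, complement eaf. se/pvalue/n are orientation-free.
.flip_rows <- function(df, idx) {
  if (!any(idx)) return(df)
  ea <- df$effect_allele[idx]
  df$effect_allele[idx] <- df$other_allele[idx]
  df$other_allele[idx] <- ea
  df$beta[idx] <- -df$beta[idx]
  df$eaf[idx] <- 1 - df$eaf[idx]
  df
}

#' Harmonize effect alleles across two or more traits
#'
#' Takes one summary-statistics set per trait role (exposure first, then
#' outcome and optionally mediators/co-exposures), intersects them on
#' `snp_id`, and aligns every role to a single effect/other-allele
#' orientation per SNP. A role whose alleles are swapped relative to the
#' exposure has its beta negated and eaf complemented; alleles reconcilable
#' by a strand (complement) flip are accepted without sign change; SNPs whose
#' allele pairs cannot be reconciled by swap and/or strand flip are dropped.
#'
#' Palindromic SNPs (A/T or G/C pairs, strand unresolvable from alleles) are
#' dropped wholesale under `palindrome_policy = "drop-all"` (the default,
#' the conservative blanket exclusion). Under `"drop-ambiguous"` they are
#' retained only when every role's effect-allele frequency lies outside
#' `[0.5 - eaf_window, 0.5 + eaf_window]`; orientation is then inferred by
#' frequency concordance (a role whose frequency falls on the opposite side
#' of 0.5 from the exposure's is flipped).
#'
#' After alignment each SNP is put into a canonical orientation (the
#' alphabetically first allele of the pair becomes the effect allele, all
#' roles flipped together), so the output is invariant to how any input
#' record happened to be oriented, and harmonizing an already-harmonized set
#' is a no-op.
#'
#' @param sets Named list of summary-statistics data frames, one per trait
#'   role; the first element is the reference (exposure).
#' @param palindrome_policy `"drop-all"` (default) or `"drop-ambiguous"`.
#' @param eaf_window Half-width of the frequency ambiguity zone around 0.5
#'   used by `"drop-ambiguous"` (default 0.08).
#' @return An object of class `harmonized_set`: a list with elements
#'   `roles` (character), `data` (one row per retained SNP with columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele` and, per role
#'   `r`, `beta_r`, `se_r`, `eaf_r`, `pvalue_r`, `n_r`), and `dropped`
#'   (`snp_id`, `reason`).
#' @examples
#' exp <- data.frame(snp_id = "rs1", chrom = "1", pos = 100,
#'                   effect_allele = "A", other_allele = "G",
#'                   eaf = 0.3, beta = 0.1, se = 0.01, pvalue = 1e-10, n = 1e5)
#' out <- exp
#' out$effect_allele <- "G"; out$other_allele <- "A"
#' out$beta <- 0.05; out$eaf <- 0.7
#' h <- harmonize(list(exposure = exp, outcome = out))
#' h$data$beta_outcome  # -0.05: aligned to the exposure's orientation
#' @export
harmonize <- function(sets, palindrome_policy = c("drop-all", "drop-ambiguous"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  if (!is.list(sets) || length(sets) < 2L) {
    mr_abort("harmonize() needs a named list of at least two summary-statistics sets",
             "mr_input_error")
  }
  roles <- names(sets)
  if (is.null(roles) || any(!nzchar(roles)) || anyDuplicated(roles)) {
    mr_abort("every element of `sets` must have a unique non-empty role name",
             "mr_input_error")
  }
  sets <- lapply(seq_along(sets), function(i) {
    s <- validate_sumstats_strict(sets[[i]], sprintf("role '%s'", roles[i]))
    if (anyDuplicated(s$snp_id)) {
      mr_abort(sprintf("duplicate snp_id within role '%s'", roles[i]), "mr_input_error")
    }
    s
  })
  names(sets) <- roles

  ids <- lapply(sets, `[[`, "snp_id")
  shared <- Reduce(intersect, ids)
  dropped <- list()
  not_shared <- setdiff(unique(unlist(ids)), shared)
  if (length(not_shared)) {
    miss_role <- vapply(not_shared, function(s) {
      roles[which(!vapply(ids, function(v) s %in% v, logical(1)))[1]]
    }, character(1))
    dropped$shared <- data.frame(snp_id = not_shared,
                                 reason = sprintf("missing-in-%s", miss_role),
                                 stringsAsFactors = FALSE)
  }
  if (length(shared) == 0L) {
    mr_abort("no SNPs shared across all roles", "mr_harmonization_error")
  }

  ref <- sets[[1]][match(shared, sets[[1]]$snp_id), , drop = FALSE]
  ref <- .flip_rows(ref, ref$effect_allele > ref$other_allele)  # canonical
  pal <- .COMP[ref$effect_allele] == ref$other_allele
  n <- nrow(ref)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  aligned <- vector("list", length(sets))
  aligned[[1]] <- ref

  for (k in seq_along(sets)[-1]) {
    rr <- sets[[k]][match(shared, sets[[k]]$snp_id), , drop = FALSE]
    ea <- rr$effect_allele; oa <- rr$other_allele
    same <- ea == ref$effect_allele & oa == ref$other_allele
    swap <- ea == ref$other_allele & oa == ref$effect_allele
    strand <- .COMP[ea] == ref$effect_allele & .COMP[oa] == ref$other_allele
    strand_swap <- .COMP[ea] == ref$other_allele & .COMP[oa] == ref$effect_allele
    ok <- same | swap | strand | strand_swap
    bad <- !ok & keep
    keep[bad] <- FALSE
    reason[bad] <- "incompatible-alleles"
    # For non-palindromic SNPs the allele labels decide the orientation; for
    # palindromic SNPs swap and strand flip are indistinguishable from labels
    # alone and the frequency decides (below).
    rr <- .flip_rows(rr, !pal & (swap | strand_swap))
    if (any(pal & ok)) {
      if (palindrome_policy == "drop-all") {
        hit <- pal & ok & keep
        keep[hit] <- FALSE
        reason[hit] <- "palindromic"
      } else {
        ambig <- abs(rr$eaf - 0.5) <= eaf_window | abs(ref$eaf - 0.5) <= eaf_window
        hit <- pal & ok & ambig & keep
        keep[hit] <- FALSE
        reason[hit] <- "palindromic-ambiguous"
        discord <- pal & ok & !ambig & ((rr$eaf < 0.5) != (ref$eaf < 0.5))
        rr <- .flip_rows(rr, discord)
      }
    }
    aligned[[k]] <- rr
  }

  if (any(!keep)) {
    dropped$aligned <- data.frame(snp_id = ref$snp_id[!keep],
                                  reason = reason[!keep],
                                  stringsAsFactors = FALSE)
  }
  if (!any(keep)) {
    mr_abort("all shared SNPs were dropped during harmonization",
             "mr_harmonization_error")
  }

  out <- data.frame(snp_id = ref$snp_id[keep],
                    chrom = ref$chrom[keep],
                    pos = ref$pos[keep],
                    effect_allele = ref$effect_allele[keep],
                    other_allele = ref$other_allele[keep],
                    stringsAsFactors = FALSE)
  for (k in seq_along(sets)) {
    a <- aligned[[k]][keep, , drop = FALSE]
    out[[paste0("beta_", roles[k])]] <- a$beta
    out[[paste0("se_", roles[k])]] <- a$se
    out[[paste0("eaf_", roles[k])]] <- a$eaf
    out[[paste0("pvalue_", roles[k])]] <- a$pvalue
    out[[paste0("n_", roles[k])]] <- a$n
  }
  rownames(out) <- NULL
  drops <- if (length(dropped)) do.call(rbind, unname(dropped)) else
    data.frame(snp_id = character(), reason = character(), stringsAsFactors = FALSE)
  rownames(drops) <- NULL
  structure(list(roles = roles, data = out, dropped = drops,
                 palindrome_policy = palindrome_policy, eaf_window = eaf_window),
            class = "harmonized_set")
}

#' Construct a harmonized set from an already-aligned data frame
#'
#' Low-level constructor for programmatic use (simulation studies, tests):
#' wraps a data frame whose per-role columns are already expressed for one
#' shared effect allele per SNP.
#'
#' @param data Data frame with columns `snp_id` and, for each role `r`,
#'   `beta_r` and `se_r` (optionally `eaf_r`, `pvalue_r`, `n_r`,
#'   `chrom`, `pos`, alleles).
#' @param roles Character vector of role names, exposure(s) first and the
#'   outcome last.
#' @return A `harmonized_set`.
#' @export
as_harmonized_set <- function(data, roles) {
  if (!is.data.frame(data) || is.null(data$snp_id)) {
    mr_abort("`data` must be a data.frame with an snp_id column", "mr_input_error")
  }
  need <- c(paste0("beta_", roles), paste0("se_", roles))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    mr_abort(sprintf("missing aligned column(s): %s", paste(missing, collapse = ", ")),
             "mr_input_error")
  }
  for (r in roles) {
    if (any(data[[paste0("se_", r)]] <= 0)) {
      mr_abort(sprintf("nonpositive se for role '%s'", r), "mr_input_error")
    }
  }
  if (anyDuplicated(data$snp_id)) {
    mr_abort("duplicate snp_id in harmonized data", "mr_input_error")
  }
  rownames(data) <- NULL
  structure(list(roles = roles, data = data,
                 dropped = data.frame(snp_id = character(), reason = character(),
                                      stringsAsFactors = FALSE),
                 palindrome_policy = NA_character_, eaf_window = NA_real_),
            class = "harmonized_set")
}

#' Split a harmonized set back into per-role summary statistics
#'
#' @param h A `harmonized_set`.
#' @return Named list of canonical summary-statistics data frames, one per
#'   role, all expressed in the shared orientation.
#' @export
split_harmonized <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  d <- h$data
  stats::setNames(lapply(h$roles, function(r) {
    data.frame(snp_id = d$snp_id, chrom = d$chrom, pos = d$pos,
               effect_allele = d$effect_allele, other_allele = d$other_allele,
               eaf = d[[paste0("eaf_", r)]], beta = d[[paste0("beta_", r)]],
               se = d[[paste0("se_", r)]], pvalue = d[[paste0("pvalue_", r)]],
               n = d[[paste0("n_", r)]], stringsAsFactors = FALSE)
  }), h$roles)
}

#' Subset a harmonized set to selected SNPs
#'
#' @param h A `harmonized_set`.
#' @param snp_ids Character vector of SNP ids to retain.
#' @return A `harmonized_set` restricted to `snp_ids` (in `h`'s row order).
#' @export
subset_harmonized <- function(h, snp_ids) {
  stopifnot(inherits(h, "harmonized_set"))
  h$data <- h$data[h$data$snp_id %in% snp_ids, , drop = FALSE]
  rownames(h$data) <- NULL
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %d SNPs x %d roles (%s)\n",
              nrow(x$data), length(x$roles), paste(x$roles, collapse = ", ")))
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    cat("Dropped:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
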