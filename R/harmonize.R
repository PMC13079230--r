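# Allele harmonization: put all traits on the exposure's effect-allele frame.

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) unname(.complement[ea]) == oa

#' Harmonize two or three summary tables to a shared effect-allele frame
#'
#' Matches variants across tables by rsID, aligns every non-exposure table to
#' the exposure's effect allele, and returns the aligned multi-trait effect
#' matrix that all estimators operate on.  Per variant and non-exposure
#' table, the recorded action is one of `as_is`, `sign_flipped` (alleles
#' swapped: beta negated, eaf reflected), `strand_flipped` (complementary
#' strand, effects unchanged) or `strand_flipped_and_sign_flipped`.
#' Irreconcilable allele pairs are dropped with a reason code, as are
#' variants absent from any table (no proxy lookup is attempted).
#'
#' Palindromic variants (A/T or C/G) cannot be resolved from alleles alone.
#' Under `infer_by_freq` (default) they are kept only when the exposure and
#' the other trait's effect-allele frequencies both fall outside
#' `(freq_threshold, 1 - freq_threshold)`; the variant is aligned `as_is`
#' when the frequencies sit on the same side of 0.5 and sign-flipped when on
#' opposite sides.  Under `drop_all` every palindromic variant is removed.
#'
#' Retained variants are ordered by exposure p-value (ascending, rsID
#' tiebreak), so the output order is deterministic.
#'
#' @param tables list of 2 or 3 [summary_table()] objects; the first is the
#'   exposure and defines the effect-allele frame.
#' @param palindrome_policy `"infer_by_freq"` or `"drop_all"`.
#' @param freq_threshold ambiguity band half-width for `infer_by_freq`;
#'   default 0.42, i.e. frequencies in (0.42, 0.58) are ambiguous.
#' @return A `harmonized_set`: list with `snps` (data.frame: rsid, chrom,
#'   pos, effect_allele, other_allele), `traits` (named list of data.frames
#'   with beta, se, eaf, pval, n aligned to `snps`), `actions` (data.frame of
#'   per-variant actions, one column per non-exposure trait), `exposure`
#'   (trait id) and `dropped` (data.frame: rsid, reason).
#' @export
harmonize <- function(tables,
                      palindrome_policy = c("infer_by_freq", "drop_all"),
                      freq_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(is.list(tables), length(tables) %in% c(2L, 3L))
  ids <- vapply(tables, function(t) {
    id <- attr(t, "trait_id")
    if (is.null(id)) stop("harmonize() expects summary_table inputs",
                          call. = FALSE)
    id
  }, character(1))
  if (anyDuplicated(ids)) stop("trait ids must be distinct", call. = FALSE)
  names(tables) <- ids

  common <- Reduce(intersect, lapply(tables, function(t) t$rsid))
  exp_tab <- tables[[1L]]
  exp_tab <- exp_tab[match(common, exp_tab$rsid), , drop = FALSE]
  ord <- order(exp_tab$pval, exp_tab$rsid)
  exp_tab <- exp_tab[ord, , drop = FALSE]
  snp_ids <- exp_tab$rsid

  dropped <- data.frame(rsid = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop_snp <- function(rsid, reason) {
    dropped <<- rbind(dropped, data.frame(rsid = rsid, reason = reason,
                                          stringsAsFactors = FALSE))
  }
  for (tab in tables)
    for (r in setdiff(tab$rsid, common)) drop_snp(r, "unmatched_rsid")

  ea <- exp_tab$effect_allele
  oa <- exp_tab$other_allele
  pal <- .is_palindromic(ea, oa)
  ambiguous <- function(f) f > freq_threshold & f < (1 - freq_threshold)

  keep <- rep(TRUE, length(snp_ids))
  if (palindrome_policy == "drop_all") {
    keep[pal] <- FALSE
    for (r in snp_ids[pal]) drop_snp(r, "palindromic")
  } else {
    bad <- pal & ambiguous(exp_tab$eaf)
    keep[bad] <- FALSE
    for (r in snp_ids[bad]) drop_snp(r, "palindromic_ambiguous_freq")
  }

  traits <- list()
  traits[[ids[1L]]] <- data.frame(beta = exp_tab$beta, se = exp_tab$se,
                                  eaf = exp_tab$eaf, pval = exp_tab$pval,
                                  n = exp_tab$n)
  actions <- list()

  for (k in seq_along(tables)[-1L]) {
    tab <- tables[[k]][match(snp_ids, tables[[k]]$rsid), , drop = FALSE]
    act <- rep(NA_character_, length(snp_ids))
    beta <- tab$beta; se <- tab$se; eaf <- tab$eaf
    t_ea <- tab$effect_allele; t_oa <- tab$other_allele

    for (i in seq_along(snp_ids)) {
      if (!keep[i]) next
      if (pal[i]) {
        # allele labels cannot disambiguate strand for palindromes: use
        # frequency under infer_by_freq (drop_all already removed them)
        if (ambiguous(eaf[i])) {
          keep[i] <- FALSE; drop_snp(snp_ids[i], "palindromic_ambiguous_freq")
          next
        }
        same_side <- (exp_tab$eaf[i] > 0.5) == (eaf[i] > 0.5)
        if (same_side) {
          act[i] <- "as_is"
        } else {
          act[i] <- "sign_flipped"
          beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
        }
        next
      }
      cea <- unname(.complement[t_ea[i]]); coa <- unname(.complement[t_oa[i]])
      if (t_ea[i] == ea[i] && t_oa[i] == oa[i]) {
        act[i] <- "as_is"
      } else if (t_ea[i] == oa[i] && t_oa[i] == ea[i]) {
        act[i] <- "sign_flipped"
        beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
      } else if (cea == ea[i] && coa == oa[i]) {
        act[i] <- "strand_flipped"
      } else if (cea == oa[i] && coa == ea[i]) {
        act[i] <- "strand_flipped_and_sign_flipped"
        beta[i] <- -beta[i]; eaf[i] <- 1 - eaf[i]
      } else {
        keep[i] <- FALSE
        drop_snp(snp_ids[i], "irreconcilable_alleles")
      }
    }
    traits[[ids[k]]] <- data.frame(beta = beta, se = se, eaf = eaf,
                                   pval = tab$pval, n = tab$n)
    actions[[ids[k]]] <- act
  }

  snps <- data.frame(rsid = snp_ids, chrom = exp_tab$chrom, pos = exp_tab$pos,
                     effect_allele = ea, other_allele = oa,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(snps) <- NULL
  traits <- lapply(traits, function(d) {
    d <- d[keep, , drop = FALSE]; rownames(d) <- NULL; d
  })
  actions <- as.data.frame(lapply(actions, function(a) a[keep]),
                           optional = TRUE, stringsAsFactors = FALSE)

  structure(list(snps = snps, traits = traits, actions = actions,
                 exposure = ids[1L], dropped = dropped),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set: ", nrow(x$snps), " variants, traits: ",
      paste(names(x$traits), collapse = ", "),
      " (exposure: ", x$exposure, ")\n", sep = "")
  if (nrow(x$dropped))
    cat("Dropped:", paste(names(table(x$dropped$reason)),
                          table(x$dropped$reason),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of variants in a harmonized set
#' @param x a `harmonized_set`.
#' @export
n_snps <- function(x) nrow(x$snps)

#' Rebuild per-trait summary tables from a harmonized set
#'
#' Useful to feed harmonized data back through the pipeline (e.g. to check
#' idempotence, or to subset by instrument).
#'
#' @param x a `harmonized_set`.
#' @return named list of [summary_table()] objects, exposure first.
#' @export
as_summary_tables <- function(x) {
  stopifnot(inherits(x, "harmonized_set"))
  out <- lapply(names(x$traits), function(id) {
    tr <- x$traits[[id]]
    summary_table(data.frame(
      rsid = x$snps$rsid, chrom = x$snps$chrom, pos = x$snps$pos,
      effect_allele = x$snps$effect_allele, other_allele = x$snps$other_allele,
      eaf = tr$eaf, beta = tr$beta, se = tr$se, pval = tr$pval, n = tr$n,
      stringsAsFactors = FALSE), trait_id = id, quiet = TRUE)
  })
  names(out) <- names(x$traits)
  out
}

#' Subset a harmonized set to a set of variants
#' @param x a `harmonized_set`.
#' @param rsids character vector of rsIDs to retain (order of `x` is kept).
#' @export
subset_snps <- function(x, rsids) {
  stopifnot(inherits(x, "harmonized_set"))
  keep <- x$snps$rsid %in% rsids
  x$snps <- x$snps[keep, , drop = FALSE]; rownames(x$snps) <- NULL
  x$traits <- lapply(x$traits, function(d) {
    d <- d[keep, , drop = FALSE]; rownames(d) <- NULL; d
  })
  if (nrow(x$actions))
    x$actions <- x$actions[keep, , drop = FALSE]
  x
}
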