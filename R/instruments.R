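# Instrument selection: genome-wide significance and MAF screens, greedy LD
# clumping, and instrument-strength (F-statistic) filtering.

#' Significance and frequency screen for candidate instruments
#'
#' Keeps variants with association p-value strictly below `p_thresh` and
#' minor-allele frequency `min(eaf, 1 - eaf)` at or above `maf_min`.  Both
#' boundaries follow the usual conventions: `P < 5e-8` to enter clumping,
#' variants with MAF `< 0.01` removed.
#'
#' @param table a [summary_table()].
#' @param p_thresh genome-wide significance threshold (default `5e-8`).
#' @param maf_min minimum minor-allele frequency (default `0.01`).
#' @return a `summary_table` subset (possibly empty rows are allowed here;
#'   emptiness is reported by the caller).
#' @export
filter_candidates <- function(table, p_thresh = 5e-8, maf_min = 0.01) {
  stopifnot(inherits(table, "summary_table"))
  maf <- pmin(table$eaf, 1 - table$eaf)
  keep <- table$pval < p_thresh & maf >= maf_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    message("filter_candidates [", attr(table, "trait_id"),
            "]: no variants pass p < ", format(p_thresh), " and MAF >= ",
            maf_min)
  out
}

#' Greedy LD clumping of candidate variants
#'
#' Iteratively takes the lowest-p unclaimed variant as an index SNP and
#' removes every unclaimed variant on the same chromosome within
#' `window_kb` kilobases whose r2 with the index is at or above `r2_thresh`.
#' Ties in p-value are broken by rsID, so the result is invariant to input
#' row order.
#'
#' @param candidates a `summary_table` (typically from [filter_candidates()]).
#' @param ld an [ld_pairs()]/[ld_genotypes()] source covering candidate
#'   pairs, or `NULL`.
#' @param r2_thresh clumping r2 cut-off (default `0.001`).
#' @param window_kb clumping window in kilobases (default `10000`).
#' @param distance_fallback if `TRUE` and `ld` is `NULL`, fall back to
#'   distance-only clumping (keep only the best variant per window).  This
#'   changes results and is loudly warned about; default `FALSE`, in which
#'   case a missing LD source is an error.
#' @return the retained (index) variants as a `summary_table` subset, in
#'   p-value order.
#' @export
greedy_clump <- function(candidates, ld, r2_thresh = 0.001,
                         window_kb = 10000, distance_fallback = FALSE) {
  stopifnot(inherits(candidates, "summary_table"))
  if (is.null(ld) && !distance_fallback)
    stop("no LD source supplied and distance_fallback = FALSE; ",
         "clumping requires pairwise r2 coverage", call. = FALSE)
  if (is.null(ld) && distance_fallback)
    warning("clumping without LD data: keeping only the lowest-p variant ",
            "per ", window_kb, " kb window (distance-only fallback)",
            call. = FALSE)
  if (nrow(candidates) == 0L) return(candidates)

  ord <- order(candidates$pval, candidates$rsid)
  cand <- candidates[ord, , drop = FALSE]
  claimed <- rep(FALSE, nrow(cand))
  index <- logical(nrow(cand))
  win_bp <- window_kb * 1000

  for (i in seq_len(nrow(cand))) {
    if (claimed[i]) next
    index[i] <- TRUE
    claimed[i] <- TRUE
    near <- which(!claimed & cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= win_bp)
    if (!length(near)) next
    if (is.null(ld)) {
      claimed[near] <- TRUE
    } else {
      r2 <- ld_r2(ld, cand$rsid[i], cand$rsid[near])
      claimed[near[r2 >= r2_thresh]] <- TRUE
    }
  }
  out <- cand[index, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength: per-SNP and overall F-statistics
#'
#' The per-variant F is the squared z-score `(beta/se)^2`.  The variance in
#' the exposure explained by variant j (standardized trait) is
#' `r2_j = 2 * eaf_j * (1 - eaf_j) * beta_j^2`, and the overall F over the L
#' retained variants is `((n - L - 1) / L) * (R2 / (1 - R2))` with
#' `R2 = sum(r2_j)`.  Variants with per-SNP F below `f_min` are removed
#' (weak-instrument screen); with `f_min = 10` a variant with F = 10 exactly
#' survives.
#'
#' @param snps a `summary_table` subset of clumped index variants.
#' @param n exposure GWAS sample size; defaults to the median per-variant
#'   `n` of `snps`.
#' @param f_min per-SNP F threshold (default 10).
#' @return an `instrument_set`: list with `exposure_id`, `snps` (the records
#'   plus columns `f_stat`, `r2_snp` and the filter flags), and `summary`
#'   (`n_selected`, `mean_f`, `total_r2`, `overall_f`, `n`).
#' @export
instrument_strength <- function(snps, n = NULL, f_min = 10) {
  stopifnot(inherits(snps, "summary_table"))
  if (is.null(n)) n <- stats::median(snps$n)
  f_stat <- (snps$beta / snps$se)^2
  r2_snp <- 2 * snps$eaf * (1 - snps$eaf) * snps$beta^2
  passed_f <- f_stat >= f_min
  kept <- snps[passed_f, , drop = FALSE]
  kept$f_stat <- f_stat[passed_f]
  kept$r2_snp <- r2_snp[passed_f]
  rownames(kept) <- NULL

  L <- nrow(kept)
  total_r2 <- sum(kept$r2_snp)
  overall_f <- NA_real_
  if (L > 0) {
    if (!is.na(n) && n > L + 1) {
      overall_f <- ((n - L - 1) / L) * (total_r2 / (1 - total_r2))
    } else {
      warning("overall F undefined: sample size n must exceed L + 1",
              call. = FALSE)
    }
  }
  structure(list(
    exposure_id = attr(snps, "trait_id"),
    snps = as.data.frame(kept),
    summary = list(n_selected = L,
                   mean_f = if (L) mean(kept$f_stat) else NA_real_,
                   total_r2 = total_r2, overall_f = overall_f, n = n)),
    class = "instrument_set")
}

#' Select independent, strong instruments for one trait
#'
#' Full selection pipeline: significance/MAF screen ([filter_candidates()]),
#' greedy LD clumping ([greedy_clump()]), then the per-SNP F screen
#' ([instrument_strength()]).  Defaults reproduce the conventional strict
#' setting: `P < 5e-8`, MAF `>= 0.01`, `r2 < 0.001` within a 10,000 kb
#' window, per-SNP F `>= 10`.
#'
#' @inheritParams filter_candidates
#' @inheritParams greedy_clump
#' @inheritParams instrument_strength
#' @return an `instrument_set`; `summary$n_selected` may be zero.
#' @export
select_instruments <- function(table, ld, p_thresh = 5e-8, maf_min = 0.01,
                               r2_thresh = 0.001, window_kb = 10000,
                               f_min = 10, n = NULL,
                               distance_fallback = FALSE) {
  cand <- filter_candidates(table, p_thresh = p_thresh, maf_min = maf_min)
  if (nrow(cand) == 0L) {
    return(structure(list(exposure_id = attr(table, "trait_id"),
                          snps = cbind(as.data.frame(cand),
                                       f_stat = numeric(0),
                                       r2_snp = numeric(0)),
                          summary = list(n_selected = 0L, mean_f = NA_real_,
                                         total_r2 = 0, overall_f = NA_real_,
                                         n = n %||% NA_real_)),
                     class = "instrument_set"))
  }
  idx <- greedy_clump(cand, ld, r2_thresh = r2_thresh, window_kb = window_kb,
                      distance_fallback = distance_fallback)
  instrument_strength(idx, n = n, f_min = f_min)
}

#' @export
print.instrument_set <- function(x, ...) {
  s <- x$summary
  cat("Instrument set for '", x$exposure_id, "': ", s$n_selected,
      " variants\n", sep = "")
  if (s$n_selected > 0)
    cat(sprintf("  mean per-SNP F = %.1f, R2 = %.4f, overall F = %s\n",
                s$mean_f, s$total_r2,
                ifelse(is.na(s$overall_f), "NA",
                       sprintf("%.1f", s$overall_f))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
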