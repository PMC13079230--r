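# Two-step MR mediation: path coefficients a (exposure -> mediator),
# b (mediator -> outcome), total effect c, direct effect c' (multivariable
# IVW), indirect effect a*b with a distribution-of-product CI, proportion
# mediated, and the difference-method cross-check.

#' Monte-Carlo confidence interval for a product of two coefficients
#'
#' Sampling analogue of the analytic distribution-of-product method: draw
#' `A ~ N(a, se_a^2)` and `B ~ N(b, se_b^2)` independently and take the
#' percentile interval of `A * B`.  The product-normal distribution is
#' asymmetric, so the interval is generally not centred on `a * b`.
#'
#' @param a,se_a first coefficient and its standard error.
#' @param b,se_b second coefficient and its standard error.
#' @param level confidence level (default 0.95).
#' @param mc_draws Monte-Carlo draws (default 1e6).
#' @param seed RNG seed (`NULL` leaves the RNG state as is).
#' @return numeric length-2 vector `c(low, high)`.
#' @export
product_ci <- function(a, se_a, b, se_b, level = 0.95, mc_draws = 1e6,
                       seed = NULL) {
  stopifnot(se_a >= 0, se_b >= 0)
  if (se_a == 0 && se_b == 0) return(c(a * b, a * b))
  if (!is.null(seed)) set.seed(seed)
  prod <- stats::rnorm(mc_draws, a, se_a) * stats::rnorm(mc_draws, b, se_b)
  unname(stats::quantile(prod, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Difference-method indirect effect
#'
#' `indirect = c - c'` where `c` is the total effect and `c'` the direct
#' effect of the exposure conditional on the mediator (multivariable IVW);
#' the proportion mediated is `(c - c') / c`.
#'
#' @param c_est total-effect estimate: one-row data.frame as returned by
#'   [mr_ivw()], or a numeric scalar.
#' @param mvmr_fit result of [mr_mvmr_ivw()] whose first row (term
#'   `"exposure"` if named) is the exposure direct effect, or a numeric
#'   scalar c'.
#' @return list with `indirect_diff`, `proportion_diff` (`NA` and flagged
#'   when `c` is zero).
#' @export
difference_method <- function(c_est, mvmr_fit) {
  c_val <- if (is.data.frame(c_est)) c_est$beta[1] else as.numeric(c_est)
  c_prime <- if (is.data.frame(mvmr_fit)) {
    i <- if ("term" %in% names(mvmr_fit) && "exposure" %in% mvmr_fit$term)
      which(mvmr_fit$term == "exposure")[1] else 1L
    mvmr_fit$beta[i]
  } else as.numeric(mvmr_fit)
  indirect <- c_val - c_prime
  if (c_val == 0)
    return(list(indirect_diff = indirect, proportion_diff = NA_real_,
                flag = "total_effect_zero"))
  list(indirect_diff = indirect, proportion_diff = indirect / c_val,
       flag = NULL)
}

#' Two-step MR mediation analysis
#'
#' Estimates the mediated pathway exposure -> mediator -> outcome from three
#' GWAS summary tables.  Step 1 estimates the exposure -> mediator effect
#' `a` by IVW using the exposure's instruments; step 2 estimates the
#' mediator -> outcome effect `b` by IVW using the mediator's own
#' instruments (optionally conditional on the exposure via multivariable
#' IVW); the total effect `c` uses the exposure's instruments against the
#' outcome.  The indirect effect is the product `a * b`, its confidence
#' interval comes from [product_ci()], and the proportion mediated is
#' `(a * b) / c`.  As a cross-check, the direct effect `c'` is estimated by
#' multivariable IVW over the union of both instrument sets and the
#' difference method (`c - c'`) is reported alongside.
#'
#' Instruments for exposure and mediator are selected with
#' [select_instruments()] at the supplied thresholds.  Variants shared by
#' the two instrument sets are reported (`overlap_snps`) but not removed.
#' A proportion outside [0, 1], or an indirect effect whose sign differs
#' from the total effect, is reported verbatim with an
#' `"inconsistent_mediation"` flag, never truncated.
#'
#' @param exposure,mediator,outcome [summary_table()] objects.
#' @param ld an LD source for clumping; the default [ld_independent()] is
#'   appropriate for pre-pruned or simulated independent panels.
#' @param p_thresh,maf_min,r2_thresh,window_kb,f_min instrument-selection
#'   thresholds, see [select_instruments()].
#' @param b_method `"univariable"` (default) estimates `b` by univariable
#'   IVW from the mediator's instruments; `"mvmr"` conditions `b` on the
#'   exposure.
#' @param variance_model IVW variance model.
#' @param mc_draws draws for the product CI.
#' @param seed RNG seed (product CI and any bootstrap).
#' @param palindrome_policy passed to [harmonize()].
#' @return an object of class `mr_mediation`: list with the component
#'   estimates `a`, `b`, `c`, `c_prime` (one-row data.frames), `indirect`,
#'   `indirect_ci`, `proportion`, `indirect_diff`, `proportion_diff`,
#'   `flags`, `instruments` (the two `instrument_set`s), `overlap_snps`,
#'   `mc_draws`, `seed`.
#' @export
mr_mediation <- function(exposure, mediator, outcome,
                         ld = ld_independent(),
                         p_thresh = 5e-8, maf_min = 0.01, r2_thresh = 0.001,
                         window_kb = 10000, f_min = 10,
                         b_method = c("univariable", "mvmr"),
                         variance_model = c("multiplicative_random", "fixed"),
                         mc_draws = 1e6, seed = NULL,
                         palindrome_policy = "infer_by_freq") {
  b_method <- match.arg(b_method)
  variance_model <- match.arg(variance_model)
  sel <- function(tab) select_instruments(
    tab, ld, p_thresh = p_thresh, maf_min = maf_min, r2_thresh = r2_thresh,
    window_kb = window_kb, f_min = f_min)

  iv_x <- sel(exposure)
  if (iv_x$summary$n_selected == 0L)
    stop("no instruments selectable for exposure '", trait_id(exposure),
         "'", call. = FALSE)
  iv_m <- sel(mediator)
  if (iv_m$summary$n_selected == 0L)
    stop("step 2 infeasible: no instruments selectable for mediator '",
         trait_id(mediator), "'", call. = FALSE)

  keep_x <- iv_x$snps$rsid
  keep_m <- iv_m$snps$rsid
  overlap <- intersect(keep_x, keep_m)

  sub_tab <- function(tab, rsids) {
    out <- tab[tab$rsid %in% rsids, , drop = FALSE]
    summary_table(as.data.frame(out), trait_id = attr(tab, "trait_id"),
                  quiet = TRUE)
  }

  h_xm <- harmonize(list(sub_tab(exposure, keep_x),
                         sub_tab(mediator, keep_x)),
                    palindrome_policy = palindrome_policy)
  h_xy <- harmonize(list(sub_tab(exposure, keep_x),
                         sub_tab(outcome, keep_x)),
                    palindrome_policy = palindrome_policy)
  a_est <- mr_ivw(h_xm, variance_model = variance_model)
  c_est <- mr_ivw(h_xy, variance_model = variance_model)

  # step 2: mediator's own instruments against the outcome
  h_my <- harmonize(list(sub_tab(mediator, keep_m),
                         sub_tab(outcome, keep_m)),
                    palindrome_policy = palindrome_policy)
  b_est <- if (b_method == "univariable") {
    mr_ivw(h_my, variance_model = variance_model)
  } else {
    h_xmy_m <- harmonize(list(sub_tab(mediator, keep_m),
                              sub_tab(exposure, keep_m),
                              sub_tab(outcome, keep_m)),
                         palindrome_policy = palindrome_policy)
    bX <- cbind(mediator = h_xmy_m$traits[[1]]$beta,
                exposure = h_xmy_m$traits[[2]]$beta)
    fit <- mr_mvmr_ivw(bX, h_xmy_m$traits[[3]]$beta,
                       h_xmy_m$traits[[3]]$se)
    fit[fit$term == "mediator", , drop = FALSE]
  }

  # difference method: direct effect c' from multivariable IVW over the
  # union of both instrument sets
  union_ids <- union(keep_x, keep_m)
  h_union <- harmonize(list(sub_tab(exposure, union_ids),
                            sub_tab(mediator, union_ids),
                            sub_tab(outcome, union_ids)),
                       palindrome_policy = palindrome_policy)
  bX <- cbind(exposure = h_union$traits[[1]]$beta,
              mediator = h_union$traits[[2]]$beta)
  mv <- mr_mvmr_ivw(bX, h_union$traits[[3]]$beta, h_union$traits[[3]]$se)
  c_prime <- mv[mv$term == "exposure", , drop = FALSE]

  indirect <- a_est$beta * b_est$beta
  ci <- product_ci(a_est$beta, a_est$se, b_est$beta, b_est$se,
                   mc_draws = mc_draws, seed = seed)
  proportion <- if (c_est$beta != 0) indirect / c_est$beta else NA_real_
  diff <- difference_method(c_est, mv)

  flags <- character(0)
  if (is.na(proportion)) flags <- c(flags, "total_effect_zero")
  else if (sign(indirect) != sign(c_est$beta) && indirect != 0)
    flags <- c(flags, "inconsistent_mediation")
  else if (proportion < 0 || proportion > 1)
    flags <- c(flags, "inconsistent_mediation")

  structure(list(
    a = a_est, b = b_est, c = c_est, c_prime = c_prime,
    indirect = indirect, indirect_ci = ci, proportion = proportion,
    indirect_diff = diff$indirect_diff,
    proportion_diff = diff$proportion_diff,
    flags = flags, b_method = b_method,
    instruments = list(exposure = iv_x, mediator = iv_m),
    overlap_snps = overlap, mc_draws = mc_draws, seed = seed,
    traits = c(exposure = trait_id(exposure), mediator = trait_id(mediator),
               outcome = trait_id(outcome))),
    class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 4, ...) {
  tr <- x$traits
  cat("Two-step MR mediation: ", tr[["exposure"]], " -> ", tr[["mediator"]],
      " -> ", tr[["outcome"]], "\n", sep = "")
  fmt <- function(e) sprintf("%+.*f (se %.*f)", digits, e$beta, digits, e$se)
  cat("  a (exposure -> mediator): ", fmt(x$a), ", ",
      x$a$n_snp, " instruments\n", sep = "")
  cat("  b (mediator -> outcome):  ", fmt(x$b), ", ",
      x$b$n_snp, " instruments [", x$b_method, "]\n", sep = "")
  cat("  c (total effect):         ", fmt(x$c), "\n", sep = "")
  cat("  c' (direct effect, MVMR): ", fmt(x$c_prime), "\n", sep = "")
  cat(sprintf("  indirect a*b = %+.*f  [95%% CI %+.*f, %+.*f]\n",
              digits, x$indirect, digits, x$indirect_ci[1], digits,
              x$indirect_ci[2]))
  if (!is.na(x$proportion))
    cat(sprintf("  proportion mediated (product):    %.1f%%\n",
                100 * x$proportion))
  if (!is.na(x$proportion_diff))
    cat(sprintf("  proportion mediated (difference): %.1f%%\n",
                100 * x$proportion_diff))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (length(x$overlap_snps))
    cat("  instrument overlap:", length(x$overlap_snps), "variant(s)\n")
  invisible(x)
}

#' Mediation result as a one-row data.frame
#' @param x an `mr_mediation`.
#' @param ... unused.
#' @export
as.data.frame.mr_mediation <- function(x, ...) {
  data.frame(
    exposure = x$traits[["exposure"]], mediator = x$traits[["mediator"]],
    outcome = x$traits[["outcome"]],
    a = x$a$beta, a_se = x$a$se, b = x$b$beta, b_se = x$b$se,
    c = x$c$beta, c_se = x$c$se, c_prime = x$c_prime$beta,
    c_prime_se = x$c_prime$se,
    indirect = x$indirect, indirect_ci_low = x$indirect_ci[1],
    indirect_ci_high = x$indirect_ci[2], proportion = x$proportion,
    indirect_diff = x$indirect_diff, proportion_diff = x$proportion_diff,
    flags = paste(x$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}
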