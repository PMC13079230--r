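# Heterogeneity, pleiotropy, outlier and power diagnostics.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j w_j (theta_j - beta_ivw)^2` over the per-variant ratio
#' estimates `theta_j = by_j / bx_j`, with first-order weights
#' `w_j = 1 / se(theta_j)^2 = (bx_j / byse_j)^2`; under homogeneity Q is
#' chi-square with `L - 1` degrees of freedom.  A p-value below 0.05 is
#' conventionally read as heterogeneity among the variant-specific causal
#' estimates.
#'
#' @inheritParams mr_ivw
#' @param ivw_beta the pooled estimate to measure dispersion around;
#'   defaults to the fixed-effect IVW estimate recomputed from `x`.
#' @return list with `q_stat`, `q_df`, `q_pval` (all `NA` with fewer than 2
#'   variants).
#' @export
cochran_q <- function(x, ivw_beta = NULL, exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 2L)
    return(list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_))
  w <- (d$bx / d$byse)^2
  if (is.null(ivw_beta)) {
    wy <- 1 / d$byse^2
    ivw_beta <- sum(wy * d$bx * d$by) / sum(wy * d$bx^2)
  }
  theta <- d$by / d$bx
  q <- sum(w * (theta - ivw_beta)^2)
  list(q_stat = q, q_df = L - 1L,
       q_pval = stats::pchisq(q, df = L - 1L, lower.tail = FALSE))
}

#' Egger intercept test for directional pleiotropy
#'
#' Flags horizontal pleiotropy when the MR-Egger intercept differs from zero
#' at `alpha` (the intercept estimates the average direct effect of the
#' variants on the outcome).
#'
#' @param egger_fit result of [mr_egger()] (or anything containing a row
#'   with `method == "egger_intercept"`).
#' @param alpha significance level (default 0.05).
#' @return list with `intercept`, `se`, `pval`, `pleiotropy` (logical).
#' @export
egger_intercept_test <- function(egger_fit, alpha = 0.05) {
  row <- egger_fit[egger_fit$method == "egger_intercept", , drop = FALSE]
  if (nrow(row) != 1L)
    stop("egger_fit does not contain an egger_intercept row", call. = FALSE)
  list(intercept = row$beta, se = row$se, pval = row$pval,
       pleiotropy = row$pval < alpha)
}

#' Residual-sum-of-squares global pleiotropy and outlier test (MR-PRESSO)
#'
#' The observed statistic is `RSS = sum_j w_j (by_j - theta_(-j) bx_j)^2`
#' with `theta_(-j)` the leave-one-out IVW estimate and `w_j = 1/byse_j^2`.
#' Its null distribution is built by parametric simulation: in each of
#' `n_sim` draws, `bx*_j ~ N(bx_j, bxse_j)` and
#' `by*_j ~ N(theta_(-j) bx_j, byse_j)`, and the RSS (including the
#' leave-one-out estimates) is recomputed on the simulated data.  The global
#' p-value uses the `(1 + k) / (n_sim + 1)` convention so empirical p-values
#' are never exactly zero.  Per-variant outlier p-values compare each
#' observed weighted squared residual with its simulated counterparts and
#' are Bonferroni-adjusted by L; variants with adjusted p below
#' `outlier_alpha` are flagged.
#'
#' @inheritParams mr_ivw
#' @param n_sim number of parametric simulations (default 1000; the p-value
#'   resolution is `1/(n_sim + 1)`).
#' @param seed RNG seed (`NULL` leaves the RNG state as is).
#' @param outlier_alpha threshold on the Bonferroni-adjusted per-variant
#'   p-value (default 0.05).
#' @return list with `global_pval`, `outlier_ids`, `outlier_pvals` (named,
#'   adjusted), `rss_obs`, `n_sim`.
#' @export
mr_presso <- function(x, n_sim = 1000, seed = NULL, outlier_alpha = 0.05,
                      exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 4L)
    stop("the global pleiotropy test requires at least 4 variants",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w <- 1 / d$byse^2

  loo_resid_sq <- function(bx, by) {
    sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
    theta_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
    w * (by - theta_loo * bx)^2
  }
  obs_sq <- loo_resid_sq(d$bx, d$by)
  rss_obs <- sum(obs_sq)

  # expected outcome effects under the no-pleiotropy null for each variant
  sxx <- sum(w * d$bx^2); sxy <- sum(w * d$bx * d$by)
  theta_loo <- (sxy - w * d$bx * d$by) / (sxx - w * d$bx^2)
  mu_y <- theta_loo * d$bx

  sim_sq <- matrix(0, nrow = L, ncol = n_sim)
  for (s in seq_len(n_sim)) {
    bxs <- stats::rnorm(L, d$bx, d$bxse)
    bys <- stats::rnorm(L, mu_y, d$byse)
    sim_sq[, s] <- loo_resid_sq(bxs, bys)
  }
  rss_sim <- colSums(sim_sq)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + rowSums(sim_sq >= obs_sq)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * L)
  names(p_adj) <- d$snps
  outliers <- d$snps[p_adj < outlier_alpha]

  list(global_pval = global_pval, outlier_ids = outliers,
       outlier_pvals = p_adj, rss_obs = rss_obs, n_sim = n_sim)
}

#' Analytic power for MR with a continuous outcome
#'
#' Two-sided normal approximation (Burgess-style): with outcome sample size
#' `n`, instrument variance explained `r2` and assumed true effect `beta`
#' (SD per SD),
#' `power = pnorm(-z + |beta| sqrt(n r2)) + pnorm(-z - |beta| sqrt(n r2))`
#' with `z = qnorm(1 - alpha/2)`.  At `beta = 0` the power equals `alpha`.
#'
#' @param n outcome GWAS sample size.
#' @param r2 proportion of exposure variance explained by the instruments,
#'   in (0, 1).
#' @param beta assumed true causal effect, SD units.
#' @param alpha significance level (default 0.05).
#' @return power in `[alpha, 1]`.
#' @export
power_continuous <- function(n, r2, beta, alpha = 0.05) {
  stopifnot(n > 0)
  if (!is.finite(r2) || r2 <= 0 || r2 >= 1)
    stop("r2 must lie strictly between 0 and 1", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(beta) * sqrt(n * r2)
  stats::pnorm(-z + ncp) + stats::pnorm(-z - ncp)
}

#' Full sensitivity report for one exposure-outcome analysis
#'
#' Bundles Cochran's Q, the Egger intercept test, the simulation-based
#' global pleiotropy/outlier test (when at least 4 variants are available),
#' and analytic power for a user-supplied assumed effect.
#'
#' @inheritParams mr_ivw
#' @param n_sim simulations for the global pleiotropy test.
#' @param seed RNG seed for the simulations.
#' @param power_beta assumed true effect for the power calculation (`NULL`
#'   skips it).
#' @param n_outcome outcome sample size for power.
#' @param r2 instrument variance explained for power (e.g.
#'   `instrument_set$summary$total_r2`).
#' @param alpha significance level used by the flagging rules.
#' @return a `sensitivity_report` list.
#' @export
mr_sensitivity <- function(x, n_sim = 1000, seed = NULL, power_beta = NULL,
                           n_outcome = NULL, r2 = NULL, alpha = 0.05,
                           exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  q <- cochran_q(d)

  eg <- if (L >= 3L) mr_egger(d) else NULL
  eg_test <- if (!is.null(eg)) egger_intercept_test(eg, alpha = alpha) else
    list(intercept = NA_real_, se = NA_real_, pval = NA_real_,
         pleiotropy = NA)

  pr <- if (L >= 4L) mr_presso(d, n_sim = n_sim, seed = seed) else
    list(global_pval = NA_real_, outlier_ids = character(0), n_sim = 0L)

  pw <- if (!is.null(power_beta) && !is.null(n_outcome) && !is.null(r2))
    power_continuous(n_outcome, r2, power_beta, alpha) else NA_real_

  structure(list(
    q_stat = q$q_stat, q_df = q$q_df, q_pval = q$q_pval,
    egger_intercept = eg_test$intercept,
    egger_intercept_se = eg_test$se,
    egger_intercept_pval = eg_test$pval,
    pleiotropy_flag = eg_test$pleiotropy,
    presso_global_pval = pr$global_pval,
    presso_outlier_ids = pr$outlier_ids,
    power = pw, n_sim = pr$n_sim, seed = seed, n_snp = L),
    class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report (", x$n_snp, " variants)\n", sep = "")
  if (!is.na(x$q_stat))
    cat(sprintf("  Cochran's Q = %.3f (df %d), p = %.3g\n",
                x$q_stat, x$q_df, x$q_pval))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g%s\n",
                x$egger_intercept, x$egger_intercept_se,
                x$egger_intercept_pval,
                if (isTRUE(x$pleiotropy_flag)) "  ** pleiotropy" else ""))
  if (!is.na(x$presso_global_pval))
    cat(sprintf("  Global pleiotropy test p = %.3g (%d sims), outliers: %s\n",
                x$presso_global_pval, x$n_sim,
                if (length(x$presso_outlier_ids))
                  paste(x$presso_outlier_ids, collapse = ", ") else "none"))
  if (!is.na(x$power))
    cat(sprintf("  Power at assumed effect: %.3f\n", x$power))
  invisible(x)
}
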