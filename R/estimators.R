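# Causal-effect estimators over harmonized summary statistics.
#
# All methods operate on per-variant exposure effects bx (se bxse) and
# outcome effects by (se byse) in a shared effect-allele frame.  The IVW
# estimate is the inverse-variance-weighted combination of per-variant Wald
# ratios, equivalently WLS of by on bx through the origin with weights
# 1/byse^2; the robust methods (Egger, weighted median, mode-based) relax
# the no-pleiotropy assumption in different ways.

Z95 <- 1.96  # conventional normal 95% half-width used throughout MR reports

#' Bundle per-variant effects for the estimators
#'
#' @param bx,bxse exposure effects and standard errors.
#' @param by,byse outcome effects and standard errors.
#' @param snps optional rsIDs.
#' @return an `mr_input` list.
#' @export
mr_input <- function(bx, bxse, by, byse, snps = NULL) {
  L <- length(bx)
  stopifnot(length(bxse) == L, length(by) == L, length(byse) == L,
            all(bxse > 0), all(byse > 0))
  if (is.null(snps)) snps <- paste0("snp", seq_len(L))
  structure(list(bx = as.numeric(bx), bxse = as.numeric(bxse),
                 by = as.numeric(by), byse = as.numeric(byse),
                 snps = as.character(snps)),
            class = "mr_input")
}

# Coerce a harmonized_set (exposure = first trait, outcome = `outcome` or
# last trait) or an mr_input to the common input form.
as_mr_input <- function(x, exposure = NULL, outcome = NULL) {
  if (inherits(x, "mr_input")) return(x)
  if (!inherits(x, "harmonized_set"))
    stop("expected a harmonized_set or mr_input", call. = FALSE)
  ids <- names(x$traits)
  exposure <- exposure %||% x$exposure
  outcome <- outcome %||% ids[length(ids)]
  ex <- x$traits[[exposure]]; ou <- x$traits[[outcome]]
  if (is.null(ex) || is.null(ou))
    stop("trait not present in harmonized set", call. = FALSE)
  mr_input(ex$beta, ex$se, ou$beta, ou$se, snps = x$snps$rsid)
}

.mr_est <- function(method, beta, se, n_snp, variance_model = NA_character_,
                    df = NULL) {
  if (is.null(df)) {
    pval <- 2 * stats::pnorm(-abs(beta / se))
    half <- Z95 * se
  } else {
    pval <- 2 * stats::pt(-abs(beta / se), df = df)
    half <- stats::qt(0.975, df = df) * se
  }
  data.frame(method = method, beta = beta, se = se,
             ci_low = beta - half, ci_high = beta + half,
             pval = max(pval, .Machine$double.xmin), n_snp = n_snp,
             variance_model = variance_model, stringsAsFactors = FALSE)
}

#' Wald ratio for a single variant
#'
#' `beta = by / bx` with first-order standard error `byse / |bx|`; the
#' second-order (delta-method) option also propagates the exposure-side
#' uncertainty: `sqrt(byse^2 / bx^2 + by^2 * bxse^2 / bx^4)`.
#'
#' @param bx,bxse exposure effect and standard error (`bx` must be nonzero).
#' @param by,byse outcome effect and standard error.
#' @param second_order use the second-order standard error.
#' @return one-row data.frame (`method = "wald"`).
#' @export
wald_ratio <- function(bx, bxse, by, byse, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined: exposure effect bx is zero",
                    call. = FALSE)
  beta <- by / bx
  se <- if (second_order) {
    sqrt(byse^2 / bx^2 + by^2 * bxse^2 / bx^4)
  } else {
    byse / abs(bx)
  }
  .mr_est("wald", beta, se, n_snp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' With weights `w_j = 1/byse_j^2`, `beta = sum(w bx by) / sum(w bx^2)` and
#' fixed-effect `se = sqrt(1 / sum(w bx^2))`.  Under the multiplicative
#' random-effects model (the default, which accommodates balanced
#' heterogeneity in the variant-specific ratios) the standard error is
#' scaled by `max(1, sqrt(Q / (L - 1)))` where Q is Cochran's Q.  P-values
#' use the normal distribution.
#'
#' @param x a `harmonized_set` or [mr_input()].
#' @param variance_model `"multiplicative_random"` (default) or `"fixed"`.
#' @param exposure,outcome trait ids when `x` is a harmonized set (defaults:
#'   first and last trait).
#' @return one-row data.frame (`method = "ivw_mre"` or `"ivw_fe"`).
#' @export
mr_ivw <- function(x, variance_model = c("multiplicative_random", "fixed"),
                   exposure = NULL, outcome = NULL) {
  variance_model <- match.arg(variance_model)
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 1L) stop("IVW requires at least one variant", call. = FALSE)
  w <- 1 / d$byse^2
  sxx <- sum(w * d$bx^2)
  beta <- sum(w * d$bx * d$by) / sxx
  se <- sqrt(1 / sxx)
  if (variance_model == "multiplicative_random" && L >= 2L) {
    q <- cochran_q(d, ivw_beta = beta)
    se <- se * max(1, sqrt(q$q_stat / (L - 1)))
  }
  method <- if (variance_model == "fixed") "ivw_fe" else "ivw_mre"
  .mr_est(method, beta, se, n_snp = L, variance_model =
            if (variance_model == "fixed") "fixed" else "multiplicative_random")
}

#' MR-Egger regression
#'
#' Weighted regression of `by` on `bx` with an intercept (weights
#' `1/byse^2`), after jointly flipping `(bx, by)` signs so all exposure
#' effects are positive.  The slope is the pleiotropy-adjusted causal
#' estimate under the InSIDE assumption; the intercept estimates the average
#' directional pleiotropic effect.  Standard errors are scaled by
#' `max(1, sqrt(RSS_w / (L - 2)))` and inference uses t with `L - 2` df.
#'
#' @inheritParams mr_ivw
#' @return two-row data.frame: `egger_slope` and `egger_intercept`.
#' @export
mr_egger <- function(x, exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 3L)
    stop("MR-Egger requires at least 3 variants (", L, " supplied)",
         call. = FALSE)
  flip <- sign(d$bx); flip[flip == 0] <- 1
  bx <- d$bx * flip; by <- d$by * flip
  w <- 1 / d$byse^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- solve(xtwx, crossprod(X, w * by))
  resid <- by - X %*% coefs
  rss_w <- sum(w * resid^2)
  scale <- max(1, sqrt(rss_w / (L - 2)))
  ses <- sqrt(diag(solve(xtwx))) * scale
  rbind(
    .mr_est("egger_slope", coefs["slope", 1], ses["slope"], n_snp = L,
            variance_model = "multiplicative_random", df = L - 2),
    .mr_est("egger_intercept", coefs["intercept", 1], ses["intercept"],
            n_snp = L, variance_model = "multiplicative_random", df = L - 2)
  )
}

# Weighted median of ratio estimates theta with normalized weights w:
# cumulative midpoints s_j = cumsum(w)_j - w_j/2, linear interpolation at 0.5.
.weighted_median <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  L <- length(theta)
  if (s[L] <= 0.5) return(theta[L])
  k <- max(which(s < 0.5))
  theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

.boot_se <- function(d, estimator, n_boot, seed) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(d$bx)
  ests <- vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(L, d$bx, d$bxse)
    by <- stats::rnorm(L, d$by, d$byse)
    estimator(bx, by)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant ratio estimates
#' `theta_j = by_j / bx_j` with inverse-variance weights
#' `1 / se(theta_j)^2` (first-order).  Consistent when at least half the
#' weight comes from valid instruments.  The standard error is obtained by
#' parametric bootstrap: `bx` and `by` are resampled from normal
#' distributions centred at the observed values.
#'
#' @inheritParams mr_ivw
#' @param weighted if `FALSE`, use uniform weights (simple median).
#' @param n_boot bootstrap draws for the standard error.
#' @param seed RNG seed for the bootstrap (`NULL` leaves the RNG state as is).
#' @return one-row data.frame (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(x, weighted = TRUE, n_boot = 1000,
                               seed = NULL, exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 3L)
    stop("weighted median requires at least 3 variants", call. = FALSE)
  wfun <- if (weighted) {
    function(bx, by) (bx / d$byse)^2
  } else {
    function(bx, by) rep(1, length(bx))
  }
  est_fun <- function(bx, by) .weighted_median(by / bx, wfun(bx, by))
  beta <- est_fun(d$bx, d$by)
  se <- .boot_se(d, est_fun, n_boot, seed)
  .mr_est("weighted_median", beta, se, n_snp = L)
}

# Mode of the kernel-smoothed density of ratio estimates.  Normal kernel;
# bandwidth h = phi * 0.9 * min(sd, mad) * L^(-1/5) (mad normal-consistent);
# argmax taken on a 512-point grid spanning mean(theta) +/- 5 sd(theta).
.smoothed_mode <- function(theta, w, phi) {
  s <- stats::sd(theta)
  if (!is.finite(s) || s == 0) return(theta[1])
  m <- stats::mad(theta)  # default constant 1.4826 is normal-consistent
  h <- phi * 0.9 * min(s, if (m > 0) m else s) * length(theta)^(-1 / 5)
  grid <- seq(mean(theta) - 5 * s, mean(theta) + 5 * s, length.out = 512)
  w <- w / sum(w)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - theta) / h)) / h, numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The mode of the kernel-smoothed empirical density of the per-variant
#' ratio estimates; consistent when the largest homogeneous subset of
#' instruments is valid (ZEMPA).  `weighted = TRUE` weights the kernel
#' contributions by inverse ratio variance.  Standard error by parametric
#' bootstrap, as for the weighted median.
#'
#' @inheritParams mr_weighted_median
#' @param phi bandwidth multiplier (default 1).
#' @return one-row data.frame (`method = "weighted_mode"` or
#'   `"simple_mode"`).
#' @export
mr_mode <- function(x, weighted = FALSE, phi = 1.0, n_boot = 1000,
                    seed = NULL, exposure = NULL, outcome = NULL) {
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)
  if (L < 3L)
    stop("mode-based estimate requires at least 3 variants", call. = FALSE)
  wfun <- if (weighted) {
    function(bx, by) (bx / d$byse)^2
  } else {
    function(bx, by) rep(1, length(bx))
  }
  est_fun <- function(bx, by) .smoothed_mode(by / bx, wfun(bx, by), phi)
  beta <- est_fun(d$bx, d$by)
  se <- .boot_se(d, est_fun, n_boot, seed)
  .mr_est(if (weighted) "weighted_mode" else "simple_mode", beta, se,
          n_snp = L)
}

#' Multivariable IVW (direct effects of several exposures)
#'
#' Weighted regression of the outcome effects on two or more columns of
#' exposure effects without an intercept, weights `1/byse^2`.  Returns the
#' direct effect of each predictor conditional on the others; with exposure
#' and mediator columns this yields the direct effect c' used by the
#' difference method.  Standard errors carry the same multiplicative
#' random-effects scaling as [mr_ivw()].
#'
#' @param bX numeric matrix of per-variant exposure effects (columns are
#'   predictors, named), or a `harmonized_set` with 3 traits (first two are
#'   predictors, last the outcome).
#' @param by,byse outcome effects and standard errors (ignored when `bX` is
#'   a harmonized set).
#' @return data.frame with one row per predictor (`method = "mvmr_ivw"`,
#'   rownames/`term` column give the predictor).
#' @export
mr_mvmr_ivw <- function(bX, by = NULL, byse = NULL) {
  if (inherits(bX, "harmonized_set")) {
    h <- bX
    ids <- names(h$traits)
    if (length(ids) < 3L)
      stop("multivariable IVW from a harmonized set needs 3 traits",
           call. = FALSE)
    bX <- sapply(ids[-length(ids)], function(id) h$traits[[id]]$beta)
    by <- h$traits[[ids[length(ids)]]]$beta
    byse <- h$traits[[ids[length(ids)]]]$se
  }
  bX <- as.matrix(bX)
  if (is.null(colnames(bX))) colnames(bX) <- paste0("x", seq_len(ncol(bX)))
  L <- nrow(bX)
  stopifnot(length(by) == L, length(byse) == L)
  # a predictor with no instrument effects at all carries no information:
  # drop it from the regression (its direct effect is unidentified)
  zero_col <- apply(bX == 0, 2, all)
  bXa <- bX[, !zero_col, drop = FALSE]
  k <- ncol(bXa)
  if (k == 0L) stop("all predictor columns are zero", call. = FALSE)
  if (L < k + 1L)
    stop("multivariable IVW requires more variants than predictors",
         call. = FALSE)
  if (qr(bXa)$rank < k)
    stop("collinear exposure effects: predictor matrix is rank deficient",
         call. = FALSE)
  w <- 1 / byse^2
  xtwx <- crossprod(bXa, w * bXa)
  coefs <- drop(solve(xtwx, crossprod(bXa, w * by)))
  resid <- by - drop(bXa %*% coefs)
  scale <- if (L > k) max(1, sqrt(sum(w * resid^2) / (L - k))) else 1
  ses <- sqrt(diag(solve(xtwx))) * scale
  est <- stats::setNames(rep(NA_real_, ncol(bX)), colnames(bX))
  se_all <- est
  est[!zero_col] <- coefs
  se_all[!zero_col] <- ses
  out <- do.call(rbind, lapply(seq_len(ncol(bX)), function(j) {
    if (is.na(est[j]))
      return(data.frame(method = "mvmr_ivw", beta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        pval = NA_real_, n_snp = L,
                        variance_model = "multiplicative_random",
                        stringsAsFactors = FALSE))
    .mr_est("mvmr_ivw", est[[j]], se_all[[j]], n_snp = L,
            variance_model = "multiplicative_random")
  }))
  out$term <- colnames(bX)
  out[c("term", setdiff(names(out), "term"))]
}
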