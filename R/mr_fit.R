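#' Fit a two-sample Mendelian randomization analysis
#'
#' The main model-fitting entry point: runs the requested estimators on a
#' harmonized exposure-outcome pair and attaches the standard sensitivity
#' diagnostics.  Returns a classed object with `print`, `summary`, `coef`,
#' `confint`, `plot` and `residuals` methods, in the style of other
#' model-fitting functions.
#'
#' @param x a `harmonized_set` (exposure = first trait, outcome = last) or
#'   an [mr_input()].
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "simple_mode", "weighted_mode")`.
#' @param variance_model IVW variance model, see [mr_ivw()].
#' @param n_boot bootstrap draws for median/mode standard errors.
#' @param phi mode bandwidth multiplier.
#' @param seed RNG seed for bootstraps and the pleiotropy simulations.
#' @param sensitivity attach a [mr_sensitivity()] report (default TRUE).
#' @param n_sim simulations for the global pleiotropy test.
#' @param exposure,outcome trait ids when `x` is a harmonized set.
#' @return an object of class `mr_fit` with elements `estimates` (data.frame
#'   of per-method estimates), `sensitivity`, `data` (the `mr_input`),
#'   `exposure`, `outcome`.
#' @export
#' @examples
#' d <- mr_input(bx = c(0.1, 0.2, 0.15, 0.12), bxse = rep(0.01, 4),
#'               by = c(0.02, 0.041, 0.0295, 0.0246), byse = rep(0.01, 4))
#' fit <- mr_fit(d, methods = "ivw", sensitivity = FALSE)
#' coef(fit)
mr_fit <- function(x,
                   methods = c("ivw", "egger", "weighted_median",
                               "simple_mode", "weighted_mode"),
                   variance_model = c("multiplicative_random", "fixed"),
                   n_boot = 1000, phi = 1.0, seed = NULL,
                   sensitivity = TRUE, n_sim = 1000,
                   exposure = NULL, outcome = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  variance_model <- match.arg(variance_model)
  d <- as_mr_input(x, exposure, outcome)
  L <- length(d$bx)

  ests <- list()
  if ("ivw" %in% methods)
    ests$ivw <- mr_ivw(d, variance_model = variance_model)
  if ("egger" %in% methods && L >= 3L)
    ests$egger <- mr_egger(d)
  if ("weighted_median" %in% methods && L >= 3L)
    ests$wm <- mr_weighted_median(d, n_boot = n_boot, seed = seed)
  if ("simple_mode" %in% methods && L >= 3L)
    ests$sm <- mr_mode(d, weighted = FALSE, phi = phi, n_boot = n_boot,
                       seed = seed)
  if ("weighted_mode" %in% methods && L >= 3L)
    ests$wmode <- mr_mode(d, weighted = TRUE, phi = phi, n_boot = n_boot,
                          seed = seed)
  estimates <- do.call(rbind, ests)
  rownames(estimates) <- NULL

  sens <- if (sensitivity)
    mr_sensitivity(d, n_sim = n_sim, seed = seed) else NULL

  exposure_id <- if (inherits(x, "harmonized_set"))
    (exposure %||% x$exposure) else "exposure"
  outcome_id <- if (inherits(x, "harmonized_set"))
    (outcome %||% names(x$traits)[length(x$traits)]) else "outcome"

  structure(list(estimates = estimates, sensitivity = sens, data = d,
                 exposure = exposure_id, outcome = outcome_id,
                 seed = seed),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR: ", x$exposure, " -> ", x$outcome, " (",
      length(x$data$bx), " instruments)\n\n", sep = "")
  est <- x$estimates
  est[c("beta", "se", "ci_low", "ci_high")] <-
    lapply(est[c("beta", "se", "ci_low", "ci_high")], signif, digits)
  est$pval <- signif(est$pval, 3)
  print.data.frame(est[c("method", "beta", "se", "ci_low", "ci_high",
                         "pval", "n_snp")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$fit$sensitivity)) {
    cat("\n")
    print(x$fit$sensitivity)
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  if (!missing(parm)) est <- est[est$method %in% parm, , drop = FALSE]
  out <- as.matrix(est[c("ci_low", "ci_high")])
  rownames(out) <- est$method
  out
}

#' Residuals of the IVW fit
#'
#' Weighted residuals `(by - beta_ivw * bx) / byse` of the inverse-variance
#' weighted regression through the origin; large values point at variants
#' driving heterogeneity.
#' @param object an `mr_fit`.
#' @param ... unused.
#' @export
residuals.mr_fit <- function(object, ...) {
  ivw_row <- object$estimates[grepl("^ivw", object$estimates$method), ,
                              drop = FALSE]
  if (nrow(ivw_row) == 0L)
    stop("no IVW estimate in this fit", call. = FALSE)
  d <- object$data
  stats::setNames((d$by - ivw_row$beta[1] * d$bx) / d$byse, d$snps)
}

#' Scatter plot of variant effects with fitted causal slopes
#'
#' Plots per-variant outcome effects against exposure effects with error
#' bars and overlays the fitted slope of each estimate in the object (the
#' Egger line includes its intercept).
#'
#' @param x an `mr_fit`.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  flip <- sign(d$bx); flip[flip == 0] <- 1
  bx <- d$bx * flip; by <- d$by * flip
  graphics::plot(bx, by,
                 xlab = paste("effect on", x$exposure),
                 ylab = paste("effect on", x$outcome),
                 pch = 19, col = "grey30", ...)
  graphics::segments(bx, by - Z95 * d$byse, bx, by + Z95 * d$byse,
                     col = "grey70")
  graphics::segments(bx - Z95 * d$bxse, by, bx + Z95 * d$bxse, by,
                     col = "grey70")
  est <- x$estimates
  cols <- stats::setNames(
    c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e", "#666666"),
    c("ivw_mre", "ivw_fe", "egger_slope", "weighted_median", "simple_mode",
      "weighted_mode"))
  shown <- character(0)
  for (i in seq_len(nrow(est))) {
    m <- est$method[i]
    if (m == "egger_intercept") next
    icpt <- if (m == "egger_slope")
      est$beta[est$method == "egger_intercept"] else 0
    graphics::abline(a = icpt, b = est$beta[i],
                     col = cols[[m]] %||% "black", lwd = 2,
                     lty = if (m == "egger_slope") 2 else 1)
    shown <- c(shown, m)
  }
  graphics::legend("topleft", legend = shown, bty = "n", lwd = 2,
                   col = vapply(shown, function(m) cols[[m]] %||% "black",
                                character(1)))
  invisible(x)
}
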