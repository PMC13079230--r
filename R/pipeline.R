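# Multistage orchestration: total effects, exposure -> mediator screen,
# mediator -> outcome, and mediation for the surviving triplets, with
# explicit Bonferroni families and a JSON run manifest.

#' Bonferroni correction for a family of tests
#'
#' Significance means `p < alpha / m`; adjusted p-values `min(1, p * m)`
#' are reported alongside.  If `m` is smaller than the number of p-values
#' supplied it is raised to that number with a warning.
#'
#' @param pvals numeric vector of raw p-values.
#' @param m family size (defaults to `length(pvals)`).
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `significant` (logical), `p_adjusted`, `threshold`
#'   (`alpha / m`), `m`.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals), alpha = 0.05) {
  stopifnot(m >= 1)
  if (m < length(pvals)) {
    warning("family size m = ", m, " is smaller than the number of tests (",
            length(pvals), "); raising m", call. = FALSE)
    m <- length(pvals)
  }
  list(significant = pvals < alpha / m,
       p_adjusted = pmin(1, pvals * m),
       threshold = alpha / m, m = m)
}

.pair_fit <- function(x_tab, y_tab, ld, thresholds, seed, n_sim,
                      palindrome_policy) {
  iv <- select_instruments(x_tab, ld,
                           p_thresh = thresholds$p_thresh,
                           maf_min = thresholds$maf_min,
                           r2_thresh = thresholds$r2_thresh,
                           window_kb = thresholds$window_kb,
                           f_min = thresholds$f_min)
  if (iv$summary$n_selected == 0L) return(NULL)
  keep <- iv$snps$rsid
  sub <- function(tab) summary_table(
    as.data.frame(tab[tab$rsid %in% keep, , drop = FALSE]),
    trait_id = attr(tab, "trait_id"), quiet = TRUE)
  h <- harmonize(list(sub(x_tab), sub(y_tab)),
                 palindrome_policy = palindrome_policy)
  if (n_snps(h) == 0L) return(NULL)
  fit <- mr_fit(h, seed = seed, n_sim = n_sim)
  list(fit = fit, instruments = iv)
}

.stage_row <- function(exposure, outcome, res) {
  ivw <- res$fit$estimates[grepl("^ivw", res$fit$estimates$method), ,
                           drop = FALSE][1, ]
  s <- res$fit$sensitivity
  data.frame(exposure = exposure, outcome = outcome, beta = ivw$beta,
             se = ivw$se, ci_low = ivw$ci_low, ci_high = ivw$ci_high,
             pval = ivw$pval, n_snp = ivw$n_snp,
             q_pval = s$q_pval, egger_intercept_pval = s$egger_intercept_pval,
             presso_global_pval = s$presso_global_pval,
             stringsAsFactors = FALSE)
}

#' Run the multistage MR and mediation analysis
#'
#' Stage 1 estimates total effects of every exposure on every outcome;
#' stage 2 estimates effects of every exposure on every mediator; mediators
#' with a Bonferroni-significant stage-2 estimate (for some exposure whose
#' stage-1 effect on the outcome is itself significant) are carried into
#' stage 3, where mediator -> outcome effects and the full two-step
#' mediation are computed.  Every IVW estimate carries its sensitivity
#' report; all thresholds, family sizes and seeds are recorded in the
#' manifest.  Stages with no selectable instruments are skipped with an
#' explicit entry rather than an error.
#'
#' @param exposures,mediators,outcomes named lists of [summary_table()]s.
#' @param ld an LD source for clumping (default: no-LD source, appropriate
#'   for pre-pruned or simulated panels).
#' @param thresholds list of instrument-selection thresholds
#'   (`p_thresh`, `maf_min`, `r2_thresh`, `window_kb`, `f_min`); defaults
#'   are the conventional strict settings.
#' @param families list of Bonferroni family sizes for `total`, `step1`
#'   (exposure -> mediator) and `step2` (mediator -> outcome); each
#'   defaults to the number of tests run in that family.
#' @param alpha family-wise error rate.
#' @param seed seed driving bootstraps, pleiotropy simulations and the
#'   product CI.
#' @param n_sim simulations for the global pleiotropy test.
#' @param mc_draws draws for the mediation product CI.
#' @param palindrome_policy passed to [harmonize()].
#' @return a `bundle` list: `total_effects`, `exposure_to_mediators`,
#'   `mediators_to_outcomes` (data.frames), `mediation` (list of
#'   [mr_mediation()] objects), `screened_mediators`, `skipped`,
#'   `manifest`.
#' @export
run_multistage <- function(exposures, mediators, outcomes,
                           ld = ld_independent(),
                           thresholds = list(), families = list(),
                           alpha = 0.05, seed = 1, n_sim = 1000,
                           mc_draws = 1e5,
                           palindrome_policy = "infer_by_freq") {
  thr <- utils::modifyList(list(p_thresh = 5e-8, maf_min = 0.01,
                                r2_thresh = 0.001, window_kb = 10000,
                                f_min = 10), thresholds)
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1)
  skipped <- character(0)

  run_family <- function(xs, ys) {
    rows <- list()
    for (xn in names(xs)) for (yn in names(ys)) {
      res <- .pair_fit(xs[[xn]], ys[[yn]], ld, thr, seed, n_sim,
                       palindrome_policy)
      if (is.null(res)) {
        skipped <<- c(skipped, paste0(xn, " -> ", yn,
                                      ": no instruments selectable"))
        next
      }
      rows[[paste(xn, yn)]] <- .stage_row(xn, yn, res)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }

  total <- run_family(exposures, outcomes)
  if (!is.null(total)) {
    adj <- bonferroni_adjust(total$pval,
                             m = families$total %||% nrow(total),
                             alpha = alpha)
    total$p_adjusted <- adj$p_adjusted
    total$significant <- adj$significant
    rownames(total) <- NULL
  }

  step1 <- NULL
  if (length(mediators)) {
    step1 <- run_family(exposures, mediators)
    if (!is.null(step1)) {
      adj <- bonferroni_adjust(step1$pval,
                               m = families$step1 %||% nrow(step1),
                               alpha = alpha)
      step1$p_adjusted <- adj$p_adjusted
      step1$significant <- adj$significant
      rownames(step1) <- NULL
    }
  }

  screened <- character(0)
  if (!is.null(step1)) screened <- unique(step1$outcome[step1$significant])

  step2 <- NULL
  mediation <- list()
  if (length(screened)) {
    step2 <- run_family(mediators[screened], outcomes)
    if (!is.null(step2)) {
      adj <- bonferroni_adjust(step2$pval,
                               m = families$step2 %||% nrow(step2),
                               alpha = alpha)
      step2$p_adjusted <- adj$p_adjusted
      step2$significant <- adj$significant
      rownames(step2) <- NULL
    }
    for (mn in screened) for (xn in names(exposures)) for (yn in names(outcomes)) {
      ok_x <- any(step1$exposure == xn & step1$outcome == mn &
                    step1$significant)
      ok_tot <- is.null(total) ||
        any(total$exposure == xn & total$outcome == yn & total$significant)
      ok_m <- !is.null(step2) &&
        any(step2$exposure == mn & step2$outcome == yn & step2$significant)
      if (ok_x && ok_tot && ok_m) {
        med <- tryCatch(
          mr_mediation(exposures[[xn]], mediators[[mn]], outcomes[[yn]],
                       ld = ld, p_thresh = thr$p_thresh,
                       maf_min = thr$maf_min, r2_thresh = thr$r2_thresh,
                       window_kb = thr$window_kb, f_min = thr$f_min,
                       mc_draws = mc_draws, seed = seed,
                       palindrome_policy = palindrome_policy),
          error = function(e) {
            skipped <<- c(skipped, paste0("mediation ", xn, " -> ", mn,
                                          " -> ", yn, ": ",
                                          conditionMessage(e)))
            NULL
          })
        if (!is.null(med))
          mediation[[paste(xn, mn, yn, sep = " -> ")]] <- med
      }
    }
  }

  manifest <- list(
    thresholds = thr, alpha = alpha, seed = seed, n_sim = n_sim,
    mc_draws = mc_draws, palindrome_policy = palindrome_policy,
    families = list(total = families$total %||% NROW(total),
                    step1 = families$step1 %||% NROW(step1),
                    step2 = families$step2 %||% NROW(step2)),
    n_exposures = length(exposures), n_mediators = length(mediators),
    n_outcomes = length(outcomes),
    screened_mediators = screened,
    package_version = as.character(utils::packageVersion("mrmediate")))

  structure(list(total_effects = total, exposure_to_mediators = step1,
                 mediators_to_outcomes = step2, mediation = mediation,
                 screened_mediators = screened, skipped = skipped,
                 manifest = manifest),
            class = "mr_bundle")
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat("Multistage MR bundle\n")
  for (nm in c("total_effects", "exposure_to_mediators",
               "mediators_to_outcomes")) {
    tab <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(tab)) "skipped" else
      paste0(nrow(tab), " tests, ", sum(tab$significant),
             " Bonferroni-significant"), "\n", sep = "")
  }
  cat("  mediation analyses: ", length(x$mediation), "\n", sep = "")
  if (length(x$skipped))
    cat("  skipped:", length(x$skipped), "entr(y/ies)\n")
  invisible(x)
}

#' Write per-stage TSV reports and a JSON manifest
#'
#' Writes `total_effects.tsv`, `exposure_to_mediators.tsv`,
#' `mediators_to_outcomes.tsv` (when present), `mediation.tsv` (one row per
#' mediated pathway: a, b, c, c', indirect with CI, proportion by both
#' methods) and `manifest.json` into `dir`.  Optional diagnostic scatter
#' plots are drawn only when `plots = TRUE`, so disabling them touches no
#' graphics device.  An empty bundle yields stub files.
#'
#' @param bundle result of [run_multistage()].
#' @param dir output directory (created if missing).
#' @param plots also write per-stage scatter plots (PDF).
#' @return `invisible(dir)`.
#' @export
render_report <- function(bundle, dir, plots = FALSE) {
  stopifnot(inherits(bundle, "mr_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  empty_stage <- data.frame(exposure = character(0), outcome = character(0),
                            beta = numeric(0), se = numeric(0),
                            pval = numeric(0), stringsAsFactors = FALSE)
  for (nm in c("total_effects", "exposure_to_mediators",
               "mediators_to_outcomes"))
    write_results(bundle[[nm]] %||% empty_stage,
                  file.path(dir, paste0(nm, ".tsv")))

  med_tab <- if (length(bundle$mediation))
    do.call(rbind, lapply(bundle$mediation, as.data.frame)) else
      as.data.frame(matrix(nrow = 0, ncol = 0))
  rownames(med_tab) <- NULL
  write_results(med_tab, file.path(dir, "mediation.tsv"))

  manifest <- bundle$manifest
  manifest$skipped <- bundle$skipped
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (plots && !is.null(bundle$total_effects)) {
    grDevices::pdf(file.path(dir, "total_effects_forest.pdf"), width = 7,
                   height = 1 + 0.4 * nrow(bundle$total_effects))
    on.exit(grDevices::dev.off(), add = TRUE)
    tab <- bundle$total_effects
    y <- rev(seq_len(nrow(tab)))
    graphics::plot(tab$beta, y, xlim = range(tab$ci_low, tab$ci_high, 0),
                   pch = 18, yaxt = "n", ylab = "",
                   xlab = "IVW estimate (SD per SD)")
    graphics::segments(tab$ci_low, y, tab$ci_high, y)
    graphics::abline(v = 0, lty = 3)
    graphics::axis(2, at = y, las = 1, cex.axis = 0.7,
                   labels = paste(tab$exposure, "→", tab$outcome))
  }
  invisible(dir)
}
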