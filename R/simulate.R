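# Synthetic three-trait GWAS summary statistics under a known linear
# structural model X -> M -> Y with direct effect X -> Y:
#
#   per-variant standardized instrument effects g_j on X (sum g^2 = h2_x)
#   and optional mediator-specific effects delta_j (sum delta^2 = h2_med);
#   true associations: exposure g_j, mediator a*g_j + delta_j,
#   outcome (d + a*b)*g_j + b*delta_j + alpha_j, with alpha_j horizontal
#   pleiotropy.  Observed effects add independent normal sampling error
#   with the standardized-trait closed form se = 1/sqrt(2 maf (1-maf) n).

#' Configuration for the summary-statistic generator
#'
#' Defaults encode the calibrated mediation scenario used throughout the
#' package's validation: 80 exposure instruments and 80 mediator-specific
#' instruments, 500,000 individuals per trait GWAS, structural paths
#' `a = -0.125` (exposure to mediator), `b = 0.080` (mediator to outcome)
#' and direct effect `d = -0.0247`, hence total effect
#' `c = d + a*b = -0.0347` and true proportion mediated
#' `a*b / c = 28.8\%`; no pleiotropy.
#'
#' @param L number of exposure instruments.
#' @param L_med number of mediator-specific instruments (give the mediator
#'   its own genome-wide-significant variants; 0 for none).
#' @param n_x,n_m,n_y GWAS sample sizes per trait.
#' @param maf_range range of the uniform minor-allele-frequency draw.
#' @param h2_x exposure variance explained by its L instruments.
#' @param h2_med mediator variance explained by its own instruments
#'   (beyond the exposure-transmitted part).
#' @param a,b,d structural paths (SD per SD); total effect is `d + a*b`.
#' @param rho_invalid fraction of exposure instruments with a direct
#'   (pleiotropic) outcome effect.
#' @param mu_alpha,sigma_alpha mean and sd of the pleiotropic effects;
#'   `mu_alpha != 0` gives directional pleiotropy, applied relative to the
#'   exposure-increasing allele.
#' @param inside_violation if `TRUE`, pleiotropic effects are correlated
#'   with instrument strength `|g_j|` (violating InSIDE).
#' @param outliers optional data.frame with columns `index`, `effect`
#'   passed to [inject_outliers()] after generation.
#' @param ld_blocks optional list `list(size =, rho =)`: each instrument is
#'   expanded into a block of `size` variants with AR(1) correlation `rho`;
#'   non-lead variants carry the LD-attenuated marginal effects.
#' @param n_ref reference-panel individuals for [make_ld_reference()].
#' @param seed RNG seed; all randomness flows from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(L = 80, L_med = 80, n_x = 5e5, n_m = 5e5, n_y = 5e5,
                       maf_range = c(0.05, 0.5), h2_x = 0.10, h2_med = 0.10,
                       a = -0.125, b = 0.080, d = -0.0247,
                       rho_invalid = 0, mu_alpha = 0, sigma_alpha = 0,
                       inside_violation = FALSE, outliers = NULL,
                       ld_blocks = NULL, n_ref = 1000, seed = 1) {
  cfg <- list(L = as.integer(L), L_med = as.integer(L_med),
              n_x = n_x, n_m = n_m, n_y = n_y, maf_range = maf_range,
              h2_x = h2_x, h2_med = h2_med, a = a, b = b, d = d,
              rho_invalid = rho_invalid, mu_alpha = mu_alpha,
              sigma_alpha = sigma_alpha,
              inside_violation = isTRUE(inside_violation),
              outliers = outliers, ld_blocks = ld_blocks,
              n_ref = as.integer(n_ref), seed = as.integer(seed))
  if (cfg$L < 1L) stop("L must be at least 1", call. = FALSE)
  if (cfg$L_med < 0L) stop("L_med must be non-negative", call. = FALSE)
  if (any(c(cfg$n_x, cfg$n_m, cfg$n_y) <= 0))
    stop("sample sizes must be positive", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (h2_x <= 0 || h2_x >= 1) stop("h2_x must lie in (0, 1)", call. = FALSE)
  if (cfg$L_med > 0L && (h2_med <= 0 || h2_med >= 1))
    stop("h2_med must lie in (0, 1)", call. = FALSE)
  if (rho_invalid < 0 || rho_invalid > 1)
    stop("rho_invalid must lie in [0, 1]", call. = FALSE)
  if (sigma_alpha < 0) stop("sigma_alpha must be non-negative", call. = FALSE)
  if (!is.null(ld_blocks)) {
    if (!is.list(ld_blocks) || is.null(ld_blocks$size) ||
        is.null(ld_blocks$rho) || ld_blocks$size < 1 ||
        abs(ld_blocks$rho) >= 1)
      stop("ld_blocks must be list(size >= 1, |rho| < 1)", call. = FALSE)
    cfg$ld_blocks$size <- as.integer(ld_blocks$size)
  }
  structure(cfg, class = "sim_config")
}

# Deterministic variant layout shared by the generator and the reference
# panel: one block per instrument, blocks 20 Mb apart (outside any clumping
# window), block members 5 kb apart; chromosomes cycle 1..22.
.snp_layout <- function(config) {
  n_instr <- config$L + config$L_med
  block_size <- if (is.null(config$ld_blocks)) 1L else config$ld_blocks$size
  m <- n_instr * block_size
  block <- rep(seq_len(n_instr), each = block_size)
  offset <- rep(seq_len(block_size) - 1L, times = n_instr)
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  pos <- 1e6 + ((block - 1L) %/% 22L) * 2e7 + offset * 5000
  data.frame(rsid = sprintf("rs%06d", seq_len(m)), chrom = chrom,
             pos = pos, block = block, offset = offset,
             stringsAsFactors = FALSE)
}

#' Simulate a three-trait GWAS summary-statistic study
#'
#' Draws minor-allele frequencies, standardized instrument effects scaled
#' to the configured heritabilities, optional pleiotropic and
#' mediator-specific effects, and observed per-variant associations for
#' exposure, mediator and outcome with independent normal sampling error
#' (`se = 1/sqrt(2 maf (1-maf) n)`; non-overlapping samples).  All
#' randomness derives from `config$seed` via a single stream with a fixed
#' draw order, so identical configs give bit-identical studies.
#'
#' @param config a [sim_config()].
#' @return a `simulated_study`: list with `exposure`, `mediator`, `outcome`
#'   ([summary_table()]s), `truth` (structural parameters and per-variant
#'   true effects), `ld` (an [ld_genotypes()] reference when LD blocks are
#'   configured, else `NULL`) and `config`.
#' @export
simulate_gwas_triplet <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lay <- .snp_layout(config)
  n_instr <- config$L + config$L_med
  is_x_iv <- seq_len(n_instr) <= config$L

  maf_b <- stats::runif(n_instr, config$maf_range[1], config$maf_range[2])

  # standardized effect sizes, rescaled to the target heritabilities
  g_std <- numeric(n_instr)
  g_raw <- stats::rnorm(config$L)
  g_std[is_x_iv] <- g_raw * sqrt(config$h2_x / sum(g_raw^2))
  delta_std <- numeric(n_instr)
  if (config$L_med > 0L) {
    d_raw <- stats::rnorm(config$L_med)
    delta_std[!is_x_iv] <- d_raw * sqrt(config$h2_med / sum(d_raw^2))
  }

  # horizontal pleiotropy on the exposure instruments, oriented relative to
  # the exposure-increasing allele (sign of g)
  alpha_std <- numeric(n_instr)
  n_invalid <- round(config$rho_invalid * config$L)
  invalid <- integer(0)
  if (n_invalid > 0L) {
    invalid <- sample(which(is_x_iv), n_invalid)
    if (config$inside_violation) {
      strength <- abs(g_std[invalid])
      zs <- if (stats::sd(strength) > 0)
        (strength - mean(strength)) / stats::sd(strength) else
          rep(0, n_invalid)
      raw <- 0.7 * zs + sqrt(1 - 0.7^2) * stats::rnorm(n_invalid)
      alpha_std[invalid] <- config$mu_alpha + config$sigma_alpha * raw
    } else {
      alpha_std[invalid] <- stats::rnorm(n_invalid, config$mu_alpha,
                                         config$sigma_alpha)
    }
    alpha_std[invalid] <- alpha_std[invalid] * sign(g_std[invalid])
  }

  # expand to the variant level (LD blocks attenuate marginal effects)
  block_size <- if (is.null(config$ld_blocks)) 1L else config$ld_blocks$size
  rho <- if (is.null(config$ld_blocks)) 0 else config$ld_blocks$rho
  atten <- rho^lay$offset
  maf <- maf_b[lay$block]
  g <- g_std[lay$block] * atten
  delta <- delta_std[lay$block] * atten
  alpha <- alpha_std[lay$block] * atten

  ctot <- config$d + config$a * config$b
  sd2pq <- sqrt(2 * maf * (1 - maf))
  true_std <- list(x = g,
                   m = config$a * g + delta,
                   y = ctot * g + config$b * delta + alpha)

  # non-palindromic allele pairs so harmonization keeps everything
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- sample.int(nrow(pairs), nrow(lay), replace = TRUE)

  ns <- c(x = config$n_x, m = config$n_m, y = config$n_y)
  labels <- c(x = "exposure", m = "mediator", y = "outcome")
  tabs <- lapply(names(ns), function(t) {
    se <- 1 / (sd2pq * sqrt(ns[[t]]))
    beta_true <- true_std[[t]] / sd2pq        # allelic scale
    beta_hat <- stats::rnorm(nrow(lay), beta_true, se)
    pval <- pmax(2 * stats::pnorm(-abs(beta_hat / se)),
                 .Machine$double.xmin)
    summary_table(data.frame(
      rsid = lay$rsid, chrom = lay$chrom, pos = lay$pos,
      effect_allele = pairs[pick, 1], other_allele = pairs[pick, 2],
      eaf = maf, beta = beta_hat, se = se, pval = pval, n = ns[[t]],
      stringsAsFactors = FALSE), trait_id = labels[[t]], quiet = TRUE)
  })
  names(tabs) <- labels

  ld <- if (!is.null(config$ld_blocks)) make_ld_reference(config) else NULL

  truth <- list(a = config$a, b = config$b, d = config$d, c = ctot,
                proportion = if (ctot != 0) config$a * config$b / ctot
                             else NA_real_,
                gamma = g / sd2pq, delta = delta / sd2pq,
                alpha = alpha / sd2pq, maf = maf,
                is_exposure_iv = is_x_iv[lay$block] & lay$offset == 0L,
                is_mediator_iv = (!is_x_iv[lay$block]) & lay$offset == 0L,
                invalid_idx = which(lay$block %in% invalid & lay$offset == 0L))

  study <- structure(list(exposure = tabs$exposure, mediator = tabs$mediator,
                          outcome = tabs$outcome, truth = truth, ld = ld,
                          config = config),
                     class = "simulated_study")
  if (!is.null(config$outliers)) study <- inject_outliers(study,
                                                          config$outliers)
  study
}

#' @export
print.simulated_study <- function(x, ...) {
  cfg <- x$config
  cat("Simulated GWAS triplet: ", nrow(x$exposure), " variants (",
      cfg$L, " exposure + ", cfg$L_med, " mediator instruments",
      if (!is.null(cfg$ld_blocks))
        paste0(", LD blocks of ", cfg$ld_blocks$size) else "",
      ")\n", sep = "")
  cat(sprintf("  truth: a = %+.4f, b = %+.4f, d = %+.4f, c = %+.4f%s\n",
              x$truth$a, x$truth$b, x$truth$d, x$truth$c,
              if (!is.na(x$truth$proportion))
                sprintf(", proportion mediated = %.1f%%",
                        100 * x$truth$proportion) else ""))
  invisible(x)
}

#' Synthetic LD reference panel matching a simulation config
#'
#' Generates a Gaussian dosage panel (mean `2 maf`, variance
#' `2 maf (1 - maf)`) with AR(1) correlation within each configured LD
#' block and independence across blocks.  The panel is synthetic: only its
#' correlation structure matters, and the pairwise r2 table derived from it
#' is by construction consistent with the matrix.  Without configured
#' blocks the panel has no LD (off-diagonal r2 near 0).
#'
#' @param config a [sim_config()].
#' @return an [ld_genotypes()] source over the config's variant ids.
#' @export
make_ld_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)  # panel substream, distinct from the study
  lay <- .snp_layout(config)
  maf_b <- stats::runif(config$L + config$L_med,
                        config$maf_range[1], config$maf_range[2])
  maf <- maf_b[lay$block]
  rho <- if (is.null(config$ld_blocks)) 0 else config$ld_blocks$rho
  n <- config$n_ref

  z <- matrix(0, nrow = n, ncol = nrow(lay))
  for (b in unique(lay$block)) {
    idx <- which(lay$block == b)
    e <- matrix(stats::rnorm(n * length(idx)), nrow = n)
    if (length(idx) > 1L && rho != 0) {
      for (k in seq_along(idx)[-1L])
        e[, k] <- rho * e[, k - 1L] + sqrt(1 - rho^2) * e[, k]
    }
    z[, idx] <- e
  }
  dos <- sweep(sweep(z, 2, sqrt(2 * maf * (1 - maf)), `*`),
               2, 2 * maf, `+`)
  colnames(dos) <- lay$rsid
  ld_genotypes(dos)
}

#' Inject direct-outcome-effect outliers into a simulated study
#'
#' Adds the specified direct effect (allelic scale) to the outcome beta of
#' the chosen variants, both in the observed table and in the recorded
#' truth, to exercise outlier detection.
#'
#' @param study a `simulated_study`.
#' @param spec data.frame with columns `index` (variant row) and `effect`,
#'   or a list of `list(index =, effect =)`.
#' @return the modified `simulated_study`.
#' @export
inject_outliers <- function(study, spec) {
  stopifnot(inherits(study, "simulated_study"))
  if (is.list(spec) && !is.data.frame(spec))
    spec <- do.call(rbind, lapply(spec, function(s)
      data.frame(index = s$index, effect = s$effect)))
  if (is.null(spec) || nrow(spec) == 0L) return(study)
  m <- nrow(study$outcome)
  if (any(spec$index < 1 | spec$index > m))
    stop("outlier index out of range 1..", m, call. = FALSE)
  out <- study$outcome
  out$beta[spec$index] <- out$beta[spec$index] + spec$effect
  out$pval[spec$index] <- pmax(
    2 * stats::pnorm(-abs(out$beta[spec$index] / out$se[spec$index])),
    .Machine$double.xmin)
  study$outcome <- summary_table(as.data.frame(out), trait_id = "outcome",
                                 quiet = TRUE)
  study$truth$alpha[spec$index] <- study$truth$alpha[spec$index] +
    spec$effect
  study$truth$outlier_idx <- sort(unique(c(study$truth$outlier_idx,
                                           spec$index)))
  study
}
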