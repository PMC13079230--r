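test_that("Wald ratio arithmetic, error contract and second-order se", {
  w <- wald_ratio(bx = 0.10, bxse = 0.01, by = 0.02, byse = 0.005)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.05)
  expect_equal(wald_ratio(0.10, 0.01, 0, 0.005)$beta, 0)
  expect_error(wald_ratio(0, 0.01, 0.02, 0.005), "bx is zero")

  # second-order se against a Monte-Carlo delta-method oracle
  set.seed(1)
  ratio <- rnorm(2e5, 0.02, 0.005) / rnorm(2e5, 0.1, 0.002)
  w2 <- wald_ratio(0.1, 0.002, 0.02, 0.005, second_order = TRUE)
  expect_equal(w2$se, sd(ratio), tolerance = 0.02)
  expect_gt(w2$se, wald_ratio(0.1, 0.002, 0.02, 0.005)$se)
})

test_that("IVW equals the Wald ratio at one variant and a WLS oracle at three", {
  d1 <- mr_input(bx = 0.1, bxse = 0.01, by = 0.02, byse = 0.005)
  expect_equal(mr_ivw(d1)$beta, wald_ratio(0.1, 0.01, 0.02, 0.005)$beta)
  expect_equal(mr_ivw(d1)$se, wald_ratio(0.1, 0.01, 0.02, 0.005)$se)

  # independent normal-equations oracle for WLS through the origin
  bx <- c(0.1, 0.2, 0.15); by <- c(0.02, 0.041, 0.0295)
  byse <- c(0.01, 0.01, 0.01)
  w <- 1 / byse^2
  beta_oracle <- solve(t(bx) %*% diag(w) %*% bx, t(bx) %*% diag(w) %*% by)[1]
  se_oracle <- sqrt(solve(t(bx) %*% diag(w) %*% bx)[1])
  fit <- mr_ivw(mr_input(bx, rep(0.01, 3), by, byse),
                variance_model = "fixed")
  expect_equal(fit$beta, beta_oracle, tolerance = 1e-12)
  expect_equal(fit$se, se_oracle, tolerance = 1e-12)
  expect_equal(fit$n_snp, 3L)
})

test_that("multiplicative random-effects se never undercuts the fixed-effect se", {
  set.seed(21)
  for (i in 1:20) {
    L <- sample(3:30, 1)
    bx <- rnorm(L, 0, 0.1); bx[abs(bx) < 0.01] <- 0.05
    by <- 0.2 * bx + rnorm(L, 0, 0.02)
    d <- mr_input(bx, rep(0.005, L), by, rep(0.01, L))
    expect_gte(mr_ivw(d)$se, mr_ivw(d, variance_model = "fixed")$se)
  }
})

test_that("estimates are invariant to joint sign flips of (bx, by)", {
  set.seed(4)
  L <- 25
  bx <- rnorm(L, 0, 0.08); bx[abs(bx) < 0.01] <- 0.03
  by <- 0.15 * bx + rnorm(L, 0, 0.01)
  d <- mr_input(bx, rep(0.004, L), by, rep(0.01, L))
  flip <- rep(c(1, -1), length.out = L)
  d2 <- mr_input(bx * flip, rep(0.004, L), by * flip, rep(0.01, L))

  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$beta, mr_egger(d)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(d2, seed = 1)$beta,
               mr_weighted_median(d, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(d2, seed = 1)$beta, mr_mode(d, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers directional pleiotropy and matches IVW without it", {
  expect_error(mr_egger(mr_input(c(0.1, 0.2), c(0.01, 0.01),
                                 c(0.02, 0.04), c(0.01, 0.01))),
               "at least 3")

  # 1000 strong variants with mean direct effect 0.01: the intercept
  # estimates the average pleiotropic effect
  set.seed(31)
  L <- 1000
  bx <- abs(rnorm(L, 0.1, 0.03)) + 0.02
  alpha <- rnorm(L, 0.01, 0.002)
  by <- 0.2 * bx + alpha + rnorm(L, 0, 0.001)
  eg <- mr_egger(mr_input(bx, rep(1e-4, L), by, rep(0.001, L)))
  icpt <- eg[eg$method == "egger_intercept", ]
  expect_lt(abs(icpt$beta - 0.01), 0.002)
  slope <- eg[eg$method == "egger_slope", ]
  expect_equal(slope$beta, 0.2, tolerance = 0.02)

  # no pleiotropy: slope consistent with IVW within joint sampling error
  set.seed(32)
  by0 <- 0.2 * bx + rnorm(L, 0, 0.001)
  d0 <- mr_input(bx, rep(1e-4, L), by0, rep(0.001, L))
  eg0 <- mr_egger(d0)[1, ]
  ivw0 <- mr_ivw(d0)
  expect_lt(abs(eg0$beta - ivw0$beta), 2 * sqrt(eg0$se^2 + ivw0$se^2))
})

test_that("weighted median interpolates the inverse-variance weight CDF", {
  # uniform weights reduce to the simple median
  d <- toy_input(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
                 byse = c(0.01, 0.01, 0.01))
  expect_equal(mr_weighted_median(d, n_boot = 10, seed = 1)$beta, 0.2)

  # a variant holding ~99% of the weight pins the estimate to its ratio
  d_conc <- mr_input(bx = c(1, 1, 1), bxse = rep(1e-4, 3),
                     by = c(0.1, 0.5, 0.9), byse = c(0.001, 0.1, 0.1))
  expect_equal(mr_weighted_median(d_conc, n_boot = 10, seed = 1)$beta, 0.1,
               tolerance = 1e-3)

  # 4-ratio unequal-weight case against an independently executed
  # interpolation: theta sorted, s_j = cumsum(w')_j - w'_j/2, linear
  # interpolation at 0.5
  bx <- c(1, 1, 1, 1); by <- c(0.10, 0.20, 0.30, 0.40)
  byse <- c(0.02, 0.01, 0.015, 0.03)
  wm <- mr_weighted_median(mr_input(bx, rep(1e-4, 4), by, byse),
                           n_boot = 10, seed = 1)
  theta <- by / bx
  wts <- (bx / byse)^2; wts <- wts / sum(wts)
  o <- order(theta); theta <- theta[o]; wts <- wts[o]
  s <- cumsum(wts) - wts / 2
  k <- max(which(s < 0.5))
  oracle <- theta[k] + (theta[k + 1] - theta[k]) * (0.5 - s[k]) /
    (s[k + 1] - s[k])
  expect_equal(wm$beta, oracle, tolerance = 1e-12)

  # same seed, same answer (bootstrap determinism)
  expect_identical(mr_weighted_median(d, n_boot = 50, seed = 7),
                   mr_weighted_median(d, n_boot = 50, seed = 7))
})

test_that("mode-based estimate finds the dominant ratio cluster", {
  d_eq <- mr_input(bx = rep(1, 3), bxse = rep(1e-4, 3),
                   by = rep(0.15, 3), byse = rep(0.01, 3))
  expect_equal(mr_mode(d_eq, n_boot = 10, seed = 1)$beta, 0.15)

  # 7 of 10 ratios near 0.2, 3 outliers at 1.0: mode sits at the cluster,
  # and matches an independent grid search over the smoothed density
  set.seed(41)
  theta <- c(rnorm(7, 0.2, 0.01), rnorm(3, 1.0, 0.01))
  d <- mr_input(bx = rep(1, 10), bxse = rep(1e-4, 10),
                by = theta, byse = rep(0.05, 10))
  m <- mr_mode(d, n_boot = 10, seed = 2)
  expect_equal(m$beta, 0.2, tolerance = 0.05)

  h <- 0.9 * min(sd(theta), mad(theta)) * 10^(-1 / 5)
  grid <- seq(mean(theta) - 5 * sd(theta), mean(theta) + 5 * sd(theta),
              length.out = 512)
  dens <- sapply(grid, function(g) mean(dnorm((g - theta) / h)) / h)
  expect_equal(m$beta, grid[which.max(dens)], tolerance = 1e-12)

  expect_identical(mr_mode(d, n_boot = 100, seed = 5),
                   mr_mode(d, n_boot = 100, seed = 5))
  expect_error(mr_mode(mr_input(1, 0.01, 0.1, 0.01)), "at least 3")
})

test_that("multivariable IVW reduces, recovers truth, and rejects collinearity", {
  set.seed(51)
  L <- 40
  bx <- rnorm(L, 0, 0.08)
  byse <- rep(0.01, L)
  by <- 0.3 * bx + rnorm(L, 0, 0.01)

  # an all-zero mediator column carries nothing: exposure direct effect
  # equals the univariable IVW estimate
  fit0 <- mr_mvmr_ivw(cbind(exposure = bx, mediator = 0), by, byse)
  uni <- mr_ivw(mr_input(bx, rep(1e-4, L), by, byse))
  expect_equal(fit0$beta[fit0$term == "exposure"], uni$beta,
               tolerance = 1e-12)
  expect_true(is.na(fit0$beta[fit0$term == "mediator"]))

  # generator truth: direct effect d recovered within 2 se
  st <- simulate_gwas_triplet(sim_config(seed = 51))
  fit <- mr_mvmr_ivw(cbind(exposure = st$exposure$beta,
                           mediator = st$mediator$beta),
                     st$outcome$beta, st$outcome$se)
  dhat <- fit[fit$term == "exposure", ]
  expect_lt(abs(dhat$beta - st$truth$d), 2 * dhat$se)

  expect_error(mr_mvmr_ivw(cbind(x = bx, m = 2 * bx), by, byse),
               "collinear")
})

test_that("mr_fit bundles estimators with methods behaving like a model object", {
  set.seed(61)
  st <- simulate_gwas_triplet(sim_config(L = 40, L_med = 0, seed = 61))
  h <- harmonize(list(st$exposure, st$outcome))
  fit <- mr_fit(h, seed = 3, n_boot = 50, n_sim = 100)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw_mre", "egger_slope", "egger_intercept",
                    "weighted_median", "simple_mode", "weighted_mode"))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$beta &
                    fit$estimates$beta <= fit$estimates$ci_high))
  expect_named(coef(fit))
  expect_equal(unname(coef(fit)["ivw_mre"]),
               fit$estimates$beta[fit$estimates$method == "ivw_mre"])
  ci <- confint(fit, parm = "ivw_mre")
  expect_equal(unname(ci[1, ]),
               unlist(fit$estimates[fit$estimates$method == "ivw_mre",
                                    c("ci_low", "ci_high")], use.names = FALSE))
  r <- residuals(fit)
  expect_length(r, n_snps(h))
  expect_output(print(fit), "Two-sample MR")
  expect_output(print(summary(fit)), "Cochran")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("under no pleiotropy all estimators agree and the IVW CI covers truth", {
  set.seed(71)
  cfg <- sim_config(L = 50, L_med = 0, a = 0, b = 0, d = 0.1, seed = 71)
  st <- simulate_gwas_triplet(cfg)
  d <- mr_input(st$exposure$beta, st$exposure$se,
                st$outcome$beta, st$outcome$se)
  fits <- c(ivw = mr_ivw(d)$beta,
            egger = mr_egger(d)$beta[1],
            wm = mr_weighted_median(d, n_boot = 20, seed = 1)$beta,
            sm = mr_mode(d, n_boot = 20, seed = 1)$beta,
            wmode = mr_mode(d, weighted = TRUE, n_boot = 20, seed = 1)$beta)
  expect_true(all(abs(fits - 0.1) < 0.05))

  # coverage of the fixed-effect IVW CI across replicates
  hits <- vapply(1:150, function(s) {
    sti <- simulate_gwas_triplet(sim_config(L = 50, L_med = 0, a = 0, b = 0,
                                            d = 0.1, seed = 1000 + s))
    f <- mr_ivw(mr_input(sti$exposure$beta, sti$exposure$se,
                         sti$outcome$beta, sti$outcome$se),
                variance_model = "fixed")
    f$ci_low <= 0.1 && 0.1 <= f$ci_high
  }, logical(1))
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)
})
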