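test_that("Cochran's Q matches hand evaluation and behaves at the boundaries", {
  # two ratios 0.1 and 0.3 with se(theta) = 0.1 each around their weighted
  # mean 0.2: Q = 100*(0.01) + 100*(0.01) = 2
  d <- mr_input(bx = c(1, 1), bxse = c(1e-4, 1e-4),
                by = c(0.1, 0.3), byse = c(0.1, 0.1))
  q <- cochran_q(d, ivw_beta = 0.2)
  expect_equal(q$q_stat, 2, tolerance = 1e-12)
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(2, 1, lower.tail = FALSE))

  # no dispersion: Q = 0, p = 1
  d0 <- mr_input(bx = c(0.1, 0.2, 0.4), bxse = rep(1e-4, 3),
                 by = c(0.02, 0.04, 0.08), byse = rep(0.01, 3))
  q0 <- cochran_q(d0)
  expect_equal(q0$q_stat, 0, tolerance = 1e-20)
  expect_equal(q0$q_pval, 1)

  expect_true(is.na(cochran_q(mr_input(1, 0.01, 0.1, 0.01))$q_stat))
})

test_that("Q is chi-square under homogeneity and drops with its top contributor", {
  qs <- vapply(1:400, function(s) {
    st <- simulate_gwas_triplet(sim_config(L = 20, L_med = 0, a = 0, b = 0,
                                           d = 0, seed = 5000 + s))
    cochran_q(mr_input(st$exposure$beta, st$exposure$se,
                       st$outcome$beta, st$outcome$se))$q_stat
  }, numeric(1))
  # mean of chi2(19) is 19; se of the mean over 400 draws ~ sqrt(38/400)
  expect_lt(abs(mean(qs) - 19), 3 * sqrt(2 * 19 / 400))

  # removing the largest contributor never increases Q
  set.seed(81)
  for (i in 1:10) {
    L <- 12
    bx <- rnorm(L, 0.1, 0.02); by <- 0.2 * bx + rnorm(L, 0, 0.02)
    d <- mr_input(bx, rep(1e-3, L), by, rep(0.01, L))
    q_full <- cochran_q(d)$q_stat
    contrib <- (bx / 0.01)^2 * (by / bx - sum((1 / 0.01^2) * bx * by) /
                                  sum((1 / 0.01^2) * bx^2))^2
    worst <- which.max(contrib)
    d_red <- mr_input(bx[-worst], rep(1e-3, L - 1), by[-worst],
                      rep(0.01, L - 1))
    expect_lte(cochran_q(d_red)$q_stat, q_full + 1e-9)
  }
})

test_that("the Egger intercept test flags directional pleiotropy only", {
  # intercept exactly zero with tiny se: p near 1, no flag
  eg <- data.frame(method = c("egger_slope", "egger_intercept"),
                   beta = c(0.2, 0), se = c(0.01, 1e-6),
                   pval = c(1e-5, 1), stringsAsFactors = FALSE)
  t0 <- egger_intercept_test(eg)
  expect_false(t0$pleiotropy)
  expect_equal(t0$pval, 1)
  expect_error(egger_intercept_test(eg[1, , drop = FALSE]), "intercept")

  # balanced pleiotropy: type-I error near the nominal level
  rej <- vapply(1:300, function(s) {
    st <- simulate_gwas_triplet(sim_config(
      L = 60, L_med = 0, a = 0, b = 0, d = 0.05, rho_invalid = 1,
      mu_alpha = 0, sigma_alpha = 0.003, seed = 7000 + s))
    d <- mr_input(st$exposure$beta, st$exposure$se,
                  st$outcome$beta, st$outcome$se)
    egger_intercept_test(mr_egger(d))$pleiotropy
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
})

test_that("the global pleiotropy test is deterministic, specific and sensitive", {
  st <- simulate_gwas_triplet(sim_config(L = 40, L_med = 0, seed = 91))
  d <- mr_input(st$exposure$beta, st$exposure$se,
                st$outcome$beta, st$outcome$se)
  p1 <- mr_presso(d, n_sim = 200, seed = 13)
  p2 <- mr_presso(d, n_sim = 200, seed = 13)
  expect_identical(p1$global_pval, p2$global_pval)
  expect_identical(p1$outlier_ids, p2$outlier_ids)
  # empirical p has resolution 1/(n_sim+1), never exactly zero
  expect_gte(p1$global_pval, 1 / 201)
  expect_error(mr_presso(mr_input(c(1, 1, 1), rep(0.01, 3),
                                  rep(0.1, 3), rep(0.01, 3))), "at least 4")

  # specificity on clean data, sensitivity to one large outlier
  res <- vapply(1:40, function(s) {
    sti <- simulate_gwas_triplet(sim_config(L = 50, L_med = 0,
                                            seed = 9000 + s))
    keep <- sti$truth$is_exposure_iv
    typical <- median(abs(sti$truth$c * sti$truth$gamma[keep]))
    di <- mr_input(sti$exposure$beta, sti$exposure$se,
                   sti$outcome$beta, sti$outcome$se,
                   snps = sti$exposure$rsid)
    clean <- mr_presso(di, n_sim = 1000, seed = s)
    stio <- inject_outliers(sti, data.frame(index = 1, effect = 10 * typical))
    dio <- mr_input(stio$exposure$beta, stio$exposure$se,
                    stio$outcome$beta, stio$outcome$se,
                    snps = stio$exposure$rsid)
    dirty <- mr_presso(dio, n_sim = 1000, seed = s)
    c(clean_p = clean$global_pval, dirty_p = dirty$global_pval,
      hit = stio$exposure$rsid[1] %in% dirty$outlier_ids)
  }, numeric(3))
  expect_gt(mean(res["clean_p", ] > 0.05), 0.85)
  expect_gt(mean(res["hit", ]), 0.85)
  # a larger outlier never makes the global test less alarmed on average
  expect_lte(mean(res["dirty_p", ]), mean(res["clean_p", ]))
})

test_that("analytic power matches simulation and is monotone", {
  expect_equal(power_continuous(1e5, 0.02, 0), 0.05)
  expect_error(power_continuous(1e5, 0, 0.1), "r2")

  # Monte-Carlo oracle: IVW z-test with se 1/sqrt(n r2) at the study scale
  set.seed(101)
  z <- rnorm(2e5, 0.08 * sqrt(80852 * 0.02), 1)
  mc_power <- mean(abs(z) > qnorm(0.975))
  expect_equal(power_continuous(80852, 0.02, 0.08), mc_power,
               tolerance = 0.02)

  # monotone in n, r2 and |beta|
  ns <- c(1e4, 5e4, 2e5, 1e6)
  expect_true(all(diff(power_continuous(ns, 0.02, 0.08)) > 0))
  r2s <- c(0.005, 0.02, 0.08, 0.3)
  expect_true(all(diff(sapply(r2s, power_continuous, n = 5e4,
                              beta = 0.08)) > 0))
  bs <- c(0.01, 0.05, 0.1, 0.3)
  expect_true(all(diff(sapply(bs, function(b)
    power_continuous(5e4, 0.02, b))) > 0))
  expect_gt(power_continuous(1e9, 0.02, 0.08), 0.999)
})

test_that("the sensitivity report bundles all diagnostics", {
  st <- simulate_gwas_triplet(sim_config(L = 30, L_med = 0, seed = 111))
  d <- mr_input(st$exposure$beta, st$exposure$se,
                st$outcome$beta, st$outcome$se)
  rep <- mr_sensitivity(d, n_sim = 100, seed = 3, power_beta = 0.0347,
                        n_outcome = 5e5, r2 = 0.1)
  expect_s3_class(rep, "sensitivity_report")
  expect_gte(rep$q_stat, 0)
  expect_true(rep$power >= 0.05 && rep$power <= 1)
  expect_gte(rep$presso_global_pval, 1 / 101)
  expect_output(print(rep), "Cochran")
})
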