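test_that("Wald ratio arithmetic, null, and sign follow the exposure", {
  rec <- toy_instruments(bx = 0.1, by = 0.05, sy = 0.02)
  w <- wald_ratio(rec)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$or_, exp(0.5))

  null <- wald_ratio(toy_instruments(bx = 0.2, by = 0, sy = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$or_, 1)

  neg <- wald_ratio(toy_instruments(bx = -0.1, by = 0.05, sy = 0.02))
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.2)

  expect_error(wald_ratio(toy_instruments(bx = 0, by = 0.1, sy = 0.02)),
               "exposure_beta")
})

test_that("IVW reduces to the known weighted mean of Wald ratios", {
  expect_error(mr_ivw(toy_instruments(bx = 0.1, by = 0.02, sy = 0.01)),
               "wald_ratio")

  # identical ratios: no heterogeneity, no overdispersion
  rec <- toy_instruments(bx = c(0.1, 0.2, 0.4), by = 0.3 * c(0.1, 0.2, 0.4),
                         sy = c(0.01, 0.02, 0.03))
  est <- mr_ivw(rec)
  expect_equal(est$beta, 0.3)
  expect_equal(est$extra$q, 0, tolerance = 1e-20)
  expect_equal(est$extra$overdispersion, 1)

  # ratio/weight pairs (0.1, 100), (0.2, 25), (0.4, 4):
  # beta = (10 + 5 + 1.6) / 129
  rec <- toy_instruments(bx = c(1, 1, 1),
                         by = c(0.1, 0.2, 0.4),
                         sy = 1 / sqrt(c(100, 25, 4)))
  expect_equal(mr_ivw(rec)$beta, 16.6 / 129, tolerance = 1e-12)
})

test_that("IVW equals an independent WLS-through-origin oracle", {
  set.seed(101)
  for (i in 1:50) {
    j <- sample(3:30, 1)
    rec <- toy_instruments(bx = rnorm(j, 0.1, 0.05),
                           by = rnorm(j, 0.02, 0.02),
                           sy = runif(j, 0.005, 0.05),
                           sx = runif(j, 0.005, 0.02))
    est <- mr_ivw(rec)
    # oracle: closed-form weighted least squares through the origin
    w <- 1 / rec$outcome_se^2
    beta_hat <- sum(w * rec$exposure_beta * rec$outcome_beta) /
      sum(w * rec$exposure_beta^2)
    q <- sum(w * (rec$outcome_beta - beta_hat * rec$exposure_beta)^2)
    se_hat <- sqrt(1 / sum(w * rec$exposure_beta^2)) *
      max(1, sqrt(q / (j - 1)))
    expect_equal(est$beta, beta_hat, tolerance = 1e-10)
    expect_equal(est$se, se_hat, tolerance = 1e-10)
  }
})

test_that("IVW with equal weights is the mean of Wald ratios", {
  rec <- toy_instruments(bx = rep(1, 4), by = c(0.1, 0.3, 0.2, 0.6),
                         sy = rep(0.1, 4))
  expect_equal(mr_ivw(rec)$beta, mean(c(0.1, 0.3, 0.2, 0.6)))
})

test_that("IVW is invariant to jointly flipping a record's signs", {
  set.seed(5)
  rec <- toy_instruments(bx = rnorm(6, 0.1, 0.03),
                         by = rnorm(6, 0.02, 0.01), sy = runif(6, 0.01, 0.03))
  flipped <- rec
  flipped$exposure_beta[2] <- -flipped$exposure_beta[2]
  flipped$outcome_beta[2] <- -flipped$outcome_beta[2]
  expect_equal(mr_ivw(flipped)$beta, mr_ivw(rec)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(flipped)$se, mr_ivw(rec)$se, tolerance = 1e-12)
})

test_that("Egger recovers a planted intercept and slope", {
  bx <- seq(0.05, 0.5, length.out = 10)
  rec <- toy_instruments(bx = bx, by = 0.02 + 0.1 * bx,
                         sy = rep(1e-4, 10))
  est <- mr_egger(rec)
  expect_equal(est$beta, 0.1, tolerance = 1e-6)
  expect_equal(est$extra$egger_intercept, 0.02, tolerance = 1e-6)
})

test_that("Egger equals an independent weighted-LS-with-intercept oracle", {
  set.seed(202)
  for (i in 1:20) {
    j <- sample(4:25, 1)
    rec <- toy_instruments(bx = abs(rnorm(j, 0.1, 0.05)) + 0.01,
                           by = rnorm(j, 0.02, 0.02),
                           sy = runif(j, 0.005, 0.05))
    est <- mr_egger(rec)
    w <- 1 / rec$outcome_se^2
    x <- cbind(1, rec$exposure_beta)   # all bx positive: no reorientation
    xtw <- t(x * w)
    coef <- solve(xtw %*% x, xtw %*% rec$outcome_beta)
    resid <- rec$outcome_beta - x %*% coef
    sigma2 <- sum(w * resid^2) / (j - 2)
    vc <- solve(xtw %*% x)
    scale <- max(1, sqrt(sigma2))
    expect_equal(est$beta, coef[2], tolerance = 1e-10)
    expect_equal(est$se, sqrt(vc[2, 2]) * scale, tolerance = 1e-10)
    expect_equal(est$extra$egger_intercept, coef[1], tolerance = 1e-10)
  }
})

test_that("Egger slope matches IVW under exactly balanced pleiotropy", {
  bx <- c(1, 1, 2, 2)
  a <- 0.05
  rec <- toy_instruments(bx = bx, by = 0.1 * bx + c(a, -a, a, -a),
                         sy = rep(0.02, 4))
  expect_equal(mr_egger(rec)$beta, mr_ivw(rec)$beta, tolerance = 1e-6)
  expect_lt(abs(mr_egger(rec)$extra$egger_intercept), 1e-10)
})

test_that("Egger refuses a collinear design and tiny sets", {
  rec <- toy_instruments(bx = rep(0.2, 5), by = rnorm(5, 0.02, 0.01),
                         sy = rep(0.02, 5))
  expect_error(mr_egger(rec), "degenerate design")
  expect_error(mr_egger(toy_instruments(bx = c(1, 2), by = c(1, 2),
                                        sy = c(1, 1))), ">= 3")
})

test_that("weighted median interpolates the weighted CDF at one half", {
  rec <- toy_instruments(bx = rep(1, 3), by = c(0.1, 0.2, 0.3),
                         sy = rep(0.1, 3))
  expect_equal(mr_weighted_median(rec, n_boot = 50)$beta, 0.2)

  # majority weight on one SNP drags the estimate to its ratio
  rec <- toy_instruments(bx = c(1, 1, 1), by = c(0.4, 0.1, 0.2),
                         sy = c(0.01, 0.2, 0.2))
  expect_equal(mr_weighted_median(rec, n_boot = 50)$beta, 0.4,
               tolerance = 5e-3)
})

test_that("weighted median matches a brute-force CDF oracle", {
  brute <- function(r, w) {
    o <- order(r)
    r <- r[o]; w <- w[o] / sum(w)
    s <- cumsum(w) - w / 2
    if (0.5 <= s[1]) return(r[1])
    if (0.5 >= s[length(s)]) return(r[length(s)])
    k <- max(which(s <= 0.5))
    r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
  }
  set.seed(303)
  for (i in 1:30) {
    j <- sample(3:20, 1)
    rec <- toy_instruments(bx = rnorm(j, 0.2, 0.05),
                           by = rnorm(j, 0.04, 0.03),
                           sy = runif(j, 0.01, 0.1))
    est <- mr_weighted_median(rec, n_boot = 10)
    expect_equal(est$beta,
                 brute(rec$outcome_beta / rec$exposure_beta,
                       rec$exposure_beta^2 / rec$outcome_se^2),
                 tolerance = 1e-12)
  }
})

test_that("weighted median is robust to a low-weight outlier", {
  rec <- toy_instruments(bx = rep(1, 7),
                         by = c(rep(0.2, 6), 5),
                         sy = c(rep(0.02, 6), 1))
  expect_equal(mr_weighted_median(rec, n_boot = 200)$beta, 0.2,
               tolerance = 0.05)
})

test_that("weighted median bootstrap is seed-reproducible", {
  rec <- toy_instruments(bx = rnorm(8, 0.2, 0.05), by = rnorm(8, 0.04, 0.02),
                         sy = runif(8, 0.01, 0.05))
  a <- mr_weighted_median(rec, seed = 9)
  b <- mr_weighted_median(rec, seed = 9)
  expect_identical(a$se, b$se)
})

test_that("cML recovers the causal effect and plants no false invalids", {
  sim <- simulate_two_sample(sim_config(n_snp = 30, theta = 0.2, seed = 21))
  rec <- harmonize(sim$exposure, sim$outcome)
  est <- mr_cml(rec, seed = 1)
  expect_equal(est$extra$cml_k_invalid, 0)
  expect_lt(abs(est$beta - 0.2), 3 * est$se)
})

test_that("cML flags planted pleiotropic instruments", {
  sim <- simulate_two_sample(sim_config(n_snp = 20, theta = 0.2, seed = 33))
  rec <- harmonize(sim$exposure, sim$outcome)
  planted <- c(3, 11)
  rec$outcome_beta[planted] <- rec$outcome_beta[planted] + c(0.15, -0.2)
  est <- mr_cml(rec, seed = 1)
  expect_equal(est$extra$cml_k_invalid, 2)
  expect_setequal(est$extra$invalid_ids, rec$variant_id[planted])
  expect_lt(abs(est$beta - 0.2), 4 * est$se)
})

test_that("cML stays near zero under a null effect across replicates", {
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(n_snp = 20, theta = 0,
                                          seed = 5000 + r))
    rec <- harmonize(sim$exposure, sim$outcome)
    est <- mr_cml(rec, seed = 1, max_k = 3, n_start = 1)
    if (abs(est$beta) < 3 * est$se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("run_uvmr dispatches by instrument count", {
  one <- toy_instruments(bx = 0.1, by = 0.02, sy = 0.01)
  expect_named(run_uvmr(one), "wald")

  two <- toy_instruments(bx = c(0.1, 0.2), by = c(0.02, 0.05),
                         sy = c(0.01, 0.01))
  res2 <- run_uvmr(two)
  expect_setequal(names(res2), c("wald", "ivw_mre"))
  expect_length(res2$wald, 2)

  sim <- simulate_two_sample(sim_config(n_snp = 12, theta = 0.15, seed = 8))
  rec <- harmonize(sim$exposure, sim$outcome)
  res <- run_uvmr(rec, seed = 4)
  expect_setequal(names(res),
                  c("wald", "ivw_mre", "egger", "weighted_median", "cml"))
  expect_true(all(vapply(res[-1], function(e) e$n_snp, 0L) == 12))
  # consistent data: every estimator's CI overlaps every other's
  ests <- res[c("ivw_mre", "egger", "weighted_median", "cml")]
  for (a in ests) {
    for (b in ests) {
      expect_lt(a$ci_low, b$ci_high)
    }
  }
  expect_error(run_uvmr(one[0, , drop = FALSE]), "no instruments")
})
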