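test_that("intercept calibration: closed form at zero effects, symmetry, self-check", {
  des0 <- simulation_design(3, 2, matrix(0, 2, 2), c(0.5, 0.3, 0.2))
  des0 <- calibrate_intercepts(des0)
  expect_equal(des0$intercepts, log(c(0.3, 0.2) / 0.5), tolerance = 1e-12)

  # equal targets with identical sub-model coefficients -> equal intercepts
  des_sym <- simulation_design(3, 2, cbind(c(0.5, 0.3), c(0.5, 0.3)),
                               c(1, 1, 1) / 3)
  des_sym <- calibrate_intercepts(des_sym, n_cal = 2e5, seed = 2)
  expect_equal(des_sym$intercepts[1], des_sym$intercepts[2], tolerance = 0.01)

  # calibrated design regenerates its target proportions on fresh data
  des <- calibrate_intercepts(toy_design(), n_cal = 2e5, seed = 3)
  dat <- simulate_multinomial_data(des, 2e5, seed = 99)
  freqs <- tabulate(dat$y, 3) / 2e5
  expect_equal(freqs, des$targets, tolerance = 0.01)
})

test_that("simulated datasets are reproducible and honour the probability model", {
  des <- calibrate_intercepts(toy_design(), n_cal = 1e5, seed = 3)
  a <- simulate_multinomial_data(des, 500, seed = 7)
  b <- simulate_multinomial_data(des, 500, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$y %in% 1:3))

  # per-individual category probabilities sum to one
  p <- mnlsampsize:::softmax_probs(a$x, des$intercepts, des$beta)
  expect_equal(rowSums(p), rep(1, 500), tolerance = 1e-12)

  # zero-coefficient design: label frequencies consistent with the targets
  des0 <- calibrate_intercepts(simulation_design(3, 2, matrix(0, 2, 2),
                                                 c(0.5, 0.3, 0.2)))
  d0 <- simulate_multinomial_data(des0, 1e5, seed = 13)
  gof <- chisq.test(tabulate(d0$y, 3), p = des0$targets)
  expect_gt(gof$p.value, 0.001)

  expect_error(simulate_multinomial_data(toy_design(), 100), "calibrate")
})

test_that("multinomial fitting matches logistic regression when K = 2", {
  set.seed(17)
  n <- 600
  x <- matrix(rnorm(n * 2), n, 2)
  y <- 1L + rbinom(n, 1L, plogis(-0.3 + x %*% c(0.8, -0.5)))
  fit <- fit_multinomial(x, y, K = 2)
  ref <- glm(I(y == 2) ~ x, family = binomial())
  expect_equal(unname(fit$coef[, 2]), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$lnL_model, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_gte(fit$LR, 0)
})

test_that("the fitted multinomial likelihood dominates a perturbation grid", {
  set.seed(23)
  des <- calibrate_intercepts(toy_design(3, 1), n_cal = 1e5, seed = 4)
  dat <- simulate_multinomial_data(des, 40, seed = 5)
  while (any(tabulate(dat$y, 3) == 0))
    dat <- simulate_multinomial_data(des, 40)
  fit <- fit_multinomial(dat$x, dat$y, K = 3)
  ll_opt <- mnlsampsize:::mnl_loglik(fit$coef, dat$x, dat$y)
  expect_equal(ll_opt, fit$lnL_model, tolerance = 1e-8)
  # grid over the two slope parameters around the optimum
  eps <- seq(-0.5, 0.5, length.out = 50)
  for (e1 in eps[c(1, 13, 25, 38, 50)]) {
    for (e2 in eps) {
      b <- fit$coef
      b[2, 2] <- b[2, 2] + e1
      b[2, 3] <- b[2, 3] + e2
      expect_lte(mnlsampsize:::mnl_loglik(b, dat$x, dat$y), ll_opt + 1e-8)
    }
  }
  # random full-vector perturbations
  for (i in 1:200) {
    b <- fit$coef
    b[, 2:3] <- b[, 2:3] + matrix(rnorm(4, sd = 0.3), 2, 2)
    expect_lte(mnlsampsize:::mnl_loglik(b, dat$x, dat$y), ll_opt + 1e-8)
  }
  expect_error(fit_multinomial(dat$x, pmin(dat$y, 2), K = 3), "missing")
})

test_that("heuristic shrinkage factor obeys its limits", {
  expect_equal(heuristic_shrinkage((3 - 1) * 5, 3, 5), 0)
  expect_equal(heuristic_shrinkage(1e9, 3, 5), 1, tolerance = 1e-6)
  expect_error(heuristic_shrinkage(0, 3, 5), "undefined")
  expect_warning(s <- heuristic_shrinkage(5, 3, 5), "negative")
  expect_lt(s, 0)
})

test_that("recalibration slopes recover truth and invert coefficient scaling", {
  des <- calibrate_intercepts(toy_design(), n_cal = 2e5, seed = 8)
  b_true <- rbind(c(0, des$intercepts), cbind(0, des$beta))
  val <- simulate_multinomial_data(des, 1e6, seed = 9)
  for (r in 1:3) {
    rc <- submodel_shrinkage(b_true, val$x, val$y, reference = r)
    expect_true(rc$converged)
    expect_true(all(abs(rc$slopes - 1) < 0.02))
  }
  # doubling the developed coefficients halves the calibration slopes
  b_twice <- b_true; b_twice[-1, ] <- 2 * b_twice[-1, ]
  rc2 <- submodel_shrinkage(b_twice, val$x, val$y, reference = 1)
  expect_true(all(abs(rc2$slopes - 0.5) < 0.02))
})

test_that("recalibration reduces to the logistic calibration slope when K = 2", {
  des2 <- calibrate_intercepts(simulation_design(2, 2,
                                                 matrix(c(0.7, -0.4), 2, 1),
                                                 c(0.6, 0.4)),
                               n_cal = 1e5, seed = 10)
  b <- rbind(c(0, des2$intercepts), cbind(0, des2$beta))
  b[-1, 2] <- b[-1, 2] * 1.7  # a miscalibrated model
  val <- simulate_multinomial_data(des2, 5e4, seed = 11)
  rc <- submodel_shrinkage(b, val$x, val$y, reference = 1)
  lp <- val$x %*% b[-1, 2]
  ref <- glm(I(val$y == 2) ~ lp, family = binomial())
  expect_equal(unname(rc$slopes), unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(unname(rc$intercepts), unname(coef(ref)[1]), tolerance = 1e-6)
  # and the distinct-logistic route gives the same slope for the only pair
  sdl <- distinct_logistic_shrinkage(b, val$x, val$y, 2, 1)
  expect_equal(sdl, unname(coef(ref)[2]), tolerance = 1e-6)
})

test_that("distinct-logistic slopes recover truth and invert halved coefficients", {
  des <- calibrate_intercepts(toy_design(), n_cal = 2e5, seed = 8)
  b_true <- rbind(c(0, des$intercepts), cbind(0, des$beta))
  val <- simulate_multinomial_data(des, 5e5, seed = 12)
  for (pr in list(c(2, 1), c(3, 1), c(3, 2))) {
    s <- distinct_logistic_shrinkage(b_true, val$x, val$y, pr[1], pr[2])
    expect_equal(s, 1, tolerance = 0.03)
  }
  b_half <- b_true; b_half[-1, ] <- b_half[-1, ] / 2
  s2 <- distinct_logistic_shrinkage(b_half, val$x, val$y, 2, 1)
  expect_equal(s2, 2, tolerance = 0.06)
  # one-sided subset flags cleanly
  expect_warning(
    s3 <- distinct_logistic_shrinkage(b_true, val$x[1:10, ],
                                      rep(c(1L, 2L), 5), 3, 1),
    "one-sided")
  expect_true(is.na(s3))
})

test_that("one-vs-one fits agree with the multinomial sub-model coefficients", {
  des <- calibrate_intercepts(toy_design(), n_cal = 2e5, seed = 14)
  dat <- simulate_multinomial_data(des, 2e5, seed = 15)
  fit <- fit_multinomial(dat$x, dat$y, K = 3)
  for (k in 2:3) {
    idx <- dat$y %in% c(k, 1L)
    g <- glm.fit(cbind(1, dat$x[idx, ]), as.numeric(dat$y[idx] == k),
                 family = binomial())
    expect_lt(max(abs(g$coefficients - fit$coef[, k])), 0.05)
  }
})

test_that("the experiment wrapper is reproducible and surfaces degenerate designs", {
  des <- toy_design()
  ex <- run_shrinkage_experiment(des, n_sims = 6, pilot_n = 3e4,
                                 n_val_mult = 20, seed = 77)
  expect_s3_class(ex, "shrinkage_experiment")
  expect_true(ex$n_dev > 0)
  expect_equal(nrow(ex$pilot_r2), 3)
  expect_true(all(c("S_MN", "S_DL") %in% ex$shrinkage$quantity))
  # S_MN estimated under every reference category (6 ordered pairs for K=3)
  smn <- ex$shrinkage[ex$shrinkage$quantity == "S_MN", ]
  expect_equal(nrow(unique(smn[c("k", "r")])), 6)
  expect_equal(nrow(ex$summary), 6)
  expect_equal(nrow(ex$agreement), 3)
  # bit-identical reproduction under the same master seed
  ex2 <- run_shrinkage_experiment(des, n_sims = 6, pilot_n = 3e4,
                                  n_val_mult = 20, seed = 77)
  expect_identical(ex$shrinkage, ex2$shrinkage)
  expect_identical(ex$n_dev, ex2$n_dev)

  # zero-effect design cannot be sized and says so
  des0 <- simulation_design(3, 2, matrix(0, 2, 2), c(0.5, 0.3, 0.2))
  expect_error(run_shrinkage_experiment(des0, n_sims = 2, pilot_n = 2e4,
                                        seed = 1),
               "approximately zero")
})
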