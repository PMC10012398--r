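test_that("binary shrinkage size matches direct arithmetic and is monotone", {
  # independent arithmetic evaluation, frozen: 17 / (-0.1 * log(1 - 0.497/0.9))
  expect_equal(binary_shrinkage_size(17, 0.9, 0.497), 211.5854,
               tolerance = 1e-4)
  # monotone: increasing in Q and S, decreasing in r2
  set.seed(5)
  for (i in 1:20) {
    Q <- sample(1:40, 1); S <- runif(1, 0.6, 0.95); r2 <- runif(1, 0.05, S - 0.1)
    base <- binary_shrinkage_size(Q, S, r2)
    expect_gt(binary_shrinkage_size(Q + 1, S, r2), base)
    expect_gt(binary_shrinkage_size(Q, S + 0.02, r2), base)
    expect_lt(binary_shrinkage_size(Q, S, r2 + 0.02), base)
  }
  # divergence as S -> 1
  expect_gt(binary_shrinkage_size(5, 0.9999, 0.1),
            binary_shrinkage_size(5, 0.99, 0.1) * 50)
  expect_error(binary_shrinkage_size(10, 0.5, 0.6), "unattainable")
  expect_error(binary_shrinkage_size(0.5, 0.9, 0.1), "Q")
})

test_that("root-finding on the returned size recovers the shrinkage target", {
  set.seed(6)
  for (i in 1:15) {
    Q <- sample(2:30, 1); S <- runif(1, 0.7, 0.95); r2 <- runif(1, 0.05, S - 0.15)
    m <- binary_shrinkage_size(Q, S, r2)
    s_hat <- uniroot(function(s) Q / ((s - 1) * log(1 - r2 / s)) - m,
                     lower = r2 + 1e-9, upper = 1 - 1e-9, tol = 1e-12)$root
    expect_equal(s_hat, S, tolerance = 1e-8)
  }
})

test_that("criterion (i) reproduces the worked example pairwise grid", {
  crit <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17,
                              S_target = 0.9)
  tab <- crit$pairs
  # pair {4,1}: printed value reproduced exactly
  expect_equal(tab$n_pair[tab$k == 4 & tab$r == 1], 246)
  # full grid within 1% of the published values (which used unrounded R2)
  cmp <- merge(tab, iota_published_grid, by = c("k", "r"))
  expect_true(all(abs(cmp$n_pair - cmp$n_published) / cmp$n_published < 0.01))
  # binding pair is {5,3}
  expect_equal(unname(crit$binding), c(5, 3))
  expect_equal(crit$n, max(tab$n_pair))
})

test_that("criterion (i) reduces to the binary formula when K = 2", {
  d <- outcome_distribution(c(300, 100))
  ev <- data.frame(k = 2L, r = 1L, r2 = 0.25)
  crit <- criterion_shrinkage(d, ev, Q = 8, S_target = 0.9)
  expect_equal(crit$n, ceiling(binary_shrinkage_size(8, 0.9, 0.25)))
  expect_equal(crit$pairs$p_pair, 1)
})

test_that("relaxing one pair's shrinkage target only lowers that pair and can shift the binding pair", {
  base <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17,
                              S_target = 0.9)
  relaxed <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17,
                                 S_target = 0.9,
                                 S_overrides = c("5,3" = 0.8))
  b <- base$pairs$n_pair
  r <- relaxed$pairs$n_pair
  expect_true(all(r <= b))
  i53 <- which(base$pairs$k == 5 & base$pairs$r == 3)
  expect_lt(r[i53], b[i53])
  expect_equal(r[-i53], b[-i53])
  # binding pair moves to {3,2}
  expect_equal(unname(relaxed$binding), c(3, 2))
})

test_that("criterion (i) errors are actionable", {
  expect_error(criterion_shrinkage(iota_dist(),
                                   data.frame(k = 2L, r = 1L, r2 = 0.1),
                                   Q = 17),
               "missing pairwise R-squared")
  ev <- iota_resolved()
  ev$r2[ev$k == 5 & ev$r == 3] <- 0.95
  expect_error(criterion_shrinkage(iota_dist(), ev, Q = 17),
               "pair \\{5,3\\}")
})

test_that("heuristic (direct) multinomial size warns and understates criterion (i)", {
  expect_warning(h <- heuristic_shrinkage_size(5, 17, 0.126, 0.9),
                 "not guarantee")
  # independent arithmetic: 68 / (-0.1 * log(1 - 0.126 / 0.9))
  expect_equal(h, ceiling(68 / (0.1 * -log(1 - 0.126 / 0.9))))
  crit_i_n <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17)$n
  expect_lt(h, crit_i_n)
  # K = 2 reduction
  expect_warning(h2 <- heuristic_shrinkage_size(2, 8, 0.2, 0.9))
  expect_equal(h2, ceiling(binary_shrinkage_size(8, 0.9, 0.2)))
})

test_that("criterion (ii) reproduces the worked example and its algebraic identity", {
  crit <- criterion_r2_difference(5, 17, r2_adj = 0.126, max_r2 = 0.841,
                                  delta = 0.05)
  expect_equal(crit$n_raw, 1477.08, tolerance = 1e-2)
  expect_gte(crit$n, 1477)   # printed lower bound
  expect_equal(crit$n, 1478) # ceiling of the unrounded bound
  # smallest-integer semantics: bound holds at n, fails at n - 1
  expect_gte(crit$n, crit$n_raw)
  expect_lt(crit$n - 1, crit$n_raw)
  # with R2 = 0.15 * max and delta = 0.05 the implied shrinkage bound is
  # 0.75 regardless of max
  for (mx in c(0.5, 0.841, 0.95)) {
    c2 <- criterion_r2_difference(4, 10, r2_adj = 0.15 * mx, max_r2 = mx,
                                  delta = 0.05)
    expect_equal(c2$S_bound, 0.75, tolerance = 1e-12)
  }
  expect_error(criterion_r2_difference(3, 10, r2_adj = 0.97, max_r2 = 0.9,
                                       delta = 0.5),
               "not\\s+attainable")
})

test_that("criterion (ii) reduces to the binary formula when K = 2", {
  crit <- criterion_r2_difference(2, 9, r2_adj = 0.2, max_r2 = 0.7,
                                  delta = 0.05)
  s_bound <- 0.2 / (0.2 + 0.05 * 0.7)
  expect_equal(crit$n_raw, 9 / ((s_bound - 1) * log(1 - 0.2 - 0.05 * 0.7)),
               tolerance = 1e-10)
})

test_that("criterion (iii) reproduces the worked example category sizes", {
  crit <- criterion_precision(iota_dist(), delta = 0.05, alpha = 0.05)
  expect_equal(crit$per_category$n_k, c(524, 134, 127, 307, 88))
  expect_equal(crit$n, 524)
  expect_equal(crit$binding, 1L)
  expect_equal(crit$quantile, qchisq(0.99, 1), tolerance = 1e-12)
})

test_that("criterion (iii) properties: balanced worst case, pointwise option, degenerate categories", {
  # p = 0.5 maximises the per-category requirement at fixed K, delta, alpha
  d_even <- outcome_distribution(c(500, 500))
  n_even <- criterion_precision(d_even)$n
  for (p1 in c(0.1, 0.3, 0.45)) {
    d <- outcome_distribution(c(p1 * 1000, (1 - p1) * 1000))
    expect_lt(criterion_precision(d)$n, n_even)
  }
  # pointwise quantile (1.96^2) is smaller than the simultaneous one
  pw <- criterion_precision(iota_dist(), pointwise = TRUE)
  expect_equal(pw$quantile, qnorm(0.975)^2, tolerance = 1e-12)
  expect_lt(pw$n, 524)
  # degenerate proportion contributes zero with a warning
  expect_warning(cz <- criterion_precision(outcome_distribution(c(0, 10, 10))),
                 "proportion 0")
  expect_equal(cz$per_category$n_k[1], 0)
})

test_that("EPV comparator matches the worked example and simple arithmetic", {
  d <- iota_dist()
  expect_equal(epv_size(10, 17, d), 4967)
  expect_equal(epv_size(20, 17, d), 9934)
  expect_equal(epv_size(10, 1, outcome_distribution(c(100, 900))), 100)
  expect_equal(epv_size(c(10, 20), 17, d), c(4967, 9934))
})

test_that("every criterion is monotone in its drivers", {
  d <- iota_dist()
  ev <- iota_resolved()
  n_q <- vapply(c(5, 10, 17, 25), function(q)
    criterion_shrinkage(d, ev, Q = q)$n, numeric(1))
  expect_true(all(diff(n_q) > 0))
  n_s <- vapply(c(0.8, 0.85, 0.9, 0.95), function(s)
    criterion_shrinkage(d, ev, Q = 17, S_target = s)$n, numeric(1))
  expect_true(all(diff(n_s) > 0))
  ev_hi <- ev; ev_hi$r2 <- pmin(ev$r2 + 0.05, 0.6)
  expect_lt(criterion_shrinkage(d, ev_hi, Q = 17)$n,
            criterion_shrinkage(d, ev, Q = 17)$n)
  n_d2 <- vapply(c(0.02, 0.05, 0.1), function(dd)
    criterion_r2_difference(5, 17, 0.126, 0.841, delta = dd)$n, numeric(1))
  expect_true(all(diff(n_d2) < 0))
  n_d3 <- vapply(c(0.02, 0.05, 0.1), function(dd)
    criterion_precision(d, delta = dd)$n, numeric(1))
  expect_true(all(diff(n_d3) < 0))
})

test_that("nearest rounding is available for audit and never exceeds ceiling", {
  cc <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17,
                            rounding = "nearest")
  ce <- criterion_shrinkage(iota_dist(), iota_resolved(), Q = 17,
                            rounding = "ceiling")
  expect_true(all(cc$pairs$n_pair <= ce$pairs$n_pair))
  expect_true(all(ce$pairs$n_pair - cc$pairs$n_pair <= 1))
})
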