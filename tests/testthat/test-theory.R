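# Closed-form first-order theory. The full printed-table reproduction lives
# in test-acceptance.R; here the focus is internal consistency: exact
# quadratic minima vs printed minimum-MSE formulas, printed coefficients vs
# exact minimizers, limits, and invariances.

test_that("usual-estimator variance and PRE base behave", {
  fx <- table1_fixture("population1")
  r0 <- var_usual(fx$m, fx$d)
  expect_equal(r0$mse, fx$d$lam * fx$m$Sy2^2 * fx$m$lam400s)
  expect_equal(r0$pre, 100)
  # quadrupling Sy2 (y scaled by sqrt(2)) multiplies the variance by 16
  m2 <- fx$m; m2$Sy2 <- 4 * m2$Sy2
  expect_equal(var_usual(m2, fx$d)$mse, 16 * r0$mse)
  expect_error(pre_of(0, r0$mse), "positive")
  expect_equal(pre_of(r0$mse, r0$mse), 100)
})

test_that("gamma_star matches direct evaluation and degenerates correctly", {
  fx <- fixture_pair()
  expect_equal(gamma_star(fx$population1$m), -0.8769876, tolerance = 1e-6)
  expect_equal(gamma_star(fx$population2$m), -0.9098564, tolerance = 1e-6)
  m0 <- moment_set(1, 1, 1, lam400s = 2, lam040s = 2, lam004s = 2,
                   lam220s = 0, lam202s = 0, lam022s = 0)
  expect_equal(gamma_star(m0), 0)
  msing <- moment_set(1, 1, 1, lam400s = 2, lam040s = 2, lam004s = 2,
                      lam220s = 1, lam202s = 1, lam022s = 2)
  expect_error(gamma_star(msing), "singular")
})

test_that("aux_scalars reproduce direct evaluation on Population 1", {
  fx <- table1_fixture("population1")
  a <- aux_scalars(fx$m, fx$d)
  expect_equal(a$y1, 0.7350700, tolerance = 1e-6)
  expect_equal(a$n1, 9.2462282, tolerance = 1e-6)
  expect_equal(a$y11, 1.2377418, tolerance = 1e-6)
  expect_equal(a$n11, -0.1763154, tolerance = 1e-6)
  # zero crosses with lam*022 = 0: y1 = 0, n1 = lam*040 + lam*004
  m0 <- moment_set(1, 1, 1, lam400s = 2, lam040s = 3, lam004s = 5,
                   lam220s = 0, lam202s = 0, lam022s = 0)
  a0 <- aux_scalars(m0, fx$d)
  expect_equal(a0$y1, 0)
  expect_equal(a0$n1, 3 + 5)
  # n1 is symmetric under exchanging the two auxiliary variables
  mswap <- moment_set(1, 1, 1, lam400s = fx$m$lam400s,
                      lam040s = fx$m$lam004s, lam004s = fx$m$lam040s,
                      lam220s = fx$m$lam202s, lam202s = fx$m$lam220s,
                      lam022s = fx$m$lam022s)
  expect_equal(aux_scalars(mswap, fx$d)$n1, a$n1, tolerance = 1e-12)
})

test_that("exact quadratic minima equal the printed minimum-MSE closed forms", {
  for (fx in fixture_pair()) {
    m <- fx$m; d <- fx$d
    expect_equal(dualvar:::.quad_minimize(dualvar:::.quad_rao(m, d))$value,
                 mse_rao(m, d)$mse, tolerance = 1e-12)
    expect_equal(
      dualvar:::.quad_minimize(dualvar:::.quad_grover_kaur(m, d))$value,
      mse_grover_kaur(m, d)$mse, tolerance = 1e-12)
    expect_equal(dualvar:::.quad_minimize(dualvar:::.quad_ahmad(m, d))$value,
                 mse_ahmad(m, d)$mse, tolerance = 1e-12)
  }
})

test_that("printed w1..w5 coefficients are the exact minimizers; w6..w10 are not", {
  for (fx in fixture_pair()) {
    ce <- optimal_coefficients(fx$m, fx$d, "exact")
    cp <- optimal_coefficients(fx$m, fx$d, "printed")
    expect_equal(ce$psi11, cp$psi11)
    for (k in c("w1", "w2", "w3", "w4", "w5"))
      expect_equal(cp$w[[k]], ce$w[[k]], tolerance = 1e-9, label = k)
    # the printed w6/w7 and w8..w10 displays carry typos: evaluating the
    # MSE quadratics at the printed values must sit strictly above the
    # exact minimum (documented discrepancy, not hidden)
    q_ah <- dualvar:::.quad_ahmad(fx$m, fx$d)
    expect_gt(dualvar:::.quad_value(q_ah, cp$w[c("w5", "w6", "w7")]),
              mse_ahmad(fx$m, fx$d)$mse * (1 + 1e-6))
    q_pr <- dualvar:::.quad_proposed(fx$m, fx$d)
    expect_gt(dualvar:::.quad_value(q_pr, cp$w[c("w8", "w9", "w10")]),
              mse_proposed_exact(fx$m, fx$d)$mse + 1)
  }
})

test_that("proposed-estimator exact minimum: fixture values and minimization property", {
  fx <- fixture_pair()
  r1 <- mse_proposed_exact(fx$population1$m, fx$population1$d)
  expect_equal(r1$mse, 4.415769e12, tolerance = 1e-5)
  expect_equal(r1$coefficients$w[["w8"]], 0.8261233, tolerance = 1e-5)
  expect_identical(r1$coefficients$provenance, "exact_minimization")
  # the reported minimum is below the quadratic at 100 random triples
  q <- dualvar:::.quad_proposed(fx$population1$m, fx$population1$d)
  set.seed(99)
  w0 <- r1$coefficients$w[c("w8", "w9", "w10")]
  for (i in 1:100) {
    w <- w0 * (1 + stats::rnorm(3, 0, 0.5)) + stats::rnorm(3, 0, 0.1)
    expect_gte(dualvar:::.quad_value(q, w), r1$mse)
  }
  # Population 2: the bias cross-terms push the algebraic minimum negative;
  # the result must be flagged and its PRE undefined
  r2 <- mse_proposed_exact(fx$population2$m, fx$population2$d)
  expect_lt(r2$mse, 0)
  expect_true("nonpositive_mse" %in% r2$flags)
  expect_true(is.na(r2$pre))
})

test_that("zero auxiliary information: proposed minimum is at most the shrinkage-only MSE", {
  d <- design_spec(100, 10)
  m0 <- moment_set(10, 4, 6, lam400s = 2, lam040s = 2, lam004s = 2,
                   lam220s = 0, lam202s = 0, lam022s = 0)
  shrink_only <- d$lam * m0$Sy2^2 * m0$lam400s / (1 + d$lam * m0$lam400s)
  r <- mse_proposed_exact(m0, d)
  expect_lte(r$mse, shrink_only)
  # independent zooming-grid oracle agrees with the 3x3 solve
  q <- dualvar:::.quad_proposed(m0, d)
  g <- grid_search_min(function(w) dualvar:::.quad_value(q, w),
                       lower = c(-2, -40, -40), upper = c(2, 40, 40))
  expect_equal(r$mse, g$value, tolerance = 1e-6)
})

test_that("printed closed-form proposed MSE is negative on Population 1 and flagged", {
  fx <- table1_fixture("population1")
  r <- mse_proposed_printed(fx$m, fx$d)
  expect_equal(r$mse, -9.9611e11, tolerance = 1e-4)
  expect_true("printed_formula_inconsistent" %in% r$flags)
  expect_true("nonpositive_mse" %in% r$flags)
})

test_that("census limit sends every first-order MSE to zero", {
  fx <- table1_fixture("population1")
  d0 <- design_spec(1e6, 1e6 - 1)   # lam ~ 1e-12
  for (f in list(var_usual, mse_ratio, var_difference, mse_rao,
                 mse_exp_ratio, mse_grover_kaur, mse_ahmad,
                 mse_proposed_printed))
    expect_lt(abs(f(fx$m, d0)$mse), 1e-12 * fx$m$Sy2^2 * 10)
})

test_that("scale equivariance: y -> c y multiplies MSEs by c^4, leaves PREs alone", {
  fx <- table1_fixture("population2")
  c2 <- 2.7   # multiplies Sy2
  m2 <- moment_set(Sy2 = c2 * fx$m$Sy2, Sx2 = fx$m$Sx2, Srx2 = fx$m$Srx2,
                   lam400s = fx$m$lam400s, lam040s = fx$m$lam040s,
                   lam004s = fx$m$lam004s, lam220s = fx$m$lam220s,
                   lam202s = fx$m$lam202s, lam022s = fx$m$lam022s)
  t1 <- theory_table(fx$m, fx$d)
  t2 <- theory_table(m2, fx$d)
  expect_equal(t2$mse, c2^2 * t1$mse, tolerance = 1e-10)
  expect_equal(t2$pre, t1$pre, tolerance = 1e-10)
})

test_that("headline MSE ordering holds on both fixtures", {
  for (fx in fixture_pair()) {
    m <- fx$m; d <- fx$d
    expect_lt(mse_proposed_exact(m, d)$mse, mse_ahmad(m, d)$mse)
    expect_lt(mse_ahmad(m, d)$mse, mse_grover_kaur(m, d)$mse)
    expect_lt(mse_grover_kaur(m, d)$mse, var_difference(m, d)$mse)
    expect_lt(var_difference(m, d)$mse, var_usual(m, d)$mse)
  }
})

test_that("scaled bias table reproduces the two verified entries and zeroes", {
  fx <- table1_fixture("population1")
  tab <- scaled_bias_table(fx$m, fx$d)
  expect_equal(tab[["ratio"]], 1.187433e14, tolerance = 1e-6)
  expect_equal(tab[["exp_ratio"]], -1.912397e13, tolerance = 1e-6)
  expect_identical(tab[["usual"]], 0)
  expect_identical(tab[["difference"]], 0)
  expect_true(all(c("rao", "ahmad") %in% attr(tab, "unit_mismatch")))
  # lam*040 = lam*220 zeroes the ratio entry
  m0 <- moment_set(1, 1, 1, lam400s = 2, lam040s = 3, lam004s = 2,
                   lam220s = 3, lam202s = 1, lam022s = 1)
  expect_equal(scaled_bias_table(m0, fx$d)[["ratio"]], 0)
})

test_that("theory_table assembles all eight estimators with flags", {
  fx <- table1_fixture("population1")
  tab <- theory_table(fx$m, fx$d)
  expect_identical(tab$estimator, estimator_ids())
  expect_identical(attr(tab, "flags")$usual, character(0))
  tabp <- theory_table(fx$m, fx$d, proposed_mode = "printed")
  expect_true("printed_formula_inconsistent" %in%
                attr(tabp, "flags")$proposed)
})
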