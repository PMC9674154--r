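test_that("rank_auxiliary follows the average-rank tie rule", {
  expect_equal(rank_auxiliary(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(rank_auxiliary(c(2, 2, 7)), c(1.5, 1.5, 3))
  # sum invariant with and without ties
  set.seed(1)
  for (x in list(rnorm(25), round(rnorm(25), 1), rep(1, 10))) {
    N <- length(x)
    expect_equal(sum(rank_auxiliary(x)), N * (N + 1) / 2)
  }
  expect_error(rank_auxiliary(numeric(0)), "degenerate")
  expect_error(rank_auxiliary(c(1, NA, 3)), "missing")
})

test_that("tie-free ranks of 69 units have mean 35 and variance 402.5", {
  set.seed(7)
  x <- rnorm(69)   # continuous, tie-free a.s.
  rk <- rank_auxiliary(x)
  expect_equal(mean(rk), 35)
  expect_equal(var(rk), 402.5)          # N(N+1)/12 identity
})

test_that("sampling_factor is 1/n - 1/N with design validation", {
  expect_equal(sampling_factor(69, 15), 1 / 15 - 1 / 69)
  expect_equal(sampling_factor(69, 15), 0.0521739, tolerance = 1e-6)
  expect_equal(sampling_factor(100, 10), 0.09)
  expect_lt(sampling_factor(5000, 4999), 1e-7)   # census limit
  expect_error(sampling_factor(10, 10), "invalid design")
  expect_error(sampling_factor(10, 12), "invalid design")
  expect_error(sampling_factor(10, 1), "invalid design")
})

test_that("central_moment and moment_ratio agree with brute-force loops", {
  pop <- toy_population(50)
  for (rst in list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2), c(4, 0, 0),
                   c(0, 4, 0), c(0, 0, 4), c(2, 2, 0), c(2, 0, 2),
                   c(0, 2, 2), c(1, 1, 1), c(3, 1, 0))) {
    expect_equal(
      central_moment(pop, rst[1], rst[2], rst[3]),
      bf_central_moment(pop$y, pop$x, pop$rank_x, rst[1], rst[2], rst[3]),
      tolerance = 1e-12)
    expect_equal(
      moment_ratio(pop, rst[1], rst[2], rst[3]),
      bf_moment_ratio(pop$y, pop$x, pop$rank_x, rst[1], rst[2], rst[3]),
      tolerance = 1e-12)
  }
  # second moments are the divisor-(N-1) variances
  expect_equal(central_moment(pop, 2, 0, 0), var(pop$y))
  expect_equal(central_moment(pop, 0, 2, 0), var(pop$x))
  expect_error(central_moment(pop, 0, 0, 0), "r \\+ s \\+ t")
})

test_that("moment ratios are self-normalizing and catch degeneracy", {
  pop <- toy_population(40)
  expect_equal(moment_ratio(pop, 2, 0, 0), 1)
  expect_equal(moment_ratio(pop, 0, 2, 0), 1)
  expect_equal(moment_ratio(pop, 0, 0, 2), 1)
  # kurtosis ratio of a near-normal y is near 3
  set.seed(123)
  gauss <- population_frame(rnorm(20000), rnorm(20000))
  expect_equal(moment_ratio(gauss, 4, 0, 0), 3, tolerance = 0.05)
  # constant auxiliary variable -> degenerate second moment
  const_x <- population_frame(c(1, 2, 3, 4), rep(5, 4))
  expect_error(moment_ratio(const_x, 4, 0, 0), "degenerate")
})

test_that("lambda* ratios are invariant to separate affine rescalings", {
  pop <- toy_population(35, seed = 9)
  m1 <- summarize_population(pop)
  pop2 <- population_frame(-3 * pop$y + 100, 0.01 * pop$x - 2)
  m2 <- summarize_population(pop2)
  # all six ratios have even exponents, so sign flips cancel too
  for (f in c("lam400s", "lam040s", "lam004s", "lam220s", "lam202s",
              "lam022s"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-10, label = f)
})

test_that("summarize_population matches the brute-force oracle field by field", {
  pop <- toy_population(30, seed = 11, ties = TRUE)
  m <- summarize_population(pop, design_spec(30, 8))
  bf <- bf_moment_set(pop$y, pop$x)
  for (f in names(bf))
    expect_equal(m[[f]], bf[[f]], tolerance = 1e-12, label = f)
  # starred fields are the unstarred ratios minus one
  for (f in c("lam400", "lam040", "lam004", "lam220", "lam202", "lam022"))
    expect_equal(m[[paste0(f, "s")]], m[[f]] - 1, label = f)
  expect_error(summarize_population(pop, design_spec(31, 8)), "does not match")
})

test_that("perfect rank correlation when x is already a permutation of 1..N", {
  set.seed(2)
  x <- sample(1:40)
  pop <- population_frame(rnorm(40), x)
  m <- summarize_population(pop)
  expect_equal(m$rho_xrx, 1)
})

test_that("rank variance identity N(N+1)/12 holds at N = 69 and N = 5000", {
  for (N in c(69L, 5000L)) {
    set.seed(N)
    pop <- population_frame(rnorm(N), rnorm(N))
    m <- summarize_population(pop)
    expect_identical(m$Srx2, N * (N + 1) / 12)
  }
})

test_that("constructors validate their inputs", {
  expect_error(population_frame(1:2, 1:2), "at least 3")
  expect_error(population_frame(c(1, NA, 3), 1:3), "missing")
  expect_error(population_frame(1:4, 1:3), "same length")
  expect_error(moment_set(-1, 1, 1, 1, 1, 1, 1, 1, 1), "positive")
  expect_error(moment_set(1, 1, 1, NA, 1, 1, 1, 1, 1), "finite")
  d <- design_spec(69, 15)
  expect_identical(d$N, 69L)
  expect_equal(d$lam, 1 / 15 - 1 / 69)
})
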