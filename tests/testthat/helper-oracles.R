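# Independent oracles: deliberately written with explicit loops / naive
# formulas so they share no code path with the implementation.

# average-rank by counting, not base::rank
bf_rank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (1 + sum(x == xi)) / 2, numeric(1))
}

# mixed central moment by explicit loop
bf_central_moment <- function(y, x, rk, r, s, t) {
  my <- sum(y) / length(y); mx <- sum(x) / length(x); mr <- sum(rk) / length(rk)
  acc <- 0
  for (i in seq_along(y))
    acc <- acc + (y[i] - my)^r * (x[i] - mx)^s * (rk[i] - mr)^t
  acc / (length(y) - 1)
}

bf_moment_ratio <- function(y, x, rk, r, s, t) {
  bf_central_moment(y, x, rk, r, s, t) /
    (bf_central_moment(y, x, rk, 2, 0, 0)^(r / 2) *
       bf_central_moment(y, x, rk, 0, 2, 0)^(s / 2) *
       bf_central_moment(y, x, rk, 0, 0, 2)^(t / 2))
}

# every moment_set field, brute force
bf_moment_set <- function(y, x) {
  rk <- bf_rank(x)
  lam <- function(r, s, t) bf_moment_ratio(y, x, rk, r, s, t) - 1
  pearson <- function(a, b) {
    ma <- mean(a); mb <- mean(b)
    sum((a - ma) * (b - mb)) /
      sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }
  list(Sy2 = bf_central_moment(y, x, rk, 2, 0, 0),
       Sx2 = bf_central_moment(y, x, rk, 0, 2, 0),
       Srx2 = bf_central_moment(y, x, rk, 0, 0, 2),
       mean_y = mean(y), mean_x = mean(x), mean_rx = mean(rk),
       rho_yx = pearson(y, x), rho_yrx = pearson(y, rk),
       rho_xrx = pearson(x, rk),
       lam400s = lam(4, 0, 0), lam040s = lam(0, 4, 0),
       lam004s = lam(0, 0, 4), lam220s = lam(2, 2, 0),
       lam202s = lam(2, 0, 2), lam022s = lam(0, 2, 2))
}

# all SRSWOR samples of size n from a population frame
enumerate_samples <- function(pop, n) {
  idx <- utils::combn(pop$N, n, simplify = FALSE)
  lapply(idx, function(i) sample_frame(pop$y[i], pop$x[i], pop$rank_x[i]))
}

# zooming grid search: minimizes f over a box, re-centering on the best
# grid point (walking while the optimum sits on the box boundary, shrinking
# once it is interior). Independent of the linear-solve minimizer.
grid_search_min <- function(f, lower, upper, pts = 9L, iters = 80L) {
  k <- length(lower)
  centre <- (lower + upper) / 2
  width <- upper - lower
  best <- list(w = centre, value = f(centre))
  for (it in seq_len(iters)) {
    grids <- lapply(seq_len(k), function(j)
      seq(centre[j] - width[j] / 2, centre[j] + width[j] / 2, length.out = pts))
    pts_mat <- as.matrix(expand.grid(grids))
    vals <- apply(pts_mat, 1L, f)
    i <- which.min(vals)
    if (vals[i] < best$value) best <- list(w = pts_mat[i, ], value = vals[i])
    on_edge <- any(pts_mat[i, ] <= centre - width / 2 + 1e-12 * abs(width) |
                     pts_mat[i, ] >= centre + width / 2 - 1e-12 * abs(width))
    centre <- pts_mat[i, ]
    if (!on_edge) width <- width * 0.35
  }
  best
}

fixture_pair <- function() {
  list(population1 = table1_fixture("population1"),
       population2 = table1_fixture("population2"))
}

# a reproducible raw population for oracle comparisons
toy_population <- function(N = 50L, seed = 42L, ties = FALSE) {
  set.seed(seed)
  x <- stats::rnorm(N, 10, 3)
  if (ties) x <- round(x)
  y <- 2 * x + stats::rnorm(N, 0, 2)
  population_frame(y, x)
}
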