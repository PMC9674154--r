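#' Rank the auxiliary variable
#'
#' Computes ranks of the auxiliary variable on the 1..N scale. Ties receive
#' their average rank, so the sum of the returned ranks is always
#' \eqn{N(N+1)/2} and, for tie-free data, their variance (divisor \eqn{N-1})
#' is exactly \eqn{N(N+1)/12}.
#'
#' @param x Numeric vector of auxiliary values (length \eqn{\ge} 1, no NA).
#' @return Numeric vector of ranks, same length as `x`.
#' @examples
#' rank_auxiliary(c(5, 1, 3))   # 3 1 2
#' rank_auxiliary(c(2, 2, 7))   # 1.5 1.5 3
#' @export
rank_auxiliary <- function(x) {
  if (length(x) == 0L)
    stop("degenerate population: auxiliary vector is empty")
  if (anyNA(x))
    stop("missing values in auxiliary variable are not supported")
  if (!is.numeric(x))
    stop("auxiliary variable must be numeric")
  rank(x, ties.method = "average")
}

#' Sampling factor for SRSWOR
#'
#' The first-order design factor \eqn{\lambda = 1/n - 1/N} that multiplies
#' every approximate variance and MSE under simple random sampling without
#' replacement.
#'
#' @param N Population size (integer, \eqn{N > n}).
#' @param n Sample size (integer, \eqn{2 \le n < N}).
#' @return Positive scalar \eqn{1/n - 1/N}.
#' @examples
#' sampling_factor(69, 15)   # 0.05217391
#' @export
sampling_factor <- function(N, n) {
  if (!is.numeric(N) || !is.numeric(n) || length(N) != 1L || length(n) != 1L)
    stop("N and n must be scalars")
  if (n < 2)
    stop("invalid design: sample size n must be at least 2")
  if (n >= N)
    stop("invalid design: sample size n must be smaller than population size N")
  1 / n - 1 / N
}

#' Sampling design under SRSWOR
#'
#' @param N Population size.
#' @param n Sample size, \eqn{2 \le n < N}.
#' @return An object of class `design_spec` with fields `N`, `n` and the
#'   sampling factor `lam`.
#' @export
design_spec <- function(N, n) {
  lam <- sampling_factor(N, n)
  structure(list(N = as.integer(N), n = as.integer(n), lam = lam),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("SRSWOR design: N = %d, n = %d, lam = %.7g\n", x$N, x$n, x$lam))
  invisible(x)
}

#' Population frame
#'
#' Per-unit study and auxiliary values for all N population units, with the
#' ranks of the auxiliary variable computed once on the full population.
#'
#' @param y Numeric vector, study variable.
#' @param x Numeric vector, auxiliary variable (same length as `y`).
#' @return An object of class `population_frame` with fields `y`, `x`,
#'   `rank_x` and `N`.
#' @export
population_frame <- function(y, x) {
  if (!is.numeric(y) || !is.numeric(x))
    stop("y and x must be numeric vectors")
  if (length(y) != length(x))
    stop("y and x must have the same length")
  if (anyNA(y) || anyNA(x))
    stop("missing values are not supported; remove or impute them first")
  N <- length(y)
  if (N < 3L)
    stop("population must contain at least 3 units")
  structure(list(y = as.numeric(y), x = as.numeric(x),
                 rank_x = rank_auxiliary(x), N = N),
            class = "population_frame")
}

#' @export
print.population_frame <- function(x, ...) {
  cat(sprintf("population_frame: N = %d units (y, x, rank_x)\n", x$N))
  invisible(x)
}

#' Mixed central moment of a population
#'
#' \eqn{\upsilon_{rst} = \sum_i (y_i-\bar Y)^r (x_i-\bar X)^s
#' (r_{xi}-\bar R_x)^t / (N-1)}. In particular \eqn{\upsilon_{200} = S_y^2},
#' \eqn{\upsilon_{020} = S_x^2}, \eqn{\upsilon_{002} = S_{rx}^2}.
#'
#' @param pop A [population_frame()].
#' @param r,s,t Non-negative integer exponents, \eqn{r+s+t \ge 1}.
#' @return Scalar moment.
#' @export
central_moment <- function(pop, r, s, t) {
  stopifnot(inherits(pop, "population_frame"))
  if (r < 0 || s < 0 || t < 0 || r + s + t < 1)
    stop("exponents must be non-negative with r + s + t >= 1")
  if (pop$N < 2L)
    stop("central moment undefined for N < 2 (zero divisor)")
  dy <- pop$y - mean(pop$y)
  dx <- pop$x - mean(pop$x)
  dr <- pop$rank_x - mean(pop$rank_x)
  sum(dy^r * dx^s * dr^t) / (pop$N - 1)
}

#' Scale-free moment ratio
#'
#' \eqn{\lambda_{rst} = \upsilon_{rst} / (\upsilon_{200}^{r/2}
#' \upsilon_{020}^{s/2} \upsilon_{002}^{t/2})}; invariant under separate
#' affine rescaling of each variable. \eqn{\lambda_{400}} is the kurtosis
#' ratio of y.
#'
#' @inheritParams central_moment
#' @return Scalar ratio.
#' @export
moment_ratio <- function(pop, r, s, t) {
  v200 <- central_moment(pop, 2, 0, 0)
  v020 <- central_moment(pop, 0, 2, 0)
  v002 <- central_moment(pop, 0, 0, 2)
  if (v200 <= 0 || v020 <= 0 || v002 <= 0)
    stop("degenerate variable: a second moment is zero")
  central_moment(pop, r, s, t) / (v200^(r / 2) * v020^(s / 2) * v002^(t / 2))
}

#' Population moment set
#'
#' Container for every population parameter the closed-form theory needs:
#' the three variances, means, product-moment correlations, and the grid of
#' centred moment ratios \eqn{\lambda^*_{rst} = \lambda_{rst} - 1}.
#' Can be filled directly from printed summary parameters (no raw data
#' needed) or computed from a [population_frame()] via
#' [summarize_population()].
#'
#' @param Sy2,Sx2,Srx2 Population variances (divisor \eqn{N-1}) of the study
#'   variable, auxiliary variable and auxiliary ranks.
#' @param lam400s,lam040s,lam004s,lam220s,lam202s,lam022s Centred moment
#'   ratios \eqn{\lambda^*_{rst}}.
#' @param rho_yx,rho_yrx,rho_xrx Optional product-moment correlations.
#' @param mean_y,mean_x,mean_rx Optional means.
#' @param N Optional population size the parameters refer to.
#' @return An object of class `moment_set`. Unstarred ratios (`lam400`, ...)
#'   and `rho_star` \eqn{= \lambda^*_{220}/\sqrt{\lambda^*_{400}
#'   \lambda^*_{040}}} are derived fields.
#' @export
moment_set <- function(Sy2, Sx2, Srx2,
                       lam400s, lam040s, lam004s,
                       lam220s, lam202s, lam022s,
                       rho_yx = NA_real_, rho_yrx = NA_real_,
                       rho_xrx = NA_real_,
                       mean_y = NA_real_, mean_x = NA_real_,
                       mean_rx = NA_real_, N = NA_integer_) {
  vals <- c(Sy2 = Sy2, Sx2 = Sx2, Srx2 = Srx2,
            lam400s = lam400s, lam040s = lam040s, lam004s = lam004s,
            lam220s = lam220s, lam202s = lam202s, lam022s = lam022s)
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("all variances and starred moment ratios must be finite")
  if (Sy2 <= 0 || Sx2 <= 0 || Srx2 <= 0)
    stop("variances must be strictly positive")
  m <- list(Sy2 = Sy2, Sx2 = Sx2, Srx2 = Srx2,
            mean_y = mean_y, mean_x = mean_x, mean_rx = mean_rx,
            rho_yx = rho_yx, rho_yrx = rho_yrx, rho_xrx = rho_xrx,
            lam400s = lam400s, lam040s = lam040s, lam004s = lam004s,
            lam220s = lam220s, lam202s = lam202s, lam022s = lam022s,
            lam400 = lam400s + 1, lam040 = lam040s + 1, lam004 = lam004s + 1,
            lam220 = lam220s + 1, lam202 = lam202s + 1, lam022 = lam022s + 1,
            rho_star = lam220s / sqrt(lam400s * lam040s),
            N = N)
  structure(m, class = "moment_set")
}

#' @export
print.moment_set <- function(x, ...) {
  cat("moment_set\n")
  cat(sprintf("  Sy2 = %.7g  Sx2 = %.7g  Srx2 = %.7g\n", x$Sy2, x$Sx2, x$Srx2))
  cat(sprintf("  lam*400 = %.7g  lam*040 = %.7g  lam*004 = %.7g\n",
              x$lam400s, x$lam040s, x$lam004s))
  cat(sprintf("  lam*220 = %.7g  lam*202 = %.7g  lam*022 = %.7g\n",
              x$lam220s, x$lam202s, x$lam022s))
  cat(sprintf("  rho* = %.7g\n", x$rho_star))
  invisible(x)
}

#' Summarize a population frame into a moment set
#'
#' Computes every [moment_set()] field from raw per-unit data: variances
#' (divisor \eqn{N-1}), means, correlations and the
#' \eqn{\lambda^*_{rst}} grid.
#'
#' @param pop A [population_frame()].
#' @param design Optional [design_spec()]; when supplied its `N` must match
#'   the frame.
#' @return A `moment_set`.
#' @export
summarize_population <- function(pop, design = NULL) {
  stopifnot(inherits(pop, "population_frame"))
  if (!is.null(design)) {
    stopifnot(inherits(design, "design_spec"))
    if (design$N != pop$N)
      stop("design N does not match population size")
  }
  lam_rs <- function(r, s, t) moment_ratio(pop, r, s, t) - 1
  moment_set(
    Sy2  = central_moment(pop, 2, 0, 0),
    Sx2  = central_moment(pop, 0, 2, 0),
    Srx2 = central_moment(pop, 0, 0, 2),
    lam400s = lam_rs(4, 0, 0), lam040s = lam_rs(0, 4, 0),
    lam004s = lam_rs(0, 0, 4), lam220s = lam_rs(2, 2, 0),
    lam202s = lam_rs(2, 0, 2), lam022s = lam_rs(0, 2, 2),
    rho_yx  = stats::cor(pop$y, pop$x),
    rho_yrx = stats::cor(pop$y, pop$rank_x),
    rho_xrx = stats::cor(pop$x, pop$rank_x),
    mean_y = mean(pop$y), mean_x = mean(pop$x), mean_rx = mean(pop$rank_x),
    N = pop$N)
}
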