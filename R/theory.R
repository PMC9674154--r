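# First-order (Taylor) bias/MSE/PRE theory for all eight estimators.
#
# Everything is expressed through the centred moment ratios lam*rst of the
# error terms xi0 = (sy2-Sy2)/Sy2, xi1 = (sx2-Sx2)/Sx2, xi2 = (srx2-Srx2)/Srx2:
#   E(xi_i) = 0, E(xi0^2) = lam*400*lam, E(xi1^2) = lam*040*lam, ...
# with lam = 1/n - 1/N. Starred cross-moments are used throughout (the one
# unstarred E(xi1 xi2) printing in the source derivation is a typo).

.theory_result <- function(id, bias, mse, m, d, coefficients = NULL,
                           flags = character()) {
  var0 <- d$lam * m$Sy2^2 * m$lam400s
  pre <- if (is.finite(mse) && mse > 0) 100 * var0 / mse else NA_real_
  if (!is.na(mse) && mse <= 0)
    flags <- union(flags, "nonpositive_mse")
  structure(list(estimator_id = id, bias = bias, mse = mse, pre = pre,
                 coefficients = coefficients, flags = flags),
            class = "theory_result")
}

#' @export
print.theory_result <- function(x, ...) {
  cat(sprintf("%-12s bias = %s  MSE = %s  PRE = %s\n", x$estimator_id,
              formatC(x$bias, digits = 7, format = "g"),
              formatC(x$mse, digits = 7, format = "g"),
              formatC(x$pre, digits = 7, format = "g")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Percentage relative efficiency
#'
#' \eqn{100 \cdot \mathrm{Var}(\hat Y_0) / \mathrm{MSE}}; values above 100
#' indicate improvement over the usual estimator.
#'
#' @param mse Candidate MSE (> 0).
#' @param var0 Variance of the usual estimator (> 0).
#' @export
pre_of <- function(mse, var0) {
  if (!is.finite(mse) || mse <= 0)
    stop("PRE undefined: MSE must be finite and strictly positive")
  if (!is.finite(var0) || var0 <= 0)
    stop("PRE undefined: Var of the usual estimator must be positive")
  100 * var0 / mse
}

#' First-order variance of the usual estimator
#'
#' \eqn{\mathrm{Var}(\hat Y_0) = \lambda S_y^4 \lambda^*_{400}}.
#'
#' @param m A [moment_set()].
#' @param d A [design_spec()].
#' @return A `theory_result` (PRE is exactly 100).
#' @export
var_usual <- function(m, d) {
  mse <- d$lam * m$Sy2^2 * m$lam400s
  .theory_result("usual", bias = 0, mse = mse, m = m, d = d)
}

#' First-order MSE of the ratio estimator
#'
#' MSE \eqn{= \lambda S_y^4 (\lambda^*_{400} + \lambda^*_{040} -
#' 2\lambda^*_{220})}; bias \eqn{= \lambda S_y^2 (\lambda^*_{040} -
#' \lambda^*_{220})}.
#'
#' @inheritParams var_usual
#' @export
mse_ratio <- function(m, d) {
  Sy4 <- m$Sy2^2
  mse <- d$lam * Sy4 * (m$lam400s + m$lam040s - 2 * m$lam220s)
  bias <- d$lam * m$Sy2 * (m$lam040s - m$lam220s)
  .theory_result("ratio", bias, mse, m, d)
}

#' Minimum variance of the difference estimator
#'
#' \eqn{\lambda S_y^4 \lambda^*_{400}(1 - \rho^2)} with \eqn{\rho =
#' \lambda^*_{220}/\sqrt{\lambda^*_{400}\lambda^*_{040}}}; attained at
#' \eqn{\Psi_{11} = S_y^2\lambda^*_{220} / (S_x^2\lambda^*_{040})}.
#'
#' @inheritParams var_usual
#' @export
var_difference <- function(m, d) {
  if (m$lam400s <= 0 || m$lam040s <= 0)
    stop("lam*400 and lam*040 must be positive")
  rho <- m$lam220s / sqrt(m$lam400s * m$lam040s)
  mse <- d$lam * m$Sy2^2 * m$lam400s * (1 - rho^2)
  psi11 <- m$Sy2 * m$lam220s / (m$Sx2 * m$lam040s)
  .theory_result("difference", bias = 0, mse, m, d,
                 coefficients = coefficient_set(psi11 = psi11,
                                                provenance = "closed_form_printed"))
}

#' First-order minimum MSE of the difference-type estimator
#'
#' With \eqn{A = \lambda^*_{400}\lambda^*_{040} - \lambda^{*2}_{220}},
#' MSE \eqn{= \lambda S_y^4 A / (\lambda A + \lambda^*_{040})}, attained at
#' the printed \eqn{w_1, w_2}.
#'
#' @inheritParams var_usual
#' @export
mse_rao <- function(m, d) {
  A <- m$lam400s * m$lam040s - m$lam220s^2
  den <- d$lam * A + m$lam040s
  if (den <= 0) stop("degenerate denominator in difference-type MSE")
  mse <- d$lam * m$Sy2^2 * A / den
  w1 <- m$lam040s / den
  w2 <- m$Sy2 * m$lam220s / (m$Sx2 * den)
  bias <- m$Sy2 * (w1 - 1)
  .theory_result("rao", bias, mse, m, d,
                 coefficient_set(w = c(w1 = w1, w2 = w2),
                                 provenance = "closed_form_printed"))
}

#' First-order MSE of the exponential-ratio estimator
#'
#' MSE \eqn{= \lambda S_y^4(\lambda^*_{400} + \lambda^*_{040}/4 -
#' \lambda^*_{220})}; bias \eqn{= \lambda S_y^2 (3\lambda^*_{040}/8 -
#' \lambda^*_{220}/2)}.
#'
#' @inheritParams var_usual
#' @export
mse_exp_ratio <- function(m, d) {
  Sy4 <- m$Sy2^2
  mse <- d$lam * Sy4 * (m$lam400s + m$lam040s / 4 - m$lam220s)
  bias <- d$lam * m$Sy2 * (3 / 8 * m$lam040s - m$lam220s / 2)
  .theory_result("exp_ratio", bias, mse, m, d)
}

#' First-order minimum MSE of the regression-exponential estimator
#'
#' With \eqn{A = \lambda^*_{400}\lambda^*_{040} - \lambda^{*2}_{220}}:
#' \deqn{\lambda S_y^4 [64A - \lambda\lambda^{*3}_{040} -
#' 16\lambda\lambda^*_{040}A] / (64[\lambda A + \lambda^*_{040}]).}
#' The \eqn{S_y^4} prefactor is used (the published display prints
#' \eqn{S_y^2}): it is the only dimensionally consistent choice and the one
#' the published MSE tables are computed with.
#'
#' @inheritParams var_usual
#' @export
mse_grover_kaur <- function(m, d) {
  lam <- d$lam
  A <- m$lam400s * m$lam040s - m$lam220s^2
  den <- 64 * (lam * A + m$lam040s)
  if (den <= 0) stop("degenerate denominator in regression-exponential MSE")
  mse <- lam * m$Sy2^2 *
    (64 * A - lam * m$lam040s^3 - 16 * lam * m$lam040s * A) / den
  w3 <- (8 * m$lam040s - lam * m$lam040s^2) / (8 * (lam * A + m$lam040s))
  w4 <- m$Sy2 * (lam * m$lam040s^2 - lam * m$lam040s * m$lam220s +
                   8 * m$lam220s - 4 * (m$lam040s - lam * A)) /
    (8 * m$Sx2 * (lam * A + m$lam040s))
  coef <- coefficient_set(w = c(w3 = w3, w4 = w4),
                          provenance = "closed_form_printed")
  bias <- -m$Sy2 + w3 * m$Sy2 *
    (1 + lam * (3 / 8 * m$lam040s - m$lam220s / 2)) +
    w4 * m$Sx2 * lam * m$lam040s / 2
  .theory_result("grover_kaur", bias, mse, m, d, coef)
}

#' Dual-auxiliary efficiency scalar
#'
#' \deqn{\Gamma^* = \frac{2\lambda^*_{220}\lambda^*_{202}\lambda^*_{022} -
#' \lambda^*_{040}\lambda^{*2}_{202} - \lambda^*_{004}\lambda^{*2}_{220}}
#' {\lambda^*_{400}(\lambda^*_{040}\lambda^*_{004} - \lambda^{*2}_{022})}}
#' The \eqn{\lambda^{*2}_{022}} denominator is used (one published display
#' prints \eqn{\lambda^{*2}_{220}}): it is the reading that reproduces the
#' published minimum-MSE table for the dual-auxiliary estimator on both
#' bench populations.
#'
#' @param m A [moment_set()].
#' @export
gamma_star <- function(m) {
  den <- m$lam400s * (m$lam040s * m$lam004s - m$lam022s^2)
  if (!is.finite(den) || den == 0)
    stop("singular denominator in Gamma*: lam*040 lam*004 = lam*022^2")
  (2 * m$lam220s * m$lam202s * m$lam022s -
     m$lam040s * m$lam202s^2 - m$lam004s * m$lam220s^2) / den
}

#' First-order minimum MSE of the dual-auxiliary regression-exponential
#' estimator
#'
#' With \eqn{G = \Gamma^*}:
#' \deqn{\lambda S_y^4 [64(G+1) - \lambda\lambda^{*2}_{040}/\lambda^*_{400}
#' - 16\lambda\lambda^*_{040}(G+1)] / (64[1/\lambda^*_{400} + \lambda
#' (G+1)]).}
#' \eqn{S_y^4} prefactor and division in the middle term, both validated
#' against the published MSE tables.
#'
#' @inheritParams var_usual
#' @export
mse_ahmad <- function(m, d) {
  lam <- d$lam
  G <- gamma_star(m)
  den <- 64 * (1 / m$lam400s + lam * (G + 1))
  if (den <= 0) stop("degenerate denominator in dual-auxiliary MSE")
  mse <- lam * m$Sy2^2 *
    (64 * (G + 1) - lam * m$lam040s^2 / m$lam400s -
       16 * lam * m$lam040s * (G + 1)) / den
  cden <- 8 * (1 / m$lam400s + lam * (G + 1))
  w5 <- (8 - lam * m$lam040s) / (m$lam400s * cden)
  D <- m$lam040s * m$lam004s - m$lam022s^2
  w6 <- m$Sy2 * (lam * m$lam040s * (m$lam040s * m$lam004s - m$lam220s^2) +
                   (m$lam004s * m$lam220s - m$lam202s * m$lam022s) *
                     (8 - lam * m$lam040s) +
                   4 * m$lam400s * D * (-1 / m$lam400s + lam * (G + 1))) /
    (8 * m$Sx2 * m$lam400s * (m$lam040s * m$lam004s - m$lam220s^2) *
       (1 / m$lam400s + lam * (G + 1)))
  w7 <- m$Sy2 * (8 - lam * m$lam040s) *
    (m$lam220s * m$lam022s - m$lam040s * m$lam202s) /
    (8 * m$Srx2 * m$lam400s * (m$lam040s * m$lam004s - m$lam220s^2) *
       (1 / m$lam400s + lam * (G + 1)))
  coef <- coefficient_set(w = c(w5 = w5, w6 = w6, w7 = w7),
                          provenance = "closed_form_printed")
  bias <- -m$Sy2 + w5 * m$Sy2 *
    (1 + lam * (3 / 8 * m$lam040s - m$lam220s / 2)) +
    lam / 2 * (w6 * m$Sx2 * m$lam040s + w7 * m$Srx2 * m$lam022s)
  .theory_result("ahmad", bias, mse, m, d, coef)
}

#' Auxiliary scalars of the proposed estimator's closed forms
#'
#' The scalars entering the printed optimum coefficients and minimum MSE of
#' the proposed estimator, all sharing the denominator
#' \eqn{\lambda^*_{040}\lambda^*_{004} - \lambda^{*2}_{022}} (times
#' \eqn{\lambda^*_{400}} where printed), plus the efficiency-comparison
#' threshold \eqn{M} (the printed minimum MSE divided by
#' \eqn{\lambda S_y^4}).
#'
#' @inheritParams var_usual
#' @return List with `gamma_star`, `y1`, `n1`, `y11`, `n11`, `m_threshold`.
#' @export
aux_scalars <- function(m, d) {
  D <- m$lam040s * m$lam004s - m$lam022s^2
  if (!is.finite(D) || D == 0 || m$lam400s == 0)
    stop("singular shared denominator in auxiliary scalars")
  G <- gamma_star(m)
  y1 <- (m$lam202s^2 * m$lam040s^2 + m$lam004s^2 * m$lam220s^2 -
           2 * m$lam040s * m$lam004s * m$lam220s * m$lam202s) /
    (m$lam400s * D)
  n1 <- m$lam040s * m$lam004s *
    (m$lam040s + m$lam004s - 2 * m$lam022s) / D
  y11 <- m$lam004s * m$lam220s * (m$lam040s - m$lam022s) / (m$lam400s * D)
  n11 <- m$lam040s * m$lam202s * (m$lam004s - m$lam022s) / (m$lam400s * D)
  num <- (y1 - n1) * d$lam + (G + 1)
  den <- d$lam * (4 * ((G + 1) + (y11 + n11)) - n1 * m$lam400s) +
    4 * m$lam400s
  if (den == 0) stop("zero denominator in efficiency threshold M")
  list(gamma_star = G, y1 = y1, n1 = n1, y11 = y11, n11 = n11,
       m_threshold = num / den)
}

# --- quadratic MSE surfaces -------------------------------------------------
#
# Each coefficient-bearing estimator has a first-order MSE that is an exact
# quadratic in its coefficient vector w:
#   MSE(w) = c0 + b'w + (1/2) w'Qw.
# The Q, b below are hand-assembled from the Taylor expansions of the
# estimator errors; minimizing the quadratic exactly (3x3 or 2x2 solve)
# gives the estimator's attainable first-order minimum and is the package's
# authoritative optimum, cross-checked in the tests against an independent
# zooming grid-search oracle and against the printed closed forms.

.quad_rao <- function(m, d) {
  Sy4 <- m$Sy2^2; Sx4 <- m$Sx2^2; lam <- d$lam
  Q <- matrix(c(2 * Sy4 * (1 + lam * m$lam400s),
                -2 * lam * m$Sy2 * m$Sx2 * m$lam220s,
                -2 * lam * m$Sy2 * m$Sx2 * m$lam220s,
                2 * lam * Sx4 * m$lam040s), 2, 2)
  list(Q = Q, b = c(-2 * Sy4, 0), c0 = Sy4, ids = c("w1", "w2"))
}

.quad_grover_kaur <- function(m, d) {
  Sy4 <- m$Sy2^2; Sx4 <- m$Sx2^2; lam <- d$lam
  q11 <- 2 * Sy4 * (1 + lam * (m$lam400s + m$lam040s - 2 * m$lam220s))
  q12 <- 2 * lam * m$Sy2 * m$Sx2 * (m$lam040s - m$lam220s)
  q22 <- 2 * lam * Sx4 * m$lam040s
  b <- c(-2 * Sy4 - lam * Sy4 * (3 / 4 * m$lam040s - m$lam220s),
         -lam * m$Sy2 * m$Sx2 * m$lam040s)
  list(Q = matrix(c(q11, q12, q12, q22), 2, 2), b = b, c0 = Sy4,
       ids = c("w3", "w4"))
}

.quad_ahmad <- function(m, d) {
  Sy4 <- m$Sy2^2; Sx4 <- m$Sx2^2; Srx4 <- m$Srx2^2; lam <- d$lam
  q11 <- 2 * Sy4 * (1 + lam * (m$lam400s + m$lam040s - 2 * m$lam220s))
  q12 <- 2 * lam * m$Sy2 * m$Sx2 * (m$lam040s - m$lam220s)
  q13 <- 2 * lam * m$Sy2 * m$Srx2 * (m$lam022s - m$lam202s)
  q22 <- 2 * lam * Sx4 * m$lam040s
  q23 <- 2 * lam * m$Sx2 * m$Srx2 * m$lam022s
  q33 <- 2 * lam * Srx4 * m$lam004s
  Q <- matrix(c(q11, q12, q13, q12, q22, q23, q13, q23, q33), 3, 3)
  b <- c(-2 * Sy4 - lam * Sy4 * (3 / 4 * m$lam040s - m$lam220s),
         -lam * m$Sy2 * m$Sx2 * m$lam040s,
         -lam * m$Sy2 * m$Srx2 * m$lam022s)
  list(Q = Q, b = b, c0 = Sy4, ids = c("w5", "w6", "w7"))
}

.quad_proposed <- function(m, d) {
  Sy4 <- m$Sy2^2; Sx4 <- m$Sx2^2; Srx4 <- m$Srx2^2; lam <- d$lam
  q11 <- 2 * Sy4 * (1 + lam * m$lam400s)
  q12 <- lam * m$Sy2 * m$Sx2 * (m$lam040s - 2 * m$lam220s)
  q13 <- lam * m$Sy2 * m$Srx2 * (m$lam004s - 2 * m$lam202s)
  q22 <- 2 * lam * Sx4 * m$lam040s
  q23 <- 2 * lam * m$Sx2 * m$Srx2 * m$lam022s
  q33 <- 2 * lam * Srx4 * m$lam004s
  Q <- matrix(c(q11, q12, q13, q12, q22, q23, q13, q23, q33), 3, 3)
  b <- c(-2 * Sy4,
         -lam * m$Sy2 * m$Sx2 * m$lam040s,
         -lam * m$Sy2 * m$Srx2 * m$lam004s)
  list(Q = Q, b = b, c0 = Sy4, ids = c("w8", "w9", "w10"))
}

# Evaluate a quadratic surface at coefficient vector w.
.quad_value <- function(quad, w) {
  quad$c0 + sum(quad$b * w) + 0.5 * drop(crossprod(w, quad$Q %*% w))
}

# Exact stationary point of the quadratic; errors on singular systems,
# flags non-positive-definite surfaces (stationary point not a minimum).
.quad_minimize <- function(quad) {
  Q <- quad$Q
  if (!is.finite(rcond(Q)) || rcond(Q) < .Machine$double.eps)
    stop("singular coefficient system (rcond = ",
         formatC(rcond(Q), digits = 3, format = "e"),
         "); first-order MSE surface has no unique stationary point")
  w <- solve(Q, -quad$b)
  pd <- all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values > 0)
  list(w = stats::setNames(w, quad$ids), value = .quad_value(quad, w),
       positive_definite = pd)
}

#' Exact first-order minimum MSE of the proposed estimator
#'
#' The first-order MSE of the proposed estimator is an exact quadratic in
#' \eqn{(w_8, w_9, w_{10})} (with the \eqn{S_x^2 S_{rx}^2} cross-product in
#' the final term, correcting a misprint, and including the
#' \eqn{(w_8-1)}-bias cross terms of the published expansion). This
#' operation minimizes it by solving the 3x3 stationarity system exactly;
#' it is the package's authoritative MSE for the proposed estimator. Note
#' that the bias cross terms break the sum-of-squares structure, so on some
#' parameter sets the algebraic minimum can be negative, signalling that the
#' first-order approximation has broken down there; such results carry a
#' `"nonpositive_mse"` flag and an undefined (NA) PRE.
#'
#' @inheritParams var_usual
#' @return A `theory_result` with `coefficients` of provenance
#'   `"exact_minimization"`.
#' @export
mse_proposed_exact <- function(m, d) {
  quad <- .quad_proposed(m, d)
  opt <- .quad_minimize(quad)
  flags <- character()
  if (!opt$positive_definite)
    flags <- "not_positive_definite"
  coef <- coefficient_set(w = opt$w, provenance = "exact_minimization")
  bias <- (opt$w[["w8"]] - 1) * m$Sy2 +
    d$lam / 2 * (opt$w[["w9"]] * m$Sx2 * m$lam040s +
                   opt$w[["w10"]] * m$Srx2 * m$lam004s)
  .theory_result("proposed", bias, opt$value, m, d, coef, flags)
}

#' Printed closed-form minimum MSE of the proposed estimator
#'
#' Evaluates the published closed-form minimum literally:
#' \deqn{\lambda S_y^4 [(\gamma_1 - \eta_1)\lambda + (\Gamma^*+1)] /
#' (\lambda[4\{(\Gamma^*+1) + (\gamma_{11}+\eta_{11})\} -
#' \eta_1\lambda^*_{400}] + 4\lambda^*_{400}).}
#' As printed this expression does not reproduce the published MSE table
#' for the proposed estimator and can be negative, so every result carries
#' the flag `"printed_formula_inconsistent"`; [mse_proposed_exact()] is the
#' authoritative replacement.
#'
#' @inheritParams var_usual
#' @export
mse_proposed_printed <- function(m, d) {
  a <- aux_scalars(m, d)
  mse <- d$lam * m$Sy2^2 * a$m_threshold
  .theory_result("proposed", bias = NA_real_, mse, m, d,
                 flags = "printed_formula_inconsistent")
}

#' Printed optimal coefficients of the proposed estimator
#'
#' Evaluates the published closed-form \eqn{w_8, w_9, w_{10}} literally
#' (provenance `"closed_form_printed"`), for documentation and comparison
#' against the exact minimizer of [mse_proposed_exact()].
#'
#' @inheritParams var_usual
#' @export
proposed_coefficients_printed <- function(m, d) {
  lam <- d$lam
  a <- aux_scalars(m, d)
  G <- a$gamma_star
  D <- m$lam040s * m$lam004s - m$lam022s^2
  den <- lam * (4 * ((G + 1) + (a$y11 + a$n11)) - a$n1 * m$lam400s) +
    4 * m$lam400s
  if (den == 0) stop("zero denominator in printed w8")
  w8 <- (lam * (a$n1 * m$lam400s - 2 * (a$y11 + a$n11)) - 4 * m$lam400s) /
    (lam * (4 * ((G + 1) + (a$y11 + a$n11)) - a$n11 * m$lam400s) +
       4 * m$lam400s)
  den9 <- m$Sx2 * m$lam400s * D * den
  if (den9 == 0) stop("zero denominator in printed w9")
  w9 <- m$Sy2 * (2 * lam * m$lam400s * m$lam004s *
                   (m$lam040s - m$lam022s) +
                   lam * m$lam040s * m$lam202s *
                     (m$lam004s - 2 * m$lam202s) +
                   lam * m$lam004s * m$lam220s *
                     (-m$lam004s + 2 * m$lam202s) +
                   4 * (m$lam004s * m$lam220s - m$lam202s * m$lam022s)) /
    den9
  den10 <- m$Srx2 * m$lam400s * D *
    (lam * (4 * ((G + 1) + (a$y11 + a$n11)) - a$n1 * m$lam400s) +
       a$n1 * m$lam400s)
  if (den10 == 0) stop("zero denominator in printed w10")
  w10 <- m$Sy2 * (2 * lam * m$lam400s * m$lam040s *
                    (m$lam004s - m$lam022s) +
                    lam * m$lam040s * m$lam202s *
                      (-m$lam040s + 2 * m$lam220s) +
                    lam * m$lam004s * m$lam220s *
                      (m$lam040s - 2 * m$lam220s) +
                    4 * (m$lam040s * m$lam202s - m$lam220s * m$lam022s)) /
    den10
  coefficient_set(w = c(w8 = w8, w9 = w9, w10 = w10),
                  provenance = "closed_form_printed")
}

#' Optimal coefficients for every coefficient-bearing estimator
#'
#' In `"exact"` mode each coefficient vector is the exact minimizer of the
#' estimator's first-order MSE quadratic (the evaluation convention used in
#' Monte-Carlo mode). In `"printed"` mode the published closed forms are
#' evaluated literally.
#'
#' @inheritParams var_usual
#' @param method `"exact"` or `"printed"`.
#' @return A [coefficient_set()] with `psi11` and `w1`...`w10`.
#' @export
optimal_coefficients <- function(m, d, method = c("exact", "printed")) {
  method <- match.arg(method)
  psi11 <- m$Sy2 * m$lam220s / (m$Sx2 * m$lam040s)
  if (method == "printed") {
    w <- c(mse_rao(m, d)$coefficients$w[c("w1", "w2")],
           mse_grover_kaur(m, d)$coefficients$w[c("w3", "w4")],
           mse_ahmad(m, d)$coefficients$w[c("w5", "w6", "w7")],
           proposed_coefficients_printed(m, d)$w[c("w8", "w9", "w10")])
    return(coefficient_set(psi11 = psi11, w = w,
                           provenance = "closed_form_printed"))
  }
  w <- c(.quad_minimize(.quad_rao(m, d))$w,
         .quad_minimize(.quad_grover_kaur(m, d))$w,
         .quad_minimize(.quad_ahmad(m, d))$w,
         .quad_minimize(.quad_proposed(m, d))$w)
  coefficient_set(psi11 = psi11, w = w, provenance = "exact_minimization")
}

#' Tabulated-scale bias entries
#'
#' Bias entries on the scale used by the published bias tables. Only the
#' ratio and exponential-ratio entries were verified to equal the tabulated
#' values; they are the theoretical biases multiplied by \eqn{S_y^2}
#' (\eqn{\lambda S_y^4(\lambda^*_{040}-\lambda^*_{220})} and
#' \eqn{\lambda S_y^4(3\lambda^*_{040}/8 - \lambda^*_{220}/2)}). All other
#' entries are reported from the bias formulas in natural \eqn{S_y^2} units
#' and carry a `"unit_mismatch"` attribute because the corresponding
#' tabulated values could not be reconciled with any stated formula.
#'
#' @inheritParams var_usual
#' @return Named numeric vector over estimator ids, with attribute
#'   `unit_mismatch` listing the non-verified entries.
#' @export
scaled_bias_table <- function(m, d) {
  tab <- c(
    usual       = 0,
    ratio       = d$lam * m$Sy2^2 * (m$lam040s - m$lam220s),
    difference  = 0,
    rao         = mse_rao(m, d)$bias,
    exp_ratio   = d$lam * m$Sy2^2 * (3 / 8 * m$lam040s - m$lam220s / 2),
    grover_kaur = mse_grover_kaur(m, d)$bias,
    ahmad       = mse_ahmad(m, d)$bias,
    proposed    = mse_proposed_exact(m, d)$bias
  )
  attr(tab, "unit_mismatch") <- c("rao", "grover_kaur", "ahmad", "proposed")
  tab
}

#' Full theory table for all eight estimators
#'
#' @inheritParams var_usual
#' @param proposed_mode `"exact"` (authoritative quadratic minimum) or
#'   `"printed"` (literal published closed form, flagged inconsistent).
#' @return A data.frame with columns `estimator`, `bias`, `mse`, `pre` and
#'   attribute `flags` (named list of per-estimator flags).
#' @export
theory_table <- function(m, d, proposed_mode = c("exact", "printed")) {
  proposed_mode <- match.arg(proposed_mode)
  res <- list(var_usual(m, d), mse_ratio(m, d), var_difference(m, d),
              mse_rao(m, d), mse_exp_ratio(m, d), mse_grover_kaur(m, d),
              mse_ahmad(m, d),
              if (proposed_mode == "exact") mse_proposed_exact(m, d)
              else mse_proposed_printed(m, d))
  out <- data.frame(
    estimator = vapply(res, `[[`, character(1), "estimator_id"),
    bias = vapply(res, `[[`, numeric(1), "bias"),
    mse = vapply(res, `[[`, numeric(1), "mse"),
    pre = vapply(res, `[[`, numeric(1), "pre"),
    stringsAsFactors = FALSE)
  flags <- lapply(res, `[[`, "flags")
  names(flags) <- out$estimator
  attr(out, "flags") <- flags
  out
}
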