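#' Sample frame
#'
#' A drawn SRSWOR sample: per-unit values plus the sample variances
#' (divisor \eqn{n-1}). `rank_x` carries the *population* ranks of the
#' sampled units, so `srx2` is the sample variance of the rank variable as
#' observed on the sample.
#'
#' @param y,x,rank_x Numeric vectors of length n.
#' @return Object of class `sample_frame` with fields `y`, `x`, `rank_x`,
#'   `n`, `sy2`, `sx2`, `srx2`.
#' @export
sample_frame <- function(y, x, rank_x) {
  n <- length(y)
  if (length(x) != n || length(rank_x) != n)
    stop("y, x and rank_x must have the same length")
  if (n < 2L)
    stop("sample must contain at least 2 units")
  if (anyNA(y) || anyNA(x) || anyNA(rank_x))
    stop("missing values are not supported")
  structure(list(y = as.numeric(y), x = as.numeric(x),
                 rank_x = as.numeric(rank_x), n = n,
                 sy2 = stats::var(y), sx2 = stats::var(x),
                 srx2 = stats::var(rank_x)),
            class = "sample_frame")
}

#' @export
print.sample_frame <- function(x, ...) {
  cat(sprintf("sample_frame: n = %d, sy2 = %.7g, sx2 = %.7g, srx2 = %.7g\n",
              x$n, x$sy2, x$sx2, x$srx2))
  invisible(x)
}

#' Estimator tuning coefficients
#'
#' Holds the difference-estimator coefficient `psi11` and the coefficients
#' `w1`...`w10` of the coefficient-bearing estimators, tagged with their
#' provenance: `"closed_form_printed"` (the published closed forms),
#' `"exact_minimization"` (exact minimizers of the first-order MSE
#' quadratics) or `"user_supplied"`.
#'
#' @param psi11 Difference-estimator coefficient.
#' @param w Named numeric vector or list with any of `w1`...`w10`.
#' @param provenance One of `"closed_form_printed"`, `"exact_minimization"`,
#'   `"user_supplied"`.
#' @return Object of class `coefficient_set`.
#' @export
coefficient_set <- function(psi11 = NA_real_, w = numeric(),
                            provenance = c("user_supplied",
                                           "closed_form_printed",
                                           "exact_minimization")) {
  provenance <- match.arg(provenance)
  full <- stats::setNames(rep(NA_real_, 10), paste0("w", 1:10))
  w <- unlist(w)
  if (length(w)) {
    if (is.null(names(w)) || !all(names(w) %in% names(full)))
      stop("coefficients must be named w1...w10")
    full[names(w)] <- w
  }
  structure(list(psi11 = psi11, w = full, provenance = provenance),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("coefficient_set (%s)\n", x$provenance))
  if (!is.na(x$psi11)) cat(sprintf("  psi11 = %.7g\n", x$psi11))
  w <- x$w[!is.na(x$w)]
  if (length(w))
    cat(" ", paste(sprintf("%s = %.7g", names(w), w), collapse = ", "), "\n")
  invisible(x)
}

# exponential damping factor exp{(S2 - s2)/(S2 + s2)}
.exp_damp <- function(S2, s2) {
  den <- S2 + s2
  if (den <= 0)
    stop("non-positive denominator in exponential damping factor")
  exp((S2 - s2) / den)
}

#' Usual (sample-variance) estimator
#'
#' @param s A [sample_frame()].
#' @return The sample variance \eqn{s_y^2}, design-unbiased for
#'   \eqn{S_y^2} under SRSWOR.
#' @export
est_usual <- function(s) {
  stopifnot(inherits(s, "sample_frame"))
  s$sy2
}

#' Ratio estimator
#'
#' \eqn{s_y^2 \, (S_x^2 / s_x^2)}: corrects the sample variance by the
#' known-to-observed auxiliary variance ratio.
#'
#' @param s A [sample_frame()].
#' @param Sx2 Known population variance of the auxiliary variable.
#' @export
est_ratio <- function(s, Sx2) {
  stopifnot(inherits(s, "sample_frame"))
  if (s$sx2 <= 0)
    stop("sample auxiliary variance is zero; ratio estimator undefined")
  s$sy2 * Sx2 / s$sx2
}

#' Difference (regression-type) estimator
#'
#' \eqn{s_y^2 + \Psi_{11}(S_x^2 - s_x^2)}.
#'
#' @inheritParams est_ratio
#' @param psi11 Regression coefficient.
#' @export
est_difference <- function(s, Sx2, psi11) {
  stopifnot(inherits(s, "sample_frame"))
  s$sy2 + psi11 * (Sx2 - s$sx2)
}

#' Difference-type estimator with shrinkage
#'
#' \eqn{w_1 s_y^2 + w_2 (S_x^2 - s_x^2)}.
#'
#' @inheritParams est_ratio
#' @param w1,w2 Coefficients.
#' @export
est_rao <- function(s, Sx2, w1, w2) {
  stopifnot(inherits(s, "sample_frame"))
  w1 * s$sy2 + w2 * (Sx2 - s$sx2)
}

#' Exponential-ratio estimator
#'
#' \eqn{s_y^2 \exp\{(S_x^2 - s_x^2)/(S_x^2 + s_x^2)\}}.
#'
#' @inheritParams est_ratio
#' @export
est_exp_ratio <- function(s, Sx2) {
  stopifnot(inherits(s, "sample_frame"))
  s$sy2 * .exp_damp(Sx2, s$sx2)
}

#' Regression-exponential estimator
#'
#' \eqn{[w_3 s_y^2 + w_4 (S_x^2 - s_x^2)]\exp\{(S_x^2 - s_x^2)/(S_x^2 +
#' s_x^2)\}}.
#'
#' @inheritParams est_ratio
#' @param w3,w4 Coefficients.
#' @export
est_grover_kaur <- function(s, Sx2, w3, w4) {
  stopifnot(inherits(s, "sample_frame"))
  (w3 * s$sy2 + w4 * (Sx2 - s$sx2)) * .exp_damp(Sx2, s$sx2)
}

#' Dual-auxiliary regression-exponential estimator
#'
#' \eqn{[w_5 s_y^2 + w_6 (S_x^2 - s_x^2) + w_7 (S_{rx}^2 - s_{rx}^2)]
#' \exp\{(S_x^2 - s_x^2)/(S_x^2 + s_x^2)\}}.
#'
#' @inheritParams est_ratio
#' @param Srx2 Known population variance of the auxiliary ranks.
#' @param w5,w6,w7 Coefficients.
#' @export
est_ahmad <- function(s, Sx2, Srx2, w5, w6, w7) {
  stopifnot(inherits(s, "sample_frame"))
  (w5 * s$sy2 + w6 * (Sx2 - s$sx2) + w7 * (Srx2 - s$srx2)) *
    .exp_damp(Sx2, s$sx2)
}

#' Improved ratio-in-regression exponential estimator
#'
#' \eqn{w_8 s_y^2 + w_9 (S_x^2 - s_x^2)\exp\{(S_x^2-s_x^2)/(S_x^2+s_x^2)\}
#' + w_{10} (S_{rx}^2 - s_{rx}^2)\exp\{(S_{rx}^2-s_{rx}^2)/(S_{rx}^2+
#' s_{rx}^2)\}}. Each auxiliary correction is damped by its own
#' exponential factor; the leading term is the (shrunken) sample variance.
#'
#' @inheritParams est_ahmad
#' @param w8,w9,w10 Coefficients.
#' @export
est_proposed <- function(s, Sx2, Srx2, w8, w9, w10) {
  stopifnot(inherits(s, "sample_frame"))
  w8 * s$sy2 +
    w9  * (Sx2 - s$sx2)   * .exp_damp(Sx2, s$sx2) +
    w10 * (Srx2 - s$srx2) * .exp_damp(Srx2, s$srx2)
}

#' Evaluate a named estimator on a sample
#'
#' Convenience dispatcher used by the Monte-Carlo driver and the CLI.
#'
#' @param id One of `"usual"`, `"ratio"`, `"difference"`, `"rao"`,
#'   `"exp_ratio"`, `"grover_kaur"`, `"ahmad"`, `"proposed"`.
#' @param s A [sample_frame()].
#' @param m A [moment_set()] supplying the known population variances.
#' @param coef A [coefficient_set()] supplying any needed coefficients.
#' @return Point estimate of \eqn{S_y^2}.
#' @export
evaluate_estimator <- function(id, s, m, coef = NULL) {
  w <- if (is.null(coef)) stats::setNames(rep(NA_real_, 10), paste0("w", 1:10))
       else coef$w
  switch(id,
    usual       = est_usual(s),
    ratio       = est_ratio(s, m$Sx2),
    difference  = est_difference(s, m$Sx2, coef$psi11),
    rao         = est_rao(s, m$Sx2, w[["w1"]], w[["w2"]]),
    exp_ratio   = est_exp_ratio(s, m$Sx2),
    grover_kaur = est_grover_kaur(s, m$Sx2, w[["w3"]], w[["w4"]]),
    ahmad       = est_ahmad(s, m$Sx2, m$Srx2, w[["w5"]], w[["w6"]],
                            w[["w7"]]),
    proposed    = est_proposed(s, m$Sx2, m$Srx2, w[["w8"]], w[["w9"]],
                               w[["w10"]]),
    stop("unknown estimator id: ", id)
  )
}

#' All estimator identifiers, in report order
#' @export
estimator_ids <- function() {
  c("usual", "ratio", "difference", "rao", "exp_ratio",
    "grover_kaur", "ahmad", "proposed")
}

# Moment set computed from a sample's own data (plug-in mode): treats the
# sample frame as a small population. Used when population lambda* values
# are unknown; never used for the acceptance evaluation, which follows the
# convention of evaluating coefficients at true population parameters.
sample_moment_set <- function(s) {
  stopifnot(inherits(s, "sample_frame"))
  pop <- structure(list(y = s$y, x = s$x, rank_x = s$rank_x, N = s$n),
                   class = "population_frame")
  summarize_population(pop)
}
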