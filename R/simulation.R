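# Design-based Monte-Carlo evaluation on synthetic bivariate-normal
# populations.
#
# The generator emulates the bench simulation setting: x ~ N(5, 10) and
# y = x + independent N(2, 8) noise (population 1) or y = x + N(1, 3)
# (population 2), N = 5000 units, normal parameterized as N(mean, sd)
# (validated against the stated realized variances, e.g. Sx2 ~ 95.7 for
# N(5,10)). The evaluation sample size is not part of the stated setting
# and defaults to n = 250; reverse-engineering the published Var(Y0) from
# its simulation table is consistent with n of this order, but that is a
# comment, not an assertion.

#' Simulation specification
#'
#' @param population_id 1 or 2 (selects the noise law: N(2,8) or N(1,3)).
#' @param N Population size (default 5000).
#' @param mean_x,sd_x Auxiliary-variable normal parameters (defaults 5, 10).
#' @param noise_mean,noise_sd Noise normal parameters; defaults follow
#'   `population_id`.
#' @param n Sample size per replicate (default 250; not part of the stated
#'   setting, always reported).
#' @param replicates Monte-Carlo replicates.
#' @param seed Integer seed. Population generation and sampling consume
#'   independent sub-streams, so changing `replicates` does not change the
#'   generated population.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(population_id = 1L, N = 5000L, mean_x = 5,
                            sd_x = 10, noise_mean = NULL, noise_sd = NULL,
                            n = 250L, replicates = 1000L, seed = 1L) {
  if (!population_id %in% c(1L, 2L))
    stop("population_id must be 1 or 2")
  if (is.null(noise_mean))
    noise_mean <- if (population_id == 1L) 2 else 1
  if (is.null(noise_sd))
    noise_sd <- if (population_id == 1L) 8 else 3
  if (sd_x <= 0 || noise_sd <= 0) stop("standard deviations must be positive")
  if (n >= N) stop("sample size n must be smaller than N")
  structure(list(population_id = as.integer(population_id), N = as.integer(N),
                 mean_x = mean_x, sd_x = sd_x, noise_mean = noise_mean,
                 noise_sd = noise_sd, n = as.integer(n),
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic population
#'
#' Draws `x ~ N(mean_x, sd_x)` and `y = x + N(noise_mean, noise_sd)` for N
#' units and computes the auxiliary ranks. Continuous draws are tie-free
#' almost surely, so the rank variance equals \eqn{N(N+1)/12} (2083750 for
#' N = 5000). Reproducible under `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A [population_frame()].
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  x <- stats::rnorm(spec$N, spec$mean_x, spec$sd_x)
  y <- x + stats::rnorm(spec$N, spec$noise_mean, spec$noise_sd)
  population_frame(y, x)
}

#' Draw an SRSWOR sample
#'
#' Selects n distinct units uniformly (every size-n subset equally likely
#' under R's sampler) and builds a [sample_frame()] carrying the population
#' ranks of the sampled units.
#'
#' @param pop A [population_frame()].
#' @param n Sample size, \eqn{2 \le n < N}.
#' @param seed Optional seed for reproducibility of this single draw.
#' @export
draw_srswor <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_frame"))
  if (n >= pop$N) stop("sample size n must be smaller than N")
  if (n < 2) stop("sample size n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(pop$N, n)
  sample_frame(pop$y[idx], pop$x[idx], pop$rank_x[idx])
}

#' Run a design-based Monte-Carlo comparison
#'
#' Generates the population, computes its true moment set, fixes every
#' coefficient once from the population parameters (exact-minimization
#' optima by default, the evaluation convention of the closed-form theory;
#' `"plugin"` re-estimates coefficients from each sample's own moment
#' ratios), then draws `replicates` SRSWOR samples and accumulates each
#' estimator's empirical MSE about the generated population's true
#' \eqn{S_y^2}.
#'
#' @param spec A [simulation_spec()].
#' @param estimators Character vector of estimator ids (default all eight).
#' @param coefficient_mode `"population"` (default) or `"plugin"`.
#' @return A data.frame (class `monte_carlo_result`) with one row per
#'   estimator: `estimator`, `empirical_mse`, `theoretical_mse`,
#'   `empirical_pre`, `theoretical_pre`, `replicates`, `n`. Attributes
#'   `moment_set`, `design` and `Sy2` carry the generated population's
#'   parameters.
#' @export
run_monte_carlo <- function(spec, estimators = estimator_ids(),
                            coefficient_mode = c("population", "plugin")) {
  stopifnot(inherits(spec, "simulation_spec"))
  coefficient_mode <- match.arg(coefficient_mode)
  bad <- setdiff(estimators, estimator_ids())
  if (length(bad)) stop("unknown estimator ids: ", paste(bad, collapse = ", "))
  pop <- generate_population(spec)
  m <- summarize_population(pop)
  d <- design_spec(spec$N, spec$n)
  coef <- optimal_coefficients(m, d, method = "exact")
  theo <- theory_table(m, d, proposed_mode = "exact")
  theo <- theo[match(estimators, theo$estimator), ]

  # independent sampling sub-stream: the population above used spec$seed
  set.seed(spec$seed + 1L)
  est <- matrix(NA_real_, nrow = spec$replicates, ncol = length(estimators),
                dimnames = list(NULL, estimators))
  for (r in seq_len(spec$replicates)) {
    s <- draw_srswor(pop, spec$n)
    cf <- if (coefficient_mode == "plugin")
      optimal_coefficients(sample_moment_set(s), d, method = "exact")
    else coef
    for (id in estimators)
      est[r, id] <- evaluate_estimator(id, s, m, cf)
  }
  emp_mse <- colMeans((est - m$Sy2)^2)
  emp_var0 <- if ("usual" %in% estimators) emp_mse[["usual"]] else
    mean((est[, 1] - m$Sy2)^2)  # PRE base requires the usual estimator
  out <- data.frame(
    estimator = estimators,
    empirical_mse = as.numeric(emp_mse),
    theoretical_mse = theo$mse,
    empirical_pre = 100 * emp_var0 / as.numeric(emp_mse),
    theoretical_pre = theo$pre,
    replicates = spec$replicates,
    n = spec$n,
    stringsAsFactors = FALSE)
  attr(out, "moment_set") <- m
  attr(out, "design") <- d
  attr(out, "Sy2") <- m$Sy2
  class(out) <- c("monte_carlo_result", "data.frame")
  out
}
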