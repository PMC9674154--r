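#' Pairwise efficiency conditions for the proposed estimator
#'
#' Evaluates, for each competitor, the condition "MSE(competitor) -
#' MSE(proposed) > 0". Dividing each difference by \eqn{\lambda S_y^4}
#' gives the published \eqn{\lambda^*}-form inequalities: the competitor's
#' unitless MSE factor must exceed the threshold \eqn{M =
#' \mathrm{MSE}(\hat Y_{prop}) / (\lambda S_y^4)}. Strict inequality, no
#' tolerance: a tie is reported as not-better.
#'
#' @inheritParams var_usual
#' @param proposed_mode `"exact"` uses the quadratic-minimum MSE
#'   ([mse_proposed_exact()]); `"printed"` uses the literal published
#'   closed form, in which case the result inherits its
#'   `"printed_formula_inconsistent"` flag (the threshold can be negative).
#' @return Object of class `efficiency_report`: a data.frame `comparisons`
#'   with columns `competitor`, `lhs` (competitor MSE / \eqn{\lambda
#'   S_y^4}), `rhs` (the threshold M), `proposed_better`; plus
#'   `m_threshold` and `flags`.
#' @export
compare_all <- function(m, d, proposed_mode = c("exact", "printed")) {
  proposed_mode <- match.arg(proposed_mode)
  prop <- if (proposed_mode == "exact") mse_proposed_exact(m, d)
          else mse_proposed_printed(m, d)
  scale <- d$lam * m$Sy2^2
  competitors <- list(var_usual(m, d), mse_ratio(m, d), var_difference(m, d),
                      mse_rao(m, d), mse_exp_ratio(m, d),
                      mse_grover_kaur(m, d), mse_ahmad(m, d))
  comparisons <- data.frame(
    competitor = vapply(competitors, `[[`, character(1), "estimator_id"),
    lhs = vapply(competitors, `[[`, numeric(1), "mse") / scale,
    rhs = prop$mse / scale,
    stringsAsFactors = FALSE)
  comparisons$proposed_better <-
    vapply(competitors, `[[`, numeric(1), "mse") - prop$mse > 0
  structure(list(comparisons = comparisons,
                 m_threshold = prop$mse / scale,
                 proposed_mode = proposed_mode,
                 flags = prop$flags),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("Efficiency conditions (proposed MSE mode: %s, M = %.7g)\n",
              x$proposed_mode, x$m_threshold))
  df <- x$comparisons
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-12s lhs = %12.7g  >  M : %s\n", df$competitor[i],
                df$lhs[i], ifelse(df$proposed_better[i], "TRUE", "FALSE")))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
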