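# File input/output: population CSVs, printed-parameter blocks, reports.

#' Load a population from a delimited text file
#'
#' Requires numeric columns `y` and `x`; ranks are always recomputed on the
#' full population (a precomputed rank column, if present, is ignored).
#'
#' @param path Path to a CSV file.
#' @return A [population_frame()].
#' @export
load_population_csv <- function(path) {
  if (!file.exists(path)) stop("population file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("y", "x") %in% names(df)))
    stop("population file must contain columns named 'y' and 'x'")
  if (!is.numeric(df$y) || !is.numeric(df$x))
    stop("columns 'y' and 'x' must be numeric")
  if (nrow(df) < 3L)
    stop("population file must contain at least 3 rows")
  population_frame(df$y, df$x)
}

#' Write a population frame to CSV
#'
#' Writes columns `y`, `x`, `rank_x` with full double precision, so a
#' round trip through [load_population_csv()] preserves every moment to
#' machine precision.
#'
#' @param pop A [population_frame()].
#' @param path Output path.
#' @export
write_population_csv <- function(pop, path) {
  stopifnot(inherits(pop, "population_frame"))
  df <- data.frame(y = sprintf("%.17g", pop$y), x = sprintf("%.17g", pop$x),
                   rank_x = sprintf("%.17g", pop$rank_x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a printed parameter block
#'
#' Reads a flat `key: value` block (Debian-control format) holding the
#' population parameters a summary table prints: `N`, `n`, `Sy2`, `Sx2`,
#' `Srx2`, the six starred moment ratios `lam400s` ... `lam022s`, and
#' optionally correlations, means and the printed sampling factor `lam`
#' (checked for consistency with `1/n - 1/N` when present).
#'
#' @param path Path to the parameter file, or the name of a packaged
#'   fixture (`"population1"` or `"population2"`).
#' @return List with elements `m` (a [moment_set()]) and `d`
#'   (a [design_spec()]).
#' @export
load_table1_params <- function(path) {
  if (!file.exists(path)) {
    candidate <- system.file("extdata", paste0(path, ".dcf"),
                             package = "dualvar")
    if (!nzchar(candidate))
      stop("parameter file not found: ", path)
    path <- candidate
  }
  raw <- read.dcf(path)
  vals <- stats::setNames(as.list(raw[1L, ]), colnames(raw))
  required <- c("N", "n", "Sy2", "Sx2", "Srx2", "lam400s", "lam040s",
                "lam004s", "lam220s", "lam202s", "lam022s")
  missing <- setdiff(required, names(vals))
  if (length(missing))
    stop("missing required parameter key(s): ",
         paste(missing, collapse = ", "))
  num <- function(k, default = NA_real_) {
    if (!k %in% names(vals)) return(default)
    v <- suppressWarnings(as.numeric(vals[[k]]))
    if (is.na(v)) stop("parameter '", k, "' is not numeric")
    v
  }
  d <- design_spec(num("N"), num("n"))
  if ("lam" %in% names(vals) &&
      abs(num("lam") - d$lam) > 1e-6 * d$lam)
    stop("printed sampling factor 'lam' inconsistent with 1/n - 1/N")
  m <- moment_set(
    Sy2 = num("Sy2"), Sx2 = num("Sx2"), Srx2 = num("Srx2"),
    lam400s = num("lam400s"), lam040s = num("lam040s"),
    lam004s = num("lam004s"), lam220s = num("lam220s"),
    lam202s = num("lam202s"), lam022s = num("lam022s"),
    rho_yx = num("rho_yx"), rho_yrx = num("rho_yrx"),
    rho_xrx = num("rho_xrx"),
    mean_y = num("mean_y"), mean_x = num("mean_x"),
    mean_rx = num("mean_rx"), N = as.integer(num("N")))
  list(m = m, d = d)
}

#' Names of the packaged parameter fixtures
#' @export
table1_fixtures <- function() c("population1", "population2")

#' Load a packaged parameter fixture
#'
#' @param name `"population1"` or `"population2"`.
#' @return As [load_table1_params()].
#' @export
table1_fixture <- function(name = table1_fixtures()) {
  name <- match.arg(name)
  load_table1_params(name)
}

.render_num <- function(x) {
  ifelse(is.na(x), "-", trimws(formatC(x, digits = 7, format = "g")))
}

#' Render a theory or Monte-Carlo table as text
#'
#' Deterministic column order, 7 significant digits, scientific notation in
#' the `e+NN` style for large magnitudes. `"csv"` output parses back to the
#' same values via [utils::read.csv()].
#'
#' @param results A data.frame from [theory_table()] or
#'   [run_monte_carlo()].
#' @param format `"plain"` or `"csv"`.
#' @return Character vector of report lines (invisibly printed by `cat`
#'   in the CLI).
#' @export
render_report <- function(results, format = c("plain", "csv")) {
  format <- match.arg(format)
  if (!is.data.frame(results) || nrow(results) == 0L)
    stop("results must be a non-empty data.frame")
  num_cols <- names(results)[vapply(results, is.numeric, logical(1))]
  out <- results
  for (nc in num_cols) out[[nc]] <- .render_num(results[[nc]])
  for (nc in names(out)) out[[nc]] <- as.character(out[[nc]])
  if (format == "csv") {
    lines <- c(paste(names(out), collapse = ","),
               apply(out, 1L, paste, collapse = ","))
  } else {
    widths <- pmax(nchar(names(out)),
                   apply(nchar(as.matrix(out)), 2L, max)) + 2L
    pad <- function(v, w) formatC(v, width = w, flag = "-")
    lines <- c(paste(mapply(pad, names(out), widths), collapse = ""),
               apply(mapply(pad, out, widths), 1L, paste, collapse = ""))
  }
  lines
}
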