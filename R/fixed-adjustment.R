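#' Observed 2x2 case-control table
#'
#' Apparent (self-reported) exposure by case status: `a` exposed cases,
#' `b` unexposed cases, `c` exposed controls, `d` unexposed controls.
#' An all-zero table is permitted (used by priors-only Bayesian runs);
#' operations that need a nonempty margin check it themselves.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return An object of class `observed_table`.
#' @export
observed_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  for (nm in names(cells)) {
    if (!is_count(cells[[nm]])) {
      stop_input("observed_table cell '%s' must be a nonnegative integer count", nm)
    }
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "observed_table")
}

#' @export
print.observed_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("cases", "controls"), c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Read/write a 2x2 study table as CSV
#'
#' CSV layout: rows `cases`/`controls` (column `group`), columns `exposed`
#' and `unexposed`.
#' @param path file path.
#' @return [observed_table()] for the reader; invisibly the path for the writer.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("group", "exposed", "unexposed")
  if (!all(need %in% names(df))) {
    stop_input("study-table CSV must have columns: %s", paste(need, collapse = ", "))
  }
  row <- function(g) df[df$group == g, , drop = FALSE]
  ca <- row("cases"); co <- row("controls")
  if (nrow(ca) != 1L || nrow(co) != 1L) {
    stop_input("study-table CSV needs exactly one 'cases' and one 'controls' row")
  }
  observed_table(ca$exposed, ca$unexposed, co$exposed, co$unexposed)
}

#' @rdname read_table_csv
#' @param tab an [observed_table()].
#' @export
write_table_csv <- function(tab, path) {
  stopifnot(inherits(tab, "observed_table"))
  df <- data.frame(group = c("cases", "controls"),
                   exposed = c(tab$a, tab$c),
                   unexposed = c(tab$b, tab$d))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Matrix correction of a misclassified 2x2 table
#'
#' Back-corrects apparent exposure counts with fixed sensitivity and
#' specificity per stratum: with case margin `M1 = a + b`,
#' `A = (a - (1 - sp_cases) * M1) / (se_cases + sp_cases - 1)` and
#' `B = M1 - A`; controls analogously. The corrected cells are expected
#' true-exposure counts and are in general not integers; margins are
#' conserved exactly.
#'
#' @param obs an [observed_table()], or numeric cells `c(a, b, c, d)`
#'   (nonnegative reals are accepted, so expected counts can be corrected
#'   too).
#' @param se_cases,sp_cases,se_controls,sp_controls fixed misclassification
#'   probabilities; each stratum must satisfy `se + sp > 1` (the
#'   identifiability region).
#' @return An object of class `corrected_table` with cells `A`, `B`, `C`,
#'   `D` and flag `rounded = FALSE`.
#' @examples
#' obs <- observed_table(80, 120, 100, 100)
#' correct_counts(obs, 0.8, 0.9, 0.8, 0.9)
#' @export
correct_counts <- function(obs, se_cases, sp_cases, se_controls, sp_controls) {
  if (is.numeric(obs) && length(obs) == 4L) {
    if (any(!is.finite(obs)) || any(obs < 0)) stop_input("cells must be nonnegative reals")
    obs <- structure(list(a = obs[1], b = obs[2], c = obs[3], d = obs[4]),
                     class = "observed_table")
  }
  stopifnot(inherits(obs, "observed_table"))
  for (p in list(se_cases = se_cases, sp_cases = sp_cases,
                 se_controls = se_controls, sp_controls = sp_controls)) {
    if (!is_proportion(p)) stop_input("sensitivities/specificities must be proportions in [0, 1]")
  }
  M1 <- obs$a + obs$b
  M0 <- obs$c + obs$d
  if (M1 < 1 || M0 < 1) stop_input("correction needs at least one subject per stratum")
  if (se_cases + sp_cases <= 1 || se_controls + sp_controls <= 1) {
    stop_input("non-identifiable correction: se + sp must exceed 1 in each stratum")
  }
  A <- (obs$a - (1 - sp_cases) * M1) / (se_cases + sp_cases - 1)
  B <- M1 - A
  C <- (obs$c - (1 - sp_controls) * M0) / (se_controls + sp_controls - 1)
  D <- M0 - C
  cells <- c(A = A, B = B, C = C, D = D)
  bad <- names(cells)[cells < 0]
  if (length(bad)) {
    stop_input("infeasible correction: corrected cell(s) %s negative (%s)",
               paste(bad, collapse = ", "),
               paste(sprintf("%s=%.4g", bad, cells[bad]), collapse = ", "))
  }
  structure(list(A = A, B = B, C = C, D = D, rounded = FALSE),
            class = "corrected_table")
}

#' @export
print.corrected_table <- function(x, ...) {
  m <- matrix(c(x$A, x$C, x$B, x$D), 2, 2,
              dimnames = list(c("cases", "controls"), c("exposed", "unexposed")))
  cat(sprintf("Corrected expected counts%s\n", if (x$rounded) " (rounded)" else ""))
  print(m)
  invisible(x)
}

#' Forward (mis)classification of true expected counts
#'
#' The inverse of [correct_counts()]: given expected true-exposure counts,
#' returns the expected apparent table
#' `a = A * se_cases + B * (1 - sp_cases)` etc. Used for round-trip checks
#' and simulation design.
#'
#' @param tab a `corrected_table` (or list with `A`, `B`, `C`, `D`).
#' @inheritParams correct_counts
#' @return List with expected apparent cells `a`, `b`, `c`, `d` (reals).
#' @export
apply_misclassification <- function(tab, se_cases, sp_cases, se_controls, sp_controls) {
  a <- tab$A * se_cases + tab$B * (1 - sp_cases)
  b <- tab$A * (1 - se_cases) + tab$B * sp_cases
  c <- tab$C * se_controls + tab$D * (1 - sp_controls)
  d <- tab$C * (1 - se_controls) + tab$D * sp_controls
  list(a = a, b = b, c = c, d = d)
}

#' Round corrected cells to integers (spreadsheet style)
#'
#' Rounds half away from zero, mimicking spreadsheet rounding. Present only
#' to demonstrate the pitfall: corrected expected counts need not be
#' integers, and rounding them changes the odds ratio and its confidence
#' interval.
#'
#' @param tab a `corrected_table`.
#' @return A `corrected_table` with `rounded = TRUE`.
#' @export
round_corrected <- function(tab) {
  stopifnot(inherits(tab, "corrected_table"))
  structure(list(A = round_half_away(tab$A), B = round_half_away(tab$B),
                 C = round_half_away(tab$C), D = round_half_away(tab$D),
                 rounded = TRUE),
            class = "corrected_table")
}

table_cells <- function(tab) {
  if (inherits(tab, "corrected_table")) {
    c(tab$A, tab$B, tab$C, tab$D)
  } else if (inherits(tab, "observed_table")) {
    c(tab$a, tab$b, tab$c, tab$d)
  } else if (is.numeric(tab) && length(tab) == 4L) {
    as.numeric(tab)
  } else {
    stop_input("expected an observed_table, corrected_table, or 4 cells")
  }
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (A * D) / (B * C)` with a normal approximation on the log scale
#' using variance `1/A + 1/B + 1/C + 1/D`, evaluated on the (possibly
#' non-integer) cells. No continuity correction by default; a zero cell is
#' an error unless `continuity = TRUE` adds 0.5 to every cell.
#'
#' @param tab an [observed_table()], `corrected_table`, or numeric cells
#'   `c(A, B, C, D)`.
#' @param level confidence level (default 0.95).
#' @param continuity add 0.5 to all cells when any is zero (off by default).
#' @return An object of class `or_estimate` with `or_point`, `ci_low`,
#'   `ci_high`, `level` and `log_width`.
#' @export
odds_ratio_ci <- function(tab, level = 0.95, continuity = FALSE) {
  cells <- table_cells(tab)
  if (!is_proportion(level) || level <= 0 || level >= 1) {
    stop_input("level must be in (0, 1)")
  }
  if (any(cells == 0)) {
    if (!continuity) {
      stop_input("undefined estimate: zero cell(s) in the 2x2 table (set continuity = TRUE to add 0.5)")
    }
    cells <- cells + 0.5
  }
  if (any(cells < 0)) stop_input("negative cell in 2x2 table")
  lor <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(or_point = exp(lor),
                 ci_low = exp(lor - z * se),
                 ci_high = exp(lor + z * se),
                 level = level,
                 log_width = 2 * z * se),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (%.0f%% CI %.3f-%.3f)\n",
              x$or_point, 100 * x$level, x$ci_low, x$ci_high))
  invisible(x)
}

#' Demonstrate the rounding pitfall of fixed-value correction
#'
#' Performs the fixed-value correction twice — once on the exact non-integer
#' expected counts and once after rounding them to integers — and returns
#' both odds-ratio estimates with their log-scale CI widths. Corrected
#' expected counts do not have to be integers; rounding them before
#' estimating silently changes both the point estimate and the interval.
#'
#' @inheritParams correct_counts
#' @param level confidence level.
#' @return List with `unrounded` and `rounded` [odds_ratio_ci()] results and
#'   the two log-scale CI widths.
#' @export
rounding_pitfall_report <- function(obs, se_cases, sp_cases, se_controls, sp_controls,
                                    level = 0.95) {
  corr <- correct_counts(obs, se_cases, sp_cases, se_controls, sp_controls)
  est_exact <- odds_ratio_ci(corr, level = level)
  est_round <- odds_ratio_ci(round_corrected(corr), level = level)
  list(unrounded = est_exact,
       rounded = est_round,
       log_width_unrounded = est_exact$log_width,
       log_width_rounded = est_round$log_width)
}
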