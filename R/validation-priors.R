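#' Validation cross-tabulation of self-reported vs gold-standard exposure
#'
#' Holds the four cells of a validation study within one case-status stratum:
#' subjects cross-classified by self-reported exposure (ever/never) and
#' gold-standard (e.g. payroll register) exposure (ever/never). Sensitivity is
#' estimated down the gold-standard "ever" column, specificity down the
#' "never" column.
#'
#' @param n_ee count: self-report ever, record ever (true positives).
#' @param n_en count: self-report ever, record never (false positives).
#' @param n_ne count: self-report never, record ever (false negatives).
#' @param n_nn count: self-report never, record never (true negatives).
#' @param stratum `"cases"` or `"controls"`.
#' @return An object of class `validation_crosstab`.
#' @examples
#' validation_crosstab(50, 29, 8, 138, stratum = "cases")
#' @export
validation_crosstab <- function(n_ee, n_en, n_ne, n_nn,
                                stratum = c("cases", "controls")) {
  stratum <- match.arg(stratum)
  counts <- c(n_ee = n_ee, n_en = n_en, n_ne = n_ne, n_nn = n_nn)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]])) {
      stop_input("validation cell '%s' must be a nonnegative integer count (got %s)",
                 nm, format(counts[[nm]]))
    }
  }
  structure(list(n_ee = as.numeric(n_ee), n_en = as.numeric(n_en),
                 n_ne = as.numeric(n_ne), n_nn = as.numeric(n_nn),
                 stratum = stratum),
            class = "validation_crosstab")
}

#' @export
print.validation_crosstab <- function(x, ...) {
  cat(sprintf("Validation cross-tab (%s)\n", x$stratum))
  m <- matrix(c(x$n_ee, x$n_ne, x$n_en, x$n_nn), 2, 2,
              dimnames = list(`self-report` = c("ever", "never"),
                              record = c("ever", "never")))
  print(m)
  invisible(x)
}

#' Beta distribution specification
#'
#' A `Beta(alpha, beta)` distribution used as a prior for a misclassification
#' probability (sensitivity or specificity).
#'
#' @param alpha,beta positive shape parameters.
#' @return An object of class `beta_spec`.
#' @seealso [beta_point()] for a degenerate (known-value) prior.
#' @export
beta_spec <- function(alpha, beta) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 ||
      !is.numeric(beta)  || length(beta)  != 1L || !is.finite(beta)  || beta  <= 0) {
    stop_input("beta_spec requires finite alpha > 0 and beta > 0")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_spec")
}

#' Point-mass (degenerate) prior for a misclassification probability
#'
#' Represents exact knowledge of a sensitivity or specificity: every draw
#' equals `value` and, in the Bayesian model, the parameter is held fixed.
#' Useful for fixed-value bias analysis expressed through the probabilistic
#' machinery, and for oracle checks.
#'
#' @param value a proportion strictly inside (0, 1).
#' @return An object of classes `beta_point` and `beta_spec`.
#' @export
beta_point <- function(value) {
  if (!is_proportion(value) || value <= 0 || value >= 1) {
    stop_input("beta_point requires a value strictly inside (0, 1)")
  }
  structure(list(alpha = Inf, beta = Inf, value = as.numeric(value)),
            class = c("beta_point", "beta_spec"))
}

is_beta_point <- function(x) inherits(x, "beta_point")

#' @export
print.beta_spec <- function(x, ...) {
  if (is_beta_point(x)) {
    cat(sprintf("Point mass at %.6g\n", x$value))
  } else {
    m <- beta_moments(x)
    cat(sprintf("Beta(%g, %g)  mean %.4f  var %.3g\n",
                x$alpha, x$beta, m[["mean"]], m[["variance"]]))
  }
  invisible(x)
}

#' Conjugate Beta update for a validated proportion
#'
#' Observing `k` successes in `N` trials, starting from ignorance about the
#' underlying proportion, yields a `Beta(k + 1, N - k + 1)` distribution for
#' it (the Bernoulli-conjugate update of a uniform prior). A Jeffreys variant
#' (`Beta(k + 1/2, N - k + 1/2)`) is available but off by default.
#'
#' @param k number of successes, `0 <= k <= N`.
#' @param N number of trials, `N >= 1`.
#' @param prior starting prior: `"uniform"` (default) or `"jeffreys"`.
#' @return A [beta_spec()].
#' @examples
#' derive_beta(50, 58)    # Beta(51, 9)
#' derive_beta(1118, 1336) # Beta(1119, 219)
#' @export
derive_beta <- function(k, N, prior = c("uniform", "jeffreys")) {
  prior <- match.arg(prior)
  if (!is_count(k) || !is_count(N) || N < 1 || k > N) {
    stop_input("derive_beta requires integer counts with 0 <= k <= N and N >= 1 (got k=%s, N=%s)",
               format(k), format(N))
  }
  off <- if (prior == "uniform") 1 else 0.5
  beta_spec(k + off, N - k + off)
}

#' Mean and variance of a Beta distribution
#'
#' Closed forms `mean = a/(a+b)` and
#' `variance = ab / ((a+b)^2 (a+b+1))`, returned as raw proportions.
#' Percent formatting belongs to the reporting layer.
#'
#' @param spec a [beta_spec()].
#' @return Named numeric vector `c(mean =, variance =)`.
#' @export
beta_moments <- function(spec) {
  stopifnot(inherits(spec, "beta_spec"))
  if (is_beta_point(spec)) {
    return(c(mean = spec$value, variance = 0))
  }
  a <- spec$alpha
  b <- spec$beta
  s <- a + b
  c(mean = a / s, variance = a * b / (s^2 * (s + 1)))
}

#' Misclassification priors for both strata
#'
#' Bundles the four Beta priors: sensitivity and specificity, each for cases
#' and for controls.
#'
#' @param se_cases,sp_cases,se_controls,sp_controls [beta_spec()] objects.
#' @return An object of class `misclass_priors`.
#' @export
misclass_priors <- function(se_cases, sp_cases, se_controls, sp_controls) {
  comps <- list(se_cases = se_cases, sp_cases = sp_cases,
                se_controls = se_controls, sp_controls = sp_controls)
  for (nm in names(comps)) {
    if (!inherits(comps[[nm]], "beta_spec")) {
      stop_input("'%s' must be a beta_spec", nm)
    }
  }
  structure(comps, class = "misclass_priors")
}

#' @export
print.misclass_priors <- function(x, ...) {
  cat("Misclassification priors (Beta)\n")
  df <- priors_table(x)
  df$mean_pct <- round(100 * df$mean, 1)
  df$variance_pct <- signif(100 * df$variance, 3)
  print(df[, c("stratum", "parameter", "alpha", "beta", "mean_pct", "variance_pct")],
        row.names = FALSE)
  invisible(x)
}

#' Tabulate misclassification priors
#'
#' @param priors a [misclass_priors()].
#' @return A data.frame with one row per (stratum, parameter) carrying the
#'   Beta shapes and moments as raw proportions.
#' @export
priors_table <- function(priors) {
  stopifnot(inherits(priors, "misclass_priors"))
  rows <- lapply(names(priors), function(nm) {
    sp <- priors[[nm]]
    m <- beta_moments(sp)
    data.frame(
      stratum = if (grepl("cases$", nm)) "cases" else "controls",
      parameter = if (grepl("^se", nm)) "sensitivity" else "specificity",
      alpha = sp$alpha, beta = sp$beta,
      mean = m[["mean"]], variance = m[["variance"]],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Elicit Beta priors from a pair of validation cross-tabulations
#'
#' Sensitivity uses the gold-standard "ever" column (`k = n_ee`,
#' `N = n_ee + n_ne`); specificity uses the gold-standard "never" column
#' (`k = n_nn`, `N = n_nn + n_en`); each proportion gets the conjugate
#' update of [derive_beta()].
#'
#' @param cases,controls [validation_crosstab()] objects for the two strata.
#' @param prior starting prior passed to [derive_beta()].
#' @return A [misclass_priors()].
#' @examples
#' cases <- validation_crosstab(50, 29, 8, 138, "cases")
#' controls <- validation_crosstab(374, 218, 90, 1118, "controls")
#' priors_from_crosstab(cases, controls)
#' @export
priors_from_crosstab <- function(cases, controls, prior = c("uniform", "jeffreys")) {
  prior <- match.arg(prior)
  stopifnot(inherits(cases, "validation_crosstab"),
            inherits(controls, "validation_crosstab"))
  one <- function(tab, stratum) {
    n_se <- tab$n_ee + tab$n_ne
    n_sp <- tab$n_nn + tab$n_en
    if (n_se < 1) {
      stop_input("cannot elicit sensitivity for %s: gold-standard 'ever' margin is zero",
                 stratum)
    }
    if (n_sp < 1) {
      stop_input("cannot elicit specificity for %s: gold-standard 'never' margin is zero",
                 stratum)
    }
    list(se = derive_beta(tab$n_ee, n_se, prior),
         sp = derive_beta(tab$n_nn, n_sp, prior))
  }
  ca <- one(cases, "cases")
  co <- one(controls, "controls")
  misclass_priors(se_cases = ca$se, sp_cases = ca$sp,
                  se_controls = co$se, sp_controls = co$sp)
}

#' Read validation counts from CSV
#'
#' Expects columns `stratum` (cases/controls), `self_report` (ever/never),
#' `record` (ever/never) and `count`, one row per cell.
#'
#' @param path path to the CSV file.
#' @return Named list with `cases` and `controls` [validation_crosstab()]s.
#' @export
read_validation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stratum", "self_report", "record", "count")
  if (!all(need %in% names(df))) {
    stop_input("validation CSV must have columns: %s", paste(need, collapse = ", "))
  }
  get_cell <- function(stratum, sr, rec) {
    hit <- df$stratum == stratum & df$self_report == sr & df$record == rec
    if (sum(hit) != 1L) {
      stop_input("validation CSV: expected exactly one row for (%s, %s, %s)",
                 stratum, sr, rec)
    }
    df$count[hit]
  }
  build <- function(stratum) {
    validation_crosstab(
      n_ee = get_cell(stratum, "ever", "ever"),
      n_en = get_cell(stratum, "ever", "never"),
      n_ne = get_cell(stratum, "never", "ever"),
      n_nn = get_cell(stratum, "never", "never"),
      stratum = stratum
    )
  }
  list(cases = build("cases"), controls = build("controls"))
}

#' Night-shift work validation counts
#'
#' The bundled example dataset: self-reported ever/never night-shift work
#' cross-classified against payroll-register records, separately for breast
#' cancer cases (50/29/8/138) and controls (374/218/90/1118), from a
#' published Danish validation study of occupational night work.
#'
#' @return Named list with `cases` and `controls` [validation_crosstab()]s.
#' @export
nightshift_validation <- function() {
  read_validation_csv(system.file("extdata", "nightshift_validation.csv",
                                  package = "oradjust", mustWork = TRUE))
}

#' Export elicited priors as JSON
#'
#' Writes `{stratum: {parameter: {alpha, beta, mean, variance}}}`.
#'
#' @param priors a [misclass_priors()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
priors_to_json <- function(priors, path = NULL) {
  df <- priors_table(priors)
  out <- list()
  for (i in seq_len(nrow(df))) {
    st <- df$stratum[i]
    pa <- df$parameter[i]
    out[[st]][[pa]] <- list(alpha = df$alpha[i], beta = df$beta[i],
                            mean = df$mean[i], variance = df$variance[i])
  }
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
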