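#' Ground truth for a synthetic case-control study
#'
#' Defines a case-control study with binary true exposure and differential
#' misclassification of self-report. Defaults emulate the motivating
#' night-shift-work setting: control exposure prevalence 0.15, true OR 1,
#' sensitivity/specificity at the means of the validation-elicited Beta
#' priors (cases 0.850/0.822, controls 0.805/0.836), 4000 subjects per arm,
#' and validation subsamples of 225 cases and 1800 controls.
#'
#' @param true_or true odds ratio of exposure for cases vs controls.
#' @param p0 true exposure prevalence among controls.
#' @param se_cases,sp_cases,se_controls,sp_controls misclassification
#'   probabilities applied to self-report; each stratum needs `se + sp > 1`.
#' @param n_cases,n_controls main-study sample sizes (margins fixed by design).
#' @param n_val_cases,n_val_controls validation subsample sizes.
#' @param seed RNG seed for reproducible generation.
#' @return An object of class `synthetic_truth`. The implied case prevalence
#'   `p1 = expit(logit(p0) + log(true_or))` is stored as `$p1`.
#' @export
synthetic_truth <- function(true_or = 1, p0 = 0.15,
                            se_cases = 0.85, sp_cases = 0.8225,
                            se_controls = 0.8047, sp_controls = 0.8363,
                            n_cases = 4000L, n_controls = 4000L,
                            n_val_cases = 225L, n_val_controls = 1800L,
                            seed = 1L) {
  if (!is.numeric(true_or) || true_or <= 0) stop_input("true_or must be positive")
  for (p in list(p0 = p0, se_cases = se_cases, sp_cases = sp_cases,
                 se_controls = se_controls, sp_controls = sp_controls)) {
    if (!is_proportion(p)) stop_input("prevalence and misclassification parameters must be proportions")
  }
  if (p0 <= 0 || p0 >= 1) stop_input("p0 must lie strictly inside (0, 1)")
  if (se_cases + sp_cases <= 1 || se_controls + sp_controls <= 1) {
    stop_input("synthetic truth must satisfy se + sp > 1 in each stratum")
  }
  if (!is_count(n_cases) || !is_count(n_controls) || n_cases < 1 || n_controls < 1) {
    stop_input("n_cases and n_controls must be positive integers")
  }
  if (!is_count(n_val_cases) || !is_count(n_val_controls)) {
    stop_input("validation sizes must be nonnegative integers")
  }
  p1 <- expit(logit(p0) + log(true_or))
  structure(list(true_or = true_or, p0 = p0, p1 = p1,
                 se_cases = se_cases, sp_cases = sp_cases,
                 se_controls = se_controls, sp_controls = sp_controls,
                 n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 n_val_cases = as.integer(n_val_cases),
                 n_val_controls = as.integer(n_val_controls),
                 seed = seed),
            class = "synthetic_truth")
}

#' Generate an observed (misclassified) case-control study
#'
#' True exposure is Binomial within each fixed margin; each subject's
#' self-report then flips independently according to the stratum's
#' sensitivity (if truly exposed) or specificity (if truly unexposed).
#'
#' @param truth a [synthetic_truth()].
#' @return List with `observed` (the apparent [observed_table()]), `latent`
#'   (true exposed counts per stratum) and `truth`.
#' @export
generate_study <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(truth$seed, {
    x1 <- stats::rbinom(1L, truth$n_cases, truth$p1)
    x0 <- stats::rbinom(1L, truth$n_controls, truth$p0)
    a <- stats::rbinom(1L, x1, truth$se_cases) +
      stats::rbinom(1L, truth$n_cases - x1, 1 - truth$sp_cases)
    c_ <- stats::rbinom(1L, x0, truth$se_controls) +
      stats::rbinom(1L, truth$n_controls - x0, 1 - truth$sp_controls)
    list(observed = observed_table(a, truth$n_cases - a, c_, truth$n_controls - c_),
         latent = c(true_exposed_cases = x1, true_exposed_controls = x0),
         truth = truth)
  })
}

#' Generate a gold-standard validation subsample
#'
#' Draws validation subjects with record-based (gold standard) exposure
#' Bernoulli at the stratum's true prevalence, applies the same
#' misclassification to their self-report, and cross-tabulates. The RNG
#' stream is offset from [generate_study()]'s so the two samples are
#' independent under a shared seed.
#'
#' @param truth a [synthetic_truth()].
#' @return Named list of `cases` and `controls` [validation_crosstab()]s.
#' @export
generate_validation <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  seed <- if (is.null(truth$seed)) NULL else (truth$seed + 1L) %% .Machine$integer.max
  with_seed(seed, {
    one <- function(n, p, se, sp, stratum) {
      gold <- stats::rbinom(1L, n, p)
      ee <- stats::rbinom(1L, gold, se)          # exposed, report ever
      nn <- stats::rbinom(1L, n - gold, sp)      # unexposed, report never
      validation_crosstab(n_ee = ee, n_en = (n - gold) - nn,
                          n_ne = gold - ee, n_nn = nn, stratum = stratum)
    }
    list(cases = one(truth$n_val_cases, truth$p1, truth$se_cases,
                     truth$sp_cases, "cases"),
         controls = one(truth$n_val_controls, truth$p0, truth$se_controls,
                        truth$sp_controls, "controls"))
  })
}
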