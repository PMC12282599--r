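#' Configuration for probabilistic bias analysis
#'
#' @param n_iter number of Monte-Carlo draws (default 100000).
#' @param rho cross-stratum correlation of the misclassification parameters:
#'   sensitivity(cases) with sensitivity(controls), and specificity(cases)
#'   with specificity(controls); sensitivity-specificity pairs stay
#'   independent. Default 0.1 (weak correlation).
#' @param include_random_error draw conventional random error on the log-OR
#'   scale in addition to the systematic correction (default `TRUE`).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @param level width of the reported simulation interval (default 0.95).
#' @return An object of class `pba_config`.
#' @export
pba_config <- function(n_iter = 100000L, rho = 0.1, include_random_error = TRUE,
                       seed = NULL, level = 0.95) {
  if (!is_count(n_iter) || n_iter < 1) stop_input("n_iter must be a positive integer")
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop_input("rho must satisfy |rho| < 1")
  }
  if (!is_proportion(level) || level <= 0 || level >= 1) stop_input("level must be in (0, 1)")
  structure(list(n_iter = as.integer(n_iter), rho = rho,
                 include_random_error = isTRUE(include_random_error),
                 seed = seed, level = level),
            class = "pba_config")
}

beta_quantile <- function(spec, u) {
  if (is_beta_point(spec)) rep(spec$value, length(u)) else stats::qbeta(u, spec$alpha, spec$beta)
}

#' Correlated draws from the four misclassification priors
#'
#' Gaussian copula: a 4-dimensional normal with correlation `rho` between
#' the two sensitivities and between the two specificities (sensitivities
#' and specificities mutually independent) is mapped through the normal CDF
#' and the Beta quantile functions, so the marginals are exactly the four
#' Beta priors.
#'
#' @param priors a [misclass_priors()].
#' @param rho copula correlation, `|rho| < 1`.
#' @param n number of quadruples.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return Data frame with columns `se_cases`, `sp_cases`, `se_controls`,
#'   `sp_controls`, one row per draw.
#' @export
sample_correlated_betas <- function(priors, rho, n, seed = NULL) {
  stopifnot(inherits(priors, "misclass_priors"))
  if (!is.numeric(rho) || abs(rho) >= 1) stop_input("rho must satisfy |rho| < 1")
  if (!is_count(n) || n < 1) stop_input("n must be a positive integer")
  # order: se_cases, sp_cases, se_controls, sp_controls
  sigma <- diag(4)
  sigma[1, 3] <- sigma[3, 1] <- rho
  sigma[2, 4] <- sigma[4, 2] <- rho
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop_input("copula correlation matrix is not positive definite"))
  z <- with_seed(seed, matrix(stats::rnorm(4L * n), nrow = n, ncol = 4L)) %*% ch
  u <- stats::pnorm(z)
  data.frame(
    se_cases = beta_quantile(priors$se_cases, u[, 1]),
    sp_cases = beta_quantile(priors$sp_cases, u[, 2]),
    se_controls = beta_quantile(priors$se_controls, u[, 3]),
    sp_controls = beta_quantile(priors$sp_controls, u[, 4])
  )
}

#' Summary-level probabilistic bias analysis
#'
#' Repeats the matrix correction of [correct_counts()] with sensitivity and
#' specificity drawn from their Beta priors ([sample_correlated_betas()]).
#' Draws that land outside the identifiability region (`se + sp <= 1`) or
#' produce a non-positive corrected cell are rejected and counted. With
#' `include_random_error` the conventional sampling error is added on the
#' log-OR scale: `log OR_i - z_i * SE_conv`, `z_i` standard normal and
#' `SE_conv` the Woolf standard error of the *observed* table. The retained
#' draws are summarized by their median and central percentile interval
#' (linear interpolation between order statistics).
#'
#' @param obs an [observed_table()].
#' @param priors a [misclass_priors()].
#' @param config a [pba_config()].
#' @return An object of class `pba_result`: `draws` (simulated ORs),
#'   `median`, `lo`, `hi`, `n_rejected`, `level`, `config`.
#' @export
run_pba <- function(obs, priors, config = pba_config()) {
  stopifnot(inherits(obs, "observed_table"), inherits(priors, "misclass_priors"),
            inherits(config, "pba_config"))
  M1 <- obs$a + obs$b
  M0 <- obs$c + obs$d
  if (M1 < 1 || M0 < 1) stop_input("probabilistic bias analysis needs a nonempty table")

  n <- config$n_iter
  sim <- with_seed(config$seed, {
    q <- sample_correlated_betas(priors, config$rho, n, seed = NULL)
    z <- if (config$include_random_error) stats::rnorm(n) else numeric(n)
    list(q = q, z = z)
  })
  q <- sim$q

  denom1 <- q$se_cases + q$sp_cases - 1
  denom0 <- q$se_controls + q$sp_controls - 1
  A <- (obs$a - (1 - q$sp_cases) * M1) / denom1
  B <- M1 - A
  C <- (obs$c - (1 - q$sp_controls) * M0) / denom0
  D <- M0 - C

  ok <- denom1 > 0 & denom0 > 0 & A > 0 & B > 0 & C > 0 & D > 0
  n_rejected <- sum(!ok)
  if (n_rejected == n) {
    stop_input("degenerate probabilistic bias analysis: all %d draws rejected", n)
  }
  lor <- log(A[ok]) - log(B[ok]) - log(C[ok]) + log(D[ok])
  if (config$include_random_error) {
    se_conv <- sqrt(1 / obs$a + 1 / obs$b + 1 / obs$c + 1 / obs$d)
    lor <- lor - sim$z[ok] * se_conv
  }
  draws <- exp(lor)
  alpha <- (1 - config$level) / 2
  qs <- stats::quantile(draws, c(alpha, 0.5, 1 - alpha), names = FALSE, type = 7)
  structure(list(draws = draws, median = qs[2], lo = qs[1], hi = qs[3],
                 n_rejected = n_rejected, level = config$level, config = config),
            class = "pba_result")
}

#' @export
print.pba_result <- function(x, ...) {
  cat(sprintf("Probabilistic bias analysis: %d retained draws (%d rejected)\n",
              length(x$draws), x$n_rejected))
  cat(sprintf("OR median %.3f, %.0f%% simulation interval %.3f-%.3f\n",
              x$median, 100 * x$level, x$lo, x$hi))
  invisible(x)
}
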