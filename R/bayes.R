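#' Bayesian misclassification model specification
#'
#' Binomial likelihood on the apparent exposure counts with latent true
#' prevalences: `a ~ Binomial(M1, q1)` with
#' `q1 = p1 * se_cases + (1 - p1) * (1 - sp_cases)`, and analogously for
#' controls. Priors: independent Betas on the four misclassification
#' probabilities, `p0 ~ Beta(1, 1)` (uniform) on the control prevalence, and
#' a null-centred normal on the log odds ratio whose default SD,
#' `ln(50)/1.96`, makes the prior OR 95% interval (0.02, 50). The case
#' prevalence is derived, `p1 = expit(logit(p0) + theta)`, not a free
#' parameter.
#'
#' @param priors a [misclass_priors()] (point-mass components via
#'   [beta_point()] hold a parameter fixed).
#' @param logor_prior_mean prior mean of the log OR (default 0).
#' @param logor_prior_sd prior SD of the log OR (default `log(50)/qnorm(0.975)`,
#'   approximately 1.996).
#' @param p0_prior Beta prior for the control prevalence (default uniform).
#' @return An object of class `bayes_model`.
#' @export
bayes_model <- function(priors,
                        logor_prior_mean = 0,
                        logor_prior_sd = log(50) / stats::qnorm(0.975),
                        p0_prior = beta_spec(1, 1)) {
  stopifnot(inherits(priors, "misclass_priors"), inherits(p0_prior, "beta_spec"))
  if (!is.numeric(logor_prior_sd) || logor_prior_sd <= 0) {
    stop_input("logor_prior_sd must be positive")
  }
  structure(list(priors = priors,
                 logor_prior_mean = logor_prior_mean,
                 logor_prior_sd = logor_prior_sd,
                 p0_prior = p0_prior),
            class = "bayes_model")
}

#' MCMC run configuration
#'
#' @param n_chains number of independent chains (default 4).
#' @param n_iter iterations per chain including burn-in (default 50000).
#' @param burn_in iterations discarded per chain; step sizes adapt only
#'   during this phase (default 10000).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_iter = 50000L, burn_in = 10000L,
                        thin = 1L, seed = NULL) {
  if (!is_count(n_chains) || n_chains < 1) stop_input("n_chains must be >= 1")
  if (!is_count(n_iter) || n_iter < 1) stop_input("n_iter must be >= 1")
  if (!is_count(burn_in) || burn_in >= n_iter) stop_input("burn_in must satisfy 0 <= burn_in < n_iter")
  if (!is_count(thin) || thin < 1) stop_input("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed),
            class = "mcmc_config")
}

PARAM_NAMES <- c("p0", "theta", "se_cases", "sp_cases", "se_controls", "sp_controls")

#' Log posterior density of the misclassification model
#'
#' Natural-scale density (no transformation Jacobians): binomial log
#' likelihood of the apparent exposed counts plus the log prior densities.
#' States outside the identifiability region (`se + sp <= 1` in either
#' stratum) or with a prevalence outside (0, 1) return `-Inf` rather than
#' raising an error, so samplers can simply reject them.
#'
#' @param state named list or vector with `p0`, `theta`, `se_cases`,
#'   `sp_cases`, `se_controls`, `sp_controls`.
#' @param obs an [observed_table()]; a zero-margin table gives a
#'   priors-only posterior.
#' @param model a [bayes_model()].
#' @return The log posterior density (up to the normalizing constant).
#' @export
log_posterior <- function(state, obs, model) {
  stopifnot(inherits(obs, "observed_table"), inherits(model, "bayes_model"))
  s <- as.list(state)
  p0 <- s$p0; theta <- s$theta
  se1 <- s$se_cases; sp1 <- s$sp_cases
  se0 <- s$se_controls; sp0 <- s$sp_controls
  if (p0 <= 0 || p0 >= 1) return(-Inf)
  if (se1 + sp1 <= 1 || se0 + sp0 <= 1) return(-Inf)
  if (any(c(se1, sp1, se0, sp0) <= 0) || any(c(se1, sp1, se0, sp0) >= 1)) return(-Inf)
  p1 <- expit(logit(p0) + theta)
  if (p1 <= 0 || p1 >= 1) return(-Inf)

  q1 <- p1 * se1 + (1 - p1) * (1 - sp1)
  q0 <- p0 * se0 + (1 - p0) * (1 - sp0)
  M1 <- obs$a + obs$b
  M0 <- obs$c + obs$d
  ll <- stats::dbinom(obs$a, M1, q1, log = TRUE) +
        stats::dbinom(obs$c, M0, q0, log = TRUE)

  pr <- stats::dnorm(theta, model$logor_prior_mean, model$logor_prior_sd, log = TRUE) +
        stats::dbeta(p0, model$p0_prior$alpha, model$p0_prior$beta, log = TRUE)
  vals <- c(se_cases = se1, sp_cases = sp1, se_controls = se0, sp_controls = sp0)
  for (nm in names(vals)) {
    spec <- model$priors[[nm]]
    if (!is_beta_point(spec)) {
      pr <- pr + stats::dbeta(vals[[nm]], spec$alpha, spec$beta, log = TRUE)
    }
  }
  ll + pr
}

# Log posterior on the sampling scale: x = (logit p0, theta, logit se1,
# logit sp1, logit se0, logit sp0), with logit-transform Jacobians for the
# Beta/uniform parameters. `fixed` marks point-mass coordinates whose value
# is carried in `fixed_val` and excluded from the density.
make_logpost_x <- function(obs, model) {
  a <- obs$a; M1 <- obs$a + obs$b
  cc <- obs$c; M0 <- obs$c + obs$d
  pri <- model$priors
  fixed <- vapply(pri, is_beta_point, logical(1))[c("se_cases", "sp_cases",
                                                    "se_controls", "sp_controls")]
  fixed_val <- numeric(4)
  shapes <- matrix(NA_real_, 4, 2)
  for (i in seq_len(4)) {
    nm <- c("se_cases", "sp_cases", "se_controls", "sp_controls")[i]
    if (fixed[i]) fixed_val[i] <- pri[[nm]]$value else {
      shapes[i, ] <- c(pri[[nm]]$alpha, pri[[nm]]$beta)
    }
  }
  a0 <- model$p0_prior$alpha; b0 <- model$p0_prior$beta
  mu <- model$logor_prior_mean; sd <- model$logor_prior_sd

  list(
    fixed = fixed,
    fixed_val = fixed_val,
    lp = function(x) {
      p0 <- expit(x[1])
      theta <- x[2]
      m <- ifelse(fixed, fixed_val, expit(x[3:6]))
      se1 <- m[1]; sp1 <- m[2]; se0 <- m[3]; sp0 <- m[4]
      if (se1 + sp1 <= 1 || se0 + sp0 <= 1) return(-Inf)
      p1 <- expit(x[1] + theta)
      q1 <- p1 * se1 + (1 - p1) * (1 - sp1)
      q0 <- p0 * se0 + (1 - p0) * (1 - sp0)
      out <- stats::dbinom(a, M1, q1, log = TRUE) +
             stats::dbinom(cc, M0, q0, log = TRUE) +
             stats::dnorm(theta, mu, sd, log = TRUE) +
             stats::dbeta(p0, a0, b0, log = TRUE) + log(p0) + log1p(-p0)
      for (i in which(!fixed)) {
        v <- m[i]
        out <- out + stats::dbeta(v, shapes[i, 1], shapes[i, 2], log = TRUE) +
               log(v) + log1p(-v)
      }
      out
    }
  )
}

# Crude starting values: misclassification at prior means (jittered),
# control prevalence back-solved from the apparent exposure proportion.
mcmc_start <- function(obs, model, lpx) {
  pri <- model$priors
  means <- vapply(c("se_cases", "sp_cases", "se_controls", "sp_controls"),
                  function(nm) beta_moments(pri[[nm]])[["mean"]], numeric(1))
  M0 <- obs$c + obs$d
  p0 <- if (M0 >= 1) {
    q0 <- (obs$c + 0.5) / (M0 + 1)
    min(max((q0 - (1 - means[4])) / (means[3] + means[4] - 1), 0.02), 0.98)
  } else {
    stats::runif(1, 0.2, 0.8)
  }
  for (try in seq_len(100)) {
    x <- c(logit(p0) + stats::rnorm(1, 0, 0.3),
           stats::rnorm(1, 0, 0.5),
           logit(means) + stats::rnorm(4, 0, 0.25))
    x[3:6][lpx$fixed] <- 0 # unused coordinates for fixed parameters
    if (is.finite(lpx$lp(x))) return(x)
  }
  stop_input("could not find a finite-density starting state")
}

run_one_chain <- function(obs, model, config, lpx, keep_n) {
  n_iter <- config$n_iter
  burn <- config$burn_in
  thin <- config$thin
  lp <- lpx$lp

  x <- mcmc_start(obs, model, lpx)
  cur <- lp(x)

  blocks <- c(list(c(1L, 2L)), as.list((3:6)[!lpx$fixed]))
  n_blocks <- length(blocks)
  log_step <- rep(log(0.4), n_blocks)
  target <- ifelse(lengths(blocks) > 1, 0.35, 0.44)
  acc_win <- integer(n_blocks)
  n_win <- 0L
  acc_tot <- integer(n_blocks)
  prop_tot <- integer(n_blocks)

  keep <- matrix(NA_real_, nrow = keep_n, ncol = 6L)
  k <- 0L
  for (it in seq_len(n_iter)) {
    for (bi in seq_len(n_blocks)) {
      idx <- blocks[[bi]]
      prop <- x
      prop[idx] <- x[idx] + exp(log_step[bi]) * stats::rnorm(length(idx))
      lp_prop <- lp(prop)
      if (lp_prop - cur > log(stats::runif(1))) {
        x <- prop
        cur <- lp_prop
        acc_win[bi] <- acc_win[bi] + 1L
        acc_tot[bi] <- acc_tot[bi] + 1L
      }
      prop_tot[bi] <- prop_tot[bi] + 1L
    }
    n_win <- n_win + 1L
    if (it <= burn && n_win == 50L) {
      rate <- acc_win / 50
      log_step <- pmin(pmax(log_step + (rate - target), log(1e-4)), log(10))
      acc_win[] <- 0L
      n_win <- 0L
    }
    if (it > burn && (it - burn) %% thin == 0L) {
      k <- k + 1L
      m <- ifelse(lpx$fixed, lpx$fixed_val, expit(x[3:6]))
      keep[k, ] <- c(expit(x[1]), x[2], m)
    }
  }
  colnames(keep) <- PARAM_NAMES
  list(draws = keep[seq_len(k), , drop = FALSE],
       acceptance = acc_tot / pmax(prop_tot, 1L),
       step = exp(log_step))
}

#' Run the blocked Metropolis sampler
#'
#' Component-blocked random-walk Metropolis on transformed scales: the pair
#' (logit control prevalence, log OR) is updated jointly, each
#' non-degenerate sensitivity/specificity separately on the logit scale.
#' Step sizes adapt toward standard acceptance targets during burn-in only,
#' so the post-burn-in kernel is a valid fixed Metropolis kernel. A warning
#' (not an error) is issued if any block's overall acceptance rate falls
#' outside (0.05, 0.95).
#'
#' @param obs an [observed_table()] (a zero-margin table yields a
#'   priors-only run).
#' @param model a [bayes_model()].
#' @param config a [mcmc_config()].
#' @return An object of class `or_mcmc` holding one draws matrix per chain
#'   (columns `p0`, `theta`, `se_cases`, `sp_cases`, `se_controls`,
#'   `sp_controls`), acceptance rates and the configuration.
#' @export
run_mcmc <- function(obs, model, config = mcmc_config()) {
  stopifnot(inherits(obs, "observed_table"), inherits(model, "bayes_model"),
            inherits(config, "mcmc_config"))
  lpx <- make_logpost_x(obs, model)
  keep_n <- (config$n_iter - config$burn_in) %/% config$thin + 1L

  chains <- with_seed(config$seed, {
    lapply(seq_len(config$n_chains), function(i) {
      run_one_chain(obs, model, config, lpx, keep_n)
    })
  })
  acc <- do.call(rbind, lapply(chains, `[[`, "acceptance"))
  if (any(acc < 0.05 | acc > 0.95)) {
    warning("Metropolis acceptance rate outside (0.05, 0.95) after adaptation; ",
            "inspect diagnostics()", call. = FALSE)
  }
  structure(list(chains = lapply(chains, `[[`, "draws"),
                 acceptance = acc,
                 fixed = lpx$fixed,
                 model = model, obs = obs, config = config),
            class = "or_mcmc")
}

#' @export
print.or_mcmc <- function(x, ...) {
  cat(sprintf("Bayesian misclassification adjustment: %d chains x %d kept draws\n",
              length(x$chains), nrow(x$chains[[1]])))
  print(summary(x))
  invisible(x)
}

split_chains <- function(mat_list) {
  out <- list()
  for (m in mat_list) {
    n <- nrow(m)
    h <- n %/% 2L
    out <- c(out, list(m[seq_len(h), , drop = FALSE],
                       m[(n - h + 1L):n, , drop = FALSE]))
  }
  out
}

rhat_one <- function(cols) {
  # cols: list of numeric vectors (split chains), equal length
  m <- length(cols)
  n <- length(cols[[1]])
  means <- vapply(cols, mean, numeric(1))
  vars <- vapply(cols, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# Effective sample size across chains: Geyer initial-monotone truncation of
# the multi-chain autocorrelation estimate (the standard split-chain ESS).
ess_one <- function(cols) {
  m <- length(cols)
  n <- length(cols[[1]])
  vars <- vapply(cols, stats::var, numeric(1))
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  means <- vapply(cols, mean, numeric(1))
  B <- if (m > 1) n * stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B / n

  max_lag <- n - 1L
  acov <- matrix(0, nrow = max_lag + 1L, ncol = m)
  for (j in seq_len(m)) {
    v <- cols[[j]] - means[j]
    nf <- stats::nextn(2L * n)
    f <- stats::fft(c(v, rep(0, nf - n)))
    ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)] / nf
    acov[, j] <- ac / n
  }
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus

  # Geyer: sum of adjacent pairs must stay positive and non-increasing
  tau <- 1
  prev_pair <- Inf
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2L
  }
  max(m * n / tau, 1e-8)
}

#' Convergence diagnostics: split-Rhat and effective sample size
#'
#' Each chain is split in half; the potential scale reduction factor
#' (split-Rhat) and a multi-chain effective sample size are computed per
#' parameter. The run is flagged non-converged if any Rhat exceeds 1.01.
#' Parameters held fixed by point-mass priors are skipped.
#'
#' @param fit an `or_mcmc` object from [run_mcmc()], or a list of draws
#'   matrices with common column names.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, and attribute
#'   `converged`.
#' @export
diagnostics <- function(fit) {
  mats <- if (inherits(fit, "or_mcmc")) fit$chains else fit
  if (!is.list(mats) || length(mats) < 2L) {
    stop_input("diagnostics need at least 2 chains")
  }
  mats <- lapply(mats, as.matrix)
  n <- nrow(mats[[1]])
  if (n < 100L || any(vapply(mats, nrow, integer(1)) != n)) {
    stop_input("diagnostics need >= 100 post-burn-in draws per chain, equal across chains")
  }
  fixed <- if (inherits(fit, "or_mcmc")) {
    c(FALSE, FALSE, fit$fixed)
  } else {
    rep(FALSE, ncol(mats[[1]]))
  }
  pars <- colnames(mats[[1]])
  keep <- which(!fixed)
  halves <- split_chains(mats)
  res <- data.frame(parameter = pars[keep],
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(keep)) {
    cols <- lapply(halves, function(m) m[, keep[i]])
    res$rhat[i] <- rhat_one(cols)
    res$ess[i] <- ess_one(cols)
  }
  attr(res, "converged") <- all(res$rhat < 1.01, na.rm = TRUE)
  res
}

#' Posterior summaries in the standard reporting layout
#'
#' Pools the post-burn-in draws of all chains and reports mean and
#' 2.5/50/97.5 percentiles (linear interpolation) for the odds ratio
#' (`exp(theta)` per draw), the four misclassification probabilities, and
#' the exposure prevalences in cases (`p1`, derived per draw) and controls
#' (`p0`).
#'
#' @param object an `or_mcmc` fit.
#' @param ... unused.
#' @return Data frame (class `posterior_summary`) with rows `or`,
#'   `se_controls`, `se_cases`, `sp_controls`, `sp_cases`, `p0`, `p1` and
#'   columns `mean`, `pct2_5`, `pct50`, `pct97_5`.
#' @export
summary.or_mcmc <- function(object, ...) {
  draws <- do.call(rbind, object$chains)
  p0 <- draws[, "p0"]
  theta <- draws[, "theta"]
  out <- list(
    or = exp(theta),
    se_controls = draws[, "se_controls"],
    se_cases = draws[, "se_cases"],
    sp_controls = draws[, "sp_controls"],
    sp_cases = draws[, "sp_cases"],
    p0 = p0,
    p1 = expit(logit(p0) + theta)
  )
  summ <- t(vapply(out, function(v) {
    c(mean = mean(v),
      stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE, type = 7))
  }, numeric(4)))
  colnames(summ) <- c("mean", "pct2_5", "pct50", "pct97_5")
  res <- as.data.frame(summ)
  res <- cbind(parameter = rownames(summ), res)
  rownames(res) <- NULL
  class(res) <- c("posterior_summary", "data.frame")
  res
}

#' Pooled posterior draws
#'
#' @param fit an `or_mcmc` fit.
#' @return Data frame of pooled post-burn-in draws with an added `or`
#'   column (`exp(theta)`).
#' @export
posterior_draws <- function(fit) {
  stopifnot(inherits(fit, "or_mcmc"))
  draws <- as.data.frame(do.call(rbind, fit$chains))
  draws$or <- exp(draws$theta)
  draws$p1 <- expit(logit(draws$p0) + draws$theta)
  draws
}
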