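# Shared fixtures: the published night-shift validation counts and the Beta
# priors they imply, plus a small study table used by the Bayesian oracles.

table1_cases <- function() validation_crosstab(50, 29, 8, 138, stratum = "cases")

table1_controls <- function() validation_crosstab(374, 218, 90, 1118, stratum = "controls")

table2_priors <- function() priors_from_crosstab(table1_cases(), table1_controls())

# prior means of the four elicited Betas, in sampler order
table2_means <- function() {
  pt <- priors_table(table2_priors())
  stats::setNames(pt$mean, paste(substr(pt$parameter, 1, 2), pt$stratum, sep = "_"))
}

small_study <- function() observed_table(12, 88, 20, 180)

# Independent evaluation of the model density from first principles
# (lchoose/lgamma, no dbinom/dbeta), used as the log_posterior oracle.
logpost_by_hand <- function(state, obs, model) {
  with(as.list(state), {
    if (se_cases + sp_cases <= 1 || se_controls + sp_controls <= 1) return(-Inf)
    p1 <- 1 / (1 + exp(-(log(p0 / (1 - p0)) + theta)))
    q1 <- p1 * se_cases + (1 - p1) * (1 - sp_cases)
    q0 <- p0 * se_controls + (1 - p0) * (1 - sp_controls)
    M1 <- obs$a + obs$b
    M0 <- obs$c + obs$d
    lbinom <- function(k, n, q) lchoose(n, k) + k * log(q) + (n - k) * log1p(-q)
    lbeta_d <- function(x, a, b) {
      (a - 1) * log(x) + (b - 1) * log1p(-x) - (lgamma(a) + lgamma(b) - lgamma(a + b))
    }
    out <- lbinom(obs$a, M1, q1) + lbinom(obs$c, M0, q0) +
      (-0.5 * log(2 * pi) - log(model$logor_prior_sd) -
         0.5 * ((theta - model$logor_prior_mean) / model$logor_prior_sd)^2) +
      lbeta_d(p0, model$p0_prior$alpha, model$p0_prior$beta)
    vals <- c(se_cases = se_cases, sp_cases = sp_cases,
              se_controls = se_controls, sp_controls = sp_controls)
    for (nm in names(vals)) {
      spec <- model$priors[[nm]]
      if (!inherits(spec, "beta_point")) {
        out <- out + lbeta_d(vals[[nm]], spec$alpha, spec$beta)
      }
    }
    out
  })
}

# Exact posterior of (p0, theta) by 2-D grid quadrature when the four
# misclassification probabilities are fixed. Returns posterior means.
quadrature_posterior_means <- function(obs, model, se1, sp1, se0, sp0,
                                       n_p0 = 800L, n_theta = 801L,
                                       theta_range = c(-8, 8)) {
  p0 <- seq(1 / (2 * n_p0), 1 - 1 / (2 * n_p0), length.out = n_p0)
  theta <- seq(theta_range[1], theta_range[2], length.out = n_theta)
  g <- expand.grid(p0 = p0, theta = theta)
  p1 <- 1 / (1 + exp(-(log(g$p0 / (1 - g$p0)) + g$theta)))
  q1 <- p1 * se1 + (1 - p1) * (1 - sp1)
  q0 <- g$p0 * se0 + (1 - g$p0) * (1 - sp0)
  M1 <- obs$a + obs$b
  M0 <- obs$c + obs$d
  lp <- dbinom(obs$a, M1, q1, log = TRUE) + dbinom(obs$c, M0, q0, log = TRUE) +
    dnorm(g$theta, model$logor_prior_mean, model$logor_prior_sd, log = TRUE) +
    dbeta(g$p0, model$p0_prior$alpha, model$p0_prior$beta, log = TRUE)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(p0 = sum(w * g$p0), theta = sum(w * g$theta))
}
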