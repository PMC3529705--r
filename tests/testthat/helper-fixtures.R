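# Small fixtures shared across test files. Everything is built in code.

# Toy 2-compartment chain: stomach-like "a" draining into absorbing "urine".
toy_chain_model <- function() {
  compartmental_model(
    name = "toychain",
    compartments = c("a", "urine"),
    transfers = data.frame(rate = 1, source = "a", target = "urine"),
    entry = "a", terminals = "urine", plasma = "a", bones = character(0))
}

# 3-compartment toy with separate plasma, urine and feces-like sink:
# entry "a" -> plasma "b" (x1); b -> urine (x2). Used where a plasma and a
# urine channel must both exist.
toy_two_channel_model <- function() {
  compartmental_model(
    name = "toy2ch",
    compartments = c("a", "b", "urine"),
    transfers = data.frame(rate = c(1, 2),
                           source = c("a", "b"),
                           target = c("b", "urine")),
    entry = "a", terminals = "urine", plasma = "b", bones = character(0))
}

toy_two_channel_prior <- function() {
  prior_spec(list(
    `1` = list(family = "lognormal", params = list(meanlog = 0, sdlog = 0.5)),
    `2` = list(family = "lognormal", params = list(meanlog = -1, sdlog = 0.5))),
    model_name = "toy2ch")
}

# 1-d lognormal prior for scalar-parameter tests.
prior_1d <- function(meanlog = 0, sdlog = 1) {
  prior_spec(list(`1` = list(family = "lognormal",
                             params = list(meanlog = meanlog, sdlog = sdlog))))
}

# Quick annealing settings for tests.
sa_quick <- function() sa_control(n_temps = 12, n_iter = 60,
                                  polish_maxit = 400)

# Reduced sampler settings for tests.
ctl_quick <- function(n_proposals = 1000, prerun_n = 1500)
  sampler_control(n_proposals = n_proposals, prerun_n = prerun_n,
                  sa = sa_quick())

# Closed-form log evidence of the conjugate toy: y_i ~ N(theta, sigma^2)
# with theta ~ N(mu0, s0^2) truncated to theta > 0.
# Z = m(y) * P_post(theta>0) / P_prior(theta>0), with m(y) the untruncated
# marginal likelihood.
conjugate_log_evidence <- function(y, sigma, mu0, s0) {
  n <- length(y)
  sn2 <- 1 / (n / sigma^2 + 1 / s0^2)
  mun <- sn2 * (sum(y) / sigma^2 + mu0 / s0^2)
  log_m <- sum(stats::dnorm(y, mu0, sqrt(sigma^2), log = TRUE)) # placeholder
  # exact untruncated marginal: y ~ N(mu0 * 1, sigma^2 I + s0^2 J)
  # computed via the standard decomposition:
  log_m <- -n / 2 * log(2 * pi) - n * log(sigma) - 0.5 * log(1 + n * s0^2 / sigma^2) -
    0.5 * (sum((y - mean(y))^2) / sigma^2 +
             n * (mean(y) - mu0)^2 / (sigma^2 + n * s0^2))
  log_m + stats::pnorm(0, mun, sqrt(sn2), lower.tail = FALSE, log.p = TRUE) -
    stats::pnorm(0, mu0, s0, lower.tail = FALSE, log.p = TRUE)
}

# Truncated-normal prior spec for the conjugate toy.
prior_normal_1d <- function(mu0, s0) {
  prior_spec(list(`1` = list(family = "normal",
                             params = list(mean = mu0, sd = s0))))
}

# Vectorised conjugate-toy log likelihood factory.
conjugate_loglik <- function(y, sigma) {
  function(X) {
    th <- X[, 1]
    vapply(th, function(t) sum(stats::dnorm(y, t, sigma, log = TRUE)),
           numeric(1))
  }
}
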