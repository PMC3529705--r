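test_that("temperature schedule follows the fifth-power ladder", {
  s <- make_schedule(30)
  expect_length(s, 30)
  expect_equal(s[1], 0)
  expect_equal(s[30], 1)
  expect_equal(s[2], (1 / 29)^5)
  expect_true(all(diff(s) > 0))
  expect_equal(as.numeric(make_schedule(2)), c(0, 1))
  expect_error(make_schedule(1), "at least 2")
})

test_that("power posterior interpolates prior and posterior", {
  expect_equal(log_power_posterior(0, -10, -2), -2)
  expect_equal(log_power_posterior(1, -10, -2), -12)
  expect_equal(log_power_posterior(0.5, -10, -2), -7)
  expect_error(log_power_posterior(1.5, -10, -2), "\\[0, 1\\]")
})

test_that("constant likelihood yields that constant as log evidence", {
  p1 <- prior_1d(0, 1)
  ev <- suppressWarnings(
    ti_evidence(function(X) rep(-3.7, nrow(X)), p1,
                schedule = make_schedule(5),
                control = ctl_quick(n_proposals = 300, prerun_n = 400),
                seed = 1))
  expect_equal(ev$log_evidence, -3.7, tolerance = 1e-9)
})

test_that("TI recovers the closed-form evidence of a conjugate toy", {
  mu0 <- 2; s0 <- 1; sigma <- 0.8
  set.seed(21)
  y <- stats::rnorm(12, 1.5, sigma)
  exact <- conjugate_log_evidence(y, sigma, mu0, s0)
  pn <- prior_normal_1d(mu0, s0)
  ev <- ti_evidence(conjugate_loglik(y, sigma), pn,
                    schedule = make_schedule(30),
                    control = ctl_quick(n_proposals = 3000,
                                        prerun_n = 2000),
                    seed = 22)
  expect_lt(abs(ev$log_evidence - exact), 0.1)
  # tempered expectations are nondecreasing within MC noise
  slack <- 2 * ifelse(is.na(ev$E_se), 0, ev$E_se)
  expect_true(all(diff(ev$E_n) > -(slack[-1] + slack[-length(slack)])))
})

test_that("TI matches brute-force quadrature for a 1-parameter model", {
  # evidence integral computed on a fine grid for a lognormal prior and a
  # single-exponential decay likelihood
  p1 <- prior_1d(0, 0.5)
  tt <- c(0.4, 1, 2, 4)
  lam_true <- 1.2
  set.seed(31)
  yobs <- 100 * exp(-lam_true * tt) + stats::rnorm(length(tt), 0, 3)
  ll1 <- function(X)
    vapply(X[, 1], function(l)
      sum(stats::dnorm(yobs, 100 * exp(-l * tt), 3, log = TRUE)),
      numeric(1))
  grid <- seq(1e-4, 8, length.out = 200001)
  integrand <- exp(ll1(matrix(grid, ncol = 1)) +
                     stats::dlnorm(grid, 0, 0.5, log = TRUE))
  exact <- log(sum(integrand) * diff(grid[1:2]))
  # a larger defensive weight keeps the low-temperature (prior-like)
  # chains well covered by the independence proposal
  ev <- ti_evidence(ll1, p1, schedule = make_schedule(30),
                    control = sampler_control(n_proposals = 5000,
                                              prerun_n = 3000,
                                              defensive = 0.2,
                                              sa = sa_quick()),
                    seed = 32)
  expect_lt(abs(ev$log_evidence - exact), 0.05)
})

test_that("evidence penalises a spurious extra parameter", {
  # data from the 1-parameter decay model; the 2-parameter supermodel adds
  # an amplitude with a wide prior and must pay an Occam penalty
  tt <- c(0.4, 1, 2, 4)
  set.seed(41)
  yobs <- 100 * exp(-1.2 * tt) + stats::rnorm(length(tt), 0, 2)
  p1 <- prior_1d(0, 0.5)
  ll1 <- function(X)
    vapply(X[, 1], function(l)
      sum(stats::dnorm(yobs, 100 * exp(-l * tt), 2, log = TRUE)),
      numeric(1))
  p2 <- prior_spec(list(
    `1` = list(family = "lognormal", params = list(meanlog = 0, sdlog = 0.5)),
    `2` = list(family = "lognormal", params = list(meanlog = log(100),
                                                   sdlog = 2))))
  ll2 <- function(X)
    vapply(seq_len(nrow(X)), function(i)
      sum(stats::dnorm(yobs, X[i, 2] * exp(-X[i, 1] * tt), 2, log = TRUE)),
      numeric(1))
  ev1 <- ti_evidence(ll1, p1, schedule = make_schedule(15),
                     control = ctl_quick(n_proposals = 2000,
                                         prerun_n = 2500), seed = 42)
  ev2 <- suppressWarnings(
    ti_evidence(ll2, p2, schedule = make_schedule(15),
                control = ctl_quick(n_proposals = 2000, prerun_n = 2500),
                seed = 43))
  expect_gt(ev1$log_evidence, ev2$log_evidence)
})

test_that("Bayes factor arithmetic and Jeffreys interpretation", {
  mk <- function(logz, model = "A", fp = "fp") {
    structure(list(model = model, log_evidence = logz, se = 0.01,
                   fingerprint = fp), class = "evidence_result")
  }
  # equal evidences: BF exactly 1
  expect_equal(bayes_factor(mk(-100), mk(-100, "B"))$bf, 1)
  # swapping arguments inverts the BF exactly
  b1 <- bayes_factor(mk(-100), mk(-103, "B"))
  b2 <- bayes_factor(mk(-103, "B"), mk(-100))
  expect_equal(b1$bf, exp(3))
  expect_equal(b1$bf * b2$bf, 1, tolerance = 1e-12)
  # mismatched datasets rejected
  expect_error(bayes_factor(mk(-1), mk(-2, "B", fp = "other")),
               "different datasets")

  expect_equal(interpret_bf(150), "decisive")
  expect_equal(interpret_bf(5), "substantial")
  expect_equal(interpret_bf(2), "not worth more than a bare mention")
  expect_equal(interpret_bf(0.2), "substantial (denominator)")
  expect_equal(interpret_bf(0.005), "decisive (denominator)")
  expect_error(interpret_bf(-1), "positive")
})

test_that("evidence is channel-consistent on plasma-only data", {
  # a dataset with an empty urine channel: 'both' and 'plasma' agree
  # exactly (identical likelihood factors, identical chains)
  m <- zr_model("hmgu"); p <- zr_prior("hmgu")
  set.seed(51)
  r <- rate_vector(m, rprior(p, 1)[1, ])
  sch <- sampling_schedule()
  ivp <- generate_investigation(m, r, sigmas = c(0.005, 0), seed = 52)
  ivp$urine <- ivp$urine[0, ]
  noise <- noise_params(0.005, NA)
  mp <- map_estimate(m, ivp, p, noise, channels = "plasma",
                     control = sa_quick(), seed = 53)
  ctl <- ctl_quick(n_proposals = 400, prerun_n = 600)
  ev_b <- suppressWarnings(
    estimate_evidence(m, ivp, p, noise, schedule = make_schedule(5),
                      control = ctl, channels = "both", seed = 54,
                      map = mp))
  ev_p <- suppressWarnings(
    estimate_evidence(m, ivp, p, noise, schedule = make_schedule(5),
                      control = ctl, channels = "plasma", seed = 54,
                      map = mp))
  expect_equal(ev_b$log_evidence, ev_p$log_evidence, tolerance = 1e-12)
})
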