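#' Fifth-power temperature schedule
#'
#' tau_n = ((n-1)/(N-1))^5 for n = 1..N: a ladder from the prior (tau = 0)
#' to the posterior (tau = 1), concentrated near zero where the
#' power-posterior expectation of the log likelihood changes fastest.
#'
#' @param N number of temperatures (default 30).
#' @return an object of class `temperature_schedule` (numeric vector of
#'   temperatures).
#' @export
make_schedule <- function(N = 30) {
  if (N < 2) stop("need at least 2 temperatures")
  structure(((seq_len(N) - 1) / (N - 1))^5, class = "temperature_schedule")
}

#' Unnormalised log power posterior
#'
#' tau * log likelihood + log prior: the prior at tau = 0, the full
#' posterior at tau = 1.
#'
#' @param tau temperature in `[0, 1]`.
#' @param log_lik,log_prior log likelihood and log prior values.
#' @return numeric.
#' @export
log_power_posterior <- function(tau, log_lik, log_prior) {
  if (any(tau < 0 | tau > 1)) stop("tau must lie in [0, 1]")
  tau * log_lik + log_prior
}

# batch-means Monte Carlo standard error of the mean of v
batch_se <- function(v, n_batches = 30) {
  v <- v[is.finite(v)]
  if (length(v) < 2 * n_batches) n_batches <- max(2, length(v) %/% 10)
  if (length(v) < 4) return(NA_real_)
  b <- floor(length(v) / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(i) mean(v[((i - 1) * b + 1):(i * b)]), numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

#' Sampler settings for evidence estimation
#'
#' @param n_proposals copula-MH proposals per temperature (study-scale
#'   default 30000; tests use far fewer).
#' @param prerun_n length of the unthinned adaptive prerun on which the
#'   copula proposal is fitted (study-scale runs used much longer preruns).
#' @param defensive defensive mixture weight of the proposal.
#' @param sa an [sa_control()] for the MAP initialisation.
#' @return list of class `sampler_control`.
#' @export
sampler_control <- function(n_proposals = 30000, prerun_n = 100000,
                            defensive = 0.05, sa = sa_control()) {
  structure(list(n_proposals = n_proposals, prerun_n = prerun_n,
                 defensive = defensive, sa = sa),
            class = "sampler_control")
}

# deterministic 31-bit seed derivation from a master seed and labels
derive_seed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

dataset_fingerprint <- function(invs, channels) {
  if (inherits(invs, "investigation")) invs <- list(invs)
  paste(channels,
        paste(vapply(invs, function(iv)
          sprintf("%s:%d:%d:%.6g:%.6g", iv$id, nrow(iv$plasma),
                  nrow(iv$urine),
                  sum(iv$plasma$value), sum(iv$urine$value)),
          character(1)), collapse = ";"))
}

#' Estimate the log marginal likelihood by thermodynamic integration
#'
#' For each temperature of the schedule an independent copula-MH chain is
#' run on the power posterior (initialised at the MAP estimate; one copula
#' proposal fitted once per model/dataset from an adaptive prerun of the
#' tau = 1 posterior). The expectation of the log likelihood under each
#' power posterior is the chain mean over all post-init samples, and the
#' expectations are combined by the trapezoidal rule over the ladder. The
#' Monte Carlo standard error is propagated from per-temperature
#' batch-means SEs through the trapezoid weights.
#'
#' @param model a `compartmental_model`.
#' @param invs an `investigation` or list (concatenated analysis).
#' @param prior a `prior_spec` for the model.
#' @param noise a [noise_params()] (typically from [fit_noise()]).
#' @param schedule a [make_schedule()] ladder.
#' @param control a [sampler_control()].
#' @param channels channel selection as in [log_likelihood()].
#' @param seed master seed; per-temperature seeds are derived from it.
#' @param map optional precomputed MAP `rate_vector` (skips the annealing).
#' @param proposal optional precomputed `copula_proposal` (skips the
#'   prerun).
#' @return an object of class `evidence_result`: `log_evidence`, `se`,
#'   per-temperature expectations `E_n` with SEs, acceptance rates, ESS,
#'   and metadata.
#' @export
estimate_evidence <- function(model, invs, prior, noise,
                              schedule = make_schedule(30),
                              control = sampler_control(),
                              channels = "both", seed = 1,
                              map = NULL, proposal = NULL) {
  channels <- match.arg(channels, c("both", "plasma", "urine"))
  ll <- make_loglik(model, invs, noise, channels)$loglik
  if (is.null(map))
    map <- map_estimate(model, invs, prior, noise, channels,
                        control = control$sa,
                        seed = derive_seed(seed, model$name, "map"))
  ev <- ti_evidence(ll, prior, schedule = schedule, control = control,
                    seed = seed, init = as.numeric(map),
                    proposal = proposal, label = model$name)
  ev$channels <- channels
  ev$fingerprint <- dataset_fingerprint(invs, channels)
  ev
}

#' Thermodynamic integration for a generic likelihood
#'
#' The engine behind [estimate_evidence()], usable with any vectorised log
#' likelihood over the parameter space of a `prior_spec`: runs one
#' independence copula-MH chain per temperature of the ladder on the power
#' posterior, averages the log likelihood over all post-init samples
#' (Monte Carlo estimate of the power-posterior expectation), and combines
#' the per-temperature expectations with the trapezoidal rule.
#'
#' @param log_lik function mapping a matrix of parameter vectors (rows,
#'   columns in prior order) to a vector of log likelihoods.
#' @param prior a `prior_spec`.
#' @param schedule a [make_schedule()] ladder.
#' @param control a [sampler_control()].
#' @param seed master seed (per-temperature seeds derived from it).
#' @param init starting parameter vector (default: componentwise prior
#'   modes); chains are all initialised here, normally the MAP.
#' @param proposal optional prefitted `copula_proposal`; otherwise fitted
#'   on an adaptive prerun of the tau = 1 posterior.
#' @param label model label stored in the result.
#' @return an `evidence_result`.
#' @export
ti_evidence <- function(log_lik, prior, schedule = make_schedule(30),
                        control = sampler_control(), seed = 1,
                        init = NULL, proposal = NULL, label = "model") {
  ks <- names(prior$priors)
  if (is.null(init)) init <- as.numeric(prior_modes(prior))
  if (is.null(proposal)) {
    pre <- prerun_chain(function(x) {
      lp <- log_prior(prior, stats::setNames(x, ks))
      if (!is.finite(lp)) return(-Inf)
      lp + log_lik(matrix(x, nrow = 1))
    }, prior, init = init, n = control$prerun_n,
    seed = derive_seed(seed, label, "prerun"))
    proposal <- fit_copula(pre, prior, defensive = control$defensive)
  }
  taus <- as.numeric(schedule)
  E <- SE <- acc <- ess <- numeric(length(taus))
  warn_low_ess <- character(0)
  for (n in seq_along(taus)) {
    tau <- taus[n]
    lt <- function(X) {
      X <- as_prior_matrix(X, prior)
      lp <- log_prior(prior, X)
      lk <- rep(-Inf, nrow(X))
      ok <- is.finite(lp)
      if (any(ok)) lk[ok] <- log_lik(X[ok, , drop = FALSE])
      list(lp = ifelse(ok & is.finite(lk),
                       log_power_posterior(tau, lk, lp),
                       ifelse(ok & tau == 0, lp, -Inf)),
           ll = lk)
    }
    ch <- run_chain(lt, proposal, control$n_proposals, init,
                    seed = derive_seed(seed, label, "tau", n), tau = tau)
    E[n] <- mean(ch$log_lik[is.finite(ch$log_lik)])
    SE[n] <- batch_se(ch$log_lik)
    acc[n] <- ch$acceptance_rate
    ess[n] <- effective_sample_size(ch)
    if (ess[n] < 10) warn_low_ess <- c(warn_low_ess, sprintf("tau=%g", tau))
  }
  w <- numeric(length(taus))
  dt <- diff(taus)
  w[-length(w)] <- w[-length(w)] + dt / 2
  w[-1] <- w[-1] + dt / 2
  logZ <- sum(w * E)
  se <- sqrt(sum((w * SE)^2))
  if (length(warn_low_ess))
    warning("low ESS (<10) at ", paste(warn_low_ess, collapse = ", "))
  structure(list(model = label, log_evidence = logZ, se = se,
                 taus = taus, E_n = E, E_se = SE,
                 acceptance = acc, ess = ess,
                 n_proposals = control$n_proposals, seed = seed,
                 channels = NA_character_,
                 fingerprint = NA_character_,
                 low_ess = warn_low_ess),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("<evidence_result> model %s (%s): log evidence %.3f (MC se %.3f)\n",
              x$model, x$channels, x$log_evidence, x$se))
  cat(sprintf("  %d temperatures, %d proposals each; acceptance %.2f +/- %.2f, ESS %.0f +/- %.0f\n",
              length(x$taus), x$n_proposals, mean(x$acceptance),
              stats::sd(x$acceptance) / sqrt(length(x$acceptance)),
              mean(x$ess), stats::sd(x$ess) / sqrt(length(x$ess))))
  invisible(x)
}

#' Bayes factor from two evidence estimates
#'
#' BF = exp(log evidence of `ev_k` - log evidence of `ev_kprime`). With a
#' uniform model prior (no initial preference between models) the Bayes
#' factor equals the posterior odds. Both evidences must refer to the same
#' dataset and channel selection.
#'
#' @param ev_k,ev_kprime `evidence_result`s for the numerator and
#'   denominator model.
#' @return an object of class `bayes_factor_result`: `bf`, `log10_bf`,
#'   `category` (Jeffreys label from [interpret_bf()]), model names.
#' @export
bayes_factor <- function(ev_k, ev_kprime) {
  if (!identical(ev_k$fingerprint, ev_kprime$fingerprint))
    stop("evidences were computed on different datasets or channels")
  logbf <- ev_k$log_evidence - ev_kprime$log_evidence
  bf <- exp(logbf)
  structure(list(numerator = ev_k$model, denominator = ev_kprime$model,
                 bf = bf, log_bf = logbf, log10_bf = logbf / log(10),
                 se = sqrt(ev_k$se^2 + ev_kprime$se^2),
                 category = interpret_bf(bf)),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("<bayes_factor> B(%s,%s) = %.4g (log10 %.2f): %s\n",
              x$numerator, x$denominator, x$bf, x$log10_bf, x$category))
  invisible(x)
}

#' Jeffreys interpretation of a Bayes factor
#'
#' B > 100: decisive support for the numerator model; B > 3: substantial;
#' 1 <= B <= 3: not worth more than a bare mention. For B < 1 the
#' reciprocal is interpreted for the denominator model.
#'
#' @param bf positive Bayes factor (or a `bayes_factor_result`).
#' @return character label.
#' @export
interpret_bf <- function(bf) {
  if (inherits(bf, "bayes_factor_result")) bf <- bf$bf
  if (!is.numeric(bf) || bf <= 0) stop("Bayes factor must be positive")
  if (bf < 1) return(paste0(interpret_bf(1 / bf), " (denominator)"))
  if (bf > 100) "decisive"
  else if (bf > 3) "substantial"
  else "not worth more than a bare mention"
}
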