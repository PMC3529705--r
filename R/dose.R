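# Predicted urine excretion rate (% of a unit intake per day) at times t
# for each posterior rate vector; rows = samples, columns = times.
predicted_excretion <- function(model, rate_samples, times) {
  if (is.matrix(rate_samples))
    rate_samples <- lapply(seq_len(nrow(rate_samples)),
                           function(i) rate_samples[i, ])
  if (!length(rate_samples)) stop("empty posterior sample list")
  out <- vapply(rate_samples, function(x) {
    r <- rate_vector(model, x)
    tra <- solve_trajectory(model, r, times)
    urine_excretion_rate(model, r, tra)
  }, numeric(length(times)))
  if (is.matrix(out)) t(out) else matrix(out, ncol = 1)
}

#' Retrospective intake estimate from a urine measurement
#'
#' By linearity of the compartmental ODEs, a measured urinary excretion
#' rate at time t after an (unobserved) ingestion scales one-to-one with
#' the ingested amount: for each posterior rate vector x the implied
#' intake is `measurement * 100 / predicted_rate_x(t)`, where
#' `predicted_rate_x(t)` is the model's excretion rate (\%/day) for a
#' 100\% reference intake. The posterior sample of implied intakes yields
#' the median and a 90\% credible interval.
#'
#' @param posterior matrix or list of posterior rate vectors.
#' @param model a `compartmental_model`.
#' @param t time of the measurement (days, > 0).
#' @param measurement measured urinary excretion rate (mass/day, > 0); the
#'   intake is returned in the same mass unit.
#' @param level credibility level (default 0.90).
#' @return object of class `intake_estimate`: `lower`, `median`, `upper`,
#'   `n_skipped` (samples with nonpositive predicted rate).
#' @export
intake_from_urine <- function(posterior, model, t, measurement,
                              level = 0.90) {
  if (measurement <= 0) stop("measurement must be positive")
  if (t <= 0) stop("measurement time must be positive")
  pr <- predicted_excretion(model, posterior, t)[, 1]
  bad <- !(pr > 0)
  if (all(bad)) stop("all samples predict nonpositive excretion rate")
  intakes <- measurement * 100 / pr[!bad]
  a <- (1 - level) / 2
  q <- stats::quantile(intakes, probs = c(a, 0.5, 1 - a), names = FALSE,
                       type = 7)
  structure(list(time = t, measurement = measurement, level = level,
                 lower = q[1], median = q[2], upper = q[3],
                 n_skipped = sum(bad)),
            class = "intake_estimate")
}

#' @export
print.intake_estimate <- function(x, ...) {
  cat(sprintf("<intake_estimate> measurement %g/d at t=%g d: median %g, %g%% CI [%g, %g]%s\n",
              x$measurement, x$time, x$median, 100 * x$level, x$lower,
              x$upper,
              if (x$n_skipped) sprintf(" (%d samples skipped)", x$n_skipped)
              else ""))
  invisible(x)
}

#' Extrapolation-factor table for retrospective intake assessment
#'
#' Dimensionless multipliers turning a urinary excretion-rate measurement
#' (mass/day) at time t into bounds on the ingested amount (same mass
#' unit): at each grid time the 5\% (lbf), 50\% (mf) and 95\% (ubf)
#' posterior quantiles of `100 / predicted_rate_x(t)`.
#'
#' @param posterior matrix or list of posterior rate vectors.
#' @param model a `compartmental_model`.
#' @param times_h grid of measurement times in hours (default 6 h to 60 h
#'   in 6 h steps).
#' @return data frame of class `extrapolation_table` with columns
#'   `time_h`, `lbf`, `mf`, `ubf`.
#' @export
extrapolation_table <- function(posterior, model,
                                times_h = seq(6, 60, by = 6)) {
  td <- times_h / 24
  pr <- predicted_excretion(model, posterior, td)
  out <- data.frame(time_h = times_h, lbf = NA_real_, mf = NA_real_,
                    ubf = NA_real_)
  for (j in seq_along(td)) {
    f <- 100 / pr[pr[, j] > 0, j]
    q <- stats::quantile(f, probs = c(0.05, 0.5, 0.95), names = FALSE,
                         type = 7)
    out$lbf[j] <- q[1]; out$mf[j] <- q[2]; out$ubf[j] <- q[3]
  }
  class(out) <- c("extrapolation_table", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of posterior marginals
#'
#' Compares one-parameter posterior samples between two investigations
#' (e.g. the marginal of a shared transfer rate) with the two-sample KS
#' test (asymptotic p-value).
#'
#' @param samples_a,samples_b numeric sample vectors.
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_marginal_comparison <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b)) stop("empty sample(s)")
  if (length(samples_a) < 5 || length(samples_b) < 5)
    warning("fewer than 5 samples on one side; KS comparison unreliable")
  kt <- suppressWarnings(stats::ks.test(samples_a, samples_b))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Kendall rank correlation between two sampled parameters
#'
#' Kendall's tau between two columns of an MCMC sample (e.g. the x7-x8
#' dependence visible in the preruns), with a batch standard error.
#'
#' @param samples matrix of samples (rows = draws) or `mcmc_chain`.
#' @param pair length-2 vector of column names or indices.
#' @param n_batches batches for the standard error.
#' @return list with `tau` and `se`.
#' @export
kendall_tau <- function(samples, pair, n_batches = 10) {
  X <- if (inherits(samples, "mcmc_chain")) samples$samples else samples
  if (nrow(X) < 2) stop("need at least 2 samples")
  a <- X[, pair[1]]; b <- X[, pair[2]]
  if (length(unique(a)) == 1 || length(unique(b)) == 1)
    stop("ties-only data: Kendall tau undefined")
  tau <- stats::cor(a, b, method = "kendall")
  se <- NA_real_
  if (nrow(X) >= 2 * n_batches) {
    bsz <- floor(nrow(X) / n_batches)
    bt <- vapply(seq_len(n_batches), function(i) {
      ix <- ((i - 1) * bsz + 1):(i * bsz)
      suppressWarnings(stats::cor(a[ix], b[ix], method = "kendall"))
    }, numeric(1))
    se <- stats::sd(bt, na.rm = TRUE) / sqrt(n_batches)
  }
  list(tau = tau, se = se)
}
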