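# -- marginal conversion ------------------------------------------------------

#' Convert samples to/from the unit hypercube via the prior CDFs
#'
#' Componentwise application of each rate's zero-truncated prior CDF
#' (`to_uniform`) or inverse CDF (`from_uniform`); the round trip is the
#' identity on the prior support. This is the marginal-conversion step of
#' the copula proposal: dependence is modelled on the uniform scale while
#' the marginals are carried by the priors.
#'
#' @param samples numeric matrix (one sample per row; columns in the order
#'   of `names(prior$priors)`, or named by rate index).
#' @param u matrix of values in `[0,1]^d`.
#' @param prior a `prior_spec`.
#' @return matrix of the same shape.
#' @export
to_uniform <- function(samples, prior) {
  samples <- as_prior_matrix(samples, prior)
  ks <- names(prior$priors)
  if (any(samples < 0))
    stop("value outside support for parameter ",
         ks[which(apply(samples < 0, 2, any))[1]])
  U <- samples
  for (j in seq_along(ks))
    U[, j] <- prior_cdf1(samples[, j], prior$priors[[ks[j]]])
  U
}

#' @rdname to_uniform
#' @export
from_uniform <- function(u, prior) {
  u <- as_prior_matrix(u, prior)
  ks <- names(prior$priors)
  X <- u
  for (j in seq_along(ks))
    X[, j] <- prior_quantile1(u[, j], prior$priors[[ks[j]]])
  X
}

as_prior_matrix <- function(x, prior) {
  ks <- names(prior$priors)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(ks)) stop("expected ", length(ks), " columns")
  if (!is.null(colnames(x))) x <- x[, ks, drop = FALSE]
  colnames(x) <- ks
  x
}

# -- Gaussian-copula proposal -------------------------------------------------

# Small multivariate-normal helpers via Cholesky (no external dependency).
chol_safe <- function(S) {
  for (eps in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("covariance not positive definite")
}

dmvnorm_log <- function(Z, mean, cholS) {
  d <- ncol(Z)
  W <- backsolve(cholS, t(Z) - mean, transpose = TRUE)
  -0.5 * colSums(W^2) - sum(log(diag(cholS))) - 0.5 * d * log(2 * pi)
}

#' Fit the copula proposal from prerun samples
#'
#' Prerun samples are converted to the unit hypercube through the prior
#' CDFs and then to normal scores; a Gaussian dependence model (mean and
#' covariance of the normal scores) is fitted. With Gaussian pair families
#' a pair-copula construction collapses to exactly this Gaussian copula, so
#' the fitted object is the default pair-copula proposal. A small
#' *defensive* mixture component (standard-normal scores, i.e. the prior
#' itself) keeps the independence proposal supported over the whole prior,
#' which stabilises sampling of the flat low-temperature power posteriors.
#'
#' @param prerun_samples matrix of prerun draws (rows = samples, columns =
#'   rates in prior order).
#' @param prior a `prior_spec`.
#' @param defensive weight in `[0, 1)` of the prior-shaped mixture
#'   component (default 0.05).
#' @param inflate multiplicative inflation of the fitted normal-scores
#'   covariance (default 1.2): an independence proposal slightly wider than
#'   the target mixes better than one slightly narrower, which matters when
#'   the prerun is short.
#' @return an object of class `copula_proposal` with fitted mean,
#'   covariance, and Kendall-tau matrix implied by the Gaussian dependence.
#' @export
fit_copula <- function(prerun_samples, prior, defensive = 0.05,
                       inflate = 1.2) {
  X <- as_prior_matrix(prerun_samples, prior)
  d <- ncol(X)
  if (nrow(X) < d + 1) stop("need at least d+1 prerun samples")
  sds <- apply(X, 2, stats::sd)
  if (any(!is.finite(sds)) || any(sds == 0))
    stop("degenerate (constant) prerun marginal for parameter ",
         colnames(X)[which(sds == 0)[1]])
  U <- to_uniform(X, prior)
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  Z <- stats::qnorm(U)
  m <- colMeans(Z)
  S <- stats::cov(Z) * inflate
  R <- stats::cov2cor(S)
  structure(list(prior = prior, mean = m, cov = S, chol = chol_safe(S),
                 kendall_tau = (2 / pi) * asin(pmin(pmax(R, -1), 1)),
                 defensive = defensive,
                 fitted_from = list(n = nrow(X))),
            class = "copula_proposal")
}

#' @export
print.copula_proposal <- function(x, ...) {
  cat(sprintf("<copula_proposal> d=%d, fitted on %d samples, defensive %.2f\n",
              length(x$mean), x$fitted_from$n, x$defensive))
  invisible(x)
}

#' Draw from / evaluate the copula proposal
#'
#' `rproposal` draws rate vectors: normal scores from the fitted Gaussian
#' (or, with probability `defensive`, standard-normal scores), mapped
#' through the probability scale and the prior inverse CDFs.
#' `dproposal_log` evaluates the matching log density.
#'
#' @param proposal a `copula_proposal`.
#' @param n number of draws.
#' @param x matrix of rate vectors (rows).
#' @return `rproposal`: n x d matrix; `dproposal_log`: numeric vector.
#' @export
rproposal <- function(proposal, n) {
  d <- length(proposal$mean)
  Z <- matrix(stats::rnorm(n * d), n, d)
  use_def <- stats::runif(n) < proposal$defensive
  Zm <- Z %*% proposal$chol + rep(proposal$mean, each = n)
  Zm[use_def, ] <- Z[use_def, , drop = FALSE]
  U <- pmin(pmax(stats::pnorm(Zm), 1e-12), 1 - 1e-12)
  X <- from_uniform(U, proposal$prior)
  colnames(X) <- names(proposal$prior$priors)
  X
}

#' @rdname rproposal
#' @export
dproposal_log <- function(proposal, x) {
  X <- as_prior_matrix(x, proposal$prior)
  U <- to_uniform(X, proposal$prior)
  U <- pmin(pmax(U, 1e-12), 1 - 1e-12)
  Z <- stats::qnorm(U)
  lg <- dmvnorm_log(Z, proposal$mean, proposal$chol)
  l0 <- rowSums(stats::dnorm(Z, log = TRUE))
  b <- proposal$defensive
  mix <- if (b > 0) {
    mx <- pmax(lg, l0)
    mx + log((1 - b) * exp(lg - mx) + b * exp(l0 - mx))
  } else lg
  # Jacobian of z = qnorm(F(x)): prior density over standard-normal density
  lp <- log_prior(proposal$prior, X)
  mix - l0 + lp
}

# -- chains -------------------------------------------------------------------

#' Run an independence Metropolis-Hastings chain with a copula proposal
#'
#' Proposals are drawn independently from the fitted copula proposal and
#' accepted with probability min(1, pi(x') q(x) / (pi(x) q(x'))). On
#' rejection the current state is repeated, so the returned chain has
#' exactly `n_proposals` rows.
#'
#' @param log_target function taking a matrix of rate vectors (rows) and
#'   returning either a numeric vector of log target densities or a list
#'   with elements `lp` (log target) and `ll` (log likelihood, recorded in
#'   the chain for thermodynamic integration).
#' @param proposal a `copula_proposal`.
#' @param n_proposals chain length.
#' @param init starting rate vector (must have finite log target).
#' @param seed integer seed.
#' @param tau temperature label stored with the chain.
#' @return an object of class `mcmc_chain`: `samples` (matrix),
#'   `log_posterior` trace, `log_lik` trace (if provided), `acceptance_rate`,
#'   `seed`, `tau`.
#' @export
run_chain <- function(log_target, proposal, n_proposals, init, seed = NULL,
                      tau = NA_real_) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(proposal$mean)
  init <- as.numeric(init)
  ev <- function(X) {
    r <- log_target(X)
    if (is.list(r)) r else list(lp = r, ll = rep(NA_real_, nrow(X)))
  }
  t0 <- ev(matrix(init, nrow = 1))
  if (!is.finite(t0$lp)) stop("log target not finite at init")
  P <- rproposal(proposal, n_proposals)
  lq <- dproposal_log(proposal, P)
  tp <- ev(P)
  lq0 <- dproposal_log(proposal, matrix(init, nrow = 1))
  samples <- matrix(NA_real_, n_proposals, d,
                    dimnames = list(NULL, colnames(P)))
  lp_tr <- numeric(n_proposals); ll_tr <- numeric(n_proposals)
  cur <- init; lp_cur <- t0$lp; ll_cur <- t0$ll; lq_cur <- lq0
  un <- stats::runif(n_proposals)
  acc <- 0L
  for (i in seq_len(n_proposals)) {
    la <- (tp$lp[i] + lq_cur) - (lp_cur + lq[i])
    if (is.finite(la) && (la >= 0 || un[i] < exp(la))) {
      cur <- P[i, ]; lp_cur <- tp$lp[i]; ll_cur <- tp$ll[i]; lq_cur <- lq[i]
      acc <- acc + 1L
    }
    samples[i, ] <- cur; lp_tr[i] <- lp_cur; ll_tr[i] <- ll_cur
  }
  if (acc == 0L) warning("no accepted moves in chain (tau=", tau, ")")
  structure(list(samples = samples, log_posterior = lp_tr,
                 log_lik = ll_tr, acceptance_rate = acc / n_proposals,
                 seed = seed, tau = tau),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %d x %d, acceptance %.2f%s\n",
              nrow(x$samples), ncol(x$samples), x$acceptance_rate,
              if (is.finite(x$tau)) sprintf(", tau=%g", x$tau) else ""))
  invisible(x)
}

#' Autocorrelation-based effective sample size
#'
#' ESS = M / (1 + 2 * sum of lag autocorrelations), with the sum truncated
#' at the first lag whose autocorrelation falls below 0.05 (configurable).
#' For multivariate chains the minimum across parameters is returned
#' (conservative). A constant chain has ESS 1 by convention.
#'
#' @param chain an `mcmc_chain`, matrix (rows = iterations), or numeric
#'   vector.
#' @param rho_cut truncation threshold for the autocorrelation sum.
#' @return effective sample size (scalar, in `[1, M]`).
#' @export
effective_sample_size <- function(chain, rho_cut = 0.05) {
  X <- if (inherits(chain, "mcmc_chain")) chain$samples
       else if (is.matrix(chain)) chain else matrix(chain, ncol = 1)
  M <- nrow(X)
  if (M < 10) stop("chain too short for ESS estimation")
  ess1 <- function(v) {
    if (stats::sd(v) == 0) return(1)
    rho <- stats::acf(v, lag.max = min(M - 1, 2000), plot = FALSE,
                      demean = TRUE)$acf[-1]
    cut <- which(rho < rho_cut)[1]
    s <- if (is.na(cut)) sum(rho) else if (cut == 1) 0 else sum(rho[1:(cut - 1)])
    max(1, min(M, M / (1 + 2 * s)))
  }
  min(apply(X, 2, ess1))
}

#' Thin a chain to approximately independent samples
#'
#' Keeps every ceil(M/ESS)-th sample, so consecutive retained samples can
#' be considered approximately independent.
#'
#' @param chain an `mcmc_chain`.
#' @param ess optional precomputed ESS.
#' @return the thinned `mcmc_chain` (with `ess` and `thin_by` recorded).
#' @export
thin <- function(chain, ess = NULL) {
  if (is.null(ess)) ess <- effective_sample_size(chain)
  k <- max(1L, as.integer(ceiling(nrow(chain$samples) / ess)))
  keep <- seq(k, nrow(chain$samples), by = k)
  out <- chain
  out$samples <- chain$samples[keep, , drop = FALSE]
  out$log_posterior <- chain$log_posterior[keep]
  out$log_lik <- chain$log_lik[keep]
  out$ess <- ess; out$thin_by <- k
  out
}

#' Adaptive random-walk prerun
#'
#' A Gaussian random walk on the normal-scores scale (prior-CDF transform
#' followed by the standard-normal quantile), with Robbins-Monro step-size
#' adaptation toward 23.4\% acceptance and periodic covariance adaptation.
#' Used to obtain the unthinned prerun sample on which the copula proposal
#' is fitted.
#'
#' @param log_target function of a single rate vector returning the log
#'   target density (e.g. unnormalised posterior).
#' @param prior a `prior_spec`.
#' @param init starting rate vector (e.g. the MAP estimate).
#' @param n number of iterations.
#' @param seed integer seed.
#' @return matrix of prerun samples on the rate scale.
#' @export
prerun_chain <- function(log_target, prior, init, n = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ks <- names(prior$priors)
  d <- length(ks)
  x2z <- function(x) stats::qnorm(pmin(pmax(
    to_uniform(matrix(x, 1), prior), 1e-12), 1 - 1e-12))
  z2x <- function(z) as.numeric(from_uniform(stats::pnorm(matrix(z, 1)), prior))
  ltz <- function(z, x) {
    # change of variables x -> z: add log prior, subtract normal scores
    log_target(x) + sum(stats::dnorm(z, log = TRUE)) -
      log_prior(prior, stats::setNames(x, ks))
  }
  z <- as.numeric(x2z(as.numeric(init)))
  x <- z2x(z)
  lcur <- ltz(z, x)
  if (!is.finite(lcur)) stop("log target not finite at init")
  out <- matrix(NA_real_, n, d, dimnames = list(NULL, ks))
  ls <- log(2.38 / sqrt(d))
  C <- diag(d); cholC <- diag(d)
  for (i in seq_len(n)) {
    zp <- z + exp(ls) * as.numeric(stats::rnorm(d) %*% cholC)
    xp <- z2x(zp)
    lp <- ltz(zp, xp)
    a <- min(1, exp(lp - lcur))
    if (is.finite(lp) && stats::runif(1) < a) { z <- zp; x <- xp; lcur <- lp }
    out[i, ] <- x
    if (!is.finite(a)) a <- 0
    ls <- ls + (a - 0.234) / max(20, i)^0.6
    if (i %% 200 == 0 && i >= 400) {
      # expanding-window covariance (diminishing adaptation, ergodic)
      Zh <- stats::qnorm(pmin(pmax(to_uniform(out[seq_len(i), ,
                                                  drop = FALSE], prior),
                                   1e-12), 1 - 1e-12))
      C <- stats::cov(Zh) + diag(1e-8, d)
      cholC <- tryCatch(chol(C), error = function(e) cholC)
    }
  }
  out
}
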