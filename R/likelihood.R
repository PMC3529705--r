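#' Gaussian noise parameters for the two measurement channels
#'
#' @param sigma_b plasma noise SD (\% per kg), > 0.
#' @param sigma_u urine noise SD (\%/day), > 0 (may be `NA` when the urine
#'   channel is unused).
#' @param scope `"per-investigation"` (one pair per investigation) or
#'   `"shared"` (one pair for the concatenated analysis).
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(sigma_b, sigma_u = NA_real_,
                         scope = c("per-investigation", "shared")) {
  scope <- match.arg(scope)
  if (!is.na(sigma_b) && sigma_b <= 0) stop("sigma_b must be > 0")
  if (!is.na(sigma_u) && sigma_u <= 0) stop("sigma_u must be > 0")
  structure(list(sigma_b = sigma_b, sigma_u = sigma_u, scope = scope),
            class = "noise_params")
}

# Fast evaluation context: one matrix build + one eigendecomposition +
# one propagation over the pooled unique measurement times per rate vector,
# shared across all investigations (they see the same kinetics).
make_loglik <- function(model, invs, noise, channels = "both") {
  if (inherits(invs, "investigation")) invs <- list(invs)
  channels <- match.arg(channels, c("both", "plasma", "urine"))
  use_b <- channels %in% c("both", "plasma")
  use_u <- channels %in% c("both", "urine")
  comp <- model$compartments
  n <- length(comp)
  tr <- model$transfers
  ridx <- as.character(rate_indices(model))
  tr_pos <- match(as.character(tr$rate), ridx)
  si <- match(tr$source, comp)
  ti <- match(tr$target, comp)
  urine_comp <- model$terminals[1]
  uin <- which(tr$target == urine_comp)
  pidx <- match(model$plasma, comp)
  y0 <- numeric(n); y0[match(model$entry, comp)] <- 100

  per <- lapply(invs, function(iv) {
    list(pt = if (use_b) iv$plasma$time else numeric(0),
         pv = if (use_b) iv$plasma$value else numeric(0),
         ut = if (use_u) iv$urine$time else numeric(0),
         uv = if (use_u) iv$urine$value else numeric(0),
         pm = iv$plasma_mass)
  })
  TT <- sort(unique(unlist(lapply(per, function(p) c(p$pt, p$ut)))))
  for (i in seq_along(per)) {
    per[[i]]$ip <- match(per[[i]]$pt, TT)
    per[[i]]$iu <- match(per[[i]]$ut, TT)
  }

  predict_at <- function(x) {
    A <- matrix(0, n, n)
    for (k in seq_along(si)) {
      r <- x[tr_pos[k]]
      A[ti[k], si[k]] <- A[ti[k], si[k]] + r
      A[si[k], si[k]] <- A[si[k], si[k]] - r
    }
    e <- eigen(A)
    Y <- tryCatch({
      w <- solve(e$vectors, as.complex(y0))
      Re(e$vectors %*% (exp(outer(e$values, TT)) * as.vector(w)))
    }, error = function(err) NULL)
    if (is.null(Y) || !all(is.finite(Y)))
      Y <- vapply(TT, function(t)
        as.numeric(Matrix::expm(A * t) %*% y0), numeric(n))
    urate <- numeric(length(TT))
    for (k in uin) urate <- urate + x[tr_pos[k]] * Y[si[k], ]
    list(plasma = Y[pidx, ], urate = urate)
  }

  # residual sums of squares and counts per channel, at rate vector x
  rss <- function(x) {
    p <- predict_at(x)
    if (!all(is.finite(p$plasma))) return(NULL)
    rb <- 0; nb <- 0L; ru <- 0; nu <- 0L
    for (pc in per) {
      if (length(pc$ip)) {
        rb <- rb + sum((pc$pv - p$plasma[pc$ip] / pc$pm)^2)
        nb <- nb + length(pc$ip)
      }
      if (length(pc$iu)) {
        ru <- ru + sum((pc$uv - p$urate[pc$iu])^2)
        nu <- nu + length(pc$iu)
      }
    }
    list(rb = rb, nb = nb, ru = ru, nu = nu)
  }

  loglik1 <- function(x) {
    r <- rss(x)
    if (is.null(r)) return(-Inf)
    ll <- 0
    if (r$nb > 0) {
      sb <- noise$sigma_b
      ll <- ll - r$nb * log(sb * sqrt(2 * pi)) - r$rb / (2 * sb^2)
    }
    if (r$nu > 0) {
      su <- noise$sigma_u
      ll <- ll - r$nu * log(su * sqrt(2 * pi)) - r$ru / (2 * su^2)
    }
    ll
  }

  list(loglik = function(x) {
         if (is.matrix(x)) apply(x, 1, loglik1) else loglik1(x)
       },
       rss = rss, predict_at = predict_at, times = TT)
}

#' Two-channel Gaussian log likelihood of a rate vector
#'
#' The likelihood of an investigation factorises over channels and
#' measurement points: each plasma measurement is normal around the
#' model-predicted plasma concentration (state of the transfer compartment
#' divided by the plasma mass, \%/kg) with SD `sigma_b`, and each urine
#' measurement is normal around the model-predicted instantaneous urine
#' excretion rate (\%/day) with SD `sigma_u`. For a list of investigations
#' the log likelihoods add (concatenated-data likelihood, one shared rate
#' vector and shared noise).
#'
#' @param model a `compartmental_model`.
#' @param rates a `rate_vector` (or a matrix of rate vectors, one per row,
#'   columns ordered by rate index — a vector of log likelihoods is then
#'   returned).
#' @param inv an `investigation` or list of investigations.
#' @param noise a [noise_params()].
#' @param channels which likelihood factors to include: `"both"`,
#'   `"plasma"`, or `"urine"` (enabling plasma-only / urine-only Bayes
#'   factors).
#' @return log likelihood (finite for finite inputs; `-Inf` if the ODE
#'   solution degenerates).
#' @export
log_likelihood <- function(model, rates, inv, noise,
                           channels = c("both", "plasma", "urine")) {
  channels <- match.arg(channels)
  ll <- make_loglik(model, inv, noise, channels)$loglik
  if (is.matrix(rates)) return(ll(rates))
  ll(as.numeric(rate_vector(model, rates)))
}

#' Simulated-annealing controls
#'
#' Geometric cooling between `t0` and `t1` over `n_temps` temperature
#' levels with `n_iter` Gaussian proposals per level, step sizes scaled to
#' the componentwise prior SDs (shrinking with temperature). `polish`
#' appends a Nelder-Mead refinement of the best point found.
#'
#' @param n_temps,n_iter annealing schedule size.
#' @param t0,t1 initial/final temperature.
#' @param step initial proposal scale as a fraction of the prior SDs.
#' @param polish,polish_maxit local refinement toggle and iteration cap.
#' @return list of class `sa_control`.
#' @export
sa_control <- function(n_temps = 50, n_iter = 200, t0 = 5, t1 = 0.01,
                       step = 0.5, polish = TRUE, polish_maxit = 1000) {
  structure(list(n_temps = n_temps, n_iter = n_iter, t0 = t0, t1 = t1,
                 step = step, polish = polish, polish_maxit = polish_maxit),
            class = "sa_control")
}

# Maximize f over x (componentwise scales given); support defined by
# is.finite(f). Returns list(x, value).
anneal <- function(f, x0, scales, control = sa_control(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  temps <- exp(seq(log(control$t0), log(control$t1),
                   length.out = control$n_temps))
  x <- x0; fx <- f(x0)
  if (!is.finite(fx)) stop("objective not finite at the starting point")
  best <- x; fbest <- fx
  for (j in seq_along(temps)) {
    Tj <- temps[j]
    sc <- scales * control$step * sqrt(Tj / control$t0)
    for (i in seq_len(control$n_iter)) {
      xp <- x + stats::rnorm(length(x)) * sc
      fp <- f(xp)
      if (is.finite(fp) &&
          (fp >= fx || stats::runif(1) < exp((fp - fx) / Tj))) {
        x <- xp; fx <- fp
        if (fx > fbest) { best <- x; fbest <- fx }
      }
    }
  }
  if (control$polish) {
    negf <- function(z) { v <- f(z); if (is.finite(v)) -v else 1e300 }
    if (length(x0) == 1L) {
      sc <- max(scales, 1e-8)
      op <- stats::optimize(negf, lower = max(0, best - 5 * sc),
                            upper = best + 5 * sc, tol = 1e-10)
      if (-op$objective > fbest) { best <- op$minimum; fbest <- -op$objective }
    } else {
      # restarted Nelder-Mead on the log scale: rates span several orders
      # of magnitude, so a natural-scale simplex is badly conditioned
      negf_log <- function(z) negf(exp(z))
      zb <- log(pmax(best, 1e-300))
      for (round in 1:4) {
        op <- stats::optim(zb, negf_log, method = "Nelder-Mead",
                           control = list(maxit = control$polish_maxit,
                                          reltol = 1e-12))
        improved <- -op$value > fbest + 1e-10
        if (-op$value > fbest) {
          zb <- op$par; best <- exp(op$par); fbest <- -op$value
        }
        if (!improved) break
      }
    }
  }
  list(x = best, value = fbest)
}

#' Fit channel noise SDs by simulated annealing with profiled sigma
#'
#' Maximizes the likelihood over the transfer rates (restricted to the
#' prior support) with the noise SDs profiled out in closed form at every
#' step — at fixed rates the maximizing SD per channel is the RMS residual.
#' With `scope = "shared"` one `(sigma_b, sigma_u)` pair is fitted against
#' all investigations jointly (the concatenated-data likelihood); with
#' `scope = "per-investigation"` each investigation is fitted separately
#' and a list is returned.
#'
#' @param model a `compartmental_model`.
#' @param invs an `investigation` or list of investigations.
#' @param prior a `prior_spec` (support constraint and proposal scaling).
#' @param channels channel selection as in [log_likelihood()].
#' @param scope `"per-investigation"` or `"shared"`.
#' @param control an [sa_control()].
#' @param seed integer seed.
#' @param sigma_floor lower bound applied to fitted SDs.
#' @param df_correct apply a degrees-of-freedom correction to the returned
#'   SDs (default `TRUE`): the maximum-likelihood RMS residual is biased
#'   low when the rate vector is fitted from few points, so each channel's
#'   residual sum of squares is divided by `n_ch - p * n_ch / n_tot`
#'   (the fitted parameters apportioned to channels by their share of the
#'   data) instead of `n_ch`, as in regression practice.
#' @return list with `noise` (a [noise_params()]), `rates` (best-fit
#'   `rate_vector`), `logLik`; or a list of such lists for
#'   `scope = "per-investigation"` with several investigations.
#' @export
fit_noise <- function(model, invs, prior, channels = "both",
                      scope = c("per-investigation", "shared"),
                      control = sa_control(), seed = NULL,
                      sigma_floor = 1e-12, df_correct = TRUE) {
  scope <- match.arg(scope)
  if (inherits(invs, "investigation")) invs <- list(invs)
  if (scope == "per-investigation" && length(invs) > 1L) {
    out <- lapply(seq_along(invs), function(i)
      fit_noise(model, invs[[i]], prior, channels, "per-investigation",
                control, seed = if (is.null(seed)) NULL else seed + i,
                sigma_floor = sigma_floor, df_correct = df_correct))
    names(out) <- vapply(invs, function(iv) iv$id, character(1))
    return(out)
  }
  channels <- match.arg(channels, c("both", "plasma", "urine"))
  nb <- sum(vapply(invs, function(iv) nrow(iv$plasma), integer(1)))
  nu <- sum(vapply(invs, function(iv) nrow(iv$urine), integer(1)))
  if (channels %in% c("both", "plasma") && nb == 0L) {
    warning("no plasma measurements; dropping plasma channel")
    channels <- "urine"
  }
  if (channels %in% c("both", "urine") && nu == 0L) {
    warning("no urine measurements; dropping urine channel")
    channels <- "plasma"
  }
  ctx <- make_loglik(model, invs, noise_params(1, 1), channels)
  profile <- function(x) {
    r <- ctx$rss(x)
    if (is.null(r)) return(-Inf)
    ll <- 0
    if (r$nb > 0) {
      sb <- max(sqrt(r$rb / r$nb), sigma_floor)
      ll <- ll - r$nb * log(sb * sqrt(2 * pi)) - r$rb / (2 * sb^2)
    }
    if (r$nu > 0) {
      su <- max(sqrt(r$ru / r$nu), sigma_floor)
      ll <- ll - r$nu * log(su * sqrt(2 * pi)) - r$ru / (2 * su^2)
    }
    ll
  }
  ks <- as.character(rate_indices(model))
  obj <- function(x) {
    if (!is.finite(log_prior(prior, stats::setNames(x, ks)))) return(-Inf)
    profile(x)
  }
  x0 <- prior_modes(prior)[ks]
  scales <- vapply(prior$priors[ks], prior_sd1, numeric(1))
  fit <- anneal(obj, as.numeric(x0), scales, control, seed)
  r <- ctx$rss(fit$x)
  p <- length(ks); ntot <- r$nb + r$nu
  dfb <- if (df_correct) max(1, r$nb - p * r$nb / ntot) else r$nb
  dfu <- if (df_correct) max(1, r$nu - p * r$nu / ntot) else r$nu
  sb <- if (r$nb > 0) max(sqrt(r$rb / dfb), sigma_floor) else NA_real_
  su <- if (r$nu > 0) max(sqrt(r$ru / dfu), sigma_floor) else NA_real_
  list(noise = noise_params(sb, su,
                            scope = if (scope == "shared") "shared"
                            else "per-investigation"),
       rates = rate_vector(model, stats::setNames(fit$x, ks)),
       logLik = fit$value)
}

#' Maximum a posteriori rate estimate
#'
#' Approximate argmax of log likelihood + log prior, by simulated annealing
#' started at the componentwise prior modes followed by a Nelder-Mead
#' polish. Used to initialize the MCMC chains, making a burn-in period
#' dispensable.
#'
#' @inheritParams fit_noise
#' @param noise fixed [noise_params()] (e.g. from [fit_noise()]).
#' @return a `rate_vector` with attribute `log_posterior`.
#' @export
map_estimate <- function(model, invs, prior, noise, channels = "both",
                         control = sa_control(), seed = NULL) {
  ks <- as.character(rate_indices(model))
  has_data <- !is.null(invs) &&
    (inherits(invs, "investigation") || length(invs) > 0)
  ll <- if (has_data) make_loglik(model, invs, noise, channels)$loglik
        else function(x) 0
  obj <- function(x) {
    lp <- log_prior(prior, stats::setNames(x, ks))
    if (!is.finite(lp)) return(-Inf)
    lp + ll(x)
  }
  x0 <- as.numeric(prior_modes(prior)[ks])
  scales <- vapply(prior$priors[ks], prior_sd1, numeric(1))
  fit <- anneal(obj, x0, scales, control, seed)
  out <- rate_vector(model, stats::setNames(fit$x, ks))
  attr(out, "log_posterior") <- fit$value
  out
}
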