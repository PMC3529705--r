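#' Build the system matrix of a compartmental model
#'
#' Returns the matrix A such that dy/dt = A y: the off-diagonal entry
#' (target, source) holds the transfer rate of that edge and each diagonal
#' entry holds minus the sum of outgoing rates, so every column sums to
#' zero (mass balance).
#'
#' @param model a `compartmental_model`.
#' @param rates a `rate_vector` (or named numeric) matching the model's
#'   rate indices.
#' @return square numeric matrix with dimnames = compartment labels.
#' @export
build_system_matrix <- function(model, rates) {
  rates <- rate_vector(model, rates)
  comp <- model$compartments
  n <- length(comp)
  A <- matrix(0, n, n, dimnames = list(comp, comp))
  tr <- model$transfers
  for (i in seq_len(nrow(tr))) {
    r <- rates[[as.character(tr$rate[i])]]
    A[tr$target[i], tr$source[i]] <- A[tr$target[i], tr$source[i]] + r
    A[tr$source[i], tr$source[i]] <- A[tr$source[i], tr$source[i]] - r
  }
  A
}

# Eigen-decomposition propagator: y(t) = V exp(L t) V^{-1} y0, with a
# scaling-and-squaring fallback when V is numerically near-defective.
# Returns compartments x times matrix.
propagate <- function(A, y0, times, cond_tol = 1e12) {
  e <- eigen(A)
  kappa <- tryCatch(kappa(e$vectors, exact = FALSE), error = function(e) Inf)
  if (is.finite(kappa) && kappa < cond_tol) {
    w <- solve(e$vectors, as.complex(y0))
    E <- exp(outer(e$values, times))        # n x T
    Y <- Re(e$vectors %*% (E * as.vector(w)))
  } else {
    warning("near-defective system matrix (cond ", format(kappa, digits = 3),
            "); falling back to scaling-and-squaring matrix exponential")
    Y <- vapply(times,
                function(t) as.numeric(Matrix::expm(A * t) %*% y0),
                numeric(length(y0)))
    Y <- matrix(Y, nrow = length(y0))
  }
  dimnames(Y) <- list(rownames(A), NULL)
  Y
}

#' Solve the compartmental dynamics exactly
#'
#' Computes the analytical solution y(t) = e^{At} y(0) of the linear system
#' at the requested times via eigendecomposition of the system matrix
#' (falling back to a scaling-and-squaring matrix exponential when the
#' eigenvector matrix is ill-conditioned, with a warning).
#'
#' @param model a `compartmental_model`.
#' @param rates a `rate_vector`.
#' @param times nonnegative times in days.
#' @param initial initial amounts (\% of ingested tracer) per compartment;
#'   default puts 100\% in the entry (stomach) compartment.
#' @return a `trajectory`: list with `times`, `values` (time x compartment
#'   matrix, \%), `model`.
#' @export
solve_trajectory <- function(model, rates, times, initial = NULL) {
  if (any(times < 0)) stop("negative time(s)")
  comp <- model$compartments
  if (is.null(initial)) {
    initial <- stats::setNames(numeric(length(comp)), comp)
    initial[model$entry] <- 100
  }
  if (length(initial) != length(comp)) stop("initial has wrong length")
  A <- build_system_matrix(model, rates)
  Y <- propagate(A, initial, times)
  structure(list(times = as.numeric(times), values = t(Y),
                 model = model$name),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> model %s: %d times in [%g, %g] d, %d compartments\n",
              x$model, length(x$times), min(x$times), max(x$times),
              ncol(x$values)))
  invisible(x)
}

#' Urine excretion rate along a trajectory
#'
#' The urine compartment is absorbing, so its time derivative is the sum of
#' its inflow terms: dy7/dt = sum over transfers into urine of
#' x_alpha * y_source(t), evaluated analytically from the trajectory.
#'
#' @param model a `compartmental_model`.
#' @param rates a `rate_vector` (same values used to produce `trajectory`).
#' @param trajectory a `trajectory` from [solve_trajectory()].
#' @param urine label of the urine compartment; default the first terminal.
#' @return numeric vector (\%/day) at `trajectory$times`.
#' @export
urine_excretion_rate <- function(model, rates, trajectory,
                                 urine = model$terminals[1]) {
  if (trajectory$model != model$name)
    stop("trajectory was computed for model ", trajectory$model)
  rates <- rate_vector(model, rates)
  tr <- model$transfers
  if (any(tr$source == urine))
    stop("compartment ", urine, " has outgoing transfers; not an absorbing",
         " excreta compartment")
  inflow <- tr[tr$target == urine, , drop = FALSE]
  out <- numeric(length(trajectory$times))
  for (i in seq_len(nrow(inflow)))
    out <- out + rates[[as.character(inflow$rate[i])]] *
      trajectory$values[, inflow$source[i]]
  out
}

#' Correct a time series for radioactive decay
#'
#' Multiplies each value by exp(-ln 2 * t / half_life). The bundled
#' application is the 95Zr isotope with half-life 64.032 days: stable-tracer
#' kinetics are converted to radionuclide retention.
#'
#' @param values numeric values.
#' @param times times in days matching `values`.
#' @param half_life half-life in days (> 0); default 64.032 (95Zr).
#' @return decayed values.
#' @export
decay_correct <- function(values, times, half_life = 64.032) {
  if (!is.numeric(half_life) || half_life <= 0)
    stop("half_life must be positive")
  if (length(values) != length(times)) stop("length mismatch")
  values * exp(-log(2) * times / half_life)
}

#' Posterior bone-retention band
#'
#' For each posterior rate vector, sums the bone-compartment trajectories
#' (two bone-surface pools for the ICRP structure, one combined pool for the
#' HMGU structure), optionally applies radioactive-decay correction, and
#' returns the pointwise 5\%/50\%/95\% quantiles across samples — a median
#' curve with a 90\% credible band.
#'
#' @param model a `compartmental_model`.
#' @param rate_samples list of `rate_vector`s (or a matrix with one sample
#'   per row, columns ordered/named by rate index).
#' @param times times in days.
#' @param apply_decay logical; decay-correct with `half_life`.
#' @param half_life half-life in days (default 64.032, 95Zr).
#' @return data frame with columns `time_d`, `lower`, `median`, `upper`.
#' @export
bone_retention <- function(model, rate_samples, times, apply_decay = FALSE,
                           half_life = 64.032) {
  if (is.matrix(rate_samples))
    rate_samples <- lapply(seq_len(nrow(rate_samples)),
                           function(i) rate_samples[i, ])
  if (length(rate_samples) == 0L) stop("empty sample list")
  curves <- vapply(rate_samples, function(x) {
    tra <- solve_trajectory(model, rate_vector(model, x), times)
    b <- rowSums(tra$values[, model$bones, drop = FALSE])
    if (apply_decay) b <- decay_correct(b, times, half_life)
    b
  }, numeric(length(times)))
  curves <- matrix(curves, nrow = length(times))
  q <- t(apply(curves, 1, stats::quantile, probs = c(0.05, 0.5, 0.95),
               type = 7, names = FALSE))
  data.frame(time_d = as.numeric(times), lower = q[, 1], median = q[, 2],
             upper = q[, 3])
}
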