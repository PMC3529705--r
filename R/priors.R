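# Triangular distribution on [lower, upper] with the given mode.
dtri <- function(x, lower, mode, upper) {
  d <- numeric(length(x))
  h <- 2 / (upper - lower)
  up <- x >= lower & x <= mode
  dn <- x > mode & x <= upper
  if (mode > lower) d[up] <- h * (x[up] - lower) / (mode - lower)
  else d[x == lower] <- h
  if (upper > mode) d[dn] <- h * (upper - x[dn]) / (upper - mode)
  d
}

ptri <- function(q, lower, mode, upper) {
  p <- numeric(length(q))
  p[q >= upper] <- 1
  up <- q > lower & q <= mode
  dn <- q > mode & q < upper
  if (mode > lower)
    p[up] <- (q[up] - lower)^2 / ((upper - lower) * (mode - lower))
  if (upper > mode)
    p[dn] <- 1 - (upper - q[dn])^2 / ((upper - lower) * (upper - mode))
  p
}

qtri <- function(p, lower, mode, upper) {
  pc <- (mode - lower) / (upper - lower)
  ifelse(p <= pc,
         lower + sqrt(p * (upper - lower) * (mode - lower)),
         upper - sqrt((1 - p) * (upper - lower) * (upper - mode)))
}

#' Prior specifications for transfer rates
#'
#' A `prior_spec` assigns each rate index a univariate distribution —
#' lognormal, normal, or triangular — truncated at zero and renormalised.
#' The joint prior is the product of the univariate priors (no prior
#' dependence is assumed between rates).
#'
#' @param priors named list keyed by rate index; each element a list with
#'   `family` in `c("lognormal","normal","triangular")` and `params`
#'   (lognormal: `meanlog`, `sdlog`; normal: `mean`, `sd`; triangular:
#'   `lower`, `mode`, `upper`).
#' @param model_name optional model label the prior belongs to.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(priors, model_name = NULL) {
  for (k in names(priors)) {
    p <- priors[[k]]
    if (!p$family %in% c("lognormal", "normal", "triangular"))
      stop("unknown prior family '", p$family, "' for rate ", k)
    if (p$family == "triangular") {
      pr <- p$params
      if (!(pr$lower <= pr$mode && pr$mode <= pr$upper))
        stop("triangular prior for rate ", k, " violates lower<=mode<=upper")
      if (pr$upper <= 0)
        stop("triangular prior for rate ", k, " has no mass above zero")
    }
    if (p$family == "normal" && p$params$sd <= 0)
      stop("normal prior for rate ", k, " needs sd > 0")
    if (p$family == "lognormal" && p$params$sdlog <= 0)
      stop("lognormal prior for rate ", k, " needs sdlog > 0")
  }
  ks <- names(priors)
  if (!is.null(ks) && all(grepl("^[0-9]+$", ks)))
    priors <- priors[as.character(sort(as.integer(ks)))]
  structure(list(priors = priors, model_name = model_name),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  fam <- vapply(x$priors, function(p) p$family, character(1))
  cat(sprintf("<prior_spec>%s %d rates: %s\n",
              if (is.null(x$model_name)) "" else paste0(" [", x$model_name, "]"),
              length(fam),
              paste(sprintf("%s x%d", names(table(fam)), as.integer(table(fam))),
                    collapse = ", ")))
  invisible(x)
}

# Normalisation constant of the zero-truncated density (mass above 0).
trunc_mass <- function(p) {
  switch(p$family,
    lognormal = 1,
    normal = 1 - stats::pnorm(0, p$params$mean, p$params$sd),
    triangular = {
      pr <- p$params
      if (pr$lower >= 0) 1 else 1 - ptri(0, pr$lower, pr$mode, pr$upper)
    })
}

# Vectorised univariate truncated log-density / cdf / quantile.
prior_logdens1 <- function(x, p) {
  z <- trunc_mass(p)
  ld <- switch(p$family,
    lognormal = stats::dlnorm(x, p$params$meanlog, p$params$sdlog, log = TRUE),
    normal = stats::dnorm(x, p$params$mean, p$params$sd, log = TRUE) - log(z),
    triangular = {
      d <- dtri(x, p$params$lower, p$params$mode, p$params$upper) / z
      ifelse(d > 0, log(d), -Inf)
    })
  ld[x < 0] <- -Inf
  ld
}

prior_cdf1 <- function(x, p) {
  z <- trunc_mass(p)
  u <- switch(p$family,
    lognormal = stats::plnorm(x, p$params$meanlog, p$params$sdlog),
    normal = (stats::pnorm(x, p$params$mean, p$params$sd) -
                stats::pnorm(0, p$params$mean, p$params$sd)) / z,
    triangular = {
      pr <- p$params
      p0 <- if (pr$lower >= 0) 0 else ptri(0, pr$lower, pr$mode, pr$upper)
      (ptri(x, pr$lower, pr$mode, pr$upper) - p0) / z
    })
  pmin(pmax(u, 0), 1)
}

prior_quantile1 <- function(u, p) {
  z <- trunc_mass(p)
  switch(p$family,
    lognormal = stats::qlnorm(u, p$params$meanlog, p$params$sdlog),
    normal = stats::qnorm(stats::pnorm(0, p$params$mean, p$params$sd) + u * z,
                          p$params$mean, p$params$sd),
    triangular = {
      pr <- p$params
      p0 <- if (pr$lower >= 0) 0 else ptri(0, pr$lower, pr$mode, pr$upper)
      qtri(p0 + u * z, pr$lower, pr$mode, pr$upper)
    })
}

prior_mode1 <- function(p) {
  switch(p$family,
    lognormal = exp(p$params$meanlog - p$params$sdlog^2),
    normal = max(0, p$params$mean),
    triangular = max(0, p$params$mode))
}

prior_sd1 <- function(p) {
  switch(p$family,
    lognormal = sqrt((exp(p$params$sdlog^2) - 1)) *
      exp(p$params$meanlog + p$params$sdlog^2 / 2),
    normal = p$params$sd,
    triangular = (p$params$upper - p$params$lower) / sqrt(24))
}

#' Joint log prior density of a rate vector
#'
#' Sum of the zero-truncated, renormalised univariate log densities; returns
#' `-Inf` for any rate below zero or outside a triangular support.
#'
#' @param prior a `prior_spec`.
#' @param rates named numeric rate vector (names = rate indices), or a
#'   matrix with one rate vector per row.
#' @return numeric log density (vector if `rates` is a matrix).
#' @export
log_prior <- function(prior, rates) {
  if (is.matrix(rates)) {
    ks <- names(prior$priors)
    if (is.null(colnames(rates))) colnames(rates) <- ks
    out <- numeric(nrow(rates))
    for (k in ks) out <- out + prior_logdens1(rates[, k], prior$priors[[k]])
    return(out)
  }
  ks <- names(prior$priors)
  if (is.null(names(rates))) names(rates) <- ks
  if (!setequal(names(rates), ks))
    stop("rate index set does not match prior")
  sum(vapply(ks, function(k) prior_logdens1(rates[[k]], prior$priors[[k]]),
             numeric(1)))
}

#' Draw rate vectors from the prior
#'
#' Inverse-CDF sampling from each zero-truncated univariate prior
#' (independent components).
#'
#' @param prior a `prior_spec`.
#' @param n number of draws.
#' @return n x d matrix, columns named by rate index.
#' @export
rprior <- function(prior, n = 1) {
  ks <- names(prior$priors)
  out <- vapply(ks, function(k)
    prior_quantile1(stats::runif(n), prior$priors[[k]]), numeric(n))
  matrix(out, nrow = n, dimnames = list(NULL, ks))
}

#' Componentwise prior modes (used as a default starting point)
#' @param prior a `prior_spec`.
#' @return named numeric vector.
#' @export
prior_modes <- function(prior) {
  vapply(prior$priors, prior_mode1, numeric(1))
}

#' Read a prior specification from JSON
#'
#' The file is keyed by rate index with `family` and `params` per rate.
#' When `model` is supplied, the index set is checked against the model and,
#' for the two bundled structures, the documented family counts are
#' validated (ICRP: 4 lognormal / 5 triangular / 6 normal; HMGU: 8
#' lognormal / 4 triangular).
#'
#' @param path path to a prior JSON file.
#' @param model optional `compartmental_model` to validate against.
#' @return a `prior_spec`.
#' @export
read_prior_json <- function(path, model = NULL) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  pr <- prior_spec(lapply(j$priors, function(p)
    list(family = p$family, params = lapply(p$params, as.numeric))),
    model_name = j$model)
  if (!is.null(model)) {
    if (!setequal(names(pr$priors), as.character(rate_indices(model))))
      stop("prior rate indices do not match model ", model$name)
    fam <- table(vapply(pr$priors, function(p) p$family, character(1)))
    want <- switch(toupper(model$name),
      ICRP = c(lognormal = 4, normal = 6, triangular = 5),
      HMGU = c(lognormal = 8, triangular = 4),
      NULL)
    if (!is.null(want)) {
      got <- as.integer(fam[names(want)]); got[is.na(got)] <- 0L
      if (!all(got == want))
        stop("prior family counts for ", model$name, " do not match the ",
             "documented counts (",
             paste(names(want), want, sep = "=", collapse = ", "), ")")
    }
  }
  pr
}

#' Load the bundled prior specification for a bundled model
#'
#' Hyperparameters are editable placeholders satisfying the documented
#' family counts; see the shipped JSON files under
#' `system.file("extdata/priors", package = "zirbayes")`.
#'
#' @param which `"hmgu"` or `"icrp"`.
#' @return a `prior_spec`.
#' @export
zr_prior <- function(which = c("hmgu", "icrp")) {
  which <- match.arg(which)
  path <- system.file("extdata", "priors", paste0(which, "_priors.json"),
                      package = "zirbayes", mustWork = TRUE)
  read_prior_json(path, model = zr_model(which))
}
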