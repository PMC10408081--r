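#' Fit a beta distribution from a mean and standard error
#'
#' Method-of-moments fit used for probabilities and utilities, which are
#' reported in the input table as a mean and standard error only. With
#' `K = mean (1 - mean) / se^2 - 1`, the shape parameters are
#' `alpha = mean K` and `beta = (1 - mean) K`, so the fitted distribution
#' reproduces the requested first two moments exactly.
#'
#' @param mean Target mean, strictly inside (0, 1).
#' @param se Target standard error (the SD of the fitted distribution),
#'   with `se^2 < mean * (1 - mean)`.
#' @return An object of class `dist_params`: a list with `family = "beta"`
#'   and elements `alpha`, `beta`.
#' @examples
#' fit_beta_from_moments(0.798, 0.031)
#' @export
fit_beta_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (!(mean > 0 && mean < 1)) {
    stop("beta fit requires 0 < mean < 1, got ", mean)
  }
  if (!(se > 0)) stop("beta fit requires se > 0, got ", se)
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "infeasible moments for a beta distribution: se^2 = %g >= mean(1-mean) = %g",
      v, mean * (1 - mean)
    ))
  }
  K <- mean * (1 - mean) / v - 1
  dist_params("beta", alpha = mean * K, beta = (1 - mean) * K)
}

#' Fit a gamma distribution from a mean and standard error
#'
#' Method-of-moments fit used for cost parameters: `shape = (mean/se)^2`,
#' `scale = se^2 / mean`.
#'
#' @param mean Target mean, > 0.
#' @param se Target standard error, > 0.
#' @return A `dist_params` object with `family = "gamma"` and elements
#'   `shape`, `scale`.
#' @examples
#' fit_gamma_from_moments(42673806, 2021475)
#' @export
fit_gamma_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (mean <= 0 || se <= 0) {
    stop("gamma fit requires mean > 0 and se > 0, got mean = ", mean, ", se = ", se)
  }
  dist_params("gamma", shape = (mean / se)^2, scale = se^2 / mean)
}

#' Fit a lognormal distribution from a mean and standard error
#'
#' Mean-preserving parameterization on the natural scale:
#' `sigma^2 = log(1 + (se/mean)^2)` and `mu = log(mean) - sigma^2 / 2`, so
#' that `exp(mu + sigma^2/2)` equals the input mean. Used for relative
#' risks, whose point estimates are reported as means.
#'
#' @param mean Target mean on the natural scale, > 0.
#' @param se Target standard error on the natural scale, > 0.
#' @return A `dist_params` object with `family = "lognormal"` and elements
#'   `mu`, `sigma` (log scale).
#' @examples
#' fit_lognormal_from_moments(0.948, 0.080)
#' @export
fit_lognormal_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (mean <= 0 || se <= 0) {
    stop("lognormal fit requires mean > 0 and se > 0, got mean = ", mean, ", se = ", se)
  }
  sigma2 <- log1p((se / mean)^2)
  dist_params("lognormal", mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Construct a distribution-parameter object
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param ... Named shape parameters (all strictly positive), or `value`
#'   for the `fixed` family.
#' @return A list of class `dist_params`.
#' @export
dist_params <- function(family, ...) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  pars <- list(...)
  if (family != "fixed") {
    # location parameters (lognormal mu) may be any real; scale/shape
    # parameters must be strictly positive
    strict <- setdiff(names(pars), "mu")
    bad <- vapply(pars[strict], function(p) !is.finite(p) || p <= 0, logical(1))
    if (any(bad)) {
      stop(
        "non-positive shape parameter(s) for ", family, ": ",
        paste(strict[bad], collapse = ", ")
      )
    }
    if (!is.null(pars$mu) && !is.finite(pars$mu)) {
      stop("non-finite location parameter for ", family)
    }
  }
  structure(c(list(family = family), pars), class = "dist_params")
}

#' @export
print.dist_params <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat(
    x$family, "(",
    paste(sprintf("%s = %g", names(pars), unlist(pars)), collapse = ", "),
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' Analytic mean and SD of a fitted distribution
#'
#' @param dist A `dist_params` object.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "dist_params"))
  switch(dist$family,
    beta = {
      a <- dist$alpha
      b <- dist$beta
      c(mean = a / (a + b), sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = c(
      mean = dist$shape * dist$scale,
      sd = sqrt(dist$shape) * dist$scale
    ),
    lognormal = {
      m <- exp(dist$mu + dist$sigma^2 / 2)
      c(mean = m, sd = m * sqrt(exp(dist$sigma^2) - 1))
    },
    fixed = c(mean = dist$value, sd = 0)
  )
}

#' Draw random variates from a fitted distribution
#'
#' @param dist A `dist_params` object.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(dist, n = 1) {
  stopifnot(inherits(dist, "dist_params"))
  switch(dist$family,
    beta = stats::rbeta(n, dist$alpha, dist$beta),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    lognormal = stats::rlnorm(n, dist$mu, dist$sigma),
    fixed = rep(dist$value, n)
  )
}

#' Fit the distribution recorded for one parameter row
#'
#' Dispatches on the `distribution` field of a parameter record. Parameters
#' with `se = 0` (or a `fixed` family) are treated as degenerate and always
#' return their mean when sampled.
#'
#' @param mean,se Moments for the fit.
#' @param distribution `"beta"`, `"gamma"`, `"lognormal"` or `"fixed"`.
#' @return A `dist_params` object.
#' @export
fit_parameter_distribution <- function(mean, se, distribution) {
  distribution <- match.arg(distribution, c("beta", "gamma", "lognormal", "fixed"))
  if (distribution == "fixed" || se == 0) {
    return(dist_params("fixed", value = mean))
  }
  switch(distribution,
    beta = fit_beta_from_moments(mean, se),
    gamma = fit_gamma_from_moments(mean, se),
    lognormal = fit_lognormal_from_moments(mean, se)
  )
}
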