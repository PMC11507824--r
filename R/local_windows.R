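# Windowing at the long timescale T, local distribution fits, the xi(t)
# series of local variance, and the mixing distribution of xi.
#
# Parametrizations (mean-parametrized local families):
#   gamma:          f(l) = (k/xi)^k l^(k-1) exp(-k l / xi) / Gamma(k)
#                   i.e. shape k, rate k/xi; mean = xi.
#   inverse gamma:  f(l) = (a xi)^(a+1) l^(-a-2) exp(-a xi / l) / Gamma(a+1)
#                   with a = alpha, i.e. standard InvGamma(shape alpha + 1,
#                   scale alpha * xi); mean = xi.
# Mixing laws for xi:
#   gamma:          shape delta, scale omega.
#   inverse gamma:  shape mu, scale omega (InvGamma(mu, omega)).

#' Local family densities (mean-parametrized)
#'
#' `dlocal_gamma` is the gamma density with shape `k` and mean `xi`;
#' `dlocal_invgamma` the inverse-gamma density with shape `alpha` (tail
#' exponent; standard shape alpha + 1) and mean `xi`.
#'
#' @param l Lengths (bp), positive.
#' @param k,alpha Shape parameters (> 0).
#' @param xi Mean length (bp, > 0).
#' @param log Return log density?
#' @return Density values (1/bp).
#' @export
dlocal_gamma <- function(l, k, xi, log = FALSE) {
  stats::dgamma(l, shape = k, rate = k / xi, log = log)
}

#' @rdname dlocal_gamma
#' @export
dlocal_invgamma <- function(l, alpha, xi, log = FALSE) {
  dinvgamma_std(l, shape = alpha + 1, scale = alpha * xi, log = log)
}

# standard inverse-gamma density; 1/X ~ Gamma(shape, rate = scale)
#' @keywords internal
#' @noRd
dinvgamma_std <- function(x, shape, scale, log = FALSE) {
  # recycles over x, shape and scale like the d* functions in stats
  lp <- suppressWarnings(
    shape * base::log(scale) - lgamma(shape) -
      (shape + 1) * base::log(x) - scale / x)
  lp[rep_len(x <= 0, length(lp))] <- -Inf
  if (log) lp else exp(lp)
}

#' Mixing-law densities for the intensive parameter
#'
#' `dmix_gamma` is a gamma law with shape `delta` and scale `omega`;
#' `dmix_invgamma` an inverse-gamma law with shape `mu` and scale `omega`.
#'
#' @param xi Positive values of the intensive parameter.
#' @param delta,mu Shapes (> 0).
#' @param omega Scale (> 0).
#' @param log Return log density?
#' @export
dmix_gamma <- function(xi, delta, omega, log = FALSE) {
  stats::dgamma(xi, shape = delta, scale = omega, log = log)
}

#' @rdname dmix_gamma
#' @export
dmix_invgamma <- function(xi, mu, omega, log = FALSE) {
  dinvgamma_std(xi, shape = mu, scale = omega, log = log)
}

#' Cut a series into non-overlapping windows of length T
#'
#' @param series An `exon_series` or numeric vector.
#' @param T Window length (rounded to the nearest integer >= 2). A trailing
#'   remainder shorter than the window is discarded.
#' @param sliding If `TRUE`, windows advance by `step` instead of `T`.
#' @param step Stride for sliding windows.
#' @return List of windows; each a list with `start` (index of first element)
#'   and `lengths`.
#' @export
segment_series <- function(series, T, sliding = FALSE, step = 1L) {
  x <- if (inherits(series, "exon_series")) series$lengths else as.numeric(series)
  if (!is.finite(T) || round(T) < 2)
    abort("window size T must round to an integer >= 2", "superexon_window_error")
  w <- as.integer(round(T))
  n <- length(x)
  if (n < w)
    abort(sprintf("window size %d exceeds series length %d", w, n),
          "superexon_window_error")
  starts <- if (sliding) seq(1L, n - w + 1L, by = step) else seq(1L, n - w + 1L, by = w)
  lapply(starts, function(s) list(start = s, lengths = x[s:(s + w - 1L)]))
}

#' Maximum-likelihood fit of a local family in one window
#'
#' Fits the mean-parametrized gamma (shape k, mean xi) or inverse gamma
#' (shape alpha, mean xi) by ML. Degenerate windows (size < 4, zero
#' variance, non-positive values) are skipped: a classed warning is raised
#' and `NULL` returned, so callers can exclude and log them.
#'
#' @param window Numeric vector of lengths, or a window from
#'   [segment_series()].
#' @param family `"gamma"` or `"inverse_gamma"`.
#' @return List with `k` (or `alpha`), `xi` and `loglik`; or `NULL` on skip.
#' @export
fit_local <- function(window, family = c("gamma", "inverse_gamma")) {
  family <- match.arg(family)
  x <- if (is.list(window)) window$lengths else as.numeric(window)
  if (length(x) < 4L) return(skip_signal("window smaller than 4; skipped"))
  if (any(x <= 0)) return(skip_signal("non-positive lengths in window; skipped"))
  if (stats::var(x) == 0) return(skip_signal("zero-variance window; skipped"))
  if (family == "gamma") {
    f <- tryCatch(suppressWarnings(MASS::fitdistr(x, "gamma")),
                  error = function(e) NULL)
    if (is.null(f)) {
      # fall back to direct optimisation in (log k, log xi)
      nll <- function(p) -sum(dlocal_gamma(x, exp(p[1]), exp(p[2]), log = TRUE))
      o <- stats::optim(c(log(mean(x)^2 / stats::var(x)), log(mean(x))), nll)
      return(list(k = exp(o$par[1]), xi = exp(o$par[2]), loglik = -o$value))
    }
    k <- unname(f$estimate["shape"])
    list(k = k, xi = k / unname(f$estimate["rate"]),
         loglik = f$loglik)
  } else {
    # 1/x ~ Gamma(alpha + 1, rate = alpha * xi); refine by constrained optim
    nll <- function(p) -sum(dlocal_invgamma(x, exp(p[1]), exp(p[2]), log = TRUE))
    init <- c(log(1), log(mean(x)))
    g <- tryCatch(suppressWarnings(MASS::fitdistr(1 / x, "gamma")),
                  error = function(e) NULL)
    if (!is.null(g) && g$estimate["shape"] > 1.05) {
      a0 <- unname(g$estimate["shape"]) - 1
      init <- c(log(a0), log(unname(g$estimate["rate"]) / a0))
    }
    o <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    list(alpha = exp(o$par[1]), xi = exp(o$par[2]), loglik = -o$value)
  }
}

#' Local-variance series xi(t)
#'
#' Per window of length T, the population variance v = <l^2> - <l>^2 is
#' computed; the gamma flavour reports xi = 1/v (units 1/bp^2), the
#' inverse-gamma flavour xi = v (bp^2). The proportionality constant is fixed
#' to 1: the shape of the mixing law is invariant under rescaling of xi
#' (scale family), so only its scale parameter absorbs the constant.
#'
#' @param series An `exon_series` or numeric vector.
#' @param T Window length.
#' @param family `"gamma"` or `"inverse_gamma"`.
#' @return Object of class `xi_series`: list with `window_starts`,
#'   `xi_values`, `family` and `T`. Zero-variance windows are skipped with a
#'   classed warning.
#' @export
xi_series <- function(series, T, family = c("gamma", "inverse_gamma")) {
  family <- match.arg(family)
  wins <- segment_series(series, T)
  starts <- vapply(wins, `[[`, integer(1), "start")
  v <- vapply(wins, function(w) {
    x <- w$lengths
    mean(x^2) - mean(x)^2
  }, numeric(1))
  bad <- v <= 0
  if (any(bad)) {
    skip_signal(sprintf("%d zero-variance window(s) skipped", sum(bad)))
    starts <- starts[!bad]; v <- v[!bad]
  }
  structure(list(window_starts = starts,
                 xi_values = if (family == "gamma") 1 / v else v,
                 family = family, T = round(T)),
            class = "xi_series")
}

#' @export
print.xi_series <- function(x, ...) {
  cat(sprintf("xi_series (%s flavour): %d windows of T = %d, median xi = %.4g\n",
              x$family, length(x$xi_values), x$T, stats::median(x$xi_values)))
  invisible(x)
}

#' Fit the mixing distribution of xi
#'
#' Maximum-likelihood fit of a gamma law (shape delta, scale omega) or an
#' inverse-gamma law (shape mu, scale omega) to the windowed xi values. The
#' inverse-gamma ML fit uses the exact reciprocal identity
#' 1/xi ~ Gamma(mu, rate = omega).
#'
#' @param xi An `xi_series` or positive numeric vector.
#' @param family `"gamma"` or `"inverse_gamma"`.
#' @param min_windows Minimum number of xi values required (default 20).
#' @return For gamma: list with `delta`, `omega`, `loglik`, `n`; for inverse
#'   gamma: `mu`, `omega`, `loglik`, `n`.
#' @export
fit_mixing <- function(xi, family = c("gamma", "inverse_gamma"),
                       min_windows = 20L) {
  family <- match.arg(family)
  v <- if (inherits(xi, "xi_series")) xi$xi_values else as.numeric(xi)
  if (length(v) < min_windows)
    abort(sprintf("only %d windows; need >= %d for a mixing fit",
                  length(v), min_windows), "superexon_insufficient_data")
  m <- mean(v)  # rescale to O(1) for a stable gamma MLE; shape is invariant
  if (family == "gamma") {
    f <- suppressWarnings(MASS::fitdistr(v / m, "gamma"))
    delta <- unname(f$estimate["shape"])
    omega <- m / unname(f$estimate["rate"])
    list(delta = delta, omega = omega,
         loglik = sum(dmix_gamma(v, delta, omega, log = TRUE)), n = length(v))
  } else {
    f <- suppressWarnings(MASS::fitdistr(m / v, "gamma"))
    mu <- unname(f$estimate["shape"])
    omega <- m * unname(f$estimate["rate"])
    list(mu = mu, omega = omega,
         loglik = sum(dmix_invgamma(v, mu, omega, log = TRUE)), n = length(v))
  }
}
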