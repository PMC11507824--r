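# The q-Gamma and inverse q-Gamma families.
#
# The q-exponential generalises the exponential:
#   exp_q(-u) = [1 + (q - 1) u]^(-1/(q-1)),  u >= 0,  q > 1,
# recovering exp(-u) as q -> 1+.  The two marginal families are
#   q-Gamma:          p(l) = A  (l/sigma)^a      exp_q(-l/sigma)
#   inverse q-Gamma:  p(l) = A  (l/sigma)^(-alpha-2) exp_q(-sigma/l)
# Both arise exactly as mixtures of a local family over a slowly varying
# mean parameter xi: a gamma local law mixed over an inverse-gamma xi gives
# the q-Gamma; an inverse-gamma local law mixed over a gamma xi gives the
# inverse q-Gamma. q measures how broadly xi fluctuates; q -> 1 recovers the
# classical gamma / inverse gamma.
#
# Normalizability requires 1/(q-1) - shape_exponent - 1 > 0, i.e. the
# power-law tail must be integrable; validity is enforced everywhere.

#' The q-exponential function
#'
#' `q_exponential(u, q)` evaluates exp_q(-u) = `[1 + (q-1) u]^(-1/(q-1))`
#' for `u >= 0` and `q >= 1` (evaluated in log space; `q = 1` gives
#' `exp(-u)`). The `q < 1` compact-support regime is not supported.
#'
#' @param u Non-negative argument(s).
#' @param q Entropic index, `>= 1`.
#' @return exp_q(-u), in (0, 1].
#' @export
q_exponential <- function(u, q) {
  if (q < 1)
    abort("q < 1 (compact-support regime) is not supported", "superexon_unsupported_regime")
  stopifnot(all(u >= 0))
  if (q == 1) return(exp(-u))
  exp(-log1p((q - 1) * u) / (q - 1))
}

#' Constrained q-family parameter sets
#'
#' Builders validate parameters and, unless `A` is supplied (`A_free` use),
#' set the normalization to its closed-form value so the pdf integrates
#' to 1. Validity: `sigma > 0`, `q > 1` (or 1 in the classical limit),
#' `a > -1` (q-Gamma), `alpha > 0` (inverse q-Gamma), and tail
#' integrability `1/(q-1) - a - 1 > 0` resp. `1/(q-1) - alpha - 1 > 0`.
#'
#' @param a Power-law exponent of the q-Gamma (local gamma shape minus 1).
#' @param alpha Tail exponent of the inverse q-Gamma.
#' @param sigma Scale (bp).
#' @param q Entropic index.
#' @param A Optional free normalization (1/bp); default the closed form.
#' @return Object of class `qgamma_params` / `invqgamma_params`.
#' @export
qgamma_params <- function(a, sigma, q, A = NULL) {
  if (!is.finite(a) || !is.finite(sigma) || !is.finite(q) ||
      sigma <= 0 || a <= -1 || q <= 1 || 1 / (q - 1) - a - 1 <= 0)
    abort(sprintf(
      "invalid q-Gamma parameters (a=%.4g, sigma=%.4g, q=%.4g): need sigma>0, a>-1, q>1, 1/(q-1)-a-1>0",
      a, sigma, q), "superexon_validity_error")
  structure(list(a = a, sigma = sigma, q = q,
                 A = if (is.null(A)) qgamma_norm(a, sigma, q) else A,
                 constrained = is.null(A)),
            class = "qgamma_params")
}

#' @rdname qgamma_params
#' @export
invqgamma_params <- function(alpha, sigma, q, A = NULL) {
  if (!is.finite(alpha) || !is.finite(sigma) || !is.finite(q) ||
      sigma <= 0 || alpha <= 0 || q <= 1 || 1 / (q - 1) - alpha - 1 <= 0)
    abort(sprintf(
      "invalid inverse q-Gamma parameters (alpha=%.4g, sigma=%.4g, q=%.4g): need sigma>0, alpha>0, q>1, 1/(q-1)-alpha-1>0",
      alpha, sigma, q), "superexon_validity_error")
  structure(list(alpha = alpha, sigma = sigma, q = q,
                 A = if (is.null(A)) invqgamma_norm(alpha, sigma, q) else A,
                 constrained = is.null(A)),
            class = "invqgamma_params")
}

#' Closed-form normalization constants
#'
#' `qgamma_norm` returns
#' `(q-1)^(a+1) * Gamma(1/(q-1)) / (sigma * Gamma(1/(q-1)-a-1) * Gamma(a+1))`;
#' `invqgamma_norm` returns
#' `(q-1)^(alpha+1) * Gamma(1/(q-1)) / (sigma * Gamma(alpha+1) * Gamma(1/(q-1)-alpha-1))`.
#' Both are computed in log space and make the corresponding pdf integrate
#' to 1 (verified by quadrature in the test suite).
#'
#' @inheritParams qgamma_params
#' @return Normalization constant (1/bp).
#' @export
qgamma_norm <- function(a, sigma, q) {
  nu <- 1 / (q - 1)
  exp((a + 1) * log(q - 1) + lgamma(nu) - log(sigma) -
        lgamma(nu - a - 1) - lgamma(a + 1))
}

#' @rdname qgamma_norm
#' @export
invqgamma_norm <- function(alpha, sigma, q) {
  nu <- 1 / (q - 1)
  exp((alpha + 1) * log(q - 1) + lgamma(nu) - log(sigma) -
        lgamma(alpha + 1) - lgamma(nu - alpha - 1))
}

#' q-Gamma and inverse q-Gamma densities
#'
#' Pointwise densities, evaluated in log space (safe for extreme q or very
#' long tails). `params` may come from [qgamma_params()] /
#' [invqgamma_params()] (constrained or with free A) or from the mixture
#' mappings.
#'
#' @param l Lengths (bp), positive; vectorised.
#' @param params A `qgamma_params` / `invqgamma_params` object.
#' @param log Return log density?
#' @return Density (1/bp).
#' @export
dqgamma <- function(l, params, log = FALSE) {
  stopifnot(inherits(params, "qgamma_params"))
  lp <- ifelse(l > 0,
               base::log(params$A) +
                 params$a * (base::log(l) - base::log(params$sigma)) -
                 log1p((params$q - 1) * l / params$sigma) / (params$q - 1),
               -Inf)
  if (log) lp else exp(lp)
}

#' @rdname dqgamma
#' @export
dinvqgamma <- function(l, params, log = FALSE) {
  stopifnot(inherits(params, "invqgamma_params"))
  lp <- ifelse(l > 0,
               base::log(params$A) +
                 (-params$alpha - 2) * (base::log(l) - base::log(params$sigma)) -
                 log1p((params$q - 1) * params$sigma / l) / (params$q - 1),
               -Inf)
  if (log) lp else exp(lp)
}

#' @export
print.qgamma_params <- function(x, ...) {
  cat(sprintf("q-Gamma params: a = %.4g, sigma = %.4g bp, q = %.4g, A = %.4g (%s)\n",
              x$a, x$sigma, x$q, x$A,
              if (x$constrained) "constrained" else "free"))
  invisible(x)
}

#' @export
print.invqgamma_params <- function(x, ...) {
  cat(sprintf("inverse q-Gamma params: alpha = %.4g, sigma = %.4g bp, q = %.4g, A = %.4g (%s)\n",
              x$alpha, x$sigma, x$q, x$A,
              if (x$constrained) "constrained" else "free"))
  invisible(x)
}

# ---- mixture <-> marginal mappings -----------------------------------------

#' Closed-form marginal of the superstatistical mixture
#'
#' A gamma local law (shape `k`, mean xi) whose mean xi is drawn from an
#' inverse-gamma mixing law (shape `mu`, scale `omega`) has marginal exactly
#' the constrained q-Gamma with
#' `a = k - 1`, `q = 1 + 1/(k + mu)`, `sigma = omega / (k (k + mu))`.
#' Dually, an inverse-gamma local law (shape `alpha`, mean xi) with
#' xi ~ gamma (shape `delta`, scale `omega`) has marginal the constrained
#' inverse q-Gamma with
#' `q = 1 + 1/(alpha + delta + 1)`, `sigma = alpha omega (alpha + delta + 1)`.
#' These mappings are validated against numerical quadrature of the mixture
#' integral in the test suite (see [mixture_marginal_quadrature()]).
#'
#' @param k Local gamma shape (> 0).
#' @param mu,omega Inverse-gamma mixing shape and scale (> 0).
#' @return A constrained `qgamma_params`.
#' @export
qgamma_from_mixture <- function(k, mu, omega) {
  if (!all(is.finite(c(k, mu, omega))) || any(c(k, mu, omega) <= 0))
    abort("mixture parameters must be positive and finite", "superexon_validity_error")
  qgamma_params(a = k - 1,
                sigma = omega / (k * (k + mu)),
                q = 1 + 1 / (k + mu))
}

#' @rdname qgamma_from_mixture
#' @param alpha Local inverse-gamma shape (> 0).
#' @param delta Gamma mixing shape (> 0).
#' @export
invqgamma_from_mixture <- function(alpha, delta, omega) {
  if (!all(is.finite(c(alpha, delta, omega))) || any(c(alpha, delta, omega) <= 0))
    abort("mixture parameters must be positive and finite", "superexon_validity_error")
  invqgamma_params(alpha = alpha,
                   sigma = alpha * omega * (alpha + delta + 1),
                   q = 1 + 1 / (alpha + delta + 1))
}

#' Invert the mixture mapping
#'
#' Given constrained marginal parameters, recover the generating local shape
#' and mixing law. Inverse of [qgamma_from_mixture()] /
#' [invqgamma_from_mixture()]; used by the exact sampler and the synthetic
#' generator.
#'
#' @param params Constrained `qgamma_params` or `invqgamma_params`.
#' @return List: for q-Gamma, `k`, `mu`, `omega`; for inverse q-Gamma,
#'   `alpha`, `delta`, `omega`.
#' @export
mixture_from_marginal <- function(params) {
  if (inherits(params, "qgamma_params")) {
    k <- params$a + 1
    mu <- 1 / (params$q - 1) - k
    if (mu <= 0) abort("marginal has no inverse-gamma mixing representation (mu <= 0)",
                       "superexon_validity_error")
    list(k = k, mu = mu, omega = params$sigma * k * (k + mu))
  } else if (inherits(params, "invqgamma_params")) {
    delta <- 1 / (params$q - 1) - params$alpha - 1
    if (delta <= 0) abort("marginal has no gamma mixing representation (delta <= 0)",
                          "superexon_validity_error")
    list(alpha = params$alpha, delta = delta,
         omega = params$sigma * (params$q - 1) / params$alpha)
  } else abort("params must be qgamma_params or invqgamma_params",
               "superexon_validity_error")
}

#' Numerical quadrature of the mixture integral
#'
#' Independent oracle for the closed-form marginals: evaluates
#' `p(l) = integral f(l | xi) p(xi) dxi` by adaptive quadrature in log(xi),
#' rescaled by the integrand's peak so the relative accuracy is retained far
#' into the tail.
#'
#' @param l Lengths at which to evaluate (vectorised).
#' @param local `list(family = "gamma", k =)` or
#'   `list(family = "inverse_gamma", alpha =)`.
#' @param mixing `list(family = "inverse_gamma", mu =, omega =)` or
#'   `list(family = "gamma", delta =, omega =)`.
#' @return Marginal density values (1/bp).
#' @export
mixture_marginal_quadrature <- function(l, local, mixing) {
  log_f <- function(li, xi) {
    if (local$family == "gamma") dlocal_gamma(li, local$k, xi, log = TRUE)
    else dlocal_invgamma(li, local$alpha, xi, log = TRUE)
  }
  log_p <- function(xi) {
    if (mixing$family == "gamma") dmix_gamma(xi, mixing$delta, mixing$omega, log = TRUE)
    else dmix_invgamma(xi, mixing$mu, mixing$omega, log = TRUE)
  }
  vapply(l, function(li) {
    log_integrand <- function(u) log_f(li, exp(u)) + log_p(exp(u)) + u  # jacobian
    u_grid <- seq(log(mixing$omega) - 25, log(mixing$omega) + 25, length.out = 400)
    lv <- log_integrand(u_grid)
    m <- max(lv)
    lo <- min(u_grid[lv > m - 60]); hi <- max(u_grid[lv > m - 60])
    val <- stats::integrate(function(u) exp(log_integrand(u) - m), lo, hi,
                            rel.tol = 1e-11, subdivisions = 500L)$value
    val * exp(m)
  }, numeric(1))
}

# ---- sampling --------------------------------------------------------------

#' Draw from a q-family via its exact mixture representation
#'
#' Samples xi from the mixing law, then the length from the conditional
#' local law with mean xi; the marginal of the draws is exactly the target
#' q-family (no accept/reject approximation).
#'
#' @param params Constrained `qgamma_params` or `invqgamma_params`.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; same seed, same sample.
#' @return Numeric vector of n positive lengths (continuous, bp).
#' @export
sample_marginal <- function(params, n, seed = NULL) {
  if (!is_count(n) || n < 1) abort("n must be a positive integer", "superexon_validity_error")
  mix <- mixture_from_marginal(params)
  with_seed(seed, {
    if (inherits(params, "qgamma_params")) {
      xi <- 1 / stats::rgamma(n, shape = mix$mu, rate = mix$omega)
      stats::rgamma(n, shape = mix$k, rate = mix$k / xi)
    } else {
      xi <- stats::rgamma(n, shape = mix$delta, scale = mix$omega)
      (mix$alpha * xi) / stats::rgamma(n, shape = mix$alpha + 1)
    }
  })
}

#' Analytic CDF of a constrained q-family (by quadrature of the pdf)
#'
#' @param x Evaluation points.
#' @param params Constrained params object.
#' @return CDF values; used as the goodness-of-fit reference for the exact
#'   sampler.
#' @export
qfamily_cdf <- function(x, params) {
  pdf <- if (inherits(params, "qgamma_params")) function(l) dqgamma(l, params)
         else function(l) dinvqgamma(l, params)
  ord <- order(x)
  xs <- x[ord]  # cumulative quadrature over consecutive intervals
  pieces <- vapply(seq_along(xs), function(i) {
    lo <- if (i == 1) 0 else xs[i - 1]
    stats::integrate(pdf, lo, xs[i], rel.tol = 1e-10)$value
  }, numeric(1))
  out <- numeric(length(x))
  out[ord] <- cumsum(pieces)
  out
}

# ---- Levenberg-Marquardt marginal fitting ----------------------------------

# 7-point Gauss-Legendre nodes/weights on [-1, 1]
gl7 <- list(
  x = c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
        0.4058451513773972, 0.7415311855993945, 0.9491079123427585),
  w = c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
        0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
        0.1294849661688697))

# bin-averaged model density over [lo, hi): the exact expectation an
# empirical bin density estimates, so wide bins do not bias the fit
#' @keywords internal
#' @noRd
bin_average_pdf <- function(params, lo, hi) {
  pdf <- if (inherits(params, "qgamma_params")) function(l) dqgamma(l, params)
         else function(l) dinvqgamma(l, params)
  nodes <- outer((hi + lo) / 2, rep(1, 7)) + outer((hi - lo) / 2, gl7$x)
  vals <- matrix(pdf(as.vector(nodes)), nrow = length(lo))
  as.vector(vals %*% gl7$w) / 2
}

#' Fit a q-family to a binned density by Levenberg-Marquardt least squares
#'
#' Minimises squared residuals between the empirical bin densities and the
#' model's bin-averaged density (the exact expectation the histogram
#' estimates; evaluating the pdf at bin midpoints instead visibly biases
#' wide bins and is available via `bin_model = "midpoint"`).
#' `A_constrained` (default) ties the normalization to its closed-form
#' value, leaving 3 free parameters; `A_free` treats A as a 4th free
#' parameter. Residuals on the linear density by default; `log` scale
#' weights the tail. Linear residuals are scaled by the per-bin Poisson
#' standard error `sqrt(count)/(N width)` by default (`weights = "poisson"`,
#' the usual chi-square histogram weighting), which keeps the entropic index
#' identified both when the density diverges at the origin (all unweighted
#' residual mass sits in the first bins) and in the far tail;
#' `weights = "none"` gives plain least squares. Multistart over q.
#'
#' @param density A `binned_density`.
#' @param family `"q_gamma"` or `"inv_q_gamma"`.
#' @param mode `"A_constrained"` or `"A_free"`.
#' @param residual_scale `"linear"` or `"log"`.
#' @param init Optional named list of starting values
#'   (`a`/`alpha`, `sigma`, `q`, optionally `A`).
#' @param min_bins Minimum occupied bins (default 5).
#' @param bin_model `"average"` (default) or `"midpoint"`.
#' @param weights `"poisson"` (default; residuals scaled by the per-bin
#'   Poisson standard error) or `"none"`.
#' @return Object of class `marginal_fit`: list with `params`, `rss`,
#'   `n_points`, `mode`, `residual_scale`.
#' @export
fit_marginal <- function(density, family = c("q_gamma", "inv_q_gamma"),
                         mode = c("A_constrained", "A_free"),
                         residual_scale = c("linear", "log"),
                         init = NULL, min_bins = 5L,
                         bin_model = c("average", "midpoint"),
                         weights = c("poisson", "none")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  residual_scale <- match.arg(residual_scale)
  bin_model <- match.arg(bin_model)
  weights <- match.arg(weights)
  stopifnot(inherits(density, "binned_density"))
  occ <- density$counts > 0
  if (sum(occ) < min_bins)
    abort(sprintf("only %d occupied bins; need >= %d", sum(occ), min_bins),
          "superexon_validation_error")
  lc <- density$centers[occ]
  lo <- density$edges[-length(density$edges)][occ]
  hi <- density$edges[-1][occ]
  y <- density$density[occ]
  ly <- log(y)
  sd_y <- if (weights == "poisson") {
    sqrt(density$counts[occ]) / (density$n * density$widths[occ])
  } else rep(1, length(y))
  npar <- if (mode == "A_free") 4L else 3L
  if (sum(occ) < npar)
    abort("fewer occupied bins than free parameters", "superexon_validation_error")

  make_params <- function(th) {
    # th: shape, log sigma, q [, log A]
    tryCatch({
      if (family == "q_gamma")
        qgamma_params(th[1], exp(th[2]), th[3],
                      A = if (mode == "A_free") exp(th[4]) else NULL)
      else
        invqgamma_params(th[1], exp(th[2]), th[3],
                         A = if (mode == "A_free") exp(th[4]) else NULL)
    }, error = function(e) NULL)
  }
  resid_fn <- function(th) {
    p <- make_params(th)
    if (is.null(p)) return(rep(1e6, length(y)))
    mu <- if (bin_model == "average") bin_average_pdf(p, lo, hi)
          else if (family == "q_gamma") dqgamma(lc, p) else dinvqgamma(lc, p)
    if (residual_scale == "linear") (mu - y) / sd_y
    else ifelse(mu > 0, log(mu) - ly, 1e6)
  }

  # moment-flavoured default starts, multistarted over q
  mean_l <- sum(lc * y * density$widths[occ]) / sum(y * density$widths[occ])
  starts <- list()
  for (q0 in c(1.05, 1.12, 1.2, 1.35)) {
    sh0 <- if (family == "q_gamma") 0.5 else 0.8
    sg0 <- if (family == "q_gamma") mean_l / 2 else mean_l
    th0 <- c(sh0, log(sg0), q0)
    if (mode == "A_free") {
      p0 <- make_params(c(th0, 0))
      if (!is.null(p0)) {
        A0 <- if (family == "q_gamma") qgamma_norm(sh0, sg0, q0)
              else invqgamma_norm(sh0, sg0, q0)
        th0 <- c(th0, log(A0))
      } else th0 <- c(th0, 0)
    }
    starts[[length(starts) + 1L]] <- th0
  }
  if (!is.null(init)) {
    shape0 <- if (family == "q_gamma") init$a else init$alpha
    th0 <- c(shape0, log(init$sigma), init$q)
    if (mode == "A_free")
      th0 <- c(th0, log(if (is.null(init$A)) 1 else init$A))
    starts <- c(list(th0), starts)
  }

  lower <- c(if (family == "q_gamma") -1 + 1e-8 else 1e-8, -Inf, 1 + 1e-8)
  upper <- c(Inf, Inf, 3)
  if (mode == "A_free") { lower <- c(lower, -Inf); upper <- c(upper, Inf) }

  best <- NULL
  msgs <- character()
  for (th0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) e)
    if (inherits(f, "error")) { msgs <- c(msgs, conditionMessage(f)); next }
    rss <- sum(resid_fn(f$par)^2)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$rss) best <- list(par = f$par, rss = rss)
  }
  if (is.null(best) || is.null(make_params(best$par)))
    abort(paste("marginal fit failed from all starts:",
                paste(unique(msgs), collapse = "; ")), "superexon_fit_failure")
  structure(list(params = make_params(best$par), rss = best$rss,
                 n_points = sum(occ), mode = mode,
                 residual_scale = residual_scale),
            class = "marginal_fit")
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat(sprintf("marginal_fit (%s, %s residuals, %d bins, rss = %.3g)\n",
              x$mode, x$residual_scale, x$n_points, x$rss))
  print(x$params)
  invisible(x)
}
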