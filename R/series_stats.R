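# Empirical density, autocorrelation, and two-timescale extraction.

#' Binned probability density of exon lengths
#'
#' Default scheme is the linear box scale: bin widths grow linearly, the i-th
#' bin having width `25*i`, i.e. edges e_0 = 0, e_i = 25*i*(i+1)/2. This
#' smooths the sparse tail of heavy-tailed length distributions while keeping
#' the peak resolved. A uniform-width alternative is available.
#'
#' @param series An `exon_series`, or a numeric vector of positive lengths.
#' @param scheme `"linear_box"` (width of bin i is `base*i`) or
#'   `"uniform"` (constant width).
#' @param base Width increment for the linear box scale (bp). Default 25.
#' @param width Bin width for the uniform scheme (bp).
#' @return An object of class `binned_density`: list with `edges`, `centers`
#'   (midpoints), `widths`, `counts`, `density` (counts / (N * width)) and `n`.
#' @export
binned_density <- function(series, scheme = c("linear_box", "uniform"),
                           base = 25, width = 25) {
  scheme <- match.arg(scheme)
  x <- if (inherits(series, "exon_series")) series$lengths else as.numeric(series)
  if (length(x) < 1L) abort("empty series", "superexon_empty_input")
  if (any(x <= 0)) abort("lengths must be positive", "superexon_validation_error")
  mx <- max(x)
  if (scheme == "linear_box") {
    # smallest m with base*m*(m+1)/2 > mx (edges are half-open [lo, hi))
    m <- ceiling((-1 + sqrt(1 + 8 * (mx + 1) / base)) / 2)
    i <- seq_len(m)
    edges <- c(0, base * i * (i + 1) / 2)
  } else {
    edges <- seq(0, width * (ceiling(mx / width) + (mx %% width == 0)), by = width)
  }
  counts <- as.integer(table(cut(x, breaks = edges, right = FALSE,
                                 include.lowest = FALSE)))
  widths <- diff(edges)
  structure(list(edges = edges,
                 centers = (edges[-1] + edges[-length(edges)]) / 2,
                 widths = widths,
                 counts = counts,
                 density = counts / (length(x) * widths),
                 n = length(x)),
            class = "binned_density")
}

#' @export
print.binned_density <- function(x, ...) {
  cat(sprintf("binned_density: %d bins covering [0, %g) bp, n = %d, sum(d*w) = %.6f\n",
              length(x$counts), max(x$edges), x$n, sum(x$density * x$widths)))
  invisible(x)
}

#' Write a binned density as TSV (edge_lo, edge_hi, count, density)
#' @param density A `binned_density`.
#' @param path File path.
#' @export
write_density <- function(density, path) {
  d <- data.frame(edge_lo = density$edges[-length(density$edges)],
                  edge_hi = density$edges[-1],
                  count = density$counts,
                  density = density$density)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample autocorrelation of an exon-length series
#'
#' Biased (1/n) sample autocorrelation of the mean-centred lengths,
#' normalised so C(0) = 1.
#'
#' @param series An `exon_series` or numeric vector.
#' @param tau_max Maximum lag (exon index units).
#' @return Object of class `correlogram`: list with `lags` (0..tau_max) and
#'   `values`.
#' @export
autocorrelation <- function(series, tau_max) {
  x <- if (inherits(series, "exon_series")) series$lengths else as.numeric(series)
  stopifnot(is_count(tau_max), tau_max >= 1)
  if (length(x) < tau_max + 2)
    abort("series too short for requested tau_max", "superexon_validation_error")
  if (stats::var(x) == 0)
    abort("series has zero variance; autocorrelation undefined",
          "superexon_degenerate_series")
  ac <- stats::acf(x, lag.max = tau_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  ac <- ac / ac[1]  # exact C(0) = 1
  structure(list(lags = 0:tau_max, values = as.numeric(ac)),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("correlogram: lags 0..%d, C(1) = %.4f\n",
              max(x$lags), x$values[2]))
  invisible(x)
}

# model C(tau) = a exp(-tau/t1) + b exp(-tau/t2)
two_exp <- function(tau, a, b, t1, t2) a * exp(-tau / t1) + b * exp(-tau / t2)

#' Fit a double-exponential decay to a correlogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `C(tau) = a*exp(-tau/t1) + b*exp(-tau/t2)` with `t2 >= t1 > 0`,
#' multistarted over decades of initial (t1, t2). The short scale t1 is the
#' local relaxation scale and the long scale t2 the persistence scale of the
#' slowly varying intensive parameter; their ratio quantifies timescale
#' separation, a prerequisite of the superstatistical description.
#'
#' @param correlogram A `correlogram`.
#' @param fit_lags Integer lags to fit over; default all lags present.
#' @param ratio_threshold Separation flag threshold on t2/t1 (default 10).
#' @param starts Optional data.frame of starting values (a, b, t1, t2).
#' @return Object of class `timescale_fit`: list with `a`, `b`, `t1`, `t2`,
#'   `ratio` (= t2/t1), `fit_rss` and `scale_separation` (logical).
#' @export
fit_two_exponential <- function(correlogram, fit_lags = NULL,
                                ratio_threshold = 10, starts = NULL) {
  stopifnot(inherits(correlogram, "correlogram"))
  tau <- correlogram$lags
  y <- correlogram$values
  if (!is.null(fit_lags)) {
    keep <- tau %in% fit_lags
    tau <- tau[keep]; y <- y[keep]
  }
  if (length(tau) < 4L)
    abort("need at least 4 lags to fit 4 parameters", "superexon_validation_error")
  if (is.null(starts)) {
    grid <- expand.grid(t1 = c(0.5, 1.5, 5, 15), t2 = c(10, 50, 150, 500))
    grid <- grid[grid$t2 > grid$t1, ]
    starts <- data.frame(a = 0.6, b = 0.4, t1 = grid$t1, t2 = grid$t2)
  }
  best <- NULL
  diagnostics <- character()
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_exp(tau, a, b, t1, t2),
        start = as.list(starts[s, c("a", "b", "t1", "t2")]),
        lower = c(a = -Inf, b = -Inf, t1 = 1e-6, t2 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    abort(paste("two-exponential fit failed from all starts:",
                paste(unique(diagnostics), collapse = "; ")),
          "superexon_fit_failure")
  p <- stats::coef(best$fit)
  if (p[["t1"]] > p[["t2"]])  # enforce convention t2 >= t1 by swapping terms
    p <- c(a = p[["b"]], b = p[["a"]], t1 = p[["t2"]], t2 = p[["t1"]])
  ratio <- p[["t2"]] / p[["t1"]]
  structure(list(a = p[["a"]], b = p[["b"]], t1 = p[["t1"]], t2 = p[["t2"]],
                 ratio = ratio, fit_rss = best$rss,
                 scale_separation = ratio >= ratio_threshold),
            class = "timescale_fit")
}

#' @export
print.timescale_fit <- function(x, ...) {
  cat(sprintf(
    "timescale_fit: t1 = %.4g, t2 = %.4g, ratio t2/t1 = %.4g (%s), rss = %.3g\n",
    x$t1, x$t2, x$ratio,
    if (x$scale_separation) "scales separated" else "NO scale separation",
    x$fit_rss))
  invisible(x)
}
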