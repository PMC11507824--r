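# Per-chromosome and per-genome orchestration: series -> density ->
# autocorrelation -> timescales -> windows -> xi -> mixing -> marginal fits
# -> evidences -> Bayes factor, with stage-level error capture so one failed
# stage does not abort independent later stages.

#' Analysis configuration
#'
#' @param binning `"linear_box"` or `"uniform"`.
#' @param tau_max Maximum autocorrelation lag; default
#'   `min(600, floor(n/4))` at run time.
#' @param window_T Window length override; default the fitted `t2`.
#' @param fit_mode `"A_constrained"` or `"A_free"` for the marginal fits.
#' @param residual_scale `"linear"` or `"log"`.
#' @param run_evidence Run nested sampling for both families (the slow
#'   stage)?
#' @param nlive Live points for nested sampling.
#' @param min_exons Chromosomes with fewer exons are skipped (default 200).
#' @param seed Seed recorded in the report and used for every stochastic
#'   stage.
#' @return List of class `run_config`.
#' @export
run_config <- function(binning = "linear_box", tau_max = NULL,
                       window_T = NULL, fit_mode = "A_constrained",
                       residual_scale = "linear", run_evidence = FALSE,
                       nlive = 100L, min_exons = 200L, seed = 1L) {
  structure(list(binning = binning, tau_max = tau_max, window_T = window_T,
                 fit_mode = fit_mode, residual_scale = residual_scale,
                 run_evidence = run_evidence, nlive = as.integer(nlive),
                 min_exons = as.integer(min_exons), seed = as.integer(seed)),
            class = "run_config")
}

#' @keywords internal
#' @noRd
stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch(
    list(status = "ok", value = suppressWarnings(expr)),
    error = function(e) list(status = "failed", error = conditionMessage(e)))
  report
}

#' Run the full analysis on one chromosome
#'
#' @param series An `exon_series` (use [parse_exons()] + [build_series()] or
#'   [read_series()] to obtain one from files).
#' @param config A [run_config()].
#' @return Object of class `chromosome_report`: list with `chromosome`,
#'   `n_exons`, `status`, a `stages` list (each `status` + `value` or
#'   `error`), and convenience top-level fields `timescales`, `mixing`,
#'   `marginal_q_gamma`, `marginal_inv_q_gamma`, `comparison`, `provenance`.
#' @export
run_chromosome <- function(series, config = run_config()) {
  stopifnot(inherits(series, "exon_series"), inherits(config, "run_config"))
  n <- length(series$lengths)
  report <- list(chromosome = series$chromosome, n_exons = n,
                 stages = list(),
                 provenance = list(seed = config$seed, config = unclass(config),
                                   package_version = as.character(utils::packageVersion("superexon"))))
  if (n < config$min_exons) {
    report$status <- "skipped"
    report$reason <- sprintf("%d exons < minimum %d", n, config$min_exons)
    class(report) <- "chromosome_report"
    return(report)
  }
  report <- stage(report, "density", binned_density(series, scheme = config$binning))
  tau_max <- if (is.null(config$tau_max)) min(600L, floor(n / 4)) else config$tau_max
  report <- stage(report, "autocorrelation", autocorrelation(series, tau_max))
  if (report$stages$autocorrelation$status == "ok")
    report <- stage(report, "timescales",
                    fit_two_exponential(report$stages$autocorrelation$value))
  Tw <- config$window_T
  if (is.null(Tw) && !is.null(report$stages$timescales) &&
      report$stages$timescales$status == "ok")
    Tw <- max(2, min(round(report$stages$timescales$value$t2), floor(n / 20)))
  if (!is.null(Tw)) {
    report <- stage(report, "xi_gamma", xi_series(series, Tw, "gamma"))
    report <- stage(report, "xi_inverse_gamma", xi_series(series, Tw, "inverse_gamma"))
    if (report$stages$xi_gamma$status == "ok")
      report <- stage(report, "mixing_of_xi_gamma",
                      fit_mixing(report$stages$xi_gamma$value, "inverse_gamma"))
    if (report$stages$xi_inverse_gamma$status == "ok")
      report <- stage(report, "mixing_of_xi_inverse_gamma",
                      fit_mixing(report$stages$xi_inverse_gamma$value, "gamma"))
  }
  if (report$stages$density$status == "ok") {
    d <- report$stages$density$value
    report <- stage(report, "marginal_q_gamma",
                    fit_marginal(d, "q_gamma", mode = config$fit_mode,
                                 residual_scale = config$residual_scale))
    report <- stage(report, "marginal_inv_q_gamma",
                    fit_marginal(d, "inv_q_gamma", mode = config$fit_mode,
                                 residual_scale = config$residual_scale))
  }
  if (config$run_evidence) {
    report <- stage(report, "evidence_q_gamma",
                    compute_evidence(series, "q_gamma", nlive = config$nlive,
                                     seed = config$seed))
    report <- stage(report, "evidence_inv_q_gamma",
                    compute_evidence(series, "inv_q_gamma", nlive = config$nlive,
                                     seed = config$seed + 1L))
    if (report$stages$evidence_q_gamma$status == "ok" &&
        report$stages$evidence_inv_q_gamma$status == "ok")
      report <- stage(report, "comparison",
                      bayes_factor(report$stages$evidence_q_gamma$value,
                                   report$stages$evidence_inv_q_gamma$value))
  }
  ok <- function(s) !is.null(report$stages[[s]]) && report$stages[[s]]$status == "ok"
  val <- function(s) if (ok(s)) report$stages[[s]]$value else NULL
  report$timescales <- val("timescales")
  report$mixing <- list(of_xi_gamma = val("mixing_of_xi_gamma"),
                        of_xi_inverse_gamma = val("mixing_of_xi_inverse_gamma"))
  report$marginal_q_gamma <- val("marginal_q_gamma")
  report$marginal_inv_q_gamma <- val("marginal_inv_q_gamma")
  report$comparison <- val("comparison")
  report$status <- if (ok("marginal_q_gamma") || ok("marginal_inv_q_gamma"))
    "ok" else "failed"
  class(report) <- "chromosome_report"
  report
}

#' @export
print.chromosome_report <- function(x, ...) {
  cat(sprintf("chromosome_report: %s (%d exons, status %s)\n",
              x$chromosome, x$n_exons, x$status))
  if (!is.null(x$timescales)) print(x$timescales)
  if (!is.null(x$marginal_q_gamma))
    cat(sprintf("  q-Gamma fit:          q = %.4f\n", x$marginal_q_gamma$params$q))
  if (!is.null(x$marginal_inv_q_gamma))
    cat(sprintf("  inverse q-Gamma fit:  q = %.4f\n", x$marginal_inv_q_gamma$params$q))
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Run the analysis over several chromosomes and aggregate
#'
#' The genome-level summary is the unweighted mean of the chromosome-level
#' fitted entropic indices with the standard error of the mean (reported as
#' `NA` for a single chromosome).
#'
#' @param series_list Named list of `exon_series` objects.
#' @param config A [run_config()].
#' @return Object of class `genome_report`: `chromosomes` (reports),
#'   `table` (per-chromosome data.frame), `aggregate` (means and SEs of q),
#'   `failures`.
#' @export
run_genome <- function(series_list, config = run_config()) {
  stopifnot(length(series_list) >= 1)
  reports <- lapply(series_list, run_chromosome, config = config)
  succ <- vapply(reports, function(r) identical(r$status, "ok"), logical(1))
  if (!any(succ))
    abort("all chromosomes failed or were skipped", "superexon_aggregate_error")
  get_q <- function(r, fam) {
    f <- r[[fam]]
    if (is.null(f)) NA_real_ else f$params$q
  }
  tab <- data.frame(
    chromosome = vapply(reports, function(r) r$chromosome, character(1)),
    n_exons = vapply(reports, function(r) r$n_exons, numeric(1)),
    status = vapply(reports, function(r) r$status %||% "failed", character(1)),
    t2_over_t1 = vapply(reports, function(r)
      if (is.null(r$timescales)) NA_real_ else r$timescales$ratio, numeric(1)),
    q_G = vapply(reports, get_q, numeric(1), fam = "marginal_q_gamma"),
    q_IG = vapply(reports, get_q, numeric(1), fam = "marginal_inv_q_gamma"),
    ln_B12 = vapply(reports, function(r)
      if (is.null(r$comparison)) NA_real_ else r$comparison$ln_B12, numeric(1)),
    row.names = NULL)
  agg <- function(v) {
    v <- v[is.finite(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
         n = length(v))
  }
  structure(list(chromosomes = reports, table = tab,
                 aggregate = list(q_G = agg(tab$q_G[succ]),
                                  q_IG = agg(tab$q_IG[succ])),
                 failures = tab$chromosome[!succ]),
            class = "genome_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genome_report <- function(x, ...) {
  cat(sprintf("genome_report: %d chromosomes (%d ok)\n",
              nrow(x$table), sum(x$table$status == "ok")))
  print(x$table)
  a <- x$aggregate
  cat(sprintf("mean q_G  = %.4f +/- %s (n = %d)\n", a$q_G$mean,
              ifelse(is.na(a$q_G$se), "NA", sprintf("%.4f", a$q_G$se)), a$q_G$n))
  cat(sprintf("mean q_IG = %.4f +/- %s (n = %d)\n", a$q_IG$mean,
              ifelse(is.na(a$q_IG$se), "NA", sprintf("%.4f", a$q_IG$se)), a$q_IG$n))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' @param report A `chromosome_report` or `genome_report`.
#' @param path Output path.
#' @export
report_to_json <- function(report, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  jsonlite::write_json(strip(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
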