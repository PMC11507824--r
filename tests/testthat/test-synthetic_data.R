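test_that("generator config is validated", {
  expect_error(synthetic_config("gamma_local_invgamma_mixing", 0.5,
                                list(delta = 1, omega = 1)),
               class = "superexon_validation_error")
  expect_error(synthetic_config("gamma_local_invgamma_mixing", -0.5,
                                list(mu = 15, omega = 4000)),
               class = "superexon_validation_error")
  expect_warning(synthetic_config("gamma_local_invgamma_mixing", 0.5,
                                  list(mu = 15, omega = 4000),
                                  T_true = 121, n = 500),
                 "recommended")
})

test_that("generated series are reproducible and carry ground truth", {
  cfg <- synthetic_config("gamma_local_invgamma_mixing", 0.5,
                          list(mu = 15, omega = 4000), n = 5000, seed = 2)
  g1 <- generate_series(cfg)
  g2 <- generate_series(cfg)
  expect_identical(g1$series$lengths, g2$series$lengths)
  expect_s3_class(g1$truth$marginal, "qgamma_params")
  expect_equal(g1$truth$marginal$q, 1 + 1 / 15.5)
  expect_equal(sum(g1$truth$durations) >= 5000, TRUE)
})

test_that("the generated marginal matches the implied q-family", {
  cfg <- synthetic_config("gamma_local_invgamma_mixing", 0.5,
                          list(mu = 15, omega = 4000), T_true = 121,
                          t1_true = 1.3, n = 1e5, seed = 3)
  g <- generate_series(cfg)
  p <- g$truth$marginal
  x <- g$series$lengths
  grid <- exp(seq(log(0.5), log(max(x) + 1), length.out = 3000))
  cdf <- approxfun(grid, qfamily_cdf(grid, p), yleft = 0, yright = 1)
  # thin far beyond the persistence scale T so draws are near-independent,
  # and jitter the integer rounding back out
  set.seed(1)
  idx <- seq(1, length(x), by = 400)
  ks <- suppressWarnings(ks.test(x[idx] + runif(length(idx)) - 0.5, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("windowed xi estimates track the true per-window xi", {
  cfg <- synthetic_config("gamma_local_invgamma_mixing", 0.5,
                          list(mu = 15, omega = 4000), T_true = 121,
                          t1_true = 1.3, n = 121 * 500, seed = 4,
                          sojourn = "fixed")
  g <- generate_series(cfg)
  xv <- quiet(xi_series(g$series, 121, "inverse_gamma"))$xi_values
  truth_var <- g$truth$xi[seq_along(xv)]^2 / 0.5  # window variance xi^2/k
  expect_gt(cor(xv, truth_var, method = "spearman"), 0.5)
})

test_that("short relaxation disappears in the t1 -> 0 limit", {
  cfg <- synthetic_config("gamma_local_invgamma_mixing", 0.5,
                          list(mu = 15, omega = 4000), T_true = 2000,
                          t1_true = 1e-6, n = 2e4, seed = 5)
  g <- generate_series(cfg)
  # within-segment lag-1 correlation of the copula ranks is ~ 0
  z <- qnorm(pmin(pmax(stats::pgamma(g$series$lengths + 0.5, 0.5,
                                     rate = 0.5 / rep(g$truth$xi,
                                                      g$truth$durations)[seq_len(2e4)]),
                       1e-9), 1 - 1e-9))
  expect_lt(abs(cor(z[-1], z[-2e4])), 0.03)
})

test_that("iid generator hits the family mean and is seeded", {
  s <- generate_iid("gamma", list(k = 0.3785, xi = 768.3620), 1e5, seed = 6)
  expect_equal(mean(s$lengths), 768.3620, tolerance = 0.01)
  expect_identical(generate_iid("gamma", list(k = 0.3785, xi = 768.3620),
                                1e5, seed = 6)$lengths, s$lengths)
  one <- generate_iid("inverse_gamma", list(alpha = 1.2, xi = 260), 1, seed = 7)
  expect_length(one$lengths, 1L)
  expect_gte(one$lengths, 1L)
  expect_error(generate_iid("gamma", list(k = 1, xi = 100), 0),
               class = "superexon_validation_error")
})

test_that("fixtures round-trip through GFF3 and TSV", {
  s <- exon_series(c(100L, 150L, 11L), chromosome = "F1")
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_fixture(s, "gff3", gff)
  back <- build_series(parse_exons(gff), "F1")
  expect_identical(back$lengths, s$lengths)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fixture(s, "tsv", tsv)
  expect_identical(read_series(tsv, "F1")$lengths, s$lengths)

  big <- generate_iid("gamma", list(k = 0.5, xi = 300), 2000, seed = 8)
  gff2 <- withr::local_tempfile(fileext = ".gff3")
  write_fixture(big, "gff3", gff2)
  expect_identical(build_series(parse_exons(gff2), "synthetic_iid")$lengths,
                   big$lengths)
})
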