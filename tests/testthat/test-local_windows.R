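test_that("segmentation discards the trailing remainder", {
  s <- exon_series(rep(5L, 1000))
  w <- segment_series(s, 121)
  expect_length(w, 8L)
  expect_true(all(vapply(w, function(x) length(x$lengths), integer(1)) == 121L))
  expect_equal(vapply(w, `[[`, integer(1), "start"), seq(1L, by = 121L, length.out = 8))
  expect_length(segment_series(exon_series(rep(2L, 121)), 121), 1L)
  expect_error(segment_series(s, 0), class = "superexon_window_error")
  expect_error(segment_series(exon_series(rep(2L, 10)), 50),
               class = "superexon_window_error")
})

test_that("local ML fits recover the mean-parametrized families", {
  set.seed(31)
  xg <- rgamma(1e5, shape = 0.5, rate = 0.5 / 700)
  fg <- fit_local(xg, "gamma")
  expect_equal(fg$k, 0.5, tolerance = 0.02 / 0.5)
  expect_equal(fg$xi, 700, tolerance = 0.02)

  xi_true <- 260
  xig <- (1.2 * xi_true) / rgamma(1e5, shape = 2.2)
  fig <- fit_local(xig, "inverse_gamma")
  expect_equal(fig$alpha, 1.2, tolerance = 0.05 / 1.2)
  expect_equal(fig$xi, 260, tolerance = 0.03)
})

test_that("fitted xi approaches the sample mean in both families", {
  set.seed(32)
  x <- rgamma(2e4, shape = 3, rate = 3 / 100)
  expect_equal(fit_local(x, "gamma")$xi, mean(x), tolerance = 0.01)
  y <- (2 * 150) / rgamma(2e4, shape = 3)  # alpha = 2, xi = 150
  expect_equal(fit_local(y, "inverse_gamma")$xi, mean(y), tolerance = 0.05)
})

test_that("degenerate windows are skipped with a classed warning", {
  expect_warning(out <- fit_local(rep(5, 50), "gamma"),
                 class = "superexon_skip")
  expect_null(out)
  expect_warning(fit_local(c(1, 2, 3), "gamma"), class = "superexon_skip")
})

test_that("xi series uses population variance with unit constant", {
  s <- exon_series(c(10L, 14L, 10L, 14L))
  xg <- quiet(xi_series(s, 2, "gamma"))
  xig <- quiet(xi_series(s, 2, "inverse_gamma"))
  expect_equal(xg$xi_values, c(0.25, 0.25))
  expect_equal(xig$xi_values, c(4, 4))
  # gamma flavour is the reciprocal of the inverse-gamma flavour per window
  expect_equal(xg$xi_values * xig$xi_values, rep(1, 2))
})

test_that("xi fluctuations shrink with window size on iid data", {
  set.seed(33)
  x <- exon_series(pmax(1, round(rgamma(6e4, 2, scale = 100))))
  v_small <- var(xi_series(x, 50, "inverse_gamma")$xi_values)
  v_large <- var(xi_series(x, 500, "inverse_gamma")$xi_values)
  expect_lt(v_large, v_small)
})

test_that("two variance regimes give bimodal xi values", {
  set.seed(34)
  lo <- pmax(1, round(rnorm(5000, 100, 5)))
  hi <- pmax(1, round(rnorm(5000, 100, 50)))
  s <- exon_series(c(lo, hi))
  xv <- xi_series(s, 100, "inverse_gamma")$xi_values
  first <- xv[1:50]; second <- xv[51:100]
  expect_gt(median(second) / median(first), 10)
})

test_that("mixing fits recover generating parameters within 5%", {
  set.seed(35)
  xi_g <- rgamma(1e4, shape = 18, scale = 18)
  fg <- fit_mixing(xi_g, "gamma")
  expect_equal(fg$delta, 18, tolerance = 0.05)
  expect_equal(fg$omega, 18, tolerance = 0.05)

  xi_ig <- 4000 / rgamma(1e4, shape = 15)
  fig <- fit_mixing(xi_ig, "inverse_gamma")
  expect_equal(fig$mu, 15, tolerance = 0.05)
  expect_equal(fig$omega, 4000, tolerance = 0.05)

  expect_error(fit_mixing(xi_g[1:5], "gamma"),
               class = "superexon_insufficient_data")
})
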