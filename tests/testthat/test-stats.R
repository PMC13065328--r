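# build an sf_spectrum object directly from bin powers
toy_spectrum <- function(power, lo = 5, hi = 50, f = 10,
                         max_size = 1 / 5) {
  structure(list(bin_edges = seq(lo, hi, length.out = length(power) + 1),
                 power = power, f = f, rank = 14L, variant = "phase_only",
                 sf_range = c(lo, hi), dc_removal = TRUE,
                 total_weight = sum(power), excluded_weight = 0,
                 n_standing_components = 0L, max_triangle_size = max_size),
            class = "sf_spectrum")
}

test_that("a noiseless power law is fit exactly", {
  sp <- toy_spectrum(rep(1, 20))
  lam <- 1 / spectrum_bin_centers(sp)
  sp$power <- lam^1.0          # P ~ lambda
  fit <- loglog_regression(sp)
  expect_equal(fit$slope, 1.0, tolerance = 1e-6)
  expect_equal(fit$r, 1.0, tolerance = 1e-9)
  flat <- loglog_regression(toy_spectrum(rep(2.5, 20)))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
})

test_that("bins below the maximum triangle size are excluded, zeros dropped", {
  sp <- toy_spectrum(c(0, 1, 2, 0, 3, 4, 5, 6, 1, 2), lo = 2, hi = 12,
                     max_size = 1 / 5)
  fit <- loglog_regression(sp)
  ctr <- spectrum_bin_centers(sp)
  expect_equal(fit$n_points, sum(ctr >= 5 & sp$power > 0))
  expect_equal(fit$n_zero_dropped, sum(ctr >= 5 & sp$power == 0))
  expect_error(loglog_regression(toy_spectrum(c(0, 0, 1, 1, 0), lo = 2,
                                              hi = 12, max_size = 1 / 5)),
               "fewer than 3")
})

test_that("a noisy planted power law is recovered without bias", {
  set.seed(20)
  slopes <- replicate(100, {
    sp <- toy_spectrum(rep(1, 24))
    lam <- 1 / spectrum_bin_centers(sp)
    sp$power <- lam^1.5 * exp(rnorm(24, sd = 0.05))
    loglog_regression(sp)$slope
  })
  expect_lt(abs(mean(slopes) - 1.5), 0.1)
})

test_that("permutation p-values are calibrated at the extremes", {
  y <- log(seq(2, 40, length.out = 15))
  fit <- list(y = y, yhat = y)   # perfect fit
  p <- permutation_pvalue(list(fit), n_perm = 1000, seed = 1)
  expect_equal(as.numeric(p), 1 / 1001)
  expect_error(permutation_pvalue(list(list(y = rep(1, 5),
                                            yhat = 1:5)), n_perm = 1000),
               "constant")
  expect_error(permutation_pvalue(list(fit), n_perm = 10), "at least")
})

test_that("duplicating every group member leaves the statistic unchanged", {
  set.seed(21)
  g <- list(list(y = rnorm(12), yhat = rnorm(12)),
            list(y = rnorm(12), yhat = rnorm(12)))
  p1 <- permutation_pvalue(g, n_perm = 2000, seed = 3)
  p2 <- permutation_pvalue(c(g, g), n_perm = 2000, seed = 3)
  expect_equal(attr(p1, "observed"), attr(p2, "observed"))
  expect_true(as.numeric(p2) > 0 && as.numeric(p2) <= 1)
})

test_that("p-values are invariant to monotone rescaling of power", {
  sp <- toy_spectrum(rep(1, 18))
  lam <- 1 / spectrum_bin_centers(sp)
  set.seed(22)
  sp$power <- lam^1.2 * exp(rnorm(18, sd = 0.3))
  f1 <- loglog_regression(sp)
  sp2 <- sp; sp2$power <- sp$power * 1e4
  f2 <- loglog_regression(sp2)
  p1 <- permutation_pvalue(f1, n_perm = 1000, seed = 5)
  p2 <- permutation_pvalue(f2, n_perm = 1000, seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
})

test_that("peak statistics separate a power trend from a static peak location", {
  # spectra share one shape, scaled by 1/f across temporal frequencies
  tfs <- c(2, 4, 8, 16, 32)
  shape <- c(1, 3, 6, 4, 2, 1, 0.5, 0.2, 0.1, 0.05)
  spectra <- lapply(tfs, function(f)
    toy_spectrum(shape / f, lo = 5, hi = 25, f = f))
  ps <- peak_statistics(spectra, n_perm = 2000, seed = 6)
  expect_lt(ps$peak_power_fit$slope, 0)
  expect_lt(ps$peak_power_fit$p, 0.05)
  expect_false(any(ps$table$tie))
  expect_equal(length(unique(ps$table$peak_sf)), 1)
  expect_true(is.na(ps$peak_sf_fit$p) || ps$peak_sf_fit$p > 0.05)
  expect_equal(ps$peak_sf_fit$slope, 0, tolerance = 1e-9)
  expect_error(peak_statistics(spectra[1]), ">= 3")
  # ties go to the lowest spatial-frequency bin and are flagged
  tied <- toy_spectrum(c(1, 5, 5, 2), lo = 5, hi = 25)
  pk <- spectrum_peak_sf(tied)
  expect_true(attr(pk, "tie"))
  expect_equal(as.numeric(pk), spectrum_bin_centers(tied)[2])
})

test_that("shuffled temporal-frequency labels destroy the peak-power trend", {
  tfs <- c(2, 4, 8, 16, 32)
  shape <- c(1, 3, 6, 4, 2, 1, 0.5, 0.2, 0.1, 0.05)
  powers <- shape[3] / tfs
  set.seed(7)
  hits <- 0
  for (i in 1:20) {
    perm <- sample(powers)
    fit <- lm(perm ~ log(tfs))
    p <- permutation_pvalue(list(list(y = perm,
                                      yhat = as.numeric(fitted(fit)))),
                            n_perm = 1000, seed = 100 + i)
    if (as.numeric(p) > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of label shuffles non-significant
})
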