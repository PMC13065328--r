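test_that("the spherical gradient basis encodes arc length along the axis", {
  fx <- fix_seeg()
  b <- suppressWarnings(
    spherical_gradient_basis(fx$mesh, fx$projection, "ap", 4))
  expect_equal(Mod(as.complex(b)), rep(1, nrow(fx$gray)))
  s <- attr(b, "arc_length")
  # closed form: arc length = R * polar angle from the +y pole
  hemi <- as.character(fx$gray$hemisphere)
  for (h in unique(hemi)) {
    vsel <- fx$mesh$hemisphere == h
    vv <- fx$mesh$vertices[vsel, , drop = FALSE]
    ctr <- colMeans(vv)
    R <- mean(sqrt(rowSums(sweep(vv, 2, ctr)^2)))
    idx <- which(hemi == h)
    u <- sweep(fx$projection$points[idx, , drop = FALSE], 2, ctr)
    u <- u / sqrt(rowSums(u^2))
    expect_equal(s[idx], R * acos(pmin(1, pmax(-1, u %*% c(0, 1, 0)))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # phase difference of 2 pi * sf * delta_s between two contacts
  i <- which.max(s); j <- which.min(s)
  dphi <- Arg(b[j] * Conj(b[i]))
  expect_equal(dphi, Arg(exp(1i * 2 * pi * 4 * (s[i] - s[j]))),
               tolerance = 1e-10)
  # near-zero sf approaches a constant phase vector
  b0 <- suppressWarnings(
    spherical_gradient_basis(fx$mesh, fx$projection, "ap", 1e-9))
  expect_lt(max(abs(Arg(b0 * Conj(b0[1])))), 1e-6)
  expect_error(spherical_gradient_basis(fx$mesh, fx$projection, "ap", -1),
               "positive")
})

test_that("surrogate time series are rank one and involutive in time", {
  set.seed(2)
  basis <- exp(-1i * runif(20, -pi, pi))
  rsv <- complex(real = rnorm(100), imaginary = rnorm(100))
  sur <- surrogate_timeseries(basis, rsv)
  s <- svd(sur)
  expect_lt(s$d[2] / s$d[1], 1e-10)
  # constant unit rsv: static field equal to the basis at every sample
  sur2 <- surrogate_timeseries(basis, rep(1 + 0i, 50))
  expect_equal(sur2, matrix(basis, 20, 50), ignore_attr = TRUE)
  # double reversal plus double conjugation is the identity
  expect_equal(Conj(rev(Conj(rev(rsv)))), rsv)
})

test_that("injection is phasor addition with the identity at zero weight", {
  fxp <- fix_seeg_field()
  sur <- matrix(exp(-1i * 0.5), nrow(fxp$values), ncol(fxp$values))
  out0 <- inject_surrogate(fxp, sur, 0)
  expect_equal(out0$values, fxp$values)
  out_inf <- inject_surrogate(fxp, sur, 1e8)
  expect_lt(max(Mod(out_inf$values - sur)), 1e-6)
  # two unit phasors at 0 and pi/2 with equal weight average to pi/4
  z <- inject_surrogate(matrix(exp(0i), 1, 1),
                        matrix(exp(1i * pi / 2), 1, 1), 1)
  expect_equal(Arg(z[1, 1]), pi / 4)
  expect_error(inject_surrogate(fxp, sur[, 1:10], 1), "shape")
  expect_error(inject_surrogate(fxp, sur, -0.1), "non-negative")
})

test_that("mixture ratios convert to additive weights", {
  expect_equal(ratio_to_weight(0), 0)
  expect_equal(ratio_to_weight(1 / 3), 0.5)
  expect_equal(ratio_to_weight(1 / 2), 1)
  expect_equal(ratio_to_weight(2 / 3), 2)
  expect_equal(ratio_to_weight(7 / 8), 7)
  expect_error(ratio_to_weight(1), "ratio")
})

test_that("reversing one singular value is the identity up to renormalization", {
  set.seed(3)
  z <- exp(-1i * matrix(runif(20 * 80, -pi, pi), 20, 80))
  sv <- complex_svd(phase_matrix(z, 10, 500), rank = 5)
  out <- reverse_singular_weights(sv, n = 1)
  ref <- reconstruct(sv)
  expect_equal(out$values, ref / Mod(ref))
  expect_error(reverse_singular_weights(sv, n = 6), "below")
  # weight-level involution
  d <- sv$d
  w1 <- d; w1[1:4] <- rev(w1[1:4])
  w2 <- w1; w2[1:4] <- rev(w2[1:4])
  expect_identical(w2, d)
})

test_that("sparsification keeps the printed count and is seed-stable", {
  z <- matrix(exp(0i), 151, 10)
  contacts <- data.frame(hemisphere = rep("left", 151))
  out <- sparsify_contacts(z, contacts, 1 / 3, seed = 1)
  expect_length(out$indices, 51)
  out2 <- sparsify_contacts(z, contacts, 1 / 3, seed = 2)
  expect_length(out2$indices, 51)
  expect_false(identical(out$indices, out2$indices))
  same <- sparsify_contacts(z, contacts, 1 / 3, seed = 1)
  expect_identical(out$indices, same$indices)
  all_kept <- sparsify_contacts(z, contacts, 1, seed = 1)
  expect_identical(all_kept$indices, 1:151)
  expect_error(sparsify_contacts(z[1:6, ], contacts[1:6, , drop = FALSE],
                                 1 / 3, seed = 1), "fewer than 3")
})

test_that("average-reference loading subtracts the scaled common mode", {
  set.seed(4)
  m <- matrix(rnorm(60), 6, 10)
  expect_identical(load_average_reference(m, 0), m)
  centered <- sweep(m, 2, colMeans(m))
  expect_equal(load_average_reference(centered, 1), centered)
  out <- load_average_reference(m, 8)
  expect_equal(out, m - 8 * matrix(colMeans(m), 6, 10, byrow = TRUE))
  rec <- raw_recording(m, 500)
  expect_equal(load_average_reference(rec, 2)$signal,
               m - 2 * matrix(colMeans(m), 6, 10, byrow = TRUE))
})

test_that("reference loading neither drowns the spectrum nor fakes a low-SF peak", {
  fx <- fix_seeg()
  basis <- suppressWarnings(
    spherical_gradient_basis(fx$mesh, fx$projection, "ap", 9))
  v <- exp(-1i * 2 * pi * 8 * (1:400) / 500)
  z <- outer(as.complex(basis), Conj(v))
  spec_of <- function(zz) {
    pmx <- phase_matrix(zz / Mod(zz), 8, 500)
    build_spectrum(complex_svd(pmx, rank = 3), fx$triangles,
                   K = 50, sf_range = c(0, 50), dc_removal = TRUE)
  }
  sp0 <- spec_of(z)
  sp2 <- spec_of(load_average_reference(z, 2))
  sp8 <- spec_of(load_average_reference(z, 8))
  ctr <- spectrum_bin_centers(sp0)
  inr <- ctr >= 5
  # in-range spectral ordering survives reference loading, degrading
  # gracefully as the loading grows to eight times the usual reference
  expect_gt(cor(sp0$power[inr], sp2$power[inr], method = "spearman"), 0.7)
  expect_gt(cor(sp0$power[inr], sp8$power[inr], method = "spearman"), 0.6)
  # standing-wave removal leaves no spurious maximum below the range
  expect_lt(sum(sp8$power[!inr]), 0.1 * sum(sp8$power))
})
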