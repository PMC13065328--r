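# count sign changes, ignoring exact zeros
zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Random-walk Hankel demonstration of the SVD-Fourier correspondence
#'
#' Generates a one-dimensional random walk, removes its very low frequency
#' drift (first difference, re-integration, and subtraction of a centered
#' moving average one window long), windows successive length-`w` segments
#' with a Gaussian to form a Hankel matrix, and decomposes it.  The left
#' singular vectors come in quadrature pairs approximating one-cycle
#' Morlet wavelets of increasing frequency; the first pair completes about
#' one cycle across the window.
#'
#' @param t number of random-walk samples (default 6144; must be >= 2 * w).
#' @param w window / Hankel row count (default 1024).
#' @param sigma Gaussian window width (default `w / 3`, wide enough
#'   that the quadrature partners of a pair stay strongly correlated
#'   under a quarter-period shift while the taper still suppresses
#'   segment edges).
#' @param n_pairs leading singular-vector pairs to return (default 4).
#' @param seed integer seed.
#' @return List with `lsv` (w x 2 * n_pairs), `d` (singular values),
#'   `pair_crossings` (zero-crossing count per pair, from the first member),
#'   `window`, `w`.
#' @export
random_walk_hankel_demo <- function(t = 6144L, w = 1024L, sigma = w / 3,
                                    n_pairs = 4L, seed = NULL) {
  if (t < 2L * w) stop("need t >= 2 * w")
  if (!is.null(seed)) set.seed(seed)
  walk <- cumsum(rnorm(t))
  # high-pass: difference, re-integrate, subtract centered moving average
  x <- cumsum(diff(walk))
  ma <- stats::filter(x, rep(1 / w, w), sides = 2)
  keep <- !is.na(ma)
  x <- x[keep] - ma[keep]
  n <- length(x)
  Tcols <- n - w + 1L
  g <- exp(-((seq_len(w) - (w + 1) / 2)^2) / (2 * sigma^2))
  A <- matrix(NA_real_, w, Tcols)
  for (j in seq_len(Tcols)) A[, j] <- x[j:(j + w - 1L)] * g
  s <- svd(A, nu = 2L * n_pairs, nv = 0L)
  lsv <- s$u[, seq_len(2L * n_pairs), drop = FALSE]
  pair_crossings <- vapply(seq_len(n_pairs), function(p)
    zero_crossings(lsv[, 2L * p - 1L]), numeric(1))
  list(lsv = lsv, d = s$d, pair_crossings = pair_crossings,
       window = g, w = w)
}

#' Wave-image demonstration of reading singular values as a spectrum
#'
#' Builds a synthetic diagonal plane-wave image: components at horizontal
#' wavenumbers 1..`n_components` cycles per `width`-pixel array with
#' amplitudes `1 / k`, each at a slightly different temporal frequency
#' near `tf` inside the two-cycle wavelet band (mimicking the dispersion
#' of natural waves) plus mild smooth noise.  The vertical axis is treated
#' as time at 1 ms/pixel; phase at `tf` is extracted per column, the
#' horizontal phase vectors are decomposed by SVD, and each component's
#' wavenumber (cycles across the array) is read off its spatial Fourier
#' peak.  The singular values then form a monotone spatial-frequency
#' spectrum: the dominant component is one cycle per array, successive
#' components increment the wavenumber and contribute successively less.
#'
#' @param width array width in pixels (default 512).
#' @param tf nominal temporal frequency in Hz at 1 ms/pixel (default 15,
#'   i.e. the image's dominant vertical spatial frequency is 15 cycles per
#'   1000 pixels).
#' @param scans number of vertical scans of the array (image height =
#'   `scans * width` pixels; default 3).
#' @param n_components planted horizontal wavenumbers (default 6).
#' @param noise_sd amplitude of the smooth noise texture (default 0.02).
#' @param rank components retained in the SVD (default 8).
#' @param seed integer seed.
#' @return List with `wavenumbers` (cycles per array, per component),
#'   `d` (singular values), `svd`, `phase` (the [phase_matrix()]), `image`.
#' @export
wave_image_demo <- function(width = 512L, tf = 15, scans = 3L,
                            n_components = 6L, noise_sd = 0.02,
                            rank = 8L, seed = 1L) {
  if (!is.null(seed)) set.seed(seed)
  fs <- 1000
  height <- scans * width
  x <- seq_len(width) - 1L
  y <- seq_len(height) - 1L
  img <- matrix(0, height, width)
  # spread the component TFs across the wavelet band so the time courses
  # decorrelate and the SVD can separate the spatial wavenumbers
  tfs <- tf + (seq_len(n_components) - 1L) * 1.5
  phi0 <- runif(n_components, -pi, pi)
  for (k in seq_len(n_components)) {
    theta <- outer(2 * pi * tfs[k] * y / fs, 2 * pi * k * x / width, `-`) +
      phi0[k]
    img <- img + (1 / k) * cos(theta)
  }
  if (noise_sd > 0) {
    noise <- matrix(rnorm(height * width), height, width)
    sm <- function(m) {
      kk <- rep(1 / 9, 9)
      m <- t(apply(m, 1L, function(r)
        as.numeric(stats::filter(r, kk, circular = TRUE))))
      apply(m, 2L, function(cl)
        as.numeric(stats::filter(cl, kk, circular = TRUE)))
    }
    img <- img + noise_sd * sm(noise)
  }
  # columns are 'contacts', vertical axis is time.  The band amplitude is
  # retained (amplitude variant): re-normalizing a dominant wave plus
  # weaker components to unit modulus mirrors each component about the
  # dominant wavenumber (two-sided sidebands), which would split every
  # planted wavenumber into a degenerate pair; the complex band signal
  # keeps the spectrum one-sided so the components read off cleanly.
  pm <- morlet_phase(t(img), fs = fs, f = tf, variant = "amplitude")
  sv <- complex_svd(pm, rank = rank)
  wavenumbers <- vapply(seq_len(rank), function(r) {
    sp <- Mod(fft(sv$lsv[, r]))
    which.max(sp[2:(width %/% 2)])   # skip DC; index = cycles per array
  }, numeric(1))
  list(wavenumbers = wavenumbers, d = sv$d, svd = sv, phase = pm,
       image = img)
}
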