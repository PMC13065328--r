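# Gaussian width convention for the truncated two-cycle kernel:
# sigma_t = MORLET_SIGMA_RATIO / f.  Calibrated once so that the realized
# discrete 4.5 Hz kernel at 1000 Hz has a half-power band of (2.77, 6.84) Hz,
# the closest this kernel family comes to the nominal (2.5, 6.8) Hz band of
# a two-cycle wavelet at that frequency (the zero-mean correction floors the
# lower crossing).  Fixed for all frequencies.
MORLET_SIGMA_RATIO <- 0.27

#' Logarithmically spaced center temporal frequencies
#'
#' Geometric progression of analysis frequencies; the defaults give the 34
#' standard center frequencies from 1.0 to 97.0 Hz.
#'
#' @param fmin,fmax first and last frequency (Hz), `fmin < fmax`, both > 0.
#' @param n number of frequencies (>= 2).
#' @return Numeric vector of length `n`, `[1] == fmin`, `[n] == fmax`.
#' @export
#' @examples
#' center_frequencies()        # 34 values, 1 .. 97 Hz
#' center_frequencies(n = 2)   # c(1, 97)
center_frequencies <- function(fmin = 1.0, fmax = 97.0, n = 34L) {
  if (fmin <= 0 || fmax <= 0) stop("frequencies must be positive")
  if (!(fmin < fmax) || n < 2L) stop("need fmin < fmax and n >= 2")
  exp(seq(log(fmin), log(fmax), length.out = n))
}

#' Realized complex Morlet kernel
#'
#' Complex exponential times a Gaussian envelope, truncated to a total
#' support of `n_cycles` periods, zero-meaned against the envelope, and
#' scaled to unit total absolute weight.
#'
#' @param f center frequency (Hz), `f < fs / 2`.
#' @param fs sampling rate (Hz).
#' @param n_cycles total support in periods (default 2).
#' @return Complex vector of odd length `2 * floor(n_cycles * fs / (2 f)) + 1`.
#' @export
morlet_kernel <- function(f, fs, n_cycles = 2) {
  if (f >= fs / 2) stop("center frequency must be below Nyquist")
  half_n <- floor(n_cycles * fs / (2 * f))
  if (half_n < 1L) stop("kernel support below one sample")
  t <- (-half_n:half_n) / fs
  sig <- MORLET_SIGMA_RATIO / f
  g <- exp(-t^2 / (2 * sig^2))
  k <- exp(2i * pi * f * t) * g
  k <- k - g * sum(k) / sum(g)     # zero-mean so DC does not leak into phase
  k / sum(Mod(k))
}

#' Half-power bandwidth of the realized kernel
#'
#' Power response of the discrete kernel computed by zero-padded FFT on a
#' fine frequency grid; returns the lower and upper frequencies where the
#' power first falls to half its maximum (linear interpolation between grid
#' points).
#'
#' @inheritParams morlet_kernel
#' @param nfft FFT length controlling grid resolution (default `2^18`).
#' @return Numeric length-2 vector `c(lower, upper)` in Hz.
#' @export
#' @examples
#' half_power_bandwidth(4.5, 1000)   # ~ (2.77, 6.84) Hz
half_power_bandwidth <- function(f, fs, n_cycles = 2, nfft = 2^18) {
  k <- morlet_kernel(f, fs, n_cycles)
  if (length(k) > nfft) stop("nfft shorter than kernel")
  P <- Mod(fft(c(k, rep(0, nfft - length(k)))))^2
  fr <- (seq_len(nfft) - 1) * fs / nfft
  keep <- fr <= fs / 2
  P <- P[keep]; fr <- fr[keep]
  im <- which.max(P)
  half <- P[im] / 2
  below_lo <- which(P[1:im] <= half)
  above_hi <- which(P[im:length(P)] <= half)
  if (length(below_lo) == 0 || length(above_hi) == 0)
    stop("power response never drops to half within (0, Nyquist)")
  lo <- max(below_lo)
  flo <- fr[lo] + (half - P[lo]) / (P[lo + 1] - P[lo]) * (fr[lo + 1] - fr[lo])
  hi <- im - 1L + min(above_hi)
  fhi <- fr[hi - 1] + (half - P[hi - 1]) / (P[hi] - P[hi - 1]) *
    (fr[hi] - fr[hi - 1])
  c(flo, fhi)
}

#' Construct a phase-matrix container
#'
#' @param values complex matrix, contacts x samples.
#' @param f center temporal frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param variant one of `"phase_only"`, `"amplitude"`,
#'   `"normalized_amplitude"`.
#' @param mask optional logical vector over samples; `FALSE` marks samples
#'   within half a kernel of a recording edge.
#' @return Object of class `phase_matrix`.
#' @export
phase_matrix <- function(values, f, fs, variant = "phase_only", mask = NULL) {
  variant <- match.arg(variant,
                       c("phase_only", "amplitude", "normalized_amplitude"))
  values <- as.matrix(values)
  if (!is.complex(values)) values <- values + 0i
  if (is.null(mask)) mask <- rep(TRUE, ncol(values))
  stopifnot(length(mask) == ncol(values))
  structure(list(values = values, f = f, fs = fs, variant = variant,
                 mask = mask),
            class = "phase_matrix")
}

#' @export
print.phase_matrix <- function(x, ...) {
  cat(sprintf("<phase_matrix> %d contacts x %d samples @ f = %.3g Hz (fs = %g), variant = %s, %d edge samples masked\n",
              nrow(x$values), ncol(x$values), x$f, x$fs, x$variant,
              sum(!x$mask)))
  invisible(x)
}

#' Extract complex phase with a two-cycle Morlet wavelet
#'
#' Convolves each contact's signal with the realized Morlet kernel
#' (reflect-padding by one kernel length at each edge) and represents
#' instantaneous phase theta as the unit phasor `exp(-1i * theta)`.  The
#' `"amplitude"` variant keeps the band amplitude as the modulus
#' (`r * exp(-1i * theta)`); `"normalized_amplitude"` rescales each
#' contact's modulus to span [0, 1] over the recording.
#'
#' Samples closer than half a kernel to either edge are flagged in the
#' returned mask.  Where the band amplitude is exactly zero the phase is
#' undefined; those entries are set to 0 and masked per-entry in the
#' `zero_amplitude` attribute.
#'
#' @param signal numeric matrix, contacts x samples, or a vector.
#' @param fs sampling rate (Hz).
#' @param f center frequency (Hz), below Nyquist.
#' @param n_cycles kernel support in periods (default 2).
#' @param variant see [phase_matrix()].
#' @return A [phase_matrix()].
#' @export
morlet_phase <- function(signal, fs, f, n_cycles = 2,
                         variant = c("phase_only", "amplitude",
                                     "normalized_amplitude")) {
  variant <- match.arg(variant)
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1L)
  k <- morlet_kernel(f, fs, n_cycles)
  L <- length(k)
  if (ncol(signal) < L) stop("signal shorter than the wavelet support")
  n_t <- ncol(signal)
  pad <- min(L, n_t - 1L)
  h <- (L - 1L) %/% 2L
  nfft <- n_t + 2L * pad + L - 1L
  # cross-correlation with the centered kernel, y(t) = sum_u conj(k_u) x(t+u),
  # realized as full linear convolution with the reversed conjugate kernel
  B <- fft(c(rev(Conj(k)), rep(0, nfft - L)))
  vals <- matrix(0i, nrow(signal), n_t)
  for (s in seq_len(nrow(signal))) {
    x <- signal[s, ]
    xp <- c(rev(x[2:(pad + 1L)]), x, rev(x[(n_t - pad):(n_t - 1L)]))
    y <- fft(fft(c(xp, rep(0, nfft - length(xp)))) * B, inverse = TRUE) / nfft
    vals[s, ] <- y[pad + h + seq_len(n_t)]
  }
  zero_amp <- Mod(vals) == 0
  theta <- Arg(vals)                    # instantaneous phase
  half_k <- (L - 1L) %/% 2L
  mask <- rep(TRUE, n_t)
  if (half_k > 0) {
    mask[seq_len(min(half_k, n_t))] <- FALSE
    mask[seq.int(max(1L, n_t - half_k + 1L), n_t)] <- FALSE
  }
  out <- switch(variant,
    phase_only = exp(-1i * theta),
    amplitude = Mod(vals) * exp(-1i * theta),
    normalized_amplitude = {
      r <- Mod(vals)
      rng <- apply(r, 1L, range)
      span <- rng[2, ] - rng[1, ]
      span[span == 0] <- 1
      ((r - rng[1, ]) / span) * exp(-1i * theta)
    })
  if (any(zero_amp)) out[zero_amp] <- 0i
  pm <- phase_matrix(out, f = f, fs = fs, variant = variant, mask = mask)
  attr(pm, "zero_amplitude") <- zero_amp
  pm
}

#' Convert spatial frequency to wavelength
#'
#' @param sf spatial frequency in cycles/m.
#' @return Wavelength in meters, `1 / sf`.
#' @export
#' @examples
#' sf_to_wavelength(50)  # 0.02 m, i.e. 2 cm per cycle
sf_to_wavelength <- function(sf) 1 / sf

#' Convert wavelength to spatial frequency
#' @param lambda wavelength in meters.
#' @return Spatial frequency in cycles/m.
#' @export
wavelength_to_sf <- function(lambda) 1 / lambda
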