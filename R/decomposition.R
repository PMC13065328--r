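#' Complex SVD of a phase matrix
#'
#' Decomposes a contacts x samples complex phase matrix into left singular
#' vectors (spatial covariance patterns of phase), singular values, and
#' right singular vectors (their time courses), truncated to `rank`.
#' Each left singular vector column is rotated by a global unit phasor so
#' that its largest-magnitude entry is real-positive, which pins the SVD
#' gauge freedom for reproducible serialization; the matching inverse
#' rotation is applied to the right singular vector, so the reconstruction
#' is unchanged.
#'
#' @param phase a [phase_matrix()] or a complex matrix.
#' @param rank number of components to retain (default 14, the standard
#'   operating point; robustness is conventionally checked over 10-40).
#' @param drop_masked if `TRUE` (default), samples masked as edge-invalid in
#'   a [phase_matrix()] are excluded before decomposition.
#' @return Object of class `phase_svd` with fields `lsv` (contacts x rank),
#'   `d` (singular values, non-increasing), `rsv` (samples x rank), `rank`,
#'   `f`, `variant`, `n_contacts`, `n_samples`.
#' @export
complex_svd <- function(phase, rank = 14L, drop_masked = TRUE) {
  f <- NA_real_; fs <- NA_real_; variant <- NA_character_
  if (inherits(phase, "phase_matrix")) {
    vals <- phase$values
    if (drop_masked) vals <- vals[, phase$mask, drop = FALSE]
    f <- phase$f; fs <- phase$fs; variant <- phase$variant
  } else {
    vals <- as.matrix(phase)
  }
  if (rank > min(dim(vals)))
    stop("rank exceeds matrix dimensions (", nrow(vals), " x ", ncol(vals), ")")
  s <- svd(vals, nu = min(dim(vals)), nv = min(dim(vals)))
  keep <- seq_len(rank)
  u <- s$u[, keep, drop = FALSE]
  v <- s$v[, keep, drop = FALSE]
  # gauge fix: largest-magnitude entry of each LSV real-positive
  for (j in keep) {
    i <- which.max(Mod(u[, j]))
    z <- u[i, j]
    if (Mod(z) > 0) {
      rot <- Conj(z) / Mod(z)
      u[, j] <- u[, j] * rot
      v[, j] <- v[, j] * rot   # same rotation: u v^H is unchanged
    }
  }
  structure(list(lsv = u, d = s$d[keep], rsv = v, rank = as.integer(rank),
                 f = f, fs = fs, variant = variant,
                 n_contacts = nrow(vals), n_samples = ncol(vals)),
            class = "phase_svd")
}

#' @export
print.phase_svd <- function(x, ...) {
  cat(sprintf("<phase_svd> rank %d of %d x %d phase matrix; leading singular values: %s\n",
              x$rank, x$n_contacts, x$n_samples,
              paste(signif(head(x$d, 4), 4), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a phase matrix from its decomposition
#'
#' Weighted sum of rank-one outer products `sum_i w_i u_i v_i*`.  With the
#' original singular values as weights this inverts [complex_svd()] at full
#' rank; alternative weights implement surrogate constructions such as
#' singular-weight reversal.
#'
#' @param svd a `phase_svd`.
#' @param weights optional override of the singular values; length must
#'   equal the retained rank.
#' @return Complex matrix, contacts x samples.
#' @export
reconstruct <- function(svd, weights = NULL) {
  stopifnot(inherits(svd, "phase_svd"))
  if (is.null(weights)) weights <- svd$d
  if (length(weights) != svd$rank)
    stop("weights length (", length(weights), ") must equal rank (", svd$rank, ")")
  svd$lsv %*% (weights * Conj(t(svd$rsv)))
}

#' Remove the standing (zero spatial frequency) part of a spatial component
#'
#' A left singular vector of phase mixes traveling and standing (globally
#' synchronous) wave content.  The vector is extended over one full
#' temporal cycle by the outer product with a unit-phase vector of
#' `n = round(fs / f)` samples, the real part of the extended matrix is
#' decomposed by SVD, and the first two left singular vectors are
#' recombined as the real and imaginary parts of a unit-modulus phasor.
#' The result is the pure traveling part; downstream, this suppresses the
#' DC bin of the spatial-frequency spectrum.
#'
#' Each of the two singular vectors is defined only up to sign, which
#' leaves two possible propagation orientations; the orientation whose
#' output best matches the input's phase pattern (maximal
#' `|sum_s out_s * conj(in_s / |in_s|)|`) is returned, recorded in the
#' `orientation` attribute.
#'
#' @param lsv_column complex vector (one left singular vector over contacts).
#' @param fs sampling rate (Hz).
#' @param f center temporal frequency (Hz), `f <= fs`.
#' @return Unit-modulus complex vector of the same length.  If the input is
#'   spatially constant (pure standing wave) the attribute `pure_standing`
#'   is `TRUE` and the output is the input's unit normalization.
#' @export
remove_standing_component <- function(lsv_column, fs, f) {
  if (f > fs) stop("center frequency above sampling rate")
  z <- as.complex(lsv_column)
  if (length(z) < 3L) stop("need at least 3 contacts")
  ang <- Arg(z)
  if (max(abs(Arg(exp(1i * (ang - ang[1]))))) < 1e-12 || all(Mod(z) == 0)) {
    out <- exp(1i * Arg(ifelse(Mod(z) > 0, z, 1)))
    attr(out, "pure_standing") <- TRUE
    return(out)
  }
  n <- round(fs / f)
  phi_c <- exp(-1i * 2 * pi * (0:(n - 1)) / n)   # one full cycle of unit phase
  ext <- Re(outer(z, phi_c))                     # contacts x n, real part
  s <- svd(ext, nu = 2L, nv = 0L)
  u1 <- s$u[, 1]; u2 <- s$u[, 2]
  unit_in <- z / ifelse(Mod(z) > 0, Mod(z), 1)
  cand <- list(u1 + 1i * u2, u1 - 1i * u2)
  score <- vapply(cand, function(w) {
    wn <- w / ifelse(Mod(w) > 0, Mod(w), 1)
    Mod(sum(wn * Conj(unit_in)))
  }, numeric(1))
  pick <- which.max(score)
  w <- cand[[pick]]
  out <- w / ifelse(Mod(w) > 0, Mod(w), 1)
  attr(out, "pure_standing") <- FALSE
  attr(out, "orientation") <- pick
  out
}
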