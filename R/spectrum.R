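#' Phase gradient over one embedded triangle
#'
#' Exact three-point plane fit of phase over the planar embedding of a
#' triangle, using circular phase differences
#' `delta = Arg(exp(1i * (omega_2 - omega_1)))` so that wrapped values
#' difference correctly.
#'
#' @param bx,cx,cy planar coordinates of B and C (A at the origin; see
#'   [planar_embed()]).
#' @param omega phase angles (radians) at A, B, C, length 3 (or a 3-column
#'   matrix for many triangles).
#' @return Numeric 2-vector `c(d_omega/dx, d_omega/dy)` in rad/m (or a
#'   2-column matrix).
#' @export
triangle_phase_gradient <- function(bx, cx, cy, omega) {
  if (is.matrix(omega)) {
    dab <- Arg(exp(1i * (omega[, 2] - omega[, 1])))
    dac <- Arg(exp(1i * (omega[, 3] - omega[, 1])))
  } else {
    dab <- Arg(exp(1i * (omega[2] - omega[1])))
    dac <- Arg(exp(1i * (omega[3] - omega[1])))
  }
  if (any(bx <= 0) || any(cy <= 0)) stop("degenerate planar coordinates")
  gx <- dab / bx
  gy <- (dac - cx * gx) / cy
  if (is.matrix(omega)) cbind(gx, gy) else c(gx, gy)
}

#' Spatial frequency of a phase gradient
#'
#' @param gradient 2-vector (or 2-column matrix) in rad/m.
#' @return Spatial frequency in cycles/m: Euclidean norm over `2 * pi`.
#' @export
triangle_sf <- function(gradient) {
  if (is.matrix(gradient))
    sqrt(gradient[, 1]^2 + gradient[, 2]^2) / (2 * pi)
  else sqrt(sum(gradient^2)) / (2 * pi)
}

#' Weight of one triangle's contribution to the spectrum
#'
#' @param sigma singular value of the spatial component.
#' @param a magnitudes of the component at the three vertices (length 3 or
#'   3-column matrix).
#' @param n_t triangle-bin normalization weight.
#' @return `sigma * mean(a) * n_t`.
#' @export
triangle_weight <- function(sigma, a, n_t) {
  if (is.matrix(a)) sigma * rowMeans(a) * n_t else sigma * mean(a) * n_t
}

#' Build the binned spatial-frequency spectrum
#'
#' For every retained spatial component and every triangle, estimates the
#' local spatial frequency from the component's phases at the triangle's
#' vertices and accumulates the triangle's weight (singular value x mean
#' vertex magnitude x size-bin normalization) into `K` equal-width bins
#' over `sf_range`.  Weights whose spatial frequency falls outside
#' `sf_range` are excluded and reported.
#'
#' @param svd a `phase_svd` from [complex_svd()].
#' @param triangles a binned `triangle_set` (see [bin_triangles()]).
#' @param K number of spectrum bins (default 32).
#' @param sf_range bin range in cycles/m; default depends on `purpose`:
#'   from the spatial frequency of twice the maximum triangle size
#'   (`"plot"`) or of the maximum triangle size (`"regression"`) up to 50.
#' @param purpose `"regression"` (default) or `"plot"`; sets the default
#'   lower bound of `sf_range`.
#' @param dc_removal if `TRUE` (default), each component's standing
#'   (globally synchronous) part is removed with
#'   [remove_standing_component()] before differencing; components flagged
#'   as purely standing contribute nothing.
#' @param fs,f sampling rate and center frequency for the standing-wave
#'   extension; default to the values stored in `svd`.
#' @return Object of class `sf_spectrum`: `bin_edges` (length `K + 1`),
#'   `power` (length `K`), `f`, `rank`, `variant`, `sf_range`,
#'   `dc_removal`, `total_weight`, `excluded_weight`,
#'   `n_standing_components`.
#' @export
build_spectrum <- function(svd, triangles, K = 32L, sf_range = NULL,
                           purpose = c("regression", "plot"),
                           dc_removal = TRUE, fs = NULL, f = NULL) {
  stopifnot(inherits(svd, "phase_svd"), inherits(triangles, "triangle_set"))
  purpose <- match.arg(purpose)
  tr <- triangles$triangles
  if (nrow(tr) == 0) stop("empty triangle set")
  if (is.null(tr$n_t)) stop("triangle set is not binned; call bin_triangles() first")
  if (max(tr$a, tr$b, tr$c) > nrow(svd$lsv))
    stop("triangle contact indices exceed the decomposition's contacts")
  if (is.null(f)) f <- svd$f
  if (is.null(fs)) fs <- svd$fs
  if (dc_removal && (is.null(fs) || is.na(fs) || is.null(f) || is.na(f)))
    stop("dc_removal needs fs and f (absent from this decomposition); pass them explicitly")
  max_size <- max(1 / tr$xi)
  if (is.null(sf_range)) {
    lo <- if (purpose == "plot") 1 / (2 * max_size) else 1 / max_size
    sf_range <- c(lo, 50)
  }
  edges <- seq(sf_range[1], sf_range[2], length.out = K + 1L)
  w <- diff(edges)[1]
  power <- numeric(K)
  excluded <- 0; total <- 0; n_standing <- 0L
  for (r in seq_len(svd$rank)) {
    zeta <- svd$lsv[, r]
    mags <- Mod(zeta)
    if (dc_removal) {
      ph <- remove_standing_component(zeta, fs = fs, f = f)
      if (isTRUE(attr(ph, "pure_standing"))) {
        n_standing <- n_standing + 1L
        next
      }
      omega <- Arg(ph)
    } else {
      omega <- Arg(zeta)
    }
    om <- cbind(omega[tr$a], omega[tr$b], omega[tr$c])
    g <- triangle_phase_gradient(tr$bx, tr$cx, tr$cy, om)
    xi <- triangle_sf(g)
    a3 <- cbind(mags[tr$a], mags[tr$b], mags[tr$c])
    W <- triangle_weight(svd$d[r], a3, tr$n_t)
    # half-open bins [kw, (k+1)w), last bin closed
    bin <- floor((xi - edges[1]) / w) + 1L
    bin[xi == edges[K + 1L]] <- K
    inr <- bin >= 1L & bin <= K
    excluded <- excluded + sum(W[!inr])
    total <- total + sum(W[inr])
    power <- power + as.numeric(
      tapply(W[inr], factor(bin[inr], levels = seq_len(K)), sum,
             default = 0))
  }
  structure(list(bin_edges = edges, power = power, f = f, rank = svd$rank,
                 variant = svd$variant, sf_range = sf_range,
                 dc_removal = dc_removal, total_weight = total,
                 excluded_weight = excluded,
                 n_standing_components = n_standing,
                 max_triangle_size = max_size),
            class = "sf_spectrum")
}

#' @export
print.sf_spectrum <- function(x, ...) {
  pk <- which.max(x$power)
  ctr <- (x$bin_edges[pk] + x$bin_edges[pk + 1]) / 2
  cat(sprintf("<sf_spectrum> %d bins over [%.3g, %.3g] cycles/m @ f = %.3g Hz (rank %d, dc_removal %s); peak %.3g at %.3g cycles/m\n",
              length(x$power), x$sf_range[1], x$sf_range[2], x$f, x$rank,
              x$dc_removal, max(x$power), ctr))
  invisible(x)
}

#' Bin centers of a spectrum
#' @param spectrum an `sf_spectrum`.
#' @return Numeric vector of bin-center spatial frequencies (cycles/m).
#' @export
spectrum_bin_centers <- function(spectrum) {
  e <- spectrum$bin_edges
  (e[-length(e)] + e[-1]) / 2
}

#' Spatial frequency at the spectrum's power peak
#'
#' @param spectrum an `sf_spectrum`.
#' @param interpolate if `TRUE`, refine the peak to sub-bin resolution by
#'   a parabolic fit through the maximum bin and its two neighbors (the
#'   standard spectral peak interpolation); falls back to the bin center
#'   at the spectrum edges.
#' @return Bin-center (or interpolated) spatial frequency of the
#'   maximum-power bin; ties go to the lowest spatial frequency (flagged
#'   in the `tie` attribute).
#' @export
spectrum_peak_sf <- function(spectrum, interpolate = FALSE) {
  p <- spectrum$power
  i <- which(p == max(p))
  ctr <- spectrum_bin_centers(spectrum)
  out <- ctr[i[1]]
  if (interpolate && i[1] > 1L && i[1] < length(p)) {
    a <- p[i[1] - 1L]; b <- p[i[1]]; c <- p[i[1] + 1L]
    den <- a - 2 * b + c
    if (den < 0) {
      off <- 0.5 * (a - c) / den
      out <- out + off * diff(spectrum$bin_edges)[1]
    }
  }
  attr(out, "tie") <- length(i) > 1L
  out
}
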