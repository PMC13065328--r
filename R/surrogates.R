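# best-fit sphere of one hemisphere's vertices: centroid + mean radius
.fit_sphere <- function(vertices) {
  ctr <- colMeans(vertices)
  r <- mean(sqrt(rowSums(sweep(vertices, 2L, ctr)^2)))
  list(center = ctr, radius = r)
}

.axis_vector <- function(direction) {
  switch(direction,
         "anterior-posterior" = , "ap" = c(0, 1, 0),
         "left-right" = , "lr" = c(1, 0, 0),
         stop("direction must be 'anterior-posterior' or 'left-right'"))
}

#' Spherical phase-gradient surrogate basis
#'
#' Constructs a ground-truth phase gradient over the contacts: the mesh of
#' each hemisphere is inflated to its best-fit sphere by radial projection,
#' each projected contact gets an arc-length coordinate `s` (meters) along
#' the chosen axis's great-circle (meridian) coordinate, and the basis is
#' the unit phasor `exp(-1i * 2 * pi * sf * s)`.
#'
#' @param mesh a [cortical_mesh()].
#' @param projection result of [project_to_surface()] for the contacts.
#' @param direction `"anterior-posterior"` (or `"ap"`) or `"left-right"`
#'   (`"lr"`).
#' @param sf spatial frequency of the planted gradient, cycles/m (> 0).
#' @return Complex unit-modulus vector over contacts, with the arc-length
#'   coordinates in the `arc_length` attribute.  Warns when the gradient is
#'   aliased on the array (closest contact pair differs by >= pi).
#' @export
spherical_gradient_basis <- function(mesh, projection,
                                     direction = "anterior-posterior", sf) {
  if (sf <= 0) stop("sf must be positive")
  axis <- .axis_vector(direction)
  pts <- projection$points
  hemi <- as.character(projection$contacts$hemisphere)
  s <- numeric(nrow(pts))
  for (h in unique(hemi)) {
    vsel <- mesh$hemisphere == h
    sph <- .fit_sphere(mesh$vertices[vsel, , drop = FALSE])
    idx <- which(hemi == h)
    u <- sweep(pts[idx, , drop = FALSE], 2L, sph$center)
    u <- u / sqrt(rowSums(u^2))
    s[idx] <- sph$radius * acos(pmin(1, pmax(-1, u %*% axis)))
  }
  # aliasing check on the closest contact pair
  if (nrow(pts) > 1L) {
    d3 <- as.matrix(stats::dist(pts))
    diag(d3) <- Inf
    if (2 * pi * sf * min(d3) >= pi)
      warning("surrogate gradient aliased: nearest contacts differ by >= pi")
  }
  out <- exp(-1i * 2 * pi * sf * s)
  attr(out, "arc_length") <- s
  out
}

#' Rank-one surrogate phase time series
#'
#' Combines a surrogate spatial basis with an empirical right singular
#' vector whose time order is reversed and which is conjugated (restoring
#' the direction of phase change over time), at unit scaling.
#'
#' @param basis complex vector over contacts (e.g. from
#'   [spherical_gradient_basis()]).
#' @param rsv complex vector over samples (an empirical right singular
#'   vector).
#' @return Complex matrix, contacts x samples, rank one, unit modulus
#'   (phase is a unit-length complex number, so the reconstruction is
#'   renormalized entrywise; samples where the right singular vector
#'   vanishes keep modulus zero).
#' @export
surrogate_timeseries <- function(basis, rsv) {
  v_sur <- Conj(rev(as.complex(rsv)))
  z <- outer(as.complex(basis), Conj(v_sur))
  m <- Mod(z)
  z / ifelse(m > 0, m, 1)
}

#' Inject a surrogate phase signal into a phase matrix
#'
#' Vector addition of unit phasors: the output phase is the angle of
#' `phase + w_sur * surrogate`, re-normalized to unit modulus.
#'
#' @param phase a [phase_matrix()] (phase-only variant) or complex matrix.
#' @param surrogate complex matrix of the same shape.
#' @param w_sur non-negative surrogate weight (0 returns the input phases).
#' @return A [phase_matrix()] (or complex matrix, matching the input).
#' @export
inject_surrogate <- function(phase, surrogate, w_sur) {
  if (w_sur < 0) stop("w_sur must be non-negative")
  is_pm <- inherits(phase, "phase_matrix")
  vals <- if (is_pm) phase$values else as.matrix(phase)
  if (!all(dim(vals) == dim(surrogate))) stop("shape mismatch")
  z <- vals + w_sur * surrogate
  m <- Mod(z)
  out <- z / ifelse(m > 0, m, 1)
  if (is_pm) phase_matrix(out, phase$f, phase$fs, "phase_only", phase$mask)
  else out
}

#' Reverse the weighting of the leading singular values
#'
#' Reconstructs the phase matrix with the first `n` singular values in
#' reversed order (weights of the dominant low-spatial-frequency patterns
#' swapped with the weakest retained ones), re-normalized to unit modulus
#' per entry.  On a spectrum falling off as a power of spatial frequency
#' this flips the sign of the wavelength-power slope.
#'
#' @param svd a `phase_svd` with `rank >= n`.
#' @param n how many leading singular values to reverse (default 28).
#' @return A [phase_matrix()] (phase-only).
#' @export
reverse_singular_weights <- function(svd, n = 28L) {
  stopifnot(inherits(svd, "phase_svd"))
  if (svd$rank < n) stop("rank (", svd$rank, ") below n (", n, ")")
  wts <- svd$d
  wts[seq_len(n)] <- rev(wts[seq_len(n)])
  z <- reconstruct(svd, wts)
  m <- Mod(z)
  phase_matrix(z / ifelse(m > 0, m, 1), f = svd$f, fs = svd$fs,
               variant = "phase_only")
}

#' Randomly remove contacts, keeping a fraction
#'
#' Seeded uniform sampling without replacement; the number kept is
#' `ceiling(keep_fraction * n)` (151 contacts at 1/3 keep 51).
#'
#' @param phase a [phase_matrix()] or complex/numeric matrix
#'   (contacts x samples).
#' @param contacts contact table (data frame) aligned with the rows.
#' @param keep_fraction fraction of contacts to retain (default 1/3).
#' @param seed integer seed for reproducible subsets.
#' @return List with `phase`, `contacts`, and the retained row `indices`
#'   (sorted).  Errors if fewer than 3 contacts survive in any represented
#'   hemisphere.
#' @export
sparsify_contacts <- function(phase, contacts, keep_fraction = 1 / 3,
                              seed = NULL) {
  is_pm <- inherits(phase, "phase_matrix")
  vals <- if (is_pm) phase$values else as.matrix(phase)
  n <- nrow(vals)
  stopifnot(nrow(contacts) == n)
  keep_n <- ceiling(keep_fraction * n)
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(n, keep_n))
  kept_h <- table(contacts$hemisphere[idx])
  if (any(kept_h < 3L))
    stop("fewer than 3 surviving contacts in a hemisphere")
  vals <- vals[idx, , drop = FALSE]
  out_phase <- if (is_pm)
    phase_matrix(vals, phase$f, phase$fs, phase$variant, phase$mask)
  else vals
  list(phase = out_phase, contacts = contacts[idx, , drop = FALSE],
       indices = idx)
}

#' Load an average reference onto the data
#'
#' Subtracts `weight` times the across-contact mean (per sample) from every
#' contact, emulating increasing levels of artefactual global synchrony
#' introduced by average referencing.
#'
#' @param x a [raw_recording()] or numeric/complex matrix
#'   (contacts x samples).
#' @param weight non-negative multiple of the standard average reference
#'   (0 is the identity; the conventional stress test goes up to 8).
#' @return Same type as the input with the loaded reference applied.
#' @export
load_average_reference <- function(x, weight) {
  if (weight < 0) stop("weight must be non-negative")
  if (inherits(x, "raw_recording")) {
    x$signal <- x$signal - weight * matrix(colMeans(x$signal),
                                           nrow(x$signal), ncol(x$signal),
                                           byrow = TRUE)
    x
  } else {
    m <- as.matrix(x)
    m - weight * matrix(colMeans(m), nrow(m), ncol(m), byrow = TRUE)
  }
}

#' Convert a surrogate mixture ratio to the additive injection weight
#'
#' Surrogate strengths are conventionally quoted as the surrogate's
#' fraction of the combined signal (a 2/3 ratio means the surrogate is
#' twice the strength of the empirical signal; 7/8 means seven times).
#' [inject_surrogate()] adds the surrogate to the unit-strength empirical
#' phase, so the additive weight is `ratio / (1 - ratio)`.
#'
#' @param ratio surrogate fraction of the mixture, in `[0, 1)`.
#' @return The additive weight `w_sur` for [inject_surrogate()].
#' @export
#' @examples
#' ratio_to_weight(1/3)  # 0.5: surrogate at half the signal strength
#' ratio_to_weight(7/8)  # 7: surrogate dominates seven to one
ratio_to_weight <- function(ratio) {
  if (any(ratio < 0 | ratio >= 1)) stop("ratio must be in [0, 1)")
  ratio / (1 - ratio)
}
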