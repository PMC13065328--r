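# unit icosahedron vertices/faces
.icosahedron <- function() {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c(1,  t,  0), c(-1, -t,  0), c(1, -t,  0),
    c(0, -1,  t), c(0,  1,  t), c(0, -1, -t), c(0,  1, -t),
    c(t,  0, -1), c(t,  0,  1), c(-t, 0, -1), c(-t, 0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

# midpoint subdivision on the unit sphere
.subdivide_sphere <- function(v, f) {
  key_env <- new.env(hash = TRUE)
  verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
  midpoint <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    id <- key_env[[key]]
    if (!is.null(id)) return(id)
    p <- verts[[i]] + verts[[j]]
    p <- p / sqrt(sum(p^2))
    verts[[length(verts) + 1L]] <<- p
    id <- length(verts)
    key_env[[key]] <- id
    id
  }
  nf <- matrix(NA_integer_, nrow(f) * 4L, 3L)
  for (k in seq_len(nrow(f))) {
    a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
  }
  list(vertices = do.call(rbind, verts), faces = nf)
}

# smooth low-order radial perturbation field on the unit sphere, in [-1, 1]
.smooth_radial_field <- function(unit_pts, n_terms = 4L) {
  g <- numeric(nrow(unit_pts))
  for (j in seq_len(n_terms)) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    p <- sample(1:3, 1L)
    g <- g + rnorm(1) * (unit_pts %*% u)^p
  }
  mx <- max(abs(g))
  if (mx > 0) g <- g / mx
  as.numeric(g)
}

#' Synthetic two-hemisphere distorted-spheroid mesh
#'
#' Builds two closed icosphere shells (one per hemisphere, offset along the
#' left-right axis) with an optional smooth low-order radial distortion,
#' emulating the folded-spheroid geometry of the cortical sheet at the
#' scale the method resolves.
#'
#' @param radius shell radius in meters (default 0.09, a realistic hemispheric scale: geodesic extents up to ~28 cm).
#' @param distortion relative amplitude of the smooth radial perturbation
#'   (default 0; e.g. 0.05 for a mildly distorted spheroid).
#' @param subdivisions icosphere subdivision depth (default 3: 642 vertices
#'   per shell).
#' @param gap separation between the two shells in meters (default 0.004).
#' @param seed integer seed for the distortion field.
#' @return A [cortical_mesh()] with per-vertex hemisphere labels.
#' @export
make_spheroid_mesh <- function(radius = 0.09, distortion = 0,
                               subdivisions = 3L, gap = 0.004,
                               seed = NULL) {
  if (radius <= 0) stop("radius must be positive")
  if (!is.null(seed)) set.seed(seed)
  ico <- .icosahedron()
  for (i in seq_len(subdivisions)) ico <- .subdivide_sphere(ico$vertices, ico$faces)
  n <- nrow(ico$vertices)
  shells <- list()
  offs <- c(left = -(radius + gap / 2), right = radius + gap / 2)
  verts <- NULL; faces <- NULL; hemi <- character(0)
  for (h in names(offs)) {
    r <- radius
    if (distortion > 0) {
      g <- .smooth_radial_field(ico$vertices)
      r <- radius * (1 + distortion * g)
    }
    v <- ico$vertices * r
    v[, 1] <- v[, 1] + offs[[h]]
    faces <- rbind(faces, ico$faces + length(hemi))
    verts <- rbind(verts, v)
    hemi <- c(hemi, rep(h, n))
  }
  cortical_mesh(verts, faces, hemi)
}

#' Synthetic depth-electrode contact table
#'
#' Plants straight-line electrode runs with fixed inter-contact spacing.
#' Entry points are drawn inside a lateral cap of each hemisphere's shell
#' (emulating the clustered lateral insertion of clinical depth
#' electrodes), directions point toward a jittered interior target, and
#' contacts are labeled gray when within a cortical-thickness band of the
#' surface, else white.
#'
#' @param mesh a [cortical_mesh()] from [make_spheroid_mesh()].
#' @param n_electrodes number of electrodes (split over hemispheres).
#' @param contacts_per_electrode contacts per electrode run.
#' @param spacing inter-contact spacing in meters (default 0.005).
#' @param thickness gray-matter band: contacts within this distance of the
#'   surface are labeled gray (default 0.003).
#' @param cap_half_angle half-angle (radians) of the lateral entry cap
#'   (default `pi / 3`).
#' @param seed integer seed.
#' @return Data frame with columns `id`, `x`, `y`, `z`, `label`,
#'   `hemisphere`, `electrode`.
#' @export
make_depth_electrodes <- function(mesh, n_electrodes = 8L,
                                  contacts_per_electrode = 12L,
                                  spacing = 0.005, thickness = 0.003,
                                  cap_half_angle = pi / 3, seed = NULL) {
  stopifnot(n_electrodes >= 1L, contacts_per_electrode >= 1L)
  if (!is.null(seed)) set.seed(seed)
  hemis <- rep(c("left", "right"), length.out = n_electrodes)
  rows <- list()
  for (e in seq_len(n_electrodes)) {
    h <- hemis[e]
    vsel <- mesh$hemisphere == h
    sph <- .fit_sphere(mesh$vertices[vsel, , drop = FALSE])
    lateral <- if (h == "left") c(-1, 0, 0) else c(1, 0, 0)
    # direction within the lateral cap
    repeat {
      d <- rnorm(3); d <- d / sqrt(sum(d^2))
      if (acos(sum(d * lateral)) <= cap_half_angle) break
    }
    # entry: projection of an exterior point along d onto the shell
    probe <- data.frame(x = sph$center[1] + 1.5 * sph$radius * d[1],
                        y = sph$center[2] + 1.5 * sph$radius * d[2],
                        z = sph$center[3] + 1.5 * sph$radius * d[3],
                        hemisphere = h)
    pr <- suppressWarnings(project_to_surface(probe, mesh, max_dist = Inf))
    entry <- pr$points[1, ]
    # aim at a second surface point in the cap so the run grazes the sheet
    # (depth contacts in clinical arrays traverse the folded gray matter;
    # on a smooth shell a grazing chord reproduces the gray/white mix)
    run_len <- (contacts_per_electrode - 1L) * spacing
    w <- NULL
    for (try in 1:50) {
      repeat {
        d2 <- rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
        if (acos(sum(d2 * lateral)) <= cap_half_angle) break
      }
      probe2 <- data.frame(x = sph$center[1] + 1.5 * sph$radius * d2[1],
                           y = sph$center[2] + 1.5 * sph$radius * d2[2],
                           z = sph$center[3] + 1.5 * sph$radius * d2[3],
                           hemisphere = h)
      q <- suppressWarnings(project_to_surface(probe2, mesh,
                                               max_dist = Inf))$points[1, ]
      chord <- sqrt(sum((q - entry)^2))
      if (chord >= 0.9 * run_len && chord <= 1.4 * run_len) {
        w <- q - entry
        break
      }
    }
    if (is.null(w)) w <- q - entry
    w <- w / sqrt(sum(w^2))
    pos <- t(vapply(seq_len(contacts_per_electrode) - 1L,
                    function(j) entry + j * spacing * w, numeric(3)))
    rows[[e]] <- data.frame(
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      hemisphere = h, electrode = e)
  }
  tab <- do.call(rbind, rows)
  tab$id <- sprintf("E%02dC%02d", tab$electrode,
                    stats::ave(tab$electrode, tab$electrode,
                               FUN = seq_along))
  # gray/white by distance-to-surface band
  pr <- suppressWarnings(project_to_surface(tab, mesh, max_dist = Inf))
  tab$label <- ifelse(pr$dist <= thickness, "gray", "white")
  tab[, c("id", "x", "y", "z", "label", "hemisphere", "electrode")]
}

#' Synthetic wave recording with known spatio-temporal content
#'
#' Generates a multi-contact recording as a sum of traveling-wave
#' components, each a plane wave in surface arc-length coordinates:
#' `x_s(t) = sum_j A_j cos(2 pi f_j t - 2 pi xi_j s_j(contact) + phi0_j)`
#' plus Gaussian noise.  The arc-length coordinate `s_j` of a contact is
#' its geodesic distance (on the mesh) from the pole of the component's
#' propagation axis, so the planted spatial frequency is expressed in the
#' same surface metric the estimator uses.  White-matter contacts carry
#' the wave attenuated by `white_gain` (they sit outside the active
#' sheet).
#'
#' @param mesh a [cortical_mesh()].
#' @param contacts contact table from [make_depth_electrodes()].
#' @param components data frame (or list coercible to one) with columns
#'   `tf` (Hz), `sf` (cycles/m), `direction` (`"ap"` or `"lr"`),
#'   `amplitude`, and optionally `phi0` (radians, default 0).
#' @param noise_sd Gaussian noise SD in signal units (default 0.1).
#' @param fs sampling rate (Hz, default 500).
#' @param duration recording length in seconds (default 6).
#' @param white_gain amplitude factor for white-matter contacts
#'   (default 0.1).
#' @param seed integer seed.
#' @param projection optional precomputed [project_to_surface()] result.
#' @return List with `recording` (a [raw_recording()]) and `sidecar`:
#'   per-component arc-length coordinates `s` (contacts x components),
#'   the `components` table, `fs`, and per-contact spatial phase offsets
#'   `spatial_phase = 2 pi sf s` so expected instantaneous phases
#'   `theta_s(t) = 2 pi tf t - spatial_phase + phi0` can be reconstructed
#'   exactly.  Warns (recorded in `sidecar$aliased`) when a component's
#'   spatial frequency is aliased at the array's closest contact spacing.
#' @export
make_wave_recording <- function(mesh, contacts, components,
                                noise_sd = 0.1, fs = 500, duration = 6,
                                white_gain = 0.1, seed = NULL,
                                projection = NULL) {
  components <- as.data.frame(components)
  if (is.null(components$phi0)) components$phi0 <- 0
  if (any(components$tf >= fs / 2)) stop("component TF at or above Nyquist")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(projection))
    projection <- suppressWarnings(project_to_surface(contacts, mesh,
                                                      max_dist = Inf))
  n_s <- nrow(contacts)
  n_c <- nrow(components)
  s_mat <- matrix(NA_real_, n_s, n_c)
  for (j in seq_len(n_c)) {
    axis <- .axis_vector(as.character(components$direction[j]))
    for (h in unique(contacts$hemisphere)) {
      vsel <- which(mesh$hemisphere == h)
      pole <- vsel[which.max(mesh$vertices[vsel, , drop = FALSE] %*% axis)]
      d <- geodesic_from_vertex(mesh, pole, projection)
      idx <- contacts$hemisphere == h
      s_mat[idx, j] <- d[idx]
    }
  }
  t <- seq_len(round(fs * duration)) / fs
  gain <- ifelse(contacts$label == "white", white_gain, 1)
  sig <- matrix(0, n_s, length(t))
  spatial_phase <- matrix(NA_real_, n_s, n_c)
  for (j in seq_len(n_c)) {
    sp <- 2 * pi * components$sf[j] * s_mat[, j]
    spatial_phase[, j] <- sp
    theta <- outer(-sp + components$phi0[j], 2 * pi * components$tf[j] * t, `+`)
    sig <- sig + components$amplitude[j] * gain * cos(theta)
  }
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), sd = noise_sd), n_s)
  # aliasing check at the closest contact spacing
  aliased <- rep(FALSE, n_c)
  if (n_s > 1) {
    d3 <- as.matrix(stats::dist(as.matrix(contacts[, c("x", "y", "z")])))
    diag(d3) <- Inf
    aliased <- 2 * pi * components$sf * min(d3) >= pi
    if (any(aliased))
      warning("component(s) ", paste(which(aliased), collapse = ", "),
              " aliased at the closest contact spacing")
  }
  rec <- raw_recording(sig, fs,
                       contact_ids = contacts$id,
                       labels = contacts$label,
                       hemisphere = as.character(contacts$hemisphere))
  list(recording = rec,
       sidecar = list(s = s_mat, spatial_phase = spatial_phase,
                      components = components, fs = fs,
                      aliased = aliased, projection = projection))
}

#' Synthetic phase field with known spatial-frequency content
#'
#' Builds a unit-modulus complex phase matrix directly in phase space as a
#' mixture of spatial-gradient components: each component couples a
#' spherical phase-gradient basis over the contacts (known spatial
#' frequency and direction) to its own unit-modulus time course (the
#' nominal oscillation at `f` plus a slow random phase drift, so that
#' component time courses decorrelate and the SVD can separate the spatial
#' patterns).  With amplitudes proportional to a negative power of spatial
#' frequency this emulates the 1/f^alpha spatial spectrum of cortical
#' phase dynamics; complex Gaussian noise emulates measurement phase
#' noise.
#'
#' @param mesh a [cortical_mesh()].
#' @param projection [project_to_surface()] result for the contacts.
#' @param components data frame with columns `sf` (cycles/m), `direction`
#'   (`"ap"` / `"lr"`), `amplitude`.
#' @param n_samples number of time samples.
#' @param f,fs nominal temporal frequency and sampling rate (Hz).
#' @param noise_sd SD of the additive complex Gaussian noise before
#'   re-normalization (default 0.2).
#' @param drift_sd per-sample SD of each component's random phase drift
#'   (default 0.05 rad).
#' @param tf_spread spacing in Hz between successive components' temporal
#'   frequencies (default 0.4).  Components of different spatial frequency
#'   ride slightly different temporal frequencies (dispersion), which
#'   decorrelates their time courses so the decomposition can separate
#'   them; the offsets stay well inside a two-cycle wavelet's band.
#' @param site_jitter_sd SD (radians) of a per-contact, per-component
#'   random phase offset frozen over time (default 0).  This emulates the
#'   effect of irregular sampling and contact-localization error: the
#'   offsets are part of the spatial pattern, so they survive the SVD and
#'   appear in the left singular vectors as site-level corrections to the
#'   smooth gradients, exactly the structure an irregular array imprints.
#' @param normalize if `TRUE` (default) the mixture is re-normalized to
#'   unit modulus (phase-only variant); `FALSE` keeps the complex
#'   amplitudes (amplitude variant), in which case the planted components
#'   stay exactly rank-one and the decomposition recovers them cleanly.
#' @param seed integer seed.
#' @return A [phase_matrix()] with attributes `components` and `bases`
#'   (the planted spatial bases).
#' @export
make_phase_field <- function(mesh, projection, components, n_samples,
                             f, fs, noise_sd = 0.2, drift_sd = 0.05,
                             tf_spread = 0.4, site_jitter_sd = 0,
                             normalize = TRUE, seed = NULL) {
  components <- as.data.frame(components)
  if (!is.null(seed)) set.seed(seed)
  n_s <- nrow(projection$points)
  tt <- seq_len(n_samples) / fs
  z <- matrix(0i, n_s, n_samples)
  bases <- matrix(0i, n_s, nrow(components))
  for (j in seq_len(nrow(components))) {
    b <- suppressWarnings(spherical_gradient_basis(
      mesh, projection, as.character(components$direction[j]),
      components$sf[j]))
    bases[, j] <- b
    f_j <- f + (j - (nrow(components) + 1) / 2) * tf_spread
    drift <- cumsum(rnorm(n_samples, sd = drift_sd))
    v <- exp(-1i * (2 * pi * f_j * tt + drift + runif(1, -pi, pi)))
    z <- z + components$amplitude[j] * outer(as.complex(b), v)
  }
  if (noise_sd > 0)
    z <- z + matrix(complex(real = rnorm(length(z), sd = noise_sd),
                            imaginary = rnorm(length(z), sd = noise_sd)),
                    n_s, n_samples)
  if (normalize) {
    m <- Mod(z)
    pm <- phase_matrix(z / ifelse(m > 0, m, 1), f = f, fs = fs,
                       variant = "phase_only")
  } else {
    pm <- phase_matrix(z, f = f, fs = fs, variant = "amplitude")
  }
  attr(pm, "components") <- components
  attr(pm, "bases") <- bases
  pm
}
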