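# Shared synthetic fixtures, built lazily once per test run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# sEEG-style study array: distorted two-shell spheroid, 16 clustered depth
# electrodes, ~75 gray contacts, geodesic triangle set.
fix_seeg <- function() memo("seeg", function() {
  mesh <- make_spheroid_mesh(distortion = 0.05, seed = 11)
  el <- make_depth_electrodes(mesh, 16L, 12L, cap_half_angle = pi / 5,
                              seed = 12)
  gray <- el[el$label == "gray", ]
  pr <- suppressWarnings(project_to_surface(gray, mesh, max_dist = Inf))
  D <- geodesic_distances(mesh, pr)
  tri <- bin_triangles(enumerate_triangles(D, as.character(gray$hemisphere)))
  list(mesh = mesh, electrodes = el, gray = gray, projection = pr,
       dist = D, triangles = tri)
})

# broadband 1/f-style base field on the sEEG array (phase-only variant)
fix_seeg_field <- function() memo("seeg_field", function() {
  fx <- fix_seeg()
  sfs <- c(3, 5, 8, 12, 18, 27, 40)
  comps <- data.frame(sf = sfs,
                      direction = rep(c("ap", "lr"), length.out = 7),
                      amplitude = (sfs / 3)^-1)
  make_phase_field(fx$mesh, fx$projection, comps, n_samples = 1500,
                   f = 9.2, fs = 500, seed = 21)
})

# dense irregular one-hemisphere array (MEG/ECoG-like): 240 sensors drawn
# from a fine lattice within a lateral cap; resolves SFs up to ~20 cycles/m
fix_dense <- function() memo("dense", function() {
  mesh <- make_spheroid_mesh(radius = 0.09, distortion = 0,
                             subdivisions = 4L, seed = 1)
  vl <- mesh$vertices[mesh$hemisphere == "left", , drop = FALSE]
  ctr <- colMeans(vl)
  u <- sweep(vl, 2L, ctr)
  u <- u / sqrt(rowSums(u^2))
  ang <- acos(pmax(-1, pmin(1, u %*% c(-1, 0, 0))))
  set.seed(7)
  sel <- sample(which(ang <= 1.2), 240L)
  sens <- data.frame(x = vl[sel, 1], y = vl[sel, 2], z = vl[sel, 3],
                     hemisphere = "left")
  pr <- suppressWarnings(project_to_surface(sens, mesh, max_dist = Inf))
  D <- geodesic_distances(mesh, pr)
  tri <- bin_triangles(enumerate_triangles(D, sens$hemisphere))
  rng <- c(1 / max(1 / tri$triangles$xi), 20)
  list(mesh = mesh, sensors = sens, projection = pr, dist = D,
       triangles = tri, sf_range = rng)
})

# separable five-component 1/f^1.5 field on the dense array (amplitude
# variant: planted components stay exactly rank one)
fix_dense_field <- function() memo("dense_field", function() {
  fx <- fix_dense()
  sf5 <- c(4, 8, 12, 16, 20)
  comps <- data.frame(sf = sf5, direction = c("ap", "lr", "ap", "lr", "ap"),
                      amplitude = (sf5 / 4)^-1.5)
  make_phase_field(fx$mesh, fx$projection, comps, n_samples = 1200,
                   f = 9.2, fs = 500, noise_sd = 0.02, drift_sd = 0.08,
                   normalize = FALSE, seed = 21)
})

# small homogeneous multi-trial recording for preprocessing tests
make_trial_recording <- function(n_trials = 10L, n_sensors = 4L,
                                 len = 100L, fs = 500, seed = 1L,
                                 labels = NULL) {
  set.seed(seed)
  sig <- matrix(rnorm(n_sensors * n_trials * len), n_sensors)
  bounds <- lapply(seq_len(n_trials), function(i)
    c((i - 1L) * len + 1L, i * len + 1L))
  raw_recording(sig, fs, bounds, labels = labels)
}

# circular correlation of two phase-angle vectors
circ_cor <- function(a, b) {
  Mod(sum(exp(1i * (a - b)))) / length(a)
}
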