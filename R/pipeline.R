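#' Default pipeline configuration
#'
#' @return Named list of every tunable pipeline parameter with its default:
#'   wavelet cycles, analysis frequencies, SVD rank, DC removal, triangle
#'   angle threshold, size bins, spectrum bins and range, permutation
#'   count, and seeds.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    fmin = 1.0, fmax = 97.0, n_freq = 34L,
    n_cycles = 2,
    rank = 14L,
    dc_removal = TRUE,
    variant = "phase_only",
    angle_min = pi / 4,
    n_size_bins = 32L,
    size_range = c(0.32, 0.01),
    K = 32L,
    sf_max = 50,
    purpose = "regression",
    n_steiner = 3L,
    n_perm = 10000L,
    reject = TRUE,
    reference = "white_matter"
  )
}

#' Run the full spectrum-estimation pipeline
#'
#' Orchestrates preprocessing (artifact rejection and white-matter
#' re-referencing), phase extraction at the configured temporal
#' frequencies, complex SVD with optional standing-wave removal, contact
#' geometry (surface projection, geodesic distances, triangle enumeration
#' and binning — computed once and reused across frequencies), spectrum
#' construction, and log-log wavelength-power regressions with permutation
#' p-values.  Deterministic given the configuration seed.
#'
#' @param recording a [raw_recording()].
#' @param contacts contact table (columns `id`, `x`, `y`, `z`, `label`,
#'   `hemisphere`).
#' @param mesh a [cortical_mesh()].
#' @param config named list overriding entries of [default_config()], or a
#'   path to a YAML file of overrides.
#' @param frequencies optional explicit vector of center frequencies
#'   (overrides `fmin` / `fmax` / `n_freq`).
#' @param out_dir optional directory; when given, spectrum tables
#'   (`spectrum_<freq>.tsv`), the triangle table and a JSON summary are
#'   written there, each embedding the configuration and seed.
#' @return List with `spectra`, `regressions`, `pvalues`, `peaks` (when
#'   >= 3 frequencies), `triangles`, `report` (rejection report),
#'   `config`.
#' @export
run_pipeline <- function(recording, contacts, mesh, config = list(),
                         frequencies = NULL, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  bad <- setdiff(names(config), names(default_config()))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  set.seed(cfg$seed)

  report <- NULL
  if (isTRUE(cfg$reject) && length(recording$trial_bounds) >= 2L) {
    rj <- reject_noisy(recording)
    recording <- rj$recording
    report <- rj$report
    keep_ids <- recording$contact_ids
    contacts <- contacts[match(keep_ids, contacts$id), , drop = FALSE]
  }
  if (identical(cfg$reference, "white_matter") &&
      sum(recording$labels == "white") >= 2L) {
    sig <- white_matter_reference(recording)
    gray <- contacts[match(attr(sig, "contact_ids"), contacts$id), ,
                     drop = FALSE]
  } else {
    gray_idx <- recording$labels == "gray"
    sig <- recording$signal[gray_idx, , drop = FALSE]
    gray <- contacts[gray_idx, , drop = FALSE]
  }

  projection <- project_to_surface(gray, mesh)
  D <- geodesic_distances(mesh, projection, n_steiner = cfg$n_steiner)
  tri <- enumerate_triangles(D, as.character(gray$hemisphere),
                             angle_min = cfg$angle_min)
  tri <- bin_triangles(tri, n_bins = cfg$n_size_bins,
                       size_range = cfg$size_range)

  if (is.null(frequencies))
    frequencies <- center_frequencies(cfg$fmin, cfg$fmax, cfg$n_freq)
  spectra <- vector("list", length(frequencies))
  regressions <- vector("list", length(frequencies))
  pvalues <- rep(NA_real_, length(frequencies))
  for (i in seq_along(frequencies)) {
    f <- frequencies[i]
    pm <- morlet_phase(sig, fs = recording$fs, f = f,
                       n_cycles = cfg$n_cycles, variant = cfg$variant)
    sv <- complex_svd(pm, rank = min(cfg$rank, nrow(sig)))
    max_size <- max(1 / tri$triangles$xi)
    lo <- if (cfg$purpose == "plot") 1 / (2 * max_size) else 1 / max_size
    sp <- build_spectrum(sv, tri, K = cfg$K,
                         sf_range = c(lo, cfg$sf_max),
                         dc_removal = cfg$dc_removal)
    spectra[[i]] <- sp
    reg <- try(loglog_regression(sp), silent = TRUE)
    if (!inherits(reg, "try-error")) {
      reg$p <- as.numeric(permutation_pvalue(reg, n_perm = cfg$n_perm,
                                             seed = cfg$seed + i))
      pvalues[i] <- reg$p
      regressions[[i]] <- reg
    }
  }
  peaks <- if (length(frequencies) >= 3L)
    peak_statistics(spectra, n_perm = cfg$n_perm, seed = cfg$seed)
  else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    meta <- list(seed = cfg$seed,
                 config = cfg[order(names(cfg))])
    for (i in seq_along(frequencies))
      write_spectrum(spectra[[i]],
                     file.path(out_dir, sprintf("spectrum_%07.3fHz.tsv",
                                                frequencies[i])),
                     extra = meta)
    write_triangles(tri, file.path(out_dir, "triangles.tsv"))
    jsonlite::write_json(
      list(seed = cfg$seed, config = meta$config,
           frequencies = frequencies, pvalues = pvalues,
           n_triangles = nrow(tri$triangles)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  list(spectra = spectra, regressions = regressions, pvalues = pvalues,
       peaks = peaks, triangles = tri, report = report, config = cfg,
       frequencies = frequencies)
}
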