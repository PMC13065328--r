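#' Construct a raw multi-trial recording
#'
#' Container for a contacts-by-samples signal matrix together with the
#' sampling rate, the trial structure, and per-contact anatomical labels.
#'
#' @param signal numeric matrix, contacts x samples (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param trial_bounds list of half-open sample intervals `c(start, end)`
#'   (1-based start, exclusive end, so a trial covers `start:(end-1)`).
#'   Intervals must be non-overlapping and within the sample range.
#' @param contact_ids character or integer vector of contact identifiers.
#' @param labels per-contact tissue label, `"gray"` or `"white"`.
#' @param hemisphere per-contact hemisphere, `"left"` or `"right"`.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(signal, fs, trial_bounds = NULL,
                          contact_ids = NULL, labels = NULL,
                          hemisphere = NULL) {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  n_s <- nrow(signal); n_t <- ncol(signal)
  if (is.null(trial_bounds)) trial_bounds <- list(c(1L, n_t + 1L))
  for (b in trial_bounds) {
    if (length(b) != 2L || b[1] < 1 || b[2] > n_t + 1 || b[1] >= b[2])
      stop("trial bounds must be half-open intervals within the sample range")
  }
  starts <- vapply(trial_bounds, `[`, numeric(1), 1L)
  ends   <- vapply(trial_bounds, `[`, numeric(1), 2L)
  o <- order(starts)
  if (any(ends[o][-length(o)] > starts[o][-1]))
    stop("trial intervals overlap")
  if (is.null(contact_ids)) contact_ids <- seq_len(n_s)
  if (is.null(labels)) labels <- rep("gray", n_s)
  if (is.null(hemisphere)) hemisphere <- rep("left", n_s)
  stopifnot(length(contact_ids) == n_s, length(labels) == n_s,
            length(hemisphere) == n_s)
  if (!all(labels %in% c("gray", "white")))
    stop("labels must be 'gray' or 'white'")
  structure(list(signal = signal, fs = fs, trial_bounds = trial_bounds,
                 contact_ids = contact_ids, labels = labels,
                 hemisphere = hemisphere),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d contacts x %d samples @ %g Hz, %d trial(s); %d gray / %d white\n",
    nrow(x$signal), ncol(x$signal), x$fs, length(x$trial_bounds),
    sum(x$labels == "gray"), sum(x$labels == "white")))
  invisible(x)
}

# per-(trial, sensor) SD of signal over samples, unbiased denominator
.trial_sensor_sd <- function(rec, trials = seq_along(rec$trial_bounds),
                             sensors = seq_len(nrow(rec$signal))) {
  out <- matrix(NA_real_, length(trials), length(sensors))
  for (i in seq_along(trials)) {
    b <- rec$trial_bounds[[trials[i]]]
    seg <- rec$signal[sensors, b[1]:(b[2] - 1L), drop = FALSE]
    out[i, ] <- apply(seg, 1L, sd)
  }
  out
}

#' Three-stage rejection of noisy trials, sensors and cells
#'
#' Sequential artifact screening on per-(trial, sensor) standard deviations,
#' with recalculation between stages: (1) trials whose mean per-sensor SD
#' exceeds `trial_k` times the mean over all trials are dropped; (2) after
#' recomputing on the retained trials, sensors whose mean SD exceeds
#' `sensor_k` times the mean over all sensors are dropped; (3) after
#' recomputing again, individual trial-by-sensor cells whose SD deviates
#' from the mean of all cells by more than `cell_k` standard deviations of
#' the cells are replaced by that sensor's average signal across retained
#' trials, the average being computed after excluding every over-threshold
#' cell.  Stages 1-2 are multiples of the mean (so homogeneous data is
#' never touched); stage 3 is a deviation in cell-SD units.
#'
#' @param recording a [raw_recording()].
#' @param trial_k,sensor_k,cell_k rejection thresholds (defaults 3, 1.5,
#'   3): multiples of the stage mean for trials and sensors, standard
#'   deviations of the cell statistics for cells.
#'
#' @return A list with the cleaned `recording` and a `report` (class
#'   `rejection_report`) holding `dropped_trials`, `dropped_sensors`,
#'   `replaced_cells` (data frame of trial/sensor pairs, indices into the
#'   retained recording), and `replacement_axis = "per-sensor across trials"`.
#' @export
reject_noisy <- function(recording, trial_k = 3, sensor_k = 1.5, cell_k = 3) {
  stopifnot(inherits(recording, "raw_recording"))
  n_trials <- length(recording$trial_bounds)
  n_sensors <- nrow(recording$signal)
  if (n_sensors < 2L) stop("need at least 2 sensors")
  dropped_trials <- integer(0)

  # stage 1: trials
  if (n_trials < 2L) {
    warning("single-trial recording: trial-rejection stage skipped")
  } else {
    sds <- .trial_sensor_sd(recording)
    trial_means <- rowMeans(sds)
    dropped_trials <- which(trial_means > trial_k * mean(trial_means))
    if (length(dropped_trials) == n_trials)
      stop("all trials rejected at stage 1")
  }
  kept_trials <- setdiff(seq_len(n_trials), dropped_trials)

  # stage 2: sensors, recomputed on retained trials
  sds <- .trial_sensor_sd(recording, trials = kept_trials)
  sensor_means <- colMeans(sds)
  dropped_sensors <- which(sensor_means > sensor_k * mean(sensor_means))
  kept_sensors <- setdiff(seq_len(n_sensors), dropped_sensors)
  if (length(kept_sensors) < 2L) stop("fewer than 2 sensors retained")

  # stage 3: cells, recomputed on retained trials x sensors
  sds <- .trial_sensor_sd(recording, trials = kept_trials,
                          sensors = kept_sensors)
  dev <- abs(sds - mean(sds))
  thr <- cell_k * sd(as.vector(sds))
  bad <- which(dev > thr & thr > 0, arr.ind = TRUE)

  sig <- recording$signal[kept_sensors, , drop = FALSE]
  bounds <- recording$trial_bounds[kept_trials]
  if (nrow(bad) > 0) {
    bad_mask <- matrix(FALSE, length(kept_trials), length(kept_sensors))
    bad_mask[bad] <- TRUE
    # per-sensor average over retained trials, excluding over-threshold cells
    for (s in unique(bad[, 2])) {
      ok_tr <- which(!bad_mask[, s])
      if (length(ok_tr) == 0)
        stop("sensor ", kept_sensors[s], ": every retained trial over threshold")
      # trials may have unequal lengths; average within-trial sample position
      len <- min(vapply(bounds, function(b) b[2] - b[1], numeric(1)))
      acc <- rep(0, len)
      for (tr in ok_tr) {
        b <- bounds[[tr]]
        acc <- acc + sig[s, b[1]:(b[1] + len - 1L)]
      }
      avg <- acc / length(ok_tr)
      for (tr in which(bad_mask[, s])) {
        b <- bounds[[tr]]
        n_fill <- b[2] - b[1]
        sig[s, b[1]:(b[2] - 1L)] <- rep_len(avg, n_fill)
      }
    }
  }

  cleaned <- raw_recording(
    sig, recording$fs, bounds,
    contact_ids = recording$contact_ids[kept_sensors],
    labels = recording$labels[kept_sensors],
    hemisphere = recording$hemisphere[kept_sensors])
  report <- structure(list(
    dropped_trials = as.integer(dropped_trials),
    dropped_sensors = as.integer(dropped_sensors),
    replaced_cells = data.frame(trial = as.integer(bad[, 1]),
                                sensor = as.integer(bad[, 2])),
    replacement_axis = "per-sensor across trials"),
    class = "rejection_report")
  list(recording = cleaned, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d trial(s), %d sensor(s) dropped; %d cell(s) replaced (%s)\n",
              length(x$dropped_trials), length(x$dropped_sensors),
              nrow(x$replaced_cells), x$replacement_axis))
  invisible(x)
}

#' Re-reference gray-matter contacts to quiet white matter
#'
#' Builds a reference as the per-sample average of the white-matter contacts
#' whose signal-amplitude SD lies in the bottom 50% of white contacts (the
#' lower `floor(n/2)`, ties broken by contact index), and subtracts it from
#' every gray-matter contact.
#'
#' @param recording a [raw_recording()] with both gray and white contacts.
#' @return Numeric matrix, gray contacts x samples, with attributes
#'   `contact_ids` (the gray contacts) and `reference_contacts` (indices of
#'   the white contacts used).
#' @export
white_matter_reference <- function(recording) {
  stopifnot(inherits(recording, "raw_recording"))
  white <- which(recording$labels == "white")
  gray <- which(recording$labels == "gray")
  if (length(white) == 0)
    stop("no white-matter contacts: pass an explicit reference, or none")
  if (length(white) < 2L)
    stop("need at least 2 white-matter contacts for the pooled reference")
  wsd <- apply(recording$signal[white, , drop = FALSE], 1L, sd)
  n_keep <- max(1L, floor(length(white) / 2))
  keep <- white[order(wsd, seq_along(wsd))[seq_len(n_keep)]]
  ref <- colMeans(recording$signal[keep, , drop = FALSE])
  out <- sweep(recording$signal[gray, , drop = FALSE], 2L, ref)
  attr(out, "contact_ids") <- recording$contact_ids[gray]
  attr(out, "reference_contacts") <- keep
  out
}
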