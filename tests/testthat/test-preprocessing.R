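# independent oracle for the three-stage rejection, written directly from
# the screening rules (per-(trial, sensor) SDs, recomputed between stages)
oracle_reject <- function(sig, bounds, trial_k = 3, sensor_k = 1.5,
                          cell_k = 3) {
  sds <- function(trials, sensors) {
    out <- matrix(NA_real_, length(trials), length(sensors))
    for (i in seq_along(trials)) {
      b <- bounds[[trials[i]]]
      for (j in seq_along(sensors))
        out[i, j] <- sd(sig[sensors[j], b[1]:(b[2] - 1)])
    }
    out
  }
  trials <- seq_along(bounds); sensors <- seq_len(nrow(sig))
  s1 <- sds(trials, sensors)
  tm <- rowMeans(s1)
  drop_t <- which(tm > trial_k * mean(tm))
  trials <- setdiff(trials, drop_t)
  s2 <- sds(trials, sensors)
  sm <- colMeans(s2)
  drop_s <- which(sm > sensor_k * mean(sm))
  sensors <- setdiff(sensors, drop_s)
  s3 <- sds(trials, sensors)
  bad <- which(abs(s3 - mean(s3)) > cell_k * sd(as.vector(s3)) &
                 sd(as.vector(s3)) > 0, arr.ind = TRUE)
  list(dropped_trials = drop_t, dropped_sensors = drop_s, cells = bad)
}

test_that("homogeneous recordings pass the three-stage screen untouched", {
  rec <- make_trial_recording(seed = 4)
  # identical trials x identical sensors: replicate one trial everywhere
  sig <- rec$signal
  len <- 100L
  for (i in 2:10) sig[, (i - 1) * len + 1:len] <- sig[, 1:len]
  sig <- sig[rep(1L, 4), , drop = FALSE]
  rec2 <- raw_recording(sig, rec$fs, rec$trial_bounds)
  out <- reject_noisy(rec2)
  expect_length(out$report$dropped_trials, 0)
  expect_length(out$report$dropped_sensors, 0)
  expect_equal(nrow(out$report$replaced_cells), 0)
  expect_equal(out$recording$signal, sig)
})

test_that("a single scaled-up trial is dropped, matching the brute-force oracle", {
  rec <- make_trial_recording(seed = 5)
  b <- rec$trial_bounds[[4]]
  rec$signal[, b[1]:(b[2] - 1)] <- rec$signal[, b[1]:(b[2] - 1)] * 20
  orc <- oracle_reject(rec$signal, rec$trial_bounds)
  expect_equal(orc$dropped_trials, 4L)
  out <- reject_noisy(rec)
  expect_equal(out$report$dropped_trials, 4L)
  expect_length(out$report$dropped_sensors, 0)
  expect_equal(length(out$recording$trial_bounds), 9L)
})

test_that("a single hot trial-by-sensor cell is replaced by the excluding average", {
  # the cell is hot enough for the cell screen but dilute in both the
  # trial and sensor margins
  rec <- make_trial_recording(n_trials = 12L, n_sensors = 8L, seed = 6)
  b <- rec$trial_bounds[[3]]
  rec$signal[2, b[1]:(b[2] - 1)] <- rec$signal[2, b[1]:(b[2] - 1)] * 6
  orc <- oracle_reject(rec$signal, rec$trial_bounds)
  expect_length(orc$dropped_trials, 0)
  expect_length(orc$dropped_sensors, 0)
  expect_equal(unname(orc$cells[1, ]), c(3L, 2L))
  out <- reject_noisy(rec)
  expect_equal(out$report$replaced_cells,
               data.frame(trial = 3L, sensor = 2L))
  # replacement equals the mean of sensor 2 over the other trials
  other <- setdiff(1:12, 3)
  len <- 100L
  avg <- rowMeans(vapply(other, function(tr)
    rec$signal[2, (tr - 1) * len + 1:len], numeric(len)))
  expect_equal(unname(out$recording$signal[2, b[1]:(b[2] - 1)]), avg)
  # everything else untouched
  expect_equal(out$recording$signal[-2, ], rec$signal[-2, ])
})

test_that("stage order is trial, then sensor, then cell", {
  # a sensor made hot in every trial: the sensor stage (after trial
  # recalculation) must catch it, not the cell stage
  rec <- make_trial_recording(seed = 7)
  rec$signal[1, ] <- rec$signal[1, ] * 20
  out <- reject_noisy(rec)
  orc <- oracle_reject(rec$signal, rec$trial_bounds)
  expect_equal(out$report$dropped_sensors, as.integer(orc$dropped_sensors))
  expect_equal(out$report$dropped_sensors, 1L)
  expect_equal(nrow(out$report$replaced_cells), 0)
})

test_that("single-trial recordings skip the trial stage with a warning", {
  sig <- matrix(rnorm(400), 4)
  rec <- raw_recording(sig, 500)
  expect_warning(out <- reject_noisy(rec), "single-trial")
  expect_length(out$report$dropped_trials, 0)
})

test_that("white-matter reference pools the quiet half of white contacts", {
  set.seed(8)
  n_t <- 200
  w <- rnorm(n_t)
  g1 <- rnorm(n_t); g2 <- rnorm(n_t)
  # four white contacts with SDs 1 < 2 < 3 < 4, two gray contacts
  white <- rbind(w * 1, w * 2, w * 3, w * 4)
  sig <- rbind(g1, g2, white)
  rec <- raw_recording(sig, 500,
                       labels = c("gray", "gray", rep("white", 4)))
  ref <- white_matter_reference(rec)
  expect_equal(attr(ref, "reference_contacts"), c(3L, 4L))
  expected_ref <- (w * 1 + w * 2) / 2
  expect_equal(unname(ref[1, ]), g1 - expected_ref)
  expect_equal(unname(ref[2, ]), g2 - expected_ref)
})

test_that("identical white contacts subtract exactly and zero out a matching gray", {
  set.seed(9)
  w <- rnorm(150)
  g <- rnorm(150)
  sig <- rbind(g, w, w, w)
  rec <- raw_recording(sig, 500, labels = c("gray", rep("white", 3)))
  ref <- white_matter_reference(rec)
  expect_equal(unname(ref[1, ]), g - w)
  # gray contact equal to the reference itself
  sig2 <- rbind(w, w, w, w)
  rec2 <- raw_recording(sig2, 500, labels = c("gray", rep("white", 3)))
  expect_equal(max(abs(white_matter_reference(rec2))), 0)
})

test_that("re-referencing cancels any common-mode signal", {
  set.seed(10)
  sig <- matrix(rnorm(5 * 120), 5)
  rec <- raw_recording(sig, 500, labels = c("gray", "gray", rep("white", 3)))
  base <- white_matter_reference(rec)
  common <- sin(seq_len(120))
  rec2 <- rec
  rec2$signal <- sweep(sig, 2L, -common)
  shifted <- white_matter_reference(rec2)
  expect_equal(unclass(base), unclass(shifted), ignore_attr = TRUE)
})

test_that("missing white matter is an instructive error", {
  rec <- raw_recording(matrix(rnorm(200), 2), 500,
                       labels = c("gray", "gray"))
  expect_error(white_matter_reference(rec), "explicit reference")
})
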