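#' Log-log wavelength-power regression of a spectrum
#'
#' Ordinary least squares of log power on log wavelength (`1 / SF`) over
#' the spectrum bins with spatial frequency at or above `min_sf`.
#' Zero-power bins are dropped (count recorded).  The conventional lower
#' bound excludes spatial frequencies below the reciprocal of the maximum
#' triangle size, where estimates are not meaningful.
#'
#' @param spectrum an `sf_spectrum`.
#' @param min_sf lower spatial-frequency bound (cycles/m); defaults to the
#'   reciprocal of the maximum triangle size recorded in the spectrum.
#' @return Object of class `sfp_regression`: `slope`, `offset`, `r`
#'   (correlation of y with fitted values), `n_points`,
#'   `n_zero_dropped`, `sf_bounds`, and the `y`, `yhat` vectors for
#'   permutation testing.  `p` is `NA` until [permutation_pvalue()] is
#'   applied.
#' @export
loglog_regression <- function(spectrum, min_sf = NULL) {
  stopifnot(inherits(spectrum, "sf_spectrum"))
  if (is.null(min_sf)) min_sf <- 1 / spectrum$max_triangle_size
  ctr <- spectrum_bin_centers(spectrum)
  sel <- ctr >= min_sf
  n_zero <- sum(sel & spectrum$power <= 0)
  sel <- sel & spectrum$power > 0
  if (sum(sel) < 3L) stop("fewer than 3 usable bins in range")
  x <- log(1 / ctr[sel])
  y <- log(spectrum$power[sel])
  fit <- lm(y ~ x)
  yhat <- as.numeric(fitted(fit))
  r <- if (sd(y) > 0 && sd(yhat) > 0) cor(y, yhat) else NA_real_  # flat
  structure(list(slope = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
                 r = r, p = NA_real_, n_points = sum(sel),
                 n_zero_dropped = n_zero,
                 sf_bounds = c(min_sf, spectrum$sf_range[2]),
                 y = y, yhat = yhat, x = x),
            class = "sfp_regression")
}

#' @export
print.sfp_regression <- function(x, ...) {
  cat(sprintf("<sfp_regression> log(power) ~ log(wavelength): slope %.4g, offset %.4g, r = %.4f, p = %s (n = %d, %d zero bins dropped)\n",
              x$slope, x$offset, x$r,
              if (is.na(x$p)) "NA" else format.pval(x$p), x$n_points,
              x$n_zero_dropped))
  invisible(x)
}

#' Two-tailed permutation p-value for one or many regressions
#'
#' The observed statistic is the unsigned mean, over group members, of the
#' correlation between each member's `y` and its regression model values
#' `yhat`.  Each permutation shuffles every member's `yhat` independently
#' (within-member shuffling) and recomputes the unsigned mean correlation;
#' the p-value uses the add-one correction
#' `p = (#(|perm| >= |obs|) + 1) / (n_perm + 1)` so the smallest
#' attainable value is `1 / (n_perm + 1)`.
#'
#' @param fits a single `sfp_regression`, a list of them, or a list of
#'   `list(y =, yhat =)` pairs.
#' @param n_perm number of permutations (default 10000; must be >= 1000).
#' @param seed integer seed.
#' @return The p-value, with the observed unsigned mean correlation in the
#'   `observed` attribute.
#' @export
permutation_pvalue <- function(fits, n_perm = 10000L, seed = NULL) {
  if (n_perm < 1000L) stop("n_perm must be at least 1000")
  if (inherits(fits, "sfp_regression") ||
      (is.list(fits) && !is.null(fits$y))) fits <- list(fits)
  ys <- lapply(fits, `[[`, "y")
  yh <- lapply(fits, `[[`, "yhat")
  for (i in seq_along(ys)) {
    if (sd(ys[[i]]) == 0 || sd(yh[[i]]) == 0)
      stop("constant y or yhat: correlation undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  obs <- abs(mean(mapply(cor, ys, yh)))
  perm_sum <- numeric(n_perm)
  for (i in seq_along(ys)) {
    y <- ys[[i]]; h <- yh[[i]]; n <- length(y)
    sh <- vapply(seq_len(n_perm), function(j) h[sample.int(n)],
                 numeric(n))
    perm_sum <- perm_sum + as.numeric(cor(y, sh))
  }
  perm <- abs(perm_sum / length(ys))
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  attr(p, "observed") <- obs
  p
}

#' Peak statistics of spectra across temporal frequencies
#'
#' Locates the maximum-power bin of each spectrum (ties go to the lowest
#' spatial frequency and are flagged), then regresses (a) peak power and
#' (b) log wavelength at peak on log temporal frequency, each with a
#' permutation p-value.
#'
#' @param spectra list of `sf_spectrum` objects at different temporal
#'   frequencies (>= 3).
#' @param n_perm,seed passed to [permutation_pvalue()].
#' @return List with `table` (data frame: `tf`, `peak_power`, `peak_sf`,
#'   `tie`), `peak_power_fit` and `peak_sf_fit` (each with `slope`,
#'   `offset`, `r`, `p`).
#' @export
peak_statistics <- function(spectra, n_perm = 10000L, seed = NULL) {
  if (length(spectra) < 3L) stop("need spectra at >= 3 temporal frequencies")
  tf <- vapply(spectra, `[[`, numeric(1), "f")
  pk <- lapply(spectra, spectrum_peak_sf)
  tab <- data.frame(
    tf = tf,
    peak_power = vapply(spectra, function(s) max(s$power), numeric(1)),
    peak_sf = vapply(pk, as.numeric, numeric(1)),
    tie = vapply(pk, function(z) isTRUE(attr(z, "tie")), logical(1)))
  fit_one <- function(y) {
    x <- log(tf)
    fit <- lm(y ~ x)
    yhat <- as.numeric(fitted(fit))
    if (sd(y) == 0 || sd(yhat) == 0) {
      # no variation: nothing to test (e.g. the peak never moves)
      return(list(slope = unname(coef(fit)[2]),
                  offset = unname(coef(fit)[1]), r = NA_real_,
                  p = NA_real_))
    }
    p <- permutation_pvalue(list(list(y = y, yhat = yhat)),
                            n_perm = n_perm, seed = seed)
    list(slope = unname(coef(fit)[2]), offset = unname(coef(fit)[1]),
         r = cor(y, yhat), p = as.numeric(p))
  }
  list(table = tab,
       peak_power_fit = fit_one(tab$peak_power),
       peak_sf_fit = fit_one(log(1 / tab$peak_sf)))
}
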