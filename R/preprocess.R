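#' Preprocessing configuration
#'
#' Collects the tunable parameters of the replicate-spectrum processing
#' chain. Defaults follow common DUV Raman practice: recalibration against
#' the atmospheric N2 line at 2330 cm^-1, atmospheric N2/O2 subtraction at
#' ~2331 and ~1550 cm^-1, the 800-1800 cm^-1 organic fingerprint window,
#' a robust z threshold of 5 for cosmic-ray spikes, and guanine-peak
#' normalization over 1440-1480 cm^-1.
#'
#' @param n2_reference N2 reference position, cm^-1.
#' @param n2_search_halfwidth half-width of the N2 search window, cm^-1.
#' @param atmospheric_positions positions of atmospheric lines to subtract,
#'   cm^-1 (N2, O2).
#' @param atmospheric_window half-width of each atmospheric fit window,
#'   cm^-1 (default 25).
#' @param fingerprint_lo,fingerprint_hi organic fingerprint range, cm^-1.
#' @param cosmic_ray_zmax robust z-score threshold for spike detection.
#' @param guanine_window guanine normalization window, cm^-1 (length-2).
#' @param guanine_stat `"max"` (peak apex, default) or `"mean"` over the
#'   window.
#' @param recalibrate,subtract_atmospheric,normalize logical switches for the
#'   optional stages.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(n2_reference = 2330,
                              n2_search_halfwidth = 30,
                              atmospheric_positions = c(2331, 1550),
                              atmospheric_window = 25,
                              fingerprint_lo = 800,
                              fingerprint_hi = 1800,
                              cosmic_ray_zmax = 5,
                              guanine_window = c(1440, 1480),
                              guanine_stat = c("max", "mean"),
                              recalibrate = TRUE,
                              subtract_atmospheric = TRUE,
                              normalize = TRUE) {
  guanine_stat <- match.arg(guanine_stat)
  if (fingerprint_lo >= fingerprint_hi)
    stop("fingerprint_lo must be < fingerprint_hi", call. = FALSE)
  if (cosmic_ray_zmax <= 0 || n2_search_halfwidth <= 0 ||
      atmospheric_window <= 0)
    stop("thresholds and window widths must be > 0", call. = FALSE)
  structure(list(n2_reference = n2_reference,
                 n2_search_halfwidth = n2_search_halfwidth,
                 atmospheric_positions = atmospheric_positions,
                 atmospheric_window = atmospheric_window,
                 fingerprint_lo = fingerprint_lo,
                 fingerprint_hi = fingerprint_hi,
                 cosmic_ray_zmax = cosmic_ray_zmax,
                 guanine_window = guanine_window,
                 guanine_stat = guanine_stat,
                 recalibrate = recalibrate,
                 subtract_atmospheric = subtract_atmospheric,
                 normalize = normalize),
            class = "preprocess_config")
}

#' Remove cosmic-ray spikes from a replicate set
#'
#' Cosmic rays are single-channel, single-exposure CCD artifacts. They are
#' detected per wavenumber channel as outliers of the across-replicate
#' intensity distribution: a replicate value with robust z-score
#' (median/MAD) above `zmax` is replaced by the mean of the two spectrally
#' adjacent channels of the same replicate (one-sided at the axis
#' boundaries). No other values are modified.
#'
#' @param set a [spectrum_set] with at least 3 replicates.
#' @param zmax robust z threshold (default 5).
#' @return A [spectrum_set]; the replaced cells are recorded in
#'   `attr(, "replaced")` as a data frame with columns `channel`,
#'   `replicate`, `original`.
#' @export
remove_cosmic_rays <- function(set, zmax = 5) {
  stopifnot(is_spectrum_set(set))
  m <- set$intensity
  if (ncol(m) < 3L)
    stop("insufficient replicates for outlier detection (need >= 3)",
         call. = FALSE)
  med <- apply(m, 1L, stats::median)
  madv <- apply(m, 1L, stats::mad)           # constant = 1.4826 (consistent)
  denom <- pmax(madv, .Machine$double.eps)
  z <- abs(m - med) / denom
  flagged <- which(z > zmax & madv > 0, arr.ind = TRUE)
  out <- m
  n <- nrow(m)
  if (nrow(flagged) > 0L) {
    for (k in seq_len(nrow(flagged))) {
      i <- flagged[k, 1L]; j <- flagged[k, 2L]
      lo <- if (i > 1L) m[i - 1L, j] else NA_real_
      hi <- if (i < n) m[i + 1L, j] else NA_real_
      out[i, j] <- mean(c(lo, hi), na.rm = TRUE)
    }
  }
  res <- spectrum_set(set$shift, out, meta = set$meta)
  attr(res, "replaced") <- if (nrow(flagged) > 0L)
    data.frame(channel = flagged[, 1L], replicate = flagged[, 2L],
               original = m[flagged])
  else
    data.frame(channel = integer(), replicate = integer(),
               original = numeric())
  res
}

#' Correct for laser-intensity variability
#'
#' Divides intensities by a normalized laser intensity correction factor
#' (the relative laser power during acquisition). For a [spectrum_set],
#' `factor` may be a per-replicate vector.
#'
#' @param x a [raman_spectrum] or [spectrum_set].
#' @param factor positive scalar (or per-replicate vector for sets). For a
#'   set, defaults to `meta$laser_factors` when present.
#' @return Object of the same class with corrected intensities; the factor
#'   applied is recorded in the metadata.
#' @export
correct_laser_intensity <- function(x, factor = NULL) {
  if (is_spectrum_set(x)) {
    if (is.null(factor)) factor <- x$meta$laser_factors
    if (is.null(factor)) factor <- 1
    if (any(factor <= 0)) stop("invalid correction factor (must be > 0)",
                               call. = FALSE)
    factor <- rep_len(factor, ncol(x$intensity))
    out <- sweep(x$intensity, 2L, factor, "/")
    m <- x$meta; m$laser_factor_applied <- factor
    return(spectrum_set(x$shift, out, meta = m))
  }
  stopifnot(is_raman_spectrum(x))
  if (is.null(factor)) factor <- 1
  if (length(factor) != 1L || factor <= 0)
    stop("invalid correction factor (must be > 0)", call. = FALSE)
  m <- x$meta
  m$laser_factor <- factor
  raman_spectrum(x$shift, x$intensity / factor, meta = m)
}

## 3-point parabolic apex refinement around index i of (x, y)
parabolic_apex <- function(x, y, i) {
  if (i <= 1L || i >= length(x)) return(x[i])
  y1 <- y[i - 1L]; y2 <- y[i]; y3 <- y[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(x[i])
  delta <- 0.5 * (y1 - y3) / den
  # local grid assumed ~uniform
  x[i] + delta * (x[i + 1L] - x[i - 1L]) / 2
}

#' Recalibrate the shift axis against the atmospheric N2 line
#'
#' Locates the N2 peak apex within `reference +/- search_halfwidth`
#' (3-point parabolic refinement of the window maximum) and applies the
#' rigid shift `reference - apex` to the whole axis, so the re-detected
#' apex lands within half a channel of `reference`.
#'
#' @param x a [raman_spectrum] or [spectrum_set] (sets use the replicate
#'   mean for apex detection; the shared axis is shifted).
#' @param reference N2 standard position, cm^-1 (default 2330).
#' @param search_halfwidth search half-window, cm^-1 (default 30).
#' @return Same class as `x`, axis rigidly shifted; the shift applied is in
#'   `attr(, "delta_cm1")`.
#' @export
recalibrate_shift <- function(x, reference = 2330, search_halfwidth = 30) {
  shift <- x$shift
  y <- if (is_spectrum_set(x)) rowMeans(x$intensity) else x$intensity
  if (min(shift) > reference - search_halfwidth ||
      max(shift) < reference + search_halfwidth)
    stop("N2 region absent: spectrum does not cover the search window",
         call. = FALSE)
  win <- which(shift >= reference - search_halfwidth &
                 shift <= reference + search_halfwidth)
  iw <- win[which.max(y[win])]
  # apex must be an interior local maximum standing above the window floor
  if (iw == win[1L] || iw == win[length(win)] ||
      y[iw] <= stats::median(y[win]))
    stop("N2 peak not found: no local maximum above local background",
         call. = FALSE)
  apex <- parabolic_apex(shift, y, iw)
  delta <- reference - apex
  out <- if (is_spectrum_set(x))
    spectrum_set(shift + delta, x$intensity, meta = x$meta)
  else
    raman_spectrum(shift + delta, x$intensity, meta = x$meta)
  attr(out, "delta_cm1") <- delta
  out
}

## unit-height pseudo-Voigt line shape
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  u <- (x - center) / (fwhm / 2)
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

## Fit one symmetric pseudo-Voigt + local polynomial offset in a window by
## profiled linear least squares over a small (center, fwhm) grid, with a
## non-negative amplitude. The peak position is assumed known to a few
## cm^-1 (atmospheric lines after recalibration; the sulfate internal
## standard) and the default width is pinned to the instrument resolution:
## a looser parametrization soaks up real neighbouring signal in crowded
## regions. Returns the fitted peak evaluated on `x` (full axis).
fit_local_peak <- function(x, y, position, halfwidth = 25,
                           center_halfwidth = 2, fwhm = 25, degree = 3,
                           eta = 0.5) {
  win <- which(x >= position - halfwidth & x <= position + halfwidth)
  if (length(win) < degree + 4L) return(NULL)
  xw <- x[win]; yw <- y[win]
  centers <- seq(position - center_halfwidth, position + center_halfwidth,
                 by = 0.5)
  fwhms <- if (length(fwhm) == 1L) fwhm
           else seq(fwhm[1L], fwhm[2L], length.out = 13L)
  B <- outer(xw - position, 0:degree, `^`)
  best <- NULL
  for (cc in centers) for (ff in fwhms) {
    p <- pseudo_voigt(xw, cc, ff, eta)
    fit <- tryCatch(stats::lm.fit(cbind(B, p), yw), error = function(e) NULL)
    if (is.null(fit)) next
    amp <- fit$coefficients[degree + 2L]
    if (is.na(amp)) next
    if (amp < 0) { # profile under the non-negativity constraint
      f0 <- stats::lm.fit(B, yw)
      rss <- sum(f0$residuals^2); amp <- 0
    } else {
      rss <- sum(fit$residuals^2)
    }
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, center = cc, fwhm = ff, amplitude = amp)
  }
  if (is.null(best)) return(NULL)
  peak <- best$amplitude * pseudo_voigt(x, best$center, best$fwhm, eta)
  c(best, list(peak = peak, window = win))
}

#' Subtract atmospheric N2/O2 lines
#'
#' At each requested position a single symmetric pseudo-Voigt peak plus a
#' local cubic offset is fitted within `+/- window` cm^-1 by profiled
#' linear least squares, and the fitted peak (not the offset) is
#' subtracted. The peak center is searched within +/- 2 cm^-1 of the
#' nominal position (the axis is already recalibrated) and the width is
#' pinned to the instrument resolution by default: a looser
#' parametrization absorbs real signal from neighbouring organic modes,
#' biasing the O2 line amplitude in the crowded 1500-1600 cm^-1 region.
#' Positions not covered by the axis are skipped with a warning; a window
#' too narrow to fit is flagged and the spectrum passed through unchanged.
#'
#' @param x a [raman_spectrum] or [spectrum_set] (sets are processed per
#'   replicate, sharing the peak location grid).
#' @param positions line positions, cm^-1; default N2 ~2331 and O2 ~1550.
#' @param window fit half-window, cm^-1 (default 25).
#' @param fwhm line width in cm^-1: a fixed value (default 25, the
#'   instrument resolution) or a `c(lo, hi)` range to profile over.
#' @return Same class as `x`; fitted line parameters in
#'   `attr(, "atmospheric_fits")`, and `attr(, "flag")` is TRUE when any
#'   requested line could not be fitted.
#' @export
subtract_atmospheric <- function(x, positions = c(2331, 1550), window = 25,
                                 fwhm = 25) {
  fits <- list()
  flag <- FALSE
  sub_one <- function(shift, y) {
    for (pos in positions) {
      if (min(shift) > pos - window || max(shift) < pos + window) {
        warning(sprintf("axis does not cover %g cm^-1 fit window; skipped",
                        pos))
        next
      }
      f <- fit_local_peak(shift, y, pos, halfwidth = window, fwhm = fwhm)
      if (is.null(f)) {
        warning(sprintf("atmospheric fit at %g cm^-1 failed; spectrum left unmodified", pos))
        flag <<- TRUE
        next
      }
      y <- y - f$peak
      fits[[length(fits) + 1L]] <<-
        list(position = pos, center = f$center, fwhm = f$fwhm,
             amplitude = f$amplitude)
    }
    y
  }
  if (is_spectrum_set(x)) {
    out <- x$intensity
    for (j in seq_len(ncol(out))) out[, j] <- sub_one(x$shift, out[, j])
    res <- spectrum_set(x$shift, out, meta = x$meta)
  } else {
    stopifnot(is_raman_spectrum(x))
    res <- raman_spectrum(x$shift, sub_one(x$shift, x$intensity),
                          meta = x$meta)
  }
  attr(res, "atmospheric_fits") <- fits
  attr(res, "flag") <- flag
  res
}

#' Crop to the organic fingerprint range
#'
#' Retains channels with `lo <= shift <= hi` (closed interval); the
#' diagnostic organic modes of nucleobases and aromatic amino acids lie in
#' the 800-1800 cm^-1 window.
#'
#' @param x a [raman_spectrum] or [spectrum_set].
#' @param lo,hi crop bounds in cm^-1 (defaults 800, 1800).
#' @return Same class as `x`, restricted to the window.
#' @export
crop_fingerprint <- function(x, lo = 800, hi = 1800) {
  keep <- x$shift >= lo & x$shift <= hi
  if (sum(keep) < 2L) stop("empty crop: window does not overlap the axis",
                           call. = FALSE)
  if (is_spectrum_set(x))
    spectrum_set(x$shift[keep], x$intensity[keep, , drop = FALSE],
                 meta = x$meta)
  else
    raman_spectrum(x$shift[keep], x$intensity[keep], meta = x$meta)
}

## OLS line over (x, y); returns fitted values
ols_line <- function(x, y) {
  xc <- x - mean(x)
  b <- sum(xc * y) / sum(xc^2)
  mean(y) + b * xc
}

#' Subtract a linear background
#'
#' Fits an ordinary least-squares line to intensity vs shift over the full
#' (cropped) range and subtracts it. The output may contain negative
#' values; the operation is idempotent to numerical precision.
#'
#' @param x a [raman_spectrum] or [spectrum_set] (sets are processed per
#'   replicate).
#' @return Same class as `x`; the fitted `(intercept, slope)` of the last
#'   spectrum processed is recorded in `attr(, "baseline")`.
#' @export
subtract_linear_baseline <- function(x) {
  if (length(x$shift) < 3L)
    stop("degenerate baseline: need at least 3 channels", call. = FALSE)
  if (is_spectrum_set(x)) {
    out <- x$intensity
    for (j in seq_len(ncol(out))) out[, j] <- out[, j] - ols_line(x$shift, out[, j])
    res <- spectrum_set(x$shift, out, meta = x$meta)
    line <- ols_line(x$shift, rowMeans(x$intensity))
  } else {
    stopifnot(is_raman_spectrum(x))
    line <- ols_line(x$shift, x$intensity)
    res <- raman_spectrum(x$shift, x$intensity - line, meta = x$meta)
  }
  slope <- (line[length(line)] - line[1L]) / (x$shift[length(x$shift)] - x$shift[1L])
  attr(res, "baseline") <- c(intercept = line[1L] - slope * x$shift[1L],
                             slope = slope)
  res
}

#' Average replicate spectra
#'
#' Channelwise arithmetic mean of the replicates; the channelwise sample
#' standard deviation is kept in `meta$channel_sd` for downstream
#' uncertainty propagation.
#'
#' @param set a [spectrum_set].
#' @return A [raman_spectrum] (the mean), with `meta$channel_sd`.
#' @export
average_replicates <- function(set) {
  stopifnot(is_spectrum_set(set))
  m <- set$meta
  m$n_replicates <- ncol(set$intensity)
  m$channel_sd <- if (ncol(set$intensity) > 1L)
    apply(set$intensity, 1L, stats::sd)
  else
    rep(0, nrow(set$intensity))
  raman_spectrum(set$shift, rowMeans(set$intensity), meta = m)
}

#' Normalize to the guanine peak
#'
#' Scales the spectrum so that the guanine ~1460 cm^-1 peak intensity
#' within `window` equals 1. The statistic is the window maximum by
#' default ("peak apex" convention) or the window mean.
#'
#' @param spectrum a [raman_spectrum].
#' @param window length-2 window in cm^-1 (default `c(1440, 1480)`).
#' @param stat `"max"` (default) or `"mean"`.
#' @return A [raman_spectrum] scaled so the window statistic is 1; the
#'   scale factor is stored in `meta$norm_factor` (and `channel_sd`, if
#'   present, is scaled consistently).
#' @export
normalize_to_guanine <- function(spectrum, window = c(1440, 1480),
                                 stat = c("max", "mean")) {
  stopifnot(is_raman_spectrum(spectrum))
  stat <- match.arg(stat)
  keep <- spectrum$shift >= window[1L] & spectrum$shift <= window[2L]
  if (!any(keep)) stop("cannot normalize: window outside the axis",
                       call. = FALSE)
  val <- if (stat == "max") max(spectrum$intensity[keep])
         else mean(spectrum$intensity[keep])
  if (!is.finite(val) || val <= 0)
    stop("cannot normalize: nonpositive intensity in guanine window",
         call. = FALSE)
  m <- spectrum$meta
  m$norm_factor <- val
  if (!is.null(m$channel_sd)) m$channel_sd <- m$channel_sd / val
  raman_spectrum(spectrum$shift, spectrum$intensity / val, meta = m)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: cosmic-ray removal, laser-intensity correction,
#' wavenumber recalibration (N2 line; must precede the crop, which discards
#' the N2 region), atmospheric N2/O2 subtraction, fingerprint crop, linear
#' baseline subtraction, replicate averaging, and guanine-peak
#' normalization. Stage effect sizes are logged.
#'
#' @param set a [spectrum_set] of raw replicate spectra.
#' @param config a [preprocess_config].
#' @return The final fingerprint-range [raman_spectrum]; the per-stage log
#'   (cosmic rays replaced, recalibration shift, baseline slope,
#'   normalization factor, ...) is in `attr(, "log")`.
#' @export
preprocess_spectra <- function(set, config = preprocess_config()) {
  stopifnot(is_spectrum_set(set))
  log <- list()
  x <- remove_cosmic_rays(set, config$cosmic_ray_zmax)
  log$cosmic_rays_replaced <- nrow(attr(x, "replaced"))
  x <- correct_laser_intensity(x)
  if (isTRUE(config$recalibrate)) {
    x <- recalibrate_shift(x, config$n2_reference, config$n2_search_halfwidth)
    log$recalibration_delta_cm1 <- attr(x, "delta_cm1")
  }
  if (isTRUE(config$subtract_atmospheric)) {
    x <- subtract_atmospheric(x, config$atmospheric_positions,
                              config$atmospheric_window)
    log$atmospheric_fits <- attr(x, "atmospheric_fits")
  }
  x <- crop_fingerprint(x, config$fingerprint_lo, config$fingerprint_hi)
  x <- subtract_linear_baseline(x)
  log$baseline <- attr(x, "baseline")
  out <- average_replicates(x)
  if (isTRUE(config$normalize)) {
    out <- normalize_to_guanine(out, config$guanine_window,
                                config$guanine_stat)
    log$norm_factor <- out$meta$norm_factor
  }
  attr(out, "log") <- log
  out
}
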