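#' Synthetic acquisition configuration
#'
#' Parameters of the seeded replicate-spectrum generator, chosen to mirror
#' the statistical structure of a DUV Raman point-array acquisition of
#' dried cells: 25 replicate points, ~25 cm^-1 lines at the standard peak
#' positions, a featureless broad unmodeled background contributing ~16%
#' of fingerprint intensity for cell-like targets, additive Gaussian
#' detector noise, occasional single-channel cosmic-ray spikes, a rigid
#' wavenumber miscalibration, and atmospheric N2 (~2330 cm^-1) and O2
#' (~1550 cm^-1) lines.
#'
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @param axis shift grid, cm^-1 (default 400-2400 by 2).
#' @param tier generating standard-library tier.
#' @param true_weights named component weights; default a cell-like
#'   composition over all 8 components.
#' @param background_fraction fraction of integrated fingerprint intensity
#'   contributed by the unmodeled broad background (0.16 cell-like, 0 for
#'   mixture-like targets).
#' @param noise_sigma Gaussian noise sd as a fraction of the dominant-peak
#'   height (default 0.01).
#' @param cosmic_ray_rate expected spikes per replicate (default 0.2).
#' @param n_replicates number of replicate points (default 25).
#' @param axis_offset_cm1 rigid miscalibration; `NULL` (default) draws it
#'   uniformly in +/- 12 cm^-1.
#' @param include_atmospheric add N2/O2 lines (default TRUE).
#' @param laser_cv coefficient of variation of per-replicate laser power
#'   (default 0 = stable laser).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             axis = seq(400, 2400, by = 2),
                             tier = "dNTP",
                             true_weights = NULL,
                             background_fraction = 0.16,
                             noise_sigma = 0.01,
                             cosmic_ray_rate = 0.2,
                             n_replicates = 25L,
                             axis_offset_cm1 = NULL,
                             include_atmospheric = TRUE,
                             laser_cv = 0) {
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)", call. = FALSE)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  if (is.null(true_weights))
    true_weights <- c(adenine = 0.30, cytosine = 0.10, guanine = 0.35,
                      thymine = 0.06, uracil = 0.09,
                      phenylalanine = 0.04, tryptophan = 0.02,
                      tyrosine = 0.04)
  structure(list(seed = as.integer(seed), axis = as.numeric(axis),
                 tier = tier, true_weights = true_weights,
                 background_fraction = background_fraction,
                 noise_sigma = noise_sigma,
                 cosmic_ray_rate = cosmic_ray_rate,
                 n_replicates = as.integer(n_replicates),
                 axis_offset_cm1 = axis_offset_cm1,
                 include_atmospheric = include_atmospheric,
                 laser_cv = laser_cv),
            class = "synthetic_config")
}

## Broad unmodeled background. Starts from a featureless Gaussian bump
## (center 1300, fwhm 600) and keeps only the part that the analysis model
## cannot represent: the component orthogonal (over the fingerprint
## window) to the span of a linear baseline and the generating standard
## spectra. Any non-orthogonal part would simply be absorbed by the
## baseline stage or the fit coefficients and is, by construction, not
## "unmodeled". The result is scaled by fixed-point iteration so its
## integrated |intensity| equals `fraction` of the processed target's
## integrated |intensity| over the window.
make_background <- function(axis, signal, fraction, standards = NULL,
                            lo = 800, hi = 1800, center = 1300, fwhm = 600) {
  if (fraction <= 0) return(numeric(length(axis)))
  win <- axis >= lo & axis <= hi
  bump <- exp(-4 * log(2) * ((axis - center) / fwhm)^2)
  M <- cbind(1, axis[win])
  if (!is.null(standards)) M <- cbind(M, standards[win, , drop = FALSE])
  beta <- stats::lm.fit(M, bump[win])$coefficients
  beta[is.na(beta)] <- 0
  bump_perp <- numeric(length(axis))
  bump_perp[win] <- bump[win] - drop(M %*% beta)
  sig_bl <- signal[win] - ols_line(axis[win], signal[win])
  b_abs <- trapz(axis[win], abs(bump_perp[win]))
  if (b_abs <= 0) return(numeric(length(axis)))
  s_abs <- trapz(axis[win], abs(sig_bl))
  alpha <- fraction * s_abs / ((1 - fraction) * b_abs)
  for (i in 1:25) {
    tot <- trapz(axis[win], abs(sig_bl + alpha * bump_perp[win]))
    alpha_new <- fraction * tot / b_abs
    if (abs(alpha_new - alpha) < 1e-12 * max(alpha, 1)) break
    alpha <- alpha_new
  }
  alpha * bump_perp
}

#' Generate a synthetic replicate spectrum set with known truth
#'
#' Builds the noise-free truth `sum_i w_i S_i` plus (optionally) the broad
#' unmodeled background, then per replicate adds atmospheric lines,
#' Gaussian noise, Poisson-count cosmic-ray spikes (amplitude 10-100x the
#' noise sd at a uniform channel) and applies a rigid axis miscalibration.
#' The truth record stores everything the generator injected, so every
#' preprocessing stage and the unmixing fit can be validated against it.
#'
#' @param config a [synthetic_config].
#' @param library a [standard_library]; default built from `config$tier`
#'   on `config$axis`.
#' @return List with `set` (a [spectrum_set]) and `truth`: list of
#'   `weights`, `clean` (noise-free truth [raman_spectrum], background
#'   included), `signal` (components only), `background`, `offset_cm1`,
#'   `spikes` (data frame), `noise_sd`, `laser_factors`, `config`.
#' @export
generate_target <- function(config, library = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(library))
    library <- standard_library(config$tier, axis = config$axis)
  w <- config$true_weights
  unknown <- setdiff(names(w), names(library$members))
  if (length(unknown) > 0L)
    stop(sprintf("weight for unknown component: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  set.seed(config$seed)
  axis <- config$axis
  S <- vapply(library$members, function(s) {
    if (length(s$shift) == length(axis) && all(s$shift == axis)) s$intensity
    else stats::approx(s$shift, s$intensity, xout = axis, rule = 2)$y
  }, numeric(length(axis)))
  signal <- drop(S %*% vapply(colnames(S), function(nm)
    if (nm %in% names(w)) w[[nm]] else 0, 0))
  bg <- make_background(axis, signal, config$background_fraction,
                        standards = S)
  clean <- signal + bg

  fp <- axis >= 800 & axis <= 1800
  peak_h <- max(signal[fp])
  noise_sd <- config$noise_sigma * peak_h
  spike_base <- max(noise_sd, 0.01 * peak_h)

  offset <- if (is.null(config$axis_offset_cm1))
    stats::runif(1, -12, 12) else config$axis_offset_cm1

  ## features truly at wavenumber v appear at v + offset on the recorded
  ## axis: the detector samples the true spectrum at (axis - offset).
  ## Line components are evaluated analytically at the shifted positions
  ## (no resampling error); only the smooth broad background, defined on
  ## the generator grid, is interpolated.
  shifted <- axis - offset
  S_shift <- vapply(names(library$members), function(nm) {
    pk <- library$peaks[library$peaks$molecule == nm, ]
    if (nrow(pk) > 0L)
      synthesize_standard(pk, shifted, label = nm)$intensity
    else # measured member: fall back to interpolation
      stats::approx(library$members[[nm]]$shift,
                    library$members[[nm]]$intensity, xout = shifted,
                    rule = 2)$y
  }, numeric(length(axis)))
  signal_rec <- drop(S_shift %*% vapply(colnames(S_shift), function(nm)
    if (nm %in% names(w)) w[[nm]] else 0, 0))
  atm_rec <- numeric(length(axis))
  if (isTRUE(config$include_atmospheric))
    atm_rec <- 0.5 * peak_h * pseudo_voigt(shifted, 2330, 25) +
      0.2 * peak_h * pseudo_voigt(shifted, 1550, 25)
  bg_rec <- stats::approx(axis, bg, xout = shifted, rule = 2)$y
  base_rec <- signal_rec + bg_rec + atm_rec
  laser <- if (config$laser_cv > 0)
    exp(stats::rnorm(config$n_replicates, 0, config$laser_cv))
  else rep(1, config$n_replicates)

  n <- length(axis)
  reps <- matrix(0, n, config$n_replicates)
  spikes <- list()
  for (j in seq_len(config$n_replicates)) {
    yj <- base_rec * laser[j]
    if (noise_sd > 0) yj <- yj + stats::rnorm(n, 0, noise_sd)
    nspk <- stats::rpois(1, config$cosmic_ray_rate)
    if (nspk > 0) {
      ch <- sample.int(n, nspk)
      amp <- stats::runif(nspk, 10, 100) * spike_base
      yj[ch] <- yj[ch] + amp
      spikes[[length(spikes) + 1L]] <-
        data.frame(replicate = j, channel = ch, amplitude = amp)
    }
    reps[, j] <- yj
  }
  spikes <- if (length(spikes) > 0L) do.call(rbind, spikes)
  else data.frame(replicate = integer(), channel = integer(),
                  amplitude = numeric())
  set <- spectrum_set(axis, reps, label = "synthetic",
                      laser_factors = laser)
  truth <- list(weights = w,
                clean = raman_spectrum(axis, clean, label = "truth"),
                signal = raman_spectrum(axis, signal, label = "signal"),
                background = raman_spectrum(axis, bg, label = "background"),
                offset_cm1 = offset, spikes = spikes, noise_sd = noise_sd,
                laser_factors = laser, config = config)
  list(set = set, truth = truth)
}

#' Write a tier's standard spectra to disk
#'
#' Synthesizes the 8 standards of a tier, optionally adds the sulfate
#' internal-standard band (~981 cm^-1) and Gaussian noise, and writes one
#' two-column file per standard plus a `manifest.csv`, readable by
#' [read_spectrum()] / [standard_library()].
#'
#' @param tier standards tier.
#' @param out_dir output directory (created if needed).
#' @param config a [synthetic_config] (controls axis, seed, noise).
#' @param sulfate add a sulfate band of unit peak height (default FALSE).
#' @param noise_sigma noise sd relative to dominant-peak height
#'   (default 0).
#' @return Invisibly, a data frame manifest (`molecule`, `file`).
#' @export
generate_standard_files <- function(tier, out_dir,
                                    config = synthetic_config(),
                                    sulfate = FALSE, noise_sigma = 0) {
  lib <- standard_library(tier, axis = config$axis)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", out_dir), call. = FALSE)
  set.seed(config$seed)
  files <- character()
  for (nm in names(lib$members)) {
    s <- lib$members[[nm]]
    y <- s$intensity
    if (sulfate) y <- y + pseudo_voigt(s$shift, 981, 25)
    if (noise_sigma > 0)
      y <- y + stats::rnorm(length(y), 0, noise_sigma * max(s$intensity))
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write_spectrum(raman_spectrum(s$shift, y, label = nm), f)
    files <- c(files, f)
  }
  manifest <- data.frame(molecule = names(lib$members),
                         file = basename(files), tier = tier,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' One-call end-to-end fixture
#'
#' Produces everything a full pipeline run needs: the raw synthetic
#' replicate set, the generating standard library, and the truth record.
#'
#' @param config a [synthetic_config].
#' @return List with `set`, `library`, `truth`.
#' @export
end_to_end_fixture <- function(config = synthetic_config()) {
  lib <- standard_library(config$tier, axis = config$axis)
  g <- generate_target(config, lib)
  list(set = g$set, library = lib, truth = g$truth)
}
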