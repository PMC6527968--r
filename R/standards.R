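## Dominant Raman modes of the eight DUV-resonant molecular standards, by
## structural-complexity tier of the nucleic-acid components: free
## nucleobase, deoxy-/ribonucleotide triphosphate (dNTP), and
## single-stranded 10-mer oligomer. Aromatic amino acids share one tier.
.dominant_modes <- data.frame(
  molecule = rep(c("adenine", "cytosine", "guanine", "thymine", "uracil"), 3),
  tier = rep(c("nucleobase", "dNTP", "ssDNA_10mer"), each = 5),
  center = c(1291, 1512, 1440, 1647, 1210,    # free bases
             1322, 1523, 1474, 1651, 1214,    # dNTPs (UTP for uracil)
             1314, 1508, 1462, 1634, 1203),   # ssDNA/ssRNA 10-mers
  assignment = rep(c("C8H (b), C8N7 (s)", "N3C4 (s)", "C8H (b), N9C8 (s)",
                     "C4=O (s), C5C7 (s)", "C5H (b), N3C4 (s)"), 3),
  stringsAsFactors = FALSE
)

.amino_modes <- data.frame(
  molecule = c("phenylalanine", "tryptophan", "tyrosine"),
  tier = "amino_acid",
  center = c(1595, 1610, 1591),
  assignment = "benzene ring (s)",
  stringsAsFactors = FALSE
)

## Secondary features transcribed from the cellular-spectrum description
## (relative heights are placeholders, not measured values).
.extended_modes <- data.frame(
  molecule = c("guanine", "phenylalanine", "tyrosine", "cytosine", "cytosine"),
  tier = c("ssDNA_10mer", "amino_acid", "amino_acid", "nucleobase",
           "ssDNA_10mer"),
  center = c(1550, 1000, 1000, 1350, 1574),
  assignment = c("N3C4 (s), C5C4/C4N3 (s) composite", "ring breathing (s)",
                 "ring breathing (s)", "C2H, N9C8 (s) shoulder",
                 "ssDNA-C mode (s)"),
  stringsAsFactors = FALSE
)

.nucleic_tiers <- c("nucleobase", "dNTP", "ssDNA_10mer")
.amino_acids <- c("phenylalanine", "tryptophan", "tyrosine")

#' Built-in peak table for a standards tier
#'
#' Returns the dominant-mode peak descriptors of the five nucleic-acid
#' standards of the requested tier together with the three aromatic amino
#' acids (which are tier-independent). With `extended = TRUE`, secondary
#' features described for cellular spectra are added with placeholder
#' relative heights of 0.3.
#'
#' @param tier one of `"nucleobase"`, `"dNTP"`, `"ssDNA_10mer"`.
#' @param extended include transcribed secondary modes (default FALSE).
#' @param fwhm full width at half maximum assigned to every mode, cm^-1
#'   (default 25, the instrument's true spectral resolution).
#' @return A data frame with columns `molecule`, `tier`, `center`,
#'   `relative_height`, `fwhm`, `assignment`, `dominant`.
#' @examples
#' builtin_peak_table("nucleobase")
#' @export
builtin_peak_table <- function(tier = c("nucleobase", "dNTP", "ssDNA_10mer"),
                               extended = FALSE, fwhm = 25) {
  tier <- match.arg(tier)
  nuc <- .dominant_modes[.dominant_modes$tier == tier, ]
  tab <- rbind(nuc, .amino_modes)
  tab$relative_height <- 1
  tab$dominant <- TRUE
  if (extended) {
    ext <- .extended_modes[.extended_modes$tier %in% c(tier, "amino_acid"), ]
    if (nrow(ext) > 0L) {
      ext$relative_height <- 0.3
      ext$dominant <- FALSE
      tab <- rbind(tab, ext)
    }
  }
  tab$fwhm <- fwhm
  rownames(tab) <- NULL
  tab[, c("molecule", "tier", "center", "relative_height", "fwhm",
          "assignment", "dominant")]
}

#' Shift of a molecule's dominant mode between tiers
#'
#' Signed difference `center(tier_to) - center(tier_from)` of the dominant
#' vibrational mode, e.g. +31 cm^-1 for adenine from free base to dATP,
#' reflecting the redistribution of pi-electron density on the aromatic
#' moiety upon addition of the ribose triphosphate.
#'
#' @param molecule one of the five nucleic-acid standards.
#' @param tier_from,tier_to nucleic-acid tiers.
#' @return Signed shift in cm^-1.
#' @examples
#' dominant_mode_shift("adenine", "nucleobase", "dNTP")  # +31
#' @export
dominant_mode_shift <- function(molecule, tier_from, tier_to) {
  if (molecule %in% .amino_acids)
    stop("amino-acid standards do not change across nucleic-acid tiers",
         call. = FALSE)
  if (!all(c(tier_from, tier_to) %in% .nucleic_tiers))
    stop("tiers must be nucleic-acid tiers", call. = FALSE)
  pick <- function(tr) {
    row <- .dominant_modes[.dominant_modes$molecule == molecule &
                             .dominant_modes$tier == tr, ]
    if (nrow(row) != 1L)
      stop(sprintf("molecule '%s' not present in tier '%s'", molecule, tr),
           call. = FALSE)
    row$center
  }
  pick(tier_to) - pick(tier_from)
}

#' Synthesize a standard spectrum from its peak table
#'
#' Builds a model spectrum as a sum of line shapes, one per tabulated mode,
#' each scaled to height `relative_height`. Peaks whose centers fall
#' outside the axis are truncated with a warning.
#'
#' @param peaks data frame with columns `center`, `relative_height`,
#'   `fwhm` (one row per mode), e.g. one molecule's rows of
#'   [builtin_peak_table()].
#' @param axis shift grid, cm^-1.
#' @param lineshape `"pseudo_voigt"` (default, eta = 0.5), `"gaussian"` or
#'   `"lorentzian"`.
#' @param eta pseudo-Voigt mixing parameter (Lorentzian fraction).
#' @param label spectrum label.
#' @return A [raman_spectrum].
#' @export
synthesize_standard <- function(peaks, axis, lineshape = c("pseudo_voigt",
                                                           "gaussian",
                                                           "lorentzian"),
                                eta = 0.5, label = "") {
  lineshape <- match.arg(lineshape)
  if (nrow(peaks) == 0L) stop("non-empty peak list required", call. = FALSE)
  eta_use <- switch(lineshape, pseudo_voigt = eta, gaussian = 0,
                    lorentzian = 1)
  axis <- as.numeric(axis)
  y <- numeric(length(axis))
  for (k in seq_len(nrow(peaks))) {
    if (peaks$center[k] < min(axis) || peaks$center[k] > max(axis))
      warning(sprintf("peak at %g cm^-1 outside axis; truncated",
                      peaks$center[k]))
    y <- y + peaks$relative_height[k] *
      pseudo_voigt(axis, peaks$center[k], peaks$fwhm[k], eta_use)
  }
  raman_spectrum(axis, y, label = label)
}

#' Build a standard library for one complexity tier
#'
#' Assembles the eight-component library of one nucleic-acid tier (the five
#' nucleic-acid standards of that tier plus phenylalanine, tryptophan and
#' tyrosine) on a shared axis — the component set of the linear-combination
#' cell-spectrum model. Member spectra are synthesized from the built-in
#' peak tables unless measured spectra are supplied.
#'
#' @param tier `"nucleobase"`, `"dNTP"` or `"ssDNA_10mer"`.
#' @param axis shared shift grid, cm^-1 (default 400-2400 by 2).
#' @param lineshape,eta passed to [synthesize_standard()].
#' @param extended include secondary modes (see [builtin_peak_table()]).
#' @param fwhm line width, cm^-1.
#' @param spectra optional named list of measured [raman_spectrum] objects
#'   overriding the synthetic members (names = molecule names).
#' @return An object of class `standard_library`: list with `tier`, `axis`,
#'   `members` (named list of [raman_spectrum]), `peaks` (the peak table).
#' @examples
#' lib <- standard_library("dNTP")
#' names(lib$members)
#' @export
standard_library <- function(tier = c("nucleobase", "dNTP", "ssDNA_10mer"),
                             axis = seq(400, 2400, by = 2),
                             lineshape = "pseudo_voigt", eta = 0.5,
                             extended = FALSE, fwhm = 25, spectra = NULL) {
  tier <- match.arg(tier)
  tab <- builtin_peak_table(tier, extended = extended, fwhm = fwhm)
  members <- list()
  for (mol in unique(tab$molecule)) {
    if (!is.null(spectra) && mol %in% names(spectra)) {
      members[[mol]] <- resample_to_axis(spectra[[mol]], axis)
    } else {
      members[[mol]] <- synthesize_standard(tab[tab$molecule == mol, ], axis,
                                            lineshape, eta, label = mol)
    }
  }
  if (length(members) != 8L)
    stop("a standard library must have exactly 8 members", call. = FALSE)
  structure(list(tier = tier, axis = as.numeric(axis), members = members,
                 peaks = tab, preprocessed = FALSE),
            class = "standard_library")
}

is_standard_library <- function(x) inherits(x, "standard_library")

#' @export
print.standard_library <- function(x, ...) {
  cat(sprintf("Standard library, tier '%s'%s: %s\n", x$tier,
              if (isTRUE(x$preprocessed)) " (preprocessed)" else "",
              paste(names(x$members), collapse = ", ")))
  invisible(x)
}

#' Preprocess library members like a target spectrum
#'
#' Applies the fingerprint crop and linear baseline subtraction to every
#' member so the standards are processed consistently with a pipeline-
#' processed target. Because ordinary least squares is linear, a target
#' that is a linear combination of raw standards remains the same linear
#' combination of the processed standards, so the fit coefficients are
#' unchanged while the reconstruction stays exact.
#'
#' @param library a [standard_library].
#' @param lo,hi crop window, cm^-1.
#' @return A [standard_library] on the cropped axis with
#'   `preprocessed = TRUE`.
#' @export
preprocess_library <- function(library, lo = 800, hi = 1800) {
  stopifnot(is_standard_library(library))
  library$members <- lapply(library$members, function(s)
    subtract_linear_baseline(crop_fingerprint(s, lo, hi)))
  library$axis <- library$members[[1L]]$shift
  library$preprocessed <- TRUE
  library
}

#' Anchor a measured standard to its sulfate internal standard
#'
#' Measured standards are co-dissolved with Na2SO4 as an internal
#' concentration standard (symmetric SO4 stretch at ~981 cm^-1). The
#' spectrum is scaled so the fitted sulfate peak area equals 1, then the
#' fitted sulfate peak is subtracted, making spectra of equal analyte
#' concentration comparable across laser powers.
#'
#' @param spectrum a [raman_spectrum] covering the sulfate region.
#' @param sulfate_position sulfate band position, cm^-1 (default 981).
#' @param window fit half-window, cm^-1.
#' @return A [raman_spectrum]; the scale factor is in `meta$sulfate_scale`.
#'   If no sulfate peak is found the input is returned unscaled with
#'   `attr(, "flag") = TRUE` and a warning.
#' @export
prepare_measured_standard <- function(spectrum, sulfate_position = 981,
                                      window = 25) {
  stopifnot(is_raman_spectrum(spectrum))
  f <- if (min(spectrum$shift) <= sulfate_position - window &&
             max(spectrum$shift) >= sulfate_position + window)
    fit_local_peak(spectrum$shift, spectrum$intensity, sulfate_position,
                   halfwidth = window, center_halfwidth = 5)
  else NULL
  if (is.null(f) ||
      f$amplitude <= 0.01 * max(abs(spectrum$intensity))) {
    warning("sulfate internal-standard peak absent; spectrum returned unscaled")
    out <- spectrum
    attr(out, "flag") <- TRUE
    return(out)
  }
  area <- trapz(spectrum$shift, f$peak)
  m <- spectrum$meta
  m$sulfate_scale <- area
  out <- raman_spectrum(spectrum$shift,
                        (spectrum$intensity - f$peak) / area, meta = m)
  attr(out, "flag") <- FALSE
  out
}
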