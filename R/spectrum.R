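#' Construct a Raman spectrum
#'
#' A `raman_spectrum` is the basic data carrier of the package: a calibrated
#' Raman shift axis (cm^-1, strictly increasing) paired with detector
#' intensities, plus acquisition metadata. All preprocessing and unmixing
#' operations consume and return this class.
#'
#' @param shift numeric vector of Raman shifts in cm^-1. Must be strictly
#'   increasing after sorting; duplicated values are an error.
#' @param intensity numeric vector of detector counts, same length as `shift`.
#' @param label character label for the spectrum (sample name).
#' @param excitation_nm excitation wavelength in nm. Default 248.6 (DUV
#'   NeCu laser line).
#' @param laser_factor dimensionless laser-intensity correction factor
#'   already applied to this spectrum (1 = none).
#' @param meta optional named list of further metadata fields (e.g.
#'   `channel_sd` after replicate averaging, `norm_factor` after
#'   normalization).
#'
#' @return An object of class `raman_spectrum`: a list with elements
#'   `shift`, `intensity` and `meta`.
#' @examples
#' s <- raman_spectrum(seq(800, 1800, 2), rnorm(501), label = "demo")
#' print(s)
#' @export
raman_spectrum <- function(shift, intensity, label = "",
                           excitation_nm = 248.6, laser_factor = 1,
                           meta = list()) {
  shift <- as.numeric(shift)
  intensity <- as.numeric(intensity)
  if (length(shift) != length(intensity))
    stop("shift and intensity must have the same length", call. = FALSE)
  if (length(shift) < 2L)
    stop("insufficient data: a spectrum needs at least 2 channels",
         call. = FALSE)
  if (anyNA(shift) || any(!is.finite(shift)))
    stop("shift axis contains non-finite values", call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity contains non-finite values", call. = FALSE)
  if (is.unsorted(shift)) {
    o <- order(shift)
    shift <- shift[o]
    intensity <- intensity[o]
  }
  if (any(diff(shift) <= 0))
    stop("duplicate channel: shift axis must be strictly increasing",
         call. = FALSE)
  m <- meta
  m$label <- if (is.null(m$label)) label else m$label
  m$excitation_nm <- if (is.null(m$excitation_nm)) excitation_nm else m$excitation_nm
  m$laser_factor <- if (is.null(m$laser_factor)) laser_factor else m$laser_factor
  structure(list(shift = shift, intensity = intensity, meta = m),
            class = "raman_spectrum")
}

is_raman_spectrum <- function(x) inherits(x, "raman_spectrum")

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("Raman spectrum%s: %d channels, %.1f-%.1f cm^-1\n",
              if (nzchar(x$meta$label)) paste0(" '", x$meta$label, "'") else "",
              length(x$shift), min(x$shift), max(x$shift)))
  cat(sprintf("  excitation %.1f nm; intensity range [%.4g, %.4g]\n",
              x$meta$excitation_nm, min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ..., xlab = expression(Raman~shift~(cm^-1)),
                                ylab = "Intensity", type = "l") {
  graphics::plot(x$shift, x$intensity, type = type, xlab = xlab, ylab = ylab,
                 main = x$meta$label, ...)
  invisible(x)
}

#' @export
as.data.frame.raman_spectrum <- function(x, ...) {
  data.frame(shift = x$shift, intensity = x$intensity)
}

#' Construct a set of replicate spectra on a shared axis
#'
#' Holds the replicate point spectra of one sample (e.g. the 25 points of a
#' 5 x 5 acquisition array) as an intensity matrix over one shared shift
#' axis.
#'
#' @param shift shared Raman shift axis (cm^-1, strictly increasing).
#' @param intensity numeric matrix, `length(shift)` rows, one column per
#'   replicate.
#' @param label sample label.
#' @param laser_factors optional per-replicate laser-intensity correction
#'   factors (length = number of replicates).
#' @param meta optional named metadata list.
#'
#' @return An object of class `spectrum_set` with elements `shift`,
#'   `intensity` (matrix) and `meta`.
#' @export
spectrum_set <- function(shift, intensity, label = "", laser_factors = NULL,
                         meta = list()) {
  shift <- as.numeric(shift)
  intensity <- as.matrix(intensity)
  if (nrow(intensity) != length(shift))
    stop("intensity matrix must have one row per channel", call. = FALSE)
  if (ncol(intensity) < 1L) stop("non-empty replicate set required", call. = FALSE)
  if (any(diff(shift) <= 0))
    stop("duplicate channel: shift axis must be strictly increasing",
         call. = FALSE)
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity contains non-finite values", call. = FALSE)
  m <- meta
  m$label <- if (is.null(m$label)) label else m$label
  if (!is.null(laser_factors)) {
    if (length(laser_factors) != ncol(intensity))
      stop("one laser factor per replicate required", call. = FALSE)
    m$laser_factors <- laser_factors
  }
  structure(list(shift = shift, intensity = intensity, meta = m),
            class = "spectrum_set")
}

is_spectrum_set <- function(x) inherits(x, "spectrum_set")

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("Raman spectrum set%s: %d replicates x %d channels, %.1f-%.1f cm^-1\n",
              if (nzchar(x$meta$label)) paste0(" '", x$meta$label, "'") else "",
              ncol(x$intensity), length(x$shift), min(x$shift), max(x$shift)))
  invisible(x)
}

n_replicates <- function(set) ncol(set$intensity)

## trapezoidal integral; workhorse for all intensity budgets
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

## --------------------------------------------------------------------------
## file I/O: two-column delimited text, '#' comments, delimiter auto-detected

detect_delim <- function(line) {
  if (grepl(",", line, fixed = TRUE)) return(",")
  if (grepl("\t", line, fixed = TRUE)) return("\t")
  ""
}

parse_spectrum_lines <- function(lines, path = "<text>", delim = NULL) {
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("insufficient data: no data rows in '%s'", path),
         call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(lines[idx[1L]])
  split_row <- function(ln) {
    if (delim == "") strsplit(trimws(ln), "\\s+")[[1L]]
    else strsplit(trimws(ln), delim, fixed = TRUE)[[1L]]
  }
  first <- split_row(lines[idx[1L]])
  ## tolerate a single header row of non-numeric column names
  start <- 1L
  if (anyNA(suppressWarnings(as.numeric(first))) && length(idx) > 1L) {
    second <- suppressWarnings(as.numeric(split_row(lines[idx[2L]])))
    if (!anyNA(second)) start <- 2L
  }
  rows <- lapply(idx[start:length(idx)], function(i) {
    fields <- split_row(lines[i])
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop(sprintf("parse error at line %d of '%s': '%s'", i, path, lines[i]),
           call. = FALSE)
    vals
  })
  ncols <- min(vapply(rows, length, 1L))
  mat <- do.call(rbind, lapply(rows, function(r) r[seq_len(ncols)]))
  mat
}

#' Read a Raman spectrum from a delimited text file
#'
#' Reads a two-column (shift cm^-1, intensity) plain-text spectrum. The
#' delimiter is auto-detected among comma, tab and whitespace; lines
#' starting with `#` (and an optional single header row) are skipped. Rows
#' are sorted by ascending shift.
#'
#' @param path file path.
#' @param delim optional explicit delimiter (`","`, `"\t"`, or `""` for
#'   whitespace); default auto-detect.
#' @param label spectrum label; defaults to the file name.
#' @return A [raman_spectrum].
#' @seealso [write_spectrum()], [read_spectrum_set()]
#' @export
read_spectrum <- function(path, delim = NULL, label = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path),
                               call. = FALSE)
  mat <- parse_spectrum_lines(readLines(path, warn = FALSE), path, delim)
  if (nrow(mat) < 2L)
    stop("insufficient data: a spectrum needs at least 2 channels",
         call. = FALSE)
  raman_spectrum(mat[, 1L], mat[, 2L],
                 label = if (is.null(label)) basename(path) else label)
}

#' Read a replicate spectrum set
#'
#' Reads either one multi-column file (column 1 = shift, columns 2..n =
#' replicate intensities) or a directory of two-column per-point files that
#' share an identical axis.
#'
#' @param path file or directory path.
#' @param delim optional delimiter override, as in [read_spectrum()].
#' @return A [spectrum_set].
#' @export
read_spectrum_set <- function(path, delim = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(csv|tsv|txt|dat)$"))
    files <- files[!grepl("manifest", basename(files))]
    if (length(files) == 0L)
      stop(sprintf("no spectrum files in directory '%s'", path), call. = FALSE)
    specs <- lapply(files, read_spectrum, delim = delim)
    shift <- specs[[1L]]$shift
    for (s in specs[-1L])
      if (length(s$shift) != length(shift) || any(s$shift != shift))
        stop("axis mismatch: replicates must share an identical shift axis",
             call. = FALSE)
    spectrum_set(shift, vapply(specs, function(s) s$intensity,
                               numeric(length(shift))),
                 label = basename(path))
  } else {
    mat <- parse_spectrum_lines(readLines(path, warn = FALSE), path, delim)
    if (ncol(mat) < 2L) stop("need at least one intensity column", call. = FALSE)
    o <- order(mat[, 1L])
    spectrum_set(mat[o, 1L], mat[o, -1L, drop = FALSE], label = basename(path))
  }
}

#' Write a Raman spectrum to a delimited text file
#'
#' Writes the spectrum at full double precision so that
#' `read_spectrum(write_spectrum(s))` round-trips losslessly.
#'
#' @param spectrum a [raman_spectrum].
#' @param path output file path.
#' @param delim delimiter to use (default comma).
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path, delim = ",") {
  stopifnot(is_raman_spectrum(spectrum))
  header <- sprintf("# %s", spectrum$meta$label)
  rows <- sprintf("%.17g%s%.17g", spectrum$shift, delim, spectrum$intensity)
  ok <- tryCatch({
    writeLines(c(header, rows), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write to '%s'", path), call. = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a target shift axis
#'
#' Linear interpolation of intensities onto `axis`. Channels of `axis`
#' outside the source support are dropped, never extrapolated. With
#' `axis` identical to the source axis this is the identity.
#'
#' @param spectrum a [raman_spectrum].
#' @param axis numeric target shift grid (cm^-1).
#' @return A [raman_spectrum] on the overlapping part of `axis`.
#' @export
resample_to_axis <- function(spectrum, axis) {
  stopifnot(is_raman_spectrum(spectrum))
  axis <- sort(as.numeric(axis))
  keep <- axis >= min(spectrum$shift) & axis <= max(spectrum$shift)
  if (!any(keep)) stop("disjoint axes: no overlap with source spectrum",
                       call. = FALSE)
  out <- stats::approx(spectrum$shift, spectrum$intensity, xout = axis[keep],
                       method = "linear", rule = 1)$y
  raman_spectrum(axis[keep], out, meta = spectrum$meta)
}
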