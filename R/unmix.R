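#' Linear-combination deconvolution of a Raman spectrum
#'
#' Fits a target spectrum as a scalable linear combination of the eight
#' molecular-standard spectra of a library,
#' `I_fit = a*Adenine + c*Cytosine + g*Guanine + t*Thymine + u*Uracil +
#' f*Phenylalanine + w*Tryptophan + y*Tyrosine`,
#' by least squares over the fingerprint window, varying only the
#' component scale coefficients. Physical scale factors cannot be
#' negative, so coefficients are bounded below by zero by default
#' (active-set non-negative least squares); an unconstrained mode solves
#' the normal equations directly.
#'
#' Goodness of fit is the chi-squared value, the raw (unweighted) sum of
#' squared residuals over the fitted channels, with
#' `dof = n_channels - n_components`. Coefficient standard errors come
#' from the residual-variance-scaled covariance of the least-squares
#' solution, combined in quadrature with the error propagated from the
#' replicate channelwise standard deviation of the target
#' (`meta$channel_sd`, present after [average_replicates()]); both terms
#' are retained separately in the fit object. Relative integrated
#' intensities are `c_i * int |S_i| / int |I_target|` and need not sum
#' to 1 — the shortfall is the unexplained residual.
#'
#' @param target a [raman_spectrum] (typically the output of
#'   [preprocess_spectra()]).
#' @param library a [standard_library] sharing (or resampled onto) the
#'   target axis. For baseline-subtracted targets, pass the library
#'   through [preprocess_library()] so standards receive the same
#'   treatment.
#' @param nonneg constrain coefficients to be >= 0 (default TRUE).
#' @param range fit window in cm^-1 (default `c(800, 1800)`).
#' @return An object of class `unmix` with components `coefficients`,
#'   `se` (combined), `se_fit`, `se_spectrum`, `relative_intensity`,
#'   `chi_squared`, `reduced_chi_squared`, `dof`, `correlation`,
#'   `residual` and `fitted` ([raman_spectrum]s), `target`, `tier`.
#' @examples
#' lib <- standard_library("dNTP", axis = seq(800, 1800, 2))
#' truth <- 0.3 * lib$members$adenine$intensity +
#'          0.7 * lib$members$guanine$intensity
#' target <- raman_spectrum(lib$axis, truth)
#' fit <- unmix(target, lib)
#' coef(fit)
#' @seealso [compare_standard_sets()], [residual_fraction()],
#'   [coefficient_correlations()], [report_fit()]
#' @export
unmix <- function(target, library, nonneg = TRUE, range = c(800, 1800)) {
  stopifnot(is_raman_spectrum(target), is_standard_library(library))
  keep <- target$shift >= range[1L] & target$shift <= range[2L]
  if (sum(keep) <= length(library$members))
    stop("too few channels in the fit window", call. = FALSE)
  axis <- target$shift[keep]
  y <- target$intensity[keep]
  X <- vapply(library$members, function(s) {
    if (min(s$shift) > min(axis) || max(s$shift) < max(axis))
      stop("axis mismatch: standard does not cover the fit window",
           call. = FALSE)
    stats::approx(s$shift, s$intensity, xout = axis, rule = 1)$y
  }, numeric(length(axis)))
  comp <- colnames(X) <- names(library$members)
  if (all(X == 0)) stop("library spectra are all zero", call. = FALSE)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p)
    warning("rank-deficient library (collinear components); coefficient correlations are unreliable")

  if (nonneg) {
    sol <- nnls_solve(X, y)
    coefs <- sol$x
    free <- sol$passive
  } else {
    coefs <- qr.coef(qrX, y)
    coefs[is.na(coefs)] <- 0
    free <- rep(TRUE, p)
  }
  names(coefs) <- comp
  fitted_y <- drop(X %*% coefs)
  res <- y - fitted_y
  chi2 <- sum(res^2)
  dof <- length(y) - p
  sigma2 <- chi2 / dof

  se_fit <- se_spec <- stats::setNames(numeric(p), comp)
  corr <- diag(p)
  dimnames(corr) <- list(comp, comp)
  if (any(free)) {
    XF <- X[, free, drop = FALSE]
    XtXi <- tryCatch(solve(crossprod(XF)), error = function(e) NULL)
    if (!is.null(XtXi)) {
      covb <- sigma2 * XtXi
      se_fit[free] <- sqrt(pmax(diag(covb), 0))
      d <- sqrt(diag(covb))
      cF <- covb / outer(d, d)
      corr[free, free] <- cF
      sdch <- target$meta$channel_sd
      if (!is.null(sdch)) {
        sdw <- sdch[keep]
        Ai <- XtXi %*% t(XF)
        covs <- Ai %*% (sdw^2 * t(Ai))
        se_spec[free] <- sqrt(pmax(diag(covs), 0))
      }
    }
  }
  se <- sqrt(se_fit^2 + se_spec^2)

  denom <- trapz(axis, abs(y))
  rel <- if (denom > 0)
    coefs * vapply(seq_len(p), function(j) trapz(axis, abs(X[, j])), 0) / denom
  else rep(NA_real_, p)
  names(rel) <- comp

  structure(list(coefficients = coefs, se = se, se_fit = se_fit,
                 se_spectrum = se_spec, relative_intensity = rel,
                 chi_squared = chi2, reduced_chi_squared = sigma2,
                 dof = dof, correlation = corr,
                 residual = raman_spectrum(axis, res, label = "residual"),
                 fitted = raman_spectrum(axis, fitted_y, label = "fit"),
                 target = raman_spectrum(axis, y, meta = target$meta),
                 design = X, tier = library$tier, nonneg = nonneg,
                 range = range),
            class = "unmix")
}

#' @export
print.unmix <- function(x, digits = 4, ...) {
  cat(sprintf("Spectral deconvolution (%s standards, %s)\n", x$tier,
              if (x$nonneg) "non-negative" else "unconstrained"))
  cat(sprintf("  chi-squared %.4g on %d degrees of freedom\n",
              x$chi_squared, x$dof))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.unmix <- function(object, ...) object$coefficients

#' @export
fitted.unmix <- function(object, ...) object$fitted

#' @export
residuals.unmix <- function(object, ...) object$residual

#' Predict the fitted spectrum, optionally on a new axis
#' @param object an [unmix] fit.
#' @param newaxis optional shift axis to interpolate the fitted spectrum
#'   onto; default the fitted axis.
#' @param ... unused.
#' @return A [raman_spectrum].
#' @export
predict.unmix <- function(object, newaxis = NULL, ...) {
  if (is.null(newaxis)) return(object$fitted)
  resample_to_axis(object$fitted, newaxis)
}

#' @export
summary.unmix <- function(object, ...) {
  tab <- data.frame(component = names(object$coefficients),
                    coefficient = unname(object$coefficients),
                    se = unname(object$se),
                    relative_intensity = unname(object$relative_intensity),
                    stringsAsFactors = FALSE)
  out <- list(table = tab, chi_squared = object$chi_squared,
              reduced_chi_squared = object$reduced_chi_squared,
              dof = object$dof, tier = object$tier,
              residual_fraction = residual_fraction(object))
  class(out) <- "summary.unmix"
  out
}

#' @export
print.summary.unmix <- function(x, digits = 3, ...) {
  cat(sprintf("Deconvolution with %s standards\n", x$tier))
  tab <- x$table
  tab$coefficient <- signif(tab$coefficient, digits)
  tab$se <- signif(tab$se, digits)
  tab$relative_intensity <- signif(tab$relative_intensity, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("chi-squared = %.4g (reduced %.4g, dof %d); residual fraction %.3f\n",
              x$chi_squared, x$reduced_chi_squared, x$dof,
              x$residual_fraction))
  invisible(x)
}

#' @export
plot.unmix <- function(x, ...) {
  graphics::plot(x$target$shift, x$target$intensity, type = "l",
                 xlab = expression(Raman~shift~(cm^-1)), ylab = "Intensity",
                 main = sprintf("Deconvolution (%s standards)", x$tier), ...)
  graphics::lines(x$fitted$shift, x$fitted$intensity, col = "red")
  graphics::lines(x$residual$shift, x$residual$intensity, col = "blue")
  graphics::legend("topleft", c("target", "fit", "residual"),
                   col = c("black", "red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Compare standard sets of increasing complexity
#'
#' Fits the target with each supplied library and ranks the fits by
#' ascending chi-squared — the model-comparison step that identifies the
#' minimum structural complexity needed to describe a cellular spectrum.
#' Ties are broken by fewer effective (nonzero) components, then by tier
#' order nucleobase < dNTP < ssDNA_10mer.
#'
#' @param target a [raman_spectrum].
#' @param libraries list of [standard_library] objects on a shared axis.
#' @param ... passed to [unmix()].
#' @return An object of class `unmix_comparison`: list with `ranking`
#'   (data frame: tier, chi_squared, n_effective, rank) and `fits`
#'   (named by tier, in ranked order).
#' @export
compare_standard_sets <- function(target, libraries, ...) {
  if (is_standard_library(libraries)) libraries <- list(libraries)
  fits <- lapply(libraries, function(lib) unmix(target, lib, ...))
  tiers <- vapply(fits, function(f) f$tier, "")
  chi2 <- vapply(fits, function(f) f$chi_squared, 0)
  neff <- vapply(fits, function(f) sum(f$coefficients > 0), 0L)
  tier_rank <- match(tiers, c("nucleobase", "dNTP", "ssDNA_10mer"))
  o <- order(chi2, neff, tier_rank)
  ranking <- data.frame(tier = tiers[o], chi_squared = chi2[o],
                        n_effective = neff[o], rank = seq_along(o),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, fits = stats::setNames(fits[o], tiers[o])),
            class = "unmix_comparison")
}

#' @export
print.unmix_comparison <- function(x, ...) {
  cat("Standard-set comparison (ascending chi-squared):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Groups of cross-correlated fit coefficients
#'
#' Components whose coefficient estimates are strongly correlated (the
#' aromatic amino acids share a common ~1600 cm^-1 dominant mode and
#' cannot be separated) are reported as pooled groups: connected
#' components of the graph with an edge where `|r| > threshold`, with the
#' pooled coefficient (sum) and pooled relative intensity.
#'
#' @param result an [unmix] fit.
#' @param threshold absolute correlation threshold (default 0.9).
#' @return List of groups (each: `components`, `coefficient`,
#'   `relative_intensity`); empty list when no group of size > 1 exists.
#' @export
coefficient_correlations <- function(result, threshold = 0.9) {
  stopifnot(inherits(result, "unmix"))
  r <- result$correlation
  p <- nrow(r)
  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  seen <- rep(FALSE, p)
  groups <- list()
  for (i in seq_len(p)) {
    if (seen[i]) next
    queue <- i; members <- integer()
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE
      members <- c(members, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    if (length(members) > 1L) {
      nm <- colnames(r)[sort(members)]
      groups[[length(groups) + 1L]] <-
        list(components = nm,
             coefficient = sum(result$coefficients[nm]),
             relative_intensity = sum(result$relative_intensity[nm]))
    }
  }
  groups
}

#' Unexplained residual fraction
#'
#' The integrated absolute fit residual divided by the integrated absolute
#' target intensity over the fitted fingerprint window — the "cell is more
#' than the sum of its parts" statistic: the share of measured intensity
#' that no linear combination of the standards accounts for.
#'
#' @param result an [unmix] fit.
#' @return Dimensionless fraction in `[0, ...)`.
#' @export
residual_fraction <- function(result) {
  stopifnot(inherits(result, "unmix"))
  denom <- trapz(result$target$shift, abs(result$target$intensity))
  if (denom <= 0) stop("zero target integral", call. = FALSE)
  trapz(result$residual$shift, abs(result$residual$intensity)) / denom
}

#' Structured fit report
#'
#' Per-component relative intensities with uncertainties plus the fit
#' chi-squared, as a data frame and (optionally) as a JSON string whose
#' values round-trip exactly. Pooled cross-correlated groups (see
#' [coefficient_correlations()]) are annotated.
#'
#' @param result an [unmix] fit.
#' @param pool_threshold correlation threshold for group annotation; set
#'   above 1 to disable pooling.
#' @param format `"data.frame"` (default) or `"json"`.
#' @return A data frame with attributes `chi_squared`, `dof`, `groups`,
#'   or a JSON string.
#' @export
report_fit <- function(result, pool_threshold = 0.9,
                       format = c("data.frame", "json")) {
  stopifnot(inherits(result, "unmix"))
  format <- match.arg(format)
  tab <- data.frame(component = names(result$coefficients),
                    coefficient = unname(result$coefficients),
                    se = unname(result$se),
                    relative_intensity = unname(result$relative_intensity),
                    stringsAsFactors = FALSE)
  groups <- if (pool_threshold <= 1) coefficient_correlations(result,
                                                              pool_threshold)
            else list()
  tab$group <- ""
  for (k in seq_along(groups))
    tab$group[tab$component %in% groups[[k]]$components] <-
      paste0("pooled_", k)
  if (format == "json") {
    return(jsonlite::toJSON(list(tier = result$tier, table = tab,
                                 chi_squared = result$chi_squared,
                                 dof = result$dof,
                                 groups = groups),
                            auto_unbox = TRUE, digits = NA))
  }
  attr(tab, "chi_squared") <- result$chi_squared
  attr(tab, "dof") <- result$dof
  attr(tab, "groups") <- groups
  tab
}
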