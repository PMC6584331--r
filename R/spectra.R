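#' Subtract a background spectrum
#'
#' Removes the absolute background (typically the borate-buffer blank) from a
#' sample spectrum point by point. Photon counts cannot be negative, so the
#' difference is floored at zero; flooring before unmixing also stabilises the
#' nonnegative least-squares fit.
#'
#' @param sample,background `emission_spectrum` objects on the same grid.
#' @return Background-subtracted `emission_spectrum`.
#' @export
subtract_background <- function(sample, background) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(background, "emission_spectrum"))
  if (!identical(sample$wavelengths, background$wavelengths)) {
    stop("sample and background are not on the same wavelength grid")
  }
  out <- sample
  out$intensities <- pmax(sample$intensities - background$intensities, 0)
  out
}

#' Linear spectral unmixing (emission fingerprinting)
#'
#' Decomposes a background-subtracted sample spectrum into nonnegative
#' abundances of the library components (cyan QD-apatite, red QD-apatite,
#' tissue autofluorescence) by least squares. Physical abundances cannot be
#' negative, so the default solver is nonnegative least squares; set
#' `nonneg = FALSE` for an ordinary unconstrained fit.
#'
#' @param sample `emission_spectrum`, background-subtracted.
#' @param refs `reference_library`.
#' @param nonneg Constrain coefficients to be >= 0 (default `TRUE`).
#' @return An `unmix_result` with elements `coefficients` (named),
#'   `residual_norm`, `curves` (matrix of per-component unmixed curves,
#'   coefficient x reference), `fitted` (their sum) and `photons` (integrated
#'   photons per component, see [integrate_photons()]).
#' @export
unmix <- function(sample, refs, nonneg = TRUE) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(refs, "reference_library"))
  A <- unclass(refs)
  y <- sample$intensities
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    dropped <- colnames(A)[qrA$pivot[seq(qrA$rank + 1L, ncol(A))]]
    stop("reference library is rank deficient; collinear component(s): ",
         paste(dropped, collapse = ", "))
  }
  if (nonneg) {
    coef <- pracma::lsqnonneg(A, y)$x
  } else {
    coef <- qr.coef(qrA, y)
  }
  names(coef) <- colnames(A)
  fitted <- as.numeric(A %*% coef)
  curves <- sweep(A, 2L, coef, `*`)
  structure(
    list(coefficients = coef,
         residual_norm = sqrt(sum((y - fitted)^2)),
         curves = curves,
         fitted = fitted,
         photons = colSums(curves),
         nonneg = nonneg,
         sample_id = sample$sample_id),
    class = "unmix_result"
  )
}

#' @export
print.unmix_result <- function(x, ...) {
  cat("<unmix_result>", x$sample_id,
      if (x$nonneg) "(nonnegative least squares)" else "(unconstrained)", "\n")
  print(round(x$coefficients, 6))
  cat(sprintf("  residual norm: %.4g\n", x$residual_norm))
  invisible(x)
}

#' Moving-average smoothing of an unmixed curve
#'
#' Centered moving average with an odd window; at the ends the window shrinks
#' symmetrically so the output has the same length as the input.
#'
#' @param curve Numeric vector (e.g. one column of an unmixing result).
#' @param window Odd positive integer; default 5 points (10 nm).
#' @return Smoothed numeric vector.
#' @export
smooth_curve <- function(curve, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer")
  }
  n <- length(curve)
  h <- window %/% 2L
  if (h == 0L) return(curve)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1L, n - i)  # shrink symmetrically at the ends
    mean(curve[(i - hh):(i + hh)])
  }, numeric(1))
}

#' Integrated photon count of a curve
#'
#' Total photons of an unmixed component: the sum of its intensities across
#' the canonical grid.
#'
#' @param curve Numeric vector on the canonical grid.
#' @return Scalar photon count (A.U.).
#' @export
integrate_photons <- function(curve) {
  if (length(curve) != length(qd_wavelengths())) {
    stop("curve is not on the canonical 176-point grid")
  }
  sum(curve)
}

#' Fit a photon-vs-concentration calibration line
#'
#' Ordinary least-squares line through (concentration, photons) pairs, e.g.
#' the eight-point QD-apatite dilution series. The stored detection limit is
#' used by [specific_uptake()] to flag unreliable amounts.
#'
#' @param nmol Known QD-apatite amounts (nmol).
#' @param photons Integrated photon responses (A.U.).
#' @param detection_limit Specific-uptake detection limit
#'   (nmol QD per mg tissue); default `1e-6`.
#' @return A `calibration_curve` with `slope`, `intercept`, `points` and
#'   `detection_limit`.
#' @export
fit_calibration <- function(nmol, photons, detection_limit = 1e-6) {
  stopifnot(length(nmol) == length(photons), length(nmol) >= 2)
  if (length(unique(nmol)) < 2) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(photons ~ nmol)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; got ", format(slope))
  }
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[1L]),
         points = data.frame(nmol = nmol, photons = photons),
         detection_limit = detection_limit),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("<calibration_curve>\n")
  cat(sprintf("  photons = %.6g + %.6g * nmol  (%d points)\n",
              x$intercept, x$slope, nrow(x$points)))
  cat(sprintf("  detection limit: %g nmol QD / mg tissue\n", x$detection_limit))
  invisible(x)
}

#' Convert integrated photons to specific uptake
#'
#' Inverts the calibration line and divides by tissue mass, yielding
#' nmol QD-apatite per mg dry tissue. Photon counts below the calibration
#' intercept are clipped to zero amount (no negative extrapolation); values
#' below the detection limit are flagged.
#'
#' @param photons Integrated photon count(s) (A.U.); vectorised.
#' @param calibration A `calibration_curve`.
#' @param tissue_mass_mg Dry tissue mass (mg), > 0.
#' @return Data frame with `nmol_per_mg`, `below_detection`, `clipped`.
#' @export
specific_uptake <- function(photons, calibration, tissue_mass_mg) {
  stopifnot(inherits(calibration, "calibration_curve"))
  if (!is.finite(tissue_mass_mg) || tissue_mass_mg <= 0) {
    stop("tissue_mass_mg must be > 0")
  }
  amount <- (photons - calibration$intercept) / calibration$slope
  clipped <- amount < 0
  amount[clipped] <- 0
  per_mg <- amount / tissue_mass_mg
  data.frame(nmol_per_mg = per_mg,
             below_detection = per_mg < calibration$detection_limit,
             clipped = clipped)
}

#' Aggregate subsample uptake values
#'
#' Each sample is measured as several subsamples (five in the standard
#' workflow) that are averaged. Below-detection subsamples contribute zero by
#' default (`below = "zero"`); set `below = "exclude"` to drop them instead.
#'
#' @param nmol_per_mg Per-subsample specific uptake values.
#' @param below_detection Logical vector marking below-detection subsamples
#'   (default none).
#' @param below Either `"zero"` or `"exclude"`.
#' @return List with `mean`, `se` (NA for a single value) and `n`.
#' @export
aggregate_subsamples <- function(nmol_per_mg, below_detection = NULL,
                                 below = c("zero", "exclude")) {
  below <- match.arg(below)
  if (length(nmol_per_mg) == 0) stop("no subsample values supplied")
  if (is.null(below_detection)) below_detection <- rep(FALSE, length(nmol_per_mg))
  stopifnot(length(below_detection) == length(nmol_per_mg))
  x <- nmol_per_mg
  if (below == "zero") {
    x[below_detection] <- 0
  } else {
    x <- x[!below_detection]
    if (length(x) == 0) return(list(mean = 0, se = NA_real_, n = 0L))
  }
  n <- length(x)
  list(mean = mean(x),
       se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = n)
}
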