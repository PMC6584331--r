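#' Canonical emission wavelength grid
#'
#' The plate reader records emission from 450 to 800 nm in 2 nm steps, giving
#' a fixed 176-point grid. Every spectrum and reference library in the package
#' lives on this grid.
#'
#' @return Numeric vector of 176 wavelengths (nm).
#' @export
#' @examples
#' length(qd_wavelengths())  # 176
qd_wavelengths <- function() {
  seq(450, 800, by = 2)
}

#' Construct an emission spectrum
#'
#' @param intensities Numeric vector of photon counts (A.U.), one per grid
#'   point; must be finite and of length 176.
#' @param sample_id Character identifier for the tissue subsample.
#' @param tissue_mass_mg Dry mass (mg) of the subsample, used later when
#'   converting photons to specific uptake. `NA` if unknown.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(intensities, sample_id = "sample",
                              tissue_mass_mg = NA_real_) {
  grid <- qd_wavelengths()
  if (length(intensities) != length(grid)) {
    stop("intensities must have length ", length(grid),
         " (450-800 nm in 2 nm steps); got ", length(intensities))
  }
  if (!all(is.finite(intensities))) {
    stop("intensities must be finite")
  }
  structure(
    list(wavelengths = grid,
         intensities = as.numeric(intensities),
         sample_id = as.character(sample_id),
         tissue_mass_mg = as.numeric(tissue_mass_mg)),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat("<emission_spectrum>", x$sample_id, "\n")
  cat("  grid: 450-800 nm / 2 nm (", length(x$wavelengths), " points)\n",
      sep = "")
  cat(sprintf("  intensity: total %.4g, peak %.4g at %d nm\n",
              sum(x$intensities), max(x$intensities),
              x$wavelengths[which.max(x$intensities)]))
  if (!is.na(x$tissue_mass_mg)) {
    cat("  tissue mass:", x$tissue_mass_mg, "mg\n")
  }
  invisible(x)
}

#' Construct a reference spectral library
#'
#' Holds named component spectra on the canonical grid. The standard library
#' for the in-vitro system has components `cyan` (QD-apatite, 488 nm
#' emission), `red` (QD-apatite, 666 nm emission) and `autofluorescence`
#' (tissue); the borate-buffer background is kept as a separate spectrum and
#' removed with [subtract_background()] before unmixing.
#'
#' @param ... Named numeric vectors (length 176), or a single matrix with
#'   named columns.
#' @return Matrix (176 x n components) of class `reference_library`.
#' @export
reference_library <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.matrix(args[[1L]])) {
    mat <- args[[1L]]
  } else {
    mat <- do.call(cbind, args)
  }
  grid <- qd_wavelengths()
  if (nrow(mat) != length(grid)) {
    stop("reference spectra must have ", length(grid), " rows (canonical grid)")
  }
  if (is.null(colnames(mat)) || any(!nzchar(colnames(mat)))) {
    stop("all reference components must be named")
  }
  if (!all(is.finite(mat))) stop("reference spectra must be finite")
  zero <- colSums(abs(mat)) == 0
  if (any(zero)) {
    stop("reference component(s) identically zero: ",
         paste(colnames(mat)[zero], collapse = ", "))
  }
  structure(mat, class = c("reference_library", "matrix"))
}
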