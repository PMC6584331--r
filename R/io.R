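## Plain-text and TIFF input/output. Spectra, reference libraries, plate
## tables and track/speed tables travel as CSV; image stacks as multi-page
## TIFF with a JSON sidecar carrying the scan geometry; truth records and
## mixture fits as JSON.

#' Write / read spectra as CSV
#'
#' Long format with columns `wavelength_nm`, `intensity`, `sample_id`
#' (and `tissue_mass_mg`).
#'
#' @param spectra List of `emission_spectrum` objects (or one).
#' @param path CSV path.
#' @return `read_spectra_csv()` returns a list of `emission_spectrum`.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (inherits(spectra, "emission_spectrum")) spectra <- list(spectra)
  df <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(wavelength_nm = s$wavelengths, intensity = s$intensities,
               sample_id = s$sample_id, tissue_mass_mg = s$tissue_mass_mg)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$sample_id), function(d) {
    d <- d[order(d$wavelength_nm), ]
    emission_spectrum(d$intensity, sample_id = d$sample_id[1L],
                      tissue_mass_mg = d$tissue_mass_mg[1L])
  })
}

#' Write / read a reference library as CSV
#'
#' Wide format: `wavelength_nm` plus one column per named component.
#'
#' @param refs A `reference_library`.
#' @param path CSV path.
#' @return `read_reference_csv()` returns a `reference_library`.
#' @export
write_reference_csv <- function(refs, path) {
  stopifnot(inherits(refs, "reference_library"))
  df <- data.frame(wavelength_nm = qd_wavelengths(), unclass(refs))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_csv
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$wavelength_nm), ]
  reference_library(as.matrix(df[setdiff(names(df), "wavelength_nm")]))
}

#' Write / read a raster stack as multi-page TIFF + JSON sidecar
#'
#' Intensities are rescaled to [0, 1] for 32-bit float TIFF storage; the
#' scale factor and scan geometry live in `<path>.json`.
#'
#' @param stack A `raster_stack`.
#' @param path TIFF path (`.tif`).
#' @return `read_raster_tiff()` returns a `raster_stack`.
#' @export
write_raster_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "raster_stack"))
  lo <- min(stack$frames)
  hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(stack$frames)[3L]), function(t) {
    (stack$frames[, , t] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_nm = stack$pixel_size_nm,
               dwell_time_us = stack$dwell_time_us,
               line_time_ms = stack$line_time_ms,
               beam_waist_um = stack$beam_waist_um,
               axial_ratio = stack$axial_ratio,
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_raster_tiff
#' @export
read_raster_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) {
    frames[, , t] <- pages[[t]] * meta$intensity_scale + meta$intensity_offset
  }
  raster_stack(frames, pixel_size_nm = meta$pixel_size_nm,
               dwell_time_us = meta$dwell_time_us,
               line_time_ms = meta$line_time_ms,
               beam_waist_um = meta$beam_waist_um,
               axial_ratio = meta$axial_ratio)
}

#' Write / read plate tables as CSV
#'
#' @param plates Validated plate table.
#' @param path CSV path.
#' @return `read_plates_csv()` returns a validated plate table.
#' @export
write_plates_csv <- function(plates, path) {
  utils::write.csv(validate_plates(plates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plates_csv
#' @export
read_plates_csv <- function(path) {
  validate_plates(utils::read.csv(path))
}

#' Write a speed-mixture fit as JSON
#'
#' @param fit A `speed_mixture_fit`.
#' @param path JSON path.
#' @export
write_mixture_json <- function(fit, path) {
  stopifnot(inherits(fit, "speed_mixture_fit"))
  jsonlite::write_json(
    list(k = fit$k, n = fit$n, weights = fit$weights, means = fit$means,
         sds = fit$sds, loglik = fit$loglik, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
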