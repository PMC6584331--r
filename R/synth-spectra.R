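#' Configuration for the spectra simulator
#'
#' Defines the shapes used to synthesise plate-reader emission scans: two
#' quantum-dot peaks (Gaussian, centered at the 488 nm cyan and 666 nm red
#' emission lines), a broad log-normal-shaped tissue autofluorescence curve,
#' a flat buffer background level, and an optional noise model. Unmixing is
#' shape-agnostic, so any smooth positive shapes serve; these defaults mimic
#' the real system's geometry.
#'
#' @param peak_center_cyan,peak_center_red Peak centers (nm); must lie inside
#'   the 450-800 nm grid.
#' @param peak_sd_nm Gaussian width (sd, nm) of both QD peaks.
#' @param auto_meanlog,auto_sdlog Log-normal shape parameters of the
#'   autofluorescence curve (on the wavelength axis, relative to 450 nm).
#' @param background_level Constant buffer background (photon counts).
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise sd (counts); ignored otherwise.
#' @return A `spectra_sim_config`.
#' @export
spectra_sim_config <- function(peak_center_cyan = 488, peak_center_red = 666,
                               peak_sd_nm = 15,
                               auto_meanlog = log(120), auto_sdlog = 0.55,
                               background_level = 0,
                               noise = c("none", "gaussian", "poisson"),
                               noise_sd = 0) {
  noise <- match.arg(noise)
  grid <- qd_wavelengths()
  for (ctr in c(peak_center_cyan, peak_center_red)) {
    if (ctr < min(grid) || ctr > max(grid)) {
      stop("peak center ", ctr, " nm lies outside the 450-800 nm grid")
    }
  }
  stopifnot(peak_sd_nm > 0, background_level >= 0, noise_sd >= 0)
  structure(
    list(peak_center_cyan = peak_center_cyan,
         peak_center_red = peak_center_red,
         peak_sd_nm = peak_sd_nm,
         auto_meanlog = auto_meanlog, auto_sdlog = auto_sdlog,
         background_level = background_level,
         noise = noise, noise_sd = noise_sd),
    class = "spectra_sim_config"
  )
}

#' Reference library implied by a simulator configuration
#'
#' @param config A [spectra_sim_config()].
#' @return `reference_library` with components `cyan`, `red`,
#'   `autofluorescence` (each scaled to unit peak height).
#' @export
simulated_reference_library <- function(config = spectra_sim_config()) {
  grid <- qd_wavelengths()
  gauss <- function(ctr) exp(-(grid - ctr)^2 / (2 * config$peak_sd_nm^2))
  auto <- stats::dlnorm(grid - min(grid) + 1, config$auto_meanlog,
                        config$auto_sdlog)
  reference_library(cyan = gauss(config$peak_center_cyan),
                    red = gauss(config$peak_center_red),
                    autofluorescence = auto / max(auto))
}

#' Simulate mixed emission spectra with known ground truth
#'
#' Each replicate spectrum is the linear combination
#' `sum(coefficients * reference) + background + noise`, so a noiseless
#' simulation followed by background subtraction and unmixing must recover
#' the coefficients exactly.
#'
#' @param config A [spectra_sim_config()].
#' @param true_coefficients Nonnegative numeric length-3 vector
#'   (cyan, red, autofluorescence).
#' @param n_replicates Number of replicate spectra.
#' @param tissue_mass_mg Dry mass attached to each spectrum.
#' @param seed Optional integer seed.
#' @return List with `spectra` (list of `emission_spectrum`), `refs`
#'   (`reference_library`), `background` (`emission_spectrum`) and `truth`
#'   (the coefficients and config).
#' @export
simulate_spectra <- function(config = spectra_sim_config(),
                             true_coefficients, n_replicates = 1L,
                             tissue_mass_mg = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(true_coefficients) != 3L) {
    stop("true_coefficients must have length 3 (cyan, red, autofluorescence)")
  }
  if (any(true_coefficients < 0)) {
    stop("true_coefficients must be nonnegative (physical abundances)")
  }
  refs <- simulated_reference_library(config)
  clean <- as.numeric(unclass(refs) %*% true_coefficients) +
    config$background_level
  spectra <- lapply(seq_len(n_replicates), function(i) {
    y <- switch(config$noise,
                none = clean,
                gaussian = clean + stats::rnorm(length(clean),
                                                sd = config$noise_sd),
                poisson = stats::rpois(length(clean), pmax(clean, 0)))
    emission_spectrum(pmax(y, 0), sample_id = sprintf("sim_%03d", i),
                      tissue_mass_mg = tissue_mass_mg)
  })
  background <- emission_spectrum(
    rep(config$background_level, length(qd_wavelengths())),
    sample_id = "buffer_background")
  list(spectra = spectra, refs = refs, background = background,
       truth = list(coefficients = stats::setNames(
                      as.numeric(true_coefficients),
                      c("cyan", "red", "autofluorescence")),
                    config = config))
}
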