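## Raster image correlation spectroscopy (RICS): spatial autocorrelation of
## raster-scanned confocal stacks. The zero-lag amplitude is inversely
## proportional to the mean number of fluorescent particles in the
## observation volume, which is how QD-apatite retention inside hyphae is
## counted without resolving individual particles.

#' Gamma factor for a 3D Gaussian observation profile
#'
#' For a detection profile `exp(-2 r^2/w0^2 - 2 z^2/wz^2)` the amplitude of
#' the normalised intensity autocorrelation is `gamma / N`, with
#' `gamma = 2^(-3/2) ~ 0.3536` and `N` the mean particle count in the
#' effective observation volume (the integral of the profile,
#' `(pi/2)^(3/2) w0^2 wz`).
#'
#' @export
RICS_GAMMA_3D <- 2^(-3 / 2)

#' Construct a raster-scanned image stack
#'
#' @param frames Numeric array `height x width x n_frames`.
#' @param pixel_size_nm Pixel size (nm; default 16).
#' @param dwell_time_us Pixel dwell time (us; default 20).
#' @param line_time_ms Raster line time (ms; default 1.248).
#' @param beam_waist_um Lateral 1/e^2 beam waist `w0` (um; default 0.250).
#' @param axial_ratio Axial-to-lateral waist ratio `wz / w0` (default 3).
#' @return A `raster_stack`.
#' @export
raster_stack <- function(frames, pixel_size_nm = 16, dwell_time_us = 20,
                         line_time_ms = 1.248, beam_waist_um = 0.250,
                         axial_ratio = 3) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  geom <- c(pixel_size_nm = pixel_size_nm, dwell_time_us = dwell_time_us,
            line_time_ms = line_time_ms, beam_waist_um = beam_waist_um,
            axial_ratio = axial_ratio)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("all scan geometry fields must be positive; got: ",
         paste(names(geom)[geom <= 0 | !is.finite(geom)], collapse = ", "))
  }
  if (dim(frames)[3L] < 5L) {
    stop("need at least 5 frames (moving-average subtraction)")
  }
  structure(
    list(frames = frames, pixel_size_nm = pixel_size_nm,
         dwell_time_us = dwell_time_us, line_time_ms = line_time_ms,
         beam_waist_um = beam_waist_um, axial_ratio = axial_ratio),
    class = "raster_stack"
  )
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<raster_stack> %d x %d px, %d frames\n", d[2L], d[1L], d[3L]))
  cat(sprintf("  pixel %g nm, dwell %g us, line %g ms, waist %g um (wz/w0 = %g)\n",
              x$pixel_size_nm, x$dwell_time_us, x$line_time_ms,
              x$beam_waist_um, x$axial_ratio))
  invisible(x)
}

#' Moving-average subtraction of slow structures
#'
#' Subtracts from each frame the local temporal moving average (default 4
#' frames, current frame included) and restores the grand mean, removing
#' static background and non-moving hyphal autofluorescence while keeping
#' the fluctuations of mobile particles. For temporally independent
#' fluctuations the subtraction deflates the fluctuation variance by
#' `(w-1)/w`; the compensating factor `w/(w-1)` is attached as the attribute
#' `"var_correction"` and applied by [rics_autocorrelation()].
#'
#' @param stack A `raster_stack`.
#' @param window Frames in the moving average (default 4; must be < n_frames
#'   and >= 2).
#' @return Detrended `raster_stack` (attribute `var_correction` set).
#' @export
moving_average_subtract <- function(stack, window = 4L) {
  stopifnot(inherits(stack, "raster_stack"))
  window <- as.integer(window)
  nf <- dim(stack$frames)[3L]
  if (window < 2L) stop("window must be >= 2 frames")
  if (window >= nf) stop("window (", window, ") must be < n_frames (", nf, ")")
  lo_off <- floor((window - 1) / 2)
  hi_off <- ceiling((window - 1) / 2)
  grand <- mean(stack$frames)
  out <- stack$frames
  eff <- numeric(nf)
  for (t in seq_len(nf)) {
    idx <- max(1L, t - lo_off):min(nf, t + hi_off)
    eff[t] <- length(idx)
    ma <- Reduce(`+`, lapply(idx, function(i) stack$frames[, , i])) /
      length(idx)
    out[, , t] <- stack$frames[, , t] - ma + grand
  }
  res <- stack
  res$frames <- out
  attr(res, "var_correction") <- mean(eff / pmax(eff - 1, 1))
  res
}

#' RICS spatial autocorrelation surface
#'
#' Computes `G(xi, psi) = <dI(x, y) dI(x + xi, y + psi)> / <I>^2` per frame
#' (FFT-based, periodic boundaries) and averages over frames. If the stack
#' carries a `var_correction` attribute from [moving_average_subtract()], the
#' amplitude deflation of the detrending is compensated.
#'
#' @param stack Detrended `raster_stack`.
#' @param max_lag Maximum spatial lag (pixels) retained in each direction.
#' @return A `rics_estimate` with `acf` (`(2 max_lag + 1)^2` matrix, lag 0 at
#'   the center, dimnames = lags), `amplitude` (`G(0,0)`), `mean_intensity`
#'   and the stack geometry.
#' @export
rics_autocorrelation <- function(stack, max_lag = 16L) {
  stopifnot(inherits(stack, "raster_stack"))
  fr <- stack$frames
  d <- dim(fr)
  H <- d[1L]; W <- d[2L]; nf <- d[3L]
  max_lag <- as.integer(max_lag)
  stopifnot(max_lag >= 0L, max_lag < H / 2, max_lag < W / 2)
  if (mean(fr) <= 0) stop("empty field: mean intensity is not positive")
  acc <- matrix(0, H, W)
  for (t in seq_len(nf)) {
    img <- fr[, , t]
    mu <- mean(img)
    if (mu <= 0) stop("frame ", t, " has non-positive mean intensity")
    dimg <- img - mu
    ft <- stats::fft(dimg)
    corr <- Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / (H * W)
    acc <- acc + corr / (H * W) / mu^2
  }
  G <- acc / nf
  vc <- attr(stack, "var_correction")
  if (!is.null(vc)) G <- G * vc
  lags <- -max_lag:max_lag
  wrap <- function(l, n) ifelse(l >= 0, l + 1L, n + l + 1L)
  sub <- G[wrap(lags, H), wrap(lags, W)]
  dimnames(sub) <- list(psi = lags, xi = lags)
  structure(
    list(acf = sub,
         amplitude = sub[max_lag + 1L, max_lag + 1L],
         mean_intensity = mean(fr),
         beam_waist_um = stack$beam_waist_um,
         axial_ratio = stack$axial_ratio,
         n_frames = nf),
    class = "rics_estimate"
  )
}

#' @export
print.rics_estimate <- function(x, ...) {
  cat("<rics_estimate>\n")
  cat(sprintf("  zero-lag amplitude G(0,0) = %.5g over %d frames\n",
              x$amplitude, x$n_frames))
  invisible(x)
}

#' Particle number and density from a RICS amplitude
#'
#' Inverts the amplitude relation `G(0,0) = gamma / N`: the mean number of
#' particles in the effective observation volume is `N = gamma / G(0,0)`.
#' The effective volume is the integral of the 3D Gaussian detection profile,
#' `V_eff = (pi/2)^(3/2) w0^2 wz = gamma * pi^(3/2) w0^2 wz`, so
#' `density = N / V_eff` recovers the true concentration. Both `V_eff` and
#' the conventional `V_obs = pi^(3/2) w0^2 wz` are reported.
#'
#' @param estimate A `rics_estimate`.
#' @param gamma Profile shape factor (default [RICS_GAMMA_3D]).
#' @param beam_waist_um,axial_ratio Override the geometry carried by the
#'   estimate.
#' @return List with `n_particles`, `density_um3`, `v_eff_um3`, `v_obs_um3`,
#'   `amplitude` and `estimable` (FALSE, with NA results, when the amplitude
#'   is not positive).
#' @export
estimate_particle_number <- function(estimate, gamma = RICS_GAMMA_3D,
                                     beam_waist_um = NULL,
                                     axial_ratio = NULL) {
  stopifnot(inherits(estimate, "rics_estimate"))
  w0 <- if (is.null(beam_waist_um)) estimate$beam_waist_um else beam_waist_um
  ar <- if (is.null(axial_ratio)) estimate$axial_ratio else axial_ratio
  wz <- ar * w0
  v_obs <- pi^(3 / 2) * w0^2 * wz
  v_eff <- gamma * v_obs
  if (!is.finite(estimate$amplitude) || estimate$amplitude <= 0) {
    return(list(n_particles = NA_real_, density_um3 = NA_real_,
                v_eff_um3 = v_eff, v_obs_um3 = v_obs,
                amplitude = estimate$amplitude, estimable = FALSE))
  }
  n <- gamma / estimate$amplitude
  list(n_particles = n, density_um3 = n / v_eff,
       v_eff_um3 = v_eff, v_obs_um3 = v_obs,
       amplitude = estimate$amplitude, estimable = TRUE)
}

#' Convert particle density to QD-apatite retention
#'
#' Scales a particle concentration inside hyphae up to the whole hyphal
#' compartment: dry biomass is converted to fresh volume using a fresh
#' hyphal density of 1.1 g/cm^3 and a 60% water weight content, multiplied
#' by the particle density, and converted from particles to nmol via the
#' Avogadro constant.
#'
#' @param density_um3 Particle density (particles / um^3 hypha).
#' @param biomass_dry_mg Dry hyphal biomass (mg), >= 0.
#' @param fresh_density_g_cm3 Fresh hyphal density (default 1.1).
#' @param water_fraction Water weight fraction of fresh hyphae (default 0.60;
#'   must be in [0, 1)).
#' @return List with `nmol_total`, `nmol_per_mg`, `fresh_volume_um3` and
#'   `particles_total`.
#' @export
retention <- function(density_um3, biomass_dry_mg,
                      fresh_density_g_cm3 = 1.1, water_fraction = 0.60) {
  stopifnot(density_um3 >= 0, biomass_dry_mg >= 0, fresh_density_g_cm3 > 0)
  if (water_fraction < 0 || water_fraction >= 1) {
    stop("water_fraction must be in [0, 1)")
  }
  avogadro <- 6.02214076e23
  fresh_mg <- biomass_dry_mg / (1 - water_fraction)
  vol_cm3 <- fresh_mg / 1000 / fresh_density_g_cm3
  vol_um3 <- vol_cm3 * 1e12
  particles <- density_um3 * vol_um3
  nmol <- particles / avogadro * 1e9
  list(nmol_total = nmol,
       nmol_per_mg = if (biomass_dry_mg > 0) nmol / biomass_dry_mg else 0,
       fresh_volume_um3 = vol_um3,
       particles_total = particles)
}

#' Percent vacuole area within the hyphal mask
#'
#' Storage structures (vacuoles) appear as distinct low-intensity regions in
#' white-light images of hyphae. Pixels inside the hyphal mask falling below
#' the threshold are counted as vacuole; the result is
#' `100 * vacuole pixels / hyphal pixels`. With `threshold = "otsu"` the
#' threshold is chosen by Otsu's method on the masked intensities.
#'
#' @param image Numeric matrix (grayscale field).
#' @param hyphal_mask Logical matrix of the same dimension; must contain at
#'   least one `TRUE` pixel.
#' @param threshold Numeric intensity cutoff, or `"otsu"` (default).
#' @return List with `percent`, `threshold`, `n_vacuole`, `n_hyphae`.
#' @export
vacuole_fraction <- function(image, hyphal_mask, threshold = "otsu") {
  stopifnot(is.matrix(image), is.logical(hyphal_mask),
            identical(dim(image), dim(hyphal_mask)))
  n_hyphae <- sum(hyphal_mask)
  if (n_hyphae == 0) stop("empty hyphal mask")
  vals <- image[hyphal_mask]
  if (identical(threshold, "otsu")) {
    rng <- range(vals)
    if (diff(rng) == 0) {
      thr <- rng[1L]  # constant field: nothing below threshold
    } else {
      scaled <- (vals - rng[1L]) / diff(rng)
      thr01 <- EBImage::otsu(matrix(scaled, nrow = 1L), range = c(0, 1))
      thr <- rng[1L] + thr01 * diff(rng)
    }
  } else {
    thr <- as.numeric(threshold)
  }
  n_vac <- sum(vals < thr)
  list(percent = 100 * n_vac / n_hyphae, threshold = thr,
       n_vacuole = n_vac, n_hyphae = n_hyphae)
}
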