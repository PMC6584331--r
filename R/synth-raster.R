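## Synthetic raster-scanned confocal stacks of diffusing / flowing point
## particles, for validating the RICS estimators against known ground truth.

#' Total particle count needed for a target occupancy
#'
#' Converts a desired mean number of particles in the effective observation
#' volume into the total number to place in the simulated (periodic) box.
#'
#' @param n_in_volume Target mean particles in `V_eff = (pi/2)^(3/2) w0^2 wz`.
#' @param width,height Field size in pixels.
#' @param pixel_size_nm,beam_waist_um,axial_ratio Scan geometry.
#' @param z_extent_waists Axial box half-extent in units of `wz` (default 3).
#' @return Integer particle count (at least 1).
#' @export
raster_particles_for_occupancy <- function(n_in_volume, width = 256L,
                                           height = 256L, pixel_size_nm = 16,
                                           beam_waist_um = 0.250,
                                           axial_ratio = 3,
                                           z_extent_waists = 3) {
  px_um <- pixel_size_nm / 1000
  wz <- axial_ratio * beam_waist_um
  v_eff <- (pi / 2)^(3 / 2) * beam_waist_um^2 * wz
  v_box <- (width * px_um) * (height * px_um) * (2 * z_extent_waists * wz)
  max(1L, as.integer(round(n_in_volume * v_box / v_eff)))
}

#' Simulate a raster-scanned stack of diffusing / flowing particles
#'
#' Particles are placed uniformly in a periodic box spanning the field
#' laterally and `2 * z_extent_waists * wz` axially. Each particle carries a
#' fixed axial detection weight `exp(-2 z^2 / wz^2)` and moves laterally by
#' Brownian steps (coefficient `D`) plus a constant drift `flow` along x.
#' The raster scan is emulated at row-block resolution: positions advance
#' every `lines_per_update` scan lines and each block of rows is imaged
#' through the lateral Gaussian point-spread function of waist `w0`
#' (FFT convolution, periodic boundaries). Over the study's range of
#' diffusion coefficients a particle moves well under a pixel during one
#' line, so finer-than-block dynamics would not change the images
#' measurably, and the zero-lag amplitude used for particle counting is
#' independent of intra-frame motion altogether.
#'
#' @param n_particles Total particles in the box (>= 1); see
#'   [raster_particles_for_occupancy()].
#' @param D Diffusion coefficient (um^2/s).
#' @param flow Drift speed along x (um/s).
#' @param width,height,n_frames Stack dimensions (default 256 x 256 x 40).
#' @param pixel_size_nm,dwell_time_us,line_time_ms,beam_waist_um,axial_ratio
#'   Scan geometry (defaults 16 nm, 20 us, 1.248 ms, 0.250 um, 3).
#' @param lines_per_update Scan lines between particle-position updates.
#' @param z_extent_waists Axial half-extent of the box in units of `wz`.
#' @param background Constant offset added to every pixel.
#' @param noise_sd Additive Gaussian noise sd (default 0; note shot noise
#'   biases the zero-lag amplitude upward).
#' @param seed Optional integer seed.
#' @return List with `stack` (a [raster_stack()]) and `truth`
#'   (`n_particles`, `n_in_volume` -- mean count in `V_eff`, `density_um3`,
#'   `D`, `flow`).
#' @export
simulate_raster_stack <- function(n_particles, D = 0, flow = 0,
                                  width = 256L, height = 256L,
                                  n_frames = 40L,
                                  pixel_size_nm = 16, dwell_time_us = 20,
                                  line_time_ms = 1.248,
                                  beam_waist_um = 0.250, axial_ratio = 3,
                                  lines_per_update = 32L,
                                  z_extent_waists = 3,
                                  background = 0, noise_sd = 0,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_particles < 1) stop("n_particles must be >= 1")
  geom <- c(pixel_size_nm, dwell_time_us, line_time_ms, beam_waist_um,
            axial_ratio)
  if (any(!is.finite(geom)) || any(geom <= 0)) {
    stop("degenerate scan geometry: all geometry fields must be positive")
  }
  stopifnot(D >= 0, n_frames >= 5, lines_per_update >= 1)
  px <- pixel_size_nm / 1000                       # um / pixel
  Lx <- width * px
  Ly <- height * px
  wz <- axial_ratio * beam_waist_um
  Lz <- 2 * z_extent_waists * wz
  np <- as.integer(n_particles)

  x <- stats::runif(np, 0, Lx)
  y <- stats::runif(np, 0, Ly)
  z <- stats::runif(np, -Lz / 2, Lz / 2)
  q <- exp(-2 * z^2 / wz^2)                        # static axial weight

  ## wrapped lateral PSF kernel and its FFT
  dx <- pmin(0:(width - 1), width - 0:(width - 1)) * px
  dy <- pmin(0:(height - 1), height - 0:(height - 1)) * px
  kern <- exp(-2 * outer(dy^2, dx^2, `+`) / beam_waist_um^2)
  fk <- stats::fft(kern)

  blocks <- split(seq_len(height),
                  ceiling(seq_len(height) / lines_per_update))
  dt_block <- lines_per_update * line_time_ms / 1000
  sd_step <- sqrt(2 * D * dt_block)

  frames <- array(0, dim = c(height, width, n_frames))
  for (f in seq_len(n_frames)) {
    for (b in seq_along(blocks)) {
      if (f > 1 || b > 1) {                        # advance positions
        if (sd_step > 0) {
          x <- x + stats::rnorm(np, sd = sd_step)
          y <- y + stats::rnorm(np, sd = sd_step)
        }
        if (flow != 0) x <- x + flow * dt_block
        x <- x %% Lx
        y <- y %% Ly
      }
      ix <- pmin(pmax(floor(x / px), 0), width - 1)
      iy <- pmin(pmax(floor(y / px), 0), height - 1)
      idx <- iy + height * ix + 1
      dep <- numeric(height * width)
      agg <- rowsum(q, group = idx)
      dep[as.integer(rownames(agg))] <- agg
      img <- Re(stats::fft(stats::fft(matrix(dep, height, width)) * fk,
                           inverse = TRUE)) / (height * width)
      rows <- blocks[[b]]
      frames[rows, , f] <- img[rows, ]
    }
  }
  frames <- frames + background
  if (noise_sd > 0) {
    frames <- frames + array(stats::rnorm(length(frames), sd = noise_sd),
                             dim = dim(frames))
  }
  v_eff <- (pi / 2)^(3 / 2) * beam_waist_um^2 * wz
  dens <- np / (Lx * Ly * Lz)
  list(stack = raster_stack(frames, pixel_size_nm, dwell_time_us,
                            line_time_ms, beam_waist_um, axial_ratio),
       truth = list(n_particles = np,
                    n_in_volume = dens * v_eff,
                    density_um3 = dens,
                    D = D, flow = flow))
}
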