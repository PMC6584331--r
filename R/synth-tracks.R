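#' Configuration for the intra-hyphal track simulator
#'
#' Emulates cytoplasmic streaming of traceable cellular contents along a
#' hypha: each particle draws its speed from a three-component zero-truncated
#' normal mixture, moves along the hyphal axis (x), and reverses direction as
#' a constant-hazard (telegraph) process, mirroring the oscillatory flows
#' that reverse on the order of seconds. Optional Brownian jitter is added on
#' top of the directed motion.
#'
#' @param n_tracks Number of particles.
#' @param frame_rate_hz Acquisition rate (default 10 Hz).
#' @param n_frames Frames per movie (default 200).
#' @param speed_weights,speed_means,speed_sds Mixture parameters
#'   (weights sum to 1, means > 0, um/s). Defaults use the low/intermediate/
#'   high-mobility centers 5, 20 and 30 um/s.
#' @param reversal_rate_hz Telegraph switching rate of flow direction
#'   (1/s, default 0.2 -- reversals on the order of seconds).
#' @param diffusion_um2_s Brownian jitter diffusion coefficient (um^2/s).
#' @param pixel_size_um Pixel size of the rendered movie (um).
#' @param seed Optional integer seed.
#' @return A `track_sim_config`.
#' @export
track_sim_config <- function(n_tracks = 60L, frame_rate_hz = 10,
                             n_frames = 200L,
                             speed_weights = c(0.35, 0.40, 0.25),
                             speed_means = c(5, 20, 30),
                             speed_sds = c(2, 5, 8),
                             reversal_rate_hz = 0.2,
                             diffusion_um2_s = 0,
                             pixel_size_um = 0.4,
                             seed = NULL) {
  stopifnot(length(speed_weights) == length(speed_means),
            length(speed_means) == length(speed_sds))
  if (abs(sum(speed_weights) - 1) > 1e-8) stop("speed_weights must sum to 1")
  if (any(speed_means <= 0)) stop("speed means must be > 0")
  if (any(speed_sds <= 0)) stop("speed sds must be > 0")
  if (reversal_rate_hz < 0) stop("reversal_rate_hz must be >= 0")
  stopifnot(n_tracks >= 1, n_frames >= 2, frame_rate_hz > 0,
            pixel_size_um > 0, diffusion_um2_s >= 0)
  structure(as.list(environment()), class = "track_sim_config")
}

#' Simulate particle tracks along hyphae with known ground truth
#'
#' @param config A [track_sim_config()].
#' @return List with `tracks` (data.frame: `track_id`, `frame`, `x`, `y`, in
#'   pixels) and `truth` (per-track mixture `component`, `speed_um_s`,
#'   initial `direction`, and the config).
#' @export
simulate_tracks <- function(config = track_sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  nt <- config$n_tracks
  nf <- config$n_frames
  dt <- 1 / config$frame_rate_hz
  px <- config$pixel_size_um
  comp <- sample.int(length(config$speed_weights), nt, replace = TRUE,
                     prob = config$speed_weights)
  speed <- rtnorm0(nt, config$speed_means[comp], config$speed_sds[comp])
  dir0 <- sample(c(-1, 1), nt, replace = TRUE)
  p_flip <- 1 - exp(-config$reversal_rate_hz * dt)
  sd_jit <- sqrt(2 * config$diffusion_um2_s * dt) / px

  ## extent of the field in x scales with the largest excursion possible
  span_px <- max(speed) * dt * nf / px
  x0 <- stats::runif(nt, 0, span_px)
  y0 <- stats::runif(nt, 5, 60)

  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    dirs <- numeric(nf - 1)
    d <- dir0[i]
    for (s in seq_len(nf - 1)) {
      dirs[s] <- d
      if (p_flip > 0 && stats::runif(1) < p_flip) d <- -d
    }
    step_x <- dirs * speed[i] * dt / px
    if (sd_jit > 0) {
      step_x <- step_x + stats::rnorm(nf - 1, sd = sd_jit)
      step_y <- stats::rnorm(nf - 1, sd = sd_jit)
    } else {
      step_y <- numeric(nf - 1)
    }
    out[[i]] <- data.frame(track_id = i, frame = seq_len(nf),
                           x = x0[i] + c(0, cumsum(step_x)),
                           y = y0[i] + c(0, cumsum(step_y)))
  }
  list(tracks = do.call(rbind, out),
       truth = list(component = comp, speed_um_s = speed, direction0 = dir0,
                    config = config))
}

#' Render tracks as a synthetic movie of Gaussian spots
#'
#' Produces an image stack suitable for the full tracking pipeline
#' ([track_preprocess()], [track_detect()], [track_link()]), with one
#' Gaussian spot per particle per frame.
#'
#' @param tracks Track data.frame (`track_id`, `frame`, `x`, `y`, pixels).
#' @param width,height Movie dimensions (pixels); defaults enclose the
#'   tracks with a margin.
#' @param spot_sigma_px Gaussian spot sd in pixels (default 2.5, a ~10 px
#'   object).
#' @param amplitude Peak spot intensity.
#' @param background Constant background level.
#' @param noise_sd Additive Gaussian noise sd.
#' @return Numeric array `height x width x n_frames`.
#' @export
render_track_movie <- function(tracks, width = NULL, height = NULL,
                               spot_sigma_px = 2.5, amplitude = 100,
                               background = 10, noise_sd = 0) {
  nf <- max(tracks$frame)
  if (is.null(width)) width <- ceiling(max(tracks$x) + 15)
  if (is.null(height)) height <- ceiling(max(tracks$y) + 15)
  movie <- array(background, dim = c(height, width, nf))
  half <- ceiling(4 * spot_sigma_px)
  for (r in seq_len(nrow(tracks))) {
    cx <- tracks$x[r]
    cy <- tracks$y[r]
    f <- tracks$frame[r]
    x_lo <- max(1, floor(cx - half)); x_hi <- min(width, ceiling(cx + half))
    y_lo <- max(1, floor(cy - half)); y_hi <- min(height, ceiling(cy + half))
    if (x_hi < x_lo || y_hi < y_lo) next   # spot entirely outside the field
    ix <- x_lo:x_hi
    iy <- y_lo:y_hi
    gx <- exp(-(ix - cx)^2 / (2 * spot_sigma_px^2))
    gy <- exp(-(iy - cy)^2 / (2 * spot_sigma_px^2))
    movie[iy, ix, f] <- movie[iy, ix, f] + amplitude * outer(gy, gx)
  }
  if (noise_sd > 0) {
    movie <- movie + array(stats::rnorm(length(movie), sd = noise_sd),
                           dim = dim(movie))
  }
  movie
}
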