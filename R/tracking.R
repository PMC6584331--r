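## Single-particle tracking of cellular contents streaming inside hyphae:
## FFT bandpass + minimum-projection preprocessing, Laplacian-of-Gaussian
## spot detection, constant-velocity linking, the study's track filters, and
## directional per-step speeds.

## FFT transfer function of an isotropic Gaussian blur with sd sigma (px)
gaussian_transfer <- function(height, width, sigma) {
  fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  if (height %% 2 == 0) fy <- c(0:(height / 2 - 1), -(height / 2):-1) / height
  if (width %% 2 == 0) fx <- c(0:(width / 2 - 1), -(width / 2):-1) / width
  exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
}

fft_filter <- function(img, transfer) {
  Re(stats::fft(stats::fft(img) * transfer, inverse = TRUE)) / length(img)
}

#' Bandpass and background preprocessing of a hyphal movie
#'
#' Per frame, applies a frequency-domain bandpass (difference of Gaussians)
#' that removes structures larger than `large_px` and smooths features
#' smaller than `small_px`; then subtracts the minimum projection across
#' frames as a background reference and floors intensities at zero.
#'
#' @param movie Numeric array `height x width x n_frames` (>= 2 frames).
#' @param small_px,large_px Bandpass size cutoffs (default 3 and 40 px).
#' @return Filtered array of the same dimensions.
#' @export
track_preprocess <- function(movie, small_px = 3, large_px = 40) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  d <- dim(movie)
  if (d[3L] < 2L) stop("movie must have at least 2 frames")
  stopifnot(small_px > 0, large_px > small_px)
  hs <- gaussian_transfer(d[1L], d[2L], small_px / 2)
  hl <- gaussian_transfer(d[1L], d[2L], large_px / 2)
  band <- hs - hl
  out <- array(0, dim = d)
  for (t in seq_len(d[3L])) out[, , t] <- fft_filter(movie[, , t], band)
  bg <- apply(out, c(1L, 2L), min)   # minimum projection as background
  for (t in seq_len(d[3L])) out[, , t] <- pmax(out[, , t] - bg, 0)
  out
}

#' Detect spot centroids in a single frame
#'
#' Laplacian-of-Gaussian blob detection tuned to objects of
#' `object_diameter_px` (scale `sigma = d / (2 sqrt(2))`), followed by
#' 8-neighbour local-maximum selection, an intensity-quantile threshold on
#' the response, and sub-pixel refinement by quadratic interpolation.
#'
#' @param frame Numeric matrix (preprocessed).
#' @param object_diameter_px Expected object size (default 10 px).
#' @param threshold_quantile Quantile of the LoG response image below which
#'   maxima are discarded (default 0.995; spots of the expected size cover
#'   well under 0.5% of a field).
#' @param rel_threshold Maxima must also reach this fraction of the frame's
#'   peak response (default 0.2), suppressing ripple and noise maxima.
#' @return Data frame with `x`, `y` (sub-pixel, column/row) and `score`.
#' @export
track_detect <- function(frame, object_diameter_px = 10,
                         threshold_quantile = 0.995, rel_threshold = 0.2) {
  stopifnot(is.matrix(frame))
  H <- nrow(frame); W <- ncol(frame)
  sigma <- object_diameter_px / (2 * sqrt(2))
  blur <- fft_filter(frame, gaussian_transfer(H, W, sigma))
  ## negated discrete Laplacian of the blurred image, scale-normalised
  lap <- matrix(0, H, W)
  lap[2:(H - 1), 2:(W - 1)] <-
    4 * blur[2:(H - 1), 2:(W - 1)] -
    blur[1:(H - 2), 2:(W - 1)] - blur[3:H, 2:(W - 1)] -
    blur[2:(H - 1), 1:(W - 2)] - blur[2:(H - 1), 3:W]
  resp <- sigma^2 * lap
  min_response <- max(stats::quantile(resp, threshold_quantile),
                      rel_threshold * max(resp), 0)
  ## strict local maxima over the 8-neighbourhood
  ok <- matrix(FALSE, H, W)
  core_i <- 2:(H - 1); core_j <- 2:(W - 1)
  r <- resp[core_i, core_j]
  ok[core_i, core_j] <-
    r > resp[core_i - 1, core_j] & r > resp[core_i + 1, core_j] &
    r > resp[core_i, core_j - 1] & r > resp[core_i, core_j + 1] &
    r > resp[core_i - 1, core_j - 1] & r > resp[core_i - 1, core_j + 1] &
    r > resp[core_i + 1, core_j - 1] & r > resp[core_i + 1, core_j + 1] &
    r > min_response
  if (!any(ok)) {
    return(data.frame(x = numeric(0), y = numeric(0), score = numeric(0)))
  }
  pos <- which(ok, arr.ind = TRUE)
  scores <- resp[ok]
  subpix <- function(a, b, c) {
    den <- a - 2 * b + c
    if (is.finite(den) && den < 0) 0.5 * (a - c) / den else 0
  }
  y <- pos[, 1L] + vapply(seq_len(nrow(pos)), function(i) {
    subpix(resp[pos[i, 1L] - 1L, pos[i, 2L]], resp[pos[i, 1L], pos[i, 2L]],
           resp[pos[i, 1L] + 1L, pos[i, 2L]])
  }, numeric(1))
  x <- pos[, 2L] + vapply(seq_len(nrow(pos)), function(i) {
    subpix(resp[pos[i, 1L], pos[i, 2L] - 1L], resp[pos[i, 1L], pos[i, 2L]],
           resp[pos[i, 1L], pos[i, 2L] + 1L])
  }, numeric(1))
  data.frame(x = x, y = y, score = scores)
}

#' Link per-frame detections into tracks (constant-velocity prediction)
#'
#' Minimal linear-motion linker in the spirit of a Kalman tracker: each open
#' track predicts its next position from its current position plus its last
#' displacement, and is greedily matched (closest pair first) to a detection
#' within `gate_px`. Unmatched detections seed new tracks; unmatched tracks
#' terminate immediately (no gap closing).
#'
#' @param detections Either a list of per-frame data frames (`x`, `y`) or a
#'   single data frame with a `frame` column.
#' @param gate_px Maximum allowed distance between prediction and detection
#'   (default 15 px/frame).
#' @return Data frame with `track_id`, `frame`, `x`, `y`.
#' @export
track_link <- function(detections, gate_px = 15) {
  if (is.data.frame(detections)) {
    stopifnot("frame" %in% names(detections))
    nf <- max(detections$frame)
    detections <- lapply(seq_len(nf), function(f) {
      detections[detections$frame == f, c("x", "y"), drop = FALSE]
    })
  }
  nf <- length(detections)
  if (nf < 2L) stop("need detections for at least 2 frames")
  rows <- list()
  active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                       vx = numeric(0), vy = numeric(0))
  next_id <- 1L
  emit <- function(id, f, x, y) {
    rows[[length(rows) + 1L]] <<- data.frame(track_id = id, frame = f,
                                             x = x, y = y)
  }
  det1 <- detections[[1L]]
  if (nrow(det1)) {
    ids <- next_id:(next_id + nrow(det1) - 1L)
    next_id <- next_id + nrow(det1)
    active <- data.frame(id = ids, x = det1$x, y = det1$y, vx = 0, vy = 0)
    for (i in seq_len(nrow(det1))) emit(ids[i], 1L, det1$x[i], det1$y[i])
  }
  for (f in 2:nf) {
    det <- detections[[f]]
    matched_trk <- rep(FALSE, nrow(active))
    matched_det <- rep(FALSE, nrow(det))
    if (nrow(active) && nrow(det)) {
      px <- active$x + active$vx
      py <- active$y + active$vy
      dmat <- sqrt(outer(px, det$x, `-`)^2 + outer(py, det$y, `-`)^2)
      repeat {
        dmin <- suppressWarnings(min(dmat[!matched_trk, !matched_det,
                                          drop = FALSE]))
        if (!is.finite(dmin) || dmin > gate_px) break
        hit <- which(dmat == dmin & !matched_trk &
                       matrix(rep(!matched_det, each = nrow(dmat)),
                              nrow(dmat)), arr.ind = TRUE)[1, , drop = TRUE]
        ti <- hit[[1L]]; di <- hit[[2L]]
        matched_trk[ti] <- TRUE
        matched_det[di] <- TRUE
        active$vx[ti] <- det$x[di] - active$x[ti]
        active$vy[ti] <- det$y[di] - active$y[ti]
        active$x[ti] <- det$x[di]
        active$y[ti] <- det$y[di]
        emit(active$id[ti], f, det$x[di], det$y[di])
      }
    }
    active <- active[matched_trk, , drop = FALSE]   # terminate unmatched
    if (any(!matched_det)) {
      new <- det[!matched_det, , drop = FALSE]
      ids <- next_id:(next_id + nrow(new) - 1L)
      next_id <- next_id + nrow(new)
      for (i in seq_len(nrow(new))) emit(ids[i], f, new$x[i], new$y[i])
      active <- rbind(active,
                      data.frame(id = ids, x = new$x, y = new$y,
                                 vx = 0, vy = 0))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$track_id, out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the track quality filters
#'
#' Keeps tracks with at least `min_frames` frames (reliable speed
#' estimation) AND an end-to-end displacement of at least
#' `min_displacement_px` (removes immobile objects; the default 10 px is the
#' size of the tracked objects). Both bounds are inclusive, since the
#' exclusion rules are strictly "< 5 frames" and "shorter than 10 px".
#'
#' @param tracks Data frame with `track_id`, `frame`, `x`, `y`.
#' @param min_frames Minimum track length in frames (default 5).
#' @param min_displacement_px Minimum end-to-end distance (default 10).
#' @return Filtered track data frame. Idempotent.
#' @export
filter_tracks <- function(tracks, min_frames = 5L, min_displacement_px = 10) {
  if (!nrow(tracks)) return(tracks)
  keep_ids <- vapply(split(tracks, tracks$track_id), function(tr) {
    if (nrow(tr) < min_frames) return(FALSE)
    tr <- tr[order(tr$frame), ]
    d <- sqrt((tr$x[nrow(tr)] - tr$x[1L])^2 + (tr$y[nrow(tr)] - tr$y[1L])^2)
    d >= min_displacement_px
  }, logical(1))
  out <- tracks[tracks$track_id %in%
                  as.numeric(names(keep_ids)[keep_ids]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-step speeds with direction labels
#'
#' Converts per-step displacements to speeds in um/s and assigns a direction
#' by the sign of the velocity projected onto a reference axis in the lab
#' frame: negative (leftward, toward the host root compartment) vs positive
#' (rightward, away from it). Steps with zero projection have an undefined
#' direction and are flagged (`direction = NA`).
#'
#' @param tracks Filtered track data frame (`track_id`, `frame`, `x`, `y`).
#' @param pixel_size_um Pixel size (um).
#' @param frame_rate_hz Frame rate (Hz).
#' @param axis Reference unit vector (default `c(1, 0)`, +x pointing away
#'   from the root); any nonzero vector is normalised.
#' @return Data frame with `track_id`, `frame`, `speed_um_s`, `direction`
#'   (+1 rightward, -1 leftward, NA undefined).
#' @export
track_speeds <- function(tracks, pixel_size_um, frame_rate_hz,
                         axis = c(1, 0)) {
  stopifnot(pixel_size_um > 0, frame_rate_hz > 0, length(axis) == 2L)
  if (sqrt(sum(axis^2)) == 0) stop("axis must be a nonzero vector")
  axis <- axis / sqrt(sum(axis^2))
  res <- lapply(split(tracks, tracks$track_id), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2L) return(NULL)
    dfr <- diff(tr$frame)
    dx <- diff(tr$x) / dfr
    dy <- diff(tr$y) / dfr
    proj <- dx * axis[1L] + dy * axis[2L]
    data.frame(track_id = tr$track_id[1L], frame = tr$frame[-1L],
               speed_um_s = sqrt(dx^2 + dy^2) * pixel_size_um * frame_rate_hz,
               direction = ifelse(proj > 0, 1, ifelse(proj < 0, -1, NA)))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(track_id = numeric(0), frame = numeric(0),
                      speed_um_s = numeric(0), direction = numeric(0))
  }
  rownames(out) <- NULL
  out
}
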