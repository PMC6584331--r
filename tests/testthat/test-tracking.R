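test_that("preprocessing removes constant background and large structures", {
  const <- array(7, dim = c(64, 64, 4))
  expect_equal(track_preprocess(const), array(0, dim = c(64, 64, 4)),
               tolerance = 1e-9)
  expect_error(track_preprocess(array(1, dim = c(8, 8, 1))), "2 frames")

  # static large blob (> 40 px) is suppressed; a small moving spot survives
  blob <- spot_frame(96, 96, 48, 48, sigma = 30, amp = 50)
  spot_mov <- array(0, dim = c(96, 96, 4))
  for (t in 1:4) {
    spot_mov[, , t] <- blob + spot_frame(96, 96, 20 + 8 * t, 30, sigma = 2.5,
                                         amp = 50)
  }
  out <- track_preprocess(spot_mov)
  blob_only <- array(blob, dim = c(96, 96, 4))
  blob_residual <- track_preprocess(blob_only)
  expect_lt(sum(blob_residual^2), 0.01 * sum(blob^2))
  # the moving spot retains most of its energy relative to a blob-free render
  spot_only <- spot_mov - blob_only
  out_spot <- track_preprocess(spot_only)
  expect_gt(sum(out^2), 0.5 * sum(out_spot^2))
})

test_that("spot detection finds centroids to sub-pixel accuracy", {
  blank <- matrix(0, 64, 64)
  expect_equal(nrow(track_detect(blank)), 0)

  one <- spot_frame(64, 64, 30.4, 22.7)
  d <- track_detect(one)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 30.4), 0.5)
  expect_lt(abs(d$y - 22.7), 0.5)

  two <- spot_frame(64, 64, 15, 32) + spot_frame(64, 64, 45, 32)
  expect_equal(nrow(track_detect(two)), 2)
})

test_that("linking follows linear motion without identity swaps", {
  frames <- lapply(1:10, function(f) data.frame(x = 5 + 3 * (f - 1), y = 20))
  tr <- track_link(frames, gate_px = 10)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(diff(tr$x), rep(3, 9))

  # two parallel non-crossing particles keep their identities
  frames2 <- lapply(1:10, function(f) {
    data.frame(x = c(5 + 3 * (f - 1), 5 + 3 * (f - 1)), y = c(10, 40))
  })
  tr2 <- track_link(frames2, gate_px = 10)
  expect_equal(length(unique(tr2$track_id)), 2)
  ys <- tapply(tr2$y, tr2$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))   # no swap: each track stays on its own y

  # disappearance terminates a track rather than inventing positions
  frames3 <- c(lapply(1:5, function(f) data.frame(x = 5 + 3 * (f - 1), y = 8)),
               lapply(6:10, function(f) data.frame(x = numeric(0),
                                                   y = numeric(0))))
  tr3 <- track_link(frames3, gate_px = 10)
  expect_equal(max(tr3$frame), 5)
  expect_equal(nrow(tr3), 5)
})

test_that("track filters apply the inclusive length and displacement rules", {
  mk <- function(id, n, step) {
    data.frame(track_id = id, frame = seq_len(n),
               x = seq(0, by = step, length.out = n), y = 0)
  }
  short <- mk(1, 4, 5)        # 4 frames: excluded
  still <- data.frame(track_id = 2, frame = 1:20,
                      x = rep(c(0, 3), 10), y = 0)  # end-to-end 3 px
  edge <- mk(3, 5, 2.5)       # 5 frames, end-to-end exactly 10 px: kept
  all_tracks <- rbind(short, still, edge)
  kept <- filter_tracks(all_tracks)
  expect_equal(unique(kept$track_id), 3)
  expect_identical(filter_tracks(kept), kept)   # idempotent
})

test_that("speeds and directions follow the lab-frame projection convention", {
  tr <- data.frame(track_id = 1, frame = 1:2, x = c(10, 8), y = c(5, 5))
  sp <- track_speeds(tr, pixel_size_um = 0.1625, frame_rate_hz = 10)
  expect_equal(sp$speed_um_s, 3.25)
  expect_equal(sp$direction, -1)    # toward the root: leftward

  # orthogonal displacement: direction undefined, speed retained
  tr2 <- data.frame(track_id = 1, frame = 1:2, x = c(10, 10), y = c(5, 9))
  sp2 <- track_speeds(tr2, 0.1625, 10)
  expect_true(is.na(sp2$direction))
  expect_equal(sp2$speed_um_s, 4 * 0.1625 * 10)

  # flipping the axis flips every defined label, speeds unchanged
  sim <- simulate_tracks(track_sim_config(n_tracks = 8, n_frames = 30,
                                          seed = 12))
  a <- track_speeds(sim$tracks, 0.4, 10, axis = c(1, 0))
  b <- track_speeds(sim$tracks, 0.4, 10, axis = c(-1, 0))
  expect_equal(a$speed_um_s, b$speed_um_s)
  expect_equal(a$direction, -b$direction)

  expect_error(track_speeds(tr, 0.1625, 10, axis = c(0, 0)), "nonzero")
})

test_that("EM fits a single zero-truncated component and is monotone", {
  set.seed(5)
  x <- rtnorm0(2000, 10, 2)
  fit <- fit_speed_mixture(x, k = 1, n_restarts = 3)
  se_mean <- 2 / sqrt(2000)
  expect_lt(abs(fit$means - 10), 2 * se_mean * 3)   # generous 2-SE-ish band
  expect_lt(abs(fit$sds - 2), 0.2)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))

  set.seed(6)
  y <- draw_mixture_speeds(1500, c(0.5, 0.5), c(4, 25), c(1.5, 3))
  fit2 <- fit_speed_mixture(y, k = 2, n_restarts = 8)
  expect_equal(sum(fit2$weights), 1, tolerance = 1e-9)
  expect_true(all(diff(fit2$means) > 0))            # ascending order
  expect_lt(abs(fit2$means[1] - 4), 0.3)
  expect_lt(abs(fit2$means[2] - 25), 0.5)
  expect_true(all(diff(fit2$loglik_trace) > -1e-6))

  expect_error(fit_speed_mixture(c(1, -2, 3), k = 1), "positive")
  expect_error(fit_speed_mixture(rtnorm0(10, 5, 1), k = 3), "at least")
})

test_that("the full tracking pipeline recovers simulated motion", {
  cfg <- track_sim_config(n_tracks = 8, n_frames = 40, reversal_rate_hz = 0,
                          diffusion_um2_s = 0, seed = 14)
  sim <- simulate_tracks(cfg)
  movie <- render_track_movie(sim$tracks, noise_sd = 1)
  dets <- lapply(seq_len(dim(movie)[3]), function(f) {
    track_detect(track_preprocess(movie)[, , f])
  })
  linked <- filter_tracks(track_link(dets))
  expect_gte(length(unique(linked$track_id)), 0.9 * cfg$n_tracks)
  sp <- track_speeds(linked, cfg$pixel_size_um, cfg$frame_rate_hz)
  est <- sort(tapply(sp$speed_um_s, sp$track_id, median))
  truth <- sim$truth$speed_um_s
  matched <- vapply(est, function(e) {
    truth[which.min(abs(truth - e))]
  }, numeric(1))
  rmse <- sqrt(mean((est - matched)^2))
  expect_lt(rmse, 0.1 * mean(matched))

  # mirror imaging the movie exchanges the direction labels exactly
  mirrored <- sim$tracks
  mirrored$x <- max(sim$tracks$x) - mirrored$x
  a <- track_speeds(sim$tracks, cfg$pixel_size_um, cfg$frame_rate_hz)
  b <- track_speeds(mirrored, cfg$pixel_size_um, cfg$frame_rate_hz)
  expect_equal(table(a$direction)[["1"]], table(b$direction)[["-1"]])
  expect_equal(table(a$direction)[["-1"]], table(b$direction)[["1"]])
})
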