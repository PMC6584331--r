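# Shared fixtures, built in code at test time.

# Draw n speeds from a zero-truncated normal mixture (component-wise).
draw_mixture_speeds <- function(n, weights, means, sds) {
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  rtnorm0(n, means[comp], sds[comp])
}

# The study's mixture recovery settings: printed low/intermediate/high
# centers with package-chosen sds and weights.
MIX_TRUTH <- list(weights = c(0.35, 0.40, 0.25),
                  means = c(5, 20, 30),
                  sds = c(2, 5, 8))

# A small noiseless plate cohort covering all treatments.
make_plate_cohort <- function(noise = "none", n_plates = 3L, seed = 101L) {
  do.call(rbind, lapply(c("90:10", "70:30", "50:50"), function(tr) {
    simulate_plates(plate_sim_config(treatment = tr, noise = noise,
                                     n_plates = n_plates,
                                     seed = seed))$plates
  }))
}

# One bright Gaussian spot rendered into a frame.
spot_frame <- function(height, width, cx, cy, sigma = 2.5, amp = 100) {
  xs <- seq_len(width); ys <- seq_len(height)
  amp * outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
              exp(-(xs - cx)^2 / (2 * sigma^2)))
}
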