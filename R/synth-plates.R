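#' Configuration for the compartmented-plate simulator
#'
#' Emulates the three-compartment inequality experiment: a fixed total of
#' QD-apatite is injected into the two fungal compartments in the
#' treatment's ratio (cyan marking the rich source unless `color_swap`),
#' taken up by hyphae, translocated between compartments, and partitioned
#' between transfer to the host root and hyphal retention; the remainder
#' stays unrecovered in the medium. Per-plate mass balance is exact:
#' `root + hyphae + unrecovered = injected`.
#'
#' @param treatment `"90:10"`, `"70:30"` or `"50:50"`.
#' @param total_injected_nmol Total QD-apatite injected (default 0.18 nmol).
#' @param uptake_fraction Fraction of injected QD taken up by hyphae in each
#'   compartment (length 1 or `c(rich, poor)`).
#' @param transfer_fraction_rich,transfer_fraction_poor Fraction of a
#'   compartment's hyphal holdings (after translocation) passed on to the
#'   host root.
#' @param transloc_rich_to_poor,transloc_poor_to_rich Fraction of a
#'   compartment's holdings moved to the other compartment before
#'   measurement.
#' @param biomass_mean_mg Mean dry hyphal biomass `c(rich, poor)` (mg).
#' @param biomass_shape Gamma shape of the biomass distribution.
#' @param root_mass_mean_mg,root_mass_shape Dry root mass Gamma model (mg).
#' @param noise `"none"` or `"gamma"`: multiplicative Gamma measurement
#'   noise (mean 1, shape `noise_shape`) on every QD measurement.
#' @param noise_shape Shape of the measurement-noise Gamma.
#' @param n_plates Number of replicate plates (default 30, the study's
#'   replication per treatment).
#' @param color_swap Swap the color-to-source mapping (mirrors the
#'   color-switch control).
#' @param seed Optional integer seed.
#' @return A `plate_sim_config`.
#' @export
plate_sim_config <- function(treatment = "90:10",
                             total_injected_nmol = 0.18,
                             uptake_fraction = 0.6,
                             transfer_fraction_rich = 0.35,
                             transfer_fraction_poor = 0.45,
                             transloc_rich_to_poor = 0.20,
                             transloc_poor_to_rich = 0.05,
                             biomass_mean_mg = c(3, 2),
                             biomass_shape = 10,
                             root_mass_mean_mg = 50,
                             root_mass_shape = 20,
                             noise = c("gamma", "none"),
                             noise_shape = 25,
                             n_plates = 30L,
                             color_swap = FALSE,
                             seed = NULL) {
  noise <- match.arg(noise)
  treatment_split(treatment)  # validates
  uptake_fraction <- rep(uptake_fraction, length.out = 2L)
  fracs <- c(uptake_fraction, transfer_fraction_rich, transfer_fraction_poor,
             transloc_rich_to_poor, transloc_poor_to_rich)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("all fractions must lie in [0, 1]")
  }
  if (transloc_rich_to_poor + 0 > 1 || transloc_poor_to_rich > 1) {
    stop("translocation fractions imply negative remainders")
  }
  stopifnot(total_injected_nmol > 0, n_plates >= 1,
            all(biomass_mean_mg > 0), biomass_shape > 0,
            root_mass_mean_mg > 0, root_mass_shape > 0, noise_shape > 0)
  structure(as.list(environment()), class = "plate_sim_config")
}

## Deterministic QD bookkeeping for one plate; the noise-free expectation.
plate_bookkeeping <- function(config) {
  split <- treatment_split(config$treatment)
  inj <- split * config$total_injected_nmol
  up <- config$uptake_fraction
  taken <- inj * up                          # rich-source in rich, etc.
  unrecovered <- sum(inj) - sum(taken)
  moved_rp <- config$transloc_rich_to_poor * taken[["rich"]]
  moved_pr <- config$transloc_poor_to_rich * taken[["poor"]]
  hold_rich <- c(richsrc = taken[["rich"]] - moved_rp, poorsrc = moved_pr)
  hold_poor <- c(richsrc = moved_rp, poorsrc = taken[["poor"]] - moved_pr)
  f_r <- config$transfer_fraction_rich
  f_p <- config$transfer_fraction_poor
  root <- hold_rich * f_r + hold_poor * f_p
  ret_rich <- hold_rich * (1 - f_r)
  ret_poor <- hold_poor * (1 - f_p)
  list(injected = inj, unrecovered = unrecovered,
       root_from_rich = root[["richsrc"]], root_from_poor = root[["poorsrc"]],
       hyphae_rich = ret_rich, hyphae_poor = ret_poor)
}

#' Simulate compartmented-plate records with known ground truth
#'
#' @param config A [plate_sim_config()].
#' @return List with `plates` (a validated plate table, see
#'   [validate_plates()]) and `truth`: the bookkeeping amounts plus the
#'   noise-free expected values of every downstream trade quantity
#'   (`pct_rich_to_poor`, `pct_poor_to_rich`, `net_movement`,
#'   `share_rich_pct`, `transfer_total_per_mg` at the mean root mass, and
#'   the config).
#' @export
simulate_plates <- function(config = plate_sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  bk <- plate_bookkeeping(config)
  n <- config$n_plates
  gnoise <- function(k) {
    if (config$noise == "none") rep(1, k)
    else stats::rgamma(k, shape = config$noise_shape,
                       rate = config$noise_shape)
  }
  rmass <- function(k, mean, shape) {
    if (config$noise == "none") rep(mean, k)
    else stats::rgamma(k, shape = shape, rate = shape / mean)
  }
  ## measured amounts by color
  swap <- isTRUE(config$color_swap)
  to_color <- function(richsrc, poorsrc) {
    if (swap) list(cyan = poorsrc, red = richsrc)
    else list(cyan = richsrc, red = poorsrc)
  }
  root_col <- to_color(bk$root_from_rich * gnoise(n),
                       bk$root_from_poor * gnoise(n))
  hr_col <- to_color(bk$hyphae_rich[["richsrc"]] * gnoise(n),
                     bk$hyphae_rich[["poorsrc"]] * gnoise(n))
  hp_col <- to_color(bk$hyphae_poor[["richsrc"]] * gnoise(n),
                     bk$hyphae_poor[["poorsrc"]] * gnoise(n))
  plates <- data.frame(
    plate_id = sprintf("plate_%03d", seq_len(n)),
    treatment = config$treatment,
    color_swap = swap,
    injected_rich_nmol = bk$injected[["rich"]],
    injected_poor_nmol = bk$injected[["poor"]],
    root_mass_mg = rmass(n, config$root_mass_mean_mg,
                         config$root_mass_shape),
    root_qd_cyan = root_col$cyan,
    root_qd_red = root_col$red,
    hyphae_rich_qd_cyan = hr_col$cyan,
    hyphae_rich_qd_red = hr_col$red,
    hyphae_rich_biomass_mg = rmass(n, config$biomass_mean_mg[1L],
                                   config$biomass_shape),
    hyphae_poor_qd_cyan = hp_col$cyan,
    hyphae_poor_qd_red = hp_col$red,
    hyphae_poor_biomass_mg = rmass(n, config$biomass_mean_mg[2L],
                                   config$biomass_shape))
  tot_poor <- sum(bk$hyphae_poor)
  tot_rich <- sum(bk$hyphae_rich)
  pct_rp <- if (tot_poor > 0) 100 * bk$hyphae_poor[["richsrc"]] / tot_poor
            else NA_real_
  pct_pr <- if (tot_rich > 0) 100 * bk$hyphae_rich[["poorsrc"]] / tot_rich
            else NA_real_
  root_tot <- bk$root_from_rich + bk$root_from_poor
  truth <- list(
    bookkeeping = bk,
    pct_rich_to_poor = pct_rp,
    pct_poor_to_rich = pct_pr,
    net_movement = pct_rp - pct_pr,
    share_rich_pct = if (root_tot > 0) 100 * bk$root_from_rich / root_tot
                     else NA_real_,
    transfer_total_per_mg = root_tot / config$root_mass_mean_mg,
    exchange_rich = log(config$biomass_mean_mg[1L] / bk$root_from_rich),
    exchange_poor = log(config$biomass_mean_mg[2L] / bk$root_from_poor),
    mass_balance = bk$root_from_rich + bk$root_from_poor +
      sum(bk$hyphae_rich) + sum(bk$hyphae_poor) + bk$unrecovered,
    config = config)
  list(plates = validate_plates(plates), truth = truth)
}
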