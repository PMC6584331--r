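test_that("transfer to root scales with mass and converts to phosphorus", {
  plates <- make_plate_cohort(n_plates = 1)
  tr <- transfer_to_root(plates)
  expect_equal(tr$p_total_per_mg, tr$transfer_total_per_mg * 708)

  # hand-built plate: 0.001 nmol QD in 1 mg root -> 0.708 nmol P / mg
  p <- plates[1, ]
  p$root_mass_mg <- 1
  p$root_qd_cyan <- 0.001
  p$root_qd_red <- 0
  t1 <- transfer_to_root(p)
  expect_equal(t1$transfer_total_per_mg, 0.001)
  expect_equal(t1$p_total_per_mg, 0.708)
  p$root_mass_mg <- 2
  expect_equal(transfer_to_root(p)$transfer_total_per_mg, 0.0005)

  p$root_mass_mg <- 0
  expect_error(transfer_to_root(p), "root_mass")
})

test_that("translocation percentages and net movement follow the bookkeeping", {
  # hand-built: poor hyphae hold 2 nmol rich-color + 8 nmol own color
  base <- make_plate_cohort(n_plates = 1)[1, ]
  base$hyphae_poor_qd_cyan <- 2e-3    # rich source (cyan, no swap)
  base$hyphae_poor_qd_red <- 8e-3
  base$hyphae_rich_qd_cyan <- 9e-3
  base$hyphae_rich_qd_red <- 1e-3
  pc <- translocation_percentages(base)
  expect_equal(pc$pct_rich_to_poor, 20)
  expect_equal(pc$pct_poor_to_rich, 10)
  expect_equal(net_movement(pc), 10)

  # no cross-color QD anywhere: both percentages zero
  clean <- base
  clean$hyphae_poor_qd_cyan <- 0
  clean$hyphae_rich_qd_red <- 0
  pc0 <- translocation_percentages(clean)
  expect_equal(pc0$pct_rich_to_poor, 0)
  expect_equal(pc0$pct_poor_to_rich, 0)

  # zero hyphal QD leaves a direction undefined and flagged
  empty <- base
  empty$hyphae_poor_qd_cyan <- 0
  empty$hyphae_poor_qd_red <- 0
  pce <- translocation_percentages(empty)
  expect_true(is.na(pce$pct_rich_to_poor))
  expect_true(pce$undefined)
  expect_true(is.na(net_movement(pce)))
})

test_that("noise-free simulations reproduce truth-record values exactly", {
  for (tr in c("90:10", "70:30", "50:50")) {
    sim <- simulate_plates(plate_sim_config(treatment = tr, noise = "none",
                                            n_plates = 2))
    pc <- translocation_percentages(sim$plates)
    expect_equal(pc$pct_rich_to_poor, rep(sim$truth$pct_rich_to_poor, 2))
    expect_equal(pc$pct_poor_to_rich, rep(sim$truth$pct_poor_to_rich, 2))
    expect_equal(net_movement(pc), rep(sim$truth$net_movement, 2))
    rc <- relative_contribution(sim$plates)
    expect_equal(rc$share_rich_pct, rep(sim$truth$share_rich_pct, 2))
    tt <- transfer_to_root(sim$plates)
    expect_equal(tt$transfer_total_per_mg,
                 rep(sim$truth$transfer_total_per_mg, 2))
    ex <- exchange_rate(sim$plates)
    expect_equal(ex$exchange_rich, rep(sim$truth$exchange_rich, 2))
    expect_equal(ex$exchange_poor, rep(sim$truth$exchange_poor, 2))
  }
})

test_that("symmetric 50:50 plates have zero net movement; relabeling negates it", {
  sym <- simulate_plates(plate_sim_config(
    treatment = "50:50", noise = "none", n_plates = 1,
    transfer_fraction_rich = 0.4, transfer_fraction_poor = 0.4,
    transloc_rich_to_poor = 0.1, transloc_poor_to_rich = 0.1))
  expect_equal(net_movement(translocation_percentages(sym$plates)), 0)

  # swapping which compartment is called rich negates net movement exactly
  sim <- simulate_plates(plate_sim_config(treatment = "50:50", noise = "none",
                                          n_plates = 1))
  p <- sim$plates
  swapped <- p
  swapped[c("hyphae_rich_qd_cyan", "hyphae_rich_qd_red",
            "hyphae_rich_biomass_mg")] <-
    p[c("hyphae_poor_qd_cyan", "hyphae_poor_qd_red", "hyphae_poor_biomass_mg")]
  swapped[c("hyphae_poor_qd_cyan", "hyphae_poor_qd_red",
            "hyphae_poor_biomass_mg")] <-
    p[c("hyphae_rich_qd_cyan", "hyphae_rich_qd_red", "hyphae_rich_biomass_mg")]
  swapped$color_swap <- TRUE   # the rich-source color now sits in "poor"
  nm <- net_movement(translocation_percentages(p))
  nm_sw <- net_movement(translocation_percentages(swapped))
  expect_equal(nm_sw, -nm)
})

test_that("every trade quantity is invariant under the color-swap flag", {
  a <- simulate_plates(plate_sim_config(treatment = "70:30", noise = "none",
                                        n_plates = 1, color_swap = FALSE))
  b <- simulate_plates(plate_sim_config(treatment = "70:30", noise = "none",
                                        n_plates = 1, color_swap = TRUE))
  la <- trade_summary(a$plates)
  lb <- trade_summary(b$plates)
  expect_equal(la$value, lb$value)
})

test_that("relative contribution compares shares with the injected split", {
  p <- make_plate_cohort(n_plates = 1)[1, ]  # 90:10 plate
  p$root_qd_cyan <- 0.9e-2
  p$root_qd_red <- 0.1e-2
  rc <- relative_contribution(p)
  expect_equal(rc$share_rich_pct, 90)
  expect_equal(rc$deviation_poor, 0)

  p$root_qd_cyan <- 0.8e-2
  p$root_qd_red <- 0.2e-2
  rc2 <- relative_contribution(p)
  expect_equal(rc2$deviation_poor, 10)     # poor patch over-contributes
  expect_equal(rc2$share_rich_pct + rc2$share_poor_pct, 100)
})

test_that("exchange rates follow ln(biomass / transfer) with zero-transfer flags", {
  p <- make_plate_cohort(n_plates = 1)[1, ]
  p$hyphae_rich_biomass_mg <- 1
  p$root_qd_cyan <- 1
  ex <- exchange_rate(p)
  expect_equal(ex$exchange_rich, 0)
  p$hyphae_rich_biomass_mg <- exp(1)
  expect_equal(exchange_rate(p)$exchange_rich, 1)

  p$root_qd_cyan <- 0
  ex0 <- exchange_rate(p)
  expect_true(is.na(ex0$exchange_rich))
  expect_true(ex0$undefined)

  # poor compartment transferring less per mg biomass earns a higher rate
  sim <- simulate_plates(plate_sim_config(treatment = "90:10", noise = "none",
                                          n_plates = 1))
  exs <- exchange_rate(sim$plates)
  expect_gt(exs$exchange_poor, exs$exchange_rich)
})

test_that("the grouped summary matches brute-force means and SEs", {
  plates <- make_plate_cohort(noise = "gamma", n_plates = 4, seed = 33)
  summ <- summarize_trade(plates)
  long <- trade_summary(plates)
  row <- summ[summ$treatment == "70:30" & summ$measure == "net_movement", ]
  vals <- long$value[long$treatment == "70:30" &
                       long$measure == "net_movement"]
  expect_equal(row$mean, mean(vals))
  expect_equal(row$se, sd(vals) / sqrt(length(vals)))
  expect_equal(row$n, 4L)

  single <- summarize_trade(make_plate_cohort(n_plates = 1))
  expect_true(all(is.na(single$se)))
  expect_error(summarize_trade(plates[0, ]), "empty")
})

test_that("plate tables round-trip through CSV", {
  plates <- make_plate_cohort(n_plates = 2)
  tmp <- tempfile(fileext = ".csv")
  write_plates_csv(plates, tmp)
  back <- read_plates_csv(tmp)
  expect_equal(back$root_qd_cyan, plates$root_qd_cyan)
  expect_equal(back$treatment, plates$treatment)
})
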