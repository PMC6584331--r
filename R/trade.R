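## Compartment-level trade and translocation accounting. A plate record is
## one three-compartment Petri dish: QD-apatite of two colors injected into
## the rich and poor fungal compartments, measured after 60 days in the host
## root and in the hyphae of each compartment. All internal accounting is in
## nmol QD; the P:QD conversion is applied only at reporting time.

#' Phosphorus carried per quantum dot
#'
#' Each nmol of QD-apatite carries ~708 nmol phosphorus (nmol P : nmol QD).
#' @export
P_PER_QD <- 708

#' Injection split for an inequality treatment
#'
#' @param treatment One of `"90:10"`, `"70:30"`, `"50:50"`.
#' @return Numeric `c(rich, poor)` fractions.
#' @export
treatment_split <- function(treatment) {
  parts <- switch(as.character(treatment),
                  "90:10" = c(0.9, 0.1),
                  "70:30" = c(0.7, 0.3),
                  "50:50" = c(0.5, 0.5),
                  stop("unknown treatment: ", treatment,
                       " (expected 90:10, 70:30 or 50:50)"))
  stats::setNames(parts, c("rich", "poor"))
}

#' Validate a table of plate records
#'
#' A plate-record table has one row per plate with columns `plate_id`,
#' `treatment`, `color_swap` (logical; `FALSE` means cyan marks the
#' rich-source phosphorus), `injected_rich_nmol`, `injected_poor_nmol`,
#' `root_mass_mg`, `root_qd_cyan`, `root_qd_red`, and per compartment
#' `hyphae_<comp>_qd_cyan`, `hyphae_<comp>_qd_red`,
#' `hyphae_<comp>_biomass_mg` for `<comp>` in `rich`, `poor`.
#'
#' @param plates Data frame of plate records.
#' @return The validated data frame (invisibly usable downstream).
#' @export
validate_plates <- function(plates) {
  needed <- c("plate_id", "treatment", "color_swap",
              "injected_rich_nmol", "injected_poor_nmol", "root_mass_mg",
              "root_qd_cyan", "root_qd_red",
              "hyphae_rich_qd_cyan", "hyphae_rich_qd_red",
              "hyphae_rich_biomass_mg",
              "hyphae_poor_qd_cyan", "hyphae_poor_qd_red",
              "hyphae_poor_biomass_mg")
  missing <- setdiff(needed, names(plates))
  if (length(missing)) {
    stop("plate table is missing column(s): ", paste(missing, collapse = ", "))
  }
  num <- setdiff(needed, c("plate_id", "treatment", "color_swap"))
  for (cn in num) {
    if (any(!is.finite(plates[[cn]])) || any(plates[[cn]] < 0)) {
      stop("column ", cn, " must be finite and >= 0")
    }
  }
  for (tr in plates$treatment) treatment_split(tr)  # known treatments only
  plates
}

## Resolve color-coded measurements into source compartments. Color is
## metadata: with color_swap = FALSE cyan tags the rich-source phosphorus.
resolve_sources <- function(plates) {
  swap <- as.logical(plates$color_swap)
  pick <- function(cyan, red) ifelse(swap, red, cyan)
  data.frame(
    plate_id = plates$plate_id,
    treatment = plates$treatment,
    root_qd_from_rich = pick(plates$root_qd_cyan, plates$root_qd_red),
    root_qd_from_poor = pick(plates$root_qd_red, plates$root_qd_cyan),
    hyphae_rich_richsrc = pick(plates$hyphae_rich_qd_cyan,
                               plates$hyphae_rich_qd_red),
    hyphae_rich_poorsrc = pick(plates$hyphae_rich_qd_red,
                               plates$hyphae_rich_qd_cyan),
    hyphae_poor_richsrc = pick(plates$hyphae_poor_qd_cyan,
                               plates$hyphae_poor_qd_red),
    hyphae_poor_poorsrc = pick(plates$hyphae_poor_qd_red,
                               plates$hyphae_poor_qd_cyan))
}

#' Phosphorus transfer to the host root, per mg root
#'
#' QD concentration in the root per source compartment and in total
#' (nmol QD per mg root), plus the phosphorus equivalent via the 708:1
#' P:QD ratio.
#'
#' @param plates Validated plate table (see [validate_plates()]).
#' @return Data frame per plate with `transfer_rich_per_mg`,
#'   `transfer_poor_per_mg`, `transfer_total_per_mg` (nmol QD/mg root) and
#'   `p_total_per_mg` (nmol P/mg root).
#' @export
transfer_to_root <- function(plates) {
  plates <- validate_plates(plates)
  if (any(plates$root_mass_mg <= 0)) stop("root_mass_mg must be > 0")
  src <- resolve_sources(plates)
  out <- data.frame(
    plate_id = plates$plate_id,
    treatment = plates$treatment,
    transfer_rich_per_mg = src$root_qd_from_rich / plates$root_mass_mg,
    transfer_poor_per_mg = src$root_qd_from_poor / plates$root_mass_mg)
  out$transfer_total_per_mg <- out$transfer_rich_per_mg +
    out$transfer_poor_per_mg
  out$p_total_per_mg <- out$transfer_total_per_mg * P_PER_QD
  out
}

#' Cross-compartment translocation percentages
#'
#' In each compartment's hyphae, the percentage of QD bearing the other
#' compartment's source color: `pct_rich_to_poor` is the share of
#' rich-source QD among all QD in the poor compartment's hyphae, and
#' symmetrically for `pct_poor_to_rich`. A compartment with zero total
#' hyphal QD leaves that direction undefined (`NA`) and sets the flag.
#'
#' @param plates Validated plate table.
#' @return Data frame per plate with `pct_rich_to_poor`, `pct_poor_to_rich`
#'   and `undefined` (logical).
#' @export
translocation_percentages <- function(plates) {
  plates <- validate_plates(plates)
  src <- resolve_sources(plates)
  tot_poor <- src$hyphae_poor_richsrc + src$hyphae_poor_poorsrc
  tot_rich <- src$hyphae_rich_richsrc + src$hyphae_rich_poorsrc
  p_rp <- ifelse(tot_poor > 0, 100 * src$hyphae_poor_richsrc / tot_poor, NA)
  p_pr <- ifelse(tot_rich > 0, 100 * src$hyphae_rich_poorsrc / tot_rich, NA)
  data.frame(plate_id = plates$plate_id, treatment = plates$treatment,
             pct_rich_to_poor = p_rp, pct_poor_to_rich = p_pr,
             undefined = tot_poor <= 0 | tot_rich <= 0)
}

#' Net movement between compartments
#'
#' Difference of the two translocation percentages,
#' rich-to-poor minus poor-to-rich (percentage points). Undefined
#' directions propagate as `NA`.
#'
#' @param pcts Output of [translocation_percentages()].
#' @return Numeric vector of percentage points.
#' @export
net_movement <- function(pcts) {
  stopifnot(all(c("pct_rich_to_poor", "pct_poor_to_rich") %in% names(pcts)))
  pcts$pct_rich_to_poor - pcts$pct_poor_to_rich
}

#' Relative contribution of each source compartment to root phosphorus
#'
#' Shares of the root's QD content by source compartment, compared with the
#' treatment's injected shares (90/10, 70/30, 50/50). A positive
#' `deviation_poor` means the poor patch over-contributed to trade relative
#' to the resources it held.
#'
#' @param plates Validated plate table.
#' @return Data frame per plate with `share_rich_pct`, `share_poor_pct`,
#'   `expected_rich_pct`, `expected_poor_pct`, `deviation_poor`.
#' @export
relative_contribution <- function(plates) {
  plates <- validate_plates(plates)
  src <- resolve_sources(plates)
  tot <- src$root_qd_from_rich + src$root_qd_from_poor
  if (any(tot <= 0)) stop("root QD total must be > 0 on every plate")
  exp_share <- t(vapply(plates$treatment, treatment_split, numeric(2))) * 100
  out <- data.frame(
    plate_id = plates$plate_id, treatment = plates$treatment,
    share_rich_pct = 100 * src$root_qd_from_rich / tot,
    share_poor_pct = 100 * src$root_qd_from_poor / tot,
    expected_rich_pct = exp_share[, "rich"],
    expected_poor_pct = exp_share[, "poor"])
  out$deviation_poor <- out$share_poor_pct - out$expected_poor_pct
  out
}

#' Per-compartment exchange rate
#'
#' `ln(mg hyphal biomass / nmol QD transferred to the root from that
#' compartment)` -- carbon received per phosphorus traded, using biomass as
#' the carbon proxy (the fungus is an obligate biotroph). Zero transfer
#' leaves the rate undefined (`NA`, not `-Inf`) and flags the plate.
#'
#' @param plates Validated plate table.
#' @return Data frame per plate with `exchange_rich`, `exchange_poor`,
#'   `undefined`.
#' @export
exchange_rate <- function(plates) {
  plates <- validate_plates(plates)
  src <- resolve_sources(plates)
  safe_ln <- function(biomass, transfer) {
    ifelse(transfer > 0 & biomass > 0, log(biomass / transfer), NA)
  }
  ex_r <- safe_ln(plates$hyphae_rich_biomass_mg, src$root_qd_from_rich)
  ex_p <- safe_ln(plates$hyphae_poor_biomass_mg, src$root_qd_from_poor)
  data.frame(plate_id = plates$plate_id, treatment = plates$treatment,
             exchange_rich = ex_r, exchange_poor = ex_p,
             undefined = is.na(ex_r) | is.na(ex_p))
}

#' Tidy per-plate trade summary table
#'
#' One row per plate x measure in long format, combining transfer,
#' translocation, net movement, relative contribution and exchange rates.
#' This is the table handed to external statistical modelling (e.g. Gamma
#' GLMs with treatment as the explanatory variable).
#'
#' @param plates Validated plate table.
#' @return Long data frame: `plate_id`, `treatment`, `measure`, `value`.
#' @export
trade_summary <- function(plates) {
  plates <- validate_plates(plates)
  tr <- transfer_to_root(plates)
  pc <- translocation_percentages(plates)
  rc <- relative_contribution(plates)
  ex <- exchange_rate(plates)
  wide <- data.frame(
    plate_id = plates$plate_id, treatment = plates$treatment,
    transfer_rich_per_mg = tr$transfer_rich_per_mg,
    transfer_poor_per_mg = tr$transfer_poor_per_mg,
    transfer_total_per_mg = tr$transfer_total_per_mg,
    p_total_per_mg = tr$p_total_per_mg,
    pct_rich_to_poor = pc$pct_rich_to_poor,
    pct_poor_to_rich = pc$pct_poor_to_rich,
    net_movement = net_movement(pc),
    share_rich_pct = rc$share_rich_pct,
    share_poor_pct = rc$share_poor_pct,
    deviation_poor = rc$deviation_poor,
    exchange_rich = ex$exchange_rich,
    exchange_poor = ex$exchange_poor)
  measures <- setdiff(names(wide), c("plate_id", "treatment"))
  long <- do.call(rbind, lapply(measures, function(m) {
    data.frame(plate_id = wide$plate_id, treatment = wide$treatment,
               measure = m, value = wide[[m]])
  }))
  rownames(long) <- NULL
  long
}

#' Per-treatment means and standard errors of all trade measures
#'
#' Groups the tidy summary by treatment and measure; plates with undefined
#' (`NA`) values are excluded from that measure's mean, with the excluded
#' count reported.
#'
#' @param plates Validated plate table (>= 1 plate).
#' @return Data frame: `treatment`, `measure`, `mean`, `se` (`NA` for a
#'   single plate), `n`, `n_excluded`.
#' @export
summarize_trade <- function(plates) {
  if (!nrow(plates)) stop("empty plate table")
  long <- trade_summary(plates)
  groups <- split(long, list(long$treatment, long$measure), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g$value
    ok <- !is.na(v)
    data.frame(treatment = g$treatment[1L], measure = g$measure[1L],
               mean = if (any(ok)) mean(v[ok]) else NA_real_,
               se = if (sum(ok) > 1) stats::sd(v[ok]) / sqrt(sum(ok))
                    else NA_real_,
               n = sum(ok), n_excluded = sum(!ok))
  }))
  rownames(out) <- NULL
  out[order(out$measure, out$treatment), ]
}
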