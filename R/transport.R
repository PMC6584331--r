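## Analytic advection-versus-diffusion model: could the observed movement of
## QD-apatite across a compartmented plate arise from Brownian diffusion
## alone, or does it require advective transport (cytoplasmic streaming /
## motor-driven flow)?

#' Physical and experimental parameters for the transport model
#'
#' @param viscosity_Ns_m2 Cytosol viscosity, approximated by water
#'   (default 1e-3 N s/m^2).
#' @param temperature_K Absolute temperature (default 298.15 K; cultures are
#'   kept at 25 C).
#' @param boltzmann_J_K Boltzmann constant (1.380649e-23 J/K).
#' @param radius_range_nm Particle radius extremes `[a_min, a_max]`
#'   (default 4 and 104 nm: 8 nm QD-apatite crystals and ~208 nm composite
#'   aggregates).
#' @param harvest_days Experiment duration `T_H` (default 60 days).
#' @param min_length_cm Minimum distance to the other compartment `L_min`
#'   (default 3 cm).
#' @param v_min_um_s Conservative advective speed lower bound
#'   (default 0.1 um/s).
#' @return A `transport_params` list.
#' @export
transport_params <- function(viscosity_Ns_m2 = 1e-3,
                             temperature_K = 298.15,
                             boltzmann_J_K = 1.380649e-23,
                             radius_range_nm = c(4, 104),
                             harvest_days = 60,
                             min_length_cm = 3,
                             v_min_um_s = 0.1) {
  vals <- c(viscosity_Ns_m2, temperature_K, boltzmann_J_K,
            radius_range_nm, harvest_days, min_length_cm, v_min_um_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all transport parameters must be positive and finite")
  }
  if (radius_range_nm[1L] > radius_range_nm[2L]) {
    stop("radius_range_nm must be ordered [a_min, a_max]")
  }
  structure(as.list(environment()), class = "transport_params")
}

#' Stokes-Einstein diffusion coefficient
#'
#' `D = kB T / (6 pi eta a)` for a sphere of radius `a`, returned in um^2/s.
#'
#' @param radius_nm Particle radius (nm), > 0; vectorised.
#' @param params A [transport_params()].
#' @return Diffusion coefficient(s), um^2/s.
#' @export
stokes_einstein <- function(radius_nm, params = transport_params()) {
  if (any(!is.finite(radius_nm)) || any(radius_nm <= 0)) {
    stop("radius_nm must be > 0")
  }
  a_m <- radius_nm * 1e-9
  d_m2_s <- params$boltzmann_J_K * params$temperature_K /
    (6 * pi * params$viscosity_Ns_m2 * a_m)
  d_m2_s * 1e12
}

#' Root-mean-square diffusive displacement
#'
#' From `r^2 = 2 D t`: `sqrt(2 D t)` in um.
#'
#' @param D Diffusion coefficient (um^2/s).
#' @param t_s Time (s), >= 0; vectorised.
#' @return Displacement (um).
#' @export
diffusive_displacement <- function(D, t_s) {
  if (any(t_s < 0)) stop("t_s must be >= 0")
  sqrt(2 * D * t_s)
}

#' Advective displacement
#'
#' From `r^2 = (v t)^2`: `v * t` in um.
#'
#' @param v_um_s Advective speed (um/s).
#' @param t_s Time (s), >= 0; vectorised.
#' @return Displacement (um).
#' @export
advective_displacement <- function(v_um_s, t_s) {
  if (any(t_s < 0)) stop("t_s must be >= 0")
  v_um_s * t_s
}

#' Expected diffusive compartment-crossing time
#'
#' `tau = L^2 / (2 D)`, converted to days.
#'
#' @param L_cm Distance to cross (cm), > 0.
#' @param D Diffusion coefficient (um^2/s), > 0.
#' @return Crossing time (days).
#' @export
crossing_time <- function(L_cm, D) {
  if (any(L_cm <= 0) || any(D <= 0)) stop("L_cm and D must be > 0")
  L_um <- L_cm * 1e4
  tau_s <- L_um^2 / (2 * D)
  tau_s / 86400
}

#' Full advection-vs-diffusion transport report
#'
#' Evaluates the Stokes-Einstein diffusion coefficient at both radius
#' extremes, the diffusive crossing-time bounds for `L_min`, diffusive and
#' advective displacement curves over the experiment duration, and the
#' verdict: diffusion is insufficient to explain cross-compartment transport
#' when even the fastest diffusion (smallest particle) needs longer than the
#' harvest time to cross.
#'
#' @param params A [transport_params()].
#' @param n_curve Number of points in the displacement curves.
#' @return A `transport_report` with `D_range` (um^2/s, at `a_max` and
#'   `a_min`), `tau_range` (days, at `D_max` and `D_min`), rounded reporting
#'   values (`D` to one significant figure, the upper `tau` to two),
#'   `curves` (data.frame: `t_days`, `diffusive_um` at `D_max`,
#'   `advective_um` at `v_min`), and `diffusion_insufficient`.
#' @export
transport_report <- function(params = transport_params(), n_curve = 101L) {
  a <- params$radius_range_nm
  D_max <- stokes_einstein(a[1L], params)   # smallest particle: fastest
  D_min <- stokes_einstein(a[2L], params)
  tau_min <- crossing_time(params$min_length_cm, D_max)
  tau_max <- crossing_time(params$min_length_cm, D_min)
  t_days <- seq(0, params$harvest_days, length.out = n_curve)
  t_s <- t_days * 86400
  curves <- data.frame(
    t_days = t_days,
    diffusive_um = diffusive_displacement(D_max, t_s),
    advective_um = advective_displacement(params$v_min_um_s, t_s))
  structure(
    list(D_range = c(D_min = D_min, D_max = D_max),
         tau_range = c(tau_min = tau_min, tau_max = tau_max),
         D_rounded = signif(c(D_min = D_min, D_max = D_max), 1),
         tau_rounded = c(tau_min = signif(tau_min, 1),
                         tau_max = signif(crossing_time(
                           params$min_length_cm,
                           signif(D_min, 1)), 2)),
         curves = curves,
         diffusion_insufficient = tau_min > params$harvest_days,
         params = params),
    class = "transport_report"
  )
}

#' @export
print.transport_report <- function(x, ...) {
  cat("<transport_report>\n")
  cat(sprintf("  D: %.3g - %.3g um^2/s (radii %g - %g nm)\n",
              x$D_range[["D_min"]], x$D_range[["D_max"]],
              x$params$radius_range_nm[1L], x$params$radius_range_nm[2L]))
  cat(sprintf("  diffusive crossing of %g cm: %.4g - %.4g days\n",
              x$params$min_length_cm, x$tau_range[["tau_min"]],
              x$tau_range[["tau_max"]]))
  cat(sprintf("  harvest time: %g days -> diffusion %s\n",
              x$params$harvest_days,
              if (x$diffusion_insufficient) {
                "insufficient (advection required)"
              } else "possible"))
  invisible(x)
}
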