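#' Bimolecular and unimolecular rate table
#'
#' All association rates are macroscopic bimolecular constants in uM^-1 s^-1;
#' dissociation rates in s^-1. The clathrin-clathrin association rate is
#' gated on AP-2: it is `k_cc_free` (zero by default) when neither partner's
#' cluster contains an AP-2, and `k_cc_gated` when at least one does.
#'
#' The shipped dissociation defaults are documented placeholders: the
#' upstream kinetic set they belong to is not restated here, so simulations
#' that leave them untouched are flagged by [parse_config()].
#'
#' @param k_cc_gated clathrin-clathrin association rate when at least one
#'   partner is AP-2-bound, uM^-1 s^-1. Default `50 * 0.913` (the reference
#'   condition of the assembly study).
#' @param k_cc_free clathrin-clathrin association rate when neither partner
#'   is AP-2-bound, uM^-1 s^-1 (default 0).
#' @param k_ap2_clat clathrin to AP-2 association rate, uM^-1 s^-1.
#' @param koff_cc clathrin-clathrin dissociation rate, s^-1.
#' @param koff_ap2_clat clathrin-AP-2 dissociation rate, s^-1.
#' @return an object of class `fcl_rate_table`.
#' @export
rate_table <- function(k_cc_gated = 50 * 0.913, k_cc_free = 0,
                       k_ap2_clat = 0.0012, koff_cc = 1,
                       koff_ap2_clat = 0.1) {
  vals <- c(k_cc_gated = k_cc_gated, k_cc_free = k_cc_free,
            k_ap2_clat = k_ap2_clat, koff_cc = koff_cc,
            koff_ap2_clat = koff_ap2_clat)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all rates must be finite and non-negative")
  }
  structure(as.list(vals), class = "fcl_rate_table")
}

#' Convert a bimolecular rate constant to particle units
#'
#' `uM^-1 s^-1 -> nm^3/us`: one micromolar is `6.02214076e-7` molecules per
#' nm^3, so `1 uM^-1 s^-1 = 1.6606e6 nm^3/s = 1.6606 nm^3/us`.
#'
#' @param k rate in uM^-1 s^-1.
#' @return rate in nm^3/us.
#' @export
convert_bimolecular_rate <- function(k) {
  if (!is.numeric(k) || any(k < 0)) stop("k must be non-negative")
  avogadro <- 6.02214076e23
  nm3_per_uM_inv <- 1e24 / (avogadro * 1e-6)  # nm^3 per molecule at 1 uM
  k * nm3_per_uM_inv * 1e-6                   # s^-1 -> us^-1
}

#' Per-step dissociation probability
#'
#' Poisson-process probability `1 - exp(-k dt)` that a bond dissociates
#' within one time step.
#'
#' @param koff dissociation rate, s^-1.
#' @param dt time step, us.
#' @return probability in `[0, 1)`.
#' @export
dissociation_probability <- function(koff, dt) {
  if (any(koff < 0)) stop("koff must be non-negative")
  if (any(dt <= 0)) stop("dt must be positive")
  1 - exp(-koff * 1e-6 * dt)
}

#' AP-2-gated clathrin-clathrin association rate
#'
#' @param bound_a,bound_b logical: is the partner's cluster AP-2-bound?
#' @param rates a [rate_table()].
#' @return the applicable macroscopic rate, uM^-1 s^-1.
#' @export
gate_cc_rate <- function(bound_a, bound_b, rates) {
  if (isTRUE(bound_a) || isTRUE(bound_b)) rates$k_cc_gated else rates$k_cc_free
}

#' Doi-style association acceptance probability
#'
#' Two sites closer than the reaction radius `sigma` react within a step
#' with probability `1 - exp(-lambda dt)`, where `lambda = k_micro / V` and
#' `V` is the reaction volume `(4/3) pi sigma^3` (3D) or area `pi sigma^2`
#' (2D, both partners membrane-bound). Sites beyond `sigma` never react.
#' This is a volume-reaction acceptance whose macroscopic rate is verified
#' by a well-mixed calibration test; it replaces propagator-reweighting
#' schemes while preserving the macroscopic kinetics the cluster statistics
#' depend on.
#'
#' @param site_distance separation of the two candidate sites, nm.
#' @param k_micro microscopic rate, nm^3/us (3D) or nm^2/us (2D).
#' @param dt time step, us.
#' @param reaction_radius capture radius sigma, nm.
#' @param dims 3 (volume) or 2 (membrane plane).
#' @return acceptance probability in `[0, 1)`.
#' @export
association_acceptance <- function(site_distance, k_micro, dt,
                                   reaction_radius = 1, dims = 3) {
  if (any(site_distance < 0)) stop("site_distance must be non-negative")
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3")
  v <- if (dims == 3) (4 / 3) * pi * reaction_radius^3 else
    pi * reaction_radius^2
  p <- 1 - exp(-(k_micro / v) * dt)
  p[site_distance > reaction_radius] <- 0
  p
}

#' Implicit-pool AP-2 capture probability
#'
#' Unbound AP-2 is not explicitly represented; it forms a well-mixed
#' membrane pool of surface density `free_count / L^2`. A clathrin whose
#' AP-2 site is within `capture_height` of the membrane binds one AP-2 from
#' the pool with probability `1 - exp(-k2d rho dt)`, where
#' `k2d = convert_bimolecular_rate(k_ap2_clat) / capture_height`.
#'
#' @param ap2_site_height height of the clathrin's AP-2 site above the
#'   membrane, nm.
#' @param free_count free AP-2 molecules in the pool.
#' @param rates a [rate_table()].
#' @param dt time step, us.
#' @param box_edge membrane edge length L, nm.
#' @param capture_height reaction-layer height h, nm.
#' @return capture probability in `[0, 1)`.
#' @export
ap2_binding_probability <- function(ap2_site_height, free_count, rates, dt,
                                    box_edge, capture_height = 10) {
  stopifnot(free_count >= 0)
  if (free_count == 0) return(0)
  if (ap2_site_height > capture_height || ap2_site_height < 0) return(0)
  k2d <- convert_bimolecular_rate(rates$k_ap2_clat) / capture_height
  rho <- free_count / box_edge^2
  1 - exp(-k2d * rho * dt)
}

#' Sample the reaction events of one time step
#'
#' Runs a single engine step on a copy of `state` and returns the reaction
#' events that fired, together with the set of molecules frozen (excluded
#' from diffusion) in that step. Dissociation events are tested before
#' association events, and a molecule participates in at most one event per
#' step. `state` itself is not modified.
#'
#' @param state an `fcl_state`.
#' @param config an [simulation_config()].
#' @param seed integer seed for the step's random draws.
#' @return list with `events` (data.frame: kind, mol_a, site_a, mol_b,
#'   site_b, time_us) and `frozen` (integer molecule ids).
#' @export
sample_events <- function(state, config, seed = 1) {
  out <- engine_run(state, config, n_steps = 1L, seed = seed,
                    record_events = TRUE)
  list(events = out$events, frozen = out$frozen_last_step)
}
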