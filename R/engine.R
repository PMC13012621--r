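#' Simulation configuration
#'
#' Collects every physical, kinetic and scheduling parameter of a run.
#' Units are fixed package-wide: lengths in nm, times in us, rates in
#' uM^-1 s^-1 (associations) and s^-1 (dissociations).
#'
#' @param box_edge cubic domain edge length L, nm.
#' @param dt time step, us.
#' @param n_clathrin number of clathrin molecules (conserved).
#' @param n_ap2 total AP-2 molecules (explicit bound + implicit free pool).
#' @param rates a [rate_table()].
#' @param env a [physical_environment()].
#' @param geometry a [clathrin_geometry()].
#' @param diffusion list with elements `clathrin` and `ap2`, each an
#'   [diffusion_spec()]; defaults derive from `env` via Stokes-Einstein.
#' @param duration total simulated time, us.
#' @param frame_interval trajectory sampling interval, us (also the
#'   resolution of dwelling-time statistics).
#' @param seed integer seed; fixes the initial condition and every random
#'   draw of the run.
#' @param schedule optional [parameter_schedule()].
#' @param reaction_radius association capture radius sigma, nm.
#' @param capture_height membrane reaction-layer height h, nm (also the 3D
#'   to 2D rate conversion length).
#' @param max_retries overlap-resampling retries before the zero-move
#'   fallback.
#' @return an object of class `fcl_config`.
#' @export
simulation_config <- function(box_edge = 1000, dt = 3, n_clathrin = 300,
                              n_ap2 = 150, rates = rate_table(),
                              env = physical_environment(),
                              geometry = clathrin_geometry(),
                              diffusion = NULL,
                              duration = 1e6, frame_interval = 1e5,
                              seed = 1, schedule = NULL,
                              reaction_radius = 1, capture_height = 10,
                              max_retries = 100) {
  if (box_edge <= 0 || dt <= 0 || duration <= 0 || frame_interval <= 0) {
    stop("box_edge, dt, duration and frame_interval must be positive")
  }
  if (frame_interval < dt) stop("frame_interval must be >= dt")
  if (n_clathrin < 0 || n_ap2 < 0) stop("molecule counts must be >= 0")
  if (is.null(diffusion)) {
    diffusion <- list(clathrin = clathrin_diffusion(env),
                      ap2 = ap2_diffusion(env))
  }
  stopifnot(inherits(rates, "fcl_rate_table"),
            inherits(geometry, "fcl_geometry"),
            inherits(diffusion$clathrin, "fcl_diffusion_spec"),
            inherits(diffusion$ap2, "fcl_diffusion_spec"))
  if (!is.null(schedule)) stopifnot(inherits(schedule, "fcl_schedule"))
  structure(list(box_edge = box_edge, dt = dt,
                 n_clathrin = as.integer(n_clathrin),
                 n_ap2 = as.integer(n_ap2), rates = rates, env = env,
                 geometry = geometry, diffusion = diffusion,
                 duration = duration, frame_interval = frame_interval,
                 seed = as.integer(seed), schedule = schedule,
                 reaction_radius = reaction_radius,
                 capture_height = capture_height,
                 max_retries = as.integer(max_retries)),
            class = "fcl_config")
}

#' Piecewise-constant parameter schedule
#'
#' Emulates a stimulus protocol: at each breakpoint time the listed
#' overrides take effect and stay in force until the next breakpoint.
#' Allowed override keys: `n_ap2` (absolute), and the multipliers (relative
#' to the baseline configuration) `k_cc_gated_mult`, `k_cc_free_mult`,
#' `k_ap2_clat_mult`, `koff_cc_mult`, `koff_ap2_mult`, `d_clat_mult`.
#'
#' @param breakpoints list of lists; each element must contain `time` (us,
#'   strictly increasing) plus overrides.
#' @return an object of class `fcl_schedule`.
#' @examples
#' # growth-factor protocol: more AP-2, faster clathrin-clathrin binding,
#' # slower clathrin diffusion; everything reverts after 30 simulated min
#' parameter_schedule(list(
#'   list(time = 0, n_ap2 = 200, k_cc_gated_mult = 50, d_clat_mult = 1 / 50),
#'   list(time = 30 * 60 * 1e6, n_ap2 = 100, k_cc_gated_mult = 1,
#'        d_clat_mult = 1)
#' ))
#' @export
parameter_schedule <- function(breakpoints) {
  allowed <- c("time", "n_ap2", "k_cc_gated_mult", "k_cc_free_mult",
               "k_ap2_clat_mult", "koff_cc_mult", "koff_ap2_mult",
               "d_clat_mult")
  times <- vapply(breakpoints, function(b) as.numeric(b$time), numeric(1))
  if (any(diff(times) <= 0)) stop("breakpoint times must be strictly increasing")
  for (b in breakpoints) {
    unknown <- setdiff(names(b), allowed)
    if (length(unknown)) {
      stop("unknown schedule override field(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(breakpoints = breakpoints), class = "fcl_schedule")
}

#' Effective parameters at a given time
#'
#' Resolves the schedule to the parameter set in force at simulated time
#' `t`: baseline values before the first breakpoint, then the overrides of
#' the latest breakpoint at or before `t` (piecewise constant, multipliers
#' applied to the baseline, never compounded).
#'
#' @param config an [simulation_config()].
#' @param t simulated time, us.
#' @return list with `n_ap2`, `rates` (an `fcl_rate_table`) and `d_clat`
#'   (the clathrin `fcl_diffusion_spec`).
#' @export
apply_schedule <- function(config, t) {
  eff <- list(n_ap2 = config$n_ap2, rates = config$rates,
              d_clat = config$diffusion$clathrin)
  sch <- config$schedule
  if (is.null(sch)) return(eff)
  for (b in sch$breakpoints) {
    if (b$time > t) break
    r <- config$rates
    eff$n_ap2 <- if (!is.null(b$n_ap2)) as.integer(b$n_ap2) else config$n_ap2
    m <- function(key) if (!is.null(b[[key]])) b[[key]] else 1
    eff$rates <- rate_table(
      k_cc_gated = r$k_cc_gated * m("k_cc_gated_mult"),
      k_cc_free = r$k_cc_free * m("k_cc_free_mult"),
      k_ap2_clat = r$k_ap2_clat * m("k_ap2_clat_mult"),
      koff_cc = r$koff_cc * m("koff_cc_mult"),
      koff_ap2_clat = r$koff_ap2_clat * m("koff_ap2_mult"))
    dm <- m("d_clat_mult")
    d <- config$diffusion$clathrin
    eff$d_clat <- diffusion_spec(d$d_trans * dm, d$d_rot)
  }
  eff
}

#' System state
#'
#' Full molecular snapshot: clathrin poses, the bond graph (leg partners),
#' which clathrins carry a bound AP-2, and the implicit AP-2 pool counters.
#'
#' @param pos n x 3 matrix of clathrin centers, nm.
#' @param quat n x 4 matrix of unit orientation quaternions.
#' @param leg_partner n x 3 integer matrix, bound partner molecule per leg
#'   (0 = free).
#' @param leg_partner_site n x 3 integer matrix, partner leg index (0 when
#'   free).
#' @param ap2_bound logical/integer length n: clathrin carries an AP-2.
#' @param ap2_free free (implicit) AP-2 count.
#' @param ap2_total total AP-2 (free + bound).
#' @param ap2_pending AP-2 flagged for removal at next unbinding.
#' @param time_us simulated time of the snapshot.
#' @return an object of class `fcl_state`.
#' @export
fcl_state <- function(pos, quat, leg_partner = NULL, leg_partner_site = NULL,
                      ap2_bound = NULL, ap2_free = 0,
                      ap2_total = ap2_free, ap2_pending = 0, time_us = 0) {
  n <- nrow(pos)
  if (is.null(leg_partner)) leg_partner <- matrix(0L, n, 3)
  if (is.null(leg_partner_site)) leg_partner_site <- matrix(0L, n, 3)
  if (is.null(ap2_bound)) ap2_bound <- integer(n)
  stopifnot(nrow(quat) == n, nrow(leg_partner) == n,
            length(ap2_bound) == n)
  if (ap2_free + sum(ap2_bound != 0) != ap2_total) {
    stop("AP-2 accounting: total must equal free + bound")
  }
  structure(list(pos = pos, quat = quat,
                 leg_partner = matrix(as.integer(leg_partner), n, 3),
                 leg_partner_site = matrix(as.integer(leg_partner_site), n, 3),
                 ap2_bound = as.integer(ap2_bound != 0),
                 ap2_free = as.integer(ap2_free),
                 ap2_total = as.integer(ap2_total),
                 ap2_pending = as.integer(ap2_pending),
                 time_us = time_us),
            class = "fcl_state")
}

# engine parameter block: schedule resolved into step-indexed segments with
# rates converted to particle units (nm^3/us, us^-1)
engine_params <- function(config, n_steps, seed, frame_every = 0L,
                          record_events = FALSE, validate_every = 0L,
                          pair_mode = FALSE) {
  btimes <- 0
  if (!is.null(config$schedule)) {
    btimes <- unique(c(0, vapply(config$schedule$breakpoints,
                                 function(b) as.numeric(b$time), numeric(1))))
  }
  segs <- t(vapply(btimes, function(t0) {
    eff <- apply_schedule(config, t0)
    c(start_step = floor(t0 / config$dt),
      k_cc_gated = convert_bimolecular_rate(eff$rates$k_cc_gated),
      k_cc_free = convert_bimolecular_rate(eff$rates$k_cc_free),
      k_ap2 = convert_bimolecular_rate(eff$rates$k_ap2_clat),
      koff_cc = eff$rates$koff_cc * 1e-6,
      koff_ap2 = eff$rates$koff_ap2_clat * 1e-6,
      d_clat_t = eff$d_clat$d_trans,
      d_clat_r = eff$d_clat$d_rot)
  }, numeric(12)))
  seg_ap2 <- vapply(seq_along(btimes), function(k) {
    if (k == 1 && btimes[1] == 0 && is.null(config$schedule)) return(-1L)
    eff <- apply_schedule(config, btimes[k])
    as.integer(eff$n_ap2)
  }, integer(1))
  # baseline segment never adjusts the pool: the state owns the counters
  if (btimes[1] == 0 && is.null(config$schedule)) seg_ap2[1] <- -1L
  list(L = config$box_edge, dt = config$dt,
       sigma = config$reaction_radius,
       capture_height = config$capture_height,
       excl = config$geometry$excluded_diameter,
       leg_off = config$geometry$leg_site_offsets,
       ap2_drop = -config$geometry$ap2_site_offset[3],
       leg_radius = config$geometry$leg_radius,
       bond_gap = config$geometry$bond_gap,
       d_ap2_trans = config$diffusion$ap2$d_trans,
       d_ap2_rot = config$diffusion$ap2$d_rot,
       segments = segs, segment_n_ap2 = seg_ap2,
       n_steps = as.integer(n_steps), frame_every = as.integer(frame_every),
       seed = as.numeric(seed), max_retries = config$max_retries,
       pair_mode = pair_mode, record_events = record_events,
       validate_every = as.integer(validate_every))
}

event_kind_labels <- c("bind_cc", "unbind_cc", "bind_ap2", "unbind_ap2")

#' Advance a system state through the compiled stepper
#'
#' Low-level driver used by [step()] and [run_simulation()].
#'
#' @param state an [fcl_state()].
#' @param config an [simulation_config()].
#' @param n_steps number of time steps.
#' @param seed engine RNG seed.
#' @param frame_every record a frame every this many steps (0 = none).
#' @param record_events keep the full reaction event log.
#' @param validate_every run internal invariant checks every this many
#'   steps (0 = off).
#' @param pair_mode restrict associations to monomer-monomer
#'   clathrin-clathrin events at the ungated rate (calibration harness).
#' @return list with `frames` (list of frame snapshots), `events`
#'   (data.frame), `frozen_last_step`, `event_counts` and `state` (the
#'   advanced [fcl_state()]).
#' @export
engine_run <- function(state, config, n_steps, seed = config$seed,
                       frame_every = 0L, record_events = FALSE,
                       validate_every = 0L, pair_mode = FALSE) {
  cfg <- engine_params(config, n_steps, seed, frame_every, record_events,
                       validate_every, pair_mode)
  out <- engine_run_cpp(state$pos, state$quat, state$leg_partner,
                        state$leg_partner_site, state$ap2_bound,
                        state$ap2_free, state$ap2_total, state$ap2_pending,
                        state$time_us, cfg)
  n <- nrow(state$pos)
  frames <- list()
  n_frames <- length(out$time_frames)
  if (n_frames > 0) {
    for (k in seq_len(n_frames)) {
      idx <- ((k - 1) * n + 1):(k * n)
      b <- out$bond_frames[out$bond_frames[, 1] == k, , drop = FALSE]
      frames[[k]] <- fcl_frame(
        time_us = out$time_frames[k],
        pos = out$pos_frames[idx, , drop = FALSE],
        quat = out$quat_frames[idx, , drop = FALSE],
        ap2_bound = out$ap2_frames[k, ],
        bonds = b[, 2:5, drop = FALSE],
        ap2_free = out$free_frames[k])
    }
  }
  ev <- out$events
  events <- data.frame(step = integer(0), kind = character(0),
                       mol_a = integer(0), site_a = integer(0),
                       mol_b = integer(0), site_b = integer(0),
                       time_us = numeric(0))
  if (nrow(ev) > 0) {
    events <- data.frame(step = ev[, 1],
                         kind = event_kind_labels[ev[, 2]],
                         mol_a = ev[, 3] + 1L, site_a = ev[, 4] + 1L,
                         mol_b = ev[, 5] + 1L, site_b = ev[, 6] + 1L,
                         time_us = state$time_us + (ev[, 1] + 1) * config$dt)
    events$mol_b[events$mol_b == 0] <- NA_integer_
    events$site_b[events$site_b == 0] <- NA_integer_
  }
  s <- out$state
  new_state <- fcl_state(s$pos, s$quat, s$leg_partner, s$leg_partner_site,
                         s$ap2_bound, s$ap2_free, s$ap2_total,
                         s$ap2_pending, s$time_us)
  list(frames = frames, events = events,
       frozen_last_step = out$frozen_last_step,
       event_counts = out$event_counts, state = new_state)
}

#' One trajectory frame
#'
#' @param time_us frame time, us.
#' @param pos,quat clathrin poses.
#' @param ap2_bound integer/logical per clathrin.
#' @param bonds 4-column matrix `mol_a, site_a, mol_b, site_b` (each bond
#'   once, `mol_a < mol_b`).
#' @param ap2_free free AP-2 count at the frame.
#' @return an object of class `fcl_frame`.
#' @export
fcl_frame <- function(time_us, pos, quat, ap2_bound, bonds, ap2_free) {
  if (is.null(dim(bonds))) bonds <- matrix(bonds, ncol = 4)
  colnames(bonds) <- c("mol_a", "site_a", "mol_b", "site_b")
  structure(list(time_us = time_us, pos = pos, quat = quat,
                 ap2_bound = as.integer(ap2_bound), bonds = bonds,
                 ap2_free = ap2_free, n_clathrin = nrow(pos)),
            class = "fcl_frame")
}

state_to_frame <- function(state) {
  keep <- state$leg_partner > row(state$leg_partner)
  bonds <- cbind(mol_a = row(state$leg_partner)[keep],
                 site_a = col(state$leg_partner)[keep],
                 mol_b = state$leg_partner[keep],
                 site_b = state$leg_partner_site[keep])
  fcl_frame(state$time_us, state$pos, state$quat, state$ap2_bound,
            bonds, state$ap2_free)
}

#' Advance the system by one time step
#'
#' Reactions first (dissociations, then associations), then diffusion of
#' the unfrozen entities with reflecting boundaries and excluded-volume
#' resampling. Clathrin count and total AP-2 are conserved.
#'
#' @inheritParams engine_run
#' @return the advanced [fcl_state()].
#' @export
simulation_step <- function(state, config, seed = config$seed) {
  engine_run(state, config, n_steps = 1L, seed = seed)$state
}

#' Run a full simulation
#'
#' Generates the random initial condition from `config$seed` (unless an
#' explicit `init` state is supplied), advances the system for
#' `config$duration`, and returns the sampled trajectory. Runs with the
#' same configuration and seed are bit-identical.
#'
#' @param config an [simulation_config()].
#' @param init optional [fcl_state()] to start from.
#' @param record_events keep the full reaction event log.
#' @param validate_every internal invariant-check interval in steps (0 =
#'   off).
#' @return an object of class `fcl_trajectory`: list with `frames` (the
#'   initial frame plus one frame per `frame_interval`), `config`, `seed`,
#'   `event_counts`, `final_state` and `events` (empty unless
#'   `record_events`).
#' @export
run_simulation <- function(config, init = NULL, record_events = FALSE,
                           validate_every = 0L) {
  if (is.null(init)) {
    init <- random_initial_condition(config)
  }
  n_steps <- floor(config$duration / config$dt)
  frame_every <- max(1L, as.integer(round(config$frame_interval / config$dt)))
  out <- if (n_steps > 0) {
    engine_run(init, config, n_steps, seed = config$seed,
               frame_every = frame_every, record_events = record_events,
               validate_every = validate_every)
  } else {
    list(frames = list(), events = NULL,
         event_counts = c(bind_cc = 0, unbind_cc = 0, bind_ap2 = 0,
                          unbind_ap2 = 0),
         state = init)
  }
  frames <- c(list(state_to_frame(init)), out$frames)
  structure(list(frames = frames, config = config, seed = config$seed,
                 event_counts = out$event_counts, events = out$events,
                 final_state = out$state,
                 version = as.character(utils::packageVersion("fclsim"))),
            class = "fcl_trajectory")
}

#' @export
print.fcl_trajectory <- function(x, ...) {
  cat("fclsim trajectory:", length(x$frames), "frames,",
      x$config$n_clathrin, "clathrins, L =", x$config$box_edge, "nm\n")
  cat("  simulated time:", x$final_state$time_us / 1e6, "s; seed:",
      x$seed, "\n")
  cat("  events:", paste(names(x$event_counts), x$event_counts,
                         collapse = ", "), "\n")
  invisible(x)
}

#' Reflect a position into the simulation domain
#'
#' Mirrors each coordinate at the walls (`pos -> -pos` at 0,
#' `pos -> 2L - pos` at L), iterating until the point is inside the closed
#' box.
#'
#' @param position numeric length-3 (or n x 3 matrix), nm.
#' @param L domain edge, nm.
#' @return reflected position(s) in `[0, L]`.
#' @export
reflect_into_domain <- function(position, L) {
  if (any(!is.finite(position))) stop("non-finite position")
  refl1 <- function(v) {
    for (it in 1:64) {
      if (v < 0) v <- -v
      else if (v > L) v <- 2 * L - v
      else break
    }
    v
  }
  if (is.matrix(position)) {
    apply(position, c(1, 2), refl1)
  } else {
    vapply(position, refl1, numeric(1))
  }
}

#' Propose a Brownian move for a rigid entity
#'
#' Per-axis Gaussian displacement with variance `2 D_p dt` and per-axis
#' rotation angles with variance `2 D_R,p dt`, applied about the x, y and z
#' axes through `center` (in that order, z applied last). Zero
#' coefficients produce exactly zero motion on the corresponding axis.
#' Draws come from the R RNG stream.
#'
#' @param position entity center, nm.
#' @param orientation unit quaternion.
#' @param spec an [diffusion_spec()].
#' @param dt time step, us.
#' @param center rotation pivot (defaults to `position`).
#' @return list with `position`, `orientation`, `displacement`, `angles`.
#' @export
diffusion_step <- function(position, orientation, spec, dt,
                           center = position) {
  disp <- vapply(1:3, function(a) {
    if (spec$d_trans[a] > 0) sqrt(2 * spec$d_trans[a] * dt) * stats::rnorm(1)
    else 0
  }, numeric(1))
  ang <- vapply(1:3, function(a) {
    if (spec$d_rot[a] > 0) sqrt(2 * spec$d_rot[a] * dt) * stats::rnorm(1)
    else 0
  }, numeric(1))
  q <- c(1, 0, 0, 0)
  axes <- diag(3)
  for (a in 1:3) {
    if (ang[a] != 0) q <- quat_multiply(quat_from_axis_angle(axes[a, ], ang[a]), q)
  }
  rel <- position - center
  newpos <- center + quat_rotate(q, rel) + disp
  newq <- quat_normalize(quat_multiply(q, orientation))
  list(position = newpos, orientation = newq, displacement = disp,
       angles = ang)
}

#' Resolve excluded-volume conflicts among proposed moves
#'
#' Entities whose proposals land closer than `excluded_diameter` to any
#' other entity are resampled with fresh draws (via `resample`) up to
#' `max_retries` times; entities still conflicting afterwards keep their
#' pre-move position.
#'
#' @param current n x 3 matrix of pre-move positions (must be
#'   conflict-free).
#' @param proposed n x 3 matrix of proposed positions.
#' @param excluded_diameter minimum pairwise distance, nm.
#' @param resample `function(i)` returning a fresh length-3 proposal for
#'   entity `i`.
#' @param max_retries maximum resampling rounds.
#' @return n x 3 matrix of accepted positions.
#' @export
resolve_overlaps <- function(current, proposed, excluded_diameter,
                             resample, max_retries = 100) {
  dmin <- function(m) min(stats::dist(m))
  if (nrow(current) > 1 && dmin(current) < excluded_diameter) {
    stop("pre-move state already contains overlaps")
  }
  n <- nrow(proposed)
  if (n <= 1) return(proposed)
  conflicted <- function(m) {
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    which(apply(d < excluded_diameter, 1, any))
  }
  retry <- 0
  repeat {
    bad <- conflicted(proposed)
    if (length(bad) == 0) return(proposed)
    if (retry < max_retries) {
      retry <- retry + 1
      for (i in bad) proposed[i, ] <- resample(i)
    } else {
      repeat {
        bad <- conflicted(proposed)
        if (length(bad) == 0) return(proposed)
        for (i in bad) proposed[i, ] <- current[i, ]
      }
    }
  }
}

#' Reject an association that would leave the domain
#'
#' An association event is rejected when any center or binding site of the
#' post-binding cluster pose falls strictly outside the closed box
#' `[0, L]^3`.
#'
#' @param points m x 3 matrix of post-binding centers and sites, nm.
#' @param L domain edge, nm.
#' @return `TRUE` if the event must be rejected.
#' @export
reject_out_of_domain_association <- function(points, L) {
  any(points < -1e-9 | points > L + 1e-9)
}
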