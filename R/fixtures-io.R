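#' Random initial condition
#'
#' Clathrin centers uniform in the box with pairwise distance at least the
#' excluded diameter (rejection sampling), uniform random orientations, no
#' bonds, and the whole AP-2 pool free. Reproducible from the seed.
#'
#' @param config an [simulation_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return an [fcl_state()] at time 0.
#' @export
random_initial_condition <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_clathrin
  L <- config$box_edge
  d <- config$geometry$excluded_diameter
  # coarse packing feasibility: sphere volume fraction must stay dilute
  if (n * (4 / 3) * pi * (d / 2)^3 > 0.25 * L^3) {
    stop("packing infeasible: ", n, " clathrins at excluded diameter ", d,
         " nm do not fit in a ", L, " nm box")
  }
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  max_tries <- 1000L * max(n, 1L)
  while (placed < n) {
    p <- stats::runif(3, 0, L)
    ok <- placed == 0 ||
      min(colSums((t(pos[seq_len(placed), , drop = FALSE]) - p)^2)) >= d^2
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("packing infeasible: rejection sampling exhausted after ",
           max_tries, " draws")
    }
  }
  quat <- random_quaternion(n)
  fcl_state(pos, quat, ap2_free = config$n_ap2, ap2_total = config$n_ap2,
            time_us = 0)
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Write a trajectory to plain-text tables
#'
#' Writes `<prefix>_frames.csv` (one row per molecule per frame; bound
#' AP-2 appears as species `ap2` with id `n_clathrin + host id`),
#' `<prefix>_bonds.csv` (one row per clathrin-clathrin bond per frame) and
#' `<prefix>_manifest.yaml` (config snapshot, seed, version, MD5
#' checksums). Numeric columns carry full double precision.
#'
#' @param traj an `fcl_trajectory`.
#' @param prefix output path prefix.
#' @return invisibly, the manifest list.
#' @export
write_trajectory <- function(traj, prefix) {
  rows <- list()
  bonds <- list()
  geom <- traj$config$geometry
  for (k in seq_along(traj$frames)) {
    f <- traj$frames[[k]]
    n <- f$n_clathrin
    df <- data.frame(frame = k, time_us = fmt_full(f$time_us),
                     mol_id = seq_len(n), species = "clathrin",
                     x = fmt_full(f$pos[, 1]), y = fmt_full(f$pos[, 2]),
                     z = fmt_full(f$pos[, 3]),
                     qw = fmt_full(f$quat[, 1]), qx = fmt_full(f$quat[, 2]),
                     qy = fmt_full(f$quat[, 3]), qz = fmt_full(f$quat[, 4]))
    hosts <- which(f$ap2_bound != 0)
    if (length(hosts) > 0) {
      ap2pos <- t(vapply(hosts, function(i) {
        mol <- rigid_molecule(i, "clathrin", f$pos[i, ], f$quat[i, ])
        s <- site_world_coordinates(mol, geom)["ap2", ]
        c(s[1], s[2], 0)
      }, numeric(3)))
      df <- rbind(df, data.frame(
        frame = k, time_us = fmt_full(f$time_us),
        mol_id = n + hosts, species = "ap2",
        x = fmt_full(ap2pos[, 1]), y = fmt_full(ap2pos[, 2]),
        z = fmt_full(ap2pos[, 3]),
        qw = fmt_full(1), qx = fmt_full(0), qy = fmt_full(0),
        qz = fmt_full(0)))
    }
    rows[[k]] <- df
    if (nrow(f$bonds) > 0) {
      bonds[[k]] <- data.frame(frame = k, time_us = fmt_full(f$time_us),
                               mol_a = f$bonds[, "mol_a"],
                               site_a = f$bonds[, "site_a"],
                               mol_b = f$bonds[, "mol_b"],
                               site_b = f$bonds[, "site_b"])
    }
  }
  frames_file <- paste0(prefix, "_frames.csv")
  bonds_file <- paste0(prefix, "_bonds.csv")
  manifest_file <- paste0(prefix, "_manifest.yaml")
  utils::write.csv(do.call(rbind, rows), frames_file, row.names = FALSE,
                   quote = FALSE)
  bt <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(frame = integer(0), time_us = character(0),
               mol_a = integer(0), site_a = integer(0), mol_b = integer(0),
               site_b = integer(0))
  utils::write.csv(bt, bonds_file, row.names = FALSE, quote = FALSE)
  manifest <- list(
    format_version = 1L,
    package_version = as.character(utils::packageVersion("fclsim")),
    seed = traj$seed,
    n_frames = length(traj$frames),
    n_clathrin = traj$config$n_clathrin,
    time_start_us = traj$frames[[1]]$time_us,
    time_end_us = traj$frames[[length(traj$frames)]]$time_us,
    config = config_to_list(traj$config),
    checksums = list(
      frames = unname(tools::md5sum(frames_file)),
      bonds = unname(tools::md5sum(bonds_file))))
  yaml::write_yaml(manifest, manifest_file)
  invisible(manifest)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Verifies the manifest checksums before parsing; a truncated or edited
#' table raises a corruption error rather than loading silently.
#'
#' @param prefix path prefix used at write time.
#' @return an `fcl_trajectory` (config restored from the manifest
#'   snapshot; event log not persisted).
#' @export
read_trajectory <- function(prefix) {
  frames_file <- paste0(prefix, "_frames.csv")
  bonds_file <- paste0(prefix, "_bonds.csv")
  manifest_file <- paste0(prefix, "_manifest.yaml")
  if (!file.exists(manifest_file)) stop("missing manifest: ", manifest_file)
  manifest <- yaml::read_yaml(manifest_file)
  if (is.null(manifest$format_version) || manifest$format_version != 1) {
    stop("unsupported trajectory format version")
  }
  for (nm in c("frames", "bonds")) {
    f <- paste0(prefix, "_", nm, ".csv")
    if (!file.exists(f)) stop("missing trajectory table: ", f)
    if (!identical(unname(tools::md5sum(f)),
                   unname(unlist(manifest$checksums[[nm]])))) {
      stop("trajectory file corrupt (checksum mismatch): ", f)
    }
  }
  config <- config_from_list(manifest$config)
  fr <- utils::read.csv(frames_file)
  bt <- utils::read.csv(bonds_file)
  n <- manifest$n_clathrin
  frames <- lapply(seq_len(manifest$n_frames), function(k) {
    fk <- fr[fr$frame == k, , drop = FALSE]
    cl <- fk[fk$species == "clathrin", , drop = FALSE]
    cl <- cl[order(cl$mol_id), , drop = FALSE]
    hosts <- fk$mol_id[fk$species == "ap2"] - n
    ap2 <- integer(n)
    ap2[hosts] <- 1L
    bk <- bt[bt$frame == k, c("mol_a", "site_a", "mol_b", "site_b"),
             drop = FALSE]
    fcl_frame(time_us = cl$time_us[1],
              pos = as.matrix(cl[, c("x", "y", "z")]),
              quat = as.matrix(cl[, c("qw", "qx", "qy", "qz")]),
              ap2_bound = ap2,
              bonds = matrix(as.integer(as.matrix(bk)), ncol = 4),
              ap2_free = NA_integer_)
  })
  structure(list(frames = frames, config = config, seed = manifest$seed,
                 event_counts = NULL, events = NULL, final_state = NULL,
                 version = manifest$package_version),
            class = "fcl_trajectory")
}

# ---- configuration files ---------------------------------------------------

# numeric config fields are serialized as %.17g strings so a manifest
# restores the configuration (and hence the trajectory) bit-exactly
config_to_list <- function(config) {
  list(box_edge = fmt_full(config$box_edge), dt = fmt_full(config$dt),
       n_clathrin = config$n_clathrin, n_ap2 = config$n_ap2,
       duration = fmt_full(config$duration),
       frame_interval = fmt_full(config$frame_interval),
       seed = config$seed,
       reaction_radius = fmt_full(config$reaction_radius),
       capture_height = fmt_full(config$capture_height),
       max_retries = config$max_retries,
       temperature = fmt_full(config$env$temperature),
       viscosity = fmt_full(config$env$viscosity),
       d_clat = fmt_full(config$diffusion$clathrin$d_trans[1]),
       d_ap2_trans = fmt_full(config$diffusion$ap2$d_trans),
       d_ap2_rot = fmt_full(config$diffusion$ap2$d_rot),
       leg_radius = fmt_full(config$geometry$leg_radius),
       excluded_diameter = fmt_full(config$geometry$excluded_diameter),
       bond_gap = fmt_full(config$geometry$bond_gap),
       ap2_site_drop = fmt_full(-config$geometry$ap2_site_offset[3]),
       footprint_radius = fmt_full(config$geometry$footprint_radius),
       rates = lapply(unclass(config$rates), fmt_full),
       schedule = if (is.null(config$schedule)) NULL else
         config$schedule$breakpoints)
}

config_from_list <- function(x) {
  nm <- function(v) as.numeric(unlist(v))
  rates <- do.call(rate_table, lapply(x$rates, nm))
  env <- physical_environment(nm(x$temperature), nm(x$viscosity))
  geometry <- clathrin_geometry(
    leg_radius = nm(x$leg_radius),
    excluded_diameter = nm(x$excluded_diameter),
    bond_gap = nm(x$bond_gap), ap2_site_drop = nm(x$ap2_site_drop),
    footprint_radius = nm(x$footprint_radius))
  diffusion <- list(
    clathrin = clathrin_diffusion(env, nm(x$d_clat)),
    ap2 = if (!is.null(x$d_ap2_trans)) {
      diffusion_spec(nm(x$d_ap2_trans), nm(x$d_ap2_rot))
    } else ap2_diffusion(env))
  schedule <- if (is.null(x$schedule)) NULL else
    parameter_schedule(x$schedule)
  simulation_config(
    box_edge = nm(x$box_edge), dt = nm(x$dt), n_clathrin = x$n_clathrin,
    n_ap2 = x$n_ap2, rates = rates, env = env, geometry = geometry,
    diffusion = diffusion, duration = nm(x$duration),
    frame_interval = nm(x$frame_interval), seed = x$seed,
    schedule = schedule,
    reaction_radius = nm(x$reaction_radius),
    capture_height = nm(x$capture_height),
    max_retries = x$max_retries)
}

# parse "50x0.913 uM-1s-1" style values: optional multiplier, optional unit
parse_quantity <- function(x, field, unit_scale = NULL) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  parts <- strsplit(s, "\\s+")[[1]]
  num <- parts[1]
  val <- if (grepl("x", num, fixed = TRUE)) {
    f <- as.numeric(strsplit(num, "x", fixed = TRUE)[[1]])
    if (any(is.na(f))) stop("cannot parse value for ", field, ": ", s)
    prod(f)
  } else {
    v <- suppressWarnings(as.numeric(num))
    if (is.na(v)) stop("cannot parse value for ", field, ": ", s)
    v
  }
  if (length(parts) > 1) {
    unit <- parts[2]
    if (is.null(unit_scale) || is.null(unit_scale[[unit]])) {
      stop("unknown unit '", unit, "' for ", field)
    }
    val <- val * unit_scale[[unit]]
  }
  val
}

time_units <- list(us = 1, ms = 1e3, s = 1e6, min = 6e7)
length_units <- list(nm = 1, um = 1e3)
rate2_units <- list(`uM-1s-1` = 1)
rate1_units <- list(`s-1` = 1)

#' Parse a simulation configuration file
#'
#' Structured YAML with explicit units; values may be plain numbers (native
#' units: nm, us, uM^-1 s^-1, s^-1), `"NUMBER unit"` strings, or
#' `"AxB unit"` multiplier shorthand (e.g. `"50x0.913 uM-1s-1"`). Unknown
#' keys are rejected. Omitted fields take the package defaults; leaving the
#' placeholder dissociation rates at their defaults triggers a warning,
#' since those values are not calibrated.
#'
#' @param file path to a YAML configuration.
#' @return an [simulation_config()]; any `sweep` block is attached as
#'   attribute `"sweep"`.
#' @export
parse_config <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  x <- yaml::read_yaml(file)
  allowed <- c("box_edge", "dt", "n_clathrin", "n_ap2", "duration",
               "frame_interval", "seed", "reaction_radius",
               "capture_height", "max_retries", "temperature", "viscosity",
               "d_clat", "r_ap2", "leg_radius", "excluded_diameter",
               "bond_gap", "ap2_site_drop", "footprint_radius", "rates",
               "schedule", "sweep")
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  num <- function(key, default, units = NULL, positive = FALSE) {
    v <- if (is.null(x[[key]])) default else
      parse_quantity(x[[key]], key, units)
    if (positive && v <= 0) stop("config field ", key, " must be positive")
    v
  }
  env <- physical_environment(num("temperature", 298.15),
                              num("viscosity", 8.9e-4))
  geometry <- clathrin_geometry(
    leg_radius = num("leg_radius", 12.5, length_units, TRUE),
    excluded_diameter = num("excluded_diameter", 10, length_units, TRUE),
    bond_gap = num("bond_gap", 5, length_units, TRUE),
    ap2_site_drop = num("ap2_site_drop", 2, length_units, TRUE),
    footprint_radius = num("footprint_radius", 12.5, length_units, TRUE))
  rk_allowed <- c("k_cc_gated", "k_cc_free", "k_ap2_clat", "koff_cc",
                  "koff_ap2_clat")
  rk <- x$rates
  if (!is.null(rk)) {
    bad <- setdiff(names(rk), rk_allowed)
    if (length(bad)) stop("unknown rate field(s): ", paste(bad, collapse = ", "))
  }
  rnum <- function(key, default, units) {
    if (is.null(rk[[key]])) default else parse_quantity(rk[[key]], key, units)
  }
  if (is.null(rk$koff_cc) || is.null(rk$koff_ap2_clat)) {
    warning("dissociation rate(s) not specified: using the placeholder ",
            "defaults (koff_cc = 1 s-1, koff_ap2_clat = 0.1 s-1)",
            call. = FALSE)
  }
  rates <- rate_table(
    k_cc_gated = rnum("k_cc_gated", 50 * 0.913, rate2_units),
    k_cc_free = rnum("k_cc_free", 0, rate2_units),
    k_ap2_clat = rnum("k_ap2_clat", 0.0012, rate2_units),
    koff_cc = rnum("koff_cc", 1, rate1_units),
    koff_ap2_clat = rnum("koff_ap2_clat", 0.1, rate1_units))
  diffusion <- list(
    clathrin = clathrin_diffusion(env, num("d_clat", 13)),
    ap2 = ap2_diffusion(env, num("r_ap2", 10, length_units, TRUE)))
  schedule <- if (is.null(x$schedule)) NULL else {
    parameter_schedule(lapply(x$schedule, function(b) {
      b$time <- parse_quantity(b$time, "schedule time", time_units)
      b
    }))
  }
  cfg <- simulation_config(
    box_edge = num("box_edge", 1000, length_units, TRUE),
    dt = num("dt", 3, time_units, TRUE),
    n_clathrin = num("n_clathrin", 300),
    n_ap2 = num("n_ap2", 150),
    rates = rates, env = env, geometry = geometry, diffusion = diffusion,
    duration = num("duration", 1e6, time_units, TRUE),
    frame_interval = num("frame_interval", 1e5, time_units, TRUE),
    seed = num("seed", 1), schedule = schedule,
    reaction_radius = num("reaction_radius", 1, length_units, TRUE),
    capture_height = num("capture_height", 10, length_units, TRUE),
    max_retries = num("max_retries", 100))
  if (!is.null(x$sweep)) attr(cfg, "sweep") <- x$sweep
  cfg
}

#' Desk-scale analog of a full-scale AP-2 sweep condition
#'
#' The desk-scale study conditions (see the shipped `desk_small.yaml`) use a
#' quarter of the full membrane area (500 nm box edge), 60 clathrins and
#' rate constants scaled so assembly, exchange and disassembly play out
#' within a few simulated seconds. AP-2 numbers are scaled by membrane
#' area, so the analog of a full-scale sweep value `n_ap2_full` is
#' `round(n_ap2_full / 4)`.
#'
#' @param n_ap2_full AP-2 number of the full-scale condition (1 um box).
#' @param seed run seed.
#' @param duration simulated time, us.
#' @return an [simulation_config()].
#' @export
desk_condition <- function(n_ap2_full, seed = 1, duration = 3e6) {
  cfg <- parse_config(reference_config("desk_small"))
  cfg$n_ap2 <- as.integer(round(n_ap2_full / 4))
  cfg$seed <- as.integer(seed)
  cfg$duration <- duration
  cfg
}

#' Path to a shipped reference configuration
#'
#' @param name one of `"baseline"`, `"sweep_ap2"`, `"egf_protocol4"`,
#'   `"desk_small"`.
#' @return file path inside the installed package.
#' @export
reference_config <- function(name = c("baseline", "sweep_ap2",
                                      "egf_protocol4", "desk_small")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".yaml"), package = "fclsim",
              mustWork = TRUE)
}
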