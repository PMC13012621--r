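#' Physical environment for Stokes-Einstein diffusion
#'
#' Holds the temperature and solvent viscosity used to derive translational
#' and rotational diffusion coefficients. The solvent is assumed to be water
#' at room temperature unless overridden.
#'
#' @param temperature absolute temperature in kelvin.
#' @param viscosity dynamic viscosity in Pa s.
#' @return an object of class `fcl_environment`.
#' @export
physical_environment <- function(temperature = 298.15, viscosity = 8.9e-4) {
  stopifnot(is.numeric(temperature), length(temperature) == 1,
            is.numeric(viscosity), length(viscosity) == 1)
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  if (viscosity <= 0) stop("viscosity must be positive (Pa s)")
  structure(list(temperature = temperature,
                 viscosity = viscosity,
                 boltzmann_constant = 1.380649e-23),
            class = "fcl_environment")
}

#' Stokes-Einstein diffusion coefficient
#'
#' Translational: `k_B T / (6 pi eta r)`; rotational: `k_B T / (8 pi eta r^3)`.
#' Results are returned in the package's internal units, nm^2/us for
#' translation (numerically equal to um^2/s) and rad^2/us for rotation.
#'
#' @param radius hydrodynamic radius in nm.
#' @param env a [physical_environment()].
#' @param mode `"translational"` or `"rotational"`.
#' @return diffusion coefficient (nm^2/us or rad^2/us).
#' @examples
#' env <- physical_environment()
#' stokes_einstein(1, env, "translational") # ~245 nm^2/us for a 1 nm sphere
#' @export
stokes_einstein <- function(radius, env, mode = c("translational", "rotational")) {
  mode <- match.arg(mode)
  if (!is.numeric(radius) || any(radius <= 0)) {
    stop("radius must be positive (nm)")
  }
  kBT <- env$boltzmann_constant * env$temperature
  r_m <- radius * 1e-9
  if (mode == "translational") {
    d_si <- kBT / (6 * pi * env$viscosity * r_m)    # m^2/s
    d_si * 1e12                                     # nm^2/us
  } else {
    d_si <- kBT / (8 * pi * env$viscosity * r_m^3)  # rad^2/s
    d_si * 1e-6                                     # rad^2/us
  }
}

#' Invert the translational Stokes-Einstein relation
#'
#' Radius (nm) of a sphere with translational diffusion coefficient
#' `d_trans` (nm^2/us) in the given environment. Used to derive a
#' self-consistent rotational coefficient for a species whose translational
#' coefficient is specified directly.
#'
#' @param d_trans translational diffusion coefficient, nm^2/us.
#' @param env a [physical_environment()].
#' @return hydrodynamic radius in nm.
#' @export
stokes_einstein_radius <- function(d_trans, env) {
  if (d_trans <= 0) stop("d_trans must be positive")
  kBT <- env$boltzmann_constant * env$temperature
  kBT / (6 * pi * env$viscosity * d_trans * 1e12) * 1e9
}

#' Per-axis diffusion specification
#'
#' Diffusion is anisotropic per axis: membrane-confined AP-2 has zero
#' z-translation and zero x/y-axis rotation, which composes into clusters as
#' zero components (a membrane-bound cluster cannot leave the membrane).
#'
#' @param d_trans length-3 numeric, translational coefficients (x, y, z) in
#'   nm^2/us.
#' @param d_rot length-3 numeric, rotational coefficients about the x, y, z
#'   axes in rad^2/us.
#' @return an object of class `fcl_diffusion_spec`.
#' @export
diffusion_spec <- function(d_trans, d_rot) {
  stopifnot(length(d_trans) == 3, length(d_rot) == 3)
  if (any(d_trans < 0) || any(d_rot < 0)) {
    stop("diffusion coefficients must be non-negative")
  }
  structure(list(d_trans = as.numeric(d_trans), d_rot = as.numeric(d_rot)),
            class = "fcl_diffusion_spec")
}

#' Default clathrin diffusion specification
#'
#' Isotropic translation at `d_iso` (13 um^2/s by default); the rotational
#' coefficient is derived through Stokes-Einstein from the radius implied by
#' `d_iso`, so the pair is hydrodynamically self-consistent.
#'
#' @param env a [physical_environment()].
#' @param d_iso isotropic translational coefficient, nm^2/us (= um^2/s).
#' @return an `fcl_diffusion_spec`.
#' @export
clathrin_diffusion <- function(env = physical_environment(), d_iso = 13) {
  r <- stokes_einstein_radius(d_iso, env)
  dr <- stokes_einstein(r, env, "rotational")
  diffusion_spec(rep(d_iso, 3), rep(dr, 3))
}

#' Default AP-2 diffusion specification
#'
#' AP-2 is a zero-volume dot confined to the membrane: translation in x and y
#' only, rotation about z only. In-plane coefficients follow Stokes-Einstein
#' at hydrodynamic radius `r_ap2`.
#'
#' @param env a [physical_environment()].
#' @param r_ap2 hydrodynamic radius in nm.
#' @return an `fcl_diffusion_spec` with `d_trans[3] = 0`,
#'   `d_rot[1] = d_rot[2] = 0`.
#' @export
ap2_diffusion <- function(env = physical_environment(), r_ap2 = 10) {
  dt <- stokes_einstein(r_ap2, env, "translational")
  dr <- stokes_einstein(r_ap2, env, "rotational")
  diffusion_spec(c(dt, dt, 0), c(0, 0, dr))
}

#' Compose the diffusion coefficient of a rigid cluster
#'
#' A bound assembly diffuses as one unit. Assuming the effective
#' hydrodynamic radius of the cluster is the sum of member radii, the
#' per-axis translational coefficient is the harmonic-style composition
#' `D = (sum_i 1/D_i)^-1` and the rotational one is
#' `D_R = (sum_i D_R,i^(-1/3))^-3`. A zero member component (membrane
#' confinement) forces the corresponding cluster component to zero.
#'
#' @param members non-empty list of [diffusion_spec()] objects.
#' @return composed `fcl_diffusion_spec`.
#' @examples
#' env <- physical_environment()
#' cl <- clathrin_diffusion(env)
#' compose_cluster_diffusion(list(cl, cl))$d_trans  # D/2 per axis
#' @export
compose_cluster_diffusion <- function(members) {
  if (length(members) == 0) stop("members must be a non-empty list")
  trans <- vapply(members, function(m) m$d_trans, numeric(3))
  rot <- vapply(members, function(m) m$d_rot, numeric(3))
  comp_trans <- apply(trans, 1, function(d) {
    if (any(d == 0)) 0 else 1 / sum(1 / d)
  })
  comp_rot <- apply(rot, 1, function(d) {
    if (any(d == 0)) 0 else sum(d^(-1 / 3))^(-3)
  })
  diffusion_spec(comp_trans, comp_rot)
}

#' Clathrin triskelion geometry
#'
#' The rigid clathrin body: three clathrin-binding leg sites arranged as a
#' planar pinwheel at 120 degree spacing in the body x-y plane, and one
#' AP-2-binding site below the center along the body -z axis. The body
#' center and the three leg sites are coplanar; head-to-head leg binding at
#' the 5 nm bond gap then reproduces a planar lattice with ~30 nm
#' center-to-center spacing.
#'
#' @param leg_radius distance from body center to each leg site, nm.
#' @param excluded_diameter minimum allowed clathrin center-center
#'   distance, nm.
#' @param bond_gap site-site separation of a formed clathrin-clathrin
#'   bond, nm.
#' @param ap2_site_drop distance of the AP-2 site below the body center
#'   along -z, nm.
#' @param footprint_radius disc radius used when buffering projected cluster
#'   areas, nm.
#' @return an object of class `fcl_geometry` with `leg_site_offsets`
#'   (3 x 3 matrix, one row per leg) and `ap2_site_offset` (length 3).
#' @export
clathrin_geometry <- function(leg_radius = 12.5, excluded_diameter = 10,
                              bond_gap = 5, ap2_site_drop = 2,
                              footprint_radius = 12.5) {
  if (excluded_diameter <= 0) stop("excluded_diameter must be positive")
  if (bond_gap <= 0) stop("bond_gap must be positive")
  if (leg_radius <= 0) stop("leg_radius must be positive")
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  legs <- cbind(leg_radius * cos(ang), leg_radius * sin(ang), 0)
  rownames(legs) <- paste0("leg", 1:3)
  structure(list(leg_site_offsets = legs,
                 ap2_site_offset = c(0, 0, -ap2_site_drop),
                 leg_radius = leg_radius,
                 excluded_diameter = excluded_diameter,
                 bond_gap = bond_gap,
                 footprint_radius = footprint_radius),
            class = "fcl_geometry")
}

#' Construct a rigid molecule
#'
#' @param id integer molecule id.
#' @param species `"clathrin"` or `"ap2"`.
#' @param position length-3 numeric, nm. AP-2 must sit on the membrane
#'   (z = 0).
#' @param orientation unit quaternion `c(w, x, y, z)`.
#' @param bonds list of `c(own_site, partner_id, partner_site)` triples.
#' @return an object of class `fcl_molecule`.
#' @export
rigid_molecule <- function(id, species = c("clathrin", "ap2"),
                           position = c(0, 0, 0),
                           orientation = c(1, 0, 0, 0),
                           bonds = list()) {
  species <- match.arg(species)
  stopifnot(length(position) == 3, length(orientation) == 4)
  if (abs(sqrt(sum(orientation^2)) - 1) > 1e-9) {
    stop("orientation must be a unit quaternion (|q| = 1 within 1e-9)")
  }
  if (species == "ap2" && abs(position[3]) > 1e-9) {
    stop("an AP-2 molecule must lie on the membrane (z = 0)")
  }
  own <- vapply(bonds, `[`, numeric(1), 1)
  if (anyDuplicated(own)) stop("each site can be bound at most once")
  structure(list(id = as.integer(id), species = species,
                 position = as.numeric(position),
                 orientation = as.numeric(orientation),
                 bonds = bonds),
            class = "fcl_molecule")
}

#' World coordinates of a clathrin's binding sites
#'
#' @param mol an `fcl_molecule` of species clathrin.
#' @param geom a [clathrin_geometry()].
#' @return 4 x 3 matrix: rows `leg1`, `leg2`, `leg3`, `ap2`.
#' @export
site_world_coordinates <- function(mol, geom) {
  offsets <- rbind(geom$leg_site_offsets, ap2 = geom$ap2_site_offset)
  world <- quat_rotate(mol$orientation, offsets)
  world <- sweep(world, 2, mol$position, `+`)
  rownames(world) <- c("leg1", "leg2", "leg3", "ap2")
  world
}

#' Pose a binding partner for an accepted association event
#'
#' For `clathrin_clathrin`, returns a new clathrin bound head-to-head at leg
#' site `site_index` of `mol`: the two bound sites are separated by exactly
#' `bond_gap` along the leg axis, both body centers and all six leg sites lie
#' in `mol`'s leg plane, and the partner's AP-2 site points to the same side
#' of that plane as `mol`'s. For `clathrin_ap2`, `mol` (a clathrin) is
#' re-oriented so its AP-2-site axis is perpendicular to the membrane with
#' the site on the membrane plane, preserving its in-plane heading, and an
#' AP-2 molecule is instantiated at z = 0 directly beneath the site.
#'
#' @param mol the already-placed clathrin (`fcl_molecule`).
#' @param site_index leg site (1-3) of `mol` involved in the bond; ignored
#'   for `clathrin_ap2`.
#' @param kind `"clathrin_clathrin"` or `"clathrin_ap2"`.
#' @param geom a [clathrin_geometry()].
#' @param partner_id id for the newly created molecule.
#' @return for `clathrin_clathrin`, the partner `fcl_molecule` (clathrin,
#'   bound via its leg 1); for `clathrin_ap2`, a list with elements
#'   `clathrin` (the re-oriented input) and `ap2` (the new membrane dot).
#' @export
place_bound_partner <- function(mol, site_index, kind = c("clathrin_clathrin",
                                                          "clathrin_ap2"),
                                geom = clathrin_geometry(), partner_id = NA) {
  kind <- match.arg(kind)
  if (mol$species != "clathrin") stop("mol must be a clathrin")
  R_a <- quat_to_matrix(mol$orientation)
  if (kind == "clathrin_clathrin") {
    if (!site_index %in% 1:3) stop("site_index must be a leg site (1-3)")
    site_a <- as.numeric(mol$position +
                           R_a %*% geom$leg_site_offsets[site_index, ])
    u <- site_a - mol$position
    u <- u / sqrt(sum(u * u))
    n <- R_a[, 3]
    center_b <- mol$position + (2 * geom$leg_radius + geom$bond_gap) * u
    if (sqrt(sum((center_b - mol$position)^2)) < geom$excluded_diameter) {
      stop("placement failure: partner overlaps the excluded volume")
    }
    # partner leg 1 points back along -u; shared plane normal n; same-side
    # AP-2 axis
    x_b <- -u
    z_b <- n
    y_b <- c(z_b[2] * x_b[3] - z_b[3] * x_b[2],
             z_b[3] * x_b[1] - z_b[1] * x_b[3],
             z_b[1] * x_b[2] - z_b[2] * x_b[1])
    R_b <- cbind(x_b, y_b, z_b)
    rigid_molecule(partner_id, "clathrin", center_b, quat_from_matrix(R_b),
                   bonds = list(c(1, mol$id, site_index)))
  } else {
    bx <- R_a[, 1]
    xy <- c(bx[1], bx[2], 0)
    if (sqrt(sum(xy^2)) < 1e-9) xy <- c(1, 0, 0)
    x_hat <- xy / sqrt(sum(xy^2))
    z_hat <- c(0, 0, 1)
    y_hat <- c(-x_hat[2], x_hat[1], 0)
    R_new <- cbind(x_hat, y_hat, z_hat)
    drop <- -geom$ap2_site_offset[3]
    center <- c(mol$position[1], mol$position[2], drop)
    clat <- rigid_molecule(mol$id, "clathrin", center,
                           quat_from_matrix(R_new), bonds = mol$bonds)
    ap2 <- rigid_molecule(partner_id, "ap2",
                          c(center[1], center[2], 0),
                          bonds = list(c(1, mol$id, 4)))
    list(clathrin = clat, ap2 = ap2)
  }
}
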