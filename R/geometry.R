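# Coarse-grained Fo geometry: the rotating c-ring carries one proton-binding
# glutamate per subunit at mid-membrane; the stator a-subunit carries the two
# half-channel glutamates (IMS side and matrix side) and the conserved
# arginine that separates them. c-site coordinates live in the ring body
# frame and rotate with phi; a-subunit sites live in the stator frame.
#
# Conventions: right-handed frame, ring axis = +z toward the matrix side,
# azimuth counter-clockwise viewed from the matrix, ATP-synthesis rotation =
# positive phi. Angles in degrees at the interface, distances in Angstrom.

SITE_ROLES <- c("c_carrier", "channel_ims", "channel_matrix", "arginine")

#' Construct a ring rotation state
#'
#' @param phi Ring rotation angle in degrees (wrapped to `[0, 360)`).
#' @param phi_cumulative Unwrapped cumulative rotation in degrees; must equal
#'   `phi` modulo 360.
#' @param bead_coords Optional per-residue C-alpha coordinate matrix
#'   (elastic-network mode only).
#' @return An object of class `ring_state`.
#' @export
ring_state <- function(phi = 0, phi_cumulative = phi, bead_coords = NULL) {
  stopifnot(is.numeric(phi), length(phi) == 1L)
  if (abs(wrap180(phi_cumulative - phi)) > 1e-9) {
    stop("phi_cumulative must equal phi modulo 360")
  }
  structure(list(phi = wrap360(phi), phi_cumulative = phi_cumulative,
                 bead_coords = bead_coords),
            class = "ring_state")
}

# body-frame azimuth (deg) of each site row
.body_azimuth <- function(sites) wrap360(rad2deg(atan2(sites$y, sites$x)))

#' Build an idealized synthetic Fo geometry
#'
#' Places `n_c` proton-carrier sites uniformly on a ring of radius
#' `ring_radius` at mid-membrane (z = 0), the conserved arginine at stator
#' azimuth 0 deg, and the two half-channel glutamates at `channel_offsets`
#' degrees on either side of the arginine, slightly outside the ring.
#' Side-chain direction vectors point radially outward for c-sites and
#' radially inward for a-subunit sites. The result is deterministic for
#' fixed arguments (`jitter_sd = 0`).
#'
#' The default layout puts each half-channel glutamate 25 deg on either
#' side of the arginine and close to the carrier track (3 Angstrom radial
#' gap, so a carrier rotated onto a channel azimuth reaches hydrogen-bond
#' contact), while the arginine guanidinium sits farther out (6 Angstrom
#' radial gap): its attraction to a deprotonated carrier is then a broad,
#' moderate well that localizes the charge between the two channels
#' without freezing the ring (see the methods vignette).
#'
#' @param n_c Number of c-subunits (>= 3); 10 for the mitochondrial c10-ring.
#' @param ring_radius Radius of the carrier-site circle, Angstrom.
#' @param channel_offsets Named pair `c(ims = , matrix = )` of stator azimuths
#'   (degrees, relative to the arginine) of the two half-channel sites; they
#'   must lie on opposite sides of the arginine and inside `a_sector`.
#' @param slab Membrane slab `[z_min, z_max]`, Angstrom.
#' @param a_sector Angular interval (degrees, relative to the arginine
#'   azimuth) within which a c-site faces the a-subunit rather than lipid.
#' @param sector_switch Width (degrees) of the smooth switch between the
#'   a-facing and lipid-facing regimes at each sector boundary.
#' @param channel_radial_offset Radial offset of the half-channel sites
#'   beyond `ring_radius`, Angstrom.
#' @param arg_radial_offset Radial offset of the conserved arginine beyond
#'   `ring_radius`, Angstrom.
#' @param jitter_sd Optional Gaussian jitter (Angstrom) on site positions.
#' @param seed Optional integer seed; only consulted when `jitter_sd > 0`.
#' @return An object of class `fo_geometry`.
#' @export
build_synthetic_geometry <- function(n_c = 10, ring_radius = 25,
                                     channel_offsets = c(ims = 25, matrix = -25),
                                     slab = c(-15, 15),
                                     a_sector = c(-50, 50),
                                     sector_switch = 10,
                                     channel_radial_offset = 3,
                                     arg_radial_offset = 6,
                                     jitter_sd = 0, seed = NULL) {
  stopifnot(n_c >= 3, ring_radius > 0, length(channel_offsets) == 2L,
            length(slab) == 2L, slab[1] < slab[2],
            length(a_sector) == 2L, a_sector[1] < a_sector[2])
  if (is.null(names(channel_offsets))) names(channel_offsets) <- c("ims", "matrix")
  if (diff(a_sector) >= 180) stop("a_sector must span less than 180 degrees")

  az_c <- (seq_len(n_c) - 1L) * 360 / n_c
  labels <- letters[seq_len(n_c)]

  pos <- function(az, r, z) c(r * cos(deg2rad(az)), r * sin(deg2rad(az)), z)
  rows <- vector("list", n_c + 3L)
  for (k in seq_len(n_c)) {
    p <- pos(az_c[k], ring_radius, 0)
    d <- c(cos(deg2rad(az_c[k])), sin(deg2rad(az_c[k])), 0)  # outward
    rows[[k]] <- data.frame(site_id = k, role = "c_carrier",
                            subunit_label = labels[k],
                            x = p[1], y = p[2], z = p[3],
                            dirx = d[1], diry = d[2], dirz = d[3])
  }
  a_def <- list(channel_ims = channel_offsets[["ims"]],
                channel_matrix = channel_offsets[["matrix"]],
                arginine = 0)
  a_r <- c(rep(ring_radius + channel_radial_offset, 2),
           ring_radius + arg_radial_offset)
  for (m in seq_along(a_def)) {
    az <- a_def[[m]]
    p <- pos(az, a_r[m], 0)
    d <- -c(cos(deg2rad(az)), sin(deg2rad(az)), 0)           # inward
    rows[[n_c + m]] <- data.frame(site_id = n_c + m, role = names(a_def)[m],
                                  subunit_label = NA_character_,
                                  x = p[1], y = p[2], z = p[3],
                                  dirx = d[1], diry = d[2], dirz = d[3])
  }
  sites <- do.call(rbind, rows)

  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    sites[, c("x", "y", "z")] <- sites[, c("x", "y", "z")] +
      matrix(rnorm(3 * nrow(sites), sd = jitter_sd), ncol = 3)
  }

  geom <- structure(list(
    sites = sites, n_c = as.integer(n_c),
    ring_axis = c(0, 0, 1), ring_radius = ring_radius,
    membrane_slab = slab, arg_azimuth = 0,
    a_sector = a_sector, sector_switch = sector_switch
  ), class = "fo_geometry")
  geom$theta_ref <- .reference_transfer_angle(geom)
  validate_geometry(geom)
  geom
}

# angle (deg) between the IMS channel side chain and that of its nearest
# c-site at phi = 0; used as the Gaussian center of the transfer-angle gate
.reference_transfer_angle <- function(geom) {
  s <- geom$sites
  ims <- s[s$role == "channel_ims", ]
  cc <- s[s$role == "c_carrier", ]
  d2 <- (cc$x - ims$x)^2 + (cc$y - ims$y)^2 + (cc$z - ims$z)^2
  k <- which.min(d2)
  v1 <- c(ims$dirx, ims$diry, ims$dirz)
  v2 <- c(cc$dirx[k], cc$diry[k], cc$dirz[k])
  rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2)))))
}

#' Validate an fo_geometry object
#'
#' Checks the structural invariants: unit side-chain vectors, exactly one
#' site per a-subunit role, all c-carriers on the ring radius, and both
#' channels plus the arginine inside the a-facing sector.
#'
#' @param geom An `fo_geometry`.
#' @param radius_tol Allowed deviation of c-carrier radial distance from
#'   `ring_radius`, Angstrom.
#' @return `geom`, invisibly; errors describe the offending site.
#' @export
validate_geometry <- function(geom, radius_tol = 0.5) {
  s <- geom$sites
  norms <- sqrt(s$dirx^2 + s$diry^2 + s$dirz^2)
  if (any(abs(norms - 1) > 1e-9)) {
    stop("side-chain direction not unit length for site(s) ",
         paste(s$site_id[abs(norms - 1) > 1e-9], collapse = ", "))
  }
  for (role in c("channel_ims", "channel_matrix", "arginine")) {
    if (sum(s$role == role) != 1L) stop("expected exactly one ", role, " site")
  }
  cc <- s[s$role == "c_carrier", ]
  rr <- sqrt(cc$x^2 + cc$y^2)
  if (any(abs(rr - geom$ring_radius) > radius_tol)) {
    stop("c-carrier site(s) off the ring radius: ",
         paste(cc$site_id[abs(rr - geom$ring_radius) > radius_tol], collapse = ", "))
  }
  for (role in c("channel_ims", "channel_matrix")) {
    az <- wrap180(.body_azimuth(s[s$role == role, ]) - geom$arg_azimuth)
    if (az <= geom$a_sector[1] || az >= geom$a_sector[2]) {
      stop("site ", role, " lies outside the a-subunit-facing sector")
    }
  }
  off_ims <- wrap180(.body_azimuth(s[s$role == "channel_ims", ]) - geom$arg_azimuth)
  off_mat <- wrap180(.body_azimuth(s[s$role == "channel_matrix", ]) - geom$arg_azimuth)
  if (sign(off_ims) == sign(off_mat)) {
    stop("channel sites must lie on opposite azimuthal sides of the arginine")
  }
  invisible(geom)
}

#' Carrier-site ordering of the protonation vector
#'
#' Returns the site ids of all proton-carrier sites in the canonical order
#' used by [protonation_state()]: the `n_c` c-ring carriers (subunit a, b,
#' ...), then the IMS-channel glutamate, then the matrix-channel glutamate.
#'
#' @param geom An `fo_geometry`.
#' @return Integer vector of site ids (length `n_c + 2`).
#' @export
carrier_ids <- function(geom) {
  s <- geom$sites
  c(s$site_id[s$role == "c_carrier"][order(s$subunit_label[s$role == "c_carrier"])],
    s$site_id[s$role == "channel_ims"],
    s$site_id[s$role == "channel_matrix"])
}

# stator-frame azimuths (deg) of every site at ring rotation phi;
# c-sites co-rotate, a-subunit sites do not
stator_azimuths <- function(geom, phi) {
  az <- .body_azimuth(geom$sites)
  rot <- geom$sites$role == "c_carrier"
  az[rot] <- wrap360(az[rot] + phi)
  az
}

# right-multiplication matrix rotating row vectors by +a about +z
.rot_z <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# stator-frame positions (n x 3) of every site at ring rotation phi
stator_positions <- function(geom, phi) {
  s <- geom$sites
  xyz <- as.matrix(s[, c("x", "y", "z")])
  rot <- s$role == "c_carrier"
  if (any(rot)) {
    xyz[rot, ] <- xyz[rot, , drop = FALSE] %*% .rot_z(deg2rad(phi))
  }
  xyz
}

# stator-frame side-chain directions at ring rotation phi
stator_dirs <- function(geom, phi) {
  s <- geom$sites
  d <- as.matrix(s[, c("dirx", "diry", "dirz")])
  rot <- s$role == "c_carrier"
  if (any(rot)) {
    d[rot, ] <- d[rot, , drop = FALSE] %*% .rot_z(deg2rad(phi))
  }
  d
}

#' Stator-frame azimuth of a site under a ring rotation
#'
#' c-ring sites co-rotate with `phi`; a-subunit sites are fixed in the
#' stator frame.
#'
#' @param site Site id (integer) into `geom$sites`.
#' @param ring A [ring_state()].
#' @param geom An `fo_geometry`.
#' @return Azimuth in degrees, in `[0, 360)`.
#' @export
site_azimuth <- function(site, ring, geom) {
  i <- match(site, geom$sites$site_id)
  if (is.na(i)) stop("unknown site id: ", site)
  stator_azimuths(geom, ring$phi)[i]
}

# smooth cubic step: 0 for x<=0, 1 for x>=1
.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

# lipid-facing weight as a function of stator azimuth (deg), vectorized
lipid_weight_az <- function(az, geom) {
  delta <- wrap180(az - geom$arg_azimuth)
  lo <- geom$a_sector[1]; hi <- geom$a_sector[2]; s <- geom$sector_switch
  x <- ifelse(delta >= 0, (delta - hi) / s + 0.5, (lo - delta) / s + 0.5)
  .smoothstep(x)
}

#' Degree to which a c-site faces the lipid membrane
#'
#' 0 deep inside the a-subunit-facing sector, 1 deep in the lipid-facing
#' sector, with a smooth monotone switch of width `sector_switch` across
#' each sector boundary. A deprotonated (charged) carrier pays the membrane
#' burial penalty in proportion to this weight.
#'
#' @inheritParams site_azimuth
#' @return Weight in `[0, 1]`.
#' @export
lipid_facing_weight <- function(site, ring, geom) {
  i <- match(site, geom$sites$site_id)
  if (is.na(i)) stop("unknown site id: ", site)
  if (geom$sites$role[i] != "c_carrier") stop("site ", site, " is not a c_carrier")
  lipid_weight_az(site_azimuth(site, ring, geom), geom)
}

#' Does the arc between two sites straddle the conserved arginine?
#'
#' TRUE iff the arginine azimuth lies strictly inside the shorter azimuthal
#' arc between the two sites at the current ring rotation. Proton transfer
#' across the arginine is blocked in the wild type (the leakage gate).
#'
#' @param i,j Site ids of the two (distinct) sites.
#' @inheritParams site_azimuth
#' @return Logical scalar; symmetric in `i` and `j`.
#' @export
straddles_arginine <- function(i, j, ring, geom) {
  if (i == j) stop("straddles_arginine requires two distinct sites")
  az <- stator_azimuths(geom, ring$phi)
  ii <- match(i, geom$sites$site_id); jj <- match(j, geom$sites$site_id)
  if (is.na(ii) || is.na(jj)) stop("unknown site id")
  .straddles_az(az[ii], az[jj], geom$arg_azimuth)
}

.straddles_az <- function(a1, a2, aR) {
  d12 <- wrap180(a2 - a1)
  dR <- wrap180(aR - a1)
  if (abs(abs(d12) - 180) < 1e-9) {
    # antipodal sites: both arcs have equal length, so the arginine lies on
    # a "shorter" arc whenever it is not collinear with the pair
    return(abs(dR) > 1e-9 && abs(wrap180(aR - a2)) > 1e-9)
  }
  if (d12 > 0) (dR > 0 && dR < d12) else (dR < 0 && dR > d12)
}

#' @export
print.fo_geometry <- function(x, ...) {
  cat("fo_geometry:", x$n_c, "c-carrier sites, ring radius",
      format(x$ring_radius, digits = 4), "A\n")
  cat("  arginine azimuth", x$arg_azimuth, "deg; a-sector [",
      x$a_sector[1], ",", x$a_sector[2], "] deg; switch width",
      x$sector_switch, "deg\n")
  cat("  membrane slab [", x$membrane_slab[1], ",", x$membrane_slab[2], "] A\n")
  invisible(x)
}
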