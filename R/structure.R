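# Geometry extraction from experimental structures (C-alpha only) and
# plain-text geometry import/export.

#' Extract a coarse-grained Fo geometry from a PDB/mmCIF structure
#'
#' Reads C-alpha coordinates (model 1) with \pkg{bio3d}, places one bead per
#' residue, maps the configured proton-carrier residues (c-ring glutamates,
#' the two half-channel glutamates and the conserved arginine), fits the
#' ring axis and radius to the c-carrier positions by least squares, and
#' re-expresses everything in the package's standard frame (ring axis = +z,
#' arginine azimuth = 0). Side-chain directions are synthesized as radial
#' unit vectors (outward for c-sites, inward for a-subunit sites), since a
#' C-alpha model carries no explicit side chains.
#'
#' @param path Path to a PDB (`.pdb`) or mmCIF (`.cif`/`.mmcif`) file.
#' @param chain_map List with `c_chains` (chain ids of the c-subunits, in
#'   ring order; labelled a, b, ... in that order) and `a_chain` (the
#'   a-subunit chain id).
#' @param carrier_residue_ids List with residue numbers `c_carrier` (the
#'   carrier glutamate, same number in every c chain), `channel_ims`,
#'   `channel_matrix`, and `arginine` (all in `a_chain`).
#' @param slab,a_sector,sector_switch Membrane/sector parameters as in
#'   [build_synthetic_geometry()].
#' @param radius_tol Tolerance for the on-ring invariant check, Angstrom
#'   (experimental rings are not perfect circles).
#' @return An `fo_geometry` with per-residue `bead_coords`/`bead_info`
#'   attached for elastic-network use.
#' @export
load_ca_structure <- function(path, chain_map, carrier_residue_ids,
                              slab = c(-15, 15), a_sector = c(-50, 50),
                              sector_switch = 10, radius_tol = 2) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path)
         else bio3d::read.pdb(path)
  if (ext == "pdb") {
    n_models <- length(grep("^MODEL", readLines(path, warn = FALSE)))
    if (n_models > 1) warning("multiple models in ", path, "; using model 1")
  }
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no C-alpha records in ", path)

  find_ca <- function(chain, resno) {
    hit <- which(ca$chain == chain & ca$resno == resno)
    if (length(hit) == 0L) {
      stop("missing C-alpha for chain ", chain, " residue ", resno)
    }
    as.numeric(ca[hit[1], c("x", "y", "z")])
  }

  c_chains <- chain_map$c_chains
  a_chain <- chain_map$a_chain
  if (length(c_chains) < 3L) stop("chain_map$c_chains must name >= 3 c-subunit chains")
  c_pos <- t(vapply(c_chains, find_ca, numeric(3),
                    resno = carrier_residue_ids$c_carrier))
  a_pos <- rbind(
    channel_ims    = find_ca(a_chain, carrier_residue_ids$channel_ims),
    channel_matrix = find_ca(a_chain, carrier_residue_ids$channel_matrix),
    arginine       = find_ca(a_chain, carrier_residue_ids$arginine))

  # least-squares ring fit: plane through the carrier centroid (normal =
  # weakest principal direction), radius = mean in-plane distance
  center <- colMeans(c_pos)
  sv <- svd(sweep(c_pos, 2, center))
  axis <- sv$v[, 3]
  if (axis[3] < 0) axis <- -axis   # keep +z-ish orientation (matrix side up)

  # orthonormal stator frame with e3 = axis, e1 s.t. arginine azimuth = 0
  to_frame <- function(p, e1, e2, e3, origin) {
    q <- p - origin
    c(sum(q * e1), sum(q * e2), sum(q * e3))
  }
  seed_vec <- a_pos["arginine", ] - center
  seed_vec <- seed_vec - sum(seed_vec * axis) * axis
  if (sqrt(sum(seed_vec^2)) < 1e-6) stop("arginine lies on the ring axis")
  e1 <- seed_vec / sqrt(sum(seed_vec^2))
  e3 <- axis
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  # put the z origin at the c-carrier mid-plane
  origin <- center

  c_new <- t(apply(c_pos, 1, to_frame, e1 = e1, e2 = e2, e3 = e3, origin = origin))
  a_new <- t(apply(a_pos, 1, to_frame, e1 = e1, e2 = e2, e3 = e3, origin = origin))
  ring_radius <- mean(sqrt(c_new[, 1]^2 + c_new[, 2]^2))

  radial_dir <- function(p, outward = TRUE) {
    v <- c(p[1], p[2], 0)
    n <- sqrt(sum(v^2))
    if (n < 1e-9) stop("site on the ring axis; cannot synthesize direction")
    if (outward) v / n else -v / n
  }

  n_c <- length(c_chains)
  rows <- vector("list", n_c + 3L)
  for (k in seq_len(n_c)) {
    d <- radial_dir(c_new[k, ], TRUE)
    rows[[k]] <- data.frame(site_id = k, role = "c_carrier",
                            subunit_label = letters[k],
                            x = c_new[k, 1], y = c_new[k, 2], z = c_new[k, 3],
                            dirx = d[1], diry = d[2], dirz = d[3])
  }
  for (m in seq_len(3L)) {
    role <- rownames(a_new)[m]
    d <- radial_dir(a_new[m, ], FALSE)
    rows[[n_c + m]] <- data.frame(site_id = n_c + m, role = role,
                                  subunit_label = NA_character_,
                                  x = a_new[m, 1], y = a_new[m, 2], z = a_new[m, 3],
                                  dirx = d[1], diry = d[2], dirz = d[3])
  }
  sites <- do.call(rbind, rows)

  bead_xyz <- matrix(as.numeric(unlist(ca[, c("x", "y", "z")])), ncol = 3)
  bead_new <- t(apply(bead_xyz, 1, to_frame, e1 = e1, e2 = e2, e3 = e3,
                      origin = origin))

  geom <- structure(list(
    sites = sites, n_c = as.integer(n_c),
    ring_axis = c(0, 0, 1), ring_radius = ring_radius,
    membrane_slab = slab, arg_azimuth = 0,
    a_sector = a_sector, sector_switch = sector_switch,
    bead_coords = bead_new,
    bead_info = data.frame(chain = ca$chain, resno = ca$resno,
                           resid = ca$resid, stringsAsFactors = FALSE)
  ), class = "fo_geometry")
  geom$theta_ref <- .reference_transfer_angle(geom)
  validate_geometry(geom, radius_tol = radius_tol)
  geom
}

#' Write a geometry to a plain TSV file
#'
#' One row per site (site_id, role, subunit_label, position, side-chain
#' direction) plus `#`-prefixed header lines holding the scalar fields, so
#' the file round-trips through [read_geometry()].
#'
#' @param geom An `fo_geometry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  hdr <- c(
    sprintf("# n_c=%d", geom$n_c),
    sprintf("# ring_radius=%.10g", geom$ring_radius),
    sprintf("# membrane_slab=%.10g,%.10g", geom$membrane_slab[1], geom$membrane_slab[2]),
    sprintf("# arg_azimuth=%.10g", geom$arg_azimuth),
    sprintf("# a_sector=%.10g,%.10g", geom$a_sector[1], geom$a_sector[2]),
    sprintf("# sector_switch=%.10g", geom$sector_switch),
    sprintf("# theta_ref=%.10g", geom$theta_ref))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  s <- geom$sites
  num <- function(v) sprintf("%.10g", v)
  writeLines(paste("site_id", "role", "subunit_label", "x", "y", "z",
                   "dirx", "diry", "dirz", sep = "\t"), con)
  writeLines(paste(s$site_id, s$role, ifelse(is.na(s$subunit_label), ".",
                                             s$subunit_label),
                   num(s$x), num(s$y), num(s$z),
                   num(s$dirx), num(s$diry), num(s$dirz), sep = "\t"), con)
  invisible(path)
}

#' Read a geometry written by [write_geometry()]
#'
#' @param path Path to a geometry TSV.
#' @return An `fo_geometry`.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln) == 0L) stop("geometry file missing header field: ", key)
    as.numeric(strsplit(sub(paste0("^# ", key, "="), "", ln[1]), ",")[[1]])
  }
  body <- lines[!grepl("^#", lines)]
  sites <- read.table(text = body, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  sites$subunit_label[sites$subunit_label == "."] <- NA_character_
  geom <- structure(list(
    sites = sites, n_c = as.integer(get("n_c")),
    ring_axis = c(0, 0, 1), ring_radius = get("ring_radius"),
    membrane_slab = get("membrane_slab"), arg_azimuth = get("arg_azimuth"),
    a_sector = get("a_sector"), sector_switch = get("sector_switch"),
    theta_ref = get("theta_ref")
  ), class = "fo_geometry")
  validate_geometry(geom, radius_tol = Inf)
  geom
}
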