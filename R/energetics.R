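# Energy model, all terms in kBT:
#   V_total(R, H+) = V_non-es(R) + V_es(R, H+) + V_pKa(H+)
# V_non-es is the structure-maintaining term (zero for the rigid rotor,
# elastic-network energy in bead mode); V_es = screened Coulomb between all
# charged sites + membrane burial penalty for lipid-facing deprotonated
# carriers; V_pKa = -(ln 10) kBT pKa_i per *protonated* site, the intrinsic
# protonation preference.

#' Protonation state of the proton-carrier sites
#'
#' A binary occupancy vector over the `n_c + 2` carrier sites in the
#' canonical order of [carrier_ids()] (c-subunits a, b, ..., then the IMS
#' channel, then the matrix channel). An entry is 0 when the glutamate is
#' protonated (neutral) and 1 when it is deprotonated (charge -1).
#'
#' @param geom An `fo_geometry`.
#' @param h Integer vector of 0/1 of length `n_c + 2`; default all
#'   protonated.
#' @return An object of class `protonation_state`.
#' @export
protonation_state <- function(geom, h = rep(0L, geom$n_c + 2L)) {
  ids <- carrier_ids(geom)
  if (length(h) != length(ids)) {
    stop("h must have length ", length(ids), " (n_c + 2 carrier sites)")
  }
  if (!all(h %in% c(0L, 1L))) stop("h entries must be 0 (protonated) or 1 (deprotonated)")
  s <- geom$sites
  labs <- character(length(ids))
  for (k in seq_along(ids)) {
    i <- match(ids[k], s$site_id)
    labs[k] <- if (s$role[i] == "c_carrier") s$subunit_label[i] else s$role[i]
  }
  structure(as.integer(h), names = labs, carrier_ids = ids,
            class = "protonation_state")
}

#' @export
print.protonation_state <- function(x, ...) {
  cat("protonation state (0 = protonated, 1 = deprotonated):\n")
  print(setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Physical energy parameters
#'
#' All defaults follow the standard driving conditions of the model: IMS pH
#' 7.0, matrix pH 8.0, intrinsic pKa 6.0 (IMS channel aE223), 8.0 (carrier
#' cE59), 9.0 (matrix channel aE162), membrane potential 150 mV. The
#' screened-Coulomb and membrane-penalty settings are model choices
#' documented in the methods vignette.
#'
#' @param pH_ims,pH_matrix Bulk pH of the intermembrane space and matrix.
#' @param pKa Named list of intrinsic pKa values: `aE223` (IMS channel),
#'   `cE59` (c-ring carrier), `aE162` (matrix channel).
#' @param pKa_overrides Optional named numeric vector of per-subunit carrier
#'   pKa values (names = subunit letters), used by the Glu-to-Asp mutants.
#' @param delta_psi Membrane potential in mV (positive drives protons
#'   IMS to matrix).
#' @param temperature Temperature in Kelvin.
#' @param debye_length Debye screening length, Angstrom.
#' @param dielectric Uniform relative dielectric constant.
#' @param coulomb_cutoff Pair interaction cutoff, Angstrom.
#' @param membrane_penalty Burial penalty (kBT) for a fully lipid-facing
#'   deprotonated carrier.
#' @param charge_arginine Charge of the conserved arginine in elementary
#'   charges (0 after arginine-to-alanine mutation).
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(pH_ims = 7.0, pH_matrix = 8.0,
                          pKa = list(aE223 = 6.0, cE59 = 8.0, aE162 = 9.0),
                          pKa_overrides = NULL,
                          delta_psi = 150, temperature = 300,
                          debye_length = 10, dielectric = 20,
                          coulomb_cutoff = 30, membrane_penalty = 8,
                          charge_arginine = 1) {
  stopifnot(temperature > 0, debye_length > 0, membrane_penalty >= 0,
            dielectric > 0, coulomb_cutoff > 0)
  stopifnot(all(c("aE223", "cE59", "aE162") %in% names(pKa)))
  structure(list(pH_ims = pH_ims, pH_matrix = pH_matrix, pKa = pKa,
                 pKa_overrides = pKa_overrides, delta_psi = delta_psi,
                 temperature = temperature, debye_length = debye_length,
                 dielectric = dielectric, coulomb_cutoff = coulomb_cutoff,
                 membrane_penalty = membrane_penalty,
                 charge_arginine = charge_arginine),
            class = "energy_params")
}

# kBT-unit Coulomb prefactor: unit charges at 1 A in the chosen dielectric
coulomb_prefactor <- function(params) {
  COULOMB_KCAL_A / (params$dielectric * KB_KCAL * params$temperature)
}

# intrinsic pKa of every carrier site, canonical order
site_pkas <- function(params, geom) {
  n_c <- geom$n_c
  pk <- c(rep(params$pKa$cE59, n_c), params$pKa$aE223, params$pKa$aE162)
  if (!is.null(params$pKa_overrides) && length(params$pKa_overrides) > 0) {
    labs <- letters[seq_len(n_c)]
    for (nm in names(params$pKa_overrides)) {
      k <- match(nm, labs)
      if (is.na(k)) stop("pKa override names unknown subunit: ", nm)
      pk[k] <- params$pKa_overrides[[nm]]
    }
  }
  pk
}

#' Intrinsic protonation free energy V_pKa
#'
#' \eqn{V_{pKa} = -\ln(10)\,k_BT \sum_i pKa_i (1 - h_i)}: each protonated
#' site (h = 0) contributes its intrinsic proton affinity.
#'
#' @param state A [protonation_state()].
#' @param params An [energy_params()].
#' @param geom The `fo_geometry` the state is indexed against.
#' @return Energy in kBT.
#' @export
v_pka <- function(state, params, geom) {
  -LN10 * sum(site_pkas(params, geom) * (1 - as.integer(state)))
}

#' Per-site charges in elementary units
#'
#' Carrier glutamates carry charge \eqn{-h_i} (0 protonated, -1
#' deprotonated); the conserved arginine carries `charge_arginine`
#' (+1 in the wild type); all other beads are neutral.
#'
#' @inheritParams v_pka
#' @return Numeric vector of charges, one per row of `geom$sites`.
#' @export
site_charges <- function(state, geom, params = energy_params()) {
  q <- numeric(nrow(geom$sites))
  ids <- attr(state, "carrier_ids")
  q[match(ids, geom$sites$site_id)] <- -as.integer(state)
  q[geom$sites$role == "arginine"] <- params$charge_arginine
  q
}

#' Screened Coulomb energy of all charged sites
#'
#' Debye-Hueckel pair sum \eqn{\sum_{i<j} q_i q_j B \exp(-r_{ij}/\lambda_D)/r_{ij}}
#' over non-zero charges within the cutoff, with the prefactor B fixed so
#' two unit charges at 1 Angstrom in the chosen dielectric reproduce the
#' unscreened Coulomb energy.
#'
#' @inheritParams v_pka
#' @param ring A [ring_state()] (c-sites are rotated by `ring$phi`).
#' @return Energy in kBT.
#' @export
v_coulomb <- function(state, geom, ring, params) {
  q <- site_charges(state, geom, params)
  nz <- which(q != 0)
  if (length(nz) < 2L) return(0)
  pos <- stator_positions(geom, ring$phi)[nz, , drop = FALSE]
  qq <- q[nz]
  d <- as.matrix(dist(pos))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  r <- d[upper.tri(d)]
  if (any(r < 0.1)) stop("coincident charged sites (r < 0.1 A): geometry invalid")
  keep <- r <= params$coulomb_cutoff
  if (!any(keep)) return(0)
  B <- coulomb_prefactor(params)
  sum(qq[iu[keep, 1]] * qq[iu[keep, 2]] *
        B * exp(-r[keep] / params$debye_length) / r[keep])
}

#' Membrane burial penalty for deprotonated carriers
#'
#' \eqn{\sum_i h_i\, w_{lipid}(i)\, E_{pen}} over c-ring carriers: a charged
#' (deprotonated) glutamate pays `membrane_penalty` kBT in proportion to
#' its lipid-facing weight. Always non-negative; zero for fully protonated
#' states.
#'
#' @inheritParams v_coulomb
#' @return Energy in kBT.
#' @export
v_membrane <- function(state, geom, ring, params) {
  ids <- attr(state, "carrier_ids")
  idx <- match(ids, geom$sites$site_id)
  is_c <- geom$sites$role[idx] == "c_carrier"
  dep <- which(is_c & as.integer(state) == 1L)
  if (length(dep) == 0L) return(0)
  az <- stator_azimuths(geom, ring$phi)[idx[dep]]
  params$membrane_penalty * sum(lipid_weight_az(az, geom))
}

#' Total energy with per-term breakdown
#'
#' @inheritParams v_coulomb
#' @param mode `"rigid_rotor"` (V_non-es = 0) or `"bead"` (elastic-network
#'   energy of `ring$bead_coords`).
#' @param network Elastic network from [build_elastic_network()] (bead mode).
#' @return An `energy_breakdown` list with components `v_non_es`,
#'   `v_coulomb`, `v_membrane`, `v_pka`, `v_total` (kBT).
#' @export
v_total <- function(state, geom, ring, params, mode = c("rigid_rotor", "bead"),
                    network = NULL) {
  mode <- match.arg(mode)
  vne <- 0
  if (mode == "bead") {
    if (is.null(network) || is.null(ring$bead_coords)) {
      stop("bead mode requires an elastic network and ring$bead_coords")
    }
    vne <- elastic_energy(ring$bead_coords, network)
  }
  vc <- v_coulomb(state, geom, ring, params)
  vm <- v_membrane(state, geom, ring, params)
  vp <- v_pka(state, params, geom)
  structure(list(v_non_es = vne, v_coulomb = vc, v_membrane = vm,
                 v_pka = vp, v_total = vne + vc + vm + vp),
            class = "energy_breakdown")
}

# protonation-dependent part of V_total (V_non-es cancels in transfer moves)
.v_state <- function(state, geom, ring, params) {
  v_coulomb(state, geom, ring, params) +
    v_membrane(state, geom, ring, params) +
    v_pka(state, params, geom)
}

#' Protonation energy of a half-channel glutamate
#'
#' \deqn{\epsilon_{aE223} = \ln(10) k_BT (pH_{IMS} - pKa_{aE223}) - \Delta\Psi/2}
#' \deqn{\epsilon_{aE162} = \ln(10) k_BT (pH_{matrix} - pKa_{aE162}) + \Delta\Psi/2}
#' The half-potential \eqn{\Delta\Psi/2} reflects the mid-membrane position
#' of the carrier glutamates; the mV value is converted through
#' \eqn{e\Delta\Psi/k_BT} at `params$temperature`.
#'
#' @param site_role `"channel_ims"` (aE223) or `"channel_matrix"` (aE162).
#' @param params An [energy_params()].
#' @return Protonation energy in kBT (negative favors protonation).
#' @export
channel_epsilon <- function(site_role = c("channel_ims", "channel_matrix"),
                            params = energy_params()) {
  site_role <- match.arg(site_role)
  half_psi <- psi_kbt(params$delta_psi, params$temperature) / 2
  if (site_role == "channel_ims") {
    LN10 * (params$pH_ims - params$pKa$aE223) - half_psi
  } else {
    LN10 * (params$pH_matrix - params$pKa$aE162) + half_psi
  }
}

#' Local equilibrium protonation probability
#'
#' \eqn{P(\epsilon) = e^{-\epsilon}/(1 + e^{-\epsilon})}: the Boltzmann
#' probability that a site of protonation energy \eqn{\epsilon} (kBT) is
#' protonated. Strictly decreasing, P(0) = 0.5, and
#' \eqn{P(\epsilon) + P(-\epsilon) = 1}.
#'
#' @param epsilon Protonation energy in kBT (vectorized).
#' @return Probability in (0, 1).
#' @export
equilibrium_protonation_probability <- function(epsilon) {
  stats::plogis(-epsilon)
}
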