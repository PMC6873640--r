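# Defibrillation efficacy metrics computed from potential fields: the DFT
# surrogate (voltage at which 95% of ventricular myocardium sees
# ||grad phi_e|| > 5 V/cm, obtained by linear scaling from a reference
# solve), shock energy C V^2 / 2, pathway impedance from current
# injection, and the shock vector efficiency eta = myocardial fraction of
# the total Joule dissipation.

#' Gradient magnitude of a potential field on a voxel mask
#'
#' Central differences on interior mask voxels, one-sided at the mask
#' boundary.
#'
#' @param field a `potential_field`.
#' @param mask logical 3-D array (e.g. the myocardium).
#' @return numeric vector of `||grad phi_e||` in V/cm at the mask voxels
#'   (in `which(mask)` order).
#' @export
gradient_magnitude <- function(field, mask) {
  stopifnot(inherits(field, "potential_field"))
  if (sum(mask) < 2) {
    stop("gradient undefined: mask must contain at least two voxels")
  }
  g <- masked_gradient(field$phi, mask, field$spacing)  # V/mm
  idx <- which(mask)
  10 * sqrt(g$gx[idx]^2 + g$gy[idx]^2 + g$gz[idx]^2)    # V/cm
}

#' Defibrillation threshold surrogate
#'
#' From a field solved at `v_ref`, computes `g5`, the 5th volume-weighted
#' percentile of the myocardial gradient magnitude (so that 95% of the
#' myocardium exceeds it), and linearly scales the applied voltage to the
#' level where `g5` reaches the 5 V/cm criterion.
#'
#' @param field a `potential_field` from a Dirichlet solve at a known
#'   applied voltage.
#' @param mask logical myocardial mask.
#' @param v_ref reference voltage (defaults to the field's applied voltage).
#' @param criterion gradient criterion, V/cm.
#' @return list with `dft_voltage` (V) and `g5` (V/cm).
#' @export
compute_dft <- function(field, mask, v_ref = NULL, criterion = 5) {
  if (is.null(v_ref)) v_ref <- field$boundary_record$v_applied
  if (is.null(v_ref)) stop("field has no applied voltage on record")
  gmag <- gradient_magnitude(field, mask)
  g5 <- unname(quantile(gmag, 0.05, type = 7))
  if (g5 <= 0) {
    stop("infinite DFT: the shock vector misses the myocardium (g5 = 0)")
  }
  list(dft_voltage = v_ref * criterion / g5, g5 = g5)
}

#' Capacitor shock energy
#'
#' `E = C V^2 / 2` for a device capacitance `C` (default 100 uF).
#'
#' @param dft_voltage shock voltage, V.
#' @param capacitance device capacitance, uF.
#' @return energy in joules.
#' @export
#' @examples
#' dft_energy(1000)  # 50 J
dft_energy <- function(dft_voltage, capacitance = 100) {
  stopifnot(dft_voltage >= 0, capacitance > 0)
  capacitance * dft_voltage^2 / 2e6
}

#' Pathway impedance from a current-injection solve
#'
#' Mean potential over the shocking-electrode voxels divided by the
#' injected current (ground at 0 V), per Ohm's law.
#'
#' @param field a `potential_field` with mode `"current_injection"`.
#' @param electrodes the `electrode_set` used for the solve.
#' @return resistance in ohms.
#' @export
compute_impedance <- function(field, electrodes = field$electrodes) {
  stopifnot(inherits(field, "potential_field"))
  if (field$mode != "current_injection") {
    stop("impedance requires a field solved in current-injection mode")
  }
  mean(field$phi[electrodes$shocking_idx]) / field$boundary_record$i_total
}

# Joule power per cell (watts), computed consistently with the discrete
# operator so that the total equals the injected electrode power exactly:
# the isotropic part is accumulated face-wise (each face's dissipation
# F (du)^2 split half/half between its two cells), the myocardial tensor
# remainder cell-wise from the same masked central-difference gradient the
# operator uses. Electrode voxels are excluded by default (their gradient
# is a Dirichlet artifact).
.joule_density <- function(field, phantom, fibres, model,
                           exclude_electrodes = TRUE) {
  L <- phantom$label_names
  d <- dim(phantom$labels)
  h_m <- field$spacing / 1000
  lut <- .label_sigma(model, "bulk")
  sig <- array(lut[phantom$labels + 1L], d)
  indom <- sig > 0
  u <- field$phi
  dens <- array(0, d)
  for (ax in 1:3) {
    Fax <- face_conductance(sig, ax, h_m)
    du <- shift_array(u, ax, +1L) - u
    p <- Fax * du * du
    dens <- dens + 0.5 * p + 0.5 * shift_array(p, ax, -1L)
  }
  myo_idx <- which(phantom$labels == L["myocardium"])
  if (length(myo_idx)) {
    if (is.null(fibres)) stop("fibres required for myocardial Joule power")
    g <- masked_gradient(u, indom, field$spacing)
    k <- .aniso_strength(model, "bulk")
    f <- fibres$fibre[match(myo_idx, fibres$myo_idx), , drop = FALSE]
    fdotg <- (f[, 1] * g$gx[myo_idx] + f[, 2] * g$gy[myo_idx] +
              f[, 3] * g$gz[myo_idx]) * 1e3   # V/mm -> V/m
    dens[myo_idx] <- dens[myo_idx] + h_m^3 * k * fdotg^2
  }
  if (exclude_electrodes) {
    excl <- c(field$electrodes$shocking_idx, field$electrodes$ground_idx)
    if (length(excl)) dens[excl] <- 0
  }
  dens
}

#' Shock vector efficiency
#'
#' The fraction of the total Joule-dissipated power deposited in
#' ventricular myocardium:
#' `eta = sum_myo J.E dV / sum_torso J.E dV`, with the full fibre tensor
#' in the myocardium and scalar conductivities elsewhere. Blood pools
#' count as non-myocardial (denominator only); electrode voxels are
#' excluded from both integrals. Invariant under scaling of the applied
#' voltage.
#'
#' @param field a `potential_field` from a Dirichlet solve.
#' @param phantom,fibres,model the inputs that produced the field.
#' @param details return the component powers as well.
#' @param exclude_electrodes drop the electrode voxels from both integrals
#'   (default; documented sensitivity switch).
#' @return the efficiency (fraction in (0, 1)), or a list with
#'   `eta`, `power_myo`, `power_total` (watts) when `details = TRUE`.
#' @export
compute_eta <- function(field, phantom, fibres, model, details = FALSE,
                        exclude_electrodes = TRUE) {
  dens <- .joule_density(field, phantom, fibres, model, exclude_electrodes)
  myo <- phantom$labels == phantom$label_names["myocardium"]
  p_myo <- sum(dens[myo])
  p_tot <- sum(dens)
  if (p_tot <= 0) stop("zero total dissipation: no current flows")
  if (details) {
    list(eta = p_myo / p_tot, power_myo = p_myo, power_total = p_tot)
  } else {
    p_myo / p_tot
  }
}

#' Shock vector efficiency with a height-truncated analysis region
#'
#' Recomputes eta with the denominator integral restricted to voxels
#' within `half_height` of the heart's axial midpoint; the numerator
#' (myocardial dissipation) is unchanged. The full-domain field is reused,
#' so this is the "truncate the analysis, not the simulation" variant.
#'
#' @inheritParams compute_eta
#' @param half_height half-torso height (mm) of the analysis region.
#' @return list with `eta`, `power_myo`, `power_region`.
#' @export
eta_truncated_analysis <- function(field, phantom, fibres, model,
                                   half_height, exclude_electrodes = TRUE) {
  g <- .phantom_grid(phantom)
  myo <- phantom$labels == phantom$label_names["myocardium"]
  myo_z <- g$zs[apply(myo, 3, any)]
  zmid <- mean(range(myo_z))
  if (half_height < (max(myo_z) - min(myo_z)) / 2) {
    stop("half_height must cover the heart")
  }
  dens <- .joule_density(field, phantom, fibres, model, exclude_electrodes)
  keep_z <- abs(g$zs - zmid) <= half_height
  keep <- rep(keep_z, each = g$nx * g$ny)
  p_myo <- sum(dens[myo])
  p_reg <- sum(dens[keep])
  list(eta = p_myo / p_reg, power_myo = p_myo, power_region = p_reg)
}

#' Total Joule dissipation of a field (watts)
#'
#' Volume integral of J.E over the torso (electrode voxels excluded);
#' the denominator of the shock vector efficiency.
#'
#' @inheritParams compute_eta
#' @return power in watts.
#' @export
total_dissipation <- function(field, phantom, fibres, model,
                              exclude_electrodes = TRUE) {
  sum(.joule_density(field, phantom, fibres, model, exclude_electrodes))
}
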