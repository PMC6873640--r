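# Extracellular potential solves under electrode boundary conditions:
# the static Laplace formulation, constant-current injection, and the
# passive elliptic-parabolic bidomain time-stepped to shock-end.

#' Passive bidomain parameters
#'
#' @param beta membrane surface-to-volume ratio, 1/cm.
#' @param Cm membrane capacitance, uF/cm^2.
#' @param Rm membrane resistance, kOhm cm^2.
#' @param vm_rest resting transmembrane potential, mV.
#' @param shock_duration monophasic shock length, ms.
#' @param dt time step, ms (must resolve the membrane time constant
#'   Rm*Cm; default 0.5 ms).
#' @param iion_form `"rest"` uses the rest-referenced passive current
#'   (Vm - Vm_rest)/Rm so that rest is an equilibrium; `"literal"` uses
#'   Vm/Rm.
#' @return object of class `bidomain_params`.
#' @export
bidomain_params <- function(beta = 1400, Cm = 1, Rm = 9, vm_rest = -80,
                            shock_duration = 30, dt = 0.5,
                            iion_form = c("rest", "literal")) {
  iion_form <- match.arg(iion_form)
  if (dt >= shock_duration) stop("dt must be smaller than shock_duration")
  if (any(c(beta, Cm, Rm, shock_duration, dt) <= 0)) {
    stop("beta, Cm, Rm, shock_duration and dt must be positive")
  }
  structure(list(beta = beta, Cm = Cm, Rm = Rm, vm_rest = vm_rest,
                 shock_duration = shock_duration, dt = dt,
                 iion_form = iion_form,
                 # SI conversions: 1/cm -> 1/m, uF/cm^2 -> F/m^2,
                 # kOhm cm^2 -> Ohm m^2, mV -> V, ms -> s
                 beta_si = beta * 100, Cm_si = Cm * 1e-2, Rm_si = Rm * 0.1,
                 vm_rest_si = vm_rest * 1e-3,
                 duration_si = shock_duration * 1e-3, dt_si = dt * 1e-3),
            class = "bidomain_params")
}

.field_object <- function(phi, dim, spacing, mode, electrodes,
                          boundary_record, residual, iterations, extra = list()) {
  structure(c(list(phi = array(phi, dim), spacing = spacing, mode = mode,
                   electrodes = electrodes, boundary_record = boundary_record,
                   residual = residual, iterations = iterations), extra),
            class = "potential_field")
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("<potential_field> mode=%s, range [%.3g, %.3g] V, relres %.2e (%d it)\n",
              x$mode, min(x$phi), max(x$phi), x$residual, x$iterations))
  invisible(x)
}

#' Solve the static Laplace problem for the extracellular potential
#'
#' Shocking-electrode voxels are fixed at `v_applied` volts, ground
#' electrodes at 0 V, with no-flux conditions at the torso surface; the
#' heart carries the bulk tensor (sigma_i + sigma_e), all other organs
#' their scalar conductivity.
#'
#' @param phantom a `voxel_phantom`.
#' @param fibres a `fibre_field` for the myocardium.
#' @param model a [conductivity_model()].
#' @param electrodes an `electrode_set`.
#' @param v_applied applied shock voltage, V.
#' @param tol relative residual tolerance of the linear solve.
#' @param op optionally a pre-assembled bulk `conduction_operator`.
#' @param x0 optional initial guess (warm start).
#' @param maxit iteration cap (default scales with the domain size).
#' @return a `potential_field` (`phi` in volts).
#' @export
solve_laplace <- function(phantom, fibres, model, electrodes, v_applied = 50,
                          tol = 1e-8, op = NULL, x0 = NULL, maxit = NULL) {
  stopifnot(inherits(electrodes, "electrode_set"), v_applied > 0)
  if (is.null(op)) op <- assemble_operator(phantom, fibres, model, "bulk")
  N <- prod(op$dim)
  fixed <- c(electrodes$shocking_idx, electrodes$ground_idx)
  if (is.null(x0)) x0 <- numeric(N)
  x0[electrodes$shocking_idx] <- v_applied
  x0[electrodes$ground_idx] <- 0
  res <- .op_solve(op, fixed, x0, numeric(N), tol, maxit)
  .field_object(res$x, op$dim, op$spacing, "laplace", electrodes,
                list(v_applied = v_applied), res$relres, res$iterations)
}

#' Constant-current injection between shocking and ground electrodes
#'
#' The total current is spread uniformly over the shocking-electrode
#' voxels as a source density; ground voxels are held at 0 V (fixing the
#' null space). Pathway impedance follows from the mean shocking-electrode
#' potential via Ohm's law.
#'
#' @inheritParams solve_laplace
#' @param i_total injected current, A.
#' @return a `potential_field` with mode `"current_injection"`.
#' @export
inject_current <- function(phantom, fibres, model, electrodes, i_total = 1,
                           tol = 1e-8, op = NULL) {
  stopifnot(inherits(electrodes, "electrode_set"), i_total > 0)
  if (!length(electrodes$ground_idx)) {
    stop("singular system: current injection requires a ground electrode")
  }
  if (is.null(op)) op <- assemble_operator(phantom, fibres, model, "bulk")
  N <- prod(op$dim)
  b <- numeric(N)
  b[electrodes$shocking_idx] <- i_total / length(electrodes$shocking_idx)
  x0 <- numeric(N)
  res <- .op_solve(op, electrodes$ground_idx, x0, b, tol)
  .field_object(res$x, op$dim, op$spacing, "current_injection", electrodes,
                list(i_total = i_total), res$relres, res$iterations)
}

#' Passive elliptic-parabolic bidomain solve to shock-end
#'
#' Operator-split time stepping: each step solves the elliptic equation
#' for phi_e given Vm, then an implicit diffusion step for Vm (sigma_i
#' operator, no-flux at the myocardial boundary), then exact exponential
#' integration of the linear membrane term. Returns phi_e at shock-end
#' (by default 30 ms, several membrane time constants, so the system is
#' near steady state) together with a Vm/steady-state summary.
#'
#' @inheritParams solve_laplace
#' @param params a [bidomain_params()].
#' @return a `potential_field` with mode `"bidomain"`; extra elements
#'   `vm` (myocardial transmembrane potential at shock-end, mV),
#'   `steady_rel_change` (relative phi_e change over the final 10% of the
#'   shock) and `vm_range_mV`.
#' @export
solve_passive_bidomain <- function(phantom, fibres, model, params,
                                   electrodes, v_applied = 50, tol = 1e-8) {
  stopifnot(inherits(params, "bidomain_params"), v_applied >= 0)
  op_b <- assemble_operator(phantom, fibres, model, "bulk")
  op_i <- assemble_operator(phantom, fibres, model, "intracellular")
  N <- prod(op_b$dim)
  myo <- op_i$dom == 1L
  h3 <- op_b$h_m^3
  mass_coef <- h3 * params$beta_si * params$Cm_si / params$dt_si
  mass <- numeric(N)
  mass[myo] <- mass_coef
  tau <- params$Rm_si * params$Cm_si
  decay <- exp(-params$dt_si / tau)
  v_target <- if (params$iion_form == "rest") params$vm_rest_si else 0

  vm <- numeric(N)
  vm[myo] <- params$vm_rest_si
  phi <- numeric(N)
  fixed <- c(electrodes$shocking_idx, electrodes$ground_idx)
  nt <- as.integer(round(params$duration_si / params$dt_si))
  i_mark <- max(1L, as.integer(floor(0.9 * nt)))
  phi_mark <- NULL
  total_it <- 0L

  for (it in seq_len(nt)) {
    b_e <- -cpp_apply_op(op_i$dim, op_i$h_m, op_i$Fx, op_i$Fy, op_i$Fz,
                         op_i$M, op_i$dom, numeric(0), vm)
    phi[electrodes$shocking_idx] <- v_applied
    phi[electrodes$ground_idx] <- 0
    res_e <- .op_solve(op_b, fixed, phi, b_e, tol)
    phi <- res_e$x
    total_it <- total_it + res_e$iterations

    rhs_v <- mass * vm - cpp_apply_op(op_i$dim, op_i$h_m, op_i$Fx, op_i$Fy,
                                      op_i$Fz, op_i$M, op_i$dom, numeric(0),
                                      phi)
    res_v <- .op_solve(op_i, integer(0), vm, rhs_v, tol, diag_add = mass)
    vm_star <- res_v$x
    if (any(!is.finite(vm_star))) {
      stop("bidomain instability: Vm diverged; reduce dt")
    }
    vm[myo] <- v_target + (vm_star[myo] - v_target) * decay
    if (it == i_mark) phi_mark <- phi
  }
  steady <- if (!is.null(phi_mark) && max(abs(phi)) > 0) {
    max(abs(phi - phi_mark)) / max(abs(phi))
  } else NA_real_
  .field_object(phi, op_b$dim, op_b$spacing, "bidomain", electrodes,
                list(v_applied = v_applied, params = params),
                res_e$relres, total_it,
                extra = list(vm = vm[myo] * 1e3,
                             vm_range_mV = range(vm[myo]) * 1e3,
                             steady_rel_change = steady))
}

#' Electrode power balance of a Dirichlet solve
#'
#' Injected power through the electrode node sets, computed from the
#' operator residual at the fixed cells: P = phi' A phi. Used for the
#' energy-conservation check against the volume Joule integral.
#'
#' @inheritParams solve_laplace
#' @param field a `potential_field` from [solve_laplace()].
#' @return injected power in watts.
#' @export
injected_power <- function(phantom, fibres, model, field, op = NULL) {
  if (is.null(op)) op <- assemble_operator(phantom, fibres, model, "bulk")
  Aphi <- apply_operator(op, field$phi)
  sum(as.vector(field$phi) * Aphi)
}
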