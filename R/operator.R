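# Discrete divergence-form operator A = -div(sigma grad .) on the voxel
# grid: cell-centred finite volume, harmonic-mean face conductances for the
# isotropic part, and a symmetric D' M D mixed-derivative stencil (masked
# central differences) for the myocardial fibre tensor remainder. Air is
# excluded (zero conductance faces), giving no-flux at the torso surface.

#' Assemble the conduction operator for a phantom
#'
#' @param phantom a `voxel_phantom`.
#' @param fibres a `fibre_field` (required when the mode carries myocardial
#'   anisotropy and the phantom has myocardium).
#' @param model a [conductivity_model()].
#' @param mode `"bulk"` (sigma_i + sigma_e in the heart, organs elsewhere),
#'   `"extracellular"` (sigma_e in the heart, organs elsewhere) or
#'   `"intracellular"` (sigma_i in the heart, nothing elsewhere; no-flux at
#'   the myocardial boundary).
#' @return object of class `conduction_operator` (matrix-free
#'   representation: face conductances, tensor components, domain mask).
#' @export
assemble_operator <- function(phantom, fibres, model,
                              mode = c("bulk", "extracellular",
                                       "intracellular")) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(model, "conductivity_model"))
  d <- dim(phantom$labels)
  N <- prod(d)
  h_m <- phantom$spacing / 1000
  lut <- .label_sigma(model, mode)
  sig <- array(lut[phantom$labels + 1L], d)
  Fx <- as.vector(face_conductance(sig, 1L, h_m))
  Fy <- as.vector(face_conductance(sig, 2L, h_m))
  Fz <- as.vector(face_conductance(sig, 3L, h_m))
  myo_idx <- which(phantom$labels == phantom$label_names["myocardium"])

  M <- numeric(0)
  if (length(myo_idx)) {
    if (missing(fibres) || is.null(fibres)) {
      stop("fibres are required for a phantom with myocardium")
    }
    if (!all(myo_idx %in% fibres$myo_idx)) {
      stop("myocardial voxel with no fibre vector")
    }
    k <- .aniso_strength(model, mode)
    f <- fibres$fibre[match(myo_idx, fibres$myo_idx), , drop = FALSE]
    M <- numeric(6L * N)
    M[myo_idx] <- k * f[, 1]^2
    M[N + myo_idx] <- k * f[, 2]^2
    M[2L * N + myo_idx] <- k * f[, 3]^2
    M[3L * N + myo_idx] <- k * f[, 1] * f[, 2]
    M[4L * N + myo_idx] <- k * f[, 1] * f[, 3]
    M[5L * N + myo_idx] <- k * f[, 2] * f[, 3]
  }
  dom <- as.integer(sig > 0)
  structure(list(dim = d, h_m = h_m, spacing = phantom$spacing,
                 Fx = Fx, Fy = Fy, Fz = Fz, M = M, dom = dom,
                 mode = mode, myo_idx = myo_idx),
            class = "conduction_operator")
}

#' Apply a conduction operator to a potential vector
#'
#' Returns `A u` (amperes per cell). Mainly for verification (symmetry,
#' conservation) and for the bidomain right-hand sides.
#'
#' @param op a `conduction_operator`.
#' @param u numeric vector/array of potentials (V).
#' @param diag_add optional lumped diagonal (siemens) added to the operator.
#' @return numeric vector of length `prod(op$dim)`.
#' @export
apply_operator <- function(op, u, diag_add = numeric(0)) {
  cpp_apply_op(op$dim, op$h_m, op$Fx, op$Fy, op$Fz, op$M, op$dom,
               diag_add, as.vector(u))
}

# shared CG front-end
.op_solve <- function(op, fixed_idx, x0, b, tol, maxit = NULL,
                      diag_add = numeric(0)) {
  N <- prod(op$dim)
  if (is.null(maxit)) maxit <- as.integer(min(2e5, 1000 * ceiling(N^(1 / 3))))
  res <- cpp_cg_solve(op$dim, op$h_m, op$Fx, op$Fy, op$Fz, op$M, op$dom,
                      diag_add, as.integer(fixed_idx - 1L),
                      as.vector(x0), as.vector(b), tol, maxit)
  if (!res$converged) {
    stop(sprintf("linear solve did not converge: relative residual %.3e after %d iterations",
                 res$relres, res$iterations))
  }
  res
}
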