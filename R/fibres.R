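# Rule-based myocardial fibre architecture. Two Laplace-Dirichlet scalar
# fields (transmural: endocardium 0 -> epicardium 1; apicobasal: apex 0 ->
# base 1) define a local frame from their gradients; the fibre direction is
# the circumferential axis rotated by the linearly interpolated helix angle
# alpha(d) = alpha_endo (1 - d) + alpha_epi d about the transmural axis.
# Convention (documented, tested): with t = grad(transmural) pointing
# outward and ab the apicobasal tangent, c = t x ab is circumferential and
# fibre = c cos(alpha) + ab sin(alpha); positive alpha tilts the fibre from
# the circumferential toward the basal direction.

#' Discrete-harmonic scalar field with two Dirichlet boundaries
#'
#' Solves the 7-point Laplacian on the voxel mask with value 0 on
#' `boundary_a` and 1 on `boundary_b`.
#'
#' @param mask logical 3-D array (the solve domain).
#' @param boundary_a,boundary_b linear voxel indices inside `mask`.
#' @param spacing voxel edge length (mm); the harmonic solution is
#'   scale-invariant, the argument only sets the physical grid.
#' @param tol linear-solve relative residual tolerance.
#' @return numeric 3-D array, `NA` outside the mask, values in `[0, 1]`.
#' @export
solve_laplace_dirichlet <- function(mask, boundary_a, boundary_b,
                                    spacing = 1, tol = 1e-8) {
  d <- dim(mask)
  if (!length(boundary_a) || !length(boundary_b)) {
    stop("both boundary sets must be non-empty")
  }
  if (length(intersect(boundary_a, boundary_b))) {
    stop("boundary sets must be disjoint")
  }
  if (!all(mask[boundary_a]) || !all(mask[boundary_b])) {
    stop("boundary voxels must lie inside the mask")
  }
  reached <- cpp_flood6(d, as.vector(mask),
                        as.integer(c(boundary_a, boundary_b) - 1L))
  orphan <- which(mask & !array(reached, d))
  if (length(orphan)) {
    stop(sprintf(paste0("disconnected component: %d mask voxel(s) touch ",
                        "neither boundary (first at linear index %d)"),
                 length(orphan), orphan[1]))
  }
  h_m <- spacing / 1000
  sig <- array(0, d)
  sig[mask] <- 1
  op <- list(dim = d, h_m = h_m, spacing = spacing,
             Fx = as.vector(face_conductance(sig, 1L, h_m)),
             Fy = as.vector(face_conductance(sig, 2L, h_m)),
             Fz = as.vector(face_conductance(sig, 3L, h_m)),
             M = numeric(0), dom = as.integer(as.vector(mask)))
  N <- prod(d)
  x0 <- numeric(N)
  x0[boundary_b] <- 1
  res <- .op_solve(op, c(boundary_a, boundary_b), x0, numeric(N), tol)
  out <- array(res$x, d)
  out[!mask] <- NA_real_
  # clamp tiny round-off excursions
  out[mask] <- pmin(pmax(out[mask], 0), 1)
  out
}

#' Linear transmural fibre rotation angle
#'
#' `alpha(d) = alpha_endo (1 - d) + alpha_epi d`, with `d` the normalized
#' transmural depth (0 endocardium, 1 epicardium).
#'
#' @param d transmural depth(s) in `[0, 1]`.
#' @param alpha_endo,alpha_epi rotation angles at the surfaces, degrees.
#' @return angle(s) in degrees.
#' @export
#' @examples
#' rotation_angle(c(0, 0.5, 1), 60, -60)
rotation_angle <- function(d, alpha_endo = 60, alpha_epi = -60) {
  if (any(d < 0 | d > 1 | is.na(d))) {
    stop("transmural depth d must lie in [0, 1]")
  }
  alpha_endo * (1 - d) + alpha_epi * d
}

#' Build the rule-based myocardial fibre field
#'
#' @param phantom a `voxel_phantom`.
#' @param apex physical apex coordinate (mm); defaults to the phantom's
#'   heart apex.
#' @param alpha_endo,alpha_epi helix angles at endo-/epicardium, degrees.
#' @param tol Laplace-solve tolerance.
#' @return object of class `fibre_field`: unit fibre vectors, transmural
#'   depth `d`, apicobasal field, the local frame (`t_hat`, `ab_hat`,
#'   `c_hat`) and the myocardial voxel indices.
#' @export
build_fibres <- function(phantom, apex = NULL, alpha_endo = 60,
                         alpha_epi = -60, tol = 1e-8) {
  L <- phantom$label_names
  g <- .phantom_grid(phantom)
  d3 <- dim(phantom$labels)
  myo <- phantom$labels == L["myocardium"]
  if (!any(myo)) stop("phantom has no myocardium")
  blood <- phantom$labels == L["lv_blood"] | phantom$labels == L["rv_blood"]
  outside <- !myo & !blood

  endo <- adjacent_to(myo, blood)
  epi <- adjacent_to(myo, outside) & !endo   # endo wins on thin walls
  # basal cut plane: myocardium within one voxel of the base plane
  myo_idx <- which(myo)
  ai <- arrayInd(myo_idx, d3)
  P <- cbind(g$xs[ai[, 1]], g$ys[ai[, 2]], g$zs[ai[, 3]])
  loc <- .heart_local(P, phantom$heart_info)
  base_set <- myo_idx[loc$zb <= g$h]
  endo_idx <- setdiff(which(endo), base_set)
  epi_idx <- setdiff(which(epi), base_set)
  if (!length(endo_idx) || !length(epi_idx)) {
    stop("could not identify endocardial/epicardial surfaces")
  }

  d_field <- solve_laplace_dirichlet(myo, endo_idx, epi_idx,
                                     spacing = g$h, tol = tol)
  if (is.null(apex)) apex <- phantom$heart_info$apex
  d_apex <- sqrt((P[, 1] - apex[1])^2 + (P[, 2] - apex[2])^2 +
                 (P[, 3] - apex[3])^2)
  apex_idx <- myo_idx[which.min(d_apex)]
  ab_field <- solve_laplace_dirichlet(myo, apex_idx,
                                      setdiff(base_set, apex_idx),
                                      spacing = g$h, tol = tol)

  gt <- masked_gradient(ifelse(is.na(d_field), 0, d_field), myo, g$h)
  ga <- masked_gradient(ifelse(is.na(ab_field), 0, ab_field), myo, g$h)
  tmat <- cbind(gt$gx[myo_idx], gt$gy[myo_idx], gt$gz[myo_idx])
  amat <- cbind(ga$gx[myo_idx], ga$gy[myo_idx], ga$gz[myo_idx])

  tn <- sqrt(rowSums(tmat^2))
  valid <- tn > 1e-9
  tmat[valid, ] <- tmat[valid, , drop = FALSE] / tn[valid]
  # apicobasal tangent: Gram-Schmidt against the (trusted) transmural axis
  proj <- rowSums(amat * tmat)
  amat <- amat - proj * tmat
  an <- sqrt(rowSums(amat^2))
  valid <- valid & an > 1e-9
  amat[valid, ] <- amat[valid, , drop = FALSE] / an[valid]

  frames <- .fill_degenerate_frames(d3, myo_idx, valid, tmat, amat)
  tmat <- frames$t; amat <- frames$ab
  cmat <- cbind(tmat[, 2] * amat[, 3] - tmat[, 3] * amat[, 2],
                tmat[, 3] * amat[, 1] - tmat[, 1] * amat[, 3],
                tmat[, 1] * amat[, 2] - tmat[, 2] * amat[, 1])

  dvals <- d_field[myo_idx]
  alpha <- rotation_angle(dvals, alpha_endo, alpha_epi) * pi / 180
  fib <- cmat * cos(alpha) + amat * sin(alpha)
  fib <- fib / sqrt(rowSums(fib^2))

  structure(list(fibre = fib, d = dvals, apicobasal = ab_field[myo_idx],
                 t_hat = tmat, ab_hat = amat, c_hat = cmat,
                 myo_idx = myo_idx, alpha_endo = alpha_endo,
                 alpha_epi = alpha_epi, dim = d3),
            class = "fibre_field")
}

# Voxels whose Laplace gradients degenerate inherit the nearest valid
# neighbour's frame (breadth-first over the 6-neighbour graph).
.fill_degenerate_frames <- function(d3, myo_idx, valid, tmat, amat) {
  if (all(valid)) return(list(t = tmat, ab = amat))
  pos <- array(0L, d3)
  pos[myo_idx] <- seq_along(myo_idx)
  strides <- c(1L, d3[1], d3[1] * d3[2])
  ai <- arrayInd(myo_idx, d3)
  repeat {
    todo <- which(!valid)
    if (!length(todo)) break
    progressed <- FALSE
    for (k in todo) {
      i <- myo_idx[k]
      for (ax in 1:3) {
        for (s in c(-1L, 1L)) {
          ci <- ai[k, ax] + s
          if (ci < 1L || ci > d3[ax]) next
          j <- i + s * strides[ax]
          pj <- pos[j]
          if (pj > 0L && valid[pj]) {
            tmat[k, ] <- tmat[pj, ]
            amat[k, ] <- amat[pj, ]
            valid[k] <- TRUE
            progressed <- TRUE
            break
          }
        }
        if (valid[k]) break
      }
    }
    if (!progressed) {
      stop(sprintf("degenerate fibre frame at %d voxel(s) with no valid neighbour (first linear index %d)",
                   length(todo), myo_idx[todo[1]]))
    }
  }
  list(t = tmat, ab = amat)
}

#' @export
print.fibre_field <- function(x, ...) {
  cat(sprintf("<fibre_field> %d myocardial voxels, alpha %g/%g deg, d in [%.2f, %.2f]\n",
              length(x$myo_idx), x$alpha_endo, x$alpha_epi,
              min(x$d), max(x$d)))
  invisible(x)
}
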