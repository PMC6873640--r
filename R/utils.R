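# Internal grid helpers. Voxel indices are 0-based in C++ and 1-based in R;
# linear index i = x + nx*(y + ny*z) matches R column-major array order.

#' Voxel-center physical coordinates along one axis
#' @noRd
axis_coords <- function(n, origin, spacing) origin + spacing * (seq_len(n) - 1)

#' Shift an array by one voxel along an axis, zero-padding the vacated slab.
#' `shift_array(a, 1, +1)[x,y,z] == a[x+1,y,z]` (value of the +x neighbour).
#' @noRd
shift_array <- function(a, axis, dir) {
  d <- dim(a)
  out <- array(0, d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0) {
    idx_src[[axis]] <- 2:n
    idx_dst[[axis]] <- 1:(n - 1L)
  } else {
    idx_src[[axis]] <- 1:(n - 1L)
    idx_dst[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Masked central-difference gradient of a 3-D field.
#'
#' Central differences where both axis neighbours are inside `mask`,
#' one-sided at the mask boundary, zero where the voxel has no in-mask
#' neighbour on the axis. Returns V/mm when `phi` is in volts and
#' `spacing_mm` in millimetres.
#' @noRd
masked_gradient <- function(phi, mask, spacing_mm) {
  stopifnot(identical(dim(phi), dim(mask)))
  phi0 <- phi
  phi0[!mask] <- 0
  g <- vector("list", 3L)
  for (ax in 1:3) {
    up <- shift_array(phi0, ax, +1L)
    dn <- shift_array(phi0, ax, -1L)
    vp <- shift_array(mask, ax, +1L) > 0
    vm <- shift_array(mask, ax, -1L) > 0
    h <- spacing_mm
    gax <- array(0, dim(phi))
    both <- vp & vm & mask
    ponly <- vp & !vm & mask
    monly <- !vp & vm & mask
    gax[both] <- (up[both] - dn[both]) / (2 * h)
    gax[ponly] <- (up[ponly] - phi0[ponly]) / h
    gax[monly] <- (phi0[monly] - dn[monly]) / h
    g[[ax]] <- gax
  }
  names(g) <- c("gx", "gy", "gz")
  g
}

#' Convert array (1-based triple) indices to linear indices
#' @noRd
lin_index <- function(xyz, dim) {
  (xyz[, 1] - 1L) + dim[1] * ((xyz[, 2] - 1L) + dim[2] * (xyz[, 3] - 1L)) + 1L
}

#' Harmonic mean of adjacent-cell conductivities on faces along `axis`,
#' scaled by the edge length (metres) to give face conductances in siemens.
#' Fx[i] couples cell i with its +axis neighbour; zero at the last slab.
#' @noRd
face_conductance <- function(sig, axis, h_m) {
  nb <- shift_array(sig, axis, +1L)
  num <- 2 * sig * nb
  den <- sig + nb
  f <- array(0, dim(sig))
  ok <- den > 0
  f[ok] <- num[ok] / den[ok]
  f * h_m
}

#' Voxels of `mask` with a 6-neighbour in `other` (face adjacency)
#' @noRd
adjacent_to <- function(mask, other) {
  adj <- array(FALSE, dim(mask))
  for (ax in 1:3) {
    adj <- adj | shift_array(other, ax, +1L) > 0 | shift_array(other, ax, -1L) > 0
  }
  mask & adj
}
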