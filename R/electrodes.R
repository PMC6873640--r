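# ICD electrode configurations. Electrodes are analytic cylinder solids
# rasterized to voxel index sets; they act as Dirichlet boundary-condition
# node sets (host-tissue labels underneath are preserved, electrodes are
# not conductive solids). Coil axes are snapped to the nearest voxel-centre
# line so that thin coils rasterize to a non-empty column at coarse spacing.

#' Electrode geometry defaults
#'
#' Dimensions in mm. The S-ICD coil (80 x 3 mm diameter) and can
#' (70 mm diameter x 20 mm) follow the standard device geometry; the
#' transvenous RV coil is 50 mm, the SVC coil 80 mm. The sub-clavicle can
#' for the transvenous configurations and the parasternal offset of the
#' S-ICD coil are not standardised and are exposed here.
#'
#' @param sicd_coil_length,sicd_coil_radius,sicd_parasternal_offset S-ICD coil.
#' @param can_radius,can_thickness,can_inset S-ICD can (mid-axillary).
#' @param tv_coil_length,tv_coil_radius RV shocking coil.
#' @param svc_coil_length SVC ground coil.
#' @param tvcan_radius,tvcan_thickness,tvcan_depth sub-clavicle can.
#' @return list of geometry parameters.
#' @export
electrode_defaults <- function(sicd_coil_length = 80, sicd_coil_radius = 1.5,
                               sicd_parasternal_offset = 25,
                               can_radius = 35, can_thickness = 20,
                               can_inset = 24,
                               tv_coil_length = 50, tv_coil_radius = 1.5,
                               svc_coil_length = 80,
                               tvcan_radius = 25, tvcan_thickness = 15,
                               tvcan_depth = 28) {
  as.list(environment())
}

#' Rasterize a finite cylinder onto a voxel grid
#'
#' A voxel belongs to the solid iff its centre lies inside the analytic
#' cylinder (axial projection within the segment, radial distance within
#' the radius).
#'
#' @param solid list with `p0`, `p1` (endpoint coordinates, mm) and
#'   `radius` (mm).
#' @param dim integer grid dimensions.
#' @param spacing voxel edge length, mm.
#' @param origin centre of voxel `[1,1,1]`, mm.
#' @return integer vector of linear voxel indices.
#' @export
rasterize_cylinder <- function(solid, dim, spacing, origin) {
  p0 <- solid$p0; p1 <- solid$p1; r <- solid$radius
  lo <- pmin(p0, p1) - r
  hi <- pmax(p0, p1) + r
  xs <- axis_coords(dim[1], origin[1], spacing)
  ys <- axis_coords(dim[2], origin[2], spacing)
  zs <- axis_coords(dim[3], origin[3], spacing)
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  nxb <- length(ix); nyb <- length(iy); nzb <- length(iz)
  P <- cbind(rep(xs[ix], times = nyb * nzb),
             rep(rep(ys[iy], each = nxb), times = nzb),
             rep(zs[iz], each = nxb * nyb))
  v <- p1 - p0
  len2 <- sum(v^2)
  rel <- sweep(P, 2, p0)
  t <- as.vector(rel %*% v) / len2
  perp <- rel - t %*% t(v)
  inside <- t >= -1e-9 & t <= 1 + 1e-9 & rowSums(perp^2) <= r^2 + 1e-9
  if (!any(inside)) return(integer(0))
  sel <- which(inside)
  li <- (sel - 1) %% nxb + 1
  lj <- ((sel - 1) %/% nxb) %% nyb + 1
  lk <- (sel - 1) %/% (nxb * nyb) + 1
  lin_index(cbind(ix[li], iy[lj], iz[lk]), dim)
}

.snap <- function(value, coords) coords[which.min(abs(coords - value))]

#' Place ICD electrodes on a phantom
#'
#' Builds the analytic electrode solids for one configuration, rasterizes
#' them, and validates host-tissue containment:
#' \describe{
#'   \item{S-ICD}{80 mm parasternal subcutaneous shocking coil (left of the
#'     sternum, within the fat/muscle layers) + mid-axillary can (ground)
#'     at heart level.}
#'   \item{TV-ICD1}{50 mm shocking coil inside the RV blood pool +
#'     sub-clavicle can (ground).}
#'   \item{TV-ICD2}{TV-ICD1 plus an 80 mm SVC coil as additional ground
#'     (two simultaneous shock vectors).}
#' }
#'
#' @param phantom a `voxel_phantom`.
#' @param config `"sicd"`, `"tvicd1"` or `"tvicd2"`.
#' @param params geometry defaults, see [electrode_defaults()].
#' @return an object of class `electrode_set` with the solids and the
#'   rasterized shocking/ground voxel index sets.
#' @export
place_electrodes <- function(phantom, config = c("sicd", "tvicd1", "tvicd2"),
                             params = electrode_defaults()) {
  config <- match.arg(config)
  L <- phantom$label_names
  g <- .phantom_grid(phantom)
  info <- phantom$heart_info
  torso <- phantom$torso
  a <- torso$width / 2; b <- torso$depth / 2
  z_h <- (info$apex[3] + info$base_c[3]) / 2
  # available (non-air) axial range, so placement adapts to truncation
  nonair_z <- g$zs[apply(phantom$labels != L["air"], 3, any)]
  z_top <- max(nonair_z)

  shocking <- list(); ground <- list()
  if (config == "sicd") {
    xo <- .snap(params$sicd_parasternal_offset, g$xs)
    t_mid <- torso$skin_layer + torso$fat_layer / 2
    yc <- -(b - t_mid) * sqrt(max(0, 1 - (xo / (a - t_mid))^2))
    yc <- .snap(yc, g$ys)
    half <- params$sicd_coil_length / 2
    shocking$coil <- list(
      p0 = c(xo, yc, z_h - half), p1 = c(xo, yc, z_h + half),
      radius = params$sicd_coil_radius, name = "parasternal coil",
      host = c(L["fat"], L["muscle"]))
    ground$can <- list(
      p0 = c(a - params$can_inset - params$can_thickness / 2, 0, z_h),
      p1 = c(a - params$can_inset + params$can_thickness / 2, 0, z_h),
      radius = params$can_radius, name = "mid-axillary can", host = NULL)
  } else {
    vdir <- cos(info$theta0) * info$e1 + sin(info$theta0) * info$e2
    rv_c <- info$base_c + vdir * (info$R_o + info$w_cav / 2)
    cx <- .snap(rv_c[1], g$xs); cy <- .snap(rv_c[2], g$ys)
    ztop_coil <- info$base_c[3] - 2 * g$h
    shocking$rv_coil <- list(
      p0 = c(cx, cy, ztop_coil), p1 = c(cx, cy, ztop_coil - params$tv_coil_length),
      radius = params$tv_coil_radius, name = "RV coil",
      host = L["rv_blood"])
    xc <- 0.25 * torso$width
    dpt <- params$tvcan_depth
    ycv <- -(b - dpt) * sqrt(max(0, 1 - (xc / (a - dpt))^2))
    zc <- min(z_top - params$tvcan_radius - 2 * g$h,
              g$zs[g$nz] - 35)
    ground$can <- list(
      p0 = c(xc, ycv - params$tvcan_thickness / 2, zc),
      p1 = c(xc, ycv + params$tvcan_thickness / 2, zc),
      radius = params$tvcan_radius, name = "sub-clavicle can", host = NULL)
    if (config == "tvicd2") {
      sx <- .snap(info$svc_xy[1], g$xs); sy <- .snap(info$svc_xy[2], g$ys)
      z0 <- info$base_c[3] + 1.5 * g$h
      z1 <- z0 + params$svc_coil_length
      z_cap <- min(z_top, info$svc_z[2]) - g$h / 2
      if (z1 > z_cap) {
        if (z_cap - z0 < 0.6 * params$svc_coil_length) {
          stop("placement error: SVC coil does not fit in the vessel column")
        }
        warning(sprintf("SVC coil shortened to %.0f mm to fit the vessel column",
                        z_cap - z0))
        z1 <- z_cap
      }
      ground$svc_coil <- list(
        p0 = c(sx, sy, z0), p1 = c(sx, sy, z1),
        radius = params$tv_coil_radius, name = "SVC coil",
        host = L["svc_blood"])
    }
  }

  rast <- function(solids) {
    lapply(solids, function(s) {
      idx <- rasterize_cylinder(s, dim(phantom$labels), g$h, g$origin)
      if (!length(idx)) {
        stop(sprintf("placement error: %s rasterized to zero voxels", s$name))
      }
      labs <- phantom$labels[idx]
      if (any(labs == L["air"])) {
        stop(sprintf("placement error: %s extends outside the torso", s$name))
      }
      if (!is.null(s$host) && !all(labs %in% s$host)) {
        bad <- setdiff(unique(labs), s$host)
        stop(sprintf("placement error: %s leaves its host tissue (found %s)",
                     s$name,
                     paste(names(L)[match(bad, L)], collapse = ", ")))
      }
      idx
    })
  }
  shock_idx <- rast(shocking)
  ground_idx <- rast(ground)
  si <- sort(unique(unlist(shock_idx)))
  gi <- sort(unique(unlist(ground_idx)))
  if (length(intersect(si, gi))) {
    stop("placement error: shocking and ground voxel sets overlap")
  }
  structure(list(config_name = config, shocking = shocking, ground = ground,
                 shocking_voxels = shock_idx, ground_voxels = ground_idx,
                 shocking_idx = si, ground_idx = gi),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set> %s: %d shocking voxel(s) in %d solid(s), %d ground voxel(s) in %d solid(s)\n",
              x$config_name, length(x$shocking_idx), length(x$shocking),
              length(x$ground_idx), length(x$ground)))
  invisible(x)
}

#' Construct an electrode set from explicit voxel index sets
#'
#' Low-level constructor for custom electrode node sets (plate electrodes,
#' point sources, test fixtures).
#'
#' @param shocking_idx,ground_idx linear voxel indices.
#' @param config_name label recorded with the set.
#' @return an `electrode_set`.
#' @export
electrode_set <- function(shocking_idx, ground_idx,
                          config_name = "custom") {
  shocking_idx <- sort(unique(as.integer(shocking_idx)))
  ground_idx <- sort(unique(as.integer(ground_idx)))
  if (!length(shocking_idx) || !length(ground_idx)) {
    stop("shocking and ground sets must be non-empty")
  }
  if (length(intersect(shocking_idx, ground_idx))) {
    stop("shocking and ground voxel sets must be disjoint")
  }
  structure(list(config_name = config_name, shocking = list(),
                 ground = list(),
                 shocking_voxels = list(custom = shocking_idx),
                 ground_voxels = list(custom = ground_idx),
                 shocking_idx = shocking_idx, ground_idx = ground_idx),
            class = "electrode_set")
}
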