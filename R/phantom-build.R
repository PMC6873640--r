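# Synthetic whole-torso voxel phantom. The torso is an elliptical cylinder
# (width along x = patient-left, depth along y = posterior, height along z =
# superior) wrapped by skin / subcutaneous fat / skeletal muscle shells, with
# analytic organs inside: two lungs, a spine + rib bands, a liver, a
# two-ventricle heart (bullet-shaped LV with a crescent RV), intracavitary
# blood pools and a great-vessel blood column rising to the SVC position.
# Optional extra organs (spinal cord, spleen, stomach, kidneys) lie off the
# shock pathways and are disabled by default. Remaining interior volume is
# filled with fat (mediastinal / visceral adipose and connective tissue).

#' Build a synthetic whole-torso voxel phantom
#'
#' Generates the labelled voxel volume for one torso/heart parameter set.
#' The heart is always constructed with the healthy dimensions; for
#' `heart$variant` of `"hcm"` or `"dcm"` the cardiomyopathy morph
#' ([apply_cardiomyopathy()]) is applied before returning, so preset
#' phantoms reproduce the tabulated variant dimensions directly.
#'
#' @param torso a [torso_params()] object.
#' @param heart a [heart_params()] object.
#' @param spacing isotropic voxel edge length in mm.
#' @param include_extras also label spinal cord, spleen, stomach and
#'   kidneys (default `FALSE`; they lie off the studied shock vectors).
#' @return an object of class `voxel_phantom`: a list with `labels`
#'   (3-D integer array), `spacing` (mm), `origin` (mm, centre of voxel
#'   `[1,1,1]`), `label_names`, `myocardial_labels`, and the generating
#'   parameters plus derived heart geometry (`heart_info`).
#' @export
#' @examples
#' ph <- build_torso_phantom(torso_params("small"), heart_params("small"),
#'                           spacing = 4)
#' table(ph$labels)[1:5]
build_torso_phantom <- function(torso, heart, spacing = 2,
                                include_extras = FALSE) {
  stopifnot(inherits(torso, "torso_params"), inherits(heart, "heart_params"))
  h <- spacing
  if (h <= 0) stop("spacing must be positive")
  if (min(torso$width, torso$depth, torso$height) < 10 * h) {
    stop("torso dimensions must be at least 10 voxels per axis")
  }
  if (heart$wall_thickness / h < 2) {
    stop(sprintf(paste0("resolution error: spacing %.1f mm resolves the ",
                        "%.1f mm LV wall with fewer than 2 voxels"),
                 h, heart$wall_thickness))
  }

  W <- torso$width; D <- torso$depth; H <- torso$height
  a <- W / 2; b <- D / 2
  nx <- as.integer(round(W / h)) + 2L
  ny <- as.integer(round(D / h)) + 2L
  nz <- as.integer(round(H / h))
  origin <- c(-(nx * h) / 2 + h / 2, -(ny * h) / 2 + h / 2, h / 2)
  xs <- axis_coords(nx, origin[1], h)
  ys <- axis_coords(ny, origin[2], h)
  zs <- axis_coords(nz, origin[3], h)
  L <- .sv_labels

  inside_shell <- function(off) {
    aa <- a - off; bb <- b - off
    if (aa <= 0 || bb <= 0) return(matrix(FALSE, nx, ny))
    outer((xs / aa)^2, (ys / bb)^2, "+") <= 1
  }
  t1 <- torso$skin_layer
  t2 <- t1 + torso$fat_layer
  t3 <- t2 + torso$muscle_layer

  in0 <- inside_shell(0)
  in1 <- inside_shell(t1)
  in2 <- inside_shell(t2)
  in3 <- inside_shell(t3)

  lbl2 <- matrix(L["air"], nx, ny)
  lbl2[in0] <- L["skin"]
  lbl2[in1] <- L["fat"]
  lbl2[in2] <- L["muscle"]
  lbl2[in3] <- L["fat"]   # interior filler: visceral/mediastinal fat
  labels <- array(rep(as.integer(lbl2), nz), dim = c(nx, ny, nz))

  # rib bands: partial-thickness bone rings in the muscle layer
  rib2 <- in2 & !inside_shell(t2 + 6)
  ribz <- ((zs - 0.30 * H) %% 25) < 8 & zs >= 0.30 * H & zs <= 0.92 * H
  if (any(rib2) && any(ribz)) {
    rib_lin <- which(rep(as.vector(rib2), nz) & rep(ribz, each = nx * ny))
    labels[rib_lin] <- L["bone"]
  }

  grid <- list(nx = nx, ny = ny, nz = nz, h = h, origin = origin,
               xs = xs, ys = ys, zs = zs)

  # lungs: two ellipsoids in the upper thorax
  for (sgn in c(-1, 1)) {
    labels <- .fill_ellipsoid(labels, grid,
                              center = c(sgn * 0.24 * W, 0.03 * D, 0.62 * H),
                              semi = c(0.14 * W, 0.30 * b, 0.28 * H),
                              value = L["lung"])
  }
  # liver: large ellipsoid, right upper abdomen
  labels <- .fill_ellipsoid(labels, grid,
                            center = c(-0.15 * W, 0.02 * D, 0.22 * H),
                            semi = c(0.25 * W, 0.32 * b, 0.14 * H),
                            value = L["liver"])
  if (include_extras) {
    labels <- .fill_ellipsoid(labels, grid,
                              center = c(0.15 * W, -0.05 * D, 0.28 * H),
                              semi = c(0.10 * W, 0.10 * b, 0.07 * H),
                              value = L["stomach"])
    labels <- .fill_ellipsoid(labels, grid,
                              center = c(0.27 * W, 0.06 * D, 0.30 * H),
                              semi = c(0.05 * W, 0.12 * b, 0.06 * H),
                              value = L["spleen"])
    for (sgn in c(-1, 1)) {
      labels <- .fill_ellipsoid(labels, grid,
                                center = c(sgn * 0.14 * W, 0.22 * D, 0.16 * H),
                                semi = c(0.05 * W, 0.10 * b, 0.07 * H),
                                value = L["kidney"])
    }
  }
  # spine: posterior bone column, full height (+ optional cord)
  y_spine <- b - 35
  spine2 <- outer((xs / 14)^2, ((ys - y_spine) / 14)^2, "+") <= 1
  labels[rep(as.vector(spine2), nz)] <- L["bone"]
  if (include_extras) {
    cord2 <- outer((xs / 5)^2, ((ys - y_spine) / 5)^2, "+") <= 1
    labels[rep(as.vector(cord2), nz)] <- L["spinal_cord"]
  }

  # heart pose
  z_h <- 0.54 * H
  heart_center <- c(0.10 * W, -0.08 * D, z_h)
  dirn <- heart$long_axis_direction
  Lax <- heart$long_axis_length
  apex <- heart$apex_position
  if (is.null(apex)) apex <- heart_center + dirn * (Lax / 2)
  base_c <- apex - dirn * Lax

  hinfo <- .heart_geometry(heart, apex, base_c, dirn)
  labels <- .fill_heart(labels, grid, hinfo, L)

  # great-vessel (SVC) blood column from just above the base to near the top
  svc_xy <- c(base_c[1] - 0.8 * hinfo$R_o, base_c[2])
  svc_r <- 8
  z_lo <- base_c[3] + grid$h
  z_hi <- H - grid$h
  svc2 <- outer(((xs - svc_xy[1]) / svc_r)^2, ((ys - svc_xy[2]) / svc_r)^2,
                "+") <= 1
  svcz <- zs >= z_lo & zs <= z_hi
  svc_lin <- which(rep(as.vector(svc2), nz) & rep(svcz, each = nx * ny))
  # do not overwrite myocardium (column ends where the heart begins)
  svc_lin <- svc_lin[!(labels[svc_lin] %in% c(L["myocardium"], L["lv_blood"],
                                              L["rv_blood"]))]
  labels[svc_lin] <- L["svc_blood"]
  hinfo$svc_xy <- svc_xy
  hinfo$svc_r <- svc_r
  hinfo$svc_z <- c(z_lo, z_hi)

  ph <- structure(list(labels = labels, spacing = h, origin = origin,
                       label_names = L,
                       myocardial_labels = unname(L["myocardium"]),
                       torso = torso, heart = heart, heart_info = hinfo),
                  class = "voxel_phantom")
  if (heart$variant != "healthy") {
    ph <- apply_cardiomyopathy(ph, heart, heart$variant)
  }
  ph
}

# Derived heart geometry shared by the builder, the morphs and electrode
# placement. Radii in mm; bullet LV: cylindrical from the base down to
# z_cyl = 0.6 L, ellipsoidal cap to the apex.
.heart_geometry <- function(heart, apex, base_c, dirn) {
  R_i <- heart$lvedd / 2
  wall <- heart$wall_thickness
  zax <- c(0, 0, 1)
  e1 <- c(dirn[2] * zax[3] - dirn[3] * zax[2],
          dirn[3] * zax[1] - dirn[1] * zax[3],
          dirn[1] * zax[2] - dirn[2] * zax[1])
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0) else e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dirn[2] * e1[3] - dirn[3] * e1[2],
          dirn[3] * e1[1] - dirn[1] * e1[3],
          dirn[1] * e1[2] - dirn[2] * e1[1])
  rv_dir <- c(-1, -0.35, 0)  # patient-right, slightly anterior
  rv_dir <- rv_dir / sqrt(sum(rv_dir^2))
  theta0 <- atan2(sum(rv_dir * e2), sum(rv_dir * e1))
  list(apex = apex, base_c = base_c, dirn = dirn, e1 = e1, e2 = e2,
       L = heart$long_axis_length, R_i = R_i, R_o = R_i + wall,
       wall = wall, w_cav = 20, w_rv = heart$rv_wall_thickness,
       theta0 = theta0, theta_w = 70 * pi / 180,
       theta_margin = 14 * pi / 180,
       z_cyl_frac = 0.6, rv_len_frac = 0.75, rv_cav_frac = 0.70)
}

# local heart coordinates for a set of physical points (matrix n x 3):
# zb = distance below the base plane along the long axis, rho/theta in the
# transverse frame (e1, e2)
.heart_local <- function(P, info) {
  rel <- sweep(P, 2, info$base_c)
  zb <- rel %*% info$dirn
  rad <- rel - zb %*% t(info$dirn)
  rho <- sqrt(rowSums(rad^2))
  theta <- atan2(rad %*% info$e2, rad %*% info$e1)
  list(zb = as.vector(zb), rho = rho, theta = as.vector(theta), rad = rad)
}

.lv_profiles <- function(zb, info) {
  Lz <- info$L
  z_cyl <- info$z_cyl_frac * Lz
  L_i <- Lz - info$wall
  R_o <- ifelse(zb <= z_cyl, info$R_o,
                info$R_o * sqrt(pmax(0, 1 - ((zb - z_cyl) / (Lz - z_cyl))^2)))
  R_i <- ifelse(zb <= z_cyl, info$R_i,
         ifelse(zb <= L_i,
                info$R_i * sqrt(pmax(0, 1 - ((zb - z_cyl) / (L_i - z_cyl))^2)),
                -1))
  list(R_o = R_o, R_i = R_i, L_i = L_i)
}

.heart_bbox <- function(grid, info, pad) {
  R_max <- info$R_o + info$w_cav + info$w_rv + pad
  lo <- pmin(info$apex, info$base_c) - R_max
  hi <- pmax(info$apex, info$base_c) + R_max
  ix <- which(grid$xs >= lo[1] & grid$xs <= hi[1])
  iy <- which(grid$ys >= lo[2] & grid$ys <= hi[2])
  iz <- which(grid$zs >= lo[3] & grid$zs <= hi[3])
  list(ix = ix, iy = iy, iz = iz)
}

.bbox_points <- function(grid, bb) {
  nxb <- length(bb$ix); nyb <- length(bb$iy); nzb <- length(bb$iz)
  cbind(rep(grid$xs[bb$ix], times = nyb * nzb),
        rep(rep(grid$ys[bb$iy], each = nxb), times = nzb),
        rep(grid$zs[bb$iz], each = nxb * nyb))
}

.fill_heart <- function(labels, grid, info, L) {
  bb <- .heart_bbox(grid, info, pad = 2 * grid$h)
  P <- .bbox_points(grid, bb)
  loc <- .heart_local(P, info)
  prof <- .lv_profiles(loc$zb, info)
  inz <- loc$zb >= 0 & loc$zb <= info$L
  ang <- abs(atan2(sin(loc$theta - info$theta0), cos(loc$theta - info$theta0)))
  rv_region <- inz & loc$zb <= info$rv_len_frac * info$L &
    ang <= info$theta_w & loc$rho <= prof$R_o + info$w_cav + info$w_rv
  rv_cav <- inz & loc$zb <= info$rv_cav_frac * info$L &
    ang <= info$theta_w - info$theta_margin &
    loc$rho > prof$R_o & loc$rho <= prof$R_o + info$w_cav
  lv_cav <- inz & loc$zb <= prof$L_i & prof$R_i > 0 & loc$rho < prof$R_i
  lv_myo <- inz & loc$rho <= prof$R_o & !lv_cav

  sub <- labels[bb$ix, bb$iy, bb$iz]
  sub[rv_region & !rv_cav] <- L["myocardium"]
  sub[rv_cav] <- L["rv_blood"]
  sub[lv_myo] <- L["myocardium"]
  sub[lv_cav] <- L["lv_blood"]
  labels[bb$ix, bb$iy, bb$iz] <- sub
  labels
}

.fill_ellipsoid <- function(labels, grid, center, semi, value) {
  ix <- which(abs(grid$xs - center[1]) <= semi[1])
  iy <- which(abs(grid$ys - center[2]) <= semi[2])
  iz <- which(abs(grid$zs - center[3]) <= semi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(labels)
  dx2 <- ((grid$xs[ix] - center[1]) / semi[1])^2
  dy2 <- ((grid$ys[iy] - center[2]) / semi[2])^2
  dz2 <- ((grid$zs[iz] - center[3]) / semi[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
  sub <- labels[ix, iy, iz]
  sub[m] <- value
  labels[ix, iy, iz] <- sub
  labels
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %.1f mm (%s torso, %s/%s heart)\n",
              d[1], d[2], d[3], x$spacing, x$torso$size_class,
              x$heart$size_class, x$heart$variant))
  tab <- table(factor(x$labels, levels = x$label_names,
                      labels = names(x$label_names)))
  tab <- tab[tab > 0]
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Grid description of a phantom (internal)
#' @noRd
.phantom_grid <- function(phantom) {
  d <- dim(phantom$labels)
  list(nx = d[1], ny = d[2], nz = d[3], h = phantom$spacing,
       origin = phantom$origin,
       xs = axis_coords(d[1], phantom$origin[1], phantom$spacing),
       ys = axis_coords(d[2], phantom$origin[2], phantom$spacing),
       zs = axis_coords(d[3], phantom$origin[3], phantom$spacing))
}

#' Measure the torso bounding extent in a transverse plane
#'
#' Width/depth of the non-air region in the transverse plane at the given
#' height fraction (default mid-height; the synthetic torso cross-section
#' is height-invariant, as the tabulated widths are quoted for a single
#' transverse plane).
#'
#' @param phantom a `voxel_phantom`.
#' @param z_frac height fraction of the measurement plane.
#' @return named numeric: `width`, `depth` (mm).
#' @export
measure_torso_extent <- function(phantom, z_frac = 0.5) {
  g <- .phantom_grid(phantom)
  iz <- max(1L, min(g$nz, as.integer(round(z_frac * g$nz))))
  sl <- phantom$labels[, , iz] != .sv_labels["air"]
  if (!any(sl)) stop("empty transverse plane")
  xr <- range(g$xs[rowSums(sl) > 0])
  yr <- range(g$ys[colSums(sl) > 0])
  c(width = diff(xr) + g$h, depth = diff(yr) + g$h)
}

#' Construct a phantom from a user-supplied labelled voxel volume
#'
#' Low-level constructor for custom structured-grid volumes (and for test
#' fixtures): any integer label volume using the package's organ label
#' table (see [shockvec_labels()]) can be solved and analysed; phantom
#' operations that need the analytic heart geometry (morphs, electrode
#' placement, fibre generation) additionally require `heart_info` as
#' produced by [build_torso_phantom()].
#'
#' @param labels 3-D integer array of organ labels.
#' @param spacing voxel edge length, mm.
#' @param origin physical coordinate of the centre of voxel `[1,1,1]`, mm.
#' @param label_names organ-name to label map.
#' @param heart_info optional derived heart geometry.
#' @return a `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, spacing, origin = c(0, 0, 0),
                          label_names = shockvec_labels(),
                          heart_info = NULL) {
  stopifnot(length(dim(labels)) == 3, spacing > 0, length(origin) == 3)
  if (!all(labels %in% label_names)) {
    stop("labels contain values outside the label table")
  }
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 spacing = spacing, origin = origin,
                 label_names = label_names,
                 myocardial_labels = unname(label_names["myocardium"]),
                 torso = NULL, heart = NULL, heart_info = heart_info),
            class = "voxel_phantom")
}
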