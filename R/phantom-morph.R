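# Cardiomyopathy variants as voxel-level geometric operators, and torso
# truncation. HCM thickens the LV wall inward (endocardium encroaches on
# the blood pool, epicardium fixed) by Euclidean-distance-transform
# thresholding; DCM displaces the ventricular complex radially outward
# about the long axis (no apicobasal dilation) by inverse-map resampling.

#' Apply a cardiomyopathy variant to a healthy-heart phantom
#'
#' @param phantom a `voxel_phantom` containing the healthy-variant heart.
#' @param heart a [heart_params()] object carrying the morph target
#'   (`target_wall_thickness` for HCM, `target_lvedd` for DCM).
#' @param variant `"hcm"` or `"dcm"`.
#' @return the morphed `voxel_phantom`.
#' @export
apply_cardiomyopathy <- function(phantom, heart,
                                 variant = c("hcm", "dcm")) {
  variant <- match.arg(variant)
  stopifnot(inherits(phantom, "voxel_phantom"))
  L <- phantom$label_names
  info <- phantom$heart_info
  g <- .phantom_grid(phantom)

  if (variant == "hcm") {
    target <- heart$target_wall_thickness
    if (is.null(target)) stop("HCM morph needs target_wall_thickness")
    delta <- target - info$wall
    if (delta < 0) stop("HCM target wall is thinner than the current wall")
    if (delta >= info$R_i) {
      stop(sprintf(paste0("geometry error: HCM wall target %.1f mm would ",
                          "close the LV cavity (radius %.1f mm)"),
                   target, info$R_i))
    }
    if (delta == 0) return(phantom)
    bb <- .heart_bbox(g, info, pad = 2 * g$h)
    sub <- phantom$labels[bb$ix, bb$iy, bb$iz]
    myo <- sub == L["myocardium"]
    dist <- cpp_edt3d(dim(sub), as.vector(myo), rep(g$h, 3))
    grow <- sub == L["lv_blood"] & array(dist, dim(sub)) <= delta + 1e-9
    sub[grow] <- L["myocardium"]
    if (!any(sub == L["lv_blood"])) {
      stop("geometry error: HCM morph consumed the entire LV blood pool")
    }
    phantom$labels[bb$ix, bb$iy, bb$iz] <- sub
    phantom$heart_info$R_i <- info$R_i - delta
    phantom$heart_info$wall <- info$wall + delta
    phantom$heart$variant <- "hcm"
    phantom$heart$target_wall_thickness <- target
    return(phantom)
  }

  # DCM: rigid radial displacement by delta about the long axis,
  # implemented by inverse-map nearest-neighbour resampling of the
  # heart labels; non-heart source labels leave the voxel untouched.
  target <- heart$target_lvedd
  if (is.null(target)) stop("DCM morph needs target_lvedd")
  delta <- (target - 2 * info$R_i) / 2
  if (delta < 0) stop("DCM target LVEDD is smaller than the current LVEDD")
  if (delta == 0) return(phantom)
  heart_labs <- c(L["myocardium"], L["lv_blood"], L["rv_blood"])
  info_big <- info
  info_big$R_i <- info$R_i + delta
  info_big$R_o <- info$R_o + delta
  bb <- .heart_bbox(g, info_big, pad = 2 * g$h)
  P <- .bbox_points(g, bb)
  # supersample each target voxel (8 sub-voxel points) through the inverse
  # radial displacement and take the majority source label; this halves the
  # label-boundary quantisation of the double (voxel -> voxel) resampling.
  # Tie-break: myocardium wins over blood.
  offs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * g$h / 4
  vote_order <- c(L[["myocardium"]], L[["lv_blood"]], L[["rv_blood"]])
  counts <- matrix(0L, nrow(P), length(vote_order))
  inz_any <- rep(FALSE, nrow(P))
  for (s in seq_len(nrow(offs))) {
    Q <- sweep(P, 2, offs[s, ], "+")
    loc <- .heart_local(Q, info)
    inz <- loc$zb >= 0 & loc$zb <= info$L
    inz_any <- inz_any | inz
    rho_src <- pmax(loc$rho - delta, 0)
    scale <- ifelse(loc$rho > 0, rho_src / loc$rho, 0)
    src <- loc$rad * scale +
      matrix(info$base_c, nrow(Q), 3, byrow = TRUE) +
      loc$zb %*% t(info$dirn)
    si <- pmin(pmax(round((src[, 1] - g$origin[1]) / g$h) + 1, 1), g$nx)
    sj <- pmin(pmax(round((src[, 2] - g$origin[2]) / g$h) + 1, 1), g$ny)
    sk <- pmin(pmax(round((src[, 3] - g$origin[3]) / g$h) + 1, 1), g$nz)
    src_lab <- phantom$labels[cbind(si, sj, sk)]
    src_lab[!inz] <- -1L
    for (v in seq_along(vote_order)) {
      counts[, v] <- counts[, v] + (src_lab == vote_order[v])
    }
  }
  best <- max.col(counts, ties.method = "first")
  nbest <- counts[cbind(seq_len(nrow(counts)), best)]
  take <- inz_any & nbest > nrow(offs) / 2
  sub <- phantom$labels[bb$ix, bb$iy, bb$iz]
  sub[take] <- vote_order[best[take]]
  phantom$labels[bb$ix, bb$iy, bb$iz] <- sub
  phantom$heart_info$R_i <- info$R_i + delta
  phantom$heart_info$R_o <- info$R_o + delta
  phantom$heart$variant <- "dcm"
  phantom$heart$target_lvedd <- target
  phantom
}

#' Measure heart dimensions from the labelled volume
#'
#' LVEDD and mean LV free-wall thickness in the transverse plane midway up
#' the heart (mid-myocardium z slice). LVEDD is the maximal LV-cavity
#' diameter in that plane; wall thickness is the mean radial run length of
#' myocardium along rays from the cavity centroid, excluding rays that exit
#' into the RV blood pool (the septum).
#'
#' @param phantom a `voxel_phantom`.
#' @return list with `lvedd` (mm) and `wall_thickness` (cm).
#' @export
measure_heart_dimensions <- function(phantom) {
  L <- phantom$label_names
  g <- .phantom_grid(phantom)
  myo_z <- which(apply(phantom$labels == L["myocardium"], 3, any))
  if (!length(myo_z)) stop("measurement error: no myocardium in phantom")
  iz <- as.integer(round(mean(range(myo_z))))
  sl <- phantom$labels[, , iz]
  cav <- which(sl == L["lv_blood"], arr.ind = TRUE)
  if (!nrow(cav)) stop("measurement error: no LV cavity found in mid-LV plane")
  px <- g$xs[cav[, 1]]
  py <- g$ys[cav[, 2]]
  # maximal diameter: max pairwise centre span plus half a voxel (the
  # extreme centres sit on average a quarter voxel inside the boundary at
  # each end)
  dmax <- 0
  if (nrow(cav) > 1) {
    dd <- dist(cbind(px, py))
    dmax <- max(dd)
  }
  lvedd <- dmax + g$h / 2

  cx <- mean(px); cy <- mean(py)
  # free-wall rays: the hemicircle facing away from the RV, so neither the
  # septum nor the RV attachment caps contaminate the run lengths
  angles <- seq(0, 2 * pi, by = 2 * pi / 180)[-181]
  rv <- which(sl == L["rv_blood"], arr.ind = TRUE)
  if (nrow(rv)) {
    th_rv <- atan2(mean(g$ys[rv[, 2]]) - cy, mean(g$xs[rv[, 1]]) - cx)
    keep_ang <- abs(atan2(sin(angles - th_rv), cos(angles - th_rv))) >
      (100 * pi / 180)
    if (any(keep_ang)) angles <- angles[keep_ang]
  }
  step <- g$h / 4
  tmax <- max(g$xs) - min(g$xs)
  walls <- c()
  for (th in angles) {
    ts <- seq(step, tmax, by = step)
    qx <- cx + ts * cos(th); qy <- cy + ts * sin(th)
    ii <- round((qx - g$origin[1]) / g$h) + 1
    jj <- round((qy - g$origin[2]) / g$h) + 1
    ok <- ii >= 1 & ii <= g$nx & jj >= 1 & jj <= g$ny
    labs <- rep(NA_integer_, length(ts))
    labs[ok] <- sl[cbind(ii[ok], jj[ok])]
    first_myo <- match(L["myocardium"], labs)
    if (is.na(first_myo)) next
    after <- labs[first_myo:length(labs)]
    exit <- match(TRUE, after != L["myocardium"])
    if (is.na(exit)) next
    exit_lab <- after[exit]
    if (!is.na(exit_lab) && exit_lab %in% c(L["rv_blood"], L["lv_blood"])) next
    walls <- c(walls, (exit - 1) * step)
  }
  if (!length(walls)) stop("measurement error: no free-wall rays found")
  list(lvedd = lvedd, wall_thickness = mean(walls) / 10)
}

#' Truncate a phantom in height about the heart
#'
#' Voxels with centres further than `half_height` from the heart's axial
#' midpoint (along z) become air; the heart must be fully retained.
#'
#' @param phantom a `voxel_phantom`.
#' @param half_height half-torso height in mm.
#' @return the clipped `voxel_phantom`.
#' @export
truncate_torso <- function(phantom, half_height) {
  L <- phantom$label_names
  g <- .phantom_grid(phantom)
  myo <- phantom$labels == L["myocardium"]
  myo_z <- g$zs[apply(myo, 3, any)]
  if (!length(myo_z)) stop("no myocardium in phantom")
  zmid <- mean(range(myo_z))
  keep <- abs(g$zs - zmid) <= half_height
  if (any(!keep & apply(myo, 3, any))) {
    stop(sprintf("half_height %.0f mm would clip the myocardium", half_height))
  }
  drop_z <- which(!keep)
  if (length(drop_z)) phantom$labels[, , drop_z] <- L[["air"]]
  phantom
}

#' Is the ventricular myocardium a single 6-connected component?
#' @param phantom a `voxel_phantom`.
#' @return logical.
#' @export
myocardium_connected <- function(phantom) {
  myo <- phantom$labels == phantom$label_names["myocardium"]
  idx <- which(myo)
  if (!length(idx)) return(FALSE)
  reached <- cpp_flood6(dim(phantom$labels), as.vector(myo), idx[1] - 1L)
  sum(reached) == length(idx)
}
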