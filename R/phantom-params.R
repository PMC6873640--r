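# Parameter containers for the synthetic torso and heart. Preset dimensions
# are the cohort values tabulated for the Small/Medium/Large/TAVI torsos and
# for the healthy, hypertrophic (HCM) and dilated (DCM) heart variants.
# All lengths are stored in millimetres.

.torso_presets <- list(
  large  = list(width = 420.0, depth = 310.0, height = 375.0),
  medium = list(width = 369.0, depth = 275.0, height = 305.0),
  small  = list(width = 287.0, depth = 200.0, height = 275.0),
  tavi1  = list(width = 383.0, depth = 271.0, height = 421.0),
  tavi2  = list(width = 361.0, depth = 286.0, height = 357.0)
)

# lvedd (mm), wall (mm): healthy / DCM lvedd, healthy / HCM wall.
# TAVI torsos reuse the medium heart (no cardiac abnormality in the cohort).
.heart_presets <- list(
  large  = list(lvedd = 54.7, lvedd_dcm = 73.4, wall = 10.0, wall_hcm = 19.0,
                long_axis = 95.0),
  medium = list(lvedd = 39.8, lvedd_dcm = 65.0, wall = 10.0, wall_hcm = 17.0,
                long_axis = 85.0),
  small  = list(lvedd = 40.0, lvedd_dcm = 55.6, wall = 9.0, wall_hcm = 17.0,
                long_axis = 80.0),
  tavi1  = list(lvedd = 39.8, lvedd_dcm = 65.0, wall = 10.0, wall_hcm = 17.0,
                long_axis = 85.0),
  tavi2  = list(lvedd = 39.8, lvedd_dcm = 65.0, wall = 10.0, wall_hcm = 17.0,
                long_axis = 85.0)
)

#' Torso dimension parameters
#'
#' Describes the outer envelope of the synthetic torso: an elliptical
#' cylinder of the given width (patient left-right), depth
#' (anterior-posterior) and height, wrapped by skin, subcutaneous fat and
#' skeletal-muscle layers. The named presets reproduce the tabulated cohort
#' dimensions (width/depth measured in a transverse plane).
#'
#' @param size_class one of `"small"`, `"medium"`, `"large"`, `"tavi1"`,
#'   `"tavi2"`, or `"custom"` (then `width`, `depth`, `height` are required).
#' @param width,depth,height torso extents in mm; override the preset.
#' @param fat_layer,skin_layer,muscle_layer layer thicknesses in mm.
#' @return an object of class `torso_params`.
#' @export
#' @examples
#' torso_params("small")
torso_params <- function(size_class = c("small", "medium", "large",
                                        "tavi1", "tavi2", "custom"),
                         width = NULL, depth = NULL, height = NULL,
                         fat_layer = 10, skin_layer = 2, muscle_layer = 15) {
  size_class <- match.arg(size_class)
  if (size_class != "custom") {
    p <- .torso_presets[[size_class]]
    if (is.null(width)) width <- p$width
    if (is.null(depth)) depth <- p$depth
    if (is.null(height)) height <- p$height
  }
  if (is.null(width) || is.null(depth) || is.null(height)) {
    stop("custom torso_params require width, depth and height")
  }
  vals <- c(width = width, depth = depth, height = height,
            fat_layer = fat_layer, skin_layer = skin_layer,
            muscle_layer = muscle_layer)
  if (any(vals <= 0)) stop("all torso dimensions must be positive")
  structure(list(width = width, depth = depth, height = height,
                 fat_layer = fat_layer, skin_layer = skin_layer,
                 muscle_layer = muscle_layer, size_class = size_class),
            class = "torso_params")
}

#' Heart dimension parameters
#'
#' Left-ventricular end-diastolic diameter (LVEDD), wall thicknesses and
#' pose of the synthetic two-ventricle heart. Variant presets carry the
#' cohort's tabulated targets: `"hcm"` thickens the LV wall at fixed
#' epicardium, `"dcm"` dilates the cavity radially at fixed apicobasal
#' extent. The geometry is always *built* healthy;
#' [apply_cardiomyopathy()] (called automatically by
#' [build_torso_phantom()] for non-healthy variants) morphs it to the
#' variant targets.
#'
#' @param size_class torso/heart size preset (see [torso_params()]).
#' @param variant `"healthy"`, `"hcm"` or `"dcm"`.
#' @param lvedd LV end-diastolic diameter, mm (healthy value).
#' @param wall_thickness LV wall thickness, mm (healthy value).
#' @param rv_wall_thickness RV free-wall thickness, mm.
#' @param long_axis_length base-to-apex length, mm.
#' @param apex_position,long_axis_direction heart pose; `NULL` lets the
#'   phantom builder place the heart (axis along -z, apex inferior).
#' @param target_lvedd,target_wall_thickness morph targets for the variant;
#'   filled from the preset table when `NULL`.
#' @return an object of class `heart_params`.
#' @export
#' @examples
#' heart_params("small", "hcm")
heart_params <- function(size_class = c("small", "medium", "large",
                                        "tavi1", "tavi2"),
                         variant = c("healthy", "hcm", "dcm"),
                         lvedd = NULL, wall_thickness = NULL,
                         rv_wall_thickness = 6,
                         long_axis_length = NULL,
                         apex_position = NULL,
                         long_axis_direction = c(0, 0, -1),
                         target_lvedd = NULL, target_wall_thickness = NULL) {
  size_class <- match.arg(size_class)
  variant <- match.arg(variant)
  p <- .heart_presets[[size_class]]
  if (is.null(lvedd)) lvedd <- p$lvedd
  if (is.null(wall_thickness)) wall_thickness <- p$wall
  if (is.null(long_axis_length)) long_axis_length <- p$long_axis
  if (variant == "hcm" && is.null(target_wall_thickness)) {
    target_wall_thickness <- p$wall_hcm
  }
  if (variant == "dcm" && is.null(target_lvedd)) {
    target_lvedd <- p$lvedd_dcm
  }
  if (lvedd <= 0 || wall_thickness <= 0 || rv_wall_thickness <= 0 ||
      long_axis_length <= 0) {
    stop("all heart dimensions must be positive")
  }
  dirn <- long_axis_direction / sqrt(sum(long_axis_direction^2))
  structure(list(size_class = size_class, variant = variant,
                 lvedd = lvedd, wall_thickness = wall_thickness,
                 rv_wall_thickness = rv_wall_thickness,
                 long_axis_length = long_axis_length,
                 apex_position = apex_position,
                 long_axis_direction = dirn,
                 target_lvedd = target_lvedd,
                 target_wall_thickness = target_wall_thickness),
            class = "heart_params")
}

#' @export
print.torso_params <- function(x, ...) {
  cat(sprintf("<torso_params> %s: %.1f x %.1f x %.1f cm (W x D x H)\n",
              x$size_class, x$width / 10, x$depth / 10, x$height / 10))
  invisible(x)
}

#' @export
print.heart_params <- function(x, ...) {
  cat(sprintf("<heart_params> %s/%s: LVEDD %.1f mm, wall %.1f mm, length %.0f mm\n",
              x$size_class, x$variant, x$lvedd, x$wall_thickness,
              x$long_axis_length))
  invisible(x)
}

# organ label table shared across the package
.sv_labels <- c(air = 0L, skin = 1L, fat = 2L, muscle = 3L, bone = 4L,
                lung = 5L, liver = 6L, myocardium = 7L, lv_blood = 8L,
                rv_blood = 9L, svc_blood = 10L, spinal_cord = 11L,
                spleen = 12L, stomach = 13L, kidney = 14L)

#' Organ label table
#'
#' The fixed organ-name to integer-label map used by every phantom.
#' @return named integer vector.
#' @export
shockvec_labels <- function() .sv_labels
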