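# Tissue conductivities (S/m). All organs are homogeneous isotropic
# resistors; ventricular myocardium carries the anisotropic tensor
# sigma(f) = sigma_t I + (sigma_l - sigma_t) f f' assembled from the local
# fibre direction f, with separate intracellular and extracellular
# longitudinal/transverse values.

#' Conductivity model
#'
#' Organ conductivities and the myocardial intra-/extracellular tensor
#' values. Blood pools (LV, RV, great vessel) share the blood value. Bone
#' is not part of the tabulated organ set; the default of 0.02 S/m is a
#' standard literature value for bulk bone and is exposed here.
#'
#' @param overrides named numeric vector of organ conductivities (S/m) to
#'   override, e.g. `c(fat = 0.04)`.
#' @param intra longitudinal/transverse intracellular myocardial
#'   conductivities, S/m.
#' @param extra longitudinal/transverse extracellular myocardial
#'   conductivities, S/m.
#' @return object of class `conductivity_model`.
#' @export
#' @examples
#' conductivity_model()$organs[["blood"]]
conductivity_model <- function(overrides = NULL,
                               intra = c(longitudinal = 0.24,
                                         transverse = 0.035),
                               extra = c(longitudinal = 0.24,
                                         transverse = 0.2)) {
  organs <- c(blood = 0.6667, fat = 0.0500, kidney = 0.1667, liver = 0.1667,
              lung = 0.0714, muscle = 0.4444, skin = 0.0500,
              spinal_cord = 0.1000, spleen = 0.1000, stomach = 0.1000,
              bone = 0.0200)
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(organs))
    if (length(bad)) stop("unknown organs: ", paste(bad, collapse = ", "))
    organs[names(overrides)] <- overrides
  }
  if (any(organs <= 0) || any(intra <= 0) || any(extra <= 0)) {
    stop("all conductivities must be positive")
  }
  structure(list(organs = organs, intra = intra, extra = extra),
            class = "conductivity_model")
}

#' @export
print.conductivity_model <- function(x, ...) {
  cat("<conductivity_model>\n  organs (S/m):",
      paste(sprintf("%s=%.4f", names(x$organs), x$organs), collapse = ", "),
      "\n")
  cat(sprintf("  myocardium intra l/t: %.3f/%.3f, extra l/t: %.3f/%.3f S/m\n",
              x$intra[1], x$intra[2], x$extra[1], x$extra[2]))
  invisible(x)
}

# per-label scalar conductivity lookup (air = 0) for one solve mode
.label_sigma <- function(model, mode) {
  L <- .sv_labels
  lut <- numeric(max(L) + 1L)
  org <- model$organs
  map <- c(skin = "skin", fat = "fat", muscle = "muscle", bone = "bone",
           lung = "lung", liver = "liver", lv_blood = "blood",
           rv_blood = "blood", svc_blood = "blood",
           spinal_cord = "spinal_cord", spleen = "spleen",
           stomach = "stomach", kidney = "kidney")
  if (mode == "intracellular") {
    lut[] <- 0
    lut[L["myocardium"] + 1L] <- model$intra[["transverse"]]
  } else {
    for (nm in names(map)) lut[L[nm] + 1L] <- org[[map[[nm]]]]
    lut[L["myocardium"] + 1L] <- switch(mode,
      bulk = model$intra[["transverse"]] + model$extra[["transverse"]],
      extracellular = model$extra[["transverse"]])
  }
  lut
}

.aniso_strength <- function(model, mode) {
  switch(mode,
    bulk = (model$intra[["longitudinal"]] + model$extra[["longitudinal"]]) -
           (model$intra[["transverse"]] + model$extra[["transverse"]]),
    extracellular = model$extra[["longitudinal"]] - model$extra[["transverse"]],
    intracellular = model$intra[["longitudinal"]] - model$intra[["transverse"]])
}
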