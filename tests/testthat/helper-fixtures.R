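# Shared fixtures, built once per session and cached. Everything is
# generated in code; no stored data. Heavy solves are reused across test
# files (test_dir runs all files in one session).

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (!exists(key, envir = .fx, inherits = FALSE)) {
    assign(key, builder(), envir = .fx)
  }
  get(key, envir = .fx, inherits = FALSE)
}

fx_phantom <- function(size, variant = "healthy", spacing = 4) {
  fx_get(sprintf("ph_%s_%s_%g", size, variant, spacing), function() {
    build_torso_phantom(torso_params(size), heart_params(size, variant),
                        spacing = spacing)
  })
}

# phantom + fibre field
fx_case <- function(size, variant = "healthy", spacing = 4) {
  fx_get(sprintf("case_%s_%s_%g", size, variant, spacing), function() {
    ph <- fx_phantom(size, variant, spacing)
    list(phantom = ph, fibres = build_fibres(ph))
  })
}

fx_config <- function(spacing = 4) {
  experiment_config(spacing = spacing)
}

# S-ICD Laplace solve at 50 V (2 mm cohort resolution)
fx_sicd_2mm <- function(size) {
  fx_get(sprintf("sicd2_%s", size), function() {
    case <- fx_case(size, "healthy", 2)
    md <- conductivity_model()
    el <- place_electrodes(case$phantom, "sicd")
    fld <- solve_laplace(case$phantom, case$fibres, md, el, 50)
    list(case = case, electrodes = el, field = fld,
         eta = compute_eta(fld, case$phantom, case$fibres, md))
  })
}

# 4 mm healthy cohort: 3 sizes x 3 electrode configurations
fx_cohort_4mm <- function() {
  fx_get("cohort4", function() {
    suppressWarnings(
      run_cohort(experiment_config(spacing = 4, variants = "healthy")))
  })
}

# ---- analytic fixtures -------------------------------------------------

# homogeneous bar with end-face electrodes; labels/conductivity by organ
fx_bar <- function(n = c(200, 2, 2), spacing = 0.5, organ = "muscle") {
  L <- shockvec_labels()
  lab <- array(L[organ], n)
  ph <- voxel_phantom(lab, spacing = spacing)
  face <- function(i) {
    m <- array(FALSE, n); m[i, , ] <- TRUE; which(m)
  }
  list(phantom = ph,
       electrodes = electrode_set(face(1), face(n[1])),
       area_mm2 = n[2] * n[3] * spacing^2,
       length_mm = n[1] * spacing)
}

# uniform field cube: v volts across the x extent
fx_uniform_field <- function(n = c(50, 10, 10), spacing = 2, v = 49) {
  L <- shockvec_labels()
  lab <- array(L["muscle"], n)
  ph <- voxel_phantom(lab, spacing = spacing)
  m1 <- array(FALSE, n); m1[1, , ] <- TRUE
  m2 <- array(FALSE, n); m2[n[1], , ] <- TRUE
  el <- electrode_set(which(m2), which(m1))
  fld <- solve_laplace(ph, NULL, conductivity_model(), el, v)
  list(phantom = ph, electrodes = el, field = fld)
}

# hand-made fibre field (uniform direction) for slab fixtures
fx_uniform_fibres <- function(labels, direction) {
  L <- shockvec_labels()
  myo_idx <- which(labels == L["myocardium"])
  dirn <- direction / sqrt(sum(direction^2))
  structure(list(fibre = matrix(rep(dirn, each = length(myo_idx)), ncol = 3),
                 myo_idx = myo_idx, dim = dim(labels)),
            class = "fibre_field")
}

# synthetic potential_field around given phi values (for metric arithmetic)
fx_field <- function(phi, spacing, v_applied = 50,
                     electrodes = NULL, mode = "laplace") {
  structure(list(phi = phi, spacing = spacing, mode = mode,
                 electrodes = electrodes,
                 boundary_record = if (mode == "current_injection")
                   list(i_total = 1) else list(v_applied = v_applied),
                 residual = 0, iterations = 0L),
            class = "potential_field")
}
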