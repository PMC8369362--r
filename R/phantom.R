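# Seed-deterministic DBT phantom generator. Phantoms are statistical
# look-alikes of reconstructed DBT views -- a half-elliptical breast of
# textured elevated intensity against a zero background, a thin bright
# skin rim, and sparse bright lesions (3-D Gaussian masses or radial
# spicule patterns for architectural distortions) -- not physically
# simulated tomosynthesis. They exist so every pipeline stage can be
# exercised without patient data.

#' Lesion specification
#'
#' @param kind `"mass"` or `"architectural_distortion"`.
#' @param center `c(x, y, z)` in raw full-resolution pixels / slice index.
#' @param size characteristic diameter in raw pixels (>= 8). A mass is an
#'   additive 3-D Gaussian with in-plane sd `size/4` and z sd `size/8`
#'   slices; a distortion is 8-16 radial spicules of length about
#'   `0.4-0.6 * size` each side with a faint Gaussian core.
#' @param contrast peak added intensity (must exceed the background noise
#'   sd).
#' @param lesion_class `"cancer"` or `"benign"`.
#' @return A `dbt_lesion_spec`.
#' @export
lesion_spec <- function(kind = c("mass", "architectural_distortion"),
                        center, size, contrast, lesion_class = "benign",
                        rays = NULL) {
  kind <- match.arg(kind)
  lesion_class <- match.arg(lesion_class, c("cancer", "benign"))
  if (size < 8) stop_dbt("spec", "lesion size must be >= 8 px")
  if (kind == "architectural_distortion" && is.null(rays))
    rays <- draw_rays(size)
  structure(list(kind = kind, center = center, size = size,
                 contrast = contrast, lesion_class = lesion_class,
                 rays = rays),
            class = "dbt_lesion_spec")
}

# spicule geometry for a distortion; drawn at spec time so the tight
# annotation box is known without rendering the volume
draw_rays <- function(size) {
  n_rays <- sample(8:16, 1)
  list(angles = stats::runif(n_rays, 0, 2 * pi),
       lens = stats::runif(n_rays, 0.4, 0.6) * size,
       widths = sample(1:2, n_rays, replace = TRUE))
}

# tight half-extent of a lesion's annotation box
lesion_half_extent <- function(l) {
  if (l$kind == "mass") l$size / 2 else ceiling(max(l$rays$lens))
}

#' Phantom volume specification
#'
#' The breast is a half ellipse attached to the chest-wall edge (x = 0)
#' with semi-axes `breast_a` (into the image) and `breast_b` (along the
#' chest wall), constant across slices. Background texture inside the
#' breast is Gaussian with `noise` = (mean, sd); the skin rim of
#' `skin_thickness` px is set to `mean + 8 sd`. Lesion centers must stay
#' inside the breast with a margin so that they survive erosion-based
#' masking.
#'
#' @param n_slices slices (>= 4).
#' @param rows,cols raw (pre-downscale) slice dimensions.
#' @param breast_a,breast_b ellipse semi-axes in raw px.
#' @param skin_thickness rim thickness in raw px.
#' @param noise `c(mean, sd)` of the in-breast texture.
#' @param lesions list of [lesion_spec()]s.
#' @param seed integer; generation is bitwise deterministic given it.
#' @return A `dbt_phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 40L, rows = 768L, cols = 512L,
                         breast_a = 400, breast_b = 330,
                         skin_thickness = 6, noise = c(300, 50),
                         lesions = list(), seed = 1L) {
  if (n_slices < 4) stop_dbt("spec", "n_slices must be >= 4")
  spec <- structure(
    list(n_slices = as.integer(n_slices), rows = as.integer(rows),
         cols = as.integer(cols), breast_a = breast_a, breast_b = breast_b,
         skin_thickness = skin_thickness, noise = noise, lesions = lesions,
         seed = as.integer(seed)),
    class = "dbt_phantom_spec")
  for (l in lesions) check_lesion_inside(l, spec)
  spec
}

check_lesion_inside <- function(l, spec) {
  if (l$contrast <= spec$noise[2])
    stop_dbt("spec", "lesion contrast must exceed the noise sd")
  m <- l$size / 2 + spec$skin_thickness + 20
  cy <- spec$rows / 2
  rho <- sqrt((l$center[1] / max(spec$breast_a - m, 1))^2 +
                ((l$center[2] - cy) / max(spec$breast_b - m, 1))^2)
  if (rho > 1 || l$center[3] < 1 || l$center[3] >= spec$n_slices - 1)
    stop_dbt("spec", "lesion center outside the breast interior")
  invisible(TRUE)
}

phantom_geometry <- function(spec) {
  x <- matrix(rep(seq_len(spec$cols) - 0.5, each = spec$rows),
              spec$rows, spec$cols)
  y <- matrix(rep(seq_len(spec$rows) - 0.5, times = spec$cols),
              spec$rows, spec$cols)
  cy <- spec$rows / 2
  rho <- sqrt((x / spec$breast_a)^2 + ((y - cy) / spec$breast_b)^2)
  inside <- rho <= 1
  rim <- inside & ((1 - rho) * min(spec$breast_a, spec$breast_b) <=
                     spec$skin_thickness)
  list(inside = inside, rim = rim)
}

add_mass <- function(px, l, spec) {
  sxy <- l$size / 4
  sz <- l$size / 8
  cx <- l$center[1]
  cy <- l$center[2]
  cz <- l$center[3]
  r <- ceiling(3 * sxy)
  rr <- max(1, floor(cy - r) + 1):min(spec$rows, ceiling(cy + r))
  cc <- max(1, floor(cx - r) + 1):min(spec$cols, ceiling(cx + r))
  dx2 <- outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, `+`)
  blob <- l$contrast * exp(-dx2 / (2 * sxy^2))
  for (z in seq_len(spec$n_slices)) {
    g <- exp(-((z - 1) - cz)^2 / (2 * sz^2))
    if (g < 0.01) next
    px[rr, cc, z] <- px[rr, cc, z] + blob * g
  }
  px
}

add_distortion <- function(px, l, spec) {
  n_rays <- length(l$rays$angles)
  angles <- l$rays$angles
  lens <- l$rays$lens
  widths <- l$rays$widths
  cx <- l$center[1]
  cy <- l$center[2]
  cz <- l$center[3]
  sz <- l$size / 12
  core_s <- l$size / 8
  zs <- which(exp(-((seq_len(spec$n_slices) - 1) - cz)^2 / (2 * sz^2)) >=
                0.05)
  for (z in zs) {
    g <- exp(-((z - 1) - cz)^2 / (2 * sz^2))
    sl <- px[, , z]
    for (k in seq_len(n_rays)) {
      for (t in seq(1.5, lens[k], by = 0.7)) {
        rx <- cx + t * cos(angles[k])
        ry <- cy + t * sin(angles[k])
        w <- widths[k] - 1
        rr <- max(1, round(ry) - w + 1):min(spec$rows, round(ry) + 1)
        cc <- max(1, round(rx) - w + 1):min(spec$cols, round(rx) + 1)
        sl[rr, cc] <- sl[rr, cc] + l$contrast * g * 0.35
      }
    }
    # faint core
    r <- ceiling(2 * core_s)
    rr <- max(1, floor(cy - r) + 1):min(spec$rows, ceiling(cy + r))
    cc <- max(1, floor(cx - r) + 1):min(spec$cols, ceiling(cx + r))
    dx2 <- outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, `+`)
    sl[rr, cc] <- sl[rr, cc] +
      0.5 * l$contrast * g * exp(-dx2 / (2 * core_s^2))
    px[, , z] <- sl
  }
  px
}

#' Generate a phantom volume
#'
#' Bitwise deterministic given `spec$seed`. Lesion annotations give the
#' tight 2-D box on the lesion's center slice in full-resolution
#' coordinates (masses: `size x size`; distortions: twice the realized
#' maximum spicule length per side). The lesion z extent follows the
#' lesion's own Gaussian profile, which deliberately differs from the
#' square-root ground-truth slice rule so that the rule's effect is
#' observable.
#'
#' @param spec a [phantom_spec()].
#' @param view,patient_id,study_id identity stamped on the volume and
#'   annotations.
#' @return List `volume` (a `dbt_volume` with raw intensities and header
#'   window covering the intensity range) and `annotations` (data.frame in
#'   the [read_annotations()] schema).
#' @export
generate_volume <- function(spec, view = "LCC", patient_id = "P0001",
                            study_id = "S0001") {
  geom <- phantom_geometry(spec)
  ann <- NULL
  px <- with_seed(spec$seed, {
    npx <- spec$rows * spec$cols
    px <- array(0, dim = c(spec$rows, spec$cols, spec$n_slices))
    idx_in <- which(geom$inside)
    idx_rim <- which(geom$rim)
    n_in <- length(idx_in)
    skin_val <- spec$noise[1] + 8 * spec$noise[2]
    all_idx <- rep(idx_in, spec$n_slices) +
      rep((seq_len(spec$n_slices) - 1L) * npx, each = n_in)
    px[all_idx] <- pmax(spec$noise[1] +
                          stats::rnorm(n_in * spec$n_slices,
                                       sd = spec$noise[2]), 1)
    px[rep(idx_rim, spec$n_slices) +
         rep((seq_len(spec$n_slices) - 1L) * npx,
             each = length(idx_rim))] <- skin_val
    for (l in spec$lesions) {
      px <- if (l$kind == "mass") add_mass(px, l, spec)
            else add_distortion(px, l, spec)
      half <- lesion_half_extent(l)
      ann <- rbind(ann, data.frame(
        PatientID = patient_id, StudyUID = study_id, View = view,
        X = round(l$center[1] - half), Y = round(l$center[2] - half),
        Width = round(2 * half), Height = round(2 * half),
        Slice = as.integer(l$center[3]), Class = l$lesion_class,
        LesionType = l$kind, stringsAsFactors = FALSE))
    }
    round(pmin(px, 65535))
  })
  vol <- new_volume(px, view = view, patient_id = patient_id,
                    study_id = study_id,
                    window_center = (spec$noise[1] + 8 * spec$noise[2]) / 2,
                    window_width = spec$noise[1] + 8 * spec$noise[2])
  if (is.null(ann))
    ann <- utils::read.csv(text = paste(ANNOTATION_COLS, collapse = ","))
  list(volume = vol, annotations = ann)
}

#' Phantom presets
#'
#' `"small"`: 768 x 512 raw slices, 40 per volume -- a scaled-down stand-in
#' for realistic DBT dimensions, sized for CPU pipelines. `"tiny"`:
#' 256 x 192 x 16, for fast unit tests. `"realistic"`: 2048 x 1024 x 64,
#' approaching true reconstruction geometry -- slow; expect minutes per
#' volume on one CPU.
#'
#' @param preset `"small"`, `"realistic"` or `"tiny"`.
#' @return Named list of [phantom_spec()] arguments (without lesions/seed).
#' @export
phantom_preset <- function(preset = c("small", "realistic", "tiny")) {
  preset <- match.arg(preset)
  switch(preset,
    small = list(n_slices = 40L, rows = 768L, cols = 512L, breast_a = 400,
                 breast_b = 330, skin_thickness = 6, noise = c(300, 50),
                 size_range = c(48, 96)),
    realistic = list(n_slices = 64L, rows = 2048L, cols = 1024L,
                     breast_a = 800, breast_b = 880, skin_thickness = 12,
                     noise = c(300, 50), size_range = c(96, 260)),
    tiny = list(n_slices = 16L, rows = 256L, cols = 192L, breast_a = 110,
                breast_b = 85, skin_thickness = 4, noise = c(300, 50),
                size_range = c(24, 36))
  )
}

draw_lesion_center <- function(p, size, half = size / 2) {
  m <- size / 2 + p$skin_thickness + 20
  cy <- p$rows / 2
  a <- max(p$breast_a - m, 1)
  b <- max(p$breast_b - m, 1)
  # x >= half + 2 keeps the annotation box inside the image (the chest
  # wall is the image edge at x = 0)
  repeat {
    x <- stats::runif(1, max(0.1 * a, half + 2), 0.9 * a)
    y <- cy + stats::runif(1, -0.85, 0.85) * b
    if ((x / a)^2 + ((y - cy) / b)^2 <= 0.92) return(c(x, y))
  }
}

#' Plan a phantom dataset
#'
#' Lays out studies (4 views each) for the four cohort groups and draws
#' per-volume seeds and lesion parameters, all deterministically from
#' `seed`. Benign and cancer studies carry one lesion, inserted on both
#' views of one breast and annotated on each; actionable studies carry a
#' subtle low-contrast lesion and no annotation; normal studies carry
#' none.
#'
#' @param n_normal,n_actionable,n_benign,n_cancer study counts.
#' @param seed master seed.
#' @param preset see [phantom_preset()].
#' @return A `dbt_phantom_plan`: list with `volumes` (index-schema
#'   data.frame plus `VolSeed`), `annotations`, `lesions` (per volume
#'   key), and `preset` parameters.
#' @export
plan_dataset <- function(n_normal, n_actionable, n_benign, n_cancer,
                         seed = 1L, preset = "small") {
  p <- phantom_preset(preset)
  groups <- rep(c("normal", "actionable", "benign", "cancer"),
                c(n_normal, n_actionable, n_benign, n_cancer))
  n_st <- length(groups)
  if (n_st == 0) stop_dbt("config", "no studies requested")
  vol_rows <- NULL
  ann <- NULL
  lesions <- list()
  with_seed(seed, {
    vol_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_st * 4L),
                        n_st, 4L)
    for (s in seq_len(n_st)) {
      pid <- sprintf("P%04d", s)
      sid <- sprintf("S%04d", s)
      grp <- groups[s]
      lat <- if (grp %in% c("benign", "cancer", "actionable"))
        sample(c("L", "R"), 1) else NA
      kind <- if (!is.na(lat) && stats::runif(1) < 0.75) "mass"
              else "architectural_distortion"
      size <- if (!is.na(lat))
        stats::runif(1, p$size_range[1], p$size_range[2]) else NA
      contrast <- if (grp %in% c("benign", "cancer"))
        stats::runif(1, 4, 6) * p$noise[2]
      else if (grp == "actionable") 1.3 * p$noise[2] else NA
      for (vi in 1:4) {
        view <- c("LCC", "LMLO", "RCC", "RMLO")[vi]
        key <- vkey(pid, sid, view)
        les <- list()
        if (!is.na(lat) && substr(view, 1, 1) == lat) {
          rays <- if (kind == "architectural_distortion") draw_rays(size)
                  else NULL
          half <- if (is.null(rays)) size / 2 else ceiling(max(rays$lens))
          ctr2 <- draw_lesion_center(p, size, half)
          z <- sample_int_range(max(2L, round(0.2 * p$n_slices)),
                                min(p$n_slices - 3L,
                                    round(0.8 * p$n_slices)))
          les <- list(lesion_spec(kind, c(ctr2, z), size, contrast,
                                  if (grp == "cancer") "cancer"
                                  else "benign", rays = rays))
        }
        lesions[[key]] <- les
        vol_rows <- rbind(vol_rows, data.frame(
          PatientID = pid, StudyUID = sid, View = view, Path = "",
          NumSlices = p$n_slices, Group = grp, VolSeed = vol_seeds[s, vi],
          stringsAsFactors = FALSE))
      }
    }
  })
  plan <- structure(list(volumes = vol_rows, lesions = lesions,
                         preset = p, seed = seed),
                    class = "dbt_phantom_plan")
  plan$annotations <- plan_annotations(plan)
  plan
}

# annotation table straight from the plan's lesion geometry (no volume
# rendering needed; spicule lengths are drawn at plan time)
plan_annotations <- function(plan) {
  ann <- NULL
  for (i in seq_len(nrow(plan$volumes))) {
    v <- plan$volumes[i, ]
    if (!(v$Group %in% c("benign", "cancer"))) next
    for (l in plan$lesions[[vkey(v$PatientID, v$StudyUID, v$View)]]) {
      half <- lesion_half_extent(l)
      ann <- rbind(ann, data.frame(
        PatientID = v$PatientID, StudyUID = v$StudyUID, View = v$View,
        X = round(l$center[1] - half), Y = round(l$center[2] - half),
        Width = round(2 * half), Height = round(2 * half),
        Slice = as.integer(l$center[3]), Class = l$lesion_class,
        LesionType = l$kind, stringsAsFactors = FALSE))
    }
  }
  if (is.null(ann))
    ann <- utils::read.csv(text = paste(ANNOTATION_COLS, collapse = ","))
  ann
}

#' Generate one planned volume
#'
#' Regenerates volume `i` of a [plan_dataset()] plan, bitwise identical on
#' every call, so large datasets can be streamed without holding them in
#' memory.
#'
#' @param plan a `dbt_phantom_plan`.
#' @param i row index into `plan$volumes`.
#' @return As [generate_volume()].
#' @export
generate_plan_volume <- function(plan, i) {
  v <- plan$volumes[i, ]
  p <- plan$preset
  spec <- phantom_spec(n_slices = p$n_slices, rows = p$rows, cols = p$cols,
                       breast_a = p$breast_a, breast_b = p$breast_b,
                       skin_thickness = p$skin_thickness, noise = p$noise,
                       lesions = plan$lesions[[vkey(v$PatientID, v$StudyUID,
                                                    v$View)]],
                       seed = v$VolSeed)
  out <- generate_volume(spec, view = v$View, patient_id = v$PatientID,
                         study_id = v$StudyUID)
  if (v$Group == "actionable")
    out$annotations <- out$annotations[0, , drop = FALSE]
  out
}

#' Generate a phantom dataset on disk
#'
#' Writes one multi-frame DICOM per volume plus `volume-index.csv` and
#' `annotations.csv` (benign/cancer lesions only) in the package's CSV
#' schemas.
#'
#' @inheritParams plan_dataset
#' @param out_dir output directory (created if needed).
#' @return The plan, with `volumes$Path` filled in; index and annotation
#'   CSVs are written under `out_dir`.
#' @export
generate_dataset <- function(n_normal, n_actionable, n_benign, n_cancer,
                             out_dir, seed = 1L, preset = "small") {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_dbt("io", "cannot create ", out_dir)
  plan <- plan_dataset(n_normal, n_actionable, n_benign, n_cancer, seed,
                       preset)
  for (i in seq_len(nrow(plan$volumes))) {
    v <- plan$volumes[i, ]
    g <- generate_plan_volume(plan, i)
    path <- file.path(out_dir, sprintf("%s_%s_%s.dcm", v$PatientID,
                                       v$StudyUID, v$View))
    write_dicom_volume(path, g$volume$pixels, view = v$View,
                       patient_id = v$PatientID, study_uid = v$StudyUID,
                       window_center = g$volume$window_center,
                       window_width = g$volume$window_width)
    plan$volumes$Path[i] <- path
  }
  write_volume_index(plan$volumes[INDEX_COLS],
                     file.path(out_dir, "volume-index.csv"))
  write_annotations(plan$annotations, file.path(out_dir, "annotations.csv"))
  plan
}
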