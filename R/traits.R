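#' Biphasic muscle/fat attenuation mixture model
#'
#' Per-voxel decomposition of a Hounsfield value into fat and muscle volume
#' fractions, assuming a two-component linear mixture at a nominal 50 keV
#' effective energy. When intravenous contrast is present a configurable HU
#' offset is subtracted before decomposition.
#'
#' @param hu_muscle HU of pure muscle at the effective energy.
#' @param hu_fat HU of pure fat at the effective energy (must be below
#'   `hu_muscle`).
#' @param contrast_offset HU subtracted when the contrast flag is set.
#' @return An object of class `mixture_model`.
#' @export
mixture_model <- function(hu_muscle = 60, hu_fat = -120, contrast_offset = 0) {
  assert_that(hu_muscle > hu_fat,
              "degenerate mixture endpoints: hu_muscle must exceed hu_fat")
  structure(list(hu_muscle = hu_muscle, hu_fat = hu_fat,
                 contrast_offset = contrast_offset),
            class = "mixture_model")
}

#' Locate the two femoral head centres
#'
#' Finds the centres of the two quasi-spherical high-density bodies in a bone
#' volume. The interior distance transform of the thresholded bone mask peaks
#' at a sphere centre, so the two dominant, well-separated peaks identify the
#' heads; each is then refined as the centroid of the deep-interior voxels
#' around the peak (which for a sphere is its exact centre). With `hint`
#' points the peak search is skipped and each hint is refined the same way,
#' making the result a deterministic function of the hint.
#'
#' @param v a [bct_volume()] in HU or g/cm3.
#' @param hint optional 2 x 3 matrix of approximate centres (world mm).
#' @param threshold bone threshold in the volume's unit (default 0.05 g/cm3
#'   or 150 HU).
#' @return A 2 x 3 matrix of centres (mm), row 1 = left (smaller x),
#'   row 2 = right.
#' @export
locate_femoral_heads <- function(v, hint = NULL, threshold = NULL) {
  assert_that(inherits(v, "bct_volume"), "v must be a bct_volume")
  threshold <- threshold %||% if (v$unit == "g/cm3") 0.05 else 150
  mask <- v$data >= threshold
  assert_that(any(mask), "no bone voxels above threshold")
  dist_in <- distance_to_mask(!mask, v$spacing)
  dist_in[!mask] <- 0
  axes <- lapply(1:3, axis_coords, v = v)
  vox_world <- function(ijk) {
    c(axes[[1]][ijk[1]], axes[[2]][ijk[2]], axes[[3]][ijk[3]])
  }
  refine <- function(pt) {
    # deep-interior centroid: voxels near the local distance peak whose
    # interior depth is at least 70% of the peak depth
    idx <- pmin(pmax(round(world_to_index(v, pt)), 1), dim(v$data))
    peak <- dist_in[idx[1], idx[2], idx[3]]
    if (peak <= 0) {  # hint off the bone: snap to deepest voxel within 40 mm
      cand <- which(dist_in > 0, arr.ind = TRUE)
      w <- cbind(axes[[1]][cand[, 1]], axes[[2]][cand[, 2]], axes[[3]][cand[, 3]])
      d2 <- colSums((t(w) - as.numeric(pt))^2)
      near <- d2 <= 40^2
      assert_that(any(near), "hint is not near any bone body")
      best <- cand[near, , drop = FALSE][which.max(dist_in[cand[near, , drop = FALSE]]), ]
      pt <- vox_world(best)
      idx <- pmin(pmax(round(world_to_index(v, pt)), 1), dim(v$data))
      peak <- dist_in[idx[1], idx[2], idx[3]]
    }
    for (i in 1:8) {
      idx <- pmin(pmax(round(world_to_index(v, pt)), 1), dim(v$data))
      peak <- max(peak, dist_in[idx[1], idx[2], idx[3]])
      sel <- which(dist_in >= 0.7 * peak, arr.ind = TRUE)
      w <- cbind(axes[[1]][sel[, 1]], axes[[2]][sel[, 2]], axes[[3]][sel[, 3]])
      d2 <- colSums((t(w) - as.numeric(pt))^2)
      near <- d2 <= (1.5 * peak)^2
      if (!any(near)) break
      pt <- colMeans(w[near, , drop = FALSE])
    }
    pt
  }
  if (!is.null(hint)) {
    hint <- matrix(hint, ncol = 3)
    assert_that(nrow(hint) == 2, "hint must give two points")
    centers <- rbind(refine(hint[1, ]), refine(hint[2, ]))
  } else {
    i1 <- arrayInd(which.max(dist_in), dim(dist_in))
    p1 <- vox_world(i1)
    r1 <- max(dist_in)
    # mask out the first body and look for a second comparable peak
    co <- list(x = rep(axes[[1]], times = dim(v$data)[2] * dim(v$data)[3]),
               y = rep(rep(axes[[2]], each = dim(v$data)[1]),
                       times = dim(v$data)[3]),
               z = rep(axes[[3]], each = dim(v$data)[1] * dim(v$data)[2]))
    excl <- (co$x - p1[1])^2 + (co$y - p1[2])^2 + (co$z - p1[3])^2 <=
      (1.6 * r1)^2
    dist2 <- dist_in
    dist2[array(excl, dim = dim(dist_in))] <- 0
    if (max(dist2) < 0.7 * r1)
      stop_bct(paste("fewer than two candidate femoral heads found;",
                     "supply approximate centres via `hint`"))
    p2 <- vox_world(arrayInd(which.max(dist2), dim(dist2)))
    centers <- rbind(refine(p1), refine(p2))
  }
  centers[order(centers[, 1]), , drop = FALSE]
}

#' Distance between the femoral head centres
#'
#' Three-dimensional Euclidean distance between the left and right femoral
#' head centres (the hip-width trait).
#'
#' @param centers 2 x 3 matrix of head centres (mm).
#' @return Width in mm.
#' @export
hip_width <- function(centers) {
  centers <- matrix(centers, ncol = 3)
  assert_that(nrow(centers) == 2, "need exactly two centres")
  d <- sqrt(sum((centers[2, ] - centers[1, ])^2))
  assert_that(d > 0, "femoral head centres are coincident")
  d
}

#' Transverse section through both femoral head centres
#'
#' The 10-mm-thick transverse slab used for the gluteus maximus and posterior
#' fat measurements. Starting from the axial plane, the slab is rotated about
#' the anterior-posterior (y) axis so its mid-plane contains both head
#' centres; the rotation angle is `atan` of the superior-inferior offset over
#' the left-right offset of the centres.
#'
#' @param centers 2 x 3 matrix of head centres (mm).
#' @param thickness slab thickness in mm (default 10).
#' @return An object of class `section_geometry` with fields `center` (mm),
#'   `normal` (unit vector, z-component >= 0), `thickness` (mm) and
#'   `rotation` (radians).
#' @export
section_through_heads <- function(centers, thickness = 10) {
  centers <- matrix(centers, ncol = 3)
  d <- centers[2, ] - centers[1, ]
  assert_that(sqrt(sum(d^2)) > 0, "femoral head centres are coincident")
  if (abs(d[1]) < 1e-9 && abs(d[3]) < 1e-9)
    stop_bct("centres are separated only along the section normal; no unique rotated transverse plane")
  rotation <- atan2(d[3], d[1])
  n <- c(-d[3], 0, d[1])
  n <- n / sqrt(sum(n^2))
  if (n[3] < 0) n <- -n
  structure(list(center = colMeans(centers), normal = n,
                 thickness = thickness, rotation = rotation),
            class = "section_geometry")
}

#' Section for the gluteus medius/minimus fat measurement
#'
#' A slab parallel to the maximus section, displaced superiorly by a
#' configurable multiple of the femoral head diameter (default 1.5
#' diameters).
#'
#' @param section the maximus [section_through_heads()] geometry.
#' @param head_diameter femoral head diameter (mm, > 0).
#' @param offset_in_diameters superior displacement in head diameters.
#' @return A `section_geometry` parallel to `section`.
#' @export
medius_minimus_section <- function(section, head_diameter,
                                   offset_in_diameters = 1.5) {
  assert_that(inherits(section, "section_geometry"), "need a section_geometry")
  assert_that(head_diameter > 0, "head diameter must be > 0")
  out <- section
  out$center <- section$center +
    section$normal * offset_in_diameters * head_diameter
  out
}

#' Signed distance of points from a section mid-plane, and slab membership
#'
#' @param section a `section_geometry`.
#' @param pts n x 3 matrix of world points (mm).
#' @return `section_distance()`: signed mm distances; `section_contains()`:
#'   logical, `TRUE` when |distance| <= thickness / 2 (voxel-centre
#'   inclusion).
#' @export
section_distance <- function(section, pts) {
  pts <- matrix(pts, ncol = 3)
  as.numeric((pts - matrix(section$center, nrow(pts), 3, byrow = TRUE)) %*%
               section$normal)
}

#' @rdname section_distance
#' @export
section_contains <- function(section, pts) {
  abs(section_distance(section, pts)) <= section$thickness / 2
}

# logical slab mask over a volume's voxel centres
section_mask <- function(v, section) {
  co <- phantom_coords(list(grid_shape = dim(v$data), voxel_size = v$spacing,
                            origin = v$origin))
  d <- (co$x - section$center[1]) * section$normal[1] +
       (co$y - section$center[2]) * section$normal[2] +
       (co$z - section$center[3]) * section$normal[3]
  array(abs(d) <= section$thickness / 2, dim = dim(v$data))
}

# segment one muscle body: HU window inside the slab, split left/right at the
# section centre, connected components, component containing the seed (or the
# largest). A threshold + connected-component stand-in for the segmentation
# network used on clinical scans; adequate on phantoms with known compartments.
segment_muscle <- function(v, section, side = c("left", "right"),
                           hu_window = c(-50, 150), seed_point = NULL,
                           n_components = 1L) {
  side <- match.arg(side)
  slab <- section_mask(v, section)
  xs <- axis_coords(v, 1)
  side_ok <- if (side == "left") xs < section$center[1] else xs >= section$center[1]
  cand <- slab & (v$data >= hu_window[1]) & (v$data <= hu_window[2]) &
    array(side_ok, dim = dim(v$data))
  if (!any(cand))
    stop_bct("empty muscle segmentation on %s side", side)
  lab <- connected_components(cand)
  if (!is.null(seed_point)) {
    idx <- pmin(pmax(round(world_to_index(v, seed_point)), 1), dim(v$data))
    keep <- lab[idx[1], idx[2], idx[3]]
    if (keep == 0)
      stop_bct("seed point falls outside the segmented tissue on %s side", side)
    keep <- c(keep)
  } else {
    sizes <- tabulate(lab[lab > 0])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(n_components, length(sizes)))]
  }
  array(lab %in% keep, dim = dim(v$data))
}

#' Gluteus maximus cross-sectional area
#'
#' Area of the segmented gluteus maximus in the 10-mm transverse slab through
#' the femoral head centres, per side: slab voxel volume divided by the
#' effective slab thickness. The trait value combines sides with the *lower*
#' of left/right.
#'
#' @param v HU [bct_volume()].
#' @param section [section_through_heads()] geometry.
#' @param side `"left"`, `"right"`, or `"both"` (returns the trait value =
#'   min of sides plus per-side attribute).
#' @param hu_window HU window regarded as muscle tissue.
#' @param seed_points optional list with `left`/`right` world points inside
#'   each muscle, used to pick the connected component.
#' @return Area in cm2.
#' @export
gluteus_maximus_area <- function(v, section, side = c("both", "left", "right"),
                                 hu_window = c(-50, 150), seed_points = NULL) {
  side <- match.arg(side)
  one <- function(s) {
    mask <- segment_muscle(v, section, s, hu_window,
                           seed_point = seed_points[[s]])
    n_vox <- sum(mask)
    co <- which(mask, arr.ind = TRUE)
    w <- cbind(axis_coords(v, 1)[co[, 1]], axis_coords(v, 2)[co[, 2]],
               axis_coords(v, 3)[co[, 3]])
    dists <- section_distance(section, w)
    # effective thickness: span of included voxel layers plus one layer step
    h_layer <- sum(abs(section$normal) * v$spacing)
    t_eff <- (max(dists) - min(dists)) + h_layer
    n_vox * prod(v$spacing) / t_eff / 100  # cm^2
  }
  if (side != "both") return(one(side))
  per_side <- c(left = one("left"), right = one("right"))
  structure(min(per_side), sides = per_side)
}

#' Posterior subcutaneous fat thickness
#'
#' Along the posterior ray from each femoral head centre (within the head
#' section), the distance between the muscle-fat and fat-skin interfaces of
#' the subcutaneous fat layer. The ray is sampled with trilinear
#' interpolation; the most posterior contiguous fat run before the exterior
#' is taken as the subcutaneous layer. The trait value is the *lower* of the
#' two sides.
#'
#' @param v HU [bct_volume()].
#' @param section the head section (the rays lie in its mid-plane).
#' @param centers 2 x 3 matrix of head centres (mm).
#' @param fat_window HU interval classified as fat.
#' @param air_threshold HU below which a sample counts as exterior.
#' @param step ray sampling step (mm).
#' @return Thickness in mm (min of sides), with per-side values in attribute
#'   `sides`.
#' @export
posterior_fat_thickness <- function(v, section, centers,
                                    fat_window = c(-180, -30),
                                    air_threshold = -400, step = 0.25) {
  centers <- matrix(centers, ncol = 3)
  cross <- function(t, hu, i, level) {
    # sub-sample position where hu crosses `level` between samples i and i+1
    a <- hu[i]; b <- hu[i + 1]
    if (a == b) t[i] else t[i] + (a - level) / (a - b) * (t[i + 1] - t[i])
  }
  one <- function(s) {
    p0 <- centers[s, ]
    tmax <- p0[2] - v$origin[2]
    t <- seq(0, tmax, by = step)
    pts <- cbind(p0[1], p0[2] - t, p0[3])
    hu <- interp_trilinear(v, pts)
    n <- length(hu)
    if (hu[n] > air_threshold)
      stop_bct("posterior ray exits the grid before reaching the skin surface (%s side)",
               c("left", "right")[s])
    # fat-skin interface: where the ray enters the trailing exterior-air
    # block; muscle-fat interface: the last point anterior to it where the
    # signal still reads muscle/soft tissue (above the fat window)
    a0 <- n
    while (a0 > 1 && hu[a0 - 1] <= air_threshold) a0 <- a0 - 1
    if (a0 == 1)
      stop_bct("posterior ray sees no tissue before the skin surface (%s side)",
               c("left", "right")[s])
    skin_pos <- cross(t, hu, a0 - 1, air_threshold)
    m_idx <- a0 - 1
    while (m_idx > 1 && hu[m_idx] <= fat_window[2]) m_idx <- m_idx - 1
    muscle_pos <- if (hu[m_idx] > fat_window[2])
      cross(t, hu, m_idx, fat_window[2]) else t[m_idx]
    max(skin_pos - muscle_pos, 0)
  }
  per_side <- c(left = one(1), right = one(2))
  structure(min(per_side), sides = per_side)
}

#' Intramuscular fat fraction from the mixture model
#'
#' For each voxel in the muscle mask, the fat volume fraction is
#' `f = (hu_muscle - HU') / (hu_muscle - hu_fat)` with
#' `HU' = HU - contrast_offset` when contrast is present, clamped to
#' `[0, 1]`. The returned value is `100 * mean(f)` over the mask.
#'
#' @param v HU [bct_volume()].
#' @param muscle_mask logical array over `v`'s grid.
#' @param m a [mixture_model()].
#' @param contrast_present logical; subtract the contrast offset first.
#' @return Percent fat by volume in `[0, 100]`.
#' @export
intramuscular_fat_fraction <- function(v, muscle_mask, m = mixture_model(),
                                       contrast_present = FALSE) {
  assert_that(inherits(m, "mixture_model"), "m must be a mixture_model")
  assert_that(any(muscle_mask), "empty muscle mask")
  hu <- v$data[muscle_mask]
  if (isTRUE(contrast_present)) hu <- hu - m$contrast_offset
  f <- (m$hu_muscle - hu) / (m$hu_muscle - m$hu_fat)
  100 * mean(pmin(pmax(f, 0), 1))
}

#' Trabecular/cortical BMD ratio
#'
#' Within the region of interest, the cortical compartment is every bone
#' voxel with apparent density >= 1.0 g/cm3 *or* within 2 mm of the
#' periosteal surface (ties at exactly 2 mm count as cortical); the
#' trabecular compartment is the remainder. Returns mean trabecular density
#' over mean cortical density.
#'
#' @param density a [bct_volume()] in g/cm3.
#' @param femur_mask logical array marking bone (defines the periosteal
#'   surface).
#' @param roi_z length-2 z range (mm) of the axial ROI slab, typically from
#'   just below the femoral head centre down to just below the greater
#'   trochanter.
#' @param density_cutoff cortical density rule (g/cm3).
#' @param shell_mm cortical shell depth rule (mm).
#' @return Unitless ratio.
#' @export
trab_cort_ratio <- function(density, femur_mask, roi_z,
                            density_cutoff = 1.0, shell_mm = 2) {
  assert_that(density$unit == "g/cm3", "density volume must be in g/cm3")
  assert_that(any(femur_mask), "empty femur mask")
  zc <- axis_coords(density, 3)
  in_z <- zc >= min(roi_z) & zc <= max(roi_z)
  roi <- femur_mask &
    array(rep(in_z, each = prod(dim(density$data)[1:2])), dim = dim(density$data))
  assert_that(any(roi), "trabecular/cortical ROI contains no bone")
  dist_surf <- distance_to_mask(!femur_mask, density$spacing)
  cort <- roi & (density$data >= density_cutoff | dist_surf <= shell_mm)
  trab <- roi & !cort
  assert_that(any(cort), "cortical compartment is empty in the ROI")
  assert_that(any(trab), "trabecular compartment is empty in the ROI")
  mean(density$data[trab]) / mean(density$data[cort])
}

#' Femoral neck volume
#'
#' Volume of bone inside the femoral neck region of interest (the same region
#' as used for the femoral neck BMD measurement; on phantoms, the cylindrical
#' neck primitive).
#'
#' @param v a [bct_volume()] supplying the voxel geometry.
#' @param femur_mask logical array marking bone.
#' @param neck_roi list with `base` (mm, the head centre), `axis` (unit
#'   direction), `s_range` (axial mm range) and `radius` (mm).
#' @return Volume in cm3.
#' @export
femoral_neck_volume <- function(v, femur_mask, neck_roi) {
  co <- phantom_coords(list(grid_shape = dim(v$data), voxel_size = v$spacing,
                            origin = v$origin))
  roi <- cylinder_mask(co, neck_roi$base, neck_roi$axis, neck_roi$s_range,
                       neck_roi$radius)
  roi <- array(roi, dim = dim(v$data))
  assert_that(any(roi), "empty femoral neck ROI")
  sum(femur_mask & roi) * prod(v$spacing) / 1000
}

#' Configuration for full trait extraction
#'
#' @param target_spacing isotropic resampling target (mm).
#' @param mixture a [mixture_model()].
#' @param contrast_present logical contrast flag.
#' @param muscle_hu_window HU window for muscle segmentation.
#' @param offset_in_diameters superior offset of the medius/minimus section,
#'   in head diameters (default 1.5; 1.0 is also in clinical use).
#' @param head_hint optional 2 x 3 matrix of approximate head centres.
#' @param imf_erosion_mm erosion applied to the medius/minimus mask before
#'   the fat-fraction average, excluding partial-volume boundary voxels
#'   (mm; 0 disables).
#' @param trabcort_roi_z explicit z range for the trabecular/cortical ROI; if
#'   `NULL`, defaults to 5 mm below the head-centre plane down 25 mm.
#' @param neck_axis,neck_radius,neck_s_range femoral neck ROI geometry
#'   (right-side axis; x mirrored for the left).
#' @param neck_side which side's neck volume is reported (`"left"`
#'   nominally).
#' @param bone_density_threshold g/cm3 above which a voxel is bone.
#' @return A list of class `trait_config`.
#' @export
trait_config <- function(target_spacing = 1,
                         mixture = mixture_model(),
                         contrast_present = FALSE,
                         muscle_hu_window = c(-50, 150),
                         offset_in_diameters = 1.5,
                         imf_erosion_mm = 1,
                         head_hint = NULL,
                         trabcort_roi_z = NULL,
                         neck_axis = c(0.8, 0, -0.6),
                         neck_radius = 15,
                         neck_s_range = c(25, 65),
                         neck_side = "left",
                         bone_density_threshold = 0.05) {
  structure(list(target_spacing = target_spacing, mixture = mixture,
                 contrast_present = contrast_present,
                 muscle_hu_window = muscle_hu_window,
                 offset_in_diameters = offset_in_diameters,
                 imf_erosion_mm = imf_erosion_mm,
                 head_hint = head_hint, trabcort_roi_z = trabcort_roi_z,
                 neck_axis = neck_axis / sqrt(sum(neck_axis^2)),
                 neck_radius = neck_radius, neck_s_range = neck_s_range,
                 neck_side = neck_side,
                 bone_density_threshold = bone_density_threshold),
            class = "trait_config")
}

#' Measure all six image-derived physical traits
#'
#' Composes the individual trait operations: head localisation, hip width,
#' the head section and its superiorly offset medius/minimus section, muscle
#' area (min of sides), posterior fat thickness (min of sides), intramuscular
#' fat (mean of sides), trabecular/cortical BMD ratio and femoral neck
#' volume. A trait whose anatomy cannot be measured (e.g. truncated by the
#' grid) is flagged missing rather than aborting the whole measurement.
#'
#' @param hu HU [bct_volume()].
#' @param density matching density [bct_volume()] in g/cm3.
#' @param config a [trait_config()].
#' @return An object of class `trait_measurements`: list with `values` (named
#'   numeric: trab_cort_ratio, fat_thickness, muscle_area, intramuscular_fat,
#'   fn_volume, hip_width), `sides` (per-side intermediates), `missing`
#'   (named logical), `centers`, `section` and `errors` (messages for missing
#'   traits).
#' @export
measure_all_traits <- function(hu, density, config = trait_config()) {
  assert_that(inherits(config, "trait_config"), "config must be a trait_config")
  if (any(abs(hu$spacing - config$target_spacing) > 1e-9))
    hu <- resample_isotropic(hu, config$target_spacing)
  if (any(abs(density$spacing - config$target_spacing) > 1e-9))
    density <- resample_isotropic(density, config$target_spacing)

  values <- setNames(rep(NA_real_, 6),
                     c("trab_cort_ratio", "fat_thickness", "muscle_area",
                       "intramuscular_fat", "fn_volume", "hip_width"))
  sides <- list()
  errors <- list()
  grab <- function(trait, expr) {
    tryCatch(expr, error = function(e) {
      errors[[trait]] <<- conditionMessage(e)
      NA_real_
    })
  }

  centers <- locate_femoral_heads(density, hint = config$head_hint,
                                  threshold = config$bone_density_threshold)
  values["hip_width"] <- grab("hip_width", hip_width(centers))
  section <- section_through_heads(centers)
  head_diameter <- 2 * max(distance_to_mask(
    !(density$data >= config$bone_density_threshold), density$spacing))

  values["muscle_area"] <- grab("muscle_area", {
    a <- gluteus_maximus_area(hu, section, "both", config$muscle_hu_window)
    sides$muscle_area <- attr(a, "sides")
    as.numeric(a)
  })
  values["fat_thickness"] <- grab("fat_thickness", {
    ft <- posterior_fat_thickness(hu, section, centers)
    sides$fat_thickness <- attr(ft, "sides")
    as.numeric(ft)
  })
  values["intramuscular_fat"] <- grab("intramuscular_fat", {
    mm_sec <- medius_minimus_section(section, head_diameter,
                                     config$offset_in_diameters)
    per_side <- vapply(c("left", "right"), function(s) {
      mask <- segment_muscle(hu, mm_sec, s, config$muscle_hu_window,
                             n_components = 2L)
      if (config$imf_erosion_mm > 0) {
        core <- mask & (distance_to_mask(!mask, hu$spacing) >
                          config$imf_erosion_mm)
        if (any(core)) mask <- core  # drop partial-volume boundary voxels
      }
      intramuscular_fat_fraction(hu, mask, config$mixture,
                                 config$contrast_present)
    }, numeric(1))
    sides$intramuscular_fat <- per_side
    mean(per_side)  # average of left/right
  })
  femur_mask <- density$data >= config$bone_density_threshold
  values["trab_cort_ratio"] <- grab("trab_cort_ratio", {
    roi_z <- config$trabcort_roi_z %||%
      (mean(centers[, 3]) - 5 - c(25, 0))
    trab_cort_ratio(density, femur_mask, roi_z)
  })
  values["fn_volume"] <- grab("fn_volume", {
    s <- if (config$neck_side == "left") 1 else 2
    ax <- config$neck_axis * c(if (s == 1) -1 else 1, 1, 1)
    femoral_neck_volume(density, femur_mask,
                        list(base = centers[s, ], axis = ax,
                             s_range = config$neck_s_range,
                             radius = config$neck_radius))
  })

  structure(list(values = values, sides = sides,
                 missing = is.na(values), centers = centers,
                 section = section, errors = errors),
            class = "trait_measurements")
}

#' @export
print.trait_measurements <- function(x, ...) {
  cat("<trait_measurements>\n")
  for (nm in names(x$values)) {
    cat(sprintf("  %-18s %s\n", nm,
                if (is.na(x$values[nm])) paste0("missing (", x$errors[[nm]], ")")
                else signif(x$values[nm], 5)))
  }
  invisible(x)
}
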