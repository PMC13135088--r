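#' Specification of a parametric hip phantom
#'
#' Builds the configuration for a stylised voxel phantom of the hip region:
#' two spherical femoral heads with cylindrical necks (cortical shell around a
#' trabecular interior), three gluteal muscles per side as ellipsoids with a
#' prescribed intramuscular fat fraction, a posterior subcutaneous fat slab
#' per side, and air elsewhere. Every trait the extraction stage measures has
#' a closed-form value computable from these parameters, which
#' [generate_phantom()] returns as ground truth.
#'
#' Coordinates are world mm: x left-to-right, y posterior-to-anterior,
#' z inferior-to-superior; the origin sits midway between the femoral heads.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size mm per axis.
#' @param origin world mm of the centre of voxel `[1, 1, 1]`.
#' @param head_centers 2 x 3 matrix, left and right femoral head centres (mm).
#' @param head_radius femoral head radius (mm).
#' @param neck_axis unit direction of the right femoral neck, head to
#'   trochanter (x mirrored for the left side).
#' @param neck_length,neck_radius femoral neck cylinder dimensions (mm); the
#'   cylinder spans axial distance `[head_radius, head_radius + neck_length]`
#'   from the head centre, so it is disjoint from the head sphere.
#' @param cortical_shell_thickness outer bone shell thickness (mm).
#' @param cortical_density,trabecular_density apparent densities (g/cm3).
#' @param muscle_regions per-muscle, per-side ellipsoids: a list with entries
#'   `maximus`, `medius`, `minimus`, each a list with `left`/`right`, each of
#'   those `list(center, semiaxes)` in mm.
#' @param muscle_fat_fraction fat volume fraction in `[0, 1]` per muscle
#'   (named vector: maximus, medius, minimus).
#' @param subcut_fat_thickness_posterior posterior fat slab thickness (mm),
#'   named `left`/`right`.
#' @param fat_inner_y posterior y coordinate (mm) of the inner (anterior) fat
#'   slab surface.
#' @param background HU of the surround (air by default; the phantom is a
#'   bodies-in-air stylisation, so the outer fat surface plays the role of
#'   the skin boundary).
#' @param noise_sd additive Gaussian HU noise (0 = noise free).
#' @param contrast_offset HU added to muscle voxels, emulating intravenous
#'   contrast enhancement.
#' @param hu_muscle,hu_fat pure-tissue HU at the nominal 50 keV effective
#'   energy.
#' @param density_slope,density_intercept affine map from bone apparent
#'   density (g/cm3) to HU.
#' @param seed integer RNG seed used for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(240L, 170L, 170L),
                         voxel_size = c(1, 1, 1),
                         origin = c(-120, -120, -70),
                         head_centers = rbind(c(-50, 0, 0), c(50, 0, 0)),
                         head_radius = 25,
                         neck_axis = c(0.8, 0, -0.6),
                         neck_length = 40,
                         neck_radius = 15,
                         cortical_shell_thickness = 2,
                         cortical_density = 1.2,
                         trabecular_density = 0.3,
                         muscle_regions = default_muscle_regions(),
                         muscle_fat_fraction = c(maximus = 0.15, medius = 0.25,
                                                 minimus = 0.25),
                         subcut_fat_thickness_posterior = c(left = 20, right = 20),
                         fat_inner_y = -85,
                         background = -1000,
                         noise_sd = 0,
                         contrast_offset = 0,
                         hu_muscle = 60,
                         hu_fat = -120,
                         density_slope = 800,
                         density_intercept = 0,
                         seed = 1L) {
  spec <- list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
               origin = origin, head_centers = head_centers,
               head_radius = head_radius, neck_axis = neck_axis / sqrt(sum(neck_axis^2)),
               neck_length = neck_length, neck_radius = neck_radius,
               cortical_shell_thickness = cortical_shell_thickness,
               cortical_density = cortical_density,
               trabecular_density = trabecular_density,
               muscle_regions = muscle_regions,
               muscle_fat_fraction = muscle_fat_fraction,
               subcut_fat_thickness_posterior = subcut_fat_thickness_posterior,
               fat_inner_y = fat_inner_y, background = background,
               noise_sd = noise_sd, contrast_offset = contrast_offset,
               hu_muscle = hu_muscle, hu_fat = hu_fat,
               density_slope = density_slope,
               density_intercept = density_intercept, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

#' Default gluteal muscle ellipsoids (right side; left mirrored in x)
#' @return Nested list of per-muscle, per-side `list(center, semiaxes)` (mm).
#' @export
default_muscle_regions <- function() {
  mirror <- function(m) { m$center[1] <- -m$center[1]; m }
  right <- list(
    maximus = list(center = c(45, -60, 0),  semiaxes = c(30, 25, 45)),
    medius  = list(center = c(48, -15, 75), semiaxes = c(18, 15, 22)),
    minimus = list(center = c(40, 15, 75),  semiaxes = c(12, 12, 18)))
  lapply(right, function(m) list(left = mirror(m), right = m))
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    assert_that(all(grid_shape >= 2) && all(voxel_size > 0),
                "grid_shape and voxel_size must be positive")
    assert_that(head_radius > 0 && neck_length > 0 && neck_radius > 0 &&
                cortical_shell_thickness > 0, "all lengths must be > 0")
    assert_that(cortical_density >= 0 && trabecular_density >= 0,
                "densities must be >= 0")
    assert_that(all(muscle_fat_fraction >= 0 & muscle_fat_fraction <= 1),
                "muscle fat fractions must lie in [0, 1]")
    assert_that(hu_muscle > hu_fat, "hu_muscle must exceed hu_fat")
    assert_that(all(subcut_fat_thickness_posterior >= 0),
                "fat thickness must be >= 0")
  })
  lo <- spec$origin
  hi <- spec$origin + (spec$grid_shape - 1) * spec$voxel_size
  inside <- function(bmin, bmax, what) {
    assert_that(all(bmin >= lo - 1e-9) && all(bmax <= hi + 1e-9),
                "phantom primitive '%s' extends beyond the grid", what)
  }
  for (s in 1:2) {
    ctr <- spec$head_centers[s, ]
    side <- if (s == 1) "left" else "right"
    inside(ctr - spec$head_radius, ctr + spec$head_radius,
           paste("femoral head", side))
    ax <- spec$neck_axis * c(if (s == 1) -1 else 1, 1, 1)
    far <- ctr + ax * (spec$head_radius + spec$neck_length)
    inside(pmin(ctr, far) - spec$neck_radius, pmax(ctr, far) + spec$neck_radius,
           paste("femoral neck", side))
  }
  for (m in names(spec$muscle_regions))
    for (side in c("left", "right")) {
      e <- spec$muscle_regions[[m]][[side]]
      inside(e$center - e$semiaxes, e$center + e$semiaxes,
             paste(m, side))
    }
  invisible(spec)
}

phantom_coords <- function(spec) {
  ax <- lapply(1:3, function(a)
    spec$origin[a] + (seq_len(spec$grid_shape[a]) - 1) * spec$voxel_size[a])
  n <- spec$grid_shape
  list(x = rep(ax[[1]], times = n[2] * n[3]),
       y = rep(rep(ax[[2]], each = n[1]), times = n[3]),
       z = rep(ax[[3]], each = n[1] * n[2]))
}

ellipsoid_mask <- function(co, e) {
  ((co$x - e$center[1]) / e$semiaxes[1])^2 +
  ((co$y - e$center[2]) / e$semiaxes[2])^2 +
  ((co$z - e$center[3]) / e$semiaxes[3])^2 <= 1
}

cylinder_mask <- function(co, base, axis, s_range, radius) {
  vx <- co$x - base[1]; vy <- co$y - base[2]; vz <- co$z - base[3]
  s <- vx * axis[1] + vy * axis[2] + vz * axis[3]
  rho2 <- vx^2 + vy^2 + vz^2 - s^2
  s >= s_range[1] & s <= s_range[2] & rho2 <= radius^2
}

neck_axis_side <- function(spec, side) {
  spec$neck_axis * c(if (side == "left") -1 else 1, 1, 1)
}

# analytic (closed-form) trait values implied by a phantom spec,
# independent of voxelisation
phantom_ground_truth <- function(spec) {
  d <- spec$head_centers[2, ] - spec$head_centers[1, ]
  hip_width <- sqrt(sum(d^2))
  # mid-plane of the head section at the z of each maximus centre: the plane
  # contains both head centres, so for equal-height heads it is z = head z
  plane_z <- mean(spec$head_centers[, 3])
  area <- vapply(c("left", "right"), function(side) {
    e <- spec$muscle_regions$maximus[[side]]
    dz <- plane_z - e$center[3]
    if (abs(dz) >= e$semiaxes[3]) return(0)
    pi * e$semiaxes[1] * e$semiaxes[2] * (1 - (dz / e$semiaxes[3])^2) / 100
  }, numeric(1))  # cm^2
  volumes <- function(m) {
    vapply(c("left", "right"), function(side) {
      e <- spec$muscle_regions[[m]][[side]]
      4 / 3 * pi * prod(e$semiaxes)
    }, numeric(1))
  }
  f <- spec$muscle_fat_fraction
  imf_side <- vapply(c("left", "right"), function(side) {
    vmed <- volumes("medius")[side]; vmin <- volumes("minimus")[side]
    100 * (f[["medius"]] * vmed + f[["minimus"]] * vmin) / (vmed + vmin)
  }, numeric(1))
  fn_vol <- pi * spec$neck_radius^2 * spec$neck_length / 1000  # cm^3
  troch <- lapply(c(left = 1, right = 2), function(s) {
    spec$head_centers[s, ] +
      neck_axis_side(spec, c("left", "right")[s]) *
        (spec$head_radius + spec$neck_length)
  })
  list(
    hip_width = hip_width,
    head_centers = spec$head_centers,
    head_diameter = 2 * spec$head_radius,
    fat_thickness_side = spec$subcut_fat_thickness_posterior,
    fat_thickness = min(spec$subcut_fat_thickness_posterior),
    muscle_area_side = area,
    muscle_area = min(area),
    intramuscular_fat_side = imf_side,
    intramuscular_fat = mean(imf_side),
    fn_volume_side = c(left = fn_vol, right = fn_vol),
    fn_volume = fn_vol,
    trab_cort_ratio = spec$trabecular_density / spec$cortical_density,
    trochanter = troch,
    # ROI bounds the extractor uses on phantoms: axial slab from just below
    # the head centre to just below the trochanter landmark (5 mm offsets)
    trabcort_roi_z = c(min(troch$left[3], troch$right[3]) - 5, plane_z - 5),
    neck_roi = list(radius = spec$neck_radius,
                    s_range = c(spec$head_radius,
                                spec$head_radius + spec$neck_length)))
}

#' Generate a voxel phantom with closed-form ground truth
#'
#' Rasterises a [phantom_spec()] into an HU volume and a paired apparent-
#' density volume (g/cm3, bone only), and returns the analytic trait values
#' implied by the spec. The ground truth is computed from the geometry alone
#' and never from the voxel data, so it is an independent reference for the
#' extraction stage.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `hu` ([bct_volume()], Hounsfield Units),
#'   `density` ([bct_volume()], g/cm3), `ground_truth` (closed-form trait
#'   values and extraction ROIs), and `spec`.
#' @export
generate_phantom <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  validate_phantom_spec(spec)
  co <- phantom_coords(spec)
  n <- prod(spec$grid_shape)
  hu <- rep(spec$background, n)
  density <- numeric(n)

  # muscles: biphasic muscle/fat mixture HU, plus any contrast enhancement
  f <- spec$muscle_fat_fraction
  for (m in names(spec$muscle_regions)) {
    hu_mix <- spec$hu_muscle + f[[m]] * (spec$hu_fat - spec$hu_muscle) +
      spec$contrast_offset
    for (side in c("left", "right")) {
      mask <- ellipsoid_mask(co, spec$muscle_regions[[m]][[side]])
      hu[mask] <- hu_mix
    }
  }

  # posterior subcutaneous fat slabs (one per side)
  for (side in c("left", "right")) {
    t_fat <- spec$subcut_fat_thickness_posterior[[side]]
    if (t_fat <= 0) next
    xs <- if (side == "left") co$x < 0 else co$x >= 0
    mask <- xs & co$y <= spec$fat_inner_y & co$y >= spec$fat_inner_y - t_fat
    hu[mask] <- spec$hu_fat
  }

  # bone: heads + necks; cortical shell by distance to the periosteal surface
  bone <- rep(FALSE, n)
  for (s in 1:2) {
    ctr <- spec$head_centers[s, ]
    side <- c("left", "right")[s]
    bone <- bone |
      ((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2 <=
         spec$head_radius^2) |
      cylinder_mask(co, ctr, neck_axis_side(spec, side),
                    c(spec$head_radius, spec$head_radius + spec$neck_length),
                    spec$neck_radius)
  }
  bone_arr <- array(bone, dim = spec$grid_shape)
  dist_out <- distance_to_mask(!bone_arr, spec$voxel_size)
  cortical <- bone & (as.vector(dist_out) <= spec$cortical_shell_thickness)
  density[bone] <- spec$trabecular_density
  density[cortical] <- spec$cortical_density
  hu[bone] <- spec$density_slope * density[bone] + spec$density_intercept

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu <- hu + rnorm(n, 0, spec$noise_sd)
  }

  list(hu = bct_volume(array(hu, spec$grid_shape), spec$voxel_size,
                       unit = "HU", origin = spec$origin),
       density = bct_volume(array(density, spec$grid_shape), spec$voxel_size,
                            unit = "g/cm3", origin = spec$origin),
       ground_truth = phantom_ground_truth(spec),
       spec = spec)
}
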