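# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, value) {
  if (!exists(key, .fixture_cache)) assign(key, value, .fixture_cache)
  get(key, .fixture_cache)
}

# full-size noise-free phantom (the precision reference)
default_phantom <- function() memo("default_phantom",
                                   generate_phantom(phantom_spec()))

default_phantom_traits <- function() memo("default_traits", {
  ph <- default_phantom()
  cfg <- trait_config(trabcort_roi_z = ph$ground_truth$trabcort_roi_z)
  measure_all_traits(ph$hu, ph$density, cfg)
})

# compact phantom for rule/robustness tests (2 mm voxels, small anatomy);
# closed-form ground truth still holds
mini_phantom_spec <- function(...) {
  mirror <- function(m) { m$center[1] <- -m$center[1]; m }
  right <- list(
    maximus = list(center = c(28, -40, 0), semiaxes = c(16, 14, 24)),
    medius  = list(center = c(28, -10, 36), semiaxes = c(10, 8, 12)),
    minimus = list(center = c(24, 8, 36),  semiaxes = c(7, 7, 9)))
  args <- list(
    grid_shape = c(80L, 70L, 70L), voxel_size = c(2, 2, 2),
    origin = c(-80, -90, -50),
    head_centers = rbind(c(-30, 0, 0), c(30, 0, 0)), head_radius = 12,
    neck_length = 20, neck_radius = 7,
    muscle_regions = lapply(right, function(m) list(left = mirror(m),
                                                    right = m)),
    subcut_fat_thickness_posterior = c(left = 10, right = 10),
    fat_inner_y = -54)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantom_spec, args)
}

mini_trait_config <- function(spec = mini_phantom_spec()) {
  gt <- generate_phantom(spec)$ground_truth
  trait_config(trabcort_roi_z = gt$trabcort_roi_z,
               neck_radius = spec$neck_radius,
               neck_s_range = c(spec$head_radius,
                                spec$head_radius + spec$neck_length))
}

# small cohort for statistics tests
small_cohort <- function(seed = 1, F = 6000, M = 3000, ...) {
  generate_cohort(cohort_spec(n_per_sex = c(F = F, M = M), seed = seed, ...))
}

# reflect a volume about the mid-sagittal (x = 0) plane
mirror_volume_x <- function(v) {
  nx <- dim(v$data)[1]
  flipped <- v$data[nx:1, , , drop = FALSE]
  x_max <- v$origin[1] + (nx - 1) * v$spacing[1]
  bct_volume(flipped, v$spacing, unit = v$unit,
             origin = c(-x_max, v$origin[2], v$origin[3]))
}

# crop a volume to world y >= y_min (drops the posterior part of the grid)
crop_posterior <- function(v, y_min) {
  ys <- v$origin[2] + (seq_len(dim(v$data)[2]) - 1) * v$spacing[2]
  keep <- which(ys >= y_min)
  bct_volume(v$data[, keep, , drop = FALSE], v$spacing, unit = v$unit,
             origin = c(v$origin[1], ys[keep[1]], v$origin[3]))
}
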