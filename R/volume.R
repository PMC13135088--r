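#' CT-like scalar volume
#'
#' A minimal 3-D volume container: a numeric array plus voxel spacing (mm),
#' value unit, and the world coordinate (mm) of the centre of voxel
#' `[1, 1, 1]`. Axis order is x (left-right), y (posterior-anterior),
#' z (inferior-superior).
#'
#' @param data 3-D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis (> 0).
#' @param unit `"HU"` (Hounsfield Units) or `"g/cm3"` (apparent density).
#' @param origin numeric length-3, mm position of the centre of voxel
#'   `[1, 1, 1]`.
#' @return An object of class `bct_volume`.
#' @export
bct_volume <- function(data, spacing, unit = c("HU", "g/cm3"),
                       origin = c(0, 0, 0)) {
  unit <- match.arg(unit)
  assert_that(is.array(data) && length(dim(data)) == 3L,
              "volume data must be a 3-D array")
  assert_that(length(spacing) == 3L && all(spacing > 0),
              "spacing must be three positive mm values")
  assert_that(all(is.finite(data)), "volume contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing), unit = unit,
                 origin = as.numeric(origin)),
            class = "bct_volume")
}

#' @export
print.bct_volume <- function(x, ...) {
  cat(sprintf("<bct_volume> %s, dim %s, spacing %s mm, origin (%s) mm\n",
              x$unit, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

# world-coordinate axis vectors (mm, voxel centres)
axis_coords <- function(v, axis) {
  v$origin[axis] + (seq_len(dim(v$data)[axis]) - 1) * v$spacing[axis]
}

# fractional (1-based) array index of world points; pts is n x 3 (mm)
world_to_index <- function(v, pts) {
  pts <- matrix(pts, ncol = 3)
  sweep(sweep(pts, 2, v$origin, "-"), 2, v$spacing, "/") + 1
}

# trilinear interpolation of volume values at scattered world points (n x 3 mm);
# coordinates outside the grid are clamped to the border voxel centres
interp_trilinear <- function(v, pts) {
  idx <- world_to_index(v, pts)
  dm <- dim(v$data)
  ax <- pmin(pmax(idx[, 1], 1), dm[1])
  ay <- pmin(pmax(idx[, 2], 1), dm[2])
  az <- pmin(pmax(idx[, 3], 1), dm[3])
  i0 <- pmin(floor(ax), dm[1] - 1L); wx <- ax - i0
  j0 <- pmin(floor(ay), dm[2] - 1L); wy <- ay - j0
  k0 <- pmin(floor(az), dm[3] - 1L); wz <- az - k0
  g <- function(i, j, k) v$data[cbind(i, j, k)]
  (1 - wz) * ((1 - wy) * ((1 - wx) * g(i0, j0, k0) + wx * g(i0 + 1, j0, k0)) +
              wy       * ((1 - wx) * g(i0, j0 + 1, k0) + wx * g(i0 + 1, j0 + 1, k0))) +
  wz       * ((1 - wy) * ((1 - wx) * g(i0, j0, k0 + 1) + wx * g(i0 + 1, j0, k0 + 1)) +
              wy       * ((1 - wx) * g(i0, j0 + 1, k0 + 1) + wx * g(i0 + 1, j0 + 1, k0 + 1)))
}

# linear interpolation of an array along one margin at fractional indices fi
interp_axis <- function(a, axis, fi) {
  dm <- dim(a)
  fi <- pmin(pmax(fi, 1), dm[axis])
  i0 <- pmin(floor(fi), dm[axis] - 1L)
  w <- fi - i0
  take <- function(i) {
    ix <- rep(list(quote(expr = )), 3)
    ix[[axis]] <- i
    do.call(`[`, c(list(a), ix, list(drop = FALSE)))
  }
  lo <- take(i0)
  hi <- take(i0 + 1L)
  wshape <- c(1L, 1L, 1L)
  wshape[axis] <- length(fi)
  lo + array(rep(w, each = prod(dm[seq_len(axis - 1)])),
             dim = replace(dm, axis, length(fi))) * (hi - lo)
}

#' Resample a volume to isotropic voxels
#'
#' Separable linear interpolation onto an isotropic grid. The output grid
#' starts at the input origin and has `round(extent / target)` voxels per
#' axis, where extent is voxel count times spacing. When the input is already
#' isotropic at the target spacing the result is bitwise identical.
#'
#' @param v a [bct_volume()].
#' @param target target voxel size in mm (> 0), default 1.
#' @return A [bct_volume()] with `spacing = c(target, target, target)`.
#' @export
resample_isotropic <- function(v, target = 1) {
  assert_that(inherits(v, "bct_volume"), "v must be a bct_volume")
  assert_that(is.numeric(target) && length(target) == 1L && target > 0,
              "target voxel size must be a single positive mm value")
  dm <- dim(v$data)
  newdim <- pmax(as.integer(round(dm * v$spacing / target)), 1L)
  a <- v$data
  for (axis in 1:3) {
    if (newdim[axis] == dm[axis] && isTRUE(all.equal(v$spacing[axis], target)))
      next
    fi <- ((seq_len(newdim[axis]) - 1) * target) / v$spacing[axis] + 1
    a <- interp_axis(a, axis, fi)
  }
  bct_volume(a, rep(target, 3), unit = v$unit, origin = v$origin)
}

#' Write / read a volume in NIfTI format
#'
#' The array and voxel spacing are stored in the NIfTI file; the unit and
#' world origin travel in a small JSON sidecar (`<path>.meta.json`) so a
#' round trip restores the object exactly.
#'
#' @param v a [bct_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [bct_volume()].
#' @export
write_volume <- function(v, path) {
  assert_that(inherits(v, "bct_volume"), "v must be a bct_volume")
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(unit = v$unit, origin = v$origin,
                            spacing = v$spacing),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  assert_that(file.exists(path), "volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  spacing <- RNifti::pixdim(img)[1:3]
  bct_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing,
             unit = meta$unit %||% "HU",
             origin = as.numeric(unlist(meta$origin %||% c(0, 0, 0))))
}

# Euclidean distance (mm) from each voxel to the nearest TRUE voxel
distance_to_mask <- function(mask, spacing) {
  assert_that(any(mask), "distance transform of an empty mask")
  .edt3d(mask, dim(mask), as.numeric(spacing))
}

# connected components of a logical 3-D mask, 6-connectivity
connected_components <- function(mask) {
  .label3d(mask, dim(mask))
}
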