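# Uniform 3D Cartesian occupancy and annotation grids, anchored in world
# space. Voxel i (0-based) spans the half-open world interval
# [origin + i*h, origin + (i+1)*h) on each axis; grids are isotropic.

#' Grid specification
#'
#' World-space anchoring of a uniform, isotropic voxel grid.
#'
#' @param origin numeric length-3: world position of the grid's minimum corner
#'   (\eqn{\mu m}).
#' @param voxel_size scalar voxel side length (\eqn{\mu m}); the voxelization
#'   resolution in voxels per micron is `1 / voxel_size`.
#' @param dims integer length-3: voxels per axis.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin, voxel_size, dims) {
  origin <- as.numeric(origin)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(dims) == 3)
  if (!is.finite(voxel_size) || voxel_size <= 0) {
    stop_param("grid_spec: voxel_size must be > 0 (got %g)", voxel_size)
  }
  if (any(dims < 1L)) stop_param("grid_spec: all dims must be >= 1")
  structure(list(origin = origin, voxel_size = as.numeric(voxel_size),
                 dims = dims),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec %d x %d x %d voxels, h = %g um, origin (%g, %g, %g)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Build a grid covering a world-space box
#'
#' Creates the smallest grid at the requested resolution whose extent contains
#' `aabb` expanded by `padding_voxels` voxels on every side. Padding keeps
#' rasterized shells away from the grid boundary so that flood filling always
#' has an exterior corridor.
#'
#' @param aabb an [aabb3] box.
#' @param resolution voxels per micron (> 0).
#' @param padding_voxels integer voxels added on every side (default 2).
#' @return A [grid_spec].
#' @export
grid_from_aabb <- function(aabb, resolution, padding_voxels = 2L) {
  stopifnot(inherits(aabb, "aabb3"))
  if (!is.finite(resolution) || resolution <= 0) {
    stop_param("grid_from_aabb: resolution must be > 0 (got %g)", resolution)
  }
  padding_voxels <- as.integer(padding_voxels)
  h <- 1 / resolution
  extent <- aabb$max - aabb$min
  core <- as.integer(ceiling(extent * resolution - 1e-9))
  core <- pmax(core, 1L)
  dims <- core + 2L * padding_voxels
  origin <- aabb$min - padding_voxels * h
  grid_spec(origin, h, dims)
}

#' World-space box of one voxel
#'
#' @param spec a [grid_spec].
#' @param index 0-based integer triple.
#' @return An [aabb3] spanning `[origin + index*h, origin + (index+1)*h]`.
#' @export
voxel_world_box <- function(spec, index) {
  stopifnot(inherits(spec, "grid_spec"))
  index <- as.integer(index)
  if (any(index < 0L) || any(index >= spec$dims)) {
    stop_param("voxel_world_box: index (%s) out of range for dims (%s)",
               paste(index, collapse = ","), paste(spec$dims, collapse = ","))
  }
  aabb3(spec$origin + index * spec$voxel_size,
        spec$origin + (index + 1L) * spec$voxel_size)
}

#' Map world points to 0-based voxel indices
#'
#' @param spec a [grid_spec].
#' @param points n x 3 matrix of world points.
#' @return n x 3 integer matrix of 0-based indices (unclamped).
#' @export
world_to_index <- function(spec, points) {
  points <- rbind(points)
  idx <- floor(sweep(sweep(points, 2, spec$origin), 2, spec$voxel_size, "/"))
  storage.mode(idx) <- "integer"
  idx
}

#' Voxel centers of 0-based indices
#' @param spec a [grid_spec].
#' @param index n x 3 integer matrix (0-based).
#' @return n x 3 matrix of world-space voxel centers.
#' @export
index_to_center <- function(spec, index) {
  index <- rbind(index)
  sweep((index + 0.5) * spec$voxel_size, 2, spec$origin, "+")
}

#' Occupancy bit grid
#'
#' One occupancy flag per voxel. Kept as a logical array in memory for fast
#' whole-grid operations; serialized in 1-bit packed form (see
#' [write_volume()]), which takes exactly `ceiling(prod(dims) / 8)` bytes.
#'
#' @param spec a [grid_spec].
#' @param bits optional logical array of dim `spec$dims` (default all unset).
#' @return An object of class `bit_grid`.
#' @export
bit_grid <- function(spec, bits = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(bits)) {
    bits <- array(FALSE, dim = spec$dims)
  } else {
    bits <- as.logical(bits)
    if (length(bits) != prod(spec$dims)) {
      stop_param("bit_grid: bits length %d != prod(dims) %d",
                 length(bits), prod(spec$dims))
    }
    bits <- array(bits, dim = spec$dims)
  }
  structure(list(spec = spec, bits = bits), class = "bit_grid")
}

#' @export
print.bit_grid <- function(x, ...) {
  cat(sprintf("<bit_grid %d x %d x %d, %d set voxels, h = %g um>\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              count_set(x), x$spec$voxel_size))
  invisible(x)
}

#' Count set voxels
#' @param grid a [bit_grid].
#' @return Integer count of set voxels.
#' @export
count_set <- function(grid) {
  stopifnot(inherits(grid, "bit_grid"))
  sum(grid$bits)
}

#' Annotated voxel grid
#'
#' One non-negative integer label per voxel; 0 means background.
#'
#' @param spec a [grid_spec].
#' @param labels optional integer array (default all 0).
#' @return An object of class `annotated_grid`.
#' @export
annotated_grid <- function(spec, labels = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(labels)) {
    labels <- array(0L, dim = spec$dims)
  } else {
    labels <- as.integer(labels)
    if (length(labels) != prod(spec$dims)) {
      stop_param("annotated_grid: labels length mismatch")
    }
    if (any(labels < 0L)) stop_param("annotated_grid: labels must be >= 0")
    labels <- array(labels, dim = spec$dims)
  }
  structure(list(spec = spec, labels = labels), class = "annotated_grid")
}

#' Paint occupancy into an annotation grid
#'
#' Voxels set in `source` receive `label` in `target`; later calls overwrite
#' earlier labels (painter's order).
#'
#' @param target an [annotated_grid].
#' @param source a [bit_grid] with an identical [grid_spec].
#' @param label positive integer label.
#' @return The updated [annotated_grid].
#' @export
tag_occupancy <- function(target, source, label) {
  stopifnot(inherits(target, "annotated_grid"), inherits(source, "bit_grid"))
  if (!isTRUE(all.equal(target$spec$origin, source$spec$origin)) ||
      target$spec$voxel_size != source$spec$voxel_size ||
      !all(target$spec$dims == source$spec$dims)) {
    stop_param("tag_occupancy: grid specs differ between target and source")
  }
  label <- as.integer(label)
  if (label < 0L) stop_param("tag_occupancy: label must be >= 0")
  target$labels[source$bits] <- label
  target
}
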