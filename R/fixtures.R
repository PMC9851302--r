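# Deterministic synthetic fixtures: analytic shapes with known topology and
# volume, defect injection emulating segmentation damage (deleted and
# duplicated facets, jitter, shifted overlapping partitions), and SWC
# morphology generators. Everything is seeded and reproducible; nothing is
# downloaded or stored.

#' Icosphere fixture
#'
#' @param radius sphere radius (\eqn{\mu m}).
#' @param subdivisions icosahedron subdivision level (0 = 20 triangles).
#' @param center sphere center.
#' @return A closed [surface_mesh] with Euler characteristic 2; vertices
#'   lie exactly on the sphere, so the enclosed volume approaches
#'   \eqn{4\pi r^3/3} from below as subdivisions increase.
#' @export
make_icosphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  if (radius <= 0) stop_param("make_icosphere: radius must be > 0")
  icosphere_mesh(radius, subdivisions, center)
}

#' Torus fixture
#'
#' @param R major radius (center of tube to axis).
#' @param r minor (tube) radius, r < R.
#' @param segments major-circle segment count (minor circle uses
#'   `ceiling(segments / 2)`).
#' @param center torus center; the symmetry axis is z.
#' @return A closed [surface_mesh] with Euler characteristic 0 and
#'   analytic volume \eqn{2\pi^2 R r^2} in the smooth limit.
#' @export
make_torus <- function(R = 2, r = 0.8, segments = 48L, center = c(0, 0, 0)) {
  if (r >= R) stop_param("make_torus: need r < R")
  nu <- as.integer(segments)
  nv <- as.integer(ceiling(segments / 2))
  iu <- rep(seq_len(nu) - 1L, each = nv)
  iv <- rep(seq_len(nv) - 1L, times = nu)
  u <- 2 * pi * iu / nu
  v <- 2 * pi * iv / nv
  verts <- cbind((R + r * cos(v)) * cos(u),
                 (R + r * cos(v)) * sin(u),
                 r * sin(v))
  vid <- function(a, b) (a %% nu) * nv + (b %% nv) + 1L
  a <- iu; b <- iv
  t1 <- cbind(vid(a, b), vid(a + 1L, b), vid(a + 1L, b + 1L))
  t2 <- cbind(vid(a, b), vid(a + 1L, b + 1L), vid(a, b + 1L))
  surface_mesh(sweep(verts, 2, center, "+"), rbind(t1, t2))
}

#' Axis-aligned box fixture
#'
#' @param extent scalar or length-3 edge lengths.
#' @param center box center.
#' @return A closed 12-triangle [surface_mesh] with volume `prod(extent)`.
#' @export
make_box <- function(extent = 1, center = c(0, 0, 0)) {
  e <- rep(extent, length.out = 3) / 2
  v <- as.matrix(expand.grid(x = c(-e[1], e[1]), y = c(-e[2], e[2]),
                             z = c(-e[3], e[3])))
  quads <- list(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
  surface_mesh(sweep(v, 2, center, "+"), triangulate_ngons(quads))
}

#' Break a mesh into a defective triangle soup
#'
#' Seeded damage emulating segmentation output: random triangle deletion
#' (boundary edges), duplication (duplicate facets), vertex jitter and
#' shifted overlapping copies of the whole mesh (self-intersecting
#' partitions). The result is asserted to fail watertightness.
#'
#' @param mesh a watertight [surface_mesh].
#' @param seed RNG seed.
#' @param del_frac fraction of triangles to delete.
#' @param dup_frac fraction of triangles to duplicate.
#' @param jitter vertex jitter standard deviation (\eqn{\mu m}).
#' @param n_shift_partitions copies of the mesh shifted by half its radius
#'   into itself.
#' @return A defective [surface_mesh] soup.
#' @export
break_mesh <- function(mesh, seed = 1L, del_frac = 0.05, dup_frac = 0.0,
                       jitter = 0, n_shift_partitions = 0L) {
  stopifnot(del_frac >= 0, del_frac <= 1, dup_frac >= 0, dup_frac <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- mesh$triangles
  m <- nrow(t)
  if (del_frac > 0) {
    ndel <- max(1L, round(del_frac * m))
    t <- t[-sample.int(nrow(t), ndel), , drop = FALSE]
  }
  if (dup_frac > 0) {
    ndup <- max(1L, round(dup_frac * m))
    t <- rbind(t, t[sample.int(nrow(t), ndup), , drop = FALSE])
  }
  v <- mesh$vertices
  if (jitter > 0) v <- v + matrix(rnorm(length(v), sd = jitter), ncol = 3)
  out <- surface_mesh(v, t)
  if (n_shift_partitions > 0) {
    box <- mesh_aabb(mesh)
    shift_mag <- 0.25 * vnorm(box$max - box$min)
    copies <- list(out)
    for (i in seq_len(n_shift_partitions)) {
      dir <- rnorm(3)
      dir <- dir / vnorm(dir)
      copies[[i + 1L]] <- translate_mesh(mesh, dir * shift_mag)
    }
    out <- merge_meshes(copies)
  }
  rep0 <- watertightness_report(out)
  stopifnot(!rep0$is_watertight)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Synthetic neuron SWC text
#'
#' A three-sample type-1 soma block followed by recursively bifurcating
#' neurites with tapering radii. Radii stay at or above 0.35 um so that
#' branches remain resolvable at the default 5 voxels per micron.
#'
#' @param seed RNG seed (byte-identical output per seed).
#' @param depth bifurcation depth (0 = unbranched stems).
#' @param branch_prob probability that a section bifurcates at each level.
#' @param taper per-level radius multiplier.
#' @param n_stems root neurites leaving the soma.
#' @return Character vector of SWC lines.
#' @export
make_neuron_swc <- function(seed = 1L, depth = 2L, branch_prob = 1.0,
                            taper = 0.85, n_stems = 3L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  soma_r <- 1.6
  rows <- list(c(1, 1, 0, 0, 0, soma_r, -1),
               c(2, 1, 0.3, 0, 0, soma_r * 0.9, 1),
               c(3, 1, -0.3, 0, 0, soma_r * 0.9, 1))
  next_id <- 4L
  emit_section <- function(parent_id, start, dir, radius, level) {
    n_seg <- 3L
    step <- 1.1
    pid <- parent_id
    pos <- start
    for (i in seq_len(n_seg)) {
      bend <- rnorm(3, sd = 0.12)
      dir <- dir + bend
      dir <- dir / vnorm(dir)
      pos <- pos + dir * step
      r <- max(radius * (1 - 0.05 * i), 0.35)
      rows[[length(rows) + 1L]] <<- c(next_id, 3, pos, r, pid)
      pid <- next_id
      next_id <<- next_id + 1L
    }
    if (level < depth && runif(1) <= branch_prob) {
      axis <- perp_frame(dir)[1, ]
      for (s in c(-1, 1)) {
        child_dir <- dir + s * 0.8 * axis
        child_dir <- child_dir / vnorm(child_dir)
        emit_section(pid, pos, child_dir, max(radius * taper, 0.35), level + 1L)
      }
    }
  }
  dirs <- rbind(c(1, 0, 0), c(-0.4, 1, 0.2), c(-0.3, -0.9, 0.4),
                c(0.2, 0.1, -1), c(0.8, -0.5, 0.6))
  for (s in seq_len(n_stems)) {
    d <- dirs[(s - 1L) %% nrow(dirs) + 1L, ]
    d <- d / vnorm(d)
    emit_section(1L, d * soma_r, d, 0.6, 0L)
  }
  vapply(rows, function(r) {
    sprintf("%d %d %.6f %.6f %.6f %.6f %d", as.integer(r[1]), as.integer(r[2]),
            r[3], r[4], r[5], r[6], as.integer(r[7]))
  }, "")
}

#' Synthetic vascular network SWC text
#'
#' A chain of `n_loops` rectangular loops sharing junction nodes; loops
#' are closed by repeating the closing sample's coordinates (the SWC
#' parent pointer cannot express a back edge). The resulting graph has
#' cycle-space rank `n_loops`.
#'
#' @param seed RNG seed.
#' @param n_loops independent cycles (>= 1).
#' @param radius vessel radius (\eqn{\mu m}).
#' @param loop_size loop edge length (\eqn{\mu m}).
#' @return Character vector of SWC lines.
#' @export
make_vessel_graph <- function(seed = 1L, n_loops = 1L, radius = 0.5,
                              loop_size = 4) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- list()
  nid <- 0L
  add <- function(pos, r, parent) {
    nid <<- nid + 1L
    rows[[nid]] <<- c(nid, 2, pos, r, parent)
    nid
  }
  half <- loop_size / 2
  for (k in seq_len(n_loops)) {
    x0 <- (k - 1) * loop_size
    jitter_r <- radius * (1 + 0.1 * runif(4))
    corner <- rbind(c(x0, -half, 0), c(x0 + loop_size, -half, 0),
                    c(x0 + loop_size, half, 0), c(x0, half, 0))
    if (k == 1) {
      a <- add(corner[1, ], jitter_r[1], -1L)
    } else {
      a <- start_of_next   # shared junction with previous loop
    }
    b <- add(corner[2, ], jitter_r[2], a)
    c_ <- add(corner[3, ], jitter_r[3], b)
    d <- add(corner[4, ], jitter_r[4], c_)
    # close the loop: coincident coordinates with corner 1
    add(corner[1, ], jitter_r[1], d)
    start_of_next <- b
  }
  vapply(rows, function(r) {
    sprintf("%d %d %.6f %.6f %.6f %.6f %d", as.integer(r[1]), as.integer(r[2]),
            r[3], r[4], r[5], r[6], as.integer(r[7]))
  }, "")
}

#' Synthetic astrocyte fixture
#'
#' A small process skeleton plus `n_endfeet` triangular endfoot patches
#' with per-vertex thickness, placed near process terminals.
#'
#' @param seed RNG seed.
#' @param n_endfeet endfoot patch count.
#' @return List with `swc` (character lines) and `endfeet`
#'   (`endfoot_patch` list, serializable with [write_endfeet_json()]).
#' @export
make_astrocyte <- function(seed = 1L, n_endfeet = 2L) {
  swc <- make_neuron_swc(seed = seed, depth = 1L, branch_prob = 1,
                         n_stems = 2L)
  tab <- do.call(rbind, lapply(strsplit(swc, " "), as.numeric))
  tips <- tab[tab[, 1] %in% setdiff(tab[, 1], tab[, 7]), , drop = FALSE]
  tips <- tips[tips[, 2] != 1, , drop = FALSE]
  patches <- lapply(seq_len(n_endfeet), function(i) {
    tip <- tips[(i - 1L) %% nrow(tips) + 1L, 3:5]
    r <- max(tips[(i - 1L) %% nrow(tips) + 1L, 6], 0.4)
    base <- tip + c(0.8, 0, 0)
    v <- rbind(base + c(0, -1.0, 0), base + c(0, 1.0, 0),
               base + c(0.9, 0, 0.8), base + c(0.9, 0, -0.8))
    structure(list(vertices = v,
                   thickness = rep(2 * r, 4),
                   triangles = matrix(c(1L, 2L, 3L, 1L, 4L, 2L), 2, 3,
                                      byrow = TRUE)),
              class = "endfoot_patch")
  })
  list(swc = swc, endfeet = patches)
}

#' Serialize endfeet patches to the JSON sidecar schema
#' @param patches list of `endfoot_patch`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_endfeet_json <- function(patches, path) {
  payload <- lapply(patches, function(p) {
    list(vertices = unclass(p$vertices), thickness = p$thickness,
         triangles = unclass(p$triangles))
  })
  jsonlite::write_json(payload, path, digits = NA)
  invisible(path)
}

#' Ball occupancy mask
#'
#' @param radius_voxels ball radius in voxels; voxels whose center lies
#'   within the radius of the grid center are set.
#' @param dims grid dims (default fits the ball with 2 voxels padding).
#' @param voxel_size voxel size (default 1).
#' @return A [bit_grid]; the attribute `n_set` records the exact count.
#' @export
make_ball_mask <- function(radius_voxels, dims = NULL, voxel_size = 1) {
  r <- radius_voxels
  if (is.null(dims)) dims <- rep(2L * ceiling(r) + 5L, 3L)
  dims <- as.integer(dims)
  spec <- grid_spec(c(0, 0, 0), voxel_size, dims)
  ctr <- (dims - 1) / 2
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) - ctr[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  g <- bit_grid(spec, d2 <= r^2 + 1e-9)
  attr(g, "n_set") <- sum(g$bits)
  g
}
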