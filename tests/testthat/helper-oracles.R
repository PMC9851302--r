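# Independent oracles and small utilities shared by the tests. Each oracle
# is deliberately implemented with a different algorithm than the code path
# it checks.

euler_char <- function(mesh) {
  topo <- build_topology(mesh)
  nrow(mesh$vertices) - length(topo$edges$count) + nrow(mesh$triangles)
}

genus_of <- function(mesh) (2 - euler_char(mesh)) / 2

# --- brute-force self-intersection oracle -------------------------------
# All non-adjacent pairs, tested by Moller-Trumbore segment/triangle
# crossing of each triangle's edges against the other triangle (general
# position; distinct from the interval-based kernel under test).
seg_tri_cross <- function(p0, p1, a, b, c) {
  d <- p1 - p0
  e1 <- b - a
  e2 <- c - a
  pv <- c(d[2] * e2[3] - d[3] * e2[2],
          d[3] * e2[1] - d[1] * e2[3],
          d[1] * e2[2] - d[2] * e2[1])
  det <- sum(e1 * pv)
  if (abs(det) < 1e-14) return(FALSE)
  tv <- p0 - a
  u <- sum(tv * pv) / det
  if (u < -1e-9 || u > 1 + 1e-9) return(FALSE)
  qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
          tv[3] * e1[1] - tv[1] * e1[3],
          tv[1] * e1[2] - tv[2] * e1[1])
  v <- sum(d * qv) / det
  if (v < -1e-9 || u + v > 1 + 1e-9) return(FALSE)
  t <- sum(e2 * qv) / det
  t >= -1e-9 && t <= 1 + 1e-9
}

tri_pair_crosses <- function(A, B) {
  for (i in 1:3) {
    j <- i %% 3 + 1
    if (seg_tri_cross(A[i, ], A[j, ], B[1, ], B[2, ], B[3, ])) return(TRUE)
    if (seg_tri_cross(B[i, ], B[j, ], A[1, ], A[2, ], A[3, ])) return(TRUE)
  }
  FALSE
}

self_intersections_oracle <- function(mesh) {
  t <- mesh$triangles
  V <- mesh$vertices
  m <- nrow(t)
  hits <- matrix(integer(0), 0, 2)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (length(intersect(t[i, ], t[j, ]))) next
      if (tri_pair_crosses(V[t[i, ], ], V[t[j, ], ])) {
        hits <- rbind(hits, c(i, j))
      }
    }
  }
  hits
}

# --- 3D flood-fill oracle -----------------------------------------------
# 6-connected exterior flood from all boundary voxels; solid = shell plus
# complement of the exterior.
flood3d_oracle <- function(grid) {
  d <- grid$spec$dims
  b <- grid$bits
  ext <- array(FALSE, dim = d)
  idx <- which(!b, arr.ind = TRUE)
  border <- idx[idx[, 1] %in% c(1, d[1]) | idx[, 2] %in% c(1, d[2]) |
                idx[, 3] %in% c(1, d[3]), , drop = FALSE]
  frontier <- border
  ext[border] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(frontier) > 0) {
    nxt <- do.call(rbind, lapply(1:6, function(k) sweep(frontier, 2, offs[k, ], "+")))
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] & nxt[, 2] >= 1 & nxt[, 2] <= d[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= d[3]
    nxt <- nxt[ok, , drop = FALSE]
    new <- nxt[!ext[nxt] & !b[nxt], , drop = FALSE]
    if (!nrow(new)) break
    new <- unique(new)
    ext[new] <- TRUE
    frontier <- new
  }
  bit_grid(grid$spec, b | !ext)
}

# --- surface voxelization oracle ----------------------------------------
# Exhaustive all-(triangle, voxel) overlap test through the exported
# single-pair predicate.
surface_voxelize_oracle <- function(mesh, spec) {
  d <- spec$dims
  bits <- array(FALSE, dim = d)
  for (x in seq_len(d[1]) - 1L) {
    for (y in seq_len(d[2]) - 1L) {
      for (z in seq_len(d[3]) - 1L) {
        box <- voxel_world_box(spec, c(x, y, z))
        for (f in seq_len(nrow(mesh$triangles))) {
          tri <- mesh$vertices[mesh$triangles[f, ], ]
          if (triangle_box_overlap(tri, box)) {
            bits[x + 1L, y + 1L, z + 1L] <- TRUE
            break
          }
        }
      }
    }
  }
  bit_grid(spec, bits)
}

# --- centripetal Catmull-Rom closed form (Barry-Goldman pyramid) --------
bg_catmull_rom <- function(P, u) {
  t <- c(0, cumsum(rowSums(diff(P)^2)^0.25))
  A1 <- outer((t[2] - u) / (t[2] - t[1]), P[1, ]) + outer((u - t[1]) / (t[2] - t[1]), P[2, ])
  A2 <- outer((t[3] - u) / (t[3] - t[2]), P[2, ]) + outer((u - t[2]) / (t[3] - t[2]), P[3, ])
  A3 <- outer((t[4] - u) / (t[4] - t[3]), P[3, ]) + outer((u - t[3]) / (t[4] - t[3]), P[4, ])
  B1 <- ((t[3] - u) / (t[3] - t[1])) * A1 + ((u - t[1]) / (t[3] - t[1])) * A2
  B2 <- ((t[4] - u) / (t[4] - t[2])) * A2 + ((u - t[2]) / (t[4] - t[2])) * A3
  ((t[3] - u) / (t[3] - t[2])) * B1 + ((u - t[2]) / (t[3] - t[2])) * B2
}

# --- misc fixtures -------------------------------------------------------
punctured_icosphere <- function(radius = 2, subdivisions = 3, cap_deg = 12) {
  ico <- make_icosphere(radius, subdivisions)
  cen <- tri_centroids_of(ico)
  ang <- acos(pmin(1, cen[, 3] / sqrt(rowSums(cen^2))))
  keep <- ang > cap_deg * pi / 180
  surface_mesh(ico$vertices, ico$triangles[keep, , drop = FALSE])
}

tri_centroids_of <- function(mesh) {
  (mesh$vertices[mesh$triangles[, 1], , drop = FALSE] +
   mesh$vertices[mesh$triangles[, 2], , drop = FALSE] +
   mesh$vertices[mesh$triangles[, 3], , drop = FALSE]) / 3
}

tri_areas_of <- function(mesh) voxmesh:::tri_areas(mesh)

# 26-connected component count of the set voxels of a bit grid.
voxel_components_26 <- function(grid) {
  idx <- which(grid$bits, arr.ind = TRUE)
  if (!nrow(idx)) return(0L)
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  id_of <- stats::setNames(seq_len(nrow(idx)), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, offs[k, ], "+")
    nb_key <- paste(nb[, 1], nb[, 2], nb[, 3])
    hit <- !is.na(id_of[nb_key])
    if (any(hit)) edges <- rbind(edges, cbind(which(hit), id_of[nb_key[hit]]))
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

write_swc_tmp <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

random_small_mesh <- function(seed) {
  set.seed(seed)
  n_tri <- sample(2:6, 1)
  verts <- matrix(runif(9 * n_tri, 0.2, 2.2), ncol = 3)
  surface_mesh(verts, matrix(seq_len(3 * n_tri), ncol = 3, byrow = TRUE))
}
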