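# Indexed triangle set. Triangle soups are legal: no connectivity or
# orientation constraints at construction; analysis and repair derive and
# enforce structure as needed.

#' Indexed triangle mesh
#'
#' @param vertices n x 3 numeric matrix of world-space points (\eqn{\mu m}).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3) stop_param("surface_mesh: vertices must be n x 3")
  if (nrow(triangles) > 0) {
    if (ncol(triangles) != 3) stop_param("surface_mesh: triangles must be m x 3")
    if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
      stop_param("surface_mesh: triangle index out of range")
    }
    if (any(triangles[, 1] == triangles[, 2] |
            triangles[, 2] == triangles[, 3] |
            triangles[, 1] == triangles[, 3])) {
      stop_param("surface_mesh: a triangle repeats a vertex index")
    }
  } else {
    triangles <- matrix(integer(0), 0, 3)
  }
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh %d vertices, %d triangles>\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

n_triangles <- function(mesh) nrow(mesh$triangles)
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Fan-triangulate polygons
#'
#' Splits every n-gon (n > 3) into a fan of n - 2 triangles anchored at its
#' first vertex; triangles pass through unchanged.
#'
#' @param polygons list of integer index vectors (1-based), each of length
#'   3 or more with distinct entries.
#' @return m x 3 integer triangle matrix.
#' @export
triangulate_ngons <- function(polygons) {
  if (!length(polygons)) return(matrix(integer(0), 0, 3))
  tris <- lapply(polygons, function(p) {
    p <- as.integer(p)
    if (length(p) < 3) {
      stop_format("triangulate_ngons: polygon with %d < 3 vertices", length(p))
    }
    k <- length(p)
    cbind(p[1], p[2:(k - 1)], p[3:k])
  })
  out <- do.call(rbind, tris)
  storage.mode(out) <- "integer"
  out
}

#' Mesh bounding box
#' @param mesh a [surface_mesh].
#' @return An [aabb3].
#' @export
mesh_aabb <- function(mesh) {
  if (n_vertices(mesh) == 0) stop_param("mesh_aabb: empty mesh")
  aabb3(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}

translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, offset, "+")
  mesh
}

#' Weld coincident vertices
#'
#' Vertices closer than `tol` are merged (snap-to-grid on a `tol` lattice) so
#' that float export/import of shared corners cannot fabricate boundary
#' edges. Triangles that degenerate under welding are dropped.
#'
#' @param mesh a [surface_mesh].
#' @param tol welding tolerance in \eqn{\mu m} (default 1e-6).
#' @return A welded [surface_mesh].
#' @export
weld_vertices <- function(mesh, tol = 1e-6) {
  if (n_vertices(mesh) == 0) return(mesh)
  key <- apply(round(mesh$vertices / tol), 1, paste, collapse = "_")
  first <- !duplicated(key)
  map <- match(key, key[first])
  verts <- mesh$vertices[first, , drop = FALSE]
  tris <- matrix(map[mesh$triangles], ncol = 3)
  keep <- tris[, 1] != tris[, 2] & tris[, 2] != tris[, 3] & tris[, 1] != tris[, 3]
  surface_mesh(verts, tris[keep, , drop = FALSE])
}

# Remove exact-duplicate triangles (same vertex set) and zero-area triangles;
# drop unreferenced vertices. Returns mesh plus removal counts.
clean_triangles <- function(mesh, area_tol = 1e-12) {
  tris <- mesh$triangles
  if (nrow(tris) == 0) return(list(mesh = mesh, n_duplicate = 0L, n_degenerate = 0L))
  skey <- apply(tris, 1, function(t) paste(sort(t), collapse = "_"))
  dup <- duplicated(skey)
  a <- tri_areas(mesh)
  degen <- a <= area_tol
  keep <- !dup & !degen
  out <- drop_unused_vertices(surface_mesh(mesh$vertices, tris[keep, , drop = FALSE]))
  list(mesh = out, n_duplicate = sum(dup), n_degenerate = sum(degen & !dup))
}

drop_unused_vertices <- function(mesh) {
  used <- sort(unique(as.vector(mesh$triangles)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  map <- integer(nrow(mesh$vertices))
  map[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(map[mesh$triangles], ncol = 3))
}

tri_corner <- function(mesh, k) mesh$vertices[mesh$triangles[, k], , drop = FALSE]

tri_areas <- function(mesh) {
  a <- tri_corner(mesh, 1); b <- tri_corner(mesh, 2); c <- tri_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * rownorms(cr)
}

tri_normals <- function(mesh) {
  a <- tri_corner(mesh, 1); b <- tri_corner(mesh, 2); c <- tri_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  normalize_rows(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                       e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                       e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]))
}

tri_centroids <- function(mesh) {
  (tri_corner(mesh, 1) + tri_corner(mesh, 2) + tri_corner(mesh, 3)) / 3
}

#' Total surface area
#' @param mesh a [surface_mesh].
#' @return Area in \eqn{\mu m^2}.
#' @export
surface_area <- function(mesh) sum(tri_areas(mesh))

signed_volume <- function(mesh) {
  a <- tri_corner(mesh, 1); b <- tri_corner(mesh, 2); c <- tri_corner(mesh, 3)
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Orientation is fixed internally by propagating from a seed triangle across
#' shared edges; the sign of the summed signed tetrahedron volumes is then
#' normalized positive. Meshes with boundary edges have no defined interior.
#'
#' @param mesh a closed [surface_mesh] (possibly multiple closed partitions).
#' @return Volume in \eqn{\mu m^3}.
#' @export
enclosed_volume <- function(mesh) {
  if (n_triangles(mesh) == 0) stop_param("enclosed_volume: empty mesh")
  topo <- build_topology(mesh)
  if (length(boundary_edges(topo))) {
    stop_param("enclosed_volume: mesh has %d boundary edges, no defined interior",
               length(boundary_edges(topo)))
  }
  parts <- split_partitions(mesh)
  sum(vapply(parts, function(p) {
    abs(signed_volume(orient_consistently(p)))
  }, numeric(1)))
}

# Propagate a coherent triangle orientation from an arbitrary seed across
# manifold (incidence-2) edges; flips the minority side. Requires each
# connected component to be orientable.
orient_consistently <- function(mesh) {
  m <- n_triangles(mesh)
  if (m == 0) return(mesh)
  ed <- edge_incidence(mesh)
  two <- which(ed$count == 2L)
  # adjacency pairs and whether the shared edge is traversed in the same
  # direction by both triangles (same direction => inconsistent orientation)
  t1 <- ed$tri1[two]; t2 <- ed$tri2[two]
  same <- ed$dir1[two] == ed$dir2[two]
  adj <- vector("list", m)
  for (i in seq_along(two)) {
    adj[[t1[i]]] <- c(adj[[t1[i]]], i)
    adj[[t2[i]]] <- c(adj[[t2[i]]], i)
  }
  flip <- rep(NA, m)
  for (seed in seq_len(m)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      t <- queue[[1]]; queue <- queue[-1]
      for (i in adj[[t]]) {
        o <- if (t1[i] == t) t2[i] else t1[i]
        want <- if (same[i]) !flip[t] else flip[t]
        if (is.na(flip[o])) {
          flip[o] <- want
          queue <- c(queue, o)
        }
      }
    }
  }
  tris <- mesh$triangles
  if (any(flip)) tris[flip, c(2, 3)] <- tris[flip, c(3, 2)]
  out <- surface_mesh(mesh$vertices, tris)
  if (signed_volume(out) < 0) out$triangles[, c(2, 3)] <- out$triangles[, c(3, 2)]
  out
}
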