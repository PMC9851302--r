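# Geometric comparison measures between surfaces.

# Deterministic area-weighted surface sampling: all vertices plus extra
# points drawn per face with a Kronecker (golden-ratio) low-discrepancy
# sequence of barycentric coordinates; no RNG involved.
sample_surface <- function(mesh, n_samples) {
  pts <- mesh$vertices
  extra <- n_samples - nrow(pts)
  if (extra > 0 && n_triangles(mesh) > 0) {
    areas <- tri_areas(mesh)
    alloc <- floor(extra * areas / sum(areas))
    rem <- extra - sum(alloc)
    if (rem > 0) {
      top <- order(-(extra * areas / sum(areas) - alloc))[seq_len(rem)]
      alloc[top] <- alloc[top] + 1L
    }
    face <- rep.int(seq_along(alloc), alloc)
    k <- length(face)
    if (k > 0) {
      i <- seq_len(k)
      u <- (i * 0.7548776662466927) %% 1       # plastic-number sequence
      v <- (i * 0.5698402909980532) %% 1
      flip <- u + v > 1
      u[flip] <- 1 - u[flip]
      v[flip] <- 1 - v[flip]
      a <- mesh$vertices[mesh$triangles[face, 1], , drop = FALSE]
      b <- mesh$vertices[mesh$triangles[face, 2], , drop = FALSE]
      c <- mesh$vertices[mesh$triangles[face, 3], , drop = FALSE]
      pts <- rbind(pts, a + u * (b - a) + v * (c - a))
    }
  }
  pts
}

#' Symmetric Hausdorff distance estimate
#'
#' Maximum over sampled surface points of one mesh of the exact
#' point-to-triangle distance to the other mesh, maximized both ways.
#' Samples comprise all vertices plus deterministic area-weighted face
#' samples totalling at least `n_samples` per mesh.
#'
#' @param a,b non-empty [surface_mesh] objects.
#' @param n_samples minimum samples per mesh (default 1000).
#' @return Distance in \eqn{\mu m}.
#' @export
hausdorff_distance <- function(a, b, n_samples = 1000) {
  if (n_triangles(a) == 0 || n_triangles(b) == 0) {
    stop_param("hausdorff_distance: both meshes must be non-empty")
  }
  pa <- sample_surface(a, n_samples)
  pb <- sample_surface(b, n_samples)
  max(max(cpp_min_dist_to_mesh(pa, b$vertices, b$triangles)),
      max(cpp_min_dist_to_mesh(pb, a$vertices, a$triangles)))
}

#' Point containment by ray parity
#'
#' @param mesh a closed [surface_mesh].
#' @param points n x 3 matrix of query points.
#' @return Logical vector, `TRUE` for points inside.
#' @export
points_in_mesh <- function(mesh, points) {
  points <- rbind(points)
  storage.mode(points) <- "double"
  cpp_points_in_mesh(points, mesh$vertices, mesh$triangles)
}

#' Boundary surface of a tetrahedral mesh
#'
#' Faces appearing in exactly one tetrahedron, oriented outward (away from
#' the owning tetrahedron's centroid).
#'
#' @param tets k x 4 integer matrix of tetrahedron vertex indices (1-based).
#' @param vertices n x 3 matrix.
#' @return A [surface_mesh] of the boundary faces.
#' @export
extract_tet_boundary <- function(tets, vertices) {
  tets <- rbind(tets)
  storage.mode(tets) <- "integer"
  vertices <- as.matrix(vertices)
  if (nrow(tets) == 0) return(surface_mesh(vertices, matrix(integer(0), 0, 3)))
  if (any(tets < 1L) || any(tets > nrow(vertices))) {
    stop_param("extract_tet_boundary: tet index out of range")
  }
  faces_of <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(k) tets[, faces_of[k, ], drop = FALSE]))
  owner <- rep(seq_len(nrow(tets)), 4)
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "_"))
  once <- key %in% names(which(table(key) == 1))
  faces <- faces[once, , drop = FALSE]
  owner <- owner[once]
  # orient outward from the owning tet centroid
  tc <- t(vapply(owner, function(i) colMeans(vertices[tets[i, ], , drop = FALSE]),
                 numeric(3)))
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  inward <- rowSums(n * ((a + b + c_) / 3 - tc)) < 0
  faces[inward, c(2, 3)] <- faces[inward, c(3, 2)]
  drop_unused_vertices(surface_mesh(vertices, faces))
}
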