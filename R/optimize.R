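# Angle-based adaptive coarsening and normal-based smoothing. Re-tessellates
# densely triangulated isosurface output: nearly coplanar regions (flat
# coarsening) and under-length edges (dense coarsening) are simplified by
# batched edge collapses that respect manifoldness and orientation.

#' Optimization parameters
#'
#' @param iterations coarsening/smoothing iterations (default 5, the
#'   operating point of the resolution/iteration tuning study).
#' @param flat_angle_deg interior edges whose face pair deviates by less
#'   than this dihedral angle are collapse candidates (default 8).
#' @param dense_angle_deg short edges are only collapsed where the local
#'   dihedral deviation stays below this guard angle (default 60).
#' @param min_edge_length edges shorter than this are dense-coarsening
#'   candidates (\eqn{\mu m}; default 0 disables dense coarsening).
#' @return An `optimization_params` list.
#' @export
optimization_params <- function(iterations = 5L, flat_angle_deg = 8,
                                dense_angle_deg = 60, min_edge_length = 0) {
  if (flat_angle_deg <= 0 || flat_angle_deg >= 180 ||
      dense_angle_deg <= 0 || dense_angle_deg >= 180) {
    stop_param("optimization_params: angles must be in (0, 180)")
  }
  if (iterations < 0) stop_param("optimization_params: iterations must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 flat_angle_deg = flat_angle_deg,
                 dense_angle_deg = dense_angle_deg,
                 min_edge_length = min_edge_length),
            class = "optimization_params")
}

# One batch of edge collapses. Candidates are processed shortest-first;
# each accepted collapse blocks the one-rings of its endpoints so batch
# application is order-independent. A collapse is rejected if it would
# violate the link condition (create a non-manifold edge) or flip a face
# normal by more than 90 degrees.
collapse_batch <- function(mesh, candidates, lens) {
  V <- mesh$vertices
  t <- mesh$triangles
  nv <- nrow(V)
  ed <- edge_incidence(mesh)
  nbr <- vector("list", nv)
  for (i in seq_along(ed$a)) {
    nbr[[ed$a[i]]] <- c(nbr[[ed$a[i]]], ed$b[i])
    nbr[[ed$b[i]]] <- c(nbr[[ed$b[i]]], ed$a[i])
  }
  vfaces <- split(rep.int(seq_len(nrow(t)), 3L),
                  factor(as.vector(t), levels = seq_len(nv)))
  nrm <- tri_normals(mesh)
  ord <- order(lens, candidates$a, candidates$b)
  blocked <- logical(nv)
  col_a <- integer(0); col_b <- integer(0)
  for (i in ord) {
    a <- candidates$a[i]; b <- candidates$b[i]
    if (blocked[a] || blocked[b]) next
    common <- intersect(nbr[[a]], nbr[[b]])
    if (length(common) != 2L) next      # link condition
    mid <- (V[a, ] + V[b, ]) / 2
    faces <- unique(c(vfaces[[a]], vfaces[[b]]))
    ok <- TRUE
    for (f in faces) {
      tf <- t[f, ]
      if (a %in% tf && b %in% tf) next  # face collapses away
      p <- V[tf, , drop = FALSE]
      p[tf == a | tf == b, ] <- rep(mid, each = sum(tf == a | tf == b))
      e1 <- p[2, ] - p[1, ]; e2 <- p[3, ] - p[1, ]
      nn <- c(e1[2] * e2[3] - e1[3] * e2[2],
              e1[3] * e2[1] - e1[1] * e2[3],
              e1[1] * e2[2] - e1[2] * e2[1])
      if (sum(nn * nrm[f, ]) <= 1e-12) { ok <- FALSE; break }
    }
    if (!ok) next
    col_a <- c(col_a, a); col_b <- c(col_b, b)
    blocked[c(a, b, nbr[[a]], nbr[[b]])] <- TRUE
  }
  if (!length(col_a)) return(NULL)
  map <- seq_len(nv)
  map[col_b] <- col_a
  V[col_a, ] <- (V[col_a, , drop = FALSE] + V[col_b, , drop = FALSE]) / 2
  t2 <- matrix(map[t], ncol = 3)
  keep <- t2[, 1] != t2[, 2] & t2[, 2] != t2[, 3] & t2[, 1] != t2[, 3]
  drop_unused_vertices(surface_mesh(V, t2[keep, , drop = FALSE]))
}

# Normal-based smoothing: relax each vertex towards its one-ring centroid,
# but only within the local tangent plane defined by the area-weighted
# one-ring normal. Tangential relaxation regularizes triangle shape
# without the systematic inward drift of full centroid smoothing.
normal_smooth <- function(mesh, beta = 0.5) {
  t <- mesh$triangles
  V <- mesh$vertices
  nv <- nrow(V)
  nrm <- tri_normals(mesh)
  areas <- tri_areas(mesh)
  cent <- tri_centroids(mesh)
  vid <- as.vector(t)
  fid <- rep.int(seq_len(nrow(t)), 3L)
  aw <- areas[fid]
  nsum <- rowsum(nrm[fid, , drop = FALSE] * aw, vid)
  csum <- rowsum(cent[fid, , drop = FALSE] * aw, vid)
  asum <- rowsum(aw, vid)
  rows <- as.integer(rownames(nsum))
  nbar <- normalize_rows(nsum / as.vector(asum))
  cbar <- csum / as.vector(asum)
  full <- cbar - V[rows, , drop = FALSE]
  dn <- rowSums(full * nbar)
  tangential <- full - dn * nbar
  V[rows, ] <- V[rows, , drop = FALSE] + beta * tangential
  surface_mesh(V, t)
}

#' Adaptive mesh optimization
#'
#' Per iteration: (a) flat coarsening collapses edges across nearly
#' coplanar face pairs, (b) dense coarsening collapses edges shorter than
#' `min_edge_length`, and (c) normal-based smoothing regularizes vertex
#' placement. Collapses that would create non-manifold edges, flip a face
#' normal or break closedness are rejected, so triangle count is
#' non-increasing and a closed input stays closed.
#'
#' @param mesh a closed manifold [surface_mesh] (e.g. isosurface output).
#' @param params an [optimization_params].
#' @return The optimized [surface_mesh].
#' @export
optimize_adaptively <- function(mesh, params = optimization_params()) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ed0 <- edge_incidence(mesh)
  if (any(ed0$count == 1L)) {
    stop_param("optimize_adaptively: input mesh has %d boundary edges; a closed mesh is required",
               sum(ed0$count == 1L))
  }
  for (it in seq_len(params$iterations)) {
    ed <- edge_incidence(mesh)
    interior <- which(ed$count == 2L & !is.na(ed$tri2))
    if (!length(interior)) break
    nrm <- tri_normals(mesh)
    dih <- acos(pmax(-1, pmin(1, rowSums(nrm[ed$tri1[interior], , drop = FALSE] *
                                         nrm[ed$tri2[interior], , drop = FALSE])))) * 180 / pi
    lens <- rownorms(mesh$vertices[ed$a[interior], , drop = FALSE] -
                     mesh$vertices[ed$b[interior], , drop = FALSE])
    flat <- dih < params$flat_angle_deg
    dense <- lens < params$min_edge_length & dih < params$dense_angle_deg
    sel <- which(flat | dense)
    if (!length(sel)) break
    cand <- list(a = ed$a[interior][sel], b = ed$b[interior][sel])
    out <- collapse_batch(mesh, cand, lens[sel])
    if (is.null(out)) break
    chk <- edge_incidence(out)
    if (any(chk$count != 2L)) break     # refuse a batch that broke closedness
    mesh <- normal_smooth(out)
  }
  mesh
}
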