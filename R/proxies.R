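# Disposable proxy geometry: possibly self-intersecting meshes whose only
# contract is faithful conservative rasterization into an occupancy grid.

#' Concatenate meshes into one (possibly overlapping) soup
#' @param meshes list of [surface_mesh] objects.
#' @return A single [surface_mesh].
#' @export
merge_meshes <- function(meshes) {
  meshes <- meshes[vapply(meshes, n_triangles, integer(1)) > 0]
  if (!length(meshes)) stop_param("merge_meshes: no non-empty meshes")
  offs <- cumsum(c(0L, vapply(meshes, n_vertices, integer(1))))
  verts <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  tris <- do.call(rbind, lapply(seq_along(meshes), function(i) {
    meshes[[i]]$triangles + offs[i]
  }))
  surface_mesh(verts, tris)
}

# Subdivided icosahedron with vertices on the sphere of given radius.
icosphere_mesh <- function(radius = 1, subdivisions = 0, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_mid <- new.env()
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- edge_mid[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / vnorm(p)
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      edge_mid[[key]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(4 * i - 3):(4 * i), ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  surface_mesh(sweep(v * radius, 2, center, "+"), f)
}

# Orthonormal frame perpendicular to t (any fixed convention).
perp_frame <- function(t) {
  a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- a - sum(a * t) * t
  n1 <- n1 / vnorm(n1)
  n2 <- c(t[2] * n1[3] - t[3] * n1[2],
          t[3] * n1[1] - t[1] * n1[3],
          t[1] * n1[2] - t[2] * n1[1])
  rbind(n1, n2)
}

rotate_to <- function(v, from, to) {
  # Rodrigues rotation taking unit vector `from` onto `to`, applied to v
  axis <- c(from[2] * to[3] - from[3] * to[2],
            from[3] * to[1] - from[1] * to[3],
            from[1] * to[2] - from[2] * to[1])
  s <- vnorm(axis)
  cth <- sum(from * to)
  if (s < 1e-12) {
    if (cth > 0) return(v) else return(-v)
  }
  axis <- axis / s
  v * cth + c(axis[2] * v[3] - axis[3] * v[2],
              axis[3] * v[1] - axis[1] * v[3],
              axis[1] * v[2] - axis[2] * v[1]) * s +
    axis * sum(axis * v) * (1 - cth)
}

#' Sweep a circular cross-section along a path
#'
#' One ring of `n_ring` vertices is placed per path point in the plane
#' normal to the local tangent, with the sample radius; ring frames are
#' propagated by parallel transport so the tube does not twist. Consecutive
#' rings are stitched with `2 * n_ring` triangles; the ends are closed with
#' triangle fans whose apices sit half a radius beyond the end points
#' (rounded caps), keeping terminal skeleton samples strictly inside.
#'
#' @param path dense k x 4 sample matrix (k >= 2).
#' @param n_ring vertices per ring (>= 3, default 16).
#' @return A proxy [surface_mesh].
#' @export
sweep_tube <- function(path, n_ring = 16L) {
  path <- rbind(path)
  k <- nrow(path)
  if (k < 2) stop_param("sweep_tube: need >= 2 path points")
  n_ring <- as.integer(n_ring)
  if (n_ring < 3L) stop_param("sweep_tube: n_ring must be >= 3")
  P <- path[, 1:3, drop = FALSE]
  R <- pmax(path[, 4], 1e-6)
  # tangents: central differences
  Tg <- matrix(0, k, 3)
  Tg[1, ] <- P[2, ] - P[1, ]
  Tg[k, ] <- P[k, ] - P[k - 1, ]
  if (k > 2) Tg[2:(k - 1), ] <- P[3:k, , drop = FALSE] - P[1:(k - 2), , drop = FALSE]
  Tg <- normalize_rows(Tg)
  theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  verts <- matrix(0, k * n_ring + 2L, 3)
  frame <- perp_frame(Tg[1, ])
  for (i in seq_len(k)) {
    if (i > 1) {
      frame[1, ] <- rotate_to(frame[1, ], Tg[i - 1, ], Tg[i, ])
      frame[2, ] <- rotate_to(frame[2, ], Tg[i - 1, ], Tg[i, ])
    }
    ring <- outer(cos(theta), frame[1, ]) + outer(sin(theta), frame[2, ])
    verts[(i - 1) * n_ring + seq_len(n_ring), ] <-
      sweep(ring * R[i], 2, P[i, ], "+")
  }
  apex0 <- k * n_ring + 1L
  apex1 <- k * n_ring + 2L
  verts[apex0, ] <- P[1, ] - Tg[1, ] * R[1] * 0.5
  verts[apex1, ] <- P[k, ] + Tg[k, ] * R[k] * 0.5
  tris <- vector("list", k + 1L)
  jn <- c(seq_len(n_ring)[-1], 1L)    # next ring index, wrapped
  for (i in seq_len(k - 1)) {
    a <- (i - 1) * n_ring + seq_len(n_ring)
    b <- i * n_ring + seq_len(n_ring)
    an <- (i - 1) * n_ring + jn
    bn <- i * n_ring + jn
    tris[[i]] <- rbind(cbind(a, an, b), cbind(b, an, bn))
  }
  a <- seq_len(n_ring); an <- jn
  tris[[k]] <- cbind(an, a, apex0)
  b <- (k - 1) * n_ring + seq_len(n_ring); bn <- (k - 1) * n_ring + jn
  tris[[k + 1L]] <- cbind(b, bn, apex1)
  surface_mesh(verts, do.call(rbind, tris))
}

#' Per-section proxy geometry with packing spheres
#'
#' Every section becomes an independent swept tube; at every branching
#' point where two or more section ends meet, a packing icosphere is added
#' whose radius is the largest terminal-sample radius of the sections
#' meeting there, guaranteeing continuity between neighboring sections.
#' Suited to cyclic graphs (vasculature).
#'
#' @param m a repaired, resampled `morphology`.
#' @param n_ring vertices per tube ring.
#' @param step maximum spacing of the dense path samples; `NULL` uses each
#'   section's minimum radius.
#' @return List with `tubes` (one mesh per section) and `spheres` (one mesh
#'   per branching point).
#' @export
per_section_proxies <- function(m, n_ring = 16L, step = NULL) {
  stopifnot(inherits(m, "morphology"))
  tubes <- lapply(m$sections, function(sec) {
    st <- if (is.null(step)) max(min(sec$samples[, 4]), 1e-3) else step
    sweep_tube(interpolate_path(sec$samples, st), n_ring)
  })
  # collect section end samples at junctions
  ends <- do.call(rbind, lapply(m$sections, function(sec) {
    s <- sec$samples
    rbind(s[1, ], s[nrow(s), ])
  }))
  key <- pos_key(ends[, 1:3, drop = FALSE])
  spheres <- list()
  for (kk in unique(key[duplicated(key)])) {
    at <- which(key == kk)
    r <- max(ends[at, 4])
    spheres[[length(spheres) + 1L]] <-
      icosphere_mesh(r, 2, ends[at[1], 1:3])
  }
  list(tubes = tubes, spheres = spheres)
}

#' Soma reconstruction by projective pulling
#'
#' The soma starts as a subdivision-3 icosphere with the mean soma radius.
#' For every soma-connected neurite, the icosphere vertices inside the
#' spherical cap subtended by the neurite's initial cross-section are
#' pulled in `pull_steps` increments along the centroid-to-initial-segment
#' direction until the cluster centroid reaches the initial segment;
#' afterwards a global uniform scale restores the initial enclosed volume
#' (within 1 percent).
#'
#' @param m a `morphology` with a soma.
#' @param pull_steps number of pulling increments (default 10).
#' @param k soma-connection threshold passed to [neurite_connectivity()].
#' @return A proxy [surface_mesh] for the soma.
#' @export
reconstruct_soma <- function(m, pull_steps = 10L, k = 2.0) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(m$soma)) stop_param("reconstruct_soma: morphology has no soma")
  c0 <- m$soma$centroid
  r0 <- m$soma$radius
  ico <- icosphere_mesh(r0, 3, c0)
  conn <- if (isTRUE(m$soma$has_soma_samples)) {
    suppressWarnings(neurite_connectivity(m, k))$connected
  } else {
    m$soma$root_sections
  }
  if (!length(conn)) {
    warning("reconstruct_soma: no soma-connected neurites; returning plain icosphere")
    return(ico)
  }
  v0 <- enclosed_volume(ico)
  V <- ico$vertices
  for (sid in conn) {
    first <- m$sections[[sid]]$samples[1, ]
    dir <- first[1:3] - c0
    dist <- vnorm(dir)
    if (dist < 1e-9) next
    dir <- dir / dist
    cap <- asin(min(1, first[4] / r0))
    rel <- normalize_rows(sweep(V, 2, c0))
    ang <- acos(pmax(-1, pmin(1, rel %*% dir)))
    cluster <- which(ang <= cap)
    if (!length(cluster)) cluster <- which.min(ang)
    target <- first[1:3]
    cl_centroid <- colMeans(V[cluster, , drop = FALSE])
    delta <- (target - cl_centroid) / pull_steps
    for (s in seq_len(pull_steps)) {
      V[cluster, ] <- sweep(V[cluster, , drop = FALSE], 2, delta, "+")
    }
  }
  out <- surface_mesh(V, ico$triangles)
  v1 <- enclosed_volume(out)
  scale <- (v0 / v1)^(1 / 3)
  out$vertices <- sweep(sweep(out$vertices, 2, c0) * scale, 2, c0, "+")
  out
}

#' Rasterize endfeet patches into an occupancy grid
#'
#' Patch edges longer than the local thickness are midpoint-subdivided
#' (thickness averaged) until compliant; the implicit thickened sheet is
#' then realized as the union of spheres of radius thickness/2 placed at
#' every vertex, at triangle centroids, and swept along every edge at
#' half-voxel spacing, rasterized conservatively into the grid.
#'
#' @param patches list of `endfoot_patch` objects (see [read_endfeet()]).
#' @param grid an allocated [bit_grid]; endfeet voxels are ORed in.
#' @return The updated [bit_grid].
#' @export
endfeet_proxy <- function(patches, grid) {
  stopifnot(inherits(grid, "bit_grid"))
  if (!length(patches)) return(grid)
  h <- grid$spec$voxel_size
  for (p in patches) {
    if (any(p$thickness <= 0)) stop_format("endfeet_proxy: non-positive thickness")
    v <- p$vertices; th <- p$thickness; f <- p$triangles
    # midpoint-subdivide triangles with an edge longer than local thickness
    for (gen in 1:12) {
      e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
      len <- rownorms(v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])
      lim <- (th[e[, 1]] + th[e[, 2]]) / 2
      if (!any(len > lim)) break
      bad_tri <- unique(((which(len > lim) - 1L) %% nrow(f)) + 1L)
      edge_mid <- new.env()
      midpoint <- function(a, b) {
        keyv <- paste(min(a, b), max(a, b))
        hit <- edge_mid[[keyv]]
        if (!is.null(hit)) return(hit)
        v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
        th <<- c(th, (th[a] + th[b]) / 2)
        edge_mid[[keyv]] <- nrow(v)
        nrow(v)
      }
      newf <- list()
      for (i in seq_len(nrow(f))) {
        if (!(i %in% bad_tri)) { newf[[length(newf) + 1L]] <- f[i, , drop = FALSE]; next }
        a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
        ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
        newf[[length(newf) + 1L]] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                           c(c, ca, bc), c(ab, bc, ca))
      }
      f <- do.call(rbind, newf)
    }
    centers <- v
    radii <- th / 2
    # triangle centroids plug interior gaps
    if (nrow(f)) {
      centers <- rbind(centers, (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3)
      radii <- c(radii, (th[f[, 1]] + th[f[, 2]] + th[f[, 3]]) / 6)
    }
    # sweep spheres along edges at <= h/2 spacing
    e <- unique(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]))
    for (i in seq_len(nrow(e))) {
      a <- e[i, 1]; b <- e[i, 2]
      len <- vnorm(v[a, ] - v[b, ])
      nsub <- ceiling(len / (h / 2))
      if (nsub > 1) {
        u <- seq_len(nsub - 1) / nsub
        centers <- rbind(centers, outer(1 - u, v[a, ]) + outer(u, v[b, ]))
        radii <- c(radii, ((1 - u) * th[a] + u * th[b]) / 2)
      }
    }
    bits <- cpp_rasterize_spheres(centers, radii, grid$spec$origin, h, grid$spec$dims)
    grid$bits <- grid$bits | array(bits, dim = grid$spec$dims)
  }
  grid
}
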