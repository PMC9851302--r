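# SWC morphology skeletons. Neurons are rooted trees with a soma described
# by type-1 samples; vascular networks are general graphs in which loops are
# closed by coincident sample positions (the 7-column parent pointer cannot
# express a back edge, so vectorized vascular datasets repeat the closing
# sample's coordinates).

#' Read an SWC morphology skeleton
#'
#' @param path SWC file: whitespace-separated 7-column records
#'   (id, type, x, y, z, radius, parent), `#` comments skipped. Sample ids
#'   must be unique and parents must be defined before use.
#' @param kind `"neuron"` builds a rooted acyclic tree with a soma (type-1
#'   samples); `"vasculature"` builds a general graph in which coincident
#'   sample positions are merged, so cycles and multiple components are
#'   permitted.
#' @param diameter set `TRUE` for datasets that store diameters in the
#'   radius column; values are halved on load.
#' @return A `morphology` object: a linear list of sections (each a matrix
#'   of samples x, y, z, radius with parent/child references), plus a soma
#'   description for neurons.
#' @export
read_swc <- function(path, kind = c("neuron", "vasculature"), diameter = FALSE) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_format("%s: no SWC records", path)
  toks <- strsplit(lines, "\\s+")
  bad <- which(lengths(toks) != 7L)
  if (length(bad)) {
    stop_format("%s: record %d has %d fields, expected 7 ('%s')",
                path, bad[1], length(toks[[bad[1]]]), lines[bad[1]])
  }
  tab <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 7, byrow = TRUE)
  if (anyNA(tab)) {
    r <- which(rowSums(is.na(tab)) > 0)[1]
    stop_format("%s: non-numeric field in record '%s'", path, lines[r])
  }
  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2])
  xyz <- tab[, 3:5, drop = FALSE]
  radius <- tab[, 6]
  parent <- as.integer(tab[, 7])
  if (anyDuplicated(id)) {
    d <- id[duplicated(id)][1]
    stop_format("%s: duplicate sample id %d", path, d)
  }
  if (any(radius < 0)) {
    stop_format("%s: negative radius in record '%s'", path, lines[which(radius < 0)[1]])
  }
  if (diameter) radius <- radius / 2
  seen <- logical(max(id))
  for (i in seq_along(id)) {
    if (parent[i] != -1L && (parent[i] < 1L || parent[i] > length(seen) || !seen[parent[i]])) {
      stop_format("%s: record '%s' references unknown or forward parent %d",
                  path, lines[i], parent[i])
    }
    seen[id[i]] <- TRUE
  }
  row_of <- integer(max(id)); row_of[id] <- seq_along(id)
  parent_row <- ifelse(parent == -1L, NA_integer_, row_of[pmax(parent, 1L)])
  if (kind == "neuron") {
    swc_build_neuron(xyz, radius, type, parent_row, path)
  } else {
    swc_build_vasculature(xyz, radius, parent_row, path)
  }
}

new_morphology <- function(kind, sections, soma = NULL, endfeet = list()) {
  structure(list(kind = kind, sections = sections, soma = soma,
                 endfeet = endfeet), class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  ns <- vapply(x$sections, function(s) nrow(s$samples), integer(1))
  cat(sprintf("<morphology kind=%s, %d sections, %d samples%s%s>\n",
              x$kind, length(x$sections), sum(ns),
              if (!is.null(x$soma)) sprintf(", soma r=%.3g", x$soma$radius) else "",
              if (length(x$endfeet)) sprintf(", %d endfeet", length(x$endfeet)) else ""))
  invisible(x)
}

make_section <- function(id, samples, parent = NA_integer_, children = integer(0),
                         cyclic = FALSE) {
  colnames(samples) <- c("x", "y", "z", "r")
  list(id = id, samples = samples, parent = parent, children = children,
       cyclic = cyclic)
}

pos_key <- function(xyz, tol = 1e-9) {
  apply(round(rbind(xyz) / tol), 1, paste, collapse = "_")
}

swc_build_neuron <- function(xyz, radius, type, parent_row, path) {
  n <- nrow(xyz)
  is_soma <- type == 1L
  # coincident non-soma samples would close a loop when merged: reject
  keys <- pos_key(xyz[, , drop = FALSE])
  if (any(is_soma)) {
    nk <- keys[!is_soma]
  } else nk <- keys
  if (anyDuplicated(nk)) {
    stop_format("%s: cycle: coincident neurite samples close a loop (position %s)",
                path, nk[duplicated(nk)][1])
  }
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent_row[i]
    if (!is.na(p) && !is_soma[i]) children[[p]] <- c(children[[p]], i)
  }
  roots <- which(!is_soma & (is.na(parent_row) | is_soma[pmax(parent_row, 1L)]))
  n_children <- lengths(children)
  sections <- list()
  walk <- function(start) {
    # one section from `start` through degree-1 chain
    chain <- start
    cur <- start
    while (n_children[cur] == 1L) {
      cur <- children[[cur]][1]
      chain <- c(chain, cur)
    }
    chain
  }
  pending <- list()
  for (r in roots) {
    pending[[length(pending) + 1L]] <-
      list(start = r, parent = NA_integer_, anchor = NA_integer_)
  }
  while (length(pending)) {
    job <- pending[[1]]; pending <- pending[-1]
    chain <- walk(job$start)
    stopv <- chain[length(chain)]
    # prepend the branch-point sample so geometry is continuous
    if (!is.na(job$anchor)) chain <- c(job$anchor, chain)
    if (length(chain) < 2) {
      # a root that branches immediately: anchor its children directly
      for (c in children[[stopv]]) {
        pending[[length(pending) + 1L]] <-
          list(start = c, parent = NA_integer_, anchor = stopv)
      }
      next
    }
    samples <- cbind(xyz[chain, , drop = FALSE], radius[chain])
    sid <- length(sections) + 1L
    sections[[sid]] <- make_section(sid, samples, parent = job$parent)
    if (!is.na(job$parent)) {
      sections[[job$parent]]$children <- c(sections[[job$parent]]$children, sid)
    }
    for (c in children[[stopv]]) {
      pending[[length(pending) + 1L]] <-
        list(start = c, parent = sid, anchor = stopv)
    }
  }
  soma <- NULL
  if (any(is_soma)) {
    centroid <- colMeans(xyz[is_soma, , drop = FALSE])
  } else {
    centroid <- if (length(roots)) colMeans(xyz[roots, , drop = FALSE]) else colMeans(xyz)
  }
  root_secs <- which(vapply(sections, function(s) is.na(s$parent), logical(1)))
  first_pts <- t(vapply(sections[root_secs], function(s) s$samples[1, 1:3], numeric(3)))
  if (length(root_secs)) {
    soma_radius <- mean(sqrt(rowSums(sweep(first_pts, 2, centroid)^2)))
  } else {
    soma_radius <- if (any(is_soma)) mean(radius[is_soma]) else 1
  }
  if (!is.finite(soma_radius) || soma_radius <= 0) {
    soma_radius <- if (any(is_soma)) max(mean(radius[is_soma]), 1e-6) else 1
  }
  soma <- list(centroid = as.numeric(centroid), radius = soma_radius,
               root_sections = root_secs, has_soma_samples = any(is_soma))
  new_morphology("neuron", sections, soma)
}

swc_build_vasculature <- function(xyz, radius, parent_row, path) {
  n <- nrow(xyz)
  key <- pos_key(xyz)
  node_of <- match(key, unique(key))       # merged node per sample
  nn <- max(node_of)
  npos <- xyz[!duplicated(key), , drop = FALSE]
  nrad <- radius[!duplicated(key)]
  e_from <- node_of[which(!is.na(parent_row))]
  e_to <- node_of[parent_row[!is.na(parent_row)]]
  keep <- e_from != e_to
  e_from <- e_from[keep]; e_to <- e_to[keep]
  ek <- paste(pmin(e_from, e_to), pmax(e_from, e_to))
  dupe <- duplicated(ek)
  e_from <- e_from[!dupe]; e_to <- e_to[!dupe]
  adj <- vector("list", nn)
  for (i in seq_along(e_from)) {
    adj[[e_from[i]]] <- c(adj[[e_from[i]]], e_to[i])
    adj[[e_to[i]]] <- c(adj[[e_to[i]]], e_from[i])
  }
  deg <- lengths(adj)
  used <- new.env()
  edge_id <- function(a, b) paste(min(a, b), max(a, b))
  sections <- list()
  emit <- function(nodes, cyclic = FALSE) {
    samples <- cbind(npos[nodes, , drop = FALSE], nrad[nodes])
    sid <- length(sections) + 1L
    sections[[sid]] <<- make_section(sid, samples, cyclic = cyclic)
  }
  # chains from every junction/terminal node
  for (v in which(deg != 2L)) {
    for (w in adj[[v]]) {
      if (!is.null(used[[edge_id(v, w)]])) next
      chain <- c(v, w)
      used[[edge_id(v, w)]] <- TRUE
      prev <- v; cur <- w
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        if (!is.null(used[[edge_id(cur, nxt)]])) break
        used[[edge_id(cur, nxt)]] <- TRUE
        chain <- c(chain, nxt)
        prev <- cur; cur <- nxt
      }
      emit(chain)
    }
  }
  # remaining pure cycles (all nodes degree 2)
  for (v in seq_len(nn)) {
    if (deg[v] != 2L) next
    w <- adj[[v]][1]
    if (!is.null(used[[edge_id(v, w)]])) {
      w <- adj[[v]][2]
      if (!is.null(used[[edge_id(v, w)]])) next
    }
    chain <- c(v, w)
    used[[edge_id(v, w)]] <- TRUE
    prev <- v; cur <- w
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      if (!length(nxt)) break
      nxt <- nxt[1]
      if (!is.null(used[[edge_id(cur, nxt)]])) break
      used[[edge_id(cur, nxt)]] <- TRUE
      chain <- c(chain, nxt)
      prev <- cur; cur <- nxt
      if (cur == v) break
    }
    emit(chain, cyclic = chain[1] == chain[length(chain)])
  }
  new_morphology("vasculature", sections)
}

#' Read endfeet patches from a JSON sidecar
#'
#' Astrocytic endfeet are triangular surface patches with a per-vertex
#' thickness. The sidecar is a JSON array of patches, each an object with
#' `vertices` (n x 3), `thickness` (length n, \eqn{\mu m}, > 0) and
#' `triangles` (m x 3, 1-based).
#'
#' @param path JSON file.
#' @return List of `endfoot_patch` objects.
#' @export
read_endfeet <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(p) {
    v <- matrix(as.numeric(unlist(p$vertices)), ncol = 3, byrow = !is.matrix(p$vertices))
    if (is.matrix(p$vertices)) v <- p$vertices
    th <- as.numeric(p$thickness)
    tr <- if (is.matrix(p$triangles)) p$triangles else
      matrix(as.integer(unlist(p$triangles)), ncol = 3, byrow = TRUE)
    storage.mode(tr) <- "integer"
    if (any(th <= 0)) stop_format("%s: endfoot thickness must be > 0", path)
    if (length(th) != nrow(v)) stop_format("%s: thickness length != vertex count", path)
    if (nrow(tr) && (any(tr < 1L) || any(tr > nrow(v)))) {
      stop_format("%s: endfoot triangle index out of range", path)
    }
    structure(list(vertices = v, thickness = th, triangles = tr),
              class = "endfoot_patch")
  })
}

#' Read a stack of binary mask slices into an occupancy grid
#'
#' @param paths ordered character vector of image files (one z-slice each),
#'   or a single multi-page TIFF. Pixels with value > 0 are set.
#' @param voxel_size voxel size to stamp on the grid (masks carry no units).
#' @param origin world origin of the grid.
#' @return A [bit_grid] of dims (width, height, n_slices).
#' @export
read_mask_stack <- function(paths, voxel_size = 1, origin = c(0, 0, 0)) {
  imgs <- list()
  for (p in paths) {
    im <- tiff::readTIFF(p, all = TRUE)
    imgs <- c(imgs, im)
  }
  dims <- lapply(imgs, dim)
  wh <- vapply(dims, function(d) d[1:2], numeric(2))
  if (any(wh[1, ] != wh[1, 1]) || any(wh[2, ] != wh[2, 1])) {
    stop_format("read_mask_stack: inconsistent slice shapes (%s vs %s)",
                paste(wh[, 1], collapse = "x"),
                paste(wh[, which(wh[1, ] != wh[1, 1] | wh[2, ] != wh[2, 1])[1]], collapse = "x"))
  }
  nz <- length(imgs)
  # readTIFF returns row x col (y, x); transpose to x fastest
  nx <- wh[2, 1]; ny <- wh[1, 1]
  bits <- array(FALSE, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    sl <- imgs[[k]]
    if (length(dim(sl)) == 3) sl <- sl[, , 1]
    bits[, , k] <- t(sl > 0)
  }
  bit_grid(grid_spec(origin, voxel_size, c(nx, ny, nz)), bits)
}
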