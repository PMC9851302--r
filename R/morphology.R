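# Skeleton conditioning and path construction. Sections are matrices of
# samples (x, y, z, radius); segments are adjacent sample pairs.

#' Repair a morphology skeleton
#'
#' Zero/near-zero radii are replaced by linear interpolation from the
#' nearest valid neighbors along the section; duplicate (zero-length)
#' segments are merged; radius sequences of sections with at least five
#' samples are median-filtered (window 3) to remove high-frequency
#' cross-sectional noise. Connectivity is preserved.
#'
#' @param m a `morphology`.
#' @param min_radius radii at or below this are considered invalid
#'   (default 1e-6 \eqn{\mu m}).
#' @return The repaired `morphology`.
#' @export
repair_skeleton <- function(m, min_radius = 1e-6) {
  stopifnot(inherits(m, "morphology"))
  m$sections <- lapply(m$sections, function(sec) {
    s <- sec$samples
    # merge zero-length segments
    if (nrow(s) > 1) {
      d <- rownorms(diff(s[, 1:3, drop = FALSE]))
      keep <- c(TRUE, d > 1e-9)
      s <- s[keep, , drop = FALSE]
    }
    if (nrow(s) < 2) {
      stop_param("repair_skeleton: section %d left with %d < 2 samples",
                 sec$id, nrow(s))
    }
    # interpolate invalid radii from nearest valid neighbors
    r <- s[, 4]
    bad <- r <= min_radius
    if (any(bad)) {
      if (all(bad)) {
        stop_param("repair_skeleton: section %d has no valid radius", sec$id)
      }
      r <- stats::approx(which(!bad), r[!bad], xout = seq_along(r), rule = 2)$y
    }
    # window-3 median filter on long sections
    if (length(r) >= 5) {
      rf <- r
      for (i in 2:(length(r) - 1)) rf[i] <- median(r[(i - 1):(i + 1)])
      r <- rf
    }
    s[, 4] <- r
    sec$samples <- s
    sec
  })
  m
}

#' Adaptive section resampling
#'
#' Greedy walk that keeps a sample only when its distance from the last
#' kept sample exceeds the local radius (the adaptive step); the first and
#' last samples are always kept and never moved.
#'
#' @param section a section (as stored in a `morphology`).
#' @return The resampled section; the attribute `n_removed` logs the count.
#' @export
resample_adaptive <- function(section) {
  s <- section$samples
  n <- nrow(s)
  if (n <= 2) {
    attr(section, "n_removed") <- 0L
    return(section)
  }
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:(n - 1)) {
    if (vnorm(s[i, 1:3] - s[last, 1:3]) > s[i, 4]) {
      keep[i] <- TRUE
      last <- i
    }
  }
  keep[n] <- TRUE
  section$samples <- s[keep, , drop = FALSE]
  attr(section, "n_removed") <- sum(!keep)
  section
}

#' Resample every section of a morphology
#' @param m a `morphology`.
#' @return The morphology with each section passed through
#'   [resample_adaptive()]; attribute `n_removed` totals the removals.
#' @export
resample_morphology <- function(m) {
  res <- lapply(m$sections, resample_adaptive)
  removed <- sum(vapply(res, function(s) attr(s, "n_removed"), integer(1)))
  m$sections <- res
  attr(m, "n_removed") <- removed
  m
}

# Centripetal Catmull-Rom knot parameters: t[i+1] = t[i] + |P[i+1]-P[i]|^0.5
cr_knots <- function(P, alpha = 0.5) {
  d <- rownorms(diff(P))
  d[d < 1e-12] <- 1e-12
  c(0, cumsum(d^alpha))
}

#' Dense path interpolation with cubic Hermite splines
#'
#' Positions follow cubic Hermite segments whose per-knot tangents come from
#' the centripetal Catmull-Rom formulation (alpha = 0.5) using the previous
#' and next knots; endpoint tangents are one-sided differences. Radii are
#' interpolated linearly in the knot parameter. Output spacing never
#' exceeds `step`.
#'
#' @param samples k x 4 matrix (x, y, z, radius), k >= 2.
#' @param step maximum spacing between consecutive output samples
#'   (\eqn{\mu m}).
#' @return A dense matrix of samples including all input knots.
#' @export
interpolate_path <- function(samples, step) {
  samples <- rbind(samples)
  k <- nrow(samples)
  if (k < 2) stop_param("interpolate_path: need >= 2 samples")
  P <- samples[, 1:3, drop = FALSE]
  R <- samples[, 4]
  t <- cr_knots(P)
  # Catmull-Rom tangent (derivative of the centripetal spline at knot i):
  # m_i = (P_i-P_{i-1})/(t_i-t_{i-1}) - (P_{i+1}-P_{i-1})/(t_{i+1}-t_{i-1})
  #       + (P_{i+1}-P_i)/(t_{i+1}-t_i)
  M <- matrix(0, k, 3)
  for (i in seq_len(k)) {
    if (i == 1) {
      M[i, ] <- (P[2, ] - P[1, ]) / (t[2] - t[1])
    } else if (i == k) {
      M[i, ] <- (P[k, ] - P[k - 1, ]) / (t[k] - t[k - 1])
    } else {
      M[i, ] <- (P[i, ] - P[i - 1, ]) / (t[i] - t[i - 1]) -
        (P[i + 1, ] - P[i - 1, ]) / (t[i + 1] - t[i - 1]) +
        (P[i + 1, ] - P[i, ]) / (t[i + 1] - t[i])
    }
  }
  out <- list(samples[1, , drop = FALSE])
  for (i in seq_len(k - 1)) {
    dt <- t[i + 1] - t[i]
    seg_len <- vnorm(P[i + 1, ] - P[i, ])
    nsub <- max(1L, ceiling(seg_len / step))
    u <- seq_len(nsub) / nsub
    h00 <- 2 * u^3 - 3 * u^2 + 1
    h10 <- u^3 - 2 * u^2 + u
    h01 <- -2 * u^3 + 3 * u^2
    h11 <- u^3 - u^2
    pos <- outer(h00, P[i, ]) + outer(h10 * dt, M[i, ]) +
      outer(h01, P[i + 1, ]) + outer(h11 * dt, M[i + 1, ])
    rad <- R[i] + u * (R[i + 1] - R[i])
    out[[length(out) + 1L]] <- cbind(pos, rad)
  }
  dense <- do.call(rbind, out)
  colnames(dense) <- c("x", "y", "z", "r")
  dense
}

#' Enumerate root-to-terminal sample paths
#'
#' Depth-first enumeration of every route from the soma to a terminal
#' section; every parent/child section adjacency appears in at least one
#' path and every root-to-leaf route exactly once. Paths start at the soma
#' centroid so the swept proxies leave no gap at the soma.
#'
#' @param m an acyclic `morphology` (neuron or astrocyte processes).
#' @return List of k x 4 sample matrices.
#' @export
build_paths <- function(m) {
  stopifnot(inherits(m, "morphology"))
  if (any(vapply(m$sections, function(s) isTRUE(s$cyclic), logical(1)))) {
    stop_param("build_paths: morphology contains a cycle; use per-section proxies")
  }
  roots <- which(vapply(m$sections, function(s) is.na(s$parent), logical(1)))
  soma_pt <- if (!is.null(m$soma)) m$soma$centroid else NULL
  paths <- list()
  visiting <- integer(0)
  descend <- function(sid, prefix) {
    if (sid %in% visiting) {
      stop_param("build_paths: section cycle detected at section %d", sid)
    }
    visiting <<- c(visiting, sid)
    sec <- m$sections[[sid]]
    s <- sec$samples
    if (nrow(prefix) > 0) s <- s[-1, , drop = FALSE]   # shared junction sample
    acc <- rbind(prefix, s)
    if (!length(sec$children)) {
      paths[[length(paths) + 1L]] <<- acc
    } else {
      for (c in sec$children) descend(c, acc)
    }
    visiting <<- setdiff(visiting, sid)
  }
  for (r in roots) {
    first <- m$sections[[r]]$samples[1, , drop = FALSE]
    prefix <- if (!is.null(soma_pt)) {
      rbind(c(soma_pt, first[4]))
    } else {
      matrix(numeric(0), 0, 4)
    }
    descend(r, prefix)
  }
  paths
}

#' Classify root sections as soma-connected or detached
#'
#' A root section counts as connected when its first sample lies within
#' `k` times the mean soma radius of the soma centroid; detached roots are
#' reported and later bridged to the centroid by a straight proxy segment.
#'
#' @param m a `morphology` with a soma.
#' @param k distance threshold in units of the mean soma radius
#'   (default 2).
#' @return List with integer vectors `connected` and `detached` (section
#'   ids).
#' @export
neurite_connectivity <- function(m, k = 2.0) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(m$soma)) stop_param("neurite_connectivity: morphology has no soma")
  if (!isTRUE(m$soma$has_soma_samples)) {
    warning("neurite_connectivity: no soma samples; all roots bridged to the mean-position centroid")
    return(list(connected = integer(0), detached = m$soma$root_sections))
  }
  roots <- m$soma$root_sections
  d <- vapply(roots, function(sid) {
    vnorm(m$sections[[sid]]$samples[1, 1:3] - m$soma$centroid)
  }, numeric(1))
  list(connected = roots[d <= k * m$soma$radius],
       detached = roots[d > k * m$soma$radius])
}
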