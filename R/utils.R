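# Internal helpers shared across modules.

vnorm <- function(x) sqrt(sum(x^2))

rownorms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) {
  n <- rownorms(m)
  n[n < 1e-300] <- 1
  m / n
}

#' Axis-aligned bounding box
#'
#' A world-space box represented as a list with `min` and `max` corners.
#'
#' @param min,max numeric length-3 corners (\eqn{\mu m}).
#' @return An object of class `aabb3`.
#' @export
aabb3 <- function(min, max) {
  min <- as.numeric(min); max <- as.numeric(max)
  stopifnot(length(min) == 3, length(max) == 3)
  if (any(max < min)) {
    stop("aabb3: box is inverted (max < min on some axis)")
  }
  # zero extent is legal: flat geometry still voxelizes into a padded grid
  structure(list(min = min, max = max), class = "aabb3")
}

#' @export
print.aabb3 <- function(x, ...) {
  cat(sprintf("<aabb3 [%g, %g, %g] - [%g, %g, %g]>\n",
              x$min[1], x$min[2], x$min[3], x$max[1], x$max[2], x$max[3]))
  invisible(x)
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

stop_format <- function(...) {
  cond <- simpleError(sprintf(...))
  class(cond) <- c("voxmesh_format_error", class(cond))
  stop(cond)
}
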