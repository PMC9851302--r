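# Volume readers/writers: 1-bit BIT/HDR, RAW/HDR (uint8/16/32) and NRRD.
# The HDR companion is a plain-text header carrying dims, data precision,
# voxel size and origin; payload axis order is x fastest, then y, then z
# (R array order). BIT payloads are packed LSB-first, ceil(N/8) bytes.

hdr_type_size <- c(uint8 = 1L, uint16 = 2L, uint32 = 4L)

#' Write a volume grid to disk
#'
#' @param grid a [bit_grid] or [annotated_grid].
#' @param path output stem or file name. For `bit` and `raw8` a payload file
#'   (`.bit` / `.raw`) plus a `.hdr` text header are written next to each
#'   other; for `nrrd` a single `.nrrd` file is written.
#' @param format one of `"bit"`, `"raw8"`, `"nrrd"`.
#' @return The payload path, invisibly.
#' @export
write_volume <- function(grid, path, format = c("bit", "raw8", "nrrd")) {
  format <- match.arg(format)
  stopifnot(inherits(grid, "bit_grid") || inherits(grid, "annotated_grid"))
  spec <- grid$spec
  vals <- if (inherits(grid, "bit_grid")) as.integer(grid$bits) else as.integer(grid$labels)
  stem <- sub("\\.(bit|raw|hdr|nrrd)$", "", path)
  if (format == "nrrd") {
    if (any(vals > 255L)) stop_param("write_volume: labels exceed uint8 range for nrrd")
    con <- file(paste0(stem, ".nrrd"), "wb")
    on.exit(close(con))
    hdr <- c("NRRD0004",
             "type: uint8",
             "dimension: 3",
             sprintf("sizes: %d %d %d", spec$dims[1], spec$dims[2], spec$dims[3]),
             "encoding: raw",
             "endian: little",
             sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                     spec$voxel_size, spec$voxel_size, spec$voxel_size),
             sprintf("space origin: (%.17g,%.17g,%.17g)",
                     spec$origin[1], spec$origin[2], spec$origin[3]),
             "")
    writeLines(hdr, con, sep = "\n")
    writeBin(as.raw(vals), con)
    return(invisible(paste0(stem, ".nrrd")))
  }
  type <- if (format == "bit") "bit" else "uint8"
  hdr <- c(sprintf("dims %d %d %d", spec$dims[1], spec$dims[2], spec$dims[3]),
           sprintf("type %s", type),
           sprintf("voxel_size %.17g", spec$voxel_size),
           sprintf("origin %.17g %.17g %.17g",
                   spec$origin[1], spec$origin[2], spec$origin[3]),
           "order x-fastest")
  writeLines(hdr, paste0(stem, ".hdr"))
  if (format == "bit") {
    n <- length(vals)
    pad <- (8L - n %% 8L) %% 8L
    bits <- c(as.logical(vals), rep(FALSE, pad))
    payload <- packBits(bits, type = "raw")   # LSB-first
    writeBin(payload, paste0(stem, ".bit"))
    invisible(paste0(stem, ".bit"))
  } else {
    if (any(vals > 255L)) stop_param("write_volume: labels exceed uint8 range for raw8")
    writeBin(as.raw(vals), paste0(stem, ".raw"))
    invisible(paste0(stem, ".raw"))
  }
}

parse_hdr <- function(hdr_path) {
  lines <- readLines(hdr_path, warn = FALSE)
  kv <- strsplit(trimws(lines[nzchar(trimws(lines))]), "\\s+")
  fields <- list()
  for (tok in kv) fields[[tok[1]]] <- tok[-1]
  for (need in c("dims", "type", "voxel_size", "origin")) {
    if (is.null(fields[[need]])) {
      stop_format("malformed HDR header %s: missing field '%s'", hdr_path, need)
    }
  }
  dims <- suppressWarnings(as.integer(fields$dims))
  if (length(dims) != 3 || any(is.na(dims))) {
    stop_format("malformed HDR header %s: field 'dims' is not 3 integers", hdr_path)
  }
  type <- fields$type[1]
  if (!type %in% c("bit", names(hdr_type_size))) {
    stop_format("malformed HDR header %s: unsupported field 'type' = %s", hdr_path, type)
  }
  list(dims = dims, type = type,
       voxel_size = as.numeric(fields$voxel_size[1]),
       origin = as.numeric(fields$origin))
}

#' Read a volume grid from disk
#'
#' Accepts a `.hdr` header (or its `.bit`/`.raw` payload path) or a `.nrrd`
#' file. Round trips of [write_volume()] reproduce the occupancy and the grid
#' spec exactly.
#'
#' @param path file written by [write_volume()].
#' @return A [bit_grid] (1-bit payloads) or [annotated_grid].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nrrd$", path)) return(read_nrrd(path))
  stem <- sub("\\.(bit|raw|hdr)$", "", path)
  hdr <- parse_hdr(paste0(stem, ".hdr"))
  spec <- grid_spec(hdr$origin, hdr$voxel_size, hdr$dims)
  n <- prod(hdr$dims)
  if (hdr$type == "bit") {
    payload_path <- paste0(stem, ".bit")
    expect <- ceiling(n / 8)
    sz <- file.info(payload_path)$size
    if (is.na(sz) || sz != expect) {
      stop_format("BIT payload %s: size %s does not match header dims (expected %d bytes)",
                  payload_path, sz, expect)
    }
    payload <- readBin(payload_path, "raw", n = expect)
    bits <- as.logical(rawToBits(payload))[seq_len(n)]
    bit_grid(spec, bits)
  } else {
    payload_path <- paste0(stem, ".raw")
    size <- hdr_type_size[[hdr$type]]
    sz <- file.info(payload_path)$size
    if (is.na(sz) || sz != n * size) {
      stop_format("RAW payload %s: size %s does not match header dims/type (expected %d bytes)",
                  payload_path, sz, n * size)
    }
    vals <- if (size == 1L) {
      as.integer(readBin(payload_path, "raw", n = n))
    } else {
      readBin(payload_path, "integer", n = n, size = size,
              signed = size > 2L, endian = "little")
    }
    annotated_grid(spec, vals)
  }
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop_format("NRRD %s: bad magic line '%s'", path, magic)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop_format("NRRD %s: header not terminated by blank line", path)
    if (!nzchar(line)) break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3) fields[[m[2]]] <- m[3]
  }
  if (is.null(fields$sizes)) stop_format("NRRD %s: missing field 'sizes'", path)
  dims <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  if (length(dims) != 3 || any(is.na(dims))) {
    stop_format("NRRD %s: field 'sizes' is not 3 integers", path)
  }
  if (!identical(fields$encoding, "raw")) {
    stop_format("NRRD %s: unsupported field 'encoding' = %s", path, fields$encoding)
  }
  if (!identical(fields$type, "uint8") && !identical(fields$type, "uchar")) {
    stop_format("NRRD %s: unsupported field 'type' = %s", path, fields$type)
  }
  h <- 1
  if (!is.null(fields[["space directions"]])) {
    nums <- as.numeric(regmatches(fields[["space directions"]],
                                  gregexpr("-?[0-9.eE+-]+", fields[["space directions"]]))[[1]])
    if (length(nums) == 9) h <- nums[1]
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    nums <- as.numeric(regmatches(fields[["space origin"]],
                                  gregexpr("-?[0-9.eE+-]+", fields[["space origin"]]))[[1]])
    if (length(nums) == 3) origin <- nums
  }
  n <- prod(dims)
  payload <- readBin(con, "raw", n = n + 1L)
  if (length(payload) != n) {
    stop_format("NRRD %s: payload size %d does not match field 'sizes' (%d voxels)",
                path, length(payload), n)
  }
  annotated_grid(grid_spec(origin, h, dims), as.integer(payload))
}
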