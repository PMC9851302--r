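# Mesh interchange: OBJ, PLY (ascii + binary little-endian), OFF and STL
# (ascii + binary). Polygons with more than three vertices are fan-split on
# load. STL carries no indexing, so its reader welds coincident corners.

mesh_format_of <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("obj", "ply", "off", "stl")) {
    stop_format("read_mesh: unknown mesh extension '.%s' in %s", ext, path)
  }
  ext
}

#' Read a surface mesh
#'
#' @param path file in OBJ, PLY (ascii or binary little-endian), OFF or STL
#'   (ascii or binary) format; the format is inferred from the extension
#'   unless given.
#' @param format override the extension-based format choice.
#' @return A [surface_mesh]. n-gon faces are fan-triangulated; STL corners
#'   are welded.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- mesh_format_of(path)
  switch(format,
         obj = read_obj(path),
         off = read_off(path),
         ply = read_ply(path),
         stl = read_stl(path),
         stop_format("read_mesh: unsupported format '%s'", format))
}

#' Write a surface mesh
#'
#' @param mesh a [surface_mesh].
#' @param path output path; format inferred from the extension unless given.
#' @param format one of `"obj"`, `"ply"`, `"off"`, `"stl"`.
#' @param binary write binary PLY/STL (default) instead of ascii; ignored
#'   for OBJ and OFF.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(format)) format <- mesh_format_of(path)
  switch(format,
         obj = write_obj(mesh, path),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path, binary),
         stl = write_stl(mesh, path, binary),
         stop_format("write_mesh: unsupported format '%s'", format))
  invisible(path)
}

num_or_die <- function(tok, path, lineno, what) {
  x <- suppressWarnings(as.numeric(tok))
  if (any(is.na(x))) {
    stop_format("%s line %d: non-numeric %s field '%s'", path, lineno, what,
                paste(tok[is.na(x)], collapse = " "))
  }
  x
}

# ------------------------------------------------------------------- OBJ
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grepl("^v\\s", lines)
  flines <- grepl("^f\\s", lines)
  verts <- matrix(numeric(0), 0, 3)
  if (any(vlines)) {
    toks <- strsplit(trimws(lines[vlines]), "\\s+")
    verts <- t(vapply(seq_along(toks), function(i) {
      num_or_die(toks[[i]][2:4], path, which(vlines)[i], "vertex")
    }, numeric(3)))
  }
  nv <- nrow(verts)
  polys <- list()
  if (any(flines)) {
    toks <- strsplit(trimws(lines[flines]), "\\s+")
    polys <- lapply(seq_along(toks), function(i) {
      # keep the position index before any '/'; texture/normal slots ignored
      raw <- sub("/.*$", "", toks[[i]][-1])
      idx <- as.integer(num_or_die(raw, path, which(flines)[i], "face index"))
      idx[idx < 0] <- nv + 1L + idx[idx < 0]   # negative = relative indexing
      idx
    })
  }
  surface_mesh(verts, triangulate_ngons(polys))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (n_triangles(mesh)) {
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  }
}

# ------------------------------------------------------------------- OFF
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines) || trimws(lines[1]) != "OFF") {
    stop_format("%s line 1: missing OFF magic", path)
  }
  counts <- as.integer(num_or_die(strsplit(trimws(lines[2]), "\\s+")[[1]], path, 2, "count"))
  if (length(counts) < 2) stop_format("%s line 2: malformed count line", path)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) {
    stop_format("%s: header announces %d vertices and %d faces but file is short",
                path, nv, nf)
  }
  verts <- if (nv) t(vapply(seq_len(nv), function(i) {
    num_or_die(strsplit(trimws(lines[2 + i]), "\\s+")[[1]][1:3], path, 2 + i, "vertex")
  }, numeric(3))) else matrix(numeric(0), 0, 3)
  polys <- lapply(seq_len(nf), function(i) {
    tok <- as.integer(num_or_die(strsplit(trimws(lines[2 + nv + i]), "\\s+")[[1]],
                                 path, 2 + nv + i, "face"))
    k <- tok[1]
    if (length(tok) < k + 1) stop_format("%s line %d: face shorter than its count", path, 2 + nv + i)
    tok[2:(k + 1)] + 1L   # OFF is 0-based
  })
  surface_mesh(verts, triangulate_ngons(polys))
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", n_vertices(mesh), n_triangles(mesh)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  if (n_triangles(mesh)) {
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  }
}

# ------------------------------------------------------------------- PLY
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "ply")) stop_format("%s line 1: missing ply magic", path)
  fmt <- NULL
  elements <- list()   # list of list(name, count, props = list(type, is_list, index_type))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) stop_format("%s: header missing end_header", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") {
      fmt <- tok[2]
      if (!fmt %in% c("ascii", "binary_little_endian")) {
        stop_format("%s: unsupported PLY format '%s'", path, fmt)
      }
    } else if (tok[1] == "element") {
      elements[[length(elements) + 1L]] <-
        list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      i <- length(elements)
      if (!i) stop_format("%s: property before any element", path)
      p <- if (tok[2] == "list") {
        list(type = tok[4], is_list = TRUE, count_type = tok[3], name = tok[5])
      } else {
        list(type = tok[2], is_list = FALSE, name = tok[3])
      }
      elements[[i]]$props <- c(elements[[i]]$props, list(p))
    } else if (tok[1] == "end_header") break
  }
  type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                 short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                 int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                 float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  read_scalar_bin <- function(type, n) {
    sz <- type_size[[type]]
    if (type %in% c("float", "float32", "double", "float64")) {
      readBin(con, "double", n = n, size = sz, endian = "little")
    } else {
      readBin(con, "integer", n = n, size = sz,
              signed = !(sz <= 2 && grepl("^u", type)), endian = "little")
    }
  }
  verts <- matrix(numeric(0), 0, 3)
  polys <- list()
  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    cursor <- 0L
    for (el in elements) {
      n <- el$count
      block <- rest[cursor + seq_len(n)]
      cursor <- cursor + n
      if (el$name == "vertex") {
        scalar_names <- vapply(el$props, function(p) p$name, "")
        xyz <- match(c("x", "y", "z"), scalar_names)
        if (any(is.na(xyz))) stop_format("%s: vertex element lacks x/y/z", path)
        toks <- strsplit(trimws(block), "\\s+")
        verts <- t(vapply(seq_len(n), function(i) {
          num_or_die(toks[[i]][xyz], path, i, "vertex")
        }, numeric(3)))
      } else if (el$name == "face") {
        toks <- strsplit(trimws(block), "\\s+")
        polys <- lapply(seq_len(n), function(i) {
          v <- as.integer(num_or_die(toks[[i]], path, i, "face"))
          if (length(v) < v[1] + 1L) stop_format("%s: face %d shorter than its count", path, i)
          v[2:(v[1] + 1L)] + 1L
        })
      }
    }
  } else {
    for (el in elements) {
      if (el$name == "vertex") {
        scalar_names <- vapply(el$props, function(p) p$name, "")
        xyz <- match(c("x", "y", "z"), scalar_names)
        if (any(is.na(xyz))) stop_format("%s: vertex element lacks x/y/z", path)
        vals <- matrix(NA_real_, el$count, length(el$props))
        for (i in seq_len(el$count)) {
          for (j in seq_along(el$props)) {
            vals[i, j] <- read_scalar_bin(el$props[[j]]$type, 1L)
          }
        }
        verts <- vals[, xyz, drop = FALSE]
      } else if (el$name == "face") {
        lp <- el$props[[1]]
        polys <- vector("list", el$count)
        for (i in seq_len(el$count)) {
          k <- read_scalar_bin(lp$count_type, 1L)
          polys[[i]] <- read_scalar_bin(lp$type, k) + 1L
        }
      } else if (el$count > 0) {
        stop_format("%s: unsupported binary element '%s'", path, el$name)
      }
    }
  }
  surface_mesh(verts, triangulate_ngons(polys))
}

write_ply <- function(mesh, path, binary = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n_vertices(mesh)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", n_triangles(mesh)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con)
  if (binary) {
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    if (n_triangles(mesh)) {
      for (i in seq_len(n_triangles(mesh))) {
        writeBin(as.raw(3L), con)
        writeBin(mesh$triangles[i, ] - 1L, con, size = 4, endian = "little")
      }
    }
  } else {
    writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    if (n_triangles(mesh)) {
      writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                         mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
    }
  }
}

# ------------------------------------------------------------------- STL
read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = 80)
  ntri_guess <- if (sz >= 84) readBin(con, "integer", n = 1, size = 4, endian = "little") else -1
  close(con)
  is_binary <- sz >= 84 && sz == 84 + 50 * as.numeric(ntri_guess)
  tris_xyz <- if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 84)
    out <- matrix(NA_real_, ntri_guess * 3L, 3)
    for (i in seq_len(ntri_guess)) {
      rec <- readBin(con, "double", n = 12, size = 4, endian = "little")
      out[(3 * i - 2):(3 * i), ] <- matrix(rec[4:12], 3, 3, byrow = TRUE)
      readBin(con, "raw", n = 2)
    }
    out
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines)
    if (length(vl) %% 3 != 0) {
      stop_format("%s: ascii STL vertex count %d not a multiple of 3", path, length(vl))
    }
    toks <- strsplit(trimws(lines[vl]), "\\s+")
    t(vapply(seq_along(toks), function(i) {
      num_or_die(toks[[i]][2:4], path, vl[i], "vertex")
    }, numeric(3)))
  }
  k <- nrow(tris_xyz) / 3
  soup <- surface_mesh(tris_xyz, matrix(seq_len(3 * k), ncol = 3, byrow = TRUE))
  weld_vertices(soup)
}

write_stl <- function(mesh, path, binary = TRUE) {
  nt <- n_triangles(mesh)
  nrm <- if (nt) tri_normals(mesh) else matrix(0, 0, 3)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    for (i in seq_len(nt)) {
      rec <- c(nrm[i, ],
               mesh$vertices[mesh$triangles[i, 1], ],
               mesh$vertices[mesh$triangles[i, 2], ],
               mesh$vertices[mesh$triangles[i, 3], ])
      writeBin(rec, con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid voxmesh", con)
    for (i in seq_len(nt)) {
      writeLines(sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3) {
        v <- mesh$vertices[mesh$triangles[i, k], ]
        writeLines(sprintf("    vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid voxmesh", con)
  }
}
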