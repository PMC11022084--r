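#' Read a triangulated surface from a mesh file
#'
#' Supported formats: OFF (ascii), PLY (ascii and binary little-endian), and
#' VTK legacy polydata (ascii). Non-triangular faces are rejected unless
#' `triangulate = TRUE`, in which case polygons are fan-triangulated.
#' VTK `POINT_DATA` scalar and vector arrays are returned in the
#' `point_data` attribute of the surface.
#'
#' @param path file path.
#' @param format one of `"off"`, `"ply"`, `"vtk"`; inferred from the file
#'   extension when `NULL`.
#' @param triangulate fan-triangulate quads and higher polygons instead of
#'   erroring.
#' @param name label for the surface; defaults to the file name.
#' @return a [triangulated_surface()].
#' @export
read_surface <- function(path, format = NULL, triangulate = FALSE,
                         name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  if (is.null(name)) name <- basename(path)
  parsed <- switch(format,
    off = read_off(path),
    ply = read_ply(path),
    vtk = read_vtk(path),
    stop("unsupported format: ", format))
  faces <- polygons_to_triangles(parsed$polys, triangulate)
  surf <- triangulated_surface(parsed$vertices, faces, name = name)
  if (!is.null(parsed$point_data) && length(parsed$point_data))
    attr(surf, "point_data") <- parsed$point_data
  surf
}

#' Write a triangulated surface to a mesh file
#'
#' For VTK, named entries of `fields` (scalars: numeric vectors; vectors:
#' `n x 3` matrices, one row per mesh vertex) are written as `POINT_DATA`
#' arrays. PLY can be written in ascii (default) or binary little-endian.
#'
#' @param surf a [triangulated_surface()].
#' @param path output file path.
#' @param format one of `"off"`, `"ply"`, `"vtk"`; inferred from the
#'   extension when `NULL`.
#' @param fields named list of per-vertex fields (VTK only).
#' @param binary write binary little-endian PLY.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surf, path, format = NULL, fields = list(),
                          binary = FALSE) {
  validate_surface(surf)
  format <- infer_format(path, format)
  nv <- nrow(surf$vertices)
  for (nm in names(fields)) {
    len <- if (is.matrix(fields[[nm]])) nrow(fields[[nm]]) else length(fields[[nm]])
    if (len != nv)
      stop(sprintf("field '%s' has length %d but mesh has %d vertices",
                   nm, len, nv))
  }
  switch(format,
    off = write_off(surf, path),
    ply = if (binary) write_ply_binary(surf, path) else write_ply_ascii(surf, path),
    vtk = write_vtk(surf, path, fields),
    stop("unsupported format: ", format))
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(tolower(format))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("off", "ply", "vtk")) return(ext)
  stop("cannot infer mesh format from extension '", ext,
       "'; pass format= explicitly")
}

# polygons come in as a list of integer vectors (1-based)
polygons_to_triangles <- function(polys, triangulate) {
  sizes <- lengths(polys)
  if (any(sizes < 3L)) stop("polygon with fewer than 3 vertices")
  if (all(sizes == 3L))
    return(matrix(unlist(polys), ncol = 3, byrow = TRUE))
  if (!triangulate)
    stop("mesh contains non-triangular faces; set triangulate = TRUE to fan-triangulate")
  tri <- lapply(polys, function(p) {
    k <- length(p)
    cbind(p[1], p[2:(k - 1)], p[3:k])
  })
  do.call(rbind, tri)
}

## ---------------------------------------------------------------- OFF

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file")
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  polys <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    x <- scan(text = l, quiet = TRUE)
    k <- x[1]
    as.integer(x[2:(1 + k)]) + 1L
  })
  list(vertices = verts, polys = polys, point_data = NULL)
}

write_off <- function(surf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surf$vertices), nrow(surf$faces)), con)
  writeLines(apply(surf$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(paste(3L, surf$faces[, 1] - 1L, surf$faces[, 2] - 1L,
                   surf$faces[, 3] - 1L), con)
}

## ---------------------------------------------------------------- PLY

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_is_float <- function(ty) ty %in% c("float", "float32", "double", "float64")

read_ply_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- trimws(readLines(con, n = 1))
    if (length(line) == 0L) stop("truncated PLY header")
    tok <- strsplit(line, "[[:space:]]+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") { fmt <- tok[2]; next }
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
      next
    }
    if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
      next
    }
    if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  list(format = fmt, elements = elements)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_ply_header(con)
  if (is.null(hdr$elements$vertex) || is.null(hdr$elements$face))
    stop("PLY file must contain vertex and face elements")
  if (hdr$format == "ascii") {
    read_ply_ascii_body(con, hdr)
  } else if (hdr$format == "binary_little_endian") {
    read_ply_binary_body(con, hdr)
  } else {
    stop("unsupported PLY format: ", hdr$format)
  }
}

read_ply_ascii_body <- function(con, hdr) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  i <- 0L
  verts <- NULL; polys <- NULL
  for (el in hdr$elements) {
    block <- lines[(i + 1L):(i + el$count)]
    i <- i + el$count
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- matrix(scan(text = block, quiet = TRUE),
                     ncol = length(el$props), byrow = TRUE)
      verts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else if (el$name == "face") {
      polys <- lapply(block, function(l) {
        x <- scan(text = l, quiet = TRUE)
        as.integer(x[2:(1 + x[1])]) + 1L
      })
    }
  }
  list(vertices = verts, polys = polys, point_data = NULL)
}

read_ply_scalar <- function(con, ty, n = 1L) {
  sz <- ply_type_size[[ty]]
  if (ply_is_float(ty)) {
    readBin(con, "double", n = n, size = sz, endian = "little")
  } else {
    readBin(con, "integer", n = n, size = sz, endian = "little",
            signed = !(ty %in% c("uchar", "uint8", "ushort", "uint16")))
  }
}

read_ply_binary_body <- function(con, hdr) {
  verts <- NULL; polys <- NULL
  for (el in hdr$elements) {
    anylist <- any(vapply(el$props, `[[`, TRUE, "list"))
    if (!anylist) {
      types <- vapply(el$props, `[[`, "", "type")
      pnames <- vapply(el$props, `[[`, "", "name")
      if (length(unique(types)) == 1L) {
        vals <- matrix(read_ply_scalar(con, types[1],
                                       n = el$count * length(types)),
                       ncol = length(types), byrow = TRUE)
      } else {
        vals <- matrix(0, el$count, length(types))
        for (r in seq_len(el$count))
          for (j in seq_along(types))
            vals[r, j] <- read_ply_scalar(con, types[j])
      }
      if (el$name == "vertex")
        verts <- vals[, match(c("x", "y", "z"), pnames), drop = FALSE]
    } else {
      if (length(el$props) != 1L)
        stop("PLY element mixing list and scalar properties is not supported")
      p <- el$props[[1]]
      pl <- vector("list", el$count)
      for (r in seq_len(el$count)) {
        k <- read_ply_scalar(con, p$count_type)
        pl[[r]] <- as.integer(read_ply_scalar(con, p$type, n = k)) + 1L
      }
      if (el$name == "face") polys <- pl
    }
  }
  list(vertices = verts, polys = polys, point_data = NULL)
}

write_ply_header <- function(con, surf, fmt) {
  writeLines(c("ply",
               paste("format", fmt, "1.0"),
               sprintf("element vertex %d", nrow(surf$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(surf$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
}

write_ply_ascii <- function(surf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write_ply_header(con, surf, "ascii")
  writeLines(apply(surf$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(paste(3L, surf$faces[, 1] - 1L, surf$faces[, 2] - 1L,
                   surf$faces[, 3] - 1L), con)
}

write_ply_binary <- function(surf, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write_ply_header(con, surf, "binary_little_endian")
  writeBin(as.vector(t(surf$vertices)), con, size = 8, endian = "little")
  f0 <- t(surf$faces) - 1L
  for (j in seq_len(ncol(f0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f0[, j]), con, size = 4, endian = "little")
  }
}

## ---------------------------------------------------------------- VTK

read_vtk <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^# vtk DataFile", lines[1])) stop("not a VTK legacy file")
  if (toupper(trimws(lines[3])) != "ASCII")
    stop("only ascii VTK legacy files are supported")
  if (!grepl("POLYDATA", toupper(lines[4])))
    stop("VTK dataset is not POLYDATA")
  i <- 5L
  verts <- NULL; polys <- NULL; point_data <- list()
  npts <- 0L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    kw <- toupper(tok[1])
    if (kw == "POINTS") {
      npts <- as.integer(tok[2])
      nums <- numeric(0); j <- i + 1L
      while (length(nums) < 3L * npts) {
        nums <- c(nums, scan(text = lines[j], quiet = TRUE))
        j <- j + 1L
      }
      verts <- matrix(nums, ncol = 3, byrow = TRUE)
      i <- j
    } else if (kw == "POLYGONS") {
      ncell <- as.integer(tok[2]); ntot <- as.integer(tok[3])
      nums <- numeric(0); j <- i + 1L
      while (length(nums) < ntot) {
        nums <- c(nums, scan(text = lines[j], quiet = TRUE))
        j <- j + 1L
      }
      polys <- vector("list", ncell); k <- 1L
      for (ci in seq_len(ncell)) {
        sz <- nums[k]
        polys[[ci]] <- as.integer(nums[(k + 1L):(k + sz)]) + 1L
        k <- k + sz + 1L
      }
      i <- j
    } else if (kw == "POINT_DATA") {
      i <- i + 1L
    } else if (kw == "SCALARS") {
      nm <- tok[2]
      j <- i + 1L
      if (grepl("^LOOKUP_TABLE", toupper(lines[j]))) j <- j + 1L
      nums <- numeric(0)
      while (length(nums) < npts) {
        nums <- c(nums, scan(text = lines[j], quiet = TRUE))
        j <- j + 1L
      }
      point_data[[nm]] <- nums
      i <- j
    } else if (kw == "VECTORS" || kw == "NORMALS") {
      nm <- tok[2]
      nums <- numeric(0); j <- i + 1L
      while (length(nums) < 3L * npts) {
        nums <- c(nums, scan(text = lines[j], quiet = TRUE))
        j <- j + 1L
      }
      point_data[[nm]] <- matrix(nums, ncol = 3, byrow = TRUE)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  list(vertices = verts, polys = polys, point_data = point_data)
}

write_vtk <- function(surf, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(surf$vertices); nf <- nrow(surf$faces)
  writeLines(c("# vtk DataFile Version 3.0",
               paste("lamcoord surface:", surf$name),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nv)), con)
  writeLines(apply(surf$vertices, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(paste(3L, surf$faces[, 1] - 1L, surf$faces[, 2] - 1L,
                   surf$faces[, 3] - 1L), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", nv), con)
    for (nm in names(fields)) {
      fv <- fields[[nm]]
      if (is.matrix(fv)) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(apply(fv, 1, function(r)
          paste(sprintf("%.17g", r), collapse = " ")), con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.17g", fv), con)
      }
    }
  }
}
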