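#' Oriented triangulated surface
#'
#' The basic container for a surface: an `n x 3` matrix of vertex positions
#' (mm by convention, but unit-free mathematically) and an `m x 3` integer
#' matrix of 1-based vertex indices with counterclockwise winding, so that the
#' right-hand rule gives the outward (positively oriented) unit normal.
#' Both closed (sphere-like) and open (disk-like) meshes are supported.
#'
#' @param vertices numeric matrix, one row per vertex, three columns.
#' @param faces integer matrix, one row per triangle, three columns of
#'   1-based vertex indices, counterclockwise as seen from outside.
#' @param name optional label carried through I/O and reports.
#' @param validate if `TRUE` (default) run [validate_surface()].
#' @return An object of class `triangulated_surface` with elements
#'   `vertices`, `faces`, `name`.
#' @export
triangulated_surface <- function(vertices, faces, name = "surface",
                                 validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  surf <- structure(list(vertices = vertices, faces = faces,
                         name = as.character(name)[1]),
                    class = "triangulated_surface")
  if (validate) validate_surface(surf)
  surf
}

#' @export
print.triangulated_surface <- function(x, ...) {
  nb <- length(boundary_vertices(x))
  cat(sprintf("<triangulated_surface '%s': %d vertices, %d faces, %s>\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              if (nb == 0L) "closed" else sprintf("open (%d boundary vertices)", nb)))
  invisible(x)
}

#' Validate a triangulated surface
#'
#' Checks index ranges, degenerate faces (area below
#' `1e-12 * (bounding-box diagonal)^2`), and global winding consistency
#' (every interior edge must appear once in each direction).
#'
#' @param surf a [triangulated_surface()].
#' @return `surf`, invisibly; errors on violation.
#' @export
validate_surface <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  if (anyNA(v) || any(!is.finite(v))) stop("non-finite vertex coordinates")
  if (nrow(f) < 1L) stop("mesh has no faces")
  if (min(f) < 1L || max(f) > nrow(v))
    stop(sprintf("face index out of range: mesh has %d vertices but faces reference %d",
                 nrow(v), max(f)))
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    stop("degenerate face: repeated vertex index within a triangle")
  bbox <- apply(v, 2, range)
  diag2 <- sum((bbox[2, ] - bbox[1, ])^2)
  a <- face_areas(surf)
  tol <- 1e-12 * max(diag2, .Machine$double.eps)
  if (any(a < tol))
    stop(sprintf("%d degenerate face(s) with area below tolerance %.3g",
                 sum(a < tol), tol))
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    stop("inconsistent winding: a directed edge appears in two faces")
  invisible(surf)
}

#' Per-face quantities
#'
#' `face_areas`, `face_normals` (unit), `face_centers`, and
#' `face_cross` (the un-normalized cross product `(v1-v0) x (v2-v0)`,
#' whose norm is twice the face area).
#'
#' @param surf a [triangulated_surface()].
#' @return numeric vector (areas) or matrix (normals/centers/cross).
#' @export
face_areas <- function(surf) {
  0.5 * sqrt(rowSums(face_cross(surf)^2))
}

#' @rdname face_areas
#' @export
face_cross <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cross3(u, w)
}

#' @rdname face_areas
#' @export
face_normals <- function(surf) {
  cr <- face_cross(surf)
  nrm <- sqrt(rowSums(cr^2))
  cr / pmax(nrm, .Machine$double.xmin)
}

#' @rdname face_areas
#' @export
face_centers <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Boundary vertices of an open mesh
#'
#' A boundary edge belongs to exactly one face. Returns the (sorted) indices
#' of vertices on any boundary edge; empty for closed meshes.
#'
#' @param surf a [triangulated_surface()].
#' @return integer vector of vertex indices (possibly empty).
#' @export
boundary_vertices <- function(surf) {
  f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (length(bkey) == 0L) return(integer(0))
  idx <- unique(as.integer(unlist(strsplit(bkey, " ", fixed = TRUE))))
  sort(idx)
}

#' Total mesh area
#' @param surf a [triangulated_surface()].
#' @return scalar area.
#' @export
surface_area <- function(surf) sum(face_areas(surf))

#' Euler characteristic V - E + F
#' @param surf a [triangulated_surface()].
#' @return integer.
#' @export
euler_characteristic <- function(surf) {
  f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(surf$vertices) - length(key) + nrow(f)
}

#' Reverse the winding (orientation) of every face
#' @param surf a [triangulated_surface()].
#' @return the surface with all normals flipped.
#' @export
reverse_orientation <- function(surf) {
  surf$faces <- surf$faces[, c(1, 3, 2), drop = FALSE]
  surf
}

#' Replace the vertex positions of a surface, keeping its topology
#' @param surf a [triangulated_surface()].
#' @param vertices new vertex matrix, same number of rows.
#' @return a `triangulated_surface`.
#' @export
with_vertices <- function(surf, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) != nrow(surf$vertices))
    stop("vertex count mismatch")
  surf$vertices <- vertices
  surf
}

#' Mean edge length of a mesh
#' @param surf a [triangulated_surface()].
#' @return scalar.
#' @export
mean_edge_length <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keep <- !duplicated(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e <- e[keep, , drop = FALSE]
  mean(sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2)))
}

# rowwise cross product of two n x 3 matrices
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
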