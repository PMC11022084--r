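#' Area-weighted unit vertex normals
#'
#' Each vertex normal is the normalized sum of the (un-normalized) cross
#' products of its incident faces; the cross-product magnitude is twice the
#' face area, so this is the usual area-weighted average with the orientation
#' given by the counterclockwise winding.
#'
#' @param surf a [triangulated_surface()].
#' @return `n x 3` matrix of unit vectors.
#' @export
vertex_normals <- function(surf) {
  cr <- face_cross(surf)
  acc <- accumulate_faces(surf, cr)
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm == 0))
    stop("isolated vertex (no incident face) at index ",
         which(nrm == 0)[1])
  acc / nrm
}

#' One-ring areas
#'
#' `a(x)` is the summed area of all triangles containing vertex `x`
#' (boundary vertices sum only their incident triangles). On a closed mesh
#' the one-ring areas total three times the mesh area.
#'
#' @param surf a [triangulated_surface()].
#' @return numeric vector, strictly positive.
#' @export
one_ring_area <- function(surf) {
  a <- face_areas(surf)
  acc <- accumulate_faces(surf, cbind(a, 0, 0))[, 1]
  if (any(acc == 0))
    stop("isolated vertex (no incident face) at index ", which(acc == 0)[1])
  acc
}

# sum an m x k per-face quantity into each face's three vertices
accumulate_faces <- function(surf, per_face) {
  f <- surf$faces
  nv <- nrow(surf$vertices)
  idx <- c(f[, 1], f[, 2], f[, 3])
  vals <- rbind(per_face, per_face, per_face)
  out <- matrix(0, nv, ncol(per_face))
  s <- rowsum(vals, idx)
  rows <- as.integer(rownames(s))
  out[rows, ] <- s
  out
}

#' Discrete mean curvature
#'
#' Cotangent-Laplacian estimator: the Laplace--Beltrami operator applied to
#' the coordinate functions gives the mean-curvature normal, which is
#' projected onto the unit vertex normal. The sign convention is that of the
#' trace of the differential of the outward normal: a sphere of radius `r`
#' with outward orientation has `H = -1/r` everywhere.
#'
#' Boundary vertices have no full one-ring; their values are still computed
#' from the partial ring but flagged in the `"boundary"` attribute of the
#' result.
#'
#' @param surf a [triangulated_surface()].
#' @return numeric vector of per-vertex `H`, with attribute `boundary`
#'   (logical vector).
#' @export
mean_curvature <- function(surf) {
  L <- cotan_laplacian(surf)
  A <- one_ring_area(surf) / 3
  n <- vertex_normals(surf)
  lx <- as.matrix(L %*% surf$vertices)
  H <- rowSums(lx * n) / (2 * A)
  bmask <- rep(FALSE, nrow(surf$vertices))
  bmask[boundary_vertices(surf)] <- TRUE
  attr(H, "boundary") <- bmask
  H
}

# sparse cotangent Laplacian, (Lx)_i = 1/2 sum_j (cot a_ij + cot b_ij)(x_j - x_i)
cotan_laplacian <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  nv <- nrow(v)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  # for each face corner k, the opposite edge (i,j) receives cot(angle at k)/2
  corner <- list(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (cn in corner) {
    k <- f[, cn[1]]; i <- f[, cn[2]]; j <- f[, cn[3]]
    u <- v[i, , drop = FALSE] - v[k, , drop = FALSE]
    w <- v[j, , drop = FALSE] - v[k, , drop = FALSE]
    cosang <- rowSums(u * w)
    sinang <- sqrt(rowSums(cross3(u, w)^2))
    cot <- cosang / pmax(sinang, .Machine$double.eps)
    ii <- c(ii, i, j); jj <- c(jj, j, i); ww <- c(ww, cot / 2, cot / 2)
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nv, nv))
  Matrix::Diagonal(x = Matrix::rowSums(W)) * -1 + W
}

#' Tangential divergence of a vertex vector field
#'
#' Implements the intrinsic divergence
#' `div_S(rho)(p) = e1' Drho(p) e1 + e2' Drho(p) e2` for an orthonormal
#' tangent basis `(e1, e2)` at each vertex. The field is first projected onto
#' the tangent plane of the vertex normal; its differential is then estimated
#' by a least-squares linear fit over the one-ring neighbours in tangent
#' coordinates.
#'
#' @param surf a [triangulated_surface()].
#' @param rho `n x 3` matrix, one vector per vertex (tangentially projected
#'   internally).
#' @return numeric vector of per-vertex divergence, with attribute
#'   `boundary` (logical vector).
#' @export
surface_divergence <- function(surf, rho) {
  rho <- as.matrix(rho)
  nv <- nrow(surf$vertices)
  if (nrow(rho) != nv) stop("field length mismatch")
  n <- vertex_normals(surf)
  rho_t <- rho - n * rowSums(rho * n)
  adj <- vertex_adjacency(surf)
  v <- surf$vertices
  e1 <- tangent_basis_e1(n)
  e2 <- cross3(n, e1)
  out <- numeric(nv)
  for (i in seq_len(nv)) {
    nb <- adj[[i]]
    if (length(nb) < 2L) { out[i] <- NA_real_; next }
    d <- v[nb, , drop = FALSE] - matrix(v[i, ], length(nb), 3, byrow = TRUE)
    U <- cbind(d %*% e1[i, ], d %*% e2[i, ])
    R <- rho_t[nb, , drop = FALSE] -
      matrix(rho_t[i, ], length(nb), 3, byrow = TRUE)
    # least squares R ~ U %*% t(Ahat), Ahat is 3 x 2 (columns: d/de1, d/de2)
    G <- crossprod(U)
    if (abs(det(G)) < 1e-14 * (sum(diag(G)) / 2)^2) { out[i] <- NA_real_; next }
    Ahat <- t(solve(G, crossprod(U, R)))
    out[i] <- sum(e1[i, ] * Ahat[, 1]) + sum(e2[i, ] * Ahat[, 2])
  }
  bmask <- rep(FALSE, nv)
  bmask[boundary_vertices(surf)] <- TRUE
  attr(out, "boundary") <- bmask
  out
}

# a unit vector orthogonal to each row of n
tangent_basis_e1 <- function(n) {
  ref <- matrix(rep(c(1, 0, 0), each = nrow(n)), ncol = 3)
  flip <- abs(n[, 1]) > 0.9
  ref[flip, ] <- matrix(rep(c(0, 1, 0), each = sum(flip)), ncol = 3)
  e1 <- cross3(n, ref)
  e1 / sqrt(rowSums(e1^2))
}

# list of neighbour vertex indices per vertex
vertex_adjacency <- function(surf) {
  f <- surf$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  e <- e[!duplicated(paste(e[, 1], e[, 2])), , drop = FALSE]
  split(e[, 2], factor(e[, 1], levels = seq_len(nrow(surf$vertices))))
}
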