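#' Reproducing kernel for the deformation space
#'
#' Matrix-valued kernel `K(x, y) = k(|x - y|) I3` with a scalar profile
#' normalized to `k(0) = 1`. Families: a single Gaussian
#' `k(r) = exp(-r^2 / (2 w^2))`, or a sum of Gaussians over several widths
#' (a heavier-tailed, Matern-like multiscale profile), averaged so the value
#' at zero stays 1.
#'
#' @param width positive kernel width(s) (mm); a vector gives the
#'   sum-of-Gaussians family.
#' @param family `"gaussian"` or `"sum_gaussian"` (implied by a vector
#'   width).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(width, family = c("gaussian", "sum_gaussian")) {
  family <- match.arg(family)
  width <- as.numeric(width)
  if (any(width <= 0)) stop("kernel width must be positive")
  if (length(width) > 1L) family <- "sum_gaussian"
  structure(list(family = family, width = width), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec %s, width %s>\n", x$family,
              paste(signif(x$width, 4), collapse = "/")))
  invisible(x)
}

# scalar kernel matrix k(|x_i - y_j|) for n x 3 and m x 3 point sets
kernel_matrix <- function(spec, x, y = x) {
  d2 <- pdist2(x, y)
  K <- 0
  for (w in spec$width) K <- K + exp(-d2 / (2 * w^2))
  K / length(spec$width)
}

# squared Euclidean distance matrix
pdist2 <- function(x, y) {
  x2 <- rowSums(x^2); y2 <- rowSums(y^2)
  d2 <- outer(x2, y2, `+`) - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

#' Evaluate the kernel vector field at query points
#'
#' `v(x) = sum_l K(x, q_l) alpha_l`: the optimal deformation field carried
#' by support points `points` with momenta `weights`.
#'
#' @param spec a [kernel_spec()].
#' @param points `m x 3` support points.
#' @param weights `m x 3` momentum vectors.
#' @param query `n x 3` evaluation points.
#' @return `n x 3` matrix of field values.
#' @export
kernel_field <- function(spec, points, weights, query) {
  if (nrow(points) != nrow(weights)) stop("points/weights length mismatch")
  if (nrow(points) > 5000L)
    warning("direct O(N^2) kernel sum over ", nrow(points), " points")
  kernel_matrix(spec, query, points) %*% weights
}

#' Exact spatial Jacobian of the kernel vector field
#'
#' Analytic `d v / d x` at each query point; no finite-difference
#' approximation is involved. For the (sum-of-)Gaussian family,
#' `grad_x k(x, q) = -k_w(|x-q|) (x - q) / w^2` summed over widths.
#'
#' @inheritParams kernel_field
#' @return `3 x 3 x n` array of Jacobians.
#' @export
kernel_field_jacobian <- function(spec, points, weights, query) {
  n <- nrow(query); m <- nrow(points)
  d2 <- pdist2(query, points)
  # C[i, l] = sum_w exp(-d2/(2w^2)) / w^2, already including the -1 sign below
  C <- 0
  for (w in spec$width) C <- C + exp(-d2 / (2 * w^2)) / w^2
  C <- C / length(spec$width)
  out <- array(0, c(3, 3, n))
  # dv/dx = sum_l alpha_l %o% grad_x k = -sum_l C[i,l] alpha_l (x_i - q_l)^T
  for (a in 1:3) for (b in 1:3) {
    # entry (a,b): -sum_l C[i,l] * alpha[l,a] * (x[i,b] - q[l,b])
    s1 <- (C %*% weights[, a, drop = FALSE]) * query[, b]
    s2 <- C %*% (weights[, a] * points[, b])
    out[a, b, ] <- -(s1 - s2)
  }
  out
}

#' Divergence of the kernel field at query points
#'
#' Trace of [kernel_field_jacobian()], evaluated analytically.
#'
#' @inheritParams kernel_field
#' @return numeric vector of length `nrow(query)`.
#' @export
kernel_field_divergence <- function(spec, points, weights, query) {
  J <- kernel_field_jacobian(spec, points, weights, query)
  J[1, 1, ] + J[2, 2, ] + J[3, 3, ]
}

#' RKHS energy of a momentum configuration
#'
#' `sum_{k,l} alpha_k' K(q_k, q_l) alpha_l`, the squared deformation-space
#' norm of the field carried by `(points, weights)`; non-negative by
#' positive semidefiniteness of the kernel.
#'
#' @inheritParams kernel_field
#' @return non-negative scalar.
#' @export
rkhs_energy <- function(spec, points, weights) {
  G <- kernel_matrix(spec, points)
  sum(weights * (G %*% weights))
}
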