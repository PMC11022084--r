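#' FreeSurfer-style symmetric vertex distance
#'
#' For each vertex `x_i` of `A`: let `y_n` be the nearest vertex of `B` to
#' `x_i`, and `x_m` the nearest vertex of `A` to `y_n`; the reported
#' distance is `d_i = (d(x_i, y_n) + d(x_m, y_n)) / 2`. Vertex-to-vertex
#' Euclidean distances, deterministic nearest-neighbour tie-break by lowest
#' index. Returns one value per vertex of `A`, which is what makes the
#' metric robust to the outliers that inflate a Hausdorff distance.
#'
#' @param A,B [triangulated_surface()]s (`A` plays the role of the compared
#'   surface, `B` the reference).
#' @return an object of class `distance_report` with per-vertex `distances`,
#'   summary `quantiles`, and the two surfaces' names.
#' @export
freesurfer_vertex_distance <- function(A, B) {
  if (nrow(A$vertices) == 0L || nrow(B$vertices) == 0L)
    stop("empty surface")
  d2 <- pdist2(A$vertices, B$vertices)
  n_idx <- apply(d2, 1, which.min)
  m_idx <- apply(d2[, n_idx, drop = FALSE], 2, which.min)
  # the selected distances are recomputed from coordinates: the expanded
  # quadratic form loses precision near zero
  d_in <- sqrt(rowSums((A$vertices - B$vertices[n_idx, , drop = FALSE])^2))
  d_mn <- sqrt(rowSums((A$vertices[m_idx, , drop = FALSE] -
                          B$vertices[n_idx, , drop = FALSE])^2))
  d <- (d_in + d_mn) / 2
  structure(list(distances = d,
                 quantiles = stats::quantile(d, c(0, .25, .5, .75, .9, 1)),
                 from = A$name, to = B$name),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report '%s' vs '%s': %d vertices>\n",
              x$from, x$to, length(x$distances)))
  print(signif(x$quantiles, 4))
  invisible(x)
}

#' Empirical CDF of a distance report
#'
#' Right-continuous empirical distribution of the per-vertex distances,
#' sampled on a grid.
#'
#' @param report a [freesurfer_vertex_distance()] result.
#' @param grid numeric grid; defaults to 101 points spanning `[0, max d]`.
#' @return data.frame with columns `distance` and `cdf`.
#' @export
distance_cdf <- function(report, grid = NULL) {
  d <- report$distances
  if (length(d) == 0L) stop("empty distance report")
  if (is.null(grid)) grid <- seq(0, max(d), length.out = 101L)
  Fn <- stats::ecdf(d)
  data.frame(distance = grid, cdf = Fn(grid))
}

#' Plot the cumulative distribution of vertex distances
#'
#' @param x a `distance_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.distance_report <- function(x, ...) {
  cdf <- distance_cdf(x)
  graphics::plot(cdf$distance, cdf$cdf, type = "s",
                 xlab = "vertex distance", ylab = "CDF",
                 main = sprintf("%s vs %s", x$from, x$to), ...)
  invisible(x)
}

#' Residual of the area-evolution identity along a laminar system
#'
#' Checks the differential identity
#' `sigma^{-1} d sigma/dt = div_S(rho) - 2 zeta H` per vertex and time node,
#' where the streamline velocity `w` is decomposed into its tangential part
#' `rho` and normal part `zeta n`, the tangential divergence and mean
#' curvature are evaluated on each evolving slice, and `d sigma/dt` uses
#' centered time differences (one-sided at the ends). Boundary vertices are
#' excluded (no full one-ring).
#'
#' @param ls a [laminar_system()] with at least 3 time nodes.
#' @param sigma optional `(T+1) x N` matrix from [surface_jacobian()].
#' @return an object of class `prop1_report`: residual matrix (`NA` at
#'   boundary vertices), the two sides of the identity, `rms`, `max`,
#'   `rms_relative` (residual RMS over the RMS of the left-hand side), and
#'   the grid spacings used.
#' @export
prop1_residual <- function(ls, sigma = NULL) {
  nt <- dim(ls$psi)[1]
  if (nt < 3L) stop("need at least 3 time nodes")
  if (is.null(sigma)) sigma <- surface_jacobian(ls)
  nv <- dim(ls$psi)[2]
  dsig <- matrix(0, nt, nv)
  tt <- ls$times
  dsig[1, ] <- (sigma[2, ] - sigma[1, ]) / (tt[2] - tt[1])
  dsig[nt, ] <- (sigma[nt, ] - sigma[nt - 1L, ]) / (tt[nt] - tt[nt - 1L])
  for (i in 2:(nt - 1L))
    dsig[i, ] <- (sigma[i + 1L, ] - sigma[i - 1L, ]) / (tt[i + 1L] - tt[i - 1L])
  lhs <- dsig / sigma
  rhs <- matrix(NA_real_, nt, nv)
  for (i in seq_len(nt)) {
    slice <- layer_surface(ls, i)
    n <- ls$normals[i, , ]
    w <- ls$velocities[i, , ]
    zeta <- rowSums(w * n)
    rho <- w - n * zeta
    dv <- surface_divergence(slice, rho)
    H <- mean_curvature(slice)
    rhs[i, ] <- dv - 2 * zeta * H
  }
  resid <- lhs - rhs
  resid[, ls$boundary] <- NA_real_
  ok <- !is.na(resid)
  structure(list(residual = resid, lhs = lhs, rhs = rhs,
                 rms = sqrt(mean(resid[ok]^2)),
                 max = max(abs(resid[ok])),
                 rms_relative = sqrt(mean(resid[ok]^2)) /
                   sqrt(mean(lhs[ok]^2)),
                 dt = mean(diff(tt)),
                 mean_edge = mean_edge_length(layer_surface(ls, 1)),
                 boundary = ls$boundary),
            class = "prop1_report")
}

#' @export
print.prop1_report <- function(x, ...) {
  cat(sprintf(paste0("<prop1_report: RMS residual %.4g (relative %.3g), ",
                     "max %.4g; dt = %.3g, mean edge = %.3g>\n"),
              x$rms, x$rms_relative, x$max, x$dt, x$mean_edge))
  invisible(x)
}

#' Equivolume deviation of a laminar system
#'
#' Recomputes the surface Jacobian and equivolumetric depth on the system's
#' own grid and returns the maximum over vertices and time nodes of
#' `|gamma(t, x) / c0(x) - t|`. Zero (to quadrature accuracy) exactly when
#' the layers are equivolumetric, i.e. after [reparametrize()].
#'
#' @param ls a [laminar_system()].
#' @param use_velocities quadrature from stored velocities when available
#'   (`NULL` = auto); displacement-based otherwise.
#' @return scalar maximum deviation, with attribute `per_time` (maximum per
#'   time node).
#' @export
equivolume_check <- function(ls, use_velocities = NULL) {
  sys <- ls
  if (isFALSE(use_velocities)) sys$velocities <- NULL
  sig <- surface_jacobian(sys)
  gam <- equivol_depth(sys, sig)
  tc <- time_change(gam)
  dev <- abs(sweep(tc$tau, 1, sys$times, `-`))
  structure(max(dev), per_time = apply(dev, 1, max))
}
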