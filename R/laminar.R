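#' Laminar coordinate system
#'
#' A discrete embedding `psi(t, x)`: one vertex position per time node and
#' per vertex of the reference surface, all slices sharing the reference
#' topology. Slice `t = 0` is the inner surface, `t = 1` its image on the
#' outer surface; rows of `psi` along `t` are the streamlines. Unit normals
#' are recomputed per slice and oriented so that the normal component of the
#' streamline velocity is non-negative at `t = 0`, then propagated by
#' continuity in `t`.
#'
#' @param faces face matrix shared by all slices.
#' @param psi `(T+1) x N x 3` array of positions.
#' @param times increasing vector of `T+1` values in `[0, 1]`.
#' @param velocities optional `(T+1) x N x 3` array of streamline velocities
#'   `w = d psi / dt`; when absent, centered finite differences of `psi` are
#'   used where velocities are required.
#' @param name label.
#' @param check_embedding additionally verify that no slice has collapsed
#'   (degenerate) triangles.
#' @return an object of class `laminar_system`.
#' @export
laminar_system <- function(faces, psi, times, velocities = NULL,
                           name = "laminar", check_embedding = TRUE) {
  stopifnot(length(dim(psi)) == 3L, dim(psi)[3] == 3L,
            length(times) == dim(psi)[1])
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (abs(times[1]) > 1e-12 || abs(times[length(times)] - 1) > 1e-12)
    stop("times must span [0, 1]")
  nt <- dim(psi)[1]; nv <- dim(psi)[2]
  if (check_embedding) {
    for (i in seq_len(nt)) {
      surf <- triangulated_surface(psi[i, , ], faces, validate = FALSE)
      a <- face_areas(surf)
      bbox <- apply(surf$vertices, 2, range)
      if (any(a < 1e-12 * max(sum((bbox[2, ] - bbox[1, ])^2),
                              .Machine$double.eps)))
        stop("degenerate layer (collapsed triangles) at time index ", i)
    }
  }
  velocity_source <- if (is.null(velocities)) "finite_difference" else "supplied"
  if (is.null(velocities)) velocities <- fd_velocities(psi, times)
  normals <- array(0, dim(psi))
  prev <- NULL
  for (i in seq_len(nt)) {
    n <- vertex_normals(triangulated_surface(psi[i, , ], faces,
                                             validate = FALSE))
    if (i == 1L) {
      if (mean(rowSums(n * velocities[1, , ])) < 0) n <- -n
    } else if (mean(rowSums(n * prev)) < 0) {
      n <- -n
    }
    normals[i, , ] <- n
    prev <- n
  }
  bmask <- rep(FALSE, nv)
  bmask[boundary_vertices(triangulated_surface(psi[1, , ], faces,
                                               validate = FALSE))] <- TRUE
  structure(list(faces = faces, psi = psi, times = times,
                 velocities = velocities, velocity_source = velocity_source,
                 normals = normals, boundary = bmask, name = name),
            class = "laminar_system")
}

# centered differences in t (one-sided at the ends) on a (T+1) x N x 3 array
fd_velocities <- function(psi, times) {
  nt <- length(times)
  w <- array(0, dim(psi))
  w[1, , ] <- (psi[2, , ] - psi[1, , ]) / (times[2] - times[1])
  w[nt, , ] <- (psi[nt, , ] - psi[nt - 1L, , ]) / (times[nt] - times[nt - 1L])
  if (nt > 2L) for (i in 2:(nt - 1L))
    w[i, , ] <- (psi[i + 1L, , ] - psi[i - 1L, , ]) / (times[i + 1L] - times[i - 1L])
  w
}

#' @export
print.laminar_system <- function(x, ...) {
  cat(sprintf("<laminar_system '%s': %d time slices x %d streamlines>\n",
              x$name, dim(x$psi)[1], dim(x$psi)[2]))
  invisible(x)
}

#' Extract one layer (time slice) as a surface
#' @param ls a [laminar_system()].
#' @param i time index (1-based).
#' @return a [triangulated_surface()].
#' @export
layer_surface <- function(ls, i) {
  triangulated_surface(ls$psi[i, , ], ls$faces,
                       name = sprintf("%s_t%g", ls$name, ls$times[i]),
                       validate = FALSE)
}

#' Build the laminar coordinate system from a registration
#'
#' The registration's vertex trajectories are the streamlines. With
#' `refinement > 1`, the streamlines are re-integrated with RK4 on a grid
#' refined by that factor, using the stored analytic field
#' (the momentum is piecewise constant in time). Velocities are evaluated
#' from the same analytic field at every node.
#'
#' @param result a `registration_result`.
#' @param refinement time-grid refinement factor (integer >= 1).
#' @param integrator `"euler"` keeps the registration's stored (Euler)
#'   trajectories when `refinement = 1`; `"rk4"` re-integrates the
#'   streamlines through the analytic field.
#' @param check_embedding see [laminar_system()].
#' @return a [laminar_system()].
#' @export
build_laminar_system <- function(result, refinement = 1L,
                                 integrator = c("euler", "rk4"),
                                 check_embedding = TRUE) {
  integrator <- match.arg(integrator)
  T <- dim(result$alpha)[1]
  refinement <- as.integer(refinement)
  if (refinement < 1L) stop("refinement must be >= 1")
  if (refinement == 1L && integrator == "euler") {
    psi <- result$q
  } else {
    psi <- transport_points(result, result$S0$vertices, "rk4",
                            substeps = refinement)
  }
  nt <- dim(psi)[1]
  times <- seq(0, 1, length.out = nt)
  vel <- array(0, dim(psi))
  for (i in seq_len(nt)) {
    step <- min(1L + (i - 1L) %/% refinement, T)
    vel[i, , ] <- kernel_field(result$flow_kernel, result$q[step, , ],
                               matrix(result$alpha[step, , ], ncol = 3),
                               psi[i, , ])
  }
  laminar_system(result$faces, psi, times, velocities = vel,
                 name = "registered", check_embedding = check_embedding)
}

#' Streamline thickness
#'
#' Length of each streamline polyline: the discrete
#' `theta(x) = int_0^1 |d psi/dt| dt`.
#'
#' @param ls a [laminar_system()].
#' @return numeric vector, one length per streamline.
#' @export
thickness <- function(ls) {
  nt <- dim(ls$psi)[1]
  th <- numeric(dim(ls$psi)[2])
  for (i in seq_len(nt - 1L))
    th <- th + sqrt(rowSums((ls$psi[i + 1L, , ] - ls$psi[i, , ])^2))
  th
}

#' Surface Jacobian from one-ring areas
#'
#' `sigma(t, x) = a(t, x) / a(0, x)` with `a` the one-ring area around each
#' vertex on the corresponding slice; `sigma(0, .) = 1` exactly.
#'
#' @param ls a [laminar_system()].
#' @return `(T+1) x N` matrix of area ratios.
#' @export
surface_jacobian <- function(ls) {
  nt <- dim(ls$psi)[1]
  a0 <- one_ring_area(layer_surface(ls, 1))
  if (any(a0 <= 0)) stop("zero initial one-ring area")
  out <- matrix(0, nt, dim(ls$psi)[2])
  out[1, ] <- 1
  for (i in 2:nt) out[i, ] <- one_ring_area(layer_surface(ls, i)) / a0
  out
}

#' Surface Jacobian by cofactor transport along streamlines
#'
#' Independent estimator of the area ratio using the whole-space flow: with
#' `F = dphi/dx`, the vector `zeta = det(F) F^{-T} nu0` satisfies
#' `d zeta/dt = div(v) zeta - (Dv)' zeta` along streamlines, and
#' `sigma = |zeta|` (the initial `nu0` being the unit vertex normal).
#' The transport is integrated with RK4 using the exact analytic kernel
#' Jacobians; no mesh areas are involved.
#'
#' @param result a `registration_result`.
#' @param substeps RK4 sub-steps per registration time step.
#' @param literal_form integrate the non-conservative variant
#'   `d zeta/dt = div(v) - (Dv) zeta` instead (debugging aid; not the
#'   cofactor transport).
#' @return `(T+1) x N` matrix of `sigma` values on the registration grid.
#' @export
surface_jacobian_transport <- function(result, substeps = 4L,
                                       literal_form = FALSE) {
  n0 <- vertex_normals(result$S0)
  T <- dim(result$alpha)[1]
  spec <- result$flow_kernel
  vfun <- function(t_step, x)
    kernel_field(spec, result$q[t_step, , ],
                 matrix(result$alpha[t_step, , ], ncol = 3), x)
  jfun <- function(t_step, x)
    kernel_field_jacobian(spec, result$q[t_step, , ],
                          matrix(result$alpha[t_step, , ], ncol = 3), x)
  y <- result$S0$vertices
  zeta <- n0
  out <- matrix(0, T + 1L, nrow(y))
  out[1, ] <- 1
  h <- 1 / (T * substeps)
  for (t in seq_len(T)) {
    rhs <- function(state) {
      J <- jfun(t, state$y)
      dv <- J[1, 1, ] + J[2, 2, ] + J[3, 3, ]
      Jtz <- jt_apply(J, state$z, transpose = !literal_form)
      dz <- if (literal_form) dv - Jtz else dv * state$z - Jtz
      list(y = vfun(t, state$y), z = dz)
    }
    for (s in seq_len(substeps)) {
      st <- list(y = y, z = zeta)
      k1 <- rhs(st)
      k2 <- rhs(list(y = y + h / 2 * k1$y, z = zeta + h / 2 * k1$z))
      k3 <- rhs(list(y = y + h / 2 * k2$y, z = zeta + h / 2 * k2$z))
      k4 <- rhs(list(y = y + h * k3$y, z = zeta + h * k3$z))
      y <- y + h / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
      zeta <- zeta + h / 6 * (k1$z + 2 * k2$z + 2 * k3$z + k4$z)
    }
    if (any(!is.finite(zeta))) stop("non-finite transport at step ", t)
    out[t + 1L, ] <- sqrt(rowSums(zeta^2))
  }
  out
}

# apply J (3 x 3 x n, optionally transposed) rowwise to z (n x 3)
jt_apply <- function(J, z, transpose = TRUE) {
  out <- matrix(0, nrow(z), 3)
  for (a in 1:3) for (b in 1:3) {
    Jab <- if (transpose) J[b, a, ] else J[a, b, ]
    out[, a] <- out[, a] + Jab * z[, b]
  }
  out
}

#' Cofactor transport of a generic flow field
#'
#' Same transport as [surface_jacobian_transport()] but for a user-supplied
#' analytic field: `v(t, x)` and its spatial Jacobian. Useful for verifying
#' the estimator against closed-form diffeomorphisms (e.g. uniform scaling,
#' where `sigma = s(t)^2`).
#'
#' @param vfun function `(t, x)` returning the `n x 3` field at rows of `x`.
#' @param jfun function `(t, x)` returning the `3 x 3 x n` spatial Jacobian.
#' @param X `n x 3` starting points.
#' @param nu0 `n x 3` initial unit normals.
#' @param times increasing time grid.
#' @param substeps RK4 sub-steps per grid interval.
#' @return `length(times) x n` matrix of `sigma = |zeta|`.
#' @export
zeta_transport <- function(vfun, jfun, X, nu0, times, substeps = 4L) {
  y <- X; zeta <- nu0
  out <- matrix(0, length(times), nrow(X))
  out[1, ] <- sqrt(rowSums(nu0^2))
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1L] - times[i]) / substeps
    t0 <- times[i]
    for (s in seq_len(substeps)) {
      ts <- t0 + (s - 1) * h
      rhs <- function(t, yy, zz) {
        J <- jfun(t, yy)
        dv <- J[1, 1, ] + J[2, 2, ] + J[3, 3, ]
        list(y = vfun(t, yy), z = dv * zz - jt_apply(J, zz, TRUE))
      }
      k1 <- rhs(ts, y, zeta)
      k2 <- rhs(ts + h / 2, y + h / 2 * k1$y, zeta + h / 2 * k1$z)
      k3 <- rhs(ts + h / 2, y + h / 2 * k2$y, zeta + h / 2 * k2$z)
      k4 <- rhs(ts + h, y + h * k3$y, zeta + h * k3$z)
      y <- y + h / 6 * (k1$y + 2 * k2$y + 2 * k3$y + k4$y)
      zeta <- zeta + h / 6 * (k1$z + 2 * k2$z + 2 * k3$z + k4$z)
    }
    out[i + 1L, ] <- sqrt(rowSums(zeta^2))
  }
  out
}

#' Equivolumetric depth along streamlines
#'
#' `gamma(t, x) = int_0^t (d psi/dt . n) sigma du`, the cumulative volume
#' swept per unit reference area (mm). Trapezoidal quadrature on the time
#' grid; when the system carries analytic velocities those are used,
#' otherwise the quadrature is applied to the slice-to-slice displacements.
#'
#' @param ls a [laminar_system()].
#' @param sigma `(T+1) x N` matrix from [surface_jacobian()] (computed if
#'   missing).
#' @return `(T+1) x N` matrix with `gamma(0, .) = 0`.
#' @export
equivol_depth <- function(ls, sigma = NULL) {
  if (is.null(sigma)) sigma <- surface_jacobian(ls)
  nt <- dim(ls$psi)[1]
  gam <- matrix(0, nt, dim(ls$psi)[2])
  use_vel <- !is.null(ls$velocities) &&
    identical(ls$velocity_source, "supplied")
  if (use_vel) {
    f <- sapply(seq_len(nt), function(i)
      rowSums(ls$velocities[i, , ] * ls$normals[i, , ]) * sigma[i, ])
    for (i in 2:nt)
      gam[i, ] <- gam[i - 1L, ] +
        (ls$times[i] - ls$times[i - 1L]) * (f[, i - 1L] + f[, i]) / 2
  } else {
    for (i in 2:nt) {
      disp <- ls$psi[i, , ] - ls$psi[i - 1L, , ]
      fl <- rowSums(disp * ls$normals[i - 1L, , ]) * sigma[i - 1L, ]
      fr <- rowSums(disp * ls$normals[i, , ]) * sigma[i, ]
      gam[i, ] <- gam[i - 1L, ] + (fl + fr) / 2
    }
  }
  gam
}

#' Equivolumetric time change
#'
#' `c0(x) = gamma(1, x)` (the total equivolumetric thickness) and the
#' relative volumetric depth `tau(t, x) = gamma(t, x) / c0(x)`, which is the
#' space-dependent time change making layers equivolumetric:
#' `tau(0, .) = 0` and `tau(1, .) = 1` exactly.
#'
#' @param gamma `(T+1) x N` matrix from [equivol_depth()].
#' @return list with `c0` (vector) and `tau` (`(T+1) x N` matrix).
#' @export
time_change <- function(gamma) {
  nt <- nrow(gamma)
  c0 <- gamma[nt, ]
  if (any(c0 <= 0))
    stop("non-positive equivolumetric thickness (backtracking flow) at vertex ",
         which(c0 <= 0)[1])
  tau <- sweep(gamma, 2, c0, `/`)
  tau[1, ] <- 0
  tau[nt, ] <- 1
  list(c0 = c0, tau = tau)
}

# piecewise-linear inversion: for each vertex the first t with tau = eps.
# Stalled segments (zero tau increment) resolve to the left endpoint.
invert_tau <- function(ls, tau, eps, tol = 1e-9) {
  nt <- dim(ls$psi)[1]; nv <- dim(ls$psi)[2]
  if (eps < 0 || eps > 1) stop("level must be in [0, 1]")
  bad <- which(apply(tau, 2, function(cc) any(diff(cc) < -tol)))
  if (length(bad))
    stop("non-monotone tau at vertex/vertices ",
         paste(utils::head(bad, 5), collapse = ", "))
  out <- matrix(0, nv, 3)
  tstar <- numeric(nv)
  for (k in seq_len(nv)) {
    ck <- tau[, k]
    if (eps <= 0) { i <- 1L; lam <- 0 }
    else if (eps >= 1) { i <- nt - 1L; lam <- 1 }
    else {
      i <- which(ck[-1] >= eps - tol)[1]
      if (is.na(i)) i <- nt - 1L
      dc <- ck[i + 1L] - ck[i]
      lam <- if (dc <= tol) 0 else (eps - ck[i]) / dc
      lam <- min(max(lam, 0), 1)
    }
    out[k, ] <- (1 - lam) * ls$psi[i, k, ] + lam * ls$psi[i + 1L, k, ]
    tstar[k] <- (1 - lam) * ls$times[i] + lam * ls$times[i + 1L]
  }
  list(points = out, tstar = tstar)
}

#' Extract an equivolumetric layer
#'
#' Finds, along each streamline, the point where the relative volumetric
#' depth equals `eps` (piecewise-linear inversion of `tau` over the time
#' grid, linear interpolation of positions) and returns the layer mesh with
#' the reference topology. `eps = 0` returns the inner slice, `eps = 1` the
#' outer slice.
#'
#' @param ls a [laminar_system()].
#' @param tau `(T+1) x N` matrix from [time_change()].
#' @param eps level in `[0, 1]`.
#' @return a [triangulated_surface()] with attribute `tstar` (the
#'   per-vertex original time parameter of the extracted points).
#' @export
extract_equivol_layer <- function(ls, tau, eps) {
  inv <- invert_tau(ls, tau, eps)
  surf <- triangulated_surface(inv$points, ls$faces,
                               name = sprintf("equivol_%g", eps),
                               validate = FALSE)
  attr(surf, "tstar") <- inv$tstar
  surf
}

#' Reparametrize a laminar system to equivolumetric time
#'
#' Resamples every streamline at the `tau`-levels `0, 1/L, ..., 1`. The
#' streamlines as point sets are unchanged (points move along them); the
#' layers of the resampled system are equivolumetric. Normality of
#' streamlines to the new layers, if present before, is generally lost.
#'
#' @param ls a [laminar_system()].
#' @param tau `(T+1) x N` matrix from [time_change()].
#' @param levels either an integer `L` (number of intervals) or a vector of
#'   levels starting at 0 and ending at 1.
#' @return a [laminar_system()] on the level grid.
#' @export
reparametrize <- function(ls, tau, levels = dim(ls$psi)[1] - 1L) {
  lv <- if (length(levels) == 1L) seq(0, 1, length.out = levels + 1L)
        else as.numeric(levels)
  psi <- array(0, c(length(lv), dim(ls$psi)[2], 3))
  for (j in seq_along(lv))
    psi[j, , ] <- invert_tau(ls, tau, lv[j])$points
  laminar_system(ls$faces, psi, lv, velocities = NULL,
                 name = paste0(ls$name, "_equivol"),
                 check_embedding = FALSE)
}

#' Per-streamline depth table
#'
#' Long-format table of the laminar fields: one row per (vertex, time node)
#' with `t`, `tau`, `gamma`, `sigma`, plus per-vertex `theta` and `c0`.
#'
#' @param ls a [laminar_system()].
#' @param sigma,gamma,tau optional precomputed fields (computed if missing).
#' @return a data.frame.
#' @export
streamline_table <- function(ls, sigma = NULL, gamma = NULL, tau = NULL) {
  if (is.null(sigma)) sigma <- surface_jacobian(ls)
  if (is.null(gamma)) gamma <- equivol_depth(ls, sigma)
  if (is.null(tau)) tau <- time_change(gamma)$tau
  th <- thickness(ls)
  c0 <- gamma[nrow(gamma), ]
  nt <- dim(ls$psi)[1]; nv <- dim(ls$psi)[2]
  data.frame(vertex = rep(seq_len(nv), each = nt),
             t = rep(ls$times, nv),
             tau = as.vector(tau),
             gamma = as.vector(gamma),
             sigma = as.vector(sigma),
             theta = rep(th, each = nt),
             c0 = rep(c0, each = nt))
}
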