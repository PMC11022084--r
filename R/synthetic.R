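#' Phantom specification
#'
#' A deterministic description of a synthetic surface pair with analytic
#' ground truth. Kinds: `concentric_spheres` (radial laminae),
#' `ring_pair` (a torus-like inner tube of constant cross-section radius and
#' an outer tube of angle-dependent radius, i.e. variable thickness),
#' `wavy_shell` (an open folded sheet and its normal offset, the idealized
#' gyrus/sulcus geometry), and `flat_slab` (two parallel square sheets, the
#' degenerate flat limit where equivolumetric and equidistant laminae
#' coincide).
#'
#' @param kind one of `"concentric_spheres"`, `"ring_pair"`, `"wavy_shell"`,
#'   `"flat_slab"`.
#' @param ... geometric parameters passed to the generator (see the
#'   individual generator documentation).
#' @param jitter optional uniform vertex jitter amplitude (default 0, exact
#'   analytic geometry).
#' @param seed RNG seed used only when `jitter > 0`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("concentric_spheres", "ring_pair",
                                  "wavy_shell", "flat_slab"),
                         ..., jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...), jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the surface pair described by a phantom spec
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `S0` and `S1` ([triangulated_surface()]s) and
#'   the `spec` echoed back.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  pair <- switch(spec$kind,
    concentric_spheres = do.call(concentric_spheres, spec$params),
    ring_pair = do.call(ring_pair, spec$params),
    wavy_shell = do.call(wavy_shell, spec$params),
    flat_slab = do.call(flat_slab, spec$params))
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    for (nm in c("S0", "S1")) {
      v <- pair[[nm]]$vertices
      v <- v + matrix(stats::runif(length(v), -spec$jitter, spec$jitter),
                      ncol = 3)
      pair[[nm]] <- with_vertices(pair[[nm]], v)
    }
  }
  pair$spec <- spec
  pair
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivision` times, vertices projected to the
#' sphere of radius `radius` about `center`; outward counterclockwise
#' winding.
#'
#' @param radius sphere radius.
#' @param subdivision number of 4-to-1 refinements (0 = icosahedron,
#'   3 = 642 vertices, 4 = 2562 vertices).
#' @param center length-3 center.
#' @return a [triangulated_surface()].
#' @export
icosphere <- function(radius = 1, subdivision = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- 1L + rbind(
    c(0, 11, 5), c(0, 5, 1), c(0, 1, 7), c(0, 7, 10), c(0, 10, 11),
    c(1, 5, 9), c(5, 11, 4), c(11, 10, 2), c(10, 7, 6), c(7, 1, 8),
    c(3, 9, 4), c(3, 4, 2), c(3, 2, 6), c(3, 6, 8), c(3, 8, 9),
    c(4, 9, 5), c(2, 4, 11), c(6, 2, 10), c(8, 6, 7), c(9, 8, 1))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivision)) {
    res <- subdivide_mesh(v, f)
    v <- res$v / sqrt(rowSums(res$v^2))
    f <- res$f
  }
  v <- v * radius
  v <- sweep(v, 2, center, `+`)
  surf <- triangulated_surface(v, f, name = sprintf("icosphere_r%g", radius))
  ensure_outward(surf, center)
}

# 4-to-1 loop-style midpoint subdivision with edge-midpoint deduplication
subdivide_mesh <- function(v, f) {
  nv <- nrow(v)
  edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  uk <- unique(ekey)
  mid_idx <- nv + match(ekey, uk)
  ue <- edges[!duplicated(ekey), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  m12 <- mid_idx[seq_len(nrow(f))]
  m23 <- mid_idx[nrow(f) + seq_len(nrow(f))]
  m31 <- mid_idx[2 * nrow(f) + seq_len(nrow(f))]
  fnew <- rbind(cbind(f[, 1], m12, m31),
                cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23),
                cbind(m12, m23, m31))
  list(v = rbind(v, mids), f = fnew)
}

# flip winding if the signed volume about `center` is negative
ensure_outward <- function(surf, center = c(0, 0, 0)) {
  v <- sweep(surf$vertices, 2, center, `-`)
  cr <- face_cross(with_vertices(surf, v))
  c0 <- face_centers(with_vertices(surf, v))
  vol <- sum(rowSums(c0 * cr)) / 6
  if (vol < 0) reverse_orientation(surf) else surf
}

#' Concentric-sphere phantom
#'
#' Two concentric icospheres of radii `r0 < r1` with identical topology and
#' outward winding. The radial laminar system between them has closed-form
#' thickness `r1 - r0`, surface Jacobian `(r/r0)^2`, equivolumetric depth
#' `(r^3 - r0^3)/(3 r0^2)`, and equivolumetric level-`eps` layer radius
#' `(r0^3 + eps (r1^3 - r0^3))^(1/3)`.
#'
#' @param r0,r1 inner and outer radii, `0 < r0 < r1`.
#' @param subdivision icosphere subdivision level.
#' @return list with `S0`, `S1`.
#' @export
concentric_spheres <- function(r0 = 1, r1 = 2, subdivision = 3) {
  if (!(r0 > 0 && r1 > r0)) stop("need 0 < r0 < r1")
  S0 <- icosphere(r0, subdivision)
  S1 <- icosphere(r1, subdivision)
  S0$name <- "inner_sphere"; S1$name <- "outer_sphere"
  list(S0 = S0, S1 = S1)
}

#' Ring-pair phantom (inner tube of fixed radius, outer of variable radius)
#'
#' Torus-like tubes around the circle of radius `ring_radius` in the
#' xy-plane. The inner tube has constant cross-section radius `tube_r0`; the
#' outer tube's cross-section radius varies with the ring angle `phi` via
#' `profile(phi)` (default a single-harmonic cosine), so the radial gap
#' `profile(phi) - tube_r0` is the analytic thickness per angle.
#'
#' @param tube_r0 inner tube cross-section radius.
#' @param profile function of the ring angle, `profile(phi) > tube_r0`;
#'   default `0.3 + 0.1 cos(phi)`.
#' @param ring_radius radius of the center circle.
#' @param n_ring,n_tube grid resolution along the ring / around the tube.
#' @return list with `S0`, `S1`.
#' @export
ring_pair <- function(tube_r0 = 0.15,
                      profile = function(phi) 0.3 + 0.1 * cos(phi),
                      ring_radius = 1, n_ring = 48, n_tube = 24) {
  phi <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  rout <- profile(phi)
  if (any(rout <= tube_r0))
    stop("profile must stay above tube_r0 everywhere")
  S0 <- torus_mesh(ring_radius, rep(tube_r0, n_ring), phi, n_tube,
                   name = "inner_ring")
  S1 <- torus_mesh(ring_radius, rout, phi, n_tube, name = "outer_ring")
  list(S0 = S0, S1 = S1)
}

torus_mesh <- function(R, tube_r, phi, n_tube, name = "torus") {
  n_ring <- length(phi)
  theta <- 2 * pi * (seq_len(n_tube) - 1) / n_tube
  idx <- function(i, j) (i - 1L) * n_tube + j   # i: ring, j: tube
  v <- matrix(0, n_ring * n_tube, 3)
  for (i in seq_len(n_ring)) {
    r <- tube_r[i]
    v[idx(i, seq_len(n_tube)), ] <-
      cbind((R + r * cos(theta)) * cos(phi[i]),
            (R + r * cos(theta)) * sin(phi[i]),
            r * sin(theta))
  }
  f <- matrix(0L, 2 * n_ring * n_tube, 3)
  k <- 1L
  for (i in seq_len(n_ring)) {
    i2 <- if (i == n_ring) 1L else i + 1L
    for (j in seq_len(n_tube)) {
      j2 <- if (j == n_tube) 1L else j + 1L
      a <- idx(i, j); b <- idx(i2, j); c <- idx(i2, j2); d <- idx(i, j2)
      f[k, ] <- c(a, b, c); f[k + 1L, ] <- c(a, c, d)
      k <- k + 2L
    }
  }
  surf <- triangulated_surface(v, f, name = name)
  # orient outward: positive signed volume... a torus encloses its interior
  ensure_outward(surf)
}

#' Wavy-shell phantom (open folded sheet and its normal offset)
#'
#' Inner sheet `z = A sin(2 pi f x)` over the square `[0, L]^2`, outer sheet
#' offset by `h` along the inner unit normals (upward orientation). Crests
#' ("gyral crowns") have sphere-like curvature with respect to the upward
#' normal (`H < 0` in this package's convention) and troughs ("sulcal
#' fundi") the opposite sign, so the pair supports qualitative
#' equivolumetric (Bok) checks on an open geometry.
#'
#' @param amplitude fold amplitude `A` (>= 0).
#' @param frequency folds per unit length `f`.
#' @param separation offset distance `h > 0`.
#' @param side patch side length `L`.
#' @param nx,ny grid resolution.
#' @return list with `S0`, `S1`.
#' @export
wavy_shell <- function(amplitude = 0.15, frequency = 0.5, separation = 0.4,
                       side = 2, nx = 40, ny = 20) {
  if (amplitude < 0 || separation <= 0) stop("need amplitude >= 0, separation > 0")
  k <- 2 * pi * frequency
  kap_max <- amplitude * k^2      # max curvature of the graph, at crests
  if (kap_max * separation >= 1)
    stop("fold self-intersection: amplitude * (2 pi f)^2 * separation >= 1")
  g <- grid_sheet(side, side, nx, ny)
  x <- g$v[, 1]
  z <- amplitude * sin(k * x)
  gp <- amplitude * k * cos(k * x)
  nrm <- sqrt(1 + gp^2)
  n <- cbind(-gp / nrm, 0, 1 / nrm)
  v0 <- cbind(x, g$v[, 2], z)
  v1 <- v0 + separation * n
  list(S0 = triangulated_surface(v0, g$f, name = "inner_shell"),
       S1 = triangulated_surface(v1, g$f, name = "outer_shell"))
}

#' Flat-slab phantom
#'
#' Two parallel square sheets `z = 0` and `z = height` with identical
#' topology; the vertical-translation laminar system has `theta = height`,
#' `sigma = 1`, `tau(t) = t`, and equivolumetric layers equal to
#' equidistant ones.
#'
#' @param side side length `L`.
#' @param height slab height `h`.
#' @param nx,ny grid resolution.
#' @return list with `S0`, `S1`.
#' @export
flat_slab <- function(side = 1, height = 0.5, nx = 10, ny = 10) {
  if (side <= 0 || height <= 0) stop("need side > 0, height > 0")
  g <- grid_sheet(side, side, nx, ny)
  v0 <- cbind(g$v, 0)
  v1 <- cbind(g$v, height)
  list(S0 = triangulated_surface(v0, g$f, name = "lower_slab"),
       S1 = triangulated_surface(v1, g$f, name = "upper_slab"))
}

# triangulated rectangular grid in the plane, ccw seen from +z
grid_sheet <- function(lx, ly, nx, ny) {
  xs <- seq(0, lx, length.out = nx + 1)
  ys <- seq(0, ly, length.out = ny + 1)
  v <- as.matrix(expand.grid(x = xs, y = ys))
  idx <- function(i, j) (j - 1L) * (nx + 1L) + i
  f <- matrix(0L, 2L * nx * ny, 3)
  k <- 1L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- idx(i, j); b <- idx(i + 1L, j); c <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
    f[k, ] <- c(a, b, c); f[k + 1L, ] <- c(a, c, d)
    k <- k + 2L
  }
  list(v = v, f = f)
}
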