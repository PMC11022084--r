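test_that("icospheres match analytic area with outward winding", {
  s <- icosphere(1, 4)
  expect_lt(abs(surface_area(s) - 4 * pi) / (4 * pi), 0.01)
  n <- vertex_normals(s)
  expect_true(all(rowSums(n * s$vertices) > 0))
  p <- concentric_spheres(1, 2, 2)
  gaps <- sqrt(rowSums(p$S1$vertices^2)) - sqrt(rowSums(p$S0$vertices^2))
  expect_equal(gaps, rep(1, nrow(p$S0$vertices)), tolerance = 1e-12)
  expect_error(concentric_spheres(2, 1), "r0 < r1")
})

test_that("ring pair realizes the variable-thickness profile on closed tori", {
  p <- ring_pair()
  expect_equal(euler_characteristic(p$S0), 0L)
  expect_equal(euler_characteristic(p$S1), 0L)
  expect_length(boundary_vertices(p$S1), 0L)
  # constant profile: two concentric tori with constant radial gap
  pc <- ring_pair(tube_r0 = 0.15, profile = function(phi) rep(0.4, length(phi)))
  R <- 1
  d0 <- sqrt((sqrt(pc$S0$vertices[, 1]^2 + pc$S0$vertices[, 2]^2) - R)^2 +
               pc$S0$vertices[, 3]^2)
  d1 <- sqrt((sqrt(pc$S1$vertices[, 1]^2 + pc$S1$vertices[, 2]^2) - R)^2 +
               pc$S1$vertices[, 3]^2)
  expect_equal(d0, rep(0.15, length(d0)), tolerance = 1e-12)
  expect_equal(d1, rep(0.40, length(d1)), tolerance = 1e-12)
  # cosine profile: per-angle tube radius spans [0.2, 0.4]
  pv <- ring_pair(tube_r0 = 0.15,
                  profile = function(phi) 0.3 + 0.1 * cos(phi))
  dv <- sqrt((sqrt(pv$S1$vertices[, 1]^2 + pv$S1$vertices[, 2]^2) - R)^2 +
               pv$S1$vertices[, 3]^2)
  expect_equal(range(dv), c(0.2, 0.4), tolerance = 1e-9)
  expect_error(ring_pair(tube_r0 = 0.35,
                         profile = function(phi) 0.3 + 0.1 * cos(phi)),
               "above tube_r0")
})

test_that("wavy shell offsets along normals and flags its boundary", {
  w <- wavy_shell(0.15, 0.5, 0.4, 2, 24, 12)
  gaps <- sqrt(rowSums((w$S1$vertices - w$S0$vertices)^2))
  expect_equal(gaps, rep(0.4, length(gaps)), tolerance = 1e-12)
  expect_gt(length(boundary_vertices(w$S0)), 0L)
  # flat limit: two parallel planes
  w0 <- wavy_shell(0, 0.5, 0.4, 2, 10, 10)
  expect_equal(unique(round(w0$S0$vertices[, 3], 12)), 0)
  expect_equal(unique(round(w0$S1$vertices[, 3], 12)), 0.4)
  # curvature sign follows the fold: H and -sin(k x) share their sign
  H <- mean_curvature(w$S0)
  bd <- attr(H, "boundary")
  sgn <- -sin(2 * pi * 0.5 * w$S0$vertices[, 1])
  strong <- !bd & abs(sgn) > 0.3
  expect_true(all(sign(H[strong]) == sign(sgn[strong])))
  expect_error(wavy_shell(0.5, 2, 0.5), "self-intersection")
})

test_that("flat slab is exact", {
  p <- flat_slab(1.5, 0.5, 6, 6)
  expect_equal(surface_area(p$S0), 1.5^2, tolerance = 1e-12)
  expect_equal(surface_area(p$S1), 1.5^2, tolerance = 1e-12)
  for (s in list(p$S0, p$S1)) {
    n <- vertex_normals(s)
    expect_equal(n, matrix(rep(c(0, 0, 1), each = nrow(n)), ncol = 3))
  }
})

test_that("generators are deterministic and pass surface validation", {
  spec <- phantom_spec("concentric_spheres", r0 = 1, r1 = 2, subdivision = 2)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$S0$vertices, b$S0$vertices)
  expect_identical(a$S1$faces, b$S1$faces)
  for (kind in c("concentric_spheres", "ring_pair", "wavy_shell",
                 "flat_slab")) {
    pair <- generate_phantom(phantom_spec(kind))
    expect_silent(validate_surface(pair$S0))
    expect_silent(validate_surface(pair$S1))
  }
  # jitter is seed-reproducible
  js <- phantom_spec("flat_slab", jitter = 0.01, seed = 7L)
  expect_identical(generate_phantom(js)$S0$vertices,
                   generate_phantom(js)$S0$vertices)
})
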