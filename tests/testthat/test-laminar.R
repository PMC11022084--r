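test_that("zero-flow registration yields a constant laminar system", {
  r <- identity_registration()
  ls <- build_laminar_system(r)
  for (i in seq_len(dim(ls$psi)[1]))
    expect_equal(ls$psi[i, , ], r$S0$vertices)
  expect_equal(dim(ls$psi)[2], nrow(r$S0$vertices))
  expect_equal(thickness(ls), rep(0, nrow(r$S0$vertices)))
  expect_equal(surface_jacobian_transport(r),
               matrix(1, dim(ls$psi)[1], dim(ls$psi)[2]), tolerance = 1e-12)
})

test_that("thickness is the streamline polyline length", {
  # zig-zag slab streamlines: 3 segments of known lengths
  p <- flat_slab(1, 1, 3, 3)
  nv <- nrow(p$S0$vertices)
  z <- c(0, 0.3, 0.1, 1)
  psi <- array(0, c(4, nv, 3))
  for (i in 1:4) { psi[i, , ] <- p$S0$vertices; psi[i, , 3] <- z[i] }
  ls <- laminar_system(p$S0$faces, psi, c(0, 1/3, 2/3, 1))
  expect_equal(thickness(ls), rep(0.3 + 0.2 + 0.9, nv))
  # concentric spheres: radial closed form r1 - r0
  lsr <- radial_sphere_system(1, 2, 3, 10)
  expect_lt(max(abs(thickness(lsr) - 1)), 0.05)
})

test_that("surface Jacobian: similarity, rigidity, and the radial closed form",
{
  lsr <- radial_sphere_system(1, 2, 2, 5)
  sig <- surface_jacobian(lsr)
  rt <- 1 + lsr$times
  for (i in seq_along(rt))
    expect_equal(sig[i, ], rep(rt[i]^2, ncol(sig)), tolerance = 0.01)
  expect_equal(sig[1, ], rep(1, ncol(sig)))
  # rigid motion: rotating slab slices keep sigma = 1
  p <- flat_slab(1, 1, 4, 4)
  nv <- nrow(p$S0$vertices)
  psi <- array(0, c(5, nv, 3))
  for (i in 1:5) {
    ang <- (i - 1) / 8
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
    psi[i, , ] <- p$S0$vertices %*% t(R)
    psi[i, , 3] <- (i - 1) / 4
  }
  lsrot <- laminar_system(p$S0$faces, psi, seq(0, 1, 0.25))
  expect_equal(surface_jacobian(lsrot),
               matrix(1, 5, nv), tolerance = 1e-12)
})

test_that("cofactor transport matches one-ring areas and closed forms", {
  # uniform scaling flow phi = e^{ct} x: sigma = e^{2ct} = s(t)^2
  cc <- log(1.6)
  S <- icosphere(1, 2)
  vf <- function(t, x) cc * x
  jf <- function(t, x) {
    J <- array(0, c(3, 3, nrow(x)))
    for (a in 1:3) J[a, a, ] <- cc
    J
  }
  sig <- zeta_transport(vf, jf, S$vertices, vertex_normals(S),
                        seq(0, 1, 0.2))
  expect_equal(sig[6, ], rep(1.6^2, nrow(S$vertices)), tolerance = 1e-7)
  # against the one-ring estimator on a real registration
  r <- dilation_registration()
  ls <- build_laminar_system(r, integrator = "rk4")
  s_ring <- surface_jacobian(ls)
  s_tr <- surface_jacobian_transport(r)
  expect_lt(max(abs(s_ring - s_tr) / s_ring), 0.02)
  # the literal (printed) variant is not the cofactor transport
  s_lit <- surface_jacobian_transport(r, literal_form = TRUE)
  expect_gt(max(abs(s_lit - s_ring) / s_ring),
            max(abs(s_tr - s_ring) / s_ring))
})

test_that("equivolumetric depth closed forms", {
  lsr <- radial_sphere_system(1, 2, 3, 10)
  gam <- equivol_depth(lsr)
  expect_equal(gam[1, ], rep(0, ncol(gam)))
  expect_lt(max(abs(gam[11, ] - 7 / 3)) / (7 / 3), 0.02)
  sl <- slab_system(0.5, 1, 6, 10)
  gs <- equivol_depth(sl)
  expect_equal(gs[11, ], rep(0.5, ncol(gs)), tolerance = 1e-12)
  r <- identity_registration()
  expect_equal(max(abs(equivol_depth(build_laminar_system(r)))), 0)
})

test_that("time change normalizes depth and rejects backtracking", {
  sl <- slab_system(0.5, 1, 6, 10)
  tc <- time_change(equivol_depth(sl))
  expect_equal(tc$tau, matrix(rep(sl$times, ncol(tc$tau)), ncol = ncol(tc$tau)),
               tolerance = 1e-12)
  lsr <- radial_sphere_system(1, 2, 3, 10)
  tcr <- time_change(equivol_depth(lsr))
  expect_equal(tcr$tau[11, ], rep(1, ncol(tcr$tau)))
  expect_equal(tcr$tau[1, ], rep(0, ncol(tcr$tau)))
  exact <- ((1 + lsr$times)^3 - 1) / 7
  expect_lt(max(abs(sweep(tcr$tau, 1, exact, `-`))), 1e-3)
  expect_equal(tcr$c0, gamma_final <- equivol_depth(lsr)[11, ])
  # reversed flow: gamma(1) < 0 at every vertex
  bad <- lsr
  bad$psi <- lsr$psi[11:1, , , drop = FALSE]
  bad$velocities <- -lsr$velocities[11:1, , , drop = FALSE]
  bad$normals <- lsr$normals[11:1, , , drop = FALSE]
  expect_error(time_change(equivol_depth(bad)), "backtracking")
})

test_that("layer extraction inverts tau with exact endpoints", {
  lsr <- radial_sphere_system(1, 2, 3, 10)
  tc <- time_change(equivol_depth(lsr))
  expect_equal(extract_equivol_layer(lsr, tc$tau, 0)$vertices,
               lsr$psi[1, , ])
  expect_equal(extract_equivol_layer(lsr, tc$tau, 1)$vertices,
               lsr$psi[11, , ])
  mid <- extract_equivol_layer(lsr, tc$tau, 0.5)
  radii <- sqrt(rowSums(mid$vertices^2))
  expect_lt(abs(mean(radii) - 4.5^(1/3)) / 4.5^(1/3), 0.01)
  # distinct from the equidistant mid-surface at r = 1.5
  expect_gt(mean(radii) - 1.5, 0.1)
  # non-monotone tau is flagged with the offending vertex
  tau_bad <- tc$tau
  tau_bad[5, 3] <- tc$tau[7, 3]
  expect_error(extract_equivol_layer(lsr, tau_bad, 0.5), "vertex")
})

test_that("reparametrization yields equivolumetric layers, identity on slabs",
{
  lsr <- radial_sphere_system(1, 2, 3, 20)
  tc <- time_change(equivol_depth(lsr))
  rp <- reparametrize(lsr, tc$tau, 20)
  expect_lt(as.numeric(equivolume_check(rp)), 1e-3)
  sl <- slab_system(0.5, 1, 6, 10)
  tcs <- time_change(equivol_depth(sl))
  expect_equal(reparametrize(sl, tcs$tau, 10)$psi, sl$psi, tolerance = 1e-12)
})

test_that("extracted layers are stable under time-grid resampling", {
  tc10 <- time_change(equivol_depth(radial_sphere_system(1, 2, 2, 10)))
  tc40 <- time_change(equivol_depth(radial_sphere_system(1, 2, 2, 40)))
  l10 <- extract_equivol_layer(radial_sphere_system(1, 2, 2, 10), tc10$tau, 0.5)
  l40 <- extract_equivol_layer(radial_sphere_system(1, 2, 2, 40), tc40$tau, 0.5)
  expect_lt(mean(abs(sqrt(rowSums(l10$vertices^2)) -
                       sqrt(rowSums(l40$vertices^2)))), 5e-3)
})

test_that("streamline tables carry consistent per-vertex fields", {
  sl <- slab_system(0.5, 1, 4, 5)
  tab <- streamline_table(sl)
  expect_equal(nrow(tab), 6 * nrow(sl$psi[1, , ]))
  expect_equal(unique(tab$theta), 0.5, tolerance = 1e-12)
  expect_equal(unique(tab$c0), 0.5, tolerance = 1e-12)
  expect_equal(tab$tau, tab$t, tolerance = 1e-12)
})
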