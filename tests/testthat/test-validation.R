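test_that("symmetric vertex distance: identity, closed form, permutation invariance",
{
  s <- icosphere(1, 2)
  rep0 <- freesurfer_vertex_distance(s, s)
  expect_equal(rep0$distances, rep(0, nrow(s$vertices)))
  inner <- icosphere(1, 3)
  outer <- icosphere(1.2, 3)
  repd <- freesurfer_vertex_distance(outer, inner)
  expect_lt(max(abs(repd$distances - 0.2)), mean_edge_length(inner))
  # invariance under any permutation of the reference's vertex order
  set.seed(1)
  perm <- sample(nrow(inner$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  inner_p <- triangulated_surface(inner$vertices[perm, ],
                                  matrix(inv[inner$faces], ncol = 3))
  repp <- freesurfer_vertex_distance(outer, inner_p)
  expect_equal(repp$distances, repd$distances, tolerance = 1e-12)
})

test_that("distance CDF is a right-continuous step distribution", {
  s <- icosphere(1, 1)
  rep0 <- freesurfer_vertex_distance(s, s)
  cdf0 <- distance_cdf(rep0, grid = c(0, 0.1))
  expect_equal(cdf0$cdf, c(1, 1))
  outer <- icosphere(1.15, 2)
  repd <- freesurfer_vertex_distance(outer, icosphere(1, 2))
  cdf <- distance_cdf(repd)
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_equal(cdf$cdf[nrow(cdf)], 1)
  med <- stats::median(repd$distances)
  expect_gte(distance_cdf(repd, grid = med)$cdf, 0.5)
})

test_that("area-evolution identity is exact on flat uniform translation", {
  sl <- slab_system(0.5, 1, 8, 10)
  p <- prop1_residual(sl)
  expect_lt(p$rms, 1e-10)
})

test_that("rigid rotation of a sphere satisfies the identity to mesh accuracy",
{
  S <- icosphere(1, 3)
  nv <- nrow(S$vertices)
  nt <- 11
  times <- seq(0, 1, length.out = nt)
  omega <- pi / 4
  psi <- array(0, c(nt, nv, 3))
  vel <- array(0, c(nt, nv, 3))
  for (i in seq_len(nt)) {
    ang <- omega * times[i]
    R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0),
               c(0, 0, 1))
    psi[i, , ] <- S$vertices %*% t(R)
    vel[i, , ] <- cbind(-omega * psi[i, , 2], omega * psi[i, , 1], 0)
  }
  ls <- laminar_system(S$faces, psi, times, velocities = vel)
  p <- prop1_residual(ls)
  # sigma is exactly 1 (isometry); div of the rotation field vanishes
  expect_lt(p$rms, 0.02)
})

test_that("sphere inflation matches the closed form and improves under refinement",
{
  p_coarse <- prop1_residual(inflation_system(3, 10))
  expect_lt(p_coarse$rms_relative, 0.05)
  # spot-check the analytic sides: sigma^-1 dsigma/dt = 2/r(t) = -2 zeta H
  ls <- inflation_system(3, 10)
  sig <- surface_jacobian(ls)
  rts <- 1 + ls$times
  i <- 6
  dsig_exact <- 2 * rts[i]
  expect_lt(abs(mean((sig[i + 1, ] - sig[i - 1, ]) /
                       (ls$times[i + 1] - ls$times[i - 1])) - dsig_exact),
            0.02 * dsig_exact)
})

test_that("equivolume deviation drops after reparametrization on curved phantoms",
{
  for (ls in list(radial_sphere_system(1, 2, 2, 10),
                  wavy_offset_system(nx = 24, ny = 12))) {
    tc <- time_change(equivol_depth(ls))
    before <- as.numeric(equivolume_check(ls))
    after <- as.numeric(equivolume_check(reparametrize(ls, tc$tau)))
    expect_lt(after, before)
    expect_gt(before, 0.01)
  }
  sl <- slab_system(0.5, 1, 6, 10)
  expect_lt(as.numeric(equivolume_check(sl)), 1e-10)
})
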