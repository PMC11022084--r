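test_that("flow energy closed forms", {
  spec <- kernel_spec(0.5)
  q0 <- matrix(c(0, 0, 0), 1, 3)
  a <- array(c(1, 2, 2), c(1, 1, 3))
  expect_equal(flow_energy(array(0, c(4, 1, 3)), q0, spec), 0)
  # T = 1, N = 1: K(q, q) = I so energy = |alpha|^2
  expect_equal(flow_energy(a, q0, spec), 9)
  expect_equal(flow_energy(a * 3, q0, spec), 81)
})

test_that("flow integration closed forms", {
  spec <- kernel_spec(0.5)
  q0 <- matrix(c(1, -1, 0.5), 1, 3)
  T <- 8
  alpha <- array(rep(c(0.2, -0.1, 0.4), each = T), c(T, 1, 3))
  qs <- integrate_flow(q0, alpha, spec)
  # single particle: K(q, q) alpha = alpha, exact straight line under Euler
  expect_equal(qs[T + 1, 1, ], q0[1, ] + c(0.2, -0.1, 0.4),
               tolerance = 1e-14)
  # zero momentum: stationary
  expect_equal(integrate_flow(q0, alpha * 0, spec)[T + 1, 1, ], q0[1, ])
  # two particles separated by 100 widths move independently
  q2 <- rbind(q0, q0 + c(100 * 0.5, 0, 0))
  alpha2 <- array(0, c(T, 2, 3))
  alpha2[, 1, ] <- matrix(rep(c(0.2, 0, 0), each = T), ncol = 3)
  alpha2[, 2, ] <- matrix(rep(c(0, 0.3, 0), each = T), ncol = 3)
  qs2 <- integrate_flow(q2, alpha2, spec)
  expect_equal(qs2[T + 1, 1, ], q2[1, ] + c(0.2, 0, 0), tolerance = 1e-10)
  expect_equal(qs2[T + 1, 2, ], q2[2, ] + c(0, 0.3, 0), tolerance = 1e-10)
})

# plain-loop varifold double sum, independent of the package implementation
brute_varifold <- function(A, B, width) {
  inner <- function(S1, S2) {
    c1 <- face_centers(S1); c2 <- face_centers(S2)
    n1 <- face_normals(S1); n2 <- face_normals(S2)
    a1 <- face_areas(S1); a2 <- face_areas(S2)
    s <- 0
    for (i in seq_len(nrow(c1))) for (j in seq_len(nrow(c2))) {
      k <- exp(-sum((c1[i, ] - c2[j, ])^2) / (2 * width^2))
      s <- s + k * sum(n1[i, ] * n2[j, ])^2 * a1[i] * a2[j]
    }
    s
  }
  inner(A, A) - 2 * inner(A, B) + inner(B, B)
}

test_that("varifold discrepancy matches a brute-force double sum", {
  set.seed(5)
  A <- icosphere(1, 0)
  B <- icosphere(1.2, 0, center = c(0.3, 0.1, -0.2))
  spec <- kernel_spec(0.5)
  expect_equal(varifold_discrepancy(A, B, spec), brute_varifold(A, B, 0.5),
               tolerance = 1e-12)
  expect_equal(varifold_discrepancy(A, A, spec), 0, tolerance = 1e-12)
  expect_equal(varifold_discrepancy(A, B, spec),
               varifold_discrepancy(B, A, spec), tolerance = 1e-12)
})

test_that("far-separated surfaces saturate at the sum of squared norms", {
  A <- icosphere(1, 1)
  B <- icosphere(1, 1, center = c(100, 0, 0))
  spec <- kernel_spec(0.4)
  fa <- lamcoord:::vf_faces(A); fb <- lamcoord:::vf_faces(B)
  nrmA <- lamcoord:::vf_inner(fa, fa, spec)$value
  nrmB <- lamcoord:::vf_inner(fb, fb, spec)$value
  expect_equal(varifold_discrepancy(A, B, spec), nrmA + nrmB,
               tolerance = 1e-12)
})

test_that("objective gradients match finite differences on small instances", {
  set.seed(2)
  S0 <- icosphere(1, 1); S1 <- icosphere(1.4, 1)
  T <- 3; N <- nrow(S0$vertices)
  spec <- kernel_spec(0.5); vs <- kernel_spec(0.5)
  fb <- lamcoord:::vf_faces(S1)
  bb <- lamcoord:::vf_inner(fb, fb, vs)$value
  par <- rnorm(T * N * 3) * 0.3
  for (case in list(list(lam = NULL, mu = NULL, form = "norm"),
                    list(lam = matrix(0.1, T, N), mu = 2.5, form = "norm"),
                    list(lam = matrix(0.1, T, N), mu = 2.5,
                         form = "quadratic"))) {
    obj <- function(p)
      lamcoord:::registration_objective(p, S0$vertices, S0$faces, fb, bb,
                                        spec, vs, 50, T, lam = case$lam,
                                        mu = case$mu, form = case$form)
    r <- obj(par)
    h <- 1e-6
    idx <- sample(length(par), 12)
    for (i in idx) {
      pp <- par; pp[i] <- pp[i] + h
      pm <- par; pm[i] <- pm[i] - h
      fd <- (obj(pp)$value - obj(pm)$value) / (2 * h)
      expect_lt(abs(fd - r$grad[i]) / max(abs(r$grad)), 1e-4)
    }
  }
})

test_that("registering a surface to itself stays at the identity", {
  S0 <- icosphere(1, 1)
  r <- register(S0, S0, registration_config(time_steps = 3))
  expect_lt(r$energy, 1e-10)
  expect_lt(max(abs(r$alpha)), 1e-6)
  expect_equal(r$q[1, , ], S0$vertices)
})

test_that("radial dilation is recovered with large discrepancy reduction", {
  r <- dilation_registration()
  expect_lt(r$discrepancy, 0.01 * r$initial_discrepancy)
  rad <- sqrt(rowSums(r$q[dim(r$q)[1], , ]^2))
  expect_lt(abs(mean(rad) - 1.5), 0.02)
  # accepted objective values never increase
  expect_true(all(diff(r$accepted_trace) <= 0))
})

test_that("translation by half a radius is recovered within a mean edge", {
  S0 <- icosphere(1, 2)
  S1 <- icosphere(1, 2, center = c(0.5, 0, 0))
  # a translation is a global mode: use a flow kernel at the body scale
  cfg <- registration_config(flow_kernel = kernel_spec(1),
                             varifold_kernel = kernel_spec(0.5))
  r <- register(S0, S1, cfg)
  d <- sqrt(rowSums((r$q[dim(r$q)[1], , ] - S1$vertices)^2))
  expect_lt(mean(d), mean_edge_length(S0))
})

test_that("stored momentum reconstructs the trajectories through the kernel field",
{
  r <- dilation_registration()
  T <- dim(r$alpha)[1]
  h <- 1 / T
  for (t in c(1, T)) {
    v <- kernel_field(r$flow_kernel, r$q[t, , ],
                      matrix(r$alpha[t, , ], ncol = 3), r$q[t, , ])
    expect_equal(r$q[t + 1, , ], r$q[t, , ] + h * v, tolerance = 1e-12)
  }
})

test_that("the flow extends off-surface and stays locally invertible", {
  r <- dilation_registration()
  probe <- as.matrix(expand.grid(x = c(-0.6, 0.6), y = c(-0.6, 0.6),
                                 z = c(-0.6, 0.6)))
  path <- transport_points(r, probe)
  expect_true(all(is.finite(path)))
  # FD Jacobian of the end-to-end map at one probe point
  h <- 1e-4
  J <- matrix(0, 3, 3)
  for (b in 1:3) {
    pp <- probe[1, , drop = FALSE]; pp[b] <- pp[b] + h
    pm <- probe[1, , drop = FALSE]; pm[b] <- pm[b] - h
    fp <- transport_points(r, pp)[dim(path)[1], 1, ]
    fm <- transport_points(r, pm)[dim(path)[1], 1, ]
    J[, b] <- (fp - fm) / (2 * h)
  }
  expect_gt(det(J), 0)
})

test_that("a purely normal field has zero normality residual", {
  S0 <- icosphere(1, 2)
  n <- vertex_normals(S0)
  V <- 0.7 * n
  cc <- lamcoord:::constraint_residual(V, n, "norm")
  expect_lt(max(abs(cc)), 1e-12)
  # tangential contamination is detected
  V2 <- V; V2[, 1] <- V2[, 1] + 0.3
  expect_gt(max(abs(lamcoord:::constraint_residual(V2, n, "norm"))), 0.01)
})

test_that("constrained registration of identical surfaces is the identity", {
  S0 <- icosphere(1, 1)
  r <- register_normal(S0, S0, registration_config(time_steps = 3))
  expect_lt(max(abs(r$q[dim(r$q)[1], , ] - S0$vertices)), 1e-6)
  expect_false(r$warning)
})
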