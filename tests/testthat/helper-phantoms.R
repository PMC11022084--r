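# Shared fixtures, generated in code. Expensive registrations are memoised so
# several test files can reuse one run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# unconstrained radial dilation, coarse mesh. Kernel widths are set to the
# phantom's feature scale (radius ~1, gap 0.5): the flow kernel must be wide
# enough that the off-surface field stays smooth between the shells.
dilation_registration <- function() cached_fixture("dilation", {
  p <- concentric_spheres(1, 1.5, subdivision = 2)
  register(p$S0, p$S1,
           registration_config(flow_kernel = kernel_spec(0.4),
                               varifold_kernel = kernel_spec(0.5)))
})

# normality-constrained registration on the main sphere phantom
normal_sphere_registration <- function() cached_fixture("normal_sphere", {
  p <- concentric_spheres(1, 2, subdivision = 3)
  register_normal(p$S0, p$S1)
})

# closed-form laminar systems -------------------------------------------

# psi(t, x) = x * r(t) / r0 with r(t) = r0 + t (r1 - r0)
radial_sphere_system <- function(r0 = 1, r1 = 2, subdivision = 3,
                                 time_steps = 10) {
  S0 <- icosphere(r0, subdivision)
  times <- seq(0, 1, length.out = time_steps + 1)
  nv <- nrow(S0$vertices)
  psi <- array(0, c(length(times), nv, 3))
  vel <- array(0, c(length(times), nv, 3))
  w <- S0$vertices * (r1 - r0) / r0
  for (i in seq_along(times)) {
    psi[i, , ] <- S0$vertices * (r0 + times[i] * (r1 - r0)) / r0
    vel[i, , ] <- w
  }
  laminar_system(S0$faces, psi, times, velocities = vel,
                 name = "radial_spheres")
}

# flat slab translated vertically at constant speed
slab_system <- function(height = 0.5, side = 1, n = 8, time_steps = 10) {
  p <- flat_slab(side, height, n, n)
  times <- seq(0, 1, length.out = time_steps + 1)
  nv <- nrow(p$S0$vertices)
  psi <- array(0, c(length(times), nv, 3))
  vel <- array(0, c(length(times), nv, 3))
  for (i in seq_along(times)) {
    psi[i, , ] <- p$S0$vertices
    psi[i, , 3] <- times[i] * height
    vel[i, , 3] <- height
  }
  laminar_system(p$S0$faces, psi, times, velocities = vel, name = "slab")
}

# open folded sheet offset along its initial normals at constant speed
wavy_offset_system <- function(amplitude = 0.15, frequency = 0.5,
                               separation = 0.4, side = 2, nx = 40, ny = 20,
                               time_steps = 10) {
  p <- wavy_shell(amplitude, frequency, separation, side, nx, ny)
  n0 <- vertex_normals(p$S0)
  times <- seq(0, 1, length.out = time_steps + 1)
  nv <- nrow(p$S0$vertices)
  psi <- array(0, c(length(times), nv, 3))
  vel <- array(0, c(length(times), nv, 3))
  for (i in seq_along(times)) {
    psi[i, , ] <- p$S0$vertices + times[i] * separation * n0
    vel[i, , ] <- separation * n0
  }
  laminar_system(p$S0$faces, psi, times, velocities = vel, name = "wavy")
}

# unit-speed normal inflation of the unit sphere: r(t) = 1 + t
inflation_system <- function(subdivision = 4, time_steps = 20) {
  radial_sphere_system(1, 2, subdivision, time_steps)
}

# zero-momentum registration result (identity flow) for transport tests
identity_registration <- function(subdivision = 1, time_steps = 5) {
  S0 <- icosphere(1, subdivision)
  cfg <- registration_config(time_steps = time_steps,
                             flow_kernel = kernel_spec(0.5),
                             varifold_kernel = kernel_spec(0.5))
  T <- cfg$time_steps; N <- nrow(S0$vertices)
  q <- array(0, c(T + 1, N, 3))
  for (i in seq_len(T + 1)) q[i, , ] <- S0$vertices
  structure(list(q = q, alpha = array(0, c(T, N, 3)), faces = S0$faces,
                 S0 = S0, target_name = S0$name,
                 flow_kernel = cfg$flow_kernel,
                 varifold_kernel = cfg$varifold_kernel, config = cfg,
                 energy = 0, discrepancy = 0, initial_discrepancy = 0,
                 trace = numeric(0), accepted_trace = numeric(0),
                 residuals = NULL, residual_trace = NULL, warning = FALSE),
            class = "registration_result")
}
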