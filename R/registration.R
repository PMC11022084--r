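#' Registration configuration
#'
#' Settings for the kernel-flow surface registration. When `flow_kernel` or
#' `varifold_kernel` is `NULL`, the width defaults to a multiple of the mean
#' inter-surface distance `d` (0.4 d for the flow, 1.0 d for the varifold
#' term, the latter so the matching kernel spans the gap), measured at
#' [register()] time.
#'
#' @param time_steps number of uniform time steps `T` (>= 2 recommended;
#'   >= 1 accepted).
#' @param flow_kernel a [kernel_spec()] for the deformation space, or `NULL`
#'   for the automatic width.
#' @param varifold_kernel a [kernel_spec()] for the spatial part of the
#'   varifold matching term, or `NULL` for the automatic width.
#' @param discrepancy_weight weight of the matching term relative to the
#'   kinetic energy.
#' @param lbfgs list of inner optimizer settings: `memory` (L-BFGS history),
#'   `maxit`, `pgtol`, `factr` (see [stats::optim()]).
#' @param al list of augmented-Lagrangian settings: `mu0` (initial penalty),
#'   `growth` (penalty multiplier when the residual stalls),
#'   `stall_ratio` (required residual decrease factor per outer iteration),
#'   `max_outer`, `tol_rel` (convergence tolerance on the maximum relative
#'   normality residual).
#' @param constraint_form `"norm"` for the residual `|v| - n'v` (zero
#'   exactly when `v = lambda n`, `lambda >= 0`), or `"quadratic"` for the
#'   form `v'v - n'v` (selectable for comparison; not scale-invariant).
#' @param integrator `"euler"` (matches the discrete energy and gradients)
#'   or `"rk4"`.
#' @param seed seed for any randomized initialization; the default momentum
#'   initialization is deterministic (all zeros) and ignores it.
#' @return an object of class `registration_config`.
#' @export
registration_config <- function(time_steps = 10L,
                                flow_kernel = NULL,
                                varifold_kernel = NULL,
                                discrepancy_weight = 100,
                                lbfgs = list(),
                                al = list(),
                                constraint_form = c("norm", "quadratic"),
                                integrator = c("euler", "rk4"),
                                seed = 1L) {
  lb <- utils::modifyList(list(memory = 10L, maxit = 150L,
                               pgtol = 1e-6, factr = 1e7), lbfgs)
  alx <- utils::modifyList(list(mu0 = 1, growth = 10, stall_ratio = 0.25,
                                max_outer = 8L, tol_rel = 5e-3), al)
  stopifnot(time_steps >= 1L, discrepancy_weight > 0)
  structure(list(time_steps = as.integer(time_steps),
                 flow_kernel = flow_kernel,
                 varifold_kernel = varifold_kernel,
                 discrepancy_weight = discrepancy_weight,
                 lbfgs = lb, al = alx,
                 constraint_form = match.arg(constraint_form),
                 integrator = match.arg(integrator),
                 seed = as.integer(seed)),
            class = "registration_config")
}

#' Kinetic (flow) energy of a momentum path
#'
#' Discrete `int_0^1 |v(t)|_V^2 dt` with uniform step `1/T`: the vertex
#' positions are integrated alongside by forward Euler and the quadratic
#' kernel form is summed per step.
#'
#' @param alpha momentum array `T x N x 3`.
#' @param q0 `N x 3` initial vertex positions.
#' @param spec flow [kernel_spec()].
#' @return non-negative scalar.
#' @export
flow_energy <- function(alpha, q0, spec) {
  alpha <- as_momentum(alpha, nrow(q0))
  h <- 1 / dim(alpha)[1]
  q <- q0
  E <- 0
  for (t in seq_len(dim(alpha)[1])) {
    a <- alpha[t, , , drop = TRUE]
    if (is.null(dim(a))) a <- matrix(a, ncol = 3)
    G <- kernel_matrix(spec, q)
    V <- G %*% a
    E <- E + h * sum(a * V)
    q <- q + h * V
  }
  E
}

as_momentum <- function(alpha, N) {
  if (is.matrix(alpha)) alpha <- array(alpha, c(1, dim(alpha)))
  if (length(dim(alpha)) != 3L || dim(alpha)[2] != N || dim(alpha)[3] != 3L)
    stop("momentum must be a T x N x 3 array matching the vertex count")
  if (any(!is.finite(alpha))) stop("non-finite momentum entries")
  alpha
}

#' Integrate the reduced point flow
#'
#' Solves `dq(t,k)/dt = sum_l K(q(t,k), q(t,l)) alpha(t,l)` from `q(0) = q0`
#' over the uniform time grid carried by `alpha`. `"euler"` matches the
#' discrete energy; `"rk4"` treats the field as autonomous within each step
#' (the momentum is piecewise constant in time).
#'
#' @inheritParams flow_energy
#' @param integrator `"euler"` or `"rk4"`.
#' @return `(T+1) x N x 3` array of trajectories.
#' @export
integrate_flow <- function(q0, alpha, spec,
                           integrator = c("euler", "rk4")) {
  integrator <- match.arg(integrator)
  alpha <- as_momentum(alpha, nrow(q0))
  T <- dim(alpha)[1]; N <- nrow(q0)
  h <- 1 / T
  qs <- array(0, c(T + 1L, N, 3))
  qs[1, , ] <- q0
  q <- q0
  for (t in seq_len(T)) {
    a <- matrix(alpha[t, , ], ncol = 3)
    f <- function(x) kernel_matrix(spec, x) %*% a
    if (integrator == "euler") {
      q <- q + h * f(q)
    } else {
      k1 <- f(q); k2 <- f(q + h / 2 * k1)
      k3 <- f(q + h / 2 * k2); k4 <- f(q + h * k3)
      q <- q + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (any(!is.finite(q))) stop("flow diverged at step ", t)
    qs[t + 1L, , ] <- q
  }
  qs
}

## ------------------------------------------------------------ varifold

# face-based quantities for the varifold representation
vf_faces <- function(surf) {
  list(c = face_centers(surf), N = face_cross(surf))
}

# scalar kernel and its radial-derivative factor from one distance matrix:
# K = mean_w exp(-d2 / 2w^2), C = mean_w exp(-d2 / 2w^2) / w^2
# (grad_x k(x, y) = -C * (x - y))
kernel_KC <- function(spec, x, y = x) {
  d2 <- pdist2(x, y)
  K <- 0; C <- 0
  for (w in spec$width) {
    E <- exp(-d2 / (2 * w^2))
    K <- K + E
    C <- C + E / w^2
  }
  nw <- length(spec$width)
  list(K = K / nw, C = C / nw)
}

# one-sided inner product <A, B> over face lists, optionally with the
# gradient with respect to A's centers and (un-normalized) normals
vf_inner <- function(fa, fb, spec, grad = FALSE) {
  kc <- kernel_KC(spec, fa$c, fb$c)
  K <- kc$K
  nA <- sqrt(rowSums(fa$N^2)); nB <- sqrt(rowSums(fb$N^2))
  dotNN <- tcrossprod(fa$N, fb$N)
  W <- sweep(dotNN^2 / (4 * nA), 2, nB, `/`)
  val <- sum(K * W)
  if (!grad) return(list(value = val))
  CW <- kc$C * W
  g_c <- -(rowSums(CW) * fa$c - CW %*% fb$c)
  KD <- K * dotNN
  g_N <- (KD %*% (fb$N / nB)) / (2 * nA) -
    fa$N * (rowSums(sweep(K * dotNN^2, 2, nB, `/`)) / (4 * nA^3))
  list(value = val, g_c = g_c, g_N = g_N)
}

#' Varifold discrepancy between two oriented surfaces
#'
#' Squared kernel-varifold distance using face centers, areas and unit
#' normals: the spatial kernel is (sum-of-)Gaussian and the orientation
#' kernel is `(n' n2)^2`, so the measure is insensitive to the surfaces'
#' parametrizations. Zero iff the two varifolds coincide; symmetric.
#'
#' @param A,B [triangulated_surface()]s (vertex counts may differ).
#' @param spec spatial [kernel_spec()].
#' @return non-negative scalar.
#' @export
varifold_discrepancy <- function(A, B, spec) {
  if (nrow(A$faces) == 0L || nrow(B$faces) == 0L) stop("empty mesh")
  fa <- vf_faces(A); fb <- vf_faces(B)
  vf_inner(fa, fa, spec)$value - 2 * vf_inner(fa, fb, spec)$value +
    vf_inner(fb, fb, spec)$value
}

# value and gradient of D(A, B) with respect to A's vertex positions;
# B enters through precomputed face quantities
vf_grad_vertices <- function(vertsA, facesA, fb, bb_self, spec) {
  A <- triangulated_surface(vertsA, facesA, validate = FALSE)
  fa <- vf_faces(A)
  aa <- vf_inner(fa, fa, spec, grad = TRUE)
  ab <- vf_inner(fa, fb, spec, grad = TRUE)
  val <- aa$value - 2 * ab$value + bb_self
  g_c <- 2 * aa$g_c - 2 * ab$g_c     # <A,A> is quadratic in A: factor 2
  g_N <- 2 * aa$g_N - 2 * ab$g_N
  grad <- matrix(0, nrow(vertsA), 3)
  f <- facesA
  # centers: each face vertex receives g_c / 3
  for (j in 1:3) {
    s <- rowsum(g_c / 3, f[, j])
    rows <- as.integer(rownames(s))
    grad[rows, ] <- grad[rows, ] + s
  }
  # un-normalized normals N = (x1 - x0) x (x2 - x0)
  u <- vertsA[f[, 2], , drop = FALSE] - vertsA[f[, 1], , drop = FALSE]
  v <- vertsA[f[, 3], , drop = FALSE] - vertsA[f[, 1], , drop = FALSE]
  gu <- cross3(v, g_N)
  gv <- cross3(g_N, u)
  for (term in list(list(j = 2L, g = gu), list(j = 3L, g = gv),
                    list(j = 1L, g = -(gu + gv)))) {
    s <- rowsum(term$g, f[, term$j])
    rows <- as.integer(rownames(s))
    grad[rows, ] <- grad[rows, ] + s
  }
  list(value = val, grad = grad)
}

## ------------------------------------------------ objective + adjoint

# gradient wrt q_m of sum_{k,l} S[k,l] k(q_k, q_l)
kq_grad <- function(spec, q, S) {
  kq_grad_C(q, S, kernel_KC(spec, q)$C)
}

# same, with the precomputed radial-derivative factor C
kq_grad_C <- function(q, S, C) {
  M <- (S + t(S)) * C
  -(rowSums(M) * q - M %*% q)
}

# backpropagate a gradient on unit vertex normals to vertex positions
normal_backprop <- function(verts, faces, g_n) {
  surf <- triangulated_surface(verts, faces, validate = FALSE)
  cr <- face_cross(surf)
  acc <- accumulate_faces(surf, cr)
  nrm <- sqrt(rowSums(acc^2))
  n <- acc / nrm
  g_acc <- (g_n - n * rowSums(n * g_n)) / nrm
  f <- faces
  gN <- g_acc[f[, 1], , drop = FALSE] + g_acc[f[, 2], , drop = FALSE] +
    g_acc[f[, 3], , drop = FALSE]
  u <- verts[f[, 2], , drop = FALSE] - verts[f[, 1], , drop = FALSE]
  v <- verts[f[, 3], , drop = FALSE] - verts[f[, 1], , drop = FALSE]
  gu <- cross3(v, gN)
  gv <- cross3(gN, u)
  out <- matrix(0, nrow(verts), 3)
  for (term in list(list(j = 2L, g = gu), list(j = 3L, g = gv),
                    list(j = 1L, g = -(gu + gv)))) {
    s <- rowsum(term$g, f[, term$j])
    rows <- as.integer(rownames(s))
    out[rows, ] <- out[rows, ] + s
  }
  out
}

# normality residual of a velocity field against vertex normals
constraint_residual <- function(V, n, form) {
  vn <- rowSums(V * n)
  if (form == "norm") sqrt(rowSums(V^2)) - vn else rowSums(V^2) - vn
}

# forward pass + objective + full adjoint gradient.
# lam/mu = NULL disables the augmented-Lagrangian terms.
registration_objective <- function(par, q0, faces0, fb, bb_self, spec,
                                   vspec, wD, T, lam = NULL, mu = NULL,
                                   form = "norm", want_grad = TRUE) {
  N <- nrow(q0)
  h <- 1 / T
  alpha <- array(par, c(T, N, 3))
  qs <- array(0, c(T + 1L, N, 3))
  qs[1, , ] <- q0
  Gs <- vector("list", T); Vs <- vector("list", T); Cs <- vector("list", T)
  ns <- vector("list", T); cs <- vector("list", T)
  E <- 0; P <- 0
  q <- q0
  constrained <- !is.null(lam)
  for (t in seq_len(T)) {
    a <- matrix(alpha[t, , ], ncol = 3)
    kc <- kernel_KC(spec, q)
    G <- kc$K
    if (want_grad) Cs[[t]] <- kc$C
    V <- G %*% a
    E <- E + h * sum(a * V)
    if (constrained) {
      n <- vertex_normals(triangulated_surface(q, faces0, validate = FALSE))
      cc <- constraint_residual(V, n, form)
      P <- P + sum(lam[t, ] * cc) + mu / 2 * sum(cc^2)
      ns[[t]] <- n; cs[[t]] <- cc
    }
    Gs[[t]] <- G; Vs[[t]] <- V
    q <- q + h * V
    qs[t + 1L, , ] <- q
  }
  if (any(!is.finite(q)))
    return(list(value = 1e30, grad = rep(0, length(par))))
  dfin <- vf_grad_vertices(qs[T + 1L, , ], faces0, fb, bb_self, vspec)
  J <- E + wD * dfin$value + P
  out <- list(value = J, energy = E, discrepancy = dfin$value,
              qs = qs, residuals = if (constrained) do.call(rbind, cs),
              velocities = Vs)
  if (!want_grad) return(out)
  p <- wD * dfin$grad
  grad <- array(0, c(T, N, 3))
  eps <- 1e-12
  for (t in rev(seq_len(T))) {
    a <- matrix(alpha[t, , ], ncol = 3)
    G <- Gs[[t]]; V <- Vs[[t]]
    qt <- qs[t, , ]
    ga <- 2 * h * V + h * (G %*% p)
    # all q-gradient kernel terms share the factor C: fuse their S matrices
    # (energy h*a a', step h*p a', constraint gV a'; kq_grad_C symmetrizes)
    S_tot <- tcrossprod(h * a + h * p, a)
    if (constrained) {
      n <- ns[[t]]; cc <- cs[[t]]
      gc <- lam[t, ] + mu * cc
      if (form == "norm") {
        vn2 <- pmax(sqrt(rowSums(V^2)), eps)
        dCdV <- V / vn2 - n
      } else {
        dCdV <- 2 * V - n
      }
      gV <- gc * dCdV
      ga <- ga + G %*% gV
      S_tot <- S_tot + tcrossprod(gV, a)
    }
    pq <- kq_grad_C(qt, S_tot, Cs[[t]])
    if (constrained) pq <- pq + normal_backprop(qt, faces0, g_n = -(gc * V))
    grad[t, , ] <- ga
    p <- p + pq
  }
  out$grad <- as.vector(grad)
  out
}

## ------------------------------------------------------------ drivers

mean_intersurface_distance <- function(S0, S1) {
  d2 <- pdist2(S0$vertices, S1$vertices)
  mean(sqrt(apply(d2, 1, min)))
}

resolve_kernels <- function(S0, S1, config) {
  if (is.null(config$flow_kernel) || is.null(config$varifold_kernel)) {
    d <- mean_intersurface_distance(S0, S1)
    if (d == 0) d <- mean_edge_length(S0)
    if (is.null(config$flow_kernel))
      config$flow_kernel <- kernel_spec(0.4 * d)
    # the spatial matching kernel must span the inter-surface gap, or
    # shrinking the source can lower the discrepancy instead of matching
    if (is.null(config$varifold_kernel))
      config$varifold_kernel <- kernel_spec(d)
  }
  config
}

run_lbfgs <- function(par0, fngr, lbfgs) {
  cache <- new.env(parent = emptyenv())
  cache$trace <- numeric(0)
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- fngr(par)
    cache$par <- par
    cache$res <- res
    cache$trace <- c(cache$trace, res$value)
    res
  }
  opt <- stats::optim(par0,
                      fn = function(p) eval_at(p)$value,
                      gr = function(p) eval_at(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = lbfgs$maxit, lmm = lbfgs$memory,
                                     pgtol = lbfgs$pgtol, factr = lbfgs$factr))
  list(par = opt$par, value = opt$value, convergence = opt$convergence,
       trace = cache$trace)
}

#' Kernel-flow (LDDMM) surface registration
#'
#' Minimizes `flow energy + weight * varifold discrepancy` over a per-vertex,
#' per-time momentum path using L-BFGS with exact adjoint gradients of the
#' discrete Euler flow. The source and target may have different vertex
#' counts and topologies (the matching term is parametrization-invariant).
#'
#' @param S0,S1 source and target [triangulated_surface()]s.
#' @param config a [registration_config()].
#' @return an object of class `registration_result` with the trajectories
#'   `q` (`(T+1) x N x 3` array), the momentum path `alpha`, kernel specs,
#'   final `energy` and `discrepancy`, the objective `trace`,
#'   the per-evaluation accepted-value envelope `accepted_trace`, and a
#'   `warning` flag on non-convergence.
#' @export
register <- function(S0, S1, config = registration_config()) {
  validate_surface(S0); validate_surface(S1)
  config <- resolve_kernels(S0, S1, config)
  T <- config$time_steps
  N <- nrow(S0$vertices)
  fb <- vf_faces(S1)
  bb_self <- vf_inner(fb, fb, config$varifold_kernel)$value
  fngr <- function(par)
    registration_objective(par, S0$vertices, S0$faces, fb, bb_self,
                           config$flow_kernel, config$varifold_kernel,
                           config$discrepancy_weight, T)
  d0 <- varifold_discrepancy(S0, S1, config$varifold_kernel)
  sol <- run_lbfgs(rep(0, T * N * 3), fngr, config$lbfgs)
  fin <- registration_objective(sol$par, S0$vertices, S0$faces, fb, bb_self,
                                config$flow_kernel, config$varifold_kernel,
                                config$discrepancy_weight, T,
                                want_grad = FALSE)
  new_registration_result(S0, S1, config, sol, fin,
                          initial_discrepancy = d0,
                          residual_trace = NULL,
                          warning = sol$convergence != 0)
}

#' Normality-constrained surface registration
#'
#' As [register()], subject to the per-vertex, per-time-step constraint that
#' the velocity is parallel to the evolving layer normal with non-negative
#' component (streamlines perpendicular to layers, no backtracking). The
#' constraint residual (`|v| - n'v` by default) is driven to zero by an
#' augmented Lagrangian outer loop with L-BFGS inner solves; the evolving
#' normals are recomputed from the deformed triangulation at every time
#' step, and their dependence on the vertex positions is included in the
#' adjoint gradient.
#'
#' @inheritParams register
#' @return a `registration_result`; `residual_trace` holds the maximum
#'   relative normality residual after each outer iteration, and `warning`
#'   is set if the tolerance was not reached.
#' @export
register_normal <- function(S0, S1, config = registration_config()) {
  validate_surface(S0); validate_surface(S1)
  config <- resolve_kernels(S0, S1, config)
  T <- config$time_steps
  N <- nrow(S0$vertices)
  fb <- vf_faces(S1)
  bb_self <- vf_inner(fb, fb, config$varifold_kernel)$value
  d0 <- varifold_discrepancy(S0, S1, config$varifold_kernel)
  al <- config$al
  lam <- matrix(0, T, N)
  mu <- al$mu0
  par <- rep(0, T * N * 3)
  prev_cmax <- Inf
  residual_trace <- numeric(0)
  traces <- numeric(0)
  warn <- TRUE
  eps <- 1e-8
  for (outer in seq_len(al$max_outer)) {
    fngr <- function(p)
      registration_objective(p, S0$vertices, S0$faces, fb, bb_self,
                             config$flow_kernel, config$varifold_kernel,
                             config$discrepancy_weight, T,
                             lam = lam, mu = mu,
                             form = config$constraint_form)
    sol <- run_lbfgs(par, fngr, config$lbfgs)
    par <- sol$par
    traces <- c(traces, sol$trace)
    fin <- registration_objective(par, S0$vertices, S0$faces, fb, bb_self,
                                  config$flow_kernel, config$varifold_kernel,
                                  config$discrepancy_weight, T,
                                  lam = lam, mu = mu,
                                  form = config$constraint_form,
                                  want_grad = FALSE)
    cc <- fin$residuals
    speed <- do.call(rbind, lapply(fin$velocities,
                                   function(V) sqrt(rowSums(V^2))))
    rel <- abs(cc) / pmax(speed, eps)
    cmax_rel <- max(rel)
    cmax_abs <- max(abs(cc))
    residual_trace <- c(residual_trace, cmax_rel)
    if (cmax_rel < al$tol_rel) { warn <- FALSE; break }
    lam <- lam + mu * cc
    if (cmax_abs > al$stall_ratio * prev_cmax) mu <- mu * al$growth
    prev_cmax <- cmax_abs
  }
  sol$trace <- traces
  new_registration_result(S0, S1, config, sol, fin,
                          initial_discrepancy = d0,
                          residual_trace = residual_trace,
                          warning = warn)
}

new_registration_result <- function(S0, S1, config, sol, fin,
                                    initial_discrepancy, residual_trace,
                                    warning) {
  T <- config$time_steps
  N <- nrow(S0$vertices)
  res <- structure(list(
    q = fin$qs,
    alpha = array(sol$par, c(T, N, 3)),
    faces = S0$faces,
    S0 = S0,
    target_name = S1$name,
    flow_kernel = config$flow_kernel,
    varifold_kernel = config$varifold_kernel,
    config = config,
    energy = fin$energy,
    discrepancy = fin$discrepancy,
    initial_discrepancy = initial_discrepancy,
    trace = sol$trace,
    accepted_trace = cummin(sol$trace),
    residuals = fin$residuals,
    residual_trace = residual_trace,
    warning = warning), class = "registration_result")
  res
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(paste0("<registration_result: %d vertices, T = %d, ",
                     "energy %.4g, discrepancy %.4g (initial %.4g)%s>\n"),
              dim(x$q)[2], dim(x$alpha)[1], x$energy, x$discrepancy,
              x$initial_discrepancy,
              if (isTRUE(x$warning)) ", WARNING: not converged" else ""))
  if (!is.null(x$residual_trace))
    cat("  max relative normality residual per outer iteration:",
        paste(signif(x$residual_trace, 3), collapse = " "), "\n")
  invisible(x)
}

#' Transport arbitrary points through a registration flow
#'
#' Advects probe points with the stored time-dependent field
#' `v(t, x) = sum_l K(x, q(t, l)) alpha(t, l)` (piecewise constant in time
#' over the registration's steps, analytic in space). Euler uses one step
#' per stored step; RK4 additionally allows `substeps` per stored step.
#'
#' @param result a `registration_result`.
#' @param X `n x 3` matrix of points.
#' @param integrator `"euler"` or `"rk4"`.
#' @param substeps sub-steps per registration time step (RK4 only).
#' @return `(T * substeps + 1) x n x 3` array of transported positions.
#' @export
transport_points <- function(result, X, integrator = c("rk4", "euler"),
                             substeps = 1L) {
  integrator <- match.arg(integrator)
  T <- dim(result$alpha)[1]
  if (integrator == "euler") substeps <- 1L
  h <- 1 / (T * substeps)
  out <- array(0, c(T * substeps + 1L, nrow(X), 3))
  out[1, , ] <- X
  k <- 1L
  for (t in seq_len(T)) {
    supp <- result$q[t, , ]
    a <- matrix(result$alpha[t, , ], ncol = 3)
    f <- function(x) kernel_matrix(result$flow_kernel, x, supp) %*% a
    for (s in seq_len(substeps)) {
      if (integrator == "euler") {
        X <- X + h * f(X)
      } else {
        k1 <- f(X); k2 <- f(X + h / 2 * k1)
        k3 <- f(X + h / 2 * k2); k4 <- f(X + h * k3)
        X <- X + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      k <- k + 1L
      out[k, , ] <- X
    }
  }
  out
}
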