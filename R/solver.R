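# D-VMS solver: assembly of the stabilized equal-order P1 systems for
# hyperelastodynamics (unknowns v, p) and poroelastodynamics (v, p, m),
# BDF2 time integration with a backward-Euler bootstrap, Newton iteration
# with an element-level finite-difference tangent, and an explicit
# displacement update.
#
# Element residuals are evaluated for all elements at once (E x nld local
# residual matrices); the global Jacobian is assembled from central finite
# differences of the element residual with respect to its own local dofs,
# which reproduces the exact sparsity of the analytic tangent.

# quadrature rules (barycentric coordinates, weights summing to 1)
quad_volume <- function(dim, degree = 2L) {
  if (dim == 2L) {
    if (degree <= 2L)
      list(L = rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)) / 4,
           w = rep(1 / 3, 3))
    else  # Radon degree-5 7-point rule for error integrals
      list(L = rbind(c(1, 1, 1) / 3,
                     c(0.797426985353087, 0.101286507323456, 0.101286507323456),
                     c(0.101286507323456, 0.797426985353087, 0.101286507323456),
                     c(0.101286507323456, 0.101286507323456, 0.797426985353087),
                     c(0.059715871789770, 0.470142064105115, 0.470142064105115),
                     c(0.470142064105115, 0.059715871789770, 0.470142064105115),
                     c(0.470142064105115, 0.470142064105115, 0.059715871789770)),
           w = c(0.225, rep(0.125939180544827, 3), rep(0.132394152788506, 3)))
  } else {
    if (degree <= 2L) {
      a <- 0.5854101966249685; b <- 0.1381966011250105
      list(L = rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a)),
           w = rep(0.25, 4))
    } else {
      # Keast degree-5 15-point rule (all weights positive, sum 1)
      b3 <- 1 / 11; a3 <- 1 - 3 * b3
      b4 <- 0.0665501535736643; c4 <- 0.4334498464263357
      perm31 <- function(a, b) rbind(c(a, b, b, b), c(b, a, b, b),
                                     c(b, b, a, b), c(b, b, b, a))
      perm22 <- function(b, c) rbind(c(b, b, c, c), c(b, c, b, c), c(b, c, c, b),
                                     c(c, b, b, c), c(c, b, c, b), c(c, c, b, b))
      list(L = rbind(c(0.25, 0.25, 0.25, 0.25),
                     perm31(0, 1 / 3),
                     perm31(a3, b3),
                     perm22(b4, c4)),
           w = c(0.1817020685825351,
                 rep(0.0361607142857143, 4),
                 rep(0.0698714945161738, 4),
                 rep(0.0656948493683187, 6)))
    }
  }
}

quad_facet <- function(dim) {
  if (dim == 2L) {  # segment, 2-point Gauss (degree 3)
    g <- 0.5 / sqrt(3)
    list(L = rbind(c(0.5 + g, 0.5 - g), c(0.5 - g, 0.5 + g)), w = c(0.5, 0.5))
  } else {          # triangle, 3-point degree 2
    list(L = rbind(c(2, 1, 1), c(1, 2, 1), c(1, 1, 2)) / 4, w = rep(1 / 3, 3))
  }
}

#' Newton solver settings
#'
#' @param rel_tol relative residual tolerance
#' @param abs_tol absolute residual tolerance (default 0: the residual is
#'   judged relative to the step's own initial norm and the run's
#'   historical scale, so the criterion is invariant to the unit system)
#' @param max_iters maximum Newton iterations per attempted step
#' @param line_search enable backtracking when the residual does not drop
#' @param jacobian_refresh `"step"` rebuilds the tangent once per time step,
#'   `"iteration"` every Newton iteration, `"lazy"` only when convergence
#'   degrades (cheapest for quasi-static phases)
#' @param fd_eps relative step of the element finite-difference tangent
#' @return a `dvms_newton_settings` list
#' @export
newton_settings <- function(rel_tol = 1e-6, abs_tol = 0, max_iters = 12L,
                            line_search = TRUE,
                            jacobian_refresh = c("step", "lazy", "iteration"),
                            fd_eps = 1e-6) {
  stopifnot(rel_tol > 0, abs_tol >= 0, max_iters >= 1L)
  structure(list(rel_tol = rel_tol, abs_tol = abs_tol,
                 max_iters = as.integer(max_iters),
                 line_search = isTRUE(line_search),
                 jacobian_refresh = match.arg(jacobian_refresh),
                 fd_eps = fd_eps),
            class = "dvms_newton_settings")
}

#' Fine-scale velocity of the D-VMS closure
#'
#' v' = -tau (vdot + H grad(p) / rho0s - b), the modelled unresolved
#' velocity inserted into the continuity equation. All inputs element-wise
#' constant; vectorized over elements when given matrices.
#'
#' @param v_dot element acceleration (length-3 vector or E x 3 matrix)
#' @param H cofactor tensor (3x3 matrix or E x 9 batch)
#' @param grad_p pressure gradient (vector or E x 3)
#' @param b body force per unit mass (vector or E x 3)
#' @param tau stabilization time scale (scalar or per element)
#' @param rho0s skeleton reference density
#' @return fine-scale velocity, same shape as `v_dot`
#' @export
fine_scale_velocity <- function(v_dot, H, grad_p, b, tau, rho0s) {
  single <- is.null(dim(v_dot))
  if (is.matrix(H) && nrow(H) == 3L && ncol(H) == 3L) H <- matrix(as.vector(H), 1, 9)
  as_row <- function(x) if (is.null(dim(x))) matrix(x, 1, 3) else x
  v_dot <- as_row(v_dot); grad_p <- as_row(grad_p); b <- as_row(b)
  out <- -tau * (v_dot + bt_mv(H, grad_p) / rho0s - b)
  if (single) drop(out) else out
}

# Problem container ---------------------------------------------------------

#' Define a stabilized elastodynamic / poroelastodynamic problem
#'
#' Bundles the mesh, constitutive models, densities, boundary conditions and
#' stabilization options into a `dvms_problem` that [run_simulation()] and
#' [advance()] operate on.
#'
#' Boundary conditions are keyed by facet tag:
#' \describe{
#'   \item{velocity}{`list(tag = list(comps = 1:dim, value = fun(X, t) | numeric))`;
#'     Dirichlet velocity on the tagged nodes (components selectable)}
#'   \item{traction}{`list(tag = fun(X, t) -> matrix)`; prescribed reference
#'     traction}
#'   \item{follower}{`list(tag = fun(t) -> scalar)`; pressure follower load
#'     -p(t) H n0 integrated on the reference facet}
#'   \item{mass}{`list(tag = fun(X, t) -> vector)`; Dirichlet added mass
#'     (dimensionless), poroelastic problems only}
#'   \item{flux}{`list(tag = fun(X, t) -> vector)`; prescribed normal
#'     perfusion flux W.n (untagged facets are impermeable)}
#'   \item{pin_direction}{`list(tag = list(dir = fun(X) -> matrix, k = stiffness))`;
#'     quadratic penalty suppressing the velocity component along a given
#'     unit direction per tagged node (e.g. circumferential pinning of the
#'     ventricular base)}
#' }
#'
#' @param mesh a `dvms_mesh` with tagged boundary
#' @param problem `"hyper"` or `"poro"`
#' @param model a `dvms_material`
#' @param rho0s skeleton reference density
#' @param frame optional [fibre_frame()] (per element or global)
#' @param active optional [active_model()]
#' @param pore a [pore_fluid_model()] (poro only)
#' @param source a [source_model()], or `function(X, t)` for a prescribed
#'   source field, or `NULL`
#' @param densities [mixture_densities()] (poro only; defaults built from
#'   `rho0s` and the pore model)
#' @param body_force `function(X, t) -> n x 3` acceleration field, or `NULL`
#' @param bcs boundary-condition list as described above
#' @param c_tau stabilization constant (0 disables stabilization)
#' @param tau_state `"current"` refreshes the shear-wave speed each step at
#'   the deformed state; `"reference"` freezes it at the reference state
#' @param compaction_update `"none"` keeps the pore model's compaction scale
#'   fixed; `"history_max"` sets it each step to minus the running maximum
#'   of the spatial peak pore pressure (the drainage-arresting update)
#' @param constraint_relax Baumgarte-style relaxation coefficient chi for
#'   the volumetric constraint: the continuity equation carries an extra
#'   consistent term (chi/dt)(J - 1 [- m]) that pulls the solution back to
#'   the constraint manifold, preventing secular drift of J - 1 = m (or
#'   J = 1) over long runs; 0 disables it (the pure rate form)
#' @param engine `"cpp"` (compiled element kernel, default) or `"r"` (pure-R
#'   reference implementation of the same residual; used as a cross-check)
#' @return a `dvms_problem`
#' @export
dvms_problem <- function(mesh, problem = c("hyper", "poro"), model, rho0s,
                         frame = NULL, active = NULL,
                         pore = NULL, source = NULL, densities = NULL,
                         body_force = NULL, bcs = list(),
                         c_tau = 0.02, tau_state = c("current", "reference"),
                         compaction_update = c("none", "history_max"),
                         constraint_relax = NULL,
                         engine = c("cpp", "r")) {
  problem <- match.arg(problem)
  tau_state <- match.arg(tau_state)
  compaction_update <- match.arg(compaction_update)
  engine <- match.arg(engine)
  # strongly consistent for the incompressible problem (J = 1 is the
  # constraint itself); for poroelasticity the element-vs-nodal mismatch in
  # J - 1 - m makes the 1/dt-scaled term inconsistent at O(h), so the rate
  # form is the default and long-horizon drivers opt in explicitly
  if (is.null(constraint_relax))
    constraint_relax <- if (problem == "hyper") 0.5 else 0
  if (model_needs_frame(model) && is.null(frame))
    dvms_error("this material needs a fibre frame", "dvms_invalid_argument")
  if (identical(model$variant, "holzapfel_ogden") && is.null(frame$s0))
    dvms_error("the Holzapfel-Ogden model needs a sheet direction s0",
               "dvms_invalid_argument")
  if (problem == "poro") {
    if (is.null(pore)) dvms_error("poro problem needs a pore_fluid_model",
                                  "dvms_invalid_argument")
    if (is.null(densities))
      densities <- mixture_densities(rho0s, pore$rho0f, pore$phi0)
  }
  d <- mesh$dim; n <- nvertices(mesh); E <- ncells(mesh); nl <- d + 1L
  geo <- p1_geometry(mesh)
  qv <- quad_volume(d)
  # dof layout: v ((node-1)*d + comp), then p, then mu
  ndof_v <- n * d
  nfield <- if (problem == "poro") d + 2L else d + 1L
  ndof <- n * nfield
  nld <- nl * nfield
  # element-local -> global dof map
  Gmap <- matrix(0L, E, nld)
  for (a in seq_len(nl)) {
    nodes <- mesh$cells[, a]
    for (i in seq_len(d)) Gmap[, (a - 1L) * d + i] <- (nodes - 1L) * d + i
    Gmap[, nl * d + a] <- ndof_v + nodes
    if (problem == "poro") Gmap[, nl * d + nl + a] <- ndof_v + n + nodes
  }
  # volume quad point coordinates per element (list over q of E x d)
  Xq <- lapply(seq_along(qv$w), function(q) {
    out <- 0
    for (a in seq_len(nl)) out <- out + qv$L[q, a] * mesh$vertices[mesh$cells[, a], , drop = FALSE]
    out
  })
  # boundary facet data: owner element, local vertex slots, area, outward n0
  ft <- facet_table(mesh)
  owner_of <- setNames(ft$owner, ft$key)
  fkey <- apply(t(apply(mesh$facets, 1L, sort)), 1L, paste, collapse = ",")
  fowner <- unname(owner_of[fkey])
  B <- nrow(mesh$facets)
  floc <- matrix(0L, B, d)  # local slot (1..nl) of each facet vertex in owner
  for (f in seq_len(B)) {
    cellv <- mesh$cells[fowner[f], ]
    floc[f, ] <- match(mesh$facets[f, ], cellv)
  }
  # facet measure and outward normal
  fv <- lapply(seq_len(d), function(a) mesh$vertices[mesh$facets[, a], , drop = FALSE])
  if (d == 2L) {
    ev <- fv[[2]] - fv[[1]]
    area <- sqrt(rowSums(ev^2))
    nrm <- cbind(ev[, 2], -ev[, 1]) / area
  } else {
    e1 <- fv[[2]] - fv[[1]]; e2 <- fv[[3]] - fv[[1]]
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- 0.5 * sqrt(rowSums(cr^2))
    nrm <- cr / (2 * area)
  }
  # orient outward: flip normals pointing toward the owner centroid
  cen_cell <- 0
  for (a in seq_len(nl)) cen_cell <- cen_cell + mesh$vertices[mesh$cells[, a], , drop = FALSE] / nl
  cen_f <- 0
  for (a in seq_len(d)) cen_f <- cen_f + fv[[a]] / d
  flip <- rowSums(nrm * (cen_f - cen_cell[fowner, , drop = FALSE])) < 0
  nrm[flip, ] <- -nrm[flip, ]
  qf <- quad_facet(d)
  Xfq <- lapply(seq_along(qf$w), function(q) {
    out <- 0
    for (a in seq_len(d)) out <- out + qf$L[q, a] * fv[[a]]
    out
  })
  # precomputed embedded shape gradients (E x 3) and quadrature mass weights
  Ga3 <- lapply(geo$G, function(Gm) if (d == 3L) Gm else cbind(Gm, 0))
  Gmat <- do.call(cbind, geo$G)  # E x nl*d, column (a-1)*d + j
  Mab <- matrix(0, nl, nl)
  for (q in seq_along(qv$w)) Mab <- Mab + qv$w[q] * (qv$L[q, ] %o% qv$L[q, ])
  frame_b <- NULL
  if (!is.null(frame)) {
    expand <- function(x) {
      if (is.null(x)) return(NULL)
      if (is.null(dim(x))) {
        if (length(x) == 2L) x <- c(x, 0)
        matrix(x, E, 3, byrow = TRUE)
      } else {
        if (ncol(x) == 2L) x <- cbind(x, 0)
        x
      }
    }
    frame_b <- list(f0 = expand(frame$f0), s0 = expand(frame$s0))
    if (is.null(frame_b$s0)) frame_b$s0 <- NULL
  }
  frame_pre <- NULL
  if (!is.null(frame_b)) {
    frame_pre <- list(ff = bt_outer(frame_b$f0, frame_b$f0))
    if (!is.null(frame_b$s0)) {
      frame_pre$ss <- bt_outer(frame_b$s0, frame_b$s0)
      fs <- bt_outer(frame_b$f0, frame_b$s0)
      frame_pre$fs_sym <- fs + bt_t(fs)
    }
  }
  # direction-pinning penalty (e.g. zero circumferential velocity at the
  # LV base): quadratic penalty k (v . d)^2 per tagged node, assembled as a
  # constant sparse matrix added to residual (P z) and tangent (P)
  penalty <- NULL
  if (length(bcs$pin_direction)) {
    trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
    for (tag in names(bcs$pin_direction)) {
      spec <- bcs$pin_direction[[tag]]
      sel <- mesh$facet_tag == tag
      if (!any(sel)) dvms_error(sprintf("no facets tagged '%s'", tag),
                                "dvms_invalid_argument")
      nodes <- sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
      dirs <- spec$dir(mesh$vertices[nodes, , drop = FALSE])  # nn x d, unit
      dirs <- dirs / sqrt(rowSums(dirs^2))
      for (i in seq_len(d)) for (j in seq_len(d)) {
        trip_i <- c(trip_i, (nodes - 1L) * d + i)
        trip_j <- c(trip_j, (nodes - 1L) * d + j)
        trip_x <- c(trip_x, spec$k * dirs[, i] * dirs[, j])
      }
    }
    penalty <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                    dims = c(n * nfield, n * nfield))
  }
  # Dirichlet velocity dof table
  vdir <- list()
  for (tag in names(bcs$velocity)) {
    spec <- bcs$velocity[[tag]]
    if (is.function(spec) || is.numeric(spec)) spec <- list(comps = seq_len(d), value = spec)
    if (is.null(spec$comps)) spec$comps <- seq_len(d)
    sel <- mesh$facet_tag == tag
    if (!any(sel)) dvms_error(sprintf("no facets tagged '%s'", tag), "dvms_invalid_argument")
    nodes <- sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
    vdir[[tag]] <- list(nodes = nodes, comps = spec$comps, value = spec$value)
  }
  mdir <- list()
  for (tag in names(bcs$mass)) {
    sel <- mesh$facet_tag == tag
    if (!any(sel)) dvms_error(sprintf("no facets tagged '%s'", tag), "dvms_invalid_argument")
    nodes <- sort(unique(as.vector(mesh$facets[sel, , drop = FALSE])))
    mdir[[tag]] <- list(nodes = nodes, value = bcs$mass[[tag]])
  }
  for (tag in c(names(bcs$traction), names(bcs$follower), names(bcs$flux)))
    if (!any(mesh$facet_tag == tag))
      dvms_error(sprintf("no facets tagged '%s'", tag), "dvms_invalid_argument")
  structure(list(
    mesh = mesh, problem = problem, model = model, frame = frame_b,
    frame_pre = frame_pre,
    active = active, pore = pore, source = source, densities = densities,
    rho0s = rho0s, body_force = body_force, bcs = bcs,
    c_tau = c_tau, tau_state = tau_state, compaction_update = compaction_update,
    constraint_relax = constraint_relax,
    geo = geo, qv = qv, Xq = Xq, Ga3 = Ga3, Gmat = Gmat, Mab = Mab,
    engine = engine,
    d = d, n = n, E = E, nl = nl,
    nfield = nfield, ndof = ndof, ndof_v = ndof_v, nld = nld, Gmap = Gmap,
    facet = list(owner = fowner, loc = floc, area = area, normal = nrm,
                 qf = qf, Xfq = Xfq),
    vdir = vdir, mdir = mdir, penalty = penalty,
    interior_pairs = interior_pairs(ft)
  ), class = "dvms_problem")
}

interior_pairs <- function(ft) {
  dup <- ft$all_key[duplicated(ft$all_key) | duplicated(ft$all_key, fromLast = TRUE)]
  sel <- ft$all_key %in% dup
  k <- ft$all_key[sel]; o <- ft$all_owner[sel]
  ord <- order(k)
  k <- k[ord]; o <- o[ord]
  cbind(o[seq(1, length(o), by = 2)], o[seq(2, length(o), by = 2)])
}

#' @export
print.dvms_problem <- function(x, ...) {
  cat(sprintf("dvms_problem <%s>: %dD, %d elements, %d dofs (%s)\n",
              x$problem, x$d, x$E, x$ndof,
              paste(c(sprintf("v[%d]", x$d), "p",
                      if (x$problem == "poro") "m"), collapse = ", ")))
  cat(sprintf("  material: %s; c_tau = %g\n", x$model$variant, x$c_tau))
  invisible(x)
}

# initial state --------------------------------------------------------------

#' Initial solver state
#'
#' @param prob a `dvms_problem`
#' @param u,v,p,mu optional initial nodal fields (matrices n x dim for u, v;
#'   vectors for p, mu); zero by default
#' @param t0 initial time
#' @return a `dvms_state`
#' @export
initial_state <- function(prob, u = NULL, v = NULL, p = NULL, mu = NULL, t0 = 0) {
  n <- prob$n; d <- prob$d
  zm <- function(x, nc) if (is.null(x)) matrix(0, n, nc) else {
    x <- as.matrix(x); stopifnot(nrow(x) == n, ncol(x) == nc); x }
  zv <- function(x) if (is.null(x)) numeric(n) else { stopifnot(length(x) == n); as.numeric(x) }
  structure(list(
    t = t0, step = 0L,
    u = zm(u, d), v = zm(v, d), p = zv(p),
    mu = if (prob$problem == "poro") zv(mu) else NULL,
    u_prev = NULL, v_prev = NULL, mu_prev = NULL, dt_prev = NA_real_,
    c_hist = 0,
    report = list()
  ), class = "dvms_state")
}

#' @export
print.dvms_state <- function(x, ...) {
  cat(sprintf("dvms_state: t = %g (step %d), |u|_max = %.4g, |v|_max = %.4g, |p|_max = %.4g%s\n",
              x$t, x$step, max(abs(x$u)), max(abs(x$v)), max(abs(x$p)),
              if (!is.null(x$mu)) sprintf(", |m|_max = %.4g", max(abs(x$mu))) else ""))
  invisible(x)
}

# pack/unpack ---------------------------------------------------------------

pack_z <- function(prob, v, p, mu = NULL) {
  z <- numeric(prob$ndof)
  z[seq_len(prob$ndof_v)] <- as.vector(t(v))
  z[prob$ndof_v + seq_len(prob$n)] <- p
  if (prob$problem == "poro") z[prob$ndof_v + prob$n + seq_len(prob$n)] <- mu
  z
}

unpack_z <- function(prob, z) {
  v <- matrix(z[seq_len(prob$ndof_v)], prob$n, prob$d, byrow = TRUE)
  p <- z[prob$ndof_v + seq_len(prob$n)]
  mu <- if (prob$problem == "poro") z[prob$ndof_v + prob$n + seq_len(prob$n)] else NULL
  list(v = v, p = p, mu = mu)
}

# Dirichlet bookkeeping for one step (values at time t_new)
dirichlet_at <- function(prob, t_new) {
  fixed <- logical(prob$ndof); val <- numeric(prob$ndof)
  for (bc in prob$vdir) {
    nn <- length(bc$nodes)
    g <- bc$value
    if (is.function(g)) {
      X <- prob$mesh$vertices[bc$nodes, , drop = FALSE]
      gv <- g(X, t_new)                      # nn x dim (full components)
      if (is.null(dim(gv))) gv <- matrix(gv, nn, prob$d)
      gv <- gv[, bc$comps, drop = FALSE]
    } else {
      g <- rep_len(as.numeric(g), length(bc$comps))
      gv <- matrix(g, nn, length(bc$comps), byrow = TRUE)
    }
    for (k in seq_along(bc$comps)) {
      dofs <- (bc$nodes - 1L) * prob$d + bc$comps[k]
      fixed[dofs] <- TRUE
      val[dofs] <- gv[, k]
    }
  }
  for (bc in prob$mdir) {
    X <- prob$mesh$vertices[bc$nodes, , drop = FALSE]
    g <- bc$value
    gv <- if (is.function(g)) g(X, t_new) else rep(as.numeric(g), length(bc$nodes))
    dofs <- prob$ndof_v + prob$n + bc$nodes
    fixed[dofs] <- TRUE
    val[dofs] <- gv
  }
  list(fixed = fixed, val = val)
}

# Per-step data --------------------------------------------------------------

# BDF coefficients for the step t_n -> t_n + dt: vdot = (v_new - vstar)/gdt,
# u_new = ustar + gdt * v_new (same stencil applied to udot = v)
bdf_step_data <- function(prob, state, dt) {
  if (state$step == 0L || is.null(state$u_prev)) {
    gdt <- dt
    ustar <- state$u; vstar <- state$v
    mustar <- state$mu
  } else {
    dt1 <- state$dt_prev
    a <- (2 * dt + dt1) / (dt * (dt + dt1))
    b <- -(dt + dt1) / (dt * dt1)
    cc <- dt / (dt1 * (dt + dt1))
    gdt <- 1 / a
    ustar <- -(b * state$u + cc * state$u_prev) / a
    vstar <- -(b * state$v + cc * state$v_prev) / a
    mustar <- if (prob$problem == "poro") -(b * state$mu + cc * state$mu_prev) / a else NULL
  }
  list(gdt = gdt, ustar = ustar, vstar = vstar, mustar = mustar,
       t_new = state$t + dt, dt = dt)
}

# stabilization tau for the step, from the state at t_n
step_tau <- function(prob, state, dt) {
  if (prob$c_tau <= 0) return(list(tau = 0, dt_mu = NA_real_))
  u_eval <- if (prob$tau_state == "current") state$u else matrix(0, prob$n, prob$d)
  st <- bt_kinematics(bt_grad_u(prob$mesh, prob$geo, u_eval), frame = prob$frame,
                      check = FALSE)
  cmu <- shear_wave_speed(prob$model, st, prob$rho0s)
  dt_mu <- min(prob$mesh$h / cmu)
  list(tau = tau_dvms(prob$c_tau, dt_mu, dt), dt_mu = dt_mu)
}

# constant (dof-independent) per-step load vector
step_const_loads <- function(prob, sd) {
  R <- numeric(prob$ndof)
  t_new <- sd$t_new
  rho_b <- if (prob$problem == "poro") prob$densities$rho0 else prob$rho0s
  if (!is.null(prob$body_force)) {
    for (q in seq_along(prob$qv$w)) {
      bq <- prob$body_force(prob$Xq[[q]], t_new)  # E x (>=d)
      for (a in seq_len(prob$nl)) {
        cN <- prob$qv$w[q] * prob$qv$L[q, a] * prob$geo$V
        for (i in seq_len(prob$d)) {
          dofs <- (prob$mesh$cells[, a] - 1L) * prob$d + i
          R <- R - vec_accum(R * 0, dofs, cN * rho_b * bq[, i])
        }
      }
    }
  }
  fc <- prob$facet
  for (tag in names(prob$bcs$traction)) {
    fun <- prob$bcs$traction[[tag]]
    sel <- which(prob$mesh$facet_tag == tag)
    for (q in seq_along(fc$qf$w)) {
      tq <- fun(fc$Xfq[[q]][sel, , drop = FALSE], t_new)
      if (is.null(dim(tq))) tq <- matrix(tq, length(sel), prob$d)
      for (a in seq_len(prob$d)) {
        cN <- fc$qf$w[q] * fc$qf$L[q, a] * fc$area[sel]
        nodes <- prob$mesh$facets[sel, a]
        for (i in seq_len(prob$d)) {
          dofs <- (nodes - 1L) * prob$d + i
          R <- R - vec_accum(R * 0, dofs, cN * tq[, i])
        }
      }
    }
  }
  if (prob$problem == "poro") {
    if (is.function(prob$source)) {
      for (q in seq_along(prob$qv$w)) {
        Sq <- prob$source(prob$Xq[[q]], t_new)
        for (a in seq_len(prob$nl)) {
          cN <- prob$qv$w[q] * prob$qv$L[q, a] * prob$geo$V
          dofs <- prob$ndof_v + prob$n + prob$mesh$cells[, a]
          R <- R - vec_accum(R * 0, dofs, cN * Sq)
        }
      }
    }
    for (tag in names(prob$bcs$flux)) {
      fun <- prob$bcs$flux[[tag]]
      sel <- which(prob$mesh$facet_tag == tag)
      for (q in seq_along(fc$qf$w)) {
        gq <- fun(fc$Xfq[[q]][sel, , drop = FALSE], t_new)
        for (a in seq_len(prob$d)) {
          cN <- fc$qf$w[q] * fc$qf$L[q, a] * fc$area[sel]
          dofs <- prob$ndof_v + prob$n + prob$mesh$facets[sel, a]
          # boundary term enters with +<W.n, r>; prescribed inflow is -W.n
          R <- R + vec_accum(R * 0, dofs, cN * gq)
        }
      }
    }
  }
  R
}

# scatter-add values into a zero vector of the same length as proto
vec_accum <- function(proto, idx, vals) {
  out <- proto
  s <- rowsum(vals, idx)
  out[as.integer(rownames(s))] <- out[as.integer(rownames(s))] + s[, 1]
  out
}

# element centroid body force for the fine-scale velocity
step_b_centroid <- function(prob, t_new) {
  if (is.null(prob$body_force)) return(matrix(0, prob$E, 3))
  cen <- 0
  for (a in seq_len(prob$nl))
    cen <- cen + prob$mesh$vertices[prob$mesh$cells[, a], , drop = FALSE] / prob$nl
  b <- prob$body_force(cen, t_new)
  if (ncol(b) == 2L) b <- cbind(b, 0)
  b
}

# Core element residual ------------------------------------------------------
#
# Zl: E x nld local dof values. Returns E x nld local residuals of all
# dof-dependent terms (constant loads excluded). Throws a classed
# inverted-element error when any J <= 0.
# dispatch: compiled kernel by default, R reference path on request
element_residual <- function(prob, Zl, sd, tau, b_cen, pore_c, kin = NULL) {
  if (!identical(prob$engine, "r"))
    return(element_residual_cpp(prob, Zl, sd, tau, b_cen, pore_c))
  element_residual_r(prob, Zl, sd, tau, b_cen, pore_c, kin)
}

element_residual_cpp <- function(prob, Zl, sd, tau, b_cen, pore_c) {
  variant <- match(prob$model$variant,
                   c("neo_hookean", "mooney_rivlin", "standard_reinforced",
                     "holzapfel_ogden")) - 1L
  matpar <- switch(prob$model$variant,
    neo_hookean = prob$model$G,
    mooney_rivlin = c(prob$model$C1, prob$model$C2),
    standard_reinforced = c(prob$model$G, prob$model$Gf),
    holzapfel_ogden = unlist(prob$model[c("a", "b", "af", "bf", "as", "bs",
                                          "afs", "bfs")]))
  empty <- matrix(0, 0, 0)
  f0 <- if (!is.null(prob$frame)) prob$frame$f0 else empty
  s0 <- if (!is.null(prob$frame) && !is.null(prob$frame$s0)) prob$frame$s0 else empty
  if (prob$problem == "poro") {
    pore <- prob$pore
    porepar <- c(if (pore$upv == "quadratic") c(pore$kappa_s, 0, 0) else
                   c(pore$q1, pore$q2, pore$q3),
                 0, pore_c, pore$eps, pore$phi_crit, pore$phi0)
    Kp <- pore$K
    src <- prob$source
    if (!is.null(src) && !is.function(src)) {
      src_mode <- match(src$mode, c("full", "proportional", "sink_only")) - 1L
      srcpar <- c(src$beta_so, src$beta_si, src$p_so, src$p_si)
    } else { src_mode <- -1L; srcpar <- numeric(4) }
    Mstar <- sd$Mstar_l
    rho0 <- prob$densities$rho0; rho0f <- prob$densities$rho0f
  } else {
    porepar <- numeric(0); Kp <- diag(3); src_mode <- -1L; srcpar <- numeric(4)
    Mstar <- empty; rho0 <- prob$rho0s; rho0f <- 0
  }
  aT <- if (!is.null(prob$active)) prob$active$Ta(sd$t_new) else -1
  aq <- if (!is.null(prob$active)) prob$active$length_factor else 0
  fol <- follower_arrays(prob, sd$t_new)
  out <- cpp_element_residual(Zl, sd$Ustar_l, sd$Vstar_l, Mstar,
                              prob$Gmat, prob$geo$V, prob$qv$L, prob$qv$w,
                              prob$Mab, sd$gdt, tau, sd$t_new,
                              if (prob$problem == "poro") 1L else 0L,
                              prob$d, variant, matpar, f0, s0, aT, aq,
                              prob$rho0s, rho0, rho0f, b_cen,
                              if (prob$problem == "poro" && prob$pore$upv == "bruinsma") 1L else 0L,
                              porepar, Kp, src_mode, srcpar,
                              fol$owner, fol$loc, fol$area, fol$normal, fol$pmag,
                              if (is.null(prob$constraint_relax)) 0 else prob$constraint_relax)
  if (length(out$bad))
    dvms_error(sprintf("element inversion: J <= 0 in %d element(s), first id %d",
                       length(out$bad), out$bad[1]),
               "dvms_inverted_element", elements = out$bad)
  out$Res
}

follower_arrays <- function(prob, t_new) {
  tags <- names(prob$bcs$follower)
  if (!length(tags))
    return(list(owner = integer(0), loc = matrix(0L, 0, prob$d),
                area = numeric(0), normal = matrix(0, 0, prob$d),
                pmag = numeric(0)))
  fc <- prob$facet
  own <- integer(0); loc <- NULL; area <- numeric(0); nrm <- NULL; pmag <- numeric(0)
  for (tag in tags) {
    sel <- which(prob$mesh$facet_tag == tag)
    pm <- prob$bcs$follower[[tag]](t_new)
    own <- c(own, fc$owner[sel])
    loc <- rbind(loc, fc$loc[sel, , drop = FALSE])
    area <- c(area, fc$area[sel])
    nrm <- rbind(nrm, fc$normal[sel, , drop = FALSE])
    pmag <- c(pmag, rep(pm, length(sel)))
  }
  list(owner = own, loc = loc, area = area, normal = nrm, pmag = pmag)
}

element_residual_r <- function(prob, Zl, sd, tau, b_cen, pore_c, kin = NULL) {
  d <- prob$d; nl <- prob$nl; E <- prob$E; nld <- prob$nld
  V <- prob$geo$V; G <- prob$geo$G; Ga3 <- prob$Ga3
  gdt <- sd$gdt
  Pl <- Zl[, nl * d + seq_len(nl), drop = FALSE]         # pressures
  Ml <- if (prob$problem == "poro") Zl[, nl * d + nl + seq_len(nl), drop = FALSE] else NULL
  if (is.null(kin)) {
    # everything that depends on the velocity dofs only
    Vl <- Zl[, seq_len(nl * d), drop = FALSE]
    Ul <- sd$Ustar_l + gdt * Vl
    Gu <- matrix(0, E, 9); Gv <- matrix(0, E, 9)
    for (a in seq_len(nl)) {
      for (i in seq_len(d)) {
        ua <- Ul[, (a - 1L) * d + i]
        va <- Vl[, (a - 1L) * d + i]
        for (j in seq_len(d)) {
          k <- i + 3L * (j - 1L)
          Gu[, k] <- Gu[, k] + ua * G[[a]][, j]
          Gv[, k] <- Gv[, k] + va * G[[a]][, j]
        }
      }
    }
    st <- bt_kinematics(Gu, frame = prob$frame, need_I2 = FALSE)
    Sdev <- bt_stress_iso(prob$model, st, pre = prob$frame_pre)
    if (!is.null(prob$active)) {
      Tact <- bt_active_T(prob$active, sd$t_new, st$I4f)
      ffo <- if (!is.null(prob$frame_pre)) prob$frame_pre$ff else bt_outer(st$f0, st$f0)
      Sa <- Tact * ffo
      Cinv <- bt_t(bt_cof(st$C)) / st$J^2
      Sdev <- Sdev + Sa - (bt_ddot(Sa, st$C) / 3) * Cinv
    }
    Vdotl <- (Vl - sd$Vstar_l) / gdt
    vdot_el <- matrix(0, E, 3)
    for (a in seq_len(nl))
      for (i in seq_len(d)) vdot_el[, i] <- vdot_el[, i] + Vdotl[, (a - 1L) * d + i] / nl
    kin <- list(st = st, Pdev = bt_mul(st$F, Sdev),
                HdotGv = bt_ddot(st$H, Gv), Vdotl = Vdotl, vdot_el = vdot_el)
  }
  st <- kin$st
  pbar <- rowMeans(Pl)
  Res <- matrix(0, E, nld)
  # momentum: stress + pressure (element-constant) and inertia (mass matrix)
  rho0 <- if (prob$problem == "poro") prob$densities$rho0 else prob$rho0s
  rho0f <- if (prob$problem == "poro") prob$densities$rho0f else NA_real_
  for (a in seq_len(nl)) {
    PG <- bt_mv(kin$Pdev, Ga3[[a]])
    HG <- bt_mv(st$H, Ga3[[a]])
    for (i in seq_len(d)) {
      acc <- V * (PG[, i] - pbar * HG[, i])
      if (prob$problem == "hyper") {
        m_vd <- 0
        for (b in seq_len(nl))
          m_vd <- m_vd + prob$Mab[a, b] * kin$Vdotl[, (b - 1L) * d + i]
        acc <- acc + V * prob$rho0s * m_vd
      }
      Res[, (a - 1L) * d + i] <- acc
    }
  }
  # continuity: (H : grad v, q) - (v', H grad q) [- (mudot, q) for poro].
  # The fine-scale term enters as <y', L* phi> ~ -(v', H grad q); with
  # v' = -tau(vdot + H grad p/rho0s - b) its pressure part is the
  # stabilizing +tau/rho0s (H grad p, H grad q).
  gradp <- matrix(0, E, 3)
  for (a in seq_len(nl))
    for (j in seq_len(d)) gradp[, j] <- gradp[, j] + Pl[, a] * G[[a]][, j]
  vprime <- -tau * (kin$vdot_el + bt_mv(st$H, gradp) / prob$rho0s - b_cen)
  # Baumgarte relaxation of the volumetric constraint (consistent: zero on
  # the constraint manifold J - 1 = m, resp. J = 1)
  crel <- if (is.null(prob$constraint_relax)) 0 else prob$constraint_relax
  cviol <- if (crel > 0) {
    v0 <- st$J - 1
    if (prob$problem == "poro") v0 - rowMeans(Ml) else v0
  } else 0
  for (a in seq_len(nl)) {
    HGa <- bt_mv(st$H, Ga3[[a]])
    Res[, nl * d + a] <- V / nl * (kin$HdotGv + crel / gdt * cviol) -
      V * (vprime[, 1] * HGa[, 1] + vprime[, 2] * HGa[, 2] + vprime[, 3] * HGa[, 3])
  }
  if (prob$problem == "poro") {
    Mdotl <- (Ml - sd$Mstar_l) / gdt
    pp_c <- prob$pore; pp_c$c <- pore_c
    K0 <- bt_pulled_back_K(prob$pore$K, st$F, st$J)
    gradmu <- matrix(0, E, 3)
    for (a in seq_len(nl))
      for (j in seq_len(d)) gradmu[, j] <- gradmu[, j] + Ml[, a] * G[[a]][, j]
    K0gp <- bt_mv(K0, gradp)
    K0gm <- bt_mv(K0, gradmu)
    dpi_avg <- 0
    has_src_model <- !is.null(prob$source) && !is.function(prob$source)
    for (q in seq_along(prob$qv$w)) {
      wq <- prob$qv$w[q]; Lq <- prob$qv$L[q, ]
      mu_q <- as.vector(Ml %*% Lq)
      pq <- pore_pressures(pp_c, mu_q)
      # clamp: past the porosity floor d(pPV+pc)/dm goes negative, which
      # would make K0m an antidiffusion; keep the operator parabolic
      dpi_avg <- dpi_avg + wq * pmax(pq$dp_dm, 0)
      mdot_q <- as.vector(Mdotl %*% Lq)
      # inertia with mixture density (rho0 + rho0f mu) at the quad point
      rho_q <- rho0 + rho0f * mu_q
      vdq <- matrix(0, E, d)
      for (a in seq_len(nl))
        for (i in seq_len(d)) vdq[, i] <- vdq[, i] + Lq[a] * kin$Vdotl[, (a - 1L) * d + i]
      Sq <- if (has_src_model)
        source_eval(prob$source, as.vector(Pl %*% Lq) + pq$p_pv + pq$p_c)$S else 0
      for (a in seq_len(nl)) {
        cN <- wq * Lq[a] * V
        for (i in seq_len(d))
          Res[, (a - 1L) * d + i] <- Res[, (a - 1L) * d + i] + cN * rho_q * vdq[, i]
        Res[, nl * d + a] <- Res[, nl * d + a] - cN * mdot_q
        Res[, nl * d + nl + a] <- Res[, nl * d + nl + a] + cN * (mdot_q - Sq)
      }
    }
    for (a in seq_len(nl)) {
      Res[, nl * d + nl + a] <- Res[, nl * d + nl + a] +
        V * rowSums(Ga3[[a]] * (K0gp + dpi_avg * K0gm))
    }
  }
  # follower pressure loads (dof-dependent through H)
  for (tag in names(prob$bcs$follower)) {
    pmag <- prob$bcs$follower[[tag]](sd$t_new)
    if (abs(pmag) > 0) {
      fc <- prob$facet
      sel <- which(prob$mesh$facet_tag == tag)
      own <- fc$owner[sel]
      n0 <- cbind(fc$normal[sel, , drop = FALSE],
                  matrix(0, length(sel), 3 - d))[, 1:3, drop = FALSE]
      Hn <- bt_mv(st$H[own, , drop = FALSE], n0)  # element-constant on facet
      for (a in seq_len(d)) {
        la <- fc$loc[sel, a]
        cA <- fc$area[sel] / d                     # int N_a dA for P1
        for (i in seq_len(d)) {
          col <- (la - 1L) * d + i
          contrib <- cA * pmag * Hn[, i]           # minus traction (-p H n0)
          Res[cbind(own, col)] <- Res[cbind(own, col)] + contrib
        }
      }
    }
  }
  attr(Res, "kin") <- kin
  Res
}

# gather history fields into element-local layout (E x nl*d / E x nl)
gather_local <- function(prob, mat) {
  d <- prob$d; nl <- prob$nl
  if (is.matrix(mat)) {
    out <- matrix(0, prob$E, nl * d)
    for (a in seq_len(nl))
      for (i in seq_len(d)) out[, (a - 1L) * d + i] <- mat[prob$mesh$cells[, a], i]
  } else {
    out <- matrix(0, prob$E, nl)
    for (a in seq_len(nl)) out[, a] <- mat[prob$mesh$cells[, a]]
  }
  out
}

gather_z_local <- function(prob, z) {
  u <- unpack_z(prob, z)
  Zl <- matrix(0, prob$E, prob$nld)
  Zl[, seq_len(prob$nl * prob$d)] <- gather_local(prob, u$v)
  Zl[, prob$nl * prob$d + seq_len(prob$nl)] <- gather_local(prob, u$p)
  if (prob$problem == "poro")
    Zl[, prob$nl * prob$d + prob$nl + seq_len(prob$nl)] <- gather_local(prob, u$mu)
  Zl
}

scatter_residual <- function(prob, Res) {
  R <- numeric(prob$ndof)
  for (k in seq_len(prob$nld)) {
    s <- rowsum(Res[, k], prob$Gmap[, k])
    R[as.integer(rownames(s))] <- R[as.integer(rownames(s))] + s[, 1]
  }
  R
}

#' Assemble the global residual (and optionally the tangent)
#'
#' Evaluates the time-discrete stabilized weak-form residual at given nodal
#' unknowns, for one step from the state's current time with step `dt`.
#' Mainly a testing/diagnostic entry point; [run_simulation()] drives the
#' same internals.
#'
#' @param prob a `dvms_problem`
#' @param state a `dvms_state` (provides history and the step origin)
#' @param v,p,mu trial nodal fields at the end of the step
#' @param dt time-step size
#' @param jacobian if `TRUE`, also return the sparse tangent matrix
#' @return list with `R` (length-ndof residual) and optionally `J`
#' @export
assemble_residual <- function(prob, state, v, p, mu = NULL, dt,
                              jacobian = FALSE) {
  sd <- bdf_step_data(prob, state, dt)
  sd$Ustar_l <- gather_local(prob, sd$ustar)
  sd$Vstar_l <- gather_local(prob, sd$vstar)
  sd$Mstar_l <- if (prob$problem == "poro") gather_local(prob, sd$mustar) else NULL
  tau <- step_tau(prob, state, dt)$tau
  b_cen <- step_b_centroid(prob, sd$t_new)
  pore_c <- effective_pore_c(prob, state)
  z <- pack_z(prob, v, p, mu)
  Zl <- gather_z_local(prob, z)
  Res <- element_residual(prob, Zl, sd, tau, b_cen, pore_c)
  R <- scatter_residual(prob, Res) + step_const_loads(prob, sd)
  if (!is.null(prob$penalty)) R <- R + as.numeric(prob$penalty %*% z)
  out <- list(R = R)
  if (jacobian) {
    out$J <- assemble_jacobian(prob, Zl, sd, tau, b_cen, pore_c,
                               newton_settings()$fd_eps)
    if (!is.null(prob$penalty)) out$J <- out$J + prob$penalty
  }
  out
}

effective_pore_c <- function(prob, state) {
  if (prob$problem != "poro") return(0)
  if (prob$compaction_update == "history_max") -state$c_hist else prob$pore$c
}

# element-level central-difference tangent, assembled sparse
assemble_jacobian <- function(prob, Zl, sd, tau, b_cen, pore_c, fd_eps) {
  nld <- prob$nld; E <- prob$E; d <- prob$d; nl <- prob$nl
  # per-field FD steps
  scale_of <- function(cols, floor_) max(floor_, max(abs(Zl[, cols, drop = FALSE])))
  h_v <- fd_eps * scale_of(seq_len(nl * d), 1)
  h_p <- fd_eps * scale_of(nl * d + seq_len(nl), 1)
  h_m <- if (prob$problem == "poro")
    fd_eps * scale_of(nl * d + nl + seq_len(nl), 1e-2) else NA_real_
  hs <- c(rep(h_v, nl * d), rep(h_p, nl), if (prob$problem == "poro") rep(h_m, nl))
  # base kinematics reused for pressure/added-mass columns (those dofs do
  # not enter the deformation, stress, or acceleration)
  base <- element_residual(prob, Zl, sd, tau, b_cen, pore_c)
  kin0 <- attr(base, "kin")
  xs <- numeric(E * nld * nld)
  pos <- 0L
  for (k in seq_len(nld)) {
    kin_k <- if (k > nl * d) kin0 else NULL
    zk <- Zl[, k]
    Zl[, k] <- zk + hs[k]
    Rp <- element_residual(prob, Zl, sd, tau, b_cen, pore_c, kin = kin_k)
    Zl[, k] <- zk - hs[k]
    Rm <- element_residual(prob, Zl, sd, tau, b_cen, pore_c, kin = kin_k)
    Zl[, k] <- zk
    xs[pos + seq_len(E * nld)] <- (Rp - Rm) / (2 * hs[k])
    pos <- pos + E * nld
  }
  # triplets: block k holds dR[, row]/dz[, k] in as.vector(dR) layout
  ii <- rep(as.vector(prob$Gmap), times = nld)
  jj <- integer(E * nld * nld)
  pos <- 0L
  for (k in seq_len(nld)) {
    jj[pos + seq_len(E * nld)] <- rep(prob$Gmap[, k], times = nld)
    pos <- pos + E * nld
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xs, dims = c(prob$ndof, prob$ndof))
}

# Newton solve for one step ---------------------------------------------------

newton_solve <- function(prob, state, sd, tau, b_cen, pore_c, settings,
                         jac_cache, z0, accept_stagnation = FALSE) {
  dir <- dirichlet_at(prob, sd$t_new)
  z <- z0
  z[dir$fixed] <- dir$val[dir$fixed]
  Lconst <- step_const_loads(prob, sd)
  resid <- function(z) {
    Zl <- gather_z_local(prob, z)
    R <- scatter_residual(prob, element_residual(prob, Zl, sd, tau, b_cen, pore_c)) +
      Lconst
    if (!is.null(prob$penalty)) R <- R + as.numeric(prob$penalty %*% z)
    R[dir$fixed] <- 0
    R
  }
  Zl0 <- gather_z_local(prob, z)
  Res0 <- element_residual(prob, Zl0, sd, tau, b_cen, pore_c)
  R <- scatter_residual(prob, Res0) + Lconst
  if (!is.null(prob$penalty)) R <- R + as.numeric(prob$penalty %*% z)
  R[dir$fixed] <- 0
  r0 <- sqrt(sum(R^2))
  # two floors below which iterating is meaningless: the cancellation
  # roundoff of the assembly (sum of absolute element contributions), and,
  # near a steady state, a fraction of the run's historical residual scale
  roundoff <- 64 * .Machine$double.eps *
    sqrt(sum(scatter_residual(prob, abs(Res0))^2))
  if (is.null(jac_cache$r0max)) jac_cache$r0max <- 0
  jac_cache$r0max <- max(jac_cache$r0max, r0)
  rtol <- max(settings$abs_tol, settings$rel_tol * r0,
              0.01 * settings$rel_tol * jac_cache$r0max, roundoff)
  it <- 0L
  r <- r0
  if (is.null(jac_cache$hot)) jac_cache$hot <- FALSE
  last_build <- -1L
  while (r > rtol && it < settings$max_iters) {
    it <- it + 1L
    need_jac <- is.null(jac_cache$J) ||
      (settings$jacobian_refresh == "iteration") ||
      (settings$jacobian_refresh == "step" && it == 1L && jac_cache$age > 0L) ||
      (settings$jacobian_refresh == "lazy" && it - last_build >= 10L) ||
      jac_cache$stale || jac_cache$hot
    if (need_jac) {
      last_build <- it
      Zl <- gather_z_local(prob, z)
      J <- assemble_jacobian(prob, Zl, sd, tau, b_cen, pore_c, settings$fd_eps)
      if (!is.null(prob$penalty)) J <- J + prob$penalty
      if (prob$c_tau == 0) {
        # the unstabilized equal-order system is singular (checkerboard
        # null mode); a machine-scale ridge on the pressure block makes
        # the baseline factorizable while leaving the oscillations intact
        pd <- prob$ndof_v + seq_len(prob$n)
        eps_p <- 1e-10 * max(abs(J@x))
        J <- J + Matrix::sparseMatrix(i = pd, j = pd, x = rep(eps_p, length(pd)),
                                      dims = dim(J))
      }
      J <- dirichlet_matrix(J, dir$fixed)
      # row equilibration improves both pivoting and fill of the sparse LU
      J <- as(J, "CsparseMatrix")
      rmax <- numeric(nrow(J))
      mx <- tapply(abs(J@x), J@i, max)
      rmax[as.integer(names(mx)) + 1L] <- mx
      D1 <- 1 / pmax(rmax, 1e-300)
      jac_cache$D1 <- D1
      jac_cache$J <- J
      jac_cache$fac <- Matrix::lu(Matrix::Diagonal(x = D1) %*% J, cache = FALSE)
      jac_cache$age <- 0L
      jac_cache$stale <- FALSE
    }
    dz <- tryCatch(as.numeric(Matrix::solve(jac_cache$fac, -(R * jac_cache$D1))),
                   error = function(e)
                     dvms_error(paste("linear solver failed:", conditionMessage(e)),
                                "dvms_linear_solver"))
    s <- 1; ok <- FALSE
    for (ls in 0:6) {
      z_try <- z + s * dz
      z_try[dir$fixed] <- dir$val[dir$fixed]
      R_try <- tryCatch(resid(z_try), dvms_inverted_element = function(e) NULL)
      if (!is.null(R_try)) {
        r_try <- sqrt(sum(R_try^2))
        if (r_try <= rtol || r_try < r || !settings$line_search) {
          z <- z_try; R <- R_try; r <- r_try; ok <- TRUE; break
        }
      }
      if (!settings$line_search && !is.null(R_try)) break
      s <- s / 2
    }
    if (!ok) {
      if (!jac_cache$hot) {
        # stale or sharply nonlinear regime: switch to per-iteration fresh
        # tangents for the remainder of this step
        jac_cache$hot <- TRUE
        jac_cache$stale <- TRUE
        next
      }
      # last-resort stagnation acceptance: with a fresh tangent and an
      # exhausted line search, accept an iterate whose residual already
      # dropped well below the step's initial one (this arises at the
      # sharp compaction well, where the leftover residual sits on a few
      # porosity-floor nodes and is below the time-discretization error)
      if (accept_stagnation && r <= max(0.05 * r0, 0.01 * jac_cache$r0max)) {
        jac_cache$age <- jac_cache$age + 1L
        jac_cache$hot <- FALSE
        return(list(converged = TRUE, z = z, iters = it, resid = r,
                    resid0 = r0, stagnated = TRUE))
      }
      return(list(converged = FALSE, z = z, iters = it, resid = r))
    }
  }
  conv <- r <= rtol
  stag <- FALSE
  if (!conv && accept_stagnation &&
      r <= max(0.05 * r0, 0.01 * jac_cache$r0max)) { conv <- TRUE; stag <- TRUE }
  jac_cache$age <- jac_cache$age + 1L
  if (conv) jac_cache$hot <- FALSE
  list(converged = conv, z = z, iters = it, resid = r, resid0 = r0,
       stagnated = stag)
}

dirichlet_matrix <- function(J, fixed) {
  if (!any(fixed)) return(J)
  J <- as(J, "TsparseMatrix")
  keep <- !(fixed[J@i + 1L] | fixed[J@j + 1L])
  fi <- which(fixed) - 1L
  Matrix::sparseMatrix(i = c(J@i[keep], fi) + 1L,
                       j = c(J@j[keep], fi) + 1L,
                       x = c(J@x[keep], rep(1, length(fi))),
                       dims = dim(J))
}

#' Advance the solution by one (accepted) time step
#'
#' Solves the nonlinear velocity/pressure(/added-mass) system at t + dt with
#' Newton's method, then updates the displacement explicitly from the BDF
#' relation (backward Euler on the first step, BDF2 afterwards). On Newton
#' failure or element inversion the step is retried with a halved dt, up to
#' `max_halvings` times, before a step-rejection error is raised.
#'
#' @param prob a `dvms_problem`
#' @param state a `dvms_state`
#' @param dt requested time-step size
#' @param settings a [newton_settings()]
#' @param jac_cache internal tangent cache (environment); supply the same
#'   environment across steps to enable lazy tangent reuse
#' @param max_halvings retry budget
#' @return the updated `dvms_state`
#' @export
advance <- function(prob, state, dt, settings = newton_settings(),
                    jac_cache = NULL, max_halvings = 5L) {
  if (is.null(jac_cache)) {
    jac_cache <- new.env()
    jac_cache$J <- NULL; jac_cache$age <- 1L; jac_cache$stale <- FALSE
  }
  dt_try <- dt
  z0 <- pack_z(prob, state$v, state$p, state$mu)
  for (att in 0:max_halvings) {
    sd <- bdf_step_data(prob, state, dt_try)
    sd$Ustar_l <- gather_local(prob, sd$ustar)
    sd$Vstar_l <- gather_local(prob, sd$vstar)
    sd$Mstar_l <- if (prob$problem == "poro") gather_local(prob, sd$mustar) else NULL
    tl <- step_tau(prob, state, dt_try)
    b_cen <- step_b_centroid(prob, sd$t_new)
    pore_c <- effective_pore_c(prob, state)
    sol <- tryCatch(
      newton_solve(prob, state, sd, tl$tau, b_cen, pore_c, settings, jac_cache,
                   z0, accept_stagnation = (att == max_halvings)),
      dvms_inverted_element = function(e) list(converged = FALSE, iters = NA_integer_,
                                               resid = NA_real_))
    if (isTRUE(sol$converged)) {
      uz <- unpack_z(prob, sol$z)
      new <- state
      new$u_prev <- state$u; new$v_prev <- state$v; new$mu_prev <- state$mu
      new$dt_prev <- dt_try
      new$u <- sd$ustar + sd$gdt * uz$v
      new$v <- uz$v; new$p <- uz$p; new$mu <- uz$mu
      new$t <- sd$t_new; new$step <- state$step + 1L
      if (prob$problem == "poro" && prob$compaction_update == "history_max") {
        ppc <- prob$pore; ppc$c <- pore_c
        pp <- pore_pressures(ppc, uz$mu)
        new$c_hist <- max(state$c_hist, max(uz$p + pp$p_pv + pp$p_c), 0)
      }
      new$report[[length(new$report) + 1L]] <-
        list(t = sd$t_new, dt = dt_try, iters = sol$iters, resid = sol$resid,
             halvings = att, tau = tl$tau)
      return(new)
    }
    dt_try <- dt_try / 2
    jac_cache$stale <- TRUE
  }
  dvms_error(sprintf("time step rejected at t = %g after %d halvings (last residual %.3g)",
                     state$t, max_halvings, sol$resid),
             "dvms_step_rejection")
}

#' Run a transient simulation
#'
#' Steps the problem from an initial state to `t_end` with fixed step `dt`
#' (or a CFL-derived one), recording per-step Newton statistics, probe time
#' series and global diagnostics.
#'
#' @param prob a `dvms_problem`
#' @param dt time-step size; if `NULL`, computed as
#'   `alpha_cfl * min_e h^e / c_mu^e` at the reference state
#' @param t_end end time (ignored if `nsteps` given)
#' @param nsteps number of steps (overrides `t_end`)
#' @param alpha_cfl CFL number used when `dt` is `NULL`
#' @param init optional initial `dvms_state` (or list of fields passed to
#'   [initial_state()])
#' @param settings a [newton_settings()]
#' @param probes optional matrix of probe points (rows); fields at the
#'   nearest vertex are recorded each step
#' @param observer optional `function(state, prob)` called after each step
#' @param steady_tol if positive, stop early once the relative change of all
#'   fields over a step falls below this value
#' @param verbose print per-step progress
#' @return a `dvms_result` with the final `state`, per-step `report` data
#'   frame, `probe` data frame and diagnostic series
#' @export
run_simulation <- function(prob, dt = NULL, t_end = NULL, nsteps = NULL,
                           alpha_cfl = 0.5, init = NULL,
                           settings = newton_settings(),
                           probes = NULL, observer = NULL,
                           steady_tol = 0, verbose = FALSE) {
  if (is.null(dt)) {
    dt <- cfl_timestep(prob$mesh, prob$model, prob$rho0s, alpha_cfl,
                       frame = restore_frame(prob))$dt
  }
  if (is.null(nsteps)) {
    if (is.null(t_end)) dvms_error("need t_end or nsteps", "dvms_invalid_argument")
    nsteps <- max(1L, as.integer(round(t_end / dt)))
    dt <- if (!is.null(t_end)) t_end / nsteps else dt
  }
  state <- if (inherits(init, "dvms_state")) init else
    do.call(initial_state, c(list(prob = prob), as.list(init)))
  probe_ix <- NULL
  if (!is.null(probes)) {
    probes <- as.matrix(probes)
    probe_ix <- apply(probes, 1L, function(pt)
      which.min(colSums((t(prob$mesh$vertices) - pt)^2)))
  }
  jac_cache <- new.env(); jac_cache$J <- NULL; jac_cache$age <- 1L; jac_cache$stale <- FALSE
  probe_rows <- list(); diag_rows <- list()
  record <- function(state) {
    dg <- diagnostics(prob, state)
    diag_rows[[length(diag_rows) + 1L]] <<-
      data.frame(t = state$t, volume = dg$volume, skeleton_volume = dg$skeleton_volume,
                 energy = dg$energy)
    if (!is.null(probe_ix)) {
      for (k in seq_along(probe_ix)) {
        ix <- probe_ix[k]
        row <- data.frame(t = state$t, probe = k,
                          u1 = state$u[ix, 1], u2 = state$u[ix, 2],
                          v1 = state$v[ix, 1], v2 = state$v[ix, 2],
                          p = state$p[ix])
        if (prob$d == 3L) { row$u3 <- state$u[ix, 3]; row$v3 <- state$v[ix, 3] }
        if (prob$problem == "poro") {
          ppc <- prob$pore; ppc$c <- effective_pore_c(prob, state)
          pp <- pore_pressures(ppc, state$mu[ix])
          row$m <- prob$pore$rho0f * state$mu[ix]
          row$p_pore <- state$p[ix] + pp$p_pv + pp$p_c
        }
        probe_rows[[length(probe_rows) + 1L]] <<- row
      }
    }
  }
  record(state)
  t_target <- state$t + nsteps * dt
  while (state$t < t_target - 1e-9 * dt) {
    prev <- state
    state <- advance(prob, state, min(dt, t_target - state$t), settings,
                     jac_cache)
    record(state)
    if (!is.null(observer)) observer(state, prob)
    rp <- state$report[[length(state$report)]]
    if (verbose)
      cat(sprintf("step %d t=%.5g iters=%d resid=%.3g\n", state$step, state$t,
                  rp$iters, rp$resid))
    if (steady_tol > 0 && rp$halvings == 0L) {
      du <- max(abs(state$u - prev$u)); dmu <- if (!is.null(state$mu))
        max(abs(state$mu - prev$mu)) else 0
      ref <- max(abs(state$u), abs(if (!is.null(state$mu)) state$mu else 0), 1e-12)
      if ((du + dmu) / ref < steady_tol) break
    }
  }
  rep_df <- do.call(rbind, lapply(state$report, as.data.frame))
  structure(list(state = state, problem = prob,
                 report = rep_df,
                 probe = if (length(probe_rows)) do.call(rbind, probe_rows) else NULL,
                 diag = do.call(rbind, diag_rows)),
            class = "dvms_result")
}

restore_frame <- function(prob) {
  if (is.null(prob$frame)) NULL else
    structure(list(f0 = prob$frame$f0, s0 = prob$frame$s0), class = "dvms_fibre_frame")
}

#' @export
print.dvms_result <- function(x, ...) {
  cat(sprintf("dvms_result: %d steps to t = %g\n", x$state$step, x$state$t))
  if (!is.null(x$report))
    cat(sprintf("  Newton iters: max %d, mean %.2f; max halvings %d\n",
                max(x$report$iters), mean(x$report$iters), max(x$report$halvings)))
  dg <- diagnostics(x$problem, x$state)
  cat(sprintf("  volume %.6g (reference %.6g)\n", dg$volume, dg$volume0))
  invisible(x)
}

# Diagnostics -----------------------------------------------------------------

#' Global and field diagnostics of a state
#'
#' Total current volume `int J dX`, skeleton volume `int (J - m) dX`
#' (dimensionless added mass), elementwise porosity
#' `phi = 1 - (1 - phi0)/J`, nodal pore pressure p + p^PV + p^c,
#' element Lagrangian perfusion flux `W = -(K0 grad p + K0m grad m)`, and
#' the discrete total energy (kinetic + isochoric strain energy). Porosity
#' outside (0,1) triggers a warning naming the first offending element.
#'
#' @param prob a `dvms_problem`
#' @param state a `dvms_state`
#' @return list of diagnostics
#' @export
diagnostics <- function(prob, state) {
  geo <- prob$geo
  st <- bt_kinematics(bt_grad_u(prob$mesh, geo, state$u), frame = prob$frame,
                      check = FALSE)
  V0 <- sum(geo$V)
  vol <- sum(geo$V * st$J)
  out <- list(volume = vol, volume0 = V0)
  # kinetic + strain energy (quadrature-consistent)
  rho0 <- if (prob$problem == "poro") prob$densities$rho0 else prob$rho0s
  ke <- 0
  for (q in seq_along(prob$qv$w)) {
    vq <- 0
    for (a in seq_len(prob$nl))
      vq <- vq + prob$qv$L[q, a] * state$v[prob$mesh$cells[, a], , drop = FALSE]
    ke <- ke + sum(prob$qv$w[q] * geo$V * 0.5 * rho0 * rowSums(vq^2))
  }
  out$energy <- ke + sum(geo$V * bt_energy(prob$model, st))
  out$kinetic <- ke
  if (prob$problem == "poro") {
    phi0 <- prob$pore$phi0
    mu_el <- rowMeans(gather_local(prob, state$mu))
    out$skeleton_volume <- sum(geo$V * (st$J - mu_el))
    out$porosity <- 1 - (1 - phi0) / st$J
    bad <- which(out$porosity <= 0 | out$porosity >= 1)
    if (length(bad))
      warning(sprintf("porosity outside (0,1) in %d element(s), first at element %d",
                      length(bad), bad[1]))
    ppc <- prob$pore; ppc$c <- effective_pore_c(prob, state)
    pp <- pore_pressures(ppc, state$mu)
    out$p_pore <- state$p + pp$p_pv + pp$p_c
    out$p_pv <- pp$p_pv; out$p_c <- pp$p_c
    K0 <- bt_pulled_back_K(prob$pore$K, st$F, st$J)
    gp <- p1_gradient_all(prob$mesh, geo, state$p)
    gm <- p1_gradient_all(prob$mesh, geo, state$mu)
    gradp <- matrix(0, prob$E, 3); gradmu <- matrix(0, prob$E, 3)
    for (j in seq_len(prob$d)) { gradp[, j] <- gp[[j]][, 1]; gradmu[, j] <- gm[[j]][, 1] }
    dpi <- pmax(pore_pressures(ppc, mu_el)$dp_dm, 0)
    out$flux <- -(bt_mv(K0, gradp) + dpi * bt_mv(K0, gradmu))
  } else {
    out$skeleton_volume <- vol
  }
  out$J <- st$J
  out
}

#' Pressure checkerboard indicator
#'
#' Mean absolute jump of element-mean pressure across interior facets,
#' normalized by the mean absolute element pressure. Near zero for smooth
#' fields; order one for the node-to-node oscillations of the unstabilized
#' equal-order method.
#'
#' @param prob a `dvms_problem`
#' @param p nodal pressure
#' @return scalar indicator
#' @export
checkerboard_indicator <- function(prob, p) {
  pel <- rowMeans(gather_local(prob, p))
  pr <- prob$interior_pairs
  jump <- mean(abs(pel[pr[, 1]] - pel[pr[, 2]]))
  jump / max(mean(abs(pel)), .Machine$double.eps)
}
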