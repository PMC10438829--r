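# Assembly, Newton, time stepping, diagnostics.

make_hyper_prob <- function(div = 2L, c_tau = 0.02) {
  mesh <- unit_cube_mesh(div)
  mesh <- tag_boundary(mesh, list(bottom = on_plane(3, 0), rest = "otherwise"))
  dvms_problem(mesh, "hyper", standard_reinforced(1, 1), rho0s = 1,
               frame = fibre_frame(c(1, 1, 1)),
               bcs = list(velocity = list(bottom = 0)), c_tau = c_tau)
}

make_poro_prob <- function(div = 2L, source = NULL) {
  mesh <- unit_cube_mesh(div)
  mesh <- tag_boundary(mesh, list(all = "otherwise"))
  pore <- pore_fluid_model("quadratic", kappa_s = 1, c = 0, phi0 = 0.1,
                           rho0f = 1, K = 0.05)
  dvms_problem(mesh, "poro", neo_hookean(1), rho0s = 1, pore = pore,
               source = source, bcs = list(), c_tau = 0.02)
}

test_that("zero state is an equilibrium of the unloaded problems", {
  prob <- make_hyper_prob()
  st <- initial_state(prob)
  out <- assemble_residual(prob, st, v = st$v, p = st$p, dt = 0.05)
  expect_lt(max(abs(out$R)), 1e-13)

  # poro: impermeable, no sources -> m = 0 stays a residual root
  probp <- make_poro_prob()
  stp <- initial_state(probp)
  outp <- assemble_residual(probp, stp, v = stp$v, p = stp$p, mu = stp$mu,
                            dt = 0.05)
  expect_lt(max(abs(outp$R)), 1e-13)
})

test_that("fine-scale velocity formula", {
  expect_equal(fine_scale_velocity(c(0, 0, 0), diag(3), c(0, 0, 0),
                                   c(0, 0, 0), 0.01, 1), c(0, 0, 0))
  b <- c(0.3, -1, 2)
  expect_equal(fine_scale_velocity(b, diag(3), c(0, 0, 0), b, 0.01, 1),
               c(0, 0, 0))
  expect_equal(fine_scale_velocity(c(0, 0, 0), diag(3), c(1, 0, 0),
                                   c(0, 0, 0), 0.01, 1), c(-0.01, 0, 0))
  expect_equal(fine_scale_velocity(c(1, 1, 1), diag(3), c(1, 0, 0),
                                   c(0, 0, 0), 0, 1), c(0, 0, 0))
})

test_that("assembled tangent matches global directional finite differences", {
  set.seed(9)
  for (maker in list(function() make_hyper_prob(2L),
                     function() make_poro_prob(2L,
                       source_model("full", 0.1, 0.2, 1, 0.2)))) {
    prob <- maker()
    n <- prob$n
    st <- initial_state(prob, v = matrix(rnorm(n * 3, sd = 0.05), n, 3))
    v <- st$v + matrix(rnorm(n * 3, sd = 0.02), n, 3)
    p <- rnorm(n, sd = 0.05)
    mu <- if (prob$problem == "poro") rnorm(n, sd = 0.02) else NULL
    out <- assemble_residual(prob, st, v, p, mu, dt = 0.04, jacobian = TRUE)
    z <- dvmsfem:::pack_z(prob, v, p, mu)
    f <- function(z) {
      u <- dvmsfem:::unpack_z(prob, z)
      assemble_residual(prob, st, u$v, u$p, u$mu, dt = 0.04)$R
    }
    for (k in 1:3) {
      dirv <- rnorm(prob$ndof); dirv <- dirv / sqrt(sum(dirv^2))
      h <- 1e-6
      Jv_fd <- (f(z + h * dirv) - f(z - h * dirv)) / (2 * h)
      Jv <- as.numeric(out$J %*% dirv)
      expect_lt(max(abs(Jv - Jv_fd)) / max(abs(Jv)), 1e-6)
    }
  }
})

test_that("compiled and reference element kernels agree", {
  set.seed(10)
  for (maker in list(function() make_hyper_prob(2L),
                     function() make_poro_prob(2L,
                       source_model("sink_only", beta_si = 0.05, p_si = 0.1)))) {
    prob <- maker()
    prob_r <- prob; prob_r$engine <- "r"
    n <- prob$n
    st <- initial_state(prob, v = matrix(rnorm(n * 3, sd = 0.05), n, 3))
    v <- st$v + matrix(rnorm(n * 3, sd = 0.02), n, 3)
    p <- rnorm(n, sd = 0.1)
    mu <- if (prob$problem == "poro") rnorm(n, sd = 0.02) else NULL
    Rc <- assemble_residual(prob, st, v, p, mu, dt = 0.03)$R
    Rr <- assemble_residual(prob_r, st, v, p, mu, dt = 0.03)$R
    expect_equal(Rc, Rr, tolerance = 1e-12)
  }
})

test_that("BDF update: constant velocity integrates displacement exactly", {
  mesh <- unit_cube_mesh(2)
  mesh <- tag_boundary(mesh, list(top = on_plane(3, 1), all = "otherwise"))
  # one traction-free face keeps the pressure level determined
  prob <- dvms_problem(mesh, "hyper", neo_hookean(1), rho0s = 1,
                       bcs = list(velocity = list(all = c(0.02, -0.01, 0.005))),
                       c_tau = 0.02)
  cvec <- c(0.02, -0.01, 0.005)
  st <- initial_state(prob, v = matrix(cvec, prob$n, 3, byrow = TRUE))
  res <- run_simulation(prob, dt = 0.05, nsteps = 4, init = st)
  uexp <- outer(rep(res$state$t, prob$n), cvec)
  expect_equal(res$state$u, matrix(res$state$t * cvec, prob$n, 3, byrow = TRUE),
               tolerance = 1e-9)

  # v = 0 throughout freezes the displacement
  prob0 <- make_hyper_prob()
  res0 <- run_simulation(prob0, dt = 0.05, nsteps = 3)
  expect_equal(max(abs(res0$state$u)), 0, tolerance = 1e-12)
})

test_that("free response: energy non-increasing after startup, no blow-up", {
  # property of the pure rate-form scheme (no constraint relaxation)
  mesh <- unit_cube_mesh(2)
  mesh <- tag_boundary(mesh, list(bottom = on_plane(3, 0), rest = "otherwise"))
  prob <- dvms_problem(mesh, "hyper", standard_reinforced(1, 1), rho0s = 1,
                       frame = fibre_frame(c(1, 1, 1)),
                       bcs = list(velocity = list(bottom = 0)), c_tau = 0.02,
                       constraint_relax = 0)
  v0 <- cbind(0.3 * prob$mesh$vertices[, 3], 0, 0)
  res <- run_simulation(prob, dt = 0.05, nsteps = 40,
                        init = initial_state(prob, v = v0))
  en <- res$diag$energy
  expect_true(all(diff(en[-1]) <= 1e-8 * en[1]))
  expect_lt(max(abs(res$state$u)), 1)
  expect_equal(max(res$report$halvings), 0)
})

test_that("Newton failure triggers step rejection with halving retries", {
  prob <- make_hyper_prob(1L)
  # violent initial velocity with a single allowed iteration and no retries
  v0 <- cbind(50 * prob$mesh$vertices[, 3], 0, 0)
  st <- initial_state(prob, v = v0)
  expect_error(
    advance(prob, st, 0.5, newton_settings(max_iters = 1L), max_halvings = 0L),
    class = "dvms_step_rejection")
  # with retries enabled the same step succeeds at a reduced dt
  st2 <- advance(prob, st, 0.5, newton_settings(max_iters = 12L),
                 max_halvings = 5L)
  expect_s3_class(st2, "dvms_state")
})

test_that("diagnostics report volumes, porosity and pore pressure", {
  probp <- make_poro_prob()
  stp <- initial_state(probp)
  dg <- diagnostics(probp, stp)
  expect_equal(dg$volume, 1, tolerance = 1e-12)
  expect_equal(dg$skeleton_volume, 1, tolerance = 1e-12)
  expect_equal(unique(round(dg$porosity, 12)), 0.1)
  pc0 <- pore_pressures(probp$pore, 0)$p_c
  expect_equal(dg$p_pore, rep(pc0, probp$n), tolerance = 1e-14)
})

test_that("checkerboard indicator separates oscillatory from smooth pressure", {
  prob <- make_hyper_prob(3L)
  smooth <- prob$mesh$vertices[, 1]
  osc <- (-1)^(round(prob$mesh$vertices[, 1] * 3))   # striped node pattern
  expect_gt(checkerboard_indicator(prob, osc),
            3 * checkerboard_indicator(prob, smooth))
})

test_that("incompressibility holds along a hyperelastic trajectory", {
  prob <- make_hyper_prob(2L)
  v0 <- cbind(0.3 * prob$mesh$vertices[, 3], 0, 0)
  res <- run_simulation(prob, dt = 0.05, nsteps = 20,
                        init = initial_state(prob, v = v0))
  expect_lt(abs(res$state$u[1, 1]), 1)  # sanity: finite motion happened
  expect_lt(max(abs(res$diag$volume - 1)), 1e-3)
})
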