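# Manufactured solutions: exact fields, derived forcing, error norms.

test_that("exact anisotropic shear fields match their closed forms", {
  X <- rbind(c(0.3, 0.7, 1), c(0, 0, 0), c(0.5, 0.2, 0.4))
  ex0 <- exact_hyper_shear(X, 0)
  expect_equal(ex0$lambda, rep(1, 3), tolerance = 1e-13)   # sin(0) = 0
  expect_equal(ex0$u, matrix(0, 3, 3), tolerance = 1e-15)
  # pressure vanishes at the origin for all times
  for (t in c(0.3, 1, 2.5))
    expect_equal(exact_hyper_shear(matrix(0, 1, 3), t)$p, 0, tolerance = 1e-14)
  # fibre stretch at Z = 1, t = pi/2 with alpha = beta = 0.1
  exl <- exact_hyper_shear(matrix(c(0.2, 0.9, 1), 1), pi / 2)
  expect_equal(exl$lambda, sqrt(10.95) / 3, tolerance = 1e-12)
})

test_that("exact poroelastic shear fields satisfy their identities", {
  X <- rbind(c(0.4, 0.8, 0.6), c(0.9, 0.1, 0.3))
  e0 <- exact_poro_shear(X, 0)
  expect_equal(e0$mu, c(0, 0))
  e <- exact_poro_shear(matrix(c(0.3, 0.2, 1), 1), pi / 2, alpha = 0.1, rho0f = 1)
  expect_equal(e$m, 0.1, tolerance = 1e-13)
  # at X = Y = 0 only the pressure-volume term survives
  for (t in c(0.4, 1.1)) {
    ez <- exact_poro_shear(matrix(c(0, 0, 0.7), 1), t, kappa_s = 1, rho0f = 1)
    expect_equal(ez$p_pore, 1 * 1 * 0.1 * 0.7 * sin(t), tolerance = 1e-12)
  }
  # J - 1 = mu identically: J = 1 + alpha Z sin t for this map
  cs <- manufactured_case("poro_iso_shear")
  set.seed(7)
  for (k in 1:20) {
    x <- runif(3); t1 <- runif(1, 0, 3)
    h <- 1e-6
    Fm <- diag(3)
    for (j in 1:3) {
      ep <- numeric(3); ep[j] <- h
      Fm[, j] <- Fm[, j] +
        (cs$u_fun(x[1] + ep[1], x[2] + ep[2], x[3] + ep[3], t1)[1, ] -
         cs$u_fun(x[1] - ep[1], x[2] - ep[2], x[3] - ep[3], t1)[1, ]) / (2 * h)
    }
    expect_equal(det(Fm), 1 + cs$mu_fun(x[1], x[2], x[3], t1)[1, 1],
                 tolerance = 1e-8)
  }
})

test_that("derived forcing closes the strong-form balances", {
  cs <- manufactured_case("hyper_aniso_shear")
  set.seed(8)
  expect_lt(derive_forcing_check(cs), 1e-10)
  csp <- manufactured_case("poro_iso_shear")
  expect_lt(derive_forcing_check(csp), 1e-10)

  # independent oracle: momentum residual with the stress divergence
  # recomputed by Richardson finite differences of the *numeric*
  # constitutive evaluation at the exact fields
  num_P <- function(cs, x, t) {
    h <- 1e-5
    Fm <- diag(3)
    for (j in 1:3) {
      e <- numeric(3); e[j] <- h
      Fm[, j] <- Fm[, j] +
        (cs$u_fun(x[1] + e[1], x[2] + e[2], x[3] + e[3], t)[1, ] -
         cs$u_fun(x[1] - e[1], x[2] - e[2], x[3] - e[3], t)[1, ]) / (2 * h)
    }
    f0 <- if (cs$kind == "hyper_aniso_shear") rep(1, 3) / sqrt(3) else NULL
    st <- state_from_F(Fm, f0 = f0)
    Fm %*% passive_stress(cs$model, st, p = cs$p_fun(x[1], x[2], x[3], t))
  }
  for (case in list(cs, csp)) {
    rmax <- 0
    for (k in 1:6) {
      x <- runif(3, 0.1, 0.9); t1 <- runif(1, 0.3, 2.7)
      divnum <- function(h) {
        out <- numeric(3)
        for (j in 1:3) {
          e <- numeric(3); e[j] <- h
          out <- out + (num_P(case, x + e, t1) - num_P(case, x - e, t1))[, j] / (2 * h)
        }
        out
      }
      dP <- (4 * divnum(5e-4) - divnum(1e-3)) / 3
      vdot <- -case$u_fun(x[1], x[2], x[3], t1)[1, ]  # u ~ f(X) sin t
      b <- case$b_fun(x[1], x[2], x[3], t1)[1, ]
      if (case$kind == "hyper_aniso_shear") {
        res <- case$rho0s * vdot - dP - case$rho0s * b
      } else {
        mu <- case$mu_fun(x[1], x[2], x[3], t1)[1, 1]
        res <- (case$rho0 + case$rho0f * mu) * vdot - dP - case$rho0 * b
      }
      rmax <- max(rmax, max(abs(res)))
    }
    expect_lt(rmax, 1e-7)
  }
})

test_that("L2 error norm and convergence orders behave as designed", {
  m <- unit_cube_mesh(3)
  lin <- function(X, t) 2 * X[, 1] - X[, 3] + 0.5
  nodal <- lin(m$vertices, 0)
  expect_lt(l2_error(nodal, lin, m, 0), 1e-13)

  # constructed h^2 sequence gives order exactly 2
  h <- c(1 / 2, 1 / 4, 1 / 8)
  ords <- convergence_orders(h, h^2)
  expect_equal(ords$ls_order, 2, tolerance = 1e-12)
  expect_equal(ords$pairwise, c(2, 2), tolerance = 1e-12)

  # interpolating a quadratic: error ratio 4 between h and h/2
  quad <- function(X, t) X[, 1]^2 + 0.3 * X[, 2] * X[, 3]
  e1 <- l2_error(quad(unit_cube_mesh(2)$vertices, 0), quad, unit_cube_mesh(2), 0)
  e2 <- l2_error(quad(unit_cube_mesh(4)$vertices, 0), quad, unit_cube_mesh(4), 0)
  expect_equal(e1 / e2, 4, tolerance = 0.05)

  expect_error(l2_error(nodal[-1], lin, m, 0), class = "dvms_invalid_argument")
})
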