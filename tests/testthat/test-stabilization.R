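# Shear-wave speed, stabilization time scale, CFL rule.

test_that("shear-wave speed from the energy derivatives", {
  id <- state_from_F(diag(3), f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  expect_equal(shear_wave_speed(neo_hookean(1), id, 1), sqrt(0.5),
               tolerance = 1e-14)
  expect_equal(shear_wave_speed(mooney_rivlin(0.8, 0.3), id, 2),
               sqrt((0.8 + 0.3) / 2), tolerance = 1e-14)
  # standard reinforced below unit fibre stretch equals neo-Hookean
  st <- state_from_F(diag(c(0.8, 1.2, 1.05)), f0 = c(1, 0, 0))
  expect_lt(st$I4f_bar, 1)
  expect_equal(shear_wave_speed(standard_reinforced(1, 10), st, 1),
               shear_wave_speed(neo_hookean(1), st, 1), tolerance = 1e-14)
  # above unit stretch the fibre term stiffens the wave
  st2 <- state_from_F(diag(c(1.3, 0.9, 0.9)), f0 = c(1, 0, 0))
  expect_gt(shear_wave_speed(standard_reinforced(1, 10), st2, 1),
            shear_wave_speed(neo_hookean(1), st2, 1))
  expect_error(shear_wave_speed(neo_hookean(1), id, 0),
               class = "dvms_invalid_argument")
})

test_that("tau saturates at both ends and is linear in between", {
  c_tau <- 0.02; dt_mu <- 0.4
  expect_equal(tau_dvms(c_tau, dt_mu, 10 * dt_mu), c_tau * dt_mu / 2)
  expect_equal(tau_dvms(c_tau, dt_mu, dt_mu / 1000), c_tau * dt_mu / 200)
  dt <- 0.07
  expect_equal(tau_dvms(c_tau, dt_mu, dt), c_tau * dt / 2)
  # nondecreasing in dt and dt_mu, and within the global bounds
  dts <- 10^seq(-5, 1, length.out = 40)
  taus <- tau_dvms(c_tau, dt_mu, dts)
  expect_true(all(diff(taus) >= 0))
  expect_true(all(taus >= c_tau * dt_mu / 200 - 1e-15))
  expect_true(all(taus <= c_tau * dt_mu / 2 + 1e-15))
  expect_true(all(tau_dvms(c_tau, c(0.1, 0.2), 0.05) ==
                  c(tau_dvms(c_tau, 0.1, 0.05), tau_dvms(c_tau, 0.2, 0.05))))
})

test_that("CFL time step dt = alpha * min h/c", {
  m <- build_box_mesh(c(0.1, 0.1, 0.1), c(1, 1, 1), dim = 3)
  out <- cfl_timestep(m, neo_hookean(1), rho0s = 1, alpha_cfl = 1)
  expect_equal(out$dt_mu, 0.1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(out$dt, 0.1 / sqrt(0.5), tolerance = 1e-12)
  half <- cfl_timestep(m, neo_hookean(1), rho0s = 1, alpha_cfl = 0.5)
  expect_equal(half$dt, out$dt / 2, tolerance = 1e-14)
})
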