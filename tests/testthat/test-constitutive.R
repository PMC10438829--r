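# Passive/active stresses, deviatoric projection, pore-fluid laws, sources.

test_that("reference state is stress-free; pressure enters as -p J C^-1", {
  id <- state_from_F(diag(3), f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  models <- list(neo_hookean(2), mooney_rivlin(1, 0.4),
                 standard_reinforced(2, 1),
                 holzapfel_ogden(1, 1.6, 2, 1.8, 0.5, 0.8, 0.3, 1.7))
  for (mdl in models) {
    expect_equal(passive_stress(mdl, id, p = 0), matrix(0, 3, 3),
                 tolerance = 1e-14)
    expect_equal(passive_stress(mdl, id, p = 2.5), -2.5 * diag(3),
                 tolerance = 1e-14)
  }
})

test_that("PK2 stress equals the symbolic derivative of the coded energy", {
  set.seed(5)
  f0 <- c(1, 1, 1) / sqrt(3)
  s0 <- c(1, -1, 0) / sqrt(2)
  models <- list(neo_hookean(1.3), mooney_rivlin(0.8, 0.25),
                 standard_reinforced(1, 0.7),
                 holzapfel_ogden(0.6, 1.6215, 1.2, 1.8268, 0.5, 0.7746,
                                 0.4, 1.695))
  for (mdl in models) {
    oracle <- symbolic_stress_oracle(mdl, f0, s0)
    n_ok <- 0
    while (n_ok < 25) {
      F <- matrix(random_F_batch(1)[1, ], 3, 3)
      st <- state_from_F(F, f0, s0)
      # the oracle is built on the fibre/sheet tension branch
      if (!is.null(st$I4f_bar) && (st$I4f_bar <= 1.01 || st$I4s_bar <= 1.01))
        next
      S_impl <- passive_stress(mdl, st, p = 0)
      S_sym <- oracle(st$C)
      expect_equal(S_impl, S_sym, tolerance = 1e-8)
      n_ok <- n_ok + 1
    }
  }
})

test_that("fibre terms vanish in compression (max clamp)", {
  # uniaxial compression along the fibre: I4f_bar < 1
  F <- diag(c(0.7, 1.3, 1.1))
  st_f <- state_from_F(F, f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  expect_lt(st_f$I4f_bar, 1)
  sr <- passive_stress(standard_reinforced(2, 5), st_f, 0)
  nh <- passive_stress(neo_hookean(2), st_f, 0)
  expect_equal(sr, nh, tolerance = 1e-12)

  # HO with both families in compression and zero fibre-sheet shear
  st2 <- state_from_F(diag(c(0.8, 0.9, 1.4)), f0 = c(1, 0, 0), s0 = c(0, 1, 0))
  expect_lt(st2$I4f_bar, 1); expect_lt(st2$I4s_bar, 1)
  expect_equal(st2$I8fs_bar, 0)
  ho <- holzapfel_ogden(1, 1.6, 50, 1.8, 30, 0.8, 20, 1.7)
  ho_iso <- holzapfel_ogden(1, 1.6, 1e-12, 1.8, 1e-12, 0.8, 1e-12, 1.7)
  expect_equal(passive_stress(ho, st2, 0), passive_stress(ho_iso, st2, 0),
               tolerance = 1e-10)
})

test_that("deviatoric projection annihilates C and matches hand values", {
  C <- diag(3)
  expect_equal(dev_projection(solve(C), C), matrix(0, 3, 3), tolerance = 1e-14)
  expect_equal(dev_projection(diag(c(1, 0, 0)), diag(3)),
               diag(c(2 / 3, -1 / 3, -1 / 3)), tolerance = 1e-14)
  set.seed(6)
  for (k in 1:20) {
    A <- matrix(rnorm(9), 3); S <- A + t(A)
    F <- matrix(random_F_batch(1)[1, ], 3, 3); C <- t(F) %*% F
    expect_equal(sum(dev_projection(S, C) * C), 0, tolerance = 1e-12 * sum(abs(S)))
  }
  expect_error(dev_projection(diag(3), diag(c(1, -1, 1))),
               class = "dvms_invalid_argument")
})

test_that("active stress follows the length-dependent tension law", {
  act <- active_model(function(t) 10 * t)
  f0 <- c(0, 0, 1)
  expect_equal(active_stress(act, 0, 1.2, f0)$S_a, matrix(0, 3, 3))
  expect_equal(active_stress(act, 1, 1, f0)$T, 10)
  out <- active_stress(act, 1, 1.1, f0, C = diag(3))
  expect_equal(out$T, 10 * (1 + 4.9 * 0.1), tolerance = 1e-12)
  expect_equal(out$S_a, 14.9 * (f0 %o% f0), tolerance = 1e-12)
  expect_equal(sum(out$DEV * diag(3)), 0, tolerance = 1e-12)
})

test_that("pore pressures: quadratic and Bruinsma laws with compaction", {
  pq <- pore_fluid_model("quadratic", kappa_s = 2, c = 0, phi0 = 0.1,
                         rho0f = 1, K = 1)
  expect_equal(pore_pressures(pq, 0)$p_pv, 0)
  expect_equal(pore_pressures(pq, 3)$p_pv, 6)

  # compaction peak: p_c = c exactly at m + phi0 = phi_crit
  pc <- pore_fluid_model("quadratic", kappa_s = 2, c = 5, phi0 = 0.1,
                         rho0f = 1, K = 1)
  at_crit <- pore_pressures(pc, pc$phi_crit - pc$phi0)
  expect_equal(at_crit$p_c, 5, tolerance = 1e-14)
  # decays away from the floor and is monotone decreasing in m above it
  ms <- seq(pc$phi_crit - pc$phi0 + 1e-4, 0.1, length.out = 50)
  pcs <- pore_pressures(pc, ms)$p_c
  expect_true(all(diff(pcs) < 0))
  expect_lt(pore_pressures(pc, 0.1)$p_c, 5e-3)

  pb <- pore_fluid_model("bruinsma", q1 = 220, q2 = 10090, q3 = 75, c = 0,
                         phi0 = 0.1, rho0f = 1, K = 1)
  expect_equal(pore_pressures(pb, 0)$p_pv, 10090 * log(75), tolerance = 1e-10)
  expect_error(pore_pressures(pb, -0.2), class = "dvms_numerical_domain")

  # analytic derivative vs central finite differences
  for (pore in list(pq, pc, pb)) {
    for (m0 in c(-0.05, 0.02, 0.3)) {
      h <- 1e-6
      fd <- (sum(unlist(pore_pressures(pore, m0 + h)[c("p_pv", "p_c")])) -
             sum(unlist(pore_pressures(pore, m0 - h)[c("p_pv", "p_c")]))) / (2 * h)
      expect_equal(pore_pressures(pore, m0)$dp_dm, fd,
                   tolerance = 1e-6 * max(1, abs(fd)))
    }
  }
})

test_that("mass-dependent permeability K0m = K0 d(pPV+pc)/dm", {
  pq <- pore_fluid_model("quadratic", kappa_s = 3, c = 0, phi0 = 0.1,
                         rho0f = 1, K = 0.5)
  id <- state_from_F(diag(3))
  expect_equal(mass_permeability(pq, id, 0), 3 * 0.5 * diag(3),
               tolerance = 1e-12)
  st <- state_from_F(diag(c(2, 1, 1)))
  expect_equal(mass_permeability(pq, st, 0.1),
               3 * diag(c(0.25, 1, 1)), tolerance = 1e-12)
})

test_that("mixture density and source models", {
  mx <- mixture_densities(1.2, 1.05, 0.1)
  expect_equal(mx$rho0, 1.05 * 0.1 + 1.2 * 0.9)

  full <- source_model("full", beta_so = 3e-6, beta_si = 3e-6,
                       p_so = 2.7e4, p_si = 1.3e4)
  peq <- (3e-6 * 2.7e4 + 3e-6 * 1.3e4) / (6e-6)
  expect_equal(source_eval(full, peq)$S, 0, tolerance = 1e-12)
  prop <- source_model("proportional", beta_so = 1e-5)
  expect_equal(source_eval(prop, 100)$S, 1e-3)
  sink <- source_model("sink_only", beta_si = 0.01, p_si = 0.3)
  expect_equal(source_eval(sink, 0.3)$S, 0)
  expect_equal(source_eval(sink, 1.3)$S, -0.01)
  # derivatives are the slopes
  for (src in list(full, prop, sink)) {
    ev <- source_eval(src, c(0, 1))
    expect_lt(abs(ev$dS_dp[1] - diff(ev$S)), 1e-9 * max(1e-6, abs(ev$dS_dp[1])))
  }
})
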