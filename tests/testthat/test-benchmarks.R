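# Benchmark fixtures: waveforms, case constants, null tests, LV geometry.

test_that("endocardial pressure and active tension waveforms", {
  w <- lv_waveforms()
  expect_equal(w$p_endo(0.3), 1.067)          # diastolic plateau
  expect_equal(w$Ta(0.4), 0)                  # no tension before systole
  expect_equal(w$p_endo(0.1), 1.067 * 0.5)    # linear filling ramp
  # continuity at the systolic switch t = 0.65 (branches are mirror images)
  eps <- 1e-9
  expect_equal(w$p_endo(0.65 - eps), w$p_endo(0.65 + eps), tolerance = 1e-9)
  expect_equal(w$Ta(0.65 - eps), w$Ta(0.65 + eps), tolerance = 1e-9)
  # cycle periodicity
  ts <- c(0.05, 0.3, 0.55, 0.7)
  expect_equal(w$p_endo(ts + 0.8), w$p_endo(ts), tolerance = 1e-12)
  expect_equal(w$Ta(ts + 1.6), w$Ta(ts), tolerance = 1e-12)
  # asymptotic systolic peak: plateau + ramp amplitude
  expect_equal(round(waveform_systolic_peak(w), 2), 14.53)
  wc <- lv_waveforms("cgs")
  expect_equal(wc$p_endo(0.3), 1.067e4)
  # swelling ramp
  expect_equal(swelling_ramp(0), 0)
  expect_equal(swelling_ramp(Inf), 0.5)
})

test_that("benchmark cases carry the published constants", {
  res <- run_compressed_block("hyper", h = 2.5, t_end = 0.2)
  mdl <- res$problem$model
  expect_equal(mdl$G, 80.194); expect_equal(mdl$Gf, 80.194)
  expect_equal(res$problem$rho0s, 1)
  expect_equal(res$problem$frame$f0[1, ],
               c(0.866, 0.5, 0) / sqrt(0.866^2 + 0.5^2), tolerance = 1e-12)

  resp <- run_compressed_block("poro", h = 2.5, t_end = 0.1)
  expect_equal(resp$problem$pore$phi0, 0.1)
  expect_equal(resp$problem$pore$K, 1e-5 * diag(3))
  expect_equal(resp$problem$source$beta_so, 1e-5)

  resc <- run_column("bending", h = 1, dt = 0.01, t_end = 0.02)
  expect_equal(resc$problem$model$G, 5.67e6)
  expect_equal(resc$problem$rho0s, 1100)
  expect_equal(resc$problem$frame$f0[1, ],
               c(0, 0.5, 0.866) / sqrt(0.5^2 + 0.866^2), tolerance = 1e-12)
})

test_that("zero load leaves the compressed block at rest", {
  res <- run_compressed_block("hyper", h = 2.5, t_end = 0.1, load = 0)
  expect_lt(max(abs(res$state$u)), 1e-10)
  expect_lt(max(abs(res$state$p)), 1e-6)
})

test_that("columns stay at rest without initial velocity, move with it", {
  # at rest the residual is pure assembly roundoff (~1e-9 on a Pa-scale
  # modulus); an absolute tolerance far below any physical residual keeps
  # the solver from chasing cancellation noise
  res0 <- run_column("bending", h = 1, dt = 0.01, t_end = 0.03, v0_scale = 0,
                     settings = newton_settings(abs_tol = 1e-6))
  expect_lt(max(abs(res0$state$u)), 1e-10)
  res <- run_column("twisting", h = 1, dt = 0.005, t_end = 0.02)
  expect_gt(max(abs(res$state$u)), 1e-4)
})

test_that("swelling cube: zero ramp means zero deformation; ramp drives swelling", {
  res0 <- run_swelling_cube(divisions = 2, dt = 0.05, t_end = 0.2,
                            ramp_amplitude = 0)
  expect_lt(max(abs(res0$state$u)), 1e-10)
  expect_lt(max(abs(res0$state$mu)), 1e-12)

  res <- run_swelling_cube(divisions = 2, dt = 0.05, t_end = 0.4)
  expect_gt(diagnostics(res$problem, res$state)$volume, (0.01)^3 * (1 + 1e-4))
  # added mass is largest at the ramped face, decreasing toward the outlet
  mu <- res$state$mu; X <- res$problem$mesh$vertices
  expect_gt(mean(mu[X[, 1] < 1e-9]), mean(mu[X[, 1] > 0.01 - 1e-9]) + 1e-4)
})

test_that("porous compressed block couples source to added mass", {
  res <- run_compressed_block("poro", h = 2.5, t_end = 0.2)
  dg <- diagnostics(res$problem, res$state)
  expect_gt(max(abs(dg$p_pore)), 1e-6)
  expect_gt(max(abs(res$state$mu)), 1e-10)  # source feeds the pores
})

test_that("idealized LV mesh is well-formed with a unit fibre architecture", {
  lv <- build_lv_mesh(n_trans = 1, n_circ = 8, n_long = 4)
  m <- lv$mesh
  expect_true(all(cell_volumes(m) > 0))
  expect_setequal(unique(m$facet_tag), c("base", "endo", "epi", "apex"))
  expect_true(all(abs(m$vertices[unique(as.vector(
    m$facets[m$facet_tag == "base", ])), 3]) < 1e-9))
  fr <- lv_fibre_field(lv)
  expect_equal(rowSums(fr$f0^2), rep(1, ncells(m)), tolerance = 1e-12)
  expect_equal(rowSums(fr$s0^2), rep(1, ncells(m)), tolerance = 1e-12)
  expect_lt(max(abs(rowSums(fr$f0 * fr$s0))), 1e-10)
})

test_that("LV demo relaxes toward the source/sink equilibrium without loads", {
  res <- suppressWarnings(run_lv_demo(cycles = 0.05,
                     geometry = list(n_trans = 1, n_circ = 6, n_long = 3),
                     dt = 0.005, pressure_scale = 0, tension_scale = 0))
  s <- res$series
  # equilibrium pore pressure of the full source model
  peq <- (3e-6 * 2.7e4 + 3e-6 * 1.3e4) / 6e-6
  # the Bruinsma law has a large positive reference pressure, so with zero
  # loads the pore pressure relaxes *down* to the source/sink equilibrium
  gap <- abs(s$ppore_endo - peq)
  expect_lt(tail(gap, 1), 0.1 * gap[1])
  expect_lt(max(abs(s$m_endo)), 5e-3)         # equilibrium added mass is small
})

test_that("LV diastolic inflation gives negative skeleton pressure", {
  res <- suppressWarnings(run_lv_demo(cycles = 0.45 / 0.8,
                     geometry = list(n_trans = 1, n_circ = 6, n_long = 3),
                     dt = 0.0025, tension_scale = 0))
  s <- res$series
  last <- tail(s, 1)
  expect_lt(last$p_endo, 0)
  expect_lt(last$p_epi, 0)
  # inflation increased the cavity-side wall motion; volume stays near the
  # reference because the added fluid mass is still small
  expect_gt(max(abs(res$result$state$u)), 1e-3)
})
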