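# Benchmark case drivers: 2D compressed block (hyperelastic and porous),
# 3D bending/twisting columns, poroelastic swelling and shrinking cubes,
# and the idealized left-ventricle perfusion demonstration, each with the
# published material constants as defaults.

#' Left-ventricle driving waveforms
#'
#' Piecewise endocardial pressure (diastolic ramp to a 1.067 kPa plateau,
#' then a systolic exponential rise of amplitude 13.46 kPa and symmetric
#' decay) and active-tension waveform (amplitude 84.26 kPa during systole),
#' cycle-periodic with period 0.8 s. `units = "cgs"` rescales pressures to
#' dyne/cm^2 (1 kPa = 1e4 dyne/cm^2).
#'
#' @param units `"kPa"` or `"cgs"`
#' @return a `dvms_waveforms` list with `p_endo(t)`, `Ta(t)`, the `period`,
#'   and the defining constants
#' @export
lv_waveforms <- function(units = c("kPa", "cgs")) {
  units <- match.arg(units)
  sc <- if (units == "cgs") 1e4 else 1
  p_dia <- 1.067; p_sys_amp <- 13.46; tau_p <- 0.004
  Ta_amp <- 84.26; tau_a <- 0.005
  period <- 0.8
  p_endo <- function(t) {
    tm <- t %% period
    sc * ifelse(tm < 0.2, p_dia * tm / 0.2,
         ifelse(tm < 0.5, p_dia,
         ifelse(tm < 0.65, p_dia + p_sys_amp * (1 - exp(-(tm - 0.5)^2 / tau_p)),
                p_dia + p_sys_amp * (1 - exp(-(period - tm)^2 / tau_p)))))
  }
  Ta <- function(t) {
    tm <- t %% period
    sc * ifelse(tm < 0.5, 0,
         ifelse(tm < 0.65, Ta_amp * (1 - exp(-(tm - 0.5)^2 / tau_a)),
                Ta_amp * (1 - exp(-(period - tm)^2 / tau_a))))
  }
  structure(list(p_endo = p_endo, Ta = Ta, period = period,
                 p_dia = sc * p_dia, p_sys_amp = sc * p_sys_amp,
                 Ta_amp = sc * Ta_amp, units = units),
            class = "dvms_waveforms")
}

#' Evaluate the waveforms
#'
#' @param w a [lv_waveforms()]
#' @param t time(s)
#' @return data frame with `t`, `p_endo`, `Ta`
#' @export
waveform_eval <- function(w, t) {
  data.frame(t = t, p_endo = w$p_endo(t), Ta = w$Ta(t))
}

#' Asymptotic systolic peak pressure of the waveform
#'
#' The diastolic plateau plus the full systolic exponential-ramp amplitude
#' (the value the systolic branch approaches as the ramp saturates).
#'
#' @param w a [lv_waveforms()]
#' @return peak pressure in the waveform's units
#' @export
waveform_systolic_peak <- function(w) w$p_dia + w$p_sys_amp

#' Swelling-cube added-mass ramp
#'
#' Dimensionless boundary added mass 0.5 (1 - exp(-t^2/0.25)) applied at
#' the inflow face of the swelling cube.
#'
#' @param t time(s)
#' @return dimensionless added mass
#' @export
swelling_ramp <- function(t) 0.5 * (1 - exp(-t^2 / 0.25))

# ---------------------------------------------------------------------------

#' Compressed anisotropic block (2D)
#'
#' A 10 cm x 10 cm plane-strain block of fibre-reinforced material
#' (G = Gf = 80.194 dyne/cm^2, f0 = (0.866, 0.5), rho0s = 1 g/cm^3), with
#' the vertical displacement fixed on the bottom edge, the horizontal
#' displacement fixed on the top edge, traction-free sides, and a constant
#' vertical load of 200 dyne/cm^2 on the central half of the top edge.
#' The porous variant adds phi0 = 0.1, K = 1e-5 I cm^4/(dyne s), and a
#' source proportional to the pore pressure (beta_so = 1e-5).
#' CGS units throughout.
#'
#' @param variant `"hyper"` or `"poro"`
#' @param h target mesh spacing in cm (the paper uses 5 cm down to 0.2 cm)
#' @param dt time step in s (default scales as 0.02 h, following the
#'   published pairings)
#' @param t_end end time in s
#' @param c_tau stabilization constant (0 gives the unstabilized P1-P1
#'   method)
#' @param load vertical load magnitude (dyne/cm^2)
#' @param kappa_s pore stiffness (dyne/cm^2; the porous variant's
#'   pressure-volume constant is not fixed by the benchmark and defaults to
#'   the load scale)
#' @param settings Newton settings
#' @return a `dvms_result`; probe 1 is the top-surface midpoint A
#' @export
run_compressed_block <- function(variant = c("hyper", "poro"), h = 1.25,
                                 dt = 0.02 * h, t_end = 0.5, c_tau = 0.02,
                                 load = 200, kappa_s = 200,
                                 settings = newton_settings()) {
  variant <- match.arg(variant)
  L <- 10
  div <- max(2L, round(L / h))
  mesh <- build_box_mesh(c(L, L), c(div, div), dim = 2)
  in_mid <- function(X) {  # facet centroid within the central half
    xc <- mean(X[, 1])
    xc > L / 4 - 1e-9 && xc < 3 * L / 4 + 1e-9
  }
  on_top <- function(X) all(abs(X[, 2] - L) < 1e-9)
  mesh <- tag_boundary(mesh, list(
    bottom = on_plane(2, 0),
    top_mid = function(X) on_top(X) && in_mid(X),
    top = function(X) on_top(X) && !in_mid(X),
    side = "otherwise"))
  model <- standard_reinforced(80.194, 80.194)
  frame <- fibre_frame(c(0.866, 0.5))
  bcs <- list(
    velocity = list(bottom = list(comps = 2L, value = 0),
                    top_mid = list(comps = 1L, value = 0)),
    traction = list(top_mid = function(X, t) cbind(0 * X[, 1], -load)))
  if (any(mesh$facet_tag == "top"))
    bcs$velocity$top <- list(comps = 1L, value = 0)
  if (variant == "hyper") {
    prob <- dvms_problem(mesh, "hyper", model, rho0s = 1, frame = frame,
                         bcs = bcs, c_tau = c_tau)
  } else {
    pore <- pore_fluid_model("quadratic", kappa_s = kappa_s, c = 0,
                             phi0 = 0.1, rho0f = 1, K = 1e-5)
    prob <- dvms_problem(mesh, "poro", model, rho0s = 1, frame = frame,
                         pore = pore,
                         source = source_model("proportional", beta_so = 1e-5),
                         bcs = bcs, c_tau = c_tau)
  }
  run_simulation(prob, dt = dt, t_end = t_end, settings = settings,
                 probes = matrix(c(L / 2, L), 1))
}

#' Bending and twisting anisotropic columns (3D)
#'
#' A 1 m x 6 m x 1 m column (axis along Y, cross-section centred on the
#' axis), standard reinforced material with G = Gf = 5.67e6 Pa,
#' f0 = (0, 0.5, 0.866), rho0s = 1100 kg/m^3; the base plane Y = 0 is
#' fixed, all other faces traction-free. The bending case starts from
#' v(X, 0) = (5Y/3, 0, 0) m/s; the twisting case from
#' v(X, 0) = 100 sin(pi Y / 12) (Z, 0, -X) m/s.
#'
#' @param case `"bending"` or `"twisting"`
#' @param h mesh spacing in m (0.5, 0.25, ...)
#' @param dt time step (s); default 0.01 h, following the published
#'   pairings
#' @param t_end end time (s)
#' @param alpha_cfl if not `NULL`, override dt with the CFL rule
#' @param c_tau stabilization constant
#' @param Gf fibre modulus (Pa); 0 removes the reinforcement
#' @param v0_scale multiplier on the initial velocity field (0 leaves the
#'   column at rest)
#' @param settings Newton settings
#' @return a `dvms_result`; probe 1 is the column tip centre
#' @export
run_column <- function(case = c("bending", "twisting"), h = 0.5,
                       dt = 0.01 * h, t_end = 0.5, alpha_cfl = NULL,
                       c_tau = 0.02, Gf = 5.67e6, v0_scale = 1,
                       settings = newton_settings()) {
  case <- match.arg(case)
  dims <- c(1, 6, 1)
  div <- pmax(1L, round(dims / h))
  mesh <- build_box_mesh(dims, div, dim = 3)
  mesh$vertices[, 1] <- mesh$vertices[, 1] - 0.5  # centre the cross-section
  mesh$vertices[, 3] <- mesh$vertices[, 3] - 0.5
  mesh <- tag_boundary(mesh, list(base = on_plane(2, 0), free = "otherwise"))
  model <- standard_reinforced(5.67e6, Gf)
  frame <- fibre_frame(c(0, 0.5, 0.866))
  prob <- dvms_problem(mesh, "hyper", model, rho0s = 1100, frame = frame,
                       bcs = list(velocity = list(base = 0)), c_tau = c_tau)
  X <- mesh$vertices
  v0 <- v0_scale * (if (case == "bending") cbind(5 / 3 * X[, 2], 0, 0)
        else 100 * sin(pi * X[, 2] / 12) * cbind(X[, 3], 0, -X[, 1]))
  if (!is.null(alpha_cfl))
    dt <- cfl_timestep(mesh, model, 1100, alpha_cfl,
                       frame = frame)$dt
  run_simulation(prob, dt = dt, t_end = t_end,
                 init = initial_state(prob, v = v0),
                 settings = settings,
                 probes = matrix(c(0, 6, 0), 1))
}

#' Poroelastic swelling cube
#'
#' A 1 cm cube (SI units) of Mooney-Rivlin skeleton (C1 = 2 kPa,
#' C2 = 0.033 kPa), rho0s = rho0f = 1000 kg/m^3, phi0 = 0.1,
#' kappa_s = 2 kPa, K = 1e-4 m^2/(kPa s). No external loads: swelling is
#' driven purely by Darcy flow between the left face, where the added mass
#' is ramped up as [swelling_ramp()], and the right face held at zero; the
#' other four faces are impermeable.
#'
#' @param divisions elements per edge
#' @param dt time step (s)
#' @param t_end end time (s)
#' @param ramp_amplitude scale factor on the boundary ramp (0 gives the
#'   no-load null test)
#' @param c_tau stabilization constant
#' @param settings Newton settings
#' @return a `dvms_result`; probes are the cube centre and the (0.5, 0.5,
#'   0.5) cm corner-quadrant point
#' @export
run_swelling_cube <- function(divisions = 4, dt = 0.02, t_end = 2,
                              ramp_amplitude = 1, c_tau = 0.02,
                              settings = newton_settings(jacobian_refresh = "lazy",
                                                          max_iters = 30L)) {
  L <- 0.01
  mesh <- build_box_mesh(rep(L, 3), rep(divisions, 3), dim = 3)
  mesh <- tag_boundary(mesh, list(left = on_plane(1, 0), right = on_plane(1, L),
                                  lateral = "otherwise"))
  model <- mooney_rivlin(2000, 33)
  pore <- pore_fluid_model("quadratic", kappa_s = 2000, c = 0, phi0 = 0.1,
                           rho0f = 1000, K = 1e-7)
  prob <- dvms_problem(mesh, "poro", model, rho0s = 1000, pore = pore,
                       bcs = list(
                         mass = list(left = function(X, t)
                                       rep(ramp_amplitude * swelling_ramp(t), nrow(X)),
                                     right = function(X, t) rep(0, nrow(X)))),
                       c_tau = c_tau, constraint_relax = 0.5)
  run_simulation(prob, dt = dt, t_end = t_end, settings = settings,
                 probes = rbind(c(0, 0, 0), rep(L / 2, 3)),
                 steady_tol = 1e-6)
}

#' Poroelastic shrinking cube
#'
#' A 1 mm cube (SI units), Mooney-Rivlin skeleton and pore law as in
#' [run_swelling_cube()] but K = 2.5e-3 m^2/(kPa s). Normal displacement is
#' fixed on the three coordinate planes; compressive normal tractions are
#' ramped on the opposite three faces; a pressure-dependent sink
#' S = -beta_si (p_pore - p_si) with beta_si = 0.01 1/(kPa s), p_si = 0
#' drains the pore fluid, and the added mass has zero normal gradient on
#' all faces. The compaction scale follows the running-maximum pore
#' pressure (`compaction_update = "history_max"`), which arrests drainage
#' at the porosity floor: at steady state the volume reduction approaches
#' phi0 - phi_crit, just under 10 percent.
#'
#' @param divisions elements per edge
#' @param dt time step (s)
#' @param t_end maximum simulated time (s); the run stops earlier at the
#'   steady state
#' @param traction peak compressive normal traction (Pa), ramped over
#'   `t_ramp`; a fraction of the skeleton modulus suffices (the steady
#'   reduction is set by the porosity floor once drainage completes)
#' @param t_ramp ramp duration (s)
#' @param c_tau stabilization constant
#' @param settings Newton settings
#' @return a `dvms_result`; probe 1 is the cube midpoint
#' @export
run_shrinking_cube <- function(divisions = 10, dt = 0.02, t_end = 60,
                               traction = 400, t_ramp = 0.5, c_tau = 0.02,
                               settings = newton_settings(jacobian_refresh = "lazy",
                                                          max_iters = 30L)) {
  L <- 1e-3
  mesh <- build_box_mesh(rep(L, 3), rep(divisions, 3), dim = 3)
  mesh <- tag_boundary(mesh, list(
    xmin = on_plane(1, 0), ymin = on_plane(2, 0), zmin = on_plane(3, 0),
    xmax = on_plane(1, L), ymax = on_plane(2, L), zmax = on_plane(3, L)))
  model <- mooney_rivlin(2000, 33)
  pore <- pore_fluid_model("quadratic", kappa_s = 2000, c = 0, phi0 = 0.1,
                           rho0f = 1000, K = 2.5e-6)
  ramp <- function(t) traction * pmin(t / t_ramp, 1)
  trac_on <- function(nrm) {
    force(nrm)
    function(X, t) matrix(-ramp(t) * nrm, nrow(X), 3, byrow = TRUE)
  }
  prob <- dvms_problem(mesh, "poro", model, rho0s = 1000, pore = pore,
                       source = source_model("sink_only", beta_si = 1e-5, p_si = 0),
                       bcs = list(
                         velocity = list(xmin = list(comps = 1L, value = 0),
                                         ymin = list(comps = 2L, value = 0),
                                         zmin = list(comps = 3L, value = 0)),
                         traction = list(xmax = trac_on(c(1, 0, 0)),
                                         ymax = trac_on(c(0, 1, 0)),
                                         zmax = trac_on(c(0, 0, 1)))),
                       c_tau = c_tau, compaction_update = "history_max",
                       constraint_relax = 0.5)
  run_simulation(prob, dt = dt, t_end = t_end, settings = settings,
                 probes = matrix(rep(L / 2, 3), 1),
                 steady_tol = 1e-6)
}

#' Idealized left-ventricle perfusion demonstration
#'
#' Poroelastodynamics on the idealized half-ellipsoid wall of
#' [build_lv_mesh()] with the rule-based fibre architecture of
#' [lv_fibre_field()], the Holzapfel-Ogden passive law, active fibre
#' tension and endocardial pressure waveforms of [lv_waveforms()], the
#' Bruinsma pore pressure-volume law, and the pressure-dependent
#' source/sink model. CGS units (cm, g, s, dyne). The base is constrained
#' against normal (longitudinal) and circumferential motion, leaving
#' radial expansion free. The endocardial pressure acts as a follower load
#' on the deformed surface through the cofactor.
#'
#' @param cycles number of 0.8 s cardiac cycles
#' @param geometry list of [build_lv_mesh()] arguments overriding the
#'   defaults
#' @param dt time step (s); default from the CFL rule at the reference
#'   state with `alpha_cfl`
#' @param alpha_cfl CFL number used when `dt` is `NULL`
#' @param pressure_scale,tension_scale multipliers on the endocardial
#'   pressure and active tension waveforms (1 = published amplitudes)
#' @param settings Newton settings
#' @return list with the `dvms_result`, per-step surface-averaged series
#'   (`series`: volume, skeleton volume, mean m / p / p_pore / S on the
#'   endo- and epicardial surfaces), and the waveforms used
#' @export
run_lv_demo <- function(cycles = 1, geometry = list(), dt = NULL,
                        alpha_cfl = 0.5, pressure_scale = 1,
                        tension_scale = 1,
                        settings = newton_settings(jacobian_refresh = "lazy",
                                                          max_iters = 30L)) {
  lv <- do.call(build_lv_mesh, geometry)
  mesh <- lv$mesh
  frame <- lv_fibre_field(lv)
  model <- holzapfel_ogden(a = 2244.87, b = 1.6215, af = 24267, bf = 1.8268,
                           as = 5562.38, bs = 0.7746, afs = 3905.16,
                           bfs = 1.695)
  pore <- pore_fluid_model("bruinsma", q1 = 220, q2 = 10090, q3 = 75,
                           c = 0, phi0 = 0.1, rho0f = 1, K = 1e-8)
  wf <- lv_waveforms("cgs")
  circum <- function(X) {
    th <- atan2(X[, 2], X[, 1])
    cbind(-sin(th), cos(th), 0)
  }
  prob <- dvms_problem(
    mesh, "poro", model, rho0s = 1, frame = frame,
    active = active_model(function(t) tension_scale * wf$Ta(t)),
    pore = pore,
    source = source_model("full", beta_so = 3e-6, beta_si = 3e-6,
                          p_so = 2.7e4, p_si = 1.3e4),
    bcs = list(velocity = list(base = list(comps = 3L, value = 0)),
               pin_direction = list(base = list(dir = circum, k = 1e6)),
               follower = list(endo = function(t) pressure_scale * wf$p_endo(t))),
    c_tau = 0.02, constraint_relax = 0.5)
  if (is.null(dt))
    dt <- cfl_timestep(mesh, model, 1, alpha_cfl, frame = frame)$dt
  # surface-node sets for the averaged series
  surf_nodes <- function(tag)
    sort(unique(as.vector(mesh$facets[mesh$facet_tag == tag, , drop = FALSE])))
  endo_n <- surf_nodes("endo"); epi_n <- surf_nodes("epi")
  series <- list()
  obs <- function(state, prob) {
    dg <- diagnostics(prob, state)
    src <- source_eval(prob$source, dg$p_pore)
    series[[length(series) + 1L]] <<- data.frame(
      t = state$t, volume = dg$volume, skeleton_volume = dg$skeleton_volume,
      m_endo = mean(prob$pore$rho0f * state$mu[endo_n]),
      m_epi = mean(prob$pore$rho0f * state$mu[epi_n]),
      p_endo = mean(state$p[endo_n]), p_epi = mean(state$p[epi_n]),
      ppore_endo = mean(dg$p_pore[endo_n]), ppore_epi = mean(dg$p_pore[epi_n]),
      S_endo = mean(src$S[endo_n]), S_epi = mean(src$S[epi_n]))
  }
  res <- run_simulation(prob, dt = dt, t_end = cycles * wf$period,
                        settings = settings, observer = obs)
  list(result = res, series = do.call(rbind, series), waveforms = wf,
       mesh = mesh, problem = prob)
}

#' Dispatch a named benchmark case
#'
#' Thin dispatcher used by the command-line interface.
#'
#' @param name one of `"compressed-block"`, `"compressed-block-poro"`,
#'   `"bending"`, `"twisting"`, `"swelling"`, `"shrinking"`, `"lv-demo"`,
#'   `"shear-aniso"`, `"shear-poro"`
#' @param ... arguments forwarded to the case driver
#' @return the driver's return value
#' @export
run_benchmark <- function(name, ...) {
  switch(name,
    "compressed-block" = run_compressed_block("hyper", ...),
    "compressed-block-poro" = run_compressed_block("poro", ...),
    "bending" = run_column("bending", ...),
    "twisting" = run_column("twisting", ...),
    "swelling" = run_swelling_cube(...),
    "shrinking" = run_shrinking_cube(...),
    "lv-demo" = run_lv_demo(...),
    "shear-aniso" = run_manufactured(manufactured_case("hyper_aniso_shear"), ...),
    "shear-poro" = run_manufactured(manufactured_case("poro_iso_shear"), ...),
    dvms_error(paste("unknown benchmark", name), "dvms_invalid_argument"))
}
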