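# D-VMS stabilization: shear-wave speed, intrinsic time scale tau, and the
# CFL time-step rule.

#' Element shear-wave speed
#'
#' c_mu = sqrt((W1 + W2 + W4f + W4s + W8fs) / rho0s), with the W_i the
#' derivatives of the isochoric strain energy with respect to the
#' (distortional) invariants, evaluated at the element's current
#' deformation state. Fibre/sheet terms carry the same in-compression clamp
#' as the stress, so they vanish below unit stretch. The mixed-invariant
#' contribution W8fs can be negative under reversed fibre-sheet shear; the
#' sum under the square root is floored at a small positive fraction of
#' W1 + W2 to keep the speed defined.
#'
#' @param model a `dvms_material`
#' @param state a kinematic state from [kinematic_state()] (or a batch
#'   state used internally)
#' @param rho0s skeleton reference density
#' @return shear-wave speed (length/time), vectorized over elements
#' @export
shear_wave_speed <- function(model, state, rho0s) {
  if (rho0s <= 0) dvms_error("rho0s must be > 0", "dvms_invalid_argument")
  st <- if (!is.null(state$E)) state else state_to_batch(state)
  W <- bt_W_derivs(model, st)
  tot <- W$W1 + W$W2 + W$W4f + W$W4s + W$W8fs
  if (any(!is.finite(tot)))
    dvms_error("non-finite energy derivatives", "dvms_numerical_domain")
  tot <- pmax(tot, 1e-8 * pmax(W$W1 + W$W2, .Machine$double.xmin))
  sqrt(tot / rho0s)
}

#' D-VMS stabilization time scale
#'
#' tau = (c_tau / 2) max(dt_mu / 100, min(dt_mu, dt)): proportional to the
#' time step in the interior regime, saturating at c_tau dt_mu / 2 for
#' large steps and at c_tau dt_mu / 200 as dt -> 0.
#'
#' @param c_tau dimensionless stabilization constant (typical range
#'   0.01-0.03; the unstabilized equal-order method is recovered at 0)
#' @param dt_mu global shear-wave time scale min_e h^e / c_mu^e
#' @param dt time-step size
#' @return tau (time units)
#' @export
tau_dvms <- function(c_tau, dt_mu, dt) {
  stopifnot(c_tau >= 0, dt_mu > 0, dt > 0)
  c_tau / 2 * pmax(dt_mu / 100, pmin(dt_mu, dt))
}

#' CFL-based time step
#'
#' dt = alpha_cfl * dt_mu with dt_mu = min_e h^e / c_mu^e, evaluated at a
#' given displacement state (the reference state by default). alpha_cfl in
#' [0.1, 1] keeps the Newton iteration count low for strongly nonlinear
#' steps.
#'
#' @param mesh a `dvms_mesh`
#' @param model a `dvms_material`
#' @param rho0s skeleton reference density
#' @param alpha_cfl CFL number (> 0)
#' @param u optional nodal displacement at which to evaluate the wave speed
#' @param frame optional fibre frame (needed by anisotropic models)
#' @return list with `dt` and `dt_mu`
#' @export
cfl_timestep <- function(mesh, model, rho0s, alpha_cfl = 0.5, u = NULL,
                         frame = NULL) {
  stopifnot(alpha_cfl > 0)
  geo <- p1_geometry(mesh)
  if (is.null(u)) u <- matrix(0, nvertices(mesh), mesh$dim)
  st <- bt_kinematics(bt_grad_u(mesh, geo, u), frame = frame)
  cmu <- shear_wave_speed(model, st, rho0s)
  dt_mu <- min(mesh$h / cmu)
  list(dt = alpha_cfl * dt_mu, dt_mu = dt_mu)
}
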