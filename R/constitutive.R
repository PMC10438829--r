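# Constitutive models: passive strain energies and PK2 stresses, deviatoric
# projections, active stress, pore-fluid pressures and permeabilities.
#
# All stresses are second Piola-Kirchhoff (PK2). The isochoric stress is
#   S_iso = 2 dW(Cbar)/dC = J^{-2/3} [ Stil - (1/3)(Stil : Cbar) Cbar^{-1} ],
# with Stil = 2 dW/dCbar, which is automatically deviatoric (S_iso : C = 0).

#' Passive hyperelastic material models
#'
#' Constructors for the isochoric strain-energy variants:
#' \describe{
#'   \item{neo-Hookean}{W = G/2 (I1bar - 3)}
#'   \item{Mooney-Rivlin}{W = C1 (I1bar - 3) + C2 (I2bar - 3)}
#'   \item{standard reinforced}{W = G/2 (I1bar - 3) +
#'     Gf/2 (max(I4fbar, 1) - 1)^2, transversely isotropic with fibre
#'     direction f0}
#'   \item{Holzapfel-Ogden}{the orthotropic myocardium model with isotropic
#'     (a, b), fibre (af, bf), sheet (as, bs) and fibre-sheet shear
#'     (afs, bfs) terms; fibre and sheet terms are clamped to zero in
#'     compression (max(I4bar, 1))}
#' }
#' Moduli are in the stress units of the case; exponents are dimensionless.
#'
#' @param G,Gf,C1,C2,a,b,af,bf,as,bs,afs,bfs material constants
#' @return a `dvms_material` object
#' @export
neo_hookean <- function(G) {
  stopifnot(G >= 0)
  structure(list(variant = "neo_hookean", G = G), class = "dvms_material")
}

#' @rdname neo_hookean
#' @export
mooney_rivlin <- function(C1, C2) {
  stopifnot(C1 >= 0, C2 >= 0)
  structure(list(variant = "mooney_rivlin", C1 = C1, C2 = C2),
            class = "dvms_material")
}

#' @rdname neo_hookean
#' @export
standard_reinforced <- function(G, Gf) {
  stopifnot(G >= 0, Gf >= 0)
  structure(list(variant = "standard_reinforced", G = G, Gf = Gf),
            class = "dvms_material")
}

#' @rdname neo_hookean
#' @export
holzapfel_ogden <- function(a, b, af, bf, as, bs, afs, bfs) {
  stopifnot(a >= 0, af >= 0, as >= 0, afs >= 0,
            b > 0, bf > 0, bs > 0, bfs > 0)
  structure(list(variant = "holzapfel_ogden", a = a, b = b, af = af, bf = bf,
                 as = as, bs = bs, afs = afs, bfs = bfs),
            class = "dvms_material")
}

#' @export
print.dvms_material <- function(x, ...) {
  pars <- x[setdiff(names(x), "variant")]
  cat(sprintf("dvms_material <%s>: %s\n", x$variant,
              paste(sprintf("%s = %g", names(pars), unlist(pars)), collapse = ", ")))
  invisible(x)
}

# needs_frame: whether the model uses fibre (and sheet) directions
model_needs_frame <- function(model)
  model$variant %in% c("standard_reinforced", "holzapfel_ogden")

# Stil = 2 dW/dCbar as an E x 9 batch tensor, from a bt_kinematics state.
# `pre` optionally carries precomputed structural outer products
# (ff = f0 (x) f0, ss, fs_sym = f0 (x) s0 + s0 (x) f0).
bt_Stil <- function(model, st, pre = NULL) {
  E <- st$E
  ff <- function() if (!is.null(pre)) pre$ff else bt_outer(st$f0, st$f0)
  switch(model$variant,
    neo_hookean = model$G * bt_eye(E),
    mooney_rivlin = {
      2 * (model$C1 + model$C2 * st$I1bar) * bt_eye(E) - 2 * model$C2 * st$Cbar
    },
    standard_reinforced = {
      g <- pmax(st$I4f_bar - 1, 0)
      model$G * bt_eye(E) + 2 * model$Gf * g * ff()
    },
    holzapfel_ogden = {
      g4f <- pmax(st$I4f_bar - 1, 0)
      g4s <- pmax(st$I4s_bar - 1, 0)
      i8 <- st$I8fs_bar
      ss <- if (!is.null(pre)) pre$ss else bt_outer(st$s0, st$s0)
      fs_sym <- if (!is.null(pre)) pre$fs_sym else {
        fs <- bt_outer(st$f0, st$s0); fs + bt_t(fs)
      }
      model$a * exp(model$b * (st$I1bar - 3)) * bt_eye(E) +
        2 * model$af * g4f * exp(model$bf * g4f^2) * ff() +
        2 * model$as * g4s * exp(model$bs * g4s^2) * ss +
        model$afs * i8 * exp(model$bfs * i8^2) * fs_sym
    },
    dvms_error(paste("unknown material variant", model$variant),
               "dvms_invalid_argument"))
}

# isochoric PK2 stress (deviatoric by construction), E x 9.
# det(Cbar) = 1 identically (also under the 2D plane-strain embedding), so
# the inverse is the plain transposed cofactor.
bt_stress_iso <- function(model, st, pre = NULL) {
  Stil <- bt_Stil(model, st, pre)
  Cbar_inv <- bt_t(bt_cof(st$Cbar))
  tr <- bt_ddot(Stil, st$Cbar)  # Stil : Cbar (both symmetric)
  pmax(st$J, 1e-12)^(-2 / 3) * (Stil - (tr / 3) * Cbar_inv)
}

# isochoric strain-energy density W(Cbar), per element
bt_energy <- function(model, st) {
  switch(model$variant,
    neo_hookean = model$G / 2 * (st$I1bar - 3),
    mooney_rivlin = model$C1 * (st$I1bar - 3) + model$C2 * (st$I2bar - 3),
    standard_reinforced = model$G / 2 * (st$I1bar - 3) +
      model$Gf / 2 * pmax(st$I4f_bar - 1, 0)^2,
    holzapfel_ogden = {
      g4f <- pmax(st$I4f_bar - 1, 0); g4s <- pmax(st$I4s_bar - 1, 0)
      model$a / (2 * model$b) * exp(model$b * (st$I1bar - 3)) +
        model$af / (2 * model$bf) * (exp(model$bf * g4f^2) - 1) +
        model$as / (2 * model$bs) * (exp(model$bs * g4s^2) - 1) +
        model$afs / (2 * model$bfs) * (exp(model$bfs * st$I8fs_bar^2) - 1)
    })
}

# dW/dI1bar, dW/dI2bar, dW/dI4fbar, dW/dI4sbar, dW/dI8fsbar per element,
# with the same in-compression clamps as the stress (used by the shear-wave
# speed of the stabilization parameter).
bt_W_derivs <- function(model, st) {
  E <- st$E
  z <- numeric(E)
  switch(model$variant,
    neo_hookean = list(W1 = rep(model$G / 2, E), W2 = z, W4f = z, W4s = z, W8fs = z),
    mooney_rivlin = list(W1 = rep(model$C1, E), W2 = rep(model$C2, E),
                         W4f = z, W4s = z, W8fs = z),
    standard_reinforced = list(W1 = rep(model$G / 2, E), W2 = z,
                               W4f = model$Gf * pmax(st$I4f_bar - 1, 0),
                               W4s = z, W8fs = z),
    holzapfel_ogden = {
      g4f <- pmax(st$I4f_bar - 1, 0); g4s <- pmax(st$I4s_bar - 1, 0)
      list(W1 = model$a / 2 * exp(model$b * (st$I1bar - 3)),
           W2 = z,
           W4f = model$af * g4f * exp(model$bf * g4f^2),
           W4s = model$as * g4s * exp(model$bs * g4s^2),
           W8fs = model$afs * st$I8fs_bar * exp(model$bfs * st$I8fs_bar^2))
    })
}

#' Passive PK2 stress of one kinematic state
#'
#' S_p = 2 dW(Cbar)/dC - p J C^{-1}: the isochoric stress (deviatoric by
#' construction) plus the pressure term from the incompressibility
#' multiplier p.
#'
#' @param model a `dvms_material`
#' @param state a kinematic state from [kinematic_state()]
#' @param p scalar solid pressure (Lagrange multiplier)
#' @return 3x3 PK2 stress matrix
#' @export
passive_stress <- function(model, state, p = 0) {
  st <- state_to_batch(state)
  if (!all(is.finite(c(st$I1bar, st$J))))
    dvms_error("non-finite kinematic invariants", "dvms_numerical_domain")
  Siso <- bt_stress_iso(model, st)
  Cinv <- solve(state$C)
  matrix(Siso[1, ], 3, 3) - p * state$J * Cinv
}

# promote a single kinematic_state to a 1-row batch state
state_to_batch <- function(state) {
  st <- list(E = 1L,
             F = matrix(as.vector(state$F), 1, 9),
             H = matrix(as.vector(state$H), 1, 9),
             J = state$J,
             C = matrix(as.vector(state$C), 1, 9),
             Cbar = matrix(as.vector(state$Cbar), 1, 9),
             I1bar = state$I1bar, I2bar = state$I2bar)
  for (nm in c("I4f_bar", "I4f", "I4s_bar", "I8fs_bar"))
    if (!is.null(state[[nm]])) st[[nm]] <- state[[nm]]
  if (!is.null(state$f0)) st$f0 <- matrix(state$f0, 1, 3)
  if (!is.null(state$s0)) st$s0 <- matrix(state$s0, 1, 3)
  st
}

#' Deviatoric PK2 projection
#'
#' DEV[S] = S - (1/3)(S : C) C^{-1}, the PK2 tensor whose push-forward is
#' the deviatoric Cauchy stress; satisfies DEV[S] : C = 0 identically.
#'
#' @param S 3x3 PK2 tensor
#' @param C 3x3 right Cauchy-Green tensor (symmetric positive definite)
#' @return 3x3 matrix
#' @export
dev_projection <- function(S, C) {
  d <- det(C)
  if (!is.finite(d) || d <= 0)
    dvms_error("C must be positive definite", "dvms_invalid_argument")
  S - (sum(S * C) / 3) * solve(C)
}

#' Active contraction model
#'
#' Active PK2 stress S_a = T(t, I4f) f0 (x) f0 with the length-dependent
#' tension T = Ta(t) [1 + q (I4f - 1)] (q = 4.9 by default). Only the
#' deviatoric part DEV[S_a] enters the total stress, the spherical part
#' being absorbed by the pressure.
#'
#' @param Ta waveform function of time returning active tension (stress
#'   units), or a single number for constant tension
#' @param length_factor slope q of the length dependence
#' @return a `dvms_active` object
#' @export
active_model <- function(Ta, length_factor = 4.9) {
  if (is.numeric(Ta)) { Ta_val <- Ta; Ta <- function(t) rep(Ta_val, length(t)) }
  structure(list(Ta = Ta, length_factor = length_factor), class = "dvms_active")
}

#' Active PK2 stress
#'
#' @param active a [active_model()]
#' @param t time
#' @param I4f total fibre invariant f0 . C f0
#' @param f0 unit fibre direction (length 3)
#' @param C optional 3x3 C tensor; if given, the deviatoric projection is
#'   also returned
#' @return list with `T` (scalar tension), `S_a` (3x3), and `DEV` if `C`
#'   was supplied
#' @export
active_stress <- function(active, t, I4f, f0, C = NULL) {
  T <- active$Ta(t) * (1 + active$length_factor * (I4f - 1))
  S_a <- T * (f0 %o% f0)
  out <- list(T = T, S_a = S_a)
  if (!is.null(C)) out$DEV <- dev_projection(S_a, C)
  out
}

# batch tension per element
bt_active_T <- function(active, t, I4f)
  active$Ta(t) * (1 + active$length_factor * (I4f - 1))

#' Pore-fluid constitutive model
#'
#' Bundles the pressure-volume energy (quadratic, p^PV = kappa_s m, or the
#' Bruinsma exponential-logarithmic law), the compaction penalization
#' (scale `c`, width `eps`, critical porosity `phi_crit`), the reference
#' porosity, fluid reference density and the reference permeability tensor.
#' The added mass `m` is dimensionless throughout (volume of added fluid
#' per unit reference volume, i.e. the paper-level added mass divided by
#' rho0f), so that J - 1 = m.
#'
#' @param upv `"quadratic"` or `"bruinsma"`
#' @param kappa_s bulk-like pore stiffness (pressure units; quadratic law)
#' @param q1,q2,q3 Bruinsma constants (q1, q2 pressure units)
#' @param c compaction pressure scale (pressure units, signed; updated in
#'   time by the solver)
#' @param eps compaction width (dimensionless, default 0.001)
#' @param phi_crit critical porosity (default 0.001)
#' @param phi0 reference porosity in (0,1)
#' @param rho0f fluid reference density
#' @param K reference permeability tensor (scalar for isotropic, or 3x3
#'   symmetric PSD; units area^2/(pressure time) of the case)
#' @return a `dvms_pore_fluid` object
#' @export
pore_fluid_model <- function(upv = c("quadratic", "bruinsma"),
                             kappa_s = NULL, q1 = NULL, q2 = NULL, q3 = NULL,
                             c = 0, eps = 0.001, phi_crit = 0.001,
                             phi0, rho0f, K) {
  upv <- match.arg(upv)
  stopifnot(phi0 > 0, phi0 < 1, eps > 0, phi_crit >= 0, rho0f > 0)
  if (upv == "quadratic") stopifnot(is.numeric(kappa_s))
  else stopifnot(is.numeric(q1), is.numeric(q2), is.numeric(q3))
  if (length(K) == 1L) K <- diag(3) * K
  if (nrow(K) == 2L) { K2 <- matrix(0, 3, 3); K2[1:2, 1:2] <- K; K2[3, 3] <- mean(diag(K)); K <- K2 }
  if (max(abs(K - t(K))) > 1e-12 * max(1, max(abs(K))))
    dvms_error("K must be symmetric", "dvms_invalid_argument")
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev)))
    dvms_error("K must be positive semi-definite", "dvms_invalid_argument")
  structure(list(upv = upv, kappa_s = kappa_s, q1 = q1, q2 = q2, q3 = q3,
                 c = c, eps = eps, phi_crit = phi_crit,
                 phi0 = phi0, rho0f = rho0f, K = K),
            class = "dvms_pore_fluid")
}

#' @export
print.dvms_pore_fluid <- function(x, ...) {
  cat(sprintf("dvms_pore_fluid <%s>: phi0 = %g, rho0f = %g, c = %g, eps = %g, phi_crit = %g\n",
              x$upv, x$phi0, x$rho0f, x$c, x$eps, x$phi_crit))
  invisible(x)
}

#' Pore pressures and their added-mass derivative
#'
#' p^PV = dU^PV/dm (kappa_s m for the quadratic law; the Bruinsma
#' derivative otherwise), the compaction pressure
#' p^c = c eps^2 / (eps^2 + (m + phi0 - phi_crit)^2), and the exact
#' analytic derivative d(p^PV + p^c)/dm needed by the mass-dependent
#' permeability and the Newton linearization.
#'
#' @param pore a [pore_fluid_model()]
#' @param m dimensionless added mass (vectorized)
#' @return list with `p_pv`, `p_c`, `dp_dm` (same length as `m`)
#' @export
pore_pressures <- function(pore, m) {
  if (pore$upv == "quadratic") {
    p_pv <- pore$kappa_s * m
    dpv <- rep(pore$kappa_s, length(m))
  } else {
    x <- m + pore$phi0
    if (any(x <= 0))
      dvms_error("m + phi0 must be positive for the bruinsma law",
                 "dvms_numerical_domain")
    # dU/dm = q1 e^{q3 x} + q2 ln(q3 x) - q1 e^{q3 phi0} - q2 ln(phi0)
    p_pv <- pore$q1 * (exp(pore$q3 * x) - exp(pore$q3 * pore$phi0)) +
      pore$q2 * log(pore$q3 * x / pore$phi0)
    dpv <- pore$q1 * pore$q3 * exp(pore$q3 * x) + pore$q2 / x
  }
  d <- m + pore$phi0 - pore$phi_crit
  den <- pore$eps^2 + d^2
  p_c <- pore$c * pore$eps^2 / den
  dpc <- -2 * pore$c * pore$eps^2 * d / den^2
  list(p_pv = p_pv, p_c = p_c, dp_dm = dpv + dpc)
}

#' Added-mass-dependent permeability
#'
#' K0m = K0 d(p^PV + p^c)/dm, the tensor multiplying the added-mass
#' gradient in the Darcy flux.
#'
#' @param pore a [pore_fluid_model()]
#' @param state a kinematic state (for the pull-back K0)
#' @param m dimensionless added mass at the evaluation point
#' @return 3x3 matrix
#' @export
mass_permeability <- function(pore, state, m) {
  K0 <- pulled_back_permeability(pore$K, state)
  pp <- pore_pressures(pore, m)
  K0 * pp$dp_dm
}

#' Mixture densities
#'
#' @param rho0s,rho0f skeleton and fluid reference densities
#' @param phi0 reference porosity
#' @return list with the inputs and the mixture density
#'   `rho0 = rho0f phi0 + rho0s (1 - phi0)`
#' @export
mixture_densities <- function(rho0s, rho0f, phi0) {
  stopifnot(rho0s > 0, rho0f > 0, phi0 > 0, phi0 < 1)
  list(rho0s = rho0s, rho0f = rho0f, phi0 = phi0,
       rho0 = rho0f * phi0 + rho0s * (1 - phi0))
}

#' Pore-fluid source/sink model
#'
#' Volumetric source S(p_pore): `"full"` uses
#' S = beta_so (p_so - p_pore) - beta_si (p_pore - p_si);
#' `"proportional"` uses S = beta_so p_pore; `"sink_only"` uses
#' S = -beta_si (p_pore - p_si).
#'
#' @param mode one of `"full"`, `"proportional"`, `"sink_only"`
#' @param beta_so,beta_si source/sink conductances (>= 0)
#' @param p_so,p_si source and sink pressures
#' @return a `dvms_source` object
#' @export
source_model <- function(mode = c("full", "proportional", "sink_only"),
                         beta_so = 0, beta_si = 0, p_so = 0, p_si = 0) {
  mode <- match.arg(mode)
  stopifnot(beta_so >= 0, beta_si >= 0)
  structure(list(mode = mode, beta_so = beta_so, beta_si = beta_si,
                 p_so = p_so, p_si = p_si), class = "dvms_source")
}

#' Evaluate a source model
#'
#' @param src a [source_model()]
#' @param p_pore pore pressure (vectorized)
#' @return list with `S` and the derivative `dS_dp` (for Newton)
#' @export
source_eval <- function(src, p_pore) {
  switch(src$mode,
    full = list(S = src$beta_so * (src$p_so - p_pore) -
                    src$beta_si * (p_pore - src$p_si),
                dS_dp = rep(-(src$beta_so + src$beta_si), length(p_pore))),
    proportional = list(S = src$beta_so * p_pore,
                        dS_dp = rep(src$beta_so, length(p_pore))),
    sink_only = list(S = -src$beta_si * (p_pore - src$p_si),
                     dS_dp = rep(-src$beta_si, length(p_pore))))
}
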