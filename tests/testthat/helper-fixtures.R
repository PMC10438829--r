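# Shared fixtures: small meshes and random states built in code.

unit_cube_mesh <- function(div = 2L) build_box_mesh(c(1, 1, 1), rep(div, 3), dim = 3)

unit_square_mesh <- function(div = 2L) build_box_mesh(c(1, 1), rep(div, 2), dim = 2)

# random deformation gradients with positive determinant, as E x 9 batch
random_F_batch <- function(E, sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- matrix(rnorm(E * 9, sd = sd), E, 9)
  F[, c(1, 5, 9)] <- F[, c(1, 5, 9)] + 1
  J <- dvmsfem:::bt_det(F)
  while (any(J <= 0.05)) {
    bad <- J <= 0.05
    F[bad, ] <- matrix(rnorm(sum(bad) * 9, sd = sd), sum(bad), 9)
    F[bad, c(1, 5, 9)] <- F[bad, c(1, 5, 9)] + 1
    J <- dvmsfem:::bt_det(F)
  }
  F
}

# a kinematic-state-like list from a single 3x3 F (for constitutive calls)
state_from_F <- function(F, f0 = NULL, s0 = NULL) {
  J <- det(F)
  C <- t(F) %*% F
  Cbar <- J^(-2 / 3) * C
  st <- list(F = F, H = J * t(solve(F)), J = J, C = C, Cbar = Cbar,
             I1bar = sum(diag(Cbar)),
             I2bar = 0.5 * (sum(diag(Cbar))^2 - sum(Cbar * Cbar)))
  if (!is.null(f0)) {
    st$f0 <- f0
    st$I4f_bar <- drop(f0 %*% Cbar %*% f0)
    st$I4f <- drop(f0 %*% C %*% f0)
  }
  if (!is.null(s0)) {
    st$s0 <- s0
    st$I4s_bar <- drop(s0 %*% Cbar %*% s0)
    st$I8fs_bar <- drop(f0 %*% Cbar %*% s0)
  }
  st
}

# Independent symbolic oracle for the passive PK2 stress: builds the energy
# W(Cbar(C)) as an expression in the 9 entries of C (treated as independent)
# and differentiates with stats::D; S_ij = 2 dW/dC_ij. Clamped fibre terms
# are built on their tension branch, so callers must supply states with the
# corresponding invariants above 1.
symbolic_stress_oracle <- function(model, f0 = NULL, s0 = NULL) {
  sy <- function(i, j) as.name(paste0("c", i, j))
  sm <- asNamespace("dvmsfem")
  C <- sm$sm_zero()
  for (i in 1:3) for (j in 1:3) C <- sm$sm_set(C, i, j, sy(i, j))
  detC <- sm$sm_det(C)
  Jm23 <- sm$s_pow(detC, -1 / 3)       # J^{-2/3} = det(C)^{-1/3}
  Cbar <- sm$sm_scale(Jm23, C)
  I1b <- sm$sm_trace(Cbar)
  # symmetrized coefficients: C is a symmetric tensor, so the derivative
  # convention is d(a.Cb)/dC_ij = (a_i b_j + a_j b_i)/2
  quad <- function(a, b) {
    e <- 0
    for (i in 1:3) for (j in 1:3)
      e <- sm$s_add(e, sm$s_mul((a[i] * b[j] + a[j] * b[i]) / 2,
                                sm$sm_get(Cbar, i, j)))
    e
  }
  W <- switch(model$variant,
    neo_hookean = sm$s_mul(model$G / 2, sm$s_sub(I1b, 3)),
    mooney_rivlin = {
      tr2 <- sm$sm_ddot(Cbar, sm$sm_t(Cbar))
      I2b <- sm$s_mul(0.5, sm$s_sub(sm$s_mul(I1b, I1b), tr2))
      sm$s_add(sm$s_mul(model$C1, sm$s_sub(I1b, 3)),
               sm$s_mul(model$C2, sm$s_sub(I2b, 3)))
    },
    standard_reinforced = {
      g <- sm$s_sub(quad(f0, f0), 1)
      sm$s_add(sm$s_mul(model$G / 2, sm$s_sub(I1b, 3)),
               sm$s_mul(model$Gf / 2, sm$s_mul(g, g)))
    },
    holzapfel_ogden = {
      g4f <- sm$s_sub(quad(f0, f0), 1)
      g4s <- sm$s_sub(quad(s0, s0), 1)
      i8 <- quad(f0, s0)
      e1 <- sm$s_mul(model$a / (2 * model$b),
                     sm$s_fun("exp", sm$s_mul(model$b, sm$s_sub(I1b, 3))))
      e2 <- sm$s_mul(model$af / (2 * model$bf),
                     sm$s_fun("exp", sm$s_mul(model$bf, sm$s_mul(g4f, g4f))))
      e3 <- sm$s_mul(model$as / (2 * model$bs),
                     sm$s_fun("exp", sm$s_mul(model$bs, sm$s_mul(g4s, g4s))))
      e4 <- sm$s_mul(model$afs / (2 * model$bfs),
                     sm$s_fun("exp", sm$s_mul(model$bfs, sm$s_mul(i8, i8))))
      sm$s_add(sm$s_add(e1, e2), sm$s_add(e3, e4))
    })
  dW <- lapply(1:9, function(k) {
    i <- (k - 1) %% 3 + 1; j <- (k - 1) %/% 3 + 1
    stats::D(W, paste0("c", i, j))
  })
  function(Cnum) {
    env <- list()
    for (i in 1:3) for (j in 1:3) env[[paste0("c", i, j)]] <- Cnum[i, j]
    matrix(2 * vapply(dW, function(e) eval(e, env), numeric(1)), 3, 3)
  }
}
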