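# Kinematics: P1 gradients, deformation tensors, invariants.
#
# Batch layer: tensors for all E elements at once, stored as E x 9 matrices
# in column-major 3x3 order (entry (i,j) in column i + 3*(j-1)). 2D meshes
# are embedded in 3D as plane strain: F = blockdiag(F_2x2, 1).

BT_I3 <- c(1, 0, 0, 0, 1, 0, 0, 0, 1)

bt_eye <- function(E) matrix(rep(BT_I3, each = E), E, 9)

bt_det <- function(F) {
  F[, 1] * (F[, 5] * F[, 9] - F[, 8] * F[, 6]) -
  F[, 4] * (F[, 2] * F[, 9] - F[, 8] * F[, 3]) +
  F[, 7] * (F[, 2] * F[, 6] - F[, 5] * F[, 3])
}

bt_t <- function(F) F[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]

bt_mul <- function(A, B) {
  out <- matrix(0, nrow(A), 9)
  for (i in 1:3) for (j in 1:3) {
    out[, i + 3 * (j - 1)] <-
      A[, i] * B[, 1 + 3 * (j - 1)] +
      A[, i + 3] * B[, 2 + 3 * (j - 1)] +
      A[, i + 6] * B[, 3 + 3 * (j - 1)]
  }
  out
}

# cofactor matrix H: H_ij = d(det F)/d(F_ij), so H = det(F) F^{-T}
bt_cof <- function(F) {
  out <- matrix(0, nrow(F), 9)
  out[, 1] <- F[, 5] * F[, 9] - F[, 6] * F[, 8]
  out[, 2] <- F[, 6] * F[, 7] - F[, 4] * F[, 9]
  out[, 3] <- F[, 4] * F[, 8] - F[, 5] * F[, 7]
  out[, 4] <- F[, 8] * F[, 3] - F[, 9] * F[, 2]
  out[, 5] <- F[, 9] * F[, 1] - F[, 7] * F[, 3]
  out[, 6] <- F[, 7] * F[, 2] - F[, 8] * F[, 1]
  out[, 7] <- F[, 2] * F[, 6] - F[, 3] * F[, 5]
  out[, 8] <- F[, 3] * F[, 4] - F[, 1] * F[, 6]
  out[, 9] <- F[, 1] * F[, 5] - F[, 2] * F[, 4]
  out
}

bt_inv <- function(F, det = bt_det(F)) bt_t(bt_cof(F)) / det

# A : B  (full contraction) for E x 9 tensors
bt_ddot <- function(A, B) {
  out <- A[, 1] * B[, 1]
  for (k in 2:9) out <- out + A[, k] * B[, k]
  out
}

# matrix-vector product, V an E x 3 matrix
bt_mv <- function(A, V) {
  out <- matrix(0, nrow(A), 3)
  out[, 1] <- A[, 1] * V[, 1] + A[, 4] * V[, 2] + A[, 7] * V[, 3]
  out[, 2] <- A[, 2] * V[, 1] + A[, 5] * V[, 2] + A[, 8] * V[, 3]
  out[, 3] <- A[, 3] * V[, 1] + A[, 6] * V[, 2] + A[, 9] * V[, 3]
  out
}

# outer product of E x 3 vectors
bt_outer <- function(a, b) {
  out <- matrix(0, nrow(a), 9)
  for (j in 1:3) for (i in 1:3)
    out[, i + 3 * (j - 1)] <- a[, i] * b[, j]
  out
}

# quadratic form a . A b for E x 3 vectors
bt_quad <- function(a, A, b) rowSums(a * bt_mv(A, b))

# Batch kinematic state from the element-constant displacement gradient
# Gu (E x 9, reference gradient of u, already 3D-embedded).
# `need_I2` skips the second invariant when the material does not use it.
bt_kinematics <- function(Gu, frame = NULL, check = TRUE, need_I2 = TRUE) {
  E <- nrow(Gu)
  F <- Gu
  F[, c(1, 5, 9)] <- F[, c(1, 5, 9)] + 1
  J <- bt_det(F)
  if (check && any(J <= 1e-12)) {
    bad <- which(J <= 1e-12)
    dvms_error(sprintf("element inversion: J <= 0 in %d element(s), first id %d (J = %.3g)",
                       length(bad), bad[1], J[bad[1]]),
               "dvms_inverted_element", elements = bad)
  }
  H <- bt_cof(F)
  C <- bt_mul(bt_t(F), F)
  # floor only protects unchecked evaluations (e.g. the tau refresh); the
  # checked path has already rejected J <= 1e-12
  Jm23 <- pmax(J, 1e-12)^(-2 / 3)
  Cbar <- C * Jm23
  st <- list(E = E, F = F, H = H, J = J, C = C, Cbar = Cbar,
             I1bar = Cbar[, 1] + Cbar[, 5] + Cbar[, 9])
  if (need_I2)
    st$I2bar <- 0.5 * (st$I1bar^2 - bt_ddot(Cbar, bt_t(Cbar)))
  if (!is.null(frame)) {
    f0 <- frame$f0
    if (is.null(dim(f0))) f0 <- matrix(f0, E, 3, byrow = TRUE)
    st$f0 <- f0
    st$I4f_bar <- bt_quad(f0, Cbar, f0)
    st$I4f <- bt_quad(f0, C, f0)
    if (!is.null(frame$s0)) {
      s0 <- frame$s0
      if (is.null(dim(s0))) s0 <- matrix(s0, E, 3, byrow = TRUE)
      st$s0 <- s0
      st$I4s_bar <- bt_quad(s0, Cbar, s0)
      st$I8fs_bar <- bt_quad(f0, Cbar, s0)
    }
  }
  st
}

#' Fibre (and sheet) frame in the reference configuration
#'
#' Directions are normalized to unit length. If a sheet direction is given
#' and is not orthogonal to the fibre direction (|f0.s0| > 1e-8), the
#' misalignment is reported via a message; orthogonality is not required by
#' the constitutive models.
#'
#' @param f0 fibre direction: length-3 vector, or E x 3 matrix (per element)
#' @param s0 optional sheet direction, same shape
#' @return a `dvms_fibre_frame`
#' @export
fibre_frame <- function(f0, s0 = NULL) {
  normz <- function(x, nm) {
    if (is.null(dim(x))) {
      if (length(x) == 2L) x <- c(x, 0)
      n <- sqrt(sum(x^2))
      if (n == 0) dvms_error(paste(nm, "must be nonzero"), "dvms_invalid_argument")
      x / n
    } else {
      if (ncol(x) == 2L) x <- cbind(x, 0)
      n <- sqrt(rowSums(x^2))
      if (any(n == 0)) dvms_error(paste(nm, "must be nonzero"), "dvms_invalid_argument")
      x / n
    }
  }
  f0 <- normz(f0, "f0")
  if (!is.null(s0)) {
    s0 <- normz(s0, "s0")
    dot <- if (is.null(dim(f0)) && is.null(dim(s0))) sum(f0 * s0) else {
      f <- if (is.null(dim(f0))) matrix(f0, 1) else f0
      s <- if (is.null(dim(s0))) matrix(s0, 1) else s0
      max(abs(rowSums(f * s)))
    }
    if (max(abs(dot)) > 1e-8)
      message(sprintf("fibre_frame: |f0.s0| = %.3g (not orthogonal)", max(abs(dot))))
  }
  structure(list(f0 = f0, s0 = s0), class = "dvms_fibre_frame")
}

# Precomputed P1 geometry: shape-function gradients and volumes.
# Returns list(G = list of (dim+1) E x dim gradient matrices, V = volumes).
p1_geometry <- function(mesh) {
  v <- mesh$vertices; c <- mesh$cells; d <- mesh$dim
  V <- cell_volumes(mesh)
  if (any(V <= 0))
    dvms_error("degenerate element in mesh", "dvms_degenerate_element")
  if (d == 2L) {
    x1 <- v[c[, 1], , drop = FALSE]; x2 <- v[c[, 2], , drop = FALSE]
    x3 <- v[c[, 3], , drop = FALSE]
    det <- 2 * V
    # gradients of barycentric shape functions
    G1 <- cbind(x2[, 2] - x3[, 2], x3[, 1] - x2[, 1]) / det
    G2 <- cbind(x3[, 2] - x1[, 2], x1[, 1] - x3[, 1]) / det
    G3 <- cbind(x1[, 2] - x2[, 2], x2[, 1] - x1[, 1]) / det
    list(G = list(G1, G2, G3), V = V)
  } else {
    x1 <- v[c[, 1], , drop = FALSE]
    e1 <- v[c[, 2], , drop = FALSE] - x1
    e2 <- v[c[, 3], , drop = FALSE] - x1
    e3 <- v[c[, 4], , drop = FALSE] - x1
    det <- 6 * V
    cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                  a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                  a[, 1] * b[, 2] - a[, 2] * b[, 1])
    G2 <- cross(e2, e3) / det
    G3 <- cross(e3, e1) / det
    G4 <- cross(e1, e2) / det
    G1 <- -(G2 + G3 + G4)
    list(G = list(G1, G2, G3, G4), V = V)
  }
}

# Element-constant 3D-embedded gradient of a nodal field.
# field: n x k matrix (k components); returns list of E x k matrices, one
# per reference direction actually present (dim of mesh); or for vector
# fields the full E x 9 displacement gradient via bt_grad_u.
p1_gradient_all <- function(mesh, geo, field) {
  if (is.null(dim(field))) field <- matrix(field, ncol = 1L)
  d <- mesh$dim; nl <- d + 1L
  out <- vector("list", d)
  for (j in seq_len(d)) out[[j]] <- matrix(0, ncells(mesh), ncol(field))
  for (a in seq_len(nl)) {
    fa <- field[mesh$cells[, a], , drop = FALSE]
    for (j in seq_len(d)) out[[j]] <- out[[j]] + geo$G[[a]][, j] * fa
  }
  out
}

# E x 9 embedded displacement gradient from nodal displacement (n x dim)
bt_grad_u <- function(mesh, geo, u) {
  d <- mesh$dim; E <- ncells(mesh)
  Gu <- matrix(0, E, 9)
  for (a in seq_len(d + 1L)) {
    ua <- u[mesh$cells[, a], , drop = FALSE]
    for (i in seq_len(d)) for (j in seq_len(d))
      Gu[, i + 3 * (j - 1)] <- Gu[, i + 3 * (j - 1)] + ua[, i] * geo$G[[a]][, j]
  }
  Gu
}

#' Gradient of a P1 field on one element
#'
#' The exact (element-constant) reference gradient of the linear interpolant
#' of a nodal field on a single element.
#'
#' @param nodal_field numeric vector over mesh vertices (or matrix for
#'   vector fields)
#' @param mesh a `dvms_mesh`
#' @param element element index
#' @return gradient: length-`dim` vector, or `k x dim` matrix for a k-vector
#'   field
#' @export
p1_gradient <- function(nodal_field, mesh, element) {
  geo <- p1_geometry(mesh)
  if (is.null(dim(nodal_field))) nodal_field <- matrix(nodal_field, ncol = 1L)
  d <- mesh$dim
  g <- matrix(0, ncol(nodal_field), d)
  for (a in seq_len(d + 1L)) {
    fa <- nodal_field[mesh$cells[element, a], ]
    g <- g + outer(fa, geo$G[[a]][element, ])
  }
  if (nrow(g) == 1L) drop(g) else g
}

#' Kinematic state of one element
#'
#' Deformation gradient and derived tensors/invariants of a single element,
#' computed from nodal displacements. 2D meshes use the plane-strain
#' embedding F = blockdiag(F_2x2, 1), so the cofactor satisfies
#' H = J F^{-T} in both dimensions. Raises an inverted-element error
#' (carrying the element id) if J <= 0.
#'
#' @param u_nodal n x dim nodal displacement matrix
#' @param mesh a `dvms_mesh`
#' @param element element index
#' @param frame optional [fibre_frame()]
#' @return list with `F`, `H`, `J`, `C`, `Fbar`, `Cbar` (3x3 matrices) and
#'   invariants `I1bar`, `I2bar`, and where a frame is given `I4f_bar`,
#'   `I4f`, `I4s_bar`, `I8fs_bar`
#' @export
kinematic_state <- function(u_nodal, mesh, element, frame = NULL) {
  geo <- p1_geometry(mesh)
  Gu <- bt_grad_u(mesh, geo, u_nodal)[element, , drop = FALSE]
  fr <- NULL
  if (!is.null(frame)) {
    pick <- function(x) if (is.null(x)) NULL else if (is.null(dim(x))) x else x[element, ]
    fr <- list(f0 = pick(frame$f0), s0 = pick(frame$s0))
    if (is.null(fr$s0)) fr$s0 <- NULL
  }
  st <- tryCatch(bt_kinematics(Gu, frame = fr),
                 dvms_inverted_element = function(e) {
                   dvms_error(sprintf("element %d inverted (J <= 0)", element),
                              "dvms_inverted_element", elements = element)
                 })
  m3 <- function(x) matrix(x[1, ], 3, 3)
  out <- list(F = m3(st$F), H = m3(st$H), J = st$J, C = m3(st$C),
              Cbar = m3(st$Cbar), Fbar = m3(st$F) * st$J^(-1 / 3),
              I1bar = st$I1bar, I2bar = st$I2bar)
  for (nm in c("I4f_bar", "I4f", "I4s_bar", "I8fs_bar"))
    if (!is.null(st[[nm]])) out[[nm]] <- st[[nm]]
  out
}

#' Pull back a reference permeability tensor to the Lagrangian frame
#'
#' Computes K0 = J F^{-1} K F^{-T}, the Lagrangian (material) permeability
#' used by the Darcy terms of the added-mass equation. K must be symmetric
#' positive semi-definite; the congruence preserves symmetry and
#' semi-definiteness.
#'
#' @param K 3x3 (or 2x2, embedded) symmetric permeability tensor, or a
#'   scalar for isotropic permeability
#' @param state a kinematic state from [kinematic_state()] (or any list with
#'   `F` and `J`)
#' @return 3x3 matrix K0
#' @export
pulled_back_permeability <- function(K, state) {
  if (length(K) == 1L) K <- diag(3) * K
  if (nrow(K) == 2L) {K2 <- diag(3) * 0; K2[1:2, 1:2] <- K; K2[3, 3] <- mean(diag(K)); K <- K2}
  if (max(abs(K - t(K))) > 1e-12 * max(1, max(abs(K))))
    dvms_error("K must be symmetric", "dvms_invalid_argument")
  Fi <- solve(state$F)
  state$J * Fi %*% K %*% t(Fi)
}

# batch version: K 3x3 fixed, returns E x 9
bt_pulled_back_K <- function(K, F, J) {
  Fi <- bt_inv(F, J)
  KE <- matrix(rep(as.vector(K), each = nrow(F)), nrow(F), 9)
  J * bt_mul(bt_mul(Fi, KE), bt_t(Fi))
}
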