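# P1 gradients, deformation tensors, invariants, permeability pull-back.

test_that("p1_gradient is exact for linears and matches finite differences", {
  m <- unit_cube_mesh(2)
  phi <- m$vertices[, 1]
  for (e in c(1L, 5L, ncells(m)))
    expect_equal(p1_gradient(phi, m, e), c(1, 0, 0), tolerance = 1e-13)
  expect_equal(p1_gradient(rep(3.7, nvertices(m)), m, 4L), c(0, 0, 0),
               tolerance = 1e-13)

  # random field on a random nondegenerate tetrahedron vs central FD of the
  # interpolant at the centroid
  set.seed(1)
  verts <- matrix(runif(12), 4, 3)
  while (abs(det(t(verts[2:4, ]) - verts[1, ])) < 0.05)
    verts <- matrix(runif(12), 4, 3)
  m1 <- dvmsfem:::new_dvms_mesh(3L, verts, matrix(1:4, 1), matrix(c(1:3), 1),
                                "b")
  f <- rnorm(4)
  g <- p1_gradient(f, m1, 1L)
  # barycentric interpolant evaluated via solve
  interp <- function(X) {
    A <- rbind(1, t(m1$vertices))
    lam <- solve(A, c(1, X))
    sum(lam * f)
  }
  X0 <- colMeans(m1$vertices)
  h <- 1e-6
  for (j in 1:3) {
    e <- numeric(3); e[j] <- h
    expect_equal(g[j], (interp(X0 + e) - interp(X0 - e)) / (2 * h),
                 tolerance = 1e-7)
  }
})

test_that("kinematic_state reproduces hand-computed tensors", {
  m <- unit_cube_mesh(1)
  st0 <- kinematic_state(matrix(0, 8, 3), m, 1L, frame = fibre_frame(c(1, 1, 1)))
  expect_equal(st0$F, diag(3))
  expect_equal(st0$H, diag(3))
  expect_equal(st0$J, 1)
  expect_equal(st0$I1bar, 3)
  expect_equal(st0$I4f_bar, 1)

  A <- diag(c(2, 3, 4)) - diag(3)
  st <- kinematic_state(m$vertices %*% t(A), m, 2L)
  expect_equal(st$J, 24, tolerance = 1e-12)
  expect_equal(st$H, diag(c(12, 8, 6)), tolerance = 1e-12)
  expect_equal(det(st$Cbar), 1, tolerance = 1e-10)

  # exact shear map at Z = 1, t = pi/2: fibre stretch sqrt(10.95)/3
  a <- 0.1
  Fex <- diag(3); Fex[1, 3] <- 2 * a * 1; Fex[2, 3] <- a
  u <- m$vertices %*% t(Fex - diag(3))
  st <- kinematic_state(u, m, 1L, frame = fibre_frame(c(1, 1, 1)))
  expect_equal(sqrt(st$I4f_bar), sqrt(10.95) / 3, tolerance = 1e-12)

  # inversion raises a classed error carrying the element
  uin <- m$vertices %*% t(diag(c(-1, 1, 1)) - diag(3))
  expect_error(kinematic_state(uin, m, 1L), class = "dvms_inverted_element")
})

test_that("cofactor identities hold on random deformation gradients", {
  F <- random_F_batch(1e4, seed = 2)
  J <- dvmsfem:::bt_det(F)
  H <- dvmsfem:::bt_cof(F)
  # H = J F^{-T} via the inverse computed independently per element
  idx <- sample(1e4, 200)
  for (e in idx) {
    Fm <- matrix(F[e, ], 3, 3)
    expect_equal(matrix(H[e, ], 3, 3), det(Fm) * t(solve(Fm)),
                 tolerance = 1e-12 * max(1, abs(det(Fm))))
  }
  # det H = J^(dim-1)
  expect_equal(dvmsfem:::bt_det(H), J^2, tolerance = 1e-10)
})

test_that("invariants are unchanged under rotations of the deformation", {
  set.seed(3)
  f0 <- c(0.2, -0.5, 0.6); f0 <- f0 / sqrt(sum(f0^2))
  s0 <- c(1, 0.3, 0); s0 <- s0 - sum(s0 * f0) * f0; s0 <- s0 / sqrt(sum(s0^2))
  for (k in 1:10) {
    F <- matrix(random_F_batch(1)[1, ], 3, 3)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    st1 <- state_from_F(F, f0, s0)
    st2 <- state_from_F(Q %*% F, f0, s0)
    for (nm in c("I1bar", "I2bar", "I4f_bar", "I4s_bar", "I8fs_bar"))
      expect_equal(st2[[nm]], st1[[nm]], tolerance = 1e-10)
  }
})

test_that("permeability pull-back K0 = J F^-1 K F^-T", {
  id <- state_from_F(diag(3))
  K <- diag(3) * 0.3
  expect_equal(pulled_back_permeability(K, id), K)

  st <- state_from_F(diag(c(2, 1, 1)))
  k <- 0.7
  expect_equal(pulled_back_permeability(k * diag(3), st),
               diag(c(k / 2, 2 * k, 2 * k)), tolerance = 1e-12)

  set.seed(4)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3); K <- A %*% t(A) + diag(3) * 0.1
    F <- matrix(random_F_batch(1)[1, ], 3, 3)
    K0 <- pulled_back_permeability(K, state_from_F(F))
    expect_equal(K0, t(K0), tolerance = 1e-10)
    expect_true(min(eigen(K0, symmetric = TRUE, only.values = TRUE)$values) > 0)
  }
  expect_error(pulled_back_permeability(matrix(rnorm(9), 3), id),
               class = "dvms_invalid_argument")
})
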