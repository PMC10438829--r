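# Minimal symbolic layer over base R expression trees.
#
# Expressions are R language objects (numbers, symbols, calls). The
# arithmetic constructors fold constants and apply 0/1 identities, which
# keeps the trees from the manufactured-solution stress derivations small
# enough to differentiate with stats::D and evaluate vectorized.

s_num <- function(e) is.numeric(e) && length(e) == 1L
s_zero <- function(e) s_num(e) && e == 0
s_one <- function(e) s_num(e) && e == 1

s_add <- function(a, b) {
  if (s_zero(a)) return(b)
  if (s_zero(b)) return(a)
  if (s_num(a) && s_num(b)) return(a + b)
  call("+", a, b)
}

s_sub <- function(a, b) {
  if (s_zero(b)) return(a)
  if (s_num(a) && s_num(b)) return(a - b)
  if (s_zero(a)) return(s_neg(b))
  call("-", a, b)
}

s_neg <- function(a) {
  if (s_num(a)) return(-a)
  call("-", a)
}

s_mul <- function(a, b) {
  if (s_zero(a) || s_zero(b)) return(0)
  if (s_one(a)) return(b)
  if (s_one(b)) return(a)
  if (s_num(a) && s_num(b)) return(a * b)
  call("*", a, b)
}

s_div <- function(a, b) {
  if (s_zero(a)) return(0)
  if (s_one(b)) return(a)
  if (s_num(a) && s_num(b)) return(a / b)
  call("/", a, b)
}

s_pow <- function(a, n) {
  if (s_one(n)) return(a)
  if (s_zero(n)) return(1)
  if (s_num(a) && s_num(n)) return(a^n)
  if (s_one(a)) return(1)
  call("^", a, n)
}

s_fun <- function(f, a) {
  if (s_num(a)) return(do.call(f, list(a)))
  call(f, a)
}

s_d <- function(e, var) {
  if (s_num(e)) return(0)
  de <- stats::D(e, var)
  s_clean(de)
}

# light cleanup pass: refold constants produced by D()
s_clean <- function(e) {
  if (is.numeric(e) || is.symbol(e)) return(e)
  if (!is.call(e)) return(e)
  op <- as.character(e[[1]])
  args <- lapply(as.list(e)[-1], s_clean)
  if (op %in% c("+", "-", "*", "/", "^")) {
    if (length(args) == 1L && op == "-") return(s_neg(args[[1]]))
    if (length(args) == 2L)
      return(switch(op,
                    `+` = s_add(args[[1]], args[[2]]),
                    `-` = s_sub(args[[1]], args[[2]]),
                    `*` = s_mul(args[[1]], args[[2]]),
                    `/` = s_div(args[[1]], args[[2]]),
                    `^` = s_pow(args[[1]], args[[2]])))
  }
  as.call(c(e[[1]], args))
}

# symbolic 3x3 matrices: plain lists of 9 expressions, column-major
sm_zero <- function() as.list(rep(0, 9))
sm_eye <- function() as.list(c(1, 0, 0, 0, 1, 0, 0, 0, 1))
sm_ix <- function(i, j) i + 3L * (j - 1L)
sm_get <- function(M, i, j) M[[sm_ix(i, j)]]
sm_set <- function(M, i, j, e) { M[[sm_ix(i, j)]] <- e; M }

sm_t <- function(M) M[c(1, 4, 7, 2, 5, 8, 3, 6, 9)]

sm_add <- function(A, B) Map(s_add, A, B)
sm_sub <- function(A, B) Map(s_sub, A, B)
sm_scale <- function(s, A) lapply(A, function(e) s_mul(s, e))

sm_mul <- function(A, B) {
  M <- sm_zero()
  for (i in 1:3) for (j in 1:3) {
    e <- 0
    for (k in 1:3) e <- s_add(e, s_mul(sm_get(A, i, k), sm_get(B, k, j)))
    M <- sm_set(M, i, j, e)
  }
  M
}

sm_det <- function(F) {
  m <- function(i, j) sm_get(F, i, j)
  s_add(s_sub(s_mul(m(1, 1), s_sub(s_mul(m(2, 2), m(3, 3)), s_mul(m(2, 3), m(3, 2)))),
              s_mul(m(1, 2), s_sub(s_mul(m(2, 1), m(3, 3)), s_mul(m(2, 3), m(3, 1))))),
        s_mul(m(1, 3), s_sub(s_mul(m(2, 1), m(3, 2)), s_mul(m(2, 2), m(3, 1)))))
}

# cofactor matrix (H = det(F) F^{-T})
sm_cof <- function(F) {
  m <- function(i, j) sm_get(F, i, j)
  co <- function(a, b, c, d) s_sub(s_mul(a, b), s_mul(c, d))
  M <- sm_zero()
  M <- sm_set(M, 1, 1, co(m(2, 2), m(3, 3), m(2, 3), m(3, 2)))
  M <- sm_set(M, 2, 1, co(m(2, 3), m(3, 1), m(2, 1), m(3, 3)))
  M <- sm_set(M, 3, 1, co(m(2, 1), m(3, 2), m(2, 2), m(3, 1)))
  M <- sm_set(M, 1, 2, co(m(3, 2), m(1, 3), m(3, 3), m(1, 2)))
  M <- sm_set(M, 2, 2, co(m(3, 3), m(1, 1), m(3, 1), m(1, 3)))
  M <- sm_set(M, 3, 2, co(m(3, 1), m(1, 2), m(3, 2), m(1, 1)))
  M <- sm_set(M, 1, 3, co(m(1, 2), m(2, 3), m(1, 3), m(2, 2)))
  M <- sm_set(M, 2, 3, co(m(1, 3), m(2, 1), m(1, 1), m(2, 3)))
  M <- sm_set(M, 3, 3, co(m(1, 1), m(2, 2), m(1, 2), m(2, 1)))
  sm_t(M)  # entries above were filled as the adjugate (transposed cofactor)
}

sm_inv <- function(F, det = sm_det(F)) {
  lapply(sm_t(sm_cof(F)), function(e) s_div(e, det))
}

sm_trace <- function(M) s_add(s_add(sm_get(M, 1, 1), sm_get(M, 2, 2)), sm_get(M, 3, 3))

sm_ddot <- function(A, B) {
  e <- 0
  for (k in 1:9) e <- s_add(e, s_mul(A[[k]], B[[k]]))
  e
}

# outer product of two symbolic 3-vectors (lists of 3 expressions)
sm_outer <- function(a, b) {
  M <- sm_zero()
  for (i in 1:3) for (j in 1:3) M <- sm_set(M, i, j, s_mul(a[[i]], b[[j]]))
  M
}

# matrix * vector
sm_mv <- function(A, v) {
  lapply(1:3, function(i)
    s_add(s_add(s_mul(sm_get(A, i, 1), v[[1]]), s_mul(sm_get(A, i, 2), v[[2]])),
          s_mul(sm_get(A, i, 3), v[[3]])))
}

# divergence of a matrix field over reference coordinates: (div P)_i =
# sum_j d P_ij / dX_j
sm_div <- function(P, vars = c("X", "Y", "Z")) {
  lapply(1:3, function(i) {
    e <- 0
    for (j in 1:3) e <- s_add(e, s_d(sm_get(P, i, j), vars[j]))
    e
  })
}

# compile an expression (or list of expressions) to a vectorized function
# of (X, Y, Z, t)
s_compile <- function(e) {
  if (is.list(e)) {
    funs <- lapply(e, s_compile)
    return(function(X, Y, Z, t) {
      n <- max(length(X), length(Y), length(Z), length(t))
      out <- matrix(0, n, length(funs))
      for (k in seq_along(funs)) out[, k] <- rep_len(funs[[k]](X, Y, Z, t), n)
      out
    })
  }
  force(e)
  function(X, Y, Z, t) {
    n <- max(length(X), length(Y), length(Z), length(t))
    rep_len(eval(e, list(X = X, Y = Y, Z = Z, t = t)), n)
  }
}
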