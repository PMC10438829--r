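# Idealized left-ventricle geometry: a truncated half-ellipsoid shell with
# a structured hexahedral parameter grid split into tetrahedra, plus a
# rule-based fibre/sheet architecture (helix angle varying linearly across
# the wall). This is a synthetic stand-in for image-derived ventricular
# geometry, intended for qualitative perfusion demonstrations.

#' Idealized half-ellipsoid left-ventricle mesh
#'
#' The wall is the region between two confocal-ish ellipsoids truncated at
#' the base plane z = 0 and near the apex (the apex cap is cut at
#' `phi_apex` to keep the parameterization nondegenerate). Boundary tags:
#' `base` (z = 0), `endo`, `epi`, `apex` (truncation rim).
#'
#' @param a_endo,c_endo endocardial equatorial/longitudinal semi-axes
#' @param a_epi,c_epi epicardial semi-axes
#' @param n_trans,n_circ,n_long element counts across the wall, around the
#'   circumference, and from apex rim to base
#' @param phi_apex latitude of the apex truncation (radians below the
#'   equator plane; pi/2 would be the closed apex)
#' @return list with `mesh` (a `dvms_mesh`) and `params` (per-vertex
#'   transmural/circumferential/longitudinal coordinates)
#' @export
build_lv_mesh <- function(a_endo = 2, c_endo = 4, a_epi = 3, c_epi = 4.5,
                          n_trans = 2, n_circ = 12, n_long = 6,
                          phi_apex = 1.3) {
  nt <- n_trans + 1L; nc <- n_circ; nlg <- n_long + 1L
  xi <- seq(0, 1, length.out = nt)
  th <- seq(0, 2 * pi, length.out = nc + 1L)[seq_len(nc)]
  ph <- seq(-phi_apex, 0, length.out = nlg)
  vid <- function(i, j, k) i + (j %% nc) * nt + k * nt * nc + 1L  # 0-based i,j,k
  nv <- nt * nc * nlg
  vertices <- matrix(0, nv, 3)
  params <- matrix(0, nv, 3)
  for (k in 0:(nlg - 1L)) for (j in 0:(nc - 1L)) for (i in 0:(nt - 1L)) {
    a <- a_endo + xi[i + 1L] * (a_epi - a_endo)
    cc <- c_endo + xi[i + 1L] * (c_epi - c_endo)
    id <- vid(i, j, k)
    vertices[id, ] <- c(a * cos(ph[k + 1L]) * cos(th[j + 1L]),
                        a * cos(ph[k + 1L]) * sin(th[j + 1L]),
                        cc * sin(ph[k + 1L]))
    params[id, ] <- c(xi[i + 1L], th[j + 1L], ph[k + 1L])
  }
  paths <- list(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
                c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))
  corner <- function(i, j, k, code) {
    di <- bitwAnd(code, 1L); dj <- bitwAnd(bitwShiftR(code, 1L), 1L)
    dk <- bitwShiftR(code, 2L)
    vid(i + di, j + dj, k + dk)
  }
  cells <- matrix(0L, 0, 4)
  cl <- vector("list", n_trans * nc * n_long * 6L); ci <- 0L
  for (k in 0:(n_long - 1L)) for (j in 0:(nc - 1L)) for (i in 0:(n_trans - 1L))
    for (p in paths) {
      ci <- ci + 1L
      cl[[ci]] <- c(corner(i, j, k, p[1]), corner(i, j, k, p[2]),
                    corner(i, j, k, p[3]), corner(i, j, k, p[4]))
    }
  cells <- do.call(rbind, cl)
  ft <- facet_table(list(dim = 3L, vertices = vertices, cells = cells))
  facets <- ft$facets[ft$boundary, , drop = FALSE]
  # classify boundary facets by vertex parameters
  tag <- character(nrow(facets))
  for (f in seq_len(nrow(facets))) {
    pp <- params[facets[f, ], , drop = FALSE]
    if (all(abs(pp[, 3]) < 1e-9)) tag[f] <- "base"
    else if (all(pp[, 1] < 1e-9)) tag[f] <- "endo"
    else if (all(pp[, 1] > 1 - 1e-9)) tag[f] <- "epi"
    else tag[f] <- "apex"
  }
  mesh <- new_dvms_mesh(3L, vertices, cells, facets, tag)
  list(mesh = mesh, params = params)
}

#' Rule-based myocardial fibre and sheet field
#'
#' Fibres lie in the circumferential-longitudinal plane with a helix angle
#' varying linearly from `+helix_deg` at the endocardium to `-helix_deg` at
#' the epicardium; sheets point transmurally (radially), orthonormalized
#' against the fibre direction.
#'
#' @param lv output of [build_lv_mesh()]
#' @param helix_deg endocardial helix angle in degrees
#' @return a [fibre_frame()] with per-element `f0`, `s0`
#' @export
lv_fibre_field <- function(lv, helix_deg = 60) {
  mesh <- lv$mesh; params <- lv$params
  E <- ncells(mesh)
  f0 <- matrix(0, E, 3); s0 <- matrix(0, E, 3)
  for (e in seq_len(E)) {
    nd <- mesh$cells[e, ]
    xi <- mean(params[nd, 1])
    th <- atan2(mean(sin(params[nd, 2])), mean(cos(params[nd, 2])))
    ph <- mean(params[nd, 3])
    chat <- c(-sin(th), cos(th), 0)
    lhat <- c(-sin(ph) * cos(th), -sin(ph) * sin(th), cos(ph))
    rhat <- c(chat[2] * lhat[3] - chat[3] * lhat[2],
              chat[3] * lhat[1] - chat[1] * lhat[3],
              chat[1] * lhat[2] - chat[2] * lhat[1])
    rhat <- rhat / sqrt(sum(rhat^2))
    alpha <- helix_deg * pi / 180 * (1 - 2 * xi)
    f <- cos(alpha) * chat + sin(alpha) * lhat
    s <- rhat - sum(rhat * f) * f
    f0[e, ] <- f / sqrt(sum(f^2))
    s0[e, ] <- s / sqrt(sum(s^2))
  }
  fibre_frame(f0, s0)
}
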