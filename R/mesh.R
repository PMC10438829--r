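#' @importFrom Matrix sparseMatrix Diagonal
#' @importFrom stats setNames
#' @importFrom utils head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib dvmsfem, .registration = TRUE
NULL

# Simplicial meshes --------------------------------------------------------
#
# A `dvms_mesh` is a plain list:
#   dim        2 or 3
#   vertices   n x dim numeric matrix (reference coordinates)
#   cells      E x (dim+1) integer matrix, 1-based, positively oriented
#   facets     B x dim integer matrix of boundary facets (edges in 2D,
#              triangular faces in 3D)
#   facet_tag  character vector of length B
#   h          per-element characteristic size (shortest edge by default)

new_dvms_mesh <- function(dim, vertices, cells, facets, facet_tag) {
  cells <- orient_cells(vertices, cells, dim)
  m <- structure(list(
    dim = as.integer(dim),
    vertices = vertices,
    cells = cells,
    facets = facets,
    facet_tag = facet_tag
  ), class = "dvms_mesh")
  m$h <- element_sizes(m)
  m
}

dvms_error <- function(msg, class, ...) {
  stop(structure(class = c(class, "dvms_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Signed volumes of all elements
#'
#' Signed area (2D) or volume (3D) of every cell under the stored vertex
#' ordering. A valid mesh has all signed volumes positive.
#'
#' @param mesh a `dvms_mesh`
#' @return numeric vector of length `ncells(mesh)`
#' @export
cell_volumes <- function(mesh) {
  v <- mesh$vertices; c <- mesh$cells
  if (mesh$dim == 2L) {
    ax <- v[c[, 1], 1]; ay <- v[c[, 1], 2]
    bx <- v[c[, 2], 1]; by <- v[c[, 2], 2]
    cx <- v[c[, 3], 1]; cy <- v[c[, 3], 2]
    0.5 * ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  } else {
    a <- v[c[, 1], , drop = FALSE]
    e1 <- v[c[, 2], , drop = FALSE] - a
    e2 <- v[c[, 3], , drop = FALSE] - a
    e3 <- v[c[, 4], , drop = FALSE] - a
    (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
     e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
     e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
  }
}

orient_cells <- function(vertices, cells, dim) {
  m <- list(dim = dim, vertices = vertices, cells = cells)
  vol <- cell_volumes(m)
  flip <- vol < 0
  if (any(flip)) { # swap the last two vertices of negatively oriented cells
    tmp <- cells[flip, dim]
    cells[flip, dim] <- cells[flip, dim + 1L]
    cells[flip, dim + 1L] <- tmp
  }
  cells
}

#' Number of vertices / cells
#' @param mesh a `dvms_mesh`
#' @return integer count
#' @export
nvertices <- function(mesh) nrow(mesh$vertices)

#' @rdname nvertices
#' @export
ncells <- function(mesh) nrow(mesh$cells)

#' Structured simplicial box mesh
#'
#' Builds a structured triangulation of an axis-aligned box. Each grid
#' quadrilateral is split into 2 triangles and each hexahedron into 6
#' tetrahedra by the Kuhn split, with a single global diagonal orientation
#' (from the low corner to the high corner of every grid cell) so meshes are
#' reproducible bit-for-bit.
#'
#' @param extents numeric vector of per-axis lengths (length `dim`)
#' @param divisions integer vector of per-axis cell counts (length `dim`)
#' @param dim 2 or 3
#' @return a `dvms_mesh` with all boundary facets tagged `"boundary"`
#' @examples
#' m <- build_box_mesh(c(1, 1, 1), c(2, 2, 2), dim = 3)
#' ncells(m)   # 6 * 2^3
#' @export
build_box_mesh <- function(extents, divisions, dim = length(extents)) {
  dim <- as.integer(dim)
  if (!dim %in% c(2L, 3L)) dvms_error("dim must be 2 or 3", "dvms_invalid_argument")
  extents <- as.numeric(extents); divisions <- as.integer(divisions)
  if (length(extents) != dim || length(divisions) != dim)
    dvms_error("extents and divisions must have length dim", "dvms_invalid_argument")
  if (any(!is.finite(extents)) || any(extents <= 0))
    dvms_error("extents must be positive", "dvms_invalid_argument")
  if (any(is.na(divisions)) || any(divisions < 1L))
    dvms_error("divisions must be >= 1", "dvms_invalid_argument")

  n <- divisions + 1L
  if (dim == 2L) {
    xs <- seq(0, extents[1], length.out = n[1])
    ys <- seq(0, extents[2], length.out = n[2])
    vertices <- cbind(rep(xs, times = n[2]), rep(ys, each = n[1]))
    vid <- function(i, j) i + (j - 1L) * n[1]  # i,j 1-based grid indices
    i <- rep(seq_len(divisions[1]), times = divisions[2])
    j <- rep(seq_len(divisions[2]), each = divisions[1])
    v00 <- vid(i, j); v10 <- vid(i + 1L, j)
    v01 <- vid(i, j + 1L); v11 <- vid(i + 1L, j + 1L)
    # split along the (low corner)-(high corner) diagonal
    cells <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  } else {
    xs <- seq(0, extents[1], length.out = n[1])
    ys <- seq(0, extents[2], length.out = n[2])
    zs <- seq(0, extents[3], length.out = n[3])
    vertices <- cbind(rep(xs, times = n[2] * n[3]),
                      rep(rep(ys, each = n[1]), times = n[3]),
                      rep(zs, each = n[1] * n[2]))
    vid <- function(i, j, k) i + (j - 1L) * n[1] + (k - 1L) * n[1] * n[2]
    i <- rep(seq_len(divisions[1]), times = divisions[2] * divisions[3])
    j <- rep(rep(seq_len(divisions[2]), each = divisions[1]), times = divisions[3])
    k <- rep(seq_len(divisions[3]), each = divisions[1] * divisions[2])
    corner <- function(di, dj, dk) vid(i + di, j + dj, k + dk)
    v <- list(`000` = corner(0L, 0L, 0L), `100` = corner(1L, 0L, 0L),
              `010` = corner(0L, 1L, 0L), `110` = corner(1L, 1L, 0L),
              `001` = corner(0L, 0L, 1L), `101` = corner(1L, 0L, 1L),
              `011` = corner(0L, 1L, 1L), `111` = corner(1L, 1L, 1L))
    # Kuhn split: one tetrahedron per monotone lattice path 000 -> 111
    paths <- list(c("000", "100", "110", "111"),
                  c("000", "100", "101", "111"),
                  c("000", "010", "110", "111"),
                  c("000", "010", "011", "111"),
                  c("000", "001", "101", "111"),
                  c("000", "001", "011", "111"))
    cells <- do.call(rbind, lapply(paths, function(p)
      cbind(v[[p[1]]], v[[p[2]]], v[[p[3]]], v[[p[4]]])))
  }
  ft <- facet_table(list(dim = dim, vertices = vertices, cells = cells))
  facets <- ft$facets[ft$boundary, , drop = FALSE]
  new_dvms_mesh(dim, vertices, cells,
                facets, rep("boundary", nrow(facets)))
}

# All facets of all cells with multiplicity; boundary facets appear once.
# Returns facets (vertex index matrix), owner cell ids, and a boundary flag
# for the unique facet list.
facet_table <- function(mesh) {
  d <- mesh$dim; cells <- mesh$cells; E <- nrow(cells)
  if (d == 2L) {
    loc <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  } else {
    loc <- list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  }
  fac <- do.call(rbind, lapply(loc, function(ix) cells[, ix, drop = FALSE]))
  owner <- rep(seq_len(E), times = length(loc))
  key <- apply(t(apply(fac, 1L, sort)), 1L, paste, collapse = ",")
  cnt <- table(key)
  once <- names(cnt)[cnt == 1L]
  first <- !duplicated(key)
  list(facets = fac[first, , drop = FALSE],
       owner = owner[first],
       key = key[first],
       boundary = key[first] %in% once,
       all_key = key, all_owner = owner, all_facets = fac)
}

#' Tag boundary facets by geometric predicates
#'
#' Each predicate is a function taking the coordinate matrix of one facet's
#' vertices (rows are vertices) and returning `TRUE` if the facet belongs to
#' that tag, or the string `"otherwise"`, which matches facets no explicit
#' predicate claims. The explicit predicates must partition the boundary:
#' a facet matched by none (without an `"otherwise"` entry) or by two or
#' more predicates raises a tagging-conflict error naming the facet.
#'
#' @param mesh a `dvms_mesh`
#' @param named_predicates named list of predicate functions (or the string
#'   `"otherwise"` for the catch-all tag)
#' @return the mesh with `facet_tag` rewritten
#' @examples
#' m <- build_box_mesh(c(1, 1), c(2, 2), dim = 2)
#' m <- tag_boundary(m, list(
#'   bottom = on_plane(2, 0),
#'   rest = "otherwise"))
#' table(m$facet_tag)
#' @export
tag_boundary <- function(mesh, named_predicates) {
  tags <- names(named_predicates)
  if (is.null(tags) || any(tags == ""))
    dvms_error("predicates must be named", "dvms_invalid_argument")
  is_otherwise <- vapply(named_predicates, function(p)
    is.character(p) && identical(p, "otherwise"), logical(1))
  if (sum(is_otherwise) > 1L)
    dvms_error("at most one 'otherwise' tag", "dvms_invalid_argument")
  B <- nrow(mesh$facets)
  hit <- matrix(FALSE, B, length(named_predicates))
  for (f in seq_len(B)) {
    X <- mesh$vertices[mesh$facets[f, ], , drop = FALSE]
    for (tI in which(!is_otherwise))
      hit[f, tI] <- isTRUE(named_predicates[[tI]](X))
  }
  nhit <- rowSums(hit)
  if (any(is_otherwise)) {
    hit[nhit == 0L, which(is_otherwise)] <- TRUE
    nhit <- rowSums(hit)
  }
  bad <- which(nhit != 1L)
  if (length(bad)) {
    f <- bad[1]
    dvms_error(sprintf(
      "facet %d (vertices %s) matched by %d predicates; predicates must partition the boundary",
      f, paste(mesh$facets[f, ], collapse = ","), nhit[f]),
      "dvms_tagging_conflict", facet = f)
  }
  mesh$facet_tag <- tags[apply(hit, 1L, which)]
  mesh
}

#' Plane membership predicate for [tag_boundary()]
#'
#' @param axis coordinate index (1 = X, 2 = Y, 3 = Z)
#' @param value plane coordinate
#' @param tol absolute tolerance
#' @return predicate function for [tag_boundary()]
#' @export
on_plane <- function(axis, value, tol = 1e-9) {
  force(axis); force(value); force(tol)
  function(X) all(abs(X[, axis] - value) <= tol)
}

#' Per-element characteristic length
#'
#' The characteristic element size h entering the stabilization time scale
#' and the CFL rule. The default is the shortest edge of each simplex (the
#' conservative choice for a wave-speed CFL bound); `"inradius"` uses twice
#' the inscribed-sphere radius instead.
#'
#' @param mesh a `dvms_mesh`
#' @param method `"shortest_edge"` (default) or `"inradius"`
#' @return numeric vector, one positive length per element
#' @export
element_sizes <- function(mesh, method = c("shortest_edge", "inradius")) {
  method <- match.arg(method)
  vol <- cell_volumes(mesh)
  if (any(vol <= 0))
    dvms_error("mesh contains degenerate (non-positive volume) elements",
               "dvms_degenerate_element")
  v <- mesh$vertices; c <- mesh$cells; d <- mesh$dim
  pairs <- utils::combn(d + 1L, 2L)
  edge_len2 <- sapply(seq_len(ncol(pairs)), function(k) {
    a <- v[c[, pairs[1, k]], , drop = FALSE]
    b <- v[c[, pairs[2, k]], , drop = FALSE]
    rowSums((a - b)^2)
  })
  if (is.null(dim(edge_len2))) edge_len2 <- matrix(edge_len2, nrow = 1L)
  if (method == "shortest_edge") return(sqrt(apply(edge_len2, 1L, min)))
  # inradius: r = d * V / (total facet measure); h := 2r
  if (d == 2L) {
    per <- sqrt(edge_len2[, 1]) + sqrt(edge_len2[, 2]) + sqrt(edge_len2[, 3])
    2 * 2 * vol / per
  } else {
    tri_area <- function(ix) {
      a <- v[c[, ix[1]], , drop = FALSE]
      b <- v[c[, ix[2]], , drop = FALSE] - a
      cc <- v[c[, ix[3]], , drop = FALSE] - a
      n1 <- b[, 2] * cc[, 3] - b[, 3] * cc[, 2]
      n2 <- b[, 3] * cc[, 1] - b[, 1] * cc[, 3]
      n3 <- b[, 1] * cc[, 2] - b[, 2] * cc[, 1]
      0.5 * sqrt(n1^2 + n2^2 + n3^2)
    }
    A <- tri_area(c(1, 2, 3)) + tri_area(c(1, 2, 4)) +
         tri_area(c(1, 3, 4)) + tri_area(c(2, 3, 4))
    2 * 3 * vol / A
  }
}

#' @export
print.dvms_mesh <- function(x, ...) {
  cat(sprintf("dvms_mesh: %dD, %d vertices, %d %s, %d boundary facets\n",
              x$dim, nvertices(x), ncells(x),
              if (x$dim == 2L) "triangles" else "tetrahedra",
              nrow(x$facets)))
  cat(sprintf("  h: min %.4g, max %.4g; volume %.6g\n",
              min(x$h), max(x$h), sum(cell_volumes(x))))
  tt <- table(x$facet_tag)
  cat("  facet tags:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

# VTU / MSH i/o ------------------------------------------------------------

#' Write a mesh (plus nodal/cell fields) as a VTK XML unstructured grid
#'
#' @param mesh a `dvms_mesh`
#' @param path output `.vtu` path
#' @param point_data named list of nodal fields (numeric vector of length
#'   `nvertices`, or matrix with that many rows for vector fields)
#' @param cell_data named list of per-cell fields
#' @return `path`, invisibly
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nvertices(mesh); E <- ncells(mesh)
  chk <- function(fields, len, what) {
    for (nm in names(fields)) {
      f <- fields[[nm]]
      sz <- if (is.matrix(f)) nrow(f) else length(f)
      if (sz != len)
        dvms_error(sprintf("field '%s' has %d rows, expected %d %s",
                           nm, sz, len, what), "dvms_invalid_field")
    }
  }
  chk(point_data, n, "vertices"); chk(cell_data, E, "cells")
  pts <- mesh$vertices
  if (ncol(pts) == 2L) pts <- cbind(pts, 0)
  vtk_type <- if (mesh$dim == 2L) 5L else 10L  # triangle / tetra
  num <- function(x) paste(format(x, digits = 17, scientific = TRUE, trim = TRUE),
                           collapse = " ")
  arr <- function(name, data) {
    ncomp <- if (is.matrix(data)) ncol(data) else 1L
    if (is.matrix(data) && ncomp == 2L) { data <- cbind(data, 0); ncomp <- 3L }
    vals <- if (is.matrix(data)) as.vector(t(data)) else data
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, ncomp, num(vals))
  }
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, E)
  w('<Points>')
  w('<DataArray type="Float64" NumberOfComponents="3" format="ascii">\n%s\n</DataArray>',
    num(as.vector(t(pts))))
  w('</Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n</DataArray>',
    paste(as.vector(t(mesh$cells)) - 1L, collapse = " "))
  w('<DataArray type="Int64" Name="offsets" format="ascii">\n%s\n</DataArray>',
    paste(seq_len(E) * (mesh$dim + 1L), collapse = " "))
  w('<DataArray type="UInt8" Name="types" format="ascii">\n%s\n</DataArray>',
    paste(rep(vtk_type, E), collapse = " "))
  w('</Cells>')
  w('<PointData>')
  for (nm in names(point_data)) w("%s", arr(nm, point_data[[nm]]))
  w('</PointData>')
  w('<CellData>')
  for (nm in names(cell_data)) w("%s", arr(nm, cell_data[[nm]]))
  w('</CellData>')
  w('</Piece>')
  w('</UnstructuredGrid>')
  w('</VTKFile>')
  invisible(path)
}

#' Read a Gmsh MSH (ASCII v2.2 or v4.1) simplicial mesh
#'
#' Triangles (2D) or tetrahedra (3D) become cells; lower-dimensional
#' elements on the boundary become tagged boundary facets, with physical
#' group names (from `$PhysicalNames`) used as tags where present, and the
#' numeric physical id otherwise. Gmsh's 1-based node tags are remapped to
#' the package's contiguous 1-based indexing. Hexahedral, quadrilateral, or
#' higher-order cells raise an unsupported-format error.
#'
#' @param path path to an ASCII `.msh` file
#' @return a `dvms_mesh`
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    a <- which(lines == paste0("$", name)); b <- which(lines == paste0("$End", name))
    if (!length(a)) return(NULL)
    lines[(a[1] + 1L):(b[1] - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) dvms_error("not a Gmsh MSH file", "dvms_unsupported_format")
  ver <- as.numeric(strsplit(trimws(fmt[1]), "\\s+")[[1]][1])
  phys <- sec("PhysicalNames")
  phys_names <- character()
  if (!is.null(phys)) {
    for (ln in phys[-1]) {
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      phys_names[tk[2]] <- gsub('"', "", paste(tk[-(1:2)], collapse = " "))
    }
  }
  if (ver < 4) {
    nl <- sec("Nodes")
    nn <- as.integer(nl[1])
    nod <- matrix(as.numeric(unlist(strsplit(trimws(nl[1 + seq_len(nn)]), "\\s+"))),
                  ncol = 4, byrow = TRUE)
    node_tag <- as.integer(nod[, 1]); coords <- nod[, 2:4, drop = FALSE]
    el <- sec("Elements")
    ne <- as.integer(el[1])
    etype <- integer(ne); ephys <- integer(ne); enodes <- vector("list", ne)
    for (e in seq_len(ne)) {
      tk <- as.integer(strsplit(trimws(el[1 + e]), "\\s+")[[1]])
      etype[e] <- tk[2]; ntags <- tk[3]
      ephys[e] <- if (ntags >= 1L) tk[4] else 0L
      enodes[[e]] <- tk[(4 + ntags):length(tk)]
    }
  } else {
    # v4.1: $Entities maps (dim, entityTag) -> physical tags
    ent <- sec("Entities")
    ent_phys <- list()
    if (!is.null(ent)) {
      counts <- as.integer(strsplit(trimws(ent[1]), "\\s+")[[1]])  # pts, crv, srf, vol
      row <- 2L
      for (ed in 0:3) {
        for (r in seq_len(counts[ed + 1])) {
          tk <- as.numeric(strsplit(trimws(ent[row]), "\\s+")[[1]]); row <- row + 1L
          tag <- as.integer(tk[1])
          nbox <- if (ed == 0L) 3L else 6L
          nphys <- as.integer(tk[1 + nbox + 1L])
          p <- if (nphys >= 1L) as.integer(tk[1 + nbox + 2L]) else 0L
          ent_phys[[paste(ed, tag)]] <- p
        }
      }
    }
    nl <- sec("Nodes")
    hdr <- as.numeric(strsplit(trimws(nl[1]), "\\s+")[[1]])
    nblocks <- hdr[1]; nn <- hdr[2]
    node_tag <- integer(nn); coords <- matrix(0, nn, 3); row <- 2L; at <- 0L
    for (b in seq_len(nblocks)) {
      bh <- as.integer(strsplit(trimws(nl[row]), "\\s+")[[1]]); row <- row + 1L
      nb <- bh[4]
      if (nb > 0L) {
        node_tag[at + seq_len(nb)] <- as.integer(nl[row:(row + nb - 1L)])
        row <- row + nb
        cc <- matrix(as.numeric(unlist(strsplit(trimws(nl[row:(row + nb - 1L)]), "\\s+"))),
                     ncol = 3, byrow = TRUE)
        coords[at + seq_len(nb), ] <- cc
        row <- row + nb; at <- at + nb
      }
    }
    el <- sec("Elements")
    hdr <- as.integer(strsplit(trimws(el[1]), "\\s+")[[1]])
    nblocks <- hdr[1]; ne <- hdr[2]
    etype <- integer(0); ephys <- integer(0); enodes <- list(); row <- 2L
    for (b in seq_len(nblocks)) {
      bh <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]]); row <- row + 1L
      bdim <- bh[1]; btag <- bh[2]; btype <- bh[3]; nb <- bh[4]
      p <- ent_phys[[paste(bdim, btag)]]
      if (is.null(p)) p <- 0L
      for (r in seq_len(nb)) {
        tk <- as.integer(strsplit(trimws(el[row]), "\\s+")[[1]]); row <- row + 1L
        etype <- c(etype, btype); ephys <- c(ephys, p)
        enodes[[length(enodes) + 1L]] <- tk[-1]
      }
    }
  }
  supported <- c(`1` = 2L, `2` = 3L, `4` = 4L, `15` = 1L)  # line, tri, tet, point
  if (any(!as.character(etype) %in% names(supported)))
    dvms_error(sprintf("unsupported element type(s) in MSH file: %s",
                       paste(unique(etype[!as.character(etype) %in% names(supported)]),
                             collapse = ", ")),
               "dvms_unsupported_format")
  has_tet <- any(etype == 4L); has_tri <- any(etype == 2L)
  dim <- if (has_tet) 3L else if (has_tri) 2L else
    dvms_error("no triangles or tetrahedra in MSH file", "dvms_unsupported_format")
  remap <- integer(max(node_tag)); remap[node_tag] <- seq_along(node_tag)
  verts <- coords[, seq_len(dim), drop = FALSE]
  cell_type <- if (dim == 3L) 4L else 2L
  facet_type <- if (dim == 3L) 2L else 1L
  cells <- do.call(rbind, lapply(enodes[etype == cell_type], function(x) remap[x]))
  fsel <- etype == facet_type
  tagname <- function(p) {
    nm <- phys_names[as.character(p)]
    ifelse(is.na(nm) | !length(nm), as.character(p), nm)
  }
  if (any(fsel)) {
    facets <- do.call(rbind, lapply(enodes[fsel], function(x) remap[x]))
    ftag <- vapply(ephys[fsel], tagname, character(1))
  } else {
    ft <- facet_table(list(dim = dim, vertices = verts, cells = cells))
    facets <- ft$facets[ft$boundary, , drop = FALSE]
    ftag <- rep("boundary", nrow(facets))
  }
  new_dvms_mesh(dim, verts, cells, facets, ftag)
}
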