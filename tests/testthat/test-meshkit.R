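# Structured meshes, boundary tagging, element sizes and mesh i/o.

test_that("structured box meshes have the construction counts and volumes", {
  m2 <- build_box_mesh(c(1, 1), c(1, 1), dim = 2)
  expect_equal(nvertices(m2), 4L)
  expect_equal(ncells(m2), 2L)

  m3 <- build_box_mesh(c(1, 1, 1), c(1, 1, 1), dim = 3)
  expect_equal(nvertices(m3), 8L)
  expect_equal(ncells(m3), 6L)

  m6 <- build_box_mesh(c(1, 1, 1), c(6, 6, 6), dim = 3)
  expect_equal(ncells(m6), 6L * 6^3)
  expect_equal(min(m6$h), 1 / 6, tolerance = 1e-12)

  # signed volumes positive and summing to the box volume
  for (dv in list(c(2, 3), c(5, 1))) {
    m <- build_box_mesh(c(2.5, 0.8), dv, dim = 2)
    v <- cell_volumes(m)
    expect_true(all(v > 0))
    expect_equal(sum(v), 2.5 * 0.8, tolerance = 1e-12)
  }
  for (dv in list(c(2, 3, 4), c(1, 5, 2))) {
    m <- build_box_mesh(c(1.2, 2, 0.5), dv, dim = 3)
    v <- cell_volumes(m)
    expect_true(all(v > 0))
    expect_equal(sum(v), 1.2 * 2 * 0.5, tolerance = 1e-12)
  }
  # boundary facet count of the structured split: each boundary quad of the
  # grid contributes 2 triangles (3D) / each edge 1 segment (2D)
  m <- build_box_mesh(c(1, 1, 1), c(2, 3, 4), dim = 3)
  expect_equal(nrow(m$facets), 4L * (2 * 3 + 3 * 4 + 2 * 4))
  expect_error(build_box_mesh(c(-1, 1), c(1, 1), dim = 2),
               class = "dvms_invalid_argument")
  expect_error(build_box_mesh(c(1, 1), c(0, 1), dim = 2),
               class = "dvms_invalid_argument")
})

test_that("boundary tagging partitions facets and reports conflicts", {
  m <- unit_cube_mesh(2)
  m <- tag_boundary(m, list(bottom = on_plane(3, 0), rest = "otherwise"))
  expect_equal(sum(m$facet_tag == "bottom"), 2L * 2 * 2)
  # every bottom facet truly lies in Z = 0
  for (f in which(m$facet_tag == "bottom"))
    expect_true(all(abs(m$vertices[m$facets[f, ], 3]) < 1e-12))

  # swelling-cube tagging: left and right faces hold divisions^2 * 2 facets
  d <- 3L
  mc <- build_box_mesh(rep(0.01, 3), rep(d, 3), dim = 3)
  mc <- tag_boundary(mc, list(left = on_plane(1, 0), right = on_plane(1, 0.01),
                              lateral = "otherwise"))
  expect_equal(sum(mc$facet_tag == "left"), 2L * d^2)
  expect_equal(sum(mc$facet_tag == "right"), 2L * d^2)

  # unmatched facet -> tagging-conflict error naming the facet
  expect_error(tag_boundary(m, list(bottom = on_plane(3, 0))),
               class = "dvms_tagging_conflict")
  # doubly matched facet
  expect_error(tag_boundary(m, list(a = on_plane(3, 0), b = on_plane(3, 0),
                                    rest = "otherwise")),
               class = "dvms_tagging_conflict")
})

test_that("element size is the shortest edge, rigid-motion invariant and homogeneous", {
  m <- unit_square_mesh(1)  # right triangles with legs 1, 1, sqrt(2)
  expect_equal(element_sizes(m), c(1, 1), tolerance = 1e-14)
  m6 <- build_box_mesh(c(1, 1, 1), c(6, 6, 6), dim = 3)
  expect_equal(min(element_sizes(m6)), 1 / 6, tolerance = 1e-14)

  # homogeneity of degree 1 and rigid-motion invariance
  m <- unit_cube_mesh(2)
  h0 <- element_sizes(m)
  ms <- m; ms$vertices <- 2 * ms$vertices
  expect_equal(element_sizes(ms), 2 * h0, tolerance = 1e-12)
  th <- 0.7
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mr <- m; mr$vertices <- m$vertices %*% t(Q) + 3
  expect_equal(element_sizes(mr), h0, tolerance = 1e-12)

  # inradius variant is positive and below the shortest edge
  hi <- element_sizes(m, method = "inradius")
  expect_true(all(hi > 0 & hi < h0 + 1e-12))

  bad <- m
  bad$vertices[bad$cells[1, 2], ] <- bad$vertices[bad$cells[1, 1], ]
  expect_error(element_sizes(bad), class = "dvms_degenerate_element")
})

test_that("VTU writer round-trips meshes and rejects bad fields", {
  m <- unit_square_mesh(1)
  path <- tempfile(fileext = ".vtu")
  p <- seq_len(nvertices(m)) / 10
  u <- cbind(p, -p)
  write_vtu(m, path, point_data = list(p = p, u = u),
            cell_data = list(vol = cell_volumes(m)))
  # independent read-back through xml2
  doc <- xml2::read_xml(path)
  pts <- as.numeric(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc, ".//Points/DataArray"))), "\\s+")[[1]])
  expect_equal(matrix(pts, ncol = 3, byrow = TRUE)[, 1:2], unname(m$vertices),
               tolerance = 1e-12)
  conn <- as.integer(strsplit(trimws(xml2::xml_text(
    xml2::xml_find_first(doc, ".//DataArray[@Name='connectivity']"))), "\\s+")[[1]])
  expect_equal(matrix(conn, ncol = 3, byrow = TRUE) + 1L, unname(m$cells))
  parr <- xml2::xml_find_first(doc, ".//PointData/DataArray[@Name='p']")
  expect_equal(as.numeric(strsplit(trimws(xml2::xml_text(parr)), "\\s+")[[1]]), p)
  uarr <- xml2::xml_find_first(doc, ".//PointData/DataArray[@Name='u']")
  expect_equal(xml2::xml_attr(uarr, "NumberOfComponents"), "3")

  expect_error(write_vtu(m, path, point_data = list(p = p[-1])),
               class = "dvms_invalid_field")
})

msh_v2_text <- c(
  "$MeshFormat", "2.2 0 8", "$EndMeshFormat",
  "$PhysicalNames", "2",
  '2 1 "wall"', '3 2 "body"',
  "$EndPhysicalNames",
  "$Nodes", "4",
  "1 0 0 0", "2 1 0 0", "3 0 1 0", "4 0 0 1",
  "$EndNodes",
  "$Elements", "5",
  "1 4 2 2 1 1 2 3 4",
  "2 2 2 1 1 1 2 3",
  "3 2 2 1 1 1 2 4",
  "4 2 2 1 1 1 3 4",
  "5 2 2 1 1 2 3 4",
  "$EndElements")

msh_v4_text <- c(
  "$MeshFormat", "4.1 0 8", "$EndMeshFormat",
  "$PhysicalNames", "2",
  '2 1 "wall"', '3 2 "body"',
  "$EndPhysicalNames",
  "$Entities", "0 0 1 1",
  "1 0 0 0 1 1 1 1 1 0",
  "2 0 0 0 1 1 1 1 2 0",
  "$EndEntities",
  "$Nodes", "2 4 1 4",
  "2 1 0 2", "1", "2", "0 0 0", "1 0 0",
  "2 2 0 2", "3", "4", "0 1 0", "0 0 1",
  "$EndNodes",
  "$Elements", "2 5 1 5",
  "2 1 2 4",
  "1 1 2 3", "2 1 2 4", "3 1 3 4", "4 2 3 4",
  "3 2 4 1",
  "5 1 2 3 4",
  "$EndElements")

test_that("Gmsh MSH reader handles v2.2 and v4.1 tetrahedral meshes", {
  for (txt in list(msh_v2_text, msh_v4_text)) {
    path <- tempfile(fileext = ".msh")
    writeLines(txt, path)
    m <- read_msh(path)
    expect_equal(m$dim, 3L)
    expect_equal(nvertices(m), 4L)
    expect_equal(ncells(m), 1L)
    expect_equal(sum(cell_volumes(m)), 1 / 6, tolerance = 1e-12)
    expect_equal(nrow(m$facets), 4L)
    expect_true(all(m$facet_tag == "wall"))
  }
})

test_that("MSH reader rejects unsupported cell types", {
  hex <- c("$MeshFormat", "2.2 0 8", "$EndMeshFormat",
           "$Nodes", "8",
           paste(1:8, c(0,1,1,0,0,1,1,0), c(0,0,1,1,0,0,1,1), c(0,0,0,0,1,1,1,1)),
           "$EndNodes",
           "$Elements", "1",
           "1 5 2 1 1 1 2 3 4 5 6 7 8",  # type 5 = hexahedron
           "$EndElements")
  path <- tempfile(fileext = ".msh")
  writeLines(hex, path)
  expect_error(read_msh(path), class = "dvms_unsupported_format")
})
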