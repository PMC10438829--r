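Package: dvmsfem
Title: Stabilized Equal-Order Finite Elements for Incompressible
    Hyperelastodynamics and Poroelastodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A dynamic variational multiscale (D-VMS) stabilized linear
    finite element solver for anisotropic incompressible finite-strain
    elastodynamics and Darcy-coupled poroelastodynamics, aimed at cardiac
    biomechanics and perfusion. Provides structured simplicial mesh
    generation with Gmsh import and VTK export, fibre-reinforced
    hyperelastic constitutive models (neo-Hookean, Mooney-Rivlin, standard
    reinforced, Holzapfel-Ogden) with active stress, pore-fluid
    pressure-volume and compaction models, BDF2/Newton time stepping with
    equal-order velocity-pressure(-added mass) interpolation stabilized by
    a fine-scale velocity model, manufactured-solution verification with
    symbolically derived forcing, and benchmark case drivers (compressed
    block, bending and twisting columns, swelling and shrinking poroelastic
    cubes, and an idealized left-ventricle perfusion demonstration).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
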