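# Generators, VTK export and the command-line wrappers.

test_that("the illustrative example validates and matches its manifest", {
  ex <- fml_illustrative_example()
  expect_identical(nrow(fml_validate(ex$model)), 0L)
  man <- ex$manifest
  expect_identical(man$connectivity, matrix(c(1L, 2L, 4L, 5L,
                                              2L, 3L, 5L, 6L), 2L, byrow = TRUE))
  p <- fml_get(ex$model, "pressure")
  corners <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2L, byrow = TRUE)
  for (el in 1:2) for (ln in 1:4)
    expect_identical(
      fml_evaluate_mesh_field(p, ex$mesh_argument, el, corners[ln, ])$vector,
      man$corner_pressure[ln, el])
})

test_that("grid connectivity reproduces the 89-element strip pattern", {
  src <- fml_grid_connectivity(89L)
  arr <- fml_read_array(src)
  expect_identical(dim(arr), c(89L, 4L))
  expect_identical(arr[1L, ], c(1, 2, 11, 12))
  expect_identical(arr[89L, ], c(89, 90, 99, 100))

  one <- fml_read_array(fml_grid_connectivity(1L))
  expect_identical(one, matrix(c(1, 2, 11, 12), 1L))
  expect_error(fml_grid_connectivity(0L), class = "fml_definition_error")
})

test_that("multi-subject HDF5 models evaluate each subject from one resource", {
  dir <- withr::local_tempdir()
  ms <- fml_multisubject_hdf5(5L, 6L, seed = 9L, path = file.path(dir, "ms.h5"))
  expect_length(ms$fields, 5L)
  for (s in 1:5) {
    f <- fml_get(ms$model, ms$fields[s])
    for (k in c(1L, 4L)) {
      v <- fml_evaluate(f, list(nodes.argument = k))
      expect_equal(v$vector, ms$coords[s, k, ], tolerance = 1e-15)
    }
  }
  expect_identical(nrow(fml_validate(ms$model)), 0L)

  # a single-subject model equals a text-backed twin under evaluation
  one <- fml_multisubject_hdf5(1L, 4L, seed = 2L, path = file.path(dir, "one.h5"))
  twin <- local({
    lib <- fml_library()
    m <- fml_model("twin")
    for (nm in c("real.1d", "coordinates.rc.3d",
                 "coordinates.rc.3d.component.argument"))
      fml_import(m, lib, nm)
    nodes <- fml_ensemble_type("nodes", 1:4)
    narg <- fml_argument("nodes.argument", nodes)
    flat <- matrix(one$coords[1L, , ], ncol = 3L)
    res <- fml_data_resource("txt", "inline", text = fml_render_text_array(flat))
    src <- fml_data_source("txt.data", res, c(4L, 3L))
    fml_add(m, nodes, narg, res)
    par <- fml_parameter("geometry.params", fml_get(m, "real.1d"),
                         list(narg, fml_get(m, "coordinates.rc.3d.component.argument")),
                         src)
    agg <- fml_aggregate("geometry", fml_get(m, "coordinates.rc.3d"),
                         delegate = par,
                         index_argument = fml_get(m, "coordinates.rc.3d.component.argument"))
    fml_add(m, par, agg)
    m
  })
  for (k in 1:4)
    expect_identical(
      fml_evaluate(fml_get(one$model, one$fields[1L]),
                   list(nodes.argument = k))$vector,
      fml_evaluate(fml_get(twin, "geometry"), list(nodes.argument = k))$vector)

  # determinism: same seed, byte-identical HDF5
  pa <- file.path(dir, "det1.h5"); pb <- file.path(dir, "det2.h5")
  fml_multisubject_hdf5(2L, 3L, seed = 7L, path = pa)
  fml_multisubject_hdf5(2L, 3L, seed = 7L, path = pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
})

test_that("VTK export tessellates without merging points and matches evaluation", {
  ex <- fml_illustrative_example()
  lines <- fml_export_vtk(ex$model, "geometry", "pressure", samples_per_edge = 1L)
  expect_identical(lines[grep("^POINTS", lines)], "POINTS 8 double")
  expect_identical(lines[grep("^CELLS ", lines)], "CELLS 2 10")
  expect_identical(sum(lines == "9"), 2L)
  expect_identical(sum(grepl("^SCALARS pressure", lines)), 1L)
  # corner point data equal direct evaluation (order: xi1 fastest per element)
  i0 <- grep("LOOKUP_TABLE default", lines)[1L]
  vals <- as.numeric(lines[(i0 + 1L):(i0 + 8L)])
  p <- fml_get(ex$model, "pressure")
  corners <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2L, byrow = TRUE)
  expected <- c(vapply(1:2, function(el) vapply(1:4, function(ln)
    fml_evaluate_mesh_field(p, ex$mesh_argument, el, corners[ln, ])$vector,
    0), numeric(4L)))
  expect_identical(vals, as.numeric(sprintf("%.17g", expected)))

  expect_error(fml_export_vtk(ex$model, "geometry", samples_per_edge = 0L),
               class = "fml_definition_error")
  # finer tessellation: (n+1)^2 points and n^2 quads per element
  l3 <- fml_export_vtk(ex$model, "geometry", character(), samples_per_edge = 3L)
  expect_identical(l3[grep("^POINTS", l3)], "POINTS 32 double")
  expect_identical(l3[grep("^CELLS ", l3)], "CELLS 18 90")
})

test_that("cli validate exit status reflects diagnostics and eval prints values", {
  dir <- withr::local_tempdir()
  ex <- fml_illustrative_example()
  f <- file.path(dir, "ex.xml")
  fml_write_xml(ex$model, f)
  out <- capture.output(status <- fml_cli_validate(f))
  expect_identical(status, 0L)
  expect_match(out, "valid", all = FALSE)

  # a document with a type diagnostic exits non-zero
  bad <- '<?xml version="1.0"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
<Region name="bad">
  <ContinuousType name="real"/>
  <BooleanType name="bool"/>
  <EnsembleType name="E"><Members><MemberRange min="1" max="2"/></Members></EnsembleType>
  <ArgumentEvaluator name="n" valueType="E"/>
  <ConstantEvaluator name="k" valueType="real" value="1"/>
  <PiecewiseEvaluator name="pw" valueType="bool">
    <IndexEvaluator evaluator="n"/>
    <EvaluatorMap><EvaluatorMapEntry value="1" evaluator="k"/></EvaluatorMap>
  </PiecewiseEvaluator>
</Region></Fieldml>'
  bf <- file.path(dir, "bad.xml")
  writeLines(bad, bf)
  out2 <- capture.output(status2 <- fml_cli_validate(bf))
  expect_identical(status2, 1L)
  expect_match(out2, "branch-type", all = FALSE)

  out3 <- capture.output(status3 <- fml_cli_eval(
    f, "pressure", "mesh.argument=1,0.5,0.5"))
  expect_identical(status3, 0L)
  expect_identical(as.numeric(out3), ex$manifest$center_pressure[1L])

  out4 <- capture.output(status4 <- fml_cli_info(f))
  expect_identical(status4, 0L)
  expect_match(out4, "two_square_example", all = FALSE)

  out5 <- capture.output(status5 <- fml_cli_make_example(file.path(dir, "gen")))
  expect_identical(status5, 0L)
  expect_true(file.exists(file.path(dir, "gen", "two_square_example.xml")))
  expect_true(file.exists(file.path(dir, "gen", "FieldML_Library_0.5.xml")))
  regen <- fml_parse_xml(file.path(dir, "gen", "two_square_example.xml"))
  expect_true(fml_isomorphic(ex$model, regen))
})
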