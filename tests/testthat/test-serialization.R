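# XML serialization: round-trip isomorphism, determinism, imports.

test_that("the illustrative example survives an XML round-trip", {
  ex <- fml_illustrative_example()
  doc <- fml_write_xml(ex$model)
  m2 <- fml_parse_xml(doc)
  expect_identical(nrow(attr(m2, "diagnostics")), 0L)
  expect_true(fml_isomorphic(ex$model, m2))
  # object counts match the generator's manifest
  expect_identical(length(m2$types), ex$manifest$counts$types)
  expect_identical(length(m2$evaluators), ex$manifest$counts$evaluators)
  expect_identical(length(m2$data_resources), ex$manifest$counts$data_resources)
  # evaluations are preserved at seeded sample points
  set.seed(55)
  p1 <- fml_get(ex$model, "pressure"); p2 <- fml_get(m2, "pressure")
  ma2 <- fml_get(m2, "mesh.argument")
  for (i in 1:50) {
    el <- sample(1:2, 1L); xi <- runif(2)
    expect_identical(
      fml_evaluate_mesh_field(p1, ex$mesh_argument, el, xi)$vector,
      fml_evaluate_mesh_field(p2, ma2, el, xi)$vector)
  }
})

test_that("write is deterministic and round-trips 100 seeded random models", {
  for (seed in 1:100) {
    m <- random_model(seed)
    s1 <- as.character(fml_write_xml(m))
    expect_identical(s1, as.character(fml_write_xml(m)))
    m2 <- fml_parse_xml(xml2::read_xml(s1))
    expect_true(fml_isomorphic(m, m2))
    expect_identical(nrow(attr(m2, "diagnostics")), 0L)
    # and the re-written copy is byte-identical to the first rendering
    expect_identical(as.character(fml_write_xml(m2)), s1)
  }
})

test_that("an empty region produces a minimal valid document", {
  m <- fml_model("empty")
  doc <- fml_write_xml(m)
  expect_identical(xml2::xml_name(xml2::xml_root(doc)), "Fieldml")
  region <- xml2::xml_find_first(doc, "./Region")
  expect_identical(xml2::xml_attr(region, "name"), "empty")
  expect_length(xml2::xml_children(region), 0L)
  expect_true(fml_isomorphic(m, fml_parse_xml(doc)))
})

test_that("inline payloads are embedded verbatim and non-contiguous members listed", {
  m <- fml_model("payload")
  res <- fml_data_resource("r", "inline", text = "1 2 11 12\n2 3 12 13")
  fml_data_source("d", res, c(2L, 4L))
  fml_add(m, res, fml_ensemble_type("gappy", c(4L, 37L, 60L, 1002L)),
          fml_ensemble_type("contig", 3:7))
  s <- as.character(fml_write_xml(m))
  expect_match(s, "1 2 11 12\n2 3 12 13", fixed = TRUE)
  expect_match(s, "<MemberList>4 37 60 1002</MemberList>", fixed = TRUE)
  expect_match(s, "<MemberRange min=\"3\" max=\"7\"/>", fixed = TRUE)
})

test_that("library imports resolve to the shared library objects", {
  dir <- withr::local_tempdir()
  m <- fml_model("user")
  lib <- fml_library()
  fml_import(m, lib, "coordinates.rc.3d", local_name = "rc3")
  fml_import(m, lib, "interpolator.2d.unit.bilinearLagrange")
  f <- file.path(dir, "user.xml")
  fml_write_xml(m, f)
  m2 <- fml_parse_xml(f)
  # the imported type IS the library type (nominal compatibility preserved)
  expect_true(fml_type_compatible(fml_get(m2, "rc3"),
                                  fml_get(lib, "coordinates.rc.3d")))
  # the external resolves to the registered stdlib implementation
  ext <- fml_get(m2, "interpolator.2d.unit.bilinearLagrange")
  env <- list()
  for (a in ext$arguments)
    env[[a$name]] <- fml_real_value(a$value_type, rep(0, a$value_type$dimension))
  env[[ext$arguments[[2L]]$name]] <- fml_real_value(
    ext$arguments[[2L]]$value_type, c(42, 0, 0, 0))
  expect_identical(fml_evaluate(ext, env)$vector, 42)
})

test_that("two imported ensembles with equal members stay incompatible", {
  dir <- withr::local_tempdir()
  mk <- function(region, path) {
    m <- fml_model(region)
    fml_add(m, fml_ensemble_type("idx", 1:3))
    fml_write_xml(m, path)
  }
  mk("src1", file.path(dir, "s1.xml"))
  mk("src2", file.path(dir, "s2.xml"))
  main <- sprintf('<?xml version="1.0" encoding="UTF-8"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
  <Region name="main">
    <Import xlink:href="s1.xml" region="src1">
      <ImportType localName="idx1" remoteName="idx"/>
    </Import>
    <Import xlink:href="s2.xml" region="src2">
      <ImportType localName="idx2" remoteName="idx"/>
    </Import>
  </Region>
</Fieldml>')
  mf <- file.path(dir, "main.xml")
  writeLines(main, mf)
  m <- fml_parse_xml(mf)
  expect_false(fml_type_compatible(fml_get(m, "idx1"), fml_get(m, "idx2")))
  # but a diamond: importing the same document twice shares objects
  m2 <- fml_parse_xml(mf)  # fresh locator, fresh parse: still distinct from m
  expect_false(fml_type_compatible(fml_get(m, "idx1"), fml_get(m2, "idx1")))
})

test_that("import cycles and self-imports are rejected; absent names error", {
  dir <- withr::local_tempdir()
  a <- file.path(dir, "a.xml"); b <- file.path(dir, "b.xml")
  writeLines(sprintf('<?xml version="1.0"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
<Region name="a"><Import xlink:href="b.xml" region="b">
<ImportType localName="t" remoteName="t"/></Import></Region></Fieldml>'), a)
  writeLines(sprintf('<?xml version="1.0"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
<Region name="b"><Import xlink:href="a.xml" region="a">
<ImportType localName="t" remoteName="t"/></Import></Region></Fieldml>'), b)
  expect_error(fml_parse_xml(a), class = "fml_import_error")

  selfi <- file.path(dir, "self.xml")
  writeLines('<?xml version="1.0"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
<Region name="self"><Import xlink:href="self.xml" region="self">
<ImportType localName="t" remoteName="t"/></Import></Region></Fieldml>', selfi)
  expect_error(fml_parse_xml(selfi), class = "fml_import_error")

  # remote name absent in the source region
  src <- fml_model("src"); fml_add(src, fml_continuous_type("real"))
  expect_error(fml_import(fml_model("dst"), src, "no.such.name"),
               class = "fml_import_error")
})

test_that("unknown elements are skipped in lenient mode and rejected in strict", {
  doc <- '<?xml version="1.0"?>
<Fieldml xmlns:xlink="http://www.w3.org/1999/xlink" version="0.5">
<Region name="fwd">
  <ContinuousType name="real"/>
  <FancyFutureElement name="x"/>
</Region></Fieldml>'
  expect_warning(m <- fml_parse_xml(xml2::read_xml(doc)), "FancyFutureElement")
  expect_s3_class(fml_get(m, "real"), "fml_continuous_type")
  expect_error(suppressWarnings(fml_parse_xml(xml2::read_xml(doc), mode = "strict")),
               class = "fml_schema_error")

  expect_error(fml_parse_xml("<Fieldml><Region"), class = "fml_parse_error")
})

test_that("unknown external evaluators survive a round-trip untouched", {
  m <- fml_model("vendor")
  r <- fml_continuous_type("real")
  x <- fml_argument("x", r)
  ext <- fml_external("vendor.secret.sauce", r, list(x))
  fml_add(m, r, x, ext)
  m2 <- fml_parse_xml(fml_write_xml(m))
  e2 <- fml_get(m2, "vendor.secret.sauce")
  expect_s3_class(e2, "fml_external")
  expect_identical(e2$value_type$name, "real")
  expect_true(fml_isomorphic(m, m2))
  expect_error(fml_evaluate(e2, list(x = 1)), class = "fml_unimplemented_external")
})

test_that("serializing a model with a dangling reference is refused", {
  m <- fml_model("dangling")
  r <- fml_continuous_type("real")
  k <- fml_constant("k", r, "1")  # r registered, k's value type fine
  ref <- fml_reference("ref", fml_constant("ghost", r, "2"))
  fml_add(m, r, k, ref)  # "ghost" itself never registered
  expect_error(fml_write_xml(m, validate = FALSE),
               class = "fml_serialization_error")
})
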