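# Typed object model: ensembles, meshes, nominal typing, composition
# checking, validation.

test_that("ensembles keep their member identifiers and reject bad definitions", {
  A <- fml_ensemble_type("A", c(4, 37, 60, 1002))
  expect_s3_class(A, "fml_ensemble_type")
  expect_length(A$members, 4L)
  expect_identical(max(A$members), 1002L)

  B <- fml_ensemble_type("B", 1:3)
  expect_length(B$members, 3L)

  expect_error(fml_ensemble_type("E", integer(0)), class = "fml_definition_error")
  expect_error(fml_ensemble_type("D", c(1, 1, 2)), class = "fml_definition_error")
  expect_error(fml_ensemble_type("D", c(-1, 2)), class = "fml_definition_error")
})

test_that("mesh definition couples elements, chart and Boolean shape predicates", {
  lib <- fml_library()
  square <- fml_get(lib, "shape.unit.square")
  mesh <- fml_mesh_type("mesh", 2L, c(1, 2), square)
  expect_identical(mesh$dimension, 2L)
  expect_identical(mesh$element_ensemble$members, 1:2)
  expect_identical(mesh$chart_type$dimension, 2L)
  expect_length(mesh$shape_map, 2L)

  line <- fml_get(lib, "shape.unit.line")
  m1 <- fml_mesh_type("m1", 1L, 1L, line)
  expect_identical(m1$element_ensemble$members, 1L)

  expect_error(fml_mesh_type("m0", 0L, 1L, square), class = "fml_definition_error")
  expect_error(fml_mesh_type("gap", 2L, 1:2, list("1" = square)),
               class = "fml_definition_error")
  r <- fml_continuous_type("r")
  scalar <- fml_constant("notashape", r, "1")
  expect_error(fml_mesh_type("bad", 2L, 1L, scalar), class = "fml_type_error")
})

test_that("typing is nominal: equal member sets do not make types compatible", {
  B <- fml_ensemble_type("B", 1:3)
  C <- fml_ensemble_type("C", 1:3)
  expect_true(fml_type_compatible(B, B))
  expect_false(fml_type_compatible(B, C))

  # an imported type is the same object; a re-declaration is not
  lib <- fml_library()
  m <- fml_model("user")
  fml_import(m, lib, "coordinates.rc.3d")
  local_rc3 <- fml_continuous_type("coordinates.rc.3d", 3L)
  expect_true(fml_type_compatible(fml_get(m, "coordinates.rc.3d"),
                                  fml_get(lib, "coordinates.rc.3d")))
  expect_false(fml_type_compatible(local_rc3, fml_get(lib, "coordinates.rc.3d")))

  # property: independently defined twins are never compatible; self always is
  set.seed(41)
  for (i in 1:20) {
    members <- sort(sample(0:30, sample(2:6, 1)))
    t1 <- fml_ensemble_type("t", members)
    t2 <- fml_ensemble_type("t", members)
    expect_true(fml_type_compatible(t1, t1))
    expect_false(fml_type_compatible(t1, t2))
  }
})

test_that("composition across distinct ensembles is rejected, via a converter accepted", {
  A <- fml_ensemble_type("A", 1:3); B <- fml_ensemble_type("B", 1:3)
  C <- fml_ensemble_type("C", 1:3); D <- fml_ensemble_type("D", 1:3)
  argA <- fml_argument("a", A); argC <- fml_argument("c", C)
  # f: A -> B and g: C -> D as single-argument external declarations
  f <- fml_external("f", B, list(argA))
  g <- fml_external("g", D, list(argC))

  v <- fml_compose_check(g, f)
  expect_false(v$ok)
  expect_match(v$message, "B")
  expect_match(v$message, "C")

  # converter h: B -> C makes g(h(f)) admissible
  argB <- fml_argument("b", B)
  h <- fml_external("h", C, list(argB))
  hf <- fml_reference("h.of.f", h, list(fml_bind(argB, f)))
  expect_true(fml_compose_check(g, hf)$ok)

  idB <- fml_reference("idB", argB)
  expect_true(fml_compose_check(idB, idB)$ok)
})

test_that("compose_check agrees with a type-edge enumeration oracle on random pipelines", {
  set.seed(97)
  for (rep in 1:40) {
    n_types <- sample(3:5, 1L)
    types <- lapply(seq_len(n_types), function(i)
      fml_ensemble_type(sprintf("T%d", i), 1:4))
    # a chain of <= 10 unary evaluators with randomly chosen domains/codomains
    k <- sample(2:10, 1L)
    dom <- sample(n_types, k, replace = TRUE)
    cod <- sample(n_types, k, replace = TRUE)
    evs <- lapply(seq_len(k), function(i) {
      a <- fml_argument(sprintf("a%d", i), types[[dom[i]]])
      fml_external(sprintf("e%d", i), types[[cod[i]]], list(a))
    })
    # pick outer/inner; the oracle checks the single connecting edge against
    # the generator's ground-truth type indices
    oi <- sample(k, 2L)
    outer <- evs[[oi[1L]]]; inner <- evs[[oi[2L]]]
    expected <- dom[oi[1L]] == cod[oi[2L]]
    expect_identical(fml_compose_check(outer, inner)$ok, expected)
  }
})

test_that("validation reports cycles, type mismatches and dangling types", {
  r <- fml_continuous_type("real")
  E <- fml_ensemble_type("E", 1:2)
  n <- fml_argument("n", E)

  # reference cycle a -> b -> a, constructed by mutating the target field
  m <- fml_model("cyclic")
  a <- fml_reference("a", n)
  b <- fml_reference("b", a)
  assign("target", b, envir = a)
  fml_add(m, E, n, a, b)
  d <- fml_validate(m)
  expect_true(any(d$rule == "acyclicity"))

  # branch value type mismatching the declared value type
  m2 <- fml_model("mismatch")
  bool <- fml_boolean_type("bool")
  wrong <- fml_constant("wrong", r, "1")
  pw <- fml_piecewise("pw", bool, n, list("1" = wrong))
  fml_add(m2, r, E, bool, n, wrong, pw)
  d2 <- fml_validate(m2)
  expect_true(any(d2$rule == "branch-type"))
  expect_true(any(grepl("pw", d2$object)))

  # a valid model yields no diagnostics, idempotently and independent of
  # declaration order
  build <- function(order) {
    mm <- fml_model("ok")
    r2 <- fml_continuous_type("real")
    E2 <- fml_ensemble_type("E", 1:2)
    n2 <- fml_argument("n", E2)
    c1 <- fml_constant("c1", r2, "1.5")
    pw2 <- fml_piecewise("pw", r2, n2, list("1" = c1), default = c1)
    objs <- list(r2, E2, n2, c1, pw2)[order]
    do.call(fml_add, c(list(mm), objs))
    mm
  }
  m3 <- build(1:5)
  expect_identical(nrow(fml_validate(m3)), 0L)
  expect_identical(fml_validate(m3), fml_validate(m3))
  m4 <- build(5:1)
  expect_identical(nrow(fml_validate(m4)), 0L)
})

test_that("duplicate names within a region are rejected", {
  m <- fml_model("dup")
  fml_add(m, fml_continuous_type("real"))
  expect_error(fml_add(m, fml_continuous_type("real")),
               class = "fml_definition_error")
})
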