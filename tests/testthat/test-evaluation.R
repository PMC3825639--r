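# The evaluation engine: per-kind semantics, binding substitution, mesh
# fields.

test_that("each evaluator kind computes its defining semantics", {
  r <- fml_continuous_type("real")

  # argument only: the identity function
  x <- fml_argument("x", r)
  expect_identical(fml_evaluate(x, list(x = pi))$vector, pi)
  expect_error(fml_evaluate(x, list()), class = "fml_missing_argument")

  # constants parse their string rendering
  expect_identical(fml_evaluate(fml_constant("c", r, "1059.87"))$vector, 1059.87)
  E <- fml_ensemble_type("E", c(5L, 57L))
  expect_identical(fml_evaluate(fml_constant("i", E, "57"))$member, 57L)
  expect_error(fml_constant("bad", r, "not-a-number"), class = "fml_parse_error")

  # aggregate of three constants builds the vector in ascending member order
  v3 <- fml_continuous_type("v3", 3L)
  agg <- fml_aggregate("vec", v3, list(
    "1" = fml_constant("a1", r, "0.5"),
    "2" = fml_constant("a2", r, "-1"),
    "3" = fml_constant("a3", r, "20.1")))
  out <- fml_evaluate(agg)
  expect_identical(out$vector, c(0.5, -1, 20.1))
  expect_identical(out$vector[3L], 20.1)

  # parameter evaluators look up stored data through their index arguments
  fx <- make_node_coordinates()
  env <- list(node = 2L, component = 1L)
  expect_identical(fml_evaluate(fx$param, env)$vector, 1)
  env$component <- 2L
  expect_identical(fml_evaluate(fx$param, env)$vector, 0)
  expect_identical(fml_evaluate(fx$param, list(node = 1L, component = 1L))$vector, 0)

  # piecewise with no matching branch and no default
  n <- fml_argument("n", fml_ensemble_type("N", 1:3))
  pw <- fml_piecewise("pw", r, n, list("1" = fml_constant("k", r, "1")))
  expect_error(fml_evaluate(pw, list(n = 2L)), class = "fml_branch_error")

  # unknown externals fail only at evaluation time
  ext <- fml_external("vendor.mystery", r, list(x))
  expect_error(fml_evaluate(ext, list(x = 1)),
               class = "fml_unimplemented_external")
})

test_that("piecewise selection and constant binding reproduce the worked example", {
  fx <- make_g_fixture()
  expect_identical(fml_evaluate(fx$g, list(n = 2L, x = 0))$vector, 100)
  expect_identical(fml_evaluate(fx$g, list(n = 1L, x = 0))$vector, 7.1)
  # f(n) = g(n) such that x = k1; the binding shadows any ambient x
  expect_identical(fml_evaluate(fx$f, list(n = 3L))$vector, 0.331)
  expect_identical(fml_evaluate(fx$f, list(n = 3L, x = 999))$vector, 0.331)
  expect_identical(fml_evaluate(fx$f, list(n = 2L))$vector, 100)
})

test_that("function-valued arguments apply the bound evaluator at the operand site", {
  r <- fml_continuous_type("real")
  E <- fml_ensemble_type("N", 1:3)
  n <- fml_argument("n", E)
  xop <- fml_argument("x.operand", r)
  h <- fml_argument("h", r, list(xop))          # h: a yet-unbound function
  h29 <- fml_reference("h.at.29", h,
                       list(fml_bind(xop, fml_constant("c29", r, "29"))))
  g <- fml_piecewise("g", r, n, list(
    "1" = fml_constant("c7.1", r, "7.1"),
    "2" = fml_constant("c100", r, "100"),
    "3" = h29))
  f <- fml_reference("f", g)
  # binding h to the identity function makes case n=3 equivalent to s(29)=29
  expect_identical(fml_evaluate(f, list(n = 3L, h = xop))$vector, 29)
  # binding h to a different pipeline applies that pipeline to the operand
  halve <- fml_reference("halve", xop)  # alias of the operand; still 29
  expect_identical(fml_evaluate(f, list(n = 3L, h = halve))$vector, 29)
  expect_identical(fml_evaluate(f, list(n = 2L, h = xop))$vector, 100)
})

test_that("binding a name that is not upstream of the target is rejected", {
  fx <- make_g_fixture()
  r <- fx$r
  stranger <- fml_argument("stranger", r)
  expect_error(fml_reference("f2", fx$g,
                             list(fml_bind(stranger, fx$k1))),
               class = "fml_binding_error")
})

test_that("engine evaluation equals the substitution oracle on random pipelines", {
  set.seed(4242)
  world <- make_pipeline_world()
  for (rep in 1:200) {
    p <- random_pipeline(world, depth = sample(1:4, 1L))
    env <- list(x = round(runif(1, -10, 10), 4),
                y = round(runif(1, -10, 10), 4),
                n = sample(1:3, 1L))
    inlined <- oracle_inline(p)
    a <- fml_evaluate(p, env)$vector
    b <- fml_evaluate(inlined, env)$vector
    expect_identical(a, b)
  }
})

test_that("evaluation is pure: repeated evaluation gives identical values", {
  set.seed(77)
  world <- make_pipeline_world()
  p <- random_pipeline(world, 3L)
  env <- list(x = 1.25, y = -4, n = 2L)
  expect_identical(fml_evaluate(p, env), fml_evaluate(p, env))
})

test_that("mesh fields interpolate nodal parameters through the connectivity map", {
  ex <- fml_illustrative_example()
  p <- fml_get(ex$model, "pressure")
  g <- fml_get(ex$model, "geometry")
  man <- ex$manifest
  corners <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2L, byrow = TRUE)

  # corner reproduction: every local corner yields its global node's DOF
  for (el in 1:2) for (ln in 1:4) {
    val <- fml_evaluate_mesh_field(p, ex$mesh_argument, el, corners[ln, ])$vector
    expect_identical(val, man$pressure_dofs[man$connectivity[el, ln]])
  }
  # element centers average the four nodal DOFs
  for (el in 1:2)
    expect_equal(fml_evaluate_mesh_field(p, ex$mesh_argument, el,
                                         c(0.5, 0.5))$vector,
                 man$center_pressure[el], tolerance = 1e-12)
  # the geometry field is a 3-component aggregate
  gv <- fml_evaluate_mesh_field(g, ex$mesh_argument, 2L, c(0.25, 0.75))$vector
  expect_length(gv, 3L)
  expect_identical(gv[3L], 0)

  # piecewise totality over the mesh
  tpl <- fml_get(ex$model, "template")
  for (el in ex$model$types$mesh$element_ensemble$members)
    expect_true(!is.null(tpl$branches[[as.character(el)]]) || !is.null(tpl$default))

  # domain discipline
  expect_error(fml_evaluate_mesh_field(p, ex$mesh_argument, 1L, c(1.2, 0)),
               class = "fml_domain_error")
  expect_identical(
    fml_evaluate_mesh_field(p, ex$mesh_argument, 1L, c(1.2, 0),
                            allow_extrapolation = TRUE)$kind, "real")
  expect_error(fml_evaluate_mesh_field(p, ex$mesh_argument, 9L, c(0, 0)),
               class = "fml_member_error")
})

test_that("the pressure field is continuous across the shared element edge", {
  ex <- fml_illustrative_example()
  p <- fml_get(ex$model, "pressure")
  for (t in seq(0, 1, length.out = 11L)) {
    a <- fml_evaluate_mesh_field(p, ex$mesh_argument, 1L, c(1, t))$vector
    b <- fml_evaluate_mesh_field(p, ex$mesh_argument, 2L, c(0, t))$vector
    expect_lt(abs(a - b), 1e-12)
  }
})
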