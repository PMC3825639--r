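# The FieldML 0.5 standard library, re-created in code: chart and Cartesian
# coordinate types, local-node ensembles, external evaluator declarations for
# the common FEM interpolation bases and element shapes — plus executable
# implementations for every declared external.
#
# Local-node ordering: xi1 varies fastest, then xi2, then xi3, with node 1 at
# the origin, so the four bilinear nodes sit at (0,0),(1,0),(0,1),(1,1).
# Quadratic bases use equally spaced nodes on [0,1]; simplex bases are
# barycentric-linear.

phi_line2 <- function(x) c(1 - x, x)
phi_line3 <- function(x) c(2 * (x - 0.5) * (x - 1), -4 * x * (x - 1), 2 * x * (x - 0.5))

# tensor product over dimensions, first factor varying fastest
phi_tensor <- function(fs) {
  function(xi) {
    out <- fs[[1L]](xi[1L])
    for (d in seq_along(fs)[-1L]) out <- as.vector(outer(out, fs[[d]](xi[d])))
    out
  }
}

nodes_1d <- function(k) if (k == 2L) c(0, 1) else c(0, 0.5, 1)
nodes_tensor <- function(k, dim) {
  # expand.grid varies its first factor fastest, matching phi_tensor
  unname(as.matrix(expand.grid(rep(list(nodes_1d(k)), dim))))
}

shape_predicates <- function() {
  tol <- 1e-12
  list(
    "shape.unit.line" = list(dim = 1L, inside = function(xi)
      all(xi >= -tol & xi <= 1 + tol)),
    "shape.unit.square" = list(dim = 2L, inside = function(xi)
      all(xi >= -tol & xi <= 1 + tol)),
    "shape.unit.cube" = list(dim = 3L, inside = function(xi)
      all(xi >= -tol & xi <= 1 + tol)),
    "shape.unit.triangle" = list(dim = 2L, inside = function(xi)
      all(xi >= -tol) && sum(xi) <= 1 + tol),
    "shape.unit.tetrahedron" = list(dim = 3L, inside = function(xi)
      all(xi >= -tol) && sum(xi) <= 1 + tol)
  )
}

interpolator_specs <- function() {
  simplex_phi2 <- function(xi) c(1 - xi[1L] - xi[2L], xi[1L], xi[2L])
  simplex_phi3 <- function(xi) c(1 - sum(xi), xi[1L], xi[2L], xi[3L])
  specs <- list(
    "interpolator.1d.unit.linearLagrange" = list(
      dim = 1L, n = 2L, degree = 1L, shape = "shape.unit.line",
      local_nodes = "localNodes.1d.line2",
      phi = function(xi) phi_line2(xi[1L]),
      nodes = matrix(nodes_1d(2L), ncol = 1L)),
    "interpolator.1d.unit.quadraticLagrange" = list(
      dim = 1L, n = 3L, degree = 2L, shape = "shape.unit.line",
      local_nodes = "localNodes.1d.line3",
      phi = function(xi) phi_line3(xi[1L]),
      nodes = matrix(nodes_1d(3L), ncol = 1L)),
    "interpolator.2d.unit.bilinearLagrange" = list(
      dim = 2L, n = 4L, degree = 1L, shape = "shape.unit.square",
      local_nodes = "localNodes.2d.square2x2",
      phi = phi_tensor(list(phi_line2, phi_line2)),
      nodes = nodes_tensor(2L, 2L)),
    "interpolator.2d.unit.biquadraticLagrange" = list(
      dim = 2L, n = 9L, degree = 2L, shape = "shape.unit.square",
      local_nodes = "localNodes.2d.square3x3",
      phi = phi_tensor(list(phi_line3, phi_line3)),
      nodes = nodes_tensor(3L, 2L)),
    "interpolator.3d.unit.trilinearLagrange" = list(
      dim = 3L, n = 8L, degree = 1L, shape = "shape.unit.cube",
      local_nodes = "localNodes.3d.cube2x2x2",
      phi = phi_tensor(list(phi_line2, phi_line2, phi_line2)),
      nodes = nodes_tensor(2L, 3L)),
    "interpolator.3d.unit.triquadraticLagrange" = list(
      dim = 3L, n = 27L, degree = 2L, shape = "shape.unit.cube",
      local_nodes = "localNodes.3d.cube3x3x3",
      phi = phi_tensor(list(phi_line3, phi_line3, phi_line3)),
      nodes = nodes_tensor(3L, 3L)),
    "interpolator.2d.unit.linearSimplex" = list(
      dim = 2L, n = 3L, degree = 1L, shape = "shape.unit.triangle",
      local_nodes = "localNodes.2d.triangle3",
      phi = simplex_phi2,
      nodes = matrix(c(0, 0, 1, 0, 0, 1), ncol = 2L, byrow = TRUE)),
    "interpolator.3d.unit.linearSimplex" = list(
      dim = 3L, n = 4L, degree = 1L, shape = "shape.unit.tetrahedron",
      local_nodes = "localNodes.3d.tetrahedron4",
      phi = simplex_phi3,
      nodes = matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3L, byrow = TRUE))
  )
  for (nm in names(specs)) specs[[nm]]$name <- nm
  specs
}

get_interpolators <- function() {
  if (is.null(.fml$interpolators)) .fml$interpolators <- interpolator_specs()
  .fml$interpolators
}
get_shapes <- function() {
  if (is.null(.fml$shapes)) .fml$shapes <- shape_predicates()
  .fml$shapes
}

#' Interpolation bases and shape predicates of the standard library
#'
#' `fml_interpolators()` lists the basis specifications (dimension,
#' local-node count, polynomial degree, reference shape, node coordinates).
#' `fml_interpolate()` evaluates `sum_i phi_i(xi) * params_i`.
#' `fml_shape_inside()` tests closed-set membership of chart coordinates in a
#' reference shape (true on the boundary).
#'
#' @param basis library name of a basis (e.g.
#'   `"interpolator.2d.unit.bilinearLagrange"`) or a spec from
#'   `fml_interpolators()`.
#' @param params numeric vector of nodal values, length = local-node count.
#' @param xi chart coordinates.
#' @param allow_extrapolation evaluate outside the reference shape instead of
#'   raising a domain error.
#' @return `fml_interpolate()`: scalar; `fml_shape_inside()`: logical.
#' @examples
#' fml_interpolate("interpolator.1d.unit.linearLagrange", c(0, 1), 0.25)  # 0.25
#' fml_shape_inside("shape.unit.square", c(1, 1))   # TRUE (closed shape)
#' fml_shape_inside("shape.unit.triangle", c(0.6, 0.6))  # FALSE
#' @export
fml_interpolate <- function(basis, params, xi, allow_extrapolation = FALSE) {
  if (is.character(basis)) {
    spec <- get_interpolators()[[basis]]
    if (is.null(spec)) fml_stop("fml_definition_error", "unknown basis '%s'", basis)
  } else spec <- basis
  if (length(params) != spec$n)
    fml_stop("fml_arity_error", "basis '%s' takes %d nodal values, got %d",
             spec$name, spec$n, length(params))
  if (length(xi) != spec$dim)
    fml_stop("fml_arity_error", "basis '%s' is %d-dimensional, xi has length %d",
             spec$name, spec$dim, length(xi))
  if (!allow_extrapolation && !fml_shape_inside(spec$shape, xi))
    fml_stop("fml_domain_error", "xi = (%s) lies outside the reference shape of '%s'",
             paste(format(xi), collapse = ", "), spec$name)
  sum(spec$phi(xi) * as.numeric(params))
}

#' @rdname fml_interpolate
#' @param shape library name of a shape (e.g. `"shape.unit.triangle"`) or a
#'   spec from the shape registry.
#' @export
fml_shape_inside <- function(shape, xi) {
  if (is.character(shape)) {
    spec <- get_shapes()[[shape]]
    if (is.null(spec)) fml_stop("fml_definition_error", "unknown shape '%s'", shape)
  } else spec <- shape
  if (length(xi) != spec$dim)
    fml_stop("fml_arity_error", "shape is %d-dimensional, xi has length %d",
             spec$dim, length(xi))
  isTRUE(spec$inside(as.numeric(xi)))
}

#' @rdname fml_interpolate
#' @export
fml_interpolators <- function() get_interpolators()

#' Register an implementation for an external evaluator
#'
#' External evaluators carry semantics by convention, keyed by their
#' fully-qualified name.  The registered function receives the list of
#' evaluated argument values (in declared order) and returns a numeric,
#' logical, or [fml_value].  All standard-library externals are registered
#' when the library is first loaded; unknown externals raise an error only at
#' evaluation time.
#'
#' @param name fully-qualified external evaluator name.
#' @param fn implementation function.
#' @export
fml_register_external <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .fml$externals[[name]] <- fn
  invisible(name)
}

# ---- the library region -----------------------------------------------------

#' The FieldML 0.5 standard library
#'
#' Returns the library region as a model: continuous chart types and
#' Cartesian coordinate types (1D/2D/3D) with component-index ensembles,
#' local-node ensembles per basis, argument evaluators for all of these, and
#' external evaluator declarations for the Lagrange tensor-product and linear
#' simplex interpolators and the unit element-shape predicates.  The same
#' object is returned on every call, so types imported from the library are
#' nominally compatible across models.  All declared externals have
#' registered implementations.
#'
#' @return a `fml_model` for region `"library"`.
#' @export
fml_library <- function() {
  if (!is.null(.fml$library)) return(.fml$library)
  lib <- fml_model("library")
  lib$href <- "FieldML_Library_0.5.xml"

  boolean <- fml_boolean_type("boolean")
  real1 <- fml_continuous_type("real.1d", 1L)
  fml_add(lib, boolean, real1)
  fml_add(lib, fml_argument("real.1d.argument", real1))

  for (d in 1:3) {
    chart <- fml_continuous_type(sprintf("chart.%dd", d), d)
    coords <- fml_continuous_type(sprintf("coordinates.rc.%dd", d), d)
    fml_add(lib, chart, coords)
    fml_add(lib, fml_argument(paste0(chart$name, ".argument"), chart))
    fml_add(lib, fml_argument(paste0(coords$name, ".argument"), coords))
    if (d > 1L) {
      fml_add(lib,
              fml_argument(paste0(chart$name, ".component.argument"),
                           chart$component_ensemble),
              fml_argument(paste0(coords$name, ".component.argument"),
                           coords$component_ensemble))
    }
  }

  shapes <- get_shapes()
  for (nm in names(shapes)) {
    d <- shapes[[nm]]$dim
    chart_arg <- fml_get(lib, sprintf("chart.%dd.argument", d))
    fml_add(lib, fml_external(nm, boolean, list(chart_arg)))
  }

  interp <- get_interpolators()
  for (nm in names(interp)) {
    sp <- interp[[nm]]
    ln <- fml_ensemble_type(sp$local_nodes, seq_len(sp$n))
    fml_add(lib, ln)
    fml_add(lib, fml_argument(paste0(ln$name, ".argument"), ln))
    # the parameter vector type: one component per local node
    pname <- sub("^interpolator", "parameters", nm)
    ptype <- fml_continuous_type(pname, sp$n, component_ensemble = ln)
    fml_add(lib, ptype)
    parg <- fml_argument(paste0(pname, ".argument"), ptype)
    fml_add(lib, parg)
    chart_arg <- fml_get(lib, sprintf("chart.%dd.argument", sp$dim))
    fml_add(lib, fml_external(nm, real1, list(chart_arg, parg)))
  }

  register_library_externals()
  .fml$library <- lib
  lib
}

register_library_externals <- function() {
  for (nm in names(get_shapes())) {
    local({
      spec <- get_shapes()[[nm]]
      fml_register_external(nm, function(args) {
        xi <- args[[1L]]$vector
        isTRUE(spec$inside(xi))
      })
    })
  }
  for (nm in names(get_interpolators())) {
    local({
      spec <- get_interpolators()[[nm]]
      fml_register_external(nm, function(args) {
        xi <- args[[1L]]$vector
        params <- args[[2L]]$vector
        fml_interpolate(spec, params, xi, allow_extrapolation = TRUE)
      })
    })
  }
  invisible()
}
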