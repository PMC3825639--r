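# Runtime values and the evaluation engine.
#
# Evaluation is eager and depth-first over the pipeline, with no caching:
# identical (evaluator, environment) pairs always give identical values.
# Bindings use substitution semantics — a bound argument's delegate is
# evaluated at the site where the argument occurs, under the environment in
# effect there, with inner re-bindings shadowing outer ones.

#' Runtime values
#'
#' Tagged runtime results of evaluation: an ensemble member, a Boolean, a
#' real vector, or a mesh location (element member plus chart coordinates).
#'
#' @param type the value's domain type.
#' @param member ensemble member identifier.
#' @param x logical (Boolean) or numeric vector (real) payload.
#' @param element,xi element member and chart coordinate vector of a mesh
#'   location.
#' @return an object of class `fml_value`.
#' @name fml_value
NULL

#' @rdname fml_value
#' @export
fml_ensemble_value <- function(type, member) {
  stopifnot(inherits(type, "fml_ensemble_type"))
  member <- as.integer(member)
  if (!(member %in% type$members))
    fml_stop("fml_member_error", "%d is not a member of ensemble '%s'", member, type$name)
  structure(list(kind = "ensemble", type = type, member = member), class = "fml_value")
}

#' @rdname fml_value
#' @export
fml_boolean_value <- function(type, x) {
  stopifnot(inherits(type, "fml_boolean_type"), is.logical(x), length(x) == 1L)
  structure(list(kind = "boolean", type = type, value = x), class = "fml_value")
}

#' @rdname fml_value
#' @export
fml_real_value <- function(type, x) {
  stopifnot(inherits(type, "fml_continuous_type"))
  x <- as.numeric(x)
  if (length(x) != type$dimension)
    fml_stop("fml_type_error", "real value of length %d for type '%s' (dimension %d)",
             length(x), type$name, type$dimension)
  structure(list(kind = "real", type = type, vector = x), class = "fml_value")
}

#' @rdname fml_value
#' @export
fml_mesh_location <- function(type, element, xi) {
  stopifnot(inherits(type, "fml_mesh_type"))
  element <- as.integer(element)
  if (!(element %in% type$element_ensemble$members))
    fml_stop("fml_member_error", "element %d is not in mesh '%s'", element, type$name)
  xi <- as.numeric(xi)
  if (length(xi) != type$dimension)
    fml_stop("fml_type_error", "chart coordinate of length %d for %d-dimensional mesh '%s'",
             length(xi), type$dimension, type$name)
  structure(list(kind = "mesh_location", type = type, element = element, xi = xi),
            class = "fml_value")
}

#' @export
print.fml_value <- function(x, ...) {
  switch(x$kind,
    ensemble = cat("<fml_value> member", x$member, "of", x$type$name, "\n"),
    boolean = cat("<fml_value>", x$value, "\n"),
    real = cat("<fml_value> (", paste(format(x$vector), collapse = ", "), ") :",
               x$type$name, "\n"),
    mesh_location = cat("<fml_value> element", x$element, "xi = (",
                        paste(format(x$xi), collapse = ", "), ") in", x$type$name, "\n"))
  invisible(x)
}

#' @export
as.numeric.fml_value <- function(x, ...) {
  switch(x$kind,
    real = x$vector,
    ensemble = as.numeric(x$member),
    boolean = as.numeric(x$value),
    fml_stop("fml_type_error", "cannot coerce a %s value to numeric", x$kind))
}

# coerce a user-supplied environment entry to a value (or keep an evaluator
# for deferred evaluation)
coerce_env_entry <- function(v, arg) {
  if (inherits(v, "fml_value") || inherits(v, "fml_evaluator")) return(v)
  vt <- arg$value_type
  if (is.numeric(v) && inherits(vt, "fml_continuous_type")) return(fml_real_value(vt, v))
  if (is.numeric(v) && inherits(vt, "fml_ensemble_type")) return(fml_ensemble_value(vt, v))
  if (is.logical(v) && inherits(vt, "fml_boolean_type")) return(fml_boolean_value(vt, v))
  fml_stop("fml_type_error", "cannot interpret assignment for argument '%s'", arg$name)
}

check_value_against <- function(value, type, what) {
  ok <- identical(value$type, type) ||
    # tolerate structural match for chart/real scalars produced by accessors
    (value$kind == "real" && inherits(type, "fml_continuous_type") &&
       length(value$vector) == type$dimension)
  if (!ok)
    fml_stop("fml_type_error", "%s: value of type '%s' where '%s' expected",
             what, value$type$name, type$name)
  value
}

# A binding's delegate is a closure over the environment at the binding
# site (lexical scoping, so inner re-bindings shadow outer ones exactly as
# textual substitution would).  The bound argument's *declared dependencies*
# are the operands of a function-valued argument: they are carried over from
# the occurrence site, which is what "the bound evaluator is applied to the
# operands" means.
fml_closure <- function(delegate, env) {
  structure(list(delegate = delegate, env = env), class = "fml_closure")
}

bind_env <- function(env, bindings) {
  site <- env  # all delegates of one evaluator close over the same outer env
  for (b in bindings) env[[b$argument$name]] <- fml_closure(b$delegate, site)
  env
}

eval_node <- function(e, env) {
  if (inherits(e, "fml_argument")) {
    v <- env[[e$name]]
    if (is.null(v))
      fml_stop("fml_missing_argument",
               "argument '%s' is not assigned in the environment", e$name)
    if (inherits(v, "fml_closure")) {
      site <- v$env
      for (dep in e$arguments)
        if (!is.null(env[[dep$name]])) site[[dep$name]] <- env[[dep$name]]
      return(check_value_against(eval_node(v$delegate, site), e$value_type, e$name))
    }
    if (inherits(v, "fml_evaluator")) {
      # a bare evaluator supplied by the user: evaluate at this site; drop
      # the frame being expanded so self-references resolve outward
      return(check_value_against(eval_node(v, env[names(env) != e$name]),
                                 e$value_type, e$name))
    }
    v <- coerce_env_entry(v, e)
    return(check_value_against(v, e$value_type, e$name))
  }
  if (inherits(e, "fml_mesh_accessor")) {
    mv <- eval_node(e$mesh_argument, env)
    if (mv$kind != "mesh_location")
      fml_stop("fml_type_error", "'%s' did not evaluate to a mesh location",
               e$mesh_argument$name)
    return(if (e$part == "elements")
      fml_ensemble_value(e$value_type, mv$element)
    else
      fml_real_value(e$value_type, mv$xi))
  }
  if (inherits(e, "fml_constant")) return(parse_constant(e))
  if (inherits(e, "fml_parameter")) {
    idx <- vapply(e$index_arguments, function(ia) {
      v <- eval_node(ia, env)
      if (v$kind != "ensemble")
        fml_stop("fml_type_error", "parameter '%s': index '%s' is not an ensemble member",
                 e$name, ia$name)
      v$member
    }, integer(1L))
    val <- fml_lookup(e, idx)
    return(if (inherits(e$value_type, "fml_ensemble_type"))
      fml_ensemble_value(e$value_type, val)
    else
      fml_real_value(e$value_type, val))
  }
  if (inherits(e, "fml_piecewise")) {
    env2 <- bind_env(env, e$bindings)
    iv <- eval_node(e$index, env2)
    if (iv$kind != "ensemble")
      fml_stop("fml_type_error", "piecewise '%s': index is not an ensemble member", e$name)
    branch <- e$branches[[as.character(iv$member)]]
    if (is.null(branch)) branch <- e$default
    if (is.null(branch))
      fml_stop("fml_branch_error",
               "piecewise '%s': no branch and no default for member %d", e$name, iv$member)
    return(eval_node(branch, env2))
  }
  if (inherits(e, "fml_aggregate")) {
    env2 <- bind_env(env, e$bindings)
    members <- sort(e$component_ensemble$members)
    out <- numeric(length(members))
    for (i in seq_along(members)) {
      m <- members[i]
      env3 <- env2
      if (!is.null(e$index_argument))
        env3[[e$index_argument$name]] <- fml_ensemble_value(e$index_argument$value_type, m)
      comp <- e$components[[as.character(m)]]
      if (is.null(comp)) comp <- e$delegate
      if (is.null(comp))
        fml_stop("fml_branch_error", "aggregate '%s': no evaluator for component %d",
                 e$name, m)
      cv <- eval_node(comp, env3)
      if (cv$kind != "real" || length(cv$vector) != 1L)
        fml_stop("fml_type_error", "aggregate '%s': component %d is not scalar-real",
                 e$name, m)
      out[i] <- cv$vector
    }
    return(fml_real_value(e$value_type, out))
  }
  if (inherits(e, "fml_reference")) {
    return(eval_node(e$target, bind_env(env, e$bindings)))
  }
  if (inherits(e, "fml_external")) {
    impl <- .fml$externals[[e$name]]
    if (is.null(impl))
      fml_stop("fml_unimplemented_external",
               "external evaluator '%s' has no registered implementation", e$name)
    args <- lapply(e$arguments, eval_node, env = env)
    res <- impl(args)
    if (inherits(res, "fml_value")) return(res)
    if (is.logical(res)) return(fml_boolean_value(e$value_type, res))
    return(fml_real_value(e$value_type, res))
  }
  fml_stop("fml_definition_error", "cannot evaluate object of class %s", class(e)[1L])
}

#' Evaluate an evaluator pipeline
#'
#' Numerically evaluates an evaluator under an environment assigning each
#' free argument either a value (`fml_value`, or a bare numeric/logical that
#' is coerced against the argument's type) or an evaluator (for
#' function-valued arguments, applied at the operand site).
#'
#' @param e the evaluator to evaluate.
#' @param env named list keyed by argument name.
#' @param ... ignored.
#' @return an [fml_value].
#' @examples
#' r <- fml_continuous_type("r")
#' x <- fml_argument("x", r)
#' fml_evaluate(x, list(x = pi))$vector  # identity pipeline
#' @export
fml_evaluate <- function(e, env = list(), ...) {
  stopifnot(inherits(e, "fml_evaluator"))
  if (is.null(names(env)) && length(env)) names(env) <- rep("", length(env))
  eval_node(e, env)
}

#' Evaluate a field at a mesh location
#'
#' Sets the mesh argument to the location `(element, xi)` and evaluates the
#' field.  The element's shape predicate is checked at `xi` first; points
#' outside the closed reference shape raise a domain error unless
#' extrapolation is explicitly allowed.
#'
#' @param field the field evaluator (typically the final piecewise or an
#'   evaluator referencing it).
#' @param mesh_argument the mesh-valued argument evaluator of the pipeline.
#' @param element element member identifier.
#' @param xi chart coordinates within the element.
#' @param env additional argument assignments.
#' @param allow_extrapolation evaluate even when the shape predicate is false
#'   at `xi`.
#' @return an [fml_value].
#' @export
fml_evaluate_mesh_field <- function(field, mesh_argument, element, xi,
                                    env = list(), allow_extrapolation = FALSE) {
  mesh <- mesh_argument$value_type
  stopifnot(inherits(mesh, "fml_mesh_type"))
  loc <- fml_mesh_location(mesh, element, xi)  # member error if not in mesh
  shape <- mesh$shape_map[[as.character(loc$element)]]
  if (!is.null(shape) && !allow_extrapolation) {
    inside <- eval_shape_predicate(shape, loc$xi, env)
    if (!isTRUE(inside))
      fml_stop("fml_domain_error",
               "xi = (%s) is outside the shape of element %d",
               paste(format(xi), collapse = ", "), loc$element)
  }
  env[[mesh_argument$name]] <- loc
  fml_evaluate(field, env)
}

# evaluate a Boolean shape predicate at chart coordinates: assign xi to the
# predicate's (single) free chart-valued argument
eval_shape_predicate <- function(shape, xi, env = list()) {
  free <- tryCatch(fml_free_arguments(shape), error = function(e) list())
  for (a in free) {
    if (inherits(a$value_type, "fml_continuous_type") &&
        a$value_type$dimension == length(xi))
      env[[a$name]] <- fml_real_value(a$value_type, xi)
  }
  v <- fml_evaluate(shape, env)
  if (v$kind != "boolean")
    fml_stop("fml_type_error", "shape predicate '%s' is not Boolean-valued", shape$name)
  v$value
}
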