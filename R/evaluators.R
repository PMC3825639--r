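# The seven evaluator kinds and bindings.
#
# Evaluators form a directed acyclic pipeline; each declares a value type.
# References between evaluators are object references (environments), never
# names, so pipelines can be assembled before anything is registered in a
# model.

new_evaluator <- function(class, fields) {
  stopifnot(!is.null(fields$name))
  new_fml_object(c(class, "fml_evaluator"), fields)
}

check_value_type <- function(value_type, name) {
  if (!inherits(value_type, "fml_domain_type"))
    fml_stop("fml_definition_error", "evaluator '%s': value type missing", name)
  value_type
}

#' Argument evaluator
#'
#' Names an input to an evaluation pipeline.  A plain argument stands for a
#' value of its type; a *function-valued* argument additionally declares the
#' arguments it depends on, and a binding must supply an evaluator that is
#' applied at the original operand site.
#'
#' @param name identifier.
#' @param value_type the argument's domain type.
#' @param arguments for function-valued arguments, list of the argument
#'   evaluators the function consumes (empty for plain values).
#' @return an `fml_argument` evaluator.
#' @export
fml_argument <- function(name, value_type, arguments = list()) {
  check_identifier(name)
  check_value_type(value_type, name)
  stopifnot(all(vapply(arguments, inherits, TRUE, "fml_argument")))
  new_evaluator("fml_argument",
                list(name = name, value_type = value_type, arguments = arguments))
}

# Accessor onto a mesh-valued argument: extracts the element member or the
# chart coordinates from a mesh location.  These are the implicit
# "<argument>.elements" / "<argument>.xi" objects; they are not serialized
# as XML elements, only referenced by their dotted names.
fml_mesh_accessor <- function(mesh_argument, part = c("elements", "xi")) {
  part <- match.arg(part)
  stopifnot(inherits(mesh_argument, "fml_argument"),
            inherits(mesh_argument$value_type, "fml_mesh_type"))
  cache_field <- paste0(".accessor_", part)
  cached <- mesh_argument[[cache_field]]
  if (!is.null(cached)) return(cached)
  mesh <- mesh_argument$value_type
  vt <- if (part == "elements") mesh$element_ensemble else mesh$chart_type
  acc <- new_evaluator("fml_mesh_accessor",
                       list(name = paste0(mesh_argument$name, ".", part),
                            value_type = vt, mesh_argument = mesh_argument,
                            part = part))
  assign(cache_field, acc, envir = mesh_argument)
  acc
}

#' Constant evaluator
#'
#' Represents a constant by its string rendering: a real number
#' (`"1059.87"`), an ensemble member identifier, or a Boolean
#' (`"true"`/`"false"`).
#'
#' @param name identifier.
#' @param value_type domain type of the constant (scalar continuous,
#'   ensemble, or Boolean).
#' @param value_string textual representation; a numeric is accepted and
#'   rendered.
#' @return an `fml_constant` evaluator.
#' @export
fml_constant <- function(name, value_type, value_string) {
  check_identifier(name)
  check_value_type(value_type, name)
  if (is.numeric(value_string)) value_string <- format(value_string, digits = 17)
  ev <- new_evaluator("fml_constant",
                      list(name = name, value_type = value_type,
                           value_string = as.character(value_string)))
  parse_constant(ev)  # fail fast on an unparseable literal
  ev
}

parse_constant <- function(ev) {
  vt <- ev$value_type
  s <- trimws(ev$value_string)
  if (inherits(vt, "fml_continuous_type")) {
    if (vt$dimension != 1L)
      fml_stop("fml_type_error", "constant '%s': only scalar continuous constants", ev$name)
    x <- suppressWarnings(as.numeric(s))
    if (is.na(x))
      fml_stop("fml_parse_error", "constant '%s': '%s' is not a number", ev$name, s)
    return(fml_real_value(vt, x))
  }
  if (inherits(vt, "fml_ensemble_type")) {
    m <- suppressWarnings(as.integer(s))
    if (is.na(m) || !(m %in% vt$members))
      fml_stop("fml_parse_error", "constant '%s': '%s' is not a member of ensemble '%s'",
               ev$name, s, vt$name)
    return(fml_ensemble_value(vt, m))
  }
  if (inherits(vt, "fml_boolean_type")) {
    if (!(tolower(s) %in% c("true", "false")))
      fml_stop("fml_parse_error", "constant '%s': '%s' is not a Boolean", ev$name, s)
    return(fml_boolean_value(vt, tolower(s) == "true"))
  }
  fml_stop("fml_type_error", "constant '%s': unsupported value type", ev$name)
}

#' Parameter evaluator
#'
#' A piecewise function from one or more ensemble-valued indices to a scalar
#' (real or ensemble member), realised by looking up values in a data source.
#' Dense layout addresses the source row-major over the declared index order
#' (last index fastest), a member's position being its rank in the ascending
#' member list of its ensemble.  Sparse layout pairs a key source (one column
#' per index) with an aligned value source; missing keys are lookup errors.
#'
#' @param name identifier.
#' @param value_type scalar continuous or ensemble type of the stored values.
#' @param index_arguments list of ensemble-valued evaluators (argument
#'   evaluators or mesh element accessors) indexing the data.
#' @param data_source `fml_data_source` holding the values.
#' @param layout `"dense"` or `"sparse"`.
#' @param key_source for sparse layout, the `fml_data_source` of index-tuple
#'   rows aligned with `data_source`.
#' @return an `fml_parameter` evaluator.
#' @export
fml_parameter <- function(name, value_type, index_arguments, data_source,
                          layout = c("dense", "sparse"), key_source = NULL) {
  check_identifier(name)
  check_value_type(value_type, name)
  layout <- match.arg(layout)
  if (!is.list(index_arguments)) index_arguments <- list(index_arguments)
  for (ia in index_arguments) {
    if (!inherits(ia$value_type, "fml_ensemble_type"))
      fml_stop("fml_type_error",
               "parameter '%s': index '%s' is not ensemble-valued", name, ia$name)
  }
  if (layout == "sparse" && is.null(key_source))
    fml_stop("fml_definition_error", "parameter '%s': sparse layout needs a key source", name)
  new_evaluator("fml_parameter",
                list(name = name, value_type = value_type,
                     index_arguments = index_arguments,
                     data_source = data_source, layout = layout,
                     key_source = key_source))
}

#' Create a binding
#'
#' Associates an upstream argument evaluator with a delegate evaluator;
#' semantically a term substitution.  For plain arguments the delegate's
#' value type must be compatible with the argument's; for function-valued
#' arguments the delegate is applied at the operand site.
#'
#' @param argument the `fml_argument` (or mesh accessor) being bound.
#' @param delegate the evaluator substituted for it.
#' @return an `fml_binding`.
#' @export
fml_bind <- function(argument, delegate) {
  stopifnot(inherits(argument, "fml_evaluator"), inherits(delegate, "fml_evaluator"))
  if (!fml_type_compatible(argument$value_type, delegate$value_type))
    fml_stop("fml_type_error",
             "binding: delegate '%s' (type '%s') incompatible with argument '%s' (type '%s')",
             delegate$name, delegate$value_type$name, argument$name,
             argument$value_type$name)
  structure(list(argument = argument, delegate = delegate), class = "fml_binding")
}

check_bindings <- function(bindings, name) {
  stopifnot(all(vapply(bindings, inherits, TRUE, "fml_binding")))
  bindings
}

#' Piecewise evaluator
#'
#' A piecewise function from a discrete (ensemble) index to the value type:
#' the index evaluator selects a branch evaluator by member identifier; an
#' optional default covers unlisted members.  This is the usual final step of
#' a field over an FEM mesh, the index being the mesh element.
#'
#' @param name identifier.
#' @param value_type declared value type; every branch must be compatible.
#' @param index ensemble-valued evaluator selecting the branch.
#' @param branches named list mapping member identifier (as character) to
#'   evaluator.
#' @param default optional evaluator used when no branch matches.
#' @param bindings list of [fml_bind()] substitutions applied over the
#'   subtree.
#' @return an `fml_piecewise` evaluator.
#' @export
fml_piecewise <- function(name, value_type, index, branches = list(),
                          default = NULL, bindings = list()) {
  check_identifier(name)
  check_value_type(value_type, name)
  if (!inherits(index$value_type, "fml_ensemble_type"))
    fml_stop("fml_type_error", "piecewise '%s': index is not ensemble-valued", name)
  new_evaluator("fml_piecewise",
                list(name = name, value_type = value_type, index = index,
                     branches = branches, default = default,
                     bindings = check_bindings(bindings, name)))
}

#' Aggregate evaluator
#'
#' Builds a vector value componentwise: component `c` (components taken in
#' ascending numerical order of the component ensemble's member identifiers)
#' is produced by the evaluator mapped to `c`, or by a single delegate
#' evaluated with the component-index argument bound to `c`.
#'
#' @param name identifier.
#' @param value_type continuous type of the assembled vector.
#' @param components named list mapping member identifier to a scalar
#'   evaluator (may be empty when `delegate` is given).
#' @param delegate single index-dependent evaluator used for every component.
#' @param index_argument ensemble-valued argument that receives the component
#'   member when `delegate` is used.
#' @param component_ensemble ensemble indexing the components; defaults to
#'   the value type's component ensemble.
#' @param bindings list of [fml_bind()] substitutions applied over the
#'   subtree.
#' @return an `fml_aggregate` evaluator.
#' @export
fml_aggregate <- function(name, value_type, components = list(), delegate = NULL,
                          index_argument = NULL, component_ensemble = NULL,
                          bindings = list()) {
  check_identifier(name)
  check_value_type(value_type, name)
  if (!inherits(value_type, "fml_continuous_type"))
    fml_stop("fml_type_error", "aggregate '%s': value type must be continuous", name)
  if (is.null(component_ensemble)) {
    component_ensemble <- value_type$component_ensemble
    if (is.null(component_ensemble))  # scalar value type: single pseudo-component
      component_ensemble <- fml_ensemble_type(paste0(name, ".component"), 1L)
  }
  if (is.null(delegate) && length(components) == 0L)
    fml_stop("fml_definition_error", "aggregate '%s': no components given", name)
  if (!is.null(delegate) && is.null(index_argument))
    fml_stop("fml_definition_error",
             "aggregate '%s': a delegate needs an index argument", name)
  new_evaluator("fml_aggregate",
                list(name = name, value_type = value_type,
                     component_ensemble = component_ensemble,
                     components = components, delegate = delegate,
                     index_argument = index_argument,
                     bindings = check_bindings(bindings, name)))
}

#' Reference evaluator
#'
#' Aliases another evaluator, optionally binding upstream arguments of the
#' target to delegate evaluators.  Binding an argument that is not free in
#' the target is rejected.
#'
#' @param name identifier.
#' @param target the referenced evaluator; the reference takes its value
#'   type.
#' @param bindings list of [fml_bind()] substitutions.
#' @return an `fml_reference` evaluator.
#' @export
fml_reference <- function(name, target, bindings = list()) {
  check_identifier(name)
  stopifnot(inherits(target, "fml_evaluator"))
  check_bindings(bindings, name)
  free <- fml_free_arguments(target)
  free_names <- vapply(free, function(a) a$name, "")
  for (b in bindings) {
    if (!(b$argument$name %in% free_names) ||
        !any(vapply(free, identical, TRUE, b$argument)))
      fml_stop("fml_binding_error",
               "reference '%s': '%s' is not an upstream argument of '%s'",
               name, b$argument$name, target$name)
  }
  new_evaluator("fml_reference",
                list(name = name, value_type = target$value_type,
                     target = target, bindings = bindings))
}

#' External evaluator
#'
#' Declares an evaluator whose semantics live outside the document, keyed by
#' its fully-qualified name — the language's extension mechanism.  The
#' standard library's interpolators and shape predicates are externals with
#' registered implementations (see [fml_register_external()]); unknown
#' externals survive parsing and serialization untouched and only error at
#' evaluation time.
#'
#' @param name identifier (the implementation key).
#' @param value_type declared value type.
#' @param arguments list of argument evaluators the external consumes.
#' @return an `fml_external` evaluator.
#' @export
fml_external <- function(name, value_type, arguments = list()) {
  check_identifier(name)
  check_value_type(value_type, name)
  stopifnot(all(vapply(arguments, inherits, TRUE, "fml_evaluator")))
  new_evaluator("fml_external",
                list(name = name, value_type = value_type, arguments = arguments))
}

# ---- free arguments ---------------------------------------------------------

# The set of argument evaluators (and mesh accessors' parent arguments) that
# must be supplied for `e` to evaluate: bindings remove their argument and add
# the free arguments of their delegate; a function-valued argument
# contributes itself plus its declared dependencies.  No cross-branch
# memoisation: the same subtree can have different free sets under different
# binding scopes.  `path` guards against reference cycles.
collect_free <- function(e, acc, path = character()) {
  key <- as.character(e$.uid)
  if (key %in% path)
    fml_stop("fml_cycle_error", "evaluator '%s' participates in a reference cycle", e$name)
  seen <- c(path, key)
  add <- function(acc, a) {
    if (!any(vapply(acc, identical, TRUE, a))) acc[[length(acc) + 1L]] <- a
    acc
  }
  drop <- function(acc, a) Filter(function(x) !identical(x, a), acc)
  # free args contributed by a binding delegate: the delegate of a
  # function-valued argument receives that argument's declared dependencies
  # at the application site, so those do not become free here
  add_delegate <- function(acc, bd) {
    dfree <- collect_free(bd$delegate, list(), seen)
    if (inherits(bd$argument, "fml_argument"))
      for (dep in bd$argument$arguments) dfree <- drop(dfree, dep)
    for (a in dfree) acc <- add(acc, a)
    acc
  }
  if (inherits(e, "fml_argument")) {
    acc <- add(acc, e)
    for (d in e$arguments) acc <- collect_free(d, acc, seen)
  } else if (inherits(e, "fml_mesh_accessor")) {
    acc <- add(acc, e$mesh_argument)
  } else if (inherits(e, "fml_constant") || inherits(e, "fml_external")) {
    if (inherits(e, "fml_external"))
      for (a in e$arguments) acc <- collect_free(a, acc, seen)
  } else if (inherits(e, "fml_parameter")) {
    for (a in e$index_arguments) acc <- collect_free(a, acc, seen)
  } else if (inherits(e, "fml_piecewise")) {
    inner <- list()
    inner <- collect_free(e$index, inner, seen)
    for (b in e$branches) inner <- collect_free(b, inner, seen)
    if (!is.null(e$default)) inner <- collect_free(e$default, inner, seen)
    for (bd in e$bindings) inner <- drop(inner, bd$argument)
    for (a in inner) acc <- add(acc, a)
    for (bd in e$bindings) acc <- add_delegate(acc, bd)
  } else if (inherits(e, "fml_aggregate")) {
    inner <- list()
    for (b in e$components) inner <- collect_free(b, inner, seen)
    if (!is.null(e$delegate)) inner <- collect_free(e$delegate, inner, seen)
    if (!is.null(e$index_argument)) inner <- drop(inner, e$index_argument)
    for (bd in e$bindings) inner <- drop(inner, bd$argument)
    for (a in inner) acc <- add(acc, a)
    for (bd in e$bindings) acc <- add_delegate(acc, bd)
  } else if (inherits(e, "fml_reference")) {
    inner <- collect_free(e$target, list(), seen)
    for (bd in e$bindings) inner <- drop(inner, bd$argument)
    for (a in inner) acc <- add(acc, a)
    for (bd in e$bindings) acc <- add_delegate(acc, bd)
  }
  acc
}

#' Free (unbound) arguments of an evaluator pipeline
#'
#' @param e an evaluator.
#' @return list of argument evaluators that must be assigned (or bound) for
#'   evaluation.
#' @export
fml_free_arguments <- function(e) {
  stopifnot(inherits(e, "fml_evaluator"))
  collect_free(e, list(), character())
}
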