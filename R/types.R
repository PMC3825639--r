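# Domain types and the model container.
#
# Every FieldML object is an environment so that references between objects
# are true references: two independently defined types are distinct objects
# even when structurally identical, which is exactly the nominal typing rule
# of the language, and an imported object is the very same object as in its
# source region.

new_fml_object <- function(class, fields) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  .fml$uid <- if (is.null(.fml$uid)) 1L else .fml$uid + 1L
  e$.uid <- .fml$uid
  class(e) <- c(class, if (grepl("_type$", class[1L])) "fml_domain_type", "fml_object")
  e
}

fml_stop <- function(code, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(code, "fml_error")))
}

check_identifier <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    fml_stop("fml_definition_error", "object name must be a non-empty string")
  name
}

#' Define an ensemble type
#'
#' An ensemble is a finite discrete domain whose members carry unique
#' non-negative integer identifiers (node numbers, element numbers, component
#' indices).  Members are stored in the order given; serialization always
#' orders them ascending.
#'
#' @param name identifier for the type.
#' @param members vector of unique non-negative integers; must be non-empty.
#' @return an object of class `fml_ensemble_type`.
#' @examples
#' A <- fml_ensemble_type("A", c(4, 37, 60, 1002))
#' max(A$members)  # 1002
#' @export
fml_ensemble_type <- function(name, members) {
  check_identifier(name)
  if (length(members) == 0L)
    fml_stop("fml_definition_error", "ensemble '%s': member set must not be empty", name)
  m <- suppressWarnings(as.integer(members))
  if (anyNA(m) || any(m < 0L) || any(as.numeric(members) != m))
    fml_stop("fml_definition_error",
             "ensemble '%s': members must be non-negative integers", name)
  if (anyDuplicated(m))
    fml_stop("fml_definition_error", "ensemble '%s': duplicate member identifier", name)
  new_fml_object("fml_ensemble_type", list(name = name, members = m))
}

#' Define a Boolean type
#'
#' The two-valued discrete type used for element-shape predicates.  FieldML
#' 0.5 has no Boolean operators; Boolean-valued evaluators only serve as
#' predicates.
#'
#' @param name identifier for the type.
#' @return an object of class `fml_boolean_type`.
#' @export
fml_boolean_type <- function(name) {
  check_identifier(name)
  new_fml_object("fml_boolean_type", list(name = name))
}

#' Define a continuous type
#'
#' An n-dimensional real domain.  For dimension greater than one an implicit
#' component ensemble (members `1..dimension`, named `<name>.component` unless
#' supplied) indexes the vector components.
#'
#' @param name identifier for the type.
#' @param dimension positive integer.
#' @param component_ensemble optional ensemble used to index components; its
#'   cardinality must equal `dimension`.  Required form for interpolation
#'   parameter vectors whose components are local nodes.
#' @return an object of class `fml_continuous_type`.
#' @export
fml_continuous_type <- function(name, dimension = 1L, component_ensemble = NULL) {
  check_identifier(name)
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 1L)
    fml_stop("fml_definition_error", "continuous type '%s': dimension must be >= 1", name)
  if (dimension > 1L && is.null(component_ensemble))
    component_ensemble <- fml_ensemble_type(paste0(name, ".component"), seq_len(dimension))
  if (!is.null(component_ensemble)) {
    stopifnot(inherits(component_ensemble, "fml_ensemble_type"))
    if (length(component_ensemble$members) != dimension)
      fml_stop("fml_definition_error",
               "continuous type '%s': component ensemble cardinality %d != dimension %d",
               name, length(component_ensemble$members), dimension)
  }
  new_fml_object("fml_continuous_type",
                 list(name = name, dimension = dimension,
                      component_ensemble = component_ensemble))
}

#' Define a mesh type
#'
#' A mesh couples an element ensemble with a chart (local coordinate)
#' continuous type of the mesh dimension.  Every element carries a
#' Boolean-valued shape predicate, true on the closed reference shape of the
#' element.  The implicit element ensemble is named `<name>.elements` and the
#' chart type `<name>.xi`.
#'
#' @param name identifier for the type.
#' @param dimension positive integer mesh (and chart) dimension.
#' @param elements vector of element member identifiers.
#' @param shapes either a single Boolean-valued evaluator used for every
#'   element, or a named list mapping element identifier to evaluator.
#' @param chart_type optional continuous type to use as the chart; pass the
#'   library's chart type (e.g. `chart.2d`) so that bindings of library
#'   chart arguments to the mesh's xi accessor are nominally well-typed.
#'   Defaults to a fresh implicit `<name>.xi` type.
#' @return an object of class `fml_mesh_type`.
#' @export
fml_mesh_type <- function(name, dimension, elements, shapes, chart_type = NULL) {
  check_identifier(name)
  dimension <- as.integer(dimension)
  if (is.na(dimension) || dimension < 1L)
    fml_stop("fml_definition_error", "mesh '%s': dimension must be >= 1", name)
  element_ensemble <- fml_ensemble_type(paste0(name, ".elements"), elements)
  if (is.null(chart_type)) {
    chart_type <- fml_continuous_type(paste0(name, ".xi"), dimension)
  } else {
    stopifnot(inherits(chart_type, "fml_continuous_type"))
    if (chart_type$dimension != dimension)
      fml_stop("fml_definition_error",
               "mesh '%s': chart type '%s' has dimension %d, mesh has %d",
               name, chart_type$name, chart_type$dimension, dimension)
  }
  shape_map <- list()
  if (inherits(shapes, "fml_evaluator")) {
    for (m in element_ensemble$members) shape_map[[as.character(m)]] <- shapes
  } else if (is.list(shapes)) {
    shape_map <- shapes
  } else {
    fml_stop("fml_definition_error", "mesh '%s': invalid shape assignment", name)
  }
  for (m in element_ensemble$members) {
    sh <- shape_map[[as.character(m)]]
    if (is.null(sh))
      fml_stop("fml_definition_error", "mesh '%s': element %d has no shape predicate",
               name, m)
    if (!inherits(sh$value_type, "fml_boolean_type"))
      fml_stop("fml_type_error",
               "mesh '%s': shape predicate '%s' for element %d is not Boolean-valued",
               name, sh$name, m)
  }
  extra <- setdiff(names(shape_map), as.character(element_ensemble$members))
  if (length(extra))
    fml_stop("fml_definition_error", "mesh '%s': shape assigned to unknown element %s",
             name, extra[1L])
  new_fml_object("fml_mesh_type",
                 list(name = name, dimension = dimension,
                      element_ensemble = element_ensemble,
                      chart_type = chart_type, shape_map = shape_map))
}

#' Create an empty model region
#'
#' A model is a named region holding domain types, evaluators, data resources
#' and import records.  It is a mutable reference object: `fml_add()`
#' registers objects in place.
#'
#' @param region_name name of the region.
#' @return an object of class `fml_model`.
#' @export
fml_model <- function(region_name = "region") {
  check_identifier(region_name)
  new_fml_object("fml_model",
                 list(region_name = region_name,
                      types = list(), evaluators = list(),
                      data_resources = list(),
                      imports = list(),        # records: href, region, kind, local, remote
                      imported = list(),       # local name -> object (shared identity)
                      href = NA_character_))
}

model_has_name <- function(model, name) {
  name %in% c(names(model$types), names(model$evaluators),
              names(model$data_resources), names(model$imported))
}

#' Register objects in a model region
#'
#' Adds domain types, evaluators or data resources to a model.  Names must be
#' unique within the region.  Returns the model invisibly so calls can be
#' chained.
#'
#' @param model a `fml_model`.
#' @param ... objects to add.
#' @export
fml_add <- function(model, ...) {
  stopifnot(inherits(model, "fml_model"))
  for (obj in list(...)) {
    nm <- obj$name
    if (model_has_name(model, nm))
      fml_stop("fml_definition_error", "region '%s': name '%s' already defined",
               model$region_name, nm)
    if (inherits(obj, "fml_domain_type")) {
      model$types[[nm]] <- obj
    } else if (inherits(obj, "fml_evaluator")) {
      model$evaluators[[nm]] <- obj
    } else if (inherits(obj, "fml_data_resource")) {
      model$data_resources[[nm]] <- obj
    } else {
      fml_stop("fml_definition_error", "cannot add object of class %s", class(obj)[1L])
    }
  }
  invisible(model)
}

#' Import an object from another model
#'
#' The imported object is the *same* object as in the source region, so
#' nominal type compatibility is preserved across imports.  A local alias may
#' be given.
#'
#' @param model destination model.
#' @param source source model (for example `fml_library()`).
#' @param name name of the object in the source region.
#' @param local_name optional alias in the destination region.
#' @export
fml_import <- function(model, source, name, local_name = name) {
  stopifnot(inherits(model, "fml_model"), inherits(source, "fml_model"))
  obj <- fml_get(source, name)
  if (is.null(obj))
    fml_stop("fml_import_error", "import: '%s' not found in region '%s'",
             name, source$region_name)
  if (model_has_name(model, local_name))
    fml_stop("fml_definition_error", "region '%s': name '%s' already defined",
             model$region_name, local_name)
  model$imported[[local_name]] <- obj
  model$imports[[length(model$imports) + 1L]] <-
    list(href = source$href, region = source$region_name,
         kind = if (inherits(obj, "fml_domain_type")) "type" else "evaluator",
         local = local_name, remote = name)
  invisible(model)
}

#' Look up an object by name
#'
#' Resolves a name within a region: locally defined types, evaluators, data
#' resources and sources, imported objects, and the implicit dotted names of
#' mesh/continuous constituents (`<mesh>.elements`, `<mesh>.xi`,
#' `<type>.component`) and mesh-argument accessors
#' (`<argument>.elements`, `<argument>.xi`).
#'
#' @param model a `fml_model`.
#' @param name the name to resolve.
#' @return the object, or `NULL` when the name does not resolve.
#' @export
fml_get <- function(model, name) {
  stopifnot(inherits(model, "fml_model"))
  for (tab in list(model$types, model$evaluators, model$data_resources, model$imported)) {
    if (!is.null(tab[[name]])) return(tab[[name]])
  }
  # data sources live under their resource
  for (res in model$data_resources) {
    if (!is.null(res$sources[[name]])) return(res$sources[[name]])
  }
  # implicit dotted names: strip the last component and look for a parent
  if (grepl(".", name, fixed = TRUE)) {
    parent <- sub("\\.[^.]+$", "", name)
    leaf <- sub("^.*\\.", "", name)
    p <- fml_get(model, parent)
    if (!is.null(p)) {
      if (inherits(p, "fml_mesh_type")) {
        if (leaf == "elements") return(p$element_ensemble)
        if (leaf == "xi") return(p$chart_type)
      }
      if (inherits(p, "fml_continuous_type") && leaf == "component")
        return(p$component_ensemble)
      if (inherits(p, "fml_argument") && inherits(p$value_type, "fml_mesh_type")) {
        if (leaf == "elements") return(fml_mesh_accessor(p, "elements"))
        if (leaf == "xi") return(fml_mesh_accessor(p, "xi"))
      }
    }
  }
  NULL
}

#' @export
print.fml_object <- function(x, ...) {
  cat("<", class(x)[1L], "> ", x$name, "\n", sep = "")
  if (inherits(x, "fml_ensemble_type"))
    cat("  members:", paste(x$members, collapse = " "), "\n")
  if (inherits(x, "fml_continuous_type"))
    cat("  dimension:", x$dimension, "\n")
  if (inherits(x, "fml_mesh_type"))
    cat("  dimension:", x$dimension, " elements:",
        paste(x$element_ensemble$members, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.fml_model <- function(x, ...) {
  cat("<fml_model> region '", x$region_name, "'\n", sep = "")
  cat("  types:", length(x$types),
      " evaluators:", length(x$evaluators),
      " data resources:", length(x$data_resources),
      " imports:", length(x$imports), "\n")
  invisible(x)
}
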