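# Structural model comparison, used to state round-trip properties: two
# models are isomorphic when their named object graphs match, independent of
# document order and of object identity (a parsed copy of a region is
# isomorphic to, but nominally distinct from, its source).

desc_ref <- function(model, obj) {
  if (is.null(obj)) return(NULL)
  object_name(model, obj)
}

describe_object <- function(model, obj) {
  if (inherits(obj, "fml_ensemble_type"))
    return(list(kind = "ensemble", members = sort(obj$members)))
  if (inherits(obj, "fml_boolean_type"))
    return(list(kind = "boolean"))
  if (inherits(obj, "fml_continuous_type"))
    return(list(kind = "continuous", dim = obj$dimension,
                component = if (obj$dimension > 1L) desc_ref(model, obj$component_ensemble)))
  if (inherits(obj, "fml_mesh_type")) {
    ms <- sort(obj$element_ensemble$members)
    return(list(kind = "mesh", dim = obj$dimension, elements = ms,
                chart = desc_ref(model, obj$chart_type),
                shapes = lapply(stats::setNames(as.character(ms), as.character(ms)),
                                function(m) desc_ref(model, obj$shape_map[[m]]))))
  }
  if (inherits(obj, "fml_data_resource"))
    return(list(kind = paste0("resource.", obj$kind), text = obj$text,
                path = obj$path,
                sources = lapply(obj$sources, function(s)
                  list(shape = s$shape, first = s$first_record,
                       count = s$record_count, dataset = s$dataset,
                       offset = s$offset))))
  vt <- desc_ref(model, obj$value_type)
  bnd <- function(bs) lapply(bs, function(b)
    list(arg = desc_ref(model, b$argument), del = desc_ref(model, b$delegate)))
  sort_by_name <- function(x) if (length(x)) x[order(as.integer(names(x)))] else x
  if (inherits(obj, "fml_argument"))
    return(list(kind = "argument", vt = vt,
                args = lapply(obj$arguments, desc_ref, model = model)))
  if (inherits(obj, "fml_mesh_accessor"))
    return(list(kind = "accessor", vt = vt, part = obj$part,
                of = desc_ref(model, obj$mesh_argument)))
  if (inherits(obj, "fml_constant"))
    return(list(kind = "constant", vt = vt, value = obj$value_string))
  if (inherits(obj, "fml_parameter"))
    return(list(kind = "parameter", vt = vt, layout = obj$layout,
                data = desc_ref(model, obj$data_source),
                keys = desc_ref(model, obj$key_source),
                idx = lapply(obj$index_arguments, desc_ref, model = model)))
  if (inherits(obj, "fml_piecewise"))
    return(list(kind = "piecewise", vt = vt,
                index = desc_ref(model, obj$index),
                branches = lapply(sort_by_name(obj$branches), desc_ref, model = model),
                default = desc_ref(model, obj$default),
                bindings = bnd(obj$bindings)))
  if (inherits(obj, "fml_aggregate"))
    return(list(kind = "aggregate", vt = vt,
                ensemble = desc_ref(model, obj$component_ensemble),
                components = lapply(sort_by_name(obj$components), desc_ref, model = model),
                delegate = desc_ref(model, obj$delegate),
                index_arg = desc_ref(model, obj$index_argument),
                bindings = bnd(obj$bindings)))
  if (inherits(obj, "fml_reference"))
    return(list(kind = "reference", vt = vt,
                target = desc_ref(model, obj$target),
                bindings = bnd(obj$bindings)))
  if (inherits(obj, "fml_external"))
    return(list(kind = "external", vt = vt,
                args = lapply(obj$arguments, desc_ref, model = model)))
  list(kind = class(obj)[1L])
}

model_descriptor <- function(model) {
  nms <- function(x) if (length(x)) x[order(names(x))] else x
  list(region = model$region_name,
       imports = lapply(model$imports[order(vapply(model$imports, function(r)
         paste(r$region, r$remote, r$local), ""))],
         function(r) r[c("region", "kind", "local", "remote")]),
       types = lapply(nms(model$types), describe_object, model = model),
       evaluators = lapply(nms(model$evaluators), describe_object, model = model),
       resources = lapply(nms(model$data_resources), describe_object, model = model))
}

#' Structural equivalence of two models
#'
#' Deep comparison of the named object graphs of two regions, ignoring
#' declaration order and object identity.  This is the relation preserved by
#' an XML round-trip (`fml_parse_xml(fml_write_xml(m))`).
#'
#' @param a,b models to compare.
#' @return `TRUE` or `FALSE`.
#' @export
fml_isomorphic <- function(a, b) {
  isTRUE(all.equal(model_descriptor(a), model_descriptor(b),
                   check.attributes = TRUE))
}
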