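# Deterministic FieldML 0.5 XML output.
#
# Objects are emitted grouped by kind (imports, data resources, types by
# kind, evaluators by kind), each group in declaration order, so equal models
# produce byte-identical documents.  Ensembles are serialized as contiguous
# ranges where possible, else as ascending member lists.  Implicit objects
# (component ensembles, mesh element/chart constituents, mesh-argument
# accessors) are referenced by their dotted names and never emitted as
# elements of their own.

FML_NS <- "http://www.fieldml.org/FieldML/0.5"
XLINK_NS <- "http://www.w3.org/1999/xlink"

# resolve the serialization name of a referenced object within the region
object_name <- function(model, obj) {
  for (tab in list(model$types, model$evaluators, model$imported)) {
    for (nm in names(tab)) if (identical(tab[[nm]], obj)) return(nm)
  }
  for (res in model$data_resources) {
    for (nm in names(res$sources)) if (identical(res$sources[[nm]], obj)) return(nm)
  }
  if (inherits(obj, "fml_mesh_accessor"))
    return(paste0(object_name(model, obj$mesh_argument), ".", obj$part))
  if (inherits(obj, "fml_ensemble_type") || inherits(obj, "fml_continuous_type")) {
    # implicit constituents of registered (or imported) types
    for (tab in list(model$types, model$imported)) {
      for (nm in names(tab)) {
        t <- tab[[nm]]
        if (inherits(t, "fml_continuous_type") &&
            identical(t$component_ensemble, obj)) return(paste0(nm, ".component"))
        if (inherits(t, "fml_mesh_type")) {
          if (identical(t$element_ensemble, obj)) return(paste0(nm, ".elements"))
          if (identical(t$chart_type, obj)) return(paste0(nm, ".xi"))
        }
      }
    }
  }
  fml_stop("fml_serialization_error",
           "dangling reference: '%s' is not defined or imported in region '%s'",
           obj$name, model$region_name)
}

members_xml <- function(parent, members) {
  m <- sort(unique(as.integer(members)))
  node <- xml2::xml_add_child(parent, "Members")
  if (length(m) == diff(range(m)) + 1L) {
    xml2::xml_add_child(node, "MemberRange", min = as.character(min(m)),
                        max = as.character(max(m)))
  } else {
    xml2::xml_add_child(node, "MemberList", paste(m, collapse = " "))
  }
  node
}

write_bindings <- function(parent, model, bindings) {
  if (length(bindings) == 0L) return(invisible())
  bn <- xml2::xml_add_child(parent, "Bindings")
  for (b in bindings)
    xml2::xml_add_child(bn, "Bind",
                        argument = object_name(model, b$argument),
                        source = object_name(model, b$delegate))
  invisible()
}

#' Serialize a model to FieldML 0.5 XML
#'
#' @param model a validated `fml_model` (a model with outstanding
#'   diagnostics, dangling references included, is refused).
#' @param path optional file to write; when `NULL` the `xml_document` is
#'   returned.
#' @param validate run [fml_validate()] first (default `TRUE`).
#' @return the `xml_document` (invisibly when written to a file).
#' @export
fml_write_xml <- function(model, path = NULL, validate = TRUE) {
  stopifnot(inherits(model, "fml_model"))
  if (validate) {
    d <- fml_validate(model)
    if (nrow(d) > 0L)
      fml_stop("fml_serialization_error",
               "model has %d validation diagnostics; first: %s", nrow(d), d$message[1L])
  }
  # the xlink namespace carries import/resource hrefs; no default namespace is
  # declared so that XPath over parsed documents stays prefix-free
  doc <- xml2::xml_new_root("Fieldml", version = "0.5", "xmlns:xlink" = XLINK_NS)
  region <- xml2::xml_add_child(doc, "Region", name = model$region_name)

  # imports, grouped by (href, region) in first-occurrence order
  if (length(model$imports)) {
    keys <- vapply(model$imports, function(r) paste0(r$href, "|", r$region), "")
    for (key in unique(keys)) {
      recs <- model$imports[keys == key]
      node <- xml2::xml_add_child(region, "Import",
                                  "xlink:href" = recs[[1L]]$href,
                                  region = recs[[1L]]$region)
      for (r in recs) {
        tag <- if (r$kind == "type") "ImportType" else "ImportEvaluator"
        xml2::xml_add_child(node, tag, localName = r$local, remoteName = r$remote)
      }
    }
  }

  for (res in model$data_resources) {
    node <- xml2::xml_add_child(region, "DataResource", name = res$name)
    desc <- xml2::xml_add_child(node, "DataResourceDescription")
    if (res$kind == "inline") {
      xml2::xml_add_child(desc, "DataResourceString", res$text)
    } else {
      xml2::xml_add_child(desc, "DataResourceHref", "xlink:href" = res$path,
                          format = if (res$kind == "hdf5") "HDF5" else "PLAIN_TEXT")
    }
    for (src in res$sources) {
      attrs <- list(name = src$name, rank = as.character(length(src$shape)))
      if (res$kind != "hdf5") {
        attrs$firstRecord <- as.character(src$first_record)
        attrs$recordCount <- as.character(src$record_count)
      } else {
        attrs$dataset <- src$dataset
        if (!is.null(src$offset))
          attrs$offsets <- paste(as.integer(src$offset), collapse = " ")
      }
      sn <- do.call(xml2::xml_add_child, c(list(node, "ArrayDataSource"), attrs))
      if (length(src$shape))
        xml2::xml_add_child(sn, "ArrayDataSize", paste(src$shape, collapse = " "))
    }
  }

  is_kind <- function(objs, cls) Filter(function(x) inherits(x, cls), objs)

  for (t in is_kind(model$types, "fml_ensemble_type")) {
    node <- xml2::xml_add_child(region, "EnsembleType", name = t$name)
    members_xml(node, t$members)
  }
  for (t in is_kind(model$types, "fml_boolean_type"))
    xml2::xml_add_child(region, "BooleanType", name = t$name)
  for (t in is_kind(model$types, "fml_continuous_type")) {
    node <- xml2::xml_add_child(region, "ContinuousType", name = t$name)
    if (t$dimension > 1L) {
      ce <- t$component_ensemble
      named <- !is.null(ce) && !identical(object_name_or_null(model, t, ce),
                                          paste0(t$name, ".component"))
      if (named) {
        xml2::xml_set_attr(node, "componentEnsemble", object_name(model, ce))
      } else {
        xml2::xml_add_child(node, "Components",
                            name = paste0(t$name, ".component"),
                            count = as.character(t$dimension))
      }
    }
  }
  for (t in is_kind(model$types, "fml_mesh_type")) {
    node <- xml2::xml_add_child(region, "MeshType", name = t$name,
                                dimension = as.character(t$dimension))
    el <- xml2::xml_add_child(node, "Elements", name = paste0(t$name, ".elements"))
    members_xml(el, t$element_ensemble$members)
    chart_name <- object_name_or_null(model, t, t$chart_type)
    if (!is.null(chart_name) && chart_name != paste0(t$name, ".xi")) {
      xml2::xml_add_child(node, "Chart", type = chart_name)
    } else {
      xml2::xml_add_child(node, "Chart", name = paste0(t$name, ".xi"))
    }
    shape_names <- vapply(sort(t$element_ensemble$members), function(m)
      object_name(model, t$shape_map[[as.character(m)]]), "")
    if (length(unique(shape_names)) == 1L) {
      xml2::xml_add_child(node, "Shapes", evaluator = shape_names[1L])
    } else {
      sh <- xml2::xml_add_child(node, "Shapes")
      ms <- sort(t$element_ensemble$members)
      for (i in seq_along(ms))
        xml2::xml_add_child(sh, "Shape", element = as.character(ms[i]),
                            evaluator = shape_names[i])
    }
  }

  evs <- model$evaluators
  for (e in is_kind(evs, "fml_argument")) {
    node <- xml2::xml_add_child(region, "ArgumentEvaluator", name = e$name,
                                valueType = object_name(model, e$value_type))
    if (length(e$arguments)) {
      an <- xml2::xml_add_child(node, "Arguments")
      for (a in e$arguments)
        xml2::xml_add_child(an, "Argument", name = object_name(model, a))
    }
  }
  for (e in is_kind(evs, "fml_external")) {
    node <- xml2::xml_add_child(region, "ExternalEvaluator", name = e$name,
                                valueType = object_name(model, e$value_type))
    if (length(e$arguments)) {
      an <- xml2::xml_add_child(node, "Arguments")
      for (a in e$arguments)
        xml2::xml_add_child(an, "Argument", name = object_name(model, a))
    }
  }
  for (e in is_kind(evs, "fml_constant"))
    xml2::xml_add_child(region, "ConstantEvaluator", name = e$name,
                        valueType = object_name(model, e$value_type),
                        value = e$value_string)
  for (e in is_kind(evs, "fml_parameter")) {
    node <- xml2::xml_add_child(region, "ParameterEvaluator", name = e$name,
                                valueType = object_name(model, e$value_type))
    if (e$layout == "dense") {
      dn <- xml2::xml_add_child(node, "DenseArrayData",
                                data = object_name(model, e$data_source))
      ix <- xml2::xml_add_child(dn, "DenseIndexes")
      for (ia in e$index_arguments)
        xml2::xml_add_child(ix, "IndexEvaluator", evaluator = object_name(model, ia))
    } else {
      sn <- xml2::xml_add_child(node, "SparseArrayData",
                                keyData = object_name(model, e$key_source),
                                valueData = object_name(model, e$data_source))
      ix <- xml2::xml_add_child(sn, "SparseIndexes")
      for (ia in e$index_arguments)
        xml2::xml_add_child(ix, "IndexEvaluator", evaluator = object_name(model, ia))
    }
  }
  for (e in is_kind(evs, "fml_piecewise")) {
    node <- xml2::xml_add_child(region, "PiecewiseEvaluator", name = e$name,
                                valueType = object_name(model, e$value_type))
    write_bindings(node, model, e$bindings)
    xml2::xml_add_child(node, "IndexEvaluator", evaluator = object_name(model, e$index))
    em <- xml2::xml_add_child(node, "EvaluatorMap")
    if (!is.null(e$default))
      xml2::xml_set_attr(em, "default", object_name(model, e$default))
    for (m in as.character(sort(as.integer(names(e$branches)))))
      xml2::xml_add_child(em, "EvaluatorMapEntry", value = m,
                          evaluator = object_name(model, e$branches[[m]]))
  }
  for (e in is_kind(evs, "fml_aggregate")) {
    node <- xml2::xml_add_child(region, "AggregateEvaluator", name = e$name,
                                valueType = object_name(model, e$value_type))
    write_bindings(node, model, e$bindings)
    cn <- xml2::xml_add_child(node, "ComponentEvaluators",
                              ensemble = object_name(model, e$component_ensemble))
    if (!is.null(e$index_argument))
      xml2::xml_set_attr(cn, "index", object_name(model, e$index_argument))
    if (!is.null(e$delegate))
      xml2::xml_set_attr(cn, "default", object_name(model, e$delegate))
    for (m in as.character(sort(as.integer(names(e$components)))))
      xml2::xml_add_child(cn, "ComponentEvaluator", component = m,
                          evaluator = object_name(model, e$components[[m]]))
  }
  for (e in is_kind(evs, "fml_reference")) {
    node <- xml2::xml_add_child(region, "ReferenceEvaluator", name = e$name,
                                evaluator = object_name(model, e$target),
                                valueType = object_name(model, e$value_type))
    write_bindings(node, model, e$bindings)
  }

  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

# like object_name but NULL instead of error (used to decide whether a
# component ensemble is the type's own implicit one)
object_name_or_null <- function(model, parent_type, obj) {
  tryCatch(object_name(model, obj), error = function(e) NULL)
}
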