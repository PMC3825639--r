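# Parsing FieldML 0.5 XML documents, with import resolution across files.
#
# Parsing is two-pass: pass A creates every named object (types, data
# resources, evaluator shells) in document order and resolves imports through
# the locator; pass B fills evaluator fields, resolving names — including the
# implicit dotted names of mesh constituents and mesh-argument accessors.

#' Document locator for import resolution
#'
#' Maps import hrefs to documents.  Relative hrefs resolve against the
#' importing document's location; the standard library href (any href whose
#' basename is `FieldML_Library_0.5.xml`) resolves to the bundled in-memory
#' library, never the network.  Parsed documents are cached by normalized
#' path, so diamond imports share objects and nominal typing is preserved;
#' cyclic imports (self-imports included) are detected and rejected.
#'
#' @param map named character vector mapping hrefs to file paths.
#' @return an `fml_locator`.
#' @export
fml_locator <- function(map = character()) {
  loc <- new.env(parent = emptyenv())
  loc$map <- map
  loc$cache <- list()   # normalized path -> model
  loc$active <- character()
  class(loc) <- "fml_locator"
  loc
}

locator_resolve <- function(locator, href, base, mode) {
  if (basename(href) == "FieldML_Library_0.5.xml") return(fml_library())
  target <- if (href %in% names(locator$map)) locator$map[[href]]
            else if (grepl("^(/|[A-Za-z]:)", href)) href
            else file.path(base, href)
  if (!file.exists(target))
    fml_stop("fml_import_error", "import: cannot resolve href '%s' (tried '%s')",
             href, target)
  norm <- normalizePath(target)
  if (norm %in% locator$active)
    fml_stop("fml_import_error", "import cycle detected at '%s'", href)
  if (!is.null(locator$cache[[norm]])) return(locator$cache[[norm]])
  locator$active <- c(locator$active, norm)
  on.exit(locator$active <- setdiff(locator$active, norm), add = TRUE)
  m <- fml_parse_xml(target, locator = locator, mode = mode)
  locator$cache[[norm]] <- m
  m
}

req_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  # a prefixed attribute (xlink:href) is namespace-qualified once a document
  # has been serialized and re-read; fall back to the local name
  if (is.na(v) && grepl(":", name, fixed = TRUE))
    v <- xml2::xml_attr(node, sub("^.*:", "", name))
  if (is.na(v))
    fml_stop("fml_parse_error", "<%s> is missing attribute '%s'",
             xml2::xml_name(node), name)
  v
}

parse_members <- function(node) {
  mn <- xml2::xml_find_first(node, "./Members")
  if (inherits(mn, "xml_missing"))
    fml_stop("fml_parse_error", "<%s>: missing <Members>", xml2::xml_name(node))
  rng <- xml2::xml_find_first(mn, "./MemberRange")
  if (!inherits(rng, "xml_missing"))
    return(seq.int(as.integer(req_attr(rng, "min")), as.integer(req_attr(rng, "max"))))
  lst <- xml2::xml_find_first(mn, "./MemberList")
  if (!inherits(lst, "xml_missing"))
    return(as.integer(strsplit(trimws(xml2::xml_text(lst)), "[[:space:]]+")[[1L]]))
  fml_stop("fml_parse_error", "<Members>: expected <MemberRange> or <MemberList>")
}

#' Parse a FieldML 0.5 XML document
#'
#' Reads a document, resolves its imports through the locator, and returns
#' the fully resolved model with validation diagnostics attached as the
#' `"diagnostics"` attribute.  Unknown external evaluators are retained with
#' their declared value types and only fail at evaluation time.  In lenient
#' mode (the default) unknown region-level elements are skipped with a
#' warning; strict mode rejects them.
#'
#' @param x a file path, an XML string, or an `xml_document`.
#' @param locator an [fml_locator()]; created automatically when omitted.
#' @param mode `"lenient"` or `"strict"`.
#' @return a `fml_model`.
#' @export
fml_parse_xml <- function(x, locator = NULL, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (is.null(locator)) locator <- fml_locator()
  path <- NULL
  if (inherits(x, "xml_document")) {
    doc <- x
  } else if (is.character(x) && length(x) == 1L && !grepl("<", x, fixed = TRUE)) {
    path <- x
    doc <- tryCatch(xml2::read_xml(x), error = function(e)
      fml_stop("fml_parse_error", "malformed XML in '%s': %s", x, conditionMessage(e)))
  } else {
    doc <- tryCatch(xml2::read_xml(x), error = function(e)
      fml_stop("fml_parse_error", "malformed XML: %s", conditionMessage(e)))
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "Fieldml")
    fml_stop("fml_parse_error", "root element is <%s>, expected <Fieldml>",
             xml2::xml_name(root))
  region <- xml2::xml_find_first(root, "./Region")
  if (inherits(region, "xml_missing"))
    fml_stop("fml_parse_error", "document has no <Region>")
  model <- fml_model(req_attr(region, "name"))
  if (!is.null(path)) model$href <- path
  base <- if (!is.null(path)) dirname(path) else "."

  known <- c("Import", "DataResource", "EnsembleType", "BooleanType",
             "ContinuousType", "MeshType", "ArgumentEvaluator",
             "ExternalEvaluator", "ConstantEvaluator", "ParameterEvaluator",
             "PiecewiseEvaluator", "AggregateEvaluator", "ReferenceEvaluator")
  children <- xml2::xml_children(region)
  shells <- list()  # list of (node, shell) pairs for pass B

  resolve <- function(name, what = "object") {
    obj <- fml_get(model, name)
    if (is.null(obj))
      fml_stop("fml_parse_error", "region '%s': cannot resolve %s '%s'",
               model$region_name, what, name)
    obj
  }

  # ---- pass A: create named objects -----------------------------------------
  for (node in children) {
    tag <- xml2::xml_name(node)
    if (!(tag %in% known)) {
      if (mode == "strict")
        fml_stop("fml_schema_error", "unknown element <%s> in region '%s'",
                 tag, model$region_name)
      warning(sprintf("skipping unknown element <%s>", tag), call. = FALSE)
      next
    }
    if (tag == "Import") {
      href <- req_attr(node, "xlink:href")
      src <- locator_resolve(locator, href, base, mode)
      for (entry in xml2::xml_children(node)) {
        etag <- xml2::xml_name(entry)
        if (!(etag %in% c("ImportType", "ImportEvaluator"))) next
        fml_import(model, src, req_attr(entry, "remoteName"),
                   req_attr(entry, "localName"))
      }
      # record the href as written so round-trips preserve it
      n <- length(model$imports)
      k <- length(xml2::xml_children(node))
      for (i in seq_len(min(n, k))) model$imports[[n - k + i]]$href <- href
    } else if (tag == "DataResource") {
      desc <- xml2::xml_find_first(node, "./DataResourceDescription")
      inline <- xml2::xml_find_first(desc, "./DataResourceString")
      if (!inherits(inline, "xml_missing")) {
        res <- fml_data_resource(req_attr(node, "name"), "inline",
                                 text = xml2::xml_text(inline))
      } else {
        hn <- xml2::xml_find_first(desc, "./DataResourceHref")
        fmt <- req_attr(hn, "format")
        res <- fml_data_resource(req_attr(node, "name"),
                                 if (fmt == "HDF5") "hdf5" else "text_file",
                                 path = req_attr(hn, "xlink:href"))
      }
      for (sn in xml2::xml_find_all(node, "./ArrayDataSource")) {
        rank <- as.integer(req_attr(sn, "rank"))
        shape <- if (rank == 0L) integer(0) else {
          sz <- xml2::xml_find_first(sn, "./ArrayDataSize")
          as.integer(strsplit(trimws(xml2::xml_text(sz)), "[[:space:]]+")[[1L]])
        }
        first <- xml2::xml_attr(sn, "firstRecord")
        count <- xml2::xml_attr(sn, "recordCount")
        offs <- xml2::xml_attr(sn, "offsets")
        fml_data_source(req_attr(sn, "name"), res, shape,
                        first_record = if (is.na(first)) 1L else as.integer(first),
                        record_count = if (is.na(count)) NULL else as.integer(count),
                        dataset = if (res$kind == "hdf5") req_attr(sn, "dataset"),
                        offset = if (!is.na(offs))
                          as.integer(strsplit(trimws(offs), "[[:space:]]+")[[1L]]))
      }
      fml_add(model, res)
    } else if (tag == "EnsembleType") {
      fml_add(model, fml_ensemble_type(req_attr(node, "name"), parse_members(node)))
    } else if (tag == "BooleanType") {
      fml_add(model, fml_boolean_type(req_attr(node, "name")))
    } else if (tag == "ContinuousType") {
      nm <- req_attr(node, "name")
      ce_attr <- xml2::xml_attr(node, "componentEnsemble")
      comp <- xml2::xml_find_first(node, "./Components")
      if (!is.na(ce_attr)) {
        ce <- resolve(ce_attr, "component ensemble")
        fml_add(model, fml_continuous_type(nm, length(ce$members),
                                           component_ensemble = ce))
      } else if (!inherits(comp, "xml_missing")) {
        fml_add(model, fml_continuous_type(nm, as.integer(req_attr(comp, "count"))))
      } else {
        fml_add(model, fml_continuous_type(nm, 1L))
      }
    } else if (tag == "MeshType") {
      nm <- req_attr(node, "name")
      dim <- as.integer(req_attr(node, "dimension"))
      el <- xml2::xml_find_first(node, "./Elements")
      members <- parse_members(el)
      chart_node <- xml2::xml_find_first(node, "./Chart")
      chart_ref <- xml2::xml_attr(chart_node, "type")
      chart <- if (!is.na(chart_ref)) resolve(chart_ref, "chart type")
               else fml_continuous_type(paste0(nm, ".xi"), dim)
      # shells: shapes reference evaluators parsed later
      mesh <- new_fml_object("fml_mesh_type",
                             list(name = nm, dimension = dim,
                                  element_ensemble =
                                    fml_ensemble_type(paste0(nm, ".elements"), members),
                                  chart_type = chart,
                                  shape_map = list()))
      shells[[length(shells) + 1L]] <- list(node = node, shell = mesh)
      fml_add(model, mesh)
    } else {
      cls <- switch(tag,
                    ArgumentEvaluator = "fml_argument",
                    ExternalEvaluator = "fml_external",
                    ConstantEvaluator = "fml_constant",
                    ParameterEvaluator = "fml_parameter",
                    PiecewiseEvaluator = "fml_piecewise",
                    AggregateEvaluator = "fml_aggregate",
                    ReferenceEvaluator = "fml_reference")
      shell <- new_fml_object(c(cls, "fml_evaluator"),
                              list(name = req_attr(node, "name")))
      shells[[length(shells) + 1L]] <- list(node = node, shell = shell)
      fml_add(model, shell)
    }
  }

  # ---- pass B: fill fields --------------------------------------------------
  parse_bindings <- function(node) {
    out <- list()
    for (bn in xml2::xml_find_all(node, "./Bindings/Bind")) {
      out[[length(out) + 1L]] <-
        structure(list(argument = resolve(req_attr(bn, "argument"), "argument"),
                       delegate = resolve(req_attr(bn, "source"), "evaluator")),
                  class = "fml_binding")
    }
    out
  }
  for (sh in shells) {
    node <- sh$node; e <- sh$shell
    tag <- xml2::xml_name(node)
    if (tag == "MeshType") {
      shapes <- xml2::xml_find_first(node, "./Shapes")
      shared <- xml2::xml_attr(shapes, "evaluator")
      if (!is.na(shared)) {
        ev <- resolve(shared, "shape evaluator")
        for (m in e$element_ensemble$members) e$shape_map[[as.character(m)]] <- ev
      } else {
        for (s in xml2::xml_find_all(shapes, "./Shape"))
          e$shape_map[[req_attr(s, "element")]] <-
            resolve(req_attr(s, "evaluator"), "shape evaluator")
      }
      next
    }
    e$value_type <- resolve(req_attr(node, "valueType"), "type")
    if (tag == "ArgumentEvaluator" || tag == "ExternalEvaluator") {
      e$arguments <- lapply(xml2::xml_find_all(node, "./Arguments/Argument"),
                            function(a) resolve(req_attr(a, "name"), "argument"))
    } else if (tag == "ConstantEvaluator") {
      e$value_string <- req_attr(node, "value")
    } else if (tag == "ParameterEvaluator") {
      dn <- xml2::xml_find_first(node, "./DenseArrayData")
      if (!inherits(dn, "xml_missing")) {
        e$layout <- "dense"
        e$data_source <- resolve(req_attr(dn, "data"), "data source")
        e$key_source <- NULL
        e$index_arguments <-
          lapply(xml2::xml_find_all(dn, "./DenseIndexes/IndexEvaluator"),
                 function(n) resolve(req_attr(n, "evaluator"), "index evaluator"))
      } else {
        sn <- xml2::xml_find_first(node, "./SparseArrayData")
        e$layout <- "sparse"
        e$key_source <- resolve(req_attr(sn, "keyData"), "data source")
        e$data_source <- resolve(req_attr(sn, "valueData"), "data source")
        e$index_arguments <-
          lapply(xml2::xml_find_all(sn, "./SparseIndexes/IndexEvaluator"),
                 function(n) resolve(req_attr(n, "evaluator"), "index evaluator"))
      }
    } else if (tag == "PiecewiseEvaluator") {
      e$bindings <- parse_bindings(node)
      e$index <- resolve(req_attr(xml2::xml_find_first(node, "./IndexEvaluator"),
                                  "evaluator"), "index evaluator")
      em <- xml2::xml_find_first(node, "./EvaluatorMap")
      dflt <- xml2::xml_attr(em, "default")
      e$default <- if (is.na(dflt)) NULL else resolve(dflt, "evaluator")
      e$branches <- list()
      for (en in xml2::xml_find_all(em, "./EvaluatorMapEntry"))
        e$branches[[req_attr(en, "value")]] <-
          resolve(req_attr(en, "evaluator"), "evaluator")
    } else if (tag == "AggregateEvaluator") {
      e$bindings <- parse_bindings(node)
      cn <- xml2::xml_find_first(node, "./ComponentEvaluators")
      e$component_ensemble <- resolve(req_attr(cn, "ensemble"), "ensemble")
      idx <- xml2::xml_attr(cn, "index")
      e$index_argument <- if (is.na(idx)) NULL else resolve(idx, "argument")
      dflt <- xml2::xml_attr(cn, "default")
      e$delegate <- if (is.na(dflt)) NULL else resolve(dflt, "evaluator")
      e$components <- list()
      for (en in xml2::xml_find_all(cn, "./ComponentEvaluator"))
        e$components[[req_attr(en, "component")]] <-
          resolve(req_attr(en, "evaluator"), "evaluator")
    } else if (tag == "ReferenceEvaluator") {
      e$target <- resolve(req_attr(node, "evaluator"), "evaluator")
      e$bindings <- parse_bindings(node)
      e$value_type <- e$target$value_type
    }
  }

  attr(model, "diagnostics") <- fml_validate(model)
  model
}
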