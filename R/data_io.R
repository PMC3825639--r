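# Data resources and sources: uniform dense-array access over inline text,
# external text files and HDF5 datasets.
#
# Text arrays are whitespace/newline delimited and row-major with the LAST
# declared index varying fastest (each leading-index record is one line, as
# in connectivity matrices where each line lists one element's local nodes).
# HDF5 arrays are stored one dataset per source as native doubles.

#' Declare a data resource
#'
#' A container of raw bulk data: an inline string, an external
#' whitespace-delimited text file, or an HDF5 file.
#'
#' @param name identifier.
#' @param kind `"inline"`, `"text_file"` or `"hdf5"`.
#' @param text inline payload (inline kind).
#' @param path file path (text_file and hdf5 kinds).
#' @return an `fml_data_resource`.
#' @export
fml_data_resource <- function(name, kind = c("inline", "text_file", "hdf5"),
                              text = NULL, path = NULL) {
  check_identifier(name)
  kind <- match.arg(kind)
  if (kind == "inline" && is.null(text))
    fml_stop("fml_definition_error", "resource '%s': inline kind needs text", name)
  if (kind != "inline" && is.null(path))
    fml_stop("fml_definition_error", "resource '%s': kind '%s' needs a path", name, kind)
  new_fml_object("fml_data_resource",
                 list(name = name, kind = kind, text = text, path = path,
                      sources = list()))
}

#' Declare a data source
#'
#' Marks up a dense array of zero or more dimensions inside a resource.  For
#' text resources, `first_record` and `record_count` select the line range
#' holding the array (a record is one line, one leading-index slice per
#' record; a 0-dim source is a single scalar).  For HDF5 resources, `dataset`
#' names the dataset and `offset` an optional 0-based hyperslab origin.
#'
#' @param name identifier (unique within the region).
#' @param resource the `fml_data_resource` container.
#' @param shape integer vector of extents; `integer(0)` for a 0-dim scalar.
#' @param first_record 1-based first line of the array block (text kinds).
#' @param record_count number of lines; defaults to the leading extent.
#' @param dataset HDF5 dataset path.
#' @param offset 0-based hyperslab origin within the HDF5 dataset.
#' @return an `fml_data_source`, registered under its resource.
#' @export
fml_data_source <- function(name, resource, shape, first_record = 1L,
                            record_count = NULL, dataset = NULL, offset = NULL) {
  check_identifier(name)
  stopifnot(inherits(resource, "fml_data_resource"))
  shape <- as.integer(shape)
  if (any(shape < 1L))
    fml_stop("fml_definition_error", "source '%s': extents must be positive", name)
  if (is.null(record_count))
    record_count <- if (length(shape) == 0L) 1L else shape[1L]
  if (resource$kind == "hdf5" && is.null(dataset))
    fml_stop("fml_definition_error", "source '%s': HDF5 source needs a dataset path", name)
  src <- new_fml_object("fml_data_source",
                        list(name = name, resource = resource, shape = shape,
                             first_record = as.integer(first_record),
                             record_count = as.integer(record_count),
                             dataset = dataset, offset = offset))
  resource$sources[[name]] <- src
  src
}

# ---- text rendering ---------------------------------------------------------

render_num <- function(x) {
  # exact round-trip decimal rendering
  sprintf("%.17g", x)
}

# row-major flattening: last index fastest
flatten_row_major <- function(x) {
  if (is.null(dim(x))) return(as.numeric(x))
  as.numeric(aperm(x, rev(seq_along(dim(x)))))
}

unflatten_row_major <- function(vals, shape) {
  if (length(shape) == 0L) return(vals[1L])
  if (length(shape) == 1L) return(array(vals, dim = shape))
  aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
}

#' Render or write an array as whitespace-delimited text
#'
#' Row-major with the last index varying fastest; one line per leading-index
#' record; entries rendered with 17 significant digits so text round-trips
#' reproduce IEEE doubles exactly.
#'
#' @param x numeric scalar, vector or array.
#' @param path optional file to write; when `NULL` the payload string is
#'   returned.
#' @return the payload (invisibly when written to a file).
#' @export
fml_render_text_array <- function(x, path = NULL) {
  shape <- if (is.null(dim(x))) {
    if (length(x) == 1L) integer(0) else length(x)
  } else dim(x)
  vals <- flatten_row_major(x)
  if (length(shape) == 0L) {
    lines <- render_num(vals)
  } else {
    per_rec <- prod(shape[-1L])
    recs <- matrix(vapply(vals, render_num, ""), nrow = per_rec)
    lines <- apply(recs, 2L, paste, collapse = " ")
  }
  payload <- paste(lines, collapse = "\n")
  if (is.null(path)) return(payload)
  writeLines(lines, path)
  invisible(payload)
}

#' Write an array to an HDF5 dataset
#'
#' One dataset per data source, stored as native 64-bit doubles with the same
#' logical index order as the declared shape.
#'
#' @param x numeric scalar, vector or array.
#' @param path HDF5 file (created if absent).
#' @param dataset dataset path within the file.
#' @export
fml_write_hdf5_array <- function(x, path, dataset) {
  if (!file.exists(path)) rhdf5::h5createFile(path)
  storage.mode(x) <- "double"
  rhdf5::h5write(x, path, dataset)
  rhdf5::h5closeAll()
  invisible(path)
}

# ---- reading ----------------------------------------------------------------

read_text_payload <- function(resource) {
  if (resource$kind == "inline") return(resource$text)
  if (!file.exists(resource$path))
    fml_stop("fml_io_error", "resource '%s': file '%s' not found",
             resource$name, resource$path)
  paste(readLines(resource$path, warn = FALSE), collapse = "\n")
}

parse_tokens <- function(lines, source) {
  tokens <- unlist(strsplit(trimws(lines), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (anyNA(vals)) {
    bad <- tokens[which(is.na(vals))[1L]]
    fml_stop("fml_parse_error", "source '%s': non-numeric token '%s'", source$name, bad)
  }
  vals
}

#' Read the dense array addressed by a data source
#'
#' @param source an `fml_data_source`.
#' @return a numeric scalar (0-dim), vector (1-dim) or array of exactly the
#'   declared shape.
#' @export
fml_read_array <- function(source) {
  stopifnot(inherits(source, "fml_data_source"))
  res <- source$resource
  shape <- source$shape
  n_expected <- if (length(shape) == 0L) 1L else prod(shape)
  if (res$kind %in% c("inline", "text_file")) {
    all_lines <- strsplit(read_text_payload(res), "\n", fixed = TRUE)[[1L]]
    last <- source$first_record + source$record_count - 1L
    if (last > length(all_lines))
      fml_stop("fml_shape_error",
               "source '%s': records %d..%d but payload has %d lines",
               source$name, source$first_record, last, length(all_lines))
    vals <- parse_tokens(all_lines[source$first_record:last], source)
    if (length(vals) != n_expected)
      fml_stop("fml_shape_error", "source '%s': %d values for declared shape (%s)",
               source$name, length(vals),
               paste(if (length(shape)) shape else "scalar", collapse = "x"))
    return(unflatten_row_major(vals, shape))
  }
  if (res$kind == "hdf5") {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    if (!file.exists(res$path))
      fml_stop("fml_io_error", "resource '%s': file '%s' not found", res$name, res$path)
    if (is.null(source$offset)) {
      x <- rhdf5::h5read(res$path, source$dataset)
    } else {
      idx <- mapply(function(o, n) seq.int(o + 1L, o + n),
                    as.integer(source$offset), shape, SIMPLIFY = FALSE)
      x <- rhdf5::h5read(res$path, source$dataset, index = idx)
    }
    x <- if (length(shape) == 0L) as.numeric(x)[1L] else {
      storage.mode(x) <- "double"
      array(x, dim = shape)
    }
    if (length(shape) == 1L) x <- array(x, dim = shape)
    n_got <- length(x)
    if (n_got != n_expected)
      fml_stop("fml_shape_error", "source '%s': dataset has %d values, declared %d",
               source$name, n_got, n_expected)
    return(x)
  }
  fml_stop("fml_definition_error", "unknown resource kind '%s'", res$kind)
}

#' Read a hyperslab of a data source
#'
#' Equivalent to [fml_read_array()] followed by slicing, but for HDF5
#' resources the slab is read directly.
#'
#' @param source an `fml_data_source` of rank >= 1.
#' @param offsets 0-based origin per dimension.
#' @param counts extent per dimension.
#' @return numeric array of shape `counts`.
#' @export
fml_read_slab <- function(source, offsets, counts) {
  stopifnot(inherits(source, "fml_data_source"))
  shape <- source$shape
  offsets <- as.integer(offsets); counts <- as.integer(counts)
  if (length(shape) == 0L)
    fml_stop("fml_bounds_error", "source '%s': cannot slab a 0-dim source", source$name)
  if (length(offsets) != length(shape) || length(counts) != length(shape))
    fml_stop("fml_bounds_error", "source '%s': slab rank mismatch", source$name)
  if (any(offsets < 0L) || any(counts < 1L) || any(offsets + counts > shape))
    fml_stop("fml_bounds_error",
             "source '%s': slab [%s]+[%s] out of range for shape (%s)",
             source$name, paste(offsets, collapse = ","),
             paste(counts, collapse = ","), paste(shape, collapse = "x"))
  if (source$resource$kind == "hdf5") {
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    idx <- mapply(function(o, n) seq.int(o + 1L, o + n), offsets, counts,
                  SIMPLIFY = FALSE)
    base <- if (is.null(source$offset)) rep(0L, length(shape)) else as.integer(source$offset)
    idx <- mapply(function(i, b) i + b, idx, base, SIMPLIFY = FALSE)
    x <- rhdf5::h5read(source$resource$path, source$dataset, index = idx)
    storage.mode(x) <- "double"
    return(array(x, dim = counts))
  }
  full <- fml_read_array(source)
  if (length(shape) == 1L) return(array(full[(offsets + 1L):(offsets + counts)], counts))
  idx <- mapply(function(o, n) seq.int(o + 1L, o + n), offsets, counts, SIMPLIFY = FALSE)
  array(do.call(`[`, c(list(full), idx, list(drop = FALSE))), dim = counts)
}

# ---- parameter lookup -------------------------------------------------------

#' Look up a parameter value at an index tuple
#'
#' Dense layout: the position along each index is the member's rank in the
#' ascending member list of that index's ensemble (ensembles need not be
#' contiguous).  Sparse layout: the tuple is matched against the key source's
#' rows; a missing key is a lookup error, not a zero.
#'
#' @param parameter an `fml_parameter` evaluator.
#' @param index_tuple integer vector of member identifiers, one per declared
#'   index, in declaration order.
#' @return the stored scalar (numeric).
#' @export
fml_lookup <- function(parameter, index_tuple) {
  stopifnot(inherits(parameter, "fml_parameter"))
  idx <- as.integer(index_tuple)
  ias <- parameter$index_arguments
  if (length(idx) != length(ias))
    fml_stop("fml_bounds_error", "parameter '%s': %d indices given, %d declared",
             parameter$name, length(idx), length(ias))
  for (k in seq_along(ias)) {
    ens <- ias[[k]]$value_type
    if (!(idx[k] %in% ens$members))
      fml_stop("fml_bounds_error",
               "parameter '%s': %d is not a member of index ensemble '%s'",
               parameter$name, idx[k], ens$name)
  }
  if (parameter$layout == "dense") {
    pos <- vapply(seq_along(ias), function(k) {
      match(idx[k], sort(ias[[k]]$value_type$members))
    }, integer(1L))
    arr <- fml_read_array(parameter$data_source)
    if (length(ias) == 0L) return(as.numeric(arr)[1L])
    if (is.null(dim(arr))) dim(arr) <- length(arr)
    return(arr[matrix(pos, nrow = 1L)])
  }
  keys <- fml_read_array(parameter$key_source)
  vals <- fml_read_array(parameter$data_source)
  if (is.null(dim(keys))) keys <- matrix(keys, ncol = 1L)
  hit <- which(apply(keys, 1L, function(r) all(r == idx)))
  if (length(hit) == 0L)
    fml_stop("fml_lookup_error",
             "parameter '%s': no value stored for index (%s)",
             parameter$name, paste(idx, collapse = ", "))
  as.numeric(vals)[hit[1L]]
}
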