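# VTK legacy ASCII export: per-element tessellation of mesh fields for
# visualization.  Coincident points on shared edges are deliberately not
# merged, so the export never has to make tolerance-based merging decisions.

#' Export mesh fields to a VTK legacy ASCII unstructured grid
#'
#' Tessellates every element of the mesh on a regular
#' `(samples_per_edge + 1)^dim` chart grid, evaluates the geometry field for
#' point positions (2D geometry is padded with z = 0) and each scalar field
#' as a point-data array.
#'
#' @param model the model holding the fields.
#' @param geometry name of the geometry field (value dimension 2 or 3).
#' @param fields character vector of scalar field names to attach as point
#'   data.
#' @param samples_per_edge number of cells along each element edge (>= 1).
#' @param mesh_argument name of the mesh-valued argument evaluator
#'   (default `"mesh.argument"`).
#' @param path optional output file; when `NULL` the VTK text is returned as
#'   a character vector of lines.
#' @return the VTK lines (invisibly when written to a file).
#' @export
fml_export_vtk <- function(model, geometry, fields = character(),
                           samples_per_edge = 1L, mesh_argument = "mesh.argument",
                           path = NULL) {
  samples_per_edge <- as.integer(samples_per_edge)
  if (is.na(samples_per_edge) || samples_per_edge < 1L)
    fml_stop("fml_definition_error", "samples_per_edge must be >= 1")
  geo <- fml_get(model, geometry)
  if (is.null(geo)) fml_stop("fml_definition_error", "no field '%s'", geometry)
  marg <- fml_get(model, mesh_argument)
  if (is.null(marg) || !inherits(marg$value_type, "fml_mesh_type"))
    fml_stop("fml_definition_error", "'%s' is not a mesh-valued argument", mesh_argument)
  mesh <- marg$value_type
  if (mesh$dimension != 2L)
    fml_stop("fml_definition_error", "VTK export supports 2D meshes (got %dD)",
             mesh$dimension)
  gdim <- geo$value_type$dimension
  if (!(gdim %in% c(2L, 3L)))
    fml_stop("fml_definition_error", "geometry field must be 2- or 3-dimensional")
  field_evs <- lapply(fields, function(f) {
    fe <- fml_get(model, f)
    if (is.null(fe)) fml_stop("fml_definition_error", "no field '%s'", f)
    ok <- any(vapply(fml_free_arguments(fe), identical, TRUE, marg))
    if (!ok)
      fml_stop("fml_definition_error",
               "field '%s' is not defined over mesh argument '%s'", f, mesh_argument)
    fe
  })

  n <- samples_per_edge
  grid1 <- seq(0, 1, length.out = n + 1L)
  elements <- sort(mesh$element_ensemble$members)
  pts <- matrix(0, nrow = 0L, ncol = 3L)
  cells <- list()
  fvals <- matrix(0, nrow = 0L, ncol = length(fields))
  for (el in elements) {
    base <- nrow(pts)
    for (j in seq_along(grid1)) for (i in seq_along(grid1)) {
      xi <- c(grid1[i], grid1[j])
      gv <- fml_evaluate_mesh_field(geo, marg, el, xi)$vector
      if (gdim == 2L) gv <- c(gv, 0)
      pts <- rbind(pts, gv)
      if (length(fields))
        fvals <- rbind(fvals, vapply(field_evs, function(fe)
          fml_evaluate_mesh_field(fe, marg, el, xi)$vector[1L], 0))
    }
    for (j in seq_len(n)) for (i in seq_len(n)) {
      p00 <- base + (j - 1L) * (n + 1L) + i - 1L
      cells[[length(cells) + 1L]] <-
        c(p00, p00 + 1L, p00 + n + 2L, p00 + n + 1L)  # VTK_QUAD, ccw
    }
  }

  lines <- c("# vtk DataFile Version 3.0",
             "fieldmlr export", "ASCII", "DATASET UNSTRUCTURED_GRID",
             sprintf("POINTS %d double", nrow(pts)),
             apply(pts, 1L, function(p) paste(sprintf("%.17g", p), collapse = " ")),
             sprintf("CELLS %d %d", length(cells), 5L * length(cells)),
             vapply(cells, function(cl) paste(c(4L, cl), collapse = " "), ""),
             sprintf("CELL_TYPES %d", length(cells)),
             rep("9", length(cells)))
  if (length(fields)) {
    lines <- c(lines, sprintf("POINT_DATA %d", nrow(pts)))
    for (k in seq_along(fields)) {
      lines <- c(lines,
                 sprintf("SCALARS %s double 1", fields[k]),
                 "LOOKUP_TABLE default",
                 sprintf("%.17g", fvals[, k]))
    }
  }
  lines <- unname(lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
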