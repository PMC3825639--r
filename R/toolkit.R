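# Model and fixture generators: the two-element illustrative example, the
# square-grid connectivity matrix, and a multi-subject HDF5 geometry model.

#' Build the two-element illustrative example model
#'
#' Constructs a complete, evaluable model of a 2D mesh with two unit-square
#' quadrilateral elements sharing an edge (6 global nodes, nodes 2 and 5
#' shared), together with the manifest of counts and closed-form spot values
#' used by the test-suite:
#' \itemize{
#'   \item a *shared field template*: the element ensemble, per-element unit
#'     square shapes, the local-to-global node map as an ensemble-valued
#'     parameter evaluator, and a piecewise evaluator delegating each element
#'     to bilinear Lagrange interpolation of a yet-unbound nodal-value
#'     function;
#'   \item a scalar *pressure* field: a reference evaluator binding the
#'     pressure degrees of freedom to the template;
#'   \item a 3-component *geometry* field: an aggregate evaluator binding the
#'     nodal coordinate table componentwise.
#' }
#' All library objects are imported from [fml_library()].
#'
#' @param pressure_dofs numeric vector of 6 nodal pressure values.
#' @param coords 6 x 3 matrix of nodal coordinates; defaults to the flat
#'   2 x 1 arrangement with z = 0.
#' @return list with elements `model`, `manifest`, and the argument
#'   evaluators `mesh_argument`, `nodes_argument`.
#' @export
fml_illustrative_example <- function(
    pressure_dofs = c(0.1, 0.5, 55.9, 80, 35, 100),
    coords = cbind(x = c(0, 1, 2, 0, 1, 2), y = c(0, 0, 0, 1, 1, 1), z = 0)) {
  stopifnot(length(pressure_dofs) == 6L, all(dim(coords) == c(6L, 3L)))
  lib <- fml_library()
  m <- fml_model("two_square_example")
  for (nm in c("real.1d", "chart.2d", "coordinates.rc.3d",
               "localNodes.2d.square2x2", "parameters.2d.unit.bilinearLagrange",
               "interpolator.2d.unit.bilinearLagrange", "shape.unit.square",
               "chart.2d.argument", "localNodes.2d.square2x2.argument",
               "parameters.2d.unit.bilinearLagrange.argument",
               "coordinates.rc.3d.component.argument"))
    fml_import(m, lib, nm)

  real1 <- fml_get(m, "real.1d")
  connectivity <- matrix(c(1L, 2L, 4L, 5L,
                           2L, 3L, 5L, 6L), nrow = 2L, byrow = TRUE)

  nodes <- fml_ensemble_type("nodes", 1:6)
  nodes_arg <- fml_argument("nodes.argument", nodes)
  mesh <- fml_mesh_type("mesh", 2L, 1:2, fml_get(m, "shape.unit.square"),
                        chart_type = fml_get(m, "chart.2d"))
  mesh_arg <- fml_argument("mesh.argument", mesh)
  fml_add(m, nodes, mesh, nodes_arg, mesh_arg)

  conn_res <- fml_data_resource("connectivity.resource", "inline",
                                text = fml_render_text_array(connectivity))
  conn_src <- fml_data_source("connectivity.data", conn_res, c(2L, 4L))
  p_res <- fml_data_resource("pressure.resource", "inline",
                             text = fml_render_text_array(pressure_dofs))
  p_src <- fml_data_source("pressure.data", p_res, 6L)
  g_res <- fml_data_resource("geometry.resource", "inline",
                             text = fml_render_text_array(unname(as.matrix(coords))))
  g_src <- fml_data_source("geometry.data", g_res, c(6L, 3L))
  fml_add(m, conn_res, p_res, g_res)

  conn <- fml_parameter("connectivity", nodes,
                        list(fml_mesh_accessor(mesh_arg, "elements"),
                             fml_get(m, "localNodes.2d.square2x2.argument")),
                        conn_src)
  p_dofs <- fml_parameter("pressure.dofs", real1, list(nodes_arg), p_src)
  g_dofs <- fml_parameter("geometry.dofs", real1,
                          list(nodes_arg,
                               fml_get(m, "coordinates.rc.3d.component.argument")),
                          g_src)
  fml_add(m, conn, p_dofs, g_dofs)

  # the shared template: nodal values enter through a function-valued
  # argument, so the same pipeline serves pressure and each geometry
  # component
  nodal_arg <- fml_argument("nodal.dofs.argument", real1, list(nodes_arg))
  template_dofs <- fml_reference("template.dofs", nodal_arg,
                                 list(fml_bind(nodes_arg, conn)))
  elem_params <- fml_aggregate(
    "element.parameters", fml_get(m, "parameters.2d.unit.bilinearLagrange"),
    delegate = template_dofs,
    index_argument = fml_get(m, "localNodes.2d.square2x2.argument"))
  interp_ref <- fml_reference(
    "template.interpolation", fml_get(m, "interpolator.2d.unit.bilinearLagrange"),
    list(fml_bind(fml_get(m, "chart.2d.argument"), fml_mesh_accessor(mesh_arg, "xi")),
         fml_bind(fml_get(m, "parameters.2d.unit.bilinearLagrange.argument"),
                  elem_params)))
  template <- fml_piecewise("template", real1,
                            fml_mesh_accessor(mesh_arg, "elements"),
                            branches = list("1" = interp_ref, "2" = interp_ref))
  fml_add(m, nodal_arg, template_dofs, elem_params, interp_ref, template)

  pressure <- fml_reference("pressure", template,
                            list(fml_bind(nodal_arg, p_dofs)))
  geometry_tpl <- fml_reference("geometry.template", template,
                                list(fml_bind(nodal_arg, g_dofs)))
  geometry <- fml_aggregate(
    "geometry", fml_get(m, "coordinates.rc.3d"),
    delegate = geometry_tpl,
    index_argument = fml_get(m, "coordinates.rc.3d.component.argument"))
  fml_add(m, pressure, geometry_tpl, geometry)

  manifest <- list(
    model = "two_square_example",
    counts = list(types = length(m$types), evaluators = length(m$evaluators),
                  data_resources = length(m$data_resources),
                  imports = length(m$imports)),
    connectivity = connectivity,
    pressure_dofs = pressure_dofs,
    coords = unname(as.matrix(coords)),
    # closed-form spot checks (bilinear: corners reproduce nodal values,
    # the element center averages the four corner values)
    corner_pressure = apply(connectivity, 1L, function(r) pressure_dofs[r]),
    center_pressure = apply(connectivity, 1L, function(r) mean(pressure_dofs[r])))

  list(model = m, manifest = manifest,
       mesh_argument = mesh_arg, nodes_argument = nodes_arg)
}

#' Square-grid element connectivity matrix
#'
#' Builds the classic local-to-global node map of a strip of square elements
#' on a 10-wide node grid: row `e` is `[e, e+1, e+10, e+11]`, one column per
#' local node.
#'
#' @param n_elements number of elements (rows), >= 1.
#' @return an `fml_data_source` of shape `n_elements x 4` over an inline
#'   resource.
#' @export
fml_grid_connectivity <- function(n_elements) {
  n_elements <- as.integer(n_elements)
  if (is.na(n_elements) || n_elements < 1L)
    fml_stop("fml_definition_error", "n_elements must be >= 1")
  e <- seq_len(n_elements)
  mat <- cbind(e, e + 1L, e + 10L, e + 11L)
  res <- fml_data_resource("grid.connectivity.resource", "inline",
                           text = fml_render_text_array(unname(mat)))
  fml_data_source("grid.connectivity.data", res, c(n_elements, 4L))
}

#' Multi-subject geometry model over a single HDF5 resource
#'
#' Emulates, at toy scale, capturing the anatomy of several subjects within
#' one data source: one HDF5 dataset of shape
#' `n_subjects x nodes_per_subject x 3` feeds per-subject 3-component
#' geometry fields through a subject ensemble.  Coordinates are synthetic
#' (seeded uniform perturbations of a common template), so the structure —
#' not any particular anatomy — is what the model represents.
#'
#' @param n_subjects number of subjects, >= 1.
#' @param nodes_per_subject nodes per subject.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param path HDF5 file to create (overwritten).
#' @return list with `model`, the coordinate array `coords`, `path`, and the
#'   per-subject field names `fields`.
#' @export
fml_multisubject_hdf5 <- function(n_subjects = 5L, nodes_per_subject = 6L,
                                  seed = 1L,
                                  path = tempfile(fileext = ".h5")) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 1L, nodes_per_subject >= 1L)
  set.seed(seed)
  template <- cbind(runif(nodes_per_subject), runif(nodes_per_subject),
                    runif(nodes_per_subject))
  coords <- array(0, dim = c(n_subjects, nodes_per_subject, 3L))
  for (s in seq_len(n_subjects))
    coords[s, , ] <- template + matrix(runif(nodes_per_subject * 3L, -0.05, 0.05),
                                       ncol = 3L)
  if (file.exists(path)) file.remove(path)
  fml_write_hdf5_array(coords, path, "geometry")

  lib <- fml_library()
  m <- fml_model("multisubject")
  for (nm in c("real.1d", "coordinates.rc.3d", "coordinates.rc.3d.component.argument"))
    fml_import(m, lib, nm)
  subjects <- fml_ensemble_type("subjects", seq_len(n_subjects))
  nodes <- fml_ensemble_type("nodes", seq_len(nodes_per_subject))
  subj_arg <- fml_argument("subjects.argument", subjects)
  nodes_arg <- fml_argument("nodes.argument", nodes)
  fml_add(m, subjects, nodes, subj_arg, nodes_arg)

  res <- fml_data_resource("geometry.resource", "hdf5", path = path)
  src <- fml_data_source("geometry.data", res,
                         c(n_subjects, nodes_per_subject, 3L), dataset = "geometry")
  fml_add(m, res)
  params <- fml_parameter("geometry.params", fml_get(m, "real.1d"),
                          list(subj_arg, nodes_arg,
                               fml_get(m, "coordinates.rc.3d.component.argument")),
                          src)
  fml_add(m, params)
  fields <- character(n_subjects)
  for (s in seq_len(n_subjects)) {
    const <- fml_constant(sprintf("subject.%d", s), subjects, as.character(s))
    agg <- fml_aggregate(sprintf("geometry.subject%d", s),
                         fml_get(m, "coordinates.rc.3d"),
                         delegate = fml_reference(
                           sprintf("geometry.subject%d.params", s), params,
                           list(fml_bind(subj_arg, const))),
                         index_argument = fml_get(m, "coordinates.rc.3d.component.argument"))
    fml_add(m, const, agg$delegate, agg)
    fields[s] <- agg$name
  }
  list(model = m, coords = coords, path = path, fields = fields,
       nodes_argument = nodes_arg)
}
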