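# Test helpers: an independent binding-substitution oracle, seeded random
# pipeline and model generators, and small fixture builders.

# ---- substitution oracle ----------------------------------------------------
# Inlines bindings by structural term substitution: a bound argument's
# occurrences are replaced by a copy of the delegate built under the *outer*
# mapping (capture-avoiding, so inner re-bindings shadow outer ones).  The
# resulting pipeline has no bindings and is evaluated plainly — a path fully
# independent of the engine's environment-frame mechanics.
oracle_inline <- function(e, mapping = list()) {
  if (inherits(e, "fml_argument")) {
    sub <- mapping[[e$name]]
    return(if (is.null(sub)) e else sub)
  }
  if (inherits(e, "fml_constant") || inherits(e, "fml_external") ||
      inherits(e, "fml_parameter") || inherits(e, "fml_mesh_accessor"))
    return(e)
  if (inherits(e, "fml_piecewise")) {
    m2 <- mapping
    for (b in e$bindings) m2[[b$argument$name]] <- oracle_inline(b$delegate, mapping)
    branches <- lapply(e$branches, oracle_inline, mapping = m2)
    return(fml_piecewise(paste0(e$name, ".inl"), e$value_type,
                         oracle_inline(e$index, m2), branches,
                         default = if (!is.null(e$default))
                           oracle_inline(e$default, m2)))
  }
  if (inherits(e, "fml_reference")) {
    m2 <- mapping
    for (b in e$bindings) m2[[b$argument$name]] <- oracle_inline(b$delegate, mapping)
    return(oracle_inline(e$target, m2))
  }
  if (inherits(e, "fml_aggregate")) {
    m2 <- mapping
    for (b in e$bindings) m2[[b$argument$name]] <- oracle_inline(b$delegate, mapping)
    comps <- lapply(e$components, oracle_inline, mapping = m2)
    return(fml_aggregate(paste0(e$name, ".inl"), e$value_type, comps,
                         delegate = if (!is.null(e$delegate))
                           oracle_inline(e$delegate, m2),
                         index_argument = e$index_argument,
                         component_ensemble = e$component_ensemble))
  }
  e
}

# ---- random scalar pipelines ------------------------------------------------
# Pipelines over a scalar real type and a 3-member ensemble index: constants,
# plain arguments x/y, piecewise over n, references with random bindings.
make_pipeline_world <- function() {
  r <- fml_continuous_type("oracle.real")
  E <- fml_ensemble_type("oracle.index", 1:3)
  list(r = r, E = E,
       x = fml_argument("x", r), y = fml_argument("y", r),
       n = fml_argument("n", E))
}

random_pipeline <- function(world, depth, counter = new.env()) {
  if (is.null(counter$i)) counter$i <- 0L
  nm <- function(p) { counter$i <- counter$i + 1L; sprintf("%s.%d", p, counter$i) }
  leaf <- function() {
    if (runif(1) < 0.5) fml_constant(nm("c"), world$r, round(runif(1, -50, 50), 3))
    else if (runif(1) < 0.5) world$x else world$y
  }
  if (depth == 0L) return(leaf())
  roll <- runif(1)
  if (roll < 0.4) {
    branches <- list("1" = random_pipeline(world, depth - 1L, counter),
                     "2" = random_pipeline(world, depth - 1L, counter))
    dflt <- if (runif(1) < 0.7) random_pipeline(world, depth - 1L, counter)
    if (is.null(dflt)) branches[["3"]] <- random_pipeline(world, depth - 1L, counter)
    fml_piecewise(nm("pw"), world$r, world$n, branches, default = dflt)
  } else if (roll < 0.85) {
    target <- random_pipeline(world, depth - 1L, counter)
    free <- fml_free_arguments(target)
    free <- Filter(function(a) a$name %in% c("x", "y"), free)
    bindings <- list()
    for (a in free) {
      if (runif(1) < 0.6)
        bindings[[length(bindings) + 1L]] <-
          fml_bind(a, random_pipeline(world, max(depth - 2L, 0L), counter))
    }
    fml_reference(nm("ref"), target, bindings)
  } else {
    leaf()
  }
}

# ---- random serializable models --------------------------------------------
# Small valid regions exercising every serializable object kind with inline
# data, used for round-trip isomorphism.
random_model <- function(seed) {
  set.seed(seed)
  m <- fml_model(sprintf("random.%d", seed))
  r <- fml_continuous_type("real")
  nmem <- sample(2:5, 1L)
  members <- sort(sample(0:40, nmem))
  E <- fml_ensemble_type("idx", members)
  vec <- fml_continuous_type("vec", sample(2:3, 1L))
  fml_add(m, r, E, vec)
  n <- fml_argument("n", E)
  x <- fml_argument("x", r)
  fml_add(m, n, x)

  vals <- round(runif(nmem, -10, 10), 4)
  res <- fml_data_resource("res", "inline", text = fml_render_text_array(vals))
  src <- fml_data_source("vals", res, nmem)
  fml_add(m, res)
  par <- fml_parameter("par", r, list(n), src)
  fml_add(m, par)

  consts <- lapply(seq_len(3), function(i)
    fml_constant(sprintf("k%d", i), r, round(runif(1, -5, 5), 4)))
  do.call(fml_add, c(list(m), consts))

  branch_members <- sample(members, min(2L, nmem))
  branches <- stats::setNames(
    lapply(branch_members, function(mm) consts[[sample(3, 1L)]]),
    as.character(branch_members))
  pw <- fml_piecewise("pw", r, n, branches, default = par)
  fml_add(m, pw)

  depth <- sample(1:4, 1L)
  cur <- pw
  for (d in seq_len(depth)) {
    bindings <- if (runif(1) < 0.5) list(fml_bind(x, consts[[sample(3, 1L)]])) else list()
    bindings <- Filter(function(b) {
      any(vapply(fml_free_arguments(cur), identical, TRUE, b$argument))
    }, bindings)
    cur <- fml_reference(sprintf("ref%d", d), cur, bindings)
    fml_add(m, cur)
  }

  comp_members <- sort(vec$component_ensemble$members)
  agg <- fml_aggregate("agg", vec,
                       stats::setNames(lapply(comp_members, function(i)
                         consts[[sample(3, 1L)]]), as.character(comp_members)))
  fml_add(m, agg)
  m
}

# the worked piecewise/binding fixture: g(n) = 7.1 | 100 | x, f = g with x = k1
make_g_fixture <- function() {
  r <- fml_continuous_type("real")
  E <- fml_ensemble_type("n.ensemble", 1:3)
  n <- fml_argument("n", E)
  x <- fml_argument("x", r)
  g <- fml_piecewise("g", r, n, list(
    "1" = fml_constant("c7.1", r, "7.1"),
    "2" = fml_constant("c100", r, "100"),
    "3" = x))
  k1 <- fml_constant("k1", r, "0.331")
  f <- fml_reference("f", g, list(fml_bind(x, k1)))
  list(r = r, E = E, n = n, x = x, g = g, k1 = k1, f = f)
}

# the node-coordinate parameter fixture: nodes 1..4 -> corners of the unit
# square, stored densely as a 4 x 2 inline array
make_node_coordinates <- function() {
  r <- fml_continuous_type("real")
  nodes <- fml_ensemble_type("nodes", 1:4)
  comp <- fml_ensemble_type("coords.component", 1:2)
  narg <- fml_argument("node", nodes)
  carg <- fml_argument("component", comp)
  coords <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2L, byrow = TRUE)
  res <- fml_data_resource("coords.res", "inline",
                           text = fml_render_text_array(coords))
  src <- fml_data_source("coords", res, c(4L, 2L))
  param <- fml_parameter("node.coordinates", r, list(narg, carg), src)
  list(param = param, narg = narg, carg = carg, coords = coords)
}
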