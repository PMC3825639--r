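---
title: "The FieldML 0.5 data model in fieldmlr: evaluators, typing, and numeric evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The FieldML 0.5 data model in fieldmlr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldmlr)
```

## The model

FieldML 0.5 describes a *field* — a function from a domain, typically a
finite-element mesh, to a value space — declaratively, as a pipeline of
composable **evaluators** over strongly typed **domains**, with bulk numeric
data ("heavy data": nodal values, connectivity) segregated from the
structural markup ("light data") into separate text or HDF5 resources.

There are four domain-type kinds:

* **ensembles** — finite discrete sets whose members carry unique
  non-negative integer identifiers (node numbers, element numbers,
  component indices).  Members are conceptually unordered; an ascending
  order is imposed only to serialize data indexed by the ensemble.
* **Booleans** — the two-valued type.  The language has no Boolean
  operators; Boolean evaluators exist solely as element-shape predicates,
  true on the closed reference shape and false outside.
* **continuous types** — n-dimensional real spaces; for n > 1 an implicit
  component ensemble indexes the vector components.
* **mesh types** — an element ensemble coupled with a chart (local
  coordinate) continuous type of the mesh dimension, plus a shape predicate
  per element.  All elements of a mesh share its dimension.  Connectivity is
  *not* part of the mesh type; it enters as ordinary parameter data.

Seven evaluator kinds form the pipeline algebra: **argument** (a named
input; function-valued arguments additionally declare the arguments they
consume), **constant** (a scalar with a string rendering), **parameter**
(lookup into stored data through ensemble-valued indices, dense or sparse),
**piecewise** (discrete index selects a branch; the usual final step of a
mesh field, indexed by element), **aggregate** (assembles a vector
componentwise in ascending component-member order), **reference** (aliases a
target, optionally *binding* upstream arguments to delegates), and
**external** (semantics by convention, keyed by name — the extension
mechanism through which all interpolators and shapes are supplied).

## Strong typing

Typing is *nominal*: two types are compatible exactly when they are the same
resolved type object.  Ensembles `B = {1,2,3}` and `C = {1,2,3}` are
incompatible despite equal members; composing `g: C -> D` after `f: A -> B`
is rejected, and becomes admissible only through an explicit converter field
`h: B -> C`.  `fieldmlr` realises this directly: every type and evaluator is
a reference object (an R environment), `fml_type_compatible()` is object
identity, and an imported object *is* its source-region object, so imports
never break compatibility.  A consequence worth knowing: re-declaring a
structurally identical type — even with the same name, even by re-parsing
the same document — yields a distinct, incompatible type.  That is the
intended semantics, not an accident.

A mesh's chart type may either be implicit (`<mesh>.xi`) or be a shared
continuous type such as the library's `chart.2d`.  Passing
`chart_type = chart.2d` to `fml_mesh_type()` is what makes the idiomatic
binding of the library's chart argument to the mesh's xi accessor nominally
well-typed; with an implicit chart the same binding would be a type error.

## Binding semantics

A binding substitutes a delegate evaluator for an upstream argument — term
substitution, not assignment.  `fieldmlr` implements this with lexical
closures: each delegate captures the environment at its binding site, and
inner re-bindings shadow outer ones, so the engine agrees *exactly* (to the
last bit) with an independent oracle that inlines bindings by structural
substitution and then evaluates plainly.  The test-suite checks this
equivalence on 200 seeded random pipelines of depth up to 4.

Function-valued arguments are the one refinement: the delegate of a
function-valued argument is applied *at the operand site*, meaning the
argument's declared dependencies (its operands) are taken from the
environment where the argument occurs.  This is what makes the shared field
template work: one piecewise/interpolation pipeline with an unbound nodal
value function serves both the scalar pressure field (one reference binding
the pressure DOF table) and the 3-component geometry field (an aggregate
binding the coordinate table, one component at a time).

Evaluation is eager and depth-first with no caching; identical inputs give
identical values.  A delegate is re-evaluated at every occurrence — an
intentional correctness-first choice at the model sizes in scope
(memoisation would be observationally invisible and can be added later).

## Data access

Text arrays (inline or external files) are whitespace-delimited and
row-major with the **last** declared index varying fastest, one line per
leading-index record — so a connectivity matrix reads exactly as printed,
one element per line.  Values are rendered with `%.17g` so a text round-trip
reproduces IEEE doubles bit-exactly.  HDF5 arrays are stored one dataset per
source as native 64-bit doubles (exact for any ensemble member below 2^53;
a distinct integer storage class would buy nothing here).  Dense parameter
layout addresses the array by each member's rank in the ascending member
list of its ensemble, so ensembles need not be contiguous.  Sparse layout
pairs a key source (one column per index) with an aligned value source;
a missing key is a lookup **error** — the format defines no default fill,
and silently returning zero would mask connectivity bugs.

## The standard library

`fml_library()` re-creates the FieldML 0.5 standard library as an ordinary
region: chart and Cartesian coordinate types for 1D/2D/3D with their
component ensembles and argument evaluators; local-node ensembles per basis;
external declarations for linear and quadratic Lagrange tensor-product
bases (1D/2D/3D), linear simplex bases (triangle, tetrahedron), and the unit
line/square/cube/triangle/tetrahedron shape predicates.  Every declared
external has a registered implementation, so models importing the library
are executable, not merely well-formed.  Conventions fixed here:

* **Local-node ordering**: xi1 varies fastest, then xi2, then xi3, node 1 at
  the origin — the bilinear nodes sit at (0,0), (1,0), (0,1), (1,1),
  matching the classic node-coordinate table.
* **Quadratic bases** use equally spaced nodes on [0, 1]; simplex bases are
  barycentric-linear.
* Shape predicates are closed-set memberships evaluated with an absolute
  slack of 1e-12, so boundary points (e.g. (1,1) on the unit square) are
  inside, and accumulated rounding in chart arithmetic cannot eject a
  corner.
* Evaluating an interpolator outside its reference shape is a domain error
  by default (`allow_extrapolation` overrides); silent extrapolation hides
  connectivity mistakes.

The library is emitted as a byte-stable XML document and serves as its own
serialization fixture.  Its import href resolves to the in-memory singleton,
never the network, so two models importing it share its type objects and
remain mutually compatible.

## Serialization

Documents are UTF-8 XML, version attribute `0.5`, one region per document,
with xlink hrefs for imports and external resources.  The authoritative
element vocabulary of this implementation is the one its writer emits
(`Region`, `EnsembleType`/`MemberRange`/`MemberList`, `ContinuousType`,
`MeshType`/`Elements`/`Chart`/`Shapes`, `DataResource`/`ArrayDataSource`,
the seven `*Evaluator` elements, `Bindings/Bind`, `Import`); the parser
reads exactly this dialect.  Implicit constituents — component ensembles,
`<mesh>.elements`, `<mesh>.xi`, and mesh-argument accessors
`<argument>.elements` / `<argument>.xi` — are referenced by dotted names and
never serialized as elements.

The writer is deterministic: objects are emitted grouped by kind, each group
in declaration order; ensembles serialize as contiguous ranges where
possible, else ascending member lists.  Equal models therefore produce
byte-identical documents, and `parse(write(m))` is isomorphic to `m` — the
property is exercised on the example model, the library, and 100 seeded
random models per run.  Parsing is lenient by default (unknown elements are
skipped with a warning, for forward compatibility); strict mode rejects
them.  Unknown *external evaluators* are never an error at parse or write
time — they round-trip untouched and fail only if evaluated.

## The illustrative example and generators

`fml_illustrative_example()` builds the canonical two-element model: a 2D
mesh of two unit-square elements sharing an edge, 6 global nodes, bilinear
interpolation, a scalar pressure field and a 3-component geometry field
sharing one template.  The published listing of this example is not
available to this implementation, so the DOF tables are the package's own
fixed choice: pressure `(0.1, 0.5, 55.9, 80, 35, 100)` over a flat
2 x 1 node layout with z = 0, chosen once to be visibly asymmetric (so
transposed connectivity or swapped node ordering cannot cancel out).  The
generator writes a manifest whose spot values are computed from closed
forms — corner reproduction and the center-equals-mean property of the
bilinear basis — not typed by hand.

`fml_grid_connectivity()` reproduces the square-strip connectivity pattern
(`row e = [e, e+1, e+10, e+11]`).  `fml_multisubject_hdf5()` emulates, at
toy scale, several subjects' geometry captured in a single HDF5 dataset
indexed by a subject ensemble; coordinates are seeded uniform perturbations
of a common template and are synthetic — the model's structure, not any
anatomy, is the point.  Generation is deterministic per seed, to the byte
for the HDF5 file.

`fml_export_vtk()` writes legacy ASCII unstructured grids, tessellating each
element independently without merging coincident points: merging would need
a tolerance, and the un-merged export doubles as a continuity check (shared
edge points from both sides must coincide to within 1e-12).

## What the tests do and do not show

All fixtures are generated in code at test time; the corpora are seeded and
small (models with tens of objects, meshes with two elements, 100 random
documents, 200 random pipelines, 1000 quadrature points per basis).  Those
sizes exercise every semantic rule — nominal typing, binding scope, dense
rank arithmetic over non-contiguous ensembles, text/HDF5 equivalence — but
say nothing about I/O throughput on models with hundreds of thousands of
nodes, about parallel HDF5 access, or about real anatomical data; the
published large-vessel and multi-subject ventricle models are external data
and are not reproduced here.  Numeric comparisons use absolute tolerance
1e-12 unless a property is exact by construction, in which case tests assert
bit-identity.

Known limitations, by design: no Boolean operators, no domain subsetting, no
topological or differential structure, no implicit fields or PDE systems, no
algebraic (MathML) basis definitions, no Hermite bases, and curvilinear
coordinates only at declaration level — all outside the 0.5 feature set this
package implements.  The command-line tool takes its configuration from
flags alone; with five subcommands and a handful of options, a config-file
layer would add surface without value.

## A worked evaluation

```{r example}
ex <- fml_illustrative_example()
p <- fml_get(ex$model, "pressure")

# corner of element 1 = DOF of global node 1
fml_evaluate_mesh_field(p, ex$mesh_argument, 1, c(0, 0))$vector

# element-2 center = mean of its four nodal DOFs
fml_evaluate_mesh_field(p, ex$mesh_argument, 2, c(0.5, 0.5))$vector
mean(ex$manifest$pressure_dofs[c(2, 3, 5, 6)])

# the geometry field assembles a 3-vector
fml_evaluate_mesh_field(fml_get(ex$model, "geometry"),
                        ex$mesh_argument, 2, c(1, 1))$vector
```
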