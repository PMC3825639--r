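# fieldmlr

Read, write and **numerically evaluate** FieldML 0.5 field descriptions in R.

FieldML 0.5 is a declarative XML language for exchanging mathematical
fields over domains — most prominently finite-element meshes — between
physiological and anatomical modelling tools. A field is expressed as a
pipeline of composable *evaluators* over strongly typed *domains*
(ensembles, Booleans, continuous spaces, meshes), while bulk numeric data
(nodal values, connectivity) lives in separate whitespace-text or HDF5
resources marked up as dense array *sources*. The format's own API is
serialization-only; every consumer must supply its own numerics. This
package is for people who want both halves in R: a faithful object model
with the format's nominal typing rules, and an engine that makes every
declared field computable.

The core semantics, in the field's notation: a mesh field is the piecewise
composition

```
f(e, ξ) = Σ_i φ_i(ξ) · d(M(e, i))        ξ ∈ element chart,
```

where `M(e, i)` is the local-to-global node map (a parameter evaluator over
the element and local-node ensembles), `d(n)` the nodal degrees of freedom
(a parameter evaluator over the node ensemble), and `φ_i` the basis
functions of an interpolator external — linear/quadratic Lagrange tensor
products on [0,1]^d or barycentric-linear simplex bases, with local node 1
at the origin and ξ1 varying fastest. Bindings are term substitutions:
`f(n) = g(n) such that x = k1` overrides the upstream argument `x` with the
delegate `k1` throughout `g`'s subtree, with inner re-bindings shadowing
outer ones, and function-valued arguments applied at the operand site.
Typing is nominal: ensembles `B = {1,2,3}` and `C = {1,2,3}` are
incompatible, so `g∘f` with `f: A→B`, `g: C→D` is rejected unless routed
through an explicit converter `h: B→C`.

What's inside:

* **Object model & validation** — the four domain-type kinds, the seven
  evaluator kinds, bindings, regions; `fml_validate()` returns diagnostics
  (reference resolution, acyclicity, type checks) instead of throwing.
* **Data access** — one interface over inline text, text files and HDF5
  (`fml_read_array`, `fml_read_slab`, `fml_lookup`) with dense and sparse
  parameter layouts; text rendering is `%.17g`, so round-trips are
  bit-exact.
* **XML serialization** — deterministic writer (equal models ⇒ byte-identical
  documents), two-pass parser, xlink imports with cycle detection; the
  standard library import resolves to a bundled in-memory region, never the
  network.
* **Standard library** — re-created in code and *executable*: every declared
  interpolator and shape-predicate external has a registered
  implementation.
* **Evaluation engine** — `fml_evaluate()` / `fml_evaluate_mesh_field()`,
  eager, pure, closure-based binding semantics verified against an
  independent substitution oracle.
* **Toolkit** — the two-element illustrative example with manifest, grid
  connectivity and multi-subject HDF5 generators, VTK legacy ASCII export,
  and a `fieldml` CLI (`validate`, `info`, `eval`, `export-vtk`,
  `make-example`).

## A worked example

```r
library(fieldmlr)

ex <- fml_illustrative_example()     # two quads sharing an edge, 6 nodes
fml_validate(ex$model)               # zero-row data frame: valid

p <- fml_get(ex$model, "pressure")
fml_evaluate_mesh_field(p, ex$mesh_argument, 1, c(0, 0))$vector
#> [1] 0.1
fml_evaluate_mesh_field(p, ex$mesh_argument, 2, c(0.5, 0.5))$vector
#> [1] 47.85
fml_evaluate_mesh_field(fml_get(ex$model, "geometry"),
                        ex$mesh_argument, 2, c(1, 1))$vector
#> [1] 2 1 0
```

`0.1` is the pressure DOF of global node 1, reproduced exactly at the
element corner (Lagrange delta property); `47.85` is the mean of element
2's four nodal DOFs `(0.5, 55.9, 35, 100)`, which is what bilinear
interpolation gives at the element center; `(2, 1, 0)` is the position of
global node 6, the far corner of the second element in the flat 2 × 1 node
layout.

The same model round-trips through XML:

```r
m2 <- fml_parse_xml(fml_write_xml(ex$model))
fml_isomorphic(ex$model, m2)
#> [1] TRUE
```

And from the shell:

```sh
exec/fieldml make-example --out /tmp/ex
exec/fieldml validate /tmp/ex/two_square_example.xml
#> /tmp/ex/two_square_example.xml: valid (region 'two_square_example')
exec/fieldml eval /tmp/ex/two_square_example.xml \
    --evaluator pressure --set mesh.argument=1,0.5,0.5
#> 28.899999999999999
```

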