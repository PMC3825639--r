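Package: fieldmlr
Title: Read, Write and Evaluate FieldML 0.5 Field Descriptions
Version: 0.5.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for the FieldML 0.5 declarative language for
    representing mathematical fields over domains such as finite-element
    meshes. Provides the typed object model (ensemble, Boolean, continuous
    and mesh domain types; the seven evaluator kinds forming composable
    pipelines), strong nominal typing with composition checking, XML
    serialization with cross-document imports, uniform array access over
    inline text, external text files and HDF5 datasets with dense and
    sparse parameter layouts, a re-creation of the FieldML 0.5 standard
    library of interpolation bases and element-shape predicates with
    executable implementations, a numeric evaluation engine that makes
    every declared field computable, model and fixture generators, and
    VTK export for visualization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    rhdf5,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
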