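# Strong nominal typing and composition checking.

#' Nominal type compatibility
#'
#' FieldML is strongly typed with *nominal* typing: two types are compatible
#' exactly when they are the same resolved type object.  Independently
#' declared ensembles with identical member sets are incompatible; an
#' imported type and its source definition are the same object and therefore
#' compatible.
#'
#' @param expected,actual resolved domain types.
#' @return `TRUE` or `FALSE`.
#' @examples
#' B <- fml_ensemble_type("B", 1:3)
#' C <- fml_ensemble_type("C", 1:3)
#' fml_type_compatible(B, B)  # TRUE
#' fml_type_compatible(B, C)  # FALSE: same members, distinct types
#' @export
fml_type_compatible <- function(expected, actual) {
  stopifnot(inherits(expected, "fml_domain_type"), inherits(actual, "fml_domain_type"))
  identical(expected, actual)
}

#' Check whether two evaluators can be composed
#'
#' `outer` must expose exactly one free argument; composition `outer o inner`
#' is admissible iff `inner`'s value type is nominally compatible with that
#' argument's type.  Composing across identically-membered but distinct
#' ensembles is rejected; routing through an explicit converter evaluator
#' (an ensemble-to-ensemble mapping field) makes the chain admissible.
#'
#' @param outer evaluator with exactly one free argument.
#' @param inner evaluator supplying that argument.
#' @return an object of class `fml_verdict`: list with elements `ok`
#'   (logical), `argument`, and `message` naming both types on rejection.
#' @export
fml_compose_check <- function(outer, inner) {
  stopifnot(inherits(outer, "fml_evaluator"), inherits(inner, "fml_evaluator"))
  free <- fml_free_arguments(outer)
  if (length(free) != 1L)
    fml_stop("fml_definition_error",
             "compose: outer evaluator '%s' has %d free arguments (need exactly 1)",
             outer$name, length(free))
  arg <- free[[1L]]
  ok <- fml_type_compatible(arg$value_type, inner$value_type)
  msg <- if (ok) "ok" else
    sprintf("cannot compose: '%s' yields type '%s' but '%s' expects argument '%s' of type '%s'",
            inner$name, inner$value_type$name, outer$name, arg$name,
            arg$value_type$name)
  structure(list(ok = ok, argument = arg, message = msg), class = "fml_verdict")
}

#' @export
print.fml_verdict <- function(x, ...) {
  cat(if (x$ok) "composition ok\n" else paste0(x$message, "\n"))
  invisible(x)
}
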