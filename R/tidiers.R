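# Broom-style generics for the package's result objects. Defined here so the
# methods work without broom on the search path; if broom is attached its
# generics dispatch to the same methods.

#' Turn an mmcg result object into a tidy tibble
#' @param x a result object
#' @param ... passed to methods
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an mmcg result object
#' @param x a result object
#' @param ... passed to methods
#' @export
glance <- function(x, ...) UseMethod("glance")
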