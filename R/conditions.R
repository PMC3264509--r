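# Classed conditions used across the package. Every error carries the
# "chemmorph_error" class plus a specific subclass so callers (and the CLI)
# can dispatch on the failure kind.

cm_abort <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "chemmorph_error")))
}

cm_warn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "chemmorph_warning")))
}

#' Error and warning classes
#'
#' All conditions signalled by chemmorph are classed. Errors inherit from
#' `"chemmorph_error"`; the specific classes are:
#' `chemmorph_capacity_error` (drawing would exceed the 100000-atom capacity),
#' `chemmorph_duplicate_id_error`, `chemmorph_dangling_bond_error`,
#' `chemmorph_self_bond_error`, `chemmorph_empty_drawing_error`,
#' `chemmorph_format_error`, `chemmorph_unsupported_version_error`,
#' `chemmorph_degenerate_error` (collinear / zero-area mapping input),
#' `chemmorph_horizon_error` (projective denominator vanishes),
#' `chemmorph_domain_error` (parameter outside its stated domain),
#' `chemmorph_correspondence_error`, `chemmorph_chain_error`,
#' `chemmorph_topology_error`, `chemmorph_empty_input_error`.
#' The single warning class is `chemmorph_compatibility_warning`, emitted when
#' a written molfile exceeds the 999-atom/999-bond interchange limit.
#'
#' @name chemmorph-conditions
#' @keywords internal
NULL
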