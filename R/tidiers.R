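#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per (class, metric) pair in long form, mirroring the standard
#' evaluation-table layout.
#'
#' @param x A `fourms_eval` from [evaluate_extractions()].
#' @param ... Unused.
#' @return Tibble: `m_class`, `metric`, `value`.
#' @export
tidy.fourms_eval <- function(x, ...) {
  tidyr::pivot_longer(
    x$per_class,
    cols = -"m_class", names_to = "metric", values_to = "value"
  )
}

#' @rdname tidy.fourms_eval
#' @export
glance.fourms_eval <- function(x, ...) {
  tibble::tibble(
    overall_kappa = x$overall_kappa,
    macro_kappa = x$macro_kappa,
    n_messages = x$n_messages,
    gate = x$gate,
    gate_passed = x$gate_passed
  )
}

#' Tidy a taxonomy
#'
#' @param x A `fourms_taxonomy`.
#' @param ... Unused.
#' @return Node tibble with member counts instead of member lists.
#' @export
tidy.fourms_taxonomy <- function(x, ...) {
  nodes <- x$nodes
  tibble::tibble(
    node_id = nodes$node_id, m_class = nodes$m_class, level = nodes$level,
    parent_id = nodes$parent_id, label = nodes$label, flag = nodes$flag,
    n_members = lengths(nodes$members)
  )
}

#' @rdname tidy.fourms_taxonomy
#' @export
glance.fourms_taxonomy <- function(x, ...) {
  tibble::tibble(
    n_expressions = nrow(x$expressions),
    n_nodes = nrow(x$nodes),
    n_classes = length(unique(x$nodes$m_class)),
    n_levels = max(x$nodes$level)
  )
}

#' Tidy a corpus summary
#'
#' @param x A `fourms_summary`.
#' @param ... Unused.
#' @return The per-class totals tibble.
#' @export
tidy.fourms_summary <- function(x, ...) {
  x$totals
}

#' @rdname tidy.fourms_summary
#' @export
glance.fourms_summary <- function(x, ...) {
  tibble::tibble(
    n_extractions = x$n_extractions,
    messages_with_content = x$messages_with_content
  )
}
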