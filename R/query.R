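#' Query the taxonomy for a concept
#'
#' Matches expressions by direct quotation (the normalized term occurs in
#' the expression text at a word boundary) and, when an embedder is
#' supplied, by relatedness (cosine similarity between the term's embedding
#' and each expression's vector at or above `relatedness_threshold`). The
#' resulting concept graph contains every match with its full ancestor
#' chain of clusters up to its class root; class components are linked only
#' through shared clusters, never by an artificial super-root.
#'
#' @param taxonomy A labeled `fourms_taxonomy`.
#' @param term Non-empty query term.
#' @param embedder Optional embedder for relatedness matching (the
#'   expression tibble must carry vectors).
#' @param relatedness_threshold Cosine threshold for "related terms"
#'   (default 0.6).
#' @return A `fourms_graph`: `nodes` (`node_id`, `kind`, `label`, `level`,
#'   `m_class`), `edges` (`from`, `to`), `query_term`, and per-class match
#'   `counts`. Attribute `"no_matches"` is set when only flagged roots are
#'   returned.
#' @export
query_concept <- function(taxonomy, term, embedder = NULL,
                          relatedness_threshold = 0.6) {
  stopifnot(nzchar(trimws(term)))
  expr <- taxonomy$expressions
  nterm <- norm_text(term)
  quoted <- stringr::str_detect(
    norm_text(expr$text), paste0("\\b\\Q", nterm, "\\E\\b")
  )
  related <- rep(FALSE, nrow(expr))
  if (!is.null(embedder) && "vector" %in% names(expr)) {
    tv <- embedder(term)[1, ]
    if (sqrt(sum(tv^2)) == 0) {
      stop("query term embeds to a zero vector", call. = FALSE)
    }
    u <- unit_rows(expr$vector, what = "expression vector")
    related <- as.numeric(u %*% (tv / sqrt(sum(tv^2)))) >=
      relatedness_threshold
  }
  match_idx <- which(quoted | related)
  nodes_tbl <- taxonomy$nodes
  # expression row -> finest-level node
  max_lev <- max(nodes_tbl$level)
  leafnodes <- nodes_tbl[nodes_tbl$level == max_lev, ]
  node_of_expr <- rep(NA_character_, nrow(expr))
  for (i in seq_len(nrow(leafnodes))) {
    node_of_expr[leafnodes$members[[i]]] <- leafnodes$node_id[i]
  }
  parent_of <- stats::setNames(nodes_tbl$parent_id, nodes_tbl$node_id)
  keep_nodes <- character(0)
  edges <- list()
  g_nodes <- list()
  for (i in match_idx) {
    eid <- paste0("expr_", i)
    g_nodes[[length(g_nodes) + 1]] <- tibble::tibble(
      node_id = eid, kind = "expression", label = expr$text[i],
      level = max_lev + 1, m_class = expr$m_class[i]
    )
    child <- eid
    anc <- node_of_expr[i]
    while (!is.na(anc)) {
      edges[[length(edges) + 1]] <- tibble::tibble(from = anc, to = child)
      keep_nodes <- c(keep_nodes, anc)
      child <- anc
      anc <- parent_of[[anc]]
    }
  }
  keep_nodes <- unique(keep_nodes)
  cluster_nodes <- nodes_tbl[nodes_tbl$node_id %in% keep_nodes, ]
  no_matches <- length(match_idx) == 0
  if (no_matches) cluster_nodes <- nodes_tbl[nodes_tbl$level == 0, ]
  nodes <- dplyr::bind_rows(
    tibble::tibble(
      node_id = cluster_nodes$node_id,
      kind = ifelse(cluster_nodes$level == 0, "class_root", "cluster"),
      label = cluster_nodes$label,
      level = as.numeric(cluster_nodes$level),
      m_class = cluster_nodes$m_class
    ),
    if (length(g_nodes) > 0) dplyr::bind_rows(g_nodes) else NULL
  )
  edges <- if (length(edges) > 0) {
    dplyr::distinct(dplyr::bind_rows(edges))
  } else {
    tibble::tibble(from = character(), to = character())
  }
  counts <- tibble::tibble(m_class = m_classes()) |>
    dplyr::left_join(
      dplyr::count(
        tibble::tibble(m_class = expr$m_class[match_idx]), .data$m_class
      ),
      by = "m_class"
    ) |>
    dplyr::mutate(n_matches = ifelse(is.na(.data$n), 0L, .data$n)) |>
    dplyr::select("m_class", "n_matches")
  out <- structure(
    list(
      nodes = dplyr::arrange(nodes, .data$node_id), edges = edges,
      query_term = term, counts = counts
    ),
    class = "fourms_graph"
  )
  attr(out, "no_matches") <- no_matches
  out
}

#' @export
print.fourms_graph <- function(x, ...) {
  cat(
    "<fourms_graph> '", x$query_term, "': ", nrow(x$nodes), " nodes, ",
    nrow(x$edges), " edges\n",
    sep = ""
  )
  print(x$counts)
  invisible(x)
}

#' Export or import a concept graph
#'
#' `"graphml"` writes GraphML via igraph with all node attributes and the
#' query term as a graph attribute; `"node_link"` writes the standard
#' node-link JSON shape. Both round-trip losslessly: exporting and
#' re-importing yields an identical graph.
#'
#' @param graph A `fourms_graph`.
#' @param path Output file.
#' @param format `"graphml"` or `"node_link"`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "node_link")) {
  format <- match.arg(format)
  if (format == "graphml") {
    vert <- as.data.frame(graph$nodes)
    names(vert)[1] <- "name"
    g <- igraph::graph_from_data_frame(
      as.data.frame(graph$edges), directed = TRUE, vertices = vert
    )
    g <- igraph::set_graph_attr(g, "query_term", graph$query_term)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    payload <- list(
      query_term = graph$query_term,
      nodes = graph$nodes,
      edges = graph$edges
    )
    writeLines(
      as.character(jsonlite::toJSON(payload, dataframe = "rows", digits = NA)),
      path
    )
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "node_link")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vert <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- tibble::tibble(
      node_id = vert$name, kind = vert$kind, label = vert$label,
      level = as.numeric(vert$level), m_class = vert$m_class
    )
    edges <- tibble::tibble(
      from = as.character(ed$from), to = as.character(ed$to)
    )
    qt <- igraph::graph_attr(g, "query_term")
  } else {
    p <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    nodes <- if (length(p$nodes) == 0) {
      tibble::tibble(
        node_id = character(), kind = character(), label = character(),
        level = numeric(), m_class = character()
      )
    } else {
      tibble::as_tibble(p$nodes)
    }
    nodes$level <- as.numeric(nodes$level)
    edges <- if (length(p$edges) == 0) {
      tibble::tibble(from = character(), to = character())
    } else {
      tibble::as_tibble(p$edges)
    }
    qt <- p$query_term
  }
  nodes <- dplyr::arrange(nodes, .data$node_id)
  counts <- tibble::tibble(m_class = m_classes()) |>
    dplyr::left_join(
      dplyr::count(nodes[nodes$kind == "expression", ], .data$m_class),
      by = "m_class"
    ) |>
    dplyr::mutate(n_matches = ifelse(is.na(.data$n), 0L, .data$n)) |>
    dplyr::select("m_class", "n_matches")
  structure(
    list(nodes = nodes, edges = edges, query_term = qt, counts = counts),
    class = "fourms_graph"
  )
}

#' Corpus-level summary of validated extractions
#'
#' Tallies, over validated spans: total extractions per 4M class, the
#' number of messages with any 4M content, the sender-role distribution of
#' extractions (counts and percentages), and the
#' (sender role, receiver role, class) cross-tabulation as percentages of
#' all extractions. Display percentages round to one decimal; full
#' precision is kept in the tables.
#'
#' @param results A validated `fourms_extractions`.
#' @param corpus A linked corpus from [link_to_transfers()], or a message
#'   tibble.
#' @return A `fourms_summary` list of tibbles: `totals`, `role_distribution`,
#'   `crosstab`, and scalar `messages_with_content`.
#' @export
summarize_corpus <- function(results, corpus) {
  messages <- if (inherits(corpus, "fourms_corpus")) corpus$messages else corpus
  spans <- tibble::as_tibble(results)
  spans <- spans[spans$valid, ]
  idx <- match(spans$message_id, messages$message_id)
  spans$sender_role <- messages$sender_role[idx]
  spans$receiver_role <- messages$receiver_role[idx]
  total <- nrow(spans)
  totals <- tibble::tibble(m_class = m_classes()) |>
    dplyr::left_join(dplyr::count(spans, .data$m_class), by = "m_class") |>
    dplyr::mutate(n_extractions = ifelse(is.na(.data$n), 0L, .data$n)) |>
    dplyr::select("m_class", "n_extractions")
  role_distribution <- if (total == 0) {
    tibble::tibble(
      sender_role = character(), n = integer(), percentage = numeric()
    )
  } else {
    dplyr::count(spans, .data$sender_role) |>
      dplyr::mutate(percentage = 100 * .data$n / total) |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  crosstab <- if (total == 0) {
    tibble::tibble(
      sender_role = character(), receiver_role = character(),
      m_class = character(), n = integer(), percentage = numeric()
    )
  } else {
    dplyr::count(
      spans, .data$sender_role, .data$receiver_role, .data$m_class
    ) |>
      dplyr::mutate(percentage = 100 * .data$n / total) |>
      dplyr::arrange(dplyr::desc(.data$n))
  }
  structure(
    list(
      totals = totals,
      messages_with_content = length(unique(spans$message_id)),
      role_distribution = role_distribution,
      crosstab = crosstab,
      n_extractions = total
    ),
    class = "fourms_summary"
  )
}

#' @export
print.fourms_summary <- function(x, ...) {
  cat("<fourms_summary> ", x$n_extractions, " extractions in ",
    x$messages_with_content, " messages\n",
    sep = ""
  )
  tot <- x$totals
  for (i in seq_len(nrow(tot))) {
    cat("  ", m_class_labels()[tot$m_class[i]], " = ", tot$n_extractions[i],
      "\n",
      sep = ""
    )
  }
  rd <- x$role_distribution
  for (i in seq_len(nrow(rd))) {
    cat(sprintf(
      "  %s = %d (%.1f%%)\n", rd$sender_role[i], rd$n[i], rd$percentage[i]
    ))
  }
  invisible(x)
}
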