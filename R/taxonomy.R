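#' Collect unique expressions from validated extractions
#'
#' Groups validated spans by (class, normalized text) into Expression units
#' — the atoms of taxonomy building — keeping the first surface form and
#' accumulating message provenance.
#'
#' @param results A `fourms_extractions` or `fourms_gold` object.
#' @return Tibble: `text`, `m_class`, `provenance` (list of message ids).
#' @export
collect_expressions <- function(results) {
  spans <- tibble::as_tibble(results)
  if ("valid" %in% names(spans)) spans <- spans[spans$valid, ]
  span_col <- if ("span" %in% names(spans)) "span" else "phrase"
  spans$.norm <- norm_text(spans[[span_col]])
  out <- spans |>
    dplyr::group_by(.data$m_class, .data$.norm) |>
    dplyr::summarise(
      text = .data[[span_col]][1],
      provenance = list(unique(.data$message_id)),
      .groups = "drop"
    )
  out <- out[order(match(out$m_class, m_classes()), out$.norm), ]
  tibble::tibble(
    text = out$text, m_class = out$m_class, provenance = out$provenance
  )
}

#' Attach embedding vectors to expressions
#'
#' The embedder plug-in maps a character vector of texts to a numeric
#' matrix with one row per text and a fixed dimension; it must be
#' deterministic (identical texts give identical vectors). The dimension is
#' recorded as attribute `"embed_dim"`.
#'
#' @param expressions Expression tibble from [collect_expressions()].
#' @param embedder Function `character -> matrix`.
#' @return The tibble with a matrix column `vector`.
#' @export
embed_expressions <- function(expressions, embedder) {
  if (nrow(expressions) == 0) {
    expressions$vector <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(expressions)
  }
  v <- embedder(expressions$text)
  if (!is.matrix(v) || nrow(v) != nrow(expressions)) {
    stop("embedder must return one row per text", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("non-finite embedding values", call. = FALSE)
  expressions$vector <- v
  attr(expressions, "embed_dim") <- ncol(v)
  expressions
}

#' Semantic deduplication of embedded expressions
#'
#' Greedy first-kept scan in input order: an expression whose cosine
#' similarity to any already-kept expression reaches `threshold` is merged
#' into the earliest such kept expression (provenance unioned); output
#' order is preserved. By default the scan runs within each class (merging
#' across classes would delete class-specific provenance); set
#' `by_class = FALSE` to deduplicate the pooled set before any class split.
#'
#' @param expressions Embedded expression tibble.
#' @param threshold Cosine similarity threshold in (0, 1\] (default 0.95).
#' @param by_class Scan within class (default) or across the pooled set.
#' @return Kept expressions; attribute `"merge_map"` is a tibble
#'   (`kept_text`, `merged_text`, `m_class`) recording each fold-in.
#' @export
semantic_dedup <- function(expressions, threshold = 0.95, by_class = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- nrow(expressions)
  if (n == 0) {
    attr(expressions, "merge_map") <- tibble::tibble(
      kept_text = character(), merged_text = character(), m_class = character()
    )
    return(expressions)
  }
  u <- unit_rows(expressions$vector, what = "embedding vector")
  groups <- if (by_class) expressions$m_class else rep("all", n)
  keep <- logical(n)
  merged_into <- integer(n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    kept_idx <- integer(0)
    for (i in idx) {
      if (length(kept_idx) == 0) {
        keep[i] <- TRUE
        kept_idx <- i
        next
      }
      sims <- as.numeric(u[kept_idx, , drop = FALSE] %*% u[i, ])
      hit <- which(sims >= threshold - 1e-12)
      if (length(hit) == 0) {
        keep[i] <- TRUE
        kept_idx <- c(kept_idx, i)
      } else {
        merged_into[i] <- kept_idx[hit[1]]
      }
    }
  }
  merge_map <- tibble::tibble(
    kept_text = expressions$text[merged_into[merged_into > 0]],
    merged_text = expressions$text[which(merged_into > 0)],
    m_class = expressions$m_class[which(merged_into > 0)]
  )
  out <- expressions
  for (i in which(merged_into > 0)) {
    k <- merged_into[i]
    out$provenance[[k]] <- unique(c(out$provenance[[k]], out$provenance[[i]]))
  }
  out <- out[keep, ]
  attr(out, "merge_map") <- merge_map
  attr(out, "embed_dim") <- attr(expressions, "embed_dim")
  out
}

#' Ward agglomerative linkage
#'
#' Hierarchical agglomeration under Ward's criterion on Euclidean distance:
#' at each step the pair of clusters whose merger minimally increases the
#' total within-cluster variance is joined. Heights follow the
#' Euclidean-commensurate convention `sqrt(2 * increase)` (two singletons
#' merge at their Euclidean distance). Leaves are numbered `1..n`; the
#' cluster created by merge `i` is node `n + i`.
#'
#' @param x Numeric matrix, one row per item (finite entries).
#' @return A `fourms_linkage` object: `n_leaves` and a `merges` tibble
#'   (`left`, `right`, `height`, `size`).
#' @export
ward_linkage <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  n <- nrow(x)
  if (n < 1) stop("need at least one row", call. = FALSE)
  if (n == 1) {
    return(structure(
      list(
        n_leaves = 1L,
        merges = tibble::tibble(
          left = integer(), right = integer(),
          height = numeric(), size = integer()
        )
      ),
      class = "fourms_linkage"
    ))
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  id <- function(v) ifelse(v < 0, -v, v + n)
  left <- id(hc$merge[, 1])
  right <- id(hc$merge[, 2])
  swap <- left > right
  tmp <- left[swap]
  left[swap] <- right[swap]
  right[swap] <- tmp
  sizes <- integer(n - 1)
  node_size <- function(v) ifelse(v <= n, 1L, sizes[v - n])
  for (i in seq_len(n - 1)) {
    sizes[i] <- node_size(left[i]) + node_size(right[i])
  }
  structure(
    list(
      n_leaves = as.integer(n),
      merges = tibble::tibble(
        left = as.integer(left), right = as.integer(right),
        height = hc$height, size = sizes
      )
    ),
    class = "fourms_linkage"
  )
}

#' @export
print.fourms_linkage <- function(x, ...) {
  cat("<fourms_linkage> ", x$n_leaves, " leaves, ", nrow(x$merges),
    " merges\n",
    sep = ""
  )
  invisible(x)
}

#' Export a linkage as the standard 4-column matrix
#'
#' @param x A `fourms_linkage`.
#' @param ... Unused.
#' @return Numeric matrix with columns left, right, height, size (leaf ids
#'   `1..n`, cluster from merge `i` is `n + i`).
#' @export
as.matrix.fourms_linkage <- function(x, ...) {
  m <- as.matrix(as.data.frame(x$merges))
  colnames(m) <- c("left", "right", "height", "size")
  m
}

#' Convert a linkage to an hclust object
#'
#' @param x A `fourms_linkage`.
#' @param ... Unused.
#' @export
as.hclust.fourms_linkage <- function(x, ...) {
  n <- x$n_leaves
  m <- cbind(
    ifelse(x$merges$left <= n, -x$merges$left, x$merges$left - n),
    ifelse(x$merges$right <= n, -x$merges$right, x$merges$right - n)
  )
  structure(
    list(
      merge = m, height = x$merges$height,
      order = order_leaves(m, n), labels = as.character(seq_len(n)),
      method = "ward.D2", dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

# Leaf ordering for dendrogram display: depth-first over the merge tree.
order_leaves <- function(merge, n) {
  if (n == 1) return(1L)
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut a linkage tree at a distance threshold
#'
#' Clusters are the connected components formed by applying every merge
#' with height strictly below `threshold`. Cluster ids are assigned in
#' order of each cluster's smallest member leaf index, so a cut is
#' deterministic and platform-independent.
#'
#' @param tree A `fourms_linkage`.
#' @param threshold Non-negative distance threshold.
#' @return Integer vector: cluster id per leaf.
#' @export
cut_tree <- function(tree, threshold) {
  stopifnot(threshold >= 0)
  n <- tree$n_leaves
  parent <- seq_len(n + nrow(tree$merges))
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  active <- which(tree$merges$height < threshold)
  for (i in active) {
    parent[find(tree$merges$left[i])] <- n + i
    parent[find(tree$merges$right[i])] <- n + i
  }
  roots <- vapply(seq_len(n), find, integer(1))
  first_leaf <- match(unique(roots), roots)
  cluster_of_root <- match(roots, roots[sort(first_leaf)])
  cluster_of_root
}

#' Programmatic threshold selection from target cluster counts
#'
#' Replaces manual dendrogram inspection: for each target count, returns
#' the distance threshold whose cut yields the cluster count closest to the
#' target, preferring the larger threshold on ties. Successive thresholds
#' are forced strictly decreasing (stepping a tied level down to the next
#' candidate) so they form a valid coarse-to-fine level specification.
#'
#' @param tree A `fourms_linkage`.
#' @param target_counts Increasing integer vector of target cluster counts
#'   (one per level).
#' @return Numeric vector of thresholds, strictly decreasing.
#' @export
suggest_thresholds <- function(tree, target_counts) {
  stopifnot(!is.unsorted(target_counts, strictly = TRUE))
  n <- tree$n_leaves
  if (any(target_counts > n)) {
    stop("target count exceeds number of leaves (", n, ")", call. = FALSE)
  }
  h <- tree$merges$height
  cands <- if (length(h) == 0) 1 else c(sort(unique(h)), max(h) * 1.01 + 1e-9)
  counts <- vapply(cands, function(t) n - sum(h < t), numeric(1))
  pick <- function(target) {
    err <- abs(counts - target)
    best <- which(err == min(err))
    cands[best[length(best)]] # ties -> larger threshold
  }
  ts <- vapply(target_counts, pick, numeric(1))
  for (k in seq_along(ts)[-1]) {
    if (ts[k] >= ts[k - 1]) {
      lower <- cands[cands < ts[k - 1]]
      if (length(lower) == 0) {
        stop("cannot produce strictly decreasing thresholds", call. = FALSE)
      }
      ts[k] <- max(lower)
    }
  }
  ts
}

#' Build the four-level taxonomy from per-class trees
#'
#' Cuts each class tree at its four strictly decreasing thresholds
#' (coarse to fine) to obtain nested level partitions under a level-0 class
#' root. Because all cuts come from a single tree, each level-(k+1) cluster
#' lies inside exactly one level-k cluster.
#'
#' @param expressions Embedded expression tibble (defines leaf order per
#'   class: rows of a class, in order, are that tree's leaves).
#' @param trees Named list (class -> `fourms_linkage`).
#' @param thresholds Named list (class -> strictly decreasing numeric
#'   vector, one threshold per level).
#' @return A `fourms_taxonomy` object: `nodes` tibble (`node_id`, `m_class`,
#'   `level`, `parent_id`, `label`, `flag`, `members` list of expression row
#'   indices), plus the expressions and trees.
#' @export
build_hierarchy <- function(expressions, trees, thresholds) {
  classes <- intersect(m_classes(), unique(expressions$m_class))
  labels <- m_class_labels()
  nodes <- list()
  for (cls in classes) {
    t_cls <- thresholds[[cls]]
    if (is.null(t_cls)) stop("no thresholds for class ", cls, call. = FALSE)
    if (is.unsorted(rev(t_cls), strictly = TRUE)) {
      stop("thresholds for ", cls, " must be strictly decreasing",
        call. = FALSE
      )
    }
    rows <- which(expressions$m_class == cls)
    tree <- trees[[cls]]
    if (is.null(tree) || tree$n_leaves != length(rows)) {
      stop("tree for ", cls, " does not match its expressions", call. = FALSE)
    }
    root_id <- paste0(cls, "_root")
    nodes[[length(nodes) + 1]] <- tibble::tibble(
      node_id = root_id, m_class = cls, level = 0L, parent_id = NA_character_,
      label = unname(labels[cls]), flag = NA_character_,
      members = list(rows)
    )
    prev_assign <- rep(1L, length(rows)) # all leaves under the root
    prev_ids <- root_id
    for (lev in seq_along(t_cls)) {
      part <- cut_tree(tree, t_cls[lev])
      ids <- sprintf("%s_L%d_C%03d", cls, lev, seq_len(max(part)))
      parent_of <- vapply(seq_len(max(part)), function(cid) {
        p <- unique(prev_assign[part == cid])
        if (length(p) != 1) {
          stop("nesting violated at level ", lev, " for ", cls, call. = FALSE)
        }
        prev_ids[p]
      }, character(1))
      nodes[[length(nodes) + 1]] <- tibble::tibble(
        node_id = ids, m_class = cls, level = as.integer(lev),
        parent_id = parent_of, label = NA_character_, flag = NA_character_,
        members = lapply(seq_len(max(part)), function(cid) rows[part == cid])
      )
      prev_assign <- part
      prev_ids <- ids
    }
  }
  structure(
    list(
      nodes = dplyr::bind_rows(nodes), expressions = expressions,
      trees = trees, thresholds = thresholds
    ),
    class = "fourms_taxonomy"
  )
}

#' One-call taxonomy construction
#'
#' Convenience wrapper: per class, runs [ward_linkage()] on the expression
#' vectors, selects thresholds (given explicitly or via
#' [suggest_thresholds()] from `target_counts`), and assembles the
#' hierarchy.
#'
#' @param expressions Embedded expression tibble.
#' @param thresholds Named list of per-class threshold vectors, or `NULL`.
#' @param target_counts Named list of per-class increasing target cluster
#'   counts (used when `thresholds` is `NULL`).
#' @return A `fourms_taxonomy`.
#' @export
build_taxonomy <- function(expressions, thresholds = NULL,
                           target_counts = NULL) {
  classes <- intersect(m_classes(), unique(expressions$m_class))
  trees <- lapply(classes, function(cls) {
    ward_linkage(expressions$vector[expressions$m_class == cls, , drop = FALSE])
  })
  names(trees) <- classes
  if (is.null(thresholds)) {
    if (is.null(target_counts)) {
      stop("supply thresholds or target_counts", call. = FALSE)
    }
    thresholds <- lapply(classes, function(cls) {
      suggest_thresholds(trees[[cls]], target_counts[[cls]])
    })
    names(thresholds) <- classes
  }
  build_hierarchy(expressions, trees, thresholds)
}

#' @export
print.fourms_taxonomy <- function(x, ...) {
  cat(
    "<fourms_taxonomy> ", nrow(x$expressions), " expressions, ",
    nrow(x$nodes), " nodes over ", length(unique(x$nodes$m_class)),
    " classes\n",
    sep = ""
  )
  lev <- table(x$nodes$m_class, x$nodes$level)
  print(lev)
  invisible(x)
}

#' Flat per-class cluster summary table
#'
#' Mirrors the standard report layout: one row per level-1 cluster with its
#' label and unique-expression count, plus per-class totals of clusters at
#' levels 2-4.
#'
#' @param taxonomy A `fourms_taxonomy`.
#' @return Tibble: `m_class`, `level1_label`, `n_expressions`,
#'   `n_clusters_l2`, `n_clusters_l3`, `n_clusters_l4`.
#' @export
taxonomy_table <- function(taxonomy) {
  nodes <- taxonomy$nodes
  l1 <- nodes[nodes$level == 1, ]
  counts <- nodes |>
    dplyr::filter(.data$level >= 2) |>
    dplyr::count(.data$m_class, .data$level) |>
    tidyr::pivot_wider(
      names_from = "level", values_from = "n", names_prefix = "n_clusters_l"
    )
  out <- tibble::tibble(
    m_class = l1$m_class,
    level1_label = l1$label,
    n_expressions = lengths(l1$members)
  )
  out <- dplyr::arrange(
    out,
    match(.data$m_class, m_classes()), dplyr::desc(.data$n_expressions)
  )
  dplyr::left_join(out, counts, by = "m_class")
}

#' Serialize or load a taxonomy tree file
#'
#' The tree file is JSON: per node its id, label, level, class, parent,
#' flag, and member expression texts with message provenance. Reloading
#' yields a `fourms_taxonomy` whose nodes and expressions equal the
#' original's (linkage trees are not serialized).
#'
#' @param taxonomy A `fourms_taxonomy`.
#' @param path File path.
#' @export
write_taxonomy <- function(taxonomy, path) {
  nodes <- taxonomy$nodes
  payload <- list(
    expressions = list(
      text = taxonomy$expressions$text,
      m_class = taxonomy$expressions$m_class,
      provenance = taxonomy$expressions$provenance
    ),
    nodes = lapply(seq_len(nrow(nodes)), function(i) {
      list(
        node_id = nodes$node_id[i], m_class = nodes$m_class[i],
        level = nodes$level[i], parent_id = nodes$parent_id[i],
        label = nodes$label[i], flag = nodes$flag[i],
        members = nodes$members[[i]]
      )
    }),
    thresholds = taxonomy$thresholds
  )
  writeLines(
    as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null",
      digits = NA
    )),
    path
  )
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expressions <- tibble::tibble(
    text = unname(vapply(p$expressions$text, identity, character(1))),
    m_class = unname(vapply(p$expressions$m_class, identity, character(1))),
    provenance = lapply(p$expressions$provenance, function(v) {
      unname(vapply(v, identity, character(1)))
    })
  )
  nodes <- purrr::map_dfr(p$nodes, function(nd) {
    tibble::tibble(
      node_id = nd$node_id, m_class = nd$m_class,
      level = as.integer(nd$level),
      parent_id = if (is.null(nd$parent_id)) NA_character_ else nd$parent_id,
      label = if (is.null(nd$label)) NA_character_ else nd$label,
      flag = if (is.null(nd$flag)) NA_character_ else nd$flag,
      members = list(as.integer(unlist(nd$members)))
    )
  })
  thresholds <- lapply(p$thresholds, function(v) as.numeric(unlist(v)))
  structure(
    list(
      nodes = nodes, expressions = expressions, trees = NULL,
      thresholds = thresholds
    ),
    class = "fourms_taxonomy"
  )
}
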