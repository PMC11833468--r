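#' Deterministic fallback text embedder
#'
#' Maps each distinct normalized text to a reproducible pseudo-random unit
#' vector keyed by a string hash and the seed. Identical texts always map to
#' identical vectors, so near-verbatim duplicate detection (cosine 0.9999)
#' works; unrelated texts are near-orthogonal in expectation. Serves as the
#' default label embedder and as the unknown-text branch of the synthetic
#' embedder.
#'
#' @param dim Embedding dimension (>= 2).
#' @param seed Integer seed mixed into the hash.
#' @return Embedder function `character -> matrix`.
#' @export
hash_embedder <- function(dim = 16, seed = 0L) {
  stopifnot(dim >= 2)
  function(texts) {
    h <- str_hash(norm_text(texts), seed = seed)
    m <- t(vapply(h, function(hi) {
      v <- withr::with_seed(hi, stats::rnorm(dim))
      v / sqrt(sum(v^2))
    }, numeric(dim)))
    rownames(m) <- NULL
    m
  }
}

#' Keyword cluster labeler
#'
#' Deterministic reference labeler (and test double for generative
#' labelers): labels a cluster with its most frequent informative tokens,
#' title-cased. When asked to avoid previous labels it appends further
#' tokens until the label is new.
#'
#' @param n_tokens Number of tokens in a label.
#' @return Labeler function `(texts, avoid) -> label`.
#' @export
keyword_labeler <- function(n_tokens = 2) {
  stop_words <- c(
    "the", "a", "an", "of", "and", "or", "to", "in", "on", "for", "with",
    "is", "at", "by", "be", "as", "this", "that", "it", "from"
  )
  function(texts, avoid = character()) {
    toks <- unlist(strsplit(norm_text(texts), " ", fixed = TRUE))
    toks <- toks[nzchar(toks) & !toks %in% stop_words]
    if (length(toks) == 0) toks <- "misc"
    freq <- sort(table(toks), decreasing = TRUE)
    ordered <- names(freq)[order(-as.integer(freq), names(freq))]
    k <- min(n_tokens, length(ordered))
    title_case <- function(w) {
      paste(toupper(substring(w, 1, 1)), substring(w, 2), sep = "", collapse = " ")
    }
    lab <- title_case(ordered[seq_len(k)])
    while (lab %in% avoid && k < length(ordered)) {
      k <- k + 1
      lab <- title_case(ordered[seq_len(k)])
    }
    lab
  }
}

# The `max_members` most central member texts of a node (by Euclidean
# distance to the cluster mean), bounding what is handed to a labeler.
central_members <- function(expressions, rows, max_members = 50) {
  if (length(rows) <= max_members) return(expressions$text[rows])
  v <- expressions$vector[rows, , drop = FALSE]
  ctr <- colMeans(v)
  d <- sqrt(rowSums(sweep(v, 2, ctr)^2))
  expressions$text[rows[order(d)][seq_len(max_members)]]
}

#' Label taxonomy clusters with duplicate resolution
#'
#' Assigns labels breadth-first (level 1 before level 2, and so on). Each
#' candidate label is embedded and compared against the labels already
#' accepted at the same class and level; a cosine similarity at or above
#' `dup_threshold` (default 0.9999, i.e. a near-verbatim duplicate)
#' triggers re-labeling with the colliding labels passed back to the
#' labeler. Labeling progresses until the similarity is resolved or
#' `max_rounds` is exhausted, after which a deterministic numeric suffix
#' disambiguates the label and the node is flagged
#' `"label_suffix_disambiguated"`. A labeler failure yields the placeholder
#' `"Unlabeled-<node_id>"` and flag `"labeler_failed"`. Class roots keep
#' their canonical class names.
#'
#' @param taxonomy A `fourms_taxonomy`.
#' @param labeler Function `(member_texts, avoid) -> label`.
#' @param embedder Embedder used for the duplicate check; defaults to the
#'   same kind of embedder used for expressions ([hash_embedder()]).
#' @param dup_threshold Cosine threshold for duplicate labels.
#' @param max_rounds Re-labeling rounds before suffix disambiguation.
#' @param max_members Member-list truncation passed to the labeler.
#' @return The taxonomy with `label`/`flag` filled in.
#' @export
label_clusters <- function(taxonomy, labeler = keyword_labeler(),
                           embedder = hash_embedder(), dup_threshold = 0.9999,
                           max_rounds = 3, max_members = 50) {
  nodes <- taxonomy$nodes
  has_vectors <- "vector" %in% names(taxonomy$expressions)
  for (lev in sort(unique(nodes$level[nodes$level > 0]))) {
    for (cls in intersect(m_classes(), unique(nodes$m_class))) {
      sel <- which(nodes$level == lev & nodes$m_class == cls)
      accepted <- character(0)
      accepted_vec <- NULL
      for (i in sel) {
        rows <- nodes$members[[i]]
        texts <- if (has_vectors) {
          central_members(taxonomy$expressions, rows, max_members)
        } else {
          utils::head(taxonomy$expressions$text[rows], max_members)
        }
        avoid <- character(0)
        lab <- NULL
        flag <- NA_character_
        for (round in seq_len(max(1, max_rounds))) {
          cand <- tryCatch(labeler(texts, avoid), error = function(e) e)
          if (inherits(cand, "error")) {
            lab <- paste0("Unlabeled-", nodes$node_id[i])
            flag <- "labeler_failed"
            break
          }
          cand <- as.character(cand)[1]
          if (length(accepted) == 0) {
            lab <- cand
            break
          }
          v <- embedder(cand)
          sims <- as.numeric(
            unit_rows(accepted_vec) %*% (v[1, ] / sqrt(sum(v[1, ]^2)))
          )
          coll <- which(sims >= dup_threshold)
          if (length(coll) == 0) {
            lab <- cand
            break
          }
          avoid <- unique(c(avoid, accepted[coll]))
          lab <- cand # keep last candidate in case rounds run out
        }
        if (is.null(flag) || is.na(flag)) {
          # unresolved duplicate after max_rounds -> suffix disambiguation
          if (lab %in% accepted ||
            (length(accepted) > 0 && {
              v <- embedder(lab)
              any(as.numeric(
                unit_rows(accepted_vec) %*% (v[1, ] / sqrt(sum(v[1, ]^2)))
              ) >= dup_threshold)
            })) {
            k <- 2
            while (paste0(lab, " (", k, ")") %in% accepted) k <- k + 1
            lab <- paste0(lab, " (", k, ")")
            flag <- "label_suffix_disambiguated"
          }
        }
        nodes$label[i] <- lab
        nodes$flag[i] <- flag
        accepted <- c(accepted, lab)
        lv <- embedder(lab)
        accepted_vec <- rbind(accepted_vec, lv[1, , drop = TRUE])
      }
    }
  }
  taxonomy$nodes <- nodes
  taxonomy
}
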