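#' Read or write annotation files
#'
#' Annotations are comma-delimited with header
#' `annotator_id,message_id,m_class,phrase`, one row per extracted phrase.
#'
#' @param path File path.
#' @return Tibble of annotations.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("annotator_id", "message_id", "m_class", "phrase")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  tibble::as_tibble(raw[required])
}

#' @rdname read_annotations
#' @param annotations Annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_csv(annotations, path, progress = FALSE)
  invisible(path)
}

# Multiset matching of two annotators' phrases within each (message, class)
# group: exact normalized matches first, then greedy best-first fuzzy
# pairing at or above `fuzzy_threshold`. Returns matched pairs and the
# unmatched remainder on each side.
match_annotations <- function(a, b, fuzzy_threshold = 0.85) {
  key <- function(x) paste(x$message_id, x$m_class, sep = "\r")
  groups <- unique(c(key(a), key(b)))
  ka <- key(a)
  kb <- key(b)
  matched <- list()
  only_a <- list()
  only_b <- list()
  for (g in groups) {
    ia <- which(ka == g)
    ib <- which(kb == g)
    pa <- a$phrase[ia]
    pb <- b$phrase[ib]
    na_ <- norm_text(pa)
    nb_ <- norm_text(pb)
    used_a <- rep(FALSE, length(pa))
    used_b <- rep(FALSE, length(pb))
    pairs <- list()
    for (i in seq_along(pa)) {
      j <- which(!used_b & nb_ == na_[i])
      if (length(j) > 0) {
        used_a[i] <- TRUE
        used_b[j[1]] <- TRUE
        pairs[[length(pairs) + 1]] <- c(i, j[1])
      }
    }
    ra <- which(!used_a)
    rb <- which(!used_b)
    if (length(ra) > 0 && length(rb) > 0) {
      sim <- phrase_similarity(pa[ra], pb[rb])
      repeat {
        best <- which(sim == max(sim), arr.ind = TRUE)[1, , drop = TRUE]
        if (sim[best[1], best[2]] < fuzzy_threshold) break
        pairs[[length(pairs) + 1]] <- c(ra[best[1]], rb[best[2]])
        used_a[ra[best[1]]] <- TRUE
        used_b[rb[best[2]]] <- TRUE
        sim[best[1], ] <- -1
        sim[, best[2]] <- -1
        if (all(sim < fuzzy_threshold)) break
      }
    }
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    if (length(pairs) > 0) {
      pm <- do.call(rbind, pairs)
      matched[[length(matched) + 1]] <- tibble::tibble(
        message_id = parts[1], m_class = parts[2],
        phrase_a = pa[pm[, 1]], phrase_b = pb[pm[, 2]]
      )
    }
    if (any(!used_a)) {
      only_a[[length(only_a) + 1]] <- tibble::tibble(
        message_id = parts[1], m_class = parts[2], phrase = pa[!used_a]
      )
    }
    if (any(!used_b)) {
      only_b[[length(only_b) + 1]] <- tibble::tibble(
        message_id = parts[1], m_class = parts[2], phrase = pb[!used_b]
      )
    }
  }
  empty3 <- tibble::tibble(
    message_id = character(), m_class = character(), phrase = character()
  )
  list(
    matched = if (length(matched) > 0) dplyr::bind_rows(matched) else
      tibble::tibble(
        message_id = character(), m_class = character(),
        phrase_a = character(), phrase_b = character()
      ),
    only_a = if (length(only_a) > 0) dplyr::bind_rows(only_a) else empty3,
    only_b = if (length(only_b) > 0) dplyr::bind_rows(only_b) else empty3
  )
}

#' Differences between two annotators
#'
#' A difference is a (message, class, phrase) present in exactly one
#' annotator's set under normalized phrase matching; near-identical span
#' variants (full-string similarity at or above `fuzzy_threshold`) are
#' treated as the same phrase. Each difference is listed for adjudication.
#'
#' @param a,b Annotation tibbles (`annotator_id`, `message_id`, `m_class`,
#'   `phrase`) over the same message universe.
#' @param fuzzy_threshold Similarity above which two spans count as the same
#'   phrase (default 0.85).
#' @return Tibble of differences (`message_id`, `m_class`, `phrase`,
#'   `annotator`); attribute `"per_class"` holds per-class difference
#'   counts.
#' @export
diff_annotations <- function(a, b, fuzzy_threshold = 0.85) {
  id_a <- if (nrow(a) > 0) a$annotator_id[1] else "A"
  id_b <- if (nrow(b) > 0) b$annotator_id[1] else "B"
  m <- match_annotations(a, b, fuzzy_threshold)
  diffs <- dplyr::bind_rows(
    dplyr::mutate(m$only_a, annotator = id_a),
    dplyr::mutate(m$only_b, annotator = id_b)
  )
  if (nrow(diffs) == 0) {
    diffs <- tibble::tibble(
      message_id = character(), m_class = character(),
      phrase = character(), annotator = character()
    )
  }
  diffs <- dplyr::arrange(diffs, .data$message_id, .data$m_class, .data$phrase)
  per_class <- dplyr::count(diffs, .data$m_class, name = "differences")
  attr(diffs, "per_class") <- per_class
  attr(diffs, "annotators") <- c(a = id_a, b = id_b)
  diffs
}

new_gold <- function(spans, message_ids) {
  spans <- tibble::as_tibble(spans)
  structure(
    spans,
    message_ids = message_ids,
    class = c("fourms_gold", class(spans))
  )
}

#' Assemble a gold standard directly from span records
#'
#' @param spans Tibble with `message_id`, `m_class`, `span` (and optionally
#'   `provenance`).
#' @param message_ids Full message universe (ids with zero 4M content
#'   included).
#' @return A `fourms_gold` object.
#' @export
as_gold <- function(spans, message_ids) {
  if (!"provenance" %in% names(spans)) spans$provenance <- "both"
  new_gold(
    spans[c("message_id", "m_class", "span", "provenance")],
    unique(message_ids)
  )
}

#' @export
print.fourms_gold <- function(x, ...) {
  cat(
    "<fourms_gold> ", nrow(x), " expressions over ",
    length(message_ids(x)), " messages\n",
    sep = ""
  )
  invisible(x)
}

#' Reconcile two annotators into a gold standard
#'
#' Gold = the matched intersection of the two annotation sets plus every
#' accepted difference, mirroring the simultaneous-discussion adjudication
#' step. Every difference reported by [diff_annotations()] must carry an
#' adjudication; otherwise reconciliation is fatal and lists the
#' unadjudicated items. Provenance per phrase is `both`,
#' `A_only_accepted` or `B_only_accepted`.
#'
#' @param a,b Annotation tibbles.
#' @param adjudications Tibble `message_id`, `m_class`, `phrase`, `decision`
#'   (`"accept"` or `"reject"`), one row per difference.
#' @param message_ids Message universe; defaults to ids present in `a`/`b`.
#' @param fuzzy_threshold Passed to the phrase matcher.
#' @return A `fourms_gold` object (`message_id`, `m_class`, `span`,
#'   `provenance`).
#' @export
reconcile <- function(a, b, adjudications,
                      message_ids = NULL, fuzzy_threshold = 0.85) {
  m <- match_annotations(a, b, fuzzy_threshold)
  diffs <- dplyr::bind_rows(
    dplyr::mutate(m$only_a, side = "A"),
    dplyr::mutate(m$only_b, side = "B")
  )
  if (nrow(diffs) > 0) {
    adj_key <- paste(
      adjudications$message_id, adjudications$m_class,
      norm_text(adjudications$phrase),
      sep = "\r"
    )
    adj_used <- rep(FALSE, length(adj_key))
    decision <- character(nrow(diffs))
    for (i in seq_len(nrow(diffs))) {
      k <- paste(diffs$message_id[i], diffs$m_class[i],
        norm_text(diffs$phrase[i]),
        sep = "\r"
      )
      j <- which(!adj_used & adj_key == k)
      if (length(j) == 0) {
        decision[i] <- NA_character_
      } else {
        adj_used[j[1]] <- TRUE
        decision[i] <- adjudications$decision[j[1]]
      }
    }
    if (anyNA(decision)) {
      miss <- diffs[is.na(decision), ]
      stop(
        "unadjudicated difference(s): ",
        paste(miss$message_id, miss$m_class, miss$phrase,
          sep = "/", collapse = "; "
        ),
        call. = FALSE
      )
    }
    diffs$decision <- decision
  }
  gold_both <- tibble::tibble(
    message_id = m$matched$message_id, m_class = m$matched$m_class,
    span = m$matched$phrase_a, provenance = "both"
  )
  accepted <- if (nrow(diffs) > 0) diffs[diffs$decision == "accept", ] else diffs
  gold_acc <- if (nrow(accepted) > 0) {
    tibble::tibble(
      message_id = accepted$message_id, m_class = accepted$m_class,
      span = accepted$phrase,
      provenance = paste0(accepted$side, "_only_accepted")
    )
  } else {
    tibble::tibble(
      message_id = character(), m_class = character(),
      span = character(), provenance = character()
    )
  }
  spans <- dplyr::arrange(
    dplyr::bind_rows(gold_both, gold_acc),
    .data$message_id, .data$m_class, .data$span
  )
  if (is.null(message_ids)) {
    message_ids <- sort(unique(c(a$message_id, b$message_id)))
  }
  new_gold(spans, message_ids)
}

#' Score an extraction run against the gold standard
#'
#' Computes, per 4M class over the gold message universe, the binary metric
#' battery (recall, precision, F1, accuracy, ROC AUC, Cohen's kappa) on
#' presence indicators with the validated count as the AUC ranking score,
#' and the count metrics (Spearman's rho, binned kappa, MAE). The overall
#' kappa is micro-pooled over every (message, class) binary decision; the
#' macro average of per-class kappas is reported alongside. The performance
#' gate passes when the overall and every per-class kappa reach `gate`.
#'
#' @param results A validated `fourms_extractions` object covering the gold
#'   messages.
#' @param gold A `fourms_gold` object.
#' @param bins Count-bin spec for the binned kappa (see [bin_counts()]).
#' @param gate Kappa threshold for sufficient performance (default 0.60).
#' @return A `fourms_eval` object; see [tidy.fourms_eval()] and
#'   [glance.fourms_eval()].
#' @export
evaluate_extractions <- function(results, gold, bins = c(0, 1, 2, 3),
                                 gate = 0.60) {
  ids <- message_ids(gold)
  if (!all(ids %in% message_ids(results))) {
    stop("results do not cover the gold message universe", call. = FALSE)
  }
  gc <- extraction_counts(gold)
  pc <- extraction_counts(results)
  pc <- pc[pc$message_id %in% ids, ]
  key <- function(d) paste(d$message_id, d$m_class, sep = "\r")
  pc <- pc[match(key(gc), key(pc)), ]
  per_class <- purrr::map_dfr(m_classes(), function(cls) {
    sel <- gc$m_class == cls
    bm <- binary_metrics(pc$binary[sel], gc$binary[sel], scores = pc$count[sel])
    cm <- count_metrics(pc$count[sel], gc$count[sel], bins)
    tibble::tibble(
      m_class = cls,
      recall = bm$recall, precision = bm$precision, f1 = bm$f1,
      accuracy = bm$accuracy, auc = bm$auc, kappa = bm$kappa,
      spearman_rho = cm$spearman_rho, kappa_binned = cm$kappa_binned,
      mae = cm$mae
    )
  })
  overall <- suppressWarnings(cohen_kappa(pc$binary, gc$binary))
  structure(
    list(
      per_class = per_class,
      overall_kappa = overall,
      macro_kappa = mean(per_class$kappa),
      n_messages = length(ids),
      gate = gate,
      gate_passed = overall >= gate && all(per_class$kappa >= gate),
      bins = bins
    ),
    class = "fourms_eval"
  )
}

#' @export
print.fourms_eval <- function(x, digits = 2, ...) {
  cat("<fourms_eval> n =", x$n_messages, "messages\n")
  tab <- as.data.frame(x$per_class)
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(
    sprintf(
      "overall kappa (micro) = %.2f; macro = %.2f; gate kappa >= %.2f: %s\n",
      x$overall_kappa, x$macro_kappa, x$gate,
      if (x$gate_passed) "PASS" else "FAIL"
    )
  )
  invisible(x)
}

# Render a message's spans per class (sorted by normalized text for a
# canonical serialization).
spans_to_json <- function(spans_tbl, span_col = "span") {
  by_cls <- lapply(m_classes(), function(cls) {
    v <- spans_tbl[[span_col]][spans_tbl$m_class == cls]
    v[order(norm_text(v))]
  })
  names(by_cls) <- m_classes()
  render_extraction_json(by_cls)
}

#' Build accepted/rejected preference pairs
#'
#' For every gold message where the extractor's emitted spans differ from
#' the gold standard (per-class multiset comparison on normalized phrases),
#' emits one pair: `chosen` is the gold spans rendered through the same
#' structured-output schema the extractor uses, `rejected` is the
#' extractor's own output. Messages in exact agreement emit no pair; this is
#' the input file for preference-optimization fine-tuning.
#'
#' @param results A `fourms_extractions` object (all emitted spans,
#'   including flagged ones, are part of the rejected response). Messages
#'   whose raw output failed to parse are skipped (they are in
#'   [parse_errors()]).
#' @param gold A `fourms_gold` object.
#' @param prompt_template Template with a `{text}` placeholder.
#' @param messages Optional message tibble to fill `{text}`; when absent the
#'   message id is substituted.
#' @return Tibble of pairs: `message_id`, `prompt`, `chosen`, `rejected`.
#' @export
build_preference_pairs <- function(results, gold,
                                   prompt_template = default_prompt_template(),
                                   messages = NULL) {
  ids <- setdiff(message_ids(gold), parse_errors(results)$message_id)
  res_tbl <- tibble::as_tibble(results)
  gold_tbl <- tibble::as_tibble(gold)
  rows <- list()
  for (mid in ids) {
    r <- res_tbl[res_tbl$message_id == mid, ]
    g <- gold_tbl[gold_tbl$message_id == mid, ]
    same <- all(vapply(m_classes(), function(cls) {
      identical(
        sort(norm_text(r$span[r$m_class == cls])),
        sort(norm_text(g$span[g$m_class == cls]))
      )
    }, logical(1)))
    if (same) next
    txt <- if (!is.null(messages)) {
      messages$text[match(mid, messages$message_id)]
    } else {
      mid
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      message_id = mid,
      prompt = gsub("{text}", txt, prompt_template, fixed = TRUE),
      chosen = spans_to_json(g),
      rejected = spans_to_json(r)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      message_id = character(), prompt = character(),
      chosen = character(), rejected = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Default extraction prompt template
#'
#' A documented slot for the instruction text sent to generative extractor
#' adapters; the exact production prompt is adapter configuration.
#'
#' @return Template string with a `{text}` placeholder.
#' @export
default_prompt_template <- function() {
  paste0(
    "Extract words or phrases related to the 4M framework concepts ",
    "(What Matters, Medication, Mentation, Mobility) from the message ",
    "below. Respond with a JSON object with keys what_matters, medication, ",
    "mentation, mobility, each a list of extracted phrases; use empty ",
    "lists when a concept is absent.\n\nMessage: {text}"
  )
}

#' Split preference pairs into train and validation sets
#'
#' The split is by message id, so no message leaks across sets, and is
#' reproducible under a fixed seed. Fatal when `n_validation` is not
#' smaller than the number of pairs or cannot be met exactly by whole
#' messages.
#'
#' @param pairs Pair tibble from [build_preference_pairs()].
#' @param n_validation Number of pairs to hold out.
#' @param seed Integer seed.
#' @return List with `train` and `validation` tibbles.
#' @export
split_pairs <- function(pairs, n_validation, seed) {
  if (n_validation >= nrow(pairs)) {
    stop("n_validation must be smaller than the number of pairs", call. = FALSE)
  }
  ids <- unique(pairs$message_id)
  shuffled <- withr::with_seed(seed, sample(ids))
  sizes <- table(pairs$message_id)[shuffled]
  cum <- cumsum(as.integer(sizes))
  k <- which(cum == n_validation)
  if (length(k) == 0) {
    stop("cannot split exactly at ", n_validation, " pairs by message",
      call. = FALSE
    )
  }
  val_ids <- shuffled[seq_len(k[1])]
  list(
    train = pairs[!pairs$message_id %in% val_ids, ],
    validation = pairs[pairs$message_id %in% val_ids, ]
  )
}

#' Write or read preference pairs as JSON lines
#'
#' One JSON object per line with keys `prompt`, `chosen`, `rejected`,
#' `message_id` — the common preference-tuning interchange shape.
#'
#' @param pairs Pair tibble.
#' @param path File path.
#' @export
write_preference_pairs <- function(pairs, path) {
  lines <- vapply(seq_len(nrow(pairs)), function(i) {
    as.character(jsonlite::toJSON(
      list(
        prompt = pairs$prompt[i], chosen = pairs$chosen[i],
        rejected = pairs$rejected[i], message_id = pairs$message_id[i]
      ),
      auto_unbox = TRUE
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_preference_pairs
#' @export
read_preference_pairs <- function(path) {
  lines <- readLines(path)
  purrr::map_dfr(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble::tibble(
      message_id = x$message_id, prompt = x$prompt,
      chosen = x$chosen, rejected = x$rejected
    )
  })
}
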