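#' Build a class lexicon
#'
#' A lexicon maps each 4M class to a set of phrases; it drives the
#' deterministic reference extractor ([lexicon_extract()]) and is also the
#' planted vocabulary of the synthetic generator. Phrases must be non-empty
#' and no phrase may be assigned to two classes.
#'
#' @param entries Named list (names from [m_classes()]) of character vectors.
#' @param match_mode `"exact"` or `"fuzzy"` (recorded; the reference
#'   extractor matches exactly on normalized text).
#' @return A `fourms_lexicon` object.
#' @export
lexicon <- function(entries, match_mode = c("exact", "fuzzy")) {
  match_mode <- match.arg(match_mode)
  stopifnot(is.list(entries), all(names(entries) %in% m_classes()))
  entries <- lapply(entries, function(p) unique(as.character(p)))
  if (any(vapply(entries, function(p) any(!nzchar(trimws(p))), logical(1)))) {
    stop("lexicon phrases must be non-empty", call. = FALSE)
  }
  all_norm <- norm_text(unlist(entries, use.names = FALSE))
  if (anyDuplicated(all_norm)) {
    stop(
      "phrase assigned to more than one class: ",
      all_norm[duplicated(all_norm)][1],
      call. = FALSE
    )
  }
  structure(list(entries = entries, match_mode = match_mode),
    class = "fourms_lexicon"
  )
}

#' @export
print.fourms_lexicon <- function(x, ...) {
  cat("<fourms_lexicon> ", sum(lengths(x$entries)), " phrases in ",
    length(x$entries), " classes\n",
    sep = ""
  )
  invisible(x)
}

# Constructor for the extraction-result set. Long span tibble plus the
# message universe (so all-zero messages are represented) and a parse-error
# audit table.
new_extractions <- function(spans, message_ids, parse_errors = NULL) {
  if (is.null(parse_errors)) {
    parse_errors <- tibble::tibble(
      message_id = character(), raw = character(), reason = character()
    )
  }
  spans <- tibble::as_tibble(spans)
  structure(
    spans,
    message_ids = message_ids,
    parse_errors = parse_errors,
    class = c("fourms_extractions", class(spans))
  )
}

empty_span_tbl <- function() {
  tibble::tibble(
    message_id = character(), m_class = character(),
    span = character(), valid = logical(), flag = character()
  )
}

#' Message universe of an extraction set
#' @param x A `fourms_extractions` object.
#' @return Character vector of message ids covered (including all-zero ones).
#' @export
message_ids <- function(x) attr(x, "message_ids")

#' Parse-error audit table of an extraction run
#' @param x A `fourms_extractions` object.
#' @return Tibble with `message_id`, `raw`, `reason`.
#' @export
parse_errors <- function(x) attr(x, "parse_errors")

# ---- structured-output parsing ---------------------------------------------

# Accepted aliases for class keys in raw structured output.
class_key_aliases <- function() {
  c(
    what_matters = "what_matters", `what matters` = "what_matters",
    whatmatters = "what_matters",
    medication = "medication", medications = "medication",
    mentation = "mentation", mobility = "mobility"
  )
}

#' Parse one raw structured extractor output
#'
#' Extractors emit a JSON object mapping class names to lists of phrases.
#' Missing classes default to empty lists; unknown keys are flagged rather
#' than fatal; a syntactically invalid blob yields an error record carrying
#' the raw text for audit, never partial counts.
#'
#' @param raw Raw text blob from an extractor.
#' @param message_id Message the blob belongs to.
#' @return List with `spans` (tibble: message_id, m_class, span, valid,
#'   flag), `error` (`NULL` or reason string) and `flags`.
#' @export
parse_extraction_output <- function(raw, message_id) {
  parsed <- tryCatch(
    jsonlite::fromJSON(raw, simplifyVector = FALSE),
    error = function(e) e
  )
  if (inherits(parsed, "error") || !is.list(parsed) ||
    (length(parsed) > 0 && is.null(names(parsed)))) {
    return(list(
      spans = empty_span_tbl(), error = "invalid structured output",
      flags = character()
    ))
  }
  aliases <- class_key_aliases()
  flags <- character()
  rows <- list()
  for (k in names(parsed)) {
    cls <- unname(aliases[tolower(k)])
    if (is.na(cls) || is.null(cls)) {
      flags <- c(flags, paste0("unknown_key:", k))
      next
    }
    vals <- unlist(parsed[[k]], use.names = FALSE)
    vals <- as.character(vals)
    vals <- vals[nzchar(trimws(vals))]
    if (length(vals) > 0) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        message_id = message_id, m_class = cls, span = vals,
        valid = TRUE, flag = NA_character_
      )
    }
  }
  spans <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty_span_tbl()
  list(spans = spans, error = NULL, flags = flags)
}

#' Serialize per-class spans as the structured output schema
#'
#' Renders the JSON object shape extractors are expected to emit: all four
#' class keys, each a (possibly empty) array of phrases.
#'
#' @param spans_by_class Named list (class -> character vector).
#' @return Single JSON string.
#' @export
render_extraction_json <- function(spans_by_class) {
  out <- lapply(m_classes(), function(cls) {
    v <- spans_by_class[[cls]]
    if (is.null(v)) character() else as.character(v)
  })
  names(out) <- m_classes()
  as.character(jsonlite::toJSON(out, auto_unbox = FALSE))
}

# ---- lexicon matching ------------------------------------------------------

# All non-overlapping lexicon matches in one normalized text, longest match
# first within each class. Returns tibble (m_class, span, start).
match_lexicon_one <- function(ntext, lexicon) {
  rows <- list()
  for (cls in names(lexicon$entries)) {
    phrases <- lexicon$entries[[cls]]
    nphr <- norm_text(phrases)
    ord <- order(-nchar(nphr))
    taken <- matrix(numeric(0), ncol = 2)
    for (i in ord) {
      pat <- paste0("\\b\\Q", nphr[i], "\\E\\b")
      loc <- stringr::str_locate_all(ntext, pat)[[1]]
      if (nrow(loc) == 0) next
      for (r in seq_len(nrow(loc))) {
        s <- loc[r, 1]
        e <- loc[r, 2]
        overlaps <- nrow(taken) > 0 &&
          any(s <= taken[, 2] & e >= taken[, 1])
        if (!overlaps) {
          taken <- rbind(taken, c(s, e))
          rows[[length(rows) + 1]] <- tibble::tibble(
            m_class = cls, span = phrases[i], start = s
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      m_class = character(), span = character(), start = numeric()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}

#' Deterministic lexicon extractor
#'
#' The reference extractor: returns every lexicon phrase occurring in each
#' message's normalized text, longest-match-first and non-overlapping within
#' a class. Deterministic for fixed input, so it serves as the test double
#' for generative-model adapters.
#'
#' @param messages Message tibble.
#' @param lexicon A [lexicon()].
#' @return A `fourms_extractions` object over the messages.
#' @export
lexicon_extract <- function(messages, lexicon) {
  stopifnot(inherits(lexicon, "fourms_lexicon"))
  ntexts <- norm_text(messages$text)
  # cheap pre-filter: only locate phrases actually present as substrings
  all_phr <- unlist(lexicon$entries, use.names = FALSE)
  all_cls <- rep(names(lexicon$entries), lengths(lexicon$entries))
  nphr <- norm_text(all_phr)
  present <- lapply(seq_along(nphr), function(i) {
    which(stringr::str_detect(ntexts, stringr::fixed(nphr[i])))
  })
  by_msg <- split(
    rep(seq_along(present), lengths(present)),
    unlist(present)
  )
  msg_hits <- as.integer(names(by_msg))
  rows <- vector("list", length(msg_hits))
  for (j in seq_along(msg_hits)) {
    mi <- msg_hits[j]
    cand_idx <- by_msg[[j]]
    sub_lex <- list(entries = split(all_phr[cand_idx], all_cls[cand_idx]))
    hits <- match_lexicon_one(ntexts[mi], sub_lex)
    if (nrow(hits) > 0) {
      rows[[j]] <- tibble::tibble(
        message_id = messages$message_id[mi],
        m_class = hits$m_class, span = hits$span,
        valid = TRUE, flag = NA_character_
      )
    }
  }
  spans <- dplyr::bind_rows(rows)
  if (nrow(spans) == 0) spans <- empty_span_tbl()
  new_extractions(spans, messages$message_id)
}

#' Decoding configuration passed to extractor plug-ins
#'
#' Defaults mirror the deterministic decoding settings used for local
#' generative extraction (temperature 0.0, top_p 0.9, top_k 40, no repeat
#' penalty, seed 418). The configuration is passed through opaquely; it is
#' inert for non-LLM extractors such as the lexicon reference extractor.
#'
#' @param temperature,top_p,top_k,repeat_penalty,seed Decoding parameters.
#' @return Named list.
#' @export
decoding_config <- function(temperature = 0.0, top_p = 0.9, top_k = 40,
                            repeat_penalty = NULL, seed = 418) {
  list(
    temperature = temperature, top_p = top_p, top_k = top_k,
    repeat_penalty = repeat_penalty, seed = seed
  )
}

#' Wrap a lexicon as an extractor plug-in
#'
#' @param lexicon A [lexicon()].
#' @return A function `(text, decoding) -> raw JSON string` satisfying the
#'   extractor plug-in contract.
#' @export
lexicon_extractor <- function(lexicon) {
  force(lexicon)
  function(text, decoding = decoding_config()) {
    hits <- match_lexicon_one(norm_text(text), lexicon)
    render_extraction_json(split(hits$span, factor(hits$m_class, m_classes())))
  }
}

#' Run an extractor plug-in over a corpus
#'
#' Applies the plug-in to every message and parses the raw structured
#' output. A plug-in failure or malformed output on one message yields an
#' error record for that message and the run continues (fault isolation).
#'
#' @param messages Message tibble.
#' @param extractor Plug-in: function `(text, decoding) -> raw text`.
#' @param decoding A [decoding_config()], passed through opaquely.
#' @return A `fourms_extractions` object; failures are in [parse_errors()].
#' @export
run_extractor <- function(messages, extractor, decoding = decoding_config()) {
  rows <- vector("list", nrow(messages))
  errs <- list()
  for (i in seq_len(nrow(messages))) {
    mid <- messages$message_id[i]
    raw <- tryCatch(extractor(messages$text[i], decoding), error = function(e) e)
    if (inherits(raw, "error")) {
      why <- paste0("extractor error: ", conditionMessage(raw))
      errs[[length(errs) + 1]] <- tibble::tibble(
        message_id = mid, raw = NA_character_, reason = why
      )
      next
    }
    parsed <- parse_extraction_output(raw, mid)
    if (!is.null(parsed$error)) {
      errs[[length(errs) + 1]] <- tibble::tibble(
        message_id = mid, raw = as.character(raw), reason = parsed$error
      )
      next
    }
    rows[[i]] <- parsed$spans
  }
  spans <- dplyr::bind_rows(rows)
  if (nrow(spans) == 0) spans <- empty_span_tbl()
  new_extractions(
    spans, messages$message_id,
    parse_errors = if (length(errs) > 0) dplyr::bind_rows(errs) else NULL
  )
}

#' Screen extracted spans against their source message
#'
#' The hallucination screen: each span must occur in its message's text at
#' or above `similarity_floor` under the normalized fuzzy-substring score of
#' [fuzzy_substring_score()]. A floor of 1.0 requires an exact (normalized)
#' substring; the default 0.85 tolerates typo variants. Failing spans are
#' flagged `"hallucination"`, marked invalid, and excluded from counts, but
#' retained in the table for audit.
#'
#' @param results A `fourms_extractions` object.
#' @param messages Message tibble supplying the source texts.
#' @param similarity_floor Fraction in \[0, 1\].
#' @return The extraction set with `valid`/`flag` updated.
#' @export
validate_spans <- function(results, messages, similarity_floor = 0.85) {
  stopifnot(similarity_floor >= 0, similarity_floor <= 1)
  if (nrow(results) == 0) return(results)
  txt <- messages$text[match(results$message_id, messages$message_id)]
  if (anyNA(txt)) {
    stop("extraction references unknown message_id: ",
      results$message_id[which(is.na(txt))[1]],
      call. = FALSE
    )
  }
  score <- mapply(fuzzy_substring_score, results$span, txt, USE.NAMES = FALSE)
  ok <- score >= similarity_floor
  out <- results
  out$valid <- ok
  out$flag <- ifelse(ok, out$flag, "hallucination")
  new_extractions(
    tibble::as_tibble(out)[names(empty_span_tbl())],
    message_ids(results), parse_errors(results)
  )
}

#' Per-message, per-class counts and binary presence
#'
#' Derives the count representation from an extraction set: one row per
#' (message, class) over the full message universe, `count` the number of
#' validated spans (duplicate identical spans count separately) and
#' `binary` its presence indicator. Messages with no 4M content carry
#' explicit zeros.
#'
#' @param x A `fourms_extractions` object, or a gold standard from
#'   [reconcile()].
#' @return Tibble `message_id`, `m_class`, `count`, `binary`.
#' @export
extraction_counts <- function(x) {
  spans <- tibble::as_tibble(x)
  if ("valid" %in% names(spans)) spans <- spans[spans$valid, ]
  g <- count_grid(spans, message_ids(x))
  tibble::tibble(
    message_id = g$message_id, m_class = g$m_class,
    count = as.integer(g$n), binary = as.integer(g$n > 0)
  )
}

#' @export
print.fourms_extractions <- function(x, ...) {
  nv <- sum(x$valid)
  cat(
    "<fourms_extractions> ", nv, " valid spans (", nrow(x) - nv,
    " flagged) over ", length(message_ids(x)), " messages; ",
    nrow(parse_errors(x)), " parse errors\n",
    sep = ""
  )
  invisible(x)
}
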