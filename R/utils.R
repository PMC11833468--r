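#' The four 4M framework classes
#'
#' Stable serialization names for the Age-Friendly Health Systems 4M
#' framework concepts, in canonical order: What Matters, Medication,
#' Mentation, Mobility.
#'
#' @return Character vector of the four class names.
#' @export
m_classes <- function() {
  c("what_matters", "medication", "mentation", "mobility")
}

#' Sender/receiver role values
#'
#' @return Character vector of the role enumeration used in message metadata.
#' @export
sender_roles <- function() {
  c("nursing_staff", "aprn", "physician", "other_staff")
}

# Display names for class roots and reports.
m_class_labels <- function() {
  c(
    what_matters = "What Matters", medication = "Medication",
    mentation = "Mentation", mobility = "Mobility"
  )
}

#' Normalize free text for matching
#'
#' Case-folds, replaces punctuation with spaces, and collapses runs of
#' whitespace. All phrase/span comparisons in the package operate on this
#' normalized form.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
norm_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^[:alnum:]]+", " ", x)
  trimws(x)
}

# Vectorized coalescing timestamp parser: minute- or second-precision
# ISO-8601, "T" or space separator, treated as timezone-naive (stored UTC).
parse_timestamp <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M", tz = "UTC"))
  }
  out
}

format_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M", tz = "UTC")
}

#' Fuzzy-substring similarity of a span against a text
#'
#' Scores how well `span` aligns to the best-matching substring of `text`,
#' as `1 - d/nchar(span)` where `d` is the minimum edit distance between the
#' normalized span and any contiguous substring of the normalized text
#' (an infix alignment: prefix/suffix of the text are free). A score of 1
#' means the span occurs verbatim (after normalization); the hallucination
#' screen in [validate_spans()] flags spans scoring below its floor.
#'
#' @param span Single candidate span string.
#' @param text Single source text.
#' @return Similarity in \[0, 1\].
#' @export
fuzzy_substring_score <- function(span, text) {
  s <- norm_text(span)
  t <- norm_text(text)
  if (!nzchar(s)) return(0)
  if (!nzchar(t)) return(0)
  if (grepl(s, t, fixed = TRUE)) return(1)
  sc <- utf8ToInt(s)
  tc <- utf8ToInt(t)
  m <- length(sc)
  n <- length(tc)
  # Infix edit-distance DP, row-vectorized. cur[j+1] = min(prev[j] + cost,
  # prev[j+1] + 1, cur[j] + 1); the left-to-right insertion term is folded
  # in with a cummin over (candidate - index).
  prev <- rep(0L, n + 1L)
  idx <- 0:n
  for (i in seq_len(m)) {
    cost <- as.integer(tc != sc[i])
    cand <- c(i, pmin(prev[2:(n + 1)] + 1L, prev[1:n] + cost))
    prev <- idx + cummin(cand - idx)
  }
  max(0, 1 - min(prev) / m)
}

# Full-string similarity between two phrases (for annotation diffing):
# 1 - levenshtein / max length, on normalized text.
phrase_similarity <- function(x, y) {
  nx <- norm_text(x)
  ny <- norm_text(y)
  d <- utils::adist(nx, ny)
  len <- outer(nchar(nx), nchar(ny), pmax)
  len[len == 0] <- 1L
  sim <- 1 - d / len
  sim[nx == ny] <- 1
  sim
}

# Row-normalize a matrix to unit L2 norm; errors on zero rows.
unit_rows <- function(m, what = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("zero-norm ", what, " at row ", which(nrm == 0)[1], call. = FALSE)
  }
  m / nrm
}

cosine_sim <- function(a, b) {
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# Deterministic 25-bit string hash (FNV-style, kept under 2^25 so the
# double-precision multiply is exact). Used to key per-phrase noise and
# fallback embedding vectors.
str_hash <- function(x, seed = 0L) {
  vapply(x, function(s) {
    h <- 216613
    for (b in utf8ToInt(s)) {
      h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 33554393
    }
    as.integer((h + as.numeric(seed)) %% 33554393)
  }, integer(1), USE.NAMES = FALSE)
}

# Complete a (message_id, m_class) span table into a wide count grid with
# explicit zeros over the given message universe.
count_grid <- function(spans, message_ids) {
  base <- tidyr::expand_grid(
    message_id = message_ids,
    m_class = m_classes()
  )
  if (nrow(spans) == 0) {
    counted <- tibble::tibble(
      message_id = character(), m_class = character(), n = integer()
    )
  } else {
    counted <- dplyr::count(spans, .data$message_id, .data$m_class)
  }
  out <- dplyr::left_join(base, counted, by = c("message_id", "m_class"))
  out$n[is.na(out$n)] <- 0L
  out
}
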