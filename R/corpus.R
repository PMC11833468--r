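#' Read a message corpus from a delimited file
#'
#' Messages are comma-delimited UTF-8 with a header row:
#' `message_id,resident_id,facility_id,sender_role,receiver_role,timestamp,text`.
#' Timestamps are timezone-naive ISO-8601 at minute (or second) precision.
#' Malformed rows (unparseable timestamp, empty text after whitespace
#' normalization) are not dropped silently: they are collected into a rejects
#' table attached as the `"rejects"` attribute and retrievable with
#' [rejects()].
#'
#' @param path Path to the file.
#' @return A tibble of messages; attribute `"rejects"` holds a tibble of the
#'   rejected raw rows with a `reason` column.
#' @export
read_messages <- function(path) {
  if (!file.exists(path)) stop("message file not found: ", path, call. = FALSE)
  required <- c(
    "message_id", "resident_id", "facility_id", "sender_role",
    "receiver_role", "timestamp", "text"
  )
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- raw[required]
  ts <- parse_timestamp(raw$timestamp)
  empty <- !nzchar(trimws(ifelse(is.na(raw$text), "", raw$text)))
  bad_ts <- is.na(ts)
  reason <- dplyr::case_when(
    empty ~ "empty text",
    bad_ts ~ "unparseable timestamp",
    .default = NA_character_
  )
  keep <- is.na(reason)
  msgs <- raw[keep, ]
  msgs$timestamp <- ts[keep]
  rejects <- raw[!keep, ]
  rejects$reason <- reason[!keep]
  msgs <- tibble::as_tibble(msgs)
  attr(msgs, "rejects") <- tibble::as_tibble(rejects)
  msgs
}

#' @rdname read_messages
#' @param messages Message tibble (as returned by [read_messages()] or
#'   [generate_corpus()]).
#' @export
write_messages <- function(messages, path) {
  out <- messages
  out$timestamp <- format_timestamp(out$timestamp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Rejected-row report from a corpus load
#'
#' @param x Object returned by [read_messages()].
#' @return Tibble of rejected rows (possibly empty) with a `reason` column.
#' @export
rejects <- function(x) {
  r <- attr(x, "rejects")
  if (is.null(r)) tibble::tibble() else r
}

#' Read or write transfer events
#'
#' Events are comma-delimited with header `event_id,resident_id,transfer_time`.
#'
#' @param path File path.
#' @return Tibble with parsed `transfer_time`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(c("event_id", "resident_id", "transfer_time"), names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw$transfer_time <- parse_timestamp(raw$transfer_time)
  tibble::as_tibble(raw)
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  out <- events
  out$transfer_time <- format_timestamp(out$transfer_time)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove duplicate messages
#'
#' The default duplicate key is every field, with the message text compared
#' after whitespace/punctuation-free normalization — the safest key, which
#' cannot merge distinct clinical events. `key = "resident_time_text"`
#' restricts the key to (resident_id, timestamp, normalized text). The first
#' occurrence in input order is retained.
#'
#' @param messages Message tibble.
#' @param key `"all"` (default) or `"resident_time_text"`.
#' @return The deduplicated tibble; attribute `"removed_count"` records how
#'   many rows were dropped (see [removed_count()]).
#' @export
dedupe_messages <- function(messages, key = c("all", "resident_time_text")) {
  key <- match.arg(key)
  norm <- norm_text(messages$text)
  keydf <- if (key == "all") {
    data.frame(
      messages$message_id, messages$resident_id, messages$facility_id,
      messages$sender_role, messages$receiver_role,
      as.numeric(messages$timestamp), norm
    )
  } else {
    data.frame(messages$resident_id, as.numeric(messages$timestamp), norm)
  }
  dup <- duplicated(keydf)
  out <- messages[!dup, ]
  attr(out, "removed_count") <- sum(dup)
  out
}

#' @rdname dedupe_messages
#' @param x Result of [dedupe_messages()].
#' @export
removed_count <- function(x) {
  rc <- attr(x, "removed_count")
  if (is.null(rc)) 0L else rc
}

#' Link messages to pre-transfer windows
#'
#' A message is linked to a transfer event when it belongs to the same
#' resident and its timestamp falls in the half-open window
#' `(transfer_time - window_days, transfer_time]` — a message sent at the
#' transfer instant is included, the same instant `window_days` earlier is
#' not. A message may link to several events.
#'
#' @param messages Message tibble.
#' @param events Event tibble.
#' @param window_days Positive window length in days (default 14, i.e. the
#'   two weeks preceding a transfer).
#' @return A linked-corpus object: list with `messages`, `events` and a
#'   `links` tibble (`event_id`, `message_id`).
#' @export
link_to_transfers <- function(messages, events, window_days = 14) {
  stopifnot(window_days > 0)
  joined <- dplyr::inner_join(
    dplyr::select(messages, "message_id", "resident_id", "timestamp"),
    dplyr::select(events, "event_id", "resident_id", "transfer_time"),
    by = "resident_id",
    relationship = "many-to-many"
  )
  w <- window_days * 86400
  hit <- joined$timestamp > joined$transfer_time - w &
    joined$timestamp <= joined$transfer_time
  links <- tibble::tibble(
    event_id = joined$event_id[hit],
    message_id = joined$message_id[hit]
  )
  links <- dplyr::arrange(links, .data$event_id, .data$message_id)
  structure(
    list(
      messages = messages, events = events, links = links,
      window_days = window_days
    ),
    class = "fourms_corpus"
  )
}

#' @export
print.fourms_corpus <- function(x, ...) {
  cat(
    "<fourms_corpus> ", nrow(x$messages), " messages, ",
    nrow(x$events), " transfer events, ", nrow(x$links),
    " links (window ", x$window_days, " d)\n",
    sep = ""
  )
  invisible(x)
}
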