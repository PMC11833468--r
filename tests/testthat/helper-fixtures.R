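# Small in-code fixtures shared across test files.

# data.frame comparison that ignores bookkeeping attributes (rejects,
# removed_count, merge_map, message_ids, ...)
plain_df <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  rownames(d) <- NULL
  d
}

make_messages <- function(texts,
                          ids = sprintf("M%03d", seq_along(texts)),
                          resident = "R001",
                          sender = "nursing_staff",
                          receiver = "aprn",
                          t0 = as.POSIXct("2016-03-01 10:00", tz = "UTC")) {
  tibble::tibble(
    message_id = ids,
    resident_id = rep_len(resident, length(texts)),
    facility_id = "F01",
    sender_role = rep_len(sender, length(texts)),
    receiver_role = rep_len(receiver, length(texts)),
    timestamp = t0 + 3600 * seq_along(texts),
    text = texts
  )
}

tiny_lexicon <- function() {
  lexicon(list(
    medication = c("prn morphine", "lasix dosage adjusted"),
    mobility = c("gait stride assisted", "walker footing supervised"),
    mentation = c("confusion episode worsening"),
    what_matters = c("family wishes honored")
  ))
}

# A tiny embedded expression set with two well-separated planted groups.
make_embedded_expressions <- function(n_per = 4, d = 8, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    c1 <- rnorm(d)
    c2 <- rnorm(d) + sep
    v <- rbind(
      t(replicate(n_per, c1 + rnorm(d, sd = 0.1))),
      t(replicate(n_per, c2 + rnorm(d, sd = 0.1)))
    )
    tibble::tibble(
      text = sprintf("expr %02d", seq_len(2 * n_per)),
      m_class = "medication",
      provenance = as.list(sprintf("M%03d", seq_len(2 * n_per))),
      vector = v
    )
  })
}
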