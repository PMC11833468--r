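ann <- function(id, ...) {
  rows <- list(...)
  out <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      annotator_id = id, message_id = r[[1]], m_class = r[[2]], phrase = r[[3]]
    )
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      annotator_id = character(), message_id = character(),
      m_class = character(), phrase = character()
    )
  }
  out
}

test_that("identical annotation sets have zero differences", {
  a <- ann("A", list("M1", "mentation", "confusion episode"))
  b <- ann("B", list("M1", "mentation", "Confusion  episode."))
  d <- diff_annotations(a, b)
  expect_equal(nrow(d), 0)
})

test_that("a phrase one annotator missed is exactly one difference", {
  a <- ann(
    "A",
    list("M1", "mentation", "symbolic disfunction"),
    list("M1", "medication", "lasix held")
  )
  b <- ann("B", list("M1", "medication", "lasix held"))
  d <- diff_annotations(a, b)
  expect_equal(nrow(d), 1)
  expect_equal(d$m_class, "mentation")
  expect_equal(d$annotator, "A")
  per <- attr(d, "per_class")
  expect_equal(per$differences[per$m_class == "mentation"], 1)
})

test_that("near-identical variants count as the same phrase when diffing", {
  a <- ann("A", list("M1", "mentation", "symbolic disfunction"))
  b <- ann("B", list("M1", "mentation", "symbolic dysfunction"))
  expect_equal(nrow(diff_annotations(a, b)), 0)
  expect_equal(nrow(diff_annotations(a, b, fuzzy_threshold = 1)), 2)
})

test_that("reconcile merges intersection with accepted differences", {
  a <- ann(
    "A",
    list("M1", "mentation", "symbolic disfunction"),
    list("M1", "medication", "lasix held"),
    list("M2", "mobility", "gait unsteady")
  )
  b <- ann(
    "B",
    list("M1", "medication", "lasix held"),
    list("M2", "mobility", "gait unsteady"),
    list("M2", "what_matters", "family meeting wishes")
  )
  adj <- tibble::tibble(
    message_id = c("M1", "M2"),
    m_class = c("mentation", "what_matters"),
    phrase = c("symbolic disfunction", "family meeting wishes"),
    decision = c("accept", "reject")
  )
  gold <- reconcile(a, b, adj)
  expect_s3_class(gold, "fourms_gold")
  expect_setequal(
    gold$span,
    c("symbolic disfunction", "lasix held", "gait unsteady")
  )
  prov <- gold$provenance[gold$span == "symbolic disfunction"]
  expect_equal(prov, "A_only_accepted")
  # all-reject -> pure intersection; no adjudications + differences -> fatal
  adj_rej <- dplyr::mutate(adj, decision = "reject")
  gold2 <- reconcile(a, b, adj_rej)
  expect_setequal(gold2$span, c("lasix held", "gait unsteady"))
  expect_error(reconcile(a, b, adj[0, ]), "unadjudicated")
})

test_that("no differences means gold equals either annotator", {
  a <- ann("A", list("M1", "medication", "lasix held"))
  b <- ann("B", list("M1", "medication", "lasix held"))
  gold <- reconcile(a, b, tibble::tibble(
    message_id = character(), m_class = character(), phrase = character(),
    decision = character()
  ))
  expect_equal(gold$span, "lasix held")
  expect_equal(gold$provenance, "both")
})

test_that("evaluation of results generated from gold is perfect", {
  sim <- generate_corpus(generator_config(seed = 31, n_messages = 120))
  gold <- gold_from_truth(sim$truth)
  res <- lexicon_extract(sim$messages, sim$lexicon)
  ev <- evaluate_extractions(res, gold)
  expect_true(all(ev$per_class$kappa == 1))
  expect_true(all(ev$per_class$mae == 0))
  expect_equal(ev$overall_kappa, 1)
  expect_true(ev$gate_passed)
})

test_that("a noisy extractor fails the kappa gate", {
  sim <- generate_corpus(generator_config(seed = 32, n_messages = 200))
  gold <- gold_from_truth(sim$truth)
  bad <- simulate_extractor_errors(gold, fpr = 0.45, fnr = 0.45,
    lexicon = sim$lexicon, seed = 1
  )
  ev2 <- evaluate_extractions(bad, gold)
  expect_false(ev2$gate_passed)
})

test_that("evaluation is invariant to message order", {
  sim <- generate_corpus(generator_config(seed = 33, n_messages = 100))
  gold <- gold_from_truth(sim$truth)
  res <- lexicon_extract(sim$messages, sim$lexicon)
  shuffled <- withr::with_seed(5, sim$messages[sample(nrow(sim$messages)), ])
  res2 <- lexicon_extract(shuffled, sim$lexicon)
  e1 <- evaluate_extractions(res, gold)
  e2 <- evaluate_extractions(res2, gold)
  expect_equal(e1$per_class, e2$per_class)
  expect_equal(e1$overall_kappa, e2$overall_kappa)
})

test_that("preference pairs appear exactly for discrepant messages", {
  sim <- generate_corpus(generator_config(seed = 34, n_messages = 150))
  gold <- gold_from_truth(sim$truth)
  res <- simulate_extractor_errors(gold, fpr = 0.05, fnr = 0.15,
    lexicon = sim$lexicon, seed = 4
  )
  flips <- attr(res, "flips")
  d <- length(unique(flips$message_id))
  pairs <- build_preference_pairs(res, gold, messages = sim$messages)
  expect_equal(nrow(pairs), d)
  expect_true(all(pairs$chosen != pairs$rejected))
  expect_true(all(vapply(pairs$chosen, jsonlite::validate, logical(1))))
  # agreement everywhere -> no pairs
  perfect <- lexicon_extract(sim$messages, sim$lexicon)
  expect_equal(nrow(build_preference_pairs(perfect, gold)), 0)
})

test_that("a spurious span produces one pair with the span only in rejected", {
  sim <- generate_corpus(generator_config(seed = 35, n_messages = 30))
  gold <- gold_from_truth(sim$truth)
  res <- lexicon_extract(sim$messages, sim$lexicon)
  spur <- fourms:::new_extractions(
    dplyr::bind_rows(
      tibble::as_tibble(res),
      tibble::tibble(
        message_id = sim$messages$message_id[1], m_class = "medication",
        span = "warfarin bolus held", valid = TRUE, flag = NA_character_
      )
    ),
    message_ids(res)
  )
  pairs <- build_preference_pairs(spur, gold)
  expect_equal(nrow(pairs), 1)
  expect_true(grepl("warfarin bolus held", pairs$rejected))
  expect_false(grepl("warfarin bolus held", pairs$chosen))
})

test_that("pair splitting is by message, exact, and seed-reproducible", {
  pairs <- tibble::tibble(
    message_id = sprintf("M%03d", 1:332),
    prompt = "p", chosen = sprintf("c%d", 1:332), rejected = "r"
  )
  sp <- split_pairs(pairs, 66, seed = 9)
  expect_equal(nrow(sp$train), 266)
  expect_equal(nrow(sp$validation), 66)
  expect_length(intersect(sp$train$message_id, sp$validation$message_id), 0)
  sp2 <- split_pairs(pairs, 66, seed = 9)
  expect_identical(sp, sp2)
  sp3 <- split_pairs(pairs, 66, seed = 10)
  expect_false(identical(sort(sp$validation$message_id),
    sort(sp3$validation$message_id)
  ))
  expect_error(split_pairs(pairs, 332, seed = 1), "smaller")
})

test_that("preference pairs round-trip through the JSON-lines file", {
  pairs <- tibble::tibble(
    message_id = c("M1", "M2"), prompt = c("p1", "p2"),
    chosen = c('{"a":1}', '{"b":2}'), rejected = c('{"c":3}', '{"d":4}')
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_preference_pairs(pairs, path)
  back <- read_preference_pairs(path)
  expect_equal(plain_df(back), plain_df(pairs))
})

test_that("annotation files round-trip", {
  a <- ann("A", list("M1", "mentation", "confusion episode"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(a, path)
  expect_equal(plain_df(read_annotations(path)), plain_df(a))
})
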