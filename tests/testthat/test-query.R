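labeled_synthetic_taxonomy <- function(seed = 51) {
  cfg <- generator_config(seed = seed)
  voc <- make_vocabulary(cfg)
  emb <- synthetic_embedder(cfg, voc$phrases)
  expr <- embed_expressions(
    tibble::tibble(
      text = voc$phrases$phrase, m_class = voc$phrases$m_class,
      provenance = as.list(voc$phrases$phrase)
    ),
    emb
  )
  targets <- lapply(split(voc$phrases, voc$phrases$m_class), function(s) {
    c(
      length(unique(s$l1)), nrow(unique(s[, c("l1", "l2")])),
      nrow(unique(s[, c("l1", "l2", "l3")])), length(unique(s$leaf_id))
    )
  })
  list(
    tax = label_clusters(build_taxonomy(expr, target_counts = targets)),
    emb = emb, vocab = voc$phrases
  )
}

test_that("a verbatim term yields its full ancestor chain to the class root", {
  fx <- labeled_synthetic_taxonomy()
  term <- fx$tax$expressions$text[1]
  cls <- fx$tax$expressions$m_class[1]
  g <- query_concept(fx$tax, term)
  expect_false(isTRUE(attr(g, "no_matches")))
  expr_nodes <- g$nodes[g$nodes$kind == "expression", ]
  expect_true(term %in% expr_nodes$label)
  expect_equal(sum(g$nodes$kind == "class_root"), 1)
  expect_equal(g$nodes$m_class[g$nodes$kind == "class_root"], cls)
  # chain: expression + one cluster per level + root
  eid <- expr_nodes$node_id[expr_nodes$label == term]
  chain <- 0
  cur <- eid
  repeat {
    up <- g$edges$from[g$edges$to == cur]
    if (length(up) == 0) break
    expect_length(up, 1) # exactly one path to the root
    cur <- up
    chain <- chain + 1
  }
  expect_equal(chain, 5) # 4 cluster levels + class root
})

test_that("an unmatched term returns flagged roots only", {
  fx <- labeled_synthetic_taxonomy()
  g <- query_concept(fx$tax, "zzzqqqxx")
  expect_true(attr(g, "no_matches"))
  expect_true(all(g$nodes$kind == "class_root"))
  expect_equal(nrow(g$edges), 0)
  expect_true(all(g$counts$n_matches == 0))
})

test_that("per-class match counts equal planted term occurrences", {
  fx <- labeled_synthetic_taxonomy()
  # word banks guarantee each word belongs to one class; count per class
  # across two different words from two classes
  word_counts <- function(term) {
    vapply(m_classes(), function(cls) {
      sum(grepl(
        paste0("\\b", term, "\\b"),
        fx$vocab$phrase[fx$vocab$m_class == cls]
      ))
    }, numeric(1))
  }
  for (term in c("lasix", "gait")) {
    planted <- word_counts(term)
    g <- query_concept(fx$tax, term)
    got <- stats::setNames(g$counts$n_matches, g$counts$m_class)[m_classes()]
    expect_equal(as.numeric(got), as.numeric(planted))
  }
})

test_that("lowering the relatedness threshold never removes a match", {
  fx <- labeled_synthetic_taxonomy()
  term <- fx$tax$expressions$text[5]
  g_hi <- query_concept(fx$tax, term, embedder = fx$emb,
    relatedness_threshold = 0.9
  )
  g_lo <- query_concept(fx$tax, term, embedder = fx$emb,
    relatedness_threshold = 0.3
  )
  hi_expr <- g_hi$nodes$node_id[g_hi$nodes$kind == "expression"]
  lo_expr <- g_lo$nodes$node_id[g_lo$nodes$kind == "expression"]
  expect_true(all(hi_expr %in% lo_expr))
  expect_gte(length(lo_expr), length(hi_expr))
})

test_that("graph exports round-trip in both formats", {
  fx <- labeled_synthetic_taxonomy()
  g <- query_concept(fx$tax, fx$tax$expressions$text[10])
  for (fmt in c("graphml", "node_link")) {
    path <- withr::local_tempfile(
      fileext = if (fmt == "graphml") ".graphml" else ".json"
    )
    export_graph(g, path, format = fmt)
    back <- import_graph(path, format = fmt)
    expect_equal(back$query_term, g$query_term)
    expect_equal(
      plain_df(back$nodes),
      plain_df(dplyr::arrange(g$nodes, node_id))
    )
    key <- function(e) sort(paste(e$from, e$to))
    expect_equal(key(back$edges), key(g$edges))
    expect_equal(back$counts, g$counts)
  }
  expect_error(export_graph(g, tempfile(), format = "dot"), "arg")
})

test_that("an empty graph exports to a valid document", {
  g <- structure(
    list(
      nodes = tibble::tibble(
        node_id = character(), kind = character(), label = character(),
        level = numeric(), m_class = character()
      ),
      edges = tibble::tibble(from = character(), to = character()),
      query_term = "nothing",
      counts = tibble::tibble(m_class = m_classes(), n_matches = 0L)
    ),
    class = "fourms_graph"
  )
  path <- withr::local_tempfile(fileext = ".json")
  export_graph(g, path, format = "node_link")
  back <- import_graph(path, format = "node_link")
  expect_equal(nrow(back$nodes), 0)
  expect_equal(nrow(back$edges), 0)
})

test_that("corpus summaries conserve counts and attribute roles", {
  sim <- generate_corpus(generator_config(seed = 52, n_messages = 200))
  res <- validate_spans(
    lexicon_extract(sim$messages, sim$lexicon), sim$messages, 1.0
  )
  lc <- link_to_transfers(sim$messages, sim$events)
  s <- summarize_corpus(res, lc)
  counts <- extraction_counts(res)
  expect_equal(sum(s$totals$n_extractions), sum(counts$count))
  per_class <- tapply(counts$count, counts$m_class, sum)
  expect_equal(
    as.numeric(
      stats::setNames(s$totals$n_extractions, s$totals$m_class)[m_classes()]
    ),
    as.numeric(per_class[m_classes()])
  )
  expect_equal(
    s$messages_with_content,
    length(unique(counts$message_id[counts$count > 0]))
  )
  expect_equal(sum(s$role_distribution$percentage), 100)
  expect_equal(sum(s$crosstab$percentage), 100, tolerance = 1e-9)
  # ground-truth tally agreement
  truth_roles <- table(sim$truth$spans$sender_role)
  got_roles <- stats::setNames(s$role_distribution$n, s$role_distribution$sender_role)
  expect_equal(
    as.numeric(got_roles[names(truth_roles)]), as.numeric(truth_roles)
  )
})

test_that("single extraction gives a 100% crosstab cell; none gives zeros", {
  msgs <- make_messages("please give prn morphine now")
  res <- lexicon_extract(msgs, tiny_lexicon())
  s <- summarize_corpus(res, msgs)
  expect_equal(nrow(s$crosstab), 1)
  expect_equal(s$crosstab$percentage, 100)
  expect_equal(s$crosstab$sender_role, "nursing_staff")
  expect_equal(s$crosstab$receiver_role, "aprn")
  empty <- lexicon_extract(make_messages("quiet night no events"), tiny_lexicon())
  s0 <- summarize_corpus(empty, make_messages("quiet night no events"))
  expect_true(all(s0$totals$n_extractions == 0))
  expect_equal(nrow(s0$role_distribution), 0)
})
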