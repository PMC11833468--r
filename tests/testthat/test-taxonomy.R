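test_that("ward linkage joins the closest 1-D points first", {
  tr <- ward_linkage(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(tr$merges$left[1], 1)
  expect_equal(tr$merges$right[1], 2)
  expect_equal(tr$merges$height[1], 1) # two singletons merge at their distance
  expect_equal(tr$merges$size, c(2, 3))
})

test_that("single points and bad input are handled", {
  tr <- ward_linkage(matrix(5, ncol = 1))
  expect_equal(nrow(tr$merges), 0)
  expect_error(ward_linkage(matrix(c(1, NaN), ncol = 1)), "non-finite")
})

test_that("linkage equals the exhaustive Ward oracle on random fixtures", {
  for (trial in 1:30) {
    x <- withr::with_seed(2000 + trial, {
      n <- sample(2:12, 1)
      matrix(rnorm(n * sample(1:3, 1)), nrow = n)
    })
    om <- oracle_ward(x)
    pm <- as.matrix(ward_linkage(x))
    expect_equal(unname(pm[, "left"]), unname(om[, "left"]))
    expect_equal(unname(pm[, "right"]), unname(om[, "right"]))
    expect_equal(unname(pm[, "height"]), unname(om[, "height"]), tolerance = 1e-9)
  }
})

test_that("tree cuts behave at the extremes and between merge heights", {
  tr <- ward_linkage(matrix(c(0, 1, 10), ncol = 1))
  expect_equal(max(cut_tree(tr, max(tr$merges$height) * 1.1)), 1)
  expect_equal(cut_tree(tr, 0), 1:3)
  mid <- mean(tr$merges$height)
  expect_equal(cut_tree(tr, mid), c(1, 1, 2))
})

test_that("cluster counts are monotone and cuts nest", {
  for (trial in 1:25) {
    x <- withr::with_seed(3000 + trial, matrix(rnorm(30 * 2), 30))
    tr <- ward_linkage(x)
    hmax <- max(tr$merges$height)
    ts <- withr::with_seed(4000 + trial, sort(runif(4, 0, hmax * 1.1), decreasing = TRUE))
    parts <- lapply(ts, function(t) cut_tree(tr, t))
    counts <- vapply(parts, max, numeric(1))
    expect_true(all(diff(counts) >= 0)) # finer thresholds, more clusters
    for (k in 2:4) {
      # each finer cluster sits inside exactly one coarser cluster
      tab <- table(parts[[k]], parts[[k - 1]])
      expect_true(all(rowSums(tab > 0) == 1))
    }
  }
})

test_that("suggested thresholds achieve the closest attainable counts", {
  x <- withr::with_seed(77, matrix(rnorm(40), 20, 2))
  tr <- ward_linkage(x)
  ts <- suggest_thresholds(tr, c(2, 5, 9, 20))
  expect_true(all(diff(ts) < 0))
  got <- vapply(ts, function(t) max(cut_tree(tr, t)), numeric(1))
  expect_equal(got, c(2, 5, 9, 20))
  expect_equal(max(cut_tree(tr, suggest_thresholds(tr, 1))), 1)
  expect_equal(max(cut_tree(tr, suggest_thresholds(tr, 20))), 20)
  expect_error(suggest_thresholds(tr, c(2, 50)), "exceeds")
  # brute-force scan over all candidate thresholds agrees
  h <- sort(unique(tr$merges$height))
  cands <- c(h, max(h) + 1)
  for (target in c(3, 7, 14)) {
    err <- vapply(cands, function(t) abs(max(cut_tree(tr, t)) - target), numeric(1))
    best_count <- max(cut_tree(tr, cands[which(err == min(err))[sum(err == min(err))]]))
    expect_equal(max(cut_tree(tr, suggest_thresholds(tr, target))), best_count)
  }
})

test_that("semantic dedup folds duplicates, keeps orthogonal vectors, idempotent", {
  v <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expr <- tibble::tibble(
    text = c("a", "a copy", "b"), m_class = "medication",
    provenance = list("M1", "M2", "M3"), vector = v
  )
  out <- semantic_dedup(expr, threshold = 0.95)
  expect_equal(out$text, c("a", "b"))
  mm <- attr(out, "merge_map")
  expect_equal(mm$kept_text, "a")
  expect_equal(mm$merged_text, "a copy")
  expect_setequal(out$provenance[[1]], c("M1", "M2"))
  again <- semantic_dedup(out, threshold = 0.95)
  expect_equal(nrow(again), nrow(out))
  expect_equal(nrow(attr(again, "merge_map")), 0)
  # zero vector is fatal
  exprz <- expr
  exprz$vector[2, ] <- 0
  expect_error(semantic_dedup(exprz), "zero-norm")
})

test_that("dedup equals the pairwise oracle on random fixtures", {
  for (trial in 1:25) {
    fix <- withr::with_seed(5000 + trial, {
      n <- sample(5:50, 1)
      list(
        v = matrix(rnorm(n * 4), n),
        thr = runif(1, 0.3, 0.95),
        cls = sample(m_classes()[1:2], n, replace = TRUE)
      )
    })
    expr <- tibble::tibble(
      text = sprintf("t%02d", seq_len(nrow(fix$v))), m_class = fix$cls,
      provenance = as.list(seq_len(nrow(fix$v))), vector = fix$v
    )
    out <- semantic_dedup(expr, threshold = fix$thr)
    keep <- oracle_dedup(fix$v, fix$thr, groups = fix$cls)
    expect_equal(out$text, expr$text[keep])
  }
})

test_that("hierarchy nests and recovers a planted 3-level structure", {
  # planted: 2 coarse groups x 2 mid x 2 leaves, separation >> noise
  v <- withr::with_seed(8, {
    rows <- list()
    for (a in 0:1) {
      for (b in 0:1) {
        for (c in 0:1) {
          ctr <- a * 400 + b * 40 + c * 8
          for (r in 1:4) rows[[length(rows) + 1]] <- ctr + rnorm(3, sd = 0.5)
        }
      }
    }
    do.call(rbind, rows)
  })
  truth_l1 <- rep(0:1, each = 16)
  truth_l2 <- rep(0:3, each = 8)
  truth_l3 <- rep(0:7, each = 4)
  expr <- tibble::tibble(
    text = sprintf("e%02d", 1:32), m_class = "mobility",
    provenance = as.list(1:32), vector = v
  )
  tr <- ward_linkage(v)
  ts <- suggest_thresholds(tr, c(2, 4, 8, 32))
  tax <- build_hierarchy(expr, list(mobility = tr), list(mobility = ts))
  for (pair in list(list(1, truth_l1), list(2, truth_l2), list(3, truth_l3))) {
    nd <- tax$nodes[tax$nodes$level == pair[[1]], ]
    assign <- integer(32)
    for (i in seq_len(nrow(nd))) assign[nd$members[[i]]] <- i
    expect_gte(helper_ari(assign, pair[[2]]), 0.9)
  }
  # parent members are the union of child members at every level
  for (lev in 1:4) {
    nd <- tax$nodes[tax$nodes$level == lev, ]
    for (i in seq_len(nrow(nd))) {
      parent <- tax$nodes[tax$nodes$node_id == nd$parent_id[i], ]
      expect_true(all(nd$members[[i]] %in% parent$members[[1]]))
    }
  }
})

test_that("non-decreasing thresholds are rejected", {
  expr <- make_embedded_expressions()
  tr <- ward_linkage(expr$vector)
  expect_error(
    build_hierarchy(expr, list(medication = tr),
      list(medication = c(1, 2, 3, 4))
    ),
    "strictly decreasing"
  )
})

test_that("labeling assigns distinct labels without re-labeling rounds", {
  expr <- make_embedded_expressions()
  tax <- build_taxonomy(expr, target_counts = list(medication = c(1, 2, 4, 8)))
  labeled <- label_clusters(tax)
  labs <- labeled$nodes$label
  expect_false(anyNA(labs))
  for (lev in unique(labeled$nodes$level)) {
    expect_false(anyDuplicated(labs[labeled$nodes$level == lev]) > 0)
  }
})

test_that("a colliding mock labeler triggers exactly one re-label round", {
  expr <- make_embedded_expressions()
  tax <- build_taxonomy(expr, target_counts = list(medication = c(2, 4, 6, 8)))
  calls <- new.env()
  calls$log <- list()
  mock <- local({
    returns <- c("Same Label", "Same Label", "Fresh Label")
    i <- 0
    function(texts, avoid = character()) {
      i <<- i + 1
      calls$log[[i]] <- avoid
      returns[min(i, length(returns))]
    }
  })
  sub <- tax
  sub$nodes <- sub$nodes[sub$nodes$level %in% c(0, 1), ]
  labeled <- label_clusters(sub, labeler = mock, max_rounds = 3)
  l1 <- labeled$nodes$label[labeled$nodes$level == 1]
  expect_setequal(l1, c("Same Label", "Fresh Label"))
  # third call (the re-label) received the colliding label to avoid
  expect_equal(calls$log[[3]], "Same Label")
})

test_that("an always-colliding labeler terminates via suffix disambiguation", {
  expr <- make_embedded_expressions(n_per = 8)
  tax <- build_taxonomy(expr, target_counts = list(medication = c(2, 4, 8, 16)))
  stubborn <- function(texts, avoid = character()) "Cluster"
  labeled <- label_clusters(tax, labeler = stubborn, max_rounds = 3)
  nodes <- labeled$nodes[labeled$nodes$level > 0, ]
  for (lev in unique(nodes$level)) {
    labs <- nodes$label[nodes$level == lev]
    expect_equal(anyDuplicated(labs), 0)
  }
  expect_true(any(nodes$flag == "label_suffix_disambiguated", na.rm = TRUE))
})

test_that("a failing labeler yields flagged placeholder labels", {
  expr <- make_embedded_expressions()
  tax <- build_taxonomy(expr, target_counts = list(medication = c(1, 2, 4, 8)))
  boom <- function(texts, avoid = character()) stop("no label today")
  labeled <- label_clusters(tax, labeler = boom)
  nodes <- labeled$nodes[labeled$nodes$level > 0, ]
  expect_true(all(grepl("^Unlabeled-", nodes$label)))
  expect_true(all(nodes$flag == "labeler_failed"))
})

test_that("taxonomy table mirrors the per-class level-1 layout", {
  cfg <- generator_config(seed = 41)
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
  tax <- label_clusters(build_taxonomy(expr, target_counts = targets))
  tab <- taxonomy_table(tax)
  expect_equal(
    as.integer(table(tab$m_class)[m_classes()]),
    c(8, 9, 4, 4)
  )
  expect_equal(sum(tab$n_expressions), nrow(expr))
  expect_true(all(c("n_clusters_l2", "n_clusters_l3", "n_clusters_l4")
  %in% names(tab)))
})

test_that("taxonomy tree files round-trip", {
  expr <- make_embedded_expressions()
  tax <- label_clusters(
    build_taxonomy(expr, target_counts = list(medication = c(1, 2, 4, 8)))
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_taxonomy(tax, path)
  back <- read_taxonomy(path)
  expect_equal(plain_df(back$nodes), plain_df(tax$nodes))
  expect_equal(back$expressions$text, tax$expressions$text)
  expect_equal(back$expressions$provenance, tax$expressions$provenance)
  expect_equal(back$thresholds, tax$thresholds)
})

test_that("embedding is deterministic and dimension mismatches are fatal", {
  emb <- hash_embedder(dim = 8, seed = 3)
  m1 <- emb(c("gait stride", "gait stride", "other text"))
  expect_equal(m1[1, ], m1[2, ])
  expect_false(isTRUE(all.equal(m1[1, ], m1[3, ])))
  expr <- tibble::tibble(
    text = "x", m_class = "mobility", provenance = list("M1")
  )
  bad <- function(texts) matrix(1, nrow = 2, ncol = 3)
  expect_error(embed_expressions(expr, bad), "one row per text")
  expect_equal(nrow(embed_expressions(expr[0, ], emb)), 0)
})
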