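#' Pipeline configuration
#'
#' Collects every tunable constant of the end-to-end flow in one place:
#' the 14-day pre-transfer window, the 0.85 hallucination similarity floor,
#' the 0.60 kappa performance gate, the 0.95 semantic-dedup cosine
#' threshold, the 0.9999 duplicate-label cosine threshold, count bins, and
#' plug-in choices. With no corpus paths the pipeline runs on a synthetic
#' corpus from `generator`.
#'
#' @param seed Master seed for the run.
#' @param generator A [generator_config()]; its seed is overridden by
#'   `seed`.
#' @param corpus_path,events_path Optional paths to a real corpus.
#' @param window_days,dedup_key,similarity_floor,bins,kappa_gate Evaluation
#'   stage constants.
#' @param dedup_threshold,label_dup_threshold,label_max_rounds Taxonomy
#'   stage constants.
#' @param level_targets Named list of per-class increasing target cluster
#'   counts for [suggest_thresholds()], or `NULL` with explicit
#'   `thresholds`.
#' @param thresholds Optional named list of explicit per-class threshold
#'   vectors.
#' @param n_validation_pairs Held-out preference pairs (`NULL` to skip the
#'   split).
#' @param query_term Optional concept to query at the end of the run.
#' @param decoding A [decoding_config()] passed to extractor plug-ins.
#' @return A `fourms_config` list.
#' @export
pipeline_config <- function(
    seed = 1L,
    generator = generator_config(seed = seed),
    corpus_path = NULL, events_path = NULL,
    window_days = 14, dedup_key = "all", similarity_floor = 0.85,
    bins = c(0, 1, 2, 3), kappa_gate = 0.60,
    dedup_threshold = 0.95, label_dup_threshold = 0.9999,
    label_max_rounds = 3,
    level_targets = NULL, thresholds = NULL,
    n_validation_pairs = NULL,
    query_term = NULL,
    decoding = decoding_config()) {
  stopifnot(
    similarity_floor >= 0, similarity_floor <= 1,
    dedup_threshold > 0, dedup_threshold <= 1,
    label_dup_threshold > 0, label_dup_threshold <= 1,
    window_days > 0
  )
  generator$seed <- as.integer(seed)
  structure(
    list(
      seed = as.integer(seed), generator = generator,
      corpus_path = corpus_path, events_path = events_path,
      window_days = window_days, dedup_key = dedup_key,
      similarity_floor = similarity_floor, bins = bins,
      kappa_gate = kappa_gate, dedup_threshold = dedup_threshold,
      label_dup_threshold = label_dup_threshold,
      label_max_rounds = label_max_rounds,
      level_targets = level_targets, thresholds = thresholds,
      n_validation_pairs = n_validation_pairs,
      query_term = query_term, decoding = decoding
    ),
    class = "fourms_config"
  )
}

#' Run the end-to-end pipeline
#'
#' Wires the stages together: load/simulate, deduplicate, link to transfer
#' events, extract, validate, reconcile gold, evaluate, build preference
#' pairs, embed, semantically deduplicate, cluster, cut, label, summarize,
#' and optionally query. Any stage failure aborts with the stage name. The
#' returned manifest records the seed, a config hash, per-stage counts, and
#' the package version; identical config and seed reproduce an identical
#' manifest (excluding the wall-clock field).
#'
#' @param config A [pipeline_config()].
#' @return List: `manifest` (tibble of stages and counts plus run metadata)
#'   and `artifacts` (every intermediate object by name).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stages <- list()
  art <- list()
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages[[length(stages) + 1]] <<- tibble::tibble(
      stage = name, status = "ok",
      n = if (is.null(attr(out, "stage_n"))) NA_integer_ else
        as.integer(attr(out, "stage_n"))
    )
    out
  }
  with_n <- function(x, n) {
    attr(x, "stage_n") <- n
    x
  }

  sim <- stage("simulate", {
    s <- generate_corpus(config$generator)
    with_n(s, nrow(s$messages))
  })
  msgs <- stage("dedupe", {
    d <- dedupe_messages(sim$messages, key = config$dedup_key)
    with_n(d, nrow(d))
  })
  corpus <- stage("link", {
    l <- link_to_transfers(msgs, sim$events, config$window_days)
    with_n(l, nrow(l$links))
  })
  results <- stage("extract", {
    r <- lexicon_extract(msgs, sim$lexicon)
    with_n(r, nrow(r))
  })
  results <- stage("validate", {
    v <- validate_spans(results, msgs, config$similarity_floor)
    with_n(v, sum(v$valid))
  })
  gold <- stage("gold", {
    ann <- simulate_annotators(
      sim$truth, config$generator$annotator_disagreement,
      seed = config$seed + 17L
    )
    g <- reconcile(ann$a, ann$b, ann$adjudications,
      message_ids = sim$truth$message_ids
    )
    with_n(g, nrow(g))
  })
  eval_report <- stage("evaluate", {
    e <- evaluate_extractions(results, gold,
      bins = config$bins, gate = config$kappa_gate
    )
    with_n(e, e$n_messages)
  })
  pairs <- stage("pairs", {
    p <- build_preference_pairs(results, gold, messages = msgs)
    if (!is.null(config$n_validation_pairs) &&
      config$n_validation_pairs < nrow(p)) {
      p <- with_n(p, nrow(p))
      attr(p, "split") <- split_pairs(
        p, config$n_validation_pairs, config$seed + 23L
      )
      p
    } else {
      with_n(p, nrow(p))
    }
  })
  embedder <- synthetic_embedder(config$generator, sim$vocabulary)
  expressions <- stage("embed", {
    ex <- embed_expressions(collect_expressions(results), embedder)
    with_n(ex, nrow(ex))
  })
  expressions <- stage("dedup", {
    dd <- semantic_dedup(expressions, config$dedup_threshold)
    with_n(dd, nrow(dd))
  })
  taxonomy <- stage("taxonomy", {
    targets <- config$level_targets
    if (is.null(targets) && is.null(config$thresholds)) {
      # default: coarse-to-fine targets scaled to the deduped set
      targets <- lapply(
        stats::setNames(nm = intersect(m_classes(), unique(expressions$m_class))),
        function(cls) {
          n <- sum(expressions$m_class == cls)
          unique(pmin(n, c(2, 4, 8, 16)))
        }
      )
    }
    tx <- build_taxonomy(expressions,
      thresholds = config$thresholds, target_counts = targets
    )
    with_n(tx, nrow(tx$nodes))
  })
  taxonomy <- stage("label", {
    lt <- label_clusters(taxonomy,
      embedder = embedder,
      dup_threshold = config$label_dup_threshold,
      max_rounds = config$label_max_rounds
    )
    with_n(lt, sum(!is.na(lt$nodes$label)))
  })
  summary <- stage("summarize", {
    s <- summarize_corpus(results, corpus)
    with_n(s, s$n_extractions)
  })
  graph <- NULL
  if (!is.null(config$query_term)) {
    graph <- stage("query", {
      q <- query_concept(taxonomy, config$query_term, embedder = embedder)
      with_n(q, nrow(q$nodes))
    })
  }
  manifest <- list(
    stages = dplyr::bind_rows(stages),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    package_version = as.character(utils::packageVersion("fourms")),
    started_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  list(
    manifest = manifest,
    artifacts = list(
      messages = msgs, events = sim$events, corpus = corpus,
      truth = sim$truth, results = results, gold = gold,
      evaluation = eval_report, pairs = pairs, expressions = expressions,
      taxonomy = taxonomy, summary = summary, graph = graph
    )
  )
}
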