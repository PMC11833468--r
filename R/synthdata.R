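# Class-specific word banks for the planted vocabulary. Words are unique
# across every bank and position, so a generated phrase can never collide
# with (or contain) a phrase from another class, and the filler/carrier
# vocabulary below is disjoint from all of them — a zero-content message
# can never accidentally contain a lexicon phrase.
class_word_banks <- function() {
  list(
    what_matters = list(
      a = c(
        "family", "comfort", "dignity", "spiritual", "personal", "cultural",
        "legacy", "autonomy", "faith", "companionship", "celebration",
        "privacy"
      ),
      b = c(
        "wishes", "preference", "goals", "values", "priorities", "choices",
        "decisions", "hopes", "requests", "traditions", "routines", "beliefs"
      ),
      c = c(
        "honored", "discussed", "documented", "respected", "shared",
        "revisited", "clarified", "affirmed", "reaffirmed", "recorded",
        "reviewed", "supported"
      )
    ),
    medication = list(
      a = c(
        "lasix", "warfarin", "insulin", "metoprolol", "lisinopril",
        "donepezil", "furosemide", "amlodipine", "gabapentin", "sertraline",
        "omeprazole", "prednisone"
      ),
      b = c(
        "dosage", "titration", "refill", "taper", "injection", "infusion",
        "tablet", "capsule", "regimen", "prescription", "ampule", "bolus"
      ),
      c = c(
        "adjusted", "administered", "held", "renewed", "increased",
        "decreased", "scheduled", "monitored", "reconciled", "tapered",
        "flagged", "verified"
      )
    ),
    mentation = list(
      a = c(
        "delirium", "confusion", "agitation", "memory", "orientation",
        "alertness", "mood", "depression", "anxiety", "lethargy",
        "restlessness", "paranoia"
      ),
      b = c(
        "episode", "fluctuation", "screen", "evaluation", "baseline",
        "decline", "lucidity", "drowsiness", "outburst", "forgetfulness",
        "disorientation", "sundowning"
      ),
      c = c(
        "worsening", "improving", "resolving", "persisting", "emerging",
        "stabilizing", "recurring", "intermittent", "nocturnal", "abrupt",
        "gradual", "pronounced"
      )
    ),
    mobility = list(
      a = c(
        "gait", "ambulation", "balance", "walker", "wheelchair", "bedrest",
        "endurance", "stumble", "limp", "shuffle", "immobility",
        "unsteadiness"
      ),
      b = c(
        "stride", "footing", "posture", "stamina", "strengthening",
        "stretching", "repositioning", "standing", "pivoting",
        "weightbearing", "sidestep", "kneeling"
      ),
      c = c(
        "assisted", "supervised", "limited", "restricted", "encouraged",
        "tolerated", "attempted", "refused", "resumed", "deferred",
        "practiced", "observed"
      )
    )
  )
}

# 4M-free clinical boilerplate; vetted word-by-word against the banks.
filler_sentences <- function() {
  c(
    "please see the note from earlier today",
    "thank you for the prompt reply",
    "will follow up after rounds",
    "lab work is pending for tomorrow",
    "no acute change overnight per report",
    "vitals within normal limits at last check",
    "the on call provider was notified",
    "appointment confirmed for next week",
    "paperwork sent to the office this morning",
    "let me know if anything else is needed",
    "copy of the chart faxed over",
    "room change completed without issue",
    "awaiting callback from the clinic",
    "census unchanged for the unit tonight",
    "maintenance fixed the call light",
    "weekly meeting moved to thursday",
    "supply order placed for the floor",
    "transport arranged for friday morning"
  )
}

carrier_templates <- function() {
  c(
    "resident reports %s this morning",
    "please note %s per the evening shift",
    "fyi %s was mentioned at rounds",
    "nurse called about %s earlier",
    "regarding %s see earlier message"
  )
}

#' Synthetic-corpus generator configuration
#'
#' Defines the study conditions the generator emulates: short clinical
#' messages (roughly 10-60 words) with class-imbalanced 4M expression rates
#' skewed toward Medication, a fraction of messages with no 4M content at
#' all, a sender-role mix matching the observed sender distribution, a
#' planted four-level vocabulary hierarchy whose level-1 cluster counts
#' default to 8/9/4/4 (What Matters/Medication/Mentation/Mobility), and
#' transfer events with a 14-day pre-transfer message window.
#'
#' @param seed Integer master seed; a fixed seed makes every generator
#'   output byte-identical.
#' @param n_messages,n_residents,n_events,n_facilities Corpus dimensions.
#' @param class_rates Expected planted expressions per (content-eligible)
#'   message and class.
#' @param zero_content_fraction Fraction of messages forced to contain no 4M
#'   content.
#' @param l1_counts Planted level-1 cluster counts per class.
#' @param branching Branching factors from level 1 to levels 2, 3, 4.
#' @param phrases_per_leaf Planted phrases in each level-4 leaf cluster.
#' @param embed_dim Synthetic embedding dimension (>= 2).
#' @param noise_sigma Isotropic Gaussian noise s.d. around leaf centroids.
#' @param centroid_separation Distance between sibling leaf centroids, in
#'   units of `noise_sigma`.
#' @param level_scale Geometric growth of centroid separation per level up
#'   the hierarchy.
#' @param role_mix Sender-role probabilities (must sum to 1).
#' @param annotator_disagreement Per-span probability a simulated annotator
#'   misses it (see [simulate_annotators()]).
#' @param window_days Pre-transfer link window.
#' @param link_fraction Fraction of messages placed inside an event window.
#' @return A `fourms_genconfig` list.
#' @export
generator_config <- function(
    seed = 1L,
    n_messages = 500, n_residents = 60, n_events = 80, n_facilities = 12,
    class_rates = c(
      what_matters = 0.35, medication = 0.95, mentation = 0.26,
      mobility = 0.16
    ),
    zero_content_fraction = 0.3,
    l1_counts = c(what_matters = 8, medication = 9, mentation = 4, mobility = 4),
    branching = c(2, 2, 2),
    phrases_per_leaf = 7,
    embed_dim = 16,
    noise_sigma = 1,
    centroid_separation = 5,
    level_scale = 4,
    role_mix = c(
      nursing_staff = 0.405, aprn = 0.336, physician = 0.093,
      other_staff = 0.166
    ),
    annotator_disagreement = 0.1,
    window_days = 14,
    link_fraction = 0.7) {
  stopifnot(
    abs(sum(role_mix) - 1) < 1e-9, noise_sigma > 0, centroid_separation > 0,
    embed_dim >= 2, all(branching >= 1), length(branching) == 3,
    zero_content_fraction >= 0, zero_content_fraction <= 1
  )
  structure(
    list(
      seed = as.integer(seed), n_messages = n_messages,
      n_residents = n_residents, n_events = n_events,
      n_facilities = n_facilities, class_rates = class_rates,
      zero_content_fraction = zero_content_fraction, l1_counts = l1_counts,
      branching = branching, phrases_per_leaf = phrases_per_leaf,
      embed_dim = embed_dim, noise_sigma = noise_sigma,
      centroid_separation = centroid_separation, level_scale = level_scale,
      role_mix = role_mix, annotator_disagreement = annotator_disagreement,
      window_days = window_days, link_fraction = link_fraction
    ),
    class = "fourms_genconfig"
  )
}

#' Generate the planted vocabulary hierarchy and its lexicon
#'
#' Builds, deterministically under the config seed, a four-level phrase
#' hierarchy per class: `l1_counts[class]` level-1 clusters, each splitting
#' by the branching factors down to level-4 leaves holding
#' `phrases_per_leaf` unique phrases. Phrases are unique across classes by
#' construction; any residual collision or substring containment is
#' resolved by perturbing the phrase with a suffix word and flagged.
#'
#' @param config A [generator_config()].
#' @return List: `phrases` (tibble `m_class`, `l1`..`l4`, `leaf_id`,
#'   `phrase`), `lexicon` (a [lexicon()]), `flags`.
#' @export
make_vocabulary <- function(config) {
  banks <- class_word_banks()
  flags <- character(0)
  out <- withr::with_seed(config$seed + 101L, {
    purrr::map_dfr(names(config$l1_counts), function(cls) {
      bank <- banks[[cls]]
      grid <- expand.grid(
        l4 = seq_len(config$branching[3]), l3 = seq_len(config$branching[2]),
        l2 = seq_len(config$branching[1]), l1 = seq_len(config$l1_counts[[cls]])
      )
      n_leaves <- nrow(grid)
      need <- n_leaves * config$phrases_per_leaf
      combos <- expand.grid(
        a = seq_along(bank$a), b = seq_along(bank$b), c = seq_along(bank$c)
      )
      if (need > nrow(combos)) {
        stop("vocabulary for ", cls, " needs ", need,
          " phrases but only ", nrow(combos), " combinations exist",
          call. = FALSE
        )
      }
      combos <- combos[sample(nrow(combos)), ][seq_len(need), ]
      phrase <- paste(
        bank$a[combos$a], bank$b[combos$b], bank$c[combos$c]
      )
      leaf_idx <- rep(seq_len(n_leaves), each = config$phrases_per_leaf)
      tibble::tibble(
        m_class = cls,
        l1 = grid$l1[leaf_idx], l2 = grid$l2[leaf_idx],
        l3 = grid$l3[leaf_idx], l4 = grid$l4[leaf_idx],
        leaf_id = paste(cls, grid$l1[leaf_idx], grid$l2[leaf_idx],
          grid$l3[leaf_idx], grid$l4[leaf_idx],
          sep = "."
        ),
        phrase = phrase
      )
    })
  })
  # collision repair: duplicates or substring containment across the bank
  repeat {
    dup <- duplicated(out$phrase)
    if (!any(dup)) break
    i <- which(dup)[1]
    out$phrase[i] <- paste(out$phrase[i], "again")
    flags <- c(flags, paste0("perturbed_duplicate:", out$phrase[i]))
  }
  ord <- order(nchar(out$phrase))
  for (i in ord) {
    hits <- which(
      nchar(out$phrase) > nchar(out$phrase[i]) &
        stringr::str_detect(
          out$phrase,
          paste0("\\b\\Q", out$phrase[i], "\\E\\b")
        )
    )
    if (length(hits) > 0) {
      out$phrase[i] <- paste(out$phrase[i], "noted")
      flags <- c(flags, paste0("perturbed_containment:", out$phrase[i]))
    }
  }
  lex <- lexicon(split(out$phrase, out$m_class)[unique(out$m_class)])
  list(phrases = out, lexicon = lex, flags = flags)
}

#' Generate a synthetic message corpus with ground truth
#'
#' Assembles messages from 4M-free clinical boilerplate plus planted
#' vocabulary phrases (each planted span is a verbatim substring of its
#' message), places timestamps inside or outside pre-transfer event windows
#' according to an intended link table, and draws sender/receiver roles
#' from the configured mix. All bookkeeping needed to test downstream
#' modules is returned as ground truth.
#'
#' @param config A [generator_config()].
#' @return List: `messages`, `events`, `truth` (a `fourms_truth`:
#'   `spans`, `links`, `message_ids`, `config`), `vocabulary` (phrase
#'   hierarchy tibble) and `lexicon`.
#' @export
generate_corpus <- function(config) {
  vocab <- make_vocabulary(config)
  fillers <- filler_sentences()
  carriers <- carrier_templates()
  rates <- config$class_rates[m_classes()]
  res <- withr::with_seed(config$seed, {
    resident_ids <- sprintf("R%03d", seq_len(config$n_residents))
    facility_of <- sample(
      sprintf("F%02d", seq_len(config$n_facilities)),
      config$n_residents,
      replace = TRUE
    )
    origin <- as.POSIXct("2016-01-01 00:00", tz = "UTC")
    events <- tibble::tibble(
      event_id = sprintf("E%04d", seq_len(config$n_events)),
      resident_id = sample(resident_ids, config$n_events, replace = TRUE),
      transfer_time = origin + round(stats::runif(config$n_events, 30, 360) *
        86400 / 60) * 60
    )
    n <- config$n_messages
    msg_res <- sample(resident_ids, n, replace = TRUE)
    sender <- sample(names(config$role_mix), n,
      replace = TRUE, prob = config$role_mix
    )
    receiver <- sample(names(config$role_mix), n,
      replace = TRUE, prob = config$role_mix
    )
    zero <- stats::runif(n) < config$zero_content_fraction
    counts <- vapply(
      rates, function(r) stats::rpois(n, r), numeric(n)
    )
    counts[zero, ] <- 0L
    phrase_pool <- split(vocab$phrases, vocab$phrases$m_class)
    span_rows <- list()
    texts <- character(n)
    message_id <- sprintf("M%05d", seq_len(n))
    for (i in seq_len(n)) {
      planted <- list()
      for (cls in m_classes()) {
        k <- counts[i, cls]
        if (k > 0) {
          pool <- phrase_pool[[cls]]
          pick <- sample(nrow(pool), k, replace = TRUE)
          planted[[cls]] <- tibble::tibble(
            message_id = message_id[i], m_class = cls,
            phrase = pool$phrase[pick], leaf_id = pool$leaf_id[pick]
          )
        }
      }
      planted <- if (length(planted) > 0) dplyr::bind_rows(planted) else NULL
      n_fill <- sample(2:4, 1)
      sentences <- sample(fillers, n_fill)
      if (!is.null(planted) && nrow(planted) > 0) {
        carr <- sprintf(
          sample(carriers, nrow(planted), replace = TRUE), planted$phrase
        )
        sentences <- sample(c(sentences, carr))
        span_rows[[length(span_rows) + 1]] <- planted
      }
      texts[i] <- paste0(paste(sentences, collapse = ". "), ".")
    }
    # timestamps: linked messages land inside a window of one of their
    # resident's events; the rest are placed well before any window
    ev_by_res <- split(seq_len(nrow(events)), events$resident_id)
    ts <- rep(origin, n)
    w <- config$window_days * 86400
    for (i in seq_len(n)) {
      evs <- ev_by_res[[msg_res[i]]]
      if (!is.null(evs) && stats::runif(1) < config$link_fraction) {
        e <- if (length(evs) == 1) evs else sample(evs, 1)
        ts[i] <- events$transfer_time[e] - round(stats::runif(1, 0, w) / 60) * 60
      } else if (!is.null(evs)) {
        first <- min(events$transfer_time[evs])
        ts[i] <- first - round(stats::runif(1, w + 5 * 86400, w + 60 * 86400) /
          60) * 60
      } else {
        ts[i] <- origin + round(stats::runif(1, 0, 360) * 86400 / 60) * 60
      }
    }
    messages <- tibble::tibble(
      message_id = message_id,
      resident_id = msg_res,
      facility_id = facility_of[match(msg_res, resident_ids)],
      sender_role = sender,
      receiver_role = receiver,
      timestamp = ts,
      text = texts
    )
    spans <- if (length(span_rows) > 0) {
      dplyr::bind_rows(span_rows)
    } else {
      tibble::tibble(
        message_id = character(), m_class = character(),
        phrase = character(), leaf_id = character()
      )
    }
    spans$sender_role <- messages$sender_role[
      match(spans$message_id, messages$message_id)
    ]
    spans$receiver_role <- messages$receiver_role[
      match(spans$message_id, messages$message_id)
    ]
    list(messages = messages, events = events, spans = spans)
  })
  # intended links: generator-side scan over the same window definition
  joined <- dplyr::inner_join(
    dplyr::select(res$messages, "message_id", "resident_id", "timestamp"),
    dplyr::select(res$events, "event_id", "resident_id", "transfer_time"),
    by = "resident_id", relationship = "many-to-many"
  )
  w <- config$window_days * 86400
  hit <- joined$timestamp > joined$transfer_time - w &
    joined$timestamp <= joined$transfer_time
  links <- dplyr::arrange(
    tibble::tibble(
      event_id = joined$event_id[hit], message_id = joined$message_id[hit]
    ),
    .data$event_id, .data$message_id
  )
  truth <- structure(
    list(
      spans = res$spans, links = links,
      message_ids = res$messages$message_id, config = config
    ),
    class = "fourms_truth"
  )
  list(
    messages = res$messages, events = res$events, truth = truth,
    vocabulary = vocab$phrases, lexicon = vocab$lexicon
  )
}

#' Gold standard directly from generator ground truth
#'
#' @param truth `fourms_truth` from [generate_corpus()].
#' @return A `fourms_gold` over the full message universe.
#' @export
gold_from_truth <- function(truth) {
  as_gold(
    tibble::tibble(
      message_id = truth$spans$message_id, m_class = truth$spans$m_class,
      span = truth$spans$phrase, provenance = "both"
    ),
    truth$message_ids
  )
}

#' Synthetic sentence embedder with planted hierarchy geometry
#'
#' Returns an embedder plug-in mapping each planted phrase to its leaf
#' centroid plus deterministic Gaussian noise (`noise_sigma`, keyed by the
#' phrase hash and the seed, so the same phrase always gets the same
#' vector). Centroids are laid out recursively: sibling groups at level l
#' are separated by `centroid_separation * level_scale^(4 - l)` (in units
#' of `noise_sigma`), so leaves within a parent are closer than leaves
#' across parents at every level. Unknown text falls back to a
#' deterministic pseudo-random unit vector.
#'
#' @param config A [generator_config()].
#' @param vocabulary Phrase hierarchy tibble from [make_vocabulary()] /
#'   [generate_corpus()].
#' @return Embedder function `character -> matrix`.
#' @export
synthetic_embedder <- function(config, vocabulary) {
  d <- config$embed_dim
  sep <- config$centroid_separation * config$noise_sigma
  g <- config$level_scale
  rand_dir <- function() {
    v <- stats::rnorm(d)
    v / sqrt(sum(v^2))
  }
  centroids <- withr::with_seed(config$seed + 211L, {
    cents <- list()
    for (cls in unique(vocabulary$m_class)) {
      sub <- vocabulary[vocabulary$m_class == cls, ]
      anchor <- rand_dir() * sep * g^4
      for (i1 in unique(sub$l1)) {
        c1 <- anchor + rand_dir() * sep * g^3
        s1 <- sub[sub$l1 == i1, ]
        for (i2 in unique(s1$l2)) {
          c2 <- c1 + rand_dir() * sep * g^2
          s2 <- s1[s1$l2 == i2, ]
          for (i3 in unique(s2$l3)) {
            c3 <- c2 + rand_dir() * sep * g
            s3 <- s2[s2$l3 == i3, ]
            for (i4 in unique(s3$l4)) {
              leaf <- s3$leaf_id[s3$l4 == i4][1]
              cents[[leaf]] <- c3 + rand_dir() * sep
            }
          }
        }
      }
    }
    cents
  })
  leaf_of <- stats::setNames(vocabulary$leaf_id, norm_text(vocabulary$phrase))
  fallback <- hash_embedder(dim = d, seed = config$seed + 307L)
  sigma <- config$noise_sigma
  function(texts) {
    nt <- norm_text(texts)
    out <- matrix(0, nrow = length(texts), ncol = d)
    known <- nt %in% names(leaf_of)
    if (any(!known)) out[!known, ] <- fallback(texts[!known])
    for (i in which(known)) {
      noise <- withr::with_seed(
        str_hash(nt[i], seed = config$seed + 401L),
        stats::rnorm(d, sd = sigma)
      )
      out[i, ] <- centroids[[leaf_of[[nt[i]]]]] + noise
    }
    out
  }
}

#' Simulate two independent annotators over the ground truth
#'
#' Both annotators start from the planted spans; each span is dropped by an
#' annotator with probability `rate`, independently, except that a span
#' both annotators would drop is reassigned to a single random annotator's
#' drop — every planted span survives in at least one set, so
#' truth-adjudicated reconciliation restores the planted gold exactly. The
#' probability a span becomes a difference is `rate * (2 - rate)`. The
#' returned adjudications accept every difference.
#'
#' @param truth `fourms_truth` from [generate_corpus()].
#' @param rate Disagreement rate in \[0, 0.5\].
#' @param seed Integer seed.
#' @return List: annotation tibbles `a` and `b`, and `adjudications`.
#' @export
simulate_annotators <- function(truth, rate, seed) {
  stopifnot(rate >= 0, rate <= 0.5)
  spans <- truth$spans
  m <- nrow(spans)
  drops <- withr::with_seed(seed, {
    da <- stats::runif(m) < rate
    db <- stats::runif(m) < rate
    both <- da & db
    if (any(both)) {
      keep_a <- stats::runif(sum(both)) < 0.5
      da[both] <- !keep_a
      db[both] <- keep_a
    }
    list(a = da, b = db)
  })
  ann <- function(id, drop) {
    tibble::tibble(
      annotator_id = id,
      message_id = spans$message_id[!drop],
      m_class = spans$m_class[!drop],
      phrase = spans$phrase[!drop]
    )
  }
  diff_idx <- which(drops$a | drops$b)
  adjudications <- tibble::tibble(
    message_id = spans$message_id[diff_idx],
    m_class = spans$m_class[diff_idx],
    phrase = spans$phrase[diff_idx],
    decision = "accept"
  )
  list(a = ann("A", drops$a), b = ann("B", drops$b),
    adjudications = adjudications
  )
}

#' Simulate an extractor with planted error rates
#'
#' Produces an extraction set by flipping the gold presence of each
#' (message, class) cell: a false positive (a fabricated lexicon span of
#' that class) with probability `fpr` where gold is absent, a false
#' negative (all gold spans dropped) with probability `fnr` where gold is
#' present. The result is already validated — it stands in for a generative
#' extractor whose per-class agreement is known analytically (see
#' [expected_kappa_from_error_rates()]).
#'
#' @param gold A `fourms_gold`.
#' @param fpr,fnr Planted false-positive and false-negative rates.
#' @param lexicon Source of fabricated spans.
#' @param seed Integer seed.
#' @return A `fourms_extractions`; attribute `"flips"` records every
#'   flipped cell.
#' @export
simulate_extractor_errors <- function(gold, fpr, fnr, lexicon, seed) {
  counts <- extraction_counts(gold)
  gold_tbl <- tibble::as_tibble(gold)
  res <- withr::with_seed(seed, {
    u <- stats::runif(nrow(counts))
    flip <- ifelse(counts$binary == 1, u < fnr, u < fpr)
    fab <- vapply(counts$m_class, function(cls) {
      sample(lexicon$entries[[cls]], 1)
    }, character(1))
    list(flip = flip, fab = fab)
  })
  pred_present <- ifelse(res$flip, 1L - counts$binary, counts$binary)
  keep_gold <- counts$binary == 1 & pred_present == 1
  kg <- counts[keep_gold, c("message_id", "m_class")]
  gold_spans <- dplyr::semi_join(
    gold_tbl, kg, by = c("message_id", "m_class")
  )
  fab_rows <- counts$binary == 0 & pred_present == 1
  spans <- dplyr::bind_rows(
    tibble::tibble(
      message_id = gold_spans$message_id, m_class = gold_spans$m_class,
      span = gold_spans$span, valid = TRUE, flag = NA_character_
    ),
    tibble::tibble(
      message_id = counts$message_id[fab_rows],
      m_class = counts$m_class[fab_rows],
      span = res$fab[fab_rows], valid = TRUE, flag = NA_character_
    )
  )
  out <- new_extractions(spans, message_ids(gold))
  attr(out, "flips") <- counts[res$flip, c("message_id", "m_class")]
  out
}

#' @export
print.fourms_genconfig <- function(x, ...) {
  cat(
    "<fourms_genconfig> n_messages=", x$n_messages, ", seed=", x$seed,
    ", L1 counts=", paste(x$l1_counts, collapse = "/"), "\n",
    sep = ""
  )
  invisible(x)
}
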