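ENTITY_TYPES <- c("disease", "symptom", "drug", "mechanism", "department",
                  "body_part")

#' Default planted composition patterns
#'
#' Three 2-hop compositional patterns whose conclusion relation exists in
#' the [synthetic_schema()]: the drug-action chain
#' drug=>mechanism followed by mechanism =>disease implying drug=>disease,
#' the disease-mechanism chain implying disease=>disease, and the
#' symptom-mechanism chain implying symptom=>symptom.
#'
#' @return data.frame with columns `first`, `second`, `implied`.
#' @export
default_pattern_rules <- function() {
  data.frame(
    first = c("drug=>mechanism", "disease=>mechanism", "symptom=>mechanism"),
    second = c("mechanism =>disease", "mechanism =>disease", "mechanism=>symptom"),
    implied = c("drug=>disease", "disease=>disease", "symptom=>symptom"),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic knowledge-graph generator
#'
#' @param n_per_type Entities per entity category; a single count or a named
#'   vector over `disease, symptom, drug, mechanism, department, body_part`.
#' @param edge_density Expected out-degree per head entity and relation
#'   (Poisson mean).
#' @param pattern_rules data.frame `(first, second, implied)` of planted
#'   2-hop compositional rules; endpoint types must be consistent with the
#'   schema and no `implied` relation may be a premise of another rule
#'   (otherwise planted closure edges would create new chains and the
#'   generator ledger could not be audited by exhaustive re-enumeration).
#' @param closure_rate Probability that a chainable pair's implied edge is
#'   materialized.
#' @param holdout_rate Fraction of materialized implied edges withheld from
#'   the training graph and emitted as the test set.
#' @param noise_rate Number of random schema-valid noise edges, as a
#'   fraction of the base edge count. Noise is drawn only on relations that
#'   are not a premise of any rule, and never duplicates an existing or
#'   implied edge.
#' @param seed Integer seed; identical configuration gives byte-identical
#'   output.
#' @param schema A [relation_schema()]; default [synthetic_schema()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_type = 50L, edge_density = 3,
                         pattern_rules = default_pattern_rules(),
                         closure_rate = 0.8, holdout_rate = 0.2,
                         noise_rate = 0.05, seed = 1L,
                         schema = synthetic_schema()) {
  if (length(n_per_type) == 1L && is.null(names(n_per_type)))
    n_per_type <- stats::setNames(rep(as.integer(n_per_type), 6L), ENTITY_TYPES)
  missing <- setdiff(ENTITY_TYPES, names(n_per_type))
  if (length(missing)) stop_("n_per_type missing type(s): %s", paste(missing, collapse = ", "))
  if (any(n_per_type < 1L)) stop_("n_per_type must be positive")
  for (r in c("closure_rate", "holdout_rate", "noise_rate")) {
    v <- get(r)
    if (!is.numeric(v) || v < 0 || v > 1) stop_("%s must be in [0, 1]", r)
  }
  if (edge_density <= 0) stop_("edge_density must be positive")
  ht <- function(r) schema$head_type[match(r, schema$relation)]
  tt <- function(r) schema$tail_type[match(r, schema$relation)]
  pr <- pattern_rules
  unknown <- setdiff(c(pr$first, pr$second, pr$implied), schema$relation)
  if (length(unknown)) stop_("pattern rule relation(s) not in schema: %s",
                             paste(unknown, collapse = ", "))
  bad <- tt(pr$first) != ht(pr$second) | ht(pr$first) != ht(pr$implied) |
    tt(pr$second) != tt(pr$implied)
  if (any(bad)) stop_("type-inconsistent pattern rule: %s + %s => %s",
                      pr$first[bad][1L], pr$second[bad][1L], pr$implied[bad][1L])
  circular <- intersect(pr$implied, c(pr$first, pr$second))
  if (length(circular))
    stop_("implied relation(s) also used as a premise: %s",
          paste(circular, collapse = ", "))
  structure(list(n_per_type = n_per_type[ENTITY_TYPES],
                 edge_density = edge_density, pattern_rules = pr,
                 closure_rate = closure_rate, holdout_rate = holdout_rate,
                 noise_rate = noise_rate, seed = as.integer(seed),
                 schema = schema),
            class = "synth_config")
}

#' Generate a synthetic clinical knowledge graph with planted structure
#'
#' Draws base edges per relation at the configured Poisson out-degree, then
#' for every rule and every chainable pair head -> r1 -> x -> r2 -> tail
#' (no repeated entity) materializes the implied closure edge with
#' probability `closure_rate`; a `holdout_rate` fraction of the
#' materialized closure edges is withheld from the training graph and
#' emitted as a test set; random noise edges are added last. A ledger
#' records every chainable pair with its materialization status so tests
#' can audit the construction by exhaustive path re-enumeration.
#'
#' @param config A [synth_config()].
#' @return Object of class `synthetic_kg`: list with `kg` (the training-side
#'   graph), `holdout` (test graph over the same entity vocabulary),
#'   `ledger` (`chainable`, `heldout`, `train_implied`, `noise`, `base`) and
#'   `config`.
#' @export
generate_kg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  schema <- config$schema
  pr <- config$pattern_rules
  with_seed(config$seed, {
    ents <- lapply(ENTITY_TYPES, function(ty) {
      sprintf("%s:%03d", ty, seq_len(config$n_per_type[[ty]]))
    })
    names(ents) <- ENTITY_TYPES

    # base edges, relation by relation in schema order
    base_list <- vector("list", nrow(schema))
    for (j in seq_len(nrow(schema))) {
      heads <- ents[[schema$head_type[j]]]
      pool <- ents[[schema$tail_type[j]]]
      deg <- pmin(rpois(length(heads), config$edge_density),
                  length(pool) - as.integer(schema$head_type[j] == schema$tail_type[j]))
      hh <- character(0); tt_ <- character(0)
      for (i in seq_along(heads)) {
        if (deg[i] < 1L) next
        cand <- setdiff(pool, heads[i])  # no self-loops
        tails <- sample(cand, deg[i])
        hh <- c(hh, rep(heads[i], deg[i])); tt_ <- c(tt_, tails)
      }
      base_list[[j]] <- data.frame(head = hh, relation = schema$relation[j],
                                   tail = tt_, stringsAsFactors = FALSE)
    }
    base <- do.call(rbind, base_list)
    base_key <- triple_key(base$head, base$relation, base$tail)

    # chainable pairs per rule (exhaustive, acyclic, deduplicated)
    chain_list <- vector("list", nrow(pr))
    for (j in seq_len(nrow(pr))) {
      e1 <- base[base$relation == pr$first[j], , drop = FALSE]
      e2 <- base[base$relation == pr$second[j], , drop = FALSE]
      m <- merge(data.frame(h = e1$head, x = e1$tail, stringsAsFactors = FALSE),
                 data.frame(x = e2$head, t = e2$tail, stringsAsFactors = FALSE),
                 by = "x")
      m <- m[m$h != m$t & m$h != m$x & m$x != m$t, , drop = FALSE]
      if (nrow(m) == 0L) next
      agg <- stats::aggregate(list(witnesses = m$x),
                              by = list(head = m$h, tail = m$t), FUN = length)
      agg <- agg[order(agg$head, agg$tail, method = "radix"), , drop = FALSE]
      chain_list[[j]] <- data.frame(first = pr$first[j], second = pr$second[j],
                                    implied = pr$implied[j], head = agg$head,
                                    tail = agg$tail, witnesses = agg$witnesses,
                                    stringsAsFactors = FALSE)
    }
    chainable <- do.call(rbind, chain_list)
    if (is.null(chainable))
      chainable <- data.frame(first = character(), second = character(),
                              implied = character(), head = character(),
                              tail = character(), witnesses = integer(),
                              stringsAsFactors = FALSE)
    rownames(chainable) <- NULL

    # materialize closure edges; an implied edge already drawn as a base
    # fact stays a base fact and cannot be held out
    n_ch <- nrow(chainable)
    chainable$materialized <- if (n_ch) runif(n_ch) < config$closure_rate else logical(0)
    chainable$already_base <- triple_key(chainable$head, chainable$implied,
                                         chainable$tail) %in% base_key
    eligible <- which(chainable$materialized & !chainable$already_base)
    n_hold <- floor(config$holdout_rate * length(eligible))
    held_idx <- if (n_hold > 0L) sort(sample(eligible, n_hold)) else integer(0)
    chainable$heldout <- seq_len(n_ch) %in% held_idx

    mk_tr <- function(idx) {
      data.frame(head = chainable$head[idx], relation = chainable$implied[idx],
                 tail = chainable$tail[idx], stringsAsFactors = FALSE)
    }
    train_implied <- mk_tr(setdiff(eligible, held_idx))
    heldout <- mk_tr(held_idx)

    # noise edges: only on relations that are no rule's premise, never
    # duplicating an existing or implied edge
    noise_rel <- setdiff(schema$relation, c(pr$first, pr$second))
    forbidden <- c(base_key,
                   triple_key(train_implied$head, train_implied$relation,
                              train_implied$tail),
                   triple_key(heldout$head, heldout$relation, heldout$tail),
                   triple_key(chainable$head, chainable$implied, chainable$tail))
    n_noise <- round(config$noise_rate * nrow(base))
    noise <- data.frame(head = character(), relation = character(),
                        tail = character(), stringsAsFactors = FALSE)
    tries <- 0L
    while (nrow(noise) < n_noise && tries < 50L * max(n_noise, 1L)) {
      tries <- tries + 1L
      rel <- sample(noise_rel, 1L)
      jr <- match(rel, schema$relation)
      h <- sample(ents[[schema$head_type[jr]]], 1L)
      t_ <- sample(ents[[schema$tail_type[jr]]], 1L)
      key <- triple_key(h, rel, t_)
      if (h == t_ || key %in% forbidden) next
      forbidden <- c(forbidden, key)
      noise <- rbind(noise, data.frame(head = h, relation = rel, tail = t_,
                                       stringsAsFactors = FALSE))
    }

    all_entities <- unlist(ents, use.names = FALSE)
    train_kg <- knowledge_graph(rbind(base, train_implied, noise), schema,
                                entities = all_entities)
    holdout_kg <- knowledge_graph(heldout, schema, entities = all_entities)
    structure(list(kg = train_kg, holdout = holdout_kg,
                   ledger = list(chainable = chainable, heldout = heldout,
                                 train_implied = train_implied, noise = noise,
                                 base = base),
                   config = config),
              class = "synthetic_kg")
  })
}

#' @export
print.synthetic_kg <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_kg> train: %d triples | held-out implied: %d",
                     " | chainable pairs: %d\n"),
              nrow(x$kg$triples), nrow(x$holdout$triples),
              nrow(x$ledger$chainable)))
  invisible(x)
}

#' Miner rules matching the planted pattern rules
#'
#' Converts a generator's pattern rules into [composition_rules()] whose
#' composed label is the implied relation, so that
#' `filter_causal(enumerate_chains(kg), planted_rules(sim))` can be compared
#' with the generator ledger.
#'
#' @param sim A `synthetic_kg` object (or a [synth_config()]).
#' @return A [composition_rules()] data.frame.
#' @export
planted_rules <- function(sim) {
  cfg <- if (inherits(sim, "synth_config")) sim else sim$config
  pr <- cfg$pattern_rules
  composition_rules(pr$first, pr$second, pr$implied)
}

#' Generate multilabel syndrome-diagnosis case records
#'
#' Each case draws between `min_labels` and `max_labels` syndromes
#' (uniformly over label counts, syndromes without replacement); its binary
#' symptom feature vector is the union of the owned symptom sets of its
#' syndromes. Feature noise resamples each bit from Bernoulli(0.5) with
#' probability `noise`, so `noise = 0` reproduces the union exactly and
#' `noise = 1` makes features independent of the labels.
#'
#' @param n_cases Number of cases (>= 1).
#' @param noise Per-bit corruption probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param n_symptoms,n_syndromes Feature and label dimensionality
#'   (defaults 121 symptoms, 8 syndromes).
#' @param min_labels,max_labels Per-case label count range (default 2--5).
#' @param symptoms_per_syndrome Size of each syndrome's owned symptom set.
#' @return Object of class `case_table`: list with binary matrices
#'   `features` (n x n_symptoms, symptom-token columns) and `labels`
#'   (n x n_syndromes), plus `ownership` (list of symptom tokens per
#'   syndrome) and the generation parameters.
#' @export
generate_cases <- function(n_cases, noise = 0.1, seed = 1L,
                           n_symptoms = 121L, n_syndromes = 8L,
                           min_labels = 2L, max_labels = 5L,
                           symptoms_per_syndrome = 22L) {
  if (n_cases < 1L) stop_("n_cases must be >= 1")
  if (noise < 0 || noise > 1) stop_("noise must be in [0, 1]")
  if (max_labels > n_syndromes) stop_("max_labels exceeds the number of syndromes")
  symptoms <- sprintf("symptom:%03d", seq_len(n_symptoms))
  syndromes <- sprintf("disease:%03d", seq_len(n_syndromes))
  with_seed(seed, {
    ownership <- lapply(seq_len(n_syndromes), function(i) {
      sort_c(sample(symptoms, min(symptoms_per_syndrome, n_symptoms)))
    })
    names(ownership) <- syndromes
    labels <- matrix(0L, n_cases, n_syndromes, dimnames = list(NULL, syndromes))
    features <- matrix(0L, n_cases, n_symptoms, dimnames = list(NULL, symptoms))
    for (i in seq_len(n_cases)) {
      k <- sample(min_labels:max_labels, 1L)
      syn <- sample(seq_len(n_syndromes), k)
      labels[i, syn] <- 1L
      features[i, unique(unlist(ownership[syn]))] <- 1L
    }
    if (noise > 0) {
      resample <- matrix(runif(n_cases * n_symptoms) < noise, n_cases)
      coin <- matrix(rbinom(n_cases * n_symptoms, 1L, 0.5), n_cases)
      features[resample] <- coin[resample]
    }
    structure(list(features = features, labels = labels,
                   ownership = ownership, noise = noise, seed = seed,
                   min_labels = min_labels, max_labels = max_labels),
              class = "case_table")
  })
}

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf("<case_table> %d cases, %d symptom features, %d syndrome labels\n",
              nrow(x$features), ncol(x$features), ncol(x$labels)))
  invisible(x)
}

#' Syndrome-to-symptom ownership triples of a case table
#'
#' Expresses the generator's planted syndrome -> symptom ownership as
#' `disease=>symptom` triples, e.g. to build a knowledge graph from which
#' symptom embeddings can be learned.
#'
#' @param cases A `case_table` from [generate_cases()].
#' @return data.frame with columns `head`, `relation`, `tail`.
#' @export
ownership_triples <- function(cases) {
  syn <- rep(names(cases$ownership), lengths(cases$ownership))
  data.frame(head = syn, relation = "disease=>symptom",
             tail = unlist(cases$ownership, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Read/write case tables as CSV
#'
#' One row per case; symptom feature columns first, then syndrome label
#' columns, with a header row.
#'
#' @param cases A `case_table`.
#' @param path CSV file path.
#' @return `write_cases` returns `path` invisibly; `read_cases` returns a
#'   `case_table` (without generator metadata).
#' @export
write_cases <- function(cases, path) {
  df <- cbind(as.data.frame(cases$features), as.data.frame(cases$labels))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cases
#' @export
read_cases <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  is_label <- grepl("^disease:", names(df))
  structure(list(features = as.matrix(df[, !is_label, drop = FALSE]),
                 labels = as.matrix(df[, is_label, drop = FALSE]),
                 ownership = NULL),
            class = "case_table")
}
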