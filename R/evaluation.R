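#' Filter index of known true triples
#'
#' Maps (head, relation) to the set of known true tails and (relation, tail)
#' to the set of known true heads, over every split passed in (conventionally
#' train, validation and test). Used by the filtered evaluation protocol:
#' when ranking a query's candidates, all other known true entities are
#' removed before the target's rank is read off.
#'
#' @param ... [knowledge_graph()]s (or data.frames with head/relation/tail).
#' @return Object of class `filter_index`.
#' @export
filter_index <- function(...) {
  parts <- lapply(list(...), function(k) {
    if (inherits(k, "knowledge_graph")) k$triples else k
  })
  tr <- do.call(rbind, parts)
  tr <- tr[!duplicated(triple_key(tr$head, tr$relation, tr$tail)), , drop = FALSE]
  ht <- list2env(split(tr$tail, pair_key(tr$head, tr$relation)),
                 envir = new.env(parent = emptyenv()))
  th <- list2env(split(tr$head, pair_key(tr$relation, tr$tail)),
                 envir = new.env(parent = emptyenv()))
  structure(list(ht = ht, th = th, n_triples = nrow(tr)),
            class = "filter_index")
}

known_tails <- function(filter, head, relation) {
  filter$ht[[pair_key(head, relation)]] %||% character(0)
}

known_heads <- function(filter, relation, tail) {
  filter$th[[pair_key(relation, tail)]] %||% character(0)
}

#' Filtered rank of a target entity
#'
#' Rank of the target within the filtered candidate set: candidates in
#' `known_true` (other known correct answers) are removed, the target itself
#' is re-admitted, and the rank is 1 plus the number of remaining candidates
#' scoring strictly higher, with ties broken uniformly at random (optimistic
#' tie-breaking is known to inflate ranking metrics). The tie-break draws
#' from the calling RNG state; wrap in a seeded context for reproducibility.
#'
#' @param scores Numeric vector of candidate scores (higher = better).
#' @param target Integer index of the true entity in `scores`.
#' @param known_true Integer indices of other known true entities to filter
#'   out (the target may be included; it is always re-admitted).
#' @return Integer rank >= 1.
#' @export
filtered_rank <- function(scores, target, known_true = integer(0)) {
  if (target < 1L || target > length(scores)) stop_("target id out of range")
  drop <- setdiff(known_true, target)
  other <- setdiff(seq_along(scores), c(drop, target))
  s_t <- scores[target]
  higher <- sum(scores[other] > s_t)
  ties <- sum(scores[other] == s_t)
  offset <- if (ties > 0L) sample.int(ties + 1L, 1L) - 1L else 0L
  1L + higher + offset
}

#' Mean reciprocal rank
#'
#' @param ranks Integer vector of ranks (one head query and one tail query
#'   per test triple).
#' @return Mean of `1/ranks`.
#' @export
mrr <- function(ranks) {
  if (length(ranks) == 0L) stop_("empty rank list")
  mean(1 / ranks)
}

#' Hits@N
#'
#' @param ranks Integer vector of ranks.
#' @param N Cutoff (>= 1).
#' @return Fraction of ranks `<= N`.
#' @export
hits_at_n <- function(ranks, N) {
  if (N < 1L) stop_("N must be >= 1")
  mean(ranks <= N)
}

#' A scorer that ranks candidates at random
#'
#' Baseline for calibrating ranking metrics: every candidate receives an
#' independent uniform score, so the filtered rank of the target is uniform
#' over the filtered candidate set.
#'
#' @param entities Character vector of entity tokens.
#' @return Object of class `random_scorer`.
#' @export
random_scorer <- function(entities) {
  structure(list(entities = sort_c(entities)), class = "random_scorer")
}

# per-model entity ordering and batched query scoring ------------------------

model_entities <- function(model) {
  if (inherits(model, "coke_model"))
    model$vocab$tokens[model$vocab$entity_ids]
  else model$entities
}

# scores matrix (n_queries x n_entities) for (h, r, ?) or (?, r, t) queries
score_queries <- function(model, heads, relations, tails, direction) {
  UseMethod("score_queries")
}

#' @export
score_queries.coke_model <- function(model, heads, relations, tails,
                                     direction) {
  vocab <- model$vocab
  nq <- length(relations)
  if (direction == "tail") {
    ids <- cbind(vocab_lookup(vocab, heads), vocab_lookup(vocab, relations),
                 rep(vocab$mask_id, nq))
    mask_pos <- rep(3L, nq)
  } else {
    ids <- cbind(rep(vocab$mask_id, nq), vocab_lookup(vocab, relations),
                 vocab_lookup(vocab, tails))
    mask_pos <- rep(1L, nq)
  }
  out <- matrix(0, nq, length(vocab$entity_ids))
  for (s in seq(1L, nq, by = 1024L)) {
    idx <- s:min(s + 1023L, nq)
    out[idx, ] <- coke_score(model, ids[idx, , drop = FALSE], mask_pos[idx])
  }
  out
}

#' @export
score_queries.random_scorer <- function(model, heads, relations, tails,
                                        direction) {
  nq <- max(length(heads), length(tails), length(relations))
  matrix(runif(nq * length(model$entities)), nq)
}

#' Filtered link-prediction evaluation
#'
#' For every test triple (h, r, t), scores all entities for the tail query
#' (h, r, ?) and the head query (?, r, t), computes filtered ranks against
#' the filter index, and aggregates MRR and Hits@1/3/10 over the
#' 2 x |test| queries.
#'
#' @param model A trained `coke_model`, a baseline `scoring_model`, or a
#'   [random_scorer()].
#' @param test [knowledge_graph()] (or triple data.frame) of test triples.
#' @param filter A [filter_index()] over train, validation and test.
#' @param seed Integer seed for tie-breaking (and random scorers).
#' @return Object of class `ranking_result`: list with `per_query`
#'   (data.frame of queries and filtered ranks), `mrr`, `hits` (named vector
#'   for N = 1, 3, 10) and `n_test`.
#' @export
evaluate_link_prediction <- function(model, test, filter, seed = 1L) {
  tr <- if (inherits(test, "knowledge_graph")) test$triples else test
  if (nrow(tr) == 0L) stop_("empty test set")
  ents <- model_entities(model)
  with_seed(seed, {
    rows <- list()
    for (direction in c("tail", "head")) {
      sc <- score_queries(model, tr$head, tr$relation, tr$tail, direction)
      for (i in seq_len(nrow(tr))) {
        if (direction == "tail") {
          target_tok <- tr$tail[i]
          known <- known_tails(filter, tr$head[i], tr$relation[i])
        } else {
          target_tok <- tr$head[i]
          known <- known_heads(filter, tr$relation[i], tr$tail[i])
        }
        target <- match(target_tok, ents)
        if (is.na(target)) stop_("test entity not scoreable: %s", target_tok)
        rk <- filtered_rank(sc[i, ], target,
                            stats::na.omit(match(known, ents)))
        rows[[length(rows) + 1L]] <-
          data.frame(head = tr$head[i], relation = tr$relation[i],
                     tail = tr$tail[i], direction = direction, rank = rk,
                     stringsAsFactors = FALSE)
      }
    }
    per_query <- do.call(rbind, rows)
    ranking_result(per_query, n_test = nrow(tr))
  })
}

ranking_result <- function(per_query, n_test) {
  structure(list(per_query = per_query, mrr = mrr(per_query$rank),
                 hits = c(`1` = hits_at_n(per_query$rank, 1L),
                          `3` = hits_at_n(per_query$rank, 3L),
                          `10` = hits_at_n(per_query$rank, 10L)),
                 n_test = n_test),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> %d queries | MRR %.4f | Hits@1 %.3f @3 %.3f @10 %.3f\n",
              nrow(x$per_query), x$mrr, x$hits["1"], x$hits["3"], x$hits["10"]))
  invisible(x)
}

#' Build path queries by exhaustive traversal
#'
#' Enumerates the (source, relation path) pairs of a knowledge graph
#' (conventionally the full graph: train, validation and test together,
#' since a path query's ground-truth target set is everything reachable)
#' and records each pair's complete target set.
#'
#' @param kg A [knowledge_graph()] or a `path_instances` data.frame.
#' @param max_hops Path length bound when `kg` is a graph.
#' @param rules Optional [composition_rules()]; if given, only rule-matching
#'   paths become queries.
#' @return data.frame of class `path_queries` with columns `source`,
#'   `relations` (list-column) and `targets` (list-column).
#' @export
path_query_set <- function(kg, max_hops = 2L, rules = NULL) {
  paths <- if (inherits(kg, "knowledge_graph")) {
    enumerate_chains(kg, max_hops)
  } else kg
  if (!is.null(rules)) paths <- filter_causal(paths, rules)
  if (nrow(paths) == 0L) stop_("no paths to build queries from")
  key <- paste(paths$source,
               vapply(paths$relations, paste, character(1), collapse = SEP),
               sep = SEP)
  groups <- split(seq_len(nrow(paths)), key)
  groups <- groups[sort_c(names(groups))]
  out <- data.frame(source = vapply(groups, function(ix) paths$source[ix[1L]],
                                    character(1)),
                    stringsAsFactors = FALSE)
  out$relations <- lapply(groups, function(ix) paths$relations[[ix[1L]]])
  out$targets <- lapply(groups, function(ix) sort_c(unique(paths$target[ix])))
  rownames(out) <- NULL
  class(out) <- c("path_queries", "data.frame")
  out
}

#' Path-query answering evaluation
#'
#' For each query (source, r1, ..., rk) the terminal entity of the path
#' sequence is masked and all entities are ranked; each true target is
#' scored with the query's other known targets filtered out. Aggregates
#' MRR and Hits@N over all (query, target) pairs.
#'
#' @param model A trained `coke_model`.
#' @param queries A [path_query_set()] data.frame.
#' @param seed Integer seed for tie-breaking.
#' @return A `ranking_result`.
#' @export
evaluate_path_query <- function(model, queries, seed = 1L) {
  if (nrow(queries) == 0L) stop_("empty query set")
  vocab <- model$vocab
  ents <- model_entities(model)
  hops <- lengths(queries$relations)
  with_seed(seed, {
    rows <- list()
    for (k in sort(unique(hops))) {
      sub <- queries[hops == k, , drop = FALSE]
      rel_ids <- matrix(vocab_lookup(vocab, unlist(sub$relations)),
                        nrow(sub), k, byrow = TRUE)
      ids <- cbind(vocab_lookup(vocab, sub$source), rel_ids,
                   rep(vocab$mask_id, nrow(sub)))
      if (ncol(ids) > model$config$max_sequence_length)
        stop_("path longer than max_sequence_length")
      sc <- matrix(0, nrow(sub), length(ents))
      for (s in seq(1L, nrow(sub), by = 1024L)) {
        idx <- s:min(s + 1023L, nrow(sub))
        sc[idx, ] <- coke_score(model, ids[idx, , drop = FALSE],
                                rep(ncol(ids), length(idx)))
      }
      for (i in seq_len(nrow(sub))) {
        known <- stats::na.omit(match(sub$targets[[i]], ents))
        for (tok in sub$targets[[i]]) {
          target <- match(tok, ents)
          rk <- filtered_rank(sc[i, ], target, known)
          rows[[length(rows) + 1L]] <-
            data.frame(source = sub$source[i],
                       path = paste(sub$relations[[i]], collapse = " | "),
                       target = tok, rank = rk, stringsAsFactors = FALSE)
        }
      }
    }
    per_query <- do.call(rbind, rows)
    structure(list(per_query = per_query, mrr = mrr(per_query$rank),
                   hits = c(`1` = hits_at_n(per_query$rank, 1L),
                            `3` = hits_at_n(per_query$rank, 3L),
                            `10` = hits_at_n(per_query$rank, 10L)),
                   n_test = nrow(queries)),
              class = "ranking_result")
  })
}

#' Random-ranking expectation of Hits@N
#'
#' Closed-form mean and standard deviation of Hits@N when every target's
#' filtered rank is uniform over its filtered candidate set: per query,
#' P(rank <= N) = min(N / m, 1) with m filtered candidates.
#'
#' @param m_candidates Integer vector: filtered candidate-set size per query.
#' @param N Cutoff.
#' @return List with `mean` and `sd` of the Hits@N estimate over the
#'   queries.
#' @export
random_hits_expectation <- function(m_candidates, N) {
  p <- pmin(N / m_candidates, 1)
  list(mean = mean(p), sd = sqrt(sum(p * (1 - p))) / length(p))
}
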