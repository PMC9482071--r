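#' Construct a knowledge graph
#'
#' A knowledge graph G = (E, R, S) holds an entity vocabulary E, a relation
#' schema R and a deduplicated triple multiset S of (head, relation, tail)
#' facts, plus a relation-keyed adjacency index used by the path miner.
#'
#' @param triples data.frame with character columns `head`, `relation`,
#'   `tail`. Duplicates are dropped (a message reports the count).
#' @param schema A [relation_schema()]; every triple's relation must be in it.
#' @param entities Optional character vector of entity tokens. Defaults to
#'   the tokens appearing in `triples`; may be a superset (e.g. the full
#'   vocabulary of a parent graph when building splits).
#' @return An object of class `knowledge_graph` with elements `entities`
#'   (sorted, unique), `schema`, `triples` and `index`.
#' @export
knowledge_graph <- function(triples, schema, entities = NULL) {
  stopifnot(inherits(schema, "relation_schema"))
  if (is.null(triples) || nrow(triples) == 0L) {
    triples <- data.frame(head = character(), relation = character(),
                          tail = character(), stringsAsFactors = FALSE)
  }
  triples <- data.frame(head = as.character(triples$head),
                        relation = as.character(triples$relation),
                        tail = as.character(triples$tail),
                        stringsAsFactors = FALSE)
  bad <- !nzchar(triples$head) | !nzchar(triples$relation) | !nzchar(triples$tail)
  if (any(bad)) stop_("triple with empty token at row %d", which(bad)[1L])
  unknown <- setdiff(unique(triples$relation), schema$relation)
  if (length(unknown))
    stop_("unknown relation token(s): %s", paste(unknown, collapse = ", "))
  dup <- duplicated(triple_key(triples$head, triples$relation, triples$tail))
  if (any(dup)) {
    message(sum(dup), " duplicate triple(s) dropped")
    triples <- triples[!dup, , drop = FALSE]
    rownames(triples) <- NULL
  }
  seen <- unique(c(triples$head, triples$tail))
  if (is.null(entities)) {
    entities <- seen
  } else {
    missing <- setdiff(seen, entities)
    if (length(missing))
      stop_("triples mention entities absent from the vocabulary: %s",
            paste(head(missing, 5L), collapse = ", "))
  }
  kg <- structure(list(entities = sort_c(unique(as.character(entities))),
                       schema = schema, triples = triples, index = NULL),
                  class = "knowledge_graph")
  kg$index <- build_index(kg)
  kg
}

# relation-keyed adjacency: out[[rel]][[head]] = tails, in_[[rel]][[tail]] = heads
build_index <- function(kg) {
  tr <- kg$triples
  out <- list(); in_ <- list()
  for (rel in unique(tr$relation)) {
    sub <- tr[tr$relation == rel, , drop = FALSE]
    out[[rel]] <- lapply(split(sub$tail, sub$head), sort_c)
    in_[[rel]] <- lapply(split(sub$head, sub$tail), sort_c)
  }
  list(out = out, "in" = in_)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d entities, %d relations, %d triples\n",
              length(x$entities), nrow(x$schema), nrow(x$triples)))
  invisible(x)
}

#' Test whether a triple is present in a knowledge graph
#'
#' @param kg A [knowledge_graph()].
#' @param head,relation,tail Character vectors (recycled to common length).
#' @return Logical vector.
#' @export
has_triple <- function(kg, head, relation, tail) {
  triple_key(head, relation, tail) %in%
    triple_key(kg$triples$head, kg$triples$relation, kg$triples$tail)
}

#' Load triples from a tab-separated file
#'
#' Reads a UTF-8 TSV with three columns (head, relation, tail), one triple
#' per line, no header -- the conventional layout for knowledge-graph
#' embedding datasets. Duplicate triples are dropped with a message.
#'
#' @param path File path.
#' @param schema A [relation_schema()]; unknown relation tokens are an error.
#' @return A [knowledge_graph()].
#' @export
load_triples <- function(path, schema) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (!length(lines)) return(knowledge_graph(NULL, schema))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 3L)) {
    ln <- which(keep)[which(nfield != 3L)[1L]]
    stop_("malformed line %d: expected 3 tab-separated fields, found %d",
          ln, nfield[nfield != 3L][1L])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  knowledge_graph(data.frame(head = m[, 1L], relation = m[, 2L],
                             tail = m[, 3L], stringsAsFactors = FALSE),
                  schema)
}

#' Write triples to a tab-separated file in canonical form
#'
#' The canonical form is the deduplicated triple set sorted by
#' (head, relation, tail) in C-locale order, so that
#' `write_triples(load_triples(f))` is byte-stable.
#'
#' @param kg A [knowledge_graph()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_triples <- function(kg, path) {
  tr <- kg$triples
  o <- order(tr$head, tr$relation, tr$tail, method = "radix")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(tr))
    writeLines(paste(tr$head[o], tr$relation[o], tr$tail[o], sep = "\t"),
               con, useBytes = TRUE)
  invisible(path)
}

#' Split a knowledge graph into train/validation/test sets
#'
#' Randomly partitions the triples, then repairs leakage: any entity or
#' relation that appears in the validation or test split but in no training
#' triple has its triples reassigned to train, because filtered ranking is
#' undefined for never-seen tokens. The three splits share the parent
#' graph's full entity vocabulary.
#'
#' @param kg A [knowledge_graph()].
#' @param fractions Numeric length-3 (train, valid, test); positive, sum 1.
#' @param seed Integer seed; the same seed gives an identical split.
#' @return Named list of three [knowledge_graph()]s: `train`, `valid`, `test`.
#' @export
split_kg <- function(kg, fractions = c(0.9, 0.05, 0.05), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop_("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_("fractions must sum to 1 (got %.6f)", sum(fractions))
  tr <- kg$triples
  n <- nrow(tr)
  perm <- with_seed(seed, sample.int(max(n, 1L)))[seq_len(n)]
  n_valid <- floor(n * fractions[2L])
  n_test <- floor(n * fractions[3L])
  assign_ <- rep("train", n)
  if (n_valid > 0L) assign_[perm[seq_len(n_valid)]] <- "valid"
  if (n_test > 0L) assign_[perm[n_valid + seq_len(n_test)]] <- "test"

  moved <- 0L
  repeat {
    in_train <- assign_ == "train"
    ents <- c(tr$head[in_train], tr$tail[in_train])
    rels <- tr$relation[in_train]
    bad <- !in_train & (!(tr$head %in% ents) | !(tr$tail %in% ents) |
                          !(tr$relation %in% rels))
    if (!any(bad)) break
    assign_[bad] <- "train"
    moved <- moved + sum(bad)
  }
  if (moved > 0L)
    message(moved, " triple(s) reassigned to train to avoid unseen tokens")
  mk <- function(which) {
    knowledge_graph(tr[assign_ == which, , drop = FALSE], kg$schema,
                    entities = kg$entities)
  }
  list(train = mk("train"), valid = mk("valid"), test = mk("test"))
}

#' Per-relation multiplicity statistics
#'
#' One row per schema relation with the number of distinct head entities,
#' distinct tail entities and triples (zeros for unused relations), the
#' summary conventionally reported for clinical KGs.
#'
#' @param kg A [knowledge_graph()].
#' @return data.frame with columns `relation`, `heads`, `tails`, `triples`.
#' @export
relation_stats <- function(kg) {
  tr <- kg$triples
  out <- data.frame(relation = kg$schema$relation,
                    heads = 0L, tails = 0L, triples = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    sub <- tr[tr$relation == out$relation[i], , drop = FALSE]
    out$heads[i] <- length(unique(sub$head))
    out$tails[i] <- length(unique(sub$tail))
    out$triples[i] <- nrow(sub)
  }
  out
}

#' Token vocabulary of a knowledge graph
#'
#' Assigns integer ids to special tokens, entities and relations. Ids are
#' deterministic: `[PAD]` = 1, `[MASK]` = 2, then entities in C-locale
#' sorted order, then schema relations in sorted order. Entity ids are the
#' contiguous block `3 : (2 + n_entities)`, which the prediction head uses
#' to restrict its candidate set to entities.
#'
#' @param kg A [knowledge_graph()].
#' @return An object of class `kg_vocabulary`: list with `tokens` (id ->
#'   token), `id` (named token -> id map), `pad_id`, `mask_id`,
#'   `entity_ids`, `relation_ids`.
#' @export
kg_vocabulary <- function(kg) {
  ents <- sort_c(kg$entities)
  rels <- sort_c(kg$schema$relation)
  clash <- intersect(ents, rels)
  if (length(clash))
    stop_("token(s) used as both entity and relation: %s",
          paste(clash, collapse = ", "))
  tokens <- c("[PAD]", "[MASK]", ents, rels)
  id <- seq_along(tokens)
  names(id) <- tokens
  structure(list(tokens = tokens, id = id, pad_id = 1L, mask_id = 2L,
                 entity_ids = seq_along(ents) + 2L,
                 relation_ids = seq_along(rels) + 2L + length(ents)),
            class = "kg_vocabulary")
}

vocab_lookup <- function(vocab, tokens) {
  ids <- unname(vocab$id[tokens])
  if (anyNA(ids))
    stop_("token(s) not in vocabulary: %s",
          paste(unique(tokens[is.na(ids)]), collapse = ", "))
  ids
}
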