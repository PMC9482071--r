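# Shared fixtures, built in code at test time.

# Schema for the drug-mechanism-disease worked example: metformin's
# mechanism targets insulin resistance, which treats diabetes mellitus;
# dyslipidemia co-occurs with two diseases (not chainable).
fig1_schema <- function() {
  relation_schema(
    relation = c("mechanism", "treat", "symptom"),
    head_type = c("drug", "mechanism", "symptom"),
    tail_type = c("mechanism", "disease", "disease"))
}

fig1_positive <- function() {
  data.frame(head = c("metformin", "insulin resistance"),
             relation = c("mechanism", "treat"),
             tail = c("insulin resistance", "diabetes mellitus"),
             stringsAsFactors = FALSE)
}

fig1_negative <- function() {
  data.frame(head = c("dyslipidemia", "dyslipidemia"),
             relation = c("symptom", "symptom"),
             tail = c("diabetes mellitus", "CKD"),
             stringsAsFactors = FALSE)
}

fig1_kg <- function(extra = NULL) {
  knowledge_graph(rbind(fig1_positive(), fig1_negative(), extra),
                  fig1_schema())
}

# Random schema-valid KG over the synthetic schema (for property tests).
random_kg <- function(n_triples, seed, schema = synthetic_schema(),
                      n_per_type = 8L) {
  ents <- lapply(pathcoke:::ENTITY_TYPES, function(ty) {
    sprintf("%s:%02d", ty, seq_len(n_per_type))
  })
  names(ents) <- pathcoke:::ENTITY_TYPES
  withr::with_seed(seed, {
    ri <- sample.int(nrow(schema), n_triples, replace = TRUE)
    tr <- data.frame(
      head = vapply(ri, function(j) sample(ents[[schema$head_type[j]]], 1L),
                    character(1)),
      relation = schema$relation[ri],
      tail = vapply(ri, function(j) sample(ents[[schema$tail_type[j]]], 1L),
                    character(1)),
      stringsAsFactors = FALSE)
    tr <- tr[tr$head != tr$tail, , drop = FALSE]
    suppressMessages(knowledge_graph(tr, schema))
  })
}

# Brute-force path enumeration oracle: depth-first expansion over an
# adjacency list, independent of the miner's iterative merge-join.
brute_force_paths <- function(kg, max_hops = 2L) {
  tr <- kg$triples
  tr <- tr[tr$head != tr$tail, , drop = FALSE]
  by_head <- split(seq_len(nrow(tr)), tr$head)
  out <- list()
  extend <- function(nodes, rels) {
    cur <- nodes[length(nodes)]
    nxt <- by_head[[cur]]
    for (j in nxt) {
      if (tr$tail[j] %in% nodes) next
      nodes2 <- c(nodes, tr$tail[j])
      rels2 <- c(rels, tr$relation[j])
      if (length(rels2) >= 2L) {
        out[[length(out) + 1L]] <<-
          list(source = nodes2[1L], target = nodes2[length(nodes2)],
               relations = rels2, intermediates = nodes2[-c(1L, length(nodes2))])
      }
      if (length(rels2) < max_hops) extend(nodes2, rels2)
    }
  }
  for (i in seq_len(nrow(tr))) {
    extend(c(tr$head[i], tr$tail[i]), tr$relation[i])
  }
  out
}

path_key_set <- function(paths_df) {
  sort(vapply(seq_len(nrow(paths_df)), function(i) {
    paste(paths_df$source[i], paste(paths_df$relations[[i]], collapse = "|"),
          paste(paths_df$intermediates[[i]], collapse = "|"),
          paths_df$target[i], sep = "@")
  }, character(1)))
}

brute_key_set <- function(paths_list) {
  sort(vapply(paths_list, function(p) {
    paste(p$source, paste(p$relations, collapse = "|"),
          paste(p$intermediates, collapse = "|"), p$target, sep = "@")
  }, character(1)))
}

# small trained model cache shared across tests in a session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}
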