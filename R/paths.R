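SEP <- "\x1f"

#' Composition rules for causal path filtering
#'
#' A composition rule whitelists an ordered pair of relations whose chain
#' head -> r1 -> x -> r2 -> tail is causally interpretable (e.g. a drug's
#' mechanism followed by a mechanism treating a disease), and names the
#' composed pseudo-relation carried by the resulting path triple. Pure
#' co-occurrence fan-outs (two edges sharing a head) are never chainable and
#' so are rejected by construction.
#'
#' @param first,second Character vectors of premise relation names.
#' @param label Composed labels; defaults to `first`-`second` joined with
#'   `"-"` (the conventional printed form, e.g. `"mechanism-treat"`).
#' @param schema Optional [relation_schema()]; if given, `first`/`second`
#'   must be schema relations and chains must be endpoint-type consistent.
#' @return data.frame of class `composition_rules` with columns `first`,
#'   `second`, `label`.
#' @export
composition_rules <- function(first, second,
                              label = paste(first, second, sep = "-"),
                              schema = NULL) {
  first <- as.character(first); second <- as.character(second)
  label <- as.character(label)
  if (length(first) != length(second) || length(first) != length(label))
    stop_("first, second and label must have equal length")
  if (any(!nzchar(label))) stop_("composed labels must be non-empty")
  if (!is.null(schema)) {
    unknown <- setdiff(c(first, second), schema$relation)
    if (length(unknown))
      stop_("rule relation(s) not in schema: %s", paste(unknown, collapse = ", "))
    ht <- function(r) schema$head_type[match(r, schema$relation)]
    tt <- function(r) schema$tail_type[match(r, schema$relation)]
    bad <- tt(first) != ht(second)
    if (any(bad))
      stop_("type-inconsistent rule: tail type of '%s' is not head type of '%s'",
            first[bad][1L], second[bad][1L])
  }
  out <- data.frame(first = first, second = second, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("composition_rules", "data.frame")
  out
}

#' Read composition rules from a YAML file
#'
#' The file is a list of records `{first, second, label}` (`label` optional).
#'
#' @param path YAML file path.
#' @param schema Optional [relation_schema()] for validation.
#' @return A [composition_rules()] data.frame.
#' @export
read_rules <- function(path, schema = NULL) {
  recs <- yaml::read_yaml(path)
  first <- vapply(recs, function(r) r$first, character(1))
  second <- vapply(recs, function(r) r$second, character(1))
  label <- vapply(recs, function(r) r$label %||% paste(r$first, r$second, sep = "-"),
                  character(1))
  composition_rules(first, second, label, schema = schema)
}

#' Enumerate chainable relation paths of a knowledge graph
#'
#' Yields every directed path source -> r1 -> ... -> rk -> target
#' (2 <= k <= `max_hops`) in which the tail entity of each step is the head
#' entity of the next and no entity is visited twice. Two edges merely
#' sharing a head entity (co-occurrence) are not chainable. The result is
#' in a deterministic C-locale sorted order, independent of triple-file
#' line order.
#'
#' @param kg A [knowledge_graph()].
#' @param max_hops Maximum path length in hops (>= 2). Default 2: clinical
#'   causal chains of interest (drug -> mechanism -> disease) are 2-hop.
#' @return data.frame of class `path_instances` with columns `source`,
#'   `target`, `hops`, and list-columns `relations`, `intermediates`.
#' @export
enumerate_chains <- function(kg, max_hops = 2L) {
  if (max_hops < 2L) stop_("max_hops must be >= 2")
  tr <- kg$triples
  empty <- data.frame(source = character(), target = character(),
                      hops = integer(), stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) {
    empty$relations <- list(); empty$intermediates <- list()
    class(empty) <- c("path_instances", "data.frame")
    return(empty)
  }
  ed <- data.frame(h = tr$head, r = tr$relation, t = tr$tail,
                   stringsAsFactors = FALSE)
  ed <- ed[ed$h != ed$t, , drop = FALSE]  # self-loops cannot extend a path
  # current frontier: delimited node / relation strings
  cur <- data.frame(source = ed$h, rels = ed$r, nodes = ed$h, target = ed$t,
                    stringsAsFactors = FALSE)
  acc <- vector("list", max_hops - 1L)
  for (k in 2:max_hops) {
    if (nrow(cur) == 0L) break
    ext <- merge(cur, ed, by.x = "target", by.y = "h", sort = FALSE)
    if (nrow(ext) == 0L) break
    # old target becomes an intermediate; reject revisits of any path node
    nodes_new <- paste(ext$nodes, ext$target, sep = SEP)
    visited <- vapply(seq_len(nrow(ext)), function(i) {
      ext$t[i] %in% strsplit(nodes_new[i], SEP, fixed = TRUE)[[1L]]
    }, logical(1))
    ext <- ext[!visited, , drop = FALSE]
    nodes_new <- nodes_new[!visited]
    if (nrow(ext) == 0L) break
    cur <- data.frame(source = ext$source,
                      rels = paste(ext$rels, ext$r, sep = SEP),
                      nodes = nodes_new, target = ext$t,
                      stringsAsFactors = FALSE)
    acc[[k - 1L]] <- data.frame(source = cur$source, target = cur$target,
                                hops = k, rels = cur$rels, nodes = cur$nodes,
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  if (is.null(out)) {
    empty$relations <- list(); empty$intermediates <- list()
    class(empty) <- c("path_instances", "data.frame")
    return(empty)
  }
  o <- order(out$hops, out$source, out$rels, out$nodes, out$target,
             method = "radix")
  out <- out[o, , drop = FALSE]
  res <- data.frame(source = out$source, target = out$target, hops = out$hops,
                    stringsAsFactors = FALSE)
  res$relations <- strsplit(out$rels, SEP, fixed = TRUE)
  mids <- strsplit(out$nodes, SEP, fixed = TRUE)
  res$intermediates <- lapply(mids, function(x) x[-1L])
  rownames(res) <- NULL
  class(res) <- c("path_instances", "data.frame")
  res
}

# Fold a relation sequence through the rule cascade; NA if no rule applies.
compose_label <- function(rel_seq, rules) {
  cur <- rel_seq[[1L]]
  for (j in 2:length(rel_seq)) {
    hit <- which(rules$first == cur & rules$second == rel_seq[[j]])
    if (!length(hit)) return(NA_character_)
    cur <- rules$label[hit[1L]]
  }
  cur
}

#' Filter paths with causal-constraint composition rules
#'
#' Keeps exactly the paths whose relation sequence matches a rule (for
#' 2-hop paths, a `(first, second)` pair; longer paths must compose through
#' a cascade of rules, each consuming the previous composed label and the
#' next relation). Matching paths are assigned the rule's composed label and
#' deduplicated on (source, composed label, target).
#'
#' @param paths A `path_instances` data.frame from [enumerate_chains()].
#' @param rules A [composition_rules()] data.frame.
#' @return `path_instances` with an additional `composed_label` column,
#'   deduplicated on (source, composed_label, target).
#' @export
filter_causal <- function(paths, rules) {
  if (nrow(paths) == 0L || nrow(rules) == 0L) {
    out <- paths[integer(0), , drop = FALSE]
    out$composed_label <- character(0)
    class(out) <- c("path_instances", "data.frame")
    return(out)
  }
  labels <- vapply(paths$relations, compose_label, character(1), rules = rules)
  keep <- !is.na(labels)
  out <- paths[keep, , drop = FALSE]
  out$composed_label <- labels[keep]
  dup <- duplicated(triple_key(out$source, out$composed_label, out$target))
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("path_instances", "data.frame")
  out
}

#' Collapse filtered paths to composed-relation triples
#'
#' Each deduplicated path becomes a triple
#' (source, composed label, target); composed labels form a derived relation
#' vocabulary and must not collide with base relations.
#'
#' @param paths A `path_instances` data.frame with `composed_label`
#'   (from [filter_causal()]).
#' @param schema Optional [relation_schema()]; a composed label equal to a
#'   base relation is an error.
#' @return data.frame with columns `head`, `relation`, `tail`; attribute
#'   `derived_relations` lists the composed labels used.
#' @export
paths_to_triples <- function(paths, schema = NULL) {
  if (is.null(paths$composed_label) && nrow(paths) > 0L)
    stop_("paths must be filtered (no composed_label column)")
  if (nrow(paths) == 0L) {
    out <- data.frame(head = character(), relation = character(),
                      tail = character(), stringsAsFactors = FALSE)
    attr(out, "derived_relations") <- character(0)
    return(out)
  }
  if (!is.null(schema)) {
    clash <- intersect(unique(paths$composed_label), schema$relation)
    if (length(clash))
      stop_("composed label(s) collide with base relations: %s",
            paste(clash, collapse = ", "))
  }
  out <- data.frame(head = paths$source, relation = paths$composed_label,
                    tail = paths$target, stringsAsFactors = FALSE)
  out <- out[!duplicated(triple_key(out$head, out$relation, out$tail)), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "derived_relations") <- sort_c(unique(out$relation))
  out
}
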