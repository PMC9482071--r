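#' Relation schema for a clinical knowledge graph
#'
#' A relation schema lists the admissible relation types of a knowledge graph
#' together with the entity category at each endpoint. Entity categories are
#' the six clinical types `disease`, `symptom`, `drug`, `mechanism`,
#' `department` and `body_part`.
#'
#' @param relation Character vector of unique relation names.
#' @param head_type,tail_type Character vectors (same length as `relation`)
#'   giving the entity category at the head/tail of each relation.
#' @return An object of class `relation_schema`: a data.frame with columns
#'   `relation`, `head_type`, `tail_type`.
#' @seealso [default_schema()] for the 17-relation clinical default,
#'   [synthetic_schema()] for the extended schema used by the generator.
#' @export
relation_schema <- function(relation, head_type, tail_type) {
  relation <- as.character(relation)
  head_type <- as.character(head_type)
  tail_type <- as.character(tail_type)
  if (length(relation) != length(head_type) || length(relation) != length(tail_type))
    stop_("relation, head_type and tail_type must have equal length")
  if (anyDuplicated(relation))
    stop_("duplicate relation names: %s",
          paste(unique(relation[duplicated(relation)]), collapse = ", "))
  bad <- !nzchar(relation) | !nzchar(head_type) | !nzchar(tail_type)
  if (any(bad)) stop_("empty relation name or endpoint type at position %d", which(bad)[1L])
  out <- data.frame(relation = relation, head_type = head_type,
                    tail_type = tail_type, stringsAsFactors = FALSE)
  class(out) <- c("relation_schema", "data.frame")
  out
}

#' Default clinical relation schema (17 relations)
#'
#' The 17 relation types of the disease--symptom--drug--mechanism graph,
#' with endpoint entity categories derived from the relation names. The name
#' `"mechanism =>disease"` (with the stray space) is kept verbatim because it
#' is how the relation is written in the source vocabulary.
#'
#' @return A [relation_schema()] with 17 rows.
#' @export
default_schema <- function() {
  rel <- c(
    "symptom=>symptom", "disease=>symptom", "disease=>drug",
    "mechanism=>mechanism", "symptom=>drug", "symptom=>mechanism",
    "symptom=>disease", "mechanism=>department", "symptom=>body parts",
    "mechanism=>body parts", "mechanism=>symptom", "symptom=>department",
    "disease=>mechanism", "disease=>body parts", "disease=>department",
    "disease=>disease", "mechanism =>disease")
  part <- function(x) {
    x <- trimws(x)
    if (x == "body parts") "body_part" else x
  }
  sides <- strsplit(rel, "=>", fixed = TRUE)
  relation_schema(
    relation = rel,
    head_type = vapply(sides, function(s) part(s[[1L]]), character(1)),
    tail_type = vapply(sides, function(s) part(s[[2L]]), character(1))
  )
}

#' Extended schema for synthetic graphs with a drug-action chain
#'
#' The default 17 relations plus `drug=>mechanism` and `drug=>disease`,
#' so that the drug -> mechanism -> disease causal chain (and its implied
#' drug=>disease closure edge) can be planted and mined. The conclusion
#' relations of the default composition rules already exist in the base
#' schema.
#'
#' @return A [relation_schema()] with 19 rows.
#' @export
synthetic_schema <- function() {
  base <- default_schema()
  relation_schema(
    relation = c(base$relation, "drug=>mechanism", "drug=>disease"),
    head_type = c(base$head_type, "drug", "drug"),
    tail_type = c(base$tail_type, "mechanism", "disease")
  )
}

#' Read or write a relation schema as YAML/JSON
#'
#' The on-disk form is a list of records `{name, head_type, tail_type}`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param schema A [relation_schema()].
#' @return `read_schema` returns a [relation_schema()]; `write_schema`
#'   returns `path` invisibly.
#' @export
read_schema <- function(path) {
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame))
  }
  relation_schema(recs$name, recs$head_type, recs$tail_type)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  recs <- lapply(seq_len(nrow(schema)), function(i) {
    list(name = schema$relation[i], head_type = schema$head_type[i],
         tail_type = schema$tail_type[i])
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}
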