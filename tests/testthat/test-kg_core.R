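test_that("TSV loading builds a deduplicated knowledge graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metformin\tmechanism\tinsulin resistance",
               "insulin resistance\ttreat\tdiabetes mellitus"), f)
  kg <- load_triples(f, fig1_schema())
  expect_equal(length(kg$entities), 3L)
  expect_equal(nrow(kg$triples), 2L)
  expect_true(all(has_triple(kg, c("metformin", "insulin resistance"),
                             c("mechanism", "treat"),
                             c("insulin resistance", "diabetes mellitus"))))

  # empty file
  writeLines(character(0), f)
  kg0 <- load_triples(f, fig1_schema())
  expect_equal(nrow(kg0$triples), 0L)
  expect_equal(length(kg0$entities), 0L)

  # duplicates collapse
  writeLines(rep("metformin\tmechanism\tinsulin resistance", 5L), f)
  expect_message(kg1 <- load_triples(f, fig1_schema()), "duplicate")
  expect_equal(nrow(kg1$triples), 1L)
})

test_that("malformed lines and unknown relations are rejected with detail", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tmechanism\tb", "broken line"), f)
  expect_error(load_triples(f, fig1_schema()), "line 2")
  writeLines("a\tnot_a_relation\tb", f)
  expect_error(load_triples(f, fig1_schema()), "not_a_relation")
  expect_error(knowledge_graph(data.frame(head = "", relation = "treat",
                                          tail = "x"), fig1_schema()),
               "empty token")
})

test_that("write/load round trip reproduces the canonical form byte-for-byte", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  kg <- random_kg(80L, seed = 5L)
  write_triples(kg, f1)
  write_triples(load_triples(f1, kg$schema), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("split_kg partitions without loss and repairs unseen tokens", {
  for (s in 1:150) {
    kg <- random_kg(60L + (s %% 40L), seed = 1000L + s)
    sp <- suppressMessages(split_kg(kg, c(0.8, 0.1, 0.1), seed = s))
    keys <- lapply(sp, function(k) {
      pathcoke:::triple_key(k$triples$head, k$triples$relation, k$triples$tail)
    })
    all_keys <- unname(unlist(keys))
    expect_equal(sort(all_keys),
                 sort(pathcoke:::triple_key(kg$triples$head,
                                            kg$triples$relation,
                                            kg$triples$tail)))
    expect_equal(anyDuplicated(all_keys), 0L)
    # no token in valid/test that train has never seen
    tre <- c(sp$train$triples$head, sp$train$triples$tail)
    for (part in c("valid", "test")) {
      expect_true(all(c(sp[[part]]$triples$head, sp[[part]]$triples$tail)
                      %in% tre))
      expect_true(all(sp[[part]]$triples$relation %in%
                        sp$train$triples$relation))
    }
  }
})

test_that("an entity occurring in exactly one triple lands in train", {
  kg <- fig1_kg(extra = data.frame(head = "orphan drug",
                                   relation = "mechanism",
                                   tail = "insulin resistance"))
  for (s in 1:20) {
    sp <- suppressMessages(split_kg(kg, c(0.34, 0.33, 0.33), seed = s))
    expect_true(any(sp$train$triples$head == "orphan drug"))
  }
})

test_that("identical seeds give byte-identical splits; fractions validated", {
  kg <- random_kg(100L, seed = 2L)
  a <- suppressMessages(split_kg(kg, seed = 7L))
  b <- suppressMessages(split_kg(kg, seed = 7L))
  expect_identical(a, b)
  expect_error(split_kg(kg, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_kg(kg, c(1, -0.1, 0.1)), "positive")
})

test_that("relation_stats counts heads, tails and triples per relation", {
  kg <- knowledge_graph(fig1_positive(), fig1_schema())
  st <- relation_stats(kg)
  expect_equal(st$triples[st$relation == "mechanism"], 1L)
  expect_equal(st$heads[st$relation == "treat"], 1L)
  expect_equal(st$tails[st$relation == "treat"], 1L)
  expect_equal(st$triples[st$relation == "symptom"], 0L)

  empty <- knowledge_graph(NULL, default_schema())
  expect_true(all(relation_stats(empty)$triples == 0L))
  expect_equal(nrow(relation_stats(empty)), 17L)
})

test_that("the default clinical schema has the 17 expected relations", {
  sch <- default_schema()
  expect_equal(nrow(sch), 17L)
  expect_true("mechanism =>disease" %in% sch$relation)  # verbatim name
  expect_setequal(unique(c(sch$head_type, sch$tail_type)),
                  c("disease", "symptom", "drug", "mechanism", "department",
                    "body_part"))
  expect_error(relation_schema(c("a", "a"), c("x", "x"), c("y", "y")),
               "duplicate")
})

test_that("vocabulary ids are deterministic with fixed special tokens", {
  kg <- random_kg(50L, seed = 3L)
  v1 <- kg_vocabulary(kg)
  v2 <- kg_vocabulary(kg)
  expect_identical(v1, v2)
  expect_equal(v1$pad_id, 1L)
  expect_equal(v1$mask_id, 2L)
  expect_equal(v1$tokens[v1$entity_ids], sort(kg$entities, method = "radix"))
  # bijection over non-special tokens
  expect_equal(anyDuplicated(v1$tokens), 0L)
  expect_equal(unname(v1$id[v1$tokens[10L]]), 10L)
})

test_that("schema files round-trip through YAML and JSON", {
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_schema(default_schema(), f)
    expect_equal(read_schema(f), default_schema())
  }
})
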