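test_that("filtered ranks follow the protocol on worked examples", {
  expect_equal(filtered_rank(c(0.3, 0.9, 0.1), 2L), 1L)
  # 5 entities, target third, second entity filtered out: only the first
  # scores higher, so the filtered rank is 2
  expect_equal(filtered_rank(c(.9, .8, .7, .6, .5), 3L, known_true = 2L), 2L)
  # the target is always re-admitted even if listed as known-true
  expect_equal(filtered_rank(c(.9, .8, .7), 1L, known_true = 1L), 1L)
  expect_error(filtered_rank(c(1, 2), 5L), "out of range")
})

test_that("ties are broken uniformly at random", {
  ranks <- withr::with_seed(10L, {
    vapply(1:10000, function(i) filtered_rank(rep(1, 10), 4L), integer(1))
  })
  expect_equal(mean(ranks), 5.5, tolerance = 0.1)
  expect_setequal(unique(ranks), 1:10)
})

test_that("aggregate metrics follow their formulas", {
  expect_equal(mrr(c(1L, 2L, 4L)), (1 + 0.5 + 0.25) / 3)
  expect_equal(mrr(rep(1L, 9L)), 1)
  withr::with_seed(3L, {
    r <- sample(1000L, 1000L, replace = TRUE)
    expect_equal(mrr(r), sum(1 / r) / 1000, tolerance = 1e-14)
    expect_equal(hits_at_n(r, 10L), sum(r <= 10L) / 1000)
  })
  expect_equal(hits_at_n(c(1L, 2L, 4L, 5L), 3L), 0.5)
  expect_equal(hits_at_n(c(7L, 9L), 1e9), 1)
  expect_error(mrr(integer(0)), "empty")
  expect_error(hits_at_n(1:3, 0L), "N")
})

test_that("ranking agrees with a sort-based oracle and filtering never hurts", {
  withr::with_seed(8L, {
    for (rep in 1:100) {
      V <- sample(5:400, 1L)
      scores <- runif(V)  # continuous: ties have probability zero
      target <- sample(V, 1L)
      known <- sample(setdiff(seq_len(V), target), min(V - 1L, 5L))
      got <- filtered_rank(scores, target, known)
      allowed <- setdiff(seq_len(V), known)
      oracle <- match(target, allowed[order(scores[allowed],
                                            decreasing = TRUE)])
      expect_identical(got, oracle)
      raw <- filtered_rank(scores, target)
      expect_lte(got, raw)
    }
  })
})

test_that("metrics are invariant to query order", {
  withr::with_seed(5L, {
    r <- sample(50L, 200L, replace = TRUE)
    expect_equal(mrr(r), mrr(rev(r)))
    expect_equal(hits_at_n(r, 3L), hits_at_n(sample(r), 3L))
  })
})

test_that("a perfect scorer reaches MRR 1 and a random one its expectation", {
  sim <- generate_kg(synth_config(n_per_type = 10L, seed = 14L))
  fi <- filter_index(sim$kg, sim$holdout)
  # perfect oracle: scores 1 on true triples, 0 elsewhere
  perfect <- structure(list(entities = sort(sim$kg$entities, method = "radix"),
                            truth = fi),
                       class = c("perfect_scorer", "random_scorer"))
  registerS3method("score_queries", "perfect_scorer",
                   function(model, heads, relations, tails, direction) {
    out <- matrix(0, length(relations), length(model$entities))
    for (i in seq_along(relations)) {
      toks <- if (direction == "tail") {
        pathcoke:::known_tails(model$truth, heads[i], relations[i])
      } else {
        pathcoke:::known_heads(model$truth, relations[i], tails[i])
      }
      out[i, match(toks, model$entities)] <- 1
    }
    out
  }, envir = asNamespace("pathcoke"))
  res <- evaluate_link_prediction(perfect, sim$holdout, fi, seed = 1L)
  expect_equal(res$mrr, 1)
  expect_equal(unname(res$hits), c(1, 1, 1))

  # random scorer: E[1/rank] = H(m)/m per query with m filtered candidates
  V <- length(sim$kg$entities)
  hd <- sim$holdout$triples
  m_sizes <- c(
    vapply(seq_len(nrow(hd)), function(i) {
      V - length(setdiff(pathcoke:::known_tails(fi, hd$head[i],
                                                hd$relation[i]), hd$tail[i]))
    }, numeric(1)),
    vapply(seq_len(nrow(hd)), function(i) {
      V - length(setdiff(pathcoke:::known_heads(fi, hd$relation[i],
                                                hd$tail[i]), hd$head[i]))
    }, numeric(1)))
  expected <- mean(vapply(m_sizes, function(m) sum(1 / seq_len(m)) / m,
                          numeric(1)))
  emp <- vapply(1:30, function(s) {
    evaluate_link_prediction(random_scorer(sim$kg$entities), sim$holdout,
                             fi, seed = s)$mrr
  }, numeric(1))
  expect_lt(abs(mean(emp) - expected), 3 * stats::sd(emp) / sqrt(30))
})

test_that("path queries rank planted targets with per-query filtering", {
  kg <- fig1_kg()
  qs <- path_query_set(kg, rules = composition_rules("mechanism", "treat"))
  expect_equal(nrow(qs), 1L)
  expect_equal(qs$targets[[1L]], "diabetes mellitus")

  sim <- cached("pq_sim", generate_kg(synth_config(n_per_type = 10L, seed = 14L)))
  model <- cached("pq_model", {
    ch <- filter_causal(enumerate_chains(sim$kg, 2L), planted_rules(sim))
    train_coke(sim$kg, coke_config(hidden_size = 32L, layers = 1L, heads = 4L,
                                   epochs = 40L, batch_size = 256L, seed = 2L),
               paths = ch)
  })
  queries <- path_query_set(sim$kg, rules = planted_rules(sim))
  res <- evaluate_path_query(model, queries, seed = 3L)
  expect_true(all(res$per_query$rank >= 1L))
  expect_gt(res$hits["10"], 0)
  expect_error(evaluate_path_query(model, queries[0, ]), "empty")
})

test_that("the filter index covers every split in both directions", {
  sim <- generate_kg(synth_config(n_per_type = 8L, seed = 2L))
  fi <- filter_index(sim$kg, sim$holdout)
  tr <- rbind(sim$kg$triples, sim$holdout$triples)
  for (i in sample(nrow(tr), 25L)) {
    expect_true(tr$tail[i] %in%
                  pathcoke:::known_tails(fi, tr$head[i], tr$relation[i]))
    expect_true(tr$head[i] %in%
                  pathcoke:::known_heads(fi, tr$relation[i], tr$tail[i]))
  }
})
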