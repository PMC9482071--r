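tiny_model <- function(n_ent = 6L, seed = 3L, layers = 2L, hidden = 8L,
                       heads = 2L, ff = 12L) {
  ents <- sprintf("e%02d", seq_len(n_ent))
  kg <- knowledge_graph(
    data.frame(head = ents[1:3], relation = "treat", tail = ents[4:6]),
    relation_schema(c("treat", "mechanism"), c("drug", "drug"),
                    c("disease", "mechanism")),
    entities = ents)
  cfg <- coke_config(hidden_size = hidden, layers = layers, heads = heads,
                     ff_size = ff, dropout = 0, max_sequence_length = 5L,
                     seed = seed)
  list(kg = kg, vocab = kg_vocabulary(kg), cfg = cfg,
       model = coke_init(kg_vocabulary(kg), cfg))
}

test_that("label smoothing matches the printed formula and sums to one", {
  y <- smooth_labels(2L, 5L, 0.8)
  expect_equal(y, c(0.05, 0.8, 0.05, 0.05, 0.05))
  expect_equal(sum(y), 1)
  expect_equal(smooth_labels(1L, 2L, 0.9), c(0.9, 0.1))
  # eps -> 1 approaches one-hot
  expect_equal(smooth_labels(3L, 4L, 1 - 1e-9)[3L], 1, tolerance = 1e-8)
  expect_error(smooth_labels(1L, 1L, 0.8), "V")
  expect_error(smooth_labels(1L, 3L, 1.2), "eps")
})

test_that("cross-entropy has its textbook identities", {
  onehot <- c(0, 1, 0, 0)
  expect_equal(cross_entropy(pmax(onehot, 1e-300), onehot), 0)
  V <- 7L
  expect_equal(cross_entropy(rep(1 / V, V), smooth_labels(3L, V, 0.8)), log(V))
  withr::with_seed(4L, {
    p <- runif(50); p <- p / sum(p)
    y <- runif(50); y <- y / sum(y)
    expect_equal(cross_entropy(p, y), -sum(y * log(p)), tolerance = 1e-12)
  })
  expect_error(cross_entropy(c(0.5, 0.5), c(1, 0, 0)), "length")
})

test_that("input embeddings are element + positional, then layer norm", {
  tm <- tiny_model()
  m <- tm$model
  ids <- c(tm$vocab$mask_id, tm$vocab$relation_ids[1L], tm$vocab$entity_ids[2L])
  h <- embed_inputs(m, ids)
  expect_equal(dim(h), c(3L, 8L))
  # independent recomputation
  for (i in 1:3) {
    x <- m$params$E[ids[i], ] + m$params$P[i, ]
    xc <- x - mean(x)
    want <- xc / sqrt(mean(xc^2) + 1e-6)
    expect_equal(unname(h[i, ]), want, tolerance = 1e-12)
  }
  # swapping two tokens changes exactly those positions
  ids2 <- ids[c(3L, 2L, 1L)]
  h2 <- embed_inputs(m, c(ids[1L], ids[2L], tm$vocab$entity_ids[3L]))
  expect_equal(h2[1:2, ], h[1:2, ])
  expect_false(isTRUE(all.equal(h2[3L, ], h[3L, ])))
  expect_error(embed_inputs(m, rep(ids, 4L)), "positional")
  expect_error(embed_inputs(m, c(1L, 999L)), "out of range")
})

test_that("a zero-layer encoder is the identity", {
  tm <- tiny_model(layers = 0L)
  h <- embed_inputs(tm$model, c(2L, 3L, 4L))
  enc <- encode(tm$model, h)
  expect_identical(enc$final, h)
  expect_length(enc$states, 0L)
})

test_that("a single-layer single-head encoder matches a hand-worked pass", {
  tm <- tiny_model(layers = 1L, hidden = 4L, heads = 1L, ff = 6L)
  m <- tm$model
  p <- m$params
  h <- embed_inputs(m, c(2L, 9L, 5L))
  # straight-line recomputation of the post-norm layer
  ln <- function(x, g, b) {
    t(apply(x, 1L, function(r) {
      rc <- r - mean(r)
      rc / sqrt(mean(rc^2) + 1e-6) * g + b
    }))
  }
  Q <- h %*% p$L1_Wq; K <- h %*% p$L1_Wk; V <- h %*% p$L1_Wv
  S <- Q %*% t(K) / sqrt(4)
  A <- t(apply(S, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  O <- (A %*% V) %*% p$L1_Wo
  O <- sweep(O, 2L, p$L1_bo, `+`)
  H1 <- ln(h + O, p$L1_ln1_g, p$L1_ln1_b)
  U <- sweep(H1 %*% p$L1_W1, 2L, p$L1_b1, `+`)
  Fo <- sweep(pmax(U, 0) %*% p$L1_W2, 2L, p$L1_b2, `+`)
  want <- ln(H1 + Fo, p$L1_ln2_g, p$L1_ln2_b)
  enc <- encode(m, h)
  expect_equal(enc$final, want, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(enc$attention[[1L]][[1L]], A, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("attention rows are probability distributions", {
  tm <- tiny_model()
  enc <- encode(tm$model, embed_inputs(tm$model, c(2L, 9L, 5L)))
  for (l in seq_along(enc$attention))
    for (a in enc$attention[[l]])
      expect_equal(rowSums(a), rep(1, nrow(a)))
})

test_that("masked prediction is a proper distribution over entities only", {
  tm <- tiny_model()
  m <- tm$model
  # all-zero logit path: uniform over the entity vocabulary
  m0 <- m
  m0$params$E[] <- 0; m0$params$head_Wz[] <- 0; m0$params$b_out[] <- 0
  hL <- encode(m0, embed_inputs(m0, c(2L, 9L, 5L)))$final
  pr <- predict_masked(m0, hL, 1L)
  expect_equal(unname(pr), rep(1 / 6, 6L))
  expect_named(pr, sort(tm$kg$entities, method = "radix"))

  for (s in 1:100) {
    tm2 <- tiny_model(seed = s)
    hL <- encode(tm2$model, embed_inputs(tm2$model, c(2L, 9L, 5L)))$final
    pr <- predict_masked(tm2$model, hL, 1L)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
  }
})

test_that("argmax of the prediction equals exhaustive dot-product scoring", {
  tm <- tiny_model(seed = 11L)
  m <- tm$model; p <- m$params
  hL <- encode(m, embed_inputs(m, c(2L, 9L, 5L)))$final
  pr <- predict_masked(m, hL, 1L)
  # oracle: explicit head transform and per-entity dot products
  z1 <- hL[1L, ] %*% p$head_Wz + p$head_bz
  zg <- pmax(z1, 0)
  zc <- zg - mean(zg)
  z <- zc / sqrt(mean(zc^2) + 1e-6) * p$lnz_g + p$lnz_b
  scores <- vapply(m$vocab$entity_ids, function(e) {
    sum(z * p$E[e, ])
  }, numeric(1)) + p$b_out
  expect_equal(which.max(pr), which.max(scores), ignore_attr = TRUE)
})

test_that("masked instances cover both directions for edges and paths", {
  tm <- tiny_model()
  kg1 <- knowledge_graph(fig1_positive(), fig1_schema())
  vocab <- kg_vocabulary(kg1)
  paths <- enumerate_chains(kg1, 2L)
  inst <- make_instances(kg1$triples[1L, ], vocab, paths = paths)
  expect_equal(inst$n_instances, 4L)
  lens <- sort(vapply(inst$buckets, function(b) b$n, integer(1)))
  expect_equal(unname(lens), c(3L, 4L))
  for (b in inst$buckets) {
    expect_true(all(rowSums(b$ids == vocab$mask_id) == 1L))
    expect_true(all(b$ids[cbind(seq_len(nrow(b$ids)), b$mask_pos)] ==
                      vocab$mask_id))
  }
  empty <- make_instances(kg1$triples[0L, ], vocab)
  expect_equal(empty$n_instances, 0L)
})

test_that("compiled and reference forward passes agree", {
  sim <- generate_kg(synth_config(n_per_type = 8L, seed = 6L))
  vocab <- kg_vocabulary(sim$kg)
  cfg <- coke_config(hidden_size = 16L, layers = 2L, heads = 4L,
                     dropout = 0, seed = 9L)
  m <- coke_init(vocab, cfg)
  inst <- make_instances(sim$kg, vocab)
  b <- inst$buckets[[1L]]
  idx <- seq_len(min(nrow(b$ids), 64L))
  ref <- pathcoke:::coke_forward(m, b$ids[idx, ], b$mask_pos[idx])$logits
  cmp <- pathcoke:::coke_score(m, b$ids[idx, ], b$mask_pos[idx])
  expect_lt(max(abs(ref - cmp)), 1e-4)
})

test_that("analytic gradients match finite differences on a tiny model", {
  tm <- tiny_model(seed = 5L)
  m <- tm$model; vocab <- tm$vocab
  ids <- rbind(c(vocab$mask_id, vocab$relation_ids[1L], vocab$entity_ids[4L]),
               c(vocab$entity_ids[2L], vocab$relation_ids[2L], vocab$mask_id))
  mask_pos <- c(1L, 3L)
  targ <- c(4L, 6L)
  lossfun <- function(model) {
    fwd <- pathcoke:::coke_forward(model, ids, mask_pos)
    pathcoke:::smoothed_ce_batch(fwd$logits, targ, 0.8)$loss
  }
  fwd <- pathcoke:::coke_forward(m, ids, mask_pos)
  lo <- pathcoke:::smoothed_ce_batch(fwd$logits, targ, 0.8)
  gr <- pathcoke:::coke_backward(m, fwd$cache, lo$dlogits)
  withr::with_seed(1L, {
    for (nm in c("E", "P", "L1_Wq", "L2_Wv", "L1_W1", "L2_ln2_g", "head_Wz",
                 "b_out")) {
      pm <- m$params[[nm]]
      for (rep in 1:2) {
        i <- sample(length(pm), 1L)
        eps <- 1e-5
        m2 <- m; m2$params[[nm]][i] <- pm[i] + eps
        m3 <- m; m3$params[[nm]][i] <- pm[i] - eps
        num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
        expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
      }
    }
  })
})

test_that("output weights are tied to the element embedding matrix", {
  tm <- tiny_model(seed = 8L)
  m <- tm$model
  ids <- c(tm$vocab$mask_id, tm$vocab$relation_ids[1L], tm$vocab$entity_ids[1L])
  hL <- encode(m, embed_inputs(m, ids))$final
  p0 <- predict_masked(m, hL, 1L)
  # non-constant perturbation: layer norm absorbs constant shifts
  m$params$E[tm$vocab$entity_ids[3L], ] <-
    m$params$E[tm$vocab$entity_ids[3L], ] + seq_len(8L) / 4
  # input side changes (the embedding of entity 3 when it appears) ...
  ids3 <- c(tm$vocab$mask_id, tm$vocab$relation_ids[1L], tm$vocab$entity_ids[3L])
  expect_false(isTRUE(all.equal(embed_inputs(m, ids3)[3L, ],
                                embed_inputs(tm$model, ids3)[3L, ])))
  # ... and so does the output logit for entity 3 on an unrelated query
  hL2 <- encode(m, embed_inputs(m, ids))$final
  p1 <- predict_masked(m, hL2, 1L)
  expect_false(isTRUE(all.equal(p0[[3L]], p1[[3L]])))
})

test_that("training reduces the loss and is seed-deterministic", {
  kg <- random_kg(60L, seed = 44L)
  cfg <- coke_config(hidden_size = 32L, layers = 2L, heads = 4L,
                     epochs = 50L, batch_size = 64L, seed = 17L)
  m1 <- train_coke(kg, cfg)
  expect_lt(tail(m1$loss_trace, 1L), m1$loss_trace[1L])
  expect_true(all(is.finite(m1$loss_trace)))
  m2 <- train_coke(kg, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
})

test_that("configuration invariants are enforced", {
  expect_error(coke_config(hidden_size = 10L, heads = 4L), "divisible")
  expect_error(coke_config(max_sequence_length = 2L), "max_sequence_length")
  expect_error(coke_config(label_smoothing = 0), "label_smoothing")
})
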