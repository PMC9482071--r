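test_that("layer mapping distills in T/S intervals", {
  expect_equal(layer_map(4L, 12L), c(`1` = 3L, `2` = 6L, `3` = 9L, `4` = 12L))
  expect_equal(layer_map(3L, 3L), c(`1` = 1L, `2` = 2L, `3` = 3L))
  expect_equal(layer_map(1L, 12L), c(`1` = 12L))
  expect_error(layer_map(5L, 12L), "divisible")
})

test_that("embedding and hidden losses are projected mean squared errors", {
  withr::with_seed(2L, {
    E_T <- matrix(rnorm(5 * 6), 5, 6)
    W <- diag(6)
    expect_equal(embedding_loss(E_T, E_T, W), 0)
    expect_equal(embedding_loss(E_T + 3, E_T, W), 9)
    E_S <- matrix(rnorm(5 * 4), 5, 4)
    W2 <- matrix(rnorm(4 * 6), 4, 6)
    # elementwise oracle
    want <- 0
    proj <- E_S %*% W2
    for (i in 1:5) for (j in 1:6) want <- want + (proj[i, j] - E_T[i, j])^2
    expect_equal(embedding_loss(E_S, E_T, W2), want / 30, tolerance = 1e-10)
    expect_equal(hidden_loss(E_S, E_T, W2), embedding_loss(E_S, E_T, W2))
    expect_error(embedding_loss(E_S, E_T, diag(5)), "shape mismatch")
  })
})

test_that("attention loss averages per-head mean squared error", {
  A <- matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2)
  expect_equal(attention_loss(list(A), list(A)), 0)
  expect_equal(attention_loss(list(A + 1), list(A)), 1)
  withr::with_seed(3L, {
    s <- lapply(1:4, function(i) matrix(runif(9), 3))
    t_ <- lapply(1:4, function(i) matrix(runif(9), 3))
    want <- 0
    for (h in 1:4) want <- want + mean((s[[h]] - t_[[h]])^2)
    expect_equal(attention_loss(s, t_), want / 4, tolerance = 1e-12)
  })
  expect_error(attention_loss(list(A), list(A, A)), "head-count")
})

test_that("prediction loss softens with temperature as expected", {
  withr::with_seed(5L, {
    z <- rnorm(9)
    p <- exp(z / 2) / sum(exp(z / 2))
    expect_equal(prediction_loss(z, z, 2), -sum(p * log(p)))  # CE(p,p) = H(p)
    # very high temperature drives both distributions to uniform
    expect_equal(prediction_loss(z, rnorm(9), 1e7), log(9), tolerance = 1e-6)
    zT <- rnorm(12); zS <- rnorm(12)
    pT <- exp(zT / 2 - max(zT / 2)); pT <- pT / sum(pT)
    lqS <- zS / 2 - max(zS / 2) - log(sum(exp(zS / 2 - max(zS / 2))))
    expect_equal(prediction_loss(zT, zS, 2), -sum(pT * lqS), tolerance = 1e-12)
  })
  expect_error(prediction_loss(1:3, 1:3, 0), "temperature")
  expect_error(prediction_loss(1:3, 1:4, 1), "mismatch")
})

test_that("a student identical to its teacher has zero distillation losses", {
  sim <- generate_kg(synth_config(n_per_type = 8L, seed = 21L))
  teacher <- cached("tiny_teacher", {
    train_coke(sim$kg, coke_config(hidden_size = 16L, layers = 2L, heads = 2L,
                                   epochs = 20L, batch_size = 128L, seed = 2L))
  })
  inst <- make_instances(sim$kg, teacher$vocab)
  b <- inst$buckets[[1L]]
  idx <- seq_len(16L)
  proj <- list(W_e = diag(16L), L1_W_h = diag(16L), L2_W_h = diag(16L))
  ls <- distill_losses(teacher, teacher, proj, b$ids[idx, ], b$mask_pos[idx],
                       temperature = 2)
  expect_lt(ls$emb, 1e-6)
  expect_lt(ls$attn, 1e-6)
  expect_lt(ls$hidn, 1e-6)
  # prediction term equals the entropy of the teacher's softened output
  lo <- pathcoke:::coke_score(teacher, b$ids[idx, ], b$mask_pos[idx])
  pT <- pathcoke:::row_softmax(lo / 2)
  expect_equal(ls$pred, mean(-rowSums(pT * log(pT))), tolerance = 1e-4)
  # cross-check the compiled terms against the reference R loss functions
  enc_t <- encode(teacher, embed_inputs(teacher, b$ids[idx[1L], ]))
  expect_equal(attention_loss(enc_t$attention[[1L]], enc_t$attention[[1L]]), 0)
})

test_that("distillation trains the student and leaves the teacher frozen", {
  sim <- generate_kg(synth_config(n_per_type = 8L, seed = 21L))
  teacher <- cached("tiny_teacher", {
    train_coke(sim$kg, coke_config(hidden_size = 16L, layers = 2L, heads = 2L,
                                   epochs = 20L, batch_size = 128L, seed = 2L))
  })
  before <- teacher$params
  dcfg <- distill_config(student_layers = 1L, epochs = 30L,
                         batch_size = 128L, seed = 5L)
  res <- distill(teacher, sim$kg, dcfg)
  expect_identical(teacher$params, before)
  expect_lt(tail(res$loss_trace, 1L), res$loss_trace[1L])
  # 10-epoch moving average is non-increasing
  ma <- stats::filter(res$loss_trace, rep(1 / 10, 10), sides = 1L)
  ma <- ma[!is.na(ma)]
  expect_true(all(diff(ma) <= 1e-8))
  expect_equal(res$layer_map, c(`1` = 2L))
  # every loss term non-negative
  for (tr in list(res$emb_trace, res$attn_trace, res$hidn_trace,
                  res$pred_trace))
    expect_true(all(tr >= 0))
  # determinism
  res2 <- distill(teacher, sim$kg, dcfg)
  expect_identical(res$student$params, res2$student$params)
  expect_identical(res$loss_trace, res2$loss_trace)
})

test_that("vocabulary mismatches and bad configs are rejected", {
  sim <- generate_kg(synth_config(n_per_type = 8L, seed = 21L))
  teacher <- cached("tiny_teacher", {
    train_coke(sim$kg, coke_config(hidden_size = 16L, layers = 2L, heads = 2L,
                                   epochs = 20L, batch_size = 128L, seed = 2L))
  })
  other <- generate_kg(synth_config(n_per_type = 7L, seed = 1L))
  expect_error(distill(teacher, other$kg, distill_config(student_layers = 1L)),
               "vocabulary mismatch")
  expect_error(distill_config(temperature = 0), "temperature")
  expect_error(distill_config(w_emb = -1), "weights")
})
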