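random_kge <- function(symptoms, D = 16L, seed = 1L) {
  withr::with_seed(seed, {
    matrix(rnorm(length(symptoms) * D), length(symptoms), D,
           dimnames = list(symptoms, NULL))
  })
}

test_that("case features map to embedding sequences in canonical order", {
  cases <- generate_cases(10L, noise = 0, seed = 2L, n_symptoms = 12L,
                          n_syndromes = 4L, max_labels = 4L,
                          symptoms_per_syndrome = 3L)
  kge <- random_kge(colnames(cases$features))
  inp <- build_case_features(cases, kge, "kge_sequence")
  n_present <- rowSums(cases$features)
  expect_equal(inp$lengths, pmax(n_present, 1L), ignore_attr = TRUE)
  i <- which(n_present >= 3L)[1L]
  present <- sort(colnames(cases$features)[cases$features[i, ] == 1L],
                  method = "radix")
  expect_equal(inp$X[i, seq_along(present), ], kge[present, ],
               ignore_attr = TRUE)
  # permuting feature columns leaves the sequence (and Xbin) unchanged
  perm <- withr::with_seed(3L, sample(ncol(cases$features)))
  cases2 <- cases
  cases2$features <- cases2$features[, perm]
  inp2 <- build_case_features(cases2, kge, "kge_sequence")
  expect_identical(inp2$X, inp$X)
  expect_identical(inp2$Xbin, inp$Xbin)
  # plain mode passes the binary matrix through
  expect_identical(build_case_features(cases, mode = "plain"), cases$features)
})

test_that("zero-symptom cases are padded and flagged; unmapped symptoms error", {
  cases <- generate_cases(5L, noise = 0, seed = 2L, n_symptoms = 6L,
                          n_syndromes = 3L, max_labels = 3L,
                          symptoms_per_syndrome = 2L)
  cases$features[2L, ] <- 0L
  kge <- random_kge(colnames(cases$features))
  inp <- build_case_features(cases, kge, "kge_sequence")
  expect_equal(inp$flagged, 2L)
  expect_equal(inp$lengths[2L], 1L)
  expect_true(all(inp$X[2L, 1L, ] == 0))
  expect_error(build_case_features(cases, kge[-1L, , drop = FALSE],
                                   "kge_sequence"),
               "no embedding")
  expect_error(build_case_features(cases, mode = "kge_sequence"), "required")
})

test_that("noiseless cases are separable in both modes", {
  cases <- generate_cases(100L, noise = 0, seed = 6L)
  plain <- train_classifier(build_case_features(cases, mode = "plain"),
                            cases$labels,
                            classifier_config(mode = "plain", epochs = 200L,
                                              seed = 1L))
  prp <- predict(plain, build_case_features(cases, mode = "plain"))
  expect_gte(multilabel_metrics(prp$label, cases$labels)$micro["f1"], 0.999)

  kge <- random_kge(colnames(cases$features))
  inp <- build_case_features(cases, kge, "kge_sequence")
  seqm <- train_classifier(inp, cases$labels,
                           classifier_config(mode = "kge_sequence",
                                             epochs = 200L, rnn_state = 16L,
                                             seed = 1L))
  prs <- predict(seqm, inp)
  expect_gte(multilabel_metrics(prs$label, cases$labels)$micro["f1"], 0.99)
})

test_that("label-shuffled training collapses to the base rate", {
  cases <- generate_cases(300L, noise = 0.1, seed = 9L)
  base_rate <- mean(cases$labels)
  f1s <- vapply(1:5, function(s) {
    shuffled <- cases
    shuffled$labels <- cases$labels[withr::with_seed(s, sample(300L)), ]
    cv <- cross_validate(shuffled,
                         classifier_config(mode = "plain", epochs = 40L,
                                           folds = 2L, seed = s))
    cv$mean$micro[["f1"]]
  }, numeric(1))
  # with independent labels, precision ~ base rate and F1 cannot stay near 1
  expect_lt(abs(mean(f1s) - base_rate), 3 * max(stats::sd(f1s), 0.03) + 0.15)
  expect_true(all(f1s < 0.8))
})

test_that("multilabel metrics match a loop-based counting oracle", {
  expect_error(multilabel_metrics(matrix(0, 2, 3), matrix(0, 3, 2)), "shape")
  perfect <- multilabel_metrics(diag(4L), diag(4L))
  expect_equal(perfect$hamming, 0)
  expect_equal(unname(perfect$micro), c(1, 1, 1))
  expect_equal(unname(perfect$macro), c(1, 1, 1))

  worst <- multilabel_metrics(matrix(0L, 5, 8), matrix(1L, 5, 8))
  expect_equal(worst$hamming, 1)
  expect_equal(worst$micro[["recall"]], 0)

  withr::with_seed(11L, {
    pred <- matrix(rbinom(400, 1, 0.4), 50)
    truth <- matrix(rbinom(400, 1, 0.4), 50)
  })
  rep_ <- multilabel_metrics(pred, truth)
  # counting oracle
  tp <- 0; fp <- 0; fn <- 0; mism <- 0
  for (i in 1:50) for (j in 1:8) {
    if (pred[i, j] != truth[i, j]) mism <- mism + 1
    if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
    if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
  }
  expect_identical(rep_$hamming, mism / 400)
  expect_identical(rep_$micro[["precision"]], tp / (tp + fp))
  expect_identical(rep_$micro[["recall"]], tp / (tp + fn))
  P <- rep_$micro[["precision"]]; R <- rep_$micro[["recall"]]
  expect_equal(rep_$micro[["f1"]], 2 * P * R / (P + R), tolerance = 1e-12)
  expect_true(all(unlist(rep_[c("hamming", "micro", "macro")]) >= 0))
  expect_true(all(unlist(rep_[c("hamming", "micro", "macro")]) <= 1))
})

test_that("cross-validation partitions cases exactly once, stratified", {
  cases <- generate_cases(20L, seed = 1L)
  cv <- cross_validate(cases, classifier_config(mode = "plain", folds = 2L,
                                                epochs = 10L, seed = 4L))
  expect_equal(sort(unique(cv$fold_of)), 1:2)
  expect_length(cv$fold_of, 20L)
  expect_equal(length(cv$folds), 2L)
  for (met in c("hamming")) {
    expect_gte(cv$mean[[met]], 0); expect_lte(cv$mean[[met]], 1)
  }
  expect_true(all(cv$mean$micro >= 0 & cv$mean$micro <= 1))
  expect_true(all(cv$mean$macro >= 0 & cv$mean$macro <= 1))
  expect_error(cross_validate(cases, classifier_config(folds = 30L)),
               "folds")

  # determinism
  cv2 <- cross_validate(cases, classifier_config(mode = "plain", folds = 2L,
                                                 epochs = 10L, seed = 4L))
  expect_identical(cv$mean, cv2$mean)
})

test_that("classifier gradients agree with finite differences", {
  cases <- generate_cases(12L, noise = 0, seed = 5L, n_symptoms = 8L,
                          n_syndromes = 3L, max_labels = 3L,
                          symptoms_per_syndrome = 3L)
  kge <- random_kge(colnames(cases$features), D = 4L)
  inp <- build_case_features(cases, kge, "kge_sequence")
  Y <- cases$labels
  p <- pathcoke:::birnn_init(4L, ncol(inp$Xbin), 3L, 5L, ncol(Y), seed = 2L)
  loss_of <- function(p) {
    pathcoke:::bce_loss(pathcoke:::birnn_forward(p, inp$X, inp$lengths,
                                                 inp$Xbin)$P, Y)
  }
  Xs <- lapply(seq_len(dim(inp$X)[2L]),
               function(t) inp$X[, t, , drop = FALSE][, 1L, ])
  f <- pathcoke:::birnn_forward(p, inp$X, inp$lengths, inp$Xbin)
  g <- pathcoke:::birnn_grads(p, f, Xs, inp$lengths, inp$Xbin, Y, 3L, 5L)
  eps <- 1e-6
  withr::with_seed(7L, {
    for (nm in c("Wf", "Uf", "Wb", "Ub", "bf", "Wd", "W1", "W2", "b2")) {
      for (rep in 1:2) {
        i <- sample(length(p[[nm]]), 1L)
        p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- p; p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
        expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
      }
    }
  })
})
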