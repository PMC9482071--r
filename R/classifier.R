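#' Configuration for the multilabel syndrome classifier
#'
#' Two modes share the training regime: `plain` feeds the binary symptom
#' vector to a feedforward network (the DNN arm); `kge_sequence` keeps that
#' branch and adds a bidirectional recurrent encoder over the sequence of
#' knowledge-graph embeddings of the case's present symptoms, pooled
#' (mean and max) and concatenated with the feedforward branch before the
#' output layer -- the DNN-plus-recurrent-KGE architecture. Both end in one
#' sigmoid output per syndrome trained with binary cross-entropy.
#'
#' @param mode `"plain"` or `"kge_sequence"`.
#' @param hidden Feedforward hidden width.
#' @param rnn_state Recurrent state size per direction (`kge_sequence`).
#' @param epochs Training epochs (full-batch Adam).
#' @param learning_rate Adam step size.
#' @param threshold Decision threshold tau in (0, 1) on the sigmoid
#'   outputs.
#' @param folds Cross-validation folds (>= 2).
#' @param seed Integer seed.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(mode = c("plain", "kge_sequence"), hidden = 64L,
                              rnn_state = 32L, epochs = 150L,
                              learning_rate = 5e-3, threshold = 0.5,
                              folds = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold >= 1) stop_("threshold must be in (0, 1)")
  if (folds < 2L) stop_("folds must be >= 2")
  structure(list(mode = mode, hidden = as.integer(hidden),
                 rnn_state = as.integer(rnn_state),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, threshold = threshold,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build classifier inputs from a case table
#'
#' `plain` mode passes the binary feature matrix through unchanged.
#' `kge_sequence` mode keeps the (canonically ordered) binary matrix for
#' the feedforward branch and additionally turns each case into the
#' ordered sequence of embeddings of its present symptoms (canonical
#' C-locale symptom order, so the result is invariant to feature-column
#' permutation), padded to the longest case; a case with no symptoms
#' contributes a single zero (`[PAD]`) embedding and is flagged.
#'
#' @param cases A `case_table` (see [generate_cases()] / [read_cases()]).
#' @param kge Entity-embedding matrix with entity tokens as row names
#'   (e.g. [coke_entity_embeddings()]); required for `kge_sequence`.
#' @param mode `"plain"` or `"kge_sequence"`.
#' @return For `plain`, the binary matrix. For `kge_sequence`, a list with
#'   `X` (cases x max-length x D array), `lengths`, `Xbin` (the canonically
#'   ordered binary matrix) and `flagged` (indices of zero-symptom cases).
#' @export
build_case_features <- function(cases, kge = NULL,
                                mode = c("plain", "kge_sequence")) {
  mode <- match.arg(mode)
  feats <- cases$features
  if (mode == "plain") return(feats)
  if (is.null(kge)) stop_("kge embeddings required for kge_sequence mode")
  symptoms <- sort_c(colnames(feats))
  unmapped <- setdiff(symptoms, rownames(kge))
  if (length(unmapped))
    stop_("symptom(s) with no embedding: %s", paste(unmapped, collapse = ", "))
  feats <- feats[, symptoms, drop = FALSE]  # canonical order
  D <- ncol(kge)
  present <- apply(feats > 0, 1L, function(x) symptoms[x], simplify = FALSE)
  lens <- pmax(lengths(present), 1L)
  Tmax <- max(lens)
  N <- nrow(feats)
  X <- array(0, c(N, Tmax, D))
  for (i in seq_len(N)) {
    if (length(present[[i]]))
      X[i, seq_along(present[[i]]), ] <- kge[present[[i]], , drop = FALSE]
    # zero-symptom cases keep a single all-zero ([PAD]) step
  }
  list(X = X, lengths = lens, Xbin = feats,
       flagged = which(lengths(present) == 0L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

bce_loss <- function(p, y) {
  eps <- 1e-7
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# ---------------------------------------------------------------- plain MLP

mlp_init <- function(n_in, hidden, n_out, seed) {
  with_seed(seed, list(W1 = rmat(n_in, hidden, sd = sqrt(2 / n_in)),
                       b1 = rep(0, hidden),
                       W2 = rmat(hidden, n_out, sd = sqrt(2 / hidden)),
                       b2 = rep(0, n_out)))
}

mlp_forward <- function(p, X) {
  A1 <- addbias(X %*% p$W1, p$b1)
  H1 <- act_fwd(A1)
  P <- sigmoid(addbias(H1 %*% p$W2, p$b2))
  list(A1 = A1, H1 = H1, P = P)
}

mlp_train <- function(X, Y, hidden, epochs, lr, seed) {
  p <- mlp_init(ncol(X), hidden, ncol(Y), seed)
  opt <- adam_init(p)
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    f <- mlp_forward(p, X)
    trace[ep] <- bce_loss(f$P, Y)
    if (!is.finite(trace[ep])) stop_("non-finite classifier loss")
    dZ <- (f$P - Y) / length(Y)
    g <- list(W2 = crossprod(f$H1, dZ), b2 = colSums(dZ))
    dH1 <- dZ %*% t(p$W2) * act_grad(f$A1)
    g$W1 <- crossprod(X, dH1); g$b1 <- colSums(dH1)
    st <- adam_step(p, g, opt, lr)
    p <- st$params; opt <- st$state
  }
  list(params = p, loss_trace = trace)
}

# ------------------------------------------------- bidirectional recurrent

birnn_init <- function(D, nbin, m, hidden, n_out, seed) {
  with_seed(seed, {
    s <- function(n, k) rmat(n, k, sd = 1 / sqrt(n))
    list(Wf = s(D, m), Uf = s(m, m), bf = rep(0, m),
         Wb = s(D, m), Ub = s(m, m), bb = rep(0, m),
         Wd = s(nbin, hidden), bd = rep(0, hidden),
         W1 = s(4L * m, hidden), b1 = rep(0, hidden),
         W2 = s(2L * hidden, n_out), b2 = rep(0, n_out))
  })
}

# forward/backward over a padded (N x T x D) array with per-case lengths;
# Xbin feeds the parallel feedforward (DNN) branch
birnn_forward <- function(p, X, lengths, Xbin) {
  N <- dim(X)[1L]; Tm <- dim(X)[2L]; m <- ncol(p$Uf)
  maskt <- lapply(seq_len(Tm), function(t) as.numeric(lengths >= t))
  Hf <- vector("list", Tm); Hb <- vector("list", Tm)
  prev <- matrix(0, N, m)
  for (t in seq_len(Tm)) {
    A <- addbias(X[, t, , drop = FALSE][, 1L, ] %*% p$Wf + prev %*% p$Uf, p$bf)
    Hf[[t]] <- tanh(A) * maskt[[t]]
    prev <- Hf[[t]]
  }
  prev <- matrix(0, N, m)
  for (t in rev(seq_len(Tm))) {
    A <- addbias(X[, t, , drop = FALSE][, 1L, ] %*% p$Wb + prev %*% p$Ub, p$bb)
    Hb[[t]] <- tanh(A) * maskt[[t]]
    prev <- Hb[[t]]
  }
  # mean and max pooling over valid steps
  mean_f <- Reduce(`+`, Hf) / lengths
  mean_b <- Reduce(`+`, Hb) / lengths
  max_f <- matrix(-Inf, N, m); arg_f <- matrix(1L, N, m)
  max_b <- matrix(-Inf, N, m); arg_b <- matrix(1L, N, m)
  for (t in seq_len(Tm)) {
    mf <- Hf[[t]]; mf[maskt[[t]] == 0, ] <- -Inf
    upd <- mf > max_f
    max_f[upd] <- mf[upd]; arg_f[upd] <- t
    mb <- Hb[[t]]; mb[maskt[[t]] == 0, ] <- -Inf
    upd <- mb > max_b
    max_b[upd] <- mb[upd]; arg_b[upd] <- t
  }
  pool <- cbind(mean_f, mean_b, max_f, max_b)
  A1 <- addbias(pool %*% p$W1, p$b1)
  H1 <- act_fwd(A1)
  Ad <- addbias(Xbin %*% p$Wd, p$bd)
  Hd <- act_fwd(Ad)
  comb <- cbind(Hd, H1)
  P <- sigmoid(addbias(comb %*% p$W2, p$b2))
  list(Hf = Hf, Hb = Hb, maskt = maskt, pool = pool, A1 = A1, H1 = H1,
       Ad = Ad, Hd = Hd, comb = comb, P = P, arg_f = arg_f, arg_b = arg_b)
}

birnn_grads <- function(p, f, Xs, lengths, Xbin, Y, m, hidden) {
  N <- nrow(Xbin); Tm <- length(Xs); D <- ncol(Xs[[1L]])
  dZ <- (f$P - Y) / length(Y)
  g <- list(W2 = crossprod(f$comb, dZ), b2 = colSums(dZ))
  dcomb <- dZ %*% t(p$W2)
  dHd <- dcomb[, seq_len(hidden), drop = FALSE] * act_grad(f$Ad)
  g$Wd <- crossprod(Xbin, dHd); g$bd <- colSums(dHd)
  dH1 <- dcomb[, hidden + seq_len(hidden), drop = FALSE] * act_grad(f$A1)
  g$W1 <- crossprod(f$pool, dH1); g$b1 <- colSums(dH1)
  dpool <- dH1 %*% t(p$W1)
  dmean_f <- dpool[, seq_len(m), drop = FALSE] / lengths
  dmean_b <- dpool[, m + seq_len(m), drop = FALSE] / lengths
  dmax_f <- dpool[, 2L * m + seq_len(m), drop = FALSE]
  dmax_b <- dpool[, 3L * m + seq_len(m), drop = FALSE]
  dHf <- lapply(seq_len(Tm), function(t) dmean_f * f$maskt[[t]])
  dHb <- lapply(seq_len(Tm), function(t) dmean_b * f$maskt[[t]])
  for (t in seq_len(Tm)) {
    sel <- f$arg_f == t
    if (any(sel)) dHf[[t]][sel] <- dHf[[t]][sel] + dmax_f[sel]
    sel <- f$arg_b == t
    if (any(sel)) dHb[[t]][sel] <- dHb[[t]][sel] + dmax_b[sel]
  }
  g$Wf <- matrix(0, D, m); g$Uf <- matrix(0, m, m); g$bf <- rep(0, m)
  g$Wb <- matrix(0, D, m); g$Ub <- matrix(0, m, m); g$bb <- rep(0, m)
  carry <- matrix(0, N, m)
  for (t in rev(seq_len(Tm))) {
    dh <- (dHf[[t]] + carry) * f$maskt[[t]]
    dA <- dh * (1 - f$Hf[[t]]^2)
    g$Wf <- g$Wf + crossprod(Xs[[t]], dA)
    prev <- if (t > 1L) f$Hf[[t - 1L]] else matrix(0, N, m)
    g$Uf <- g$Uf + crossprod(prev, dA)
    g$bf <- g$bf + colSums(dA)
    carry <- dA %*% t(p$Uf)
  }
  carry <- matrix(0, N, m)
  for (t in seq_len(Tm)) {
    dh <- (dHb[[t]] + carry) * f$maskt[[t]]
    dA <- dh * (1 - f$Hb[[t]]^2)
    g$Wb <- g$Wb + crossprod(Xs[[t]], dA)
    prev <- if (t < Tm) f$Hb[[t + 1L]] else matrix(0, N, m)
    g$Ub <- g$Ub + crossprod(prev, dA)
    g$bb <- g$bb + colSums(dA)
    carry <- dA %*% t(p$Ub)
  }
  g
}

birnn_train <- function(X, lengths, Xbin, Y, m, hidden, epochs, lr, seed) {
  Tm <- dim(X)[2L]; D <- dim(X)[3L]
  p <- birnn_init(D, ncol(Xbin), m, hidden, ncol(Y), seed)
  opt <- adam_init(p)
  trace <- numeric(epochs)
  Xs <- lapply(seq_len(Tm), function(t) X[, t, , drop = FALSE][, 1L, ])
  for (ep in seq_len(epochs)) {
    f <- birnn_forward(p, X, lengths, Xbin)
    trace[ep] <- bce_loss(f$P, Y)
    if (!is.finite(trace[ep])) stop_("non-finite classifier loss")
    g <- birnn_grads(p, f, Xs, lengths, Xbin, Y, m, hidden)
    st <- adam_step(p, g, opt, lr)
    p <- st$params; opt <- st$state
  }
  list(params = p, loss_trace = trace)
}

#' Train a multilabel syndrome classifier
#'
#' @param inputs Output of [build_case_features()] for the config's mode.
#' @param labels Binary label matrix (cases x syndromes).
#' @param config A [classifier_config()].
#' @return Object of class `syndrome_classifier` with the fitted
#'   parameters, mode and loss trace.
#' @export
train_classifier <- function(inputs, labels, config = classifier_config()) {
  labels <- as.matrix(labels)
  fit <- if (config$mode == "plain") {
    mlp_train(as.matrix(inputs), labels, config$hidden, config$epochs,
              config$learning_rate, config$seed)
  } else {
    birnn_train(inputs$X, inputs$lengths, inputs$Xbin, labels,
                config$rnn_state, config$hidden, config$epochs,
                config$learning_rate, config$seed)
  }
  structure(list(params = fit$params, mode = config$mode, config = config,
                 loss_trace = fit$loss_trace,
                 labels = colnames(labels)),
            class = "syndrome_classifier")
}

#' Predict syndrome probabilities (and labels) for cases
#'
#' @param object A `syndrome_classifier`.
#' @param inputs Features built with [build_case_features()] in the
#'   classifier's mode.
#' @param ... Unused.
#' @return List with `prob` (cases x syndromes) and `label` (binary matrix
#'   at the config's threshold).
#' @export
predict.syndrome_classifier <- function(object, inputs, ...) {
  P <- if (object$mode == "plain") {
    mlp_forward(object$params, as.matrix(inputs))$P
  } else {
    birnn_forward(object$params, inputs$X, inputs$lengths, inputs$Xbin)$P
  }
  colnames(P) <- object$labels
  list(prob = P, label = (P >= object$config$threshold) * 1L)
}

#' Multilabel classification metrics
#'
#' Hamming loss (fraction of mismatched label bits), micro-averaged
#' precision/recall/F1 (true/false positives pooled over all labels) and
#' macro-averaged precision/recall/F1 (per-label scores averaged, with
#' zero-denominator cases scored 0 and counted).
#'
#' @param predicted,truth Binary matrices of identical shape.
#' @return Object of class `multilabel_report`.
#' @export
multilabel_metrics <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!all(dim(predicted) == dim(truth))) stop_("shape mismatch")
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  micro <- prf(tp, fp, fn)
  per_label <- t(vapply(seq_len(ncol(truth)), function(j) {
    prf(sum(predicted[, j] == 1 & truth[, j] == 1),
        sum(predicted[, j] == 1 & truth[, j] == 0),
        sum(predicted[, j] == 0 & truth[, j] == 1))
  }, numeric(3)))
  zero_div <- sum(rowSums(per_label == 0) > 0)
  structure(list(hamming = mean(predicted != truth), micro = micro,
                 macro = colMeans(per_label), per_label = per_label,
                 zero_divisions = zero_div),
            class = "multilabel_report")
}

#' @export
print.multilabel_report <- function(x, ...) {
  cat(sprintf(paste0("<multilabel_report> Hamming %.3f | micro P %.3f R %.3f",
                     " F1 %.3f | macro P %.3f R %.3f F1 %.3f\n"),
              x$hamming, x$micro["precision"], x$micro["recall"],
              x$micro["f1"], x$macro["precision"], x$macro["recall"],
              x$macro["f1"]))
  invisible(x)
}

#' k-fold cross-validation of the syndrome classifier
#'
#' Folds are stratified by per-case label count so every fold sees the
#' same mix of 2-, 3-, 4- and 5-label cases. Each case appears in exactly
#' one test fold.
#'
#' @param cases A `case_table`.
#' @param config A [classifier_config()].
#' @param kge Embedding matrix (required for `kge_sequence` mode).
#' @return List with per-fold `multilabel_report`s (`folds`), their `mean`
#'   metrics, and the fold assignment.
#' @export
cross_validate <- function(cases, config = classifier_config(), kge = NULL) {
  n <- nrow(cases$features)
  if (config$folds > n) stop_("more folds than cases")
  counts <- rowSums(cases$labels)
  fold_of <- integer(n)
  with_seed(config$seed, {
    for (k in unique(counts)) {
      ix <- sample(which(counts == k))
      fold_of[ix] <- rep_len(seq_len(config$folds), length(ix))
    }
  })
  inputs_all <- build_case_features(cases, kge, config$mode)
  subset_inputs <- function(ix) {
    if (config$mode == "plain") inputs_all[ix, , drop = FALSE]
    else list(X = inputs_all$X[ix, , , drop = FALSE],
              lengths = inputs_all$lengths[ix],
              Xbin = inputs_all$Xbin[ix, , drop = FALSE],
              flagged = integer(0))
  }
  reports <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    test_ix <- which(fold_of == f)
    train_ix <- setdiff(seq_len(n), test_ix)
    clf <- train_classifier(subset_inputs(train_ix),
                            cases$labels[train_ix, , drop = FALSE], config)
    pred <- predict(clf, subset_inputs(test_ix))
    reports[[f]] <- multilabel_metrics(pred$label,
                                       cases$labels[test_ix, , drop = FALSE])
  }
  mean_metrics <- list(
    hamming = mean(vapply(reports, function(r) r$hamming, numeric(1))),
    micro = rowMeans(vapply(reports, function(r) r$micro, numeric(3))),
    macro = rowMeans(vapply(reports, function(r) r$macro, numeric(3))))
  list(folds = reports, mean = mean_metrics, fold_of = fold_of)
}
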