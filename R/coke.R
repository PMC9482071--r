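#' Configuration for the contextual transformer embedding model
#'
#' @param hidden_size Embedding/hidden width D; must be divisible by `heads`.
#' @param layers Number of transformer encoder layers L.
#' @param heads Attention heads per layer.
#' @param ff_size Position-wise feedforward width (default equal to
#'   `hidden_size`, a desk-scale choice).
#' @param dropout Dropout rate applied to the embedding block and each
#'   sublayer output during training.
#' @param max_sequence_length Longest admissible token sequence (entity,
#'   relations..., entity); >= 3.
#' @param label_smoothing Smoothing parameter epsilon in (0, 1): the target
#'   entity receives probability epsilon and every other entity
#'   (1 - epsilon) / (V - 1). Default 0.8.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; identical seed gives identical training traces.
#' @return Object of class `coke_config`.
#' @export
coke_config <- function(hidden_size = 64L, layers = 2L, heads = 4L,
                        ff_size = hidden_size, dropout = 0.1,
                        max_sequence_length = 8L, label_smoothing = 0.8,
                        learning_rate = 1e-3, batch_size = 512L,
                        epochs = 100L, seed = 1L) {
  if (hidden_size %% heads != 0L) stop_("hidden_size must be divisible by heads")
  if (max_sequence_length < 3L) stop_("max_sequence_length must be >= 3")
  if (label_smoothing <= 0 || label_smoothing >= 1)
    stop_("label_smoothing must lie strictly in (0, 1)")
  structure(list(hidden_size = as.integer(hidden_size),
                 layers = as.integer(layers), heads = as.integer(heads),
                 ff_size = as.integer(ff_size), dropout = dropout,
                 max_sequence_length = as.integer(max_sequence_length),
                 label_smoothing = label_smoothing,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "coke_config")
}

#' Initialize a contextual embedding model
#'
#' Builds the parameter set: a shared element-embedding matrix (used both to
#' encode input tokens and, transposed, as the output projection of the
#' entity softmax -- weight tying), learned positional embeddings, `layers`
#' post-norm transformer encoder layers, and a feedforward prediction head.
#'
#' @param vocab A [kg_vocabulary()].
#' @param config A [coke_config()].
#' @return Object of class `coke_model`: list with `config`, `vocab`,
#'   `params` (flat named list) and `loss_trace`.
#' @export
coke_init <- function(vocab, config) {
  D <- config$hidden_size; FF <- config$ff_size
  Vtot <- length(vocab$tokens)
  with_seed(config$seed, {
    p <- list(E = rmat(Vtot, D), P = rmat(config$max_sequence_length, D),
              ln0_g = rep(1, D), ln0_b = rep(0, D))
    for (l in seq_len(config$layers)) {
      pre <- sprintf("L%d_", l)
      p[[paste0(pre, "Wq")]] <- rmat(D, D)
      p[[paste0(pre, "Wk")]] <- rmat(D, D)
      p[[paste0(pre, "Wv")]] <- rmat(D, D)
      p[[paste0(pre, "Wo")]] <- rmat(D, D); p[[paste0(pre, "bo")]] <- rep(0, D)
      p[[paste0(pre, "ln1_g")]] <- rep(1, D); p[[paste0(pre, "ln1_b")]] <- rep(0, D)
      p[[paste0(pre, "W1")]] <- rmat(D, FF); p[[paste0(pre, "b1")]] <- rep(0, FF)
      p[[paste0(pre, "W2")]] <- rmat(FF, D); p[[paste0(pre, "b2")]] <- rep(0, D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D); p[[paste0(pre, "ln2_b")]] <- rep(0, D)
    }
    p$head_Wz <- rmat(D, D); p$head_bz <- rep(0, D)
    p$lnz_g <- rep(1, D); p$lnz_b <- rep(0, D)
    p$b_out <- rep(0, length(vocab$entity_ids))
    structure(list(config = config, vocab = vocab, params = p,
                   loss_trace = numeric(0)),
              class = "coke_model")
  })
}

#' @export
print.coke_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<coke_model> D=%d L=%d heads=%d | %d tokens (%d entities)%s\n",
              cfg$hidden_size, cfg$layers, cfg$heads, length(x$vocab$tokens),
              length(x$vocab$entity_ids),
              if (length(x$loss_trace))
                sprintf(" | final loss %.4f", tail(x$loss_trace, 1)) else ""))
  invisible(x)
}

# Batched forward pass. `ids` is a B x n integer matrix (one masked
# sequence per row), `mask_pos` the per-row mask position. Row layout of
# hidden-state matrices is sequence-major: row (b-1)*n + i is position i of
# sequence b. Returns logits over the entity block plus a full cache
# (per-layer inputs, per-head attention) for the backward pass and for
# distillation.
coke_forward <- function(model, ids, mask_pos, training = FALSE) {
  cfg <- model$config; p <- model$params; vocab <- model$vocab
  B <- nrow(ids); n <- ncol(ids)
  if (n > cfg$max_sequence_length)
    stop_("sequence length %d exceeds max_sequence_length %d", n,
          cfg$max_sequence_length)
  D <- cfg$hidden_size; h <- cfg$heads; dh <- D %/% h
  scale <- 1 / sqrt(dh)
  ids_flat <- as.vector(t(ids))
  pos_flat <- rep(seq_len(n), B)
  pos_rows <- lapply(seq_len(n), function(i) seq(i, B * n, by = n))

  X <- p$E[ids_flat, , drop = FALSE] + p$P[pos_flat, , drop = FALSE]
  l0 <- ln_fwd(X, p$ln0_g, p$ln0_b)
  d0 <- drop_fwd(l0$y, cfg$dropout, training)
  H <- d0$y

  # head bookkeeping: hexp maps a hidden column to its head; M pools an
  # elementwise product over each head's column block in one small matmul
  hexp <- rep(seq_len(h), each = dh)
  M <- matrix(0, D, h); M[cbind(seq_len(D), hexp)] <- 1

  layers <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d_", l)
    H_in <- H
    Q <- H_in %*% p[[paste0(pre, "Wq")]]
    K <- H_in %*% p[[paste0(pre, "Wk")]]
    Vv <- H_in %*% p[[paste0(pre, "Wv")]]
    Qs <- lapply(pos_rows, function(rr) Q[rr, , drop = FALSE])
    Ks <- lapply(pos_rows, function(rr) K[rr, , drop = FALSE])
    Vs <- lapply(pos_rows, function(rr) Vv[rr, , drop = FALSE])
    Aarr <- array(0, c(B, n, n, h))
    for (i in seq_len(n)) {
      Sl <- lapply(seq_len(n), function(k) (Qs[[i]] * Ks[[k]]) %*% M * scale)
      for (hd in seq_len(h)) {
        Smat <- vapply(seq_len(n), function(k) Sl[[k]][, hd], numeric(B))
        if (B == 1L) Smat <- matrix(Smat, 1L)
        Aarr[, i, , hd] <- row_softmax(Smat)
      }
    }
    C <- matrix(0, B * n, D)
    for (i in seq_len(n)) {
      Ci <- matrix(0, B, D)
      for (k in seq_len(n))
        Ci <- Ci + Vs[[k]] * matrix(Aarr[, i, k, ], B, h)[, hexp, drop = FALSE]
      C[pos_rows[[i]], ] <- Ci
    }
    O <- addbias(C %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    dO_ <- drop_fwd(O, cfg$dropout, training)
    l1 <- ln_fwd(H_in + dO_$y, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    H1 <- l1$y
    U <- addbias(H1 %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    G <- act_fwd(U)
    Fo <- addbias(G %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    dF_ <- drop_fwd(Fo, cfg$dropout, training)
    l2 <- ln_fwd(H1 + dF_$y, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    layers[[l]] <- list(H_in = H_in, Qs = Qs, Ks = Ks, Vs = Vs, C = C,
                        Aarr = Aarr,
                        mO = dO_$mask, c_ln1 = l1$cache, H1 = H1, U = U, G = G,
                        mF = dF_$mask, c_ln2 = l2$cache, H_out = l2$y)
    H <- l2$y
  }

  mask_rows <- (seq_len(B) - 1L) * n + mask_pos
  Hm <- H[mask_rows, , drop = FALSE]
  Z1 <- addbias(Hm %*% p$head_Wz, p$head_bz)
  Zg <- act_fwd(Z1)
  lz <- ln_fwd(Zg, p$lnz_g, p$lnz_b)
  Z <- lz$y
  E_ent <- p$E[vocab$entity_ids, , drop = FALSE]
  logits <- addbias(Z %*% t(E_ent), p$b_out)

  list(logits = logits,
       cache = list(B = B, n = n, ids_flat = ids_flat, pos_flat = pos_flat,
                    pos_rows = pos_rows, mask_rows = mask_rows,
                    X_ln = l0$cache, m0 = d0$mask, H0 = d0$y, layers = layers,
                    Hm = Hm, Z1 = Z1, Zg = Zg, c_lnz = lz$cache, Z = Z))
}

# Backward pass. `dlogits` is the gradient at the entity logits (may be
# NULL when only injected gradients are present). `inject` optionally adds
# gradients at intermediate activations, which is how the distillation
# losses reach the student: `dH0` at the embedding-block output, `dH[[l]]`
# at layer l's output, `dA[[l]][[head]]` at layer l's attention matrices.
coke_backward <- function(model, cache, dlogits = NULL, inject = NULL) {
  cfg <- model$config; p <- model$params; vocab <- model$vocab
  B <- cache$B; n <- cache$n
  D <- cfg$hidden_size; h <- cfg$heads; dh <- D %/% h
  scale <- 1 / sqrt(dh)
  pos_rows <- cache$pos_rows
  g <- list()

  dH <- matrix(0, B * n, D)
  if (!is.null(dlogits)) {
    E_ent <- p$E[vocab$entity_ids, , drop = FALSE]
    dZ <- dlogits %*% E_ent
    g$b_out <- colSums(dlogits)
    dE_head <- crossprod(dlogits, cache$Z)  # V_ent x D
    bz <- ln_bwd(dZ, cache$c_lnz)
    g$lnz_g <- bz$dg; g$lnz_b <- bz$db
    dZ1 <- bz$dx * act_grad(cache$Z1)
    g$head_Wz <- crossprod(cache$Hm, dZ1)
    g$head_bz <- colSums(dZ1)
    dHm <- dZ1 %*% t(p$head_Wz)
    dH[cache$mask_rows, ] <- dH[cache$mask_rows, ] + dHm
  } else {
    dE_head <- NULL
  }

  for (l in rev(seq_len(cfg$layers))) {
    pre <- sprintf("L%d_", l)
    lc <- cache$layers[[l]]
    if (!is.null(inject$dH[[l]])) dH <- dH + inject$dH[[l]]
    b2 <- ln_bwd(dH, lc$c_ln2)
    g[[paste0(pre, "ln2_g")]] <- b2$dg; g[[paste0(pre, "ln2_b")]] <- b2$db
    dH1 <- b2$dx
    dF <- drop_bwd(b2$dx, lc$mF)
    dG <- dF %*% t(p[[paste0(pre, "W2")]])
    g[[paste0(pre, "W2")]] <- crossprod(lc$G, dF)
    g[[paste0(pre, "b2")]] <- colSums(dF)
    dU <- dG * act_grad(lc$U)
    g[[paste0(pre, "W1")]] <- crossprod(lc$H1, dU)
    g[[paste0(pre, "b1")]] <- colSums(dU)
    dH1 <- dH1 + dU %*% t(p[[paste0(pre, "W1")]])

    b1 <- ln_bwd(dH1, lc$c_ln1)
    g[[paste0(pre, "ln1_g")]] <- b1$dg; g[[paste0(pre, "ln1_b")]] <- b1$db
    dH_in <- b1$dx
    dO <- drop_bwd(b1$dx, lc$mO)
    dC <- dO %*% t(p[[paste0(pre, "Wo")]])
    g[[paste0(pre, "Wo")]] <- crossprod(lc$C, dO)
    g[[paste0(pre, "bo")]] <- colSums(dO)

    hexp <- rep(seq_len(h), each = dh)
    M <- matrix(0, D, h); M[cbind(seq_len(D), hexp)] <- 1
    Aarr <- lc$Aarr
    dCs <- lapply(pos_rows, function(rr) dC[rr, , drop = FALSE])
    dAarr <- array(0, c(B, n, n, h))
    dVs <- lapply(seq_len(n), function(k) matrix(0, B, D))
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        dAarr[, i, k, ] <- (dCs[[i]] * lc$Vs[[k]]) %*% M
        dVs[[k]] <- dVs[[k]] +
          dCs[[i]] * matrix(Aarr[, i, k, ], B, h)[, hexp, drop = FALSE]
      }
    }
    if (!is.null(inject$dA[[l]]))
      for (hd in seq_len(h))
        if (!is.null(inject$dA[[l]][[hd]]))
          dAarr[, , , hd] <- dAarr[, , , hd] + inject$dA[[l]][[hd]]
    dSarr <- array(0, c(B, n, n, h))
    for (hd in seq_len(h)) {
      for (i in seq_len(n)) {
        Ai <- matrix(Aarr[, i, , hd], B, n)
        dAi <- matrix(dAarr[, i, , hd], B, n)
        dSarr[, i, , hd] <- (dAi - rowSums(dAi * Ai)) * Ai
      }
    }
    dQs <- lapply(seq_len(n), function(i) matrix(0, B, D))
    dKs <- lapply(seq_len(n), function(k) matrix(0, B, D))
    for (i in seq_len(n)) {
      for (k in seq_len(n)) {
        coef <- matrix(dSarr[, i, k, ], B, h)[, hexp, drop = FALSE] * scale
        dQs[[i]] <- dQs[[i]] + lc$Ks[[k]] * coef
        dKs[[k]] <- dKs[[k]] + lc$Qs[[i]] * coef
      }
    }
    dQ <- matrix(0, B * n, D); dK <- matrix(0, B * n, D)
    dV <- matrix(0, B * n, D)
    for (i in seq_len(n)) {
      dQ[pos_rows[[i]], ] <- dQs[[i]]
      dK[pos_rows[[i]], ] <- dKs[[i]]
      dV[pos_rows[[i]], ] <- dVs[[i]]
    }
    g[[paste0(pre, "Wq")]] <- crossprod(lc$H_in, dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(lc$H_in, dK)
    g[[paste0(pre, "Wv")]] <- crossprod(lc$H_in, dV)
    dH_in <- dH_in + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
    dH <- dH_in
  }

  if (!is.null(inject$dH0)) dH <- dH + inject$dH0
  dX0 <- drop_bwd(dH, cache$m0)
  b0 <- ln_bwd(dX0, cache$X_ln)
  g$ln0_g <- b0$dg; g$ln0_b <- b0$db
  dX <- b0$dx

  dE <- matrix(0, nrow(p$E), ncol(p$E))
  agg <- rowsum(dX, cache$ids_flat)
  dE[as.integer(rownames(agg)), ] <- agg
  if (!is.null(dE_head))
    dE[vocab$entity_ids, ] <- dE[vocab$entity_ids, ] + dE_head
  g$E <- dE
  dP <- matrix(0, nrow(p$P), ncol(p$P))
  aggp <- rowsum(dX, cache$pos_flat)
  dP[as.integer(rownames(aggp)), ] <- aggp
  g$P <- dP
  g
}

#' Label-smoothed target distribution over the entity vocabulary
#'
#' The target entity receives probability `eps`; every other entity
#' receives `(1 - eps) / (V - 1)`. The vector sums to 1.
#'
#' @param target Integer index of the target entity in `1:V`.
#' @param V Entity vocabulary size (>= 2).
#' @param eps Smoothing parameter in (0, 1); the target's share.
#' @return Numeric vector of length `V` summing to 1.
#' @export
smooth_labels <- function(target, V, eps) {
  if (V < 2L) stop_("V must be >= 2")
  if (eps <= 0 || eps >= 1) stop_("eps must lie strictly in (0, 1)")
  if (target < 1L || target > V) stop_("target out of range")
  y <- rep((1 - eps) / (V - 1), V)
  y[target] <- eps
  y
}

#' Cross-entropy between a label distribution and a predicted distribution
#'
#' @param p Predicted probability vector (strictly positive).
#' @param y Label distribution of the same length.
#' @return `-sum(y * log(p))`.
#' @export
cross_entropy <- function(p, y) {
  if (length(p) != length(y)) stop_("p and y must have the same length")
  if (any(p <= 0)) stop_("p must be strictly positive")
  -sum(y * log(p))
}

# Mean smoothed cross-entropy over a batch of entity logits, and its
# gradient. `targets` indexes the entity block.
smoothed_ce_batch <- function(logits, targets, eps) {
  B <- nrow(logits); V <- ncol(logits)
  logp <- row_log_softmax(logits)
  lp_t <- logp[cbind(seq_len(B), targets)]
  off <- (1 - eps) / (V - 1)
  loss <- -(eps * lp_t + off * (rowSums(logp) - lp_t))
  Y <- matrix(off, B, V)
  Y[cbind(seq_len(B), targets)] <- eps
  dlogits <- (exp(logp) - Y) / B
  list(loss = mean(loss), dlogits = dlogits)
}

#' Build masked training instances from triples and paths
#'
#' Every edge (h, r, t) becomes the token sequence (h, r, t) and every
#' k-hop path becomes (s, r1, ..., rk, o); each sequence yields exactly two
#' instances, one with the first token replaced by `[MASK]` (head/source
#' prediction) and one with the last token replaced (tail/target
#' prediction). Relations inside paths are fed as individual tokens so the
#' relation vocabulary stays closed.
#'
#' @param kg A [knowledge_graph()] (its triples become edge instances), or a
#'   data.frame with columns head/relation/tail.
#' @param vocab A [kg_vocabulary()].
#' @param paths Optional `path_instances` data.frame ([enumerate_chains()] /
#'   [filter_causal()]) to add as path instances.
#' @param max_sequence_length Paths longer than this are dropped.
#' @return Object of class `coke_instances`: list of same-length buckets,
#'   each with an `ids` matrix, `mask_pos` and `target` (entity-block
#'   index) vectors; plus `n_instances`.
#' @export
make_instances <- function(kg, vocab, paths = NULL,
                           max_sequence_length = 8L) {
  triples <- if (inherits(kg, "knowledge_graph")) kg$triples else kg
  ent_base <- vocab$entity_ids[1L] - 1L
  seqs <- list()
  if (nrow(triples)) {
    m <- cbind(vocab_lookup(vocab, triples$head),
               vocab_lookup(vocab, triples$relation),
               vocab_lookup(vocab, triples$tail))
    seqs[["3"]] <- m
  }
  if (!is.null(paths) && nrow(paths)) {
    for (k in sort(unique(paths$hops))) {
      if (k + 2L > max_sequence_length) next
      sub <- paths[paths$hops == k, , drop = FALSE]
      rels <- matrix(vocab_lookup(vocab, unlist(sub$relations)),
                     nrow(sub), k, byrow = TRUE)
      m <- cbind(vocab_lookup(vocab, sub$source), rels,
                 vocab_lookup(vocab, sub$target))
      key <- as.character(k + 2L)
      seqs[[key]] <- rbind(seqs[[key]], m)
    }
  }
  buckets <- list()
  for (key in names(seqs)) {
    m <- seqs[[key]]; n <- ncol(m); B <- nrow(m)
    head_ids <- m[, 1L]; tail_ids <- m[, n]
    mh <- m; mh[, 1L] <- vocab$mask_id
    mt <- m; mt[, n] <- vocab$mask_id
    buckets[[key]] <- list(
      ids = rbind(mh, mt),
      mask_pos = c(rep(1L, B), rep(n, B)),
      target = c(head_ids, tail_ids) - ent_base,
      n = n)
  }
  structure(list(buckets = buckets,
                 n_instances = sum(vapply(buckets, function(b) nrow(b$ids),
                                          integer(1)))),
            class = "coke_instances")
}

#' Train the contextual embedding model by masked entity prediction
#'
#' Minimizes the mean label-smoothed cross-entropy of the masked-position
#' entity softmax by minibatch Adam. Edge instances and (optionally) mined
#' path instances are shuffled together each epoch; batches contain
#' same-length sequences.
#'
#' @param kg Training [knowledge_graph()].
#' @param config A [coke_config()].
#' @param paths Optional `path_instances` to train on alongside edges.
#' @return A trained `coke_model` with a per-epoch `loss_trace`.
#' @export
train_coke <- function(kg, config = coke_config(), paths = NULL) {
  vocab <- kg_vocabulary(kg)
  model <- coke_init(vocab, config)
  inst <- make_instances(kg, vocab, paths = paths,
                         max_sequence_length = config$max_sequence_length)
  if (inst$n_instances == 0L) stop_("no training instances")
  res <- cpp_train_coke(model$params, unname(inst$buckets), config$epochs,
                        config$batch_size, config$learning_rate,
                        config$label_smoothing, config$dropout,
                        config$layers, config$heads,
                        vocab$entity_ids[1L] - 1L, length(vocab$entity_ids),
                        config$seed + 1L)
  model$params <- res$params
  model$loss_trace <- res$loss_trace
  model
}

#' Embed a token sequence (element + positional embeddings)
#'
#' Each position's hidden state is the sum of its element embedding and its
#' positional embedding, followed by layer normalization (no dropout at
#' inference).
#'
#' @param model A `coke_model`.
#' @param ids Integer token ids (length n <= `max_sequence_length`).
#' @return n x D matrix of hidden states.
#' @export
embed_inputs <- function(model, ids) {
  p <- model$params
  n <- length(ids)
  if (n > nrow(p$P)) stop_("sequence longer than the positional table")
  if (any(ids < 1L | ids > nrow(p$E))) stop_("token id out of range")
  X <- p$E[ids, , drop = FALSE] + p$P[seq_len(n), , drop = FALSE]
  ln_fwd(X, p$ln0_g, p$ln0_b)$y
}

#' Run the transformer encoder stack over embedded inputs
#'
#' Applies the model's L post-norm encoder layers and returns every layer's
#' hidden states together with the per-head attention matrices (needed by
#' attention-based distillation).
#'
#' @param model A `coke_model`.
#' @param h n x D matrix of embedded inputs (from [embed_inputs()]).
#' @return List with `states` (list of n x D matrices, one per layer;
#'   `states[[L]]` are the final representations) and `attention` (per
#'   layer, per head n x n matrices). With zero layers, `final` equals `h`.
#' @export
encode <- function(model, h) {
  cfg <- model$config; p <- model$params
  n <- nrow(h); D <- cfg$hidden_size
  hds <- cfg$heads; dh <- D %/% hds
  scale <- 1 / sqrt(dh)
  states <- list(); attention <- list()
  H <- h
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("L%d_", l)
    Q <- H %*% p[[paste0(pre, "Wq")]]
    K <- H %*% p[[paste0(pre, "Wk")]]
    Vv <- H %*% p[[paste0(pre, "Wv")]]
    C <- matrix(0, n, D)
    attn_l <- vector("list", hds)
    for (hd in seq_len(hds)) {
      cols <- ((hd - 1L) * dh + 1L):(hd * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) * scale
      A <- row_softmax(S)
      attn_l[[hd]] <- A
      C[, cols] <- A %*% Vv[, cols, drop = FALSE]
    }
    O <- addbias(C %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    H1 <- ln_fwd(H + O, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])$y
    U <- addbias(H1 %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    Fo <- addbias(act_fwd(U) %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    H <- ln_fwd(H1 + Fo, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])$y
    states[[l]] <- H
    attention[[l]] <- attn_l
  }
  list(states = states, attention = attention, final = H)
}

#' Predict the masked entity from final hidden states
#'
#' The masked position's final state passes through the prediction
#' feedforward and a softmax over the entity vocabulary only (relations and
#' special tokens are excluded from the candidate set); the output
#' projection is the shared element-embedding matrix.
#'
#' @param model A `coke_model`.
#' @param hL n x D matrix of final hidden states (from [encode()]).
#' @param mask_position Position of the `[MASK]` token in the sequence.
#' @return Named probability vector over entity tokens, summing to 1.
#' @export
predict_masked <- function(model, hL, mask_position) {
  p <- model$params; vocab <- model$vocab
  if (mask_position < 1L || mask_position > nrow(hL))
    stop_("mask_position out of range")
  z1 <- addbias(hL[mask_position, , drop = FALSE] %*% p$head_Wz, p$head_bz)
  z <- ln_fwd(act_fwd(z1), p$lnz_g, p$lnz_b)$y
  E_ent <- p$E[vocab$entity_ids, , drop = FALSE]
  logits <- addbias(z %*% t(E_ent), p$b_out)
  pr <- drop(row_softmax(logits))
  names(pr) <- vocab$tokens[vocab$entity_ids]
  pr
}

# Batched inference: entity logits for B masked sequences (compiled path).
coke_score <- function(model, ids, mask_pos) {
  cpp_coke_logits(model$params, ids, as.integer(mask_pos),
                  model$config$layers, model$config$heads,
                  model$vocab$entity_ids[1L] - 1L,
                  length(model$vocab$entity_ids))
}

#' Entity embeddings of a trained model
#'
#' @param model A `coke_model`.
#' @return Matrix (entities x D) with entity tokens as row names.
#' @export
coke_entity_embeddings <- function(model) {
  E <- model$params$E[model$vocab$entity_ids, , drop = FALSE]
  rownames(E) <- model$vocab$tokens[model$vocab$entity_ids]
  E
}
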