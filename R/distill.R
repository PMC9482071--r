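#' Configuration for teacher-to-student knowledge distillation
#'
#' The student compresses a trained contextual embedding model at three
#' levels: the embedding-layer output, interval-mapped transformer layers
#' (attention matrices and hidden states, both under MSE), and the
#' temperature-softened prediction distribution.
#'
#' @param student_layers Student depth S; the teacher depth T must be an
#'   integer multiple (knowledge is distilled in k = T/S layer intervals).
#' @param student_hidden Student hidden size d (may differ from the
#'   teacher's d0; trainable projections bridge the two spaces).
#' @param temperature Softmax temperature t > 0 for the prediction loss.
#'   Default 1 (no softening); exposed because no canonical value exists.
#' @param w_emb,w_attn,w_hidn,w_pred Non-negative loss weights.
#' @param learning_rate,batch_size,epochs,dropout,seed Optimization
#'   settings for the student (the teacher is frozen).
#' @return Object of class `distill_config`.
#' @export
distill_config <- function(student_layers = 1L, student_hidden = NULL,
                           temperature = 1, w_emb = 1, w_attn = 1,
                           w_hidn = 1, w_pred = 1, learning_rate = 1e-3,
                           batch_size = 512L, epochs = 100L, dropout = 0,
                           seed = 1L) {
  if (temperature <= 0) stop_("temperature must be > 0")
  if (any(c(w_emb, w_attn, w_hidn, w_pred) < 0))
    stop_("loss weights must be >= 0")
  structure(list(student_layers = as.integer(student_layers),
                 student_hidden = student_hidden, temperature = temperature,
                 w_emb = w_emb, w_attn = w_attn, w_hidn = w_hidn,
                 w_pred = w_pred, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), dropout = dropout,
                 seed = as.integer(seed)),
            class = "distill_config")
}

#' Student-to-teacher layer mapping
#'
#' With a T-layer teacher and an S-layer student (T divisible by S),
#' student layer i is supervised by teacher layer `i * (T/S)`: e.g. a
#' 4-layer student of a 12-layer teacher maps 1 -> 3, 2 -> 6, 3 -> 9,
#' 4 -> 12.
#'
#' @param S Student layer count.
#' @param T_ Teacher layer count (must be divisible by `S`).
#' @return Named integer vector mapping student layer to teacher layer.
#' @export
layer_map <- function(S, T_) {
  if (S < 1L || T_ < 1L) stop_("layer counts must be >= 1")
  if (T_ %% S != 0L) stop_("teacher layers (%d) not divisible by student layers (%d)", T_, S)
  k <- T_ %/% S
  stats::setNames(seq_len(S) * k, seq_len(S))
}

#' Embedding-layer distillation loss
#'
#' Mean squared error between the student's embedding matrix, projected
#' into the teacher's space by a trainable linear map, and the teacher's
#' embedding matrix: `MSE(E_S W_e, E_T)`, mean over all entries.
#'
#' @param E_S Student matrix (l x d).
#' @param E_T Teacher matrix (l x d0).
#' @param W_e Projection (d x d0).
#' @return Scalar loss.
#' @export
embedding_loss <- function(E_S, E_T, W_e) {
  if (ncol(E_S) != nrow(W_e) || ncol(W_e) != ncol(E_T) ||
      nrow(E_S) != nrow(E_T))
    stop_("shape mismatch: E_S %dx%d, W_e %dx%d, E_T %dx%d",
          nrow(E_S), ncol(E_S), nrow(W_e), ncol(W_e), nrow(E_T), ncol(E_T))
  d <- E_S %*% W_e - E_T
  mean(d * d)
}

#' Attention-based distillation loss
#'
#' Average over heads of the MSE between student and teacher attention
#' matrices at a mapped layer: `(1/h) sum_i MSE(A_i^S, A_i^T)`.
#'
#' @param student_attn,teacher_attn Lists (one element per head) of
#'   attention matrices, or 3-d arrays with the head as the last dimension.
#' @return Scalar loss.
#' @export
attention_loss <- function(student_attn, teacher_attn) {
  as_list <- function(a) {
    if (is.list(a)) a
    else lapply(seq_len(dim(a)[3]), function(h) a[, , h])
  }
  s <- as_list(student_attn); t_ <- as_list(teacher_attn)
  if (length(s) != length(t_))
    stop_("head-count mismatch: %d vs %d", length(s), length(t_))
  mean(vapply(seq_along(s), function(h) {
    d <- s[[h]] - t_[[h]]
    mean(d * d)
  }, numeric(1)))
}

#' Hidden-state distillation loss
#'
#' MSE between the student's hidden states at a mapped layer, projected by
#' a trainable linear map, and the teacher's: `MSE(H_S W_h, H_T)`.
#'
#' @param H_S Student hidden states (l x d).
#' @param H_T Teacher hidden states (l x d0).
#' @param W_h Projection (d x d0).
#' @return Scalar loss.
#' @export
hidden_loss <- function(H_S, H_T, W_h) {
  embedding_loss(H_S, H_T, W_h)
}

#' Temperature-softened prediction distillation loss
#'
#' Cross-entropy between the teacher's temperature-softened distribution
#' and the student's log-softmax: `CE(softmax(z_T / t), log_softmax(z_S / t))`,
#' with the teacher as the target distribution.
#'
#' @param z_T Teacher logit vector (or matrix, one row per query).
#' @param z_S Student logits, same shape.
#' @param t Temperature > 0.
#' @return Scalar loss (mean over rows for matrix input).
#' @export
prediction_loss <- function(z_T, z_S, t) {
  if (t <= 0) stop_("temperature must be > 0")
  if (length(z_T) != length(z_S)) stop_("logit shape mismatch")
  zT <- rbind(z_T) / t
  zS <- rbind(z_S) / t
  pT <- row_softmax(zT)
  logqS <- row_log_softmax(zS)
  mean(-rowSums(pT * logqS))
}

#' Distill a trained model into a compact student
#'
#' Trains a fresh student (fewer layers and optionally a smaller hidden
#' size) against a frozen teacher by minimizing
#' `w_emb L_emb + w_attn L_attn + w_hidn L_hidn + w_pred L_pred` over the
#' same masked edge/path instances the teacher was trained on. Teacher and
#' student must share the head count (the attention loss is undefined
#' otherwise) and the vocabulary.
#'
#' @param teacher A trained `coke_model`.
#' @param kg Training [knowledge_graph()] (same vocabulary as the teacher).
#' @param config A [distill_config()].
#' @param paths Optional `path_instances`, as in [train_coke()].
#' @return List of class `distill_result`: `student` (a `coke_model`),
#'   `projections` (`W_e`, per-layer `W_h`), `layer_map`, and loss traces
#'   (`loss_trace` plus one per term).
#' @export
distill <- function(teacher, kg, config = distill_config(), paths = NULL) {
  tcfg <- teacher$config
  S <- config$student_layers
  if (tcfg$layers %% S != 0L)
    stop_("teacher layers (%d) not divisible by student layers (%d)",
          tcfg$layers, S)
  d <- config$student_hidden %||% tcfg$hidden_size
  if (d %% tcfg$heads != 0L)
    stop_("student hidden size must be divisible by the (shared) head count")
  vocab <- kg_vocabulary(kg)
  if (!identical(vocab$tokens, teacher$vocab$tokens))
    stop_("teacher/student vocabulary mismatch")
  scfg <- coke_config(hidden_size = d, layers = S, heads = tcfg$heads,
                      ff_size = max(d, tcfg$ff_size %/%
                                      (tcfg$hidden_size %/% d)),
                      dropout = config$dropout,
                      max_sequence_length = tcfg$max_sequence_length,
                      label_smoothing = tcfg$label_smoothing,
                      learning_rate = config$learning_rate,
                      batch_size = config$batch_size,
                      epochs = config$epochs, seed = config$seed)
  student <- coke_init(vocab, scfg)
  d0 <- tcfg$hidden_size
  proj <- with_seed(config$seed + 7L, {
    pr <- list(W_e = if (d == d0) diag(d) else rmat(d, d0, sd = 1 / sqrt(d)))
    for (l in seq_len(S))
      pr[[sprintf("L%d_W_h", l)]] <- if (d == d0) diag(d) else
        rmat(d, d0, sd = 1 / sqrt(d))
    pr
  })
  inst <- make_instances(kg, vocab, paths = paths,
                         max_sequence_length = tcfg$max_sequence_length)
  res <- cpp_distill(teacher$params, student$params, proj,
                     unname(inst$buckets), config$epochs, config$batch_size,
                     config$learning_rate, tcfg$layers, S, tcfg$heads,
                     config$temperature,
                     c(config$w_emb, config$w_attn, config$w_hidn,
                       config$w_pred),
                     vocab$entity_ids[1L] - 1L, length(vocab$entity_ids),
                     config$dropout, config$seed + 11L)
  student$params <- res$params
  student$loss_trace <- res$loss_trace
  structure(list(student = student, projections = res$proj,
                 layer_map = layer_map(S, tcfg$layers),
                 loss_trace = res$loss_trace,
                 emb_trace = res$emb_trace, attn_trace = res$attn_trace,
                 hidn_trace = res$hidn_trace, pred_trace = res$pred_trace,
                 config = config),
            class = "distill_result")
}

#' @export
print.distill_result <- function(x, ...) {
  cat(sprintf("<distill_result> student L=%d D=%d | final distill loss %.4f\n",
              x$student$config$layers, x$student$config$hidden_size,
              tail(x$loss_trace, 1)))
  invisible(x)
}

#' Distillation loss components on a batch, without training
#'
#' Runs teacher and student forward on the same masked sequences and
#' returns the four loss terms. Useful for checking the identity
#' configuration: a student that is a copy of its teacher with identity
#' projections has zero embedding/attention/hidden losses and a prediction
#' loss equal to the entropy of the teacher's softened distribution.
#'
#' @param teacher,student `coke_model`s with equal head counts.
#' @param projections List with `W_e` and `L<i>_W_h` matrices.
#' @param ids Integer matrix of masked token sequences (one per row).
#' @param mask_pos Integer vector of mask positions.
#' @param temperature Temperature for the prediction term.
#' @return Named list `emb`, `attn`, `hidn`, `pred`.
#' @export
distill_losses <- function(teacher, student, projections, ids, mask_pos,
                           temperature = 1) {
  cpp_distill_losses(teacher$params, student$params, projections,
                     ids, as.integer(mask_pos), teacher$config$layers,
                     student$config$layers, teacher$config$heads,
                     temperature, teacher$vocab$entity_ids[1L] - 1L,
                     length(teacher$vocab$entity_ids))
}
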