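BASELINE_FAMILIES <- c("transe", "transh", "transr", "transd", "distmult",
                       "complex", "simple", "rotate")

#' Configuration for baseline knowledge-graph embedding models
#'
#' @param dim Embedding dimension.
#' @param epochs Training epochs.
#' @param learning_rate SGD step size.
#' @param margin Margin gamma of the ranking loss.
#' @param norm Distance norm p for translational families (1 or 2).
#' @param batch_size Minibatch size.
#' @param seed Integer seed.
#' @return Object of class `baseline_config`.
#' @export
baseline_config <- function(dim = 32L, epochs = 100L, learning_rate = 0.05,
                            margin = 1, norm = 2L, batch_size = 512L,
                            seed = 1L) {
  if (!norm %in% c(1L, 2L)) stop_("norm must be 1 or 2")
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 learning_rate = learning_rate, margin = margin,
                 norm = as.integer(norm), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "baseline_config")
}

#' Initialize a baseline scoring model
#'
#' Canonical scoring-function families behind one interface: translational
#' (TransE and its projection variants TransH/TransR/TransD), bilinear
#' (DistMult, ComplEx, SimplE with two vectors per entity) and rotational
#' (RotatE, whose relation embeddings are unit-modulus phases by
#' construction).
#'
#' @param family One of `"transe"`, `"transh"`, `"transr"`, `"transd"`,
#'   `"distmult"`, `"complex"`, `"simple"`, `"rotate"`.
#' @param entities,relations Character token vectors.
#' @param config A [baseline_config()].
#' @return Object of class `scoring_model`.
#' @export
scoring_model <- function(family, entities, relations,
                          config = baseline_config()) {
  family <- match.arg(family, BASELINE_FAMILIES)
  entities <- sort_c(unique(entities))
  relations <- sort_c(unique(relations))
  Ve <- length(entities); Vr <- length(relations); D <- config$dim
  with_seed(config$seed, {
    u <- function(n, m) matrix(runif(n * m, -6 / sqrt(m), 6 / sqrt(m)), n, m)
    p <- switch(family,
      transe = list(E = u(Ve, D), R = u(Vr, D)),
      transh = {
        W <- u(Vr, D); W <- W / sqrt(rowSums(W^2))
        list(E = u(Ve, D), R = u(Vr, D), W = W)
      },
      transr = list(E = u(Ve, D), R = u(Vr, D),
                    M = array(rep(diag(D), Vr), c(D, D, Vr))),
      transd = list(E = u(Ve, D), R = u(Vr, D), Ep = u(Ve, D), Rp = u(Vr, D)),
      distmult = list(E = u(Ve, D), R = u(Vr, D)),
      complex = list(Er = u(Ve, D), Ei = u(Ve, D), Rr = u(Vr, D),
                     Ri = u(Vr, D)),
      simple = list(Eh = u(Ve, D), Et = u(Ve, D), R = u(Vr, D),
                    Rinv = u(Vr, D)),
      rotate = list(Er = u(Ve, D), Ei = u(Ve, D),
                    Theta = matrix(runif(Vr * D, -pi, pi), Vr, D)))
    structure(list(family = family, entities = entities,
                   relations = relations, dim = D, p = p, config = config),
              class = "scoring_model")
  })
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf("<scoring_model:%s> %d entities, %d relations, dim %d\n",
              x$family, length(x$entities), length(x$relations), x$dim))
  invisible(x)
}

row_norm <- function(d, p) {
  if (p == 1L) rowSums(abs(d)) else sqrt(rowSums(d * d))
}

#' Score triples under a baseline model
#'
#' Higher scores mean more plausible triples. Canonical forms:
#' TransE `-||h + r - t||_p`; TransH/R/D the same distance after the
#' family's entity projection; DistMult `sum(h * r * t)`;
#' ComplEx `Re(sum(h * r * conj(t)))`; SimplE the symmetrised product with
#' two vectors per entity; RotatE `-sum |h o r - t|` in complex
#' coordinates with unit-modulus relation phases.
#'
#' @param model A [scoring_model()].
#' @param h,r,t Integer indices (into the model's sorted entity/relation
#'   vocabularies) or character tokens; recycled to a common length.
#' @return Numeric score vector.
#' @export
score_triples <- function(model, h, r, t) {
  if (is.character(h)) h <- match(h, model$entities)
  if (is.character(r)) r <- match(r, model$relations)
  if (is.character(t)) t <- match(t, model$entities)
  n <- max(length(h), length(r), length(t))
  h <- rep_len(as.integer(h), n); r <- rep_len(as.integer(r), n)
  t <- rep_len(as.integer(t), n)
  if (anyNA(h) || anyNA(t) || any(h < 1L) || any(h > length(model$entities)) ||
      any(t < 1L) || any(t > length(model$entities)))
    stop_("entity id out of range")
  if (anyNA(r) || any(r < 1L) || any(r > length(model$relations)))
    stop_("relation id out of range")
  p <- model$p; np <- model$config$norm
  switch(model$family,
    transe = -row_norm(p$E[h, , drop = FALSE] + p$R[r, , drop = FALSE] -
                         p$E[t, , drop = FALSE], np),
    transh = {
      w <- p$W[r, , drop = FALSE]
      hh <- p$E[h, , drop = FALSE]; tt_ <- p$E[t, , drop = FALSE]
      hp <- hh - rowSums(w * hh) * w
      tp <- tt_ - rowSums(w * tt_) * w
      -row_norm(hp + p$R[r, , drop = FALSE] - tp, np)
    },
    transr = {
      d <- matrix(0, n, model$dim)
      for (rr in unique(r)) {
        ix <- which(r == rr)
        M <- p$M[, , rr]
        d[ix, ] <- p$E[h[ix], , drop = FALSE] %*% M +
          p$R[rep(rr, length(ix)), , drop = FALSE] -
          p$E[t[ix], , drop = FALSE] %*% M
      }
      -row_norm(d, np)
    },
    transd = {
      hh <- p$E[h, , drop = FALSE]; tt_ <- p$E[t, , drop = FALSE]
      hp_ <- p$Ep[h, , drop = FALSE]; tp_ <- p$Ep[t, , drop = FALSE]
      rp <- p$Rp[r, , drop = FALSE]
      hproj <- hh + rowSums(hp_ * hh) * rp
      tproj <- tt_ + rowSums(tp_ * tt_) * rp
      -row_norm(hproj + p$R[r, , drop = FALSE] - tproj, np)
    },
    distmult = rowSums(p$E[h, , drop = FALSE] * p$R[r, , drop = FALSE] *
                         p$E[t, , drop = FALSE]),
    complex = {
      hr <- p$Er[h, , drop = FALSE]; hi <- p$Ei[h, , drop = FALSE]
      rr <- p$Rr[r, , drop = FALSE]; ri <- p$Ri[r, , drop = FALSE]
      tr_ <- p$Er[t, , drop = FALSE]; ti <- p$Ei[t, , drop = FALSE]
      rowSums(hr * rr * tr_ + hi * rr * ti + hr * ri * ti - hi * ri * tr_)
    },
    simple = {
      0.5 * (rowSums(p$Eh[h, , drop = FALSE] * p$R[r, , drop = FALSE] *
                       p$Et[t, , drop = FALSE]) +
             rowSums(p$Eh[t, , drop = FALSE] * p$Rinv[r, , drop = FALSE] *
                       p$Et[h, , drop = FALSE]))
    },
    rotate = {
      cr <- cos(p$Theta[r, , drop = FALSE]); sr <- sin(p$Theta[r, , drop = FALSE])
      hre <- p$Er[h, , drop = FALSE]; him <- p$Ei[h, , drop = FALSE]
      dre <- hre * cr - him * sr - p$Er[t, , drop = FALSE]
      dim_ <- hre * sr + him * cr - p$Ei[t, , drop = FALSE]
      -rowSums(sqrt(dre * dre + dim_ * dim_ + 1e-12))
    })
}

# ds/dtheta for a batch; returns list of (table, ids, grad) contributions.
baseline_grads <- function(model, h, r, t) {
  p <- model$p; np <- model$config$norm
  n <- length(h)
  unit <- function(d) {
    if (np == 1L) sign(d) else d / (row_norm(d, 2L) + 1e-9)
  }
  fam <- model$family
  if (fam == "transe") {
    u <- unit(p$E[h, , drop = FALSE] + p$R[r, , drop = FALSE] -
                p$E[t, , drop = FALSE])
    list(list("E", h, -u), list("E", t, u), list("R", r, -u))
  } else if (fam == "transh") {
    w <- p$W[r, , drop = FALSE]
    hh <- p$E[h, , drop = FALSE]; tt_ <- p$E[t, , drop = FALSE]
    hp <- hh - rowSums(w * hh) * w
    tp <- tt_ - rowSums(w * tt_) * w
    u <- unit(hp + p$R[r, , drop = FALSE] - tp)
    uw <- rowSums(u * w)
    dh <- -(u - uw * w)
    dt <- (u - uw * w)
    dw <- uw * (hh - tt_) + (rowSums(w * hh) - rowSums(w * tt_)) * u
    list(list("E", h, dh), list("E", t, dt), list("R", r, -u),
         list("W", r, dw))
  } else if (fam == "transr") {
    out <- list()
    for (rr in unique(r)) {
      ix <- which(r == rr)
      M <- p$M[, , rr]
      hh <- p$E[h[ix], , drop = FALSE]; tt_ <- p$E[t[ix], , drop = FALSE]
      u <- unit(hh %*% M + p$R[rep(rr, length(ix)), , drop = FALSE] -
                  tt_ %*% M)
      out[[length(out) + 1L]] <- list("E", h[ix], -u %*% t(M))
      out[[length(out) + 1L]] <- list("E", t[ix], u %*% t(M))
      out[[length(out) + 1L]] <- list("R", rep(rr, length(ix)), -u)
      out[[length(out) + 1L]] <- list("M", rr, -crossprod(hh - tt_, u))
    }
    out
  } else if (fam == "transd") {
    hh <- p$E[h, , drop = FALSE]; tt_ <- p$E[t, , drop = FALSE]
    hp_ <- p$Ep[h, , drop = FALSE]; tp_ <- p$Ep[t, , drop = FALSE]
    rp <- p$Rp[r, , drop = FALSE]
    u <- unit(hh + rowSums(hp_ * hh) * rp + p$R[r, , drop = FALSE] -
                tt_ - rowSums(tp_ * tt_) * rp)
    urp <- rowSums(u * rp)
    list(list("E", h, -(u + urp * hp_)),
         list("E", t, u + urp * tp_),
         list("Ep", h, -urp * hh),
         list("Ep", t, urp * tt_),
         list("Rp", r, -(rowSums(hp_ * hh) - rowSums(tp_ * tt_)) * u),
         list("R", r, -u))
  } else if (fam == "distmult") {
    hh <- p$E[h, , drop = FALSE]; rr <- p$R[r, , drop = FALSE]
    tt_ <- p$E[t, , drop = FALSE]
    list(list("E", h, rr * tt_), list("E", t, hh * rr),
         list("R", r, hh * tt_))
  } else if (fam == "complex") {
    hr <- p$Er[h, , drop = FALSE]; hi <- p$Ei[h, , drop = FALSE]
    rr <- p$Rr[r, , drop = FALSE]; ri <- p$Ri[r, , drop = FALSE]
    tr_ <- p$Er[t, , drop = FALSE]; ti <- p$Ei[t, , drop = FALSE]
    list(list("Er", h, rr * tr_ + ri * ti),
         list("Ei", h, rr * ti - ri * tr_),
         list("Rr", r, hr * tr_ + hi * ti),
         list("Ri", r, hr * ti - hi * tr_),
         list("Er", t, hr * rr - hi * ri),
         list("Ei", t, hi * rr + hr * ri))
  } else if (fam == "simple") {
    Hh <- p$Eh[h, , drop = FALSE]; Tt <- p$Et[t, , drop = FALSE]
    Th <- p$Eh[t, , drop = FALSE]; Ht <- p$Et[h, , drop = FALSE]
    rr <- p$R[r, , drop = FALSE]; rv <- p$Rinv[r, , drop = FALSE]
    list(list("Eh", h, 0.5 * rr * Tt), list("Et", t, 0.5 * Hh * rr),
         list("R", r, 0.5 * Hh * Tt),
         list("Eh", t, 0.5 * rv * Ht), list("Et", h, 0.5 * Th * rv),
         list("Rinv", r, 0.5 * Th * Ht))
  } else {  # rotate
    th <- p$Theta[r, , drop = FALSE]
    cr <- cos(th); sr <- sin(th)
    hre <- p$Er[h, , drop = FALSE]; him <- p$Ei[h, , drop = FALSE]
    rot_re <- hre * cr - him * sr
    rot_im <- hre * sr + him * cr
    dre <- rot_re - p$Er[t, , drop = FALSE]
    dim_ <- rot_im - p$Ei[t, , drop = FALSE]
    mod <- sqrt(dre * dre + dim_ * dim_ + 1e-12)
    gre <- -dre / mod; gim <- -dim_ / mod  # ds/dd
    list(list("Er", h, gre * cr + gim * sr),
         list("Ei", h, -gre * sr + gim * cr),
         list("Er", t, -gre), list("Ei", t, -gim),
         list("Theta", r, -gre * rot_im + gim * rot_re))
  }
}

#' Train a baseline model by margin-based ranking with negative sampling
#'
#' Standard regime: each positive triple is paired with a corrupted
#' negative (head or tail replaced by a uniform random entity, probability
#' 1/2 each) and the margin ranking loss
#' `max(0, gamma - s(positive) + s(negative))` is minimized by SGD.
#' Entity embeddings of translational families are renormalized to the
#' unit ball after each epoch; TransH hyperplane normals are kept unit
#' length; RotatE phases are angles, so relation modulus 1 is preserved by
#' construction.
#'
#' @param kg Training [knowledge_graph()].
#' @param family Scoring family, see [scoring_model()].
#' @param config A [baseline_config()].
#' @return A trained `scoring_model`.
#' @export
train_baseline <- function(kg, family, config = baseline_config()) {
  model <- scoring_model(family, kg$entities, kg$schema$relation, config)
  tr <- kg$triples
  if (nrow(tr) == 0L) stop_("no training triples")
  h_all <- match(tr$head, model$entities)
  r_all <- match(tr$relation, model$relations)
  t_all <- match(tr$tail, model$entities)
  Ve <- length(model$entities)
  lr <- config$learning_rate
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(length(h_all))
      for (s in seq(1L, length(perm), by = config$batch_size)) {
        ix <- perm[s:min(s + config$batch_size - 1L, length(perm))]
        h <- h_all[ix]; r <- r_all[ix]; t <- t_all[ix]
        corrupt_head <- runif(length(ix)) < 0.5
        hn <- ifelse(corrupt_head, sample.int(Ve, length(ix), replace = TRUE), h)
        tn <- ifelse(corrupt_head, t, sample.int(Ve, length(ix), replace = TRUE))
        s_pos <- score_triples(model, h, r, t)
        s_neg <- score_triples(model, hn, r, tn)
        act <- which(config$margin - s_pos + s_neg > 0)
        if (!length(act)) next
        # dL/ds_pos = -1, dL/ds_neg = +1 on the active pairs
        for (sgn in c(-1, 1)) {
          if (sgn < 0) { gh <- h[act]; gt <- t[act] }
          else { gh <- hn[act]; gt <- tn[act] }
          for (gr in baseline_grads(model, gh, r[act], gt)) {
            tab <- gr[[1L]]; ids <- gr[[2L]]; gmat <- gr[[3L]]
            if (tab == "M") {
              model$p$M[, , ids] <- model$p$M[, , ids] - lr * sgn * gmat
            } else {
              upd <- rowsum(sgn * gmat, ids)
              uix <- as.integer(rownames(upd))
              model$p[[tab]][uix, ] <- model$p[[tab]][uix, ] - lr * upd
            }
          }
        }
      }
      # norm constraints
      if (model$family %in% c("transe", "transh", "transr", "transd")) {
        nr <- sqrt(rowSums(model$p$E^2))
        over <- nr > 1
        if (any(over)) model$p$E[over, ] <- model$p$E[over, ] / nr[over]
      }
      if (model$family == "transh") {
        model$p$W <- model$p$W / sqrt(rowSums(model$p$W^2))
      }
    }
  })
  model
}

#' @export
score_queries.scoring_model <- function(model, heads, relations, tails,
                                        direction) {
  Ve <- length(model$entities)
  nq <- length(relations)
  out <- matrix(0, nq, Ve)
  all_e <- seq_len(Ve)
  h_id <- match(heads, model$entities)
  r_id <- match(relations, model$relations)
  t_id <- match(tails, model$entities)
  for (i in seq_len(nq)) {
    out[i, ] <- if (direction == "tail") {
      score_triples(model, rep(h_id[i], Ve), rep(r_id[i], Ve), all_e)
    } else {
      score_triples(model, all_e, rep(r_id[i], Ve), rep(t_id[i], Ve))
    }
  }
  out
}
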