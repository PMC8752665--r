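# Multi-task discriminator: shared embedding -> Bi-GRU || CNN -> shared MLP
# (hard parameter sharing) -> task heads for temporal class (softmax-3),
# emotion class (softmax-4) and emotion intensity (sigmoid regression).
#
# Implemented directly with batched matrix ops and analytic gradients
# (rmsprop), so training is deterministic given the seed.

PAD_IDX <- 1L
UNK_IDX <- 2L

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

#' Multi-task model configuration
#'
#' Defaults follow the tuned training regime: batch size 64, 100 epochs,
#' categorical cross-entropy, rmsprop, convolution filter width 7, dropout
#' 0.2, 200-dimensional embeddings. Encoder widths (recurrent units,
#' convolution filters, shared MLP units) are desk-scale defaults and freely
#' configurable.
#'
#' @param embedding_dim embedding dimension (default 200).
#' @param recurrent_units GRU hidden size per direction.
#' @param conv_filters number of convolution filters.
#' @param conv_filter_size convolution window width (default 7).
#' @param shared_mlp_units width of the shared MLP layer (the hard-shared
#'   representation) and of each task's private dense layer.
#' @param dropout dropout rate on the encoder output, in [0, 1).
#' @param word_dropout probability of replacing an input token with the
#'   unknown token during training (never at prediction). Regularises the
#'   task heads against extrapolating through features of the other task when
#'   a tweet lacks cues for their own: occasionally hiding the informative
#'   tokens teaches the heads that cue-absence means uncertainty.
#' @param batch_size mini-batch size (shrinks to the dataset size with a
#'   warning when a task has fewer examples).
#' @param epochs training epochs.
#' @param optimizer only \code{"rmsprop"} is implemented.
#' @param learning_rate rmsprop step size.
#' @param max_len maximum token sequence length; longer tweets are truncated
#'   from the right.
#' @param seed integer seed controlling initialisation, shuffling and dropout.
#' @param val_fraction held-out fraction per task used to select the best
#'   epoch by validation loss.
#' @return a \code{multitask_config} list.
#' @export
multitask_config <- function(embedding_dim = 200L, recurrent_units = 32L,
                             conv_filters = 32L, conv_filter_size = 7L,
                             shared_mlp_units = 32L, dropout = 0.2,
                             word_dropout = 0.1,
                             batch_size = 64L, epochs = 100L,
                             optimizer = "rmsprop", learning_rate = 1e-3,
                             max_len = 50L, seed = 1L, val_fraction = 0.1) {
  stopifnot(dropout >= 0, dropout < 1, word_dropout >= 0, word_dropout < 1,
            embedding_dim >= 1, recurrent_units >= 1, conv_filters >= 1,
            conv_filter_size >= 1, shared_mlp_units >= 1, batch_size >= 1,
            epochs >= 1, max_len >= 1)
  if (!identical(optimizer, "rmsprop"))
    stop("only the rmsprop optimizer is implemented")
  structure(list(embedding_dim = as.integer(embedding_dim),
                 recurrent_units = as.integer(recurrent_units),
                 conv_filters = as.integer(conv_filters),
                 conv_filter_size = as.integer(conv_filter_size),
                 shared_mlp_units = as.integer(shared_mlp_units),
                 dropout = dropout, word_dropout = word_dropout,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 learning_rate = learning_rate, max_len = as.integer(max_len),
                 seed = as.integer(seed), val_fraction = val_fraction),
            class = "multitask_config")
}

#' Build a vocabulary from token sequences
#' @param token_lists list of token vectors.
#' @param min_count minimum token frequency.
#' @return character vector starting with the pad and unknown placeholders.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  tab <- table(unlist(token_lists, use.names = FALSE))
  words <- sort(names(tab)[tab >= min_count])
  words <- setdiff(words, c("<pad>", "<unk>"))
  c("<pad>", "<unk>", words)
}

tokens_to_idx <- function(tokens, vocab_map) {
  idx <- unname(vocab_map[tokens])
  idx[is.na(idx)] <- UNK_IDX
  as.integer(idx)
}

#' Build the embedding table for a vocabulary
#'
#' Rows for tokens present in a word-vector file are copied; out-of-vocabulary
#' rows (including the unknown token) are drawn from seeded small-variance
#' noise; the pad row is zero and stays zero during training. When no file is
#' given the whole table is seeded noise (test mode).
#'
#' @param vocab character vector from [build_vocab()].
#' @param dim embedding dimension.
#' @param path optional word-vector file in the plain-text dialect.
#' @param seed integer seed for the noise rows.
#' @return numeric matrix length(vocab) x dim with vocab row names.
#' @export
load_word_vectors <- function(vocab, dim, path = NULL, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  E <- matrix(stats::rnorm(length(vocab) * dim, 0, 0.1), length(vocab), dim)
  rownames(E) <- vocab
  if (!is.null(path)) {
    wv <- read_word_vectors(path, vocab = vocab)
    if (ncol(wv) && ncol(wv) != dim)
      stop("word-vector file has dimension ", ncol(wv), ", expected ", dim)
    hit <- intersect(rownames(wv), vocab)
    E[hit, ] <- wv[hit, , drop = FALSE]
  }
  E[PAD_IDX, ] <- 0
  E
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- parameter initialisation ------------------------------------------

init_params <- function(cfg, vocab, embeddings = NULL) {
  D <- cfg$embedding_dim; H <- cfg$recurrent_units
  Fn <- cfg$conv_filters; k <- cfg$conv_filter_size; U <- cfg$shared_mlp_units
  p <- list()
  if (is.null(embeddings)) {
    p$E <- matrix(stats::rnorm(length(vocab) * D, 0, 0.1), length(vocab), D)
    p$E[PAD_IDX, ] <- 0
  } else {
    stopifnot(nrow(embeddings) == length(vocab), ncol(embeddings) == D)
    p$E <- unname(embeddings)
  }
  for (dir in c("f", "b")) {
    for (g in c("z", "r", "h")) {
      p[[paste0(dir, ".W", g)]] <- glorot(D, H)
      p[[paste0(dir, ".U", g)]] <- glorot(H, H)
      p[[paste0(dir, ".b", g)]] <- numeric(H)
    }
  }
  p$C.W <- glorot(k * D, Fn); p$C.b <- numeric(Fn)
  p$S.W <- glorot(2 * H + Fn, U); p$S.b <- numeric(U)
  p$Td.W <- glorot(U, U); p$Td.b <- numeric(U)
  p$To.W <- glorot(U, 3); p$To.b <- numeric(3)
  p$Ed.W <- glorot(U, U); p$Ed.b <- numeric(U)
  p$Eo.W <- glorot(U, 4); p$Eo.b <- numeric(4)
  p$I.w <- glorot(U, 1); p$I.b <- 0
  p
}

zero_like <- function(p) lapply(p, function(x) x * 0)

# ---- batch preparation --------------------------------------------------

prepare_batch <- function(token_idx_list, k, max_len) {
  seqs <- lapply(token_idx_list, function(s) utils::head(s, max_len))
  len <- lengths(seqs)
  Tm <- max(max(len, 1L), k)
  B <- length(seqs)
  idxf <- matrix(PAD_IDX, B, Tm)
  idxb <- matrix(PAD_IDX, B, Tm)
  for (i in seq_len(B)) if (len[i] > 0) {
    idxf[i, seq_len(len[i])] <- seqs[[i]]
    idxb[i, seq_len(len[i])] <- rev(seqs[[i]])
  }
  mask <- outer(len, seq_len(Tm), `>=`) * 1
  list(idxf = idxf, idxb = idxb, mask = mask, B = B, Tm = Tm)
}

# ---- GRU ----------------------------------------------------------------

gru_forward <- function(X, mask, p, dir) {
  Wz <- p[[paste0(dir, ".Wz")]]; Uz <- p[[paste0(dir, ".Uz")]]; bz <- p[[paste0(dir, ".bz")]]
  Wr <- p[[paste0(dir, ".Wr")]]; Ur <- p[[paste0(dir, ".Ur")]]; br <- p[[paste0(dir, ".br")]]
  Wh <- p[[paste0(dir, ".Wh")]]; Uh <- p[[paste0(dir, ".Uh")]]; bh <- p[[paste0(dir, ".bh")]]
  Tm <- length(X); B <- nrow(X[[1]]); H <- ncol(Wz)
  Hc <- matrix(0, B, H)
  zs <- rs <- hhs <- Hprevs <- vector("list", Tm)
  for (t in seq_len(Tm)) {
    m <- mask[, t]
    z <- sigmoid(sweep(X[[t]] %*% Wz + Hc %*% Uz, 2, bz, `+`))
    r <- sigmoid(sweep(X[[t]] %*% Wr + Hc %*% Ur, 2, br, `+`))
    hh <- tanh(sweep(X[[t]] %*% Wh + (r * Hc) %*% Uh, 2, bh, `+`))
    Hnew <- (1 - z) * Hc + z * hh
    zs[[t]] <- z; rs[[t]] <- r; hhs[[t]] <- hh; Hprevs[[t]] <- Hc
    Hc <- m * Hnew + (1 - m) * Hc
  }
  list(H = Hc, cache = list(X = X, mask = mask, zs = zs, rs = rs,
                            hhs = hhs, Hprevs = Hprevs, dir = dir))
}

gru_backward <- function(dH, cache, p) {
  dir <- cache$dir
  Wz <- p[[paste0(dir, ".Wz")]]; Uz <- p[[paste0(dir, ".Uz")]]
  Wr <- p[[paste0(dir, ".Wr")]]; Ur <- p[[paste0(dir, ".Ur")]]
  Wh <- p[[paste0(dir, ".Wh")]]; Uh <- p[[paste0(dir, ".Uh")]]
  X <- cache$X; mask <- cache$mask
  Tm <- length(X)
  g <- list()
  for (nm in c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh"))
    g[[paste0(dir, ".", nm)]] <- p[[paste0(dir, ".", nm)]] * 0
  dX <- vector("list", Tm)
  for (t in rev(seq_len(Tm))) {
    m <- mask[, t]
    z <- cache$zs[[t]]; r <- cache$rs[[t]]; hh <- cache$hhs[[t]]
    Hprev <- cache$Hprevs[[t]]
    dHact <- dH * m           # gradient for rows active at this step
    dHpass <- dH * (1 - m)    # masked rows carry state through unchanged
    dz <- dHact * (hh - Hprev)
    dhh <- dHact * z
    dHprev <- dHact * (1 - z)
    dhh_pre <- dhh * (1 - hh^2)
    drH <- dhh_pre %*% t(Uh)
    dr <- drH * Hprev
    dHprev <- dHprev + drH * r
    dr_pre <- dr * r * (1 - r)
    dz_pre <- dz * z * (1 - z)
    g[[paste0(dir, ".Wh")]] <- g[[paste0(dir, ".Wh")]] + t(X[[t]]) %*% dhh_pre
    g[[paste0(dir, ".Uh")]] <- g[[paste0(dir, ".Uh")]] + t(r * Hprev) %*% dhh_pre
    g[[paste0(dir, ".bh")]] <- g[[paste0(dir, ".bh")]] + colSums(dhh_pre)
    g[[paste0(dir, ".Wr")]] <- g[[paste0(dir, ".Wr")]] + t(X[[t]]) %*% dr_pre
    g[[paste0(dir, ".Ur")]] <- g[[paste0(dir, ".Ur")]] + t(Hprev) %*% dr_pre
    g[[paste0(dir, ".br")]] <- g[[paste0(dir, ".br")]] + colSums(dr_pre)
    g[[paste0(dir, ".Wz")]] <- g[[paste0(dir, ".Wz")]] + t(X[[t]]) %*% dz_pre
    g[[paste0(dir, ".Uz")]] <- g[[paste0(dir, ".Uz")]] + t(Hprev) %*% dz_pre
    g[[paste0(dir, ".bz")]] <- g[[paste0(dir, ".bz")]] + colSums(dz_pre)
    dX[[t]] <- dhh_pre %*% t(Wh) + dr_pre %*% t(Wr) + dz_pre %*% t(Wz)
    dHprev <- dHprev + dr_pre %*% t(Ur) + dz_pre %*% t(Uz)
    dH <- dHprev + dHpass
  }
  list(grads = g, dX = dX)
}

# ---- CNN with global max pooling ---------------------------------------

conv_forward <- function(X, p, k) {
  Tm <- length(X); B <- nrow(X[[1]]); Fn <- ncol(p$C.W)
  D <- ncol(X[[1]])
  P <- Tm - k + 1L
  Zs <- vector("list", P)
  pool <- matrix(-Inf, B, Fn); arg <- matrix(1L, B, Fn)
  for (t in seq_len(P)) {
    Z <- matrix(rep(p$C.b, each = B), B, Fn)
    for (j in seq_len(k))
      Z <- Z + X[[t + j - 1L]] %*% p$C.W[((j - 1L) * D + 1L):(j * D), , drop = FALSE]
    A <- relu(Z)
    upd <- A > pool
    pool[upd] <- A[upd]; arg[upd] <- t
    Zs[[t]] <- Z
  }
  list(pool = pool, cache = list(X = X, Zs = Zs, arg = arg, k = k, D = D))
}

conv_backward <- function(dPool, cache, p) {
  X <- cache$X; Zs <- cache$Zs; arg <- cache$arg; k <- cache$k; D <- cache$D
  dW <- p$C.W * 0; db <- p$C.b * 0
  dX <- lapply(X, function(x) x * 0)
  for (t in seq_along(Zs)) {
    sel <- (arg == t) & (Zs[[t]] > 0)
    if (!any(sel)) next
    dZ <- dPool * sel
    db <- db + colSums(dZ)
    for (j in seq_len(k)) {
      rows <- ((j - 1L) * D + 1L):(j * D)
      dW[rows, ] <- dW[rows, ] + t(X[[t + j - 1L]]) %*% dZ
      dX[[t + j - 1L]] <- dX[[t + j - 1L]] + dZ %*% t(p$C.W[rows, , drop = FALSE])
    }
  }
  list(C.W = dW, C.b = db, dX = dX)
}

# ---- full forward / backward -------------------------------------------

embed_batch <- function(idx, E) {
  lapply(seq_len(ncol(idx)), function(t) E[idx[, t], , drop = FALSE])
}

#' Encode a batch of token sequences into the shared representation
#'
#' Runs the shared encoder: embeddings into forward and backward GRUs
#' (final states) and a max-pooled convolution branch, concatenated and passed
#' through the shared MLP. Exposed for inspection and testing; dropout is off.
#'
#' @param model a trained \code{multitask_model} (or a list with
#'   \code{params}, \code{cfg}, \code{vocab_map}).
#' @param token_lists list of token character vectors.
#' @return numeric matrix, one row per sequence, \code{shared_mlp_units} cols.
#' @export
encode_batch <- function(model, token_lists) {
  if (!length(token_lists)) stop("empty batch")
  idx <- lapply(token_lists, tokens_to_idx, vocab_map = model$vocab_map)
  fw <- forward_shared(idx, model$params, model$cfg, dropout_mask = NULL)
  fw$s
}

forward_shared <- function(token_idx_list, p, cfg, dropout_mask = NULL) {
  bp <- prepare_batch(token_idx_list, cfg$conv_filter_size, cfg$max_len)
  Xf <- embed_batch(bp$idxf, p$E)
  Xb <- embed_batch(bp$idxb, p$E)
  f <- gru_forward(Xf, bp$mask, p, "f")
  b <- gru_forward(Xb, bp$mask, p, "b")
  cv <- conv_forward(Xf, p, cfg$conv_filter_size)
  concat <- cbind(f$H, b$H, cv$pool)
  concat_d <- if (is.null(dropout_mask)) concat else concat * dropout_mask
  S_pre <- sweep(concat_d %*% p$S.W, 2, p$S.b, `+`)
  s <- relu(S_pre)
  list(s = s, cache = list(bp = bp, f = f, b = b, cv = cv, concat = concat,
                           concat_d = concat_d, S_pre = S_pre,
                           dropout_mask = dropout_mask))
}

backward_shared <- function(ds, fw, p, cfg) {
  ca <- fw$cache
  H <- cfg$recurrent_units; Fn <- cfg$conv_filters
  dS_pre <- ds * (ca$S_pre > 0)
  g <- list(S.W = t(ca$concat_d) %*% dS_pre, S.b = colSums(dS_pre))
  dconcat <- dS_pre %*% t(p$S.W)
  if (!is.null(ca$dropout_mask)) dconcat <- dconcat * ca$dropout_mask
  dHf <- dconcat[, 1:H, drop = FALSE]
  dHb <- dconcat[, (H + 1):(2 * H), drop = FALSE]
  dPool <- dconcat[, (2 * H + 1):(2 * H + Fn), drop = FALSE]
  gf <- gru_backward(dHf, ca$f$cache, p)
  gb <- gru_backward(dHb, ca$b$cache, p)
  gc <- conv_backward(dPool, ca$cv$cache, p)
  g <- c(g, gf$grads, gb$grads, list(C.W = gc$C.W, C.b = gc$C.b))
  # embedding gradient: forward-direction inputs feed the forward GRU and the
  # CNN, backward-direction inputs feed the backward GRU
  dE <- p$E * 0
  dXf <- Map(`+`, gf$dX, gc$dX)
  dE <- accumulate_embedding(dE, ca$bp$idxf, dXf)
  dE <- accumulate_embedding(dE, ca$bp$idxb, gb$dX)
  dE[PAD_IDX, ] <- 0
  g$E <- dE
  g
}

accumulate_embedding <- function(dE, idxmat, dXlist) {
  allg <- do.call(rbind, dXlist)
  alli <- as.vector(idxmat)
  rs <- rowsum(allg, group = alli)
  ids <- as.integer(rownames(rs))
  dE[ids, ] <- dE[ids, , drop = FALSE] + rs
  dE
}

head_forward <- function(s, p, task) {
  if (task == "temporal") {
    h_pre <- sweep(s %*% p$Td.W, 2, p$Td.b, `+`)
    h <- relu(h_pre)
    logits <- sweep(h %*% p$To.W, 2, p$To.b, `+`)
    list(h_pre = h_pre, h = h, logits = logits, probs = softmax_rows(logits))
  } else {
    h_pre <- sweep(s %*% p$Ed.W, 2, p$Ed.b, `+`)
    h <- relu(h_pre)
    logits <- sweep(h %*% p$Eo.W, 2, p$Eo.b, `+`)
    ipre <- drop(h %*% p$I.w) + p$I.b
    list(h_pre = h_pre, h = h, logits = logits, probs = softmax_rows(logits),
         intensity = sigmoid(ipre), ipre = ipre)
  }
}

# cross-entropy + (for the emotion task) squared-error intensity loss,
# with gradients wrt the shared representation and the head parameters
head_loss_backward <- function(s, hf, p, task, y, intensity_target = NULL) {
  B <- nrow(s)
  K <- ncol(hf$probs)
  Y1 <- matrix(0, B, K); Y1[cbind(seq_len(B), y)] <- 1
  ce <- -mean(log(pmax(hf$probs[cbind(seq_len(B), y)], 1e-12)))
  dlogits <- (hf$probs - Y1) / B
  g <- list()
  if (task == "temporal") {
    g$To.W <- t(hf$h) %*% dlogits; g$To.b <- colSums(dlogits)
    dh <- dlogits %*% t(p$To.W)
    loss <- ce
  } else {
    g$Eo.W <- t(hf$h) %*% dlogits; g$Eo.b <- colSums(dlogits)
    dh <- dlogits %*% t(p$Eo.W)
    mse <- mean((hf$intensity - intensity_target)^2)
    dint <- 2 * (hf$intensity - intensity_target) / B
    dipre <- dint * hf$intensity * (1 - hf$intensity)
    g$I.w <- t(hf$h) %*% matrix(dipre, ncol = 1); g$I.b <- sum(dipre)
    dh <- dh + matrix(dipre, ncol = 1) %*% t(p$I.w)
    loss <- ce + mse
  }
  dh_pre <- dh * (hf$h_pre > 0)
  if (task == "temporal") {
    g$Td.W <- t(s) %*% dh_pre; g$Td.b <- colSums(dh_pre)
    ds <- dh_pre %*% t(p$Td.W)
  } else {
    g$Ed.W <- t(s) %*% dh_pre; g$Ed.b <- colSums(dh_pre)
    ds <- dh_pre %*% t(p$Ed.W)
  }
  list(loss = loss, ce = ce, grads = g, ds = ds)
}

rmsprop_update <- function(p, g, cache, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(g)) {
    if (is.null(cache[[nm]])) cache[[nm]] <- g[[nm]] * 0
    cache[[nm]] <- rho * cache[[nm]] + (1 - rho) * g[[nm]]^2
    p[[nm]] <- p[[nm]] - lr * g[[nm]] / (sqrt(cache[[nm]]) + eps)
  }
  list(p = p, cache = cache)
}

# ---- training -----------------------------------------------------------

as_task_data <- function(x) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "data.frame")) {
    out <- list(tokens = x$tokens)
    if (!is.null(x$label)) out$label <- x$label
    if (!is.null(x$emotion)) out$emotion <- x$emotion
    if (!is.null(x$intensity)) out$intensity <- x$intensity
    x <- out
  }
  stopifnot(is.list(x$tokens))
  if (!is.null(x$label) && is.character(x$label)) x$label <- temporal_code(x$label)
  if (!is.null(x$emotion) && is.character(x$emotion))
    x$emotion <- match(x$emotion, EMOTION_CLASSES)
  x
}

eval_task_loss <- function(p, cfg, idx_list, y, task, intensity = NULL) {
  if (!length(idx_list)) return(NA_real_)
  fw <- forward_shared(idx_list, p, cfg, dropout_mask = NULL)
  hf <- head_forward(fw$s, p, task)
  B <- length(y)
  ce <- -mean(log(pmax(hf$probs[cbind(seq_len(B), y)], 1e-12)))
  if (task == "emotion") ce + mean((hf$intensity - intensity)^2) else ce
}

#' Train the multi-task discriminator
#'
#' Alternates one mini-batch per task (temporal classification; emotion
#' classification + intensity regression), updating the shared encoder with
#' every batch and the active task's head — hard parameter sharing.
#' Classification losses are categorical cross-entropy; intensity uses squared
#' error added to the emotion-batch loss with equal weight. Ten percent of
#' each task's data (configurable) is held out; the returned model carries the
#' parameters of the epoch with the best summed validation loss. With
#' \code{emotion_data = NULL} the same encoder trains with only the temporal
#' head — the single-task ablation.
#'
#' @param temporal_data tweet tokens + temporal labels: a data frame with a
#'   \code{tokens} list-column and \code{label}, or \code{list(tokens, label)}.
#'   Labels are class names or codes 1..3.
#' @param emotion_data tokens + \code{emotion} (names or codes 1..4) +
#'   \code{intensity} in [0,1]; or NULL for the single-task ablation.
#' @param config a [multitask_config()].
#' @param embeddings optional pre-built embedding matrix (rows = vocab), e.g.
#'   from [load_word_vectors()]; when NULL a seeded random table is used.
#' @param vocab optional fixed vocabulary; default is built from the training
#'   tokens.
#' @return a \code{multitask_model}: parameters, config, vocab, loss history.
#' @export
train_multitask <- function(temporal_data, emotion_data = NULL, config = multitask_config(),
                            embeddings = NULL, vocab = NULL) {
  td <- as_task_data(temporal_data)
  ed <- as_task_data(emotion_data)
  if (is.null(td) && is.null(ed)) stop("at least one task dataset required")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  all_tokens <- c(if (!is.null(td)) td$tokens, if (!is.null(ed)) ed$tokens)
  if (is.null(vocab)) vocab <- build_vocab(all_tokens)
  vocab_map <- stats::setNames(seq_along(vocab), vocab)
  p <- init_params(config, vocab, embeddings)
  opt_cache <- list()

  prep_task <- function(dat, task) {
    if (is.null(dat)) return(NULL)
    n <- length(dat$tokens)
    if (n < 1) stop(task, " dataset is empty")
    idx <- lapply(dat$tokens, tokens_to_idx, vocab_map = vocab_map)
    y <- if (task == "temporal") as.integer(dat$label) else as.integer(dat$emotion)
    intensity <- if (task == "emotion") as.numeric(dat$intensity) else NULL
    n_val <- floor(n * config$val_fraction)
    val <- if (n_val >= 1) sample.int(n, n_val) else integer(0)
    tr <- setdiff(seq_len(n), val)
    bs <- config$batch_size
    if (bs > length(tr)) {
      warning("batch size ", bs, " exceeds ", task, " training size ",
              length(tr), "; shrinking", call. = FALSE)
      bs <- length(tr)
    }
    list(idx = idx, y = y, intensity = intensity, tr = tr, val = val,
         bs = bs, task = task)
  }
  tasks <- Filter(Negate(is.null), list(prep_task(td, "temporal"),
                                        prep_task(ed, "emotion")))

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, p = p, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    orders <- lapply(tasks, function(tk) sample(tk$tr))
    nb <- vapply(seq_along(tasks), function(i)
      ceiling(length(orders[[i]]) / tasks[[i]]$bs), numeric(1))
    steps <- max(nb)
    epoch_loss <- 0; n_steps <- 0
    dmask_dim <- 2 * config$recurrent_units + config$conv_filters
    for (s_i in seq_len(steps)) {
      for (ti in seq_along(tasks)) {
        tk <- tasks[[ti]]
        b_i <- ((s_i - 1L) %% nb[ti])  # cycle the shorter task
        sel <- orders[[ti]][(b_i * tk$bs + 1L):min((b_i + 1L) * tk$bs,
                                                   length(orders[[ti]]))]
        bidx <- tk$idx[sel]
        if (config$word_dropout > 0) {
          bidx <- lapply(bidx, function(s) {
            if (!length(s)) return(s)
            s[stats::runif(length(s)) < config$word_dropout] <- UNK_IDX
            s
          })
        }
        dm <- NULL
        if (config$dropout > 0) {
          dm <- matrix(stats::rbinom(length(sel) * dmask_dim, 1,
                                     1 - config$dropout) / (1 - config$dropout),
                       length(sel), dmask_dim)
        }
        fw <- forward_shared(bidx, p, config, dropout_mask = dm)
        hf <- head_forward(fw$s, p, tk$task)
        hb <- head_loss_backward(fw$s, hf, p, tk$task, tk$y[sel],
                                 tk$intensity[sel])
        g <- c(hb$grads, backward_shared(hb$ds, fw, p, config))
        upd <- rmsprop_update(p, g, opt_cache, config$learning_rate)
        p <- upd$p; opt_cache <- upd$cache
        epoch_loss <- epoch_loss + hb$loss; n_steps <- n_steps + 1
      }
    }
    val_loss <- sum(vapply(tasks, function(tk) {
      use <- if (length(tk$val)) tk$val else tk$tr
      eval_task_loss(p, config, tk$idx[use], tk$y[use], tk$task,
                     tk$intensity[use])
    }, numeric(1)))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = epoch_loss / n_steps,
                                         val_loss = val_loss))
    if (val_loss < best$val) best <- list(val = val_loss, p = p, epoch = epoch)
  }
  structure(list(params = best$p, final_params = p, cfg = config,
                 vocab = vocab, vocab_map = vocab_map, history = history,
                 best_epoch = best$epoch,
                 tasks = vapply(tasks, `[[`, character(1), "task")),
            class = "multitask_model")
}

#' @export
print.multitask_model <- function(x, ...) {
  cat("multitask_model:", paste(x$tasks, collapse = " + "),
      "| vocab", length(x$vocab),
      "| best epoch", x$best_epoch, "of", nrow(x$history), "\n")
  invisible(x)
}

#' Predict temporal orientation, emotion class and intensity
#'
#' @param model a trained \code{multitask_model}.
#' @param corpus a \code{tweet_corpus}, or a list of token vectors.
#' @param batch_size forward-pass batch size.
#' @return data frame with per-tweet temporal probabilities and hard label,
#'   emotion probabilities and hard label, and intensity in [0,1]. Hard labels
#'   break ties by fixed class order (past < present < future;
#'   joy < sadness < anger < fear).
#' @export
predict_multitask <- function(model, corpus, batch_size = 256L) {
  token_lists <- if (inherits(corpus, "data.frame")) corpus$tokens else corpus
  ids <- if (inherits(corpus, "data.frame")) corpus$id else as.character(seq_along(token_lists))
  n <- length(token_lists)
  idx <- lapply(token_lists, tokens_to_idx, vocab_map = model$vocab_map)
  tp <- matrix(NA_real_, n, 3); ep <- matrix(NA_real_, n, 4)
  iv <- numeric(n)
  has_emotion <- "emotion" %in% model$tasks
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    fw <- forward_shared(idx[sel], model$params, model$cfg, dropout_mask = NULL)
    ht <- head_forward(fw$s, model$params, "temporal")
    tp[sel, ] <- ht$probs
    if (has_emotion) {
      he <- head_forward(fw$s, model$params, "emotion")
      ep[sel, ] <- he$probs
      iv[sel] <- he$intensity
    }
  }
  out <- data.frame(id = ids,
                    temporal_hard = max.col(tp, ties.method = "first"),
                    stringsAsFactors = FALSE)
  colnames(tp) <- paste0("p_", TEMPORAL_CLASSES)
  out <- cbind(out, tp)
  out$temporal_label <- TEMPORAL_CLASSES[out$temporal_hard]
  if (has_emotion) {
    out$emotion_hard <- max.col(ep, ties.method = "first")
    colnames(ep) <- paste0("p_", EMOTION_CLASSES)
    out <- cbind(out, ep)
    out$emotion_label <- EMOTION_CLASSES[out$emotion_hard]
    out$intensity <- pmin(pmax(iv, 0), 1)
  }
  out
}

# ---- evaluation ---------------------------------------------------------

#' Classification metrics against gold labels
#' @param pred,gold integer class codes (same coding).
#' @param classes class names indexing the codes.
#' @return list: accuracy, per-class precision/recall/F1, confusion matrix.
#' @export
classification_metrics <- function(pred, gold, classes) {
  K <- length(classes)
  conf <- table(factor(gold, levels = seq_len(K), labels = classes),
                factor(pred, levels = seq_len(K), labels = classes))
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) > 0, tp / colSums(conf), NA_real_)
  rec <- ifelse(rowSums(conf) > 0, tp / rowSums(conf), NA_real_)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  list(accuracy = mean(pred == gold), precision = prec, recall = rec,
       f1 = f1, confusion = conf)
}

#' Evaluate multi-task predictions
#'
#' Classification accuracy, per-class precision/recall/F1 and the confusion
#' matrix for each task present, plus the Pearson correlation between
#' predicted and gold intensity (reported as undefined when the gold
#' intensities have no variance).
#'
#' @param predictions output of [predict_multitask()].
#' @param gold list with any of \code{temporal} (codes or names),
#'   \code{emotion}, \code{intensity}.
#' @return nested list of metrics.
#' @export
evaluate_predictions <- function(predictions, gold) {
  out <- list()
  if (!is.null(gold$temporal)) {
    g <- if (is.character(gold$temporal)) temporal_code(gold$temporal) else gold$temporal
    out$temporal <- classification_metrics(predictions$temporal_hard, g,
                                           TEMPORAL_CLASSES)
  }
  if (!is.null(gold$emotion)) {
    g <- if (is.character(gold$emotion)) match(gold$emotion, EMOTION_CLASSES) else gold$emotion
    out$emotion <- classification_metrics(predictions$emotion_hard, g,
                                          EMOTION_CLASSES)
  }
  if (!is.null(gold$intensity)) {
    if (stats::sd(gold$intensity) == 0 || stats::sd(predictions$intensity) == 0) {
      out$intensity <- list(pearson_r = NA_real_, defined = FALSE)
    } else {
      out$intensity <- list(pearson_r = stats::cor(predictions$intensity,
                                                   gold$intensity),
                            defined = TRUE)
    }
  }
  out
}
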