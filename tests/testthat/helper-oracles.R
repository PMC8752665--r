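# Independent oracles and fixture builders, written naively (explicit loops)
# so they share no code path with the package implementation.

# unnormalised factor score of one label-matrix row for class y
bf_row_score <- function(row, y, w_acc, w_lab, w_corr, S) {
  sc <- 0
  for (q in seq_along(row)) {
    if (row[q] == y) sc <- sc + w_acc[q]
    if (row[q] != 0) sc <- sc + w_lab[q]
  }
  if (NROW(S)) for (i in seq_len(NROW(S)))
    if (row[S[i, 1]] == row[S[i, 2]]) sc <- sc + w_corr[i]
  sc
}

# exact normaliser by enumeration of all (K+1)^L rows x K classes
bf_normalizer <- function(w_acc, w_lab, w_corr, S, L, K) {
  rows <- as.matrix(expand.grid(rep(list(0:K), L)))
  U <- 0
  for (i in seq_len(nrow(rows))) for (y in seq_len(K))
    U <- U + exp(bf_row_score(rows[i, ], y, w_acc, w_lab, w_corr, S))
  U
}

# negative log marginal likelihood by brute-force enumeration over all K^M
# joint latent-label assignments
bf_nll <- function(w_acc, w_lab, w_corr, S, lambda, K = 3) {
  m <- unclass(lambda)
  M <- nrow(m); L <- ncol(m)
  U <- bf_normalizer(w_acc, w_lab, w_corr, S, L, K)
  joints <- as.matrix(expand.grid(rep(list(1:K), M)))
  total <- 0
  for (j in seq_len(nrow(joints))) {
    pr <- 1
    for (p in seq_len(M))
      pr <- pr * exp(bf_row_score(m[p, ], joints[j, p], w_acc, w_lab, w_corr, S)) / U
    total <- total + pr
  }
  -log(total)
}

# posterior over classes for one row, by direct softmax of the scores
bf_posterior_row <- function(row, w_acc, w_lab, w_corr, S, K = 3) {
  sc <- vapply(seq_len(K), function(y)
    bf_row_score(row, y, w_acc, w_lab, w_corr, S), numeric(1))
  e <- exp(sc - max(sc))
  e / sum(e)
}

# majority vote over non-abstain labels; ties and all-abstain rows fall to
# the lowest class code
majority_vote <- function(lambda, K = 3) {
  m <- unclass(lambda)
  apply(m, 1, function(r) {
    r <- r[r != 0]
    if (!length(r)) return(1L)
    tb <- tabulate(r, nbins = K)
    which.max(tb)
  })
}

random_label_matrix <- function(M, L, K = 3, abstain_p = 0.3) {
  m <- matrix(sample(0:K, M * L, replace = TRUE,
                     prob = c(abstain_p, rep((1 - abstain_p) / K, K))), M, L)
  if (all(m == 0)) m[1, 1] <- 1L
  label_matrix(m, num_classes = K)
}

# separable marker-token fixture for the neural net
make_marker_texts <- function(classes, n_per_class, n_markers = 2,
                              filler_n = 30) {
  fillers <- sprintf("filler%02d", seq_len(filler_n))
  texts <- character(0); labels <- character(0)
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      toks <- sample(fillers, sample(5:8, 1), replace = TRUE)
      toks[sample(length(toks), n_markers)] <- sample(marker_tokens(cl), n_markers)
      texts <- c(texts, paste(toks, collapse = " "))
      labels <- c(labels, cl)
    }
  }
  list(texts = texts, labels = labels)
}
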