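# Generative label model: a factor graph over the label matrix Lambda and the
# latent true classes, with three dependency-type factors per labeling
# function -- accuracy 1{Lambda[p,q] == y_p}, labeling propensity
# 1{Lambda[p,q] != 0}, and pairwise correlation 1{Lambda[p,q] == Lambda[p,r]}
# for pairs in the correlation set S. Weights are fit by minimising the exact
# negative log marginal likelihood of the observed label matrix; the
# normaliser is computed exactly over all (K+1)^L possible label-matrix rows
# and K classes (tweets are independent, so the joint factorises row-wise).

#' Construct a correlation set
#'
#' The set S of unordered labeling-function pairs modelled as statistically
#' dependent through a pairwise-agreement factor.
#'
#' @param pairs two-column integer matrix (or data frame) of LF index pairs,
#'   or NULL/empty for no modelled correlations.
#' @param L number of labeling functions (for validation).
#' @return canonical two-column matrix with q < r, class
#'   \code{correlation_set}.
#' @export
correlation_set <- function(pairs = NULL, L = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0) {
    m <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("q", "r")))
    return(structure(m, class = c("correlation_set", "matrix", "array")))
  }
  m <- as.matrix(pairs); storage.mode(m) <- "integer"
  stopifnot(ncol(m) == 2)
  if (any(m[, 1] == m[, 2])) stop("self-pairs are not allowed in S")
  if (!is.null(L) && any(m < 1 | m > L)) stop("pair indices must lie in 1..", L)
  m <- t(apply(m, 1, sort))
  m <- unique(m)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("q", "r"))
  structure(m, class = c("correlation_set", "matrix", "array"))
}

#' Factor features for one label-matrix row and a candidate class
#'
#' Concatenates the three dependency-type indicator blocks: per-LF accuracy
#' \code{1\{row_q == y\}}, per-LF propensity \code{1\{row_q != 0\}}, and, for
#' each pair (q, r) in S, agreement \code{1\{row_q == row_r\}}.
#'
#' @param row integer vector of weak-label codes (0 = abstain).
#' @param y candidate class in 1..K.
#' @param S a [correlation_set()].
#' @return named numeric feature vector of length 2L + |S|.
#' @export
factor_features <- function(row, y, S = correlation_set()) {
  L <- length(row)
  stopifnot(y >= 1)
  acc <- as.numeric(row == y)
  lab <- as.numeric(row != 0)
  corr <- if (nrow(S)) as.numeric(row[S[, 1]] == row[S[, 2]]) else numeric(0)
  names(acc) <- paste0("acc_", seq_len(L))
  names(lab) <- paste0("lab_", seq_len(L))
  if (length(corr)) names(corr) <- paste0("corr_", S[, 1], ":", S[, 2])
  c(acc, lab, corr)
}

#' Construct factor weights
#' @param acc,lab numeric vectors of length L (accuracy and propensity
#'   weights per labeling function).
#' @param corr numeric vector, one weight per pair in \code{S}.
#' @param S a [correlation_set()].
#' @return a \code{factor_weights} object.
#' @export
factor_weights <- function(acc, lab = rep(0, length(acc)), corr = NULL,
                           S = correlation_set()) {
  if (is.null(corr)) corr <- rep(0, nrow(S))
  stopifnot(length(lab) == length(acc), length(corr) == nrow(S),
            all(is.finite(c(acc, lab, corr))))
  structure(list(acc = as.numeric(acc), lab = as.numeric(lab),
                 corr = as.numeric(corr), S = S),
            class = "factor_weights")
}

#' @export
print.factor_weights <- function(x, ...) {
  cat("factor_weights over", length(x$acc), "labeling functions,",
      nrow(x$S), "correlation pair(s)\n")
  cat("  acc:", paste(round(x$acc, 3), collapse = " "), "\n")
  cat("  lab:", paste(round(x$lab, 3), collapse = " "), "\n")
  if (length(x$corr)) cat("  corr:", paste(round(x$corr, 3), collapse = " "), "\n")
  invisible(x)
}

as_weight_vector <- function(w) c(w$acc, w$lab, w$corr)

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# all (K+1)^L label-matrix rows x K classes feature matrix, plus a per-class
# row-block index; used for the exact normaliser
enumerate_features <- function(L, K, S) {
  rows <- as.matrix(expand.grid(rep(list(0:K), L)))
  colnames(rows) <- NULL
  lab <- (rows != 0) * 1
  corr <- if (nrow(S)) {
    sapply(seq_len(nrow(S)), function(i) (rows[, S[i, 1]] == rows[, S[i, 2]]) * 1)
  } else matrix(numeric(0), nrow(rows), 0)
  if (!is.matrix(corr)) corr <- matrix(corr, nrow(rows), nrow(S))
  blocks <- lapply(seq_len(K), function(y) cbind((rows == y) * 1, lab, corr))
  do.call(rbind, blocks)
}

# per-unique-observed-row structures: accuracy features per class, shared
# lab/corr feature part, and multiplicities
observed_features <- function(lambda, K, S) {
  m <- unclass(lambda)
  key <- apply(m, 1, paste, collapse = ",")
  first <- !duplicated(key)
  counts <- as.vector(table(key)[key[first]])
  u <- m[first, , drop = FALSE]
  lab <- (u != 0) * 1
  corr <- if (nrow(S)) {
    sapply(seq_len(nrow(S)), function(i) (u[, S[i, 1]] == u[, S[i, 2]]) * 1)
  } else matrix(numeric(0), nrow(u), 0)
  if (!is.matrix(corr)) corr <- matrix(corr, nrow(u), nrow(S))
  acc <- lapply(seq_len(K), function(y) (u == y) * 1)
  list(u = u, counts = counts, acc = acc, lab = lab, corr = corr, key = key,
       ukey = key[first])
}

check_L <- function(L) {
  if (L > 10) stop("exact normaliser limited to L <= 10 labeling functions (got ",
                   L, ")")
}

#' Exact negative log marginal likelihood of a label matrix
#'
#' \code{-sum_p log sum_y rho(Lambda_p, y)} where
#' \code{rho(row, y) = exp(w . phi(row, y)) / U} and the normaliser U sums
#' \code{exp(w . phi)} over every possible label-matrix row and class. Tweets
#' are independent, so the cost is O(M K L + (K+1)^L K L); L is capped at 10.
#'
#' @param weights a [factor_weights()].
#' @param lambda a [label_matrix()].
#' @param S a [correlation_set()] (defaults to the one in \code{weights}).
#' @return scalar NLL.
#' @export
neg_log_marginal_likelihood <- function(weights, lambda, S = weights$S) {
  L <- ncol(lambda); K <- attr(lambda, "num_classes")
  check_L(L)
  if (!all(is.finite(as_weight_vector(weights)))) stop("weights must be finite")
  Phi <- enumerate_features(L, K, S)
  obs <- observed_features(lambda, K, S)
  nll_from_parts(as_weight_vector(weights), Phi, obs, K)$nll
}

nll_from_parts <- function(w, Phi, obs, K) {
  L <- ncol(obs$u)
  logU <- logsumexp(Phi %*% w)
  w_acc <- w[1:L]; w_rest <- w[-(1:L)]
  base <- drop(cbind(obs$lab, obs$corr) %*% w_rest)
  scores <- sapply(seq_len(K), function(y) drop(obs$acc[[y]] %*% w_acc) + base)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1)
  lse <- apply(scores, 1, logsumexp)
  list(nll = sum(obs$counts * (logU - lse)), scores = scores, logU = logU)
}

nll_grad <- function(w, Phi, obs, K, l2 = 0) {
  L <- ncol(obs$u)
  parts <- nll_from_parts(w, Phi, obs, K)
  M <- sum(obs$counts)
  # model expectation of the features
  sc <- drop(Phi %*% w)
  pm <- exp(sc - logsumexp(sc))
  e_model <- drop(crossprod(Phi, pm))
  # posterior expectation per observed row
  post <- exp(parts$scores - apply(parts$scores, 1, logsumexp))
  acc_post <- Reduce(`+`, lapply(seq_len(K), function(y)
    obs$acc[[y]] * post[, y]))
  e_obs <- c(drop(crossprod(acc_post, obs$counts)),
             drop(crossprod(cbind(obs$lab, obs$corr), obs$counts)))
  g <- M * e_model - e_obs + 2 * l2 * w * M
  list(nll = parts$nll + l2 * sum(w^2) * M, grad = g)
}

#' Fit the generative label model
#'
#' Minimises the exact negative log marginal likelihood by full-batch gradient
#' descent with analytic gradients (model expectation minus posterior-expected
#' observed features) and backtracking line search, so the NLL trace is
#' monotonically non-increasing. Initialisation is all-zero weights;
#' deterministic given the inputs.
#'
#' @param lambda a [label_matrix()].
#' @param S a [correlation_set()] (default empty: conditionally independent
#'   labeling functions).
#' @param learning_rate initial step size on the mean gradient.
#' @param iterations maximum gradient steps.
#' @param l2 optional L2 penalty (per-tweet scale).
#' @param tol stop when the NLL improvement falls below \code{tol}.
#' @return a \code{factor_weights} with attributes \code{trace} (NLL per
#'   accepted iterate) and \code{converged}.
#' @export
fit_generative <- function(lambda, S = correlation_set(),
                           learning_rate = 0.5, iterations = 300L, l2 = 0,
                           tol = 1e-8) {
  L <- ncol(lambda); K <- attr(lambda, "num_classes")
  check_L(L)
  if (all(unclass(lambda) == 0L)) stop("label matrix has no non-abstain entries")
  S <- correlation_set(S, L)
  Phi <- enumerate_features(L, K, S)
  obs <- observed_features(lambda, K, S)
  M <- sum(obs$counts)
  w <- numeric(2 * L + nrow(S))
  cur <- nll_grad(w, Phi, obs, K, l2)
  trace <- cur$nll
  converged <- FALSE
  for (it in seq_len(iterations)) {
    step <- learning_rate
    accepted <- FALSE
    for (half in 1:40) {
      w_new <- w - step * cur$grad / M
      new <- nll_grad(w_new, Phi, obs, K, l2)
      if (is.finite(new$nll) && new$nll <= cur$nll) { accepted <- TRUE; break }
      step <- step / 2
    }
    if (!accepted)
      stop("generative-model optimisation diverged; try a smaller learning_rate")
    improved <- cur$nll - new$nll
    w <- w_new; cur <- new
    trace <- c(trace, cur$nll)
    if (improved < tol) { converged <- TRUE; break }
  }
  out <- factor_weights(acc = w[1:L], lab = w[(L + 1):(2 * L)],
                        corr = if (nrow(S)) w[(2 * L + 1):length(w)] else NULL,
                        S = S)
  names(out$acc) <- names(out$lab) <- colnames(lambda)
  attr(out, "trace") <- trace
  attr(out, "converged") <- converged
  out
}

#' Estimate the correlation structure among labeling functions
#'
#' Agreement-lift selection: a pair (q, r) enters S when its observed
#' exact-agreement rate exceeds the agreement expected under independent
#' per-function output marginals by more than \code{threshold}. Below 20 rows
#' the estimate is unreliable and an empty set is returned with a warning.
#'
#' @param lambda a [label_matrix()].
#' @param threshold agreement-lift margin (default 0.15).
#' @return a [correlation_set()] with attribute \code{lift} (L x L matrix of
#'   observed-minus-expected agreement).
#' @export
estimate_structure <- function(lambda, threshold = 0.15) {
  m <- unclass(lambda); L <- ncol(m); K <- attr(lambda, "num_classes")
  if (nrow(m) < 20) {
    warning("fewer than 20 rows; returning an empty correlation set")
    return(correlation_set())
  }
  if (L < 2) return(correlation_set())
  marg <- sapply(seq_len(L), function(q)
    tabulate(m[, q] + 1L, nbins = K + 1) / nrow(m))
  lift <- matrix(0, L, L, dimnames = list(colnames(m), colnames(m)))
  pairs <- NULL
  for (q in seq_len(L - 1)) for (r in (q + 1):L) {
    obs <- mean(m[, q] == m[, r])
    expe <- sum(marg[, q] * marg[, r])
    lift[q, r] <- lift[r, q] <- obs - expe
    if (obs - expe > threshold) pairs <- rbind(pairs, c(q, r))
  }
  out <- correlation_set(pairs, L)
  attr(out, "lift") <- lift
  out
}

#' Posterior class probabilities from fitted factor weights
#'
#' Row p of the posterior is proportional to \code{exp(w . phi(row_p, y))}
#' over the K classes. Hard labels are the row-wise argmax with ties broken by
#' fixed class order (past < present < future). Rows that abstain everywhere
#' get the uniform posterior and are marked uninformative.
#'
#' @param weights a \code{factor_weights}.
#' @param lambda a [label_matrix()].
#' @param S correlation set (defaults to the one carried by \code{weights}).
#' @return a \code{posterior_labels} list: \code{probs} (M x K, row names =
#'   tweet ids), \code{hard} (codes 1..K), \code{informative} (logical).
#' @export
posterior_labels <- function(weights, lambda, S = weights$S) {
  m <- unclass(lambda); K <- attr(lambda, "num_classes"); L <- ncol(m)
  w_acc <- weights$acc
  base <- drop((m != 0) %*% weights$lab) +
    if (nrow(S)) drop(sapply(seq_len(nrow(S)), function(i)
      (m[, S[i, 1]] == m[, S[i, 2]]) * 1) %*% weights$corr) else 0
  scores <- sapply(seq_len(K), function(y) drop((m == y) %*% w_acc) + base)
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = nrow(m))
  probs <- exp(scores - apply(scores, 1, logsumexp))
  probs <- probs / rowSums(probs)
  rownames(probs) <- rownames(m)
  colnames(probs) <- TEMPORAL_CLASSES[seq_len(K)]
  structure(list(probs = probs,
                 hard = max.col(probs, ties.method = "first"),
                 informative = rowSums(m != 0) > 0),
            class = "posterior_labels")
}

#' @export
print.posterior_labels <- function(x, ...) {
  cat("posterior_labels:", nrow(x$probs), "tweets x", ncol(x$probs),
      "classes;", sum(!x$informative), "all-abstain row(s)\n")
  invisible(x)
}

#' Select a class-balanced probabilistic training set
#'
#' Takes the top n/3 tweets per temporal class, ranked by that class's
#' posterior probability among tweets whose hard label is the class. When n is
#' not divisible by 3 the remainder goes to the earlier classes in fixed order
#' (past, present, future). All-abstain tweets are never selected.
#'
#' @param posterior a [posterior_labels()].
#' @param corpus the matching \code{tweet_corpus} (same order as the label
#'   matrix rows).
#' @param n total number of training tweets.
#' @return data frame of temporal records: id, user_id, text, tokens, label
#'   (class name), confidence (the class posterior), sorted class-wise by
#'   descending confidence.
#' @export
select_balanced_training <- function(posterior, corpus, n) {
  K <- ncol(posterior$probs)
  stopifnot(nrow(posterior$probs) == nrow(corpus))
  per_class <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
  picks <- vector("list", K)
  for (c_i in seq_len(K)) {
    cand <- which(posterior$informative & posterior$hard == c_i)
    if (length(cand) < per_class[c_i]) {
      achievable <- K * min(table(factor(posterior$hard[posterior$informative],
                                         levels = seq_len(K))))
      stop("class '", TEMPORAL_CLASSES[c_i], "' has only ", length(cand),
           " candidates (need ", per_class[c_i],
           "); the largest achievable balanced n is ", achievable)
    }
    ord <- cand[order(-posterior$probs[cand, c_i])]
    sel <- ord[seq_len(per_class[c_i])]
    picks[[c_i]] <- data.frame(row = sel,
                               label = TEMPORAL_CLASSES[c_i],
                               confidence = posterior$probs[sel, c_i],
                               stringsAsFactors = FALSE)
  }
  picks <- do.call(rbind, picks)
  out <- corpus[picks$row, c("id", "user_id", "text"), drop = FALSE]
  out$tokens <- corpus$tokens[picks$row]
  out$label <- picks$label
  out$confidence <- picks$confidence
  rownames(out) <- NULL
  out
}

#' Write / read fitted factor weights as JSON
#' @param weights a \code{factor_weights}.
#' @param path file path.
#' @export
write_factor_weights <- function(weights, path) {
  obj <- list(acc = as.numeric(weights$acc), lab = as.numeric(weights$lab),
              corr = as.numeric(weights$corr),
              pairs = if (nrow(weights$S)) unclass(weights$S)[, , drop = FALSE]
                      else matrix(integer(0), 0, 2),
              lf_names = names(weights$acc))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_factor_weights
#' @export
read_factor_weights <- function(path) {
  obj <- jsonlite::fromJSON(path)
  S <- correlation_set(if (length(obj$pairs)) matrix(unlist(obj$pairs),
                                                     ncol = 2) else NULL)
  w <- factor_weights(obj$acc, obj$lab,
                      if (length(obj$corr)) obj$corr else NULL, S)
  if (!is.null(obj$lf_names)) names(w$acc) <- names(w$lab) <- obj$lf_names
  w
}

#' Write posterior labels as TSV (id, class probabilities, hard label)
#' @param posterior a \code{posterior_labels}.
#' @param path file path.
#' @export
write_posterior <- function(posterior, path) {
  df <- data.frame(id = rownames(posterior$probs), posterior$probs,
                   hard_label = TEMPORAL_CLASSES[posterior$hard],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
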