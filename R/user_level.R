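# User-level measurement: per-user fractions of tweets over temporal classes,
# emotion classes and emotion x intensity-bin cells, and Pearson correlation
# between user-level orientation and emotion measures.

INTENSITY_BINS <- c("VLI", "LI", "MI", "HI")

#' Assign an intensity score to its bin
#'
#' Very Low (\code{score < 0.25}), Low (\code{0.25 <= score < 0.5}),
#' Moderate (\code{0.5 <= score < 0.75}), High (\code{score >= 0.75}).
#' Intervals are half-open on the right as printed; a score of exactly 1
#' falls in HI (the bins otherwise leave a measure-zero gap at 1).
#'
#' @param score numeric vector in [0,1].
#' @return factor with levels VLI, LI, MI, HI.
#' @export
bin_intensity <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1))
    stop("intensity scores must lie in [0,1]")
  cut(score, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf), right = FALSE,
      labels = INTENSITY_BINS)
}

#' Aggregate tweet-level predictions to user-level fractions
#'
#' For each user: the fraction of their tweets in each temporal class
#' (orientation), in each emotion class, and in each emotion x intensity-bin
#' cell (counts over total tweets, so the 4 bin fractions of an emotion sum to
#' that emotion's fraction).
#'
#' @param predictions data frame with columns \code{user_id},
#'   \code{temporal_hard} (codes 1..3 or class names in
#'   \code{temporal_label}), and optionally \code{emotion_hard} /
#'   \code{emotion_label} and \code{intensity}.
#' @param min_tweets users with fewer tweets are dropped (default 1).
#' @return data frame, one row per user: \code{user_id}, \code{n_tweets},
#'   three \code{frac_<orientation>} columns, four \code{frac_<emotion>}
#'   columns and sixteen \code{frac_<emotion>_<bin>} columns.
#' @export
aggregate_users <- function(predictions, min_tweets = 1L) {
  if (is.null(predictions$user_id) || any(is.na(predictions$user_id)))
    stop("every tweet must carry a user_id")
  tcode <- if (!is.null(predictions$temporal_hard)) predictions$temporal_hard
           else temporal_code(predictions$temporal_label)
  ecode <- if (!is.null(predictions$emotion_hard)) predictions$emotion_hard
           else if (!is.null(predictions$emotion_label))
             match(predictions$emotion_label, EMOTION_CLASSES) else NULL
  has_emotion <- !is.null(ecode) && !is.null(predictions$intensity)
  users <- split(seq_len(nrow(predictions)), predictions$user_id)
  rows <- lapply(names(users), function(u) {
    i <- users[[u]]
    n <- length(i)
    if (n < min_tweets) return(NULL)
    ofrac <- tabulate(tcode[i], nbins = 3) / n
    row <- data.frame(user_id = u, n_tweets = n, stringsAsFactors = FALSE)
    row[paste0("frac_", TEMPORAL_CLASSES)] <- as.list(ofrac)
    if (has_emotion) {
      efrac <- tabulate(ecode[i], nbins = 4) / n
      row[paste0("frac_", EMOTION_CLASSES)] <- as.list(efrac)
      bins <- as.integer(bin_intensity(predictions$intensity[i]))
      cell <- table(factor(ecode[i], levels = 1:4),
                    factor(bins, levels = 1:4)) / n
      for (e in 1:4) for (b in 1:4)
        row[[paste0("frac_", EMOTION_CLASSES[e], "_", INTENSITY_BINS[b])]] <-
          as.numeric(cell[e, b])
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no user passed the min_tweets filter")
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two user-level measures
#'
#' Standard Pearson r with a two-sided significance test from the t
#' distribution on n - 2 degrees of freedom. When either field has zero
#' variance the result is flagged undefined rather than raising an error.
#'
#' @param users output of [aggregate_users()].
#' @param x_field,y_field column names (e.g. \code{"frac_future"},
#'   \code{"frac_joy"}).
#' @return list: \code{r}, \code{p_value}, \code{n}, \code{defined}.
#' @export
correlate <- function(users, x_field, y_field) {
  x <- users[[x_field]]; y <- users[[y_field]]
  if (is.null(x) || is.null(y)) stop("unknown field(s): ", x_field, ", ", y_field)
  n <- length(x)
  if (n < 3) stop("need at least 3 users")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Orientation x emotion correlation matrix
#'
#' Pearson r between every user-level temporal-orientation fraction and every
#' emotion fraction (3 x 4) and every emotion x intensity-bin fraction
#' (3 x 16), each with its p-value and a significance flag at \code{alpha}.
#'
#' @param users output of [aggregate_users()].
#' @param alpha significance level (default 0.05).
#' @return data frame of rows (x, y, r, p_value, n, significant).
#' @export
correlation_matrix <- function(users, alpha = 0.05) {
  xs <- paste0("frac_", TEMPORAL_CLASSES)
  ys <- c(paste0("frac_", EMOTION_CLASSES),
          as.vector(outer(EMOTION_CLASSES, INTENSITY_BINS,
                          function(e, b) paste0("frac_", e, "_", b))))
  ys <- intersect(ys, names(users))
  grid <- expand.grid(x = xs, y = ys, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- correlate(users, grid$x[i], grid$y[i])
    data.frame(x = grid$x[i], y = grid$y[i], r = ct$r, p_value = ct$p_value,
               n = ct$n,
               significant = isTRUE(ct$defined) && ct$p_value < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' McNemar's test comparing two paired classifiers
#'
#' A paired-classifier comparison on a shared gold standard: tests whether the
#' two classifiers' error rates differ, from the discordant pairs. (This is
#' the legitimate use of McNemar's test; it does not apply to correlation
#' coefficients.)
#'
#' @param pred_a,pred_b predicted labels from the two classifiers.
#' @param gold gold labels.
#' @return \code{htest} from [stats::mcnemar.test()] on the 2x2
#'   correct/incorrect contingency table.
#' @export
mcnemar_compare <- function(pred_a, pred_b, gold) {
  stopifnot(length(pred_a) == length(gold), length(pred_b) == length(gold))
  a_ok <- pred_a == gold; b_ok <- pred_b == gold
  tab <- table(factor(a_ok, levels = c(TRUE, FALSE)),
               factor(b_ok, levels = c(TRUE, FALSE)))
  stats::mcnemar.test(tab)
}

#' Write user aggregates / correlation report as CSV
#' @param x data frame from [aggregate_users()] or [correlation_matrix()].
#' @param path file path.
#' @export
write_user_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
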