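#' Ensemble annotation confidence from alignment scores
#'
#' Competing subfamily alignments of the same genomic sequence are converted
#' into a probability over subfamilies: treating each score as a scaled
#' base-2 log-odds of homology, the confidence of candidate `i` is
#' \deqn{\mathrm{Conf}(q_i \mid t) = \frac{2^{s_i/\lambda}}{\sum_j 2^{s_j/\lambda}},}
#' i.e. a softmax over scores at temperature `lambda / log(2)`. The random
#' (non-homology) likelihood of `t` cancels in the normalisation, so only
#' scores and `lambda` are needed. Computation subtracts the maximal score
#' first, making the result invariant to adding a constant to all scores and
#' immune to overflow.
#'
#' @param candidates tibble with `subfamily` and `score` columns.
#' @param lambda positive scale relating scores to base-2 log-odds
#'   (see [infer_lambda()]).
#' @return an object of class `confidence_set`: a list with `confidences`
#'   (named numeric, sums to 1), `lambda_used`, `best` (subfamily of maximal
#'   confidence, lexicographic tie-break) and `tie` (TRUE when the two top
#'   scores are equal).
#' @export
confidence <- function(candidates, lambda) {
  if (nrow(candidates) == 0) abort("need at least one candidate")
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0) {
    abort("lambda must be a single positive number")
  }
  s <- candidates$score
  w <- 2^((s - max(s)) / lambda)
  conf <- setNames(w / sum(w), candidates$subfamily)
  ord <- order(-conf, names(conf))
  top <- sort(s, decreasing = TRUE)
  structure(
    list(
      confidences = conf,
      lambda_used = lambda,
      best = names(conf)[ord[1]],
      tie = length(s) > 1L && top[1] == top[2]
    ),
    class = "confidence_set"
  )
}

#' @export
print.confidence_set <- function(x, ...) {
  cat(sprintf("<confidence_set: best = %s (%.4f)%s, lambda = %.4g>\n",
              x$best, x$confidences[[x$best]],
              if (x$tie) ", tied" else "", x$lambda_used))
  invisible(x)
}

#' @rdname confidence
#' @param x a `confidence_set`.
#' @param ... unused.
#' @method tidy confidence_set
#' @export
tidy.confidence_set <- function(x, ...) {
  tibble(
    subfamily = names(x$confidences),
    confidence = unname(x$confidences),
    best = names(x$confidences) == x$best
  ) |>
    arrange(desc(.data$confidence), .data$subfamily)
}

#' @rdname confidence
#' @method glance confidence_set
#' @export
glance.confidence_set <- function(x, ...) {
  tibble(
    best = x$best,
    best_confidence = unname(x$confidences[[x$best]]),
    tie = x$tie,
    lambda_used = x$lambda_used,
    n_candidates = length(x$confidences)
  )
}
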