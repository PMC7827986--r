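#' Infer the Karlin-Altschul scale lambda of a scoring matrix
#'
#' Integer substitution scores are interpreted as scaled log-odds,
#' `score(a,b) = int(lambda * log2(P(a,b) / (P(a) P(b))))`. Summing the
#' implied pair probabilities over the background gives the consistency
#' condition
#' \deqn{\sum_{a,b} p_a p_b \, 2^{s_{ab}/\lambda} = 1,}
#' which has a unique positive root whenever the expected score under the
#' background is negative and at least one score is positive. The root is
#' located by bisection on `1/lambda` to a relative tolerance of `1e-10`.
#'
#' @param matrix a [scoring_matrix].
#' @param background letter frequencies over the matrix alphabet (named or in
#'   alphabet order); defaults to uniform.
#' @return the positive scale `lambda` (for base-2 exponentiation).
#' @export
infer_lambda <- function(matrix, background = NULL) {
  s <- matrix$scores
  k <- length(matrix$alphabet)
  if (is.null(background)) background <- rep(1 / k, k)
  if (!is.null(names(background))) {
    background <- background[matrix$alphabet]
  }
  if (length(background) != k || any(is.na(background)) ||
      any(background < 0) || abs(sum(background) - 1) > 1e-8) {
    abort("background must be letter frequencies summing to 1 over the alphabet")
  }
  w <- outer(background, background)
  if (max(s) <= 0) {
    abort("no valid lambda: the matrix has no positive score")
  }
  if (sum(w * s) >= 0) {
    abort("no valid lambda: expected score under the background is nonnegative")
  }

  f <- function(x) sum(w * 2^(s * x)) - 1   # x = 1/lambda; f(0) = 0, f dips < 0
  hi <- 1e-3
  while (f(hi) < 0) hi <- hi * 2
  lo <- hi / 2
  while (f(lo) > 0) {
    hi <- lo
    lo <- lo / 2
  }
  # bisection on x to relative tolerance 1e-10
  repeat {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / mid < 1e-10) break
  }
  2 / (lo + hi)
}
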