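#' Score a genomic sequence against every subfamily consensus
#'
#' In `positional` mode the score is the gapless sum of substitution-matrix
#' scores at corresponding positions — valid for instances that are
#' positionally aligned to the consensus, which is what the substitution-only
#' simulator emits (sequence and consensus must then be equal length). In
#' `local` mode an affine-gap local alignment (Smith-Waterman) is computed
#' with the matrix's gap penalties, so 5'/3' trimming and indels are allowed.
#'
#' @param instance nucleotide sequence (character scalar).
#' @param library a `subfamily_library` (tibble with `name` and `consensus`).
#' @param matrix a [scoring_matrix].
#' @param mode `"positional"` or `"local"`.
#' @return tibble with one row per subfamily: `subfamily`, `score`.
#' @export
score_candidates <- function(instance, library, matrix,
                             mode = c("positional", "local")) {
  mode <- match.arg(mode)
  if (!is_string(instance) || nchar(instance) == 0) {
    abort("instance must be a non-empty sequence")
  }
  if (nrow(library) == 0) abort("library must be non-empty")
  letters_seen <- unique(seq_chars(instance))
  if (!all(letters_seen %in% matrix$alphabet)) {
    abort(sprintf("instance letters {%s} outside matrix alphabet {%s}",
                  paste(setdiff(letters_seen, matrix$alphabet), collapse = ","),
                  paste(matrix$alphabet, collapse = ",")))
  }
  score <- switch(
    mode,
    positional = {
      ci <- seq_chars(instance)
      vapply(library$consensus, function(cons) {
        cc <- seq_chars(cons)
        if (length(cc) != length(ci)) {
          abort("positional mode requires instance and consensus of equal length")
        }
        sum(matrix$scores[cbind(ci, cc)])
      }, numeric(1), USE.NAMES = FALSE)
    },
    local = {
      vapply(library$consensus, function(cons) {
        Biostrings::pairwiseAlignment(
          instance, cons,
          type = "local",
          substitutionMatrix = matrix$scores,
          gapOpening = matrix$gap_open,
          gapExtension = matrix$gap_extend,
          scoreOnly = TRUE
        )
      }, numeric(1), USE.NAMES = FALSE)
    }
  )
  tibble(subfamily = library$name, score = as.numeric(score))
}

#' Pick the annotation among candidates by highest score
#'
#' The standard adjudication rule: the subfamily of the maximal score wins.
#' Ties are broken deterministically by the lexicographically smallest
#' subfamily name and recorded in the `tie` flag.
#'
#' @param candidates tibble with `subfamily` and `score` columns
#'   (from [score_candidates()]).
#' @return one-row tibble: `subfamily`, `score`, `tie`.
#' @export
annotate_instance <- function(candidates) {
  if (nrow(candidates) == 0) abort("need at least one candidate")
  top <- max(candidates$score)
  at_top <- sort(candidates$subfamily[candidates$score == top])
  tibble(subfamily = at_top[1], score = top, tie = length(at_top) > 1L)
}
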