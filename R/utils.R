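DNA_BASES <- c("A", "C", "G", "T")

# split a sequence string into a character vector of single letters
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

random_dna <- function(n) {
  chars_seq(sample(DNA_BASES, n, replace = TRUE))
}

#' Point-substitute a sequence
#'
#' Each site is independently substituted with probability `rate`; a
#' substituted site is replaced by one of the three other nucleotides with
#' equal probability (Jukes-Cantor-like, single event per site).
#'
#' @param seq character scalar over A/C/G/T.
#' @param rate per-site substitution probability in \[0, 1\].
#' @return list with `seq` (mutated sequence) and `n_sub` (number of
#'   substituted sites).
#' @keywords internal
mutate_seq <- function(seq, rate) {
  ch <- seq_chars(seq)
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) > 0) {
    ch[hit] <- vapply(
      ch[hit],
      function(b) sample(setdiff(DNA_BASES, b), 1L),
      character(1),
      USE.NAMES = FALSE
    )
  }
  list(seq = chars_seq(ch), n_sub = length(hit))
}

# Hamming distance between two equal-length sequences
hamming <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}
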