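# Fixture builders and independent oracles shared across test files.

# Build a subfamily library tibble by hand from explicit consensuses.
toy_library <- function(consensus, name = sprintf("SF%02d", seq_along(consensus)),
                        type_label = "T1", frequency = 1, identity = 0.9,
                        family = "SIM") {
  out <- tibble::tibble(
    name = name,
    type_label = rep_len(type_label, length(consensus)),
    parent = c(NA_character_, name[-length(name)]),
    consensus = consensus,
    frequency = rep_len(frequency, length(consensus)),
    identity = rep_len(identity, length(consensus))
  )
  attr(out, "family") <- family
  class(out) <- c("subfamily_library", class(out))
  out
}

# Write a minimal RepeatMasker .out file: 3 header lines + given body rows.
# Each row is a list/df-row with fields used by the parser.
write_rm_out <- function(path, rows) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  body <- vapply(rows, function(r) {
    paste(r$score, r$div, "0.0", "0.0", r$chrom, r$begin, r$end, "(0)",
          r$strand, r$name, r$class_family, "1", r$end - r$begin + 1, "(0)",
          r$id, sep = "  ")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

rm_row <- function(chrom = "chr1", begin = 101, end = 200, strand = "+",
                   name = "AluSx", class_family = "SINE/Alu",
                   score = 1000, div = 10.0, id = "1") {
  list(chrom = chrom, begin = begin, end = end, strand = strand, name = name,
       class_family = class_family, score = score, div = div, id = id)
}

# A gapless 2-copy segment with TE annotations at given (start, end) pairs.
# rows default to identical random sequence.
toy_segment <- function(len = 400, id = "seg1", row_a = NULL, row_b = NULL) {
  if (is.null(row_a)) {
    row_a <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
  }
  if (is.null(row_b)) row_b <- row_a
  segment_alignment(
    id = id,
    interval_a = list(chrom = paste0(id, "_A"), start = 0L,
                      end = sum(strsplit(row_a, "")[[1]] != "-"),
                      strand = "+"),
    interval_b = list(chrom = paste0(id, "_B"), start = 0L,
                      end = sum(strsplit(row_b, "")[[1]] != "-"),
                      strand = "+"),
    row_a = row_a, row_b = row_b
  )
}

toy_annos <- function(chrom, starts, ends, subfamily, family = "Alu",
                      ambiguous = NULL) {
  te_annotations(
    chrom = chrom, start = starts, end = ends, strand = "+",
    family = family, subfamily = subfamily,
    source_id = sprintf("%s:%d", chrom, starts),
    ambiguous = ambiguous
  )
}

# Exhaustive-enumeration oracle for the subfamily-conversion probability:
# every diagnostic site independently stays (p_a), switches to the
# j-diagnostic base (p_b), or becomes non-informative (p_o); the instance is
# recognised as j when j-agreeing sites outnumber i-agreeing sites (strictly,
# or with ties when strict = FALSE).
enum_conversion_prob <- function(n, p_a, strict = TRUE) {
  if (n == 0) return(0)
  p_b <- (1 - p_a) / 3
  p_o <- 2 * (1 - p_a) / 3
  probs <- c(stay = p_a, to_j = p_b, other = p_o)
  states <- expand.grid(rep(list(1:3), n))
  total <- 0
  for (r in seq_len(nrow(states))) {
    s <- as.integer(states[r, ])
    n_stay <- sum(s == 1); n_j <- sum(s == 2)
    # the all-other outcome never converts (the model's k sum stops at n - 1)
    flip <- if (strict) n_j > n_stay else (n_j >= n_stay && n_stay + n_j > 0)
    if (flip) total <- total + prod(probs[s])
  }
  total
}

# Brute-force gapless local alignment score: best-scoring pair of equal-length
# substrings. Exact oracle for local alignment when gap penalties are too
# high to ever pay off.
brute_local_score <- function(a, b, scores) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- 0
  for (ia in seq_along(ca)) for (ib in seq_along(cb)) {
    run <- 0
    len <- min(length(ca) - ia, length(cb) - ib) + 1
    for (k in seq_len(len)) {
      run <- run + scores[ca[ia + k - 1], cb[ib + k - 1]]
      if (run > best) best <- run
    }
  }
  best
}

# Random background + integer score matrix pair lying on the exact
# Karlin-Altschul lattice for a given lambda0: background frequencies are
# solved on the simplex so that sum_ab p_a p_b 2^(M_ab/lambda0) = 1, making
# the log-odds construction round losslessly.
lattice_matrix <- function(lambda0) {
  ab <- c("A", "C", "G", "T")
  repeat {
    m <- matrix(sample(-8:-3, 16, replace = TRUE), 4, 4,
                dimnames = list(ab, ab))
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- sample(1:2, 4, replace = TRUE)
    # solve for a background with sum_ab p_a p_b 2^(m_ab) = 1 exactly
    h <- function(p) sum(outer(p, p) * 2^m) - 1
    u <- as.vector(stats::rgamma(4, 5)); u <- u / sum(u)
    corner <- as.numeric(seq_len(4) == which.max(diag(m)))
    if (h(u) >= 0) next
    t_star <- stats::uniroot(function(t) h((1 - t) * u + t * corner),
                             c(0, 1 - 1e-9), tol = 1e-14)$root
    p <- (1 - t_star) * u + t_star * corner
    if (all(p > 1e-6)) {
      # scores from the log-odds construction at scale lambda0 are exactly
      # lambda0 * m, so integer rounding is lossless
      return(list(matrix = scoring_matrix(lambda0 * m), background = p,
                  lambda0 = lambda0))
    }
  }
}
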