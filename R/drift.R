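#' Diagnostic sites between two subfamily consensuses
#'
#' The sites that differentiate subfamily `i` from subfamily `j` are the
#' substitution columns of their pairwise alignment. Equal-length consensuses
#' are compared position by position; unequal-length consensuses are first
#' globally aligned (Needleman-Wunsch, affine gaps). Indel columns are never
#' diagnostic: the drift model is substitution-only.
#'
#' @param consensus_i,consensus_j consensus sequences (character scalars).
#' @return tibble with one row per diagnostic site: `pos` (0-based position
#'   on `consensus_i`), `base_i`, `base_j`. The site count `n` is `nrow()`.
#' @export
diagnostic_sites <- function(consensus_i, consensus_j) {
  if (!is_string(consensus_i) || nchar(consensus_i) == 0 ||
      !is_string(consensus_j) || nchar(consensus_j) == 0) {
    abort("consensus sequences must be non-empty")
  }
  if (nchar(consensus_i) == nchar(consensus_j)) {
    ai <- seq_chars(consensus_i)
    aj <- seq_chars(consensus_j)
  } else {
    ab <- c("A", "C", "G", "T", "N")
    sub <- matrix(-1, 5, 5, dimnames = list(ab, ab))
    diag(sub) <- 1
    aln <- Biostrings::pairwiseAlignment(consensus_i, consensus_j,
                                         type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 2, gapExtension = 1)
    ai <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    aj <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  }
  keep <- ai != "-" & aj != "-" & ai != aj
  pos_i <- cumsum(ai != "-") - 1L   # 0-based position on consensus_i
  tibble(pos = pos_i[keep], base_i = ai[keep], base_j = aj[keep])
}

#' Per-site fate probabilities for a diagnostic site
#'
#' After insertion, a site of a subfamily-`i` instance keeps the diagnostic
#' nucleotide with probability `p_a` = P(A_i), the mean identity of instances
#' to their consensus. A mutation hits the site with probability `1 - p_a`
#' and lands uniformly on the three other nucleotides, so the site switches
#' to the nucleotide diagnostic for a specific other subfamily `j` with
#' probability `p_b = (1 - p_a)/3` and to a non-informative *other* value
#' with probability `p_o = 2(1 - p_a)/3`. Conditional on not mutating to an
#' *other* value, the site stays at `i` with probability
#' `p_c = 3 p_a / (1 + 2 p_a)`.
#'
#' @param p_a identity fraction P(A_i) in \[0, 1\].
#' @return one-row tibble: `p_a`, `p_b`, `p_o`, `p_c`.
#' @export
site_change_probs <- function(p_a) {
  check_fraction(p_a, "p_a")
  tibble(
    p_a = p_a,
    p_b = (1 - p_a) / 3,
    p_o = 2 * (1 - p_a) / 3,
    p_c = 3 * p_a / (1 + 2 * p_a)
  )
}

#' Binomial cumulative distribution function
#'
#' `binom_cdf(x, n, p)` is the probability of at most `floor(x)` successes in
#' `n` trials at success probability `p`; `x >= n` gives 1 and `x < 0` gives
#' 0.
#'
#' @param x count threshold (may be fractional; floored).
#' @param n number of trials (>= 0).
#' @param p success probability in \[0, 1\].
#' @return the CDF value.
#' @export
binom_cdf <- function(x, n, p) {
  check_fraction(p, "p")
  if (n < 0) abort("n must be >= 0")
  pbinom(floor(x), size = n, prob = p)
}

#' Probability that point mutations convert subfamily i into subfamily j
#'
#' For an instance inserted in full agreement with subfamily `i` at all `n`
#' sites that differentiate `i` from `j`, the instance comes to look like `j`
#' when some `k` sites mutate to non-informative values and, among the
#' remaining `n - k`, the sites agreeing with `j` outnumber those still
#' agreeing with `i`:
#' \deqn{P(S{:}\,i \to j) = \sum_{k=0}^{n-1} \binom{n}{k} (1-P_O)^{n-k} P_O^{\,k}
#'   \; B\!\left(\left\lfloor \tfrac{n-k-1}{2} \right\rfloor,\; n-k,\; p_c\right)}
#' with \eqn{P_O} and \eqn{p_c} from [site_change_probs()]. `strict = FALSE`
#' relaxes the majority to "at least half" (bound
#' \eqn{\lfloor (n-k)/2 \rfloor}), for sensitivity analysis.
#'
#' @param n number of diagnostic sites (>= 0).
#' @param p_a identity fraction P(A_i).
#' @param strict require strictly more `j`-agreeing than `i`-agreeing sites
#'   (the default); `FALSE` counts exact ties as converted.
#' @return the conversion probability; 0 when `n = 0`.
#' @export
conversion_prob <- function(n, p_a, strict = TRUE) {
  check_fraction(p_a, "p_a")
  if (n < 0) abort("n must be >= 0")
  if (n == 0) return(0)
  pr <- site_change_probs(p_a)
  k <- 0:(n - 1)
  bound <- if (strict) floor((n - k - 1) / 2) else floor((n - k) / 2)
  terms <- choose(n, k) * (1 - pr$p_o)^(n - k) * pr$p_o^k *
    pbinom(bound, size = n - k, prob = pr$p_c)
  sum(terms)
}

#' Pairwise subfamily-conversion matrix
#'
#' Applies [conversion_prob()] to every ordered pair of subfamilies in a
#' library, using the diagnostic-site count from [diagnostic_sites()] and the
#' source subfamily's identity P(A_i). The matrix is generally asymmetric:
#' converting `i` to `j` depends on `i`'s identity.
#'
#' @param library a `subfamily_library` (tibble with `name`, `consensus`,
#'   `type_label`, `frequency`; see [make_subfamily_library()]).
#' @param identities named numeric vector of P(A_i) per subfamily; defaults
#'   to the library's `identity` column.
#' @param strict passed to [conversion_prob()].
#' @return an object of class `drift_matrix`: list with `pairwise` (row =
#'   source `i`, column = target `j`, diagonal 0), `n_sites` (diagnostic-site
#'   counts), `identities`, and `meta` (per-subfamily `name`, `type_label`,
#'   `frequency`).
#' @export
conversion_matrix <- function(library, identities = NULL, strict = TRUE) {
  nm <- library$name
  if (is.null(identities)) {
    identities <- setNames(library$identity, nm)
  }
  missing <- setdiff(nm, names(identities))
  if (length(missing) > 0) {
    abort(sprintf("missing identity for subfamily: %s",
                  paste(missing, collapse = ", ")))
  }
  k <- length(nm)
  n_sites <- matrix(0L, k, k, dimnames = list(nm, nm))
  pairwise <- matrix(0, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      n_sites[i, j] <- nrow(diagnostic_sites(library$consensus[i],
                                             library$consensus[j]))
      pairwise[i, j] <- conversion_prob(n_sites[i, j], identities[[nm[i]]],
                                        strict = strict)
    }
  }
  structure(
    list(
      pairwise = pairwise,
      n_sites = n_sites,
      identities = identities[nm],
      meta = library[, c("name", "type_label", "frequency")]
    ),
    class = "drift_matrix"
  )
}

#' @export
print.drift_matrix <- function(x, ...) {
  cat(sprintf("<drift_matrix over %d subfamilies>\n", nrow(x$pairwise)))
  print(signif(x$pairwise, 3))
  invisible(x)
}

#' @rdname conversion_matrix
#' @param x a `drift_matrix`.
#' @param ... unused.
#' @method tidy drift_matrix
#' @export
tidy.drift_matrix <- function(x, ...) {
  nm <- rownames(x$pairwise)
  grid <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  tibble(
    from = grid$from,
    to = grid$to,
    n_sites = x$n_sites[cbind(grid$from, grid$to)],
    probability = x$pairwise[cbind(grid$from, grid$to)]
  ) |>
    arrange(.data$from, .data$to)
}

#' Aggregate a drift matrix into a type-by-type table
#'
#' For each coarse type (the AluJ/AluS/AluY analogue), the probability of
#' converting into each other type is the frequency-weighted average over
#' source subfamilies of the summed pairwise probabilities into target-type
#' subfamilies. The `combined_mismatch` column sums over all targets
#' regardless of type, i.e. it is the row sum of the type cells.
#'
#' @param matrix a [conversion_matrix()] result.
#' @param frequencies optional named weights per subfamily (defaults to the
#'   library frequencies carried in the matrix).
#' @param type_map optional named character vector `subfamily -> type`
#'   (defaults to the library types).
#' @return tibble with one row per source type: `type`, one `to_<type>`
#'   column per target type, and `combined_mismatch`.
#' @export
aggregate_by_type <- function(matrix, frequencies = NULL, type_map = NULL) {
  nm <- rownames(matrix$pairwise)
  if (is.null(frequencies)) {
    frequencies <- setNames(matrix$meta$frequency, matrix$meta$name)
  }
  if (is.null(type_map)) {
    type_map <- setNames(matrix$meta$type_label, matrix$meta$name)
  }
  missing <- setdiff(nm, names(type_map))
  if (length(missing) > 0) {
    abort(sprintf("subfamily missing from type_map: %s",
                  paste(missing, collapse = ", ")))
  }
  missing_w <- setdiff(nm, names(frequencies))
  if (length(missing_w) > 0) {
    abort(sprintf("subfamily missing from frequencies: %s",
                  paste(missing_w, collapse = ", ")))
  }
  if (any(frequencies[nm] < 0)) abort("frequencies must be nonnegative")
  types <- unique(type_map[nm])
  rows <- lapply(types, function(t1) {
    src <- nm[type_map[nm] == t1]
    w <- frequencies[src]
    if (sum(w) <= 0) {
      abort(sprintf("type '%s' has zero total frequency weight", t1))
    }
    cells <- vapply(types, function(t2) {
      tgt <- nm[type_map[nm] == t2]
      per_src <- vapply(src, function(i) {
        sum(matrix$pairwise[i, setdiff(tgt, i)])
      }, numeric(1))
      sum(w * per_src) / sum(w)
    }, numeric(1))
    out <- c(list(type = t1), as.list(setNames(cells, paste0("to_", types))))
    out$combined_mismatch <- sum(cells)
    as_tibble(out)
  })
  dplyr::bind_rows(rows)
}
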