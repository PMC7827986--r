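#' Percent identity of a segmental-duplication alignment
#'
#' Identity is the number of columns with identical nucleotides in both rows
#' divided by the number of non-gap columns; any column holding a gap in
#' either row is excluded from the denominator. `N` counts as non-identical
#' (and non-gap).
#'
#' @param seg a [segment_alignment], or a list with `row_a`/`row_b`.
#' @return identity fraction in \[0, 1\].
#' @export
segment_identity <- function(seg) {
  ca <- seq_chars(seg$row_a)
  cb <- seq_chars(seg$row_b)
  nongap <- ca != "-" & cb != "-"
  if (!any(nongap)) abort("alignment has no non-gap columns")
  ident <- nongap & ca == cb & ca != "N"
  sum(ident) / sum(nongap)
}

#' Windowed binomial scan for recombination signatures
#'
#' The two-row alignment of a TE pair is split into non-overlapping windows
#' of `window` non-gap columns, starting at the first aligned position;
#' left-over columns (fewer than `window`) at the end are not used. Columns
#' gapped in either row are skipped when counting off the `window` columns,
#' consistently with how identity is defined. Each window's identical-column
#' count is compared against the background identity of the full containing
#' segment: the binomial CDF at the *smallest* window count gives the raw
#' p-value, which is Bonferroni-corrected by the number of windows in this
#' pair. A pair is flagged when the corrected p-value falls below `alpha`.
#'
#' @param pair_alignment two-row gapped alignment of the TE pair: a list with
#'   `row_a` and `row_b` (e.g. a [segment_alignment] or the output of
#'   [pair_alignment()]).
#' @param background_identity identity fraction of the full segmental
#'   duplication (see [segment_identity()]).
#' @param window window size in non-gap columns.
#' @param alpha family-wise significance level.
#' @return an object of class `window_scan`: list with `window_counts`,
#'   `n_windows`, `min_count`, `background_identity`, `raw_p`, `corrected_p`
#'   and `flagged`. With fewer than `window` non-gap columns there are 0
#'   windows, `raw_p = corrected_p = 1` and the pair is not flagged.
#' @export
window_scan <- function(pair_alignment, background_identity,
                        window = 100L, alpha = 0.001) {
  check_fraction(background_identity, "background_identity")
  ca <- seq_chars(pair_alignment$row_a)
  cb <- seq_chars(pair_alignment$row_b)
  nongap <- which(ca != "-" & cb != "-")
  n_windows <- length(nongap) %/% window
  if (n_windows == 0) {
    return(structure(
      list(window_counts = integer(), n_windows = 0L, min_count = NA_integer_,
           background_identity = background_identity,
           raw_p = 1, corrected_p = 1, flagged = FALSE,
           window = as.integer(window), alpha = alpha),
      class = "window_scan"))
  }
  used <- nongap[seq_len(n_windows * window)]
  win <- rep(seq_len(n_windows), each = window)
  ident <- ca[used] == cb[used] & ca[used] != "N"
  counts <- as.integer(tapply(ident, win, sum))
  min_count <- min(counts)
  raw_p <- binom_cdf(min_count, as.integer(window), background_identity)
  corrected_p <- min(1, raw_p * n_windows)
  structure(
    list(window_counts = counts, n_windows = n_windows,
         min_count = min_count, background_identity = background_identity,
         raw_p = raw_p, corrected_p = corrected_p,
         flagged = corrected_p < alpha,
         window = as.integer(window), alpha = alpha),
    class = "window_scan")
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "<window_scan: %d windows of %d, min count %s, corrected p %.3g%s>\n",
    x$n_windows, x$window,
    if (is.na(x$min_count)) "-" else x$min_count,
    x$corrected_p, if (x$flagged) ", FLAGGED" else ""))
  invisible(x)
}

#' @rdname window_scan
#' @param x a `window_scan`.
#' @param ... unused.
#' @method glance window_scan
#' @export
glance.window_scan <- function(x, ...) {
  tibble(
    n_windows = x$n_windows,
    min_count = x$min_count,
    background_identity = x$background_identity,
    raw_p = x$raw_p,
    corrected_p = x$corrected_p,
    flagged = x$flagged
  )
}

#' Cut the column span of a TE pair out of its segment alignment
#'
#' @param seg a [segment_alignment].
#' @param col_start,col_end 1-based inclusive column span (as produced by
#'   [extract_te_pairs()]).
#' @return list with `row_a` and `row_b` restricted to the span.
#' @export
pair_alignment <- function(seg, col_start, col_end) {
  list(row_a = substr(seg$row_a, col_start, col_end),
       row_b = substr(seg$row_b, col_start, col_end))
}

#' Summarise recombination evidence by group and concordance
#'
#' @param pairs a labelled `te_pairs` tibble with one extra list-column
#'   `scan` holding the [window_scan()] of each pair, or a separate `scans`
#'   list parallel to the rows.
#' @param type_map named character vector `subfamily -> group` used to group
#'   rows (e.g. family or type); must cover every subfamily present. Pairs
#'   whose members fall in different groups are counted in both groups.
#' @param scans optional list of `window_scan` objects, one per pair row.
#' @return tibble with one row per group: `group`, `n_concordant`,
#'   `n_discordant`, `percent_flagged_concordant`,
#'   `percent_flagged_discordant`. Empty groups are omitted.
#' @export
summarize_recombination <- function(pairs, type_map, scans = NULL) {
  if (is.null(scans)) scans <- pairs$scan
  if (length(scans) != nrow(pairs)) {
    abort("need exactly one window_scan per pair")
  }
  missing <- setdiff(unique(c(pairs$subfamily_a, pairs$subfamily_b)),
                     names(type_map))
  if (length(missing) > 0) {
    abort(sprintf("subfamily missing from type_map: %s",
                  paste(missing, collapse = ", ")))
  }
  flagged <- purrr::map_lgl(scans, function(s) isTRUE(s$flagged))
  ga <- unname(type_map[pairs$subfamily_a])
  gb <- unname(type_map[pairs$subfamily_b])
  # a pair contributes to each distinct member group once
  d <- dplyr::bind_rows(
    tibble(group = ga, concordant = pairs$concordant, flagged = flagged),
    tibble(group = gb, concordant = pairs$concordant, flagged = flagged)[gb != ga, ]
  )
  d |>
    group_by(.data$group) |>
    summarise(
      n_concordant = sum(.data$concordant),
      n_discordant = sum(!.data$concordant),
      percent_flagged_concordant =
        100 * sum(.data$flagged & .data$concordant) /
          max(1L, sum(.data$concordant)),
      percent_flagged_discordant =
        100 * sum(.data$flagged & !.data$concordant) /
          max(1L, sum(!.data$concordant)),
      .groups = "drop"
    )
}
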