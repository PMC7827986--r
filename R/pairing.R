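# Map an annotation interval to the set of alignment columns in which its
# copy's sequence participates. `row_off` is the 0-based sequence offset per
# column (NA at gaps); `iv` the copy's genomic interval.
anno_columns <- function(anno, iv, row_off) {
  if (anno$start < iv$start || anno$end > iv$end) {
    abort(sprintf("annotation %s:%d-%d lies outside segment copy %s:%d-%d",
                  anno$chrom, anno$start, anno$end,
                  iv$chrom, iv$start, iv$end))
  }
  if (identical(iv$strand, "-")) {
    s <- iv$end - anno$end
    e <- iv$end - anno$start
  } else {
    s <- anno$start - iv$start
    e <- anno$end - iv$start
  }
  which(!is.na(row_off) & row_off >= s & row_off < e)
}

# longest run of TRUE in a logical vector (0 when none)
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Extract replicate TE pairs from a segmental-duplication alignment
#'
#' TEs annotated on copy A are matched to TEs on copy B by projecting both
#' through the alignment columns of the segment. A candidate pair (any two
#' TEs sharing at least one column) is retained only if every filter holds:
#' both copies longer than `min_len` bp; the shared columns cover at least
#' `min_cov` of each copy's aligned columns (reciprocally); neither TE
#' overlaps more than one TE on the other copy; the projected overlap is one
#' contiguous alignment (no single indel/unaligned block longer than
#' `max_gap_run` columns inside it); and neither subfamily call is ambiguous.
#' Filters are conjunctive, so the retained set does not depend on their
#' order; every candidate's outcome is recorded in the `"trace"` attribute.
#'
#' @param seg a [segment_alignment].
#' @param annos_a,annos_b [te_annotations] for the two copies (chromosome
#'   names matching the segment's intervals).
#' @param min_len minimum copy length in bp (a copy of exactly `min_len` is
#'   dropped).
#' @param min_cov minimum reciprocal coverage fraction, on alignment columns.
#' @param max_gap_run longest tolerated indel block inside the overlap,
#'   in columns.
#' @param allowed_chroms optional chromosome allow-list applied to the
#'   segment's intervals (e.g. canonical chromosomes); `NULL` disables it.
#' @return a `te_pairs` tibble with one row per retained pair: `pair_id`,
#'   `seg_id`, `source_a`, `source_b`, `subfamily_a`, `subfamily_b`,
#'   `family_a`, `family_b`, `col_start`, `col_end` (1-based span of the
#'   union of the two TEs' columns) and `concordant` (`NA` until
#'   [label_concordance()]). Attribute `"trace"` tabulates every candidate
#'   pair and the rules it failed.
#' @export
extract_te_pairs <- function(seg, annos_a, annos_b,
                             min_len = 50L, min_cov = 0.8,
                             max_gap_run = 30L, allowed_chroms = NULL) {
  empty <- tibble(
    pair_id = character(), seg_id = character(),
    source_a = character(), source_b = character(),
    subfamily_a = character(), subfamily_b = character(),
    family_a = character(), family_b = character(),
    col_start = integer(), col_end = integer(), concordant = logical()
  )
  trace0 <- tibble(seg_id = character(), source_a = character(),
                   source_b = character(), kept = logical(),
                   failed = character())
  if (!is.null(allowed_chroms) &&
      !(seg$interval_a$chrom %in% allowed_chroms &&
        seg$interval_b$chrom %in% allowed_chroms)) {
    return(structure(empty, trace = trace0, class = c("te_pairs", class(empty))))
  }
  ca <- seq_chars(seg$row_a)
  cb <- seq_chars(seg$row_b)
  off_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-") - 1L)
  off_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-") - 1L)

  aa <- annos_a[annos_a$chrom == seg$interval_a$chrom, ]
  bb <- annos_b[annos_b$chrom == seg$interval_b$chrom, ]
  if (nrow(aa) == 0 || nrow(bb) == 0) {
    return(structure(empty, trace = trace0, class = c("te_pairs", class(empty))))
  }
  cols_a <- lapply(seq_len(nrow(aa)),
                   function(i) anno_columns(aa[i, ], seg$interval_a, off_a))
  cols_b <- lapply(seq_len(nrow(bb)),
                   function(i) anno_columns(bb[i, ], seg$interval_b, off_b))

  cand <- list()
  for (i in seq_len(nrow(aa))) {
    for (j in seq_len(nrow(bb))) {
      if (length(intersect(cols_a[[i]], cols_b[[j]])) > 0) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(cand) == 0) {
    return(structure(empty, trace = trace0, class = c("te_pairs", class(empty))))
  }
  deg_a <- table(vapply(cand, `[`, numeric(1), 1))
  deg_b <- table(vapply(cand, `[`, numeric(1), 2))

  rows <- list()
  trace <- list()
  for (p in cand) {
    i <- p[1]; j <- p[2]
    shared <- intersect(cols_a[[i]], cols_b[[j]])
    failed <- character()
    len_a <- aa$end[i] - aa$start[i]
    len_b <- bb$end[j] - bb$start[j]
    if (len_a <= min_len || len_b <= min_len) failed <- c(failed, "min_len")
    cov_a <- length(shared) / length(cols_a[[i]])
    cov_b <- length(shared) / length(cols_b[[j]])
    if (cov_a < min_cov || cov_b < min_cov) failed <- c(failed, "min_cov")
    if (deg_a[[as.character(i)]] > 1L || deg_b[[as.character(j)]] > 1L) {
      failed <- c(failed, "multiplicity")
    }
    span <- seq.int(min(shared), max(shared))
    if (longest_run(ca[span] == "-" | cb[span] == "-") > max_gap_run) {
      failed <- c(failed, "contiguity")
    }
    if (aa$ambiguous[i] || bb$ambiguous[j]) failed <- c(failed, "ambiguous")

    trace[[length(trace) + 1L]] <- tibble(
      seg_id = seg$id, source_a = aa$source_id[i], source_b = bb$source_id[j],
      kept = length(failed) == 0,
      failed = paste(failed, collapse = ",")
    )
    if (length(failed) > 0) next
    union_cols <- union(cols_a[[i]], cols_b[[j]])
    rows[[length(rows) + 1L]] <- tibble(
      pair_id = sprintf("%s|%s|%s", seg$id, aa$source_id[i], bb$source_id[j]),
      seg_id = seg$id,
      source_a = aa$source_id[i], source_b = bb$source_id[j],
      subfamily_a = aa$subfamily[i], subfamily_b = bb$subfamily[j],
      family_a = aa$family[i], family_b = bb$family[j],
      col_start = min(union_cols), col_end = max(union_cols),
      concordant = NA
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  structure(out, trace = dplyr::bind_rows(trace),
            class = c("te_pairs", class(empty)))
}

#' Pair two pre-mapped annotation sets by genomic overlap
#'
#' For annotations already mapped into a common coordinate system (e.g. one
#' genome lifted over onto another), candidate pairs are all overlapping
#' intervals on the same chromosome. Candidates are then subjected to the
#' same conjunctive filters as [extract_te_pairs()], with coverage measured
#' in base pairs: both members longer than `min_len`; the overlap covers at
#' least `min_cov` of each member; neither member overlaps more than one
#' interval on the other side; neither call ambiguous. Retained candidates
#' are matched greedily one-to-one by descending overlap length.
#'
#' @param annos_mapped,annos_target [te_annotations] in the same coordinate
#'   system.
#' @inheritParams extract_te_pairs
#' @return a `te_pairs` tibble (no `col_start`/`col_end`; `overlap_bp`
#'   instead), with a `"trace"` attribute as in [extract_te_pairs()].
#' @export
pair_by_overlap <- function(annos_mapped, annos_target,
                            min_len = 50L, min_cov = 0.8) {
  empty <- tibble(
    pair_id = character(), source_a = character(), source_b = character(),
    subfamily_a = character(), subfamily_b = character(),
    family_a = character(), family_b = character(),
    overlap_bp = integer(), concordant = logical()
  )
  trace0 <- tibble(source_a = character(), source_b = character(),
                   kept = logical(), failed = character())
  if (nrow(annos_mapped) == 0 || nrow(annos_target) == 0) {
    return(structure(empty, trace = trace0, class = c("te_pairs", class(empty))))
  }
  qr <- IRanges::IRanges(annos_mapped$start + 1L, annos_mapped$end)
  tr <- IRanges::IRanges(annos_target$start + 1L, annos_target$end)
  hits <- IRanges::findOverlaps(qr, tr)
  qi <- S4Vectors::queryHits(hits)
  ti <- S4Vectors::subjectHits(hits)
  same_chrom <- annos_mapped$chrom[qi] == annos_target$chrom[ti]
  qi <- qi[same_chrom]; ti <- ti[same_chrom]
  if (length(qi) == 0) {
    return(structure(empty, trace = trace0, class = c("te_pairs", class(empty))))
  }
  ov <- pmin(annos_mapped$end[qi], annos_target$end[ti]) -
    pmax(annos_mapped$start[qi], annos_target$start[ti])
  deg_q <- table(qi)
  deg_t <- table(ti)

  len_q <- annos_mapped$end[qi] - annos_mapped$start[qi]
  len_t <- annos_target$end[ti] - annos_target$start[ti]
  fail <- function(cond, name) ifelse(cond, name, "")
  fails <- mapply(function(k) {
    f <- character()
    if (len_q[k] <= min_len || len_t[k] <= min_len) f <- c(f, "min_len")
    if (ov[k] / len_q[k] < min_cov || ov[k] / len_t[k] < min_cov) {
      f <- c(f, "min_cov")
    }
    if (deg_q[[as.character(qi[k])]] > 1L ||
        deg_t[[as.character(ti[k])]] > 1L) {
      f <- c(f, "multiplicity")
    }
    if (annos_mapped$ambiguous[qi[k]] || annos_target$ambiguous[ti[k]]) {
      f <- c(f, "ambiguous")
    }
    paste(f, collapse = ",")
  }, seq_along(qi))

  trace <- tibble(
    source_a = annos_mapped$source_id[qi],
    source_b = annos_target$source_id[ti],
    kept = fails == "",
    failed = fails
  )
  keep <- which(fails == "")
  # greedy one-to-one matching by descending overlap
  keep <- keep[order(-ov[keep])]
  used_q <- used_t <- integer()
  rows <- list()
  for (k in keep) {
    if (qi[k] %in% used_q || ti[k] %in% used_t) next
    used_q <- c(used_q, qi[k]); used_t <- c(used_t, ti[k])
    rows[[length(rows) + 1L]] <- tibble(
      pair_id = sprintf("%s|%s", annos_mapped$source_id[qi[k]],
                        annos_target$source_id[ti[k]]),
      source_a = annos_mapped$source_id[qi[k]],
      source_b = annos_target$source_id[ti[k]],
      subfamily_a = annos_mapped$subfamily[qi[k]],
      subfamily_b = annos_target$subfamily[ti[k]],
      family_a = annos_mapped$family[qi[k]],
      family_b = annos_target$family[ti[k]],
      overlap_bp = as.integer(ov[k]),
      concordant = NA
    )
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  structure(out, trace = trace, class = c("te_pairs", class(empty)))
}

#' Label pair concordance
#'
#' A pair is concordant exactly when the two members carry the same subfamily
#' name. Ambiguous members must have been filtered out upstream and raise an
#' error here.
#'
#' @param pairs a `te_pairs` tibble.
#' @return `pairs` with the `concordant` column filled in.
#' @export
label_concordance <- function(pairs) {
  amb_a <- pairs$subfamily_a == pairs$family_a
  amb_b <- pairs$subfamily_b == pairs$family_b
  if (any(amb_a | amb_b)) {
    bad <- which(amb_a | amb_b)[1]
    abort(sprintf(
      "pair %s has an ambiguous member (family-only call '%s'); filter upstream",
      pairs$pair_id[bad],
      if (amb_a[bad]) pairs$subfamily_a[bad] else pairs$subfamily_b[bad]))
  }
  pairs$concordant <- pairs$subfamily_a == pairs$subfamily_b
  pairs
}

#' Tabulate discordant annotation by family and by type
#'
#' Produces the two standard views of pair concordance. The per-family table
#' counts pairs and discordant pairs and their percentage. The type-by-type
#' cross table assigns each concordant pair once to its type's `concordant`
#' cell; a discordant pair whose members fall in two different types is
#' counted once in each member's type row (in the column of the other
#' member's type), so off-diagonal cells are symmetric and cross-type pairs
#' are double-counted across rows; a within-type discordant pair is counted
#' once in its diagonal cell. Each row's `mismatch_percent` is
#' `100 * discordant / (concordant + discordant)` over that row.
#'
#' @param pairs a labelled `te_pairs` tibble (see [label_concordance()]).
#' @param family_map named character vector `subfamily -> family`; defaults
#'   to the pairs' own family columns.
#' @param type_map named character vector `subfamily -> type` (the
#'   AluJ/AluS/AluY analogue). Must cover every subfamily present.
#' @return an object of class `discordance_summary`: list with `by_family`
#'   (tibble: `family`, `n_pairs`, `n_discordant`, `percent_discordant`) and
#'   `cross_table` (tibble: `type`, `concordant`, one `to_<type>` column per
#'   type, `mismatch_percent`).
#' @export
summarize_discordance <- function(pairs, family_map = NULL, type_map = NULL) {
  if (any(is.na(pairs$concordant))) {
    pairs <- label_concordance(pairs)
  }
  fam_of <- function(subfam, fallback) {
    if (is.null(family_map)) return(fallback)
    missing <- setdiff(unique(subfam), names(family_map))
    if (length(missing) > 0) {
      abort(sprintf("subfamily missing from family_map: %s",
                    paste(missing, collapse = ", ")))
    }
    unname(family_map[subfam])
  }
  fa <- fam_of(pairs$subfamily_a, pairs$family_a)
  fb <- fam_of(pairs$subfamily_b, pairs$family_b)
  family <- ifelse(fa == fb, fa, "mixed")
  by_family <- tibble(family = family, concordant = pairs$concordant) |>
    group_by(.data$family) |>
    summarise(
      n_pairs = dplyr::n(),
      n_discordant = sum(!.data$concordant),
      percent_discordant = 100 * sum(!.data$concordant) / dplyr::n(),
      .groups = "drop"
    )

  cross_table <- NULL
  if (!is.null(type_map)) {
    missing <- setdiff(unique(c(pairs$subfamily_a, pairs$subfamily_b)),
                       names(type_map))
    if (length(missing) > 0) {
      abort(sprintf("subfamily missing from type_map: %s",
                    paste(missing, collapse = ", ")))
    }
    ta <- unname(type_map[pairs$subfamily_a])
    tb <- unname(type_map[pairs$subfamily_b])
    types <- sort(unique(c(ta, tb)))
    conc <- table(factor(ta[pairs$concordant], levels = types))
    cross <- matrix(0L, length(types), length(types),
                    dimnames = list(types, types))
    disc <- which(!pairs$concordant)
    for (k in disc) {
      cross[ta[k], tb[k]] <- cross[ta[k], tb[k]] + 1L
      if (ta[k] != tb[k]) cross[tb[k], ta[k]] <- cross[tb[k], ta[k]] + 1L
    }
    cross_table <- tibble(type = types, concordant = as.integer(conc))
    for (t2 in types) {
      cross_table[[paste0("to_", t2)]] <- as.integer(cross[, t2])
    }
    row_disc <- unname(rowSums(cross))
    cross_table$mismatch_percent <-
      100 * row_disc / (cross_table$concordant + row_disc)
  }
  structure(list(by_family = by_family, cross_table = cross_table),
            class = "discordance_summary")
}

#' @export
print.discordance_summary <- function(x, ...) {
  cat("<discordance_summary>\nBy family:\n")
  print(x$by_family)
  if (!is.null(x$cross_table)) {
    cat("Type cross table (discordant pairs double-counted):\n")
    print(x$cross_table)
  }
  invisible(x)
}

#' @rdname summarize_discordance
#' @param x a `discordance_summary`.
#' @param ... unused.
#' @method tidy discordance_summary
#' @export
tidy.discordance_summary <- function(x, ...) {
  x$by_family
}
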