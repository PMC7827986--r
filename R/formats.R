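#' TE annotation tables
#'
#' Throughout the package a set of TE annotations is an ordinary tibble with
#' one row per annotated element and columns:
#' \describe{
#'   \item{chrom}{chromosome / segment name}
#'   \item{start, end}{0-based half-open interval (bp)}
#'   \item{strand}{`"+"` or `"-"`}
#'   \item{family}{TE family name (e.g. `Alu`, `L1`)}
#'   \item{subfamily}{subfamily name; equals `family` when the call is
#'     ambiguous}
#'   \item{ambiguous}{logical; `TRUE` when the source record names only a
#'     family, with no specific subfamily}
#'   \item{score}{alignment score in scoring-matrix units, or `NA`}
#'   \item{divergence}{mismatch fraction to consensus in \[0,1\], or `NA`}
#'   \item{source_id}{opaque record identifier}
#' }
#' All internal coordinates are 0-based half-open; conversion from 1-based
#' inclusive formats happens only in readers and writers.
#'
#' @param chrom,start,end,strand,family,subfamily,score,divergence,source_id
#'   vectors, recycled to a common length.
#' @param ambiguous logical; computed from `family`/`subfamily` when `NULL`.
#' @param ambiguous_names subfamily strings always treated as ambiguous.
#' @return a tibble of class `te_annotations`.
#' @export
te_annotations <- function(chrom, start, end, strand = "+",
                           family, subfamily,
                           score = NA_real_, divergence = NA_real_,
                           source_id = NA_character_,
                           ambiguous = NULL,
                           ambiguous_names = c("Alu", "L1")) {
  out <- tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    family = as.character(family),
    subfamily = as.character(subfamily),
    score = as.numeric(score),
    divergence = as.numeric(divergence),
    source_id = as.character(source_id)
  )
  if (is.null(ambiguous)) {
    ambiguous <- out$subfamily == out$family | out$subfamily %in% ambiguous_names
  }
  out$ambiguous <- as.logical(ambiguous)
  out <- out[, c("chrom", "start", "end", "strand", "family", "subfamily",
                 "ambiguous", "score", "divergence", "source_id")]
  validate_te_annotations(out)
  class(out) <- c("te_annotations", class(out))
  out
}

validate_te_annotations <- function(x) {
  if (any(nchar(x$chrom) == 0L)) abort("chromosome names must be non-empty")
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(sprintf("interval start must be < end (row %d: %d >= %d)",
                  bad, x$start[bad], x$end[bad]))
  }
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  dv <- x$divergence
  if (any(!is.na(dv) & (dv < 0 | dv > 1))) {
    abort("divergence must lie in [0, 1]")
  }
  invisible(x)
}

#' Read RepeatMasker `.out` annotations
#'
#' Parses the classic RepeatMasker `.out` layout (3 header lines followed by
#' whitespace-delimited records). The 1-based inclusive query coordinates are
#' converted to 0-based half-open; strand `C` becomes `-`; `%div` becomes a
#' divergence fraction. A record whose repeat name equals its family name (or
#' appears in `ambiguous_names`) carries no subfamily information and is
#' flagged ambiguous. The `(left)` columns are parsed but discarded; the final
#' fragment ID column is kept as `source_id` (no fragment merging is
#' performed).
#'
#' @param path path to a RepeatMasker `.out` file.
#' @param ambiguous_names repeat names treated as family-only labels.
#' @return a [te_annotations] tibble.
#' @export
read_repeatmasker_out <- function(path, ambiguous_names = c("Alu", "L1")) {
  lines <- readLines(path)
  if (length(lines) > 0) lines <- lines[-seq_len(min(3L, length(lines)))]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(te_annotations(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), family = character(), subfamily = character()
  ))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 14L || length(f) > 16L) {
      abort(sprintf("malformed RepeatMasker record on body line %d: %d columns",
                    i, length(f)))
    }
    if (!f[9] %in% c("+", "C")) {
      abort(sprintf("unknown strand symbol '%s' on body line %d", f[9], i))
    }
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    family <- cf[length(cf)]
    list(
      score = as.numeric(f[1]),
      divergence = as.numeric(f[2]) / 100,
      chrom = f[5],
      start = as.integer(f[6]) - 1L,   # 1-based inclusive -> 0-based half-open
      end = as.integer(f[7]),
      strand = if (f[9] == "C") "-" else "+",
      subfamily = f[10],
      family = family,
      source_id = if (length(f) >= 15L) f[15] else NA_character_
    )
  })
  d <- dplyr::bind_rows(lapply(rows, as_tibble))
  te_annotations(
    chrom = d$chrom, start = d$start, end = d$end, strand = d$strand,
    family = d$family, subfamily = d$subfamily,
    score = d$score, divergence = d$divergence, source_id = d$source_id,
    ambiguous_names = ambiguous_names
  )
}

#' Read and write BED6 annotations
#'
#' BED coordinates are already 0-based half-open and are taken as-is. The name
#' column is either `family/subfamily` or a bare name; a bare name is resolved
#' to a family through `family_map` (a named character vector
#' `subfamily -> family`) when possible, and otherwise treated as a
#' family-only, ambiguous call.
#'
#' @param path file path.
#' @param family_map optional named character vector mapping bare subfamily
#'   names to their family.
#' @param ambiguous_names names always treated as family-only labels.
#' @return `read_bed()`: a [te_annotations] tibble. `write_bed()`: `path`,
#'   invisibly.
#' @export
read_bed <- function(path, family_map = NULL, ambiguous_names = c("Alu", "L1")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(te_annotations(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), family = character(), subfamily = character()
  ))
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(f) < 6L) {
      abort(sprintf("BED6 requires >= 6 columns, found %d on line %d",
                    length(f), i))
    }
    nm <- strsplit(f[4], "/", fixed = TRUE)[[1]]
    if (length(nm) >= 2L) {
      family <- nm[1]; subfamily <- nm[2]
    } else if (!is.null(family_map) && f[4] %in% names(family_map)) {
      family <- unname(family_map[[f[4]]]); subfamily <- f[4]
    } else {
      family <- f[4]; subfamily <- f[4]
    }
    list(
      chrom = f[1], start = as.integer(f[2]), end = as.integer(f[3]),
      family = family, subfamily = subfamily,
      score = suppressWarnings(as.numeric(f[5])),
      strand = f[6], source_id = sprintf("%s:%s-%s", f[1], f[2], f[3])
    )
  })
  d <- dplyr::bind_rows(lapply(rows, as_tibble))
  te_annotations(
    chrom = d$chrom, start = d$start, end = d$end, strand = d$strand,
    family = d$family, subfamily = d$subfamily, score = d$score,
    source_id = d$source_id, ambiguous_names = ambiguous_names
  )
}

#' @param annos a [te_annotations] tibble.
#' @rdname read_bed
#' @export
write_bed <- function(annos, path) {
  name <- ifelse(annos$ambiguous, annos$family,
                 paste0(annos$family, "/", annos$subfamily))
  score <- ifelse(is.na(annos$score), 0, annos$score)
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   annos$chrom, annos$start, annos$end, name, score,
                   annos$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Segmental-duplication alignment objects
#'
#' A segmental duplication is stored as a two-row gapped alignment of the two
#' copies, together with the genomic interval of each copy. Rows use the
#' alphabet `A,C,G,T,N,-`; the two rows have equal gapped length, the ungapped
#' length of each row equals the width of its interval, and no column is a gap
#' in both rows.
#'
#' @param id identifier.
#' @param interval_a,interval_b one-row data frames (or named lists) with
#'   `chrom`, `start`, `end`, `strand` for each copy (0-based half-open).
#' @param row_a,row_b gapped sequence strings of equal length.
#' @return an object of class `segment_alignment`.
#' @export
segment_alignment <- function(id, interval_a, interval_b, row_a, row_b) {
  interval_a <- as.list(interval_a)[c("chrom", "start", "end", "strand")]
  interval_b <- as.list(interval_b)[c("chrom", "start", "end", "strand")]
  if (nchar(row_a) != nchar(row_b)) {
    abort(sprintf("alignment rows differ in gapped length (%d vs %d)",
                  nchar(row_a), nchar(row_b)))
  }
  ca <- seq_chars(row_a); cb <- seq_chars(row_b)
  if (any(ca == "-" & cb == "-")) {
    abort("alignment contains a column gapped in both rows")
  }
  for (nm in c("a", "b")) {
    iv <- if (nm == "a") interval_a else interval_b
    ung <- sum((if (nm == "a") ca else cb) != "-")
    width <- iv$end - iv$start
    if (ung != width) {
      abort(sprintf(
        "ungapped length of row_%s (%d) does not match interval width (%d)",
        nm, ung, width))
    }
  }
  structure(
    list(id = id, interval_a = interval_a, interval_b = interval_b,
         row_a = row_a, row_b = row_b),
    class = "segment_alignment"
  )
}

#' @export
print.segment_alignment <- function(x, ...) {
  cat(sprintf("<segment_alignment '%s': %d columns>\n", x$id, nchar(x$row_a)))
  cat(sprintf("  A: %s:%d-%d(%s)\n", x$interval_a$chrom, x$interval_a$start,
              x$interval_a$end, x$interval_a$strand))
  cat(sprintf("  B: %s:%d-%d(%s)\n", x$interval_b$chrom, x$interval_b$start,
              x$interval_b$end, x$interval_b$strand))
  invisible(x)
}

parse_region_header <- function(header) {
  m <- regmatches(header,
                  regexec("([^ \t:]+):([0-9]+)-([0-9]+)\\(([+-])\\)\\s*$",
                          header))[[1]]
  if (length(m) != 5L) {
    abort(sprintf(
      "header '%s' does not end with 'chrom:start-end(strand)'", header))
  }
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
       strand = m[5])
}

#' Read and write segmental-duplication alignments (aligned FASTA)
#'
#' The file holds exactly two gapped records of equal length; each header ends
#' with the copy's coordinates as `chrom:start-end(strand)` (0-based
#' half-open).
#'
#' @param path file path.
#' @param id identifier for the alignment; defaults to the file name without
#'   extension.
#' @return `read_segment_alignment()`: a [segment_alignment].
#'   `write_segment_alignment()`: `path`, invisibly.
#' @export
read_segment_alignment <- function(path, id = NULL) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) != 2L) {
    abort(sprintf("expected exactly 2 aligned records, found %d in %s",
                  length(recs), path))
  }
  iv <- lapply(names(recs), parse_region_header)
  segment_alignment(
    id = id %||% sub("\\.[^.]*$", "", basename(path)),
    interval_a = iv[[1]], interval_b = iv[[2]],
    row_a = as.character(recs[[1]]), row_b = as.character(recs[[2]])
  )
}

#' @param seg a [segment_alignment].
#' @rdname read_segment_alignment
#' @export
write_segment_alignment <- function(seg, path) {
  hdr <- function(tag, iv) sprintf(">%s/%s %s:%d-%d(%s)", seg$id, tag,
                                   iv$chrom, iv$start, iv$end, iv$strand)
  writeLines(c(hdr("A", seg$interval_a), seg$row_a,
               hdr("B", seg$interval_b), seg$row_b), path)
  invisible(path)
}

#' Nucleotide scoring matrices
#'
#' An integer substitution matrix over an ordered alphabet, plus nonnegative
#' affine gap penalties. The text format is a square matrix: the first row
#' lists the alphabet, each following row gives a letter label and one integer
#' score per alphabet letter.
#'
#' @param scores square integer matrix with identical row and column names
#'   (the alphabet, in order).
#' @param gap_open,gap_extend nonnegative integer penalties.
#' @return an object of class `scoring_matrix`.
#' @export
scoring_matrix <- function(scores, gap_open = 12L, gap_extend = 2L) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) {
    abort("scoring matrix must be square")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores)) ||
      !identical(rownames(scores), colnames(scores))) {
    abort("scoring matrix must carry identical row and column letter names")
  }
  if (any(scores != round(scores))) abort("scores must be integers")
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be nonnegative")
  storage.mode(scores) <- "integer"
  structure(
    list(alphabet = rownames(scores), scores = scores,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend)),
    class = "scoring_matrix"
  )
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("<scoring_matrix over {%s}, gap open/extend %d/%d>\n",
              paste(x$alphabet, collapse = ","), x$gap_open, x$gap_extend))
  print(x$scores)
  invisible(x)
}

#' @param path file path.
#' @rdname scoring_matrix
#' @export
read_scoring_matrix <- function(path, gap_open = 12L, gap_extend = 2L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) < 2L) abort("scoring matrix file has no matrix body")
  alphabet <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  k <- length(alphabet)
  body <- lines[-1]
  if (length(body) != k) {
    abort(sprintf("non-square scoring matrix: %d alphabet letters, %d rows",
                  k, length(body)))
  }
  scores <- matrix(0L, k, k, dimnames = list(alphabet, alphabet))
  for (i in seq_len(k)) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) != k + 1L) {
      abort(sprintf("row %d has %d cells, expected %d", i, length(f) - 1L, k))
    }
    if (!f[1] %in% alphabet) {
      abort(sprintf("row label '%s' is not in the header alphabet", f[1]))
    }
    vals <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(vals)) || any(vals != round(vals))) {
      abort(sprintf("non-integer cell in matrix row '%s'", f[1]))
    }
    scores[f[1], ] <- as.integer(vals)
  }
  scoring_matrix(scores, gap_open = gap_open, gap_extend = gap_extend)
}

#' @param mat a [scoring_matrix].
#' @rdname scoring_matrix
#' @export
write_scoring_matrix <- function(mat, path) {
  lines <- c(
    paste(mat$alphabet, collapse = " "),
    vapply(mat$alphabet, function(a) {
      paste(c(a, mat$scores[a, ]), collapse = " ")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
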