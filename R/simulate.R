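#' Simulate a TE subfamily library with diagnostic sites
#'
#' Builds a library of subfamily consensus sequences by serial splitting: a
#' random ancestral consensus is drawn, and each further subfamily is derived
#' from the previous one by substituting exactly `diagnostic_per_split` fresh
#' positions. Positions are never reused across splits, so adjacent
#' subfamilies in the chain differ at exactly `diagnostic_per_split` sites and
#' subfamilies `i` and `j` differ at `|i - j| * diagnostic_per_split` sites.
#' This mirrors how real subfamilies are defined by shared diagnostic variants
#' accumulated along a replication history.
#'
#' @param ancestral_length consensus length in bp (>= 50).
#' @param n_subfamilies number of subfamilies (>= 1).
#' @param diagnostic_per_split diagnostic substitutions introduced at each
#'   split.
#' @param type_partition coarse type grouping (analogue of AluJ/AluS/AluY):
#'   either a single integer giving the number of contiguous types, or a
#'   character vector of length `n_subfamilies` of type labels.
#' @param frequencies nonnegative genome-frequency weights, recycled.
#' @param identities target mean identity of instances to their consensus
#'   (the drift model's P(A_i)), recycled.
#' @param family family label shared by all subfamilies.
#' @param seed integer seed; the library is deterministic given the seed.
#' @return a tibble of class `subfamily_library` with columns `name`,
#'   `type_label`, `parent`, `consensus`, `frequency`, `identity`, and
#'   attribute `family`.
#' @export
make_subfamily_library <- function(ancestral_length,
                                   n_subfamilies,
                                   diagnostic_per_split = 5L,
                                   type_partition = 1L,
                                   frequencies = 1,
                                   identities = 0.9,
                                   family = "SIM",
                                   seed = NULL) {
  if (ancestral_length < 50) abort("ancestral_length must be >= 50")
  if (n_subfamilies < 1) abort("n_subfamilies must be >= 1")
  n_splits <- n_subfamilies - 1L
  if (diagnostic_per_split * n_splits > ancestral_length) {
    abort(sprintf(
      "infeasible: %d diagnostic sites per split over %d splits exceed the %d bp consensus",
      diagnostic_per_split, n_splits, ancestral_length))
  }
  if (!is.null(seed)) set.seed(seed)

  cons <- vector("list", n_subfamilies)
  cons[[1]] <- seq_chars(random_dna(ancestral_length))
  free_pos <- seq_len(ancestral_length)
  for (i in seq_len(n_splits)) {
    pos <- free_pos[sample.int(length(free_pos), diagnostic_per_split)]
    free_pos <- setdiff(free_pos, pos)
    child <- cons[[i]]
    child[pos] <- vapply(child[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
    cons[[i + 1L]] <- child
  }

  if (is.numeric(type_partition) && length(type_partition) == 1L) {
    k <- as.integer(type_partition)
    type_label <- paste0("T", ((seq_len(n_subfamilies) - 1L) * k) %/%
                           n_subfamilies + 1L)
  } else {
    if (length(type_partition) != n_subfamilies) {
      abort("type_partition must be a count or one label per subfamily")
    }
    type_label <- as.character(type_partition)
  }

  name <- sprintf("SF%02d", seq_len(n_subfamilies))
  out <- tibble(
    name = name,
    type_label = type_label,
    parent = c(NA_character_, name[-n_subfamilies]),
    consensus = vapply(cons, chars_seq, character(1)),
    frequency = as.numeric(rep_len(frequencies, n_subfamilies)),
    identity = as.numeric(rep_len(identities, n_subfamilies))
  )
  if (any(out$frequency < 0) || sum(out$frequency) <= 0) {
    abort("frequencies must be nonnegative with positive sum")
  }
  if (any(out$identity < 0 | out$identity > 1)) {
    abort("identities must lie in [0, 1]")
  }
  attr(out, "family") <- family
  class(out) <- c("subfamily_library", class(out))
  out
}

#' Write a subfamily library as FASTA
#'
#' @param library a `subfamily_library`.
#' @param path output path.
#' @export
write_library_fasta <- function(library, path) {
  set <- Biostrings::DNAStringSet(setNames(library$consensus, library$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Vectorised point substitution over many equal-or-unequal-length sequences.
# Each site mutates independently with probability `rate`, uniformly to one of
# the three other bases (single event per site). Returns list(seqs, n_sub).
mutate_many <- function(seqs, rate) {
  if (length(seqs) == 0) return(list(seqs = character(), n_sub = integer()))
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  all <- unlist(ch, use.names = FALSE)
  grp <- rep.int(seq_along(seqs), lens)
  hit <- runif(length(all)) < rate
  if (any(hit)) {
    cur <- match(all[hit], DNA_BASES)
    step <- sample.int(3L, sum(hit), replace = TRUE)
    all[hit] <- DNA_BASES[((cur - 1L + step) %% 4L) + 1L]
  }
  out <- vapply(split(all, grp), paste, character(1), collapse = "")
  names(out) <- NULL
  n_sub <- as.integer(tapply(hit, grp, sum))
  names(n_sub) <- NULL
  list(seqs = out, n_sub = n_sub)
}

#' Simulate diverged TE instances from a subfamily library
#'
#' Each instance picks a subfamily with probability proportional to its
#' genome-frequency weight, then accumulates point substitutions: every site
#' independently mutates with probability `1 - identity`, uniformly to one of
#' the three other nucleotides. No indels are introduced, so instances stay
#' positionally aligned to their consensus.
#'
#' @param library a [make_subfamily_library()] result.
#' @param n_instances number of instances to draw (>= 0).
#' @param seed integer seed.
#' @return list with `instances` (tibble: `instance_id`, `true_subfamily`,
#'   `family`, `sequence`) and `truth` (tibble: `instance_id`,
#'   `true_subfamily`, `realized_divergence`, `conversions` list-column,
#'   empty at this stage).
#' @export
simulate_instances <- function(library, n_instances, seed = NULL) {
  if (n_instances < 0) abort("n_instances must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  fam <- attr(library, "family") %||% "SIM"
  if (n_instances == 0) {
    return(list(
      instances = tibble(instance_id = character(), true_subfamily = character(),
                         family = character(), sequence = character()),
      truth = tibble(instance_id = character(), true_subfamily = character(),
                     realized_divergence = numeric(), conversions = list())
    ))
  }
  idx <- sample.int(nrow(library), n_instances, replace = TRUE,
                    prob = library$frequency)
  res <- mutate_many(library$consensus[idx], 1 - library$identity[idx])
  # mutate_many draws one uniform per site; unequal rates are handled by
  # mutating per-instance blocks with their own rate
  if (length(unique(library$identity)) > 1L) {
    res <- list(seqs = character(n_instances), n_sub = integer(n_instances))
    for (r in unique(library$identity[idx])) {
      sel <- which(library$identity[idx] == r)
      m <- mutate_many(library$consensus[idx[sel]], 1 - r)
      res$seqs[sel] <- m$seqs
      res$n_sub[sel] <- m$n_sub
    }
  }
  id <- sprintf("inst%05d", seq_len(n_instances))
  list(
    instances = tibble(
      instance_id = id,
      true_subfamily = library$name[idx],
      family = fam,
      sequence = res$seqs
    ),
    truth = tibble(
      instance_id = id,
      true_subfamily = library$name[idx],
      realized_divergence = res$n_sub / nchar(library$consensus[idx]),
      conversions = rep(list(tibble(copy = character(),
                                    donor_subfamily = character(),
                                    tract_start = integer(),
                                    tract_end = integer())),
                        n_instances)
    )
  )
}

#' Duplicate TE instances inside flanked segments and diverge the copies
#'
#' Emulates segmental duplication: each TE instance is embedded in uniform
#' random flanking sequence, the whole segment is duplicated once, and the
#' two copies then accumulate substitutions independently at rate
#' `1 - post_dup_identity`. Because the mutation model is substitution-only,
#' the two copies stay positionally aligned and are emitted as a gapless
#' two-row [segment_alignment] together with TE annotations for both copies.
#'
#' @param sim a [simulate_instances()] result (or a compatible `instances`
#'   tibble wrapped in a list).
#' @param post_dup_identity per-copy probability that a site is left
#'   unmutated after duplication, in \[0, 1\].
#' @param flank_length flank length on each side of the TE (bp).
#' @param seed integer seed.
#' @return list with `segments` (named list of [segment_alignment], one per
#'   instance), `annotations` (a [te_annotations] tibble holding both copies
#'   of every TE; `chrom` names the segment copy, `subfamily` is the true
#'   subfamily) and `truth` (the input truth tibble).
#' @export
duplicate_with_divergence <- function(sim, post_dup_identity = 0.95,
                                      flank_length = 500L, seed = NULL) {
  check_fraction(post_dup_identity, "post_dup_identity")
  if (!is.null(seed)) set.seed(seed)
  inst <- sim$instances
  n <- nrow(inst)
  if (n == 0) {
    return(list(segments = list(),
                annotations = te_annotations(
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), family = character(),
                  subfamily = character()),
                truth = sim$truth))
  }
  te_len <- nchar(inst$sequence)
  seg <- vapply(seq_len(n), function(i) {
    paste0(random_dna(flank_length), inst$sequence[i], random_dna(flank_length))
  }, character(1))
  rate <- 1 - post_dup_identity
  copy_a <- mutate_many(seg, rate)$seqs
  copy_b <- mutate_many(seg, rate)$seqs
  seg_len <- nchar(seg)

  segments <- lapply(seq_len(n), function(i) {
    segment_alignment(
      id = inst$instance_id[i],
      interval_a = list(chrom = paste0(inst$instance_id[i], "_A"),
                        start = 0L, end = seg_len[i], strand = "+"),
      interval_b = list(chrom = paste0(inst$instance_id[i], "_B"),
                        start = 0L, end = seg_len[i], strand = "+"),
      row_a = copy_a[i], row_b = copy_b[i]
    )
  })
  names(segments) <- inst$instance_id

  annotations <- te_annotations(
    chrom = c(paste0(inst$instance_id, "_A"), paste0(inst$instance_id, "_B")),
    start = rep(flank_length, 2L * n),
    end = rep(flank_length + te_len, 2L),
    strand = "+",
    family = rep(inst$family, 2L),
    subfamily = rep(inst$true_subfamily, 2L),
    source_id = c(paste0(inst$instance_id, "/A"), paste0(inst$instance_id, "/B")),
    ambiguous = FALSE
  )
  list(segments = segments, annotations = annotations, truth = sim$truth)
}

#' Overwrite TE tracts by gene conversion from donor instances
#'
#' With probability `rate` per duplicated pair, one copy of the TE receives a
#' conversion tract: a uniformly placed tract of uniform length in
#' `tract_range`, lying fully inside the TE copy, is replaced by the
#' homologous region of a randomly chosen donor instance. Every event is
#' logged in the truth table, whether or not it changed the sequence.
#'
#' @param dup a [duplicate_with_divergence()] result.
#' @param donor_pool tibble with `true_subfamily` and `sequence` columns;
#'   donor sequences must be positionally aligned to the TE (same length).
#' @param tract_range integer vector `c(min, max)` tract length in bp
#'   (min >= 1).
#' @param rate probability that a pair receives a conversion event.
#' @param seed integer seed.
#' @return `dup`, with modified segments and an updated `truth` table whose
#'   `conversions` list-column records `(copy, donor_subfamily, tract_start,
#'   tract_end)` tracts (0-based half-open, relative to the TE).
#' @export
apply_gene_conversion <- function(dup, donor_pool, tract_range = c(50L, 500L),
                                  rate = 0.1, seed = NULL) {
  if (tract_range[1] < 1) abort("minimum tract length must be >= 1")
  if (nrow(donor_pool) == 0) abort("donor_pool must be non-empty")
  check_fraction(rate, "rate")
  if (!is.null(seed)) set.seed(seed)
  truth <- dup$truth
  ann <- dup$annotations
  for (i in seq_along(dup$segments)) {
    if (runif(1) >= rate) next
    seg <- dup$segments[[i]]
    id <- seg$id
    a <- ann[ann$source_id == paste0(id, "/A"), ]
    te_len <- a$end - a$start
    if (tract_range[1] > te_len) {
      abort(sprintf("conversion tract (>= %d bp) longer than the %d bp TE",
                    tract_range[1], te_len))
    }
    lens <- seq.int(tract_range[1], min(tract_range[2], te_len))
    tr_len <- lens[sample.int(length(lens), 1L)]
    tr_start <- sample.int(te_len - tr_len + 1L, 1L) - 1L   # 0-based, in TE
    copy <- sample(c("A", "B"), 1L)
    donor <- donor_pool[sample.int(nrow(donor_pool), 1L), ]
    donor_tract <- substr(donor$sequence, tr_start + 1L, tr_start + tr_len)
    row_nm <- if (copy == "A") "row_a" else "row_b"
    row <- seg[[row_nm]]
    # segment rows are gapless here, so TE offsets map directly to columns
    pos <- a$start + tr_start
    substr(row, pos + 1L, pos + tr_len) <- donor_tract
    seg[[row_nm]] <- row
    dup$segments[[i]] <- seg
    j <- which(truth$instance_id == id)
    truth$conversions[[j]] <- dplyr::bind_rows(
      truth$conversions[[j]],
      tibble(copy = copy, donor_subfamily = donor$true_subfamily,
             tract_start = as.integer(tr_start),
             tract_end = as.integer(tr_start + tr_len))
    )
  }
  dup$truth <- truth
  dup
}
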