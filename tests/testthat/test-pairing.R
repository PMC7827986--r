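test_that("replicate pairs are extracted through alignment-column projection", {
  set.seed(91)
  seg <- toy_segment(len = 400)
  expect_equal(nrow(extract_te_pairs(seg,
                                     toy_annos(character(), integer(),
                                               integer(), character()),
                                     toy_annos(character(), integer(),
                                               integer(), character()))),
               0L)

  # three loci: a clean reciprocal match, a 40 bp copy, and a 60% coverage
  # overlap; only the first survives, and the trace names the violated rule
  annos_a <- toy_annos("seg1_A", c(10L, 150L, 250L), c(110L, 190L, 350L),
                       c("AluSx", "AluY", "AluSz"))
  annos_b <- toy_annos("seg1_B", c(10L, 150L, 250L), c(110L, 190L, 310L),
                       c("AluSx", "AluY", "AluSz"))
  p <- extract_te_pairs(seg, annos_a, annos_b)
  expect_equal(nrow(p), 1L)
  expect_equal(p$subfamily_a, "AluSx")
  tr <- attr(p, "trace")
  expect_equal(nrow(tr), 3L)
  expect_true(grepl("min_len", tr$failed[tr$source_a == "seg1_A:150"]))
  expect_true(grepl("min_cov", tr$failed[tr$source_a == "seg1_A:250"]))
})

test_that("a TE overlapping multiple TEs on the other copy is excluded", {
  set.seed(92)
  seg <- toy_segment(len = 400)
  annos_a <- toy_annos("seg1_A", 50L, 250L, "AluSx")
  annos_b <- toy_annos("seg1_B", c(40L, 160L), c(150L, 260L),
                       c("AluSx", "AluSz"))
  p <- extract_te_pairs(seg, annos_a, annos_b)
  expect_equal(nrow(p), 0L)
  tr <- attr(p, "trace")
  expect_equal(nrow(tr), 2L)
  expect_true(all(grepl("multiplicity", tr$failed)))
})

test_that("ambiguous members and broken contiguity drop a pair", {
  set.seed(93)
  seg <- toy_segment(len = 400)
  amb_a <- toy_annos("seg1_A", 50L, 250L, "Alu", ambiguous = TRUE)
  b <- toy_annos("seg1_B", 50L, 250L, "AluSx")
  p <- extract_te_pairs(seg, amb_a, b)
  expect_equal(nrow(p), 0L)
  expect_true(grepl("ambiguous", attr(p, "trace")$failed[1]))

  # a 40-column deletion inside the overlap breaks "one contiguous alignment"
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  row_b <- paste0(substr(base, 1, 150), strrep("-", 40),
                  substr(base, 191, 400))
  gap_seg <- segment_alignment(
    "seg1",
    list(chrom = "seg1_A", start = 0L, end = 400L, strand = "+"),
    list(chrom = "seg1_B", start = 0L, end = 360L, strand = "+"),
    base, row_b)
  ga <- toy_annos("seg1_A", 50L, 250L, "AluSx")
  gb <- toy_annos("seg1_B", 50L, 210L, "AluSx")
  p2 <- extract_te_pairs(gap_seg, ga, gb, min_cov = 0.5)
  expect_equal(nrow(p2), 0L)
  expect_true(grepl("contiguity", attr(p2, "trace")$failed[1]))
  # with a tolerant block threshold the same pair is kept
  p3 <- extract_te_pairs(gap_seg, ga, gb, min_cov = 0.5, max_gap_run = 60)
  expect_equal(nrow(p3), 1L)
})

test_that("an annotation outside its segment copy raises an error", {
  set.seed(94)
  seg <- toy_segment(len = 100)
  out <- toy_annos("seg1_A", 50L, 150L, "AluSx")
  b <- toy_annos("seg1_B", 10L, 90L, "AluSx")
  expect_error(extract_te_pairs(seg, out, b), "outside segment")
})

test_that("overlap pairing applies the same filters on pre-mapped sets", {
  a <- toy_annos("chr1", c(100L, 1000L, 5000L), c(400L, 1300L, 5300L),
                 c("AluSx", "AluSz", "AluY"))
  p <- pair_by_overlap(a, a)
  expect_equal(nrow(p), 3L)
  expect_true(all(p$source_a == p$source_b))

  b <- toy_annos("chr1", 10000L, 10300L, "AluSx")
  p2 <- pair_by_overlap(a, b)
  expect_equal(nrow(p2), 0L)

  # one mapped TE overlapping two targets is excluded by the
  # multiplicity rule even though one overlap dominates
  t2 <- toy_annos("chr1", c(100L, 340L), c(340L, 640L), c("AluSx", "AluSz"))
  q <- toy_annos("chr1", 100L, 500L, "AluSx")
  p3 <- pair_by_overlap(q, t2, min_cov = 0.1)
  expect_equal(nrow(p3), 0L)
  expect_true(all(grepl("multiplicity", attr(p3, "trace")$failed)))
})

test_that("concordance is exact subfamily-name equality", {
  pairs <- tibble::tibble(
    pair_id = c("p1", "p2"),
    subfamily_a = c("AluSx", "AluSx"), subfamily_b = c("AluSx", "AluSz"),
    family_a = "Alu", family_b = "Alu", concordant = NA
  )
  lab <- label_concordance(pairs)
  expect_equal(lab$concordant, c(TRUE, FALSE))

  amb <- tibble::tibble(pair_id = "p3", subfamily_a = "AluY",
                        subfamily_b = "Alu", family_a = "Alu",
                        family_b = "Alu", concordant = NA)
  expect_error(label_concordance(amb), "ambiguous")
})

# build a labelled pair table with given per-combination counts
pairs_from_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    tibble::tibble(
      pair_id = sprintf("%s_%s_%d", r$sub_a, r$sub_b, seq_len(r$n)),
      subfamily_a = r$sub_a, subfamily_b = r$sub_b,
      family_a = r$fam, family_b = r$fam, concordant = NA
    )
  })
  label_concordance(dplyr::bind_rows(rows))
}

test_that("discordance summaries reproduce printed-table arithmetic", {
  counts <- tibble::tibble(
    sub_a = c("L1PA3", "L1PA3"), sub_b = c("L1PA3", "L1PA4"),
    fam = "L1", n = c(6615L - 933L, 933L)
  )
  s <- summarize_discordance(pairs_from_counts(counts))
  expect_equal(s$by_family$n_pairs, 6615L)
  expect_equal(s$by_family$percent_discordant, 100 * 933 / 6615)

  # empty groups never appear, so no division by zero
  expect_equal(nrow(s$by_family), 1L)
})

test_that("the type cross table is symmetric and double-counts cross-type
           pairs only", {
  counts <- tibble::tibble(
    sub_a = c("J1", "J1", "J1", "S1", "S1", "Y1"),
    sub_b = c("J1", "J2", "S1", "S2", "Y1", "Y2"),
    fam = "Alu",
    n = c(100L, 7L, 5L, 9L, 3L, 2L)
  )
  tm <- c(J1 = "J", J2 = "J", S1 = "S", S2 = "S", Y1 = "Y", Y2 = "Y")
  s <- summarize_discordance(pairs_from_counts(counts), type_map = tm)
  ct <- s$cross_table
  expect_equal(ct$concordant[ct$type == "J"], 100L)
  expect_equal(ct$to_J[ct$type == "J"], 7L)    # within-type counted once
  expect_equal(ct$to_S[ct$type == "J"], 5L)
  expect_equal(ct$to_J[ct$type == "S"], 5L)    # mirrored cell
  expect_equal(ct$to_Y[ct$type == "S"], 3L)
  expect_equal(ct$to_S[ct$type == "Y"], 3L)
  expect_equal(ct$mismatch_percent[ct$type == "J"],
               100 * (7 + 5) / (100 + 7 + 5))

  expect_error(summarize_discordance(pairs_from_counts(counts),
                                     type_map = tm[-1]),
               "J1")
})

test_that("filters are conjunctive: a doubly-violating pair reports both
           rules", {
  set.seed(95)
  seg <- toy_segment(len = 400)
  # 40 bp copy that also fails coverage against a shifted partner
  a <- toy_annos("seg1_A", 100L, 140L, "AluSx")
  b <- toy_annos("seg1_B", 130L, 300L, "AluSx")
  p <- extract_te_pairs(seg, a, b)
  tr <- attr(p, "trace")
  expect_true(grepl("min_len", tr$failed[1]))
  expect_true(grepl("min_cov", tr$failed[1]))
})
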