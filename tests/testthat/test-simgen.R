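test_that("library construction places exact diagnostic differences", {
  one <- make_subfamily_library(100, 1, seed = 1)
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$parent[1]))

  two <- make_subfamily_library(100, 2, diagnostic_per_split = 5, seed = 2)
  d <- sum(strsplit(two$consensus[1], "")[[1]] !=
             strsplit(two$consensus[2], "")[[1]])
  expect_equal(d, 5L)

  # chain topology: non-adjacent subfamilies differ at multiples of the step
  chain <- make_subfamily_library(200, 4, diagnostic_per_split = 3, seed = 3)
  d13 <- sum(strsplit(chain$consensus[1], "")[[1]] !=
               strsplit(chain$consensus[3], "")[[1]])
  expect_equal(d13, 6L)

  expect_identical(make_subfamily_library(100, 3, seed = 9),
                   make_subfamily_library(100, 3, seed = 9))

  expect_error(make_subfamily_library(60, 5, diagnostic_per_split = 20),
               "infeasible")
})

test_that("instances diverge at the binomial rate implied by identity", {
  lib <- make_subfamily_library(300, 1, identities = 1.0, seed = 4)
  sim <- simulate_instances(lib, 5, seed = 5)
  expect_true(all(sim$instances$sequence == lib$consensus))
  expect_true(all(sim$truth$realized_divergence == 0))

  lib9 <- make_subfamily_library(300, 1, identities = 0.9, seed = 4)
  sim9 <- simulate_instances(lib9, 1000, seed = 6)
  # mean mismatch fraction within 3 SE of the per-site substitution rate
  se <- sqrt(0.1 * 0.9 / (300 * 1000))
  expect_lt(abs(mean(sim9$truth$realized_divergence) - 0.1), 3 * se)

  lib2 <- make_subfamily_library(100, 2, frequencies = c(1, 0), seed = 7)
  sim2 <- simulate_instances(lib2, 200, seed = 8)
  expect_true(all(sim2$instances$true_subfamily == "SF01"))
})

test_that("per-instance substitution counts follow the binomial law", {
  lib <- make_subfamily_library(60, 1, identities = 0.9, seed = 11)
  sim <- simulate_instances(lib, 10000, seed = 12)
  counts <- round(sim$truth$realized_divergence * 60)
  # pool bins so every expected count is >= 5, then chi-square GOF
  probs <- dbinom(0:60, 60, 0.1)
  lo <- min(which(cumsum(probs) > 0.001)) - 1L
  hi <- max(which(rev(cumsum(rev(probs))) > 0.001)) - 1L
  bins <- c(-Inf, lo:hi, Inf)
  obs <- table(cut(counts, bins))
  expd <- diff(pbinom(bins, 60, 0.1))
  gof <- chisq.test(as.vector(obs), p = expd / sum(expd))
  expect_gt(gof$p.value, 0.01)
})

test_that("duplication emits positionally aligned copies at the right identity", {
  lib <- make_subfamily_library(300, 1, identities = 1.0, seed = 21)
  sim <- simulate_instances(lib, 20, seed = 22)

  perfect <- duplicate_with_divergence(sim, post_dup_identity = 1.0,
                                       flank_length = 100, seed = 23)
  expect_true(all(vapply(perfect$segments,
                         function(s) s$row_a == s$row_b, logical(1))))

  nofl <- duplicate_with_divergence(sim, post_dup_identity = 1.0,
                                    flank_length = 0, seed = 24)
  expect_equal(nofl$segments[[1]]$row_a, sim$instances$sequence[1])
  expect_equal(nofl$annotations$start[1], 0L)

  # column-identity oracle: both copies mutate independently at rate 0.05;
  # a column matches iff neither mutated, or both mutated to the same base
  lib2 <- make_subfamily_library(1000, 1, identities = 1.0, seed = 25)
  sim2 <- simulate_instances(lib2, 20, seed = 26)
  div <- duplicate_with_divergence(sim2, post_dup_identity = 0.95,
                                   flank_length = 500, seed = 27)
  p_match <- 0.95^2 + 0.05^2 / 3
  ids <- vapply(div$segments, segment_identity, numeric(1))
  n_cols <- 20 * 2000
  se <- sqrt(p_match * (1 - p_match) / n_cols)
  expect_lt(abs(mean(ids) - p_match), 3 * se)
})

test_that("gene conversion overwrites tracts exactly and logs ground truth", {
  lib <- make_subfamily_library(300, 1, identities = 1.0, seed = 31)
  sim <- simulate_instances(lib, 10, seed = 32)
  dup <- duplicate_with_divergence(sim, post_dup_identity = 1.0,
                                   flank_length = 50, seed = 33)

  none <- apply_gene_conversion(dup, donor_pool = sim$instances,
                                tract_range = c(50, 100), rate = 0, seed = 34)
  expect_identical(lapply(none$segments, `[[`, "row_a"),
                   lapply(dup$segments, `[[`, "row_a"))
  expect_true(all(vapply(none$truth$conversions, nrow, integer(1)) == 0L))

  # identity donor: sequence unchanged but the event is logged
  ident <- apply_gene_conversion(dup, donor_pool = sim$instances[1, ],
                                 tract_range = c(50, 100), rate = 1, seed = 35)
  expect_identical(lapply(ident$segments, `[[`, "row_a"),
                   lapply(dup$segments, `[[`, "row_a"))
  expect_true(all(vapply(ident$truth$conversions, nrow, integer(1)) == 1L))

  # divergent donor: the acceptor tract equals the donor tract afterwards
  donor_seq <- teaudit:::mutate_many(sim$instances$sequence[1], 0.2)$seqs
  donor <- tibble::tibble(true_subfamily = "DONOR", sequence = donor_seq)
  conv <- apply_gene_conversion(dup, donor_pool = donor,
                                tract_range = c(200, 200), rate = 1, seed = 36)
  for (i in seq_along(conv$segments)) {
    ev <- conv$truth$conversions[[i]]
    expect_equal(nrow(ev), 1L)
    row_nm <- if (ev$copy == "A") "row_a" else "row_b"
    got <- substr(conv$segments[[i]][[row_nm]],
                  50 + ev$tract_start + 1, 50 + ev$tract_end)
    want <- substr(donor_seq, ev$tract_start + 1, ev$tract_end)
    expect_equal(got, want)
    # tract lies inside the TE
    expect_gte(ev$tract_start, 0L)
    expect_lte(ev$tract_end, 300L)
  }

  expect_error(apply_gene_conversion(dup, donor_pool = donor,
                                     tract_range = c(500, 600), rate = 1,
                                     seed = 37),
               "longer than")
})

test_that("the generator is reproducible bit-for-bit from the seed", {
  run <- function() {
    lib <- make_subfamily_library(200, 3, seed = 41)
    sim <- simulate_instances(lib, 30, seed = 42)
    dup <- duplicate_with_divergence(sim, 0.95, 100, seed = 43)
    apply_gene_conversion(dup, sim$instances, c(50, 80), 0.5, seed = 44)
  }
  expect_identical(run(), run())
})
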