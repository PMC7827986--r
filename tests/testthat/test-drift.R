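test_that("diagnostic sites are the substitution columns of the alignment", {
  d <- diagnostic_sites("ACGT", "AGGT")
  expect_equal(nrow(d), 1L)
  expect_equal(d$pos, 1L)
  expect_equal(d$base_i, "C")
  expect_equal(d$base_j, "G")

  expect_equal(nrow(diagnostic_sites("ACGT", "ACGT")), 0L)

  # a deletion column is excluded: ACGGT vs ACT aligns with a gap, and only
  # substitution columns count
  d2 <- diagnostic_sites("AACCGGTT", "AACCTT")
  expect_true(all(d2$base_i != "-" & d2$base_j != "-"))

  expect_error(diagnostic_sites("", "ACGT"), "non-empty")
})

test_that("site fate probabilities follow the uniform-mutation closed forms", {
  p1 <- site_change_probs(1)
  expect_equal(p1$p_c, 1)
  expect_equal(p1$p_o, 0)

  p07 <- site_change_probs(0.7)
  expect_equal(p07$p_b, 0.1)
  expect_equal(p07$p_o, 0.2)
  expect_equal(p07$p_c, 0.875)
  expect_equal(p07$p_a + p07$p_b + p07$p_o, 1)

  p0 <- site_change_probs(0)
  expect_equal(p0$p_c, 0)
  expect_equal(p0$p_o, 2 / 3)

  expect_error(site_change_probs(1.2), "\\[0, 1\\]")
})

test_that("the binomial CDF handles edges as specified", {
  expect_equal(binom_cdf(1, 3, 0.5), 0.5)
  expect_equal(binom_cdf(5, 5, 0.3), 1)
  expect_equal(binom_cdf(10, 5, 0.3), 1)     # x >= n -> 1
  expect_equal(binom_cdf(-1, 5, 0.3), 0)     # x < 0 -> 0
  expect_equal(binom_cdf(0, 2, 0.9), 0.01)
  expect_equal(binom_cdf(2.9, 3, 0.5), binom_cdf(2, 3, 0.5))
})

test_that("conversion probability matches hand-computed cases", {
  expect_equal(conversion_prob(0, 0.8), 0)
  for (n in 1:5) expect_equal(conversion_prob(n, 1), 0)
  expect_equal(conversion_prob(1, 0.7), 0.1)
  expect_equal(conversion_prob(2, 0.7), 0.05)
})

test_that("conversion probability equals exhaustive per-site enumeration", {
  for (n in 1:6) {
    for (p_a in seq(0.5, 1.0, by = 0.1)) {
      expect_lt(abs(conversion_prob(n, p_a) - enum_conversion_prob(n, p_a)),
                1e-12)
      expect_lt(abs(conversion_prob(n, p_a, strict = FALSE) -
                      enum_conversion_prob(n, p_a, strict = FALSE)),
                1e-12)
    }
  }
})

test_that("with no route to non-informative values the model collapses to a
           single binomial term", {
  # force P(O) = 0 in the enumeration (mutations go only to the j base);
  # the remaining mass is the k = 0 term: B(floor((n-1)/2), n, p_c)
  for (n in 1:6) {
    p_c <- 0.8
    probs <- c(stay = p_c, to_j = 1 - p_c, other = 0)
    states <- expand.grid(rep(list(1:3), n))
    total <- 0
    for (r in seq_len(nrow(states))) {
      s <- as.integer(states[r, ])
      if (sum(s == 2) > sum(s == 1)) total <- total + prod(probs[s])
    }
    expect_equal(total, pbinom(floor((n - 1) / 2), n, p_c), tolerance = 1e-12)
  }
})

test_that("the conversion matrix composes diagnostic sites with the model", {
  lib <- toy_library(c("AAAAAAAAAA", "AAAAAAAATT", "AAAATTTTTT"),
                     identity = c(0.9, 0.8, 0.9))
  dm <- conversion_matrix(lib)
  expect_equal(dm$n_sites["SF01", "SF02"], 2L)
  expect_equal(dm$n_sites["SF01", "SF03"], 6L)
  expect_equal(unname(diag(dm$pairwise)), rep(0, 3))
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(dm$pairwise[i, j],
                 conversion_prob(dm$n_sites[i, j], lib$identity[i]))
  }
  # asymmetry when identities differ
  expect_false(dm$pairwise["SF01", "SF02"] == dm$pairwise["SF02", "SF01"])

  same <- toy_library(c("AAAA" , "AAAA"))
  expect_error(conversion_matrix(same, identities = c(SF01 = 0.9)),
               "missing identity")
  dm2 <- conversion_matrix(toy_library(c("AAAAAAAAAA", "AAAAAAAAAA")))
  expect_equal(dm2$pairwise["SF01", "SF02"], 0)
})

test_that("type aggregation is a frequency-weighted average", {
  # one subfamily per type: cells equal the pairwise entries directly
  lib <- toy_library(c("AAAAAAAAAA", "AAAAAAAATT", "AAAATTTTTT"),
                     type_label = c("J", "S", "Y"))
  dm <- conversion_matrix(lib)
  tt <- aggregate_by_type(dm)
  expect_equal(tt$to_S[tt$type == "J"], dm$pairwise["SF01", "SF02"])
  expect_equal(tt$to_Y[tt$type == "J"], dm$pairwise["SF01", "SF03"])

  # combined mismatch equals the row sum of the type cells
  cells <- as.matrix(tt[, paste0("to_", tt$type)])
  expect_equal(tt$combined_mismatch, unname(rowSums(cells)))

  # hand-weighted average: within-type totals 0.1 and 0.2, weights 0.25/0.75
  dm2 <- dm
  dm2$pairwise <- matrix(0, 3, 3, dimnames = dimnames(dm$pairwise))
  dm2$pairwise["SF01", "SF02"] <- 0.1
  dm2$pairwise["SF02", "SF01"] <- 0.2
  dm2$meta$type_label <- c("X", "X", "Z")
  dm2$meta$frequency <- c(0.25, 0.75, 1)
  tt2 <- aggregate_by_type(dm2)
  expect_equal(tt2$to_X[tt2$type == "X"], 0.25 * 0.1 + 0.75 * 0.2)

  dm3 <- dm
  dm3$meta$frequency <- c(0, 0, 1)
  dm3$meta$type_label <- c("J", "J", "Y")
  expect_error(aggregate_by_type(dm3), "zero total frequency")
})

test_that("simulated diagnostic-site drift matches the closed form", {
  # two subfamilies separated by 10 diagnostic sites; instances of the first
  # accumulate substitutions at rate 1 - p_a; annotation by strict
  # diagnostic-site majority, ties kept as the original subfamily
  n_sites <- 10L
  p_a <- 0.85
  n_inst <- 20000L
  lib <- make_subfamily_library(100, 2, diagnostic_per_split = n_sites,
                                frequencies = c(1, 0),
                                identities = p_a, seed = 81)
  sim <- simulate_instances(lib, n_inst, seed = 82)
  ci <- strsplit(lib$consensus[1], "")[[1]]
  cj <- strsplit(lib$consensus[2], "")[[1]]
  sites <- which(ci != cj)
  flips <- vapply(sim$instances$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch[sites] == cj[sites]) > sum(ch[sites] == ci[sites])
  }, logical(1), USE.NAMES = FALSE)
  expected <- conversion_prob(n_sites, p_a)
  se <- sqrt(expected * (1 - expected) / n_inst)
  expect_lt(abs(mean(flips) - expected), 3 * se)
})
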