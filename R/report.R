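#' Smallest best-candidate confidence of a pair
#'
#' For a replicate pair, the lower of the two members' best-candidate
#' confidences is a proxy for the confidence that *both* members are
#' correctly annotated.
#'
#' @param conf_a,conf_b best-candidate confidences in (0, 1\]; vectorised.
#' @return `pmin(conf_a, conf_b)`.
#' @export
smallest_best_confidence <- function(conf_a, conf_b) {
  if (any(conf_a <= 0 | conf_a > 1 | conf_b <= 0 | conf_b > 1, na.rm = TRUE)) {
    abort("confidences must lie in (0, 1]")
  }
  pmin(conf_a, conf_b)
}

#' Compare smallest-best-confidence distributions of concordant and
#' discordant pairs
#'
#' Pairs are binned by smallest-best-confidence separately for the concordant
#' and the discordant group; each histogram is normalised so its bin
#' fractions sum to 1. The two groups are additionally compared with the
#' two-sample Kolmogorov-Smirnov test on the raw (unbinned) values — binning
#' is presentation only.
#'
#' @param pair_confidence tibble with columns `conf_a`, `conf_b` and
#'   `concordant` (and optionally `pair_id`).
#' @param bin_width histogram bin width on \[0, 1\].
#' @return an object of class `confidence_distributions`: list with `values`
#'   (the input plus `smallest_best`), `bins` (tibble: `group`, `bin_lo`,
#'   `bin_hi`, `fraction`), `ks_statistic` and `ks_p_value` (`NA`, with a
#'   warning, when either group is empty).
#' @export
confidence_distributions <- function(pair_confidence, bin_width = 0.05) {
  v <- pair_confidence
  v$smallest_best <- smallest_best_confidence(v$conf_a, v$conf_b)
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  groups <- list(concordant = v$smallest_best[v$concordant],
                 discordant = v$smallest_best[!v$concordant])
  bins <- purrr::list_rbind(purrr::map(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) == 0) return(NULL)
    cnt <- table(cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE))
    tibble(group = g, bin_lo = breaks[-length(breaks)],
           bin_hi = breaks[-1], fraction = as.vector(cnt) / sum(cnt))
  }))
  if (any(lengths(groups) == 0)) {
    warn("one concordance group is empty; Kolmogorov-Smirnov test skipped")
    ks_stat <- NA_real_
    ks_p <- NA_real_
  } else {
    ks <- suppressWarnings(ks.test(groups$discordant, groups$concordant))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  }
  structure(
    list(values = v, bins = bins, ks_statistic = ks_stat, ks_p_value = ks_p,
         bin_width = bin_width),
    class = "confidence_distributions")
}

#' @export
print.confidence_distributions <- function(x, ...) {
  n_c <- sum(x$values$concordant)
  n_d <- sum(!x$values$concordant)
  cat(sprintf(
    "<confidence_distributions: %d concordant, %d discordant; KS D = %s, p = %s>\n",
    n_c, n_d,
    if (is.na(x$ks_statistic)) "-" else sprintf("%.3f", x$ks_statistic),
    if (is.na(x$ks_p_value)) "-" else format(x$ks_p_value, digits = 3)))
  invisible(x)
}

#' @rdname confidence_distributions
#' @param x a `confidence_distributions` object.
#' @param ... unused.
#' @method glance confidence_distributions
#' @export
glance.confidence_distributions <- function(x, ...) {
  tibble(
    n_concordant = sum(x$values$concordant),
    n_discordant = sum(!x$values$concordant),
    median_concordant = median(x$values$smallest_best[x$values$concordant]),
    median_discordant = median(x$values$smallest_best[!x$values$concordant]),
    ks_statistic = x$ks_statistic,
    ks_p_value = x$ks_p_value
  )
}

default_audit_config <- function() {
  list(
    ancestral_length = 300L,
    n_subfamilies = 6L,
    diagnostic_per_split = 4L,
    type_partition = 2L,
    frequencies = 1,
    identities = 0.92,
    n_instances = 300L,
    post_dup_identity = 0.96,
    flank_length = 500L,
    conversion_rate = 0,
    tract_range = c(50L, 250L),
    match_score = 9L,
    mismatch_score = -15L,
    min_len = 50L,
    min_cov = 0.8,
    window = 100L,
    alpha = 0.001,
    bin_width = 0.05,
    seed = 1L
  )
}

#' Run the whole annotation-reliability audit on simulated data
#'
#' Executes the full pipeline: simulate a subfamily library and diverged
#' instances, duplicate them inside flanked segments, optionally apply gene
#' conversion, re-annotate every copy against the library by highest
#' positional score, extract filtered replicate pairs, tabulate discordance,
#' compute the point-mutation drift matrix and its type table, scan pairs for
#' recombination signatures, and compare confidence distributions. The run
#' is reproducible bit-for-bit from the configuration and seed.
#'
#' @param config named list overriding any of the defaults (see
#'   `teaudit:::default_audit_config()`): simulation sizes, identities,
#'   conversion rate, scoring, filter and scan parameters, `seed`.
#' @return an object of class `te_audit_report`: list with `library`,
#'   `pairs` (annotated, labelled, with per-pair scan results columns),
#'   `discordance` ([summarize_discordance()] result), `drift_types`
#'   ([aggregate_by_type()] table), `drift_matrix`, `recomb`
#'   ([summarize_recombination()] table), `confidence`
#'   ([confidence_distributions()] object), `filter_counts`, `lambda` and
#'   `config`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_audit_config(), config)
  set.seed(cfg$seed)

  library <- make_subfamily_library(
    ancestral_length = cfg$ancestral_length,
    n_subfamilies = cfg$n_subfamilies,
    diagnostic_per_split = cfg$diagnostic_per_split,
    type_partition = cfg$type_partition,
    frequencies = cfg$frequencies,
    identities = cfg$identities
  )
  sim <- simulate_instances(library, cfg$n_instances)
  dup <- duplicate_with_divergence(sim, post_dup_identity = cfg$post_dup_identity,
                                   flank_length = cfg$flank_length)
  if (cfg$conversion_rate > 0) {
    dup <- apply_gene_conversion(dup, donor_pool = sim$instances,
                                 tract_range = cfg$tract_range,
                                 rate = cfg$conversion_rate)
  }

  m <- matrix(as.integer(cfg$mismatch_score), 4, 4,
              dimnames = list(DNA_BASES, DNA_BASES))
  diag(m) <- as.integer(cfg$match_score)
  smat <- scoring_matrix(m)
  lambda <- infer_lambda(smat)

  # re-annotate every copy of every TE against the library
  flank <- cfg$flank_length
  te_len <- nchar(sim$instances$sequence)
  calls <- list()
  for (i in seq_len(nrow(sim$instances))) {
    id <- sim$instances$instance_id[i]
    seg <- dup$segments[[id]]
    for (copy in c("A", "B")) {
      row <- if (copy == "A") seg$row_a else seg$row_b
      te_seq <- substr(row, flank + 1L, flank + te_len[i])
      cand <- score_candidates(te_seq, library, smat, mode = "positional")
      call <- annotate_instance(cand)
      conf <- confidence(cand, lambda)
      calls[[length(calls) + 1L]] <- tibble(
        instance_id = id, copy = copy,
        chrom = paste0(id, "_", copy),
        subfamily = call$subfamily, score = call$score, tie = call$tie,
        best_confidence = unname(conf$confidences[[conf$best]])
      )
    }
  }
  calls <- dplyr::bind_rows(calls)
  annos <- te_annotations(
    chrom = calls$chrom,
    start = flank, end = flank + rep(te_len, each = 2L),
    strand = "+", family = attr(library, "family"),
    subfamily = calls$subfamily, score = calls$score,
    source_id = paste0(calls$instance_id, "/", calls$copy),
    ambiguous = FALSE
  )

  pairs <- list()
  traces <- list()
  for (id in names(dup$segments)) {
    seg <- dup$segments[[id]]
    p <- extract_te_pairs(seg,
                          annos[annos$chrom == seg$interval_a$chrom, ],
                          annos[annos$chrom == seg$interval_b$chrom, ],
                          min_len = cfg$min_len, min_cov = cfg$min_cov)
    traces[[id]] <- attr(p, "trace")
    if (nrow(p) > 0) pairs[[id]] <- p
  }
  pairs <- dplyr::bind_rows(pairs)
  trace <- dplyr::bind_rows(traces)
  filter_counts <- c(
    candidates = nrow(trace), kept = sum(trace$kept),
    table(unlist(strsplit(trace$failed[trace$failed != ""], ",")))
  )
  if (nrow(pairs) == 0) abort("no TE pairs survived filtering")
  pairs <- label_concordance(pairs)

  fam <- attr(library, "family")
  family_map <- setNames(rep(fam, nrow(library)), library$name)
  type_map <- setNames(library$type_label, library$name)
  discordance <- summarize_discordance(pairs, family_map, type_map)

  dmat <- conversion_matrix(library)
  drift_types <- aggregate_by_type(dmat)

  scans <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    seg <- dup$segments[[pairs$seg_id[k]]]
    bg <- segment_identity(seg)
    scans[[k]] <- window_scan(
      pair_alignment(seg, pairs$col_start[k], pairs$col_end[k]),
      background_identity = bg, window = cfg$window, alpha = cfg$alpha)
  }
  pairs$scan <- scans
  pairs$recomb_flagged <- purrr::map_lgl(scans, "flagged")
  recomb <- summarize_recombination(pairs, type_map)

  pair_conf <- tibble(
    pair_id = pairs$pair_id,
    conf_a = calls$best_confidence[match(pairs$source_a,
                                         paste0(calls$instance_id, "/", calls$copy))],
    conf_b = calls$best_confidence[match(pairs$source_b,
                                         paste0(calls$instance_id, "/", calls$copy))],
    concordant = pairs$concordant
  )
  conf_dist <- if (nrow(pair_conf) > 0) {
    confidence_distributions(pair_conf, bin_width = cfg$bin_width)
  } else NULL

  structure(
    list(library = library, calls = calls, pairs = pairs,
         discordance = discordance, drift_matrix = dmat,
         drift_types = drift_types, recomb = recomb,
         confidence = conf_dist, filter_counts = filter_counts,
         lambda = lambda, truth = dup$truth, config = cfg),
    class = "te_audit_report")
}

#' @export
print.te_audit_report <- function(x, ...) {
  cat(sprintf("<te_audit_report: %d pairs, %.1f%% discordant, %d flagged>\n",
              nrow(x$pairs),
              100 * mean(!x$pairs$concordant),
              sum(x$pairs$recomb_flagged)))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `te_audit_report`.
#' @param ... unused.
#' @method glance te_audit_report
#' @export
glance.te_audit_report <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    percent_discordant = 100 * mean(!x$pairs$concordant),
    percent_flagged = 100 * mean(x$pairs$recomb_flagged),
    lambda = x$lambda,
    ks_statistic = x$confidence$ks_statistic %||% NA_real_,
    ks_p_value = x$confidence$ks_p_value %||% NA_real_
  )
}
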