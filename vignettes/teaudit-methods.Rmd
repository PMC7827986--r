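---
title: "Auditing TE subfamily annotation with replicate pairs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing TE subfamily annotation with replicate pairs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teaudit)
```

## The problem

Transposable-element (TE) annotation assigns each genomic TE remnant to a
family (Alu, L1, ...) and, within a family, to a subfamily defined by shared
diagnostic sequence variants. Subfamily calls are made by aligning the
genomic sequence against every consensus in a library and keeping the single
highest-scoring candidate. When several subfamily consensuses are nearly
identical, this winner-takes-all adjudication is fragile: a handful of point
mutations, or a gene-conversion tract copied in from a cousin element, can
flip the winner.

`teaudit` quantifies that fragility using *biological replicates*: pairs of
TE copies descended from a single insertion event, created either by
segmental duplication within one genome or by speciation between two
genomes. Both copies of a replicate pair should receive the same subfamily
call; a pair whose calls differ is *discordant*. The package extracts
filtered replicate pairs, tabulates discordance, predicts how much
discordance pure point-mutation drift can explain, scans pairs for
recombination signatures, and attaches an ensemble confidence to every
subfamily call. A synthetic-data generator with complete ground truth makes
the whole audit runnable end-to-end without any genome downloads.

## Replicate pairs and filters

A segmental duplication is represented as a two-row gapped alignment of the
two copies (`segment_alignment`). TE annotations on each copy are projected
through the alignment columns, and two TEs form a candidate pair when they
share at least one column. A candidate is kept only if all of the following
hold (`extract_te_pairs()`):

* both copies are longer than `min_len` (default 50 bp);
* the shared columns cover at least `min_cov` (default 80%) of each copy's
  aligned columns, reciprocally;
* neither TE overlaps more than one TE on the other copy;
* the projected overlap is one contiguous alignment — no single
  indel/unaligned block inside it exceeds `max_gap_run` columns
  (default 30; the filter's intent is to drop pairs related through a large
  post-duplication insertion or deletion, and no published threshold exists,
  so the block length is exposed as a parameter);
* neither member is an ambiguous, family-only call (e.g. a bare `Alu`).

Filters are conjunctive, so the retained set is independent of evaluation
order; every candidate's outcome is recorded in a trace attribute so that
exclusion counts can always be reported. Coverage is measured on alignment
columns rather than raw base pairs so that gapped (indel-containing)
alignments are handled consistently.

For annotation sets already mapped into a common coordinate system (the
two-genome comparison; the coordinate mapping itself is out of scope),
`pair_by_overlap()` applies the same filters with base-pair overlap playing
the role of shared columns, and matches greedily by descending overlap.

Discordance is tabulated per family and as a type-by-type cross table
(`summarize_discordance()`). In the cross table a discordant pair whose
members belong to two different types is counted once in each member's row —
the double counting that makes row percentages exceed the per-family rates —
while a within-type discordant pair is a single case in its diagonal cell.

## Drift of diagnostic sites by point mutation

Let `p_a` be the probability that a site of an inserted instance still
matches its subfamily consensus (estimated in practice as mean percent
identity between instances and consensus). A mutated site lands uniformly on
the three other nucleotides. For the `n` diagnostic sites separating
subfamily *i* from subfamily *j*, each site independently:

* stays diagnostic for *i* with probability `p_a`;
* switches to the *j*-diagnostic base with probability `(1 - p_a)/3`;
* becomes non-informative ("other") with probability `2(1 - p_a)/3`.

The instance comes to look like *j* when, among sites that did not become
non-informative, the *j*-agreeing sites strictly outnumber the *i*-agreeing
ones. Summing over the number `k` of non-informative sites gives

$$P(S{:}\,i\to j) \;=\; \sum_{k=0}^{n-1} \binom{n}{k}\,(1-P_O)^{\,n-k} P_O^{\,k}\,
  B\!\left(\Big\lfloor \tfrac{n-k-1}{2} \Big\rfloor,\; n-k,\; p_c\right),
  \qquad p_c = \frac{3\,p_a}{1+2\,p_a},$$

implemented in `conversion_prob()`. The strict-majority bound
$\lfloor (n-k-1)/2 \rfloor$ is the primary definition; a relaxed
"at least half" reading (ties convert) is available via `strict = FALSE`
for sensitivity analysis. Note the sum stops at `k = n - 1`: an instance
whose diagnostic sites all became non-informative is not counted as
converted, and the relaxed variant keeps that convention. The implementation
is verified against exhaustive enumeration of all $3^n$ per-site outcome
vectors for $n \le 6$, to $10^{-12}$.

`conversion_matrix()` applies this to every ordered subfamily pair, taking
`n` from the substitution columns of the pairwise consensus alignment
(indel columns are never diagnostic — the model is substitution-only), and
`aggregate_by_type()` produces the type-level table as a genome-frequency
weighted average, with a combined-mismatch column that sums conversion into
all other subfamilies regardless of type.

## Recombination signatures

Gene conversion from a diverged donor leaves a local dip in the identity of
a duplication alignment. `window_scan()` splits a TE pair's alignment into
non-overlapping windows of 100 non-gap columns (columns gapped in either row
are skipped when counting, exactly as in the identity definition; trailing
columns short of a full window are unused), counts identical columns per
window, and compares the *smallest* window count against the background
identity of the **full containing segment** using the binomial CDF. The
smallest-count p-value is Bonferroni-multiplied by the number of windows in
that pair; a pair is flagged at corrected $p < 0.001$. No across-pair
correction is applied — the procedure controls the family-wise error per
pair, which is what the flagged-fraction summaries assume. The scan can only
detect two-breakpoint events interior to a TE; single-breakpoint
recombination splits the duplication itself and escapes this design.

## Ensemble annotation confidence

Integer alignment scores are treated as scaled base-2 log-odds of homology:
$\text{score}(a,b) = \mathrm{int}(\lambda \log_2 \frac{P(a,b)}{P(a)P(b)})$.
Under that reading, competing candidate scores for the same genomic range
convert to a posterior over subfamilies:

$$\mathrm{Conf}(q_i \mid t) = \frac{2^{\,s_i/\lambda}}{\sum_j 2^{\,s_j/\lambda}},$$

a softmax in which the non-homology likelihood of $t$ cancels
(`confidence()`). The maximum score is subtracted before exponentiation, so
the result is exactly invariant to shifting all scores by a constant and
cannot overflow. Equal top scores split confidence evenly — the two-way tie
gives 50% each, the honest ceiling for indistinguishable candidates — and
ties are reported. Gap penalties contribute to scores but carry no
probabilistic interpretation here; all candidates are assumed to cover the
same genomic range. Base-2 exponentiation is used throughout, which fixes
the otherwise-unspecified log base of the score construction.

`infer_lambda()` recovers $\lambda$ from a scoring matrix and background
letter frequencies (uniform by default; region-specific backgrounds can be
supplied) as the unique positive root of
$\sum_{a,b} p_a p_b\, 2^{s_{ab}/\lambda} = 1$, located by bisection on
$1/\lambda$ to a relative tolerance of $10^{-10}$. The root exists iff the
expected score under the background is negative and some score is positive;
both conditions are checked and violated inputs raise a no-valid-lambda
error.

**Validating the solver.** The natural construct-and-recover test builds
scores from a known joint distribution at scale $\lambda_0$ and asks for
$\lambda_0$ back. With unrounded scores, recovery is exact for *any* joint
distribution. Integer rounding, however, perturbs the root by roughly
$0.5/H$ in relative terms, where $H$ is the relative entropy (in bits,
times $\lambda_0$) of the joint against the background — for nucleotide
matrices $H$ is at most a couple of bits, so at $\lambda_0 = 1$ generic
joints can miss by 25% or more, through no fault of the solver. The test
suite therefore draws random joints from the lattice family in which
$\lambda_0 \log_2 \frac{P(a,b)}{P(a)P(b)}$ is exactly integer: a random
symmetric integer matrix is fixed and the background is solved on the
simplex so the consistency condition holds exactly. On that family the
log-odds construction rounds losslessly and the solver must recover
$\lambda_0$ to its bisection tolerance, which is the property worth
guaranteeing.

For a replicate pair, the lower of the two members' best-candidate
confidences (`smallest_best_confidence()`) proxies the confidence that both
members are correctly annotated. `confidence_distributions()` bins that
quantity separately for concordant and discordant pairs (bin width 0.05 by
default — presentation only) and compares the groups with the two-sample
Kolmogorov–Smirnov test on the raw values.

## The synthetic-data generator

`make_subfamily_library()` builds a subfamily library by serial splitting: a
random ancestral consensus, then each further subfamily derived from the
previous one by substituting exactly `diagnostic_per_split` fresh positions
(never reused across splits, so subfamilies $i$ and $j$ differ at exactly
$|i-j| \cdot \texttt{diagnostic\_per\_split}$ sites). `simulate_instances()`
draws instances proportional to genome-frequency weights and applies i.i.d.
per-site substitution at rate `1 - identity`, uniformly over the three
alternative bases — deliberately the same single-event, Jukes–Cantor-like
model the drift equations assume, so the generator and the model can be
checked against each other. `duplicate_with_divergence()` embeds each
instance in uniform random flanks, duplicates the segment once (two copies,
matching the audit's restriction to two-copy duplications), and mutates both
copies independently at rate `1 - post_dup_identity`; flanks diverge at the
same rate as the TE, reflecting the assumption that identity is consistent
across a duplicated segment. `apply_gene_conversion()` overwrites a
uniformly placed tract (uniform length within `tract_range`, fully inside
one TE copy) with the homologous region of a donor instance and logs every
event in the truth table.

Default conditions: 2 kb segments around 300 bp elements, post-duplication
identity 0.95–0.96 (segment pairs ≥ 90% identical, the regime in which real
duplication sets are ascertained), instance-to-consensus identities around
0.9, conversion tracts of 50–500 bp (conversion events are typically at
least 50 bp). The defaults are config-exposed but are not tuned per run.

The substitution-only default keeps copies positionally aligned, which is
what makes `positional` scoring and direct column bookkeeping exact. What
the generator does **not** emulate: insertion-target preference, 5'
truncation of L1-like elements, indel accumulation (an indel mode would
break positional alignment and is not used by the shipped analyses), tandem
duplication, selection, and GC-content heterogeneity. Green tests on
synthetic data therefore demonstrate internal consistency of the method —
filters, models, statistics and their error rates under the stated
assumptions — not the accuracy of any particular genome's annotation.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; the only
  conversions live in the readers/writers (RepeatMasker's 1-based inclusive
  records, BED passthrough).
* RepeatMasker `C` strand maps to `-`; `(left)` columns are parsed and
  discarded; fragment IDs are exposed as `source_id` but fragments are never
  merged.
* Adjudication ties break to the lexicographically smallest subfamily name —
  deterministic and documented, since annotation tools do not document
  theirs — and the tie is always reported.
* `N` letters are legal in alignments; `N` columns count as non-gap and
  non-identical.
* Identity-model inputs `P(A_i)` come from an explicit table, from mean
  `1 - divergence` of annotations, or from simulation truth — never from a
  hidden estimate.
* Degenerate inputs fail loudly: empty candidate lists, alignments with no
  non-gap columns, zero-weight types, unmapped subfamilies and out-of-range
  probabilities all raise errors naming the offender.

## Problem sizes used by the shipped analyses

The test-suite and the acceptance script exercise the audit at desk scale:
exhaustive drift enumeration at $n \le 6$ sites; drift self-consistency on
$10^5$ simulated instances at 10 diagnostic sites and `p_a = 0.85`; the
recombination null on 2,000 pairs at 95% pair identity (three 100-column
windows per 300 bp element) and power on 500 pairs receiving one 200 bp
tract from a 20%-diverged donor. Power pairs use 4 kb segments so that the
measured background identity reflects the duplication itself rather than the
injected tract — with shorter segments the tract would contaminate the
background estimate it is being tested against. End-to-end pipeline runs use
a few hundred instances over six subfamilies, and the confidence-separation
demonstration uses a deliberately hard clique: three subfamilies two
diagnostic sites apart, where discordant pairs concentrate near 50%
confidence while concordant pairs sit near 1.

## Known limitations

Published genome-scale figures (absolute pair counts, type-table entries,
genome-wide medians) depend on specific genome assemblies, repeat libraries
and duplication databases, and are out of reach of — and out of scope for —
the synthetic audit; the package reproduces the *arithmetic* of such tables
and the *statistical behaviour* of the methods. The recombination scan
underestimates event frequency by construction (trailing window columns are
unused, single-breakpoint events escape, and conversion from highly similar
donors leaves no identity dip). The confidence model ignores gap-penalty
probabilities and assumes equal genomic coverage of all candidates.
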