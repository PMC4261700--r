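---
title: "Methods: host-associated transcriptome divergence and differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host-associated transcriptome divergence and differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

When conspecific insect strains are kept on different host plants for many
generations, two transcriptome-level questions arise: how much sequence
divergence has accumulated between the strains, and which transcripts have
shifted in expression. `hadtx` implements a desk-scale, fully tested version
of the standard comparative pipeline for this setting: separate transcript
assemblies per strain, ortholog pairing by reciprocal best match, partition
of each ortholog into 5'UTR / CDS / 3'UTR, per-region substitution
divergence, Ka/Ks-based selection scanning, and count-based differential
expression with cross-strain and cross-sex intersection.

Because real strain libraries of this kind are rarely deposited, the package
treats validation as a first-class concern: a simulator
(`simulate_transcript_pairs()`, `simulate_count_matrix()`) generates data
with the statistical structure the analysis assumes and records complete
ground truth, so every stage can be checked for recovery of known
parameters.

# Orthology

`similarity_search()` is an exact-k-mer-seeded local search: subjects are
indexed by words of length 11 (the `word_size` parameter), and a subject
becomes an alignment candidate when it shares at least `min_seed_hits = 2`
distinct words with the query on a strand (the classic two-hit heuristic;
a single chance 11-mer between unrelated sequences is common enough that
extending every one roughly decuples the work while contributing no true
pairs). Candidates are aligned with affine-gap local alignment (match +2,
mismatch -3, gap open 5, gap extend 2 — conventional nucleotide-search
scoring), on both strands; minus-strand hits are reported in query-forward
coordinates with a strand flag. All coordinates are 0-based half-open
internally.

Two deliberate conventions:

* **Score cutoff rather than e-value.** E-values of the original search
  tools depend on their database sizes, which have no analogue here. Hits
  are filtered at a score threshold (`min_score = 40`, roughly a 20-base
  perfect match); `calibrate_score_threshold()` derives a data-driven
  threshold as the 99.9th percentile of scores against shuffled subjects.
  An extreme-value e-value surrogate is still reported per hit for
  interoperability.
* **Ties break to "no pair".** `reciprocal_best_matches()` pairs (a, b)
  only when each is the other's *unique* top-scoring hit, and
  `map_to_reference()` leaves a transcript unmapped when its best reference
  is tied. This trades recall for precision and keeps the pipeline
  deterministic.

Orthologs are then double-filtered (`filter_orthologs()`): both members
must map to the same pooled-reference transcript and be annotated to the
same protein (best six-frame BLOSUM62 local alignment above a score cutoff,
default 100). Every dropped pair carries a reason code so attrition is
auditable.

# CDS/UTR annotation

`locate_cds()` turns a protein hit into transcript structure: the CDS frame
is the hit frame; the start is the nearest in-frame ATG at or upstream of
the hit (never crossing an in-frame stop; falling back to the hit start
with a `partial_start` flag); the end is the first in-frame stop at or
downstream of the hit. Transcripts are rejected when an in-frame stop lies
strictly inside the hit region (`internal_stop`) or the CDS is shorter than
150 bases (`too_short`).

The stop codon is assigned to neither the CDS nor the 3'UTR: it is an
excluded three-base buffer. It sits under qualitatively different selection
from both flanks, and excluding it avoids attributing its substitutions to
either region; the choice is configurable in the sense that the partition
returns it separately. UTR region pairs additionally require at least 10
bases on both sides (`min_len`) — too-short UTRs produce divergence
estimates with enormous variance; this is also why UTR pair counts fall
below ortholog counts in the report.

# Divergence and Ka/Ks

Region pairs are aligned globally (affine gaps, same scoring as the
search); columns with a gap or an N on either side are excluded from the
denominator, and divergence is substitutions over bases compared.
Per-region summaries are unweighted means of per-pair fractions, matching
the usual presentation (pair count, mean percent).

Two Ka/Ks estimators are implemented side by side:

* `ng86_kaks()` — transparent equal-weight counting: per-codon site counts
  enumerate the nine single-base mutants, with stop-codon mutants removed
  from each position's denominator so every sense codon contributes exactly
  three sites; substitution counts average over all orderings of the
  differing positions (orderings through stop codons dropped first and
  reinstated, with stop steps counted nonsynonymous, only when every
  ordering is blocked); Jukes-Cantor correction is applied separately to
  the synonymous and nonsynonymous proportions.
* `yn00_kaks()` — the headline, transition/transversion-aware
  approximation: kappa is initialized from fourfold-degenerate and
  nondegenerate site comparisons (each K80-corrected, pooled by site
  count), site counts are weighted by kappa and F3x4 codon frequencies,
  substitution counts are split into transitions and transversions during
  pathway averaging, and K80 corrections are applied separately to the
  synonymous and nonsynonymous proportions. Kappa and the site counts are
  then iterated to a fixed point (tolerance 1e-6, at most 100 rounds; the
  update re-estimates kappa from the pooled corrected transition and
  transversion distances at synonymous and nonsynonymous sites).
  Non-convergence is flagged and the equal-weight result recorded as a
  fallback.

Numerical edge cases: a proportion at or above 3/4 (Jukes-Cantor) or a
non-positive logarithm argument (K80) flags the pair `saturated` with NA
distances. `Ks = 0` with `Ka > 0` is reported as *undefined* and tallied as
a positive-selection *candidate* rather than an infinite ratio — pairs
without observed synonymous change carry no usable denominator and would
otherwise inflate the "ratio > 1" count. Classification uses ratio > 1
(positive), < 1 (purifying), = 1 (neutral), with the scatter banding
(>1, 0.5–1, <0.5) reported alongside.

Identity with any particular external Ka/Ks tool is *not* claimed; the
stop-codon and multiple-hit conventions above are stated precisely because
published implementations differ in them. Correctness is instead pinned by
brute-force enumeration oracles (site counts and pathway averages for every
sense codon pair) and by parameter recovery from the simulator.

# Differential expression

Between-library normalization re-implements the trimmed mean of M-values
from its published definition (reference column = upper-quartile closest to
the mean; 30%/5% two-sided trims on M and A; precision-weighted mean;
factors rescaled to geometric mean 1) and is cross-checked against the
reference implementation in the test suite.

The two-library test follows the MA-plot random-sampling model: under the
null, the first count given the total `t = k1 + k2` is binomial with
success probability `n1/(n1+n2)` (effective library sizes). The reported
`z` is the plain normal deviate of `k1` under that model and the p-value
doubles the smaller *skewness-corrected* (second-order Edgeworth) normal
tail. This is the continuous analogue of the exact two-sided mid-p, the
convention adopted here for the discrete conditional test: across totals
≥ 50 the approximation stays within 0.006 of the exact mid-p, and its null
type-I error at 0.05 sits near 0.048 — a plain continuity-corrected tail
instead tracks the conservative full-tail p-value and pushes the null
rejection rate to ~0.038 at typical per-gene totals. Zero counts are offset
by 0.5 in M and A only, never in the test's counts.

q-values use the pi0-smoothing estimator (lambda grid 0.05–0.95, cubic
smoothing spline evaluated at the grid end) with a Benjamini-Hochberg
fallback below 10 p-values. Calls require `q < 0.05` *and*
`|log2 fold change| > 1`; the significance gate is on Q by default (the
fold-change-plus-Q combination is the one the tallies mirror), with both
thresholds explicit arguments. Orientation: "up" means higher in the
*original-host* library. Intersections across contrasts and sexes are
exact set algebra (`intersect_up_sets()`).

# The simulator

`simulate_transcript_pairs()` emulates one ancestral transcript pool
diverging on a derived host: per gene, an ancestral transcript
(5'UTR + ATG-initiated CDS + stop + 3'UTR) and a derived copy. UTR sites
substitute independently at their region rates; the CDS evolves by repeated
single-site events: a site is drawn uniformly, a target base with
transition weight kappa, stop-creating changes are rejected and resampled,
and nonsynonymous changes are accepted with probability proportional to
omega (acceptance `omega/max(1, omega)` versus `1/max(1, omega)`, so the
expected nonsynonymous/synonymous rate ratio equals omega for any omega).
The per-region substitution *count* is binomial at the configured rate, so
the configured value is the expected realized divergence. By default each
site is hit at most once, making truth counts exactly recountable from the
emitted sequences; a with-replacement mode exists for testing multiple-hit
corrections. The stop codon is an unmutated buffer. All randomness flows
from the single `seed` through one generator (`withr::with_seed`), giving
byte-identical reruns.

Defaults are chosen to mimic the reported magnitudes for host-strain
comparisons in this system: per-site divergence 0.23% (5'UTR), 0.13% (CDS),
0.19% (3'UTR); kappa 2 (a typical insect nuclear transition bias); a 5%
fraction of genes under positive selection (omega 2) against a purifying
background (omega 0.2); CDS mean length 450 bases (minimum 150), UTR means
100/150 bases; two libraries of 10^6 reads; 5% planted differentially
expressed genes at 4-fold change. Only ranges, not per-gene distributions,
are reported for the real data, so the defaults target the range means and
make no claim about the real variance. Per-gene baseline abundances are
gamma (shape 2) — right-skewed like real expression but lighter-tailed;
counts are multinomial per library.

What the simulator does *not* emulate: indels (substitutions only, so the
global aligner is exercised but rarely produces gaps), assembly artifacts
(chimeras, fragmentation), paralogy, sequencing error, or biological
replicates. Passing recovery tests therefore demonstrates correctness of
the statistical machinery under the stated model, not robustness to
assembly noise.

`simulate_count_matrix()` plants differential expression by dividing
(up in original) or multiplying (down) abundances in every derived-host
column before multinomial sampling; the resulting composition shift is
deliberate — it is exactly what TMM normalization exists to absorb.

# Validation problem sizes

The shipped checks use: all 61 sense codons (and all their 2–3-difference
pairs) for the enumeration oracles; 500 ortholog pairs at 0.2% CDS / 0.4%
UTR rates for divergence recovery (pooled estimates within 3 binomial
standard errors, UTR > CDS ordering); 200 replicate 500-codon CDS pairs at
omega 0.5, kappa 2 for estimator recovery — simulated at 5% total CDS
divergence, enough substitutions (~75 per pair) for a stable per-pair
ratio while corrections stay mild — with the median required in
[0.4, 0.6] and a ~50/50 positive/purifying split at omega 1; 200 genes
plus 10% decoys at 1% divergence for orthology precision/recall; a
1000-case grid and a 10^4-gene null for the test statistic; 10^4 genes
with 5% planted 4-fold changes for DE recovery. These sizes keep each
recovery property statistically sharp while the full suite runs in
minutes.

# Known limitations

* The alignment engine delegates to `Biostrings::pairwiseAlignment`;
  tie-breaking among co-optimal alignments is its deterministic internal
  order. Divergence symmetry consequently holds in the regime the pipeline
  targets (a few percent divergence, essentially unique optima) but is not
  guaranteed for arbitrarily dissimilar inputs.
* Kappa estimation per pair is noisy below ~1% divergence; at the default
  rates the kappa-aware estimator frequently falls back toward its
  equal-weight behaviour. This mirrors the small-sample reality of
  per-pair approximate methods.
* 1-vs-1 library contrasts only (no replicate dispersion modelling) — the
  random-sampling test is exactly the right null for pooled single
  libraries, and nothing more.
* No splice isoforms, selenocysteine readthrough, or codon-usage-based ORF
  scoring in the annotation step; the ATG-extension rule is a documented
  stand-in for heavier boundary predictors.
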