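# hadtx

Comparative transcriptomics of conspecific strains maintained on different
host plants. Given separately assembled transcript sets for an
original-host strain and one or more derived-host strains, a pooled
reference transcriptome and a protein set, `hadtx`:

* pairs orthologs by **reciprocal best match** (exact-k-mer-seeded local
  alignment on both strands) with a double filter — both members must map
  unambiguously to the same pooled-reference transcript *and* annotate to
  the same protein;
* partitions each ortholog into **5'UTR / CDS / 3'UTR** from its best
  six-frame protein hit, applying the removal rules (in-frame stop inside
  the hit region; CDS < 150 bp);
* measures **per-region divergence** (substitutions over bases compared,
  after global alignment; gap and N columns excluded) and estimates
  **Ka/Ks** per pair with two approximate methods — equal-weight
  Nei–Gojobori-style counting (NG86) and a transition/transversion- and
  codon-frequency-aware Yang–Nielsen-style estimator (YN00) — classifying
  pairs as under positive (Ka/Ks > 1) or purifying (< 1) selection;
* calls **differentially expressed transcripts** between libraries from a
  gene × sample count matrix: TMM normalization, the MA-plot binomial
  random-sampling statistic (`M = log2((k1/n1)/(k2/n2))`, `z` from the
  conditional binomial null `k1 | t ~ Bin(t, n1/(n1+n2))`), q-values, the
  `q < 0.05 & |log2FC| > 1` gates, and exact intersection of up-sets
  across host contrasts and sexes;
* ships a **simulator with ground truth**: ortholog pairs whose UTRs evolve
  at per-region substitution rates and whose CDS evolves codon-by-codon
  under a κ/ω scheme, plus multinomial count matrices with planted fold
  changes — so orthology precision/recall, divergence recovery, ω recovery
  and DE sensitivity/FDR are all testable against known truth.

## Worked example

Simulate 60 ortholog pairs at the default per-region rates (0.23% 5'UTR,
0.13% CDS, 0.19% 3'UTR), run the divergence pipeline, then call DE on a
matching simulated count matrix:

```r
library(hadtx)

cfg <- sim_config(n_genes = 60, seed = 42)
sim <- simulate_transcript_pairs(cfg)
res <- run_divergence(sim$original, sim$derived, sim$reference,
                      sim$proteins, contrast = "cabbage/cotton",
                      verbose = FALSE)
print(res$report, row.names = FALSE, digits = 3)
#>        contrast matched_sequences orthologs n_utr5 utr5_div_pct n_cds
#>  cabbage/cotton                60        60     60        0.215    60
#>  cds_div_pct n_utr3 utr3_div_pct kaks_gt1
#>          0.1     60        0.222        0

cm <- simulate_count_matrix(cfg)
de <- run_de(cm$counts, cm$samples, original_strain = "ca")
print(de$tally_table, row.names = FALSE)
#>  contrast de up down
#>  caf/cof1  3  2    1
```

Reading the report: all 60 reciprocal best matches survive the
double filter (`orthologs`); each region's column gives the pair count and
the mean divergence in percent — the configured UTR > CDS ordering is
recovered (0.215/0.222% vs 0.10%); `kaks_gt1` counts pairs classified
under positive selection. The DE tally finds the 3 planted genes (5% of
60): 2 up in the original-host library, 1 down, matching the planted
truth for this seed.

A thin command-line wrapper around the same functions is installed at
`inst/cli/hadtx` (subcommands `simulate`, `divergence`, `de`, `all`).

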