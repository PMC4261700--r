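# Synthetic-data generator: limiting cases, determinism, recovery of
# configured rates, and round-trips through the package's readers.

test_that("zero substitution rates reproduce the ancestral sequences", {
  cfg <- sim_config(n_genes = 10, d_utr5 = 0, d_cds_target = 0, d_utr3 = 0,
                    seed = 3)
  sim <- simulate_transcript_pairs(cfg)
  expect_identical(unname(as.character(sim$original)),
                   unname(as.character(sim$derived)))
  expect_true(all(sim$truth$substitutions[, -1] == 0))
})

test_that("omega 0 forbids nonsynonymous change", {
  cfg <- sim_config(n_genes = 15, d_cds_target = 0.05, omega = 0, seed = 8)
  sim <- simulate_transcript_pairs(cfg)
  expect_true(all(sim$truth$substitutions$cds_nonsyn == 0))
  co <- sim$truth$region_coords
  for (i in seq_len(15)) {
    a <- substr(as.character(sim$original[[i]]), co$cds_start[i] + 1,
                co$cds_end[i])
    b <- substr(as.character(sim$derived[[i]]), co$cds_start[i] + 1,
                co$cds_end[i])
    expect_identical(hadtx:::translate_cds(a), hadtx:::translate_cds(b))
  }
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 8, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixtures(simulate_transcript_pairs(cfg), d1,
                 counts = simulate_count_matrix(cfg), config = cfg)
  write_fixtures(simulate_transcript_pairs(cfg), d2,
                 counts = simulate_count_matrix(cfg), config = cfg)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
})

test_that("recounting substitutions by alignment reproduces truth exactly", {
  cfg <- sim_config(n_genes = 20, d_utr5 = 0.02, d_cds_target = 0.02,
                    d_utr3 = 0.02, seed = 12)
  sim <- simulate_transcript_pairs(cfg)
  co <- sim$truth$region_coords
  for (i in seq_len(20)) {
    o <- as.character(sim$original[[i]])
    d <- as.character(sim$derived[[i]])
    for (reg in c("utr5", "cds", "utr3")) {
      s0 <- co[[paste0(reg, "_start")]][i]
      s1 <- co[[paste0(reg, "_end")]][i]
      if (s1 <= s0) next
      aln <- align_global(substr(o, s0 + 1, s1), substr(d, s0 + 1, s1))
      cs <- count_substitutions(aln)
      expect_equal(unname(cs["substitutions"]),
                   sim$truth$substitutions[[paste0(reg, "_sub")]][i],
                   info = paste(i, reg))
    }
  }
})

test_that("mean UTR divergence recovers the configured rate within 3 SE", {
  cfg <- sim_config(n_genes = 250, seed = 5)
  sim <- simulate_transcript_pairs(cfg)
  co <- sim$truth$region_coords
  n_bases <- sum(co$utr5_end - co$utr5_start)
  d_hat <- sum(sim$truth$substitutions$utr5_sub) / n_bases
  se <- sqrt(cfg$d_utr5 * (1 - cfg$d_utr5) / n_bases)
  expect_lt(abs(d_hat - cfg$d_utr5), 3 * se)
})

test_that("realized Ka/Ks from truth labels converges to configured omega", {
  cfg <- sim_config(n_genes = 6, cds_len = c(9000, 9000),
                    utr5_len = c(10, 10), utr3_len = c(10, 10),
                    d_cds_target = 0.05, omega = 0.5, kappa = 2, seed = 9)
  sim <- simulate_transcript_pairs(cfg)
  tab <- hadtx:::codon_tables()
  co <- sim$truth$region_coords
  ratios <- vapply(seq_len(6), function(i) {
    cds <- substr(as.character(sim$original[[i]]), co$cds_start[i] + 1,
                  co$cds_end[i])
    ia <- hadtx:::codon_indices(cds)
    freq <- hadtx:::f3x4_freqs(ia, ia, tab)
    s_codon <- hadtx:::yn_site_counts(cfg$kappa, freq, tab)
    S <- sum(s_codon[ia])
    N <- 3 * length(ia) - S
    subs <- sim$truth$substitutions[i, ]
    (subs$cds_nonsyn / N) / (subs$cds_syn / S)
  }, numeric(1))
  expect_lt(abs(median(ratios) - 0.5) / 0.5, 0.15)
})

test_that("null count matrices share one abundance vector", {
  cfg <- sim_config(n_genes = 50, frac_de = 0, lib_size = 1e6, seed = 2)
  cm <- simulate_count_matrix(cfg)
  expect_length(cm$truth$de_up, 0)
  expect_length(cm$truth$de_down, 0)
  # same abundance vector: counts across samples agree within sampling noise
  expect_gt(cor(cm$counts[, 1], cm$counts[, 2]), 0.99)
  cm2 <- simulate_count_matrix(cfg)
  expect_identical(cm$counts, cm2$counts)
})

test_that("planted fold change is recovered across seeds", {
  # observed count ratio for a planted gene vs its closed-form multinomial
  # expectation (the fold change times the composition shift)
  obs <- exp <- numeric(100)
  for (s in 1:100) {
    cfg <- sim_config(n_genes = 100, frac_de = 0.1, fold_change = 4,
                      lib_size = 1e6, seed = s)
    cm <- simulate_count_matrix(cfg)
    g <- cm$truth$de_up[1]
    obs[s] <- cm$counts[g, 1] / cm$counts[g, 2]
    exp[s] <- cm$truth$abundance[g, 1] / cm$truth$abundance[g, 2]
  }
  # the expectation is the fold change scaled by the multinomial
  # renormalization of the derived column
  expect_gt(mean(exp), 4)
  se <- sd(obs - exp) / sqrt(length(obs))
  # a count ratio carries a small positive Jensen bias of order E[1/k2]
  expect_lt(abs(mean(obs - exp)), 3 * se + 0.1)
})

test_that("count matrices reject an unrepresentable library size", {
  cfg <- sim_config(n_genes = 100, lib_size = 50, seed = 1)
  expect_error(simulate_count_matrix(cfg), "lib_size")
})

test_that("fixtures round-trip through the package readers", {
  for (n in c(1, 100)) {
    cfg <- sim_config(n_genes = n, seed = n)
    sim <- simulate_transcript_pairs(cfg)
    cm <- simulate_count_matrix(cfg)
    dir <- withr::local_tempdir()
    paths <- write_fixtures(sim, dir, counts = cm, config = cfg)
    back <- read_transcripts(paths["original"], strain = "ca", sex = "f")
    expect_identical(as.character(back), as.character(sim$original))
    prot <- read_proteins(paths["proteins"])
    expect_identical(as.character(prot), as.character(sim$proteins))
    counts <- read_count_matrix(paths["counts"])
    expect_identical(counts, cm$counts)
  }
  # an empty record set also round-trips
  dir <- withr::local_tempdir()
  empty <- Biostrings::DNAStringSet()
  Biostrings::writeXStringSet(empty, file.path(dir, "empty.fasta"))
  expect_length(read_transcripts(file.path(dir, "empty.fasta")), 0)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(d_cds_target = 0.5), "rates")
  expect_error(sim_config(kappa = 0), "kappa")
  expect_error(sim_config(fraction_positive = 1.5), "fraction_positive")
  expect_error(sim_config(cds_len = c(100, 50)), "divisible")
})
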