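# Synthetic ortholog-pair and count-matrix generator with recorded ground
# truth.  Sequences emulate the study design the analysis assumes: one
# ancestral transcript pool (the original-host strain) and a derived copy
# accumulating substitutions at per-region rates, the CDS under a
# kappa/omega-weighted codon scheme.

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic-data generator.
#' Defaults mirror the magnitudes reported for host-strain transcriptome
#' comparisons: per-site divergence of about 0.13% in CDS, 0.23% in 5'UTR and
#' 0.19% in 3'UTR, a small fraction of genes under positive selection, and
#' libraries of one million reads.
#'
#' @param n_genes number of ortholog pairs to generate.
#' @param utr5_len,cds_len,utr3_len length distributions, each a
#'   `c(mean, min)` pair in base pairs; CDS lengths are rounded to multiples
#'   of 3 (the mean includes the ATG, excludes the stop codon).
#' @param d_utr5,d_cds_target,d_utr3 expected per-site substitution fractions
#'   in `[0, 0.2]`.
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega optional fixed dN/dS for every gene; when `NULL` a mixture is
#'   drawn: a fraction `fraction_positive` of genes with
#'   `omega_positive` (> 1), the rest with `omega_purifying` (< 1).
#' @param fraction_positive,omega_positive,omega_purifying mixture settings.
#' @param allow_multiple_hits if `FALSE` (default) each site is substituted
#'   at most once, so truth counts equal observable differences; `TRUE`
#'   enables repeat hits for testing multiple-hit corrections.
#' @param n_samples,lib_size count-matrix shape: samples and reads per
#'   library.
#' @param frac_de,fold_change fraction of genes with planted differential
#'   expression and their fold change.
#' @param strain_original,strain_derived,sex labels used in sequence ids.
#' @param seed integer seed; all randomness in the generator derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       utr5_len = c(100, 30),
                       cds_len = c(450, 150),
                       utr3_len = c(150, 30),
                       d_utr5 = 0.0023,
                       d_cds_target = 0.0013,
                       d_utr3 = 0.0019,
                       kappa = 2,
                       omega = NULL,
                       fraction_positive = 0.05,
                       omega_positive = 2,
                       omega_purifying = 0.2,
                       allow_multiple_hits = FALSE,
                       n_samples = 2,
                       lib_size = 1e6,
                       frac_de = 0.05,
                       fold_change = 4,
                       strain_original = "ca",
                       strain_derived = "co",
                       sex = "f",
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), utr5_len = utr5_len,
              cds_len = cds_len, utr3_len = utr3_len, d_utr5 = d_utr5,
              d_cds_target = d_cds_target, d_utr3 = d_utr3, kappa = kappa,
              omega = omega, fraction_positive = fraction_positive,
              omega_positive = omega_positive,
              omega_purifying = omega_purifying,
              allow_multiple_hits = isTRUE(allow_multiple_hits),
              n_samples = as.integer(n_samples), lib_size = lib_size,
              frac_de = frac_de, fold_change = fold_change,
              strain_original = strain_original,
              strain_derived = strain_derived, sex = sex,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1)
  rates <- c(cfg$d_utr5, cfg$d_cds_target, cfg$d_utr3)
  if (any(rates < 0) || any(rates > 0.2)) {
    stop("substitution rates must lie in [0, 0.2]")
  }
  if (cfg$kappa <= 0) stop("kappa must be > 0")
  if (!is.null(cfg$omega) && cfg$omega < 0) stop("omega must be >= 0")
  if (cfg$fraction_positive < 0 || cfg$fraction_positive > 1) {
    stop("fraction_positive must lie in [0, 1]")
  }
  if (round(cfg$cds_len[1]) %% 3 != 0) {
    stop("mean CDS length must be divisible by 3")
  }
  invisible(cfg)
}

draw_length <- function(len, n) {
  pmax(len[2], len[2] + rpois(n, max(0, len[1] - len[2])))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Random sense-codon CDS: ATG + random non-stop codons.
random_cds <- function(len) {
  tab <- codon_tables()
  n_cod <- len %/% 3
  sense <- setdiff(tab$sense, match("ATG", tab$codons))
  body <- sample(tab$codons[sense], n_cod - 1, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""))
}

# kappa-weighted choice of a replacement base.
draw_alt_base <- function(base, kappa) {
  alts <- setdiff(DNA_BASES, base)
  w <- ifelse(is_transition(base, alts), kappa, 1)
  sample(alts, 1, prob = w)
}

mutate_utr <- function(seq, d, kappa, allow_multiple_hits) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L == 0 || d == 0) return(list(seq = seq, n_sub = 0L))
  n_sub <- rbinom(1, L, d)
  if (n_sub == 0) return(list(seq = seq, n_sub = 0L))
  sites <- if (allow_multiple_hits) {
    sample.int(L, n_sub, replace = TRUE)
  } else {
    sample.int(L, min(n_sub, L))
  }
  for (s in sites) chars[s] <- draw_alt_base(chars[s], kappa)
  list(seq = paste(chars, collapse = ""), n_sub = length(sites))
}

# Codon-scheme CDS evolution: per substitution, a site is drawn uniformly, a
# target base with transition weight kappa, stop-creating changes rejected,
# nonsynonymous changes accepted with probability proportional to omega
# (relative acceptance omega/max(1, omega) vs 1/max(1, omega) so the
# expected nonsynonymous/synonymous rate ratio equals omega).
mutate_cds <- function(cds, d, kappa, omega, allow_multiple_hits,
                       max_tries = 1000) {
  tab <- codon_tables()
  chars <- strsplit(cds, "")[[1]]
  L <- length(chars)
  if (L == 0 || d == 0) {
    return(list(seq = cds, n_syn = 0L, n_nonsyn = 0L, n_ts = 0L, n_tv = 0L))
  }
  n_sub <- rbinom(1, L, d)
  acc_syn <- 1 / max(1, omega)
  acc_non <- omega / max(1, omega)
  hit <- logical(L)
  n_syn <- n_nonsyn <- n_ts <- n_tv <- 0L
  for (i in seq_len(n_sub)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(L, 1)
      if (!allow_multiple_hits && hit[s]) next
      old <- chars[s]
      new <- draw_alt_base(old, kappa)
      cstart <- s - (s - 1) %% 3
      codon_old <- paste(chars[cstart:(cstart + 2)], collapse = "")
      codon_new_chars <- chars[cstart:(cstart + 2)]
      codon_new_chars[(s - 1) %% 3 + 1] <- new
      codon_new <- paste(codon_new_chars, collapse = "")
      io <- match(codon_old, tab$codons)
      in_ <- match(codon_new, tab$codons)
      if (tab$is_stop[in_]) next
      syn <- tab$aa[io] == tab$aa[in_]
      if (runif(1) >= (if (syn) acc_syn else acc_non)) next
      chars[s] <- new
      hit[s] <- TRUE
      if (syn) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      if (is_transition(old, new)) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a CDS substitution after ", max_tries,
           " resampling attempts")
    }
  }
  list(seq = paste(chars, collapse = ""), n_syn = n_syn, n_nonsyn = n_nonsyn,
       n_ts = n_ts, n_tv = n_tv)
}

#' Simulate ortholog transcript pairs with ground truth
#'
#' Each gene yields an ancestral transcript (5'UTR + ATG-initiated CDS + stop
#' codon + 3'UTR) assigned to the original-host strain, and a derived copy in
#' which UTR sites substitute independently at their region rates and the CDS
#' evolves codon-by-codon under the kappa/omega scheme.  The stop codon is an
#' unmutated 3-base buffer.  A protein reference equal to the ancestral CDS
#' translation is emitted per gene, and a pooled reference transcriptome
#' (the ancestral sequences under `ref_g*` ids) for ortholog mapping.
#'
#' @param config a [sim_config()].
#' @param frac_decoy fraction of additional unrelated decoy transcripts added
#'   to each strain's set (no ortholog, no protein).
#' @return list with `original`, `derived`, `reference`
#'   ([Biostrings::DNAStringSet] with strain/sex metadata), `proteins`
#'   ([Biostrings::AAStringSet]) and `truth` (ortholog map, region
#'   coordinates, realized substitution counts, per-gene omega).
#' @export
simulate_transcript_pairs <- function(config, frac_decoy = 0) {
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_genes
    u5 <- draw_length(config$utr5_len, n)
    cl <- draw_length(config$cds_len, n)
    cl <- pmax(config$cds_len[2], 3 * round(cl / 3))
    u3 <- draw_length(config$utr3_len, n)
    omega <- if (!is.null(config$omega)) {
      rep(config$omega, n)
    } else {
      ifelse(runif(n) < config$fraction_positive,
             config$omega_positive, config$omega_purifying)
    }
    stops <- c("TAA", "TAG", "TGA")

    orig <- der <- prot <- character(n)
    id_o <- paste0("g", seq_len(n), "_", config$strain_original)
    id_d <- paste0("g", seq_len(n), "_", config$strain_derived)
    counts <- data.frame(gene = paste0("g", seq_len(n)),
                         utr5_sub = 0L, cds_sub = 0L, cds_syn = 0L,
                         cds_nonsyn = 0L, cds_ts = 0L, cds_tv = 0L,
                         utr3_sub = 0L, stringsAsFactors = FALSE)
    coords <- data.frame(gene = counts$gene,
                         utr5_start = 0L, utr5_end = u5,
                         cds_start = u5, cds_end = u5 + cl,
                         stop_start = u5 + cl, stop_end = u5 + cl + 3L,
                         utr3_start = u5 + cl + 3L,
                         utr3_end = u5 + cl + 3L + u3,
                         stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      utr5 <- random_dna(u5[i])
      cds <- random_cds(cl[i])
      stopc <- sample(stops, 1)
      utr3 <- random_dna(u3[i])
      orig[i] <- paste0(utr5, cds, stopc, utr3)
      m5 <- mutate_utr(utr5, config$d_utr5, config$kappa,
                       config$allow_multiple_hits)
      mc <- mutate_cds(cds, config$d_cds_target, config$kappa, omega[i],
                       config$allow_multiple_hits)
      m3 <- mutate_utr(utr3, config$d_utr3, config$kappa,
                       config$allow_multiple_hits)
      der[i] <- paste0(m5$seq, mc$seq, stopc, m3$seq)
      counts$utr5_sub[i] <- m5$n_sub
      counts$cds_sub[i] <- mc$n_syn + mc$n_nonsyn
      counts$cds_syn[i] <- mc$n_syn
      counts$cds_nonsyn[i] <- mc$n_nonsyn
      counts$cds_ts[i] <- mc$n_ts
      counts$cds_tv[i] <- mc$n_tv
      counts$utr3_sub[i] <- m3$n_sub
      prot[i] <- translate_cds(cds)
    }

    n_decoy <- round(frac_decoy * n)
    mk_set <- function(seqs, ids, strain) {
      if (n_decoy > 0) {
        dec <- vapply(draw_length(c(sum(config$cds_len[1],
                                        config$utr5_len[1],
                                        config$utr3_len[1]), 60), n_decoy),
                      random_dna, character(1))
        seqs <- c(seqs, dec)
        ids <- c(ids, paste0("d", seq_len(n_decoy), "_", strain))
      }
      x <- Biostrings::DNAStringSet(setNames(seqs, ids))
      S4Vectors::mcols(x) <- S4Vectors::DataFrame(
        strain = strain, sex = config$sex)
      x
    }
    original <- mk_set(orig, id_o, config$strain_original)
    derived <- mk_set(der, id_d, config$strain_derived)
    reference <- Biostrings::DNAStringSet(
      setNames(orig, paste0("ref_g", seq_len(n))))
    proteins <- Biostrings::AAStringSet(
      setNames(prot, paste0("p", seq_len(n))))

    truth <- list(
      ortholog_map = data.frame(original_id = id_o, derived_id = id_d,
                                ref_id = paste0("ref_g", seq_len(n)),
                                prot_id = paste0("p", seq_len(n)),
                                stringsAsFactors = FALSE),
      region_coords = coords,
      substitutions = counts,
      omega = data.frame(gene = counts$gene, omega = omega,
                         stringsAsFactors = FALSE))
    list(original = original, derived = derived, reference = reference,
         proteins = proteins, truth = truth)
  })
}

#' Simulate a count matrix with planted differential expression
#'
#' Null genes share one abundance vector (gamma-distributed weights) across
#' all samples; planted genes have their abundance divided (up in the
#' original host) or multiplied (down) by `fold_change` in every
#' derived-host sample.  Counts are multinomial draws of `lib_size` reads per
#' library.
#'
#' @param config a [sim_config()]; `n_samples` columns are generated, the
#'   first labelled as the original-host library, the rest as derived-host
#'   libraries.
#' @param samples optional data.frame with columns `sample`, `strain`, `sex`
#'   overriding the default one-original-vs-derived layout.
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (label table) and `truth` (`de_up`, `de_down` gene id sets — `de_up`
#'   is higher in the original-host library — plus the per-sample
#'   `abundance` proportions actually sampled from).
#' @export
simulate_count_matrix <- function(config, samples = NULL) {
  validate_sim_config(config)
  if (config$n_samples < 2 && is.null(samples)) {
    stop("need at least 2 samples")
  }
  if (config$lib_size < config$n_genes) {
    stop("lib_size too small to represent n_genes")
  }
  withr::with_seed(config$seed + 1L, {
    n <- config$n_genes
    genes <- paste0("g", seq_len(n))
    if (is.null(samples)) {
      samples <- data.frame(
        sample = c(paste0(config$strain_original, config$sex),
                   paste0(config$strain_derived, config$sex,
                          seq_len(config$n_samples - 1))),
        strain = c(config$strain_original,
                   rep(config$strain_derived, config$n_samples - 1)),
        sex = config$sex, stringsAsFactors = FALSE)
    }
    base <- rgamma(n, shape = 2)
    n_de <- round(config$frac_de * n)
    de_up <- de_down <- character(0)
    if (n_de > 0) {
      picked <- sample.int(n, n_de)
      half <- ceiling(n_de / 2)
      de_up <- genes[picked[seq_len(half)]]
      de_down <- genes[picked[setdiff(seq_len(n_de), seq_len(half))]]
    }
    is_original <- samples$strain == config$strain_original
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(genes, samples$sample))
    abundance <- matrix(0, n, nrow(samples),
                        dimnames = list(genes, samples$sample))
    for (j in seq_len(nrow(samples))) {
      ab <- base
      if (!is_original[j]) {
        ab[genes %in% de_up] <- ab[genes %in% de_up] / config$fold_change
        ab[genes %in% de_down] <- ab[genes %in% de_down] * config$fold_change
      }
      abundance[, j] <- ab / sum(ab)
      counts[, j] <- rmultinom(1, config$lib_size, ab)
    }
    list(counts = counts, samples = samples,
         truth = list(de_up = de_up, de_down = de_down,
                      abundance = abundance))
  })
}

#' Write simulated fixtures to a directory
#'
#' Emits FASTA for the transcript, reference and protein sets (80-column
#' wrap), TSV for truth tables and the count matrix, and the configuration
#' as YAML.  Everything round-trips through the package's readers.
#'
#' @param sim output of [simulate_transcript_pairs()].
#' @param dir output directory (created if needed).
#' @param counts optional output of [simulate_count_matrix()].
#' @param config the [sim_config()] used (written as `config.yaml`).
#' @return named character vector of file paths.
#' @export
write_fixtures <- function(sim, dir, counts = NULL, config = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create directory: ", dir)
  }
  paths <- c(original = file.path(dir, "original.fasta"),
             derived = file.path(dir, "derived.fasta"),
             reference = file.path(dir, "reference.fasta"),
             proteins = file.path(dir, "proteins.fasta"))
  Biostrings::writeXStringSet(sim$original, paths["original"], width = 80)
  Biostrings::writeXStringSet(sim$derived, paths["derived"], width = 80)
  Biostrings::writeXStringSet(sim$reference, paths["reference"], width = 80)
  Biostrings::writeXStringSet(sim$proteins, paths["proteins"], width = 80)
  for (nm in names(sim$truth)) {
    tt <- sim$truth[[nm]]
    if (is.data.frame(tt)) {
      p <- file.path(dir, paste0("truth_", nm, ".tsv"))
      write.table(tt, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[paste0("truth_", nm)] <- p
    }
  }
  if (!is.null(counts)) {
    p <- file.path(dir, "counts.tsv")
    df <- data.frame(gene = rownames(counts$counts), counts$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["counts"] <- p
    p2 <- file.path(dir, "samples.tsv")
    write.table(counts$samples, p2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["samples"] <- p2
    for (nm in c("de_up", "de_down")) {
      p3 <- file.path(dir, paste0("truth_", nm, ".tsv"))
      write.table(data.frame(gene = counts$truth[[nm]]), p3, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      paths[paste0("truth_", nm)] <- p3
    }
  }
  if (!is.null(config)) {
    p <- file.path(dir, "config.yaml")
    yaml::write_yaml(unclass(config), p)
    paths["config"] <- p
  }
  paths
}
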