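# End-to-end orchestration: divergence analysis between an original-host
# transcript set and one or more derived-host sets, and differential
# expression across a count matrix with host/sex labelled libraries.
# Both runs emit per-pair tables, a summary mirroring the divergence /
# DE report layout, and a machine-readable provenance file.

write_provenance <- function(outdir, config, seed) {
  prov <- list(package = "hadtx",
               version = as.character(packageVersion("hadtx")),
               seed = seed, config = config)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run the divergence analysis for one original/derived contrast
#'
#' Pipeline: reciprocal-best-match pairing between the two transcript sets,
#' mapping of both to the pooled reference, protein annotation of both,
#' the double ortholog filter, CDS/UTR partitioning from the protein hits
#' (with the internal-stop and minimum-length removal rules), per-region
#' global alignment and substitution counting, and Ka/Ks estimation with
#' selection classification.
#'
#' @param original,derived named [Biostrings::DNAStringSet] transcript sets.
#' @param reference pooled reference transcriptome (`DNAStringSet`).
#' @param proteins protein set (`AAStringSet`).
#' @param contrast label for the report row.
#' @param params [search_params()] for the nucleotide searches.
#' @param prot_min_score cutoff for [best_protein_match()].
#' @param min_cds_len CDS removal threshold (bases).
#' @param min_region_len minimum UTR length for a region pair.
#' @param kaks_method `"YN00"` (default) or `"NG86"`.
#' @param outdir optional directory for TSV/JSON outputs.
#' @param verbose log attrition counts at each filter.
#' @return list with `report` (one-row data.frame: matched sequences,
#'   orthologs, per-region pair counts and mean divergence %, count of
#'   Ka/Ks > 1), `divergence` (per region pair), `kaks` (per CDS pair),
#'   `orthologs`, `dropped`, `tallies`.
#' @export
run_divergence <- function(original, derived, reference, proteins,
                           contrast = "orig/derived",
                           params = search_params(),
                           prot_min_score = 100, min_cds_len = 150,
                           min_region_len = 10, kaks_method = "YN00",
                           outdir = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  hits_ab <- similarity_search(original, derived, params)
  hits_ba <- similarity_search(derived, original, params)
  rbm <- reciprocal_best_matches(hits_ab, hits_ba)
  say("[%s] reciprocal best matches: %d", contrast, nrow(rbm))

  ref_a <- map_to_reference(original, reference, params)
  ref_b <- map_to_reference(derived, reference, params)
  pidx <- kmer_index(as.character(proteins), 5)
  prot_hit <- function(set) {
    hits <- lapply(as.character(set), best_protein_match,
                   proteins = proteins, min_score = prot_min_score,
                   prot_index = pidx)
    names(hits) <- names(set)
    hits
  }
  hits_pa <- prot_hit(original)
  hits_pb <- prot_hit(derived)
  pid <- function(h) if (is.null(h)) NA_character_ else h$prot_id
  prot_a <- vapply(hits_pa, pid, character(1))
  prot_b <- vapply(hits_pb, pid, character(1))
  flt <- filter_orthologs(rbm, ref_a, ref_b, prot_a, prot_b)
  orth <- flt$orthologs
  say("[%s] orthologs after double filter: %d (dropped %d)", contrast,
      nrow(orth), nrow(flt$dropped))

  region_rows <- list()
  kaks_rows <- list()
  n_rejected <- 0
  for (i in seq_len(nrow(orth))) {
    ia <- orth$id_a[i]
    ib <- orth$id_b[i]
    ann_a <- locate_cds(original[[ia]], hits_pa[[ia]], ia, min_cds_len)
    ann_b <- locate_cds(derived[[ib]], hits_pb[[ib]], ib, min_cds_len)
    if (ann_a$status != "ok" || ann_b$status != "ok") {
      n_rejected <- n_rejected + 1
      next
    }
    pid_lbl <- paste(ia, ib, sep = "|")
    rp <- pair_regions(original[[ia]], ann_a, derived[[ib]], ann_b,
                       pair_id = pid_lbl, min_len = min_region_len)
    if (nrow(rp) == 0) next
    # one global alignment per region pair, reused for the codon alignment
    for (ri in seq_len(nrow(rp))) {
      aln <- align_global(rp$seq_a[ri], rp$seq_b[ri])
      cs <- count_substitutions(aln)
      region_rows[[length(region_rows) + 1L]] <- data.frame(
        pair_id = pid_lbl, region = rp$region[ri],
        substitutions = unname(cs["substitutions"]),
        bases_compared = unname(cs["bases_compared"]),
        divergence = unname(cs["divergence"]), stringsAsFactors = FALSE)
      if (rp$region[ri] == "cds") {
        ca <- codon_align(rp$seq_a[ri], rp$seq_b[ri], aln = aln)
        kaks_rows[[pid_lbl]] <- if (identical(kaks_method, "NG86")) {
          ng86_kaks(ca$cds_a, ca$cds_b, pid_lbl)
        } else {
          yn00_kaks(ca$cds_a, ca$cds_b, pid_lbl)
        }
      }
    }
  }
  say("[%s] annotation rejections: %d", contrast, n_rejected)
  div <- do.call(rbind, region_rows)
  if (is.null(div)) {
    div <- data.frame(pair_id = character(), region = character(),
                      substitutions = numeric(), bases_compared = numeric(),
                      divergence = numeric(), stringsAsFactors = FALSE)
  }
  kaks <- do.call(rbind, kaks_rows)
  cls <- if (!is.null(kaks) && nrow(kaks) > 0) {
    classify_selection(kaks)
  } else {
    list(results = kaks, tallies = list(positive = 0))
  }

  reg_stat <- function(r) {
    d <- div[div$region == r & is.finite(div$divergence), ]
    c(n = nrow(d), pct = if (nrow(d)) 100 * mean(d$divergence) else NA_real_)
  }
  u5 <- reg_stat("utr5"); cd <- reg_stat("cds"); u3 <- reg_stat("utr3")
  report <- data.frame(contrast = contrast,
                       matched_sequences = nrow(rbm),
                       orthologs = nrow(orth),
                       n_utr5 = u5["n"], utr5_div_pct = u5["pct"],
                       n_cds = cd["n"], cds_div_pct = cd["pct"],
                       n_utr3 = u3["n"], utr3_div_pct = u3["pct"],
                       kaks_gt1 = cls$tallies$positive,
                       stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(orth) == 0) warning("empty ortholog set for ", contrast)
  out <- list(report = report, divergence = div, kaks = cls$results,
              orthologs = orth, dropped = flt$dropped,
              tallies = cls$tallies)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report, file.path(outdir, "divergence_report.tsv"))
    write_tsv(div, file.path(outdir, "region_divergence.tsv"))
    if (!is.null(cls$results)) {
      write_tsv(cls$results, file.path(outdir, "kaks.tsv"))
    }
    write_tsv(orth, file.path(outdir, "orthologs.tsv"))
  }
  out
}

#' Run differential expression across host contrasts
#'
#' Computes TMM normalization factors for the whole matrix, then for every
#' (original strain vs derived strain, same sex) contrast the MA
#' random-sampling statistic, q-values and up/down calls; intersects the
#' per-contrast up-sets within and across sexes.
#'
#' @param counts gene x sample integer matrix.
#' @param samples data.frame with `sample`, `strain`, `sex` rows matching
#'   the columns of `counts`.
#' @param original_strain strain label of the original host.
#' @param q_max,min_abs_log2fc thresholds for [call_dets()].
#' @param qvalue_method `"storey"` or `"bh"`.
#' @param outdir optional output directory.
#' @return list with `tally_table` (per contrast: de, up, down),
#'   `results` (per-contrast DE tables), `intersections`, `factors`,
#'   `correlations`.
#' @export
run_de <- function(counts, samples, original_strain = "ca",
                   q_max = 0.05, min_abs_log2fc = 1,
                   qvalue_method = "storey", outdir = NULL) {
  stopifnot(all(samples$sample == colnames(counts)))
  factors <- tmm_normalization(counts)
  lib <- colSums(counts)
  eff <- lib * factors
  corr <- sample_correlations(counts, factors)

  orig_idx <- which(samples$strain == original_strain)
  der_idx <- which(samples$strain != original_strain)
  results <- list()
  up_sets <- list()
  sexes <- character(0)
  tally_rows <- list()
  for (j in der_idx) {
    i <- orig_idx[samples$sex[orig_idx] == samples$sex[j]]
    if (length(i) != 1) next
    contrast <- paste0(samples$sample[i], "/", samples$sample[j])
    st <- mars_statistic(counts[, i], counts[, j], eff[i], eff[j])
    st$gene <- rownames(counts)
    st$q <- qvalues(st$p, method = qvalue_method)
    st <- call_dets(st, q_max = q_max, min_abs_log2fc = min_abs_log2fc)
    results[[contrast]] <- st[, c("gene", "M", "A", "z", "p", "q", "call")]
    up_sets[[contrast]] <- st$gene[st$call == "up"]
    sexes[contrast] <- samples$sex[j]
    tl <- attr(st, "tallies")
    tally_rows[[contrast]] <- data.frame(
      contrast = contrast, de = tl["de"], up = tl["up"], down = tl["down"],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  tally_table <- do.call(rbind, tally_rows)
  rownames(tally_table) <- NULL
  inter <- intersect_up_sets(up_sets, sexes)
  out <- list(tally_table = tally_table, results = results,
              intersections = inter, factors = factors,
              correlations = corr)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tally_table, file.path(outdir, "de_tallies.tsv"))
    for (nm in names(results)) {
      write_tsv(results[[nm]],
                file.path(outdir, paste0("de_", gsub("/", "_vs_", nm),
                                         ".tsv")))
    }
    jsonlite::write_json(
      c(lapply(up_sets, I), list(per_sex = inter$per_sex,
                                 consistent = I(inter$consistent))),
      file.path(outdir, "intersections.json"), pretty = TRUE)
  }
  out
}

#' Simulate a self-contained fixture run directory
#'
#' Wraps the simulator: generates ortholog transcript sets and a count
#' matrix from one configuration, writes FASTA/TSV/YAML fixtures plus a
#' provenance record, and returns the paths.
#'
#' @param config a [sim_config()].
#' @param outdir output directory.
#' @param frac_decoy decoy fraction for the transcript sets.
#' @return named character vector of file paths (invisibly the simulation
#'   objects as attributes).
#' @export
simulate_fixtures <- function(config, outdir, frac_decoy = 0) {
  sim <- simulate_transcript_pairs(config, frac_decoy = frac_decoy)
  cm <- simulate_count_matrix(config)
  paths <- write_fixtures(sim, outdir, counts = cm, config = config)
  write_provenance(outdir, unclass(config), config$seed)
  structure(paths, sim = sim, counts = cm)
}
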