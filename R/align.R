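# Pairwise alignment wrappers.  Biostrings does the dynamic programming;
# this file fixes the scoring conventions used throughout the package.

nuc_score_matrix <- function(match = 2, mismatch = -3) {
  b <- c(DNA_BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  # N is never a match, not even against itself
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

#' Global alignment of two DNA sequences
#'
#' Needleman-Wunsch global alignment with affine gap scoring (defaults:
#' match +2, mismatch -3, gap open 5, gap extend 2; opening a gap costs
#' open + extend).  Tie-breaking among co-optimal alignments is deterministic
#' for fixed input.
#'
#' @param seq_a,seq_b character or `DNAString` sequences (A/C/G/T/N).
#' @param match,mismatch,gap_open,gap_ext scoring parameters; gap penalties
#'   are positive costs.
#' @return list with `aligned_a`, `aligned_b` (equal-length strings with `-`
#'   for gaps) and `score`.
#' @export
align_global <- function(seq_a, seq_b, match = 2, mismatch = -3,
                         gap_open = 5, gap_ext = 2) {
  a <- toupper(as.character(seq_a))
  b <- toupper(as.character(seq_b))
  stopifnot(nzchar(a), nzchar(b))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = "global", substitutionMatrix = nuc_score_matrix(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Count substitutions in a pairwise alignment
#'
#' Columns containing a gap or an N on either side are excluded from the
#' denominator; substitutions are the mismatching columns among those kept.
#'
#' @param alignment list with `aligned_a` and `aligned_b` as returned by
#'   [align_global()].
#' @return named numeric vector with `substitutions`, `bases_compared` and
#'   `divergence` (their ratio; `NaN` when nothing is compared).
#' @export
count_substitutions <- function(alignment) {
  x <- strsplit(alignment$aligned_a, "")[[1]]
  y <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(x) == length(y))
  keep <- x != "-" & y != "-" & x != "N" & y != "N"
  subs <- sum(x[keep] != y[keep])
  bases <- sum(keep)
  c(substitutions = subs, bases_compared = bases,
    divergence = if (bases > 0) subs / bases else NaN)
}

#' Per-region divergence for a set of ortholog region pairs
#'
#' Aligns each region pair globally and counts substitutions.
#'
#' @param region_pairs data.frame with columns `pair_id`, `region`, `seq_a`,
#'   `seq_b` (see [pair_regions()]).
#' @return data.frame with one row per region pair: `pair_id`, `region`,
#'   `substitutions`, `bases_compared`, `divergence`.
#' @export
region_divergence <- function(region_pairs) {
  if (nrow(region_pairs) == 0) {
    return(data.frame(pair_id = character(), region = character(),
                      substitutions = numeric(), bases_compared = numeric(),
                      divergence = numeric(), stringsAsFactors = FALSE))
  }
  res <- lapply(seq_len(nrow(region_pairs)), function(i) {
    aln <- align_global(region_pairs$seq_a[i], region_pairs$seq_b[i])
    cs <- count_substitutions(aln)
    data.frame(pair_id = region_pairs$pair_id[i],
               region = region_pairs$region[i],
               substitutions = unname(cs["substitutions"]),
               bases_compared = unname(cs["bases_compared"]),
               divergence = unname(cs["divergence"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Summarize divergence per region class
#'
#' Mean of per-pair divergence fractions (unweighted across pairs) with the
#' pair count, one row per region, the layout used for the divergence report.
#'
#' @param results data.frame from [region_divergence()].
#' @return data.frame with `region`, `n_pairs`, `mean_divergence`,
#'   `mean_divergence_pct`.
#' @export
region_divergence_summary <- function(results) {
  stopifnot(nrow(results) >= 1)
  regs <- c("utr5", "cds", "utr3")
  out <- lapply(regs, function(r) {
    d <- results$divergence[results$region == r & is.finite(results$divergence)]
    if (length(d) == 0) return(NULL)
    data.frame(region = r, n_pairs = length(d), mean_divergence = mean(d),
               mean_divergence_pct = 100 * mean(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) < length(regs)) {
    missing <- setdiff(regs, out$region)
    if (length(missing)) {
      message("no pairs for region(s): ", paste(missing, collapse = ", "))
    }
  }
  out
}
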