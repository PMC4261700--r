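# Partition transcripts into 5'UTR / CDS / 3'UTR from their protein hits.
#
# Conventions: coordinates are 0-based half-open on the coding strand (for
# minus-strand hits the transcript is reverse-complemented first and the GFF
# exporter converts back).  The stop codon is assigned to neither the CDS
# nor the 3'UTR: it is an excluded 3-base buffer, so the two regions flanking
# it are compared without a column under different selective pressure.

coding_strand_seq <- function(transcript, strand) {
  s <- Biostrings::DNAString(toupper(as.character(transcript)))
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Locate the CDS of a transcript from its protein hit
#'
#' The CDS frame is the hit frame.  The CDS start is the nearest in-frame
#' ATG at or upstream of the hit start (stopping at any intervening in-frame
#' stop; falls back to the hit start with a `partial_start` flag).  The CDS
#' end is at the first in-frame stop codon at or downstream of the hit end
#' (stop excluded from the CDS; transcript end with `partial_stop` when
#' none).  The transcript is rejected when an in-frame stop lies strictly
#' inside the hit region (`internal_stop`) or the resulting CDS is shorter
#' than `min_cds_len` bases (`too_short`).
#'
#' @param transcript DNA sequence (character or `DNAString`).
#' @param protein_hit hit as returned by [best_protein_match()].
#' @param transcript_id id recorded in the annotation.
#' @param min_cds_len minimum CDS length in bases (default 150).
#' @return a `region_annotation` list (`status = "ok"`; intervals `utr5`,
#'   `cds`, `stop`, `utr3` in coding-strand 0-based half-open coordinates,
#'   `strand`, `frame`, flags) or a rejection
#'   (`status = "rejected"`, `reason`).
#' @export
locate_cds <- function(transcript, protein_hit, transcript_id = "tx",
                       min_cds_len = 150) {
  stopifnot(!is.null(protein_hit))
  s <- coding_strand_seq(transcript, protein_hit$strand)
  L <- nchar(s)
  h0 <- protein_hit$nt_span[1]
  h1 <- protein_hit$nt_span[2]
  codon_at <- function(p) substr(s, p + 1, p + 3)

  # reject on in-frame stop strictly inside the hit region
  p <- h0
  while (p + 3 <= h1) {
    if (is_stop_codon(codon_at(p))) {
      return(list(status = "rejected", reason = "internal_stop",
                  transcript_id = transcript_id))
    }
    p <- p + 3
  }

  # extend upstream to the nearest in-frame ATG
  cds_start <- NA_integer_
  partial_start <- FALSE
  p <- h0
  while (p >= 0) {
    cod <- codon_at(p)
    if (is_stop_codon(cod)) break
    if (cod == "ATG") {
      cds_start <- p
      break
    }
    p <- p - 3
  }
  if (is.na(cds_start)) {
    cds_start <- h0
    partial_start <- TRUE
  }

  # extend downstream to the first in-frame stop
  cds_end <- NA_integer_
  stop_iv <- c(NA_integer_, NA_integer_)
  partial_stop <- FALSE
  p <- h1
  while (p + 3 <= L) {
    if (is_stop_codon(codon_at(p))) {
      cds_end <- p
      stop_iv <- c(p, p + 3L)
      break
    }
    p <- p + 3
  }
  if (is.na(cds_end)) {
    cds_end <- h1 + 3L * ((L - h1) %/% 3L)
    partial_stop <- TRUE
  }

  if (cds_end - cds_start < min_cds_len) {
    return(list(status = "rejected", reason = "too_short",
                transcript_id = transcript_id))
  }
  utr3_start <- if (partial_stop) cds_end else stop_iv[2]
  structure(list(status = "ok", transcript_id = transcript_id,
                 strand = protein_hit$strand, frame = protein_hit$frame,
                 length = L,
                 utr5 = c(0L, cds_start),
                 cds = c(cds_start, cds_end),
                 stop = stop_iv,
                 utr3 = c(utr3_start, L),
                 flags = list(partial_start = partial_start,
                              partial_stop = partial_stop)),
            class = "region_annotation")
}

#' Split a transcript into its annotated regions
#'
#' Returns the 5'UTR, CDS and 3'UTR sequences in coding orientation; their
#' concatenation (with the stop codon re-inserted) reconstructs the
#' coding-strand transcript.  Empty regions yield empty strings.
#'
#' @param transcript DNA sequence.
#' @param annotation a `region_annotation` from [locate_cds()].
#' @return named list `utr5`, `cds`, `stop`, `utr3` of character sequences.
#' @export
partition_regions <- function(transcript, annotation) {
  stopifnot(annotation$status == "ok")
  s <- coding_strand_seq(transcript, annotation$strand)
  cut0 <- function(iv) {
    if (any(is.na(iv)) || iv[2] <= iv[1]) "" else substr(s, iv[1] + 1, iv[2])
  }
  list(utr5 = cut0(annotation$utr5), cds = cut0(annotation$cds),
       stop = cut0(annotation$stop), utr3 = cut0(annotation$utr3))
}

#' Region-matched sequence pairs for an annotated ortholog pair
#'
#' A region pair is emitted only when both members have that region at least
#' `min_len` bases long; the CDS pair is always emitted when both
#' annotations are valid.  This is why UTR pair counts fall below ortholog
#' counts in the divergence report.
#'
#' @param transcript_a,transcript_b the two transcript sequences.
#' @param annotation_a,annotation_b their `region_annotation`s.
#' @param pair_id identifier for the pair.
#' @param min_len minimum region length (bases) on both sides.
#' @return data.frame with columns `pair_id`, `region`, `seq_a`, `seq_b`.
#' @export
pair_regions <- function(transcript_a, annotation_a,
                         transcript_b, annotation_b,
                         pair_id = "pair", min_len = 10) {
  pa <- partition_regions(transcript_a, annotation_a)
  pb <- partition_regions(transcript_b, annotation_b)
  rows <- list()
  for (r in c("utr5", "cds", "utr3")) {
    ok_len <- if (r == "cds") 1 else min_len
    if (nchar(pa[[r]]) >= ok_len && nchar(pb[[r]]) >= ok_len) {
      rows[[r]] <- data.frame(pair_id = pair_id, region = r,
                              seq_a = pa[[r]], seq_b = pb[[r]],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pair_id = character(), region = character(),
                      seq_a = character(), seq_b = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Export region annotations as GFF3-like rows
#'
#' Converts the internal 0-based half-open coding-strand intervals to
#' 1-based inclusive coordinates on the original (input) transcript, as GFF
#' requires; minus-strand annotations are mapped back through the
#' reverse complement.
#'
#' @param annotation a `region_annotation`.
#' @return data.frame with columns `seqid`, `source`, `feature`, `start`,
#'   `end`, `score`, `strand`, `frame`.
#' @export
annotation_to_gff <- function(annotation) {
  stopifnot(annotation$status == "ok")
  L <- annotation$length
  conv <- function(iv) {
    if (any(is.na(iv)) || iv[2] <= iv[1]) return(NULL)
    if (annotation$strand == "-") iv <- c(L - iv[2], L - iv[1])
    c(start = iv[1] + 1L, end = iv[2])
  }
  feats <- list(five_prime_UTR = annotation$utr5, CDS = annotation$cds,
                three_prime_UTR = annotation$utr3)
  rows <- list()
  for (f in names(feats)) {
    iv <- conv(feats[[f]])
    if (is.null(iv)) next
    rows[[f]] <- data.frame(seqid = annotation$transcript_id,
                            source = "hadtx", feature = f,
                            start = iv["start"], end = iv["end"],
                            score = ".", strand = annotation$strand,
                            frame = if (f == "CDS") annotation$frame else ".",
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
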