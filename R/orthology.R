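# Reciprocal-best-match orthology between two transcript sets, with the
# double filter (same pooled-reference transcript, same protein annotation).
#
# The similarity search is exact-k-mer seeded: subjects are indexed by their
# k-mers (default word size 11), candidate subjects sharing at least one
# word with the query (on either strand) are aligned locally with affine gap
# scoring, and hits above a score cutoff are reported.  An expected-chance-
# hit surrogate is attached via the standard extreme-value length-normalized
# formula with fixed parameters; the cutoff itself is expressed as a score
# threshold (stringent by default, overridable in params), since e-values of
# the original search tools depend on their database sizes.

#' Default similarity-search parameters
#'
#' @param word_size exact-match seed length (nucleotides).
#' @param match,mismatch,gap_open,gap_ext local alignment scoring.
#' @param min_score minimum alignment score for a reported hit.
#' @param min_seed_hits distinct shared words required before a subject is
#'   aligned (the classic two-hit seeding heuristic; chance single-word
#'   matches are not extended).
#' @param lambda,K extreme-value parameters for the e-value surrogate.
#' @param max_n_frac queries/subjects with a higher fraction of N are skipped.
#' @return named list of parameters.
#' @export
search_params <- function(word_size = 11, match = 2, mismatch = -3,
                          gap_open = 5, gap_ext = 2, min_score = 40,
                          min_seed_hits = 2, lambda = 1.28, K = 0.46,
                          max_n_frac = 0.5) {
  list(word_size = word_size, match = match, mismatch = mismatch,
       gap_open = gap_open, gap_ext = gap_ext, min_score = min_score,
       min_seed_hits = min_seed_hits, lambda = lambda, K = K,
       max_n_frac = max_n_frac)
}

seq_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  unique(substring(seq, 1:(L - k + 1), k:L))
}

# kmer -> subject-index inverted index
kmer_index <- function(seqs, k) {
  kl <- lapply(seqs, seq_kmers, k = k)
  split(rep(seq_along(seqs), lengths(kl)), unlist(kl, use.names = FALSE))
}

#' Calibrate a score threshold from a shuffled null
#'
#' Shuffles each subject sequence, searches the queries against the shuffled
#' set and returns the stated quantile of the null score distribution
#' (99.9th percentile by default), a data-driven stand-in for an e-value
#' cutoff.
#'
#' @param queries,subjects [Biostrings::DNAStringSet] sets.
#' @param params [search_params()].
#' @param probs quantile of the null score distribution.
#' @param seed seed for the shuffle.
#' @return numeric score threshold (the `min_score` floor when no null hit
#'   scores at all).
#' @export
calibrate_score_threshold <- function(queries, subjects,
                                      params = search_params(),
                                      probs = 0.999, seed = 1) {
  shuf <- withr::with_seed(seed, {
    Biostrings::DNAStringSet(vapply(as.character(subjects), function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1)))
  })
  names(shuf) <- paste0("shuf_", seq_along(shuf))
  p0 <- params
  p0$min_score <- 0
  hits <- similarity_search(queries, shuf, p0)
  if (nrow(hits) == 0) return(params$min_score)
  max(params$min_score, quantile(hits$score, probs = probs, names = FALSE))
}

#' k-mer-seeded local similarity search between two DNA sets
#'
#' For each query, candidate subjects sharing at least one exact word (on
#' the forward or reverse-complement strand) are aligned locally; hits with
#' score at or above `min_score` are returned sorted by descending score
#' within query.  Reverse-strand hits carry query-forward coordinates and a
#' `-` strand flag.  Coordinates are 0-based half-open.
#'
#' @param queries,subjects named [Biostrings::DNAStringSet] (or named
#'   character) sets.
#' @param params [search_params()].
#' @return data.frame: `query_id`, `subject_id`, `score`,
#'   `evalue_surrogate`, `q_start`, `q_end`, `s_start`, `s_end`, `strand`.
#' @export
similarity_search <- function(queries, subjects, params = search_params()) {
  if (!methods::is(queries, "DNAStringSet")) {
    queries <- Biostrings::DNAStringSet(queries)
  }
  if (!methods::is(subjects, "DNAStringSet")) {
    subjects <- Biostrings::DNAStringSet(subjects)
  }
  S4Vectors::mcols(queries) <- NULL
  S4Vectors::mcols(subjects) <- NULL
  stopifnot(length(queries) > 0, length(subjects) > 0,
            !is.null(names(queries)), !is.null(names(subjects)))
  qchar <- as.character(queries)
  qchar_rc <- as.character(Biostrings::reverseComplement(queries))
  schar <- as.character(subjects)
  n_frac <- function(s) {
    vapply(strsplit(s, ""), function(x) mean(x == "N"), numeric(1))
  }
  q_ok <- n_frac(qchar) <= params$max_n_frac
  s_ok <- n_frac(schar) <= params$max_n_frac
  if (!all(q_ok) || !all(s_ok)) {
    warning(sum(!q_ok) + sum(!s_ok),
            " sequence(s) with >", 100 * params$max_n_frac,
            "% N skipped")
  }
  sub_use <- which(s_ok)
  idx <- kmer_index(schar[sub_use], params$word_size)
  mat <- nuc_score_matrix(params$match, params$mismatch)
  db_len <- sum(nchar(schar[sub_use]))
  out <- vector("list", length(queries))
  for (qi in which(q_ok)) {
    rows <- list()
    qlen <- nchar(qchar[qi])
    for (strand in c("+", "-")) {
      qs <- if (strand == "+") qchar[qi] else qchar_rc[qi]
      km <- seq_kmers(qs, params$word_size)
      shared <- unlist(idx[km], use.names = FALSE)
      if (length(shared) == 0) next
      tabn <- tabulate(shared)
      cand <- which(tabn >= min(params$min_seed_hits, length(km)))
      if (length(cand) == 0) next
      cand_global <- sub_use[cand]
      # exact matches need no dynamic programming: full-length, all-match
      exact <- schar[cand_global] == qs & !grepl("N", qs, fixed = TRUE)
      qlen_qs <- nchar(qs)
      sc <- s_start1 <- s_end1 <- q_start1 <- q_end1 <- numeric(length(cand))
      if (any(exact)) {
        sc[exact] <- params$match * qlen_qs
        s_start1[exact] <- q_start1[exact] <- 1L
        s_end1[exact] <- q_end1[exact] <- qlen_qs
      }
      if (any(!exact)) {
        pa <- Biostrings::pairwiseAlignment(
          pattern = subjects[cand_global[!exact]],
          subject = Biostrings::DNAString(qs),
          type = "local", substitutionMatrix = mat,
          gapOpening = params$gap_open, gapExtension = params$gap_ext)
        sc[!exact] <- Biostrings::score(pa)
        prr <- IRanges::ranges(Biostrings::pattern(pa))
        qrr <- IRanges::ranges(Biostrings::subject(pa))
        s_start1[!exact] <- BiocGenerics::start(prr)
        s_end1[!exact] <- BiocGenerics::end(prr)
        q_start1[!exact] <- BiocGenerics::start(qrr)
        q_end1[!exact] <- BiocGenerics::end(qrr)
      }
      keep <- sc >= params$min_score
      if (!any(keep)) next
      qs0 <- q_start1[keep] - 1L
      qe0 <- q_end1[keep]
      if (strand == "-") {
        tmp <- qlen - qe0
        qe0 <- qlen - qs0
        qs0 <- tmp
      }
      rows[[strand]] <- data.frame(
        query_id = names(queries)[qi],
        subject_id = names(subjects)[cand_global][keep],
        score = sc[keep],
        evalue_surrogate = params$K * qlen * db_len *
          exp(-params$lambda * sc[keep]),
        q_start = qs0, q_end = qe0,
        s_start = s_start1[keep] - 1L, s_end = s_end1[keep],
        strand = strand, stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      r <- do.call(rbind, rows)
      # keep the best strand per subject, then sort by descending score
      r <- r[order(-r$score), ]
      r <- r[!duplicated(r$subject_id), ]
      out[[qi]] <- r
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue_surrogate = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

best_unique_hit <- function(hits) {
  # per query: the unique top-scoring subject, or NA on a tie
  split_hits <- split(hits, hits$query_id)
  best <- vapply(split_hits, function(h) {
    top <- max(h$score)
    cand <- h$subject_id[h$score == top]
    if (length(unique(cand)) == 1) cand[1] else NA_character_
  }, character(1))
  best
}

#' Reciprocal best matches between two hit lists
#'
#' A pair (a, b) is kept iff b is a's unique top-scoring subject and a is
#' b's unique top-scoring subject; ties at the top score yield no pair.
#' The output is a one-to-one matching.
#'
#' @param hits_ab hits of set A queried against set B.
#' @param hits_ba hits of set B queried against set A.
#' @return data.frame with columns `id_a`, `id_b`.
#' @export
reciprocal_best_matches <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0 || nrow(hits_ba) == 0) {
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  }
  best_ab <- best_unique_hit(hits_ab)
  best_ba <- best_unique_hit(hits_ba)
  a_ids <- names(best_ab)
  keep <- !is.na(best_ab) & !is.na(best_ba[best_ab]) &
    best_ba[best_ab] == a_ids
  keep[is.na(keep)] <- FALSE
  out <- data.frame(id_a = a_ids[keep], id_b = unname(best_ab[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$id_a), , drop = FALSE]
}

#' Map transcripts to a pooled reference transcriptome
#'
#' Each transcript is assigned its best-scoring reference sequence;
#' transcripts whose best score is tied between references are left
#' unmapped (NA), mirroring the requirement that orthologs correspond
#' unambiguously to the same reference transcript.
#'
#' @param transcripts,reference [Biostrings::DNAStringSet] sets.
#' @param params [search_params()].
#' @return named character vector transcript id -> reference id (NA when
#'   unmapped or ambiguous).
#' @export
map_to_reference <- function(transcripts, reference,
                             params = search_params()) {
  stopifnot(length(reference) > 0)
  hits <- similarity_search(transcripts, reference, params)
  best <- rep(NA_character_, length(transcripts))
  names(best) <- names(transcripts)
  if (nrow(hits) > 0) {
    b <- best_unique_hit(hits)
    best[names(b)] <- unname(b)
  }
  best
}

blosum62 <- function() {
  b62 <- .hadtx_cache$blosum62
  if (is.null(b62)) {
    data_env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
    b62 <- .hadtx_cache$blosum62 <- data_env$BLOSUM62
  }
  b62
}

# Fast frame translation: codons with anything outside A/C/G/T become X.
translate_frame <- function(seq, frame) {
  tab <- codon_tables()
  L <- nchar(seq)
  n_cod <- (L - frame) %/% 3
  if (n_cod < 1) return("")
  starts <- frame + seq(1L, by = 3L, length.out = n_cod)
  idx <- match(substring(seq, starts, starts + 2L), tab$codons)
  aa <- ifelse(is.na(idx), "X", tab$aa[idx])
  paste(aa, collapse = "")
}

#' Best protein match of a transcript (six-frame translation)
#'
#' Translates the transcript in all six frames, aligns each frame locally
#' against candidate proteins (BLOSUM62, affine gaps), and returns the best
#' hit at or above the score cutoff together with its frame and coordinate
#' spans.
#'
#' @param transcript a [Biostrings::DNAString] or single character sequence.
#' @param proteins named [Biostrings::AAStringSet].
#' @param min_score minimum local alignment score.
#' @param word_size amino-acid word length for candidate prefiltering.
#' @param prot_index optional precomputed `kmer_index()` of the proteins
#'   (built per call when `NULL`; pass it when scanning many transcripts).
#' @return list with `prot_id`, `strand`, `frame` (0/1/2), `score`,
#'   `aa_span` (protein, 0-based half-open), `q_aa_span` (frame translation),
#'   `nt_span` (coding-orientation transcript coordinates, 0-based
#'   half-open), or `NULL` when nothing scores above the cutoff.
#' @export
best_protein_match <- function(transcript, proteins, min_score = 100,
                               word_size = 5, prot_index = NULL) {
  stopifnot(length(proteins) > 0)
  dna <- Biostrings::DNAString(toupper(as.character(transcript)))
  pidx <- if (is.null(prot_index)) {
    kmer_index(as.character(proteins), word_size)
  } else {
    prot_index
  }
  b62 <- blosum62()
  dchar <- as.character(dna)
  rchar <- as.character(Biostrings::reverseComplement(dna))
  best <- NULL
  for (strand in c("+", "-")) {
    schar <- if (strand == "+") dchar else rchar
    L <- nchar(schar)
    for (frame in 0:2) {
      n_cod <- (L - frame) %/% 3
      if (n_cod < word_size) next
      aach <- translate_frame(schar, frame)
      km <- seq_kmers(aach, word_size)
      shared <- unlist(pidx[km], use.names = FALSE)
      if (length(shared) == 0) next
      tabn <- tabulate(shared)
      cand <- which(tabn >= min(2, length(km)))
      if (length(cand) == 0) next
      pa <- Biostrings::pairwiseAlignment(
        pattern = proteins[cand], subject = Biostrings::AAString(aach),
        type = "local", substitutionMatrix = b62,
        gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(pa)
      top <- which.max(sc)
      if (sc[top] < min_score) next
      if (is.null(best) || sc[top] > best$score) {
        prr <- IRanges::ranges(Biostrings::pattern(pa))
        qrr <- IRanges::ranges(Biostrings::subject(pa))
        ps <- BiocGenerics::start(prr)[top]; pe <- BiocGenerics::end(prr)[top]
        qs <- BiocGenerics::start(qrr)[top]; qe <- BiocGenerics::end(qrr)[top]
        best <- list(prot_id = names(proteins)[cand][top], strand = strand,
                     frame = frame, score = sc[top],
                     aa_span = c(ps - 1L, pe),
                     q_aa_span = c(qs - 1L, qe),
                     nt_span = c(frame + 3L * (qs - 1L), frame + 3L * qe))
      }
    }
  }
  best
}

#' Filter reciprocal best matches down to orthologs
#'
#' A pair is kept iff both members map to the same pooled-reference
#' transcript and both are annotated to the same protein; every dropped
#' pair carries a reason code (`ref_unmapped`, `ref_mismatch`,
#' `prot_missing`, `prot_mismatch`).
#'
#' @param rbm_pairs data.frame from [reciprocal_best_matches()].
#' @param ref_map_a,ref_map_b named vectors from [map_to_reference()].
#' @param prot_a,prot_b named character vectors transcript id -> protein id
#'   (NA when unannotated), e.g. from [best_protein_match()] per transcript.
#' @return list with `orthologs` (data.frame `id_a`, `id_b`, `ref_id`,
#'   `prot_id`) and `dropped` (data.frame `id_a`, `id_b`, `reason`).
#' @export
filter_orthologs <- function(rbm_pairs, ref_map_a, ref_map_b,
                             prot_a, prot_b) {
  n <- nrow(rbm_pairs)
  reason <- rep(NA_character_, n)
  ra <- unname(ref_map_a[rbm_pairs$id_a])
  rb <- unname(ref_map_b[rbm_pairs$id_b])
  pa <- unname(prot_a[rbm_pairs$id_a])
  pb <- unname(prot_b[rbm_pairs$id_b])
  reason[is.na(ra) | is.na(rb)] <- "ref_unmapped"
  reason[is.na(reason) & ra != rb] <- "ref_mismatch"
  reason[is.na(reason) & (is.na(pa) | is.na(pb))] <- "prot_missing"
  reason[is.na(reason) & pa != pb] <- "prot_mismatch"
  keep <- is.na(reason)
  list(orthologs = data.frame(id_a = rbm_pairs$id_a[keep],
                              id_b = rbm_pairs$id_b[keep],
                              ref_id = ra[keep], prot_id = pa[keep],
                              stringsAsFactors = FALSE),
       dropped = data.frame(id_a = rbm_pairs$id_a[!keep],
                            id_b = rbm_pairs$id_b[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}
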