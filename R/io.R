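# Readers and writers for the package's external formats.

#' Read a transcript FASTA
#'
#' @param path FASTA file of DNA sequences.
#' @param strain,sex labels attached to every record (stored in `mcols`).
#' @return [Biostrings::DNAStringSet] with `strain`/`sex` metadata.
#' @export
read_transcripts <- function(path, strain = NA_character_,
                             sex = NA_character_) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(strain = strain, sex = sex)
  x
}

#' Read a protein FASTA
#' @param path FASTA file of amino-acid sequences.
#' @return [Biostrings::AAStringSet]
#' @export
read_proteins <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet (sample, strain, sex) from TSV
#' @param path TSV file with header `sample`, `strain`, `sex`.
#' @return data.frame
#' @export
read_sample_sheet <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write similarity hits or other result tables as TSV
#' @param df data.frame to write.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read externally produced similarity hits in 12-column blast-tabular form
#'
#' Interoperability reader for the standard tab-separated dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore); coordinates are converted to the package's 0-based
#' half-open convention and hits on the minus strand (send < sstart) are
#' flagged.
#'
#' @param path tabular hits file.
#' @return data.frame in the package's hit layout.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE, col.names = cols)
  minus <- df$send < df$sstart
  s_lo <- ifelse(minus, df$send, df$sstart)
  s_hi <- ifelse(minus, df$sstart, df$send)
  data.frame(query_id = df$query_id, subject_id = df$subject_id,
             score = df$bitscore, evalue_surrogate = df$evalue,
             q_start = df$qstart - 1L, q_end = df$qend,
             s_start = s_lo - 1L, s_end = s_hi,
             strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
}
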