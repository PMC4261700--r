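# Codon-level tables shared by the simulator and the Ka/Ks estimators.
# Everything is derived once from the standard genetic code and cached.

.hadtx_cache <- new.env(parent = emptyenv())

DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
is_transition <- function(from, to) {
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  purine[from] == purine[to]
}

#' Single-base mutant tables for all 64 codons
#'
#' Returns (and caches) a list with, for every codon, its 9 single-base
#' mutants laid out as a 64 x 9 grid (columns 1:3 are the three alternative
#' bases at codon position 1, and so on): the mutant codon index, whether the
#' change is a transition, whether it is synonymous, and whether the mutant is
#' a stop codon.  Also carries per-codon Nei-Gojobori style synonymous site
#' counts (stop mutants removed from each position's denominator so that every
#' sense codon contributes exactly 3 sites) and per-position degeneracy flags.
#'
#' @noRd
codon_tables <- function() {
  tab <- .hadtx_cache$codon_tab
  if (!is.null(tab)) return(tab)

  gc_map <- Biostrings::GENETIC_CODE
  codons <- names(gc_map)
  aa <- unname(gc_map)
  n <- length(codons)
  codon_mat <- do.call(rbind, strsplit(codons, ""))

  target <- matrix(NA_integer_, n, 9)
  ts <- syn <- stp <- matrix(FALSE, n, 9)
  col <- 0L
  for (p in 1:3) {
    for (k in 1:3) {
      col <- col + 1L
      for (ci in seq_len(n)) {
        b_old <- codon_mat[ci, p]
        alt <- setdiff(DNA_BASES, b_old)[k]
        mut <- codon_mat[ci, ]
        mut[p] <- alt
        mi <- match(paste(mut, collapse = ""), codons)
        target[ci, col] <- mi
        ts[ci, col] <- is_transition(b_old, alt)
        syn[ci, col] <- aa[mi] == aa[ci] && aa[ci] != "*"
        stp[ci, col] <- aa[mi] == "*"
      }
    }
  }

  # NG-style site counts with stop-mutant rescaling: each position of a sense
  # codon contributes one site split between synonymous and nonsynonymous.
  s_sites <- rep(NA_real_, n)
  deg4 <- deg0 <- matrix(NA, n, 3)
  for (ci in seq_len(n)) {
    if (aa[ci] == "*") next
    s <- 0
    for (p in 1:3) {
      cols <- (3L * p - 2L):(3L * p)
      keep <- !stp[ci, cols]
      denom <- sum(keep)
      s_p <- if (denom > 0) sum(syn[ci, cols][keep]) / denom else 0
      s <- s + s_p
      deg4[ci, p] <- all(syn[ci, cols])
      deg0[ci, p] <- !any(syn[ci, cols])
    }
    s_sites[ci] <- s
  }

  tab <- list(codons = codons, aa = aa, codon_mat = codon_mat,
              sense = which(aa != "*"), is_stop = aa == "*",
              target = target, is_ts = ts, is_syn = syn, is_stop_target = stp,
              s_sites = s_sites, n_sites = 3 - s_sites,
              deg4 = deg4, deg0 = deg0)
  .hadtx_cache$codon_tab <- tab
  tab
}

# Pathway-averaged substitution counts for one codon pair.  Multi-difference
# codons average over all orderings of the differing positions; orderings that
# pass through a stop codon are dropped first, and reinstated (with the stop
# steps counted as nonsynonymous) only when every ordering is blocked.
codon_pair_path_counts <- function(ci, cj, tab) {
  if (ci == cj) return(c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0))
  a <- tab$codon_mat[ci, ]
  b <- tab$codon_mat[cj, ]
  diffs <- which(a != b)
  perms <- switch(length(diffs),
    list(diffs),
    list(diffs, diffs[c(2, 1)]),
    {
      idx <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(seq_len(6), function(i) diffs[idx[i, ]])
    })
  walk <- function(order) {
    cur <- a
    res <- c(sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0, blocked = 0)
    aa_cur <- tab$aa[ci]
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      ni <- match(paste(nxt, collapse = ""), tab$codons)
      aa_nxt <- tab$aa[ni]
      tsflag <- is_transition(cur[pos], b[pos])
      if (aa_nxt == "*" || aa_cur == "*") {
        res["blocked"] <- 1
        res[if (tsflag) "nd_ts" else "nd_tv"] <- res[if (tsflag) "nd_ts" else "nd_tv"] + 1
      } else if (aa_nxt == aa_cur) {
        res[if (tsflag) "sd_ts" else "sd_tv"] <- res[if (tsflag) "sd_ts" else "sd_tv"] + 1
      } else {
        res[if (tsflag) "nd_ts" else "nd_tv"] <- res[if (tsflag) "nd_ts" else "nd_tv"] + 1
      }
      cur <- nxt
      aa_cur <- aa_nxt
    }
    res
  }
  all_paths <- lapply(perms, walk)
  ok <- vapply(all_paths, function(r) r["blocked"] == 0, logical(1))
  use <- if (any(ok)) all_paths[ok] else all_paths
  avg <- Reduce(`+`, use) / length(use)
  avg[c("sd_ts", "sd_tv", "nd_ts", "nd_tv")]
}

# Full 64 x 64 lookup of pathway-averaged counts, cached on first use.
path_tables <- function() {
  pt <- .hadtx_cache$path_tab
  if (!is.null(pt)) return(pt)
  tab <- codon_tables()
  n <- length(tab$codons)
  sd_ts <- sd_tv <- nd_ts <- nd_tv <- matrix(NA_real_, n, n)
  for (ci in tab$sense) {
    for (cj in tab$sense) {
      v <- codon_pair_path_counts(ci, cj, tab)
      sd_ts[ci, cj] <- v["sd_ts"]
      sd_tv[ci, cj] <- v["sd_tv"]
      nd_ts[ci, cj] <- v["nd_ts"]
      nd_tv[ci, cj] <- v["nd_tv"]
    }
  }
  pt <- list(sd_ts = sd_ts, sd_tv = sd_tv, nd_ts = nd_ts, nd_tv = nd_tv)
  .hadtx_cache$path_tab <- pt
  pt
}

# Split a CDS string into codon indices (1..64); NA for codons containing
# anything outside A/C/G/T.
codon_indices <- function(cds) {
  cds <- toupper(as.character(cds))
  L <- nchar(cds)
  if (L %% 3 != 0) stop("CDS length must be a multiple of 3")
  starts <- seq(1L, L, by = 3L)
  match(substring(cds, starts, starts + 2L), codon_tables()$codons)
}

translate_cds <- function(cds) {
  tab <- codon_tables()
  idx <- codon_indices(cds)
  paste(tab$aa[idx], collapse = "")
}
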