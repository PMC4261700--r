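# Independent oracles used across the suite.  These deliberately avoid the
# package's own codon tables: translation goes through seqinr, enumeration
# is done by direct recursion.

oracle_translate_codon <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

ORACLE_BASES <- c("A", "C", "G", "T")

# Brute-force NG-style site count: enumerate the 9 single-base mutants,
# per position count the synonymous fraction among non-stop mutants.
oracle_site_count <- function(codon) {
  aa0 <- oracle_translate_codon(codon)
  stopifnot(aa0 != "*")
  s <- 0
  for (p in 1:3) {
    syn <- 0
    nonstop <- 0
    for (b in setdiff(ORACLE_BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      aam <- oracle_translate_codon(mut)
      if (aam == "*") next
      nonstop <- nonstop + 1
      if (aam == aa0) syn <- syn + 1
    }
    if (nonstop > 0) s <- s + syn / nonstop
  }
  c(s = s, n = 3 - s)
}

# Brute-force pathway enumeration for a codon pair: walk every ordering of
# the differing positions, drop orderings passing through a stop codon
# (keep all orderings, stop steps counted nonsynonymous, when every one is
# blocked), average synonymous/nonsynonymous step counts.
oracle_path_counts <- function(c1, c2) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(c(sd = 0, nd = 0))
  perms <- if (length(diffs) == 1) list(diffs) else {
    pp <- list()
    rec <- function(prefix, rest) {
      if (length(rest) == 0) {
        pp[[length(pp) + 1]] <<- prefix
      } else {
        for (i in seq_along(rest)) rec(c(prefix, rest[i]), rest[-i])
      }
    }
    rec(integer(0), diffs)
    pp
  }
  res <- lapply(perms, function(ord) {
    cur <- c1
    sd <- nd <- 0
    blocked <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      a1 <- oracle_translate_codon(cur)
      a2 <- oracle_translate_codon(nxt)
      if (a2 == "*" || a1 == "*") {
        blocked <- TRUE
        nd <- nd + 1
      } else if (a1 == a2) {
        sd <- sd + 1
      } else {
        nd <- nd + 1
      }
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  use <- if (any(ok)) res[ok] else res
  c(sd = mean(vapply(use, `[[`, numeric(1), "sd")),
    nd = mean(vapply(use, `[[`, numeric(1), "nd")))
}

# Quadratic-DP global aligner with affine gaps (three-matrix recurrence),
# returning only the optimal score.
oracle_global_score <- function(a, b, match = 2, mismatch = -3,
                                gap_open = 5, gap_ext = 2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  NEG <- -1e9
  Mm <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  Mm[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -gap_open - gap_ext * i
  for (j in seq_len(m)) Iy[1, j + 1] <- -gap_open - gap_ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j] && x[i] != "N") match else mismatch
      Mm[i + 1, j + 1] <- max(Mm[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(Mm[i, j + 1] - gap_open - gap_ext,
                              Ix[i, j + 1] - gap_ext)
      Iy[i + 1, j + 1] <- max(Mm[i + 1, j] - gap_open - gap_ext,
                              Iy[i + 1, j] - gap_ext)
    }
  }
  max(Mm[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Exact two-sided mid-p for the conditional binomial null, written directly
# from pbinom/dbinom.
oracle_midp <- function(k1, t, q) {
  atom <- dbinom(k1, t, q)
  lo <- pbinom(k1 - 1, t, q) + 0.5 * atom
  hi <- pbinom(k1, t, q, lower.tail = FALSE) + 0.5 * atom
  min(1, 2 * min(lo, hi))
}

all_sense_codons <- function() {
  cods <- as.vector(outer(as.vector(outer(ORACLE_BASES, ORACLE_BASES,
                                          paste0)),
                          ORACLE_BASES, paste0))
  cods[vapply(cods, oracle_translate_codon, character(1)) != "*"]
}

random_dna_str <- function(n) {
  paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
}
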