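# Approximate Ka/Ks estimation for codon-aligned ortholog CDS pairs.
#
# Two estimators are provided.  ng86_kaks() is the transparent
# Nei-Gojobori-style oracle: equal mutation weights, pathway averaging for
# multi-difference codons, Jukes-Cantor correction.  yn00_kaks() is the
# headline method: a Yang-Nielsen-style approximation with a
# transition/transversion rate ratio (kappa) estimated from the data,
# F3x4 codon-frequency weighting of site counts, and a Kimura two-parameter
# correction applied separately to synonymous and nonsynonymous distances.
# Stop-codon mutational paths are excluded everywhere, with site counts
# rescaled so every sense codon contributes exactly three sites.

#' Synonymous/nonsynonymous site count of a single codon
#'
#' Over the nine single-base mutants of the codon, the fraction of synonymous
#' changes is summed per position; mutants that are stop codons are excluded
#' from that position's denominator, so `s + n = 3` for every sense codon.
#'
#' @param codon 3-letter character codon (A/C/G/T only, not a stop).
#' @return named numeric vector `c(s_sites, n_sites)`.
#' @export
#' @examples
#' ng86_site_count("TTT")  # c(1/3, 8/3)
ng86_site_count <- function(codon) {
  tab <- codon_tables()
  codon <- toupper(codon)
  ci <- match(codon, tab$codons)
  if (is.na(ci)) stop("not an unambiguous codon: ", codon)
  if (tab$is_stop[ci]) stop("stop codon has no site count: ", codon)
  c(s_sites = tab$s_sites[ci], n_sites = tab$n_sites[ci])
}

# Kimura 2-parameter components from transition proportion P and transversion
# proportion Q.  Returns total distance d, the transition part (alpha*t) and
# the per-type transversion part (beta*t), or NULL when the correction is
# undefined (saturation).
k80_components <- function(P, Q) {
  R1 <- 1 - 2 * P - Q
  R2 <- 1 - 2 * Q
  if (R1 <= 0 || R2 <= 0) return(NULL)
  a <- -0.5 * log(R1) + 0.25 * log(R2)
  b <- -0.25 * log(R2)
  list(d = a + 2 * b, ts = a, tv = b)
}

jc_correct <- function(p) {
  if (is.nan(p)) return(NaN)
  if (p >= 0.75) return(NA_real_)
  if (p == 0) return(0)
  -0.75 * log(1 - 4 * p / 3)
}

classify_ratio <- function(ka, ks, ratio, threshold = 1) {
  if (is.na(ka) || is.na(ks)) return("undefined")
  if (ks == 0) return("undefined")
  if (ratio > threshold) return("positive")
  if (ratio < threshold) return("purifying")
  "neutral"
}

# Shared preparation: codon indices with unusable codon pairs dropped
# (N-containing or stop codons on either side).
kaks_prepare <- function(cds_a, cds_b) {
  ia <- codon_indices(cds_a)
  ib <- codon_indices(cds_b)
  if (length(ia) != length(ib)) {
    stop("CDS pair must be codon-aligned to equal length")
  }
  tab <- codon_tables()
  keep <- !is.na(ia) & !is.na(ib) & !tab$is_stop[ia] & !tab$is_stop[ib]
  list(ia = ia[keep], ib = ib[keep], tab = tab)
}

kaks_result <- function(pair_id, method, S, N, Sd, Nd, kappa, Ka, Ks,
                        flag = "ok") {
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  data.frame(pair_id = pair_id, method = method,
             S_sites = S, N_sites = N, Sd = Sd, Nd = Nd,
             kappa = kappa, Ka = Ka, Ks = Ks, ratio = ratio,
             classification = classify_ratio(Ka, Ks, ratio),
             flag = flag, stringsAsFactors = FALSE)
}

#' Nei-Gojobori (1986)-style Ka/Ks
#'
#' Site counts are averaged over the two sequences; substitution counts use
#' pathway averaging over all minimal mutational orderings for
#' multi-difference codons (orderings through stop codons dropped before
#' averaging); Jukes-Cantor correction is applied separately to the
#' synonymous and nonsynonymous proportions.
#'
#' @param cds_a,cds_b equal-length, gap-free, codon-aligned CDS strings.
#' @param pair_id identifier carried into the result row.
#' @return one-row data.frame (`KaKsResult`): sites, counts, Ka, Ks, ratio,
#'   selection classification and a flag (`"saturated"` when a proportion
#'   reaches 3/4 and the correction is undefined).
#' @export
ng86_kaks <- function(cds_a, cds_b, pair_id = "pair") {
  prep <- kaks_prepare(cds_a, cds_b)
  tab <- prep$tab
  pt <- path_tables()
  S <- (sum(tab$s_sites[prep$ia]) + sum(tab$s_sites[prep$ib])) / 2
  N <- (sum(tab$n_sites[prep$ia]) + sum(tab$n_sites[prep$ib])) / 2
  ij <- cbind(prep$ia, prep$ib)
  Sd <- sum(pt$sd_ts[ij]) + sum(pt$sd_tv[ij])
  Nd <- sum(pt$nd_ts[ij]) + sum(pt$nd_tv[ij])
  pS <- if (S > 0) Sd / S else NaN
  pN <- if (N > 0) Nd / N else NaN
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  flag <- if ((length(Ks) && is.na(Ks) && !is.nan(pS)) ||
              (length(Ka) && is.na(Ka) && !is.nan(pN))) "saturated" else "ok"
  kaks_result(pair_id, "NG86", S, N, Sd, Nd, NA_real_, Ka, Ks, flag)
}

# F3x4 codon frequencies (position-specific nucleotide frequencies) from the
# two sequences pooled, normalized over sense codons.
f3x4_freqs <- function(ia, ib, tab) {
  cm <- tab$codon_mat
  f <- matrix(0, 3, 4, dimnames = list(NULL, DNA_BASES))
  for (p in 1:3) {
    obs <- c(cm[ia, p], cm[ib, p])
    t4 <- table(factor(obs, levels = DNA_BASES))
    f[p, ] <- (t4 + 1e-9) / sum(t4 + 1e-9)
  }
  fc <- f[1, cm[, 1]] * f[2, cm[, 2]] * f[3, cm[, 3]]
  fc[tab$is_stop] <- 0
  fc / sum(fc)
}

# kappa/frequency-weighted site counts, rescaled per position so each sense
# codon contributes 3 sites.  Returns per-codon synonymous site counts.
yn_site_counts <- function(kappa, freq, tab) {
  W <- freq[tab$target] * ifelse(tab$is_ts, kappa, 1)
  dim(W) <- dim(tab$target)
  W[tab$is_stop_target] <- 0
  SynW <- W * tab$is_syn
  s <- rep(NA_real_, length(tab$codons))
  for (p in 1:3) {
    cols <- (3L * p - 2L):(3L * p)
    tot <- rowSums(W[, cols, drop = FALSE])
    sw <- rowSums(SynW[, cols, drop = FALSE])
    frac <- ifelse(tot > 0, sw / tot, 0)
    s <- if (p == 1) frac else s + frac
  }
  s[tab$is_stop] <- NA_real_
  s
}

# Initial kappa from sites fourfold-degenerate in both codons and sites
# nondegenerate in both, each corrected with K80 and pooled by site count.
kappa_init_estimate <- function(ia, ib, tab) {
  cm <- tab$codon_mat
  est <- list()
  for (cls in c("deg4", "deg0")) {
    deg <- tab[[cls]]
    L <- ts <- tv <- 0
    for (p in 1:3) {
      sel <- deg[ia, p] & deg[ib, p]
      if (!any(sel)) next
      ba <- cm[ia[sel], p]
      bb <- cm[ib[sel], p]
      L <- L + sum(sel)
      diff <- ba != bb
      if (any(diff)) {
        tsv <- is_transition(ba[diff], bb[diff])
        ts <- ts + sum(tsv)
        tv <- tv + sum(!tsv)
      }
    }
    if (L > 0) {
      kc <- k80_components(ts / L, tv / L)
      if (!is.null(kc) && kc$tv > 0 && kc$ts > 0) {
        est[[cls]] <- c(kappa = kc$ts / kc$tv, w = L)
      }
    }
  }
  if (length(est) == 0) return(1)
  k <- vapply(est, `[`, numeric(1), "kappa")
  w <- vapply(est, `[`, numeric(1), "w")
  max(0.01, min(99, sum(k * w) / sum(w)))
}

#' Yang-Nielsen-style approximate Ka/Ks
#'
#' Kappa is first estimated from fourfold-degenerate and nondegenerate site
#' comparisons (K80-corrected), then site counts weighted by kappa and F3x4
#' codon frequencies, pathway-averaged substitution counts split into
#' transitions and transversions, and K80 corrections applied separately to
#' synonymous and nonsynonymous proportions.  Kappa and the site counts are
#' iterated to a fixed point (tolerance `tol`, at most `max_iter` rounds);
#' non-convergence is flagged and the NG86 result recorded as fallback.
#'
#' @inheritParams ng86_kaks
#' @param tol convergence tolerance on kappa.
#' @param max_iter maximum number of iterations.
#' @return one-row data.frame as [ng86_kaks()], with the kappa estimate.
#' @export
yn00_kaks <- function(cds_a, cds_b, pair_id = "pair", tol = 1e-6,
                      max_iter = 100) {
  prep <- kaks_prepare(cds_a, cds_b)
  tab <- prep$tab
  pt <- path_tables()
  ia <- prep$ia
  ib <- prep$ib
  ij <- cbind(ia, ib)
  Sd_ts <- sum(pt$sd_ts[ij]); Sd_tv <- sum(pt$sd_tv[ij])
  Nd_ts <- sum(pt$nd_ts[ij]); Nd_tv <- sum(pt$nd_tv[ij])
  Sd <- Sd_ts + Sd_tv
  Nd <- Nd_ts + Nd_tv
  freq <- f3x4_freqs(ia, ib, tab)

  kappa <- kappa_init_estimate(ia, ib, tab)
  converged <- FALSE
  S <- N <- NA_real_
  ks_c <- kn_c <- NULL
  for (iter in seq_len(max_iter)) {
    s_codon <- yn_site_counts(kappa, freq, tab)
    S <- (sum(s_codon[ia]) + sum(s_codon[ib])) / 2
    N <- 3 * length(ia) - S
    ks_c <- if (S > 0) k80_components(Sd_ts / S, Sd_tv / S) else NULL
    kn_c <- if (N > 0) k80_components(Nd_ts / N, Nd_tv / N) else NULL
    alpha <- beta <- 0
    if (!is.null(ks_c)) { alpha <- alpha + S * ks_c$ts; beta <- beta + S * ks_c$tv }
    if (!is.null(kn_c)) { alpha <- alpha + N * kn_c$ts; beta <- beta + N * kn_c$tv }
    kappa_new <- if (beta > 0 && alpha > 0) max(0.01, min(99, alpha / beta)) else kappa
    if (abs(kappa_new - kappa) < tol) {
      kappa <- kappa_new
      converged <- TRUE
      break
    }
    kappa <- kappa_new
  }

  saturated <- (Sd > 0 && is.null(ks_c)) || (Nd > 0 && is.null(kn_c))
  if (saturated) {
    return(kaks_result(pair_id, "YN00", S, N, Sd, Nd, kappa,
                       NA_real_, NA_real_, "saturated"))
  }
  Ks <- if (is.null(ks_c)) 0 else ks_c$d
  Ka <- if (is.null(kn_c)) 0 else kn_c$d
  if (!converged) {
    fb <- ng86_kaks(cds_a, cds_b, pair_id)
    res <- kaks_result(pair_id, "YN00", S, N, Sd, Nd, kappa, fb$Ka, fb$Ks,
                       "not_converged_ng86_fallback")
    return(res)
  }
  kaks_result(pair_id, "YN00", S, N, Sd, Nd, kappa, Ka, Ks)
}

#' Classify selection from Ka/Ks results
#'
#' Ratio above the threshold is positive selection, below is purifying,
#' exactly at the threshold neutral; pairs with `Ks = 0` are undefined and
#' tallied separately (those with `Ka > 0` listed as positive candidates
#' rather than infinite ratios).  Also reports the banding used for the
#' Ka-Ks scatter (`>1`, `0.5-1`, `<0.5`).
#'
#' @param results data.frame of Ka/Ks rows ([ng86_kaks()] / [yn00_kaks()]).
#' @param threshold ratio threshold separating positive from purifying.
#' @return list with `results` (classification and band columns filled) and
#'   `tallies`.
#' @export
classify_selection <- function(results, threshold = 1) {
  stopifnot(nrow(results) >= 1)
  cls <- mapply(classify_ratio, results$Ka, results$Ks, results$ratio,
                MoreArgs = list(threshold = threshold))
  band <- rep(NA_character_, nrow(results))
  ok <- !is.na(results$ratio)
  band[ok & results$ratio > 1] <- ">1"
  band[ok & results$ratio <= 1 & results$ratio >= 0.5] <- "0.5-1"
  band[ok & results$ratio < 0.5] <- "<0.5"
  results$classification <- unname(cls)
  results$band <- band
  undef_pos <- cls == "undefined" & !is.na(results$Ka) & results$Ka > 0 &
    !is.na(results$Ks) & results$Ks == 0
  tallies <- list(
    n = nrow(results),
    positive = sum(cls == "positive"),
    purifying = sum(cls == "purifying"),
    neutral = sum(cls == "neutral"),
    undefined = sum(cls == "undefined"),
    undefined_positive_candidate = sum(undef_pos),
    band_gt1 = sum(band == ">1", na.rm = TRUE),
    band_mid = sum(band == "0.5-1", na.rm = TRUE),
    band_lt05 = sum(band == "<0.5", na.rm = TRUE))
  list(results = results, tallies = tallies)
}

#' Codon-align a CDS pair from a global alignment
#'
#' Globally aligns two CDS sequences and drops any codon (reading frame of
#' the first sequence) whose alignment columns contain a gap on either side,
#' returning equal-length gap-free codon-aligned strings suitable for
#' [ng86_kaks()] / [yn00_kaks()].
#'
#' @param cds_a,cds_b CDS strings (lengths multiples of 3 not required after
#'   gaps; complete codons only are retained).
#' @param aln optional precomputed [align_global()] result for the pair.
#' @return list with `cds_a`, `cds_b`.
#' @export
codon_align <- function(cds_a, cds_b, aln = NULL) {
  if (is.null(aln)) aln <- align_global(cds_a, cds_b)
  x <- strsplit(aln$aligned_a, "")[[1]]
  y <- strsplit(aln$aligned_b, "")[[1]]
  # codon index along sequence a; columns where a has a gap get index 0
  ca <- cumsum(x != "-")
  cod <- ifelse(x == "-", 0L, (ca - 1L) %/% 3L + 1L)
  bad <- unique(c(cod[x == "-" | y == "-"],
                  cod[ca > 0 & (x == "N" | y == "N")]))
  keep <- cod > 0 & !(cod %in% bad)
  # retain only codons with all three columns intact
  cnt <- table(cod[keep])
  full <- as.integer(names(cnt)[cnt == 3])
  keep <- keep & cod %in% full
  list(cds_a = paste(x[keep], collapse = ""),
       cds_b = paste(y[keep], collapse = ""))
}
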