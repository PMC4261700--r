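# Count-based differential expression between host libraries: TMM
# normalization, an MA-plot binomial random-sampling statistic for 1-vs-1
# library contrasts, q-values, threshold calling, intersection sets,
# Spearman sample correlations and qPCR delta-Ct.

#' Trimmed mean of M-values normalization factors
#'
#' Composition-bias normalization factors computed from the published TMM
#' definition: gene-wise M values between each sample and a reference column
#' (the one whose 75th percentile of scaled counts is closest to the mean)
#' are doubly trimmed (by M and by A), averaged with precision weights and
#' exponentiated; factors are rescaled so their geometric mean is 1.  Genes
#' with a zero in either sample are excluded.
#'
#' @param counts gene x sample integer matrix.
#' @param lib_sizes library sizes; column sums by default.
#' @param trim_m fraction trimmed from each tail of the M distribution.
#' @param trim_a fraction trimmed from each tail of the A distribution.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_normalization <- function(counts, lib_sizes = colSums(counts),
                              trim_m = 0.3, trim_a = 0.05) {
  stopifnot(ncol(counts) >= 2)
  uq <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j] / lib_sizes[j]
    quantile(x[x > 0], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    yk <- counts[, j]
    yr <- counts[, ref]
    nk <- lib_sizes[j]
    nr <- lib_sizes[ref]
    keep <- yk > 0 & yr > 0
    yk <- yk[keep]; yr <- yr[keep]
    if (length(yk) == 0) {
      warning("no usable genes for TMM; factor set to 1")
      return(1)
    }
    M <- log2((yk / nk) / (yr / nr))
    A <- 0.5 * log2((yk / nk) * (yr / nr))
    w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep2)) {
      warning("all genes trimmed in TMM; factor set to 1")
      return(1)
    }
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' MA-plot random-sampling statistic for a two-library comparison
#'
#' For each gene, `M = log2((k1/n1)/(k2/n2))` and
#' `A = 0.5 (log2(k1/n1) + log2(k2/n2))` (zero counts offset by 0.5 in M and
#' A only).  Under the null the first count given the total `t = k1 + k2`
#' is binomial with success probability `q = n1/(n1+n2)`; `z` is the normal
#' deviate of `k1` under that sampling model (signed like M) and `p` the
#' two-sided tail obtained by doubling the smaller skewness-corrected
#' (second-order Edgeworth) tail, the continuous analogue of the exact
#' mid-p.  Genes with both counts zero are untestable (`NA`).
#'
#' @param k1,k2 integer count vectors (gene-parallel).
#' @param n1,n2 effective library sizes (library size x normalization
#'   factor).
#' @return data.frame with `M`, `A`, `z`, `p`.
#' @export
mars_statistic <- function(k1, k2, n1, n2) {
  stopifnot(length(k1) == length(k2), n1 > 0, n2 > 0)
  k1o <- ifelse(k1 == 0, 0.5, k1)
  k2o <- ifelse(k2 == 0, 0.5, k2)
  M <- log2((k1o / n1) / (k2o / n2))
  A <- 0.5 * (log2(k1o / n1) + log2(k2o / n2))
  t <- k1 + k2
  q <- n1 / (n1 + n2)
  mu <- t * q
  sd0 <- sqrt(t * q * (1 - q))
  z <- ifelse(t > 0, (k1 - mu) / sd0, NA_real_)
  g <- (1 - 2 * q) / sd0  # skewness of the standardized binomial count
  corr <- g * (z^2 - 1) * stats::dnorm(z) / 6
  up <- pnorm(z, lower.tail = FALSE) + corr
  lo <- pnorm(z) - corr
  p <- ifelse(is.na(z), NA_real_,
              pmin(1, 2 * pmax(0, pmin(up, lo))))
  data.frame(M = M, A = A, z = z, p = p)
}

#' Exact conditional binomial p-value for a two-library comparison
#'
#' The reference check for [mars_statistic()]: under the null, `k1` given
#' `t = k1 + k2` is `Binomial(t, n1/(n1+n2))`.  Returns the two-sided
#' mid-p value, `min(1, 2 min(P(X < k1), P(X > k1)) + P(X = k1))`,
#' the standard continuity convention for discrete tests and the quantity
#' the normal approximation in [mars_statistic()] targets.
#'
#' @inheritParams mars_statistic
#' @return numeric p-value vector.
#' @export
exact_conditional_p <- function(k1, k2, n1, n2) {
  t <- k1 + k2
  q <- n1 / (n1 + n2)
  atom <- stats::dbinom(k1, t, q)
  lo <- stats::pbinom(k1 - 1, t, q) + 0.5 * atom
  hi <- stats::pbinom(k1, t, q, lower.tail = FALSE) + 0.5 * atom
  ifelse(t > 0, pmin(1, 2 * pmin(lo, hi)), NA_real_)
}

#' q-values from p-values
#'
#' `method = "storey"`: pi0 estimated on the lambda grid 0.05..0.95 with a
#' cubic smoothing spline evaluated at the last grid point, then the
#' step-up construction; falls back to Benjamini-Hochberg (with a warning)
#' for fewer than 10 p-values.  `method = "bh"`: standard step-up.
#' q-values are monotone nondecreasing along sorted p and invariant to
#' input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NA passed through).
#' @param method `"storey"` or `"bh"`.
#' @return q-value vector aligned with the input.
#' @export
qvalues <- function(pvals, method = c("storey", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(pvals)
  p <- pvals[ok]
  stopifnot(all(p >= 0 & p <= 1))
  out <- rep(NA_real_, length(pvals))
  if (length(p) == 0) return(out)
  if (method == "storey" && length(p) < 10) {
    warning("fewer than 10 p-values; falling back to BH")
    method <- "bh"
  }
  if (method == "bh") {
    out[ok] <- p.adjust(p, method = "BH")
    return(out)
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  pi0 <- min(1, max(pi0, 1e-8))
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- rep(NA_real_, m)
  q[o] <- cummin(pi0 * m * p[o] / rank(p, ties.method = "max")[o])
  out[ok] <- pmin(1, q)
  out
}

#' Call differentially expressed transcripts
#'
#' A gene is `up` (higher in the original-host library) when
#' `q < q_max` and `M > min_abs_log2fc`, `down` when `q < q_max` and
#' `M < -min_abs_log2fc`, otherwise `ns`.
#'
#' @param results data.frame with at least `M` and `q` columns.
#' @param q_max significance threshold on the q-value.
#' @param min_abs_log2fc fold-change gate on |log2 fold change|.
#' @return the input with a `call` column plus a `tallies` attribute
#'   (`de`, `up`, `down`).
#' @export
call_dets <- function(results, q_max = 0.05, min_abs_log2fc = 1) {
  stopifnot(all(c("M", "q") %in% names(results)))
  call <- rep("ns", nrow(results))
  sig <- !is.na(results$q) & results$q < q_max
  call[sig & results$M > min_abs_log2fc] <- "up"
  call[sig & results$M < -min_abs_log2fc] <- "down"
  results$call <- call
  attr(results, "tallies") <- c(de = sum(call != "ns"),
                                up = sum(call == "up"),
                                down = sum(call == "down"))
  results
}

#' Intersect up-regulated sets across contrasts and sexes
#'
#' The per-sex consistent set is the intersection of the up-sets over that
#' sex's host contrasts; the final set intersects the per-sex sets.
#'
#' @param up_sets named list of character vectors, one per contrast.
#' @param sexes named character vector mapping contrast name -> sex label;
#'   defaults to a single group.
#' @return list with `per_sex` (named list of intersections) and
#'   `consistent` (cross-sex intersection).
#' @export
intersect_up_sets <- function(up_sets, sexes = NULL) {
  stopifnot(length(up_sets) >= 1)
  if (is.null(sexes)) sexes <- setNames(rep("all", length(up_sets)),
                                        names(up_sets))
  groups <- split(names(up_sets), sexes[names(up_sets)])
  per_sex <- lapply(groups, function(g) Reduce(intersect, up_sets[g]))
  consistent <- Reduce(intersect, per_sex)
  list(per_sex = per_sex, consistent = sort(consistent))
}

#' Spearman correlation matrix of normalized counts
#'
#' Rank-based correlation between samples after dividing by effective
#' library sizes; ties are mid-ranked.  Zero-variance columns give NA.
#'
#' @param counts gene x sample matrix.
#' @param factors per-sample normalization factors (default 1).
#' @param lib_sizes library sizes; column sums by default.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sample_correlations <- function(counts, factors = NULL,
                                lib_sizes = colSums(counts)) {
  stopifnot(ncol(counts) >= 2)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  norm <- sweep(counts, 2, lib_sizes * factors, "/")
  suppressWarnings(cc <- cor(norm, method = "spearman"))
  diag(cc) <- ifelse(apply(norm, 2, function(x) sd(x) > 0), 1, NA)
  cc
}

#' Relative expression by the delta-Ct method
#'
#' Relative expression is `2^-(Ct_target - Ct_reference)`; replicate vectors
#' return the per-replicate values with mean and standard deviation.
#'
#' @param ct_target,ct_ref cycle-threshold values (> 0), equal length.
#' @return list with `rel` (per-replicate relative expression), `mean`,
#'   `sd`.
#' @export
delta_ct <- function(ct_target, ct_ref) {
  if (missing(ct_ref) || is.null(ct_ref) || length(ct_ref) == 0) {
    stop("reference Ct values are required")
  }
  stopifnot(length(ct_target) == length(ct_ref),
            all(ct_target > 0), all(ct_ref > 0))
  rel <- 2^(-(ct_target - ct_ref))
  list(rel = rel, mean = mean(rel), sd = if (length(rel) > 1) sd(rel) else 0)
}
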