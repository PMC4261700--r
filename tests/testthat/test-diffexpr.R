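# Normalization, the MA random-sampling statistic, q-values, calling,
# intersections, correlations and delta-Ct.

test_that("TMM factors are 1 for identical or purely rescaled samples", {
  set.seed(20)
  x <- rnbinom(2000, mu = 50, size = 10) + 1L
  m <- cbind(s1 = x, s2 = x)
  expect_equal(unname(tmm_normalization(m)), c(1, 1))
  m2 <- cbind(s1 = x, s2 = 2L * x)  # library size absorbs the scale
  expect_equal(unname(tmm_normalization(m2)), c(1, 1), tolerance = 1e-12)
})

test_that("TMM matches a hand-computed trimmed weighted mean on a toy", {
  counts <- cbind(s1 = c(100L, 200L, 300L, 400L, 500L, 600L, 700L, 800L,
                         900L, 1000L),
                  s2 = c(110L, 190L, 310L, 390L, 520L, 580L, 720L, 790L,
                         910L, 6000L))
  f <- tmm_normalization(counts, trim_m = 0.2, trim_a = 0.05)
  # hand computation of the same definition
  n1 <- sum(counts[, 1]); n2 <- sum(counts[, 2])
  uq <- c(quantile(counts[, 1] / n1, 0.75), quantile(counts[, 2] / n2, 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  j <- setdiff(1:2, ref)
  yk <- counts[, j]; yr <- counts[, ref]
  nk <- sum(yk); nr <- sum(yr)
  M <- log2((yk / nk) / (yr / nr))
  A <- 0.5 * log2((yk / nk) * (yr / nr))
  w <- (nk - yk) / (nk * yk) + (nr - yr) / (nr * yr)
  n <- length(M)
  keep <- rank(M, ties.method = "first") >= floor(n * 0.2) + 1 &
    rank(M, ties.method = "first") <= n - floor(n * 0.2) &
    rank(A, ties.method = "first") >= floor(n * 0.05) + 1 &
    rank(A, ties.method = "first") <= n - floor(n * 0.05)
  fj <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  fs <- c(1, fj); fs <- fs / exp(mean(log(fs)))
  expect_equal(unname(f[j]), fs[2], tolerance = 1e-12)
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("TMM agrees with the reference edgeR implementation", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  m <- matrix(rnbinom(4000 * 3, mu = 80, size = 5), ncol = 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  m[1:40, 2] <- m[1:40, 2] * 25L
  f_pkg <- tmm_normalization(m)
  f_ref <- edgeR::calcNormFactors(m, method = "TMM")
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 0.01)
})

test_that("the MA statistic is null-centred and swap-antisymmetric", {
  r <- mars_statistic(100, 100, 1e6, 1e6)
  expect_equal(r$M, 0)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  set.seed(22)
  k1 <- rpois(50, 200); k2 <- rpois(50, 150)
  a <- mars_statistic(k1, k2, 1e6, 2e6)
  b <- mars_statistic(k2, k1, 2e6, 1e6)
  expect_equal(a$M, -b$M)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  # both counts zero -> no test
  expect_true(is.na(mars_statistic(0, 0, 1e6, 1e6)$p))
})

test_that("the MA p-value tracks the exact conditional binomial", {
  p_impl <- mars_statistic(100, 50, 1e6, 1e6)$p
  expect_lt(abs(p_impl - oracle_midp(100, 150, 0.5)), 0.01)
  expect_equal(exact_conditional_p(100, 50, 1e6, 1e6),
               oracle_midp(100, 150, 0.5))
})

test_that("q-values reproduce hand step-up results and stay monotone", {
  expect_warning(q1 <- qvalues(0.01, method = "storey"), "fewer than 10")
  expect_equal(q1, 0.01)
  expect_equal(qvalues(c(0.01, 0.02, 0.03), method = "bh"),
               c(0.03, 0.03, 0.03))
  set.seed(23)
  p <- runif(1e4)
  q <- qvalues(p, method = "storey")
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # order invariance
  perm <- sample(length(p))
  expect_equal(qvalues(p[perm], method = "storey"), q[perm])
  # pi0 on uniform p-values is close to 1
  pi0_implied <- max(q)
  expect_gt(pi0_implied, 0.9)
  expect_lte(pi0_implied, 1)
})

test_that("DET calls apply both the significance and fold-change gates", {
  res <- data.frame(M = c(2, 0.5, -2, 2), q = c(0.01, 0.01, 0.01, 0.5))
  out <- call_dets(res)
  expect_identical(out$call, c("up", "ns", "down", "ns"))
  expect_equal(unname(attr(out, "tallies")), c(2, 1, 1))
})

test_that("up-set intersections match brute-force set algebra", {
  expect_length(intersect_up_sets(list(a = "g1", b = "g2"))$consistent, 0)
  same <- list(a = c("g1", "g2"), b = c("g2", "g1"))
  expect_setequal(intersect_up_sets(same)$consistent, c("g1", "g2"))
  set.seed(24)
  pool <- paste0("g", 1:200)
  sets <- lapply(1:6, function(i) sample(pool, 80))
  names(sets) <- paste0("c", 1:6)
  sexes <- setNames(rep(c("f", "m"), each = 3), names(sets))
  got <- intersect_up_sets(sets, sexes)
  brute_f <- intersect(intersect(sets$c1, sets$c2), sets$c3)
  brute_m <- intersect(intersect(sets$c4, sets$c5), sets$c6)
  expect_setequal(got$per_sex$f, brute_f)
  expect_setequal(got$per_sex$m, brute_m)
  expect_setequal(got$consistent, intersect(brute_f, brute_m))
})

test_that("Spearman correlations are rank-invariant with mid-ranked ties", {
  set.seed(25)
  x <- rpois(100, 50)
  m <- cbind(s1 = x, s2 = x^2 + 1L, s3 = rpois(100, 50))
  cc <- sample_correlations(m, lib_sizes = rep(1, 3))
  expect_equal(cc["s1", "s2"], 1)  # monotone transform
  expect_equal(diag(cc), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(cc, t(cc))
  toy <- cbind(a = c(1, 2, 2, 4, 5), b = c(2, 1, 4, 4, 5))
  cc2 <- sample_correlations(toy, lib_sizes = c(1, 1))
  expect_equal(cc2["a", "b"],
               cor(rank(toy[, "a"]), rank(toy[, "b"])))
})

test_that("delta-Ct relative expression follows the exponent arithmetic", {
  expect_equal(delta_ct(20, 20)$mean, 1)
  expect_equal(delta_ct(18, 20)$mean, 4)
  r <- delta_ct(c(20, 20, 20), c(20, 20, 20))
  expect_equal(r$mean, 1)
  expect_equal(r$sd, 0)
  expect_error(delta_ct(c(20, 21)), "reference")
})
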