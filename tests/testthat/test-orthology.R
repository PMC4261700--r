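# Similarity search, reciprocal best matching and the ortholog double filter.

make_set <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("a query identical to one subject dominates the hit list", {
  set.seed(1)
  subj <- make_set(c(s1 = random_dna_str(300), s2 = random_dna_str(300),
                     s3 = random_dna_str(300)))
  q <- make_set(c(q1 = as.character(subj[["s2"]])))
  hits <- similarity_search(q, subj)
  expect_gt(nrow(hits), 0)
  top <- hits[1, ]
  expect_identical(top$subject_id, "s2")
  expect_equal(c(top$q_start, top$q_end), c(0, 300))
  expect_equal(top$score, 600)
  expect_identical(top$strand, "+")
})

test_that("reverse-complement queries hit on the minus strand, same score", {
  set.seed(2)
  s <- random_dna_str(250)
  subj <- make_set(c(s1 = s))
  fw <- similarity_search(make_set(c(q = s)), subj)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rv <- similarity_search(make_set(c(q = rc)), subj)
  expect_identical(rv$strand[1], "-")
  expect_equal(rv$score[1], fw$score[1])
  expect_equal(c(rv$q_start[1], rv$q_end[1]), c(0, 250))
})

test_that("reciprocal best matching keeps mutual, unique top hits only", {
  hits_ab <- data.frame(
    query_id = c("a1", "a2", "a3", "a3"),
    subject_id = c("b1", "b1", "b3", "b4"),
    score = c(100, 90, 80, 80), stringsAsFactors = FALSE)
  hits_ba <- data.frame(
    query_id = c("b1", "b3", "b4"),
    subject_id = c("a1", "a3", "a3"),
    score = c(100, 70, 60), stringsAsFactors = FALSE)
  rbm <- reciprocal_best_matches(hits_ab, hits_ba)
  # a1-b1 mutual best; a2's best b1 belongs to a1; a3 ties at the top
  expect_identical(rbm$id_a, "a1")
  expect_identical(rbm$id_b, "b1")
  # output is an injective matching
  expect_false(any(duplicated(rbm$id_a)))
  expect_false(any(duplicated(rbm$id_b)))
})

test_that("reference mapping is exact for identical sequences, NA on ties", {
  set.seed(3)
  s <- random_dna_str(400)
  refs <- make_set(c(r1 = s, r2 = random_dna_str(400), r3 = s))
  tx <- make_set(c(t1 = s, t2 = as.character(refs[["r2"]])))
  m <- map_to_reference(tx, refs)
  expect_true(is.na(m[["t1"]]))  # r1/r3 tie
  expect_identical(m[["t2"]], "r2")
  m2 <- map_to_reference(tx, refs[c("r1", "r2")])
  expect_identical(m2[["t1"]], "r1")
})

test_that("protein matching finds the coding frame and full span", {
  set.seed(4)
  cds <- hadtx:::random_cds(300)
  tx <- paste0("AAAA", cds, "TAA", "CCCCC")
  prot <- hadtx:::translate_cds(cds)
  proteins <- Biostrings::AAStringSet(c(pX = prot,
                                        pY = paste(rep("W", 80),
                                                   collapse = "")))
  hit <- best_protein_match(tx, proteins)
  expect_identical(hit$prot_id, "pX")
  expect_identical(hit$strand, "+")
  expect_equal(hit$frame, 1)  # CDS starts at 0-based position 4
  expect_equal(hit$aa_span, c(0, 100))
  expect_equal(hit$nt_span, c(4, 304))
  # and on the reverse complement, the minus strand is reported
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  hit_rc <- best_protein_match(rc, proteins)
  expect_identical(hit_rc$prot_id, "pX")
  expect_identical(hit_rc$strand, "-")
  expect_equal(hit_rc$nt_span, c(4, 304))
})

test_that("UTR-only sequences have no protein hit", {
  set.seed(5)
  proteins <- Biostrings::AAStringSet(
    c(p1 = paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G"), 120,
                        TRUE), collapse = "")))
  expect_null(best_protein_match(random_dna_str(120), proteins))
})

test_that("the double filter keeps agreeing pairs and codes the rest", {
  rbm <- data.frame(id_a = c("a1", "a2", "a3", "a4"),
                    id_b = c("b1", "b2", "b3", "b4"),
                    stringsAsFactors = FALSE)
  ref_a <- c(a1 = "r1", a2 = "r2", a3 = NA, a4 = "r4")
  ref_b <- c(b1 = "r1", b2 = "rX", b3 = "r3", b4 = "r4")
  prot_a <- c(a1 = "p1", a2 = "p2", a3 = "p3", a4 = "p4")
  prot_b <- c(b1 = "p1", b2 = "p2", b3 = "p3", b4 = "pZ")
  flt <- filter_orthologs(rbm, ref_a, ref_b, prot_a, prot_b)
  expect_identical(flt$orthologs$id_a, "a1")
  expect_identical(flt$dropped$reason,
                   c("ref_mismatch", "ref_unmapped", "prot_mismatch"))
})

test_that("synthetic pairs at 1% divergence are each other's best hits", {
  cfg <- sim_config(n_genes = 50, d_utr5 = 0.01, d_cds_target = 0.01,
                    d_utr3 = 0.01, seed = 6)
  sim <- simulate_transcript_pairs(cfg)
  hits <- similarity_search(sim$original, sim$derived)
  best <- hadtx:::best_unique_hit(hits)
  truth <- setNames(sim$truth$ortholog_map$derived_id,
                    sim$truth$ortholog_map$original_id)
  expect_identical(best[names(truth)], truth)
  # score symmetry between the two directions
  hits_rev <- similarity_search(sim$derived, sim$original)
  key_fwd <- paste(hits$query_id, hits$subject_id)
  key_rev <- paste(hits_rev$subject_id, hits_rev$query_id)
  common <- intersect(key_fwd, key_rev)
  expect_gt(length(common), 40)
  expect_equal(hits$score[match(common, key_fwd)],
               hits_rev$score[match(common, key_rev)])
})

test_that("blast-tabular hit files are read into package coordinates", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "hits.tsv")
  writeLines(c("q1\ts1\t98.5\t200\t3\t0\t1\t200\t300\t101\t1e-50\t350"), f)
  h <- read_blast_tabular(f)
  expect_identical(h$strand, "-")
  expect_equal(c(h$q_start, h$q_end), c(0, 200))
  expect_equal(c(h$s_start, h$s_end), c(100, 300))
})
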