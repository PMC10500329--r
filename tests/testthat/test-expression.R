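test_that("TMM factors are unity for identical or scaled libraries", {
  set.seed(41)
  base <- rnbinom(500, size = 10, mu = 50)
  m <- cbind(a = base, b = base, c = base)
  expect_equal(tmm_factors(m)$factor, rep(1, 3))
  m2 <- cbind(a = base, b = 3L * base, c = base)
  expect_equal(tmm_factors(m2)$factor, rep(1, 3), tolerance = 1e-12)
})

test_that("TMM matches the naive trimmed-weighted-mean oracle and edgeR", {
  set.seed(42)
  for (rep in 1:3) {
    mu <- rlnorm(2000, 4, 1)
    m <- sapply(1:5, function(s) rnbinom(2000, size = 10,
                                         mu = mu * runif(1, 0.5, 2)))
    dimnames(m) <- list(paste0("t", 1:2000), paste0("s", 1:5))
    ours <- tmm_factors(m)$factor
    expect_equal(ours, tmm_oracle(m), tolerance = 1e-10)
    edg <- edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors
    expect_equal(ours, unname(edg), tolerance = 1e-10)
  }
})

test_that("TMM is invariant to row and column order", {
  set.seed(43)
  m <- sapply(1:4, function(s) rnbinom(800, size = 5, mu = rlnorm(800, 4, 1)))
  dimnames(m) <- list(paste0("t", 1:800), paste0("s", 1:4))
  f <- tmm_factors(m)
  perm_r <- sample(nrow(m))
  perm_c <- sample(ncol(m))
  f2 <- tmm_factors(m[perm_r, perm_c])
  expect_equal(f2$factor[match(f$sample, f2$sample)], f$factor,
               tolerance = 1e-12)
  norm <- normalize_tmm(m, f)
  norm2 <- normalize_tmm(m[perm_r, perm_c], f2)
  expect_equal(norm2[rownames(norm), colnames(norm)], norm,
               tolerance = 1e-12)
})

test_that("normalization yields CPM on effective library sizes", {
  m <- matrix(c(100L, 999900L, 50L, 999950L), ncol = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  f <- data.frame(sample = c("s1", "s2"), lib_size = colSums(m),
                  factor = c(1, 1), effective_lib_size = colSums(m))
  norm <- normalize_tmm(m, f)
  expect_equal(norm["g1", "s1"], 100)
  expect_equal(colSums(norm), c(s1 = 1e6, s2 = 1e6))
  # doubling every count leaves normalized values unchanged
  expect_equal(normalize_tmm(2L * m, tmm_factors(2L * m)),
               normalize_tmm(m, tmm_factors(m)))
  expect_error(normalize_tmm(m, f[1, ]), "missing")
})

test_that("BH adjustment reproduces the step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.123), 0.123)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(44)
  p <- runif(200)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("the built-in NB test is calibrated under the null", {
  set.seed(45)
  n <- 2000
  mu <- rlnorm(n, 5, 1)
  m <- sapply(1:8, function(s) rnbinom(n, size = 10, mu = mu))
  dimnames(m) <- list(paste0("t", 1:n), paste0("s", 1:8))
  tab <- de_test(m, rep(c("HS", "NHS"), each = 4))
  ks <- suppressWarnings(ks.test(tab$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(attr(tab, "dispersion"), 0.1, tolerance = 0.05)

  # all-zero transcript
  m[1, ] <- 0L
  tab0 <- de_test(m, rep(c("HS", "NHS"), each = 4))
  expect_equal(tab0$log2fc[1], 0)
  expect_equal(tab0$pvalue[1], 1)
})

test_that("strong clean shifts give the expected fold change", {
  set.seed(46)
  n <- 400
  mu <- rep(100, n)
  mu_hs <- mu
  mu_hs[1:20] <- 400
  m <- cbind(sapply(1:4, function(s) rpois(n, mu_hs)),
             sapply(1:4, function(s) rpois(n, mu)))
  dimnames(m) <- list(paste0("t", 1:n), paste0("s", 1:8))
  tab <- de_test(m, rep(c("HS", "NHS"), each = 4))
  expect_equal(mean(tab$log2fc[1:20]), 2, tolerance = 0.1)
  expect_true(all(tab$fdr[1:20] < 1e-6))
})

test_that("the consensus rule applies fold, FDR and sign concordance", {
  mk <- function(fc, fdr) {
    data.frame(transcript_id = paste0("t", seq_along(fc)), log2fc = fc,
               pvalue = fdr, fdr = fdr, caller = "x")
  }
  a <- mk(c(2.5, 2.1, 2.5, 0.1), c(1e-4, 5e-4, 1e-6, 1e-6))
  b <- mk(c(1.4, 2.3, -2.5, 0.2), c(1e-4, 9e-4, 1e-6, 1e-6))
  cons <- consensus_det(a, b)
  # t1: mean |fc| 1.95 < 2 -> out; t2: in, up; t3: sign conflict -> out
  expect_equal(cons$det$transcript_id, "t2")
  expect_equal(cons$det$direction, "up_HS")

  down <- consensus_det(mk(c(-3, -2.2), c(1e-5, 1e-5)),
                        mk(c(-2.5, -1.9), c(1e-5, 1e-5)))
  expect_equal(down$n_down, 2L)

  # self-consensus at trivial cut-offs: exactly the nonzero transcripts
  t_self <- mk(c(1.5, 0, -0.7), c(0.5, 0.2, 0.9))
  self <- consensus_det(t_self, t_self, fc_cut = 0, fdr_cut = 1)
  expect_setequal(self$det$transcript_id, c("t1", "t3"))

  # transcripts present in only one table are dropped and counted
  cons2 <- consensus_det(a[1:3, ], b)
  expect_equal(cons2$n_unmatched, 1L)
})

test_that("HSP panel matching is case-insensitive substring with argmax isoform", {
  ann <- new_annotation_catalog(data.frame(
    transcript_id = paste0("t", 1:7),
    annotation = c("heat shock protein 70 cognate 4", "HSP70 isoform X1",
                   "Hsp 70 paralog", "HSPA8 homolog",
                   "heat shock protein 90 alpha", "hsp90 co-chaperone",
                   "unrelated kinase")), "sp")
  set.seed(47)
  norm <- matrix(runif(7 * 4, 1, 10), nrow = 7,
                 dimnames = list(paste0("t", 1:7), paste0("s", 1:4)))
  norm[3, ] <- 100  # known-highest HSP70 isoform
  panel <- find_hsp_transcripts(ann, norm)
  expect_setequal(panel$HSP70$members$transcript_id,
                  c("t1", "t2", "t3"))  # HSPA8 does not match any term
  expect_equal(panel$HSP70$top_isoform, "t3")
  expect_setequal(panel$HSP90$members$transcript_id, c("t5", "t6"))
  expect_false(panel$HSP70$differential)

  empty <- new_annotation_catalog(data.frame(
    transcript_id = "t1", annotation = "unrelated"), "sp")
  expect_warning(find_hsp_transcripts(empty, norm[1, , drop = FALSE]),
                 "no transcripts matched")
})

test_that("response profiles reproduce the published fractions", {
  p1 <- classify_profile(53, 38726)
  expect_equal(round(p1$det_fraction, 2), 0.14)
  expect_equal(p1$profile, "weak")
  p2 <- classify_profile(698, 45701)
  expect_equal(round(p2$det_fraction, 2), 1.53)
  expect_equal(p2$profile, "medium")
  p3 <- classify_profile(10778, 84784)
  expect_equal(round(p3$det_fraction, 2), 12.71)
  expect_equal(p3$profile, "strong")
})

test_that("strategy calls combine profile, habitat and HSP evidence", {
  expect_equal(call_strategy("weak", "desert",
                             c(HSP70 = FALSE, HSP90 = FALSE), 2)$strategy,
               "constitutive")
  expect_equal(call_strategy("medium", "desert",
                             c(HSP70 = TRUE, HSP90 = FALSE), 6)$strategy,
               "reactive")
  expect_equal(call_strategy("strong", "temperate",
                             c(HSP70 = TRUE, HSP90 = TRUE), 2)$strategy,
               "temperate_like")
  expect_equal(call_strategy("weak", "desert",
                             c(HSP70 = TRUE, HSP90 = FALSE), 2)$strategy,
               "unclassified")
})
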