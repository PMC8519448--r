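make_pssm <- function(lo) {
  structure(list(motif_id = "T", name = "T", width = ncol(lo),
                 logodds = lo, bg = uniform_background()), class = "pssm")
}

test_that("build_pssm computes log2 odds", {
  u <- pwm("U", matrix(0.25, 4, 3))
  ps <- build_pssm(u)
  expect_true(all(ps$logodds == 0))

  m <- matrix(c(0.97, 0.0025, 0.0125, 0.015), 4, 1,
              dimnames = list(NUCS4, NULL))
  ps <- build_pssm(pwm("X", m))
  expect_equal(unname(ps$logodds["A", 1]), log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(unname(ps$logodds["C", 1]), log2(0.01), tolerance = 1e-12)

  cnt <- pwm("C", matrix(c(1, 0, 0, 0), 4, 1))
  expect_error(build_pssm(pwm_to_probabilities(cnt, pseudocount = 0)),
               "pseudocount")
  expect_error(build_pssm(cnt), "probability")
})

test_that("scale_pssm maps onto [0, 1000] as specified", {
  sp <- scale_pssm(make_pssm(matrix(c(2, 0, 0, 0), 4, 1)))
  expect_equal(sp$int_matrix[, 1], c(A = 1000L, C = 0L, G = 0L, T = 0L))
  expect_equal(sp$scale, 500)
  expect_equal(sp$offsets, 0)
  expect_equal(sp$max_total, 1000L)

  # per-column ranges 1 and 3 -> scale 250, column maxima 250 and 750
  sp2 <- scale_pssm(make_pssm(cbind(c(1, 0, 0, 0), c(3, 0, 0, 0))))
  expect_equal(sp2$scale, 250)
  expect_equal(apply(sp2$int_matrix, 2, max), c(250L, 750L))

  expect_error(scale_pssm(make_pssm(matrix(0, 4, 2))), "degenerate")
})

test_that("score_kmer scores consensus, anti-consensus and N windows", {
  set.seed(21)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    sp <- scale_pssm(build_pssm(pwm_to_probabilities(random_count_pwm(k))))
    cons <- paste(NUCS4[apply(sp$int_matrix, 2, which.max)], collapse = "")
    anti <- paste(NUCS4[apply(sp$int_matrix, 2, which.min)], collapse = "")
    expect_equal(score_kmer(sp, cons), sp$max_total)
    expect_equal(score_kmer(sp, anti), 0L)
    expect_equal(score_kmer(sp, tolower(cons)), sp$max_total)
  }
  sp <- scale_pssm(make_pssm(cbind(c(1, 0, 0, 0), c(3, 0, 0, 0))))
  expect_equal(score_kmer(sp, "AN"), unname(sp$int_matrix["A", 1]))
  expect_error(score_kmer(sp, "ACG"), "length")
  expect_error(score_kmer(sp, "AX"), "non-ACGTN")
})

test_that("unscale_score inverts scaling within the rounding bound", {
  set.seed(22)
  for (rep in 1:5) {
    k <- sample(2:9, 1)
    prob <- pwm_to_probabilities(random_count_pwm(k))
    ps <- build_pssm(prob)
    sp <- scale_pssm(ps)
    expect_equal(unscale_score(sp, 0L), sum(sp$offsets))
    tol <- k / (2 * sp$scale) + 1e-9
    seqs <- vapply(1:100, function(i)
      paste(sample(NUCS4, k, replace = TRUE), collapse = ""), "")
    direct <- vapply(seqs, function(s) {
      idx <- match(strsplit(s, "")[[1]], NUCS4)
      sum(ps$logodds[cbind(idx, seq_len(k))])
    }, 0)
    back <- unscale_score(sp, vgmotif:::score_kmers(sp, seqs))
    expect_true(all(abs(back - direct) <= tol))
  }
})

test_that("DP P-value table matches closed forms and exhaustive oracle", {
  sp1 <- scale_pssm(make_pssm(matrix(c(2, 0, 0, 0), 4, 1)))
  t1 <- build_pvalue_table(sp1)
  expect_equal(score_pvalue(t1, 1000L), 0.25)
  expect_equal(score_pvalue(t1, 0L), 1)

  # two columns with unique maximizers: P(max) = 1/16
  sp2 <- scale_pssm(make_pssm(cbind(c(1, 0, 0, 0), c(3, 0, 0, 0))))
  t2 <- build_pvalue_table(sp2)
  expect_equal(score_pvalue(t2, sp2$max_total), 1 / 16)

  # any 3-column matrix vs brute force over all 64 trinucleotides
  set.seed(23)
  sp3 <- scale_pssm(build_pssm(pwm_to_probabilities(random_count_pwm(3))))
  t3 <- build_pvalue_table(sp3)
  all_scores <- 0:sp3$max_total
  expect_equal(score_pvalue(t3, all_scores),
               enum_survival(sp3, uniform_background(), all_scores),
               tolerance = 1e-12)

  expect_equal(sum(t3$pmf), 1, tolerance = 1e-12)
  expect_true(all(diff(t3$survival) <= 1e-15))
  expect_equal(t3$survival[1], 1)
})

test_that("benjamini_hochberg matches the step-up formula and p.adjust", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(numeric(0)), "empty")

  set.seed(24)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    q <- benjamini_hochberg(p)
    expect_equal(q, stats::p.adjust(p, method = "BH"))
    expect_true(all(q >= p & q <= 1))
  }
})

test_that("reverse_complement_pssm is an involution that mirrors scoring", {
  set.seed(25)
  sp <- scale_pssm(build_pssm(pwm_to_probabilities(random_count_pwm(6))))
  rc <- reverse_complement_pssm(sp)
  expect_equal(reverse_complement_pssm(rc)$int_matrix, sp$int_matrix)
  expect_equal(rc$strand, "-")
  expect_equal(rc$max_total, sp$max_total)
  seqs <- vapply(1:100, function(i)
    paste(sample(NUCS4, 6, replace = TRUE), collapse = ""), "")
  expect_equal(vgmotif:::score_kmers(rc, seqs),
               vgmotif:::score_kmers(sp, vgmotif:::revcomp(seqs)))

  # palindromic matrix (column i = complement of column k+1-i) is fixed
  pal <- cbind(c(3, 1, 2, 0), c(0, 2, 1, 3))
  spp <- scale_pssm(make_pssm(pal))
  expect_equal(reverse_complement_pssm(spp)$int_matrix, spp$int_matrix)
})
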