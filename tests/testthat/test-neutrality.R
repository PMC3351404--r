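# Tajima's D, Fu's Fs, coalescent p-values, mismatch/raggedness, MK counts.

test_that("Tajima's D matches the hand-evaluated example and handles edge cases", {
  aln <- alignment(c("a", "b", "c", "d"), c("AAA", "AAT", "ATT", "TTT"))
  td <- tajimas_d(aln)
  expect_equal(td$S, 3L)
  expect_equal(td$kbar, 10 / 6, tolerance = 1e-12)
  expect_equal(td$D, 0.1677, tolerance = 1e-3)
  # monomorphic -> not calculable
  expect_true(is.na(tajimas_d(alignment(c("a", "b"),
                                        c("AAAA", "AAAA")))$D))
})

test_that("Tajima's D equals an independent formula transcription on random data", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    aln <- random_alignment(n, sample(10:40, 1),
                            bases = c("A", "A", "A", "C", "G", "T"))
    got <- tajimas_d(aln)$D
    exp <- oracle_tajimas_d(aln)
    if (is.na(exp)) expect_true(is.na(got))
    else expect_equal(got, exp, tolerance = 1e-9)
  }
})

test_that("Ewens sampling distribution: closed forms and normalization", {
  p <- ewens_pmf(2, 1)
  expect_equal(p, c(0.5, 0.5), tolerance = 1e-12)
  # theta -> 0: all mass on a single allele
  expect_gt(ewens_pmf(10, 1e-8)[1L], 0.999)
  for (n in c(2, 10, 50, 100))
    for (theta in c(0.1, 1, 10))
      expect_equal(sum(ewens_pmf(n, theta)), 1, tolerance = 1e-9)
  expect_error(ewens_pmf(5, 0), "domain")
  expect_error(ewens_pmf(5, -1), "domain")
})

test_that("Fu's Fs: zero at the two-sequence closed form, negative for star-like data", {
  expect_equal(fus_fs(alignment(c("a", "b"), c("AAAT", "AAAA"))), 0,
               tolerance = 1e-12)
  expect_true(is.na(fus_fs(alignment(c("a", "b"), c("AAAA", "AAAA")))))
  # many singleton haplotypes but low pairwise diversity
  n <- 12
  seqs <- vapply(seq_len(n), function(i) {
    s <- rep("A", 20); if (i > 1) s[i] <- "T"; paste(s, collapse = "")
  }, "")
  expect_lt(fus_fs(alignment(paste0("s", 1:n), seqs)), 0)
})

test_that("coalescent null p-values are seeded, sensible and flag expansions", {
  scn <- make_scenario("single-panmictic", seed = 5)
  g <- simulate_genealogy(scn, seed = 6)
  aln <- apply_mutations(g, scn$mutation, seed = 7)
  p1 <- coalescent_null_pvalue(aln, "D", reps = 200, seed = 42)
  p2 <- coalescent_null_pvalue(aln, "D", reps = 200, seed = 42)
  expect_identical(p1$p, p2$p)
  expect_true(p1$p > 0 && p1$p <= 1)
  pf <- coalescent_null_pvalue(aln, "Fs", reps = 150, seed = 9)
  expect_true(pf$p > 0 && pf$p <= 1)
  expect_error(coalescent_null_pvalue(aln, "D", reps = 50), "reps")
  mono <- alignment(c("a", "b", "c", "d"), rep("ACGT", 4))
  expect_error(coalescent_null_pvalue(mono, "D", reps = 100),
               "not calculable")
})

test_that("expansion scenarios drive D and Fs negative with high power", {
  scn <- make_scenario("refugial-expansion", "strong", seed = 1)
  ds <- fss <- numeric(8); flags <- logical(8)
  for (i in 1:8) {
    g <- simulate_genealogy(scn, seed = 500 + i)
    aln <- apply_mutations(g, scn$mutation, seed = 600 + i)
    ds[i] <- tajimas_d(aln)$D
    fss[i] <- fus_fs(aln)
    flags[i] <- coalescent_null_pvalue(aln, "D", reps = 150,
                                       seed = 700 + i)$significant
  }
  expect_lt(mean(ds), 0)
  expect_lt(mean(fss), 0)
  expect_gte(mean(flags), 0.8)
})

test_that("observed mismatch distribution matches pair counts", {
  expect_equal(unname(mismatch_observed(
    alignment(c("a", "b"), c("ACGT", "ACGT")))), 1)
  x <- mismatch_observed(alignment(c("a", "b", "c", "d"),
                                   c("AAA", "AAT", "ATT", "TTT")))
  expect_equal(unname(x), c(0, 3 / 6, 2 / 6, 1 / 6))
  set.seed(3)
  r <- random_alignment(8, 25)
  expect_equal(sum(mismatch_observed(r)), 1, tolerance = 1e-12)
})

test_that("expected mismatch: geometric constant model and expansion limits", {
  f <- mismatch_expected("constant", d = 5, theta = 1)
  expect_equal(unname(f[1:2]), c(0.5, 0.25))
  # geometric normalization over the full support
  expect_equal(sum(mismatch_expected("constant", d = 400, theta = 2)), 1,
               tolerance = 1e-9)
  # tau = 0 expansion reduces to the constant model at theta0
  expect_equal(mismatch_expected("expansion", d = 10, tau = 0, theta0 = 1.7),
               mismatch_expected("constant", d = 10, theta = 1.7),
               tolerance = 1e-12)
  expect_error(mismatch_expected("constant", d = 3, theta = -1), "domain")
  expect_error(mismatch_expected("expansion", d = 3, tau = -1, theta0 = 1),
               "domain")
})

test_that("raggedness index: worked examples and smoothness ordering", {
  expect_equal(raggedness_index(c(0.25, 0.5, 0.25)), 0.1875)
  expect_equal(raggedness_index(1), 1)
  expect_error(raggedness_index(numeric(0)), "domain")
  smooth <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  jagged <- c(0.4, 0.1, 0.2, 0.1, 0.2)  # same multiset, permuted
  expect_lt(raggedness_index(smooth), raggedness_index(jagged))
})

test_that("raggedness p-value is reproducible and accepts expansion data", {
  scn <- make_scenario("refugial-expansion", "strong", seed = 2)
  ps <- numeric(5)
  for (i in 1:5) {
    g <- simulate_genealogy(scn, seed = 800 + i)
    aln <- apply_mutations(g, scn$mutation, seed = 900 + i)
    ps[i] <- raggedness_pvalue(aln, reps = 100, seed = 30 + i)$p
  }
  # data generated under expansion should usually fit the expansion model
  expect_gte(sum(ps > 0.05), 3)
  g <- simulate_genealogy(scn, seed = 801)
  aln <- apply_mutations(g, scn$mutation, seed = 901)
  expect_identical(raggedness_pvalue(aln, reps = 100, seed = 77)$p,
                   raggedness_pvalue(aln, reps = 100, seed = 77)$p)
})

test_that("McDonald-Kreitman classification on hand-built codon data", {
  # one codon: species A polymorphic Phe (TTT/TTC), species B fixed Leu (TTA)
  a <- alignment(c("a1", "a2"), c("TTT", "TTC"))
  b <- alignment("b1", "TTA")
  mk <- mk_counts(a, b, frame = 0)
  expect_equal(mk$Ps, 1)
  expect_equal(mk$Pn, 0)
  expect_equal(mk$Ms, 0)
  expect_equal(mk$Mn, 1)
  expect_false(is.na(mk$Mn))
  # identical alignments -> all zeros, positive selection not indicated
  same <- alignment(c("x1", "x2"), c("ATGTTTAGA", "ATGTTTAGA"))
  mk0 <- mk_counts(same, alignment("y1", "ATGTTTAGA"), frame = 0)
  expect_equal(c(mk0$Ps, mk0$Pn, mk0$Ms, mk0$Mn), c(0, 0, 0, 0))
  expect_false(mk0$positive_selection_indicated)
  # synonymous fixed difference
  mk2 <- mk_counts(alignment("a", "ATGTTT"), alignment("b", "ATGTTC"),
                   frame = 0)
  expect_equal(c(mk2$Ms, mk2$Mn), c(1, 0))
  expect_error(mk_counts(a, alignment("z", "TTAA")), "alignment error")
})

test_that("MK frame auto-detection avoids internal stop codons", {
  # clean ORF in frame 0; the +1 shift reads a TAA stop
  s <- paste0("ATG", "CTA", "AAG", "TTC")
  a <- alignment(c("a1", "a2"), c(s, s))
  b <- alignment("b1", s)
  expect_equal(mk_counts(a, b)$frame, 0L)
})
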