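# Tree-sample handling, Fitch root states, RPS, Bayes-factor utilities.

test_that("tree samples: burn-in, seeded subsampling, rooting checks", {
  set.seed(5)
  trees <- c(lapply(1:10, function(i) ape::rcoal(6)))
  class(trees) <- "multiPhylo"
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(trees, f)
  got <- read_tree_sample(f, burnin_fraction = 0.1, subsample = 5, seed = 3)
  expect_length(got, 5L)
  got2 <- read_tree_sample(f, burnin_fraction = 0.1, subsample = 5, seed = 3)
  expect_identical(ape::write.tree(got), ape::write.tree(got2))
  # subsample == available: all retained, order preserved
  all9 <- read_tree_sample(f, burnin_fraction = 0.1, subsample = 9)
  expect_identical(ape::write.tree(all9),
                   ape::write.tree(trees[2:10]))
  expect_error(read_tree_sample(f, burnin_fraction = 0.1, subsample = 10),
               "count error")
  # unrooted trees rejected
  unr <- ape::unroot(ape::rtree(5))
  f2 <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(unr, f2)
  expect_error(read_tree_sample(f2), "rooting error")
  # NEXUS dialect readable
  f3 <- withr::local_tempfile(fileext = ".nex")
  ape::write.nexus(trees, file = f3)
  expect_length(read_tree_sample(f3), 10L)
})

test_that("locality pooling relabels codes and validates coverage", {
  tab <- read_locality_table(system.file("extdata", "locality_table.tsv",
                                         package = "refugeo"))
  codes <- sort(unique(unlist(lapply(tab$species, function(s) s$code))))
  ident <- stats::setNames(codes, codes)
  expect_identical(unname(pool_localities(ident, tab)), codes)
  pooled <- ident
  pooled[c("GA", "TO")] <- "GA+TO"
  out <- pool_localities(pooled, tab)
  expect_equal(unname(out["GA"]), "GA+TO")
  expect_equal(unname(out["TO"]), "GA+TO")
  expect_error(pool_localities(ident[-1L], tab), "mapping error")
})

test_that("Fitch root states: cherries and set-valued tips", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  fr <- fitch_root_states(cherry, list(A = "X", B = "Y"))
  expect_setequal(fr$states, c("X", "Y"))
  expect_equal(fr$w, 0.5)
  same <- fitch_root_states(cherry, list(A = "X", B = "X"))
  expect_equal(same$states, "X")
  expect_equal(same$w, 1)
  expect_error(fitch_root_states(cherry, list(A = character(0), B = "X")),
               "domain error")
  expect_error(fitch_root_states(ape::unroot(ape::rtree(4)),
                                 stats::setNames(as.list(letters[1:4]),
                                                 paste0("t", 1:4))),
               "rooting error")
})

test_that("Fitch root sets equal exhaustive minimal-labeling enumeration", {
  set.seed(13)
  states <- c("P", "Q", "R", "S")
  for (n in 3:5) {
    trees <- enumerate_rooted_trees(n)
    pick <- if (length(trees) > 40) sample(trees, 40) else trees
    for (tr in pick) {
      sets <- lapply(seq_len(n), function(i)
        sample(states, sample(c(1, 1, 1, 2), 1)))
      ph <- tree_to_phylo(tr)
      got <- sort(fitch_root_states(
        ph, stats::setNames(sets, ph$tip.label))$states)
      expect_identical(got, oracle_fitch_roots(tr, sets, states))
    }
  }
})

test_that("RPS aggregation: weights, conservation, invariances", {
  # 100 trees rooting to {X}, 150 rooting to {X,Y}
  t_x <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  states_x <- list(A = "X", B = "X", C = "X", D = "X")     # root {X}
  states_xy <- list(A = "X", B = "X", C = "Y", D = "Y")    # root {X,Y}
  trees <- c(rep(list(t_x), 100), rep(list(t_x), 150))
  class(trees) <- "multiPhylo"
  # emulate the mixture by two separate samples and combine the scores
  s1 <- tree_sample(structure(rep(list(t_x), 100), class = "multiPhylo"),
                    states_x)
  s2 <- tree_sample(structure(rep(list(t_x), 150), class = "multiPhylo"),
                    states_xy)
  r1 <- rps_scores(s1); r2 <- rps_scores(s2)
  combined <- (100 * stats::setNames(r1$rps, r1$character)[c("X")] +
                 150 * stats::setNames(r2$rps, r2$character)[c("X")]) / 250
  expect_equal(unname(combined), 70)
  expect_equal(sum(r1$rps), 100, tolerance = 1e-9)
  expect_equal(sum(r2$rps), 100, tolerance = 1e-9)
  expect_equal(r2$rps[r2$character == "Y"], 50)
  # all trees rooting to one state
  expect_equal(r1$rps[r1$character == "X"], 100)
  # invariance under tree reordering
  set.seed(2)
  trs <- structure(lapply(1:6, function(i) ape::rcoal(5)),
                   class = "multiPhylo")
  sts <- stats::setNames(as.list(sample(c("A", "B"), 5, TRUE)),
                         trs[[1L]]$tip.label)
  a <- rps_scores(tree_sample(trs, sts))
  b <- rps_scores(tree_sample(trs[c(3, 1, 2, 6, 5, 4)], sts))
  expect_equal(a, b)
  # invariance under character relabeling
  sts2 <- lapply(sts, function(s) paste0("Z", s))
  c2 <- rps_scores(tree_sample(trs, sts2))
  expect_equal(c2$rps[match(paste0("Z", a$character), c2$character)], a$rps)
})

test_that("harmonic-mean marginal likelihood and Bayes-factor grading", {
  expect_equal(harmonic_mean_log_ml(rep(-3.7, 10)), -3.7, tolerance = 1e-12)
  expect_equal(harmonic_mean_log_ml(c(log(1), log(3))), log(1.5),
               tolerance = 1e-12)
  tr <- rnorm(50, -100, 2)
  expect_equal(harmonic_mean_log_ml(tr), harmonic_mean_log_ml(rev(tr)),
               tolerance = 1e-12)
  expect_error(harmonic_mean_log_ml(-1), "domain")
  # qualitative calls on the decimal-log scale
  expect_equal(bayes_factor(2.099 * log(10), 0)$call, "decisive")
  expect_equal(bayes_factor(0.7 * log(10), 0)$call, "substantial")
  expect_equal(bayes_factor(1.5 * log(10), 0)$call, "strong")
  bf0 <- bayes_factor(-5, -5)
  expect_equal(bf0$log_bf, 0)
  expect_equal(bf0$call, "none")
  expect_equal(bf0$favored, "neither")
  expect_equal(bayes_factor(0, 0.7 * log(10))$favored, "B")
})
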