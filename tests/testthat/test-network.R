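# Statistical-parsimony networks, loop resolution, nesting and MOTUs.

hap_index <- function(seqs, counts = rep(1L, length(seqs)),
                      locs = rep("L1", length(seqs))) {
  ids <- unlist(lapply(seq_along(seqs), function(i)
    paste0("h", i, "_", seq_len(counts[i]))))
  aln <- alignment(ids, rep(seqs, counts))
  collapse_haplotypes(aln, stats::setNames(
    rep(locs, counts), ids))
}

test_that("connection limit: bounds, monotonicity and oracle agreement", {
  expect_error(parsimony_connection_limit(590, 1.2), "domain")
  expect_gte(parsimony_connection_limit(10, 0.95), 1)  # 1 step always allowed
  for (L in c(100, 350, 590, 658)) {
    expect_equal(parsimony_connection_limit(L, 0.95),
                 oracle_connection_limit(L, 0.95))
    expect_lte(parsimony_connection_limit(L, 0.99),
               parsimony_connection_limit(L, 0.95))
  }
})

test_that("network construction: chains, disconnection, intermediates", {
  # A-B=1, B-C=1, A-C=2: chain, no shortcut edge
  idx <- hap_index(c("AAAA", "AAAT", "AATT"))
  net <- build_parsimony_network(idx, max_steps = 8)
  expect_equal(nrow(net$edges_h), 2L)
  expect_false(any(net$edges_h$from == "H1" & net$edges_h$to == "H3"))
  # beyond the limit: two components
  idx2 <- hap_index(c("AAAAAA", "TTTTAA"))
  net2 <- build_parsimony_network(idx2, max_steps = 3)
  expect_equal(nrow(net2$edges_h), 0L)
  g2 <- refugeo:::net_igraph(net2, "haplotype")
  expect_equal(igraph::count_components(g2), 2)
  # multi-step edge expands into single-step intermediate chain
  net3 <- build_parsimony_network(idx2, max_steps = 8)
  expect_equal(net3$edges_h$steps, 4L)
  expect_equal(nrow(net3$edges), 4L)
  expect_equal(length(refugeo:::network_nodes(net3)), 5L)
})

test_that("network + loop resolution agrees with the brute-force minimal network", {
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    repeat {
      seqs <- apply(matrix(sample(c("A", "C", "G", "T"), k * 12, TRUE),
                           k, 12), 1, paste, collapse = "")
      if (!anyDuplicated(seqs)) break
    }
    idx <- hap_index(seqs, counts = sample(1:5, k, TRUE))
    dm <- pairwise_differences(haplotype_alignment(idx))$diff
    orc <- oracle_msn_edges(dm)
    net <- build_parsimony_network(idx, max_steps = 100)
    lab <- idx$haplotypes$label
    got <- sort(paste(match(net$edges_h$from, lab),
                      match(net$edges_h$to, lab), sep = "-"))
    expect_equal(got, orc$edges)
    # resolved network: a spanning tree of minimum total weight inside the
    # union of all minimum spanning trees
    res <- resolve_loops(net)
    expect_equal(nrow(res$edges_h), k - 1L)
    keys <- paste(match(res$edges_h$from, lab),
                  match(res$edges_h$to, lab), sep = "-")
    expect_true(all(keys %in% orc$edges))
    expect_equal(sum(res$edges_h$steps), orc$weight)
    g <- refugeo:::net_igraph(res, "haplotype")
    expect_equal(igraph::count_components(g), 1)
  }
})

test_that("loop resolution prefers high-frequency connections and is idempotent", {
  # square AA-AT-TT-TA with one dominant node
  idx <- hap_index(c("AA", "AT", "TT", "TA"), counts = c(10L, 1L, 1L, 1L))
  net <- build_parsimony_network(idx, max_steps = 8)
  expect_equal(nrow(net$edges_h), 4L)  # the full 4-cycle is retained
  res <- resolve_loops(net)
  expect_equal(nrow(res$edges_h), 3L)
  # removed edge joins two frequency-1 haplotypes, never the dominant one
  rem <- res$removed
  expect_equal(nrow(rem), 1L)
  expect_false("H1" %in% c(rem$from, rem$to))
  expect_equal(rem$criterion, "tie")  # frequencies tied between candidates
  # idempotence on acyclic input
  res2 <- resolve_loops(res)
  expect_identical(res2$edges_h, res$edges_h)
  tree_net <- resolve_loops(build_parsimony_network(
    hap_index(c("AAAA", "AAAT", "AATT")), max_steps = 8))
  expect_equal(nrow(tree_net$removed), 0L)
})

test_that("nesting follows the tip-inward rule on star and chain topologies", {
  # star: centre + two tips -> one 1-step clade holding all three
  star <- hap_index(c("AAA", "AAT", "TAA"))
  dstar <- build_nesting_design(resolve_loops(
    build_parsimony_network(star, 8)), 1)
  expect_equal(length(dstar$levels[[1L]]), 1L)
  expect_setequal(dstar$levels[[1L]][[1L]], c("H1", "H2", "H3"))
  # 5-chain: {A,B}, {C}, {D,E}, then all merged at level 2
  chain <- hap_index(c("AAAAA", "AAAAT", "AAATT", "AATTT", "ATTTT"))
  d <- build_nesting_design(resolve_loops(
    build_parsimony_network(chain, 8)), 2)
  l1 <- lapply(d$levels[[1L]], sort)
  expect_equal(length(l1), 3L)
  expect_true(list(c("H1", "H2")) %in% l1 || any(sapply(l1, identical,
                                                        c("H1", "H2"))))
  expect_true(any(sapply(l1, identical, "H3")))
  expect_true(any(sapply(l1, identical, c("H4", "H5"))))
  expect_equal(length(d$levels[[2L]]), 1L)
  # single haplotype: one clade at every level
  single <- hap_index("ACGT")
  ds <- build_nesting_design(resolve_loops(
    build_parsimony_network(single, 8)), 3)
  expect_true(all(vapply(ds$levels, length, 0L) == 1L))
})

test_that("nesting levels form a proper hierarchy on simulated data", {
  scn <- make_scenario("refugial-expansion", "strong", seed = 31)
  g <- simulate_genealogy(scn, seed = 32)
  aln <- apply_mutations(g, scn$mutation, seed = 33)
  idx <- collapse_haplotypes(aln, attr(g, "tip_deme"))
  net <- resolve_loops(build_parsimony_network(idx, 8))
  d <- build_nesting_design(net, 3)
  nodes <- refugeo:::network_nodes(net)
  for (lev in seq_along(d$levels)) {
    members <- unlist(d$levels[[lev]])
    expect_setequal(members, nodes)          # partition covers every node
    expect_equal(anyDuplicated(members), 0L) # exactly once
    if (lev > 1L) {
      # every level-k clade is a union of level-(k-1) clades
      for (cl in d$levels[[lev]]) {
        parts <- Filter(function(p) any(p %in% cl), d$levels[[lev - 1L]])
        expect_setequal(unlist(parts), cl)
      }
    }
  }
})

test_that("MOTU assignment orders by frequency and separates components", {
  chain <- hap_index(c("AAAAA", "AAAAT", "AAATT", "AATTT", "ATTTT"),
                     counts = c(1L, 1L, 1L, 5L, 2L))
  d <- build_nesting_design(resolve_loops(
    build_parsimony_network(chain, 8)), 2)
  m1 <- assign_motus(d, 1)
  expect_equal(length(unique(m1)), 3L)
  # most frequent clade ({H4,H5}, total 7) gets MOTU1
  expect_equal(unname(m1["H4"]), "MOTU1")
  expect_equal(unname(assign_motus(d, 2)["H1"]), "MOTU1")
  expect_error(assign_motus(d, 5), "domain")
  # disconnected components stay distinct MOTUs at every level
  idx2 <- hap_index(c("AAAAAA", "AAAAAT", "TTTTTT"))
  d2 <- build_nesting_design(resolve_loops(
    build_parsimony_network(idx2, 2)), 3)
  expect_equal(length(unique(assign_motus(d2, 3))), 2L)
})

test_that("network export writes readable GraphML", {
  idx <- hap_index(c("AAAA", "AAAT", "AATT"))
  net <- resolve_loops(build_parsimony_network(idx, 8))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
})
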