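# Structured-coalescent simulation of multi-deme mtDNA samples with a
# known refugial source, for calibration and recovery experiments.
#
# Timescale: haploid-copy generations (mtDNA-like), so a single deme of
# effective size N has E[pairwise TMRCA] = N generations and theta = 2*N*mu.

#' Build a simulation scenario
#'
#' Presets mirror the competing demographic structures the analysis is
#' meant to distinguish:
#' \describe{
#'   \item{refugial-expansion}{one large source deme (the refugium) founds
#'     several young daughter demes at a recent time; lineages are
#'     star-like, Tajima's D and Fu's Fs are expected negative, and the
#'     recorded truth is the source deme.}
#'   \item{island-constant}{symmetric migration among equal constant-size
#'     demes; no expansion signal.}
#'   \item{single-panmictic}{one constant-size deme; the null for type-I
#'     error calibration.}
#' }
#' The \code{strong} variant of the expansion preset uses a very recent
#' expansion from a well-sampled source (clear signal); \code{weak} uses an
#' older expansion and some post-expansion migration.
#'
#' @param preset scenario family.
#' @param strength \code{"strong"} or \code{"weak"} (expansion preset).
#' @param seed integer seed stored in the scenario and used by
#'   \code{\link{simulate_genealogy}} unless overridden.
#' @return object of class \code{"sim_scenario"}; see Details.
#' @details A scenario is a list with \code{demes} (data.frame \code{name},
#'   \code{size}, \code{lat}, \code{lon}), \code{migration} (per-generation
#'   backward rates), \code{events} (list of \code{time}/\code{type}/
#'   \code{params}), \code{mutation} (\code{model}, \code{rate} per site per
#'   generation, \code{L}), \code{samples} (named integer vector), and
#'   \code{truth} (source deme name or \code{NA}).
#' @export
make_scenario <- function(preset = c("refugial-expansion", "island-constant",
                                     "single-panmictic"),
                          strength = c("strong", "weak"), seed = 1L) {
  preset <- match.arg(preset); strength <- match.arg(strength)
  L <- 590L
  if (preset == "refugial-expansion") {
    # a small glacial refugium (RFG) that expanded in place and founded the
    # daughter demes; sizes/times are coalescent-rescaled (mutation rate
    # raised to compensate), so only the ratios matter
    strong <- strength == "strong"
    demes <- data.frame(
      name = c("RFG", "NOR", "WST", "EST", "CEN"),
      size = c(5000, rep(if (strong) 1500 else 800, 4)),
      lat = c(46.5, 54.0, 48.5, 47.5, 50.1),
      lon = c(10.5, 10.0, 2.5, 19.0, 8.7),
      stringsAsFactors = FALSE)
    t_exp <- if (strong) 400 else 1500
    n_anc <- if (strong) 200 else 1000
    mig <- matrix(0, 5, 5, dimnames = list(demes$name, demes$name))
    if (!strong) {
      mig[] <- 1e-4; diag(mig) <- 0
    }
    scn <- list(
      demes = demes, migration = mig,
      events = list(list(time = t_exp, type = "expansion-from-source",
                         params = list(source = "RFG",
                                       daughters = demes$name[-1L])),
                    list(time = t_exp, type = "size-change",
                         params = list(deme = "RFG", size = n_anc))),
      mutation = list(model = "infinite-sites", rate = 2.5e-6, L = L),
      samples = c(RFG = 16L, NOR = 7L, WST = 7L, EST = 7L, CEN = 7L),
      seed = seed, truth = "RFG", preset = preset, strength = strength)
  } else if (preset == "island-constant") {
    demes <- data.frame(name = c("D1", "D2", "D3", "D4"),
                        size = rep(2500, 4),
                        lat = c(46, 48, 50, 52), lon = c(8, 11, 14, 17),
                        stringsAsFactors = FALSE)
    mig <- matrix(1e-4, 4, 4, dimnames = list(demes$name, demes$name))
    diag(mig) <- 0
    scn <- list(demes = demes, migration = mig, events = list(),
                mutation = list(model = "infinite-sites", rate = 2.5e-6, L = L),
                samples = c(D1 = 8L, D2 = 8L, D3 = 8L, D4 = 8L),
                seed = seed, truth = NA_character_, preset = preset,
                strength = strength)
  } else {
    demes <- data.frame(name = "POP", size = 5000, lat = 48, lon = 10,
                        stringsAsFactors = FALSE)
    scn <- list(demes = demes,
                migration = matrix(0, 1, 1, dimnames = list("POP", "POP")),
                events = list(),
                mutation = list(model = "infinite-sites", rate = 2.5e-6, L = L),
                samples = c(POP = 30L), seed = seed, truth = NA_character_,
                preset = preset, strength = strength)
  }
  structure(scn, class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Simulation scenario [", x$preset, "/", x$strength, "]: ",
      nrow(x$demes), " deme(s), n = ", sum(x$samples),
      ", L = ", x$mutation$L, "\n", sep = "")
  invisible(x)
}

#' Simulate a structured-coalescent genealogy
#'
#' Backward-in-time simulation with exponential waiting times for
#' within-deme coalescence (rate \eqn{k_d(k_d-1)/2 / N_d} per generation)
#' and migration (per-lineage backward rates from the migration matrix).
#' Scheduled events are applied at their times: an
#' \code{expansion-from-source} event moves all lineages of the daughter
#' demes into the source and shuts their migration off (looking further
#' back, the daughters did not exist); a \code{size-change} event resets a
#' deme size. Reproducible under the scenario seed.
#'
#' @param scn a \code{\link{make_scenario}} result (or equivalent list).
#' @param seed seed override. When omitted, the scenario's own seed is
#'   used; pass \code{NULL} explicitly to draw from the current RNG state
#'   (replicate studies).
#' @param time_cap guard multiplier: simulation aborts if the time exceeds
#'   \code{time_cap * max(N_d)} generations without full coalescence, as
#'   happens for disconnected zero-migration demes.
#' @return a rooted \code{phylo} with branch lengths in generations, tip
#'   labels \code{"<deme>_<i>"} and attribute \code{tip_deme} (named
#'   character vector).
#' @export
simulate_genealogy <- function(scn, seed, time_cap = 200) {
  if (missing(seed)) seed <- scn$seed
  if (!is.null(seed)) set.seed(seed)
  demes <- scn$demes$name
  sizes <- stats::setNames(scn$demes$size, demes)
  mig <- scn$migration
  samples <- scn$samples[scn$samples > 0L]
  n <- sum(samples)
  if (n < 2L) stop("need a total sample of at least 2", call. = FALSE)
  tip_deme <- rep(names(samples), samples)
  tip_label <- paste0(tip_deme, "_",
                      unlist(lapply(samples, seq_len), use.names = FALSE))
  # active lineages: node id, deme; node times
  node_id <- seq_len(n)
  deme_of <- tip_deme
  node_time <- numeric(2L * n - 1L)  # tips at 0, internals filled at merges
  merges <- matrix(0L, n - 1L, 2L)   # children of the k-th internal node
  merge_time <- numeric(n - 1L)
  nm <- 0L
  t_now <- 0
  events <- scn$events[order(vapply(scn$events, `[[`, 0, "time"))]
  ev_i <- 1L
  max_t <- time_cap * max(sizes)
  while (length(node_id) > 1L) {
    k_by_deme <- table(factor(deme_of, levels = demes))
    coal_rate <- as.numeric(k_by_deme) * (as.numeric(k_by_deme) - 1) / 2 /
      sizes[demes]
    mig_rate_by_lineage <- rowSums(mig)[deme_of]
    tot <- sum(coal_rate) + sum(mig_rate_by_lineage)
    t_event <- if (ev_i <= length(events)) events[[ev_i]]$time else Inf
    dt <- if (tot > 0) stats::rexp(1L, tot) else Inf
    if (is.finite(t_event) && t_now + dt >= t_event) {
      t_now <- t_event
      ev <- events[[ev_i]]; ev_i <- ev_i + 1L
      if (ev$type == "expansion-from-source") {
        src <- ev$params$source
        dts <- ev$params$daughters
        deme_of[deme_of %in% dts] <- src
        mig[dts, ] <- 0; mig[, dts] <- 0
      } else if (ev$type == "size-change") {
        sizes[ev$params$deme] <- ev$params$size
      } else stop("unknown event type: ", ev$type, call. = FALSE)
      next
    }
    if (!is.finite(dt))
      stop("non-coalescence guard: no coalescence or migration possible; ",
           "disconnected demes with zero migration?", call. = FALSE)
    t_now <- t_now + dt
    if (t_now > max_t)
      stop("non-coalescence guard: time cap exceeded before full ",
           "coalescence", call. = FALSE)
    if (stats::runif(1L) < sum(coal_rate) / tot) {
      d <- sample(demes, 1L, prob = coal_rate)
      idx <- which(deme_of == d)
      pair <- if (length(idx) == 2L) idx else sample(idx, 2L)
      nm <- nm + 1L
      merges[nm, ] <- node_id[pair]
      merge_time[nm] <- t_now
      new_id <- n + nm
      node_time[new_id] <- t_now
      node_id <- c(node_id[-pair], new_id)
      deme_of <- c(deme_of[-pair], d)
    } else {
      li <- sample.int(length(node_id), 1L,
                       prob = mig_rate_by_lineage)
      deme_of[li] <- sample(demes, 1L, prob = mig[deme_of[li], ])
    }
  }
  # ape numbering: tips 1..n, root n+1; internal ids by reverse merge order
  ape_id <- c(seq_len(n), 2L * n - seq_len(n - 1L))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  r <- 0L
  for (m in seq_len(n - 1L)) {
    for (child in merges[m, ]) {
      r <- r + 1L
      edge[r, ] <- c(ape_id[n + m], ape_id[child])
      elen[r] <- merge_time[m] - node_time[child]
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = tip_label, Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "tip_deme") <- stats::setNames(tip_deme, tip_label)
  tr
}

#' Drop mutations on a genealogy and return the tip alignment
#'
#' Mutations are Poisson on branches at \code{rate * L} per generation.
#' Under the infinite-sites model every mutation hits a fresh site (an
#' error is raised if more mutations than sites arise); under the
#' finite-sites Jukes-Cantor model (\code{"JC-finite"}) sites can be hit
#' repeatedly, with each hit replacing the base by one of the other three.
#'
#' @param tree a rooted \code{phylo} with branch lengths in generations.
#' @param mutation list with \code{model} (\code{"infinite-sites"} or
#'   \code{"JC-finite"}), \code{rate} (per site per generation), \code{L}.
#' @param seed optional integer seed.
#' @return an \code{\link{alignment}} of the tip sequences (ids = tip
#'   labels).
#' @export
apply_mutations <- function(tree, mutation, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- mutation$L
  stopifnot(L > 0, mutation$rate >= 0)
  n <- ape::Ntip(tree)
  post <- ape::reorder.phylo(tree, "postorder")
  # tips below every edge (postorder accumulation)
  below <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) below[[i]] <- i
  for (r in seq_len(nrow(post$edge))) {
    p <- post$edge[r, 1L]; ch <- post$edge[r, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  if (mutation$model == "infinite-sites") {
    seqs <- matrix(sample(.BASES, L, replace = TRUE), nrow = n, ncol = L,
                   byrow = TRUE)
    M <- stats::rpois(1L, mutation$rate * L * sum(tree$edge.length))
    if (M > L)
      stop("site-exhaustion error: ", M, " mutations exceed ", L, " sites ",
           "under the infinite-sites model", call. = FALSE)
    if (M > 0L) {
      sites <- sample.int(L, M)
      branches <- sample.int(nrow(tree$edge), M, replace = TRUE,
                             prob = tree$edge.length)
      for (m in seq_len(M)) {
        tips <- below[[tree$edge[branches[m], 2L]]]
        tips <- tips[tips <= n]
        anc <- seqs[if (length(tips) < n) setdiff(seq_len(n), tips)[1L] else 1L,
                    sites[m]]
        seqs[tips, sites[m]] <- sample(setdiff(.BASES, anc), 1L)
      }
    }
  } else if (mutation$model == "JC-finite") {
    node_seq <- vector("list", n + tree$Nnode)
    root <- n + 1L
    node_seq[[root]] <- sample(.BASES, L, replace = TRUE)
    clade <- ape::reorder.phylo(tree, "cladewise")
    for (r in seq_len(nrow(clade$edge))) {
      p <- clade$edge[r, 1L]; ch <- clade$edge[r, 2L]
      s <- node_seq[[p]]
      nmut <- stats::rpois(1L, mutation$rate * L * clade$edge.length[r])
      if (nmut > 0L) for (site in sample.int(L, nmut, replace = TRUE))
        s[site] <- sample(setdiff(.BASES, s[site]), 1L)
      node_seq[[ch]] <- s
    }
    seqs <- do.call(rbind, node_seq[seq_len(n)])
  } else stop("unknown mutation model: ", mutation$model, call. = FALSE)
  alignment(tree$tip.label, apply(seqs, 1L, paste, collapse = ""))
}

#' Write a synthetic fixture to disk
#'
#' Produces the full input bundle the analysis consumes: a FASTA alignment
#' simulated from one genealogy, a locality table in the wide survey
#' dialect (demes as localities), a Newick file of \code{reps} independent
#' genealogies standing in for a posterior sample, an identity pooling map,
#' and a truth JSON recording the source deme and seeds.
#'
#' @param scn a \code{\link{make_scenario}} result.
#' @param reps number of genealogies in the tree sample.
#' @param outdir output directory (created if needed).
#' @param species species label used in the locality-table column names.
#' @return invisibly, a named list of the file paths written.
#' @export
export_fixture <- function(scn, reps, outdir, species = "SP1") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fasta = file.path(outdir, "alignment.fasta"),
                localities = file.path(outdir, "localities.tsv"),
                trees = file.path(outdir, "trees.nwk"),
                pooling = file.path(outdir, "pooling.tsv"),
                truth = file.path(outdir, "truth.json"))
  gen <- simulate_genealogy(scn)
  aln <- apply_mutations(gen, scn$mutation,
                         seed = if (is.null(scn$seed)) NULL else
                           scn$seed + 1L)
  write_fasta_alignment(aln, paths$fasta)

  tip_deme <- attr(gen, "tip_deme")
  index <- collapse_haplotypes(aln, tip_deme)
  per <- per_locality_summary(index)
  hap_lists <- vapply(per$code, function(cd) {
    labs <- names(Filter(function(o) cd %in% names(o), index$occurrences))
    paste(labs, collapse = ", ")
  }, "")
  dd <- scn$demes[match(per$code, scn$demes$name), ]
  loc <- data.frame(code = per$code, name = per$code,
                    lat = dd$lat, lon = dd$lon, stringsAsFactors = FALSE)
  loc[[paste0("N_", species)]] <- per$n
  loc[[paste0("haplotypes_", species)]] <- hap_lists
  utils::write.table(loc, paths$localities, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  trees <- vector("list", reps)
  for (i in seq_len(reps))
    trees[[i]] <- simulate_genealogy(scn, seed = scn$seed + 1000L + i)
  class(trees) <- "multiPhylo"
  ape::write.tree(trees, paths$trees)

  utils::write.table(data.frame(code = scn$demes$name,
                                character = scn$demes$name),
                     paths$pooling, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(source = scn$truth, preset = scn$preset,
                            strength = scn$strength, seed = scn$seed,
                            n_trees = reps),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
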