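# Neutrality and demographic-history statistics: Tajima's D, Fu's Fs with
# the Ewens sampling distribution, coalescent-simulation p-values, mismatch
# distributions with Harpending's raggedness, and McDonald-Kreitman counts.
#
# D, Fs and the mismatch distribution are computed on complete-deletion
# sites (columns unambiguous in every sequence) so that the observed
# statistic and its gap-free simulation null are internally consistent;
# nucleotide diversity for reporting stays pairwise-deletion.

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

# S, mean pairwise differences and haplotype count on complete sites
complete_summaries <- function(aln) {
  cs <- complete_sites(aln)
  m <- aln_matrix(aln)[, cs, drop = FALSE]
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1L))
  dm <- complete_deletion_diffs(aln)
  kbar <- if (aln$n >= 2) mean(dm[upper.tri(dm)]) else 0
  khap <- length(unique(apply(m, 1, paste, collapse = "")))
  list(n = aln$n, S = S, kbar = kbar, k_hap = khap, n_sites = length(cs))
}

.d_from_summaries <- function(n, S, kbar, cn = tajima_constants(n)) {
  if (S == 0) return(NA_real_)
  (kbar - S / cn$a1) / sqrt(cn$e1 * S + cn$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Compares the mean number of pairwise differences with the
#' segregating-sites estimate of theta; significantly negative values
#' indicate population expansion and/or purifying selection. Segregating
#' sites and mean pairwise differences are counted on complete-deletion
#' sites. Monomorphic data give a not-calculable marker.
#'
#' @param aln an \code{\link{alignment}} (n >= 4 recommended).
#' @return list of class \code{"tajima_d"}: \code{D}, \code{n}, \code{S},
#'   \code{kbar} and the standard constants.
#' @export
tajimas_d <- function(aln) {
  if (aln$n < 2) stop("need at least 2 sequences", call. = FALSE)
  sm <- complete_summaries(aln)
  cn <- tajima_constants(aln$n)
  structure(list(D = .d_from_summaries(aln$n, sm$S, sm$kbar, cn),
                 n = aln$n, S = sm$S, kbar = sm$kbar, constants = cn),
            class = "tajima_d")
}

#' @export
print.tajima_d <- function(x, ...) {
  cat("Tajima's D =", if (is.na(x$D)) "n. c." else formatC(x$D, digits = 4),
      " (n =", x$n, ", S =", x$S, ", mean pairwise =",
      formatC(x$kbar, digits = 4), ")\n")
  invisible(x)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
log_stirling1_row <- function(n) {
  row <- 0 # |s(1,1)| = 1
  if (n == 1L) return(row)
  for (m in seq_len(n - 1L)) {
    new <- numeric(m + 1L)
    # |s(m+1,k)| = m*|s(m,k)| + |s(m,k-1)|, in log space
    prev <- c(row, -Inf)
    shift <- c(-Inf, row)
    hi <- pmax(prev + log(m), shift)
    new <- hi + log1p(exp(pmin(prev + log(m), shift) - hi))
    new[is.nan(new)] <- -Inf
    row <- new
  }
  row
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability that a neutral sample of size n with scaled mutation rate
#' theta contains k distinct alleles:
#' \eqn{\Pr(K=k) = |s(n,k)| \theta^k / \prod_{i=0}^{n-1}(\theta+i)}, with
#' unsigned Stirling numbers of the first kind evaluated in log space.
#'
#' @param n sample size (>= 1).
#' @param theta positive scaled mutation rate.
#' @return numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_pmf <- function(n, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0)
    stop("domain error: theta must be a positive number", call. = FALSE)
  stopifnot(n >= 1)
  ls <- log_stirling1_row(n)
  k <- seq_len(n)
  lp <- ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp - max(lp)) / sum(exp(lp - max(lp)))
}

.fs_from_summaries <- function(n, k_hap, kbar) {
  if (k_hap <= 1L || kbar <= 0) return(NA_real_)
  pmf <- ewens_pmf(n, kbar)
  sp <- sum(pmf[k_hap:n])
  if (sp >= 1 - 1e-12 || sp <= 0) return(NA_real_)
  log(sp / (1 - sp))
}

#' Fu's Fs
#'
#' Uses the Ewens sampling distribution with theta estimated by the mean
#' number of pairwise differences: \eqn{S' = \Pr(K \ge k_{obs})} and
#' \eqn{F_S = \ln(S'/(1-S'))}. An excess of haplotypes relative to the
#' pairwise diversity (star-like genealogies) drives Fs negative. Samples
#' with a single haplotype are not calculable.
#'
#' @param aln an \code{\link{alignment}}.
#' @return Fs (scalar) or \code{NA} when not calculable.
#' @export
fus_fs <- function(aln) {
  if (aln$n < 2) stop("need at least 2 sequences", call. = FALSE)
  sm <- complete_summaries(aln)
  .fs_from_summaries(aln$n, sm$k_hap, sm$kbar)
}

# --- constant-size coalescent null ------------------------------------------

# One neutral constant-size genealogy for n tips. Returns branch lengths
# (coalescent units), the number of descendant tips per branch and, when
# track_members, the tip sets (needed to count haplotypes for Fs).
sim_coalescent_tree <- function(n, track_members = FALSE) {
  k <- n
  len <- numeric(n); size <- rep(1L, n)
  members <- if (track_members) as.list(seq_len(n)) else NULL
  blen <- numeric(2L * n - 2L); bsize <- integer(2L * n - 2L)
  bmembers <- if (track_members) vector("list", 2L * n - 2L) else NULL
  nb <- 0L
  while (k > 1L) {
    t <- stats::rexp(1L, k * (k - 1L) / 2)
    len <- len + t
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    for (x in c(i, j)) {
      nb <- nb + 1L
      blen[nb] <- len[x]; bsize[nb] <- size[x]
      if (track_members) bmembers[[nb]] <- members[[x]]
    }
    size[i] <- size[i] + size[j]
    if (track_members) members[[i]] <- c(members[[i]], members[[j]])
    len[i] <- 0
    size <- size[-j]; len <- len[-j]
    if (track_members) members[[j]] <- NULL
    k <- k - 1L
  }
  list(blen = blen[seq_len(nb)], bsize = bsize[seq_len(nb)],
       bmembers = if (track_members) bmembers[seq_len(nb)] else NULL)
}

# Simulate D (and optionally Fs) under the standard neutral null,
# conditioned either on the observed number of segregating sites
# (hypergeometric placement of S mutations on the genealogy) or on theta
# (Poisson mutations at rate theta/2 per branch-length unit).
sim_null_stat <- function(n, stat = c("D", "Fs"), S = NULL, theta = NULL) {
  stat <- match.arg(stat)
  tr <- sim_coalescent_tree(n, track_members = stat == "Fs")
  M <- if (!is.null(S)) S else stats::rpois(1L, theta / 2 * sum(tr$blen))
  if (M == 0L)
    return(if (stat == "D") NA_real_ else NA_real_)
  idx <- sample.int(length(tr$blen), M, replace = TRUE, prob = tr$blen)
  d <- tr$bsize[idx]
  kbar <- sum(d * (n - d)) / choose(n, 2)
  if (stat == "D") {
    .d_from_summaries(n, M, kbar)
  } else {
    sig <- vapply(seq_len(n), function(tip) {
      paste(which(vapply(idx, function(b) tip %in% tr$bmembers[[b]],
                         logical(1L))), collapse = ",")
    }, "")
    .fs_from_summaries(n, length(unique(sig)), kbar)
  }
}

#' Coalescent-simulation p-value for Tajima's D or Fu's Fs
#'
#' Simulates neutral constant-size coalescent genealogies with mutations
#' (conditioned on the observed number of segregating sites by default, or
#' on theta estimated by the mean pairwise differences), recomputes the
#' statistic, and reports \eqn{p = \Pr(\mathrm{sim} \le \mathrm{obs})} for
#' negative deviations (or a two-sided version). Significance flags use the
#' conventional thresholds 0.05 for D and 0.02 for Fs.
#'
#' @param aln an \code{\link{alignment}}.
#' @param stat \code{"D"} or \code{"Fs"}.
#' @param reps number of simulations (>= 100).
#' @param seed optional integer seed.
#' @param condition condition the null on \code{"S"} or \code{"theta"}.
#' @param alternative \code{"less"} (default) or \code{"two.sided"}.
#' @return list of class \code{"coalescent_test"}: \code{stat},
#'   \code{observed}, \code{p}, \code{significant}, \code{reps},
#'   \code{null} (simulated values).
#' @export
coalescent_null_pvalue <- function(aln, stat = c("D", "Fs"), reps = 1000,
                                   seed = NULL,
                                   condition = c("S", "theta"),
                                   alternative = c("less", "two.sided")) {
  stat <- match.arg(stat); condition <- match.arg(condition)
  alternative <- match.arg(alternative)
  if (reps < 100) stop("reps must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sm <- complete_summaries(aln)
  obs <- if (stat == "D") .d_from_summaries(sm$n, sm$S, sm$kbar)
         else .fs_from_summaries(sm$n, sm$k_hap, sm$kbar)
  if (is.na(obs))
    stop("observed ", stat, " is not calculable; p-value undefined",
         call. = FALSE)
  S <- if (condition == "S") sm$S else NULL
  theta <- if (condition == "theta") sm$kbar else NULL
  null <- vapply(seq_len(reps), function(i)
    sim_null_stat(sm$n, stat, S = S, theta = theta), numeric(1L))
  null <- null[!is.na(null)]
  r <- length(null)
  p_lo <- (1 + sum(null <= obs)) / (r + 1)
  p_hi <- (1 + sum(null >= obs)) / (r + 1)
  p <- switch(alternative, less = p_lo, two.sided = min(1, 2 * min(p_lo, p_hi)))
  thr <- if (stat == "D") 0.05 else 0.02
  structure(list(stat = stat, observed = obs, p = p,
                 significant = p < thr, threshold = thr, reps = r,
                 alternative = alternative, null = null),
            class = "coalescent_test")
}

#' @export
print.coalescent_test <- function(x, ...) {
  cat(x$stat, "=", formatC(x$observed, digits = 4), ", p =",
      formatC(x$p, digits = 3), if (x$significant) "*" else "", "(",
      x$reps, "coalescent simulations )\n")
  invisible(x)
}

# --- mismatch distribution ---------------------------------------------------

#' Observed mismatch distribution
#'
#' Relative frequency of pairwise difference counts (complete-deletion
#' counts) for all sequence pairs, classes 0..d where d is the maximum
#' observed difference.
#'
#' @param aln an \code{\link{alignment}} with n >= 2.
#' @return numeric vector \code{x} with names "0".."d", summing to 1.
#' @export
mismatch_observed <- function(aln) {
  if (aln$n < 2) stop("need at least 2 sequences", call. = FALSE)
  dm <- complete_deletion_diffs(aln)
  cnt <- dm[upper.tri(dm)]
  d <- max(cnt)
  x <- tabulate(cnt + 1L, nbins = d + 1L) / length(cnt)
  stats::setNames(x, 0:d)
}

#' Expected mismatch distribution
#'
#' Constant-size model: \eqn{F_i = \theta^i/(\theta+1)^{i+1}} (geometric).
#' Sudden-expansion model (with the common post-expansion-size-to-infinity
#' simplification): the pair separation is tau mutational units of
#' deterministic drift plus a stationary geometric component, i.e. the
#' convolution of a Poisson(tau) with the geometric law of theta0. With
#' tau = 0 the expansion model reduces to the constant model at theta0.
#'
#' @param model \code{"constant"} or \code{"expansion"}.
#' @param d largest difference class to report.
#' @param theta constant-model parameter.
#' @param tau,theta0 expansion-model parameters (both >= 0).
#' @return numeric vector F_0..F_d (head of a distribution; sums to <= 1).
#' @export
mismatch_expected <- function(model = c("constant", "expansion"), d,
                              theta = NULL, tau = NULL, theta0 = NULL) {
  model <- match.arg(model)
  j <- 0:d
  if (model == "constant") {
    if (is.null(theta) || theta < 0)
      stop("domain error: theta must be >= 0", call. = FALSE)
    return(stats::setNames(theta^j / (theta + 1)^(j + 1), j))
  }
  if (is.null(tau) || is.null(theta0) || tau < 0 || theta0 < 0)
    stop("domain error: tau and theta0 must be >= 0", call. = FALSE)
  geom <- theta0^j / (theta0 + 1)^(j + 1)
  pois <- stats::dpois(j, tau)
  f <- vapply(j, function(jj)
    sum(pois[1:(jj + 1)] * geom[(jj + 1):1]), numeric(1L))
  stats::setNames(f, j)
}

#' Fit the sudden-expansion mismatch model by least squares
#'
#' Coarse grid over (tau, theta0) followed by Nelder-Mead refinement on the
#' sum of squared deviations from the observed relative frequencies.
#'
#' @param x observed mismatch distribution (\code{\link{mismatch_observed}}).
#' @return list: \code{tau}, \code{theta0}, \code{expected}, \code{sse}.
#' @export
fit_mismatch <- function(x) {
  d <- length(x) - 1L
  mean_obs <- sum((0:d) * x)
  sse <- function(par) {
    f <- mismatch_expected("expansion", d, tau = par[1L], theta0 = par[2L])
    sum((x - f)^2)
  }
  taus <- seq(0, max(2 * mean_obs, 1), length.out = 21L)
  th0s <- seq(0.01, max(mean_obs, 1), length.out = 21L)
  grid <- expand.grid(tau = taus, theta0 = th0s)
  vals <- apply(grid, 1L, sse)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, function(p) {
    if (any(p < 0)) return(Inf)
    sse(p)
  }, method = "Nelder-Mead")
  list(tau = max(0, opt$par[1L]), theta0 = max(0, opt$par[2L]),
       expected = mismatch_expected("expansion", d, tau = max(0, opt$par[1L]),
                                    theta0 = max(0, opt$par[2L])),
       sse = opt$value)
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} with \eqn{x_{d+1} := 0}.
#' Smooth unimodal mismatch distributions (as under demographic expansion)
#' have low raggedness; multimodal ones are ragged.
#'
#' @param x relative frequencies summing to 1.
#' @return r >= 0.
#' @examples
#' raggedness_index(c(0.25, 0.5, 0.25)) # 0.1875
#' @export
raggedness_index <- function(x) {
  if (length(x) == 0L)
    stop("domain error: empty mismatch distribution", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-8)
    stop("domain error: frequencies must sum to 1", call. = FALSE)
  xx <- c(x, 0)
  sum(diff(xx)^2)
}

# Genealogy under the fitted sudden-expansion model, in mutational time
# units: no coalescence more recently than tau (post-expansion size taken
# as effectively infinite), then rate k(k-1)/theta0; branches mutate at
# rate 1. Returns the simulated mismatch distribution.
sim_expansion_mismatch <- function(n, tau, theta0) {
  k <- n
  len <- numeric(n)
  members <- as.list(seq_len(n))
  bl <- numeric(0); bm <- list()
  len <- len + tau
  while (k > 1L) {
    t <- stats::rexp(1L, k * (k - 1L) / max(theta0, 1e-9))
    len <- len + t
    pair <- sample.int(k, 2L)
    i <- pair[1L]; j <- pair[2L]
    bl <- c(bl, len[i], len[j]); bm <- c(bm, members[i], members[j])
    members[[i]] <- c(members[[i]], members[[j]])
    len[i] <- 0
    members[[j]] <- NULL; len <- len[-j]
    k <- k - 1L
  }
  M <- stats::rpois(1L, sum(bl))
  dmat <- matrix(0L, n, n)
  if (M > 0L) {
    idx <- sample.int(length(bl), M, replace = TRUE, prob = bl)
    for (b in idx) {
      inside <- bm[[b]]
      outside <- setdiff(seq_len(n), inside)
      dmat[inside, outside] <- dmat[inside, outside] + 1L
    }
  }
  cnt <- pmax(dmat, t(dmat))[upper.tri(dmat)]
  d <- max(cnt)
  tabulate(cnt + 1L, nbins = d + 1L) / length(cnt)
}

#' Goodness-of-fit p-value for the raggedness index
#'
#' Fits the sudden-expansion model to the observed mismatch distribution,
#' then simulates coalescent samples under the fitted model and reports
#' \eqn{p = \Pr(r_{sim} \ge r_{obs})}. A significantly high observed
#' raggedness (p < 0.05) rejects the expansion model.
#'
#' @inheritParams coalescent_null_pvalue
#' @return list of class \code{"raggedness_test"}: \code{r}, \code{p},
#'   \code{tau}, \code{theta0}, \code{reps}.
#' @export
raggedness_pvalue <- function(aln, reps = 1000, seed = NULL) {
  if (reps < 100) stop("reps must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- mismatch_observed(aln)
  if (length(x) == 1L)
    stop("degenerate mismatch distribution; p-value undefined", call. = FALSE)
  r_obs <- raggedness_index(x)
  fit <- fit_mismatch(x)
  r_sim <- vapply(seq_len(reps), function(i)
    raggedness_index(sim_expansion_mismatch(aln$n, fit$tau, fit$theta0)),
    numeric(1L))
  p <- (1 + sum(r_sim >= r_obs)) / (reps + 1)
  structure(list(r = r_obs, p = p, tau = fit$tau, theta0 = fit$theta0,
                 reps = reps),
            class = "raggedness_test")
}

#' @export
print.raggedness_test <- function(x, ...) {
  cat("Hri =", formatC(x$r, digits = 3), ", p =", formatC(x$p, digits = 3),
      "( expansion fit tau =", formatC(x$tau, digits = 3), ", theta0 =",
      formatC(x$theta0, digits = 3), ")\n")
  invisible(x)
}

# --- McDonald-Kreitman -------------------------------------------------------

# Average synonymous/non-synonymous split over all minimal mutational
# pathways between two codons. Pathways passing through a stop codon are
# discarded when an alternative exists.
codon_path_changes <- function(c1, c2, numcode = 5) {
  pos <- which(seqinr::s2c(c1) != seqinr::s2c(c2))
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  orders <- if (length(pos) == 1L) list(pos) else {
    perm <- function(v) if (length(v) == 1L) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perm(v[-i]), function(p) c(v[i], p))))
    perm(pos)
  }
  aa <- function(cod) seqinr::translate(seqinr::s2c(cod), numcode = numcode,
                                        NAstring = "X")
  paths <- lapply(orders, function(ord) {
    cur <- seqinr::s2c(c1)
    target <- seqinr::s2c(c2)
    syn <- 0; nonsyn <- 0; through_stop <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- target[p]
      a1 <- aa(paste(cur, collapse = "")); a2 <- aa(paste(nxt, collapse = ""))
      if (a2 == "*" && !identical(nxt, target)) through_stop <- TRUE
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, stop = through_stop)
  })
  ok <- !vapply(paths, `[[`, logical(1L), "stop")
  if (any(ok)) paths <- paths[ok]
  c(syn = mean(vapply(paths, `[[`, numeric(1L), "syn")),
    nonsyn = mean(vapply(paths, `[[`, numeric(1L), "nonsyn")))
}

# minimum spanning tree over a small set of codons (Prim), edges as index
# pairs; distance = number of differing positions
codon_mst <- function(codons) {
  k <- length(codons)
  if (k < 2L) return(NULL)
  dmat <- outer(codons, codons, Vectorize(function(a, b)
    sum(seqinr::s2c(a) != seqinr::s2c(b))))
  intree <- 1L; edges <- NULL
  while (length(intree) < k) {
    best <- NULL; bestd <- Inf
    for (i in intree) for (j in setdiff(seq_len(k), intree)) {
      if (dmat[i, j] < bestd) { bestd <- dmat[i, j]; best <- c(i, j) }
    }
    edges <- rbind(edges, best)
    intree <- c(intree, best[2L])
  }
  edges
}

#' McDonald-Kreitman polymorphism/divergence counts
#'
#' Classifies coding-sequence changes between two species' alignments into
#' polymorphic synonymous (Ps), polymorphic non-synonymous (Pn), fixed
#' synonymous (Ms) and fixed non-synonymous (Mn). Within-species variation
#' at a codon contributes polymorphic changes (summed over a minimum
#' spanning tree of the observed codon variants); a position whose allele
#' sets are disjoint between the species contributes a fixed change between
#' the species' majority codons. Synonymous/non-synonymous assignment
#' averages over minimal mutational pathways for multi-hit codons, so
#' fractional counts are possible there. Positive selection is indicated
#' when Mn/Pn greatly exceeds Ms/Ps.
#'
#' @param aln_A,aln_B alignments of the two species (same length, same
#'   reading frame).
#' @param code genetic code (see \code{\link{translate_codons}}).
#' @param frame 0, 1, 2 or \code{"auto"} (minimize internal stop codons).
#' @return list of class \code{"mk_counts"}: \code{Ps}, \code{Pn},
#'   \code{Ms}, \code{Mn}, \code{frame}, \code{neutrality_index} (Mn/Pn
#'   divided by Ms/Ps, \code{NA} when undefined) and
#'   \code{positive_selection_indicated}.
#' @export
mk_counts <- function(aln_A, aln_B, code = "invertebrate_mito",
                      frame = "auto") {
  if (aln_A$L != aln_B$L)
    stop("alignment error: species alignments differ in length",
         call. = FALSE)
  numcode <- if (is.numeric(code)) code else .GENETIC_CODES[[code]]
  all_seqs <- c(aln_A$seqs, aln_B$seqs)
  if (identical(frame, "auto")) {
    stops <- vapply(0:2, function(f) {
      aas <- vapply(all_seqs, function(s)
        translate_codons(s, code = code, frame = f), "")
      sum(vapply(aas, function(a)
        lengths(regmatches(a, gregexpr("*", a, fixed = TRUE))), 0L))
    }, 0L)
    frame <- which.min(stops) - 1L
  }
  aas <- vapply(all_seqs, function(s)
    translate_codons(s, code = code, frame = frame), "")
  n_codons <- nchar(aas[[1L]])
  stop_frac <- mean(vapply(strsplit(aas, ""), function(a)
    mean(a == "*"), 0))
  if (stop_frac > 0.5)
    warning("frame warning: chosen frame yields internal stops in >50% of codons")

  codons_of <- function(aln) {
    m <- aln_matrix(aln)[, (frame + 1L):(frame + 3L * n_codons), drop = FALSE]
    vapply(seq_len(n_codons), function(ci) {
      apply(m[, (3L * ci - 2L):(3L * ci), drop = FALSE], 1L, paste,
            collapse = "")
    }, character(aln$n))
  }
  ca <- matrix(codons_of(aln_A), nrow = aln_A$n)
  cb <- matrix(codons_of(aln_B), nrow = aln_B$n)
  clean <- function(x) x[grepl("^[ACGT]{3}$", x)]
  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1L]

  Ps <- 0; Pn <- 0; Ms <- 0; Mn <- 0
  for (ci in seq_len(n_codons)) {
    va <- clean(ca[, ci]); vb <- clean(cb[, ci])
    if (!length(va) || !length(vb)) next
    ua <- unique(va); ub <- unique(vb)
    # polymorphic changes within each species
    for (u in list(ua, ub)) {
      ed <- codon_mst(u)
      if (!is.null(ed)) for (r in seq_len(nrow(ed))) {
        ch <- codon_path_changes(u[ed[r, 1L]], u[ed[r, 2L]], numcode)
        Ps <- Ps + ch[["syn"]]; Pn <- Pn + ch[["nonsyn"]]
      }
    }
    # fixed changes: positions with disjoint allele sets between species
    pa <- matrix(unlist(strsplit(va, "")), ncol = 3L, byrow = TRUE)
    pb <- matrix(unlist(strsplit(vb, "")), ncol = 3L, byrow = TRUE)
    fixed_pos <- which(vapply(1:3, function(p)
      length(intersect(pa[, p], pb[, p])) == 0L, logical(1L)))
    if (length(fixed_pos)) {
      bga <- seqinr::s2c(majority(va)); bgb <- seqinr::s2c(majority(vb))
      c1 <- bga
      c2 <- bga; c2[fixed_pos] <- bgb[fixed_pos]
      ch <- codon_path_changes(paste(c1, collapse = ""),
                               paste(c2, collapse = ""), numcode)
      Ms <- Ms + ch[["syn"]]; Mn <- Mn + ch[["nonsyn"]]
    }
  }
  ni <- if (Pn > 0 && Ms > 0 && Ps > 0) (Mn / Pn) / (Ms / Ps) else NA_real_
  structure(list(Ps = Ps, Pn = Pn, Ms = Ms, Mn = Mn, frame = frame,
                 neutrality_index = ni,
                 positive_selection_indicated = Mn > 0 && !is.na(ni) && ni > 1),
            class = "mk_counts")
}

#' @export
print.mk_counts <- function(x, ...) {
  cat("McDonald-Kreitman counts (frame ", x$frame, "):\n", sep = "")
  cat("  polymorphic: syn =", x$Ps, ", non-syn =", x$Pn, "\n")
  cat("  fixed:       syn =", x$Ms, ", non-syn =", x$Mn, "\n")
  if (x$Mn == 0)
    cat("  no fixed non-synonymous differences: positive selection not indicated\n")
  invisible(x)
}
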