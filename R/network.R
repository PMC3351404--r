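# Statistical-parsimony haplotype networks and loop resolution.

#' Parsimony connection limit
#'
#' Largest number of mutational steps at which two haplotypes can be
#' connected while the probability that no site experienced a superimposed
#' change still exceeds the confidence level. The probability that j
#' mutational events over L sites all hit distinct sites (so every event is
#' visible and the connection is parsimonious) is
#' \eqn{P_j = \prod_{i=1}^{j-1} (1 - i/L)}; the limit is the largest j with
#' \eqn{P_j >} \code{confidence}. A single step is always connectable.
#'
#' @param L number of sites in the alignment.
#' @param confidence probability in (0, 1); conventionally 0.95.
#' @return integer, the maximum connectable number of steps.
#' @examples
#' parsimony_connection_limit(590) # 8 at 95%
#' @export
parsimony_connection_limit <- function(L, confidence = 0.95) {
  stopifnot(L > 0)
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1)
    stop("domain error: confidence must be in (0, 1)", call. = FALSE)
  j <- 1L
  while (j < L) {
    p_next <- prod(1 - seq_len(j) / L) # P_{j+1}
    if (p_next <= confidence) break
    j <- j + 1L
  }
  j
}

#' Build a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in increasing order of mutational distance
#' (pairwise-deletion difference counts): at each distance value, an edge is
#' added for every pair not yet connected through strictly shorter edges, so
#' equally parsimonious alternatives are all retained (and later resolved by
#' \code{\link{resolve_loops}}). Pairs beyond \code{max_steps} stay
#' unconnected and fall into separate subnetworks. Each retained multi-step
#' edge is expanded with inferred zero-frequency intermediate nodes so that
#' every edge of the expanded network spans exactly one mutational step.
#'
#' @param index a \code{\link{collapse_haplotypes}} result (haplotype
#'   sequences, frequencies and locality sets).
#' @param max_steps connection limit (e.g. from
#'   \code{\link{parsimony_connection_limit}}).
#' @param coords optional data.frame \code{code}, \code{lat}, \code{lon}
#'   giving locality coordinates, used by the geographic loop-resolution
#'   criterion.
#' @return Object of class \code{"parsimony_network"}: \code{nodes}
#'   (data.frame \code{node}, \code{type}, \code{freq}), \code{edges_h}
#'   (haplotype-level edges with \code{steps}), \code{edges} (expanded
#'   single-step edges), \code{localities} (named list node -> locality
#'   codes), \code{coords}, \code{removed} (loop-resolution log, empty
#'   until resolved).
#' @export
build_parsimony_network <- function(index, max_steps, coords = NULL) {
  stopifnot(max_steps >= 1)
  haln <- haplotype_alignment(index)
  dm <- pairwise_differences(haln)$diff
  labs <- index$haplotypes$label
  k <- length(labs)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), stringsAsFactors = FALSE)
  if (k > 1L) {
    comp <- seq_len(k) # union-find by relabeling
    pairs <- which(upper.tri(dm), arr.ind = TRUE)
    dvals <- dm[pairs]
    keep <- !is.na(dvals) & dvals <= max_steps & dvals > 0
    pairs <- pairs[keep, , drop = FALSE]; dvals <- dvals[keep]
    for (d in sort(unique(dvals))) {
      sel <- which(dvals == d)
      # connectivity before this distance group
      comp_before <- comp
      for (s in sel) {
        i <- pairs[s, 1L]; j <- pairs[s, 2L]
        if (comp_before[i] != comp_before[j]) {
          edges <- rbind(edges, data.frame(
            from = labs[min(i, j)], to = labs[max(i, j)],
            steps = as.integer(d), stringsAsFactors = FALSE))
          ci <- comp[i]; cj <- comp[j]
          if (ci != cj) comp[comp == cj] <- ci
        }
      }
    }
  }
  nodes <- data.frame(node = labs, type = "haplotype",
                      freq = index$haplotypes$count,
                      stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges_h = edges, edges = NULL,
                        localities = lapply(index$occurrences, names),
                        coords = coords,
                        removed = data.frame(from = character(0),
                                             to = character(0),
                                             criterion = character(0),
                                             stringsAsFactors = FALSE)),
                   class = "parsimony_network")
  net$edges <- expand_intermediates(net)
  net
}

# expand multi-step haplotype edges into chains of single-step edges with
# inferred intermediate nodes named <from>.<to>.i
expand_intermediates <- function(net) {
  out <- data.frame(from = character(0), to = character(0),
                    stringsAsFactors = FALSE)
  eh <- net$edges_h
  for (r in seq_len(nrow(eh))) {
    d <- eh$steps[r]
    if (d == 1L) {
      out <- rbind(out, data.frame(from = eh$from[r], to = eh$to[r],
                                   stringsAsFactors = FALSE))
    } else {
      mids <- paste0(eh$from[r], ".", eh$to[r], ".", seq_len(d - 1L))
      chain <- c(eh$from[r], mids, eh$to[r])
      out <- rbind(out, data.frame(from = chain[-length(chain)],
                                   to = chain[-1L], stringsAsFactors = FALSE))
    }
  }
  out
}

# all node names of the expanded network (haplotypes + intermediates)
network_nodes <- function(net) {
  unique(c(net$nodes$node, net$edges$from, net$edges$to))
}

net_igraph <- function(net, level = c("haplotype", "expanded")) {
  level <- match.arg(level)
  ed <- if (level == "haplotype") net$edges_h[, c("from", "to")] else net$edges
  vs <- if (level == "haplotype") net$nodes$node else network_nodes(net)
  igraph::graph_from_data_frame(ed, directed = FALSE,
                                vertices = data.frame(name = vs))
}

#' @export
print.parsimony_network <- function(x, ...) {
  g <- net_igraph(x, "haplotype")
  cat("Parsimony network:", nrow(x$nodes), "haplotypes,",
      nrow(x$edges_h), "connections,",
      igraph::count_components(g), "subnetwork(s)\n")
  if (nrow(x$removed))
    cat("  loops resolved:", nrow(x$removed), "edge(s) removed\n")
  invisible(x)
}

# minimum great-circle distance (m) between the locality sets of two nodes;
# Inf when coordinates or localities are unavailable
min_geo_distance <- function(net, a, b) {
  if (is.null(net$coords)) return(Inf)
  la <- net$localities[[a]]; lb <- net$localities[[b]]
  if (is.null(la) || is.null(lb) || !length(la) || !length(lb)) return(Inf)
  ca <- net$coords[match(la, net$coords$code), c("lon", "lat"), drop = FALSE]
  cb <- net$coords[match(lb, net$coords$code), c("lon", "lat"), drop = FALSE]
  ca <- ca[stats::complete.cases(ca), , drop = FALSE]
  cb <- cb[stats::complete.cases(cb), , drop = FALSE]
  if (!nrow(ca) || !nrow(cb)) return(Inf)
  min(apply(ca, 1L, function(p)
    min(geosphere::distHaversine(p, as.matrix(cb)))))
}

#' Resolve ambiguities (loops) in a parsimony network
#'
#' Breaks every cycle by removing one edge per cycle, chosen by an ordered
#' criterion cascade: (0) among the cycle's longest (most-step) edges,
#' (1) retain connections to higher-frequency haplotypes (remove the edge
#' with the lowest endpoint frequencies), (2) retain connections to
#' interior (non-tip) haplotypes, (3) retain connections between
#' geographically closer locality sets (minimum great-circle distance),
#' (4) deterministic lexicographic tie-break. Every removal is logged in
#' \code{$removed} with the deciding criterion. Idempotent on acyclic
#' networks.
#'
#' @param net a \code{\link{build_parsimony_network}} result.
#' @return the network with an acyclic \code{edges_h}/\code{edges} and a
#'   populated removal log.
#' @export
resolve_loops <- function(net) {
  freq_of <- stats::setNames(net$nodes$freq, net$nodes$node)
  repeat {
    g <- net_igraph(net, "haplotype")
    gir <- igraph::girth(g, circle = TRUE)
    if (!is.finite(gir$girth) || gir$girth == 0) break
    cyc <- names(gir$circle)
    cyc_edges <- data.frame(from = cyc, to = c(cyc[-1L], cyc[1L]),
                            stringsAsFactors = FALSE)
    # locate the cycle edges in edges_h (either orientation)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    idx <- match(key(cyc_edges$from, cyc_edges$to),
                 key(net$edges_h$from, net$edges_h$to))
    idx <- idx[!is.na(idx)]
    cand <- net$edges_h[idx, , drop = FALSE]
    crit <- "steps"
    sel <- which(cand$steps == max(cand$steps))
    if (length(sel) > 1L) { # criterion 1: haplotype frequency
      crit <- "frequency"
      fmax <- pmax(freq_of[cand$from[sel]], freq_of[cand$to[sel]])
      fmin <- pmin(freq_of[cand$from[sel]], freq_of[cand$to[sel]])
      o <- order(fmax, fmin)
      low <- fmax[o[1L]] == fmax & fmin[o[1L]] == fmin
      sel <- sel[low]
    }
    if (length(sel) > 1L) { # criterion 2: interior vs tip endpoints
      crit <- "topology"
      deg <- igraph::degree(g)
      n_int <- (deg[cand$from[sel]] > 1L) + (deg[cand$to[sel]] > 1L)
      sel <- sel[n_int == min(n_int)]
    }
    if (length(sel) > 1L) { # criterion 3: geography
      crit <- "geography"
      gd <- vapply(sel, function(s)
        min_geo_distance(net, cand$from[s], cand$to[s]), numeric(1L))
      if (any(is.finite(gd))) sel <- sel[gd == max(gd)] # remove the farthest
    }
    if (length(sel) > 1L) { # criterion 4: lexicographic
      crit <- "tie"
      o <- order(cand$from[sel], cand$to[sel])
      sel <- sel[o[1L]]
    }
    drop <- idx[sel[1L]]
    net$removed <- rbind(net$removed,
                         data.frame(from = net$edges_h$from[drop],
                                    to = net$edges_h$to[drop],
                                    criterion = crit,
                                    stringsAsFactors = FALSE))
    net$edges_h <- net$edges_h[-drop, , drop = FALSE]
  }
  net$edges <- expand_intermediates(net)
  net
}

#' Export a network as GraphML or DOT
#'
#' @param net a \code{"parsimony_network"}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @param level \code{"expanded"} (single-step edges with inferred
#'   intermediates) or \code{"haplotype"}.
#' @export
export_network <- function(net, path, format = c("graphml", "dot"),
                           level = c("expanded", "haplotype")) {
  format <- match.arg(format); level <- match.arg(level)
  g <- net_igraph(net, level)
  freq <- stats::setNames(net$nodes$freq, net$nodes$node)
  igraph::V(g)$freq <- ifelse(is.na(freq[igraph::V(g)$name]), 0,
                              freq[igraph::V(g)$name])
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
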