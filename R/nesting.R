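# Hierarchical nesting design over a resolved network and MOTU assignment.

# One nesting pass over a clade graph: nodes (character ids) and an edge
# data.frame. Works inward from tips: every terminal node joins its
# neighbour (together with all other terminals sharing that neighbour);
# interior nodes left isolated after their neighbours were absorbed form
# their own singleton clade and are merged by the same rule at the next
# level. Returns a list of character vectors (the clades).
nest_once <- function(nodes, edges) {
  remaining <- nodes
  clades <- list()
  adj <- function(x) unique(c(edges$to[edges$from == x & edges$to %in% remaining],
                              edges$from[edges$to == x & edges$from %in% remaining]))
  while (length(remaining)) {
    deg <- vapply(remaining, function(x) length(adj(x)), 0L)
    if (all(deg == 0L)) { # isolated leftovers become singleton clades
      clades <- c(clades, as.list(remaining))
      break
    }
    terminals <- remaining[deg == 1L]
    if (!length(terminals)) { # safety net; cannot occur on a forest
      clades <- c(clades, list(remaining))
      break
    }
    nbrs <- vapply(terminals, function(t) adj(t)[1L], "")
    assigned <- character(0)
    # interior centers absorb all their terminal neighbours
    centers <- setdiff(unique(nbrs), terminals)
    for (cn in sort(centers)) {
      cl <- c(cn, sort(terminals[nbrs == cn]))
      clades <- c(clades, list(cl))
      assigned <- c(assigned, cl)
    }
    # two-node components: both endpoints terminal
    left <- setdiff(terminals, assigned)
    for (t in sort(left)) {
      if (t %in% assigned) next
      nb <- nbrs[[t]]
      if (nb %in% assigned) next
      clades <- c(clades, list(sort(c(t, nb))))
      assigned <- c(assigned, t, nb)
    }
    remaining <- setdiff(remaining, assigned)
  }
  clades
}

#' Construct a hierarchical nesting design
#'
#' Builds nested clades over a resolved (acyclic) parsimony network,
#' including inferred intermediate nodes: level-1 clades unite nodes within
#' one mutational step working inward from the tips of the network; each
#' higher level applies the same rule to the graph of previous-level
#' clades. Isolated interior leftovers stay singleton clades within their
#' level and are absorbed at the next one. Disconnected subnetworks are
#' nested independently and never merge.
#'
#' @param net a resolved \code{"parsimony_network"}
#'   (\code{\link{resolve_loops}}).
#' @param max_level number of nesting levels to build (>= 1).
#' @return Object of class \code{"nesting_design"}: \code{levels}, a list
#'   whose k-th element is a named list of level-k clades (character
#'   vectors of node names); \code{freq}, named haplotype frequencies;
#'   \code{converged}, whether further levels would change nothing.
#' @export
build_nesting_design <- function(net, max_level) {
  if (max_level < 1) stop("domain error: max_level must be >= 1",
                          call. = FALSE)
  g <- net_igraph(net, "haplotype")
  if (igraph::gsize(g) >= igraph::vcount(g) -
      igraph::count_components(g) + 1L ||
      is.finite(igraph::girth(g)$girth))
    stop("network contains unresolved loops; run resolve_loops() first",
         call. = FALSE)
  nodes <- sort(network_nodes(net))
  edges <- net$edges
  levels <- list()
  # level 0 = the nodes themselves
  members <- stats::setNames(as.list(nodes), nodes)
  for (lev in seq_len(max_level)) {
    clades <- nest_once(names(members), edges)
    clades <- lapply(clades, sort)
    clades <- clades[order(vapply(clades, `[[`, "", 1L))]
    names(clades) <- paste0("L", lev, ".", seq_along(clades))
    # contract: new node per clade, edges between clades sharing a member edge
    owner <- stats::setNames(rep(names(clades), lengths(clades)),
                             unlist(clades))
    new_members <- lapply(clades, function(cl)
      sort(unique(unlist(members[cl]))))
    e_from <- owner[edges$from]; e_to <- owner[edges$to]
    keep <- e_from != e_to
    edges <- unique(data.frame(from = pmin(e_from[keep], e_to[keep]),
                               to = pmax(e_from[keep], e_to[keep]),
                               stringsAsFactors = FALSE))
    levels[[lev]] <- new_members
    members <- new_members
  }
  structure(list(levels = levels,
                 freq = stats::setNames(net$nodes$freq, net$nodes$node),
                 converged = nrow(edges) == 0L),
            class = "nesting_design")
}

#' @export
print.nesting_design <- function(x, ...) {
  cat("Nesting design:", length(x$levels), "level(s);",
      vapply(x$levels, length, 0L), "clade(s) per level\n")
  invisible(x)
}

#' Assign MOTU labels at a nesting level
#'
#' Clades of the requested level that contain at least one observed
#' haplotype become molecular operational taxonomic units, numbered by
#' decreasing total haplotype frequency. Disconnected subnetworks are
#' necessarily distinct MOTUs at every level.
#'
#' @param design a \code{\link{build_nesting_design}} result.
#' @param level nesting level (1-based; at most the design depth).
#' @param prefix label prefix, default \code{"MOTU"}.
#' @return named character vector: haplotype label -> MOTU label.
#' @export
assign_motus <- function(design, level, prefix = "MOTU") {
  if (level < 1 || level > length(design$levels))
    stop("domain error: level ", level, " beyond design depth ",
         length(design$levels), call. = FALSE)
  clades <- design$levels[[level]]
  haps <- names(design$freq)
  cl_h <- lapply(clades, function(cl) intersect(cl, haps))
  cl_h <- cl_h[lengths(cl_h) > 0L]
  tot <- vapply(cl_h, function(cl) sum(design$freq[cl]), 0)
  o <- order(-tot, vapply(cl_h, `[[`, "", 1L))
  out <- character(0)
  for (i in seq_along(o)) {
    cl <- cl_h[[o[i]]]
    out[cl] <- paste0(prefix, i)
  }
  out[haps]  # ordered as the haplotype labels
}
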