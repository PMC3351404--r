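# Refugium localization reconstruction: Fitch parsimony ancestral-locality
# inference over a sample of rooted genealogies, summarised as relative
# probability scores, plus harmonic-mean Bayes-factor utilities.

#' Read a posterior-like sample of rooted trees
#'
#' Reads Newick or NEXUS (translate-table dialect) tree files, discards a
#' burn-in prefix and optionally draws a uniform subsample with a fixed
#' seed. Every tree must be rooted.
#'
#' @param path tree file; NEXUS is detected from the \code{#NEXUS} header.
#' @param burnin_fraction proportion of leading trees to discard.
#' @param subsample number of trees to draw from the post-burn-in sample
#'   (\code{NULL} keeps all). Drawing exactly the available number keeps
#'   all trees in order.
#' @param seed integer seed for the subsampling draw.
#' @return a \code{multiPhylo} list of rooted trees.
#' @export
read_tree_sample <- function(path, burnin_fraction = 0, subsample = NULL,
                             seed = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  trees <- if (grepl("#NEXUS", toupper(first), fixed = TRUE))
    ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!length(trees)) stop("empty-input error: no trees in ", path,
                           call. = FALSE)
  if (burnin_fraction < 0 || burnin_fraction >= 1)
    stop("burnin_fraction must be in [0, 1)", call. = FALSE)
  rooted <- vapply(trees, ape::is.rooted, logical(1L))
  if (!all(rooted))
    stop("rooting error: tree(s) ",
         paste(utils::head(which(!rooted), 5L), collapse = ", "),
         " are unrooted", call. = FALSE)
  drop <- floor(burnin_fraction * length(trees))
  trees <- trees[(drop + 1L):length(trees)]
  if (!is.null(subsample)) {
    if (subsample > length(trees))
      stop("count error: requested ", subsample, " trees but only ",
           length(trees), " available after burn-in", call. = FALSE)
    if (subsample < length(trees)) {
      if (!is.null(seed)) set.seed(seed)
      trees <- trees[sort(sample.int(length(trees), subsample))]
    }
  }
  class(trees) <- "multiPhylo"
  trees
}

#' Pool adjacent localities into shared characters
#'
#' Relabels locality codes into pooled characters for the ancestral-state
#' reconstruction (pooling adjacent localities increases resolution).
#' Codes absent from the map are an error unless \code{identity_default} is
#' set, in which case they map to themselves.
#'
#' @param map named character vector: locality code -> pooled character
#'   (identity entries allowed).
#' @param table a \code{\link{read_locality_table}} result; every locality
#'   code with data must be covered.
#' @param identity_default map uncovered codes to themselves instead of
#'   erroring.
#' @return named character vector over all codes with data.
#' @export
pool_localities <- function(map, table, identity_default = FALSE) {
  codes <- sort(unique(unlist(lapply(table$species, function(s) s$code))))
  missing <- setdiff(codes, names(map))
  if (length(missing) && !identity_default)
    stop("mapping error: locality code(s) absent from pooling map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  full <- c(map, stats::setNames(missing, missing))
  full[codes]
}

#' Read a two-column pooling map
#'
#' @param path TSV with columns \code{code} and \code{character}.
#' @return named character vector code -> pooled character.
#' @export
read_pooling_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          strip.white = TRUE)
  if (!all(c("code", "character") %in% names(df)))
    stop("pooling map needs columns 'code' and 'character'", call. = FALSE)
  stats::setNames(df$character, df$code)
}

#' Fitch parsimony root states of a rooted genealogy
#'
#' Bottom-up set operations over a rooted tree whose tips carry non-empty
#' state sets: a binary node takes the intersection of its children's sets
#' when non-empty, else their union. Multifurcating nodes use the
#' generalized rule: the states attaining the maximum count across child
#' sets (which reduces to intersection-else-union for two children). The
#' root set R receives weight w = 1/|R| per member, so the weights of the
#' equally parsimonious ancestral states sum to one per genealogy.
#'
#' @param tree a rooted \code{phylo}.
#' @param tip_states named list (names = tip labels) of non-empty character
#'   vectors.
#' @return list of class \code{"fitch_root"}: \code{states}, \code{n}
#'   (number of equivalent root states), \code{w} (= 1/n).
#' @export
fitch_root_states <- function(tree, tip_states) {
  if (!ape::is.rooted(tree)) stop("rooting error: tree is unrooted",
                                  call. = FALSE)
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss))
    stop("missing tip state(s): ", paste(utils::head(miss, 5L),
                                         collapse = ", "), call. = FALSE)
  sets <- vector("list", ape::Ntip(tree) + tree$Nnode)
  for (i in seq_len(ape::Ntip(tree))) {
    st <- unique(as.character(tip_states[[tree$tip.label[i]]]))
    if (!length(st))
      stop("domain error: empty state set for tip ", tree$tip.label[i],
           call. = FALSE)
    sets[[i]] <- st
  }
  post <- ape::reorder.phylo(tree, "postorder")$edge
  for (node in unique(post[, 1L])) {
    kids <- post[post[, 1L] == node, 2L]
    tab <- table(unlist(sets[kids]))
    sets[[node]] <- sort(names(tab)[tab == max(tab)])
  }
  root <- ape::Ntip(tree) + 1L
  R <- sets[[root]]
  structure(list(states = R, n = length(R), w = 1 / length(R)),
            class = "fitch_root")
}

#' Assemble a tree sample with tip locality characters
#'
#' @param trees a \code{multiPhylo} of rooted genealogies sharing one tip
#'   label set.
#' @param tip_states named list: tip label -> character vector of (pooled)
#'   locality characters.
#' @return object of class \code{"tree_sample"}.
#' @export
tree_sample <- function(trees, tip_states) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  labs <- sort(trees[[1L]]$tip.label)
  same <- vapply(trees, function(tr)
    identical(sort(tr$tip.label), labs), logical(1L))
  if (!all(same))
    stop("trees do not share one tip label set", call. = FALSE)
  if (any(lengths(tip_states[labs]) == 0L) ||
      !all(labs %in% names(tip_states)))
    stop("every tip needs a non-empty character set", call. = FALSE)
  structure(list(trees = trees, tip_states = tip_states,
                 characters = sort(unique(unlist(tip_states[labs])))),
            class = "tree_sample")
}

#' Relative probability scores of ancestral localities
#'
#' For every genealogy, the Fitch root states receive weight w = 1/n each;
#' the relative probability score of a pooled locality character is 100
#' times the sum of its weights across trees divided by the number of
#' trees. Scores cover all characters (zeros included) and sum to 100.
#'
#' @param sample a \code{\link{tree_sample}}.
#' @return data.frame of class \code{"rps_result"} with columns
#'   \code{character} and \code{rps}, sorted by decreasing score; attribute
#'   \code{n_trees}.
#' @export
rps_scores <- function(sample) {
  stopifnot(inherits(sample, "tree_sample"))
  acc <- stats::setNames(numeric(length(sample$characters)),
                         sample$characters)
  for (tr in sample$trees) {
    fr <- fitch_root_states(tr, sample$tip_states)
    acc[fr$states] <- acc[fr$states] + fr$w
  }
  out <- data.frame(character = names(acc),
                    rps = 100 * as.numeric(acc) / length(sample$trees),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rps, out$character), ]
  rownames(out) <- NULL
  attr(out, "n_trees") <- length(sample$trees)
  class(out) <- c("rps_result", "data.frame")
  out
}

#' Harmonic-mean estimator of the log marginal likelihood
#'
#' \eqn{\log \hat{m} = -(\mathrm{logsumexp}(-\ell_i) - \log N)} over a
#' trace of sampled log likelihoods (burn-in already removed), evaluated
#' stably in log space.
#'
#' @param trace numeric vector of log-likelihood samples (length >= 2).
#' @return log marginal-likelihood estimate (natural log).
#' @export
harmonic_mean_log_ml <- function(trace) {
  if (length(trace) < 2L)
    stop("domain error: need at least 2 log-likelihood samples",
         call. = FALSE)
  neg <- -trace
  m <- max(neg)
  -(m + log(sum(exp(neg - m))) - log(length(trace)))
}

#' Bayes factor on the decimal-log scale with a qualitative call
#'
#' log10 BF between two models' log marginal likelihoods (natural-log
#' inputs), graded on the conventional scale: |log BF| in (1/2, 1] is
#' substantial, (1, 2] strong and > 2 decisive evidence; smaller values
#' warrant no call. The sign indicates the favored model.
#'
#' @param logml_A,logml_B natural-log marginal-likelihood estimates.
#' @return list of class \code{"bf_result"}: \code{log_bf} (log10),
#'   \code{favored} (\code{"A"}, \code{"B"} or \code{"neither"}),
#'   \code{call}.
#' @export
bayes_factor <- function(logml_A, logml_B) {
  stopifnot(is.finite(logml_A), is.finite(logml_B))
  lbf <- (logml_A - logml_B) / log(10)
  a <- abs(lbf)
  call <- if (a > 2) "decisive" else if (a > 1) "strong" else
    if (a > 0.5) "substantial" else "none"
  structure(list(log_bf = lbf,
                 favored = if (lbf > 0) "A" else if (lbf < 0) "B" else
                   "neither",
                 call = call),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat("log10 BF =", formatC(x$log_bf, digits = 4), "->", x$call,
      "evidence", if (x$favored != "neither")
        paste0("for model ", x$favored) else "", "\n")
  invisible(x)
}
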