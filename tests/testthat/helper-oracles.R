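# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (brute force, enumeration or closed form) kept separate from
# the package's own computation path.

# random gap-free alignment
random_alignment <- function(n, L, bases = c("A", "C", "G", "T")) {
  alignment(paste0("s", seq_len(n)),
            apply(matrix(sample(bases, n * L, replace = TRUE), n, L), 1,
                  paste, collapse = ""))
}

# --- Tajima's D, formula-by-formula from site frequencies -------------------
oracle_tajimas_d <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "")), nrow = aln$n, byrow = TRUE)
  keep <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  S <- 0L; kbar <- 0
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) > 1L) {
      S <- S + 1L
      cnt <- as.numeric(tab)
      kbar <- kbar + (sum(cnt)^2 - sum(cnt^2)) / 2
    }
  }
  kbar <- kbar / choose(n, 2)
  if (S == 0L) return(NA_real_)
  i <- 1:(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- brute-force pi under pairwise deletion ---------------------------------
oracle_pi <- function(aln) {
  m <- matrix(unlist(strsplit(aln$seqs, "")), nrow = aln$n, byrow = TRUE)
  acc <- c(); n <- nrow(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- 0L; v <- 0L
    for (s in seq_len(ncol(m))) {
      if (m[i, s] %in% c("A", "C", "G", "T") &&
          m[j, s] %in% c("A", "C", "G", "T")) {
        v <- v + 1L
        if (m[i, s] != m[j, s]) d <- d + 1L
      }
    }
    if (v > 0L) acc <- c(acc, d / v)
  }
  mean(acc)
}

# --- connection limit: literal transcription of the closed form -------------
oracle_connection_limit <- function(L, confidence = 0.95) {
  # P_j = (L-1)! / ((L-j)! * L^(j-1)); largest j with P_j > confidence
  pj <- function(j) exp(lgamma(L) - lgamma(L - j + 1) - (j - 1) * log(L))
  j <- 1
  while (pj(j + 1) > confidence) j <- j + 1
  j
}

# --- enumeration of all rooted binary labeled topologies --------------------
# representation: parent integer vector indexed by node id; tips are 1..n,
# internals n+1 .. 2n-1 (ids unique within a tree, not contiguous during
# construction); root has parent NA
enumerate_rooted_trees <- function(n) {
  stopifnot(n >= 2, n <= 7)
  root0 <- n + 1L
  base <- list(parent = rep(NA_integer_, 2L * n - 1L), root = root0,
               n = n, next_id = root0 + 1L)
  base$parent[1L] <- root0; base$parent[2L] <- root0
  base$used <- c(1L, 2L, root0)
  trees <- list(base)
  if (n == 2L) return(trees)
  for (tip in 3:n) {
    out <- vector("list", 0L)
    for (tr in trees) {
      non_root <- setdiff(tr$used, tr$root)
      for (v in non_root) { # attach on edge (parent[v], v)
        t2 <- tr
        x <- t2$next_id; t2$next_id <- x + 1L
        t2$parent[x] <- t2$parent[v]
        t2$parent[v] <- x
        t2$parent[tip] <- x
        t2$used <- c(t2$used, tip, x)
        out[[length(out) + 1L]] <- t2
      }
      t2 <- tr # attach above the root
      x <- t2$next_id; t2$next_id <- x + 1L
      t2$parent[t2$root] <- x
      t2$parent[tip] <- x
      t2$root <- x
      t2$used <- c(t2$used, tip, x)
      out[[length(out) + 1L]] <- t2
    }
    trees <- out
  }
  trees
}

# convert the parent-vector representation to an ape phylo
tree_to_phylo <- function(tr) {
  n <- tr$n
  internals <- sort(setdiff(tr$used, 1:n))
  # relabel internals: root becomes n+1, rest follow in BFS order
  newid <- integer(max(tr$used))
  newid[1:n] <- 1:n
  queue <- tr$root; nexti <- n + 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    newid[v] <- nexti; nexti <- nexti + 1L
    kids <- intersect(which(tr$parent == v), internals)
    queue <- c(queue, kids)
  }
  non_root <- setdiff(tr$used, tr$root)
  edge <- cbind(newid[tr$parent[non_root]], newid[non_root])
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, tip.label = paste0("t", 1:n),
                 Nnode = n - 1L), class = "phylo")
}

# exhaustive minimal-change labeling enumeration: set of root states over
# all most parsimonious full labelings (tips may be set-valued)
oracle_fitch_roots <- function(tr, tip_sets, states) {
  n <- tr$n
  internals <- sort(setdiff(tr$used, 1:n))
  choices <- c(tip_sets, rep(list(states), length(internals)))
  names(choices) <- as.character(c(1:n, internals))
  grid <- expand.grid(choices, stringsAsFactors = FALSE)
  non_root <- setdiff(tr$used, tr$root)
  cost <- rep(0L, nrow(grid))
  for (v in non_root) {
    cost <- cost + (grid[[as.character(tr$parent[v])]] !=
                      grid[[as.character(v)]])
  }
  sort(unique(grid[[as.character(tr$root)]][cost == min(cost)]))
}

# --- union of all minimum spanning trees via Prufer enumeration -------------
# dm: symmetric distance matrix over k labeled nodes; returns sorted edge
# keys "i-j" (i < j)
oracle_msn_edges <- function(dm) {
  k <- nrow(dm)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")
  if (k == 2L) return(key(1, 2))
  prufer_decode <- function(s) {
    deg <- rep(1L, k)
    for (x in s) deg[x] <- deg[x] + 1L
    edges <- matrix(0L, k - 1L, 2L)
    for (e in seq_along(s)) {
      leaf <- which(deg == 1L)[1L]
      edges[e, ] <- c(leaf, s[e])
      deg[leaf] <- 0L
      deg[s[e]] <- deg[s[e]] - 1L
    }
    edges[k - 1L, ] <- which(deg == 1L)
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(1:k), k - 2L)))
  best <- Inf; union_edges <- character(0)
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(as.integer(seqs[r, ]))
    w <- sum(dm[ed])
    if (w < best - 1e-9) {
      best <- w
      union_edges <- key(ed[, 1L], ed[, 2L])
    } else if (abs(w - best) < 1e-9) {
      union_edges <- union(union_edges, key(ed[, 1L], ed[, 2L]))
    }
  }
  list(edges = sort(union_edges), weight = best)
}
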