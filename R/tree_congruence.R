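#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering. Each merge joins the pair of
#' clusters at minimal average distance at height d/2 per side, so the
#' output is ultrametric (all root-to-tip path lengths equal). Ties in the
#' minimal distance are broken deterministically by the lexicographically
#' smallest pair of cluster representative labels, which makes the output
#' invariant to input label order.
#'
#' @param dm Labeled symmetric distance matrix (>= 2 labels).
#' @return Rooted binary ultrametric `ape::phylo`.
#' @export
upgma <- function(dm) {
  if (any(is.na(dm)) || any(is.nan(dm))) stop("NaN/NA in distance matrix")
  dm <- as_dist_matrix(dm)
  labels <- rownames(dm)
  n <- length(labels)
  stopifnot(n >= 2)
  nwk <- labels          # newick fragment per active cluster
  h <- numeric(n)        # current height of each cluster
  sz <- rep(1L, n)       # cluster sizes
  rep_lab <- labels      # lexicographically smallest member label
  D <- dm
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- D[active, active, drop = FALSE]
    diag(sub) <- Inf
    m <- min(sub)
    # candidate pairs at the minimum; break ties on sorted representative pair
    idx <- which(sub == m, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    keys <- apply(idx, 1, function(p) {
      r <- sort(c(rep_lab[active[p[1]]], rep_lab[active[p[2]]]))
      paste(r, collapse = "\r")
    })
    pick <- idx[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    if (rep_lab[j] < rep_lab[i]) { k <- i; i <- j; j <- k }
    height <- m / 2
    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)",
                       nwk[i], height - h[i], nwk[j], height - h[j])
    # average-linkage update into slot i
    rest <- setdiff(active, c(i, j))
    if (length(rest)) {
      dnew <- (sz[i] * D[i, rest] + sz[j] * D[j, rest]) / (sz[i] + sz[j])
      D[i, rest] <- dnew; D[rest, i] <- dnew
    }
    nwk[i] <- new_nwk
    h[i] <- height
    sz[i] <- sz[i] + sz[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active <- setdiff(active, j)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

# nontrivial unrooted bipartitions of a tree, as canonical string keys.
# A split is represented by the side NOT containing the alphabetically
# first tip, tips sorted and pasted; both sides must have >= 2 tips.
tree_splits <- function(tree, include_trivial = FALSE) {
  tips <- tree$tip.label
  n <- length(tips)
  ord <- sort(tips)
  tree <- stats::reorder(tree, "postorder")
  ntip <- n
  nnode <- ntip + tree$Nnode
  desc <- matrix(FALSE, nnode, n)              # node x (sorted tip index)
  desc[cbind(seq_len(ntip), match(tips, ord))] <- TRUE
  for (e in seq_len(nrow(tree$edge)))
    desc[tree$edge[e, 1], ] <- desc[tree$edge[e, 1], ] | desc[tree$edge[e, 2], ]
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    side <- desc[tree$edge[e, 2], ]
    k <- sum(side)
    if (k == 0 || k == n) next
    if (!include_trivial && (min(k, n - k) < 2)) next
    if (side[1]) side <- !side                 # canonical orientation
    keys <- c(keys, paste(ord[side], collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Trees are read as unrooted and branch lengths are ignored. `rf` is the
#' size of the symmetric difference of the two trees' nontrivial bipartition
#' sets; `nrf = rf / (|splits(t1)| + |splits(t2)|)`, which equals
#' `rf / (2(n-3))` for two binary trees and lies in `[0, 1]`, with 0 meaning
#' the trees share every bipartition (perfect congruence). Multifurcating
#' inputs are allowed; the normalization then uses the actual split counts.
#'
#' @param t1,t2 `ape::phylo` trees on identical tip label sets, >= 4 tips.
#' @return List with elements `rf` (even non-negative integer) and `nrf`.
#' @export
robinson_foulds <- function(t1, t2) {
  s1 <- sort(t1$tip.label); s2 <- sort(t2$tip.label)
  if (!identical(s1, s2))
    stop("tip sets differ: only in t1 {",
         paste(setdiff(s1, s2), collapse = ","), "}, only in t2 {",
         paste(setdiff(s2, s1), collapse = ","), "}")
  if (length(s1) < 4) stop("Robinson-Foulds requires >= 4 tips")
  a <- tree_splits(t1)
  b <- tree_splits(t2)
  rf <- length(setdiff(a, b)) + length(setdiff(b, a))
  denom <- length(a) + length(b)
  list(rf = rf, nrf = if (denom == 0) 0 else rf / denom)
}

#' Uniform random unrooted binary topology
#'
#' Draws uniformly over the `(2n-5)!!` unrooted binary labeled topologies
#' by sequential random leaf insertion: starting from the 3-leaf star, leaf
#' k is attached to one of the current `2k-5` edges chosen uniformly. All
#' branch lengths are 1. This is the conservative null for topology-based
#' congruence testing.
#'
#' @param labels Character vector of >= 4 tip labels.
#' @param seed Integer seed.
#' @return Unrooted binary `ape::phylo` with unit branch lengths.
#' @export
random_topology <- function(labels, seed) {
  labels <- sort(unique(as.character(labels)))
  n <- length(labels)
  stopifnot(n >= 4)
  with_seed(seed, {
    edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE)
    nextnode <- n + 2L
    for (k in 4:n) {
      e <- sample.int(nrow(edges), 1)
      v <- edges[e, 2]
      w <- nextnode; nextnode <- nextnode + 1L
      edges[e, 2] <- w
      edges <- rbind(edges, c(w, v), c(w, k))
    }
    tr <- list(edge = edges, tip.label = labels, Nnode = n - 2L,
               edge.length = rep(1, nrow(edges)))
    class(tr) <- "phylo"
    stats::reorder(tr, "cladewise")
  })
}

#' Annotate a dendrogram with bootstrap support
#'
#' For each internal node of `reference`, the support is the fraction of
#' `replicate_trees` containing that node's bipartition (matched as
#' unrooted splits, so replicate rooting is irrelevant). Replicates are
#' typically the per-iteration dendrograms from [beta_rarefaction()].
#'
#' @param replicate_trees List of `ape::phylo` sharing the reference tip set.
#' @param reference Rooted reference dendrogram.
#' @return `reference` with `node.label` set to supports (root blank);
#'   attribute `"support"` holds the numeric vector.
#' @export
bootstrap_support <- function(replicate_trees, reference) {
  ref_tips <- sort(reference$tip.label)
  for (t in replicate_trees)
    if (!identical(sort(t$tip.label), ref_tips))
      stop("replicate tip set differs from reference")
  rep_splits <- lapply(replicate_trees, tree_splits, include_trivial = TRUE)
  n <- length(ref_tips)
  ntip <- length(reference$tip.label)
  tree <- stats::reorder(reference, "postorder")
  nnode <- ntip + tree$Nnode
  desc <- matrix(FALSE, nnode, n)
  desc[cbind(seq_len(ntip), match(tree$tip.label, ref_tips))] <- TRUE
  for (e in seq_len(nrow(tree$edge)))
    desc[tree$edge[e, 1], ] <- desc[tree$edge[e, 1], ] | desc[tree$edge[e, 2], ]
  support <- rep(NA_real_, tree$Nnode)
  for (node in (ntip + 1):nnode) {
    side <- desc[node, ]
    k <- sum(side)
    if (k == n) next                          # root clade: support undefined
    if (side[1]) side <- !side
    key <- paste(ref_tips[side], collapse = "|")
    support[node - ntip] <- mean(vapply(rep_splits, function(s) key %in% s,
                                        logical(1)))
  }
  out <- reference
  out$node.label <- ifelse(is.na(support), "", format(support, trim = TRUE))
  attr(out, "support") <- support
  out
}

#' Monte-Carlo congruence test for phylosymbiosis
#'
#' Compares the observed Robinson-Foulds distance between a host phylogeny
#' and a microbial community dendrogram against the RF distances between the
#' host phylogeny and `n_random` uniform random topologies on the same tips.
#' The add-one p-value `(1 + #{null RF <= observed RF}) / (1 + n_random)` is
#' small when the dendrogram is *more congruent* with the host tree than
#' random trees are -- the standard one-sided phylosymbiosis test. The
#' `"opposite"` tail (counting null RF >= observed) is exposed for
#' completeness but is not the phylosymbiosis direction.
#'
#' @param host_tree Host phylogeny (`ape::phylo`).
#' @param dendrogram Community dendrogram on the same tip set.
#' @param n_random Number of random topologies (default 100000; scale down
#'   for interactive use).
#' @param seed Integer seed.
#' @param tail `"congruent"` (default) or `"opposite"`.
#' @return Object of class `congruence_result`: `rf`, `nrf`, `p_value`,
#'   `n_random`, `seed`, `tail`, and `null_rf_distribution` (a table).
#' @export
congruence_test <- function(host_tree, dendrogram, n_random = 100000, seed,
                            tail = c("congruent", "opposite")) {
  tail <- match.arg(tail)
  stopifnot(n_random >= 1)
  obs <- robinson_foulds(host_tree, dendrogram)
  labels <- host_tree$tip.label
  null_rf <- integer(n_random)
  for (i in seq_len(n_random)) {
    rt <- random_topology(labels, seed = child_seed(seed, i))
    null_rf[i] <- robinson_foulds(host_tree, rt)$rf
  }
  k <- if (tail == "congruent") sum(null_rf <= obs$rf) else sum(null_rf >= obs$rf)
  structure(list(rf = obs$rf, nrf = obs$nrf,
                 p_value = (1 + k) / (1 + n_random),
                 n_random = n_random, seed = seed, tail = tail,
                 null_rf_distribution = table(null_rf)),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("congruence test: RF = %d, nRF = %.4f, p = %.4g (%d random trees, %s tail)\n",
              x$rf, x$nrf, x$p_value, x$n_random, x$tail))
  invisible(x)
}
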