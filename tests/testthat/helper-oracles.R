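# Independent brute-force oracles. These deliberately use a different
# mechanism from the package (graph-component enumeration instead of
# postorder descendant accumulation) so the two routes stay independent.

# tips on the child side of each edge, found by deleting the edge and
# flooding the remaining adjacency from the child node
edge_tipsets <- function(tree) {
  edges <- tree$edge
  n <- length(tree$tip.label)
  lapply(seq_len(nrow(edges)), function(e) {
    adj <- edges[-e, , drop = FALSE]
    comp <- edges[e, 2]
    repeat {
      nb <- c(adj[adj[, 1] %in% comp, 2], adj[adj[, 2] %in% comp, 1])
      new <- setdiff(nb, comp)
      if (!length(new)) break
      comp <- c(comp, new)
    }
    sort(tree$tip.label[comp[comp <= n]])
  })
}

oracle_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  keys <- vapply(edge_tipsets(tree), function(side) {
    k <- length(side)
    if (k < 2 || k > n - 2) return(NA_character_)
    if (tips[1] %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

oracle_rf <- function(t1, t2) {
  a <- oracle_splits(t1); b <- oracle_splits(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# brute-force UniFrac between two count vectors named by tip label
oracle_unifrac <- function(x, y, tree, weighted = FALSE, normalized = FALSE) {
  sets <- edge_tipsets(tree)
  lens <- tree$edge.length
  xa <- vapply(sets, function(s) sum(x[s]), numeric(1))
  ya <- vapply(sets, function(s) sum(y[s]), numeric(1))
  if (weighted) {
    pa <- xa / sum(x); pb <- ya / sum(y)
    num <- sum(lens * abs(pa - pb))
    if (!normalized) return(num)
    den <- sum(lens * (pa + pb))
    return(if (den == 0) 0 else num / den)
  }
  pres_a <- xa > 0; pres_b <- ya > 0
  either <- pres_a | pres_b
  tot <- sum(lens[either])
  if (tot == 0) return(0)
  sum(lens[xor(pres_a, pres_b)]) / tot
}

# exhaustive enumeration of all unrooted binary topologies on labels,
# by exploring every edge choice of sequential leaf insertion
enum_topologies <- function(labels) {
  labels <- sort(labels)
  n <- length(labels)
  res <- list()
  recur <- function(edges, nextnode, k) {
    if (k > n) {
      tr <- list(edge = edges, tip.label = labels, Nnode = n - 2L,
                 edge.length = rep(1, nrow(edges)))
      class(tr) <- "phylo"
      res[[length(res) + 1L]] <<- stats::reorder(tr, "cladewise")
      return(invisible(NULL))
    }
    for (e in seq_len(nrow(edges))) {
      ed <- edges
      v <- ed[e, 2]
      ed[e, 2] <- nextnode
      ed <- rbind(ed, c(nextnode, v), c(nextnode, k))
      recur(ed, nextnode + 1L, k + 1L)
    }
  }
  recur(matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2, byrow = TRUE),
        n + 2L, 4L)
  res
}

# canonical topology key for counting distinct topologies
topo_key <- function(tree) paste(sort(oracle_splits(tree)), collapse = "#")

# random feature table fixture
random_table <- function(n_samples, n_features, seed, max_count = 50,
                         hosts = NULL) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_features, max_count / 5), n_samples,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  feature_table(m, hosts)
}

# random rooted tree over given tip labels with positive branch lengths
random_feature_tree <- function(labels, seed) {
  set.seed(seed)
  tr <- ape::rtree(length(labels), tip.label = sample(labels))
  tr
}

mean_silhouette <- function(dm, groups) {
  groups <- groups[rownames(dm)]
  s <- vapply(rownames(dm), function(i) {
    own <- groups[i]
    a <- mean(dm[i, setdiff(names(groups)[groups == own], i)])
    if (is.nan(a)) return(NA_real_)
    b <- min(vapply(setdiff(unique(groups), own), function(g)
      mean(dm[i, names(groups)[groups == g]]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)  # no separation at all
  }, numeric(1))
  mean(s, na.rm = TRUE)
}

spearman_lower <- function(a, b) {
  stats::cor(a[lower.tri(a)], b[lower.tri(b)], method = "spearman")
}
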