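#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over feature counts.
#' Abundance-aware and phylogeny-blind. A pair of all-zero samples is
#' defined to have distance 0 (and is logged via a warning).
#'
#' @param table A `feature_table` with at least 2 samples.
#' @return Labeled symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  x <- table$counts
  stopifnot(nrow(x) >= 2)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- sum(x[i, ] + x[j, ])
    if (denom == 0) {
      warning("both samples all-zero (", rownames(x)[i], ", ", rownames(x)[j],
              "); Bray-Curtis defined as 0")
      d[i, j] <- d[j, i] <- 0
    } else {
      d[i, j] <- d[j, i] <- sum(abs(x[i, ] - x[j, ])) / denom
    }
  }
  d
}

# per-edge descendant mass for every sample: returns list(edge_len, mass)
# where mass is samples x edges, mass[s, e] = reads of sample s on tips
# below edge e. Tree is midpoint-rooted if unrooted (rooting is logged).
unifrac_prep <- function(table, tree) {
  x <- table$counts
  present_feats <- colnames(x)[colSums(x) > 0]
  missing <- setdiff(present_feats, tree$tip.label)
  if (length(missing))
    stop("features absent from tree: ", paste(missing, collapse = ", "))
  if (!ape::is.rooted(tree)) {
    tree <- phangorn::midpoint(tree)
    message("unrooted input tree midpoint-rooted for UniFrac")
  }
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  # node mass accumulation in postorder
  mass <- matrix(0, nrow(x), nnode)
  tip_counts <- matrix(0, nrow(x), ntip)
  shared <- intersect(tree$tip.label, colnames(x))
  tip_counts[, match(shared, tree$tip.label)] <- x[, shared, drop = FALSE]
  mass[, seq_len(ntip)] <- tip_counts
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    mass[, par] <- mass[, par] + mass[, ch]
  }
  list(edge_len = tree$edge.length,
       edge_mass = mass[, tree$edge[, 2], drop = FALSE],
       labels = rownames(x))
}

#' Unweighted UniFrac distance matrix
#'
#' For each pair of samples, the fraction of tree branch length leading
#' only to tips present (count > 0) in exactly one of the two samples,
#' over the branch length leading to tips present in either. Branches with
#' no present descendants in either sample enter neither sum. Because every
#' branch counts equally regardless of abundance, rare shallow-branch taxa
#' dominate this metric.
#'
#' @param table A `feature_table`; every feature with nonzero counts must be
#'   a tip of `tree`.
#' @param tree An `ape::phylo` over the features; midpoint-rooted if given
#'   unrooted.
#' @return Labeled symmetric matrix, values in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  prep <- unifrac_prep(table, tree)
  pres <- prep$edge_mass > 0
  l <- prep$edge_len
  n <- length(prep$labels)
  d <- matrix(0, n, n, dimnames = list(prep$labels, prep$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    either <- pres[i, ] | pres[j, ]
    one <- xor(pres[i, ], pres[j, ])
    tot <- sum(l[either])
    d[i, j] <- d[j, i] <- if (tot == 0) 0 else sum(l[one]) / tot
  }
  d
}

#' Weighted UniFrac distance matrix
#'
#' Raw weighted UniFrac is `sum_b l_b * |p_A(b) - p_B(b)|` where `p_S(b)` is
#' the fraction of sample S's reads on tips below branch b. The normalized
#' variant divides by `sum_b l_b * (p_A(b) + p_B(b))`, bounding values to
#' `[0, 1]`. The default is un-normalized, matching the convention of the
#' standard amplicon pipelines.
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the attainable maximum (default `FALSE`).
#' @return Labeled symmetric matrix.
#' @export
weighted_unifrac <- function(table, tree, normalized = FALSE) {
  tot <- sample_depths(table)
  if (any(tot == 0))
    stop("zero-total samples: ",
         paste(rownames(table$counts)[tot == 0], collapse = ", "))
  prep <- unifrac_prep(table, tree)
  p <- prep$edge_mass / tot
  l <- prep$edge_len
  n <- length(prep$labels)
  d <- matrix(0, n, n, dimnames = list(prep$labels, prep$labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    num <- sum(l * abs(p[i, ] - p[j, ]))
    if (normalized) {
      den <- sum(l * (p[i, ] + p[j, ]))
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    } else {
      d[i, j] <- d[j, i] <- num
    }
  }
  d
}

#' Rarefaction-replicated beta diversity
#'
#' Repeats (rarefy to `depth`, compute metric) `iterations` times with
#' per-iteration seeds derived from `seed`, and returns the element-wise
#' mean distance matrix plus the per-iteration matrices. The iteration set
#' doubles as the bootstrap replicate set for dendrogram support.
#'
#' @param table A `feature_table`.
#' @param metric One of `"braycurtis"`, `"uu"` (unweighted UniFrac), `"wu"`
#'   (raw weighted), `"wun"` (normalized weighted).
#' @param tree Feature tree, required for the UniFrac metrics.
#' @param depth Rarefaction depth (default 1000 reads).
#' @param iterations Number of rarefaction replicates (>= 1).
#' @param seed Integer seed.
#' @return List with `mean` (matrix) and `iterations` (list of matrices).
#' @export
beta_rarefaction <- function(table, metric = c("braycurtis", "uu", "wu", "wun"),
                             tree = NULL, depth = 1000, iterations = 10, seed) {
  metric <- match.arg(metric)
  stopifnot(iterations >= 1)
  if (metric != "braycurtis" && is.null(tree))
    stop("UniFrac metrics require a feature tree")
  mats <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    r <- rarefy(table, depth = depth, seed = child_seed(seed, i))
    mats[[i]] <- switch(metric,
      braycurtis = bray_curtis(r),
      uu = unweighted_unifrac(r, tree),
      wu = weighted_unifrac(r, tree, normalized = FALSE),
      wun = weighted_unifrac(r, tree, normalized = TRUE))
  }
  list(mean = Reduce(`+`, mats) / iterations, iterations = mats)
}
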