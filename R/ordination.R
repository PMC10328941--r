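#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' eigenvalues, ordered by decreasing eigenvalue; axes with non-positive
#' eigenvalues are dropped and the total dropped magnitude is recorded
#' (no Cailliez/Lingoes correction is applied). When the input matrix is
#' Euclidean-embeddable, pairwise Euclidean distances over all retained
#' axes reproduce the input exactly.
#'
#' @param dm Labeled symmetric distance matrix, >= 3 samples.
#' @param n_axes Optional cap on the number of axes returned.
#' @return Object of class `pcoa_ordination`: `coordinates` (samples x
#'   axes), `eigenvalues` (positive, descending), `proportion_explained`,
#'   `negative_eigenvalue_magnitude`, `sample_ids`.
#' @export
pcoa <- function(dm, n_axes = NULL) {
  dm <- as_dist_matrix(dm)
  n <- nrow(dm)
  stopifnot(n >= 3)
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  if (sum(pos) < 1)
    stop("no positive eigenvalues; the matrix carries no metric structure")
  vals <- e$values[pos]
  vecs <- e$vectors[, pos, drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), `*`)
  if (!is.null(n_axes)) {
    k <- min(n_axes, ncol(coords))
    coords <- coords[, seq_len(k), drop = FALSE]
    vals_kept <- vals[seq_len(k)]
  } else vals_kept <- vals
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = vals_kept,
                 proportion_explained = vals_kept / sum(vals),
                 negative_eigenvalue_magnitude = sum(abs(e$values[e$values < -tol])),
                 sample_ids = rownames(dm)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes; first axes explain %s\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained, 3)),
                    collapse = ", ")))
  invisible(x)
}

coords_of <- function(ord) {
  if (inherits(ord, "pcoa_ordination")) ord$coordinates else as.matrix(ord)
}

# center and scale a configuration to unit total sum of squares
procrustes_normalize <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  ss <- sum(X^2)
  if (ss == 0) stop("degenerate configuration: all points identical")
  X / sqrt(ss)
}

#' Symmetric Procrustes superimposition of two ordinations
#'
#' Both configurations are aligned by shared sample IDs, truncated to
#' `k_axes` (default: the smaller positive-axis count), centered, and
#' scaled to unit total sum of squares; the optimal orthogonal rotation
#' (reflections allowed) comes from the SVD of the cross-product. The
#' residual is `m2 = 1 - (sum of singular values)^2` and the Procrustes
#' correlation is `r = sqrt(1 - m2)`, symmetric in its two arguments.
#'
#' @param ord1,ord2 `pcoa_ordination` objects or coordinate matrices with
#'   row names; at least 3 shared samples required.
#' @param k_axes Number of axes used for the superimposition.
#' @return Object of class `procrustes_result`: `m2`, `r`, `k_axes`,
#'   `n_shared`; `p_value` is `NA` (see [protest()]).
#' @export
procrustes <- function(ord1, ord2, k_axes = NULL) {
  X <- coords_of(ord1); Y <- coords_of(ord2)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 3)
    stop("fewer than 3 shared samples between ordinations")
  k <- k_axes %||% min(ncol(X), ncol(Y))
  k <- min(k, ncol(X), ncol(Y))
  X <- procrustes_normalize(X[shared, seq_len(k), drop = FALSE])
  Y <- procrustes_normalize(Y[shared, seq_len(k), drop = FALSE])
  sv <- svd(crossprod(X, Y))$d
  m2 <- max(0, 1 - sum(sv)^2)
  structure(list(m2 = m2, r = sqrt(1 - m2), k_axes = k,
                 n_shared = length(shared), p_value = NA_real_,
                 n_permutations = 0L, seed = NA_integer_),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4f, r = %.4f (%d samples, %d axes)",
              x$m2, x$r, x$n_shared, x$k_axes))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' PROTEST: Procrustes permutation test
#'
#' Tests the observed Procrustes correlation `r` against a null built by
#' re-running the superimposition with the rows (samples) of the second
#' configuration randomly permuted. The add-one p-value is
#' `(1 + #{r_i >= r_obs}) / (1 + n_permutations)`.
#'
#' @inheritParams procrustes
#' @param n_permutations Number of row permutations (default 100000; scale
#'   down for interactive use).
#' @param seed Integer seed.
#' @return `procrustes_result` with `p_value` filled in.
#' @export
protest <- function(ord1, ord2, k_axes = NULL, n_permutations = 100000, seed) {
  stopifnot(n_permutations >= 1)
  X <- coords_of(ord1); Y <- coords_of(ord2)
  shared <- intersect(rownames(X), rownames(Y))
  if (length(shared) < 3)
    stop("fewer than 3 shared samples between ordinations")
  k <- k_axes %||% min(ncol(X), ncol(Y))
  k <- min(k, ncol(X), ncol(Y))
  Xn <- procrustes_normalize(X[shared, seq_len(k), drop = FALSE])
  Yn <- procrustes_normalize(Y[shared, seq_len(k), drop = FALSE])
  r_of <- function(A, B) {
    sv <- svd(crossprod(A, B))$d
    sqrt(max(0, 1 - max(0, 1 - sum(sv)^2)))   # = min(sum(sv), 1)
  }
  r_obs <- r_of(Xn, Yn)
  m <- length(shared)
  count <- 0L
  with_seed(seed, {
    for (i in seq_len(n_permutations)) {
      perm <- sample.int(m)
      # re-center after permutation is unnecessary (row permutation of a
      # centered configuration stays centered); rotation re-optimized
      if (r_of(Xn, Yn[perm, , drop = FALSE]) >= r_obs) count <- count + 1L
    }
  })
  structure(list(m2 = 1 - r_obs^2, r = r_obs, k_axes = k, n_shared = m,
                 p_value = (1 + count) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "procrustes_result")
}

#' Write an ordination as TSV plus eigenvalue JSON
#' @param ord A `pcoa_ordination`.
#' @param path Output TSV path; eigenvalues go to `<path>.eigen.json`.
#' @export
write_ordination_tsv <- function(ord, path) {
  df <- data.frame(sample = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(eigenvalues = ord$eigenvalues,
                            proportion_explained = ord$proportion_explained,
                            negative_eigenvalue_magnitude =
                              ord$negative_eigenvalue_magnitude),
                       paste0(path, ".eigen.json"), digits = NA)
  invisible(path)
}

#' @rdname write_ordination_tsv
#' @return `read_ordination_tsv`: coordinate matrix with sample row names.
#' @export
read_ordination_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
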