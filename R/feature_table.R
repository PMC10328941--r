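#' Construct a feature table
#'
#' A feature table is the unit of data exchanged by the pipeline: a samples x
#' features matrix of non-negative integer read counts, plus per-sample host
#' metadata and a provenance log that records every transformation applied.
#'
#' @param counts Integer matrix, samples in rows, features in columns. Both
#'   dimensions must carry unique names.
#' @param sample_meta Named character vector mapping sample IDs to host
#'   labels. Optional; defaults to each sample being its own host.
#' @param provenance List of provenance records; used internally when an
#'   operation derives one table from another.
#' @return An object of class `feature_table` with elements `counts`,
#'   `sample_meta`, `provenance`.
#' @examples
#' m <- matrix(c(3L, 2L, 0L, 5L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' ft <- feature_table(m, c(s1 = "horse", s2 = "horse"))
#' sample_depths(ft)
#' @export
feature_table <- function(counts, sample_meta = NULL, provenance = list()) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample (row) and feature (column) names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate feature IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(sample_meta)) {
    sample_meta <- stats::setNames(rownames(counts), rownames(counts))
  } else {
    missing <- setdiff(rownames(counts), names(sample_meta))
    if (length(missing))
      stop("samples without host metadata: ", paste(missing, collapse = ", "))
    sample_meta <- sample_meta[rownames(counts)]
  }
  structure(list(counts = counts,
                 sample_meta = sample_meta,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(as.numeric(x$counts))))
  cat(sprintf("hosts: %s\n", paste(unique(x$sample_meta), collapse = ", ")))
  if (length(x$provenance))
    cat("provenance:", paste(vapply(x$provenance, `[[`, "", "op"),
                             collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Per-sample total read counts
#' @param table A `feature_table`.
#' @return Named numeric vector of sample depths.
#' @export
sample_depths <- function(table) {
  rowSums(table$counts)
}

log_provenance <- function(table, op, ...) {
  table$provenance <- c(table$provenance, list(c(list(op = op), list(...))))
  table
}

#' Remove samples below a minimum sequencing depth
#'
#' Samples with *fewer than* `min_reads` total reads are removed; a sample
#' with exactly `min_reads` reads is kept. The default of 1000 reads is the
#' cutoff used to guard dendrograms and ordinations against shallow samples.
#' Feature columns that become all-zero are retained by default so that
#' table dimensions stay predictable across parallel datasets.
#'
#' @param table A `feature_table`.
#' @param min_reads Minimum total reads for a sample to be kept (default 1000).
#' @param drop_empty If `TRUE`, drop features that are all-zero afterwards.
#' @return Filtered `feature_table`; provenance records the retained-read
#'   fraction.
#' @export
filter_samples_min_depth <- function(table, min_reads = 1000, drop_empty = FALSE) {
  stopifnot(min_reads >= 0)
  depths <- sample_depths(table)
  keep <- depths >= min_reads
  if (!any(keep)) warning("no samples meet the minimum depth; result is empty")
  counts <- table$counts[keep, , drop = FALSE]
  dropped_features <- character(0)
  if (drop_empty && nrow(counts) > 0) {
    empty <- colSums(counts) == 0
    dropped_features <- colnames(counts)[empty]
    counts <- counts[, !empty, drop = FALSE]
  }
  out <- feature_table(counts, table$sample_meta[keep], table$provenance)
  log_provenance(out, "filter_samples_min_depth",
                 min_reads = min_reads,
                 samples_removed = sum(!keep),
                 samples_kept = sum(keep),
                 reads_kept = sum(as.numeric(counts)),
                 reads_total = sum(as.numeric(table$counts)),
                 retained_fraction = sum(depths[keep]) / sum(depths),
                 dropped_features = dropped_features)
}

#' Collapse samples by group, summing read counts
#'
#' Pools replicate samples (typically all samples of one mammalian host)
#' into a single sample per group by summing ASV counts.
#'
#' @param table A `feature_table`.
#' @param group Named character vector sample ID -> group label. Defaults to
#'   the table's host metadata.
#' @return `feature_table` with one sample per group; the grand total is
#'   conserved exactly.
#' @export
collapse_by_group <- function(table, group = table$sample_meta) {
  unmapped <- setdiff(rownames(table$counts), names(group))
  if (length(unmapped))
    stop("samples without a group label: ", paste(unmapped, collapse = ", "))
  g <- factor(group[rownames(table$counts)])
  counts <- rowsum(table$counts, g)
  storage.mode(counts) <- "integer"
  meta <- stats::setNames(rownames(counts), rownames(counts))
  out <- feature_table(counts, meta, table$provenance)
  log_provenance(out, "collapse_by_group", n_groups = nlevels(g))
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads uniformly *without replacement*
#' (multivariate hypergeometric) down to `depth` reads. Samples with fewer
#' than `depth` total reads are dropped.
#'
#' @param table A `feature_table`.
#' @param depth Target depth (reads per sample), default 1000.
#' @param seed Integer seed; rarefaction is reproducible given (table, depth,
#'   seed).
#' @return Rarefied `feature_table`; every remaining row sums to `depth`.
#' @export
rarefy <- function(table, depth = 1000, seed) {
  stopifnot(depth >= 1)
  depths <- sample_depths(table)
  keep <- depths >= depth
  if (!any(keep)) warning("rarefaction dropped every sample")
  counts <- table$counts[keep, , drop = FALSE]
  nf <- ncol(counts)
  with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      row <- counts[i, ]
      if (sum(row) == depth) next
      # without-replacement draw: expand reads to feature indices and sample
      pool <- rep.int(seq_len(nf), row)
      drawn <- pool[sample.int(length(pool), depth)]
      counts[i, ] <- tabulate(drawn, nbins = nf)
    }
  })
  out <- feature_table(counts, table$sample_meta[keep], table$provenance)
  log_provenance(out, "rarefy", depth = depth, seed = seed,
                 samples_dropped = sum(!keep))
}

#' Collapse features by taxonomy at a given rank
#'
#' Features sharing an identical lineage-prefix string through `rank` are
#' summed into a single feature named by that prefix. Lineage strings that
#' differ by any character (for example a trailing "1" disambiguator on a
#' genus name) remain distinct features -- collapsing is purely textual, as
#' in standard amplicon workflows, which is exactly why incompatible
#' taxonomy databases fail to merge at the genus level.
#'
#' @param table A `feature_table`.
#' @param taxonomy A taxonomy map (see [taxonomy_map()]).
#' @param rank One of `"domain","phylum","class","order","family","genus","species"`.
#' @return Collapsed `feature_table`. Features missing from the taxonomy go
#'   into an `"Unassigned"` bucket and are logged in provenance.
#' @export
collapse_taxonomy <- function(table, taxonomy, rank) {
  rank <- match.arg(rank, TAX_RANKS)
  depth <- match(rank, TAX_RANKS)
  fids <- colnames(table$counts)
  known <- fids %in% rownames(taxonomy$lineages)
  labels <- rep("Unassigned", length(fids))
  labels[known] <- lineage_prefix(taxonomy, fids[known], depth)
  counts <- t(rowsum(t(table$counts), labels))
  storage.mode(counts) <- "integer"
  out <- feature_table(counts, table$sample_meta, table$provenance)
  log_provenance(out, "collapse_taxonomy", rank = rank,
                 unassigned_features = fids[!known])
}

#' Mask features below a per-sample relative-abundance threshold
#'
#' Display-oriented filter: per sample, a feature passes when
#' `count / sample_total > threshold` (strict inequality -- a feature at
#' exactly the threshold does not pass). Original counts are preserved; the
#' result carries a logical mask.
#'
#' @param table A `feature_table`.
#' @param threshold Fraction in `[0, 1)`; 0.03 and 0.05 are the
#'   conventional display cutoffs for genus-level bubble plots.
#' @return List with `table` (unchanged counts), `mask` (logical samples x
#'   features matrix) and `threshold`.
#' @export
relative_abundance_filter <- function(table, threshold) {
  stopifnot(threshold >= 0, threshold < 1)
  tot <- sample_depths(table)
  rel <- table$counts / ifelse(tot == 0, 1, tot)
  mask <- rel > threshold & table$counts > 0
  list(table = log_provenance(table, "relative_abundance_filter",
                              threshold = threshold),
       mask = mask, threshold = threshold)
}

#' Subset a table to one taxon and compute within-subset abundances
#'
#' Retains the features whose lineage falls under `taxon` (a lineage-prefix
#' string, e.g. a family). Within-subset relative abundances use the subset
#' total as denominator; the proportion of each sample's reads belonging to
#' the subset is reported alongside. Samples with zero subset reads are
#' dropped from the subset view and logged.
#'
#' @param table A `feature_table`.
#' @param taxonomy A taxonomy map.
#' @param taxon Lineage prefix string (as produced by [lineage_prefix()]), or
#'   a bare rank name such as `"Staphylococcaceae"` which is matched against
#'   individual rank fields.
#' @return List with `table` (subset counts, samples with >0 subset reads),
#'   `within_relabund` (rows sum to 1), `subset_fraction` (subset reads /
#'   sample total, all input samples), and `dropped_samples`.
#' @export
subset_by_taxon <- function(table, taxonomy, taxon) {
  fids <- colnames(table$counts)
  lin <- taxonomy$lineages[fids[fids %in% rownames(taxonomy$lineages)], , drop = FALSE]
  full <- apply(lin, 1, function(r) paste(r[nzchar(r)], collapse = "; "))
  hit <- startsWith(full, taxon) | apply(lin, 1, function(r) taxon %in% r)
  match_ids <- rownames(lin)[hit]
  if (!length(match_ids))
    stop("taxon matches no feature: ", taxon)
  sub <- table$counts[, match_ids, drop = FALSE]
  subset_total <- rowSums(sub)
  sample_total <- sample_depths(table)
  frac <- subset_total / ifelse(sample_total == 0, 1, sample_total)
  keep <- subset_total > 0
  sub_kept <- sub[keep, , drop = FALSE]
  within <- sub_kept / rowSums(sub_kept)
  out <- feature_table(sub_kept, table$sample_meta[keep], table$provenance)
  out <- log_provenance(out, "subset_by_taxon", taxon = taxon,
                        dropped_samples = rownames(table$counts)[!keep])
  list(table = out, within_relabund = within, subset_fraction = frac,
       dropped_samples = rownames(table$counts)[!keep])
}

#' Round half-up to a number of decimal places
#'
#' Printed percentages in reports use conventional half-up rounding (so
#' 97.55 prints as 97.6), not banker's rounding.
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
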