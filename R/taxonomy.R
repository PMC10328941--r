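TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIXES <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")

#' Construct a taxonomy map
#'
#' Maps feature IDs to ranked lineages over the seven standard ranks
#' (domain, phylum, class, order, family, genus, species). An empty string
#' means the rank is unresolved. A resolved rank below an unresolved one is
#' permitted but flagged, since such lineages usually indicate database
#' formatting problems.
#'
#' @param lineages Character matrix or data.frame, rows named by feature ID,
#'   7 columns in rank order; or a named character vector of prefixed
#'   lineage strings (`"k__Bacteria; p__...; s__..."`) which is parsed.
#' @return Object of class `taxonomy_map` with elements `lineages` (character
#'   matrix) and `flagged` (feature IDs with a gap in the lineage).
#' @export
taxonomy_map <- function(lineages) {
  if (is.character(lineages) && is.null(dim(lineages))) {
    mat <- t(vapply(lineages, parse_lineage_string, character(7)))
    rownames(mat) <- names(lineages)
  } else {
    mat <- as.matrix(lineages)
    if (ncol(mat) != 7) stop("lineages must have 7 rank columns")
  }
  colnames(mat) <- TAX_RANKS
  mat[is.na(mat)] <- ""
  gap <- apply(mat, 1, function(r) {
    resolved <- nzchar(r)
    any(resolved & !cumprod(resolved))
  })
  structure(list(lineages = mat, flagged = rownames(mat)[gap]),
            class = "taxonomy_map")
}

#' @export
print.taxonomy_map <- function(x, ...) {
  cat(sprintf("taxonomy_map: %d features", nrow(x$lineages)))
  if (length(x$flagged))
    cat(sprintf(" (%d with lineage gaps)", length(x$flagged)))
  cat("\n")
  invisible(x)
}

parse_lineage_string <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  out <- character(7)
  for (i in seq_along(parts)) {
    if (i > 7) break
    out[i] <- sub(sprintf("^%s", TAX_PREFIXES[i]), "", parts[i])
  }
  out
}

#' Format lineages as prefixed strings
#' @param taxonomy A `taxonomy_map`.
#' @param ids Feature IDs (default all).
#' @return Named character vector of `k__...; p__...; ...` strings.
#' @export
format_lineage <- function(taxonomy, ids = rownames(taxonomy$lineages)) {
  mat <- taxonomy$lineages[ids, , drop = FALSE]
  out <- apply(mat, 1, function(r) paste0(TAX_PREFIXES, r, collapse = "; "))
  stats::setNames(out, ids)
}

# lineage-prefix string through rank index `depth` (1..7), used as the
# collapsed feature name; purely textual so one-character differences persist
lineage_prefix <- function(taxonomy, ids, depth) {
  mat <- taxonomy$lineages[ids, seq_len(depth), drop = FALSE]
  apply(mat, 1, function(r) paste0(TAX_PREFIXES[seq_len(depth)], r, collapse = "; "))
}

#' Harmonize taxonomy lineages across databases
#'
#' Taxonomies sourced from different reference databases disagree in ways
#' that break textual genus-level collapsing: trailing numeric
#' disambiguators (a genus exported as `Corynebacterium1` will not merge
#' with `Corynebacterium`), and higher-rank reclassifications (the same
#' genus filed under class Betaproteobacteria by one database and
#' Gammaproteobacteria by another). The first is fixed mechanically by the
#' digit-strip pass; the second is never resolvable automatically and
#' requires an explicit synonym table supplied by the analyst.
#'
#' @param taxonomy A `taxonomy_map`.
#' @param strip_trailing_digits Strip `[0-9]+` suffixes from rank names
#'   (default `FALSE`).
#' @param synonyms Optional data.frame with columns `from`, `to`; every
#'   occurrence of `from` as a rank name becomes `to`. Cyclic rules are an
#'   error.
#' @return A `taxonomy_map`; attribute `"changes"` is a data.frame logging
#'   (feature, rank, before, after, rule). Applying the same rules twice is
#'   a no-op.
#' @export
harmonize_lineages <- function(taxonomy, strip_trailing_digits = FALSE,
                               synonyms = NULL) {
  mat <- taxonomy$lineages
  changes <- list()
  if (!is.null(synonyms) && nrow(synonyms)) {
    from <- as.character(synonyms$from); to <- as.character(synonyms$to)
    # cycle check: follow each chain of substitutions
    for (s in from) {
      seen <- character(0); cur <- s
      while (cur %in% from) {
        if (cur %in% seen) stop("cyclic synonym rules involving: ", cur)
        seen <- c(seen, cur)
        cur <- to[match(cur, from)]
      }
    }
  }
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    new <- col
    if (strip_trailing_digits)
      new <- sub("[0-9]+$", "", new)
    if (!is.null(synonyms) && nrow(synonyms)) {
      repeat {
        hit <- match(new, as.character(synonyms$from))
        if (all(is.na(hit))) break
        new[!is.na(hit)] <- as.character(synonyms$to)[hit[!is.na(hit)]]
      }
    }
    diff <- which(new != col)
    if (length(diff))
      changes[[length(changes) + 1L]] <- data.frame(
        feature = rownames(mat)[diff], rank = TAX_RANKS[j],
        before = col[diff], after = new[diff],
        rule = ifelse(strip_trailing_digits & sub("[0-9]+$", "", col[diff]) != col[diff],
                      "digit-strip", "synonym"),
        stringsAsFactors = FALSE)
    mat[, j] <- new
  }
  out <- taxonomy_map(mat)
  attr(out, "changes") <- if (length(changes)) do.call(rbind, changes) else
    data.frame(feature = character(0), rank = character(0),
               before = character(0), after = character(0),
               rule = character(0))
  out
}

#' Read / write two-column taxonomy TSV
#'
#' Column 1 is the feature ID, column 2 the prefixed lineage string.
#' @param path File path.
#' @return `read_taxonomy_tsv`: a `taxonomy_map`.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  taxonomy_map(stats::setNames(df[[2]], df[[1]]))
}

#' @rdname read_taxonomy_tsv
#' @param taxonomy A `taxonomy_map` to write.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  df <- data.frame(`Feature ID` = rownames(taxonomy$lineages),
                   Taxon = unname(format_lineage(taxonomy)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
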