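#' Curate a reference sequence database
#'
#' Applies the two curation passes used when assembling a marker-gene
#' reference set from heterogeneous sources: exact-sequence duplicate
#' removal (sequences uppercased and gap-stripped before comparison; the
#' first occurrence is kept) and a minimum-length filter (a sequence of
#' exactly `min_length` nucleotides is kept; only shorter ones are
#' removed). An already-curated database can be merged in afterwards; the
#' merge is a plain concatenation with *no* cross-set deduplication, and
#' the provenance counts satisfy
#' `final = remaining + merged_in`, `remaining = collected -
#' removed_duplicate - removed_short` exactly.
#'
#' @param seqs Named character vector of sequences (IDs unique).
#' @param lineages A `taxonomy_map` over the same IDs.
#' @param min_length Minimum retained length in nucleotides (default 180).
#' @param merge_with Optional second `refdb` to concatenate after curation.
#' @return Object of class `refdb`: `sequences`, `taxonomy`, `provenance`
#'   (named integer vector of curation counts).
#' @export
curate_refdb <- function(seqs, lineages, min_length = 180, merge_with = NULL) {
  stopifnot(min_length >= 1)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids)) stop("sequence IDs must be unique")
  missing <- setdiff(ids, rownames(lineages$lineages))
  if (length(missing))
    stop("sequences without lineages: ", paste(missing, collapse = ", "))
  canon <- gsub("[-.]", "", toupper(seqs))
  dup <- duplicated(canon)
  short <- !dup & nchar(canon) < min_length
  keep <- !dup & !short
  collected <- length(seqs)
  kept_seqs <- stats::setNames(canon[keep], ids[keep])
  prov <- c(collected = collected,
            removed_duplicate = sum(dup),
            removed_short = sum(short),
            remaining = sum(keep),
            merged_in = 0L,
            final = sum(keep))
  tax <- taxonomy_map(lineages$lineages[ids[keep], , drop = FALSE])
  if (!is.null(merge_with)) {
    clash <- intersect(names(kept_seqs), names(merge_with$sequences))
    if (length(clash))
      stop("ID clash on merge: ", paste(utils::head(clash, 5), collapse = ", "))
    kept_seqs <- c(kept_seqs, merge_with$sequences)
    tax <- taxonomy_map(rbind(tax$lineages, merge_with$taxonomy$lineages))
    prov["merged_in"] <- length(merge_with$sequences)
    prov["final"] <- prov["remaining"] + prov["merged_in"]
  }
  structure(list(sequences = kept_seqs, taxonomy = tax, provenance = prov),
            class = "refdb")
}

#' @export
print.refdb <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(paste0("refdb: %d sequences (collected %d, removed %d duplicate",
                     " + %d short, merged in %d)\n"),
              p["final"], p["collected"], p["removed_duplicate"],
              p["removed_short"], p["merged_in"]))
  invisible(x)
}

# distinct k-mers over {A,C,G,T} in a sequence; words containing other
# characters (N, gaps) are skipped
kmer_words <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1)
  words <- substring(seq, starts, starts + k - 1)
  unique(words[!grepl("[^ACGT]", words)])
}

#' Train an RDP-style naive-Bayes k-mer classifier
#'
#' Word-presence model: a "word" is a distinct k-mer of a sequence. For
#' taxon t and word w,
#' `P(w|t) = (m(w,t) + P_w) / (M_t + 1)` with word prior
#' `P_w = (n_w + 0.5) / (N + 1)`, where `m(w,t)` counts taxon-t training
#' sequences containing w, `M_t` is the number of taxon-t sequences, `n_w`
#' counts all training sequences containing w, and N is the total number of
#' training sequences. A read's score for t is the sum of `log P(w|t)` over
#' the read's distinct words; the smoothing keeps every conditional
#' probability strictly inside (0, 1).
#'
#' @param db A `refdb`.
#' @param k Word size, 4..16 (default 8).
#' @return Object of class `nb_classifier`: vocabulary, per-taxon word
#'   presence counts, taxon lineages, `k`.
#' @export
train_classifier <- function(db, k = 8) {
  if (k < 4 || k > 16) stop("k must be in [4, 16]")
  if (any(nchar(db$sequences) < k)) stop("training sequence shorter than k")
  lin <- db$taxonomy$lineages[names(db$sequences), , drop = FALSE]
  taxa <- apply(lin, 1, function(r) paste(r, collapse = ";"))
  utaxa <- sort(unique(taxa))
  if (length(utaxa) < 2) stop("need >= 2 distinct training taxa")
  words_per_seq <- lapply(db$sequences, kmer_words, k = k)
  vocab <- sort(unique(unlist(words_per_seq)))
  N <- length(db$sequences)
  n_w <- integer(length(vocab))
  m <- matrix(0L, length(utaxa), length(vocab),
              dimnames = list(utaxa, NULL))
  for (i in seq_len(N)) {
    idx <- match(words_per_seq[[i]], vocab)
    n_w[idx] <- n_w[idx] + 1L
    ti <- match(taxa[i], utaxa)
    m[ti, idx] <- m[ti, idx] + 1L
  }
  M_t <- as.integer(table(factor(taxa, levels = utaxa)))
  lineage_mat <- do.call(rbind, strsplit(utaxa, ";", fixed = TRUE))
  lineage_mat <- cbind(lineage_mat,
                       matrix("", nrow(lineage_mat), 7 - ncol(lineage_mat)))
  colnames(lineage_mat) <- TAX_RANKS
  rownames(lineage_mat) <- utaxa
  structure(list(k = as.integer(k), vocab = vocab, n_w = n_w, N = N,
                 m = m, M_t = stats::setNames(M_t, utaxa),
                 taxa = utaxa, lineages = lineage_mat),
            class = "nb_classifier")
}

#' Serialize / restore a classifier model as JSON
#' @param model An `nb_classifier`.
#' @param path File path.
#' @export
write_classifier_json <- function(model, path) {
  jsonlite::write_json(list(k = model$k, vocab = model$vocab, n_w = model$n_w,
                            N = model$N, m = as.data.frame(model$m),
                            M_t = as.list(model$M_t), taxa = model$taxa,
                            lineages = as.data.frame(model$lineages)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_json
#' @export
read_classifier_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- as.matrix(x$m); rownames(m) <- x$taxa
  lin <- as.matrix(x$lineages); rownames(lin) <- x$taxa
  structure(list(k = as.integer(x$k), vocab = x$vocab,
                 n_w = as.integer(x$n_w), N = as.integer(x$N),
                 m = m, M_t = stats::setNames(as.integer(unlist(x$M_t)),
                                              names(x$M_t)),
                 taxa = x$taxa, lineages = lin),
            class = "nb_classifier")
}

# log P(w|t) for a set of words (possibly outside the vocabulary):
# returns taxa x words matrix
nb_log_prob <- function(model, words) {
  idx <- match(words, model$vocab)
  hit <- !is.na(idx)
  n_w <- integer(length(words))
  n_w[hit] <- model$n_w[idx[hit]]
  P_w <- (n_w + 0.5) / (model$N + 1)
  mm <- matrix(0L, nrow(model$m), length(words))
  if (any(hit)) mm[, hit] <- model$m[, idx[hit], drop = FALSE]
  log(sweep(mm, 2, P_w, `+`) / (model$M_t + 1))
}

#' Classify reads with bootstrap confidence
#'
#' Each read is assigned to the leaf taxon with the highest naive-Bayes
#' score over its distinct words (ties broken toward the first taxon in
#' sorted order). Confidence follows the standard bootstrap scheme: 100
#' draws of `ceiling(W/8)` words sampled with replacement from the read's W
#' distinct words are each assigned to a leaf taxon, and the confidence at
#' a rank is the fraction of draws whose lineage agrees with the full-read
#' assignment at that rank. The reported lineage is truncated at the
#' deepest rank whose confidence meets `confidence_threshold`, which is how
#' reads end up "unresolved to genus" when a genus has near neighbours in
#' the database. Reads shorter than k (or with no valid words) are returned
#' unclassified.
#'
#' @param model An `nb_classifier`.
#' @param reads Named character vector of reads over `{A,C,G,T,N}`.
#' @param n_bootstrap Bootstrap draws per read (default 100).
#' @param confidence_threshold Minimum per-rank confidence (default 0.8).
#' @param seed Integer seed.
#' @return data.frame with columns `read_id`, `lineage` (prefixed string,
#'   truncated), `taxon` (full-read leaf assignment), per-rank confidence
#'   columns, and `classified`.
#' @export
classify <- function(model, reads, n_bootstrap = 100,
                     confidence_threshold = 0.8, seed) {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  nr <- length(reads)
  conf_mat <- matrix(NA_real_, nr, 7, dimnames = list(ids, TAX_RANKS))
  lineage_out <- character(nr)
  taxon_out <- character(nr)
  classified <- logical(nr)
  leaf_lin <- model$lineages
  with_seed(seed, {
    for (i in seq_len(nr)) {
      words <- kmer_words(toupper(reads[[i]]), model$k)
      W <- length(words)
      if (W == 0) { lineage_out[i] <- ""; next }
      lp <- nb_log_prob(model, words)          # taxa x W
      full_scores <- rowSums(lp)
      best <- which.max(full_scores)           # first max = sorted-order tie-break
      taxon_out[i] <- model$taxa[best]
      nw_draw <- ceiling(W / 8)
      draw_idx <- matrix(sample.int(W, n_bootstrap * nw_draw, replace = TRUE),
                         n_bootstrap, nw_draw)
      agree <- matrix(FALSE, n_bootstrap, 7)
      ref_lin <- leaf_lin[best, ]
      for (b in seq_len(n_bootstrap)) {
        sc <- rowSums(lp[, draw_idx[b, ], drop = FALSE])
        bl <- leaf_lin[which.max(sc), ]
        agree[b, ] <- bl == ref_lin & nzchar(ref_lin)
      }
      conf <- colMeans(agree)
      conf_mat[i, ] <- conf
      ok <- conf >= confidence_threshold & nzchar(ref_lin)
      depth <- if (any(ok)) max(which(cumprod(ok) == 1)) else 0L
      if (depth > 0) {
        trunc_lin <- ref_lin
        trunc_lin[seq_len(7) > depth] <- ""
        lineage_out[i] <- paste0(TAX_PREFIXES, trunc_lin, collapse = "; ")
        classified[i] <- TRUE
      } else lineage_out[i] <- "Unassigned"
    }
  })
  data.frame(read_id = ids, lineage = lineage_out, taxon = taxon_out,
             conf_mat, classified = classified,
             stringsAsFactors = FALSE, check.names = FALSE)
}
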