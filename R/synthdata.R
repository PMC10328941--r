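#' Simulation configuration
#'
#' Bundles the parameters of the synthetic phylosymbiosis world. The
#' defaults emulate the study design this package is built around: 9
#' mammalian hosts, a few replicate skin swabs per host, severely uneven
#' lognormal sequencing depths placing roughly 20% of samples below the
#' 1000-read filter, and a community composition whose similarity between
#' hosts tracks the host phylogeny with strength `signal_s`.
#'
#' @param n_hosts Number of host species (>= 3; default 9).
#' @param samples_per_host Replicate samples per host (default 4).
#' @param n_genera Number of bacterial genera (default 20).
#' @param asvs_per_genus ASVs (species-level features) per genus (default 3).
#' @param signal_s Fraction in `[0, 1]` of latent log-abundance variance
#'   explained by Brownian motion on the host tree; 0 = no phylosymbiosis,
#'   1 = fully host-tracking.
#' @param depth_log_mean,depth_log_sd Lognormal read-depth parameters
#'   (defaults `log(2000)` and 0.85, putting ~20% of samples under 1000
#'   reads so the depth filter is exercised).
#' @param seed Integer seed; identical config + seed reproduces identical
#'   output.
#' @param effect_scale Multiplier on the unit-variance latent field before
#'   the softmax (default 2; controls how strongly composition separates
#'   hosts).
#' @param sample_noise_sd SD of per-sample iid noise on the latent field
#'   (default 0.3).
#' @param base_sd SD of per-feature baseline log-abundance offsets
#'   (default 1; creates a realistic uneven rank-abundance curve).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_hosts = 9, samples_per_host = 4, n_genera = 20,
                       asvs_per_genus = 3, signal_s = 0.5,
                       depth_log_mean = log(2000), depth_log_sd = 0.85,
                       seed = 1, effect_scale = 2, sample_noise_sd = 0.3,
                       base_sd = 1) {
  cfg <- list(n_hosts = n_hosts, samples_per_host = samples_per_host,
              n_genera = n_genera, asvs_per_genus = asvs_per_genus,
              signal_s = signal_s, depth_log_mean = depth_log_mean,
              depth_log_sd = depth_log_sd, seed = seed,
              effect_scale = effect_scale, sample_noise_sd = sample_noise_sd,
              base_sd = base_sd)
  with(cfg, {
    stopifnot(n_hosts >= 1, samples_per_host >= 1, n_genera >= 1,
              asvs_per_genus >= 1, signal_s >= 0, signal_s <= 1,
              depth_log_sd >= 0, sample_noise_sd >= 0, base_sd >= 0,
              effect_scale >= 0)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a host phylogeny
#'
#' Pure-birth (Yule) tree with a strict clock, so the output is rooted,
#' binary and ultrametric. Stands in for a fixed marker-gene host phylogeny
#' (e.g. a COXI tree) in synthetic runs.
#'
#' @param n_hosts Number of tips (>= 3).
#' @param seed Integer seed.
#' @return Rooted binary ultrametric `ape::phylo`, tips `host01..hostNN`.
#' @export
simulate_host_tree <- function(n_hosts, seed) {
  if (n_hosts < 3) stop("n_hosts must be >= 3")
  tr <- with_seed(seed, ape::rphylo(n_hosts, birth = 1, death = 0))
  tr$tip.label <- sprintf("host%02d", seq_len(n_hosts))
  tr
}

# hires feature tree: pure-birth genus backbone scaled to height 1, each
# genus tip replaced by a shallow polytomy of its ASVs (depth 0.05)
simulate_feature_trees <- function(n_genera, asvs_per_genus, seed) {
  genera <- sprintf("Genus%02d", seq_len(n_genera))
  if (n_genera >= 3) {
    g <- with_seed(seed, ape::rphylo(n_genera, birth = 1, death = 0))
    g$edge.length <- g$edge.length / max(ape::node.depth.edgelength(g))
  } else {
    g <- ape::read.tree(text = if (n_genera == 2) "(t1:1,t2:1);" else "(t1:1);")
  }
  g$tip.label <- genera
  nwk <- ape::write.tree(g)
  eps <- 0.05
  for (gn in genera) {
    asvs <- sprintf("%s_asv%d:%.6g", gn, seq_len(asvs_per_genus), eps)
    nwk <- sub(paste0(gn, ":"),
               sprintf("(%s)%s:", paste(asvs, collapse = ","), gn),
               nwk, fixed = TRUE)
  }
  list(hires = ape::read.tree(text = nwk), lores = g)
}

#' Simulate host-tracking microbial communities
#'
#' For each ASV-level feature, a latent per-host value
#' `z = sqrt(s) * BM(host_tree) + sqrt(1-s) * iid N(0,1)` with unit total
#' variance, where BM is Brownian motion on the (height-normalized) host
#' tree -- so `signal_s` is exactly the share of latent variance explained
#' by host phylogeny. Each sample's expected composition is a softmax over
#' features of `baseline + effect_scale * z_host + per-sample noise`, and
#' read counts are multinomial at a lognormal depth. The genus-merged
#' low-resolution view ("16S-like") is formed by summing ASV counts within
#' each genus and collapsing the feature tree's genus clades, so it
#' conserves reads exactly; the ASV-resolved view is the "cpn60-like"
#' high-resolution view.
#'
#' @param host_tree Host phylogeny whose tip count matches `cfg$n_hosts`.
#' @param cfg A [sim_config()].
#' @return List of class `phylosym_sim`: `host_tree`, `table_hires`,
#'   `table_lores` (`feature_table`s), `tree_hires`, `tree_lores`
#'   (`ape::phylo`), `taxonomy` (`taxonomy_map` over hires features),
#'   `truth` (latent matrix `z`, baseline `alpha`, `signal_s`), `config`.
#' @export
simulate_communities <- function(host_tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  hosts <- sort(host_tree$tip.label)
  if (length(hosts) != cfg$n_hosts)
    stop("host tree has ", length(hosts), " tips but cfg$n_hosts = ",
         cfg$n_hosts)
  n_feat <- cfg$n_genera * cfg$asvs_per_genus
  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  feats <- as.vector(t(outer(genera, seq_len(cfg$asvs_per_genus),
                             function(g, a) sprintf("%s_asv%d", g, a))))
  genus_of <- rep(genera, each = cfg$asvs_per_genus)
  C <- ape::vcv(host_tree)[hosts, hosts]
  C <- C / max(diag(C))
  L <- chol(C + diag(1e-10, nrow(C)))
  trees <- simulate_feature_trees(cfg$n_genera, cfg$asvs_per_genus,
                                  seed = child_seed(cfg$seed, 7919))
  with_seed(cfg$seed, {
    s <- cfg$signal_s
    bm <- t(L) %*% matrix(stats::rnorm(cfg$n_hosts * n_feat), cfg$n_hosts)
    iid <- matrix(stats::rnorm(cfg$n_hosts * n_feat), cfg$n_hosts)
    z <- sqrt(s) * bm + sqrt(1 - s) * iid
    dimnames(z) <- list(hosts, feats)
    alpha <- stats::rnorm(n_feat, 0, cfg$base_sd)
    sample_ids <- character(0)
    sample_host <- character(0)
    counts <- NULL
    for (h in hosts) for (r in seq_len(cfg$samples_per_host)) {
      eta <- alpha + cfg$effect_scale * z[h, ] +
        stats::rnorm(n_feat, 0, cfg$sample_noise_sd)
      p <- exp(eta - max(eta)); p <- p / sum(p)
      depth <- max(1, round(stats::rlnorm(1, cfg$depth_log_mean,
                                          cfg$depth_log_sd)))
      counts <- rbind(counts, as.integer(stats::rmultinom(1, depth, p)))
      sample_ids <- c(sample_ids, sprintf("%s_s%d", h, r))
      sample_host <- c(sample_host, h)
    }
  })
  dimnames(counts) <- list(sample_ids, feats)
  meta <- stats::setNames(sample_host, sample_ids)
  hires <- feature_table(counts, meta)
  lo <- t(rowsum(t(counts), genus_of))
  storage.mode(lo) <- "integer"
  lores <- feature_table(lo[, genera, drop = FALSE], meta)
  lineages <- cbind("Bacteria",
                    sprintf("Phylum%d", (match(genus_of, genera) - 1) %% 4 + 1),
                    sprintf("Class%d", (match(genus_of, genera) - 1) %% 4 + 1),
                    sprintf("Order%d", (match(genus_of, genera) - 1) %% 4 + 1),
                    sprintf("Family%d", (match(genus_of, genera) - 1) %% 8 + 1),
                    genus_of,
                    paste0(genus_of, "_sp",
                           rep(seq_len(cfg$asvs_per_genus), cfg$n_genera)))
  rownames(lineages) <- feats
  structure(list(host_tree = host_tree,
                 table_hires = hires, table_lores = lores,
                 tree_hires = trees$hires, tree_lores = trees$lores,
                 taxonomy = taxonomy_map(lineages),
                 truth = list(z = z, alpha = alpha, signal_s = cfg$signal_s),
                 config = cfg),
            class = "phylosym_sim")
}

#' @export
print.phylosym_sim <- function(x, ...) {
  cat(sprintf(paste0("phylosym_sim: %d hosts x %d samples, %d ASVs in %d",
                     " genera, signal_s = %.2f\n"),
              x$config$n_hosts, nrow(x$table_hires$counts),
              ncol(x$table_hires$counts), x$config$n_genera,
              x$config$signal_s))
  invisible(x)
}

mutate_seq <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), min(n_sub, length(chars)))
  bases <- c("A", "C", "G", "T")
  for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Simulate a reference database and labeled reads
#'
#' Evolves a random root sequence down a ranked taxonomy tree: at each rank
#' every taxon splits into `counts[rank]` children, and each child's
#' sequence accumulates `round(budgets[rank] * seq_len)` random
#' substitutions. One reference sequence per species leaf is emitted with
#' its full 7-rank lineage. Labeled reads are `read_len`-nucleotide windows
#' of leaf sequences with iid substitution errors, carrying their true
#' lineage -- ground truth for classifier evaluation.
#'
#' @param spec List with `counts` and `budgets`, named vectors over
#'   `phylum, class, order, family, genus, species`, and optional `seq_len`
#'   (default 500). See [default_reference_spec()].
#' @param read_len Read length in nucleotides (default 200, the truncation
#'   length amplicon reads are classified at).
#' @param error_rate Per-base substitution error probability in `[0, 0.25)`.
#' @param n_reads Number of labeled reads to draw (default 100).
#' @param seed Integer seed.
#' @return List with `refdb` (a `refdb`), `reads` (named character vector)
#'   and `read_truth` (data.frame `read_id`, `source`, `lineage`).
#' @export
simulate_references <- function(spec = default_reference_spec(),
                                read_len = 200, error_rate = 0.01,
                                n_reads = 100, seed) {
  if (error_rate < 0 || error_rate >= 0.25)
    stop("error_rate must be in [0, 0.25)")
  seq_len_ <- spec$seq_len %||% 500
  if (read_len > seq_len_)
    stop("read_len (", read_len, ") exceeds reference length (", seq_len_, ")")
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  stopifnot(all(ranks %in% names(spec$counts)),
            all(ranks %in% names(spec$budgets)))
  with_seed(seed, {
    root <- paste(sample(c("A", "C", "G", "T"), seq_len_, replace = TRUE),
                  collapse = "")
    nodes <- list(list(seq = root, lineage = c(domain = "Bacteria"),
                       path = integer(0)))
    for (rk in ranks) {
      nxt <- list()
      for (nd in nodes) {
        for (ch in seq_len(spec$counts[[rk]])) {
          path <- c(nd$path, ch)
          nm <- paste0(toupper(substr(rk, 1, 2)), paste(path, collapse = "."))
          child <- nd
          child$seq <- mutate_seq(nd$seq,
                                  round(spec$budgets[[rk]] * seq_len_))
          child$lineage <- c(nd$lineage, stats::setNames(nm, rk))
          child$path <- path
          nxt[[length(nxt) + 1L]] <- child
        }
      }
      nodes <- nxt
    }
    seqs <- vapply(nodes, `[[`, "", "seq")
    ids <- sprintf("ref%03d", seq_along(nodes))
    names(seqs) <- ids
    lin <- do.call(rbind, lapply(nodes, `[[`, "lineage"))
    rownames(lin) <- ids
    tax <- taxonomy_map(lin)
    db <- structure(list(sequences = seqs, taxonomy = tax,
                         provenance = c(collected = length(seqs),
                                        removed_duplicate = 0L,
                                        removed_short = 0L,
                                        remaining = length(seqs),
                                        merged_in = 0L,
                                        final = length(seqs))),
                    class = "refdb")
    src <- sample.int(length(seqs), n_reads, replace = TRUE)
    starts <- sample.int(seq_len_ - read_len + 1, n_reads, replace = TRUE)
    reads <- substring(seqs[src], starts, starts + read_len - 1)
    if (error_rate > 0) {
      reads <- vapply(reads, function(r) {
        n_err <- stats::rbinom(1, read_len, error_rate)
        mutate_seq(r, n_err)
      }, character(1))
    }
    read_ids <- sprintf("%s_read%04d", ids[src], seq_len(n_reads))
    names(reads) <- read_ids
    truth <- data.frame(read_id = read_ids, source = ids[src],
                        lineage = unname(format_lineage(tax)[ids[src]]),
                        stringsAsFactors = FALSE)
  })
  list(refdb = db, reads = reads, read_truth = truth)
}

#' Default ranked-taxonomy specification for reference simulation
#'
#' Two phyla, one class/order per phylum, two families, three genera per
#' family and two species per genus (24 leaves), with per-rank substitution
#' budgets decreasing toward the tips; the genus budget of 3% of sites
#' keeps genera distinguishable at 200 nt while species within a genus stay
#' close.
#' @return List with `counts`, `budgets`, `seq_len`.
#' @export
default_reference_spec <- function() {
  list(counts = c(phylum = 2, class = 1, order = 1, family = 2,
                  genus = 3, species = 2),
       budgets = c(phylum = 0.10, class = 0.06, order = 0.05, family = 0.04,
                   genus = 0.03, species = 0.01),
       seq_len = 500)
}

#' Write a simulation's artifacts to a directory
#'
#' Emits the standard on-disk formats: feature tables and taxonomy as TSV,
#' trees as Newick, truth and config as JSON.
#' @param sim A `phylosym_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table_tsv(sim$table_hires, file.path(dir, "table_hires.tsv"))
  write_feature_table_tsv(sim$table_lores, file.path(dir, "table_lores.tsv"))
  write_taxonomy_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(sim$host_tree, file.path(dir, "host_tree.nwk"))
  ape::write.tree(sim$tree_hires, file.path(dir, "tree_hires.nwk"))
  ape::write.tree(sim$tree_lores, file.path(dir, "tree_lores.nwk"))
  jsonlite::write_json(list(signal_s = sim$truth$signal_s,
                            z = as.data.frame(sim$truth$z),
                            alpha = sim$truth$alpha),
                       file.path(dir, "truth.json"), digits = NA)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
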