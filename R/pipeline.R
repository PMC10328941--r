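#' Pipeline configuration with study defaults
#'
#' Every analysis parameter defaults to the value of the workflow this
#' package reproduces: 1000-read minimum sample depth, rarefaction to 1000
#' reads, 1000 rarefaction/bootstrap iterations, 100,000 random topologies
#' for the congruence test and 100,000 PROTEST permutations, display
#' thresholds of 3% and 5%. Interactive and test profiles scale the
#' Monte-Carlo sizes down.
#'
#' @param seed Integer seed (mandatory).
#' @param min_reads,depth,iterations,n_random,n_permutations,thresholds
#'   Analysis parameters; see Details.
#' @param metrics Distance metrics to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, min_reads = 1000, depth = 1000,
                            iterations = 1000, n_random = 100000,
                            n_permutations = 100000,
                            thresholds = c(0.03, 0.05),
                            metrics = c("braycurtis", "uu", "wu")) {
  stopifnot(min_reads >= 0, depth >= 1, iterations >= 1, n_random >= 1,
            n_permutations >= 1)
  structure(list(seed = seed, min_reads = min_reads, depth = depth,
                 iterations = iterations, n_random = n_random,
                 n_permutations = n_permutations, thresholds = thresholds,
                 metrics = metrics),
            class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full phylosymbiosis workflow
#'
#' Executes, for each marker view: depth filter, host collapse,
#' rarefaction-replicated distances per metric, UPGMA with bootstrap
#' support from the rarefaction replicates, and the Robinson-Foulds
#' congruence test against the host phylogeny (pruned to the hosts
#' surviving the depth filter). Across the two views it runs sample-level
#' PCoA and PROTEST per metric. Stage failures abort with the stage name.
#'
#' @param sim A `phylosym_sim` (or a list with the same elements read from
#'   disk) providing `host_tree`, `table_hires`, `table_lores`,
#'   `tree_hires`, `tree_lores`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the report, dendrograms,
#'   distance matrices and resolved config snapshot are written there.
#' @return List of class `phylosym_report`: per view and metric the nRF and
#'   congruence p, per metric the PROTEST r and p, plus provenance.
#' @export
run_phylosymbiosis <- function(sim, config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  views <- list(hires = list(table = sim$table_hires, tree = sim$tree_hires),
                lores = list(table = sim$table_lores, tree = sim$tree_lores))
  hash <- config_hash(config)
  report <- list(config = unclass(config), config_hash = hash,
                 congruence = list(), procrustes = list(), stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  dendros <- list()
  collapsed_dms <- list()
  sample_dms <- list()
  si <- 0L
  for (v in names(views)) {
    tab <- views[[v]]$table
    tree <- views[[v]]$tree
    filt <- stage(paste0(v, ":filter"),
                  filter_samples_min_depth(tab, config$min_reads))
    coll <- stage(paste0(v, ":collapse"), collapse_by_group(filt))
    report$stages[[v]] <- list(
      samples_in = nrow(tab$counts), samples_kept = nrow(filt$counts),
      hosts = nrow(coll$counts))
    # sample-level rarefied table for ordination concordance
    samp_rar <- stage(paste0(v, ":rarefy"),
                      rarefy(filt, config$depth,
                             seed = child_seed(config$seed, 1000 + si)))
    for (m in config$metrics) {
      si <- si + 1L
      br <- stage(paste0(v, ":", m, ":beta_rarefaction"),
                  beta_rarefaction(coll, metric = m, tree = tree,
                                   depth = config$depth,
                                   iterations = config$iterations,
                                   seed = child_seed(config$seed, si)))
      dend <- stage(paste0(v, ":", m, ":upgma"), upgma(br$mean))
      reps <- lapply(br$iterations, upgma)
      dend <- bootstrap_support(reps, dend)
      host_sub <- ape::keep.tip(sim$host_tree, dend$tip.label)
      ct <- stage(paste0(v, ":", m, ":congruence"),
                  congruence_test(host_sub, dend,
                                  n_random = config$n_random,
                                  seed = child_seed(config$seed, 500 + si)))
      report$congruence[[paste(v, m, sep = ".")]] <-
        list(view = v, metric = m, rf = ct$rf, nrf = ct$nrf,
             p_value = ct$p_value, n_random = ct$n_random,
             n_hosts = length(dend$tip.label))
      dendros[[paste(v, m, sep = ".")]] <- dend
      collapsed_dms[[paste(v, m, sep = ".")]] <- br$mean
      sample_dms[[paste(v, m, sep = ".")]] <- switch(m,
        braycurtis = bray_curtis(samp_rar),
        uu = unweighted_unifrac(samp_rar, tree),
        wu = weighted_unifrac(samp_rar, tree),
        wun = weighted_unifrac(samp_rar, tree, normalized = TRUE))
    }
  }
  for (m in config$metrics) {
    si <- si + 1L
    # a saturated view (e.g. genus-level presence/absence at high depth)
    # yields an all-zero distance matrix with no ordination; record the
    # degenerate concordance rather than aborting the whole report
    report$procrustes[[m]] <- tryCatch({
      o1 <- pcoa(sample_dms[[paste0("hires.", m)]])
      o2 <- pcoa(sample_dms[[paste0("lores.", m)]])
      pr <- protest(o1, o2, n_permutations = config$n_permutations,
                    seed = child_seed(config$seed, 900 + si))
      list(metric = m, r = pr$r, m2 = pr$m2, p_value = pr$p_value,
           n_permutations = pr$n_permutations, n_shared = pr$n_shared)
    }, error = function(e)
      list(metric = m, r = NA_real_, m2 = NA_real_, p_value = NA_real_,
           n_permutations = 0L, n_shared = 0L,
           degenerate = conditionMessage(e)))
  }
  class(report) <- "phylosym_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cg <- do.call(rbind, lapply(report$congruence, as.data.frame))
    utils::write.table(cg, file.path(out_dir, "congruence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    pc <- do.call(rbind, lapply(report$procrustes, function(x)
      as.data.frame(x[c("metric", "r", "m2", "p_value", "n_permutations",
                        "n_shared")])))
    utils::write.table(pc, file.path(out_dir, "procrustes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in names(dendros))
      ape::write.tree(dendros[[nm]],
                      file.path(out_dir, paste0("dendro_", nm, ".nwk")))
    for (nm in names(collapsed_dms))
      write_dist_tsv(collapsed_dms[[nm]],
                     file.path(out_dir, paste0("dist_", nm, ".tsv")))
    jsonlite::write_json(c(unclass(config), list(hash = hash)),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.phylosym_report <- function(x, ...) {
  cat("phylosymbiosis report (config", substr(x$config_hash, 1, 8), ")\n")
  for (cg in x$congruence)
    cat(sprintf("  %-6s %-10s nRF = %.3f  p = %.4g\n",
                cg$view, cg$metric, cg$nrf, cg$p_value))
  for (pr in x$procrustes)
    cat(sprintf("  PROTEST %-10s r = %.3f  p = %.4g\n",
                pr$metric, pr$r, pr$p_value))
  invisible(x)
}
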