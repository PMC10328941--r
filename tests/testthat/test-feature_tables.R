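make_table <- function(depths, n_features = 4, seed = 1) {
  set.seed(seed)
  counts <- t(vapply(depths, function(d) {
    as.integer(rmultinom(1, d, rep(1, n_features)))
  }, integer(n_features)))
  dimnames(counts) <- list(sprintf("s%d", seq_along(depths)),
                           sprintf("f%d", seq_len(n_features)))
  feature_table(counts)
}

test_that("constructor validates counts and metadata", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_s3_class(feature_table(m), "feature_table")
  expect_error(feature_table(matrix(1:4, 2, 2)), "names")
  expect_error(feature_table(m - 3), "non-negative")
  expect_error(feature_table(m, c(a = "h1")), "metadata")
  m2 <- m; rownames(m2) <- c("a", "a")
  expect_error(feature_table(m2), "duplicate")
})

test_that("depth filter keeps samples at exactly the boundary", {
  tab <- make_table(c(999, 1000, 5142))
  out <- filter_samples_min_depth(tab, 1000)
  expect_identical(rownames(out$counts), c("s2", "s3"))
  expect_identical(filter_samples_min_depth(tab, 0)$counts, tab$counts)
  expect_warning(filter_samples_min_depth(tab, 10^7), "no samples")
})

test_that("depth filter provenance reports the retained-read fraction", {
  set.seed(42)
  depths <- c(sample(1000:9000, 7), sample(100:999, 3))
  tab <- make_table(depths)
  out <- filter_samples_min_depth(tab, 1000)
  expect_equal(nrow(out$counts), 7)
  prov <- out$provenance[[length(out$provenance)]]
  expect_equal(prov$retained_fraction, sum(depths[1:7]) / sum(depths))
  expect_equal(sum(out$counts), sum(depths[1:7]))
})

test_that("empty features are retained unless drop_empty", {
  counts <- matrix(c(0L, 5L, 0L, 900L, 1200L, 0L), 2, 3,
                   dimnames = list(c("lo", "hi"), c("fA", "fB", "fC")))
  tab <- feature_table(counts)
  kept <- filter_samples_min_depth(tab, 1000)
  expect_identical(colnames(kept$counts), c("fA", "fB", "fC"))
  dropped <- filter_samples_min_depth(tab, 1000, drop_empty = TRUE)
  expect_identical(colnames(dropped$counts), "fC")
})

test_that("group collapse sums counts and conserves totals", {
  counts <- rbind(s1 = c(3L, 0L), s2 = c(2L, 5L))
  colnames(counts) <- c("f1", "f2")
  tab <- feature_table(counts, c(s1 = "horse", s2 = "horse"))
  out <- collapse_by_group(tab)
  expect_equal(unname(out$counts["horse", ]), c(5L, 5L))
  # one sample per group: identity up to relabeling
  tab2 <- feature_table(counts, c(s1 = "a", s2 = "b"))
  out2 <- collapse_by_group(tab2)
  expect_equal(unname(out2$counts), unname(counts[order(c("a", "b")), ]))
  expect_error(collapse_by_group(tab, c(s1 = "x")), "without a group")
  # property: grand total conserved on random tables
  for (s in 1:5) {
    rt <- random_table(6, 8, seed = s)
    grp <- setNames(rep(c("g1", "g2", "g3"), 2), rownames(rt$counts))
    expect_identical(sum(collapse_by_group(rt, grp)$counts), sum(rt$counts))
  }
})

test_that("rarefaction hits depth exactly and is seeded", {
  tab <- make_table(c(500, 1500, 2500))
  out <- rarefy(tab, 500, seed = 11)
  expect_true(all(rowSums(out$counts) == 500))
  expect_equal(nrow(out$counts), 3)
  # depth == total leaves the sample unchanged
  expect_identical(out$counts["s1", ], tab$counts["s1", ])
  out2 <- rarefy(tab, 500, seed = 11)
  expect_identical(out$counts, out2$counts)
  expect_false(identical(rarefy(tab, 500, seed = 12)$counts, out$counts))
  expect_warning(rarefy(tab, 10^7, seed = 1), "every sample")
})

test_that("rarefaction matches the hypergeometric expectation", {
  counts <- matrix(c(900L, 100L), 1, 2,
                   dimnames = list("s1", c("big", "small")))
  tab <- feature_table(counts)
  n_seeds <- 2000
  draws <- vapply(seq_len(n_seeds), function(s)
    rarefy(tab, 100, seed = s)$counts[1, "big"], integer(1))
  # mean of hypergeometric(900 of 1000, draw 100) = 90
  sd1 <- sqrt(100 * 0.9 * 0.1 * (1000 - 100) / 999)
  se <- sd1 / sqrt(n_seeds)
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

simple_tax <- function(genera, species = NULL) {
  n <- length(genera)
  lin <- cbind("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
               "Staphylococcaceae", genera,
               species %||% paste0(genera, "_sp"))
  rownames(lin) <- sprintf("asv%d", seq_len(n))
  taxonomy_map(lin)
}

test_that("taxonomy collapse merges identical prefixes only", {
  tax <- simple_tax(c("Corynebacterium", "Corynebacterium", "Corynebacterium1"))
  counts <- matrix(c(1L, 2L, 4L), 1, 3,
                   dimnames = list("s1", sprintf("asv%d", 1:3)))
  tab <- feature_table(counts)
  out <- collapse_taxonomy(tab, tax, "genus")
  expect_equal(ncol(out$counts), 2)  # trailing "1" stays distinct
  expect_equal(sum(out$counts), 7L)
  merged <- grep("g__Corynebacterium$", colnames(out$counts), value = TRUE)
  expect_equal(unname(out$counts[1, merged]), 3L)
})

test_that("species-then-genus collapse equals genus collapse directly", {
  sim <- simulate_communities(simulate_host_tree(4, seed = 3),
                              sim_config(n_hosts = 4, samples_per_host = 2,
                                         n_genera = 6, seed = 9))
  at_species <- collapse_taxonomy(sim$table_hires, sim$taxonomy, "species")
  # collapsed feature names are themselves prefixed lineage strings
  tax2 <- taxonomy_map(setNames(colnames(at_species$counts),
                                colnames(at_species$counts)))
  via_species <- collapse_taxonomy(at_species, tax2, "genus")
  direct <- collapse_taxonomy(sim$table_hires, sim$taxonomy, "genus")
  cols <- sort(colnames(direct$counts))
  expect_equal(via_species$counts[, cols], direct$counts[, cols])
})

test_that("features missing from taxonomy land in Unassigned", {
  tax <- simple_tax(c("Staphylococcus", "Macrococcus"))
  counts <- matrix(c(1L, 2L, 9L), 1, 3,
                   dimnames = list("s1", c("asv1", "asv2", "mystery")))
  out <- collapse_taxonomy(feature_table(counts), tax, "genus")
  expect_true("Unassigned" %in% colnames(out$counts))
  expect_equal(unname(out$counts[1, "Unassigned"]), 9L)
})

test_that("relative-abundance threshold is strictly greater-than", {
  counts <- matrix(c(97L, 3L), 1, 2, dimnames = list("s1", c("f1", "f2")))
  res <- relative_abundance_filter(feature_table(counts), 0.03)
  expect_true(res$mask[1, "f1"])
  expect_false(res$mask[1, "f2"])   # 3% is not > 3%
  # threshold 0: all nonzero features retained
  res0 <- relative_abundance_filter(feature_table(counts), 0)
  expect_equal(unname(res0$mask[1, ]), c(TRUE, TRUE))
  # contract: masked relative abundances all exceed the threshold
  rt <- random_table(5, 10, seed = 4)
  res2 <- relative_abundance_filter(rt, 0.1)
  rel <- rt$counts / rowSums(rt$counts)
  expect_true(all(rel[res2$mask] > 0.1))
})

test_that("taxon subsetting computes within-subset proportions", {
  tax <- taxonomy_map(rbind(
    asv1 = c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
             "Staphylococcaceae", "Staphylococcus", ""),
    asv2 = c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
             "Staphylococcaceae", "Jeotgalicoccus", ""),
    asv3 = c("Bacteria", "Proteobacteria", "", "", "", "", "")))
  counts <- rbind(eland = c(1000L, 339L, 3803L),
                  hyena = c(0L, 0L, 2307L))
  colnames(counts) <- rownames(tax$lineages)
  res <- subset_by_taxon(feature_table(counts), tax, "Staphylococcaceae")
  expect_equal(round_half_up(100 * res$subset_fraction[["eland"]], 1), 26.0)
  expect_identical(res$dropped_samples, "hyena")
  expect_equal(unname(rowSums(res$within_relabund)), 1)
  expect_error(subset_by_taxon(feature_table(counts), tax, "Nosuchfamily"),
               "matches no feature")
})
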