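rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

flat_tax <- function(ids) {
  lin <- cbind("Bacteria", "P1", "C1", "O1", "F1", "G1",
               paste0("sp_", seq_along(ids)))
  rownames(lin) <- ids
  taxonomy_map(lin)
}

test_that("curation removes duplicates and short sequences at the boundary", {
  s200 <- rand_seq(200, 1)
  seqs <- c(r1 = s200, r2 = s200, r3 = rand_seq(179, 2),
            r4 = rand_seq(185, 3), r5 = rand_seq(300, 4))
  db <- curate_refdb(seqs, flat_tax(names(seqs)), min_length = 180)
  expect_setequal(names(db$sequences), c("r1", "r4", "r5"))
  p <- db$provenance
  expect_equal(unname(p["collected"]), 5L)
  expect_equal(unname(p["removed_duplicate"]), 1L)
  expect_equal(unname(p["removed_short"]), 1L)
  expect_equal(unname(p["remaining"]), 3L)
  expect_equal(unname(p["final"]), 3L)
  # a 180-mer is kept ("below 180" removed); case/gaps ignored for dedupe
  seqs2 <- c(a = rand_seq(180, 5), b = tolower(rand_seq(250, 6)))
  seqs2["c"] <- paste0(substr(seqs2["b"], 1, 100), "-",
                       substr(seqs2["b"], 101, 250))
  db2 <- curate_refdb(seqs2, flat_tax(names(seqs2)), min_length = 180)
  expect_setequal(names(db2$sequences), c("a", "b"))
  expect_error(curate_refdb(c(x = "ACGT"), flat_tax("y")), "lineages")
})

test_that("merging concatenates without cross-set deduplication", {
  shared <- rand_seq(250, 7)
  base <- curate_refdb(c(m1 = shared, m2 = rand_seq(260, 8)),
                       flat_tax(c("m1", "m2")), min_length = 180)
  main <- curate_refdb(c(q1 = shared, q2 = rand_seq(240, 9),
                         q3 = rand_seq(255, 10)),
                       flat_tax(c("q1", "q2", "q3")),
                       min_length = 180, merge_with = base)
  p <- main$provenance
  # q1 duplicates m1 across sets yet both survive: provenance arithmetic exact
  expect_equal(unname(p["final"]), 5L)
  expect_equal(unname(p["final"]), unname(p["remaining"] + p["merged_in"]))
  expect_equal(unname(p["remaining"]),
               unname(p["collected"] - p["removed_duplicate"] -
                        p["removed_short"]))
})

test_that("lineage harmonization strips digits and applies synonyms", {
  lin <- rbind(
    asv1 = c("Bacteria", "Actinobacteria", "", "", "", "Corynebacterium1", ""),
    asv2 = c("Bacteria", "Actinobacteria", "", "", "", "Corynebacterium", ""),
    asv3 = c("Bacteria", "Proteobacteria", "Betaproteobacteria", "", "",
             "Massilia", ""))
  tax <- taxonomy_map(lin)
  # digit-strip off: identity
  same <- harmonize_lineages(tax)
  expect_identical(same$lineages, tax$lineages)
  # digit-strip on merges the two Corynebacterium spellings
  fixed <- harmonize_lineages(tax, strip_trailing_digits = TRUE)
  expect_identical(unname(fixed$lineages["asv1", "genus"]), "Corynebacterium")
  expect_gt(nrow(attr(fixed, "changes")), 0)
  # class conflicts resolve only via the synonym table
  syn <- data.frame(from = "Betaproteobacteria", to = "Gammaproteobacteria")
  moved <- harmonize_lineages(tax, synonyms = syn)
  expect_identical(unname(moved$lineages["asv3", "class"]),
                   "Gammaproteobacteria")
  # idempotence
  twice <- harmonize_lineages(fixed, strip_trailing_digits = TRUE)
  expect_identical(twice$lineages, fixed$lineages)
  # cyclic rules rejected
  cyc <- data.frame(from = c("A", "B"), to = c("B", "A"))
  expect_error(harmonize_lineages(tax, synonyms = cyc), "cyclic")
})

test_that("training validates inputs and separates disjoint taxa", {
  refs <- simulate_references(error_rate = 0, n_reads = 1, seed = 21)
  expect_error(train_classifier(refs$refdb, k = 3), "k must")
  expect_error(train_classifier(refs$refdb, k = 17), "k must")
  # two taxa with disjoint word sets: reads from A always score A higher
  a <- paste(rep("ACGT", 30), collapse = "")   # only ACGT-cycle words
  b <- paste(rep("GGCC", 30), collapse = "")
  lin <- rbind(ra = c("Bacteria", "P1", "C1", "O1", "F1", "GA", "s1"),
               rb = c("Bacteria", "P2", "C2", "O2", "F2", "GB", "s2"))
  db <- curate_refdb(c(ra = a, rb = b), taxonomy_map(lin), min_length = 1)
  model <- train_classifier(db, k = 8)
  lp <- phylosymr:::nb_log_prob(model, phylosymr:::kmer_words(substr(a, 1, 40), 8))
  scores <- rowSums(lp)
  expect_gt(scores[grep("GA", names(model$M_t))],
            scores[grep("GB", names(model$M_t))])
})

test_that("equal duplication of training sequences preserves score order", {
  refs <- simulate_references(error_rate = 0, n_reads = 5, seed = 22)
  db1 <- refs$refdb
  dup <- db1
  dup$sequences <- c(db1$sequences,
                     stats::setNames(db1$sequences,
                                     paste0(names(db1$sequences), "_dup")))
  dup$taxonomy <- taxonomy_map(rbind(
    db1$taxonomy$lineages,
    `rownames<-`(db1$taxonomy$lineages,
                 paste0(rownames(db1$taxonomy$lineages), "_dup"))))
  m1 <- train_classifier(db1, k = 8)
  m2 <- train_classifier(dup, k = 8)
  words <- phylosymr:::kmer_words(refs$reads[[1]], 8)
  s1 <- rowSums(phylosymr:::nb_log_prob(m1, words))
  s2 <- rowSums(phylosymr:::nb_log_prob(m2, words))
  expect_identical(order(s1), order(s2))
})

test_that("classifier model serialization round-trips", {
  refs <- simulate_references(error_rate = 0, n_reads = 1, seed = 23)
  model <- train_classifier(refs$refdb, k = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(model, path)
  back <- read_classifier_json(path)
  expect_equal(back, model, ignore_attr = TRUE)
  # byte-identical on re-serialization
  path2 <- withr::local_tempfile(fileext = ".json")
  write_classifier_json(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("verbatim reads classify to their source with confidence 1", {
  refs <- simulate_references(error_rate = 0, n_reads = 20, seed = 24)
  model <- train_classifier(refs$refdb, k = 8)
  res <- classify(model, refs$reads, seed = 25)
  # genus and above always recovered; species may be conservatively
  # truncated when a 200-nt window carries few of the ~5 species-level
  # substitutions (that is the classifier doing its job)
  strip_sp <- function(x) sub("s__.*$", "", x)
  expect_identical(strip_sp(res$lineage[1:20]),
                   strip_sp(refs$read_truth$lineage[1:20]))
  expect_true(all(res$genus == 1))
  # all words unique to one taxon: full lineage at confidence 1.0
  a <- rand_seq(300, 51); b <- rand_seq(300, 52)
  lin <- rbind(ra = c("Bacteria", "P1", "C1", "O1", "F1", "GA", "spA"),
               rb = c("Bacteria", "P2", "C2", "O2", "F2", "GB", "spB"))
  db2 <- curate_refdb(c(ra = a, rb = b), taxonomy_map(lin), min_length = 1)
  m2 <- train_classifier(db2, k = 8)
  r2 <- classify(m2, c(q = substr(a, 40, 240)), seed = 26)
  expect_identical(r2$lineage,
                   "k__Bacteria; p__P1; c__C1; o__O1; f__F1; g__GA; s__spA")
  expect_true(all(r2[, phylosymr:::TAX_RANKS] == 1))
  # unreachable threshold leaves every read unclassified
  res_hi <- classify(model, refs$reads[1:5], confidence_threshold = 1.01,
                     seed = 26)
  expect_true(all(res_hi$lineage == "Unassigned"))
  expect_false(any(res_hi$classified))
  # reads shorter than k are unclassified, not an error
  res_short <- classify(model, c(tiny = "ACGT"), seed = 27)
  expect_false(res_short$classified)
})

test_that("classification is deterministic and order-invariant per read", {
  refs <- simulate_references(error_rate = 0.02, n_reads = 12, seed = 28)
  model <- train_classifier(refs$refdb, k = 8)
  r1 <- classify(model, refs$reads, seed = 30)
  r2 <- classify(model, refs$reads, seed = 30)
  expect_identical(r1, r2)
  # full-read assignment of each single read unaffected by batch order
  one <- classify(model, refs$reads[3], seed = 30)
  expect_identical(one$taxon, r1$taxon[3])
})

test_that("genus confusion rises as the genus-level budget shrinks", {
  recov <- vapply(c(0.03, 0.008, 0), function(budget) {
    spec <- default_reference_spec()
    spec$budgets["genus"] <- budget
    refs <- simulate_references(spec, error_rate = 0.01, n_reads = 150,
                                seed = 31)
    model <- train_classifier(refs$refdb, k = 8)
    res <- classify(model, refs$reads, seed = 32)
    truth_g <- sub(".*g__([^;]*);.*", "\\1", refs$read_truth$lineage)
    pred_g <- sub(".*g__([^;]*).*", "\\1", sub(";? *s__.*", "", res$lineage))
    mean(pred_g == truth_g)
  }, numeric(1))
  expect_true(all(diff(recov) <= 0.05))   # monotone trend with slack
  expect_gt(recov[1], recov[3])
})
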