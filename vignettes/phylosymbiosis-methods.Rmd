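---
title: "Detecting phylosymbiosis: models, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phylosymbiosis: models, conventions, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the procedure

Phylosymbiosis is the observation that microbial community dissimilarity
among host species can recapitulate host phylogeny. `phylosymr` operationalizes
the standard dendrogram-congruence test of that pattern:

1. filter samples below a minimum sequencing depth (default 1000 reads;
   a sample with *exactly* 1000 reads is kept, because the convention
   removes samples with *fewer than* the cutoff);
2. collapse replicate samples by host, summing counts;
3. compute community distances (Bray–Curtis, unweighted UniFrac, weighted
   UniFrac) under repeated rarefaction to a common depth (default 1000
   reads, default 1000 iterations);
4. build a UPGMA dendrogram from the mean distance matrix, with per-clade
   bootstrap support taken as the fraction of rarefaction-replicate
   dendrograms containing each bipartition;
5. score congruence between the dendrogram and the host phylogeny with the
   normalized Robinson–Foulds distance, and obtain a p-value by comparing
   the observed RF against RF values for uniformly random topologies on
   the same tips (default 100,000);
6. separately, compare two marker datasets' PCoA ordinations with
   symmetric Procrustes and the PROTEST permutation test (default 100,000
   permutations).

The package assumes a feature (ASV) table is the entry point; denoising,
chimera removal, and host-phylogeny inference are upstream concerns, and
the host tree is always a Newick input (or simulated).

## The synthetic world

The generator exists so the full pipeline can be exercised, calibrated,
and power-tested without any sequence downloads. Its stated world:

* **Host tree** — pure-birth (Yule) with a strict clock; rooted, binary,
  ultrametric. Nine hosts by default, matching the scale of mammalian
  skin studies this workflow serves.
* **Latent abundances** — for each feature, a per-host latent value
  $z = \sqrt{s}\,\mathrm{BM}(T_H) + \sqrt{1-s}\,\varepsilon$, where BM is
  Brownian motion on the height-normalized host tree and $\varepsilon$ is
  iid standard normal. Both components have unit variance, so `signal_s`
  $= s$ is exactly the share of latent variance explained by host
  phylogeny. BM is the simplest process that makes "more related hosts
  have more similar communities" quantitative; the literature describes
  the pattern only qualitatively.
* **Compositions** — softmax over features of
  `baseline + effect_scale * z + sample noise`. The softmax link
  guarantees a valid probability vector at every `signal_s`; the
  per-feature baseline (SD 1) produces the uneven rank-abundance curves
  real communities show; `effect_scale = 2` makes a full-signal world
  clearly, but not trivially, detectable.
* **Counts and depths** — multinomial draws at lognormal depths
  (`meanlog = log(2000)`, `sdlog = 0.85` by default), placing roughly 20%
  of samples under 1000 reads so the depth filter is genuinely exercised —
  emulating the severe per-host unevenness of real amplicon runs.
* **Two marker views** — the high-resolution view is the ASV table itself
  ("cpn60-like", species-resolved); the low-resolution view sums ASV
  counts within each genus and collapses the feature tree's genus clades
  ("16S-like"). Merging is exact, so reads are conserved between views by
  construction. No sequence-level 16S simulation is attempted: the
  Discussion-level mechanism (limited fragment resolution) is modeled
  directly as genus merging.
* **References and reads** — a root sequence evolved down a ranked
  taxonomy with per-rank substitution budgets (defaults 10/6/5/4/3/1% of
  sites at phylum/class/order/family/genus/species over 500 nt), read as
  200-nt windows with iid substitution errors. The 200-nt length matches
  the truncation length amplicon classifiers typically see.

What the generator does **not** emulate: PCR and primer bias, chimeras,
gene copy-number variation, overdispersion beyond multinomial sampling,
within-genome evolution models. A green test therefore establishes that
the *statistical machinery* behaves as specified on a community whose
host-tracking structure is known — not that any particular biological
dataset exhibits phylosymbiosis.

Power experiments (rejection rate at `signal_s` 0 and 1) simulate deeper
sequencing (`meanlog = log(20000)`, `sdlog = 0.3`) because the stated
experiment rarefies host-collapsed tables to 5000 reads, which requires
every host to accumulate at least that many.

## Numerical conventions

* **Boundary semantics** — depth filter keeps equality (`>= min_reads`);
  relative-abundance display masks are strict (`> threshold`), so a
  feature at exactly 3% does not pass a 3% filter.
* **Rarefaction** — uniform subsampling *without* replacement
  (multivariate hypergeometric), seeded; samples below the target depth
  are dropped.
* **UPGMA** — ties in the minimal average distance are broken by the
  lexicographically smallest pair of cluster representative labels, and
  the two children of each merge are emitted in representative order, so
  the output is invariant to input label order. Merge height is d/2 per
  side; the output is ultrametric by construction.
* **Robinson–Foulds** — trees are read as unrooted (dendrograms are
  unrooted for scoring even though UPGMA output is rooted), branch
  lengths ignored, nontrivial bipartitions only. nRF divides by the sum
  of the two trees' actual split counts, which equals $2(n-3)$ for binary
  trees and stays coherent for multifurcating inputs.
* **Random topologies** — uniform over unrooted binary labeled topologies
  via sequential leaf insertion (leaf $k$ on one of the $2k-5$ edges).
  Uniformity, rather than any generative tree process, is the
  conservative reading of an unspecified "random trees" null.
* **Congruence p-value** — add-one Monte-Carlo estimator, one-sided
  toward congruence (null trees at least as congruent, RF ≤ observed).
  The literal prose of some methods sections counts the opposite tail
  ("scores equal to or greater than"), which would make *small* p mean
  *incongruence*; that reading contradicts the phylosymbiosis literature
  the procedure descends from, so the congruent tail is the default and
  the opposite tail is exposed as `tail = "opposite"`.
* **Discreteness of the RF null** — on nine tips, ~76% of uniform random
  topologies sit at the maximal RF from any fixed binary tree. The null
  p-value distribution is therefore *super-uniform*
  ($P(p \le \alpha) \le \alpha$), with mean ≈ 0.8 rather than 0.5 — a
  property of any correct Monte-Carlo test with a concentrated discrete
  statistic. Calibration tests assert super-uniformity at several
  $\alpha$; asserting mean-p ≈ 0.5 would be wrong for this statistic.
  The discreteness also makes the test slightly conservative: its
  realized size at nominal 5% is ≈ 4.5% on nine tips.
* **UniFrac** — presence is `count > 0`; branches with no present
  descendants in either sample enter neither sum. Weighted UniFrac is
  un-normalized by default (the convention of the standard pipelines),
  with the normalized variant behind a flag. Unrooted input trees are
  midpoint-rooted, and that rooting is logged; rooting conventions are
  otherwise never assumed.
* **PCoA** — Gower double-centering, symmetric eigendecomposition, axes
  scaled by the square root of their eigenvalues. Negative eigenvalues
  are dropped with their total magnitude recorded; no Cailliez/Lingoes
  correction is applied, because the reproduced workflow applies none.
  A degenerate matrix with no positive eigenvalue is an error; a single
  positive axis (collinear configurations) is legitimate output.
* **Procrustes/PROTEST** — symmetric scaling (both configurations
  centered and scaled to unit total sum of squares), reflections allowed,
  both configurations truncated to the smaller positive-axis count before
  superimposition (an alternative convention pads the smaller one with
  zero columns; for the symmetric statistic at the default axis count the
  difference is immaterial). PROTEST permutes the rows (samples) of the
  second configuration, not distance-matrix labels, and uses the add-one
  estimator. With $n$ distinct points the identity permutation recurs
  with probability $1/n!$ per draw, so the textbook "p = 1/(B+1) for
  identical inputs" holds only when $n!$ dwarfs the permutation count.
* **Classifier** — RDP-style word-presence naïve Bayes with $k = 8$,
  word prior $(n_w + 0.5)/(N+1)$, per-taxon conditional
  $(m_{w,t} + P_w)/(M_t + 1)$; bootstrap confidence from 100 draws of
  $\lceil W/8 \rceil$ of the read's $W$ distinct words; the reported
  lineage is truncated at the deepest rank meeting the confidence
  threshold (default 0.8), so reads from closely related congeners come
  back "unresolved to genus" rather than over-claimed. Words containing
  non-ACGT characters are skipped; reads shorter than $k$ are
  unclassified, never an error.
* **Curation accounting** — duplicate removal is by exact uppercased,
  gap-stripped sequence identity (first occurrence kept); "below
  `min_length`" removes strictly shorter sequences, so a 180-nt sequence
  survives the 180-nt filter. Merging a second curated set performs *no*
  cross-set deduplication — the provenance identities
  `remaining = collected − removed_duplicate − removed_short` and
  `final = remaining + merged_in` hold exactly, which is the only reading
  consistent with published database arithmetic of the form
  12,224 + 5,489 = 17,713.
* **Printed percentages** — half-up rounding at the printed precision
  (97.55…% prints as 97.6%). Published tables occasionally show truncated
  rounding (e.g., 2/2307 as 0.08% rather than 0.09%); this package rounds
  half-up consistently and documents the discrepancy rather than
  reproducing it.

## Design choices on genuinely open points

* The number of rarefaction iterations behind "1000 bootstraps" is never
  stated in the workflows this package reproduces; iterations and
  bootstrap replicates are coupled here (the iteration set *is* the
  replicate set), which is the only reading that does not invent a second
  free parameter.
* Distances for dendrograms are computed on host-collapsed tables
  (collapse precedes rarefaction), following the stated methods order;
  ordination concordance uses sample-level tables, as core-metrics-style
  workflows do.
* Mean (not median) aggregation across rarefaction replicates: simple,
  variance-reducing, and the dendrogram's uncertainty is carried by the
  replicate set, not the point estimate.
* `beta_rarefaction` with one iteration equals rarefy-then-metric at the
  derived per-iteration seed (`child_seed(seed, 1)`), keeping the
  iteration seeds independent of the iteration count.
* The default `signal_s` sweep used in examples (0, 0.25, 0.5, 0.75, 1)
  is a package choice; no quantitative effect size for phylosymbiosis
  exists to borrow.
* Duplicate removal considers sequence only, not lineage: accession-level
  metadata is not available offline, and sequence-identical records with
  conflicting lineages are exactly the pathology the harmonization tools
  exist to surface, not silently resolve.
* Class-level lineage conflicts (a genus filed under Betaproteobacteria
  by one database and Gammaproteobacteria by another) are resolvable only
  through an explicit, user-supplied synonym table; automatic resolution
  would have to pick a taxonomy authority, which is a scientific choice,
  not a software one. Trailing-digit disambiguators, by contrast, are
  mechanical artifacts and can be stripped by a flag.

## Known limitations

* UniFrac and Bray–Curtis are computed densely per sample pair; the
  implementation targets study-scale tables (tens to hundreds of
  samples), not thousands.
* The congruence test's resolution is bounded by `1/(n_random + 1)`; at
  the default 100,000 the floor is ~1e-5.
* The uniform-topology null ignores branch lengths and any biological
  tree shape prior; with few tips its discreteness makes the test
  conservative (see above).
* The classifier holds the full taxon-by-vocabulary count matrix densely
  in memory; it is sized for curated marker databases (thousands to tens
  of thousands of references), not shotgun catalogs.
* The generator's two marker views share the *same* underlying
  communities by construction; it cannot emulate marker-specific
  amplification bias, so PROTEST concordance on synthetic data is an
  upper bound relative to real paired datasets.
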