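test_that("two well-separated genomes yield two accurate bins", {
  d <- two_genome_profiles(gc = c(0.35, 0.60), abund = c(0.9, 0.1),
                           depth = 40)
  bins <- preliminary_bins(d$profiles)
  expect_equal(nrow(bins$bins), 2)
  mem <- bins$membership
  mem$genome <- genome_of(d$truth, mem$scaffold_id)
  acc <- mem |>
    dplyr::count(.data$bin_id, .data$genome) |>
    dplyr::group_by(.data$bin_id) |>
    dplyr::summarise(purity = max(n) / sum(n))
  expect_true(all(acc$purity >= 0.95))
  expect_gte(nrow(mem) / nrow(d$profiles), 0.95)
})

test_that("a single genome collapses to one bin", {
  truth <- tiny_community(n_genomes = 1, gc_targets = 0.5, abundances = 1,
                          labels = "TaxA", genome_length = 60000)
  reads <- simulate_reads(truth)
  bins <- preliminary_bins(profile_community(truth, reads))
  expect_equal(nrow(bins$bins), 1)
  expect_equal(bins$bins$n_scaffolds, nrow(truth$scaffolds))
})

test_that("coverage alone separates genomes with identical GC and shared label", {
  d <- two_genome_profiles(gc = c(0.50, 0.50), abund = c(20 / 21, 1 / 21),
                           depth = 42, labels = c("Tax", "Tax"))
  bins <- preliminary_bins(d$profiles)
  expect_equal(nrow(bins$bins), 2)
  mem <- bins$membership
  mem$genome <- genome_of(d$truth, mem$scaffold_id)
  expect_true(all(tapply(mem$genome, mem$bin_id,
                         function(g) max(table(g)) / length(g)) >= 0.95))
})

test_that("unlabeled profiles fall back to density clustering with a warning", {
  d <- two_genome_profiles()
  p <- d$profiles
  p$taxonomy_label <- NA_character_
  expect_warning(bins <- preliminary_bins(p), "unlabeled")
  expect_equal(nrow(bins$bins), 2)
})

test_that("screen applies the strict >90% paired-read rule", {
  d <- two_genome_profiles()
  bins <- preliminary_bins(d$profiles)
  p <- d$profiles
  # force exact paired fractions on three scaffolds of one bin
  scf <- bins$membership$scaffold_id[bins$membership$bin_id == "bin01"][1:3]
  p$paired_fraction[match(scf, p$scaffold_id)] <- c(0.85, 0.90, 0.95)
  rep <- screen_scaffolds(bins, p)
  verdict <- rep[match(scf, rep$scaffold_id), ]
  expect_equal(verdict$accepted, c(FALSE, FALSE, TRUE))
  expect_equal(verdict$reason, c("paired_fraction", "paired_fraction", NA))
  # undefined paired fraction rejects too
  p$paired_fraction[match(scf[3], p$scaffold_id)] <- NA
  rep2 <- screen_scaffolds(bins, p)
  expect_equal(rep2$reason[match(scf[3], rep2$scaffold_id)], "paired_fraction")
  # report partitions its input
  expect_setequal(rep$scaffold_id, bins$membership$scaffold_id)
  expect_equal(sum(rep$accepted) + sum(!rep$accepted), nrow(rep))
})

test_that("screen flags GC, coverage, composition and taxonomy outliers", {
  d <- two_genome_profiles()
  bins <- preliminary_bins(d$profiles)
  p <- d$profiles
  in_bin1 <- bins$membership$scaffold_id[bins$membership$bin_id == "bin01"]
  s <- in_bin1[1:4]
  p$gc_percent[match(s[1], p$scaffold_id)] <-
    p$gc_percent[match(s[1], p$scaffold_id)] + 8
  p$coverage[match(s[2], p$scaffold_id)] <-
    p$coverage[match(s[2], p$scaffold_id)] * 5
  p$tnf[[match(s[3], p$scaffold_id)]] <-
    rev(p$tnf[[match(s[3], p$scaffold_id)]])
  p$taxonomy_label[match(s[4], p$scaffold_id)] <- "SomethingElse"
  rep <- screen_scaffolds(bins, p)
  expect_equal(rep$reason[match(s, rep$scaffold_id)],
               c("gc_outlier", "coverage_outlier", "composition_outlier",
                 "taxonomy_conflict"))
})

test_that("host-contaminant scaffolds planted into a bin are composition outliers", {
  d <- two_genome_profiles(host_fraction = 0.15, seed = 13)
  host_scf <- d$truth$scaffolds$scaffold_id[
    d$truth$scaffolds$genome_id == "host"][1:2]
  prof <- d$profiles
  # plant the host scaffolds into the bacterial bin with benign stats
  bins <- preliminary_bins(prof)
  b1 <- bins$bins$bin_id[1]
  b1_scf <- bins$membership$scaffold_id[bins$membership$bin_id == b1]
  med_gc <- median(prof$gc_percent[prof$scaffold_id %in% b1_scf])
  med_cov <- median(prof$coverage[prof$scaffold_id %in% b1_scf])
  rows <- match(host_scf, prof$scaffold_id)
  prof$gc_percent[rows] <- med_gc
  prof$coverage[rows] <- med_cov
  prof$taxonomy_label[rows] <- NA
  bins$membership <- dplyr::bind_rows(
    bins$membership, tibble::tibble(bin_id = b1, scaffold_id = host_scf))
  rep <- screen_scaffolds(bins, prof)
  expect_true(all(rep$reason[match(host_scf, rep$scaffold_id)] ==
                    "composition_outlier"))
})

test_that("refinement converges, is monotone, and drops to a clean bin set", {
  d <- two_genome_profiles()
  bins <- preliminary_bins(d$profiles)
  # clean bins converge in one round with zero rejections
  ref <- refine_bins(bins, d$profiles)
  expect_true(all(ref$bins$status == "screened"))
  log <- attr(ref, "screen_log")
  expect_equal(max(log$round), 1)
  expect_true(all(log$accepted))
  # max_rounds = 1 equals a single screen application
  p <- d$profiles
  bad <- bins$membership$scaffold_id[1:2]
  p$paired_fraction[match(bad, p$scaffold_id)] <- 0.5
  one <- refine_bins(bins, p, max_rounds = 1)
  single <- screen_scaffolds(bins, p)
  expect_setequal(
    setdiff(bins$membership$scaffold_id, one$membership$scaffold_id),
    single$scaffold_id[!single$accepted])
  # contaminated bin: planted contaminants are gone by round 2, purity >= 0.99
  d2 <- two_genome_profiles(seed = 77)
  bins2 <- preliminary_bins(d2$profiles)
  b1 <- bins2$bins$bin_id[1]
  b2_scf <- bins2$membership$scaffold_id[bins2$membership$bin_id != b1][1:2]
  contaminated <- bins2
  contaminated$membership <- dplyr::bind_rows(
    dplyr::filter(bins2$membership, .data$bin_id == b1),
    tibble::tibble(bin_id = b1, scaffold_id = b2_scf))
  contaminated$bins <- contaminated$bins[contaminated$bins$bin_id == b1, ]
  ref2 <- refine_bins(contaminated, d2$profiles, max_rounds = 3)
  kept <- ref2$membership$scaffold_id
  purity <- mean(genome_of(d2$truth, kept) == "g01")
  expect_gte(purity, 0.99)
  # monotone: accepted set never grew
  expect_true(all(kept %in% contaminated$membership$scaffold_id))
})

test_that("marker tallies match brute-force counts, including duplicates", {
  truth <- tiny_community(n_marker_families = 100, genome_length = 150000)
  reads <- simulate_reads(truth)
  prof <- profile_community(truth, reads)
  bins <- preliminary_bins(prof)
  marker_set <- sprintf("m%03d", 1:100)
  ann <- dplyr::select(truth$marker_loci, "scaffold_id", "family")
  qc <- marker_qc(bins, ann, marker_set)
  for (b in qc$bin_id) {
    scf <- bins$membership$scaffold_id[bins$membership$bin_id == b]
    obs <- ann$family[ann$scaffold_id %in% scf]
    oracle <- oracle_marker_tally(obs, marker_set)
    expect_equal(qc$completeness[qc$bin_id == b], oracle[["completeness"]])
    expect_equal(qc$contamination[qc$bin_id == b], oracle[["contamination"]])
  }
  # a complete single-copy bin, then one duplicated family
  all_mem <- tibble::tibble(bin_id = "all",
                            scaffold_id = truth$scaffolds$scaffold_id)
  whole <- bins
  whole$membership <- all_mem
  whole$bins <- tibble::tibble(
    bin_id = "all", taxonomy_label = NA, n_scaffolds = nrow(all_mem),
    total_length = 1, gc_mean = 1, gc_sd = 0, coverage_median = 1,
    status = "preliminary")
  ann1 <- ann[ann$scaffold_id %in%
                truth$scaffolds$scaffold_id[truth$scaffolds$genome_id == "g01"], ]
  qc1 <- marker_qc(whole, ann1, marker_set)
  expect_equal(qc1$completeness, 100)
  expect_equal(qc1$contamination, 0)
  dup <- dplyr::bind_rows(ann1, ann1[1, ])
  qc2 <- marker_qc(whole, dup, marker_set)
  expect_equal(qc2$completeness, 100)
  expect_equal(qc2$contamination, 1)
  half <- ann1[match(sprintf("m%03d", 1:50), ann1$family), ]
  expect_equal(marker_qc(whole, half, marker_set)$completeness, 50)
  expect_error(marker_qc(whole, tibble::tibble(scaffold_id = "x",
                                               family = "nope"),
                         marker_set), "unknown")
})

test_that("bin summaries and tidy methods mirror the bin table", {
  d <- two_genome_profiles()
  bins <- preliminary_bins(d$profiles)
  s <- bin_summary(bins)
  expect_setequal(s$bin_id, bins$bins$bin_id)
  expect_equal(s$total_length, bins$bins$total_length)
  expect_equal(tidy(bins), s)
  g <- glance(bins)
  expect_equal(g$n_bins, nrow(bins$bins))
})
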