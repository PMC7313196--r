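mapped_community <- function(..., min_identity = 100) {
  truth <- tiny_community(...)
  reads <- simulate_reads(truth)
  idx <- build_read_index(tibble::tibble(id = truth$scaffolds$scaffold_id,
                                         seq = truth$scaffolds$seq))
  aln <- map_reads(reads, idx, min_identity)
  bins <- tibble::tibble(
    bin_id = truth$scaffolds$genome_id,
    scaffold_id = truth$scaffolds$scaffold_id,
    taxon_group = truth$scaffolds$genome_id)
  list(truth = truth, reads = reads, aln = aln,
       bins = bins[bins$bin_id != "host", ])
}

test_that("read recruitment recovers a 50/50 community and normalizes", {
  d <- mapped_community(genome_length = 60000, depth_total = 40, seed = 3)
  ab <- metagenomic_abundance(d$aln, d$bins)
  cl <- ab[ab$metric == "read_recruitment_classified", ]
  expect_equal(sum(cl$relative_abundance), 1, tolerance = 1e-9)
  expect_true(all(abs(cl$relative_abundance - 0.5) < 0.01))
  tot <- ab[ab$metric == "read_recruitment_total", ]
  expect_equal(sum(tot$relative_abundance), 1, tolerance = 1e-9)
  expect_error(
    metagenomic_abundance(d$aln, dplyr::bind_rows(d$bins, d$bins[1, ])),
    "overlap")
})

test_that("read-based shares under-represent small genomes by length weighting", {
  # equal cell abundance, genome sizes 30 kb vs 60 kb: expected shares 1/3, 2/3
  truth <- generate_genomes(tiny_config(seed = 21, genome_length = 30000))
  withr::with_seed(22, {
    extra <- paste(sample(c("A", "C", "G", "T"), 30000, TRUE), collapse = "")
  })
  truth$genomes$seq[2] <- paste0(truth$genomes$seq[2], extra)
  truth <- fragment_genomes(truth, min_len = 5000, mean_len = 10000)
  # coverage equal for both (equal abundance): reads scale with length
  reads <- simulate_reads(truth)
  idx <- build_read_index(tibble::tibble(id = truth$scaffolds$scaffold_id,
                                         seq = truth$scaffolds$seq))
  aln <- map_reads(reads, idx, 100)
  bins <- tibble::tibble(bin_id = truth$scaffolds$genome_id,
                         scaffold_id = truth$scaffolds$scaffold_id,
                         taxon_group = truth$scaffolds$genome_id)
  ab <- metagenomic_abundance(aln, bins)
  cl <- ab[ab$metric == "read_recruitment_classified", ]
  expect_lt(abs(cl$relative_abundance[cl$taxon_group == "g01"] - 1 / 3), 0.02)
  expect_lt(abs(cl$relative_abundance[cl$taxon_group == "g02"] - 2 / 3), 0.02)
})

test_that("ASVs are assigned at the identity floor and pooled when below it", {
  truth <- tiny_community(seed = 5)
  ssu <- truth$ssu_loci
  refs <- tibble::tibble(id = paste0(ssu$genome_id, "_ssu"), seq = ssu$seq,
                         taxon_group = ssu$genome_id)
  amp <- simulate_amplicons(truth, n_reads = 10000)
  ab <- amplicon_abundance(amp, refs)
  asn <- attr(ab, "asv_assignment")
  # exact planted subsequences match their own genome
  expect_equal(asn$taxon_group[match(amp$asv_id, asn$asv_id)],
               amp$genome_id)
  expect_equal(sum(ab$relative_abundance), 1, tolerance = 1e-6)
  # an ASV at ~96% identity to its nearest reference stays unassigned
  seq96 <- amp$sequence[1]
  ch <- strsplit(seq96, "")[[1]]
  withr::with_seed(6, pos <- sample(length(ch), ceiling(length(ch) * 0.04)))
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  amp2 <- tibble::tibble(sample_id = "S1", asv_id = "mut",
                         sequence = paste(ch, collapse = ""), count = 10)
  ab2 <- amplicon_abundance(amp2, refs)
  expect_equal(attr(ab2, "asv_assignment")$taxon_group, "unassigned")
  expect_equal(ab2$relative_abundance[ab2$taxon_group == "unassigned"], 1)
  # empty table gives empty output
  expect_equal(nrow(amplicon_abundance(amp[0, ], refs)), 0)
})

test_that("per-sample normalization compensates for unequal amplicon yields", {
  truth <- tiny_community(seed = 8)
  ssu <- truth$ssu_loci
  refs <- tibble::tibble(id = paste0(ssu$genome_id, "_ssu"), seq = ssu$seq,
                         taxon_group = ssu$genome_id)
  a1 <- simulate_amplicons(truth, n_reads = 30000, sample_id = "big")
  a2 <- simulate_amplicons(truth, n_reads = 3000, sample_id = "small",
                           seed = 100)
  ab <- amplicon_abundance(dplyr::bind_rows(a1, a2), refs)
  sums <- tapply(ab$relative_abundance, ab$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
})

test_that("environmental match filters behave exactly at their cutoffs", {
  withr::with_seed(11, {
    ref <- paste(sample(c("A", "C", "G", "T"), 1500, TRUE), collapse = "")
  })
  refs <- tibble::tibble(id = "ref", seq = ref)
  # full-length identical pair is retained with identity 100
  full <- environmental_match(tibble::tibble(id = "q", seq = ref), refs)
  expect_equal(nrow(full), 1)
  expect_equal(full$identity, 100)
  expect_equal(full$align_len, 1500)
  expect_lt(full$evalue, 1e-7)
  # 359 nt alignment dropped, 360 nt retained
  q359 <- tibble::tibble(id = "q", seq = substr(ref, 100, 458))
  q360 <- tibble::tibble(id = "q", seq = substr(ref, 100, 459))
  expect_equal(nrow(environmental_match(q359, refs)), 0)
  expect_equal(nrow(environmental_match(q360, refs)), 1)
  # identity tiers: a ~95% match fails the species tier, passes the genus tier
  ch <- strsplit(ref, "")[[1]]
  withr::with_seed(12, pos <- sample(1500, 75))
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  q95 <- tibble::tibble(id = "q", seq = paste(ch, collapse = ""))
  expect_equal(nrow(environmental_match(q95, refs, min_identity = 97)), 0)
  expect_equal(nrow(environmental_match(q95, refs, min_identity = 95)), 1)
  # filter composition commutes: same result regardless of filter order
  loose <- environmental_match(q95, refs, min_align_len = 1,
                               max_evalue = Inf, min_identity = 1)
  strict <- loose[loose$align_len >= 360 & loose$evalue <= 1e-7 &
                    loose$identity >= 95, ]
  direct <- environmental_match(q95, refs, min_identity = 95)
  expect_equal(strict$identity, direct$identity)
})

test_that("metric concordance is perfect for a copy-balanced community", {
  d <- mapped_community(genome_length = 60000, depth_total = 40,
                        abundances = c(0.7, 0.3), seed = 9)
  meta <- metagenomic_abundance(d$aln, d$bins)
  ssu <- d$truth$ssu_loci
  refs <- tibble::tibble(id = paste0(ssu$genome_id, "_ssu"), seq = ssu$seq,
                         taxon_group = ssu$genome_id)
  amp_tab <- simulate_amplicons(d$truth, n_reads = 20000)
  amp <- amplicon_abundance(amp_tab, refs)
  comp <- compare_metrics(dplyr::bind_rows(meta, amp))
  expect_equal(attr(comp, "rank_correlation")$rho, 1)
  expect_true(all(abs(comp$difference) < 0.05))
  # single-metric input is skipped with a warning
  expect_warning(expect_null(compare_metrics(meta)), "skipped")
})

test_that("multi-copy 16S inflates the amplicon share about copy-fold", {
  truth <- tiny_community(n_16s_copies = c(1, 4), seed = 10)
  ssu <- truth$ssu_loci
  refs <- tibble::tibble(id = paste0(ssu$genome_id, "_", ssu$copy),
                         seq = ssu$seq, taxon_group = ssu$genome_id)
  amp <- amplicon_abundance(simulate_amplicons(truth, n_reads = 50000), refs)
  share <- amp$relative_abundance[amp$taxon_group == "g02"]
  # single-copy expectation is 0.5; 4 copies inflate it to ~4x before
  # correction (0.8 = 4 * 0.5 / (1 * 0.5 + 4 * 0.5))
  expect_lt(abs(share / 0.2 - 4), 0.4)
})
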