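test_that("index construction validates its input", {
  scf <- tibble::tibble(id = c("a", "a"), seq = c("ACGTACGTACGTACGT", "ACGT"))
  expect_error(build_read_index(scf), "duplicate")
  expect_error(build_read_index(scf[1, ], k = 8), ">= 11")
  expect_warning(
    build_read_index(tibble::tibble(id = "a", seq = "ACGTACGTAC"), k = 16),
    "empty")
})

test_that("error-free reads all map back to their scaffold of origin", {
  truth <- tiny_community(genome_length = 40000)
  reads <- simulate_reads(truth)
  idx <- build_read_index(tibble::tibble(id = truth$scaffolds$scaffold_id,
                                         seq = truth$scaffolds$seq))
  aln <- map_reads(reads, idx, min_identity = 100)
  expect_true(all(!is.na(aln$scaffold_id)))
  org <- reads$read_origin
  key <- paste(org$read_id, org$mate)
  truth_scf <- setNames(org$scaffold_id, key)
  expect_true(all(aln$scaffold_id == truth_scf[paste(aln$read_id, aln$mate)]))
  # positions agree with the generator's ground truth
  truth_pos <- setNames(org$position, key)
  expect_true(all(aln$position == truth_pos[paste(aln$read_id, aln$mate)]))
})

test_that("identity floor separates one-substitution reads exactly", {
  withr::with_seed(31, {
    scf <- tibble::tibble(id = "s1", seq = paste(
      sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = ""))
  })
  idx <- build_read_index(scf)
  clean <- substr(scf$seq, 101, 200)
  ch <- strsplit(clean, "")[[1]]
  ch[50] <- setdiff(c("A", "C", "G", "T"), ch[50])[1]
  dirty <- paste(ch, collapse = "")
  reads <- tibble::tibble(read_id = c("ok", "sub"), mate = 1L,
                          seq = c(clean, dirty))
  at100 <- map_reads(reads, idx, min_identity = 100)
  expect_equal(at100$scaffold_id, c("s1", NA))
  at99 <- map_reads(reads, idx, min_identity = 99)
  expect_equal(at99$scaffold_id, c("s1", "s1"))
  expect_equal(at99$identity, c(100, 99))
  expect_equal(at99$position, c(100L, 100L))
})

test_that("exact mapping rate under substitution errors matches (1-e)^L", {
  truth <- tiny_community(error_rate = 0.01, depth_total = 60,
                          genome_length = 50000, seed = 17)
  reads <- simulate_reads(truth)
  idx <- build_read_index(tibble::tibble(id = truth$scaffolds$scaffold_id,
                                         seq = truth$scaffolds$seq))
  aln <- map_reads(reads, idx, min_identity = 100)
  expect_gt(nrow(aln), 10000)
  expect_lt(abs(mean(!is.na(aln$scaffold_id)) - 0.99^100), 0.02)
})

test_that("ties break deterministically to the lowest scaffold/position", {
  seg <- strrep("ACGTGGCCTTAAGGCCAATT", 5)  # 100 bp, repeated on two scaffolds
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  withr::with_seed(32, {
    scf <- tibble::tibble(
      id = c("sA", "sB"),
      seq = c(paste0(pad(500), seg, pad(400)), paste0(pad(200), seg, pad(700))))
  })
  reads <- tibble::tibble(read_id = "r", mate = 1L, seq = seg)
  aln <- map_reads(reads, build_read_index(scf), 100)
  expect_equal(aln$scaffold_id, "sA")
  expect_equal(aln$position, 500L)
  expect_true(aln$ambiguous)
})

test_that("empty reads are skipped with a warning", {
  scf <- tibble::tibble(id = "s", seq = strrep("ACGT", 100))
  reads <- tibble::tibble(read_id = c("a", "b"), mate = 1L,
                          seq = c("", substr(scf$seq, 1, 40)))
  expect_warning(aln <- map_reads(reads, build_read_index(scf)), "empty")
  expect_equal(nrow(aln), 1)
})

test_that("pair recruitment completes mates and is idempotent", {
  truth <- tiny_community(genome_length = 40000, singleton_rate = 0.1,
                          seed = 19)
  reads <- simulate_reads(truth)
  idx <- build_read_index(tibble::tibble(id = truth$scaffolds$scaffold_id,
                                         seq = truth$scaffolds$seq))
  aln <- map_reads(reads, idx, 100)
  bin_scf <- truth$scaffolds$scaffold_id[truth$scaffolds$genome_id == "g01"]
  rec <- recruit_pairs(aln, bin_scf, reads, bin_id = "g01")
  # both mates present whenever both exist in input
  both_in_input <- intersect(reads$r1$id, reads$r2$id)
  ids <- rec$recruited_read_ids
  expect_setequal(intersect(rec$r1$id, both_in_input),
                  intersect(rec$r2$id, both_in_input))
  # conservation: total emitted = 2 * complete pairs + true singletons
  expect_equal(nrow(rec$r1) + nrow(rec$r2),
               2 * rec$n_pairs_complete + rec$n_true_singletons)
  # precision: recruited reads originate from the bin genome
  org <- reads$read_origin
  origin_of <- setNames(org$genome_id, paste(org$read_id, org$mate))
  prec <- mean(c(origin_of[paste(rec$r1$id, 1)],
                 origin_of[paste(rec$r2$id, 2)]) == "g01", na.rm = TRUE)
  expect_gte(prec, 0.99)
  # idempotence: recruiting from the recruited set returns the same set
  aln2 <- map_reads(list(r1 = rec$r1, r2 = rec$r2), idx, 100)
  rec2 <- recruit_pairs(aln2, bin_scf, list(r1 = rec$r1, r2 = rec$r2))
  expect_setequal(rec2$recruited_read_ids, rec$recruited_read_ids)
})

test_that("mate rescue is counted and unmappable pairs are excluded", {
  scf <- tibble::tibble(id = "s", seq = strrep("ACGTTGCAAC", 200))
  idx <- build_read_index(scf)
  r1 <- tibble::tibble(id = c("p1", "p2"),
                       seq = c(substr(scf$seq, 1, 100), strrep("A", 100)))
  r2 <- tibble::tibble(id = c("p1", "p2"),
                       seq = c(strrep("C", 100), strrep("G", 100)))
  aln <- map_reads(list(r1 = r1, r2 = r2), idx, 100)
  rec <- recruit_pairs(aln, "s", list(r1 = r1, r2 = r2))
  # p1: R1 maps, R2 rescued; p2: neither maps, absent
  expect_setequal(rec$recruited_read_ids, "p1")
  expect_equal(rec$n_pairs_complete, 1)
  expect_equal(rec$n_mates_rescued, 1)
  expect_equal(rec$r2$id, "p1")
})
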