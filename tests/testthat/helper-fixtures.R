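# small communities and hand-built alignment records used across tests

tiny_config <- function(n_genomes = 2, genome_length = 30000,
                        gc_targets = c(0.40, 0.60),
                        abundances = c(0.5, 0.5),
                        labels = c("TaxA", "TaxB"),
                        host_fraction = 0, n_marker_families = 10,
                        n_16s_copies = 1, depth_total = 20,
                        error_rate = 0, singleton_rate = 0, seed = 42, ...) {
  community_config(
    n_genomes = n_genomes, genome_length = genome_length,
    gc_targets = gc_targets, abundances = abundances, labels = labels,
    host_fraction = host_fraction, n_marker_families = n_marker_families,
    n_16s_copies = n_16s_copies, depth_total = depth_total,
    error_rate = error_rate, singleton_rate = singleton_rate, seed = seed, ...
  )
}

tiny_community <- function(..., min_len = 5000, mean_len = 10000) {
  truth <- generate_genomes(tiny_config(...))
  fragment_genomes(truth, min_len = min_len, mean_len = mean_len)
}

# alignment records with a chosen number of paired / singleton reads
manual_alignments <- function(scaffold_id, n_paired, n_singleton,
                              aligned_length = 100) {
  n <- n_paired + n_singleton
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    mate = 1L,
    scaffold_id = scaffold_id,
    position = seq_len(n) - 1L,
    aligned_length = aligned_length,
    identity = 100,
    pair_status = rep(c("paired", "singleton"), c(n_paired, n_singleton))
  )
}

truth_labels <- function(truth) {
  lab <- tibble::tibble(
    scaffold_id = truth$scaffolds$scaffold_id,
    taxonomy_label = truth$genomes$label[
      match(truth$scaffolds$genome_id, truth$genomes$genome_id)]
  )
  lab[!is.na(lab$taxonomy_label), ]
}

profile_community <- function(truth, reads = NULL, min_identity = 100,
                              min_len = 5000) {
  scf <- tibble::tibble(scaffold_id = truth$scaffolds$scaffold_id,
                        seq = truth$scaffolds$seq)
  aln <- NULL
  if (!is.null(reads)) {
    idx <- build_read_index(scf)
    aln <- annotate_pair_status(map_reads(reads, idx, min_identity))
  }
  profile_scaffolds(scf, aln, truth_labels(truth), min_len = min_len)
}

two_genome_profiles <- function(gc = c(0.35, 0.60), depth = 20,
                                abund = c(0.5, 0.5), labels = c("TaxA", "TaxB"),
                                host_fraction = 0, seed = 42) {
  truth <- tiny_community(gc_targets = gc, abundances = abund, labels = labels,
                          depth_total = depth, host_fraction = host_fraction,
                          genome_length = 60000, seed = seed)
  reads <- simulate_reads(truth)
  list(truth = truth, reads = reads,
       profiles = profile_community(truth, reads))
}

genome_of <- function(truth, scaffold_ids) {
  truth$scaffolds$genome_id[match(scaffold_ids, truth$scaffolds$scaffold_id)]
}
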