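#' Configure a synthetic holobiont community
#'
#' Defines the study conditions for the seeded community generator: a small
#' number of bacterial genomes spanning a wide GC and abundance range, one
#' dominant high-coverage member, optional host-like contaminant scaffolds of
#' distinct nucleotide composition, planted single-copy marker loci and
#' multi-copy 16S rRNA genes, paired-end reads with a controllable
#' singleton-mate rate, and a V4-V5-style amplicon pool.
#'
#' Defaults describe a 6-member community of 200 kb genomes at GC 30-62%,
#' relative abundances 0.5-60% and 20-fold pooled depth, i.e. a low-diversity
#' cyanobacterium-dominated sponge holobiont at desk scale. `depth_total` is
#' the summed fold-coverage over community members, so each genome's expected
#' coverage is `depth_total * abundance` (coverage tracks relative abundance).
#'
#' @param n_genomes Number of bacterial genomes.
#' @param genome_length Genome length in bases (scalar, recycled).
#' @param gc_targets Target GC fractions in `[0, 1]`, one per genome.
#' @param abundances Relative cell abundances, one per genome, summing to 1.
#' @param labels Phylum/class-level taxonomy labels per genome (the pluggable
#'   stand-in for protein-homology classification of scaffolds).
#' @param read_length Read length in bases for both mates.
#' @param insert_mean,insert_sd Fragment insert size model (Normal, truncated
#'   below at `read_length`).
#' @param depth_total Summed expected fold-coverage across genomes.
#' @param singleton_rate Expected fraction of emitted reads whose mate was
#'   discarded before output (the community-wide singleton fraction).
#' @param error_rate Per-base substitution probability.
#' @param n_16s_copies 16S rRNA gene copies planted per genome (recycled).
#' @param host_fraction Approximate fraction of community scaffolds that are
#'   host-like contaminant (distinct dinucleotide bias, coverage matched to a
#'   mid-abundance bacterium). 0 disables the contaminant.
#' @param n_marker_families,marker_length Size of the synthetic single-copy
#'   marker set designated per genome.
#' @param ssu_length Length of the planted 16S template.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated `community_config` object (a list).
#' @export
community_config <- function(n_genomes = 6,
                             genome_length = 200000,
                             gc_targets = c(0.47, 0.40, 0.58, 0.52, 0.62, 0.30),
                             abundances = c(0.600, 0.200, 0.100, 0.060, 0.035, 0.005),
                             labels = c("Cyanobacteria", "Bacteroidetes",
                                        "Alphaproteobacteria", "Alphaproteobacteria",
                                        "Gammaproteobacteria", "Oligoflexia"),
                             read_length = 100,
                             insert_mean = 300,
                             insert_sd = 50,
                             depth_total = 20,
                             singleton_rate = 0.02,
                             error_rate = 0.002,
                             n_16s_copies = 2,
                             host_fraction = 0.1,
                             n_marker_families = 100,
                             marker_length = 900,
                             ssu_length = 1500,
                             seed = 1L) {
  if (length(gc_targets) != n_genomes || length(abundances) != n_genomes) {
    abort("gc_targets and abundances must have length n_genomes")
  }
  if (abs(sum(abundances) - 1) > 1e-9) {
    abort("abundances must sum to 1 (within 1e-9)")
  }
  rates <- c(gc_targets, abundances, singleton_rate, error_rate, host_fraction)
  if (any(rates < 0 | rates > 1)) abort("all rates/fractions must lie in [0, 1]")
  if (length(labels) != n_genomes) labels <- rep_len(labels, n_genomes)
  cfg <- list(
    n_genomes = as.integer(n_genomes),
    genome_length = as.integer(genome_length),
    gc_targets = as.numeric(gc_targets),
    abundances = as.numeric(abundances),
    labels = as.character(labels),
    read_length = as.integer(read_length),
    insert_mean = as.numeric(insert_mean),
    insert_sd = as.numeric(insert_sd),
    depth_total = as.numeric(depth_total),
    singleton_rate = as.numeric(singleton_rate),
    error_rate = as.numeric(error_rate),
    n_16s_copies = as.integer(rep_len(n_16s_copies, n_genomes)),
    host_fraction = as.numeric(host_fraction),
    n_marker_families = as.integer(n_marker_families),
    marker_length = as.integer(marker_length),
    ssu_length = as.integer(ssu_length),
    seed = as.integer(seed)
  )
  structure(cfg, class = "community_config")
}

#' @export
print.community_config <- function(x, ...) {
  cat("<community_config> ", x$n_genomes, " genomes x ", x$genome_length,
      " bp, depth ", x$depth_total, "x, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

# iid nucleotides at a target GC fraction
random_dna <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# first-order Markov sequence with strong same-base runs: the host-like
# contaminant's dinucleotide bias, separable from iid bacteria in TNF space
markov_dna <- function(n, gc = 0.42, self = 0.55) {
  p0 <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  trans <- matrix(0, 4, 4)
  for (i in 1:4) {
    rest <- p0[-i] / sum(p0[-i]) * (1 - self)
    trans[i, -i] <- rest
    trans[i, i] <- self
  }
  out <- integer(n)
  out[1] <- sample.int(4, 1, prob = p0)
  u <- runif(n)
  for (i in 2:n) {
    out[i] <- findInterval(u[i], cumsum(trans[out[i - 1], ])) + 1L
  }
  paste(BASES[pmin(out, 4L)], collapse = "")
}

mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1), "")
  }
  paste(ch, collapse = "")
}

#' Generate community genomes with planted loci
#'
#' Draws each genome independently as i.i.d. nucleotides at its target GC
#' (genomes are mutually non-homologous outside planted loci), designates a
#' single-copy marker set (`n_marker_families` spans of `marker_length` bp),
#' and plants `n_16s_copies` copies of a per-genome 16S template (copies
#' within a genome >= 99% identical, templates between genomes unrelated).
#' When `host_fraction > 0` an additional host-like contaminant sequence with
#' a distinct dinucleotide bias is generated.
#'
#' @param config A [community_config()].
#' @return A `community_truth` object: list with `genomes` (tibble:
#'   `genome_id`, `seq`, `gc_target`, `label`, `abundance`, `is_host`),
#'   `marker_loci`, `ssu_loci` (tibbles of planted spans, 1-based inclusive
#'   genome coordinates), `true_abundance`, and the `config`.
#' @export
generate_genomes <- function(config) {
  stopifnot(inherits(config, "community_config"))
  withr::with_seed(config$seed, generate_genomes_impl(config))
}

generate_genomes_impl <- function(cfg) {
  ids <- sprintf("g%02d", seq_len(cfg$n_genomes))
  L <- cfg$genome_length
  genomes <- character(cfg$n_genomes)
  marker_loci <- list()
  ssu_loci <- list()
  for (i in seq_len(cfg$n_genomes)) {
    seq <- random_dna(L, cfg$gc_targets[i])
    # non-overlapping slots for markers + 16S copies, evenly spread
    n_loci <- cfg$n_marker_families + cfg$n_16s_copies[i]
    lens <- c(rep(cfg$marker_length, cfg$n_marker_families),
              rep(cfg$ssu_length, cfg$n_16s_copies[i]))
    if (sum(lens) > L) abort("genome_length too small for planted loci")
    ord <- sample.int(n_loci)  # shuffle marker/16S placement order
    lens <- lens[ord]
    gap_total <- L - sum(lens)
    gaps <- floor(gap_total * diff(c(0, sort(runif(n_loci)), 1)))
    starts <- cumsum(gaps[seq_len(n_loci)] + c(0, lens[-n_loci])) + 1L
    ends <- starts + lens - 1L
    is_ssu <- ord > cfg$n_marker_families
    fam <- integer(n_loci)
    fam[!is_ssu] <- ord[!is_ssu]
    fam[is_ssu] <- ord[is_ssu] - cfg$n_marker_families
    # plant 16S copies: per-genome template, per-copy light mutation (>=99% id)
    if (any(is_ssu)) {
      template <- random_dna(cfg$ssu_length, cfg$gc_targets[i])
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      for (j in which(is_ssu)) {
        copy <- mutate_dna(template, 0.002)
        ch[starts[j]:ends[j]] <- strsplit(copy, "", fixed = TRUE)[[1]]
      }
      seq <- paste(ch, collapse = "")
    }
    genomes[i] <- seq
    marker_loci[[i]] <- tibble(
      genome_id = ids[i],
      family = sprintf("m%03d", fam[!is_ssu]),
      start = starts[!is_ssu], end = ends[!is_ssu]
    )
    ssu_loci[[i]] <- tibble(
      genome_id = ids[i],
      copy = seq_len(sum(is_ssu)),
      start = starts[is_ssu][order(fam[is_ssu])],
      end = ends[is_ssu][order(fam[is_ssu])]
    )
  }
  gen_tbl <- tibble(
    genome_id = ids, seq = genomes,
    gc_target = cfg$gc_targets, label = cfg$labels,
    abundance = cfg$abundances, is_host = FALSE
  )
  if (cfg$host_fraction > 0) {
    host_len <- as.integer(round(
      L * cfg$n_genomes * cfg$host_fraction / (1 - cfg$host_fraction)))
    gen_tbl <- bind_rows(gen_tbl, tibble(
      genome_id = "host", seq = markov_dna(host_len),
      gc_target = 0.42, label = NA_character_,
      abundance = NA_real_, is_host = TRUE
    ))
  }
  ssu <- bind_rows(ssu_loci)
  ssu$seq <- substr(gen_tbl$seq[match(ssu$genome_id, gen_tbl$genome_id)],
                    ssu$start, ssu$end)
  structure(list(
    genomes = gen_tbl,
    marker_loci = bind_rows(marker_loci),
    ssu_loci = ssu,
    true_abundance = tibble(genome_id = ids, abundance = cfg$abundances),
    scaffolds = NULL,
    config = cfg
  ), class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("<community_truth> ", sum(!x$genomes$is_host), " genomes",
      if (any(x$genomes$is_host)) " + host contaminant", sep = "")
  if (!is.null(x$scaffolds)) cat("; ", nrow(x$scaffolds), " scaffolds", sep = "")
  cat("\n")
  invisible(x)
}

#' Fragment genomes into scaffolds
#'
#' Partitions each genome (and the host contaminant, if present) into
#' contiguous, non-overlapping scaffolds covering it exactly, all of length
#' at least `min_len`. Planted marker and 16S loci are re-mapped to the
#' scaffold containing their midpoint.
#'
#' @param truth A `community_truth` from [generate_genomes()].
#' @param min_len Minimum scaffold length (downstream binning conventionally
#'   considers scaffolds above 10 kb).
#' @param mean_len Target mean scaffold length; must satisfy
#'   `min_len <= mean_len <= genome length`.
#' @param seed Integer seed.
#' @return The `community_truth` with a `scaffolds` tibble (`scaffold_id`,
#'   `genome_id`, `start`, `end`, `length`, `seq`) and scaffold-mapped
#'   `marker_loci` / `ssu_loci`.
#' @export
fragment_genomes <- function(truth, min_len = 10000, mean_len = 20000,
                             seed = truth$config$seed + 1L) {
  stopifnot(inherits(truth, "community_truth"))
  if (!(mean_len >= min_len && min_len > 0)) {
    abort("require mean_len >= min_len > 0")
  }
  if (any(mean_len > nchar(truth$genomes$seq[!truth$genomes$is_host]))) {
    abort("mean_len exceeds a genome length")
  }
  withr::with_seed(seed, {
    scf <- purrr::pmap(truth$genomes, function(genome_id, seq, ...) {
      L <- nchar(seq)
      n_frag <- max(1L, as.integer(round(L / mean_len)))
      while (n_frag > 1L && n_frag * min_len > L) n_frag <- n_frag - 1L
      # stick-breaking with a guaranteed min_len floor per piece
      if (n_frag == 1L) {
        lens <- L
      } else {
        free <- L - n_frag * min_len
        cuts <- sort(sample.int(free + 1L, n_frag - 1L, replace = TRUE) - 1L)
        lens <- diff(c(0L, cuts, free)) + min_len
      }
      ends <- cumsum(lens)
      starts <- c(1L, head(ends, -1L) + 1L)
      tibble(
        genome_id = genome_id,
        start = starts, end = as.integer(ends),
        length = as.integer(lens),
        seq = substr(rep(seq, n_frag), starts, ends)
      )
    })
  })
  scf <- bind_rows(scf)
  scf$scaffold_id <- sprintf("scf%04d", seq_len(nrow(scf)))
  scf <- select(scf, "scaffold_id", "genome_id", "start", "end", "length", "seq")
  truth$scaffolds <- scf
  truth$marker_loci <- map_loci_to_scaffolds(truth$marker_loci, scf)
  truth$ssu_loci <- map_loci_to_scaffolds(truth$ssu_loci, scf)
  truth
}

# assign each locus to the scaffold containing its midpoint
map_loci_to_scaffolds <- function(loci, scf) {
  if (!nrow(loci)) return(loci)
  mid <- (loci$start + loci$end) %/% 2L
  idx <- purrr::map2_int(loci$genome_id, mid, function(g, m) {
    rows <- which(scf$genome_id == g & scf$start <= m & scf$end >= m)
    rows[1]
  })
  loci$scaffold_id <- scf$scaffold_id[idx]
  loci
}

#' Simulate paired-end reads with ground-truth origins
#'
#' Draws forward-reverse read pairs from the community scaffolds. Expected
#' genome fold-coverage is `depth_total * abundance`; the host contaminant
#' (if present) is sequenced at the median bacterial coverage. Insert sizes
#' are Normal(`insert_mean`, `insert_sd`) truncated to
#' `[read_length, scaffold length]`; R2 is emitted as the reverse complement
#' of the insert's 3' end. A fraction `singleton_rate` of pairs loses one
#' mate; substitution errors are applied at `error_rate`.
#'
#' @param truth A fragmented `community_truth`.
#' @param config Defaults to the truth's config.
#' @param seed Integer seed.
#' @return List with tibbles `r1`, `r2` (`id`, `seq`, `qual`) and
#'   `read_origin` (`read_id`, `mate`, `genome_id`, `scaffold_id`,
#'   `position` 0-based, `emitted`).
#' @export
simulate_reads <- function(truth, config = truth$config,
                           seed = config$seed + 2L) {
  stopifnot(inherits(truth, "community_truth"), !is.null(truth$scaffolds))
  rl <- config$read_length
  if (rl > min(truth$scaffolds$length)) {
    abort("read_length exceeds the shortest scaffold")
  }
  withr::with_seed(seed, simulate_reads_impl(truth, config))
}

simulate_reads_impl <- function(truth, cfg) {
  rl <- cfg$read_length
  gen <- truth$genomes
  glen <- nchar(gen$seq)
  cov <- ifelse(gen$is_host,
                median(cfg$depth_total * cfg$abundances),
                cfg$depth_total * gen$abundance)
  n_pairs <- pmax(0L, as.integer(round(cov * glen / (2 * rl))))
  scf <- truth$scaffolds
  # per-pair scaffold of origin, sampled within genome proportional to length
  pick <- purrr::map2(gen$genome_id, n_pairs, function(g, n) {
    rows <- which(scf$genome_id == g)
    if (!n) return(integer())
    if (length(rows) == 1L) return(rep.int(rows, n))
    sample(rows, n, replace = TRUE, prob = scf$length[rows])
  })
  pick <- unlist(pick)
  n <- length(pick)
  slen <- scf$length[pick]
  insert <- pmin(slen, pmax(rl, round(rnorm(n, cfg$insert_mean, cfg$insert_sd))))
  start <- floor(runif(n) * (slen - insert + 1)) + 1L  # 1-based on scaffold
  r1 <- substr(scf$seq[pick], start, start + rl - 1L)
  end2 <- start + insert - 1L
  r2 <- revcomp(substr(scf$seq[pick], end2 - rl + 1L, end2))
  if (cfg$error_rate > 0) {
    r1 <- add_substitutions(r1, cfg$error_rate)
    r2 <- add_substitutions(r2, cfg$error_rate)
  }
  ids <- sprintf("read%06d", seq_len(n))
  # singleton_rate is the expected fraction of *emitted reads* lacking their
  # mate; a pair loses one mate with probability 2r/(1+r) so that singletons
  # make up r of the emitted records
  drop <- runif(n) < 2 * cfg$singleton_rate / (1 + cfg$singleton_rate)
  drop_mate <- sample(1:2, n, replace = TRUE)
  keep1 <- !(drop & drop_mate == 1L)
  keep2 <- !(drop & drop_mate == 2L)
  qual <- strrep("I", rl)
  origin <- tibble(
    read_id = rep(ids, 2),
    mate = rep(1:2, each = n),
    genome_id = rep(scf$genome_id[pick], 2),
    scaffold_id = rep(scf$scaffold_id[pick], 2),
    position = c(start - 1L, end2 - rl),
    emitted = c(keep1, keep2)
  )
  list(
    r1 = tibble(id = ids[keep1], seq = r1[keep1], qual = qual),
    r2 = tibble(id = ids[keep2], seq = r2[keep2], qual = qual),
    read_origin = filter(origin, .data$emitted)
  )
}

# vectorized substitution errors over a character vector of reads
add_substitutions <- function(reads, rate) {
  if (!length(reads)) return(reads)
  rl <- nchar(reads[1])
  n_err <- rbinom(length(reads), rl, rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(rl, n_err[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @return Character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a 16S amplicon ASV count table
#'
#' Samples `n_reads` amplicons multinomially over the planted 16S copies,
#' each copy weighted by its genome's cell abundance, so a genome's total
#' sampling weight is `abundance * n_16s_copies`: taxa with multiple gene
#' copies are over-represented exactly as in real amplicon data. Each ASV is the exact planted subsequence of the amplified
#' region (per-copy variants within a genome may yield several ASVs).
#'
#' @param truth A `community_truth`.
#' @param region 1-based inclusive interval on the 16S template (default the
#'   V4-V5-style window 516-925).
#' @param n_reads Total amplicon count for the sample.
#' @param sample_id Sample identifier.
#' @param seed Integer seed.
#' @return Tibble (`sample_id`, `asv_id`, `sequence`, `count`, `genome_id`);
#'   `genome_id` is generator truth, not observable in real data.
#' @export
simulate_amplicons <- function(truth, region = c(516, 925), n_reads = 20000,
                               sample_id = "S1", seed = truth$config$seed + 3L) {
  stopifnot(inherits(truth, "community_truth"))
  ssu <- truth$ssu_loci
  tmpl_len <- truth$config$ssu_length
  if (region[1] < 1 || region[2] > tmpl_len || region[1] >= region[2]) {
    abort("amplicon region outside the 16S template coordinates")
  }
  ab <- truth$true_abundance
  w <- ab$abundance[match(ssu$genome_id, ab$genome_id)]  # per-copy weight
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1, n_reads, prob = w))
  })
  amp <- substr(ssu$seq, region[1], region[2])
  out <- tibble(genome_id = ssu$genome_id, sequence = amp, count = counts) |>
    group_by(.data$genome_id, .data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    filter(.data$count > 0) |>
    arrange(dplyr::desc(.data$count))
  out$asv_id <- sprintf("asv%03d", seq_len(nrow(out)))
  tibble(
    sample_id = sample_id,
    asv_id = out$asv_id,
    sequence = out$sequence,
    count = out$count,
    genome_id = out$genome_id
  )
}

#' Simulate proteomes and divergence series
#'
#' Small helpers to exercise the relatedness stage: `simulate_proteome()`
#' draws independent random proteins; `mutate_proteome()` substitutes a
#' fraction of residues, emulating evolutionary divergence at a controlled
#' amino acid distance.
#'
#' @param n Number of proteins.
#' @param length Protein length (residues).
#' @param seed Integer seed.
#' @return Tibble (`id`, `seq`).
#' @export
simulate_proteome <- function(n = 30, length = 200, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(aa, length, replace = TRUE), collapse = "")
    }, "")
  })
  tibble(id = sprintf("p%03d", seq_len(n)), seq = seqs)
}

#' @rdname simulate_proteome
#' @param proteome Tibble (`id`, `seq`).
#' @param rate Fraction of residues substituted.
#' @export
mutate_proteome <- function(proteome, rate, seed = 1L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, {
    seqs <- vapply(proteome$seq, function(s) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      k <- rbinom(1, length(ch), rate)
      if (k > 0) {
        pos <- sample.int(length(ch), k)
        ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(aa, b), 1), "")
      }
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
  })
  tibble(id = proteome$id, seq = seqs)
}
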