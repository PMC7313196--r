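#' Percent GC of nucleotide sequences
#'
#' `100 * (G + C) / (A + C + G + T)`; ambiguity characters are excluded from
#' both numerator and denominator. Vectorized.
#'
#' @param seq Character vector of DNA sequences (or a `DNAStringSet`).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  dna <- as_dna(seq)
  f <- Biostrings::letterFrequency(dna, letters = c("A", "C", "G", "T"))
  denom <- rowSums(f)
  if (any(denom == 0)) {
    abort("gc_percent undefined: sequence has no unambiguous bases")
  }
  unname(100 * (f[, "C"] + f[, "G"]) / denom)
}

# canonical k-mer classes: each k-mer pooled with its reverse complement;
# for k = 4 this gives 136 classes (16 palindromic + 120 pooled pairs)
canonical_kmer_map <- function(k = 4) {
  kmers <- sort(apply(expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE],
                      1, paste, collapse = ""))
  rc <- revcomp(kmers)
  canon <- pmin(kmers, rc)
  setNames(canon, kmers)
}

#' Canonical tetranucleotide frequency profile
#'
#' Counts all overlapping k-mers containing no ambiguity character, pools
#' each k-mer with its reverse complement into canonical classes (136 for
#' k = 4), and normalizes to sum to 1. This is the "nucleotide composition"
#' axis of the binning feature space, invariant to which strand a scaffold
#' was assembled on.
#'
#' @param seq Character vector of DNA sequences (or a `DNAStringSet`).
#' @param k k-mer size (even; default 4).
#' @return A numeric matrix, one row per sequence, columns named by the
#'   lexicographically smaller member of each canonical class, rows summing
#'   to 1.
#' @export
tnf_profile <- function(seq, k = 4) {
  dna <- as_dna(seq)
  if (any(Biostrings::width(dna) < k)) {
    abort(sprintf("tnf_profile requires sequences of length >= k (= %d)", k))
  }
  counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
  map <- canonical_kmer_map(k)
  classes <- sort(unique(map))
  pooled <- vapply(classes, function(cl) {
    rowSums(counts[, names(map)[map == cl], drop = FALSE])
  }, numeric(length(dna)))
  if (length(dna) == 1L) pooled <- matrix(pooled, nrow = 1, dimnames = list(NULL, classes))
  tot <- rowSums(pooled)
  if (any(tot == 0)) abort("tnf_profile undefined: no unambiguous k-mers")
  pooled / tot
}

#' Fold-coverage of a scaffold from alignment records
#'
#' Total aligned bases over the scaffold divided by scaffold length. Using
#' aligned bases (not read counts) makes the statistic read-length
#' independent. Zero mapped records give 0.
#'
#' @param alignments Tibble of alignment records with at least `scaffold_id`
#'   and `aligned_length`.
#' @param scaffold_id Scaffold to evaluate.
#' @param scaffold_length Scaffold length in bases (> 0).
#' @return Fold-coverage (numeric scalar >= 0).
#' @export
coverage_depth <- function(alignments, scaffold_id, scaffold_length) {
  stopifnot(scaffold_length > 0)
  hit <- alignments$scaffold_id == scaffold_id & !is.na(alignments$scaffold_id)
  sum(alignments$aligned_length[hit]) / scaffold_length
}

#' Paired-read fraction of a scaffold
#'
#' Of the records mapped to the scaffold, the fraction whose `pair_status`
#' is `"paired"`. Undefined (error) when no records map; the quality screen
#' treats that case as a failure.
#'
#' @param alignments Tibble with `scaffold_id` and `pair_status`
#'   (`"paired"` or `"singleton"`).
#' @param scaffold_id Scaffold to evaluate.
#' @return Fraction in `[0, 1]`.
#' @export
paired_fraction <- function(alignments, scaffold_id) {
  hit <- alignments$scaffold_id == scaffold_id & !is.na(alignments$scaffold_id)
  if (!any(hit)) {
    abort(sprintf("paired_fraction undefined: no reads map to '%s'", scaffold_id))
  }
  mean(alignments$pair_status[hit] == "paired")
}

#' Annotate pair status on alignment records
#'
#' A record is `"paired"` when both mates of its read mapped in the same
#' mapping run (`level = "run"`, the default: a mate on a different scaffold
#' of the same reference still counts as paired) or, with
#' `level = "scaffold"`, only when both mates mapped to the same scaffold.
#'
#' @param alignments Mapped alignment records (`read_id`, `mate`,
#'   `scaffold_id`, ...).
#' @param level `"run"` or `"scaffold"`.
#' @return The alignments with a `pair_status` column.
#' @export
annotate_pair_status <- function(alignments, level = c("run", "scaffold")) {
  level <- match.arg(level)
  mapped <- !is.na(alignments$scaffold_id)
  if (level == "run") {
    key <- alignments$read_id
  } else {
    key <- paste(alignments$read_id, alignments$scaffold_id)
  }
  tab <- table(key[mapped])
  both <- mapped & tab[key] >= 2
  alignments$pair_status <- if_else(both, "paired", if_else(mapped, "singleton", NA_character_))
  alignments
}

#' Per-scaffold feature table for binning
#'
#' One row per scaffold passing the minimum-length filter, carrying the four
#' binning features (percent GC, canonical TNF as a list-column, fold
#' coverage, paired fraction) plus an optional taxonomy label. Scaffolds
#' with no mapped reads get coverage 0 and `NA` paired fraction.
#'
#' @param scaffolds Tibble (`id`/`scaffold_id`, `seq`).
#' @param alignments Optional alignment records with `pair_status` (see
#'   [annotate_pair_status()]); `NULL` leaves coverage 0 and paired fraction
#'   `NA`.
#' @param labels Optional tibble (`scaffold_id`, `taxonomy_label`); labels
#'   naming unknown scaffolds are dropped with a warning.
#' @param min_len Minimum scaffold length retained (default 10000).
#' @return Tibble: `scaffold_id`, `length`, `gc_percent`, `coverage`,
#'   `paired_fraction`, `taxonomy_label`, `tnf` (list-column).
#' @export
profile_scaffolds <- function(scaffolds, alignments = NULL, labels = NULL,
                              min_len = 10000) {
  if ("id" %in% names(scaffolds) && !"scaffold_id" %in% names(scaffolds)) {
    scaffolds <- rename(scaffolds, scaffold_id = "id")
  }
  scaffolds <- mutate(scaffolds, length = nchar(.data$seq)) |>
    filter(.data$length >= min_len)
  if (!nrow(scaffolds)) {
    abort("no scaffolds pass the minimum-length filter")
  }
  tnf <- tnf_profile(scaffolds$seq)
  prof <- tibble(
    scaffold_id = scaffolds$scaffold_id,
    length = scaffolds$length,
    gc_percent = gc_percent(scaffolds$seq),
    coverage = 0,
    paired_fraction = NA_real_,
    taxonomy_label = NA_character_,
    tnf = lapply(seq_len(nrow(tnf)), function(i) tnf[i, ])
  )
  if (!is.null(alignments) && nrow(alignments)) {
    if (!"pair_status" %in% names(alignments)) {
      alignments <- annotate_pair_status(alignments)
    }
    cov <- alignments |>
      filter(!is.na(.data$scaffold_id)) |>
      group_by(.data$scaffold_id) |>
      summarise(
        aligned = sum(.data$aligned_length),
        pf = mean(.data$pair_status == "paired"),
        .groups = "drop"
      )
    idx <- match(prof$scaffold_id, cov$scaffold_id)
    prof$coverage <- ifelse(is.na(idx), 0, cov$aligned[idx] / prof$length)
    prof$paired_fraction <- cov$pf[idx]
  }
  if (!is.null(labels) && nrow(labels)) {
    unknown <- setdiff(labels$scaffold_id, prof$scaffold_id)
    if (length(unknown)) {
      warn(sprintf("%d label(s) reference unknown scaffolds and were ignored",
                   length(unknown)))
    }
    idx <- match(prof$scaffold_id, labels$scaffold_id)
    prof$taxonomy_label <- labels$taxonomy_label[idx]
  }
  prof
}
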