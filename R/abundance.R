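#' Relative abundance from metagenomic read recruitment
#'
#' Each unambiguously mapped read is assigned to the taxon group of the bin
#' holding its scaffold. The `read_recruitment_classified` metric normalizes
#' over classified reads; `read_recruitment_total` normalizes over all input
#' reads, with the remainder reported as the unclassified fraction
#' (unmapped plus ambiguous multi-bin reads).
#'
#' @param alignments Alignment records from [map_reads()] (one row per input
#'   read, unmapped rows included, `ambiguous` flagged).
#' @param bins Tibble (`bin_id`, `scaffold_id`) and optionally `taxon_group`
#'   (defaults to `bin_id`); bins must be disjoint in scaffolds.
#' @param sample_id Sample identifier.
#' @return An `abundance_table` tibble: `sample_id`, `taxon_group`, `metric`,
#'   `relative_abundance`, plus one `unclassified` row under the total
#'   metric.
#' @export
metagenomic_abundance <- function(alignments, bins, sample_id = "S1") {
  if (!"taxon_group" %in% names(bins)) bins$taxon_group <- bins$bin_id
  if (anyDuplicated(bins$scaffold_id)) {
    abort("bins overlap: a scaffold belongs to more than one bin")
  }
  n_total <- nrow(alignments)
  idx <- match(alignments$scaffold_id, bins$scaffold_id)
  group <- bins$taxon_group[idx]
  classified <- !is.na(group) & !alignments$ambiguous
  counts <- table(group[classified])
  n_class <- sum(counts)
  if (n_class == 0) abort("no classified reads")
  groups <- sort(unique(bins$taxon_group))
  cnt <- as.numeric(counts[groups])
  cnt[is.na(cnt)] <- 0
  out <- bind_rows(
    tibble(sample_id = sample_id, taxon_group = groups,
           metric = "read_recruitment_classified",
           relative_abundance = cnt / n_class),
    tibble(sample_id = sample_id, taxon_group = groups,
           metric = "read_recruitment_total",
           relative_abundance = cnt / n_total),
    tibble(sample_id = sample_id, taxon_group = "unclassified",
           metric = "read_recruitment_total",
           relative_abundance = 1 - n_class / n_total)
  )
  structure(out, class = c("abundance_table", class(out)))
}

# identity of a short amplicon against one reference over the full query
# length: overlap alignment, mismatches and internal gaps count against
asv_identity <- function(asv, reference_set) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = reference_set, subject = Biostrings::DNAString(toupper(asv)),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  pat <- as.character(Biostrings::pattern(aln))
  sub <- as.character(Biostrings::subject(aln))
  vapply(seq_along(reference_set), function(i) {
    a <- charToRaw(pat[i]); b <- charToRaw(sub[i])
    matches <- sum(a == b & a != charToRaw("-"))
    100 * matches / nchar(asv)  # full-length query coverage
  }, numeric(1))
}

#' Relative abundance from 16S amplicon matching
#'
#' Each ASV is assigned to the best-identity MAG 16S gene at or above
#' `min_identity` over the full ASV length (ties break to the
#' lexicographically lower taxon group); unassigned ASVs are pooled. Counts
#' are normalized per sample by total sample reads, compensating for
#' differences in amplicon yield between samples.
#'
#' @param asv_table Tibble (`sample_id`, `asv_id`, `sequence`, `count`).
#' @param mag_ssu Tibble (`id`, `seq`) of MAG 16S genes, optionally with a
#'   `taxon_group` column (defaults to `id`).
#' @param min_identity Identity floor, percent (species-level convention 97).
#' @return An `abundance_table` tibble under metric `"amplicon"`, including
#'   an `unassigned` row per sample; attribute `asv_assignment` records the
#'   per-ASV calls.
#' @export
amplicon_abundance <- function(asv_table, mag_ssu, min_identity = 97) {
  if (!nrow(asv_table)) {
    return(structure(tibble(sample_id = character(), taxon_group = character(),
                            metric = character(), relative_abundance = numeric()),
                     class = c("abundance_table", "tbl_df", "tbl", "data.frame")))
  }
  if (!"taxon_group" %in% names(mag_ssu)) mag_ssu$taxon_group <- mag_ssu$id
  refs <- as_dna(mag_ssu)
  uniq <- distinct(asv_table, .data$asv_id, .data$sequence)
  assign <- purrr::map_dfr(seq_len(nrow(uniq)), function(i) {
    ident <- asv_identity(uniq$sequence[i], refs)
    ok <- which(ident >= min_identity)
    if (!length(ok)) {
      return(tibble(asv_id = uniq$asv_id[i], taxon_group = "unassigned",
                    match_id = NA_character_, identity = max(ident)))
    }
    best <- ok[ident[ok] == max(ident[ok])]
    grp <- sort(mag_ssu$taxon_group[best])[1]
    tibble(asv_id = uniq$asv_id[i], taxon_group = grp,
           match_id = mag_ssu$id[best[order(mag_ssu$taxon_group[best])][1]],
           identity = max(ident[ok]))
  })
  groups <- sort(unique(mag_ssu$taxon_group))
  out <- asv_table |>
    left_join(assign, by = "asv_id") |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(d, key) {
      total <- sum(d$count)
      cnt <- vapply(groups, function(g) {
        sum(d$count[d$taxon_group == g])
      }, numeric(1))
      tibble(
        taxon_group = c(groups, "unassigned"),
        metric = "amplicon",
        relative_abundance = unname(c(cnt, total - sum(cnt)) / total)
      )
    }) |>
    ungroup() |>
    select("sample_id", "taxon_group", "metric", "relative_abundance")
  structure(out, class = c("abundance_table", class(out)),
            asv_assignment = assign)
}

#' Filtered matches against an environmental 16S reference set
#'
#' Local (Smith-Waterman-style) nucleotide alignments of each query against
#' each reference, filtered by minimum alignment length, maximum e-value and
#' an identity tier (97% species / 95% genus / 90% distant relative, by
#' convention). E-values use the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with ungapped nucleotide constants
#' lambda = 1.28, K = 0.46 for +1/-2 scoring, recorded in the result's
#' metadata.
#'
#' @param query_ssu Tibble (`id`, `seq`) of query 16S genes.
#' @param reference_ssu Tibble (`id`, `seq`) of reference sequences.
#' @param min_align_len Minimum alignment length, bases.
#' @param max_evalue Maximum e-value.
#' @param min_identity Identity tier, percent.
#' @return Tibble (`query_id`, `ref_id`, `identity`, `align_len`, `evalue`,
#'   `score`); attribute `karlin_altschul` records the constants.
#' @export
environmental_match <- function(query_ssu, reference_ssu,
                                min_align_len = 360, max_evalue = 1e-7,
                                min_identity = 97) {
  stopifnot(min_align_len > 0, min_identity > 0, min_identity <= 100)
  lambda <- 1.28; K <- 0.46
  q <- as_dna(query_ssu)
  r <- as_dna(reference_ssu)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  out <- list()
  for (j in seq_along(r)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = q, subject = r[[j]], type = "local",
      substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
    )
    pat <- as.character(Biostrings::pattern(aln))
    sub <- as.character(Biostrings::subject(aln))
    for (i in seq_along(q)) {
      a <- charToRaw(pat[i]); b <- charToRaw(sub[i])
      cols <- length(a)
      matches <- sum(a == b & a != charToRaw("-"))
      s <- Biostrings::score(aln)[i]
      out[[length(out) + 1L]] <- tibble(
        query_id = names(q)[i], ref_id = names(r)[j],
        identity = 100 * matches / cols,
        align_len = cols,
        evalue = K * Biostrings::width(q)[i] * Biostrings::width(r)[j] *
          exp(-lambda * s),
        score = s
      )
    }
  }
  out <- bind_rows(out) |>
    filter(.data$align_len >= min_align_len,
           .data$evalue <= max_evalue,
           .data$identity >= min_identity)
  attr(out, "karlin_altschul") <- c(lambda = lambda, K = K,
                                    match = 1, mismatch = -2)
  out
}

#' Concordance between amplicon and read-recruitment abundances
#'
#' Per-taxon difference and Spearman rank correlation between the amplicon
#' and classified-read-recruitment metrics of one sample, flagging taxa with
#' known discordance sources (multiple 16S copies inflate amplicon shares;
#' atypical genome sizes bias read recruitment).
#'
#' @param table An `abundance_table` holding both metrics for the sample(s).
#' @param flags Optional tibble (`taxon_group`, `flag`) of expected
#'   discordance sources.
#' @return Tibble per sample and taxon: both abundances, `difference`
#'   (amplicon minus reads), `flag`; attribute `rank_correlation` gives the
#'   per-sample Spearman rho.
#' @export
compare_metrics <- function(table, flags = NULL) {
  wide <- table |>
    filter(.data$metric %in% c("amplicon", "read_recruitment_classified"),
           !.data$taxon_group %in% c("unassigned", "unclassified")) |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = "relative_abundance")
  need <- c("amplicon", "read_recruitment_classified")
  if (!all(need %in% names(wide))) {
    warn("both metrics required for a concordance report; skipped")
    return(invisible(NULL))
  }
  wide <- filter(wide, !is.na(.data$amplicon),
                 !is.na(.data$read_recruitment_classified))
  if (!nrow(wide)) abort("no taxa shared between the two metrics")
  rho <- wide |>
    group_by(.data$sample_id) |>
    summarise(rho = cor(.data$amplicon, .data$read_recruitment_classified,
                        method = "spearman"), .groups = "drop")
  out <- wide |>
    mutate(difference = .data$amplicon - .data$read_recruitment_classified)
  out$flag <- if (!is.null(flags)) {
    flags$flag[match(out$taxon_group, flags$taxon_group)]
  } else {
    NA_character_
  }
  attr(out, "rank_correlation") <- rho
  out
}

#' @method autoplot abundance_table
#' @export
autoplot.abundance_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$sample_id,
                               y = .data$relative_abundance,
                               fill = .data$taxon_group)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "sample", y = "relative abundance", fill = "taxon") +
    ggplot2::theme_minimal()
}
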