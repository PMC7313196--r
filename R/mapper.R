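#' Build a seed index over scaffolds
#'
#' Exact k-mer seeds over both strands back the mapper's candidate lookup
#' (seeds are realized as pigeonhole read segments matched exactly against
#' the scaffolds, so any end-to-end placement with at most
#' `floor(L * (1 - min_identity/100))` mismatches is guaranteed a hit).
#'
#' @param scaffolds Tibble (`id`/`scaffold_id`, `seq`).
#' @param k Seed length (>= 11).
#' @return A `read_index` object.
#' @export
build_read_index <- function(scaffolds, k = 16) {
  if (k < 11) abort("seed length k must be >= 11")
  if ("id" %in% names(scaffolds) && !"scaffold_id" %in% names(scaffolds)) {
    scaffolds <- rename(scaffolds, scaffold_id = "id")
  }
  if (anyDuplicated(scaffolds$scaffold_id)) {
    abort("duplicate scaffold ids in index input")
  }
  subject <- as_dna(tibble(id = scaffolds$scaffold_id, seq = scaffolds$seq))
  if (all(Biostrings::width(subject) < k)) {
    warn("seed length k exceeds every scaffold: index is empty")
  }
  structure(
    list(subject = subject, ids = scaffolds$scaffold_id, k = as.integer(k)),
    class = "read_index"
  )
}

#' @export
print.read_index <- function(x, ...) {
  cat("<read_index> ", length(x$subject), " scaffolds, ",
      sum(Biostrings::width(x$subject)), " bp, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Map reads end-to-end at an identity floor
#'
#' Every read is aligned over its full length (no clipping, no gaps) on
#' either strand of the indexed scaffolds; a placement is reported only if
#' `identity = 100 * matches / read length >= min_identity`. The best
#' placement by identity wins; ties break to the lexicographically lowest
#' `(scaffold_id, position)` and are flagged `ambiguous`. At
#' `min_identity = 100` the contract reduces to exact full-length substring
#' matching.
#'
#' @param reads Tibble (`read_id`, `mate`, `seq`), or a list with elements
#'   `r1`/`r2` as produced by [simulate_reads()] (tibbles with `id`, `seq`).
#' @param index A [build_read_index()] object.
#' @param min_identity Identity floor in `(0, 100]`.
#' @return Tibble of alignment records: `read_id`, `mate`, `scaffold_id`
#'   (`NA` when unmapped), `position` (0-based leftmost), `strand`,
#'   `aligned_length`, `identity`, `ambiguous`. One row per input read.
#' @export
map_reads <- function(reads, index, min_identity = 100) {
  stopifnot(inherits(index, "read_index"))
  if (!(min_identity > 0 && min_identity <= 100)) {
    abort("min_identity must lie in (0, 100]")
  }
  reads <- normalize_reads(reads)
  empty <- nchar(reads$seq) == 0 | is.na(reads$seq)
  if (any(empty)) {
    warn(sprintf("%d empty read(s) skipped", sum(empty)))
    reads <- reads[!empty, ]
  }
  hits <- purrr::map(split(seq_len(nrow(reads)), nchar(reads$seq)),
                     function(ix) map_width_group(reads[ix, ], index, min_identity))
  hits <- bind_rows(hits)
  out <- tibble(
    read_id = reads$read_id, mate = reads$mate,
    scaffold_id = NA_character_, position = NA_integer_,
    strand = NA_character_, aligned_length = NA_integer_,
    identity = NA_real_, ambiguous = FALSE
  )
  if (nrow(hits)) {
    key_out <- paste(out$read_id, out$mate)
    idx <- match(paste(hits$read_id, hits$mate), key_out)
    out$scaffold_id[idx] <- hits$scaffold_id
    out$position[idx] <- hits$position
    out$strand[idx] <- hits$strand
    out$aligned_length[idx] <- hits$aligned_length
    out$identity[idx] <- hits$identity
    out$ambiguous[idx] <- hits$ambiguous
  }
  out
}

normalize_reads <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) && all(c("r1", "r2") %in% names(reads))) {
    reads <- bind_rows(
      tibble(read_id = reads$r1$id, mate = 1L, seq = reads$r1$seq),
      tibble(read_id = reads$r2$id, mate = 2L, seq = reads$r2$seq)
    )
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if (!"mate" %in% names(reads)) reads$mate <- 1L
  reads
}

# map a group of equal-length reads; pigeonhole seeding + vectorized verify
map_width_group <- function(reads, index, min_identity) {
  L <- nchar(reads$seq[1])
  max_mm <- floor(L * (1 - min_identity / 100))
  cand <- list()
  for (strand in c("+", "-")) {
    seqs <- if (strand == "+") reads$seq else revcomp(reads$seq)
    cand[[strand]] <- seed_candidates(seqs, index, max_mm, L)
    if (nrow(cand[[strand]])) cand[[strand]]$strand <- strand
  }
  cand <- bind_rows(cand)
  if (!nrow(cand)) return(tibble())
  cand <- distinct(cand, .data$read, .data$scf, .data$start, .data$strand)
  # verify: count mismatches of each candidate full-length placement
  qseq <- ifelse(cand$strand == "+", reads$seq[cand$read],
                 revcomp(reads$seq[cand$read]))
  ref <- extract_windows(index, cand$scf, cand$start, L)
  mm <- count_mismatches(qseq, ref, L)
  ok <- mm <= max_mm
  cand <- cand[ok, ]
  if (!nrow(cand)) return(tibble())
  cand$identity <- 100 * (L - mm[ok]) / L
  cand$scaffold_id <- index$ids[cand$scf]
  # best placement per read: identity desc, then (scaffold_id, position) asc
  cand <- arrange(cand, .data$read, dplyr::desc(.data$identity),
                  .data$scaffold_id, .data$start)
  n_best <- cand |>
    group_by(.data$read) |>
    summarise(n_best = sum(.data$identity == .data$identity[1]), .groups = "drop")
  best <- cand |> group_by(.data$read) |> slice(1) |> ungroup()
  tibble(
    read_id = reads$read_id[best$read],
    mate = reads$mate[best$read],
    scaffold_id = best$scaffold_id,
    position = best$start - 1L,
    strand = best$strand,
    aligned_length = L,
    identity = best$identity,
    ambiguous = n_best$n_best[match(best$read, n_best$read)] > 1
  )
}

# exact matching of max_mm + 1 read segments against all scaffolds; returns
# candidate full-read start positions (1-based), may include out-of-range
seed_candidates <- function(seqs, index, max_mm, L) {
  n_seg <- max_mm + 1L
  seg_bounds <- floor(seq(0, L, length.out = n_seg + 1L))
  out <- list()
  dna <- Biostrings::DNAStringSet(seqs)
  for (s in seq_len(n_seg)) {
    from <- seg_bounds[s] + 1L
    to <- seg_bounds[s + 1L]
    if (to - from + 1L < 1L) next
    seg <- Biostrings::subseq(dna, from, to)
    pd <- Biostrings::PDict(seg)
    for (j in seq_along(index$subject)) {
      if (Biostrings::width(index$subject)[j] < L) next
      m <- Biostrings::matchPDict(pd, index$subject[[j]])
      st <- Biostrings::startIndex(m)
      hit <- which(lengths(st) > 0)
      if (!length(hit)) next
      starts <- unlist(st[hit], use.names = FALSE)
      out[[length(out) + 1L]] <- tibble(
        read = rep.int(hit, lengths(st[hit])),
        scf = j,
        start = starts - from + 1L
      )
    }
  }
  if (!length(out)) return(tibble(read = integer(), scf = integer(), start = integer()))
  res <- bind_rows(out)
  # keep candidates where the full read fits on the scaffold
  res[res$start >= 1L &
        res$start + L - 1L <= Biostrings::width(index$subject)[res$scf], ]
}

extract_windows <- function(index, scf, start, L) {
  out <- character(length(scf))
  for (j in unique(scf)) {
    rows <- which(scf == j)
    views <- Biostrings::extractAt(
      index$subject[[j]],
      IRanges::IRanges(start = start[rows], width = L)
    )
    out[rows] <- as.character(views)
  }
  out
}

# vectorized mismatch counts between equal-width sequence vectors
count_mismatches <- function(a, b, L) {
  if (!length(a)) return(integer())
  ra <- charToRaw(paste(a, collapse = ""))
  rb <- charToRaw(paste(b, collapse = ""))
  diff <- ra != rb
  as.integer(rowsum(as.integer(diff), rep(seq_along(a), each = L)))
}

#' Recruit bin-matched read pairs with mate completion
#'
#' A pair is recruited when at least one mate maps to a scaffold of the bin;
#' both mates are then emitted, the unmapped mate being rescued from the
#' input read files. Mates absent from the input (true singletons) are
#' emitted alone and counted separately.
#'
#' @param alignments Alignment records from [map_reads()].
#' @param bin_scaffolds Character vector of the bin's scaffold ids.
#' @param reads List with `r1`, `r2` read tibbles (`id`, `seq`, optionally
#'   `qual`): the full input read set.
#' @param bin_id Identifier recorded on the result.
#' @return A `recruitment` object: list with `bin_id`, `r1`, `r2` (recruited
#'   read tibbles), `recruited_read_ids`, `n_pairs_complete`,
#'   `n_mates_rescued`, `n_true_singletons`.
#' @export
recruit_pairs <- function(alignments, bin_scaffolds, reads, bin_id = "bin") {
  if (!length(bin_scaffolds)) abort("bin has no scaffolds")
  mapped_in_bin <- alignments |>
    filter(!is.na(.data$scaffold_id), .data$scaffold_id %in% bin_scaffolds)
  ids <- unique(mapped_in_bin$read_id)
  r1 <- reads$r1[reads$r1$id %in% ids, , drop = FALSE]
  r2 <- reads$r2[reads$r2$id %in% ids, , drop = FALSE]
  both <- intersect(r1$id, r2$id)
  mapped_ids_by_mate <- split(mapped_in_bin$read_id, mapped_in_bin$mate)
  rescued <- c(
    setdiff(intersect(both, mapped_ids_by_mate[["1"]] %||% character()),
            mapped_ids_by_mate[["2"]] %||% character()),
    setdiff(intersect(both, mapped_ids_by_mate[["2"]] %||% character()),
            mapped_ids_by_mate[["1"]] %||% character())
  )
  structure(list(
    bin_id = bin_id,
    r1 = r1, r2 = r2,
    recruited_read_ids = ids,
    n_pairs_complete = length(both),
    n_mates_rescued = length(unique(rescued)),
    n_true_singletons = length(ids) - length(both)
  ), class = "recruitment")
}

#' @export
print.recruitment <- function(x, ...) {
  cat("<recruitment> bin ", x$bin_id, ": ", x$n_pairs_complete,
      " complete pairs (", x$n_mates_rescued, " mates rescued), ",
      x$n_true_singletons, " true singletons\n", sep = "")
  invisible(x)
}

#' @method tidy recruitment
#' @export
tidy.recruitment <- function(x, ...) {
  tibble(
    bin_id = x$bin_id,
    n_reads = nrow(x$r1) + nrow(x$r2),
    n_pairs_complete = x$n_pairs_complete,
    n_mates_rescued = x$n_mates_rescued,
    n_true_singletons = x$n_true_singletons
  )
}
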