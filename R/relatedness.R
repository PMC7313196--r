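# identity/coverage of one gapped alignment: matches over alignment columns,
# terminal gap columns excluded from the denominator, internal gaps counted
aligned_identity <- function(pat, sub, len_a, len_b) {
  a <- charToRaw(pat)
  b <- charToRaw(sub)
  gap <- charToRaw("-")
  both <- which(a != gap & b != gap)
  if (!length(both)) return(c(identity = NA_real_, coverage = 0, span = 0))
  span <- both[1]:both[length(both)]
  matches <- sum(a[span] == b[span] & a[span] != gap)
  c(identity = 100 * matches / length(span),
    coverage = length(span) / min(len_a, len_b),
    span = length(span))
}

# global protein alignment of many patterns against one subject
align_protein <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1
  )
}

#' Reciprocal best hits between two proteomes
#'
#' Every protein of each proteome is globally aligned (BLOSUM62, affine
#' gaps 11/1) against every protein of the other; a pair is retained when
#' each member is the other's best-scoring hit and the alignment passes the
#' identity and coverage floors. Identity is matches over alignment columns
#' excluding terminal gaps; coverage is the aligned span over the shorter
#' protein.
#'
#' @param proteome_a,proteome_b Tibbles (`id`, `seq`) of amino acid
#'   sequences.
#' @param min_identity Identity floor, percent.
#' @param min_cov Coverage floor, fraction of the shorter protein.
#' @return Tibble (`id_a`, `id_b`, `identity`, `coverage`).
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 min_identity = 30, min_cov = 0.7) {
  if (!nrow(proteome_a) || !nrow(proteome_b)) abort("empty proteome")
  aa <- as_aa(proteome_a)
  bb <- as_aa(proteome_b)
  na <- length(aa); nb <- length(bb)
  score <- matrix(-Inf, na, nb)
  idmat <- matrix(NA_real_, na, nb)
  covmat <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    aln <- align_protein(aa, bb[[j]])
    score[, j] <- Biostrings::score(aln)
    pat <- as.character(Biostrings::pattern(aln))
    sub <- as.character(Biostrings::subject(aln))
    for (i in seq_len(na)) {
      st <- aligned_identity(pat[i], sub[i],
                             Biostrings::width(aa)[i], Biostrings::width(bb)[j])
      idmat[i, j] <- st[["identity"]]
      covmat[i, j] <- st[["coverage"]]
    }
  }
  best_b_of_a <- max.col(score, ties.method = "first")
  best_a_of_b <- max.col(t(score), ties.method = "first")
  mutual <- which(best_a_of_b[best_b_of_a] == seq_len(na))
  keep <- mutual[
    idmat[cbind(mutual, best_b_of_a[mutual])] >= min_identity &
      covmat[cbind(mutual, best_b_of_a[mutual])] >= min_cov
  ]
  tibble(
    id_a = names(aa)[keep],
    id_b = names(bb)[best_b_of_a[keep]],
    identity = idmat[cbind(keep, best_b_of_a[keep])],
    coverage = covmat[cbind(keep, best_b_of_a[keep])]
  )
}

#' Average amino acid identity (AAI)
#'
#' Unweighted mean identity over reciprocal-best-hit protein pairs of two
#' genomes. Undefined (with a warning) below `min_rbh` pairs: a stable AAI
#' needs a minimum ortholog sample. Symmetric by construction, since global
#' alignment with a symmetric scoring matrix is direction-independent.
#'
#' @inheritParams reciprocal_best_hits
#' @param min_rbh Minimum RBH pairs for a reported value.
#' @param ... Floors passed to [reciprocal_best_hits()].
#' @return List with `aai` (percent, or `NA`) and `n_rbh`.
#' @export
aai <- function(proteome_a, proteome_b, min_rbh = 20, ...) {
  rbh <- reciprocal_best_hits(proteome_a, proteome_b, ...)
  if (nrow(rbh) < min_rbh) {
    warn(sprintf("only %d RBH pairs (< %d): AAI undefined", nrow(rbh), min_rbh))
    return(list(aai = NA_real_, n_rbh = nrow(rbh)))
  }
  list(aai = mean(rbh$identity), n_rbh = nrow(rbh))
}

#' 16S rRNA gene identity
#'
#' Global alignment with free terminal gaps (overlap alignment); identity is
#' matches over the shared span, internal gap columns counted in the
#' denominator. Undefined when either input or the aligned span is shorter
#' than `min_len` (mirroring genomes whose 16S is not detected or too
#' partial to compare).
#'
#' @param seq_a,seq_b DNA sequences (character scalars).
#' @param min_len Minimum input and aligned-span length, bases.
#' @return Percent identity, or `NA` when undefined.
#' @export
ssu_identity <- function(seq_a, seq_b, min_len = 360) {
  if (is.na(seq_a) || is.na(seq_b) ||
      nchar(seq_a) < min_len || nchar(seq_b) < min_len) {
    return(NA_real_)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(toupper(seq_a)),
    subject = Biostrings::DNAString(toupper(seq_b)),
    type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 2
  )
  st <- aligned_identity(
    as.character(Biostrings::pattern(aln)),
    as.character(Biostrings::subject(aln)),
    nchar(seq_a), nchar(seq_b)
  )
  if (st[["span"]] < min_len) return(NA_real_)
  st[["identity"]]
}

#' Taxonomic rank thresholds
#'
#' Default AAI boundaries 95/65/45 (species/genus/family) and 16S identity
#' boundaries 97/94.5/86.5 (species/genus/order floor) follow published
#' genome-relatedness guidelines; all are configurable and inclusive
#' (a value exactly at a threshold classifies to the higher rank).
#'
#' @param aai_species,aai_genus,aai_family AAI percent boundaries.
#' @param ssu_species,ssu_genus,ssu_order_floor 16S percent boundaries.
#' @return A `rank_thresholds` list.
#' @export
rank_thresholds <- function(aai_species = 95, aai_genus = 65, aai_family = 45,
                            ssu_species = 97, ssu_genus = 94.5,
                            ssu_order_floor = 86.5) {
  if (!(aai_species > aai_genus && aai_genus > aai_family)) {
    abort("AAI thresholds must decrease from species to family")
  }
  if (!(ssu_species > ssu_genus && ssu_genus > ssu_order_floor)) {
    abort("16S thresholds must decrease from species to order floor")
  }
  structure(
    list(aai_species = aai_species, aai_genus = aai_genus,
         aai_family = aai_family, ssu_species = ssu_species,
         ssu_genus = ssu_genus, ssu_order_floor = ssu_order_floor),
    class = "rank_thresholds"
  )
}

#' Assign a taxonomic rank call from AAI and 16S identity
#'
#' The highest rank whose AAI threshold is met wins; below the family
#' threshold, a 16S identity at or above the order floor supports
#' `same_order`, otherwise the pair is called `novel_above_order`. When AAI
#' is undefined the 16S tiers are the sole evidence; with both undefined the
#' call is `indeterminate`. Vectorized; monotone in `aai`.
#'
#' @param aai AAI percent (may be `NA`).
#' @param ssu 16S identity percent (may be `NA`).
#' @param thresholds A [rank_thresholds()].
#' @return Character vector of rank calls: `same_species`, `same_genus`,
#'   `same_family`, `same_order`, `novel_above_order`, `indeterminate`.
#' @export
assign_rank <- function(aai, ssu = NA_real_, thresholds = rank_thresholds()) {
  t <- thresholds
  n <- max(length(aai), length(ssu))
  aai <- rep_len(aai, n); ssu <- rep_len(ssu, n)
  out <- character(n)
  for (i in seq_len(n)) {
    a <- aai[i]; s <- ssu[i]
    out[i] <- if (!is.na(a)) {
      if (a >= t$aai_species) "same_species"
      else if (a >= t$aai_genus) "same_genus"
      else if (a >= t$aai_family) "same_family"
      else if (!is.na(s) && s >= t$ssu_order_floor) "same_order"
      else "novel_above_order"
    } else if (!is.na(s)) {
      if (s >= t$ssu_species) "same_species"
      else if (s >= t$ssu_genus) "same_genus"
      else if (s >= t$ssu_order_floor) "same_order"
      else "novel_above_order"
    } else {
      "indeterminate"
    }
  }
  out
}

#' Pairwise relatedness matrix and rank-call table
#'
#' All pairwise AAI (when proteomes are supplied) and 16S identities (when
#' 16S sequences are supplied) between genomes, with the AAI-based rank call
#' and the 16S-only call recorded side by side — the two can disagree, and
#' both signals are reported rather than resolved.
#'
#' @param proteomes Named list of proteome tibbles (`id`, `seq`), or `NULL`.
#' @param ssu_seqs Named character vector of 16S sequences, or `NULL`.
#' @param thresholds A [rank_thresholds()].
#' @param ... Passed to [aai()].
#' @return A `relatedness_matrix` object: list with `aai`, `n_rbh`, `ssu`
#'   matrices (self-diagonal 100), a `pairs` tibble (`genome_a`, `genome_b`,
#'   `aai`, `n_rbh`, `ssu_identity`, `rank_call`, `ssu_rank_call`), and the
#'   thresholds.
#' @export
identity_matrix <- function(proteomes = NULL, ssu_seqs = NULL,
                            thresholds = rank_thresholds(), ...) {
  ids <- union(names(proteomes) %||% character(),
               names(ssu_seqs) %||% character())
  if (length(ids) < 2) abort("need at least 2 genomes")
  n <- length(ids)
  aai_m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  rbh_m <- matrix(NA_integer_, n, n, dimnames = list(ids, ids))
  ssu_m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(aai_m) <- diag(ssu_m) <- 100
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- b <- NA_real_; nr <- NA_integer_
      if (!is.null(proteomes) && all(c(ids[i], ids[j]) %in% names(proteomes))) {
        res <- aai(proteomes[[ids[i]]], proteomes[[ids[j]]], ...)
        a <- res$aai; nr <- res$n_rbh
      }
      if (!is.null(ssu_seqs) && all(c(ids[i], ids[j]) %in% names(ssu_seqs))) {
        b <- ssu_identity(ssu_seqs[[ids[i]]], ssu_seqs[[ids[j]]])
      }
      aai_m[i, j] <- aai_m[j, i] <- a
      rbh_m[i, j] <- rbh_m[j, i] <- nr
      ssu_m[i, j] <- ssu_m[j, i] <- b
      pairs[[length(pairs) + 1L]] <- tibble(
        genome_a = ids[i], genome_b = ids[j],
        aai = a, n_rbh = nr, ssu_identity = b,
        rank_call = assign_rank(a, b, thresholds),
        ssu_rank_call = assign_rank(NA_real_, b, thresholds)
      )
    }
  }
  structure(
    list(aai = aai_m, n_rbh = rbh_m, ssu = ssu_m,
         pairs = bind_rows(pairs), thresholds = thresholds),
    class = "relatedness_matrix"
  )
}

#' @export
print.relatedness_matrix <- function(x, ...) {
  cat("<relatedness_matrix> ", nrow(x$aai), " genomes\n", sep = "")
  print(x$pairs)
  invisible(x)
}

#' @method tidy relatedness_matrix
#' @export
tidy.relatedness_matrix <- function(x, ...) x$pairs

#' @method glance relatedness_matrix
#' @export
glance.relatedness_matrix <- function(x, ...) {
  tibble(
    n_genomes = nrow(x$aai),
    n_pairs = nrow(x$pairs),
    mean_aai = mean(x$pairs$aai, na.rm = TRUE),
    mean_ssu = mean(x$pairs$ssu_identity, na.rm = TRUE)
  )
}
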