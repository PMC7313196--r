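#' Read and write FASTA files
#'
#' Thin tibble-facing wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()]. Identifiers are truncated at the first
#' whitespace character; sequence case is preserved on the round trip and
#' only uppercased inside analysis functions.
#'
#' @param path File path.
#' @return `read_fasta()` returns a tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path, format = "fasta")
  tibble(
    id  = sub("\\s.*$", "", names(x)),
    seq = as.character(unname(x))
  )
}

#' @rdname read_fasta
#' @param x Tibble with columns `id` and `seq`.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  invisible(path)
}

#' Read and write FASTQ files
#'
#' FASTQ records are strict 4-line records. `read_fastq()` validates record
#' structure up front and reports the offending line number on malformed
#' input (truncated records, missing `@`/`+` markers, length mismatches).
#'
#' @param path File path.
#' @return `read_fastq()` returns a tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    abort(sprintf("malformed FASTQ '%s': truncated record at line %d", path,
                  4L * (n %/% 4L) + 1L))
  }
  idx <- seq_len(n %/% 4L)
  hdr <- lines[4L * idx - 3L]
  sq  <- lines[4L * idx - 2L]
  plus <- lines[4L * idx - 1L]
  ql  <- lines[4L * idx]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ '%s': expected '@' header at line %d", path,
                  4L * bad[1] - 3L))
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    abort(sprintf("malformed FASTQ '%s': expected '+' separator at line %d",
                  path, 4L * bad[1] - 1L))
  }
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad)) {
    abort(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at line %d",
      path, 4L * bad[1]))
  }
  tibble(
    id   = sub("\\s.*$", "", sub("^@", "", hdr)),
    seq  = sq,
    qual = ql
  )
}

#' @rdname read_fastq
#' @param x Tibble with columns `id`, `seq` and optionally `qual` (constant
#'   quality `"I"` is filled in when absent).
#' @export
write_fastq <- function(x, path) {
  stopifnot(all(c("id", "seq") %in% names(x)))
  qual <- x$qual %||% strrep("I", nchar(x$seq))
  out <- rbind(paste0("@", x$id), x$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read and write tab-delimited tables
#'
#' All tabular artifacts of the pipeline are headered TSV.
#'
#' @param path File path.
#' @param x Data frame.
#' @return `read_table_tsv()` returns a tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_table_tsv
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

# internal: tibble(id, seq) -> DNAStringSet (uppercased for analysis)
as_dna <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(Biostrings::DNAStringSet(setNames(toupper(x), ids)))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  Biostrings::DNAStringSet(setNames(toupper(x$seq), x$id))
}

# internal: tibble(id, seq) -> AAStringSet
as_aa <- function(x) {
  if (methods::is(x, "AAStringSet")) return(x)
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(Biostrings::AAStringSet(setNames(toupper(x), ids)))
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  Biostrings::AAStringSet(setNames(toupper(x$seq), x$id))
}
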