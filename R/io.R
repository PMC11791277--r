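# File I/O: FASTA/FASTQ through Biostrings, TSV with mandatory headers,
# JSON sidecars with stable key order.

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, list of sequences, or a single
#'   `nucleotide_sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nucleotide_sequence"))
    seqs <- stats::setNames(seqs$bases, seqs$id)
  seqs <- unlist(lapply(seqs, as_bases))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a read set to FASTQ (Phred+33)
#'
#' @param read_set A [simulate_reads()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(read_set, path) {
  stopifnot(inherits(read_set, "read_set"))
  n <- length(read_set$sequences)
  ids <- sprintf("read_%06d offset=%d", seq_len(n), read_set$offsets)
  quals <- Biostrings::BStringSet(strrep(read_set$quality, nchar(read_set$sequences)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(read_set$sequences, ids)),
    path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Read offsets are recovered from `offset=` tags in the read names when
#' present (as written by [write_fastq()]), else default to 1.
#'
#' @param path FASTQ file.
#' @return A `read_set` (truth slot empty).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  off <- suppressWarnings(
    as.integer(sub(".*offset=(\\d+).*", "\\1", names(x))))
  off[is.na(off)] <- 1L
  structure(list(sequences = as.character(x), offsets = off, quality = "F",
                 read_len = if (length(x)) nchar(x[[1]]) else 0L,
                 truth = NULL),
            class = "read_set")
}

#' Write a data frame as TSV (tab-delimited, header row, '.' decimals)
#' @param x Data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Input file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
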