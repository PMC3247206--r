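#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' uppercase character strings named by sequence id (first whitespace token).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector (ACGTN alphabet).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a 12-column tabular homology hit file (outfmt-6 dialect)
#'
#' Columns follow the BLAST `-outfmt 6` convention: query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start/end,
#' subject start/end (1-based inclusive), e-value, bitscore.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return A data.frame with typed columns named
#'   `query_id, subject_id, pct_identity, aln_len, mismatches, gap_opens,
#'   q_start, q_end, s_start, s_end, evalue, bitscore`.
#' @export
read_hit_table <- function(path) {
  cols <- hit_table_columns()
  h <- utils::read.delim(path, header = FALSE, col.names = cols,
                         colClasses = c("character", "character",
                                        rep("numeric", 10)),
                         quote = "", comment.char = "#")
  h
}

#' Write a hit table in the 12-column outfmt-6 dialect
#'
#' @param hits Data.frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  stopifnot(all(hit_table_columns() %in% names(hits)))
  utils::write.table(hits[, hit_table_columns()], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

hit_table_columns <- function() {
  c("query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
    "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")
}

#' Construct a padded aligned-contig object
#'
#' An aligned contig is a consensus plus the padded read rows stacked under
#' it; all rows share one length, with `-` for pads and `N` allowed.
#'
#' @param contig_id Contig identifier.
#' @param consensus Consensus sequence (no pads required).
#' @param reads Named character vector of padded read rows, all the same
#'   length as `consensus`.
#' @return An object of class `aligned_contig`.
#' @export
aligned_contig <- function(contig_id, consensus, reads) {
  stopifnot(is.character(consensus), length(consensus) == 1L,
            is.character(reads), length(reads) >= 1L)
  if (any(nchar(reads) != nchar(consensus))) {
    stop("malformed alignment: ragged rows in contig '", contig_id, "'")
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  structure(list(contig_id = contig_id, consensus = consensus, reads = reads),
            class = "aligned_contig")
}

#' @export
print.aligned_contig <- function(x, ...) {
  cat("aligned_contig ", x$contig_id, ": ", nchar(x$consensus), " columns, ",
      length(x$reads), " reads\n", sep = "")
  invisible(x)
}

#' Write aligned contigs as padded multi-FASTA files
#'
#' One file per contig (`<id>.aln.fa`); the first record is the consensus,
#' remaining records are the padded read rows.
#'
#' @param alns List of [aligned_contig()] objects.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_alignments <- function(alns, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(alns, function(a) {
    p <- file.path(dir, paste0(a$contig_id, ".aln.fa"))
    rows <- c(stats::setNames(a$consensus, a$contig_id), a$reads)
    x <- Biostrings::BStringSet(rows)
    Biostrings::writeXStringSet(x, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read one padded aligned-contig multi-FASTA
#'
#' @param path Path written by [write_alignments()]: first record consensus,
#'   rest padded reads.
#' @return An [aligned_contig()] object.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) < 2L) stop("alignment file needs a consensus and >=1 read: ", path)
  rows <- toupper(as.character(x))
  names(rows) <- sub("\\s.*$", "", names(x))
  aligned_contig(names(rows)[1], rows[[1]], rows[-1])
}
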