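#' A read with per-base qualities
#'
#' @param id Read identifier (may carry a description after a space).
#' @param bases ACGTN string.
#' @param quals Integer phred scores (0-60), one per base.
#' @return A `qual_read` object.
#' @export
qual_read <- function(id, bases, quals) {
  bases <- toupper(bases)
  if (nchar(bases) != length(quals)) {
    stop("read '", id, "': ", nchar(bases), " bases but ",
         length(quals), " quality values")
  }
  structure(list(id = id, bases = bases, quals = as.integer(quals)),
            class = "qual_read")
}

#' @export
print.qual_read <- function(x, ...) {
  cat("qual_read ", x$id, " (", nchar(x$bases), " bp, mean Q ",
      round(mean(x$quals), 1), ")\n", sep = "")
  invisible(x)
}

#' Read-trimming configuration
#'
#' Defaults follow the pipeline that produced the 454 coral assembly:
#' reject reads with more than one N, average quality below 20, or length
#' outside 280-530 bp after clipping the SMART CAP primer from either end.
#' Boundary semantics are strict: 280 bp, 530 bp and an average quality of
#' exactly 20 are all kept.
#'
#' @param max_n Maximum tolerated N count (default 1).
#' @param min_avg_qual Minimum arithmetic-mean phred quality (default 20).
#' @param min_len,max_len Post-clip length window in bp (defaults 280, 530).
#' @param primer Primer to screen (default [smart_primer()]).
#' @param max_primer_mismatches Substitution tolerance for primer matching
#'   (no indels; default 2).
#' @return A `qc_config` list.
#' @export
qc_config <- function(max_n = 1L, min_avg_qual = 20, min_len = 280L,
                      max_len = 530L, primer = smart_primer(),
                      max_primer_mismatches = 2L) {
  if (min_len >= max_len) stop("min_len must be < max_len")
  if (!nzchar(primer)) stop("primer must be non-empty")
  structure(list(max_n = as.integer(max_n), min_avg_qual = min_avg_qual,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 primer = toupper(primer),
                 max_primer_mismatches = as.integer(max_primer_mismatches)),
            class = "qc_config")
}

primer_hits <- function(bases, primer, max_mm) {
  subj <- Biostrings::DNAString(bases)
  hits <- Biostrings::matchPattern(primer, subj, max.mismatch = max_mm,
                                   with.indels = FALSE, fixed = FALSE)
  cbind(start = BiocGenerics::start(hits), end = BiocGenerics::end(hits))
}

#' Clip SMART-primer occurrences from a read's ends
#'
#' Any occurrence of the primer, or of its reverse complement, within the
#' mismatch tolerance is removed together with all bases outboard of it
#' (toward the nearer read end); qualities are clipped in lockstep. Reads
#' without a primer occurrence are returned unchanged.
#'
#' @param read A [qual_read()].
#' @param cfg A [qc_config()].
#' @return The clipped `qual_read`.
#' @export
screen_primer <- function(read, cfg = qc_config()) {
  stopifnot(inherits(read, "qual_read"))
  len <- nchar(read$bases)
  if (len < nchar(cfg$primer)) return(read)
  occ <- rbind(primer_hits(read$bases, cfg$primer, cfg$max_primer_mismatches),
               primer_hits(read$bases, revcomp(cfg$primer),
                           cfg$max_primer_mismatches))
  if (nrow(occ) == 0L) return(read)
  keep_from <- 1L
  keep_to <- len
  mid <- (len + 1) / 2
  for (i in seq_len(nrow(occ))) {
    center <- (occ[i, "start"] + occ[i, "end"]) / 2
    if (center <= mid) {
      keep_from <- max(keep_from, occ[i, "end"] + 1L)
    } else {
      keep_to <- min(keep_to, occ[i, "start"] - 1L)
    }
  }
  if (keep_from > keep_to) {
    return(qual_read(read$id, "", integer(0)))
  }
  qual_read(read$id, substr(read$bases, keep_from, keep_to),
            read$quals[keep_from:keep_to])
}

#' Apply the whole-read rejection rules
#'
#' A read is rejected iff its N count exceeds `max_n`, its mean quality is
#' below `min_avg_qual`, or its length falls outside `[min_len, max_len]`.
#' The first failing rule (checked in the order length, N count, quality) is
#' reported as the reason.
#'
#' @param read A [qual_read()], already primer-screened.
#' @param cfg A [qc_config()].
#' @return List with `keep` (logical) and `reason` (`NA` when kept, else one
#'   of `"length"`, `"n_count"`, `"quality"`).
#' @export
filter_read <- function(read, cfg = qc_config()) {
  stopifnot(inherits(read, "qual_read"))
  len <- nchar(read$bases)
  if (len < cfg$min_len || len > cfg$max_len) {
    return(list(keep = FALSE, reason = "length"))
  }
  n_count <- lengths(regmatches(read$bases, gregexpr("N", read$bases, fixed = TRUE)))
  if (n_count > cfg$max_n) return(list(keep = FALSE, reason = "n_count"))
  if (mean(read$quals) < cfg$min_avg_qual) {
    return(list(keep = FALSE, reason = "quality"))
  }
  list(keep = TRUE, reason = NA_character_)
}

#' Run the full QC pass over a set of reads
#'
#' Primer screening first (length is judged on the clipped read), then the
#' whole-read rules. Conservation holds: `n_in = n_out + sum(rejections)`.
#'
#' @param reads List of [qual_read()] objects, or a FASTQ path.
#' @param cfg A [qc_config()].
#' @return List with `reads` (survivors, primer-clipped) and `report`
#'   (class `qc_report`): n_in, n_out, total_bp_in/out, mean_len_in/out,
#'   n_primer_clipped, and per-filter rejection tallies.
#' @export
run_qc <- function(reads, cfg = qc_config()) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  n_in <- length(reads)
  len_in <- vapply(reads, function(r) nchar(r$bases), integer(1))
  rejections <- c(length = 0L, n_count = 0L, quality = 0L)
  out <- vector("list", n_in)
  clipped <- 0L
  kept <- 0L
  for (r in reads) {
    r2 <- screen_primer(r, cfg)
    if (nchar(r2$bases) != nchar(r$bases)) clipped <- clipped + 1L
    verdict <- filter_read(r2, cfg)
    if (verdict$keep) {
      kept <- kept + 1L
      out[[kept]] <- r2
    } else {
      rejections[[verdict$reason]] <- rejections[[verdict$reason]] + 1L
    }
  }
  out <- out[seq_len(kept)]
  len_out <- vapply(out, function(r) nchar(r$bases), integer(1))
  report <- structure(list(
    n_in = n_in, n_out = kept,
    total_bp_in = sum(len_in), total_bp_out = sum(len_out),
    mean_len_in = if (n_in) mean(len_in) else NA_real_,
    mean_len_out = if (kept) mean(len_out) else NA_real_,
    n_primer_clipped = clipped,
    rejections = as.list(rejections)), class = "qc_report")
  list(reads = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC: ", x$n_in, " reads in, ", x$n_out, " kept (",
      x$n_primer_clipped, " primer-clipped)\n", sep = "")
  cat("  rejected:", paste(names(x$rejections), unlist(x$rejections),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a Sanger-encoded FASTQ file
#'
#' @param path FASTQ path (phred+33).
#' @return List of [qual_read()] objects.
#' @export
read_fastq <- function(path) {
  # Biostrings warns when headers carry descriptions (metadata cols dropped);
  # ids keep the full header line, so nothing is lost
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  quals <- as(Biostrings::quality(x), "IntegerList")
  lapply(seq_along(x), function(i) {
    qual_read(names(x)[i], as.character(x[[i]]), as.integer(quals[[i]]))
  })
}

#' Write reads as Sanger-encoded FASTQ
#'
#' @param reads List of [qual_read()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reads) {
    writeLines(c(paste0("@", r$id), r$bases, "+",
                 intToUtf8(pmin(93L, r$quals) + 33L)), con)
  }
  invisible(path)
}
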