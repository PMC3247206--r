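motif_period <- function(motif) {
  # smallest period: length of the shortest motif whose power equals `motif`
  k <- nchar(motif)
  for (d in seq_len(k - 1L)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k / d) == motif) return(d)
  }
  k
}

rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i)
    paste0(substr(motif, i, k), substr(motif, 1L, i - 1L)), character(1))
}

#' Canonical motif class of a microsatellite motif
#'
#' The canonical class is the lexicographic minimum over all rotations of the
#' motif and all rotations of its reverse complement (so GTT, TTG, TGT, AAC,
#' ACA and CAA all map to AAC). A-first alphabetical labels match the usual
#' presentation of trinucleotide spectra (AAC, AAG, AAT, ATC, ...).
#'
#' @param motif ACGT string of length 2-6 that is not a power of a shorter
#'   motif (e.g. "ATAT" is rejected: its class is that of "AT").
#' @return The canonical class string.
#' @export
canonicalize <- function(motif) {
  motif <- toupper(motif)
  if (grepl("[^ACGT]", motif)) stop("motif must be ACGT only: ", motif)
  k <- nchar(motif)
  if (k < 2L || k > 6L) stop("motif length must be 2-6 bp, got ", k)
  if (motif_period(motif) < k) {
    stop("motif '", motif, "' is a power of a shorter motif")
  }
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' Enumerate all canonical motif classes of one length
#'
#' @param k Motif length (2-6).
#' @return Sorted character vector of canonical classes (10 classes for
#'   trinucleotides).
#' @export
canonical_classes <- function(k = 3L) {
  all_motifs <- apply(do.call(expand.grid,
                              rep(list(c("A", "C", "G", "T")), k)),
                      1L, paste, collapse = "")
  irreducible <- all_motifs[vapply(all_motifs, motif_period, integer(1)) == k]
  sort(unique(vapply(irreducible, canonicalize, character(1))))
}

default_min_copies <- function() c(`2` = 6L, `3` = 5L, `4` = 4L, `5` = 4L, `6` = 4L)

# perfect tandem runs of period k in a character vector of bases
perfect_runs <- function(chars, k) {
  n <- length(chars)
  if (n < 2L * k) return(NULL)
  eq <- chars[seq_len(n - k)] == chars[seq_len(n - k) + k] &
    chars[seq_len(n - k)] != "N" & chars[seq_len(n - k) + k] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= k  # run of matches of length m => tract m + k
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep] + k)  # 1-based inclusive
}

#' Find 2-6 bp microsatellite repeats in a sequence
#'
#' A pure-run scanner: perfect tandem tracts of each period are located,
#' adjacent tracts of the same canonical class separated by at most one motif
#' length are merged when the merged tract stays above `min_purity`, tracts
#' whose motif is a power of a shorter motif are reported at the shorter
#' period only, and overlapping candidates are resolved longest-first (then
#' purest, then leftmost). Ns break repeats. Coordinates are 0-based
#' half-open.
#'
#' @param seq ACGTN string.
#' @param seq_id Identifier recorded in the output.
#' @param min_copies Named integer vector of minimum copy numbers per motif
#'   length (`names 2:6`); defaults `c(2=6, 3=5, 4=4, 5=4, 6=4)`.
#' @param min_purity Minimum percent of bases matching the perfect repeat
#'   (default 90).
#' @return Data.frame of loci: `seq_id`, `start`, `end`, `motif` (as found),
#'   `canonical_class`, `copies`, `purity`.
#' @export
find_repeats <- function(seq, seq_id = "seq",
                         min_copies = default_min_copies(),
                         min_purity = 90) {
  empty <- data.frame(seq_id = character(), start = integer(), end = integer(),
                      motif = character(), canonical_class = character(),
                      copies = numeric(), purity = numeric(),
                      stringsAsFactors = FALSE)
  seq <- toupper(seq)
  if (!nzchar(seq)) return(empty)
  chars <- strsplit(seq, NULL)[[1]]
  cand <- list()
  for (k in 2:6) {
    need <- k * min_copies[[as.character(k)]]
    runs <- perfect_runs(chars, k)
    if (is.null(runs)) next
    for (i in seq_len(nrow(runs))) {
      st <- runs$start[i]; en <- runs$end[i]
      motif <- paste(chars[st:(st + k - 1L)], collapse = "")
      if (motif_period(motif) < k) next  # reported at the true period
      if (en - st + 1L < need) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = st - 1L, end = en, motif = motif,
        canonical_class = canonicalize(motif),
        copies = (en - st + 1L) / k, purity = 100,
        k = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- merge_interrupted(cand, chars, min_purity)
  cand <- cand[order(-(cand$end - cand$start), -cand$purity, cand$start), ,
               drop = FALSE]
  taken <- rep(FALSE, nchar(seq))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[span])) {
      keep[i] <- TRUE
      taken[span] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  data.frame(seq_id = rep(seq_id, nrow(out)), out[, c("start", "end", "motif",
             "canonical_class", "copies", "purity")],
             stringsAsFactors = FALSE, row.names = NULL)
}

# merge same-class tracts separated by an impurity run of <= one motif length
merge_interrupted <- function(cand, chars, min_purity) {
  cand <- cand[order(cand$k, cand$canonical_class, cand$start), , drop = FALSE]
  out <- list()
  i <- 1L
  while (i <= nrow(cand)) {
    cur <- cand[i, ]
    j <- i + 1L
    while (j <= nrow(cand) &&
           cand$k[j] == cur$k &&
           cand$canonical_class[j] == cur$canonical_class &&
           cand$start[j] - cur$end <= cur$k &&
           cand$start[j] > cur$end &&
           !any(chars[(cur$end + 1L):cand$start[j]] == "N")) {
      merged_len <- cand$end[j] - cur$start
      matches <- (cur$end - cur$start) + (cand$end[j] - cand$start[j])
      purity <- 100 * matches / merged_len
      if (purity < min_purity) break
      cur$end <- cand$end[j]
      cur$copies <- merged_len / cur$k
      cur$purity <- purity
      j <- j + 1L
    }
    out[[length(out) + 1L]] <- cur
    i <- j
  }
  do.call(rbind, out)
}

#' Scan a set of sequences for microsatellites
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams find_repeats
#' @return Combined loci data.frame (see [find_repeats()]).
#' @export
find_repeats_all <- function(seqs, min_copies = default_min_copies(),
                             min_purity = 90) {
  out <- do.call(rbind, lapply(names(seqs), function(id)
    find_repeats(seqs[[id]], id, min_copies, min_purity)))
  rownames(out) <- NULL
  out
}

#' Motif-length and canonical-class spectrum of repeat loci
#'
#' @param loci Loci data.frame from [find_repeats_all()].
#' @return A `repeat_spectrum` list: `by_length` (counts for lengths 2-6),
#'   `by_tri_class` (counts per canonical trinucleotide class), and `n_aan`
#'   (AAN super-class tally: classes matching A, A, anything).
#' @export
spectrum <- function(loci) {
  klen <- nchar(loci$motif)
  by_length <- vapply(2:6, function(k) sum(klen == k), integer(1))
  names(by_length) <- as.character(2:6)
  tri <- loci$canonical_class[klen == 3L]
  by_tri <- table(factor(tri, levels = canonical_classes(3L)))
  structure(list(by_length = as.list(by_length),
                 by_tri_class = as.list(by_tri),
                 n_aan = sum(grepl("^AA[ACGT]$", tri))),
            class = "repeat_spectrum")
}

#' @export
print.repeat_spectrum <- function(x, ...) {
  cat("repeat spectrum by motif length:",
      paste(names(x$by_length), unlist(x$by_length), sep = "=", collapse = " "),
      "\n  AAN trinucleotides:", x$n_aan, "\n")
  invisible(x)
}

#' Write repeat loci as BED (0-based half-open) plus a motif TSV
#'
#' @param loci Loci data.frame.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_repeats <- function(loci, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(loci$seq_id, loci$start, loci$end,
                      paste0(loci$canonical_class, "x", round(loci$copies, 1)))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(loci, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
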