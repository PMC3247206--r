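#' Simulation configuration for the synthetic transcriptome
#'
#' Defaults mirror a 454-era normalized coral larval library: transcripts of
#' 1030 +/- 623 bp, reads of 398 +/- 118 bp, a SMART CAP primer carried over
#' into a fraction of reads, sparse Ns, and clipped-Gaussian per-base phred
#' qualities.
#'
#' @param n_transcripts Number of transcripts to simulate (> 0).
#' @param transcript_len_mean,transcript_len_sd Transcript length model (bp).
#' @param read_len_mean,read_len_sd Read length model (bp).
#' @param reads_per_transcript Mean sequencing depth per transcript.
#' @param primer_rate Probability a read retains the SMART primer at its
#'   5' end (and, with the same probability, its reverse complement at 3').
#' @param n_rate Per-base probability of an N call in a read.
#' @param quality_mean,quality_sd Per-read mean phred quality model.
#' @param family_geom_p Geometric parameter controlling paralog family sizes;
#'   family size is 1 + Geom(p) per species, so larger `p` means more
#'   single-member families.
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 200,
                       transcript_len_mean = 1030, transcript_len_sd = 623,
                       read_len_mean = 398, read_len_sd = 118,
                       reads_per_transcript = 8,
                       primer_rate = 0.10, n_rate = 0.001,
                       quality_mean = 30, quality_sd = 6,
                       family_geom_p = 0.7,
                       seed = 1L) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              transcript_len_mean = transcript_len_mean,
              transcript_len_sd = transcript_len_sd,
              read_len_mean = read_len_mean, read_len_sd = read_len_sd,
              reads_per_transcript = reads_per_transcript,
              primer_rate = primer_rate, n_rate = n_rate,
              quality_mean = quality_mean, quality_sd = quality_sd,
              family_geom_p = family_geom_p,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!is.finite(cfg$n_transcripts) || cfg$n_transcripts <= 0L) {
    stop("n_transcripts must be a positive count, got ", cfg$n_transcripts)
  }
  for (p in c("primer_rate", "n_rate", "family_geom_p")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]")
  }
  if (cfg$transcript_len_mean <= 0 || cfg$read_len_mean <= 0) {
    stop("length means must be positive")
  }
  invisible(cfg)
}

#' The SMART CAP primer used in cDNA synthesis
#' @return The 23-mer primer as a character scalar.
#' @export
smart_primer <- function() "AAGCAGTGGTATCAACGCAGAGT"

random_dna <- function(n, gc = 0.39) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Generate a ground-truthed synthetic transcriptome
#'
#' Transcripts ("species A") are grouped into gene families shared with a
#' second, sequence-free species ("B"); family sizes per species follow
#' 1 + Geometric(`family_geom_p`) so single-member families dominate. The
#' family structure drives [emit_hit_table()]; the sequences drive every
#' other downstream stage.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` list with elements `transcripts` (named character
#'   vector), `gene_families` (list of `list(a=,b=)` id vectors),
#'   `config`, and empty slots for `planted_snps` / `planted_repeats` filled
#'   by later stages.
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_transcripts
  lens <- pmax(200L, as.integer(round(stats::rnorm(
    n, config$transcript_len_mean, config$transcript_len_sd))))
  ids <- sprintf("apal%05d", seq_len(n))
  seqs <- vapply(lens, random_dna, character(1))
  names(seqs) <- ids

  # carve the n transcripts into families: sizes 1 + Geom(p) per species
  fams <- list()
  i <- 1L; f <- 0L
  while (i <= n) {
    f <- f + 1L
    size_a <- min(1L + stats::rgeom(1L, config$family_geom_p), n - i + 1L)
    size_b <- 1L + stats::rgeom(1L, config$family_geom_p)
    fams[[sprintf("fam%04d", f)]] <- list(
      a = ids[i:(i + size_a - 1L)],
      b = sprintf("nvec%04d_%d", f, seq_len(size_b)))
    i <- i + size_a
  }

  structure(list(transcripts = seqs, gene_families = fams,
                 planted_snps = NULL, planted_repeats = NULL,
                 redundancy_factor = NA_real_,
                 tstv_odds = NA_real_,
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$transcripts), "transcripts,",
      length(x$gene_families), "gene families\n")
  if (!is.null(x$planted_snps)) cat(" ", nrow(x$planted_snps), "planted SNPs\n")
  if (!is.null(x$planted_repeats)) cat(" ", nrow(x$planted_repeats), "planted repeats\n")
  invisible(x)
}

#' Simulate 454-style reads from a ground truth
#'
#' Reads are substrings of transcripts with Gaussian lengths, clipped
#' Gaussian per-read quality plus per-base jitter, optional SMART-primer
#' carry-over at either end, and sparse N calls. All features sit on the
#' forward strand.
#'
#' @param truth A `ground_truth` from [generate_transcriptome()].
#' @param config A [sim_config()]; defaults to the one inside `truth`.
#' @param seed Integer seed.
#' @return A list of `qual_read` objects (see [qual_read()]).
#' @export
simulate_reads <- function(truth, config = truth$config, seed = config$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(seed)
  primer <- smart_primer()
  reads <- list()
  k <- 0L
  for (tid in names(truth$transcripts)) {
    tx <- truth$transcripts[[tid]]
    tlen <- nchar(tx)
    nread <- stats::rpois(1L, config$reads_per_transcript)
    if (nread == 0L) next
    for (j in seq_len(nread)) {
      k <- k + 1L
      rl <- max(50L, as.integer(round(stats::rnorm(
        1L, config$read_len_mean, config$read_len_sd))))
      rl <- min(rl, tlen)
      st <- sample.int(tlen - rl + 1L, 1L)
      bases <- substr(tx, st, st + rl - 1L)
      if (config$n_rate > 0) {
        hit <- which(stats::runif(rl) < config$n_rate)
        if (length(hit)) {
          b <- strsplit(bases, NULL)[[1]]
          b[hit] <- "N"
          bases <- paste(b, collapse = "")
        }
      }
      if (stats::runif(1L) < config$primer_rate) bases <- paste0(primer, bases)
      if (stats::runif(1L) < config$primer_rate) bases <- paste0(bases, revcomp(primer))
      q0 <- stats::rnorm(1L, config$quality_mean, config$quality_sd)
      quals <- as.integer(pmin(40, pmax(2, round(
        q0 + stats::rnorm(nchar(bases), 0, 3)))))
      reads[[k]] <- qual_read(sprintf("read%06d %s", k, tid), bases, quals)
    }
  }
  reads
}

#' Fragment transcripts into redundant contigs
#'
#' The number of fragments per transcript is drawn from a shifted Poisson,
#' 1 + Pois(redundancy - 1), so the mean fragments per transcript equals
#' `redundancy`. Each fragment is a contiguous substring of its source
#' transcript; a provenance map records every contig's origin with 0-based
#' half-open coordinates.
#'
#' @param truth A `ground_truth`.
#' @param redundancy Target mean fragments per transcript (>= 1).
#' @param seed Integer seed.
#' @return A list with `contigs` (named character vector) and `provenance`
#'   (data.frame: contig_id, transcript_id, start, end). The truth's
#'   `redundancy_factor` field is set on the returned copy of `truth`.
#' @export
fragment_contigs <- function(truth, redundancy = 2.2, seed = truth$config$seed) {
  stopifnot(inherits(truth, "ground_truth"))
  if (!is.finite(redundancy) || redundancy < 1) {
    stop("redundancy must be >= 1, got ", redundancy)
  }
  set.seed(seed)
  ids <- names(truth$transcripts)
  nfrag <- 1L + stats::rpois(length(ids), redundancy - 1)
  total <- sum(nfrag)
  contig_id <- sprintf("contig%05d", seq_len(total))
  rows <- vector("list", length(ids))
  contigs <- character(total)
  k <- 0L
  for (i in seq_along(ids)) {
    tx <- truth$transcripts[[i]]
    tlen <- nchar(tx)
    m <- nfrag[i]
    if (m == 1L) {
      st <- 0L; en <- tlen
    } else {
      # fragment lengths 40-100% of the transcript, uniform starts
      fl <- pmax(100L, pmin(tlen, as.integer(round(
        tlen * stats::runif(m, 0.4, 1.0)))))
      st <- vapply(tlen - fl, function(s) sample.int(s + 1L, 1L) - 1L, integer(1))
      en <- st + fl
    }
    idx <- k + seq_len(m)
    contigs[idx] <- substring(tx, st + 1L, en)
    rows[[i]] <- data.frame(contig_id = contig_id[idx],
                            transcript_id = ids[i],
                            start = as.integer(st), end = as.integer(en),
                            stringsAsFactors = FALSE)
    k <- k + m
  }
  names(contigs) <- contig_id
  truth$redundancy_factor <- redundancy
  list(contigs = contigs, provenance = do.call(rbind, rows), truth = truth)
}

#' Plant SNPs into contigs and build padded read stacks
#'
#' Sites are seeded per contig with Binomial(length, density) counts. At each
#' site the alternate allele is a transition with probability
#' `tstv_odds / (1 + tstv_odds)`, else one of the two transversions. A padded
#' read stack (uniform depth in `depth_range`) is fabricated per contig with
#' the minor allele present in at least `max(2, ceiling(0.25 * depth))` rows,
#' so a caller at its default thresholds sees every planted site.
#'
#' @param contigs Named character vector of contig sequences.
#' @param density Expected SNPs per bp (> 0), e.g. `1/272`.
#' @param tstv_odds Transition:transversion odds (>= 0); 0 plants only
#'   transversions.
#' @param depth_range Integer length-2 vector of min/max stack depth.
#' @param seed Integer seed.
#' @return List with `alignments` (list of [aligned_contig()]) and
#'   `planted_snps` (data.frame: contig_id, column (0-based), ref_base,
#'   alt_base, klass, depth, minor_count).
#' @export
plant_snps <- function(contigs, density = 1 / 272, tstv_odds = 2.4,
                       depth_range = c(6L, 12L), seed = 1L) {
  if (!is.finite(density) || density <= 0) stop("density must be > 0")
  if (!is.finite(tstv_odds) || tstv_odds < 0) stop("tstv_odds must be >= 0")
  set.seed(seed)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(A = c("C", "T"), G = c("C", "T"),
                           C = c("A", "G"), T = c("A", "G"))
  p_ts <- if (tstv_odds == 0) 0 else tstv_odds / (1 + tstv_odds)
  alns <- vector("list", length(contigs))
  snp_rows <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    cid <- names(contigs)[i]
    cons <- contigs[[i]]
    len <- nchar(cons)
    depth <- sample(seq.int(depth_range[1], depth_range[2]), 1L)
    nsnp <- stats::rbinom(1L, len, density)
    cols <- if (nsnp > 0) sort(sample.int(len, nsnp)) else integer(0)
    rows <- matrix(rep(strsplit(cons, NULL)[[1]], depth),
                   nrow = depth, byrow = TRUE)
    if (nsnp > 0) {
      ref <- rows[1L, cols]
      is_ts <- stats::runif(nsnp) < p_ts
      alt <- character(nsnp)
      alt[is_ts] <- transition_of[ref[is_ts]]
      if (any(!is_ts)) {
        alt[!is_ts] <- vapply(ref[!is_ts], function(b)
          sample(transversions_of[[b]], 1L), character(1))
      }
      minor <- pmax(2L, as.integer(ceiling(0.25 * depth)))
      for (j in seq_len(nsnp)) {
        carriers <- sample.int(depth, minor)
        rows[carriers, cols[j]] <- alt[j]
      }
      snp_rows[[i]] <- data.frame(
        contig_id = cid, column = cols - 1L, ref_base = ref, alt_base = alt,
        klass = ifelse(is_ts, "transition", "transversion"),
        depth = depth, minor_count = minor, stringsAsFactors = FALSE)
    }
    reads <- apply(rows, 1L, paste, collapse = "")
    names(reads) <- sprintf("%s_r%02d", cid, seq_len(depth))
    alns[[i]] <- aligned_contig(cid, cons, reads)
  }
  planted <- do.call(rbind, snp_rows)
  if (is.null(planted)) {
    planted <- data.frame(contig_id = character(), column = integer(),
                          ref_base = character(), alt_base = character(),
                          klass = character(), depth = integer(),
                          minor_count = integer(), stringsAsFactors = FALSE)
  }
  list(alignments = alns, planted_snps = planted)
}

#' Plant perfect tandem repeats into sequences
#'
#' Each requested locus overwrites `copies` tandem copies of `motif` at a
#' random interior position of a randomly chosen sequence; the flanking base
#' on each side is forced to break the repeat so the planted locus is maximal
#' exactly as recorded. Coordinates are 0-based half-open.
#'
#' @param seqs Named character vector of sequences.
#' @param motifs Character vector of ACGT motifs, each 2-6 bp.
#' @param copies Integer vector (recycled) of tandem copy numbers (>= 3).
#' @param seed Integer seed.
#' @return List with `seqs` (modified) and `planted_repeats`
#'   (data.frame: seq_id, start, motif, copies).
#' @export
plant_repeats <- function(seqs, motifs, copies = 6L, seed = 1L) {
  bad <- nchar(motifs) < 2L | nchar(motifs) > 6L | grepl("[^ACGT]", motifs)
  if (any(bad)) {
    stop("motifs must be ACGT strings of length 2-6; offending: ",
         paste(motifs[bad], collapse = ", "))
  }
  set.seed(seed)
  copies <- rep_len(as.integer(copies), length(motifs))
  rec <- vector("list", length(motifs))
  occupied <- list()  # per seq id: planted windows incl. flanks, as start:end
  for (i in seq_along(motifs)) {
    motif <- motifs[i]
    k <- nchar(motif)
    tract <- strrep(motif, copies[i])
    L <- nchar(tract)
    ok <- names(seqs)[nchar(seqs) >= L + 4L]
    if (!length(ok)) stop("no sequence long enough for motif ", motif)
    # draw windows until one avoids every previously planted locus
    for (try in 1:200) {
      sid <- sample(ok, 1L)
      s <- seqs[[sid]]
      start <- sample.int(nchar(s) - L - 2L, 1L) + 1L  # 1 flank base each side
      window <- (start - 1L):(start + L + 2L)
      if (!length(intersect(window, occupied[[sid]]))) break
      if (try == 200L) stop("could not place motif ", motif,
                            " without overlapping an earlier locus")
    }
    occupied[[sid]] <- c(occupied[[sid]], window)
    substr(s, start + 1L, start + L) <- tract
    # break the repeat at both flanks
    first <- substr(motif, 1L, 1L)
    last <- substr(motif, k, k)
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    substr(s, start, start) <- other(last)            # base before tract
    substr(s, start + L + 1L, start + L + 1L) <- other(first)
    seqs[[sid]] <- s
    rec[[i]] <- data.frame(seq_id = sid, start = start, motif = motif,
                           copies = copies[i], stringsAsFactors = FALSE)
  }
  list(seqs = seqs, planted_repeats = do.call(rbind, rec))
}

#' Emit internally consistent homology hit tables from the family structure
#'
#' Fabricates three outfmt-6 style tables: cross-species (A vs B) and the two
#' self tables. Per family, the seed pair (first member of each species)
#' scores highest across species; other cross pairs score strictly lower;
#' within-species scores of members to their seed meet or exceed the seed
#' pair's score, so InParanoid-style clustering recovers the family exactly.
#' With `noise = 0` there are no between-family hits.
#'
#' @param truth A `ground_truth`.
#' @param noise Probability of adding a spurious low-scoring between-family
#'   cross hit per family.
#' @param seed Integer seed.
#' @return List of data.frames `ab`, `aa`, `bb` in [read_hit_table()] layout.
#' @export
emit_hit_table <- function(truth, noise = 0, seed = truth$config$seed) {
  stopifnot(inherits(truth, "ground_truth"), noise >= 0, noise <= 1)
  set.seed(seed)
  ab <- list(); aa <- list(); bb <- list()
  fam_ids <- names(truth$gene_families)
  base_score <- stats::runif(length(fam_ids), 150, 250)
  for (i in seq_along(fam_ids)) {
    fam <- truth$gene_families[[i]]
    S <- round(base_score[i], 1)
    a <- fam$a; b <- fam$b
    # cross-species: seed pair at S; pairs touching one seed just below, so a
    # non-seed member's best cross partner is always the opposite seed; pairs
    # between two non-seeds lower still
    for (x in a) for (y in b) {
      sc <- if (x == a[1] && y == b[1]) {
        S
      } else if (x == a[1] || y == b[1]) {
        round(S - stats::runif(1, 5, 15), 1)
      } else {
        round(S - stats::runif(1, 20, 30), 1)
      }
      ab[[length(ab) + 1L]] <- hit_row(x, y, sc)
    }
    # within-species: members score >= S against the seed; self scores high
    for (x in a) {
      aa[[length(aa) + 1L]] <- hit_row(x, x, round(S + 60, 1))
      if (x != a[1]) {
        aa[[length(aa) + 1L]] <- hit_row(x, a[1], round(S + stats::runif(1, 0, 40), 1))
      }
    }
    for (y in b) {
      bb[[length(bb) + 1L]] <- hit_row(y, y, round(S + 60, 1))
      if (y != b[1]) {
        bb[[length(bb) + 1L]] <- hit_row(y, b[1], round(S + stats::runif(1, 0, 40), 1))
      }
    }
    if (noise > 0 && stats::runif(1) < noise) {
      j <- sample(seq_along(fam_ids)[-i], 1L)
      y <- truth$gene_families[[j]]$b[1]
      ab[[length(ab) + 1L]] <- hit_row(a[1], y, round(S - stats::runif(1, 40, 60), 1))
    }
  }
  list(ab = do.call(rbind, ab), aa = do.call(rbind, aa), bb = do.call(rbind, bb))
}

hit_row <- function(q, s, bitscore, aln_len = 200L, pident = NULL) {
  if (is.null(pident)) pident <- round(min(99.9, 40 + bitscore / 4), 1)
  data.frame(query_id = q, subject_id = s, pct_identity = pident,
             aln_len = aln_len, mismatches = as.integer(round(aln_len * (100 - pident) / 100)),
             gap_opens = 0L, q_start = 1L, q_end = aln_len,
             s_start = 1L, s_end = aln_len,
             evalue = 10^(-pmin(180, bitscore / 2)), bitscore = bitscore,
             stringsAsFactors = FALSE)
}

#' Hit table linking fragmented contigs back to their source transcripts
#'
#' Stands in for a homology search of the assembly against a single-copy
#' reference: each contig hits exactly its source transcript with a high
#' bitscore and a tiny e-value.
#'
#' @param provenance Provenance data.frame from [fragment_contigs()].
#' @param bitscore,evalue Score assigned to each hit.
#' @return Data.frame in [read_hit_table()] layout.
#' @export
hits_from_provenance <- function(provenance, bitscore = 200, evalue = 1e-60) {
  len <- provenance$end - provenance$start
  data.frame(query_id = provenance$contig_id,
             subject_id = provenance$transcript_id,
             pct_identity = 100, aln_len = len, mismatches = 0L,
             gap_opens = 0L, q_start = 1L, q_end = len,
             s_start = provenance$start + 1L, s_end = provenance$end,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Write the ground-truth manifest as JSON
#'
#' @param truth A `ground_truth` (sequence data is replaced by lengths to keep
#'   the manifest small; FASTA files are the sequence store).
#' @param extras Named list of extra tables (e.g. planted_snps, provenance).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(truth, extras = list(), path) {
  m <- c(list(n_transcripts = length(truth$transcripts),
              transcript_lengths = as.list(stats::setNames(
                nchar(truth$transcripts), names(truth$transcripts))),
              gene_families = truth$gene_families,
              redundancy_factor = truth$redundancy_factor,
              tstv_odds = truth$tstv_odds,
              config = unclass(truth$config)),
         extras)
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
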