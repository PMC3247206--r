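#' Classify a substitution as transition or transversion
#'
#' Purine-purine (A/G) and pyrimidine-pyrimidine (C/T) pairs are transitions;
#' all other pairs are transversions. Vectorized over `a`/`b`.
#'
#' @param a,b Differing bases in ACGT.
#' @return Character vector of `"transition"` / `"transversion"`.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("bases must be in ACGT")
  if (any(a == b)) stop("a and b must differ")
  purine <- c("A", "G")
  ifelse((a %in% purine) == (b %in% purine), "transition", "transversion")
}

base_counts <- function(mat) {
  vapply(c("A", "C", "G", "T"), function(b) colSums(mat == b),
         numeric(ncol(mat)))
}

#' Call SNPs from a padded contig alignment
#'
#' A column is a candidate SNP iff its non-gap non-N depth is at least
#' `min_depth`, and the second-most-common base reaches both `min_minor`
#' reads and a `min_minor_frac` share of that depth. Columns where a third
#' allele also passes are emitted as the top-2 pair and flagged
#' `multiallelic`. Gaps and Ns never count toward depth; indels are not
#' called.
#'
#' @param aln An [aligned_contig()].
#' @param min_depth Minimum usable depth (default 4).
#' @param min_minor Minimum minor-allele read count (default 2).
#' @param min_minor_frac Minimum minor-allele frequency (default 0.2).
#' @return Data.frame of calls (`contig_id`, `column` 0-based, `major_base`,
#'   `minor_base`, `major_count`, `minor_count`, `depth`, `klass`,
#'   `multiallelic`) with attribute `assayed_bp` = number of columns meeting
#'   `min_depth`.
#' @export
call_snps <- function(aln, min_depth = 4L, min_minor = 2L,
                      min_minor_frac = 0.2) {
  stopifnot(inherits(aln, "aligned_contig"))
  rows <- strsplit(aln$reads, NULL)
  ncol <- nchar(aln$consensus)
  if (any(lengths(rows) != ncol)) stop("malformed alignment: ragged rows")
  mat <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)
  cnt <- base_counts(mat)          # ncol x 4
  if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)  # single-column case
  depth <- rowSums(cnt)            # per column (rows of cnt are columns)
  assayed <- sum(depth >= min_depth)
  ord <- apply(cnt, 1L, order, decreasing = TRUE)  # 4 x ncol
  first <- cnt[cbind(seq_len(ncol), ord[1L, ])]
  second <- cnt[cbind(seq_len(ncol), ord[2L, ])]
  third <- cnt[cbind(seq_len(ncol), ord[3L, ])]
  is_snp <- depth >= min_depth & second >= min_minor &
    second / pmax(depth, 1) >= min_minor_frac
  idx <- which(is_snp)
  bases <- c("A", "C", "G", "T")
  out <- data.frame(
    contig_id = rep(aln$contig_id, length(idx)),
    column = idx - 1L,
    major_base = bases[ord[1L, idx]],
    minor_base = bases[ord[2L, idx]],
    major_count = first[idx],
    minor_count = second[idx],
    depth = depth[idx],
    multiallelic = third[idx] >= min_minor &
      third[idx] / pmax(depth[idx], 1) >= min_minor_frac,
    stringsAsFactors = FALSE)
  out$klass <- if (nrow(out)) classify_substitution(out$major_base, out$minor_base) else character(0)
  attr(out, "assayed_bp") <- assayed
  out
}

#' Call SNPs across a list of aligned contigs
#'
#' @param alns List of [aligned_contig()] objects.
#' @inheritParams call_snps
#' @return Data.frame of all calls with attribute `assayed_bp` (total
#'   columns meeting `min_depth` across contigs) and `assayed_by_contig`.
#' @export
call_snps_all <- function(alns, min_depth = 4L, min_minor = 2L,
                          min_minor_frac = 0.2) {
  per <- lapply(alns, call_snps, min_depth = min_depth,
                min_minor = min_minor, min_minor_frac = min_minor_frac)
  bp <- vapply(per, attr, numeric(1), which = "assayed_bp")
  names(bp) <- vapply(alns, `[[`, character(1), "contig_id")
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  attr(out, "assayed_bp") <- sum(bp)
  attr(out, "assayed_by_contig") <- bp
  out
}

#' Per-contig transition/transversion ratio
#'
#' @param calls SNP calls for one or more contigs (from [call_snps_all()]).
#' @param assayed_by_contig Optional named vector of assayed bp per contig.
#' @return Data.frame (`contig_id`, `n_ts`, `n_tv`, `ratio`, `assayed_bp`);
#'   `ratio` is `NA` when `n_tv` is 0 (such contigs are excluded from ratio
#'   histograms and tallied separately).
#' @export
contig_tstv <- function(calls, assayed_by_contig = attr(calls, "assayed_by_contig")) {
  sp <- split(calls$klass, calls$contig_id)
  out <- data.frame(
    contig_id = names(sp),
    n_ts = vapply(sp, function(k) sum(k == "transition"), integer(1)),
    n_tv = vapply(sp, function(k) sum(k == "transversion"), integer(1)),
    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$n_tv > 0, out$n_ts / out$n_tv, NA_real_)
  out$assayed_bp <- if (!is.null(assayed_by_contig)) {
    as.numeric(assayed_by_contig[out$contig_id])
  } else NA_real_
  rownames(out) <- NULL
  out
}

#' The six unordered substitution types
#' @return Character vector `c("A/G","C/T","A/C","A/T","C/G","G/T")`.
#' @export
snp_types <- function() c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")

unordered_type <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  paste(lo, hi, sep = "/")
}

#' Transcriptome-wide SNP summary
#'
#' Density uses floor semantics (`1 SNP per floor(bp / n)` bp), percentages
#' are rounded to integers and the global Ts/Tv ratio to one decimal, the
#' scale on which such resources are reported.
#'
#' @param calls SNP calls (from [call_snps_all()]).
#' @param total_assayed_bp Total bp assayed (default: the calls' attribute).
#' @return A `snp_summary` list: `n_snps`, `n_contigs_with_snps`,
#'   `total_assayed_bp`, `density_bp_per_snp`, `pct_ts`, `pct_tv`,
#'   `global_tstv`, `type_counts`, `type_per_kb`.
#' @export
snp_summary <- function(calls, total_assayed_bp = attr(calls, "assayed_bp")) {
  n <- nrow(calls)
  n_ts <- sum(calls$klass == "transition")
  n_tv <- n - n_ts
  type_counts <- table(factor(unordered_type(calls$major_base, calls$minor_base),
                              levels = snp_types()))
  structure(list(
    n_snps = n,
    n_contigs_with_snps = length(unique(calls$contig_id)),
    total_assayed_bp = total_assayed_bp,
    density_bp_per_snp = if (n > 0) floor(total_assayed_bp / n) else NA_real_,
    pct_ts = if (n > 0) as.integer(round(100 * n_ts / n)) else 0L,
    pct_tv = if (n > 0) as.integer(round(100 * n_tv / n)) else 0L,
    global_tstv = if (n_tv > 0) round(n_ts / n_tv, 1) else NA_real_,
    n_ts = n_ts, n_tv = n_tv,
    type_counts = as.list(type_counts),
    type_per_kb = if (isTRUE(total_assayed_bp > 0)) {
      as.list(1000 * unclass(type_counts) / total_assayed_bp)
    } else as.list(stats::setNames(rep(NA_real_, 6), snp_types()))),
    class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  cat("SNP summary: ", x$n_snps, " SNPs in ", x$n_contigs_with_snps,
      " contigs over ", x$total_assayed_bp, " bp\n", sep = "")
  cat("  1 per ", x$density_bp_per_snp, " bp; ", x$pct_ts, "% Ts / ",
      x$pct_tv, "% Tv; Ts/Tv = ", x$global_tstv, "\n", sep = "")
  invisible(x)
}

#' Ts/Tv tail screen for putative selection
#'
#' Contigs with a defined ratio strictly below `low` (candidate positive
#' selection) or strictly above `high` (candidate purifying selection) are
#' flagged; undefined ratios (no transversions) are excluded. The empirical
#' percentile of each threshold among defined ratios is reported so the
#' thresholds can be compared with nominal 5% tails.
#'
#' @param per_contig Data.frame from [contig_tstv()].
#' @param low,high Ratio thresholds (defaults 1 and 5).
#' @return List with `low_set`, `high_set` (contig ids), `n_undefined`, and
#'   `percentile_low` / `percentile_high`.
#' @export
tstv_screen <- function(per_contig, low = 1, high = 5) {
  def <- per_contig[!is.na(per_contig$ratio), , drop = FALSE]
  ratios <- def$ratio
  list(low_set = def$contig_id[ratios < low],
       high_set = def$contig_id[ratios > high],
       n_undefined = sum(is.na(per_contig$ratio)),
       percentile_low = if (length(ratios)) 100 * mean(ratios < low) else NA_real_,
       percentile_high = if (length(ratios)) 100 * mean(ratios <= high) else NA_real_)
}

#' Write SNP calls as a minimal VCF
#'
#' CHROM = contig, 1-based POS, REF = major allele, ALT = minor allele,
#' INFO carries DP, MAC (minor allele count) and CLASS.
#'
#' @param calls SNP calls data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Usable depth\">",
               "##INFO=<ID=MAC,Number=1,Type=Integer,Description=\"Minor allele count\">",
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"transition or transversion\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;MAC=%d;CLASS=%s",
                       calls$contig_id, calls$column + 1L, calls$major_base,
                       calls$minor_base, calls$depth, calls$minor_count,
                       calls$klass), con)
  }
  invisible(path)
}
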