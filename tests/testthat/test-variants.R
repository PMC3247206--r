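stack_from <- function(cols, id = "c1") {
  # cols: list of character vectors, one per column, all same depth
  depth <- length(cols[[1]])
  rows <- vapply(seq_len(depth), function(i)
    paste(vapply(cols, `[`, character(1), i), collapse = ""), character(1))
  aligned_contig(id, paste(vapply(cols, `[`, character(1), 1L), collapse = ""),
                 rows)
}

test_that("substitution classification enumerates 4 transitions, 8 transversions", {
  expect_identical(classify_substitution("A", "G"), "transition")
  expect_identical(classify_substitution("A", "T"), "transversion")
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(a = bases, b = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  klass <- classify_substitution(pairs$a, pairs$b)
  expect_identical(sum(klass == "transition"), 4L)
  expect_identical(sum(klass == "transversion"), 8L)
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "ACGT")
})

test_that("call_snps applies the depth/minor thresholds column-wise", {
  aln <- stack_from(list(c("A", "A", "A", "G", "G"),
                         rep("C", 5),
                         c("A", "A", "A", "A", "G")))
  calls <- call_snps(aln)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$column, 0L)
  expect_identical(calls$major_base, "A")
  expect_identical(calls$minor_base, "G")
  expect_identical(calls$klass, "transition")
  expect_identical(attr(calls, "assayed_bp"), 3L)

  # minor count 1 never calls, whatever the depth
  aln2 <- stack_from(list(c(rep("A", 9), "G")))
  expect_identical(nrow(call_snps(aln2)), 0L)
  # gaps and Ns are excluded from depth
  aln3 <- stack_from(list(c("A", "A", "-", "N", "G", "G")))
  calls3 <- call_snps(aln3)
  expect_identical(calls3$depth, 4)
  expect_error(aligned_contig("x", "ACGT", c("ACGT", "ACG")), "ragged")
})

test_that("call_snps agrees with a column-counting oracle on random stacks", {
  set.seed(23)
  for (rep in 1:15) {
    depth <- sample(4:12, 1)
    width <- sample(10:50, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), depth * width, TRUE,
                         prob = c(0.3, 0.25, 0.2, 0.15, 0.05, 0.05)),
                  nrow = depth)
    rows <- apply(mat, 1, paste, collapse = "")
    aln <- aligned_contig("r", rows[1], rows)
    got <- call_snps(aln)
    want <- oracle_call_snps(mat)
    expect_identical(got$column, want$column)
    expect_identical(got$major_base, want$major_base)
    expect_identical(got$minor_base, want$minor_base)
  }
})

test_that("planted SNPs are recalled perfectly with no false calls", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 60, seed = 29L))
  ps <- plant_snps(truth$transcripts, density = 1 / 150, tstv_odds = 2.4,
                   seed = 29L)
  calls <- call_snps_all(ps$alignments)
  got <- paste(calls$contig_id, calls$column)
  want <- paste(ps$planted_snps$contig_id, ps$planted_snps$column)
  expect_setequal(got, want)
  m <- match(want, got)
  expect_identical(calls$minor_base[m], ps$planted_snps$alt_base)
  expect_identical(calls$klass[m], ps$planted_snps$klass)
})

test_that("per-contig Ts/Tv handles zero-transversion contigs", {
  calls <- data.frame(contig_id = c(rep("a", 6), rep("b", 3), rep("c", 3)),
                      klass = c(rep("transition", 4), rep("transversion", 2),
                                rep("transition", 3),
                                rep("transversion", 3)),
                      major_base = "A", minor_base = "G",
                      stringsAsFactors = FALSE)
  per <- contig_tstv(calls)
  expect_equal(per$ratio[per$contig_id == "a"], 2.0)
  expect_true(is.na(per$ratio[per$contig_id == "b"]))
  expect_equal(per$ratio[per$contig_id == "c"], 0.0)

  scr <- tstv_screen(per)
  expect_identical(scr$low_set, "c")
  expect_identical(scr$n_undefined, 1L)
})

test_that("summary arithmetic: density floor, rounded percents, 1-dp ratio", {
  set.seed(37)
  n <- 1000
  klass <- rep(c("transition", "transversion"), c(710, 290))
  major <- ifelse(klass == "transition", "A", "A")
  minor <- ifelse(klass == "transition", "G", "T")
  calls <- data.frame(contig_id = sample(paste0("c", 1:50), n, TRUE),
                      klass = klass, major_base = major, minor_base = minor,
                      stringsAsFactors = FALSE)
  s <- snp_summary(calls, total_assayed_bp = 272999)
  expect_identical(s$density_bp_per_snp, 272)
  expect_identical(s$pct_ts, 71L)
  expect_identical(s$pct_tv, 29L)
  expect_identical(s$global_tstv, round(710 / 290, 1))
  # floor semantics: density * n <= bp < (density + 1) * n
  expect_lte(s$density_bp_per_snp * n, 272999)
  expect_lt(272999, (s$density_bp_per_snp + 1) * n)
  # unordered type counts partition the calls
  expect_identical(sum(unlist(s$type_counts)), 1000L)

  s0 <- snp_summary(calls[0, ], total_assayed_bp = 1000)
  expect_true(is.na(s0$density_bp_per_snp))
  expect_identical(s0$n_snps, 0L)
})

test_that("transition fraction recovery stays within 3 binomial sd of the odds", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 500,
                                             transcript_len_mean = 1030,
                                             transcript_len_sd = 100, seed = 43L))
  ps <- plant_snps(truth$transcripts, density = 1 / 45, tstv_odds = 2.4,
                   seed = 43L)
  calls <- call_snps_all(ps$alignments)
  n <- nrow(calls)
  expect_gt(n, 10000)
  p <- 2.4 / 3.4
  frac <- mean(calls$klass == "transition")
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("Ts/Tv screen thresholds behave at boundaries", {
  per <- data.frame(contig_id = paste0("c", 1:4), n_ts = 1, n_tv = 1,
                    ratio = c(0.5, 2.0, 2.4, 6.0))
  scr <- tstv_screen(per)
  expect_identical(scr$low_set, "c1")
  expect_identical(scr$high_set, "c4")
  all2 <- data.frame(contig_id = paste0("c", 1:3), ratio = rep(2, 3))
  scr2 <- tstv_screen(all2)
  expect_length(scr2$low_set, 0L)
  expect_length(scr2$high_set, 0L)
  expect_length(tstv_screen(per, low = 0)$low_set, 0L)
})

test_that("minimal VCF writer emits one well-formed row per call", {
  calls <- data.frame(contig_id = "c1", column = 9L, major_base = "A",
                      minor_base = "G", depth = 8L, minor_count = 3L,
                      klass = "transition")
  f <- tempfile(fileext = ".vcf")
  write_snp_vcf(calls, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_identical(body, "c1\t10\t.\tA\tG\t.\tPASS\tDP=8;MAC=3;CLASS=transition")
})
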