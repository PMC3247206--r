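test_that("transcriptome generation is deterministic and validates input", {
  cfg <- sim_config(n_transcripts = 10, seed = 1L)
  t1 <- generate_transcriptome(cfg)
  t2 <- generate_transcriptome(cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  expect_identical(t1$gene_families, t2$gene_families)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(t1$transcripts, f1); write_fasta(t2$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(all(grepl("^[ACGT]+$", t1$transcripts)))
  expect_error(sim_config(n_transcripts = 0), "positive")
  expect_error(sim_config(primer_rate = 1.5), "\\[0,1\\]")
})

test_that("empirical transcript length mean matches the configured model", {
  n <- 5000
  cfg <- sim_config(n_transcripts = n, transcript_len_mean = 1030,
                    transcript_len_sd = 200, seed = 7L)
  truth <- generate_transcriptome(cfg)
  lens <- nchar(truth$transcripts)
  # lengths are floored at 200 bp; with sd 200 the truncation effect is tiny
  expect_lt(abs(mean(lens) - 1030), 3 * 200 / sqrt(n))
})

test_that("fragmentation hits the requested redundancy and keeps provenance total", {
  cfg <- sim_config(n_transcripts = 1000, transcript_len_sd = 100, seed = 3L)
  truth <- generate_transcriptome(cfg)
  frag <- fragment_contigs(truth, redundancy = 2.2, seed = 5L)
  per_tx <- table(frag$provenance$transcript_id)
  expect_lt(abs(mean(per_tx) - 2.2) / 2.2, 0.05)
  # every contig is a substring of exactly one transcript at the recorded spot
  expect_identical(sort(names(frag$contigs)), sort(frag$provenance$contig_id))
  idx <- sample(nrow(frag$provenance), 50)
  for (i in idx) {
    p <- frag$provenance[i, ]
    expect_identical(frag$contigs[[p$contig_id]],
                     substr(truth$transcripts[[p$transcript_id]],
                            p$start + 1L, p$end))
  }
  expect_error(fragment_contigs(truth, redundancy = 0.5), ">= 1")
})

test_that("redundancy 1 means one full-length contig per transcript", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 8, seed = 2L))
  frag <- fragment_contigs(truth, redundancy = 1, seed = 2L)
  expect_length(frag$contigs, 8L)
  expect_identical(unname(frag$contigs),
                   unname(truth$transcripts[frag$provenance$transcript_id]))
})

test_that("planted SNP classes follow the transition odds and Poisson density", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 300,
                                             transcript_len_mean = 1030,
                                             transcript_len_sd = 100, seed = 11L))
  ps <- plant_snps(truth$transcripts, density = 1 / 30, tstv_odds = 2.4,
                   seed = 11L)
  n <- nrow(ps$planted_snps)
  expect_gt(n, 5000)
  p <- 2.4 / 3.4
  ts_frac <- mean(ps$planted_snps$klass == "transition")
  expect_lt(abs(ts_frac - p), 3 * sqrt(p * (1 - p) / n))
  # planted count obeys the binomial/Poisson sampling bound
  total_bp <- sum(nchar(truth$transcripts))
  lambda <- total_bp / 30
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  # class labels agree with the classifier applied to the base pairs
  expect_identical(ps$planted_snps$klass,
                   classify_substitution(ps$planted_snps$ref_base,
                                         ps$planted_snps$alt_base))
  expect_error(plant_snps(truth$transcripts, density = 0), "> 0")
})

test_that("zero transition odds plants only transversions", {
  seqs <- c(s1 = strrep("ACGTGCTAAG", 200))
  ps <- plant_snps(seqs, density = 1 / 20, tstv_odds = 0, seed = 4L)
  expect_gt(nrow(ps$planted_snps), 20)
  expect_true(all(ps$planted_snps$klass == "transversion"))
})

test_that("plant_repeats records exact loci, rejects bad motifs, is deterministic", {
  set.seed(9)
  seqs <- c(a = random_seq(800), b = random_seq(800))
  p1 <- plant_repeats(seqs, c("AC", "ATC"), c(8L, 6L), seed = 9L)
  p2 <- plant_repeats(seqs, c("AC", "ATC"), c(8L, 6L), seed = 9L)
  expect_identical(p1, p2)
  for (i in seq_len(nrow(p1$planted_repeats))) {
    r <- p1$planted_repeats[i, ]
    tract <- substr(p1$seqs[[r$seq_id]], r$start + 1L,
                    r$start + nchar(r$motif) * r$copies)
    expect_identical(tract, strrep(r$motif, r$copies))
  }
  # sequence outside the planted windows is untouched
  r <- p1$planted_repeats[p1$planted_repeats$seq_id == "a", ][1, ]
  if (!is.na(r$seq_id) && r$start > 10) {
    expect_identical(substr(p1$seqs[["a"]], 1, r$start - 2),
                     substr(seqs[["a"]], 1, r$start - 2))
  }
  expect_error(plant_repeats(seqs, "ACGTACG"), "2-6")
  expect_error(plant_repeats(seqs, "AN"), "2-6")
})

test_that("emitted hit tables are self-consistent with the family structure", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 40, seed = 21L))
  hits <- emit_hit_table(truth, noise = 0, seed = 21L)
  # round-trips through the reader bit-exactly
  f <- tempfile(fileext = ".tsv")
  write_hit_table(hits$ab, f)
  back <- read_hit_table(f)
  expect_equal(back, hits$ab)
  # brute-force MBH on the emitted table equals the recorded family seeds
  cross <- data.frame(a = hits$ab$query_id, b = hits$ab$subject_id,
                      score = hits$ab$bitscore, stringsAsFactors = FALSE)
  seeds <- oracle_mbh(cross)
  expected <- do.call(rbind, lapply(truth$gene_families, function(f)
    data.frame(seed_a = f$a[1], seed_b = f$b[1], stringsAsFactors = FALSE)))
  expect_identical(seeds[order(seeds$seed_a), c("seed_a", "seed_b")],
                   `rownames<-`(expected[order(expected$seed_a), ], NULL))
  # within-family cross scores always beat any between-family score (absent = 0)
  expect_true(all(hits$ab$bitscore > 0))
})
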