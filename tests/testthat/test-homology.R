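mk_hits <- function(q, s, bits, evalue = 1e-20, pident = 95) {
  do.call(rbind, Map(function(qi, si, bi, ei)
    txchar:::hit_row(qi, si, bi, pident = pident), q, s, bits, evalue))
}

test_that("reference dedup keeps greedy longest-first survivors", {
  lens <- c(A = 500, B = 500, C = 500)
  self <- rbind(txchar:::hit_row("A", "B", 300, pident = 95),
                txchar:::hit_row("B", "C", 300, pident = 95),
                txchar:::hit_row("A", "C", 150, pident = 50))
  expect_identical(dedup_reference(lens, self), c("A", "C"))

  # identical pair: first by tie-break survives
  lens2 <- c(x = 400, y = 400)
  self2 <- txchar:::hit_row("x", "y", 400, pident = 100)
  expect_identical(dedup_reference(lens2, self2), "x")

  # no hit between them: both kept; below-threshold hit never removes
  self3 <- txchar:::hit_row("x", "y", 100, pident = 80)
  expect_identical(dedup_reference(lens2, self3), c("x", "y"))
  expect_error(dedup_reference(lens2, NULL), "all-vs-all")
})

test_that("best unique hits match the repeated-extraction oracle", {
  h <- mk_hits(c("q1", "q2", "q2"), c("s1", "s1", "s2"), c(100, 90, 80))
  got <- best_unique_hits(h)
  expect_identical(got[, c("query_id", "subject_id")],
                   data.frame(query_id = c("q1", "q2"),
                              subject_id = c("s1", "s2"),
                              stringsAsFactors = FALSE))

  expect_identical(nrow(best_unique_hits(mk_hits("q", "s", 40))), 0L)
  expect_identical(best_unique_hits(mk_hits("q", "s", 45))$subject_id, "s")

  # randomized tables up to 20x20 against the oracle
  set.seed(17)
  for (rep in 1:20) {
    nq <- sample(3:20, 1); ns <- sample(3:20, 1)
    n <- sample(10:60, 1)
    h <- mk_hits(paste0("q", sample(nq, n, TRUE)),
                 paste0("s", sample(ns, n, TRUE)),
                 round(runif(n, 30, 200), 1))
    h <- h[!duplicated(h[, c("query_id", "subject_id")]), ]
    got <- best_unique_hits(h)
    want <- oracle_best_unique(h)
    expect_identical(
      `rownames<-`(got[order(got$query_id), c("query_id", "subject_id")], NULL),
      `rownames<-`(want[order(want$query_id), c("query_id", "subject_id")], NULL))
  }
})

test_that("length ratios, modal bin, and reference coverage come out right", {
  map <- data.frame(query_id = c("c1", "c2", "c3"),
                    subject_id = c("n1", "n2", "n3"))
  ql <- c(c1 = 530, c2 = 500, c3 = 531)
  sl <- c(n1 = 500, n2 = 500, n3 = 500, n4 = 500)
  s <- length_ratio_summary(map, ql, sl, n_reference = 4)
  expect_equal(s$length_ratios[1], 106)
  expect_equal(s$length_ratios[2], 100)
  expect_equal(s$pct_reference_hit, 75)
  # two of three ratios fall in the [106,108) bin -> modal midpoint 107
  expect_equal(s$modal_ratio, 107)

  s83 <- length_ratio_summary(
    data.frame(query_id = paste0("q", 1:83), subject_id = paste0("n", 1:83)),
    stats::setNames(rep(100, 83), paste0("q", 1:83)),
    stats::setNames(rep(100, 100), paste0("n", 1:100)))
  expect_equal(s83$pct_reference_hit, 83)
})

test_that("redundancy mean counts distinct sequences per ortholog above cutoffs", {
  h <- rbind(mk_hits(c("c1"), c("gene1"), 200),
             mk_hits(c("c2", "c3", "c4"), rep("gene2", 3), c(200, 180, 150)))
  r <- redundancy_factor(h, c("gene1", "gene2"))
  expect_equal(r$mean, 2.0)
  expect_equal(r$range, c(1, 3))
  expect_equal(r$fraction_multiple, 0.5)

  r1 <- redundancy_factor(mk_hits(c("c1", "c2"), c("g1", "g2"), c(200, 200)),
                          c("g1", "g2"))
  expect_equal(r1$mean, 1.0)
  expect_equal(r1$fraction_multiple, 0)

  # below-cutoff hits and unlisted subjects are ignored; unhit reported apart
  weak <- mk_hits("c9", "g3", 60)  # bitscore < 130
  r2 <- redundancy_factor(rbind(h, weak), c("gene1", "gene2", "g3"))
  expect_equal(r2$n_unhit, 1L)
  expect_equal(r2$mean, 2.0)
  expect_error(redundancy_factor(h, character(0)), "non-empty")
})

test_that("gene count estimate uses floor semantics", {
  expect_identical(gene_count_estimate(42630, 2.2), 19377L)
  expect_identical(gene_count_estimate(100, 1.0), 100L)
  expect_identical(gene_count_estimate(7, 2.0), 3L)
  expect_error(gene_count_estimate(10, 0), "> 0")
})

test_that("synthetic fragmentation recovers redundancy and the gene count", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 1000,
                                             transcript_len_sd = 100, seed = 13L))
  frag <- fragment_contigs(truth, redundancy = 2.2, seed = 13L)
  hits <- hits_from_provenance(frag$provenance)
  r <- redundancy_factor(hits, names(truth$transcripts))
  expect_lt(abs(r$mean - 2.2) / 2.2, 0.10)
  est <- gene_count_estimate(length(frag$contigs), r$mean)
  expect_lt(abs(est - 1000) / 1000, 0.10)
})

test_that("informative-annotation selection walks ranks and flags fallbacks", {
  ranked <- data.frame(
    subject_id = c("P1", "P2"),
    description = c("Predicted protein", "Heat shock protein 70"),
    bitscore = c(200, 180), evalue = c(1e-40, 1e-35),
    stringsAsFactors = FALSE)
  a <- select_informative_annotation(ranked)
  expect_identical(a$chosen_subject, "P2")
  expect_identical(a$rank_used, 2L)
  expect_true(a$informative)

  only_bad <- data.frame(subject_id = c("U1", "U2"),
                         description = c("uncharacterized protein LOC1",
                                         "Uncharacterized protein LOC2"),
                         bitscore = c(90, 80), evalue = c(1e-20, 1e-18))
  b <- select_informative_annotation(only_bad)
  expect_identical(b$chosen_subject, "U1")
  expect_false(b$informative)

  below <- data.frame(subject_id = "X", description = "kinase",
                      bitscore = 40, evalue = 1e-10)
  expect_null(select_informative_annotation(below))
})

test_that("annotation efficiency is a rounded percentage", {
  expect_identical(annotation_efficiency(116, 119), 97L)
  expect_identical(annotation_efficiency(0, 119), 0L)
  expect_identical(annotation_efficiency(119, 119), 100L)
})
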