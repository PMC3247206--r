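mk_st <- function(a, b, scores, aa = NULL, bb = NULL, min_bitscore = 40,
                  ids_a = unique(a), ids_b = unique(b)) {
  ab <- do.call(rbind, Map(txchar:::hit_row, a, b, scores))
  score_table(ab, aa, bb, min_bitscore = min_bitscore,
              ids_a = ids_a, ids_b = ids_b)
}

test_that("mutual best hits require reciprocity and break ties by id", {
  st <- mk_st(c("a1", "a1", "a2"), c("b1", "b2", "b1"), c(100, 90, 80))
  seeds <- mutual_best_hits(st)
  expect_identical(seeds$seed_a, "a1")
  expect_identical(seeds$seed_b, "b1")

  # two disjoint perfect pairs are both seeds
  st2 <- mk_st(c("a1", "a2"), c("b1", "b2"), c(100, 90))
  expect_identical(mutual_best_hits(st2)$seed_a, c("a1", "a2"))

  # empty table
  st0 <- mk_st("a1", "b1", 10)  # below the >40 cutoff
  expect_identical(nrow(mutual_best_hits(st0)), 0L)
})

test_that("asymmetric direction pairs are averaged before comparison", {
  ab <- rbind(txchar:::hit_row("a1", "b1", 100),
              txchar:::hit_row("b1", "a1", 80))
  st <- score_table(ab, ids_a = "a1", ids_b = "b1")
  expect_equal(st$score("a1", "b1"), 90)
})

test_that("in-paralog membership follows the seed-score rule", {
  aa <- rbind(txchar:::hit_row("a2", "a1", 120),
              txchar:::hit_row("a3", "a1", 90),
              txchar:::hit_row("a1", "a1", 200))
  st <- mk_st("a1", "b1", 100, aa = aa,
              ids_a = c("a1", "a2", "a3"), ids_b = "b1")
  groups <- cluster_inparalogs(st, mutual_best_hits(st))
  expect_length(groups, 1L)
  g <- groups[[1]]
  expect_identical(sort(g$members_a$id), c("a1", "a2"))  # a3 scores 90 < 100
  expect_identical(g$size_a, 2L)
  expect_equal(g$members_a$confidence[g$members_a$id == "a1"], 1)
  expect_equal(g$members_a$confidence[g$members_a$id == "a2"],
               (120 - 100) / (200 - 100))
})

test_that("groups from a noise-free synthetic table equal the true families", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 60, seed = 53L))
  hits <- emit_hit_table(truth, noise = 0, seed = 53L)
  ids_b <- unlist(lapply(truth$gene_families, `[[`, "b"))
  st <- score_table(hits$ab, hits$aa, hits$bb,
                    ids_a = names(truth$transcripts), ids_b = ids_b)
  seeds <- mutual_best_hits(st)
  expect_identical(nrow(seeds), length(truth$gene_families))
  groups <- cluster_inparalogs(st, seeds)
  got <- lapply(groups, function(g) list(a = sort(g$members_a$id),
                                         b = sort(g$members_b$id)))
  names(got) <- vapply(groups, `[[`, character(1), "seed_a")
  for (fam in truth$gene_families) {
    g <- got[[fam$a[1]]]
    expect_identical(g$a, sort(fam$a))
    expect_identical(g$b, sort(fam$b))
  }
  # groups partition the clustered ids
  all_ids <- unlist(lapply(groups, function(g) c(g$members_a$id, g$members_b$id)))
  expect_identical(anyDuplicated(all_ids), 0L)
  # seeds form a matching
  expect_identical(anyDuplicated(c(seeds$seed_a, seeds$seed_b)), 0L)
})

test_that("implementation matches the exhaustive MBH oracle on random tables", {
  set.seed(59)
  for (rep in 1:15) {
    na <- sample(3:15, 1); nb <- sample(3:15, 1)
    n <- sample(8:40, 1)
    a <- paste0("a", sample(na, n, TRUE))
    b <- paste0("b", sample(nb, n, TRUE))
    sc <- round(runif(n, 41, 200), 1)
    df <- data.frame(a = a, b = b, score = sc, stringsAsFactors = FALSE)
    df <- df[!duplicated(df[, c("a", "b")]), ]
    st <- mk_st(df$a, df$b, df$score,
                ids_a = unique(df$a), ids_b = unique(df$b))
    got <- mutual_best_hits(st)
    want <- oracle_mbh(df)
    want <- want[order(want$seed_a), , drop = FALSE]
    expect_identical(got$seed_a, want$seed_a)
    expect_identical(got$seed_b, want$seed_b)
  }
})

test_that("raising the bitscore cutoff never increases the seed count", {
  truth <- generate_transcriptome(sim_config(n_transcripts = 40, seed = 61L))
  hits <- emit_hit_table(truth, noise = 0.3, seed = 61L)
  ids_b <- unlist(lapply(truth$gene_families, `[[`, "b"))
  n_seeds <- vapply(c(40, 100, 160, 200, 240), function(cut) {
    st <- score_table(hits$ab, hits$aa, hits$bb, min_bitscore = cut,
                      ids_a = names(truth$transcripts), ids_b = ids_b)
    nrow(mutual_best_hits(st))
  }, integer(1))
  expect_true(all(diff(n_seeds) <= 0))
})

test_that("group size distribution tallies and conserves group count", {
  groups <- list(
    structure(list(size_a = 1L, size_b = 1L), class = "paralog_group"),
    structure(list(size_a = 1L, size_b = 1L), class = "paralog_group"),
    structure(list(size_a = 2L, size_b = 1L), class = "paralog_group"))
  d <- group_size_distribution(groups)
  expect_identical(d$n_groups, 3L)
  expect_identical(d$tally$n[d$tally$size_a == 1 & d$tally$size_b == 1], 2L)
  expect_identical(d$tally$n[d$tally$size_a == 2], 1L)
  expect_identical(d$n_larger_than(1), 1L)
  expect_identical(sum(d$tally$n), 3L)

  d0 <- group_size_distribution(list())
  expect_identical(d0$n_groups, 0L)
  expect_identical(nrow(d0$tally), 0L)
})
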