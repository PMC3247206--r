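#!/usr/bin/env Rscript
# Transcriptome completeness and size: redundancy from single-copy reference
# hits, the deflated gene-count estimate, reference coverage and length
# ratios, plus the published arithmetic these procedures reproduce.

suppressPackageStartupMessages(library(txchar))

truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)
contigs <- read_fasta("results/sim/contigs.fa")
hits <- read_hit_table("results/sim/hits_contigs_vs_ref.tsv")
ref_ids <- names(truth$transcript_lengths)

red <- redundancy_factor(hits, ref_ids)
est <- gene_count_estimate(length(contigs), red$mean)
map <- best_unique_hits(hits)
lr <- length_ratio_summary(map, nchar(contigs),
                           unlist(truth$transcript_lengths))

cat(sprintf(paste0(
  "redundancy: mean %.2f (sd %.2f, range %d-%d), %.0f%% of reference genes ",
  "with multiple matches\n"),
  red$mean, red$sd, red$range[1], red$range[2], 100 * red$fraction_multiple))
cat(sprintf("gene-count estimate: %d contigs / %.2f = %d (true: %d)\n",
            length(contigs), red$mean, est, truth$n_transcripts))
cat(sprintf("reference coverage: %.0f%% of reference tagged; modal length ratio %d%%\n",
            lr$pct_reference_hit, lr$modal_ratio))

# the published arithmetic, recomputed with the same operations
anchors <- data.frame(
  quantity = c("gene_count_42630_contigs_at_2.2",
               "assembly_total_sequences",
               "annotation_rate_pct",
               "annotation_efficiency_pct"),
  value = c(gene_count_estimate(42630, 2.2),
            table1_summary(list(contigs = integer(42630),
                                singletons = integer(45390)))$n[3],
            annotation_efficiency(50118, 88020),
            annotation_efficiency(119 - 3, 119)))
print(anchors, row.names = FALSE)

out <- list(redundancy = red[c("mean", "sd", "range", "fraction_multiple")],
            gene_count_estimate = est,
            true_gene_count = truth$n_transcripts,
            pct_reference_hit = lr$pct_reference_hit,
            modal_length_ratio = lr$modal_ratio,
            anchors = anchors)
jsonlite::write_json(out, "results/completeness.json", auto_unbox = TRUE,
                     digits = NA)
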