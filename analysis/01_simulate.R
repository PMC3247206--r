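#!/usr/bin/env Rscript
# Build the ground-truthed synthetic study set every later step consumes:
# transcripts with two-species family structure, 454-style reads, fragmented
# redundant contigs, planted SNPs (2.4:1 Ts:Tv odds, 1 per 272 bp), planted
# 2-6 bp repeats, and internally consistent homology hit tables.

suppressPackageStartupMessages(library(txchar))

seed <- 42L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_transcripts = 150, seed = seed)
truth <- generate_transcriptome(cfg)
reads <- simulate_reads(truth, cfg, seed = seed + 1L)
frag <- fragment_contigs(truth, redundancy = 2.2, seed = seed + 2L)
rep_in <- plant_repeats(frag$contigs,
                        motifs = c("AC", "AAC", "ATC", "AAG", "AAT", "AAGCAG"),
                        copies = c(8L, 6L, 6L, 6L, 6L, 4L), seed = seed + 3L)
snp_in <- plant_snps(rep_in$seqs, density = 1 / 272, tstv_odds = 2.4,
                     seed = seed + 4L)
hits <- emit_hit_table(truth, noise = 0, seed = seed + 5L)

write_fasta(truth$transcripts, file.path(out, "transcripts.fa"))
write_fastq(reads, file.path(out, "reads.fq"))
write_fasta(rep_in$seqs, file.path(out, "contigs.fa"))
write_alignments(snp_in$alignments, file.path(out, "alignments"))
write_hit_table(hits$ab, file.path(out, "hits_ab.tsv"))
write_hit_table(hits$aa, file.path(out, "hits_aa.tsv"))
write_hit_table(hits$bb, file.path(out, "hits_bb.tsv"))
write_hit_table(hits_from_provenance(frag$provenance),
                file.path(out, "hits_contigs_vs_ref.tsv"))
write_manifest(frag$truth,
               list(planted_snps = snp_in$planted_snps,
                    planted_repeats = rep_in$planted_repeats,
                    provenance = frag$provenance,
                    family_b_ids = lapply(truth$gene_families, `[[`, "b")),
               file.path(out, "truth.json"))

cat(sprintf(paste0(
  "simulated %d transcripts in %d families; %d reads; %d contigs ",
  "(target redundancy 2.2);\n%d planted SNPs; %d planted repeats\n"),
  length(truth$transcripts), length(truth$gene_families), length(reads),
  length(rep_in$seqs), nrow(snp_in$planted_snps),
  nrow(rep_in$planted_repeats)))
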