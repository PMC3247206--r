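#!/usr/bin/env Rscript
# SNP discovery from the padded contig alignments, transition/transversion
# summaries, and the Ts/Tv tail screen for putative selection, checked
# against the planted ground truth.

suppressPackageStartupMessages(library(txchar))

truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)
aln_files <- list.files("results/sim/alignments", full.names = TRUE)
alns <- lapply(aln_files, read_alignment)

calls <- call_snps_all(alns)
summ <- snp_summary(calls)
per <- contig_tstv(calls)
scr <- tstv_screen(per)

planted <- truth$planted_snps
recall <- mean(paste(planted$contig_id, planted$column) %in%
                 paste(calls$contig_id, calls$column))
false_calls <- nrow(calls) - nrow(planted)

print(summ)
cat(sprintf("planted-SNP recall %.1f%%, %d false calls\n",
            100 * recall, false_calls))
cat(sprintf("Ts/Tv screen: %d contigs < 1 (%.1f percentile), %d contigs > 5; %d with no Tv\n",
            length(scr$low_set), scr$percentile_low, length(scr$high_set),
            scr$n_undefined))

write_snp_vcf(calls, "results/snps.vcf")
write.table(per, "results/contig_tstv.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(c(unclass(summ),
                       list(recall = recall, false_calls = false_calls,
                            n_low = length(scr$low_set),
                            n_high = length(scr$high_set),
                            low_set = scr$low_set, high_set = scr$high_set)),
                     "results/snp_summary.json", auto_unbox = TRUE, digits = NA)
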