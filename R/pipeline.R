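#' Table-1-style sequence-set summary
#'
#' @param sets Named list of integer length vectors (bp), one per sequence
#'   set (e.g. raw reads, trimmed reads, contigs, singletons).
#' @return Data.frame: set, n, total_mb, mean_len, sd_len, plus a `total`
#'   row (n and Mb summed; means left blank as `NA`). Empty sets report
#'   `n = 0` with undefined means.
#' @export
table1_summary <- function(sets) {
  rows <- lapply(names(sets), function(nm) {
    len <- sets[[nm]]
    data.frame(set = nm, n = length(len),
               total_mb = round(sum(len) / 1e6, 2),
               mean_len = if (length(len)) round(mean(len)) else NA_real_,
               sd_len = if (length(len) > 1) round(stats::sd(len)) else
                 if (length(len) == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(set = "total", n = sum(out$n),
                      total_mb = round(sum(out$total_mb), 2),
                      mean_len = NA_real_, sd_len = NA_real_)
  rbind(out, total)
}

default_run_config <- function() {
  list(
    seed = 42L,
    out_dir = "txchar_run",
    stages = c("simulate", "qc", "completeness", "snps", "ssrs",
               "paralogs", "enrich"),
    simulate = list(n_transcripts = 150, redundancy = 2.2,
                    snp_density = 1 / 272, tstv_odds = 2.4,
                    repeat_motifs = c("AC", "AAC", "ATC", "AAG", "AAGCAG"),
                    repeat_copies = c(8, 6, 6, 6, 4)),
    qc = list(max_n = 1, min_avg_qual = 20, min_len = 280, max_len = 530,
              max_primer_mismatches = 2),
    snps = list(min_depth = 4, min_minor = 2, min_minor_frac = 0.2,
                screen_low = 1, screen_high = 5),
    ssrs = list(min_purity = 90),
    paralogs = list(min_bitscore = 40),
    enrich = list(alpha = 1))
}

config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

merge_config <- function(user, defaults = default_run_config()) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) message("[", stage, "] ", ...)
}

#' Run the whole characterization pipeline on synthetic data
#'
#' Stages execute in dependency order: simulate -> qc -> completeness ->
#' snps -> ssrs -> paralogs -> enrich. Each stage writes its artifacts under
#' `out_dir` and contributes to the run report; a failure halts with a
#' stage-named error. All randomness flows from the single `seed` in the
#' config, so identical configs give identical reports.
#'
#' @param config A named list overriding the defaults, or a path to a YAML
#'   file of the same shape. See `txchar:::default_run_config()` for the full
#'   schema.
#' @param verbose Emit per-stage progress messages.
#' @return A `run_report` list mirroring a sequencing-summary table: per-set
#'   counts and lengths, QC report, completeness/redundancy numbers, SNP
#'   summary, repeat spectrum, paralog group tallies, enrichment rows,
#'   package version and config hash. Also written as JSON under `out_dir`.
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), names(default_run_config()))
  if (length(bad)) {
    stop("unknown config entries: ", paste(bad, collapse = ", "))
  }
  cfg <- merge_config(config)
  known <- default_run_config()$stages
  if (length(setdiff(cfg$stages, known))) {
    stop("unknown stages: ", paste(setdiff(cfg$stages, known), collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("txchar")),
                 seed = cfg$seed, config_hash = config_hash(cfg))
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fn) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    stage_log(verbose, stage, "starting")
    tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    sc <- sim_config(n_transcripts = cfg$simulate$n_transcripts,
                     seed = cfg$seed)
    truth <- generate_transcriptome(sc)
    frag <- fragment_contigs(truth, cfg$simulate$redundancy, seed = cfg$seed + 1L)
    pr <- plant_repeats(frag$contigs, cfg$simulate$repeat_motifs,
                        cfg$simulate$repeat_copies, seed = cfg$seed + 2L)
    ps <- plant_snps(pr$seqs, cfg$simulate$snp_density,
                     cfg$simulate$tstv_odds, seed = cfg$seed + 3L)
    reads <- simulate_reads(truth, sc, seed = cfg$seed + 4L)
    state$truth <- frag$truth
    state$contigs <- pr$seqs
    state$provenance <- frag$provenance
    state$planted_repeats <- pr$planted_repeats
    state$alignments <- ps$alignments
    state$planted_snps <- ps$planted_snps
    state$reads <- reads
    state$hits <- emit_hit_table(truth, noise = 0, seed = cfg$seed + 5L)
    write_fasta(state$contigs, file.path(cfg$out_dir, "contigs.fa"))
    write_fastq(reads, file.path(cfg$out_dir, "reads.fq"))
    write_manifest(frag$truth,
                   list(planted_snps = ps$planted_snps,
                        planted_repeats = pr$planted_repeats,
                        provenance = frag$provenance),
                   file.path(cfg$out_dir, "truth.json"))
    report$simulate <<- list(n_transcripts = length(state$truth$transcripts),
                             n_contigs = length(state$contigs),
                             n_reads = length(reads),
                             n_planted_snps = nrow(ps$planted_snps),
                             n_planted_repeats = nrow(pr$planted_repeats))
  })

  run_stage("qc", function() {
    if (is.null(state$reads)) stop("no reads available; run the simulate stage or supply reads")
    qcfg <- qc_config(max_n = cfg$qc$max_n, min_avg_qual = cfg$qc$min_avg_qual,
                      min_len = cfg$qc$min_len, max_len = cfg$qc$max_len,
                      max_primer_mismatches = cfg$qc$max_primer_mismatches)
    res <- run_qc(state$reads, qcfg)
    state$trimmed <- res$reads
    write_fastq(res$reads, file.path(cfg$out_dir, "reads.trimmed.fq"))
    report$qc <<- unclass(res$report)
  })

  run_stage("completeness", function() {
    if (is.null(state$provenance)) stop("no assembly provenance; run the simulate stage")
    hits <- hits_from_provenance(state$provenance)
    orthologs <- names(state$truth$transcripts)
    red <- redundancy_factor(hits, orthologs)
    map <- best_unique_hits(hits)
    lens_q <- nchar(state$contigs)
    lens_s <- nchar(state$truth$transcripts)
    lr <- length_ratio_summary(map, lens_q, lens_s)
    report$completeness <<- list(
      redundancy_mean = red$mean, redundancy_sd = red$sd,
      fraction_multiple = red$fraction_multiple,
      gene_count_estimate = gene_count_estimate(length(state$contigs), red$mean),
      true_gene_count = length(orthologs),
      pct_reference_hit = lr$pct_reference_hit,
      modal_length_ratio = lr$modal_ratio)
  })

  run_stage("snps", function() {
    if (is.null(state$alignments)) stop("no aligned contigs; run the simulate stage or supply alignments")
    calls <- call_snps_all(state$alignments, cfg$snps$min_depth,
                           cfg$snps$min_minor, cfg$snps$min_minor_frac)
    per <- contig_tstv(calls)
    scr <- tstv_screen(per, cfg$snps$screen_low, cfg$snps$screen_high)
    write_snp_vcf(calls, file.path(cfg$out_dir, "snps.vcf"))
    state$calls <- calls
    state$screen <- scr
    report$snps <<- c(unclass(snp_summary(calls)),
                      list(n_low_tstv = length(scr$low_set),
                           n_high_tstv = length(scr$high_set)))
  })

  run_stage("ssrs", function() {
    if (is.null(state$contigs)) stop("no contigs; run the simulate stage or supply contigs")
    loci <- find_repeats_all(state$contigs, min_purity = cfg$ssrs$min_purity)
    write_repeats(loci, bed_path = file.path(cfg$out_dir, "repeats.bed"),
                  tsv_path = file.path(cfg$out_dir, "repeats.tsv"))
    state$loci <- loci
    report$ssrs <<- unclass(spectrum(loci))
  })

  run_stage("paralogs", function() {
    if (is.null(state$hits)) stop("no hit tables; run the simulate stage or supply hit tables")
    st <- score_table(state$hits$ab, state$hits$aa, state$hits$bb,
                      min_bitscore = cfg$paralogs$min_bitscore)
    seeds <- mutual_best_hits(st)
    groups <- cluster_inparalogs(st, seeds)
    dist <- group_size_distribution(groups)
    utils::write.table(groups_as_table(groups),
                       file.path(cfg$out_dir, "paralog_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$paralogs <<- list(n_seeds = nrow(seeds),
                             n_groups = dist$n_groups,
                             n_inparalogs_a = sum(vapply(groups, `[[`, integer(1), "size_a")),
                             n_inparalogs_b = sum(vapply(groups, `[[`, integer(1), "size_b")),
                             size_tally = dist$tally)
  })

  run_stage("enrich", function() {
    if (is.null(state$screen)) stop("no Ts/Tv screen results; run the snps stage first")
    # synthetic GO map keyed off the contig namespace, seeded like the rest
    set.seed(cfg$seed + 6L)
    ids <- names(state$contigs)
    go_map <- data.frame(
      seq_id = sample(ids, length(ids) * 2, replace = TRUE),
      go_id = sample(sprintf("GO:%07d", 1:25), length(ids) * 2, replace = TRUE))
    subset_ids <- intersect(state$screen$low_set, ids)
    res <- if (length(subset_ids)) {
      enrich_terms(subset_ids, ids, go_map, alpha = cfg$enrich$alpha)
    } else NULL
    report$enrich <<- list(n_tested = if (is.null(res)) 0L else nrow(res),
                           n_signif = if (is.null(res)) 0L else
                             sum(res$p_adjusted <= 0.05))
  })

  # sequencing-summary table over whatever sequence sets the run produced
  sets <- list()
  if (!is.null(state$reads)) {
    sets$raw_reads <- vapply(state$reads, function(r) nchar(r$bases), integer(1))
  }
  if (!is.null(state$trimmed)) {
    sets$trimmed_reads <- vapply(state$trimmed, function(r) nchar(r$bases), integer(1))
  }
  if (!is.null(state$contigs)) sets$contigs <- unname(nchar(state$contigs))
  if (length(sets)) report$table1 <- table1_summary(sets)

  class(report) <- "run_report"
  json <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(unclass(report), json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("txchar run report (version ", x$version, ", seed ", x$seed, ")\n", sep = "")
  for (nm in intersect(c("simulate", "qc", "completeness", "snps", "ssrs",
                         "paralogs", "enrich"), names(x))) {
    cat("  ", nm, ": ", paste(names(x[[nm]])[1:min(3, length(x[[nm]]))],
                              collapse = ", "), " ...\n", sep = "")
  }
  invisible(x)
}
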