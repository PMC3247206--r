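#' Greedy longest-first de-duplication of a reference set
#'
#' Reproduces the usual pre-filter applied to a reference transcript set
#' before completeness estimation: sequences are visited longest first
#' (ties by id) and a sequence is dropped when it has an above-threshold
#' identity hit to an already-kept sequence in the all-vs-all hit table.
#' A sequence with no above-threshold hit is never removed.
#'
#' @param lengths Named numeric vector of sequence lengths (names = ids).
#' @param self_hits All-vs-all hit table in [read_hit_table()] layout.
#' @param similarity_threshold Percent identity above which two sequences are
#'   considered copies (default 90).
#' @return Character vector of surviving ids.
#' @export
dedup_reference <- function(lengths, self_hits, similarity_threshold = 90) {
  if (missing(self_hits) || is.null(self_hits)) {
    stop("dedup_reference needs an all-vs-all self-hit table; ",
         "supply `self_hits` computed over the reference set")
  }
  stopifnot(similarity_threshold > 0, similarity_threshold <= 100)
  ids <- names(lengths)
  ord <- order(-lengths, ids)
  sim <- self_hits[self_hits$query_id != self_hits$subject_id &
                     self_hits$pct_identity > similarity_threshold, ,
                   drop = FALSE]
  # symmetric neighbour lookup
  nb <- split(c(sim$subject_id, sim$query_id), c(sim$query_id, sim$subject_id))
  kept <- character(0)
  kept_set <- new.env(parent = emptyenv())
  for (id in ids[ord]) {
    neigh <- nb[[id]]
    if (is.null(neigh) || !any(vapply(neigh, exists, logical(1),
                                      envir = kept_set, inherits = FALSE))) {
      kept <- c(kept, id)
      assign(id, TRUE, envir = kept_set)
    }
  }
  sort(kept)
}

#' One-to-one best unique query/subject assignment
#'
#' Hits at or above the bitscore cutoff are walked in descending bitscore
#' (ties: ascending e-value, then lexicographic subject id, then query id)
#' and a pair is taken whenever neither its query nor its subject has been
#' used — the usual greedy reading of "only the best unique hit for each
#' query and subject".
#'
#' @param hits Hit table in [read_hit_table()] layout.
#' @param min_bitscore Bitscore cutoff, inclusive (default 45).
#' @return Data.frame with columns query_id, subject_id, bitscore, evalue.
#' @export
best_unique_hits <- function(hits, min_bitscore = 45) {
  h <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  empty <- data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(empty)
  h <- h[order(-h$bitscore, h$evalue, h$subject_id, h$query_id), , drop = FALSE]
  used_q <- new.env(parent = emptyenv())
  used_s <- new.env(parent = emptyenv())
  take <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    q <- h$query_id[i]; s <- h$subject_id[i]
    if (!exists(q, envir = used_q, inherits = FALSE) &&
        !exists(s, envir = used_s, inherits = FALSE)) {
      take[i] <- TRUE
      assign(q, TRUE, envir = used_q)
      assign(s, TRUE, envir = used_s)
    }
  }
  out <- h[take, c("query_id", "subject_id", "bitscore", "evalue"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-ratio completeness summary against a reference transcriptome
#'
#' For every mapped query/subject pair the percent length ratio
#' `100 * query_len / subject_len` is computed; the modal ratio is read from
#' a histogram with 2%-wide bins (bin midpoint reported). The fraction of the
#' reference tagged is `100 * mapped subjects / reference size`.
#'
#' @param map One-to-one map from [best_unique_hits()].
#' @param query_lens,subject_lens Named length vectors.
#' @param n_reference Reference set size (default `length(subject_lens)`).
#' @return List with `length_ratios`, `modal_ratio`, `pct_reference_hit`.
#' @export
length_ratio_summary <- function(map, query_lens, subject_lens,
                                 n_reference = length(subject_lens)) {
  ratios <- 100 * as.numeric(query_lens[map$query_id]) /
    as.numeric(subject_lens[map$subject_id])
  modal <- NA_real_
  if (length(ratios)) {
    breaks <- seq(0, ceiling(max(ratios) / 2) * 2 + 2, by = 2)
    counts <- table(cut(ratios, breaks, right = FALSE))
    top <- which.max(counts)
    modal <- breaks[top] + 1  # bin midpoint
  }
  list(length_ratios = ratios, modal_ratio = modal,
       pct_reference_hit = 100 * length(unique(map$subject_id)) / n_reference)
}

#' Assembly redundancy from single-copy ortholog hit counts
#'
#' Counts the distinct assembled sequences hitting each single-copy ortholog
#' above both score cutoffs. Orthologs without any passing hit are excluded
#' from the mean and reported separately.
#'
#' @param hits Hit table (queries = assembled sequences, subjects = orthologs).
#' @param ortholog_ids Character vector of ortholog ids (non-empty).
#' @param min_bitscore Bitscore cutoff, inclusive (default 130).
#' @param max_evalue E-value cutoff, inclusive (default 2e-38).
#' @return List with `mean`, `sd`, `range`, `fraction_multiple` (share of hit
#'   orthologs matched by >1 sequence), `n_hit`, `n_unhit`, and the
#'   per-ortholog `counts`.
#' @export
redundancy_factor <- function(hits, ortholog_ids, min_bitscore = 130,
                              max_evalue = 2e-38) {
  if (length(ortholog_ids) == 0L) stop("ortholog_ids must be non-empty")
  h <- hits[hits$bitscore >= min_bitscore & hits$evalue <= max_evalue &
              hits$subject_id %in% ortholog_ids, , drop = FALSE]
  counts <- vapply(split(h$query_id, h$subject_id),
                   function(q) length(unique(q)), integer(1))
  counts <- counts[counts > 0]
  n_unhit <- length(setdiff(ortholog_ids, names(counts)))
  if (length(counts) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, range = c(NA, NA),
                fraction_multiple = NA_real_, n_hit = 0L,
                n_unhit = n_unhit, counts = counts))
  }
  list(mean = mean(counts), sd = stats::sd(counts), range = range(counts),
       fraction_multiple = mean(counts > 1),
       n_hit = length(counts), n_unhit = n_unhit, counts = counts)
}

#' Deflate a contig count into a gene-count estimate
#'
#' `floor(n_contigs / redundancy)`: 42,630 contigs at redundancy 2.2 give
#' 19,377 genes.
#'
#' @param n_contigs Number of assembled contigs.
#' @param redundancy Mean contigs per transcript (> 0).
#' @return Integer gene-count estimate.
#' @export
gene_count_estimate <- function(n_contigs, redundancy) {
  if (!is.finite(redundancy) || redundancy <= 0) {
    stop("redundancy must be > 0, got ", redundancy)
  }
  as.integer(floor(n_contigs / redundancy))
}

#' Pick the most informative annotation from ranked hits
#'
#' Hits are walked in rank order; the first hit passing the score cutoffs
#' (bitscore strictly above `min_bitscore`, e-value strictly below
#' `max_evalue`) whose description contains none of the avoid keywords
#' (case-insensitive substring) is chosen. If every passing hit is
#' uninformative, the best passing hit is returned flagged
#' `informative = FALSE`; with no passing hit at all, `NULL`.
#'
#' @param ranked_hits Data.frame with columns `subject_id`, `description`,
#'   `bitscore`, `evalue`, ordered best hit first.
#' @param avoid_keywords Character vector of keywords marking uninformative
#'   descriptions.
#' @param min_bitscore,max_evalue Score cutoffs (defaults 45 and 1e-5).
#' @return A one-row data.frame (`chosen_subject`, `description`,
#'   `rank_used`, `informative`) or `NULL`.
#' @export
select_informative_annotation <- function(ranked_hits,
                                          avoid_keywords = c("uncharacterized protein",
                                                             "predicted protein"),
                                          min_bitscore = 45,
                                          max_evalue = 1e-5) {
  pass <- which(ranked_hits$bitscore > min_bitscore &
                  ranked_hits$evalue < max_evalue)
  if (length(pass) == 0L) return(NULL)
  desc <- tolower(ranked_hits$description)
  uninformative <- Reduce(`|`, lapply(tolower(avoid_keywords), function(k)
    grepl(k, desc, fixed = TRUE)), rep(FALSE, nrow(ranked_hits)))
  informative_pass <- pass[!uninformative[pass]]
  idx <- if (length(informative_pass)) informative_pass[1L] else pass[1L]
  data.frame(chosen_subject = ranked_hits$subject_id[idx],
             description = ranked_hits$description[idx],
             rank_used = idx,
             informative = length(informative_pass) > 0,
             stringsAsFactors = FALSE)
}

#' Annotation efficiency as a rounded percentage
#'
#' @param matched Number of reference genes whose annotation matched.
#' @param total Reference set size.
#' @return Integer percent, `round(100 * matched / total)`.
#' @export
annotation_efficiency <- function(matched, total) {
  stopifnot(total > 0, matched >= 0, matched <= total)
  as.integer(round(100 * matched / total))
}
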