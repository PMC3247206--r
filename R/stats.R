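#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test via [stats::fisher.test()]; the two-sided
#' p-value follows the point-probability rule (sum over tables no more
#' probable than the observed one). A table with a zero margin carries no
#' information: p = 1 with a warning.
#'
#' @param a,b,c,d Non-negative counts: `a` = term in subset, `b` = term in
#'   background only, `c` = subset without term, `d` = neither.
#' @param side `"two.sided"` (default) or `"greater"` (enrichment only).
#' @return The p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, side = c("two.sided", "greater")) {
  side <- match.arg(side)
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  m <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin: Fisher's exact test is undefined, returning p = 1")
    return(1)
  }
  stats::fisher.test(m, alternative = side)$p.value
}

#' Benjamini-Hochberg adjustment of a p-value vector
#'
#' @param ps Numeric vector of raw p-values.
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Adjusted p-values in the input order, capped at 1.
#' @export
adjust_pvalues <- function(ps, method = "BH") {
  stats::p.adjust(ps, method = method)
}

#' GO-term enrichment of a transcript subset by Fisher's exact test
#'
#' One 2x2 test per GO term present in the background; percentages of subset
#' and background annotated with each term are reported alongside raw and
#' BH-adjusted p-values. Terms are sorted by raw p and filtered at
#' `p_adjusted <= alpha` (use `alpha = 1` to keep everything).
#'
#' @param subset_ids Ids in the flagged subset (must be within background).
#' @param background_ids All ids under consideration.
#' @param go_map Data.frame with columns `seq_id`, `go_id` and optionally
#'   `go_term`.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param side Test sidedness, see [fisher_exact_2x2()].
#' @return Data.frame: go_id, go_term, n_subset, n_background, pct_subset,
#'   pct_background, p_raw, p_adjusted.
#' @export
enrich_terms <- function(subset_ids, background_ids, go_map, alpha = 0.05,
                         side = "two.sided") {
  if (!all(subset_ids %in% background_ids)) {
    stop("subset_ids must be a subset of background_ids")
  }
  gm <- go_map[go_map$seq_id %in% background_ids, , drop = FALSE]
  gm <- unique(gm[, intersect(c("seq_id", "go_id", "go_term"), names(gm))])
  n_sub <- length(unique(subset_ids))
  n_bg <- length(unique(background_ids))
  terms <- unique(gm$go_id)
  if (!length(terms)) {
    return(data.frame(go_id = character(), go_term = character(),
                      n_subset = integer(), n_background = integer(),
                      pct_subset = numeric(), pct_background = numeric(),
                      p_raw = numeric(), p_adjusted = numeric()))
  }
  rows <- lapply(terms, function(term) {
    with_term <- unique(gm$seq_id[gm$go_id == term])
    a <- sum(with_term %in% subset_ids)
    b <- length(with_term) - a
    cc <- n_sub - a
    d <- (n_bg - n_sub) - b
    p <- suppressWarnings(fisher_exact_2x2(a, b, cc, d, side = side))
    go_term <- if ("go_term" %in% names(gm)) gm$go_term[match(term, gm$go_id)] else NA_character_
    data.frame(go_id = term, go_term = go_term, n_subset = a,
               n_background = length(with_term),
               pct_subset = round(100 * a / n_sub, 1),
               pct_background = round(100 * length(with_term) / n_bg, 1),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_pvalues(out$p_raw)
  out <- out[order(out$p_raw, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out[out$p_adjusted <= alpha, , drop = FALSE]
}

#' Likelihood ratio test of nested models
#'
#' `2 * (lnL_alt - lnL_null)` compared to the upper tail of a chi-square
#' distribution with `df` degrees of freedom — the statistic used to compare
#' a nearly-neutral site model against one allowing positive selection on a
#' focal branch. A negative statistic (alternative fits worse) yields p = 1
#' with a warning.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the null and alternative model.
#' @param df Degrees of freedom (> 0).
#' @return An `lrt_result` list: `lnL_null`, `lnL_alt`, `two_delta`, `df`,
#'   `p`, and `p_display` (rounded to 2 decimals for reporting).
#' @export
likelihood_ratio_test <- function(lnL_null, lnL_alt, df) {
  if (!is.finite(df) || df <= 0) stop("df must be a positive integer")
  two_delta <- 2 * (lnL_alt - lnL_null)
  if (two_delta < 0) {
    warning("negative 2*delta-lnL: alternative fits worse than null; p = 1")
    p <- 1
  } else {
    p <- stats::pchisq(two_delta, df = df, lower.tail = FALSE)
  }
  structure(list(lnL_null = lnL_null, lnL_alt = lnL_alt,
                 two_delta = two_delta, df = df, p = p,
                 p_display = round(p, 2)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT: 2*dlnL = ", round(x$two_delta, 2), ", df = ", x$df,
      ", p = ", x$p_display, "\n", sep = "")
  invisible(x)
}
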