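# Independent oracles used across tests; kept free of the package's own code
# paths so they can disagree with it.

# exhaustive mutual-best-hit scan over a cross-species score data.frame
oracle_mbh <- function(cross) {
  # cross: data.frame(a, b, score)
  seeds <- list()
  for (a in sort(unique(cross$a))) {
    da <- cross[cross$a == a, , drop = FALSE]
    da <- da[order(-da$score, da$b), , drop = FALSE]
    b <- da$b[1]
    db <- cross[cross$b == b, , drop = FALSE]
    db <- db[order(-db$score, db$a), , drop = FALSE]
    if (db$a[1] == a) seeds[[length(seeds) + 1L]] <- data.frame(
      seed_a = a, seed_b = b, score = da$score[1], stringsAsFactors = FALSE)
  }
  if (!length(seeds)) {
    return(data.frame(seed_a = character(), seed_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, seeds)
}

# repeated-extraction assignment: take the single best remaining hit, retire
# its query and subject, repeat
oracle_best_unique <- function(hits, min_bitscore = 45) {
  h <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  out <- list()
  while (nrow(h) > 0L) {
    h <- h[order(-h$bitscore, h$evalue, h$subject_id, h$query_id), , drop = FALSE]
    top <- h[1L, ]
    out[[length(out) + 1L]] <- top[, c("query_id", "subject_id", "bitscore", "evalue")]
    h <- h[h$query_id != top$query_id & h$subject_id != top$subject_id, , drop = FALSE]
  }
  if (!length(out)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), evalue = numeric()))
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}

# plain column-counting SNP caller over a base matrix (reads only)
oracle_call_snps <- function(mat, min_depth = 4L, min_minor = 2L,
                             min_minor_frac = 0.2) {
  calls <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < min_depth) next
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) < 2L) next
    # deterministic tie-break: among equal counts prefer alphabetical base
    tab <- tab[order(-as.integer(tab), names(tab))]
    minor <- as.integer(tab[2L])
    if (minor < min_minor || minor / length(col) < min_minor_frac) next
    calls[[length(calls) + 1L]] <- data.frame(
      column = j - 1L, major_base = names(tab)[1L], minor_base = names(tab)[2L],
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) {
    return(data.frame(column = integer(), major_base = character(),
                      minor_base = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, calls)
}

# full hypergeometric enumeration of a 2x2 Fisher test via choose()
oracle_fisher <- function(a, b, c, d, side = "two.sided") {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  ks <- max(0L, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c) / choose(n, c1)
  if (side == "greater") {
    sum(probs[ks >= a])
  } else {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# brute-force canonical class: minimum over rotations and revcomp rotations
oracle_canonical <- function(motif) {
  ch <- strsplit(motif, NULL)[[1]]
  k <- length(ch)
  rots <- vapply(seq_len(k), function(i)
    paste(ch[c(i:k, seq_len(i - 1L))[seq_len(k)]], collapse = ""), character(1))
  rc <- rev(chartr("ACGT", "TGCA", ch))
  rots_rc <- vapply(seq_len(k), function(i)
    paste(rc[c(i:k, seq_len(i - 1L))[seq_len(k)]], collapse = ""), character(1))
  min(c(rots, rots_rc))
}

# small deterministic read builder
make_read <- function(bases, qual = 30L, id = "r1") {
  qual_read(id, bases, rep_len(qual, nchar(bases)))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
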