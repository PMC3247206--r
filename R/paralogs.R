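#' Build a symmetric bitscore table from hit tables
#'
#' Pairs are kept above the bitscore cutoff; where a search reports both
#' directions of a pair, the two bitscores are averaged before comparison.
#'
#' @param ab Cross-species hit table (queries species A, subjects species B)
#'   in [read_hit_table()] layout.
#' @param aa,bb Optional within-species self tables (provide self-hits for
#'   confidence scaling).
#' @param min_bitscore Cutoff, exclusive per the usual ">40" convention
#'   (default 40).
#' @param ids_a,ids_b Species id sets; default inferred from `ab`.
#' @return A `score_table` list with `pairs` (data.frame id1, id2, score,
#'   with id1 < id2), `ids_a`, `ids_b`, and a lookup closure `score(x, y)`.
#' @export
score_table <- function(ab, aa = NULL, bb = NULL, min_bitscore = 40,
                        ids_a = unique(ab$query_id),
                        ids_b = unique(ab$subject_id)) {
  all_hits <- rbind(ab, aa, bb)
  all_hits <- all_hits[all_hits$bitscore > min_bitscore, , drop = FALSE]
  id1 <- pmin(all_hits$query_id, all_hits$subject_id)
  id2 <- pmax(all_hits$query_id, all_hits$subject_id)
  key <- paste(id1, id2, sep = "\r")
  score <- vapply(split(all_hits$bitscore, key), mean, numeric(1))
  parts <- strsplit(names(score), "\r", fixed = TRUE)
  pairs <- data.frame(id1 = vapply(parts, `[`, character(1), 1L),
                      id2 = vapply(parts, `[`, character(1), 2L),
                      score = as.numeric(score), stringsAsFactors = FALSE,
                      row.names = NULL)
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(pairs))) {
    assign(paste(pairs$id1[i], pairs$id2[i], sep = "\r"), pairs$score[i], envir = env)
  }
  lookup <- function(x, y) {
    v <- get0(paste(min(x, y), max(x, y), sep = "\r"), envir = env,
              inherits = FALSE)
    if (is.null(v)) NA_real_ else v
  }
  structure(list(pairs = pairs, ids_a = sort(ids_a), ids_b = sort(ids_b),
                 score = lookup, min_bitscore = min_bitscore),
            class = "score_table")
}

cross_pairs <- function(st) {
  p <- st$pairs
  a_first <- p$id1 %in% st$ids_a & p$id2 %in% st$ids_b
  b_first <- p$id1 %in% st$ids_b & p$id2 %in% st$ids_a
  data.frame(a = c(p$id1[a_first], p$id2[b_first]),
             b = c(p$id2[a_first], p$id1[b_first]),
             score = c(p$score[a_first], p$score[b_first]),
             stringsAsFactors = FALSE)
}

best_partner <- function(cp, from = "a", to = "b") {
  out <- lapply(split(cp[, c(to, "score")], cp[[from]]), function(d) {
    d <- d[order(-d$score, d[[to]]), , drop = FALSE]  # ties: lexicographic id
    d[1L, ]
  })
  data.frame(from = names(out),
             to = vapply(out, `[[`, character(1), to),
             score = vapply(out, `[[`, numeric(1), "score"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mutual (reciprocal) best hits between two species
#'
#' A pair is an ortholog seed iff each member is the other's highest-scoring
#' cross-species partner; score ties are broken by lexicographic partner id,
#' making the result deterministic.
#'
#' @param st A [score_table()].
#' @return Data.frame of seeds (`seed_a`, `seed_b`, `score`), sorted by
#'   `seed_a`.
#' @export
mutual_best_hits <- function(st) {
  stopifnot(inherits(st, "score_table"))
  cp <- cross_pairs(st)
  empty <- data.frame(seed_a = character(), seed_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(cp) == 0L) return(empty)
  ba <- best_partner(cp, "a", "b")
  bb <- best_partner(cp, "b", "a")
  back <- stats::setNames(bb$to, bb$from)
  mut <- ba[!is.na(back[ba$to]) & back[ba$to] == ba$from, , drop = FALSE]
  out <- data.frame(seed_a = mut$from, seed_b = mut$to, score = mut$score,
                    stringsAsFactors = FALSE)
  out[order(out$seed_a), , drop = FALSE]
}

#' InParanoid-style in-paralog clustering around ortholog seeds
#'
#' A species-A sequence `x` joins seed `(a, b)` iff `score(x, a) >=
#' score(a, b)` (it is closer to the seed than the two seeds are to each
#' other), symmetrically for species B. Confidence is 1 for seeds; for a
#' member it is `(score(x, a) - S) / (score(a, a) - S)` (capped to [0, 1])
#' when the seed's self-score is known, else 1. A sequence qualifying for
#' several groups is assigned to the one where its confidence is highest
#' (ties: higher seed score, then lexicographic seed id), so groups partition
#' the clustered ids.
#'
#' @param st A [score_table()].
#' @param seeds Seed data.frame from [mutual_best_hits()].
#' @return List of `paralog_group` lists: `seed_a`, `seed_b`, `score`,
#'   `members_a`, `members_b` (data.frames id + confidence), `size_a`,
#'   `size_b`.
#' @export
cluster_inparalogs <- function(st, seeds) {
  stopifnot(inherits(st, "score_table"))
  candidates <- list()  # per id: best (confidence, seed score, group index)
  groups <- vector("list", nrow(seeds))
  member_conf <- function(x, seed, S) {
    if (x == seed) return(1)  # a seed always anchors its own group
    sxa <- st$score(x, seed)
    if (is.na(sxa) || sxa < S) return(NA_real_)
    self <- st$score(seed, seed)
    if (!is.na(self) && self > S) min(1, max(0, (sxa - S) / (self - S))) else 1
  }
  side_members <- function(seed, S, ids) {
    conf <- vapply(ids, member_conf, numeric(1), seed = seed, S = S)
    data.frame(id = ids[!is.na(conf)], confidence = conf[!is.na(conf)],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  for (g in seq_len(nrow(seeds))) {
    a <- seeds$seed_a[g]; b <- seeds$seed_b[g]; S <- seeds$score[g]
    ma <- side_members(a, S, st$ids_a)
    mb <- side_members(b, S, st$ids_b)
    ma$confidence[ma$id == a] <- 1
    mb$confidence[mb$id == b] <- 1
    groups[[g]] <- list(seed_a = a, seed_b = b, score = S,
                        members_a = ma, members_b = mb)
  }
  # resolve ids claimed by several groups: best confidence, then seed score,
  # then lexicographic seed id; seeds always stay in their own group
  claims <- do.call(rbind, lapply(seq_along(groups), function(g) {
    gr <- groups[[g]]
    m <- rbind(cbind(gr$members_a, side = "a"), cbind(gr$members_b, side = "b"))
    m$group <- g
    m$is_seed <- m$id %in% c(gr$seed_a, gr$seed_b)
    m$seed_score <- gr$score
    m$seed_id <- paste(gr$seed_a, gr$seed_b)
    m
  }))
  if (!is.null(claims) && nrow(claims)) {
    claims <- claims[order(claims$id, -claims$is_seed, -claims$confidence,
                           -claims$seed_score, claims$seed_id), , drop = FALSE]
    winner <- claims[!duplicated(claims$id), , drop = FALSE]
    for (g in seq_along(groups)) {
      own <- winner$id[winner$group == g]
      groups[[g]]$members_a <- groups[[g]]$members_a[
        groups[[g]]$members_a$id %in% own, , drop = FALSE]
      groups[[g]]$members_b <- groups[[g]]$members_b[
        groups[[g]]$members_b$id %in% own, , drop = FALSE]
    }
  }
  for (g in seq_along(groups)) {
    groups[[g]]$size_a <- nrow(groups[[g]]$members_a)
    groups[[g]]$size_b <- nrow(groups[[g]]$members_b)
    class(groups[[g]]) <- "paralog_group"
  }
  groups
}

#' @export
print.paralog_group <- function(x, ...) {
  cat("paralog_group seed (", x$seed_a, ", ", x$seed_b, ") score ", x$score,
      ": ", x$size_a, " + ", x$size_b, " members\n", sep = "")
  invisible(x)
}

#' Group-size distribution of paralog groups
#'
#' @param groups List from [cluster_inparalogs()].
#' @return List with `tally` (data.frame size_a, size_b, n) and a helper
#'   `n_larger_than(k)` counting groups whose larger side exceeds `k`.
#' @export
group_size_distribution <- function(groups) {
  if (!length(groups)) {
    tally <- data.frame(size_a = integer(), size_b = integer(), n = integer())
  } else {
    sa <- vapply(groups, `[[`, integer(1), "size_a")
    sb <- vapply(groups, `[[`, integer(1), "size_b")
    key <- paste(sa, sb)
    tally <- data.frame(size_a = sa[!duplicated(key)],
                        size_b = sb[!duplicated(key)],
                        n = as.integer(table(key)[unique(key)]),
                        row.names = NULL)
    tally <- tally[order(tally$size_a, tally$size_b), , drop = FALSE]
  }
  maxside <- pmax(tally$size_a, tally$size_b)
  list(tally = tally,
       n_groups = sum(tally$n),
       n_larger_than = function(k) sum(tally$n[maxside > k]))
}

#' Flatten paralog groups to a long TSV-ready data.frame
#'
#' @param groups List from [cluster_inparalogs()].
#' @return Data.frame: group, species, member, confidence.
#' @export
groups_as_table <- function(groups) {
  out <- do.call(rbind, lapply(seq_along(groups), function(g) {
    gr <- groups[[g]]
    rbind(data.frame(group = g, species = "A", member = gr$members_a$id,
                     confidence = gr$members_a$confidence),
          data.frame(group = g, species = "B", member = gr$members_b$id,
                     confidence = gr$members_b$confidence))
  }))
  rownames(out) <- NULL
  out
}
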