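#' Rank variants within one score by absolute effect weight
#'
#' Rank 1 is the variant with the largest `|effect_weight|`; ties receive the
#' average of the tied rank positions (fractional ranking), which makes the
#' result invariant to the row order of the input.
#'
#' @param score A [score_file()] with at least one variant.
#' @return Named numeric vector of ranks, names = rsids.
#' @examples
#' s <- score_file("PGS1", data.frame(rsid = c("rs1", "rs2", "rs3"),
#'                                    effect_weight = c(-0.9, 0.5, 0.1)))
#' rank_within_file(s)  # rs1 = 1, rs2 = 2, rs3 = 3
#' @export
rank_within_file <- function(score) {
  stopifnot(inherits(score, "score_file"))
  if (!nrow(score$variants)) {
    stop(sprintf("%s: cannot rank an empty score", score$pgs_id),
         call. = FALSE)
  }
  r <- rank(-abs(score$variants$effect_weight), ties.method = "average")
  stats::setNames(r, score$variants$rsid)
}

#' Build the cross-score rank matrix
#'
#' Rows are the union of rsIDs over all scores (N variants, sorted), columns
#' are scores. Each column holds that score's within-file ranks for its own
#' variants; every variant missing from a score is assigned the lowest rank,
#' N. Ranks therefore range from 1 (highest rank) to N.
#'
#' @param files List of [score_file()] objects (at least one, all
#'   quality-controlled and non-empty).
#' @return A numeric N x Q matrix of class `rank_matrix` with rsid rownames
#'   and pgs_id colnames.
#' @export
build_rank_matrix <- function(files) {
  stopifnot(length(files) >= 1L)
  ranks <- lapply(files, rank_within_file)
  ids <- vapply(files, function(f) f$pgs_id, "")
  universe <- sort(unique(unlist(lapply(ranks, names), use.names = FALSE)))
  n <- length(universe)
  m <- matrix(as.numeric(n), nrow = n, ncol = length(files),
              dimnames = list(universe, ids))
  for (j in seq_along(ranks)) {
    m[names(ranks[[j]]), j] <- ranks[[j]]
  }
  class(m) <- c("rank_matrix", class(m))
  m
}

#' Normalize a rank matrix to (0, 1]
#'
#' Two modes. `"fractional"` (default) maps rank r to r / N, keeping every
#' entry strictly positive, which the order-statistic null models (Beta
#' distributions) and the geometric mean require. `"minmax"` is literal
#' min-max scaling (r - 1) / (N - 1), mapping the best rank to 0 and the
#' worst to 1 (defined as 0 when N = 1).
#'
#' @param m A `rank_matrix`.
#' @param mode `"fractional"` or `"minmax"`.
#' @return A matrix of the same shape with attribute `normalization` set to
#'   the mode used.
#' @export
normalize_ranks <- function(m, mode = c("fractional", "minmax")) {
  mode <- match.arg(mode)
  n <- nrow(m)
  out <- if (mode == "fractional") {
    unclass(m) / n
  } else if (n == 1L) {
    array(0, dim = dim(m), dimnames = dimnames(m))
  } else {
    (unclass(m) - 1) / (n - 1)
  }
  attr(out, "normalization") <- mode
  out
}

#' Dowdall consensus score (mean reciprocal rank)
#'
#' The mean over the Q scores of the reciprocal of the variant's rank, using
#' the N-filled matrix so that a score missing the variant contributes 1/N.
#' Values lie in (0, 1]; 1 is attained exactly by a variant ranked first in
#' every score, and a higher value means a consistently higher rank.
#'
#' @param m A `rank_matrix` from [build_rank_matrix()].
#' @return Named numeric vector of MRR scores.
#' @export
mrr_scores <- function(m) {
  stopifnot(all(m >= 1))
  rowMeans(1 / unclass(m))
}

#' Robust Rank Aggregation scores
#'
#' For each variant, its Q normalized ranks are sorted ascending and each
#' r(k) is compared with the null distribution of the k-th order statistic
#' of Q independent Uniform(0,1) draws, i.e. Beta(k, Q - k + 1). The rho
#' score is the minimum of these Q tail probabilities and the corrected
#' score applies a Bonferroni factor Q for the minimum over the Q order
#' statistics tested. Smaller values mean stronger consensus.
#'
#' @param nm A normalized rank matrix from [normalize_ranks()], entries in
#'   (0, 1] (fractional mode) or \[0, 1\] (minmax mode).
#' @return Data.frame with columns `rsid`, `rho`, `corrected`.
#' @export
rra_scores <- function(nm) {
  q <- ncol(nm)
  sorted <- t(apply(unclass(nm), 1L, sort))
  if (q == 1L) sorted <- t(sorted)
  p <- matrix(NA_real_, nrow(nm), q)
  for (k in seq_len(q)) {
    p[, k] <- stats::pbeta(sorted[, k], k, q - k + 1)
  }
  rho <- apply(p, 1L, min)
  data.frame(rsid = rownames(nm), rho = rho,
             corrected = pmin(1, q * rho),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stuart joint order-statistic scores
#'
#' For each variant, the probability that the order statistics
#' U(1) <= ... <= U(Q) of Q independent Uniform(0,1) draws satisfy
#' U(k) <= r(k) simultaneously for all k, where r(1) <= ... <= r(Q) are the
#' variant's sorted normalized ranks. Evaluated exactly by the classical
#' alternating recursion over the sorted ranks, carried in a
#' binomial-coefficient form that avoids factorial overflow. Smaller values
#' mean stronger consensus.
#'
#' @param nm A normalized rank matrix from [normalize_ranks()].
#' @return Named numeric vector of joint probabilities `q` in \[0, 1\].
#' @export
stuart_scores <- function(nm) {
  out <- apply(unclass(nm), 1L, stuart_joint_probability)
  stats::setNames(out, rownames(nm))
}

# P(U(k) <= r_sorted[k] for all k), U(k) uniform order statistics.
# Recursion on u[k] = k! * v[k] where v is the classical Stuart-Aerts
# sequence: u[k] = sum_{t=1..k} (-1)^(t+1) choose(k, t) r_{(Q-k+1)}^t u[k-t],
# answer u[Q]. Keeping u instead of v avoids factorial() overflow at large Q.
stuart_joint_probability <- function(r) {
  r <- sort(r)
  q <- length(r)
  u <- numeric(q + 1L)
  u[1L] <- 1
  for (k in seq_len(q)) {
    t <- seq_len(k)
    rk <- r[q - k + 1L]
    u[k + 1L] <- sum((-1)^(t + 1) * choose(k, t) * rk^t * u[k - t + 1L])
  }
  val <- u[q + 1L]
  if (!is.finite(val)) {
    stop("Stuart joint probability is non-finite; Q too large for exact evaluation",
         call. = FALSE)
  }
  # clamp tiny negative values arising from cancellation in the alternating sum
  min(max(val, 0), 1)
}

#' Borda consensus scores
#'
#' Three classical Borda-style summaries of a variant's normalized ranks
#' across scores: the minimum rank (best position achieved anywhere), the
#' geometric mean, and the arithmetic mean. Smaller values mean stronger
#' consensus.
#'
#' @param nm A normalized rank matrix from [normalize_ranks()].
#' @param mode `"min"`, `"geom"` or `"mean"`.
#' @return Named numeric vector of scores.
#' @export
borda_scores <- function(nm, mode = c("min", "geom", "mean")) {
  mode <- match.arg(mode)
  m <- unclass(nm)
  out <- switch(mode,
    min = apply(m, 1L, min),
    mean = rowMeans(m),
    geom = ifelse(apply(m, 1L, function(x) any(x == 0)), 0,
                  exp(rowMeans(log(m))))
  )
  stats::setNames(out, rownames(nm))
}

#' The six supported rank-aggregation methods
#' @return Character vector of method labels.
#' @export
ra_methods <- function() {
  c("dowdall", "rra", "stuart", "borda_min", "borda_geom", "borda_mean")
}

#' Aggregate variant ranks across scores with consensus-ranking methods
#'
#' Builds the N-filled rank matrix once, then computes consensus scores for
#' each requested method. Dowdall consumes the raw rank matrix (mean
#' reciprocal rank, higher = better); the other five consume the normalized
#' matrix (smaller = better). Each method's scores are converted to an
#' aggregated rank 1..N (1 = strongest consensus), with ties broken
#' deterministically by lexicographic rsid order. The whole computation is
#' deterministic and invariant to the order of the input files.
#'
#' @param files List of curated, aggregation-eligible [score_file()]s.
#' @param methods Subset of [ra_methods()]; defaults to all six.
#' @param normalization Normalization mode for the five normalized-rank
#'   methods, see [normalize_ranks()].
#' @return An object of class `rank_aggregation`: a list with `scores`
#'   (data.frame rsid x per-method score columns), `ranks` (data.frame rsid x
#'   per-method aggregated-rank columns), `rank_matrix`, `normalization`,
#'   `methods`, `n_variants`, `n_files`.
#' @examples
#' f1 <- score_file("PGS1", data.frame(rsid = c("a", "b"),
#'                                     effect_weight = c(0.5, -0.9)),
#'                  source_gwas_ids = "GCST1")
#' f2 <- score_file("PGS2", data.frame(rsid = c("b", "c"),
#'                                     effect_weight = c(0.1, 0.2)),
#'                  source_gwas_ids = "GCST2")
#' agg <- aggregate_ranks(list(f1, f2), methods = "dowdall")
#' agg$scores   # MRR: b = 0.75, c = 2/3, a = 5/12
#' @export
aggregate_ranks <- function(files, methods = ra_methods(),
                            normalization = c("fractional", "minmax")) {
  normalization <- match.arg(normalization)
  unknown <- setdiff(methods, ra_methods())
  if (length(unknown)) {
    stop(sprintf("unknown rank-aggregation method(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!length(files)) {
    stop("no aggregation-eligible score files", call. = FALSE)
  }
  m <- build_rank_matrix(files)
  nm <- normalize_ranks(m, mode = normalization)
  rsids <- rownames(m)

  scores <- data.frame(rsid = rsids, stringsAsFactors = FALSE)
  ranks <- data.frame(rsid = rsids, stringsAsFactors = FALSE)
  for (method in methods) {
    s <- switch(method,
      dowdall = mrr_scores(m),
      rra = stats::setNames(rra_scores(nm)$corrected, rsids),
      stuart = stuart_scores(nm),
      borda_min = borda_scores(nm, "min"),
      borda_geom = borda_scores(nm, "geom"),
      borda_mean = borda_scores(nm, "mean")
    )
    s <- unname(s[rsids])
    scores[[method]] <- s
    # dowdall: higher score = better; others: lower = better
    key <- if (method == "dowdall") -s else s
    ord <- order(key, rsids)
    rk <- integer(length(rsids))
    rk[ord] <- seq_along(rsids)
    ranks[[method]] <- rk
  }

  structure(
    list(scores = scores, ranks = ranks, rank_matrix = m,
         normalization = normalization, methods = methods,
         n_variants = nrow(m), n_files = ncol(m)),
    class = "rank_aggregation"
  )
}

#' @export
print.rank_aggregation <- function(x, ...) {
  cat(sprintf("<rank_aggregation> %d variant(s) x %d score file(s)\n",
              x$n_variants, x$n_files))
  cat(sprintf("  methods: %s (normalization: %s)\n",
              paste(x$methods, collapse = ", "), x$normalization))
  invisible(x)
}

#' @export
summary.rank_aggregation <- function(object, top = 10L, ...) {
  lead <- object$methods[[1L]]
  ord <- order(object$ranks[[lead]])
  top_tab <- object$ranks[ord, , drop = FALSE][seq_len(min(top, object$n_variants)), ]
  cat(sprintf("Top %d variant(s) by %s aggregated rank:\n", nrow(top_tab), lead))
  print(top_tab, row.names = FALSE)
  invisible(top_tab)
}

#' Assemble the ranked output table
#'
#' Joins per-method consensus scores and ranks with gene annotations and
#' priority scores into one table, ordered by ascending Dowdall aggregated
#' rank (or the first computed method if Dowdall is absent).
#'
#' @param agg A `rank_aggregation` object.
#' @param annotations Optional data.frame `rsid`, `gene`, `distance` from
#'   [annotate_nearest_gene()].
#' @param priorities Optional data.frame `rsid`, `score` (and friends) from
#'   [priority_scores()]; variants absent from it get priority 0.
#' @return Data.frame with columns `rsid`, `gene`, `distance`,
#'   `<method>_score`, `<method>_rank`, `priority_score`.
#' @export
ranked_table <- function(agg, annotations = NULL, priorities = NULL) {
  stopifnot(inherits(agg, "rank_aggregation"))
  rsids <- agg$scores$rsid
  out <- data.frame(rsid = rsids, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    i <- match(rsids, annotations$rsid)
    out$gene <- annotations$gene[i]
    out$distance <- annotations$distance[i]
  } else {
    out$gene <- NA_character_
    out$distance <- NA_real_
  }
  for (method in agg$methods) {
    out[[paste0(method, "_score")]] <- agg$scores[[method]]
    out[[paste0(method, "_rank")]] <- agg$ranks[[method]]
  }
  if (!is.null(priorities)) {
    i <- match(rsids, priorities$rsid)
    out$priority_score <- ifelse(is.na(i), 0, priorities$score[i])
  } else {
    out$priority_score <- NA_real_
  }
  lead <- if ("dowdall" %in% agg$methods) "dowdall" else agg$methods[[1L]]
  out <- out[order(out[[paste0(lead, "_rank")]]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
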