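#' GWAS priority score for one variant
#'
#' The product of the variant's average effect size and its number of
#' genome-wide significant associations. The average effect size is the mean
#' of |ln(odds ratio)| over the variant's associations passing the
#' significance threshold; a variant with no qualifying association scores 0.
#' The score grows both with the strength of the effect and with the number
#' of independent significant reports, measuring how important and how
#' robustly associated the variant is.
#'
#' @param rsid Variant identifier.
#' @param associations GWAS association data.frame
#'   (see [read_gwas_associations()]).
#' @param gw_threshold Genome-wide significance threshold on the p-value
#'   (default `5e-8`).
#' @return A one-row data.frame: `rsid`, `avg_effect`, `n_assoc`, `score`.
#' @export
gwas_priority_score <- function(rsid, associations, gw_threshold = 5e-8) {
  stopifnot(length(rsid) == 1L)
  hit <- associations$rsid == rsid &
    associations$p_value <= gw_threshold &
    is.finite(associations$odds_ratio)
  or <- associations$odds_ratio[hit]
  n <- length(or)
  avg <- if (n) mean(abs(log(or))) else 0
  data.frame(rsid = rsid, avg_effect = avg, n_assoc = n, score = avg * n,
             stringsAsFactors = FALSE)
}

#' GWAS priority scores for a set of variants
#'
#' Vectorized form of [gwas_priority_score()].
#'
#' @param rsids Character vector of variant identifiers.
#' @param associations GWAS association data.frame.
#' @param gw_threshold Significance threshold on the p-value.
#' @return Data.frame `rsid`, `avg_effect`, `n_assoc`, `score`, one row per
#'   input rsid (order preserved); variants without qualifying associations
#'   score 0.
#' @export
priority_scores <- function(rsids, associations, gw_threshold = 5e-8) {
  keep <- associations$p_value <= gw_threshold &
    is.finite(associations$odds_ratio) &
    associations$rsid %in% rsids
  a <- associations[keep, , drop = FALSE]
  eff <- abs(log(a$odds_ratio))
  avg <- tapply(eff, a$rsid, mean)
  n <- tapply(eff, a$rsid, length)
  i <- match(rsids, names(avg))
  avg_effect <- ifelse(is.na(i), 0, unname(avg)[i])
  n_assoc <- ifelse(is.na(i), 0L, as.integer(unname(n)[i]))
  data.frame(rsid = rsids, avg_effect = avg_effect, n_assoc = n_assoc,
             score = avg_effect * n_assoc, stringsAsFactors = FALSE)
}

#' Pearson correlation with guarded degenerate cases
#'
#' Standard product-moment correlation; returns `NA` (rather than an error
#' or NaN) when fewer than three pairs are available or either vector has
#' zero variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Benchmark one consensus ranking against GWAS priority scores
#'
#' Takes the top-k variants by a method's aggregated rank and correlates
#' their rank positions (1..k) with their priority scores. A well-performing
#' method puts high-priority variants at the top, so its correlation is
#' negative. Variants absent from the association data keep priority 0 and
#' stay in the top-k vector.
#'
#' @param agg A `rank_aggregation` object.
#' @param method One of the methods computed in `agg`.
#' @param priorities Data.frame from [priority_scores()].
#' @param k Number of top variants to use (default 100, capped at N).
#' @return A one-row data.frame: `method`, `k`, `r` (`NA` when undefined).
#' @export
benchmark_correlation <- function(agg, method, priorities, k = 100L) {
  stopifnot(inherits(agg, "rank_aggregation"), method %in% agg$methods)
  k <- min(k, agg$n_variants)
  rk <- agg$ranks[[method]]
  top <- agg$ranks$rsid[order(rk)][seq_len(k)]
  i <- match(top, priorities$rsid)
  pri <- ifelse(is.na(i), 0, priorities$score[i])
  data.frame(method = method, k = k, r = pearson(seq_len(k), pri),
             stringsAsFactors = FALSE)
}

#' Compare rank-aggregation methods across dataset subsets
#'
#' Reruns aggregation and the priority-score benchmark for each (method,
#' subset) pair — for example "All", "GWAS-SV", "Bayesian", "C+T" subsets of
#' a curated collection — and averages each method's correlation over the
#' subsets into an overall R_mean. The table is sorted by R_mean ascending,
#' so the method with the strongest (most negative) average correlation
#' comes first.
#'
#' @param files List of aggregation-eligible [score_file()]s.
#' @param associations GWAS association data.frame.
#' @param subsets Named list mapping a subset label to the pgs_ids it
#'   contains; defaults to a single `"All"` subset with every file.
#' @param methods Subset of [ra_methods()].
#' @param k Top-k used in each benchmark correlation.
#' @param gw_threshold Significance threshold for the priority score.
#' @param normalization Passed to [aggregate_ranks()].
#' @return A list of class `ra_benchmark`: `cells` (data.frame method,
#'   subset, k, r) and `summary` (data.frame method, r_mean, n_subsets),
#'   sorted by `r_mean` ascending. Empty subsets and undefined correlations
#'   are excluded from the mean.
#' @export
compare_methods <- function(files, associations, subsets = NULL,
                            methods = ra_methods(), k = 100L,
                            gw_threshold = 5e-8,
                            normalization = "fractional") {
  if (is.null(subsets)) {
    subsets <- list(All = vapply(files, function(f) f$pgs_id, ""))
  }
  ids <- vapply(files, function(f) f$pgs_id, "")
  cells <- list()
  for (label in names(subsets)) {
    sub <- files[ids %in% subsets[[label]]]
    if (!length(sub)) next
    agg <- aggregate_ranks(sub, methods = methods,
                           normalization = normalization)
    pri <- priority_scores(agg$scores$rsid, associations,
                           gw_threshold = gw_threshold)
    for (method in methods) {
      b <- benchmark_correlation(agg, method, pri, k = k)
      b$subset <- label
      cells[[length(cells) + 1L]] <- b
    }
  }
  if (!length(cells)) {
    stop("every subset is empty after curation", call. = FALSE)
  }
  cells <- do.call(rbind, cells)[, c("method", "subset", "k", "r")]
  ok <- !is.na(cells$r)
  r_mean <- tapply(cells$r[ok], cells$method[ok], mean)
  summary <- data.frame(
    method = names(r_mean),
    r_mean = unname(r_mean),
    n_subsets = as.integer(tapply(cells$r[ok], cells$method[ok], length)),
    stringsAsFactors = FALSE
  )
  summary <- summary[order(summary$r_mean), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(cells = cells, summary = summary, k = k),
            class = "ra_benchmark")
}

#' @export
print.ra_benchmark <- function(x, ...) {
  cat(sprintf("<ra_benchmark> top-%d correlation with the GWAS priority score\n",
              x$k))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
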