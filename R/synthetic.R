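#' Simulate a collection of score files with planted consensus variants
#'
#' Generates a universe of `M` variants (rs1..rsM) of which `n_planted` are
#' "planted" consensus variants: they enter each simulated score with high
#' probability (`p_include`) and carry large absolute effect weights, while
#' background variants enter each score with probability 0.3 — guaranteeing
#' substantial cross-score missingness, which exercises the missing-to-N
#' fill rule — and carry small weights centred on zero. Signs are random
#' throughout, since ranking uses absolute weights. Files carry distinct
#' synthetic source GWAS accessions and method descriptions cycling through
#' the five method categories, so no redundancy or uniform classification is
#' planted.
#'
#' Variants are laid out deterministically on four synthetic chromosomes
#' (see [synthetic_variant_layout()]) so that a matching gene model can be
#' simulated independently.
#'
#' @param M Universe size (default 500).
#' @param Q Number of score files (default 8).
#' @param n_planted Number of planted consensus variants (default 20).
#' @param p_include Per-file inclusion probability of each planted variant
#'   (default 0.9).
#' @param w_planted_mean,w_planted_sd Absolute planted weights are drawn as
#'   |Normal(mean, sd)| (defaults 3.0, 0.5).
#' @param w_bg_sd Background weights are Normal(0, `w_bg_sd`) (default 0.3).
#' @param p_include_bg Per-file inclusion probability of background variants
#'   (default 0.3).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `files` (list of [score_file()]) and `truth` (class
#'   `synthetic_truth`: `planted` rsids, `universe`, `params`, `seed`).
#' @export
simulate_score_files <- function(M = 500L, Q = 8L, n_planted = 20L,
                                 p_include = 0.9, w_planted_mean = 3.0,
                                 w_planted_sd = 0.5, w_bg_sd = 0.3,
                                 p_include_bg = 0.3, seed = 1L) {
  if (n_planted > M) {
    stop("n_planted cannot exceed the universe size M", call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  layout <- synthetic_variant_layout(M)
  universe <- layout$rsid
  planted <- sort(sample(universe, n_planted))
  is_planted <- universe %in% planted

  categories <- pgs_method_categories()
  method_texts <- c(
    "GWAS-SV" = "genome-wide significant variants from the source GWAS",
    "C+T" = "clumping and thresholding, p < 5e-8",
    "Bayesian" = "LDpred2 auto model",
    "LASSO" = "lassosum penalized regression",
    "Others" = "weighted ensemble of published scores"
  )

  files <- vector("list", Q)
  for (j in seq_len(Q)) {
    inc <- stats::runif(M) < ifelse(is_planted, p_include, p_include_bg)
    idx <- which(inc)
    w <- numeric(length(idx))
    pl <- is_planted[idx]
    sign_pl <- sample(c(-1, 1), sum(pl), replace = TRUE)
    w[pl] <- sign_pl * abs(stats::rnorm(sum(pl), w_planted_mean, w_planted_sd))
    w[!pl] <- stats::rnorm(sum(!pl), 0, w_bg_sd)
    cat_j <- categories[(j - 1L) %% length(categories) + 1L]
    files[[j]] <- score_file(
      pgs_id = sprintf("PGS%06d", j),
      variants = data.frame(
        rsid = universe[idx],
        chrom = layout$chrom[idx],
        pos = layout$pos[idx],
        effect_allele = "A",
        other_allele = "G",
        effect_weight = w,
        stringsAsFactors = FALSE
      ),
      trait = "synthetic trait",
      method_text = unname(method_texts[cat_j]),
      source_gwas_ids = sprintf("GCST9%05d", j)
    )
  }

  truth <- structure(
    list(planted = planted, universe = universe,
         params = list(M = M, Q = Q, n_planted = n_planted,
                       p_include = p_include, p_include_bg = p_include_bg,
                       w_planted_mean = w_planted_mean,
                       w_planted_sd = w_planted_sd, w_bg_sd = w_bg_sd),
         seed = seed),
    class = "synthetic_truth"
  )
  list(files = files, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted / %d variants, %d files, seed %d\n",
              length(x$planted), length(x$universe), x$params$Q, x$seed))
  invisible(x)
}

#' Deterministic genomic layout of the synthetic variant universe
#'
#' Variants rs1..rsM are spread over four synthetic chromosomes in order,
#' spaced 10 kb apart. The layout is a pure function of `M`, which lets the
#' gene-model simulator place genes over the same coordinates without
#' sharing state.
#'
#' @param M Universe size.
#' @return Data.frame `rsid`, `chrom`, `pos` (1-based).
#' @export
synthetic_variant_layout <- function(M) {
  i <- seq_len(M)
  n_chrom <- 4L
  per_chrom <- ceiling(M / n_chrom)
  chrom_idx <- (i - 1L) %/% per_chrom + 1L
  within <- (i - 1L) %% per_chrom + 1L
  data.frame(
    rsid = paste0("rs", i),
    chrom = paste0("chr", chrom_idx),
    pos = within * 10000,
    stringsAsFactors = FALSE
  )
}

#' Simulate GWAS associations consistent with the planted truth
#'
#' Planted variants receive 1 + Poisson(`lambda_planted`) genome-wide
#' significant associations with strong effects (|ln OR| ~ |Normal(0.5,
#' 0.1)|, p = 1e-10); background variants receive Poisson(`lambda_bg`)
#' associations with weak effects (|ln OR| ~ |Normal(0.05, 0.02)|,
#' p = 1e-9). The direction of each odds ratio (above or below 1) is random.
#' This reproduces the empirical shape of external association support:
#' most variants with little or no support, a few with strong, repeated
#' support.
#'
#' @param truth A `synthetic_truth` from [simulate_score_files()].
#' @param lambda_planted Extra association count for planted variants
#'   (default 3).
#' @param lambda_bg Association rate for background variants (default 0.05).
#' @param seed Integer seed.
#' @return GWAS association data.frame (see [read_gwas_associations()]).
#' @export
simulate_associations <- function(truth, lambda_planted = 3,
                                  lambda_bg = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  rng <- local_rng(seed)
  on.exit(rng())
  universe <- truth$universe
  is_planted <- universe %in% truth$planted
  n_assoc <- ifelse(is_planted,
                    1L + stats::rpois(length(universe), lambda_planted),
                    stats::rpois(length(universe), lambda_bg))
  rsid <- rep(universe, n_assoc)
  planted_row <- rep(is_planted, n_assoc)
  n <- length(rsid)
  ln_or <- ifelse(planted_row,
                  abs(stats::rnorm(n, 0.5, 0.1)),
                  abs(stats::rnorm(n, 0.05, 0.02)))
  sign <- sample(c(-1, 1), n, replace = TRUE)
  data.frame(
    rsid = rsid,
    trait = "synthetic trait",
    odds_ratio = exp(sign * ln_or),
    p_value = ifelse(planted_row, 1e-10, 1e-9),
    study_id = sprintf("GCST8%05d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a gene model over the synthetic variant layout
#'
#' Tiles each synthetic chromosome with `genes_per_chrom` genes positioned
#' so that approximately `inside_fraction` of the variant positions fall
#' inside a gene (`inside_fraction = 1` covers every variant;
#' `genes_per_chrom = 0` yields an empty model). The seed picks which
#' contiguous run of variants each gene covers; identical seeds regenerate
#' the identical model.
#'
#' @param M Universe size (must match the score-file simulation).
#' @param genes_per_chrom Genes per synthetic chromosome (default 5).
#' @param inside_fraction Target fraction of variants inside genes
#'   (default 0.6).
#' @param seed Integer seed.
#' @return Gene model data.frame (`name`, `chrom`, `start`, `end`; BED
#'   0-based half-open convention), as from [read_gene_model()].
#' @export
simulate_gene_model <- function(M, genes_per_chrom = 5L,
                                inside_fraction = 0.6, seed = 1L) {
  rng <- local_rng(seed)
  on.exit(rng())
  layout <- synthetic_variant_layout(M)
  out <- list()
  for (chrom in unique(layout$chrom)) {
    pos <- sort(layout$pos[layout$chrom == chrom])
    if (genes_per_chrom < 1L) next
    blocks <- split(pos, cut(seq_along(pos), genes_per_chrom, labels = FALSE))
    for (k in seq_along(blocks)) {
      p <- blocks[[k]]
      n_in <- max(1L, round(inside_fraction * length(p)))
      offset <- if (length(p) > n_in) sample.int(length(p) - n_in + 1L, 1L) - 1L else 0L
      covered <- p[offset + seq_len(n_in)]
      out[[length(out) + 1L]] <- data.frame(
        name = sprintf("G_%s_%d", chrom, k),
        chrom = chrom,
        start = min(covered) - 1,   # 0-based inclusive
        end = max(covered),         # exclusive; covers positions exactly
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write a complete synthetic dataset to disk
#'
#' Materializes one simulation as files: a directory of scoring files, one
#' association TSV, one BED gene model, and a truth manifest (TSV with
#' columns `rsid`, `planted`).
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all three simulations.
#' @param ... Passed to [simulate_score_files()].
#' @return Invisibly, a list of the paths written plus the `truth` object.
#' @export
write_synthetic_dataset <- function(dir, seed = 1L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_score_files(seed = seed, ...)
  score_dir <- file.path(dir, "scores")
  dir.create(score_dir, showWarnings = FALSE)
  score_paths <- vapply(sim$files, function(f) {
    p <- file.path(score_dir, paste0(f$pgs_id, ".txt"))
    write_scoring_file(f, p)
    p
  }, "")
  assoc <- simulate_associations(sim$truth, seed = seed)
  assoc_path <- file.path(dir, "associations.tsv")
  write_gwas_associations(assoc, assoc_path)
  genes <- simulate_gene_model(M = sim$truth$params$M, seed = seed)
  bed_path <- file.path(dir, "genes.bed")
  writeLines(paste(genes$chrom, format(genes$start, scientific = FALSE, trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$name, sep = "\t"), bed_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(rsid = sim$truth$universe,
               planted = sim$truth$universe %in% sim$truth$planted),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(scores = score_paths, associations = assoc_path,
                 genes = bed_path, truth_manifest = truth_path,
                 truth = sim$truth))
}

# Seed the RNG restorably: returns a restore function for on.exit.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
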