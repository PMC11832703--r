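#' Build a pipeline run configuration
#'
#' Collects and validates every knob of the end-to-end workflow. All paths
#' must exist at construction time; the resolved configuration is serialized
#' into the output directory by [run_pipeline()] for provenance.
#'
#' @param scores Character vector of scoring-file paths, or a directory
#'   containing them (`.txt`, `.tsv` or gzipped).
#' @param associations Path to the GWAS association TSV.
#' @param genes Path to the BED4 gene model (optional; `NULL` skips
#'   annotation).
#' @param trait Trait label used to filter the association table (optional;
#'   `NULL` keeps all rows).
#' @param methods Rank-aggregation methods to run, see [ra_methods()].
#' @param normalization Rank normalization mode, see [normalize_ranks()].
#' @param k Top-k for the benchmark correlation.
#' @param gw_threshold Genome-wide significance threshold.
#' @param tol Redundancy weight tolerance.
#' @param overrides Optional path to a method-override TSV.
#' @param subsets Optional path to a subset-definition TSV (columns
#'   `pgs_id`, `subset`); when absent, subsets are derived from the curated
#'   method categories plus an "All" subset.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scores, associations, genes = NULL, trait = NULL,
                       methods = ra_methods(),
                       normalization = c("fractional", "minmax"),
                       k = 100L, gw_threshold = 5e-8, tol = 1e-9,
                       overrides = NULL, subsets = NULL,
                       out_dir = "pgsrank_out") {
  normalization <- match.arg(normalization)
  unknown <- setdiff(methods, ra_methods())
  if (length(unknown)) {
    stop(sprintf("unknown rank-aggregation method(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (length(scores) == 1L && dir.exists(scores)) {
    scores <- list.files(scores, pattern = "\\.(txt|tsv)(\\.gz)?$",
                         full.names = TRUE)
  }
  if (!length(scores)) stop("no scoring files found", call. = FALSE)
  for (p in c(scores, associations, overrides, subsets, genes)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("input path does not exist: %s", p), call. = FALSE)
    }
  }
  structure(
    list(scores = scores, associations = associations, genes = genes,
         trait = trait, methods = methods, normalization = normalization,
         k = as.integer(k), gw_threshold = gw_threshold, tol = tol,
         overrides = overrides, subsets = subsets, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full curation-to-benchmark workflow
#'
#' Executes, in order: scoring-file parsing, curation (rsID QC, method
#' classification, redundancy resolution, limited-scope flagging), nearest
#' gene annotation, rank aggregation with the configured methods, priority
#' scoring and the method benchmark. Writes four artifacts into the output
#' directory: `ranked_table.tsv`, `benchmark.tsv`, `audit_log.txt` and the
#' resolved `config.yaml`. The run is fully deterministic for fixed inputs.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the in-memory results (`curated`, `agg`,
#'   `annotations`, `priorities`, `benchmark`) and `paths` of the files
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- lapply(config$scores, read_scoring_file)
  associations <- read_gwas_associations(config$associations)
  if (!is.null(config$trait)) {
    associations <- associations[associations$trait == config$trait, ,
                                 drop = FALSE]
  }
  overrides <- if (!is.null(config$overrides)) {
    read_method_overrides(config$overrides)
  } else NULL

  curated <- curate(files, associations, overrides = overrides,
                    tol = config$tol)
  if (!length(curated$retained)) {
    stop("no score files remain eligible for rank aggregation after curation",
         call. = FALSE)
  }

  annotations <- if (!is.null(config$genes)) {
    index <- build_gene_index(read_gene_model(config$genes))
    annotate_score_files(curated$retained, index)
  } else NULL

  agg <- aggregate_ranks(curated$retained, methods = config$methods,
                         normalization = config$normalization)
  priorities <- priority_scores(agg$scores$rsid, associations,
                                gw_threshold = config$gw_threshold)

  subsets <- pipeline_subsets(config, curated)
  benchmark <- compare_methods(curated$retained, associations,
                               subsets = subsets, methods = config$methods,
                               k = config$k,
                               gw_threshold = config$gw_threshold,
                               normalization = config$normalization)

  tab <- ranked_table(agg, annotations = annotations,
                      priorities = priorities)
  paths <- list(
    ranked_table = file.path(config$out_dir, "ranked_table.tsv"),
    benchmark = file.path(config$out_dir, "benchmark.tsv"),
    audit_log = file.path(config$out_dir, "audit_log.txt"),
    config = file.path(config$out_dir, "config.yaml")
  )
  write_ranked_table(tab, paths$ranked_table)
  utils::write.table(benchmark$cells, paths$benchmark, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(curated$audit_log, paths$audit_log)
  yaml::write_yaml(config_as_list(config), paths$config)

  invisible(list(curated = curated, agg = agg, annotations = annotations,
                 priorities = priorities, benchmark = benchmark,
                 ranked = tab, paths = paths))
}

# Subset map for the benchmark: user-supplied TSV, else method categories.
pipeline_subsets <- function(config, curated) {
  ids <- vapply(curated$retained, function(f) f$pgs_id, "")
  if (!is.null(config$subsets)) {
    tab <- utils::read.delim(config$subsets, header = TRUE, sep = "\t",
                             colClasses = "character")
    if (!all(c("pgs_id", "subset") %in% names(tab))) {
      stop(sprintf("%s: subset table needs columns pgs_id, subset",
                   config$subsets), call. = FALSE)
    }
    subsets <- split(tab$pgs_id, tab$subset)
  } else {
    cats <- vapply(curated$retained, function(f) f$method_category, "")
    subsets <- split(ids, cats)
  }
  c(list(All = ids), subsets)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d scoring file(s), trait: %s\n",
              length(x$scores), if (is.null(x$trait)) "all" else x$trait))
  cat(sprintf("  methods: %s | normalization: %s | k = %d\n",
              paste(x$methods, collapse = ", "), x$normalization, x$k))
  cat(sprintf("  out: %s\n", x$out_dir))
  invisible(x)
}
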