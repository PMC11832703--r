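#' Read a PGS Catalog-format scoring file
#'
#' Parses the tab-separated scoring-file distribution format: `#key=value`
#' metadata header lines, then a column-header line, then one row per variant.
#' Harmonized GRCh38 columns (`hm_rsID`, `hm_chr`, `hm_pos`) take precedence
#' over the raw `rsID`/`chr_name`/`chr_position` columns when both are
#' present, so that all scores in a collection refer to one reference build.
#' Gzip-compressed files are accepted transparently.
#'
#' Recognized metadata keys: `pgs_id`, `trait_reported`, `method_name` (free
#' text, stored as `method_text`), and `source_gwas_ids` (comma-separated
#' study accessions). Unrecognized keys are ignored.
#'
#' @param path Path to the scoring file (plain or gzip-compressed).
#' @return A [score_file()] object.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("#pgs_id=PGS000001",
#'              "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
#'              "rs1\t1\t1000\tA\t0.5",
#'              "rs2\t1\t2000\tC\t-0.9"), f)
#' read_scoring_file(f)
#' @export
read_scoring_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("scoring file not found: %s", path), call. = FALSE)
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  is_meta <- startsWith(lines, "#")
  meta <- parse_metadata_lines(lines[is_meta])
  body <- lines[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    stop(sprintf("%s: no column header found", path), call. = FALSE)
  }
  header <- strsplit(body[[1]], "\t", fixed = TRUE)[[1]]

  rsid_col <- first_present(header, c("hm_rsID", "rsID", "rsid"))
  weight_col <- first_present(header, "effect_weight")
  if (is.na(rsid_col)) {
    stop(sprintf("%s: missing required rsID column (rsID or hm_rsID)", path),
         call. = FALSE)
  }
  if (is.na(weight_col)) {
    stop(sprintf("%s: missing required column effect_weight", path),
         call. = FALSE)
  }
  tab <- if (length(body) > 1L) {
    utils::read.delim(text = body, header = TRUE, sep = "\t",
                      colClasses = "character", check.names = FALSE,
                      quote = "", comment.char = "")
  } else {
    as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                  header), check.names = FALSE)
  }

  weight_chr <- tab[[weight_col]]
  weight <- suppressWarnings(as.numeric(weight_chr))
  bad <- which(is.na(weight) | !is.finite(weight))
  if (length(bad)) {
    # +2: one for the header line, one for 1-based line numbers within body
    lineno <- bad + 1L + sum(is_meta)
    stop(sprintf("%s: non-numeric effect_weight on line(s) %s", path,
                 paste(lineno, collapse = ", ")), call. = FALSE)
  }

  chrom_col <- first_present(names(tab), c("hm_chr", "chr_name"))
  pos_col <- first_present(names(tab), c("hm_pos", "chr_position"))
  variants <- data.frame(
    rsid = tab[[rsid_col]],
    chrom = if (!is.na(chrom_col)) tab[[chrom_col]] else NA_character_,
    pos = if (!is.na(pos_col))
      suppressWarnings(as.numeric(tab[[pos_col]])) else NA_real_,
    effect_allele = if ("effect_allele" %in% names(tab))
      tab[["effect_allele"]] else NA_character_,
    other_allele = if ("other_allele" %in% names(tab))
      tab[["other_allele"]] else NA_character_,
    effect_weight = weight,
    stringsAsFactors = FALSE
  )

  score_file(
    pgs_id = if (!is.null(meta$pgs_id)) meta$pgs_id
             else tools::file_path_sans_ext(basename(path), compression = TRUE),
    variants = variants,
    trait = meta$trait_reported %||% NA_character_,
    method_text = meta$method_name %||% NA_character_,
    source_gwas_ids = if (!is.null(meta$source_gwas_ids))
      trimws(strsplit(meta$source_gwas_ids, ",", fixed = TRUE)[[1]])
      else character()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

first_present <- function(haystack, candidates) {
  hit <- candidates[candidates %in% haystack]
  if (length(hit)) hit[[1]] else NA_character_
}

parse_metadata_lines <- function(lines) {
  lines <- sub("^#+\\s*", "", lines)
  has_eq <- grepl("=", lines, fixed = TRUE)
  kv <- strsplit(lines[has_eq], "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  stats::setNames(as.list(vals), keys)
}

#' Write a score back to the scoring-file format
#'
#' Inverse of [read_scoring_file()]: metadata header, column header, body.
#' Weights are serialized with full precision so that a write/read round trip
#' preserves them exactly.
#'
#' @param score A [score_file()] object.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(score, path) {
  stopifnot(inherits(score, "score_file"))
  meta <- c(sprintf("#pgs_id=%s", score$pgs_id))
  if (!is.na(score$trait)) {
    meta <- c(meta, sprintf("#trait_reported=%s", score$trait))
  }
  if (!is.na(score$method_text)) {
    meta <- c(meta, sprintf("#method_name=%s", score$method_text))
  }
  if (length(score$source_gwas_ids)) {
    meta <- c(meta, sprintf("#source_gwas_ids=%s",
                            paste(score$source_gwas_ids, collapse = ",")))
  }
  v <- score$variants
  header <- paste(c("rsID", "chr_name", "chr_position", "effect_allele",
                    "other_allele", "effect_weight"), collapse = "\t")
  rows <- paste(v$rsid,
                ifelse(is.na(v$chrom), "", v$chrom),
                ifelse(is.na(v$pos), "", format_pos(v$pos)),
                ifelse(is.na(v$effect_allele), "", v$effect_allele),
                ifelse(is.na(v$other_allele), "", v$other_allele),
                sprintf("%.17g", v$effect_weight),
                sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(meta, header, rows), con)
  invisible(path)
}

format_pos <- function(pos) {
  out <- rep("", length(pos))
  ok <- !is.na(pos)
  out[ok] <- format(pos[ok], scientific = FALSE, trim = TRUE)
  out
}

#' Read a GWAS association table
#'
#' Plain TSV with header columns `rsid`, `trait`, `odds_ratio`, `p_value`,
#' `study_id`; one row per variant-trait association. No deduplication is
#' performed at read time: the same rsID reported by several studies yields
#' several rows, which is what the priority score counts.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the five columns above, `odds_ratio` and
#'   `p_value` numeric.
#' @export
read_gwas_associations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("association table not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  required <- c("rsid", "trait", "odds_ratio", "p_value", "study_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(tab)) {
    return(data.frame(rsid = character(), trait = character(),
                      odds_ratio = numeric(), p_value = numeric(),
                      study_id = character(), stringsAsFactors = FALSE))
  }
  odds_ratio <- suppressWarnings(as.numeric(tab$odds_ratio))
  p_value <- suppressWarnings(as.numeric(tab$p_value))
  bad_p <- which(is.na(p_value) | p_value <= 0 | p_value > 1)
  if (length(bad_p)) {
    stop(sprintf("%s: malformed p_value on row(s) %s", path,
                 paste(bad_p, collapse = ", ")), call. = FALSE)
  }
  bad_or <- which(is.na(odds_ratio) | odds_ratio <= 0)
  if (length(bad_or)) {
    stop(sprintf("%s: odds_ratio must be a positive number (row(s) %s)", path,
                 paste(bad_or, collapse = ", ")), call. = FALSE)
  }
  data.frame(rsid = tab$rsid, trait = tab$trait, odds_ratio = odds_ratio,
             p_value = p_value, study_id = tab$study_id,
             stringsAsFactors = FALSE)
}

#' Write a GWAS association table
#'
#' @param associations Data.frame as returned by [read_gwas_associations()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_gwas_associations <- function(associations, path) {
  utils::write.table(associations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene model in BED4 format
#'
#' BED is 0-based, half-open: a gene occupies positions `[start, end)`. The
#' input order is preserved; sorting is the gene index's concern.
#'
#' @param path Path to a BED file with columns chrom, start, end, name.
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`
#'   (`start` 0-based inclusive, `end` exclusive).
#' @export
read_gene_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("gene model not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) &
                 !startsWith(lines, "track") & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.frame(name = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4L)) {
    stop(sprintf("%s: BED4 requires 4 columns (line %d)", path,
                 which(n_fields < 4L)[1]), call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  name <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop(sprintf("%s: invalid interval (start >= end or non-numeric) on line %d",
                 path, bad[1]), call. = FALSE)
  }
  data.frame(name = name, chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Write the consensus-ranked variant table
#'
#' Emits one row per variant, ordered by ascending Dowdall aggregated rank
#' (best consensus variant first) when Dowdall was computed, otherwise by the
#' first method present. Columns: `rsid`, `gene`, `distance`, one
#' `<method>_score` and one `<method>_rank` column per aggregation method,
#' and `priority_score`.
#'
#' @param results A ranked-table data.frame from [ranked_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @seealso [ranked_table()], [read_ranked_table()]
#' @export
write_ranked_table <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  # full precision so score values survive a write/read round trip
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.17g", x))
  })
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write ranked table to %s: %s", path,
                 conditionMessage(ok)), call. = FALSE)
  }
  invisible(path)
}

#' Read back a ranked variant table
#'
#' @param path Path written by [write_ranked_table()].
#' @return A data.frame.
#' @export
read_ranked_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
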