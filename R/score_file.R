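#' Construct a polygenic score object
#'
#' A `score_file` bundles one polygenic score: its identifier, trait label,
#' free-text development-method description, the source GWAS study accessions
#' it was derived from, and a table of weighted variants. The variant table is
#' what downstream ranking consumes: within one score, variants are ranked by
#' the absolute value of their effect weight.
#'
#' @param pgs_id Score identifier (e.g. `"PGS000025"`). Must be non-empty.
#' @param variants A data.frame with columns `rsid`, `effect_weight` and
#'   optionally `chrom`, `pos`, `effect_allele`, `other_allele`. `rsid` must
#'   be non-empty and unique within the score; `effect_weight` must be finite;
#'   `pos`, when present and non-missing, must be a 1-based position >= 1.
#' @param trait Trait label (free text).
#' @param method_text Free-text method name and parameters, as distributed in
#'   scoring-file metadata.
#' @param method_category One of `"GWAS-SV"`, `"C+T"`, `"Bayesian"`,
#'   `"LASSO"`, `"Others"`, or `NA` if not yet classified.
#' @param source_gwas_ids Character vector of source GWAS study accessions.
#'
#' @return An object of class `score_file`.
#' @seealso [read_scoring_file()], [rank_within_file()]
#' @export
score_file <- function(pgs_id, variants, trait = NA_character_,
                       method_text = NA_character_,
                       method_category = NA_character_,
                       source_gwas_ids = character()) {
  if (!is.character(pgs_id) || length(pgs_id) != 1L || is.na(pgs_id) ||
      !nzchar(pgs_id)) {
    stop("`pgs_id` must be a single non-empty string", call. = FALSE)
  }
  variants <- normalize_variant_table(variants, pgs_id)
  if (!is.na(method_category)) {
    method_category <- match.arg(method_category, pgs_method_categories())
  }
  structure(
    list(
      pgs_id = pgs_id,
      trait = as.character(trait),
      method_text = as.character(method_text),
      method_category = as.character(method_category),
      source_gwas_ids = unique(as.character(source_gwas_ids)),
      variants = variants
    ),
    class = "score_file"
  )
}

#' The five recognized PGS development-method categories
#'
#' @return Character vector of category labels.
#' @export
pgs_method_categories <- function() {
  c("GWAS-SV", "C+T", "Bayesian", "LASSO", "Others")
}

# Coerce and validate a variant table; enforces the score_file invariants.
normalize_variant_table <- function(variants, pgs_id) {
  stopifnot(is.data.frame(variants))
  required <- c("rsid", "effect_weight")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols)) {
    stop(sprintf("variant table for %s lacks column(s): %s", pgs_id,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  n <- nrow(variants)
  col_or_na <- function(col, cast, na) {
    if (col %in% names(variants)) cast(variants[[col]]) else rep(na, n)
  }
  out <- data.frame(
    rsid = as.character(variants$rsid),
    chrom = col_or_na("chrom", as.character, NA_character_),
    pos = col_or_na("pos", as.numeric, NA_real_),
    effect_allele = col_or_na("effect_allele", as.character, NA_character_),
    other_allele = col_or_na("other_allele", as.character, NA_character_),
    effect_weight = as.numeric(variants$effect_weight),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$rsid) | !nzchar(out$rsid))) {
    stop(sprintf("%s: empty variant identifiers are not allowed", pgs_id),
         call. = FALSE)
  }
  dup <- unique(out$rsid[duplicated(out$rsid)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate rsID(s): %s", pgs_id,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(out$effect_weight))) {
    stop(sprintf("%s: non-finite effect weights", pgs_id), call. = FALSE)
  }
  bad_pos <- !is.na(out$pos) & out$pos < 1
  if (any(bad_pos)) {
    stop(sprintf("%s: positions must be 1-based (>= 1)", pgs_id),
         call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.score_file <- function(x, ...) {
  cat(sprintf("<score_file> %s (%s)\n", x$pgs_id,
              if (is.na(x$trait)) "trait unset" else x$trait))
  cat(sprintf("  method: %s [%s]\n",
              if (is.na(x$method_text)) "?" else x$method_text,
              if (is.na(x$method_category)) "unclassified"
              else x$method_category))
  cat(sprintf("  source GWAS: %s\n",
              if (length(x$source_gwas_ids))
                paste(x$source_gwas_ids, collapse = ", ") else "none"))
  cat(sprintf("  variants: %d\n", nrow(x$variants)))
  invisible(x)
}

#' Number of variants in a score
#' @param x A `score_file`.
#' @return Integer count of variants.
#' @export
n_variants <- function(x) {
  stopifnot(inherits(x, "score_file"))
  nrow(x$variants)
}
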