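#' Drop variants without a standard rsID
#'
#' Composite haplotype labels (the APOE epsilon alleles are the canonical
#' example) and coordinate-style identifiers cannot be ranked in a single-SNP
#' weighting framework, so only identifiers matching `rs` followed by digits
#' are retained.
#'
#' @param score A [score_file()].
#' @return A list with `score` (the filtered score) and `dropped` (data.frame
#'   of `rsid`, `reason` for each removed variant).
#' @export
filter_standard_rsids <- function(score) {
  stopifnot(inherits(score, "score_file"))
  keep <- grepl("^rs[0-9]+$", score$variants$rsid)
  dropped <- data.frame(
    rsid = score$variants$rsid[!keep],
    reason = rep("non-standard identifier", sum(!keep)),
    stringsAsFactors = FALSE
  )
  score$variants <- score$variants[keep, , drop = FALSE]
  rownames(score$variants) <- NULL
  list(score = score, dropped = dropped)
}

# Ordered keyword table: first category whose keyword matches wins. Bayesian
# before C+T so e.g. "LDpred2 with pruning" classifies as Bayesian.
method_keyword_table <- function() {
  list(
    "Bayesian" = c("ldpred", "prs-cs", "prscs", "sbayesr", "dbslmm", "bayes"),
    "LASSO" = c("lassosum", "lasso"),
    "C+T" = c("clump", "thresholding", "pruning", "p+t", "c+t"),
    "GWAS-SV" = c("genome-wide significant", "gwas significant", "gwas-sv",
                  "significant variants")
  )
}

#' Classify a PGS development method from its free-text description
#'
#' Case-insensitive keyword matching against an ordered table; the first
#' category with a matching keyword wins and anything unmatched falls into
#' `"Others"`. Manual classifications can be injected through `overrides`,
#' which take precedence over the keywords.
#'
#' @param method_text Free-text method description (scalar or vector).
#' @param pgs_id Optional score identifier(s), used only to look up overrides.
#' @param overrides Named character vector or list mapping pgs_id to category.
#' @return Category label(s): one of [pgs_method_categories()].
#' @examples
#' classify_method("LDpred2")                       # "Bayesian"
#' classify_method("clumping and thresholding")     # "C+T"
#' classify_method("weighted ensemble of 3 scores") # "Others"
#' @export
classify_method <- function(method_text, pgs_id = NULL, overrides = NULL) {
  n <- length(method_text)
  out <- character(n)
  kw <- method_keyword_table()
  for (i in seq_len(n)) {
    if (!is.null(overrides) && !is.null(pgs_id) &&
        !is.na(pgs_id[i]) && pgs_id[i] %in% names(overrides)) {
      out[i] <- match.arg(as.character(overrides[[pgs_id[i]]]),
                          pgs_method_categories())
      next
    }
    txt <- tolower(method_text[i])
    hit <- "Others"
    if (!is.na(txt) && nzchar(txt)) {
      for (cat in names(kw)) {
        if (any(vapply(kw[[cat]], grepl, logical(1), x = txt, fixed = TRUE))) {
          hit <- cat
          break
        }
      }
    }
    out[i] <- hit
  }
  out
}

#' Read a classification override table
#'
#' Two-column TSV (`pgs_id`, `category`) preserving manual authority over the
#' keyword classifier.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping pgs_id to category.
#' @export
read_method_overrides <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  if (!all(c("pgs_id", "category") %in% names(tab))) {
    stop(sprintf("%s: override table needs columns pgs_id, category", path),
         call. = FALSE)
  }
  stats::setNames(tab$category, tab$pgs_id)
}

#' Detect redundant score files
#'
#' Two scores are directly redundant when they were developed from the same
#' original GWAS (share at least one source study accession), use exactly the
#' same variant set, and have matching effect weights (maximum absolute
#' difference at most `tol`). Groups are the transitive closure of this
#' pairwise relation, so a chain A~B, B~C forms one group even if A and C
#' share no study accession.
#'
#' @param files List of [score_file()] objects (already rsID-filtered).
#' @param tol Weight-comparison tolerance (default `1e-9`).
#' @return List of character vectors of pgs_ids, one per redundant group of
#'   size >= 2; empty list if none.
#' @export
detect_redundant <- function(files, tol = 1e-9) {
  n <- length(files)
  if (n < 2L) return(list())
  ids <- vapply(files, function(f) f$pgs_id, "")
  # union-find over the pairwise redundancy relation
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (scores_redundant(files[[i]], files[[j]], tol)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  groups <- split(ids, roots)
  groups <- groups[lengths(groups) >= 2L]
  names(groups) <- NULL
  lapply(groups, function(g) sort(unname(g)))
}

scores_redundant <- function(a, b, tol) {
  if (!length(intersect(a$source_gwas_ids, b$source_gwas_ids))) return(FALSE)
  va <- a$variants
  vb <- b$variants
  if (nrow(va) != nrow(vb)) return(FALSE)
  if (!setequal(va$rsid, vb$rsid)) return(FALSE)
  if (!nrow(va)) return(TRUE)
  wb <- vb$effect_weight[match(va$rsid, vb$rsid)]
  max(abs(va$effect_weight - wb)) <= tol
}

#' Choose the representative of a redundant group
#'
#' Keeps the member most closely aligned with the original GWAS variants,
#' operationalized as the largest overlap between the score's rsIDs and the
#' trait's association rsIDs; ties go to the lexicographically smallest
#' pgs_id.
#'
#' @param group List of [score_file()] objects in one redundant group.
#' @param associations GWAS association data.frame (see
#'   [read_gwas_associations()]).
#' @return The pgs_id of the representative member.
#' @export
select_representative <- function(group, associations) {
  stopifnot(length(group) >= 2L)
  assoc_rsids <- unique(associations$rsid)
  ids <- vapply(group, function(f) f$pgs_id, "")
  overlap <- vapply(group, function(f) {
    length(intersect(f$variants$rsid, assoc_rsids))
  }, 1L)
  best <- which(overlap == max(overlap))
  ids[best][order(ids[best])][1L]
}

#' Flag scores with no external GWAS support
#'
#' A score none of whose variants appear in the trait's association table has
#' "limited scope": its variants lack external validation, so it is excluded
#' from rank aggregation (while remaining available for annotation).
#'
#' @param score A [score_file()].
#' @param associations GWAS association data.frame, already filtered to the
#'   target trait.
#' @return `TRUE` if the score has zero overlap with the associations.
#' @export
flag_limited_scope <- function(score, associations) {
  stopifnot(inherits(score, "score_file"))
  !any(score$variants$rsid %in% associations$rsid)
}

#' Curate a collection of score files
#'
#' Applies the full curation sequence: (1) drop non-standard variant
#' identifiers from every file; (2) classify each file's development method;
#' (3) detect redundant groups and keep one representative each; (4) flag
#' limited-scope files, which stay in the flag table but leave the
#' aggregation-eligible set. Every exclusion is recorded in the audit log
#' with its rule.
#'
#' @param files List of [score_file()] objects.
#' @param associations GWAS association data.frame for the target trait.
#' @param overrides Optional named vector mapping pgs_id to a manually chosen
#'   method category.
#' @param tol Redundancy weight tolerance passed to [detect_redundant()].
#' @return An object of class `curated_set` with elements:
#'   \describe{
#'     \item{retained}{list of rsID-filtered `score_file`s eligible for rank
#'       aggregation (representatives only, limited-scope excluded).}
#'     \item{flags}{data.frame with one row per input file: `pgs_id`,
#'       `method_category`, `n_dropped_variants`, `redundant_group`,
#'       `is_representative`, `limited_scope`, `ra_eligible`.}
#'     \item{dropped_variants}{data.frame of `pgs_id`, `rsid`, `reason`.}
#'     \item{audit_log}{character vector of `pgs_id<TAB>action<TAB>reason`
#'       lines.}
#'   }
#' @export
curate <- function(files, associations, overrides = NULL, tol = 1e-9) {
  stopifnot(length(files) > 0L)
  # deterministic processing order regardless of input order
  ids <- vapply(files, function(f) f$pgs_id, "")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pgs_id in collection: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  files <- files[order(ids)]
  ids <- sort(ids)

  audit <- character()
  dropped_all <- list()

  qc <- lapply(files, filter_standard_rsids)
  files <- lapply(qc, `[[`, "score")
  for (i in seq_along(files)) {
    d <- qc[[i]]$dropped
    if (nrow(d)) {
      dropped_all[[ids[i]]] <- cbind(pgs_id = ids[i], d)
      audit <- c(audit, sprintf("%s\tdrop_variant\tnon-standard identifier: %s",
                                ids[i], paste(d$rsid, collapse = ",")))
    }
  }

  categories <- classify_method(
    vapply(files, function(f) f$method_text, ""), ids, overrides)
  for (i in seq_along(files)) files[[i]]$method_category <- categories[i]

  groups <- detect_redundant(files, tol = tol)
  group_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  representative <- stats::setNames(rep(TRUE, length(ids)), ids)
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    gid <- sprintf("group%d", g)
    group_of[members] <- gid
    rep_id <- select_representative(files[match(members, ids)], associations)
    representative[setdiff(members, rep_id)] <- FALSE
    for (m in setdiff(members, rep_id)) {
      audit <- c(audit, sprintf(
        "%s\texclude\tredundant with %s (representative %s)",
        m, paste(setdiff(members, m), collapse = ","), rep_id))
    }
  }

  limited <- vapply(files, flag_limited_scope, logical(1),
                    associations = associations)
  names(limited) <- ids
  for (id in ids[limited & representative[ids]]) {
    audit <- c(audit, sprintf(
      "%s\texclude_from_ra\tlimited scope: no variant overlaps the trait's GWAS associations",
      id))
  }

  eligible <- representative[ids] & !limited
  flags <- data.frame(
    pgs_id = ids,
    method_category = categories,
    n_dropped_variants = vapply(qc, function(x) nrow(x$dropped), 1L),
    redundant_group = unname(group_of[ids]),
    is_representative = unname(representative[ids]),
    limited_scope = unname(limited),
    ra_eligible = unname(eligible),
    stringsAsFactors = FALSE
  )

  structure(
    list(
      retained = files[eligible],
      flags = flags,
      dropped_variants = if (length(dropped_all))
        do.call(rbind, c(dropped_all, list(make.row.names = FALSE)))
      else data.frame(pgs_id = character(), rsid = character(),
                      reason = character(), stringsAsFactors = FALSE),
      audit_log = audit
    ),
    class = "curated_set"
  )
}

#' @export
print.curated_set <- function(x, ...) {
  cat(sprintf("<curated_set> %d file(s) in, %d eligible for rank aggregation\n",
              nrow(x$flags), length(x$retained)))
  cat(sprintf("  redundant groups: %d | limited scope: %d | variants dropped: %d\n",
              length(unique(stats::na.omit(x$flags$redundant_group))),
              sum(x$flags$limited_scope), nrow(x$dropped_variants)))
  if (length(x$audit_log)) {
    cat("  audit:\n")
    cat(paste0("    ", x$audit_log, collapse = "\n"), "\n")
  }
  invisible(x)
}
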