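# Fixture builders shared across the suite. Everything is generated in code;
# no fixture files on disk.

write_score_fixture <- function(lines, gz = FALSE) {
  path <- tempfile(fileext = if (gz) ".txt.gz" else ".txt")
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}

basic_score_lines <- function(pgs_id = "PGS000001",
                              rsids = c("rs1", "rs2", "rs3"),
                              weights = c(0.5, -0.9, 0.1)) {
  c(sprintf("#pgs_id=%s", pgs_id),
    "#trait_reported=test trait",
    "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
    sprintf("%s\t1\t%d\tA\t%s", rsids, seq_along(rsids) * 1000, weights))
}

make_score <- function(pgs_id, rsids, weights, gwas = character(),
                       method_text = NA_character_, chrom = NULL,
                       pos = NULL) {
  v <- data.frame(rsid = rsids, effect_weight = weights,
                  stringsAsFactors = FALSE)
  if (!is.null(chrom)) v$chrom <- chrom
  if (!is.null(pos)) v$pos <- pos
  score_file(pgs_id, v, method_text = method_text, source_gwas_ids = gwas)
}

make_assoc <- function(rsids, odds_ratio = 1.5, p_value = 1e-10,
                       trait = "t", study_id = NULL) {
  n <- length(rsids)
  data.frame(rsid = rsids, trait = rep_len(trait, n),
             odds_ratio = rep_len(odds_ratio, n),
             p_value = rep_len(p_value, n),
             study_id = if (is.null(study_id)) sprintf("GCST%03d", seq_len(n))
                        else rep_len(study_id, n),
             stringsAsFactors = FALSE)
}

# the two-file worked micro-example used throughout the ranking tests
micro_files <- function() {
  list(
    make_score("PGS1", c("a", "b"), c(0.5, -0.9), gwas = "GCST1"),
    make_score("PGS2", c("b", "c"), c(0.1, 0.2), gwas = "GCST2")
  )
}

# wrap a bare numeric matrix of normalized ranks for the score functions
as_norm_matrix <- function(values, nrow = 1L) {
  m <- matrix(values, nrow = nrow,
              dimnames = list(paste0("v", seq_len(nrow)),
                              paste0("f", seq_len(length(values) / nrow))))
  attr(m, "normalization") <- "fractional"
  m
}

# brute-force nearest-gene oracle: linear scan over every interval
oracle_nearest <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene = NA_character_, distance = NA_real_))
  start1 <- g$start + 1
  end1 <- g$end
  d <- pmax(0, start1 - pos, pos - end1)
  best <- which(d == min(d))
  best <- best[order(g$name[best])][1]
  list(gene = g$name[best], distance = d[best])
}
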