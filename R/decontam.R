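#' Prevalence-based contaminant screen against negative controls
#'
#' For each taxon, presence (count > 0) is tabulated in negative controls
#' versus biological samples and over-representation in controls is tested
#' with a one-sided Fisher exact test. A taxon is flagged when `p < alpha`
#' and its control prevalence exceeds its sample prevalence, so taxa absent
#' from controls can never be flagged.
#'
#' @param table count matrix (samples x taxa) containing both biological
#'   samples and negative controls.
#' @param metadata validated sample metadata with `is_negative_control`.
#' @param alpha flagging threshold on the Fisher p-value.
#' @return data.frame: `taxon_id`, `prevalence_in_controls`,
#'   `prevalence_in_samples`, `p_value`, `flagged`.
#' @export
prevalence_contaminant_test <- function(table, metadata, alpha = 0.05) {
  table <- as_count_table(table)
  metadata <- metadata[match(rownames(table), metadata$sample_id), ,
                       drop = FALSE]
  if (anyNA(metadata$sample_id))
    stop("metadata missing for some samples in the table")
  is_ctl <- metadata$is_negative_control
  n_ctl <- sum(is_ctl); n_smp <- sum(!is_ctl)
  if (n_ctl < 1)
    stop("no negative controls present; skip decontamination explicitly ",
         "rather than running it without controls")
  if (n_smp < 1) stop("no biological samples present")
  present <- table > 0
  in_ctl <- colSums(present[is_ctl, , drop = FALSE])
  in_smp <- colSums(present[!is_ctl, , drop = FALSE])
  p <- vapply(seq_len(ncol(table)), function(j) {
    tab <- matrix(c(in_ctl[j], n_ctl - in_ctl[j],
                    in_smp[j], n_smp - in_smp[j]), 2,
                  dimnames = list(c("present", "absent"),
                                  c("control", "sample")))
    fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
  prev_ctl <- in_ctl / n_ctl
  prev_smp <- in_smp / n_smp
  data.frame(taxon_id = colnames(table),
             prevalence_in_controls = unname(prev_ctl),
             prevalence_in_samples = unname(prev_smp),
             p_value = p,
             flagged = p < alpha & prev_ctl > prev_smp,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Remove flagged contaminants and organelle lineages from a count table
#'
#' Drops the columns of taxa flagged by [prevalence_contaminant_test()] and,
#' when a taxonomy is supplied, any taxon whose lineage matches the organelle
#' patterns (mitochondria and chloroplast 16S amplicons are host-derived, not
#' community members). Other counts are untouched.
#'
#' @param table count matrix (samples x taxa).
#' @param report contaminant report (needs `taxon_id`, `flagged`), or NULL.
#' @param taxonomy optional taxonomy data.frame from [read_taxonomy()].
#' @param organelle_patterns regular expressions matched (case-insensitively)
#'   against lineages.
#' @return filtered count matrix; removed taxa are attached as
#'   `attr(, "removed")`.
#' @export
remove_contaminants <- function(table, report = NULL, taxonomy = NULL,
                                organelle_patterns = c("Mitochondria",
                                                       "Chloroplast")) {
  table <- as_count_table(table)
  drop <- character()
  if (!is.null(report)) {
    unknown <- setdiff(report$taxon_id, colnames(table))
    if (length(unknown))
      stop("report names taxa absent from the table: ",
           paste(unknown, collapse = ", "))
    drop <- report$taxon_id[report$flagged]
  }
  if (!is.null(taxonomy)) {
    pat <- paste(organelle_patterns, collapse = "|")
    hit <- taxonomy$taxon_id[grepl(pat, taxonomy$lineage, ignore.case = TRUE)]
    drop <- union(drop, intersect(hit, colnames(table)))
  }
  if (length(drop))
    message("removing ", length(drop), " taxa: ", paste(drop, collapse = ", "))
  out <- table[, setdiff(colnames(table), drop), drop = FALSE]
  attr(out, "removed") <- drop
  out
}
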