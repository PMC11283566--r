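#' Rarefy a count table to even depth
#'
#' Each retained sample is subsampled uniformly at random without
#' replacement to exactly `depth` reads (via [vegan::rrarefy()]); samples
#' whose total is below `depth` are dropped and reported. Deterministic for
#' a given `seed`.
#'
#' @param table count matrix (samples x taxa).
#' @param depth target reads per sample (default 15000).
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @return rarefied count matrix with every row summing to `depth`; dropped
#'   sample ids in `attr(, "dropped")`.
#' @export
rarefy <- function(table, depth = 15000, seed = NULL) {
  table <- as_count_table(table)
  if (depth < 1) stop("depth must be >= 1")
  tot <- rowSums(table)
  keep <- tot >= depth
  if (!any(keep))
    stop("all samples fall below the rarefaction depth of ", depth)
  if (any(!keep))
    message("dropped ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(table)[!keep], collapse = ", "))
  kept <- table[keep, , drop = FALSE]
  out <- with_seed(seed, {
    r <- kept
    sub <- tot[keep] > depth
    # rrarefy warns heuristically when the smallest count exceeds 1; inputs
    # here are validated integer counts above the depth, so silence it
    if (any(sub))
      r[sub, ] <- suppressWarnings(
        vegan::rrarefy(kept[sub, , drop = FALSE], depth))
    r
  })
  storage.mode(out) <- "integer"
  attr(out, "dropped") <- rownames(table)[!keep]
  out
}

#' Rarefy both components of a paired assay to a common depth
#'
#' Rarefies the DNA and cDNA tables independently and keeps only samples
#' retained in both.
#'
#' @param assay a `paired_assay`.
#' @param depth reads per sample.
#' @param seed integer seed.
#' @return `paired_assay` with rarefied, re-aligned components.
#' @export
rarefy_assay <- function(assay, depth = 15000, seed = NULL) {
  stopifnot(inherits(assay, "paired_assay"))
  dna <- with_seed(seed, rarefy(assay$dna, depth))
  cdna <- with_seed(if (is.null(seed)) NULL else seed + 1L,
                    rarefy(assay$cdna, depth))
  keep <- intersect(rownames(dna), rownames(cdna))
  if (!length(keep)) stop("no samples retained in both assays")
  assay$dna <- dna[keep, , drop = FALSE]
  assay$cdna <- cdna[keep, , drop = FALSE]
  assay$pair_map <- assay$pair_map[assay$pair_map$sample_id %in% keep, ,
                                   drop = FALSE]
  assay
}

#' Classify active taxa from rRNA:rRNA-gene count ratios
#'
#' Per sample and taxon, with both tables rarefied to the same depth, the
#' activity ratio is `cDNA / DNA`. A cell is *active* when cDNA > 0 and the
#' ratio meets `ratio_threshold` (ties at the threshold are active). Cells
#' with cDNA detected but DNA absent are *phantom* detections: taxa whose
#' phantom detections occur in more than `phantom_prevalence` of samples
#' have those cells recoded to DNA = 1 and marked `phantom_rescued` (hence
#' active); all other phantom cells are `phantom_dropped` (excluded from the
#' active community). Remaining states are `inactive` (DNA detected, ratio
#' below threshold or cDNA absent) and `undetected` (neither library).
#'
#' @param assay `paired_assay` whose components are already rarefied to a
#'   common depth (see [rarefy_assay()]).
#' @param ratio_threshold minimum cDNA:DNA count ratio (default 1).
#' @param phantom_prevalence prevalence above which phantom taxa are rescued
#'   (default 0.05, i.e. detected in more than 5% of samples).
#' @param prevalence_metric what counts toward a phantom taxon's prevalence:
#'   `"phantom"` (default) counts phantom detections only;
#'   `"cdna_detection"` counts any cDNA detection.
#' @return object of class `activity_table`: `state` (character matrix),
#'   `active_counts` (DNA counts masked to active/rescued cells, with the
#'   1-substitution), the input `dna`/`cdna` matrices, and the parameters.
#' @export
classify_activity <- function(assay, ratio_threshold = 1,
                              phantom_prevalence = 0.05,
                              prevalence_metric = c("phantom",
                                                    "cdna_detection")) {
  stopifnot(inherits(assay, "paired_assay"))
  prevalence_metric <- match.arg(prevalence_metric)
  dna <- assay$dna; cdna <- assay$cdna
  if (!identical(dimnames(dna), dimnames(cdna)))
    stop("assay components are not aligned")
  if (ratio_threshold < 0) stop("ratio_threshold must be >= 0")

  state <- matrix("undetected", nrow(dna), ncol(dna), dimnames = dimnames(dna))
  phantom_cell <- dna == 0 & cdna > 0
  prev <- if (prevalence_metric == "phantom") colMeans(phantom_cell)
          else colMeans(cdna > 0)
  rescued_taxon <- prev > phantom_prevalence

  detected <- dna > 0
  ratio_ok <- detected & cdna > 0 & (cdna >= ratio_threshold * dna)
  state[detected] <- "inactive"
  state[ratio_ok] <- "active"
  state[phantom_cell] <- ifelse(
    matrix(rescued_taxon, nrow(dna), ncol(dna), byrow = TRUE)[phantom_cell],
    "phantom_rescued", "phantom_dropped")

  dna_sub <- dna
  dna_sub[state == "phantom_rescued"] <- 1L
  active_counts <- dna_sub
  active_counts[!(state %in% c("active", "phantom_rescued"))] <- 0L

  structure(list(state = state, active_counts = active_counts,
                 dna = dna, cdna = cdna,
                 ratio_threshold = ratio_threshold,
                 phantom_prevalence = phantom_prevalence,
                 prevalence_metric = prevalence_metric,
                 phantom_taxa = colnames(dna)[rescued_taxon & colSums(phantom_cell) > 0]),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d samples x %d taxa (threshold %.2g)\n",
              nrow(x$state), ncol(x$state), x$ratio_threshold))
  print(table(x$state))
  invisible(x)
}

#' Per-sample activity summary
#'
#' Percent active is computed over the DNA-observed taxa of each sample
#' (original DNA detections plus phantom-rescued cells, which acquire a DNA
#' count of 1). Samples with no observed taxa report `NA`.
#'
#' @param at `activity_table`.
#' @return data.frame, one row per sample: state counts, `n_observed`,
#'   `percent_active`, `active_reads`.
#' @export
activity_summary <- function(at) {
  stopifnot(inherits(at, "activity_table"))
  st <- at$state
  cnt <- function(s) rowSums(st == s)
  n_active <- cnt("active") + cnt("phantom_rescued")
  n_obs <- rowSums(at$dna > 0) + cnt("phantom_rescued")
  data.frame(sample_id = rownames(st),
             n_active = n_active,
             n_inactive = cnt("inactive"),
             n_phantom_rescued = cnt("phantom_rescued"),
             n_phantom_dropped = cnt("phantom_dropped"),
             n_undetected = cnt("undetected"),
             n_observed = n_obs,
             percent_active = ifelse(n_obs > 0, 100 * n_active / n_obs, NA),
             active_reads = rowSums(at$active_counts),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Four-state heatmap coding with maximum standardization
#'
#' Codes each sample x taxon cell from the paired counts — both libraries
#' absent: `NA`; DNA only: 0; both detected: the DNA count; cDNA only
#' (phantom): 1 — then divides each taxon's non-missing values by that
#' taxon's maximum, so abundance dynamics and detection changes are
#' distinguishable on one 0-1 scale.
#'
#' @param at `activity_table`.
#' @param taxa_subset taxa (columns) to include.
#' @return samples x taxa numeric matrix with values in \[0,1\] or `NA`.
#' @export
heatmap_code_and_standardize <- function(at, taxa_subset = colnames(at$dna)) {
  stopifnot(inherits(at, "activity_table"))
  if (length(taxa_subset) == 0) stop("empty taxa subset")
  missing_taxa <- setdiff(taxa_subset, colnames(at$dna))
  if (length(missing_taxa))
    stop("taxa not in the assay: ", paste(missing_taxa, collapse = ", "))
  dna <- at$dna[, taxa_subset, drop = FALSE]
  cdna <- at$cdna[, taxa_subset, drop = FALSE]
  coded <- dna * 1.0
  coded[dna == 0 & cdna == 0] <- NA
  coded[dna > 0 & cdna == 0] <- 0
  coded[dna == 0 & cdna > 0] <- 1
  mx <- apply(coded, 2, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  all_missing <- !is.finite(mx)
  if (any(all_missing))
    warning("taxa with no detections left as all-missing: ",
            paste(taxa_subset[all_missing], collapse = ", "))
  scale_by <- ifelse(is.finite(mx) & mx > 0, mx, 1)
  sweep(coded, 2, scale_by, "/")
}
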