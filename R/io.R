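#' Validate a sample-by-taxon count table
#'
#' A count table is a base integer matrix with samples as rows and taxa as
#' columns, unique row and column names, and non-negative integral entries.
#' All package functions accept and return this representation.
#'
#' @param counts numeric matrix with dimnames.
#' @return the validated matrix (storage mode integer), invisibly usable.
#' @export
as_count_table <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have sample (row) and taxon (column) names")
  dup_s <- unique(rownames(counts)[duplicated(rownames(counts))])
  dup_t <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (length(dup_t))
    stop("duplicate taxon identifiers: ", paste(dup_t, collapse = ", "))
  if (anyNA(counts)) stop("count table contains missing values")
  if (any(counts < 0)) stop("count table contains negative values")
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at sample '%s', taxon '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a count table from TSV or BIOM
#'
#' TSV tables may be written samples-as-rows or taxa-as-rows. Orientation is
#' either forced or, with `orientation = "auto"`, inferred by comparing the
#' row and column labels against `sample_ids`: the side with the larger
#' overlap holds the samples, and a tie is an error asking for an explicit
#' orientation (silent transposition being the classic amplicon-pipeline
#' bug). JSON BIOM files (extension `.biom`) are read through the biomformat
#' package, whose convention is taxa-as-rows.
#'
#' @param path file path; `.biom` triggers BIOM parsing, anything else TSV.
#' @param orientation one of `"samples_rows"` (default), `"taxa_rows"`,
#'   `"auto"`.
#' @param sample_ids character vector of known sample identifiers, required
#'   for `orientation = "auto"`.
#' @return validated count matrix (samples x taxa).
#' @export
read_count_table <- function(path,
                             orientation = c("samples_rows", "taxa_rows", "auto"),
                             sample_ids = NULL) {
  orientation <- match.arg(orientation)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(as_count_table(t(m)))   # biom stores taxa as rows
  }
  raw <- read.delim(path, row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("count table needs at least one labelled column")
  rn <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))), arr.ind = TRUE)
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s'",
                   rn[bad[1, 1]], colnames(m)[bad[1, 2]]))
    storage.mode(m) <- "numeric"
  }
  rownames(m) <- rn
  if (orientation == "auto") {
    if (is.null(sample_ids))
      stop("orientation = \"auto\" requires `sample_ids`")
    hit_rows <- sum(rownames(m) %in% sample_ids)
    hit_cols <- sum(colnames(m) %in% sample_ids)
    if (hit_rows == hit_cols)
      stop("cannot infer table orientation (equal label overlap on both ",
           "sides); pass orientation = \"samples_rows\" or \"taxa_rows\"")
    orientation <- if (hit_rows > hit_cols) "samples_rows" else "taxa_rows"
  }
  if (orientation == "taxa_rows") m <- t(m)
  as_count_table(m)
}

#' Write a count table to TSV or BIOM
#'
#' @param counts count matrix (samples x taxa).
#' @param path output path; `.biom` writes JSON BIOM via biomformat.
#' @param orientation `"samples_rows"` or `"taxa_rows"` for TSV output.
#' @param id_column header for the label column of a TSV file.
#' @export
write_count_table <- function(counts, path,
                              orientation = c("samples_rows", "taxa_rows"),
                              id_column = "sample_id") {
  orientation <- match.arg(orientation)
  counts <- as_count_table(counts)
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the biomformat package")
    biomformat::write_biom(biomformat::make_biom(t(counts)), path)
    return(invisible(path))
  }
  m <- if (orientation == "taxa_rows") t(counts) else counts
  if (orientation == "taxa_rows" && id_column == "sample_id")
    id_column <- "taxon_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# controlled vocabularies of the factorial design
.crop_levels <- c("bean", "switchgrass")
.planted_levels <- c("planted", "unplanted")
.drought_levels <- c("pre-drought", "drought", "watered")

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `crop` (bean/switchgrass), `planted`
#' (planted/unplanted), `drought` (pre-drought/drought/watered), `day`
#' (integer), `replicate`, `is_negative_control` (logical). Optional:
#' `dna_concentration` (ng/uL, non-negative). Invariants enforced on
#' non-control rows: `drought == "pre-drought"` exactly when `day == 0`, and
#' every factor level populated (missing levels are a hard error, never
#' imputed).
#'
#' @param metadata data.frame.
#' @return the validated data.frame.
#' @export
validate_sample_metadata <- function(metadata) {
  need <- c("sample_id", "crop", "planted", "drought", "day", "replicate",
            "is_negative_control")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample_id in metadata")
  smp <- metadata[!metadata$is_negative_control, , drop = FALSE]
  for (col in c("crop", "planted", "drought", "day", "replicate")) {
    if (anyNA(smp[[col]]))
      stop("non-control samples with missing '", col, "' in metadata")
  }
  if (!all(smp$crop %in% .crop_levels))
    stop("crop must be one of: ", paste(.crop_levels, collapse = ", "))
  if (!all(smp$planted %in% .planted_levels))
    stop("planted must be one of: ", paste(.planted_levels, collapse = ", "))
  if (!all(smp$drought %in% .drought_levels))
    stop("drought must be one of: ", paste(.drought_levels, collapse = ", "))
  bad <- xor(smp$drought == "pre-drought", smp$day == 0)
  if (any(bad))
    stop("drought == \"pre-drought\" must coincide with day == 0; offending ",
         "samples: ", paste(smp$sample_id[bad], collapse = ", "))
  if (!is.null(metadata$dna_concentration) &&
      any(metadata$dna_concentration < 0, na.rm = TRUE))
    stop("dna_concentration must be non-negative")
  metadata
}

#' Read a sample metadata TSV
#' @param path TSV with the columns described in
#'   [validate_sample_metadata()].
#' @return validated data.frame.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  md$is_negative_control <- as.logical(md$is_negative_control)
  validate_sample_metadata(md)
}

#' Read a taxonomy table with semicolon-delimited lineages
#'
#' Expects columns `taxon_id` and `lineage` (SILVA style,
#' `domain;phylum;...;genus`, possibly truncated) and an optional
#' `confidence` in \[0,1\]. Taxa lacking a lineage must carry the explicit
#' marker `"unclassified"`.
#'
#' @param path TSV path.
#' @return data.frame with `taxon_id`, `lineage`, and split `ranks`
#'   (list-column).
#' @export
read_taxonomy <- function(path) {
  tx <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon_id", "lineage") %in% names(tx)))
    stop("taxonomy table needs 'taxon_id' and 'lineage' columns")
  if (anyDuplicated(tx$taxon_id)) stop("duplicate taxon_id in taxonomy")
  empty <- is.na(tx$lineage) | !nzchar(trimws(tx$lineage))
  if (any(empty))
    stop("taxa without lineage must be marked 'unclassified': ",
         paste(tx$taxon_id[empty], collapse = ", "))
  tx$ranks <- lapply(strsplit(tx$lineage, ";", fixed = TRUE), trimws)
  if (!is.null(tx$confidence) &&
      any(tx$confidence < 0 | tx$confidence > 1, na.rm = TRUE))
    stop("taxonomy confidence must lie in [0, 1]")
  tx
}

#' Pair DNA and cDNA count tables over shared biological samples
#'
#' Sample correspondence is established from one of: an explicit `pair_map`
#' (columns `sample_id`, `dna_id`, `cdna_id`); the suffix convention
#' `<id><suffix_dna>` / `<id><suffix_cdna>` when the suffixes occur in the
#' row names; or identical sample identifiers in both tables. Samples
#' lacking a partner are dropped with a warning; duplicated pair keys are an
#' error. The taxon universes are unioned and missing taxa zero-filled, so
#' both components share an identical sample order and taxon set.
#'
#' @param dna,cdna count matrices (samples x taxa).
#' @param pair_map optional explicit map (data.frame).
#' @param suffix_dna,suffix_cdna suffix convention for implicit pairing.
#' @return object of class `paired_assay`: list with elements `dna`, `cdna`
#'   (aligned matrices whose row names are the shared sample ids) and
#'   `pair_map`.
#' @export
pair_assays <- function(dna, cdna, pair_map = NULL,
                        suffix_dna = "__DNA", suffix_cdna = "__cDNA") {
  dna <- as_count_table(dna)
  cdna <- as_count_table(cdna)
  if (is.null(pair_map)) {
    strip <- function(ids, suf) {
      hit <- endsWith(ids, suf)
      ids[hit] <- substr(ids[hit], 1L, nchar(ids[hit]) - nchar(suf))
      ids
    }
    dna_key <- strip(rownames(dna), suffix_dna)
    cdna_key <- strip(rownames(cdna), suffix_cdna)
    pair_map <- merge(
      data.frame(sample_id = dna_key, dna_id = rownames(dna),
                 stringsAsFactors = FALSE),
      data.frame(sample_id = cdna_key, cdna_id = rownames(cdna),
                 stringsAsFactors = FALSE),
      by = "sample_id")
  } else {
    if (!all(c("sample_id", "dna_id", "cdna_id") %in% names(pair_map)))
      stop("pair_map needs columns sample_id, dna_id, cdna_id")
    pair_map <- pair_map[pair_map$dna_id %in% rownames(dna) &
                           pair_map$cdna_id %in% rownames(cdna), ,
                         drop = FALSE]
  }
  if (anyDuplicated(pair_map$sample_id) || anyDuplicated(pair_map$dna_id) ||
      anyDuplicated(pair_map$cdna_id))
    stop("ambiguous pairing: duplicated pair key")
  if (nrow(pair_map) == 0)
    stop("no samples could be paired between the DNA and cDNA tables")
  lost_dna <- setdiff(rownames(dna), pair_map$dna_id)
  lost_cdna <- setdiff(rownames(cdna), pair_map$cdna_id)
  if (length(lost_dna) || length(lost_cdna))
    warning("dropped unpaired samples: ",
            paste(c(lost_dna, lost_cdna), collapse = ", "))
  pair_map <- pair_map[order(pair_map$sample_id), , drop = FALSE]
  taxa <- sort(union(colnames(dna), colnames(cdna)))
  fill <- function(m, ids) {
    out <- matrix(0L, nrow(pair_map), length(taxa),
                  dimnames = list(pair_map$sample_id, taxa))
    out[, colnames(m)] <- m[ids, , drop = FALSE]
    out
  }
  structure(list(dna = fill(dna, pair_map$dna_id),
                 cdna = fill(cdna, pair_map$cdna_id),
                 pair_map = pair_map),
            class = "paired_assay")
}

#' @export
print.paired_assay <- function(x, ...) {
  cat(sprintf("paired_assay: %d samples x %d taxa (DNA + cDNA)\n",
              nrow(x$dna), ncol(x$dna)))
  invisible(x)
}

#' Gravimetric soil moisture content
#'
#' Percent water mass lost during drying relative to the dry soil mass:
#' `100 * (mass_wet - mass_dry) / mass_dry`. Vectorized. A wet mass below
#' the dry mass is physically suspect and raises a warning, not an error.
#'
#' @param mass_wet,mass_dry masses in grams; `mass_dry` must be positive.
#' @return percent moisture (numeric).
#' @export
gravimetric_moisture <- function(mass_wet, mass_dry) {
  if (any(mass_dry <= 0)) stop("mass_dry must be positive")
  if (any(mass_wet < mass_dry))
    warning("mass_wet < mass_dry for some records; check the data")
  100 * (mass_wet - mass_dry) / mass_dry
}
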