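#' Read a species map
#'
#' A species map links short species codes found in gene-tree tip labels to
#' salmonid subfamilies (lineages) and flags the pre-duplication outgroup
#' (northern pike in the default setting). Required TSV columns:
#' `species_code`, `lineage`, `is_outgroup`.
#'
#' @param path TSV file path.
#' @return A tibble with columns `species_code`, `lineage`, `is_outgroup`.
#' @export
read_species_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_species_map(df)
}

validate_species_map <- function(df) {
  req <- c("species_code", "lineage", "is_outgroup")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("species map lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(df), req)
  if (length(extra)) {
    abort(paste0("unknown species map column(s): ", paste(extra, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("species map is empty")
  if (anyDuplicated(df$species_code)) {
    abort("duplicate species_code in species map")
  }
  df$is_outgroup <- as.logical(df$is_outgroup)
  if (!any(df$is_outgroup)) abort("species map must flag at least one outgroup")
  ing <- df[!df$is_outgroup, ]
  if (any(is.na(ing$lineage) | ing$lineage == "")) {
    abort("every non-outgroup species needs a lineage")
  }
  as_tibble(df)
}

#' Default salmonid species map
#'
#' Seven salmonid species spanning the three subfamilies (Salmoninae,
#' Thymallinae, Coregoninae) plus northern pike (*Esox lucius*, code `Eluc`)
#' as the pre-WGD outgroup.
#'
#' @return A species-map tibble.
#' @export
default_species_map <- function() {
  tibble(
    species_code = c("Ssal", "Blen", "Tbai", "Tgru", "Pcou", "Sleu", "Clav", "Eluc"),
    lineage = c("Salmoninae", "Salmoninae", "Thymallinae", "Thymallinae",
                "Coregoninae", "Coregoninae", "Coregoninae", NA),
    is_outgroup = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Read a count matrix
#'
#' Expects a TSV with a header row of sample ids and gene ids in the first
#' column. Counts must be non-negative numbers with no missing values.
#'
#' @param path TSV file path.
#' @return A numeric matrix, genes in rows, samples in columns.
#' @export
read_counts <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2) abort("count table needs a gene id column plus samples")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric counts in count table")
  if (anyNA(m)) abort("missing values in count table")
  if (any(m < 0)) abort("negative counts in count table")
  rownames(m) <- genes
  m
}

#' @rdname read_counts
#' @param counts A count matrix with gene row names.
#' @export
write_counts <- function(counts, path) {
  df <- as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `tissue` and optionally `condition`
#' (e.g. freshwater/saltwater) and `replicate`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("sample_id", "tissue")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("sample metadata lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in metadata")
  as_tibble(df)
}

#' Read / write BED-like locus tables
#'
#' Coordinates are 0-based half-open throughout the package, matching BED
#' conventions. Required columns: `locus_id`, `chrom`, `start`, `end`;
#' any further columns (e.g. `class`) are kept.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_loci <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("locus_id", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    abort(paste0("locus table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(df$start < 0)) abort("negative coordinates in locus table")
  if (any(df$start >= df$end)) abort("locus table requires start < end")
  as_tibble(df)
}

#' @rdname read_loci
#' @param loci A locus tibble.
#' @export
write_loci <- function(loci, path) {
  readr::write_tsv(loci, path, progress = FALSE)
  invisible(path)
}
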