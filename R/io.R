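# Readers and writers for the tabular inputs: sample metadata, count/abundance
# matrices, and gene-set annotations.  All tables are TSV, samples as rows,
# first header cell "sample_id"; missing numeric cells are empty or "NA".

#' Read a sample metadata table
#'
#' Parses a tab-separated metadata file with one row per sample.  Expected
#' columns are `sample_id`, the nesting labels `continent`, `region`, `site`,
#' the twelve continuous environmental variables (`latitude`, `longitude`,
#' `elevation`, `age`, `depth`, `total_c`, `total_n`, `cn_ratio`, `organic_c`,
#' `ph`, `ice_content`, `ec`) and `age_class` (`Holocene` / `Pleistocene`).
#' Missing numeric cells may be empty or `"NA"`.
#'
#' Validation enforces: unique sample ids; each site nested in exactly one
#' region and each region in exactly one continent; latitude in \[-90, 90\];
#' pH in (0, 14) where present.  Non-numeric text in a numeric column is an
#' error naming the offending row and column.
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata with attribute `"missingness"`, a named
#'   integer vector of missing-value counts per environmental variable (also
#'   retrievable with [missingness_report()]).
#' @seealso [missingness_report()], [read_counts()]
#' @export
read_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  if (!"sample_id" %in% names(raw)) {
    abort("metadata file must contain a 'sample_id' column")
  }
  num_cols <- intersect(ENV_VARS, names(raw))
  for (cl in num_cols) {
    v <- raw[[cl]]
    miss <- v == "" | v == "NA"
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!miss & is.na(parsed))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    v[bad[1]], cl, bad[1]))
    }
    raw[[cl]] <- parsed
  }
  for (cl in intersect(c("continent", "region", "site", "age_class"), names(raw))) {
    raw[[cl]][raw[[cl]] %in% c("", "NA")] <- NA_character_
  }
  validate_metadata(raw)
}

#' Validate an in-memory metadata table
#'
#' Applies the same invariants as [read_metadata()] to a data frame built in
#' code and attaches the per-variable missingness report.
#'
#' @param meta A data frame of sample metadata.
#' @return The validated metadata tibble.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id: %s", paste(unique(dup), collapse = ", ")))
  }
  if (all(c("site", "region") %in% names(meta))) {
    bad <- meta %>% distinct(.data$site, .data$region) %>% count(.data$site) %>%
      filter(n > 1)
    if (nrow(bad) > 0) {
      abort(sprintf("site mapped to more than one region: %s",
                    paste(bad$site, collapse = ", ")))
    }
  }
  if (all(c("region", "continent") %in% names(meta))) {
    bad <- meta %>% distinct(.data$region, .data$continent) %>%
      count(.data$region) %>% filter(n > 1)
    if (nrow(bad) > 0) {
      abort(sprintf("region mapped to more than one continent: %s",
                    paste(bad$region, collapse = ", ")))
    }
  }
  if ("latitude" %in% names(meta)) {
    lat <- meta$latitude
    if (any(!is.na(lat) & (lat < -90 | lat > 90))) {
      abort("latitude outside [-90, 90]")
    }
  }
  if ("ph" %in% names(meta)) {
    ph <- meta$ph
    if (any(!is.na(ph) & (ph <= 0 | ph >= 14))) {
      abort("pH outside (0, 14)")
    }
  }
  present <- intersect(ENV_VARS, names(meta))
  missing_counts <- vapply(meta[present], function(v) sum(is.na(v)), integer(1))
  attr(meta, "missingness") <- missing_counts
  meta
}

#' Per-variable missingness report
#'
#' @param meta Metadata tibble from [read_metadata()] / [validate_metadata()].
#' @return A tibble with columns `variable`, `n_missing`, `n_observed`, plus
#'   the total number of potential observations (samples x variables) as
#'   attribute `"n_potential"`.
#' @export
missingness_report <- function(meta) {
  meta <- validate_metadata(meta)
  mc <- attr(meta, "missingness")
  out <- tibble::tibble(variable = names(mc),
                        n_missing = unname(mc),
                        n_observed = nrow(meta) - unname(mc))
  attr(out, "n_potential") <- nrow(meta) * length(mc)
  out
}

#' Read a samples-by-features count or relative-abundance matrix
#'
#' The file is TSV with first column `sample_id` and one column per feature
#' (KEGG ortholog or taxonomic class).  `mode = "counts"` rejects negative and
#' fractional values; `mode = "relabund"` additionally checks that each row
#' sums to 1 (within 1e-9) and flags, with a warning, rows whose sums deviate
#' (all-zero rows are flagged, never silently renormalized).
#'
#' @param path Path to a TSV file.
#' @param mode `"counts"` (non-negative integers) or `"relabund"`.
#' @return A tibble (`sample_id` + feature columns) with attribute `"mode"`;
#'   for `relabund` mode also attribute `"flagged_rows"` (sample ids whose row
#'   sums are off).
#' @export
read_counts <- function(path, mode = c("counts", "relabund")) {
  mode <- match.arg(mode)
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", .default = "d"))
  validate_counts(x, mode = mode)
}

#' Validate an in-memory count table
#' @inheritParams read_counts
#' @param counts A data frame, first column `sample_id`.
#' @return The validated tibble, with `"mode"` and (for relabund)
#'   `"flagged_rows"` attributes.
#' @export
validate_counts <- function(counts, mode = c("counts", "relabund")) {
  mode <- match.arg(mode)
  counts <- tibble::as_tibble(counts)
  if (names(counts)[1] != "sample_id") {
    abort("first column must be 'sample_id'")
  }
  m <- counts_to_matrix(counts)
  if (anyNA(m)) abort("count matrix contains missing values")
  if (any(m < 0)) abort("count matrix contains negative values")
  if (mode == "counts" && any(abs(m - round(m)) > 1e-8)) {
    abort("fractional value found in integer count mode")
  }
  if (mode == "relabund") {
    rs <- rowSums(m)
    off <- abs(rs - 1) > 1e-9
    if (any(off)) {
      warn(sprintf("%d row(s) do not sum to 1 (flagged, not renormalized): %s",
                   sum(off), paste(head(counts$sample_id[off], 5), collapse = ", ")))
    }
    attr(counts, "flagged_rows") <- counts$sample_id[off]
  }
  attr(counts, "mode") <- mode
  counts
}

#' Read a feature-to-set annotation table
#'
#' Maps features (genes) to pathways, modules or functional categories.  TSV
#' with columns `feature_id`, `set_id`, `set_kind`.  A feature may belong to
#' several sets; duplicate (feature, set) rows are dropped.
#'
#' @param path Path to a TSV file.
#' @return A tibble with the three columns, deduplicated.
#' @export
read_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  need <- c("feature_id", "set_id", "set_kind")
  if (!all(need %in% names(x))) {
    abort(sprintf("annotation file must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  distinct(x[, need])
}

#' Write a tabular result to TSV
#'
#' Counterpart to the readers: round-tripping any metadata or count table
#' through `write_table()` + the matching reader reproduces values exactly.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}
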