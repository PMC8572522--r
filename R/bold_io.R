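#' Default BOLD combined-TSV column dialect
#'
#' Maps the package's internal record fields to the column names used by the
#' BOLD "combined TSV" public-portal export. Pass a modified copy to
#' [read_bold_tsv()] when working with a different export schema; column
#' matching is case-insensitive.
#'
#' @return Named character vector: names are internal field names, values are
#'   file column names.
#' @export
#' @examples
#' bold_dialect()
bold_dialect <- function() {
  c(
    record_id   = "recordID",
    sample_id   = "sampleid",
    process_id  = "processid",
    bin_uri     = "bin_uri",
    marker      = "markercode",
    order       = "order_name",
    family      = "family_name",
    subfamily   = "subfamily_name",
    genus       = "genus_name",
    species     = "species_name",
    identifier  = "identification_provided_by",
    sequence    = "nucleotides",
    lat         = "lat",
    lon         = "lon",
    country     = "country",
    source_note = "source_note"
  )
}

#' Build a barcode-record tibble
#'
#' Constructs the canonical record tibble used throughout the package,
#' filling absent optional fields with `NA` and validating the basic
#' invariants (unique `record_id`, paired coordinates within range).
#'
#' @param ... Vectors for any subset of the record fields (`record_id`,
#'   `sample_id`, `process_id`, `bin_uri`, `marker`, `order`, `family`,
#'   `subfamily`, `genus`, `species`, `identifier`, `sequence`, `lat`, `lon`,
#'   `country`, `source_note`), or a single data frame with such columns.
#' @return A tibble with one row per record and the full fixed column set.
#' @export
#' @examples
#' barcode_records(
#'   record_id = "r1", marker = "COI-5P", bin_uri = "BOLD:AAA1262",
#'   species = "Gammarus oceanicus"
#' )
barcode_records <- function(...) {
  dots <- list(...)
  if (length(dots) == 1L && is.data.frame(dots[[1L]])) {
    df <- tibble::as_tibble(dots[[1L]])
  } else {
    df <- tibble::tibble(...)
  }
  unknown <- setdiff(names(df), RECORD_COLUMNS)
  if (length(unknown)) {
    rlang::abort(paste0("unknown record fields: ", paste(unknown, collapse = ", ")))
  }
  n <- nrow(df)
  for (col in RECORD_COLUMNS) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("lat", "lon")) rep(NA_real_, n) else rep(NA_character_, n)
    }
  }
  df <- df[RECORD_COLUMNS]
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  for (col in setdiff(RECORD_COLUMNS, c("lat", "lon"))) {
    df[[col]] <- normalize_absent(df[[col]])
  }
  validate_records(df)
  df
}

validate_records <- function(df) {
  if (any(is.na(df$record_id))) rlang::abort("record_id must be present for every record")
  if (anyDuplicated(df$record_id)) {
    dup <- unique(df$record_id[duplicated(df$record_id)])
    rlang::abort(paste0("duplicate record_id: ", paste(head(dup, 5L), collapse = ", ")))
  }
  if (any(xor(is.na(df$lat), is.na(df$lon)))) {
    rlang::abort("latitude and longitude must be present together")
  }
  bad <- !is.na(df$lat) & (abs(df$lat) > 90 | abs(df$lon) > 180)
  if (any(bad)) rlang::abort("coordinates out of range")
  invisible(df)
}

#' Read a BOLD combined-TSV record file
#'
#' Reads a tab-separated specimen+sequence export into the canonical record
#' tibble. Unknown columns are ignored, empty cells (and the strings `"NA"`,
#' `"None"`) become missing, and column names are matched case-insensitively
#' against the dialect. Rows are never silently dropped: every input data row
#' yields one record.
#'
#' Malformed or out-of-range coordinates do not reject a record; its
#' geography is loaded as absent and a warning reports how many rows were
#' affected.
#'
#' @param path Path to the TSV file.
#' @param dialect Named character vector mapping internal field names to file
#'   column names; see [bold_dialect()].
#' @return A record tibble (see [barcode_records()]).
#' @export
read_bold_tsv <- function(path, dialect = bold_dialect()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  lower <- tolower(names(raw))
  picked <- list()
  for (field in names(dialect)) {
    idx <- match(tolower(dialect[[field]]), lower)
    if (!is.na(idx)) picked[[field]] <- normalize_absent(raw[[idx]])
  }
  id_fields <- intersect(c("record_id", "sample_id", "process_id"), names(picked))
  if (length(id_fields) == 0L) {
    rlang::abort("no identifier column found: need at least one of recordID, sampleid, processid")
  }
  n <- nrow(raw)
  df <- tibble::tibble(.rows = n)
  for (field in names(dialect)) {
    df[[field]] <- picked[[field]] %||% rep(NA_character_, n)
  }
  # Fall back through the ID columns so record_id is always populated.
  rid <- df$record_id
  rid[is.na(rid)] <- df$process_id[is.na(rid)]
  rid[is.na(rid)] <- df$sample_id[is.na(rid)]
  df$record_id <- rid

  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  bad <- (!is.na(df$lat) & is.na(lat)) | (!is.na(df$lon) & is.na(lon)) |
    xor(is.na(lat), is.na(lon)) |
    (!is.na(lat) & !is.na(lon) & (abs(lat) > 90 | abs(lon) > 180))
  if (any(bad)) {
    rlang::warn(paste0(sum(bad), " record(s) had malformed coordinates; geography set to absent"))
    lat[bad] <- NA_real_
    lon[bad] <- NA_real_
  }
  df$lat <- lat
  df$lon <- lon
  barcode_records(df)
}

#' Write records as a BOLD-style TSV
#'
#' Inverse of [read_bold_tsv()]: writes the canonical record tibble using the
#' column names of `dialect`, so that a write/read round trip preserves every
#' field the dialect covers.
#'
#' @param records Record tibble.
#' @param path Output path.
#' @inheritParams read_bold_tsv
#' @return `path`, invisibly.
#' @export
write_bold_tsv <- function(records, path, dialect = bold_dialect()) {
  out <- records[names(dialect)]
  names(out) <- unname(dialect)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a species checklist
#'
#' Reads a CSV checklist emulating a World Amphipoda Database export, with
#' columns `canonical_name`, `family`, and optionally `authority` and
#' `status`. By default only rows with `status == "accepted"` are returned
#' (a missing status column is treated as all-accepted). Exact duplicates are
#' collapsed with a warning; the same accepted name listed under two
#' different families is an error.
#'
#' @param path Path to the checklist CSV.
#' @param accepted_only Keep only accepted names (default `TRUE`).
#' @return Tibble with columns `canonical_name`, `authority`, `family`,
#'   `status`.
#' @export
read_checklist <- function(path, accepted_only = TRUE) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("canonical_name", "family")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    rlang::abort(paste0("checklist is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (!"authority" %in% names(df)) df$authority <- NA_character_
  if (!"status" %in% names(df)) df$status <- "accepted"
  df$status[is.na(df$status)] <- "accepted"
  df <- tibble::tibble(
    canonical_name = normalize_absent(df$canonical_name),
    authority = normalize_absent(df$authority),
    family = normalize_absent(df$family),
    status = tolower(trimws(df$status))
  )
  df <- df[!is.na(df$canonical_name) & !is.na(df$family), ]
  if (accepted_only) df <- df[df$status == "accepted", ]
  acc <- df[df$status == "accepted", ]
  fam_per_name <- tapply(acc$family, acc$canonical_name, function(f) length(unique(f)))
  conflicted <- names(fam_per_name)[fam_per_name > 1L]
  if (length(conflicted)) {
    rlang::abort(paste0("accepted name(s) listed under conflicting families: ",
                        paste(head(conflicted, 5L), collapse = ", ")))
  }
  dup <- duplicated(df[c("canonical_name", "status")])
  if (any(dup)) {
    rlang::warn(paste0(sum(dup), " duplicate checklist row(s) collapsed"))
    df <- df[!dup, ]
  }
  df
}

#' Read a taxon-to-realm habitat map
#'
#' Reads a CSV with columns `taxon_name`, `rank` (one of species, genus,
#' family) and `realm` (marine, freshwater, terrestrial). Brackish-capable
#' taxa are expected to be pre-merged into marine or freshwater before the
#' table is built, so each taxon carries exactly one realm.
#'
#' @param path Path to the habitat map CSV.
#' @return Tibble with columns `taxon_name`, `rank`, `realm`.
#' @export
read_habitat_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  need <- c("taxon_name", "rank", "realm")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    rlang::abort(paste0("habitat map is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  df <- tibble::tibble(
    taxon_name = normalize_absent(df$taxon_name),
    rank = tolower(trimws(df$rank)),
    realm = tolower(trimws(df$realm))
  )
  bad_rank <- setdiff(unique(df$rank), c("species", "genus", "family"))
  if (length(bad_rank)) rlang::abort(paste0("invalid habitat map rank: ", paste(bad_rank, collapse = ", ")))
  bad_realm <- setdiff(unique(df$realm), c("marine", "freshwater", "terrestrial"))
  if (length(bad_realm)) rlang::abort(paste0("invalid habitat map realm: ", paste(bad_realm, collapse = ", ")))
  df <- unique(df)
  key <- paste(df$taxon_name, df$rank)
  if (anyDuplicated(key)) {
    off <- unique(key[duplicated(key)])
    rlang::abort(paste0("conflicting realms for: ", paste(head(off, 5L), collapse = ", ")))
  }
  df
}

#' Write the audit output file set
#'
#' Writes every table produced by [run_audit()] (or any subset) as UTF-8
#' RFC-4180 CSV with a fixed column order and fixed row sort, so that
#' identical inputs produce byte-identical files. The run summary is written
#' as JSON.
#'
#' @param outputs Named list of tibbles/lists as produced by [run_audit()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_audit_tables <- function(outputs, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) rlang::abort(paste0("cannot create output directory: ", out_dir))
  }
  sort_keys <- list(
    curated_records = "record_id",
    removal_log = "record_id",
    bins = "bin_uri",
    bin_conflicts = "bin_uri",
    demotions = "record_id",
    species_grades = "canonical_name",
    grade_summary = NULL,
    realm_tallies = NULL,
    family_coverage = "family",
    richness_rollup = NULL,
    grade_by_category = NULL,
    unmatched_names = "canonical_name",
    id_level_summary = NULL,
    geo_completeness = NULL,
    country_tally = c("country", "realm"),
    seqs_per_bin = NULL,
    bins_per_species = NULL
  )
  paths <- character()
  for (name in names(outputs)) {
    obj <- outputs[[name]]
    if (name == "run_summary") {
      path <- file.path(out_dir, "run_summary.json")
      jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      paths <- c(paths, path)
      next
    }
    if (is.character(obj)) obj <- tibble::tibble(canonical_name = sort(obj))
    if (!is.data.frame(obj)) next
    obj <- dplyr::mutate(obj, dplyr::across(dplyr::where(is.factor), as.character))
    keys <- sort_keys[[name]]
    if (is.null(keys) && name %in% names(sort_keys)) {
      # summary tables keep their construction order, which is already fixed
    } else {
      keys <- keys %||% names(obj)[1L]
      keys <- intersect(keys, names(obj))
      if (length(keys)) obj <- dplyr::arrange(obj, dplyr::across(dplyr::all_of(keys)))
    }
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(obj, path, na = "", progress = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
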