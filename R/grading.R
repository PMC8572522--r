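#' Grade a species' barcode quality (A-E)
#'
#' Applies the five-grade quality scheme for reference barcodes, after the
#' BAGS system: A — consolidated concordance (a single BIN with more than 10
#' sequences); B — basal concordance (a single BIN, 3 to 10 sequences); C —
#' the species is split over multiple BINs; D — insufficient data (a single
#' BIN with fewer than 3 sequences); E — discordant assignment (the species
#' shares a BIN with another species). Precedence: E over C over A/B/D.
#'
#' @param n_sequences Integer vector: curated sequences bearing the species.
#' @param n_bins Integer vector: distinct BINs whose consensus is the
#'   species.
#' @param shares_bin Logical vector: some BIN of this species also carries
#'   another species name (cannot occur on input produced by
#'   [resolve_bins()]; provided for standalone use).
#' @return Factor vector of grades with levels A-E.
#' @export
#' @examples
#' grade_species(c(11, 3, 10, 2, 500), c(1, 1, 1, 1, 2))
grade_species <- function(n_sequences, n_bins, shares_bin = FALSE) {
  n <- max(length(n_sequences), length(n_bins), length(shares_bin))
  n_sequences <- rep_len(as.integer(n_sequences), n)
  n_bins <- rep_len(as.integer(n_bins), n)
  shares_bin <- rep_len(as.logical(shares_bin), n)
  stopifnot(all(n_sequences >= 1L), all(n_bins >= 1L))
  grade <- ifelse(shares_bin, "E",
           ifelse(n_bins > 1L, "C",
           ifelse(n_sequences > 10L, "A",
           ifelse(n_sequences >= 3L, "B", "D"))))
  grade_factor(grade)
}

#' Species grade table and per-realm grade summary
#'
#' Builds one audit row per distinct species name carried as a BIN consensus
#' (realm-unassigned BINs excluded), counting its curated sequences across
#' all its BINs (records demoted during BIN resolution are not counted for
#' the species) and its number of distinct BINs, and grading it with
#' [grade_species()]. The summary counts species per grade for all species
#' and within each realm; a species whose BINs span several realms is
#' counted in every realm it occurs in, so per-realm rows may sum to more
#' than the all-species row.
#'
#' Temporary-name taxa are not graded: the grading scheme is defined for
#' nominal species. Open-nomenclature records are graded under their cleaned
#' canonical name together with clean records of the same name.
#'
#' @param bins Realm-assigned BIN tibble from [assign_realms()].
#' @param records Curated record tibble.
#' @param demotions Demotions tibble from [resolve_bins()] (optional).
#' @return List with `species` (tibble: `canonical_name`, `realms`
#'   (semicolon-collapsed), `n_sequences`, `n_bins`, `shares_bin`, `grade`)
#'   and `summary` (tibble: `scope` = all/marine/freshwater/terrestrial,
#'   columns `A`-`E`, `total`).
#' @export
grade_table <- function(bins, records, demotions = NULL) {
  sp_bins <- bins[!is.na(bins$consensus_level) & bins$consensus_level == "species" &
                    as.character(bins$realm) != "unassigned", ]
  demoted_ids <- if (!is.null(demotions)) demotions$record_id else character()

  if (nrow(sp_bins) == 0L) {
    species <- tibble::tibble(canonical_name = character(), realms = character(),
                              n_sequences = integer(), n_bins = integer(),
                              shares_bin = logical(), grade = grade_factor(character()))
  } else {
    rec <- records[!is.na(records$bin_uri) & records$bin_uri %in% sp_bins$bin_uri &
                     !(records$record_id %in% demoted_ids), ]
    seqs_per_bin <- table(factor(rec$bin_uri, levels = sp_bins$bin_uri))
    per_bin <- tibble::tibble(
      bin_uri = sp_bins$bin_uri,
      canonical_name = sp_bins$species,
      realm = as.character(sp_bins$realm),
      n_seq = as.integer(seqs_per_bin)
    )
    species <- per_bin |>
      dplyr::group_by(.data$canonical_name) |>
      dplyr::summarise(
        realms = paste(sort(unique(.data$realm)), collapse = ";"),
        n_sequences = sum(.data$n_seq),
        n_bins = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::mutate(shares_bin = FALSE,
                    grade = grade_species(.data$n_sequences, .data$n_bins, .data$shares_bin)) |>
      dplyr::arrange(.data$canonical_name)
  }

  count_grades <- function(df, scope) {
    tab <- table(factor(as.character(df$grade), levels = GRADE_LEVELS))
    out <- tibble::as_tibble(as.list(tab))
    dplyr::bind_cols(tibble::tibble(scope = scope), out,
                     tibble::tibble(total = nrow(df)))
  }
  in_realm <- function(r) species[vapply(strsplit(species$realms, ";"),
                                         function(x) r %in% x, logical(1L)), ]
  summary <- dplyr::bind_rows(
    count_grades(species, "all"),
    count_grades(in_realm("freshwater"), "freshwater"),
    count_grades(in_realm("marine"), "marine"),
    count_grades(in_realm("terrestrial"), "terrestrial")
  )
  list(species = species, summary = summary)
}
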