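#' Family richness category
#'
#' Classifies a family by its number of accepted species: `low` (up to 10),
#' `moderate` (11-30), `rich` (31-100), `very_rich` (more than 100).
#'
#' @param n_accepted Integer vector of accepted-species counts.
#' @return Factor with levels `low`, `moderate`, `rich`, `very_rich`.
#' @export
richness_category <- function(n_accepted) {
  stopifnot(all(n_accepted >= 0L))
  cut(n_accepted, breaks = c(-Inf, 10, 30, 100, Inf),
      labels = c("low", "moderate", "rich", "very_rich"))
}

#' Match graded species against the reference checklist
#'
#' Exact match on canonical name. Unmatched names (misspellings, synonyms,
#' names absent from the checklist) are reported, not dropped.
#'
#' @param species Species grade tibble (from [grade_table()]`$species`) or
#'   any tibble with a `canonical_name` column.
#' @param checklist Accepted-names tibble from [read_checklist()].
#' @return List with `matched` (species rows joined with the checklist
#'   `family`) and `unmatched_names` (character vector, sorted).
#' @export
match_to_checklist <- function(species, checklist) {
  m <- match(species$canonical_name, checklist$canonical_name)
  matched <- species[!is.na(m), , drop = FALSE]
  matched$family <- checklist$family[m[!is.na(m)]]
  list(
    matched = matched,
    unmatched_names = sort(species$canonical_name[is.na(m)])
  )
}

#' Family-level and richness-category coverage tables
#'
#' For every family in the checklist: accepted species count, number of
#' distinct barcoded (matched) species, percent coverage, and richness
#' category. Roll-ups report (i) family counts per coverage band (0%, up to
#' 10%, 11-20%, 21-50%, more than 50%), separately flagging zero-coverage
#' families that nevertheless have at least one BIN identified to genus or
#' family level, and (ii) per richness category the number of families with
#' representation and the mean coverage over represented families only.
#' Families appearing in BIN consensus taxonomy but absent from the
#' checklist are listed as pseudo-families with coverage undefined.
#'
#' @param matched Matched species tibble from [match_to_checklist()].
#' @param checklist Accepted-names tibble.
#' @param bins Optional realm-assigned BIN tibble; used for the
#'   genus-/family-level flags and pseudo-family detection.
#' @return List with `families`, `rollup`, `category_rollup`,
#'   `pseudo_families`.
#' @export
family_coverage_table <- function(matched, checklist, bins = NULL) {
  acc <- checklist |>
    dplyr::count(.data$family, name = "n_accepted")
  barc <- matched |>
    dplyr::distinct(.data$canonical_name, .data$family) |>
    dplyr::count(.data$family, name = "n_barcoded_species")
  fam <- dplyr::left_join(acc, barc, by = "family") |>
    dplyr::mutate(
      n_barcoded_species = dplyr::coalesce(.data$n_barcoded_species, 0L),
      pct_coverage = 100 * .data$n_barcoded_species / .data$n_accepted,
      category = richness_category(.data$n_accepted)
    )

  fam$has_genus_level_bins <- FALSE
  fam$has_family_level_bins <- FALSE
  pseudo <- tibble::tibble(family = character(), n_bins = integer())
  if (!is.null(bins)) {
    gl <- bins[!is.na(bins$family) & bins$consensus_level == "genus", ]
    fl <- bins[!is.na(bins$family) & bins$consensus_level == "family", ]
    fam$has_genus_level_bins <- fam$family %in% gl$family
    fam$has_family_level_bins <- fam$family %in% fl$family
    seen <- unique(bins$family[!is.na(bins$family)])
    pseudo_names <- setdiff(seen, fam$family)
    if (length(pseudo_names)) {
      pseudo <- tibble::tibble(
        family = sort(pseudo_names),
        n_bins = vapply(sort(pseudo_names),
                        function(f) sum(bins$family == f, na.rm = TRUE), integer(1L))
      )
    }
  }

  band <- function(pct, n_barc) {
    dplyr::case_when(
      n_barc == 0L ~ "0%",
      pct <= 10 ~ "<=10%",
      pct <= 20 ~ "11-20%",
      pct <= 50 ~ "21-50%",
      TRUE ~ ">50%"
    )
  }
  fam$coverage_band <- factor(band(fam$pct_coverage, fam$n_barcoded_species),
                              levels = c("0%", "<=10%", "11-20%", "21-50%", ">50%"))
  rollup <- fam |>
    dplyr::count(.data$coverage_band, name = "n_families", .drop = FALSE) |>
    dplyr::mutate(
      n_zero_with_genus_bins = ifelse(
        .data$coverage_band == "0%",
        sum(fam$n_barcoded_species == 0L & fam$has_genus_level_bins), NA_integer_),
      n_zero_with_family_bins = ifelse(
        .data$coverage_band == "0%",
        sum(fam$n_barcoded_species == 0L & !fam$has_genus_level_bins &
              fam$has_family_level_bins), NA_integer_)
    )

  category_rollup <- fam |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      n_species_accepted = sum(.data$n_accepted),
      n_families_represented = sum(.data$n_barcoded_species > 0L),
      n_species_barcoded = sum(.data$n_barcoded_species),
      mean_coverage_represented = if (any(.data$n_barcoded_species > 0L))
        mean(.data$pct_coverage[.data$n_barcoded_species > 0L]) else NA_real_,
      .groups = "drop"
    )

  list(families = fam, rollup = rollup, category_rollup = category_rollup,
       pseudo_families = pseudo)
}

#' Percent of families with at least one species in each grade
#'
#' For each richness category (and over all families), the percentage of
#' families — among those with at least one barcoded species in that
#' category — having at least one species graded A, B, C or D.
#'
#' @param matched_grades Matched species tibble carrying `family` and
#'   `grade` columns (output of [match_to_checklist()] on
#'   [grade_table()]`$species`).
#' @param families Family coverage tibble from
#'   [family_coverage_table()]`$families`.
#' @return Tibble: one row per grade A-D, columns `all` plus one per
#'   richness category, values in percent; final row gives the family
#'   denominators.
#' @export
grade_category_presence <- function(matched_grades, families) {
  rep_fams <- families[families$n_barcoded_species > 0L, ]
  cats <- levels(families$category)
  fam_cat <- setNames(as.character(rep_fams$category), rep_fams$family)

  pct_for <- function(fams_in_scope) {
    denom <- length(fams_in_scope)
    unname(vapply(c("A", "B", "C", "D"), function(g) {
      with_g <- unique(matched_grades$family[as.character(matched_grades$grade) == g])
      if (denom == 0L) return(NA_real_)
      100 * length(intersect(with_g, fams_in_scope)) / denom
    }, numeric(1L)))
  }

  scopes <- c(list(all = rep_fams$family),
              setNames(lapply(cats, function(cc) rep_fams$family[fam_cat[rep_fams$family] == cc]),
                       cats))
  body <- tibble::tibble(grade = c("A", "B", "C", "D"))
  for (s in names(scopes)) body[[s]] <- pct_for(scopes[[s]])
  denoms <- tibble::tibble(grade = "n_families")
  for (s in names(scopes)) denoms[[s]] <- length(scopes[[s]])
  dplyr::bind_rows(body, denoms)
}

#' Sequences-per-BIN and BINs-per-species distributions
#'
#' Histogram summaries of library depth: how many BINs are represented by a
#' given number of sequences (overall, restricted to species-identified
#' BINs, and per realm), how many species are represented by a given number
#' of BINs (per realm), and top-N lists of the deepest BINs and the most
#' BIN-rich species.
#'
#' @param bins Realm-assigned BIN tibble.
#' @param records Curated record tibble.
#' @param species Species grade tibble from [grade_table()]`$species`.
#' @param top_n Length of the top lists (default 10).
#' @return List with `seqs_per_bin` (tibble: `scope`, `realm`,
#'   `n_sequences`, `n_bins`), `bins_per_species` (tibble: `realm`,
#'   `n_bins`, `n_species`), `top_bins`, `top_species`.
#' @export
distribution_summaries <- function(bins, records, species, top_n = 10L) {
  counts <- table(factor(records$bin_uri[!is.na(records$bin_uri)], levels = bins$bin_uri))
  per_bin <- tibble::tibble(
    bin_uri = bins$bin_uri,
    realm = as.character(bins$realm),
    species_level = !is.na(bins$consensus_level) & bins$consensus_level == "species",
    species = bins$species,
    n_sequences = as.integer(counts)
  )
  hist_of <- function(df, scope, realm) {
    if (nrow(df) == 0L) return(tibble::tibble(scope = character(), realm = character(),
                                              n_sequences = integer(), n_bins = integer()))
    tab <- table(df$n_sequences)
    tibble::tibble(scope = scope, realm = realm,
                   n_sequences = as.integer(names(tab)), n_bins = as.integer(tab))
  }
  realms <- c("overall", setdiff(unique(per_bin$realm), NA))
  seqs_per_bin <- dplyr::bind_rows(lapply(realms, function(r) {
    sel <- if (r == "overall") per_bin else per_bin[per_bin$realm == r, ]
    dplyr::bind_rows(hist_of(sel, "all_bins", r),
                     hist_of(sel[sel$species_level, ], "species_bins", r))
  }))

  sp_bins <- per_bin[per_bin$species_level & !is.na(per_bin$species), ]
  bins_per_species <- dplyr::bind_rows(lapply(c("overall", setdiff(unique(sp_bins$realm), NA)),
    function(r) {
      sel <- if (r == "overall") sp_bins else sp_bins[sp_bins$realm == r, ]
      if (nrow(sel) == 0L) return(NULL)
      nb <- table(table(sel$species))
      tibble::tibble(realm = r, n_bins = as.integer(names(nb)), n_species = as.integer(nb))
    }))

  top_bins <- per_bin |>
    dplyr::arrange(dplyr::desc(.data$n_sequences), .data$bin_uri) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::select("bin_uri", "species", "realm", "n_sequences")
  top_species <- species |>
    dplyr::arrange(dplyr::desc(.data$n_bins), .data$canonical_name) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::select("canonical_name", "realms", "n_bins", "n_sequences")

  list(seqs_per_bin = seqs_per_bin, bins_per_species = bins_per_species,
       top_bins = top_bins, top_species = top_species)
}

#' Identification-level breakdown for records and BINs
#'
#' Six-way breakdown (order, family, subfamily, genus, temporary, species)
#' of identification levels, for BINs at their consensus level and for
#' records at the consensus level of their BIN (the most detailed
#' identification within a BIN is taken to apply to all its records),
#' overall and per realm.
#'
#' @param records Curated record tibble.
#' @param bins Realm-assigned BIN tibble.
#' @return Tibble with columns `scope` (`records`/`bins`), `realm`
#'   (including `"overall"`), `level`, `n`, `fraction`.
#' @export
identification_level_summary <- function(records, bins) {
  idx <- match(records$bin_uri, bins$bin_uri)
  rec <- tibble::tibble(level = bins$consensus_level[idx], realm = as.character(bins$realm)[idx])
  rec <- rec[!is.na(rec$level), ]
  bin <- tibble::tibble(level = bins$consensus_level, realm = as.character(bins$realm))

  breakdown <- function(df, scope, realm) {
    sel <- if (realm == "overall") df else df[df$realm == realm, ]
    tab <- table(factor(sel$level, levels = ID_LEVELS))
    tibble::tibble(scope = scope, realm = realm, level = id_level_factor(names(tab)),
                   n = as.integer(tab),
                   fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab) else 0)
  }
  realms <- c("overall", REALM_LEVELS)
  dplyr::bind_rows(
    lapply(realms, function(r) breakdown(rec, "records", r)),
    lapply(realms, function(r) breakdown(bin, "bins", r))
  )
}
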