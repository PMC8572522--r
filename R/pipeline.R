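#' Run the full reference-library audit
#'
#' Chains every stage of the audit on in-memory inputs: record curation,
#' BIN consensus resolution, realm assignment, species grading, checklist
#' coverage, distribution summaries and geographic completeness. Realm-
#' unassigned BINs (and their records) take part in the initial realm
#' tallies but are excluded from grading and coverage.
#'
#' @param records Record tibble (e.g. from [read_bold_tsv()]).
#' @param checklist Accepted-names tibble (e.g. from [read_checklist()]).
#' @param habitat_map Taxon-to-realm tibble (e.g. from
#'   [read_habitat_map()]).
#' @param geo_hints Optional geographic hint table, see [assign_realms()].
#' @param curation A [curation_config()].
#' @param policy A [resolution_policy()].
#' @return Named list of output tables, suitable for
#'   [write_audit_tables()]: `curated_records`, `removal_log`, `bins`,
#'   `bin_conflicts`, `demotions`, `realm_tallies`, `species_grades`,
#'   `grade_summary`, `family_coverage`, `richness_rollup`,
#'   `grade_by_category`, `unmatched_names`, `id_level_summary`,
#'   `geo_completeness`, `country_tally`, `seqs_per_bin`,
#'   `bins_per_species`, and `run_summary` (list).
#' @export
run_audit <- function(records, checklist, habitat_map, geo_hints = NULL,
                      curation = curation_config(), policy = resolution_policy()) {
  cur <- curate_records(records, curation)
  res <- resolve_bins(cur$curated, policy)
  bins <- assign_realms(res$bins, habitat_map, geo_hints, cur$curated)
  tallies <- realm_tallies(bins, cur$curated)

  assigned_bins <- bins[as.character(bins$realm) != "unassigned", ]
  assigned_records <- cur$curated[cur$curated$bin_uri %in% assigned_bins$bin_uri, ]

  grades <- grade_table(assigned_bins, assigned_records, res$demotions)
  match <- match_to_checklist(grades$species, checklist)
  cov <- family_coverage_table(match$matched, checklist, assigned_bins)
  gcp <- grade_category_presence(match$matched, cov$families)
  dist <- distribution_summaries(assigned_bins, assigned_records, grades$species)
  idlev <- identification_level_summary(assigned_records, assigned_bins)
  geo <- geo_completeness(cur$curated, bins)
  ctry <- per_country_tally(cur$curated, bins)

  run_summary <- list(
    n_input_records = nrow(records),
    n_curated_records = nrow(cur$curated),
    removals_by_stage = as.list(setNames(cur$stage_counts$n_removed, cur$stage_counts$stage)),
    n_bins = nrow(bins),
    n_bins_unassigned = sum(as.character(bins$realm) == "unassigned"),
    n_records_unassigned = nrow(cur$curated) - nrow(assigned_records),
    n_species_graded = nrow(grades$species),
    n_species_matched = nrow(match$matched),
    n_unmatched_names = length(match$unmatched_names),
    grade_counts = as.list(grades$summary[grades$summary$scope == "all",
                                          c("A", "B", "C", "D", "E")])
  )

  list(
    curated_records = cur$curated,
    removal_log = cur$removal_log,
    duplicate_pairs = cur$pairs,
    bins = bins,
    bin_conflicts = res$conflicts,
    demotions = res$demotions,
    realm_tallies = tallies,
    species_grades = grades$species,
    grade_summary = grades$summary,
    family_coverage = cov$families,
    richness_rollup = cov$rollup,
    category_rollup = cov$category_rollup,
    pseudo_families = cov$pseudo_families,
    grade_by_category = gcp,
    unmatched_names = match$unmatched_names,
    id_level_summary = idlev,
    geo_completeness = geo,
    country_tally = ctry$tally,
    seqs_per_bin = dist$seqs_per_bin,
    bins_per_species = dist$bins_per_species,
    top_bins = dist$top_bins,
    top_species = dist$top_species,
    run_summary = run_summary
  )
}
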