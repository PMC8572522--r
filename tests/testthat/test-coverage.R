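rl <- function(x) factor(x, levels = c("marine", "freshwater", "terrestrial", "unassigned"))

mk_bins <- function(bin_uri, level, species = NA_character_, genus = NA_character_,
                    family = NA_character_, realm = "marine") {
  tibble::tibble(bin_uri = bin_uri, n_records = 1L, order = "Amphipoda",
                 family = family, subfamily = NA_character_, genus = genus,
                 species = species, consensus_level = level,
                 conflict_flag = FALSE, n_demoted = 0L, resolution_note = "",
                 realm = rl(realm))
}

mk_checklist <- function(names, families) {
  tibble::tibble(canonical_name = names, authority = NA_character_,
                 family = families, status = "accepted")
}

test_that("richness categories honour the stated family-size boundaries", {
  expect_equal(as.character(richness_category(c(1, 10, 11, 30, 31, 100, 101, 500))),
               c("low", "low", "moderate", "moderate", "rich", "rich",
                 "very_rich", "very_rich"))
})

test_that("checklist matching is exact, with misspellings reported rather than dropped", {
  species <- tibble::tibble(canonical_name = c("Gammarus balcanicus", "Gammarus balcanicuss"),
                            grade = c("A", "B"))
  checklist <- mk_checklist("Gammarus balcanicus", "Gammaridae")
  res <- match_to_checklist(species, checklist)
  expect_equal(res$matched$canonical_name, "Gammarus balcanicus")
  expect_equal(res$matched$family, "Gammaridae")
  expect_equal(res$unmatched_names, "Gammarus balcanicuss")

  res2 <- match_to_checklist(species, checklist[0, ])
  expect_equal(nrow(res2$matched), 0L)
  expect_equal(length(res2$unmatched_names), 2L)
})

test_that("family coverage percentages, bands and category roll-ups follow the table rules", {
  checklist <- mk_checklist(
    c(sprintf("Alpha sp%02d", 1:2),      # 2 accepted, 1 barcoded -> 50%
      "Mono typica",                     # monotypic, barcoded -> 100%
      sprintf("Big sp%03d", 1:120),      # very rich, 6 barcoded -> 5%
      sprintf("Empty sp%02d", 1:4)),     # no coverage
    c(rep("Alphaidae", 2), "Monotypidae", rep("Bigidae", 120), rep("Emptyidae", 4))
  )
  matched <- tibble::tibble(
    canonical_name = c("Alpha sp01", "Mono typica", sprintf("Big sp%03d", 1:6)),
    grade = c("A", "D", rep("B", 6)),
    family = c("Alphaidae", "Monotypidae", rep("Bigidae", 6))
  )
  bins <- mk_bins(c("BOLD:CVG0001", "BOLD:CVG0002"), c("genus", "family"),
                  genus = c("Emptygenus", NA), family = c("Emptyidae", "Ghostidae"))
  cov <- family_coverage_table(matched, checklist, bins)

  fam <- cov$families
  expect_equal(fam$pct_coverage[fam$family == "Alphaidae"], 50)
  expect_equal(fam$pct_coverage[fam$family == "Monotypidae"], 100)
  expect_equal(as.character(fam$category[fam$family == "Bigidae"]), "very_rich")
  expect_equal(as.character(fam$coverage_band[fam$family == "Bigidae"]), "<=10%")
  expect_true(fam$has_genus_level_bins[fam$family == "Emptyidae"])

  expect_equal(sum(cov$rollup$n_families), nrow(fam))
  expect_equal(cov$rollup$n_zero_with_genus_bins[cov$rollup$coverage_band == "0%"], 1L)
  expect_equal(cov$pseudo_families$family, "Ghostidae")

  cat_low <- cov$category_rollup[cov$category_rollup$category == "low", ]
  # represented low families: Alphaidae (50%) and Monotypidae (100%)
  expect_equal(cat_low$n_families_represented, 2L)
  expect_equal(cat_low$mean_coverage_represented, 75)
})

test_that("mean coverage ignores unrepresented families entirely", {
  checklist <- mk_checklist(
    c("Rep res", sprintf("Unrep sp%02d", 1:5)),
    c("Repidae", rep("Unrepidae", 5))
  )
  matched <- tibble::tibble(canonical_name = "Rep res", grade = "D", family = "Repidae")
  base <- family_coverage_table(matched, checklist)$category_rollup
  # grow the unrepresented family tenfold: represented-only means cannot move
  checklist2 <- mk_checklist(
    c("Rep res", sprintf("Unrep sp%02d", 1:50)),
    c("Repidae", rep("Unrepidae", 50))
  )
  grown <- family_coverage_table(matched, checklist2)$category_rollup
  expect_equal(base$mean_coverage_represented[base$category == "low"],
               grown$mean_coverage_represented[grown$category == "low"])
})

test_that("grade presence percentages count families once per grade within their category", {
  checklist <- mk_checklist(c("Aa aa", "Bb bb"), c("Aidae", "Bidae"))
  matched <- tibble::tibble(canonical_name = c("Aa aa", "Bb bb"),
                            grade = factor(c("A", "D"), levels = c("A", "B", "C", "D", "E")),
                            family = c("Aidae", "Bidae"))
  fam <- family_coverage_table(matched, checklist)$families
  pres <- grade_category_presence(matched, fam)
  expect_equal(pres$all[pres$grade == "A"], 50)
  expect_equal(pres$all[pres$grade == "D"], 50)
  expect_equal(pres$all[pres$grade == "B"], 0)
  expect_equal(pres$all[pres$grade == "n_families"], 2)

  only_d <- dplyr::mutate(matched, grade = factor("D", levels = levels(matched$grade)))
  pres_d <- grade_category_presence(only_d, fam)
  expect_equal(pres_d$all[pres_d$grade == "D"], 100)
  expect_equal(pres_d$all[pres_d$grade %in% c("A", "B", "C")], c(0, 0, 0))
})

test_that("depth histograms carry the full BIN and species mass", {
  bins <- mk_bins(sprintf("BOLD:HST%04d", 1:3), "species",
                  species = c("Aa aa", "Aa aa", "Bb bb"),
                  genus = c("Aa", "Aa", "Bb"), family = "Histidae")
  records <- barcode_records(
    record_id = sprintf("h%d", 1:7),
    bin_uri = c("BOLD:HST0001", "BOLD:HST0002", rep("BOLD:HST0003", 5)),
    order = "Amphipoda", species = c("Aa aa", "Aa aa", rep("Bb bb", 5))
  )
  species <- grade_table(bins, records)$species
  dist <- distribution_summaries(bins, records, species)
  overall <- dist$seqs_per_bin[dist$seqs_per_bin$scope == "all_bins" &
                                 dist$seqs_per_bin$realm == "overall", ]
  expect_equal(overall$n_bins[overall$n_sequences == 1], 2L)
  expect_equal(overall$n_bins[overall$n_sequences == 5], 1L)
  expect_equal(sum(overall$n_bins), nrow(bins))
  bps <- dist$bins_per_species[dist$bins_per_species$realm == "overall", ]
  expect_equal(bps$n_species[bps$n_bins == 1], 1L)   # Bb bb
  expect_equal(bps$n_species[bps$n_bins == 2], 1L)   # Aa aa
  expect_equal(sum(bps$n_species), nrow(species))
  expect_equal(dist$top_bins$bin_uri[1], "BOLD:HST0003")
  expect_equal(dist$top_species$canonical_name[1], "Aa aa")
})

test_that("identification-level shares count records at their BIN's consensus level", {
  bins <- dplyr::bind_rows(
    mk_bins("BOLD:LVL0001", "species", species = "Aa aa", genus = "Aa", family = "Lidae"),
    mk_bins("BOLD:LVL0002", "genus", genus = "Bb", family = "Lidae"),
    mk_bins("BOLD:LVL0003", "order")
  )
  records <- barcode_records(
    record_id = sprintf("l%d", 1:4),
    bin_uri = c("BOLD:LVL0001", "BOLD:LVL0001", "BOLD:LVL0002", "BOLD:LVL0003"),
    order = "Amphipoda",
    genus = c("Aa", NA, "Bb", NA),
    species = c("Aa aa", NA, NA, NA)
  )
  lv <- identification_level_summary(records, bins)
  rec_overall <- lv[lv$scope == "records" & lv$realm == "overall", ]
  expect_equal(rec_overall$fraction[rec_overall$level == "species"], 0.5)
  expect_equal(rec_overall$fraction[rec_overall$level == "genus"], 0.25)
  expect_equal(rec_overall$fraction[rec_overall$level == "order"], 0.25)
  expect_equal(sum(rec_overall$n), nrow(records))
  bin_overall <- lv[lv$scope == "bins" & lv$realm == "overall", ]
  expect_equal(sum(bin_overall$n), nrow(bins))
  # the mixed two-record BIN contributes once, at species level
  expect_equal(bin_overall$n[bin_overall$level == "species"], 1L)
})

test_that("planted identification-level mix is recovered from generator ground truth", {
  lib <- generate_library(small_sim(seed = 31L))
  cur <- curate_records(lib$records)
  res <- resolve_bins(cur$curated)
  bins <- assign_realms(res$bins, lib$habitat_map, lib$geo_hints, cur$curated)
  lv <- identification_level_summary(cur$curated, bins)
  got <- lv[lv$scope == "bins" & lv$realm == "overall", ]
  planted <- table(factor(lib$ground_truth$bins$consensus_level,
                          levels = as.character(got$level)))
  expect_equal(got$n, as.integer(planted[as.character(got$level)]))
})
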