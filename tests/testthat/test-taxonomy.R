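test_that("identification levels follow the binomial / open-nomenclature / temporary rules", {
  records <- barcode_records(
    record_id = sprintf("r%d", 1:7),
    order = "Amphipoda",
    family = c(rep("Gammaridae", 5), "Epimeriidae", NA),
    genus = c("Gammarus", "Gammarus", "Niphargus", NA, "Gammarus", "Epimeria", NA),
    species = c("Gammarus oceanicus", "Gammarus cf. fossarum", NA, NA,
                "Gammarus sp.", "Epimeria sp. 2", NA)
  )
  lv <- classify_identification(records)
  expect_equal(as.character(lv),
               c("species", "species", "genus", "family", "temporary", "temporary", "order"))

  # the open-nomenclature switch demotes cf./aff. names to temporary
  lv2 <- classify_identification(records, cf_as_species = FALSE)
  expect_equal(as.character(lv2)[2], "temporary")

  none <- barcode_records(record_id = "x")
  expect_error(classify_identification(none), "unidentifiable")
})

test_that("canonical names strip authority, subgenus and open-nomenclature qualifiers", {
  res <- canonical_species_name(c(
    "Gammarus balcanicus Schaferna, 1923",
    "Gammarus cf. balcanicus",
    "Gammarus (Rivulogammarus) balcanicus",
    "Diporeia hoyi (S.I. Smith, 1874)",
    "Orchestoidea aff. tuberculata Nicolet, 1849"
  ))
  expect_equal(res$canonical_name,
               c("Gammarus balcanicus", "Gammarus balcanicus", "Gammarus balcanicus",
                 "Diporeia hoyi", "Orchestoidea tuberculata"))
  expect_equal(res$open_nomenclature, c(FALSE, TRUE, FALSE, FALSE, TRUE))

  expect_warning(bare <- canonical_species_name("Gammarus"), "could not be parsed")
  expect_true(is.na(bare$canonical_name))
})

test_that("a unanimous BIN propagates its species to all members, whatever their own level", {
  mixed <- barcode_records(
    record_id = c("m1", "m2", "m3"), bin_uri = "BOLD:AAA1473",
    order = "Amphipoda",
    family = c("Pontoporeiidae", NA, NA),
    genus = c("Diporeia", "Diporeia", NA),
    species = c("Diporeia hoyi", NA, NA)
  )
  res <- resolve_bins(mixed)
  expect_equal(nrow(res$bins), 1L)
  expect_equal(res$bins$species, "Diporeia hoyi")
  expect_equal(res$bins$consensus_level, "species")
  expect_false(res$bins$conflict_flag)
  expect_equal(nrow(res$demotions), 0L)
})

test_that("a lone outlier against a clear congeneric majority is demoted to genus", {
  bin <- dplyr::bind_rows(
    species_bin("BOLD:MAJ0001", "Gammarus oceanicus", 9, id_prefix = "maj"),
    species_bin("BOLD:MAJ0001", "Gammarus fossarum", 1, id_prefix = "out")
  )
  res <- resolve_bins(bin)
  expect_equal(res$bins$species, "Gammarus oceanicus")
  expect_equal(res$bins$consensus_level, "species")
  expect_equal(nrow(res$demotions), 1L)
  expect_equal(res$demotions$record_id, "out_1")
  expect_equal(res$demotions$demoted_to, "genus")
  expect_false(res$bins$conflict_flag)
})

test_that("a balanced conflict falls back to the congruent rank and is flagged", {
  bin <- dplyr::bind_rows(
    species_bin("BOLD:TIE0001", "Gammarus oceanicus", 2, id_prefix = "a"),
    species_bin("BOLD:TIE0001", "Gammarus fossarum", 2, id_prefix = "b")
  )
  res <- resolve_bins(bin)
  expect_equal(res$bins$consensus_level, "genus")
  expect_equal(res$bins$genus, "Gammarus")
  expect_true(is.na(res$bins$species))
  expect_true(res$bins$conflict_flag)

  # different genera, same family: congruence climbs to family
  other <- dplyr::bind_rows(
    species_bin("BOLD:TIE0002", "Gammarus oceanicus", 2, id_prefix = "c"),
    species_bin("BOLD:TIE0002", "Niphargus aquilex", 2, id_prefix = "d")
  )
  res2 <- resolve_bins(other)
  expect_equal(res2$bins$consensus_level, "family")
})

test_that("a trusted identifier settles a conflict the majority rule cannot", {
  bin <- dplyr::bind_rows(
    species_bin("BOLD:TRU0001", "Gammarus oceanicus", 2, id_prefix = "a",
                identifier = "A. Specialist"),
    species_bin("BOLD:TRU0001", "Gammarus fossarum", 2, id_prefix = "b",
                identifier = "Monitoring pipeline")
  )
  pol <- resolution_policy(trusted_identifiers = "a. specialist")
  res <- resolve_bins(bin, pol)
  expect_equal(res$bins$species, "Gammarus oceanicus")
  expect_false(res$bins$conflict_flag)
  expect_match(res$bins$resolution_note, "trusted")

  # both names trusted: no decision, fall through to congruent rank
  pol2 <- resolution_policy(trusted_identifiers = c("a. specialist", "monitoring pipeline"))
  expect_equal(resolve_bins(bin, pol2)$bins$consensus_level, "genus")
})

test_that("a singleton identified to order resolves to order level without conflict", {
  single <- barcode_records(record_id = "s1", bin_uri = "BOLD:SGL0001",
                            order = "Amphipoda")
  res <- resolve_bins(single)
  expect_equal(res$bins$consensus_level, "order")
  expect_false(res$bins$conflict_flag)
  expect_match(res$bins$resolution_note, "singleton")
})

test_that("BIN resolution is invariant under every ordering of the member records", {
  cases <- list(
    unanimous = species_bin("BOLD:PRM0001", "Gammarus oceanicus", 5, id_prefix = "u"),
    outlier = dplyr::bind_rows(
      species_bin("BOLD:PRM0002", "Gammarus oceanicus", 4, id_prefix = "m"),
      species_bin("BOLD:PRM0002", "Gammarus fossarum", 1, id_prefix = "o")
    ),
    tie = dplyr::bind_rows(
      species_bin("BOLD:PRM0003", "Gammarus oceanicus", 2, id_prefix = "x"),
      species_bin("BOLD:PRM0003", "Gammarus fossarum", 2, id_prefix = "y")
    )
  )
  for (nm in names(cases)) {
    bin <- cases[[nm]]
    ref <- resolve_bins(bin)
    for (p in all_perms(nrow(bin))) {
      res <- resolve_bins(bin[p, ])
      expect_equal(res$bins, ref$bins, info = nm)
      expect_equal(dplyr::arrange(res$demotions, record_id),
                   dplyr::arrange(ref$demotions, record_id), info = nm)
    }
  }
})

test_that("consensus is never less detailed than the congruent information of its members", {
  lib <- generate_library(small_sim(seed = 9L))
  cur <- curate_records(lib$records)
  res <- resolve_bins(cur$curated)
  lv <- classify_identification(cur$curated)
  member_best <- tapply(as.integer(lv), cur$curated$bin_uri, max)
  consensus_lv <- setNames(match(res$bins$consensus_level, levels(lv)), res$bins$bin_uri)
  demoted <- unique(res$demotions$bin_uri)
  flagged <- res$bins$bin_uri[res$bins$conflict_flag]
  plain <- setdiff(res$bins$bin_uri, c(demoted, flagged))
  # without conflicts the consensus carries the deepest member information
  expect_true(all(consensus_lv[plain] == member_best[plain]))
})
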