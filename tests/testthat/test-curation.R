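test_that("sequence metrics exclude gaps and count every non-ACGT base as ambiguous", {
  m <- sequence_metrics(c(
    clean_seq(600),
    paste0(clean_seq(594), strrep("N", 6)),
    "ACGT----ACGT",
    paste0(clean_seq(100), "RYWS")
  ))
  expect_equal(m$effective_length, c(600L, 600L, 8L, 104L))
  expect_equal(m$ambiguous_fraction, c(0, 6 / 600, 0, 4 / 104))
  expect_error(sequence_metrics("----"), "degenerate")
})

test_that("marker filter partitions records exactly and matches case-insensitively", {
  records <- rec(sprintf("r%d", 1:10),
                 marker = c(rep("COI-5P", 2), rep("coi-5p", 2), rep("16S", 5), NA))
  res <- filter_marker(records, curation_config())
  expect_equal(nrow(res$kept), 4L)
  expect_equal(nrow(res$removed), 6L)
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(records))
  expect_equal(res$log$record_id, res$removed$record_id)
  expect_true(all(res$log$stage == "marker"))
})

test_that("quality filter applies the documented boundary semantics", {
  records <- barcode_records(
    record_id = c("short499", "exact500", "amb_exact1pct", "amb_over1pct",
                  "no_bin", "clean"),
    marker = "COI-5P",
    bin_uri = c(rep("BOLD:TEST001", 4), NA, "BOLD:TEST001"),
    sequence = c(clean_seq(499), clean_seq(500),
                 paste0(clean_seq(594), strrep("N", 6)),     # exactly 1%
                 paste0(clean_seq(593), strrep("N", 7)),     # just above 1%
                 clean_seq(650), clean_seq(650))
  )
  res <- filter_qc(records, curation_config())
  expect_setequal(res$kept$record_id, c("exact500", "amb_exact1pct", "clean"))
  expect_setequal(res$removed$record_id, c("short499", "amb_over1pct", "no_bin"))
  reasons <- setNames(res$log$reason, res$log$record_id)
  expect_match(reasons[["short499"]], "499 bp")
  expect_match(reasons[["no_bin"]], "no BIN")
  expect_match(reasons[["amb_over1pct"]], "ambiguous")
})

test_that("a record failing several QC clauses is logged once with every clause named", {
  records <- barcode_records(record_id = "multi", marker = "COI-5P",
                             bin_uri = NA, sequence = paste0(clean_seq(200), "NNNNNN"))
  res <- filter_qc(records, curation_config())
  expect_equal(nrow(res$log), 1L)
  expect_match(res$log$reason, "no BIN")
  expect_match(res$log$reason, "bp")
  expect_match(res$log$reason, "ambiguous")
})

test_that("the '.1' duplicate rule keeps the geographically richer member, with ties going to '.1'", {
  pair <- barcode_records(
    record_id = c("a", "b"),
    sample_id = c("KP713892", "KP713892.1"),
    marker = "COI-5P", bin_uri = "BOLD:TEST001", sequence = clean_seq(),
    species = "Gammarus oceanicus", genus = "Gammarus",
    lat = c(NA, 54.5), lon = c(NA, 18.7), country = c("Poland", NA)
  )
  res <- collapse_duplicates(pair)
  expect_equal(res$kept$record_id, "b")     # coordinates beat country
  expect_equal(res$removed$record_id, "a")
  expect_equal(nrow(res$pairs), 1L)

  # reversed detail: plain member has coordinates and wins
  rev <- pair
  rev$lat <- c(54.5, NA); rev$lon <- c(18.7, NA); rev$country <- c(NA, "Poland")
  expect_equal(collapse_duplicates(rev)$kept$record_id, "a")

  # equal detail: keep the '.1' record
  tie <- pair
  tie$lat <- c(NA, NA); tie$lon <- c(NA, NA); tie$country <- c(NA, NA)
  expect_equal(collapse_duplicates(tie)$kept$record_id, "b")
})

test_that("records with differing identifications never form a duplicate pair", {
  notpair <- barcode_records(
    record_id = c("a", "b"), sample_id = c("X1", "X1.1"),
    marker = "COI-5P", bin_uri = "BOLD:TEST001", sequence = clean_seq(),
    species = c("Gammarus oceanicus", "Gammarus fossarum")
  )
  res <- collapse_duplicates(notpair)
  expect_equal(nrow(res$kept), 2L)
  expect_equal(nrow(res$pairs), 0L)

  # a rank absent on one side does not break the match
  ragged <- notpair
  ragged$species <- c("Gammarus oceanicus", NA)
  ragged$genus <- c("Gammarus", "Gammarus")
  expect_equal(nrow(collapse_duplicates(ragged)$pairs), 1L)
})

test_that("suffix triples are left uncollapsed with a warning, and disjoint pairs collapse one record each", {
  triple <- barcode_records(
    record_id = c("t1", "t2", "t3"), sample_id = c("Y1", "Y1.1", "Y1.2"),
    marker = "COI-5P", bin_uri = "BOLD:TEST001", sequence = clean_seq(),
    species = "Gammarus oceanicus"
  )
  expect_warning(res <- collapse_duplicates(triple), "uncollapsed")
  expect_equal(nrow(res$kept), 3L)

  many <- barcode_records(
    record_id = sprintf("r%d", 1:10),
    sample_id = c("A1", "A1.1", "B2", "B2.1", "C3", "C3.1", "D4", "E5", "F6", "G7"),
    marker = "COI-5P", bin_uri = "BOLD:TEST001", sequence = clean_seq(),
    species = "Gammarus oceanicus"
  )
  res <- collapse_duplicates(many)
  expect_equal(nrow(res$pairs), 3L)
  expect_equal(nrow(res$kept), 7L)
  expect_equal(nrow(res$removed), 3L)
})

test_that("explicit exclusions match record or sample IDs and warn on IDs absent from the data", {
  records <- barcode_records(
    record_id = c("r1", "r2", "r3"), sample_id = c("KR858496", "S2", "S3"),
    marker = "COI-5P", bin_uri = "BOLD:ADD1128", sequence = clean_seq()
  )
  cfg <- curation_config(exclusion_ids = c(KR858496 = "sequence withdrawn by submitter"))
  res <- apply_exclusions(records, cfg)
  expect_equal(res$removed$record_id, "r1")
  expect_equal(res$log$reason, "sequence withdrawn by submitter")

  cfg2 <- curation_config(exclusion_ids = c(NOPE = "missing"))
  expect_warning(res2 <- apply_exclusions(records, cfg2), "not found")
  expect_equal(nrow(res2$kept), 3L)

  res3 <- apply_exclusions(records, curation_config())
  expect_equal(res3$kept, records)
})

test_that("curation conserves records at every stage, logs removals bijectively, and is a fixed point", {
  lib <- generate_library(small_sim(seed = 3L))
  cur <- curate_records(lib$records)
  expect_equal(nrow(lib$records), nrow(cur$curated) + nrow(cur$removal_log))
  expect_setequal(cur$removal_log$record_id, cur$removed$record_id)
  expect_equal(anyDuplicated(cur$removal_log$record_id), 0L)
  with(cur$stage_counts, expect_equal(n_in, n_kept + n_removed))

  again <- curate_records(cur$curated)
  expect_equal(nrow(again$removal_log), 0L)
  expect_equal(again$curated, cur$curated)
})
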