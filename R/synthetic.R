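#' Configuration for the synthetic-library generator
#'
#' Bundles every knob of [generate_library()]. The defaults emulate the
#' statistical structure of the global amphipod COI library: a heavy-tailed
#' family-size law populating all four richness categories, a
#' singleton-dominated zero-truncated geometric sequences-per-species law,
#' about a third of species split over several BINs, occasional congeneric
#' BIN sharing and single-record misidentifications, realm-dependent
#' identification loss (marine worse than freshwater) and geographic
#' completeness, GenBank-style `.1` duplicate pairs, and a fraction of
#' records that fail the quality screen (short or ambiguous sequence, no
#' BIN).
#'
#' `qc_fail_rate`, `nontarget_marker_rate` and `dup_rate` are fractions
#' relative to the clean curated record count; the exact planted counts are
#' recorded in the generator's ground truth.
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical output.
#' @param n_families Number of checklist families.
#' @param family_size_law List `(meanlog, sdlog)` of the lognormal species
#'   counts per family (ceiled, minimum 1).
#' @param n_species_sampled Number of checklist species that receive
#'   barcode records.
#' @param realm_mix Named probabilities over marine/freshwater/terrestrial;
#'   realms are assigned per family so that habitat lookups at any rank are
#'   consistent.
#' @param seqs_per_species_law List `(prob)`: records per species are
#'   `1 + Geometric(prob)`, so `prob` is the singleton probability.
#' @param p_split Probability a species is split across several BINs.
#' @param split_k_law List `(prob)`: number of BINs for a split species is
#'   `2 + Geometric(prob)` (capped at the record count).
#' @param p_merge Probability that a candidate pair of congeneric species
#'   shares one BIN.
#' @param id_loss Per-realm named vectors of probabilities that a species'
#'   whole identification is truncated to `genus`, `subfamily`, `family`,
#'   `order`, or replaced by a `temporary` name; the remainder keeps its
#'   species name. Identification capacity is modelled per species.
#' @param p_coords,p_country_only Per-realm probabilities that a record has
#'   coordinates, or country only; the rest have neither.
#' @param dup_rate Fraction of records duplicated under the `.1` rule.
#' @param qc_fail_rate Fraction of records planted with a failing sequence
#'   and no BIN.
#' @param nontarget_marker_rate Fraction of records planted with a
#'   non-target marker code.
#' @param misid_rate Probability that one record in a sufficiently large
#'   BIN gets a wrong congeneric species name.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_families = 239L,
    family_size_law = list(meanlog = 2.3, sdlog = 1.8),
    n_species_sampled = 1000L,
    realm_mix = c(marine = 0.50, freshwater = 0.45, terrestrial = 0.05),
    seqs_per_species_law = list(prob = 0.55),
    p_split = 0.3,
    split_k_law = list(prob = 0.6),
    p_merge = 0.02,
    id_loss = list(
      marine      = c(genus = 0.12, subfamily = 0.005, family = 0.08, order = 0.15, temporary = 0.10),
      freshwater  = c(genus = 0.06, subfamily = 0.002, family = 0.02, order = 0.02, temporary = 0.04),
      terrestrial = c(genus = 0.05, subfamily = 0.002, family = 0.03, order = 0.04, temporary = 0.03)
    ),
    p_coords = c(marine = 0.71, freshwater = 0.47, terrestrial = 0.50),
    p_country_only = c(marine = 0.12, freshwater = 0.28, terrestrial = 0.25),
    dup_rate = 0.05,
    qc_fail_rate = 0.09,
    nontarget_marker_rate = 0.01,
    misid_rate = 0.02) {
  probs <- c(p_split, p_merge, dup_rate, qc_fail_rate, nontarget_marker_rate, misid_rate,
             realm_mix, p_coords, p_country_only,
             seqs_per_species_law$prob, split_k_law$prob, unlist(id_loss))
  stopifnot(all(probs >= 0), all(probs <= 1))
  stopifnot(abs(sum(realm_mix) - 1) < 1e-8)
  stopifnot(all(vapply(id_loss, sum, numeric(1L)) < 1))
  stopifnot(n_families >= 1L, n_species_sampled >= 1L)
  structure(
    list(seed = as.integer(seed), n_families = as.integer(n_families),
         family_size_law = family_size_law,
         n_species_sampled = as.integer(n_species_sampled),
         realm_mix = realm_mix, seqs_per_species_law = seqs_per_species_law,
         p_split = p_split, split_k_law = split_k_law, p_merge = p_merge,
         id_loss = id_loss, p_coords = p_coords, p_country_only = p_country_only,
         dup_rate = dup_rate, qc_fail_rate = qc_fail_rate,
         nontarget_marker_rate = nontarget_marker_rate, misid_rate = misid_rate),
    class = "simulation_config"
  )
}

# Pronounceable synthetic names, guaranteed unique within a generator run
# and (by construction) never colliding with real taxa.
name_factory <- function() {
  used <- new.env(parent = emptyenv())
  cons <- c("br", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v", "z", "th", "cr")
  vow <- c("a", "e", "i", "o", "u", "ae", "ia")
  function(n_syll = 3L, capitalize = TRUE) {
    repeat {
      s <- paste0(vapply(seq_len(n_syll), function(i)
        paste0(sample(cons, 1L), sample(vow, 1L)), character(1L)), collapse = "")
      if (capitalize) s <- paste0(toupper(substr(s, 1L, 1L)), substr(s, 2L, nchar(s)))
      if (!exists(s, envir = used)) {
        assign(s, TRUE, envir = used)
        return(s)
      }
    }
  }
}

random_sequence <- function(len, n_ambiguous = 0L) {
  base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (n_ambiguous > 0L) base[sample.int(len, n_ambiguous)] <- "N"
  paste(base, collapse = "")
}

new_bin_factory <- function() {
  used <- new.env(parent = emptyenv())
  alphabet <- c(LETTERS, 0:9)
  function() {
    repeat {
      b <- paste0("BOLD:", paste(sample(alphabet, 7L, replace = TRUE), collapse = ""))
      if (!exists(b, envir = used)) {
        assign(b, TRUE, envir = used)
        return(b)
      }
    }
  }
}

# Country pools per realm, kept disjoint so that the emitted geo-hints table
# resolves a country to exactly one realm.
REALM_COUNTRIES <- list(
  marine = c("Norway", "Iceland", "Japan", "Chile", "Australia", "Portugal"),
  freshwater = c("Poland", "Germany", "Russia", "United States", "Canada", "Ukraine"),
  terrestrial = c("France", "Spain", "China", "New Zealand", "Brazil")
)

ztgeom <- function(n, prob) 1L + rgeom(n, prob)

#' Generate a synthetic barcode library with known ground truth
#'
#' Emits a BOLD-like record table plus a matching species checklist, a
#' taxon-to-realm habitat map and a country-to-realm hint table, together
#' with complete ground truth: each record's curation fate, each BIN's
#' consensus identification and realm, and each species' expected quality
#' grade. Running [curate_records()], [resolve_bins()], [assign_realms()]
#' and [grade_table()] on the generated files recovers the planted truth.
#'
#' Sequences are uniform-random nucleotides: downstream analysis never
#' inspects sequence content beyond length and ambiguity.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, `records.tsv`,
#'   `checklist.csv`, `habitat_map.csv` and `geo_hints.csv` are written
#'   there.
#' @return List with `records`, `checklist`, `habitat_map`, `geo_hints`
#'   (tibbles), `ground_truth` (list of tibbles `records`, `bins`,
#'   `species`, plus planted `counts`), and `config`.
#' @export
generate_library <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nm <- name_factory()
  new_bin <- new_bin_factory()
  order_name <- paste0(nm(3L), "oida")

  ## ---- checklist -------------------------------------------------------
  fam_sizes <- pmax(1L, as.integer(ceiling(rlnorm(config$n_families,
                                                  config$family_size_law$meanlog,
                                                  config$family_size_law$sdlog))))
  families <- vapply(seq_len(config$n_families), function(i) paste0(nm(3L), "idae"), character(1L))
  fam_realm <- sample(names(config$realm_mix), config$n_families,
                      replace = TRUE, prob = config$realm_mix)
  checklist_rows <- vector("list", config$n_families)
  for (i in seq_len(config$n_families)) {
    size <- fam_sizes[[i]]
    n_genera <- max(1L, ceiling(size / 6))
    genera <- vapply(seq_len(n_genera), function(j) nm(3L), character(1L))
    sp_genus <- sample(genera, size, replace = TRUE)
    epithets <- vapply(seq_len(size), function(j) tolower(nm(3L)), character(1L))
    checklist_rows[[i]] <- tibble::tibble(
      canonical_name = paste(sp_genus, epithets),
      authority = paste0(nm(2L), ", ", sample(1850:2019, size, replace = TRUE)),
      family = families[[i]],
      genus = sp_genus,
      status = "accepted",
      realm = fam_realm[[i]]
    )
  }
  species_pool <- dplyr::bind_rows(checklist_rows)
  n_other <- max(2L, round(0.02 * nrow(species_pool)))
  other_rows <- tibble::tibble(
    canonical_name = vapply(seq_len(n_other), function(i) paste(nm(3L), tolower(nm(3L))), character(1L)),
    authority = NA_character_,
    family = sample(families, n_other, replace = TRUE),
    genus = NA_character_, status = "other", realm = NA_character_
  )
  checklist <- dplyr::bind_rows(
    species_pool[c("canonical_name", "authority", "family", "status")],
    other_rows[c("canonical_name", "authority", "family", "status")]
  )

  ## ---- sample species & plant BIN structure ----------------------------
  if (config$n_species_sampled > nrow(species_pool)) {
    rlang::abort("n_species_sampled exceeds the checklist size implied by the family-size law")
  }
  w <- fam_sizes[match(species_pool$family, families)]^(-0.6)
  sampled_idx <- sample.int(nrow(species_pool), config$n_species_sampled, prob = w)
  sp <- species_pool[sampled_idx, ]
  nsp <- nrow(sp)

  loss_tab <- config$id_loss
  ceiling_of <- vapply(seq_len(nsp), function(i) {
    loss <- loss_tab[[sp$realm[[i]]]]
    sample(c("species", names(loss)), 1L, prob = c(1 - sum(loss), loss))
  }, character(1L))
  split <- runif(nsp) < config$p_split
  n_seq <- ztgeom(nsp, config$seqs_per_species_law$prob)
  # a split species needs at least two records; the conditional law given
  # n >= 2 of the zero-truncated geometric is 2 + Geometric(prob)
  n_seq[split] <- 2L + rgeom(sum(split), config$seqs_per_species_law$prob)
  k_bins <- rep(1L, nsp)
  k_bins[split] <- pmin(2L + rgeom(sum(split), config$split_k_law$prob), n_seq[split])

  ## ---- congeneric BIN merges ------------------------------------------
  merged_with <- rep(NA_integer_, nsp)  # index of the partner species
  if (config$p_merge > 0) {
    eligible <- which(!split & ceiling_of == "species")
    by_genus <- split(eligible, sp$genus[eligible])
    by_genus <- by_genus[lengths(by_genus) >= 2L]
    if (length(by_genus) == 0L) {
      rlang::abort("infeasible config: p_merge > 0 but no genus holds two mergeable sampled species")
    }
    for (g in names(by_genus)) {
      idx <- sample(by_genus[[g]])
      n_pairs <- floor(length(idx) / 2)
      for (p in seq_len(n_pairs)) {
        a <- idx[[2 * p - 1]]; b <- idx[[2 * p]]
        if (runif(1L) < config$p_merge) {
          merged_with[[a]] <- b
          merged_with[[b]] <- a
        }
      }
    }
  }

  ## ---- per-bin record plan --------------------------------------------
  identifiers <- vapply(seq_len(20L), function(i) paste0(nm(2L), ", ", toupper(substr(nm(1L), 1L, 1L)), "."),
                        character(1L))
  subfam_of <- function(fam) sub("idae$", "inae", fam)
  temp_counter <- new.env(parent = emptyenv())
  temp_name <- function(genus) {
    k <- (get0(genus, envir = temp_counter) %||% 0L) + 1L
    assign(genus, k, envir = temp_counter)
    paste0(genus, " sp. ", k)
  }

  plan <- list()   # one element per record
  species_bins <- vector("list", nsp)
  shared_done <- rep(FALSE, nsp)
  temp_label <- rep(NA_character_, nsp)
  for (i in seq_len(nsp)) {
    if (ceiling_of[[i]] == "temporary") temp_label[[i]] <- temp_name(sp$genus[[i]])
  }

  add_records <- function(sp_i, bin, n, label_ceiling, allow_ragged = TRUE) {
    rows <- vector("list", n)
    for (r in seq_len(n)) {
      ceiling_r <- label_ceiling
      # intra-BIN ragged identifications: some later records carry less
      # detail than the BIN's best identification (record 1 keeps it all)
      if (allow_ragged && r > 1L && ceiling_r %in% c("species", "temporary") &&
          runif(1L) < 0.1) {
        ceiling_r <- "genus"
      }
      species_field <- NA_character_
      genus_field <- NA_character_
      subfam_field <- NA_character_
      family_field <- NA_character_
      if (ceiling_r == "species") {
        open <- runif(1L) < 0.05
        species_field <- if (open) sub(" ", " cf. ", sp$canonical_name[[sp_i]]) else sp$canonical_name[[sp_i]]
        genus_field <- sp$genus[[sp_i]]
        family_field <- sp$family[[sp_i]]
      } else if (ceiling_r == "temporary") {
        species_field <- temp_label[[sp_i]]
        genus_field <- sp$genus[[sp_i]]
        family_field <- sp$family[[sp_i]]
      } else if (ceiling_r == "genus") {
        genus_field <- sp$genus[[sp_i]]
        family_field <- sp$family[[sp_i]]
      } else if (ceiling_r == "subfamily") {
        subfam_field <- subfam_of(sp$family[[sp_i]])
        family_field <- sp$family[[sp_i]]
      } else if (ceiling_r == "family") {
        family_field <- sp$family[[sp_i]]
      }
      rows[[r]] <- list(sp_i = sp_i, bin = bin, species = species_field,
                        genus = genus_field, subfamily = subfam_field,
                        family = family_field, level = ceiling_r)
    }
    rows
  }

  for (i in seq_len(nsp)) {
    if (!is.na(merged_with[[i]])) {
      if (shared_done[[i]]) next
      j <- merged_with[[i]]
      bin <- new_bin()
      # no ragged identifications in shared BINs: the planted name counts
      # must determine the resolution outcome exactly
      plan <- c(plan, add_records(i, bin, n_seq[[i]], "species", allow_ragged = FALSE),
                add_records(j, bin, n_seq[[j]], "species", allow_ragged = FALSE))
      species_bins[[i]] <- bin
      species_bins[[j]] <- bin
      shared_done[[i]] <- TRUE
      shared_done[[j]] <- TRUE
      next
    }
    bins_i <- vapply(seq_len(k_bins[[i]]), function(k) new_bin(), character(1L))
    species_bins[[i]] <- bins_i
    # every BIN gets at least one record, the rest are spread at random
    assignment <- c(seq_len(k_bins[[i]]),
                    sample.int(k_bins[[i]], n_seq[[i]] - k_bins[[i]], replace = TRUE))
    for (k in seq_len(k_bins[[i]])) {
      plan <- c(plan, add_records(i, bins_i[[k]], sum(assignment == k), ceiling_of[[i]]))
    }
  }

  plan_df <- dplyr::bind_rows(lapply(plan, tibble::as_tibble))
  plan_df$row <- seq_len(nrow(plan_df))

  ## ---- misidentifications ---------------------------------------------
  # one wrong congeneric name planted in sufficiently large unshared BINs
  plan_df$misid <- FALSE
  n_misid_by_sp <- rep(0L, nsp)
  if (config$misid_rate > 0) {
    unshared <- is.na(merged_with[plan_df$sp_i])
    bin_tab <- plan_df[unshared & plan_df$level == "species", ]
    for (b in unique(bin_tab$bin)) {
      members <- bin_tab[bin_tab$bin == b, ]
      if (nrow(members) < 4L) next     # majority of >= 3 must survive one outlier
      if (runif(1L) >= config$misid_rate) next
      sp_i <- members$sp_i[[1L]]
      congeners <- species_pool$canonical_name[
        species_pool$genus == sp$genus[[sp_i]] &
          species_pool$canonical_name != sp$canonical_name[[sp_i]]
      ]
      congeners <- congeners[!is.na(congeners)]
      if (length(congeners) == 0L) next
      victim <- members$row[sample.int(nrow(members) - 1L, 1L) + 1L]  # never record 1
      plan_df$species[plan_df$row == victim] <- sample(congeners, 1L)
      plan_df$misid[plan_df$row == victim] <- TRUE
      n_misid_by_sp[[sp_i]] <- n_misid_by_sp[[sp_i]] + 1L
    }
  }

  ## ---- geography, sequences, identities -------------------------------
  n_clean <- nrow(plan_df)
  realm_of_rec <- sp$realm[plan_df$sp_i]
  geo_class <- vapply(realm_of_rec, function(r) {
    p1 <- config$p_coords[[r]]; p2 <- config$p_country_only[[r]]
    sample(c("coords", "country_only", "neither"), 1L, prob = c(p1, p2, max(0, 1 - p1 - p2)))
  }, character(1L))
  country <- rep(NA_character_, n_clean)
  lat <- rep(NA_real_, n_clean)
  lon <- rep(NA_real_, n_clean)
  for (i in seq_len(n_clean)) {
    r <- realm_of_rec[[i]]
    if (geo_class[[i]] == "coords") {
      lat[[i]] <- round(runif(1L, -60, 70), 4)
      lon[[i]] <- round(runif(1L, -180, 180), 4)
      if (runif(1L) < 0.5) country[[i]] <- sample(REALM_COUNTRIES[[r]], 1L)
    } else if (geo_class[[i]] == "country_only") {
      country[[i]] <- sample(REALM_COUNTRIES[[r]], 1L)
    }
  }

  sid_counter <- 0L
  next_sample_ids <- function(n) {
    # accession-like, globally unique within the run
    letters2 <- vapply(seq_len(n), function(i)
      paste(sample(LETTERS, 2L, replace = TRUE), collapse = ""), character(1L))
    ids <- paste0(letters2, sprintf("%06d", sid_counter + seq_len(n)))
    sid_counter <<- sid_counter + n
    ids
  }
  clean <- tibble::tibble(
    record_id = character(n_clean),
    sample_id = next_sample_ids(n_clean),
    process_id = sprintf("SYN%05d-20", seq_len(n_clean)),
    bin_uri = plan_df$bin,
    marker = "COI-5P",
    order = order_name,
    family = plan_df$family,
    subfamily = plan_df$subfamily,
    genus = plan_df$genus,
    species = plan_df$species,
    identifier = sample(identifiers, n_clean, replace = TRUE),
    sequence = vapply(seq_len(n_clean), function(i) random_sequence(sample(600:658, 1L)), character(1L)),
    lat = lat, lon = lon, country = country,
    source_note = NA_character_
  )
  fate <- rep("kept", n_clean)

  ## ---- QC-failing and non-target extras -------------------------------
  make_extra <- function(n, kind) {
    if (n == 0L) return(NULL)
    src <- clean[sample.int(n_clean, n, replace = TRUE), ]
    src$sample_id <- next_sample_ids(n)
    src$process_id <- sprintf("SYNX%05d-20", seq_len(n) + if (kind == "nontarget") 50000L else 0L)
    src$lat <- NA_real_; src$lon <- NA_real_; src$country <- NA_character_
    if (kind == "qc") {
      src$bin_uri <- NA_character_
      type <- sample(c("short", "ambiguous", "nobin"), n, replace = TRUE)
      src$sequence <- vapply(seq_len(n), function(i) {
        switch(type[[i]],
               short = random_sequence(sample(150:499, 1L)),
               ambiguous = random_sequence(620L, n_ambiguous = 19L),  # ~3% N
               nobin = random_sequence(620L))
      }, character(1L))
    } else {
      src$bin_uri <- NA_character_
      src$marker <- "16S"
      src$sequence <- vapply(seq_len(n), function(i) random_sequence(550L), character(1L))
    }
    src
  }
  n_qc <- round(config$qc_fail_rate * n_clean)
  n_nt <- round(config$nontarget_marker_rate * n_clean)
  extras <- dplyr::bind_rows(make_extra(n_qc, "qc"), make_extra(n_nt, "nontarget"))
  extra_fates <- c(rep("removed_qc", n_qc), rep("removed_marker", n_nt))

  ## ---- '.1' duplicate pairs -------------------------------------------
  n_dup <- round(config$dup_rate * n_clean)
  dup_rows <- if (n_dup > 0L) sort(sample.int(n_clean, n_dup)) else integer()
  twins <- NULL
  twin_fates <- character()
  if (n_dup > 0L) {
    twins <- clean[dup_rows, ]
    twins$sample_id <- paste0(clean$sample_id[dup_rows], ".1")
    twins$process_id <- sprintf("SYND%05d-20", seq_len(n_dup))
    for (t in seq_len(n_dup)) {
      orig <- dup_rows[[t]]
      # degrade one geography step on the twin, then randomly swap sides
      if (!is.na(twins$lat[[t]])) {
        twins$lat[[t]] <- NA_real_; twins$lon[[t]] <- NA_real_
        if (is.na(twins$country[[t]])) {
          twins$country[[t]] <- sample(REALM_COUNTRIES[[realm_of_rec[[orig]]]], 1L)
        }
      } else if (!is.na(twins$country[[t]])) {
        twins$country[[t]] <- NA_character_
      }
      if (runif(1L) < 0.5) {
        for (col in c("lat", "lon", "country")) {
          tmp <- clean[[col]][[orig]]
          clean[[col]][orig] <- twins[[col]][[t]]
          twins[[col]][t] <- tmp
        }
      }
      score <- function(la, co) if (!is.na(la)) 2L else if (!is.na(co)) 1L else 0L
      s_orig <- score(clean$lat[[orig]], clean$country[[orig]])
      s_twin <- score(twins$lat[[t]], twins$country[[t]])
      if (s_twin >= s_orig) {          # twin kept on ties, per the '.1' rule
        fate[[orig]] <- "removed_duplicate"
        twin_fates[[t]] <- "kept"
      } else {
        twin_fates[[t]] <- "removed_duplicate"
      }
    }
  }

  records <- dplyr::bind_rows(clean, extras, twins)
  all_fates <- c(fate, extra_fates, twin_fates)
  records$record_id <- sprintf("R%06d", seq_len(nrow(records)))
  shuffle <- sample.int(nrow(records))
  records <- records[shuffle, ]
  all_fates <- all_fates[shuffle]
  records <- barcode_records(records)

  ## ---- habitat map & geo hints ----------------------------------------
  habitat_map <- tibble::tibble(taxon_name = families, rank = "family", realm = fam_realm)
  sp_entries <- sp[runif(nsp) < 0.5, ]
  if (nrow(sp_entries)) {
    habitat_map <- dplyr::bind_rows(habitat_map, tibble::tibble(
      taxon_name = sp_entries$canonical_name, rank = "species", realm = sp_entries$realm))
  }
  geo_hints <- dplyr::bind_rows(lapply(names(REALM_COUNTRIES), function(r)
    tibble::tibble(token = REALM_COUNTRIES[[r]], realm = r)))

  ## ---- ground truth ----------------------------------------------------
  kept_mask <- all_fates == "kept"
  kept_bin <- records$bin_uri[kept_mask]
  bin_counts <- table(kept_bin)

  gt_species <- tibble::tibble(
    canonical_name = sp$canonical_name, family = sp$family, genus = sp$genus,
    realm = sp$realm, ceiling = ceiling_of, split = split,
    merged = !is.na(merged_with),
    n_records = n_seq, n_bins = k_bins, n_misid = n_misid_by_sp,
    fate = NA_character_, true_grade = NA_character_
  )
  for (i in seq_len(nsp)) {
    if (!is.na(merged_with[[i]])) {
      j <- merged_with[[i]]
      ni <- n_seq[[i]]; nj <- n_seq[[j]]
      if (nj <= 1L && ni >= 3L) {
        gt_species$fate[[i]] <- "graded"
        gt_species$true_grade[[i]] <- as.character(grade_species(ni, 1L))
      } else if (ni <= 1L && nj >= 3L) {
        gt_species$fate[[i]] <- "absorbed"
      } else {
        gt_species$fate[[i]] <- "congruent"
      }
    } else if (ceiling_of[[i]] != "species") {
      gt_species$fate[[i]] <- "truncated"
    } else {
      gt_species$fate[[i]] <- "graded"
      n_eff <- n_seq[[i]] - n_misid_by_sp[[i]]
      gt_species$true_grade[[i]] <- as.character(grade_species(n_eff, k_bins[[i]]))
    }
  }

  bin_rows <- list()
  for (i in seq_len(nsp)) {
    if (!is.na(merged_with[[i]]) && merged_with[[i]] < i) next  # partner already emitted
    shared <- !is.na(merged_with[[i]])
    for (b in species_bins[[i]]) {
      lvl <- if (shared) "species" else ceiling_of[[i]]
      consensus_sp <- if (shared) {
        j <- merged_with[[i]]
        ni <- n_seq[[i]]; nj <- n_seq[[j]]
        if (nj <= 1L && ni >= 3L) sp$canonical_name[[i]]
        else if (ni <= 1L && nj >= 3L) sp$canonical_name[[j]]
        else NA_character_
      } else if (ceiling_of[[i]] == "species") sp$canonical_name[[i]]
      else if (ceiling_of[[i]] == "temporary") temp_label[[i]]
      else NA_character_
      eff_level <- if (shared && is.na(consensus_sp)) "genus" else lvl
      taxon_assignable <- eff_level %in% c("species", "temporary", "genus", "subfamily", "family")
      in_bin <- !is.na(records$bin_uri) & records$bin_uri == b
      geo_assignable <- any(kept_mask & in_bin & !is.na(records$country), na.rm = TRUE)
      cnt <- bin_counts[b]
      bin_rows[[length(bin_rows) + 1L]] <- tibble::tibble(
        bin_uri = b, species = consensus_sp,
        consensus_level = eff_level,
        true_realm = sp$realm[[i]],
        expected_realm = if (taxon_assignable || geo_assignable) sp$realm[[i]] else "unassigned",
        shared = shared,
        n_records_clean = if (is.na(cnt)) 0L else as.integer(cnt)
      )
    }
  }
  gt_bins <- dplyr::bind_rows(bin_rows)

  gt_records <- tibble::tibble(
    record_id = records$record_id,
    fate = all_fates,
    bin_uri = records$bin_uri
  )

  ground_truth <- list(
    records = gt_records,
    bins = gt_bins,
    species = gt_species,
    counts = list(
      n_clean = n_clean, n_qc_fail = n_qc, n_nontarget = n_nt,
      n_duplicate_pairs = n_dup,
      n_total = nrow(records),
      n_kept = sum(kept_mask)
    )
  )

  out <- list(records = records, checklist = checklist, habitat_map = habitat_map,
              geo_hints = geo_hints, ground_truth = ground_truth, config = config)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_bold_tsv(records, file.path(out_dir, "records.tsv"))
    readr::write_csv(checklist, file.path(out_dir, "checklist.csv"), na = "", progress = FALSE)
    readr::write_csv(habitat_map, file.path(out_dir, "habitat_map.csv"), na = "", progress = FALSE)
    readr::write_csv(geo_hints, file.path(out_dir, "geo_hints.csv"), na = "", progress = FALSE)
  }
  out
}

#' Analytic grade probabilities for a simulation configuration
#'
#' Closed-form expected frequencies of grades A-D among species retained at
#' species level, valid when no BIN sharing is planted (`p_merge = 0`):
#' a split species is always grade C, and an unsplit species is graded by
#' its record count `n ~ 1 + Geometric(prob)` — A above 10, B for 3-10,
#' D below 3.
#'
#' @param config A [simulation_config()] with `p_merge = 0`.
#' @return Named numeric vector with entries `A`, `B`, `C`, `D` summing
#'   to 1.
#' @export
#' @examples
#' expected_grade_profile(simulation_config(p_split = 0.3, p_merge = 0))
expected_grade_profile <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$p_merge > 0) {
    rlang::abort("expected_grade_profile requires p_merge = 0; use simulation for shared BINs")
  }
  prob <- config$seqs_per_species_law$prob
  ps <- config$p_split
  # n = 1 + G, G ~ Geom(prob): P(n <= k) = pgeom(k - 1, prob)
  p_gt10 <- 1 - pgeom(9L, prob)
  p_le2 <- pgeom(1L, prob)
  c(A = (1 - ps) * p_gt10,
    B = (1 - ps) * (1 - p_le2 - p_gt10),
    C = ps,
    D = (1 - ps) * p_le2)
}
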