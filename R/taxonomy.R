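#' Default temporary-name patterns
#'
#' Regular expressions recognising morphospecies placeholders in species
#' fields: `"Genus sp."`, `"Genus sp. 3"`, `"Genus sp. nov."`, `"Genus n.
#' sp."`, BOLD-style BIN placeholders, and all-numeric epithets. Patterns
#' are matched case-insensitively against the raw species string.
#'
#' @return Character vector of regular expressions.
#' @export
temporary_name_patterns <- function() {
  c(
    "\\bsp{1,2}\\.",          # "sp.", "spp.", "sp. 3", "sp. nov."
    "\\bsp\\b",               # bare "sp" token
    "\\bn\\. ?sp\\b",         # "n. sp."
    "\\bnov\\.?\\b",          # "nov."
    "BOLD:",                  # BIN URI used as a name placeholder
    "^\\S+\\s+[A-Z0-9][A-Z0-9-]*$",  # trailing code token: "Epimeria 2", "Genus MX-1"
    "^\\S+\\s+\\d"            # numeric epithet
  )
}

is_temporary_name <- function(x, patterns = temporary_name_patterns()) {
  hit <- rep(FALSE, length(x))
  for (p in patterns) {
    hit <- hit | grepl(p, x, ignore.case = (p != "^\\S+\\s+[A-Z0-9][A-Z0-9-]*$"))
  }
  hit & !is.na(x)
}

#' Canonicalize a species name
#'
#' Reduces a raw species string to `"Genus epithet"`: strips authority
#' strings (capitalised author + year), subgenus parentheses, and the open
#' nomenclature qualifiers `"cf."`/`"aff."` — the latter are flagged rather
#' than dropped silently. Names without a parseable genus + lowercase
#' epithet (including bare genus names and temporary names) yield `NA` with
#' a warning.
#'
#' @param raw_species_name Character vector of raw species strings.
#' @return Tibble with columns `canonical_name` (character, `NA` when
#'   unparseable) and `open_nomenclature` (logical).
#' @export
#' @examples
#' canonical_species_name("Gammarus cf. balcanicus")
canonical_species_name <- function(raw_species_name) {
  x <- normalize_absent(raw_species_name)
  open <- rep(FALSE, length(x))
  out <- rep(NA_character_, length(x))
  present <- !is.na(x)
  if (any(present)) {
    y <- x[present]
    y <- stringr::str_squish(y)
    y <- gsub("\\(([^)]*)\\)", " ", y)           # subgenus / bracketed authority
    open_here <- grepl("\\b(cf|aff)\\.?\\s", y, ignore.case = TRUE)
    y <- gsub("\\b(cf|aff)\\.?\\s+", "", y, ignore.case = TRUE)
    y <- stringr::str_squish(y)
    genus <- stringr::str_match(y, "^([A-Z][a-zA-Z-]+)\\s+([a-z][a-z-]+)\\b")
    parsed <- !is.na(genus[, 1L])
    res <- ifelse(parsed, paste(genus[, 2L], genus[, 3L]), NA_character_)
    open[present] <- open_here & parsed
    out[present] <- res
    n_bad <- sum(!parsed)
    if (n_bad > 0L) {
      rlang::warn(paste0(n_bad, " species name(s) could not be parsed to 'Genus epithet'"))
    }
  }
  tibble::tibble(canonical_name = out, open_nomenclature = open)
}

#' Classify the identification level of records
#'
#' Assigns each record one of the ordered levels
#' `order < family < subfamily < genus < temporary < species`. A populated
#' species field yields `species` when it parses to a clean binomial —
#' open-nomenclature names (`"cf."`, `"aff."`) count as species unless
#' `cf_as_species = FALSE` — and `temporary` when it matches a
#' morphospecies-placeholder pattern; otherwise the deepest populated rank
#' wins. A record with no rank populated at all is an error.
#'
#' @param records Record tibble.
#' @param cf_as_species Treat `"cf."`/`"aff."` names as full species
#'   identifications (default `TRUE`).
#' @param temp_patterns Patterns for temporary names, see
#'   [temporary_name_patterns()].
#' @return Factor vector of levels, one per record.
#' @export
classify_identification <- function(records, cf_as_species = TRUE,
                                    temp_patterns = temporary_name_patterns()) {
  n <- nrow(records)
  level <- rep(NA_character_, n)
  sp <- records$species
  has_sp <- !is.na(sp)
  temp <- is_temporary_name(sp, temp_patterns)
  canon <- suppressWarnings(canonical_species_name(sp))
  is_species <- has_sp & !temp & !is.na(canon$canonical_name) &
    (cf_as_species | !canon$open_nomenclature)
  is_temp <- has_sp & (temp | (!cf_as_species & canon$open_nomenclature &
                                 !is.na(canon$canonical_name)))
  level[is_species] <- "species"
  level[is.na(level) & is_temp] <- "temporary"
  for (rank in c("genus", "subfamily", "family", "order")) {
    fill <- is.na(level) & !is.na(records[[rank]])
    level[fill] <- rank
  }
  if (any(is.na(level))) {
    bad <- records$record_id[is.na(level)]
    rlang::abort(paste0("unidentifiable record(s): no rank populated for ",
                        paste(head(bad, 5L), collapse = ", ")))
  }
  id_level_factor(level)
}

#' BIN conflict-resolution policy
#'
#' Parameters governing how conflicting identifications within one BIN are
#' reconciled by [resolve_bins()]: a lone outlier against a clear majority
#' is demoted as a presumed misidentification; failing that, a name assigned
#' by a trusted specialist wins; failing that, the BIN falls back to the
#' deepest rank on which all members agree.
#'
#' @param outlier_max Largest minority size treated as misidentification
#'   (default 1).
#' @param majority_min Smallest majority size required to overrule an
#'   outlier (default 3; must exceed `outlier_max`).
#' @param trusted_identifiers Character vector of determiner names
#'   (case-insensitive exact match) whose identifications take priority.
#' @param cf_as_species Passed to [classify_identification()].
#' @param temp_patterns Passed to [classify_identification()].
#' @return A list of class `resolution_policy`.
#' @export
resolution_policy <- function(outlier_max = 1L, majority_min = 3L,
                              trusted_identifiers = character(),
                              cf_as_species = TRUE,
                              temp_patterns = temporary_name_patterns()) {
  stopifnot(outlier_max >= 1L, majority_min > outlier_max)
  structure(
    list(outlier_max = as.integer(outlier_max),
         majority_min = as.integer(majority_min),
         trusted_identifiers = tolower(trusted_identifiers),
         cf_as_species = cf_as_species,
         temp_patterns = temp_patterns),
    class = "resolution_policy"
  )
}

# Name a record carries at a given identification level.
name_at_level <- function(records, level, canon) {
  switch(level,
    species = canon$canonical_name,
    temporary = records$species,
    genus = records$genus,
    subfamily = records$subfamily,
    family = records$family,
    order = records$order
  )
}

# Deepest rank (genus > family > order) on which all given records agree,
# with the agreed name; NULL if none.
congruent_rank <- function(members) {
  for (rank in c("genus", "subfamily", "family", "order")) {
    vals <- unique(members[[rank]][!is.na(members[[rank]])])
    # absent values never break congruence (real exports are rank-ragged)
    if (length(vals) == 1L) {
      return(list(rank = rank, name = vals))
    }
  }
  NULL
}

resolve_one_bin <- function(members, policy) {
  if (nrow(members) == 0L) rlang::abort("empty BIN record set")
  bin <- members$bin_uri[[1L]]
  levels <- classify_identification(members, policy$cf_as_species, policy$temp_patterns)
  canon <- suppressWarnings(canonical_species_name(members$species))
  deepest <- max(as.integer(levels))
  lvl <- ID_LEVELS[deepest]
  names_at <- name_at_level(members, lvl, canon)
  at_deepest <- as.integer(levels) == deepest
  cand <- names_at[at_deepest]
  cand <- cand[!is.na(cand)]
  counts <- sort(table(cand), decreasing = TRUE)

  demotions <- tibble::tibble(record_id = character(), bin_uri = character(),
                              original_species = character(), demoted_to = character())
  conflict <- FALSE
  note <- ""
  consensus_name <- NULL
  consensus_level <- lvl

  if (length(counts) <= 1L) {
    consensus_name <- if (length(counts)) names(counts)[[1L]] else NA_character_
    note <- if (nrow(members) == 1L) "singleton" else "unanimous"
  } else {
    majority_n <- counts[[1L]]
    tied <- sum(counts == majority_n) > 1L
    minority_n <- sum(counts) - majority_n
    if (!tied && minority_n <= policy$outlier_max && majority_n >= policy$majority_min) {
      # (a) lone outlier against a clear majority: presumed misidentification
      consensus_name <- names(counts)[[1L]]
      out_idx <- which(at_deepest & !is.na(names_at) & names_at != consensus_name)
      maj <- members[which(at_deepest & !is.na(names_at) & names_at == consensus_name), ]
      for (i in out_idx) {
        cr <- congruent_rank(dplyr::bind_rows(members[i, ], maj[1L, ]))
        demotions <- dplyr::bind_rows(demotions, tibble::tibble(
          record_id = members$record_id[[i]], bin_uri = bin,
          original_species = members$species[[i]] %||% NA_character_,
          demoted_to = if (is.null(cr)) "order" else cr$rank
        ))
      }
      note <- paste0("majority rule: ", majority_n, " vs ", minority_n,
                     "; minority demoted to congruent rank")
    } else {
      trusted_names <- unique(names_at[
        at_deepest & !is.na(names_at) &
          !is.na(members$identifier) &
          tolower(members$identifier) %in% policy$trusted_identifiers
      ])
      if (length(trusted_names) == 1L) {
        # (b) exactly one of the conflicting names backed by a specialist
        consensus_name <- trusted_names
        note <- "trusted-identifier priority"
      } else {
        # (c) fall back to the deepest congruent rank
        cr <- congruent_rank(members)
        conflict <- TRUE
        if (is.null(cr)) {
          consensus_level <- "order"
          consensus_name <- modal_value(members$order)
          note <- "unresolved conflict: no congruent rank below order"
        } else {
          consensus_level <- cr$rank
          consensus_name <- cr$name
          note <- paste0("unresolved conflict: congruent at ", cr$rank)
        }
      }
    }
  }

  consensus <- list(order = modal_value(members$order),
                    family = modal_value(members$family),
                    subfamily = modal_value(members$subfamily),
                    genus = modal_value(members$genus),
                    species = NA_character_)
  if (consensus_level == "species") {
    consensus$species <- consensus_name
    if (!is.na(consensus_name)) {
      consensus$genus <- strsplit(consensus_name, " ")[[1L]][[1L]]
    }
  } else if (consensus_level == "temporary") {
    consensus$species <- consensus_name
  } else if (consensus_level %in% c("genus", "subfamily", "family", "order")) {
    consensus[[consensus_level]] <- consensus_name
    # ranks deeper than the consensus are not trusted
    deeper <- which(RECORD_RANKS == consensus_level) < seq_along(RECORD_RANKS)
    for (r in RECORD_RANKS[deeper]) consensus[[r]] <- NA_character_
  }

  list(
    row = tibble::tibble(
      bin_uri = bin,
      n_records = nrow(members),
      order = consensus$order, family = consensus$family,
      subfamily = consensus$subfamily, genus = consensus$genus,
      species = consensus$species,
      consensus_level = consensus_level,
      conflict_flag = conflict,
      n_demoted = nrow(demotions),
      resolution_note = note
    ),
    demotions = demotions
  )
}

#' Derive one consensus identification per BIN
#'
#' Groups curated records by BIN URI and reconciles identifications within
#' each BIN. When all species-level names agree (after canonicalization) the
#' most detailed identification is propagated to the whole BIN. When names
#' conflict at the deepest shared level, the policy applies in order: (a) a
#' minority of at most `outlier_max` records against a majority of at least
#' `majority_min` is demoted as misidentified and the majority name adopted;
#' (b) a single conflicting name backed by a trusted identifier wins; (c)
#' otherwise the BIN is assigned the deepest rank congruent across all
#' members and flagged as a conflict. After resolution each BIN carries at
#' most one species name, so a downstream grade E (one BIN shared by several
#' species) cannot occur.
#'
#' The result is invariant under permutation of record order.
#'
#' @param records Curated record tibble (all records, any number of BINs);
#'   records without a BIN URI are ignored with a warning.
#' @param policy A [resolution_policy()].
#' @return List with `bins` (one row per BIN: consensus ranks,
#'   `consensus_level`, `conflict_flag`, `n_demoted`, `resolution_note`),
#'   `demotions` (one row per demoted record with its original name and the
#'   rank it was demoted to) and `conflicts` (the subset of `bins` where
#'   branch (a)/(b)/(c) fired — the decision ledger).
#' @export
resolve_bins <- function(records, policy = resolution_policy()) {
  no_bin <- is.na(records$bin_uri)
  if (any(no_bin)) {
    rlang::warn(paste0(sum(no_bin), " record(s) without BIN URI ignored by resolve_bins"))
    records <- records[!no_bin, ]
  }
  if (nrow(records) == 0L) {
    empty <- resolve_one_bin(barcode_records(record_id = "x", bin_uri = "b", order = "O"),
                             policy)$row[0, ]
    return(list(bins = empty,
                demotions = tibble::tibble(record_id = character(), bin_uri = character(),
                                           original_species = character(), demoted_to = character()),
                conflicts = empty))
  }
  # sort for deterministic output order; per-BIN logic is order-free
  records <- dplyr::arrange(records, .data$bin_uri, .data$record_id)
  parts <- split(records, records$bin_uri)
  res <- lapply(parts, resolve_one_bin, policy = policy)
  bins <- dplyr::bind_rows(lapply(res, `[[`, "row"))
  demotions <- dplyr::bind_rows(lapply(res, `[[`, "demotions"))
  list(
    bins = bins,
    demotions = demotions,
    conflicts = bins[bins$conflict_flag | bins$n_demoted > 0L |
                       grepl("trusted", bins$resolution_note), ]
  )
}
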