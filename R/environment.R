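#' Assign each BIN to an environmental realm
#'
#' Looks up the consensus identification of every BIN in the habitat map,
#' species entries first, then genus, then family. The family Talitridae is
#' always treated as terrestrial (built-in family-level rule); an explicit
#' species-level map entry still overrides it, with a warning, as for any
#' species-vs-family conflict. BINs without a taxon hit fall back to
#' geographic hints: country tokens and/or coordinate boxes supplied by the
#' user, matched against the BIN's member records, with the modal realm
#' winning and an exact tie yielding `unassigned`. BINs with no information
#' at all stay `unassigned`.
#'
#' @param bins BIN consensus tibble from [resolve_bins()].
#' @param habitat_map Tibble with columns `taxon_name`, `rank`
#'   (species/genus/family), `realm` (marine/freshwater/terrestrial); see
#'   [read_habitat_map()].
#' @param geo_hints Optional tibble with columns `token` (country name,
#'   matched case-insensitively) and `realm`, and/or coordinate-box rows
#'   with `lat_min`, `lat_max`, `lon_min`, `lon_max` (token `NA`).
#' @param records Curated record tibble; required when `geo_hints` is used
#'   (supplies member countries/coordinates).
#' @return `bins` with added columns `realm` (factor) and `realm_note`.
#' @export
assign_realms <- function(bins, habitat_map, geo_hints = NULL, records = NULL) {
  builtin <- tibble::tibble(taxon_name = "Talitridae", rank = "family", realm = "terrestrial")
  map <- dplyr::bind_rows(habitat_map, builtin)
  map <- map[!duplicated(map[c("taxon_name", "rank")]), ]  # user entries win over built-in

  lookup <- function(name, rank) {
    if (is.na(name)) return(NA_character_)
    hit <- map$realm[map$rank == rank & map$taxon_name == name]
    if (length(hit)) hit[[1L]] else NA_character_
  }

  n <- nrow(bins)
  realm <- rep(NA_character_, n)
  note <- rep("", n)
  n_conflicts <- 0L
  for (i in seq_len(n)) {
    sp_hit <- if (!is.na(bins$consensus_level[i]) && bins$consensus_level[i] == "species")
      lookup(bins$species[i], "species") else NA_character_
    ge_hit <- lookup(bins$genus[i], "genus")
    fa_hit <- lookup(bins$family[i], "family")
    hits <- c(species = sp_hit, genus = ge_hit, family = fa_hit)
    hits <- hits[!is.na(hits)]
    if (length(hits)) {
      realm[i] <- hits[[1L]]
      note[i] <- paste0("habitat map: ", names(hits)[[1L]], " level")
      if (length(unique(hits)) > 1L) n_conflicts <- n_conflicts + 1L
    }
  }
  if (n_conflicts > 0L) {
    rlang::warn(paste0(n_conflicts,
                       " BIN(s) had conflicting habitat-map entries at different ranks; deepest rank used"))
  }

  need_geo <- which(is.na(realm))
  if (length(need_geo) && !is.null(geo_hints) && !is.null(records)) {
    token_rows <- geo_hints[!is.na(geo_hints$token %||% NA), , drop = FALSE]
    box_rows <- if (all(c("lat_min", "lat_max", "lon_min", "lon_max") %in% names(geo_hints))) {
      geo_hints[!is.na(geo_hints$lat_min), , drop = FALSE]
    } else geo_hints[0, ]
    for (i in need_geo) {
      members <- records[!is.na(records$bin_uri) & records$bin_uri == bins$bin_uri[i], ]
      votes <- character()
      if (nrow(token_rows)) {
        ctry <- tolower(trimws(members$country))
        m <- match(ctry, tolower(trimws(token_rows$token)))
        votes <- c(votes, token_rows$realm[m[!is.na(m)]])
      }
      if (nrow(box_rows)) {
        for (j in seq_len(nrow(box_rows))) {
          inside <- !is.na(members$lat) &
            members$lat >= box_rows$lat_min[j] & members$lat <= box_rows$lat_max[j] &
            members$lon >= box_rows$lon_min[j] & members$lon <= box_rows$lon_max[j]
          votes <- c(votes, rep(box_rows$realm[j], sum(inside)))
        }
      }
      if (length(votes)) {
        tab <- sort(table(votes), decreasing = TRUE)
        if (sum(tab == tab[[1L]]) == 1L) {
          realm[i] <- names(tab)[[1L]]
          note[i] <- paste0("geographic hint (", tab[[1L]], " of ", sum(tab), " member votes)")
        } else {
          note[i] <- "geographic hints tied; left unassigned"
        }
      }
    }
  }

  note[is.na(realm) & note == ""] <- "no habitat or geographic information"
  realm[is.na(realm)] <- "unassigned"
  bins$realm <- realm_factor(realm)
  bins$realm_note <- note
  bins
}

#' Tally records and BINs per realm
#'
#' Counts records and BINs in each realm (including `unassigned`), with
#' fractions over the full totals. Records inherit the realm of their BIN.
#'
#' @param bins Realm-assigned BIN tibble from [assign_realms()].
#' @param records Curated record tibble.
#' @return Tibble with columns `scope` (`"records"`/`"bins"`), `realm`,
#'   `n`, `fraction`.
#' @export
realm_tallies <- function(bins, records) {
  rec_realm <- bins$realm[match(records$bin_uri, bins$bin_uri)]
  tally_one <- function(x, scope) {
    tab <- table(factor(as.character(x), levels = REALM_LEVELS))
    tibble::tibble(scope = scope, realm = realm_factor(names(tab)),
                   n = as.integer(tab),
                   fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab) else 0)
  }
  out <- dplyr::bind_rows(
    tally_one(rec_realm[!is.na(rec_realm)], "records"),
    tally_one(bins$realm, "bins")
  )
  stopifnot(sum(out$n[out$scope == "bins"]) == nrow(bins))
  out
}
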