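#' Geographic completeness of records
#'
#' Classifies each record into exactly one of three classes: `coords`
#' (latitude/longitude present, regardless of country), `country_only`
#' (country but no coordinates), `neither`. Reported overall and, when a
#' realm-assigned BIN table is supplied, per realm (records inherit the
#' realm of their BIN).
#'
#' @param records Curated record tibble.
#' @param bins Optional realm-assigned BIN tibble from [assign_realms()].
#' @return Tibble with columns `scope` (`"overall"` or a realm), `class`,
#'   `n`, `fraction`; the three class counts sum to the scope's record
#'   total.
#' @export
geo_completeness <- function(records, bins = NULL) {
  cls <- ifelse(!is.na(records$lat), "coords",
         ifelse(!is.na(records$country), "country_only", "neither"))
  cls <- factor(cls, levels = c("coords", "country_only", "neither"))
  one_scope <- function(sel, scope) {
    tab <- table(cls[sel])
    tibble::tibble(scope = scope, class = factor(names(tab), levels = levels(cls)),
                   n = as.integer(tab),
                   fraction = if (sum(tab) > 0) as.integer(tab) / sum(tab) else 0)
  }
  out <- one_scope(rep(TRUE, nrow(records)), "overall")
  if (!is.null(bins)) {
    realm <- as.character(bins$realm)[match(records$bin_uri, bins$bin_uri)]
    for (r in setdiff(unique(realm), NA)) {
      out <- dplyr::bind_rows(out, one_scope(!is.na(realm) & realm == r, r))
    }
  }
  out
}

normalize_country <- function(x, aliases = NULL) {
  y <- stringr::str_squish(as.character(x))
  y <- stringr::str_to_title(y)
  if (!is.null(aliases)) {
    m <- match(tolower(y), tolower(stringr::str_squish(aliases$from)))
    y[!is.na(m)] <- aliases$to[m[!is.na(m)]]
  }
  y
}

#' Per-country record tally
#'
#' Counts records per (country, realm) after lexical normalization of
#' country strings (whitespace squeeze, title case, optional alias table
#' for historical names). Records with no country but with coordinates are
#' reported as a separate count, as are records with neither.
#'
#' @param records Curated record tibble.
#' @param bins Optional realm-assigned BIN tibble (for the realm column).
#' @param aliases Optional tibble with columns `from`, `to` mapping country
#'   spellings to a canonical form.
#' @return List with `tally` (tibble: `country`, `realm`, `n`),
#'   `n_coords_no_country`, `n_excluded` (neither coordinates nor country).
#' @export
per_country_tally <- function(records, bins = NULL, aliases = NULL) {
  realm <- if (!is.null(bins)) {
    as.character(bins$realm)[match(records$bin_uri, bins$bin_uri)]
  } else rep(NA_character_, nrow(records))
  has_country <- !is.na(records$country)
  has_coords <- !is.na(records$lat)
  df <- tibble::tibble(
    country = normalize_country(records$country[has_country], aliases),
    realm = dplyr::coalesce(realm[has_country], "unassigned")
  )
  tally <- df |>
    dplyr::count(.data$country, .data$realm, name = "n") |>
    dplyr::arrange(.data$country, .data$realm)
  list(
    tally = tally,
    n_coords_no_country = sum(has_coords & !has_country),
    n_excluded = sum(!has_coords & !has_country)
  )
}
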