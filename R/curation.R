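#' Curation configuration
#'
#' Bundles the record-level quality thresholds applied by [curate_records()].
#' Defaults follow common practice for COI reference-library audits: keep
#' COI-5P records at least 500 bp long with at most 1% ambiguous nucleotides
#' and a BIN assigned.
#'
#' Boundary semantics: a 500 bp sequence is kept (only strictly shorter
#' sequences are removed) and exactly 1% ambiguity is kept (only strictly
#' more is removed).
#'
#' @param required_marker Marker code to keep (case-insensitive), default
#'   `"COI-5P"`.
#' @param min_length Minimum sequence length in bp after gap removal.
#' @param max_ambiguous_fraction Maximum tolerated fraction of non-ACGT
#'   characters.
#' @param require_bin Remove records without a BIN URI (default `TRUE`).
#' @param qc_combine How the three QC clauses combine: `"or"` (default,
#'   any failing clause removes the record) or `"and"` (all clauses must
#'   fail).
#' @param exclusion_ids Named character vector: names are record or sample
#'   IDs to drop, values the reason. An unnamed vector gets a generic reason.
#' @return A list of class `curation_config`.
#' @export
#' @examples
#' curation_config(exclusion_ids = c(KR858496 = "sequence withdrawn by submitter"))
curation_config <- function(required_marker = "COI-5P",
                            min_length = 500L,
                            max_ambiguous_fraction = 0.01,
                            require_bin = TRUE,
                            qc_combine = c("or", "and"),
                            exclusion_ids = character()) {
  qc_combine <- match.arg(qc_combine)
  stopifnot(min_length > 0, max_ambiguous_fraction >= 0, max_ambiguous_fraction <= 1)
  if (length(exclusion_ids) && is.null(names(exclusion_ids))) {
    exclusion_ids <- setNames(rep("listed for exclusion", length(exclusion_ids)), exclusion_ids)
  }
  structure(
    list(required_marker = required_marker,
         min_length = as.integer(min_length),
         max_ambiguous_fraction = max_ambiguous_fraction,
         require_bin = require_bin,
         qc_combine = qc_combine,
         exclusion_ids = exclusion_ids),
    class = "curation_config"
  )
}

removal_log_entry <- function(record_id, stage, reason) {
  tibble::tibble(record_id = record_id, stage = stage, reason = reason)
}

#' Sequence length and ambiguity metrics
#'
#' Computes the effective length and the ambiguous-base fraction of
#' nucleotide strings. Gap characters (`-` and `.`) are removed first and
#' count toward neither length nor ambiguity; every remaining character
#' outside `{A, C, G, T}` (case-insensitive), i.e. any IUPAC ambiguity code,
#' counts as ambiguous.
#'
#' @param sequence Character vector of nucleotide strings.
#' @return Tibble with columns `effective_length` (integer, bp) and
#'   `ambiguous_fraction` (in `[0, 1]`). Missing sequences yield `NA` rows.
#' @export
#' @examples
#' sequence_metrics("ACGT----ACGT")  # length 8, ambiguity 0
sequence_metrics <- function(sequence) {
  stripped <- gsub("[-.]", "", sequence)
  len <- nchar(stripped)
  if (any(!is.na(len) & len == 0L)) {
    rlang::abort("degenerate sequence: no nucleotides left after gap removal")
  }
  clean <- nchar(gsub("[^ACGTacgt]", "", stripped))
  tibble::tibble(
    effective_length = as.integer(len),
    ambiguous_fraction = (len - clean) / len
  )
}

#' Marker filter
#'
#' Partitions records into those carrying the required marker
#' (case-insensitive match) and the rest; records with no marker code are
#' removed.
#'
#' @param records Record tibble.
#' @param config A [curation_config()].
#' @return List with `kept`, `removed` (record tibbles) and `log`
#'   (removal-log tibble with columns `record_id`, `stage`, `reason`).
#' @export
filter_marker <- function(records, config = curation_config()) {
  keep <- !is.na(records$marker) &
    toupper(records$marker) == toupper(config$required_marker)
  removed <- records[!keep, ]
  list(
    kept = records[keep, ],
    removed = removed,
    log = removal_log_entry(
      removed$record_id, "marker",
      paste0("marker '", ifelse(is.na(removed$marker), "<absent>", removed$marker),
             "' is not ", config$required_marker)
    )
  )
}

#' Sequence quality and BIN filter
#'
#' Removes records that fail the quality screen: no BIN assigned (when
#' `require_bin`), effective sequence length below `min_length`, or
#' ambiguous-base fraction above `max_ambiguous_fraction`. By default any
#' one failing clause removes the record (`qc_combine = "or"`); the reason
#' string records every clause that fired. Records without any sequence fail
#' the length clause.
#'
#' @inheritParams filter_marker
#' @return List with `kept`, `removed`, `log` as in [filter_marker()].
#' @export
filter_qc <- function(records, config = curation_config()) {
  n <- nrow(records)
  has_seq <- !is.na(records$sequence)
  len <- rep(NA_integer_, n)
  amb <- rep(NA_real_, n)
  if (any(has_seq)) {
    m <- sequence_metrics(records$sequence[has_seq])
    len[has_seq] <- m$effective_length
    amb[has_seq] <- m$ambiguous_fraction
  }
  no_bin <- config$require_bin & is.na(records$bin_uri)
  short <- !has_seq | (len < config$min_length)
  ambiguous <- has_seq & (amb > config$max_ambiguous_fraction)
  fail <- if (config$qc_combine == "or") no_bin | short | ambiguous else no_bin & short & ambiguous
  reason <- vapply(seq_len(n), function(i) {
    clauses <- c(
      if (no_bin[i]) "no BIN assigned",
      if (short[i]) {
        if (!has_seq[i]) "no sequence" else paste0("sequence ", len[i], " bp < ", config$min_length, " bp")
      },
      if (ambiguous[i]) sprintf("ambiguous fraction %.4f > %.4f", amb[i], config$max_ambiguous_fraction)
    )
    paste(clauses, collapse = "; ")
  }, character(1L))
  removed <- records[fail, ]
  list(
    kept = records[!fail, ],
    removed = removed,
    log = removal_log_entry(removed$record_id, "qc", reason[fail])
  )
}

# TRUE when two records agree at every rank populated on both sides; a rank
# absent on one side never breaks the match.
identification_matches <- function(a, b) {
  for (rank in RECORD_RANKS) {
    va <- a[[rank]]
    vb <- b[[rank]]
    if (!is.na(va) && !is.na(vb) && va != vb) return(FALSE)
  }
  TRUE
}

geo_detail_score <- function(rec) {
  if (!is.na(rec$lat)) 2L else if (!is.na(rec$country)) 1L else 0L
}

#' Collapse GenBank-update duplicate pairs
#'
#' Detects pairs of records whose sample IDs are `X` and `X.1` (the pattern
#' left by repository updates of harvested GenBank accessions) with an
#' identical identification at every rank populated on both sides, and keeps
#' the member with the more detailed geography (coordinates beat country,
#' country beats nothing; ties keep the `.1` record). Triples such as
#' `X`, `X.1`, `X.2` fall outside the rule and are left untouched with a
#' warning.
#'
#' @param records Record tibble.
#' @return List with `kept`, `removed`, `log`, and `pairs` — a tibble with
#'   one row per collapsed pair (`sample_id_base`, `kept_record_id`,
#'   `removed_record_id`).
#' @export
collapse_duplicates <- function(records) {
  pairs <- tibble::tibble(sample_id_base = character(),
                          kept_record_id = character(),
                          removed_record_id = character())
  drop_ids <- character()
  sid <- records$sample_id
  has_sid <- !is.na(sid)
  base <- sub("\\.1$", "", sid)
  # candidate bases: every ID carrying a ".1" suffix
  cand <- unique(base[has_sid & grepl("\\.1$", sid)])
  n_triples <- 0L
  for (b in cand) {
    plain_idx <- which(has_sid & sid == b)
    dot_idx <- which(has_sid & sid == paste0(b, ".1"))
    extra <- which(has_sid & grepl(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", b), "\\.[0-9]+$"), sid) &
                     sid != paste0(b, ".1"))
    if (length(extra) || length(plain_idx) > 1L || length(dot_idx) > 1L) {
      n_triples <- n_triples + 1L
      next
    }
    if (length(plain_idx) != 1L || length(dot_idx) != 1L) next
    a <- records[plain_idx, ]
    d <- records[dot_idx, ]
    if (!identification_matches(a, d)) next
    keep_dot <- geo_detail_score(d) >= geo_detail_score(a)
    kept_rec <- if (keep_dot) d else a
    removed_rec <- if (keep_dot) a else d
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(
      sample_id_base = b,
      kept_record_id = kept_rec$record_id,
      removed_record_id = removed_rec$record_id
    ))
    drop_ids <- c(drop_ids, removed_rec$record_id)
  }
  if (n_triples > 0L) {
    rlang::warn(paste0(n_triples, " sample-ID group(s) with more than one suffixed twin left uncollapsed"))
  }
  fail <- records$record_id %in% drop_ids
  removed <- records[fail, ]
  list(
    kept = records[!fail, ],
    removed = removed,
    log = removal_log_entry(removed$record_id, "duplicate",
                            "duplicate of '.1'-suffixed GenBank accession pair; less detailed geography"),
    pairs = pairs
  )
}

#' Apply an explicit exclusion list
#'
#' Removes records whose `record_id` or `sample_id` appears in
#' `config$exclusion_ids`, logging the supplied reason. Listed IDs absent
#' from the data produce a warning, not an error.
#'
#' @inheritParams filter_marker
#' @return List with `kept`, `removed`, `log` as in [filter_marker()].
#' @export
apply_exclusions <- function(records, config = curation_config()) {
  ids <- names(config$exclusion_ids)
  if (length(ids) == 0L) {
    return(list(kept = records, removed = records[0, ],
                log = removal_log_entry(character(), character(), character())))
  }
  hit_record <- records$record_id %in% ids
  hit_sample <- !is.na(records$sample_id) & records$sample_id %in% ids
  fail <- hit_record | hit_sample
  matched_ids <- unique(c(records$record_id[hit_record], records$sample_id[hit_sample]))
  missing <- setdiff(ids, matched_ids)
  if (length(missing)) {
    rlang::warn(paste0("exclusion ID(s) not found in data: ", paste(missing, collapse = ", ")))
  }
  key <- ifelse(records$record_id %in% ids, records$record_id, records$sample_id)
  reason <- unname(config$exclusion_ids[key])
  removed <- records[fail, ]
  list(
    kept = records[!fail, ],
    removed = removed,
    log = removal_log_entry(removed$record_id, "exclusion", reason[fail])
  )
}

#' Run the full record-level curation pipeline
#'
#' Applies, in fixed order, the marker filter, the quality/BIN screen, the
#' duplicate-pair collapse and the explicit exclusion list. Every removed
#' record receives exactly one removal-log entry naming the stage and
#' reason, so `nrow(input) == nrow(curated) + nrow(removal_log)`; re-running
#' on the curated output is a fixed point.
#'
#' @inheritParams filter_marker
#' @return List with `curated` (record tibble), `removed` (record tibble
#'   with a `stage` column), `removal_log`, `pairs` (collapsed duplicate
#'   pairs) and `stage_counts` (tibble of input/kept/removed per stage).
#' @export
curate_records <- function(records, config = curation_config()) {
  stages <- list()
  log <- removal_log_entry(character(), character(), character())
  removed_all <- records[0, ]
  removed_all$stage <- character()
  current <- records

  run_stage <- function(name, res) {
    stages[[name]] <<- tibble::tibble(
      stage = name, n_in = nrow(current), n_kept = nrow(res$kept), n_removed = nrow(res$removed)
    )
    if (nrow(res$removed)) {
      rem <- res$removed
      rem$stage <- name
      removed_all <<- dplyr::bind_rows(removed_all, rem)
    }
    log <<- dplyr::bind_rows(log, res$log)
    current <<- res$kept
  }

  run_stage("marker", filter_marker(current, config))
  run_stage("qc", filter_qc(current, config))
  dup <- collapse_duplicates(current)
  run_stage("duplicate", dup)
  run_stage("exclusion", apply_exclusions(current, config))

  stopifnot(nrow(records) == nrow(current) + nrow(log))
  list(
    curated = current,
    removed = removed_all,
    removal_log = log,
    pairs = dup$pairs,
    stage_counts = dplyr::bind_rows(stages)
  )
}
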