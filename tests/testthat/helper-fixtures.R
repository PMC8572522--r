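# Shared fixture builders: every fixture is constructed in code.

clean_seq <- function(len = 600L) strrep("ACGT", ceiling(len / 4)) |> substr(1L, len)

# A record with sensible defaults that pass every curation filter.
rec <- function(record_id, ..., marker = "COI-5P", bin_uri = "BOLD:TEST001",
                sequence = clean_seq()) {
  barcode_records(record_id = record_id, marker = marker, bin_uri = bin_uri,
                  sequence = sequence, ...)
}

# n records of one species in one BIN
species_bin <- function(bin, species, n, genus = sub(" .*", "", species),
                        family = "Testidae", id_prefix = bin, identifier = NA_character_) {
  barcode_records(
    record_id = paste0(id_prefix, "_", seq_len(n)),
    bin_uri = bin, marker = "COI-5P", sequence = clean_seq(),
    order = "Testoida", family = family, genus = genus, species = species,
    identifier = identifier
  )
}

# all permutations of seq_len(n) (n <= 6)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

small_sim <- function(seed = 42L, ...) {
  simulation_config(seed = seed, n_families = 30L, n_species_sampled = 120L, ...)
}
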