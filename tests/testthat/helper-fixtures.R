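# In-code fixtures shared across test files.

# One SV record row in the internal (0-based) layout.
sv_record <- function(donor = "D1", sv = "sv1", type = "DEL",
                      chrom1 = "chr1", pos1 = 1000,
                      chrom2 = chrom1, pos2 = pos1 + 5000,
                      cohort = "TEST") {
  data.frame(cohort_code = cohort, donor_id = donor, variant_type = type,
             sv_id = sv, chrom1 = chrom1, start1 = pos1, end1 = pos1 + 1,
             strand1 = "+", chrom2 = chrom2, start2 = pos2, end2 = pos2 + 1,
             strand2 = "-", stringsAsFactors = FALSE)
}

# Write a 1-based 12-column SV table file from rows given in 1-based coords.
write_sv_file <- function(rows, path) {
  header <- c("cohort_code", "donor_id", "variant_type", "sv_id",
              "chr_from", "chr_from_bkpt_start", "chr_from_bkpt_end",
              "chr_from_strand", "chr_to", "chr_to_bkpt_start",
              "chr_to_bkpt_end", "chr_to_strand")
  lines <- c(paste(header, collapse = "\t"),
             vapply(rows, function(r) paste(r, collapse = "\t"), ""))
  writeLines(lines, path)
  path
}

# A small binary/factor/numeric track built in memory.
toy_track <- function(kind, chrom, start, end, value, name = "toy",
                      levels = NULL) {
  interval_track(name, kind, chrom, start, end, value, levels = levels)
}

# Compact simulation config for pipeline-level tests (smaller than the
# default study conditions so each scan stays fast).
small_sim_config <- function(seed, drivers = NULL, ...) {
  sim_config(seed = seed,
             chrom_lengths = stats::setNames(rep(1.2e7, 6),
                                             paste0("chr", 1:6)),
             n_donors = 80L, mean_svs = 30, drivers = drivers, ...)
}

# Linear-scan oracle for point-in-interval lookup.
lookup_oracle <- function(track, chrom, pos) {
  iv <- track$intervals
  vapply(seq_along(pos), function(i) {
    hit <- which(iv$chrom == chrom[i] & iv$start <= pos[i] & pos[i] < iv$end)
    if (length(hit)) as.character(iv$value[hit[1L]]) else NA_character_
  }, character(1))
}
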