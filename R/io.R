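#' Read a cohort SV call table
#'
#' Parses the 12-column tab-separated somatic structural-variant table used as
#' the main pipeline input. Each row describes one SV by cohort code, donor,
#' variant type, SV id and the two breakend coordinates
#' (`chr_from`/`chr_to` blocks of chrom, start, end, strand). Input
#' coordinates are taken as 1-based inclusive and converted to the internal
#' 0-based half-open convention on read; the breakend point position used
#' downstream is the (converted) start coordinate.
#'
#' Rows with a breakend on a chromosome other than chr1..chr22 or chrX are
#' dropped; the number of dropped rows is recorded in the `"n_dropped"`
#' attribute of the result.
#'
#' @param path Path to a tab-separated file with a header row and 12 columns.
#' @param cohort_filter Optional cohort code; when given, only rows of that
#'   cohort are kept (before the chromosome filter).
#' @return A `data.frame` with one row per retained SV and columns
#'   `cohort_code`, `donor_id`, `variant_type`, `sv_id`, `chrom1`, `start1`,
#'   `end1`, `strand1`, `chrom2`, `start2`, `end2`, `strand2`; positions are
#'   0-based half-open. Attribute `n_dropped` counts rows removed by the
#'   chromosome filter.
#' @seealso [sv_to_breakpoints()], [read_bedpe()]
#' @export
read_sv_table <- function(path, cohort_filter = NULL) {
  if (!file.exists(path)) stop("SV table not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (ncol(raw) != 12L) {
    stop("SV table must have exactly 12 tab-separated columns, found ",
         ncol(raw), " in ", path)
  }
  names(raw) <- c("cohort_code", "donor_id", "variant_type", "sv_id",
                  "chrom1", "start1", "end1", "strand1",
                  "chrom2", "start2", "end2", "strand2")
  .finish_sv_table(raw, cohort_filter, path)
}

#' Read an SV table in BEDPE layout
#'
#' Alternate reader mapping the 10+ column BEDPE convention
#' (chrom1, start1, end1, chrom2, start2, end2, name, score, strand1, strand2)
#' onto the same record layout as [read_sv_table()]. BEDPE coordinates are
#' already 0-based half-open and are kept as-is. The `name` column supplies
#' the SV id; `score` is ignored. Donor and variant type are taken from two
#' extra columns (`donor_id`, `variant_type`) when present, otherwise filled
#' with `"NA"` / `"DEL"`.
#'
#' @inheritParams read_sv_table
#' @param cohort_code Cohort code to assign to all records.
#' @return Same layout as [read_sv_table()].
#' @export
read_bedpe <- function(path, cohort_code = "cohort", cohort_filter = NULL) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) < 10L) stop("BEDPE input needs >= 10 columns, found ", ncol(raw))
  out <- data.frame(
    cohort_code = cohort_code,
    donor_id = if (ncol(raw) >= 11L) as.character(raw[[11L]]) else "NA",
    variant_type = if (ncol(raw) >= 12L) as.character(raw[[12L]]) else "DEL",
    sv_id = as.character(raw[[7L]]),
    chrom1 = as.character(raw[[1L]]), start1 = raw[[2L]], end1 = raw[[3L]],
    strand1 = as.character(raw[[9L]]),
    chrom2 = as.character(raw[[4L]]), start2 = raw[[5L]], end2 = raw[[6L]],
    strand2 = as.character(raw[[10L]]),
    stringsAsFactors = FALSE)
  .finish_sv_table(out, cohort_filter, path, convert_coords = FALSE)
}

# Shared validation/filtering; convert_coords turns 1-based inclusive input
# into the internal 0-based half-open convention.
.finish_sv_table <- function(df, cohort_filter, path, convert_coords = TRUE) {
  for (col in c("start1", "end1", "start2", "end2")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("Non-numeric coordinate in column '", col, "' at data line ", bad,
           " of ", path)
    }
    df[[col]] <- v
  }
  if (!is.null(cohort_filter)) {
    df <- df[df$cohort_code == cohort_filter, , drop = FALSE]
  }
  if (convert_coords) {
    df$start1 <- df$start1 - 1
    df$start2 <- df$start2 - 1
  }
  bad_span <- df$start1 > df$end1 | df$start2 > df$end2
  if (any(bad_span)) {
    stop("Breakend start > end at data line ", which(bad_span)[1L], " of ", path)
  }
  keep <- df$chrom1 %in% .ALLOWED_CHROMS & df$chrom2 %in% .ALLOWED_CHROMS
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  df
}

#' Decompose SV records into a sorted breakpoint table
#'
#' Every SV record contributes exactly two breakpoints, one per breakend, at
#' the breakend point coordinate. Identical coordinates across donors are
#' retained (each donor's breakpoint is represented separately), so recurrent
#' positions appear multiple times. Output is sorted per chromosome by
#' position with the deterministic tie order (position, donor_id, sv_id).
#'
#' @param records SV record table from [read_sv_table()].
#' @return A `data.frame` with columns `chrom`, `pos`, `donor_id`, `sv_id`,
#'   `variant_type`, `breakend` (1 or 2), sorted by (chrom, pos, donor_id,
#'   sv_id, breakend).
#' @export
sv_to_breakpoints <- function(records) {
  bp <- data.frame(
    chrom = c(records$chrom1, records$chrom2),
    pos = c(records$start1, records$start2),
    donor_id = rep(records$donor_id, 2L),
    sv_id = rep(records$sv_id, 2L),
    variant_type = rep(records$variant_type, 2L),
    breakend = rep(c(1L, 2L), each = nrow(records)),
    stringsAsFactors = FALSE)
  ord <- order(bp$chrom, bp$pos, bp$donor_id, bp$sv_id, bp$breakend,
               method = "radix")
  bp <- bp[ord, , drop = FALSE]
  rownames(bp) <- NULL
  bp
}

#' Read a BED-like interval track
#'
#' Reads BED3 (binary presence track), BED4/bedGraph (factor or numeric
#' values) files into the internal track container. Coordinates are taken as
#' 0-based half-open, the BED convention. Unsorted input is sorted with a
#' warning; zero- or negative-length intervals are an error.
#'
#' @param path BED-like file, 3 or more tab-separated columns, no header.
#' @param kind One of `"binary"` (value 1 on every interval), `"numeric"`
#'   (column 4 coerced to numeric) or `"factor"` (column 4 as label).
#' @param name Track name; defaults to the file name without extension.
#' @param levels Declared label set for a factor track; defaults to the
#'   observed labels. Labels outside the declared set are an error.
#' @return An object of class `interval_track`: a list with `name`, `kind`,
#'   `levels` (factor tracks) and `intervals` (data.frame chrom/start/end/value
#'   sorted within chromosome).
#' @export
read_interval_track <- function(path, kind = c("binary", "numeric", "factor"),
                                name = NULL, levels = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("Track file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) < 3L) stop("Track file needs >= 3 columns: ", path)
  if (kind != "binary" && ncol(raw) < 4L) {
    stop("A ", kind, " track needs a 4th value column: ", path)
  }
  value <- switch(kind,
    binary = rep(1, nrow(raw)),
    numeric = suppressWarnings(as.numeric(raw[[4L]])),
    factor = as.character(raw[[4L]]))
  if (kind == "numeric" && anyNA(value)) {
    stop("Non-numeric value in numeric track ", path)
  }
  interval_track(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
                 kind = kind,
                 chrom = as.character(raw[[1L]]),
                 start = as.numeric(raw[[2L]]), end = as.numeric(raw[[3L]]),
                 value = value, levels = levels)
}

#' Construct an interval track in memory
#'
#' @param name Track name.
#' @param kind `"binary"`, `"numeric"` or `"factor"`.
#' @param chrom,start,end,value Parallel interval vectors (0-based half-open).
#' @param levels Declared label set for factor tracks.
#' @return An `interval_track` object.
#' @export
interval_track <- function(name, kind, chrom, start, end, value,
                           levels = NULL) {
  if (any(start >= end)) {
    stop("Track '", name, "': intervals must have positive length ",
         "(start < end), offending interval at row ",
         which(start >= end)[1L])
  }
  iv <- data.frame(chrom = chrom, start = start, end = end, value = value,
                   stringsAsFactors = FALSE)
  ord <- order(iv$chrom, iv$start, method = "radix")
  if (is.unsorted(ord)) {
    warning("Track '", name, "': intervals were unsorted; sorting")
  }
  iv <- iv[ord, , drop = FALSE]
  rownames(iv) <- NULL
  if (kind == "factor") {
    obs <- unique(iv$value)
    if (is.null(levels)) levels <- obs
    if (!all(obs %in% levels)) {
      stop("Track '", name, "': labels outside declared level set: ",
           paste(setdiff(obs, levels), collapse = ", "))
    }
    # Overlap inside a chromosome is ambiguous for a factor value.
    by_chr <- split(iv, iv$chrom)
    for (ch in names(by_chr)) {
      s <- by_chr[[ch]]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)])) {
        stop("Track '", name, "': overlapping intervals in factor track on ", ch)
      }
    }
  }
  structure(list(name = name, kind = kind, levels = levels, intervals = iv),
            class = "interval_track")
}

#' @export
print.interval_track <- function(x, ...) {
  cat("interval_track '", x$name, "' (", x$kind, "): ",
      nrow(x$intervals), " intervals on ",
      length(unique(x$intervals$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Write an interval track to a BED/bedGraph file
#'
#' @param track An `interval_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interval_track <- function(track, path) {
  iv <- track$intervals
  df <- if (track$kind == "binary") iv[c("chrom", "start", "end")] else iv
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write SV records as a 12-column SV table
#'
#' Inverse of [read_sv_table()]: internal 0-based half-open coordinates are
#' converted back to the 1-based inclusive convention of the external
#' format.
#'
#' @param records SV record table in the internal layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(records, path) {
  out <- records
  out$start1 <- format(out$start1 + 1, scientific = FALSE, trim = TRUE)
  out$start2 <- format(out$start2 + 1, scientific = FALSE, trim = TRUE)
  out$end1 <- format(out$end1, scientific = FALSE, trim = TRUE)
  out$end2 <- format(out$end2, scientific = FALSE, trim = TRUE)
  names(out) <- c("cohort_code", "donor_id", "variant_type", "sv_id",
                  "chr_from", "chr_from_bkpt_start", "chr_from_bkpt_end",
                  "chr_from_strand", "chr_to", "chr_to_bkpt_start",
                  "chr_to_bkpt_end", "chr_to_strand")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write pipeline result tables
#'
#' Writes the peak catalog and the element-score table as TSV files, plus a
#' JSON run manifest (parameters, seed, input checksums, per-chromosome
#' inclusion log) so a run can be audited and reproduced.
#'
#' @param scan An `sv_scan` result from [scan_sv_drivers()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(scan, dir) {
  stopifnot(inherits(scan, "sv_scan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  peak_path <- file.path(dir, "peaks.tsv")
  elem_path <- file.path(dir, "elements.tsv")
  man_path <- file.path(dir, "manifest.json")
  .write_tsv(scan$peaks, peak_path)
  .write_tsv(scan$elements, elem_path)
  jsonlite::write_json(scan$manifest, man_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(c(peaks = peak_path, elements = elem_path, manifest = man_path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}
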