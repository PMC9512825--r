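#' Look up track values at point positions
#'
#' Point-in-interval lookup: for each (chrom, pos) query, returns the value
#' of the interval containing the point (half-open convention), or `NA` when
#' the point lies in no interval. Lookup is a binary search over the sorted
#' interval starts of each chromosome.
#'
#' @param track An `interval_track`.
#' @param chrom,pos Parallel query vectors.
#' @return Vector of values (numeric for binary/numeric tracks, character for
#'   factor tracks) with `NA` for uncovered points.
#' @export
track_lookup <- function(track, chrom, pos) {
  iv <- track$intervals
  out <- rep(if (track$kind == "factor") NA_character_ else NA_real_,
             length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    s <- iv[iv$chrom == ch, , drop = FALSE]
    if (!nrow(s)) next
    idx <- findInterval(pos[sel], s$start)
    hit <- idx >= 1L & pos[sel] < s$end[pmax(idx, 1L)]
    vals <- out[sel]
    vals[hit] <- s$value[idx[hit]]
    out[sel] <- vals
  }
  out
}

#' GC content in a centered window
#'
#' Fraction of G+C among non-N bases in a `window`-bp window centered at each
#' position (default 101 bp). Windows are clipped at sequence ends; windows
#' containing only Ns give `NA`.
#'
#' @param sequences A named `Biostrings::DNAStringSet` (names = chromosomes)
#'   or a named character vector of sequences.
#' @param chrom,pos Parallel query vectors (0-based positions).
#' @param window Window width in bp (odd, default 101).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
gc_content <- function(sequences, chrom, pos, window = 101L) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  half <- (window - 1L) %/% 2L
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    if (!ch %in% names(sequences)) next
    seq_len_ch <- Biostrings::width(sequences[ch])
    sel <- which(chrom == ch)
    from <- pmax(pos[sel] - half + 1L, 1L)        # 1-based subseq bounds
    to <- pmin(pos[sel] + half + 1L, seq_len_ch)
    views <- Biostrings::extractAt(sequences[[ch]],
                                   IRanges::IRanges(from, to))
    freq <- Biostrings::alphabetFrequency(views, baseOnly = TRUE)
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- rowSums(freq[, c("C", "G"), drop = FALSE])
    out[sel] <- ifelse(acgt > 0, gc / acgt, NA_real_)
  }
  out
}

#' Gene density at point positions
#'
#' Number of genes overlapping the fixed-width bin (default 1 Mb) containing
#' each query position. A gene spanning several bins is counted in each of
#' them.
#'
#' @param genes Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open gene intervals).
#' @param chrom,pos Parallel query vectors.
#' @param binsize Bin width in bp (default 1e6).
#' @return Numeric vector: genes per bin at each query.
#' @export
gene_density <- function(genes, chrom, pos, binsize = 1e6) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    bin_start <- floor(pos[sel] / binsize) * binsize
    qr <- IRanges::IRanges(start = bin_start + 1, width = binsize)
    gr <- IRanges::IRanges(start = g$start + 1, end = g$end)
    out[sel] <- IRanges::countOverlaps(qr, gr)
  }
  out
}

#' Annotate breakpoints with the model covariates
#'
#' Assembles one covariate row per breakpoint from a set of interval tracks.
#' Binary tracks give 0/1 (absent interval = 0), factor tracks give the label
#' at the point (uncovered points get the declared reference level, counted),
#' numeric tracks give the value at the point (uncovered points are imputed
#' to the track median, counted). Missingness per covariate is reported in
#' the `"missingness"` attribute.
#'
#' @param breakpoints Breakpoint table (`chrom`, `pos` columns).
#' @param tracks Named list of `interval_track` objects; names become
#'   covariate column names.
#' @param reference Named list of reference levels for factor tracks
#'   (default: `"none"`, or the first declared level when `"none"` is not
#'   declared).
#' @param numeric_fill Named list of fallback values for numeric tracks
#'   (default: median of covered values; tracks named `TAD_recurr` or
#'   `TADB_recurr` fall back to 0, the outside-TAD convention).
#' @return `data.frame` of covariates aligned with `breakpoints`; factor
#'   columns are R factors over the declared level sets.
#' @export
annotate_breakpoints <- function(breakpoints, tracks, reference = list(),
                                 numeric_fill = list()) {
  n <- nrow(breakpoints)
  out <- list()
  missing_n <- integer(0)
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    v <- track_lookup(tr, breakpoints$chrom, breakpoints$pos)
    n_miss <- sum(is.na(v))
    if (tr$kind == "binary") {
      v[is.na(v)] <- 0
      n_miss <- 0L                       # absence is informative, not missing
      out[[nm]] <- as.numeric(v)
    } else if (tr$kind == "factor") {
      lev <- tr$levels
      ref <- reference[[nm]]
      if (is.null(ref)) ref <- if ("none" %in% lev) "none" else lev[1L]
      if (!ref %in% lev) lev <- c(lev, ref)
      v[is.na(v)] <- ref
      out[[nm]] <- factor(v, levels = unique(c(ref, lev)))
    } else {
      fill <- numeric_fill[[nm]]
      if (is.null(fill)) {
        fill <- if (nm %in% c("TAD_recurr", "TADB_recurr")) 0 else
          stats::median(v, na.rm = TRUE)
      }
      v[is.na(v)] <- fill
      out[[nm]] <- v
    }
    missing_n[nm] <- n_miss
  }
  res <- as.data.frame(out, check.names = FALSE)
  if (!nrow(res)) res <- data.frame(row.names = seq_len(n))
  attr(res, "missingness") <- missing_n
  res
}
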