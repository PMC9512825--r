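#' Breakpoint neighbor reachability
#'
#' For each breakpoint in a position-sorted chromosome, the neighbor
#' reachability is the mean genomic distance to its two flanking neighbors,
#' `(d(i, i-1) + d(i, i+1)) / 2`. The first and last breakpoints have a
#' single neighbor and use that one-sided distance, which keeps the output
#' aligned 1:1 with the input and retains telomeric signal.
#'
#' @param pos Numeric vector of breakpoint positions, sorted non-decreasing.
#' @return Numeric vector of neighbor-reachability distances (bp), same
#'   length as `pos`.
#' @examples
#' compute_bpnr(c(100, 200, 500))  # 100, 200, 300
#' @export
compute_bpnr <- function(pos) {
  n <- length(pos)
  if (n < 2L) stop("neighbor reachability needs at least 2 breakpoints")
  if (is.unsorted(pos)) stop("breakpoint positions must be sorted")
  d <- diff(pos)
  bpnr <- numeric(n)
  bpnr[1L] <- d[1L]
  bpnr[n] <- d[n - 1L]
  if (n > 2L) bpnr[2:(n - 1L)] <- (d[-(n - 1L)] + d[-1L]) / 2
  bpnr
}

#' Proximity transform
#'
#' Maps a neighbor-reachability distance onto the reverse-scale proximity
#' value `-log10(bpnr + 1)`: zero distance maps to 0, larger distances to
#' increasingly negative values, so that tight breakpoint clusters become
#' peaks after smoothing.
#'
#' @param bpnr Non-negative distances (bp).
#' @return `-log10(bpnr + 1)`, same length.
#' @export
proximity_transform <- function(bpnr) {
  if (any(bpnr < 0)) stop("neighbor reachability must be non-negative")
  -log10(bpnr + 1)
}

#' Fit the breakpoint proximity curve
#'
#' Smooths per-breakpoint proximity values along one chromosome with local
#' polynomial regression (LOESS, degree 2, tricube weights, no robustness
#' iterations), evaluated at the breakpoint positions themselves. The span is
#' the fraction of breakpoints in each local neighborhood. Chromosomes with
#' fewer than `min_points` breakpoints cannot be smoothed reliably and are
#' rejected; the pipeline skips them.
#'
#' @param pos Breakpoint positions (sorted).
#' @param bpp Proximity values aligned with `pos`.
#' @param span_alpha LOESS span as a fraction of points (default 0.2).
#' @param min_points Minimum number of points required (default 100).
#' @param chrom Chromosome label stored with the curve.
#' @param exact Use the exact LOESS surface (default). The interpolating
#'   kd-tree approximation evaluates the local fit only at cell vertices and
#'   erases clusters narrower than a cell, which is precisely the signal of
#'   interest, so it is only offered for quick exploratory passes.
#' @return A `proximity_curve`: list with `chrom`, `positions`, `observed`
#'   (input values), `smoothed` and `span_alpha`.
#' @export
fit_bppc <- function(pos, bpp, span_alpha = 0.2, min_points = 100L,
                     chrom = NA_character_, exact = TRUE) {
  n <- length(pos)
  if (n != length(bpp)) stop("pos and bpp must be aligned")
  if (n < min_points) {
    stop("chromosome has ", n, " breakpoints (< ", min_points,
         "); proximity cannot be modeled reliably")
  }
  if (span_alpha <= 0 || span_alpha > 1) stop("span_alpha must be in (0, 1]")
  fit <- stats::loess(bpp ~ pos,
                      data = data.frame(pos = pos, bpp = bpp),
                      span = span_alpha, degree = 2, family = "gaussian",
                      control = stats::loess.control(
                        surface = if (exact) "direct" else "interpolate",
                        statistics = "none"))
  structure(list(chrom = chrom, positions = pos, observed = bpp,
                 smoothed = as.numeric(stats::fitted(fit)),
                 span_alpha = span_alpha),
            class = "proximity_curve")
}

#' @export
print.proximity_curve <- function(x, ...) {
  cat("proximity_curve on ", x$chrom, ": ", length(x$positions),
      " breakpoints, span ", x$span_alpha, "\n", sep = "")
  cat("  smoothed range [", round(min(x$smoothed), 3), ", ",
      round(max(x$smoothed), 3), "]\n", sep = "")
  invisible(x)
}

#' @export
plot.proximity_curve <- function(x, ...) {
  graphics::plot(x$positions, x$observed, pch = ".", col = "grey60",
                 xlab = paste0("position on ", x$chrom),
                 ylab = "breakpoint proximity", ...)
  graphics::lines(x$positions, x$smoothed, col = "red3", lwd = 2)
  invisible(x)
}

#' Export a proximity curve as bedGraph
#'
#' Writes `positions`/`smoothed` as single-bp bedGraph records for genome
#' browser inspection.
#'
#' @param curve A `proximity_curve`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_bppc_bedgraph <- function(curve, path) {
  df <- data.frame(chrom = curve$chrom,
                   start = format(curve$positions, scientific = FALSE, trim = TRUE),
                   end = format(curve$positions + 1, scientific = FALSE, trim = TRUE),
                   value = curve$smoothed)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-chromosome proximity curves for a breakpoint table
#'
#' Convenience wrapper running [compute_bpnr()], [proximity_transform()] and
#' [fit_bppc()] for every chromosome with enough breakpoints. Chromosomes
#' below the reliability threshold are skipped and recorded.
#'
#' @param breakpoints Breakpoint table from [sv_to_breakpoints()].
#' @param span_alpha LOESS span (fraction of points).
#' @param min_points Minimum breakpoints per chromosome (default 100).
#' @return List with `curves` (named list of `proximity_curve`), `breakpoints`
#'   (the rows belonging to modeled chromosomes, with `bpnr` and `bpp`
#'   columns appended) and `skipped` (named integer vector of breakpoint
#'   counts of excluded chromosomes).
#' @export
proximity_curves <- function(breakpoints, span_alpha = 0.2,
                             min_points = 100L) {
  by_chr <- split(breakpoints, breakpoints$chrom)
  curves <- list()
  kept <- list()
  skipped <- integer(0)
  for (ch in names(by_chr)) {
    b <- by_chr[[ch]]
    if (nrow(b) < min_points) {
      skipped[ch] <- nrow(b)
      next
    }
    bpnr <- compute_bpnr(b$pos)
    bpp <- proximity_transform(bpnr)
    b$bpnr <- bpnr
    b$bpp <- bpp
    curves[[ch]] <- fit_bppc(b$pos, bpp, span_alpha = span_alpha,
                             min_points = min_points, chrom = ch)
    kept[[ch]] <- b
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " chromosome(s) with < ", min_points,
            " breakpoints: ", paste(names(skipped), collapse = ", "))
  }
  list(curves = curves,
       breakpoints = do.call(rbind, c(kept, list(make.row.names = FALSE))),
       skipped = skipped)
}
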