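#' Adjusted proximity curve
#'
#' Pointwise difference between the observed smoothed proximity curve and
#' the expected curve from the background model, on the same breakpoint
#' support. Positive values mark regions where breakpoints are closer than
#' expected; negative values, sparser.
#'
#' @param observed A `proximity_curve`.
#' @param expected Numeric vector of expected proximity values aligned with
#'   `observed$positions`.
#' @return An `adjusted_curve`: list with `chrom`, `positions`, `values`.
#' @export
adjust_curve <- function(observed, expected) {
  stopifnot(inherits(observed, "proximity_curve"))
  if (length(expected) != length(observed$positions)) {
    stop("expected values not aligned with the observed curve")
  }
  structure(list(chrom = observed$chrom, positions = observed$positions,
                 values = observed$smoothed - expected),
            class = "adjusted_curve")
}

#' @export
print.adjusted_curve <- function(x, ...) {
  cat("adjusted_curve on ", x$chrom, ": ", length(x$positions), " points, ",
      sum(x$values > 0), " above expectation\n", sep = "")
  invisible(x)
}

#' Call peaks on an adjusted curve
#'
#' Positive excursions of the adjusted curve (maximal runs of consecutive
#' positive values between zero-crossings) are segmented; within each
#' excursion the summit is the maximum, and the reported peak region is the
#' maximal contiguous run around the summit where the curve stays at or
#' above `summit_frac` (default 75%) of the summit height — the "top of the
#' summit" region of local maximum clustering. The peak area is the
#' trapezoidal integral of the curve over the region with respect to
#' genomic position, in value x Mb units.
#'
#' Excursions whose summit region contains a single curve point have no
#' measurable genomic extent or area and are discarded.
#'
#' @param adjusted An `adjusted_curve`.
#' @param summit_frac Fraction of summit height defining the region
#'   (default 0.75).
#' @return Data frame with one row per peak: `chrom`, `start`, `end` (the
#'   summit region), `exc_start`, `exc_end` (the full positive excursion,
#'   the peak's genomic footprint used for element association),
#'   `summit_pos`, `summit_height`, `peak_gr` (genomic range, bp), `peak_a`
#'   (area), ordered left to right. Zero rows when the curve never rises
#'   above zero.
#' @export
call_peaks <- function(adjusted, summit_frac = 0.75) {
  stopifnot(inherits(adjusted, "adjusted_curve"))
  v <- adjusted$values
  p <- adjusted$positions
  pos_run <- v > 0
  if (!any(pos_run)) return(.empty_peaks())
  r <- rle(pos_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    seg <- i0:i1
    s_rel <- which.max(v[seg])
    summit <- seg[s_rel]
    thr <- summit_frac * v[summit]
    # expand from the summit while the curve stays above the threshold
    lo <- summit
    while (lo > i0 && v[lo - 1L] >= thr) lo <- lo - 1L
    hi <- summit
    while (hi < i1 && v[hi + 1L] >= thr) hi <- hi + 1L
    region <- lo:hi
    if (length(region) < 2L || p[hi] <= p[lo]) next  # degenerate blip
    area <- sum(diff(p[region]) * (utils::head(v[region], -1L) +
                                     utils::tail(v[region], -1L)) / 2) / 1e6
    out[[length(out) + 1L]] <- data.frame(
      chrom = adjusted$chrom, start = p[lo], end = p[hi],
      exc_start = p[i0], exc_end = p[i1],
      summit_pos = p[summit], summit_height = v[summit],
      peak_gr = p[hi] - p[lo], peak_a = area)
  }
  if (!length(out)) return(.empty_peaks())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_peaks <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             exc_start = numeric(), exc_end = numeric(),
             summit_pos = numeric(), summit_height = numeric(),
             peak_gr = numeric(), peak_a = numeric())
}

#' Count donors, SVs and breakpoints inside peak regions
#'
#' @param peaks Peak table from [call_peaks()].
#' @param breakpoints Breakpoint table with `chrom`, `pos`, `donor_id`,
#'   `sv_id`.
#' @return `peaks` with `n_smp`, `n_sv`, `n_bp` columns appended (counts
#'   over the peak region, inclusive of its bounds).
#' @export
count_peak_support <- function(peaks, breakpoints) {
  n <- nrow(peaks)
  peaks$n_smp <- peaks$n_sv <- peaks$n_bp <- integer(n)
  for (i in seq_len(n)) {
    inb <- breakpoints$chrom == peaks$chrom[i] &
      breakpoints$pos >= peaks$start[i] & breakpoints$pos <= peaks$end[i]
    peaks$n_bp[i] <- sum(inb)
    peaks$n_smp[i] <- length(unique(breakpoints$donor_id[inb]))
    peaks$n_sv[i] <- length(unique(breakpoints$sv_id[inb]))
  }
  peaks
}

#' Peak recurrence score
#'
#' `PRs = (Nsmp / Nsv) x (Peak_A / Peak_GR)`: highest for peaks where many
#' donors contribute few distinct SVs forming a tight cluster (large area)
#' over a narrow region. The square-root transform reduces dispersion while
#' keeping the ordering.
#'
#' @param n_smp,n_sv Unique donors and unique SVs in the peak region.
#' @param peak_a,peak_gr Peak area and genomic range.
#' @return List with `prs` and `prs_sqrt`, vectorized over peaks.
#' @export
peak_recurrence_score <- function(n_smp, n_sv, peak_a, peak_gr) {
  if (any(n_sv == 0)) stop("peak with no SVs; PRs undefined")
  if (any(peak_gr <= 0)) stop("peak with non-positive genomic range")
  prs <- (n_smp / n_sv) * (peak_a / peak_gr)
  list(prs = prs, prs_sqrt = sqrt(prs))
}

#' Fit the cohort-wide Gamma null to peak scores
#'
#' Maximum-likelihood Gamma fit to the cohort's score distribution
#' (square-root peak recurrence scores, or single-sample scores). Each
#' peak's p-value is the upper-tail probability under the fitted Gamma.
#' Fewer than `min_peaks` scores do not support a stable fit and return
#' `NULL` with a warning.
#'
#' @param scores Positive score values, one per peak.
#' @param min_peaks Minimum number of peaks (default 10).
#' @return List with `shape`, `rate`, `n_peaks` and `p_values`, or `NULL`.
#' @export
fit_gamma_null <- function(scores, min_peaks = 10L) {
  if (length(scores) < min_peaks) {
    warning("only ", length(scores), " peaks; Gamma null not fitted")
    return(NULL)
  }
  if (stats::sd(scores) == 0) stop("degenerate scores (all equal)")
  if (any(scores <= 0)) stop("scores must be positive for a Gamma fit")
  m <- mean(scores); v <- stats::var(scores)
  start <- list(shape = m^2 / v, rate = m / v)  # moment start for the MLE
  fd <- fitdistrplus::fitdist(scores, "gamma", method = "mle", start = start,
                              control = list(maxit = 1000))
  shape <- unname(fd$estimate["shape"])
  rate <- unname(fd$estimate["rate"])
  list(shape = shape, rate = rate, n_peaks = length(scores),
       p_values = stats::pgamma(scores, shape = shape, rate = rate,
                                lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up q-values with a significance flag at the given FDR
#' threshold (default 0.2).
#'
#' @param p_values P-values in `[0, 1]`.
#' @param threshold FDR threshold for the flag.
#' @return List with `q_values` and logical `significant`.
#' @export
benjamini_hochberg <- function(p_values, threshold = 0.2) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, significant = !is.na(q) & q < threshold)
}

#' Single-sample rearrangement score
#'
#' `SSRs = N_BP / Nsmp`, the mean breakpoint contribution per donor in a
#' peak. The cohort's SSRs distribution is tested with the same Gamma +
#' Benjamini-Hochberg machinery to flag peaks whose breakpoint load comes
#' from fewer donors than expected; peaks supported by at most two donors
#' are flagged `single_or_two_sample` regardless.
#'
#' @param n_bp,n_smp Breakpoint and donor counts per peak.
#' @param threshold FDR threshold (default 0.2).
#' @return List with `ssrs`, `p_values`, `q_values`,
#'   `single_sample_significant` and `single_or_two_sample` (all vectors
#'   aligned with the input; p/q are `NA` when the Gamma null is not
#'   fitted).
#' @export
single_sample_score <- function(n_bp, n_smp, threshold = 0.2) {
  if (any(n_smp == 0)) stop("peak with no donors; SSRs undefined")
  ssrs <- n_bp / n_smp
  nn <- length(ssrs)
  p <- q <- rep(NA_real_, nn)
  sig <- rep(FALSE, nn)
  null <- if (stats::sd(ssrs) > 0) fit_gamma_null(ssrs) else NULL
  if (!is.null(null)) {
    p <- null$p_values
    bh <- benjamini_hochberg(p, threshold)
    q <- bh$q_values
    sig <- bh$significant
  }
  list(ssrs = ssrs, p_values = p, q_values = q,
       single_sample_significant = sig,
       single_or_two_sample = n_smp <= 2)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Without continuity correction (df = 1), as used to compare
#' cancer-type-specific versus multi-cancer peak counts between methods.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_squared_2x2(matrix(c(16, 25, 26, 7), 2))  # p ~ 0.0006
#' @export
chi_squared_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin; chi-squared undefined")
  }
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
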