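#' Background hit probability for a peak
#'
#' Probability that one donor carries at least one background SV in a peak
#' of length `L` megabases: `p0 = 1 - (1 - mu * f_p)^L`, where `mu` is the
#' cohort-average SV rate per Mb per donor and `f_p` the peak breakpoint
#' rate factor (local enrichment over the genome-wide rate).
#'
#' @param mu Average SV rate per Mb per donor.
#' @param f_p Peak breakpoint rate factor (dimensionless).
#' @param L Peak genomic length in Mb.
#' @return `p0` in `[0, 1]`.
#' @export
background_hit_prob <- function(mu, f_p, L) {
  if (any(mu < 0) || any(f_p < 0)) stop("mu and f_p must be non-negative")
  if (any(mu * f_p > 1)) stop("mu * f_p must not exceed 1")
  1 - (1 - mu * f_p)^L
}

#' Alternative hit probability under a driver
#'
#' `p1 = 1 - (1 - p0) * (1 - r * s)`: a donor hits the peak either through
#' the background or through the driver event of prevalence `r` detected
#' with sensitivity `s`.
#'
#' @param p0 Background hit probability.
#' @param r Driver prevalence fraction.
#' @param s Detection sensitivity fraction.
#' @return `p1` in `[0, 1]`.
#' @export
alternative_hit_prob <- function(p0, r, s) {
  stopifnot(all(p0 >= 0 & p0 <= 1), all(r >= 0 & r <= 1),
            all(s >= 0 & s <= 1))
  1 - (1 - p0) * (1 - r * s)
}

#' Detection power for a recurrent peak
#'
#' Power at cohort size `n` is the binomial tail probability
#' `P(Binomial(n, p1) >= m_min)` of seeing at least `m_min` recurrent
#' donors; `n_90` is the smallest cohort size reaching 90% power.
#'
#' @param mu,f_p,L Background model parameters (see
#'   [background_hit_prob()]).
#' @param r Driver prevalence fraction.
#' @param s Detection sensitivity (default 0.9).
#' @param n Cohort size(s) at which to evaluate the power.
#' @param m_min Minimum recurrent-donor count defining a detectable peak
#'   (default 3).
#' @param power_target Power level for `n_90` (default 0.9).
#' @param n_max Search bound for `n_90` (default 1e5).
#' @return List with `p0`, `p1`, `power` (aligned with `n`) and `n_90`
#'   (`NA` when the target is unreachable below `n_max`).
#' @export
detection_power <- function(mu, f_p, L, r, s = 0.9, n = 100L, m_min = 3L,
                            power_target = 0.9, n_max = 1e5L) {
  stopifnot(m_min >= 1L)
  p0 <- background_hit_prob(mu, f_p, L)
  p1 <- alternative_hit_prob(p0, r, s)
  pow <- stats::pbinom(m_min - 1L, size = n, prob = p1, lower.tail = FALSE)
  n_90 <- NA_integer_
  if (p1 > 0) {
    # power is monotone in n; bisect on the integer grid
    lo <- m_min; hi <- n_max
    f <- function(nn) stats::pbinom(m_min - 1L, nn, p1, lower.tail = FALSE)
    if (f(hi) >= power_target) {
      while (lo < hi) {
        mid <- (lo + hi) %/% 2L
        if (f(mid) >= power_target) hi <- mid else lo <- mid + 1L
      }
      n_90 <- lo
    }
  }
  list(p0 = p0, p1 = p1, power = pow, n_90 = n_90)
}

#' Power-versus-cohort-size table
#'
#' Evaluates [detection_power()] over a grid of cohort sizes and driver
#' prevalences (default 2%, 5% and 25%), optionally across a range of peak
#' lengths to expose how peak geometry and the local breakpoint rate factor
#' trade off against cohort size.
#'
#' @param mu,f_p Background model parameters.
#' @param L Peak length(s) in Mb.
#' @param r Prevalence grid (default `c(0.02, 0.05, 0.25)`).
#' @param n Cohort-size grid.
#' @param s,m_min See [detection_power()].
#' @return Long-format data frame: `L`, `r`, `n`, `power`, `n_90`.
#' @export
power_curve <- function(mu, f_p, L, r = c(0.02, 0.05, 0.25),
                        n = seq(25L, 500L, by = 25L), s = 0.9, m_min = 3L) {
  out <- list()
  for (l in L) for (rr in r) {
    dp <- detection_power(mu, f_p, l, rr, s = s, n = n, m_min = m_min)
    out[[length(out) + 1L]] <- data.frame(L = l, r = rr, n = n,
                                          power = dp$power, n_90 = dp$n_90)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate power-model inputs from a scan
#'
#' `mu` is the mean SV count per donor divided by the effective genome
#' length (Mb of modeled chromosomes); `f_p` is the breakpoint rate inside
#' the top 2% of peaks (by summit height) relative to the genome-wide rate;
#' `L` is the median length of those top peaks in Mb.
#'
#' @param scan An `sv_scan` result.
#' @return List with `mu`, `f_p`, `L`.
#' @export
estimate_power_params <- function(scan) {
  stopifnot(inherits(scan, "sv_scan"))
  bp <- scan$breakpoints
  genome_mb <- sum(vapply(scan$curves, function(cv) {
    diff(range(cv$positions))
  }, numeric(1))) / 1e6
  n_donors <- length(unique(bp$donor_id))
  mu <- (nrow(bp) / 2) / n_donors / genome_mb
  pk <- scan$peaks
  if (!nrow(pk)) return(list(mu = mu, f_p = NA_real_, L = NA_real_))
  top <- pk[pk$summit_height >= stats::quantile(pk$summit_height, 0.98), ,
            drop = FALSE]
  rate_in <- sum(top$n_bp) / max(sum(top$peak_gr) / 1e6, 1e-9)
  rate_genome <- nrow(bp) / genome_mb
  list(mu = mu, f_p = rate_in / rate_genome,
       L = stats::median(top$peak_gr) / 1e6)
}
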