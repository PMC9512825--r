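#' Configuration for the synthetic SV cohort generator
#'
#' Defines the study conditions the simulator emulates: a compact genome
#' (default 16 chromosomes of 15 Mb) with autocorrelated covariate tracks,
#' donors whose background SV breakends are drawn from an inhomogeneous
#' intensity linked to the covariates, and injected driver loci carried by
#' a Bernoulli(prevalence) subset of donors with jittered breakends.
#'
#' @param seed Integer seed; the full output (tracks, cohort, elements) is
#'   reproducible byte-for-byte given the config.
#' @param n_donors Cohort size (default 200).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param mean_svs Mean background SVs per donor (Poisson, default 72).
#' @param coefficients Named vector linking covariates to the log (or
#'   identity) scale local breakpoint intensity.
#' @param link `"log"` (default) for a log-linear intensity, or
#'   `"identity"` for exact-recovery stress tests matching the analysis
#'   model's link.
#' @param type_probs Named probabilities of background SV types.
#' @param sv_size_meanlog,sv_size_sdlog Log-normal intra-chromosomal SV size
#'   parameters.
#' @param drivers Data frame of injected loci: `chrom`, `pos`, `prevalence`,
#'   `jitter_sd` (bp), `type`. `NULL` for a driver-free cohort. The default
#'   injects 5 deletion-dominant loci at 25% prevalence.
#' @param bin_bp Intensity discretization (default 10 kb).
#' @return A `sim_config` object.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 200L,
                       chrom_lengths = stats::setNames(rep(1.5e7, 16),
                                                       paste0("chr", 1:16)),
                       mean_svs = 72,
                       coefficients = c(RT = 0.06, GC = 0.4, LAD = 0.12,
                                        FS = 0.15, GeneDensity = 0.008,
                                        TAD_recurr = 0.1),
                       link = c("log", "identity"),
                       type_probs = c(DEL = 0.4, DUP = 0.2, h2hINV = 0.15,
                                      t2tINV = 0.15, TRA = 0.1),
                       sv_size_meanlog = log(5e4), sv_size_sdlog = 1,
                       drivers = default_drivers(),
                       bin_bp = 1e4) {
  link <- match.arg(link)
  if (!is.null(drivers)) {
    stopifnot(all(drivers$prevalence > 0 & drivers$prevalence <= 1))
    for (i in seq_len(nrow(drivers))) {
      stopifnot(drivers$pos[i] < chrom_lengths[[drivers$chrom[i]]])
    }
  }
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 chrom_lengths = chrom_lengths, mean_svs = mean_svs,
                 coefficients = coefficients, link = link,
                 type_probs = type_probs / sum(type_probs),
                 sv_size_meanlog = sv_size_meanlog,
                 sv_size_sdlog = sv_size_sdlog,
                 drivers = drivers, bin_bp = bin_bp),
            class = "sim_config")
}

#' Default injected driver loci
#'
#' Five deletion-dominant loci at 25% prevalence with 300 bp breakend
#' jitter (tight, fusion-like recurrent breakpoints), spread over five
#' chromosomes of the default genome.
#'
#' @return Data frame of driver loci.
#' @export
default_drivers <- function() {
  data.frame(chrom = c("chr1", "chr3", "chr5", "chr7", "chr9"),
             pos = c(8e6, 1.1e7, 4e6, 1.2e7, 7e6),
             prevalence = 0.25, jitter_sd = 300,
             type = c("DEL", "DEL", "DUP", "DEL", "DEL"),
             stringsAsFactors = FALSE)
}

# Piecewise-constant segments of exponential length covering [0, len).
.segment_genome <- function(len, mean_len) {
  n_guess <- ceiling(len / mean_len * 2) + 10L
  w <- stats::rexp(n_guess, rate = 1 / mean_len)
  while (sum(w) < len) w <- c(w, stats::rexp(n_guess, rate = 1 / mean_len))
  ends <- pmin(cumsum(w), len)
  ends <- ends[c(ends[-length(ends)] < len, TRUE)]
  ends <- unique(ceiling(ends))
  data.frame(start = c(0, utils::head(ends, -1L)), end = ends)
}

#' Simulate covariate tracks
#'
#' Generates the full covariate set consumed by the background model:
#' replication timing as a Gaussian random walk over 1 Mb bins, GC content
#' as a squashed random walk over 100 kb bins, gene density per 1 Mb bin,
#' sparse fragile-site intervals, LAD blocks from a two-state renewal
#' process, repeat-class and chromatin-state factor tracks from memoryless
#' label chains over exponential-length segments, a TAD partition with
#' Beta-distributed recurrence, TAD-boundary flanks with their own
#' recurrence, and a TAD-segment class track.
#'
#' @param config A [sim_config()].
#' @return Named list of `interval_track` objects (`RT`, `GC`,
#'   `GeneDensity`, `FS`, `LAD`, `repClass`, `ChromMark`, `TAD_recurr`,
#'   `TADB_recurr`, `TADsegm_class`).
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed * 7L + 1L, {
    chroms <- names(config$chrom_lengths)
    tr <- function(kind, name, rows, levels = NULL) {
      rows <- rows[order(rows$chrom, rows$start, method = "radix"), ]
      interval_track(name, kind, rows$chrom, rows$start, rows$end, rows$value,
                     levels = levels)
    }
    bins <- function(width) {
      do.call(rbind, lapply(chroms, function(ch) {
        len <- config$chrom_lengths[[ch]]
        s <- seq(0, len - 1, by = width)
        data.frame(chrom = ch, start = s, end = pmin(s + width, len))
      }))
    }
    # replication timing: random walk per chromosome, 1 Mb bins
    rt <- bins(1e6)
    rt$value <- unlist(lapply(chroms, function(ch) {
      n <- sum(rt$chrom == ch)
      cumsum(stats::rnorm(n, 0, 0.25))
    }))
    rt$value <- rt$value - mean(rt$value)
    # GC: squashed walk, 100 kb bins
    gc <- bins(1e5)
    gc$value <- unlist(lapply(chroms, function(ch) {
      n <- sum(gc$chrom == ch)
      w <- cumsum(stats::rnorm(n, 0, 0.15))
      0.30 + 0.30 * stats::plogis(w)
    }))
    # gene density: genes per 1 Mb bin
    gd <- bins(1e6)
    gd$value <- stats::rpois(nrow(gd), 8)
    # fragile sites: sparse ~1 Mb intervals
    fs <- do.call(rbind, lapply(chroms, function(ch) {
      len <- config$chrom_lengths[[ch]]
      n <- stats::rpois(1, len / 2e7)
      if (n == 0) n <- 1L   # keep the covariate exercised on every chrom
      s <- sort(stats::runif(n, 0, len - 1.5e6))
      data.frame(chrom = ch, start = floor(s), end = floor(s) + 1e6,
                 value = 1)
    }))
    # LAD: alternating in/out blocks
    lad <- do.call(rbind, lapply(chroms, function(ch) {
      seg <- .segment_genome(config$chrom_lengths[[ch]], 2.5e6)
      inlad <- seq_len(nrow(seg)) %% 2L == stats::rbinom(1, 1, 0.5)
      cbind(chrom = ch, seg[inlad, , drop = FALSE], value = 1)
    }))
    # factor tracks: label per exponential-length segment
    factor_track <- function(mean_len, labels, probs) {
      do.call(rbind, lapply(chroms, function(ch) {
        seg <- .segment_genome(config$chrom_lengths[[ch]], mean_len)
        seg$value <- sample(labels, nrow(seg), replace = TRUE, prob = probs)
        cbind(chrom = ch, seg)
      }))
    }
    rep_labels <- setdiff(REP_CLASSES, "none")
    rep_probs <- c(LTR = 0.12, LINE = 0.24, SINE = 0.24, LCR = 0.05,
                   simple = 0.12, rDNA = 0.04, `RNA-repeat` = 0.04,
                   satellite = 0.05, other = 0.05, unknown = 0.05)[rep_labels]
    repc <- factor_track(5e4, rep_labels, rep_probs)
    state_probs <- c(TssA = 0.04, TssAFlnk = 0.04, TxFlnk = 0.04, Tx = 0.08,
                     TxWk = 0.12, EnhG = 0.04, Enh = 0.06,
                     `ZNF/Rpts` = 0.04, Het = 0.09, TssBiv = 0.04,
                     BivFlnk = 0.04, EnhBiv = 0.04, ReprPC = 0.05,
                     ReprPCWk = 0.08, Quies = 0.20)
    chrm <- factor_track(2e4, CHROM_STATES, state_probs[CHROM_STATES])
    # TAD partition with Beta recurrence; boundary flanks; segment class
    tads <- do.call(rbind, lapply(chroms, function(ch) {
      seg <- .segment_genome(config$chrom_lengths[[ch]], 8e5)
      cbind(chrom = ch, seg)
    }))
    # recurrence is a fraction over a finite panel of reference samples, so
    # it lives on a discrete k/n grid shared across TADs
    n_panel <- 37L
    tads$value <- pmax(round(stats::rbeta(nrow(tads), 2, 1.2) * n_panel),
                       1) / n_panel
    bounds <- do.call(rbind, lapply(split(tads, tads$chrom), function(t) {
      e <- utils::head(t$end, -1L)     # internal boundaries only
      data.frame(chrom = t$chrom[1L], start = pmax(e - 5e4, 0), end = e + 5e4,
                 value = round(stats::rbeta(length(e), 1.5, 2.5) * n_panel) /
                   n_panel)
    }))
    bounds <- bounds[order(bounds$chrom, bounds$start), ]
    segcl <- tads
    segcl$value <- sample(c("quiescent", "low-active", "active"),
                          nrow(segcl), replace = TRUE,
                          prob = c(0.4, 0.35, 0.25))
    list(RT = tr("numeric", "RT", rt),
         GC = tr("numeric", "GC", gc),
         GeneDensity = tr("numeric", "GeneDensity", gd),
         FS = tr("binary", "FS", fs),
         LAD = tr("binary", "LAD", lad),
         repClass = tr("factor", "repClass", repc, levels = REP_CLASSES),
         ChromMark = tr("factor", "ChromMark", chrm, levels = CHROM_STATES),
         TAD_recurr = tr("numeric", "TAD_recurr", tads),
         TADB_recurr = tr("numeric", "TADB_recurr", bounds),
         TADsegm_class = tr("factor", "TADsegm_class", segcl,
                            levels = c("quiescent", "low-active", "active")))
  })
}

# Per-bin sampling intensity from the covariate link.
.bin_intensity <- function(config, covariates) {
  b <- do.call(rbind, lapply(names(config$chrom_lengths), function(ch) {
    len <- config$chrom_lengths[[ch]]
    s <- seq(0, len - 1, by = config$bin_bp)
    data.frame(chrom = ch, start = s, end = pmin(s + config$bin_bp, len))
  }))
  mid <- data.frame(chrom = b$chrom, pos = floor((b$start + b$end) / 2))
  cf <- config$coefficients
  covs <- annotate_breakpoints(mid, covariates[names(cf)])
  lp <- numeric(nrow(b))
  for (nm in names(cf)) {
    x <- covs[[nm]]
    if (is.factor(x)) x <- as.numeric(x) - 1
    lp <- lp + cf[[nm]] * (x - mean(x))
  }
  b$intensity <- if (config$link == "log") exp(lp) else pmax(1 + lp, 0.05)
  b
}

#' Simulate an SV cohort
#'
#' Draws, per donor, a Poisson number of background SVs whose first
#' breakends follow the covariate-linked inhomogeneous intensity; the
#' partner breakend sits at a log-normal distance for intra-chromosomal
#' types, or at an intensity-weighted position on another chromosome for
#' translocations. Each configured driver locus then receives one SV in a
#' Bernoulli(prevalence) subset of donors, with breakends jittered around
#' the locus.
#'
#' @param config A [sim_config()].
#' @param covariates Track set from [simulate_covariates()].
#' @return SV record table in the internal layout of [read_sv_table()]
#'   (0-based positions), with attribute `"driver_donor_counts"` giving the
#'   number of carrier donors per injected locus.
#' @export
simulate_cohort <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  bins <- .bin_intensity(config, covariates)
  if (!all(is.finite(bins$intensity)) || sum(bins$intensity) <= 0) {
    stop("intensity normalization failure")
  }
  with_seed(config$seed * 7L + 2L, {
    chroms <- names(config$chrom_lengths)
    donors <- sprintf("D%03d", seq_len(config$n_donors))
    n_bg <- stats::rpois(config$n_donors, config$mean_svs)
    total <- sum(n_bg)
    idx1 <- sample(nrow(bins), total, replace = TRUE, prob = bins$intensity)
    chrom1 <- bins$chrom[idx1]
    pos1 <- floor(bins$start[idx1] +
                    stats::runif(total) * (bins$end[idx1] - bins$start[idx1]))
    type <- sample(names(config$type_probs), total, replace = TRUE,
                   prob = config$type_probs)
    chrom2 <- chrom1
    pos2 <- numeric(total)
    intra <- type != "TRA"
    size <- stats::rlnorm(total, config$sv_size_meanlog, config$sv_size_sdlog)
    lens <- config$chrom_lengths[chrom1]
    pos2[intra] <- pmin(pos1[intra] + pmax(50, floor(size[intra])),
                        lens[intra] - 1)
    if (any(!intra)) {
      for (i in which(!intra)) {
        other <- if (length(chroms) > 1L) {
          sample(setdiff(chroms, chrom1[i]), 1L)
        } else chrom1[i]
        sel <- bins$chrom == other
        j <- sample(which(sel), 1L, prob = bins$intensity[sel])
        chrom2[i] <- other
        pos2[i] <- floor(bins$start[j] +
                           stats::runif(1) * (bins$end[j] - bins$start[j]))
      }
    }
    rec <- data.frame(
      cohort_code = "SYNTH",
      donor_id = rep(donors, n_bg),
      variant_type = type,
      sv_id = sprintf("sv%06d", seq_len(total)),
      chrom1 = chrom1, start1 = pos1, end1 = pos1 + 1,
      strand1 = "+",
      chrom2 = chrom2, start2 = pos2, end2 = pos2 + 1,
      strand2 = "-", stringsAsFactors = FALSE)
    drv_counts <- integer(0)
    if (!is.null(config$drivers) && nrow(config$drivers)) {
      extra <- list()
      for (d in seq_len(nrow(config$drivers))) {
        dr <- config$drivers[d, ]
        carrier <- donors[stats::rbinom(config$n_donors, 1L,
                                        dr$prevalence) == 1L]
        drv_counts[d] <- length(carrier)
        if (!length(carrier)) next
        len <- config$chrom_lengths[[dr$chrom]]
        p1 <- pmin(pmax(round(dr$pos + stats::rnorm(length(carrier), 0,
                                                    dr$jitter_sd)), 1), len - 2e4)
        p2 <- pmin(p1 + pmax(200, round(stats::rlnorm(length(carrier),
                                                      log(2e3), 0.5))),
                   len - 1)
        extra[[d]] <- data.frame(
          cohort_code = "SYNTH", donor_id = carrier, variant_type = dr$type,
          sv_id = sprintf("drv%d_%s", d, carrier),
          chrom1 = dr$chrom, start1 = p1, end1 = p1 + 1, strand1 = "+",
          chrom2 = dr$chrom, start2 = p2, end2 = p2 + 1, strand2 = "-",
          stringsAsFactors = FALSE)
      }
      rec <- rbind(rec, do.call(rbind, extra))
    }
    rownames(rec) <- NULL
    attr(rec, "driver_donor_counts") <- drv_counts
    rec
  })
}

#' Simulate element annotations
#'
#' Emits one coding (CDS) element of width `driver_halfwidth * 2` centered
#' on each injected driver locus (gene symbols `DRV1`, `DRV2`, ...), plus
#' `n_decoys` decoy elements of mixed classes at covariate-independent
#' random positions.
#'
#' @param config A [sim_config()].
#' @param n_decoys Number of decoy elements (default 150).
#' @param driver_halfwidth Half-width of each driver element in bp
#'   (default 25 kb).
#' @return Element table in the layout of [read_elements()].
#' @export
simulate_elements <- function(config, n_decoys = 150L,
                              driver_halfwidth = 2.5e4) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed * 7L + 3L, {
    chroms <- names(config$chrom_lengths)
    drv <- NULL
    if (!is.null(config$drivers) && nrow(config$drivers)) {
      drv <- data.frame(
        chrom = config$drivers$chrom,
        start = pmax(config$drivers$pos - driver_halfwidth, 0),
        end = config$drivers$pos + driver_halfwidth,
        element_id = sprintf("DRV%d", seq_len(nrow(config$drivers))),
        element_class = "CDS",
        gene_symbol = sprintf("DRV%d", seq_len(nrow(config$drivers))),
        stringsAsFactors = FALSE)
    }
    ch <- sample(chroms, n_decoys, replace = TRUE,
                 prob = config$chrom_lengths / sum(config$chrom_lengths))
    width <- round(stats::runif(n_decoys, 5e3, 1e5))
    start <- floor(stats::runif(n_decoys) *
                     (config$chrom_lengths[ch] - width))
    dec <- data.frame(
      chrom = ch, start = start, end = start + width,
      element_id = sprintf("EL%04d", seq_len(n_decoys)),
      element_class = sample(ELEMENT_CLASSES, n_decoys, replace = TRUE,
                             prob = c(0.4, 0.3, 0.15, 0.15)),
      gene_symbol = sprintf("GENE%04d", seq_len(n_decoys)),
      stringsAsFactors = FALSE)
    out <- rbind(drv, dec)
    out$length <- out$end - out$start
    rownames(out) <- NULL
    out
  })
}
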