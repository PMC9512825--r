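#' TAD recurrence across samples
#'
#' For each query TAD, the recurrence is the fraction of sample TAD sets that
#' contain a TAD overlapping at least `min_overlap` (default 70%) of the
#' query TAD's own length. The query length is the denominator of the
#' overlap fraction, so nested calls in other samples still count when they
#' cover enough of the query.
#'
#' @param tad_sets List of per-sample TAD sets; each element is a data frame
#'   with columns `chrom`, `start`, `end` (non-overlapping within a sample).
#' @param query Data frame of query TADs (`chrom`, `start`, `end`).
#' @param min_overlap Minimum overlap fraction of the query length
#'   (default 0.7).
#' @return Numeric vector of recurrence fractions in `[0, 1]`, one per query
#'   row.
#' @export
tad_recurrence <- function(tad_sets, query, min_overlap = 0.7) {
  if (!length(tad_sets)) stop("need at least one sample TAD set")
  n_samples <- length(tad_sets)
  hits <- integer(nrow(query))
  qlen <- query$end - query$start
  for (s in tad_sets) {
    for (ch in unique(query$chrom)) {
      qi <- which(query$chrom == ch)
      si <- s[s$chrom == ch, , drop = FALSE]
      if (!length(qi) || !nrow(si)) next
      qr <- IRanges::IRanges(query$start[qi] + 1, query$end[qi])
      sr <- IRanges::IRanges(si$start + 1, si$end)
      ov <- IRanges::findOverlaps(qr, sr)
      if (!length(ov)) next
      w <- IRanges::width(IRanges::pintersect(
        qr[S4Vectors::queryHits(ov)], sr[S4Vectors::subjectHits(ov)]))
      ok <- w >= min_overlap * qlen[qi][S4Vectors::queryHits(ov)]
      matched <- unique(S4Vectors::queryHits(ov)[ok])
      hits[qi[matched]] <- hits[qi[matched]] + 1L
    }
  }
  hits / n_samples
}

#' TAD-boundary intervals
#'
#' Boundaries are the flanking intervals of width `width` (default 50 kb)
#' centered at each TAD endpoint. Used to compute boundary recurrence with
#' the same overlap rule as [tad_recurrence()].
#'
#' @param tads Data frame of TADs (`chrom`, `start`, `end`).
#' @param width Boundary interval width in bp.
#' @return Data frame of boundary intervals (`chrom`, `start`, `end`).
#' @export
tad_boundaries <- function(tads, width = 5e4) {
  half <- width / 2
  ends <- c(tads$start, tads$end)
  data.frame(chrom = rep(tads$chrom, 2L),
             start = pmax(ends - half, 0),
             end = ends + half)
}

#' Partition TADs into segments of constant recurrence
#'
#' Splits the union of (possibly overlapping) TADs at every TAD endpoint,
#' yielding maximal segments on which the set of covering TADs, and hence
#' the recurrence, is constant. The recurrence of a segment covered by
#' several TADs is the maximum recurrence among them.
#'
#' @param tads Data frame with `chrom`, `start`, `end` and a `recurrence`
#'   column.
#' @return Data frame of segments (`chrom`, `start`, `end`, `recurrence`),
#'   covering exactly the union of the input TADs.
#' @export
segment_tads_by_recurrence <- function(tads) {
  out <- list()
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, , drop = FALSE]
    cuts <- sort(unique(c(t$start, t$end)))
    if (length(cuts) < 2L) next
    seg <- data.frame(chrom = ch, start = cuts[-length(cuts)], end = cuts[-1L])
    mid <- (seg$start + seg$end) / 2
    rec <- vapply(mid, function(m) {
      cover <- t$start <= m & m < t$end
      if (any(cover)) max(t$recurrence[cover]) else NA_real_
    }, numeric(1))
    seg$recurrence <- rec
    out[[ch]] <- seg[!is.na(rec), , drop = FALSE]
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  rownames(res) <- NULL
  res
}

#' Classify TAD segments by chromatin-state composition
#'
#' Each segment is summarised by the coverage fraction of the 15 chromatin
#' states within it; segments are projected onto the top three principal
#' components of that coverage matrix and clustered with k-means (k = 3,
#' seeded). Clusters are labeled by their mean composition: the cluster with
#' the highest Quies+Het coverage is `quiescent`, the one with the highest
#' TssA+Tx+TxWk+Enh+EnhG coverage is `active`, and the remaining cluster is
#' `low-active`. With fewer than 3 segments the direct coverage rule is
#' applied per segment without clustering.
#'
#' @param segments Data frame of segments (`chrom`, `start`, `end`).
#' @param chrom_mark_track A factor `interval_track` over the 15 states.
#' @param seed Seed for k-means initialization (default 1).
#' @return Factor vector (`quiescent`, `low-active`, `active`) per segment.
#' @export
classify_tad_segments <- function(segments, chrom_mark_track, seed = 1L) {
  cov <- .state_coverage(segments, chrom_mark_track)
  lab_levels <- c("quiescent", "low-active", "active")
  quies_score <- function(m) rowSums(m[, intersect(c("Quies", "Het"),
                                                   colnames(m)), drop = FALSE])
  active_score <- function(m) rowSums(m[, intersect(c("TssA", "TssAFlnk", "Tx",
                                                      "TxWk", "TxFlnk", "Enh",
                                                      "EnhG"),
                                                    colnames(m)), drop = FALSE])
  if (nrow(segments) < 3L) {
    q <- quies_score(cov); a <- active_score(cov)
    lab <- ifelse(q >= a & q >= 1 - q - a, "quiescent",
                  ifelse(a >= q & a >= 1 - q - a, "active", "low-active"))
    return(factor(lab, levels = lab_levels))
  }
  pc <- stats::prcomp(cov, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  km <- with_seed(seed, stats::kmeans(scores, centers = 3L, nstart = 10L,
                                       iter.max = 50L))
  cl_q <- tapply(quies_score(cov), km$cluster, mean)
  cl_a <- tapply(active_score(cov), km$cluster, mean)
  lab_of <- rep("low-active", 3L)
  lab_of[which.max(cl_q)] <- "quiescent"
  # active = highest transcription/enhancer coverage among the others
  rest <- setdiff(seq_len(3L), which.max(cl_q))
  lab_of[rest[which.max(cl_a[rest])]] <- "active"
  factor(lab_of[km$cluster], levels = lab_levels)
}

# Coverage fraction of each chromatin state within each segment.
.state_coverage <- function(segments, track) {
  states <- track$levels
  iv <- track$intervals
  m <- matrix(0, nrow(segments), length(states),
              dimnames = list(NULL, states))
  for (i in seq_len(nrow(segments))) {
    s <- iv[iv$chrom == segments$chrom[i] &
              iv$end > segments$start[i] & iv$start < segments$end[i], ,
            drop = FALSE]
    if (!nrow(s)) next
    w <- pmin(s$end, segments$end[i]) - pmax(s$start, segments$start[i])
    tot <- segments$end[i] - segments$start[i]
    for (st in unique(s$value)) {
      m[i, st] <- sum(w[s$value == st]) / tot
    }
  }
  m
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
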