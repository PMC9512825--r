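#' Read element annotations
#'
#' Reads functional element annotations (coding exons / gene bodies,
#' enhancers, CTCF insulators, lncRNAs) from a BED6-like file whose name
#' column is the element id and whose extra columns give the element class
#' and optionally an associated gene symbol.
#'
#' @param path Tab-separated file: chrom, start, end, element_id, class,
#'   optional gene_symbol (0-based half-open coordinates, no header).
#' @return Data frame with columns `chrom`, `start`, `end`, `element_id`,
#'   `element_class`, `gene_symbol`, `length`.
#' @export
read_elements <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(raw) < 5L) stop("element file needs >= 5 columns: ", path)
  out <- data.frame(chrom = as.character(raw[[1L]]),
                    start = as.numeric(raw[[2L]]), end = as.numeric(raw[[3L]]),
                    element_id = as.character(raw[[4L]]),
                    element_class = as.character(raw[[5L]]),
                    gene_symbol = if (ncol(raw) >= 6L) as.character(raw[[6L]])
                    else NA_character_,
                    stringsAsFactors = FALSE)
  bad <- !out$element_class %in% ELEMENT_CLASSES
  if (any(bad)) {
    stop("unknown element class(es): ",
         paste(unique(out$element_class[bad]), collapse = ", "))
  }
  out$length <- out$end - out$start
  if (any(out$length <= 0)) stop("elements must have positive length")
  out
}

# Does each SV record overlap the interval [start, end) on `chrom`?
# Intra-chromosomal SVs overlap through the genomic span between their two
# breakends; translocations (breakends on different chromosomes) have no
# contiguous span and overlap iff either breakend point falls inside.
.sv_overlaps <- function(records, chrom, start, end) {
  intra <- records$chrom1 == records$chrom2
  lo <- pmin(records$start1, records$start2)
  hi <- pmax(records$start1, records$start2)
  span_hit <- intra & records$chrom1 == chrom & lo < end & hi >= start
  bp1_hit <- records$chrom1 == chrom &
    records$start1 >= start & records$start1 < end
  bp2_hit <- records$chrom2 == chrom &
    records$start2 >= start & records$start2 < end
  span_hit | (!intra & (bp1_hit | bp2_hit))
}

#' Element SV rearrangement score
#'
#' `ERS_SV = (Nsmp_E / Nsmp) x (Nsv_E / L_E)`, where `Nsmp_E` and `Nsv_E`
#' are the unique donors and SVs whose span (or, for translocations, either
#' breakend) overlaps the element, `Nsmp` is the donor count of the peak and
#' `L_E` the element length. Length normalization discounts long elements
#' that collect SVs by chance.
#'
#' @param element One row of an element table ([read_elements()]).
#' @param records SV records of the cohort.
#' @param n_smp_peak Unique donors in the peak region.
#' @return List with `ers_sv`, `n_smp_e`, `n_sv_e`.
#' @export
element_sv_score <- function(element, records, n_smp_peak) {
  l_e <- element$end - element$start
  if (l_e <= 0) stop("element length must be positive")
  hit <- .sv_overlaps(records, element$chrom, element$start, element$end)
  n_smp_e <- length(unique(records$donor_id[hit]))
  n_sv_e <- length(unique(records$sv_id[hit]))
  list(ers_sv = (n_smp_e / n_smp_peak) * (n_sv_e / l_e),
       n_smp_e = n_smp_e, n_sv_e = n_sv_e)
}

#' Element breakpoint rearrangement score (coding genes)
#'
#' `ERS_BP = (Nsmp_E / Nsmp) x (Nbp_E / L_E)` with `Nbp_E` the breakpoints
#' falling strictly inside the gene body. Distinguishes genes broken within
#' their body (fusion / disruption) from genes merely spanned by large SVs.
#'
#' @param element One row of an element table (a CDS gene body).
#' @param breakpoints Breakpoint table of the cohort.
#' @param n_smp_peak Unique donors in the peak region.
#' @return List with `ers_bp`, `n_bp_e` and `n_smp_e` (donors with a
#'   breakpoint inside the element).
#' @export
element_bp_score <- function(element, breakpoints, n_smp_peak) {
  l_e <- element$end - element$start
  if (l_e <= 0) stop("element length must be positive")
  inb <- breakpoints$chrom == element$chrom &
    breakpoints$pos >= element$start & breakpoints$pos < element$end
  n_bp_e <- sum(inb)
  n_smp_e <- length(unique(breakpoints$donor_id[inb]))
  list(ers_bp = (n_smp_e / n_smp_peak) * (n_bp_e / l_e), n_bp_e = n_bp_e,
       n_smp_e = n_smp_e)
}

#' Score all elements inside significant peaks
#'
#' For every element whose interval overlaps a significant peak's genomic
#' footprint (the full positive excursion when available, else the summit
#' region), computes `ERS_SV` (all classes) and, for coding elements,
#' `ERS_BP`; the best score of a coding element is the larger of the two.
#' The excursion is used because the summit region measures clustering
#' intensity over a deliberately narrow top slice, while the elements under
#' selection may sit anywhere in the territory elevated above background.
#'
#' @param peaks Peak table with `peak_id`, `chrom`, `start`, `end`, `n_smp`
#'   columns (typically the significant subset of an [sv_scan] peak table).
#' @param elements Element table from [read_elements()].
#' @param records SV records of the cohort.
#' @param breakpoints Breakpoint table of the cohort.
#' @return Data frame of element scores, one row per (peak, element) pair.
#' @export
score_elements <- function(peaks, elements, records, breakpoints) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    fp_start <- if (!is.null(pk$exc_start)) pk$exc_start else pk$start
    fp_end <- if (!is.null(pk$exc_end)) pk$exc_end else pk$end
    el <- elements[elements$chrom == pk$chrom &
                     elements$end > fp_start & elements$start < fp_end, ,
                   drop = FALSE]
    if (!nrow(el)) next
    for (j in seq_len(nrow(el))) {
      e <- el[j, ]
      sv <- element_sv_score(e, records, pk$n_smp)
      bp <- if (e$element_class == "CDS") {
        element_bp_score(e, breakpoints, pk$n_smp)
      } else NULL
      out[[length(out) + 1L]] <- data.frame(
        peak_id = pk$peak_id, element_id = e$element_id,
        element_class = e$element_class, gene_symbol = e$gene_symbol,
        chrom = e$chrom, start = e$start, end = e$end,
        length = e$end - e$start,
        n_smp_e = max(sv$n_smp_e, if (is.null(bp)) 0 else bp$n_smp_e),
        n_sv_e = sv$n_sv_e,
        n_bp_e = if (is.null(bp)) NA_integer_ else bp$n_bp_e,
        ers_sv = sv$ers_sv,
        ers_bp = if (is.null(bp)) NA_real_ else bp$ers_bp,
        best_score = max(sv$ers_sv, if (is.null(bp)) -Inf else bp$ers_bp),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_element_scores())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_element_scores <- function() {
  data.frame(peak_id = integer(), element_id = character(),
             element_class = character(), gene_symbol = character(),
             chrom = character(), start = numeric(), end = numeric(),
             length = numeric(), n_smp_e = integer(), n_sv_e = integer(),
             n_bp_e = integer(), ers_sv = numeric(), ers_bp = numeric(),
             best_score = numeric(), candidate = logical(),
             most_likely = logical())
}

#' Nominate driver candidates per peak
#'
#' Within each significant peak, the top-scoring element of each class is a
#' candidate. When several classes tie at the top score and one of them is
#' (or is the enhancer of) a gene on the optional known-cancer-gene list,
#' that element is marked most likely. Ties in score are broken
#' deterministically by higher donor count, then smaller length, then
#' element id.
#'
#' @param scores Element-score table from [score_elements()].
#' @param known_cancer_genes Optional character vector of gene symbols.
#' @return `scores` with logical columns `candidate` (top of its class in
#'   its peak) and `most_likely` appended, ordered by peak then descending
#'   best score.
#' @export
nominate_candidates <- function(scores, known_cancer_genes = NULL) {
  if (!nrow(scores)) return(.empty_element_scores())
  ord <- order(scores$peak_id, -scores$best_score, -scores$n_smp_e,
               scores$length, scores$element_id, method = "radix")
  scores <- scores[ord, , drop = FALSE]
  scores$candidate <- FALSE
  scores$most_likely <- FALSE
  for (pid in unique(scores$peak_id)) {
    sel <- which(scores$peak_id == pid)
    sub <- scores[sel, ]
    top <- sel[!duplicated(sub$element_class)]  # best row per class
    scores$candidate[top] <- TRUE
    best <- max(scores$best_score[top])
    tied <- top[scores$best_score[top] == best]
    ml <- tied[1L]
    if (length(tied) > 1L && !is.null(known_cancer_genes)) {
      known <- tied[!is.na(scores$gene_symbol[tied]) &
                      scores$gene_symbol[tied] %in% known_cancer_genes]
      if (length(known)) ml <- known[1L]
    }
    scores$most_likely[ml] <- TRUE
  }
  rownames(scores) <- NULL
  scores
}
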