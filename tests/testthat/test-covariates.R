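test_that("TAD recurrence counts samples reaching the 70% overlap of the query length", {
  query <- data.frame(chrom = "chr1", start = 0, end = 1000)
  full <- replicate(37, data.frame(chrom = "chr1", start = 0, end = 1000),
                    simplify = FALSE)
  expect_equal(tad_recurrence(full, query), 1.0)
  # present only in its own source sample
  one <- c(list(data.frame(chrom = "chr1", start = 0, end = 1000)),
           replicate(36, data.frame(chrom = "chr2", start = 0, end = 1000),
                     simplify = FALSE))
  expect_equal(tad_recurrence(one, query), 1 / 37, tolerance = 1e-12)
  # exactly 70% overlap counts, 69.9% does not
  at70 <- replicate(5, data.frame(chrom = "chr1", start = 300, end = 1200),
                    simplify = FALSE)     # overlap 700 of 1000
  below <- replicate(5, data.frame(chrom = "chr1", start = 301, end = 1200),
                     simplify = FALSE)    # overlap 699
  expect_equal(tad_recurrence(c(at70, below), query), 0.5)
  expect_error(tad_recurrence(list(), query), "at least one")
})

test_that("recurrence is monotone when the overlap threshold is lowered", {
  set.seed(11)
  query <- data.frame(chrom = "chr1", start = 0, end = 1e4)
  sets <- replicate(10, data.frame(chrom = "chr1",
                                   start = sample(0:5000, 3),
                                   end = sample(6000:12000, 3)),
                    simplify = FALSE)
  r_strict <- tad_recurrence(sets, query, min_overlap = 0.9)
  r_loose <- tad_recurrence(sets, query, min_overlap = 0.5)
  expect_gte(r_loose, r_strict)
})

test_that("TAD segmentation cuts at endpoints and covers the union without gaps", {
  nested <- data.frame(chrom = "chr1", start = c(0, 200), end = c(1000, 600),
                       recurrence = c(0.3, 0.9))
  seg <- segment_tads_by_recurrence(nested)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$start, c(0, 200, 600))
  expect_equal(seg$end, c(200, 600, 1000))
  expect_equal(seg$recurrence, c(0.3, 0.9, 0.3))  # overlap takes the max

  apart <- data.frame(chrom = "chr1", start = c(0, 500), end = c(300, 900),
                      recurrence = c(0.2, 0.8))
  seg2 <- segment_tads_by_recurrence(apart)
  # the uncovered gap between the TADs is dropped; segments equal the TADs
  expect_equal(seg2$start, c(0, 500))
  expect_equal(seg2$end, c(300, 900))
  expect_equal(seg2$recurrence, c(0.2, 0.8))

  # property: segment boundaries are the sorted unique TAD endpoints
  set.seed(3)
  for (rep in 1:20) {
    t <- data.frame(chrom = "chr1", start = sort(sample(0:1e4, 5)))
    t$end <- t$start + sample(500:5000, 5)
    t$recurrence <- runif(5)
    seg <- segment_tads_by_recurrence(t)
    cuts <- sort(unique(c(t$start, t$end)))
    expect_true(all(seg$start %in% cuts) && all(seg$end %in% cuts))
    # no overlaps, sorted
    expect_true(all(seg$start[-1L] >= seg$end[-nrow(seg)]))
    # total segment length equals the union of the TADs
    cover <- IRanges::reduce(IRanges::IRanges(t$start + 1, t$end))
    expect_equal(sum(seg$end - seg$start), sum(IRanges::width(cover)))
  }
})

test_that("TAD segments classify by chromatin composition, directly and by clustering", {
  states <- svproximity:::CHROM_STATES
  seg2 <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000))
  quies_track <- toy_track("factor", "chr1", 0, 2000, "Quies",
                           levels = states)
  expect_equal(as.character(classify_tad_segments(seg2[1, ], quies_track)),
               "quiescent")
  tssa_track <- toy_track("factor", "chr1", 0, 2000, "TssA", levels = states)
  expect_equal(as.character(classify_tad_segments(seg2[1, ], tssa_track)),
               "active")

  # planted three-cluster composition is recovered
  set.seed(9)
  mk <- function(state, n) {
    start <- seq(0, by = 1000, length.out = n) + runif(n, 0, 10)
    data.frame(chrom = "chr9", start = floor(start),
               end = floor(start) + 900, state = state)
  }
  blocks <- rbind(mk("Quies", 30), mk("TssA", 30), mk("ReprPC", 30))
  blocks <- blocks[order(blocks$start), ]
  blocks$start <- seq(0, by = 1000, length.out = nrow(blocks))
  blocks$end <- blocks$start + 900
  track <- toy_track("factor", "chr9", blocks$start, blocks$end,
                     blocks$state, levels = states)
  segs <- data.frame(chrom = "chr9", start = blocks$start, end = blocks$end)
  cl <- classify_tad_segments(segs, track, seed = 1)
  truth <- blocks$state
  # Rand index of the 3-way partition against the planted labels
  tab <- table(cl, truth)
  n <- sum(tab)
  rand <- (choose(n, 2) + 2 * sum(choose(tab, 2)) -
             sum(choose(rowSums(tab), 2)) - sum(choose(colSums(tab), 2))) /
    choose(n, 2)
  expect_gt(rand, 0.95)
})

test_that("GC content over centered windows matches direct base counting", {
  seqs <- c(chrA = paste(rep("G", 200), collapse = ""))
  expect_equal(gc_content(seqs, "chrA", 100), 1.0)
  seqs2 <- c(chrA = paste(rep("AC", 100), collapse = ""))
  expect_equal(gc_content(seqs2, "chrA", 100), 0.5, tolerance = 0.01)
  # random window equals a character-count oracle
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 400, replace = TRUE,
                    prob = c(.3, .2, .2, .25, .05)), collapse = "")
  pos <- 200
  got <- gc_content(c(chrB = s), "chrB", pos)
  win <- strsplit(substr(s, pos - 49, pos + 51), "")[[1]]
  expect_equal(got, sum(win %in% c("G", "C")) / sum(win != "N"),
               tolerance = 1e-12)
  # all-N window is missing
  expect_true(is.na(gc_content(c(chrN = paste(rep("N", 200), collapse = "")),
                               "chrN", 100)))
})

test_that("gene density counts genes per containing megabase bin", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1e5, 2e5, 3e5, 4e5, 5e5, 9.5e5),
                      end = c(1.5e5, 2.5e5, 3.5e5, 4.5e5, 5.5e5, 1.2e6))
  expect_equal(gene_density(genes[0, ], "chr1", 5e5), 0)
  expect_equal(gene_density(genes[1:5, ], "chr1", 5e5), 5)
  # a gene spanning the bin boundary is counted in both bins
  expect_equal(gene_density(genes, "chr1", 5e5), 6)
  expect_equal(gene_density(genes, "chr1", 1.5e6), 1)
})

test_that("breakpoint annotation equals a linear-scan oracle and handles missingness", {
  fs <- toy_track("binary", "chr1", 5e5, 6e5, 1, name = "FS")
  rep_tr <- toy_track("factor", c("chr1", "chr1"), c(0, 5e5), c(5e5, 1e6),
                      c("LINE", "SINE"), name = "repClass",
                      levels = svproximity:::REP_CLASSES)
  rt <- toy_track("numeric", "chr1", c(0, 5e5), c(5e5, 1e6), c(-1, 2),
                  name = "RT")
  bp1 <- data.frame(chrom = "chr1", pos = c(5.5e5, 1e4))
  ann <- annotate_breakpoints(bp1, list(FS = fs, repClass = rep_tr, RT = rt))
  expect_equal(ann$FS, c(1, 0))
  expect_equal(as.character(ann$repClass), c("SINE", "LINE"))
  expect_equal(ann$RT, c(2, -1))

  # uncovered points: factor falls back to the reference, numeric to median
  bp2 <- data.frame(chrom = "chr1", pos = 2e6)
  ann2 <- annotate_breakpoints(bp2, list(repClass = rep_tr, RT = rt))
  expect_equal(as.character(ann2$repClass), "none")
  expect_equal(attr(ann2, "missingness")[["repClass"]], 1L)

  # random fixture against the linear-scan oracle
  set.seed(4)
  n_iv <- 50
  starts <- sort(sample(seq(0, 9e5, by = 1e4), n_iv))
  tr <- toy_track("numeric", rep("chr1", n_iv), starts, starts + 5e3,
                  value = round(runif(n_iv), 3), name = "x")
  qpos <- sample.int(1e6, 1000)
  got <- track_lookup(tr, rep("chr1", 1000), qpos)
  want <- as.numeric(lookup_oracle(tr, rep("chr1", 1000), qpos))
  expect_equal(got, want)
})
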