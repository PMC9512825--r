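element_row <- function(id = "E1", class = "CDS", chrom = "chr1",
                        start = 0, end = 1000, gene = "G1") {
  data.frame(chrom = chrom, start = start, end = end, element_id = id,
             element_class = class, gene_symbol = gene,
             length = end - start, stringsAsFactors = FALSE)
}

test_that("the element SV score follows its formula and overlap rules", {
  el <- element_row(end = 1000)
  # 8 SVs spanning the element from 5 donors, peak has 10 donors
  rec <- do.call(rbind, lapply(1:8, function(i) {
    sv_record(donor = paste0("D", (i - 1) %% 5 + 1), sv = paste0("s", i),
              pos1 = -500 + i, pos2 = 2000 + i)
  }))
  got <- element_sv_score(el, rec, n_smp_peak = 10)
  expect_equal(got$ers_sv, (5 / 10) * (8 / 1000))
  # an element with no overlapping SV scores zero
  far <- element_row(chrom = "chr9", start = 5e6, end = 5.01e6)
  expect_equal(element_sv_score(far, rec, 10)$ers_sv, 0)
  # a translocation overlaps only where a breakend falls inside
  tra <- sv_record(donor = "D1", sv = "t1", type = "TRA", chrom1 = "chr1",
                   pos1 = 500, chrom2 = "chr5", pos2 = 3e6)
  expect_equal(element_sv_score(el, tra, 10)$n_sv_e, 1L)
  el_chr5 <- element_row(chrom = "chr5", start = 0, end = 1000)
  expect_equal(element_sv_score(el_chr5, tra, 10)$n_sv_e, 0L)
})

test_that("the breakpoint score distinguishes genes broken inside from genes merely spanned", {
  gene <- element_row(start = 0, end = 2e6)
  # SVs span the whole gene but break outside it
  bp_out <- data.frame(chrom = "chr1", pos = c(-100, 2.5e6),
                       donor_id = "D1", sv_id = "s1")
  expect_equal(element_bp_score(gene, bp_out, 10)$ers_bp, 0)
  # six internal breakpoints from four donors
  bp_in <- data.frame(chrom = "chr1", pos = seq(1e5, 6e5, by = 1e5),
                      donor_id = paste0("D", c(1, 1, 2, 2, 3, 4)),
                      sv_id = paste0("s", 1:6))
  got <- element_bp_score(gene, bp_in, 10)
  expect_equal(got$ers_bp, (4 / 10) * (6 / 2e6))
})

test_that("rearrangement scores match formula oracles on random fixtures", {
  set.seed(6)
  for (rep in 1:100) {
    l_e <- sample(500:5e4, 1)
    el <- element_row(start = 1e5, end = 1e5 + l_e)
    n_sv <- sample(1:15, 1)
    donors <- paste0("D", sample(1:8, n_sv, replace = TRUE))
    inside <- runif(n_sv) < 0.6
    p1 <- ifelse(inside, 1e5 + sample.int(l_e, n_sv, replace = TRUE) - 1,
                 3e5 + sample.int(1e4, n_sv, replace = TRUE))
    rec <- do.call(rbind, lapply(seq_len(n_sv), function(i) {
      sv_record(donor = donors[i], sv = paste0("s", i), pos1 = p1[i],
                pos2 = p1[i] + 100)
    }))
    got <- element_sv_score(el, rec, 10)
    hit <- vapply(seq_len(n_sv), function(i) {
      p1[i] + 100 > el$start && p1[i] < el$end
    }, logical(1))
    expect_equal(got$n_sv_e, length(unique(rec$sv_id[hit])))
    expect_equal(got$ers_sv,
                 length(unique(donors[hit])) / 10 *
                   length(unique(rec$sv_id[hit])) / l_e,
                 tolerance = 1e-12)
  }
})

test_that("score halves when the element length doubles at fixed counts", {
  rec <- sv_record(pos1 = 100, pos2 = 400)
  s1 <- element_sv_score(element_row(start = 0, end = 1000), rec, 5)$ers_sv
  s2 <- element_sv_score(element_row(start = 0, end = 2000), rec, 5)$ers_sv
  expect_equal(s1, 2 * s2)
})

test_that("candidates are the top element per class with deterministic ties and known-gene priority", {
  scores <- data.frame(
    peak_id = 1L,
    element_id = c("cds1", "cds2", "enh1", "lnc1"),
    element_class = c("CDS", "CDS", "enhancer", "lncRNA"),
    gene_symbol = c("AAA", "BBB", "ONC1", "CCC"),
    chrom = "chr1", start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
    length = 50, n_smp_e = c(5, 3, 5, 2), n_sv_e = 5, n_bp_e = NA,
    ers_sv = c(0.02, 0.01, 0.02, 0.005), ers_bp = NA,
    best_score = c(0.02, 0.01, 0.02, 0.005),
    stringsAsFactors = FALSE)
  out <- nominate_candidates(scores, known_cancer_genes = "ONC1")
  expect_equal(sort(out$element_id[out$candidate]),
               c("cds1", "enh1", "lnc1"))
  # two classes tie at the top; the known cancer gene wins most-likely
  expect_equal(out$element_id[out$most_likely], "enh1")
  # without the gene list, the deterministic tie-break applies
  out2 <- nominate_candidates(scores)
  expect_equal(sum(out2$most_likely), 1L)

  # a coding element is ranked by the larger of its two scores
  cds <- data.frame(peak_id = 2L, element_id = c("a", "b"),
                    element_class = "CDS", gene_symbol = c("A", "B"),
                    chrom = "chr1", start = c(0, 100), end = c(50, 150),
                    length = 50, n_smp_e = c(2, 2), n_sv_e = 2,
                    n_bp_e = c(1, 9), ers_sv = c(0.004, 0.001),
                    ers_bp = c(0.001, 0.007),
                    best_score = c(0.004, 0.007), stringsAsFactors = FALSE)
  out3 <- nominate_candidates(cds)
  expect_equal(out3$element_id[out3$most_likely], "b")
})

test_that("candidate ranking is invariant to donor relabeling and record order", {
  set.seed(7)
  cfg <- small_sim_config(seed = 30,
                          drivers = data.frame(chrom = "chr2", pos = 6e6,
                                               prevalence = 0.3,
                                               jitter_sd = 300,
                                               type = "DEL"))
  cov <- simulate_covariates(cfg)
  rec <- simulate_cohort(cfg, cov)
  el <- simulate_elements(cfg, n_decoys = 40)
  bp <- sv_to_breakpoints(rec)
  peaks <- data.frame(peak_id = 1L, chrom = "chr2", start = 5.9e6,
                      end = 6.1e6, n_smp = 20)
  s1 <- nominate_candidates(score_elements(peaks, el, rec, bp))
  # relabel donors bijectively and shuffle record order
  rec2 <- rec[sample(nrow(rec)), ]
  rec2$donor_id <- paste0("X", rec2$donor_id)
  bp2 <- sv_to_breakpoints(rec2)
  s2 <- nominate_candidates(score_elements(peaks, el, rec2, bp2))
  expect_equal(s1$element_id, s2$element_id)
  expect_equal(s1$best_score, s2$best_score)
})

test_that("element files read with class validation", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t5000\tE1\tCDS\tG1",
               "chr1\t6000\t7000\tE2\tenhancer\tG2"), f)
  el <- read_elements(f)
  expect_equal(el$length, c(5000, 1000))
  f2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t5000\tE1\tpromoter\tG1", f2)
  expect_error(read_elements(f2), "unknown element class")
})
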