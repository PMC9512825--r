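# svproximity

Detection of candidate driver loci from somatic structural-variant (SV)
breakpoints in cancer cohorts, by modeling genome-wide breakpoint
*proximity* against a covariate-aware background.

Somatic SVs (deletions, duplications, inversions, translocations) are
heterogeneously distributed along tumor genomes: replication timing,
chromatin state, GC content, gene density, fragile sites, lamina-associated
domains (LADs) and the 3D-genome organisation of topologically associating
domains (TADs) all shape where breakpoints fall under neutral evolution. A
locus is a credible driver candidate only when its breakpoints cluster more
tightly than that background predicts. `svproximity` implements the full
workflow for cohort-level SV calls, and a synthetic-cohort generator so
every stage can be exercised and validated without access to controlled
patient data.

## The method

1. **Breakpoint proximity curve.** All breakends of a cohort are pooled and
   sorted per chromosome. Each breakpoint *BP<sub>i</sub>* gets its
   *neighbor reachability*
   *BPnr<sub>i</sub>* = (Δ(BP<sub>i</sub>,BP<sub>i−1</sub>) +
   Δ(BP<sub>i</sub>,BP<sub>i+1</sub>)) / 2,
   mapped to the reverse scale *BPp<sub>i</sub>* = −log10(*BPnr<sub>i</sub>*+1)
   and smoothed with LOESS (span α = 0.2 as a fraction of points, degree 2).
   The smooth curve — the *BPpc* — is high where breakpoints cluster.
2. **Expected background.** A generalized additive model (Gamma family,
   identity link, fitted with `mgcv`) describes the expected curve from
   genomic covariates:
   linear factors FS, LAD, repClass, ChromMark; thin-plate spline smooths
   s(RT), s(GC), s(TAD.recurr), s(TAD-B.recurr), s(GeneDensity), each
   interacted with LAD status; and tensor-product interactions
   te(GeneDensity, TAD.recurr), te(GeneDensity, RT), te(RT, TAD.recurr) per
   TAD-segment class (quiescent / low-active / active). Explained deviance
   and Bayesian-covariance Wald tests quantify each term's contribution.
3. **Adjusted curve.** Observed minus expected; positive excursions are
   regions with more clustering than the background explains.
4. **Peak significance.** Each excursion's summit region (curve ≥ 75% of the
   summit) is scored with the peak recurrence score
   **PRs = (Nsmp / Nsv) × (Peak_A / Peak_GR)** —
   high for tight clusters contributed by many donors through few distinct
   SVs. A Gamma distribution is fitted (maximum likelihood) to the cohort's
   √PRs values; upper-tail p-values are corrected with Benjamini–Hochberg
   and peaks with FDR < 0.2 are called significantly recurrent. The
   single-sample score **SSRs = N_BP / Nsmp** flags peaks driven by one or
   few donors through the same machinery.
5. **Driver elements.** Inside each significant peak, functional elements
   (coding sequence, enhancers, CTCF insulators, lncRNAs) are ranked by
   **ERS_SV = (Nsmp_E / Nsmp) × (Nsv_E / L_E)** and, for coding genes,
   **ERS_BP = (Nsmp_E / Nsmp) × (Nbp_E / L_E)**; the top-scoring element per
   class is nominated.

A binomial power model
(p0 = 1 − (1 − μ·f_p)^L, p1 = 1 − (1 − p0)(1 − r·s),
power(n) = P(Bin(n, p1) ≥ m_min)) relates cohort size to the prevalence of
detectable driver events.

## Worked example

A fully synthetic cohort: 200 donors on a compact 16-chromosome genome with
five driver loci injected at 25% prevalence.

```r
library(svproximity)

cfg      <- sim_config(seed = 1)            # study conditions
tracks   <- simulate_covariates(cfg)        # RT, GC, LAD, TADs, chromatin...
svs      <- simulate_cohort(cfg, tracks)    # 12-column SV records
elements <- simulate_elements(cfg)          # driver + decoy annotations

scan <- scan_sv_drivers(svs, tracks = tracks, elements = elements, seed = 1)
summary(scan)
```

```
SV breakpoint-proximity scan
  breakpoints: 29464 on 16 modeled chromosome(s)
  background explained deviance: 27.1%
  peaks: 434 called; 5 significant at FDR < 0.2
  candidate elements: 5 in 5 peak(s)

Significant peaks:
 chrom    start      end n_smp n_sv n_bp      prs q_value
  chr1  7706242  7999992    28   33   42 8.22e-07  0.0385
  chr3 10682631 10735761     5    5    7 8.39e-07  0.0385
  chr5  3744787  4096091    74   75  141 1.14e-06  0.0290
  chr7 11782661 12154637    85  100  182 9.13e-07  0.0365
  chr9  7143505  7255422    11   11   15 9.21e-07  0.0365

Most likely elements per peak:
 peak_id element_id element_class gene_symbol best_score
       8       DRV1           CDS        DRV1    0.00270
     290       DRV2           CDS        DRV2    0.01656
     323       DRV3           CDS        DRV3    0.00179
     379       DRV4           CDS        DRV4    0.00187
     427       DRV5           CDS        DRV5    0.00973
```

The five flagged peaks sit on the five chromosomes carrying injected loci;
each peak's top-ranked element is the planted driver element. The
background GAM explains 27% of the proximity deviance from the simulated
covariates. `write_results(scan, "out/")` serializes the peak catalog,
element scores and a JSON run manifest (parameters, seed, input checksums,
per-chromosome log).

Real cohorts enter through `read_sv_table()` (12-column tab-separated SV
calls) or `read_bedpe()`, covariates through `read_interval_track()`
(BED3/BED4/bedGraph), elements through `read_elements()`. A thin
command-line wrapper with `simulate`, `run` and `power` subcommands is
installed under `inst/cli/svproximity.R`.

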