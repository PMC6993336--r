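# exocnv

Copy-number variant (CNV) calling from exome-sequencing read depth, with
mappability-based target filtering, resampling-based reproducibility
scoring, and SNP-array-anchored benchmarking.

## The problem

Exome sequencing is the workhorse diagnostic test for Mendelian
disorders, but calling CNVs from it is hard: per-target read depth varies
with batch, GC content, capture efficiency and mappability, so real
dosage changes must be separated from technical artifacts. `exocnv`
implements a clinically oriented workflow for this problem:

1. **Target filtering.** Per-exon mean 35-mer mappability is computed
   from a base-level uniqueness track, and every exon with mean
   mappability ≤ 0.75 is excluded before counting. Low-uniqueness exons
   (pseudogenes, segmental duplications) are where short-read depth is
   least trustworthy.
2. **Reference panel selection.** For each test sample, controls are
   ranked by Pearson correlation of per-target counts and aggregated
   greedily; the panel kept is the rank prefix whose aggregate correlates
   best with the test sample. Samples whose squared correlation with the
   aggregate falls below r² = 0.97 are rejected rather than called.
3. **Segmentation.** The test sample's count `y_i` out of the combined
   test + reference total `n_i` at target `i` is modelled as
   beta-binomial with expected diploid proportion `p` and overdispersion
   `φ` (fitted per sample by robust maximum likelihood). Copy number `c`
   rescales the odds: `p' = q·p / (q·p + 1 − p)` with `q = c/2`. A
   three-state HMM (deletion CN1 / diploid CN2 / duplication CN3, entry
   probability 10⁻⁴, expected CNV length 5 targets) is decoded by
   Viterbi; maximal non-diploid runs become calls with a log₁₀ Bayes
   factor (called state vs diploid, summed over the segment) and an
   observed/expected depth ratio.
4. **Reproducibility.** Each sample is re-called many times against
   random control subsets (by default 1000 iterations × 200 controls);
   the number of iterations in which each initial call recurs ranks calls
   from high to low confidence, and regions called as both deletion and
   duplication are flagged type-inconsistent.
5. **Benchmarking.** Array-derived CNVs pass a staged cascade (no chrY,
   ≥ 10 probes, ≥ 1 exon and ≥ 1 bait overlap) to form a truth set;
   stratified sensitivity (type, zygosity, chromosome, size, clinical
   status) and a false-discovery-rate review protocol (≥ 10 probes, two
   polymorphic regions excluded, manual labels consumed as data) produce
   the summary tables.

A synthetic-cohort simulator (negative-binomial counts over a log-normal
target baseline, batch factors, decoy low-mappability targets with shared
mis-mapping noise, spiked CNVs, and matching array-style truth records)
makes the entire workflow runnable and testable without any external
data.

## Worked example

```r
library(exocnv)

# simulate a 30-sample cohort with one heterozygous deletion spiked into
# sample S005 over five consecutive targets
ev  <- tibble::tibble(sample = "S005", start_target = 40L,
                      end_target = 44L, copy_number = 1L)
cfg <- simulation_config(n_controls = 30, n_targets = 200, chromosomes = 2,
                         mean_depth = 200, events = ev, seed = 42)
sim <- simulate_cohort(cfg)

# mappability filter, then call the spiked sample against the rest
targets <- sim$targets |>
  annotate_mappability(simulate_mappability_track(sim$targets)) |>
  filter_by_mappability()          # excludes mean mappability <= 0.75
calls <- call_sample("S005", sim$counts, targets)
calls
#> # A tibble: 1 x 8
#>   sample_id chrom start   end cnv_type  n_targets    bf ratio
#>   <chr>     <chr> <int> <int> <chr>         <int> <dbl> <dbl>
#> 1 S005      chr1  40000 44150 deletion          5  16.5 0.522
attr(calls, "r2")   # 0.982 — passes the 0.97 correlation QC gate
attr(calls, "phi")  # 0.00298 — fitted overdispersion
```

The single call spans exactly the five spiked targets; `bf = 16.5` means
the deletion is 10^16 times more likely than the diploid state over the
segment, and `ratio = 0.52` is the observed/expected depth — a
heterozygous deletion. Scoring it over 10 recalling iterations against
random 20-control subsets (`run_iterations()` + `score_reproducibility()`)
detects it in 10/10.

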