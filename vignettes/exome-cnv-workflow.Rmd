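---
title: "Calling copy-number variants from exome read depth with exocnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling copy-number variants from exome read depth with exocnv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exocnv)
library(dplyr)
```

## The model

Read-depth CNV detection rests on one assumption: at a given capture
target, depth is proportional to the underlying copy number. Everything
else in the workflow exists to protect that assumption from the things
that break it in practice — batch effects, capture efficiency, GC
content, and above all mappability.

For a test sample with count $y_i$ at target $i$ and an aggregated
reference panel with count $R_i$, we model the test's share of the
combined count $n_i = y_i + R_i$:

$$y_i \mid n_i \sim \mathrm{BetaBin}(n_i,\; p'_i,\; \varphi),$$

where the diploid expected proportion $p$ is the ratio of total test to
total test-plus-reference counts over informative targets, and copy
number $c$ rescales the odds:

$$p' = \frac{q\,p}{q\,p + 1 - p}, \qquad q = c/2 .$$

A heterozygous deletion ($c = 1$) halves the test sample's odds of
contributing a fragment; a duplication ($c = 3$) multiplies them by 1.5.
The beta-binomial is parameterised with shape $\alpha = p'/\varphi$,
$\beta = (1-p')/\varphi$, so $\varphi \to 0$ recovers the binomial
exactly — a limit the test suite checks against `dbinom()`, and the
reason `phi = 0` is a legal caller setting.

Conditioning on $n_i$ rather than modelling $y_i$ directly makes the
per-target baseline cancel: a target that always captures poorly
captures poorly in both test and reference, so only *relative* dosage
remains. This is why no GC or depth normalisation step precedes the
caller — reference matching absorbs it.

### Segmentation

States CN1 (deletion), CN2 (diploid), CN3 (duplication) form a hidden
Markov chain along the ordered targets of each chromosome. With entry
probability $t$ (default $10^{-4}$) and expected CNV length $E$ targets
(default 5):

* CN2 → CN1 or CN3 with probability $t$ each;
* a CNV state persists with probability $1 - 1/E$, returns to CN2 with
  $1/E - t$, and jumps to the opposite CNV state with $t$;
* the initial distribution is $(t,\, 1-2t,\, t)$.

Transitions are distance-independent: the paper-scale workflows this
package follows do not model inter-target genomic gaps, and adding a
decay would introduce a parameter nothing in our validation can
constrain. Viterbi decoding gives the MAP state path; ties are resolved
in favour of CN2, so degenerate inputs yield fewer calls. Each maximal
non-CN2 run becomes a call with a log₁₀ Bayes factor — the summed
emission log-likelihood difference between the called state and CN2 —
and an observed/expected depth ratio. For chromosomes of ≤ 8 targets the
test suite checks the decoder against exhaustive enumeration of all
$3^8$ paths.

### Reference panel selection

Controls are ranked by Pearson correlation with the test sample's count
profile and aggregated cumulatively in rank order; the panel kept is the
rank prefix whose aggregate correlates best with the test sample
(`select_reference()`). We deliberately evaluate every prefix rather
than stopping at the first non-improving control: one locally unhelpful
control can precede several helpful ones, and stopping early measurably
misses the optimum. On pools of six controls with graded noise the
chosen panel matches exhaustive search over all 63 subsets; when the
unconstrained optimum is not a prefix of the correlation ranking (rare,
and unreachable for any rank-ordered greedy) the two can differ — a
limitation we accept for the enormous saving over $2^n$ subsets.

`call_sample()` additionally enforces a minimum panel of 3 controls
(`min_panel`): a single-control reference leaves so much counting noise
in the per-target expectation that 1.5× duplications become
undetectable, and we observed exactly this failure on artifact-affected
samples whose best single control shared their artifact profile.

### Overdispersion

$\varphi$ is fitted per sample by maximum likelihood under the
assumption that every target is diploid. That assumption is wrong at CNV
and artifact loci, so the fit is robust: after an initial fit, targets
deviating more than 4 beta-binomial standard deviations from expectation
are dropped and $\varphi$ is refit (up to twice). Without trimming, a
handful of mis-mapping artifact loci can inflate $\varphi$ several-fold,
which silently desensitises segmentation genome-wide — the failure mode
is not a wrong $\varphi$ so much as a caller that stops seeing
duplications. Parameter recovery on 10,000 simulated targets returns
$\varphi$ within ±20% of the generating value, and pure-binomial data
returns $\varphi = 0$.

### Quality gate

Before calling, the squared Pearson correlation between the test sample
and its aggregate reference over the included targets must reach 0.97;
the gate is inclusive (exactly 0.97 passes). Rejected samples get a
`qc_failed` status and an empty call set rather than unreliable calls.

## Mappability filtering

Per-exon mean mappability is the base-wise arithmetic mean of the 35-mer
uniqueness score over the exon body $[\mathrm{start}, \mathrm{end})$ —
no flanking padding, because the exon footprint is the minimal reading
of "mean mappability across the exon". Bases absent from the track count
as 0: missing uniqueness data is treated as non-unique, the conservative
direction for a filter whose purpose is exclusion. Exons with mean
mappability **≤ 0.75** are excluded (the boundary itself is excluded).
The filter runs before counting and calling; excluded exons can never
appear inside a call.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws a per-target baseline depth from a log-normal
(median depth spread of roughly an order of magnitude across targets,
`sdlog = 1`), multiplies by a per-sample batch factor, applies the
spiked copy-number events as a $c/2$ factor, and draws counts from a
negative binomial (`size = 100`). Three choices deserve comment:

* **Different family on purpose.** The generator is negative-binomial
  over a log-normal baseline while the caller fits beta-binomial
  proportions. Simulating from the fitted family would make every test a
  self-confirmation; generating from a different family tests
  robustness.
* **The depth regime.** `sdlog = 1` and `size = 100` put cohorts in the
  regime where target-to-target depth variation dominates counting
  noise, which is what makes reference correlation high (r² ≈ 0.98) and
  the 0.97 QC gate meaningful — most samples pass, as real cohorts do.
  Mean depth defaults to 200 fragments/target, the depth used throughout
  the validation experiments.
* **Decoys.** A fraction of targets (default 5%) are decoys emulating
  pseudogene/segmental-duplication territory: their mappability track
  averages 0.3, and they receive an extra mis-mapping count term (mean
  2× the target depth — a near-identical homolog donates read mass
  comparable to the true locus) shared by a random half of the samples.
  A quarter of decoys are "escaped" decoys with mean mappability 0.8:
  they survive the 0.75 filter while still carrying noise, reproducing
  the recurrent artifact calls that motivate reproducibility ranking in
  the first place.

The simulator does **not** model GC-content effects, read-level errors,
breakpoints inside targets, sex chromosomes, or correlated (LD-like)
artifact structure across regions. Passing tests therefore demonstrate
that the implementation behaves correctly under the stated statistical
structure — not that real-exome sensitivity will match the simulated
numbers.

Simulated experiments place spiked CNVs on *callable windows*
(`callable_windows()`: runs of non-decoy targets, optionally with a
baseline-depth floor). This mirrors the benchmarking reality that
array-confirmed truth CNVs necessarily sit on assayable territory;
spiking a CNV onto a near-zero-depth or decoy target would test nothing
a read-depth method can deliver. Duplication spikes span 8 targets where
deletion spikes span 5: a 1.5× odds shift carries less information per
target than a 0.5× shift, consistent with duplication sensitivity
trailing deletion sensitivity in every benchmark stratum.

## Reproducibility framework

`run_iterations()` re-calls a sample `n_iterations` times (default 1000)
against control subsets of `subset_size` (default 200) drawn uniformly
without replacement from the pool. Child seeds are a counter-based
integer mix of (master seed, sample id, iteration), so per-sample runs
are reproducible, parallelisable and resumable without changing any
draw; identical master seeds produce byte-identical score tables.

Two calls are "the same region" if they share at least one included
target and have the same type. Target sharing, rather than coordinate
equality or reciprocal overlap, is robust to the boundary jitter that
different reference panels induce; a region called as deletion in some
iterations and duplication in others is flagged `type_consistent =
FALSE`, the signature of polymorphic or reference-artifact loci.
Iterations in which the sample fails QC against the subset's aggregate
still count in the denominator — a call not made is a call not detected.

At test scale (50 iterations × 20-control subsets on a 300-target
cohort), spiked true CNVs are detected in every iteration while artifact
calls score visibly lower (medians around 25–45 of 50), which is the
ranking premise the framework exists to exploit.

## Benchmarking choices

* The truth cascade keeps array CNVs with ≥ 10 probes (inclusive), at
  least 1 bp overlap with ≥ 1 exon and ≥ 1 bait, and drops every chrY
  record; stage counts are recorded for cascade reporting.
* Truth-to-call matching is shared-included-target + compatible type
  (het/hom/hemi deletions ↔ called deletion; duplications and
  triplications ↔ called duplication). No reciprocal-overlap fraction is
  used: both platforms are compared on exonic territory, and exon
  sharing is the natural unit there.
* Probe counting for FDR review uses the closed interval — a probe on a
  call boundary counts.
* Interval sizes are reported as end − start on 1-based display
  coordinates, applied uniformly.
* Display percentages round to the nearest integer, except FDR, which is
  reported to one decimal; empty strata report `NA`, never 0%.
* The two polymorphic exclusion regions (KIR on chr19 and HLA on chr6,
  hg19) ship as a packaged BED; users may substitute their own.

## Numerical and degenerate-input behaviour

* Targets with zero aggregate reference coverage have undefined expected
  proportion; they are masked from segmentation and can never sit inside
  a call.
* `phi = 0` dispatches to the exact binomial log-pmf, so the limit is
  exact rather than approximate.
* Viterbi ties prefer CN2, then CN1, then CN3 — deterministic and
  call-minimising on degenerate (e.g. exactly proportional) input.
* Multiplying every count by a constant changes no call boundary on
  noiseless fixtures (scale consistency).
* Duplicate target intervals collapse to one with a warning; a BED
  record with `start >= end` is a parse error naming the line.

## Problem sizes used in the shipped experiments

Simulated experiments use cohorts of 25–30 samples over 200–3000
targets at mean depth 200, 100 spiked deletions for recall estimation,
50 × 20 resampling for reproducibility, 200 eight-target fixtures for
the Viterbi oracle, and 10,000 targets for overdispersion recovery.
These sizes were chosen so each experiment measures its quantity with
adequate precision while the whole suite stays convenient to run
routinely.

## Known limitations

* Zygosity (het/hom/hemi, dup vs trip) is consumed from the array side,
  never inferred: the caller has no CN0 or CN4 state, and homozygous
  deletions surface as CN1 segments with ratio ≈ 0.
* chrX is processed like an autosome; correlation-based panel selection
  matches sex implicitly, which is adequate for cohorts with both sexes
  represented but has no explicit ploidy model.
* Transition probabilities are distance-independent and the emission
  expectation is a single genome-wide proportion; both are configurable
  but deliberately simple.
* The reproducibility score is a frequency, not a calibrated
  probability; thresholds for "high confidence" are cohort-specific
  empirical choices.
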