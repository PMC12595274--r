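---
title: "Methods: MSI screening from cell-free DNA allele spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MSI screening from cell-free DNA allele spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiscreen)
```

This vignette is the package's account of its statistical model, the
choices made where the design was genuinely open, and what the simulation
framework does and does not establish about real data.

## The measurement

A mononucleotide microsatellite amplicon yields, per sample and marker, a
histogram of read counts over allele-length *offsets* — signed
nucleotide differences from the reference repeat length, with 0 the
reference allele, negative offsets deletions, positive insertions. Two
processes move reads off the reference allele:

* **PCR/sequencing stutter**: polymerase slippage during amplification,
  strongly deletion-biased for mononucleotide runs and increasing with
  repeat length. It affects every sample, including DNA from normal
  tissue.
* **Somatic instability**: in mismatch-repair-deficient (MMRd) tumours,
  replication slippage goes unrepaired and markers acquire somatic
  alleles, typically multi-nucleotide deletions. In a cell-free DNA
  (cfDNA) specimen these alleles appear at a frequency proportional to
  the *tumour fraction* — the proportion of cfDNA molecules of tumour
  origin, high in tumour tissue, much lower in urine cfDNA, near zero in
  plasma and blood.

The per-marker evidence summary is the variant allele frequency (VAF):
one minus the reference-allele read fraction.

## The generative model used for simulation

`simulate_spectrum()` draws `depth` reads from a two-component mixture
over offsets, with exact probabilities available from `spectrum_pmf()`:

* **Background** (weight `1 − tumour_fraction`): the reference allele
  convolved with a stutter kernel. The number of 1-nt slippage steps is
  geometric with parameter `stutter_rate` (truncated at 8 steps and
  renormalised), and each stuttered read is a deletion with probability
  3/4, an insertion with 1/4 — the deletion:insertion odds reflecting
  the empirical deletion dominance of mononucleotide stutter.
* **Unstable** (weight `tumour_fraction`): a somatic deletion whose size
  is a discretised normal (`mmrd_deletion_mean` = 4 nt,
  `mmrd_deletion_sd` = 1.5 by default, floored at 1 nt), convolved with
  the same stutter kernel.

Key parameter defaults, chosen once as field-realistic values:

| parameter | default | rationale |
|---|---|---|
| panel size | 14 markers | screening panel size for this assay class |
| reference repeat length | 20–27 nt | typical clinical mononucleotide markers |
| `stutter_rate` | 0.06–0.16, increasing with repeat length | longer homopolymers slip more |
| `mmrd_deletion_mean` / sd | 4 / 1.5 nt | multi-nucleotide deletion shifts seen in MMRd spectra |
| depth per marker | 2,000 reads | comfortably above the QC floor; the assay itself works from sub-nanogram input so depth is a free parameter |
| urine tumour fraction (affected) | log-uniform on [0.01, 0.5] | urine cfDNA tumour content is unmeasured in the screening literature; log-uniform spreads an order of magnitude |
| tissue tumour fraction | uniform on [0.4, 0.9] | resected tumour tissue with a purity floor |
| per-marker instability | uniform on [0.3, 1], shared within a subject | not every tumour-derived molecule carries the unstable allele at every marker; the shared subject-level pattern is what makes urine–tumour VAF concordance informative for source attribution |

Cohort simulation (`simulate_cohort()`) supports two designs: a
*symptomatic* design in which each subject is MMRd with a fixed
prevalence and contributes paired urine, tumour and blood specimens, and
a *screening* design in which each subject harbours an occult carcinoma
with probability `1 − (1 − annual_incidence)^lead_time_years`. The
geometric compounding is used rather than the linear approximation
`incidence × lead` on probabilistic-correctness grounds; at screening
incidences the two differ negligibly. All randomness flows from one
master seed through counter-based substreams per subject and marker, so
cohorts are bit-reproducible and independent of evaluation order.
Longitudinal trajectories (`simulate_longitudinal()`) set the urine
tumour fraction to zero after a resection or ablation event and restore
it after a recurrence.

## The classifier

`train_classifier()` fits, per marker, class-conditional beta densities
for the VAF under the MSI-high and MSS classes, and `score_sample()`
combines them naively (independence across markers):

$$ S \;=\; c \sum_m \log_{10}
   \frac{f_m(v_m \mid \mathrm{MSI\text{-}H})}{f_m(v_m \mid \mathrm{MSS})}. $$

Design choices that were genuinely open, and how they were resolved:

* **Density family and fit.** Beta densities, method of moments, with
  class-specific means but a **pooled concentration** (the smaller of
  the two class moment estimates). With independently fitted
  dispersions, a tightly concentrated MSS fit sends the likelihood ratio
  back *down* once the VAF passes the MSI-high mode, so a sample with
  extreme instability could score lower than a moderately unstable one
  — and scores were observed to be non-monotone in tumour fraction.
  With a pooled concentration the log ratio is linear in logit(VAF) with
  positive slope whenever the MSI-high mean exceeds the MSS mean, so
  evidence is monotone in instability by construction. Choosing the
  *smaller* concentration is deliberate: the MSI-high class spread is
  dominated by biology (tumour fraction varies), the MSS spread by
  binomial sampling at one depth, and the wider class should set how
  sharply a VAF can be scored.
* **Evidence bound.** The per-marker log ratio is evaluated in log space
  (no density underflow) and bounded at ±`-log10(pseudocount)` (default
  pseudocount `1e-6`, so ±6 log10 units): one marker can contribute at
  most that much in either direction, and every ratio is finite at
  boundary VAFs. Flooring raw densities instead would collapse the
  ratio to 0/0 at VAFs in neither class's support.
* **Equal class priors.** The score is a pure summed log-likelihood
  ratio; no prior term.
* **Log base 10**, with the reporting scale set by a single positive
  multiplier `c` calibrated so that the 1st–99th percentile of
  training-set scores spans approximately [−25, +30]:
  `c = min(30/q99, −25/q01)`. One multiplier cannot pin both ends, so
  one end of the calibrated range touches its target and the other lies
  inside it; on fresh data the extreme percentiles can exceed the range
  by sampling variation (tests allow 20%).
* **Calls and ties.** `S ≥ 0` is MSI-high. A score of exactly 0 is
  called MSI-high: the sensitive tie-break for a screening test, and 0
  is inside the borderline zone, so the call triggers repeat testing
  regardless. The borderline zone is the closed interval [−5, +5].
* **QC.** Markers need ≥ 100 reads to contribute; samples need ≥ 10 of
  14 contributing markers to pass QC (a call is still reported, flagged,
  down to 1 marker; zero usable markers yield a no-call QC failure).
  These thresholds are package defaults, not assay constants.

## Screening workflow

Borderline primary results trigger repeat testing (`resolve_call()`):
a clear repeat's call stands; a borderline that cannot be repeated or
stays borderline is treated as MSI-high. In simulation, a repeat is a
fresh specimen drawn at the subject's true tumour fraction (emulating
re-collection, not re-sequencing). Adjudication requires at least 365
days of follow-up for a negative to count as a true negative; cases
failing that gate are unevaluable and excluded from the contingency.
This policy is monotone: treating borderlines as positive can only
increase sensitivity relative to a strict `S > 0` rule, which the tests
assert on matched simulated cohorts.

## Spectra analysis

`normalize_spectrum()` subtracts a matched background specimen's allele
frequencies per offset (blood cfDNA taken to represent amplification
error, not tumour signal), over the union of observed offsets; deltas
are signed and never truncated, and sum to zero by construction.
`vaf_concordance()` correlates per-marker VAFs between two specimens
(product-moment by default, rank correlation as a robustness option),
using background-corrected VAFs when references are supplied — without
that correction, the shared marker-wise stutter floor inflates the
correlation between unrelated samples. No hypothesis test is attached:
attribution is reported as a descriptive statistic.

## Diagnostics

Clopper–Pearson intervals use the beta-quantile closed form; the test
suite validates them against a bisection solver of the binomial tail
equations and against `stats::binom.test`, guarding against off-by-one
tail conventions. ROC curves sweep thresholds over unique scores with
trapezoidal AUC, cross-checked internally against the Mann–Whitney rank
statistic with half-weight ties, and externally (in tests) against
pROC. Percentages are displayed to one decimal with the convention that
a bound strictly inside (0, 1) never prints as 0.0% or 100.0% — an
upper bound of 0.9997 displays as 99.9%, so the display never
overstates certainty.

## Problem sizes and what the tests show

The simulation studies in the test suite use: 60 training samples per
class at depth 2,000; 100-replicate screens of 80-subject cohorts with
4 detectable cancers (urine tumour fraction ≥ 0.1); monotonicity grids
of 200 profiles per tumour fraction at depth 500; 200-seed concordance
studies; and 10⁴-replicate coverage checks per (n, p) cell. These sizes
make the full suite run in a few minutes while leaving Monte-Carlo
margins well beyond the assertion thresholds.

Passing tests establish that the pipeline is internally correct — the
scorer is additive, monotone in tumour fraction, equivalent to
brute-force naive Bayes, and recovers known simulation parameters; the
screen detects simulated cancers at detectable fractions with the
published policy. They do not establish field performance: the
generator has independent markers (no inter-marker covariance), clean
multinomial sampling (no PCR duplicates, contamination, or alignment
artefacts), a single stutter kernel shared by both mixture components,
and urine tumour fractions drawn from an assumed distribution, since no
published measurements exist to calibrate against. Real-data
sensitivity at low tumour fractions depends on where true urine tumour
fractions lie relative to the classifier's decision region, which
simulation cannot settle.

## Known limitations

* The classifier is re-trained on synthetic data; no claim is made to
  reproduce any proprietary trained model's per-sample scores.
* Mutation-hotspot evidence (which would extend the assay beyond MSI)
  is out of scope, as are raw-read processing and plasma-specific
  modelling beyond a near-zero tumour-fraction sample type.
* Comparator modalities (urinalysis, cytology, imaging) enter only as
  fixed contingency counts for the diagnostics module; their operating
  characteristics are not modelled.
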