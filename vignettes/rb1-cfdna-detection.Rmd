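---
title: "Detecting somatic RB1 mutations in plasma cfDNA: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic RB1 mutations in plasma cfDNA: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rbcfdna)
```

## The problem

Retinoblastoma is driven by biallelic inactivation of *RB1*. Modern therapy
preserves the eye in most children, which removes the traditional source of
tumor tissue for molecular profiling; without the tumor's *RB1* mutations,
clinical germline testing of blood is formally non-informative. Plasma
cell-free DNA (cfDNA) offers a non-invasive alternative: a small fraction
of cfDNA is tumor-derived, so a targeted panel over the 27 *RB1* exons
sequenced to ~1500x unique coverage can, in principle, reveal the tumor's
somatic mutations at variant allele frequencies (VAF) of a fraction of a
percent.

At those VAFs the signal competes with sequencing and library-preparation
error, so detection must be framed statistically. This package implements
two complementary tracks over per-site allele counts:

* **tumor-guided genotyping** — query cfDNA only at mutations already known
  from the patient's tumor. Because the prior probability that a specific
  tumor mutation recurs as an artifact is small, a low evidence bar is
  justified;
* **de novo calling** — discover mutations across the panel with no tumor
  knowledge, under a much stricter filter cascade.

## The detection model

Let a variant have $b$ alt-supporting reads out of $d$ qualifying reads in
cfDNA, so $\hat v = b/d$ (defined as 0 when $d = 0$: an uncovered site can
never be detected). For each variant, the buffy coats of the *other*
patients in the cohort — where the somatic mutation cannot be present —
provide an empirical error null: with per-sample VAFs $x_1,\dots,x_n$,

$$ T \;=\; \bar x + k\,s, \qquad
   s^2 = \tfrac{1}{n-1}\sum_i (x_i - \bar x)^2, \quad k = 2 . $$

A tumor-guided variant is **detected** iff all of

1. $b \ge 3$ supporting reads;
2. $\hat v_{\text{cfDNA}} > \hat v_{\text{buffy, matched}}$ (strict);
3. $\hat v_{\text{cfDNA}} > T$ (strict);
4. at most 50% of the $b$ alt reads are artifact-flagged.

A de novo candidate must instead satisfy $\hat v > 0.5\%$ **and** $b \ge
10$, have $\hat v_{\text{cfDNA}} \ge 2\,\hat v_{\text{buffy}}$ ("at least 2
times" — ties pass, unlike the strict inequalities above, following the
wording difference between the two rules), again clear $T$, pass the
artifact rule, and pass an extreme strand-bias screen. Given the same
background model, every de novo call would also be detected by genotyping:
the de novo criteria are uniformly stricter, which the test suite asserts
on simulated cohorts.

The read-count floor sets the theoretical detection limit at a site:

```{r}
theoretical_detection_limit(3, 1596)   # ~0.0019, i.e. just under 0.19%
```

### Numerical conventions

* *Sample* standard deviation ($n-1$) is used for the null; with a single
  panel sample the SD is defined as 0. This is the conservative convention
  for a nine-sample panel.
* Ties never pass a strict criterion; an all-zero panel gives $T = 0$, so
  criterion 3 passes for any non-zero VAF and the read floor of criterion 1
  carries the burden. No artificial floor is added in the genotyping
  track; the de novo track has its own 0.5% floor.
* Panel samples with zero coverage at a variant enter the null as VAF 0
  (logged). Excluding them would be equally defensible; including them is
  the more conservative choice only when the panel is otherwise noisy, and
  it keeps $n$ stable across variants.
* Criterion 2 with both VAFs zero fails (0 > 0 is false); such cases
  already fail the read floor.
* The artifact fraction uses alt-supporting reads as its denominator
  (artifact-flagged alt reads / alt reads), the usual genotyping-review
  convention; zero alt reads passes vacuously.

### Surrogates for manual review

The original workflow manually reviewed candidate calls in a genome
browser. Reproducibility demands an algorithmic stand-in, so two automated
heuristics act in its place: the artifact-fraction rule above and a
strand-bias screen that fires only when *all* alt reads sit on one strand,
there are at least 10 of them, and a two-sided Fisher exact test against
the reference reads gives $p < 0.005$. The pileup dialect does not carry
the reference strand split, so the reference reads are taken as evenly
split; since the screen only ever acts on all-one-strand support, this
convention does not change any decision it is allowed to make. The
thresholds are deliberately lax: the screen should only remove gross
artifacts, never borderline biology.

## Germline versus somatic

Germline heterozygotes sit near 50% VAF in the buffy coat; tumor-derived
somatic variants are absent from it. The published procedure names the
goal (filter out germline variants) but not a numeric rule, so the package
instantiates one with all constants exposed in `detection_thresholds()`:

* **germline** — exact two-sided binomial test of the buffy alt count
  against 0.5 not rejected at level 0.01, and buffy VAF ≥ 0.30;
* **somatic** — buffy coat essentially clean: ≤ 3 alt reads or VAF < 2%;
* **ambiguous** — anything between, e.g. mosaic-like intermediate VAFs.
  Mosaicism is deliberately mapped to "ambiguous" and never auto-resolved;
  ambiguous variants stay in the somatic report carrying a flag.

Because the germline branch is tested at level 0.01, about 1% of true
heterozygotes will be rejected by the exact test and land in "ambiguous";
germline recall is therefore bounded near 99% by construction, while
somatic precision is unaffected (a rejected heterozygote never routes to
"somatic" — its VAF is far above the 2% ceiling). The property tests
assert exactly this behaviour rather than a nominal 100% recall.

```{r}
buffy <- allele_count("P07.buffy", "buffy_matched", "chr13", 48941648,
                      "C", "T", depth = 1500, alt_reads = 737)
cfdna <- allele_count("P07.cfdna", "cfdna", "chr13", 48941648,
                      "C", "T", depth = 1520, alt_reads = 745)
v <- variant_key("chr13", 48941648, "C", "T")
classify_germline(v, buffy, cfdna)[, c("buffy_vaf", "binomial_p", "verdict")]
```

## The synthetic cohort generator

No raw sequencing data ships with the package; a count-level generator
produces cohorts with the statistical structure the analysis assumes,
plus ground truth for scoring. Per sample and site:

* depth $\sim$ NegBin(mean $\mu$, size 60) — mildly overdispersed around
  the cohort mean of 1530x so that low-depth and depth-0 edge cases occur;
  site-level capture-efficiency multipliers scale $\mu$;
* reads split multinomially: true-variant reads with probability
  $v(1-e)$, allele-specific error reads with probability $(1-v)e/3$
  (substitutions; indel errors use their own, lower, rate of $5\times
  10^{-5}$), reference reads otherwise. The default $e = 5\times 10^{-4}$
  is a typical post-deduplication substitution error rate for hybrid-
  capture sequencing;
* artifact flags are Bernoulli(0.1) on error-origin reads only, so the
  artifact-fraction rule can be exercised without contaminating true
  signal; strand split is Binomial(alt, 0.5);
* germline variants are drawn at $v = 0.5$ in cfDNA, buffy coat and tumor;
  somatic variants at their true cfDNA VAF, 0 in the buffy coat, 0.45 in
  the tumor;
* recurrent, library-type-specific artifacts can be seeded at chosen sites
  via `panel_error_vaf`, which adds error VAF to every *buffy-coat*
  library at that site — the situation the unmatched-panel null exists to
  catch;
* technical replicates are fresh draws under identical truth.

Simulation is count-level, not read-level: every detection criterion
operates on counts, so simulating reads would add cost without test
power. The generator does **not** model fragment-size distributions,
GC/coverage bias, UMI families, or clonal hematopoiesis; passing tests
demonstrate correctness of the decision rules under binomial sampling and
a stylized error model, not performance on real libraries.

### The reference cohort

`rb1_reference_cohort()` is a fixed truth object emulating a ten-patient
study: 13 somatic mutations plus one germline heterozygote, five patients
with technical replicates, and a synthetic 27-exon *RB1* panel
(`rb1_panel()`; coordinates are plausible for chromosome 13 but synthetic —
the statistics never depend on real genomic coordinates). Its construction
encodes the qualitative pattern such a study observes:

* ten genotyping-detectable somatic VAFs with median 0.049 and maximum
  0.126; the mean over all 13 somatic variants is ~0.038;
* exactly seven of the ten also clear the de novo floors. The three
  genotyping-only variants are placed at true VAF 0.003 on deeply captured
  sites (~6000x): deep enough that the 3-read genotyping floor is met
  essentially always, while the estimated VAF sits ~2.8 SE below the 0.5%
  de novo floor. Seeding them just above 0.5% instead would leave their de
  novo verdict a coin flip at this depth — the two floors would not
  separate reproducibly;
* one patient's two variants are seeded below threshold by a recurrent
  buffy-coat artifact (`panel_error_vaf = 0.004`) at their sites: the
  background threshold (~0.8%) and the matched-buffy VAF both sit far above
  their faint cfDNA signal (~0.09% and ~0.04%), so criteria 2 and 3 fail
  deterministically while at least one supporting read remains —
  subthreshold evidence, not detection;
* one patient sheds nothing (true VAF 0; the analogue of a patient treated
  with systemic chemotherapy before the blood draw), and one patient
  carries a germline heterozygote alongside a distinct somatic mutation at
  VAF 0.0137, exercising the germline filter end to end.

With these margins the end-to-end counts (10/13 mutations in 8/10 patients
by genotyping; 7/13 in 6/10 de novo) follow from the construction with
high probability per seed; the residual risk is dominated by the germline
binomial test's 1% level.

```{r}
truth <- rb1_reference_cohort()
truth
ds <- simulate_cohort(truth)
geno <- genotype_cohort(ds$tumor_variants, ds$pileup)
part <- filter_germline(geno$results,
                        classify_germline_cohort(ds$tumor_variants, ds$pileup))
cohort_summary(part$somatic[part$somatic$primary, ])
```

## Replicate concordance and scoring

`score_pipeline()` compares results with truth: genotyping and de novo
sensitivity over shedding somatic variants, false de novo calls, VAF bias
and absolute error, and the squared Pearson correlation between VAF pairs
of variants detected in both technical replicates. At ~1500x, binomial
noise alone bounds the attainable $r^2$: with measurement variance
$v(1-v)/d$ on each replicate and between-variant VAF variance
$\sigma_T^2$, the expected correlation is
$\sigma_T^2 / (\sigma_T^2 + v(1-v)/d)$. The acceptance property therefore
uses VAF pairs spread over 0.02–0.15, where the expected $r^2$ is ~0.98.

## Problem sizes and determinism

All stochastic tests fix their seeds, and `simulate_cohort()` is
bit-identical given (truth, seed). The test suite works at the cohort
sizes the methods target — 9-sample panels, ~1500x depths — with
Monte-Carlo sizes (1000 replicates for the sensitivity/specificity and
VAF-recovery properties, a few hundred for background calibration) chosen
to keep each property's sampling error a small fraction of its margin.

## Known limitations

* Variant normalization trims shared bases but does not left-align across
  repeat tracts (that requires the reference sequence); inputs are assumed
  to come from a consistent caller.
* The background null is strictly per-variant; there is no position-level
  or trinucleotide-context error model, and nothing is learned across
  sites.
* The germline rule is a documented surrogate, not a reimplementation of
  any clinical matched-normal caller.
* Discovery is pileup-based; no local assembly or indel realignment is
  performed, so complex indels observable only after realignment will not
  be recovered.
* No copy-number analysis (e.g. *MYCN* amplification) and no longitudinal
  tracking across serial timepoints.
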