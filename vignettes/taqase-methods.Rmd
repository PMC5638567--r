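---
title: "Quantifying allele-specific expression from dual-probe TaqMan curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific expression from dual-probe TaqMan curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taqase)
library(dplyr)
```

## The problem

A hybrid organism that is heterozygous at (essentially) every locus — such
as a clonal, gynogenetic fish carrying one genome from each of two ancestral
species — raises a simple question with a non-trivial measurement problem:
are the two alleles of a gene expressed equally? Allele-specific expression
(ASE) at a single gene can be quantified with a dual-probe TaqMan real-time
PCR assay: one primer pair amplifies both alleles, while two
allele-discriminating MGB probes, labelled FAM (one allele) and VIC (the
other), report each allele's amplicon in its own fluorescence channel.
`taqase` implements the complete analysis path from raw per-cycle
fluorescence to tissue-level ASE statistics, together with a promoter-allele
comparison (variant detection and CpG-island prediction) and a seeded
simulator used to validate every stage.

## From raw curves to k′

### Four-parameter sigmoid, fitted in two steps

Each single-channel amplification curve (46 cycles by default) is fitted
with the four-parameter logistic

$$F(t) = y_0 + \frac{a}{1 + e^{-(t-b)/c}},$$

where $y_0$ is the baseline fluorescence, $a$ the plateau amplitude above
baseline, $b$ the inflection cycle and $c$ the slope scale (cycles). The
raw signal is fitted directly — no baseline pre-subtraction — so $y_0$ is a
fitted quantity, which is also why the model needs four parameters although
the ratio statistic below uses only $a$, $b$ and $c$.

The number of plateau-phase cycles varies from reaction to reaction and
biases a single-pass fit, so fitting is done twice: step 1 on the full
curve, step 2 on cycles up to $\lceil \hat b + 3\hat c\rceil$ (roughly 95%
of plateau height), clamped to $[\hat b + 2, n_\text{cycles}]$. If
truncation would remove fewer than two cycles the step-1 fit stands; if the
step-2 fit fails, the step-1 fit is returned with a fallback flag. The
multiplier 3 is exposed (`plateau_mult`) because the truncation rule is a
design choice, not a law: any cut safely past the inflection does the job,
and the tests verify that truncation strictly reduces the inflection bias on
curves with plateau drift.

Optimisation uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, ftol/ptol `1e-10`, up to 500 iterations) seeded by
closed-form heuristics (curve minimum, range, steepest single-cycle rise,
25–75% crossing width). On failure, five deterministic restarts jitter the
seeds by up to ±30%. Bounds keep $a > 0$ and $c > 0$ so the branch logic of
the ratio statistic is always well defined. Flat curves (range below
machine scale) are refused with a classed "no amplification" condition —
this is the designed behaviour for the empty channel of a pure standard.

### The transformed fluorescence ratio

One reaction yields two fitted channels. They are combined into the
branch-conditional ratio R′, keyed on which channel reached its maximum
amplification speed (inflection cycle) first:

* if $b_{fam} < b_{vic}$:
  $R' = \tfrac12\,\frac{a_{fam}}{a_{vic}}\left(1 + e^{-(b_{fam}-b_{vic})/c_{vic}}\right)$
* if $b_{fam} > b_{vic}$:
  $R' = 2\,\frac{a_{fam}}{a_{vic}}\,\frac{1}{1 + e^{-(b_{vic}-b_{fam})/c_{fam}}}$

and mapped to the unit interval as $k' = R'/(R'+1)$. Both branch formulas
coincide at $b_{fam} = b_{vic}$ (value $a_{fam}/a_{vic}$), so R′ is
continuous in the inflection difference; ties are resolved (tolerance
`1e-9` cycles) to that common value. A pleasant algebraic fact, asserted in
the tests: because each branch uses the slope scale of the *later*
channel, swapping the two channels maps R′ to exactly $1/R'$ and hence k′
to $1-k'$ for *all* parameter values, not only for symmetric slopes.

The orientation of k′ in the allele fraction is deliberately left to the
data. Under a simple generative model, k′ *decreases* as the VIC-detected
allele fraction grows, while published calibrations can show the opposite
sign; the package fits the calibration slope unconstrained, and estimation
is invariant to the orientation (negating every k′ flips the slope and
leaves the estimates unchanged — a tested property).

## Calibration and inversion

Standards are plasmid mixtures with predefined VIC-allele fractions
$x \in \{0, 0.05, 0.1, 0.2, \ldots, 0.9, 0.95, 1\}$, measured in
triplicate. Replicates are averaged per standard (k′ per standard is
defined as the replicate mean), and an ordinary least-squares line
$k' = \beta_0 + \beta_1 x$ is fitted over the 11 *mixed* standards: the
pure standards ($x = 0, 1$) are measured and reported — their replicate CVs
enter the Intra-CV average over all 13 standards — but are excluded from
the regression by default because one of their channels has no template and
behaves aberrantly. A flag (`exclude_pure = FALSE`) restores them.

Unknown samples are inverted analytically,
$\hat x = (\bar k' - \beta_0)/\beta_1$, averaging the technical replicates
first and reporting the spread of per-replicate inversions alongside.
Whether to average-then-invert or invert-then-average is an open choice for
a linear map (they coincide exactly); the package averages first and keeps
both views. Estimates outside $[0, 1]$ are clamped with an explicit flag
rather than erroring, since raw inversions can legitimately leave the
calibrated range. Replicate precision is summarised as
$CV = 100\,\mathrm{sd}(k')/\mathrm{mean}(k')$ (sample sd), and Intra-CV as
the unweighted mean CV over all 13 standards.

The packaged dataset `reference_standards()` contains the published
replicate-averaged k′ and CV values of one cDNA and one gDNA calibration
run of this assay; fitting it reproduces $R^2 > 0.99$ on both assays and
Intra-CVs of 0.70% (cDNA) and 0.45% (gDNA):

```{r reference}
curve <- build_standard_curve(reference_standards("cDNA"), assay = "cDNA")
glance(curve)
intra_cv(reference_standards("cDNA"))
```

## Tissue-level inference

Each biological specimen contributes one estimate per tissue (technical
replicates are pooled before inversion — the study sizes here, four
specimens per tissue, do not support replicate-nested mixed models, which
is a deliberate non-goal). Per tissue, the package reports mean, sd, and a
two-sided one-sample t-test of the mean against 0.5, the balanced 1:1
expression ratio, at $\alpha = 0.05$. Degenerate cases stay visible
instead of erroring: single-specimen tissues are flagged untested, and
zero-variance tissues report $p = 1$ at exactly 0.5 and an infinite-t flag
otherwise. Across tissues, a one-way fixed-effects ANOVA on the per-sample
estimates is followed by Tukey HSD pairwise contrasts (Bonferroni-adjusted
pairwise t-tests are available as an alternative); Tukey is the
conventional companion of a one-way ANOVA and its family-wise adjusted p
is never smaller than the corresponding unadjusted pairwise p (tested).

## The simulator

`simulate_reaction()` is a mechanistic stand-in for the assay: both
amplicons grow by a discrete per-cycle logistic recursion against a
*shared* carrying capacity,

$$N_{ch}(c+1) = N_{ch}(c) + E_{ch}\,N_{ch}(c)\,\bigl(1 - \tfrac{N_{FAM}(c)+N_{VIC}(c)}{K}\bigr),$$

because the two alleles are amplified by the same primers and compete for
the same reagents; fluorescence is a linear readout per channel plus iid
Gaussian read noise. Defaults (1e5 template copies, $K = 10^{12}$,
efficiencies FAM 0.90 / VIC 0.905, gain 3e-12, baseline 0.1, noise sd
0.005, 46 cycles) put inflections in the low-to-mid 20s of 46 cycles, as in
typical runs. The slight efficiency asymmetry mimics the small allelic
asymmetry real dual-probe assays show (a published balanced standard reads
k′ = 0.522, not 0.5); it is kept small so that the k′–x link stays close to
linear — at these defaults the noiseless link has $R^2 > 0.999$ and the
inversion bias is below 0.01 everywhere on $[0.05, 0.95]$. The link is
strictly monotone in the true fraction (tested over a grid), which is what
makes calibration invertible; pure-template reactions leave one channel at
baseline noise and are flagged rather than fitted, reproducing the
aberrant behaviour of measured pure standards.

Two structural notes. First, PCR is genuinely discrete per cycle, and the
discrete logistic map is *not* exactly a continuous four-parameter
logistic: the structural lack of fit is about $1.3\times10^{-3}$ of the
squared plateau amplitude, which the tests freeze as a bound rather than
pretending the model is exact. Second, with a shared carrying capacity and
equal efficiencies both channels would inflect at identical cycles
whatever the composition; the efficiency asymmetry is what makes the
better-represented allele's channel inflect measurably earlier.

Plates derive one well seed per reaction from a fixed hash,
`(seed * 1000003 + index) mod (2^31 - 1)`, so simulations are
bit-reproducible. Tissue studies draw per-specimen true fractions from
tissue-specific Gaussians; the defaults use the ovary-biased /
brain-and-gill-balanced pattern of the hybrid-fish system this package
models, with its reported between-specimen sds (ovary 0.770 ± 0.02, brain
0.462 ± 0.04, gill 0.407 ± 0.09). For gDNA null checks the tests use a
between-extract sd of 0.015 around 0.5: real heterozygous gDNA runs spread
on that scale once measurement error is included, and a simulation with
*only* shared technical noise would let any systematic calibration bias,
however small, reject the 1:1 null — a property of the t-test, not of the
assay.

What the simulator does *not* emulate: probe cross-talk between channels,
cycle-correlated drift (available only as an explicit option when
exercising the two-step fit), thermodynamic probe binding, or
instrument-specific noise spectra. Passing the simulation-based tests
therefore demonstrates that the estimator chain is correct and unbiased
under a plausible competitive-amplification model — not that it is robust
to every artefact of a particular instrument.

A consequence worth stating plainly: with four specimens per tissue and
per-tissue t-tests at $\alpha = 0.05$, a tissue whose true fraction sits
near 0.5 still gets rejected about 5% of the time (more, with the gill's
wide biological spread). The joint event "only the ovary-like tissue is
significant" therefore cannot occur in much more than ~90% of repeated
studies even in the best case, and at the realistic effect sizes and
spreads above the observed rate is near 50–65%. The package reports this
measured rate honestly instead of engineering the simulation to hide it.

## Promoter comparison

The two promoter alleles are aligned with Needleman–Wunsch (match +1,
mismatch −1, linear gap −2; ties broken deterministically diagonal → up →
left). A linear gap penalty is appropriate because the target use case is
two alleles differing by a SNP and a single 1 bp indel; affine scoring is
unnecessary and the scores are configurable anyway. Variants are read off
the alignment columnwise, adjacent gap columns merged into single indel
events, and positions reported 1-based on the first sequence (insertions
anchored at the base immediately 5′ of the inserted run). Which allele
provides the coordinate system is a documented convention — the source
data do not fix it.

CpG islands use the classical sliding-window criteria: a 200 bp window
qualifies when GC > 50% and observed/expected CpG > 60%, with
$O/E = N_{CpG}\,L/(N_C N_G)$ and N bases excluded from all counts;
overlapping qualifying windows are merged and the merged region is reported
with *recomputed* whole-region statistics, which must themselves satisfy
the length (> 200 bp) and threshold criteria. The exact post-processing of
the popular web tools is not public, so the merged-region convention here
is stated explicitly and verified against a naive per-window brute-force
oracle on every test sequence.

```{r promoter}
pair <- simulate_promoter_pair(seed = 7)
find_variants(align_pair(pair$seq_a, pair$seq_b))
predict_cpg_islands(pair$seq_a)
```

## Numerical choices, in one place

* Optimiser tolerances `1e-10`, 500 iterations, 5 deterministic restarts
  (fixed internal jitter table, seed 24601) — identical inputs give
  identical fits.
* Branch tie tolerance `1e-9` cycles; both branch formulas coincide there.
* Calibration refuses fewer than 3 distinct standard fractions; slope
  magnitudes below `1e-10` are treated as non-informative.
* Estimates are clamped to $[0,1]$ with a flag, never silently.
* Zero-variance and single-sample tissues are flagged degenerate.
* All frequencies are fractions in machine-readable outputs; percentages
  appear only in human-readable reporting.
* Simulation problem sizes used in the validation suite: 13 × 3 standard
  plates plus triplicate unknowns; 20 seeded repetitions for recovery
  checks and 100 for the tissue-pattern rate — large enough for stable
  rates while keeping the whole suite quick to run.

## Known limitations

* No Ct/Cq calling, efficiency estimation from dilution series, melt-curve
  analysis, or alternative sigmoid families (5PL, Richards) — the
  four-parameter model with two-step truncation is the estimator of
  record here.
* No Fieller-type confidence intervals from calibration-error propagation;
  replicate sds are reported instead, matching the scale of information the
  assay provides.
* The exact plateau-truncation rule used by earlier two-step
  implementations is not published; the rule here is a documented,
  configurable stand-in with the same intent.
* Vendor instrument exports must be converted to the documented CSV; no
  proprietary parsers are included.
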