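---
title: "Absolute quantification of plaque metagenomes with spike-in calibration"
author: "cmuQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute quantification of plaque metagenomes with spike-in calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmuQuant)
library(SummarizedExperiment)
```

## The problem

Shotgun metagenomic profiling of dental plaque yields *relative*
abundances: each species' share of the reads. Relative data cannot tell a
treatment that suppresses the whole community from one that reshuffles
it, yet that distinction is exactly what an antimicrobial oral-care trial
needs to make. The remedy used here is to spike every specimen with known
masses of exogenous control DNA before extraction. The controls ride
through extraction, library preparation and sequencing alongside the
community, so their observed relative abundances give each sample its own
calibration line from DNA mass to read share. Inverting that line — and
dividing by each species' genome molecular weight — converts every
species' read share into an absolute cell-count estimate, a *calculated
microbial unit* (CMU).

## The model

For sample $s$ with controls $j = 1 \dots m$ of added mass $w_j$ (ng) and
observed relative abundance $r_{js}$, the package fits by ordinary least
squares

$$ r_{js} = \beta_{0s} + \beta_{1s} w_j + \varepsilon_{js}. $$

For a community species $i$ with relative abundance $r_{is}$, predicted
DNA mass and cell count are

$$ \hat w_{is} = \frac{r_{is} - \beta_{0s}}{\beta_{1s}}, \qquad
   \mathrm{CMU}_{is} = \frac{\hat w_{is} \times 10^{-9} \, N_A}
                            {L_i \, m_{bp}}, $$

with $L_i$ the genome length (bp), $m_{bp}$ the average base-pair
molecular weight, and $N_A$ Avogadro's number. On noise-free input this
chain is exact: the spike-in share is proportional to its mass in
base-pair equivalents, so the inversion returns precisely the DNA mass
each species contributed, and the genome-length division converts mass to
genome copies.

### Parameters that matter

* `w_bp` (default **650 g/mol per bp**): the standard average molecular
  weight of a double-stranded DNA base pair. It cancels out of
  noise-free round trips (it enters the simulated control shares and the
  inversion identically) but sets the absolute scale for real data.
* `intercept` (default **TRUE**): the intercept absorbs background
  signal mapping to the control channel at zero added mass. A
  through-origin fit is available; predicted masses below zero are
  clamped to 0 and counted.
* `direction` (default **relabund_on_mass**): the calibration regresses
  observed relative abundance on added mass, as the analysis methods
  describe; the inverse orientation is provided because the two
  least-squares problems differ on noisy controls. On exact data they
  coincide, which the tests verify.
* Curves with non-positive slope are flagged unusable rather than
  silently inverted, and controls observed at zero abundance stay in the
  fit as $(w_j, 0)$ points — dropping them would bias the slope upward.

## Clinical-category aggregation

Plaque species are annotated with a residency class (oral resident,
transient/extraoral, unknown) and any subset of four clinical categories
(commensal, gingivitis-associated, malodor-associated, acidogenic);
categories may overlap. The per-sample category aggregate is

$$ A_{cs} = \log_{10}\!\Big(1 + \sum_{i \in c} \mathrm{CMU}_{is}\Big), $$

i.e. summed biomass on the log scale. The sum-then-log order was chosen
because reported category levels (around $10^8$ cells for commensals
after mouthrinsing, $10^6$ for gingivitis or malodor organisms) read as
community totals, not per-species averages; the alternative, the mean of
per-species $\log_{10}(1 + \mathrm{CMU})$, is available via
`mode = "mean_log10"`. The $1 +$ floor maps empty categories to exactly
0, matching how absent species are reported as hard zeros on the log
scale. "Total oral bacteria" sums oral residents only; transient and
unclassified taxa are excluded.

Treatment effects are summarized as percent reductions,
$100\,(1 - 10^{\bar A_{\text{treat}} - \bar A_{\text{ctrl}}})$, which is
exactly the back-transform of a difference of log-scale means.

## Diversity and ordination

Alpha diversity is observed richness and Shannon–Weaver
$H = -\sum p_i \ln p_i$. Beta diversity is weighted UniFrac, computed by
a single post-order pass that accumulates, for every branch $b$ of
length $l_b$, the fraction $A_b$ of each sample's total abundance
descending through it:

$$ d_{\mathrm{raw}}(a, b) = \sum_b l_b \, |A_b - B_b|, \qquad
   d_{\mathrm{norm}} = \frac{d_{\mathrm{raw}}}
        {\sum_b l_b (A_b + B_b)}. $$

The normalized form (default) is scale-free in tree depth; since the
variant used upstream is not recorded, both are exposed. Multifurcating
trees — the common shape of taxonomy-derived phylogenies — are handled
directly, and missing branch lengths default to 1 with a warning.

Ordination is classical PCoA: Gower double-centering of $-\tfrac12 d^2$,
eigendecomposition, coordinates scaled by $\sqrt{\lambda_k}$. Negative
eigenvalues (non-Euclidean distances) are reported and their axes
dropped; proportions explained are taken over the positive spectrum.
Group separation is tested with one-factor PERMANOVA using Anderson's
pseudo-F on the distance matrix and the permutation p-value
$(1 + \#\{F^\pi \ge F\}) / (1 + n_\pi)$, which can never fall below
$1/(n_\pi + 1)$. The implementation is first-principles; the test suite
cross-checks it against `vegan::adonis2` (pseudo-F) and against a
brute-force branch enumerator and `phyloseq::UniFrac` for the distances.

## Group statistics and power

Healthy-versus-gingivitis style contrasts use Welch's unequal-variance
t-test; per-species and per-category treatment contrasts use the
Wilcoxon rank-sum test, exact by full enumeration when the two samples
total at most 12 observations without ties, otherwise the
tie-and-continuity-corrected normal approximation. P-values are reported
unadjusted by default, matching how per-species tables are conventionally
reported; Benjamini–Hochberg adjustment is one flag away.

The trial-sizing computation is the power of the two-sided two-sample
t-test from the noncentral t distribution:
$\mathrm{ncp} = \delta / (\sigma \sqrt{2/n})$, $df = 2n - 2$,
$\text{power} = P(|T_{\mathrm{ncp}}| > t_{1-\alpha/2, df})$. The quoted
"two-sided test at the 2.5% significance level" is read as total
two-sided $\alpha = 0.025$; that reading reproduces the published 95%
power for $n = 50$, $\delta = 0.34$, $\sigma = 0.43$ (the halved-alpha
reading does not). Note this includes both rejection tails, i.e.
`power.t.test(strict = TRUE)`.

```{r power}
tTestPower(50, 0.34, 0.43, alpha = 0.025)
tTestPower(50, 0.54, 0.38, alpha = 0.025)
```

## What the synthetic generator emulates — and what it does not

`simulateStudy()` generates study-shaped data so the full chain can be
validated against known truth:

* **Design**: arms × subjects × ordered visits, defaulting to the
  five-arm (B, BF, BA, BZ, BFZ), three-visit, 50-subjects-per-arm
  layout with 3.5 million reads per sample.
* **Community**: 574 candidate species split 236 oral / 228 transient /
  110 unknown (the "unknown" class absorbs the seat left over by
  rounding the published mix, whose printed classes sum to one less
  than the total). Presence is Bernoulli per taxon and sample, with
  per-residency Beta-distributed prevalence (means 0.51 / 0.04 / 0.24)
  chosen so an average sample carries ~155 species of which ~120 are
  oral residents, echoing the per-subject richness reported at
  baseline.
* **Abundance**: present taxa draw
  $10^{\mathcal N(\mu_i + \theta, \sigma_i)}$ cells, $\mu_i \sim
  U(3, 7.5)$, $\sigma_i \sim U(0.4, 1.0)$. The $\sigma$ range reflects
  the spread reported for near-ubiquitous species (~0.5–1.0 on the
  log10 scale); the much larger spreads printed for sporadic species
  arise from zero-inflation, which the prevalence model carries
  separately.
* **Effects** $\theta$: per arm × visit × category log10 shifts; a taxon
  in several affected categories takes the most negative applicable
  shift. Defaults are back-computed from the published percent
  reductions, e.g. a 93.6% gingivitis-category reduction becomes
  $\log_{10}(1 - 0.936) \approx -1.19$.
* **Sequencing**: expected read share $\propto$ cells × genome length
  (shotgun reads follow DNA mass, not cell count — which is what makes
  the genome-size correction in the CMU formula non-trivial and
  testable), controls contribute their added masses in base-pair
  equivalents, and reads are drawn multinomially at the target depth.
* **Reproducibility**: one master seed; per-sample sub-seeds derived by
  stable string hashing of (subject, visit), so results are independent
  of evaluation order.

Deliberately *not* modelled: species co-occurrence and ecological
interactions, within-subject longitudinal autocorrelation, read-level
artefacts (GC bias, extraction efficiency, mapping error), and
compositional effects of unmapped reads. Passing tests therefore
demonstrate that the estimators recover what the generative model puts
in — calibration inversion, genome-size correction, category effects,
type-I control — not that real plaque data satisfy those generative
assumptions.

## Worked example

```{r example}
fx <- buildClassificationFixture(
    40, c(oral = 0.6, transient_extraoral = 0.2, unknown = 0.2), seed = 7)
eff <- data.frame(arm = "BA", visit = "week4",
                  category = "gingivitis", effect = -1.0)
design <- studyDesign(fx$taxa, arms = c("B", "BA"), effects = eff,
                      n_subjects_per_arm = 20L,
                      visits = c("baseline", "week4"),
                      read_depth = 1e5, seed = 7)
sim <- simulateStudy(design)
cmu <- quantifySamples(relabund(sim), design@manifest)
agg <- aggregateCategory(cmu, fx$classification, "gingivitis")
md <- studyMetadata(sim)
sel <- md$visit == "week4"
percentReduction(mean(agg$value[sel & md$arm == "BA"]),
                 mean(agg$value[sel & md$arm == "B"]))
```

A $-1.0$ log10 category effect corresponds to a 90% reduction; the
recovered value differs from 90 only by sampling noise of the finite
arms.

## Numerical choices and edge cases

* Fitted slopes within $100\,\epsilon$ of zero are squashed to exactly
  zero so flat calibration lines are deterministically flagged unusable.
* Negative predicted masses clamp to zero and are counted per sample in
  the calibration report.
* Taxa lacking a genome length become `NA` CMU ("unquantified") and are
  listed, never dropped.
* An all-zero community column is an error ("empty community"), as is a
  spike-in control missing from a sample (named in the message).
* PCoA treats eigenvalues below $10^{-9}$ of the spectral radius as
  zero; PERMANOVA requires every group to have at least two members.
* Pipeline tables serialize floats at 12 significant digits, making
  repeat runs byte-identical and the run manifest's MD5 hashes
  meaningful.

## Problem sizes used in validation

The packaged tests and the acceptance script run reduced-scale studies —
up to 80 taxa, 50 subjects per arm, two visits, $10^5$ reads per sample —
which preserve every structural feature of the full design while keeping
the suite quick; the depth-sensitive CMU recovery check alone uses the
trial's $3.5 \times 10^6$ read depth, since its error bound depends on
depth. Type-I error rates are estimated from 1000 null replicates with
199 permutations each.

## Known limitations

CMU accuracy inherits every upstream bias the calibration cannot see:
differential extraction efficiency, GC-dependent library bias, and
misassigned reads all fold into the per-species estimates. The
calibration assumes the controls behave like community DNA from
extraction onward. Aggregates use a hard $\log_{10}(1 + x)$ floor, which
compresses genuinely tiny categories toward zero. PERMANOVA here is
single-factor; repeated-measures or baseline-adjusted designs need
per-visit contrasts, which is how the pipeline reports treatment
effects.
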