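---
title: "Quantifying lysine acetylation stoichiometry from paired light/heavy acetyl fragment ions"
author: "acstoich authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysine acetylation stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acstoich)
```

## The measurement model

Most acetyl-proteomics experiments report relative changes in acetyl-peptide
intensity, which confound changes in site occupancy with changes in protein
abundance. The stoichiometry approach implemented here removes that
confounding chemically. Proteins are denatured and every unmodified lysine
is chemically acetylated with D6-acetic anhydride (two labeling rounds,
driving labeling efficiency above 99%). After labeling, *every* lysine
carries an acetyl group: the endogenous one (light, CH~3~CO) or the chemical
one (heavy, CD~3~CO). The two differ by three deuterium atoms,

$$\Delta m = 3\,(m_{^2\mathrm{H}} - m_{^1\mathrm{H}}) = 3.018830\ \mathrm{Da},$$

so each fragment ion that covers an acetyl-lysine appears as a resolvable
light/heavy pair. The stoichiometry of acetylation at a site is then simply

$$s = \frac{L}{L + H},$$

the light fraction of the total signal, where $L$ and $H$ are the light and
heavy fragment-ion peak areas. Because both channels come from the same
peptide molecules, $s$ is self-normalizing: protein abundance cancels, and
no protein-level normalization is applied anywhere in the package.

Because lysine acetylation (endogenous or chemical) blocks tryptic cleavage,
digestion is performed with Trypsin plus GluC: cleavage C-terminal to R and
to E (optionally D), suppressed before proline, with up to five missed
cleavages in the reference configuration. `digest()` implements exactly
these rules; `build_pair_table()` enumerates, for every digest peptide, the
b/y fragment ions covering at least one lysine in both the all-light and the
all-heavy acetyl state, mirroring how a spectral library is augmented with
in-silico heavy counterparts.

## Envelope correction

The heavy label adds a *nominal* +3 Da per site. The +3 natural isotopologue
of the light species (mostly ^13^C~3~, plus ^2^H/^15^N/^18^O combinations at
the same nominal offset) therefore lands on the heavy monoisotopic peak. At
the resolution of a typical DIA quantification this coincidence is not
resolved — the ^2^H~3~ vs ^13^C~3~ fine-structure split is a few mDa — so
the observed heavy area contains a light leakage term:

$$H_{\mathrm{obs}} = H + L\, r, \qquad r = \frac{a_{3k}}{a_0},$$

where $a_i$ is the light fragment's natural isotope envelope (computed by
`isotope_envelope()` as a repeated convolution of per-element isotope
distributions, aggregated by nominal mass offset) and $k$ is the number of
acetyl-lysines the fragment covers. `correct_heavy()` subtracts the leakage,
$H_{\mathrm{corr}} = \max(0,\ H_{\mathrm{obs}} - L r)$, clamping at zero
because a negative area is physically meaningless; clamped measurements are
flagged and counted in the QC output. For peptide-sized fragments $r$ is of
the order of 0.2–3%, so the correction mainly matters for sites with high
endogenous occupancy — exactly the sites where a biased denominator would be
most misleading. Skipping the correction biases $\hat{s}$ *downward* for all
$s < 1$, which the test suite demonstrates by re-running the benchmark study
with `correction = FALSE`.

Numerical choices: the envelope is indexed by integer nominal offset (fine
structure is irrelevant at the +3k coincidence this correction targets);
deuterium at labeled positions is treated as isotopically pure; envelopes
are computed to `max_iso = max(10, 3k + 2)` offsets and reported as absolute
probabilities of the untruncated distribution (no renormalization), so the
tiny truncated tail never inflates $r$. We compute the full fixed-length
envelope rather than stopping early at cumulative $1 - 10^{-9}$ mass: at
these sizes the envelope is cheap and a fixed length keeps the ratio lookup
trivial.

## From fragments to sites

Only *site-informative* fragments — those covering exactly one lysine — are
used for quantification; a fragment spanning two acetyl-lysines cannot
attribute its signal to either. Fragment stoichiometries are aggregated per
site, group and replicate by the median across fragments, peptidoforms and
charge states (the mean is available via `aggregate = "mean"`), and a
site/replicate value is only reported when at least `min_fragments = 3`
measurements support it, so that a single interfered fragment cannot
dominate. Unlabeled lysines that escaped the chemistry are indistinguishable
light signal; with labeling efficiency $\eta$ the estimator converges to
$s\eta + (1-\eta)$, a positive bias bounded by $1 - \eta \le 0.005$ at the
>99% efficiency the labeling QC (`qc_labeling()`) enforces.

## Group comparison

For each site, a one-way fixed-effects ANOVA (`stoichiometry ~ group`, no
covariates) is run per peptidoform on the replicate-level values, and the
per-peptidoform p-values are combined across peptidoforms with Fisher's
method, $X = -2\sum \ln p_i \sim \chi^2_{2k}$. The split is deliberate:
fragments within a peptidoform sample the same precursor and are pooled
before testing, while distinct peptidoforms (different digest spans covering
the same site) are treated as approximately independent. Charge states of
one peptidoform are pooled with its fragments, not treated as peptidoforms.
Sites lacking `min_replicates = 3` replicates in every compared group are
excluded from testing and reported in a presence/absence table (with n = 5
animals per group in the reference design this leaves headroom for
missingness). Significance is called at unadjusted Fisher p < 0.05 to mirror
the display convention of the original analysis; BH-adjusted q-values are
always written alongside, and distribution-level shifts between models can
be tested with `ks_two_sample()`.

Two models are compared against the same reference with `compare_models()`,
which reports shared and model-unique significant sites and proteins, the
shared fraction (shared count divided by the mean per-model significant
count), and volcano tables ($\Delta s$ vs $-\log_{10} p$). A direct
model-vs-model test is the same `test_sites()` call with those two groups.

## Over-representation

`enrich()` performs standard ORA: upper-tail hypergeometric p per category,
BH across all tested categories, fold enrichment $(k/n)/(m/N)$. The
background universe is the set of proteins with at least one quantified site
— conditioning on detectability — not the whole proteome. Categories with
fewer than two members in the universe are dropped before testing. The
display filters reproduce the reference presentation: keep categories with
fold enrichment above 5 and BH FDR below 0.05, sorted by descending fold
(ties broken by ascending q, then category id), truncated to the top 10.
"Enrichment score" is read as fold enrichment throughout.

## What the synthetic generator emulates

`make_study()` generates ground-truthed inputs with the statistical
structure the analysis assumes, standing in for deposited raw data that
cannot be reprocessed at desk scale:

* **Design**: three groups (wild type plus two transporter-overexpression
  models) × 5 replicates; 200 quantifiable sites in the default benchmark.
* **Baseline truth**: wild-type stoichiometries uniform on [0.05, 0.95] —
  chosen to exercise the estimator across its full range rather than to
  mimic the strongly low-occupancy skew of a real liver acetylome.
* **Effects**: 35% of sites carry a true effect in each model;
  30% of each model's affected sites are shared between the models (with a
  common delta, a shared biological response), echoing the ~30% overlap
  observed between the two transporter models; $|\Delta s| \sim
  U(0.05, 0.30)$ with random sign, truncated to [0.01, 0.99].
* **Chemistry**: labeling efficiency $\eta = 0.995$; the unlabeled fraction
  is added to the light channel — the conservative worst case for bias,
  since in reality an unmodified-K peptide co-elutes with neither channel.
* **Signal**: per fragment/replicate latent total $T \sim$ log-normal
  (median 10^5^, sdlog 0.5); expected light $T(s\eta + 1 - \eta)$; expected
  heavy $T(1-s)\eta$ plus envelope leakage `expected light` × $r$ with $r$
  taken from the same pair table the quantifier uses; independent
  multiplicative log-normal noise of CV 0.10 on each channel; 5% of fragment
  rows missing completely at random (group-dependent missingness is
  available for robustness experiments).
* **Digestion for simulation** uses `max_missed = 2`: higher settings
  mostly add long multi-lysine peptides that the localization rule discards
  anyway, while two missed cleavages already give most sites several
  peptidoforms for Fisher combination.
* **Annotations**: 15 random categories plus one planted category drawing
  half its members from proteins harboring shared-effect sites. A separate,
  larger ORA benchmark (`simulate_enrichment()`: universe 1000, category 40,
  list ~100, planted fold 5) is used to measure detection rates, because a
  200-site study is too small to host a 5-fold enriched category.

What the generator does **not** model — and hence what passing benchmarks do
not demonstrate about real data: chromatographic interference and
co-elution, retention-time alignment errors, correlated biological
(animal-level) variation across peptidoforms of the same site,
intensity-dependent missingness, and protease miscleavage biases. In
particular, because peptidoform-level noise is independent by construction,
the Fisher combination is exactly calibrated here; on real data, correlated
animal effects would make it anti-conservative, which is one reason the
per-site significance is also reported with BH adjustment.

## Benchmark sizes and reproducibility

The shipped benchmarks use: a 50-site noise-free study (exact recovery to
1e-9 through the full pipeline), the 200-site default study (median absolute
site error, observed ≈ 0.003–0.005, against the < 0.02 bound; correction-off
regression; overlap recovery within the 95% binomial band of 0.30), a
1000-site global-null study for type-I calibration (fraction of Fisher p <
0.05 within [0.03, 0.07]), and 100 seeded ORA simulations (planted-category
detection ≥ 95%). `scripts/acceptance.R --seed N --out results.json`
regenerates every one of these quantities from scratch; all randomness flows
from the single seed, and identical configurations are byte-reproducible.

## Known limitations

* Single-ratio correction: only the $a_{3k}/a_0$ leakage into the heavy
  monoisotopic peak is corrected, following the design of the original
  in-house analysis; integrating several heavy isotopologues would require
  a per-isotopologue quantification table that DIA reports do not provide.
* No mixed-effects or empirical-Bayes moderation; each site is tested
  independently.
* GluC specificity defaults to E-only (buffer-dependent); switchable to E+D.
* Fragment charge states default to {1, 2}; the original fragment-series
  and charge retention rules are not published, so these defaults are
  package decisions, as are the 6–30 residue peptide length bounds.
* The site-level aggregation rule (median over site-informative fragments,
  `min_fragments = 3`) is likewise a package decision; the reference
  analysis reports site-level values without stating its aggregation.
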