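# acstoich

Site-level **lysine acetylation stoichiometry** from paired light/heavy
acetyl fragment ions.

## The problem

Relative acetyl-peptide quantification confounds changes in site occupancy
with changes in protein abundance. The stoichiometry approach removes the
confounding chemically: after denaturation, every unmodified lysine is
chemically acetylated with D6-acetic anhydride (two rounds, >99% labeling
efficiency), so every lysine ends up carrying either the endogenous acetyl
group (light, CH3CO) or the chemical one (heavy, CD3CO), 3.018830 Da apart.
For every fragment ion covering an acetyl-lysine the stoichiometry of
acetylation is

```
s = L / (L + H)
```

— the endogenous (light) fraction of the total signal. Because the heavy
label is a *nominal* +3 Da per site, the +3k natural isotopologue of the
light species overlaps the heavy monoisotopic peak; the package corrects
the heavy channel with the ratio `r = a_3k / a_0` of the light fragment's
isotope envelope:

```
H_corr = max(0, H_obs - L * r)
```

This package is the full desk-side pipeline around that estimator, written
for proteomics researchers who have fragment-level DIA quantification
tables (light/heavy peak areas) and want per-site stoichiometries and group
statistics:

* **Chemistry** — elemental compositions, monoisotopic masses, isotope
  envelopes by per-element convolution, in-silico Trypsin+GluC digestion
  with acetyl-blocked lysines (no cleavage of K, none before P, up to 5
  missed cleavages), b/y fragment m/z, and in-silico light/heavy fragment
  pair tables with envelope-correction ratios.
* **Quantification** — envelope correction, fragment stoichiometries,
  site-level aggregation (median over site-informative fragments,
  `min_fragments = 3`), labeling-efficiency QC.
* **Statistics** — per-peptidoform one-way ANOVA combined per site by
  Fisher's method; BH FDR; two-sample KS; model-vs-model overlap summaries
  and volcano tables.
* **Enrichment** — hypergeometric over-representation with fold-enrichment
  and FDR display filters.
* **Synthetic data** — a ground-truthed generator (3 groups × 5 replicates,
  planted effect and overlap structure, labeling inefficiency, envelope
  leakage, log-normal noise, missingness) standing in for deposited raw
  data.

## Worked example

Simulate the default benchmark study, quantify it, and compare both
overexpression models against wild type:

```r
library(acstoich)

study <- make_study(study_config(n_sites = 200, seed = 1))
study
#> <acetyl_study> seed 1: 150 proteins, 200 sites, groups WT/sTgA/sTgB x 5 replicates
#>   quant rows 171469; cv 0.10, eta 0.995, missing 0.05

sq <- quantify_sites(study$quant, study$pairs)
sq
#> <site_quant> 171469 fragment measurements, 12475 peptidoform rows, 3000 site rows
#>   clamp rate 0.0028; 0 zero-total dropped; 0 multi-K fragments discarded

resA <- test_sites(sq$peptidoforms, groups = c("WT", "sTgA"), ref = "WT")
resB <- test_sites(sq$peptidoforms, groups = c("WT", "sTgB"), ref = "WT")
head(as.data.frame(resA)[, c("site_key", "mean_WT", "mean_sTgA", "delta",
                             "p_site", "q_bh", "significant")], 4)
#>      site_key   mean_WT mean_sTgA        delta       p_site         q_bh significant
#> 1 SYN0001:111 0.5384585 0.7844630  0.246004510 7.144086e-41 1.020584e-39        TRUE
#> 2   SYN0002:3 0.3468907 0.3509218  0.004031106 5.776580e-02 1.426316e-01       FALSE
#> 3  SYN0002:20 0.6554447 0.6570429  0.001598219 5.921020e-01 8.223639e-01       FALSE
#> 4  SYN0003:51 0.2367710 0.2355400 -0.001231070 3.618516e-01 5.931994e-01       FALSE

compare_models(resA, resB)
#> <model_overlap> alpha = 0.05
#>   sites:    A-only 52 | shared 26 | B-only 53  (totals 78 / 79)
#>   proteins: A-only 30 | shared 33 | B-only 23  (totals 63 / 56)
#>   shared fraction of significant sites: 0.331
```

Reading the output: 3000 site rows are 200 sites × 3 groups × 5 replicates;
`delta` is the model-minus-WT mean stoichiometry; `p_site` is the
Fisher-combined p over the site's peptidoform-level ANOVAs
(`SYN0001:111` carries a planted +0.25 occupancy shift and is called at
p ≈ 7e-41); the overlap summary recovers the planted structure — the
generator plants a true effect in 70 sites per model of which 21 are shared,
and the recovered shared fraction of significant sites (0.331) sits on the
planted 30% within sampling error.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/acstoich.R simulate --outdir sim --seed 1
Rscript inst/cli/acstoich.R test --fasta sim/proteome.fasta --quant sim/quant_table.tsv --outdir out
Rscript inst/cli/acstoich.R enrich --comparisons out/comparison_sTgA_vs_WT.tsv,out/comparison_sTgB_vs_WT.tsv \
    --annotations sim/annotations.tsv --outdir out
Rscript inst/cli/acstoich.R report --outdir out
```

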