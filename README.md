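# hgscreen

Screening and quantification of mercury-cycling genes (*hgcA*, *hgcB*,
*merA*, *merB*) in marine metagenomic protein catalogs.

Marine methylmercury budgets are controlled by a handful of microbial gene
systems: *hgcAB* (Hg(II) methylation), *merB* (organomercury lyase,
demethylation) and *merA* (mercuric reductase). Surveys of these genes in
ocean metagenomes share one analysis skeleton, which this package
implements as a tested, reusable pipeline:

1. **Detection** — per-family profile hidden Markov models (Viterbi /
   forward log-odds scoring) with empirically calibrated E-values and
   family-specific thresholds (1e-5 for *hgcA*/*hgcB*/*merB*, 1e-10 for
   *merA*).
2. **Curation** — conserved catalytic and metal-binding residues checked
   in the coordinates of a named anchor reference (e.g. MerA Cys-207/212,
   Tyr-264, Tyr/Phe-605, vicinal Cys-628/629; HgcA Cys-93; MerB Cys-96,
   Asp-99, Cys-117, Cys-159; two `CX2CX2CX3C` clusters for HgcB). A gap at
   a rule position fails, so fragments cannot pass.
3. **Quantification** — validated counts per sample as a percentage of the
   single-copy marker *rpoB*: `relative_pct = 100 · validated / rpoB`.
4. **Dereplication & lineages** — greedy CD-HIT-style clustering at 90%
   identity (identity = identical columns / shorter sequence length) and
   best-labeled-reference lineage assignment with an ambiguity margin.
5. **Hydrographic statistics** — Spearman rank correlations (asymptotic t
   p-values, exact permutation p for small n) between gene abundances,
   mercury species (dTHg, dMeHg) and environmental depth profiles.

Because real reference sets and metagenomes are external data, the package
also ships first-class, seeded synthetic-data generators — reference
families with planted rule residues, per-sample catalogs of valid /
rule-ablated / decoy proteins with abundances rising into the mesopelagic,
and environment tables with monotone depth structure — so the entire
pipeline is verified end to end against known ground truth.

See `vignettes/hgscreen-methods.Rmd` for the model, the numerical choices
and what the synthetic benchmark does and does not establish.

## Worked example

```r
library(hgscreen)

out <- file.path(tempdir(), "readme_run")
cfg <- default_config(out, seed = 1L)
cfg$simulate <- list(decoys_per_sample = 50, rpob_per_sample = 200)
run_pipeline(cfg)   # simulate -> profiles -> search -> validate ->
                    # dereplicate -> quantify -> correlate (+ manifest)

ab <- read_tsv(file.path(out, "abundance.tsv"))
head(subset(ab, family == "hgcA"), 8)
#>  sample_id station depth_m family validated_count rpob_count relative_pct
#>  St1_0200m     St1     200   hgcA               5        200          2.5
#>  St1_0500m     St1     500   hgcA               8        200          4.0
#>  St1_1000m     St1    1000   hgcA              16        200          8.0
#>  St1_1500m     St1    1500   hgcA              20        200         10.0
#>  St6_0200m     St6     200   hgcA               5        200          2.5
#>  St6_0500m     St6     500   hgcA               8        200          4.0
#>  St6_0967m     St6     967   hgcA              16        200          8.0
#>  St6_1500m     St6    1500   hgcA              20        200         10.0
```

Every planted *hgcA* copy was detected, survived residue curation and was
normalized to the 200 *rpoB* records per sample — the relative abundance
rises into the mesopelagic exactly as planted (rule-ablated and decoy
records were excluded: the validation report in `validation.tsv` names the
failing rule for each).

```r
head(read_tsv(file.path(out, "lineage_proportions.tsv")), 5)
#>  family             lineage n_records pct_of_family
#>    hgcA          Nitrospina        29      51.78571
#>    hgcA Deltaproteobacteria        17      30.35714
#>    hgcA Alphaproteobacteria        10      17.85714
#>    hgcB          Nitrospina        13      76.47059
#>    hgcB Deltaproteobacteria         4      23.52941

cors <- read_tsv(file.path(out, "correlations.tsv"))
subset(cors, variable_x == "dMeHg_pM" &
             variable_y %in% c("AOU_umol_kg", "dTHg_pM"))
#>  variable_x  variable_y       rho      p_value  n     method
#>    dMeHg_pM     dTHg_pM 0.2237762 4.844517e-01 12 asymptotic
#>    dMeHg_pM AOU_umol_kg 0.9160839 2.842805e-05 12 asymptotic
```

The statistics reproduce the structure such surveys report: dissolved
methylmercury correlates strongly with apparent oxygen utilization
(rho = 0.92, p < 0.001, n = 12 — MeHg production tracks cumulative
microbial respiration) while total mercury shows no depth relation.

A subcommand CLI wraps the same stages
(`inst/cli/hgscreen.R simulate|build-profiles|search|validate|dereplicate|quantify|correlate|run-all`,
exit codes 0/2/3).

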