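# crbdia

Sensory-guided nontargeted metabolite discovery for LC-HRMS
data-independent acquisition (DIA), built around **chromatographic
retention behavior (CRB) deconvolution**: because a fragment's retention
must track its precursor's across LC gradients, re-acquiring a pooled QC
sample under a systematic series of **nine gradients** lets fragments be
assigned to precursors even when precursors co-elute under any single
gradient — the case peak-shape matching cannot solve.

The package is aimed at metabolomics method developers and flavor/food
chemists who want to link compositional differences to sensory panel
outcomes. It covers the whole workflow as tidyverse-style functions
(tibbles in, tibbles out):

* **Synthetic study generator** — ground-truthed multi-gradient DIA runs
  (linear-solvent-strength retention physics, 12 variable SWATH windows,
  70–1200 Da, 750 ms duty cycle), spectral libraries with isomer decoys,
  standards tables, and linked sensory-panel scores for 57 samples in four
  groups (24 T, 5 N1, 24 N2, 4 N3).
* **Deconvolution** — untargeted MS1 peak detection, cross-gradient
  feature linking by elution rank, CRB fragment assignment, targeted
  re-quantification of QC features in single-gradient sample runs.
* **Sensory grouping** — IQR outlier screening (Tukey hinges), radar
  profiles, PCA + seeded k-means subgrouping.
* **Differential analysis** — abundant ion features by fold change > 2 and
  Welch-t p < 0.05, accumulated ion chromatograms, volcano plots,
  feature-list overlap matching.
* **Annotation** — spectral dot product (cosine with greedy peak pairing),
  level 2 at mass error < 10 ppm and dot product > 0.4, level 1 by
  standard retention agreement within 0.1 min, isomer flags beyond
  0.5 min.
* **Quantification** — single-point standard addition
  `C_s = C_std · A_sample / (A_spiked − A_sample)` and validation-formula
  composition (all / majors / minors).

mzML I/O goes through Bioconductor's `mzR`; spectra are exchanged as MSP.

## Worked example

```r
library(crbdia)

cfg <- pipeline_config(seed = 7, n_compounds = 60,
                       modes = "positive", columns = "RPLC",
                       n_t = 6, n_n1 = 4, n_n2 = 6, n_n3 = 3,
                       isomer_decoys = 3)
report <- run_pipeline(cfg, out_dir = "crbdia_out")
report
#> <crbdia_report>
#> features per dataset:
#> positive_RPLC
#>            22
#> differential (selected) per contrast:
#> N1_vs_N2T N2T_vs_N3
#>         6         1
#> annotated: 6, level 1: 2, validated compounds: 2
#> fragment precision/recall: 1.000 / 0.986, grouping ARI: 1.00
```

Reading the output: all 22 positive-mode compounds detectable in the QC
runs were recovered as ion features; 6 features were significantly more
abundant in the N1 sensory group than in the merged N2&T group (1 for
N2&T over N3); 6 of the selected features received a level-2 library
annotation, 2 were confirmed at level 1 against standards and quantified.
The scorecard line compares everything against the generator's planted
truth: 100% of assigned fragments were correct, 98.6% of expected
fragments were assigned, and the PCA/k-means grouping reproduced the
planted subgroups exactly (adjusted Rand index 1.0).

Stage products (feature lists, deconvolved spectra as MSP, feature tables,
differential results, annotations, concentrations, formulas, a JSON
summary) are written under `out_dir`. A thin command-line wrapper is at
`inst/scripts/run_pipeline.R`:

```sh
Rscript inst/scripts/run_pipeline.R --config config.yaml --out out_dir
```

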