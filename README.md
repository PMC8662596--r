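# mttrnaseq

Analysis of mitochondrial tRNA import from dual-compartment tRNA
sequencing in plants.

Plant mitochondrial genomes encode only part of the tRNA set needed for
organellar translation; the rest is imported from the cytosol. Sequencing
tRNA pools from purified mitochondria alongside paired total-cellular
samples exposes the import pattern: for each reference sequence *r* the
pipeline estimates the mitochondrial enrichment

```
log2FC(r) = log2( (mean CPM_mito(r) + c) / (mean CPM_total(r) + c) ),  c = 0.5 CPM
```

on TMM-normalized counts per million, and summarizes each anticodon
(isodecoder) family by weighting members by their expression share:

```
w_i = CPM_i / sum_family(CPM),   weighted_log2FC = sum_i w_i * log2FC_i
```

A family is predicted **excluded** from mitochondria when an intact
mitochondrial gene decoding the same codons is present (with the lysidine
rule mapping mt-Ile(CAU) to cytosolic Ile(UAU)), **imported** otherwise;
Welch's t-test quantifies the separation of the two predicted classes.

The package covers, end to end:

* collapsed mature-tRNA reference construction from genome annotations
  (GFF3/GenBank) and tRNA metadata tables;
* read-family building (50-95 nt length filter, identical-read collapse,
  count filters);
* exact Smith-Waterman mapping (match +1 / mismatch -1 / gap -2, score
  floor 30) with the 90% identity / 80% coverage retention rule and
  unique-assignment semantics;
* a survey of CCA-tailed reads mapping to non-tRNA mitogenome loci
  (t-elements and orphan stem-loops), discriminating post-transcriptional
  from genome-encoded CCA and reporting per-library percentages;
* TMM + CPM quantification, expression filters, compartment depletion
  summaries, anticodon family statistics, import prediction and testing,
  and cross-species gene-loss shift tables;
* a seeded synthetic-data generator (`simulate_experiment()`) producing
  complete two-compartment experiments with known ground truth.

See `vignettes/mito-trna-import.Rmd` for the model, assumptions and
numerical choices.

## Worked example

```r
library(mttrnaseq)

cfg <- simulation_config(reads_per_library = 20000)   # 3 mito + 3 total libraries
sim <- simulate_experiment(cfg, seed = 42)
res <- run_pipeline(sim$reads, cfg$libraries, sim$refs)
ia  <- run_import_analysis(res, sim$inventory)

res$depletion
#>   mean_mt_log2fc mean_nuclear_log2fc mean_plastid_log2fc nuclear_depletion plastid_depletion
#> 1           4.75                -1.5              -0.361             -6.25             -5.11

ia$separation$test
#> Welch's t-test: t = 7.317, df = 16.54, p = 1.417e-06 (n = 14 vs 6)

truth_report(sim, res)[c("bias", "rmse", "assignment_rate")]
#> $bias            [1] 0.03784...
#> $rmse            [1] 0.2646...
#> $assignment_rate [1] 0.99996...
```

Reading: mt-tRNAs are ~4.8 log2 units enriched in the mitochondrial
isolate; nuclear and plastid tRNAs are depleted ~6.3 and ~5.1 log2 units
relative to them (negative = depleted, the sign convention of compartment
depletion tables). The 14 families predicted imported are significantly
more enriched than the 6 predicted excluded (Welch p ~ 1e-06), and the
estimated family enrichments recover the simulated truth with bias < 0.05
and RMSE ~ 0.26 log2 units at this depth. The most depleted families
(e.g. Ala(AGC) at -6.6) are those sharing an anticodon with a retained
mt-tRNA gene.

A command-line front end for the same steps is in
`inst/scripts/mttrnaseq-cli.R` (`simulate`, `map`, `quantify` subcommands).

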