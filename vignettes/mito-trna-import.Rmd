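---
title: "Quantifying mitochondrial tRNA import from dual-compartment tRNA-seq"
author: "mttrnaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial tRNA import from dual-compartment tRNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant mitochondrial genomes encode only a subset of the tRNAs needed to
translate their own mRNAs; the missing isoacceptors are imported from the
cytosol. Sequencing tRNA pools from purified mitochondria alongside paired
total-cellular samples makes the import pattern measurable: a
nuclear-encoded tRNA that is imported remains relatively abundant in the
mitochondrial isolate, while one that is excluded is strongly depleted.
`mttrnaseq` implements the full desk-side analysis for such experiments:
reference construction, read-family mapping, surveying of CCA-tailed
non-tRNA transcripts (t-elements and orphan stem-loops), enrichment
quantification, anticodon-family statistics, and import prediction/testing,
plus a seeded synthetic-data generator that provides ground truth for every
stage.

## Pipeline model and assumptions

**Reads.** Input reads are merged, adapter-trimmed consensus sequences from
a CCA-directed ligation protocol (the library chemistry selects mature,
deacylated tRNAs via their 3' CCA). Reads are therefore transcript-oriented.
A 50-95 nt length window keeps full-length tRNA inserts; identical reads are
collapsed into *read families* with per-library counts, and family
identifiers are content hashes so reruns are comparable.

**References.** Mature tRNA gene sequences (introns excised) are collapsed
so that each distinct sequence is one mapping reference. Collapsing never
crosses genomic origins: a nuclear gene identical to a mitochondrial copy
yields two references and a warning, because such reads are inherently
ambiguous about compartment and are excluded rather than guessed
(`status = "ambiguous"`, flagged `cross_origin`).

**Mapping.** Hit search and filtering in this kind of protocol is traditionally done
with BLASTN; this package instead uses an exact Smith-Waterman local aligner
(match +1, mismatch -1, gap -2, score floor 30) behind an 8-mer candidate
prefilter. For reads of at least 60 nt a candidate must share two 8-mer
occurrences with the read; a counting argument shows any hit at >= 90%
identity and >= 80% coverage contributes at least `0.9c - 7(0.1c + 1)`
shared 8-mers over `c >= 48` aligned columns, so the prefilter cannot lose a
passing hit. Identity uses the BLAST convention (identical columns over all
alignment columns, gaps included); coverage is the aligned span over the
read length. A family is assigned only when exactly one reference passes
both thresholds - ties are discarded, not broken by best hit.

**Enrichment.** Counts are normalized with trimmed-mean-of-M scale factors
(reference column by 75th-percentile CPM closest to the mean; 30%/5% tail
trims; precision-weighted mean), converted to CPM, and filtered at 2 CPM in
at least as many libraries as the smaller fraction group. Per-reference
enrichment is the pseudocount ratio of means,
`log2((mean mito CPM + 0.5) / (mean total CPM + 0.5))`, replacing a
negative-binomial GLM: the downstream statistics consume only point
estimates, and the simplification is validated by simulation recovery (see
below). Family-level enrichment weights each member by its share of the
family's CPM (mean over all libraries by default; total-cellular-only
weights are selectable because either convention is defensible).

**Import prediction.** An anticodon family is predicted *excluded* when an
intact mitochondrial gene decoding the same codons exists, *imported*
otherwise. The CAU anticodons are matched through a hard-coded decoding
table: mt-Ile(CAU) carries a lysidine-modified wobble and decodes AUA, so it
matches cytosolic Ile(UAU); elongator Met(CAU) and initiator Met/fMet(CAU)
match their own classes, which are kept distinct throughout. The class
separation is tested with Welch's t-test on the weighted family enrichments;
cross-species gene-loss shifts use a strict "every loser species above every
outgroup" quantifier.

**CCA survey.** Families with more than two reads across all libraries are
mapped to the mitogenome (90% identity and coverage). A read ending in CCA
whose aligned genomic context does not read CCA carries a
post-transcriptionally added tail. Overlapping hits merge into loci (single
linkage, same strand); loci intersecting a tRNA gene are set aside, loci
within 150 bp of an annotated feature are called t-elements (processing
signals cleaved by RNase P/Z), and the rest are orphan stem-loops. The 150
bp window is a package choice: observed t-elements sit tens of bp from gene
boundaries while orphan loci are kilobases away, so any threshold in the
hundreds separates them; it is configurable. Percentages are per read (a
read matching repeated loci counts once, at its best-scoring locus), and the
denominator is all CCA-tailed mito-mapping reads - the table layout leaves
the denominator ambiguous, and this choice is documented rather than
inferred.

**Folding.** Thermodynamic folding is deliberately replaced by base-pair
maximization (Watson-Crick + GU, minimum hairpin loop 3) with a shape test:
the cloverleaf flag requires three hairpin stems of >= 3 bp inside a closing
stem of >= 4 bp. The flag is descriptive metadata, never a filter, matching
how folding is typically used in these surveys: descriptively, not as a gate.

## The synthetic world

`simulation_config()` states one world and the tests never tune it after
seeing results:

* 6 mt-tRNA genes at +6 log2 enrichment in the mitochondrial isolate
  (within the observed 37- to 146-fold range for plant mitochondrial
  isolations), 20 nuclear anticodon families of 3 members each with import
  effects `rep(seq(-5, 4), length.out = 20)`, 4 plastid references at a 2%
  contamination fraction, and non-tRNA stem-loop loci receiving 0.3% of the
  CCA-tailed mitochondrial read pool.
* 3 mitochondrial-isolate plus 3 total-cellular replicates of 2e5 reads,
  a typical dual-compartment design; tests scale the depth or seed
  count down where runtime demands it and say so in place.
* uniform per-base misincorporation at 0.02, emulating reverse-transcription
  errors on AlkB-treated tRNA; indels are off by default.
* total-cellular composition: 85% nuclear, 5% mitochondrial, 8% plastid
  (mitochondrial transcripts are a minor but real part of whole-tissue RNA).
* family members differ at 16 interleaved positions so that reads assign
  uniquely; real isodecoders can be more similar, in which case the strict
  unique-assignment rule discards more reads than in this simulation.

**Truth is recorded on the post-normalization scale.** Because every
library's composition sums to one, enrichments are identifiable only up to
the normalization anchor; the configured effects shift by a constant
(~1.2 log2 units in the default world) once the trimmed-mean normalization
centers the matrix. The generator therefore computes the true normalized
log2 fold change by applying the same trimmed-mean algorithm to the exact
expected counts and stores it as `true_log2fc` alongside the configured
value (`configured_log2fc`). Recovery metrics measure estimation error
(sampling, mapping, pseudocount), not a centering convention.

**What a green test does not establish.** The generator draws tRNA bodies
uniformly at random, so it underrepresents the shared structural core of
real tRNAs and the resulting near-ambiguities; errors are uniform rather
than concentrated at modified sites; plastid and contaminant sequences are
unrelated to the plant references rather than homologous. Green recovery
tests establish the correctness of the pipeline's logic and estimators
under the stated noise model, not performance on maximally adversarial
reference sets.

**A known bias in the CCA percentage.** The ">2 reads in all libraries
combined" family filter interacts with sequencing depth: abundant tRNA
references keep their 1-error read variants (each variant recurs often
enough to pass), while rare stem-loop loci lose theirs. At desk-scale depth
and 2% misincorporation this depresses the reported non-tRNA CCA percentage
two- to three-fold below the simulated fraction; at production sequencing depth
the distortion is smaller but not zero, and it affects the real statistic
the same way. The percentage-recovery acceptance test therefore runs the
noiseless limit, which isolates the survey logic from this retention bias;
a separate property test verifies at 2% error that species with more
stem-loop transcription still rank higher.

## Numerical choices

* Alignment tie-breaks are fully deterministic (diagonal > gap-in-reference
  > gap-in-query; best cell by score, then query, then reference index), so
  count matrices are byte-identical across runs and match the pure-R test
  oracle exactly.
* TMM factors fall back to 1 when no rows survive trimming or the weighted
  mean is numerically zero; a library with all-zero counts is an error
  naming the library.
* The enrichment pseudocount is 0.5 CPM (configurable); weighted family
  enrichment is convex in member values by construction.
* Welch's test refuses groups smaller than two and the degenerate
  equal-means/zero-variance case; the separation test returns an NA status
  when a predicted class has fewer than two families (the realistic case for
  species with very few remaining mt-tRNA genes).
* `fold_heuristic()` accepts sequences up to 120 nt (cubic-time dynamic
  program); traceback prefers leaving a base unpaired when co-optimal,
  otherwise the largest admissible partner, which reproduces stacked stems.

## Limitations

* No e-value model: hit significance is controlled by the score floor and
  the identity/coverage thresholds alone.
* The contaminant screen is reference-based; it cannot discover contaminants
  absent from the supplied contaminant set (the original taxonomy-database
  lookup is out of scope).
* Per-reference dispersion estimation and per-gene significance testing are
  out of scope; the package reports point enrichments and one group-level
  test per species.
* GenBank parsing covers the feature keys this pipeline consumes (tRNA,
  rRNA, CDS, pseudo genes) with envelope coordinates for joined locations.
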