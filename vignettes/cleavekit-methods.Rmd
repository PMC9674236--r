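---
title: "Inferring protease substrate specificity from knockout peptidomics"
author: "cleavekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring protease substrate specificity from knockout peptidomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavekit)
```

## The problem

Enteroendocrine cells excise bioactive peptide hormones from prohormone
precursors through a cascade of proteases: calcium-regulated proprotein
convertases (PCSK1/PCSK2) cleave C-terminally to dibasic K/R pairs;
carboxypeptidases (CPE, CPB1) then remove the exposed C-terminal basic
residues; a C-terminal glycine can be converted into an amide; and the
aminopeptidase DPP4 removes N-terminal dipeptides when the second residue is
proline or alanine. When one of these enzymes is knocked out, the species it
would normally consume accumulate, and the species it helps produce are
depleted. Comparing the label-free peptidome of knockout and wild-type lines
therefore reveals each enzyme's substrate repertoire: the accumulating
peptides carry the disabled enzyme's uncut signature at one terminus.

cleavekit implements this comparison as a reusable pipeline — replicate
filtering, log2 transform, left-shifted imputation, pooled-variance t tests
with permutation q-values, z-scaled clustered profiles, terminus logos,
X-P/A dipeptide-pair detection and targeted MS1 verification — together with
a ground-truthed simulator of the underlying proteolysis, so every stage can
be exercised and validated without any external data.

## Processing model and simulator

The simulator composes four mechanisms per precursor, after removing the
annotated signal peptide:

1. **Dibasic endoproteolysis.** Eligible boundaries lie immediately after
   KK/KR/RK/RR pairs; each fires independently with the configured
   efficiency. PCSK1 and PCSK2 are modelled as a single redundant activity:
   only disabling both abolishes cleavage. Monobasic sites and sequence
   context beyond the dibasic pair are not modelled, so motifs that real
   convertases spare (such as the internal RR inside the glucagon region of
   proglucagon) are cleaved by the simulator; the N-terminal dibasic logo
   is unaffected, but individual fragment identities can differ from the
   physiological products.
2. **Carboxypeptidase trimming.** C-terminal K/R residues are removed one at
   a time until a non-basic residue is exposed. `trim_carboxy()` reports the
   full chain of intermediates; the simulated peptidome keeps only the
   terminal species of each chain, because the intermediates are transient
   in vivo (at partial efficiency the chain stops stochastically, leaving
   partially trimmed species). Responsibility is assigned per precursor
   (CPB1 for the somatostatin/NPW/PPY-like precursors, CPE for the rest),
   so a single-carboxypeptidase knockout leaves a clean signature; residue
   preferences beyond K/R-specificity are not distinguished.
3. **Amidation.** A species ending in glycine additionally yields an
   amidated species with the glycine removed; both forms are emitted. The
   amide-donor rule (`amidation_valid()`) — the residue after the peptide's
   C terminus in the precursor must be glycine — is enforced during peptide
   mapping, so chemically impossible amidated observations are excluded.
4. **DPP4 trimming.** A species whose second residue is P/A is converted to
   its dipeptide-cleaved product when DPP4 is active (single removal by
   default, iterative by option); in the DPP4 knockout the substrate remains
   instead. Substrate/product pairs are therefore planted with known truth.

Species shorter than 5 residues are discarded as undetectable. Ground truth
comes from running wild type and knockout at efficiency 1: knockout-only
species are labelled `ko_accumulating`, wild-type-only species `mature`,
shared species `constitutive`.

### Precursor fixtures

The bundled registry contains the real human proglucagon sequence (P01275)
with its UniProt feature coordinates, plus seven *synthetic* prohormone
constructs (clearly labelled as such in `prohormones_synthetic.fasta`).
The synthetic precursors reproduce the architecture that drives the
analysis — 20-residue signal peptide, peptide blocks joined by dibasic
linkers, amide-donor glycines, X-P/A amino termini, no stray dibasic pairs
inside blocks — without copying any real sequence. All worked examples that
depend on actual coordinates (the glucagon substring, the GLP-1 7-36
amide/glycine relationship, the oxyntomodulin and GRPP exclusion) use the
proglucagon entry.

## Abundance model

`generate_quant_table()` mirrors the knockout study design: one bulk and one
clonal wild-type line, two knockout clones, three technical replicates, one
BMP state (BMP enters only as a sample label). On the log2 scale,

```
value = base + clone_effect - shift * depleted + technical_noise
```

* `base` ~ Normal(20, 2) per species — a typical label-free dynamic range;
* `clone_effect` ~ Normal(0, sd_biological), default 0;
* `shift` (default 4) is subtracted in the genotype where the chemistry does
  not produce the species (mature species in the knockout,
  knockout-accumulating species in the wild type), so the knockout-vs-wild
  type log2 fold change is +shift / −shift / 0 by construction;
* `technical_noise` ~ Normal(0, 0.5).

A constitutive background of 300 random peptides (unmappable to any
precursor) emulates the large unchanged fraction of a real peptidome; it
keeps total-intensity normalization and the pooled permutation null honest,
since in real data the responsive hormone peptides are a small minority.
Intensities are `2^value`; the lowest 10% of intensities (the
`censor_quantile`) are set missing — left-censoring concentrated, by
construction, in the depleted genotype — and species observed in no sample
are dropped, as they would never be identified. All draws are governed by a
single seed.

What the generator does **not** emulate: ionization efficiency and
detectability differences between sequences, retention-time structure,
match-between-runs artefacts, correlated (batch) noise, BMP-dependent
transcriptional regulation, and monobasic convertase sites. Passing the
recovery tests therefore shows that the statistical pipeline recovers the
signatures its model implies, not that it would be equally sensitive on any
real dataset.

## Differential statistics

The analysis order is fixed: replicate filter → log2 → imputation →
t/permutation-q → z-scale/cluster.

* **Replicate filter.** A peptide is kept iff it is observed in every
  technical replicate of at least one (clone, BMP) group.
* **Normalization.** Each sample is scaled so its total non-missing
  intensity equals the grand median of per-sample totals ("total" method;
  "none" is available for pre-normalized tables).
* **Imputation.** Missing log2 values are drawn per sample from
  Normal(mean − 1.8·sd, (0.3·sd)²) — the down-shifted narrow normal that
  matches left-censored non-detections. The defaults (1.8, 0.3) are the
  de-facto convention of this analysis family; both are exposed. Comparisons
  meant to run on raw observed values only (prohormone-level profiles) use
  `impute = FALSE`.
* **Test.** Classical pooled-variance Student's t (Welch is deliberately not
  the default, matching the named test), two-sided, clones pooled within
  genotype.
* **Permutation q-values.** Sample labels are permuted globally — the same
  split applied to every peptide, 250 distinct splits drawn without
  replacement (exhaustive enumeration with a warning when fewer exist,
  e.g. 20 splits for 3 vs 3). Null |t| values are pooled across peptides;
  for peptide *i*, q = (mean permutation count of null |t| ≥ |t_i|) /
  (observed count of |t| ≥ |t_i|), clipped to [0, 1] and made monotone
  non-increasing in |t| by BH-style suffix minimization. Ties are counted
  inclusively on both sides, which makes the estimator deterministic given
  the seed. Peptides with q < 0.05 are called significant; the sign of the
  knockout-vs-wild-type fold change assigns them to the knockout- or
  wild-type-enriched set.
* **Display statistics.** Rows are z-scaled with the population standard
  deviation (constant rows become zeros and are flagged) and clustered with
  Euclidean average linkage (`stats::hclust`); dendrograms are exported as
  Newick via ape.

Under the complete null the pooled estimator is conservative: with
exhaustive 3-vs-3 enumeration the identity split and its complement always
contribute, so no peptide can reach q < 0.1 and the realized false-positive
fraction is essentially zero, while per-peptide permutation p-values remain
exactly discrete-uniform. The power side is exercised with the planted
4-log2-unit effect.

## Specificity evidence

Terminus windows span positions −4..−1/+1..+4 around the cleavage boundary
(start − 1 for N termini, end for C termini), gap-padded with `.` beyond
the precursor ends. In Schechter–Berger terms, −1/−2 are P1/P2 and +1..+4
are P1'..P4'. Only uniquely mapped peptides contribute; ambiguous and
unmapped peptides are counted and skipped, so no window is fabricated.
Duplicate windows are collapsed **only** for logo construction (the
convention for unique-termini logos); enrichment fractions and substrate
repertoires use the full enriched set. Logos report per-position counts,
frequencies over non-gap observations and information content in bits
against the uniform 20-residue background. A Fisher exact comparison of two
context sets at one position is provided as a quantitative supplement to
the qualitative logos.

Dipeptide pairs (long, short) require the short sequence to equal the long
sequence minus its first two residues, P/A at position 2 of the long form,
the same precursor with consistent coordinates, and identical modifications
apart from the N-terminal state. Pair detection is an identification-level
step and is run on the mapped table *before* the replicate filter, which
exists to protect the statistics, not the string matching.

## Targeted MS1 verification

Theoretical isotope envelopes are computed by convolving pinned natural
isotope abundances of C, H, N, O, S over the ion's elemental composition
(residue formulas + water, amidation −O+N+H, oxidation +O, N-terminal
acetylation +C2H2O, plus charge protons), truncated to M..M+4 and
renormalized; truncation is exact for the retained terms. The isotope dot
product (idotp) is the scale-invariant cosine between observed and
theoretical envelopes. A target is detected iff idotp ≥ 0.88 and, when a
retention time is supplied, it elutes inside the inclusive 89–91 min
window; non-detections report abundance 0 ("n.d."), and detections report
the isotope-summed abundance with its log2 value. Peak-shape similarity and
mass-error criteria are intentionally not implemented — no thresholds exist
for them — so detection rests on idotp and retention time alone. Observed
envelopes are consumed from a plain TSV; raw spectra handling is out of
scope.

## Numerical and design choices

* Coordinates are 1-based inclusive; cleavage boundaries are between-residue
  indices 0..L. Isoleucine and leucine are treated as distinct (sequences
  come from a search engine that fixed the residue).
* Peptides matching more than one precursor position are flagged ambiguous
  and excluded from specificity analyses rather than guessed.
* Precursor-level profiles sum mapped peptide abundances; samples where
  every peptide is missing stay missing ("n.d.") rather than zero.
* Zero pooled variance: equal means give t = 0, p = 1; unequal means are
  flagged degenerate with p = 0.
* One global seed fans out additively to per-stage seeds (simulation,
  table generation, imputation, permutations), so any stage can be re-run
  in isolation and a full rerun is byte-identical.
* Problem sizes used by the bundled checks: a ~360-peptide table (45
  responsive species + 300 background) across 12 samples with 250 label
  permutations, and 20 independent 3-vs-3 null tables for the calibration
  study — small enough to re-run anywhere in seconds, large enough for the
  fractions and calibration diagnostics to be stable.

## Known limitations

* The dibasic rule has no sequence context, so simulator fragments can
  differ from physiological products at convertase-spared motifs; which
  sites are actually used in vivo is not learned from data.
* CPE and CPB1 are distinguished only by which precursors they are assigned
  to, not by residue preference.
* The permutation-FDR estimator is validated by calibration properties
  (null fraction, exact discrete-uniform p distribution), not by equation
  matching against any external implementation.
* Imputation assumes missingness is left-censored; it will mis-state
  effects if values are missing for other reasons, and it compresses fold
  changes of species whose depleted-genotype values sit near the detection
  floor.
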