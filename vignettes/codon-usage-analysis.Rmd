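---
title: "Codon-usage analysis of coding-sequence panels: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-usage analysis of coding-sequence panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonpanel)
```

## The scientific question

Synonymous codons are not used at random. The balance of directional
mutation pressure (which shifts base composition, especially at silent third
positions) and translational selection (which favours codons matched to the
tRNA pool) leaves measurable fingerprints in a gene set: biased relative
synonymous codon usage (RSCU), a depressed effective number of codons (ENc),
correlations between GC12 and GC3, parity-rule-2 deviations at third
positions, and non-random adjacent codon pairing. This package implements
that analysis battery for small panels of human coding sequences — the
bundled example tables come from a published analysis of 18
depression-associated genes and its 62-gene housekeeping comparison set —
together with a synthetic-CDS generator so that every estimator can be
validated offline against known truth.

## Sequence handling

A CDS enters as a `gene_record`: the sequence is upper-cased, RNA U mapped
to T, out-of-frame trailing bases trimmed with a warning, and codons
containing ambiguity codes dropped (counted, never imputed — downstream
counts must be exact integers). Validation (`validate_cds()`) flags internal
stops; by default an internal stop truncates translation with a warning, and
`strict = TRUE` in the pipeline rejects the gene instead, since curated
reference CDS should be clean. Terminal stop codons are retained in the
codon list — codon-pair analysis needs stop-codon contexts — but are
excluded from RSCU/ENc/SCS/CAI counting (which operate on the 59 or 61 sense
codons) and from positional composition, so that GC3 refers to sense codons
only. Overall base composition and the six skews use the full sequence.

## Conventions that the source analyses leave open

Several quantities have more than one convention in the literature; the
package fixes each one explicitly and, where reasonable, exposes a switch.

**Skew orientation.** AT and GC skews follow the universal
(A−T)/(A+T), (G−C)/(G+C). The other four are not uniformly defined in the
literature; we use purine (A−G)/(A+G), pyrimidine (C−T)/(C+T), keto
(G−T)/(G+T) and amino (A−C)/(A+C), computed on overall counts (the bundled
skew table names no codon position). Correlation analyses are unaffected by
simultaneous sign flips.

**Dinucleotide odds ratios** use whole-sequence overlapping dinucleotides,
codon junctions included, with thresholds 0.73/1.23 for under/over
representation — the classification thresholds of the odds-ratio literature.

**ENc.** Wright's estimator with Leu/Ser/Arg treated as single 6-fold
families (not 4+2 splits), F3 from Ile alone, class means over families with
n ≥ 2, and the mean of observed class means substituted (and flagged) when a
degeneracy class is unobservable. Exactly uniform usage gives a finite-sample
F below 1/n_i, so ENc is clamped to [20, 61]; this is why perfect uniformity
reports exactly 61.

**SCS.** The scaled chi-square sums per-family χ² against equal usage and
divides by the codon count of families with n_i ≥ 2; Met/Trp/stop codons
carry no synonymous choice and are excluded from the denominator.

**CAI.** The reference set behind the published CAI values is not
recoverable, so the package bundles a *synthetic* human-like codon-usage
frequency table (labelled as such in its filename and header) that mirrors
widely reported aggregate human codon preferences. CAI values are therefore
comparative within an analysis, not reproductions of any published CAI;
`reference_weights()` accepts any user-supplied reference counts and records
provenance.

**P2** is computed from panel-mean RSCU over the WWC/WWU/SSC/SSU codon
classes. Note that the ratio (WWC+SSU)/(WWY+SSY) is algebraically bounded by
1, since the numerator sums a subset of the denominator classes; published
values slightly above 1 cannot arise from this formula and are not forced.

**Codon-pair significance** uses adjusted residuals of the pooled 64×64
contingency table with a ±3.29 cutoff (two-sided p ≈ 0.001), the convention
of codon-context tools; the cutoff is a parameter. Pooling across genes is
assumed (a single panel-level matrix), and pairs never cross gene
boundaries. Reports use the RNA alphabet (GUG-GUG) to match conventional
pair naming.

**Hydrophobicity.** The protein table distinguishes GRAVY (mean
Kyte–Doolittle hydropathy) from a "hydrophobicity" column that we implement
as the hydrophobic residue-class fraction {A,V,L,I,M,F,W,C}; histidine is
classified basic. pI uses bisection on the net-charge function with the
Bjellqvist pKa set (the ProtParam convention); the instability index uses
the Guruprasad dipeptide weight table bundled as a data file.

**Neutrality and parity.** The neutrality plot regresses GC12 on GC3 by
ordinary least squares; the slope is read as the mutational ("neutrality")
fraction and 1 − slope as selectional constraint. Parity coordinates are
G3/(G3+C3) (abscissa) and A3/(A3+T3) (ordinate), with (0.5, 0.5) the
strand-symmetric point.

**Bootstrap RSCU comparison.** Per codon we report the Welch t statistic
between the two panels and a null-enforcing bootstrap p: both groups are
redrawn with replacement from the pooled gene rows, and
p = (1 + #{|t*| ≥ |t|})/(reps + 1). Resampling whole rows preserves
within-gene correlation between codons; the pooled (null-enforcing) scheme
makes p directly interpretable, which case resampling would not.

## Ordination of RSCU tables: PCA versus correspondence analysis

`pca_rscu()` offers three conventions. Covariance PCA (column-centred, no
scaling) is the default: RSCU columns share a scale, so correlation scaling
is unnecessary. Correspondence analysis (CA) — the default ordination of the
classic palaeontological-statistics toolkits often used for codon data — is
also provided, decomposing the chi-square inertia of the table instead of
variance. The distinction matters for reproducing published axis
percentages: for the bundled 18×59 RSCU table, covariance PCA puts 54.8% on
axis 1, whereas CA yields 50.47 / 10.86 / 6.63 / 5.79% (cumulative 73.76%),
which is what the published analysis of this panel reports. The acceptance
script therefore recomputes that quantity with `method = "ca"` — the
computation that actually generated the published number — while the
pipeline default remains covariance PCA.

```{r ca}
ord <- pca_rscu(load_table_fixture("rscu"), method = "ca")
round(ord$variance_percent[1:4], 2)
```

## The synthetic-CDS generator

`generate_cds()` draws an amino-acid sequence uniformly over the 20 standard
residues (or takes one), then draws each codon i.i.d. within its synonymous
family with probability proportional to the supplied weights; sequences
start with ATG and end with a stop. `generate_panel()` emulates the study
conditions of the reference panel — 18 genes, lengths uniform over
1350–1650 bp, per-gene GC3 targets uniform over 0.418–0.8382 — realising
each GC3 target by multiplicatively tilting third-position G/C weights (the
tilt solved by root-finding on the expected GC3). The housekeeping
generator defaults to 62 genes with a lower, narrower GC3 range
(0.35–0.65), so panel-versus-housekeeping differences exist by construction.
All randomness flows through explicit seeds; a panel is fully reproducible
from its arguments.

Two optional structures go beyond i.i.d. codons: a boundary-dinucleotide
accept/reject step (e.g. CpG penalties), which can only act through
synonymous choice and therefore bites where the first codon base is free
(Leu/Ser/Arg); and a codon-pair rule that forces a given pair wherever the
matching amino-acid pair occurs, used to plant detectable codon-context
signal.

What the generator does *not* emulate: real amino-acid composition,
autocorrelated codon usage along the gene, introns/UTRs, or any coupling
between GC12 and GC3 — first and second positions are driven by the uniform
amino-acid draw. Consequently the neutrality slope of a purely synthetic
panel is near 0, and slope-recovery checks are run on simulated
(GC3, GC12) feature pairs instead. Passing tests on synthetic panels
demonstrate estimator correctness under known truth, not that real gene
panels behave this way.

## Statistical calibration and problem sizes

The test suite validates the stochastic machinery at sizes chosen for
statistical resolution:

* *RSCU recovery.* The per-codon RSCU standard error in a family of size
  n_i with n codons is about n_i·sqrt(p(1−p)/n); max-over-59-codons recovery
  within ±0.05 needs on the order of 2×10⁴ codons per family, so the
  recovery check pools 18 genes × 25 000 codons (and the single-gene unit
  test uses a 1.2 Mb CDS).
* *GC3 targeting.* At 500 codons the per-gene GC3 standard deviation is
  ≈0.018, so a 1500 bp gene matches its target only to ±0.05 or so; tests
  assert the panel mean at 1500 bp and per-gene values at 15 kb.
* *Bootstrap t-test.* Type-I error is estimated over 200 null datasets
  (18 vs 62 genes, 500 codons each, 199 bootstrap replicates), measured at
  0.043 at α = 0.05. For a planted shift of one pooled standard deviation,
  the Welch noncentrality is 1/sqrt(1/18 + 1/62) ≈ 3.73, which caps
  two-sided power at α = 0.01 near 0.83 — no resampling scheme can reach
  90% under these group sizes, and the suite documents the measured ~0.82.
* *Context residuals.* The ±3.29 cutoff is calibrated on margin-preserving
  random tables (`stats::r2dtable`) of a 50-gene × 10 000-codon panel
  (~5×10⁵ pairs), where the flagged fraction is ~0.15%, consistent with the
  nominal 0.1% given residual discreteness; at the sparse counts of an
  18-gene panel (~2 000 pairs over 4 096 cells) the normal approximation is
  anticonservative, which is worth remembering when reading significance
  calls on small panels.

## Degenerate inputs and numerical choices

Families with zero observed codons yield missing RSCU (never 0); skews and
parity coordinates with zero denominators are missing, not 0; constant
columns yield missing correlations; regressions require ≥3 complete rows and
positive predictor variance. pI bisection runs to 10⁻⁴ pH units on [0, 14]
(net charge is monotone in pH, so the root is unique). Pipeline outputs are
written in full precision alongside 2-decimal display tables, and reruns
with identical inputs, configuration and seed are byte-identical.

## Known limitations

* Sequence-level published quantities for the reference panel (CAI range,
  neutrality slope 0.3276, the 2047-pair context matrix, composition means)
  depend on the exact reference CDS sequences, which are not pinned by
  accession anywhere we can resolve; they are out of the validated surface.
  The bundled fixtures cover the table-level statistics (skew correlations,
  RSCU ordination, family-sum conservation), which are fully reproducible.
* The CAI reference is synthetic (see above); treat CAI comparatively.
* Correspondence analysis is provided for axis-percentage reproduction;
  full CA biplots/scalings beyond row/column coordinates are out of scope.
* The codon-context significance model assumes pooled counts and
  independence under the null; it does not model within-gene autocorrelation.
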