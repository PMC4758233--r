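---
title: "Methods: comparing evolutionary rates between metabolic gene classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing evolutionary rates between metabolic gene classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rateherit)
```

## The scientific question

Primary metabolic pathway genes (core biosynthesis, conserved across life)
and secondary metabolic pathway genes (specialized environment-interaction
pathways) evolve under different selective regimes. The analysis this
package implements asks three questions about two such gene classes in a
plant genome: do their evolutionary rates (dN, dS, dN/dS) differ; which
gene-level features correlate with those rates; and how do those features
group into independent axes of variation. The package provides the full
chain — divergence estimation, feature extraction, nonparametric
comparison, PCA attribution — plus a synthetic-data generator so the whole
chain can be exercised and validated without any external downloads.

## Divergence estimation

`estimate_divergence()` implements Nei–Gojobori (1986) counting with
Jukes–Cantor correction for codon-aligned ortholog CDS pairs:

* **Sites.** Each sense codon contributes `s = sum over positions of the
  fraction of single-nucleotide changes at that position that are
  synonymous`, counting only changes to sense codons in the denominator;
  `n = 3 - s`. Per pair, sites are averaged over the two sequences.
* **Differences.** For a codon pair differing at *k* positions, all *k!*
  orderings of the single changes are enumerated; orderings passing
  through a stop codon are discarded; synonymous/nonsynonymous step counts
  are averaged with equal weight over the remaining pathways (classic
  equal-pathway NG86 — no transition/transversion weighting, since the
  analysis consumes only per-gene dN, dS and their ratio).
* **Correction.** `d = -3/4 log(1 - 4p/3)` for `p = pS, pN`. Proportions
  at or beyond the 3/4 saturation bound raise an error, which
  `batch_divergence()` converts to a flagged row.

A deliberate design choice: this in-package counting estimator stands
where a maximum-likelihood codon model could be used. The downstream
analysis needs only gene-level `(dN, dS, dN/dS)`, the counting method is
fully self-contained and auditable, and its behaviour is verified against
exhaustive enumeration oracles over all 61 sense codons and all 61×61
codon pairs. Exact numerical agreement with ML codon models is not a goal.

Degenerate inputs are handled explicitly: codon columns containing a gap,
an ambiguous base, or a stop codon are skipped and counted per category;
the rare pairs for which *every* substitution pathway crosses a stop are
skipped into a `pathway_blocked` tally rather than attributed arbitrarily;
`omega` is missing (never 0 or infinite) when `dS = 0`, and such genes are
excluded from ratio statistics downstream.

## Gene architecture, GC and codon usage

From GFF3 gene models (1-based inclusive coordinates) the package computes
gene length (`end - start + 1`), summed 5'/3'-UTR segment lengths, intron
number (`exons - 1`) and mean intron length (inclusive inter-exon gap,
`next_start - prev_end - 1`). Genes without annotated UTRs get UTR length
0 and missing UTR GC (GC of an empty sequence is undefined). Isoforms are
reduced to the longest CDS, with a deterministic lexicographic tie-break
on the isoform id. CDS quality control applies exactly three rules — ATG
start, TAG/TAA/TGA end, length divisible by three — and reports every
violated rule per gene; internal stop codons are deliberately not checked.

GC3 is the fraction of G/C at third positions of all sense codons
(terminal stop excluded). This is the plain definition, not the
synonymous-only GC3s variant; the output header says `gc3` unambiguously.

ENc follows Wright (1990): per amino-acid family with at least two
observed codons, homozygosity `F = (n sum p_i^2 - 1)/(n - 1)`; then
`ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, where the class averages run over
observed 2-, 3-, 4- and 6-fold families and Met/Trp contribute the
constant 2. The 6-fold families (Leu, Ser, Arg) are kept as their own
degeneracy class. When the single 3-fold family (Ile) is unobserved,
`F3 = (F2 + F4)/2` (Wright's recommendation); when the 2-, 4- or 6-fold
class is entirely unobserved the statistic is returned missing with a
warning rather than guessed. Results are clamped to the theoretical range
[20, 61]; both limits are exercised by tests (single-codon-per-family
input gives exactly 20; uniform usage approaches 61).

## Expression level and tissue specificity

Expression level is the arithmetic mean over all supplied samples. Tissue
specificity uses the log-ratio form of the tau index:

tau = sum_j (1 - log S_j / log S_max) / (n - 1)

Values are floored at 1.0 before logs — the expression floor keeps the
index defined and inside [0, 1] and never binds for microarray-scale
intensities; tau is missing when the maximum is at or below the floor.
Two properties follow from the ratio-of-logs form and are asserted in the
tests: tau is independent of the logarithm base, and it is invariant to
*powering* the profile (the log-scale analogue of rescaling). It is not
invariant to multiplying the profile by a constant — a property only the
linear-scale tau variant has; the printed equation is implemented as
stated. All supplied columns are treated as "tissues and conditions"; any
curation or aggregation of samples to anatomical tissues is the caller's
responsibility.

Annotation breadth counts distinct terms per gene (Plant Ontology terms as
an expression-breadth proxy; GO-slim biological-process terms as
multifunctionality); duplicated (gene, term) rows collapse. Domain counts,
by contrast, count table rows including duplicates, since repeated domains
are biologically real.

## The statistical battery

All tests are two-sided; no multiple-testing correction is applied (the
analysis reports raw p-values, as class-comparison batteries of this kind
conventionally do).

* **Mann–Whitney U** from midranks; exact enumeration when the pooled
  sample has at most 12 observations without ties (desk-checkable against
  the enumeration oracle in the tests), otherwise the tie-corrected normal
  approximation with continuity correction. Zero-variance pooled samples
  return p = 1 with a flag.
* **Spearman rho** as Pearson correlation of midranks with the
  t-approximation on n - 2 degrees of freedom; pairwise deletion.
* **Coefficient of variation**: sample SD (n - 1) over mean.
* **Two-proportion z** with pooled variance and no continuity correction;
  the sign follows the first group.
* **PCA** on the correlation matrix of complete cases, unrotated.
  Loadings are eigenvector times sqrt(eigenvalue); each component's sign
  is fixed so its largest-magnitude loading is positive; per component the
  retained set is variables with |loading| above the threshold (default
  0.5). Constant variables are an error naming the variable; fewer
  complete cases than variables is a warning, not an error.

The report layer stratifies the class comparison by intron number with
groups {0}, {1..10}, {>10} — the boundary 10 belongs to the middle group —
and compares GC3 between intronless and intron-containing genes within
each class. Domain-class proportions (single = 1, double = 2, multi >= 3
domains; zero-domain genes excluded) are compared with the two-proportion
z test. Correlations are computed on the pooled gene set, matching a
single correlation battery across both classes. Ranges are (min, max) of
analyzed values.

## The synthetic study generator

`simulate_study()` writes every input the pipeline reads (scaffold genome
FASTA, GFF3 gene models, CDS and aligned-pair FASTA, expression matrix,
annotation tables, class map, manifest) with the class structure the
analysis assumes. Its defaults *are* the reference conditions: per-class
dN and dS means/SDs, UTR lengths and GC, intron numbers, GC3, ENc,
expression level, tau, and domain/GO/PO count means are set to the
magnitudes observed for *A. thaliana* primary and secondary metabolic
gene classes, with 1035 and 241 genes respectively.

Choices those observations do not pin down, fixed once here:

* CDS length lognormal (median 400 codons, sdlog 0.35, minimum 60 —
  enough codons that every ENc degeneracy class is observed).
* Intron count negative binomial (size 0.8), giving roughly 18% intronless
  genes, a realistic plant-genome fraction that keeps the intronless
  stratum populated; intron length lognormal with median 180 nt and a
  GT...AG splice-site skeleton.
* Expression lognormal (sdlog 1.0) across 20 tissues; per-gene tau targets
  Beta-distributed with concentration 8 around the class mean.
* Codon-usage bias 0.24 for both classes: the bias interpolates
  within-family usage toward one preferred codon per family and was
  calibrated once so the realized post-evolution ENc means land at the
  reference class values (about 53.2 and 54.5). Notably, a single shared
  bias suffices — the ENc class difference emerges from the GC3
  difference alone, consistent with the strong positive ENc–GC3
  correlation the analysis itself reports. The realized GC3 and ENc sit
  slightly above the ancestral targets because the uniform-neighbour
  substitution process drifts both upward; the calibration accounts for
  this.
* Intronless genes receive a +0.05 GC3 shift, reproducing the direction of
  the observed GC3-by-intron-presence contrast.
* 2% of genes get an injected CDS quality failure (start- or stop-codon
  corruption), 15% carry a second, shorter isoform, half the genes sit on
  the minus strand, and 3% lack expression data — so QC, isoform
  selection, strand handling and missing-data paths are all exercised
  end-to-end.

Divergence is simulated by independent per-codon Bernoulli substitutions,
calibrated in the estimator's own currency: targets are inverted through
the Jukes–Cantor correction, each codon's substitution probability is the
resulting proportion times its NG86 site count, each lineage receives half
the divergence, and replacements are drawn from single-nucleotide *sense*
neighbours so stops are never introduced. The start codon is held fixed,
as in real ortholog pairs. This closed loop makes "the estimator recovers
the simulation targets" a meaningful calibration check (within 10%
relative error at the observed rate scale), and it is how the generator's
monotonicity (higher synonymous target, higher estimated dS) is tested.

Expression profiles place one tissue at a maximum M and the rest at
M^(1 - tau), which makes the noise-free tau exactly the target; M is
solved numerically so the profile mean hits the level target, then mild
lognormal jitter (sd 0.15) is applied to the non-maximum tissues.

### What the generator does and does not emulate

The bundles reproduce the *marginal* class differences and their
directions, plus realistic plumbing (strands, isoforms, QC failures,
missing expression). They do not emulate: insertions/deletions or
alignment error (pairs are gap-free by construction; the pipeline accepts
gapped codon-aligned input but the generator never produces it);
transition/transversion or rate-among-site heterogeneity (substitutions
are uniform over sense neighbours); microarray noise structure; ontology
semantics (terms are exchangeable labels); or the empirical correlation
*between* features within a gene (features are drawn independently given
the class, except for the GC3–intron coupling). Passing end-to-end tests
therefore demonstrates that the pipeline measures what the generator
plants — estimator calibration, sign recovery, bookkeeping integrity — not
that real genomes satisfy the generator's independence assumptions.

## Numerical and edge-case conventions

* Jukes–Cantor is undefined at p >= 3/4: an explicit saturation error,
  flagged per pair in batches.
* omega is missing when dS = 0; missing values propagate as `NA` and are
  excluded by the statistics, never imputed.
* Longest-isoform ties break lexicographically; PCA component signs are
  fixed by the largest-magnitude loading; both make reruns byte-identical.
* GC content excludes N from numerator and denominator; empty or all-N
  sequences give missing GC.
* Histogram bins are left-closed right-open and anchored at 0.
* The pipeline is deterministic given inputs; the generator is
  deterministic given its seed, which is recorded in the bundle manifest.

## Problem sizes used by the validation suite

The package's own checks run at sizes chosen to make the stochastic
assertions sharp while staying desk-scale: estimator calibration uses 200
simulated pairs of 500 codons at the observed rate scale (dS 0.15, dN
0.02); the null-calibration and power checks of the Mann–Whitney test use
1,000 and 500 replicates at the reference group sizes (1035/241); PCA
structure recovery uses a 2,000-row two-block design; and end-to-end sign
recovery runs the full default bundle across 20 seeds, requiring every
expected class difference to point the right way in at least 90% of them.

## Known limitations

* The counting estimator shares NG86's known small-sample and
  high-divergence biases; at the rate scale analyzed here (dS well below
  saturation) these are a few percent.
* ENc's treatment of rare families follows Wright's interpolation for the
  3-fold class only; CDS shorter than ~60 codons may return missing ENc.
* GC3 has two conventions in the codon-usage literature (all third
  positions vs. synonymous-only); the plain all-positions definition is
  used and named unambiguously in the output.
* Real data-set exclusion cascades (orthology calls, similarity
  thresholds, expression coverage) are not modelled; the pipeline instead
  reports its own transparent exclusion accounting.
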