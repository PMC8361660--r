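---
title: "Methods: longitudinal tumor evolution analytics in osteoevo"
author: "osteoevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal tumor evolution analytics in osteoevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoevo)
```

# Scope and model overview

`osteoevo` analyzes longitudinal tumor genome cohorts — a chemotherapy-naive
primary plus one or more local/distal recurrences per patient, with a
matched normal — of the kind collected for metastatic osteosarcoma. The
package chains six analytical stages: somatic variant filtering and
prioritization; maximum-parsimony sample phylogenies; allele-specific
copy-number analytics including the homologous-recombination-deficiency
(HRD) genomic scar scores; 96-channel mutational-signature exposure fitting
with molecular-clock back-dating; mutual-exclusivity testing of driver
alterations; and a CDK/PARP therapy decision tree. Because the real cohorts
this kind of analysis targets sit behind controlled access, the package
also ships a first-class synthetic cohort generator with complete ground
truth, so that every stage can be exercised and validated end to end.

# Variant filtering and prioritization

Annotated somatic variants carry six caller quality metrics (QD, MQ, FS,
SOR, MQRankSum, ReadPosRankSum) and six in-silico pathogenicity scores
(SIFT, PolyPhen2, MutationTaster, GERP++, CADD, PhyloP). The hard filter
retains a record iff every *present* metric satisfies its strict
inequality (QD > 10, MQ > 40, FS < 30, SOR < 3, MQRankSum > -12.5,
ReadPosRankSum > -8). Two deliberate choices:

* **Strict inequalities, boundaries fail.** The thresholds are stated with
  plain ">"/"<"; a QD of exactly 10.0 is removed. Tests pin this behavior.
* **Absent metrics pass.** Rank-sum annotations are undefined for some
  genotype configurations; a missing value is not evidence of poor quality.

Prioritization keeps a variant iff it is protein-truncating or splice-site
(overriding any score), is on a user-supplied curated-pathogenic list
(a file, not a live database lookup — no network dependency), or passes
*all six* in-silico thresholds (SIFT < 0.05, PolyPhen2 > 0.7,
MutationTaster > 0.7, GERP++ > 0, CADD > 10, PhyloP > 0). A record missing
any score cannot pass the in-silico route: missingness blocks, it never
rescues. The pipeline applies hard filters before the curated rescue; the
order is not derivable from the method description and is recorded here as
the package's choice. "PhyloP VT/PL" is read as a single PhyloP value.

# Maximum-parsimony phylogenies

Each patient's samples are encoded as a binary sample-by-variant presence
matrix with an appended all-zero row for the normal, which roots every
tree. Parsimony length is the two-state Fitch count summed over columns.

* **Search.** With at most ten rows the package scores *every* unrooted
  topology (enumeration via `phangorn::allTrees`; scoring is the package's
  own Fitch pass) and returns all minimum-length trees. The heuristic mode
  is random-start nearest-neighbor-interchange hill climbing (default ten
  seeded restarts), which on random 5-7-taxon instances matches the
  exhaustive optimum in well over 95% of cases and can never beat it.
* **Ties.** All shortest trees are reported; downstream assignment uses
  their strict consensus. On the consensus, each variant is placed on the
  unique edge subtending exactly its carrier set; variants whose carrier
  set matches no edge are flagged homoplastic and assigned to the change
  edges of one minimal Fitch labeling.
* **Trunk.** The edge from the normal-side root to the most recent common
  ancestor of the tumor samples; its variants are exactly those carried by
  every tumor sample. The homoplasy index is `1 - n_variants / length`
  (one minus the consistency index, with one minimum change per binary
  column). Bootstrap supports resample variant columns with replacement
  and report, per observed tumor clade, the fraction of replicates whose
  co-optimal trees all contain that clade (a strict and therefore slightly
  conservative convention).

Trunk/branch selection pressure is summarized by raw
non-synonymous/synonymous count ratios (missense + truncating + splice
versus synonymous); a zero denominator yields an explicit undefined marker
rather than infinity. No codon-model dN/dS is attempted.

# Copy-number analytics and HRD scars

Segment profiles are allele-specific (total = major + minor), 0-based
half-open, and are merged over identical adjacent states before any
counting, so every score is invariant under segment splitting (verified by
property-based fuzzing against an independent brute-force scan). Sex
chromosomes are carried through I/O but excluded from every computation.

* **Burden**: fraction of autosomal bases with total copy number not 2.
* **Jaccard similarity** between two profiles: bases altered in both *in
  the same direction* over bases altered in either; two fully neutral
  profiles are defined as similarity 1 with a notice.
* **Events**: gains (total > 2) and losses (< 2); amplification at 5+
  copies, biallelic deletion at 0; focal under the common 10 Mb
  cytogenetic threshold (strict), broad otherwise.
* **Complex events**: chromothripsis-like oscillations (≥ 10 switches
  among ≤ 3 total-copy states, maximal run) and staircase amplifications
  (≥ 3 strictly monotone steps whose high-copy boundary lies within 1 Mb
  of a centromere edge or chromosome end). These defaults are package
  decisions — the descriptive literature reports event sizes, not
  detection parameters — and are all exposed in `detectComplexEvents()`.

The three HRD scar scores follow their published definitions with strict
length cutoffs: **LOH** counts merged minor-copy-zero segments longer than
15 Mb that retain at least one copy and do not span a whole chromosome
(the whole-chromosome exclusion follows the original score; a toggle is
provided); **TAI** counts allele-imbalanced segments longer than 11 Mb
anchored at a chromosome terminus and not crossing the centromere
(telomere anchoring tolerance 0 bp by default, configurable for noisy
segmentations); **LST** counts junctions whose flanking segments both
exceed 10 Mb and change allele-specific state, after removing segments
under 3 Mb and re-merging. The composite is the raw sum with positivity at
42 or higher, or a pathogenic BRCA1/BRCA2 mutation; a strictly-greater
rule variant is available, as is a linear ploidy correction for LST
(`lst - 15.5 * (ploidy - 2)`), reported alongside the raw count but not
used by the composite.

# Signatures and molecular-clock timing

SNVs are tallied into the standard 96 trinucleotide channels (pyrimidine
convention, purine-reference variants reverse-complemented). Exposures are
fitted by expectation-maximization for a multinomial mixture: uniform
deterministic initialization, responsibility updates until the relative
log-likelihood change drops below 1e-8 (cap 10,000 iterations), exposures
on the count scale summing exactly to the SNV total. The log-likelihood is
asserted non-decreasing at every step, and a non-negative least-squares
mode serves as a cross-check. Indels are excluded from channel counting
but retained in burden counts.

The shipped reference table (`signatures_96_synthetic.tsv`) is a
**synthetic stand-in**: five columns with the qualitative channel
preferences of the aging/clock process (C>T at NpCpG), HRD (near-flat),
mismatch-repair deficiency (C>T at GpCpN plus T>C), UV (C>T at
dipyrimidines), and a flat background. It is not a copy of any signature
database; users analyzing real data should supply their preferred 96-by-k
reference via `referenceSignatures(path)`.

Back-dating assumes clock-like mutations accumulate linearly in calendar
time: with rate *r* (clock mutations/month), the primary tumor's clonal
clock count *c* places the origin *c/r* months before biopsy, and the
trunk-shared clock count places metastatic divergence forward from that
origin. This linear-accumulation model is the minimal one consistent with
steady clock increase across sequential samples. The rate can be estimated
by least-squares regression of clonal clock counts on collection months.
Two pooling choices are implemented; the package *recommends the
cohort-pooled regression* (all samples of all patients) because with only
2-4 samples per patient over a few-month window, per-patient two-point
slopes are dominated by Poisson noise — in simulation their median origin
error is above 2 months, versus about 0.7 months for the pooled rate.
A non-positive fitted slope raises an explicit clock-violation error.
Uncertainty intervals Poisson-resample the observed counts under a fixed
seed. "Clonal" clock mutations are those shared along the lineage path
under analysis; cancer-cell-fraction estimation from read depths is out of
scope.

# Mutual exclusivity and therapy rules

The exclusivity test binarizes the gene-by-patient alteration matrix, fits
per-cell background probabilities `plogis(a_i + b_j)` whose expected row
and column sums match the observed margins (damped Newton/IPF, tolerance
1e-8), and evaluates the coverage statistic — patients altered in at least
one group gene — against the tail P(coverage ≥ observed) of independent
Bernoulli draws: exactly, via Poisson-binomial convolution, for groups of
up to three genes, and by seeded Monte Carlo otherwise. A one-gene group
carries no exclusivity signal and returns p = 1 by construction.

A calibration caveat, measured and worth knowing: with the background
margins fitted from the same matrix, this group-coverage construction is
*conservative* on independent-gene nulls at realistic panel sizes (its
empirical size at α = 0.05 is well below nominal with eight background
genes, and only approaches nominal — from the anti-conservative side — for
implausibly small matrices where patient effects overfit). Its power
against genuinely exclusive pairs at cohort-realistic frequencies remains
essentially 1. Interpret its p-values as honest upper bounds. q-values use
Benjamini-Hochberg. Cohort prevalence percentages are *truncated* (not
rounded) at the requested decimal, matching how such cohort tables are
conventionally printed (47/78 prints as 60.2).

The therapy tree is total over genotypes: CDK4/6 inhibition requires a
CCND3/CDK4/CDK6 amplification with neither RB1 loss (the drug target's
substrate is gone) nor CCNE1 amplification (resistance via the CDK2
route); CDK2 inhibition requires CCNE1 amplification with wild-type Rb;
PARP inhibition requires HRD positivity by composite score or BRCA1/2
route. CDKN2A deletion alone does not gate CDK4/6 inhibition by default
(an opt-in flag widens eligibility); PALB2 is reported but is not a PARPi
gate. An exhaustive truth-table test covers all 2^8 genotype combinations
against both HRD states.

# The synthetic cohort generator

`simulateCohort()` emulates the discovery design: 12 patients, 2-4 samples
each (primary at month 0, recurrences 2-8 months later), a clonal
phylogeny whose first split is the metastatic divergence. Defaults are the
study conditions: clock rate 8 mutations/month, origin 9 months before the
primary biopsy, divergence 3 months after origin. Per edge, clock
mutations are Poisson(rate x duration); non-clock mutations are added so
the aging signature holds its configured share of the total (default
mixture 0.6/0.2/0.1/0.1 over clock, HRD, MMR and UV signatures) and are
spread uniformly over edges of positive duration — so a degenerate
zero-duration configuration puts everything on the trunk. Effects are
drawn at a neutral non-synonymous:synonymous ratio of 2.5:1; quality
metrics are drawn passing. With these settings primary tumors carry
roughly 90-190 coding SNVs — the clock calibration pins counts near the
upper end of the plausible 6-144 range; recurrences carry about 50% more.
Per-edge clock-rate heterogeneity is available as an optional stressor
(`branch_rate_sd`), off by default.

Copy-number profiles plant exact scar targets by construction: LOH units
are 18 Mb minor-zero segments flanked by 10 Mb buffers (so no junction
acquires two >10 Mb flanks), TAI units are 12 Mb terminal imbalances
behind a balanced 10 Mb buffer (buffers stay under the 11 Mb TAI cutoff),
and LST chains are alternating balanced blocks each longer than 10 Mb on
dedicated chromosomes. Each unit therefore moves exactly one score, and
`plantScarProfile()` verifies its own output against `hrdScores()` before
returning — unachievable targets on a given build fail loudly. Scar
targets are drawn per patient (truncal, shared by all samples); samples
additionally receive private 5 Mb focal gains/losses spliced into diploid
runs with >10 Mb margins (provably invisible to the scar scores), and some
patients carry a private chromothripsis-like oscillation and a telomeric
staircase built from sub-3-Mb steps (likewise invisible to LST). This
yields within-patient CNA Jaccard similarities around 0.6-0.9, the range
longitudinal osteosarcoma genomes show.

Driver genotypes are drawn per patient at literature-scale marginal
frequencies under hard exclusivity rules (CDK4-RB1, RB1-CCND3,
CCND3-CCNE1, CDK4-CCNE1 never co-occur) by rejection sampling; the rules
are re-verified exhaustively in tests.

What the generator deliberately does *not* emulate: read-level noise and
coverage, sequencing error, subclonality (all simulated variants are
clonal, matching the clock model's input contract), indel signatures, and
SV breakpoint structure. Passing tests therefore demonstrate correctness
of the analytics under the stated generative model, not robustness to
segmentation error or impure samples; the configurable anchors/tolerances
(telomere window, complex-event parameters) are the knobs a real-data
analysis would loosen. The generator's ground truth records the full tree,
per-variant edge and signature assignment, per-sample exposures, clock
parameters, planted scars, complex events and driver genotypes.

# Numerical and reproducibility notes

* All randomness is funneled through explicit integer seeds; simulation,
  heuristic search, bootstrap and Monte Carlo are byte-reproducible.
  Random-number state is restored after every seeded call.
* Problem sizes in the shipped tests — cohorts of 2-200 patients,
  500-profile scar fuzzing, 100-instance search comparisons, 1000-matrix
  null calibration — were chosen so the whole suite completes in a few
  minutes while leaving each statistical check adequately powered.
* Exact printed-precision assertions are reserved for genuinely exact
  quantities (worked arithmetic, boundary behavior); stochastic
  recoveries assert fractions over seeded replicate ensembles.
* Degenerate inputs have defined behavior throughout: empty matrices,
  zero-count spectra, fully neutral profile pairs, one-gene groups,
  zero-duration branches and flat clock counts all either return a
  documented value with a notice or raise a specific error.
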