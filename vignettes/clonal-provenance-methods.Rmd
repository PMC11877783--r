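---
title: "Methods: calling the clonal provenance of recurrent tumors"
author: "clonalProvenance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling the clonal provenance of recurrent tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalProvenance)
```

# The question

After gross total resection of a glioblastoma, where does the recurrent
tumor come from? Two genetic signatures distinguish the candidate answers
when matched blood, tumor-free subventricular-zone (SVZ) tissue, primary
tumor and recurrent tumor are deep-sequenced:

* **Primary-associated recurrence** — the recurrence descends from the
  dominant primary clone, so the two tumors share somatic mutations that
  the SVZ does not carry.
* **SVZ-associated recurrence** — the recurrence descends from an early
  progenitor (an SVZ-resident lineage carrying trunk drivers such as a
  TERT-promoter mutation), so the only mutations shared by the two
  tumors are those also found in the SVZ, and the high-allele-frequency
  private mutations of the primary tumor are *extinct* in the
  recurrence.

This package implements that inference as a pipeline of small, testable
stages: detection-limit-aware presence calling, mutation-sharing
categorization, rule-based patient classification, and a simplified
VAF-constraint lineage tree. Because no patient-level sequencing data
are publicly available for this design, a branched clonal-evolution
simulator generates matched four-sample datasets with known truth, and
every stage is validated against it.

# Presence calling

The elementary datum is a pair (alt reads, total depth) for one variant
in one tissue. A binary present/absent call would be dishonest at low
depth, so calls are three-state:

* **PRESENT** — at least `minAltReads` (default 3) alternate reads *and*
  a one-sided binomial tail probability
  $P(X \ge \text{alt} \mid n = \text{depth}, p = \text{errorRate})$
  at most `alpha` (default $10^{-3}$), i.e. the signal is inconsistent
  with sequencing error alone (assumed miscall fraction
  `errorRate` $= 10^{-3}$).
* **ABSENT** — the PRESENT criteria fail *and* the site is deep enough
  that a real variant at allele fraction `vafDetect` (default 0.02)
  would have been detected with probability at least `powerFloor`
  (default 0.9). `detectionPower()` computes that probability as
  $P(X \ge k^\*)$ under $\mathrm{Binomial}(\text{depth}, \text{vaf})$,
  where $k^\*$ is the smallest alt count meeting the PRESENT criteria.
* **INDETERMINATE** — otherwise: the site is too shallow to claim
  absence. At the defaults, absence becomes callable at roughly 260x.

The states are exclusive and exhaustive, and monotone in the alt count.
There is no multiple-testing correction across variants: the intended
input is a small curated panel of manually reviewed calls, not a
genome-wide discovery set. Variants PRESENT in blood at the same
thresholds are flagged germline and excluded from all somatic analysis.
The default `vafDetect` of 2% is a declared operating point for what
"low-frequency" means in the SVZ, not an empirically fitted value.

# Mutation categories

Each somatic variant's presence triple (SVZ, primary, recurrent) maps to
one of five sharing categories — SVZ-Tumor-shared, Inter-Tumor-shared,
Primary-private, Recurrent-private, SVZ-private — or to UNRESOLVED when
an INDETERMINATE call sits in a tissue the category hinges on. The one
deliberate asymmetry: SVZ PRESENT plus at least one tumor PRESENT is
SVZ-Tumor-shared regardless of the remaining tumor (a `subtype` records
which tumors share it), because the shared-lineage claim is already
established; every other combination treats an INDETERMINATE deciding
tissue as blocking. Identity is allele-level — `(chrom, pos, ref, alt)`
— so two different mutations in one gene (e.g. distinct PTEN alleles
private to primary and to recurrence) are never conflated into a shared
call. The complete 27-row truth table is enumerated in the test suite.

# Patient classification

`classifyRecurrencePattern()` applies four rules in fixed order:

1. no SVZ-Tumor-shared variant PRESENT in all three tissues → UNKNOWN
   (no trunk evidence anchors the patient to one clonal lineage);
2. any Inter-Tumor-shared variant → PRIMARY_ASSOCIATED;
3. any Primary-private variant confidently ABSENT in the recurrence →
   SVZ_ASSOCIATED;
4. otherwise UNKNOWN.

Design choices made here, where the design was genuinely open:

* **Rule 2 outranks rule 3.** An inter-tumor shared mutation directly
  links the tumors; the SVZ-associated signature explicitly excludes
  such mutations, so when both kinds of evidence coexist the direct link
  wins.
* **Trunk evidence is any all-three-shared variant**, not specifically
  the TERT promoter; TERT is the empirical trunk marker in IDH-wildtype
  GBM but the logic generalizes. A `strictTrunkGene` flag restores the
  marker-specific behaviour.
* **Extinction must be confident.** Rule 3 requires an ABSENT call (not
  INDETERMINATE) in the recurrence, which the Primary-private category
  already certifies; thin recurrent coverage therefore degrades the
  patient to UNKNOWN instead of fabricating clone extinction.
* **No VAF cutoff on the extinct primary-private variants** is imposed:
  in high-purity tumor specimens, clonal private mutations dominate the
  category anyway, and a cutoff would add a tunable with no data to set
  it.
* Patients without a recurrent sample raise an error rather than
  UNKNOWN: UNKNOWN is an evidentiary verdict about an observed
  recurrence, not a missing-data code.

`summarizeCohort()` reports counts and percentages per label.
Percentages are displayed to one decimal through an intermediate
two-decimal half-up rounding — the display chain of spreadsheet-derived
clinical reports — so a 7/13 fraction prints as 53.9 (and 4/13, 2/13 as
30.8, 15.4). Displayed percentages may consequently sum to slightly
more or less than 100.

# Lineage trees

`inferLineage()` reconstructs a clone tree in the style of
VAF-containment lineage tools, deliberately simplified: variants are
first partitioned by exact presence profile (variants seen in different
tissue sets cannot share a clone), then single-linkage clustered within
profile on the largest per-sample VAF distance with tolerance `tol`
(default 0.05 VAF). Clusters are ordered by decreasing total VAF and
each attaches to its *nearest valid ancestor*: a parent must dominate
the child's mean VAF within `tol` in every sample and be PRESENT
wherever the child is; among valid parents the smallest summed VAF
excess wins, ties broken lexicographically; with no valid parent the
cluster hangs from the germline root. After construction the pigeonhole
(sum) rule — per sample, parent VAF + `tol` must cover the summed VAF of
its children, with the germline root treated as a heterozygous ceiling
of 0.5 — is checked and violations are *reported*, never repaired by
silently dropping variants. This recovers the trunk/primary-branch/
recurrence-branch ordering the application needs; it is not a full
probabilistic network search, performs no subclone-fraction
deconvolution, and is not copy-number aware.

`treeConcordance()` scores a reconstruction against a known phylogeny as
the fraction of unordered mutation pairs whose relation (same node,
lineal with orientation, or sibling) agrees between the trees.

# The simulator

`simulatePatient()` turns a `SimulationSpec` — a rooted clone tree,
a mutation catalog, per-sample purities and clone mixtures, and a noise
model — into a variant table plus ground truth. A mutation's
cancer-cell fraction (CCF) in a sample is the summed mixture fraction of
its carrying clone's subtree; expected VAF is $0.5 \cdot \text{purity}
\cdot \text{CCF}$ (copy-number-neutral heterozygous diploid model — the
classification logic never uses absolute CCF, so modelling CNV shifts
would add parameters without changing any decision boundary). Total
depth is Poisson-dispersed around the target (fixed-depth switch for
exact tests); alt counts are binomial with success probability
$\text{vaf}(1-e) + (1-\text{vaf})e/3$, a uniform miscall model with
default $e = 10^{-3}$, a standard hybrid-capture error floor. Noiseless
mode returns rounded expectations and is seed-free by construction.
Seeds are mandatory in the spec and all randomness is local (the
caller's RNG stream is untouched).

Defaults declare the study conditions: mean depth 1063x (the panel's
median depth), tumor purity 0.5–0.8, and an SVZ mutant-cell fraction of
0.02–0.10 — the source study describes the SVZ driver mutations only as
"low-frequency", so this range is a declared choice at the edge of what
a 2%-VAF detection limit can see, not an inferred value.

Two preset architectures matter:

* `gbm244Preset()` — the whole-genome worked example: a trunk with a
  TERT-promoter-like and an EGFR-like driver shared by SVZ (mutant
  fraction 0.05) and both tumors, a primary branch with 5 private
  passengers (primary mixture: 10% trunk / 90% branch), and a sibling
  recurrence branch with 5 private passengers (15% / 85%). Noiseless,
  this yields exactly 2 shared + 5 primary-private + 5
  recurrent-private categories, an SVZ_ASSOCIATED label, and the
  root → trunk → two-siblings tree.
* `randomPatientSpec()` — randomized phylogenies with known truth label;
  the PRIMARY_ASSOCIATED variant inserts a clone carried by both tumors
  but absent from the SVZ, whose mutations are inter-tumor shared.

What the simulator does *not* emulate — and what passing tests therefore
do not certify on real data: copy-number alterations and loss of
heterozygosity (which distort VAFs), position-specific or strand-biased
sequencing error, alignment and variant-calling artifacts, intratumoral
spatial sampling bias, and contamination. The simulator validates the
decision logic downstream of a curated call set, not the upstream
calling.

# The packaged cohort fixture

`cohortFixture()` loads a ten-patient synthetic cohort
(`inst/extdata/cohort/`) transcribing the mutation-sharing relations of
the longitudinal study this pipeline operationalizes: a TERT-promoter
trunk variant shared by SVZ/primary/recurrence in all ten patients; two
patients with additional inter-tumor shared variants; six with
primary-private variants extinct in the recurrence plus
recurrent-private variants (including the allele-level PTEN/SPTA1
distinctions); and two whose deciding non-trunk calls are blocked by
shallow coverage. The read counts are synthetic, chosen so the default
parameters reproduce the stated relations; classifying the fixture
yields 6 SVZ-associated, 2 Primary-associated, 2 Unknown (60.0 / 20.0 /
20.0 percent).

# Validation sizes and numerical notes

The test suite exercises, as the package's own validation design: the
complete 27-combination category truth table; Monte-Carlo calibration of
`detectionPower()` (100,000 draws per grid cell over depths 30–1063 and
VAFs 0.01–0.25, agreement within 3 sampling standard errors); 200
stochastic simulated patients per scenario at depth 1063 for label
(≥ 95%) and category (≥ 99%) recovery, with exact recovery required on
noiseless data; and exact tree reconstruction on 50 noiseless random
phylogenies with at least 3 mutations per clone. Observed recovery at
these settings is ~99% for labels and > 99.9% for categories; the
dominant residual error mode is a trunk variant at the low end of the
SVZ fraction range (expected VAF ~1%, below `vafDetect`) being called
ABSENT in the SVZ.

Numerical conventions: binomial tails come from `pbinom()`; the PRESENT
threshold $k^\*$ is found by a local search around `qbinom()`;
percentage rounding is integer-arithmetic half-up (no floating-point
double-rounding hazards); canonical variant order is lexicographic
`(chrom, pos, alt)`; all tabular outputs are deterministic given the
config, and simulation reruns with the same seed are bit-identical.

# Limitations

Beyond the simulator's scope notes above: the classifier is rule-based
by design (no probabilistic clonal deconvolution), inherits any
upstream miscalls in real data, and treats each sample's counts as
given — how multi-sample callers merged evidence across the four
specimens is outside its contract. The UNKNOWN class is deliberately
conservative; cohorts sequenced much below ~300x in any deciding tissue
will drift toward UNKNOWN rather than misclassify.
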