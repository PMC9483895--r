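---
title: "Methods: conservation, dating and enrichment analysis of retroviral LTR loci"
author: "ltrevo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, dating and enrichment analysis of retroviral LTR loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrevo)
```

This vignette is the package's own account of the science it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
the numerical conventions, and the design decisions that were genuinely
open.

## The analysis in one paragraph

Fixed endogenous-retrovirus LTR insertions — the HERVH promoter family
LTR7 (3354 reference loci, 11 monophyletic subfamilies) and the HERVK
promoter subtype LTR5_Hs (606 loci) — are classified for conservation
in non-human primate genomes from direct and reciprocal LiftOver-style
mapping tables. The per-species conserved counts feed three downstream
analyses: a gains/losses balance and an acquisition-rate dating model;
subfamily abundance profiles whose resemblance to the human catalog is
correlated with divergence time; and a human-specific locus
classification. Independently, loci are associated with genes through
basal-plus-extension regulatory domains, and the linked-gene sets are
tested for category enrichment (offspring-survival genes,
synaptic-transmission network genes, perturbation-response sets) with
exact tests.

## Conservation calling

A reference locus is `HIGHLY_CONSERVED` in a target genome only when
both mapping requirements hold: a *single* direct hit recovering at
least `min_identity` (default 0.95) of the query, and a single
reciprocal hit at the same threshold returning to *exactly* the
queried interval. Two operational choices deserve note:

* **"Exactly the same interval"** is implemented as same chromosome
  and `|Δstart| + |Δend| ≤ slop`, with `slop = 0` by default and
  configurable — mapping coordinates are discrete, so an explicit
  tolerance is the only honest rendering of "exact".
* **Multi-hit mappings fail** regardless of identity: a locus that
  maps to two places has no single ortholog, which is the point of the
  reciprocal test.

The identity field is defined as the fraction of the query sequence
recovered at the mapped locus. Whether a LiftOver-style "95%
threshold" refers to the remap minimum-match setting or to nucleotide
identity of aligned bases is ambiguous in general; both readings are
representable in this field, and the caller decides what their mapping
tables contain.

Beyond the published two-state view (highly conserved or not), the
package distinguishes `ABSENT` (no direct hit at all) from `DIVERGED`
(hit, but failing a requirement). The distinction costs nothing and is
needed twice: by the human-specific classifier, and by the generator's
truth bookkeeping.

**Human-specific loci.** A locus is human-specific when *both* Pan
genomes show no mapping at even a 10% identity cutoff. A literal
"below 10% nucleotide identity" is beneath alignability, so the rule
is read as *failure to map at a permissive minimum-match setting* —
an interpretive commitment, recorded here. `bona_fide` additionally
requires that no alignment chain intersects the locus in either
genome, separating true insertions on the human lineage from deletions
in the Pan lineage. The classifier never contradicts conservation:
a human-specific locus cannot be highly conserved in chimpanzee or
bonobo, but it may be in more distant species (a Pan-lineage loss),
and the generator plants exactly such loci to exercise that regime.

## Acquisition-rate dating

The dating model is linear accumulation: loci accrue on the lineage to
the reference at a constant rate, so anchor species with conserved
counts `N_a` at split time `T_a` give

```
rate = (N_ref − mean(N_a)) / T_a      [loci / MYA]
t_s  = (N_ref − N_s) / rate
```

The model was committed from a graphical presentation of gains/losses
balances; the linear form is the simplest one consistent with it. Its
known bias is documented and asserted as a property: losses on
non-reference lineages inflate the deficit, so estimates are biased
*upward* when retention is imperfect — the estimator attributes every
missing locus to late birth, never to loss. Anchoring uses the mean of
the Old World Monkey counts at a configurable 29 MYA split (per-species
anchoring is supported by passing a single species). With constant
insertion and zero loss the estimator recovers planted split times up
to binomial sampling noise; the test suite asserts recovery within 15%
relative error at ≥ 1000 loci and the upward bias direction under
loss.

## Abundance profiles

Profiles are *percentages* of a species' conserved loci per subfamily,
not raw counts, so species with very different totals remain
comparable. Correlations are Pearson product-moment coefficients
(the convention of the summary statistics this package reproduces);
species with zero conserved loci are excluded from correlation
analyses with a warning rather than silently producing `NaN`. The
resemblance-vs-divergence association correlates each species'
profile-to-reference correlation with its divergence time; under
age-structured subfamily composition it is strongly negative (the
default synthetic conditions give r ≈ −0.99).

## Gene association

Regulatory domains follow the basal-plus-extension construction with
the published defaults: basal = TSS − 5 kb … TSS + 1 kb
(orientation-aware), extension from the basal boundary to the nearest
*non-overlapping* neighboring basal boundary, capped at 1 Mb per side,
clipped at chromosome ends. All three parameters are arguments, since
analyses at differing maximum extensions are standard practice.
Overlap requires ≥ 1 bp of the locus interval by default; a midpoint
mode is available. Later refinements of curated regulatory domains in
specific annotation releases are deliberately not modeled — the
construction here is the generic algorithm.

Interval overlap is delegated to GenomicRanges (`findOverlaps`), with
coordinates converted from the package's 0-based half-open (BED)
convention to IRanges' 1-based closed one at the boundary. An
independent brute-force all-pairs oracle in the test suite checks the
construction and the assignment on hundreds of random annotations.

## Enrichment statistics

`fisher_two_sided()` uses the standard two-sided convention: sum the
hypergeometric probabilities of all tables in the margin class whose
probability does not exceed the observed one (relative tie tolerance
1e-7). It is implemented directly on `stats::dhyper` and is verified
in the tests both against `stats::fisher.test` and against exhaustive
enumeration of every 2×2 table with total ≤ 60.

**The two table constructions.** The published family-level category
tables compare the observed category count among `n` linked genes
against the *rounded expected-by-chance count in an equal-sized
pseudo-group*: `[k, n−k; round(nK/U), n−round(nK/U)]`. This is the
construction that reproduces the published p-values exactly, and it is
the `method = "expected"` default of `category_enrichment()`. It is
intentionally conservative — the comparison group carries no sampling
variance, so under a random null the type-I error is far below
nominal (about 0.002 at α = 0.05 for the study-sized table). The
classical linked-vs-unlinked partition of the universe
(`method = "population"`) is also provided; it is the construction
whose four cells sum to the universe size and the one that is
calibrated under the null (exact type-I 0.048 at α = 0.05 for the
study dimensions), and it is the construction the calibration test
exercises. Users doing new analyses should prefer `"population"`;
`"expected"` exists to mirror the published tables.

Other conventions: percentages are rounded half-up to two decimals for
display while full precision is kept internally; the combined score
uses the natural logarithm, `c = ln(p)·z`, with the z-score taken as
an input (the rank-permutation machinery that produces it in the
upstream platform is out of scope); the hypergeometric overlap test is
the upper tail `P(X ≥ overlap)` via `stats::phyper`;
Benjamini–Hochberg adjustment is provided as a utility
(`stats::p.adjust`).

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed
once and are not tuned per analysis.

* **Birth process.** Loci are born on the reference lineage in
  piecewise-constant epochs. The LTR7 default plants 600 loci before
  the 29 MYA Old World Monkey split, 2579 in the great-ape expansion
  window (29–13 MYA), and 175 after the Pan split — reproducing the
  published regime of ~18% OWM-era conservation and ~175
  human-specific loci out of 3354. The LTR5_Hs default (6/137/287/176
  across 40–29–16.8–13–0 MYA) analogously places 143 loci before the
  gibbon split. A scalar `insertion_rate` collapses this to a single
  constant-rate epoch, the configuration the dating-recovery tests
  use.
* **Subfamily composition drift.** Subfamilies are sampled per epoch
  from the reference composition tilted toward "old" subtypes
  (LTR7B/C/bc/o) in ancient epochs and "young" ones (LTR7u*/up*/Y) in
  recent epochs, with LTR7Y the dominant recent source. This induces
  the monotone profile-resemblance decay the abundance analysis
  expects.
* **Presence and loss.** A locus is present in species S iff born
  before S's split and not lost: an independent per-branch loss with
  probability `retention_loss_prob` (default 0.02; no published loss
  estimate exists, so this is a pilot-chosen realistic value), plus a
  planted fraction `pan_loss_frac` (0.03) of pre-Pan loci deleted in
  both chimpanzee and bonobo to create the human-specific-yet-
  OWM-conserved loci.
* **Identity model.** Mapped identity is
  `clamp(1 − identity_decay · T_s + N(0, σ))` with
  `identity_decay = 0.001`/MYA and `σ = 0.005` — linear decay with
  Gaussian jitter, the simplest model in which present loci pass the
  95% threshold at all panel depths (0.971 ± 0.005 at 29 MYA) while
  the DIVERGED path remains reachable. A `reciprocal_fail_frac`
  (0.005) of direct hits get off-target reciprocal records,
  exercising the reciprocity requirement.
* **Genes and responses.** The universe holds 18,777 genes with
  offspring-survival prevalence 2413/18777, exactly 355 synaptic and
  88 fetal-gonad flags. Perturbation responders are drawn once per
  gene (probability 0.53 if linked, 0.04 otherwise) and each responder
  is observed in at least one named experiment, so the union of the
  response sets recovers the planted probability exactly.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: sequence-level evolution (indels,
recombination, subfamily exchange), non-uniform genomic locus and gene
placement, correlated losses across sister branches, polymorphic
insertions, and any realistic structure in which genes respond to
perturbation. Conclusions from synthetic runs are about the
*algorithms*, not about primate genomes.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open (BED) everywhere inside the
  package; conversion to 1-based closed happens only at the IRanges
  boundary.
* Profiles of species with zero conserved loci are errors, not NaNs;
  correlation of zero-variance vectors is an error.
* `conserved_count_matrix()` refuses gap-containing call sets and
  names the missing pairs.
* Reciprocal records without a corresponding direct hit are contract
  errors — they cannot arise from a well-formed reciprocal test.
* Rounding for display is half-up (`floor(x·100 + 0.5)/100`),
  matching the published tables; comparisons against printed values
  use two decimals for ratios/percentages and three significant
  figures for p-values, absorbing convention and rounding differences
  of the original report.

## Problem sizes used in validation

The test suite exercises: exhaustive Fisher enumeration over all 2×2
tables with total ≤ 60; 200 random annotations (up to 100 genes × 1000
loci) against the brute-force association oracle; 5000 null
simulations for calibration (replicates chosen so the Monte Carlo
standard error, ~0.003, is small against the ±0.01 calibration
margin); dating recovery on constant-rate histories of 2000+ loci; and
full-scale default synthetic runs (3354 + 606 loci, 18,777 genes,
10 NHP genomes).

## Known limitations

* The dating estimator ignores losses by construction; its estimates
  are upper bounds under imperfect retention.
* The `"expected"` enrichment construction is conservative and should
  not be used for new inference; it exists for comparability with the
  published tables.
* The per-subfamily epoch tilt is a stylised drift model; it
  reproduces monotone resemblance decay but not any particular
  subfamily's true age distribution.
* Published genome-scale quantities that depend on the real locus
  catalogs, chain files and annotations (per-species conserved counts,
  the 2957/935 linked-gene totals, the 175/176 human-specific totals,
  specific correlation values) are covered qualitatively by the
  synthetic regime, not reproduced numerically: the inputs are not
  distributed as files.
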