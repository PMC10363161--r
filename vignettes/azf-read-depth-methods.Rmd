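---
title: "Detecting AZFb/c rearrangements from read depth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting AZFb/c rearrangements from read depth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azfcnv)
```

## The problem and the model

The ampliconic portion of the male-specific Y chromosome is built from
families of large, near-identical repeats (amplicons), most of them arranged
as palindromes. Non-allelic homologous recombination (NAHR) between repeats
of a family produces duplications and deletions (when the repeats lie in the
same orientation) or inversions (when they are inverted), changing the
dosage of spermatogenesis genes such as DAZ, BPY2 and CDY1. Because the
amplicon copies are nearly identical, short-read alignments cannot be
assigned to individual copies — but the *total* read depth over a family is
proportional to how many copies the sampled chromosome carries.

`azfcnv` formalises this as follows. A `RegionModel` declares, for each
amplicon family $f$, its reference copies and reference copy number $R_f$,
a mask track of positions excluded from depth calling, a single-copy
control region, a gene map, and an ordered, oriented reference structure of
amplicon units. For a sample with true copy number $C_f$, per-base depth
over the family's reference copies has expectation
$\lambda \, C_f / R_f$, where $\lambda$ is the haploid coverage, while the
single-copy region has expectation $\lambda$. The normalised family depth

$$d_f \;=\; \frac{\text{masked mean depth over } f}{\text{masked mean depth over the single-copy region}}$$

therefore estimates $C_f / R_f$, and the copy-number call is the integer
$k$ minimising $|d_f - k/R_f|$: decision thresholds sit at the midpoints
$(k + \tfrac12)/R_f$, values below $\tfrac12 R_f^{-1}$ call zero copies.

## Masking

Interspersed repeats and simple sequence repeats attract depth that varies
with genome-wide repeat load rather than amplicon dosage, so they are
subtracted from every analysed interval before averaging (overlapping mask
entries are merged first, as RepeatMasker-style tracks overlap). The DAZ
gene intervals inside the red amplicons are additionally excluded — DAZ is
itself prone to partial CNVs that would contaminate the red-family signal —
via the `exclude_genes_from_depth` list of the model config. Masking is
pure interval arithmetic with the conservation property
$|I \setminus M| + |I \cap M| = |I|$, tested as such.

## Numerical choices in calling

* **Tie-breaking.** An observation exactly on a midpoint rounds *up*
  (toward more copies). Ties have probability zero in continuous data; a
  fixed rule keeps every test deterministic.
* **Cap.** Calls are capped at $4 R_f$ with a warning. The largest pattern
  the algebra produces in practice is a fourfold dosage increase; values
  beyond that almost always mean the normaliser failed (e.g. a female or
  heavily contaminated sample), which is also why a non-positive
  single-copy mean is a hard error rather than an `Inf`.
* **No-calls.** Families with under 1 kb of analysable positions after
  masking are reported as `NA` rather than guessed, and are ignored by the
  sample classifier.
* **Diagnostics.** A per-family z-score (observed family mean minus the
  called expectation, over the Poisson standard error of the mean) is
  emitted for triage only; the method itself reports point calls.

A sample is classified `reference`, `duplication`, `deletion` or `both` by
comparing every family call to its reference count. Note that the
`duplication` class is *exclusive* — a chromosome carrying both a
duplication and a deletion is `both`, which is what makes cohort counts of
the form "15 duplication / 2 deletion / 4 both" add up.

## The EMA confirmation profile

Family means compress each family to one number; to see *where* along the
region dosage changes, the package computes an exponential moving average
of depth over the unmasked positions in genomic order, normalised by the
single-copy mean. The smoothing factor uses the span convention
$\alpha = 2/(N+1)$ with $N = 10\,000$ bp by default, initialised at the
first retained position's depth and evaluated at every base; masked
positions neither update nor emit, so excluded repeats appear as gaps.
`confirm_calls()` then checks that the median normalised EMA per family
sits within a quarter of the inter-call spacing ($0.25/R_f$) of the called
ratio.

The EMA is a lagging estimator: after a dosage step it relaxes toward the
new level with time constant $\approx N/2$ positions, so the median of a
family only reflects its dosage when the window is several times smaller
than the family's copies. With full-scale amplicons (hundreds of kb) the
10 kb default is comfortably inside that regime. The compact packaged
coordinates (13–60 kb copies; see below) are not, so the agreement tests
and the workflow's agreement report use a 2 kb window while still
exporting the 10 kb default profile.

## The NAHR event algebra

Rearranged chromosomes are modelled as transformations of the ordered
oriented unit list:

* **duplication** between two same-orientation units of one family inserts
  a copy of the segment `[a, b)` immediately after it (the tandem outcome
  of inter-sister-chromatid NAHR), preserving orientations;
* **deletion** removes `[a, b)`;
* **inversion** between two opposite-orientation units reverses and flips
  the units strictly between the anchors;
* **micro-duplication** tandem-duplicates a single unit, covering the
  one-or-two-amplicon gains that repeat-pair NAHR cannot produce.

Unit orientations in the packaged reference are chosen so the classical
events are geometrically valid exactly when they should be: b1/b3, b2/b4,
g1/g2, y1/y2, r1/r2 and r3/r4 are direct pairs; b2 and b3 are inverted and
become a direct pair only after the r2/r3 inversion — which is precisely
why the b2/b3 deletion and duplication are observed downstream of that
inversion. Because inserted copies reuse unit ids, gene dosage is obtained
by counting units, and re-applying a named event re-resolves its anchors:
two successive b2/b4 duplications quadruple DAZ/BPY2/CDY1 from 4/3/2 to
16/12/8.

`infer_events()` searches breadth-first from the reference for all
*minimal-length* event sequences whose copy-number vector matches an
observation, deduplicating reached structures by their canonical form (the
ordered tuple of unit id and orientation) and pruning structures beyond 64
units. Two consequences are worth knowing. First, the search may return an
algebraically equivalent alternative to the "textbook" sequence — e.g. the
pattern generated by *r2/r3 inversion + b2/b3 duplication* is equally well
explained by *b2/b3 inversion + r2/r3 duplication*, and a pattern generated
by three events (inversion, duplication, grey micro-duplication) can admit
a two-event explanation (gr/gr duplication + green micro-duplication);
minimality, not narrative, is the search criterion. Second, an empty result
is informative: the observed vector is not reachable by simple NAHR within
the depth limit, which is how the extra-grey "complex / non-NAHR" pattern
is reported.

## Cohort statistics

Carrier incidence, per-group frequency tables (ethnic groups, clans) and
distinct-pattern counts are simple, fully deterministic tabulations. The
two-sided Fisher exact test is computed by direct enumeration of the
hypergeometric masses of all tables with the observed margins, summing
those no more probable than the observed table; the "no more probable"
comparison uses a $10^{-7}$ relative tolerance because exact floating-point
equality of hypergeometric masses is fragile. The implementation is
cross-checked in the test suite against both `stats::fisher.test()` and an
independent binomial-coefficient enumeration.

The external comparison cohort (the 1,216-male reference panel) enters as
integer carrier counts in a YAML config. Only percentages are published
for it, so the packaged counts (195/95/84 of 1,216) are the closest integer
reconstruction; the comparison p-values the workflow prints
(0.053 / 0.005 / 0.116) are consequently indicative outputs of a documented
utility, not asserted results.

## The synthetic-data generator

`simulate_depth()` draws per-position depth independently as
$\text{Poisson}(\lambda C_f/R_f)$ (or negative-binomial with dispersion
parameter `size` for overdispersed data; the default dispersion of 1000 is
near-Poisson) over every unmasked model position, with
$\lambda = 30$ by default, matching the >30× whole-genome coverage of the
study design. Masked positions are omitted from tracks, as `samtools depth`
omits zero-coverage positions; an emit-zero mode exists for testing.
Per-sample seeds derive deterministically from the cohort seed and the
sample id, so any subset of a cohort reproduces identically.

What the generator emulates: the mean structure of multi-copy pile-up
depth, its Poisson sampling noise, masking, and cohort composition with
known truth. What it does not emulate: GC and mappability bias, correlated
noise from read length and insert-size structure, partial-amplicon
breakpoints, or multi-mapping ambiguity beyond the $C/R$ mean scaling.
Passing recovery tests therefore demonstrate the estimator's correctness
and its noise margins under the assumed model, not robustness to alignment
artefacts in real data — for real cohorts the EMA profile and the z-score
diagnostics are the guard rails.

## The packaged fixtures and problem sizes

The coordinate fixture shipped with the package is an explicit synthetic
stand-in (`*_synthetic*` files): chrY-flavoured coordinates with the
published architecture — family counts 4/2/3/4/1/2 plus five two-arm
palindrome families, the unit order and orientations above, DAZ/BPY2/CDY1
placed one per red/green/yellow unit and HSFY one per P4 arm — but compact
interval sizes: 13–60 kb per copy, at least 50 kb of unmasked sequence per
family, and a 900 kb single-copy control set. At 30× the standard error of
a normalised family depth is then below $10^{-3}$, orders of magnitude
inside the tightest decision half-width ($0.125$ for the four-copy
families), so truth recovery is essentially certain while a whole-cohort
simulation stays in the tens of seconds. A physical consequence of the
compact sizes is that rearrangement *spans* (e.g. the ~8 Mb of a double
b2/b4 duplication at true scale) are not reproduced; `structure_span_bp()`
and `event_inserted_bp()` recover them when given a full-scale annotation.

The 87-sample truth cohort (66 reference chromosomes plus 21 carriers
across 8 ethnic groups) is likewise a labelled reconstruction: each
carrier's copy-number vector is the result of applying its described NAHR
event sequence to the reference structure, and the test suite verifies the
fixture against the algebra row by row. One sample encodes a deliberate
tension: the extra-grey carrier is stored as a b1/b3 deletion with one more
grey copy than the deletion predicts — unexplainable by simple NAHR, and
classified as a deletion carrier so the cohort census (21 carriers; 15
duplication / 2 deletion / 4 both; 12 distinct patterns) balances. The
clan-level Y-STR screen (93 genotyped males, 9 clans, one clan with 22/39
DYS385-duplication carriers) ships as a separate synthetic table.

## Limitations

* Breakpoints inside amplicons, inversions (depth-invisible) and partial
  CNVs are out of scope; the unit of inference is the whole amplicon.
* Event inference weights all events equally; it reports minimal
  explanations, not likelihoods, and haplogroup-aware event counting
  (collapsing shared events within a lineage) is left to the analyst.
* The calling model assumes a male sample with usable coverage on the
  single-copy region and no CNV *within* that region.
* Depth simulated independently per base cannot test window-shape effects
  of the EMA; the fragment-level correlation of real data slows EMA
  relaxation further, which only strengthens the window ≪ amplicon-size
  requirement.
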