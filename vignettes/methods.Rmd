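---
title: "Methods: copy-number segmentation, chromothripsis detection and cytogenetic concordance"
author: "karyoshatter"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoshatter)
```

# Scope

`karyoshatter` analyzes clinical array-CGH cohorts of myeloid disorders
(MDS, CMML): it segments probe-level log2 ratios, calls somatic
copy-number aberrations (CNAs), detects chromothripsis as oscillating
copy states on a single chromosome, integrates targeted-sequencing
mutation tables with deletion calls, and measures concordance between
conventional cytogenetics (CC) and array findings. This vignette is the
package's own account of the model, its assumptions, the tunable
parameters, and the design choices that were genuinely open.

# The copy-number model

The array measures, per probe, the log2 ratio of patient to control
signal. We model the underlying biology as a piecewise-constant copy
state per chromosome with states restricted to 1 (deletion), 2 (normal)
and 3 (gain); a segment with copy state $s$ has noiseless level
$\log_2(s/2)$, i.e. $-1$, $0$ or $+0.585$. Homozygous deletions and
high-level amplifications are collapsed into states 1 and 3: the
three-state description is what the chromothripsis criterion and the
calling rules operate on, and clinical aCGH in these disorders is
dominated by single-copy changes. Subclonal fractions are not modeled;
a lesion present in a minority of cells attenuates toward 0 and may drop
below the calling thresholds, which mirrors the array's real detection
limit for small clones.

## Segmentation

Per chromosome, probes are partitioned into contiguous segments by
penalized least-squares changepoint detection: minimize the residual sum
of squares around per-segment means plus a penalty $\beta$ per segment,
subject to each segment containing at least `min_probes` probes. The
optimum is found by an exact $O(n^2)$ dynamic program in compiled code;
results are deterministic, and the test suite checks them against an
independently written exhaustive dynamic program on every profile up to
200 probes.

We chose the exhaustive program over a pruned (PELT-style) search: the
classic pruning inequality is not safe under a minimum-segment-length
constraint, and at the problem sizes arrays produce per chromosome
(hundreds to ~10,000 probes) the exact quadratic program runs in
milliseconds to seconds, so there is nothing to trade away.

**Penalty default** `segmentation_penalty = 0.4` (log2² units). The
penalty must sit between two scales: the spurious RSS reduction from an
optimally placed false breakpoint in pure noise (about
$\sigma^2 \cdot 2\log\log n \approx 0.15$ at the highest noise we target,
$\sigma = 0.15$) and the RSS reduction from a true breakpoint (at least
$\tfrac{m}{2}\Delta^2 \approx 1.7$ for the smallest state difference
$\Delta = 0.415$ with $m = 20$ probes per side). 0.4 sits comfortably
between the two and recovers implanted breakpoints exactly at noise 0
and to within ±2 probes at noise SD 0.1.

**Minimum probes** `min_probes = 5` applies both to segments and to
analyzable chromosomes (smaller chromosomes are skipped with a warning).
Five probes is the conventional floor for trusting a clinical array
call; it also means events spanning fewer than five probes are by
construction unrecoverable, which the synthetic generator respects.

## Calling, filtering, classification

A segment mean at or below `loss_threshold = -0.25` is a loss (state 1),
at or above `gain_threshold = +0.25` a gain (state 3). The thresholds
sit midway between the normal level (0) and the single-copy levels
(−1, +0.585 — half the gain step is ~0.29, so ±0.25 is slightly
generous to gains); both are configurable and inclusive at the boundary
so behaviour at ties is deterministic. Adjacent same-direction calls
merge only when no normal segment lies between them; a partition is
contiguous, so "adjacent" rows are literally abutting.

Germline copy-number variants are flagged by **reciprocal overlap**: a
call is germline when the overlap covers at least
`cnv_overlap_fraction = 0.5` of the call *and* of the catalogued region.
Reciprocal overlap at 50% is the standard CNV-matching rule; requiring
both directions prevents a large somatic deletion from being swallowed
by a small polymorphic region it happens to span. Filtering sets a flag
rather than deleting rows, so it is idempotent and auditable.

Size rules: a CNA is **cryptic** when its size is at most
`cryptic_max = 5e6` bp — at or below 5 Mb, inclusive, the resolution
limit of banded metaphases. A deletion is flagged for sequencing
**follow-up** when it is strictly larger than `followup_min = 1e5` bp
(100 kb) and overlaps a panel gene by at least 1 bp: large enough to be
a confident array finding, on a locus where the remaining allele is
worth sequencing.

# Chromothripsis

A chromosome is chromothriptic when its segmental copy states switch at
least `min_switches = 10` times while using at most `max_states = 3`
distinct states, evaluated strictly per chromosome (switches never pool
across chromosomes). Switches are counted as transitions between
adjacent differing states after run-length encoding — a profile of $k$
segments with alternating states has $k-1$ switches. We deliberately do
*not* require strict two-state alternation: the criterion as used on
copy-number data asks for rapid oscillation among two or three states,
and a 1→3 transition that skips 2 still counts as one change of
segmental copy number. The distinct-state bound is enforced as a hard
condition; `chromothripsis_config(max_states = 2)` gives the stricter
two-state variant.

The whole chromosome is one evaluation unit (not per arm): the
recurrent pattern this package targets spans entire chromosomes, and an
arm-confined criterion is a stricter variant users can emulate by
slicing the segment table.

For chromosomes positive in at least one patient, a gene is *commonly
affected* when in every positive patient it overlaps (≥ 1 bp) a
non-normal segment; the direction is reported as amplified or deleted
only when it is consistent within and across all patients, otherwise
"mixed".

# Mutation integration

Variant records shaped like a published targeted-sequencing summary
(sample, gene, cDNA and protein change, type, VAF %, catalogue id) are
filtered by the scoring rules — intronic variants and known single
nucleotide polymorphisms are not scored — and classified by VAF:
`vaf >= 80` (percent, inclusive) is **homozygous-or-hemizygous**, below
is heterozygous. No numeric cutoff is established usage; 80 was chosen
because any cutoff in roughly (77, 89] reproduces the printed labels of
the bundled published table (93.5/92.5 homozygous vs 46.5/43.5
heterozygous), and 80 is a round, documented default. VAF alone cannot
distinguish homozygosity from hemizygosity (one allele deleted, the
other mutated), so the two are deliberately a single class; the
deletion context is resolved by `biallelic_status()`, which crosses
retained loss calls with retained mutations per gene and patient.

Minimal deleted regions are exact interval intersections across the
supporting deletions at a locus; disjoint deletions yield an explicit
"absent" result, never a zero-length interval, and the result is by
construction contained in every supporting deletion.

# Cytogenetic concordance

The ISCN parser covers the subset of nomenclature needed for
copy-number concordance: clones separated by `/` with `[n]` cell
counts, `del`/`dup` with arm-level band tokens, `+8`-style trisomies,
monosomies, `-Y`, and balanced translocations. Anything well-formed but
unsupported parses to kind "other" with a warning rather than failing a
cohort run; structurally malformed strings are errors naming the
offending token. An abnormality is clonal when seen in ≥ 2 metaphases
(the ISCN clonality convention for structural changes); sub-threshold
clones stay annotated but uncounted.

Matching CC abnormalities to array calls uses **any overlap** (≥ 1 bp)
of the arm- or chromosome-level interval with a same-direction somatic
call. CC banding is coarse — breakpoint assignments are often one band
off — so a reciprocal-overlap rule would punish imprecision rather than
discordance. Balanced translocations and "other" tokens are
*expected-undetectable*: they are copy-neutral or unmappable, and the
three categories (detected / missed / expected-undetectable) always
partition the counted abnormalities.

Complex karyotype is ≥ 3 clonal abnormalities by CC and ≥ 5 copy-number
changes by array; metaphase adequacy bands are ≥ 20, 11–19, ≤ 10, and 0
(non-informative, absence of mitosis). Association between patient
groupings and findings uses Fisher's exact test for categorical
outcomes and the two-sided Wilcoxon rank-sum (or Kruskal-Wallis) test
for continuous ones — the tests a clinical array study of this kind
conventionally reports; degenerate tables are an error, never a
fabricated p-value.

# The synthetic-data generator

`simulate_cohort()` defines the study conditions every recovery test
runs under. It emulates:

* a fully synthetic diploid genome — 22 autosomes from 250 Mb down to
  61 Mb, a 150 Mb X and 60 Mb Y, arm boundary at 40% of each chromosome
  — with probes spaced evenly and allocated to chromosomes
  proportionally to length (largest-remainder rounding; the default
  135,000 probes emulate a whole-genome tiling design and scale down
  freely). No coordinate corresponds to a real assembly, so no real
  genomic number is hard-coded; real chromosome lengths and BED
  annotations can be substituted;
* recurrent aberration classes at configurable per-patient fractions
  (defaults mirror the frequency profile of a ~300-patient MDS/CMML
  cohort: del(5q) most frequent, then del(20q), +8, −Y, del(7q), …,
  plus cryptic deletions at the five panel genes);
* chromothripsis confined to chromosome 13 at prevalence 1.2% with
  11–18 implanted switches, each oscillation segment spanning at least
  `chromothripsis_min_run = 20` probes;
* probe noise as i.i.d. Gaussian on log2 ratios (`noise_sd`, default
  0.1 — the source studies do not state their probe-level noise, so
  this is a free parameter chosen to be realistic for modern oligo
  arrays);
* germline CNV carriers at catalogue regions that are probe-aligned
  (9 consecutive probes plus half-spacing padding) so a carrier's call
  reciprocally overlaps its region at any probe density;
* karyotype strings that encode only events ≥ `cc_visible_min = 10 Mb`
  (or whole-chromosome), written in the supported ISCN subset, with
  metaphase counts drawn from the adequacy mix of a real cohort and
  ~13% non-informative failures emitting no metaphases;
* mutation tables drawn by binomial read sampling at `read_depth`
  (default 500×): chromothripsis patients carry TP53 mutations (two
  heterozygous in one third of carriers, one homozygous otherwise),
  half of cryptic-deletion carriers bear a high-VAF mutation on the
  remaining allele, plus a low background mutation rate;
* sex-aware structure: −Y only implanted in males, female patients
  carry no Y probes; age is drawn around 77 years independent of the
  profile, while the high/low risk group is enriched among patients
  with somatic events so that association tests have signal.

Carrier draws are binomial per patient by default;
`exact_counts = TRUE` switches to stratified construction (exactly
`round(n * fraction)` carriers per class), which reproducibility-focused
scripts use so cohort composition is independent of the seed.

**What it does not emulate** — and hence what passing recovery tests do
*not* demonstrate about real arrays: GC waves and intensity
normalization artifacts, probe-specific response, subclonal mosaicism,
focal homozygous deletions/amplifications, rearrangement breakpoints
within probes, and real DGV-scale CNV density. The generator's truth is
probe-aligned (an event is recorded as the span of the probes it
covers), which is the finest resolution any array analysis could
recover; recovery is therefore judged in probe space, exactly as an
array comparison should be.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (BED-compatible);
  reports use 1-based inclusive positions (ISCN convention).
* Thresholds are inclusive (≤ / ≥) everywhere, so ties are
  deterministic; the cryptic bound is inclusive at 5 Mb, the follow-up
  bound strict at 100 kb — both as printed in the rules they implement.
* The segmentation DP breaks cost ties toward the earlier previous
  changepoint; with continuous noise, exact ties have measure zero.
* Chromosomes with fewer than `min_probes` probes are skipped with a
  warning; empty chromosomes yield empty state sequences and zero
  switches; an empty ISCN string is a non-informative karyotype, not an
  error; disjoint MDR inputs yield an "absent" result.
* Pipelines abort with the stage name and offending record (e.g. the
  missing probe file's patient id); no patient is silently dropped.

# Problem sizes

The shipped tests and the acceptance script run, by choice, at reduced
but structure-preserving scale: cohorts of 8–100 patients at
6,000–24,000 probes genome-wide (spacing ~150 kb at 24,000, so a
cryptic deletion spans 7–12 probes), oracle comparisons on 50 random
profiles of up to 200 probes, and binomial-recovery checks at depth
500×. The defaults of `sim_config()` remain at full study scale
(135,000 probes, 1.2% chromothripsis prevalence); nothing in the
implementation depends on the reduced sizes.

# Known limitations

* Only integer states 1/2/3 are modeled; allele-specific copy number,
  copy-neutral LOH and subclonal fraction estimation are out of scope.
* The ISCN grammar is a deliberate subset; full ISCN 2013 parsing is
  not attempted.
* The chromothripsis criterion is a copy-number heuristic; it does not
  reconstruct rearrangement graphs or infer the one-step catastrophic
  origin, and array data cannot distinguish chromothripsis from
  stepwise accumulation of the same profile.
* The vendor segmentation used by the original array studies is not
  recoverable; only the downstream rules are anchored to published
  values, and the segmentation here is a documented, oracle-checked
  replacement.
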