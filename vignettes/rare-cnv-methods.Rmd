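---
title: "Rare-CNV discovery and candidate-gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-CNV discovery and candidate-gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htxcnv)
```

## The problem

Heterotaxy (Htx) is a congenital failure to establish normal left–right
body asymmetry, almost always accompanied by complex congenital heart
disease. Known laterality genes (*ZIC3*, *NODAL*, *CFC1*, …) explain only a
minority of cases, so a standard discovery strategy is: genotype a patient
cohort on a high-density SNP/CN microarray, call copy-number variants
(CNVs), discard everything that looks like common population variation,
classify what remains by its impact on genes, and prioritize genes with a
plausible left–right mechanism — ciliary function, laterality signaling
pathways (Notch, Nodal, Hedgehog, Wnt, TGF-β), or E3 ubiquitin-ligase
activity, all of which act upstream of the left-specific *nodal/pitx2/lefty*
cascade. Candidates are then screened functionally in zebrafish, where
heart-tube looping direction (d-loop / s-loop / no-loop) and the sidedness
of *pitx2* / *lefty2* expression (left / right / bilateral / absent) are
scored as categorical phenotypes and compared between morphant and control
groups with 2×2 contingency tests.

This package implements the desk half of that strategy as a reusable,
tested pipeline: interval algebra and rarity filtering, genic-impact
classification, gene-set prioritization, rare-variant exome filtering, the
contingency statistics, and seeded simulators that generate every input
with ground-truth labels.

## Coordinate and length conventions

Calls are stored with the coordinates their upstream report prints (hg19
positions), and segment length is defined as `end − start`, with no `+1`.
This choice is empirical: it reproduces all nineteen printed segment sizes
of the bundled patient fixture exactly to three decimals (e.g.
145,927,662 − 145,625,128 = 302,534 bp = "302.534" kbp). Whether the
upstream coordinates are 1-based inclusive (which would make the true
length `end − start + 1`) is unknowable from the printed record; we match
the printed arithmetic rather than assert a convention. Everything
downstream is kept consistent with it: intervals behave as half-open
`[start, end)`, marker counting includes probes with
`start ≤ p < end`, overlap of `[100,200)` with itself is 100, and the GFF3
reader shifts 1-based-inclusive ends by +1 at parse time so a 100-bp exon
has `length_bp` 100. BED export shifts both coordinates down by one, which
preserves lengths under BED's 0-based half-open convention.

The interval algebra (pairwise overlap, union coverage, reciprocal
overlap) is implemented directly in vectorised base R rather than through
`IRanges`, because `IRanges` is 1-based inclusive and every boundary would
need a shim; the operations are a few lines each. The test suite checks
them against per-base brute-force oracles at small coordinates and against
`IRanges`-based re-implementations at genome scale, so the two routes stay
independent.

## The rarity filter

A call is **rare** iff all four criteria hold:

1. size strictly greater than 50 kb (`length_kb > 50`; exactly 50.000 kb
   fails);
2. at least 25 markers (`≥ 25`). The published wording is "more than 25" in
   one place and "at least 25 contiguous markers" in another; we resolve
   toward the latter and expose `min_markers` as a parameter. A call's own
   `n_markers` annotation (the upstream ChAS-style value) takes precedence;
   a marker grid is consulted only when the annotation is missing, and a
   call with neither is an error rather than a silent pass;
3. not common against the population database. The published criterion is a
   disjunction of ways to be *rare* (frequency < 1‰, or < 50% overlap with
   published common CNVs, or absent from the database); the only reading
   consistent with all three clauses is the conjunction of their negations:
   a call is **common** iff ≥ 50% of its length is covered by the union of
   same-dosage records whose carrier frequency is ≥ 1‰. Ties at exactly 50%
   coverage count as common. Coverage is of the query by the record union
   (not reciprocal, not single-best-record) — the variant that matches the
   "< 50% overlap" phrasing most directly;
4. not identified in any control cohort. "Identified" is operationalised as
   the field's standard CNV-equivalence rule: same dosage and ≥ 50%
   reciprocal overlap (both directions). A query nested inside a 10×-larger
   control call is therefore *not* matched.

Every decision carries the full set of violated-criterion reason codes, so
the filter is auditable and each criterion is individually testable. The
filter is monotone: raising either threshold, or enlarging the database or
the cohorts, can only shrink the rare set.

Database frequencies are treated as **carrier** frequencies (fraction of
individuals carrying the CNV), matching the "present at < 1‰ frequency"
phrasing; the simulator records this choice (`freq_is_carrier`) but the
filter itself only compares the number against the threshold, so an
allele-frequency database can be used by adjusting `max_common_frequency`.

## Genic-impact classes

Non-diploid calls are classified totally and exclusively:

* **genic_del** — a loss overlapping ≥ 1 coding exon of any gene;
* **genic_dup** — a gain fully containing ≥ 1 gene;
* **internal_dup** — a gain overlapping ≥ 1 coding exon but containing no
  whole gene;
* **noncoding** — everything else (intronic or intergenic events).

"Fully containing a gene" is tested against the gene *span* (transcription
unit), not the coding exons, because the published full-duplication rows
include non-coding RNAs with no CDS at all. When a gain contains one gene
and clips a neighbour, full-gene duplication takes precedence over internal
duplication — forced by the published labels of boundary-crossing segments.
The "genes altered" list uses span overlap (a call clipping only an intron
still lists that gene), reported left-to-right by start coordinate; strand
is carried but ignored, since dosage is strand-agnostic.

## Candidate prioritization

Curated gene sets are configuration, not discovered knowledge: they ship as
editable TSVs encoding exactly the mechanism memberships asserted in the
literature for the bundled cohort (cilia: *PACRG*, *TCTN2*, *DNAH10*,
*TTC40*; Notch: *NUMB*; E3 ligase: *RNF115*), a 14-gene known-heterotaxy
screen list, and a symbol-alias table (*CFAP46* → *TTC40*). The criteria
are a union: any gene inside a rare CNV belonging to ≥ 1 set becomes a
candidate, with all matching tags recorded. Symbols are uppercased and
alias-mapped before comparison. Output order is deterministic (patient,
position, symbol), so permuting the input rows cannot change a report.

## Exome variant filter

Survivors of the five-criterion filter must be exonic/splicing, not
synonymous, rarer than 0.1% in *both* public databases, absent from both
in-house comparison sets, and flagged deleterious by ≥ 1 predictor. Two
conventions needed fixing: "lower than 0.1%" is a strict `<` applied to
each database independently, and a variant *absent* from a database is
treated as satisfying rarity (the conventional reading; a
`missing_freq_is_rare` flag turns it off). Predictor calls are input
annotations — this package does not re-implement SIFT/PolyPhen-class
scoring — and zygosity is carried for reporting but is not a criterion,
matching the published criteria list.

## Contingency statistics

Group comparisons collapse a phenotype table to 2×2
(abnormal = everything except the scheme's first, normal, category;
replicates pooled by summation — the published analysis does not say
whether replicates were pooled or tested separately, and pooling is the
default with per-replicate tables still constructible from the long-format
files). The test is chosen by the standard rule — Fisher's exact test when
any expected cell is below 5, otherwise the Yates continuity-corrected
chi-squared — since the source states both tests without a selection rule.
Fisher's two-sided p uses the point-probability method (sum of
hypergeometric point probabilities ≤ the observed one, with the customary
1 + 1e-7 tie tolerance); the Yates statistic is
\(N(|ad-bc| - N/2)^2 / (r_1 r_2 c_1 c_2)\), floored at zero. Stars follow
0.05 / 0.01 / 0.001. No multiple-testing correction is applied by default
because the source applies none. Cohort percentages round half-up to one
decimal, the convention that reproduces every printed clinical-table
percentage (e.g. 40/63 → 63.5%).

## The synthetic world

The generators state a fixed world rather than exposing dials to tune
tests: two 10-Mb chromosomes; probe positions with exponential 1-kb mean
gaps (≈ 20,000 probes — a scaled-down stand-in for the 2.6M-probe array;
1 kb spacing is needed so a 45-kb undersized decoy still clears the
25-marker criterion and violates exactly one rule); a probe-free zone on
chromosome 1 housing the under-markered decoy; 60 non-overlapping genes
with 2–20 coding exons; 20 common-CNV records at carrier frequencies
0.5–5%, each mirrored into one carrier sample; three spike-in rare CNVs of
250–400 kb; and one decoy per criterion, each violating exactly that
criterion so reason codes are individually checkable. Phenotype simulations
use 3 replicates × 80 embryos per group (the "> 70 embryos, three
repeats" design) with control abnormality ≈ 2% and morphant abnormality
≈ 25%, the magnitudes reported for the negative control and the strongest
morphants.

What the simulator does **not** emulate: probe-level intensity noise and
segmentation artefacts (call boundaries are exact), overlapping or nested
gene structure, linkage between database frequency and call frequency in
the cohort, and read-level exome data. A green spike-in-recovery test
therefore establishes that the *filter logic* is correct on unambiguous
inputs, not that the pipeline is robust to noisy breakpoints.

## Numerical and degenerate-input choices

Zero-length intervals have length 0 but an undefined coverage fraction
(error). Diploid copy number is rejected at construction — a "call" must be
a gain or a loss. An all-zero 2×2 table is an error for Fisher; a zero
margin is an error for the chi-squared. Fisher enumeration is exact (no
normal approximation) and is tested to 1e-12 against a `choose()`-based
enumerator for N ≤ 40. Thousands separators are tolerated when reading
coordinates but never written. The carrier-rate denominator (59 arrayed of
63 recruited subjects) is a configuration value: it is an upstream QC fact
the pipeline cannot recompute from a call table.

## Known limitations

* Sex chromosomes get no special ploidy handling; dosage is relative to the
  autosomal diploid state.
* Single-transcript gene models only; isoform-level impact is out of scope.
* The rarity filter's overlap semantics ("query coverage by the record
  union") is one of several defensible readings of "< 50% overlap"; the
  alternatives (reciprocal, single best record) are not implemented.
* The bundled marker counts for the published records are synthetic
  stand-ins at the array's ~1 kb mean spacing — the source does not print
  per-segment marker counts.
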