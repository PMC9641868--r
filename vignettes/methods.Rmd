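---
title: "Models and methods behind psgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind psgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`psgtools` reimplements, as plain R over coordinates and counts, the
computations a comparative study of pseudogene biology performs: origin
dating on a species ladder, expression-specificity indices, detection of
developmentally dynamic pseudogenes (DDPs), chromosomal traffic tests,
promoter/regulatory overlap metrics, and cancer-type-specificity labels.
This vignette records the models, the tunable parameters, the numerical
conventions, and the choices made where the design was genuinely open.

## Coordinates and interval algebra

All internal coordinates are 0-based half-open; GFF3 (1-based closed) is
converted at the boundary in both directions. This keeps every piece of
interval arithmetic — lengths, unions, promoter windows — in a single
convention. Interval unions, coverages and overlaps are delegated to
Bioconductor `IRanges`; the test suite verifies every exported interval
operation against a per-base boolean-array oracle on chromosomes up to
100 kb.

Two conventions deserve explicit mention:

* **TSS.** The transcription start site is "the starting coordinate of the
  first exon". For minus-strand genes that phrase is ambiguous; the
  default `tss_mode = "stranded"` reads it in transcript orientation
  (largest exon end), which is the biologically standard reading, while
  `tss_mode = "naive_start"` reproduces the literal smallest-start
  reading. Neither is asserted to be what any particular study did.
* **Promoter overlap.** Promoters are 2 kb upstream to 1 kb downstream of
  the TSS (3000 bp, clipped at chromosome edges, always containing the
  TSS). A promoter counts as annotated by a chromHMM state when the
  overlap is *more than* 1 bp, i.e. `min_overlap_bp = 2` for chromHMM;
  every other overlap call defaults to `min_overlap_bp = 1`.

## Origin dating

The phylogeny is restricted to a *ladder*: successive outgroups of the
focal species with strictly decreasing TimeTree-style divergence times.
Non-ladder trees are rejected. Consecutive divergence times bound the
branches; the open-ended oldest branch is capped at `root_cap`
(default 1.5 x the oldest divergence time — a cap must exist for a
midpoint age to exist, and 1.5x keeps the implied age inside the range a
deeper outgroup table would give).

Presence evidence is per exon and per species: the union of that species'
*reciprocal-best* alignment blocks must cover at least `min_cov` of the
exon (default 0.5; no published threshold exists, and 0.5 tolerates
partial alignment while rejecting spurious micro-hits). Non-reciprocal
blocks are always ignored — the generator plants such decoys to keep this
honest.

Branch assignment is Dollo parsimony: a pseudogene locus arises once and
can only be lost. The exon therefore originates on the branch immediately
older than the most distant species showing presence; absence in a
species younger than that is counted as loss or alignment failure, never
as independent gain. An exon absent everywhere is focal-lineage specific
(youngest branch). The gene takes the most ancient branch among its
exons, and its age is the branch midpoint in myr. Before any of this,
pseudogenes on chrY (transposon-saturated) and pseudogenes with more than
70% (strict) of their merged exonic bases covered by repeats are
excluded.

## Expression specificity

FPKM and CPM are the only normalizations:
`FPKM = count / (length/1e3) / (libsize/1e6)`, `CPM = count /
(libsize/1e6)`, with gene length the merged exonic length and library
size the per-sample total of counted uniquely mapped reads (supplied in
the metadata; recomputed as the column sum only when absent). The
specificity index over `n >= 2` conditions is
`tau = sum(1 - x_i/max(x)) / (n - 1)`, reported over per-tissue means
(replicates, sexes and stages pooled) and, within each tissue, over
per-stage means. Means are the default aggregation because no published
choice exists; `aggregate = "median"` is available. An all-zero vector
has no defined specificity and yields `NA` with a warning. "Expressed"
defaults to FPKM >= 1 in at least one sample, and every report states its
cutoff; ties in the maximum-expression tissue resolve lexicographically
and are flagged.

## DDP calling

Per gene and tissue, expression is regressed by OLS on
`{1, ln t, (ln t)^2, (ln t)^3}` of time after conception (days), and
`R^2 = 1 - SS_res/SS_tot` with a constant response defined as `R^2 = 0`.
A gene is dynamic in a tissue iff `R^2 > 0.3` strictly, and a DDP iff
dynamic in at least one tissue. This deliberately reimplements only the
stated computation — polynomial-in-log-time goodness of fit with a fixed
threshold — not the full maSigPro stepwise-significance machinery.

Open choices, and how they were settled:

* **Response scale.** Whether the time-course fit used raw or logged CPM
  is not stated. The default is `log1p(CPM)`, which stabilizes
  negative-binomial variance; `response = "raw"` is available and both
  modes are tested. Under `raw`, calls are exactly invariant to scaling
  all samples by a common constant; under `log1p` that invariance is only
  approximate.
* **Replicates** enter as separate observations at the same time value
  (preserving error degrees of freedom), never averaged.
* The null distribution of R^2 with 3 predictors has mean `3/(n-1)`;
  `null_r2_reference()` simulates it (the null law does not depend on the
  actual time values) and calibrates the 0.3 threshold.

DDPs whose profile correlates with their parent coding gene at signed
Pearson `R >= 0.6` (inclusive) are excluded as potential mis-mapping; a
missing parent leaves the gene retained with `R` missing. The
co-expression network scores all pseudogene x coding pairs by Pearson R
with the exact t-transform p (df = n-2), keeps `|R| > 0.90 & p < 0.01`
with no multiple-testing correction (matching the raw-threshold rule),
and drops testis samples first because of testis's disproportionate
expression; zero-variance genes are skipped with a recorded reason.

## Traffic, Fisher's exact test, rank tests

Under the proportional null models, a chromosome generates pseudogenes in
proportion to its protein-coding gene count and receives insertions in
proportion to its length. The 2x2 X-versus-autosome test is Fisher's
exact test implemented in-package: two-sided p by summing hypergeometric
probabilities not exceeding the observed one (relative tie tolerance
1e-7), odds ratio by conditional MLE under the noncentral hypergeometric
likelihood (solving `E_psi[A] = a` by root-finding); a zero margin gives
p = 1 with the odds ratio flagged undefined. `stats::fisher.test` serves
only as an independent cross-check in the tests.

Group comparisons of regulatory metrics use a two-sided Wilcoxon
rank-sum test, exact by complete enumeration of assignments (tie-safe)
for total n <= 20 and a tie-corrected normal approximation above; this
split exists because the stock implementation silently abandons exactness
under ties. All-tied data give p = 1 with a warning.

## Cancer-type specificity and translation

Per-gene shares are per-type mean expression over tumor samples divided
by the sum across types (the summary statistic is not published; means
are the default). Type-specific: focal share > 15% and every other share
< 5%, strictly. Ubiquitous: maximum share < 30% and each of the top-5
shares > 5%, strictly. The source phrasing of the 30% rule is garbled
("more than less than 30%"); reading it as a *maximum-share upper bound*
is the only one consistent with "ubiquitous", and the bound is a
parameter. Types are retained for differential analyses only with more
than 5 tumor *and* more than 5 normal samples (strict). A translated
candidate needs both external coding-potential flags, maximum Ribo-seq
FPKM >= 1 (inclusive — the boundary form used where the rule is stated
with the ORF condition) and at least one active ORF.

## The synthetic world

`generate_scenario()` draws every input the pipeline consumes and records
the truth. Its defaults are the stated world and were fixed before any
acceptance measurement:

| parameter | default | why |
|---|---|---|
| species ladder | 8 outgroups, 6–435 myr | primate-to-fish span of the real ladder |
| genome | 4 autosomes + X + Y, 1–3 Mb | desk-scale, room for ~700 genes |
| pseudogenes / coding | 500 / 200 | minutes-scale end-to-end runs |
| biotype mix | 72/23/3/2% proc/unproc/unitary/polymorphic | processed dominance seen in mammals |
| planted chrY / repeat-heavy | 2% / 5% | exercises both filters, ~93% retained |
| NB dispersion alpha | 0.1 | bulk-RNA-seq-typical (var = mu + alpha mu^2) |
| baseline log-mean (sd) | 4 (1) | median ~55 counts, low-expression tail |
| design | 5 tissues x 8 stages x 2 sexes x 2 reps | organogenesis-to-adult shape |
| dynamic fraction, amplitude | 0.3, 2.0 log-units | ~7-fold planted dynamic range |
| tissue-specific fraction | 0.2, off-tissue x0.02 | one-hot-like profiles for tau |
| testis factor | 5x on 25% of pseudogenes | qualitative testis dominance |
| TF enrichment at DDP promoters | 2x | detectable but not trivial |
| promoter SNP factor | 3x | promoter > transcript rate, plantable |
| cancer | 33 types, 20 specific + 20 ubiquitous planted | share rules exercised directly |

Planted dynamic genes get their baseline floored at log-mean 3 (~20
counts): a trend in an unexpressed gene is unobservable by construction,
so planting one would measure the generator, not the caller. Dynamic
tissues for a tissue-specific gene are restricted to its home tissue for
the same reason. Orthology maps are logically consistent by
construction: presence dropout (default 0) removes evidence but never
adds it, so inference can under-age but never over-age a gene.

What the generator does *not* emulate: mappability structure and shared
repeats (presence calls are clean coverage, not alignment artifacts),
GC/length biases in counts, batch effects, correlated dropout across
species, sex-specific expression, tumor heterogeneity. A green test
therefore establishes algorithmic correctness against planted truth, not
robustness to every real-data pathology.

Two interpretation notes, recorded here deliberately. First, branch
recovery is measured over *dated* pseudogenes: the default world plants
chrY and repeat-heavy exclusions, so of 500 pseudogenes ~465 are datable,
and at zero dropout all of them land on their planted branch. Second, the
DDP power properties (sensitivity >= 0.95, specificity >= 0.90) are
evaluated at the (gene, tissue) call level, the level at which the
`R^2 > 0.3 in a tissue` rule operates.

## Numerical conventions and degenerate inputs

* Constant response in a trend fit: R^2 = 0; degenerate designs (fewer
  distinct times than degree + 2) are an error naming the tissue.
* All decision thresholds follow the stated strictness exactly: repeat
  coverage > 0.70 excludes; R^2 > 0.3, cancer 15%/5%/30%/5% and sample
  retention > 5 are strict; parent R >= 0.6 and Ribo-seq FPKM >= 1 are
  inclusive.
* Intergenic shuffling samples non-overlapping windows from a free-list
  of gaps (complement of full gene spans); capacity is checked up front
  and exhaustion names the shortfall. Seeded runs are byte-identical;
  all seeding is scoped (the caller's RNG state is restored).
* The tie-break for the maximum-expression tissue is lexicographic and
  flagged, so downstream tabulations are deterministic.

## Limitations

The dating module consumes alignment blocks; it neither computes
alignments nor implements Ks-based or retrotransposon-based dating. The
expression boundary is the count matrix (no read processing), coding
potential is consumed as external predictor flags, and differential
expression is out of scope. The ubiquitous-share rule is permissive on
diffusely expressed genes: background genes with mild share spread can
qualify, which is a property of the stated rule, not of the
implementation.
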