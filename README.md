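# psgtools

Pseudogenes — degraded copies of protein-coding genes — are dated, scored
and classified here the way comparative transcriptomics studies of human
and mouse do it: from genome coordinates, alignment evidence and read
counts, never from sequence. `psgtools` is aimed at researchers who want
the bespoke computations of such studies as tested, reusable R functions,
plus a synthetic-data generator with recorded ground truth so every stage
can be validated offline.

## What it computes

**Origin dating.** The phylogeny is a ladder of successive outgroups of
the focal species with TimeTree-style divergence times. Each pseudogene
exon is called present in a species when reciprocal-best whole-genome
alignment blocks cover at least `min_cov` (default 0.5) of it. Under Dollo
parsimony (single origin, any number of losses) the exon originates on the
branch just older than its most distant presence; the gene takes its most
ancient exon's branch, and its age is the branch midpoint
(t_old + t_young)/2 in myr. Before dating, pseudogenes on chrY and those
with > 70% of merged exonic bases covered by repeats are excluded.

**Expression specificity.** With x_i the expression of a gene in condition
i (FPKM over tissues, or over stages within a tissue) and
y_i = x_i / max(x):

    tau = sum(1 - y_i) / (n - 1)

so tau = 0 is uniform expression and tau = 1 is single-condition
expression.

**Developmentally dynamic pseudogenes (DDPs).** Per tissue, CPM
(log1p-transformed by default) is regressed on
{1, ln t, (ln t)^2, (ln t)^3} of time after conception; a gene with
R^2 > 0.3 in a tissue is dynamic there, and a DDP if dynamic anywhere.
DDPs whose expression tracks their parent coding gene (Pearson R >= 0.6)
are excluded as potential mis-mapping. The pseudogene–coding co-expression
network keeps pairs with |R| > 0.90 and p < 0.01 (exact t-transform,
df = n − 2), with testis samples dropped first.

**Traffic, regulation, cancer.** Chromosomal traffic compares observed
X-versus-autosome pseudogene counts with proportional null expectations
via Fisher's exact test (p by hypergeometric tail summation, odds ratio by
conditional MLE). Promoters (2 kb up / 1 kb down of the strand-aware TSS)
are profiled for TF diversity, chromHMM states (> 1 bp rule), SNP density
and m6A distances against shuffled intergenic 3-kb controls. Cancer genes
are type-specific when one cancer type holds > 15% of the summed per-type
expression and every other type < 5%; ubiquitous when the maximum share is
< 30% and each top-5 share is > 5%. Translated candidates need both
coding-potential predictor flags, Ribo-seq FPKM >= 1 and >= 1 ORF.

## Worked example

```r
library(psgtools)

# simulate a small world with known truth, then run the pipeline on it
sc <- generate_scenario(scenario_config(), out_dir = tempdir(), seed = 1)

ages <- date_pseudogenes(sc$annotations, sc$maps, sc$branches, sc$repeats)
table(ages$status)
#>           dated   excluded_chrY excluded_repeat
#>             465              10              25
head(subset(as.data.frame(ages), status == "dated"), 3)
#>   gene_id status      branch_id age_myr t_young t_old
#> 1  PG0001  dated      pre_mouse   125.0      90   160
#> 2  PG0002  dated pre_chimpanzee    17.5       6    29
#> 3  PG0003  dated pre_chimpanzee    17.5       6    29

fpkm <- normalize_expression(sc$tensor, "FPKM")
cpm  <- normalize_expression(sc$tensor, "CPM")
spec <- tissue_and_stage_specificity(fpkm, sc$tensor$meta)
summary(spec$tissue_tau)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.1163  0.1691  0.2084  0.3647  0.6038  0.9945

calls <- call_ddps(fit_trends(cpm[sc$truth$pseudogenes$gene_id, ],
                              sc$tensor$meta))
attr(calls, "counts")
#>      brain cerebellum      heart      liver     testis  total_ddp
#>         82         79         93         83        103        196

tt <- traffic_test(matrix(c(60, 25, 440, 175), 2))
tt
#> Fisher's exact test (2x2)
#>   p = 0.8982  odds ratio = 0.9546
```

Of the 500 simulated pseudogenes, 10 sit on chrY and 25 are repeat-heavy
(planted), leaving 465 dated — every one on its planted branch at zero
dropout. The tau distribution mixes broad genes (planted baseline) with
the planted tissue-specific quarter near 1. The 196 DDP calls recover the
planted dynamic fraction; the 2x2 example shows no X enrichment in this
neutral world.

A command-line generator is included:

```sh
Rscript inst/scripts/simulate.R --config scenario.yaml --out dir --seed 3
```

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the
default scenario — generation, dating, specificity, DDP calling and
filtering, co-expression, traffic, regulatory profiling, cancer
classification — logging summary numbers as it goes, and writes its JSON
report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/methods.Rmd` documents the model and its assumptions, every
tunable threshold with its default and rationale, what the generator does
and does not emulate, and known limitations.
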