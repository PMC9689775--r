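---
title: "Methods: linking TE insertions to caste-biased expression"
author: "casteTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking TE insertions to caste-biased expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casteTE)
```

# Scope and model

`casteTE` implements an integrative comparative pipeline for Blattodea
(termites and cockroaches) asking whether transposable elements (TEs)
insert preferentially into genes whose expression is biased toward one
caste (termite queens vs. workers) or life stage (cockroach adult
females vs. nymphs), and whether the functions of TE-rich biased genes
differ between eusocial and gregarious species. The pipeline consumes
standard files — gene models (GFF3), per-tool TE calls and mapped TE
copies (BED6+2), copy/consensus alignments (TSV), RNA-seq count tables,
gene-to-GO maps with a DAG edge list, a species tree (newick) and a
trait table — and every input can be produced by the synthetic-data
module with planted ground truth, so each stage is testable end to end
without external downloads.

# Stage by stage

## TE library consolidation

De novo TE annotation panels over-report: the same element is called by
several tools with slightly different boundaries. `dedup_calls()`
removes calls longer than 10 kb (a conservative artifact guard), then
greedily sweeps calls in priority order — longer first, ties broken by
earlier start and then tool name — and drops any call overlapping an
already-kept call on the same chromosome and strand by more than 20% of
the shorter length. Two genuinely open conventions are fixed here and
exposed as arguments: the overlap fraction is measured against the
*shorter* interval (symmetric, and conservative toward removing nested
duplicates), and opposite-strand overlaps never conflict (strand is
part of an element's identity). Both choices are configurable because
neither is forced by the biology.

Mapped copies (`filter_mapped()`) follow different rules: copies with a
mapping score not greater than 1 are low-quality noise, and within any
chain of location-overlapping copies — strand-agnostic, since mapped
copies compete for the same genomic space — only the highest-scoring
member survives (ties keep the earlier start). Both filters are
idempotent and order-invariant, and the test suite holds them against
exhaustive pairwise oracles on random instances.

## Divergence landscapes

TE copy age is proxied by Kimura 2-parameter distance to the consensus:
$K = -\tfrac12\ln\big((1-2p-q)\sqrt{1-2q}\big)$ with transition
proportion $p$ and transversion proportion $q$ counted over ungapped,
unambiguous columns. CpG dinucleotides are hypermutable, which inflates
apparent age; with `cpg_correct = TRUE` a transition at a consensus CpG
position (the C and the G it precedes) contributes weight 1/10 to the
transition count — the convention of the widely used RepeatMasker
divergence script. The weight is an argument because other defensible
conventions exist (e.g. counting a CpG double transition as one event).
`build_landscape()` bins each copy's length by $100K$ (1% bins over
[0, 55%] by default, both configurable) and reports percent of genome
per bin per superfamily, the classical repeat landscape.

The generator `evolve_te_copies()` draws site outcomes from the exact
K2P transition probabilities at the site's scaled divergence, with the
CpG transition rate multiplied by `cpg_mult` and the overall rate
calibrated so the expected divergence equals `k_true`. With
`cpg_mult = 1` the estimator is consistent for `k_true`, which is the
recovery property the tests assert (mean estimate within three standard
errors at `k_true` of 0.05, 0.10 and 0.20 with 200 copies of 2 kb). The
generator refuses `k_true` so large that the K2P formula would operate
at the edge of saturation.

## Expression-bias classification

A gene is biased when its BH-adjusted p-value is strictly below 0.05;
the sign of the log2 fold change sets the direction. The package fixes
the fold-change orientation as queen/adult-female over worker/nymph and
documents it, since conventions differ between pipelines. Genes without
an adjusted p-value are `untested` and are discarded by every
downstream stage. Fold-change subsets ("at least 2-fold") are
`|log2fc| >= 1` on the supplied fold-change field, with the threshold
configurable; summary percentages divide by the total number of
differentially expressed genes and are reported raw alongside a
2-significant-figure printed form, which is the precision such tables
conventionally print.

`de_lite()` is deliberately a *stand-in*, not a negative-binomial DE
engine: median-of-ratios size factors, Welch's t on
`log2(normalized + 1)`, BH adjustment. On real data an external DE
table should be injected; it passes through `classify_bias()`
untouched. On the synthetic conditions the package targets (2000 genes,
10% planted at |log2FC| = 2, six libraries per group, NB dispersion
0.2) the stand-in attains roughly 80% sensitivity with empirical FDR
well under 5% — adequate for exercising the downstream stages, and not
presented as a substitute analysis for real libraries. Merged caste
groups (e.g. major and minor workers) are handled upstream by the
sample sheet mapping multiple labels onto one group.

## TE–gene overlap profiling

`closest_te()` mirrors the bedtools-closest convention restricted to
the gene's DNA strand: distance 0 if and only if the TE overlaps the
gene span, otherwise 1 + the separating bases; ties resolve by lower TE
start, then identifier. A TE is "within" a gene when it overlaps the
span by at least 1 bp on the same strand — the strand requirement
mirrors the closest-TE rule and is configurable, because gene-body
insertion could also be argued strand-agnostic. An insertion
overlapping any exon of its host counts as exonic (boundary-straddling
TEs take exon precedence so every insertion has exactly one category);
a TE spanning two genes is counted in both profiles. Insertion rate is
TEs per gene kilobase, and a gene is TE-rich when its rate strictly
exceeds the third quartile of the evaluation subset (type-7 linear
interpolation; both the quantile convention and the subset scope —
per-analysis by default, global optionally — are arguments).
`build_tables()` emits the four factorial count tables (gene-level TE
overlap, exon/intron split, superfamily-level insertions, superfamily
by host bias) as complete zero-filled long-format grids, and
`export_model_tables()` writes them with the conventional numeric
codings (bias 0/1/2, social level 0/1, overlap 0/1) next to the species
tree for external phylogenetic mixed-model fitting.

## GO enrichment with elim pruning and the specificity cascade

Enrichment is score-based: for stage-bias analyses the gene score is
`-log10(padj)`, for TE-rich analyses the insertion rate per kb. Each
term is tested with a one-sided two-sample Kolmogorov–Smirnov statistic
(term genes vs. the rest of the universe; asymptotic p). The `elim`
walk processes terms from most specific (greatest depth, ties in term
order) to the root; when a term's p-value falls below the elim cutoff
(0.01, the algorithm's customary default), its significant genes are
removed from all ancestors before those are tested, so signal localizes
to the most specific responsible terms. With an edge-free ontology or a
cutoff of 0 the procedure reduces exactly to classical per-term
testing, which the tests assert. No multiple-testing correction is
applied across terms by default, matching common practice for
dependency-adjusted DAG walks; BH is available via `bh_adjust()`.

One genuine ambiguity is the neutralization of genes biased toward the
*opposite* stage: "set to 1" can mean a score of 1 or an adjusted
p-value of 1. The package defaults to the p-value reading (score 0
after the log transform), because a literal score of 1 would rank an
opposite-biased gene above every unbiased gene with padj > 0.1, which
inverts the intended ordering; the literal reading remains available
via `opposite = "score_one"` and the choice is recorded in the output.

The specificity cascade then removes a TE-rich DEG term when it is also
significant (p < 0.05) in (1) same-stage DEG enrichment at *both*
social levels, (2) same-stage TE-rich enrichment at the *other* social
level, or (3) TE-rich enrichment of a *different* stage (including
no-bias) at the same social level, recording the first triggering
criterion. Surviving terms are therefore specific to their stage,
social level and high insertion rate.

## Comparative statistics

`pic_contrasts()` implements Felsenstein's pruning algorithm directly
(and is cross-checked in the tests against both a recursive oracle and
the independent `ape::pic()` implementation on every rooted binary
topology with up to five tips). Polytomies are rejected rather than
resolved silently, and zero-length branches are refused because the
standardization divides by branch length. The correlation test on
contrast pairs uses `t = r\sqrt{df/(1-r^2)}` with `df = k - 2` for `k`
contrasts: with six species (five contrasts) this gives df = 3 and with
four species df = 1, matching how such analyses are conventionally
reported; the through-origin alternative (`df = k - 1`) is available
behind a flag.

The factorial count analyses are served by a frequentist Poisson
log-linear stand-in (`loglinear_fit()`, IRLS via `glm` with tolerance
1e-8, at most 100 iterations, initialized at `log(count + 0.5)`) with
likelihood-ratio tests for the interaction terms. This tests the same
factorial hypotheses as a phylogenetic Poisson mixed model but without
phylogenetic random effects; the model-ready exports exist precisely so
that a full Bayesian phylogenetic fit can be run externally.

# The synthetic-data module

`sim_config()` fixes the study conditions. Defaults: a 16 Mb
four-chromosome genome carrying 2000 non-overlapping multi-exon genes;
four TE annotation tools with 30% redundant re-reporting jittered by
10 bp and 5% spurious calls; 40 true insertions per Mb per superfamily
across the four main superfamilies (Tc-Mariner, hAT, Gypsy, LINE); TE
copies at 10% divergence under kappa = 2 with 10-fold CpG acceleration;
six RNA-seq libraries per caste group with log-normal baselines, NB
dispersion 0.2, library size factors in [0.6, 1.5], and 10% of genes
planted at |log2FC| = 2; a 100-term GO DAG of depth 5; and a six-tip
species tree with bivariate Brownian traits at correlation 0.8. The
library counts, effect sizes and planted fraction are the conditions
the pipeline's planted-truth checks are stated under; the genome and
DAG sizes were chosen once as the smallest scales at which every stage
has non-trivial structure (overlapping calls, multi-exon assignment,
deep ancestor chains) while the full suite runs in minutes on one CPU.
Problem sizes used by the checks (200 copies of 2 kb for divergence
recovery, 500 replicates on a 64-tip tree for contrast recovery, 1000
null tables for LRT calibration, 2000 genes for DE truth) are stated in
the corresponding tests and in `scripts/acceptance.R`.

Determinism is a contract: one root seed, per-stage child seeds derived
by fixed offsets, and `simulate_all()` emits byte-identical files for
identical configs. Every planted entity (TE, biased gene, enriched
term, trait correlation) is recorded in a truth table resolvable by
identifier in the emitted files.

What the generator does *not* emulate, and hence what green tests do
not show about real data: realistic sequence composition (the consensus
is i.i.d. with a GC knob; real TEs have motif structure), TE nesting
and fragmentation, per-tool error signatures (all tools share one
jitter/false-positive model), tissue- and pooling-level expression
covariates (only group labels exist), overdispersion heterogeneity
across genes (a single dispersion parameter), and annotation bias in GO
(terms are assigned uniformly apart from planting). Passing
planted-truth tests demonstrates that the machinery recovers known
signal under its stated model, not that real Blattodea data satisfy
that model.

# Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive internally (the GFF3/GRanges
  convention); BED I/O converts to 0-based half-open at the file
  boundary. This avoids fighting the R genomics ecosystem's convention
  and confines off-by-one risk to two well-tested readers/writers.
* `kimura_k2p()` errors on a saturated argument
  (`1 - 2p - q <= 0` or `1 - 2q <= 0`); `alignment_divergence()`
  converts that error into `K = NA` with a `saturated` flag so one
  ancient copy cannot abort a landscape.
* Welch t-tests with zero variance in both groups return p = 1 when the
  means agree and p = 0 otherwise; all-zero genes are untested.
* Ties everywhere resolve deterministically (documented per function),
  so identical inputs give identical outputs regardless of row order.
* Single-gene groups in length summaries return degenerate confidence
  intervals flagged as such rather than NaN arithmetic.
* `ks_term_test()` returns 1 for empty term or background sets (e.g. a
  term annotating the entire universe).

# Known limitations

The DE stand-in has no dispersion shrinkage and loses power at two or
three libraries per group — with real data, inject an external DE
table. The log-linear stand-in ignores phylogenetic covariance, so its
interaction tests are anti-conservative when species are strongly
correlated; treat it as a screening device and fit the exported tables
with a phylogenetic mixed model for inference. The elim implementation
tests terms against the full score universe rather than topGO's exact
internal bookkeeping, so p-values can differ in detail from that
package even though the flat-ontology behaviour is identical by
construction. And the 20%-overlap deduplication rule resolves conflicts
greedily; a maximum-weight independent-set formulation could retain
slightly different call sets in dense clusters.
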