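---
title: "Scoring retroelement-linked enhancer regulation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring retroelement-linked enhancer regulation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscan)
```

# The question and the scores

Retroelements — LINEs, SINEs, LTR elements and SVA composites, together
roughly 40% of human DNA — carry ready-made regulatory sequence. A gene
whose enhancer landscape is dominated by RE-derived elements has, in
effect, had its regulation rewritten by transposition recently and
often; a gene depleted of RE-linked regulation is under purifying
pressure to keep its regulatory complement intact. `retroscan`
quantifies this with the enhancer mark H3K4me1: tags (mapped ChIP-seq
intervals, reads or peak calls alike) in the 10-kb neighborhood of a
gene's reference TSS are split into an RE-linked and an RE-free
compartment, giving per gene and cell line

* GRE — the RE-linked tag count (absolute enrichment), and
* NGRE — the RE-linked fraction of all neighborhood tags (relative
  enrichment), undefined when the gene has no tags at all.

Pathway involvement indices PII and NPII are the member-gene means of
GRE and NGRE over the genes of a pathway that are present in the scored
universe. Whether the pathway aggregate should be a mean or a sum is
not decidable from first principles; the mean is the default because it
makes pathways of different sizes comparable, and a `stat = "sum"`
option is provided.

## Coordinate and counting conventions

All intervals are held 0-based half-open, exactly as in BED;
RepeatMasker `.out` rows (1-based inclusive) are converted on input.
Chromosome names are compared by exact string equality — no `chr`
prefix normalisation — so inputs must share one namespace.

A tag belongs to a neighborhood iff its midpoint,
`floor((start + end)/2)`, lies in the half-open window; it is RE-linked
iff that midpoint lies in the flattened union of the RE intervals.
Membership by midpoint (rather than any-overlap) is a deliberate
choice: it makes the RE/RE-free dichotomy exhaustive and exclusive, so
`re_tags + free_tags = total_tags` holds exactly and a tag straddling
an RE boundary cannot be counted twice. Whether the original
methodology used midpoint or overlap counting is not documented; the
midpoint rule is ours and is stated here because it can shift counts
for tags near RE edges. Flattening REs first means nested or
overlapping repeats (an Alu inside an L1, say) contribute once.

The neighborhood is strand-aware: for a `+` gene
`[tss − upstream, tss + downstream)`, mirrored for `−`, clipped at
zero; defaults are 5 kb on each side. The reference TSS of a
multi-transcript gene is the 5′-most transcript start; pre-collapse the
input table to impose a different rule. REs are filtered to the
retroelement classes (LINE, SINE, LTR, SVA/Retroposon) by default; DNA
transposons move by a cut-and-paste mechanism without an RNA
intermediate and are excluded, though `keep_classes` makes the filter
explicit and overridable.

Genes with zero neighborhood tags get an undefined (NA) NGRE, not
zero: calling a gene "RE-deficient" because it has no signal at all
would conflate absence of data with regulatory depletion. Such genes
are excluded from NGRE-based analyses and their count is reported.

# The trend model

With scores in hand, the estimator of interest is the zero-intercept
least-squares trend of the relative score on the absolute one,
`y = βx`, `β = Σxy/Σx²` — a gene with no RE-linked signal has, by
construction, no RE-linked fraction, so a free intercept would be a
nuisance parameter. `rre_fit()` returns a classed model object with
the usual methods (`coef`, `residuals`, `fitted`, `predict`, `plot`,
`summary`).

Items are ranked by the signed *vertical* residual `y − βx`.
Perpendicular distance was rejected because the model treats the
relative score as a function of the absolute one, and because
perpendicular distances mix the units of the two axes (tags versus
fractions). The top `m` and bottom `m` items are labelled enriched and
deficient, with

```
m = round_half_away(fraction × N),  fraction = 0.05 by default.
```

Rounding half away from zero is the only rule consistent with both
reference set sizes at genome scale: 0.05 × 24,070 = 1,203.5 → 1,204
and 0.05 × 3,095 = 154.75 → 155. The two extremes are taken separately
above and below the line (not as the 10% largest absolute distances
split by sign), and residual ties are broken lexicographically by item
id so the classification is a pure function of its input.

```{r trend-example}
set.seed(1)
d <- data.frame(gene_id = sprintf("g%03d", 1:200),
                gre = rpois(200, 8) + 1)
d$ngre <- pmin(1, 0.05 * d$gre + rnorm(200, sd = 0.05))
fit <- rre_fit(ngre ~ gre, d, fraction = 0.05)
summary(fit)
```

# Representation statistics

## Hypergeometric tails, exactly as defined

For a universe of `M` genes containing `N` of a class, and an extreme
set of `n` genes containing `k`, the probability mass is
`p(k) = C(n,k)·C(M−n,N−k)/C(M,N)` and the directional tails are

* `P(over) = Σ_{i=k+1}^{n} p(i)` — strictly greater than observed;
* `P(under) = Σ_{i=1}^{k} p(i)` — from one up to observed.

Both tails exclude `i = 0`, so `P(over) + P(under) + p(0) = 1`; the
package implements the sums verbatim and tests that identity to 1e−12.
Calls use p < 0.05 in either direction. Evaluation goes through R's
log-space `dhyper`/`phyper`, stable at genome scale; the test suite
validates every small-universe case (M ≤ 12) against an exhaustive
subset-enumeration oracle.

One property deserves emphasis: a rejection rule based on the strictly
greater tail is *not* conservative. It rejects at the smallest `k*`
with `P(X > k*) < α`, so its exact size is `P(X ≥ k*) = P(X > k*−1)`,
which by the minimality of `k*` is at least α. At (M = 500, N = 50,
n = 60, α = 0.05) the exact size is 0.0604, versus 0.0253 for the
conventional `P(X ≥ k)` tail. The strict convention is retained
because it is the definition this package implements and documents;
users wanting a conventional conservative test can evaluate
`over_under_test` at `k − 1`.

## Term enrichment and the EASE variant

Term over-representation for an extreme set uses the one-sided
hypergeometric tail `P(X ≥ k)` per term (`K` universe members, `k`
selected). The `ease` variant evaluates the same tail at `k − 1`,
discounting one supporting gene — the conservative "modified Fisher"
used by annotation servers; it is never smaller than the standard p.
Benjamini–Hochberg FDR across terms is reported alongside the raw
p-values, and the significance cut is applied to raw p by default,
mirroring the annotation-server convention this step replaces. Fold
change is observed/expected and is descriptive only.

## Permutation control

The null being rejected is "extreme sets drawn at random annotate this
well". Gene names are shuffled over the (GRE, NGRE) pairs jointly — the
score multiset is preserved, only the assignment changes — so each of
the B permutations yields extreme sets of exactly the real size. Each
is annotated against the term collection and the `top_terms` smallest
p-values are kept (padded with 1 when fewer terms exist). The per-group
statistic is the minimum term p-value; with `r` permutations at or
below the real minimum, the empirical q-value is `(r+1)/(B+1)` — the
positively biased estimator, so `r = 0` at `B = 500` gives
q = 1/501 ≈ 0.002, never zero. Per-permutation seeds are derived from
the master seed by counter, making runs reproducible and
order-independent. For the distribution comparison, the mode of the
−log10 p histogram is computed on a shared real∪null binning grid
(30 equal-width bins by default — the binning behind such comparisons
is rarely stated, so it is configurable and the default documented),
with ties broken toward the smaller −log10 value.

# The synthetic epigenome

The generator emulates the *shape* of the real inputs — a gene table
with reference TSSs and class labels, an RE track, per-cell-line tag
tracks, pathway/term GMTs — with planted ground truth, at a scale a
desktop can iterate on (defaults: 2,000 genes, 4 chromosomes of 8 Mb,
5 cell lines, Poisson(30) tags per neighborhood, RE density 0.4
matching the genomic RE content, 200 pathways and 200 terms of 20
genes, 5 of each planted).

Genes sit on a jittered per-chromosome grid so neighborhoods never
overlap; a configuration whose neighborhoods cannot fit is rejected up
front. REs tile the neighborhoods as 250-bp units switched on with
probability `re_density` and merged; background REs are scattered
outside neighborhoods only, so the realized coverage where it matters
is controlled (and tested to ±0.05). Tags are fixed-width (150 bp,
read-like) so the midpoint rule is genuinely exercised.

The plant: each background gene draws Poisson(λ) tags, each landing on
an RE with probability p0 = 0.25. A planted gene's tags land on REs
with probability p1 = 0.8, and its total-tag mean is scaled by
`p0/p1`, so its expected GRE equals the background's (λ·p0) while its
NGRE rises to p1. This scaling is the design point worth explaining:
if planted genes instead kept mean λ with per-tag probability p1, both
their GRE and NGRE would rise proportionally and they would slide
*along* the zero-intercept trend (E[NGRE]/E[GRE] = 1/λ for every gene,
whatever p), splitting their amplified residuals symmetrically between
the two extremes — we measured ≈27% of planted genes in each extreme
under that construction. Re-allocating the enhancer complement toward
REs at fixed RE-linked signal is also the biologically meaningful
signature: an RRE-enriched gene is one whose regulation is
disproportionately RE-derived, not one with more total signal. With
the scaling, p0 = p1 still yields an exact null (scale 1), and the
separation limit p1 → 1, p0 → 0 keeps the background mean so NGRE → 1
remains well defined.

Gene classes are drawn per gene with baseline rates lncRNA 0.06 and
miRNA 0.07 — matched to the implied genome-wide fractions of the
reference universe this package is calibrated against (≈1,479 and
≈1,799 non-coding genes among 24,070) — and `ncrna_bias` multiplies
the *odds* of each ncRNA class for planted genes (default 3×,
lncRNA 0.06 → 0.161), the non-ncRNA classes absorbing the remainder
proportionally.

What the generator does *not* emulate: sequence content, chromatin
domain structure, tag-depth differences between cell lines, overlapping
gene neighborhoods, and the heavy-tailed per-gene tag-count variation
of real ChIP-seq. Passing tests therefore demonstrate that the
algorithms do what they claim under controlled conditions, not that
real epigenomes satisfy the planted model.

```{r sim-example}
cfg <- simulation_config(seed = 7, n_genes = 300, n_chromosomes = 2,
                         chrom_length = 2.5e6, n_cell_lines = 2,
                         n_pathways = 30, n_terms = 30)
sim <- simulate_epigenome(cfg, out_dir = tempfile())
genes <- read_gene_table(sim$paths$genes)
table(genes$gene_class)
```

# Numerical choices and degenerate inputs

* Zero-intercept slope via `lm.fit`; an all-zero abscissa is a
  degenerate-fit error, not a silent zero.
* `round_half_away` is used everywhere a set size is derived from a
  fraction; base `round()`'s banker's rounding would give 1,203 or
  1,204 depending on floating-point representation.
* The normal equation `Σ x·residual = 0` is tested to 1e−9 relative.
* Hypergeometric tails: `phyper` log-space; the complementarity
  identity to 1e−12; `k` outside the support has probability 0, not an
  error.
* Correlations require ≥3 shared defined entries and non-constant
  vectors; both violations are explicit errors.
* Pathways with no scorable members are omitted with a message, never
  silently dropped; `n_genes_scored` makes the effective membership
  visible.
* Determinism: every stochastic entry point takes a seed, restores the
  caller's RNG state, and regenerates byte-identical outputs —
  `run_all()` writes no timestamps for exactly this reason.

# Problem sizes used in validation

The shipped test suite validates the full pipeline at 2,000 genes ×
5 cell lines with B = 500 permutations (the default generator scale),
recovery and class-representation checks over ten fixed seeds, the
enumeration oracle over all universes with M ≤ 12, and Monte-Carlo
calibration at 10,000 draws; smaller fixtures (200–500 genes) exercise
orchestration and determinism. These scales were chosen so the whole
suite completes in a few minutes while keeping every statistical check
at a power where failure is informative.

# Known limitations

* The per-tag compartment assignment is binary by midpoint; signal
  values (e.g. peak heights) are not weighted.
* Distal enhancer assignment by chromatin looping is out of scope; the
  10-kb window is a deliberate, simple proximity rule.
* The term-enrichment step replaces external annotation services with
  an internal hypergeometric test over a user-supplied GMT; GO DAG
  topology is not modelled.
* The strictly-greater overrepresentation tail is anti-conservative by
  one probability mass term (see above); this is a property of the
  implemented definition, kept deliberately.
* PII as a member mean treats pathways as exchangeable gene bags;
  pathway topology is ignored.
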