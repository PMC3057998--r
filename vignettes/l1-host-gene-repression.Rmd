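---
title: "Methods: intragenic LINE-1 elements and host-gene repression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intragenic LINE-1 elements and host-gene repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineone)
```

# The analysis

`lineone` tests whether genes hosting intragenic LINE-1 (L1)
retrotransposons are preferentially repressed when the genome is
hypomethylated — in cancers, or after demethylating treatment. The chain
of evidence it implements is statistical, not mechanistic: interval
classification of L1s against a gene annotation, screening of L1
structural features, two-group expression calling, 2×2 association tests,
cross-experiment concordance, and the spatial relationship between RNA
binding-protein (AGO2) CLIP sites and intragenic L1s.

## Coordinate and classification model

All intervals use BED conventions internally: 0-based, half-open
`[start, end)`. An L1 is **intragenic** when it overlaps a gene's
transcript span by at least one base pair. Overlap, rather than full
containment, is the weakest defensible reading of a location-based
classification against a RefSeq-style annotation, and is the default;
`mode = "containment"` is available because intron-restricted definitions
are also common in the retrotransposon literature. An L1 overlapping
several genes is intragenic once and lists all host genes, which matters
for per-gene feature counting. Overlap detection is delegated to
`GenomicRanges::findOverlaps()`; the package's own tests verify it against
a brute-force all-pairs scan.

Flank assignment (intergenic L1s near gene termini) measures the distance
from the gene terminus to the nearest L1 edge on the *outward* side only —
intergenic L1s cannot overlap the gene body by construction, so the gene
body never enters a distance. Distances of exactly the window size are
included (`distance_bp <= window_bp`). Pairs in which either element has
unknown strand are skipped with a warning, since orientation
(sense/antisense) would be undefined.

## Probe-level tests and the gene-calling rule

Each probe receives two one-sided pooled-variance Student *t*-tests:
"up" tests test > control, "down" tests test < control. Two one-sided
tests — rather than one two-sided test with a sign — make the four-way
gene classification (up / not-up / down / not-down) internally coherent:
"not up" is a statement about one tail, not about both. A
`mode = "two_sided"` alternative is provided, which assigns the two-sided
p to the side matching the sign of the mean difference.

The gene-level rule: a gene is called in a direction when at least one
*unique* probe (mapping to exactly one gene) is significant in that
direction; a gene represented only by *homologous* probes (mapping to more
than one gene) needs at least two significant homologous probes, and we
additionally require them to be significant in the same direction — a
single contradictory pair should not produce a call. A gene qualifying in
both directions is resolved to the direction with the smaller best
p-value and flagged. Genes with no mapped probes are excluded from the
call set entirely (they are *unobserved*, not "not regulated"), and are
therefore absent from every downstream universe.

The significance threshold is α = 0.01, relaxed to α = 0.05 when either
group has exactly two samples (the *t*-test is then too weak for 0.01 to
be informative) or the mRNA is immunoprecipitation-derived (IP material is
noisier and groups are typically tiny).

Degenerate probes: zero pooled variance with equal means gives
p_up = p_down = 1 (no evidence either way); zero variance with unequal
means gives 0/1 according to the sign. Probes with missing values are
tested on the available samples when at least two remain per group,
otherwise skipped.

## 2×2 statistics

Every association in the package funnels through one function,
`chisq_or()`: Pearson chi-square on the raw counts (df = 1), the odds
ratio OR = *ad*/*bc*, and the Woolf (log-scale) 95% CI. Numerical
choices:

* **No continuity correction by default.** The tables this machinery is
  built for have hundreds to thousands of genes per margin, where the
  Yates correction only biases the statistic; it is exposed as a flag for
  small-table use.
* **Haldane–Anscombe +0.5 on zero cells, OR/CI only.** A zero cell makes
  the OR 0 or infinite; adding 0.5 to every cell is the standard fix and
  is flagged in the result (`zero_cell_corrected`). The chi-square is
  always computed on the raw counts — correcting it too would silently
  change the p-value of a perfectly valid test.
* **Woolf CI** because the package reports ln-OR-scale intervals;
  the CI method is a convention choice and is stated in the result object.
* **Degenerate margins** (an empty row or column) return p = 1 and an
  undefined OR with a `degenerate` flag rather than an error: screens over
  many features/conditions should not abort on one empty stratum.

Tests verify the implementation against an independent direct-formula
oracle (Σ(O−E)²/E), against `stats::chisq.test(correct = FALSE)`, and —
for large tables — against the exact test within a tolerance that widens
with the p-value itself, since the conditional exact two-sided p and the
asymptotic p agree tightly only in the tails.

## Cross-experiment concordance

Two call sets are intersected on their shared gene universe and
cross-tabulated: regulated in both / in B only / in A only / in neither.
The table's transpose symmetry under experiment swap and the conservation
of the shared-universe total are asserted as exact properties. Mixed
direction pairs (`"up"` vs `"not_up"`, etc.) are supported because
knockdown-versus-disease comparisons need them. The commonality score
counts, per gene, the experiments in which it is down-regulated; the
default universe is genes present in **all** experiments (the strictest
reading of "presented in both experiments" generalised to many), with a
union mode for sparser platforms; group means (L1 vs non-L1 genes) are
compared with the same homoscedastic *t*-test used in the feature screen.

## AGO2 sites

CLIP-derived binding sites shorter than 19 bp are discarded (strictly
longer than 18 bp — the boundary case is excluded). The proximity
histogram counts (L1, site) *pairs*: a site within range of two L1s
contributes to both anchors, matching a per-anchor vicinity count. The
anchor is the L1's 5′ edge in host-gene orientation by default — the
biologically motivated choice, since readthrough transcription from the
L1 5′ region is the proposed source of complementary RNA — with
`three_prime` and `midpoint` exposed because the convention is genuinely
open. Distances are signed positive downstream in the host gene's
transcription direction and binned as `floor(d / 25000)` over
`[-600000, +600000)`, giving exactly 48 bins. Intragenic L1s whose host
genes disagree in strand have no defined orientation and are skipped with
a warning.

## COBRA

Percent methylation is `100 * taqI / (taqI + tasI)` — the
methylation-dependent (TaqI-cut) band intensity over the total. The
identity `cobra_percent(a, b) + cobra_percent(b, a) == 100` is asserted
exactly. Correlation of methylation with expression uses the
product-moment coefficient with the *t*-transform p-value via
`stats::cor.test()`.

# The synthetic-data generator

`sim_config()` defaults define the package's reference study conditions:
2,000 genes on 5 chromosomes, 20% of genes hosting one intragenic L1,
1,500 intergenic L1s (keeping the intergenic:intragenic ratio near the
roughly 3.7:1 seen in genome-wide L1 catalogues), 5 samples per group,
probe noise σ = 1 on a log-like scale with baselines ~N(8, 1), a
2σ mean shift in regulated genes, 15% of genes down-regulated and 5%
up-regulated overall, and a planted odds ratio of 3 linking L1 hosting to
down-regulation. Feature prevalences default to intragenic-enriched
conserved sequence and CpG islands and intragenic-shifted G–C content and
intactness, mirroring the qualitative direction reported for real L1
catalogues. These values were fixed once as a realistic operating point;
they are arguments, not constants, so every recovery experiment states
its own conditions.

The planted odds ratio is enforced **in expectation** via closed-form
conditional probabilities: given the overall down fraction *f*, the L1
gene fraction *q* and the target odds ratio ω, the per-class down
probabilities (p₁ for L1 genes, p₂ for the rest) solve
p₁/(1−p₁) = ω·p₂/(1−p₂) subject to q·p₁ + (1−q)·p₂ = f (a monotone
one-dimensional root). Binding sites are Poisson-uniform over each
chromosome plus a Poisson excess within ±12.5 kb of each intragenic L1
anchor scaled so local density is `ago2_fold_excess` × background.

What the generator does **not** emulate: array-platform intensity
distributions, probe-specific affinity, correlated noise across probes of
a gene, L1 sequence content, overlapping genes, and truncation/subfamily
structure of real L1s. Passing recovery tests therefore show the
*statistical machinery* is correct under its own assumptions, not that
real microarray data meet those assumptions.

## A known property: attenuation of the recovered odds ratio

The planted odds ratio links L1 hosting to *true* down-regulation; the
pipeline estimate links L1 hosting to *called* down-regulation. Calling
is imperfect: at the reference conditions (2σ shift, n = 5/5, α = 0.01),
the per-probe one-sided power is
`1 - pt(qt(0.99, 8), 8, ncp = 2*sqrt(2.5))` ≈ 0.62, and the per-gene
false-call rate is the family-wise α over its probes. Nondifferential
misclassification of the outcome shrinks an odds ratio toward 1: with
sensitivity *s* and false rate *g*, the observed per-class call rates are
s·pᵢ + g·(1−pᵢ), and for every probe-per-gene configuration the planted
ω = 3 yields an expected observed OR of about 2.5–2.6 — increasing probe
counts raises sensitivity and the false rate together, so no
configuration escapes the ceiling. The acceptance suite asserts recovery
within 10% of the planted value and the acceptance script reports the
empirical median, so this attenuation is measured, visible, and
documented rather than hidden; the matched null (ω = 1) is calibrated,
with the estimate centred at 1 and ~5% of seeds significant at α = 0.05.
Users comparing a recovered OR against a planted one should expect this
shrinkage whenever call power is materially below 1.

# Problem sizes in the test suite

Unit tests run on small layouts (tens of genes, hundreds of intervals)
against brute-force oracles; the rule-equivalence suite uses 500 small
experiments (60 genes, ~100 probes, n = 3/3); recovery experiments use the
reference conditions with 500 (planted) and 200 (null) expression draws
over a fixed genome, since the quantity under test varies with the
expression noise, not the genome layout; histogram excess detection uses
200 single-chromosome genomes. These sizes were chosen to make sampling
variability small relative to the asserted tolerances.

# Limitations

* Gene identifiers are matched as exact strings across experiments; no
  symbol aliasing or platform reconciliation is attempted.
* No normalisation is applied to expression matrices; they are consumed
  as deposited.
* No multiple-testing correction is applied inside the feature screen
  (matching raw-p reporting conventions for this analysis); a Bonferroni
  column is emitted for convenience.
* The enrichment universe is genes with calls on the platform; genes
  without probes are invisible to the analysis, which can bias the
  universe if probe coverage correlates with L1 hosting.
* Exon/intron structure is not modelled: "intragenic" means within the
  transcript span, and intron-level placement is out of scope.
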