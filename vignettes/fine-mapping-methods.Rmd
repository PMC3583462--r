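---
title: "Methods: fine-mapping a recessive dwarfing locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-mapping a recessive dwarfing locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pmfinemap implements the inference chain used to localise a recessive
dwarfing gene (*d2*-type) in an outcrossing cereal: recombinant screening
of an F2 population, progeny-test genotype calling from F3 height
distributions, cosegregation placement of the trait locus, haplotype
delineation across inbred panels, and synteny-based projection of the
candidate interval onto a reference genome.  This vignette explains each
model, its assumptions, the tunable parameters, and the design choices
made where the method description left the design open.

## The genetic model and the simulator

An F2 plant is formed from two independent gametes of a fully
heterozygous F1.  `simulate_gametes()` draws the allele at the first
locus fairly and then recombines each inter-locus interval independently
with fraction $r = \tfrac12(1 - e^{-2d/100})$, the Haldane map function
for a distance of $d$ cM.  We deliberately model **no crossover
interference**: the intervals of interest are short (a few cM), where
interference has negligible effect on two-point quantities, and the
Haldane function is the one consistent with independent recombination.  A
`map_function = "morgan"` option ($r = d/100$) is exposed for comparison.

The recessive trait locus is placed at its cM position among the markers
(`Inf` simulates an unlinked locus).  Dominant markers are reported with
the heterozygote and the dominant homozygote collapsed (`A-`), exactly as
a presence/absence assay would score them; nothing downstream can, or
tries to, distinguish `Dd` from `DD` at such a locus.  Missing calls are
injected uniformly at random -- the simplest defensible missingness model,
with the rate configurable.

### Heights of F3 families

An F3 family derives from selfing one F2 plant; progeny genotypes follow
the Mendelian selfing rules (dd fixes, Dd segregates 1:2:1).  Height (cm)
is a two-component Gaussian mixture: plants homozygous for the recessive
allele draw from the dwarf component, all others from the tall component,
plus a family-level and a batch-level random effect shared within a
family.  Defaults:

| parameter | default | unit | rationale |
|---|---|---|---|
| `mu_dwarf`, `sd_dwarf` | 75, 15 | cm | places < 2% of dwarf plants at or above the 110 cm scoring threshold |
| `mu_tall`, `sd_tall` | 165, 25 | cm | tall medians in the 150--190 cm range typical of glasshouse-grown tall families |
| `family_effect_sd` | 3 | cm | see below |
| `batch_effect_sd` | 2 | cm | batches grown at different times shift whole families slightly |

The family and batch effects are kept small for two reasons that pull in
the same direction: the dwarf tail above 110 cm must stay below 2% (the
property that justified the 110 cm threshold in the original screen), and
a homozygous-dwarf family of 13 plants must yield a median below 90 cm
essentially always (> 0.99), or the progeny test could not work at the
screen's family sizes.  The cost is realism on the other side: real tall
families show family medians spanning roughly 121--210 cm, driven largely
by *other* segregating height genes.  The generator intentionally models
a single major recessive locus plus noise -- a stated non-goal is any
multi-QTL height architecture -- so passing tests demonstrate that the
decision rules are correct *under the single-locus model*, not that they
are robust to strong polygenic background variation.  Consequently the
simulated tall-family median spread (about $\pm 20$ cm) is narrower than
in real data.

One derived quantity worth recording: under these defaults the
probability that a homozygous-tall family of 25 has *zero* plants below
110 cm is about 0.70 (the tall component leaves $\Phi(-2.2) \approx
1.4\%$ of plants below the threshold).  The test suite pins the simulated
value to its analytic integral rather than to any larger round number; a
screen relying on "zero short plants" alone would misname a third of
homozygous-tall parents as heterozygous, which is exactly why the
decision rule also applies the segregation test below.

## The progeny test

`classify_family()` converts an F3 family into a genotype call at the
trait locus:

* empty family: `no_data`;
* median < 90 cm: `dd` (all progeny dwarf, the parent was homozygous
  recessive);
* median > 135 cm: the parent is tall; with no plants below 110 cm the
  call is `DD`; otherwise the count of short plants is tested against the
  3:1 expectation with an **uncorrected** Pearson chi-square on one
  degree of freedom (`chisq_3to1()`).  A compatible fraction gives `Dd`;
  a significantly *low* fraction gives `DD`.
* median in the closed band [90, 135] cm: `tall_unresolved` -- the parent
  is tall but heterozygosity cannot be established at these family sizes.

Numerical choices:

* **No Yates continuity correction.**  For 2 short among 23 the
  uncorrected statistic gives $P = 0.071$; the corrected one gives
  $\approx 0.118$.  The uncorrected Pearson statistic is the published
  convention for these family tests and the one this package reproduces.
* **The unresolved band is [90, 135] inclusive.**  The method text that
  motivated this rule states "< 90" and "> 135", leaving the closed band;
  an alternative passage says "between 90 and 130", an internal
  inconsistency in the source material.  We adopt 135; both bounds are
  parameters (`tall_median`) if a user prefers otherwise.
* **`alpha = 0.05` per family with no multiple-testing adjustment**,
  matching the convention of flagging per-family significance; a
  `bonferroni = TRUE` switch divides alpha by the family count.
* A short fraction significantly *above* 25% in a tall-median family
  never occurs under the model; rather than silently calling `DD` we
  label it `Dd` with a warning, because a dwarf-rich tall family most
  likely indicates a phenotyping or labelling problem.
* Families split across glasshouse batches are classified per batch and
  merged by consensus; conflicting batch calls are downgraded to
  `tall_unresolved`.

One fixture family (plant 778, 1 short among 21) illustrates a subtlety:
its short count is significantly below 25% at $\alpha = 0.05$, so the
rule calls `DD`, and the package keeps the rule-consistent call.

## Recombinant screening and map distance

A plant is *informative* iff its two-locus genotype cannot be assembled
from two parental gametes; `find_recombinants()` encodes the minimum
recombinant-gamete count per genotype class (validated in the tests
against exhaustive gamete enumeration).  `AA/BB`-type plants force two
recombinant chromosomes; `AB/AB` plants are parental-compatible and are
*not* counted, which makes the estimator blind to double recombinants in
repulsion -- a downward bias of $r^2/2$ in the recombinant fraction,
negligible below ~5 cM and about 0.4% of a chromosome at 10 cM.

`map_distance()` estimates distance as $100 \cdot R / 2N$ (recombinant
chromosomes over gametes scored), the estimator under which 29
recombinants among 915 plants give 1.585, printed as 1.6 cM.  The default
returns this plain recombinant fraction; `method = "haldane"` inverts the
map function for larger distances.  Plants missing either flanking call
are excluded from $N$ and reported, mirroring the removal of plants that
died or showed non-parental alleles in the original screen.

## Cosegregation clustering and trait placement

Over the informative plants, codominant markers with identical genotype
vectors merge into clusters; dominant markers attach to the unique
compatible cluster, with ambiguous attachments reported as a candidate
range rather than resolved arbitrarily (a dominant marker can never
separate clusters that differ only at `AA`/`AB` plants).  Cluster order
minimises total recombination events between adjacent clusters, with the
clusters holding the outermost loci anchored at the ends; ordering is
exhaustive over permutations (fine-mapping panels have few clusters) and
ties break lexicographically for determinism.

`place_trait()` assigns the trait the position minimising recombination
events against all clusters, excluding `tall_unresolved` and `no_data`
plants entirely -- they are not missing at random, they are plants the
progeny test chose not to classify.  `flag_double_recombinants()` flags
any plant whose trait call disagrees with identical flanking cluster
genotypes: such a call implies a recombination event on *both* sides of
the trait inside an interval where no marker recombined, and the single
most likely explanation is a borderline progeny-test call.  The flag
carries the family's segregation p-value and the re-call that removes
both events.

## Haplotype discrimination scan

`assess_locus()` classifies each locus of a tall/dwarf inbred allele
matrix.  The dwarf class defines the target allele: dwarfs must be
uniform, talls may be heterogeneous.  Up to `max_exceptions` tall lines
may share the dwarf allele ("exception", the signature of allele-size
homoplasy); more sharers, or non-uniform dwarfs, break the locus.
Missing calls (`ND`) are ignored, never imputed, and a locus missing an
entire class is uninformative -- it neither extends nor interrupts a
block.

`delineate_block()` grows the maximal contiguous run of
discriminating/exception loci.  Two rules terminate a run: `break_run`
consecutive broken loci, or -- the one genuinely open design decision in
this module -- a **per-line exception budget**: within one block each
tall line may carry the dwarf allele at no more than `max_exceptions`
loci.  An isolated shared allele is plausibly homoplasy; the *same* tall
line sharing the dwarf allele at further loci, contiguously toward one
end, is the signature of a real haplotype (an introgression or common
ancestry), and the differentiation between the classes is genuinely lost
there.  On the packaged inbred-panel fixture this reproduces the
published reading exactly: the block spans the nine distal loci
(B224C4P2 through Ca_Sb07g023440), the single Tift red exception at
Ca_Sb07g023910 stays inside the block, and the block closes at
Ca_Sb07g023430 -- where Tift red begins sharing the dwarf allele all the
way to the proximal end -- so the proximal boundary is reported as
Ca_Sb07g023430 and the locus interval is half-open there.

## Synteny chaining and interval projection

Anchors (homologous gene pairs with an E-value) are filtered to
`evalue < 1e-5` with at most 4 hits per query gene, then chained by
dynamic programming maximising $\sum \min\{-\log_{10} E, 50\}$ minus a
gap penalty of 1 per 10 kb between consecutive anchors.  Ascending and
descending chains (in the second genome's coordinate) are computed
independently and compete during greedy non-overlapping extraction by
score; blocks scoring $\le 300$ are discarded.  Choices the scoring
description leaves open, each exposed as an option:

* **Which genome's distance incurs the gap penalty** is unstated; we
  penalise the maximum of the two distances (conservative and symmetric),
  with `mean` and `sum` available.
* The penalty is applied **continuously** (distance/10 kb), not floored
  to whole 10-kb units.
* A published block-level "E-value" retrieval filter exists in the
  original tooling but no formula for it is available; block filtering
  here uses the score threshold only.

`detect_rearrangements()` calls a descending block flanked by ascending
blocks (or chromosome ends) an inversion.  One behaviour of optimal
chaining matters here: a long ascending chain bridging an inversion can
profitably absorb a single anchor from inside it, because one anchor's
score (up to 50) always exceeds the marginal gap penalty of a small
detour.  If the absorbed anchor is at the segment's edge, the naive
breakpoint (the gap to the nearest foreign anchor) lands *inside* the
inversion.  We therefore refine the inverted segment before measuring
breakpoints, extending it over neighbouring anchors that continue its
descending order -- automating what is otherwise a manual breakpoint
determination.  Breakpoint intervals are reported as the flanking gaps on
both genomes; in simulations with planted inversions of at least 10 genes
among 200 (default noise: 5 unpaired insertions, 5 deletions), the
breakpoints fall inside the true inter-gene gaps in at least 95 of 100
seeded runs.

`project_interval()` orders the two boundary markers' ortholog positions
and reports the closed interval, its length, and the annotated genes
whose representative coordinate (gene start, 1-based inclusive) falls
inside; BED export converts to 0-based half-open.  Boundary orthologs at
58.37 and 58.78 Mb give the 410-kb candidate interval.

## Problem sizes, determinism and limitations

The test and acceptance workloads use the study-scale sizes where they
are cheap (915-plant screens, 1000 replicates, families of 13--25,
5000-plant populations for recovery at 0.5--10 cM, 200-gene anchor
tables), chosen as representative of the design being emulated.  All
randomness flows through explicit integer seeds; rerunning any generator
or the pipeline with the same seed is byte-identical, and the run
manifest records seed, config, input checksums and per-stage counts.

Known limitations: the height model is a single-locus mixture (no
polygenic background, so unresolved-band frequencies are optimistic);
the distance estimator ignores repulsion-phase double recombinants (bias
$r^2/2$); cluster ordering is exhaustive and limited to eight clusters;
synteny chaining is $O(n^2)$ per chromosome pair and meant for
region-scale anchor tables, not whole-genome runs; and the haplotype
scan reports patterns only -- whether a shared allele reflects identity
by descent or size homoplasy is not decidable from an allele matrix.
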