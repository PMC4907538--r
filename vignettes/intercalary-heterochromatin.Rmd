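---
title: "Dissecting intercalary heterochromatin with ihscape: models, parameters and design choices"
author: "ihscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting intercalary heterochromatin with ihscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihscape)
library(GenomicRanges)
```

## The problem

Intercalary heterochromatin (IH) comprises the large (100–600 kb)
late-replicating, gene-poor bands of the Drosophila euchromatic
chromosome arms. Although IH looks monolithically repressed at cytological
resolution, fragment-level chromatin maps reveal internal heterogeneity:
a repressed core interrupted by transitional and even open, regulatory-like
chromatin. `ihscape` implements the analyses needed to characterise that
heterogeneity from a four-state chromatin map and standard annotation
tracks, with a seeded synthetic-data generator so that every stage can be
validated against planted ground truth without any external downloads.

The four chromatin states are named after minerals to avoid collision with
other colour-coded chromatin models:

* **aquamarine** — open, regulatory chromatin (interband-like; 5' ends of
  broadly expressed genes);
* **lazurite** — gene bodies;
* **malachite** — transitional chromatin of unclear function;
* **ruby** — repressed, compact chromatin, the bulk of IH bands.

The map arrives as 200-bp non-overlapping typed fragments plus unassigned
stretches ("gaps").

## Map processing

Two deterministic rules turn fragments into domains:

1. **Gap filling** (`fillGaps()`): an unassigned gap of at most 400 bp
   whose immediate non-gap neighbours on both sides share one state is
   relabelled to that state. The boundary value is inclusive (a 400-bp gap
   is filled; 401 bp is not). The pass runs once, not to a fixed point: a
   relabelled gap may unite two runs — merging handles that — but no
   second round of filling is performed across newly united material.
   Coordinates are never altered, only labels, which makes the operation
   idempotent.
2. **Domain merging** (`mergeDomains()`): maximal runs of same-state
   abutting fragments become one domain; residual gaps break runs.
   Per-base state assignment is preserved exactly.

Composition of a region set (`stateComposition()`) is computed over
clipped segment lengths by default: a domain straddling an IH border
counts once for the region's domain inventory (membership by ≥ 1 bp
overlap) while base-pair composition uses only the in-region part. Both
choices are configurable (`minOverlap`, `clipped`) because published
descriptive statistics do not always state which convention was used.

All in-memory intervals are `GRanges` (1-based, closed); all on-disk
formats are BED-style (0-based, half-open). Conversion happens only in
the readers and writers.

## Domain topology

`contactMatrix()` counts adjacencies between consecutive domains. The
default mode is *opaque*: only directly abutting domains count. After gap
filling, any remaining gap is > 400 bp of genuinely unassigned sequence,
and treating it as contact would fabricate adjacency; the *transparent*
mode (with a `maxSpan` cap) is provided for sensitivity analysis.

A striking topological regularity of the four-state map is the
*malachite buffer*: ruby chromatin is never directly bordered by
aquamarine or lazurite — a malachite zone always intervenes. The
synthetic generator can enforce or disable this rule, and the contact
matrix detects either regime (an acceptance property of the package).

Malachite domains overlapping an IH region are classified
(`classifyMalachite()`) as **border** (the domain touches or crosses a
mapped region boundary; tolerance 0 bp by default, configurable) or
**internal**. The formal "touches or crosses" rule is our own — the
underlying biology describes border malachite as the transition zone
between the ruby core and the flanking interband without giving a
decision rule — so the tolerance is exposed as a parameter.

## The domain-shuffle permutation test

The enrichment statistic for a chromatin type against an annotation track
is the total overlap length in bp (a domain-count statistic is available
via `statistic = "count"`; the length statistic is the default because
length is what the overlap accounting conserves). The null model
preserves the length structure of the chromosome exactly:

* Decompose the domains of one state on one chromosome into ordered
  domain lengths $A_n = \{1..N\}$ and spacer lengths
  $S_n = \{1..N{+}1\}$, where $S_1$ runs from the chromosome start to the
  first domain and $S_{N+1}$ from the last domain to the chromosome end.
* Each Monte-Carlo iteration permutes the two index arrays independently
  and uniformly (domain $i$ is not kept paired with spacer $i$) and lays
  the chromosome out as $S\,A\,S\,A\,\dots S$. Both length multisets and
  the chromosome length are conserved in every iteration; the track is
  never shuffled.
* `p_enrich` is the fraction of iterations with a null statistic ≥ the
  observed one, `p_deplete` the fraction ≤ it; ties count as extreme on
  both sides (conservative). The add-one estimators
  $(\mathrm{count}+1)/(M+1)$ are always reported as well.
* When an empirical p saturates at exactly 0 or 1 and the null is not
  degenerate, the Gaussian tail at the null sample moments is reported
  instead (`method = "normal_approx"`). A degenerate null (sd = 0) keeps
  the empirical value and is flagged.

`genomeWideTest()` shuffles every chromosome independently in each
iteration and sums the per-chromosome overlaps, yielding a single
whole-genome p-value; on a one-chromosome genome it is identical to
`permutationTest()` under the same seed. The default iteration count is
$M = 10^4$, sufficient for desk-scale resolution; raise it towards
$10^6$ when very small tails must be resolved empirically. The
Monte-Carlo loop runs in C++ but draws from R's RNG, so `set.seed()`
makes every run replayable; the slow all-R path
(`shuffleArrangement()` + `overlapLength()`) is retained and the test
suite checks that both paths target the same null distribution.

No multiple-testing correction is applied across tracks; raw p-values
are reported and thresholds are left to the user.

`densityRatio()` reports observed/expected overlap fractions. The
expected fraction defaults to the shuffle-null mean divided by the query
length, with the genome-wide track density as fallback. Note an
attenuation property: if the target state occupies fraction $w$ of the
genome and a track is enriched $f$-fold inside it, the recoverable ratio
is $f/(1+(f{-}1)w)$ — effectively $f$ only when $w$ is small. Open
regulatory chromatin is a small minority of the fly genome, which is why
the synthetic generator's default aquamarine share is 2%.

## Expression breadth

Transcripts are assigned to the chromatin class whose half-open span
contains their annotated TSS base (`assignTssClass()`); TSSs in residual
gaps are `unassigned`, and TSSs inside labelled IH malachite are refined
to `malachite_border` / `malachite_internal`. A transcript is *expressed*
in a tissue when RPKM is strictly greater than 3; RPKM exactly 3 counts
as silent. Breadth (tissues expressed per transcript) is therefore
monotone non-increasing in the threshold. Five-number summaries use
quartiles with whiskers at the 12.5th/87.5th percentiles under the
linear-interpolation convention (`stats::quantile`, `type = 7`;
configurable), since the percentile algorithm is otherwise a silent
source of irreproducibility.

## Replication timing

Probes are assigned to the class covering at least 50% of their length
(inclusive at the boundary; `assignProbeClass()`), binned in 0.5
score-unit steps and normalised to sum to 1 per class
(`binTimingScores()`). Within an IH region, the border-to-center gradient
is quantified by `borderGradient()`: per-probe distance to the nearest
region border (computed from the probe midpoint, which makes the
statistic symmetric under coordinate reversal), Spearman rank correlation
and least-squares slope of score versus distance in score units per kb.
The scalar gradient statistic is this package's addition — the underlying
observation is usually shown graphically — because a number with a
standard error is testable and a picture is not. Fewer than 3 in-region
probes leave the statistics undefined and flagged.

## The synthetic-data generator

`genMap()` lays out a chain of domains with state-dependent log-normal
lengths (heavy right tails mirror the reported skew: mean > median for
all states), a configurable adjacency rule (the malachite buffer), and
unassigned gaps at a low rate. Pre-placed IH windows switch the chain to
a ruby-dominated mixture (85% ruby / 11% malachite by bp, echoing the
published IH composition) with a longer ruby length scale, and open and
close with a malachite transition domain so that planted borders carry
border malachite the way real IH bands do.

Defaults were chosen once as the package's desk-scale study conditions
and are documented here rather than tuned per test:

| parameter | default | why |
|---|---|---|
| genome | five 3 Mb arms | five-arm layout at desk scale |
| state bp shares | ruby .45 / laz .28 / mal .25 / aqua .02 | repressed-dominated genome; open chromatin rare |
| IH regions | 10 of 100–300 kb (~13% of span) | matches the ~12% genome share of IH |
| domain lengths | log-normal; e.g. malachite median 1.2 kb, aquamarine median 0.8 kb | reported mean/median skew |
| gap rate | 0.05, log-normal lengths | sparse unassigned sequence |
| tissues | 29 + 2 cell lines | the expression panel layout |

`genTrack()` plants coverage density `fold * base` inside one state and
`base` elsewhere by uniform placement within state masks; with
`fold = 1` the track is placed uniformly over the whole genome and is
genuinely independent of the map — the null case used for type-I
calibration. `genExpression()` plants per-class per-tissue expression
probabilities (breadth is then Binomial), `genProbes()` a linear
early-to-late timing gradient with Gaussian noise, and `genPeaks()`
Poisson peak counts at per-state rates with log-normal read counts.

What the generator does *not* emulate: real sequence composition,
autocorrelated ChIP signal, irregular probe spacing, cytological band
structure. Passing tests therefore demonstrate the correctness of the
*computations* under known ground truth, not the biological conclusions
on real data, which additionally depend on the published maps and tracks.

## Numerical and testing choices

* Sizes used by the test battery (chosen once as desk-scale study
  conditions): the exhaustive-enumeration oracle uses a 2-domain /
  3-spacer arrangement (12 layouts) against $M = 10^5$ shuffles; type-I
  calibration runs 500 map-independent tracks at $M = 10^4$ on a 500-kb
  chromosome; planted-fold recovery runs on the full 15 Mb demo genome;
  gradient recovery uses 100 seeded probe sets at noise sd 0.2; the
  buffer-rule property uses 20 seeds per regime.
* The normal-approximation check batteries cases at planted folds 1.6
  and 1.75 on a 1 Mb chromosome (~170 domains), where the empirical p at
  $M = 10^5$ falls into the moderate range in which both estimates are
  informative. The null of the summed-overlap statistic is mildly
  right-skewed, so the Gaussian tail systematically underestimates
  moderate right-tail p-values; with enough domains the disagreement
  stays within a small factor, and it grows in the extreme tail — which
  is exactly why the package reports the approximation only when the
  empirical estimate saturates.
* Type-I calibration draws a fresh map *and* a fresh track per
  replicate, estimating the marginal null rejection rate of the whole
  pipeline, which symmetry pins at the nominal level. Conditioning on a
  single fixed map would leave a small arrangement-dependent bias term:
  for a random track, the variance of the overlap statistic depends on
  the inter-domain distances of the particular arrangement, so one map's
  conditional rejection rate can sit a percentage point or two off
  nominal even though the test is marginally exact.
* Coordinates are stored as doubles inside the C++ kernel — exact for
  genome-scale integers — and bp sums use numeric accumulation to avoid
  32-bit overflow.
* Ties in probe class assignment (possible only at `minFrac <= 0.5`) go
  to the class covering more bp, then to state order; documented rather
  than silent.

## Known limitations

* The formal border/internal malachite rule (touch-or-cross with a
  configurable tolerance) is one of several defensible formalisations of
  a verbally described transition zone.
* The genome-wide combination of per-chromosome shuffles is the
  sum-statistic joint shuffle; other combination rules (e.g. Fisher's
  method over per-chromosome p-values) are not implemented.
* `fillGaps()` deliberately does not iterate to a fixed point; a gap that
  becomes fillable only after a neighbouring gap was filled stays
  unassigned.
* Reproducing the published descriptive statistics of the real
  Drosophila map (IH composition percentages, malachite fragment counts,
  probe counts per class) requires the published map, IH border list and
  public track downloads, which this package treats as external inputs;
  the bundled tests run entirely on synthetic data.

## A worked session

```{r worked, eval = FALSE}
set.seed(1)
g <- genMap(mapSpec())
map <- mergeDomains(fillGaps(g$map))
stateComposition(map, g$ihRegions, includeGaps = TRUE)
cm <- contactMatrix(map)
mal <- classifyMalachite(map, g$ihRegions)
trk <- genTrack(map, trackSpec(fold = 5, baseDensity = 0.02))
dm <- chromatinDomains(map)
res <- genomeWideTest(dm[dm$state == "aquamarine"], trk, M = 10000)
densityRatio(dm[dm$state == "aquamarine"], trk,
             nullMean = nullMoments(res)[["mean"]])
```

The same flow, driven from files, is available through `runPipeline()`
and the thin command-line wrapper in `inst/scripts/ihscape.R`.
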