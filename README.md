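# ihscape

Chromatin heterogeneity of intercalary heterochromatin (IH) — the large
(100–600 kb) late-replicating, gene-poor repressed bands of the
Drosophila euchromatic chromosome arms — analysed from a fragment-level
four-state chromatin map.

## Who this is for

Researchers working with chromatin-state segmentations and genomic
annotation tracks who need, in one tested package:

* **domain construction** from 200-bp typed fragments: gap filling
  (≤ 400 bp gaps flanked by one state inherit it), merging of same-state
  runs into domains, per-region state composition;
* **domain topology**: the state-contact matrix (including the
  *malachite buffer* regularity — repressed ruby chromatin never directly
  abuts open aquamarine or gene-body lazurite) and the classification of
  IH malachite into *border* (transition-zone) vs *internal* domains;
* **overlap/enrichment statistics** of chromatin classes against
  insulator, enhancer, or any BED track, with a length-preserving
  **domain/spacer index-shuffle permutation null**;
* **expression breadth** by chromatin class (expressed = RPKM > 3,
  strictly) and quartile summaries with 12.5/87.5-percentile whiskers;
* **replication timing**: ≥ 50%-overlap probe assignment, 0.5-step score
  histograms, and the border-to-center timing gradient of IH bands
  (Spearman correlation + slope per kb);
* a **seeded synthetic-data generator** for all of the above with planted
  ground truth, so the entire pipeline is testable offline.

## The statistic at the core

For the domains of one chromatin type on one chromosome, let
`A = (A_1..A_N)` be the domain lengths and `S = (S_1..S_{N+1})` the
spacer lengths (including the stretches to the chromosome ends), so that
`sum(A) + sum(S) = L`. The observed statistic is the total overlap length
(bp) between the domains and a fixed track. Each Monte-Carlo iteration
permutes the `A` and `S` index arrays independently and uniformly and
lays the chromosome out as `S A S A … S`; this conserves both length
multisets and `L` exactly while randomising positions. One-sided
empirical p-values count ties as extreme on both sides
(`p_enrich = #{null ≥ obs}/M`); a p that saturates at exactly 0 or 1 is
replaced by the Gaussian tail at the null sample moments. The
genome-wide test shuffles all chromosomes independently per iteration
and sums the overlaps.

## Worked example

```r
library(ihscape)
set.seed(1)

g   <- genMap(mapSpec())              # 15 Mb demo genome, 10 IH regions
map <- mergeDomains(fillGaps(g$map))  # gap-fill then merge
map
#> ChromatinMap with 5 chromosome(s), total span 1.5e+07 bp
#>   mapped: 14,827,800 bp; gaps: 172,200 bp
#>   fragments: 74349 ; domains: 5078

stateComposition(map, g$ihRegions, includeGaps = TRUE)
#>        state      bp    fraction
#> 1 aquamarine   54400 0.026845638
#> 2   lazurite   40200 0.019838137
#> 3  malachite  247600 0.122187130
#> 4       ruby 1675600 0.826885116
#> 5        gap    8600 0.004243979

contactMatrix(map)["ruby", c("aquamarine", "lazurite")]
#> aquamarine   lazurite
#>          0          0          # the malachite buffer rule

dm  <- chromatinDomains(map)
aq  <- dm[dm$state == "aquamarine"]
trk <- genTrack(map, trackSpec(fold = 5, baseDensity = 0.02))
res <- genomeWideTest(aq, trk, M = 10000)
res
#> ShuffleResult [genome, statistic=length, M=10000]
#>   observed 33251 vs null 7313.09 +/- 1936.69
#>   p_enrich = 3.33e-41, p_deplete = 1 (normal_approx)
densityRatio(aq, trk, nullMean = nullMoments(res)[["mean"]])$ratio
#> [1] 4.54678                     # fold 5 planted; ratio attenuated by
                                  # the ~2% genome share of aquamarine
```

The composition table reads: the planted IH regions are ~83% ruby with
a ~12% malachite admixture and traces of open chromatin — the
repressed-core-plus-transition-zone anatomy the package is built to
quantify. The enrichment run recovers the planted 5-fold aquamarine
track enrichment with an overwhelmingly significant one-sided p.

File-driven runs use `runPipeline(config, outDir)` (config as list or
YAML; outputs are plain TSV/JSON including per-region "passport"
records), or the thin CLI wrapper:

```sh
Rscript inst/scripts/ihscape.R fixtures --seed 1 --out demo
Rscript inst/scripts/ihscape.R run --config demo_config.yaml --out demo_out
Rscript inst/scripts/ihscape.R shuffle-test --domains demo_out/domains.bed \
    --state aquamarine --track demo/track_enriched.bed \
    --chrom-sizes demo/chrom.sizes --iterations 10000 --seed 1
```

## Package layout

* `R/` — S4 classes (`ChromatinMap`, `Arrangement`, `ShuffleResult`),
  readers/writers, the analysis modules, generators and pipeline.
* `src/` — the C++ Monte-Carlo kernel (draws from R's RNG; fully
  seed-reproducible).
* `tests/testthat/` — unit, property and acceptance suites (all
  fixtures are generated in code).
* `vignettes/intercalary-heterochromatin.Rmd` — models, parameter
  defaults and design rationale.
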