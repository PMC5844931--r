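# circompare

Benchmarking and combining back-splice junction call sets from circular
RNA (circRNA) prediction algorithms.

circRNA callers disagree substantially: run on the same ribo-depleted
RNA-seq data they report from hundreds to thousands of candidates, and a
variable share of those are depleted — not enriched — by RNase R, the
exonuclease that degrades linear RNA but spares circles. Depleted
candidates behave like linear artifacts and serve as operational false
positives; enriched ones as operational true positives. `circompare` is
for researchers who run several callers on an RNase R–treated/untreated
design and want a principled way to compare tools and to pick partner
algorithms whose intersected output removes false positives while keeping
true circles.

## What it computes

After harmonizing heterogeneous call tables to 0-based half-open
coordinates, filtering (≥ 3 reads in one untreated sample, posterior ≥
0.9 where reported, no chrM, no ciRNA, optional anchor-quality 40), and
classifying every candidate by its RNase R fold f = treated/control
(resistant: f ≥ 5; sensitive: f < 1; unchanged otherwise, under the
default `jeck` preset), it scores every ordered pair of call sets (a, b):

* iTP = |resistant(a) ∩ junctions(b)| / |resistant(a)|
* iTN = 1 − |sensitive(a) ∩ junctions(b)| / |sensitive(a)|
* Complementary score = (iTP × iTN)²

The score is directional, 1 only for a partner that preserves all of a's
true positives while discarding all of its false positives, and 0 for
self-pairing. Three-wise scores, shared-by-k consensus sets, rank–overlap
curves, score-vs-size correlation diagnostics, and mature spliced-length
estimation from transcript models (with the length vs RNase R sensitivity
association) round out the toolkit. A synthetic experiment generator with
known ground truth makes the whole pipeline testable without sequencing
data.

## Worked example

```r
library(circompare)

# a full synthetic 11-channel experiment: 2500 true circles, 2500 decoys,
# 2 control + 2 RNase R samples, correlated false positives
sim <- simulate_experiment(synth_config(seed = 42))
css <- simulated_callsets(sim)   # merge -> filter -> classify per channel

css$CIRI
#> <circ_callset> algorithm=CIRI, 2278 candidates (1328 resistant, 572 unchanged, 378 sensitive)

stratify(css$CIRI)
#>   resistance    n  fraction
#> 1  resistant 1328 0.5829675
#> 2  unchanged  572 0.2510975
#> 3  sensitive  378 0.1659350

top_n_sensitive_fraction(css$CIRI)       # FP load among top-100 expressed
#> [1] 0.19

m <- pairwise_matrix(css)                # 121 ordered pairs
best_complement(m, "CIRI")
#> $partner
#> [1] "CIRI2"
#> $score
#> [1] 0.3768561
```

16.6% of this channel's filtered candidates are RNase R sensitive, i.e.
likely artifacts; pairing it with its best complement would keep most of
its resistant candidates while discarding most of the sensitive ones
(score ≈ 0.38 on the 0–1 scale). For a single pair:

```r
itp <- compute_itp(css$CIRI, css$MapSplice)   # 0.59: resistant kept
itn <- compute_itn(css$CIRI, css$MapSplice)   # 0.89: sensitive removed
complementary_score(itp, itn)                 # 0.28
```

Real call tables enter through `read_callset()` with a dialect from
`dialect_registry()` (which knows the coordinate conventions of ACFS,
CIRCexplorer/2, circRNA_finder, CIRI/2, DCC, find_circ, KNIFE, MapSplice
and Uroborus), a YAML sample manifest via `read_manifest()`, and then the
same `merge_samples()` → `apply_filters()` → `classify_candidates()`
chain. A thin CLI over these functions is in
`inst/scripts/circompare.R`.

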