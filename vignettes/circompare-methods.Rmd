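---
title: "Benchmarking and combining circRNA call sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking and combining circRNA call sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circompare)
```

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts produced by
backsplicing: a downstream splice donor joins an upstream acceptor, and the
resulting out-of-order junction — the back-splice junction — is the only
sequence evidence that distinguishes a circle from its linear host. More
than a dozen prediction algorithms call such junctions from ribo-depleted
RNA-seq, and their outputs disagree substantially, both in how many
candidates they report and in how many of those survive the biochemical
gold standard: RNase R, a 3'→5' exonuclease that degrades linear RNA but
largely spares circles. A candidate that is *depleted* after RNase R
treatment behaves like a linear artifact and is treated as an operational
false positive; a candidate *enriched* beyond a fold cutoff is an
operational true positive.

`circompare` implements the full comparison-and-combination workflow on
top of that idea: harmonizing heterogeneous call tables, filtering,
classifying by RNase R response, and quantifying how much one algorithm
gains from intersecting its output with another.

## Harmonization

Tools emit BED-like tables in incompatible coordinate conventions. Every
input is declared through a *dialect* (`circ_dialect()`): its start basis,
strand reporting, and optional score columns. One-based dialects — in the
shipped registry: ACFS, circRNA_finder, CIRI, CIRI2, DCC and MapSplice —
have 1 subtracted from the start on read; the end is never touched. All
downstream work happens in 0-based half-open coordinates.

Junction identity defaults to strand-blind `(chrom, start, end)` matching,
because several tools report unknown or inconsistent strands and no
published strand-matching rule exists for cross-tool intersection; a
strand-aware mode is available via the `match_strand` switch everywhere
junctions are compared, and mixing the two policies is an error rather
than a silent mismatch.

Two further conventions are worth stating explicitly:

* Duplicate junction rows within one file are summed with a warning; this
  matches the definition of expression as the *sum* of back-splice reads.
* When per-sample outputs of one tool are merged (`merge_samples()`), tool
  score columns are combined by best supporting evidence — the maximum for
  numeric scores such as anchor mapping qualities, `any()` for logical
  flags. Merged runs report a candidate if any sample supported it, so
  the most favorable score is the one the merged row represents.

## Candidate filters

`apply_filters()` retains a candidate only if all of the following hold,
and attributes each removal to the first failing rule for logging:

1. **Read support**: at least 3 back-splice reads in at least *one*
   untreated sample (`min_reads_one_untreated`, default 3). This is a
   per-sample maximum, not a sum across samples — "one of the untreated
   samples" is per-sample language, and the two readings differ exactly on
   candidates with weak support spread over several libraries.
2. **Posterior probability** (tools that report one): below 0.9 is
   discarded; a candidate at exactly 0.9 is kept, since only values
   *below* the threshold are excluded.
3. **Mitochondrial candidates**: chrM-derived calls are removed wholesale;
   the mitochondrial genome is circular and its names vary by reference,
   so matching is against a configurable set (`chrM`, `MT`, `chrMT`).
4. **ciRNA flag**: circular intronic RNAs are a lariat-derived class
   excluded from the exonic analysis.
5. **Anchor quality** (optional, default off): requiring both anchors at
   mapping quality 40 reproduces the find_circ refinement that removes
   multimapper-driven artifacts such as tandem-gene mis-annotations.

The filter is a conjunction, hence idempotent and order-independent in its
retained set; the rule order above matters only for attribution.

## RNase R classification

Expression is the raw sum of back-splice reads over the control samples;
treated expression sums over all RNase R samples. No library-size
normalization is applied by default — raw junction reads are the published
convention for this design, and a `scale_factors` hook exists for datasets
that need one. With fold = treated/control:

* **resistant** — fold ≥ `resistant_min_fold` (boundary inclusive:
  "≥ 5-fold enrichment");
* **sensitive** — fold < `sensitive_max_fold` (strict: a candidate with
  treated exactly equal to control is *unchanged*, not sensitive);
* **unchanged** — everything between.

Two presets ship: `jeck` (5 and 1), for deep RNase R enrichment
experiments, and `mercer` (2 and 0.7) for designs with milder enrichment.
The strict-less-than convention at the sensitive boundary is a deliberate
resolution of an ambiguity (is fold = 1 a "reduction"?); it is surfaced
here rather than hidden, and the classification is a pure function of the
fold and the two cutoffs.

## Complementarity indices

For an ordered pair of classified call sets (a, b):

* **iTP** = |resistant(a) ∩ junctions(b)| / |resistant(a)| — the fraction
  of a's true positives preserved when only shared calls are kept;
* **iTN** = 1 − |sensitive(a) ∩ junctions(b)| / |sensitive(a)| — the
  fraction of a's false positives that intersection discards;
* **Complementary score** = (iTP × iTN)².

The square sharpens the distinction between pairings that are good on both
axes and pairings good on only one; the score is 1 only for a partner that
keeps every resistant candidate while removing every sensitive one, and 0
for self-pairing whenever any sensitive candidate exists. All three are
directional: (a, b) asks what b does *for* a.

Candidates classified *unchanged* contribute to neither index, though they
do count as part of the partner's junction universe. Undefined indices (a
call set with no resistant, or no sensitive, candidates) propagate as `NA`
rather than being coerced to 0 or 1 — coercion would silently reward
degenerate call sets. Scores are stored at full precision; the printed
2-decimal form is presentation only.

Three-wise scores use the consensus-intersection reading: a candidate of
`a` is kept only if present in *both* partners. This is the natural
extension of "shared output" to three algorithms, and it degenerates to
the pairwise score when the partners coincide; other readings (union of
partners, sequential intersection) exist, and no published formal
definition fixes one, so the choice is declared here and tested for its
internal consistency only.

Supporting diagnostics: `shared_by_k()` (consensus sets),
`rank_overlap_curve()` (overlap as a function of expression rank, raw
binned fractions without smoothing), `score_count_correlations()`
(Pearson r between each index and the call-set sizes of the two pair
members, with an exclusion list for re-running without an outlier
algorithm), and `top_n_sensitive_fraction()` (false positive load among
the top expressed candidates, ties broken by coordinates for
determinism).

## Mature length and RNase R sensitivity

`annotate_lengths()` estimates a circle's mature spliced length by
assuming it retains the internal splicing of a host transcript whose exon
boundaries coincide exactly with the back-splice coordinates; the length is
the sum of exon segments clipped to the junction interval, averaged
(unweighted) over matching isoforms. Exact-coordinate matching is used —
harmonization has already fixed conventions, and a tolerance window would
trade a clear failure mode (unmatched, `NA`, the de novo case) for a fuzzy
one. Unannotated junctions simply return `NA`.

`length_sensitivity_association()` relates length to log2 fold with a
Spearman rank correlation by default: the published observation is a
monotone trend ("longer circles are more RNase R sensitive") without a
stated test, rank correlation is invariant to the log transform and
tolerant of fold = 0, and the sign convention (negative = longer circles
more depleted) is fixed in the return value. Pearson on a moderated
log-fold (pseudocount 0.5) is available for users who want a linear
association.

## The synthetic experiment generator

Real benchmark inputs are terabyte-scale SRA runs; the generator
(`simulate_experiment()`) reproduces their *structure* so that every
pipeline stage is testable offline, with recovery of configured parameters
as the test surface. It draws:

* a junction universe of true circles and linear decoys on a toy genome
  (including a small chrM to exercise the mitochondrial filter);
* per-sample control counts from a negative binomial (default mean 15,
  dispersion 2 — deep-coverage junction counts with realistic
  overdispersion), shared across channels, since all tools read the same
  sequencing data; an optional per-channel binomial count-thinning models
  mapper sensitivity differences;
* per-junction RNase R folds: lognormal with median 8 for circles (safely
  above the 5-fold cutoff, with a tail of genuinely borderline circles)
  and median 0.3 for decoys; treated counts are negative binomial around
  fold × control mean;
* mature lengths, lognormal with median 555 nt; about half of the true
  circles are two-exon so spliced length < genomic span, and host
  transcript models are emitted alongside for the annotation module;
* an optional `length_decay` coefficient attenuating a circle's fold by
  `(length/555)^-decay` — a single multiplicative decay on the log-fold
  scale, the simplest mechanism consistent with the observed
  length–sensitivity trend; off by default;
* detection channels with per-channel sensitivity, decoy pools (channels
  sharing a pool have correlated false positives, the analogue of two
  tools built on the same mapper), and channel-unique "exotic" false
  positives with high counts and depleted folds — the main failure mode
  that intersection removes.

The default profile has 2500 circles, 2500 decoys, 2 + 2 samples and 11
channels named after commonly benchmarked tools, with sensitivities and
decoy rates spread so filtered call-set sizes land in a realistic range
(roughly 500–4000); sizes are emergent, never asserted. The same config
and seed give byte-identical output files.

What the generator does *not* model — and hence what passing tests cannot
show about real data: read-level errors and alignment, linear isoform
abundance, reference annotation errors, tool-specific coordinate quirks
beyond the start-basis shift, and any dependence between a junction's
expression and its detectability. Recovered sensitivities are measured on
the *post-filter* call set, so they carry a small (~0.5%) attrition from
true circles that fail the 3-read rule under the default count model; this
is well inside the recovery tolerance used in the tests.

## Numerical and testing choices

* Problem sizes in the test suite: brute-force oracle comparisons run on
  the full 11-channel default profile (~2000-candidate call sets);
  parameter-recovery properties use 20 seeds at 400–1000 true circles per
  run, sizes at which binomial sampling error is comfortably inside the
  asserted tolerances.
* The separable-regime confusion-matrix check uses deterministic counts
  and fold laws with effectively disjoint supports (enrichment lognormal
  median 10, sd 0.1 on the log scale; depletion median 0.3, sd 0.15), so
  rounding can move a realized fold by at most 1/30 — far from either
  cutoff.
* Ties in expression rankings are broken by (chrom, start, end);
  `write_bed()` sorts the same way, so all outputs are deterministic.
* Self-pairing, partner monotonicity, filter idempotence and the
  score's monotonicity in both indices are checked as properties over
  randomized fixtures with fixed seeds, not as single examples.

## Known limitations

* The three-wise definition is one defensible reading; numbers from other
  readings are not comparable.
* Dialects cover the merged BED-like exports of the supported tools, not
  their raw native outputs, which drift across versions.
* `length_sensitivity_association()` is correlational; it cannot separate
  "long circles are false positives" from "long circles suffer unspecific
  decay".
* The generator's channels are exchangeable given their parameters; it
  does not attempt to caricature specific tools beyond the shared-pool
  and exotic-FP mechanisms.
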