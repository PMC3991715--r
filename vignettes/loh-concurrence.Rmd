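---
title: "Calling LOH tracts and assessing their concurrence in paired samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling LOH tracts and assessing their concurrence in paired samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohtrack)
```

## The model

Loss of heterozygosity (LOH) is the somatic loss of one parental allele.
At a biallelic locus it is visible as a germline heterozygote (an
*informative marker*) that is homozygous in a tissue sample: a HET→HOM
event. With copy-number information attached, LOH subdivides into
copy-neutral, copy-loss and copy-gain LOH; the copy-neutral form — two
copies of one parental allele, invisible to pure dosage methods — is the
common case in the tissues this package targets.

`lohtrack` works on a paired genotype table: an ordered panel of
autosomal biallelic loci with one call per sample from
`{AA, AB, BB, NC}`. Every germline/tissue call pair falls into exactly one
of ten transition categories (`classify_transitions()`); the partition is
total and symmetric under relabelling the two alleles, both of which are
enforced by exhaustive tests.

An **LOH tract** is a maximal run of HET→HOM events. Interior loci of a
run may be HOM→HOM, monoallelic mutations (AA→AB), or the one-sided
no-call pairs HOM→UNK and UNK→HOM; a run is terminated by HET→HET,
HET→UNK, UNK→UNK, UNK→HET, a biallelic mutation (AA→BB), a copy-number
state change, or an arm boundary. Tract coordinates are the outermost
supporting events and the length is inclusive (`end − start + 1`), so a
tract supported by a single event has the minimum length of 1 bp. The
inclusive convention is forced by that 1 bp minimum and is applied
uniformly to tract, overlap and extension lengths.

Two design points here were genuinely open and are package decisions:

* HOM→UNK and UNK→HOM are not terminators. Every terminator carries
  positive evidence against continued allele loss (an observed tissue
  heterozygote, or total information loss at an informative locus); a
  no-call over a germline homozygote carries none. They are, however,
  counted into the no-call QC fractions.
* Monoallelic mutations do not terminate a run — they are genotyping
  noise or true point events, not evidence of retained heterozygosity —
  but they are the numerator of the QC monoallelic fraction, so a run
  polluted by them is excluded rather than split.

## Calling parameters

`loh_params()` collects the tunables:

* `min_events` (default 2): support criterion. Single-event tracts have a
  high false-positive rate, so the stringent criterion (≥ 2 events) is
  the default and the loose one (≥ 1) is available for sensitivity
  analyses. Every ≥2-event tract is also a ≥1-event tract; this
  monotonicity is property-tested.
* `gap_threshold_bp` (default 40,000): on sparse array panels, a
  copy-neutral run whose consecutive events are more than this far apart
  is split and the gap called unaffected. The default corresponds to the
  upper outer fence (Q3 + 3·IQR) of heterozygous-marker spacing on a
  common genotyping array; `derive_gap_threshold()` recomputes the fence
  from any spacing sample using linear-interpolation quantiles
  (`stats::quantile` type 7). Splitting is strict (`> 40 kb`), one pass
  over all qualifying gaps, with the fragments re-filtered by
  `min_events`; it applies to copy-neutral tracts only, since loss/gain
  segments are already bounded by the CNV evidence.
* `platform` (`"array"`/`"sequencing"`): sets two defaults. Sparsity
  splitting is on for arrays and off for sequencing panels (markers dense
  enough that a 40 kb event gap is itself informative). The CNV
  minimum-length filter (`cnv_min_length_bp`, default 100 kb) applies to
  sequencing-derived (read-depth) CNV input, where short calls are
  unreliable; array CNV segments are taken as given.
* `qc_monoallelic_max`, `qc_nocall_max` (default 0.20 each): a tract is
  excluded when its monoallelic fraction, or the germline or tissue
  no-call fraction, *strictly* exceeds the bound — a tract at exactly 20%
  is retained. Denominators are all panel loci the tract spans, not only
  informative ones; this keeps the bounds stable at high marker density
  and is a package decision where practice varies. QC runs last, on the
  final (post-split) tracts, so the metrics describe the tracts actually
  reported.

Variant-level ingest QC is separate (`ingest_qc()`): variants with cohort
call rate below 95%, or with three or more no-calls across the configured
sample set, are dropped before calling, with defaults matching common
array and trio-sequencing practice.

## Concurrence and overlap patterns

Tracts from two samples of one patient are *concurrent* when they share at
least 1 bp (`find_concurrent()`). Concurrence rates are per tract, not per
pair: a tract spanning three partners counts once in its direction's
numerator. Overlapping pairs are classified (`classify_overlap()`) into

* `EQUAL` — identical endpoints;
* `EXA_S`/`EXB_S` — one shared endpoint, the low-/high-stage tract longer
  (single-end extension);
* `EXA_D`/`EXB_D` — strict containment with both endpoints differing
  (double-end extension);
* `PARTIAL` — staggered overlap, neither containing the other.

Containment is deliberately classified as double-end extension rather than
partial overlap: partial overlap is reserved for pairs where each tract
has territory the other lacks. The six classes partition all overlapping
interval pairs — verified exhaustively over every pair of intervals of
length ≤ 6 on a 12-position axis — and swapping the two samples maps
Exa↔Exb and fixes Equal/Partial. Endpoint equality is exact position
equality, which is well-defined because both samples are called on the
same locus panel.

`overlap_summary()` tallies classes and computes
`prop_of_change = (Total − Equal)/Total`, the fraction of concurrent
pairs whose boundaries moved between samples. Counting is pair-level (a
tract overlapping two partners contributes two records), which preserves
the length bookkeeping; the convention is recorded in output provenance
since published tallies do not state theirs.

## The permutation null

To ask whether observed concurrence exceeds chance, tract locations are
shuffled uniformly along their own chromosome arm (`shuffle_tracts()`),
keeping arm and length fixed — LOH abundance differs strongly between
arms, so a genome-wide shuffle would answer the wrong question. Placement
excludes 3 Mb adjacent to the centromere and 10 kb at the telomeric end of
each arm (`eligible_interval()`); both exclusions are configuration, and
the arm table itself is user-supplied because centromere coordinates
depend on the genome build. Tracts that land overlapping are merged into
one, which loses a small fraction of tracts per iteration (reported, on
realistic densities a few percent). A tract longer than its arm's eligible
interval is kept in place with a warning rather than discarded.

Both tract sets are shuffled by default (`shuffle_which = "both"`);
single-set variants exist because either convention is defensible. The
one-sided empirical p-value uses the standard `(b + 1)/(n_perm + 1)`
estimator, and the result also carries the null min/mean/max so the
distribution can be reported directly. With one tract per set (lengths
L, M; eligible length E) the null overlap probability is approximately
`(L + M − 1)/E`; the test suite verifies the simulated null against this
closed form (itself checked by exhaustive enumeration on a toy arm) and
byte-exact seed reproducibility.

## Burden profiles and enrichment

`arm_profile()` divides each arm's summed tract length by the arm length,
giving a dimensionless burden whose per-arm totals exactly sum to the
sample total (an integer identity the tests assert).
`cohort_arm_summary()` reports median and quartiles per arm and stratum;
`profile_correlation()` computes Pearson r between two profiles with a
two-sided p from the t transform on `#arms − 2` degrees of freedom
(cohort-mean profiles by default; the method is a package choice as
published analyses rarely state theirs).

`gene_concurrence()` counts, per gene, patients whose two samples both
have a qualifying tract in the gene (*concurrent*), patients where some
tract pair and the gene share ≥ 1 bp (*concurrent with overlap*), and
patients with ≥ 1 germline heterozygote in the gene (*informative*).
Only informative patients contribute to the concurrence columns. This
gating is a deliberate resolution of a tension in the interval-level
counting rule: a tract can span a gene that contains no informative
marker, and counting such patients as concurrent would break the nesting
`overlap ≤ concurrent ≤ informative` that the informative-patient
denominator implies. Gene–tract overlap is interval-level: the tract must
reach into the gene, but its supporting events need not lie inside it.

`category_enrichment()` tests over-representation of a gene category
among top-concurrence genes (default cut: ≥ 6 patients with overlapping
concurrent LOH) with a df = 1 chi-square goodness-of-fit statistic,
no continuity correction, against either of two baselines — the category
proportion over all genes or over genes with ≥ 1 concurrent patient —
both implemented because both are in circulation; results label which was
used and flag expected counts below 1 as unreliable.

## The synthetic-data generator

`sim_config()`/`simulate_patient()`/`simulate_cohort()` emulate the data
this pipeline consumes, with recorded truth:

* Marker positions are a Poisson process (exponential gaps, default mean
  3 kb, array-like), which makes the spacing fence well-defined;
  germline heterozygosity defaults to 30% per marker, typical of
  common-variant array panels.
* No-call rates default to 0.44% (blood) and 1.65% (tumor tissue),
  matching array no-call rates reported for such cohorts; monoallelic
  (0.2%) and biallelic (0.05%) mutation noise are set at realistic small
  rates.
* Low-stage tracts are planted on arms drawn by a weight vector, with
  log-uniform lengths (default 50 kb–2 Mb); overlapping placements merge
  in truth. The high-stage sample inherits each tract with probability π
  (default 2/3, the regime of interest) extended per-end by geometric
  draws, plus independent tracts — so Equal, single- and double-end
  extension arise with computable probabilities.
* Planted tracts default to copy-neutral; CNV segments are drawn
  independently per tissue sample.
* Cohorts share one annotation and weight vector; T-stage strata are
  allocated proportionally (largest remainder, shuffled order) rather
  than multinomially so a small cohort cannot lose a stratum by
  accident, and planted burden scales with per-stratum multipliers
  (defaults 1/2/3).

What the generator does **not** model: linkage disequilibrium, realistic
allele-frequency spectra, tumor purity/contamination gradients, genotype
intensity data, or read-level error processes. Passing recovery tests
therefore demonstrates correctness of the tract/overlap/permutation logic
under the stated noise model, not calling performance on raw platform
output — genotype and CNV calling are upstream of this package by design.

## Verification and problem sizes

The test suite runs entirely on generated data. The scanner is checked
against a brute-force enumeration of maximal terminator-free event runs on
2,000 random paired vectors of up to 50 loci (both support criteria); the
overlap classifier exhaustively on a 12-position axis; the permutation
null against the analytic uniform-overlap probability for three (L, M, E)
triples at 5,000 permutations. End-to-end synthetic experiments use a
2-chromosome, 50 Mb genome at 2–3 kb marker spacing for exact-recovery and
QC-exclusion checks; a 22-chromosome, 2.6 Gb genome at 8 kb spacing with
200 planted tracts per sample and 20 replicate seeds for the
inheritance-rate recovery (pooled estimate checked against the binomial
95% band around π = 2/3); and 6–9 patient cohorts for stage-ordering and
arm-weight rank recovery. These sizes keep the full suite in the
single-digit minutes while leaving every estimate comfortably inside its
sampling tolerance.

## Known limitations

* Analysis is restricted to autosomes; sex chromosomes, multi-allelic
  variants and phasing are out of scope.
* Whether QC should run before or after sparsity splitting, and whether
  the split should re-apply iteratively after re-filtering, are not
  settled by practice; the package applies QC last and splits in one
  pass. Both choices only matter for pathological marker layouts.
* The permutation merge rule slightly deflates null tract counts (the
  merged fraction is reported); no density- or GC-matched null is
  offered.
* Gene-level counting performs no multiple-testing correction across
  genes, matching the descriptive use of these tables; the enrichment
  test is a single pre-specified category comparison.
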