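---
title: "Assessing EV small RNA-seq libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing EV small RNA-seq libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Extracellular vesicles (EVs) carry a characteristic small RNA cargo —
miRNAs, Y RNAs, and fragments of rRNA, tRNA, snRNA, snoRNA and mt-tRNA —
whose profile depends strongly on how the vesicles were isolated and how
the library was prepared. `evqc` implements the complete assessment chain
for such libraries: reference-free inference of the 3' adapter pattern,
trimming, hierarchical biotype quantification, per-sample and per-study
quality gates, composition statistics, and EV-versus-donor-cell enrichment
analysis. A seeded simulator generates reference catalogs, manifests, and
FASTQ libraries with per-read ground truth, so each stage is validated
against known truth rather than against an external corpus.

This vignette documents the models, the tunable parameters, and the design
choices made where more than one reasonable convention exists.

# The synthetic data generator

Every simulated read is

```
[rand5 bases] + insert + [rand3 bases] + 3' adapter ...
```

truncated at the read length (default 51 nt, a typical small RNA
instrument configuration). Inserts are drawn from a catalog according to a
per-sample biotype composition. Catalog entries of fragment-source
biotypes (rRNA, tRNA, Y RNA, snRNA, snoRNA, mt-tRNA, lincRNA, and
genomic `host_other`) are stored full-length (80–150 nt) and contribute
random 18–35 nt windows, reproducing the fragment nature of those classes
without modeling their biogenesis; miRNA and misc entries are stored at
insert length (20–24 nt). The unassigned remainder of the composition
mass becomes uniform random sequence, expected to stay unmapped — this is
what exercises the mapping-rate gates. Per-feature abundances within a
biotype are log-normal (sigma 1 by default), giving the skew a
differential analysis has to cope with. Substitution errors are applied
per base at a configurable rate (0–5%); indels and ligation bias are not
modeled. Base qualities are constant Phred 40 because the assessment
chain inspects but never filters on qualities.

Catalog sequences are generated under a separation constraint: every
16-nt window of one entry differs from every 16-nt window of every other
entry by at least 3 substitutions. Since any longer aligned window pair
contains an aligned 16-mer pair, 1-substitution matching can then never
cross features, and error-free simulations must be recovered exactly —
the basis of the round-trip tests.

What the simulator does *not* emulate: sequence-dependent ligation bias,
isomiRs, true genomic multi-mapping, and non-host (microbial) reads
beyond a small decoy catalog. Passing the round-trip tests therefore
demonstrates correctness of the pipeline's logic, not robustness to every
artifact of real libraries.

# Adapter pattern inference

Some library kits place 0–8 degenerate bases between insert and adapter
at either end, and public metadata often records neither the adapter nor
these lengths. The inference uses only the reads and a miRNA catalog:

1. **Anchoring.** Up to `max_reads` (default 50,000) reads are scanned
   for an exact occurrence of the first 16 nt of any miRNA; the match is
   extended base by base while read and miRNA agree. Each anchored read
   yields its anchor offset (candidate 5' random-base count) and the
   suffix after the anchor (candidate 3' random bases + adapter).
2. **Calling.** The 5' random-base length is the modal offset (ties to
   the smaller value). For the 3' side, the suffixes are shifted by
   s = 0..8 and the per-position majority-base fraction of the first 8
   shifted positions is examined; the call is the smallest s at which
   *every* position reaches `consensus_threshold` (default 0.8). The
   minimum — not the mean — is used deliberately: a single residual
   random-base position (majority fraction ~0.25–0.3) then vetoes the
   shift, whereas an average would let two random positions hide behind
   six perfect adapter positions and undercall the random-base length.
   The adapter itself is the per-position majority base of the shifted
   suffixes, truncated at 30 nt or where coverage drops below
   `min_anchored / 2`; base ties break alphabetically so the call is
   deterministic.
3. **Support.** The reported support fraction is the share of anchored
   reads whose suffix matches the called adapter's first 10 nt within one
   mismatch at the called offsets. Fewer than `min_anchored` (default
   100) anchored reads, or no qualifying shift, yields a "none detected"
   result rather than a guess.

A raised `consensus_threshold` can only increase the called 3' length
(fewer shifts qualify), which is tested as an invariant.

# Trimming

The leftmost occurrence of an adapter prefix is removed together with
everything 3' of it. Minimum overlap is 7 nt; overlaps below 10 must be
exact while overlaps of 10 or more tolerate one substitution — a
deterministic stand-in for the conventional 10% error-rate matching. A
partial adapter running off the read end counts from 7 nt of overlap.
After adapter removal the called numbers of 5' and 3' random bases are
stripped; inserts shorter than 16 nt are classified "too short" and
discarded. Reads with no adapter occurrence pass through completely
untrimmed with their own status: the insert may simply fill the read, so
discarding (available via `discard_untrimmed`) is not the default, and
leaving them untouched makes trimming idempotent. The three statuses
partition the input exactly.

# Biotype assignment

Assignment is two-tier. Kept inserts are matched as substrings of host
catalog sequences with at most one substitution and no indels; exact hits
suppress one-mismatch hits. Inserts that fail the host tier and are
longer than 19 nt are matched exactly against the non-host catalog;
shorter unmapped inserts are never searched there, since a short exact
match to an exogenous database carries little evidence. A read counts
once toward the highest-priority biotype among its best hits (miRNA >
tRNA > rRNA > snRNA > snoRNA > Y RNA > mt-tRNA > lincRNA > misc >
host_other — the conventional ordering, configurable) and fractionally
(1/k) toward the k tied features of that biotype, so biotype counts stay
a partition while feature-level mass is conserved. CPM is feature count
times 10^6 over kept reads.

Internally the per-sample quantification deduplicates inserts, finds
exact hits with one Aho–Corasick pass per catalog entry, and screens the
remainder through a pigeonhole filter (one substitution leaves one
error-free insert half, which must occur exactly somewhere in the
catalog) before the full one-mismatch search. Tests verify the fast path
against a brute-force Hamming oracle.

# Quality gates

Per sample: the overall mapping rate (host + non-host over kept reads),
the host fraction, and the small RNA and miRNA fractions of host reads
(small RNA = all biotype counts except `host_other`). The default gates:
more than 100,000 kept reads; overall mapping rate at least 20%; at
least 100,000 host reads; host fraction above 50%; small RNA at least
75% and miRNA at least 10% of host reads. The strict/non-strict
direction of each boundary follows the wording of the corresponding rule
("more than", "minimum of", "greater than") and is documented in
`flag_sample()`; all thresholds are configurable, and zero denominators
yield a fraction of 0 plus the flag. A study is excluded when strictly
more than half of its samples fail either content gate — a decision that
depends only on those flags, never on raw counts.

Within-study variability is the median and IQR of small RNA proportions
per study, with IQR computed by linear-interpolation quantiles (R type
7) since no single convention is universal; studies with median > 0.9
and IQR < 0.06 are labeled high quality. Group contrasts of per-study
summaries (by donor source or isolation method) use Welch t-tests —
the safer default when variance equality is unknown.

# Composition statistics

Biotype proportions divide by total small RNA reads, with lincRNA (and
anything outside the eight reported classes) folded into misc so the
eight proportions always sum to 1 (tested to 1e-9). The log2 miRNA/rRNA
and Y RNA/tRNA ratios add a pseudocount of 1 to numerator and
denominator counts, keeping them finite when a class is absent.

# Enrichment analysis

**Biotype level.** For each biotype, proportion ~ compartment +
isolation_method + study is fit by least squares and the compartment term
tested with a type-II F-test (`car::Anova`), which is robust to the
unbalanced designs typical of multi-study collections. The isolation
method is the named confounder; study is the third factor because it is
the only remaining design variable in a multi-study setting. Proportions
are left untransformed. Main effects only — with at most a handful of
studies per isolation method, interaction terms would be mostly
inestimable. Factors with fewer than two levels, or a study factor fully
confounded with compartment, are dropped and the result annotated rather
than failing. Calibration is verified by simulation: the compartment
type-I error rate at nominal 0.05 stays within its 95% binomial interval
over 500 null simulations, and a planted 0.15 proportion shift is
detected with near-complete power at 3 studies x 10 pairs.

**miRNA level.** Within each paired study, each miRNA is modeled as
count ~ compartment + isolation_method with a log size-factor offset.
Size factors are median-of-ratios against the geometric-mean reference
(computed over zero-free features, falling back to scaled totals): raw
library totals are compositionally biased whenever a minority of features
changes strongly, which would shift every fold-change estimate. The NB
dispersion is estimated per feature by method of moments, pooled within
compartments and floored at 0.01, with no shrinkage across features —
recovery on synthetic data, not agreement with any particular external
tool, is the accuracy contract. The Wald statistic for the compartment
coefficient is referred to a t distribution with the model's residual
degrees of freedom; with a plug-in dispersion at small n the normal
reference is anti-conservative, and the t reference restores a
false-discovery proportion below 10% at n = 8 vs 8 while keeping
sensitivity near 100% for planted two-unit log2 fold changes.
Benjamini–Hochberg correction runs across tested features; significance
requires FDR < 0.05 and fold change > 1.5.

**Cross-study classification.** Per feature and study the call is
EV-enriched, cell-enriched, not significant, or untestable. A feature
EV-enriched in every testable study (at least `min_testable`, default 2)
is context-independent EV; the symmetric class exists for cell-retained
features. "Mostly EV" tolerates up to `k_tolerance` (default 3)
non-enriched studies but requires a majority of EV-enriched calls and no
cell-enriched call — without the majority condition a feature enriched
in one of three studies would absurdly qualify. Features significant
somewhere but inconsistent are study-specific.

# Numerical conventions and degenerate inputs

- All randomness flows from explicit integer seeds; per-stage seeds are
  derived from the run seed, and identical configurations reproduce
  byte-identical FASTQ and TSV outputs.
- Zero-read samples yield zero-valued profiles with a warning flag; CPM
  of an empty sample is defined as zero.
- Single-sample studies report IQR 0 with a warning annotation.
- Ties: modal-offset ties break to the smaller offset, consensus-shift
  ties to the smaller shift, majority-base ties alphabetically, so every
  call is deterministic.

# Problem sizes

The test and verification runs use desk-scale sizes chosen to make
sampling error negligible relative to the tested margins: 5,000-read
libraries across 100 seeds for adapter recovery; 3,000–4,000-read
samples for round-trip checks; 500 null and 200 shifted simulations for
ANOVA calibration; 50 seeds of 200 features at n = 8 vs 8 for
differential recovery; and 2 studies x 2 pairs x 2,500 reads for the
end-to-end determinism check.

# Limitations

The simulator's clean separation of catalog features removes genuine
multi-mapping ambiguity; real references contain paralogs and repeat
families that the fractional-count convention handles but the tests do
not stress. Adapter inference presumes the library contains a usable
share of full-length miRNA inserts; libraries dominated by degraded RNA
can fall below the anchoring minimum and are reported as "none
detected" by design. The differential model fits each feature
independently — with very few replicates, shrinkage-based tools will be
more powerful on real data, at the price of cross-feature coupling that
is harder to validate against planted truth.
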