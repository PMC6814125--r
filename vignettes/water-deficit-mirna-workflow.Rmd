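---
title: "Methods: miRNA, isomiR, degradome and target-mimic analysis of the water-deficit root growth zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: water-deficit miRNA workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This document records the statistical model, the processing rules, and the
reasoning behind every configurable parameter in `rootmir`. It is a methods
reference, not an executable tutorial; the `analysis/` scripts run the whole
pipeline and the README shows worked examples with output.

## 1. Study design emulated by the generator

The synthetic-data generator reproduces the design of a water-deficit
experiment on the maize primary-root growth zone: three watering treatments —
well-watered (`WW`), mild (−0.3 MPa) and severe (−1.6 MPa) water deficit —
with four biological replicate libraries each. `sim_config()` bundles all
knobs; `make_reference()` builds a miRBase-style reference in which every
mature miRNA is a subsequence of its hairpin, one family contains two members
with identical mature sequences (to exercise merged-ID reporting such as
`miR399e,i,j-3p`), transcripts carry planted antiparallel binding sites with a
configured mismatch count, and exactly one transcript carries a target-mimic
region.

Every simulated read, tag, count and Ct value is emitted together with truth
labels, so each pipeline stage can be scored exactly.

What the generator deliberately does **not** emulate: genome alignment and
multi-locus genomic origin of reads, ligation/sequence-composition biases,
RNA secondary structure beyond the hairpin subsequence relation, degradome
tags from transcripts outside the supplied set, and amplification-efficiency
variation in qPCR. Conclusions about those factors are out of scope.

## 2. Read cleaning

* **Quality rule.** A read is dropped iff any base in its leading window has
  Phred < 25 (strict). The window is 25 nt for small-RNA reads and 20 nt for
  degradome reads; reads shorter than the window are evaluated over their full
  length rather than auto-dropped.
* **Adapter trimming.** The read is truncated at the first exact occurrence of
  the first 8 adapter bases (`min_overlap = 8`). Shorter terminal fragments
  are kept — with ≥ 18-nt inserts and an 8-base prefix this is the
  conservative choice.
* **Unique-tag collapse.** Identical sequences collapse to one tag with a
  count; tags shorter than 18 nt are discarded (the minimum credible sRNA).
* **Ambiguity guard in the generator.** If a simulated insert happened to
  contain the 8-base adapter prefix, no trimmer could recover the labeled
  insert, making the truth label unsatisfiable. The generator therefore
  redraws canonical matures whose first prefix match is not at the true
  insert/adapter boundary and downgrades any variant read with an earlier
  prefix match to its canonical sequence. This keeps "exactly the planted
  violations are removed" a meaningful, testable statement.

## 3. Quantification and isomiR classification

Tags matching a mature sequence exactly are canonical; members sharing a
mature sequence form one merged-ID group counted once. Other tags are
classified by `classify_isomir()` against every merged group:

* End offsets: 5′ offset in [−2, +2], 3′ offset in [−3, +3]
  (positive = 5′ truncation / 3′ extension), at most 2 internal
  substitutions. These bounds cover the common plant isomiR space without
  letting unrelated tags alias onto a miRNA.
* 3′ extensions are compared with the next hairpin bases; `templated3` is
  `TRUE` only when all extension bases are templated.
* The best interpretation minimizes the cost triple
  (substitutions, untemplated end bases, total |offset|) lexicographically —
  end variation is biologically cheap (imprecise DCL processing), untemplated
  tailing rarer, internal substitutions rarest. Remaining ties go to the more
  abundant canonical (when abundances are supplied) or reference order.
* **Class combination rule:** classes are `canonical`, `5p_variant`,
  `3p_variant`, `both_variant`, `internal_variant`, `variant_novel`. When a
  tag has both an end offset and internal substitutions, the end-based class
  wins and substitutions are reported in the fields — end identity determines
  target specificity (seed register), so it takes precedence.
* IsomiR counts are never added to canonical counts.

Abundance is reported as RPTM (reads per ten million mapped tags); the
retention filter keeps a miRNA when ≥ 3 of the 4 libraries of at least one
treatment group reach ≥ 1 RPTM.

## 4. Differential abundance

Tests run on **raw counts** with TMM normalization (never on RPTM, which
destroys the mean–variance relation). `nb_test()` uses the edgeR
quasi-likelihood F-test (`calcNormFactors` → `estimateDisp` → `glmQLFit` →
`glmQLFTest`); this established implementation is used deliberately instead of
re-deriving NB GLMs. Reported `log2FC` comes from normalized group means with
a library-size-scaled prior count of 0.125, so all-zero groups stay finite;
the raw GLM coefficient is kept as `edger_log2FC`. P-values are adjusted by
Benjamini–Hochberg via `stats::p.adjust` (`bh_adjust()` is a thin wrapper,
property-tested against an independent step-up implementation).

`replicate_qc()` reports the biological coefficient of variation (square root
of the common NB dispersion of the top-100 features), 2-D MDS coordinates
(leading log-fold-change distances via `limma::plotMDS`), and outlier flags. A
library is flagged when its median distance to within-group peers exceeds the
median of all within-group distances by 3 MADs **and** by a factor of 3. The
absolute factor-of-3 guard exists because on clean data the MAD of within-group
distances can be nearly zero, which would flag ordinary replicate scatter;
with the guard, across simulation seeds clean libraries are never flagged
while a permuted (profile-destroyed) library always is (its distances are
~15–20× the typical within-group distance).

## 5. Degradome (PARE) target validation

Binding sites are antiparallel alignments: miRNA position *i* (5′→3′) pairs
the transcript base `site_start + M − i`. G:U wobble counts as a **mismatch**
by default (`gu_policy = "mismatch"`) — the strictest reading of a plain
"mismatches" rule — with `"match"` and `"half"` available. A site is a valid
target iff at least one degradome tag 5′ end falls on a base paired to miRNA
positions 9–11 **and** the site has fewer than 4 mismatches. Signal categories
follow t-plot practice: `dominant-peak` (the transcript-wide maximum lies only
at 9–11 bases), `co-dominant` (tied with an outside position), `minor`.

Degradome reads are reduced to 20-nt 5′ tags ("retain" mode keeps the first
20 nt of longer reads; "literal" mode instead keeps the remainder, for
chemistry where the tag follows a fixed prefix). Multi-mapping tags are
counted at every locus and flagged; `unique_only = TRUE` drops them.

## 6. Target-mimic scan

A mimic locus pairs a transcript region of length M + b with the miRNA,
where a transcript-side insertion of b ∈ {1, 2, 3} bases sits between the
partners of miRNA positions j+1 and j for j ∈ {9, 10} — i.e. a bulge opposite
the slicing site (miRNA positions 10–11), the IPS1/pilncr1 architecture. At
most 3 mismatches are allowed among paired positions. Windows containing a
perfect ungapped complement are cleavable sites, not mimics, and are excluded.
Overlapping alternative interpretations of one locus collapse to the best
(fewest outside mismatches, then smallest bulge, then leftmost).
`mimic_report()` joins each locus with degradome validity (a genuine mimic
shows none) and transcript differential abundance (a stress-induced mimic is
up-regulated). With `max_insert = 0` the scanner degenerates to the ungapped
site scan, which is cross-checked against `find_sites()` in the tests.

## 7. qPCR (ddCt)

Technical triplicates are collapsed by mean; per biological replicate,
dCt = Ct(target) − mean Ct(references); ddCt subtracts the calibrator-mean
dCt; RQ = 2^(−ddCt) with amplification efficiency fixed at 2. The calibrator
RQ is 1 by construction; RQ is invariant to machine Ct offsets, and using two
references equals averaging their Ct (both contract-tested).
`select_reference()` ranks candidates by the SD of their treatment-mean Ct and
accepts those ≤ 0.3 cycles — about a 1.23-fold drift across treatments,
comfortably below the ~2-fold changes of interest while still achievable by
genuinely stable miRNAs under the simulated noise (σ_bio = 0.15,
σ_tech = 0.1 cycles).

## 8. Simulation parameter choices

* `n_families = 26`, `members_per_family = 3` (~78 miRNAs), 4 libraries per
  group, `library_depth = 4e6`: desk-scale problem sizes chosen for this
  package; they mirror the order of magnitude of a real growth-zone library
  set while keeping the full test suite in minutes.
* `dispersion = 0.1` (BCV ≈ 0.32): typical for biological replicates of a
  tissue under controlled stress.
* `fold_changes = c(0.125, 0.25, 4, 8)` and
  `spike_min_abundance = 10^-4.5`: with n = 4 and BCV ≈ 0.32, a 2-fold change
  has only ~50% power, and effects planted on features below ~3 counts per
  million cannot be recovered at any fold. The default effect grid therefore
  plants ≥ 4-fold changes on quantifiable features, where the DE route should
  — and does — achieve recall ≥ 0.9 at controlled FDR. The point of the
  defaults is a benchmark with a defined answer, not a claim that small
  effects don't occur; both knobs are user-configurable.
* `de_fraction = 0.4` with pattern probabilities 0.6/0.3/0.1 for
  severe-only / both / mild-only mirrors the empirical structure where most
  responders react only to severe stress; "both"-pattern features get a
  compressed mild effect (`2^(0.6·log2(fold))`) because mild responses are
  weaker than severe ones.
* Degradome: `tags_per_site = 50`, `peak_fraction = 0.8`, `noise_rate = 0.01`
  — a clear dominant peak with realistic background; the validity rule only
  needs one 9–11 tag, so results are insensitive to these within wide ranges.

## 9. Limitations

* The generator's truth labels define correctness for the classifier and
  filters; agreement rates measured on it do not transfer to real libraries
  with sequencing error, RNA modifications, or unannotated miRNAs.
* `nb_test()` inherits edgeR's behavior for extremely low counts and its
  QL approximations at n = 4.
* The mimic scanner requires the bulge opposite positions 10–11 with at most
  a 3-nt insertion; non-canonical mimic geometries are not searched.
* Reference selection by treatment-mean SD is a pragmatic stand-in for
  algorithms such as geNorm/NormFinder.
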