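---
title: "Allele-resolved chromatin contacts and regulatory variants with ciscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved chromatin contacts and regulatory variants with ciscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciscope)
```

## The scientific setting

A constitutional promoter epimutation silences one allele of a gene in every
somatic tissue: one haplotype carries promoter methylation (the
methylation-associated allele, MAA) while the other remains active. The
canonical example is soma-wide monoallelic methylation of the bidirectional
*MLH1*/*EPM2AIP1* promoter CpG island, a rare cause of Lynch syndrome. When a
carrier is heterozygous for a variant inside the promoter — such as the
common c.-93G>A SNP, or a small deletion like c.-234_-236del — every
sequencing read spanning that position can be assigned to one haplotype. That
single observation powers the whole analysis: chromatin accessibility
(ATAC-seq), active-chromatin marks (H3K27ac CUT&Tag), transcription (RNA-seq)
and viewpoint chromatin contacts (UMI-4C) can each be split by allele and the
two haplotypes compared within the same cells.

`ciscope` implements that analysis as a reusable, tested pipeline:

1. **Allele demultiplexing** — assign aligned reads to a reporter allele and
   tabulate allele proportions per sample group.
2. **UMI-4C contact profiles** — unique-molecule contact counts over
   restriction fragments around a fixed viewpoint, split by condition and
   allele, aggregated into count-balanced smoothing windows.
3. **Differential contacts** — a per-window two-sided Fisher exact test with
   BH-FDR control, direction calls, and a multi-resolution domainogram.
4. **Overlap enrichment** — a permutation test for overlap between
   differential windows and accessible regions, plus consensus-peak voting.
5. **Rare-variant burden** — a phase-aware sliding-window scan for rare
   variant accumulation across the promoter-contacting region.
6. **Motif disruption** — PWM scanning with exact score p-values to classify
   variants that strengthen repressor motifs, weaken activator motifs, or hit
   insulator motifs.
7. **Synthetic data** — seeded generators for every input format, so each
   stage is testable without access-controlled patient data.

## Coordinates and data model

All internal coordinates are 0-based half-open (the BED/SAM convention), so
interval length is always `end - start` and adjacent intervals share a
boundary without ambiguity. Anything printed for a reader is 1-based
inclusive, the genome-browser convention; `from_one_based()`,
`to_one_based()`, `format_region()` and `parse_region()` convert exactly and
invertibly. VCF positions (1-based) are shifted on input; multi-allelic VCF
rows are rejected rather than split, because a single phase annotation per
row would be ambiguous after splitting. SAM `SEQ` fields are taken as
reference-oriented (standard SAM semantics); strand is carried as metadata
and never triggers re-complementing.

## Allele demultiplexing

`assign_allele()` walks the CIGAR to recover the bases a read aligns over the
reporter span. The design choices are deliberately conservative:

* A read must **fully span** the reporter to be counted; partial evidence is
  `NOT_COVERING`. This keeps proportion denominators interpretable.
* For a **deletion reporter**, the ALT call requires a deletion op covering
  the deleted span *exactly* (same start and end). Shifted or partial
  deletions fall into `OTHER`, guarding against local misalignment around
  indels.
* Any observed base that is neither allele is `OTHER` — a sequencing-error
  bucket, not an error. With a per-base substitution rate $\varepsilon$ and
  uniform error spectrum, the expected `OTHER` fraction at an SNV reporter is
  $2\varepsilon/3$ (errors toward the two non-allele bases), and the observed
  allele proportions are biased toward balance by flips at rate
  $\varepsilon/3$; the test-suite checks both.
* No base-quality filtering is applied: qualities are not modelled in the SAM
  subset. This is an extension point, not a modelling claim.

## Contact profiles and smoothing windows

UMI-4C counts unique ligation molecules between a viewpoint (bait) and the
restriction fragments around it. `digest_genome()` derives the fragment map
(DpnII `GATC` by default); fragments tile the chromosome and are the native
counting unit.

**Molecule identity.** A molecule is `(contact fragment id, UMI)` within one
condition-by-allele group. Ligation-junction offsets are not part of the key:
this is the simplest faithful deduplication, and the synthetic generator uses
the same key, so collision-induced undercounting is measurable (the generator
records collisions in its truth file).

**Viewpoint exclusion.** The viewpoint fragment and the 2 fragments on each
side are excluded by default (`smoothing_config()`), because self-ligation
and re-ligation artifacts dominate immediately around the bait. The zone is
configurable.

**Smoothing windows.** Walking away from the viewpoint on each side,
consecutive fragments are accumulated until the combined count across *all*
groups reaches `ceil(min_win_factor * T)` (default `min_win_factor = 0.03`,
so roughly 33 windows); a trailing partial window is merged into its
predecessor. Using combined counts means every group is tested on identical
windows — a prerequisite for a meaningful per-window 2x2 contrast — and makes
the windows invariant to swapping the groups. Near the viewpoint, where
counts are dense, windows are narrow; far away they are wide. This
count-balanced rule is this package's documented smoothing definition.

**Normalisation.** Window counts of the second profile are rescaled by
`totalA/totalB` so both trends sit on the first profile's depth. Total-count
scaling is the only depth difference the generator introduces; the function
is exposed so users can substitute another scheme.

## Differential contact testing

For each window the 2x2 table `[[a, A-a], [b, B-b]]` contrasts the window
count against the rest of the analysis region in each group, with `A` and `B`
the group totals after region restriction and viewpoint exclusion, so the
table is self-contained. The two-sided p-value follows the classical
probability-mass definition — the sum of hypergeometric probabilities of all
tables with the observed margins that are no more probable than the observed
table — with a `1e-7` relative tolerance on the inclusion comparison to keep
floating-point ties stable. The test-suite verifies this against exhaustive
enumeration for every margin pair up to 40 and against `stats::fisher.test`
on random tables. The odds ratio uses the Haldane–Anscombe 0.5 correction
when any cell is zero.

Windows with combined count `a + b < filter_low` (default 30) are excluded
both from testing and from the BH family; low-count filtering is independent
of the test statistic under the null, so the FDR guarantee is preserved.
Directions are called at `q < alpha` (default 0.05) by the sign of
`b/B - a/A`: `gained` means group 2 (conventionally the epimutant allele) is
enriched.

The **domainogram** displays `mean log2((norm_b + 1)/(norm_a + 1))` over `k`
consecutive windows for `k = 1..K`, trading spatial resolution for stability;
its scale-1 row is exactly the per-window log2 fold change. The pseudocount
of 1 on normalised counts keeps empty windows finite.

**What FDR control does and does not promise.** With eight strong effects
and ~33 windows, BH at 0.05 admits on average `0.05 x (#discoveries)` false
windows per run — about one. Zero false positives per run is therefore *not*
a property of the method, and the test-suite checks the pooled false-discovery
fraction across a 10-seed suite against `alpha + 3` Monte-Carlo SE rather
than demanding spotless runs.

## Overlap enrichment and consensus peaks

The permutation null re-places every differential window independently and
uniformly within the analysis region, preserving its width; windows may
overlap each other. This is the simplest defensible null for "do differential
contacts sit on accessible regions more than chance expects"; it is not
GC-matched or fragment-density-matched (out of scope, and documented as
such). The empirical p-value uses the add-one correction
`(1 + #{null >= obs})/(n_perm + 1)` and therefore never returns an exact
zero. On a toy instance small enough to enumerate placements exactly, the
estimate converges to the exact overlap probability; the suite checks this at
`n_perm = 10000` within 3 binomial SE.

`consensus_peaks()` merges the union of per-sample peak sets into maximal
blocks and keeps a block only when *strictly more than* `min_samples`
distinct samples overlap it (default 2, i.e. at least 3 supporters) — the
strict reading of condition-consensus voting.

## Rare-variant burden

Variants with population allele frequency below 1% are rare; variants with
*missing* AF are kept and flagged, on the reasoning that absence from the
population database implies rarity. The scan slides a 10 kb window in 1 kb
steps across the region (an ~800 kb promoter-contacting region resolves into
~800 windows); both are configurable, and with `step = width` the windows
partition the region and counts are conserved exactly. Each window reports
the number of rare variants and the subset annotated in phase with the MAA;
ties in the argmax are all reported.

## Motif disruption

A position probability matrix becomes a log-odds PWM via
$\mathrm{score}(j,b) = \log_2\frac{p_{jb} + c\,\pi_b}{(1+c)\,\pi_b}$ with
pseudocount $c = 0.01$ and background $\pi$ (uniform by default,
configurable). Relative scores rescale to `[0, 1]` between the matrix's
minimum and maximum attainable scores; promoter scans report hits at relative
score >= 0.80 by default. Both strands are always scanned.

`score_pvalue()` computes `P(score >= t)` under the background model by exact
convolution of per-position score distributions on an integer grid (grain
`1e-3` score units). The inclusion comparison carries a `floor(L/2) + 1`
grid-cell slack so rounding can never exclude a sequence whose true score
reaches the threshold; in exchange, sequences within about `(L+2)/2 * grain`
score units *below* the threshold may be counted, so near exact ties the
p-value is a slight over-estimate bounded by the probability mass in that
band. The suite verifies exact agreement with `4^L` enumeration at
well-separated thresholds for all motifs up to length 6.

`score_variant()` builds the reference and alternate sequences over the
variant span plus `L - 1` flanking bases, scores each allele's best hit over
both strands, and calls the motif *matched* when either allele's best score
has `score_pvalue <= 1e-4`. Indels are handled by realising the alternate
sequence and rescanning — no per-position correspondence is attempted, which
keeps the definition exact for arbitrary indels. Matched variants are
`strong` when `|delta| >= 0.2` relative-score units (`weak` below); the 0.2
default is this package's explicit, configurable strength rule — external
motif tools keep their internal "strong" labels undocumented, and nothing
downstream depends on reproducing them. Classification is then a pure rule:
repressor motif with `delta > 0` is a `repressor_gain`, activator motif with
`delta < 0` an `activator_loss`, a strong hit on an insulator motif an
`insulator_hit`, anything else `none` — gains of activators and losses of
repressors are deliberately not flagged.

## The synthetic-data generator

Every generator is a pure function of one seeded configuration
(`simulation_config()`); stage seeds are derived from the master seed by
fixed offsets so stages are independently reproducible, and repeated runs are
byte-identical. The defaults encode the study conditions the package
targets:

* a 1 Mb analysis region centred on a promoter viewpoint, with a heterozygous
  G>A reporter whose alternate allele rides the methylated haplotype;
* balanced reporter-read fractions in controls versus 1% MAA / 99% non-MAA in
  epimutant samples (the near-monoallelic accessibility regime), 10,000 reads
  per group at a 1% substitution error rate;
* contact molecules sampled with weights `(1 + |d|)^-1` around the viewpoint
  (a power-law distance decay; the decay exponent is a parameter, not a
  claim about chromatin physics), 10,000 molecules per group, 10-base UMIs
  with collisions allowed and truth-tracked;
* **eight implanted differential windows** — four gained at 2.5x, four lost
  at 0.4x on the epimutant MAA. Because molecules are drawn with a fixed
  count per group, multiplying weights inside implants rescales every other
  fragment's sampling probability; the default implants are therefore placed
  and sized so the extra gained mass balances the removed lost mass (net
  shift under the default decay ~0.4%), keeping non-implanted windows null.
  Implant widths also track the local count-balanced window width so each
  implant covers enough of a smoothing window to be detectable at the default
  depth;
* 99 rare variants (AF < 1%), 34 in phase with the MAA, 12 of them clustered
  in a 10 kb interval inside one upstream differential contact, plus 60
  common variants;
* a motif library mixing sharp and flat PPMs with roles assigned round-robin.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: realistic error spectra and base qualities,
ligation-junction read structure and bait trimming, replicate-level
biological variability (groups are pooled, as the allele-split design pools
by condition x allele), chromatin-state-dependent contact structure beyond
monotone distance decay, methylation levels themselves, and linkage structure
among variants. Tests on generator output validate the *machinery* —
counting, windowing, testing, calibration — not biological discovery.

## Numerical choices and degenerate inputs

* Fisher ties: `1e-7` relative tolerance on probability-mass inclusion.
* PWM p-values: grain `1e-3`, slack `floor(L/2) + 1` cells, documented
  over-estimate band; relative scores are clamped to `[0, 1]` against
  summation-order rounding.
* Zero cells: Haldane–Anscombe 0.5 for odds ratios; pseudocount 1 in
  domainogram log ratios; add-one correction in permutation p-values.
* Degenerate inputs: empty peak files give empty interval sets; a group with
  zero covering reads reports `NA` proportions (never 0/0); a profile with
  zero molecules is an error where scaling is required and an empty result
  where counting suffices; windows below `filter_low` are reported but carry
  `NA` statistics; variants without full motif flanks are flagged `partial`
  and not scored.
* Problem sizes in the test-suite (chosen to exercise the statistics at
  realistic depth while keeping the default run quick): the full Fisher sweep
  to margins 40; 200 null contact replicates at 5,000 molecules per group;
  10 recovery seeds at 10,000 molecules; demultiplexing at 10,000 reads per
  group; `4^L` motif enumeration to length 6.

## Limitations

The pipeline pools samples by condition and allele, so it inherits the
limited statistical power of small family studies; dispersion-aware count
models and replicate-level variance are out of scope. The permutation null
ignores sequence composition. The smoothing rule and the motif strength rule
are this package's own documented definitions — reasonable, configurable
stand-ins where upstream tools leave their internals unspecified — so
numerical agreement with those tools' outputs on real genomes should not be
expected, and nothing here depends on it.
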