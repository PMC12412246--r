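---
title: "quadloop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadloop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadloop)
```

`quadloop` implements the downstream, integration layer of a G-quadruplex
(G4) profiling study: everything after peak calling, loop calling and read
quantification. This vignette explains the statistical models and the
decisions behind them, in the order the pipeline runs them.

## Coordinates and containers

All in-memory intervals are `GRanges`; every file-facing reader and writer
converts to and from the 0-based half-open BED convention, which is also the
convention of the documentation and of `granges0()`, the constructor used
throughout the tests. Gene models are a plain table (`gene_id`, `chrom`,
`strand`, `tss`, gene-body span, optional exon blocks); the TSS is the
span's first base in gene orientation.

Promoter windows are strand-aware and symmetric about the TSS *base*: with
upstream $u$ and downstream $d$, a plus-strand gene gets
$[\mathrm{tss}-u,\ \mathrm{tss}+d)$ and a minus-strand gene the mirror
image $[\mathrm{tss}-d+1,\ \mathrm{tss}+u+1)$, both clipped at position 0.
The default $u = d = 2000$ bp follows the common display convention of
signal curves around the TSS; the true promoter span behind any given
published percentage is rarely stated, so the window is a parameter
everywhere it is consumed. Peak-to-feature annotation assigns the peak
*midpoint* to the single highest-priority overlapping category
(Promoter > Exon > Intron > Downstream(≤3 kb) > DistalIntergenic), with
gene ties broken by TSS distance then identifier; midpoint assignment makes
the category fractions sum to exactly 1, which downstream summaries rely
on. A `FivePrimeUTR` level exists in the factor but is never assigned —
the gene models carry no UTR resolution.

## PQS scanning

A putative quadruplex-forming sequence is at least four G-runs separated by
loops. Four structural families are scanned, with defaults in
`pattern_config()`:

| family | tract | loops | note |
|---|---|---|---|
| canonical | ≥3 G | 1–7 nt | |
| long loop | ≥3 G | 1–12 nt, max loop ≥8 | |
| bulge | one tract split by a single 1–7 nt non-G insertion, total ≥3 G; others ≥3 G | 1–7 nt | |
| two-quartet | ≥2 G | 1–12 nt | tracts of exactly 2 allowed |

The scanner decomposes each strand into maximal G-runs and chains eligible
runs whose inter-run gaps fit the family's loop bound. Three matching rules
are deliberate choices where raw regular expressions are ambiguous:

* **Maximal, leftmost-longest matches.** The regexes admit nested and
  overlapping matches; we extend every chain as far as it goes and resolve
  overlaps within a family leftmost-longest. This mirrors common PQS-scanner
  behaviour and makes output deterministic.
* **Subtype precedence.** Where families overlap at a locus, the kept hit is
  the highest-precedence one: canonical > long_loop > bulge > two_quartet.
  A canonical match inside a long-loop chain therefore survives as
  canonical and suppresses the chain. One consequence worth knowing: a
  canonical-pattern match is by construction also an extended-pattern match,
  and the precedence rule is what keeps its label canonical.
* **Loops may contain G, never N.** Loop stretches are whatever lies between
  qualifying tracts (shorter G-runs included, matching the `\w` of the
  printed patterns restricted to `ACGT`); `N` never matches a tract or a
  loop, so assembly gaps cannot seed or bridge hits.

Both strands are scanned; minus-strand hits are reported in plus
coordinates with the sequence in G4-forming orientation. The whole scanner
is validated hit-for-hit (coordinates, strand, subtype) against an
independent brute-force enumerator that tests run-boundary substrings
against the structural definitions — the two implementations share no code,
and the test suite runs them over hundreds of seeded random sequences.

`classify_subtype()` exposes the taxonomy directly for structures obtained
elsewhere; `peak_pqs_overlap()` scans whole chromosomes once and flags each
peak PQS-positive on ≥1 bp overlap with any hit on either strand.

## Peak landscape

`compare_peak_sets()` counts sharing from each side separately because
overlap is many-to-many — a single merged "Venn" number hides the
asymmetry, so we report both counts plus the size of the merged union.
Signal correlation works on fixed-width binned tracks (1-kb default) over
the union of touched bins with absent bins as 0, optionally restricted to a
region set; Pearson r is invariant to affine rescaling of either track,
which the suite asserts. TF co-binding is the fraction of G4 peaks
overlapped by each factor's peaks, independent across factors.

## Target classification

The chain is deliberately plain set algebra over two differential
contrasts:

1. promoter G4 **gain** — promoter window overlaps a stage-2 peak and no
   stage-1 peak (binary occupancy, not signal quantitation);
2. `G4_up` / `G4_down` — gain genes significantly up-/down-regulated
   between the stages (|log2FC| > 0.5, BH-adjusted p < 0.05; a
   fold-change-only mode exists for settings where no replicate-based p
   is available);
3. bona fide `G4_activated` / `G4_repressed` — G4-up genes downregulated by
   the G4-stabilising ligand, and G4-down genes upregulated by it.

The subset invariants (activated ⊆ up, repressed ⊆ down) hold by
construction and are asserted on random inputs. External DE tables are
accepted through `read_de_table()` so the chain can run on the outputs of
any dedicated DE tool.

### The differential-expression stand-in

Re-implementing a full count-based DE tool is out of scope; the package
ships a stand-in for self-contained runs: median-of-ratios size factors
(cross-checked in the suite against the reference implementation),
log2(CPM+1), and a per-gene two-group test. The default test is a
moderated t with an intensity-dependent variance prior fitted across genes
(limma-trend). The choice is driven by power at the replicate numbers this
package targets: at 3 vs 3, NB dispersion 0.1 and 4-fold planted effects, a
design-stage simulation measured BH-adjusted power of 0.2% for a plain
per-gene Welch test — small-sample variance estimates make the per-gene t
statistic essentially untestable after multiplicity adjustment — versus
~90% for the moderated fit, with null type-I fractions of 0.034 and 0.049
respectively at nominal 0.05. `method = "welch"` retains the unmoderated
test for anyone who wants it. Fold changes are always computed from the
normalised group means, not from the fitted coefficients.

## Loop analytics

**Observed/expected.** `expected(d)` is the mean raw count over *all* bin
pairs at distance $d$ on the chromosome, zeros included; O/E is
count/expected with undefined (zero-expected) pixels masked. No matrix
balancing is applied: raw-count library-depth scaling plus O/E absorbs
coverage trends at the scales this package works at. That is a documented
limitation — strong per-bin accessibility artefacts in real data would
call for KR/ICE balancing upstream.

**Loop pixel and classes.** The loop pixel is the bin pair containing the
anchor midpoints. Anchor classification (dual/single/no-G4) is ≥1 bp
overlap between the 5-kb anchor and any G4 peak; the three classes
partition every loop set and ignore anchor order. Interaction frequency is
O/E at the loop pixel, compared across classes with two-sided Wilcoxon
rank-sum tests. For promoter/enhancer typing an anchor is `P` if it
overlaps a promoter element (P beats E on ties), `E` if enhancer-only, and
the loop type is the unordered label pair.

**APA.** An 11×11-bin O/E window (half-window 5) centred on each loop pixel
is averaged element-wise over loops at distance > 10 bins from the
diagonal; the score is the centre over the mean of the 3×3 lower-left
(short-distance background) block. These window parameters are common
practice rather than universal constants and are arguments. A uniform
matrix scores exactly 1, and the score is invariant to global scaling of
the raw counts.

**Differential interactions.** The stand-in for joint-normalisation
differential tools keeps the published filtering constants — mean raw count
("A") ≥ 15 and adjusted p < 0.1 — and works as follows: depth-scale both
matrices to their geometric-mean library size; over the union of non-zero
pixels passing the A filter (optionally restricted to pixels with a G4-
containing bin *before* testing), compute $M = \log_2\frac{b+1}{a+1}$;
centre and scale $M$ within distance strata (median/MAD, one stratum per
bin distance up to 100 bins, log-spaced beyond) and report the result as
`z`. Significance, however, comes from an exact conditional test: given the
pixel total $a+b$, the condition-B count is
$\mathrm{Binom}(a+b,\ t_B/(t_A+t_B))$ under the null of equal underlying
intensity (the classic exact comparison of two Poisson rates), with mid-p
correction and BH adjustment. The reason is calibration: the A filter
admits pixels with expectations as low as ~15, where the normal tail of
the MAD-standardised log-ratio is visibly anti-conservative (2–3× the
nominal tail beyond |z| = 3.5 in direct simulation), which inflates the
empirical FDR of the calls, while the plain exact test over-corrects
through discreteness and the mid-p variant sits between the two. On the
generator's planted two-fold decreases (depth $10^6$, 100 planted pixels,
20 seeds) the shipped test measures pooled sensitivity 0.81 at empirical
FDR 0.09, with zero calls on identical inputs. Equivalence with any
external differential tool is not claimed.

**Expression stratification.** A gene belongs to a loop class when its
promoter window overlaps an anchor of a loop of that class, and to the
highest such class (dual > single > no) when several apply; medians and
pairwise rank-sum p-values are reported. Whether published gene counts
allow multi-class membership is usually unstated; precedence is our
documented choice.

## The synthetic-data generator

`generate_bundle(synth_config(seed))` emits a complete, cross-consistent
input bundle plus a truth table, deterministically from the seed. It
emulates the *statistical structure* the analysis assumes, not raw reads:

* one 2-Mb chromosome (multi-chromosome configurations are supported), a
  uniform-random background sequence, and 200 genes on a jittered TSS grid
  with ≥10-kb spacing — each gene then owns exactly two 5-kb bins, which
  makes gene↔anchor links exact by construction;
* fixed-width (300 bp) peaks at designated promoters and intergenic slots;
  80% of peak loci (the default plant rate) receive a minimal PQS motif of
  a configurable subtype mix on a random strand, and the remaining peak
  sequence is sampled free of `GG`/`CC` dinucleotides with A/T spacers at
  the edges, so a peak's PQS status is *exactly* its planted truth — in
  random sequence the two-quartet pattern is so permissive that almost any
  300-bp window would otherwise match;
* loops drawn from disjoint per-class gene pools (dual/single/no-G4
  anchors, with single loops pairing one G4-positive and one G4-negative
  pool), anchor separations of 11–100 bins;
* contact matrices with Poisson counts around a $C\,d^{-1}$ distance-decay
  expectation scaled to $10^6$ total counts, loop pixels multiplied by
  3/2/1 for dual/single/no-G4 (the planted interaction-frequency ordering);
  the paired condition shares the expectation except at planted
  differential pixels (100 two-fold down, 25 up by default) drawn among
  non-loop pixels with expectation ≥ 60 — an analytic power floor chosen at
  design time so that a two-fold Poisson change is detectable at all at
  this depth;
* negative-binomial counts (dispersion 0.1, log-normal baselines around
  150) for two 3 vs 3 contrasts: promoter-gain genes are planted ±2.5 log2
  units on activation (55% up, 25% down), 10% of background genes are
  planted differential, and a 20% reversal fraction of the regulated gain
  genes defines the planted bona fide targets in the ligand contrast;
* per-gene expression values for the loop-class stratification, with +1 /
  +0.5 / 0 log2 shifts for dual/single/no-G4 promoter genes.

`check_bundle()` re-derives every truth claim from the emitted data with
the package's own operations (scan the peak sequence, classify the loops,
recompute the gain set) and stops at the first inconsistency.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: read-level noise and mappability, GC and
fragment bias, matrix balancing artefacts, overdispersed (super-Poisson)
contact counts, replicate structure in the matrices, batch effects, and any
dependence between peak strength and sequence context. Recovery results on
the bundle demonstrate correctness of the implementations under the stated
models, not field performance.

## Problem sizes and determinism

Default desk-scale sizes keep a full bundle under ~3 s and the complete
workflow scripts under two minutes: 2-Mb genome, 400 bins, 600 loops,
200 genes, $10^6$ contacts per matrix. The recovery simulations in the
test suite use 20 seeds at exactly these conditions; the
differential-expression calibration uses 2 000 genes × 20 seeds. All
randomness flows from a single seed per run; identical seeds give
byte-identical bundles and analysis outputs (the suite hash-compares two
full pipeline runs). Known degenerate inputs are handled explicitly:
empty peak sets annotate to DistalIntergenic, all-zero genes are `ns` with
zero fold change, masked O/E pixels exclude their loops with a message,
and strata with fewer than 5 pixels or zero MAD report `z = 0`.
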