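# quadloop

Integrative analysis of DNA G-quadruplex (G4) landscapes and chromatin
architecture across cell-state transitions.

G4s are four-stranded DNA secondary structures formed by stacked guanine
tetrads in G-rich sequence. In stem-cell systems their genome-wide formation
is highly dynamic: antibody-based profiling (e.g. BG4 CUT&RUN) yields
per-stage peak sets whose sequence content, genomic placement and relation to
gene regulation and 3D genome folding carry the biology. `quadloop`
implements the downstream analysis layer of such a study as a reusable,
tested R package, exercised end-to-end on a seeded synthetic-data generator
that emulates the statistical structure of the sequencing-derived inputs:

* **PQS scanning** — strand-aware detection of putative quadruplex-forming
  sequences. A PQS is at least four G-runs separated by loops; the scanner
  implements the regex families G3+L1–7 (canonical: tracts of ≥3 G, loops
  1–7 nt), G3+L1–12 (long loop: at least one loop of 8–12 nt), G2+L1–12
  (two-quartet: tracts of 2 G, loops up to 12 nt) and a bulged class (one
  G-tract interrupted by a single 1–7 nt non-G insertion), with
  leftmost-longest maximal matching and subtype precedence
  canonical > long_loop > bulge > two_quartet. Verified hit-for-hit against
  an independent exhaustive enumerator.
* **Peak landscape** — Venn-style peak sharing between stages, binned-track
  Pearson correlation, midpoint-priority genomic feature annotation
  (Promoter > Exon > Intron > Downstream > DistalIntergenic), and
  transcription-factor co-binding fractions.
* **Target classification** — promoter-G4 *gain* (stage-2-only promoter
  occupancy) intersected with differential expression (|log2FC| > 0.5,
  adjusted p < 0.05) gives G4-up / G4-down genes; intersecting those with a
  G4-ligand (pyridostatin-type) perturbation contrast gives the bona fide
  G4-activated (up on activation, down on ligand) and G4-repressed targets.
* **Loop analytics** — G4 occupancy of 5-kb loop anchors (dual / single /
  no-G4), promoter–enhancer loop typing, observed/expected contact
  normalisation `O/E(i,j) = count / mean(count at that bin distance)`,
  aggregate peak analysis (APA: centre of the mean 11×11 O/E window over
  its 3×3 lower-left background), distance-stratified differential
  interactions between conditions (depth scaling, "A" filter ≥ 15, exact
  conditional mid-p test, BH at 0.1), and gene-expression stratification by
  the loop class of the promoter.

## Worked example

The numbered scripts under `analysis/` run the full workflow on the
synthetic bundle (`QUADLOOP_SEED` selects the seed, default 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_pqs_landscape.R
Rscript analysis/03_targets.R
Rscript analysis/04_loops.R
```

At seed 1 this prints, among other things:

```
ASC peaks overlapping a PQS: 81.3% (100/123)
peak sharing FISC vs ASC: 8/19 and 8/123 shared (union 134)
TF co-binding fractions of G4 peaks (%):
CTCF  MAX  YY1
14.6 48.8 22.0
G4-up genes: 41; G4-down genes: 27
bona fide G4-activated: 6; G4-repressed: 5
median interaction frequency (O/E) per class:
  dual_G4     no_G4 single_G4
    2.823     0.923     1.966
APA score of G4-containing loops: 2.45 (n = 400)
differential interactions at G4 bins: 65 down, 22 up (of 9315 tested)
```

Reading these numbers: 81.3% of the activated-stage peaks contain a
predicted PQS (the generator planted motifs under 80% of peak loci, so the
scanner recovers the plant); loops whose two anchors both carry a G4 peak
interact ~3× more than expected at their genomic distance, single-G4 loops
~2× and no-G4 loops ~1× — exactly the enrichment the generator planted — and
the ligand-emulating condition loses interactions at G4-containing bins far
more often than it gains them. Tables land under `results/`.

In code, the same pieces compose directly:

```r
library(quadloop)
bundle <- generate_bundle(synth_config(seed = 1))
hits <- scan_pqs("GGGAGGGAGGGAGGG")            # one canonical hit, + strand
cls <- classify_loop_anchors(bundle$loops, bundle$peaks$ASC)
apa(bundle$loops, bundle$matrices$ctrl)$score
```

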