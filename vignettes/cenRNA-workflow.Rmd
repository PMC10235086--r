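---
title: "Classifying and quantifying centromeric transcripts: methods and design"
author: "cenRNAtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and quantifying centromeric transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenRNAtools)
```

## The measurement problem

Budding-yeast point centromeres are ~117 ± 2 bp CEN cores, each a fixed
left-to-right arrangement of CDEI (a short conserved box), CDEII (an
AT-rich spacer) and CDEIII (the essential CBF3-binding box). Transcription
across the core is kept extremely low, and the transcripts of interest —
cenRNAs overlapping the core and pericenRNAs confined to the 500 bp
flanks — are orders of magnitude rarer than the surrounding mRNAs.
Gene-model-based counting is useless here: the features are sub-gene-sized
intervals, the fragments are wildly heterogeneous in length (hundreds of
nt to ~9 kb spans), and the biological questions are about *where
fragments start and stop relative to the core elements*, per strand.

cenRNAtools therefore works at the level of **fragment spans**: each
sequenced read pair is reduced to the interval from the leftmost to the
rightmost aligned base, on the strand of the transcript. Two arguments
support the span representation: with 100-nt paired-end sequencing,
multi-kilobase "read pair lengths" are only coherent as pair spans; and
yeast (peri)centromeric regions are effectively intronless, so the
genomic span approximates the transcript extent. Whether the original
measurements used spans or summed mate lengths is not knowable from the
outside; the span convention is adopted throughout and stated here once.

## Classification model

Given a genome model (chromosome sizes, one CEN core per chromosome, CDE
partition, ±`windowBp` pericentromeric windows, window-intersecting
ORFs), `classifyFragments()` assigns each span exactly one class:

1. **CEN** — ≥ 1 bp overlap with the core. The 1 bp threshold is
   deliberate: the class is defined as containing the core *or part of
   it*, with no minimum.
2. **PERICEN_NONCODING / PERICEN_CODING** — no core overlap but ≥ 1 bp
   overlap with a window; coding when the span also touches an ORF that
   intersects a window (pure coordinate intersection by default;
   `codingStrandMatched = TRUE` restricts to same-strand ORFs). This is
   exactly the subtraction semantics of intersecting against windows and
   then removing core-overlapping fragments, and the test suite verifies
   that equivalence exhaustively on a toy chromosome.
3. **OTHER** — everything else (library background).

CEN spans receive four further labels:

- **termClass**: `FULL_CEN` if the span covers the whole core. Otherwise
  the span has one or two boundaries strictly inside the core; the label
  is the CDE element containing that boundary, and when both boundaries
  are internal the 3′ boundary (with respect to the fragment strand)
  decides. The tie-break is a design decision — a span wholly inside the
  core "initiated and terminated" in elements, and a single deterministic
  label is required; the 3′ rule reads the label as *termination* class,
  matching its name. A fragment wholly inside the core counts once, not
  once per boundary.
- **lengthClass**: `SHORT` below 1000 nt, else `LONG`. The published
  partition ("<1000" / ">1000") leaves exactly 1000 unassigned; here
  1000 nt is LONG, closing the gap deterministically.
- **initiatedInPericen**: whether the strand-aware 5′ end (rightmost
  base for minus-strand spans) lies outside the core. Note two related
  statistics circulate: the fraction initiating anywhere outside the core
  (~0.79) and the fraction initiating in the *upstream* window only
  (~0.78). They are different quantities and the pipeline summary emits
  both (`cen_initiated_in_pericen_fraction`,
  `cen_initiated_upstream_fraction`) rather than reconciling them.
- **side**: which window(s) the span touches.

### Coordinate conventions

Internally everything is a `GRanges` in the Bioconductor 1-based closed
convention; BED files on disk keep 0-based half-open coordinates through
`rtracklayer`. This deviates from the "0-based half-open everywhere"
convention a standalone implementation might choose, for a simple reason:
in R the GRanges ecosystem *is* the interval arithmetic, and fighting its
convention invites off-by-one errors at every call boundary. The
correctness burden moves to the I/O layer, which is round-trip tested.

A useful translation table: a BED core `chrT 1000 1117` is
`chrT:1001-1117` (width 117); its derived CDE layout is CDEI
`1001-1008`, CDEII `1009-1092`, CDEIII `1093-1117`. The CDE sizes
(8 / remainder / 25 bp) are the canonical point-centromere architecture —
the literature does not publish per-chromosome element sizes — and can be
overridden entirely with a CDE BED when real annotation is available.

## Profiles

`coverageProfile()` and `startSiteProfile()` accumulate per-nucleotide
counts in **CEN-anchored coordinates**: offset 0 is the first core base,
negative offsets run upstream. Anchoring on the core start makes the
sixteen chromosomes superposable despite their slightly different core
widths. Coverage mass equals the summed overlap of spans with the
profiled region; start-site mass equals the number of in-region 5′ ends —
both conservation laws are asserted across 100 seeded fixtures. Whether
the published per-nucleotide curves show coverage or start density is
ambiguous; both modes are first-class here.

CPM normalisation scales each sample by `10⁶ / totalFragments` *before*
condition aggregation, where `totalFragments` is the **library depth**
from the sample sheet (tens of millions of mapped pairs in a real
experiment), not the (peri)centromeric count — normalising to the class
counts themselves would erase the condition effects being measured.
Conditions aggregate replicate CPM profiles by sum (default, consistent
with tallies of pooled replicates) or mean (`aggregate = "mean"`, as in
figure-style renderings); the two differ by the constant replicate count.
Normalising an already-normalised profile is an error by design.

## Quantification

Headline statistics are ratios of class counts. Display values use two
significant figures because that is the only rounding that reconciles the
published renderings of the same arithmetic (16369/42 = 389.7 → "390",
30346/98 = 309.7 → "310", 98/42 = 2.33 → "2.3", 30346/16369 = 1.85 →
"1.9"); machine columns always keep full precision.

Absolute abundance (`moleculesPerCell()`) calibrates the target's count
against reference genes of known copies per cell (DOA1 2.6, KAP104 5.0,
POL1 3.1, PDR5 13.4 in the packaged table). Counts are length-density
normalised before calibration: a ~117 bp core and multi-kb mRNAs differ
so grossly in countable footprint that raw-count calibration is
indefensible; `normaliseByLength = FALSE` exposes the raw variant for
sensitivity checks. The uncertainty is the SEM of the per-reference
calibration factors propagated to first order — the spread across
references, which is what a "± 0.5"-style figure can only mean when its
exact definition is unstated. The published molecules-per-cell values
cannot be recomputed without the original reference-gene read counts, so
this operation is validated by its algebra (self-calibration and
library-depth invariance), not by reproducing a number.

`ddcqFold()` implements the comparative-Cq method: ΔCq per arm, ΔΔCq
across arms, fold = 2^−ΔΔCq, with a configurable 10–40 cycle plausibility
band.

## What the generator simulates — and what it does not

`simulationConfig()` packages the study conditions as defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `nChromosomes`, `chromosomeLength` | 16 × 100 kb | bp | 16 point centromeres; 100 kb leaves room for ±500 bp windows and ~9 kb spans while keeping placement cheap (real chromosomes are 230 kb–1.5 Mb; only CEN-relative geometry matters here) |
| `coreWidthBand` | 115–119 | bp | the 117 ± 2 bp core |
| `windowBp` | 500 | bp | the pericentromere definition; 100/200 bp sub-windows remain reachable by reconfiguration |
| `nOrfs`, `orfCoreClearanceBp` | 22, 200 | — , bp | 22 window-intersecting ORFs genome-wide; no coding feature within 200 bp of a core |
| `cenTotal`, `noncodingTotal`, `scale` | 42, 16369, ×10 | fragments/condition | the mock condition counts, scaled ×10 so Monte-Carlo error on recovered ratios stays in the few-percent range at desk scale |
| `codingMultiplier` | 10 | — | coding:noncoding pericentromeric ratio |
| `backgroundFragments` | 10⁶ | fragments/sample | library-depth filler outside all windows so CPM has a realistic denominator |
| `shortWeight` | 0.5 | — | the 1:1 short:long centromeric mixture |
| length medians (sdlog) | 231 (0.45), 4458 (0.35), 225 (0.45) | nt | log-normals parameterised by median, so the published medians map exactly to the log-mean; sdlogs are chosen to keep the SHORT mass below 1000 nt and the LONG tail plausibly near the longest observed ~9.4 kb span |
| `termCompMock` | 0.48/0.12/0.24/0.17 | — | published composition; sums to 1.01 from rounding and is renormalised, so the generated FULL_CEN fraction is 47.5% |
| `termCompAuxin` | 0.32/0.23/0.26/0.19 | — | only FULL_CEN = 32% is published; the deficit is sent mostly to CDEI, where depletion-induced termination concentrates |
| `pericenInitP` | 0.79 | — | fraction of cen fragments initiating outside the core |
| `plusDominantChromosomes` | 10 (of 16) | — | plus-strand bias majority; biases 0.7/0.3 |
| depletion folds | 2.3 (cen, short-borne), 1.9 (noncoding), 1.0 (long cen, coding) | — | the condition multipliers; with the long class flat, the implied short:long ratio under depletion is 3.6:1, consistent with the published "~3:1" |
| `replicates` | 3 | — | per condition |

Fragments are not placed blindly: each centromeric fragment first draws
its annotation (termination class, initiation origin, strand, length
class, length), then a placement that *realises* that annotation is
solved directly from the boundary constraints, and the batch is
re-classified as an internal assertion — the generator is honest by
construction, with rejection only where a draw is geometrically
infeasible (e.g. a FULL_CEN span shorter than the core redraws its
length). Two consequences are worth knowing. First, per-replicate class
counts are Poisson around the per-replicate expectation, so condition
totals fluctuate with √N — at the default ~420 cen fragments per
condition the recovered 390:1 ratio carries ~5% Monte-Carlo error, and
headline folds recovered from a single default run can sit 1–2σ from
their configured values. Second, conditional length constraints (a
FULL_CEN short span must exceed the core width; some element/origin
combinations need ~100 nt minimums) truncate the short-cen log-normal
slightly from below, biasing its recovered median upward by ~2% (≈236 vs
231 nt at n = 10⁴) — well inside the 5% recovery band the tests enforce,
and stated here so nobody chases it as a bug.

Noncoding pericentromeric placement rejects any overlap with
window-intersecting ORFs; because a long ORF can make one
(chromosome, side) slot infeasible for a given length, rejection redraws
the whole placement, which mildly depletes ORF-rich window sides — a
qualitative echo of the real per-chromosome heterogeneity, though not a
calibrated model of it. Coding fragment lengths (median 1250 nt, typical
of yeast mRNAs) and background lengths (median 300 nt) are packaging
choices; nothing downstream measures them.

The generator does **not** simulate sequence (no FASTA/FASTQ), sequencing
error, PCR duplication, splicing, mappability, or calibrated
per-chromosome abundance differences. Passing recovery tests therefore
demonstrates that the *pipeline arithmetic* is correct and unbiased at
realistic scales — not that the alignment-facing steps of a real
experiment are free of artefacts.

## Determinism and problem sizes

Every stochastic stage derives its stream from `seed` plus fixed offsets
per condition/replicate/stage, so replicates differ while runs reproduce
byte for byte (`runPipeline()` outputs, including the JSON manifest,
carry no timestamps for this reason). The shipped test suite runs the
generator at 5 000–20 000 fragments per class for recovery checks, an
exhaustive 40 200-placement oracle comparison on a 200 bp toy chromosome,
100-seed property sweeps for the conservation laws, and two full
default-scale pipeline runs (~9–10 M fragments each) for the determinism
check; the whole suite completes in a few minutes on a single core.

## Known limitations

- One CEN per chromosome is enforced; regional centromeres are out of
  scope.
- `fragmentsFromSam()` trusts the aligner's proper-pair flags and skips
  cross-chromosome pairs with a counter rather than rescuing them.
- Duplicate fragments are never collapsed: the upstream protocol has no
  UMIs, and deduplication would silently alter every count.
- The SEM reported by `moleculesPerCell()` captures reference-gene spread
  only, not counting noise on the target.
- The 200-, 100-bp sub-window analyses are supported by reconfiguring
  `windowBp`, not by a dedicated multi-resolution mode.
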