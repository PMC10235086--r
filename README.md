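# cenRNAtools

Quantitative analysis of centromeric (cenRNA) and pericentromeric
(pericenRNA) transcripts in budding yeast from strand-specific paired-end
RNA-seq, for researchers studying centromere silencing, kinetochore
biology, or low-abundance noncoding transcription.

*S. cerevisiae* point centromeres comprise a ~117 ± 2 bp CEN core built
from three ordered elements (CDEI, CDEII, CDEIII). Transcription across
the core is rare — on the order of molecules per thousand cells — and its
deregulation (e.g. on depletion of the Rio1 kinase with an auxin degron)
destabilises kinetochores. Measuring these transcripts requires careful
interval bookkeeping rather than ordinary gene-level counting, and this
package implements that bookkeeping as a tested, reusable pipeline:

- **Classification.** Every sequenced fragment — represented by its full
  read-pair span `[start, end)` on the transcript strand — is assigned
  exactly one class: **CEN** if it overlaps the CEN core by ≥ 1 bp;
  otherwise **PERICEN_CODING**/**PERICEN_NONCODING** if it overlaps a
  ±500 bp pericentromeric window (coding when it also touches an ORF
  intersecting a window); otherwise **OTHER**. This mirrors the two-pass
  `bedtools intersect` / subtraction scheme used in the field.
- **CEN fragment annotation.** Termination class (FULL_CEN when the whole
  core is covered, else the CDE element containing the fragment boundary
  inside the core), SHORT/LONG length class (boundary 1000 nt),
  strand-aware 5′ initiation origin, and window side.
- **Profiles.** Per-nucleotide coverage and 5′ start-site densities in
  CEN-anchored coordinates, per strand and condition, raw and
  CPM-normalised (counts per million mapped fragments,
  `value × 10⁶ / library size`).
- **Quantification.** Class ratios and condition folds reported at two
  significant figures alongside full precision; absolute abundance by
  length-density calibration against reference genes of known copies per
  cell (`k_i = (count_i/length_i)/copies_i`; estimate
  `= (count_t/length_t)/mean(k_i)` ± SEM); 2^−ΔΔCq relative expression
  for qPCR cross-checks.
- **Simulation.** A fully seeded generator that emulates the mock vs
  auxin-depletion experiment (1:1 short:long cenRNA mixture with
  log-normal span medians 231/4458 nt, noncoding pericenRNA at ~390× the
  cenRNA count with median 225 nt, coding pericenRNA at ~10× the
  noncoding count, plus-strand bias on 10/16 chromosomes, 79%
  pericentromeric initiation, and depletion multipliers 2.3×/1.9× carried
  by the short cen and noncoding classes), so every stage is testable
  without any external data.

## Worked example

Simulate a complete 3 + 3 replicate experiment and run every stage:

```r
library(cenRNAtools)
res <- runPipeline(simulationConfig(seed = 1), outdir = "cenrna_run")
res$report
#>                            statistic  condition    value display
#> 1     noncoding_pericen_to_cen_ratio       mock 359.9736   360.0
#> 2  coding_to_noncoding_pericen_ratio       mock   9.9920    10.0
#> 3     noncoding_pericen_to_cen_ratio      auxin 323.1661   320.0
#> 4  coding_to_noncoding_pericen_ratio      auxin   5.2582     5.3
#> 5                auxin_mock_fold_CEN auxin/mock   2.1165     2.1
#> 6  auxin_mock_fold_PERICEN_NONCODING auxin/mock   1.9001     1.9
#> 7     auxin_mock_fold_PERICEN_CODING auxin/mock   0.9999     1.0
#> 8          auxin_mock_fold_CEN_SHORT auxin/mock   3.1940     3.2
#> 9           auxin_mock_fold_CEN_LONG auxin/mock   0.9955     1.0
#> 10        ratio_change_auxin_vs_mock auxin/mock   0.8977     0.9
```

Reading the table: the noncoding-pericen:cen read ratio sits near its
configured 390 in the mock arm (Poisson noise at ~420 cen fragments per
condition accounts for the deviation) and drops under depletion because
cen transcripts rise faster (2.1×, carried entirely by the short class at
3.2×) than noncoding pericen transcripts (1.9×); coding pericen
transcripts do not respond, so their ratio to the noncoding class falls
from 10 to ~5.3. The summary table shows ~0.78 of cen fragments
initiating outside the core and the distinct cen start-site count jumping
from 274 (mock) to 722 (auxin) — de novo initiation, not amplification of
existing starts. `cenrna_run/` also contains the per-class tally,
CEN-anchored coverage and start-site profiles (raw + CPM), termination
class distributions per strand, and a JSON run manifest; re-running with
the same seed reproduces every file byte for byte.

Real alignments enter through `readFragmentsBed()` (BED6 spans) or
`fragmentsFromSam()` (paired SAM/BAM, dUTP strandness by default), with
annotation via `loadGenomeModel()` (chrom sizes + CEN BED + optional
ORF/CDE BEDs).

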