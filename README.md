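# cassex

Cassette-exon alternative splicing analysis from splice-junction read
counts.

Tumors systematically rewire alternative splicing: individual cassette exons
are included or skipped at different rates in tumor versus matched normal
tissue, and the same exons recur across cancer types under the control of a
small set of splicing factors (RBFOX2, QKI, MBNL1/2, PTBP1, CELF2). `cassex`
implements the full junction-based analysis that detects and characterizes
such events, for analysts working from split-read alignments of matched
tumor/normal RNA-seq cohorts:

1. **De-novo cassette-exon discovery.** A skipping event is a junction
   triplet on one chromosome: upstream and downstream inclusion junctions
   (UJ, DJ) plus a skipping junction (SJ) sharing their outer boundaries.
   Junctions must reach 5 uniquely-mapping reads in at least one sample, and
   the inner junctions must be balanced in every sample of the dataset
   (`|UJC − DJC| < 10` or `|UJC − DJC| < 2·min(UJC, DJC)`).
2. **PSI quantification.** Percent spliced-in per event and sample:

   `PSI = 0.5·(UJC + DJC) / (0.5·(UJC + DJC) + SJC)`

   with coverage `0.5·(UJC + DJC) + SJC ≥ 10` required in both members of at
   least 15 matched pairs ("highly expressed" events).
3. **Paired differential calling.** Wilcoxon signed-rank test on tumor −
   normal PSI within matched pairs; an event is called per cancer type when
   the Benjamini–Hochberg q ≤ 0.05 **and** |mean ΔPSI| ≥ 0.10.
4. **Recurrence, coherence and markers.** Events significant in several
   cancer types are classified coherent (one sign everywhere) or
   non-coherent; events with same-direction |ΔPSI| ≥ 0.10 in ≥ 90% of pairs
   are flagged as candidate splicing markers. Frame preservation,
   hypergeometric set-overlap, interval-overlap and PSI–expression /
   ΔPSI–ΔPSI correlation utilities support the downstream comparisons.
5. **Motif enrichment and conservation.** Direction-stratified k-mer scans
   (k = 4–6) of the exon body and the adjacent 250 nt of each flanking
   intron against a background of highly expressed, non-altered exons
   (hypergeometric test on exon presence, BH at q ≤ 0.01), k-mer → splicing
   factor mapping, and mean conservation profiles around motif occurrences.

Everything runs on plain-text standard formats — STAR `SJ.out.tab`-dialect
junction tables, a sample manifest TSV, FASTA, bedGraph, BED — and a
built-in synthetic-cohort generator (`cohort_design()`, `simulate_cohort()`,
`write_cohort()`) produces complete cohorts with planted ground truth so the
entire pipeline is testable without access to controlled patient data.

## Worked example

Simulate a two-cancer-type cohort with 30 planted effects, then run
discovery, PSI quantification and differential calling:

```r
library(cassex)

design <- cohort_design(cancer_types = c("BRCA", "LUAD"), pairs_per_type = 16,
                        n_events = 200, n_altered = 30, seed = 42)
cohort <- simulate_cohort(design, with_genome = FALSE)

events <- discover_events(
  cohort$junction_counts,
  samples = cohort$manifest$sample_id[cohort$manifest$cancer_type == "BRCA"])
attr(events, "funnel")
#>  junctions_observed junctions_supported triplets_enumerated     events_balanced
#>                 600                 600                 200                 184

psi <- build_psi_matrix(events, cohort$junction_counts)
psi
#> <psi_matrix> 184 events x 64 samples; 0 missing cells

calls <- call_differential(psi, cohort$manifest)
dplyr::count(calls, cancer_type, significant)
#> # A tibble: 4 × 3
#>   cancer_type significant     n
#> 1 BRCA        FALSE         154
#> 2 BRCA        TRUE           30
#> 3 LUAD        FALSE         154
#> 4 LUAD        TRUE           30

table(classify_recurrence(calls)$coherence)
#>     coherent non_coherent
#>           24            6

head(calls[calls$significant, c("event_id", "n_pairs", "mean_delta_psi",
                                "q_value", "direction")], 3)
#>   event_id                  n_pairs mean_delta_psi q_value direction
#> 1 chrS:3370-3893|3987-4288       16         -0.253 2.01e-4 exclusion
#> 2 chrS:6432-6936|7039-7561       16         -0.287 2.01e-4 exclusion
#> 3 chrS:9586-10173|10222-10780    16         -0.260 2.01e-4 exclusion
```

The funnel mirrors the stage structure: 600 junctions (3 per planted locus)
all pass the 5-read filter at this depth, assemble into 200 candidate
triplets, and 184 survive the inner-junction balance rule in every BRCA
sample. All 30 planted effects per type are recovered at q ≤ 0.05 with mean
ΔPSI close to the planted ±0.25, and cross-type coherence labels split
24 / 6, matching the generator's 80% coherent fraction on this seed.

File-based cohorts work the same way through `run_pipeline()`:

```r
write_cohort(design, "cohort/")
cfg <- run_config(sj_dir = "cohort/sj", manifest = "cohort/manifest.tsv",
                  fasta = "cohort/genome.fa",
                  conservation = "cohort/conservation.bedGraph",
                  out_dir = "results/")
run_pipeline(cfg)   # writes events/psi/differential/recurrence/markers/motif TSVs
```

A thin command-line wrapper over the same function is provided at
`inst/scripts/run_pipeline.R`.

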