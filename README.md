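# sgrnaseg

Small-RNA profiling and tRNase Z(L) guide-RNA analysis for barcoded
deep-sequencing libraries.

## What this package does

Plasma and cellular small RNAs (5–40 nt) are dominated by degradation
fragments — tRNA halves, rRNA fragments, Y-RNA fragments, miRNAs — and a
subset of them can act as **small guide RNAs (sgRNAs)** for the
endoribonuclease **tRNase Z(L)**: the guide base-pairs with a target RNA
into a pre-tRNA-like complex and the enzyme cleaves the target
immediately 3′ of the unpaired *discriminator* nucleotide. `sgrnaseg`
implements, as tested and reusable R code, the full analysis workflow
around this biology for a six-library barcoded sequencing design:

* **Preprocessing** — barcode demultiplexing, 3′/5′ adapter trimming,
  removal of adapter-artifact inserts, 5–40 nt analysis window, with
  exact read-fate accounting.
* **Annotation** — transcript-space matching (≤2 mismatches) into the ten
  RNA categories (mRNA, rRNA, scRNA, snRNA, srpRNA, miRNA, lncRNA, piRNA,
  snoRNA, tRNA), with an rDNA repeating-unit pre-filter.
* **Profiling** — per-length read distributions, peak detection, and the
  species-frequency statistic (a sequence's count as a percentage of
  same-length reads).
* **Differential abundance** — per-length top-N "comparing sequences"
  across samples, tested 3 vs 3 with a two-tailed pooled-variance Student
  t-test (raw *P* < 0.05 by default).
* **Segregation statistic** — for all C(6,3)/2 = 10 balanced bipartitions
  of the samples, the significant-sequence count; the expected
  per-bipartition count *E* = *n*/10; and the exact binomial point
  probability of the case count,
  *P* = C(*n*, *k*) (1/10)^*k* (9/10)^(*n*−*k*), computed in log space.
  For the published input counts this gives *E* = (79+54)/10 = 13.3 and
  (109+141)/10 = 25.0, and *P*(109 of 250) = 4.2×10⁻⁴³.
* **sgRNA structure** — classification of small RNAs into the four guide
  classes (heptamer, 14-nt linear, hook, 5′-half-tRNA) by length and fold
  rules over Watson–Crick + G:U pairs, scanning of targets for
  pre-tRNA-like complexes, and prediction of the guided cleavage site.
* **Synthetic data** — a seeded generator of six barcoded libraries with
  planted length peaks, planted differential species, null controls, and
  adapter artifacts, so that every stage is verifiable against known
  truth without external data.

## Worked example

Simulate the default study conditions (six libraries, 3 vs 3, 10⁴ reads
each, four planted differential species at fold change 20), preprocess,
compare groups, and run the segregation test:

```r
library(sgrnaseg)

spec <- synthetic_spec(seed = 7)
run  <- simulate_libraries(spec)
pp   <- preprocess_reads(run$reads, run$sample_sheet)
pp$samples$S1
#> <sample_library> S1 (group A, plasma): 8934 reads, 287 species

grouping <- setNames(run$sample_sheet$group, run$sample_sheet$sample_id)
d <- significant_species(pp$samples, grouping)
d
#> <sgrna_comparison> 246 comparing sequences, 31 significant at alpha = 0.05 (case group B)
#>                   sequence length mean_ref sd_ref mean_case sd_case      t         p ...
#> 77        AAGGGGAAAAGGCAAG     16   20.221 2.4003    83.341  0.2211 -45.35 1.413e-06 ...
#> 80        GCAAUCUAACUCUUGU     16   44.241 1.4962     9.877  0.4208  38.30 2.777e-06 ...
#> 67          GAAACGUGAACGGU     14   17.682 2.1529    82.326  2.1519 -36.78 3.261e-06 ...
#> ...
```

The four most significant sequences are exactly the four planted
differential species, with the planted directions (`more`/`less`
abundant in the case group). The segregation statistic then asks whether
the case split stands out among all ten balanced bipartitions:

```r
seqs <- comparing_set(pp$samples)
tab  <- species_frequency_table(pp$samples, seqs)
segregation_test(tab, list(side_a = c("S1","S2","S3"),
                           side_b = c("S4","S5","S6")))
#> <segregation_test>
#>   bipartitions: 10   significant events: 116
#>   case count S_case = 31 (rank 1 of 10), others sum to 85
#>   expected per bipartition E = 11.6
#>   binomial point probability P = 1.89e-07 (upper tail 2.66e-07)
```

The case bipartition carries 31 of the 116 significance events against
an expected 11.6, with point probability 1.9×10⁻⁷ — the two groups
segregate. Structural analysis of the published 31-nt Y4-RNA fragment
against the published 46-nt model target RNA-Y:

```r
cx <- find_target_sites(y4_fragment_31nt, rna_y_target)
cx[[1]]
#> <pre_trna_complex> 9-bp acceptor duplex guide[1..9]:target[29..37] |
#>   discriminator 38 (G) | cleavage 3' of 38
predict_cleavage(cx[[1]])
#> position 38, len5 38, len3 8 — cleaving RNA-Y into 38-nt and 8-nt products
```

The guide folds as a 5′-half-tRNA mimic (9-nt free acceptor arm
`GGCUGGUCC`, 6-bp internal stem), pairs its arm with target positions
29–37, and the predicted cut after the discriminator releases 38-nt and
8-nt products.

A single call runs everything and writes a TSV/JSON report bundle:

```r
res <- run_pipeline(pipeline_config("out", simulate = synthetic_spec(seed = 7)))
```

A thin command-line wrapper is included at
`inst/scripts/run-pipeline.R`.

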