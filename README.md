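# oligofoot

Size-resolved MNase footprint mapping and occupancy analysis for
bacteria chromatinized with archaeal histones.

When archaeal histones (such as HMfA/HMfB of *Methanothermus
fervidus*) are expressed in *Escherichia coli*, they assemble on the
chromosome as oligomeric particles: a tetramer protects a ~60 bp core
and grows in ~30 bp steps as histone dimers are added, so micrococcal
nuclease (MNase) digestion leaves a ladder of protected fragments at
60, 90, 120 and 150 bp. `oligofoot` is an R package for analysing
this kind of experiment end to end, for researchers studying
chromatin evolution, archaeal histones, or nucleoid organisation:

* **Footprint mapping** — per-base coverage from protected-fragment
  BED files, Fourier-filtered peak calling, and assignment of each
  footprint to an oligomer rank via the model
  `L(r) = 60 + 30·(r − 1)` bp (tetramer, hexamer, octamer, decamer).
* **Empty-vector normalized occupancy** — `O(x) = c_strain(x) /
  (c_EV(x) + 1)`, per fragment-size class (60/90/120/150 ± 5 bp),
  cancelling the nuclease's AT cutting bias and mappability.
* **Sequence preference** — LASSO regression of occupancy on k-mer
  composition (k = 1..4 over 61/91/121 bp windows, 340 features),
  trained on the first sixth of the genome and evaluated on the rest,
  plus univariate k-mer rankings and read-internal dyad-symmetric
  nucleotide enrichment profiles.
* **Occupancy–transcription links** — TSS/promoter/gene-body/
  start-codon-control window comparisons between up- and
  down-regulated gene groups (with the two-strain exclusion rule),
  regional GC–occupancy–transcription interplay, nucleoid-associated
  protein (NAP) Δ-occupancy, and dot-product similarity against a
  transcriptome compendium.
* **A synthetic study generator** — genomes with AT-rich promoters,
  sequence-biased oligomer assembly, jittered AT-biased digestion, a
  matched empty-vector library, occupancy-coupled differential
  expression, and a compendium with one planted correlated
  comparison, so the whole pipeline is testable without external
  data.

All coordinates are 0-based half-open (BED-native); bacterial
chromosomes are treated as circular by default, so coverage and
windows wrap across the origin. Functions take data frames first and
return tibbles, so analyses compose with the pipe.

## Worked example

A complete synthetic study at the package's reference conditions
(200 kb genome, 100 genes, 8 particles/kb, 20 fragments per
particle):

```r
library(oligofoot)

cfg   <- sim_config(seed = 1L)
study <- simulate_study(cfg)

# 1. the oligomer ladder: histone-specific fragment-length peaks
ladder_peaks(study$fragments$length, study$ev_fragments$length)$peaks
#>   length  count background
#> 1     60 2433.       124.
#> 2     90 1122.        42
#> 3    120  333.        16.3
#> 4    149   40.7        3
```

Rungs sit at 60/90/120/~150 bp (mean spacing 29.7 bp), and none of
them appear in the empty-vector control — the ladder is the histone's
signature.

```r
# 2. footprint calling and rank recovery
cov   <- coverage_track(study$fragments, study$genome, label = "strain")
calls <- call_peaks(fft_smooth(cov$track$chrS), contig = "chrS")
mc    <- match_calls(calls, study$placements)
mean(mc$matched)
#> [1] 0.926      # 92.6% of planted particles recovered within 5 bp
```

```r
# 3. promoter occupancy vs transcriptional repression
tracks <- list(pooled = normalize_track(
  cov, coverage_track(study$ev_fragments, study$genome)))
groups <- exclusion_filter(study$expression$de_binding,
                           study$expression$de_nonbinding)
assoc  <- window_occupancy(groups, tracks, study$tss, study$promoters,
                           study$genes, start_codon_offset = cfg$utr_length)
assoc$tests[, c("window", "mean_up", "mean_down", "p")]
#>   window      mean_up mean_down          p
#> 1 gene_body    0.873      0.875  0.82
#> 2 promoter     0.127      0.404  0.0066
#> 3 start_codon  0.645      0.958  0.20
#> 4 tss_pm25     0.0169     1.15   0.000015
#> 5 tss_point    0          1.32   0.0000073
```

Down-regulated genes carry far higher occupancy at the TSS (±25 bp)
than up-regulated genes, while the 51 bp start-codon control window
shows only an attenuated echo — occupancy at the promoter, not
downstream of it, tracks repression.

```r
# 4. compendium similarity: the planted comparison ranks first
head(compendium_similarity(study$expression$de_binding,
                           study$expression$compendium), 1)
#>   comparison similarity   rho n_shared
#> 1 cmp030           67.5 0.451      100
```

`run_pipeline(default_config(seed = 1L), out_dir = "out")` chains all
stages and writes every result table as TSV;
`inst/scripts/run_pipeline.R` wraps it for shell use, and
`make_fixtures()` writes a complete on-disk synthetic input set
(FASTA/BED/TSV/YAML).

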