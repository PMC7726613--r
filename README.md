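# AmpliScreen

Multi-locus amplicon screening of individual wild-caught mosquitoes, from
pooled multiplexed reads to per-mosquito biology and microbiota
statistics.

A single multiplexed run carries, for every mosquito, amplicons from six
loci: bacterial 16S rRNA (microbiota), the *kdr* fragment spanning the
L1014F pyrethroid-resistance site, the S200X6.1 and *cox1* species
markers, mammalian 16S (blood-meal source), and eukaryotic
parasite/arbovirus markers. AmpliScreen is for vector biologists and
genomic-surveillance analysts who need all of those answers per mosquito
from one sequencing run — and a way to validate the whole pipeline
without touching real data: a synthetic-data module simulates complete
runs (barcoded read pairs, extraction controls, cross-contamination, a
site-structured bacterial community with a controllable effect size) with
known ground truth.

## What it computes

* **Read routing**: exact barcode and anchored-primer matching,
  best-overlap pair merging (>= 12 bp, quality-consensus), primer
  trimming with the 50 bp short-amplicon guard, and the > 90 bp length
  floor; every pair is accounted for in a disposition tally.
* **Unique-sequence tables** per locus with the < 10-reads-global filter
  and per-sample floors (16S: 5000 reads; *kdr*/species/blood meal:
  1000).
* **kdr genotype** from the allele-ratio statistic
  r = Seq2/(Seq1+Seq2) over the two most abundant sequences:
  r < 0.15 homozygous (RR/SS by allele match), r > 0.35 heterozygous
  (RS), the band between uncalled.
* **Species** from S200X6.1 with F1-hybrid detection (two distinct
  high-ratio alleles) and a *cox1* fallback that rescues *An. nili*.
* **Blood meal** (fed iff >= 1000 mammalian 16S reads, multi-host
  profiles) and **parasite/virus detections** (>= 70% global identity to
  the packaged references, extraction-control flags, contamination
  annotation).
* **Community statistics**: Bray-Curtis
  (d = 1 − 2·Σ min(x<sub>i</sub>, y<sub>i</sub>) / (Σx + Σy)), weighted
  UniFrac (Σ<sub>branches</sub> ℓ<sub>b</sub>·|p<sub>A</sub>(b) −
  p<sub>B</sub>(b)|), PCoA, and a sequential distance-based PERMANOVA
  (Gower-trace sums of squares, R² = SS/SS<sub>total</sub>, permutation
  p with the add-one convention) partitioning microbiota variance among
  collection site, species, *kdr* genotype, blood-meal and infection
  status.

## Worked example

Simulate a small noise-free cohort, demultiplex it, and genotype *kdr*:

```r
library(AmpliScreen)
truth <- simulateCohort(24, nSites = 3, siteEffectSize = 0.2,
                        nControls = 4, seed = 1)
ids   <- truthTable(truth)$sample_id
panel <- buildPanel(nBarcodes = length(ids), sampleIds = ids, seed = 1)
cfg   <- runConfig(depth = c(bact16S = 5200, kdr = 1200, S200X6.1 = 1200,
                             cox1 = 1200, mamm16S = 1500, parasite = 800),
                   dispersion = 0, errorRate = 0, seed = 1)
paths  <- emitRun(truth, panel, cfg, "run_out")
routed <- demuxRun(paths$fastq1, paths$fastq2, panel)
routed
#> RoutedRun: 219530 read pairs
#>         disposition      n
#>              merged 219530
#>       unmerged-kept      0
#>     discarded-short      0
#>  unassigned-barcode      0
#>       unknown-locus      0

calls <- callKdr(filterRare(dereplicate(routed, "kdr")), panel)
#>   sample_id count1 count2     ratio total    call
#>   ctrl_004      4      2 0.3333333     6 NO_CALL
#>   mosq_001   1199      0 0.0000000  1199      RR
```

Each mosquito's 1200 *kdr* reads collapse to one or two allele sequences;
ratio 0 with a resistant-allele match calls RR, while the extraction
controls sit far below the 1000-read floor and stay uncalled. The
community layer then partitions microbiota variance:

```r
tab16 <- filterRare(dereplicate(routed, "bact16S"))
asv <- buildAsvTable(tab16, truthMetadata(truth),
                     taxonomy = assignTaxonomy16S(tab16, panel))
permanova(brayCurtis(asv),
          as.data.frame(SummarizedExperiment::colData(asv)),
          c("site", "species", "kdr_genotype", "fed", "infected"),
          nPerm = 999, seed = 1)
#> Sequential (Type I) distance-based PERMANOVA, 999 permutations
#>              Df SumOfSqs     R2      F    Pr
#> site          2 0.297360 0.1998 2.6450 0.001
#> species       2 0.141010 0.0948 1.2542 0.123
#> kdr_genotype  2 0.102510 0.0689 0.9118 0.631
#> fed           1 0.072227 0.0485 1.2849 0.170
#> infected      1 0.031767 0.0213 0.5651 0.951
#> Residual     15 0.843200 0.5666     NA    NA
```

The cohort was simulated with a planted 0.2 between-site community
effect; the location term recovers R² ≈ 0.20 at the permutation floor
p = 0.001, and the biological factors contribute only marginally —
exactly the structure such a screen is designed to resolve.
`runPipeline()` wraps the whole flow (simulate → demux → tables → calls →
community) from a flat config file and writes per-stage TSVs plus a JSON
summary; `inst/scripts/ampliscreen.R` is a command-line wrapper.

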