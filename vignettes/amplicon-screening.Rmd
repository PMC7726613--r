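---
title: "Multi-locus amplicon screening of individual mosquitoes: methods and models"
author: "AmpliScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-locus amplicon screening: methods and models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AmpliScreen)
```

## Overview

AmpliScreen analyses pooled, multiplexed amplicon sequencing of individual
wild-caught *Anopheles* mosquitoes. A single sequencing run carries, for
every mosquito, amplicons from six loci: bacterial 16S rRNA (microbiota),
the voltage-gated sodium-channel *kdr* fragment spanning the L1014F
knockdown-resistance site, the nuclear S200X6.1 and mitochondrial *cox1*
species markers, mammalian mitochondrial 16S (blood-meal source), and a
panel of eukaryotic-parasite / arbovirus markers. Reads are routed to
mosquitoes by a sample barcode and to loci by the PCR primer, merged into
consensus amplicons, dereplicated into unique-sequence count tables, and
turned into per-mosquito biological calls. The bacterial stream feeds a
community analysis: Bray-Curtis and weighted UniFrac dissimilarities, PCoA
ordination, and a sequential distance-based PERMANOVA that partitions
microbiota variance among collection site, mosquito species, *kdr*
genotype, blood-meal status and infection status.

Because real screening data are large and external, the package ships a
first-class synthetic-data module: it simulates complete multiplexed runs
with known per-mosquito truth, so every stage of the pipeline — and the
variance partition at the end — can be tested against a planted answer.

## Read routing and merging

* **Barcodes and primers are matched exactly**, with zero mismatch
  tolerance; pairs whose read-1 prefix matches no barcode, or whose
  post-barcode bases match no primer, are counted as unroutable and
  discarded. When one primer is a prefix of another, the longest match
  wins. Exact matching keeps demultiplexing unambiguous and is the
  conservative choice for individual-level genotyping, where barcode
  error-correction risks mis-assigning reads between mosquitoes.
* **Merging** finds the best-scoring ungapped overlap between read 1 and
  the reverse-complemented read 2: at least 12 overlapping bases, at most
  a 0.25 mismatch fraction in the overlap (both configurable). Among
  qualifying offsets the lowest mismatch fraction wins, ties go to the
  larger overlap, and at mismatched positions the higher-quality base is
  kept (read 1 on quality ties — an arbitrary but fixed tie-break).
  Pairs that fail to merge are not discarded: they continue as
  read-1-only sequences, which still carry the barcode, the primer and
  usually most of the amplicon.
* **Trimming**: when both primers are found the insert between them is
  retained. When only the forward primer is found the sequence is left
  untrimmed at the 3' end, except that loci with an expected amplicon
  under 300 bp lose an additional 50 bp from the 5' end, a guard against
  primer dimers at short-amplicon loci. Trimmed sequences are kept only
  if strictly longer than 90 bp.

## Unique-sequence tables and filters

Retained sequences of each locus are dereplicated by exact string
identity into a unique-sequence x sample count table
(`UniqueSeqTable`, a `SummarizedExperiment`). Three filters apply:

* sequences containing `N` are dropped before dereplication;
* unique sequences observed fewer than **10 times across all samples**
  are removed as likely error sequences;
* per-sample read floors: **5000 reads** for the bacterial 16S stream
  (shallow 16S samples mostly reflect cross-contamination), **1000
  reads** for *kdr*, species and blood-meal calls. The parasite/virus
  stream has no per-sample floor — low-count detections are real signal
  there, and the contamination annotation (below) handles the rest.

All boundary semantics are deliberately literal: 4999 16S reads are
excluded and 5000 retained; 999 reads give no call and 1000 do; a
sequence of exactly 90 bp is discarded. The package treats exact unique
sequences after these filters as ASV proxies; it does not re-implement a
denoising error model or chimera removal, so counts of rare variants are
noisier than a denoised analysis would give. This is documented as a
limitation, not a hidden substitution.

## Per-mosquito calls

**kdr genotype.** For each mosquito the two most abundant unique *kdr*
sequences (Seq1, Seq2; count ties broken lexicographically) define the
ratio Seq2/(Seq1+Seq2), which is near 0 for homozygotes (Seq2 is then
sequencing error) and near 0.5 for heterozygotes. Ratios below **0.15**
call a homozygote — RR if Seq1 best-matches the packaged resistant
(L1014F) allele, SS otherwise — ratios above **0.35** call RS, and the
band between is left uncalled. A mosquito with a single unique sequence
has ratio 0, the natural limit of the formula. The call is
scale-invariant in the counts. Allele identity comes from matching
against a packaged allele reference rather than positional SNP calling,
matching the amplicon-sequence paradigm of the assay.

**Species.** The most abundant S200X6.1 sequence (at >= 1000 reads) is
matched against the species references. If the top two sequences pass the
same 0.35 heterozygosity cut-off used for *kdr* (the assay defines no
separate hybrid cut-off, so the rule is reused uniformly) and map to
different species, the mosquito is reported as a likely F1 hybrid with
both names. Mosquitoes without an S200X6.1 call but with >= 1000 *cox1*
reads are called from *cox1*; in this panel that rescues *An. nili*,
whose S200X6.1 amplification fails. The implementation reports whatever
species *cox1* best-matches rather than hard-coding *An. nili*: the locus
is the fallback, not the species.

**Blood meal.** A mosquito is blood fed iff its mammalian 16S locus
yielded **>= 1000 reads** ("at least 1000" is used rather than the
stricter ">"; the choice is configurable). Each unique sequence is
matched to the mammal references and counts aggregate per host;
multi-host meals are reported as multiple rows.

**Parasites and viruses.** Every unique sequence is matched against the
marker references; hits need **>= 70% global identity over the full
query** (end-gap-free alignment, identity = matches / alignment length).
Exact identity ties are reported together, joined with `/`; no
wider near-tie window is applied, because no such window is defined for
the assay. Extraction-control detections are flagged, and any
non-control detection with fewer reads than `ratioThreshold` (default 2)
times the same-target control mean is annotated as possible
contamination.

## Community statistics

Bray-Curtis dissimilarity is computed on raw counts (the default of the
ecology-software family this analysis belongs to; proportions can be
passed instead). Weighted UniFrac sums, over tree branches, branch length
times the absolute difference in the proportion of each sample's reads
descending from the branch; an optional flag normalises by the total
branch-weighted proportion mass. PCoA Gower-centres the squared
dissimilarities and eigendecomposes; axes are scaled by the square root
of their eigenvalues and negative eigenvalues are dropped from the
variance denominator (no Cailliez/Lingoes correction by default — the
simplest defensible convention, exposed as a choice for the caller).

The variance partition is a sequential (Type I) distance-based PERMANOVA:
factors enter in a fixed order (site, species, *kdr* genotype, blood-meal
status, infection status), each term's sum of squares is the Gower-trace
increment of its cumulative projection, and R-squared is that sum over
the total. Categorical factors use full-rank treatment contrasts with a
1e-8 rank tolerance; constant or collinear terms get zero df and an NA
p-value rather than an error. Significance permutes samples (rows and
columns of the dissimilarity jointly) with the add-one convention, so the
default 999 permutations give a minimum attainable p of 0.001. Term sums
of squares plus the residual always reconstruct the total, for every
ordering; the suite verifies this, along with exact agreement of SS, R²
and F with an independent implementation (`vegan::adonis2`, by terms) and
agreement of sampled p-values with full enumeration at small n.

## The synthetic cohort model

The generator mirrors the structure of a field screening study:

* **Cohort composition**: species frequencies follow the screened cohort
  (about 74% *An. gambiae*, 11% *An. coluzzii*, 10% *An. melas*, rare
  *An. arabiensis* and *An. nili*, and ~2% gambiae x coluzzii F1
  hybrids); *kdr* genotype frequencies are conditional on species
  (resistant alleles concentrated in *An. gambiae*, wild-type in
  *An. melas*/*An. arabiensis*, mixed in *An. coluzzii*); about 20% of
  mosquitoes are blood fed (mostly human, some cow/sheep and ~12%
  multi-host), and about 19% carry a parasite or virus. Heterozygotes
  and hybrids are simulated as 50/50 template mixtures perturbed by the
  multinomial read draw, which reproduces the bimodal allele-ratio
  distribution the genotype cut-offs assume.
* **Depths** default to the per-mosquito averages of the assay (16S
  11730; *kdr* 2436; S200X6.1 2917; *cox1* 1181; parasite 1876 reads;
  the blood-meal average is unpublished and defaults to 3000 for fed
  mosquitoes, with a 2% environmental carry-over for unfed ones), drawn
  negative-binomially with configurable dispersion (0 = exact depths).
* **Errors** are substitution-only at a configurable per-base rate
  (default 0.001); no indels, so merge and dereplication behaviour stays
  analysable. No instrument-specific quality profiles, chimeras or
  structured index-hopping are modelled — passing tests therefore speak
  to the logic of the pipeline, not to robustness against every artefact
  of real sequencers.
* **Extraction controls** carry no template; they receive only reads
  leaked from real samples at a flat per-read mis-assignment rate
  (default 5e-4), which reproduces the qualitative control signature of
  pooled runs: nonzero but low read counts, occasionally enough to
  "detect" a parasite at low support.
* **Bacterial communities** live on 60 synthetic ASVs with taxonomy and a
  reference tree. Log-abundances are Gaussian around per-site centroids:
  a cohort-level base profile, site centroids displaced by a spread
  parameter, per-sample displacement of fixed width, softmax-normalised,
  then multinomially sampled at the 16S depth.

The spread parameter is the only dial for the planted site effect. The
mapping from a requested between-site variance share to a spread is a
pre-computed monotone lookup (`inst/scripts/calibrate_site_effect.R`),
calibrated once under the package's reference condition — 120 mosquitoes,
6 sites, 16S depth 6000, the <10-read and 5000-read filters applied —
by measuring the mean location R² of a one-factor Bray-Curtis PERMANOVA.
A requested effect of 0 bypasses the lookup and places all sites on one
centroid, making compositions exchangeable across sites. Note that the
realised R² at effect 0 is not 0 but the null expectation of a sequential
R² (about df/(n-1)); the lookup is anchored to realised R², so a
requested 0.2 means "cohorts whose location R² averages 0.2", which is
how the planted-effect recovery checks read it.

## Problem sizes and numerical choices

The reference checks use the sizes at which the package is routinely
exercised: noise-free end-to-end recovery on a 120-mosquito, 6-locus run
at depths just above every floor (16S 5200, calls 1200-1500, parasite
800); planted-effect recovery as the mean location R² of 20 cohorts
(n = 120, 6 sites); null calibration as the location rejection rate at
alpha = 0.05 over 200 cohorts of 40 mosquitoes with 999 permutations.
Depth floors, ratio cut-offs, identity floor, overlap minimum and length
floor are all exercised at their exact boundaries in the unit suite.

Other numerical conventions: alignment identity uses match 2 / mismatch
-2, gap open 4 / extend 2, with reference end gaps free; ranking ties in
reference hits are broken by name for determinism; permutation streams,
barcode generation, cohort draws and read emission are all seeded, and
identical seeds give byte-identical FASTQ output.

## A short worked example

```{r example, eval = FALSE}
truth <- simulateCohort(24, nSites = 3, siteEffectSize = 0.2,
                        nControls = 4, seed = 1)
ids <- truthTable(truth)$sample_id
panel <- buildPanel(nBarcodes = length(ids), sampleIds = ids, seed = 1)
cfg <- runConfig(depth = c(bact16S = 5200, kdr = 1200, S200X6.1 = 1200,
                           cox1 = 1200, mamm16S = 1500, parasite = 800),
                 dispersion = 0, errorRate = 0, seed = 1)
paths <- emitRun(truth, panel, cfg, tempfile("run"))
routed <- demuxRun(paths$fastq1, paths$fastq2, panel)
kdrTab <- filterRare(dereplicate(routed, "kdr"))
callKdr(kdrTab, panel)
```

`runPipeline()` wraps the same flow end to end (simulate, demultiplex,
tables, calls, community statistics) from a flat key=value configuration
and writes per-stage TSVs plus a JSON summary;
`inst/scripts/ampliscreen.R` is a thin command-line wrapper around it.

## Known limitations

* Exact unique sequences stand in for denoised ASVs; no chimera removal.
* Taxonomy and best-hit identification use the packaged (synthetic-label)
  reference panel, not a live database search; real deployments should
  swap in curated per-locus references via `buildPanel()`.
* The contamination model is a flat leak rate; structured index hopping
  and within-plate spatial effects are out of scope.
* Unmerged pairs re-enter as read-1-only sequences for all loci; a
  quality-aware per-locus treatment (as a denoising pipeline would do for
  16S) is not attempted.
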