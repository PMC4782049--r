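# srexport

Tools for analysing how sequence-specific RNA-binding proteins — the
serine/arginine-rich (SR) splicing factors SRSF1–7 are the motivating
family — act as adaptors for the bulk mRNA export receptor NXF1, and how
their depletion changes cytoplasmic mRNA abundance, exon usage and 3' end
choice.

The package covers the full quantitative chain for this kind of study:

* **iCLIP cross-link calling** — PCR deduplication by random barcode,
  cross-link inference from read truncation (the cross-linked base is one
  nucleotide 5' of the read start), per-gene permutation FDR for
  significant positions (counts are compared against uniform
  redistribution of the gene's cDNAs), and merging of nearby significant
  positions into binding sites with max-count centers.
* **Binding landscapes** — metagene profiles around 5'/3' splice sites,
  spliced vs unspliced junction-read proportions, region occupancy
  normalized to feature length, exon cobinding matrices with
  Spearman/distance-correlation clustering, receptor-centric ±30 nt
  cobinding windows (a library cobinds when it has more than three
  significant positions in the window), and region-stratified 8-mer
  enrichment z-scores against a randomized-placement background.
* **Fractionated RNA-seq** — median-of-ratios normalization per fraction,
  a negative-binomial likelihood-ratio test, export-target calling
  (significant cytoplasmic decrease at least 1.5-fold beyond the
  whole-cell change), pooled 2×2 exon-usage tests with
  first/internal/last-exon classification, and APA calling: Ψ = the
  distal/long-isoform fraction of tandem-UTR or alternative-last-exon
  events, called at Beta-Binomial Bayes factor > 5 and |ΔΨ| ≥ 0.20.
* **A synthetic-data generator** with machine-readable planted truth
  (motifs, receptor cobinding rates, export targets, usage and Ψ shifts)
  that drives the whole validation suite.

Central containers are Bioconductor-native: an S4 `GenomeAnnotation`
(per-transcript exon/CDS `GRangesList` plus optional genome sequence),
`GRanges` for events/positions/sites, and `SummarizedExperiment` for
count matrices.

## Worked example

Simulate a small study, call sites, and measure receptor cobinding:

```r
library(srexport)

cfg <- simulationConfig(seed = 1, nGenes = 30, nTandemUTR = 5, nALE = 3)
sim <- simulateGenome(cfg)                 # genome + annotation + truth
ic  <- simulateIclip(cfg, sim)             # 9 iCLIP libraries with barcodes

dd  <- deduplicateReads(ic$reads)
ev  <- extractCrosslinks(dd$reads)
sig <- callSignificantPositions(ev, sim$annotation, fdrThreshold = 0.05,
                                nPerm = 100, seed = 7)
sites <- mergeBindingSites(sig)

nx <- sites[sites$library == "NXF1"]
sr <- list(SRSF3 = sig[sig$library == "SRSF3"])
cobindingRatio(nx, sr, classifyExons(sim$annotation))
```

On this 30-gene simulation the run prints, among other strata:

```
    stratum library n_cobound n_total    ratio
2 last_exon   SRSF3         7      16 0.437500
```

i.e. roughly half of the NXF1-like binding sites in last exons carry an
SRSF3-like cluster within ±30 nt, tracking the generator's
`cobindRate = 0.5` up to the sampling noise of a 16-site toy run (the
validation scenarios use >500 sites and recover the rate within ±0.05).
The motif module recovers the planted SRSF3-like 8-mer as the top-ranked
k-mer:

```r
w   <- extractWindows(sig[sig$library == "SRSF3"], sim$annotation, "all")
tab <- kmerEnrichment(w, sim$annotation, seed = 11)
head(tab, 1)
#       kmer observed bg_mean    bg_sd        z
# 1 TCAACATC     1216   49.63 6.327198 184.3423
```

`runPipeline(cfg, "out/")` executes every stage (simulate → callsites →
junctions → occupancy → cobind → motifs → diffexport → exonusage → apa →
report), writing TSV/BED artifacts and a JSON manifest with the seed,
parameters and an md5 checksum per file; a second run with the same seed
reproduces every checksum. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

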