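# condenseq

Analysis toolkit for **single-condensate RNA sequencing**: experiments in
which individual phase-separated droplets — synthetic coacervates
(CM-Dex:PDDA, CM-Dex:pLys) or protein condensates (FUS, Dhh1) — are sorted
one per well by FACS, their RNA content is sequenced, and the resulting
transcript-by-condensate quantification is mined for the sequence features
that drive RNA uptake. It is written for researchers studying RNA
partitioning into biomolecular condensates and protocell models who start
from a count/TPM matrix plus per-droplet metadata.

## What it computes

The pipeline starts downstream of quantification and covers:

* **QC and quantification** — TPM per condensate
  (`tpm_t = 10^6 · (c_t/ℓ_t) / Σ_u (c_u/ℓ_u)`), removal of large droplets
  (FSC > 2·10⁴) with pseudoalignment < 5 %, a 20 % read-coverage filter for
  poorly-aligned datasets, and zeroing of sub-TPM ( < 1) entries; plus
  partition coefficients `K = I_droplet / I_supernatant` from fluorescence
  intensities.
* **Enrichment calling** — each transcript's *detection frequency* `f_t`
  (percent of passing droplets in which it is detected) is compared with a
  penalized cubic smoothing-spline expectation `ŝ(log₁₀(TPM_t + 1))` fitted
  across the whole pool (GCV smoothing); transcripts with residual
  `f_t − ŝ > 30` percentage points are called **enriched**: taken up far
  more often than their input abundance predicts.
* **Sequence complementarity** — an affine-gap Smith–Waterman aligner
  (gap of length L costs `open + L·ext`) with two preset schemes
  (match 2 / mismatch −1 / open 30 / ext 0.05 for transcript-vs-transcript
  *trans* complementarity, scored against the reverse complement; and
  open 10 / ext 0 for motif-vs-SINE homology with top-5 hit averaging).
* **Motif tools** — PWM scanning of both strands with log-odds scores,
  cis co-occurrence of a motif and its reverse complement on one
  transcript, nearest-5′-neighbour spacing statistics, and a
  hypergeometric k-mer discovery stand-in for de novo motif discovery.
* **Cross-condensate comparison** — per-type detection-frequency Pearson
  correlations, input-normalised enriched-transcript profiles, PCA (5
  components) + seeded k-means, and Wilcoxon rank-sum differential
  transcripts with Bonferroni correction (α = 0.01).
* **Synthetic data** — `generate_pool()` / `simulate_condensates()` build
  seeded droplet populations with log-normal sizes, size-dependent capture
  depth, abundance-driven uptake, a planted complementary motif pair with
  fixed spacing, and ambient RNA contamination — ground truth for every
  stage above.

## Worked example

```r
library(condenseq)

pool <- generate_pool(n_transcripts = 2000, frac_enriched = 0.05, seed = 1)
pool
#> transcript_pool: 2000 transcripts, median length 1958 nt, 100 with planted motif pair

cm <- simulate_condensates(pool, uptake_model(beta_motif = 2),
                           n_condensates = 192, seed = 2)
qc <- filter_matrix(compute_tpm(cm))
et <- enrichment_table(detection_frequency(qc$matrix), pool$info)
et
#> enrichment_table: 2000 transcripts, 90 enriched (residual > 30, spline smoother)

summary(et)
#> not_detected         lt10          mid         gt90
#>            0           86         1892           22
```

The 100 planted transcripts carry a 24-nt motif and its reverse complement
70 nt apart and receive an `exp(2)`-fold uptake boost; the enrichment call
recovers 90 of them with no false positives (sensitivity 0.90, precision
1.00 against `pool$info$truth_enriched`). Scanning the planted pair and
measuring nearest-5′-neighbour spacings returns the planted distance
exactly:

```r
hits <- scan_motifs(pool$sequences[pool$info$truth_enriched],
                    list(motif("m1", pool$motif_pair[1]),
                         motif("m2", pool$motif_pair[2])))
neighbor_distances(hits)$medians
#>   motif_id neighbor_motif   n median_distance
#> 1       m1             m1 100              70
#> 2       m2             m1 100              70
```

A command-line wrapper with subcommands `simulate`, `qc`, `enrich`,
`scan`, `complement`, `sine` and `run` is installed at `exec/condenseq`.

## Documentation

The methods vignette (`vignettes/condenseq-methods.Rmd`) describes the
uptake model, the enrichment statistics, the alignment conventions and the
design decisions in detail.
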