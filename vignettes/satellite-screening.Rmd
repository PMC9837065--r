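---
title: "Screening pericentromeric satellite transcripts in barcoded single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening pericentromeric satellite transcripts in barcoded single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(satscreen)
```

## The problem

Pericentromeric satellite DNA — human satellites 2 and 3 (HS2/HS3), built on
ATTCC-based repeat units, and the mouse major satellite (MaSat), derived from
the GAAAAATGA unit — is transcribed into long non-coding RNA in tumours, and
cancer-associated fibroblasts are a major cellular source of these
transcripts in lung cancer. Quantifying satellite transcription in droplet
single-cell RNA-seq is awkward with standard gene-counting pipelines: the
transcripts map to tandem repeats, not to annotated gene models, and their
abundance must be compared *between annotated cell clusters* (myofibroblastic
CAFs, normal lung fibroblasts, epithelial and cancer cells), not between
genes.

`satscreen` implements this as a small, fully testable pipeline:

1. **Demultiplex** barcoded read pairs into cell clusters using a
   barcode-to-cluster whitelist (`demultiplex()`).
2. **Verify** each cluster by the expression of its marker genes
   (`verify_cluster_markers()`).
3. **Classify** each cDNA read against satellite repeat-family k-mer
   signatures by window coverage (`classify_reads()`).
4. **Count** molecules by exact UMI collapse (`dedup_umis()`) and report
   per-cluster expression as TPM (`quantify_tpm()`).

It also implements the k-mer-frequency design of satellite FISH probes
(`count_kmers()`, `top_kmers()`, `assemble_probe()`) and the quantification
of FISH signal area in two-channel microscopy fields (`segment_nuclei()`,
`quantify_field()`, `summarize_fields()`), with synthetic generators for
both data types so every stage is exercised end to end without
controlled-access patient data.

## The classification statistic

A repeat family is modelled as the set of k-mers that occur in an unbounded
tandem concatenation of its monomers — the *circular* k-mers — together with
their reverse complements (`build_family_model()`). Circular enumeration is
the right reading frame for satellites: arrays are long monomer
concatenations, so junction-spanning windows are real sequence. It is
well-defined for any $k \ge 1$ (the monomer is wrapped as often as needed),
which matters here because the informative window length (k = 12) exceeds
the 5-bp ATTCC monomer; a monomer of length $m$ with no rotational
self-collision at $k$ contributes exactly $m$ forward k-mers.

For a read $r$ of length $L$, the coverage against family $F$ is

$$ C_F(r) = \frac{1}{L-k+1} \sum_{i=1}^{L-k+1} \mathbf{1}\!\left[ r_{i..i+k-1} \in \mathrm{sig}(F) \right] $$

and the read is assigned to the family with maximal coverage when that
coverage reaches the threshold $\tau$ (ties go to the declared family
order, HS2/HS3 before MaSat). This deliberately replaces alignment: the
signature-membership test is exact, trivially auditable against a
window-by-window oracle, and insensitive to where in an array a read
originates.

### Parameters

* **k (default 12).** The window length used both for probe design — the
  probe strategy counts 12-mer frequencies in repeat units — and for read
  classification. At the 0.5% default sequencing error rate a 90-nt read
  holds 79 twelve-mer windows, giving the coverage statistic a resolution
  of about 1.3 percentage points.
* **tau (default 0.5).** A satellite read must have at least half its
  windows in the signature. For a read drawn from an array with per-base
  divergence $d$ and sequencing error $e$, the expected coverage is
  approximately $(1-d-e)^k$; tau = 0.5 therefore tolerates a combined
  per-base corruption of about 5.6% at k = 12. Raising tau only removes
  hits (threshold coherence), which the tests assert.
* **Effective length (default 1 kb per satellite family).** Satellite
  transcripts have no defined gene model, so the TPM length normalisation
  uses a nominal constant. Between-cluster TPM *ratios* for the same
  feature are invariant to this constant when the clusters share a feature
  set, which is asserted by a unit test; absolute satellite TPM values
  should be read with that convention in mind.
* **min_marker_reads (default 10).** A cluster must show at least this
  many reads matching its own marker transcripts (exact shared-k-mer seed
  match) or it is excluded from the expression table and listed in the
  report.
* **Quality gate (Q20).** Reads with mean base quality below 20 are
  dropped before classification and logged; the generator can emit Q10
  reads to exercise this path.
* **UMI handling.** Exact-match collapse of (barcode, UMI) pairs per
  feature, the droplet convention; `use_umi = FALSE` switches to raw read
  counting for data without UMI structure.

Unassigned barcodes are never rescued (no 1-mismatch correction): barcode
recovery is a droplet-caller concern, not part of this method, and exact
assignment keeps the read-conservation invariant trivial to audit
(`assigned + unassigned = total`, checked on every run).

## The probe-design strategy

The MaSat hybridization oligo is designed by counting the frequency of
every 12-mer across satellite arrays, ranking (count descending, ties
lexicographic), and greedily merging the top k-mers by maximal
suffix/prefix overlap into a probe of bounded length (default 25 nt). The
greedy rule is an explicit design choice — the historical description says
only that frequent 12-mers were "assembled" — so the rule, its tie-breaks
(higher rank wins equal overlaps) and the length cap are all configuration,
and the published 23-nt MaSat probe (`masat_probe()`) is shipped as a
verbatim regression fixture rather than re-derived: the genomic arrays it
was derived from are not redistributed with the package. Counting is
forward-strand only, because a probe hybridizes as a single strand; strand
closure lives in the family signature instead.

The published 48-nt DYZ1 oligo (`dyz1_probe()`) is pure ATTCC rotations, so
its coverage against the HS2/HS3 model at k = 5 is exactly 1.0 — a fixed
point the acceptance tests assert.

## What the read generator emulates — and what it does not

`simulate_reads()` draws, per cluster and cell, reads from a
(satellite, marker, background) mixture:

* satellite reads are random windows of a divergent tandem array
  (`expand_array()`) of the configured family;
* marker reads are windows of the cluster's own marker transcripts. The
  marker *names* are the published cluster markers (CTHRC1, VCAN, ... for
  the myCAF-like cluster 1; GPC3, MFAP4, ... for normal-fibroblast cluster
  6); the *sequences* are seeded random transcripts, keeping the package
  download-free. Cluster 3 (no detectable marker in the source study) and
  the alveolar/cancer clusters, whose marker lists were not printed, carry
  clearly synthetic placeholder names (SYN3A, SYNALV1, SYNTUM1, ...).
* background reads are windows of synthetic transcripts shared across
  clusters.

Default conditions: five clusters × 10 cells × 200 reads, satellite read
fractions 0 (cancer), 0.5%, 1%, 2% and 5% (myCAF-like), marker fraction
10%, sequencing error 0.5% per base, read length 90 nt, 16-bp barcodes,
10-bp UMIs. This reproduces the study's qualitative contrast — satellite
expression severalfold higher in myCAF-like fibroblasts than in other
fibroblast subpopulations and essentially absent from cancer cells — as a
known ground truth.

**Array divergence (default 0.02).** The expected window coverage of a
satellite read is $(1-d-e)^k$; at $d = 0.05$ this is ≈ 0.51, i.e. exactly
at the default threshold tau = 0.5, which would make detection a coin flip
and the simulation uninformative about the pipeline. The default of 0.02
puts expected coverage near 0.74 — satellite reads are reliably detectable,
as they are for a well-designed signature on real satellite transcripts,
while coverage remains strictly partial so the statistic's intermediate
regime is still exercised (classification tests additionally probe
divergence-0.05 fragments).

The generator deliberately omits droplet chemistry artefacts — ambient RNA,
doublets, barcode collisions or sequencing indels — and uses uniform random
background transcripts rather than a real transcriptome. Passing tests
therefore demonstrate the correctness of the *computation* (demultiplexing,
classification, counting, normalisation) under known truth; they do not
certify performance on real droplet libraries, where barcode errors and
repeat-like endogenous sequences add noise this generator does not model.

## FISH quantification

`segment_nuclei()` thresholds the DAPI channel (global Otsu by default),
fills holes, labels connected components and discards those below
`min_area` (default 100 px). Touching nuclei merge into one label —
documented behaviour, not an error; no watershed splitting is attempted.
`quantify_field()` thresholds the FISH channel the same way and reports,
per nucleus, the percentage of the nucleus area occupied by signal, plus
field totals of signal pixels inside nuclei and inside the cytoplasmic
compartment. "Cytoplasm" is operationalised as a 15-px dilation ring
around the nuclei: the original quantification's cell-boundary definition
is not available, so the ring radius is an explicit, documented parameter
rather than an inference. A constant channel yields zero signal pixels
under Otsu (there is nothing to separate), and a fixed-value threshold is
available for reproducibility comparisons.

`simulate_fish_image()` paints non-overlapping random ellipses (DAPI) and
sets *exactly* `round(fraction × area)` signal pixels inside each nucleus
and the requested fraction of the ring (FISH), recording the painted
counts, so area-fraction recovery is testable to integer precision. Images
are noise-free by default (recovery within one percentage point is then an
exact-accounting property, not a statistical one); optional Gaussian noise
exercises threshold behaviour. The simulated "RNase treatment" contrast —
nuclear signal fraction 0.5% versus 10% — mirrors the experimental control
in which hybridization signal is almost completely removed by RNase, and
is recovered as a ≥ 10× group-mean difference.

## Numerical and design choices

* All RNG paths go through one master seed; child streams are derived by
  seeded `sample.int`, and every generator restores the caller's RNG
  state. Identical seeds give byte-identical FASTQ, truth tables and
  expression tables (hashed in the tests).
* Ties are broken deterministically everywhere: lexicographic for k-mer
  ranks and marker genes, declared model order for family assignment.
* TPM is computed per cluster over all of that cluster's features
  (satellite families, its marker genes, and one pooled background
  feature), so $\sum \mathrm{TPM} = 10^6$ per non-empty cluster to
  machine precision; zero-count clusters get all-zero rows and are
  flagged rather than dropped.
* Monomers and signatures are uppercased; N and IUPAC ambiguity codes are
  rejected at model build. The synthetic data never emit them, and
  real-data ambiguity handling is out of scope.
* Reads shorter than k are never classified and are counted separately;
  `k` values larger than a monomer length are legal (wrapped circular
  enumeration), while `k` exceeding a *linear* array length is an error
  naming the offending array.
* The MaSat monomer reference ships the single canonical GAAAAATGA unit;
  the four historically described MaSat-derived oligonucleotide variants
  were never printed in an accessible form, so the reference documents
  this substitution and accepts additional monomers per family via the
  `">family|monomer_id"` FASTA convention.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
10,000 reads for the classifier/oracle comparison (grids of
k ∈ {8, 12, 16} and tau ∈ {0.3, 0.5, 0.8}), 50 replicates of the
five-cluster default design (10,000 reads each) for TPM rank/ratio
recovery, and 512×512 single-plane fields with five nuclei for FISH
recovery at fractions 0–50%. These sizes were chosen so the full
validation completes in a few minutes on one core while keeping the
binomial sampling noise of the smallest spike (0.5% of 2,000 reads per
cluster, ~10 reads) clearly visible in the recovery statistics — the rank
recovery rate across replicates is expected near 96–98%, not 100%, and the
acceptance check asks for ≥ 95%.

## Known limitations

* Family-level quantification only: reconstruction of individual satellite
  transcript isoforms is out of scope.
* No barcode error correction, no alignment, no indel model.
* Absolute satellite TPM depends on the nominal effective-length constant;
  only between-cluster comparisons are calibration-free.
* FISH analysis is 2-D, single-plane, two-channel; no spot counting, size
  distributions, z-stacks or colocalization.
* The marker-verification seed match is exact k-mer sharing, adequate for
  synthetic transcripts but weaker than alignment on real paralog-rich
  transcriptomes.
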