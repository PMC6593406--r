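---
title: "Verifying gene absence from raw metagenome reads"
author: "symbioscreen maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying gene absence from raw metagenome reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioscreen)
```

## The model

A genome bin assembled from a host–symbiont metagenome is a hypothesis, not
an observation. When such a bin lacks all key enzymes of the known
autotrophic CO₂-fixation pathways, three artifact explanations compete with
true absence: the gene was misassembled, it fell outside the bin, or its ORF
was mispredicted. `symbioscreen` tests the gene directly against the raw
reads, in three steps.

**Translated recruitment.** Reads are aligned in all six frames against
curated protein panels by local alignment (Smith–Waterman, BLOSUM62, gap
open 11 / extend 1), and each read keeps its single best hit passing strict
thresholds (E-value < 10⁻⁵, amino-acid identity > 30%). The thresholds are
deliberately strict inequalities, exactly as such screens are usually
reported. Subject coverage is available as a third threshold; the read
screen leaves it at 0 (a 150-bp read can never cover 70% of a full-length
enzyme) while the protein-vs-protein transporter census uses > 70%.

**FPKM with a panel reference length.** A panel of mean amino-acid length
$\bar L$ recruiting $n$ reads from a library of $N$ reads gets

$$\mathrm{FPKM} \;=\; \frac{n}{(3\bar L/1000)\,\cdot\,(N/10^6)},$$

the reference length being three times the mean amino-acid length of the
panel, in nucleotides. Two denominators exist in practice: for raw-read
screening there is no "mapped" universe, so $N$ is the library's read-record
count; for expression of assembled features (`expressionPercentile()`) $N$
is the number of reads mapped to the assembly, and the feature's own length
replaces the panel reference length. Both definitions are implemented and
the screening default is documented rather than hidden.

**Relative coverage and the two-step absence call.** Each panel's FPKM is
divided by the median FPKM of the reference panels (genes expected present
in every genome of the clade; the median of an even count is the mean of
the middle two). The call logic in `callAbsence()` is:

1. relative coverage ≤ 1/50 → `absent` outright;
2. otherwise, if the panel's candidate reads were re-mapped onto the binned
   assembly and the majority (> 0.5) of the mapped ones land outside the
   focal bin → `absent` (the signal belongs to a co-occurring organism);
3. otherwise `present` (attribution evidence mostly inside the focal bin)
   or `ambiguous` (no attribution evidence).

Unbinned contigs count as "outside" (they are not evidence for the focal
genome), while unmapped reads carry no bin evidence at all and are excluded
from the fraction's denominator. Both conventions are explicit arguments of
the implementation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `minScore` (engine floor) | 110 | raw BLOSUM62 score (≈ 43 bits) | see calibration below |
| `evalueMax` | 10⁻⁵ | — | the printed screening threshold, strict |
| `minIdentity` | 30 | % aa identity | printed threshold, strict |
| `minSubjectCov` | 0 (reads) / 70 (census) | % of subject | see above |
| `foldThreshold` | 50 | fold below reference median | the published absence criterion |
| `seedLength` | 5 | aa | exact-seed sensitivity/speed balance |
| mapper `minIdentity` | 0.97 | fraction | the usual strict re-mapping identity |
| mapper `minReadCov` | 0.9 | fraction of read | near-full-length placement |
| TM window / cutoff | 19 / 1.6 | residues / mean hydropathy | classic hydropathy-plot settings |
| `nResamples` | 200 | draws | the standard resampling depth for accumulation curves |
| NMDS `restarts` | 2000 | random starts | a thorough published configuration; small matrices need far fewer |

**Calibration of `minScore`.** The engine attaches an approximate E-value by
the Karlin–Altschul form $E = K m n e^{-\lambda S}$ with the gapped BLOSUM62
defaults ($\lambda = 0.267$, $K = 0.041$) and per-read search space
$m n = (\text{read length}/3) \times \text{total panel residues}$. For a
typical screen (150-bp reads, a few thousand panel residues) a raw score of
110 corresponds to roughly $E \approx 10^{-8}$ per read, so even libraries
of millions of unrelated reads are expected to produce no spurious hit;
conversely a read overlapping a true panel gene in frame by ~75 nt at high
identity scores well above 110. The floor therefore behaves like a
minimum-overlap rule: reads are counted once they overlap the gene by about
half a read length, which keeps the effective counting window close to the
gene length itself and the FPKM close to its depth-based expectation. The
E-value is reported for comparability with external tools but thresholding
inside the engine uses the raw score, because external E-values are
tool- and version-dependent while raw Smith–Waterman scores are exact.

External tools can replace the built-in engine at any boundary: tabular
(12-column, `outfmt 6`) hits enter through `parseTabularHits()`, SAM
mappings through `readSamMapping()` (identity recomputed from CIGAR + NM),
and precomputed transmembrane calls can replace the built-in hydropathy
predictor in `buildFamilyMatrix()`.

## The synthetic-data generator

`simulateCommunity()` draws i.i.d. nucleotide sequences at target GC — the
genomes deliberately contain *no* genes, so every protein-coding signal is
one that `implantGenes()` wrote and recorded in the truth table. Implants
are back-translated with uniform-random synonymous codons, so two copies of
a peptide share amino-acid but not nucleotide identity, exercising the
translated search rather than plain nucleotide matching. `generateReads()`
draws source genomes proportional to abundance × length, start positions
uniformly, strands equiprobably, and applies i.i.d. substitution errors
(drawing K ~ Binomial(total bases, rate) error positions without
replacement, which is exactly the per-base Bernoulli model).

`simulateScreenScenario()` fixes the study conditions used throughout the
validation: three 50-kb genomes — a focal symbiont at 80% relative
abundance and contaminants at 15% and 5%, GC 0.45/0.50/0.55 — four
single-copy reference enzymes (TCA-cycle stand-ins) implanted in the focal
genome, three autotrophy-marker targets implanted nowhere, in the focal
genome, or solely in the 5% contaminant, and single-end 150-bp error-free
reads. All panel stand-ins are 300-residue random peptides of equal length,
so coverage ratios between panels isolate sampling error from read-edge
effects. The validation sizes are 2×10⁵ reads per library (≈ 480× focal
depth) across ten seeds for the specificity and attribution conditions, and
5×10⁴ reads (≈ 120× focal depth) for presence recovery.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: GC-dependent and fragment-length coverage bias,
indel and quality-profile errors, real genomic backgrounds (paralogs,
pseudogenes, horizontally transferred fragments, RuBisCO-like proteins that
are near-homologs of a true target), incomplete or chimeric binning, and
panel proteins with real phylogenetic structure rather than random
composition. The specificity results in particular say that *unrelated*
sequence does not recruit; distinguishing a true target from a diverged
homolog is a panel-curation problem, not an alignment-threshold problem.

## Numerical choices and degenerate inputs

- Median: `stats::median` (mean of the middle two for even counts).
- Percentiles of expression: mid-rank percent rank,
  $100\,(n_{lower} + t/2)/(n-1)$ with $t$ the ties excluding self — the
  unique maximum maps to 100, the minimum to 0, full ties to 50. A
  percentile convention had to be chosen; mid-rank is symmetric and
  reproduces the "highest expressed ≈ top percentile" reading.
- Best-hit ties are broken by lexicographically smallest subject id, making
  results invariant to input order; the read mapper breaks contig ties the
  same way.
- A reference-panel median of zero makes relative coverage undefined; this
  is an error ("reference set not detected"), signalling an unusable
  library rather than silently producing infinities.
- Bray–Curtis between two all-zero repertoires is defined as 0 with a
  warning. NMDS coordinates are centered; the fit is `vegan::metaMDS` with
  `autotransform = FALSE`, "runs" interpreted as random restarts, and the
  seed set immediately before the fit so results are bit-reproducible.
- Pan/core accumulation samples genome orders **with replacement** as the
  resampling design; a genome drawn twice within a draw contributes once
  (core sizes are computed over the distinct genome set, so duplicates
  never shrink the core). Uncertainty is the 2.5/97.5 percentile envelope
  across draws. For small N, `exhaustive = TRUE` enumerates all $N^N$
  ordered draws and returns the exact expectation; the test suite checks
  the sampled mode against that enumeration.
- Six-frame translation emits stop codons as `*` and ambiguous codons as
  `X`, and never applies initiator-codon translation (a mid-read CTG is
  leucine, not methionine).

## Known limitations

The built-in engines are desk-scale: exact-seeded Smith–Waterman over
explicit panels and an exact-seeded ungapped read mapper, not heuristic
production aligners. They are contracts (score floor; identity ≥ 0.97 over
≥ 90% of the read) so that diamond/BBMap-class tools can substitute through
the tabular and SAM interfaces for real datasets. The transmembrane
predictor is a hydropathy heuristic, not an HMM; the census accepts external
TM calls for that reason. The uptake-family shortlist that ships with the
package is a small demonstration set — a real census needs the user's
curated shortlist. Paired-end support treats each mate as one read record
for counting, which is the reproducible reading when the FPKM reference
length comes from the panel rather than from fragment sizes.
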