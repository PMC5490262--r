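---
title: "Predicting NMD-eliciting somatic mutations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting NMD-eliciting somatic mutations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdcall)
```

## The biological problem

Nonsense-mediated decay (NMD) is the surveillance pathway that degrades
mRNAs carrying a premature termination codon (PTC). Whether a given somatic
mutation actually triggers NMD depends not on its nominal annotation
(nonsense, frameshift, ...) but on where translation terminates in the
*mutant* transcript relative to the transcript's architecture. A nonsense
mutation in the last exon typically escapes NMD; an in-frame deletion that
juxtaposes nucleotides into a fresh stop codon can elicit it. `nmdcall`
re-annotates somatic mutation catalogues at this mechanistic level and
provides the downstream statistics used to validate such predictions
against expression data.

## The classification procedure

For each gene we use one canonical transcript: the isoform with the longest
coding sequence (CDS), ties broken by the lexicographically smallest
transcript identifier so results are reproducible. The spliced CDS is the
strand-oriented concatenation of the CDS exons; exon–exon junctions are
recorded as offsets into this spliced sequence (the number of CDS
nucleotides strictly upstream of each junction). Junctions internal to the
CDS are the only ones modelled: UTR exon structure is not part of the gene
model, so the "last junction" below always means the last junction on the
CDS.

Wild-type models are filtered before any classification. A gene is dropped
when its CDS contains an in-frame stop before the final codon (`wt_ptc` —
likely mis-annotation, and such mRNAs are poor NMD substrates), does not
begin with ATG (`no_start`), lacks a terminal in-frame stop (`no_stop`), or
when one gene symbol maps to several loci (`duplicate_id`). Mutations are
filtered in turn: non-coding and splice classes (`Splice_Site`, `3'UTR`,
`5'UTR`, `IGR`, `Intron`, `RNA`) are excluded because splice-site mutations
perturb mRNA levels through altered splicing rather than through the PTC
mechanism; records whose reference allele disagrees with the genome are
dropped as suspect; exact duplicate annotations are collapsed to one, but
*distinct* mutations of one gene in one sample are all retained; mutations
whose genomic footprint is not contained in a single CDS exon are excluded
(their consequence depends on splicing, which we do not model).

A kept mutation is lifted into spliced-CDS coordinates (alleles
reverse-complemented for minus-strand genes, since MAF reports
forward-strand alleles) and applied to the wild-type CDS. Junction offsets
strictly downstream of the edit point are shifted by the net length change;
a deletion can never remove a junction because such footprints were already
excluded. The open reading frame is then relocated from scratch in the
mutant sequence: the most upstream start codon (default start set `{ATG}`)
defines the putative start, and translation walks in-frame triplets to the
first stop codon (TGA/TAA/TAG). A termination codon is *premature* exactly
when its third base is not the final base of the mutant sequence; this
definition makes silent and normal-stop variants fall out as `non_ptc`
without special-casing.

Three rules decide the verdict for a mutation with a PTC:

1. the gene has at least two (CDS) exons;
2. the PTC lies **more than 50 nt** upstream of the last exon–exon
   junction (`junction_min_bp`);
3. the PTC lies **more than 200 nt** downstream of the start codon
   (`start_min_bp`).

All three satisfied ⇒ `elicit`; PTC present but any rule failed ⇒
`escape`; no PTC ⇒ `non_ptc` (including the no-start and nonstop corner
cases, which are flagged). The 50-nt rule is the classical
exon-junction-complex boundary; very PTC-proximal starts allow
re-initiation, hence the 200-nt start rule.

### Distance conventions

The literature leaves the anchor bases unstated, so they are fixed here and
tested exactly: `d_start` runs from the first base of the start codon to
the first base of the PTC; `d_junction` runs from the base *after* the
PTC's third base to the last junction, both measured in mutant coordinates.
Both rules are strict inequalities, and the test suite pins the boundary:
`d_junction = 50` escapes while `51` elicits.

One arithmetic consequence is worth stating: because the stop is in frame
with the relocated start, `d_start` is always a multiple of 3. Distances of
exactly 175 or 200 nt therefore cannot occur; the start-distance rule is
exercised at the nearest realizable codon boundaries — 174 and 198 nt
(escape) versus 201 nt (elicit). The 174-nt fixture mirrors the documented
failure mode of escape calls whose PTC sits ~175 nt from the start.

### Tunable parameters

| parameter          | default | meaning                                            |
|--------------------|---------|----------------------------------------------------|
| `junction_min_bp`  | 50 nt   | strict minimum PTC→last-junction distance (rule 2) |
| `start_min_bp`     | 200 nt  | strict minimum start→PTC distance (rule 3)         |
| `start_codons`     | `ATG`   | codons accepted when relocating the ORF            |

`start_codons = c("ATG", "ATA")` widens the scan to the non-canonical ATA
initiator. ATA is not a recognized eukaryotic initiator and most likely
entered the literature as a typographical artefact, so it is off by
default; both behaviours are available and tested. Some authors use 50–54
nt for the junction rule; `junction_min_bp = 54` reproduces that reading.

Multiple mutations of one gene in one sample are classified independently
against the wild-type CDS. Joint application of co-occurring mutations
would require phasing information that MAF does not carry; independent
classification is the conservative default and keeps every mutation's
verdict attributable.

## Expression statistics

**REV (relative expression of variant).** For a mutant sample, the
gene-and-cancer-specific background is the expression of the gene in
same-cancer samples (same expression cluster when labels exist) with no
somatic mutation of any class in the gene and, when copy-number calls are
supplied, a thresholded CNV of 0. The REV is the midrank `R` of the mutant
value within background ∪ {mutant}, normalized as `R/(n+1)` with `n` the
background size. REV lies in (0, 1], is uniform on `{k/(n+1)}` under
exchangeability, and low REV means depressed expression. Backgrounds
smaller than `min_n = 8` samples are declared undefined rather than
scored — a rank among a handful of values is noise. Group contrasts report
both medians and their ratio plus one-sided Mann–Whitney–Wilcoxon and Welch
t tests (`wilcox.test` is exact for small untied samples and
normal-approximated with tie correction otherwise).

**Gene-level z-score.** For a gene and cancer with `N2 ≥ 3` NMD-elicit
mutant samples and `N1` mutation/CNV-free wild-type samples, all `N1 + N2`
expression values are midranked and the mutant-group Mann–Whitney statistic
`U` is normalized: `z = U_mut / (N1·N2) ∈ [0, 1]` — the tie-corrected
probability that a mutant sample out-expresses a wild-type one. `U_mut` is
the mutant-group U, not `min(U1, U2)`: low z must mean *reduced* mutant
expression, which a folded statistic could not express. Genes are tiered
`sensitive` (z ≤ 0.3), `intermediate` (0.3 < z ≤ 0.4), `insensitive`
(z > 0.4); both cut points are tested exactly.

## Cohort procedures

Hypermutated samples carry **more than 1,000** filtered mutations,
non-hypermutated ones **fewer than 100**; the interval between is excluded
from contrasts. Per-gene enrichment of NMD-elicit mutations in the
hypermutated stratum is measured on the 2×2 table (elicit/silent-class ×
hyper/non-hyper) with a two-sided Fisher exact test and BH adjustment
across genes. The "silent-class" counter (`Silent`, `3'UTR`, `5'UTR`,
`Intron`, `RNA`) is taken from the unfiltered MAF — those classes never
reach the classifier but are exactly the neutral yardstick the enrichment
needs. The enrichment effect size is a double quotient with ½ pseudo-counts,

$$\frac{(a+\tfrac12)/(A_h+\tfrac12)}{(b+\tfrac12)/(S_h+\tfrac12)} \Big/
  \frac{(c+\tfrac12)/(A_n+\tfrac12)}{(d+\tfrac12)/(S_n+\tfrac12)},$$

where capital letters are cohort-wide totals of each mutation type per
stratum; normalizing by the totals masks both the global mutation-load
difference and negative selection on truncating mutations. The raw counts
a–d are always emitted so any alternative normalization can be recomputed.
Counting uses *mutations* by default (matching a ratio of mutation counts);
a per-sample mode is available. Gene-set over-representation is a one-sided
hypergeometric tail over GMT sets; tumour-suppressor burden is the fraction
of samples per cancer with ≥ 1 elicit call in a TSG; deletion
co-occurrence tests elicit-presence × deletion-presence per gene (deletion
= thresholded CNV ≤ −1 by default, configurable to deep deletions only)
and compares REV of elicit mutants with versus without a co-deletion.

## The synthetic-data generators

The generators produce every input the toolkit consumes, with ground truth
attached, and are the basis of the test suite.

`simulate_genome()` writes one contig per gene (`chrS1`, ...): clean ORFs
(ATG start, single terminal stop, no internal in-frame stop) split into
2–6 exons of 120–400 nt with 80–200 nt introns, strands alternating so
both orientations are always exercised. Seven deterministic boundary genes
(`BND_*`) realize the rule edge cases listed above, including a
single-exon gene and a terminal-stop gene for the silent/nonstop corner
cases. `simulate_mutations()` draws a catalogue from a configurable mix of
nonsense SNVs, frameshift indels, in-frame deletions, missense, silent and
start-loss mutations, placing each inside a single exon with correct
forward-strand MAF alleles; every random mutation's expected class comes
from the independent brute-force oracle (`oracle_classify()`, a separate
naive implementation: character-vector edit, explicit start scan, explicit
triplet walk), never from the classifier under test. Records designed to
trip each mutation filter (wrong reference, splice-spanning deletion,
intronic position, excluded class, exact duplicate) are planted with their
expected verdicts. `simulate_expression()` draws gene means from N(8, 1)
(log-scale, RSEM-like) with N(0, 1) within-gene noise and shifts
elicit-mutant samples down by `nmd_effect_size` noise-SD units (default 2,
a strong but realistic knock-down for a degraded transcript);
`nmd_effect_size = 0` gives the calibration null.

`simulate_cohort_calls()` generates the hypermutation study at the call
level: 50 hypermutated samples at 1,500–2,500 mutations and 800
non-hypermutated samples at 50–95, with five planted genes whose elicit
probability is multiplied five-fold in the hypermutated stratum against
200 null genes. The cohort is deliberately non-hyper-dominated, as real
cohorts are; the non-hyper stratum carries the per-gene counts that give
the Fisher test its power. At per-sample counts above 1,000, simulating
individual base changes would add nothing to a counting statistic, so this
generator works at the call level by design.

A single seed drives everything: the genome stage seeds the RNG at `seed`,
mutations at `seed + 1`, expression at `seed + 2`, so each stage is
independently reproducible and outputs are byte-identical across runs.

**What the generators do not emulate:** mutational signatures and
context-dependent mutation rates; alternative splicing and UTR-containing
exon structure; correlated expression between genes; RSEM quantification
noise shapes; microsatellite-instability biology beyond a boolean label.
Passing tests therefore demonstrate the correctness of the algorithm and
statistics under the stated model, not calling performance on real tumour
data, where annotation quality and isoform usage dominate.

## Numerical choices and degenerate inputs

Midranks are used for every rank computation, making REV and z invariant
to tie order. The canonical-isoform and start-codon scans break ties
deterministically (smallest transcript id; most upstream codon).
Coordinates are normalized once at the boundary — GTF 1-based inclusive and
BED12 0-based half-open both become 0-based half-open internally — so all
arithmetic lives in a single convention. Degenerate situations are
reported, not guessed at: undefined backgrounds carry a reason, a zero
reference median makes the median ratio `NA`, constant groups flag the
comparison `degenerate`, genes with fewer than three mutants are discarded
with a reason, and an empty deletion stratum flags the REV contrast
degenerate.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the checks sharp yet quick: ~1,100 random
mutations over 40 genes for oracle equivalence; 1,500 mutants over 60
genes (REV) and 200 genes × 55 samples (z) for null calibration and
effect recovery; three seeded cohorts of 850 samples for enrichment
recovery; and all 23,256 distinct 2×2 tables with margins ≤ 30 (up to
symmetry) for the Fisher cross-check.

## Known limitations

The classifier sees one canonical isoform per gene; a PTC's NMD fate can
differ between isoforms. 3′UTR architecture, which modulates NMD in vivo,
is out of scope, as are NMD-factor mutation status and microenvironmental
NMD suppression. Gene matching is by symbol equality; identifier mapping
beyond a uniqueness check is the caller's responsibility. MAF is the only
mutation dialect read — VCF callsets should be converted upstream.
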