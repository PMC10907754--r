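---
title: "Digital UMI sequencing: model, pipeline and design notes"
author: "umiseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital UMI sequencing: model, pipeline and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model behind the simulator, the
consensus pipeline's algorithmic choices, and the reasoning behind every
default that is not dictated by the modelled chemistry. It is the place
where open design decisions are recorded; the README shows the user-facing
workflow.

## The generative model

The simulator reproduces the stages of a UMI-barcoded amplicon library,
stage by stage, with ground truth carried alongside:

1. **Template molecules** (`makeMolecules`). Each assay receives a fixed
   number of template molecules; each spike-in variant of fraction $f$ is
   carried by a $\mathrm{Binomial}(n, f)$ subset of molecules (disjoint
   across variants at one position). Templates are single-stranded RNA
   (cDNA workflow) or double-stranded genomic DNA. The model is
   substitution-only at the molecule level: amplicons are short fixed
   targets, and molecule-level indels are not part of the modelled
   chemistry (sequencing-level single-base indels are available via
   `indelRate` to exercise the deletion/insertion columns).
2. **Reverse transcription** (`reverseTranscribe`). Each RNA molecule
   converts with probability `rtEfficiency`; each base substitutes with
   probability `rtErrorRate` to a uniformly chosen other base. These
   errors precede UMI tagging and are flagged as UMI-uncorrectable in the
   truth. Published reverse-transcriptase fidelities lie around
   $9\times10^{-5}$–$1\times10^{-4}$ per base; the default is $10^{-4}$.
3. **Barcoding PCR** (`barcodePcr`). In each of `barcodeCycles` (default
   3) cycles, each *original* template strand is copied with probability
   `barcodeEfficiency`; each copy is primed by a UMI-bearing primer and
   founds a lineage with a fresh UMI drawn uniformly from
   $4^{\mathrm{umiLength}}$. Copies of already-tagged strands regenerate
   the existing UMI (the primer anneals to the universal handle), so they
   found no new lineage; they are accounted for by the lineage founding
   cycle/depth. At efficiency 1 this yields exactly 3 lineages per
   single-stranded origin and 6 per double-stranded origin — the
   identity on which strand-aware molecule counting rests. UMI collisions
   between origins are allowed and counted in the truth. Founder-synthesis
   polymerase errors are injected at `polErrorRate`; later within-lineage
   copy errors are folded into the adapter-PCR jackpot term below.
4. **Dilution** (`diluteProducts`). Each lineage independently survives
   with probability `dilutionFraction` (default 1/3), giving the expected
   1 (ss) / 2 (ds) sequenced lineages per original molecule.
5. **Adapter PCR and sequencing** (`adapterPcrSequence`). The first
   `jackpotCycles` (default 3) adapter cycles are treated as an explicit
   doubling tree: an error arising among the $2^{c-1}$ syntheses of cycle
   $c$ is inherited by each read of the lineage with probability
   $2^{-c}$. This captures the shared early errors that can survive
   consensus, while the remaining `adapterCycles − jackpotCycles` cycles
   contribute independent per-read errors
   ($\mathrm{Binomial}((\mathrm{cycles}-j)\,L,\,e)$). A full 30-cycle
   tree would be exponential; truncating it keeps the consensus-breaking
   component while the independent remainder is removed by the plurality
   vote anyway. One known approximation: the per-read expected jackpot
   burden under this scheme is $je/2$ rather than $je$ (the root strand
   itself acquires no new tag), which at the defaults ($e = 3\times10^{-7}$)
   is orders of magnitude below every measured quantity. Reads per lineage
   are $\mathrm{Poisson}$(`meanReadsPerFamily`); each read is
   `UMI | anchor | insert` with sequencing substitutions at
   `seqErrorRate` per base over the whole read and a constant Phred
   quality (`phred`, default 30) — the pipeline's consensus procedure is
   count-based and never conditions on quality.

### Parameters, units, defaults

| parameter | unit | default | rationale |
|---|---|---|---|
| `umiLength` | nt | 12 | UMIs in this chemistry are random 6–16 nt; mid-range |
| `anchorSeq` | — | `CGATGTACGCTA` | design-specific in real assays; placeholder, configurable |
| `minReadsPerUmi` | reads | 3 | the consensus cutoff of the modelled protocol |
| `rtErrorRate` | subs/base | 1e-4 | published RT fidelity range 9e-5–1e-4 |
| `rtEfficiency` | fraction | 1 | molecule counts are anchored to converted cDNA |
| `barcodeCycles` | cycles | 3 | protocol value |
| `barcodeEfficiency` | prob/strand/cycle | 1 | the 3/6 identity holds exactly at 1; real value unknown |
| `polErrorRate` | subs/base/synthesis | 3e-7 | high-fidelity enzyme, >300× better than Taq (1e-4–5e-5) |
| `dilutionFraction` | fraction | 1/3 | protocol value |
| `adapterCycles` | cycles | 30 | protocol value |
| `jackpotCycles` | cycles | 3 | early cycles dominate shared errors |
| `meanReadsPerFamily` | reads | 6 | gives ~94% of families ≥ 3 reads |
| `seqErrorRate` | subs/base/read | 2e-3 | free parameter: no instrument value is modelled; typical short-read figure |
| `indelRate` | events/base/read | 0 | optional, sequencing-level single-base indels |

### Randomness

All stages draw from one seeded R stream in a fixed stage order, so a
fixed `(seed, config)` reproduces output byte-for-byte. Per-origin
substreams (so that changing one assay's molecule count would leave other
draws untouched) were considered and rejected: they preclude the
vectorised draws that make desk-scale runs (600k reads in seconds)
possible in R, and no consumer of the package needs cross-config draw
stability — only within-config determinism, which tests assert.

## The consensus pipeline

* **UMI extraction**: first `umiLength` bases; the fixed anchor is
  verified with ≤ 1 mismatch; failures are rejected with a reason code
  and counted (`reads in = rejected + unassigned + Σ family sizes` is a
  tested invariant).
* **Assay assignment**: best amplicon at ≥ 0.8 identity, ties broken by
  panel order. Inserts whose length equals an amplicon's are scored by
  Hamming identity — exact for the substitution-only read model — and
  all remaining inserts fall back to semiglobal alignment against every
  amplicon. The 0.8 cutoff is configurable; alignment is against the
  panel's amplicons, not a genome, because a targeted panel makes genome
  alignment unnecessary at desk scale.
* **Alignment encoding**: semiglobal (insert global, reference local),
  affine gaps (match 1, mismatch −2, gap open 5, extend 2); deletions map
  to the spanned reference offsets, insertions anchor to the
  left-flanking offset. Tests verify the encoding is lossless and
  score-optimal against an independent dynamic-programming oracle.
* **UMI clustering**: directional merging — family B merges into A when
  their UMIs differ at one position and `count(A) ≥ 2·count(B) − 1`,
  parents preferred by descending count then lexicographically, chains
  resolved to roots. Because UMIs here are fixed-length slices, the
  neighbourhood is substitution-only (an indel in the UMI shifts the
  anchor and is rejected there instead). `maxDist = 0` disables
  clustering for exact-match mode.
* **Consensus**: plurality per reference position among covering members;
  ties go to the reference; a winning fraction below 0.6 marks the
  position ambiguous, and ambiguous positions are excluded from that
  family's pileup contribution rather than dropping the family — this
  preserves the per-position coverage semantics of the error-rate
  formula. The 0.6 threshold (strict majority with margin) is a package
  choice; the modelled protocol states only the ≥ 3-reads cutoff. The
  caller is tested for equality with a brute-force majority oracle on
  random small families.
* **Error rates**: `e_p = non-reference/coverage`; insertions count as
  non-reference events at their anchor position while coverage stays the
  denominator (the per-position formula does not define indel accounting;
  this choice represents the insertion class without distorting the
  denominator). Panel means are unweighted over all included positions of
  all assays. Raw-read error rates are computed from all assigned raw
  reads (not only reads in surviving families); that scope is the
  package's choice and is configurable by filtering inputs.

### Degenerate inputs and tie-breaking

Zero-coverage and excluded positions are omitted from means (an
all-excluded assay yields a flagged `NA`, never a crash); the correction
factor is `NA` exactly when no consensus errors remain; the replicate
t-test flags identical zero-variance arms and returns p = 1; Spearman
correlation of a constant profile is flagged undefined; every tie-break
in assignment, clustering and consensus is deterministic (panel order,
count-then-lexicographic, reference-first), so reruns are bit-identical.

## What the simulator does and does not emulate

Emulated: strandedness-dependent UMI multiplicity, binomial dilution,
Poisson family depth, RT/polymerase/sequencing substitution errors with
their different correctabilities, jackpot error sharing, UMI collisions
and UMI sequencing errors (exercising directional clustering), optional
sequencing indels, spike-in mixtures down to 0.078%.

Not emulated: position- or motif-dependent error spectra, quality-score
profiles, GC/length amplification bias, chimeras, polymerase slippage,
paired-end reads. Two consequences matter for interpreting green tests.
First, passing recovery tests show correctness of the counting and
correction machinery under the stated error model, not robustness to the
structured error landscape of a real instrument. Second, with uniform
per-base error rates a raw-pileup variant signal can be statistically
separable from background even below the raw error floor (replicate
noise is purely binomial here), so the "detectable only with UMIs" claim
is operationalised as the calling-threshold argument: the true fraction
must lie below the raw error floor and above the consensus floor — which
is what the acceptance suite asserts.

## Problem sizes

The test and acceptance runs use the study-scale conditions where the
claims are stated: 100,000 molecules per replicate (3 replicates plus 3
zero-spike controls) for the 0.078% endpoint, 10,000 per replicate for
the 25% endpoint, and a 5-assay, 100-nt, 20,000-molecule panel for the
error-floor bound; unit and property tests use 100–3,000 molecules. The
molecule-recovery property is tested at 3,000 origins and depth 20
because at depth 6 the ≥ 3-reads cutoff removes the ~6% Poisson tail of
families, and at 10^5 lineages random Hamming-1 adjacency between true
UMIs makes directional clustering merge a percent-level fraction of
families — both effects are properties of the regime, not defects, and
neither biases MAF estimates (merging removes variant and wild-type
children proportionally).

## Known limitations

Alignment of length-changed reads falls back to per-read pairwise
alignment and is the slow path (irrelevant at `indelRate = 0`); the
directional cluster rule uses original counts on direct edges only;
insertion consensus requires the same 0.6 support as substitutions but
insertions of different sequences at one anchor are voted separately;
plasma normalisation exposes explicit extract/RT fraction parameters
(defaults 1) because no formula for the per-mL conversion is part of the
modelled protocol.
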