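---
title: "tollscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tollscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tollscan)
```

## The problem

Toll-like receptors (TLRs) are the canonical animal innate-immunity
receptors: an extracellular array of leucine-rich repeats (LRRs), a single
transmembrane (TM) helix, and an intracellular TIR signalling domain.
Comparative work on under-sampled invertebrate lineages asks four linked
questions that this package turns into reproducible computation:

1. Which proteins in a proteome are TLRs, and which are TLR-like
   (TIR-only / LRR-only) relatives?
2. Are the TLRs V-type/scc (one membrane-proximal cysteine cap) or
   P-type/mcc (several caps, often an N-terminal cap)?
3. How do TLR gene-tree clades (here called alpha, beta, gamma) map onto
   the metazoan species tree, and what gain/loss history explains their
   distribution?
4. Are TLRs expressed during development, and in which stage windows?

Every stage runs on synthetic data with known ground truth, so the whole
pipeline is testable offline; real data enter through the same FASTA /
newick / TSV interfaces.

## Domain scanning

**LRR repeats.** Each repeat unit is 22--26 residues whose conserved
segment follows `LxxLxLxxNxL`. We score an 11-position log-odds model: the
four `L` anchors favour Leu strongly (Ile/Val/Phe/Met weakly), and the `N`
position accepts Asn/Thr/Ser/Cys but penalizes everything else hard
(log-odds -4). The hard Asn-position penalty is what stops TM helices --
which are leucine-rich but never carry the asparagine ladder -- from
satisfying the motif. Windows scoring at least 6 (perfect match scores
about 11) are anchors; anchors are thinned greedily by descending score at
a minimum spacing of `min_unit`, and each surviving anchor is extended to
the next anchor (when 22--26 away) or to a 24-residue default unit.
Repeats separated by at most 10 residues form one array.

**Cysteine caps.** For each maximal array the 60-residue flanks are
searched for a four-cysteine cluster `C-x(2..20)-C-x(2..30)-C-x(2..30)-C`.
A cluster after an array is an LRRCT; a cluster before the first array is
the LRRNT; a cluster between two arrays belongs to the upstream array
(LRRCT), never to the downstream one, so cap-delimited mcc layouts resolve
unambiguously.

**Transmembrane segment.** Mean Kyte--Doolittle hydropathy in a 19-residue
window, threshold 1.6. Consecutive passing windows form a run; within a
run the best window is extended over residues with hydropathy above the
threshold up to 25 residues, keeping hits inside the 17--25 span of real
single-pass helices.

**TIR domain.** The paper-scale analyses used unpublished profile HMMs; we
substitute a position-specific scoring matrix built from a packaged seed
alignment. No curated TIR alignment can be shipped from an offline build,
so the seed is an explicitly *synthetic* stand-in
(`inst/extdata/tir_seed_synthetic.fasta`): a fixed 140-residue consensus
with eight members at 15% substitution distance. The detection threshold
(120) was calibrated once against random background proteins (maximum
background window score about -180; profile-sampled segments score above
220) and is not a tuning knob. Consequences: the scanner demonstrates the
*mechanics* of profile search with a clean margin, and the synthetic
generators sample their TIR segments from the same profile; it will not
recognize real TIR domains unless a real seed alignment is swapped in,
which is the intended external-interface hook.

**Architecture.** Overlaps resolve by priority TIR > TM > caps > LRR; if
LRRs and a TIR are both present, the TM candidate kept is the
best-scoring one located between them. A record is a *fragment*
(`complete = FALSE`) when any retained hit comes within 5 residues of a
sequence end.

## Receptor survey and typing

The calling rule is exactly the published criterion: TLR iff TIR and TM
and at least one LRR; TIR-only, LRR-only and TIR+LRR-without-TM records
are TLR-like, never TLRs. The TIR+LRR-without-TM class is kept separate
because figure-level and methods-level definitions of non-TLRs differ on
whether the TM is definitional; it is reported but never counted as TLR.

Same-species sequences with identity strictly above 0.90 are treated as
polymorphisms/isoforms. The published rule names no metric, so we define
identity as identical aligned pairs over the shorter sequence length under
global alignment (match 2, mismatch -1, gap opening 10, extension 0.5);
components are single-linkage; the representative is the longest sequence
(ties: lexicographically smallest id), which favours complete transcripts
and is deterministic.

Typing follows the cap layout: mcc with two or more LRRCTs; scc with
exactly one LRRCT ending within 60 residues of the TM start (a typical
juxtamembrane spacer, configurable); otherwise NC. Fragments and
receptors with no detectable cap are NC -- a detection failure must not
masquerade as a structural type. The LRRNT is recorded but never decisive.

## Alignment utilities and trees

The published workflow trimmed the alignment manually to one LRR + TM +
TIR and then ran TrimAl's gappyout. The manual step is replaced by a
deterministic surrogate: per row, find the column of the membrane-proximal
LRR start and of the last TIR residue, and keep the block between the
medians of those columns. Divergence from the published 375-column
alignment is expected and documented -- the surrogate is reproducible, the
manual trim is not. Our gappyout places the cutoff at the largest jump in
the sorted per-column gap-fraction curve and removes columns above it;
masking removes an explicit 1-based inclusive column range (e.g. the
349--354 insertion window); a row carries the insertion when at least 5 of
the 6 window columns are non-gap (one alignment wobble tolerated).

Maximum-likelihood inference stays external by design. The documented
commands for a paper-scale analysis are:

```
mafft --localpair --maxiterate 1000 in.fasta > aln.fasta
iqtree2 -s trimmed.fasta -m LG+R8 -B 1000
```

The in-package tree path -- neighbor joining on p-distances (pairwise
deletion) -- exists so that rooting, clade assignment and the scenario
machinery are fully testable at desk scale; NJ on additive matrices is
exact, which the tests exploit.

Rooting uses the TIR-containing adaptor MyD88 as outgroup; the outgroup
must be a clade of the unrooted tree or the offending tips are reported.
Clade assignment is anchored: for each label the largest clade containing
all of that label's anchors, none of any other label's, with stem support
strictly above 60 (the published dot-marking convention) labels its tips;
anchor tips always keep their own label; everything else is unassigned.
Trees without support labels treat missing values as 100 so that
hand-built test trees are fully supported by default.

## Gain/loss scenarios

Characters are the three clades as presence/absence per metazoan group on
a fixed 22-taxon species tree with named internal nodes (Planulozoa,
Nephrozoa, Spiralia, Trochozoa, ...); alternative topologies load from
newick. Reconstruction is Dollo -- a single gain at the MRCA of the
presence taxa (or at a constrained node) plus the unique minimal set of
loss edges -- because the biological argument is phrased in
gained-once/lost-many terms. Absence in a transcriptome-surveyed taxon is
weighted like genomic absence; under-detection is a caveat the caller can
carry per taxon, not a model term.

The scenario families are scored mechanically: 1A (one planulozoan TLR,
alpha/beta-gamma duplication at Nephrozoa) versus 1B (two planulozoan
TLRs, beta/gamma lost in cnidarians), crossed with 2A/2B/2C (the
beta/gamma duplication at Nephrozoa, Spiralia or Trochozoa). Each
combination's events = origins + duplications + implied Dollo losses; each
hypothesis is additionally checked against the assigned gene tree: 1B
requires cnidarian TLRs nested within clade alpha, 2B/2C require gamma
nested within beta's span. Ordering puts gene-tree-consistent hypotheses
first, then ascending event count -- the package's formalization of a
verbal argument; the published study never quantified hypothesis
preference.

## Expression calls

The pipeline follows the published order: within-sample TPM first, then
cross-stage TMM. Because the TMM input is already within-sample
normalized, M-values compare TPM values directly; the reference stage is
the one whose upper-quartile is closest to the mean upper quartile, genes
zero in either sample are dropped, log-ratios are trimmed 30% per tail and
abundances 5% per tail (the standard trims; the paper does not state its
parameterization), factors are precision-weighted trimmed means rescaled
to geometric mean 1. Applying TMM to TPM differs from the common
count-based usage and is deliberate. On TPM-like input with equal column
sums the scheme coincides with edgeR's, which the test suite uses as an
independent oracle.

Expression at a stage means normalized value >= 0.15 (inclusive, per the
published wording). Temporal classes: `throughout` (all stages),
`not_detected` (none), `windowed` (some); contiguity of the window is
reported, not required, because the published usage is informal. Where two
biological replicates exist their normalized values are averaged.

## The synthetic world

The generators state a world and the tests measure recovery in it:

* **Proteomes** mix planted scc/mcc TLRs (canonical LRR units with
  per-position noise 0.05 by default, cap templates with canonical
  cysteine spacing, a 23-residue hydrophobic TM, profile-sampled TIR),
  TIR-only and LRR-only decoys, isoform pairs mutated to a target
  identity (default 0.95), and background proteins. Backgrounds are
  uniform-composition and are resampled if they contain LRR- or TM-like
  signal, because their stated truth is "no domains"; they are *not*
  screened against the TIR profile, so the <= 1% TIR false-positive
  criterion measures the scanner, not the generator.
* **Clade evolution** draws one gain per character and independent edge
  losses (no regain) at a stated rate; leaf states and realized events are
  the truth.
* **Alignments** plant carrier/non-carrier rows around an insertion
  window over a shared noisy consensus.
* **Expression** plants throughout/windowed/silent genes over a background
  pool with up to 3-fold library-size variation and negative-binomial
  counts (dispersion 0.1). The generator *enforces* its own statement:
  realized TPM of expressed gene-stages clears threshold x margin, silent
  gene-stages stay below threshold / margin, with draws minimally bumped
  when they cross. This is deliberate: with dispersion 0.1 an
  unconstrained negative binomial leaves about 3% of its mass below half
  its mean even at high counts, so "100% temporal-class recovery at 2x
  margin" is a property of margin-cleared data, not of free draws. The
  enforcement implements the stated world literally.

What a green test does establish: the detectors recover exactly what they
are specified to detect, with calibrated false-positive margins, and every
downstream computation (collapse, Dollo, TMM, calls) matches independent
oracles. What it does not establish: performance on real proteomes (real
TIR homology, degenerate repeats, compositional bias), real alignments
(alignment error, fragmentary transcripts), or real expression libraries
(composition bias beyond library size, replicate structure) -- those enter
through the external-data interfaces and were out of desk scale here.

## Numerical choices and limitations

* Coordinates are 1-based inclusive everywhere, matching the field's
  "positions 349--354" convention.
* LRR unit bounds are 22--26 at detection, relaxed to 20--30 at the
  DomainHit invariant to tolerate imperfect repeats.
* Identity threshold comparisons are strict (> 0.90); expression threshold
  comparisons are inclusive (>= 0.15); support comparisons are strict
  (> 60). All three follow the published wording.
* Ties in the gappyout break rule resolve to the first (lowest) cutoff;
  ties for collapse representatives resolve lexicographically; the NJ
  builder inherits ape's deterministic tie handling.
* The brute-force oracles in the test suite are exponential and
  intentionally restricted to <= 12 leaves / length <= 6 alignments.
* `score_gain_placement` counts every newly covered absent stem lineage
  when a gain moves rootward; on the fixture topology (which includes
  Xenacoelomorpha) moving the beta/gamma gain from Nephrozoa to
  Planulozoa therefore adds two losses, not one.
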