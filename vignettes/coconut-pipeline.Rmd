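---
title: "Detecting and classifying McrBC/CoCoNuT systems: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying McrBC/CoCoNuT systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coconutscan)
```

This vignette is the package's own account of the science it implements:
what is being modelled, which parameters matter and why they have the
defaults they do, what the synthetic data can and cannot show, and where
the design was genuinely open.

## The detection model

McrBC systems are two-component Type IV restriction systems. The unit of
detection is not a gene but a *genomic island*: a candidate anchor gene
plus up to ten genes on each side, judged by the domain evidence on the
proteins it encodes. Detection proceeds in tiers of decreasing evidence:

1. **Strict.** The island carries a hit to the McrB GTPase domain
   (COG1401), or hits to both an McrB alias (MoxR, AAA_5, COG4127,
   DUF4357, Smc, WEMBL, Myosin_tail_1, DUF3578, EVE, Mrr_N, pfam01878) and
   an McrC alias (McrBC, McrC, PF09823, DUF2357, COG1700, PDDEXK_7,
   RE_LlaJI). Several McrB aliases are not McrB-specific: they are domains
   commonly fused to McrB homologs, or broader AAA+ families, which is why
   a lone McrB alias is never sufficient.
2. **Relaxed.** Exactly one alias class is present. The island is rescued
   if a gene adjacent to the alias hit lies within 90 nt, is co-oriented,
   and encodes a protein large enough to be the undetected component:
   strictly more than 200 aa for a missing McrB, strictly more than 150 aa
   for a missing McrC. "Adjacent" means the nearest gene on either side,
   because operons occur in both orders.
3. **Rescue.** No aliases at all, but the anchor is a raw homology-search
   hit in *operonic association* — same strand, successive intergenic gaps
   within the 90 nt rule, chained transitively — with a sufficiently large
   partner.

Intergenic gaps are computed as `start(B) − end(A)` regardless of strand,
so overlapping reading frames (a hallmark of tight functional linkage in
these operons) give negative gaps and always satisfy the distance rule.
Validated McrB- and McrC-class genes are then paired greedily by proximity
(fewest intervening genes first, then genomic distance), each gene used at
most once; reversed operon order is recorded, rare B+C fusion genes are
emitted as single-gene fused systems, and unmatched components become
orphans.

## Sequence-level annotation

Profile-detectable domains (DUF2357, Hsp70, YTH, CSD, VWA, and the rest)
enter the pipeline through a *profile-search adapter* — any deterministic
`function(protein_id, sequence)` returning domain hits; the package itself
never pretends to be a profile search. What the package does implement are
the motif-level scanners, each a pure function:

* **GTPase signature.** Walker A (`G-x4-G-K-[S/T]`) and Walker B (four
  hydrophobics from {I, L, V, M, F, A} followed by `DE`) are located
  inside the GTPase region, then the first `N-x{1..3}-D` downstream of
  Walker B within a 60-aa window is reported; the spacer length names the
  variant (NxD / NxxD / NxxxD) and the residue after the D is recorded,
  since in the NxD clade it is usually, but not invariably, E or a second
  D. The 60-aa default covers the canonical motif spacing with margin; it
  is deliberately too short to reach across the Type I-A helical insert
  (see below).
* **HEPN.** All non-overlapping `R-x4-H` matches are reported; the
  shortened `R-x-H` is reported only inside HEPN-annotated regions,
  because three residues alone carry almost no information.
* **MIDAS.** The VWA-domain motif `DxSxS…T…D` is classified as intact,
  degraded (missing the middle threonine), or absent. The spacing windows
  — T within 20–80 aa of the motif, D within 10–60 aa of the T — are
  invented defaults exposed in the configuration; only the residue pattern
  itself is constrained by the biology.
* **CPxC.** Non-overlapping counts, left to right; Type I-A McrC homologs
  carry three, the reduced Type II form two.

### The coiled-coil heuristic

Coiled-coil prediction normally involves several external tools whose
outputs vary in strength. The pipeline needs one deterministic,
dependency-free signal with an adapter seam, so it uses a single
heptad-propensity sliding window: for each 28-residue window (four
heptads) the score is the best over the seven register frames of the
geometric mean of per-position propensities, with hydrophobics favoured at
positions a/d and charged/polar residues elsewhere. The table is embedded
as constants; its contrasts are sharpened (propensities raised to the
third power) so that the score separates register, not merely composition:
an ideal heptad repeat scores about 0.73, while shuffles of the same
residues and uniform random sequence stay below about 0.36. The calling
threshold of 0.5 therefore sits in a wide margin on both sides. The
maximisation over frames makes the score exactly invariant under circular
permutation of the register. Any external predictor can replace the
heuristic by supplying `coiled_coil` hits through the adapter.

## Clustering and representatives

Candidate homolog sets are organised by an iterative cluster–align–merge
procedure: greedy incremental clustering at fractional identity 0.5
(sequences processed longest-first for determinism; identity is
matches / alignment columns under global alignment with BLOSUM62, gap open
11, extend 1); center-star alignment of each cluster around its centroid;
per-column frequency profiles with a 0.01 pseudocount; and a merge round
in which every cluster pair with a cross-score to self-score ratio
strictly greater than 0.1 is merged by single-linkage connected
components. The cycle runs for three iterations by default, stopping early
once a round merges nothing. Merging can be genuinely progressive: a
merged profile has a lower self-score than its sharpest member, so a pair
that fails the ratio in round one can pass it in round two — this is
exercised directly in the test suite. Representatives are the centroids of
greedy clusters at identity 0.9 and feed an unrooted neighbor-joining
tree (exact on additive distance matrices, with `1 − identity` distances);
maximum-likelihood tree building is deliberately out of scope and sits
behind the same seam.

Three scoring choices were genuinely open and are config-exposed:

* *similarity* for the 0.5/0.9 thresholds is global-alignment fractional
  identity — the most reproducible stand-in for an external clustering
  tool's unstated similarity mode;
* profile–profile scoring is an ungapped sliding dot-product, not an
  HMM–HMM alignment; only the merge criterion (ratio > 0.1, strict) is
  part of the procedure being reproduced, and it is preserved exactly;
* the ratio denominator is the *maximum* of the two self-scores
  (conservative: prevents a long profile from absorbing every short one);
  `min` is available as a configuration value.

## The classification grammar

Classification is rule-based on domain architecture plus the signature
motif; the phylogenetic dimension of the original typing is represented by
the NxD gate plus the Type I-A helical-insert rule, with tree-based
placement left to an adapter. The rules apply in order, first match wins:

0. signature ≠ NxD → non-CoCoNuT McrBC;
1. CnuH helicase fused to a Vsr-like nuclease, no separate CnuE → III-B;
2. CnuE with two PLD domains → III-C;
3. CnuE with two HEPN domains and/or CnuC fused to an Hsp70-like unit →
   III-A;
4. CnuE with one HEPN and CnuH present → II;
5. no CnuH/CnuE and a helical insert in the CnuB GTPase → I-A;
6. separate CnuA with PYD and REC → I-B;
7. I-B-like CnuB with no CnuA anywhere in the ±10-gene island →
   Pseudo-I-B;
8. CnuB with CSD and fused coiled-coil → I-C;
9. otherwise unclassified, with diagnostics.

Roles follow the same evidence: the GTPase gene is CnuB, the
DUF2357-bearing gene CnuC (CnuCD when fused to Hsp70), the SF1 helicase
CnuH, the wHTH effector CnuE, stand-alone Hsp70 + coiled-coil proteins
CnuD, and the separate coiled-coil protein CnuA. A CnuA candidate must
carry *only* coiled-coil (plus PYD/REC in Type I-B); this exclusion rule
exists because extended Type III-A operons contain coiled-coil–nuclease
fusions that would otherwise masquerade as CnuA.

**Helical-insert detection.** Whether the Type I-A insert is detectable
from sequence alone was an open question; the pipeline uses inter-motif
spacing as a flagged heuristic. The scanner first looks for the signature
within the normal 60-aa window; if nothing is found, it re-scans with an
extended window (200 aa) and records a helical insert when the motif
appears at a spacing of at least 80 aa downstream of Walker B. The
two-stage design keeps the printed 60-aa contract for canonical GTPases
while making inserted variants reachable.

**I-C versus I-B without CnuA.** The printed discriminator is the YTH
position (between CSD and coiled-coil in I-C, between CSD and GTPase in
I-B). The grammar uses the presence of a *fused* coiled-coil on CnuB: in
I-B and Pseudo-I-B the coiled-coil is encoded separately, so a CnuB with
CSD but no fused coiled-coil and no CnuA in the island is Pseudo-I-B,
while a CnuB with both CSD and fused coiled-coil is I-C.

**Ancillary modules.** TerY-P is three consecutive co-oriented genes with
VWA, PP2C, and STK+ZnR evidence (either reading order); it is recorded
only for Types II and III-A, which are the types that carry it — never for
III-B/III-C. Extended Type III-A variants are recognised by the diagnostic
ATPase between duplicated VWA genes (EssC-like, requiring at least one
WXG100 protein; SpoVK-like, next to a glycine-zipper protein; VirB4-like,
also accepted at the 3′ end when the VWA genes are duplicated at the 5′
end), and the MIDAS states of the two VWA copies are recorded — the 5′
copy intact, the internal copy degraded. CARF/RtcR superoperons are found
by walking upstream in the transcription direction while genes stay
co-oriented and gaps stay within 200 nt (an invented, config-exposed
default standing in for "close spacing"); embedded systems (Type I RM,
Druantia III, BREX, Shield ShdA, BrnT-like) are recognised purely from
adapter hit names, with no built-in detectors of their own.

## The synthetic-data generator

The generator is first-class, tested code: it emulates annotated contigs
containing CoCoNuT operons of every subtype, non-CoCoNuT (NxxD) McrBC
operons, ancillary modules, and decoys, with a ground-truth table tying
every planted locus, role, tag, and motif coordinate to the emitted
annotation.

Two principles govern it. Motif-bearing domains carry *real literal
motifs* — Walker A `GESGSGKS`, Walker B `ILFIDE`, the NxD/NxxD/NxxxD
signatures, HEPN `R-x4-H` and `R-x-H`, MIDAS with or without its
threonine, CPxC repeats, `IEALEKK` heptads — embedded in seeded random
background, so the built-in scanners are exercised on sequence.
Profile-only domains are planted as placeholder tags consumed by the mock
adapter, mirroring the real division of labour between motif scanning and
profile search. Background composition is uniform over the 20-aa alphabet
(config-exposed); the scanners must not depend on composition, and the
sharpened coiled-coil table keeps random background far below the calling
threshold. Regions between planted motifs exclude the residues that could
create earlier spurious matches (no N/D between Walker B and the
signature, no R/H inside HEPN tokens), because the scanners report first
matches.

Operon geometry follows the detection rules being tested: within-operon
gaps are drawn in \[0, 90\] nt with a 0.15 probability of a negative gap
(overlapping reading frames); superoperon members are spaced 95–195 nt to
exercise the 200 nt rule distinctly from the 90 nt rule; loci are isolated
by twelve untagged filler genes (more than the 10-gene flank) so islands
never bleed into each other — including into the decoys, whose MoxR-like
singletons must fail the relaxed tier for the planted-truth precision of
1.0 to be meaningful. Decoys cycle through MoxR-like AAA+ singletons,
Type I RM operons, and random genes. Optional tier fixtures plant a
relaxed-only locus (a single EVE alias with an untagged 250-aa partner)
and a rescue-only locus (a raw search hit with a 300-aa operonic partner).
The mock adapter can inject reproducible false-positive hits drawn from an
innocuous vocabulary (never McrB/McrC aliases) for robustness experiments.

What passing these tests shows — and does not show. The planted
architectures are unambiguous by construction: recall, precision, and
subtype accuracy of 1.0 on synthetic genomes demonstrate that the rules
are implemented as stated, not that real genomes are this clean. Real data
bring fragmented assemblies, diverged motifs, profile-search noise, and
multi-copy islands whose cooperative structure the pairing step only
approximates; none of those are modelled here, and the adapter seams are
where that uncertainty enters.

## Numerical choices and problem sizes

* Alignment scores are integer-valued (BLOSUM62 with integer gap costs),
  so dynamic-programming tracebacks compare exactly in floating point;
  tie-breaks prefer aligned pairs over vertical over horizontal gaps,
  making the reported identity deterministic and testable against an
  independent brute-force implementation.
* Profile columns are normalised after a 0.01 pseudocount per cell; the
  merge ratio is compared with a strict inequality, and the boundary case
  (ratio exactly 0.1) is pinned by a test built from hand-constructed
  profiles whose ratio is exactly the double `0.1`.
* Greedy clustering orders sequences longest-first with lexicographic
  tie-break, so results are invariant to input order.
* Neighbor joining uses the standard algorithm for three or more leaves;
  the two-leaf tree is built directly with each branch at half the
  distance.
* Degenerate inputs: empty genomes yield empty censuses with an all-zero
  funnel; sequences shorter than the coiled-coil window yield no segments;
  missing Walker motifs yield `variant = "none"` with a diagnostic rather
  than an error; adapter failures on individual proteins are collected as
  diagnostics, not raised.
* Default problem sizes were chosen for a laptop-class single core: the
  standard synthetic genome holds 9 planted loci, 6 decoys and about 150
  filler genes across two contigs (about 190 proteins); clustering
  fixtures use 12–30 sequences of 100–300 aa. The full test suite,
  including three end-to-end seeds and 1000-sequence scanner oracles, runs
  in under a minute.

## Known limitations

* The pipeline reproduces the *procedure*, not database-scale results:
  PSI-BLAST against nr, HHpred validation, structural modelling, and the
  resulting census magnitudes and tree supports are outside its scope by
  design, reachable only through the adapter seams.
* The helical-insert rule and the I-C/Pseudo-I-B discriminator are
  sequence-level heuristics for distinctions that may ultimately require
  structure or phylogeny; both are flagged in the call evidence.
* The rescue tier assumes the raw search hit is the McrB-class component
  (the common case for GTPase-profile searches); anchor class is an
  argument, not an inference.
* How multi-copy islands resolve into cooperating versus independent
  systems is not defined by the detection rules; greedy pairing emits
  multiple systems per island without asserting cooperativity.
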