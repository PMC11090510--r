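# coconutscan

Detection and classification of McrBC-family Type IV restriction systems —
including the CoCoNuT (*co*iled-*co*il *nu*clease *t*andem) branch — from
annotated prokaryotic genomes.

## The problem

McrBC systems are two-component, modification-dependent (Type IV)
restriction systems: McrB is a GTPase of the AAA+ clade that translocates
DNA, and McrC carries a DUF2357 activator domain fused to a PD-(D/E)xK
nuclease. A large, previously underappreciated branch of this family — the
CoCoNuTs — is marked by a one-residue deletion in the GTPase signature
motif (NxxD → NxD), extensive coiled-coil structures, and tandem nucleases
(HEPN, Vsr-like, PLD), with three types and seven subtypes distinguished by
domain architecture and genomic context.

Finding these systems in genome annotations is a genomic-neighborhood
problem, not a single-gene problem: candidate islands are gathered around
homology-search hits, filtered by domain evidence in a ±10-gene window,
validated by pairing McrB with McrC homologs under distance / orientation /
size rules, and finally classified by the domain architecture of their
components. `coconutscan` implements that whole procedure as a tested R
pipeline, together with a synthetic-genome generator that plants every
subtype with literal sequence motifs and a ground-truth table, so each
stage can be validated end to end without any database download.

## The method at a glance

* **Neighborhood census.** For each anchor gene, a neighborhood of up to 10
  genes on each side is extracted and passed through a three-tier filter
  cascade: *strict* (a COG1401/McrB-GTPase hit, or hits to both an McrB
  alias and an McrC alias), *relaxed* (one alias class plus an adjacent
  gene within 90 nt, co-oriented, encoding > 200 aa for a missing McrB or
  > 150 aa for a missing McrC), and *rescue* (no aliases, but a raw search
  hit in transitive operonic association with a sufficiently large
  partner). Validated McrB/McrC genes are paired greedily by proximity,
  tolerating intervening genes and reversed operon order.
* **Motif annotation.** Pure-function scanners for the Nx(xx)D GTPase
  signature downstream of Walker A/B, HEPN RxxxxH / RxH catalytic motifs,
  the MIDAS motif state of VWA domains (DxSxS…T…D, with the degraded no-T
  form), CPxC zinc-binding repeats, and a heptad-propensity sliding-window
  coiled-coil heuristic. Profile-detectable domains enter through a
  pluggable adapter (`function(protein_id, sequence) -> hits`).
* **Profile clustering.** Greedy incremental clustering at identity 0.5,
  center-star alignment per cluster, per-column frequency profiles, and
  cluster merging whenever the profile–profile score to self-score ratio
  exceeds 0.1 (strict), iterated three times with early stopping;
  representatives at identity 0.9 feed a neighbor-joining tree.
* **Classification grammar.** An ordered rule list assigns each validated
  system one label: the NxD gate first, then III-B (Vsr fused to the CnuH
  helicase), III-C (CnuE with two PLD domains), III-A (CnuE with two HEPN
  domains and/or CnuC–Hsp70 fusion), II (CnuE with one HEPN), I-A (helical
  insert between Walker B and NxD), I-B (separate CnuA with PYD and REC),
  Pseudo-I-B (I-B architecture with CnuA lost from the island), I-C.
  Ancillary modules — the TerY-P triad, extended Type III-A inserts
  (EssC-like / SpoVK-like / VirB4-like between duplicated VWA genes), and
  CARF/RtcR superoperons with embedded defense systems — are detected for
  the types that carry them.

## Worked example

```r
library(coconutscan)

report <- run_all(default_config(seed = 7L), simulate = TRUE)
report
#> <coconut_report> 9 system(s)
#>   funnel: input=11 strict_pass=9 relaxed_pass=0 rescued_pass=0 rejected=2 paired=9 orphan=0
#>   labels: I-A=1 I-B=1 I-C=1 II=1 III-A=1 III-B=1 III-C=1 non_CoCoNuT_McrBC=1 Pseudo-I-B=1
#>   vs truth: recall 1.00, precision 1.00, subtype accuracy 1.00

report$calls[, c("locus_id", "label", "tier", "signature", "tery_p",
                 "extended_IIIA")]
#>    locus_id             label   tier signature tery_p extended_IIIA
#> 1 locus_001               I-A strict       NxD  FALSE          none
#> 2 locus_002        Pseudo-I-B strict       NxD  FALSE          none
#> 3 locus_003                II strict       NxD   TRUE          none
#> 4 locus_004             III-B strict       NxD  FALSE          none
#> 5 locus_005 non_CoCoNuT_McrBC strict      NxxD  FALSE          none
#> 6 locus_006               I-B strict       NxD  FALSE          none
#> 7 locus_007               I-C strict       NxD  FALSE          none
#> 8 locus_008             III-A strict       NxD   TRUE     EssC_like
#> 9 locus_009             III-C strict       NxD  FALSE          none
```

The simulated genome plants one locus of each of the eight CoCoNuT labels
plus one canonical (NxxD) McrBC operon and six decoys. The funnel shows 11
anchored neighborhoods: the nine planted operons pass the strict filter and
are paired; the two MoxR-like AAA+ decoys are anchored (MoxR is an McrB
alias) but rejected, because a single alias class with no qualifying
adjacent partner passes no tier. Every call matches its planted label,
including the Type II locus with its TerY-P module and CARF/RtcR
superoperon, and the extended Type III-A locus with the EssC-like insert.

Individual stages are exported for real data: `read_gff3()` /
`read_fasta()` / `read_domain_hits()` to load annotations,
`annotate_proteins()` with any profile-search adapter, `run_census()`,
`classify_locus()`, `iterate_clustering()` / `nj_tree()`, and
`write_report()` for TSV + JSON output.

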