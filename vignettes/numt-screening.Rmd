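---
title: "Screening CO1 barcode data for NUMT pseudogenes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening CO1 barcode data for NUMT pseudogenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtscreen)
```

## The problem

Population studies of the poultry red mite *Dermanyssus gallinae* (and of
many other arthropods) characterise within- and between-farm genetic
structure from Sanger-sequenced fragments of the mitochondrial CO1 gene,
collapsed into haplotypes and summarised as per-farm diversity statistics
and haplotype networks. Nuclear copies of mitochondrial DNA (NUMTs) are a
recurrent contaminant of this workflow: once integrated in the nuclear
genome a CO1 copy is released from purifying selection, accumulates
substitutions uniformly across codon positions (and eventually frameshifts
and stop codons), and can be co-amplified with — or instead of — the true
mitochondrial target. Treated as ordinary haplotypes, NUMTs create
artifactual "haplogroups" that distort diversity statistics, networks and
phylogeographic narratives. The same divergence signal, however, can also
indicate a genuine cryptic species, which is distinguished by *concordant*
nuclear divergence (private nuclear alleles) rather than allele sharing
with the main population. This package implements the full desk workflow:
haplotype extraction, diversity profiling, minimum-spanning networks,
haplogroup assignment with the published cross-study synonymy, the
codon-position tree diagnostic, a five-warning composite NUMT verdict, and
phasing of heterozygous nuclear intron consensus sequences used as the
nuclear line of evidence.

## Statistics and procedures

**Haplotypes.** A haplotype is a unique, fully resolved sequence over the
analysis window. Merged multi-study alignments are first trimmed to a
common window (`trim_to_common_window`; either the maximal contiguous
column interval at a chosen coverage, or by dropping flank-incomplete
rows); rows with in-window ambiguity codes or gaps are excluded and logged
(`collapse_haplotypes`), mirroring the usual practice of discarding
poor-chromatogram reads. Coordinates are 0-based half-open throughout.

**Diversity.** For each population, `diversity_stats` reports n, the
number of haplotypes h, segregating sites S, the ratio S/h and the
haplotype diversity

$$Hd = \frac{n}{n-1}\Big(1 - \sum_i p_i^2\Big),$$

Nei's small-sample-corrected estimator, identical to the probability that
a random unordered pair of sequences (drawn without replacement) carries
different haplotypes. S is counted over retained rows only; gaps are a
fifth state excluded from S by default. Farms are classified as carrying a
single typical haplogroup, a mixture including haplogroup C (which
inflates S/h without necessarily inflating Hd), or any atypical group.

**Networks.** `build_msn` computes the strict minimum spanning network:
the union of all minimum spanning trees of the haplotype Hamming-distance
graph, built by Kruskal's algorithm one weight class at a time (an edge
belongs to some MST iff its endpoints lie in different components before
its weight class is processed; it belongs to every MST iff it is a bridge
of the contracted class subgraph). `epsilon > 0` optionally relaxes the
network by the usual bottleneck criterion. The `star_score` of a
population is (modal haplotype share) × (fraction of remaining haplotypes
within ≤ 2 mutations of the mode): founder/bottleneck expansions — one
dominant haplotype ringed by rare 1–2-mutation satellites — score near 1,
while the balanced scattered variant sets characteristic of NUMT
co-amplification score near 0. The score is an operationalisation of a
qualitative published pattern; its threshold (0.5) is only used inside
warning W3.

**Haplogroups.** `assign_haplogroups` assigns each haplotype to its
nearest reference by p-distance, with `tau_assign = 0.03` as the
divergence ceiling — between the ≤ 2-mutation within-star scale and the
~5–9% between-haplogroup scale. `synonymize` exposes the published
correspondence between naming systems (Lmt3/Lmt2/Lmt1 ↔ A/B/C typical;
clade F/L1 ↔ D, the cryptic lineage; JOW, Co21-22, E, F, H = NUMT
artifact groups).

**Codon-position diagnostic.** Functional coding sequences accumulate
most substitutions at third codon positions; pseudogenes substitute
uniformly. `resolution_retention` builds neighbour-joining trees (p, JC69
or K2P distances; bootstrap by column resampling, support of a group = %
of replicates in which it forms a bipartition) on all positions and on
first positions only. A group "retains resolution" when its pos1 support
stays ≥ 70 *and* its pos1 stem keeps ≥ 0.5 of its all-positions stem.
Stems are measured as **synapomorphy density** — the fraction of columns
at which the group is monomorphic for a state found in no other taxon —
rather than as NJ edge lengths: on a sparse 157-column pos1 alignment,
least-squares length estimation smears single shared sites into stems 2–3×
their character content, while the synapomorphy count is deterministic and
sits on the same per-site scale in both trees (NJ edge lengths are still
reported alongside). Distance NJ replaces heavier ML machinery
deliberately: the diagnostic rests on the *differential* signal between
position sets, not on the tree inference engine.

**The composite verdict.** Five warnings are evaluated per candidate
group: W1, ≥ 3 amino-acid positions at which the group shares no state
with the reference panel, and/or retained pos1 resolution; W2, placement
on the outgroup side of the species clade (the smallest clade containing
the group and all typical references also contains an outgroup taxon);
W3, Hd > 0.70 within a building with star score < 0.5 (balanced
multiplicity; reliable only near the recommended ~20 mites/building); W4,
more than 10% of a building's raw sequences with an ambiguity-code
fraction above 2% (the in-silico proxy for chromatogram double peaks); W5,
nuclear alleles shared with typical-haplogroup carriers. The verdict rule
is explicit because the source guidance is qualitative: any in-frame stop
codon forces `numt_suspect`; otherwise ≥ 2 of W1–W4 force `numt_suspect`;
otherwise a divergent group is `cryptic_candidate` with private nuclear
alleles and `numt_suspect` with shared ones (absent nuclear data it stays
`cryptic_candidate`, flagged for manual review); otherwise `typical`
(single-warning groups carry a review flag). Adding a stop codon can only
move a verdict toward `numt_suspect`.

**Phasing.** A heterozygote with one short indel yields a trace that is,
from the indel on, the superposition of the longer allele and the shorter
allele shifted by the indel length; each position is an IUPAC union of two
bases. `phase_heterozygote` scans deletion hypotheses (position, length ≤
7) near the first ambiguous column and decodes each by dynamic programming
along the shift chains $i, i+L, i+2L, \dots$, anchored in the unambiguous
tail where only the longer allele remains, minimising the number of
columns the overlay cannot explain (inferred allele SNPs). A cheap
per-hypothesis lower bound (forced mismatches at columns whose overlay
partner is unambiguous) orders the scan and prunes hypotheses that cannot
beat the incumbent. The decoder reports the count of tied optimal allele
pairs; ties, unexplained fractions below 0.9, and multi-site SNP-only
heterozygotes (whose linkage is unknowable from a single trace) are
returned with low confidence rather than guessed. Phased alleles are
matched exactly against a homozygote catalog; novel alleles are flagged,
never merged.

## The synthetic-data generator

All tests run against `simulate_*` functions that emulate the statistical
structure the screen assumes; no sequence downloads are involved.

* **Fragment geometry**: a 471 bp (157 codon) in-frame CO1-like fragment,
  matching the region-1 alignment scale (470 bp, 157 first positions);
  translation table 5 (invertebrate mitochondrial; stops TAA/TAG) with
  frame 0 by construction — real data's frame and code are configurable
  because published analyses rarely state them.
* **Haplogroups**: three typical centroids (plus the deeper cryptic D on
  request, 1.6× the typical depth) at ~5% mutual p-distance, built from
  disjoint substitution sets so pairwise divergences are exact;
  substitutions land on third codon positions with probability
  `q3 = 0.9`, never creating a stop.
* **Farm demography**: stars are sampled directly — a dominant central
  haplotype with satellites at 1–2 mutations at expected frequency 0.15 —
  rather than via coalescent machinery, since every claim under test
  concerns the resulting pattern, not the generative process. Farm size
  defaults to 20, the recommended sampling effort.
* **NUMTs**: founders evolve position-uniformly at ~12% divergence, carry
  a frameshifting 1 bp deletion with probability 0.5 (placed so that at
  least one in-frame stop follows, as observed in the frameshifted
  haplogroup-H sequences), and appear within farms as 3–5 variants at
  balanced copy numbers (max/min ≤ 3, the operationalisation of
  "relatively balanced frequencies"). Co-amplified mode renders NUMT reads
  as IUPAC-consensus overlays with the mitochondrial hub. For tree
  diagnostics, the NUMT founder branches off partway along one outgroup
  lineage — an ancient integration — which reproduces the published
  placement "among the outgroups".
* **Diagnostic panels**: haplogroup members attach along the distal
  60–100% of each group's substitution path plus 1–2 private mutations. A
  cross-study haplogroup panel has internal phylogenetic depth; modelling
  it as a single farm-style star would make the entire group path a shared
  stem and overstate first-position resolution of functional groups.
* **Intron (Tpm-like) data**: an allele pool of SNP variants of a 360 bp
  ancestral intron; heterozygotes pair an allele with a copy of itself
  carrying one fixed 3–7 bp deletion plus up to 5 SNPs. **Identifiability
  contract**: allele differences strictly upstream of a heterozygous indel
  are assignment-symmetric in a single trace (no method can phase them),
  and coincidental base matches along the shift chain can create exact
  parsimony ties; the generator therefore places SNP differences
  downstream of the overlay start and verifies each emitted consensus is
  uniquely decodable, re-drawing SNP positions otherwise (a handful of
  redraws at most). This is what makes the exact round-trip property
  well-posed. Real chromatograms that violate it are exactly the cases the
  decoder reports as low-confidence.

What the generator does **not** emulate: chromatogram signal (ambiguity
codes stand in for double peaks), alignment error, recombination,
heteroplasmy, selection on resistance loci, or multi-farm transmission
dynamics. Passing tests therefore demonstrate the correctness and
discriminative behaviour of the statistics under the assumed structure,
not performance on raw traces.

## Numerical and design details

* Determinism: every stochastic stage takes an explicit seed; a pipeline
  run is a pure function of (inputs, config, seed) and output files carry
  a provenance header (package version, seed, thresholds), so repeated
  runs are byte-identical.
* NJ distance fallbacks: undefined JC69/K80 distances (saturation) fall
  back to p-distances with a warning. Bootstrap columns are resampled
  with replacement; a group absent from the point tree simply scores its
  bootstrap frequency (0 if never recovered).
* Ties: the modal haplotype on equal counts is the first in table order;
  equal-score phasing hypotheses prefer fewer inferred SNPs, then shorter
  indels, then smaller positions; frame inference prefers frame 0.
* Degenerate inputs: single-haplotype populations score star 1 and Hd 0;
  a group spanning (almost) all taxa is trivially "retained" and flagged
  degenerate; translation of a sequence shorter than one codon, empty
  FASTA files, and ids missing from the sample sheet fail fast with the
  offending ids.
* Problem sizes in the shipped tests and acceptance script (chosen to
  exercise each claim at suite scale): 200 random ≤ 7-haplotype networks
  against the exhaustive union-of-all-MSTs oracle; 100 random tables for
  the Hd oracle; 20 replicate diagnostic panels for retention rates; 25–50
  replicate panels (75–150 typical, 25–50 NUMT and cryptic groups) for the
  screen benchmark; 200–500 phased heterozygotes.

## Known limitations

* Assignment is nearest-reference by p-distance, not tree placement; the
  tree-based cross-check lives in the diagnostic module, and published
  accession-level memberships are not reproduced (that would require the
  original database sequences).
* W2 requires user-supplied outgroup sequences; without them the verdict
  rests on W1/W3/W4 and nuclear evidence.
* The ≥ 2-warning composite rule and the ≥ 3 amino-acid-difference
  quantification of "several segregating differences" are explicit
  codifications of qualitative guidance; both are configurable in
  `screen_config`.
* SNP-only heterozygotes with more than one ambiguous site are reported
  unphased; resolving them requires resequencing with internal primers,
  which is outside a desk tool's reach.
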