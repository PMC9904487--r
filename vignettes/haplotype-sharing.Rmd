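---
title: "Deducing locus genotypes by haplotype sharing: methods and design"
author: "haploseer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deducing locus genotypes by haplotype sharing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploseer)
```

## The problem

Breeding programs and germplasm collections accumulate two kinds of
genotypic data that do not talk to each other: historic locus-specific
assays (SSR fingerprinting panels, trait-predictive DNA tests for QTLs and
Mendelian trait loci) and modern genome-wide SNP-array profiles. For
clonally propagated crops such as apple and sweet cherry, the array data
are typically curated into *haploblocks* — chromosome segments delimited by
historic recombination events — with each individual carrying two phased
multi-SNP *haplotype codes* per haploblock, one per parental homolog.

haploseer translates between the two worlds: given a small *reference
panel* of individuals whose genotypes at a target locus were historically
reported, it associates each reported allele with a unique extended
haplotype pattern spanning the locus, and then deduces the locus genotype
of every other array-genotyped individual from the haplotype patterns it
carries. The approach relies on the high linkage disequilibrium of
pedigree-connected cultivated germplasm: a haplotype pattern around a locus
is, in practice, a durable label of the founder chromosome segment the
locus allele rides on.

## The procedure

### 1. Locus placement and windows

A target locus is placed on the haploblock map by physical position:
*within* a haploblock when their bp intervals intersect (partial overlap
counts as within), otherwise *between* the two adjacent haploblocks
flanking it. The *base window* is that one haploblock or that flanking
pair. Loci outside the haploblock coverage of a chromosome are rejected,
because the method needs flanking haplotypes on both sides.

When a window must grow, it grows by exactly one map-adjacent haploblock
per step, choosing the side that leaves the genetic lengths upstream and
downstream of the locus as near-equal as possible — the locus stays
genetically centred, and the nearest new haploblock is taken first. Two
numerical details are under-determined by the data and fixed by
convention:

* the locus's own genetic position is interpolated linearly in bp between
  the genetic coordinates of its surroundings (within a block: between the
  block's `gen_start` and `gen_end`; between blocks: across the physical
  gap);
* an exact tie in post-expansion imbalance goes to the side whose
  candidate haploblock is physically nearer the locus, and a residual tie
  goes left. This makes expansion fully deterministic.

The genetic span of a window is `gen_end` of its last haploblock minus
`gen_start` of its first.

### 2. Allele assignment

Reference-panel alleles are attached to haplotype patterns by a fixpoint
loop at the current window:

1. **Homozygotes first.** A panel individual reported homozygous pins its
   allele to both of its homolog patterns.
2. **Heterozygote propagation.** When an individual shares an allele and
   one pattern with an already-assigned case, the shared allele rides the
   shared pattern and its other allele rides its other pattern.
3. **Pedigree phase resolution.** A remaining homolog is matched to its
   parent's homolog when their patterns agree over the window; the single
   allele the two reported genotypes share rides that homolog.
4. **Conflict-driven expansion.** Whenever one pattern accumulates two
   distinct alleles (identity-by-state between different functional
   alleles), the window expands by one haploblock and matching restarts.

The loop ends when pattern-to-allele is a function or the window cannot
grow. One *global* window is used for all entries of a locus; per-source
minimal windows are a separate query (`minimalDiscriminatingWindow()`),
which reports, for sources indistinguishable at the base window, the
smallest balanced-growth window at which each becomes unique.

Patterns containing missing codes match nothing: missing never equals
anything, including missing. Panel alleles that cannot be phased
(a lone heterozygote with no informative relative) or that sit on
conflicted patterns at the maximal window are reported in the allele map's
`unresolved` slot — never dropped, never fatal. Individuals are processed
in sorted name order, so the assignment is reproducible whenever several
orders would be valid.

Each assigned pattern is then traced to its *ancestral source*: parent
links are climbed from the panel carriers for as long as the parent also
carries the pattern; the earliest such ancestor (and its carrying homolog)
is the source. Distinct ultimate ancestors of one pattern each become an
entry, so one allele may legitimately map to several (pattern, source)
pairs.

### 3. Deduction via IBD or thresholded IBS

For every individual and homolog, the pattern over the final window is
looked up in the allele map:

* a missing-contaminated pattern → undeduced, `MISSING_DATA`;
* no matching entry → undeduced, `UNIQUE_PATTERN` (these patterns are
  inventoried with carrier counts, a prioritization aid for future DNA
  testing);
* otherwise the allele of the matching entries is assigned, with the mode
  recording the evidence. Identity-by-descent is preferred: an
  `ibdPath()` chain in which every member carries the anchor pattern and
  every link is a parent-child transmission. Without a chain the call is
  identity-by-state, accepted only when the extended shared haplotype with
  the source — the maximal run of equal, non-missing codes around the
  window — is at least the threshold; shorter matches are rejected as
  `BELOW_THRESHOLD` rather than guessed.

The threshold is derived from the data: the shortest extended shared
haplotype observed among the IBD-mode calls, taken globally across the
loci analysed together (`deduceAll()` runs a two-pass protocol: IBD only,
derive, then re-admit IBS). The shipped fallback for datasets with no IBD
calls is 9.4 cM. Shared lengths are measured from `gen_start` of the first
shared haploblock to `gen_end` of the last, so full-chromosome sharing
reproduces one constant length per chromosome. Missing data terminate
extension conservatively; `bridgeMissing` optionally skips up to N
unobserved haploblocks per gap (default 0).

Tie-breaks are deterministic throughout: among IBD-reachable sources, the
shortest pedigree path wins, then the longest shared segment, then the
lexicographically first source name; among IBS sources, the longest shared
segment, then the name.

### Homolog orientation

The package adopts the convention of pedigree-phased array output that
homolog 1 is the maternally inherited chromosome copy and homolog 2 the
paternal one. `ibdPath()` exploits it: the carrying homolog determines
which parent each link climbs to, so every returned chain is
transmission-consistent, not merely carrier-consistent. Data without this
guarantee can set `oriented = FALSE`, which searches both parents per
link. When an ancestor carries the anchor pattern on both homologs
(homozygous by descent at the window), the continuation with the longer
extended shared haplotype with the descendant is preferred — the same
longest-sharing principle used for IBS source selection.

### 4. Validation and mismatch triage

`compareGenotypes()` compares deduced against independently reported
genotypes as unordered allele multisets (`MATCH`, `PARTIAL` for a
consistent single-allele deduction, `MISMATCH`, `UNTESTABLE`), with
accuracy defined as matched deduced alleles over validatable deduced
alleles; panel individuals, whose genotypes anchored the map, can be
excluded from the base. For each mismatch, `triageMismatch()` assembles
the evidence a curator needs: every parent, sibling (≥1 shared named
parent, half-sibs included) and offspring, whether it shares a homolog
across the locus, over how many cM, and which allele the deduction table
places on the shared homolog. The function emits evidence, not verdicts —
deciding that a historic database entry is wrong remains a human call.

## The simulator

`simulateDataset()` generates the ground-truthed data every stage is
tested against. Founders receive haplotype codes and one hidden locus
allele per homolog; gametes are produced by Poisson-crossover meioses
(count ~ Poisson(map length in Morgans), positions uniform on the cM axis,
fair-coin start, no interference — no claim about crossover interference
is being tested, and Poisson suffices for threshold and ambiguity
behaviour). A haploblock inherits the code of the parental homolog active
at its genetic midpoint, haploblocks being historic-recombination units;
the hidden allele always travels with the founder segment covering the
locus position.

Defaults describe the reference study conditions used throughout the
tests: 50 founders, 4 generations of 28 matings × 4 offspring (~498
individuals), one 100 cM / 40 Mb chromosome in 40 haploblocks, reference
panel = founders plus generation 1, missing-cell rate 2%. Generation 1
mates all founders round-robin so that every founder has panel offspring —
without a genotyped descendant, a heterozygous founder's phase is
unresolvable in principle. Two founder modes bracket the difficulty:

* **UNIQUE** — every founder homolog gets its own code at every
  haploblock. Patterns then identify founder homologs unambiguously, and
  the precision of every non-undeduced call is provably 1: the clean
  acceptance surface.
* **POOLED** — codes are drawn from a small per-block pool, creating the
  identity-by-state collisions that exercise window expansion and the
  shared-length threshold.

The default locus sits at the *genetic midpoint of the central
haploblock*. Because block codes are inherited by the homolog active at
the block midpoint, this makes the hidden allele co-segregate exactly with
the block code; an off-midpoint `locusBp` decouples the two under
within-block recombination, reproducing the (rare) double-recombination
failure mode of the real method. The truth table records, per homolog, the
true allele, the founder homolog of origin at the locus and the full
transmission chain; the meiosis table records every crossover.

What the simulator does *not* emulate: SNP-level genotypes and genotyping
error, the phasing/haploblocking step itself (its output is this tool's
input), population structure beyond the configured mating scheme, and
crossover interference. Passing tests on simulated data therefore
demonstrate the correctness of the deduction logic under known truth — not
the field accuracy of phasing-derived haplotype calls.

One known degeneracy: when an individual inherits the *same* founder
segment from both parents, two pedigree routes are equally valid unbroken
IBD transmissions, and the observed data cannot distinguish them. The
deduced allele and ancestral source are still correct; only the
intermediate members of the reported chain may differ from the simulator's
meiosis-level bookkeeping. The longest-sharing link preference resolves
almost all such cases in practice.

## Numerical and design choices, briefly

* Files are UTF-8 TSV with header; `NA` and empty string both mean
  missing. Physical coordinates are 1-based inclusive bp; genetic
  coordinates floating cM. Maps are sorted on load; true interval overlaps
  and non-monotone genetic order are errors, never silently repaired.
* Haplotype codes are opaque labels compared by exact equality; `";"` is
  reserved as the pattern separator.
* Unknown parents may appear as placeholder individuals carrying inferred
  haplotypes; they are ordinary pedigree members.
* The IBD search is breadth-first and depth-capped (default 10
  generations) to bound cost on dense pedigrees.
* All randomness lives in the simulator and is driven by one integer seed
  through R's default Mersenne-Twister generator; the analysis path is
  seed-free and byte-deterministic.
* Problem sizes in the test-suite: the reference conditions above for
  end-to-end recovery (~1,000 homolog deductions), 10,000 meioses for
  crossover calibration, and ~1,000 small random fixtures for the
  brute-force oracle comparisons. These sizes make every property
  decidable in minutes on one CPU.

## Limitations

* The method presumes phased, haploblocked input and high linkage
  disequilibrium; unphased data are out of scope.
* IBS acceptance is a length heuristic, not a probability: a shared
  segment above threshold can still be coincidental, and the threshold
  derived from small IBD sets is itself noisy. The shipped fallback of
  9.4 cM is a pragmatic default, not a universal constant.
* Alleles of patterns absent from the reference panel are not deducible;
  the unassigned-pattern inventory quantifies, but does not remove, this
  gap.
* Probabilistic IBD inference (HMM or likelihood based) is deliberately
  out of scope; the method is exact pattern matching plus pedigree logic.
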