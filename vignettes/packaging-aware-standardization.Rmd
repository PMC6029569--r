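---
title: "Packaging-aware standardization of phage genome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Packaging-aware standardization of phage genome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagestd)
```

## The problem

De novo assemblies of tailed-phage genomes start and end at essentially
arbitrary positions: most packaged genomes are physically circular or
circularly permuted, so the assembler's contig is one rotation (and one
orientation) out of many equivalent presentations. When a collection
contains many closely related isolates, arbitrary rotations make genomes
that share gene content and gene order look superficially different, and
make replicate assemblies impossible to compare base-by-base.

The way a phage packages its DNA, however, leaves reproducible
fingerprints in the sequencing data, and those fingerprints support a
*standardized* presentation:

* **Headful (pac) phages** cut unit-plus genome lengths (up to ~110% of
  the genome) processively from a concatemer starting at a *pac* site.
  Virions are terminally redundant and circularly permuted; mapped
  coverage is elevated over the terminally redundant span, declining or
  stepping away from *pac*. The large terminase subunit (TerL) of such
  phages clusters with known headful packagers, and the pac site
  typically sits in or near the small terminase subunit just upstream of
  TerL. These genomes are standardized by re-linearizing the circularized
  contig at the start of the ORF immediately upstream of TerL.
* **cos phages** cut at a fixed site leaving complementary 5' or 3'
  single-stranded overhangs. Library chemistry acts on those ends
  (polymerase end-fill duplicates a 5' overhang; 3'-to-5' exonuclease
  removes a 3' overhang), producing a sharply localized coverage
  peak or valley at the cos coordinate. These genomes are cut in the
  middle of that feature.
* **DTR phages** carry a direct terminal repeat that the assembler
  collapses to one copy, which then shows roughly doubled coverage — a
  short internal peak. Cut at its midpoint.
* **Mu-like transposable phages** package host DNA at both genome ends;
  assemblies show sharp drops to low-coverage host flanks, which are
  trimmed away (or the conserved core shared by group members is kept).
* **Protein-primed linear phages** carry inverted terminal repeats
  (ITRs) and no terminase; the contig that exhibits the ITR is selected.
* When none of this evidence is present, the original assembly is
  maintained.

Because evidence per genome is noisy, the decision is made per *genome
group* (genomes clustered by shared protein content): all members of a
group receive a common inferred packaging category, with precedence
Mu > ITR > headful > cos/DTR > maintain-original, and genomes lacking
their own terminase scaffold onto a proteome-identical, already
standardized relative.

This package implements that whole procedure — and, because the original
sequencing data is not required, a synthetic packaged-genome simulator
that generates every strategy with ground truth, so the engine is
testable end-to-end.

## The simulator and what it emulates

`make_genome()` produces a random genome with a planted terminase marker
(copied from a bundled archetype panel) preceded by a small random ORF
standing in for the terminase small subunit; the pac coordinate is placed
inside that small gene. `package_virions()` produces the packaged
molecules per strategy; `end_chemistry()` applies cohesive-end library
chemistry; `shear_reads()` fragments molecules uniformly (insert sizes
uniform in 100–300 bp, 150+150 nt paired reads, i.i.d. substitution
errors); `stand_in_assembly()` produces the draft contig an assembler
would report (an arbitrary rotation for circularly interpretable genomes,
the repeat collapsed for DTR, one virion's host flanks retained for
Mu-like genomes).

Key generator defaults are the simulated study conditions:

| parameter | default | why |
|---|---|---|
| genome length | 40 kb | mid-range for tailed phages (collection spans ~10–349 kb) |
| depth | 50x | comfortably above the classifier's floor, cheap to simulate |
| headful fill `f` | 1.05 | mid-range of the generic ~110% headful bound |
| series length `k` | 5 | monomers cut per concatemer |
| cos overhang `c` | 12 bp | lambda-like cohesive-end scale |
| `p_chem` | 0.8 | fraction of molecules with end chemistry applied |
| `p_lig` | 0.9 | fraction re-circularized by cohesive-end annealing before shearing; cohesive ends are sticky in virion DNA extracts, and high annealing is what lets the 12-base chemistry feature dominate the free-end edge artifact |
| DTR length | 800 bp | bracketed below by detectability (a repeat shorter than twice the insert+read span leaves no full-coverage plateau after molecule-end edge effects) and above by the feature-size cap (2% of L); short DTRs (~100–600 bp) are genuinely harder and are a stated limitation |
| ITR length | 100 bp | typical protein-primed repeat scale |
| Mu flanks | 50–150 bp left, 500–3,000 bp right | reproduces sharp terminal drops followed by low-coverage host sequence |
| Mu host genome | 200 kb random sequence | large enough that virion flanks essentially never overlap (with a small host, overlapping flanks raise flank coverage and blur the terminal drop) |

What the simulator does **not** emulate: instrument error models
(quality-by-cycle, indels), GC bias in fragment sampling, chimeric
reads, real concatemer replication biology, or real assembly artifacts
(misassemblies, repeat-induced breaks). A passing simulation therefore
shows the decision logic is sound given clean signals of the modeled
shapes, not that every real library will produce those shapes.

## Mapping and the origin of the cos signatures

`map_reads()` is an exact-seed mapper for the simulator's error-free or
low-error reads: each mate is placed by a k-mer seed (k = 31) and
ungapped extension with soft clipping — the aligned span is the
contiguous stretch around the seed not interrupted by three consecutive
mismatches. One alignment per read, leftmost hit for multi-mappers
(ambiguity counted), unplaced mates counted.

Soft clipping matters: reads that run across a cohesive-end junction
carry bases from the *other* side of the cut and are clipped at the same
base, like a local aligner would clip them. Consequently:

* a 3' (exonuclease-degraded) cos end shows a ~c-base near-zero valley
  whose boundaries are a clip-**end** pileup followed by a clip-**start**
  pileup;
* a 5' (end-filled) cos end shows a modest (~1.2x) duplicated window
  ending in a clip-end pileup, followed by a "shadow" dip of clipped
  read tails (under one-alignment-per-read mapping a duplication can
  never exceed 2x coverage, and in practice lands well below it);
* Mu host flanks show massive clip pileups exactly at the conserved-core
  boundaries.

`per_base_coverage()` therefore records, alongside depth, the number of
placements starting and ending at every base. The classifier uses these
clip pileups to locate and type narrow cohesive-end features: the
*order* of the paired pileups (end-then-start = deletion = valley;
start-then-end = duplication = peak) is the discriminator, and it proved
far more reliable than any depth-window statistic (measured over pilot
simulations: the downstream partner pile is present with the correct
sign in 10/10 seeds for both cos types, while depth-window levels
overlap between the two chemistries).

## The classification cascade

`classify_pattern()` applies a fixed, documented cascade; every
threshold is a named key in `pattern_config()`:

1. **terminal_drop_mu** — linear contigs where both terminal segments
   drop to ≤ 0.25x the interior median, each at most 10% of L, at least
   one longer than an insert+read span (so plain shear edge ramps do not
   qualify), recovering to ≥ 0.5x within two smoothing windows of the
   edge.
2. **cos_peak / short_internal_peak** — exactly one narrow clip-pileup
   feature of duplication type (≤ 100 bp wide → cos_peak), or one broad
   elevated run: 401-base running median ≥ 1.55x its wide local
   background over 150 bases to 2% of L (the collapsed-DTR plateau sits
   at 2x; the 400-base noise ceiling at 50x is ~1.4x).
3. **cos_valley** — one narrow deletion-type feature whose floor is
   ≤ 0.5x the median.
4. **multiple_peaks** — two or more disjoint peak features.
5. **gradual_shift** — circular contigs only. Step route first: an
   exhaustive two-level circular segmentation (grid of lengths from 3%
   to 70% of L, all offsets, by prefix sums) maximizing the
   standard-error-normalized contrast; accepted when the in/out fold is
   ≥ 1.1, the normalized score ≥ 10 per unit median depth (genuine
   headful plateaus score ~15–20; chance regions stay below ~6), and the
   refined upstream edge traverses ≥ 30% of the contrast within one
   window. The anchor is the refined upstream edge — the inferred pac
   position. Trend route second: a circular log-linear fit from the
   profile maximum explaining ≥ 50% of variance with a non-increasing
   profile over ≥ 60% of L. Step shifts are folded into this class
   because headful evidence in practice spans "gradual decreases/shifts";
   with a deterministic series of k monomers the expected signature *is*
   a (k+1)/k step over k(f−1)L bases, not a smooth gradient.
6. **even** — max/min of a heavily smoothed profile (window
   max(2001, L/20)) ≤ 1.5, excluding an insert+read span at the ends of
   linear contigs (where shear edge ramps always dip).
7. **none** otherwise.

Numerical choices worth knowing: median filters are used throughout
(robust to single-base artifacts) and are wrap-padded on circular
contigs, so every stage of the cascade is exactly rotation-equivariant —
a property the test suite checks. Peak detection against a *local*
(wide-window) background keeps coverage clumps atop an elevated headful
plateau from registering as peaks. Minimum profile length is 1 kb and
minimum median depth 5; below those the call is `none` with a warning.
All-zero profiles are an error.

**Anchor precision for headful genomes.** The pac-edge step has height
median/k (≈ 9.6 reads at the defaults) against per-base depth noise of
sd ≈ 12 correlated over a fragment length (~300 bp, because mates of one
fragment cover adjacent bases together). The resulting step-localization
bound is roughly ±700 bp (1 sd); over ten seeds we observe anchor errors
of 55–381 bp in eight and 1–2 kb in two. The headful *standardized
start* does not depend on this anchor — it comes from TerL
re-linearization, which is exact to the ORF — but anyone consuming the
`gradual_shift` anchor should treat it as approximate at this scale.

## Gene calling and terminase assignment

`find_orfs()` is a deliberately simple six-frame caller (translation
table 11; starts ATG/GTG/TTG; maximal ORFs from the first start after
each stop; ≥ 60 aa). Circular contigs are scanned on the doubled
sequence with de-duplication modulo L, keeping only ORFs with an
in-window upstream stop so calls are rotation-equivariant. It does not
reproduce a production gene caller's start-site model, and is not meant
to.

`assign_terminase()` aligns every ORF locally (BLOSUM62, gap open 11 /
extend 1) against an archetype panel labelled with packaging classes
(headful: Sf6, 933W, T4, P22; cos-5': lambda, P2; cos-3': HK97; DTR:
T7, N4; Mu-like: Mu) and converts raw scores to Karlin–Altschul
E-values (gapped BLOSUM62 constants λ = 0.267, K = 0.041; database size
= summed panel lengths, so results are bit-reproducible). Best hit under
E < 10⁻³ wins; ties break by bit score then name. The bundled panel is
**synthetic** — random proteins carrying the conventional archetype
names, sufficient for simulation round-trips and clearly labelled as
such — and is user-replaceable with a real terminase panel via the
`refs` argument for real data.

## Group context and strategy selection

`reciprocal_best_hits()` forms protein clusters as connected components
of the cross-genome reciprocal-best-hit graph (same scoring as above,
E ≤ 10⁻⁵, alignment covering ≥ 75% of the longer protein);
`group_genomes()` forms genome groups as connected components of the
cluster-set Jaccard graph at ≥ 0.35. Connected components deliberately
replace Markov-style clustering: they are simpler, deterministic, and
sufficient for group-consensus strategy selection; the Jaccard threshold
is an invented default and a config key. `identical_proteome_pairs()`
feeds scaffold eligibility (pairs with equal cluster sets, every cluster
containing both genomes).

`select_strategy()` applies the precedence described above with a full
decision trace per group. A group mixing Mu-like and non-Mu terminases
is an error (flagged for manual review). The design invariant that all
members of a group share a strategy is interpreted as sharing the
inferred packaging *category*: a member without a terminase may receive
`scaffold_to_reference` while its group is headful — that is the point
of scaffolding.

## Technical validation analytics

`ani_from_counts()` computes replicate ANI as
1 − (mean mismatch count)/(mean length), rounded half-up to 7 decimals —
the closed form that exactly reproduces all 36 published replicate
comparisons from their printed mismatch and length columns (the test
suite and `analysis/05_replicate_qc.R` verify all 36).
`compare_replicates()` provides the alignment route (global alignment,
match 1 / mismatch −2 / gap open 10 / extend 0.5) with gapped columns
attributed to the sequence bearing the insertion — one consistent choice
among several the published table leaves open. Pairs sharing < 90% of
31-mers are an error, never a low-ANI result.

`prophage_screen()` chains shared 31-mers along diagonals (gaps ≤ 100
bridged), reports chains ≥ 5 kb at ≥ 95% identity, and flags a virus
whose chained cover reaches 90% of its genome as a putative induced
prophage — the one real positive in the collection covered ~94% of its
genome at 100% identity, and the test suite reproduces that case from a
constructed fixture. `synteny_check()` scores collinearity as the
longest-increasing-subsequence fraction of shared unique k-mers.

## Scale choices

Simulations in the tests and analysis scripts run at L = 40 kb, 50x,
ten seeds per strategy — the conditions under which the signature
recovery targets are stated — and smaller (12–20 kb) genomes for
unit-level properties, chosen so the whole suite completes in a few
minutes on one core. The register-derived statistics are computed from
the bundled 283-row table, not simulated.

## Known limitations

* cos features narrower than a read and DTRs shorter than ~2x the
  insert span are hard to detect at 50x; the defaults avoid those
  regimes and say so above.
* The cascade returns exactly one label; genuinely mixed signatures
  (e.g. a headful genome that also shows a short internal peak) cannot
  be expressed — group consensus, not the single label, drives the final
  strategy.
* The mapper is for synthetic/low-error reads; real data should be
  mapped externally and imported via bedGraph (`read_bedgraph_coverage()`),
  in which case clip pileups are unavailable and narrow-feature typing
  falls back to depth edges, which is less reliable.
* Group numbering is arbitrary; reproducing any particular published
  grouping requires that collection's actual data.
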