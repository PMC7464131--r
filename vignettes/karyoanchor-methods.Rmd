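---
title: "Anchoring genome scaffolds with BAC-FISH physical maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchoring genome scaffolds with BAC-FISH physical maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyoanchor)
```

## The problem

Scaffold-level genome assemblies of karyotypically diverse vertebrates —
turtles are the motivating case — are often too fragmented to say which
chromosome a scaffold belongs to, and long-range scaffolding (e.g. optical
mapping) can silently join sequence from different chromosomes into one
"hybrid" scaffold. Molecular cytogenetics provides an independent line of
evidence: a BAC clone can be located *in silico* (its sequence aligns to a
scaffold) and *cytogenetically* (its FISH probe paints a chromosome, and
often an arm). Fusing the two placements anchors scaffolds to chromosomes,
and any scaffold carrying clones that FISH to two different chromosomes is
flagged as a misjoin (a chimeric scaffold). The same clone set, hybridised
onto a second species, supports chromosome-homology and nomenclature
comparisons between assemblies.

karyoanchor implements this integration as a reusable pipeline with a
truth-known synthetic-data generator, so every step can be validated
against ground truth before being pointed at real data.

## BAC window mapping

A clone of length $L$ is split into sliding windows of `window` bp
(default 150) every `step` bp (default 50). Windows sit at offsets
$0, s, 2s, \dots$ while $o + w \le L$, giving
$\lfloor (L-w)/s \rfloor + 1$ windows. Because $w \ge s$, the trailing
remainder after the last full window is always shorter than $s$, so at most
$s - 1$ bases of a clone go unexamined; a dedicated tail window is never
required for valid inputs (the guard exists but is provably unreachable).
Sequences shorter than one window yield a single full-length window
flagged `short`.

Windows are matched ungapped against both strands of every scaffold,
keeping every position whose identity reaches `min_identity` (default
0.95). The matcher is `Biostrings::vmatchPattern()` with a mismatch budget
of $\lfloor (1-\mathrm{id}_{\min}) w \rfloor$; windows with more than 10%
ambiguous bases are skipped and counted. This deliberately is a desk-scale
stand-in aligner: it is exact-match semantics with bounded substitutions,
sufficient because the synthetic clone model introduces substitutions only
(no indels), which keeps window matching a valid oracle. Real aligner
output (BWA-MEM, LAST, minimap2) enters the same pipeline through
`read_window_alignments()`, which parses SAM or PAF records whose query
names encode `cloneID:windowIndex`, dropping unmapped records and marking
secondary/supplementary ones.

A clone's placement on a scaffold is supported by the number of *distinct*
window indices hitting it — distinct, so that a tandemly duplicated target
cannot inflate support. The best scaffold is accepted when its support
fraction is at least `min_support_fraction` (default 0.5) **and** it beats
the runner-up by `min_margin` (default 2.0); otherwise every candidate is
emitted flagged `multi`. The two thresholds are explicit stand-ins for the
manual curation a cytogeneticist would apply to multi-mapping clones; they
are exposed rather than hidden because no published criterion exists to
reconstruct. Both are monotone: raising either never accepts more
placements.

## Anchoring and chimera detection

`anchor_scaffolds()` joins accepted placements to a FISH table
(`clone_id`, `chromosome`, optional `arm`). Conflict is defined on
chromosome *numbers* only: clones on 8p and 8q agree on chromosome 8, and
an arm is recorded only when unanimous. This rule is forced by real usage,
where arm-resolved and arm-unresolved assignments (e.g. "1q" and "4") mix
freely in one evidence table; an arm-less label means "arm unknown", never
"different chromosome".

A scaffold whose conflict set holds two or more chromosomes is chimeric
(`detect_chimeric_scaffolds()`). This reproduces the published evidence
rule — two or more clones painting to different chromosomes while aligning
to one scaffold — and on the packaged evidence tables recovers exactly the
seven known misjoined scaffolds totalling 190,274,700 bp. Chimeric
scaffolds stay in anchored-bp totals (their sequence *is* physically
anchored, just to more than one chromosome) but carry a flag and can be
excluded. Breakpoints are reported only as the gap between the nearest
discordant clone intervals (`chimeric_breakpoint_windows()`): FISH
evidence cannot resolve the misjoin to the nucleotide, and the package
does not pretend otherwise.

Contiguity statistics use the standard cumulative-half definition:
sort lengths descending and take the first length at which the cumulative
sum reaches **at least** half the total. The tie rule (`>=` at exactly
half) is stated because published N50 values never specify it;
`improvement_ratio()` returns `round(100 * new/old)` as an integer
percent. Anchored fractions are always reported against an explicit
denominator, which is echoed in the result — whether the published
percentages were computed against totals with or without unplaced short
contigs is generally unknowable, so the package never silently chooses
one.

## Nomenclature reconciliation

When an assembly's chromosome labels were assigned by size/synteny rather
than karyotype, microchromosome names can be arbitrary. For each assembly
label, `reconcile_nomenclature()` votes the FISH labels of its clones:

* **chimeric** — clones split across two or more FISH chromosomes. This
  takes precedence over everything else: a label whose content is
  majority-correct but carries clones from other chromosomes is still a
  misassembly, and a two-clone 50/50 split is reported chimeric rather
  than an unresolvable tie, because either way the label holds material
  from two chromosomes.
* **rename** — unanimous clones disagreeing with the label's number.
* **consistent** — unanimous agreement.
* **unresolved** — reserved for consensus ties without a cross-chromosome
  split; with the precedence above this is unreachable in practice, and
  ties surface as chimeric calls with a missing (`NA`) consensus.

Renames are emitted as a two-phase old→new map and never applied
automatically: cascades such as 14→13 while 13→15 would transiently
collide. rDNA/NOR evidence needs no special handling — it enters as
ordinary clone-like evidence rows with reserved ids.

## Synteny blocks and homology matrices

`read_alignments()` normalises PAF or MAF local alignments to 0-based
half-open coordinates on both genomes' forward strands (MAF minus-strand
coordinates are flipped via `src_size - (start + size)`). Block size is
the aligned span on the **reference** genome — the choice has to be made
and is stated here, since a minimum-block filter could equally be applied
to the query span.

`chain_blocks()` merges blocks collinear on both genomes (same chromosome
pair, same strand, both gaps at most `max_gap`, query order reversed along
the reference for minus-strand chains), iterating to a fixed point so the
operation is idempotent. A merged block's aligned length is the *sum* of
its parts, so chaining conserves total aligned bp. Filtering
(`filter_blocks()`) applies **after** chaining by default: chaining first
protects long homologies that the aligner fragmented from being discarded
piecewise, and makes the result less sensitive to the threshold; both
orders remain available by calling the two functions in either sequence.
The minimum-block presets (12 kb for close congeners, 7 kb for
intermediate divergence, 1 kb for cross-order comparisons) ship as a named
table (`synteny_min_block_presets`) and are overridable per run.

`homology_matrix()` sums aligned bp per chromosome pair; by default the
raw sum, which exactly partitions the blocks' total bp (an invariant the
tests rely on). Because overlapping local alignments can double-count
reference bases, `dedupe = TRUE` merges overlapping reference intervals
per pair before summation and keeps the raw sum in an attribute, so both
conventions are visible. Correspondence calls
(`classify_correspondence()`) use two thresholds: one-to-one when the top
partner holds at least `dominant_fraction` (default 0.8) of a chromosome's
aligned bp, one-to-many when at least two partners each exceed
`minor_floor` (default 0.05).

For synthetic genome pairs, `align_exact()` matches non-overlapping query
k-mers (default $k = 64$) exactly against both strands of every reference
chromosome (`Biostrings::matchPDict`) and chains the anchors. With i.i.d.
random sequence, 64-mers are unique with overwhelming probability, so the
chained anchors recover the true homology segments; this matcher is for
truth-known exact-copy genomes and is *not* an aligner for diverged real
genomes, which should be aligned externally and imported.

## Gene-order comparison

Shared marker genes along homologous chromosomes are compared as unsigned
permutations. The distance is the breakpoint count: adjacencies of one
order (as unordered pairs, with a single shared endpoint marker appended
at both ends) absent from the other. The shared end marker makes the
measure orientation-agnostic — reversing a list costs zero breakpoints,
reflecting that reading direction along a chromosome is arbitrary — while
terminal relocations still count (moving a terminal gene breaks its
end-marker adjacency). Verdicts: `identical` (equal orders), `reversed`
(exact mirror), `rearranged` otherwise, `unassessable` with no shared
genes. Genes residing on non-matching chromosomes between the species are
set aside as `relocated` rather than forced into the permutation; because
chromosome labels are species-specific (one species' 7 may be the other's
Z), "non-matching" is evaluated against the partner chromosome of the
comparison at hand, not by comparing label strings.

When physical positions are unavailable (published gene orders are often
given only as ordered lists), ordinal ranks are accepted as positions;
rank ties are an error rather than being broken arbitrarily.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions for the validation suites:

* **Karyotype** — 13 macro- + 12 microchromosomes (25 in total, matching
  emydid turtle karyotypes, 2n = 50). Desk-scale chromosome sizes are
  60–120 kb (macro) and 15–40 kb (micro) so that whole property suites run
  in seconds; sizes are drawn uniformly and labels assigned in decreasing
  size order, with the centromere placed uniformly in the middle 60%.
  GC defaults to 0.44, typical of turtle genomes. Sequence is i.i.d.
  random: no repeat families, so exact matching is clean and any
  off-diagonal self-homology would be a bug, not biology.
* **Assembly** — chromosomes are cut at random internal positions and
  seven cross-chromosome fragment pairs are joined into chimeric
  scaffolds (mirroring the seven misjoins found among 345 real hybrid
  scaffolds); the truth map tiles every scaffold exactly and the chimera
  registry lists exactly the induced misjoins.
* **Clones** — verbatim substrings at uniform random positions
  (insert length 150 kb nominally; smaller at desk scale), with FISH
  truth (chromosome + arm from the clone midpoint) recorded at sampling
  time. Mutations are substitutions only; indels would invalidate the
  exact-window oracle. FISH failure is modelled simply as clones absent
  from the FISH table — no hybridisation-noise model.
* **Partner genome** — an ordered list of inversions, translocations,
  fusions and fissions applied through a segment-map algebra; the log
  stores the operations plus the full derived-to-source segment map, and
  replaying the log reproduces the derived genome byte-for-byte. The
  implied (source, derived) chromosome pair set is the truth against
  which alignment-derived homology matrices are scored.

What passing these suites shows — and what it does not: recovery is
demonstrated under exact sequence identity, uniform base composition, no
repeats, and complete clone coverage of misjoin junctions. Real data add
repeat-driven multi-mapping, diverged sequence, and junctions without
clone coverage; the thresholds exposed throughout (identity, support,
margin, block filters) are the knobs that absorb those effects, and the
chimera detector can only ever test scaffolds that carry informative
clones.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; 1-based only
  at BED/GFF boundaries, per those formats.
* `n50()` rejects empty or non-positive input; `improvement_ratio()`
  rejects a non-positive baseline.
* Window splitting of a sequence shorter than one window returns a single
  flagged window instead of erroring, so degenerate clones stay visible
  in the accounting.
* Duplicate conflicting FISH records for one clone are an error;
  duplicate concordant records collapse (keeping arm detail when one
  record has it).
* Malformed SAM/PAF/MAF records warn individually and fail the file only
  above a configurable fraction (default 20%).
* Consensus ties vote `NA` rather than picking a side.
* Fixture tables are checksum-verified (MD5) at load; any edit is a hard
  failure.

## Problem sizes used by the test and acceptance suites

Property suites run on 25-chromosome genomes of ~2 Mb total (chimera
recovery), 8-chromosome genomes of ~0.5 Mb (synteny truth), 1,000 random
length lists (N50), and all permutations of up to 6 genes (breakpoint
distance). These sizes were chosen so the full validation runs in minutes
on a single CPU while still exercising every code path at the karyotype
scale of interest; genome-scale inputs flow through the same functions
unchanged.

## Known limitations

* The window mapper is ungapped and substitution-bounded; indel-rich real
  alignments must come from an external aligner via the SAM/PAF readers.
* Rearrangement requests are validated against source-genome coordinates;
  operation lists that depend on coordinates created by earlier
  operations in the same list (e.g. inverting across a fresh fusion
  boundary) are outside the validated envelope.
* `align_exact()` requires exact sequence identity and is unsuitable for
  diverged genomes.
* Chimera detection is evidence-limited: scaffolds without clones on both
  sides of a junction cannot be flagged, so its sensitivity on real data
  is bounded by clone coverage, not by the algorithm.
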