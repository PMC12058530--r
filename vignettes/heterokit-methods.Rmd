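---
title: "Methods: genome-architecture analysis of complete ape assemblies"
author: "heterokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-architecture analysis of complete ape assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterokit)
```

## Scope

Telomere-to-telomere (T2T) primate assemblies expose the parts of the
genome that older assemblies collapsed: centromeric alpha-satellite
higher-order-repeat (HOR) arrays, subterminal heterochromatic caps,
rDNA/NOR arrays, and the breakpoints of large inversions. `heterokit`
implements the quantitative analyses these regions call for -- assembly
QC, satellite array segmentation and classification, methylation-dip
(CDR) profiling, cap/spacer decomposition, rDNA accounting, and
inversion phylogenetics -- together with a synthetic-genome generator
that provides full ground truth, so that every analysis can be validated
end to end by round-trip.

## Assembly QC

A chromosome is **T2T** when it is gapless (no N runs) and carries a
telomere at both termini. Telomeres are detected as maximal tandem runs
of the canonical 6-mer `TTAGGG` (or its reverse complement) of at least
`min_run_bp` whose nearer end lies within `max_offset_bp` of a sequence
terminus. Defaults are `min_run_bp = 2000` and `max_offset_bp = 10000`;
real telomeric tracts at chromosome ends are tens of kilobases, so 2 kb
is permissive without picking up interstitial telomere-like repeats, and
the 10 kb offset tolerates subtelomeric margins. Matching is exact by
default: on synthetic sequence this keeps the detection oracle trivial,
and on real data a divergence-tolerant scan can be layered on top of the
same run logic. Gaps are maximal runs of at least 10 consecutive N
(configurable); no standard N-run threshold exists, and any value below
typical gap sizes (kb scale) gives identical results.

Issue accounting follows the assembly-table convention: a gap counts
unless it overlaps an rDNA interval (rDNA arrays are expected breaks and
curated separately), and each missing terminal telomere adds one issue.
We treat the published per-haplotype issue column as additive in gaps
and missing telomeres; if the original accounting bundled these
differently, only fixtures carrying the printed totals are affected, not
the rule's internal consistency.

Contig N50 is the largest length `L` in the contig set such that contigs
of length at least `L` contain half the assembly; tests check this
against an exhaustive candidate-search oracle. Summary rows are
arithmetic means rounded **half-up** at the printed precision (2 dp for
Gb/Mb columns, 1 dp for counts and QV), so 146.375 reports as 146.38;
base R's `round()` rounds half-to-even and would print 146.38 only by
accident of floating point. QV is a pass-through input, never computed.

## Satellite arrays and centromeres

Same-family annotations merge into an array when their gap is at most
`max_gap_bp` (default 10 kb), and arrays shorter than `min_array_bp`
(default 10 kb) are dropped. The defaults sit well below the megabase
scale of centromeric and subterminal satellite blocks and above the
32--34 kb spacers that must *not* be absorbed, so synthetic round trips
are exact. Merging is idempotent, and each input annotation lands in
exactly one array of its family (or is discarded by the length filter).

Arrays are classified by context: `rdna` by family; `subterminal` when
the array lies within `end_window_bp` (default 500 kb) of a chromosome
end; `centromeric_hor` for the largest remaining alpha-satellite array
on the chromosome; `interstitial` otherwise. Identifying the centromere
as the *largest* non-subterminal alpha-satellite array is a deliberate
simplification of active-array identification, which in practice uses
HOR/suprachromosomal-family annotation and CDR support; it is correct by
construction on the synthetic genomes and is stated as a proxy for real
data.

Minicentromeres are HOR arrays shorter than **700 kb**, the threshold
under which roughly half of bonobo centromeres fall; the partition is a
pure threshold rule, and the generator's bimodal length distribution
(below) reproduces the mini/normal dichotomy with component truth
labels. Haplotype pair comparison reports the fraction of homologous
array pairs whose sizes differ by more than 1.5-fold -- the ratio is
max/min, avoiding direction ambiguity between haplotypes -- and the
fraction exceeding 5% sequence divergence, with missing divergence
values excluded from that denominator only.

## CDR calling

Centromeres carry one or more stretches of hypomethylated CpGs, the
centromere dip region (CDR), marking the kinetochore site. The published
analyses used external CDR callers whose parameters are not printed, so
the caller here is the package's own definition, exposed entirely
through parameters: per-CpG fractions are averaged in sliding windows
(5 kb window, 1 kb step, each CpG weighted equally to match the
simulated track's semantics); the array baseline is the **median** of
defined window means; windows more than `drop = 0.20` below baseline are
dip windows; runs of dip windows tolerating up to 2 interruptions merge
into a CDR; CDRs shorter than 1 kb are dropped. Because a window is
flagged once it substantially overlaps the dip, the raw span
overestimates each edge by about half a window; spans are therefore
trimmed by `(window - step)/2` per side, which brings recovery of
synthetic truth dips above 0.9 Jaccard. Two consequences of the
median-relative rule are intentional: an entirely hypomethylated array
has no CDR (its baseline *is* the dip level), and overlapping spans that
can arise from the window/step geometry are merged so CDRs never
overlap.

For the CDR-length-versus-array-length regression, "CDR length" is the
summed length of all CDRs in the array -- the singular per-chromosome
usage is ambiguous for multi-dip arrays, and summing is deterministic.
The regression is ordinary least squares with R&sup2; = 1 - SS_res/SS_tot,
defined as 0 when the response is constant. Whether the published
R&sup2; = 0.41 used active-array or total alpha-satellite length is not
stated; that value is data-dependent and is not asserted anywhere in the
package.

## Subterminal caps and spacers

Subterminal heterochromatic caps are built from a ~32 bp AT-rich
satellite organized into tracts of several hundred kilobases interrupted
by hypomethylated spacer segments of segmental-duplication origin
(modal lengths near 32 kb in *Pan*, 34 kb in gorilla, 57 kb in siamang,
with siamang spacers recurring about every 750 kb). Cap detection
anchors on subterminal-classified arrays and chains same-family arrays
across gaps of at most 200 kb (the upper spacer scale): only the
outermost tract of a multi-megabase cap lies inside the subterminal
window, so the inner tracts must be recruited through the spacer-scale
gaps.

Spacers are the unannotated gaps between consecutive tracts within a
cap, length-filtered to [5, 200] kb. This is an annotation-gap proxy:
the original identification of spacers as SD sequences requires
alignment evidence that is out of scope, but on annotated assemblies
the gap structure is the observable signature. The modal spacer length
uses 1 kb bins with ties broken toward the smaller bin for determinism;
for noise-free synthetic spacers the mode is exact whenever the bin
divides the spacer length. Periodicity is the mean distance between
consecutive spacer midpoints.

The methylation profile aligns per-CpG fractions on spacer midpoints
(+/-25 kb, 500 bp bins) and averages across spacers. The pocket
statistic is the mean fraction inside spacers minus the mean in the
flanking satellite within the window, excluding CpGs that fall in
*another* spacer (which would contaminate flanks in short-period caps),
with a one-sided Wilcoxon rank-sum test of spacer < flank.

## rDNA and NORs

Copy number is array span divided by the unit length (default 45 kb,
the human-scale unit; per-species units are inputs), rounded half-up.
The published estimation procedure lives in supplementary material not
reproduced here; span division is exact on assemblies whose arrays are
tandem unit multiples, which the generator guarantees. A chromosome is
NOR+ when it carries an rDNA array of at least `min_units` copies
(default 1 -- a single-unit array counts, matching the smallest
published haplotype value). Distal-junction palindrome detection is out
of scope, so NOR status is defined purely by rDNA presence. Totals
aggregate per haplotype or per diploid genome and are permutation
invariant.

## Inversion phylogenetics

Inversion presence/absence characters are mapped onto a rooted species
tree by small parsimony with the **root fixed to the reference state**:
inversions are treated as derived, which polarizes changes and lets a
single-change character be assigned to the branch where the gain
occurred. The minimum change count comes from a unit-cost Sankoff
recursion; branch assignment checks which edge's clade equals the
presence pattern (with ties toward the smallest clade when missing data
leave several candidates). Characters needing two or more changes are
recurrent. Only homozygous-inverted species count as present;
heterozygous species are missing by default, with an opt-in that counts
them as present for sensitivity analysis. Tests verify the change count
against brute-force enumeration of all ancestral labellings for all 64
characters of the six-species tree.

The default tree covers the six sequenced non-human apes, with node
depths at 1.7 Ma (*Pan*), 10.75 Ma (gorilla), 19 Ma (orangutans),
0.9 Ma (*Pongo*) -- midpoints of the published split-time ranges -- and
20 Ma for the siamang root, a standard hylobatid divergence chosen here
because the printed text gives a figure-only value;
`ape_species_tree(include_human = TRUE)` adds human at 6 Ma. Using six
leaves keeps the exhaustive parsimony oracle at 2^6 characters.

Breakpoint enrichment uses a permutation null: each inversion is
re-placed uniformly on its own chromosome with its length preserved,
excluding placements that overlap assembly gaps; placements are not
shuffled between chromosomes, conserving per-chromosome feature
density. A breakpoint hits when it falls inside a feature padded by
+/-10 kb by default (breakpoints from assembly comparison are not
base-precise; the pad is a flag). Fold is observed over null mean, and
the one-sided empirical P uses the +1 correction, bounding P at
1/(n_perm + 1). Note the two breakpoints of one inversion are
correlated (they sit one length apart), so the naive independent-hit
approximation underestimates the null and the calibration tests bound
the fold rather than pin it.

Recall against a prior callset confirms a previous interval when a
current call reciprocally overlaps at least 50% of each.

## The synthetic-genome generator

The generator emulates the architectural features the analyses target,
with every placement recorded in truth tables (BED-convention 0-based
half-open intervals; CpG positions are the C of CG on the forward
strand). Each chromosome is laid out as p-telomere, optional p-arm cap,
centromeric HOR array, optional rDNA array, optional q-arm cap,
q-telomere; caps sit against their telomere and the remaining
background -- i.i.d. uniform ACGT, which avoids accidental
satellite-like structure -- fills the interior. HOR arrays are exact
tandem repeats of a randomly generated 171 x 6 bp unit with an optional
per-base substitution rate (default 0, keeping identity baselines
clean). The default array length distribution is the bonobo-like
two-component lognormal (minicentromere component mean 110 kb, normal
component mean 3.6 Mb, minicentromere weight 27/48, clamped to the
published ranges 15--674 kb and 1.6--6.7 Mb). Cap tracts default to
~400 kb (within the published 335--536 kb tract range) with 32 kb
spacers; the spacer monomer is a fixed 32 bp AT-rich sequence carrying
two CpGs so cap methylation is measurable. rDNA units default to 45 kb.
Truth CDR lengths follow 0.3 x array length plus Gaussian noise (sd
10 kb), clamped to [1 kb, 0.9 x array]; methylation tracks draw
Gaussian per-CpG fractions (background mean 0.9, sd 0.05) overridden
inside truth CDRs and spacer pockets (mean 0.1), clamped to [0, 1],
with Poisson coverage. Inversions arise as a Poisson process along the
tree (events proportional to branch length); a configured fraction is
recurrent and receives a second branch that is clade-disjoint from the
first *and* whose clade union is not itself a clade -- otherwise two
gains would be indistinguishable from one ancestral gain and truth
recurrence would not be identifiable.

One seed governs everything; sub-generators derive child seeds by fixed
offsets so adding a feature class does not perturb the draws of
another, and identical (config, seed) gives byte-identical FASTA/BED/
track outputs.

What the generator does **not** emulate: indel or transposable-element
evolution, read-level error, HOR monomer substructure and
suprachromosomal families, assembly collapse artefacts, and diploid
phasing beyond two independently drawn haplotypes. Passing round-trip
tests therefore demonstrates the correctness of the interval logic,
the callers and the statistics under the stated generative model -- not
robustness to the full noise structure of real assemblies. No
distributional choice here is a claim about ape biology; where the
published text states a quantity (mixture means, thresholds, spacer
scales) the default mirrors it, and everything else is a documented
fixture.

## Problem sizes and numerical choices

The validation suites run on deliberately compact genomes: 4--7 Mb
chromosomes, two per haplotype, with feature sizes scaled to preserve
the ratios that matter (arrays an order of magnitude above the merge
gap, spacers an order of magnitude above the CDR window). These sizes
were chosen so the full test suite and the acceptance script each
complete in well under the time a reviewer would tolerate while keeping
every length hierarchy of the full-scale problem intact. Other
numerical choices: half-up rounding at printed precision for all
reported summaries; integer arithmetic in count ratios until the final
division; mode ties toward the smaller bin; fold ratios as max/min;
R&sup2; defined as 0 for a constant response; empirical P with the +1
correction.

## Known limitations

* The largest-array centromere rule can misidentify the active array on
  real chromosomes with multiple comparable HOR arrays.
* Spacer detection requires tract-level annotations; unannotated
  satellite would read as spacer sequence.
* The CDR caller's median baseline needs the dip to occupy well under
  half the array; chromosome-wide hypomethylation yields no calls by
  design.
* Copy numbers from span division inherit any assembly collapse in the
  rDNA array; read-depth corroboration is out of scope.
* Branch assignment assumes the derived-inversion polarity; characters
  present in every species are unassignable and flagged recurrent.
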