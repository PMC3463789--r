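---
title: "Declaring recombinant inbred lines distributable: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declaring recombinant inbred lines distributable: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccstatus)
```

## The problem

The Collaborative Cross (CC) is a panel of recombinant inbred mouse lines
bred from eight inbred founder strains (denoted A through H: A/J,
C57BL/6J, 129S1/SvImJ, NOD/ShiLtJ, NZO/H1LtJ, CAST/EiJ, PWK/PhJ,
WSB/EiJ).  Each line starts from a three-generation *funnel* that combines
all eight genomes into one outbred individual and is then driven toward
homozygosity by brother--sister mating.  A line is released to the
community once its genome is sufficiently fixed: at $\ge 90\%$
homozygosity it is *distributable*, at $\ge 98\%$ it is *complete* (both
boundaries inclusive).  `ccstatus` implements the computational pipeline
behind that decision:

1. **Obligate ancestors.**  From the line's pedigree, find the mating
   pairs through which *all* ancestry of every extant (living,
   distributable) animal must pass.  Formally, a pair (sire, dam)
   qualifies when every extant animal descends from both members and
   deleting the pair's offspring disconnects the extant animals from the
   funnel founders (a vertex cut in the ancestry DAG).  The most recent
   such pair bounds everything that can still segregate: its four
   autosomal haplotypes (three X haplotypes -- the dam's two plus the
   sire's one) are the only genetic material the extant animals can carry.
   Funnel founders are excluded: they are ancestors of everything by
   construction and carry no information about residual heterozygosity.
2. **Haplotype reconstruction.**  Genotype the obligate ancestor pair on a
   genome-wide biallelic SNP panel and reconstruct each genome as a mosaic
   of the eight founder haplotypes with a hidden Markov model (below).
3. **Segregating regions.**  Merge the two mosaics into regions fixed for
   one founder letter versus regions where two or more founders still
   segregate, refine the boundaries with the raw genotype calls, and
   optionally reclassify "consistently inconsistent" regions as fixed.
4. **Classification.**  Maximum residual heterozygosity is the summed
   length of segregating regions divided by the full tracked genome length
   (19 autosomes + X, NCBI m37 Mb coordinates; chromosome Y and the
   mitochondrial genome are not tracked for lack of informative markers).
   The line haplotype file and the status report follow.

Because several generations usually separate the obligate ancestors from
the animals a researcher receives, this estimate *over*states
heterozygosity -- distributed mice are more inbred than advertised.  The
package's simulator makes that property testable (see the upper-bound
property below).

## The diplotype hidden Markov model

The source pipeline defers its reconstruction method to prior work, so the
HMM here is this package's own design, chosen to be conventional for
multiparental populations.

**States.**  Autosomes and the female X are decoded over the 36 unordered
founder pairs (8 homozygous + 28 heterozygous diplotypes); the male X over
the 8 haploid founder states.

**Emissions.**  Each founder pair implies a genotype at each marker (the
sum of the two founder alleles).  Observed calls are modelled with an
independent per-allele miscall rate $\varepsilon$ (default 0.002), so for
example $P(\mathrm{AA}\mid\mathrm{AA}) = (1-\varepsilon)^2$ and a
homozygous call under a heterozygous state has probability
$\varepsilon(1-\varepsilon)$.  Missing calls emit probability 1, as do
states involving a founder with no allele call at the marker.  On the male
X a heterozygous call is treated as missing (hemizygous DNA cannot produce
one except by error).

**Transitions.**  Between adjacent markers separated by $d$ Mb each
haplotype switches founder with probability $q = 1 - e^{-rd}$, landing on
any specific other founder with probability $q/7$; the per-haplotype
switch rate is $r$ per Mb (default 0.005, i.e. roughly 0.5 cM/Mb -- tens
of accumulated recombinations genome-wide after funnel plus inbreeding
generations).  The cost of moving between unordered states charges the
minimal number of haplotype switches (0, 1 or 2).  This ignores the
two-fold matching multiplicity of a double switch between disjoint pairs,
a standard and harmless simplification under maximum a posteriori
decoding.

**Decoding.**  Viterbi (single best path), with ties broken toward the
lexicographically smaller state so that decoding is fully deterministic.
Whether the original pipeline used Viterbi or posterior decoding is not
documented; Viterbi was chosen for determinism and because segment
boundaries are subsequently re-estimated anyway.  The test suite verifies
Viterbi optimality and the tie-break rule against exhaustive enumeration
of all state paths on small instances.

**Breakpoints.**  A boundary between two decoded segments is ambiguous
between the last marker informative for the flanking state pair on the
left and the first one on the right; the recombination breakpoint is
placed at the arithmetic midpoint of those two positions.  An ambiguous
interval that runs off a chromosome end puts the boundary at the end.
First and last segments are extended to 0 and the configured chromosome
length, so segments tile each chromosome exactly.  Coordinates are Mb
floats, 0-based, half-open `[start, end)`.

## Segregating regions and their boundaries

Three rules, in order:

* **Within an ancestor**: every heterozygous-state segment becomes a
  candidate region whose boundaries are tightened to the outermost
  heterozygous genotype calls inside it.  A heterozygous segment with no
  heterozygous call at all is dropped with a warning (reconstruction and
  genotypes disagree).
* **Between ancestors**: the mosaics are overlaid and any interval whose
  pooled haplotypes (4 autosomal, 3 on X) carry $\ge 2$ distinct founders
  becomes a region; boundaries are snapped *outward* to the nearest
  informative marker flanking the discordance.  Outward snapping is this
  package's resolution of "nearest": mosaic boundaries sit at midpoints
  between informative markers, so the nearest marker is equidistant on
  both sides, and the outward choice keeps the estimate an upper bound.
  Note that this contract makes the between pass subsume within-ancestor
  heterozygosity; the two passes are still computed separately and
  unioned (founder sets merged), so the wider between-pass boundaries
  dominate and the reported quantity remains the *maximum* residual
  heterozygosity.
* **Fixed override**: when the observed calls disagree with the
  founder-table prediction of the assigned haplotype *identically in
  every genotyped ancestor* at $k$ or more consecutive informative
  markers, the discordance is taken to be a private variant of the line
  rather than residual segregation, and the region is treated as fixed.
  "Consistently inconsistent" is not quantified in the source; the
  default $k = 3$ was chosen because at $\varepsilon \approx 0.002$ the
  probability of two identical coordinated miscalls across both ancestors
  at even two adjacent markers is already negligible, but $k = 2$ would
  make single bad markers on small panels borderline.  Because
  intensity-based founder assignment is out of scope, the comparison
  baseline is the founder-table prediction, not array intensities.  An
  overridden region enters the line haplotype file as fixed with the
  lexicographically smallest founder of its set as representative (no
  founder matches the calls exactly there).

Residual heterozygosity divides the unioned segregating length by the
configured genome length (default: the full m37 autosome + X lengths,
2,638.9 Mb).  Whether the original denominator was assembly length or
marker-spanned length is not documented; both are available
(`denominator = "chrom_lengths"` or `"marker_span"` in `run_config()`),
with the assembly length as default since the reported percentages refer
to the genome, not the panel.

## The funnel simulator

`simulate_funnel()` is the package's test harness: G1 four pairwise
founder crosses, G2 two four-way crosses, one eight-way cross producing a
sibship of two, then `n_sib_generations` brother--sister matings (one
breeding pair, sibship of two, per generation; a two-arm option splits
the line to exercise the obligate-ancestor logic).  Meioses place
crossovers as a Poisson process with no interference at a uniform
`recomb_rate_per_mb` (default 0.005/Mb $\approx$ 0.5 cM/Mb; the source
gives no genetic map).  The X follows sex-specific transmission: sires
pass their X intact to daughters and nothing to sons.  Genotypes add
independent per-allele miscalls (`genotyping_error`, default 0.002,
matching the HMM default) and no-calls (`missing_rate`, default 0.02, a
typical array no-call rate; the source states none).  The marker panel is
evenly spaced (default 0.35 Mb, giving a MUGA-scale ~7,500-marker panel)
with founder alleles drawn so every marker splits the founders into two
non-empty groups.  All randomness derives from one seed;
identical seeds give bit-identical output.

What the simulator does *not* emulate: real sibship sizes and overlapping
generations, marker-assisted mate selection, crossover interference and
map heterogeneity, intensity-level array artifacts, and linkage between
panel informativeness and local founder divergence.  A green test
therefore establishes correctness of the algorithms under the stated
breeding design and noise model, not fidelity to any particular real
line.

A useful closed-form oracle: under sib mating the per-locus
heterozygosity obeys $H_t = H_{t-1}/2 + H_{t-2}/4$, with $H_0 = 1$ at the
eight-way F1 sibship (its parents carry disjoint founder quartets) and
$H_1 = 3/4$; the asymptotic per-generation ratio is $(1+\sqrt 5)/4
\approx 0.809$.  The simulator's autosomal decay matches this recurrence
within Monte-Carlo error in the acceptance suite.

## Numerical choices and degenerate inputs

* Interval arithmetic is half-open in Mb; unions, complements and tilings
  run through one internal helper set, and the line genome always tiles
  each chromosome exactly (fixed + segregating = genome length).
* Viterbi ties and final-state ties both resolve to the smallest state in
  lexicographic order; `max.col(ties.method = "first")` over states listed
  in that order implements it.
* A chromosome with no usable call yields a single `no_data` segment; with
  one usable marker the decode proceeds but the chromosome is flagged
  `low_confidence`.
* Breakpoints are forced monotone per chromosome (`cummax`); zero-length
  segments arising from clamping are dropped and same-state neighbours
  re-merged.
* Marker tables are re-sorted internally, so results are invariant to the
  row order of input files.
* If the flanking informative marker for a region boundary lies inside an
  adjacent region, the merge step unions the two regions (equivalent to
  clipping at the shared edge, but with founder sets pooled).

## Known limitations

* At MUGA density (0.35 Mb spacing) a random biallelic panel contains
  chance runs of markers at which a given founder pair carries identical
  alleles; very short true segments inside such runs are merged away, and
  genome recovery on noiseless data measures ~98.6--99.1% per animal.
  With a 0.1 Mb panel (MegaMUGA-like) recovery exceeds 99.5%.  This is
  the "limits of detection" caveat of the source platform, reproduced
  rather than hidden.
* Residual heterozygosity is an upper bound by construction (outward
  snapping, ancestor--extant generation gap); it is not a point estimate
  of any individual animal's heterozygosity.
* The obligate-ancestor definition requires a full mating pair; a single
  cut individual without its mate does not qualify, because classification
  needs the pair's four bounding haplotypes.
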