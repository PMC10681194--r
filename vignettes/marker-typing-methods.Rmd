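---
title: "Marker-based host-strain typing of fall armyworm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based host-strain typing of fall armyworm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fawtyper)
```

## The biological problem

The fall armyworm (*Spodoptera frugiperda*, FAW) comprises two host strains
— the C-strain, associated with corn and sorghum, and the R-strain,
associated with rice and pasture grasses — that are morphologically
indistinguishable and are told apart with molecular markers. Two marker
systems dominate field studies:

* **COIB**, the 3' half of the mitochondrial *COI* gene (amplified with
  primers c891F/c1472R). Two polymorphic sites, **mCOI1164D** (observed
  states A/G/T) and **mCOI1287R** (A/G), jointly define the h-haplotype
  categories: T1164/A1287 is the R-strain marker (**R_COIB**), while
  A/A (**CSh1**), A/G (**CSh2**), G/A (**CSh3**) and G/G (**CSh4**) are the
  C-strain categories, collectively C_COIB. Within each CSh category,
  additional polymorphisms across the segment define lettered variants
  (CSh2[e] and so on). Because the frequencies of CSh1–CSh4 differ
  reproducibly between overwintering regions, the category profile of a
  collection acts as a population fingerprint. COIB is maternally
  inherited, so only females move it between populations.

* **Tpi**, a Z-linked gene. The exon-4 site **gTpi183Y** is the strain
  diagnostic: C marks the C-strain (C_Tpi), T the R-strain (R_Tpi). Two
  flanking sites, gTpi165Y and gTpi168Y, show the same bias and serve as
  consistency checks. Male FAW carry two Z chromosomes, so a directly
  sequenced Tpi amplicon superimposes two alleles: a heterozygous position
  appears as overlapping chromatogram peaks and is base-called as an IUPAC
  ambiguity letter. A C/T overlap (Y) at gTpi183Y identifies an
  inter-strain hybrid (**H_Tpi**). The intron immediately downstream
  (TpiI4) is hypervariable with frequent indels; its first ~60%
  (**TpiI4a200**, ~200 bp) is dereplicated into iC haplotypes (iC01, iC02,
  …) and used as a second, biparentally inherited population fingerprint.

`fawtyper` implements this typing scheme as a tested pipeline: sequence
I/O, alignment and site calling, the two classification rules, variant and
intron-haplotype dereplication, population frequency profiles with a
permutation G-test, p-distance matrices with Neighbor-Joining trees, and a
synthetic-data generator that emulates the diploid-Z sequencing process so
that every stage can be validated against a planted truth.

## Alignment and site calling

The original workflow aligned traces interactively; here a deterministic
global (Needleman–Wunsch/Gotoh) aligner maps each read onto an annotated
reference amplicon.

* **Scoring** (defaults, configurable via `align_scoring()`): match +1,
  mismatch −1, gap open −2, gap extend −0.5; a gap run of length $k$ costs
  $-2 - 0.5k$. These are conventional values for high-identity Sanger
  amplicons, where the biological edit distance is small and gaps are rare.
* **IUPAC semantics.** A letter scores as a match whenever its state set
  intersects the other letter's set, so a heterozygous read aligns at full
  score; `N` carries the full state set for alignment but always yields an
  `ambiguous` site call. This is deliberately conservative: ambiguity never
  creates a mismatch penalty that could push the aligner into spurious
  gaps.
* **Tie-breaking.** Equal-scoring traceback moves are resolved in the fixed
  order diagonal → gap-in-read → gap-in-ref, making alignments, and
  everything downstream of them, reproducible. One consequence worth
  knowing: when a truncated read's last bases happen to match the reference
  tail, the diagonal preference will align them there rather than extend a
  trailing gap — ties are broken, not avoided.
* **Orientation** is decided by aligning the read and its reverse
  complement and keeping the strictly better score (ties go to forward).
* **Coordinates.** Marker positions are explicit annotations interpreted
  through a per-reference `coordinate_offset` (COIB uses gene-level
  numbering, offset 891; Tpi uses the amplicon's own 1-based columns).
  The historical site names for the two genes do not share a coordinate
  convention, so positions are never derived arithmetically from primer
  names. All coordinates are 1-based and fully closed.

The DP score is verified against an exhaustive enumeration of all
alignments for short sequence pairs — an oracle that is independent of the
implementation — in the test suite and the acceptance script.

## Classification rules

**COIB.** The category is a lookup of the unambiguous two-site pair in the
defining table. Unambiguous pairs outside the table are reported as
`unknown_combo` rather than rejected, since the defining sites are
empirical observations, not a closed system. Any IUPAC or gapped site call
yields `ambiguous`; a site not covered by the read yields `no_call`.
CSh3 is retained as a first-class category despite its rarity.

**Variant dereplication** compares the read's sequence over a comparison
span — by default the full inter-primer interval, since variant-defining
polymorphisms occur across the segment — by exact match against a registry.
A novel sequence in a CSh category mints the next unused letter for that
category in discovery order; letters already present in a loaded registry
are skipped, so canonical labels survive when a published registry is used.
Minting is order-dependent by construction; the stable-label workflow is to
load a canonical registry first.

**Tpi.** The strain call is a function of the gTpi183Y state set alone:
{C} → C_Tpi, {T} → R_Tpi, {C,T} → H_Tpi, anything else → `undetermined`.
gTpi165Y/gTpi168Y are compared with the strain-expected states and
disagreements are flagged, but they never override the 183-based call.

**TpiI4a200.** The analysis window is the first
`round(0.6 × intron_length)` columns of the intron. The 60% fraction is
the field's published rule; the exact rounding is not, so
round-to-nearest is used and the fraction is exposed as a parameter. The
extracted segment includes read insertions strictly inside the window;
insertions abutting the right window edge are excluded (half-open
behaviour at the boundary), because an insertion there cannot be assigned
to the window or its flank without arbitrariness. A specimen is excluded
as `incomplete-coverage` when the read does not span the window, or
`ambiguous-base` when any non-A/C/G/T letter occurs in the segment — the
signature of intron heterozygosity. H_Tpi specimens are never
intron-haplotyped even when their window is clean
(`strain-mismatch-policy`): they are heterozygous by construction, and
their lone clean window would be an allele mixture artifact. This mirrors
the single-exception treatment of heterozygotes in the originating
workflow. Usable segments are dereplicated exactly like COIB variants,
with labels iC01, iC02, … minted at the next unused index.

## Population profiles and the G-test

Profiles tally per-category counts by population (optionally year and
habitat); ambiguous and no-call specimens are tracked in `n_excluded` and
never enter the frequencies, which therefore sum to 1 for any non-empty
profile.

Field studies typically compare such profiles descriptively. This package
adds a formal test as its own methodological choice: a 2 × k log-likelihood
ratio statistic $G = 2\sum O \ln(O/E)$ whose null distribution is obtained
by permutation — specimens are reshuffled between the two populations with
both margins fixed, realized by sampling contingency tables with
Patefield's algorithm (`stats::r2dtable`), and the p value is
$(1 + \#\{G^* \ge G\})/(R + 1)$ with $R$ = 10,000 replicates by default,
seeded. Permutation is preferred to the asymptotic χ² (also reported)
because haplotype tables routinely contain near-empty categories.
Categories absent from both populations are dropped; $O = 0$ terms
contribute zero. Pairwise comparisons across several populations are
reported with Holm-adjusted p values alongside raw ones — conservative and
free of independence assumptions. The test's type-I error at α = 0.05 is
checked by simulation (200 null comparisons of two 10,000-specimen
multinomial samples) in the acceptance suite.

## Distances and Neighbor-Joining

Haplotype sets are jointly aligned by a star alignment around the first
sequence ("once a gap, always a gap"), adequate for sets that are small
edits of a common segment, and compared by **p-distance** — mismatches over
compared columns, with pairwise deletion of columns where either sequence
has a gap or ambiguity. The distance model behind the published haplotype
trees is not stated beyond "Neighbor-Joining", so p-distance is the
default and the matrix can be supplied from any other model.

NJ is implemented directly (Q-criterion agglomeration with the
Studier–Keppler update) because the haplotype tree is part of the analysis
this package provides, not an accessory: ties in the Q matrix are broken
by the lowest pair of node indices so output is deterministic, negative
branch lengths are reported as computed (with an optional clamp), and the
serialized Newick prints 6-decimal lengths while the in-memory tree keeps
full precision. `ape::nj` serves as an independent cross-check in the test
suite, and NJ's consistency on additive matrices — exact recovery of
topology and branch lengths from distances generated off random trees —
is exercised as an oracle-backed property.

## The synthetic-data generator

`simulate_study()` generates populations of specimens with COIB and Tpi
reads, metadata and a truth table. What it emulates:

* **Maternal COIB**: one allele per specimen, drawn from a per-population
  category profile (conditioned on the maternal strain: R-strain mothers
  carry R_COIB) and a per-category variant profile.
* **Diploid-Z Tpi**: two alleles per specimen. With probability
  `hybrid_rate` the pair is inter-strain (one C, one R allele); otherwise
  both alleles share the maternal strain and differ (heterozygous) with
  probability `heterozygosity`, the difference involving an indel with
  probability `indel_het_fraction`. Strain linkage between COIB and the Z
  alleles is broken only by hybrids, which is how mito-nuclear discordance
  arises in the field.
* **The double-trace read**: identical alleles pass through; equal-length
  pairs merge positionwise, substitution differences becoming IUPAC
  overlap letters; unequal-length pairs merge cleanly up to the first
  indel difference and are `N` from there on — a frame-shifted double
  trace is unreadable, and modelling it as all-ambiguous is the
  conservative rendering of that fact.
* **Variant pools** are built per category around the bundled reference:
  defining-site states fixed, random substitutions (and for Tpi, 1–3 bp
  indels) confined to the segment interior so that every planted variant
  remains classifiable and its window segment carries all its variation.
  The two Tpi strains additionally differ at a fixed intron position, as
  distinct lineages do, so C and R intron haplotypes can never collide.

Default rates are fixed study conditions, not tuning knobs: heterozygosity
0.5 (roughly half of directly sequenced specimens yield unambiguous intron
data in field practice), hybrid rate 0.1, indel share of heterozygous
pairs 0.5 (indels are described as frequent in this intron), sequencing
noise 0 — no quantitative Sanger error model is published for this
workflow, so noise is off by default and exposed as `noise_rate`. The
bundled Tpi reference uses a 333-bp synthetic intron, giving a 200-column
window at the 60% rule; it is a stand-in with the published site
annotations, not a GenBank-derived sequence, and is labelled as such in
its provenance field.

Reproducibility: a study derives every draw from one master seed;
per-specimen streams are derived by a (population, counter) scheme, so
extending a study with another population leaves earlier populations'
reads byte-identical.

What the generator does **not** emulate: chromatogram signal intensities
and base-quality (reads are error-free unless `noise_rate` is raised),
primer artifacts, within-strain exon variation at the three diagnostic
sites, and population-genetic dynamics (drift, migration, inbreeding).
Passing the round-trip checks therefore demonstrates that the
classification logic is faithful to its rules — not that those rules are
robust to noisy or degraded field sequences.

## Problem sizes used in the checks

The package's own validation uses: a three-population study of 500
specimens per population (zero noise, heterozygosity 0.5, hybrid rate 0.1)
for the classification round trip; five seeds of the same design for
frequency recovery at the 3-sigma-per-category level (with the ~1%
expected chance-failure rate of 3σ checks budgeted for: at most 2 of the
75 checks may fall outside); single populations of 1,000 specimens at
hybrid rates 0.05 and 0.2 for H_Tpi rate recovery within the 99% binomial
CI; 200 random pairs of length ≤ 6 for the alignment oracle; 50 random
additive matrices (4–8 leaves) for NJ recovery at 1e-9; and 200 null
comparisons for G-test calibration. These sizes were chosen so the full
validation completes in a few minutes on a single core while keeping the
binomial checks meaningfully tight.

## Degenerate inputs and edge behaviour

* Empty profiles (no classifiable specimens) carry a zero total and no
  frequencies; comparisons with fewer than two non-empty categories are
  flagged `computable = FALSE` rather than erroring.
* A sequence pair with no comparable columns is an error naming the pair —
  a p-distance of convenience would silently distort the tree.
* Registries reject duplicate labels and duplicate sequences; lookups are
  exact-match over the defined span, never fuzzy.
* References validate that annotated sites fall inside the amplicon and
  warn (recording the warning on the object) when the intron boundary does
  not start with the canonical `GT` splice donor.
* The variant-letter pool extends a–z, aa, ab, … and minting skips letters
  present in a loaded registry, so canonical letter gaps are preserved
  rather than silently reassigned.

## Known limitations

* No chromatogram (AB1) parsing or base calling: input is the IUPAC
  consensus the operator exported.
* No phasing: the two Z alleles of a heterozygote are not reconstructed;
  heterozygotes are excluded from intron haplotyping by design.
* Novel-variant labels depend on discovery order when no canonical
  registry is loaded.
* The star joint alignment is adequate for near-identical haplotype sets;
  divergent sets would warrant a full progressive MSA before p-distances.
* The G-test formalization and its permutation scheme are this package's
  additions to a descriptive comparison practice; they are calibrated by
  simulation here but are not part of the original field protocol.
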