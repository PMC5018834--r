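---
title: "Models and methods behind h2aglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind h2aglyco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2aglyco)
```

h2aglyco covers three computational arms of an H2A Ser40 O-GlcNAcylation
analysis: glycopeptide mass spectrometry, a cross-species survey of
canonical H2A isoforms, and ChIP-seq peak annotation. This vignette explains
the models each arm assumes, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices that were
genuinely open.

## Mass arithmetic and the labile-glycan model

All mass computation is monoisotopic. The residue table holds the 20
standard amino-acid residue masses; water (18.010565 Da) is added once per
peptide, the proton (1.007276 Da) is the charge carrier, and one O-HexNAc
adds 203.079373 Da. Average masses are deliberately unsupported: the
printed precursor values for the G37–K74 peptide (m/z 1327.02 and 1394.72
at z = 3) are reproduced by monoisotopic arithmetic only.

Histone coordinates are used throughout: position 1 is the residue after
the cleaved initiator Met, so the serine of interest is position 40 and the
Lys-C peptide of the reference H2A spans residues 37–74. Lys-C
(Achromobacter protease I) cleaves C-terminal to every lysine *including*
Lys-Pro bonds — this differs from trypsin and is what produces the
38-residue G37–K74 peptide. Missed cleavages default to 0 and are
configurable.

Fragment enumeration follows the standard HCD conventions: b ions are
prefix sums, y ions suffix sums plus water, and internal by ions (double
backbone cleavage) are modelled as b-type — residue sum plus one proton, no
water — which matches the y∧b intersection notation (y33-b15 … y33-b20)
used for this peptide. Because O-glycosidic bonds are labile under HCD,
fragments are generated with the HexNAc *lost* by default while the
precursor retains it; the intact-glycan ladder sits behind
`glycan_retained = TRUE`. The HexNAc oxocarbenium reporter (m/z 204.0866)
is available behind `include_oxonium` as an optional diagnostic but plays
no role in localization.

### Matching and localization

`match_spectrum()` is a transparent tolerance matcher, not a search engine:
each theoretical ion is matched to the nearest peak within a ppm tolerance,
with no probabilistic score and no decoy FDR. The default tolerance is
10 ppm, a Q-Exactive-class accuracy; no instrument tolerance is normative
here, so the default is a documented choice, not a claim about any original
search configuration. In tests that match spectra simulated with 5 ppm
Gaussian jitter, matching is done at 15 ppm (3 standard deviations), the
window a practitioner would open for that error model; at exactly 2
standard deviations a ~4.5% miss rate is expected by construction.

Localization uses presence/absence logic on backbone y ions: a y ion of
index $j$ observed in the modified but not the unmodified spectrum confines
the modification to peptide-local positions $1..(n-j)$, because the sugar
must be N-terminal of the ion's first residue for the ion itself to appear
glycan-free and cleavage-enhanced. The largest such $j$ gives the tightest
window; Ser/Thr residues inside it (in protein coordinates) are the
candidates, and a unique candidate becomes the call. For G37–K74,
modification-specific y33 gives the window 37–41 whose only Ser/Thr is
Ser40. With no modification-specific ions the window is the whole peptide
and the call is ambiguous (candidates Ser40 and Thr59).

## The isoform survey

"Position 40" is only meaningful relative to a reference, so every query
sequence is globally aligned (BLOSUM62, gap open 10, gap extend 1, end gaps
penalized) to a packaged reference and the query residue aligned to
reference position 40 is classified: S → SER40, A → ALA40, anything else →
OTHER, no reliable anchor → UNALIGNED. Canonical H2A isoforms are >90%
identical, so the result is insensitive to reasonable alignment parameters;
a 40% identity floor guards against anchoring non-histone input (shuffled
or poly-G sequences fall far below it). The three-residue context around
the anchor is reported so the Y-S-E epitope window is directly checkable.

The packaged reference and species records are *synthetic* constructions:
canonical-H2A scaffolds carrying the documented position-40 residues (a
Ser40 H2A3-like and an Ala40 H2A1A-like mouse pair, and a wallaby-like
family with a 3/5 Ser40 ratio). They are not database downloads, and the
package makes no claim about the exact isoform counts of any genome
assembly; real surveys should read their own FASTA, which
`summarize_species()` accepts unchanged. The G37–K74 Lys-C peptide of the
reference is exactly the peptide whose printed precursor m/z values the
mass arm reproduces, which cross-validates the scaffold where it matters.

Trees are built by neighbor joining on p-distances (mismatches over
comparable columns; gap and X columns dropped) computed on a star multiple
alignment against the reference. NJ was chosen over likelihood methods
because it is deterministic, exact on additive matrices, and independently
checkable — the test suite compares topologies against ape's implementation
and against the generating trees of random additive matrices. Q-matrix ties
are broken by the lexicographically smallest pair of cluster labels and
negative branch lengths are clamped to zero, so identical inputs always
give identical trees. The isoform-type clustering score is $B/W$ — mean
cophenetic distance between categories over mean distance within — with
score $>1$ indicating type-dependent clustering; it is undefined (NA) when
a category has fewer than two leaves, and exactly 1 on a star tree.

## Peak annotation

Peaks are categorized by their midpoint: TSS if the midpoint is within
±2 kb of any strand-aware TSS, else gene body (GB) if inside any gene span,
else intergenic. The midpoint was chosen over summits (not present in plain
BED) or any-overlap rules because it is deterministic, order-free, and
makes the three categories a true partition; TSS priority over GB mirrors a
mutually exclusive category scheme. All genes qualifying at the winning
priority level are reported — no arbitrary single-owner selection. These
are documented choices, not claims about how any original analysis resolved
the same ambiguities.

Internally every interval is a `GRanges` (1-based, closed), with BED's
0-based half-open and GFF3's 1-based inclusive conventions converted at the
I/O boundary by rtracklayer. Exon/intron fractions are computed among peaks
whose midpoint is inside a gene span (including TSS-category peaks that
overlap a gene); a "target gene" is any gene owning a TSS- or GB-assigned
peak, a definition recorded in the annotate report's metadata.

Expression association uses a one-sided Wilcoxon rank-sum test (targets
greater), normal approximation with tie correction — adequate at the group
sizes involved and free of distributional assumptions about log-ratios. The
target group is compared against the non-target remainder of the
background, which keeps the two samples disjoint and the null p-value
uniform. A completely tied input (zero variance) returns p = 0.5 by
convention rather than NaN.

## The synthetic generators

Each generator takes an integer seed, restores the caller's RNG state, and
returns machine-readable ground truth, so every pipeline stage can be
scored without re-deriving the truth.

**Spectra.** `sim_spectrum()` emits the labile-loss ladder with Gaussian
m/z jitter (default σ = 5 ppm), independent per-ion dropout, and uniform
noise peaks (default 100) over the observed m/z range; intensities are
log-normal. It does not emulate isotope envelopes, charge-state intensity
physics, or co-eluting peptides — passing tests show the matcher and
localizer tolerate calibrated jitter and random noise, not that they would
survive chimeric spectra.

**Isoform families.** `sim_isoform_family()` evolves gene copies along a
random ultrametric species tree: Poisson duplications at branch starts,
independent per-branch survival against the loss rate, and per-site
substitutions at rate × branch length, with site 40 scaled by a multiplier
(default 0: the site-40 state is inherited, never re-invented). One root
copy carries Ala40; a planted basal duplicate carries Ser40, so with the
multiplier at 0 the SER40 leaves are exactly the planted lineage's
descendants — the bookkeeping is the oracle. Total loss of the family
returns an explicit extinct result. Default rates (duplication 0.3, loss
0.1, substitution 0.02 per site per tree depth, 6 species) produce families
of roughly 8–20 near-identical copies, the regime of canonical histone
clusters; the simulator does not model gene conversion or concerted
evolution, both of which homogenize real histone repeats.

**Genomes and peaks.** `sim_genome_and_peaks()` places non-overlapping
genes (6–12 kb, 3–6 exons, both strands) with inter-gene gaps wide enough
that a ±2 kb TSS window never reaches a neighbouring gene, then draws each
peak's category from the planted fractions — defaults 30% TSS / 55% GB /
15% intergenic, a gene-body-dominated profile — and places its midpoint
uniformly in the chosen region type. TSS-planted midpoints go in the
upstream, gene-external half of the window so that the planted exon/intron
truth (GB peaks exonic with probability `exon_fraction`, default 0.5)
stays unambiguous. Peak widths are log-normal with median 500 bp —
arbitrary but fixed — and the category truth is defined by the midpoint,
consistent with the annotator. Acceptance-style checks run 20 genomes of
2000 peaks each, which puts the binomial standard error near 0.011 and the
±0.03/±0.04 recovery bands at roughly 3 standard errors.

**Expression.** `sim_expression()` draws background values Normal(0, σ)
and targets Normal(δ, σ). The calibration tests use 1000 null replicates
(α = 0.05 band ±0.02) and 100 shifted replicates at δ = 1, σ = 1,
n_target = 200 against 2000 background genes, where the rank-sum power is
essentially 1. No array-normalization artefacts, batch effects, or
correlated genes are simulated.

## Degenerate inputs and numerical conventions

m/z values are kept at full double precision internally and compared to
printed values at 2 decimals; peptide masses are deterministic to 1e-6 Da.
Empty peak sets are rejected with an explicit message; an exon/intron
fraction with no genic peaks returns NA rather than 0; an extinct simulated
family is a result, not an error; `pair_precursors()` on empty input
returns an empty table. MGF parsing reports the offending line or block on
malformed input.

## Limitations

The mass arm performs no search-engine scoring, decoy FDR, isotope
deconvolution, or vendor-format reading. The survey arm does no
maximum-likelihood phylogenetics and does not fetch sequences at runtime.
The annotation arm starts from called peaks — read alignment, peak calling
and duplicate filtering are upstream of this package — and the synthetic
data are simplifications in the specific ways noted above.
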