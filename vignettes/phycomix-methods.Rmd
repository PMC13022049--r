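---
title: "Identifying phycobiliprotein complexes in native mass spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying phycobiliprotein complexes in native mass spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycomix)
```

## The problem

Cyanobacterial light harvesting rests on two highly conserved
phycobiliproteins: phycocyanin (PC), which builds the rods of the
phycobilisome, and allophycocyanin (APC), which builds its core. Both
assemble from an αβ dimer of two ~17–20 kDa chains into a ring-shaped
(αβ)₃ hexamer of roughly 100–120 kDa. When extracts from two
cyanobacterial strains are mixed, hexamers re-equilibrate within minutes
and heterologous complexes appear — hexamers whose three dimer units come
from different strains. Native mass spectrometry can resolve these species
because strain-level sequence differences shift each dimer's mass by tens
to hundreds of daltons, and an intact hexamer's neutral mass is simply the
sum of its subunit proteoform masses.

`phycomix` implements the full inference chain for this experiment:
theoretical proteoform masses from sequence, combinatorial enumeration of
candidate complex compositions, charge-state deconvolution of the spectra,
candidate matching under a percent-mass-error criterion, abundance
quantification, and — on the structural side — conservation scoring of the
residues at the dimer–dimer contact interfaces that make such promiscuous
assembly possible. A synthetic-data module generates diverged strain
sequence sets and Orbitrap-like spectra with known ground truth, so every
stage is testable without instrument data.

## Proteoform masses

Subunit masses are computed as the sum of average (not monoisotopic)
residue masses plus one water. At the resolving powers typical of native
MS of ~100 kDa complexes (several thousand at the relevant m/z), isotope
structure is unresolved and the average-mass envelope is the observed
quantity.

Post-translational modifications follow a fixed rule table per family and
chain:

| family | chain | chromophores | initiator Met | methylation |
|---|---|---|---|---|
| APC | alpha | 1 | always lost | 0 |
| APC | beta  | 1 | retained | 1 |
| PC  | alpha | 1 | retained | 0 |
| PC  | beta  | 2 | 0 or 1 losses | 1 |

Each phycocyanobilin chromophore adds 586.7 Da (average mass of the bilin
after thioether attachment to a cysteine), initiator-methionine loss
removes 131.2 Da, and N4-methylation of the conserved β-subunit asparagine
adds 14 Da. The variable Met loss on the PC β chain means every PC complex
has a ladder of proteoforms spaced 131.2 Da apart (up to four distinct
masses for a hexamer, from 0 to 3 losses across its three β chains). All
modification masses live in a single `mass_constants()` object and can be
overridden from JSON; in particular the methylation mass is kept at the
conventionally printed +14 Da rather than the exact CH₂ mass (+14.0157),
a 0.05 ppm effect at hexamer scale.

`alphaB` (ApcD-type) alternative α chains are accepted by the mass engine
and follow the APC α rule; they are excluded from complex enumeration by
default because the standard hexamer interpretation does not assign them.

## Candidate enumeration

Compositions are multisets of αβ dimer units: for `k` strains and `n`
dimers there are `choose(k + n - 1, n)` single-family compositions (for
two strains and a hexamer: pure A, 2A+1B, 1A+2B, pure B). Complex masses
are exact sums of subunit proteoform masses — association is non-covalent
and adds no mass. Two kinds of decoys are enumerated alongside and flow
through the identical matching path as negative controls, mirroring
species that never form in vitro: hexamers mixing APC and PC dimer units,
and single dimers whose α and β chains come from different strains.
Compositions whose masses collide within the matching tolerance are
retained; disambiguation is the assignment stage's concern.

## Synthetic spectra

The simulator emulates the study conditions: an m/z window of 1000–8000,
resolving power 7500 at m/z 400 decaying as 1/√(m/z) (the usual
Orbitrap behaviour), and positive-mode electrospray of natively folded
complexes. Charge envelopes are discrete Gaussians centred at
z₀ = 0.078·√M — the standard empirical scaling for folded proteins —
with width 1.5 charges; the centre scale is configurable because observed
envelopes of ~110 kDa hexamers sit at charges ~20–26 in the
4500–5500 m/z region. Peaks are Gaussians with FWHM = m/z ÷ R(m/z) and
area proportional to species weight × envelope weight, so with noise off
the integrated spectrum equals the summed normalised weights exactly (a
conservation property the tests exploit). Baseline noise is Gaussian with
a constant offset of three noise SDs, emulating a detector noise floor and
keeping the trace non-negative without distorting the noise statistics.
Rendering is a pure function of (mixture, model, seed).

The strain generator substitutes residues of fixed base chains
independently at a per-site rate (default 0.05), never touching protected
columns (by default position 1, so the initiator methionine required by
the PTM rules survives). The base sequences are explicitly synthetic: they
are not the sequences of any organism, but their lengths (161/161 aa for
APC α/β, 162/172 aa for PC α/β) and chain masses (≈17.3, 17.2, 17.6 and
19.3 kDa) were chosen to match real phycobiliprotein subunits, so that the
APC and PC dimers are ~3 kDa apart as in real extracts and cross-family
decoys are physically rejectable. What the generator does **not** emulate:
insertions/deletions (all strains stay aligned to the base), chromophore
occupancy variation, adduction (ammonium acetate adducts are ignored;
assignments use protonated masses), and ionisation-efficiency differences
between species. Passing recovery tests therefore demonstrate correctness
of the inference chain under these idealisations, not instrument-grade
robustness.

## Deconvolution

`pick_centroids()` finds local maxima above the baseline (trace median)
plus 5 robust noise SDs, refines apexes by log-parabolic interpolation,
and reports **peak areas** (apex height × the Gaussian σ implied by the
half-maximum crossings, using the cleaner flank when a neighbour overlaps
one side). Areas rather than heights matter because peak width grows with
m/z: a dimer peak at m/z 2400 is ~3× narrower than a hexamer peak at
m/z 4800, and height-based intensities would inflate dimer:hexamer ratios
by that factor.

`infer_charge_series()` forms a neutral-mass hypothesis
M = z·(m/z − m_H) for every centroid and charge in the search window
(default 5–40), clusters hypotheses within 50 ppm, and accepts clusters
greedily. Two deliberate choices here:

* **Tolerances are two-tier.** The 50 ppm clustering tolerance is an
  instrument-level precision; the 0.1% (1000 ppm) matching threshold is a
  biological plausibility criterion. Conflating them would make every
  Met-loss variant of every neighbouring composition an equal candidate.
* **Harmonic suppression.** A mass at an integer multiple of a true mass
  is supported by the same centroids at multiplied charges. Genuine
  electrospray envelopes populate *consecutive* charges, so clusters are
  ranked by their longest consecutive charge run before support and
  intensity; harmonic ladders (systematically gapped) lose the ranking and
  their centroids are consumed by the true series first.

In mixtures, peaks of different species collide whenever their mass ratio
approaches a ratio of small integers (e.g. ~0.926 ≈ 25/27); the merged
centroid then carries both species' area and the greedy pass awards it to
one series. `share_collided_peaks()` repairs this: centroids consistent
with more than one series' mass at a plausible charge (within a
peak-width-scale tolerance of 500 ppm — merged apexes shift by up to about
a peak width) are re-apportioned in proportion to each claimant's fitted
charge-envelope prediction. The fit is a robust log-quadratic in z (a
Gaussian envelope), excluding members far below the base peak (remnants of
earlier sharing) or more than 6 charges from it (harmonic satellites,
which would dominate the quadratic fit through leverage). Sharing iterates
twice from the preserved original centroid totals, so second-pass fits are
computed from first-pass repaired envelopes.

`series_intensity()` turns a series into an abundance using the same
robust envelope fit: observed states are kept where consistent with the
fit, while flagged outliers, harmonics and missing states (including
states beyond the observed edge, lost wholesale to collisions) are
integrated from the fitted Gaussian. Series with fewer than four usable
states fall back to the plain sum.

## Matching and quantification

A series matches a candidate when the percent mass error
100·|M_obs − M_theo|/M_theo is at most 0.1. Status is `unique` for exactly
one passing candidate, `ambiguous` for several — and ambiguity is
*surfaced*, never silently resolved: compositions whose theoretical masses
differ by less than the threshold are genuinely indistinguishable at that
criterion, and the report carries ambiguity groups (connected components
of co-matched compositions) with group-summed abundances alongside the
per-composition numbers.

For the per-composition split of an ambiguous series' intensity the
default is proportional to a Gaussian likelihood of each candidate's mass
error at the 50 ppm instrument precision. This is a measurement model, not
a mixing prior: a candidate 600 ppm away (easily under the 0.1% biological
threshold) is still >10 instrument SDs from the observed mass and receives
essentially nothing, while truly mass-degenerate candidates share roughly
equally. An unweighted equal split (`split = "equal"`) is available; it
systematically misallocates intensity whenever Met-loss variants of
neighbouring compositions interleave inside the threshold, which is the
typical situation for PC (ladder spacing ≈ strain dimer delta vs. variant
spacing 131.2 Da).

Relative abundances are percentages of assigned intensity within each
family; the dimer:hexamer ratio is reported per family (undefined, not
infinite, when no hexamer is assigned), and decoy intensity is reported as
a percentage of all assigned intensity. The mixture absorbance model is
the pointwise mean of the two component profiles, with an RMS deviation
against a measured mixture profile when given.

## Interface conservation and structure analysis

Per-column conservation uses mean pairwise identity: 100 × matching pairs
over all pairs of non-gap residues in the column (gaps excluded pairwise,
not listwise). A modal-residue-frequency mode exists for sensitivity
analysis. Similarity replaces the letter match by membership in the same
physicochemical class; the default partition is
{G,A,V,L,I}, {F,Y,W}, {C,M}, {S,T}, {K,R,H}, {D,E,N,Q}, {P}, and any
disjoint cover of the 20 letters can be supplied, since similarity
conventions vary between tools. Identity can never exceed similarity under
any partition (classes only coarsen matching) — a property the tests check
on random alignments. Columns and unaligned positions are 1-based
throughout; `map_position()`/`unmap_position()` convert between them by
counting non-gap characters.

Contacts between αβ dimers are residue pairs from different dimer groups
with minimum heavy-atom distance at or below 3.0 Å (inclusive). Hydrogens
are excluded (predicted models carry none anyway) and hetero atoms are
excluded by default. Interface confidence summaries average the predicted
aligned error over all cross-group interface residue pairs in both
orientations (PAE matrices are asymmetric) and pLDDT over the union of
interface residues. `derive_interface_columns()` composes contact search
with position mapping to hand interface alignment columns to the
conservation scorer, rejecting at the first residue where a chain's
sequence disagrees with its alignment row.

## Numerical and testing choices

* Problem sizes: the end-to-end recovery study runs 50 simulations of two
  strains at 5% divergence with all eight hexamer compositions at uniform
  random weights, baseline noise at 0.2% of the base peak (averaged native
  spectra have sub-percent noise), on a 0.25 m/z grid. A composition is
  checked when it holds at least 2% of the mixture; recovered abundance is
  compared within family at ambiguity-group resolution, ±20% relative.
* Degenerate inputs: empty spectra and flat traces yield empty centroid
  lists, not errors; zero hexamer intensity yields an undefined (NA)
  dimer:hexamer ratio; all-gap alignment columns are reported as skipped;
  an empty contact list yields empty interface sets.
* Tie-breaks: equal multiset compositions are canonicalised by ordering
  units on (family, α strain, β strain); cluster acceptance breaks ties on
  summed intensity; the most intense centroid wins when a series has two
  candidates at one charge.
* Determinism: every stochastic step (strain generation, noise, mixture
  weights in the pipeline runner) is seeded, restores the caller's RNG
  state, and reproduces byte-identical outputs for identical configs.

## Known limitations

* Compositions separated by less than the peak width in mass units
  (~50–60 Da at hexamer charges and R = 7500 at m/z 400) merge in m/z and
  are only quantifiable as a group; the ambiguity-group reporting is the
  honest resolution of this, not a workaround.
* Collision repair assumes approximately Gaussian charge envelopes; badly
  truncated envelopes (acquisition windows cutting an envelope edge) fall
  back to plain sums.
* Quantification assumes equal ionisation efficiency across species, as
  is implicit in intensity-ratio readings of native spectra.
* The conservation module consumes finished alignments; alignment building
  and trimming belong to external tools.
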