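---
title: "Designing covalent heme attachment sites on structured proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing covalent heme attachment sites on structured proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemesite)
```

## The problem

c-type cytochromes carry heme covalently: two thioether bonds join the
porphyrin's ring-A and ring-B substituents to the cysteines of a CxxCH
sequence motif, and the motif histidine serves as an axial iron ligand.  In
gram-negative bacteria the cytochrome c maturation system I (Ccm-I) attaches
heme to essentially any CxxCH motif presented in the periplasm.  That
promiscuity makes it possible to turn a structured, non-heme protein — for
example a bacterial microcompartment hexamer-forming shell protein (BMC-H) —
into a cytochrome by engineering a CxxCH motif at a well-chosen surface
position and letting Ccm-I do the chemistry in vivo.

"Well-chosen" is the hard part.  A ligated heme is rigid, so the backbone
conformation at and around the motif must be one that natural c-type hemes
are actually found on.  hemesite operationalizes this as a torsion-angle
compatibility screen: learn what backbone (phi, psi) ranges natural CxxCH
motifs occupy, then scan a target structure for 6-residue windows whose
torsions fall inside those ranges, plan the substitutions that create the
motif there, and check that a rigidly modelled heme does not collide with
the rest of the protein.

## The motif and its gates

The unit of analysis is the 6-mer `x1 C1 x2 x3 C2 H`: the CxxCH motif plus
the residue immediately preceding it (x1), whose conformation also
constrains heme support.  For each position we track backbone phi/psi in
degrees on (-180, 180], IUPAC sign convention — exactly the axes of a
Ramachandran plot.

`published_gates()` returns a fixed set of per-position acceptance
intervals: phi of x1 in (-100, -50); phi in (-100, -50) and psi in
(-100, 0) at C1; phi in (-100, -25) and psi in (-75, 50) at x2; phi in
(-160, -50) and psi in (-75, 0) at x3; phi in (-160, -50) and psi in
(-75, 25) at C2.  Psi of x1 and both histidine angles are unrestricted (the
histidine position is checked for existence only).  These windows describe
a mostly alpha-helical C1–C2 core with a broader tolerance toward the end
of the motif.

Intervals are treated as *open*: a torsion exactly on a bound fails.  The
printed gates use strict inequalities and boundary hits are measure-zero on
real data, so the literal reading costs nothing and is unambiguous.

`derive_gates()` systematizes how such gates arise from data: collect
(phi, psi) per motif position across a training set of cytochrome
structures (`find_cxxch_motifs()` + `collect_motif_torsions()`), take the
central-coverage quantile interval per angle, and round outward to a
5-degree grid.  Quantiles are computed linearly, *without* circular
statistics.  This is a deliberate simplification: every gated interval in
practice sits far from the ±180 seam, and the one seam-adjacent
position/angle (psi of x1) is conventionally ungated.  Gates derived from
data straddling ±180 would be wrong; the function is documented
accordingly and the caveat stands.

## Scanning and planning

`gate_scan()` slides the 6-residue window along every chain of a target's
dihedral table and records, per window, each gated check.  Windows touching
a terminus or a residue with missing backbone atoms *fail closed* with an
explicit `undefined:<position>.<angle>` reason rather than being silently
skipped — downstream reports must align with source-file numbering, and a
window that cannot be evaluated is not a candidate.

Passing windows are merged into regions by `merge_regions()`.  A printed
range like "residues 11–20" is ambiguous: it may span the passing window
*starts* or every residue *covered* by a passing window (start..start+5).
Both modes are computed and labelled; the pipeline reports both.

`plan_mutations()` converts a chosen window into the minimal substitution
set: positions C1, C2, H become C, C, H wherever they differ, never more
than three substitutions, and the inter-cysteine residues x2/x3 (and x1)
are never touched — their side chains are part of the native structure
being preserved.  For targets whose best option is a surface loop,
`plan_insertion()` instead inserts a validated 6-mer containing CxxCH after
a caller-designated anchor; removal of the span restores the original
sequence exactly.

## Heme placement and clash screening

`heme_template()` builds an idealized, synthetic heme c in code: a planar
porphyrin core with the iron at the origin, pyrrole nitrogens at 2.0 Å,
thioether substituent carbons on rings A and B with S-gamma stubs at the
1.81 Å thioether bond length, an axial histidine N-epsilon stub 2.0 Å above
the iron, and anchor stubs approximating the Cys C-alpha/C-beta pairs and
His C-alpha of a bound motif.  It encodes bonding topology and bond
lengths, not a crystallographic heme; its invariants are tested directly.

`place_heme()` superposes the template's anchor stubs onto the motif's
anchor atoms (Kabsch least-squares, proper rotations only) and applies the
rigid transform to the heme.  Design-stage structures carry the
*pre-mutation* side chains, so a glycine at a future cysteine position has
no C-beta; placement then falls back to C-alpha-only anchoring with a
warning rather than failing.  The anchor RMSD is reported as a placement
quality proxy.

`clash_check()` flags protein/heme atom pairs closer than the sum of their
van der Waals radii minus a tolerance.  The default tolerance of 0.4 Å is
the common "serious clash" convention; the original screen this replaces
was visual and unquantified, so the threshold is an explicit, flagged
parameter rather than a claim.  Hydrogens are ignored; the three motif
residues joined to the heme are excluded (their side chains are replaced by
the design).  A uniform-grid cell list makes the screen linear in atom
count, and the test suite pins it to an all-pairs brute-force oracle.
`heme_spacing()` reports pairwise Fe–Fe distances (nm) across multiple
placements, the quantity that matters for electron-hopping distance
arguments.

## Characterization math

* **Nernst fitting** (`fit_nernst`): least squares of
  `A(E) = A_ox + (A_red − A_ox) / (1 + 10^((E − Em) n / S))`, with
  `S = ln(10)RT/F` (59.16 mV at the default 298.15 K — the titration
  temperature is not part of the data, so it is a parameter).  `n` defaults
  to 1 (a single-electron c-type heme couple) and may be fitted.  Fitting
  raw absorbance with a free baseline and amplitude subsumes the
  fraction-reduced parameterization (baseline 0, amplitude 1), so one
  entry point covers both conventions.  Gauss–Newton is tried first; the
  `port` algorithm is the fallback for zero-residual (noiseless) curves,
  and its occasional unverifiable-convergence verdict is accepted only if
  the fit beats the flat model, otherwise an explicit error is raised.
  A curve spanning less than one transition decade (2S/n) triggers a
  warning flag.
* **Beer–Lambert** (`beer_lambert_concentration`): `c = A/(εl)` in µM.
* **Speciation** (`hh_ionized`): `[A⁻] = C/(1 + 10^(pKa − pH))`; with
  3 mM total cyanide, pH 7.8 and pKa 9.21 this gives 112.4 µM free CN⁻.
* **Net charge** (`net_charge`, `isoelectric_point`): fractional
  Henderson–Hasselbalch charges of termini and D/E/C/Y/H/K/R side chains,
  EMBOSS-style pKa set by default (selectable or user-supplied).  The
  charge is strictly decreasing in pH, so the pI is found by bisection.
  Histidines engaged as heme ligands are not charge-corrected — a known
  limitation of sequence-only charge estimates.  The suggested evaluation
  pH of 8.8 corresponds to a native-PAGE resolving gel.
* **Spectrum normalization** (`normalize_spectrum`): divide by the maximum
  in the 380–440 nm Soret window (covering oxidized ~407 nm and reduced
  ~416 nm peaks), report the peak position; idempotent.
* **Mass-weighted radius** (`mass_weighted_radius`): `Σwr/Σw` over
  size-distribution bins within 1–100 nm, the conventional window for
  protein-scale dynamic light scattering.

## What the synthetic data does and does not establish

`make_backbone()` constructs chains from fixed ideal internal coordinates
(N–CA 1.458 Å, CA–C 1.525 Å, C–N 1.329 Å, standard angles, omega 180°),
varying only phi/psi.  This makes the torsion round trip exact up to
numerical noise, so generated helices/strands/coils are *oracles* for the
dihedral and gate code.  `make_motif_chain()` embeds CxxCH motifs with
torsions drawn strictly inside (or deliberately outside) the gates, on a
beta-strand background, with x-position residues drawn from an alphabet
without C, H or G — so the ground-truth manifest is exhaustive (no
incidental motifs) and C-beta anchors always exist.  `make_titration()`
produces Nernst curves with seeded Gaussian noise at a stated fraction of
the amplitude (2% in the acceptance runs, matching the few-mV uncertainty
scale of real titrations).

None of these fixtures imitates a real cytochrome fold, side-chain
packing, mediator electrochemistry or instrument response.  A green test
therefore establishes that the *computations* are correct on their stated
inputs, not that the gate set will reproduce any particular deposited
structure's candidate regions; re-running the scan on real crystal
structures is supported (`read_structure()` handles PDB and mmCIF) but
requires those files, which this package does not download.

## Numerical and policy choices

* First model and first altloc are kept; occupancy is carried but ignored
  by geometry.  Residues with missing backbone atoms keep their row with
  undefined angles.  Both sequential indices and source-file (auth)
  numbers are carried everywhere, because deposited numbering drifts.
* Modified residues that map to Cys/His by parent annotation are *not*
  treated as C/H during motif discovery; the strict policy is
  reproducible, the permissive one is not well-defined.
* Training-set deduplication (identical chains within an entry) is left to
  the caller assembling the motif tables; motif counts on redundant
  multimers will count each chain.
* Angles are reported on (−180, 180] with −180 normalized to +180,
  matching Ramachandran-plot convention.
* All stochastic generators are pure functions of their arguments and
  seed; the pipeline records its resolved configuration and a checksum in
  a run manifest.

## Known limitations

No structure refinement, hydrogen placement, loop modelling, side-chain
repacking, force-field energies or molecular dynamics: the placement
quality proxies are anchor RMSD and clash count, which flag geometric
impossibility but do not rank feasible sites energetically.  Maturation
efficiency by Ccm-I, signal-peptide design and expression-construct layout
are out of scope.
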