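---
title: "Group epitope mapping from STD-NMR and its concordance with docking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group epitope mapping from STD-NMR and its concordance with docking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stdepitope)
library(dplyr)
```

## The measurement and the model

Saturation-transfer difference (STD) NMR is a ligand-observed experiment:
the protein is irradiated selectively, saturation spreads through the
protein by spin diffusion, and is transferred to a bound ligand through
intermolecular cross-relaxation. After the ligand exchanges back into
solution, the transferred saturation shows up as a loss of intensity in the
ligand's own resonances. For one proton, with `I0` the integral of its
signal in the off-resonance (reference) spectrum and `Isat` the integral in
the on-resonance spectrum, the fractional STD effect is

```
f = (I0 - Isat) / I0
```

and the *absolute STD percentage* is `100 f`. Because saturation transfer
decays steeply with distance, protons closer to the protein surface show
larger effects; ranking a ligand's protons by STD intensity therefore maps
the *binding epitope* — the part of the ligand facing the protein.

`stdepitope` implements this quantification and the reporting conventions
used in ligand-observed screening of an RNA-recognition-motif (RRM) protein
against a panel of small natural products:

* **Relative STD %** — each compound's intensities are normalised against
  its most intense signal, which is assigned exactly 100%. Relative values
  are invariant under rescaling all integrals by a common factor, so they
  are comparable between spectra recorded at different receiver gains.
* **Epitope colour classes** — the most intense signal is its own class
  (`MAX`, the black dot of an epitope map); otherwise relative STD over 80%
  is `DARK_RED`, over 40% is `ORANGE`, and under 40% is `LIME`. The
  thresholds are strict ("over"), so a proton at exactly 80% classifies as
  `ORANGE` and exactly 40% as `LIME`; the texts describing these maps leave
  the boundary value unassigned, and assigning down keeps both thresholds
  on the same strict convention.
* **Absolute-STD bins** — the per-compound interaction pattern is
  summarised by counting interacting protons in the ranges `>1`, `1.0–0.9`,
  `0.8–0.7`, `0.6–0.5`, `0.4–0.2`, `<0.2` (absolute STD %). Printed this
  way the ranges leave gaps (0.8–0.9, for instance); we resolve them by
  rounding to one decimal before binning, matching the one-decimal
  precision at which such values are reported.
* **Binder call** — a compound binds when at least one proton strictly
  exceeds a noise floor. The floor defaults to 0.05% absolute STD; no
  numeric detection limit is published for this kind of experiment, so the
  default is simply a conservative reading of what "visible signal above
  the noise" means for well-digitised spectra, and it is configurable
  everywhere it is used. Non-binders ("no signal shown") get undefined
  relative values and classes rather than zeros.
* **Artefacts** — `Isat > I0` (negative STD) is physically impossible for a
  clean difference spectrum and indicates phasing or subtraction problems.
  Such values are retained and flagged, never clipped, so that artefactual
  signals stay visible downstream.

```{r quantify-example}
peaks <- tibble::tibble(
  compound_id = "cpd1",
  proton_label = c("H6", "H8", "H2'", "H5'", "H4'''"),
  I0 = 100, Isat = c(98.9, 99.2, 99.5, 99.75, 99.96))
std_quantify(peaks) |>
  select(proton_label, absolute_std_pct, relative_std_pct, epitope_class)
```

## Interaction fingerprints from pose coordinates

The in-silico half of the analysis catalogues protein–ligand contacts in
complex coordinates (docking poses or trajectory snapshots) in three kinds:
hydrogen bonds, hydrophobic contacts, and cation-π interactions. The
original visual analysis of such poses does not state numeric criteria, so
the detectors use defaults that follow common structural-biology practice
and expose every cutoff in `contact_cutoffs()`:

| contact | criterion | default |
|---|---|---|
| hydrogen bond | donor–acceptor distance; D–H···A angle when the donor H is present | ≤ 3.5 Å; ≥ 120° |
| hydrophobic | apolar C (protein) – apolar C (ligand) distance | ≤ 4.5 Å |
| cation-π | cation centroid to ring centroid; angle to ring normal | ≤ 6.0 Å; ≤ 45° |

Protein donors/acceptors come from residue templates for the 20 standard
amino acids (backbone N/O plus the polar side-chain atoms); ligand N/O
atoms are acceptors, and donors when a hydrogen sits within covalent range.
Donors lacking explicit hydrogens fall back to the distance-only criterion
with a logged downgrade. Apolar carbons are side-chain carbons with no N/O
neighbour (template side) and, for the ligand, carbons with no N/O within
1.8 Å. Cations are arginine guanidinium centroids and lysine ammonium
nitrogens; aromatic rings must be declared in the ligand topology (a ring
needs at least three declared atoms).

To compare the contact map with the NMR epitope proton by proton, contacts
are projected onto protons over a *one-bond neighbourhood*: a proton counts
a contact when the contact's ligand atom is the proton's bonded heavy atom
or a heavy atom one bond away. This is the minimal rule that reproduces
"this proton sits near the contact" without a full distance-weighted model;
a ring-level cation-π contact projects onto every proton bonded to a ring
member, so one contact may contribute to several protons.

## Conformer ensembles, clustering, and the open/closed call

Trajectory snapshots are compared after least-squares rigid superposition
(Kabsch algorithm, proper rotation enforced), giving a pairwise RMSD matrix
in which each pair is fitted independently — the simplest reading of
"clustered with respect to RMSD". Such a matrix need not satisfy the
triangle inequality; violations are only warned about. Collinear point
sets, for which the optimal rotation is not unique, raise an error naming
the condition.

The ensemble is partitioned by k-medoids (PAM) on that matrix because the
representatives are then *actual frames*, matching the practice of
reporting "representative structures" from a clustered trajectory; `k`
defaults to 10, the number reported in that workflow, and is a
configuration choice rather than something the data decide. The swap phase
is run from the deterministic BUILD initialisation plus 20 seeded random
restarts, keeping the lowest-cost solution: a single BUILD+swap pass can
stall in a local optimum on unstructured dissimilarity matrices, and the
restarts make the small instances we test provably optimal (verified
against exhaustive enumeration). Heavy atoms only are compared by default.

Two reference conformations — an "open" and a "closed" arrangement of the
tandem RRM domains — turn clustering into a state call: `assign_state()`
labels a structure by the nearer reference (superposed RMSD), with a
sentinel `UNASSIGNED` for ties within 1e-6 Å.

## Concordance between the epitope and the contact map

For each compound, the per-proton absolute STD % is compared with the
per-proton contact count by Spearman rank correlation with average-rank
ties. Spearman rather than Pearson because the two variables live on
incommensurate scales (a percentage and a count) and the scientific claim
being tested is ordinal — protons with stronger STD should carry more
contacts. The correlation is undefined, and flagged rather than imputed,
when fewer than 3 protons are shared or either variable is constant.

Two further calls complete the comparison. The pose location
(`POCKET_INTERIOR` vs `EXTERNAL_SURFACE`) is decided by ligand-centroid
burial: the fraction of protein atoms within 8 Å of the ligand centroid,
against a default threshold of 0.15 — a geometric formalisation of a
qualitative visual description, with both numbers configurable. Crossing
the binder call with the pose location gives `AGREE_BINDER` (binder, buried
pose), `AGREE_NONBINDER` (non-binder, external pose) or `DISAGREE`.
Finally, `select_state()` picks the protein state whose poses maximise the
mean Spearman rho across compounds, breaking exact ties deterministically
by state id with a warning.

## What the synthetic generator emulates — and what it does not

No spectra or docking outputs are deposited for this kind of study, so the
package generates its own inputs with the statistical structure the
analysis assumes, and every recovery test runs against planted ground
truth.

* **Study conditions.** Defaults reproduce the experiment arithmetic: a
  1000:1 ligand/protein excess (400 µM against 0.4 µM — the constructor
  refuses inconsistent values), a 2.94 s saturation train, and a 13-compound
  panel of which exactly one compound is a non-binder.
* **Transfer kernel.** The simulated fractional effect is
  `f = S (1 - exp(-t_sat/T)) Σ (r0/r)^m` summed over protein heavy atoms,
  clipped to [0, 0.99], with `m = 6`, `r0 = 3` Å, `S = 0.01` and
  `T = 1.5` s. The `r^-6` form mirrors the distance dependence of
  cross-relaxation and makes "protons nearest the protein saturate most"
  quantitative; the build-up factor makes varying the saturation time (the
  0.98–2.94 s range used experimentally) behave qualitatively correctly.
  It is *not* a relaxation-matrix (CORCEMA-type) simulation: no spin
  diffusion within the ligand, no rebinding kinetics, no exchange limit.
  With proton heights of 3–5.5 Å above the pocket floor these defaults put
  absolute STD in the 0.1–1% range with a few signals above 1% — the
  regime reported for weakly binding natural-product panels.
* **Noise.** Multiplicative log-normal noise (mean-preserving, default
  CV 5%) keeps integrals positive; a planted non-binder has its pre-noise
  fraction forced to zero and its pose displaced to the pocket rim.
* **Toy complexes.** The pocket is a planar pad of apolar side-chain
  carbons from standard hydrophobic residues (64-atom grid, 1.8 Å spacing)
  optionally decorated with an asparagine donor and an arginine
  guanidinium; ligand protons sit at controlled heights, and one instance
  of each requested contact kind is planted by exact construction
  (N–H···O at 2.9 Å/180°, cation 4 Å along a ring normal). Because the
  same geometry drives both the STD kernel and the emergent hydrophobic
  contact counts, consistent poses concord by construction; decoy poses
  (proton heights permuted) break that consistency and stand in for poses
  docked against the wrong protein state.
* **Two-state ensembles.** A random base conformation and a displaced copy
  whose superposed RMSD equals the requested separation (root-finding on
  the displacement amplitude, default 5 Å) generate frames as reference
  plus isotropic Gaussian noise (default 0.2 Å); labels are recorded at
  generation time.

Passing tests on these inputs therefore show that the *algorithms* are
correct — formulas exact, detectors equal to exhaustive oracles, planted
truth recovered under the stated noise — not that the defaults reproduce
any particular real protein's residue-level biology. Real spectra add
overlapping and degenerate resonances (the peak-table schema assumes one
record per resolved resonance), baseline and phasing artefacts beyond the
negative-STD flag, and rebinding effects; real poses add charge and
polarisation effects that fixed geometric cutoffs ignore.

## Numerical choices and degenerate inputs

* Relative STD is computed as `100 * (x / max)` so the argmax is exactly
  100 in floating point; ties for the maximum resolve to the first proton
  in table order.
* Bin boundaries compare rounded values with a 1e-9 guard so one-decimal
  values sit in their intended bin regardless of binary representation.
* Superposition requires ≥ 3 atoms and non-collinear coordinates; the
  reflection case is handled by forcing `det(R) = +1`.
* `k > n_frames` is reduced with a warning; `k = n_frames` returns each
  frame as its own representative at zero cost without calling PAM.
* Empty inputs propagate as empty tibbles (contact sets, bin summaries)
  rather than errors, except where the operation is meaningless (empty
  ensembles, zero-proton ligands).

## Problem sizes

The shipped tests run panels of 2–20 compounds with 4–10 protons,
ensembles of 6–40 frames of 12–30 atoms, and toy complexes of ~50–90
atoms; the full suite and the acceptance script each complete in well
under a minute. These sizes are chosen so that every brute-force oracle
(dense rotation search, exhaustive medoid enumeration, all-pairs contact
scans) remains exact and fast; all generators scale to larger requests
through their configuration.

## Known limitations

* No spectral processing: inputs are already-integrated peaks, and no
  dissociation-constant estimation is attempted (saturation-transfer
  build-up curves are simulated but not fitted).
* Contact typing is template-based for the 20 standard amino acids;
  modified residues fall back to backbone-only typing.
* No π–π stacking, halogen bonds, charge assignment or scoring-function
  energies; the catalogue covers the three contact kinds above.
* The Spearman concordance is this package's formalisation of the
  qualitative per-proton comparison between STD intensity and contact
  counts; it is validated on synthetic ground truth only.
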