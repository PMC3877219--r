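---
title: "Methods: the amideshift shift model, observables and refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the amideshift shift model, observables and refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amideshift)
```

## The additive shift model

`amideshift` treats the backbone amide proton chemical shift (DSS-referenced,
ppm) as an exactly additive sum of five physically distinct contributions.
Additivity is an assumption of the model, not an approximation made by the
code: `predict_shifts()` reports the five terms alongside their sum, and the
sum is the row total to machine precision.

**Backbone term.** A truncated two-dimensional cosine series in the backbone
torsions $(\phi, \psi)$, evaluated term by term from a plain-text coefficient
table, then passed through an affine scaling $a x + b$ (defaults $a = 1$,
$b = 0$, settable in `shift_params()` or the YAML config). The scaling slot
exists because series of this kind are fitted at a particular level of
electronic-structure theory and geometry optimization; re-referencing to a
different level is a linear map.

**Primary hydrogen bond.** The dominant structural term. The package
classifies each backbone amide proton's acceptor into backbone amide,
side-chain amide (ASN/GLN), carboxylate (ASP/GLU/OXT), alcohol
(SER/THR/TYR), or none. Amide carbonyl acceptors use the closed form
$\exp(-k\,r_{HO})\,(a \cos^2\theta_2 + b)$ where $\theta_2$ is the
H$\cdots$O=C angle — an exponential in the bond length times a smooth
angular factor, the shape expected from perturbation of the N–H bond by the
acceptor lone pairs. Carboxylate and alcohol acceptors are interpolated
bilinearly from $(r, \theta_2)$ lookup grids that emulate dimer scans of
N-methylacetamide with acetate and methanol, respectively. A proton with no
acceptor inside the detection gate is treated as solvent-exposed and
receives the fixed water-model constant **2.07 ppm** — the value for the
minimum-energy water/N-methylacetamide bonding geometry. We treat this
constant as non-fluctuating across an ensemble; modelling a distribution of
water geometries would require an explicit-solvent picture the package does
not attempt.

**Secondary hydrogen bond.** A bond *accepted by* the same amide group's
carbonyl oxygen (the C=O of residue $i-1$ for the proton of residue $i$)
polarizes the amide and shifts the proton. Same closed form as the primary
amide term with its own, smaller coefficients.

**Tertiary term.** Cooperative polarization of chained amide networks:
fixed increments added when the primary partner amide (the amide group
owning the accepted carbonyl) is itself a donor, and/or when the secondary
partner's own carbonyl also accepts. The increments live in a two-row table
and are small by construction relative to the primary term.

**Ring current.** The point-dipole form
$i\,B\,(1 - 3\cos^2\theta)/r^3$ per aromatic ring, with $B = 30.42$
ppm Å$^3$ fixed, ring-type intensities $i$ in a parameter table, $r$ the
center-to-proton vector and $\theta$ its angle to the SVD-fitted ring plane
normal. Axial protons are shielded (negative), in-plane protons deshielded,
and the term vanishes at the magic angle; the sign of the fitted normal is
irrelevant because only $\cos^2\theta$ enters.

### Parameter provenance

The *functional forms* above are fixed by the model. The *coefficient
values* shipped under `inst/extdata/` are a **synthetic parameterization**
(each filename carries `synthetic`, regenerable with
`data-raw/make_parameter_files.R`): the original fitted coefficient sets
for the backbone series, the hydrogen-bond surfaces and the ring
intensities are not available in machine-readable published form, so the
package ships defaults with realistic magnitudes — totals near 7–8 ppm for
helical amides, primary terms of 2–4 ppm at typical bond lengths, ring
perturbations of a few tenths of a ppm at van der Waals contact, couplings
of a few tenths of a Hz. Every operation reads its coefficients from the
parameter files, so a laboratory with access to a fitted coefficient set
can drop in replacement files without touching code; all structural tests
(node exactness, monotone decay, additivity, invariances) are
parameterization-independent.

## Hydrogen-bond detection

The detection gate is $r_{HO} \le 2.5$ Å and N–H$\cdots$O $\ge 120^\circ$ —
standard amide hydrogen-bond geometry; both cutoffs are settable. Among
gate-passing candidates the smallest $r_{HO}$ wins, ties broken by the
larger N–H$\cdots$O angle; bifurcated bonds are therefore reduced to their
dominant branch, a deliberate simplification (the shift surfaces are
single-acceptor models). The donor's own carbonyl oxygen and the covalently
adjacent O($i-1$) are never candidates. Prolines and chain-initial residues
carry no amide proton and are excluded everywhere; shift predictions
additionally require both $\phi$ and $\psi$, which excludes the chain-final
residue from `predict_shifts()` (its proton still participates in bond
detection and in the solvent-exposed acceptance check). Alternate locations
other than blank/'A' are dropped at parse time; occupancies are ignored.

## Couplings, RDCs, Q-factor

h3J(NC') uses
$-A \exp(-k (r_{HO} - r_0)) \cos^2\theta_1 (p \cos^2\theta_2 + q)$ with
$\theta_1$ = N–H$\cdots$O. All shipped coefficients are non-negative, so
the coupling is $\le 0$ for any geometry and decays exponentially as a bond
opens — an opened bond back-calculates to $\sim 0$ Hz rather than
disappearing from the record. For this reason ensemble statistics are
computed over an explicit, fixed donor→acceptor pair list
(`amide_pair_geometry()` has no gate); the `HydrogenBond`-record entry
point refuses side-chain acceptor classes, across which the coupling is not
defined. Per-bond ensemble spread is reported as the root-mean-square
deviation from the per-bond mean, and agreement with experiment as the RMSD
of per-bond means.

The alignment tensor is the five-parameter Saupe tensor
($S_{xx}, S_{yy}, S_{xy}, S_{xz}, S_{yz}$; $S_{zz}$ from tracelessness),
fitted by the SVD pseudo-inverse of the quadratic orientation design built
from unit N–H vectors. The dipolar prefactor is absorbed into the tensor
(components in Hz), which changes nothing about Q-factors or comparisons.
In ensemble mode the quadratic orientation terms are averaged over
conformers *before* the fit, so one tensor fits all structures
simultaneously. A relative singular-value threshold of $10^{-10}$ guards
against degenerate geometry (e.g. all N–H vectors (anti)parallel) with an
explicit error. The Q-factor denominator is $\sum D_{exp}^2$ — the plain
normalized-RMS convention, chosen so that $D_{calc} \equiv 0$ gives exactly
$Q = 1$; RDCs are computed for backbone N–H only.

## Bayesian refinement

The posterior is $p(X \mid D) \propto e^{-E(X)/k_B T} \, L(D \mid X)$ with
$T = 300$ K by default and $k_B = 0.0019872$ kcal/mol/K. The likelihood is
Gaussian in the per-residue deviations $\Delta\delta_i$ with a standard
deviation chosen by the proton's primary-bond class — 0.3 ppm backbone
amide, 0.5 side-chain amide, 0.8 alcohol/carboxylate, 1.2 ppm
solvent-exposed or unclassified — reflecting that the amide–amide surface
is the best-constrained part of the model and the water model the crudest.
A converged run should therefore show an ensemble shift RMSD near the
$\sigma$ of the dominant bond class, which is what the recovery tests
check. The formulation assumes the prior is also a reasonable prior for the
shift deviations themselves; no compensating term is added.

**Prior energy.** Full force-field priors are out of scope. The package
defines an energy-model contract — any function `(xyz, ctx) -> kcal/mol`,
deterministic in its input — and ships three implementations: a coarse
default (soft-sphere repulsion between heavy atoms at sequence separation
$\ge 2$, a Gaussian attractive well for amide H$\cdots$O pairs centred at
1.95 Å, and a harmonic restraint of all torsions to the start structure), a
single-torsion harmonic toy used to validate the sampler against the
closed-form variance $k_B T / k$, and a flat prior. The default is a
package design choice that keeps runs desk-scale while preserving the
posterior structure; users with an external energy function plug it in as a
callable.

**Move set.** One torsion per step, perturbed by a Gaussian of width
`sd_backbone` (default 2°) for backbone $\phi/\psi$ or `sd_sidechain`
(default 10°) for side-chain $\chi_1$, applied as a rigid rotation of the
downstream atoms. The default mixture is 25% backbone / 75% side-chain
moves when side-chain torsions exist (poly-alanine fixtures fall back to
pure backbone moves). Proposals are symmetric, so the acceptance rule is
the plain Metropolis ratio; rejected moves restore the previous coordinates
bit-exactly. A single seeded generator drives the whole run — fixed seed,
bit-identical trace. Conformers are saved every 10,000 steps by default
(tests and examples use much smaller intervals); a window of 2,000
consecutive rejections triggers a frozen-chain warning.

## What the fixture generator emulates — and what it does not

`make_peptide()` builds poly-alanine (plus any of G/S/T/D/E/N/Q/F/W/H/P)
from ideal bond lengths and angles by natural-extension (NeRF)
construction, so requested torsions are recovered exactly — ideal
$\alpha$-helices bond i→i−4 at $r_{HO} \approx 2.1$ Å by construction.
`make_amide_dimer()` reproduces the two-amide model systems used to
parameterize hydrogen-bond surfaces, placing a donor tripeptide at exact
$(r_{HO}, \theta_2, \theta_1, \rho)$ geometry. `make_synthetic_*()`
forward-model shifts, couplings and RDCs with optional Gaussian noise and
keep the generating truth alongside.

These fixtures deliberately lack much of real data: no rotamer
distributions, no solvent, idealized covalent geometry, single chains, and
noise that is Gaussian and independent by construction — exactly matching
the likelihood. Passing tests therefore demonstrate internal correctness
(geometry, algebra, sampling, recovery under the model's own assumptions),
not prediction accuracy on experimental proteins, which depends on the
coefficient files discussed above.

## Numerical choices and problem sizes

* Out-of-grid geometries clamp to the surface boundary with a warning —
  extrapolating an exponential fit is worse than saturating it.
* Bilinear interpolation is exact at nodes and bounded by the surrounding
  node extrema; both properties are tested.
* Dihedrals follow the IUPAC sign convention in $(-180°, 180°]$; the
  acceptor-plane dihedral $\rho$ is set to `NA` for linear H$\cdots$O=C
  arrangements rather than erroring.
* Degenerate inputs error explicitly: structures without explicit amide
  hydrogens (naming the first offending residue), collinear dihedral atoms,
  protons on a ring center, rank-deficient RDC designs, fewer than 5 RDCs,
  fewer than 2 scored residues.
* Ensemble averages weight all saved conformers uniformly.
* Test problem sizes are the package's own choices for fast, stable
  statistics: 8–12-residue peptides, $10^5$-step two-state chains,
  6,000-step harmonic-prior runs, and a 20,000-step, 10-residue recovery
  run (perturbed start, noise-free synthetic shifts, all $\sigma$ = 0.05
  ppm, sterics-only prior) whose ensemble-mean H···O lengths return to
  within 0.05 Å of the generating conformer.

## Known limitations

Only backbone amide protons are predicted; protonation states are taken as
given (input structures must already carry hydrogens); mmCIF and
non-protein chains are unsupported; refinement is single-chain with a
deliberately coarse default prior; the shipped coefficients are synthetic
defaults, so absolute agreement with experimental shift tables should not
be read off them.
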