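---
title: "Coarse-grained Monte Carlo modelling of gluten storage proteins: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Monte Carlo modelling of gluten storage proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glutensim)
```

# Scope

`glutensim` studies the conformational ensembles of intrinsically
disordered wheat storage proteins — α-gliadins and low molecular weight
glutenin subunits (LMW-GS) — with a one-bead-per-residue Metropolis Monte
Carlo model, and provides the sequence-level statistics (hydropathy,
charge) used to reason about why particular cysteines form intra- versus
intermolecular disulfide bonds. This vignette records the model, its
assumptions, the tunable parameters and their defaults, the numerical
conventions, and the design decisions taken where more than one reasonable
choice existed.

# Sequence profiling

**Hydropathy.** `hydropathy_profile()` slides an odd window (default 15
residues) along the chain and assigns the unweighted mean of the scale
values to the centre residue. Only full windows are scored — no edge
padding — so a sequence of length $L$ yields $L - w + 1$ values; this is
the ProtScale convention and the one under which the packaged sequences
reproduce their target accumulated indices. The *accumulated hydropathy
index* is the arithmetic mean of the windowed profile over the **mature**
chain (signal peptide removed). The reported "variation" is the population
variance of the windowed values; sample variance and standard deviation
are attached as well, because the term is used loosely in the field and a
downstream consumer should be able to pick either definition.

Two scales are shipped: Kyte–Doolittle (free-energy based, the primary
scale) and Rose (mean fractional area loss — buriedness). Hydropathy
scales agree on the non-polar residues and differ mostly on polar ones;
both are exposed through the same `residue_scale()` interface.

**Charges.** The default charge scheme assigns +1 to Arg/Lys, −1 to
Asp/Glu, and leaves His and the termini neutral — the standard
physiological-pH convention. Histidine protonation is configurable
(`his_positive = TRUE`). Under this default the packaged gliadin-like and
glutenin-like chains carry 7+/6− (net +1) and 9+/2− (net +7),
respectively. The census derives the diagram-of-states coordinates
($f_+$, $f_-$, FCR, NCPR); `das_pappu_classify()` applies the published
region boundaries with ties resolved to the lower-numbered region (R1
below FCR = 0.25, R2 up to 0.35, then R3/R4/R5 by which charge fraction
exceeds 0.35). Low-charge storage prolamins land in R1, where the diagram
predicts globule/tadpole behaviour — with the caveat that the diagram says
nothing about proline-rich chains.

**Cysteine context.** `cys_context()` reports the windowed hydropathy at
each cysteine (nearest scored position for window-truncated termini,
flagged `edge`), classifying > 0 as hydrophobic. This is the sequence
feature that separates intramolecular-bonding cysteines (hydrophobic
flanks) from the cytosol-exposed intermolecular ones of LMW-GS.

# The coarse-grained model

Each mature residue is a bead of radius $a = 2.0$ Å carrying its scheme
charge; counter-ions (one per unit of net charge, opposite sign) are
explicit free beads, so the box is electroneutral. The energy has four
terms, all in units of $k_BT$ at 298 K:

* **Bonds**: harmonic, $\tfrac12 k_b (r - r_0)^2$ with $r_0 = 4.1$ Å
  (Cα–Cα-like spacing) and $k_b = 25\,k_BT/\text{Å}^2$, which keeps
  relative bond-length fluctuations below 5 % at 298 K
  ($\sigma_b/r_0 = \sqrt{k_BT/k_b}/r_0 \approx 4.9\,\%$).
* **Excluded volume**: hard spheres, infinite energy below the contact
  distance $\sigma = 2a = 4$ Å (applies to all particle pairs, bonded
  included; the equilibrium bond length sits just above contact).
* **Electrostatics**: extended Debye–Hückel between all charged pairs,
  $u(r)/k_BT = z_i z_j \, (l_B/r)\, e^{-(r-\sigma)/\lambda_D} /
  (1 + \sigma/2\lambda_D)$, with Bjerrum length $l_B = 7.14$ Å (water,
  298 K) and Debye length $\lambda_D = 3.04/\sqrt{c\,[\mathrm{M}]}$ Å for
  a 1:1 electrolyte; $c = 0$ gives unscreened Coulomb. Salt is implicit
  (through $\lambda_D$), counter-ions explicit — a deliberately mixed
  treatment. The scan values used throughout are 10, 80, 500 and 1000 mM.
* **Disulfide restraints**: harmonic springs between designated cysteine
  bead pairs. The atomistic S–S bond distance (≈2 Å) is geometrically
  impossible between 4 Å hard spheres, so the bead-level target is contact,
  $r_0^{SS} = 4.0$ Å, with $k = 10\,k_BT/\text{Å}^2$ — stiff enough that
  the pair never leaves contact range, preserving the topological intent
  (a permanently bonded pair, active throughout the whole simulation).

The chain lives in a periodic cubic box of edge 1500 Å with the
minimum-image convention for every pair distance. Chain coordinates are
kept continuous (the centre of mass may drift; internal geometry is then
trivially correct for Rg/Ree/contact analysis), ions are wrapped; the two
conventions are energetically identical under minimum image. A box smaller
than the chain contour length triggers a warning, since a fully extended
chain could then see its own periodic image.

Temperature enters only the Metropolis weight (energies are stored in
298 K units and scaled by $298/T$); the temperature dependence of the
dielectric constant, and with it of $l_B$, is intentionally out of scope.
There is no hydrophobic attraction term: beads are charged or neutral
only, so the model isolates electrostatic and topological (disulfide)
effects. That is why its ensembles are expanded self-avoiding coils rather
than the more compact ensembles an attractive force field produces.

# The sampler

`run_mc()` performs canonical Metropolis sampling with six move types:
single-bead translation, pivot rotation (random side of a random bead),
crankshaft rotation of an interior segment, whole-chain translation and
rotation, and counter-ion translation. A *sweep* is one attempted move per
particle. Energy changes are evaluated over exactly the pairs involving
moved particles, and the incremental total is checked against a full
recomputation at the end of every run (the `energy_drift` diagnostic;
typical values are $10^{-12}\,k_BT$, and the suite requires
$< 10^{-6}$). Hard-sphere overlaps reject immediately.

Step sizes auto-tune toward 30–50 % acceptance during equilibration only
and are frozen for production, so the production run is strictly
canonical. All randomness flows from a single seed through R's RNG (the
compiled core draws from the same stream), making runs bitwise
reproducible.

`run_annealed()` cycles a strictly descending temperature ladder (default:
ten temperatures from 400 K to 300 K, 1000 sweeps per rung) and records
only lowest-temperature production configurations; `anneal_counts()`
exposes the bookkeeping (e.g. 200 equilibration cycles × 1000 → 2×10⁵
produced target-temperature configurations, 800 cycles → 8×10⁵, saved
every 10th). A single-rung ladder reduces to plain `run_mc()` sampling.
`salt_scan()` runs one independent simulation per salt concentration with
deterministic child seeds.

# Ensemble observables

* `radius_of_gyration()` — RMS distance from the centroid, unit masses.
* `shape_factor()` — $R_\text{shape} = \langle R_{ee}^2\rangle /
  \langle R_g^2\rangle$ with $R_{ee}$ between the first and last chain
  bead; ≈1 for globules, ≈6 for self-avoiding walks, →12 for rods
  (exactly $12(n-1)/(n+1)$ for an $n$-bead rod).
* `flory_fit()` — $R_g = R_0 N^\nu$. Single-point mode inverts the law
  ($\nu = \ln(R_g/R_0)/\ln N$, $R_0 = 2$ Å by default, the experimental
  protein prefactor). Regression mode fits $\ln R_g$ against $\ln N$,
  with the intercept fixed at $\ln R_0$ when $R_0$ is supplied, or free
  (`R0 = NULL`) when the prefactor is unknown — the right choice for
  reference-chain ensembles, whose prefactor is set by the bond length and
  is nowhere near 2 Å; fixing it would bias the slope.
* `rg_distribution()` — normalised Rg density with exact sample moments.
* `debye_scattering()` — orientation-averaged intensity
  $I(q) = \sum_{ij} f_i f_j \sin(qr_{ij})/(qr_{ij})$ (the $q\to0$ limit is
  handled analytically, $I_0 = (\sum f)^2$), ensemble-averaged. The
  dimensionless Kratky transform $(qR_g)^2 I/I_0$ uses the ensemble-mean
  Rg. `guinier_rg()` checks low-$q$ self-consistency.
* `contact_map()` / `cys_contact_network()` — contact frequencies below a
  cutoff with near-diagonal exclusion ($|i-j| \le 1$ by default, so
  vicinal cysteine pairs carry no data). The bead cutoff default is 8 Å:
  the atomistic convention (5 Å between side-chain heavy atoms) has no
  direct analogue between bead centres, and 8 Å ≈ side-chain reach plus
  contact preserves the map's qualitative structure.

# Synthetic data: what it emulates and what it does not

`generate_gluten_like_sequence()` builds chains with the statistical
signature of gluten prolamins: a P/Q-rich repetitive N-terminal domain
from hepta-/dodecapeptide motifs (the canonical repeat classes; no claim
is made to reproduce any real accession residue-by-residue), cysteines
embedded in 11-residue blocks whose flanks are strictly hydrophobic or
strictly hydrophilic on the Kyte–Doolittle scale (so `cys_context()`
classifies them by construction), and K/D residues placed to hit an exact
target net charge. Generation is a pure function of (parameters, seed).

The packaged stand-in FASTA files were produced once by
`data-raw/make_fixtures.R`: the same construction plus a greedy residue
search that matches the documented accumulated hydropathy indices (−0.98
and −0.71) while the cysteine windows, charges and signal peptides stay
frozen. Tests against these fixtures therefore verify that the package's
profiling machinery reproduces the documented statistics on sequences
built to have them — they validate the computations end to end, but they
are not evidence about the real database sequences.

Reference conformations: `generate_rod()` (exact geometry),
`generate_ideal_chain()`/`generate_ideal_ensemble()` (freely-jointed,
$\langle R_{ee}^2\rangle = (n-1)b^2$,
$\langle R_g^2\rangle = b^2(n^2-1)/6n$), and
`generate_saw_chain()`/`generate_saw_ensemble()` (hard-sphere pivot
walks). Synthetic simulation fixtures capture topology, charge and
excluded volume but *not* hydrophobic collapse, hydrogen bonding or
secondary structure — passing tests demonstrate correct polymer physics of
the model, not all-atom realism.

# Numerical choices and conventions

* **Residue indexing** is 1-based on the mature (signal-trimmed) sequence
  everywhere — restraint pairs, contact maps, cysteine networks. The
  packaged glutenin-like chain has its intermolecular cysteines at mature
  positions 2 and 210; the gliadin-like chain's three intramolecular pairs
  are (108,138), (139,229), (151,237).
* **SAW sampling.** Pivot walks start from a rod and discard 20 n accepted
  pivots before sampling, with 20 accepted pivots between samples. Shorter
  equilibration (10 n) measurably retains rod bias at n = 400, and short
  strides leave visible autocorrelation in Flory fits. The default SAW
  radius is 0.25 b: thin enough that chains of 50–400 beads scale with the
  universal exponent (ν ≈ 0.588); thick beads (radius ≳ 0.4 b) impose
  local stiffness and push the *effective* log–log slope toward ~0.62 over
  the same range — a real crossover, worth remembering when comparing
  bead-scale chains against asymptotic exponents.
* **Kratky plateau.** Discrete freely-jointed chains obey the exact form
  $\langle \mathrm{sinc}(q r_k)\rangle = \mathrm{sinc}(qb)^k$; in the
  window $qR_g \in [5, 15]$ at n = 200 this sits at ≈1.6–1.75, below the
  Gaussian-chain plateau of 2 (which requires $qb \ll 1$). The test suite
  asserts the exact closed form rather than the continuum value.
* **Degenerate inputs.** Empty configurations, single-bead chains,
  non-positive distances, even windows, unsorted temperature ladders,
  infeasible generator parameters and non-cysteine restraint indices all
  raise descriptive errors; `flory_fit()` warns (not errors) when
  $R_g \le R_0$ makes the exponent non-positive; identical-frame Rg
  histograms degenerate to a single occupied bin.
* **Problem sizes.** The shipped tests and the acceptance script run
  chains of 2–400 beads, production runs of ~10³ sweeps and reference
  ensembles of ≤5000 chains — sizes chosen so the whole suite completes in
  minutes on one core while every stochastic assertion retains ≥3σ
  headroom. Production studies of the 248/265-residue proteins use the
  same code paths with longer schedules.

# Known limitations

* No hydrophobic/attractive interactions: the CG ensembles are expanded
  coils; compaction appears only through disulfide topology, not through
  solvent quality.
* No secondary structure, no atomistic backbone — observables requiring
  them (e.g. hydrogen-bond-based structure assignment, all-atom SAXS with
  real form factors) are out of scope.
* Counter-ions in a 1500 Å box at the default concentrations contribute
  little at the salt conditions studied; they guarantee electroneutrality
  rather than ion-specific effects.
* The annealing defaults mirror a published protocol; the package applies
  the same schedule machinery to the coarse-grained model, where shorter
  ladders usually suffice because the landscape is far smoother than an
  all-atom one.
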