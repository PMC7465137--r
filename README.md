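# glutensim

Coarse-grained Monte Carlo simulation and sequence analysis of wheat gluten
storage proteins.

## The problem

Wheat seed storage proteins — gliadins and low molecular weight glutenin
subunits (LMW-GS) — are intrinsically disordered, proline/glutamine-rich
chains whose functional behaviour is governed by disulfide crosslinking:
gliadins form only intramolecular S–S bonds and stay monomeric, while
LMW-GS additionally crosslink between molecules into the giant gluten
polymer network. Which cysteines do what is remarkably predetermined, and
sequence context (hydropathy of the flanking segments), chain flexibility
and synthesis chronology are the proposed determinants.

`glutensim` provides the computational toolkit for studying these questions
at the coarse-grained level, for structural bioinformaticians and
soft-matter modellers:

1. **Sequence profiling** — Kyte–Doolittle and Rose hydropathy profiles
   (sliding window, full-window convention), charge census and the
   Das–Pappu diagram-of-states classification, and per-cysteine hydropathy
   context scores.
2. **A bead-per-residue chain model** — one bead per amino acid (charged or
   neutral), harmonic bonds, hard-sphere excluded volume, screened
   electrostatics via an extended Debye–Hückel potential

   u(r)/kT = z_i z_j (l_B / r) · exp(−(r − σ)/λ_D) / (1 + σ/(2 λ_D)),

   explicit counter-ions for electroneutrality, and harmonic disulfide
   restraints, all in a periodic cubic box (default 1500 Å).
3. **Canonical Metropolis Monte Carlo** — single-bead, pivot, crankshaft,
   whole-chain and counter-ion moves with auto-tuned step sizes, optional
   simulated annealing over a descending temperature ladder, thinning, and
   bitwise-reproducible seeding.
4. **Ensemble analysis** — radius-of-gyration statistics and distributions,
   the Flory scaling law Rg = R0·N^ν (single-point inversion and log–log
   regression), the shape factor R_shape = ⟨Ree²⟩/⟨Rg²⟩ (≈1 globule, ≈6
   self-avoiding walk, ≈12 rod), Debye-formula scattering curves with
   dimensionless Kratky plots, residue contact maps and cysteine contact
   networks.
5. **Synthetic data** — generators for gluten-like sequences (P/Q-rich
   repeats, cysteines in controlled hydropathy contexts, target net
   charge) and reference conformations (rod, freely-jointed chain,
   pivot-sampled self-avoiding walk) that anchor every observable to a
   known answer.

The package ships two *synthetic stand-in* sequences
(`inst/extdata/synthetic_*.fasta`, built by `data-raw/make_fixtures.R`)
that emulate the documented statistics of a representative α-gliadin
(268 aa, 20-residue signal peptide, net charge +1, accumulated window-15
hydropathy index −0.98) and LMW-GS (288 aa, 23-residue signal peptide, net
+7, index −0.71), including the experimentally characterised disulfide
pairing pattern in mature numbering. They are constructed emulations, not
database sequences.

## Worked example

```r
library(glutensim)

## 1. profile the packaged gliadin-like sequence
fx   <- gluten_fixture("alpha_gliadin")
prof <- hydropathy_profile(fx$mature)      # Kyte-Doolittle, window 15
prof
#> Hydropathy profile (kyte_doolittle, window 15): 234 positions
#>   accumulated index (mean) -0.981, variance 3.015 (sd 1.740)
charge_census(fx$mature)
#> Charge census (248 residues): 7+/6- (net +1), f+ 0.028, f- 0.024,
#>   FCR 0.052, NCPR +0.004 -> R1
cys_context(fx$mature, prof)               # all six Cys in hydrophobic context

## 2. invert the Flory law for a reported ensemble size
coef(flory_fit(47.9, N = 265, R0 = 2))
#>        nu        R0
#> 0.5691975 2.0000000     # between theta (1/2) and good solvent (3/5)

## 3. simulate a gluten-like chain with two disulfide restraints
s <- generate_gluten_like_sequence(
  gluten_params(total_length = 120, n_repeat_motifs = 6,
                n_cys_hydrophobic = 4, n_cys_hydrophilic = 0,
                target_net_charge = 2, n_charge_pairs = 1, seed = 101))
pairs <- list(s$cys_positions[c(1, 2)], s$cys_positions[c(3, 4)])
cfg <- mc_config(n_equilibration_sweeps = 500,
                 n_production_sweeps = 1500, seed = 55)
ens <- run_mc(build_system(s, energy_params(salt_mM = 80),
                           restraint_pairs = pairs, seed = 55), cfg)
summary(ens)
#> Ensemble 'gluten_like_L120_seed101' (150 frames, 80 mM, 298 K)
#>   mean Rg     29.25 A   var Rg    27.61 A^2
#>   R_shape      6.28     nu        0.560
#>   max |incremental - recomputed| energy: 2.24e-12 kT
```

The mean Rg and its variance drop relative to the unrestrained run of the
same chain (34.3 Å / 46.5 Å²): intramolecular disulfide loops compact the
ensemble and narrow its size distribution. `contact_map(ens)` shows the
restrained pairs as symmetric frequency-1 loci; `salt_scan()` across
10–1000 mM changes the mean Rg of these weakly charged chains by only a
few percent.

`run_pipeline()` chains all stages (profile → build → simulate → analyze)
from a single list or YAML config and writes CSV/JSON artifacts with a
checksummed manifest; `report()` tabulates mean Rg, var Rg, ν and R_shape
per condition.

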