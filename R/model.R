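#' Energy-model parameters for the coarse-grained chain
#'
#' One bead per residue, hard spheres of radius `bead_radius`, harmonic
#' bonds, and screened Coulomb (extended Debye-Hueckel) electrostatics in a
#' periodic cubic box. Salt is implicit through the Debye screening length;
#' counter-ions are explicit. Energies are expressed in units of kT at
#' 298 K, and the Bjerrum length is fixed at its 298 K water value
#' (temperature enters only the Metropolis weighting).
#'
#' For a 1:1 electrolyte at 298 K the Debye length is
#' `3.04 / sqrt(salt [mol/L])` Angstrom; `salt_mM = 0` gives unscreened
#' Coulomb interactions.
#'
#' @param salt_mM Monovalent salt concentration in mM (paper scan values:
#'   10, 80, 500, 1000).
#' @param bead_radius Hard-sphere radius, Angstrom.
#' @param bond_length Equilibrium bond length, Angstrom (Calpha-Calpha-like
#'   spacing).
#' @param bond_k Bond spring constant, kT/Angstrom^2; the default keeps
#'   bond-length fluctuations below 5 percent at 298 K.
#' @param bjerrum_length Bjerrum length, Angstrom (7.14 at 298 K in water).
#' @param temperature Temperature in K (Metropolis weighting only).
#' @param box_length Cubic box edge, Angstrom.
#' @param excluded_volume Hard-sphere excluded volume on/off.
#' @param restraint_distance Default disulfide-restraint target between bead
#'   centres, Angstrom. The atomistic S-S distance of 2 Angstrom is
#'   geometrically forbidden between 2-Angstrom hard spheres, so the bead
#'   adaptation restrains the pair at contact (4.0).
#' @param restraint_k Restraint spring constant, kT/Angstrom^2.
#' @return An object of class `energy_params` (named list, including the
#'   derived `debye_length`).
#' @examples
#' p <- energy_params(salt_mM = 80)
#' p$debye_length  # about 10.7 Angstrom
#' @export
energy_params <- function(salt_mM = 80, bead_radius = 2.0, bond_length = 4.1,
                          bond_k = 25, bjerrum_length = 7.14,
                          temperature = 298, box_length = 1500,
                          excluded_volume = TRUE,
                          restraint_distance = 4.0, restraint_k = 10) {
  if (salt_mM < 0) stop("salt_mM must be non-negative")
  debye_length <- debye_length_from_salt(salt_mM)
  structure(list(
    salt_mM = salt_mM, debye_length = debye_length,
    bead_radius = bead_radius, bond_length = bond_length, bond_k = bond_k,
    bjerrum_length = bjerrum_length, temperature = temperature,
    box_length = box_length, excluded_volume = excluded_volume,
    restraint_distance = restraint_distance, restraint_k = restraint_k,
    bonds_on = TRUE
  ), class = "energy_params")
}

#' Debye screening length of a 1:1 electrolyte at 298 K
#'
#' @param salt_mM Salt concentration in mM; 0 gives `Inf` (no screening).
#' @return Debye length in Angstrom.
#' @export
debye_length_from_salt <- function(salt_mM) {
  if (salt_mM == 0) return(Inf)
  3.04 / sqrt(salt_mM / 1000)
}

#' @export
print.energy_params <- function(x, ...) {
  cat(sprintf(
    "CG energy model: a = %.1f A, b0 = %.1f A (k = %.0f kT/A^2), lB = %.2f A\n",
    x$bead_radius, x$bond_length, x$bond_k, x$bjerrum_length))
  cat(sprintf("  salt %.0f mM -> Debye length %.2f A; box %.0f A; T = %.0f K\n",
              x$salt_mM, x$debye_length, x$box_length, x$temperature))
  invisible(x)
}

#' Screened-Coulomb pair energy
#'
#' Extended Debye-Hueckel interaction between two point charges of
#' hard-sphere contact distance `sigma = 2 * bead_radius`:
#' `u/kT = z_i z_j (l_B / r) exp(-(r - sigma)/l_D) / (1 + sigma/(2 l_D))`.
#' The limit `l_D -> Inf` recovers plain Coulomb `z_i z_j l_B / r`.
#'
#' @param r Centre-centre distance, Angstrom (vectorised).
#' @param z_i,z_j Integer charges.
#' @param params An [energy_params()].
#' @return Energy in kT units.
#' @export
pair_electrostatic <- function(r, z_i, z_j, params) {
  if (any(r <= 0)) stop("pair distance must be positive")
  if (z_i == 0 || z_j == 0) return(rep(0, length(r)))
  sigma <- 2 * params$bead_radius
  lD <- params$debye_length
  screen <- if (is.infinite(lD)) 1 else {
    exp(-(r - sigma) / lD) / (1 + sigma / (2 * lD))
  }
  z_i * z_j * params$bjerrum_length / r * screen
}

#' Build a bead-chain system from a mature sequence
#'
#' Maps each residue to one bead (charged per the charge scheme), adds
#' `|net charge|` monovalent counter-ions of opposite sign at uniformly
#' random non-overlapping box positions so the system is electroneutral,
#' registers disulfide restraints between cysteine pairs, and draws an
#' initial self-avoiding chain conformation.
#'
#' @param seq A mature [protein_sequence()].
#' @param params An [energy_params()].
#' @param scheme Charge scheme [residue_scale()].
#' @param restraint_pairs List of 2-vectors (or k x 2 matrix) of 1-based
#'   mature cysteine positions to restrain, or `NULL`.
#' @param seed Integer seed for the initial conformation and ion placement.
#' @return An object of class `bead_system`.
#' @export
build_system <- function(seq, params = energy_params(),
                         scheme = residue_scale("charge_scheme"),
                         restraint_pairs = NULL, seed = 1L) {
  stopifnot(inherits(seq, "protein_sequence"), inherits(params, "energy_params"))
  n <- length(seq$residues)
  charges <- scale_lookup(scheme, seq$residues)
  if (params$box_length < (n - 1) * params$bond_length) {
    warning("box edge (", params$box_length,
            " A) is smaller than the chain contour length; ",
            "periodic self-images are possible for extended conformations")
  }
  restraints <- matrix(numeric(0), ncol = 4,
                       dimnames = list(NULL, c("i", "j", "r0", "k")))
  if (!is.null(restraint_pairs)) {
    if (is.matrix(restraint_pairs)) {
      restraint_pairs <- asplit(restraint_pairs, 1)
    }
    restraints <- do.call(rbind, lapply(restraint_pairs, function(p) {
      p <- sort(as.integer(p))
      if (!all(p %in% seq$cys_positions)) {
        stop("restraint pair (", p[1], ", ", p[2],
             ") does not reference two cysteine positions; cysteines are at ",
             paste(seq$cys_positions, collapse = ", "))
      }
      c(p[1], p[2], params$restraint_distance, params$restraint_k)
    }))
    colnames(restraints) <- c("i", "j", "r0", "k")
  }
  net <- sum(charges)
  with_seed(seed, {
    coords <- cpp_saw_chain(n, params$bond_length, params$bead_radius,
                            5L * n)
    # pull restrained pairs to their targets is not needed: the restraint
    # spring does it during equilibration
    m <- abs(net)
    ions <- matrix(numeric(0), ncol = 3)
    if (m > 0) {
      ions <- matrix(stats::runif(3 * m, 0, params$box_length), ncol = 3)
      # reject-and-redraw any ion overlapping the chain or another ion
      sigma <- 2 * params$bead_radius
      for (i in seq_len(m)) {
        for (tries in 1:1000) {
          d_chain <- sqrt(colSums((t(coords) - ions[i, ])^2))
          d_ion <- if (i > 1) {
            sqrt(colSums((t(ions[seq_len(i - 1), , drop = FALSE]) -
                            ions[i, ])^2))
          } else numeric(0)
          if (all(c(d_chain, d_ion) >= sigma)) break
          ions[i, ] <- stats::runif(3, 0, params$box_length)
          if (tries == 1000) stop("box too crowded to place counter-ions")
        }
      }
    }
    structure(list(
      id = seq$id,
      coords = coords,
      charges = charges,
      ions = ions,
      ion_charges = rep(-sign(net), abs(net)),
      restraints = restraints,
      params = params,
      cys_positions = seq$cys_positions,
      seed = as.integer(seed)
    ), class = "bead_system")
  })
}

#' @export
print.bead_system <- function(x, ...) {
  cat("Bead-chain system '", x$id, "': ", nrow(x$coords), " beads (",
      sum(x$charges > 0), "+/", sum(x$charges < 0), "-), ",
      nrow(x$ions), " counter-ion(s), ", nrow(x$restraints),
      " disulfide restraint(s)\n", sep = "")
  print(x$params)
  invisible(x)
}

#' Total energy of a bead-chain system
#'
#' Sums harmonic bond terms, hard-sphere excluded volume (0, or `Inf` on
#' overlap), screened electrostatics over all charged pairs (minimum-image
#' convention), and harmonic disulfide restraints.
#'
#' @param system A [build_system()] object.
#' @return Named numeric vector with components `bond`, `excluded_volume`,
#'   `electrostatic`, `restraint`, `total` (kT units at 298 K).
#' @export
total_energy <- function(system) {
  stopifnot(inherits(system, "bead_system"))
  cpp_total_energy(system$coords, system$charges,
                   system$ions, system$ion_charges,
                   system$restraints, unclass(system$params))
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
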