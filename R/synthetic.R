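#' Parameters for gluten-like synthetic sequences
#'
#' Describes the statistical structure of wheat prolamin storage proteins:
#' a proline/glutamine-rich repetitive N-terminal domain built from hepta-
#' and dodecapeptide motifs, a small number of cysteines placed in either
#' hydrophobic or hydrophilic sequence context, and a low net charge
#' (gliadin-like +1 to glutenin-like +7 over ~250-290 residues).
#'
#' @param total_length Total sequence length (default 265, the mature
#'   LMW-GS length).
#' @param n_repeat_motifs Number of repeat motifs in the N-terminal domain.
#' @param motif_alphabet P/Q-rich motifs sampled for the repeat domain.
#' @param n_cys_hydrophobic,n_cys_hydrophilic Cysteines flanked on both
#'   sides by at least 5 residues of positive (respectively negative)
#'   Kyte-Doolittle value.
#' @param target_net_charge Net charge under the default charge scheme.
#' @param n_charge_pairs Extra balanced (+,-) charge pairs beyond the net
#'   charge, so both signs occur as in the real proteins.
#' @param seed Integer seed; generation is a pure function of
#'   (params, seed).
#' @return An object of class `gluten_params`.
#' @export
gluten_params <- function(total_length = 265L,
                          n_repeat_motifs = 10L,
                          motif_alphabet = c("PQQPFPQ", "PQQPQQPFPQQP"),
                          n_cys_hydrophobic = 6L,
                          n_cys_hydrophilic = 2L,
                          target_net_charge = 7L,
                          n_charge_pairs = 2L,
                          seed = 1L) {
  structure(list(
    total_length = as.integer(total_length),
    n_repeat_motifs = as.integer(n_repeat_motifs),
    motif_alphabet = motif_alphabet,
    n_cys_hydrophobic = as.integer(n_cys_hydrophobic),
    n_cys_hydrophilic = as.integer(n_cys_hydrophilic),
    target_net_charge = as.integer(target_net_charge),
    n_charge_pairs = as.integer(n_charge_pairs),
    seed = as.integer(seed)
  ), class = "gluten_params")
}

# flank alphabets: strictly positive / strictly negative Kyte-Doolittle
HYDROPHOBIC_AA <- c("I", "L", "V", "A", "F", "M")
HYDROPHILIC_NEUTRAL_AA <- c("Q", "N", "S", "T", "G")

#' Generate a gluten-like synthetic sequence
#'
#' Deterministic for a fixed seed. The sequence is laid out as
#' `[repeat domain][cysteine blocks separated by P/Q-rich filler]`; each
#' cysteine is embedded in an 11-residue block whose 5-residue flanks are
#' drawn from strictly hydrophobic (positive Kyte-Doolittle) or strictly
#' hydrophilic (negative Kyte-Doolittle, uncharged) alphabets, so
#' [cys_context()] classifies them by construction. Charged residues (K and
#' D) are placed in filler positions to give exactly the target net charge
#' under the default charge scheme.
#'
#' @param params A [gluten_params()].
#' @return A [protein_sequence()].
#' @examples
#' s <- generate_gluten_like_sequence(gluten_params(seed = 7))
#' charge_census(s)$net
#' @export
generate_gluten_like_sequence <- function(params = gluten_params()) {
  stopifnot(inherits(params, "gluten_params"))
  n_cys <- params$n_cys_hydrophobic + params$n_cys_hydrophilic
  n_pos <- max(params$target_net_charge, 0L) + params$n_charge_pairs
  n_neg <- max(-params$target_net_charge, 0L) + params$n_charge_pairs
  with_seed(params$seed, {
    repeats <- paste(sample(params$motif_alphabet, params$n_repeat_motifs,
                            replace = TRUE), collapse = "")
    repeat_len <- nchar(repeats)
    block_len <- 11L
    gap_min <- 4L   # keeps neighbouring blocks out of each other's windows
    tail_min <- 7L  # keeps the last cysteine a full half-window from the end
    n_filler <- params$total_length - repeat_len - n_cys * block_len
    need <- n_cys * gap_min + tail_min + n_pos + n_neg
    if (n_filler < need) {
      stop("infeasible gluten_params: total_length ", params$total_length,
           " cannot hold ", params$n_repeat_motifs, " motifs (",
           repeat_len, " residues), ", n_cys, " cysteine blocks and ",
           n_pos + n_neg, " charged residues (need at least ",
           repeat_len + n_cys * block_len + need, ")")
    }
    make_block <- function(kind) {
      flank <- function() sample(
        if (kind == "hydrophobic") HYDROPHOBIC_AA else HYDROPHILIC_NEUTRAL_AA,
        5L, replace = TRUE)
      c(flank(), "C", flank())
    }
    kinds <- sample(c(rep("hydrophobic", params$n_cys_hydrophobic),
                      rep("hydrophilic", params$n_cys_hydrophilic)))
    # split filler into (n_cys + 1) segments: before first block, gaps, tail
    n_seg <- n_cys + 1L
    seg <- rep(gap_min, n_seg)  # buffer before/between blocks
    seg[n_seg] <- tail_min
    spare <- n_filler - sum(seg)
    if (spare > 0L) {
      add <- tabulate(sample.int(n_seg, spare, replace = TRUE), nbins = n_seg)
      seg <- seg + add
    }
    filler_aa <- c("Q", "Q", "P", "Q", "S", "G", "P")
    segments <- lapply(seg, function(k) sample(filler_aa, k, replace = TRUE))
    body <- segments[[1L]]
    for (i in seq_len(n_cys)) {
      body <- c(body, make_block(kinds[i]), segments[[i + 1L]])
    }
    residues <- c(strsplit(repeats, "")[[1]], body)
    # plant charges in non-block, non-repeat filler positions
    is_filler <- residues %in% filler_aa &
      seq_along(residues) > repeat_len
    slots <- sample(which(is_filler), n_pos + n_neg)
    residues[slots[seq_len(n_pos)]] <- "K"
    if (n_neg > 0L) residues[slots[n_pos + seq_len(n_neg)]] <- "D"
    protein_sequence(residues,
                     id = sprintf("gluten_like_L%d_seed%d",
                                  params$total_length, params$seed))
  })
}

#' Reference chain conformations
#'
#' Generators for the three analytic reference shapes used to anchor the
#' polymer observables: an extended rod (`R_shape -> 12`), a freely-jointed
#' ideal chain (theta conditions, `nu = 1/2`, `R_shape -> 6`), and a
#' hard-sphere self-avoiding walk (good solvent, `nu ~ 0.588`), the last
#' produced by pivot moves from a rod start with `20 n` accepted moves of
#' equilibration. The default SAW radius of `0.25 b` keeps the chain thin
#' enough that chain lengths of a few hundred beads already scale with the
#' universal exponent; thicker beads add local stiffness and push the
#' effective exponent up through a rod-like crossover.
#'
#' @param n Number of beads (>= 2).
#' @param b Bond length in Angstrom.
#' @return An object of class `chain_conformation` with fields `kind`,
#'   `n_beads`, `bond_length`, `coords` (n x 3 matrix).
#' @examples
#' radius_of_gyration(generate_rod(2, 4.1))  # 2.05
#' @export
generate_rod <- function(n, b) {
  if (n < 2) stop("a rod needs at least 2 beads")
  if (b <= 0) stop("bond length must be positive")
  coords <- cbind(0, 0, b * (seq_len(n) - 1))
  structure(list(kind = "rod", n_beads = as.integer(n), bond_length = b,
                 coords = coords), class = "chain_conformation")
}

#' @describeIn generate_rod Freely-jointed chain: each bond an independent
#'   uniformly random direction on the sphere.
#' @param seed Integer seed (generation is a pure function of arguments).
#' @export
generate_ideal_chain <- function(n, b, seed = 1L) {
  if (n < 2) stop("a chain needs at least 2 beads")
  with_seed(seed, {
    u <- random_unit_vectors(n - 1L)
    coords <- rbind(c(0, 0, 0), apply(u * b, 2, cumsum))
    if (n == 2L) coords <- rbind(c(0, 0, 0), u * b)
    structure(list(kind = "ideal_chain", n_beads = as.integer(n),
                   bond_length = b, coords = coords),
              class = "chain_conformation")
  })
}

#' @describeIn generate_rod Hard-sphere self-avoiding chain via the pivot
#'   algorithm (no two bead centres closer than `2 * radius`).
#' @param radius Hard-sphere bead radius, must satisfy `radius < b / 2`.
#' @export
generate_saw_chain <- function(n, b, radius = 0.25 * b, seed = 1L) {
  if (n < 2) stop("a chain needs at least 2 beads")
  if (radius >= b / 2) {
    stop("radius must be < b/2 so that bonded neighbours do not overlap")
  }
  with_seed(seed, {
    coords <- cpp_saw_chain(as.integer(n), b, radius, 20L * as.integer(n))
    structure(list(kind = "saw_chain", n_beads = as.integer(n),
                   bond_length = b, radius = radius, coords = coords),
              class = "chain_conformation")
  })
}

#' Reference chain ensembles
#'
#' Convenience ensemble generators: `generate_ideal_ensemble()` draws
#' independent freely-jointed chains; `generate_saw_ensemble()` samples a
#' single pivot walk every `stride` accepted moves after `20 n` accepted
#' moves of equilibration (the pivot algorithm decorrelates global chain
#' observables within a few tens of accepted moves, so strided samples are
#' effectively independent).
#'
#' @param n_chains Number of configurations.
#' @param n Beads per chain.
#' @param b Bond length, Angstrom.
#' @param seed Integer seed.
#' @return A list of n x 3 coordinate matrices, usable wherever ensemble
#'   frames are accepted (e.g. [shape_factor()], [debye_scattering()]).
#' @examples
#' fr <- generate_ideal_ensemble(100, n = 50, b = 1, seed = 2)
#' shape_factor(fr)$R_shape  # near 6
#' @export
generate_ideal_ensemble <- function(n_chains, n, b = 1, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n_chains), function(k) {
      u <- random_unit_vectors(n - 1L)
      rbind(c(0, 0, 0), apply(u * b, 2, cumsum))
    })
  })
}

#' @describeIn generate_ideal_ensemble Strided pivot sampling of
#'   hard-sphere self-avoiding chains.
#' @param radius Hard-sphere radius (`< b/2`).
#' @param stride Accepted pivot moves between samples.
#' @export
generate_saw_ensemble <- function(n_chains, n, b = 1, radius = 0.25 * b,
                                  stride = 20L, seed = 1L) {
  if (radius >= b / 2) stop("radius must be < b/2")
  with_seed(seed, {
    cpp_saw_ensemble(as.integer(n), b, radius, as.integer(n_chains),
                     20L * as.integer(n), as.integer(stride))
  })
}

# m x 3 matrix of uniformly random unit vectors
random_unit_vectors <- function(m) {
  z <- stats::runif(m, -1, 1)
  phi <- stats::runif(m, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  cbind(r * cos(phi), r * sin(phi), z)
}

#' @export
print.chain_conformation <- function(x, ...) {
  cat("Chain conformation (", x$kind, "): ", x$n_beads, " beads, b = ",
      x$bond_length, " A\n", sep = "")
  invisible(x)
}

#' Write a minimal PDB-like snapshot
#'
#' One CA pseudo-atom per bead (residue GLY, chain A), suitable for quick
#' visualisation. Only the first frame of an ensemble is written.
#'
#' @param x A `chain_conformation`, coordinate matrix, or `cg_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fr <- if (inherits(x, "cg_ensemble")) x$frames[[1]]
        else if (inherits(x, "chain_conformation")) x$coords
        else as.matrix(x)
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(fr)), seq_len(nrow(fr)), fr[, 1], fr[, 2], fr[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write coordinates in XYZ format
#'
#' Plain-text XYZ: atom count, comment, then one `element x y z` line per
#' bead. An ensemble writes one concatenated block per frame.
#'
#' @param x A `chain_conformation`, coordinate matrix, or `cg_ensemble`.
#' @param path Output path.
#' @param element Element symbol per line (recycled).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, element = "C") {
  frames <- if (inherits(x, "cg_ensemble")) x$frames
            else if (inherits(x, "chain_conformation")) list(x$coords)
            else list(as.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d", k), con)
    writeLines(sprintf("%s %.4f %.4f %.4f",
                       rep_len(element, nrow(fr)), fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  invisible(path)
}
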