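# Independent brute-force oracles, deliberately written as plain double
# loops with none of the package's computational shortcuts.

# minimum-image component
mi_oracle <- function(d, L) d - L * round(d / L)

# full energy breakdown by direct double loops over every pair
oracle_energy <- function(system) {
  p <- system$params
  x <- rbind(system$coords, system$ions)
  z <- c(system$charges, system$ion_charges)
  N <- nrow(x)
  n <- nrow(system$coords)
  L <- p$box_length
  sigma <- 2 * p$bead_radius
  e_bond <- 0
  if (n > 1) {
    for (i in 1:(n - 1)) {
      r <- sqrt(sum(mi_oracle(x[i, ] - x[i + 1, ], L)^2))
      e_bond <- e_bond + 0.5 * p$bond_k * (r - p$bond_length)^2
    }
  }
  e_ev <- 0
  e_el <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      r <- sqrt(sum(mi_oracle(x[i, ] - x[j, ], L)^2))
      if (p$excluded_volume && r < sigma) e_ev <- Inf
      if (z[i] != 0 && z[j] != 0) {
        screen <- if (is.infinite(p$debye_length)) 1 else {
          exp(-(r - sigma) / p$debye_length) /
            (1 + sigma / (2 * p$debye_length))
        }
        e_el <- e_el + z[i] * z[j] * p$bjerrum_length / r * screen
      }
    }
  }
  e_rs <- 0
  if (nrow(system$restraints) > 0) {
    for (k in seq_len(nrow(system$restraints))) {
      row <- unname(system$restraints[k, ])
      r <- sqrt(sum(mi_oracle(x[row[1], ] - x[row[2], ], L)^2))
      e_rs <- e_rs + 0.5 * row[4] * (r - row[3])^2
    }
  }
  c(bond = e_bond, excluded_volume = e_ev, electrostatic = e_el,
    restraint = e_rs, total = e_bond + e_ev + e_el + e_rs)
}

# Rg via the pair-distance identity Rg^2 = (1 / 2N^2) sum_ij d_ij^2
oracle_rg <- function(m) {
  d <- as.matrix(stats::dist(m))
  sqrt(sum(d^2) / (2 * nrow(m)^2))
}

# contact frequencies via dist()
oracle_contact <- function(frames, cutoff, exclusion) {
  n <- nrow(frames[[1]])
  acc <- matrix(0, n, n)
  for (fr in frames) {
    d <- as.matrix(stats::dist(fr))
    hit <- (d < cutoff) & (abs(row(d) - col(d)) > exclusion)
    acc <- acc + hit
  }
  acc / length(frames)
}

# mean squared bond length of a free harmonic bond (radial Boltzmann weight)
oracle_mean_sq_bond <- function(r0, k) {
  w <- function(r) r^2 * exp(-0.5 * k * (r - r0)^2)
  num <- stats::integrate(function(r) r^2 * w(r), 0, r0 + 10 / sqrt(k))$value
  den <- stats::integrate(w, 0, r0 + 10 / sqrt(k))$value
  num / den
}

# standard error of a mean from correlated series via batch means
batch_se <- function(x, n_batches = 10) {
  b <- split(x, cut(seq_along(x), n_batches, labels = FALSE))
  means <- vapply(b, mean, numeric(1))
  stats::sd(means) / sqrt(length(means))
}
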