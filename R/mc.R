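#' Monte Carlo sampler configuration
#'
#' Move mix and run lengths for canonical Metropolis sampling. A sweep is
#' one attempted move per particle (chain beads plus counter-ions). Step
#' sizes are auto-tuned toward 30-50 percent acceptance during
#' equilibration and frozen for production, so the production run is
#' strictly canonical.
#'
#' The move set is the standard coarse-grained one: single-bead
#' translation, pivot rotation, crankshaft rotation, whole-chain
#' translation, whole-chain rotation, and counter-ion translation.
#' Equilibrium averages are move-set independent; only mixing efficiency
#' differs.
#'
#' @param n_equilibration_sweeps,n_production_sweeps Run lengths in sweeps.
#' @param thinning Save every k-th produced configuration (default 10).
#' @param move_prob Named numeric vector of per-move probabilities over
#'   `c("bead", "pivot", "crankshaft", "chain_translation",
#'   "chain_rotation", "counterion")`; normalised to sum to 1.
#' @param step_init Initial step sizes: translations in Angstrom, rotations
#'   in radians, same order as `move_prob`.
#' @param temperature_K Sampling temperature.
#' @param seed Master RNG seed.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(n_equilibration_sweeps = 500L,
                      n_production_sweeps = 2000L,
                      thinning = 10L,
                      move_prob = c(bead = 0.55, pivot = 0.2,
                                    crankshaft = 0.15,
                                    chain_translation = 0.025,
                                    chain_rotation = 0.025,
                                    counterion = 0.05),
                      step_init = c(bead = 2, pivot = 0.8, crankshaft = 1.2,
                                    chain_translation = 10,
                                    chain_rotation = 0.5, counterion = 50),
                      temperature_K = 298,
                      seed = 1L) {
  move_names <- c("bead", "pivot", "crankshaft", "chain_translation",
                  "chain_rotation", "counterion")
  stopifnot(all(move_names %in% names(move_prob)),
            all(move_names %in% names(step_init)))
  move_prob <- move_prob[move_names]
  if (any(move_prob < 0) || sum(move_prob) <= 0) {
    stop("move probabilities must be non-negative and not all zero")
  }
  move_prob <- move_prob / sum(move_prob)
  if (thinning < 1L) stop("thinning must be >= 1")
  structure(list(
    n_equilibration_sweeps = as.integer(n_equilibration_sweeps),
    n_production_sweeps = as.integer(n_production_sweeps),
    thinning = as.integer(thinning),
    move_prob = move_prob,
    step_init = step_init[move_names],
    temperature_K = temperature_K,
    seed = as.integer(seed)
  ), class = "mc_config")
}

#' Simulated-annealing schedule
#'
#' A descending temperature ladder cycled repeatedly; only configurations
#' produced at the lowest (target) temperature enter the production
#' ensemble. The defaults mirror the protocol of ten temperatures spanning
#' 400 to 300 K with 1000 configurations per temperature, 200 equilibration
#' cycles and 800 production cycles, giving 2e5 and 8e5 produced
#' target-temperature configurations respectively (see [anneal_counts()]).
#'
#' @param temperatures Strictly positive, strictly descending ladder in K.
#' @param configs_per_temperature Sweeps produced at each ladder rung per
#'   cycle.
#' @param n_cycles_equilibration,n_cycles_production Cycle counts.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(temperatures = seq(400, 300, length.out = 10),
                            configs_per_temperature = 1000L,
                            n_cycles_equilibration = 200L,
                            n_cycles_production = 800L) {
  if (any(temperatures <= 0)) stop("temperatures must be positive")
  if (is.unsorted(rev(temperatures), strictly = TRUE)) {
    stop("temperature ladder must be strictly descending")
  }
  structure(list(
    temperatures = temperatures,
    configs_per_temperature = as.integer(configs_per_temperature),
    n_cycles_equilibration = as.integer(n_cycles_equilibration),
    n_cycles_production = as.integer(n_cycles_production)
  ), class = "anneal_schedule")
}

#' Configuration bookkeeping of an annealing schedule
#'
#' @param schedule An [anneal_schedule()].
#' @param thinning Saving stride applied to target-temperature production.
#' @return Named list: configurations produced at the target temperature
#'   during equilibration and production, and the saved count after
#'   thinning.
#' @export
anneal_counts <- function(schedule, thinning = 10L) {
  stopifnot(inherits(schedule, "anneal_schedule"))
  per_cycle <- schedule$configs_per_temperature
  list(
    produced_equilibration = schedule$n_cycles_equilibration * per_cycle,
    produced_production = schedule$n_cycles_production * per_cycle,
    saved_production = (schedule$n_cycles_production * per_cycle) %/%
      as.integer(thinning)
  )
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change `delta_E` (kT units at 298 K) with probability
#' `min(1, exp(-delta_E * 298 / temperature_K))`. Exposed separately so the
#' acceptance statistics can be verified against the binomial closed form.
#'
#' @param delta_E Energy change(s), kT at 298 K.
#' @param temperature_K Sampling temperature.
#' @return Logical vector of acceptance decisions (consumes one uniform
#'   draw per proposal).
#' @export
metropolis_accept <- function(delta_E, temperature_K = 298) {
  p <- pmin(1, exp(-delta_E * 298 / temperature_K))
  stats::runif(length(delta_E)) < p
}

# assemble the C++ config list
cpp_config <- function(config, n_sweeps, record, tune, step, temperature_K) {
  list(
    beta_rel = 298 / temperature_K,
    n_sweeps = as.integer(n_sweeps),
    thin = config$thinning,
    record = record,
    tune = tune,
    move_prob = unname(config$move_prob),
    step = unname(step))
}

#' Perform a single Metropolis step
#'
#' Attempts one move of the given type on a system and returns the
#' (possibly unchanged) system together with the acceptance flag. Mostly a
#' diagnostic surface; production sampling goes through [run_mc()].
#'
#' @param system A [build_system()] object.
#' @param move One of `"bead"`, `"pivot"`, `"crankshaft"`,
#'   `"chain_translation"`, `"chain_rotation"`, `"counterion"`.
#' @param config An [mc_config()] (step sizes and temperature are taken
#'   from it).
#' @return List with elements `system` and `accepted`.
#' @export
metropolis_step <- function(system, move = "bead", config = mc_config()) {
  stopifnot(inherits(system, "bead_system"))
  moves <- names(config$move_prob)
  move <- match.arg(move, moves)
  prob <- stats::setNames(rep(0, 6), moves)
  prob[move] <- 1
  cfg <- cpp_config(config, n_sweeps = 1L, record = FALSE, tune = FALSE,
                    step = config$step_init, temperature_K = config$temperature_K)
  cfg$move_prob <- unname(prob)
  cfg$attempts_per_sweep <- 1L
  res <- cpp_run_mc(system$coords, system$charges, system$ions,
                    system$ion_charges, system$restraints,
                    unclass(system$params), cfg)
  system$coords <- res$coords
  system$ions <- res$ions
  list(system = system, accepted = sum(res$accepts) == 1)
}

#' Run canonical Metropolis Monte Carlo
#'
#' Equilibrates with step-size auto-tuning, freezes the tuned step sizes,
#' and samples a production run, saving every `thinning`-th configuration
#' with its energy, radius of gyration and end-to-end distance. Bitwise
#' reproducible for a fixed seed and configuration.
#'
#' @param system A [build_system()] object.
#' @param config An [mc_config()].
#' @return An object of class `cg_ensemble`: saved chain frames (list of
#'   n x 3 matrices, coordinates continuous in Angstrom), per-frame scalars
#'   `energy`, `rg`, `ree`, per-move `acceptance` rates, the frozen step
#'   sizes, and metadata (`config`, `params`, `seed`, `cys_positions`).
#' @export
run_mc <- function(system, config = mc_config()) {
  stopifnot(inherits(system, "bead_system"), inherits(config, "mc_config"))
  if (config$n_production_sweeps < 1L) {
    stop("zero production sweeps would give an empty ensemble")
  }
  with_seed(config$seed, {
    step <- config$step_init
    if (config$n_equilibration_sweeps > 0L) {
      eq <- cpp_run_mc(system$coords, system$charges, system$ions,
                       system$ion_charges, system$restraints,
                       unclass(system$params),
                       cpp_config(config, config$n_equilibration_sweeps,
                                  record = FALSE, tune = TRUE, step = step,
                                  temperature_K = config$temperature_K))
      system$coords <- eq$coords
      system$ions <- eq$ions
      step[] <- eq$step
    }
    pr <- cpp_run_mc(system$coords, system$charges, system$ions,
                     system$ion_charges, system$restraints,
                     unclass(system$params),
                     cpp_config(config, config$n_production_sweeps,
                                record = TRUE, tune = FALSE, step = step,
                                temperature_K = config$temperature_K))
    acceptance <- stats::setNames(
      ifelse(pr$attempts > 0, pr$accepts / pr$attempts, NA_real_),
      names(config$move_prob))
    structure(list(
      id = system$id,
      frames = pr$frames,
      ion_frames = pr$ion_frames,
      energy = pr$energy,
      rg = pr$rg,
      ree = pr$ree,
      acceptance = acceptance,
      step = stats::setNames(as.numeric(pr$step), names(config$move_prob)),
      energy_drift = abs(pr$energy_incremental - pr$energy_recomputed),
      config = config,
      params = system$params,
      cys_positions = system$cys_positions,
      restraints = system$restraints,
      temperature_K = config$temperature_K,
      seed = config$seed
    ), class = "cg_ensemble")
  })
}

#' Run an annealed simulation
#'
#' Cycles through the descending temperature ladder; configurations are
#' recorded (with thinning) only at the lowest, target temperature and only
#' during production cycles. A single-temperature schedule reduces to plain
#' [run_mc()] sampling at that temperature.
#'
#' @param system A [build_system()] object.
#' @param schedule An [anneal_schedule()].
#' @param config An [mc_config()] (its sweep counts are ignored; the
#'   schedule drives run lengths).
#' @return A `cg_ensemble` of target-temperature production frames.
#' @export
run_annealed <- function(system, schedule, config = mc_config()) {
  stopifnot(inherits(system, "bead_system"),
            inherits(schedule, "anneal_schedule"),
            inherits(config, "mc_config"))
  temps <- schedule$temperatures
  target <- temps[length(temps)]
  with_seed(config$seed, {
    step <- config$step_init
    frames <- list(); ion_frames <- list()
    energy <- numeric(0); rg <- numeric(0); ree <- numeric(0)
    att <- rep(0, 6); acc <- rep(0, 6)
    drift <- 0
    n_cycles <- schedule$n_cycles_equilibration + schedule$n_cycles_production
    for (cycle in seq_len(n_cycles)) {
      production <- cycle > schedule$n_cycles_equilibration
      for (temp in temps) {
        at_target <- temp == target
        res <- cpp_run_mc(system$coords, system$charges, system$ions,
                          system$ion_charges, system$restraints,
                          unclass(system$params),
                          cpp_config(config, schedule$configs_per_temperature,
                                     record = production && at_target,
                                     tune = !production, step = step,
                                     temperature_K = temp))
        system$coords <- res$coords
        system$ions <- res$ions
        if (!production) step[] <- res$step
        if (production && at_target) {
          frames <- c(frames, res$frames)
          ion_frames <- c(ion_frames, res$ion_frames)
          energy <- c(energy, res$energy)
          rg <- c(rg, res$rg)
          ree <- c(ree, res$ree)
          att <- att + res$attempts
          acc <- acc + res$accepts
          drift <- max(drift, abs(res$energy_incremental - res$energy_recomputed))
        }
      }
    }
    acceptance <- stats::setNames(ifelse(att > 0, acc / att, NA_real_),
                                  names(config$move_prob))
    structure(list(
      id = system$id,
      frames = frames, ion_frames = ion_frames,
      energy = energy, rg = rg, ree = ree,
      acceptance = acceptance,
      step = stats::setNames(as.numeric(step), names(config$move_prob)),
      energy_drift = drift,
      config = config, params = system$params,
      cys_positions = system$cys_positions,
      restraints = system$restraints,
      schedule = schedule,
      temperature_K = target,
      seed = config$seed
    ), class = "cg_ensemble")
  })
}

#' Scan salt concentrations
#'
#' Runs an independent simulation of the same sequence at each salt
#' concentration (Debye length derived per salt), with deterministic child
#' seeds offset from the master seed.
#'
#' @param seq A mature [protein_sequence()].
#' @param params An [energy_params()] template (its `salt_mM` is replaced).
#' @param salts Salt concentrations in mM (paper scan: 10, 80, 500, 1000).
#' @param config An [mc_config()].
#' @param scheme Charge scheme.
#' @param restraint_pairs Passed to [build_system()].
#' @return Named list of `cg_ensemble`s keyed by salt concentration.
#' @export
salt_scan <- function(seq, params = energy_params(),
                      salts = c(10, 80, 500, 1000),
                      config = mc_config(),
                      scheme = residue_scale("charge_scheme"),
                      restraint_pairs = NULL) {
  if (length(salts) == 0L) stop("salts must be non-empty")
  if (any(salts <= 0)) stop("salt concentrations must be positive")
  out <- lapply(seq_along(salts), function(i) {
    p <- params
    p$salt_mM <- salts[i]
    p$debye_length <- debye_length_from_salt(salts[i])
    child <- config
    child$seed <- config$seed + i - 1L
    sys <- build_system(seq, p, scheme = scheme,
                        restraint_pairs = restraint_pairs,
                        seed = child$seed)
    run_mc(sys, child)
  })
  names(out) <- as.character(salts)
  out
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("CG Monte Carlo ensemble '", x$id, "': ", length(x$frames),
      " saved frames at ", x$temperature_K, " K\n", sep = "")
  cat(sprintf("  mean Rg %.2f A (var %.2f), <Ree^2>/<Rg^2> = %.2f\n",
              mean(x$rg), stats::var(x$rg), mean(x$ree^2) / mean(x$rg^2)))
  cat("  acceptance:",
      paste(names(x$acceptance),
            sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cg_ensemble <- function(object, ...) {
  st <- shape_factor(object)
  out <- list(
    id = object$id,
    n_frames = length(object$frames),
    temperature_K = object$temperature_K,
    salt_mM = object$params$salt_mM,
    mean_Rg = st$mean_Rg, var_Rg = st$var_Rg,
    mean_sq_Ree = st$mean_sq_Ree, mean_sq_Rg = st$mean_sq_Rg,
    R_shape = st$R_shape, nu = st$nu,
    acceptance = object$acceptance,
    energy_drift = object$energy_drift)
  class(out) <- "summary.cg_ensemble"
  out
}

#' @export
print.summary.cg_ensemble <- function(x, ...) {
  cat("Ensemble '", x$id, "' (", x$n_frames, " frames, ",
      x$salt_mM, " mM, ", x$temperature_K, " K)\n", sep = "")
  cat(sprintf("  mean Rg  %8.2f A   var Rg %8.2f A^2\n", x$mean_Rg, x$var_Rg))
  cat(sprintf("  R_shape  %8.2f     nu     %8.3f\n", x$R_shape, x$nu))
  cat(sprintf("  max |incremental - recomputed| energy: %.2e kT\n",
              x$energy_drift))
  invisible(x)
}

#' @export
plot.cg_ensemble <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$rg), x$rg, type = "l", xlab = "saved frame",
                 ylab = "Rg (A)", main = x$id, ...)
  graphics::hist(x$rg, breaks = 30, freq = FALSE, xlab = "Rg (A)",
                 main = "Rg distribution")
  invisible(x)
}
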