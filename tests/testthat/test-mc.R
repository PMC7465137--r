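test_that("config and schedule validation", {
  expect_error(mc_config(thinning = 0), "thinning")
  expect_error(anneal_schedule(temperatures = c(300, 400)), "descending")
  expect_error(anneal_schedule(temperatures = c(400, -3)), "positive")
  cfg <- mc_config(move_prob = c(bead = 2, pivot = 1, crankshaft = 1,
                                 chain_translation = 0, chain_rotation = 0,
                                 counterion = 0))
  expect_equal(sum(cfg$move_prob), 1)
})

test_that("annealing bookkeeping reproduces the published configuration counts", {
  sch <- anneal_schedule()  # 10 temperatures 400 -> 300 K, 1000 per rung
  counts <- anneal_counts(sch, thinning = 10)
  expect_equal(counts$produced_equilibration, 2e5)  # 200 cycles x 1000
  expect_equal(counts$produced_production, 8e5)     # 800 cycles x 1000
  expect_equal(counts$saved_production, 8e4)
  expect_length(sch$temperatures, 10)
  expect_equal(range(sch$temperatures), c(300, 400))
})

test_that("Metropolis acceptance frequency matches the binomial closed form", {
  set.seed(123)
  n <- 1e5
  acc <- metropolis_accept(rep(1, n))       # dE = +1 kT
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(acc) - p), 3 * se)
  # dE <= 0 always accepted
  expect_true(all(metropolis_accept(c(0, -0.5, -10))))
  # temperature scaling: at 596 K a +2 kT(298) proposal accepts like exp(-1)
  set.seed(321)
  acc2 <- metropolis_accept(rep(2, n), temperature_K = 596)
  expect_lt(abs(mean(acc2) - p), 3 * se)
})

test_that("single metropolis_step returns a valid system and flag", {
  s <- generate_gluten_like_sequence(
    gluten_params(total_length = 120, n_repeat_motifs = 4,
                  n_cys_hydrophobic = 2, target_net_charge = 1,
                  n_charge_pairs = 1, seed = 3))
  sys <- build_system(s, energy_params(), seed = 1)
  set.seed(9)
  out <- metropolis_step(sys, "bead")
  expect_type(out$accepted, "logical")
  expect_s3_class(out$system, "bead_system")
  expect_equal(dim(out$system$coords), dim(sys$coords))
})

test_that("run_mc is reproducible, thins correctly and conserves energy", {
  s <- generate_gluten_like_sequence(
    gluten_params(total_length = 110, n_repeat_motifs = 3,
                  n_cys_hydrophobic = 2, target_net_charge = 2,
                  n_charge_pairs = 1, seed = 4))
  sys <- build_system(s, energy_params(salt_mM = 80), seed = 7)
  cfg <- mc_config(n_equilibration_sweeps = 100, n_production_sweeps = 400,
                   thinning = 10, seed = 42)
  e1 <- run_mc(sys, cfg)
  e2 <- run_mc(sys, cfg)
  expect_identical(e1$frames, e2$frames)
  expect_identical(e1$energy, e2$energy)
  expect_equal(length(e1$frames), 400 %/% 10)
  # incremental bookkeeping agrees with full recomputation
  expect_lt(e1$energy_drift, 1e-6)
  # acceptance rates strictly inside (0, 1) for enabled moves on this system
  enabled <- c("bead", "pivot", "crankshaft")
  expect_true(all(e1$acceptance[enabled] > 0 & e1$acceptance[enabled] < 1))
  # hard-sphere invariant holds in every saved frame
  expect_true(all(vapply(e1$frames,
                         function(fr) min(stats::dist(fr)) >= 4 - 1e-9,
                         logical(1))))
  expect_error(run_mc(sys, mc_config(n_production_sweeps = 0)), "empty")
})

test_that("non-interacting chains reproduce the freely-jointed closed form", {
  # charges off, excluded volume off: bonds factorise, so
  # <Ree^2> = (n-1) <b^2> with <b^2> from the radial Boltzmann integral
  n <- 40
  s <- protein_sequence(strrep("G", n))
  par <- energy_params(excluded_volume = FALSE)
  sys <- build_system(s, par, seed = 11)
  cfg <- mc_config(n_equilibration_sweeps = 300, n_production_sweeps = 3000,
                   thinning = 10, seed = 13,
                   move_prob = c(bead = 0.6, pivot = 0.4, crankshaft = 0,
                                 chain_translation = 0, chain_rotation = 0,
                                 counterion = 0))
  ens <- run_mc(sys, cfg)
  expected <- (n - 1) * oracle_mean_sq_bond(par$bond_length, par$bond_k)
  ree2 <- ens$ree^2
  se <- batch_se(ree2)
  expect_lt(abs(mean(ree2) - expected), 3.5 * se)
})

test_that("a two-bead harmonic dimer samples the Boltzmann bond distribution", {
  s <- protein_sequence("GG")
  par <- energy_params(excluded_volume = FALSE)
  sys <- build_system(s, par, seed = 2)
  cfg <- mc_config(n_equilibration_sweeps = 500,
                   n_production_sweeps = 40000, thinning = 20, seed = 17,
                   move_prob = c(bead = 1, pivot = 0, crankshaft = 0,
                                 chain_translation = 0, chain_rotation = 0,
                                 counterion = 0))
  ens <- run_mc(sys, cfg)
  r <- ens$ree  # for 2 beads Ree is the bond length
  # closed form: p(r) proportional to r^2 exp(-k (r - r0)^2 / 2)
  k <- par$bond_k; r0 <- par$bond_length
  dens <- function(x) x^2 * exp(-0.5 * k * (x - r0)^2)
  norm <- stats::integrate(dens, 0, r0 + 1.5)$value
  breaks <- stats::quantile(r, probs = seq(0, 1, length.out = 11))
  breaks[1] <- 0; breaks[11] <- r0 + 1.5
  obs <- table(cut(r, breaks))
  probs <- vapply(seq_len(10), function(i) {
    stats::integrate(dens, breaks[i], breaks[i + 1])$value / norm
  }, numeric(1))
  gof <- stats::chisq.test(as.numeric(obs), p = probs / sum(probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("hard-sphere MC chains agree with the pivot-algorithm oracle", {
  # same geometry sampled by two independent routes
  n <- 50
  s <- protein_sequence(strrep("G", n))
  sys <- build_system(s, energy_params(), seed = 21)
  cfg <- mc_config(n_equilibration_sweeps = 300, n_production_sweeps = 2500,
                   thinning = 10, seed = 23,
                   move_prob = c(bead = 0.5, pivot = 0.35, crankshaft = 0.15,
                                 chain_translation = 0, chain_rotation = 0,
                                 counterion = 0))
  ens <- run_mc(sys, cfg)
  # pivot oracle at identical bond length and hard-sphere radius
  oracle <- generate_saw_ensemble(400, n = n, b = 4.1, radius = 2.0,
                                  stride = 20, seed = 29)
  rg_o <- radius_of_gyration(oracle)
  se <- sqrt(batch_se(ens$rg)^2 + (sd(rg_o) / sqrt(length(rg_o)))^2)
  expect_lt(abs(mean(ens$rg) - mean(rg_o)), 4 * se)
})

test_that("annealed runs record only target-temperature production", {
  s <- generate_gluten_like_sequence(
    gluten_params(total_length = 90, n_repeat_motifs = 2,
                  n_cys_hydrophobic = 2, target_net_charge = 1,
                  n_charge_pairs = 0, seed = 6))
  sys <- build_system(s, energy_params(), seed = 3)
  sch <- anneal_schedule(temperatures = c(400, 350, 300),
                         configs_per_temperature = 50,
                         n_cycles_equilibration = 2,
                         n_cycles_production = 4)
  cfg <- mc_config(thinning = 10, seed = 19)
  ens <- run_annealed(sys, sch, cfg)
  expect_equal(length(ens$frames), 4 * 50 %/% 10)
  expect_equal(ens$temperature_K, 300)
  expect_lt(ens$energy_drift, 1e-6)
})

test_that("a degenerate single-temperature ladder matches plain run_mc", {
  s <- protein_sequence(strrep("G", 30))
  sys <- build_system(s, energy_params(), seed = 8)
  cpt <- 50L
  sch <- anneal_schedule(temperatures = 298, configs_per_temperature = cpt,
                         n_cycles_equilibration = 2, n_cycles_production = 6)
  cfg <- mc_config(thinning = 10, seed = 77)
  a <- run_annealed(sys, sch, cfg)
  cfg2 <- mc_config(n_equilibration_sweeps = 2L * cpt,
                    n_production_sweeps = 6L * cpt, thinning = 10, seed = 77)
  b <- run_mc(sys, cfg2)
  expect_equal(length(a$frames), length(b$frames))
  expect_equal(mean(a$rg), mean(b$rg), tolerance = 0.25)
})

test_that("salt_scan produces one ensemble per concentration", {
  s <- generate_gluten_like_sequence(
    gluten_params(total_length = 40, n_repeat_motifs = 2,
                  n_cys_hydrophobic = 0, n_cys_hydrophilic = 0,
                  target_net_charge = 2, n_charge_pairs = 0, seed = 5))
  cfg <- mc_config(n_equilibration_sweeps = 50, n_production_sweeps = 100,
                   seed = 31)
  out <- salt_scan(s, energy_params(), salts = c(10, 1000), config = cfg)
  expect_named(out, c("10", "1000"))
  expect_equal(out[["10"]]$params$salt_mM, 10)
  expect_equal(out[["1000"]]$params$debye_length, 3.04, tolerance = 0.01)
  single <- salt_scan(s, energy_params(), salts = 80, config = cfg)
  expect_length(single, 1)
  expect_error(salt_scan(s, energy_params(), salts = numeric(0)), "non-empty")
  expect_error(salt_scan(s, energy_params(), salts = -5), "positive")
})
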