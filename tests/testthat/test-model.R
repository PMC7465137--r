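test_that("Debye length follows the 1:1 electrolyte closed form", {
  expect_equal(debye_length_from_salt(1000), 3.04, tolerance = 0.01)
  expect_equal(debye_length_from_salt(10), 3.04 / sqrt(0.01), tolerance = 0.01)
  expect_identical(debye_length_from_salt(0), Inf)
  expect_error(energy_params(salt_mM = -1), "non-negative")
})

test_that("screened pair potential has the right limits and monotonicity", {
  p_inf <- energy_params(salt_mM = 0)
  # Coulomb limit: r = Bjerrum length, unit charges -> exactly 1 kT
  expect_equal(pair_electrostatic(7.14, 1, 1, p_inf), 1.0)
  expect_equal(pair_electrostatic(5, 0, 1, p_inf), 0)
  expect_error(pair_electrostatic(0, 1, 1, p_inf), "positive")
  # screening strictly reduces repulsion at higher salt for all r > sigma
  p10 <- energy_params(salt_mM = 10)
  p500 <- energy_params(salt_mM = 500)
  r <- seq(4.5, 60, by = 0.5)
  expect_true(all(pair_electrostatic(r, 1, 1, p500) <
                    pair_electrostatic(r, 1, 1, p10)))
  # screened energy vanishes as the Debye length shrinks to zero
  p_tiny <- energy_params(salt_mM = 1e8)
  expect_lt(pair_electrostatic(10, 1, 1, p_tiny), 1e-6)
  # attraction for unlike charges
  expect_lt(pair_electrostatic(10, 1, -1, p10), 0)
})

test_that("build_system adds counter-ions for electroneutrality", {
  fx <- gluten_fixture("lmw_glutenin")
  sys <- build_system(fx$mature, energy_params(), seed = 2)
  expect_equal(nrow(sys$ions), 7)    # net +7
  expect_equal(sum(sys$charges) + sum(sys$ion_charges), 0)
  polyg <- protein_sequence(strrep("G", 50))
  sys0 <- build_system(polyg, energy_params(), seed = 2)
  expect_equal(nrow(sys0$ions), 0)
  # initial chain is overlap-free and continuous
  d <- sqrt(rowSums(diff(sys$coords)^2))
  expect_true(all(abs(d - 4.1) < 1e-9))
  expect_gte(min(stats::dist(sys$coords)), 4.0 - 1e-9)
})

test_that("restraint registration validates cysteine pairs", {
  fx <- gluten_fixture("alpha_gliadin")
  sys <- build_system(fx$mature, energy_params(),
                      restraint_pairs = fx$restraint_pairs, seed = 1)
  expect_equal(nrow(sys$restraints), 3)
  expect_equal(sys$restraints[, "i"], c(108, 139, 151), ignore_attr = TRUE)
  expect_equal(sys$restraints[, "r0"], rep(4.0, 3), ignore_attr = TRUE)
  expect_error(
    build_system(fx$mature, energy_params(),
                 restraint_pairs = list(c(10, 108)), seed = 1),
    "cysteine")
})

test_that("total energy vanishes for trivial configurations", {
  two <- protein_sequence("GG")
  sys <- build_system(two, energy_params(), seed = 1)
  sys$coords <- rbind(c(0, 0, 0), c(0, 0, 4.1))
  e <- total_energy(sys)
  expect_equal(unname(e["total"]), 0)
  # a restrained pair exactly at target distance contributes nothing
  cc <- protein_sequence("CGGGGGGC")
  sysr <- build_system(cc, energy_params(), restraint_pairs = list(c(1, 8)),
                       seed = 1)
  d18 <- sqrt(sum((sysr$coords[8, ] - sysr$coords[1, ])^2))
  expect_equal(unname(total_energy(sysr)["restraint"]),
               0.5 * 10 * (d18 - 4)^2, tolerance = 1e-9)
})

test_that("total_energy matches the brute-force double-loop oracle", {
  set.seed(99)
  for (rep in 1:5) {
    res <- sample(c("K", "D", "G", "Q", "C", "A"), 20, TRUE)
    res[c(3, 15)] <- "C"
    s <- protein_sequence(res)
    params <- energy_params(salt_mM = sample(c(0, 10, 80, 1000), 1),
                            excluded_volume = FALSE)
    sys <- build_system(s, params, restraint_pairs = list(c(3, 15)),
                        seed = rep)
    # scatter the chain randomly (bonds strained, distances arbitrary)
    sys$coords <- matrix(runif(60, 0, 40), ncol = 3)
    e <- total_energy(sys)
    o <- oracle_energy(sys)
    expect_equal(e[["total"]], o[["total"]], tolerance = 1e-9)
    expect_equal(e[["bond"]], o[["bond"]], tolerance = 1e-9)
    expect_equal(e[["electrostatic"]], o[["electrostatic"]], tolerance = 1e-9)
    expect_equal(e[["restraint"]], o[["restraint"]], tolerance = 1e-9)
  }
})

test_that("hard-sphere overlap is flagged as an infinite term", {
  s <- protein_sequence("GGGG")
  sys <- build_system(s, energy_params(), seed = 1)
  sys$coords[3, ] <- sys$coords[1, ] + c(1, 0, 0)  # non-bonded overlap
  e <- total_energy(sys)
  expect_true(is.infinite(e[["excluded_volume"]]))
  expect_true(is.infinite(e[["total"]]))
  expect_true(is.infinite(oracle_energy(sys)[["total"]]))
})

test_that("energy is invariant under rigid motion and periodic images", {
  fx <- gluten_fixture("alpha_gliadin")
  sys <- build_system(fx$mature, energy_params(salt_mM = 80), seed = 5)
  e0 <- total_energy(sys)[["total"]]
  shifted <- sys
  shifted$coords <- sys$coords + rep(c(333.3, -1210.9, 777.1), each = nrow(sys$coords))
  if (nrow(sys$ions) > 0) {
    shifted$ions <- (sys$ions + rep(c(333.3, -1210.9, 777.1),
                                    each = nrow(sys$ions))) %% 1500
  }
  expect_equal(total_energy(shifted)[["total"]], e0, tolerance = 1e-9)
  rot <- sys
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot$coords <- sys$coords %*% t(R)
  rot$ions <- sys$ions %*% t(R)
  expect_equal(total_energy(rot)[["total"]], e0, tolerance = 1e-9)
})
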