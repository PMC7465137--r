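test_that("radius of gyration matches the independent pair-distance oracle", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(generate_rod(2, 4.1)), 2.05)
  # 100-bead rod: closed form sqrt((N^2 - 1) / 12) b
  expect_equal(radius_of_gyration(generate_rod(100, 1)),
               sqrt((100^2 - 1) / 12), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:10) {
    m <- matrix(rnorm(3 * 30, sd = 10), ncol = 3)
    expect_equal(radius_of_gyration(m), oracle_rg(m), tolerance = 1e-9)
  }
  expect_error(radius_of_gyration(matrix(numeric(0), ncol = 3)), "empty")
})

test_that("shape factor hits the rod, ideal-chain and two-bead anchors", {
  # rod: R_shape = 12 (n-1) / (n+1) exactly
  st <- shape_factor(generate_rod(1000, 1))
  expect_equal(st$R_shape, 12 * 999 / 1001, tolerance = 1e-9)
  # single 2-bead configuration: Ree^2 / Rg^2 = 4 (Rg below the Flory
  # prefactor, so the attached single-point exponent warns)
  expect_warning(st2 <- shape_factor(generate_rod(2, 3.3)), "non-positive")
  expect_equal(st2$R_shape, 4)
  # ideal chains: about 6
  fr <- generate_ideal_ensemble(1500, n = 200, b = 1, seed = 44)
  expect_equal(shape_factor(fr)$R_shape, 6, tolerance = 0.05)
  expect_error(shape_factor(matrix(0, 1, 3)), "single-bead")
})

test_that("flory_fit inverts constructed power laws exactly", {
  for (nu in c(1 / 3, 1 / 2, 3 / 5)) {
    N <- c(50, 120, 300, 800)
    rg <- 2 * N^nu
    # single point
    expect_equal(coef(flory_fit(rg[1], N = N[1]))[["nu"]], nu,
                 tolerance = 1e-12)
    # fixed-intercept regression
    expect_equal(flory_fit(data.frame(N = N, rg = rg))$nu, nu,
                 tolerance = 1e-12)
    # free-intercept regression recovers both parameters
    f <- flory_fit(data.frame(N = N, rg = 3.7 * N^nu), R0 = NULL)
    expect_equal(f$nu, nu, tolerance = 1e-9)
    expect_equal(f$R0, 3.7, tolerance = 1e-6)
  }
  expect_warning(flory_fit(1.5, N = 100), "non-positive")
  expect_error(flory_fit(data.frame(N = c(10, 20), rg = c(5, 7))),
               "3 distinct")
  expect_equal(predict(flory_fit(20, N = 100), N = 100), 20)
})

test_that("rg_distribution reports exact sample moments", {
  fr <- generate_ideal_ensemble(400, n = 50, b = 1, seed = 3)
  rg <- radius_of_gyration(fr)
  d <- rg_distribution(fr, n_bins = 20)
  expect_equal(d$mean, mean(rg))
  expect_equal(d$variance, var(rg))
  # density normalised
  expect_equal(sum(d$density * diff(d$breaks)), 1, tolerance = 1e-9)
  # identical configurations: zero variance, single occupied bin
  same <- rep(list(generate_rod(10, 1)$coords), 5)
  d0 <- rg_distribution(same)
  expect_equal(d0$variance, 0)
  expect_equal(sum(d0$density > 0), 1)
  # mean^2 + variance recovers <Rg^2>
  n <- 100
  fr2 <- generate_ideal_ensemble(1200, n = n, b = 1, seed = 15)
  d2 <- rg_distribution(fr2)
  rg2 <- radius_of_gyration(fr2)^2
  se <- sd(rg2) / sqrt(length(rg2))
  expect_lt(abs((d2$mean^2 + d2$variance * (1 - 1 / length(rg2))) -
                  (n^2 - 1) / (6 * n)), 3 * se)
})

test_that("Debye scattering reproduces closed forms", {
  # single bead: I = 1 everywhere
  one <- matrix(0, 1, 3)
  sc1 <- debye_scattering(one, q = c(0, 0.1, 1, 5))
  expect_equal(sc1$I, rep(1, 4))
  # two beads at distance d: I = 2 (1 + sin(qd)/(qd))
  d <- 3.7
  q <- c(0.05, 0.3, 1.1, 2.4)
  sc2 <- debye_scattering(rbind(c(0, 0, 0), c(0, 0, d)), q = q)
  expect_equal(sc2$I, 2 * (1 + sin(q * d) / (q * d)), tolerance = 1e-12)
  # q -> 0 limit gives I0 = N^2
  n <- 17
  sc3 <- debye_scattering(generate_rod(n, 2), q = c(0, 0.2))
  expect_equal(sc3$I[1], n^2)
  expect_equal(sc3$I0, n^2)
  # Kratky transform vanishes at the origin
  expect_equal(sc3$kratky_y[1], 0)
})

test_that("Guinier analysis recovers the direct Rg within 5 percent", {
  fr <- generate_ideal_ensemble(150, n = 100, b = 3.8, seed = 5)
  rg_true <- sqrt(mean(radius_of_gyration(fr)^2))
  crv <- debye_scattering(fr, q = seq(0.001, 0.9 / rg_true, length.out = 30))
  expect_equal(guinier_rg(crv), rg_true, tolerance = 0.05)
})

test_that("ideal-chain Kratky curves match the exact freely-jointed form", {
  # exact FJC closed form: <sinc(q r_k)> = sinc(q b)^k, so
  # I(q)/N = 1 + 2 sum_k (1 - k/N) sinc(qb)^k -- an independent oracle
  n <- 200; b <- 1
  fr <- generate_ideal_ensemble(400, n = n, b = b, seed = 6)
  crv <- debye_scattering(fr)
  k <- seq_len(n - 1)
  I_exact <- vapply(crv$q, function(q) {
    s <- sin(q * b) / (q * b)
    n * (1 + 2 * sum((1 - k / n) * s^k))
  }, numeric(1))
  sel <- crv$q > 0
  expect_lt(max(abs(crv$I[sel] - I_exact[sel]) / I_exact[sel]), 0.06)
  # unfolded-chain signature: a flat Kratky profile over q Rg in [5, 15]
  # (discrete chains sit somewhat below the Gaussian-chain value of 2)
  plateau <- crv$kratky_y[crv$kratky_x >= 5 & crv$kratky_x <= 15]
  expect_true(all(plateau > 1.4 & plateau < 2.2))
  expect_lt(diff(range(plateau)) / mean(plateau), 0.25)
})

test_that("contact maps follow geometry and match the dist() oracle", {
  # rod with b = 4.1 and cutoff 8: nearest countable pair sits at 8.2
  cm <- contact_map(generate_rod(30, 4.1), cutoff = 8, exclusion = 1)
  expect_true(all(cm$frequency == 0))
  # symmetric by construction
  set.seed(8)
  frames <- generate_ideal_ensemble(10, n = 40, b = 4.1, seed = 8)
  cm2 <- contact_map(frames, cutoff = 8, exclusion = 1)
  expect_identical(cm2$frequency, t(cm2$frequency))
  expect_equal(cm2$frequency, oracle_contact(frames, 8, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diag(cm2$frequency) == 0))
  expect_error(contact_map(frames, cutoff = -1), "positive")
})

test_that("cysteine networks restrict the map and drop vicinal pairs", {
  frames <- generate_ideal_ensemble(5, n = 30, b = 4.1, seed = 9)
  net <- cys_contact_network(frames, cys_positions = c(4, 12, 20), cutoff = 8)
  expect_equal(nrow(net), 3)
  cm <- contact_map(frames, cutoff = 8)
  for (r in seq_len(nrow(net))) {
    expect_equal(net$frequency[r], cm$frequency[net$i[r], net$j[r]])
  }
  # no cysteines and vicinal-only cases give empty networks
  expect_equal(nrow(cys_contact_network(frames, integer(0))), 0)
  expect_equal(nrow(cys_contact_network(frames, c(15, 16))), 0)
  expect_error(cys_contact_network(frames, c(2, 95)), "bounds")
})

test_that("curve and map CSV writers emit tidy tables", {
  sc <- debye_scattering(generate_rod(5, 2), q = c(0.1, 0.2))
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(sc, f1)
  expect_equal(utils::read.csv(f1)$I, sc$I)
  cm <- contact_map(generate_ideal_ensemble(3, 20, b = 4.1, seed = 2),
                    cutoff = 10)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cm, f2)
  tidy <- utils::read.csv(f2)
  expect_true(all(tidy$j - tidy$i > cm$exclusion))
  expect_true(all(tidy$frequency >= 0 & tidy$frequency <= 1))
})
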