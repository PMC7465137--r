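kd <- residue_scale("kyte_doolittle")

test_that("hydropathy profile follows the full-window convention", {
  s <- protein_sequence(strrep("A", 30))
  p <- hydropathy_profile(s, kd, 15)
  expect_length(p$values, 30 - 15 + 1)
  expect_equal(p$values, rep(scale_lookup(kd, "A"), 16))
  expect_equal(p$positions, 8:23)
  expect_equal(p$mean, mean(p$values))
  expect_equal(p$variation, 0)
  expect_error(hydropathy_profile(s, kd, 14), "odd")
  expect_error(hydropathy_profile(s, kd, 31), "window")
})

test_that("window 1 returns raw per-residue values (GRAVY limit)", {
  set.seed(3)
  s <- protein_sequence(sample(names(kd$values), 40, TRUE))
  p1 <- hydropathy_profile(s, kd, 1)
  expect_equal(p1$values, scale_lookup(kd, s$residues))
  expect_equal(p1$mean, mean(scale_lookup(kd, s$residues)))
})

test_that("windowed values equal direct window means", {
  set.seed(11)
  s <- protein_sequence(sample(names(kd$values), 25, TRUE))
  p <- hydropathy_profile(s, kd, 7)
  raw <- scale_lookup(kd, s$residues)
  direct <- vapply(4:22, function(c) mean(raw[(c - 3):(c + 3)]), numeric(1))
  expect_equal(p$values, direct)
})

test_that("charge census counts, fractions and identities", {
  cen <- charge_census(protein_sequence("KKDD"))
  expect_equal(cen$f_pos, 0.5)
  expect_equal(cen$f_neg, 0.5)
  expect_equal(cen$net, 0)
  expect_equal(cen$FCR, 1.0)
  g <- charge_census(protein_sequence(strrep("G", 30)))
  expect_equal(g$n_pos + g$n_neg, 0)
  expect_equal(g$das_pappu_region, "R1")
  set.seed(5)
  r <- sample(names(kd$values), 80, TRUE)
  cen2 <- charge_census(protein_sequence(r))
  expect_equal(cen2$net, cen2$n_pos - cen2$n_neg)
  expect_equal(cen2$FCR, cen2$f_pos + cen2$f_neg)
  expect_true(abs(cen2$NCPR) <= cen2$FCR)
  # order invariance
  cen3 <- charge_census(protein_sequence(sample(r)))
  expect_equal(cen3$n_pos, cen2$n_pos)
  expect_equal(cen3$n_neg, cen2$n_neg)
})

test_that("diagram-of-states regions follow the published boundaries", {
  mk <- function(fp, fn) list(f_pos = fp, f_neg = fn)
  expect_equal(das_pappu_classify(mk(0.028, 0.024)), "R1")
  expect_equal(das_pappu_classify(mk(0.0, 0.5)), "R5")
  expect_equal(das_pappu_classify(mk(0.5, 0.0)), "R4")
  expect_equal(das_pappu_classify(mk(0.30, 0.30)), "R3")
  expect_equal(das_pappu_classify(mk(0.40, 0.40)), "R3")
  expect_equal(das_pappu_classify(mk(0.15, 0.15)), "R2")   # FCR = 0.30
  expect_equal(das_pappu_classify(mk(0.125, 0.125)), "R2") # tie at 0.25
  expect_equal(das_pappu_classify(mk(0.12, 0.12)), "R1")
})

test_that("cysteine context scoring uses the window at or nearest the Cys", {
  # one C flanked by 7 Ile per side: strongly hydrophobic
  s1 <- protein_sequence(paste0(strrep("I", 7), "C", strrep("I", 7)))
  ctx1 <- cys_context(s1, hydropathy_profile(s1, kd, 15))
  expect_equal(ctx1$class, "hydrophobic")
  expect_false(ctx1$edge)
  # flanked by Asp: hydrophilic
  s2 <- protein_sequence(paste0(strrep("D", 7), "C", strrep("D", 7)))
  expect_equal(cys_context(s2, hydropathy_profile(s2, kd, 15))$class,
               "hydrophilic")
  # poly-Q with a central C: exact window arithmetic
  s3 <- protein_sequence(paste0(strrep("Q", 10), "C", strrep("Q", 10)))
  ctx3 <- cys_context(s3, hydropathy_profile(s3, kd, 15))
  expect_equal(ctx3$context, (14 * (-3.5) + 2.5) / 15)
  # terminal C falls outside full windows: nearest position, flagged
  s4 <- protein_sequence(paste0("C", strrep("Q", 20)))
  ctx4 <- cys_context(s4, hydropathy_profile(s4, kd, 15))
  expect_true(ctx4$edge)
  expect_equal(nrow(ctx4), 1)
  # no cysteines: empty frame
  expect_equal(nrow(cys_context(protein_sequence(strrep("Q", 20)))), 0)
})

test_that("profile CSV and census JSON writers round-trip", {
  s <- protein_sequence(strrep("AQPC", 10))
  p <- hydropathy_profile(s, kd, 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(p, f)
  back <- utils::read.csv(f)
  expect_equal(back$value, p$values)
  expect_equal(back$position, p$positions)
  cen <- charge_census(s)
  j <- withr::local_tempfile(fileext = ".json")
  write_census_json(cen, j)
  expect_equal(jsonlite::read_json(j)$net, cen$net)
})
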