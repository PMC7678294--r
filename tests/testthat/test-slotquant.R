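test_that("plasmid insert mass follows the length share", {
  expect_equal(round(insertMass(10, 707, 3015), 1), 1.9)
  expect_equal(round(insertMass(10, 5121, 3015), 1), 6.3)
  expect_equal(insertMass(25, 1234, 0), 25)  # pure-insert limit
  expect_error(insertMass(0, 100, 100), "positive")
})

test_that("dilution matching picks the closest log-intensity pair", {
  # in a full geometric ladder every pair along the matching diagonal ties
  # exactly; the tie rule takes the smallest exponents
  pl <- dilutionSeries(3, 0:5, 1.9 * 3^-(0:5), 10)
  gd <- dilutionSeries(3, 0:5, (1.9 / 3) * 3^-(0:5), 1)
  m <- matchDilution(pl, gd)
  expect_equal(unname(m), c(1, 0))
  expect_equal(ngPerUg(1.9, 3^-m[["exp_p"]], 3^-m[["exp_g"]], 1), 1.9 / 3)
  # with the blot's usable range starting at plasmid slot 2 / genomic slot 1,
  # the published (2, 1) pair is the unique optimum
  pl2 <- dilutionSeries(3, 2:5, 1.9 * 3^-(2:5), 10)
  gd2 <- dilutionSeries(3, 1:4, (1.9 / 3) * 3^-(1:4), 1)
  expect_equal(unname(matchDilution(pl2, gd2)), c(2, 1))
  # identical series tie-break to the smallest exponents
  expect_equal(unname(matchDilution(pl, pl)), c(0, 0))
  # zero intensities are excluded; all-zero series cannot match
  gd0 <- dilutionSeries(3, 0:3, rep(0, 4), 1)
  expect_error(matchDilution(pl, gd0), "all-zero")
})

test_that("ng per microgram follows the matched dilution arithmetic", {
  expect_equal(round(ngPerUg(1.9, 3^-2, 3^-1, 1), 2), 0.63)
  expect_equal(ngPerUg(6.3, 3^-3, 3^-3, 1), 6.3)
  expect_equal(ngPerUg(5, 0.1, 0.1, 2), 2.5)  # equal factors: insert/loaded
  expect_error(ngPerUg(1.9, 0, 1, 1), "factors")
})

test_that("copies per genome reproduces the canonical chains", {
  r <- copiesPerGenome(0.63, 1.6e9, 707)
  expect_equal(r$mb_per_genome, 1.008)
  expect_equal(r$copies, 1426)
  r2 <- copiesPerGenome(6.3, 1.52e9, 5121)
  expect_equal(r2$mb_per_genome, 9.576)
  expect_equal(r2$copies, 1870)
  r0 <- copiesPerGenome(0, 1e9, 500)
  expect_equal(r0$target_bp, 0)
  expect_equal(r0$copies, 0)
  # linear in genome size and concentration before rounding
  expect_equal(copiesPerGenome(1.2, 2e9, 700)$copies_raw,
               2 * copiesPerGenome(1.2, 1e9, 700)$copies_raw)
  expect_equal(copiesPerGenome(2.4, 1e9, 700)$copies_raw,
               2 * copiesPerGenome(1.2, 1e9, 700)$copies_raw)
})

test_that("LTR:CDS ratio interpretation flags the published cases", {
  r <- interpretLtrCds(1115, 219)
  expect_equal(round(r$ratio, 2), 5.09)
  expect_equal(r$solo_ltr_estimate, 1115 - 2 * 219)
  expect_equal(r$flag, "solo_ltr_excess")

  r2 <- interpretLtrCds(1426, 1968)
  expect_equal(round(r2$ratio, 2), 0.72)
  expect_equal(r2$solo_ltr_estimate, 0)
  expect_equal(r2$flag, "ltr_deficit")

  r3 <- interpretLtrCds(200, 100)
  expect_equal(r3$ratio, 2)
  expect_equal(r3$flag, "mostly_full_length")
  # "nearly 2-fold" (2.18) must classify as mostly full length
  expect_equal(interpretLtrCds(218, 100)$flag, "mostly_full_length")
  expect_error(interpretLtrCds(100, 0), "copies_cds")
})

test_that("fold change rounds to the published integers", {
  expect_equal(foldChange(43840, 1115)$fold_reported, 39)
  expect_equal(foldChange(8618, 219)$fold_reported, 39)
  expect_equal(foldChange(777, 777)$fold_reported, 1)
  expect_error(foldChange(10, 0), "copies_b")
})

test_that("the full species-by-probe table regresses against print", {
  cfg <- phalaenopsisSlotBlot()
  tab <- slotBlotTable(cfg$ng_table, cfg$genomes)
  pub <- cfg$published
  expect_equal(nrow(tab), 24)
  # every Mb/genome cell matches at 3 decimals
  expect_equal(tab$mb_per_genome, pub$mb_per_genome)
  # copies: every cell matches except the single documented off-by-one
  mism <- which(tab$copies != pub$copies)
  expect_equal(paste(pub$species[mism], pub$segment[mism]),
               "P_aphrodite Gypsy3-LTR")
  # that cell computes 1.17e-3 * 1.52e9 / 1641 = 1083.7 -> 1084, printed 1083
  expect_equal(tab$copies[pub$species == "P_aphrodite" &
                            pub$segment == "Gypsy3-LTR"], 1084)
})

test_that("noiseless slot-blot round trip recovers mass and copies exactly", {
  # genomic DNA carrying f = 1.9/27 ng target per ng: the plasmid standard
  # at 3^-2 then lands exactly on the genomic 3^0 slot after one more step
  insert_ng <- insertMass(10, 707, 3015)
  f <- insert_ng * 3^-1 / 1000
  pl <- simulateSlotBlot(insert_ng / 10, base = 3, exponents = 0:5,
                         loaded_mass = 10, noise_cv = 0, seed = 1)
  gd <- simulateSlotBlot(f, base = 3, exponents = 0:5,
                         loaded_mass = 1000, noise_cv = 0, seed = 2)
  m <- matchDilution(pl, gd)
  conc <- ngPerUg(insert_ng, 3^-m[["exp_p"]], 3^-m[["exp_g"]], 1)
  expect_equal(conc, f * 1000)
  est <- copiesPerGenome(conc, 1.6e9, 707)
  truth <- copiesPerGenome(f * 1000, 1.6e9, 707)
  expect_equal(est$copies, truth$copies)
})

test_that("noisy round trips stay within one dilution step", {
  insert_ng <- 1.9
  f <- insert_ng * 3^-1 / 1000
  ok <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    pl <- simulateSlotBlot(insert_ng / 10, base = 3, exponents = 0:5,
                           loaded_mass = 10, noise_cv = 0.2, seed = 2 * r)
    gd <- simulateSlotBlot(f, base = 3, exponents = 0:5,
                           loaded_mass = 1000, noise_cv = 0.2, seed = 2 * r + 1)
    m <- matchDilution(pl, gd)
    conc <- ngPerUg(insert_ng, 3^-m[["exp_p"]], 3^-m[["exp_g"]], 1)
    ratio <- conc / (f * 1000)
    if (ratio >= 1 / 3 && ratio <= 3) ok <- ok + 1L
  }
  expect_gte(ok / n_rep, 0.95)
})
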