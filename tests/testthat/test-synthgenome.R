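test_that("background generation respects composition, length and seed", {
  g0 <- genBackground(1000, gc = 0, seed = 1)
  expect_equal(Biostrings::width(g0), 1000)
  freq <- Biostrings::alphabetFrequency(g0[[1]])
  expect_equal(unname(freq["G"] + freq["C"]), 0)

  g <- genBackground(10000, gc = 0.5, seed = 7)
  freq <- Biostrings::alphabetFrequency(g[[1]])
  gcn <- unname(freq["G"] + freq["C"])
  expect_lt(abs(gcn - 5000), 3 * sqrt(10000 * 0.25))  # 3 binomial sd

  expect_identical(as.character(genBackground(500, 0.4, seed = 3)),
                   as.character(genBackground(500, 0.4, seed = 3)))
  expect_false(identical(as.character(genBackground(500, 0.4, seed = 3)),
                         as.character(genBackground(500, 0.4, seed = 4))))

  expect_error(genBackground(0), "length")
  expect_error(genBackground(100, gc = 1.2), "gc")
})

test_that("planting reproduces the canonical element geometry", {
  g <- genBackground(40000, seed = 2)
  sp <- familySpec("rt1", ltr_len = 707, internal_len = 11257,
                   n_full = 1, n_solo = 0, divergence = 0)
  expect_equal(elementLength(sp), 12671)
  p <- plantFamily(g, sp, seed = 5)
  expect_equal(length(p$truth), 1)
  expect_equal(GenomicRanges::width(p$truth), 12671)
  # the two terminal repeats are identical at divergence 0
  el <- as.character(extractElementSeqs(p$genome, p$truth)[[1]])
  ltr5 <- substr(el, 1, 707)
  ltr3 <- substr(el, 12671 - 707 + 1, 12671)
  expect_identical(ltr5, ltr3)
  expect_equal(alignedIdentity(ltr5, ltr3), 1.0)
  # TSD is an exact duplication flanking the element
  s <- as.character(p$genome[[1]])
  st <- GenomicRanges::start(p$truth); en <- GenomicRanges::end(p$truth)
  expect_identical(substr(s, st - 5, st - 1), substr(s, en + 1, en + 5))
  expect_identical(substr(s, st - 5, st - 1), p$truth$tsd)
})

test_that("planting nothing leaves the genome unchanged", {
  g <- genBackground(5000, seed = 9)
  p <- plantFamily(g, familySpec("x", 100, 500, n_full = 0, n_solo = 0),
                   seed = 1)
  expect_identical(as.character(p$genome), as.character(g))
  expect_equal(length(p$truth), 0)
})

test_that("truth ledger is exact: re-extraction matches templates", {
  g <- genBackground(60000, seed = 13)
  sp <- familySpec("fam", ltr_len = 200, internal_len = 1500,
                   n_full = 3, n_solo = 2, divergence = 0)
  p <- plantFamily(g, sp, seed = 14)
  expect_equal(length(p$truth), 5)
  ex <- extractElementSeqs(p$genome, p$truth)
  ltr <- substr(p$template, 1, 200)
  for (i in seq_along(p$truth)) {
    expected <- if (p$truth$kind[i] == "full") p$template else ltr
    expect_identical(as.character(ex[[i]]), expected)
  }
  # planted base fraction from the ledger is exact: widths are the template
  # lengths and the genome grew by exactly the inserted bases + TSDs
  expect_equal(sum(GenomicRanges::width(p$truth)), 3 * 1900 + 2 * 200)
  expect_equal(unname(Biostrings::width(p$genome)),
               60000 + (3 * 1900 + 2 * 200) + 5 * 5)
  # intervals are non-overlapping
  expect_true(all(GenomicRanges::countOverlaps(p$truth, p$truth) == 1))
})

test_that("divergence produces the expected LTR pair identity", {
  g <- genBackground(80000, seed = 21)
  p <- plantFamily(g, familySpec("d", 707, 3000, n_full = 3,
                                 divergence = 0.05), seed = 22)
  for (i in which(p$truth$kind == "full")) {
    el <- as.character(extractElementSeqs(p$genome, p$truth[i])[[1]])
    id <- alignedIdentity(substr(el, 1, 707), substr(el, nchar(el) - 706, nchar(el)))
    expect_gt(id, 0.84)  # (1 - 0.05)^2 = 0.9025 with alignment slack
    expect_lt(id, 0.97)
  }
  expect_true(all(p$truth$divergence_applied > 0))
})

test_that("read simulation is uniform, error-free reads are substrings", {
  g <- genBackground(20000, seed = 31)
  empty <- simulateReads(g, "454", 100, 0, seed = 1)
  expect_equal(length(empty), 0)

  rs <- simulateReads(g, "Illumina", 80, 200, error_rate = 0, seed = 32)
  expect_equal(length(rs), 200)
  expect_true(all(Biostrings::width(reads(rs)) == 80))
  s <- as.character(g[[1]])
  rc <- as.character(Biostrings::reverseComplement(g[[1]]))
  for (r in as.character(reads(rs)))
    expect_true(grepl(r, s, fixed = TRUE) || grepl(r, rc, fixed = TRUE))
  # determinism
  rs2 <- simulateReads(g, "Illumina", 80, 200, error_rate = 0, seed = 32)
  expect_identical(as.character(reads(rs)), as.character(reads(rs2)))
})

test_that("read coverage of a planted region matches its base fraction", {
  g <- genBackground(100000, seed = 41)
  p <- plantFamily(g, familySpec("f", 400, 3200, n_full = 5, divergence = 0),
                   seed = 42)
  L <- Biostrings::width(p$genome)
  rs <- simulateReads(p$genome, "sim", 100, 4000, error_rate = 0, seed = 43)
  # count reads starting fully inside a planted interval, via exact matching
  s <- as.character(p$genome[[1]])
  fw <- reads(rs)
  rc <- Biostrings::reverseComplement(fw)
  in_any <- rep(FALSE, length(fw))  # copies are identical, so pool matches
  for (i in seq_along(p$truth)) {
    st <- GenomicRanges::start(p$truth)[i]; en <- GenomicRanges::end(p$truth)[i]
    frag <- Biostrings::DNAString(substr(s, st, en))
    hits <- Biostrings::countPDict(fw, frag) + Biostrings::countPDict(rc, frag)
    in_any <- in_any | hits > 0
  }
  n_in <- sum(in_any)
  f_region <- sum(GenomicRanges::width(p$truth) - 99) / (L - 99)
  se <- sqrt(f_region * (1 - f_region) / 4000)
  expect_lt(abs(n_in / 4000 - f_region), 3 * se)
})

test_that("slot-blot simulation follows the dilution geometry", {
  ds <- simulateSlotBlot(0.19, base = 3, exponents = 0:4, loaded_mass = 10,
                         noise_cv = 0, seed = 1)
  ii <- intensities(ds)
  expect_equal(ii[-length(ii)] / ii[-1], rep(3, 4))

  expect_true(all(intensities(simulateSlotBlot(0, seed = 1)) == 0))

  # plasmid with 1.9 ng insert at 3^-2 equals genomic DNA carrying
  # 1.9/3 ng target per ug at 3^-1  (1.9/9 == 0.6333/3)
  pl <- simulateSlotBlot(1.9 / 10, base = 3, exponents = 0:5,
                         loaded_mass = 10, noise_cv = 0, seed = 1)
  gd <- simulateSlotBlot((1.9 / 3) / 1000, base = 3, exponents = 0:5,
                         loaded_mass = 1000, noise_cv = 0, seed = 2)
  expect_equal(intensities(pl)[3], intensities(gd)[2])

  expect_error(simulateSlotBlot(0.1, noise_cv = -1), "noise_cv")
  expect_error(simulateSlotBlot(1.5), "mass_fraction")
})

test_that("simulation output files round-trip", {
  dir <- tempfile("sim")
  g <- genBackground(30000, seed = 51)
  sp <- familySpec("w", 150, 1200, n_full = 2, divergence = 0)
  p <- plantFamily(g, sp, seed = 52)
  rs <- simulateReads(p$genome, "Illumina", 100, 50, 0.01, seed = 53)
  paths <- writeSimulation(dir, p$genome, p$truth, list(rs), list(sp),
                           seed = 52)
  expect_true(all(file.exists(paths)))
  g2 <- Biostrings::readDNAStringSet(paths[["genome"]])
  expect_identical(as.character(g2[[1]]), as.character(p$genome[[1]]))
  bed <- rtracklayer::import(paths[["truth"]], format = "BED")
  expect_equal(GenomicRanges::start(bed), GenomicRanges::start(p$truth))
  expect_equal(GenomicRanges::end(bed), GenomicRanges::end(p$truth))
  rq <- Biostrings::readDNAStringSet(paths[["Illumina"]], format = "fastq")
  expect_equal(length(rq), 50)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$families[[1]]$ltr_len, 150)
  expect_equal(man$seed, 52)
})
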