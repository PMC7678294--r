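test_that("shared-word similarity behaves like a dot-plot score", {
  s <- randomSeq(500, seed = 1)
  expect_equal(pairwiseWordSimilarity(s, s, 12), 1.0)
  a <- randomSeq(5000, seed = 2)
  b <- randomSeq(5000, seed = 3)
  expect_lt(pairwiseWordSimilarity(a, b, 12), 0.01)
  expect_error(pairwiseWordSimilarity("ACGT", a, 12), "word")
})

test_that("shared-word similarity equals a nested-loop oracle", {
  for (rep in 1:5) {
    a <- randomSeq(200, seed = 3000 + rep)
    b <- if (rep %% 2) randomSeq(200, seed = 4000 + rep) else
      paste0(substr(a, 1, 150), randomSeq(50, seed = 5000 + rep))
    expect_equal(pairwiseWordSimilarity(a, b, 10),
                 wordSimOracle(a, b, 10), info = paste("pair", rep))
  }
})

test_that("clustering forms the forced partitions", {
  one <- Biostrings::DNAStringSet(c(a = randomSeq(400, seed = 11)))
  fs <- clusterElements(one)
  expect_equal(length(fs), 1)
  expect_equal(familyInfo(fs)$n_elements, 1)

  s <- randomSeq(600, seed = 12)
  els <- Biostrings::DNAStringSet(c(x = s, y = s, z = randomSeq(600, seed = 13)))
  fs <- clusterElements(els)
  expect_equal(familyInfo(fs)$n_elements, c(2, 1))
  expect_setequal(familyInfo(fs)$member_ids[[1]], c("x", "y"))

  empty <- clusterElements(Biostrings::DNAStringSet())
  expect_equal(length(empty), 0)
})

test_that("the partition is order-invariant and covers every element", {
  set.seed(21)
  base1 <- randomSeq(800, seed = 22)
  base2 <- randomSeq(800, seed = 23)
  mut <- function(s, seed) {
    set.seed(seed)
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), 16)  # 2% divergence
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  }
  els <- Biostrings::DNAStringSet(c(
    a1 = mut(base1, 31), a2 = mut(base1, 32), a3 = mut(base1, 33),
    b1 = mut(base2, 34), b2 = mut(base2, 35)))
  fs1 <- clusterElements(els)
  fs2 <- clusterElements(rev(els))
  part <- function(fs) lapply(familyInfo(fs)$member_ids, function(x) sort(x))
  expect_identical(part(fs1), part(fs2))
  expect_setequal(unlist(part(fs1)), names(els))
})

test_that("raising the threshold only refines the partition", {
  set.seed(41)
  s <- randomSeq(500, seed = 42)
  mut <- function(s, k, seed) {
    set.seed(seed)
    v <- strsplit(s, "")[[1]]
    i <- sample(length(v), k)
    v[i] <- vapply(v[i], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
    paste(v, collapse = "")
  }
  els <- Biostrings::DNAStringSet(c(
    p = s, q = mut(s, 5, 43), r = mut(s, 20, 44), u = randomSeq(500, seed = 45)))
  lo <- clusterElements(els, threshold = 0.2)
  hi <- clusterElements(els, threshold = 0.8)
  memb <- function(fs) {
    m <- rep(NA_character_, length(els)); names(m) <- names(els)
    info <- familyInfo(fs)
    for (i in seq_len(nrow(info))) m[info$member_ids[[i]]] <- info$family_id[i]
    m
  }
  mlo <- memb(lo); mhi <- memb(hi)
  # every high-threshold family sits inside one low-threshold family
  for (fam in unique(mhi)) {
    expect_equal(length(unique(mlo[names(mhi)[mhi == fam]])), 1)
  }
})

test_that("two planted families are recovered exactly", {
  g <- genBackground(150000, seed = 61)
  specs <- list(familySpec("famA", 300, 3000, n_full = 4, divergence = 0.02),
                familySpec("famB", 400, 2500, n_full = 3, divergence = 0.02))
  pf <- plantFamilies(g, specs, seed = 62)
  full <- pf$truth[pf$truth$kind == "full"]
  els <- extractElementSeqs(pf$genome, full)
  names(els) <- paste0(full$family_id, "_", seq_along(full))
  # the two templates are mutually unrelated (far below 60% identity)
  expect_lt(pairwiseWordSimilarity(pf$templates$famA, pf$templates$famB), 0.05)
  fs <- clusterElements(els, threshold = 0.5)
  expect_equal(length(fs), 2)
  got <- unname(lapply(familyInfo(fs)$member_ids, function(ids)
    sort(unique(sub("_.*", "", ids)))))
  expect_identical(got, list("famA", "famB"))
  expect_equal(familyInfo(fs)$n_elements, c(4, 3))
})

test_that("majority-vote consensus recovers the template", {
  s <- randomSeq(300, seed = 71)
  m <- Biostrings::DNAStringSet(c(s, s, s))
  expect_identical(as.character(buildConsensus(m)), s)

  s2 <- paste0(substr(s, 1, 99), if (substr(s, 100, 100) == "A") "G" else "A",
               substr(s, 101, 300))
  m2 <- Biostrings::DNAStringSet(c(s, s, s2))
  expect_identical(as.character(buildConsensus(m2)), s)

  expect_error(buildConsensus(Biostrings::DNAStringSet()), "empty")
})

test_that("consensus of diverged copies is near-identical to the template", {
  g <- genBackground(80000, seed = 81)
  p <- plantFamily(g, familySpec("c", 250, 2000, n_full = 5,
                                 divergence = 0.02), seed = 82)
  els <- extractElementSeqs(p$genome, p$truth)
  cons <- buildConsensus(els)
  expect_gte(alignedIdentity(as.character(cons), p$template), 0.99)
})

test_that("superfamily follows the RT/INT domain order", {
  expect_equal(classifySuperfamily(domainAnnotation(c("PR", "RT", "RH", "INT"))),
               "gypsy")
  expect_equal(classifySuperfamily(domainAnnotation(c("PR", "INT", "RT", "RH"))),
               "copia")
  expect_equal(classifySuperfamily(domainAnnotation(c("PR", "RT"))), "unknown")
  expect_error(domainAnnotation(c("RT", "XX")), "labels")
  expect_error(domainAnnotation(c("RT", "INT"), c(5, 2)), "increasing")
})

test_that("family table joins detection lengths with consensi", {
  g <- genBackground(100000, seed = 91)
  # copies dispersed beyond the element window so no cross-copy repeat pair
  # is a structurally valid candidate
  p <- plantFamily(g, familySpec("t", 300, 2400, n_full = 3, divergence = 0),
                   seed = 92, min_gap = 21000)
  cand <- findLTRElements(p$genome)
  els <- extractElementSeqs(p$genome, cand)
  doms <- setNames(rep(list(domainAnnotation(c("PR", "RT", "RH", "INT"))),
                       length(els)), names(els))
  fs <- clusterElements(els, domains = doms)
  tab <- familyTable(fs, cand)
  expect_equal(sum(tab$n_elements), length(els))
  expect_equal(tab$superfamily[1], "gypsy")
  expect_equal(tab$ltr_length[1], 300)
  expect_equal(tab$total_length[1], 3000)
})
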