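# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain-R dynamic programming, nested loops, per-base scans.

# Naive Needleman-Wunsch over full matrices with the same scoring and
# traceback preference (diagonal, then up, then left) as the documented
# identity metric.
nwIdentityOracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  D <- matrix(0L, n + 1, m + 1)  # 0 diag, 1 up, 2 left
  for (i in seq_len(n)) { S[i + 1, 1] <- i * gap; D[i + 1, 1] <- 1L }
  for (j in seq_len(m)) { S[1, j + 1] <- j * gap; D[1, j + 1] <- 2L }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    sd <- S[i, j] + if (av[i] == bv[j]) match else mismatch
    su <- S[i, j + 1] + gap
    sl <- S[i + 1, j] + gap
    best <- sd; dir <- 0L
    if (su > best) { best <- su; dir <- 1L }
    if (sl > best) { best <- sl; dir <- 2L }
    S[i + 1, j + 1] <- best; D[i + 1, j + 1] <- dir
  }
  i <- n; j <- m; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    d <- D[i + 1, j + 1]
    if (i > 0 && j > 0 && d == 0L) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && (d == 1L || j == 0)) i <- i - 1 else j <- j - 1
    cols <- cols + 1L
  }
  list(score = S[n + 1, m + 1], identity = matches / cols)
}

rcOracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Nested-loop shared-word fraction: every word of x compared by string
# equality against every word of y and of y's reverse complement.
wordSimOracle <- function(x, y, word) {
  wordsOf <- function(s) {
    n <- nchar(s)
    vapply(seq_len(n - word + 1), function(i) substr(s, i, i + word - 1), "")
  }
  frac <- function(wx, wy) {
    hits <- 0L
    for (w in wx) {
      found <- FALSE
      for (u in wy) if (w == u) { found <- TRUE; break }
      if (found) hits <- hits + 1L
    }
    hits / length(wx)
  }
  wxx <- wordsOf(x); wyy <- c(wordsOf(y), wordsOf(rcOracle(y)))
  wyx <- wordsOf(y); wxy <- c(wordsOf(x), wordsOf(rcOracle(x)))
  (frac(wxx, wyy) + frac(wyx, wxy)) / 2
}

# Brute-force read assignment: containment of each read against every
# element recomputed with nested loops, same best-hit >= threshold rule
# with lexicographic tie-break.
assignOracle <- function(read_chars, cons_chars, k, min_containment) {
  wordsOf <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    vapply(seq_len(n - k + 1), function(i) substr(s, i, i + k - 1), "")
  }
  elem_words <- lapply(cons_chars, function(s)
    c(wordsOf(s), wordsOf(rcOracle(s))))
  ids <- names(cons_chars)
  out <- character(length(read_chars))
  for (r in seq_along(read_chars)) {
    w <- wordsOf(read_chars[r])
    best <- 0; best_id <- NA_character_
    for (e in order(ids)) {
      hits <- 0L
      for (wi in w) {
        found <- FALSE
        for (u in elem_words[[e]]) if (wi == u) { found <- TRUE; break }
        if (found) hits <- hits + 1L
      }
      cont <- hits / length(w)
      if (cont > best) { best <- cont; best_id <- ids[e] }
    }
    out[r] <- if (best >= min_containment) best_id else NA_character_
  }
  out
}

# Per-base context oracle: walk every base of the hit over exon and gene
# span base sets.
contextOracle <- function(hit_start, hit_end, genes) {
  exon_bases <- list(); span_bases <- list()
  for (g in names(genes)) {
    ex <- genes[[g]]
    eb <- integer(0)
    for (i in seq_along(ex))
      eb <- c(eb, GenomicRanges::start(ex)[i]:GenomicRanges::end(ex)[i])
    exon_bases[[g]] <- eb
    span_bases[[g]] <- min(eb):max(eb)
  }
  hb <- hit_start:hit_end
  for (g in names(genes))
    if (any(hb %in% exon_bases[[g]])) return(list(context = "exon", gene = g))
  for (g in names(genes))
    if (all(hb %in% span_bases[[g]])) return(list(context = "intron", gene = g))
  list(context = "intergenic", gene = NA_character_)
}

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
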