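#' Global-alignment identity between two sequences
#'
#' Needleman-Wunsch global alignment with linear gap costs (match +1,
#' mismatch -1, gap -2 per base by default); identity is the number of
#' matched columns divided by the total number of alignment columns, so it
#' lies in \[0, 1\] and is symmetric in its arguments.
#'
#' @param a,b sequences (character scalars, `DNAString`s, or 1-element
#'   `DNAStringSet`s); both non-empty.
#' @param match,mismatch,gap alignment scores.
#' @return identity fraction in \[0, 1\].
#' @examples
#' alignedIdentity("ACGTACGT", "ACGTACGT")  # 1
#' alignedIdentity("AAAAACAAAA", "AAAAAGAAAA")  # 0.9
#' @export
alignedIdentity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- asDNACharacter(a)
  b <- asDNACharacter(b)
  .nw_identity_cpp(a, b, match, mismatch, gap)$identity
}

# Seed word matches (i, j), i < j, whose implied element length j - i + k
# falls inside the admissible window. Words occurring more than max_occ
# times (low-complexity) are skipped.
seedPairs <- function(words, params, max_occ = 12L) {
  k <- params@k
  tab <- table(words)
  keep <- names(tab)[tab >= 2L & tab <= max_occ]
  if (!length(keep)) return(data.frame(i = integer(0), j = integer(0)))
  pos <- split(seq_along(words), words)[keep]
  lo <- max(params@min_elem - params@max_ltr, 2L)
  hi <- params@max_elem
  ii <- integer(0); jj <- integer(0)
  for (p in pos) {
    pr <- combn(p, 2L)
    sep <- pr[2L, ] - pr[1L, ] + k
    ok <- sep >= lo & sep <= hi
    ii <- c(ii, pr[1L, ok]); jj <- c(jj, pr[2L, ok])
  }
  data.frame(i = ii, j = jj)
}

# Group seed pairs into diagonal bands (same separation +/- drift), then
# split each band into chains where consecutive i positions jump by more
# than max_ltr. Returns a list of data.frames of pairs.
bandPairs <- function(pairs, params) {
  if (!nrow(pairs)) return(list())
  d <- pairs$j - pairs$i
  o <- order(d, pairs$i)
  pairs <- pairs[o, ]; d <- d[o]
  band_id <- cumsum(c(1L, diff(d) > params@drift))
  out <- list()
  for (b in split(pairs, band_id)) {
    b <- b[order(b$i), ]
    chain_id <- cumsum(c(1L, diff(b$i) > params@max_ltr))
    out <- c(out, split(b, chain_id))
  }
  out
}

# X-drop extension of a repeat pair at offset d0. v is the contig as a
# character vector; [i_lo, i_hi] is the seed block on the left copy.
# Returns c(start, end) of the refined left block.
xdropExtend <- function(v, i_lo, i_hi, d0, xdrop = 12L) {
  n <- length(v)
  # rightward
  best <- 0L; cur <- 0L; best_t <- i_hi
  t <- i_hi + 1L
  while (t + d0 <= n && t < i_lo + d0) {   # stop before blocks collide
    cur <- cur + (if (v[t] == v[t + d0]) 1L else -3L)
    if (cur > best) { best <- cur; best_t <- t }
    if (cur < best - xdrop) break
    t <- t + 1L
  }
  end <- best_t
  # leftward
  best <- 0L; cur <- 0L; best_t <- i_lo
  t <- i_lo - 1L
  while (t >= 1L) {
    cur <- cur + (if (v[t] == v[t + d0]) 1L else -3L)
    if (cur > best) { best <- cur; best_t <- t }
    if (cur < best - xdrop) break
    t <- t - 1L
  }
  c(best_t, end)
}

# Find the exact 4-6 bp target-site duplication flanking the element and
# refine the boundaries onto it. X-drop boundaries can be off by several bp
# when mutations cluster at an LTR end (the max-score changepoint genuinely
# stops short) or when flank bases match by chance (overshoot); the exact
# duplication is the extra signal that disambiguates. Every (shift5, shift3)
# pair within +/- `w` bp carrying an exact duplication is scored by a
# changepoint log-likelihood: positions claimed as element should match
# their partner copy (P ~ 1 - 2*divergence), positions claimed as flank
# should match at the background rate (~0.25), plus log(4) per exact TSD
# base. Chance duplications far from the true boundary lose heavily on the
# changepoint term. Returns list(tsd, s5, s3) or NULL.
findTSD <- function(v, a, b3, d0, w = 40L) {
  n <- length(v)
  lmatch <- log(0.9 / 0.25); lmis <- log(0.1 / 0.75)
  sc <- function(t) {  # left-copy position t vs its partner at t + d0
    if (t < 1L || t + d0 > n) return(0)
    if (v[t] == v[t + d0]) lmatch else lmis
  }
  b <- b3 - d0
  # L5[s]: evidence that the element starts at a + s (s in -w..w)
  l5cols <- vapply((a - w):(a + w), sc, numeric(1))
  L5 <- rev(cumsum(rev(l5cols)))
  # L3[s]: evidence that the left copy ends at b + s
  l3cols <- vapply((b - w):(b + w), sc, numeric(1))
  L3 <- cumsum(l3cols)
  idx <- function(s) s + w + 1L
  # Admissible shifts: up to 5 bp inward (chance-match overshoot of the
  # X-drop boundary; +/-2 for 4 bp duplications, which carry less evidence),
  # up to w bp outward (the stopped-short case, 5-6 bp duplications only),
  # and always within `margin` of the best achievable boundary likelihood so
  # a chance duplication deep in the flank cannot win.
  margin <- 8
  floor5 <- max(L5) - margin; floor3 <- max(L3) - margin
  best <- NULL; best_obj <- -Inf
  for (len in 6:4) for (s5 in -w:5) {
    if (len < 5L && abs(s5) > 2L) next
    ls <- a + s5 - len
    if (ls < 1L) next
    if (L5[idx(s5)] < floor5) next
    left <- v[ls:(a + s5 - 1L)]
    for (s3 in -5:w) {
      if (len < 5L && abs(s3) > 2L) next
      rs <- b3 + s3 + 1L
      if (rs + len - 1L > n) next
      if (L3[idx(s3)] < floor3) next
      if (!identical(left, v[rs:(rs + len - 1L)])) next
      obj <- L5[idx(s5)] + L3[idx(s3)] + len * log(4)
      if (obj > best_obj) {
        best_obj <- obj
        best <- list(tsd = paste(left, collapse = ""), s5 = s5, s3 = s3)
      }
    }
  }
  best
}

#' Detect full-length LTR retrotransposon candidates
#'
#' Finds pairs of near-identical terminal repeats at element-scale
#' separation: all k-words of the contig are indexed; word match pairs whose
#' separation is compatible with the element length window are chained into
#' diagonal bands; each band is extended by X-drop into two maximal terminal
#' blocks; the blocks' global-alignment identity and the length windows
#' decide acceptance, and (optionally) an exact 4-6 bp target-site
#' duplication flanking the element is required. Overlapping candidates are
#' resolved by keeping the higher-identity one (ties: longer, then leftmost).
#' The terminal-repeat-pair geometry is strand-symmetric, so one forward scan
#' covers both orientations and candidates are reported in forward contig
#' coordinates with strand `*`.
#'
#' @param contig a 1-sequence `DNAStringSet` (or `DNAString`).
#' @param params a [DetectParams-class] (see [detectParams()]).
#' @return a [GenomicRanges::GRanges] of candidate elements (1-based, closed)
#'   with metadata columns `ltr5_start`, `ltr5_end`, `ltr3_start`,
#'   `ltr3_end`, `ltr_len`, `internal_len`, `ltr_identity`, `tsd`.
#' @examples
#' g <- genBackground(30000, seed = 3)
#' p <- plantFamily(g, familySpec("fam1", ltr_len = 300, internal_len = 2000,
#'                                n_full = 1), seed = 4)
#' findLTRElements(p$genome, detectParams(min_elem = 1500, max_elem = 5000))
#' @export
findLTRElements <- function(contig, params = detectParams()) {
  s <- asDNACharacter(contig)
  cname <- contigName(contig)
  n <- nchar(s)
  if (n < params@min_elem) return(emptyCandidates(cname))
  words <- seqWords(s, params@k)
  chains <- bandPairs(seedPairs(words, params), params)
  if (!length(chains)) return(emptyCandidates(cname))
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (ch in chains) {
    d <- ch$j - ch$i
    d0 <- as.integer(names(which.max(table(d))))  # modal diagonal
    on_d <- abs(d - d0) <= params@drift
    i_lo <- min(ch$i[on_d]); i_hi <- max(ch$i[on_d]) + params@k - 1L
    blk <- xdropExtend(v, i_lo, i_hi, d0)
    a <- blk[1L]; b <- blk[2L]
    ltr_len <- b - a + 1L
    elem_len <- d0 + ltr_len
    if (ltr_len < params@min_ltr || ltr_len > params@max_ltr) next
    if (elem_len < params@min_elem || elem_len > params@max_elem) next
    b3 <- b + d0
    ident <- alignedIdentity(substr(s, a, b), substr(s, a + d0, b3))
    if (ident < params@min_identity) next
    tsd <- findTSD(v, a, b3, d0)
    if (params@tsd_search && is.null(tsd)) next
    if (!is.null(tsd)) {  # snap boundaries onto the duplication
      a <- a + tsd$s5
      b3 <- b3 + tsd$s3
      ltr_len <- (b3 - d0) - a + 1L
      elem_len <- b3 - a + 1L
      if (ltr_len < params@min_ltr || ltr_len > params@max_ltr) next
      if (elem_len < params@min_elem || elem_len > params@max_elem) next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = a, end = b3, ltr5_start = a, ltr5_end = b3 - d0,
      ltr3_start = a + d0, ltr3_end = b3, ltr_len = ltr_len,
      internal_len = elem_len - 2L * ltr_len, ltr_identity = ident,
      tsd = if (is.null(tsd)) "" else tsd$tsd)
  }
  if (!length(rows)) return(emptyCandidates(cname))
  df <- do.call(rbind, rows)
  df <- unique(df)
  # winner-takes-interval: identity desc, length desc, leftmost
  df <- df[order(-df$ltr_identity, -(df$end - df$start), df$start), ]
  kept <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!any(kept & df$start <= df$end[i] & df$end >= df$start[i]))
      kept[i] <- TRUE
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = cname,
    ranges = IRanges::IRanges(start = df$start, end = df$end), strand = "*",
    ltr5_start = df$ltr5_start, ltr5_end = df$ltr5_end,
    ltr3_start = df$ltr3_start, ltr3_end = df$ltr3_end,
    ltr_len = df$ltr_len, internal_len = df$internal_len,
    ltr_identity = df$ltr_identity, tsd = df$tsd)
  names(gr) <- sprintf("%s_cand%03d", cname, seq_along(gr))
  gr
}

emptyCandidates <- function(cname) {
  gr <- GenomicRanges::GRanges(
    ltr5_start = integer(0), ltr5_end = integer(0),
    ltr3_start = integer(0), ltr3_end = integer(0), ltr_len = integer(0),
    internal_len = integer(0), ltr_identity = numeric(0), tsd = character(0))
  gr
}

#' Extract element sequences for a set of intervals
#'
#' @param genome a 1-sequence `DNAStringSet`.
#' @param ranges a `GRanges` (e.g. detection output or a truth ledger).
#' @return a named `DNAStringSet`, one sequence per range.
#' @export
extractElementSeqs <- function(genome, ranges) {
  s <- asDNACharacter(genome)
  out <- Biostrings::DNAStringSet(vapply(seq_along(ranges), function(i)
    substr(s, GenomicRanges::start(ranges)[i], GenomicRanges::end(ranges)[i]),
    character(1)))
  names(out) <- if (!is.null(names(ranges))) names(ranges)
    else sprintf("elem%03d", seq_along(ranges))
  out
}

#' Export detected candidates as GFF3
#'
#' Writes one `LTR_retrotransposon` feature per candidate with two child
#' `long_terminal_repeat` features (1-based inclusive coordinates, as GFF3
#' requires).
#'
#' @param cands detection output `GRanges`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
exportCandidatesGFF3 <- function(cands, file) {
  feats <- list()
  for (i in seq_along(cands)) {
    cn <- as.character(GenomicRanges::seqnames(cands))[i]
    id <- names(cands)[i]
    elem <- GenomicRanges::GRanges(cn, IRanges::IRanges(
      GenomicRanges::start(cands)[i], GenomicRanges::end(cands)[i]))
    elem$type <- "LTR_retrotransposon"
    elem$ID <- id
    elem$Parent <- NA_character_
    elem$ltr_identity <- cands$ltr_identity[i]
    l5 <- GenomicRanges::GRanges(cn, IRanges::IRanges(
      cands$ltr5_start[i], cands$ltr5_end[i]))
    l5$type <- "long_terminal_repeat"; l5$ID <- paste0(id, "_ltr5")
    l5$Parent <- id; l5$ltr_identity <- NA_real_
    l3 <- GenomicRanges::GRanges(cn, IRanges::IRanges(
      cands$ltr3_start[i], cands$ltr3_end[i]))
    l3$type <- "long_terminal_repeat"; l3$ID <- paste0(id, "_ltr3")
    l3$Parent <- id; l3$ltr_identity <- NA_real_
    feats <- c(feats, list(elem, l5, l3))
  }
  gr <- if (length(feats)) do.call(c, feats) else
    GenomicRanges::GRanges(type = character(0), ID = character(0))
  gr$source <- "ltrcensus"
  rtracklayer::export(gr, file, format = "GFF3")
  invisible(file)
}
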