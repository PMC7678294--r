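#' Assign reads to elements by word containment
#'
#' A read is assigned to the element whose word set contains the largest
#' fraction of the read's words (the better of the read's two strands),
#' provided that fraction reaches `min_containment`; ties break to the
#' lexicographically smallest element id, and each read is assigned to at
#' most one element. Chance containment for unrelated sequence is tiny at
#' word length 13, so background reads stay unassigned.
#'
#' @param reads a [ReadSet-class] or `DNAStringSet`.
#' @param consensi a named `DNAStringSet` of element/family references, all
#'   at least `k` bp.
#' @param k word length in bp.
#' @param min_containment minimum fraction of the read's words found in the
#'   element word set, in (0, 1].
#' @return integer vector of per-element read counts (named by element),
#'   with attribute `total_reads`.
#' @export
assignReads <- function(reads, consensi, k = 13, min_containment = 0.5) {
  if (min_containment <= 0 || min_containment > 1)
    stop("min_containment must lie in (0, 1]")
  if (!length(consensi)) stop("consensi must be non-empty")
  if (any(Biostrings::width(consensi) < k))
    stop("every element must be at least k bp long")
  rs <- if (is(reads, "ReadSet")) reads(reads) else reads
  ids <- names(consensi)
  if (is.null(ids)) ids <- sprintf("elem%03d", seq_along(consensi))
  ord <- order(ids)  # lexicographic tie-break
  sets <- lapply(seq_along(consensi), function(i) {
    s <- as.character(consensi[[i]])
    unique(c(seqWords(s, k), seqWords(revComp(s), k)))
  })
  counts <- setNames(integer(length(consensi)), ids)
  for (r in seq_along(rs)) {
    w <- seqWords(as.character(rs[[r]]), k)
    if (!length(w)) next
    best <- 0; best_id <- NA_character_
    for (i in ord) {
      cont <- mean(w %in% sets[[i]])
      if (cont > best) { best <- cont; best_id <- ids[i] }
    }
    if (best >= min_containment) counts[best_id] <- counts[best_id] + 1L
  }
  attr(counts, "total_reads") <- length(rs)
  counts
}

#' Per-dataset read census of a set of elements
#'
#' Runs [assignReads()] on each read set and assembles one row per element
#' with counts and fractions per platform plus a totals row, mirroring the
#' usual high-copy-repeat census layout (element size, per-platform counts,
#' per-platform fractions).
#'
#' @param read_sets list of [ReadSet-class] objects.
#' @param consensi named `DNAStringSet` of element references.
#' @param k,min_containment see [assignReads()].
#' @return a data.frame with columns `element`, `size`, one count column and
#'   one `frac_` column per platform; attribute `totals` holds per-platform
#'   read totals; fractions are raw (see [censusFractions()] for rounding).
#' @export
readCensus <- function(read_sets, consensi, k = 13, min_containment = 0.5) {
  ids <- names(consensi)
  df <- data.frame(element = ids, size = Biostrings::width(consensi))
  totals <- integer(0)
  for (rs in read_sets) {
    cnt <- assignReads(rs, consensi, k, min_containment)
    df[[platform(rs)]] <- as.integer(cnt[ids])
    df[[paste0("frac_", platform(rs))]] <-
      as.numeric(cnt[ids]) / attr(cnt, "total_reads")
    totals[platform(rs)] <- attr(cnt, "total_reads")
  }
  attr(df, "totals") <- totals
  df
}

#' Read-count fractions at reporting precision
#'
#' `fraction = count / total`, reported rounded to 3 decimals (the raw
#' value is returned alongside for downstream arithmetic).
#'
#' @param counts numeric vector (or matrix, elements x datasets) of read
#'   counts.
#' @param totals per-dataset totals (> 0), recycled across counts.
#' @return data.frame with columns `count`, `total`, `fraction` (raw) and
#'   `fraction_reported` (3 decimals).
#' @examples
#' censusFractions(57245, 439604)$fraction_reported  # 0.130
#' @export
censusFractions <- function(counts, totals) {
  if (any(totals <= 0)) stop("totals must be > 0")
  if (any(counts < 0) || any(counts > totals))
    stop("need 0 <= count <= total")
  f <- as.numeric(counts) / as.numeric(totals)
  data.frame(count = as.numeric(counts), total = as.numeric(totals),
             fraction = f, fraction_reported = roundHalfUp(f, 3))
}

#' Genome proportion to target bp and copy number
#'
#' The fraction of sequenced reads attributable to an element, multiplied by
#' genome size, gives the bp the element occupies per genome; dividing by
#' the element length gives its copy number (rounded half-up to the nearest
#' integer; the raw value is kept).
#'
#' @param fraction genome proportion in \[0, 1\].
#' @param genome_bp genome size in bp (> 0).
#' @param element_len element length in bp (> 0).
#' @return list with `target_bp`, `copies` (rounded) and `copies_raw`.
#' @examples
#' copiesFromFraction(0.138, 1.6e9, 12671)$target_bp / 1e6  # 220.8 Mbp
#' @export
copiesFromFraction <- function(fraction, genome_bp, element_len) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (genome_bp <= 0 || element_len <= 0)
    stop("genome_bp and element_len must be > 0")
  target_bp <- fraction * genome_bp
  raw <- target_bp / element_len
  list(target_bp = target_bp, copies = roundHalfUp(raw), copies_raw = raw)
}

#' Example read census: six high-copy orchid repeats over three read sets
#'
#' Published per-element read counts for six high-copy Phalaenopsis
#' repeats (a 16S rDNA, a MITE, an anc-like element and three LTR
#' retrotransposons) across three sequencing datasets (454, BAC-end
#' sequences, Illumina), with dataset totals and element sizes — the input
#' to the count -> fraction -> Mbp -> copies chain.
#'
#' @return list with `counts` (data.frame: element, size, one column per
#'   platform), `totals` (named numeric) and `published_fractions`
#'   (data.frame of the printed 3-decimal fractions).
#' @export
phalaenopsisReadCounts <- function() {
  counts <- data.frame(
    element = c("Orchid-its16S", "Orchid-mite1", "Orchid-rt-anc1",
                "Orchid-rt1", "Orchid-rt2", "Orchid-rt3"),
    size = c(2060, 317, 3396, 12754, 3059, 3410),
    c454 = c(1625, 500, 6961, 57245, 4650, 17457),
    BES = c(345, 30, 764, 2927, 247, 1999),
    Illumina = c(20914, 6640, 59493, 358553, 41109, 112842))
  totals <- c(c454 = 439604, BES = 18486, Illumina = 3354752)
  published_fractions <- data.frame(
    element = counts$element,
    c454 = c(0.004, 0.001, 0.016, 0.130, 0.011, 0.040),
    BES = c(0.019, 0.002, 0.041, 0.158, 0.013, 0.108),
    Illumina = c(0.006, 0.000, 0.018, 0.107, 0.012, 0.034))
  list(counts = counts, totals = totals,
       published_fractions = published_fractions)
}
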