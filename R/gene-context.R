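#' Map a consensus sequence onto a genome
#'
#' Seed-chain-extend local alignment on both strands: shared k-words between
#' the consensus and each contig are grouped into diagonal bands, chained,
#' and extended by X-drop; maximal blocks with `aligned_len >= min_len` and
#' identity `>= min_identity` are reported, with overlapping genomic loci
#' resolved to the best hit (identity, then length).
#'
#' @param consensus the query sequence (>= `min_len` bp).
#' @param genome a `DNAStringSet` of contigs.
#' @param min_len minimum aligned block length in bp.
#' @param min_identity minimum block identity.
#' @param k seed word length.
#' @param drift diagonal drift tolerance in bp.
#' @return a `GRanges` of hits with metadata columns `aligned_len`,
#'   `identity`; strand records the matching orientation.
#' @export
mapConsensusHits <- function(consensus, genome, min_len = 100,
                             min_identity = 0.8, k = 13, drift = 20) {
  q <- asDNACharacter(consensus)
  if (nchar(q) < min_len) stop("consensus shorter than min_len")
  if (!length(genome)) return(emptyHits())
  cnames <- names(genome)
  if (is.null(cnames)) cnames <- sprintf("contig%03d", seq_along(genome))
  hits <- list()
  for (ci in seq_along(genome)) {
    s <- asDNACharacter(genome[ci])
    for (str in c("+", "-")) {
      qq <- if (str == "+") q else revComp(q)
      blocks <- seedExtendBlocks(qq, s, k, drift, min_len, min_identity)
      if (nrow(blocks)) {
        blocks$contig <- cnames[ci]
        blocks$strand <- str
        hits[[length(hits) + 1L]] <- blocks
      }
    }
  }
  if (!length(hits)) return(emptyHits())
  df <- do.call(rbind, hits)
  # best-hit per locus: identity desc, length desc, leftmost
  df <- df[order(-df$identity, -df$aligned_len, df$start), ]
  kept <- rep(FALSE, nrow(df))
  for (i in seq_len(nrow(df))) {
    same <- kept & df$contig == df$contig[i] &
      df$start <= df$end[i] & df$end >= df$start[i]
    if (!any(same)) kept[i] <- TRUE
  }
  df <- df[kept, , drop = FALSE]
  df <- df[order(df$contig, df$start), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand, aligned_len = df$aligned_len, identity = df$identity)
}

emptyHits <- function() {
  GenomicRanges::GRanges(aligned_len = integer(0), identity = numeric(0))
}

# Shared-word seeding of query qq against subject s, banding by diagonal
# (j - i), X-drop extension of each chain, identity via global alignment of
# the two blocks. Returns a data.frame of subject blocks.
seedExtendBlocks <- function(qq, s, k, drift, min_len, min_identity) {
  none <- data.frame(start = integer(0), end = integer(0),
                     aligned_len = integer(0), identity = numeric(0))
  wq <- seqWords(qq, k)
  if (!length(wq)) return(none)
  pos_s <- split(seq_len(nchar(s) - k + 1L), seqWords(s, k))
  qi <- which(wq %in% names(pos_s))
  if (!length(qi)) return(none)
  ii <- integer(0); jj <- integer(0)
  for (i in qi) {
    js <- pos_s[[wq[i]]]
    if (length(js) > 24L) next  # low-complexity guard
    ii <- c(ii, rep.int(i, length(js))); jj <- c(jj, js)
  }
  if (!length(ii)) return(none)
  d <- jj - ii
  o <- order(d, ii)
  ii <- ii[o]; jj <- jj[o]; d <- d[o]
  band <- cumsum(c(1L, diff(d) > drift))
  vq <- strsplit(qq, "", fixed = TRUE)[[1L]]
  vs <- strsplit(s, "", fixed = TRUE)[[1L]]
  rows <- list()
  for (b in split(seq_along(ii), band)) {
    # split chains where query positions jump far apart (re-sort by query
    # position: band members arrive ordered by diagonal)
    b <- b[order(ii[b])]
    ib <- ii[b]; jb <- jj[b]
    ch <- cumsum(c(1L, diff(ib) > 2L * min_len + 200L))
    for (cc in split(seq_along(ib), ch)) {
      i0 <- min(ib[cc]); i1 <- max(ib[cc]) + k - 1L
      d0 <- as.integer(roundHalfUp(median(jb[cc] - ib[cc])))
      ext <- xdropExtendPair(vq, vs, i0, i1, d0)
      q0 <- ext[1L]; q1 <- ext[2L]
      len <- q1 - q0 + 1L
      if (len < min_len) next
      ident <- alignedIdentity(substr(qq, q0, q1),
                               substr(s, q0 + d0, q1 + d0))
      if (ident < min_identity) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = q0 + d0, end = q1 + d0, aligned_len = len, identity = ident)
    }
  }
  if (!length(rows)) return(none)
  unique(do.call(rbind, rows))
}

# X-drop extension of query block [i0, i1] against subject at offset d0.
xdropExtendPair <- function(vq, vs, i0, i1, d0, xdrop = 15L) {
  nq <- length(vq); ns <- length(vs)
  best <- 0L; cur <- 0L; best_t <- i1
  t <- i1 + 1L
  while (t <= nq && t + d0 <= ns) {
    cur <- cur + (if (vq[t] == vs[t + d0]) 1L else -2L)
    if (cur > best) { best <- cur; best_t <- t }
    if (cur < best - xdrop) break
    t <- t + 1L
  }
  end <- best_t
  best <- 0L; cur <- 0L; best_t <- i0
  t <- i0 - 1L
  while (t >= 1L && t + d0 >= 1L) {
    cur <- cur + (if (vq[t] == vs[t + d0]) 1L else -2L)
    if (cur > best) { best <- cur; best_t <- t }
    if (cur < best - xdrop) break
    t <- t - 1L
  }
  c(best_t, end)
}

#' Read gene models from GFF3
#'
#' Imports `exon` features and groups them by gene (via `Parent`/`gene_id`
#' attributes), returning one `GRangesList` element per gene with its exons
#' sorted and checked for overlap.
#'
#' @param path GFF3 file.
#' @return a named `GRangesList` of exons per gene.
#' @export
readGeneModels <- function(path) {
  gff <- rtracklayer::import(path, format = "GFF3")
  ex <- gff[tolower(gff$type) == "exon"]
  gene <- if (!is.null(ex$gene_id)) as.character(ex$gene_id)
    else vapply(ex$Parent, function(p)
      if (length(p)) sub("^(transcript|mRNA)[:_.]?", "", p[[1]])
      else NA_character_, character(1))
  grl <- S4Vectors::split(ex, gene)
  validateGeneModels(grl)
  grl
}

validateGeneModels <- function(genes) {
  for (nm in names(genes)) {
    ex <- genes[[nm]]
    ex <- ex[order(GenomicRanges::start(ex))]
    if (length(ex) > 1L &&
        any(GenomicRanges::start(ex)[-1L] <=
            GenomicRanges::end(ex)[-length(ex)]))
      stop("gene model ", nm, " has overlapping exons")
  }
  invisible(TRUE)
}

#' Classify an insertion hit against gene models
#'
#' A hit overlapping any exon by at least 1 bp is exonic (exon overlap takes
#' precedence for boundary-straddling hits); otherwise a hit fully inside a
#' gene's genomic span is intronic; otherwise it is intergenic (and carries
#' no gene id).
#'
#' @param hit a length-1 `GRanges` (one row of [mapConsensusHits()] output).
#' @param genes a named `GRangesList` of exons per gene
#'   (see [readGeneModels()]).
#' @return a data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `fragment_len`, `gene_id`, `context`.
#' @export
classifyInsertion <- function(hit, genes) {
  stopifnot(length(hit) == 1L)
  validateGeneModels(genes)
  gene_id <- NA_character_
  context <- "intergenic"
  if (length(genes)) {
    allex <- unlist(genes, use.names = FALSE)
    allex$gene <- rep(names(genes), lengths(genes))
    ov <- GenomicRanges::findOverlaps(hit, allex, minoverlap = 1L,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      gene_id <- allex$gene[S4Vectors::subjectHits(ov)[1L]]
      context <- "exon"
    } else {
      spans <- unlist(range(genes, ignore.strand = TRUE))
      within <- GenomicRanges::findOverlaps(hit, spans, type = "within",
                                            ignore.strand = TRUE)
      if (length(within)) {
        gene_id <- names(spans)[S4Vectors::subjectHits(within)[1L]]
        context <- "intron"
      }
    }
  }
  data.frame(
    contig = as.character(GenomicRanges::seqnames(hit)),
    start = GenomicRanges::start(hit), end = GenomicRanges::end(hit),
    strand = as.character(GenomicRanges::strand(hit)),
    fragment_len = GenomicRanges::width(hit),
    gene_id = gene_id, context = context)
}

#' Classify every hit in a set
#'
#' @param hits `GRanges` of hits.
#' @param genes named `GRangesList` of exons per gene.
#' @return data.frame, one row per hit (see [classifyInsertion()]).
#' @export
classifyInsertions <- function(hits, genes) {
  if (!length(hits))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      fragment_len = integer(0), gene_id = character(0),
                      context = character(0)))
  do.call(rbind, lapply(seq_along(hits), function(i)
    classifyInsertion(hits[i], genes)))
}

#' Summarize insertion contexts
#'
#' Partition counts over contexts and contig classes. Contigs whose name
#' matches `chrom_pattern` count as assembled chromosomes, the rest as
#' unplaced scaffolds. Counts always sum to the number of calls.
#'
#' @param calls data.frame from [classifyInsertions()].
#' @param chrom_pattern regex identifying chromosome-level contigs.
#' @return list with `total`, `chromosomal`, `scaffold`, `genic` (exon or
#'   intron), and `by_context` (named counts over exon/intron/intergenic).
#' @export
summarizeContexts <- function(calls, chrom_pattern = "^[Cc]hr") {
  ctx <- factor(calls$context, levels = c("exon", "intron", "intergenic"))
  on_chrom <- grepl(chrom_pattern, calls$contig)
  list(total = nrow(calls),
       chromosomal = sum(on_chrom),
       scaffold = sum(!on_chrom),
       genic = sum(ctx %in% c("exon", "intron")),
       by_context = table(ctx))
}
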