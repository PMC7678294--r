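#' Generate a random background contig
#'
#' Bases are drawn i.i.d. with the requested GC content; the result is
#' reproducible bit-for-bit for a fixed seed.
#'
#' @param length contig length in bp (> 0).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed.
#' @param id contig name.
#' @return a named [Biostrings::DNAStringSet] of length 1.
#' @examples
#' genBackground(1000, gc = 0.4, seed = 1)
#' @export
genBackground <- function(length, gc = 0.5, seed = 1, id = "contig") {
  if (length <= 0) stop("length must be > 0")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  s <- withSeed(seed, paste(randomBases(length, gc), collapse = ""))
  out <- Biostrings::DNAStringSet(s)
  names(out) <- id
  out
}

# Final coordinates for insertions at ascending original points p, where each
# insertion adds elen + tsd bases after p.
plantFinalStarts <- function(p, elens, tsd) {
  shift <- c(0, cumsum(elens + tsd))[seq_along(p)]
  p + shift + 1L
}

#' Plant an LTR element family into a genome
#'
#' Builds a random family template (LTR + internal region + LTR), then
#' inserts `n_full` mutated full-length copies and `n_solo` mutated solo LTRs
#' at uniform random positions. Each insertion duplicates the `tsd_len` host
#' bases immediately 5' of the insertion point on the 3' side of the element
#' (the target-site duplication). Copies are mutated independently at
#' substitution rate `divergence` (and, if `indel_rate > 0`, with single-base
#' indels), so the two LTRs of a full copy have expected pairwise identity
#' about `(1 - divergence)^2`.
#'
#' @param genome a 1-sequence `DNAStringSet` (or `DNAString`).
#' @param spec a [FamilySpec-class].
#' @param seed integer seed.
#' @param max_attempts placement rejection-sampling cap.
#' @param avoid optional `GRanges` of intervals insertion points must not
#'   fall inside (used to keep previously planted copies intact).
#' @param min_gap minimum distance in bp between insertion points (default
#'   just over the TSD length); raise it to emulate dispersed insertions.
#' @return a list with elements `genome` (the enlarged contig), `truth` (a
#'   [GenomicRanges::GRanges] ledger with metadata columns `family_id`,
#'   `kind` ("full"/"solo"), `divergence_applied`, `tsd`), and `template`
#'   (the unmutated full-element sequence).
#' @examples
#' g <- genBackground(20000, seed = 1)
#' p <- plantFamily(g, familySpec("fam1", 200, 1000, n_full = 1), seed = 2)
#' p$truth
#' @export
plantFamily <- function(genome, spec, seed = 1, max_attempts = 1000,
                        avoid = NULL, min_gap = 0) {
  host <- asDNACharacter(genome)
  cname <- contigName(genome)
  res <- withSeed(seed,
                  plantFamilyImpl(host, spec, max_attempts, avoid, min_gap))
  g <- Biostrings::DNAStringSet(res$genome)
  names(g) <- cname
  truth <- if (length(res$starts)) {
    GenomicRanges::GRanges(
      seqnames = cname,
      ranges = IRanges::IRanges(start = res$starts, width = res$elens),
      strand = "*",
      family_id = spec@family_id, kind = res$kinds,
      divergence_applied = res$div_applied, tsd = res$tsds)
  } else emptyTruth()
  list(genome = g, truth = truth, template = res$template)
}

plantFamilyImpl <- function(host, spec, max_attempts, avoid, min_gap = 0) {
  ltr <- paste(randomBases(spec@ltr_len), collapse = "")
  internal <- if (spec@internal_len > 0)
    paste(randomBases(spec@internal_len), collapse = "") else ""
  template <- paste0(ltr, internal, ltr)
  n <- spec@n_full + spec@n_solo
  if (n == 0L)
    return(list(genome = host, starts = integer(0), template = template))
  kinds <- c(rep("full", spec@n_full), rep("solo", spec@n_solo))
  copies <- vapply(kinds, function(kind) {
    raw <- if (kind == "full") template else ltr
    applyIndels(mutateBases(raw, spec@divergence)$seq, spec@indel_rate)
  }, character(1), USE.NAMES = FALSE)
  div_applied <- vapply(seq_along(kinds), function(i) {
    raw <- if (kinds[i] == "full") template else ltr
    # realized divergence against the unmutated copy (NA once indels shift frames)
    if (spec@indel_rate > 0) NA_real_
    else sum(strsplit(raw, "")[[1]] != strsplit(copies[i], "")[[1]]) / nchar(raw)
  }, numeric(1))
  # insertion points chosen on the ORIGINAL host, pairwise > tsd_len apart,
  # and outside `avoid` intervals (an insertion after position p splits p|p+1,
  # so p inside [start, end-1] of an interval would disrupt it)
  L <- nchar(host)
  lo <- spec@tsd_len + 1L
  hi <- L - 1L
  if (hi < lo) stop("genome too short to hold any insertion")
  av_s <- if (!is.null(avoid)) GenomicRanges::start(avoid) else integer(0)
  av_e <- if (!is.null(avoid)) GenomicRanges::end(avoid) else integer(0)
  pts <- integer(0)
  attempts <- 0L
  gap <- max(min_gap, spec@tsd_len + 1)
  while (length(pts) < n) {
    cand <- sample(lo:hi, 1L)
    ok <- (!length(pts) || min(abs(pts - cand)) >= gap) &&
      (!length(av_s) || !any(cand >= av_s & cand <= av_e - 1L))
    if (ok) {
      pts <- c(pts, cand)
    } else {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n, " non-overlapping copies (capacity error)")
    }
  }
  o <- order(pts)
  pts <- pts[o]; kinds <- kinds[o]; copies <- copies[o]
  div_applied <- div_applied[o]
  elens <- nchar(copies)
  tsds <- vapply(pts, function(p)
    if (spec@tsd_len > 0) substr(host, p - spec@tsd_len + 1L, p) else "",
    character(1))
  # assemble host[..p] + copy + tsd + host[p+1..], rightmost insertion first
  out <- host
  for (i in rev(seq_along(pts))) {
    out <- paste0(substr(out, 1L, pts[i]), copies[i], tsds[i],
                  substr(out, pts[i] + 1L, nchar(out)))
  }
  list(genome = out, starts = plantFinalStarts(pts, elens, spec@tsd_len),
       elens = elens, kinds = kinds, div_applied = div_applied, tsds = tsds,
       template = template)
}

emptyTruth <- function() {
  GenomicRanges::GRanges(family_id = character(0), kind = character(0),
                         divergence_applied = numeric(0), tsd = character(0))
}

#' Plant several families into one genome
#'
#' Families are planted sequentially; later families land in the genome as
#' enlarged by earlier ones (truth coordinates of earlier families are
#' shifted accordingly and remain exact).
#'
#' @param genome a 1-sequence `DNAStringSet`.
#' @param specs list of [FamilySpec-class] objects.
#' @param seed integer seed (one derived seed per family).
#' @return list with `genome`, combined `truth` ledger, and named `templates`.
#' @export
plantFamilies <- function(genome, specs, seed = 1) {
  truth <- emptyTruth()
  templates <- list()
  for (i in seq_along(specs)) {
    res <- plantFamily(genome, specs[[i]], seed = seed + i, avoid = truth)
    # shift previously planted intervals past each new insertion
    if (length(truth)) {
      newt <- res$truth
      for (j in seq_along(newt)) {
        ins_start <- GenomicRanges::start(newt)[j]
        ins_w <- GenomicRanges::width(newt)[j] + specs[[i]]@tsd_len
        later <- GenomicRanges::start(truth) >= ins_start
        truth[later] <- GenomicRanges::shift(truth[later], ins_w)
      }
    }
    truth <- c(truth, res$truth)
    templates[[specs[[i]]@family_id]] <- res$template
    genome <- res$genome
  }
  truth <- sort(truth)
  list(genome = genome, truth = truth, templates = templates)
}

#' Simulate uniform shotgun reads
#'
#' Read start positions are uniform over the genome on both strands;
#' sequencing errors are i.i.d. substitutions at `error_rate`.
#'
#' @param genome a 1-sequence `DNAStringSet`.
#' @param platform platform label (e.g. "454", "BES", "Illumina").
#' @param read_len read length in bp (<= genome length).
#' @param n_reads number of reads (>= 0).
#' @param error_rate per-base substitution error rate in \[0, 0.1\].
#' @param seed integer seed.
#' @return a [ReadSet-class].
#' @examples
#' g <- genBackground(5000, seed = 1)
#' simulateReads(g, "Illumina", read_len = 100, n_reads = 10,
#'               error_rate = 0.01, seed = 2)
#' @export
simulateReads <- function(genome, platform, read_len, n_reads,
                          error_rate = 0, seed = 1) {
  s <- asDNACharacter(genome)
  L <- nchar(s)
  if (read_len > L) stop("read_len exceeds genome length")
  if (n_reads < 0) stop("n_reads must be >= 0")
  reads <- if (n_reads == 0L) character(0) else withSeed(seed, {
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    vapply(seq_len(n_reads), function(i) {
      r <- substr(s, starts[i], starts[i] + read_len - 1L)
      if (strands[i] == "-") r <- revComp(r)
      mutateBases(r, error_rate)$seq
    }, character(1))
  })
  rs <- Biostrings::DNAStringSet(reads)
  if (length(rs))
    names(rs) <- sprintf("%s_read%06d", platform, seq_len(n_reads))
  new("ReadSet", reads = rs, platform = as.character(platform),
      read_len = as.integer(read_len), error_rate = as.numeric(error_rate))
}

#' Simulate a slot-blot dilution series
#'
#' Slot intensity at exponent e follows
#' `K * loaded_mass * mass_fraction * base^-e * (1 + eps)`, with `K` a fixed
#' arbitrary gain and `eps` multiplicative log-normal noise of coefficient of
#' variation `noise_cv` (mean 1). With `noise_cv = 0` consecutive slots have
#' intensity ratio exactly `base`.
#'
#' @param mass_fraction fraction of the loaded mass that is probe target,
#'   in \[0, 1\] (for a plasmid standard, insert mass / total mass; for
#'   genomic DNA, ng target per ng loaded).
#' @param base dilution factor per step.
#' @param exponents non-negative integer exponents of the ladder.
#' @param loaded_mass mass loaded at exponent 0, in ng.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return a [DilutionSeries-class].
#' @export
simulateSlotBlot <- function(mass_fraction, base = 3, exponents = 0:5,
                             loaded_mass = 10, noise_cv = 0, seed = 1) {
  if (mass_fraction < 0 || mass_fraction > 1)
    stop("mass_fraction must lie in [0, 1]")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  K <- 1000  # arbitrary fixed gain (intensity units per ng of target)
  mu <- K * loaded_mass * mass_fraction * base^(-exponents)
  eps <- withSeed(seed, {
    if (noise_cv == 0) rep(1, length(exponents))
    else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      rlnorm(length(exponents), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  })
  dilutionSeries(base, exponents, mu * eps, loaded_mass)
}

#' Write a simulated data set to disk
#'
#' Writes the genome as FASTA, each read set as FASTA or FASTQ (constant
#' quality), the truth ledger as BED (0-based half-open) and a JSON manifest
#' echoing the family specifications and seed.
#'
#' @param dir output directory (created if absent).
#' @param genome 1-sequence `DNAStringSet`.
#' @param truth truth-ledger `GRanges`.
#' @param read_sets list of [ReadSet-class] objects.
#' @param specs list of [FamilySpec-class] objects used.
#' @param seed the seed used.
#' @param fastq write reads as FASTQ (default) rather than FASTA.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(dir, genome, truth, read_sets = list(),
                            specs = list(), seed = NA, fastq = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             truth = file.path(dir, "truth.bed"),
             manifest = file.path(dir, "manifest.json"))
  Biostrings::writeXStringSet(genome, paths[["genome"]])
  tr <- truth
  names(tr) <- paste(tr$family_id, tr$kind, seq_along(tr), sep = "_")
  rtracklayer::export(tr, paths[["truth"]], format = "BED")
  for (rs in read_sets) {
    ext <- if (fastq) "fastq" else "fasta"
    p <- file.path(dir, paste0("reads_", rs@platform, ".", ext))
    if (fastq) {
      q <- Biostrings::BStringSet(rep(paste(rep("I", rs@read_len), collapse = ""),
                                      length(rs@reads)))
      Biostrings::writeXStringSet(rs@reads, p, format = "fastq", qualities = q)
    } else {
      Biostrings::writeXStringSet(rs@reads, p, format = "fasta")
    }
    paths[rs@platform] <- p
  }
  manifest <- list(
    seed = seed,
    genome_length = Biostrings::width(genome)[1],
    families = lapply(specs, function(sp) list(
      family_id = sp@family_id, ltr_len = sp@ltr_len,
      internal_len = sp@internal_len, n_full = sp@n_full,
      n_solo = sp@n_solo, divergence = sp@divergence, tsd_len = sp@tsd_len)),
    read_sets = lapply(read_sets, function(rs) list(
      platform = rs@platform, n_reads = length(rs@reads),
      read_len = rs@read_len, error_rate = rs@error_rate)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
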