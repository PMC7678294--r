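#' Shared-word (dot-plot style) similarity between two sequences
#'
#' A reproducible surrogate for visual dot-plot comparison: the fraction of
#' one sequence's words (counting both strands) found in the other's word
#' set, symmetrized by averaging the two directions. Identical sequences
#' score 1; unrelated random sequences score near 0 for `word` around 12
#' because chance word hits are rare (about `n / 4^word` per word).
#'
#' @param a,b sequences, each at least `word` bp long.
#' @param word word length in bp.
#' @return similarity in \[0, 1\].
#' @examples
#' s <- genBackground(500, seed = 1)[[1]]
#' pairwiseWordSimilarity(s, s)  # 1
#' @export
pairwiseWordSimilarity <- function(a, b, word = 12) {
  a <- asDNACharacter(a)
  b <- asDNACharacter(b)
  if (nchar(a) < word || nchar(b) < word)
    stop("sequences must be at least `word` bp long")
  wa <- seqWords(a, word); wb <- seqWords(b, word)
  hitFrac <- function(wx, y) {
    set <- unique(c(seqWords(y, word), seqWords(revComp(y), word)))
    mean(wx %in% set)
  }
  (hitFrac(wa, b) + hitFrac(wb, a)) / 2
}

#' Cluster elements into families by single linkage
#'
#' Two elements are connected when their shared-word similarity is at least
#' `threshold`; families are the connected components of that graph, ordered
#' by size (descending) then by smallest member id. Elements connected to
#' nothing become singleton families. A majority-vote consensus is built for
#' each family, and a Gypsy/Copia superfamily is assigned where domain
#' annotations are supplied.
#'
#' @param elements a named `DNAStringSet` (e.g. from [extractElementSeqs()]).
#' @param threshold similarity threshold in (0, 1].
#' @param word word length for [pairwiseWordSimilarity()].
#' @param domains optional named list of [domainAnnotation()] objects keyed
#'   by element name; a family's superfamily is the unanimous call over its
#'   annotated members ("unknown" otherwise).
#' @param prefix family id prefix.
#' @return an [LTRFamilySet-class].
#' @examples
#' e <- genBackground(400, seed = 1)
#' els <- Biostrings::DNAStringSet(c(a = as.character(e[[1]]),
#'                                   b = as.character(e[[1]])))
#' clusterElements(els)
#' @export
clusterElements <- function(elements, threshold = 0.5, word = 12,
                            domains = NULL, prefix = "family") {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  n <- length(elements)
  if (n == 0L)
    return(new("LTRFamilySet",
               info = S4Vectors::DataFrame(
                 family_id = character(0), n_elements = integer(0),
                 superfamily = character(0),
                 member_ids = IRanges::CharacterList()),
               consensus = Biostrings::DNAStringSet()))
  ids <- names(elements)
  if (is.null(ids)) ids <- sprintf("elem%03d", seq_len(n))
  adj <- matrix(FALSE, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      adj[i, j] <- adj[j, i] <-
        pairwiseWordSimilarity(elements[[i]], elements[[j]], word) >= threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(seq_len(n), comp)
  # order: size descending, then smallest member id
  ord <- order(-lengths(groups),
               vapply(groups, function(ix) min(ids[ix]), character(1)))
  groups <- groups[ord]
  member_ids <- IRanges::CharacterList(unname(lapply(groups, function(ix) ids[ix])))
  cons <- Biostrings::DNAStringSet(vapply(groups, function(ix)
    as.character(buildConsensus(elements[ix])), character(1)))
  superf <- vapply(groups, function(ix) {
    if (is.null(domains)) return("unknown")
    calls <- unique(vapply(ids[ix], function(id) {
      if (is.null(domains[[id]])) "unknown"
      else classifySuperfamily(domains[[id]])
    }, character(1)))
    calls <- setdiff(calls, "unknown")
    if (length(calls) == 1L) calls else "unknown"
  }, character(1))
  info <- S4Vectors::DataFrame(
    family_id = sprintf("%s%d", prefix, seq_along(groups)),
    n_elements = unname(lengths(groups)), superfamily = unname(superf),
    member_ids = member_ids)
  names(info$member_ids) <- info$family_id
  names(cons) <- info$family_id
  new("LTRFamilySet", info = info, consensus = cons)
}

#' Majority-vote consensus of a family
#'
#' Star alignment of every member to the longest member; each reference
#' column takes the majority base over the aligned members (gaps count;
#' base ties break alphabetically; columns whose majority is a gap are
#' dropped), so the consensus is never longer than the longest member.
#'
#' @param members a `DNAStringSet` with at least one sequence.
#' @return a `DNAString` consensus.
#' @examples
#' m <- Biostrings::DNAStringSet(c("ACGTACGT", "ACGTACGT", "ACGAACGT"))
#' buildConsensus(m)
#' @export
buildConsensus <- function(members) {
  if (length(members) == 0L) stop("empty family")
  if (length(members) == 1L) return(members[[1L]])
  ref_i <- which.max(Biostrings::width(members))
  ref <- members[[ref_i]]
  L <- length(ref)
  # votes[base, column] over reference coordinates; '-' rows are deletions
  bases <- c("A", "C", "G", "T", "-")
  votes <- matrix(0L, nrow = 5L, ncol = L, dimnames = list(bases, NULL))
  rv <- strsplit(as.character(ref), "")[[1L]]
  for (m in seq_along(members)) {
    if (m == ref_i) {
      idx <- cbind(match(rv, bases), seq_len(L))
      votes[idx] <- votes[idx] + 1L
      next
    }
    aln <- Biostrings::pairwiseAlignment(members[[m]], ref, type = "global")
    ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    col <- 0L
    for (t in seq_along(as_)) {
      if (as_[t] == "-") next  # insertion relative to reference: dropped
      col <- col + 1L
      bi <- match(ap[t], bases)
      if (!is.na(bi)) votes[bi, col] <- votes[bi, col] + 1L
    }
  }
  win <- apply(votes, 2L, function(cl) bases[which.max(cl)])  # ties: alphabetical
  Biostrings::DNAString(paste(win[win != "-"], collapse = ""))
}

#' Domain annotation of an element's pol polyprotein
#'
#' Ordered protein-domain labels with their start coordinates on the
#' element: PR (protease), RT (reverse transcriptase), RH (RNase H),
#' INT (integrase).
#'
#' @param labels character vector over {"PR", "RT", "RH", "INT"}.
#' @param starts strictly increasing start positions (bp); defaults to the
#'   label order given.
#' @return a data.frame with columns `label`, `start`.
#' @export
domainAnnotation <- function(labels, starts = seq_along(labels)) {
  if (!all(labels %in% c("PR", "RT", "RH", "INT")))
    stop("labels must be among PR, RT, RH, INT")
  if (length(labels) != length(starts)) stop("one start per label required")
  if (is.unsorted(starts, strictly = TRUE))
    stop("starts must be strictly increasing")
  data.frame(label = labels, start = as.numeric(starts))
}

#' Classify an element's superfamily from its domain order
#'
#' Gypsy and Copia elements differ in the order of reverse transcriptase
#' (RT) and integrase (INT) in the pol polyprotein: INT downstream of RT is
#' Gypsy-like, INT upstream of RT is Copia-like. If either domain is absent
#' the call is "unknown".
#'
#' @param domains a [domainAnnotation()] data.frame.
#' @return "gypsy", "copia" or "unknown".
#' @examples
#' classifySuperfamily(domainAnnotation(c("PR", "RT", "RH", "INT")))  # gypsy
#' classifySuperfamily(domainAnnotation(c("PR", "INT", "RT", "RH")))  # copia
#' @export
classifySuperfamily <- function(domains) {
  rt <- domains$start[domains$label == "RT"]
  int <- domains$start[domains$label == "INT"]
  if (!length(rt) || !length(int)) return("unknown")
  if (int[1L] > rt[1L]) "gypsy" else "copia"
}

#' Family summary table
#'
#' One row per family with element counts and representative lengths:
#' consensus total length plus, when detection output is supplied, the
#' median LTR and internal (CDS) lengths over member candidates.
#'
#' @param famset an [LTRFamilySet-class].
#' @param candidates optional detection `GRanges` whose names match member
#'   ids (provides per-member `ltr_len` / `internal_len`).
#' @return a data.frame with columns `family_id`, `n_elements`,
#'   `superfamily`, `total_length`, `ltr_length`, `cds_length`.
#' @export
familyTable <- function(famset, candidates = NULL) {
  info <- familyInfo(famset)
  ltr_len <- cds_len <- rep(NA_real_, nrow(info))
  if (!is.null(candidates) && length(candidates)) {
    for (i in seq_len(nrow(info))) {
      ix <- match(info$member_ids[[i]], names(candidates))
      ix <- ix[!is.na(ix)]
      if (length(ix)) {
        ltr_len[i] <- median(candidates$ltr_len[ix])
        cds_len[i] <- median(candidates$internal_len[ix])
      }
    }
  }
  data.frame(family_id = info$family_id, n_elements = info$n_elements,
             superfamily = info$superfamily,
             total_length = Biostrings::width(consensi(famset)),
             ltr_length = ltr_len, cds_length = cds_len)
}
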