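#' Specification of a planted LTR-retrotransposon family
#'
#' Describes the geometry and copy structure of one family to be planted in a
#' synthetic genome: full-length elements are two near-identical long terminal
#' repeats (LTRs) flanking an internal coding region; solo LTRs are single
#' terminal repeats left behind by unequal homologous recombination. The
#' default geometry (707 bp LTR, 11,257 bp internal region, 12,671 bp total)
#' is that of a high-copy orchid Gypsy-like element.
#'
#' @slot family_id single character family label.
#' @slot ltr_len LTR length in bp (>= 50).
#' @slot internal_len internal (coding) region length in bp (>= 0).
#' @slot n_full number of full-length copies to plant.
#' @slot n_solo number of solo-LTR copies to plant.
#' @slot divergence per-copy substitution rate per site, in \[0, 0.5).
#' @slot tsd_len target-site duplication length in bp, in \[0, 10\].
#' @slot indel_rate optional per-site indel rate applied after substitutions
#'   (default 0; keeps the coordinate truth exact).
#' @export
setClass("FamilySpec",
  representation(family_id = "character", ltr_len = "integer",
                 internal_len = "integer", n_full = "integer",
                 n_solo = "integer", divergence = "numeric",
                 tsd_len = "integer", indel_rate = "numeric"))

setValidity("FamilySpec", function(object) {
  msg <- character(0)
  if (length(object@family_id) != 1L || !nzchar(object@family_id))
    msg <- c(msg, "family_id must be a non-empty character scalar")
  if (object@ltr_len < 50L) msg <- c(msg, "ltr_len must be >= 50")
  if (object@internal_len < 0L) msg <- c(msg, "internal_len must be >= 0")
  if (object@n_full < 0L || object@n_solo < 0L)
    msg <- c(msg, "copy counts must be >= 0")
  if (object@divergence < 0 || object@divergence >= 0.5)
    msg <- c(msg, "divergence must lie in [0, 0.5)")
  if (object@tsd_len < 0L || object@tsd_len > 10L)
    msg <- c(msg, "tsd_len must lie in [0, 10]")
  if (object@indel_rate < 0 || object@indel_rate > 0.1)
    msg <- c(msg, "indel_rate must lie in [0, 0.1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FamilySpec
#'
#' @param family_id family label.
#' @param ltr_len,internal_len element geometry in bp; the full element is
#'   `2 * ltr_len + internal_len` bp long.
#' @param n_full,n_solo numbers of full-length and solo-LTR copies.
#' @param divergence per-copy substitution rate per site.
#' @param tsd_len target-site duplication length in bp.
#' @param indel_rate optional per-site indel rate (default 0).
#' @return a [FamilySpec-class] object.
#' @examples
#' familySpec("rt1", ltr_len = 707, internal_len = 11257, n_full = 1)
#' @export
familySpec <- function(family_id, ltr_len = 707, internal_len = 11257,
                       n_full = 1, n_solo = 0, divergence = 0,
                       tsd_len = 5, indel_rate = 0) {
  new("FamilySpec", family_id = as.character(family_id),
      ltr_len = as.integer(ltr_len), internal_len = as.integer(internal_len),
      n_full = as.integer(n_full), n_solo = as.integer(n_solo),
      divergence = as.numeric(divergence), tsd_len = as.integer(tsd_len),
      indel_rate = as.numeric(indel_rate))
}

#' @describeIn FamilySpec-class total length of one full element in bp.
#' @param object,x a `FamilySpec`.
#' @export
setGeneric("elementLength", function(x) standardGeneric("elementLength"))

#' @rdname FamilySpec-class
#' @export
setMethod("elementLength", "FamilySpec",
          function(x) 2L * x@ltr_len + x@internal_len)

setMethod("show", "FamilySpec", function(object) {
  cat("FamilySpec", object@family_id, ": ",
      object@ltr_len, "bp LTR + ", object@internal_len,
      "bp internal (", elementLength(object), " bp total); ",
      object@n_full, " full, ", object@n_solo, " solo; divergence ",
      object@divergence, ", TSD ", object@tsd_len, " bp\n", sep = "")
})

#' A simulated shotgun read set
#'
#' Fixed-length single-end reads drawn uniformly from both strands of a
#' genome with i.i.d. substitution errors, tagged with a platform label
#' (e.g. "454", "BES", "Illumina").
#'
#' @slot reads named [Biostrings::DNAStringSet] of reads.
#' @slot platform platform label.
#' @slot read_len declared read length in bp.
#' @slot error_rate per-base substitution error rate in \[0, 0.1\].
#' @export
setClass("ReadSet",
  representation(reads = "DNAStringSet", platform = "character",
                 read_len = "integer", error_rate = "numeric"))

setValidity("ReadSet", function(object) {
  msg <- character(0)
  if (length(object@reads) && !all(Biostrings::width(object@reads) == object@read_len))
    msg <- c(msg, "all reads must have the declared read_len")
  if (object@error_rate < 0 || object@error_rate > 0.1)
    msg <- c(msg, "error_rate must lie in [0, 0.1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ReadSet-class number of reads.
#' @param object,x a `ReadSet`.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

#' @describeIn ReadSet-class the reads as a `DNAStringSet`.
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname ReadSet-class
#' @export
setMethod("reads", "ReadSet", function(x) x@reads)

#' @describeIn ReadSet-class the platform label.
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))

#' @rdname ReadSet-class
#' @export
setMethod("platform", "ReadSet", function(x) x@platform)

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet [", object@platform, "]: ", length(object@reads), " reads of ",
      object@read_len, " bp, error rate ", object@error_rate, "\n", sep = "")
})

#' A slot-blot serial dilution series
#'
#' Hybridization intensities for a geometric dilution ladder: slot at
#' exponent e received `loaded_mass * base^-e` of DNA, and its intensity is
#' proportional to the mass of probe target present.
#'
#' @slot base dilution factor per step (e.g. 3).
#' @slot exponents non-negative integer exponents, one per slot.
#' @slot intensities non-negative intensities (arbitrary units), one per slot.
#' @slot loaded_mass mass loaded at exponent 0, in ng.
#' @export
setClass("DilutionSeries",
  representation(base = "numeric", exponents = "integer",
                 intensities = "numeric", loaded_mass = "numeric"))

setValidity("DilutionSeries", function(object) {
  msg <- character(0)
  if (object@base <= 1) msg <- c(msg, "base must be > 1")
  if (length(object@exponents) != length(object@intensities))
    msg <- c(msg, "one intensity per exponent required")
  if (any(object@exponents < 0L)) msg <- c(msg, "exponents must be >= 0")
  if (any(object@intensities < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@loaded_mass <= 0) msg <- c(msg, "loaded_mass must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DilutionSeries from measured intensities
#'
#' @param base dilution factor per step.
#' @param exponents integer exponents of the ladder.
#' @param intensities measured intensities, one per exponent.
#' @param loaded_mass mass loaded at exponent 0 (ng).
#' @return a [DilutionSeries-class] object.
#' @export
dilutionSeries <- function(base, exponents, intensities, loaded_mass) {
  new("DilutionSeries", base = as.numeric(base),
      exponents = as.integer(exponents),
      intensities = as.numeric(intensities),
      loaded_mass = as.numeric(loaded_mass))
}

#' @describeIn DilutionSeries-class slot intensities.
#' @param object,x a `DilutionSeries`.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname DilutionSeries-class
#' @export
setMethod("intensities", "DilutionSeries", function(x) x@intensities)

setMethod("show", "DilutionSeries", function(object) {
  cat("DilutionSeries: base ", object@base, ", ", length(object@exponents),
      " slots, ", object@loaded_mass, " ng loaded at exponent 0\n", sep = "")
})

#' Parameters for structural LTR element detection
#'
#' @slot k seed word length in bp (>= 8).
#' @slot min_ltr,max_ltr admissible LTR length window in bp.
#' @slot min_elem,max_elem admissible full-element length window in bp.
#' @slot min_identity minimum global-alignment identity of the two LTRs.
#' @slot tsd_search if `TRUE`, a 4-6 bp exact target-site duplication
#'   flanking the element is required (and annotated).
#' @slot drift diagonal drift tolerance in bp when chaining seed matches.
#' @export
setClass("DetectParams",
  representation(k = "integer", min_ltr = "integer", max_ltr = "integer",
                 min_elem = "integer", max_elem = "integer",
                 min_identity = "numeric", tsd_search = "logical",
                 drift = "integer"))

setValidity("DetectParams", function(object) {
  msg <- character(0)
  if (object@k < 8L) msg <- c(msg, "k must be >= 8")
  if (!(object@min_ltr <= object@max_ltr && object@min_elem <= object@max_elem &&
        object@min_ltr < object@min_elem && object@max_ltr <= object@max_elem))
    msg <- c(msg, "need min_ltr <= max_ltr <= max_elem and min_ltr < min_elem <= max_elem")
  if (object@min_identity <= 0 || object@min_identity > 1)
    msg <- c(msg, "min_identity must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct detection parameters
#'
#' Defaults bracket the element geometries typically seen for plant
#' Gypsy/Copia elements (LTRs of a few hundred bp to ~3 kb, elements up to
#' ~20 kb) with margin.
#'
#' @param k seed word length (bp).
#' @param min_ltr,max_ltr LTR length window (bp).
#' @param min_elem,max_elem element length window (bp).
#' @param min_identity minimum LTR pair identity.
#' @param tsd_search require/annotate a 4-6 bp target-site duplication.
#' @param drift diagonal drift tolerance (bp) for seed chaining.
#' @return a [DetectParams-class] object.
#' @export
detectParams <- function(k = 13, min_ltr = 100, max_ltr = 3000,
                         min_elem = 1500, max_elem = 20000,
                         min_identity = 0.8, tsd_search = TRUE, drift = 20) {
  new("DetectParams", k = as.integer(k), min_ltr = as.integer(min_ltr),
      max_ltr = as.integer(max_ltr), min_elem = as.integer(min_elem),
      max_elem = as.integer(max_elem), min_identity = as.numeric(min_identity),
      tsd_search = as.logical(tsd_search), drift = as.integer(drift))
}

setMethod("show", "DetectParams", function(object) {
  cat("DetectParams: k=", object@k, ", LTR [", object@min_ltr, ",",
      object@max_ltr, "] bp, element [", object@min_elem, ",",
      object@max_elem, "] bp, identity >= ", object@min_identity,
      if (object@tsd_search) ", TSD required" else "", "\n", sep = "")
})

#' A set of LTR element families
#'
#' The result of clustering detected elements by shared-word similarity:
#' families are the connected components of the similarity graph, ordered by
#' size (largest first). Each family carries its members, a majority-vote
#' consensus and, when domain annotations were supplied, a Gypsy/Copia
#' superfamily call.
#'
#' @slot info a [S4Vectors::DataFrame] with one row per family: `family_id`,
#'   `n_elements`, `superfamily`, and `member_ids` (a CharacterList).
#' @slot consensus [Biostrings::DNAStringSet] of per-family consensi, parallel
#'   to `info`.
#' @export
setClass("LTRFamilySet",
  representation(info = "DataFrame", consensus = "DNAStringSet"))

setValidity("LTRFamilySet", function(object) {
  msg <- character(0)
  need <- c("family_id", "n_elements", "superfamily", "member_ids")
  if (!all(need %in% colnames(object@info)))
    msg <- c(msg, paste("info must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(object@info) != length(object@consensus))
      msg <- c(msg, "one consensus per family required")
    n <- lengths(object@info$member_ids)
    if (!all(object@info$n_elements == n))
      msg <- c(msg, "n_elements must equal the member count")
    ids <- unlist(object@info$member_ids)
    if (anyDuplicated(ids))
      msg <- c(msg, "families must partition the element set")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LTRFamilySet-class number of families.
#' @param object,x an `LTRFamilySet`.
#' @export
setMethod("length", "LTRFamilySet", function(x) nrow(x@info))

#' @describeIn LTRFamilySet-class per-family metadata `DataFrame`.
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))

#' @rdname LTRFamilySet-class
#' @export
setMethod("familyInfo", "LTRFamilySet", function(x) x@info)

#' @describeIn LTRFamilySet-class per-family consensus sequences.
#' @export
setGeneric("consensi", function(x) standardGeneric("consensi"))

#' @rdname LTRFamilySet-class
#' @export
setMethod("consensi", "LTRFamilySet", function(x) x@consensus)

setMethod("show", "LTRFamilySet", function(object) {
  n <- nrow(object@info)
  cat("LTRFamilySet with ", n, " famil", if (n == 1) "y" else "ies",
      " over ", sum(object@info$n_elements), " elements\n", sep = "")
  if (n) {
    df <- data.frame(family_id = object@info$family_id,
                     n_elements = object@info$n_elements,
                     superfamily = object@info$superfamily,
                     consensus_len = Biostrings::width(object@consensus))
    print(head(df, 8))
    if (n > 8) cat("... and", n - 8, "more\n")
  }
})
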