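#' Probe-target mass of a plasmid standard
#'
#' A plasmid of known total mass carries the probe target as an insert; the
#' insert's share of the mass is its share of the length:
#' `total_mass * insert_len / (insert_len + vector_len)`.
#'
#' @param total_mass plasmid mass loaded (ng).
#' @param insert_len insert length (bp).
#' @param vector_len vector backbone length (bp, >= 0).
#' @return insert mass in ng.
#' @examples
#' insertMass(10, 707, 3015)   # 1.9 ng
#' insertMass(10, 5121, 3015)  # 6.3 ng
#' @export
insertMass <- function(total_mass, insert_len, vector_len) {
  if (total_mass <= 0 || insert_len <= 0 || vector_len < 0)
    stop("masses and lengths must be positive (vector_len >= 0)")
  total_mass * insert_len / (insert_len + vector_len)
}

#' Match intensities between two dilution series
#'
#' Finds the plasmid/genomic exponent pair whose (non-zero) intensities are
#' closest in log space — the computational analogue of spotting "similar
#' intensity" slots on a blot. Ties go to the smallest plasmid exponent,
#' then the smallest genomic exponent.
#'
#' @param plasmid,gdna [DilutionSeries-class] objects.
#' @return named numeric of the matched exponents, `c(exp_p, exp_g)`.
#' @export
matchDilution <- function(plasmid, gdna) {
  ip <- intensities(plasmid); ig <- intensities(gdna)
  ep <- plasmid@exponents; eg <- gdna@exponents
  okp <- ip > 0; okg <- ig > 0
  if (!any(okp) || !any(okg))
    stop("cannot match all-zero intensity series")
  ip <- ip[okp]; ep <- ep[okp]; ig <- ig[okg]; eg <- eg[okg]
  grid <- expand.grid(p = seq_along(ep), g = seq_along(eg))
  d <- abs(log(ip[grid$p]) - log(ig[grid$g]))
  o <- order(d, ep[grid$p], eg[grid$g])
  c(exp_p = ep[grid$p[o[1L]]], exp_g = eg[grid$g[o[1L]]])
}

#' Target mass per microgram of genomic DNA
#'
#' From the matched dilution pair: the plasmid slot held
#' `insert_ng * factor_p` of target; the genomic slot held
#' `gdna_loaded * factor_g` of genomic DNA; their intensities being equal,
#' a microgram of genomic DNA carries
#' `insert_ng * factor_p / (gdna_loaded * factor_g)` ng of target.
#'
#' @param insert_ng probe-target mass in the undiluted plasmid standard (ng).
#' @param factor_p,factor_g dilution factors in (0, 1] (e.g. `3^-2`).
#' @param gdna_loaded genomic DNA loaded at exponent 0 (micrograms).
#' @return ng of target per microgram of genomic DNA.
#' @examples
#' ngPerUg(1.9, 3^-2, 3^-1, 1)  # ~0.63
#' @export
ngPerUg <- function(insert_ng, factor_p, factor_g, gdna_loaded = 1) {
  if (factor_p <= 0 || factor_p > 1 || factor_g <= 0 || factor_g > 1)
    stop("dilution factors must lie in (0, 1]")
  if (gdna_loaded <= 0) stop("gdna_loaded must be > 0")
  insert_ng * factor_p / (gdna_loaded * factor_g)
}

#' Copies per genome from a hybridization mass estimate
#'
#' `ng_per_ug * 1e-3` is the target's mass fraction of genomic DNA; times
#' the genome size it gives the bp of target per genome, and divided by the
#' segment length the copy number (rounded half-up).
#'
#' @param ng_per_ug ng of target per microgram of genomic DNA.
#' @param genome_bp genome size in bp.
#' @param segment_len probe segment length in bp (e.g. the LTR or CDS).
#' @param species optional species label.
#' @param segment optional segment label.
#' @return data.frame with `species`, `segment`, `ng_per_ug`, `target_bp`,
#'   `mb_per_genome` (3 decimals), `copies` and `copies_raw`.
#' @examples
#' copiesPerGenome(0.63, 1.6e9, 707)   # 1.008 Mbp, 1426 copies
#' copiesPerGenome(6.3, 1.52e9, 5121)  # 9.576 Mbp, 1870 copies
#' @export
copiesPerGenome <- function(ng_per_ug, genome_bp, segment_len,
                            species = NA_character_, segment = NA_character_) {
  if (ng_per_ug < 0) stop("ng_per_ug must be >= 0")
  if (genome_bp <= 0 || segment_len <= 0)
    stop("genome_bp and segment_len must be > 0")
  target_bp <- ng_per_ug * 1e-3 * genome_bp
  raw <- target_bp / segment_len
  data.frame(species = species, segment = segment, ng_per_ug = ng_per_ug,
             target_bp = target_bp,
             mb_per_genome = roundHalfUp(target_bp / 1e6, 3),
             copies = roundHalfUp(raw), copies_raw = raw)
}

#' Interpret the LTR:CDS copy-number ratio
#'
#' An intact element carries two LTRs per CDS, so a ratio near 2 means the
#' population is mostly full-length; a ratio well above 2 indicates excess
#' solo LTRs (recombination-deleted elements); below 2(1 - tol) an LTR
#' deficit. The solo-LTR estimate is `max(copies_ltr - 2 * copies_cds, 0)`.
#'
#' @param copies_ltr,copies_cds LTR and CDS copy numbers (`copies_cds` > 0).
#' @param tol relative tolerance around the 2:1 expectation.
#' @return list with `ratio`, `solo_ltr_estimate` and `flag` (one of
#'   "mostly_full_length", "solo_ltr_excess", "ltr_deficit").
#' @examples
#' interpretLtrCds(1115, 219)   # ~5.1-fold: solo-LTR excess
#' interpretLtrCds(1426, 1968)  # 0.72: LTR deficit
#' @export
interpretLtrCds <- function(copies_ltr, copies_cds, tol = 0.25) {
  if (copies_cds <= 0) stop("copies_cds must be > 0")
  ratio <- copies_ltr / copies_cds
  flag <- if (abs(ratio - 2) <= 2 * tol) "mostly_full_length"
    else if (ratio > 2 * (1 + tol)) "solo_ltr_excess"
    else "ltr_deficit"
  list(ratio = ratio,
       solo_ltr_estimate = max(copies_ltr - 2 * copies_cds, 0),
       flag = flag)
}

#' Copy-number fold change between two genomes
#'
#' @param copies_a,copies_b copy numbers (`copies_b` > 0).
#' @return list with `fold` (raw ratio) and `fold_reported` (rounded
#'   half-up to the nearest integer).
#' @examples
#' foldChange(43840, 1115)$fold_reported  # 39
#' @export
foldChange <- function(copies_a, copies_b) {
  if (copies_b <= 0) stop("copies_b must be > 0")
  f <- copies_a / copies_b
  list(fold = f, fold_reported = roundHalfUp(f))
}

#' Slot-blot copy-number table for a panel of species and probes
#'
#' Applies [copiesPerGenome()] to every species x probe combination of a
#' measured ng-per-microgram table, reproducing the usual three-block layout
#' (ng/ug, Mb/genome, copies/genome).
#'
#' @param ng_table data.frame with columns `species`, `segment`,
#'   `ng_per_ug`, `segment_len`.
#' @param genomes named numeric of genome sizes in bp, keyed by species.
#' @return data.frame, one row per species x segment, as in
#'   [copiesPerGenome()].
#' @export
slotBlotTable <- function(ng_table, genomes) {
  need <- c("species", "segment", "ng_per_ug", "segment_len")
  if (!all(need %in% names(ng_table)))
    stop("ng_table needs columns: ", paste(need, collapse = ", "))
  if (!all(ng_table$species %in% names(genomes)))
    stop("every species needs a genome size")
  do.call(rbind, lapply(seq_len(nrow(ng_table)), function(i)
    copiesPerGenome(ng_table$ng_per_ug[i], genomes[[ng_table$species[i]]],
                    ng_table$segment_len[i], species = ng_table$species[i],
                    segment = ng_table$segment[i])))
}

#' Example slot-blot panel: four Phalaenopsis genomes, four Gypsy-like probes
#'
#' Measured hybridization results for the LTR (and, where assayed, CDS)
#' probes of four high-copy Gypsy-like retrotransposons (Orchid-rt1 and
#' Gypsy1-3) across four Phalaenopsis species, as ng of target per microgram
#' of genomic DNA, together with the probe segment lengths, published genome
#' sizes and the published Mb/copies values for regression checks.
#'
#' @return list with `ng_table` (input to [slotBlotTable()]), `genomes`
#'   (bp), and `published` (the printed Mb/genome and copies/genome values).
#' @export
phalaenopsisSlotBlot <- function() {
  species <- c("P_equestris", "P_aphrodite", "P_violacea", "P_bellina")
  genomes <- c(P_equestris = 1.6e9, P_aphrodite = 1.52e9,
               P_violacea = 6.99e9, P_bellina = 7.07e9)
  seg <- rbind(
    data.frame(segment = "Orchid-rt1-LTR", segment_len = 707,
               ng = c(0.63, 1.9, 1.9, 1.9)),
    data.frame(segment = "Orchid-rt1-CDS", segment_len = 5121,
               ng = c(6.3, 6.3, 6.3, 6.3)),
    data.frame(segment = "Gypsy1-LTR", segment_len = 1722,
               ng = c(1.2, 3.6, 10.8, 10.8)),
    data.frame(segment = "Gypsy1-CDS", segment_len = 5110,
               ng = c(0.7, 2.1, 6.3, 6.3)),
    data.frame(segment = "Gypsy2-LTR", segment_len = 1720,
               ng = c(3.6, 10.8, 3.6, 3.6)),
    data.frame(segment = "Gypsy3-LTR", segment_len = 1641,
               ng = c(3.5, 1.17, 3.5, 3.5)))
  ng_table <- data.frame(species = rep(species, times = 6),
                         segment = seg$segment, ng_per_ug = seg$ng,
                         segment_len = seg$segment_len)
  published <- data.frame(
    species = ng_table$species, segment = ng_table$segment,
    mb_per_genome = c(1.008, 2.888, 13.281, 13.433,
                      10.08, 9.576, 44.037, 44.541,
                      1.92, 5.472, 75.492, 76.356,
                      1.12, 3.192, 44.037, 44.541,
                      5.76, 16.416, 25.164, 25.452,
                      5.6, 1.778, 24.465, 24.745),
    copies = c(1426, 4085, 18785, 19000,
               1968, 1870, 8599, 8698,
               1115, 3178, 43840, 44341,
               219, 625, 8618, 8716,
               3349, 9544, 14630, 14798,
               3413, 1083, 14909, 15079))
  list(ng_table = ng_table, genomes = genomes, published = published)
}
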