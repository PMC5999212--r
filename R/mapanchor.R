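# Anchoring unmapped loci onto the linkage map via proximity to mapped loci
# on proxy-genome alignments. Coordinates are 0-based half-open (BED).

#' Assign unmapped loci to the nearest mapped locus on a proxy genome
#'
#' For every unmapped locus with a qualifying alignment, finds the nearest
#' mapped locus on the same contig of the same genome (gap distance between
#' intervals, 0 when they overlap) and assigns the donor's linkage-map
#' position when the gap is at most `max_distance` and both alignments have
#' mapping quality at least `min_mapq`. Ties are broken by the
#' lexicographically smallest donor locus id.
#'
#' @param alignments Tibble `locus`, `genome`, `contig`, `start`, `end`,
#'   `mapq` covering both mapped and unmapped loci.
#' @param linkage_map Tibble `locus`, `chromosome`, `cM`, `mapped`.
#' @param min_mapq Minimum mapping quality for both ends (default 10).
#' @param max_distance Maximum gap in bp (default 100000).
#' @return Tibble `locus`, `donor`, `genome`, `distance`, `chromosome`, `cM`
#'   with one row per (unmapped locus, genome) that found a qualifying donor.
#' @export
closest_mapped <- function(alignments, linkage_map, min_mapq = 10L,
                           max_distance = 1e5) {
  stopifnot(all(alignments$start < alignments$end), all(alignments$mapq >= 0))
  mapped_ids <- linkage_map$locus[linkage_map$mapped]
  aln <- dplyr::filter(alignments, .data$mapq >= min_mapq)
  m <- dplyr::filter(aln, .data$locus %in% mapped_ids)
  u <- dplyr::filter(aln, !.data$locus %in% mapped_ids)
  if (!nrow(m) || !nrow(u)) {
    return(tibble::tibble(locus = character(), donor = character(),
                          genome = character(), distance = numeric(),
                          chromosome = integer(), cM = numeric()))
  }
  pairs <- dplyr::inner_join(
    u, m, by = c("genome", "contig"), suffix = c("", "_donor"),
    relationship = "many-to-many")
  pairs <- dplyr::mutate(pairs, distance = pmax(
    0, pmax(.data$start, .data$start_donor) -
      pmin(.data$end, .data$end_donor)))
  pairs <- dplyr::filter(pairs, .data$distance <= max_distance)
  best <- dplyr::arrange(pairs, .data$locus, .data$genome, .data$distance,
                         .data$locus_donor)
  best <- dplyr::distinct(best, .data$locus, .data$genome, .keep_all = TRUE)
  out <- dplyr::select(best, "locus", donor = "locus_donor", "genome",
                       "distance")
  dplyr::left_join(out,
                   dplyr::select(linkage_map, donor = "locus", "chromosome",
                                 "cM"),
                   by = "donor")
}

#' Reconcile map assignments made through different proxy genomes
#'
#' A locus assigned through exactly one genome keeps that assignment. A locus
#' assigned through both keeps it only when the assigned chromosomes agree,
#' taking the position of the smaller-distance donor; chromosome conflicts
#' are dropped and reported.
#'
#' @param assignments Output of [closest_mapped()] over one or more genomes
#'   (rows carry a `genome` column), or a list of such tibbles.
#' @return Tibble with one row per retained locus (`locus`, `donor`,
#'   `genome`, `distance`, `chromosome`, `cM`, `n_genomes`); dropped
#'   conflicting loci in `attr(, "conflicts")`.
#' @export
reconcile_genomes <- function(assignments) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    assignments <- dplyr::bind_rows(assignments)
  }
  grp <- dplyr::group_by(assignments, .data$locus)
  info <- dplyr::mutate(grp,
                        n_genomes = dplyr::n(),
                        agree = dplyr::n_distinct(.data$chromosome) == 1L)
  conflicts <- dplyr::ungroup(dplyr::filter(info, !.data$agree))
  kept <- dplyr::ungroup(dplyr::filter(info, .data$agree))
  kept <- dplyr::arrange(kept, .data$locus, .data$distance, .data$genome)
  kept <- dplyr::distinct(kept, .data$locus, .keep_all = TRUE)
  out <- dplyr::select(kept, -"agree")
  attr(out, "conflicts") <- dplyr::arrange(
    dplyr::select(conflicts, -"agree", -"n_genomes"), .data$locus)
  out
}

#' Anchor unmapped loci and extend the linkage map
#'
#' Runs [closest_mapped()] per genome, reconciles across genomes, and returns
#' the map with inferred positions filled in (`inferred` flags them).
#'
#' @inheritParams closest_mapped
#' @return List of class `hatch_anchor`: `assignments` (reconciled),
#'   `conflicts`, and `map` (input map with anchored loci given their donor's
#'   chromosome and cM, `mapped` left FALSE, `inferred` TRUE).
#' @export
anchor_map <- function(alignments, linkage_map, min_mapq = 10L,
                       max_distance = 1e5) {
  asg <- closest_mapped(alignments, linkage_map, min_mapq, max_distance)
  rec <- reconcile_genomes(asg)
  map <- dplyr::mutate(linkage_map, inferred = FALSE)
  hit <- match(rec$locus, map$locus)
  ok <- !is.na(hit)
  map$chromosome[hit[ok]] <- rec$chromosome[ok]
  map$cM[hit[ok]] <- rec$cM[ok]
  map$inferred[hit[ok]] <- TRUE
  structure(list(assignments = rec, conflicts = attr(rec, "conflicts"),
                 map = map),
            class = "hatch_anchor")
}
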