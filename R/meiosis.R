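#' Random bivalent pairing
#'
#' Partitions the `ploidy` homologue indices into `ploidy/2` disjoint pairs,
#' uniformly over all perfect matchings (3 for a tetraploid, 15 for a
#' hexaploid). Only bivalents are formed; quadrivalents and preferential
#' pairing are not modelled.
#'
#' @param ploidy even integer `>= 2`.
#' @return A `ploidy/2 x 2` integer matrix of 1-based homologue indices.
#' @examples
#' set.seed(1)
#' pair_bivalents(4)
#' @export
pair_bivalents <- function(ploidy) {
  if (length(ploidy) != 1 || ploidy < 2 || ploidy %% 2 != 0)
    stop("ploidy must be an even integer >= 2")
  perm <- sample.int(ploidy)
  matrix(perm, ncol = 2, byrow = TRUE)
}

#' One recombinant chromatid from a bivalent
#'
#' Simulates the meiotic product of one bivalent as a two-state Markov walk
#' along the ordered markers of a single chromosome: the first marker's
#' source homologue is chosen uniformly from the pair, and between adjacent
#' markers at distance `d` the source switches with probability
#' [haldane_r()]`(d)`, independently per interval (no interference).
#'
#' @param parent integer matrix of homologue rows (`ploidy x m` allele or
#'   founder-label codes) restricted to one chromosome.
#' @param pair length-2 vector of 1-based homologue row indices.
#' @param positions_cM marker positions (non-decreasing) of the chromosome.
#' @return Integer vector of length `m`: the chromatid's codes.
#' @export
recombinant_chromatid <- function(parent, pair, positions_cM) {
  stopifnot(is.matrix(parent), length(pair) == 2,
            all(pair >= 1), all(pair <= nrow(parent)),
            length(positions_cM) == ncol(parent))
  r <- haldane_r(pmax(diff(positions_cM), 0))
  drop(cpp_chromatid(parent, pair[1] - 1L, pair[2] - 1L, r))
}

#' Simulate one gamete
#'
#' For each chromosome independently, a fresh random bivalent pairing is
#' drawn and one recombinant chromatid is produced per bivalent. Founder
#' labels are propagated segment-wise together with the SNP states they
#' index.
#'
#' @param parent integer matrix (`ploidy x m`) of homologue codes over the
#'   whole map.
#' @param map a [genetic_map()] with `m` markers.
#' @return Integer matrix (`ploidy/2 x m`): the gamete's homologues.
#' @export
make_gamete <- function(parent, map) {
  stopifnot(is.matrix(parent), ncol(parent) == nrow(map),
            nrow(parent) %% 2 == 0)
  cpp_gamete(parent, .map_chrom_start(map), .map_r_adj(map))
}

#' Cross two parents
#'
#' Offspring genotype = one gamete from each parent (maternal homologues
#' first). Selfing is not forbidden here; enforcing outbreeding is the
#' caller's responsibility (as it is during drift simulation).
#'
#' @param mother,father integer matrices (`ploidy x m`) of homologue codes.
#' @param map a [genetic_map()].
#' @return Integer matrix (`ploidy x m`).
#' @export
cross <- function(mother, father, map) {
  if (nrow(mother) != nrow(father)) stop("ploidy mismatch between parents")
  rbind(make_gamete(mother, map), make_gamete(father, map))
}
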