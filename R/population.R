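#' Simulate founder genotypes
#'
#' Each founder homologue receives an independent fair-coin SNP state per
#' marker, and a globally unique founder label (constant along the
#' homologue). With the defaults (10 tetraploid founders) an ancestral group
#' segregates for 40 founder (IBD) alleles.
#'
#' @param n_founders number of founder individuals.
#' @param map a [genetic_map()].
#' @param ploidy even integer, 4 by default.
#' @param label_offset integer added to all founder labels, so several
#'   ancestral groups can share one global label universe.
#' @return A `pq_founders` list: `labels` (`(n_founders*ploidy) x m` matrix,
#'   each row constant), `states` (same shape, 0/1 SNP states, row `i` is
#'   the haplotype of founder label `label_offset + i`), `label_offset`,
#'   `ploidy`, `map`.
#' @export
simulate_founders <- function(n_founders = 10, map, ploidy = 4,
                              label_offset = 0L) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) >= 1, ploidy %% 2 == 0)
  m <- nrow(map)
  H <- n_founders * ploidy
  labels <- matrix(rep(label_offset + seq_len(H), m), nrow = H)
  states <- matrix(as.integer(stats::runif(H * m) < 0.5), nrow = H)
  structure(list(labels = labels, states = states,
                 label_offset = as.integer(label_offset),
                 n_founders = n_founders, ploidy = ploidy, map = map),
            class = "pq_founders")
}

#' Random-mating drift of an ancestral group
#'
#' Starting from the founders, each generation consists of `size` offspring
#' of uniformly random distinct parent pairs drawn from the previous
#' generation (no selfing, no monogamy constraint, no selection, migration
#' or mutation). Founder labels drift to fixation or loss; after 50
#' generations at size 100 roughly a third of the 40 founder alleles
#' typically survive at a locus.
#'
#' @param founders a `pq_founders` object from [simulate_founders()].
#' @param generations number of generations of random mating (0 returns the
#'   founders unchanged).
#' @param size constant population size per generation.
#' @return An `ancestral_group` list: `labels`
#'   (`(size*ploidy) x m` homologue matrix of founder labels),
#'   `founder_states`, `founder_labels` (the 40-label universe), `ploidy`,
#'   `map`, plus the history parameters.
#' @export
drift_generations <- function(founders, generations = 50, size = 100) {
  stopifnot(inherits(founders, "pq_founders"), founders$n_founders >= 2)
  map <- founders$map
  ploidy <- founders$ploidy
  cs <- .map_chrom_start(map)
  r <- .map_r_adj(map)
  cur <- founders$labels
  n_cur <- founders$n_founders
  gen <- generations
  while (gen > 0) {
    pairs <- .sample_parent_pairs(n_cur, size)
    cur <- cpp_cross_batch(cur, ploidy, pairs[, 1], pairs[, 2], cs, r)
    n_cur <- size
    gen <- gen - 1
  }
  structure(list(labels = cur, founder_states = founders$states,
                 founder_labels = founders$label_offset +
                   seq_len(founders$n_founders * ploidy),
                 n_founders = founders$n_founders,
                 generations = generations,
                 size = n_cur, ploidy = ploidy, map = map),
            class = "ancestral_group")
}

# uniform over ordered pairs of distinct individuals, redrawn per offspring
.sample_parent_pairs <- function(n, size) {
  mo <- sample.int(n, size, replace = TRUE)
  fa <- sample.int(n, size, replace = TRUE)
  while (any(bad <- fa == mo))
    fa[bad] <- sample.int(n, sum(bad), replace = TRUE)
  cbind(mo, fa)
}

#' Simulate a pool of ancestral groups
#'
#' Convenience wrapper generating `n_ag` independent ancestral groups with a
#' shared global founder-label universe (group `g` owns labels
#' `(g-1)*n_founders*ploidy + 1 ...`).
#'
#' @inheritParams simulate_founders
#' @inheritParams drift_generations
#' @param n_ag number of ancestral groups.
#' @return List of `ancestral_group` objects.
#' @export
simulate_ag_pool <- function(n_ag = 10, map, n_founders = 10,
                             generations = 50, size = 100, ploidy = 4) {
  lapply(seq_len(n_ag), function(g) {
    f <- simulate_founders(n_founders, map, ploidy,
                           label_offset = (g - 1L) * n_founders * ploidy)
    drift_generations(f, generations, size)
  })
}

#' Per-locus distinct founder-allele counts
#'
#' @param ag an `ancestral_group` (or any object with a homologue `labels`
#'   matrix).
#' @return Integer vector: number of distinct founder labels segregating at
#'   each marker.
#' @export
founder_allele_counts <- function(ag) {
  L <- if (is.matrix(ag)) ag else ag$labels
  apply(L, 2, function(x) length(unique(x)))
}

#' Build a NAM population
#'
#' A nested association mapping population: one central parent crossed to
#' `n_peripheral` peripheral parents, each cross producing
#' `offspring_per_cross` offspring (10 + 9*50 = 460 individuals with the
#' defaults). The 10 parents are sampled without replacement from
#' `diversity_k` ancestral groups with per-group counts as equal as
#' possible; the central parent always comes from the group providing the
#' most parents (ties broken by lowest group index). Parents are part of the
#' analyzed population.
#'
#' @param ags list of `ancestral_group` objects (the fixed pool).
#' @param diversity_k number of distinct ancestral groups parents are drawn
#'   from (1, 3, 7 or 10 in the standard design).
#' @param n_peripheral number of peripheral parents (crosses).
#' @param offspring_per_cross offspring per cross.
#' @return A `nam_pop` list: `labels` (`(n_ind*ploidy) x m` founder-label
#'   homologue matrix; central parent first, then peripheral parents, then
#'   offspring family by family), `states_lookup` (row `l` = SNP haplotype
#'   of founder label `l`; `NA` rows for labels of uninvolved groups),
#'   `family` (0 for parents, 1..n_peripheral for offspring),
#'   `individual` ids, `ploidy`, `map`, `diversity_k`, `parent_ag` (group
#'   index of each parent, central first).
#' @export
build_nam <- function(ags, diversity_k, n_peripheral = 9,
                      offspring_per_cross = 50) {
  n_parents <- n_peripheral + 1L
  if (diversity_k > length(ags)) stop("diversity_k exceeds available AGs")
  map <- ags[[1]]$map
  ploidy <- ags[[1]]$ploidy
  m <- nrow(map)

  chosen <- sort(sample.int(length(ags), diversity_k))
  base <- n_parents %/% diversity_k
  counts <- rep(base, diversity_k)
  extra <- n_parents %% diversity_k
  if (extra > 0) counts[sample.int(diversity_k, extra)] <- base + 1L
  central_slot <- which(counts == max(counts))[1]  # lowest index on ties

  # sample parent individuals without replacement within each AG
  parent_ag <- integer(0); parent_rows <- list()
  for (i in seq_len(diversity_k)) {
    ag <- ags[[chosen[i]]]
    ids <- sample.int(ag$size, counts[i])
    for (id in ids) {
      parent_rows[[length(parent_rows) + 1L]] <-
        ag$labels[((id - 1L) * ploidy + 1L):(id * ploidy), , drop = FALSE]
      parent_ag <- c(parent_ag, chosen[i])
    }
  }
  # reorder: a random parent of the central slot's AG first
  central_cand <- which(parent_ag == chosen[central_slot])
  central <- central_cand[sample.int(length(central_cand), 1)]
  ord <- c(central, setdiff(seq_len(n_parents), central))
  parent_rows <- parent_rows[ord]
  parent_ag <- parent_ag[ord]

  parent_labels <- do.call(rbind, parent_rows)
  mothers <- rep(1L, n_peripheral * offspring_per_cross)
  fathers <- rep(2:(n_peripheral + 1L), each = offspring_per_cross)
  off <- cpp_cross_batch(parent_labels, ploidy, mothers, fathers,
                         .map_chrom_start(map), .map_r_adj(map))

  max_label <- max(vapply(ags[chosen], function(a) max(a$founder_labels), 0))
  states_lookup <- matrix(NA_integer_, nrow = max_label, ncol = m)
  label_ag <- rep(NA_integer_, max_label)
  for (g in chosen) {
    a <- ags[[g]]
    states_lookup[a$founder_labels, ] <- a$founder_states
    label_ag[a$founder_labels] <- g
  }

  n_ind <- n_parents + n_peripheral * offspring_per_cross
  structure(list(
    labels = rbind(parent_labels, off),
    states_lookup = states_lookup,
    individual = c(sprintf("P%02d", seq_len(n_parents)),
                   sprintf("F%d_%02d", fathers - 1L,
                           rep(seq_len(offspring_per_cross), n_peripheral))),
    family = c(rep(0L, n_parents),
               rep(seq_len(n_peripheral), each = offspring_per_cross)),
    n_ind = n_ind, ploidy = ploidy, map = map, label_ag = label_ag,
    diversity_k = diversity_k, parent_ag = parent_ag),
    class = "nam_pop")
}

#' @export
print.nam_pop <- function(x, ...) {
  cat(sprintf(
    "NAM population: %d individuals (ploidy %d), %d markers, diversity %d AG(s)\n",
    x$n_ind, x$ploidy, ncol(x$labels), x$diversity_k))
  invisible(x)
}

#' SNP states of every homologue
#'
#' Looks each founder label up in the founder haplotypes to recover the 0/1
#' SNP state carried at every marker.
#'
#' @param pop a `nam_pop`.
#' @return Integer 0/1 matrix, same shape as `pop$labels`.
#' @export
snp_states <- function(pop) {
  L <- pop$labels
  m <- ncol(L)
  S <- pop$states_lookup[cbind(as.vector(L), rep(seq_len(m), each = nrow(L)))]
  if (anyNA(S)) stop("founder label without a haplotype in states_lookup")
  matrix(S, nrow = nrow(L))
}
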