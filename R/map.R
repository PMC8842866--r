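#' Construct a genetic map
#'
#' A genetic map is an ordered table of markers with a chromosome identifier
#' and a position in centimorgan (cM). Within a chromosome positions must be
#' non-decreasing; marker names must be unique. Duplicate positions are
#' allowed (co-segregating markers) and the given order of tied markers is
#' preserved.
#'
#' @param marker character vector of unique marker names.
#' @param chromosome chromosome identifier per marker (coerced to character).
#' @param position_cM numeric map position per marker, in cM, `>= 0`.
#' @return A `genetic_map`: a `data.frame` with columns `marker`,
#'   `chromosome`, `position_cM`, sorted by chromosome (first-appearance
#'   order) and position.
#' @examples
#' gm <- genetic_map(c("m1", "m2", "m3"), c(1, 1, 2), c(0, 10.5, 3))
#' chrom_lengths(gm)
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  n <- length(marker)
  stopifnot(length(chromosome) == n, length(position_cM) == n, n >= 1)
  if (anyDuplicated(marker)) stop("duplicate marker names in map")
  if (any(!is.finite(position_cM)) || any(position_cM < 0))
    stop("map positions must be finite and >= 0")
  chrom_order <- unique(chromosome)
  o <- order(match(chromosome, chrom_order), position_cM)
  map <- data.frame(marker = marker[o], chromosome = chromosome[o],
                    position_cM = position_cM[o], stringsAsFactors = FALSE)
  rownames(map) <- NULL
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' @export
print.genetic_map <- function(x, ...) {
  cl <- chrom_lengths(x)
  cat(sprintf("genetic map: %d markers on %d chromosome(s), %.1f cM total\n",
              nrow(x), length(cl), sum(cl)))
  invisible(x)
}

#' Chromosome lengths of a map
#'
#' @param map a [genetic_map()].
#' @return Named numeric vector: maximum position per chromosome (cM).
#' @export
chrom_lengths <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  vapply(split(map$position_cM, factor(map$chromosome, unique(map$chromosome))),
         max, numeric(1))
}

#' Haldane mapping function
#'
#' Converts a map distance in cM to a recombination fraction under the
#' no-interference (Haldane) model: `r = 0.5 * (1 - exp(-2 d / 100))`.
#'
#' @param d numeric vector of map distances in cM; must be finite and `>= 0`.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane_r(50) # 0.5 * (1 - exp(-1))
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0))
    stop("haldane_r: distances must be finite and >= 0")
  0.5 * (1 - exp(-2 * d / 100))
}

#' Map distance between two markers
#'
#' Absolute cM distance if the markers are on the same chromosome, `Inf`
#' ("unlinked") otherwise. `Inf` compares greater than any finite linking
#' distance, so unlinked pairs can never be chained into one QTL interval.
#'
#' @param map a [genetic_map()].
#' @param a,b marker names.
#' @return Numeric distance in cM, or `Inf` for cross-chromosome pairs.
#' @seealso [is_unlinked()]
#' @export
marker_distance <- function(map, a, b) {
  ia <- match(a, map$marker); ib <- match(b, map$marker)
  if (is.na(ia)) stop("unknown marker: ", a)
  if (is.na(ib)) stop("unknown marker: ", b)
  if (map$chromosome[ia] != map$chromosome[ib]) return(Inf)
  abs(map$position_cM[ia] - map$position_cM[ib])
}

#' Is a marker distance "unlinked"?
#'
#' @param d value returned by [marker_distance()].
#' @return `TRUE` for cross-chromosome (infinite) distances.
#' @export
is_unlinked <- function(d) is.infinite(d)

#' Generate a synthetic genetic map
#'
#' Markers are distributed over chromosomes proportionally to chromosome
#' length, with positions drawn uniformly and sorted; the first and last
#' marker of each chromosome are anchored at 0 and the chromosome length so
#' the requested total length is realized exactly. The default emulates a
#' dense tetraploid crop map: 3509 markers on 5 chromosomes spanning 485 cM.
#'
#' @param n_markers total number of markers.
#' @param lengths_cM numeric vector of chromosome lengths in cM. The
#'   default mimics the first five chromosomes of a dense tetraploid potato
#'   map (485 cM total, chromosome 4 long enough to carry a QTL at
#'   100.49 cM).
#' @return A [genetic_map()].
#' @export
synthetic_map <- function(n_markers = 3509,
                          lengths_cM = c(115, 96, 88, 106, 80)) {
  nchrom <- length(lengths_cM)
  stopifnot(n_markers >= 2 * nchrom, all(lengths_cM > 0))
  # proportional allocation, remainders to the longest chromosomes
  frac <- n_markers * lengths_cM / sum(lengths_cM)
  cnt <- pmax(floor(frac), 2L)
  while (sum(cnt) < n_markers) {
    i <- which.max(frac - cnt); cnt[i] <- cnt[i] + 1L
  }
  while (sum(cnt) > n_markers) {
    ok <- cnt > 2L
    i <- which(ok)[which.min((frac - cnt)[ok])]; cnt[i] <- cnt[i] - 1L
  }
  pos <- lapply(seq_len(nchrom), function(c) {
    k <- cnt[c]
    p <- sort(stats::runif(k - 2L, 0, lengths_cM[c]))
    c(0, p, lengths_cM[c])
  })
  genetic_map(marker = paste0("c", rep(seq_len(nchrom), cnt), "_m",
                              unlist(lapply(cnt, seq_len))),
              chromosome = rep(seq_len(nchrom), cnt),
              position_cM = unlist(pos))
}

#' Thin a map to one marker per cM
#'
#' For kinship construction, marker density bias is mitigated by selecting an
#' evenly distributed subset: per chromosome, for each integer cM gridpoint
#' from 0 up to the chromosome end, the nearest marker is selected
#' (deduplicated, map order preserved). The selection depends only on the
#' map, never on genotype data.
#'
#' @param map a [genetic_map()].
#' @return Integer vector of row indices into `map` (sorted, unique).
#' @export
thin_one_per_cM <- function(map) {
  stopifnot(inherits(map, "genetic_map"), nrow(map) >= 1)
  idx <- integer(0)
  for (ch in unique(map$chromosome)) {
    rows <- which(map$chromosome == ch)
    pos <- map$position_cM[rows]
    grid <- 0:ceiling(max(pos))
    sel <- vapply(grid, function(g) rows[which.min(abs(pos - g))], integer(1))
    idx <- c(idx, unique(sel))
  }
  sort(unique(idx))
}

# interval recombination fractions between adjacent markers; entries that
# straddle a chromosome boundary are set to 0.5 but are never used by the
# meiosis walk (pairing restarts per chromosome)
.map_r_adj <- function(map) {
  m <- nrow(map)
  if (m < 2) return(numeric(0))
  d <- diff(map$position_cM)
  r <- haldane_r(pmax(d, 0))
  r[map$chromosome[-m] != map$chromosome[-1]] <- 0.5
  r
}

# 0-based chromosome start offsets plus terminal m, for the C++ core
.map_chrom_start <- function(map) {
  ch <- factor(map$chromosome, unique(map$chromosome))
  c(0L, cumsum(tabulate(ch)))
}
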