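#' Specify QTL architecture
#'
#' Three major QTLs plus a configurable number of small-effect polygenic
#' loci define the standard simulated trait. Major positions default to the
#' standard design (chr 1 at 67.88 cM, chr 2 at 61.2 cM, chr 4 at
#' 100.49 cM); positions are validated against the map and later snapped to
#' the nearest marker for effect lookup.
#'
#' @param major data.frame with columns `chromosome`, `position_cM`.
#' @param n_polygenic number of polygenic loci placed uniformly at random
#'   across the genome.
#' @param map optional [genetic_map()] used to validate that every major
#'   position lies within its chromosome's range.
#' @return A `qtl_spec` list.
#' @export
qtl_spec <- function(major = data.frame(
                       chromosome = c("1", "2", "4"),
                       position_cM = c(67.88, 61.2, 100.49)),
                     n_polygenic = 50, map = NULL) {
  major$chromosome <- as.character(major$chromosome)
  if (!is.null(map)) {
    cl <- chrom_lengths(map)
    if (!all(major$chromosome %in% names(cl)))
      stop("QTL chromosome not on the map")
    if (any(major$position_cM > cl[major$chromosome] + 1e-9) ||
        any(major$position_cM < 0))
      stop("QTL position outside its chromosome's range")
  }
  structure(list(major = major, n_polygenic = as.integer(n_polygenic)),
            class = "qtl_spec")
}

#' Realized (marker-snapped) QTL positions
#'
#' Effects are assigned at the map marker nearest to each requested QTL
#' position; power metrics should therefore score intervals against these
#' realized positions rather than the nominal ones.
#'
#' @param qtls a [qtl_spec()] or data.frame with `chromosome`,
#'   `position_cM`.
#' @param map a [genetic_map()].
#' @return data.frame with `chromosome`, `position_cM` of the snapped
#'   markers.
#' @export
qtl_positions <- function(qtls, map) {
  major <- if (inherits(qtls, "qtl_spec")) qtls$major else qtls
  idx <- vapply(seq_len(nrow(major)), function(i)
    .snap_to_marker(map, major$chromosome[i], major$position_cM[i]),
    integer(1))
  data.frame(chromosome = map$chromosome[idx],
             position_cM = map$position_cM[idx], stringsAsFactors = FALSE)
}

# nearest map marker index to (chromosome, position)
.snap_to_marker <- function(map, chromosome, position_cM) {
  rows <- which(map$chromosome == as.character(chromosome))
  if (length(rows) == 0) stop("QTL chromosome not on the map: ", chromosome)
  rows[which.min(abs(map$position_cM[rows] - position_cM))]
}

#' Assign additive effects to founder alleles
#'
#' At each major QTL, every contributing ancestral group receives a random
#' allelic mean (`Normal(0, sigma_ag^2)`) and each of its founder labels an
#' effect drawn around that mean (`Normal(mean, sigma_within^2)`); allele
#' effects are constant across individuals. Polygenic loci are placed
#' uniformly on the map and receive independent per-label effects, rescaled
#' so that jointly they contribute `polygenic_fraction` of the realized
#' genetic variance. The residual standard deviation is then set so the
#' realized broad-sense heritability matches `h2` in expectation.
#'
#' @param nam a `nam_pop`.
#' @param qtls a [qtl_spec()].
#' @param sigma_ag SD of ancestral-group allelic means (trait units).
#' @param sigma_within SD of allele effects around their group mean.
#' @param polygenic_fraction fraction of genetic variance contributed by the
#'   polygenic loci.
#' @param h2 target broad-sense heritability `Var(g)/Var(y)`.
#' @return An `effect_model` list: per-QTL label-indexed effect vectors,
#'   snapped marker indices, and the realized `sigma_poly` scale and
#'   `sigma_e`.
#' @export
assign_effects <- function(nam, qtls, sigma_ag = 1, sigma_within = 0.5,
                           polygenic_fraction = 0.3, h2 = 0.6) {
  map <- nam$map
  max_label <- length(nam$label_ag)
  ags_present <- sort(unique(nam$label_ag[!is.na(nam$label_ag)]))

  major_idx <- vapply(seq_len(nrow(qtls$major)), function(i)
    .snap_to_marker(map, qtls$major$chromosome[i], qtls$major$position_cM[i]),
    integer(1))

  draw_major <- function() {
    eff <- rep(NA_real_, max_label)
    for (g in ags_present) {
      lab <- which(!is.na(nam$label_ag) & nam$label_ag == g)
      mu_g <- stats::rnorm(1, 0, sigma_ag)
      eff[lab] <- stats::rnorm(length(lab), mu_g, sigma_within)
    }
    eff
  }
  major_eff <- lapply(seq_along(major_idx), function(i) draw_major())

  # polygenic loci: chromosome chosen proportionally to length, position
  # uniform, snapped to the nearest marker; unit-scale effects first
  cl <- chrom_lengths(map)
  poly_chr <- names(cl)[sample.int(length(cl), qtls$n_polygenic,
                                   replace = TRUE, prob = cl / sum(cl))]
  poly_pos <- stats::runif(qtls$n_polygenic, 0, cl[poly_chr])
  poly_idx <- vapply(seq_len(qtls$n_polygenic), function(i)
    .snap_to_marker(map, poly_chr[i], poly_pos[i]), integer(1))
  poly_eff <- lapply(seq_len(qtls$n_polygenic), function(i) {
    eff <- rep(NA_real_, max_label)
    present <- which(!is.na(nam$label_ag))
    eff[present] <- stats::rnorm(length(present))
    eff
  })

  g_major <- .genetic_value(nam, major_idx, major_eff)
  g_poly1 <- .genetic_value(nam, poly_idx, poly_eff)
  v_major <- stats::var(g_major)
  v_poly1 <- stats::var(g_poly1)
  sigma_poly <- if (v_major > 0 && v_poly1 > 0 && polygenic_fraction > 0)
    sqrt(polygenic_fraction / (1 - polygenic_fraction) * v_major / v_poly1)
  else 0
  poly_eff <- lapply(poly_eff, function(e) e * sigma_poly)

  v_g <- stats::var(g_major + sigma_poly * g_poly1)
  sigma_e <- if (v_g > 0 && h2 > 0 && h2 < 1) sqrt(v_g * (1 - h2) / h2) else
    if (h2 == 0) 1 else 0

  structure(list(major_idx = major_idx, major_eff = major_eff,
                 poly_idx = poly_idx, poly_eff = poly_eff,
                 sigma_ag = sigma_ag, sigma_within = sigma_within,
                 sigma_poly = sigma_poly, sigma_e = sigma_e, h2 = h2),
            class = "effect_model")
}

# sum of allele effects carried at a set of effect loci (additive model)
.genetic_value <- function(nam, idx, eff_list) {
  ploidy <- nam$ploidy
  g <- numeric(nam$n_ind)
  for (i in seq_along(idx)) {
    lab <- matrix(nam$labels[, idx[i]], nrow = ploidy)
    g <- g + colSums(matrix(eff_list[[i]][lab], nrow = ploidy))
  }
  g
}

#' Genotypic values under an effect model
#'
#' @param nam a `nam_pop`.
#' @param effects an `effect_model`.
#' @return List with components `major`, `poly` and `total` (numeric vectors
#'   of per-individual genotypic values).
#' @export
genotypic_values <- function(nam, effects) {
  gm <- .genetic_value(nam, effects$major_idx, effects$major_eff)
  gp <- .genetic_value(nam, effects$poly_idx, effects$poly_eff)
  list(major = gm, poly = gp, total = gm + gp)
}

#' Simulate phenotypes
#'
#' `y_i` = sum of the effects of all founder alleles carried at every effect
#' locus, plus `Normal(0, sigma_e^2)` noise. Purely additive: no dominance,
#' no epistasis, no interactions between alleles at one locus.
#'
#' @param nam a `nam_pop`.
#' @param effects an `effect_model` from [assign_effects()].
#' @return Named numeric vector of phenotypes (names = individual ids).
#' @export
phenotype <- function(nam, effects) {
  g <- genotypic_values(nam, effects)$total
  if (anyNA(g)) stop("missing effect for a carried founder label")
  y <- g + stats::rnorm(nam$n_ind, 0, effects$sigma_e)
  names(y) <- nam$individual
  y
}
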