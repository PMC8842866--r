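#' Realized-relationship kinship matrix
#'
#' `K = D D' / Delta`, where `D` is a column-centered dosage matrix
#' (individuals on rows; SNP dosages, or concatenated per-allele dosage
#' columns for multiallelic systems) and `Delta` is the mean of the diagonal
#' of `D D'`. By construction the mean diagonal of `K` is exactly 1 and `K`
#' is positive semidefinite.
#'
#' @param D numeric matrix, individuals x marker (or allele) columns.
#' @param center if `TRUE` (default) columns are centered to mean zero
#'   first, as the definition requires.
#' @return `n x n` kinship matrix with attribute `delta`.
#' @export
realized_kinship <- function(D, center = TRUE) {
  D <- as.matrix(D) * 1.0
  if (center) D <- sweep(D, 2, colMeans(D))
  G <- tcrossprod(D)
  delta <- mean(diag(G))
  if (delta <= 0) stop("all-constant dosage matrix: kinship undefined")
  K <- G / delta
  attr(K, "delta") <- delta
  K
}

# one-per-cM thinning on arbitrary locus tables (same rule as the map)
.thin_idx <- function(chromosome, position) {
  idx <- integer(0)
  for (ch in unique(chromosome)) {
    rows <- which(chromosome == ch)
    pos <- position[rows]
    grid <- 0:ceiling(max(pos))
    sel <- vapply(grid, function(g) rows[which.min(abs(pos - g))], integer(1))
    idx <- c(idx, unique(sel))
  }
  sort(unique(idx))
}

#' Kinship matched to a marker system
#'
#' Builds the realized-relationship matrix from loci thinned to one per cM
#' (density-bias mitigation). For the `snp` system, `D` holds SNP dosages of
#' the thinned markers; for multiallelic systems (`ibd`, `hap`), `D`
#' concatenates the non-reference allele dosage columns of the thinned loci,
#' mirroring the incidence parametrization.
#'
#' @param x either a dosage matrix with an accompanying `map`, or an
#'   `ma_loci` object.
#' @param map required when `x` is a dosage matrix.
#' @return Kinship matrix (see [realized_kinship()]).
#' @export
kinship_for <- function(x, map = NULL) {
  if (inherits(x, "ma_loci")) {
    keep <- .thin_idx(x$info$chromosome, x$info$position_cM)
    cols <- which(x$col_locus %in% keep & !(seq_along(x$col_locus) %in% x$ref_col))
    realized_kinship(x$D[, cols, drop = FALSE])
  } else {
    stopifnot(is.matrix(x), inherits(map, "genetic_map"),
              ncol(x) == nrow(map))
    realized_kinship(x[, thin_one_per_cM(map), drop = FALSE])
  }
}
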