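#' SNP allele dosages
#'
#' Counts the `1` ("B") SNP state among each individual's homologues at every
#' marker: an integer in `0..ploidy`. This is the biallelic marker system.
#'
#' @param pop a phased population (`nam_pop` / `phased_pop`).
#' @return Integer matrix, individuals x markers; dimnames set.
#' @export
snp_dosages <- function(pop) {
  S <- snp_states(pop)
  ploidy <- pop$ploidy
  n <- nrow(S) / ploidy
  D <- matrix(0L, nrow = n, ncol = ncol(S),
              dimnames = list(pop$individual, pop$map$marker))
  for (h in seq_len(ploidy)) D <- D + S[seq(h, nrow(S), by = ploidy) +
                                          0L, , drop = FALSE]
  D
}

# count per-individual dosages of each distinct code at one locus
.count_alleles <- function(codes, ploidy) {
  u <- sort(unique(codes))
  cm <- matrix(codes, nrow = ploidy)
  D <- vapply(u, function(a) colSums(cm == a), numeric(length(codes) / ploidy))
  if (!is.matrix(D)) D <- matrix(D, ncol = length(u))
  list(alleles = u, D = D)
}

# reference allele = most frequent by total dosage, ties -> lexicographically
# smallest label
.ref_allele <- function(alleles, D) {
  tot <- colSums(D)
  cand <- which(tot == max(tot))
  cand[order(as.character(alleles[cand]))[1]]
}

# assemble a multiallelic locus set from per-locus code vectors
.build_ma <- function(codes_by_locus, info, allele_names, ploidy, n_ind) {
  nloc <- length(codes_by_locus)
  Ds <- vector("list", nloc)
  col_locus <- vector("list", nloc)
  col_allele <- vector("list", nloc)
  ref_col <- integer(nloc)
  n_alleles <- integer(nloc)
  off <- 0L
  for (i in seq_len(nloc)) {
    ca <- .count_alleles(codes_by_locus[[i]], ploidy)
    a <- length(ca$alleles)
    Ds[[i]] <- ca$D
    col_locus[[i]] <- rep(i, a)
    col_allele[[i]] <- allele_names(ca$alleles)
    ref_col[i] <- off + .ref_allele(ca$alleles, ca$D)
    n_alleles[i] <- a
    off <- off + a
  }
  info$n_alleles <- n_alleles
  structure(list(info = info, D = do.call(cbind, Ds),
                 col_locus = unlist(col_locus),
                 col_allele = unlist(col_allele),
                 ref_col = ref_col, ploidy = ploidy, n_ind = n_ind),
            class = "ma_loci")
}

#' @export
print.ma_loci <- function(x, ...) {
  cat(sprintf("multiallelic loci: %d loci, %d individuals, %.1f alleles/locus (max %d)\n",
              nrow(x$info), x$n_ind, mean(x$info$n_alleles),
              max(x$info$n_alleles)))
  invisible(x)
}

#' True-IBD multiallelic loci
#'
#' Encodes every marker as a multiallelic locus whose alleles are the
#' founder (IBD) labels observed there; dosages count label occurrences
#' among each individual's homologues and always sum to the ploidy.
#'
#' @param pop a phased population carrying founder labels.
#' @return An `ma_loci` object: per-locus allele inventories, the
#'   concatenated individuals x alleles dosage matrix `D`, column-to-locus
#'   and column-to-allele maps, and the per-locus reference allele (most
#'   frequent; ties broken by smallest label).
#' @export
ibd_loci <- function(pop) {
  L <- pop$labels
  m <- ncol(L)
  codes <- lapply(seq_len(m), function(j) L[, j])
  info <- data.frame(locus = pop$map$marker, chromosome = pop$map$chromosome,
                     position_cM = pop$map$position_cM,
                     stringsAsFactors = FALSE)
  .build_ma(codes, info, allele_names = function(a) paste0("f", a),
            ploidy = pop$ploidy, n_ind = nrow(L) / pop$ploidy)
}

#' Sliding-window haplotype blocks
#'
#' Concatenates `window` consecutive phased SNP states per homologue into a
#' haplotype string; distinct strings are the block's alleles (at most
#' `2^window`, 64 for the default window of 6). Blocks start at SNP 1,
#' 1+step, ... per chromosome with `step = window - overlap`; trailing SNPs
#' that cannot fill a window are dropped, and windows never span
#' chromosomes. The block position is the mean of the member SNP positions.
#'
#' @param pop a phased population.
#' @param window number of consecutive SNPs per block.
#' @param overlap number of SNPs shared by consecutive blocks.
#' @return An `ma_loci` object (see [ibd_loci()]).
#' @export
build_haploblocks <- function(pop, window = 6, overlap = 4) {
  if (window <= overlap) stop("window must exceed overlap")
  S <- snp_states(pop)
  map <- pop$map
  step <- window - overlap
  pow <- 2L^(seq_len(window) - 1L)
  codes <- list(); loc <- character(0); chr <- character(0); pos <- numeric(0)
  for (ch in unique(map$chromosome)) {
    cols <- which(map$chromosome == ch)
    if (length(cols) < window) next
    starts <- seq(1L, length(cols) - window + 1L, by = step)
    for (b in seq_along(starts)) {
      idx <- cols[starts[b] + seq_len(window) - 1L]
      codes[[length(codes) + 1L]] <-
        as.integer(S[, idx, drop = FALSE] %*% pow)
      loc <- c(loc, sprintf("hb%s_%d", ch, b))
      chr <- c(chr, ch)
      pos <- c(pos, mean(map$position_cM[idx]))
    }
  }
  if (length(codes) == 0) stop("no chromosome holds a full window of SNPs")
  info <- data.frame(locus = loc, chromosome = chr, position_cM = pos,
                     stringsAsFactors = FALSE)
  hapname <- function(a) vapply(a, function(code)
    paste(c("A", "B")[bitwAnd(code, pow) > 0L], collapse = ""), character(1))
  .build_ma(codes, info, allele_names = hapname, ploidy = pop$ploidy,
            n_ind = nrow(S) / pop$ploidy)
}

#' Extract one multiallelic locus
#'
#' @param ma an `ma_loci` object.
#' @param i locus index.
#' @return List: `locus`, `chromosome`, `position_cM`, `alleles`, `dosage`
#'   (individuals x alleles), `ref` (reference allele name).
#' @export
ma_locus <- function(ma, i) {
  cols <- which(ma$col_locus == i)
  list(locus = ma$info$locus[i], chromosome = ma$info$chromosome[i],
       position_cM = ma$info$position_cM[i],
       alleles = ma$col_allele[cols],
       dosage = ma$D[, cols, drop = FALSE],
       ref = ma$col_allele[ma$ref_col[i]])
}

#' Biallelic incidence matrix
#'
#' Fixed-effect design for one SNP: an intercept column of ones plus the
#' dosage of one SNP allele (additive model; no dominance or epistasis).
#'
#' @param dosages integer dosage vector (0..ploidy), one per individual.
#' @return Numeric matrix `[1, dosage]` with attribute `rank_deficient` set
#'   when the marker is monomorphic.
#' @export
incidence_biallelic <- function(dosages) {
  X <- cbind(intercept = 1, dosage = as.numeric(dosages))
  attr(X, "rank_deficient") <- stats::var(as.numeric(dosages)) == 0
  X
}

#' Multiallelic incidence matrix
#'
#' Fixed-effect design for one multiallelic locus: an intercept plus one
#' dosage column per non-reference allele. The reference allele is the most
#' frequent one (ties broken by lexicographically smallest label); estimated
#' effects are relative to it.
#'
#' @param dosage individuals x alleles dosage matrix (columns named by
#'   allele; per-row sums equal the ploidy).
#' @param alleles allele names (defaults to `colnames(dosage)`).
#' @return Numeric matrix with attributes `reference` (dropped allele) and
#'   `untestable` (`TRUE` for a single-allele locus, which yields an
#'   intercept-only matrix).
#' @export
incidence_multiallelic <- function(dosage, alleles = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(alleles)) alleles <- paste0("a", seq_len(ncol(dosage)))
  ref <- .ref_allele(alleles, dosage)
  X <- cbind(intercept = 1, dosage[, -ref, drop = FALSE])
  colnames(X) <- c("intercept", alleles[-ref])
  attr(X, "reference") <- alleles[ref]
  attr(X, "untestable") <- ncol(dosage) == 1
  X
}
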