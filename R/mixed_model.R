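# Q+K mixed model: y = [1|Q] eta + u + e,  Var(u) = K sigma_G^2,
# Var(e) = R sigma_e^2.  Variance components by REML through the spectral
# decomposition of the null-projected kinship (one eigendecomposition, then
# a 1-D search over the variance ratio); genome scans recycle the components
# at every locus (EMMAX/P3D) and test marker effects with GLS F-tests.

# fold a diagonal weight matrix R (Var(e) = R sigma_e^2) into y, K and the
# fixed design, reducing to the identity-residual case
.apply_weights <- function(y, K, X, weights) {
  if (is.null(weights)) return(list(y = y, K = K, X = X))
  s <- 1 / sqrt(weights)
  list(y = y * s, K = K * outer(s, s), X = X * s)
}

# y-independent REML ingredients: eigendecomposition of P (K + I) P with
# P = I - X (X'X)^-1 X'.  Decomposing K + I rather than K keeps the n-p
# informative eigenpairs (eigenvalues >= 1 on the range of P) cleanly
# separated from the null space of P even when K is singular; subtracting 1
# recovers the eigenvalues of the projected kinship.
.reml_prep <- function(K, X) {
  n <- nrow(K); p <- qr(X)$rank
  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- P %*% (K + diag(n)) %*% P
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  list(xi = pmax(e$values[seq_len(n - p)] - 1, 0),
       U1 = e$vectors[, seq_len(n - p), drop = FALSE], n = n, p = p)
}

# restricted log-likelihood profile in log(delta), delta = sigma_e^2/sigma_G^2
.reml_fit <- function(prep, y, bounds = c(-10, 10), grid_n = 100, tol = 1e-8) {
  np <- prep$n - prep$p
  eta2 <- drop(crossprod(prep$U1, y))^2
  xi <- prep$xi
  # profile on scale-normalized contrasts so the optimizer's trajectory (and
  # hence the fitted ratio) is exactly invariant to rescaling y; the scale
  # factor re-enters sigma_g2 analytically
  s2 <- mean(eta2)
  if (s2 <= 0) s2 <- 1
  eta2n <- eta2 / s2
  lln <- function(logdelta) {  # scale-free profile (s2 term re-added below)
    delta <- exp(logdelta)
    rq <- sum(eta2n / (xi + delta))
    0.5 * (np * (log(np / (2 * pi)) - 1 - log(rq)) - sum(log(xi + delta)))
  }
  ll <- function(logdelta) lln(logdelta) - 0.5 * np * log(s2)
  grid <- seq(bounds[1], bounds[2], length.out = grid_n)
  gv <- vapply(grid, lln, numeric(1))
  i <- which.max(gv)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, grid_n)]
  opt <- stats::optimize(lln, interval = c(lo, hi), maximum = TRUE, tol = tol)
  if (opt$objective < gv[i]) opt <- list(maximum = grid[i], objective = gv[i])
  opt$objective <- opt$objective - 0.5 * np * log(s2)
  delta <- exp(opt$maximum)
  sigma_g2 <- s2 * sum(eta2n / (xi + delta)) / np
  structure(list(sigma_g2 = sigma_g2, sigma_e2 = delta * sigma_g2,
                 delta = delta, log_delta = opt$maximum,
                 loglik = opt$objective, loglik_fun = ll,
                 n = prep$n, p = prep$p),
            class = "var_comp")
}

#' REML variance components of the no-marker null model
#'
#' Maximizes the restricted likelihood of `y = [1|Q] eta + u + e` with
#' `Var(u) = K sigma_G^2`, `Var(e) = R sigma_e^2`, using one spectral
#' decomposition and a 1-D search over `log(sigma_e^2 / sigma_G^2)`
#' (100-point coarse grid on `[-10, 10]`, then refinement to tolerance
#' `1e-8`).
#'
#' @param y numeric phenotype vector.
#' @param K kinship matrix (positive semidefinite).
#' @param Q optional matrix of fixed structure covariates (no intercept;
#'   one is added).
#' @param weights optional diagonal of `R` (reciprocal observation counts);
#'   `NULL` means one observation per genotype (`R = I`).
#' @param bounds,grid_n,tol search parameters for the variance-ratio
#'   profile.
#' @return A `var_comp` object: `sigma_g2`, `sigma_e2`, `delta`
#'   (= `sigma_e2/sigma_g2`), the restricted log-likelihood at the optimum,
#'   and `loglik_fun` (the profile as a function of `log(delta)`, useful for
#'   diagnostics).
#' @export
reml_null <- function(y, K, Q = NULL, weights = NULL,
                      bounds = c(-10, 10), grid_n = 100, tol = 1e-8) {
  X <- cbind(rep(1, length(y)), Q)
  stopifnot(length(y) >= ncol(X) + 2, nrow(K) == length(y))
  tw <- .apply_weights(y, K, X, weights)
  .reml_fit(.reml_prep(tw$K, tw$X), tw$y, bounds, grid_n, tol)
}

#' @export
print.var_comp <- function(x, ...) {
  cat(sprintf("REML variance components: sigma_G2 = %.4g, sigma_e2 = %.4g (logLik %.3f)\n",
              x$sigma_g2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' Assemble a scan design
#'
#' Packs a marker system into the uniform structure used by [scan_qtl()]:
#' the full matrix of testable fixed-effect columns and, per locus, the
#' column indices tested jointly. For `snp` each locus contributes its
#' single dosage column; for multiallelic systems each locus contributes
#' one dosage column per non-reference allele.
#'
#' @param x dosage matrix (individuals x markers) or an `ma_loci` object.
#' @param map required for a dosage matrix.
#' @param model tag stored in scan results; defaults to `"snp"` for dosage
#'   input and `"ibd"` for `ma_loci`.
#' @return A `scan_design` list: `X`, `blocks`, `info`, `model`.
#' @export
scan_design <- function(x, map = NULL, model = NULL) {
  if (inherits(x, "ma_loci")) {
    keep <- !(seq_along(x$col_locus) %in% x$ref_col)
    newcol <- cumsum(keep)
    blocks <- lapply(seq_len(nrow(x$info)), function(i)
      newcol[x$col_locus == i & keep])
    structure(list(X = x$D[, keep, drop = FALSE],
                   blocks = blocks, info = x$info,
                   model = if (is.null(model)) "ibd" else model),
              class = "scan_design")
  } else {
    stopifnot(is.matrix(x), inherits(map, "genetic_map"),
              ncol(x) == nrow(map))
    info <- data.frame(locus = map$marker, chromosome = map$chromosome,
                       position_cM = map$position_cM,
                       stringsAsFactors = FALSE)
    structure(list(X = x * 1.0, blocks = as.list(seq_len(ncol(x))),
                   info = info, model = if (is.null(model)) "snp" else model),
              class = "scan_design")
  }
}

# rotation of everything that does not change with y or the variance ratio
.scan_prep <- function(design, K, Q = NULL, weights = NULL) {
  n <- nrow(K)
  X0 <- cbind(rep(1, n), Q)
  tw <- .apply_weights(rep(0, n), K, X0, weights)
  eK <- eigen(tw$K, symmetric = TRUE)
  lam <- pmax(eK$values, 0)
  V <- eK$vectors
  list(lam = lam, V = V, X0r = crossprod(V, tw$X),
       Xr = crossprod(V, if (is.null(weights)) design$X else design$X / sqrt(weights)),
       n = n, design = design, weights = weights)
}

# GLS F-tests for every locus given rotated data and variance components
.scan_core <- function(prep, y_rot, vc, tol = 1e-10) {
  w <- pmax(vc$sigma_g2 * prep$lam + vc$sigma_e2, 1e-12)
  sw <- 1 / sqrt(w)
  yw <- y_rot * sw
  X0w <- prep$X0r * sw
  Xw <- prep$Xr * sw
  f0 <- stats::.lm.fit(X0w, yw, tol = tol)
  rss0 <- sum(f0$residuals^2)
  rank0 <- f0$rank
  n <- prep$n
  blocks <- prep$design$blocks
  nloc <- length(blocks)
  Fv <- rep(NA_real_, nloc); df1 <- integer(nloc); nlp <- numeric(nloc)
  for (i in seq_len(nloc)) {
    cols <- blocks[[i]]
    if (length(cols) == 0) { df1[i] <- 0L; nlp[i] <- 0; next }
    fit <- stats::.lm.fit(cbind(X0w, Xw[, cols, drop = FALSE]), yw, tol = tol)
    d1 <- fit$rank - rank0
    if (d1 < 1) { df1[i] <- 0L; nlp[i] <- 0; next }
    rss1 <- sum(fit$residuals^2)
    d2 <- n - fit$rank
    Fi <- max((rss0 - rss1) / d1 / (rss1 / d2), 0)
    Fv[i] <- Fi; df1[i] <- d1
    nlp[i] <- -stats::pf(Fi, d1, d2, lower.tail = FALSE, log.p = TRUE) / log(10)
  }
  list(F = Fv, df1 = df1, neglog10p = nlp)
}

#' EMMAX/P3D genome scan
#'
#' Tests every locus of a [scan_design()] with a generalized least-squares
#' F-test under `V = K sigma_G^2 + R sigma_e^2`, recycling variance
#' components estimated once on the no-marker null model (the EMMAX/P3D
#' approximation). The joint null is that all marker-effect coefficients of
#' the locus are zero; numerator df is the post-projection rank of the
#' tested columns (rank-deficient columns are dropped with df reduced),
#' denominator df is `n - rank(full design)`. A locus with no testable
#' columns (monomorphic) gets `p = 1` and is flagged.
#'
#' @param design a [scan_design()].
#' @param y phenotype vector.
#' @param K kinship matrix matched to the marker system (see
#'   [kinship_for()]).
#' @param vc optional `var_comp`; estimated via [reml_null()] when `NULL`.
#' @param Q optional structure covariates.
#' @param weights optional diagonal of `R`.
#' @return A `qtl_scan` data.frame: `locus`, `chromosome`, `position_cM`,
#'   `F`, `df1`, `neglog10p`, `model`, `untestable`; the variance components
#'   are attached as attribute `vc`.
#' @export
scan_qtl <- function(design, y, K, vc = NULL, Q = NULL, weights = NULL) {
  stopifnot(inherits(design, "scan_design"), length(y) == nrow(K))
  if (is.null(vc)) vc <- reml_null(y, K, Q, weights)
  prep <- .scan_prep(design, K, Q, weights)
  yt <- if (is.null(weights)) y else y / sqrt(weights)
  res <- .scan_core(prep, drop(crossprod(prep$V, yt)), vc)
  out <- data.frame(design$info,
                    F = res$F, df1 = res$df1, neglog10p = res$neglog10p,
                    model = design$model,
                    untestable = res$df1 == 0L,
                    stringsAsFactors = FALSE)
  attr(out, "vc") <- vc
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Permutation significance threshold
#'
#' Churchill-Doerge phenotype permutation: `y` is permuted across
#' individuals (`K` fixed), variance components are re-estimated per
#' permutation under the permuted null (P3D within each scan), and the
#' genome-wide maximum `-log10 p` is recorded. The empirical `1 - alpha`
#' quantile of the maxima is the threshold.
#'
#' @inheritParams scan_qtl
#' @param n_perm number of permutations (at least 20).
#' @param alpha genome-wide type-I error rate.
#' @return List: `threshold` (on the `-log10 p` scale), `maxima`, `alpha`,
#'   `n_perm`.
#' @export
permutation_threshold <- function(design, y, K, Q = NULL, weights = NULL,
                                  n_perm = 100, alpha = 0.05) {
  stopifnot(n_perm >= 20)
  prep <- .scan_prep(design, K, Q, weights)
  X0 <- cbind(rep(1, length(y)), Q)
  tw <- .apply_weights(y, K, X0, weights)
  rprep <- .reml_prep(tw$K, tw$X)
  s <- if (is.null(weights)) NULL else 1 / sqrt(weights)
  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(length(y))
    yp <- if (is.null(s)) y[perm] else y[perm] * s
    vc <- .reml_fit(rprep, yp)
    res <- .scan_core(prep, drop(crossprod(prep$V, yp)), vc)
    maxima[b] <- max(res$neglog10p)
  }
  list(threshold = stats::quantile(maxima, 1 - alpha, names = FALSE),
       maxima = maxima, alpha = alpha, n_perm = n_perm)
}
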