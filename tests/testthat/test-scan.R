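test_that("with zero genetic variance the GLS scan equals the OLS F-test", {
  set.seed(60)
  n <- 80
  gm <- tiny_map(40, c(20, 20))
  D <- matrix(sample(0:4, n * 40, TRUE), n)
  y <- rnorm(n)
  K <- realized_kinship(matrix(rnorm(n * 60), n))
  vc0 <- structure(list(sigma_g2 = 0, sigma_e2 = 1), class = "var_comp")
  sc <- scan_qtl(scan_design(D, gm), y, K, vc0)
  for (j in sample(40, 12)) {
    a <- anova(lm(y ~ D[, j]))
    expect_equal(sc$F[j], a$`F value`[1], tolerance = 1e-8)
    expect_equal(sc$neglog10p[j], -log10(a$`Pr(>F)`[1]), tolerance = 1e-8)
  }
})

test_that("multiallelic joint F-test matches the OLS oracle at sigma_G2 = 0", {
  fx <- shared_nam()
  set.seed(61)
  ma <- ibd_loci(fx$nam)
  des <- scan_design(ma)
  y <- rnorm(fx$nam$n_ind)
  K <- kinship_for(ma)
  vc0 <- structure(list(sigma_g2 = 0, sigma_e2 = 1), class = "var_comp")
  sc <- scan_qtl(des, y, K, vc0)
  for (i in sample(nrow(ma$info), 8)) {
    X <- des$X[, des$blocks[[i]], drop = FALSE]
    a <- anova(lm(y ~ 1), lm(y ~ X))
    expect_equal(sc$F[i], a$F[2], tolerance = 1e-8)
    expect_equal(sc$df1[i], a$Df[2])
    expect_equal(sc$neglog10p[i], -log10(a$`Pr(>F)`[2]), tolerance = 1e-8)
  }
})

test_that("p-values are invariant to rescaling the phenotype", {
  fx <- shared_nam()
  ma <- ibd_loci(fx$nam)
  des <- scan_design(ma)
  K <- kinship_for(ma)
  sc1 <- scan_qtl(des, fx$y, K)
  sc2 <- scan_qtl(des, fx$y * 1000, K)
  expect_lt(max(abs(sc1$neglog10p - sc2$neglog10p)), 1e-10)
})

test_that("monomorphic loci are flagged and given p = 1", {
  set.seed(62)
  n <- 40
  gm <- tiny_map(6, c(3, 3))
  D <- matrix(sample(0:4, n * 6, TRUE), n)
  D[, 3] <- 2  # monomorphic
  y <- rnorm(n)
  K <- realized_kinship(matrix(rnorm(n * 30), n))
  sc <- scan_qtl(scan_design(D, gm), y, K)
  expect_true(sc$untestable[3])
  expect_equal(sc$neglog10p[3], 0)
  expect_false(any(sc$untestable[-3]))
})

test_that("null p-values are approximately uniform on thinned loci", {
  fx <- shared_nam()
  set.seed(63)
  dos <- snp_dosages(fx$nam)
  keep <- thin_one_per_cM(fx$map)
  gm_thin <- genetic_map(fx$map$marker[keep], fx$map$chromosome[keep],
                         fx$map$position_cM[keep])
  des <- scan_design(dos[, keep], gm_thin)
  K <- kinship_for(dos, fx$map)
  yp <- sample(fx$y)
  sc <- scan_qtl(des, yp, K)
  p <- 10^(-sc$neglog10p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("EMMAX recycling tracks exact per-locus REML within 0.3 -log10 units", {
  set.seed(64)
  map <- synthetic_map(600, c(60, 60))
  ags <- simulate_ag_pool(4, map, 10, 30, 60)
  nam <- build_nam(ags, 2, offspring_per_cross = 30)
  qt <- qtl_spec(data.frame(chromosome = c("1", "2"),
                            position_cM = c(30, 40)), 10, map)
  eff <- assign_effects(nam, qt)
  y <- phenotype(nam, eff)
  # probe with the 1-df SNP system: single dosage covariates perturb the
  # null variance components only marginally, which is what the recycling
  # approximation assumes (a many-column multiallelic locus can absorb
  # family structure on its own, shifting the components legitimately)
  dos <- snp_dosages(nam)
  des <- scan_design(dos, map)
  K <- kinship_for(dos, map)
  sc <- scan_qtl(des, y, K)
  loci <- sample(ncol(dos), 25)
  diffs <- vapply(loci, function(i) {
    Xl <- des$X[, i, drop = FALSE]
    if (var(Xl[, 1]) == 0) return(0)
    vc_exact <- reml_null(y, K, Q = Xl)
    des1 <- des; des1$blocks <- des$blocks[i]; des1$info <- des$info[i, ]
    abs(scan_qtl(des1, y, K, vc = vc_exact)$neglog10p - sc$neglog10p[i])
  }, numeric(1))
  expect_gte(mean(diffs < 0.3), 0.9)
  expect_lt(median(diffs), 0.1)
})
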