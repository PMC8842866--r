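test_that("qtl_spec validates positions against the map", {
  gm <- tiny_map(20, c(10, 10))
  expect_error(qtl_spec(data.frame(chromosome = "1", position_cM = 50),
                        map = gm), "outside")
  expect_error(qtl_spec(data.frame(chromosome = "9", position_cM = 1),
                        map = gm), "not on the map")
  expect_s3_class(qtl_spec(data.frame(chromosome = "2", position_cM = 8),
                           map = gm), "qtl_spec")
})

test_that("degenerate effect SDs give all-zero effects", {
  fx <- shared_nam()
  set.seed(21)
  eff <- assign_effects(fx$nam, fx$qt, sigma_ag = 0, sigma_within = 0)
  expect_true(all(unlist(eff$major_eff) == 0, na.rm = TRUE))
  expect_equal(eff$sigma_poly, 0)
})

test_that("phenotype is the exact sum of carried allele effects when noise-free", {
  fx <- shared_nam()
  set.seed(22)
  eff <- assign_effects(fx$nam, fx$qt)
  eff$sigma_e <- 0
  y <- phenotype(fx$nam, eff)
  # hand-sum for a few individuals over all effect loci
  idx <- c(eff$major_idx, eff$poly_idx)
  effs <- c(eff$major_eff, eff$poly_eff)
  for (i in c(1, 25, 100)) {
    rows <- (i - 1) * 4 + 1:4
    expect_equal(unname(y[i]),
                 sum(vapply(seq_along(idx), function(k)
                   sum(effs[[k]][fx$nam$labels[rows, idx[k]]]), numeric(1))),
                 tolerance = 1e-12)
  }
})

test_that("phenotype is invariant to permuting an individual's homologues", {
  fx <- shared_nam()
  set.seed(23)
  eff <- assign_effects(fx$nam, fx$qt)
  g1 <- genotypic_values(fx$nam, eff)$total
  nam2 <- fx$nam
  for (i in seq_len(nam2$n_ind)) {
    rows <- (i - 1) * 4 + 1:4
    nam2$labels[rows, ] <- nam2$labels[rows[sample(4)], ]
  }
  g2 <- genotypic_values(nam2, eff)$total
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("same seed reproduces the same trait vector", {
  fx <- shared_nam()
  set.seed(24); eff <- assign_effects(fx$nam, fx$qt); y1 <- phenotype(fx$nam, eff)
  set.seed(24); eff2 <- assign_effects(fx$nam, fx$qt); y2 <- phenotype(fx$nam, eff2)
  expect_identical(y1, y2)
})

test_that("realized heritability and variance decomposition track their targets", {
  fx <- shared_nam()
  set.seed(25)
  h2 <- replicate(30, {
    eff <- assign_effects(fx$nam, fx$qt, h2 = 0.6)
    y <- phenotype(fx$nam, eff)
    var(genotypic_values(fx$nam, eff)$total) / var(y)
  })
  expect_lt(abs(mean(h2) - 0.6), 0.05)
  # empirical Var(y) ~ Var(g) + sigma_e^2
  set.seed(26)
  eff <- assign_effects(fx$nam, fx$qt)
  dec <- replicate(40, {
    y <- phenotype(fx$nam, eff)
    var(y)
  })
  vg <- var(genotypic_values(fx$nam, eff)$total)
  expect_lt(abs(mean(dec) - (vg + eff$sigma_e^2)) / (vg + eff$sigma_e^2), 0.1)
})

test_that("polygenic loci count and variance share are honoured", {
  fx <- shared_nam()
  set.seed(27)
  eff <- assign_effects(fx$nam, fx$qt, polygenic_fraction = 0.3)
  expect_equal(length(eff$poly_idx), fx$qt$n_polygenic)
  g <- genotypic_values(fx$nam, eff)
  share <- var(g$poly) / (var(g$poly) + var(g$major))
  # exact at the calibration draw up to major/poly covariance
  expect_lt(abs(share - 0.3), 0.1)
})
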