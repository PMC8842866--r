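test_that("SNP dosages count the B state and conserve ploidy", {
  # one individual with homologue states A,A,B,B then extremes
  st <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 1), c(1, 1, 1),  # ind 1
              matrix(0, 4, 3),                                  # ind 2: all A
              matrix(1, 4, 3))                                  # ind 3: all B
  pop <- toy_pop(st)
  D <- snp_dosages(pop)
  expect_equal(unname(D[1, ]), c(2L, 2L, 4L))
  expect_equal(unname(D[2, ]), c(0L, 0L, 0L))
  expect_equal(unname(D[3, ]), c(4L, 4L, 4L))
  expect_true(all(D + (4 - D) == 4))
})

test_that("IBD loci count founder-label dosages summing to ploidy", {
  st <- matrix(0, 8, 2)
  labels <- cbind(c(1L, 1L, 7L, 9L, 2L, 2L, 2L, 2L),
                  c(1L, 1L, 7L, 9L, 2L, 2L, 2L, 2L))
  pop <- toy_pop(st, labels = labels)
  ma <- ibd_loci(pop)
  loc <- ma_locus(ma, 1)
  expect_equal(sort(loc$alleles), c("f1", "f2", "f7", "f9"))
  expect_equal(unname(loc$dosage[1, ]), c(2, 0, 1, 1))  # f1,f2,f7,f9 order
  expect_equal(unname(loc$dosage[2, ]), c(0, 4, 0, 0))
  expect_true(all(rowSums(loc$dosage) == 4))
  expect_equal(loc$ref, "f2")  # most frequent
})

test_that("haploblocks: window arithmetic, positions, allele bound", {
  set.seed(30)
  gm <- genetic_map(paste0("m", 1:10), rep(1, 10), seq(0, 9))
  st <- matrix(rbinom(40 * 10, 1, 0.5), 40, 10)
  pop <- toy_pop(st, map = gm)
  hb <- build_haploblocks(pop, window = 6, overlap = 4)
  expect_equal(nrow(hb$info), 3)  # SNPs 1-6, 3-8, 5-10
  expect_equal(hb$info$position_cM, c(mean(0:5), mean(2:7), mean(4:9)))
  expect_true(all(hb$info$n_alleles <= 64))
  expect_error(build_haploblocks(pop, window = 4, overlap = 4), "exceed")
  # monomorphic SNPs give exactly one allele
  pop1 <- toy_pop(matrix(0, 12, 6))
  hb1 <- build_haploblocks(pop1)
  expect_equal(hb1$info$n_alleles, 1)
  # windows never span chromosomes; trailing SNPs dropped
  gm2 <- tiny_map(18, c(9, 9))  # 9 SNPs per chromosome -> 2 blocks each
  pop2 <- toy_pop(matrix(rbinom(8 * 18, 1, 0.5), 8, 18), map = gm2)
  hb2 <- build_haploblocks(pop2)
  expect_equal(as.integer(table(hb2$info$chromosome)), c(2L, 2L))
})

test_that("haploblock allele inventory is invariant to individual order", {
  fx <- shared_nam()
  nam <- fx$nam
  hb1 <- build_haploblocks(nam)
  perm <- sample(nam$n_ind)
  nam2 <- nam
  rows <- as.vector(t(outer((perm - 1) * 4, 1:4, "+")))
  nam2$labels <- nam$labels[rows, ]
  nam2$individual <- nam$individual[perm]
  hb2 <- build_haploblocks(nam2)
  for (i in c(1, 10, nrow(hb1$info)))
    expect_equal(sort(ma_locus(hb1, i)$alleles), sort(ma_locus(hb2, i)$alleles))
})

test_that("biallelic incidence is intercept plus dosage", {
  X <- incidence_biallelic(c(0, 2, 4))
  expect_equal(unname(X), cbind(c(1, 1, 1), c(0, 2, 4)), ignore_attr = TRUE)
  expect_false(attr(X, "rank_deficient"))
  expect_true(attr(incidence_biallelic(c(2, 2, 2)), "rank_deficient"))
  expect_equal(sum(X[, 1]), 3)
})

test_that("multiallelic incidence drops the most frequent allele", {
  # genotypes (a,a,b,c) and (b,b,b,c): counts a:2 b:4 c:2 -> reference b
  dos <- rbind(c(2, 1, 1), c(0, 3, 1))
  colnames(dos) <- c("a", "b", "c")
  X <- incidence_multiallelic(dos)
  expect_equal(attr(X, "reference"), "b")
  expect_equal(unname(X), rbind(c(1, 2, 1), c(1, 0, 1)), ignore_attr = TRUE)
  # allele columns sum to ploidy - dosage(reference)
  expect_equal(rowSums(X[, -1, drop = FALSE]), 4 - dos[, "b"],
               ignore_attr = TRUE)
  # tie -> lexicographically smallest label
  dos2 <- rbind(c(2, 2), c(2, 2)); colnames(dos2) <- c("z", "k")
  expect_equal(attr(incidence_multiallelic(dos2), "reference"), "k")
  # single-allele locus: intercept-only, untestable
  dos3 <- matrix(4, 2, 1); colnames(dos3) <- "only"
  X3 <- incidence_multiallelic(dos3)
  expect_equal(ncol(X3), 1)
  expect_true(attr(X3, "untestable"))
})

test_that("reconstructing the reference column restores the ploidy row-sum", {
  fx <- shared_nam()
  ma <- ibd_loci(fx$nam)
  for (i in sample(nrow(ma$info), 5)) {
    loc <- ma_locus(ma, i)
    expect_true(all(rowSums(loc$dosage) == fx$nam$ploidy))
  }
})

test_that("haploblock allele richness grows with NAM diversity", {
  fx <- shared_nam()
  set.seed(31)
  n_all <- sapply(c(1, 3), function(k) {
    nam <- build_nam(fx$ags, k, offspring_per_cross = 10)
    mean(build_haploblocks(nam)$info$n_alleles)
  })
  expect_gt(n_all[2], n_all[1])
})
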