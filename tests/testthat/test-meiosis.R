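test_that("bivalent pairing is a uniform random perfect matching", {
  expect_equal(sort(as.vector(pair_bivalents(2))), 1:2)
  expect_error(pair_bivalents(3), "even")

  canon <- function(p) paste(apply(t(apply(p, 1, sort)), 1,
                                   paste, collapse = "-")[order(
                                     apply(p, 1, min))], collapse = "|")
  set.seed(11)
  # tetraploid: 3 matchings, each within 3 SE of 1/3 over 30000 draws
  draws <- replicate(30000, canon(pair_bivalents(4)))
  tab <- table(draws)
  expect_equal(length(tab), 3)
  se <- sqrt((1 / 3) * (2 / 3) / 30000)
  expect_true(all(abs(tab / 30000 - 1 / 3) < 3 * se))
  # hexaploid: 15 matchings, uniform by chi-square
  draws6 <- replicate(30000, canon(pair_bivalents(6)))
  tab6 <- table(draws6)
  expect_equal(length(tab6), 15)
  expect_gt(chisq.test(tab6)$p.value, 1e-3)
})

test_that("chromatid walk: zero distance copies a parental homologue", {
  parent <- rbind(rep(1L, 5), rep(2L, 5), rep(3L, 5), rep(4L, 5))
  set.seed(2)
  for (i in 1:20) {
    ch <- recombinant_chromatid(parent, c(1, 2), rep(0, 5))
    expect_true(all(ch == 1L) || all(ch == 2L))
  }
})

test_that("chromatid switch frequency matches the Haldane oracle at 50 cM", {
  parent <- rbind(c(1L, 1L), c(2L, 2L))
  set.seed(3)
  sw <- replicate(20000, {
    ch <- recombinant_chromatid(parent, c(1, 2), c(0, 50))
    ch[1] != ch[2]
  })
  r <- haldane_r(50)
  se <- sqrt(r * (1 - r) / 20000)
  expect_lt(abs(mean(sw) - r), 3 * se)
  # marginal allele at one locus is a fair coin between the pair
  first <- replicate(5000, recombinant_chromatid(parent, c(1, 2), c(0, 50))[1])
  expect_lt(abs(mean(first == 1L) - 0.5), 3 * sqrt(0.25 / 5000))
})

test_that("gametes: size, transmission neutrality and conservation", {
  gm <- tiny_map(20, c(10, 10))
  parent <- matrix(rep(1:4, 20), nrow = 4)
  set.seed(4)
  g <- make_gamete(parent, gm)
  expect_equal(dim(g), c(2, 20))
  # each of the 4 homologues transmitted with marginal frequency 1/4
  lab1 <- replicate(8000, make_gamete(parent, gm)[1, 1])
  frq <- tabulate(lab1, 4) / 8000
  expect_true(all(abs(frq - 0.25) < 3 * sqrt(0.25 * 0.75 / 8000)))
  # homozygous parent transmits its allele always
  hom <- matrix(7L, nrow = 4, ncol = 20)
  expect_true(all(make_gamete(hom, gm) == 7L))
})

test_that("cross: forced transmission, ploidy checks, label conservation", {
  gm <- tiny_map(10, c(5, 5))
  mo <- matrix(1L, 4, 10); fa <- matrix(2L, 4, 10)
  off <- cross(mo, fa, gm)
  expect_equal(dim(off), c(4, 10))
  expect_true(all(colSums(off == 2L) == 2))  # dosage of B exactly 2
  expect_error(cross(mo, matrix(1L, 6, 10), gm), "ploidy mismatch")
  # cross(x, x) is mechanically valid (outbreeding enforced by callers)
  expect_silent(cross(mo, mo, gm))
  # conservation under a random pedigree
  set.seed(5)
  p1 <- matrix(sample(1:8, 40, TRUE), 4, 10)
  p2 <- matrix(sample(11:18, 40, TRUE), 4, 10)
  off <- cross(p1, p2, gm)
  for (j in 1:10)
    expect_true(all(off[, j] %in% c(p1[, j], p2[, j])))
})

test_that("observed recombination between adjacent markers converges to Haldane", {
  gm <- genetic_map(c("a", "b"), c(1, 1), c(0, 20))
  parent <- rbind(c(1L, 1L), c(2L, 2L), c(3L, 3L), c(4L, 4L))
  set.seed(6)
  # a recombinant chromatid mixes the two labels of its bivalent
  n <- 20000
  rec <- replicate(n, { g <- make_gamete(parent, gm); g[1, 1] != g[1, 2] })
  r <- haldane_r(20)
  expect_lt(abs(mean(rec) - r), 3 * sqrt(r * (1 - r) / n))
})
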