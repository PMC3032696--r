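test_that("ng_pair reproduces hand counts and basic identities", {
  r0 <- ng_pair("ATGAAACCC", "ATGAAACCC")
  expect_equal(r0$Sd, 0)
  expect_equal(r0$Nd, 0)
  expect_equal(r0$dS, 0)
  expect_equal(r0$dN, 0)

  # TTT vs TTC: third position of TTT has 1 synonymous of 3 one-step changes
  r <- ng_pair("TTT", "TTC")
  expect_equal(r$S, 1 / 3)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ps, 3)
  expect_true(is.na(r$dS))

  # symmetry and S + N = 3 * codons
  s1 <- random_cds(50, seed = 101)
  s2 <- mutate_jc(s1, 0.3, seed = 102)
  a <- ng_pair(s1, s2)
  b <- ng_pair(s2, s1)
  expect_equal(a$Sd, b$Sd)
  expect_equal(a$Nd, b$Nd)
  expect_equal(a$S, b$S)
  expect_equal(a$S + a$N, 3 * a$codons)
  expect_error(ng_pair("ATGC", "ATGC"), "divisible by 3")
})

test_that("ng_pair equals the pathway-enumeration oracle on random pairs", {
  withr::with_seed(103, {
    for (rep in 1:60) {
      c1 <- random_cds(30)
      c2 <- mutate_jc(c1, runif(1, 0, 0.8))
      # sprinkle gaps and Ns to exercise pairwise deletion
      if (rep %% 3 == 0) substr(c2, 4, 6) <- "---"
      if (rep %% 4 == 0) substr(c1, 10, 10) <- "N"
      got <- ng_pair(c1, c2)
      exp <- oracle_ng(c1, c2)
      expect_equal(got$codons, exp$codons)
      expect_equal(got$S, exp$S)
      expect_equal(got$N, exp$N)
      expect_equal(got$Sd, exp$Sd)
      expect_equal(got$Nd, exp$Nd)
    }
  })
})

test_that("JC correction is monotone and defined only below 3/4", {
  p <- seq(0, 0.74, by = 0.01)
  d <- jc_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(is.na(jc_correct(0.75)))
  expect_equal(jc_correct(0), 0)
})

test_that("ks_matrix handles identical rows, empty comparisons and recovery", {
  rows <- c(a = "ATGAAATTT", b = "ATGAAATTT", c = "ATGAAATTT")
  m <- ks_matrix(rows)
  expect_true(all(m == 0))
  expect_equal(rownames(m), c("a", "b", "c"))

  # a pair sharing no gap-free codons is undefined
  m2 <- ks_matrix(c(x = "ATG---", y = "---AAA"))
  expect_true(is.na(m2["x", "y"]))
  expect_error(ks_matrix(c(solo = "ATG")), "two taxa")

  # dS recovery: pairs diverged under JC with true d = 0.15
  est <- vapply(1:20, function(k) {
    s1 <- random_cds(1600, seed = 110 + k)
    s2 <- mutate_jc(s1, 0.15, seed = 210 + k)
    ng_pair(s1, s2)$dS
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.15), 0.015)
})

test_that("duplication-age calibration follows the calibrated Ks ratio", {
  expect_equal(round(estimate_duplication_age(0.0443, 0.1517, 19.6), 1), 5.7)
  expect_equal(estimate_duplication_age(0, 0.2, 19.6), 0)
  expect_equal(estimate_duplication_age(0.12, 0.12, 7), 7)
  # linear in each argument
  expect_equal(estimate_duplication_age(0.2, 0.1, 10),
               2 * estimate_duplication_age(0.1, 0.1, 10))
  expect_error(estimate_duplication_age(0.1, 0, 10), "interspecies")
})

test_that("nj_tree recovers additive distances exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  phy <- nj_tree(D)
  expect_equal(unname(ape::cophenetic.phylo(phy)[LETTERS[1:4],
                                                 LETTERS[1:4]]),
               unname(D), tolerance = 1e-9)
  expect_equal(ape::dist.topo(phy, ape::nj(D)), 0, ignore_attr = TRUE)

  # three taxa: closed-form branch lengths
  D3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  cp <- ape::cophenetic.phylo(t3)
  expect_equal(cp["x", "y"], 2)
  expect_equal(cp["x", "z"], 3)
  expect_equal(cp["y", "z"], 5)

  # degenerate all-zero matrix: star with zero branch lengths
  Z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tz <- nj_tree(Z)
  expect_true(all(tz$edge.length == 0))

  expect_error(nj_tree(matrix(NA_real_, 3, 3,
                              dimnames = list(1:3, 1:3))), "undefined")
})

test_that("nj_tree recovers random additive trees (topology and lengths)", {
  for (k in 1:15) {
    ra <- random_additive(sample(5:8, 1), seed = 500 + k)
    phy <- nj_tree(ra$d)
    expect_equal(ape::dist.topo(phy, ra$tree), 0, ignore_attr = TRUE)
    expect_equal(unname(ape::cophenetic.phylo(phy)[rownames(ra$d),
                                                   colnames(ra$d)]),
                 unname(ra$d), tolerance = 1e-8)
  }
})

test_that("bootstrap support is deterministic and strong for clear clades", {
  # two clades: intra ~0.01, inter ~0.3 substitutions/site, 600 codons
  anc <- random_cds(600, seed = 120)
  a0 <- mutate_jc(anc, 0.15, seed = 121)
  b0 <- mutate_jc(anc, 0.15, seed = 122)
  rows <- c(a1 = mutate_jc(a0, 0.005, seed = 123),
            a2 = mutate_jc(a0, 0.005, seed = 124),
            a3 = mutate_jc(a0, 0.005, seed = 125),
            b1 = mutate_jc(b0, 0.005, seed = 126),
            b2 = mutate_jc(b0, 0.005, seed = 127))
  bs <- bootstrap_support(rows, n_reps = 100, seed = 9)
  sep <- bs$support$support[bs$support$split %in%
                              c("a1|a2|a3", "b1|b2")]
  expect_true(length(sep) >= 1)
  expect_true(all(sep >= 95))

  bs2 <- bootstrap_support(rows, n_reps = 100, seed = 9)
  expect_identical(bs$support, bs2$support)

  one <- bootstrap_support(rows, n_reps = 1, seed = 10)
  expect_true(all(one$support$support %in% c(0, 100)))
})
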