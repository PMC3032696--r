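test_that("mutate_jc matches the JC69 expected difference fraction", {
  s <- random_dna(100000, seed = 1)
  expect_identical(mutate_jc(s, 0, seed = 2), s)
  expect_identical(mutate_jc(s, 0.1, seed = 2), mutate_jc(s, 0.1, seed = 2))
  expect_error(mutate_jc(s, -0.1), "non-negative")
  m <- mutate_jc(s, 0.1, seed = 3)
  pstar <- 0.75 * (1 - exp(-4 * 0.1 / 3))
  obs <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  tol <- 3 * sqrt(pstar * (1 - pstar) / 100000)
  expect_lt(abs(obs - pstar), tol)
})

test_that("simulate_family degenerate cases and truth invariants", {
  p0 <- family_params(duplication_rate = 0, substitution_rate = 0,
                      indel_rate = 0, ancestral_block = small_block(),
                      seed = 3)
  fam <- simulate_family(p0)
  expect_equal(nrow(fam$truth), 2L)
  expect_true(all(fam$truth$is_active))
  expect_true(all(fam$truth$birth_time == p0$total_time))
  expect_setequal(fam$truth$family, c("B-like", "A-like"))

  # no indels (and no substitutions) => no pseudogenization channel
  p1 <- family_params(duplication_rate = 0.1, substitution_rate = 0,
                      indel_rate = 0, ancestral_block = small_block(),
                      seed = 4)
  f1 <- simulate_family(p1)
  expect_true(all(f1$truth$is_active))
  expect_true(all(f1$truth$birth_time >= 0 &
                  f1$truth$birth_time <= p1$total_time))

  # determinism
  f2 <- simulate_family(p1)
  expect_identical(f1$truth, f2$truth)
  expect_identical(f1$loci, f2$loci)

  # resource cap on expected copy number
  expect_error(simulate_family(family_params(duplication_rate = 1,
                                             max_loci = 100)),
               "max_loci")
})

test_that("extant block count follows the Yule expectation", {
  lambda <- log(10) / 19.6          # expected 10 blocks, 20 loci
  counts <- vapply(1:200, function(k) {
    fam <- simulate_family(family_params(
      duplication_rate = lambda, substitution_rate = 0, indel_rate = 0,
      ancestral_block = small_block(), max_loci = 10000L, seed = k))
    nrow(fam$truth)
  }, numeric(1))
  expected <- 2 * exp(lambda * 19.6)
  # per-replicate variance of the Yule count (geometric offspring law)
  v <- 4 * (exp(lambda * 19.6)^2 - exp(lambda * 19.6))
  se <- sqrt(v / 200)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("active fraction is monotone non-increasing in indel rate", {
  frac <- vapply(c(0, 0.05, 0.2), function(ir) {
    act <- unlist(lapply(1:20, function(k) {
      fam <- simulate_family(family_params(
        duplication_rate = 0.08, substitution_rate = 0, indel_rate = ir,
        ancestral_block = small_block(), seed = k))
      fam$truth$is_active
    }))
    mean(act)
  }, numeric(1))
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
})

test_that("amplicon layout places oriented units where truth says", {
  blocks <- data.frame(id = "U", seq = random_dna(400, seed = 5))
  fwd <- layout_amplicon(blocks, amplicon_plan(c("U", "U"), c("+", "+"),
                                               100L), seed = 6)
  expect_equal(nrow(fwd$features), 2L)
  expect_true(all(fwd$features$strand == "+"))
  for (k in 1:2) {
    got <- substr(fwd$contig$seq, fwd$features$start[k] + 1L,
                  fwd$features$end[k])
    expect_identical(got, blocks$seq)
  }
  inv <- layout_amplicon(blocks, amplicon_plan(c("U", "U"), c("+", "-"),
                                               100L), seed = 6)
  got <- substr(inv$contig$seq, inv$features$start[2] + 1L,
                inv$features$end[2])
  expect_identical(revcomp(got), blocks$seq)
  expect_error(layout_amplicon(blocks,
                               amplicon_plan("X", "+", integer(0))),
               "unknown block")
})

test_that("expression levels respect the fold range and family scaling", {
  truth <- data.frame(locus_id = sprintf("L%04d", 1:2000),
                      family = rep(c("B-like", "A-like"), each = 1000),
                      expression_level = NA_real_)
  t1 <- assign_expression(truth, max_fold = 1, seed = 7)
  expect_true(all(t1$expression_level[t1$family == "B-like"] == 1))
  t2 <- assign_expression(truth, seed = 8)
  b <- t2$expression_level[t2$family == "B-like"]
  a <- t2$expression_level[t2$family == "A-like"]
  expect_lte(max(b) / min(b), 60)
  expect_lt(abs(mean(a) / mean(b) - 1 / 6), 0.05 / 6)
  expect_error(assign_expression(truth, max_fold = 0.5), "max_fold")
})

test_that("simulated read pairs have the stated structure", {
  cfg <- run_config()
  tr <- data.frame(id = c("t1", "t2"),
                   seq = c(random_dna(1000, seed = 9),
                           random_dna(1000, seed = 10)))
  truth <- data.frame(locus_id = c("t1", "t2"), family = "B-like",
                      expression_level = c(1, 3))
  z <- simulate_read_pairs(tr, truth, 0, config = cfg)
  expect_equal(nrow(z$pairs), 0L)

  # error-free reads are exact substrings in FR orientation
  r <- simulate_read_pairs(tr[1, ], truth[1, ], 200, error_rate = 0,
                           config = cfg, seed = 11)
  expect_true(all(vapply(r$pairs$seq1, grepl, TRUE, x = tr$seq[1],
                         fixed = TRUE)))
  rc1 <- revcomp(tr$seq[1])
  expect_true(all(vapply(r$pairs$seq2, grepl, TRUE, x = rc1, fixed = TRUE)))
  expect_true(all(r$sources$insert >= cfg$insert_min &
                  r$sources$insert <= cfg$insert_max))
  expect_equal(nrow(r$sources), 200L)

  # source counts follow expression levels (3:1), binomial tolerance
  big <- simulate_read_pairs(tr, truth, 40000, error_rate = 0,
                             config = cfg, seed = 12)
  n2 <- sum(big$sources$locus_id == "t2")
  p <- 3 / 4
  expect_lt(abs(n2 - 40000 * p), 3 * sqrt(40000 * p * (1 - p)))

  expect_error(simulate_read_pairs(
    data.frame(id = "short", seq = random_dna(250, seed = 1)),
    data.frame(locus_id = "short", expression_level = 1), 10,
    config = cfg), "short")
})
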