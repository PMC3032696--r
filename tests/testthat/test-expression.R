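cfg_expr <- run_config(seed = 1)

test_that("identical transcripts collapse into unique references", {
  tr <- data.frame(id = c("s2", "s1", "s3"),
                   seq = c("ACGT", "ACGT", "ACGA"))
  refs <- collapse_identical(tr)
  expect_equal(nrow(refs), 2L)
  expect_equal(refs$ref_id, c("s1", "s3"))
  expect_equal(refs$copy_number, c(2L, 1L))
  expect_equal(refs$members[1], "s1,s2")

  tr2 <- data.frame(id = c("a", "b"), seq = c("AAAA", "CCCC"))
  expect_equal(collapse_identical(tr2)$copy_number, c(1L, 1L))

  n <- 7L
  trn <- data.frame(id = sprintf("x%d", 1:n), seq = rep("ACGTACGT", n))
  cn <- collapse_identical(trn)
  expect_equal(nrow(cn), 1L)
  expect_equal(cn$copy_number, n)
  expect_error(collapse_identical(trn[0, ]), "no transcripts")
})

test_that("pair alignment verdicts follow the concordant-unique contract", {
  refs <- collapse_identical(data.frame(
    id = c("r1", "r2"),
    seq = c(random_dna(1000, seed = 51), random_dna(1000, seed = 52))))
  # exact pair 236 bp apart on r1
  p <- data.frame(id = "p1",
                  seq1 = substr(refs$seq[1], 101, 136),
                  seq2 = revcomp(substr(refs$seq[1], 301, 336)))
  v <- align_read_pairs(p, refs, cfg_expr)
  expect_equal(v$verdict, "unique")
  expect_equal(v$ref_id, "r1")
  expect_equal(c(v$mm1, v$mm2), c(0L, 0L))
  expect_equal(v$insert, 236L)

  # a mate with 3 mismatches to its best locus is unmapped
  s1 <- substr(refs$seq[1], 101, 136)
  substr(s1, 1, 1) <- flip_base(substr(s1, 1, 1))
  substr(s1, 10, 10) <- flip_base(substr(s1, 10, 10))
  substr(s1, 20, 20) <- flip_base(substr(s1, 20, 20))
  v2 <- align_read_pairs(
    data.frame(id = "p2", seq1 = s1,
               seq2 = revcomp(substr(refs$seq[1], 301, 336))),
    refs, cfg_expr)
  expect_equal(v2$verdict, "unmapped")

  # pair lying wholly in a block shared by two references is multi
  shared <- random_dna(400, seed = 53)
  refs2 <- collapse_identical(data.frame(
    id = c("u1", "u2"),
    seq = c(paste0(random_dna(300, seed = 54), shared),
            paste0(shared, random_dna(300, seed = 55)))))
  p3 <- data.frame(id = "p3",
                   seq1 = substr(shared, 21, 56),
                   seq2 = revcomp(substr(shared, 241, 276)))
  v3 <- align_read_pairs(p3, refs2, cfg_expr)
  expect_equal(v3$verdict, "multi")

  # wrong read length is rejected
  expect_error(align_read_pairs(
    data.frame(id = "p", seq1 = "ACGT", seq2 = "ACGT"), refs, cfg_expr),
    "read_length")
})

test_that("seeded alignment equals exhaustive scan and the external oracle", {
  refs <- collapse_identical(data.frame(
    id = sprintf("r%02d", 1:6),
    seq = vapply(1:6, function(k) random_dna(500, seed = 60 + k), "")))
  truth <- data.frame(locus_id = refs$ref_id, family = "B-like",
                      expression_level = 1)
  tr <- data.frame(id = refs$ref_id, seq = refs$seq)
  sim <- simulate_read_pairs(tr, truth, 120, error_rate = 0.02,
                             config = cfg_expr, seed = 66)
  # add unmappable read pairs
  junk <- data.frame(id = sprintf("j%d", 1:20),
                     seq1 = vapply(1:20, function(k)
                       random_dna(36, seed = 200 + k), ""),
                     seq2 = vapply(1:20, function(k)
                       random_dna(36, seed = 300 + k), ""),
                     qual1 = strrep("I", 36), qual2 = strrep("I", 36))
  pairs <- rbind(sim$pairs, junk)
  va <- align_read_pairs(pairs, refs, cfg_expr, method = "seed")
  vb <- align_read_pairs(pairs, refs, cfg_expr, method = "exhaustive")
  expect_identical(va, vb)
  for (k in seq_len(nrow(pairs))) {
    o <- oracle_pair_verdict(pairs$seq1[k], pairs$seq2[k], refs$seq,
                             cfg_expr)
    expect_equal(va$verdict[k], o$verdict)
    if (o$verdict == "unique") {
      expect_equal(va$ref_id[k], refs$ref_id[o$ref])
      expect_equal(va$mm1[k], o$mm1)
      expect_equal(va$mm2[k], o$mm2)
    }
  }
})

test_that("category counts respect their definitions and nesting", {
  refs <- collapse_identical(data.frame(id = "r1",
                                        seq = random_dna(800, seed = 71)))
  mk_pair <- function(id, n_mm1, n_mm2) {
    s1 <- substr(refs$seq, 101, 136)
    s2 <- revcomp(substr(refs$seq, 301, 336))
    for (p in seq_len(n_mm1)) substr(s1, p, p) <- flip_base(substr(s1, p, p))
    for (p in seq_len(n_mm2)) substr(s2, p, p) <- flip_base(substr(s2, p, p))
    data.frame(id = id, seq1 = s1, seq2 = s2)
  }
  v <- align_read_pairs(rbind(mk_pair("a", 0, 2), mk_pair("b", 0, 0),
                              mk_pair("c", 1, 2)), refs, cfg_expr)
  cc <- count_categories(v, refs)
  # (0,2) -> A,B; (0,0) -> A,B,C; (1,2) -> A only
  expect_equal(cc$countA, 3L)
  expect_equal(cc$countB, 2L)
  expect_equal(cc$countC, 1L)
  expect_true(cc$countC <= cc$countB && cc$countB <= cc$countA)
})

test_that("unique-site enumeration matches closed form and brute force", {
  cfg <- run_config(insert_min = 40L, insert_max = 50L)
  # single reference: every placement unique
  one <- collapse_identical(data.frame(id = "solo",
                                       seq = random_dna(300, seed = 81)))
  u1 <- count_unique_sites(one, cfg)
  L <- 300
  expect_equal(u1$unique_sites, sum(L - (40:50) + 1L))

  # a reference contained in another has no private sequence
  big <- random_dna(600, seed = 82)
  refs <- collapse_identical(data.frame(
    id = c("whole", "part"), seq = c(big, substr(big, 101, 400))))
  u2 <- count_unique_sites(refs, cfg)
  expect_equal(u2$unique_sites[u2$ref_id == "part"], 0L)

  # two references differing at one interior position: brute-force equality
  a <- random_dna(250, seed = 83)
  b <- a
  substr(b, 125, 125) <- flip_base(substr(b, 125, 125))
  refs3 <- collapse_identical(data.frame(id = c("a", "b"), seq = c(a, b)))
  u3 <- count_unique_sites(refs3, cfg)
  for (k in 1:2) {
    expect_equal(u3$unique_sites[k],
                 oracle_unique_sites(k, refs3$seq, cfg))
  }

  # too-short reference warns and returns zero
  short <- collapse_identical(data.frame(
    id = c("tiny", "full"),
    seq = c(random_dna(39, seed = 84), random_dna(300, seed = 85))))
  expect_warning(u4 <- count_unique_sites(short, cfg), "insert_min")
  expect_equal(u4$unique_sites[u4$ref_id == "tiny"], 0L)
})

test_that("a reference without unique sites receives no unique pairs", {
  cfg <- run_config(insert_min = 60L, insert_max = 80L)
  big <- random_dna(700, seed = 91)
  refs <- collapse_identical(data.frame(
    id = c("whole", "part"), seq = c(big, substr(big, 201, 500))))
  refs <- count_unique_sites(refs, cfg)
  expect_equal(refs$unique_sites[refs$ref_id == "part"], 0L)
  part_tr <- data.frame(id = "part",
                        seq = refs$seq[refs$ref_id == "part"])
  truth <- data.frame(locus_id = "part", family = "B-like",
                      expression_level = 1)
  sim <- simulate_read_pairs(part_tr, truth, 300, error_rate = 0.001,
                             config = cfg, seed = 92)
  v <- align_read_pairs(sim$pairs, refs, cfg)
  u <- v[v$verdict == "unique", ]
  expect_false(any(u$ref_id == "part"))
})

test_that("normalization applies the count/copy/length/unique-site formula", {
  refs <- data.frame(ref_id = "r", copy_number = 2L, length = 2000L,
                     unique_sites = 5L)
  counts <- data.frame(ref_id = "r", countA = 60L, countB = 10L,
                       countC = 0L)
  norm <- normalize_counts(counts, refs, avg_length = 2500)
  expect_equal(norm$normalized[norm$category == "A"], 7.5)
  expect_equal(norm$normalized[norm$category == "C"], 0)

  ident <- normalize_counts(data.frame(ref_id = "r", countA = 100L,
                                       countB = 0L, countC = 0L),
                            data.frame(ref_id = "r", copy_number = 1L,
                                       length = 1000L, unique_sites = 1L),
                            avg_length = 1000)
  expect_equal(ident$normalized[ident$category == "A"], 100)

  undef <- normalize_counts(counts,
                            transform(refs, unique_sites = 0L), 2500)
  expect_true(all(is.na(undef$normalized)))
  expect_error(normalize_counts(transform(counts, countA = -1L), refs, 2500),
               "negative")
})

test_that("expression summaries report fold changes and family ratios", {
  norm <- data.frame(ref_id = c("b1", "b2", "a1", "a2"),
                     category = "A", raw = c(2, 120, 1, 1),
                     normalized = c(2, 120, 6, 6))
  fmap <- data.frame(ref_id = c("b1", "b2", "a1", "a2"),
                     family = c("B-like", "B-like", "A-like", "A-like"))
  sm <- summarize_expression(norm, fmap)
  b <- sm$per_family[sm$per_family$family == "B-like", ]
  expect_equal(b$fold_change, 60)
  a <- sm$per_family[sm$per_family$family == "A-like", ]
  expect_equal(a$fold_change, 1)
  expect_equal(sm$mean_ratio$ratio_a_to_b, 6 / 61)
  expect_error(summarize_expression(transform(norm, normalized = NA_real_),
                                    fmap), "no defined")
})
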