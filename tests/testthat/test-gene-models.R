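test_that("splicing concatenates exons and checks GT-AG", {
  m <- gene_model(3, 13, 14, 20)
  locus <- paste0("AAA", "GT", "CCCCCC", "AG", "CCCTTT")
  sp <- splice_transcript(locus, m)
  expect_equal(sp$transcript, "AAACCCTTT")
  expect_true(sp$valid)

  bad <- paste0("AAA", "GC", "CCCCCC", "AG", "CCCTTT")
  sp2 <- splice_transcript(bad, gene_model(3, 13, 14, 20))
  expect_equal(sp2$transcript, "AAACCCTTT")
  expect_false(sp2$valid)

  # zero-length exon 1
  sp3 <- splice_transcript(paste0("GT", "AAAA", "AG", "ATGTTT"),
                           gene_model(0, 8, 9, 14))
  expect_equal(sp3$transcript, "ATGTTT")
  expect_true(sp3$valid)

  expect_error(splice_transcript("ACGT", gene_model(1, 10, 11, 12)),
               "out of bounds")
})

test_that("find_orfs matches a brute-force scan", {
  orfs <- find_orfs("ATGAAATAA")
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$peptide_aa, 2L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 6L)
  expect_equal(nrow(find_orfs("CCCCCC")), 0L)

  # oracle: every ATG paired with its first in-frame stop, all frames
  brute_orfs <- function(s, min_aa) {
    gc <- Biostrings::GENETIC_CODE
    res <- list()
    for (st in seq_len(nchar(s) - 2L)) {
      if (substr(s, st, st + 2L) != "ATG") next
      k <- st
      while (k + 2L <= nchar(s)) {
        cod <- substr(s, k, k + 2L)
        if (!is.na(gc[cod]) && gc[[cod]] == "*") {
          pep <- (k - st) / 3
          if (pep >= min_aa)
            res[[length(res) + 1L]] <- c(st - 1L, k - 1L, pep)
          break
        }
        k <- k + 3L
      }
    }
    if (length(res) == 0L) return(NULL)
    m <- do.call(rbind, res)
    m[order(m[, 1]), , drop = FALSE]
  }
  s <- random_dna(10000, seed = 21)
  got <- find_orfs(s, min_aa = 1)
  got <- got[order(got$start), ]
  exp <- brute_orfs(s, 1)
  expect_equal(nrow(got), nrow(exp))
  expect_equal(got$start, unname(exp[, 1]))
  expect_equal(got$end, unname(exp[, 2]))
  expect_equal(got$peptide_aa, unname(exp[, 3]))

  # prefix invariance: coordinates shift by the prefix length
  pre <- "CCCCC"
  shifted <- find_orfs(paste0(pre, s), min_aa = 1)
  shifted <- shifted[order(shifted$start), ]
  expect_equal(shifted$start, got$start + nchar(pre))
  expect_equal(shifted$peptide_aa, got$peptide_aa)
})

test_that("peptide length from a premature stop follows (stop - 1) / 3", {
  expect_equal(peptide_length_from_stop(1273), 424)
  expect_equal(peptide_length_from_stop(4), 1)
  expect_equal(peptide_length_from_stop(1), 0)
  expect_error(peptide_length_from_stop(1293), "mod 3")
  # strictly increasing
  stops <- seq(1, 301, by = 3)
  expect_true(all(diff(peptide_length_from_stop(stops)) > 0))
})

test_that("coding assessment detects indels, frameshifts and stop position", {
  ref <- random_cds(543, seed = 31)

  # identical transcript: full-length peptide, type A-like
  a0 <- assess_coding(ref, ref)
  expect_equal(nrow(a0$indels), 0L)
  expect_false(a0$frameshift)
  expect_true(is.na(a0$premature_stop_start))
  expect_equal(a0$peptide_aa, 543L)
  expect_equal(a0$structural_type, "A-like")

  # engineered 8 bp deletion at 1218 with shifted-frame stop at nt 1273
  fx <- engineer_premature_stop_cds(543, 1218, 8, 1273, seed = 32)
  expect_equal(oracle_first_stop(fx$mutated), 1273L)
  ac <- assess_coding(fx$mutated, fx$reference)
  expect_equal(ac$indels$ref_pos, 1218L)
  expect_equal(ac$indels$size, -8L)
  expect_true(ac$frameshift)
  expect_equal(ac$premature_stop_start, 1273L)
  expect_equal(ac$peptide_aa, 424L)
  expect_equal(ac$structural_type, "C-like")

  # insertion-driven frameshift is typed B-like; stop verified by oracle
  ins13 <- paste0(substr(ref, 1, 1246), "GGACCTGGACCTG",
                  substr(ref, 1247, nchar(ref)))
  ab <- assess_coding(ins13, ref)
  expect_true(ab$frameshift)
  expect_equal(ab$structural_type, "B-like")
  expect_equal(ab$indels$size, 13L)
  expect_equal(ab$premature_stop_start, oracle_first_stop(ins13))

  # in-frame 9 bp deletion: no frameshift, peptide shorter by 3
  del9 <- paste0(substr(ref, 1, 300), substr(ref, 310, nchar(ref)))
  ai <- assess_coding(del9, ref)
  expect_false(ai$frameshift)
  expect_equal(ai$peptide_aa, 540L)
  expect_equal(ai$structural_type, "other")

  expect_error(assess_coding("ACGT", "CCCCCC"), "ATG")
})

test_that("active/pseudogene classification follows the length thresholds", {
  mk <- function(pep) structure(list(peptide_aa = pep,
                                     status = NA_character_),
                                class = "coding_assessment")
  expect_equal(classify_locus(mk(543), 543)$status, "active")
  expect_equal(classify_locus(mk(0), 543)$status, "pseudogene")
  # threshold for a 543 aa reference is max(200, ceil(0.4 * 543)) = 218
  expect_equal(classify_locus(mk(222), 543)$status, "active")
  expect_equal(classify_locus(mk(217), 543)$status, "pseudogene")
  expect_error(classify_locus(mk(10), 0), "reference_aa")
})

test_that("classification agrees with simulation truth one-sidedly at
           substitution rate zero", {
  fam <- simulate_family(family_params(duplication_rate = 0.1,
                                       substitution_rate = 0,
                                       indel_rate = 0.15, seed = 41))
  tr <- family_transcripts(fam)
  ref_b <- ancestral_cds(fam$ancestral, "B")
  ref_a <- ancestral_cds(fam$ancestral, "A")
  res <- rbind(assess_transcripts(tr[startsWith(tr$id, "B"), ], ref_b),
               assess_transcripts(tr[startsWith(tr$id, "A"), ], ref_a))
  truth <- fam$truth[match(res$locus_id, fam$truth$locus_id), ]
  # every truth-active locus is classified active
  expect_true(all(res$status[truth$is_active] == "active"))
  # every classified pseudogene is a truth pseudogene
  expect_true(all(!truth$is_active[res$status == "pseudogene"]))
  # confusion table is reportable
  conf <- table(truth = truth$is_active, called = res$status)
  expect_true(sum(conf) == nrow(res))
})
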