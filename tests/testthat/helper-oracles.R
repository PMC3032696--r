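# Independent oracles used to cross-check the package's implementations.

# --- Nei-Gojobori oracle: explicit pathway enumeration per codon pair ------

oracle_codon_syn_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (gc[[alt]] != "*" && gc[[alt]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (rest in oracle_perms(v[-k]))
      out[[length(out) + 1L]] <- c(v[k], rest)
  out
}

# Pathway-averaged (Sd, Nd) for one codon pair, skipping pathways through
# stop codons (falling back to all pathways when every one is blocked).
oracle_codon_diff <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  diffpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffpos) == 0L) return(c(0, 0))
  acc <- list(valid = c(0, 0, 0), all = c(0, 0, 0))
  for (ord in oracle_perms(diffpos)) {
    cur <- c1
    sd <- nd <- 0
    blocked <- FALSE
    for (k in seq_along(ord)) {
      nxt <- cur
      substr(nxt, ord[k], ord[k]) <- substr(c2, ord[k], ord[k])
      if (gc[[cur]] != "*" && gc[[nxt]] != "*" && gc[[cur]] == gc[[nxt]])
        sd <- sd + 1 else nd <- nd + 1
      if (k < length(ord) && gc[[nxt]] == "*") blocked <- TRUE
      cur <- nxt
    }
    acc$all <- acc$all + c(sd, nd, 1)
    if (!blocked) acc$valid <- acc$valid + c(sd, nd, 1)
  }
  use <- if (acc$valid[3] > 0) acc$valid else acc$all
  use[1:2] / use[3]
}

# Full NG oracle for an aligned pair: returns S, N, Sd, Nd.
oracle_ng <- function(row1, row2) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(row1) %/% 3L
  S <- N <- Sd <- Nd <- 0
  ncmp <- 0L
  for (k in seq_len(n)) {
    c1 <- substr(row1, 3 * k - 2, 3 * k)
    c2 <- substr(row2, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    ncmp <- ncmp + 1L
    S <- S + (oracle_codon_syn_sites(c1) + oracle_codon_syn_sites(c2)) / 2
    d <- oracle_codon_diff(c1, c2)
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  list(codons = ncmp, S = S, N = 3 * ncmp - S, Sd = Sd, Nd = Nd)
}

# --- paired-read alignment oracle via Biostrings pattern matching ----------

# All hits of one read on one reference strand set, <= mm mismatches.
oracle_read_hits <- function(read, refs_seq, mm) {
  hits <- list()
  for (r in seq_along(refs_seq)) {
    for (st in c("+", "-")) {
      qry <- if (st == "+") read else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read)))
      m <- Biostrings::matchPattern(qry, Biostrings::DNAString(refs_seq[r]),
                                    max.mismatch = mm, with.indels = FALSE)
      if (length(m) > 0L) {
        ed <- Biostrings::neditStartingAt(Biostrings::DNAString(qry),
                                          Biostrings::DNAString(refs_seq[r]),
                                          starting.at = Biostrings::start(m))
        hits[[length(hits) + 1L]] <- data.frame(
          ref = r, pos = Biostrings::start(m) - 1L, strand = st, mm = ed)
      }
    }
  }
  if (length(hits) == 0L)
    return(data.frame(ref = integer(0), pos = integer(0),
                      strand = character(0), mm = integer(0)))
  do.call(rbind, hits)
}

# Independent pair-level verdict under the package's stated contract:
# concordant inward placements, unique iff all minimum-total-mismatch
# placements lie on one reference.
oracle_pair_verdict <- function(seq1, seq2, refs_seq, config) {
  rl <- config$read_length
  h1 <- oracle_read_hits(seq1, refs_seq, config$max_mismatches)
  h2 <- oracle_read_hits(seq2, refs_seq, config$max_mismatches)
  if (nrow(h1) == 0L || nrow(h2) == 0L)
    return(list(verdict = "unmapped"))
  combos <- merge(h1, h2, by = "ref", suffixes = c("1", "2"))
  ok <- list()
  if (nrow(combos) > 0L) {
    for (k in seq_len(nrow(combos))) {
      x <- combos[k, ]
      if (x$strand1 == x$strand2) next
      fwd <- if (x$strand1 == "+") x$pos1 else x$pos2
      rev <- if (x$strand1 == "+") x$pos2 else x$pos1
      ins <- rev + rl - fwd
      if (fwd <= rev && ins >= config$insert_min && ins <= config$insert_max)
        ok[[length(ok) + 1L]] <- cbind(x, fwd = fwd, ins = ins)
    }
  }
  if (length(ok) == 0L) return(list(verdict = "discordant"))
  cc <- do.call(rbind, ok)
  cc$s <- cc$mm1 + cc$mm2
  cc <- cc[cc$s == min(cc$s), , drop = FALSE]
  if (length(unique(cc$ref)) > 1L) return(list(verdict = "multi"))
  cc <- cc[order(cc$fwd, cc$strand1, cc$pos1), , drop = FALSE]
  list(verdict = "unique", ref = cc$ref[1], pos1 = cc$pos1[1],
       pos2 = cc$pos2[1], mm1 = cc$mm1[1], mm2 = cc$mm2[1],
       strand1 = cc$strand1[1], insert = cc$ins[1])
}

# --- unique-site enumeration oracle ---------------------------------------

oracle_unique_sites <- function(k, refs_seq, config) {
  rl <- config$read_length
  L <- nchar(refs_seq[k])
  if (L < config$insert_min) return(0L)
  others <- paste(c(refs_seq[-k],
                    as.character(Biostrings::reverseComplement(
                      Biostrings::DNAStringSet(refs_seq[-k])))),
                  collapse = "#")
  private <- vapply(seq_len(L - rl + 1L), function(p) {
    !grepl(substr(refs_seq[k], p, p + rl - 1L), others, fixed = TRUE)
  }, logical(1))
  total <- 0L
  for (I in config$insert_min:min(config$insert_max, L)) {
    for (p in 0:(L - I)) {
      if (private[p + 1L] || private[p + I - rl + 1L]) total <- total + 1L
    }
  }
  total
}

# --- misc helpers ----------------------------------------------------------

# Random additive distance matrix from a random unrooted binary tree.
random_additive <- function(ntaxa, seed) {
  withr::with_seed(seed, {
    phy <- ape::rtree(ntaxa, rooted = FALSE,
                      br = function(n) stats::runif(n, 0.5, 3))
    phy$tip.label <- sort(phy$tip.label)
    list(tree = phy, d = ape::cophenetic.phylo(phy))
  })
}

# First stop position (1-based, first base) of a CDS by direct translation.
oracle_first_stop <- function(cds) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  for (k in seq_len(n)) {
    if (gc[[substr(cds, 3 * k - 2, 3 * k)]] == "*") return(3L * (k - 1L) + 1L)
  }
  NA_integer_
}

# Deterministically substitute a base with a different one.
flip_base <- function(b) {
  c(A = "C", C = "G", G = "T", T = "A", N = "A")[[b]]
}

# Tiny ancestral block for fast family simulations.
small_block <- function(seed = 1) {
  ancestral_block(b_aa = 40L, a_aa = 40L, exon1_len = 30L, intron_len = 30L,
                  utr5_gap = 10L, utr3_len = 20L, seed = seed)
}
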