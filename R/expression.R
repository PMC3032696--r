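# Locus-specific expression from short paired reads of near-identical loci:
# collapse byte-identical transcripts, align both mates with at most
# max_mismatches substitutions, keep unique both-end concordant pairs, count
# the A/B/C mismatch categories, and normalize by copy number, length ratio
# and unique-site count.

#' Collapse byte-identical transcripts into unique references
#'
#' @param transcripts sequence table (`id`, `seq`); sequences are uppercased
#'   before comparison.
#' @return data.frame with `ref_id` (lexicographically smallest member id),
#'   `copy_number`, `length`, `seq`, `members` (comma-separated locus ids).
#' @export
collapse_identical <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L)
    stop("no transcripts to collapse", call. = FALSE)
  seqs <- toupper(transcripts$seq)
  grp <- split(transcripts$id, seqs)
  rows <- lapply(names(grp), function(s) {
    ids <- sort(grp[[s]])
    data.frame(ref_id = ids[1], copy_number = length(ids),
               length = nchar(s), seq = s,
               members = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$ref_id), , drop = FALSE]
}

# Precomputed reference set: integer-coded forward strands plus a seed-kmer
# index (pigeonhole: a read with <= m mismatches contains an exact
# floor(rl/(m+1))-mer chunk at one of the m+1 fixed offsets).
ref_index <- function(refs, config) {
  rl <- config$read_length
  seed_len <- rl %/% (config$max_mismatches + 1L)
  ints <- lapply(refs$seq, utf8ToInt)
  tabs <- lapply(seq_len(nrow(refs)), function(r) {
    km <- kmers(refs$seq[r], seed_len)
    if (length(km) == 0L) return(NULL)
    data.table::data.table(kmer = km, ref = r,
                           pos = seq_along(km) - 1L)
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, kmer)
  list(refs = refs, ints = ints, lens = nchar(refs$seq), index = idx,
       seed_len = seed_len,
       offsets = seq(0L, by = seed_len,
                     length.out = config$max_mismatches + 1L))
}

# All hits of each query (forward orientation vs reference forward strand)
# with <= mm mismatches. queries: character vector of equal-length reads.
# Returns data.table(q, ref, pos, mm).
seed_scan <- function(queries, ri, config) {
  rl <- config$read_length
  mmax <- config$max_mismatches
  nq <- length(queries)
  empty <- data.table::data.table(q = integer(0), ref = integer(0),
                                  pos = integer(0), mm = integer(0))
  if (nq == 0L || nrow(ri$index) == 0L) return(empty)
  off <- ri$offsets
  qdt <- data.table::data.table(
    q = rep(seq_len(nq), each = length(off)),
    off = rep(off, times = nq))
  qdt[, kmer := substring(queries[q], off + 1L, off + ri$seed_len)]
  cand <- ri$index[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0L) return(empty)
  cand[, pos := pos - off]
  cand <- unique(cand[pos >= 0L & pos + rl <= ri$lens[ref],
                      c("q", "ref", "pos")])
  if (nrow(cand) == 0L) return(empty)
  qint <- matrix(unlist(lapply(queries, utf8ToInt)), ncol = rl, byrow = TRUE)
  out <- vector("list", nrow(ri$refs))
  for (r in seq_len(nrow(ri$refs))) {
    cr <- cand[ref == r]
    if (nrow(cr) == 0L) next
    refv <- ri$ints[[r]]
    M <- matrix(refv[outer(cr$pos, seq_len(rl), `+`)], ncol = rl)
    mm <- rowSums(M != qint[cr$q, , drop = FALSE])
    keep <- mm <= mmax
    if (!any(keep)) next
    out[[r]] <- data.table::data.table(q = cr$q[keep], ref = r,
                                       pos = cr$pos[keep],
                                       mm = as.integer(mm[keep]))
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L) empty else res
}

# Exhaustive full scan (every position of every reference); same output
# contract as seed_scan.
exhaustive_scan <- function(queries, ri, config) {
  rl <- config$read_length
  mmax <- config$max_mismatches
  out <- list()
  qints <- lapply(queries, utf8ToInt)
  for (r in seq_along(ri$ints)) {
    refv <- ri$ints[[r]]
    npos <- ri$lens[r] - rl + 1L
    if (npos < 1L) next
    for (j in seq_along(queries)) {
      qv <- qints[[j]]
      m <- integer(npos)
      for (k in seq_len(rl))
        m <- m + (refv[k:(k + npos - 1L)] != qv[k])
      hit <- which(m <= mmax)
      if (length(hit) > 0L)
        out[[length(out) + 1L]] <- data.table::data.table(
          q = j, ref = r, pos = hit - 1L, mm = as.integer(m[hit]))
    }
  }
  res <- data.table::rbindlist(out)
  if (nrow(res) == 0L)
    data.table::data.table(q = integer(0), ref = integer(0),
                           pos = integer(0), mm = integer(0))
  else res
}

# Hits of a set of mates over both strands: forward queries hit strand "+",
# reverse-complemented queries hit strand "-".
mate_hits <- function(seqs, ri, config, method) {
  scan <- if (method == "seed") seed_scan else exhaustive_scan
  fw <- scan(seqs, ri, config)
  rv <- scan(revcomp(seqs), ri, config)
  fw[, strand := "+"]
  rv[, strand := "-"]
  data.table::rbindlist(list(fw, rv))
}

#' Align read pairs against a collapsed reference set
#'
#' Each mate is searched over both strands of every reference allowing at
#' most `config$max_mismatches` substitutions (no indels). Concordant pair
#' placements are then enumerated: both mates on the same reference, on
#' opposite strands in inward (FR) orientation, with implied insert length
#' within `[insert_min, insert_max]`. A pair is `unique` iff all of its
#' minimum-total-mismatch concordant placements lie on one reference
#' (read pairs shared by two or more references are excluded; multiple
#' placements within one reference do not disqualify). The reported
#' placement is the best one: fewest total mismatches, ties broken by
#' smallest forward position, `+` strand of mate 1 preferred.
#'
#' @param pairs read-pair table (`id`, `seq1`, `seq2`).
#' @param refs collapsed references from [collapse_identical()].
#' @param config a [run_config()].
#' @param method `"seed"` (pigeonhole k-mer seeding) or `"exhaustive"` (full
#'   scan); results are identical by contract.
#' @return data.frame per pair: `pair_id`, `verdict` (`unique`, `multi`,
#'   `unmapped`, `discordant`), `ref_id`, `pos1`, `strand1`, `mm1`, `pos2`,
#'   `strand2`, `mm2`, `insert`.
#' @export
align_read_pairs <- function(pairs, refs, config = run_config(),
                             method = c("seed", "exhaustive")) {
  method <- match.arg(method)
  rl <- config$read_length
  if (nrow(pairs) > 0L &&
      (any(nchar(pairs$seq1) != rl) || any(nchar(pairs$seq2) != rl)))
    stop("read length differs from config read_length (", rl, ")",
         call. = FALSE)
  ri <- ref_index(refs, config)
  n <- nrow(pairs)
  res <- data.frame(pair_id = pairs$id, verdict = "unmapped",
                    ref_id = NA_character_, pos1 = NA_integer_,
                    strand1 = NA_character_, mm1 = NA_integer_,
                    pos2 = NA_integer_, strand2 = NA_character_,
                    mm2 = NA_integer_, insert = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  h1 <- mate_hits(pairs$seq1, ri, config, method)
  h2 <- mate_hits(pairs$seq2, ri, config, method)
  mapped1 <- unique(h1$q)
  mapped2 <- unique(h2$q)
  both_mapped <- intersect(mapped1, mapped2)
  if (nrow(h1) == 0L || nrow(h2) == 0L || length(both_mapped) == 0L)
    return(res)
  data.table::setnames(h1, c("pos", "mm", "strand"),
                       c("pos1", "mm1", "strand1"))
  data.table::setnames(h2, c("pos", "mm", "strand"),
                       c("pos2", "mm2", "strand2"))
  cc <- h1[h2, on = c("q", "ref"), nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cc) > 0L) {
    cc <- cc[strand1 != strand2]
    cc[, fwd := data.table::fifelse(strand1 == "+", pos1, pos2)]
    cc[, rev := data.table::fifelse(strand1 == "+", pos2, pos1)]
    cc[, ins := rev + rl - fwd]
    cc <- cc[fwd <= rev & ins >= config$insert_min &
             ins <= config$insert_max]
  }
  res$verdict[both_mapped] <- "discordant"
  if (nrow(cc) > 0L) {
    cc[, s := mm1 + mm2]
    data.table::setorder(cc, q, s, fwd, strand1, pos1)
    best_s <- cc[, list(i = .I[s == s[1L]]), by = "q"]$i
    bb <- cc[best_s]
    agg <- bb[, list(nr = data.table::uniqueN(ref)), by = "q"]
    first <- bb[!duplicated(bb$q)]
    qs <- first$q
    res$ref_id[qs] <- ri$refs$ref_id[first$ref]
    res$pos1[qs] <- first$pos1
    res$strand1[qs] <- first$strand1
    res$mm1[qs] <- first$mm1
    res$pos2[qs] <- first$pos2
    res$strand2[qs] <- first$strand2
    res$mm2[qs] <- first$mm2
    res$insert[qs] <- first$ins
    res$verdict[qs] <- ifelse(agg$nr[match(qs, agg$q)] == 1L,
                              "unique", "multi")
  }
  res
}

#' Count the A/B/C mismatch categories per reference
#'
#' For unique pairs: category A = both mates within the mismatch allowance,
#' B = at least one mate an exact match, C = both mates exact. By
#' construction `countC <= countB <= countA`.
#'
#' @param verdicts result of [align_read_pairs()].
#' @param refs collapsed references (to report zero-count references too).
#' @return data.frame `ref_id`, `countA`, `countB`, `countC`.
#' @export
count_categories <- function(verdicts, refs) {
  u <- verdicts[verdicts$verdict == "unique", , drop = FALSE]
  out <- data.frame(ref_id = refs$ref_id, countA = 0L, countB = 0L,
                    countC = 0L, stringsAsFactors = FALSE)
  if (nrow(u) > 0L) {
    for (k in seq_len(nrow(out))) {
      s <- u[u$ref_id == out$ref_id[k], , drop = FALSE]
      out$countA[k] <- nrow(s)
      out$countB[k] <- sum(s$mm1 == 0L | s$mm2 == 0L)
      out$countC[k] <- sum(s$mm1 == 0L & s$mm2 == 0L)
    }
  }
  out
}

#' Count unique read-pair placements per reference
#'
#' Enumerates every admissible placement (all start positions and insert
#' lengths within `[insert_min, insert_max]`) on each reference; a placement
#' is unique iff at least one of its two implied read-length words occurs --
#' exactly, on either strand -- in no other reference. Computed by exhaustive
#' enumeration over the reference set itself.
#'
#' @param refs collapsed references.
#' @param config a [run_config()].
#' @return the `refs` data.frame with a `unique_sites` integer column added.
#' @export
count_unique_sites <- function(refs, config = run_config()) {
  rl <- config$read_length
  nref <- nrow(refs)
  # which references contain each read-length word (on either strand)
  tabs <- lapply(seq_len(nref), function(r) {
    km <- kmers(refs$seq[r], rl)
    if (length(km) == 0L) return(NULL)
    data.table::data.table(kmer = unique(c(km, revcomp(km))), ref = r)
  })
  occ <- unique(data.table::rbindlist(tabs))
  cnt <- occ[, list(nref = .N), by = "kmer"]
  refs$unique_sites <- vapply(seq_len(nref), function(r) {
    L <- refs$length[r]
    if (L < config$insert_min) {
      warning("reference ", refs$ref_id[r], " shorter than insert_min; ",
              "unique_sites = 0")
      return(0L)
    }
    km <- kmers(refs$seq[r], rl)
    priv <- cnt$nref[match(km, cnt$kmer)] == 1L
    total <- 0L
    for (I in config$insert_min:min(config$insert_max, L)) {
      np <- L - I + 1L
      u <- priv[seq_len(np)] | priv[seq.int(I - rl + 1L, length.out = np)]
      total <- total + sum(u)
    }
    as.integer(total)
  }, integer(1))
  refs
}

#' Normalize category counts
#'
#' normalized = raw / copy_number * avg_length / length * 1 / unique_sites;
#' undefined (NA) when unique_sites is 0.
#'
#' @param counts data.frame from [count_categories()].
#' @param refs references with `unique_sites` (see [count_unique_sites()]).
#' @param avg_length average reference length for the normalizing family.
#' @return long data.frame `ref_id`, `category`, `raw`, `normalized`.
#' @export
normalize_counts <- function(counts, refs, avg_length) {
  stopifnot(avg_length > 0)
  m <- match(counts$ref_id, refs$ref_id)
  out <- list()
  for (cat in c("A", "B", "C")) {
    raw <- counts[[paste0("count", cat)]]
    if (any(raw < 0)) stop("negative raw count", call. = FALSE)
    normalized <- ifelse(refs$unique_sites[m] > 0L,
                         raw / refs$copy_number[m] *
                           avg_length / refs$length[m] /
                           refs$unique_sites[m],
                         NA_real_)
    out[[cat]] <- data.frame(ref_id = counts$ref_id, category = cat,
                             raw = raw, normalized = normalized,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Summarize normalized expression per family
#'
#' @param normalized long table from [normalize_counts()].
#' @param family_map data.frame `ref_id`, `family`.
#' @return list with `per_family` (family, category, n, fold_change, mean)
#'   and `mean_ratio` (category, A-family mean over B-family mean).
#' @export
summarize_expression <- function(normalized, family_map) {
  x <- merge(normalized, family_map, by = "ref_id")
  x <- x[!is.na(x$normalized), , drop = FALSE]
  if (nrow(x) == 0L) stop("no defined normalized values", call. = FALSE)
  per <- do.call(rbind, lapply(split(x, list(x$family, x$category),
                                     drop = TRUE), function(s) {
    pos <- s$normalized[s$normalized > 0]
    data.frame(family = s$family[1], category = s$category[1],
               n = nrow(s),
               fold_change = if (length(pos) > 0) max(pos) / min(pos)
                             else NA_real_,
               mean = mean(s$normalized), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  ratio <- do.call(rbind, lapply(split(x, x$category), function(s) {
    mb <- mean(s$normalized[s$family == "B-like"])
    ma <- mean(s$normalized[s$family == "A-like"])
    data.frame(category = s$category[1], ratio_a_to_b = ma / mb,
               stringsAsFactors = FALSE)
  }))
  rownames(ratio) <- NULL
  list(per_family = per, mean_ratio = ratio)
}

#' Full expression-quantification stage
#'
#' Collapse transcripts, align all pairs, count categories, enumerate unique
#' sites, and normalize (average length taken over unique references within
#' each family).
#'
#' @param transcripts sequence table (`id`, `seq`).
#' @param pairs read-pair table (`id`, `seq1`, `seq2`).
#' @param family_map data.frame `locus_id`, `family`.
#' @param config a [run_config()].
#' @param method alignment method (see [align_read_pairs()]).
#' @return list with `refs`, `verdicts`, `counts`, `normalized`,
#'   `ref_families`.
#' @export
quantify_expression <- function(transcripts, pairs, family_map,
                                config = run_config(),
                                method = "seed") {
  refs <- collapse_identical(transcripts)
  refs <- count_unique_sites(refs, config)
  fam <- family_map$family[match(refs$ref_id, family_map$locus_id)]
  ref_families <- data.frame(ref_id = refs$ref_id, family = fam,
                             stringsAsFactors = FALSE)
  verdicts <- align_read_pairs(pairs, refs, config, method = method)
  counts <- count_categories(verdicts, refs)
  norm <- do.call(rbind, lapply(split(seq_len(nrow(refs)), fam),
                                function(ix) {
    avg_len <- mean(refs$length[ix])
    normalize_counts(counts[ix, , drop = FALSE],
                     refs[ix, , drop = FALSE], avg_len)
  }))
  rownames(norm) <- NULL
  list(refs = refs, verdicts = verdicts, counts = counts, normalized = norm,
       ref_families = ref_families)
}
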