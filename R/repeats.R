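# Ampliconic repeat-structure analysis: exact word-match dot-plots, direct /
# inverted repeat arm detection by diagonal chaining, arm-to-arm identity,
# and suffix-prefix overlap assembly under identity/length thresholds.

#' Exact word matches between two sequences (dot-plot)
#'
#' All length-`w` exact matches, forward and reverse-complement. Coordinates
#' are 0-based word starts; a self-comparison includes the main diagonal.
#'
#' @param seq1,seq2 DNA strings (each at least `w` bp).
#' @param w word size in bp.
#' @return data.frame `i`, `j`, `strand` (`"forward"` or `"rc"`).
#' @export
dotplot_matches <- function(seq1, seq2, w = 10L) {
  if (nchar(seq1) < w || nchar(seq2) < w)
    stop("sequences must be at least w = ", w, " bp", call. = FALSE)
  k1 <- data.table::data.table(kmer = kmers(seq1, w))
  k1[, i := .I - 1L]
  fw2 <- data.table::data.table(kmer = kmers(seq2, w))
  fw2[, j := .I - 1L]
  fw <- k1[fw2, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  rc2 <- data.table::data.table(kmer = kmers(revcomp(seq2), w))
  rc2[, q := .I - 1L]
  rc <- k1[rc2, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  L2 <- nchar(seq2)
  out <- rbind(
    if (nrow(fw) > 0L) data.frame(i = fw$i, j = fw$j, strand = "forward")
    else NULL,
    if (nrow(rc) > 0L) data.frame(i = rc$i, j = L2 - rc$q - w, strand = "rc")
    else NULL)
  if (is.null(out))
    out <- data.frame(i = integer(0), j = integer(0), strand = character(0))
  out
}

# Chain sorted word starts into runs with internal gaps <= max_gap.
chain_runs <- function(i_sorted, max_gap) {
  brk <- c(0L, which(diff(i_sorted) > max_gap), length(i_sorted))
  lapply(seq_len(length(brk) - 1L), function(k)
    i_sorted[seq.int(brk[k] + 1L, brk[k + 1L])])
}

#' Detect candidate direct/inverted repeat arm pairs from a self dot-plot
#'
#' Forward matches off the main diagonal are chained along diagonals into
#' direct-repeat (DR) candidates; reverse-complement matches are chained
#' along anti-diagonals into inverted-repeat (IR) candidates. Runs with
#' internal gaps up to `max_gap` are merged; candidates with arms shorter
#' than `min_arm` or with overlapping arms are discarded.
#'
#' @param matches word matches from a self-comparison
#'   (`dotplot_matches(s, s, w)`).
#' @param w the word size the matches were computed with.
#' @param min_arm minimum arm length in bp.
#' @param max_gap maximum internal gap within a chained run, in bp.
#' @return data.frame `armA_start`, `armA_end`, `armB_start`, `armB_end`
#'   (0-based half-open), `orientation` (`"DR"`/`"IR"`), `arm_length`.
#' @export
detect_arm_pairs <- function(matches, w = 10L, min_arm = 1000L,
                             max_gap = 500L) {
  out <- list()
  emit <- function(a0, a1, b0, b1, orient) {
    if (a1 - a0 < min_arm) return()
    if (max(a0, b0) < min(a1, b1)) return()   # overlapping arms
    if (b0 < a0) { tmp <- c(a0, a1); a0 <- b0; a1 <- b1; b0 <- tmp[1]
                   b1 <- tmp[2] }
    out[[length(out) + 1L]] <<- data.frame(
      armA_start = a0, armA_end = a1, armB_start = b0, armB_end = b1,
      orientation = orient, arm_length = a1 - a0, stringsAsFactors = FALSE)
  }
  fw <- matches[matches$strand == "forward" & matches$j > matches$i, ,
                drop = FALSE]
  if (nrow(fw) > 0L) {
    for (s in split(fw, fw$j - fw$i)) {
      d <- s$j[1] - s$i[1]
      for (run in chain_runs(sort(s$i), max_gap)) {
        a0 <- run[1]; a1 <- run[length(run)] + w
        emit(a0, a1, a0 + d, a1 + d, "DR")
      }
    }
  }
  rc <- matches[matches$strand == "rc" & matches$i < matches$j, ,
                drop = FALSE]
  if (nrow(rc) > 0L) {
    for (s in split(rc, rc$i + rc$j)) {
      a <- s$i[1] + s$j[1]
      for (run in chain_runs(sort(s$i), max_gap)) {
        a0 <- run[1]; a1 <- run[length(run)] + w
        emit(a0, a1, a - (a1 - w), a - a0 + w, "IR")
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(armA_start = integer(0), armA_end = integer(0),
                      armB_start = integer(0), armB_end = integer(0),
                      orientation = character(0), arm_length = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$armA_start, res$armB_start), , drop = FALSE]
}

#' Arm-to-arm percent identity
#'
#' Global alignment (match +1, mismatch -1, gap open -5, gap extend -1);
#' identity is matches over aligned columns excluding gap columns, times
#' 100 ("without considering gaps"). For IR pairs, arm B is
#' reverse-complemented before comparison.
#'
#' @param armA_seq,armB_seq arm sequences.
#' @param orientation `"DR"` or `"IR"`.
#' @return percent identity in `[0, 100]`.
#' @export
arm_identity <- function(armA_seq, armB_seq, orientation = c("DR", "IR")) {
  orientation <- match.arg(orientation)
  if (nchar(armA_seq) == 0L || nchar(armB_seq) == 0L)
    stop("empty arm sequence", call. = FALSE)
  if (orientation == "IR") armB_seq <- revcomp(armB_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(armA_seq, armB_seq, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 1)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  100 * sum(a[both] == b[both]) / sum(both)
}

#' Detect repeat arm pairs on a contig and compute their identities
#'
#' Convenience wrapper: self dot-plot, arm chaining, then arm-to-arm
#' identity for every candidate.
#'
#' @param contig_seq contig DNA string.
#' @param w dot-plot word size.
#' @param min_arm,max_gap see [detect_arm_pairs()].
#' @return the [detect_arm_pairs()] table with an `identity` column.
#' @export
repeat_pairs <- function(contig_seq, w = 10L, min_arm = 1000L,
                         max_gap = 500L) {
  m <- dotplot_matches(contig_seq, contig_seq, w)
  arms <- detect_arm_pairs(m, w = w, min_arm = min_arm, max_gap = max_gap)
  arms$identity <- vapply(seq_len(nrow(arms)), function(k) {
    arm_identity(substr(contig_seq, arms$armA_start[k] + 1L,
                        arms$armA_end[k]),
                 substr(contig_seq, arms$armB_start[k] + 1L,
                        arms$armB_end[k]),
                 arms$orientation[k])
  }, numeric(1))
  arms
}

#' Cut a sequence into overlapping tiles
#'
#' Test/driver helper that emulates a BAC tiling path: `n_tiles` pieces with
#' exact `overlap` bp suffix-prefix overlaps, covering the input end to end.
#'
#' @param seq source DNA string.
#' @param n_tiles number of tiles.
#' @param overlap overlap length in bp.
#' @return sequence table (`id`, `seq`) of tiles in order.
#' @export
tile_sequence <- function(seq, n_tiles, overlap) {
  L <- nchar(seq)
  step <- ceiling((L - overlap) / n_tiles)
  starts <- pmin((seq_len(n_tiles) - 1L) * step + 1L, L)
  ends <- pmin(starts + step + overlap - 1L, L)
  ends[n_tiles] <- L
  data.frame(id = sprintf("tile%02d", seq_len(n_tiles)),
             seq = substring(seq, starts, ends), stringsAsFactors = FALSE)
}

# Identity of an exact-offset (gapless) overlap between a's suffix and b's
# prefix of length V.
overlap_identity <- function(a, b, V) {
  sa <- utf8ToInt(substr(a, nchar(a) - V + 1L, nchar(a)))
  sb <- utf8ToInt(substr(b, 1L, V))
  mean(sa == sb)
}

# Best suffix(a)-prefix(b) overlap candidate found through exact seed words.
best_overlap <- function(a, b, min_overlap, min_identity, seed_len = 64L) {
  la <- nchar(a); lb <- nchar(b)
  if (la < seed_len || lb < seed_len) return(NULL)
  cand <- integer(0)
  occ <- gregexpr(substr(a, la - seed_len + 1L, la), b, fixed = TRUE)[[1]]
  if (occ[1] != -1L) cand <- c(cand, occ + seed_len - 1L)
  occ <- gregexpr(substr(b, 1L, seed_len), a, fixed = TRUE)[[1]]
  if (occ[1] != -1L) cand <- c(cand, la - occ + 1L)
  cand <- unique(cand[cand >= min_overlap & cand <= min(la, lb)])
  if (length(cand) == 0L) return(NULL)
  best <- NULL
  for (V in sort(cand, decreasing = TRUE)) {
    id <- overlap_identity(a, b, V)
    if (id >= min_identity) { best <- c(V, id); break }
  }
  best
}

#' Assemble sequences by suffix-prefix overlap chaining
#'
#' Detects pairwise end overlaps in both relative orientations through exact
#' seed words, retains edges meeting the length and identity thresholds,
#' and merges unambiguous chains into contigs. Branching nodes split the
#' chain and are reported in the edge table.
#'
#' @param sequences sequence table (`id`, `seq`).
#' @param min_overlap minimum overlap length in bp.
#' @param min_identity minimum overlap identity as a fraction.
#' @param seed_len exact seed word length used to anchor overlaps.
#' @return list with `contigs` (sequence table of merged contigs), `layout`
#'   (contig member table: `contig_id`, `member`, `offset`, `orientation`),
#'   and `edges` (`seq_a`, `orient_a`, `seq_b`, `orient_b`, `overlap`,
#'   `identity`; each overlap also appears as its mirrored pair).
#' @export
assemble_overlaps <- function(sequences, min_overlap = 30000L,
                              min_identity = 0.9999, seed_len = 64L) {
  stopifnot(nrow(sequences) >= 1L)
  ids <- sequences$id
  seqs <- stats::setNames(sequences$seq, ids)
  oriented <- function(id, o) if (o == "+") seqs[[id]] else
    revcomp(seqs[[id]])
  # all ordered pairs in all four orientation combinations; the mirror of
  # an overlap (suffix of a+ vs prefix of b-) appears as its own combo of
  # the reversed pair, so no extra mirror bookkeeping is needed
  edges <- list()
  for (ai in ids) {
    for (bi in ids) {
      if (ai == bi) next
      for (oa in c("+", "-")) {
        for (ob in c("+", "-")) {
          bo <- best_overlap(oriented(ai, oa), oriented(bi, ob),
                             min_overlap, min_identity, seed_len)
          if (!is.null(bo))
            edges[[length(edges) + 1L]] <- data.frame(
              seq_a = ai, orient_a = oa, seq_b = bi, orient_b = ob,
              overlap = as.integer(bo[1]), identity = bo[2],
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(seq_a = character(0), orient_a = character(0),
               seq_b = character(0), orient_b = character(0),
               overlap = integer(0), identity = numeric(0),
               stringsAsFactors = FALSE)
  onode <- function(id, o) paste0(id, "/", o)
  adj <- list(); radj <- list()
  add_edge <- function(from, to, overlap) {
    adj[[from]] <<- rbind(adj[[from]],
                          data.frame(to = to, overlap = overlap,
                                     stringsAsFactors = FALSE))
    radj[[to]] <<- rbind(radj[[to]],
                         data.frame(from = from, overlap = overlap,
                                    stringsAsFactors = FALSE))
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      add_edge(onode(edges$seq_a[k], edges$orient_a[k]),
               onode(edges$seq_b[k], edges$orient_b[k]),
               edges$overlap[k])
    }
  }
  deg_out <- function(nd) if (is.null(adj[[nd]])) 0L else nrow(adj[[nd]])
  deg_in <- function(nd) if (is.null(radj[[nd]])) 0L else nrow(radj[[nd]])
  oriented_seq <- function(nd) {
    parts <- strsplit(nd, "/", fixed = TRUE)[[1]]
    if (parts[2] == "+") seqs[[parts[1]]] else revcomp(seqs[[parts[1]]])
  }
  base_id <- function(nd) strsplit(nd, "/", fixed = TRUE)[[1]][1]
  visited <- character(0)
  contigs <- list(); layout <- list()
  emit_chain <- function(chain, overlaps, cid) {
    s <- oriented_seq(chain[1])
    offs <- 0L
    for (k in seq_along(chain)[-1]) {
      nxt <- oriented_seq(chain[k])
      V <- overlaps[k - 1L]
      offs <- c(offs, nchar(s) - V)
      s <- paste0(s, substr(nxt, V + 1L, nchar(nxt)))
    }
    contigs[[cid]] <<- data.frame(id = cid, seq = s,
                                  stringsAsFactors = FALSE)
    layout[[cid]] <<- data.frame(
      contig_id = cid, member = vapply(chain, base_id, character(1)),
      offset = offs,
      orientation = vapply(chain, function(nd)
        strsplit(nd, "/", fixed = TRUE)[[1]][2], character(1)),
      stringsAsFactors = FALSE)
  }
  cid_n <- 0L
  for (start_id in ids) {
    if (start_id %in% visited) next
    # choose a start orientation whose node has no unambiguous predecessor
    nd <- onode(start_id, "+")
    repeat {
      preds <- radj[[nd]]
      if (is.null(preds) || nrow(preds) != 1L) break
      pnd <- preds$from[1]
      if (base_id(pnd) %in% visited || base_id(pnd) == start_id ||
          deg_out(pnd) != 1L) break
      nd <- pnd
    }
    chain <- nd
    overlaps <- integer(0)
    visited <- c(visited, base_id(nd))
    repeat {
      nxts <- adj[[chain[length(chain)]]]
      if (is.null(nxts) || nrow(nxts) != 1L) break
      nxt <- nxts$to[1]
      if (base_id(nxt) %in% visited || deg_in(nxt) != 1L) break
      chain <- c(chain, nxt)
      overlaps <- c(overlaps, nxts$overlap[1])
      visited <- c(visited, base_id(nxt))
    }
    cid_n <- cid_n + 1L
    emit_chain(chain, overlaps, sprintf("contig%02d", cid_n))
  }
  list(contigs = do.call(rbind, c(contigs, make.row.names = FALSE)),
       layout = do.call(rbind, c(layout, make.row.names = FALSE)),
       edges = edges)
}
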