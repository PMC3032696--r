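# Synthetic-data generators: a birth-and-death (pure-birth with
# pseudogenization) gene-family simulator, ampliconic contig layout,
# per-locus expression levels, and 2 x 36 bp paired-end reads.

#' Evolve a DNA sequence under the Jukes-Cantor (JC69) model
#'
#' Each site is independently substituted with branch length `distance`
#' (substitutions per site); the expected observed difference proportion is
#' `(3/4) * (1 - exp(-4 d / 3))`. Non-ACGT characters are left untouched.
#'
#' @param sequence DNA string.
#' @param distance branch length in substitutions per site (>= 0).
#' @param seed optional integer seed.
#' @return the mutated DNA string.
#' @export
mutate_jc <- function(sequence, distance, seed = NULL) {
  if (!is.finite(distance) || distance < 0)
    stop("distance must be a finite non-negative number", call. = FALSE)
  n <- nchar(sequence)
  if (n == 0L || distance == 0) return(sequence)
  local_seed(seed, {
    p_off <- 0.25 - 0.25 * exp(-4 * distance / 3)
    x <- strsplit(sequence, "", fixed = TRUE)[[1]]
    code <- match(x, c("A", "C", "G", "T"))
    hit <- runif(n) < 3 * p_off & !is.na(code)
    k <- sum(hit)
    if (k > 0L) {
      off <- sample.int(3L, k, replace = TRUE)
      x[hit] <- c("A", "C", "G", "T")[(code[hit] - 1L + off) %% 4L + 1L]
    }
    paste(x, collapse = "")
  })
}

#' Random CDS of a given peptide length
#'
#' ATG start, `n_aa - 1` random non-stop codons, TAA terminal stop; total
#' length `3 * (n_aa + 1)` bp.
#'
#' @param n_aa peptide length in amino acids (including the initial Met).
#' @param seed optional integer seed.
#' @return a DNA string.
#' @export
random_cds <- function(n_aa, seed = NULL) {
  stopifnot(n_aa >= 1)
  local_seed(seed, {
    all_cod <- names(Biostrings::GENETIC_CODE)
    ok <- all_cod[Biostrings::GENETIC_CODE != "*"]
    body <- sample(ok, n_aa - 1L, replace = TRUE)
    paste(c("ATG", body, "TAA"), collapse = "")
  })
}

#' Ancestral two-gene block
#'
#' Builds the ancestral gene pair the family simulator amplifies: each gene
#' has two exons, a GT-AG intron confined to the 5'-UTR, and the CDS in exon
#' 2 starting `utr5_gap` bp downstream of the intron's 3' end.
#'
#' @param b_aa,a_aa reference peptide lengths for the two genes (aa).
#' @param exon1_len,intron_len,utr5_gap,utr3_len structural lengths in bp.
#' @param seed optional integer seed.
#' @return list with elements `B` and `A`, each `list(seq, model)` where the
#'   model holds 0-based locus coordinates `intron_start`, `intron_end`,
#'   `cds_start`, `cds_end`.
#' @export
ancestral_block <- function(b_aa = 543L, a_aa = 538L, exon1_len = 200L,
                            intron_len = 500L, utr5_gap = 71L,
                            utr3_len = 150L, seed = NULL) {
  stopifnot(intron_len >= 4L)
  local_seed(seed, {
    build <- function(n_aa) {
      cds <- random_cds(n_aa)
      intron <- paste0("GT", random_dna(intron_len - 4L), "AG")
      locus <- paste0(random_dna(exon1_len), intron, random_dna(utr5_gap),
                      cds, random_dna(utr3_len))
      model <- list(intron_start = exon1_len,
                    intron_end = exon1_len + intron_len,
                    cds_start = exon1_len + intron_len + utr5_gap,
                    cds_end = exon1_len + intron_len + utr5_gap + nchar(cds))
      list(seq = locus, model = model)
    }
    list(B = build(b_aa), A = build(a_aa))
  })
}

#' Parameters for the gene-family simulator
#'
#' Defaults give an expected family of ~21 blocks over 19.6 My with a neutral
#' substitution rate whose implied interspecies Ks over the full calibration
#' time is ~0.157; indel sizes include the +13 and -8 events alongside
#' smaller in-frame and frameshifting sizes.
#'
#' @param duplication_rate block duplications per lineage per My.
#' @param substitution_rate substitutions per site per My (neutral clock).
#' @param indel_rate indel events per locus per My.
#' @param indel_sizes signed indel sizes sampled uniformly.
#' @param total_time simulated time span in My.
#' @param ancestral_block an [ancestral_block()] result, or `NULL` to build
#'   one from the seed.
#' @param max_loci resource cap on the total locus count.
#' @param seed integer seed.
#' @return a validated list of class `"family_params"`.
#' @export
family_params <- function(duplication_rate = 0.12,
                          substitution_rate = 0.004,
                          indel_rate = 0.08,
                          indel_sizes = c(-13L, -8L, -6L, -3L, -2L, -1L,
                                          1L, 2L, 3L, 6L, 8L, 13L),
                          total_time = 19.6,
                          ancestral_block = NULL,
                          max_loci = 1000L,
                          seed = 1L) {
  p <- list(duplication_rate = duplication_rate,
            substitution_rate = substitution_rate,
            indel_rate = indel_rate,
            indel_sizes = as.integer(indel_sizes),
            total_time = total_time,
            ancestral_block = ancestral_block,
            max_loci = as.integer(max_loci),
            seed = as.integer(seed))
  if (any(c(duplication_rate, substitution_rate, indel_rate) < 0))
    stop("rates must be >= 0", call. = FALSE)
  if (total_time <= 0) stop("total_time must be > 0", call. = FALSE)
  if (any(p$indel_sizes == 0L)) stop("indel sizes must be nonzero",
                                     call. = FALSE)
  class(p) <- "family_params"
  p
}

# Apply one indel to a locus; returns updated seq/model plus the event row.
apply_indel <- function(seq, model, size) {
  len <- nchar(seq)
  m <- model
  if (size > 0L) {
    p <- sample.int(len + 1L, 1L) - 1L         # 0-based insertion point
    ins <- random_dna(size)
    seq <- paste0(substr(seq, 1L, p), ins, substr(seq, p + 1L, len))
    in_cds <- p > m$cds_start && p < m$cds_end
    for (f in names(m)) if (m[[f]] >= p) m[[f]] <- m[[f]] + size
    fs <- in_cds && (size %% 3L != 0L)
    ev <- data.frame(position = p, size = size, in_cds = in_cds,
                     frameshifting = fs)
  } else {
    p <- sample.int(len, 1L) - 1L
    L <- min(-size, len - p)
    seq <- paste0(substr(seq, 1L, p), substr(seq, p + L + 1L, len))
    ov <- max(0L, min(p + L, m$cds_end) - max(p, m$cds_start))
    for (f in names(m)) if (m[[f]] > p) m[[f]] <- max(p, m[[f]] - L)
    fs <- ov > 0L && (ov %% 3L != 0L)
    ev <- data.frame(position = p, size = -L, in_cds = ov > 0L,
                     frameshifting = fs)
  }
  list(seq = seq, model = m, event = ev)
}

# Evolve one block lineage (both family members) for dt My.
evolve_lineage <- function(st, dt, params) {
  if (dt <= 0) return(st)
  for (fam in c("B", "A")) {
    st$seq[[fam]] <- mutate_jc(st$seq[[fam]], params$substitution_rate * dt)
    n_ind <- stats::rpois(1L, params$indel_rate * dt)
    if (n_ind > 0L) {
      for (i in seq_len(n_ind)) {
        res <- apply_indel(st$seq[[fam]], st$model[[fam]],
                           sample(params$indel_sizes, 1L))
        st$seq[[fam]] <- res$seq
        st$model[[fam]] <- res$model
        st$indels[[fam]] <- rbind(st$indels[[fam]], res$event)
      }
    }
  }
  st
}

# Splice a locus given its model and report CDS translation status.
locus_truth_status <- function(seq, model) {
  intron_len <- model$intron_end - model$intron_start
  transcript <- paste0(substr(seq, 1L, model$intron_start),
                       substr(seq, model$intron_end + 1L, nchar(seq)))
  cds_start <- model$cds_start - intron_len
  cds_end <- model$cds_end - intron_len
  cds <- substr(transcript, cds_start + 1L, cds_end)
  aa <- translate_codons(cds)
  stops <- which(aa == "*")
  premature <- length(stops) > 0L && stops[1] < length(aa)
  list(premature_stop = premature, cds = cds, transcript = transcript)
}

#' Simulate a gene family under repeated block duplication
#'
#' A pure-birth (Yule) process on two-gene blocks over `total_time` My: every
#' extant block duplicates at `duplication_rate`, and each lineage
#' independently accrues JC69 substitutions and indels. Both family members
#' (gene-B-like and gene-A-like) share duplication events. A locus is active
#' in truth iff it carries no frameshifting CDS indel and no premature stop.
#'
#' @param params a [family_params()] object.
#' @return list with `truth` (one row per locus: `locus_id`, `parent_id`,
#'   `birth_time` in Mya, `family`, `n_indels`, `frameshift`,
#'   `premature_stop`, `is_active`, `expression_level`), `loci` (sequence
#'   table), `models` (per-locus gene models), `indels` (event table), and
#'   `params`.
#' @export
simulate_family <- function(params) {
  stopifnot(inherits(params, "family_params"))
  expected <- 2 * exp(params$duplication_rate * params$total_time)
  if (expected > params$max_loci)
    stop("expected locus count ", round(expected), " exceeds max_loci (",
         params$max_loci, "); reduce duplication_rate or total_time",
         call. = FALSE)
  local_seed(params$seed, {
    anc <- params$ancestral_block
    if (is.null(anc)) anc <- ancestral_block()
    stopifnot((anc$B$model$cds_end - anc$B$model$cds_start) %% 3L == 0L,
              (anc$A$model$cds_end - anc$A$model$cds_start) %% 3L == 0L)
    lineages <- list(list(id = 1L, parent = NA_integer_,
                          birth = params$total_time,
                          seq = list(B = anc$B$seq, A = anc$A$seq),
                          model = list(B = anc$B$model, A = anc$A$model),
                          indels = list(B = NULL, A = NULL)))
    next_id <- 1L
    t <- 0
    repeat {
      rate <- length(lineages) * params$duplication_rate
      dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
      step <- min(dt, params$total_time - t)
      lineages <- lapply(lineages, evolve_lineage, dt = step, params = params)
      t <- t + step
      if (t >= params$total_time - 1e-12) break
      i <- sample.int(length(lineages), 1L)
      next_id <- next_id + 1L
      child <- lineages[[i]]
      child$parent <- child$id
      child$id <- next_id
      child$birth <- params$total_time - t
      lineages <- c(lineages, list(child))
      if (2L * length(lineages) > params$max_loci)
        stop("locus count exceeded max_loci (", params$max_loci, ")",
             call. = FALSE)
    }
    out <- assemble_family(lineages, params)
    out$ancestral <- anc
    out
  })
}

assemble_family <- function(lineages, params) {
  rows <- list(); seqs <- list(); models <- list(); events <- list()
  for (st in lineages) {
    for (fam in c("B", "A")) {
      lid <- sprintf("%s%03d", fam, st$id)
      pid <- if (is.na(st$parent)) NA_character_ else
        sprintf("%s%03d", fam, st$parent)
      ind <- st$indels[[fam]]
      fs <- !is.null(ind) && any(ind$frameshifting)
      status <- locus_truth_status(st$seq[[fam]], st$model[[fam]])
      rows[[lid]] <- data.frame(
        locus_id = lid, parent_id = pid, birth_time = st$birth,
        family = if (fam == "B") "B-like" else "A-like",
        n_indels = if (is.null(ind)) 0L else nrow(ind),
        frameshift = fs, premature_stop = status$premature_stop,
        is_active = !fs && !status$premature_stop,
        expression_level = NA_real_, stringsAsFactors = FALSE)
      seqs[[lid]] <- st$seq[[fam]]
      models[[lid]] <- st$model[[fam]]
      if (!is.null(ind) && nrow(ind) > 0L)
        events[[lid]] <- cbind(data.frame(locus_id = lid), ind)
    }
  }
  ord <- order(names(rows))
  truth <- do.call(rbind, rows[ord])
  rownames(truth) <- NULL
  list(truth = truth,
       loci = data.frame(id = names(seqs)[ord], desc = "",
                         seq = unlist(seqs[ord], use.names = FALSE),
                         stringsAsFactors = FALSE),
       models = models[ord],
       indels = if (length(events)) do.call(rbind, c(events,
                                                     make.row.names = FALSE))
                else data.frame(locus_id = character(0), position = integer(0),
                                size = integer(0), in_cds = logical(0),
                                frameshifting = logical(0)),
       params = params)
}

#' Spliced transcripts for a simulated family
#'
#' @param fam a [simulate_family()] result.
#' @return data.frame with columns `id`, `desc`, `seq` (spliced transcripts)
#'   and `cds_start` (0-based CDS offset within the transcript).
#' @export
family_transcripts <- function(fam) {
  out <- lapply(fam$loci$id, function(lid) {
    m <- fam$models[[lid]]
    s <- fam$loci$seq[fam$loci$id == lid]
    intron_len <- m$intron_end - m$intron_start
    data.frame(id = lid, desc = "",
               seq = paste0(substr(s, 1L, m$intron_start),
                            substr(s, m$intron_end + 1L, nchar(s))),
               cds_start = m$cds_start - intron_len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Amplicon layout plan
#'
#' @param block_ids ids of the repeat units, in contig order.
#' @param orientations `"+"` (forward) or `"-"` (reverse complement), one per
#'   unit.
#' @param spacer_lengths non-negative spacer lengths in bp, one per junction
#'   (length `length(block_ids) - 1`).
#' @return a list of class `"amplicon_plan"`.
#' @export
amplicon_plan <- function(block_ids, orientations, spacer_lengths) {
  n <- length(block_ids)
  stopifnot(length(orientations) == n,
            all(orientations %in% c("+", "-")),
            length(spacer_lengths) == max(0L, n - 1L),
            all(spacer_lengths >= 0))
  structure(list(block_ids = block_ids, orientations = orientations,
                 spacer_lengths = as.integer(spacer_lengths)),
            class = "amplicon_plan")
}

#' Lay out repeat units into one ampliconic contig
#'
#' Concatenates oriented copies of the given blocks with random spacers.
#' Same-orientation repeated units form direct repeats by construction;
#' opposite-orientation units form inverted repeats.
#'
#' @param blocks sequence table (`id`, `seq`) of available units.
#' @param plan an [amplicon_plan()].
#' @param seed optional integer seed (spacer sequence).
#' @return list with `contig` (a one-row sequence table) and `features`
#'   (block intervals and strands, 0-based half-open).
#' @export
layout_amplicon <- function(blocks, plan, seed = NULL) {
  stopifnot(inherits(plan, "amplicon_plan"))
  missing <- setdiff(plan$block_ids, blocks$id)
  if (length(missing) > 0)
    stop("unknown block id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  local_seed(seed, {
    parts <- character(0)
    feats <- list()
    pos <- 0L
    for (k in seq_along(plan$block_ids)) {
      s <- blocks$seq[blocks$id == plan$block_ids[k]]
      if (plan$orientations[k] == "-") s <- revcomp(s)
      parts <- c(parts, s)
      feats[[k]] <- data.frame(contig_id = "amplicon", start = pos,
                               end = pos + nchar(s),
                               strand = plan$orientations[k],
                               type = "repeat_unit",
                               name = sprintf("%s_copy%d",
                                              plan$block_ids[k], k),
                               stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
      if (k < length(plan$block_ids) && plan$spacer_lengths[k] > 0L) {
        sp <- random_dna(plan$spacer_lengths[k])
        parts <- c(parts, sp)
        pos <- pos + nchar(sp)
      }
    }
    list(contig = data.frame(id = "amplicon", desc = "",
                             seq = paste(parts, collapse = ""),
                             stringsAsFactors = FALSE),
         features = do.call(rbind, feats))
  })
}

#' Assign per-locus expression levels
#'
#' B-like loci draw log-uniform levels on `[1, max_fold]`; A-like loci draw
#' log-uniform levels that are then rescaled so the A-family mean equals
#' `family_a_scale` times the B-family mean.
#'
#' @param truth truth table from [simulate_family()].
#' @param max_fold maximum fold difference within a family (>= 1).
#' @param family_a_scale ratio of A-family mean to B-family mean (> 0).
#' @param seed optional integer seed.
#' @return the truth table with `expression_level` filled in.
#' @export
assign_expression <- function(truth, max_fold = 60, family_a_scale = 1 / 6,
                              seed = NULL) {
  if (!is.numeric(max_fold) || max_fold < 1)
    stop("max_fold must be >= 1", call. = FALSE)
  if (family_a_scale <= 0) stop("family_a_scale must be > 0", call. = FALSE)
  local_seed(seed, {
    b <- truth$family == "B-like"
    a <- truth$family == "A-like"
    truth$expression_level[b] <- exp(stats::runif(sum(b), 0, log(max_fold)))
    raw_a <- exp(stats::runif(sum(a), 0, log(max_fold)))
    if (sum(a) > 0L) {
      target <- family_a_scale * mean(truth$expression_level[b])
      truth$expression_level[a] <- raw_a * target / mean(raw_a)
    }
    truth
  })
}

#' Simulate 2 x 36 bp paired-end reads from transcripts
#'
#' Fragments are sampled from loci with probability proportional to
#' `expression_level * transcript length`; insert lengths are uniform on
#' `[insert_min, insert_max]`; mate 1 is the first `read_length` bases of the
#' fragment and mate 2 the reverse complement of its last `read_length` bases
#' (inward FR orientation). Sequencing errors are independent per-base
#' substitutions; qualities are constant.
#'
#' @param transcripts sequence table (`id`, `seq`); every sequence must be
#'   longer than `config$insert_max`.
#' @param truth truth table with `expression_level` set (matched by
#'   `locus_id`).
#' @param n_pairs number of read pairs.
#' @param error_rate per-base substitution error probability.
#' @param config a [run_config()].
#' @param seed optional integer seed (defaults to `config$seed`).
#' @return list with `pairs` (id, seq1, qual1, seq2, qual2) and `sources`
#'   (pair id, source locus, fragment start, insert length).
#' @export
simulate_read_pairs <- function(transcripts, truth, n_pairs,
                                error_rate = 0.001, config = run_config(),
                                seed = config$seed) {
  stopifnot(n_pairs >= 0)
  short <- transcripts$id[nchar(transcripts$seq) <= config$insert_max]
  if (length(short) > 0)
    stop("transcript(s) shorter than insert_max: ",
         paste(short, collapse = ", "), call. = FALSE)
  lev <- truth$expression_level[match(transcripts$id, truth$locus_id)]
  if (anyNA(lev))
    stop("missing expression levels for: ",
         paste(transcripts$id[is.na(lev)], collapse = ", "), call. = FALSE)
  rl <- config$read_length
  empty <- list(
    pairs = data.frame(id = character(0), seq1 = character(0),
                       qual1 = character(0), seq2 = character(0),
                       qual2 = character(0), stringsAsFactors = FALSE),
    sources = data.frame(pair_id = character(0), locus_id = character(0),
                         frag_start = integer(0), insert = integer(0),
                         stringsAsFactors = FALSE))
  if (n_pairs == 0L) return(empty)
  local_seed(seed, {
    len <- nchar(transcripts$seq)
    w <- lev * len
    src <- sample.int(nrow(transcripts), n_pairs, replace = TRUE,
                      prob = w / sum(w))
    insert <- config$insert_min +
      sample.int(config$insert_max - config$insert_min + 1L, n_pairs,
                 replace = TRUE) - 1L
    maxstart <- len[src] - insert
    start <- floor(stats::runif(n_pairs) * (maxstart + 1L))  # 0-based
    seq1 <- substring(transcripts$seq[src], start + 1L, start + rl)
    last <- substring(transcripts$seq[src], start + insert - rl + 1L,
                      start + insert)
    seq2 <- revcomp(last)
    seq1 <- add_seq_errors(seq1, error_rate)
    seq2 <- add_seq_errors(seq2, error_rate)
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    qual <- strrep("I", rl)
    list(pairs = data.frame(id = ids, seq1 = seq1, qual1 = qual,
                            seq2 = seq2, qual2 = qual,
                            stringsAsFactors = FALSE),
         sources = data.frame(pair_id = ids,
                              locus_id = transcripts$id[src],
                              frag_start = as.integer(start),
                              insert = insert, stringsAsFactors = FALSE))
  })
}

# Independent per-base substitution errors on a vector of equal-length reads.
add_seq_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads[1])
  n_err <- stats::rbinom(1L, length(reads) * rl, error_rate)
  if (n_err == 0L) return(reads)
  pos <- sample.int(length(reads) * rl, n_err)
  ridx <- (pos - 1L) %/% rl + 1L
  cidx <- (pos - 1L) %% rl + 1L
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_err)) {
    cur <- substr(reads[ridx[k]], cidx[k], cidx[k])
    alt <- bases[bases != cur]
    if (length(alt) == 0L) alt <- bases
    substr(reads[ridx[k]], cidx[k], cidx[k]) <- sample(alt, 1L)
  }
  reads
}
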