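# Codon-level divergence (Nei-Gojobori with Jukes-Cantor correction,
# pairwise deletion), Ks matrices, duplication dating against a calibrated
# species split, and neighbor-joining trees with bootstrap support.

.pkg_env <- new.env(parent = emptyenv())

PERMS <- list(list(1L),
              list(c(1L, 2L), c(2L, 1L)),
              list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                   c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Precomputed codon tables: per-codon synonymous site counts and per-pair
# (Sd, Nd) averaged over minimal substitution pathways. Pathways passing
# through stop codons are excluded; if every pathway is blocked, the
# unrestricted average is used. Steps to a stop codon count as
# nonsynonymous.
ng_tables <- function() {
  if (!is.null(.pkg_env$ng)) return(.pkg_env$ng)
  codons <- names(Biostrings::GENETIC_CODE)
  aa <- unname(Biostrings::GENETIC_CODE)
  bases <- c("A", "C", "G", "T")
  ncod <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  idx_of <- function(cd) match(cd, codons)
  # synonymous site count per codon: sum over positions of
  # (synonymous one-step changes at that position) / 3
  syn_sites <- numeric(ncod)
  for (i in seq_len(ncod)) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, cmat[i, p])) {
        alt <- cmat[i, ]
        alt[p] <- b
        j <- idx_of(paste(alt, collapse = ""))
        if (aa[j] != "*" && aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  # pathway-averaged synonymous/nonsynonymous differences per codon pair
  Sd <- matrix(0, ncod, ncod)
  Nd <- matrix(0, ncod, ncod)
  step_syn <- function(i, j) aa[i] != "*" && aa[j] != "*" && aa[i] == aa[j]
  for (i in seq_len(ncod)) {
    for (j in seq_len(ncod)) {
      if (i == j) next
      diffpos <- which(cmat[i, ] != cmat[j, ])
      nd <- length(diffpos)
      paths <- PERMS[[nd]]
      tot_s <- tot_n <- 0
      kept <- 0L
      all_s <- all_n <- 0
      for (ord in paths) {
        cur <- cmat[i, ]
        ps <- pn <- 0
        blocked <- FALSE
        for (st in seq_len(nd)) {
          p <- diffpos[ord[st]]
          from <- idx_of(paste(cur, collapse = ""))
          cur[p] <- cmat[j, p]
          to <- idx_of(paste(cur, collapse = ""))
          if (step_syn(from, to)) ps <- ps + 1 else pn <- pn + 1
          if (st < nd && aa[to] == "*") blocked <- TRUE
        }
        all_s <- all_s + ps; all_n <- all_n + pn
        if (!blocked) {
          tot_s <- tot_s + ps; tot_n <- tot_n + pn
          kept <- kept + 1L
        }
      }
      if (kept > 0L) {
        Sd[i, j] <- tot_s / kept
        Nd[i, j] <- tot_n / kept
      } else {
        Sd[i, j] <- all_s / length(paths)
        Nd[i, j] <- all_n / length(paths)
      }
    }
  }
  .pkg_env$ng <- list(codons = codons, aa = aa, syn_sites = syn_sites,
                      Sd = Sd, Nd = Nd)
  .pkg_env$ng
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) ln(1 - 4p/3)`, defined for `p < 3/4`; returns `NA` otherwise.
#'
#' @param p observed difference proportion.
#' @return corrected distance (or `NA` where undefined).
#' @export
jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Nei-Gojobori synonymous/nonsynonymous divergence for one aligned pair
#'
#' Codons containing a gap, `N`, or a stop codon in either row are excluded
#' (pairwise deletion). Synonymous site counts come from the standard genetic
#' code and are averaged between the two sequences; multi-substitution codon
#' differences are averaged over all minimal pathways, excluding pathways
#' through stop codons. Jukes-Cantor correction is applied where defined.
#'
#' @param seq1_row,seq2_row aligned CDS strings of equal length divisible
#'   by 3 (gaps `-`).
#' @return list of class `"ks_result"`: `codons` (compared codon count), `S`,
#'   `N`, `Sd`, `Nd`, `ps`, `pn`, `dS`, `dN` (`NA` where undefined).
#' @export
ng_pair <- function(seq1_row, seq2_row) {
  if (nchar(seq1_row) != nchar(seq2_row))
    stop("aligned rows must have equal length", call. = FALSE)
  if (nchar(seq1_row) %% 3L != 0L)
    stop("aligned length must be divisible by 3", call. = FALSE)
  ng <- ng_tables()
  c1 <- codon_split(seq1_row)
  c2 <- codon_split(seq2_row)
  i1 <- match(c1, ng$codons)
  i2 <- match(c2, ng$codons)
  ok <- !is.na(i1) & !is.na(i2)
  ok[ok] <- ng$aa[i1[ok]] != "*" & ng$aa[i2[ok]] != "*"
  i1 <- i1[ok]; i2 <- i2[ok]
  ncod <- length(i1)
  S <- sum((ng$syn_sites[i1] + ng$syn_sites[i2]) / 2)
  N <- 3 * ncod - S
  Sd <- sum(ng$Sd[cbind(i1, i2)])
  Nd <- sum(ng$Nd[cbind(i1, i2)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  structure(list(codons = ncod, S = S, N = N, Sd = Sd, Nd = Nd,
                 ps = ps, pn = pn, dS = jc_correct(ps), dN = jc_correct(pn)),
            class = "ks_result")
}

validate_alignment <- function(rows) {
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    stop("alignment rows must be named by taxon", call. = FALSE)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  if (nchar(rows[1]) %% 3L != 0L)
    stop("alignment length must be divisible by 3", call. = FALSE)
  if (any(grepl("[^ACGTN-]", rows)))
    stop("alignment alphabet must be {A,C,G,T,N,-}", call. = FALSE)
  invisible(TRUE)
}

#' Pairwise Ks (dS) matrix for a codon alignment
#'
#' @param rows named character vector of aligned CDS rows (equal lengths
#'   divisible by 3; gaps `-`).
#' @return symmetric matrix of Jukes-Cantor-corrected dS values with zero
#'   diagonal; undefined entries are `NA`.
#' @export
ks_matrix <- function(rows) {
  validate_alignment(rows)
  n <- length(rows)
  if (n < 2L) stop("at least two taxa are required", call. = FALSE)
  taxa <- names(rows)
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- ng_pair(rows[[i]], rows[[j]])
      m[i, j] <- m[j, i] <- if (r$codons == 0L) NA_real_ else r$dS
    }
  }
  m
}

#' Summary statistics of a Ks matrix
#'
#' @param m a [ks_matrix()] result.
#' @return list with `mean`, `max` (over defined off-diagonal entries), and
#'   `most_distant` (taxon whose maximum pairwise Ks to the others is
#'   largest).
#' @export
ks_summary <- function(m) {
  v <- m[upper.tri(m)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("no defined Ks values", call. = FALSE)
  rowmax <- apply(m, 1, function(x) suppressWarnings(max(x, na.rm = TRUE)))
  list(mean = mean(v), max = max(v),
       most_distant = rownames(m)[which.max(rowmax)])
}

#' Date a duplication against a calibrated species split
#'
#' age = max_intrafamily_ks / interspecies_ks_mean * t_split.
#'
#' @param max_intrafamily_ks maximum pairwise Ks among family loci.
#' @param interspecies_ks_mean mean Ks between the two calibrating species
#'   (> 0).
#' @param t_split calibration split time in Mya.
#' @return estimated duplication age in Mya.
#' @export
estimate_duplication_age <- function(max_intrafamily_ks,
                                     interspecies_ks_mean,
                                     t_split = 19.6) {
  if (!is.numeric(interspecies_ks_mean) || interspecies_ks_mean <= 0)
    stop("interspecies_ks_mean must be > 0", call. = FALSE)
  if (max_intrafamily_ks < 0) stop("Ks must be >= 0", call. = FALSE)
  max_intrafamily_ks / interspecies_ks_mean * t_split
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with deterministic tie-breaking (smallest index
#' pair); negative branch-length estimates are clamped to zero and counted
#' in the `"clamped"` attribute.
#'
#' @param m symmetric distance matrix with taxon dimnames (>= 3 taxa, all
#'   entries finite).
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(m) {
  if (is.null(rownames(m))) stop("matrix must have taxon names", call. = FALSE)
  n <- nrow(m)
  if (n < 3L) stop("at least 3 taxa are required", call. = FALSE)
  if (any(is.na(m)) || any(!is.finite(m)))
    stop("distance matrix has undefined entries; exclude those taxa first",
         call. = FALSE)
  clamped <- 0L
  cl <- function(x) {
    if (x < 0) clamped <<- clamped + 1L
    max(x, 0)
  }
  lab <- rownames(m)
  nodes <- as.list(lab)          # newick fragment per active node
  d <- m
  while (length(nodes) > 3L) {
    k <- length(nodes)
    r <- rowSums(d)
    Q <- (k - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- c(NA_integer_, NA_integer_)
    bq <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    vi <- cl(d[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2)))
    vj <- cl(d[i, j] - d[i, j] / 2 - (r[i] - r[j]) / (2 * (k - 2)))
    newick <- sprintf("(%s:%.12g,%s:%.12g)", nodes[[i]], vi, nodes[[j]], vj)
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    d <- d2
    nodes <- c(nodes[keep], newick)
  }
  v1 <- cl((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- cl((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- cl((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nodes[[1]], v1, nodes[[2]], v2, nodes[[3]], v3)
  phy <- ape::read.tree(text = txt)
  attr(phy, "clamped") <- clamped
  phy
}

# Canonical bipartition keys for the internal nodes of a phylo tree
# (complement taken so the first alphabetical taxon is never in the set;
# trivial splits get NA).
node_split_keys <- function(phy) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  anchor <- sort(labs)[1]
  vapply(pp, function(ix) {
    s <- labs[ix]
    if (anchor %in% s) s <- setdiff(labs, s)
    if (length(s) == 0L || length(s) >= length(labs) - 1L) NA_character_
    else paste(sort(s), collapse = "|")
  }, character(1))
}

#' Neighbor-joining tree with bootstrap support from a codon alignment
#'
#' Codon columns are resampled with replacement; each replicate's Ks matrix
#' and NJ tree are recomputed, and support for each internal bipartition of
#' the full-data tree is the percentage of usable replicates containing it.
#' Replicates with undefined distances are skipped and counted.
#'
#' @param rows named character vector of aligned CDS rows.
#' @param n_reps bootstrap replicate count.
#' @param seed integer seed.
#' @return list with `tree` (the full-data `phylo`, node labels set to
#'   support percentages), `support` (per-split table), `n_reps`,
#'   `n_skipped`.
#' @export
bootstrap_support <- function(rows, n_reps = 1000L, seed = 1L) {
  validate_alignment(rows)
  stopifnot(n_reps >= 1L)
  full_m <- ks_matrix(rows)
  full <- nj_tree(full_m)
  keys <- node_split_keys(full)
  cod <- lapply(rows, codon_split)
  ncod <- length(cod[[1]])
  counts <- stats::setNames(rep(0L, sum(!is.na(keys))),
                            keys[!is.na(keys)])
  local_seed(seed, {
    n_skipped <- 0L
    for (b in seq_len(n_reps)) {
      idx <- sample.int(ncod, ncod, replace = TRUE)
      rrows <- vapply(cod, function(cs) paste(cs[idx], collapse = ""),
                      character(1))
      mb <- ks_matrix(rrows)
      if (any(is.na(mb))) { n_skipped <- n_skipped + 1L; next }
      bk <- node_split_keys(nj_tree(mb))
      hit <- intersect(names(counts), bk)
      counts[hit] <- counts[hit] + 1L
    }
    used <- n_reps - n_skipped
    pct <- if (used > 0L) 100 * counts / used else counts * NA_real_
    node_lab <- rep(NA_real_, length(keys))
    node_lab[!is.na(keys)] <- pct[keys[!is.na(keys)]]
    full$node.label <- ifelse(is.na(node_lab), "",
                              sprintf("%.0f", node_lab))
    list(tree = full,
         support = data.frame(split = names(counts), support = unname(pct),
                              stringsAsFactors = FALSE),
         n_reps = n_reps, n_skipped = n_skipped)
  })
}
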