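# End-to-end pipeline driver: simulate -> annotate -> quantify -> evolve ->
# repeats, each stage reading its inputs from and writing its outputs to a
# run directory. Same seed + config => byte-identical tabular outputs.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the CDS of one gene of an ancestral block
#'
#' @param anc an [ancestral_block()] result.
#' @param fam `"B"` or `"A"`.
#' @return the CDS DNA string.
#' @export
ancestral_cds <- function(anc, fam = c("B", "A")) {
  fam <- match.arg(fam)
  m <- anc[[fam]]$model
  substr(anc[[fam]]$seq, m$cds_start + 1L, m$cds_end)
}

log_line <- function(outdir, ...) {
  cat(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ..., "\n"),
      file = file.path(outdir, "run.log"), append = TRUE)
}

#' Run the analysis pipeline
#'
#' Subcommands: `simulate` (gene family, amplicon contig, expression levels,
#' paired reads, truth tables), `annotate` (coding assessment and
#' active/pseudogene classification of the simulated transcripts),
#' `quantify` (locus-specific expression from the simulated read pairs),
#' `evolve` (Ks matrix, NJ tree with bootstrap, duplication age), `repeats`
#' (dot-plot arm detection and overlap assembly), or `all`. Later stages
#' read the files earlier stages wrote into `outdir`.
#'
#' @param config a [run_config()].
#' @param subcommand one of `simulate`, `annotate`, `quantify`, `evolve`,
#'   `repeats`, `all`.
#' @param outdir run directory (created if needed).
#' @param family optional [family_params()]; defaults to
#'   `family_params(seed = config$seed)`.
#' @param n_pairs read pairs to simulate.
#' @param error_rate per-base sequencing error rate.
#' @param bootstrap_reps bootstrap replicates for the `evolve` stage
#'   (defaults to `config$bootstrap_reps`).
#' @return invisibly, the run directory.
#' @export
run_pipeline <- function(config, subcommand = c("all", "simulate", "annotate",
                                                "quantify", "evolve",
                                                "repeats"),
                         outdir = "ygenefam_run", family = NULL,
                         n_pairs = 20000L, error_rate = 0.001,
                         bootstrap_reps = NULL) {
  if (!subcommand[1] %in% c("all", "simulate", "annotate", "quantify",
                            "evolve", "repeats"))
    stop("unknown subcommand: ", subcommand[1], call. = FALSE)
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(outdir, "config.yaml"))
  log_line(outdir, "run started: subcommand=", subcommand,
           " seed=", config$seed)
  stages <- if (subcommand == "all")
    c("simulate", "annotate", "quantify", "evolve", "repeats")
  else subcommand
  for (st in stages) {
    switch(st,
           simulate = stage_simulate(config, outdir, family, n_pairs,
                                     error_rate),
           annotate = stage_annotate(config, outdir),
           quantify = stage_quantify(config, outdir),
           evolve = stage_evolve(config, outdir,
                                 bootstrap_reps %||% config$bootstrap_reps),
           repeats = stage_repeats(config, outdir))
    log_line(outdir, "stage done: ", st)
  }
  invisible(outdir)
}

stage_simulate <- function(config, outdir, family, n_pairs, error_rate) {
  params <- family %||% family_params(seed = config$seed)
  fam <- simulate_family(params)
  truth <- assign_expression(fam$truth, seed = config$seed + 1L)
  tr <- family_transcripts(fam)
  write_fasta(fam$loci, file.path(outdir, "loci.fasta"))
  write_fasta(tr, file.path(outdir, "transcripts.fasta"))
  write_tsv(tr[, c("id", "cds_start")],
            file.path(outdir, "transcripts_cds.tsv"))
  write_tsv(truth, file.path(outdir, "truth_loci.tsv"))
  write_tsv(fam$indels, file.path(outdir, "truth_indels.tsv"))
  write_fasta(data.frame(id = c("refB", "refA"),
                         seq = c(ancestral_cds(fam$ancestral, "B"),
                                 ancestral_cds(fam$ancestral, "A"))),
              file.path(outdir, "reference_cds.fasta"))
  feats <- do.call(rbind, lapply(fam$loci$id, function(lid) {
    m <- fam$models[[lid]]
    feature_table(lid, c(0L, m$intron_start, m$cds_start),
                  c(nchar(fam$loci$seq[fam$loci$id == lid]),
                    m$intron_end, m$cds_end),
                  strand = "+", type = c("gene", "intron", "coding_region"),
                  name = paste0(lid, c("", "_intron", "_cds")))
  }))
  write_features(feats, file.path(outdir, "loci.gff3"), "gff3")
  usable <- tr[nchar(tr$seq) > config$insert_max, , drop = FALSE]
  reads <- simulate_read_pairs(usable, truth, n_pairs,
                               error_rate = error_rate, config = config,
                               seed = config$seed + 2L)
  write_fastq_pairs(reads$pairs, file.path(outdir, "reads_1.fastq"),
                    file.path(outdir, "reads_2.fastq"))
  write_tsv(reads$sources, file.path(outdir, "truth_read_sources.tsv"))
  log_line(outdir, "simulated ", nrow(fam$loci), " loci, ",
           nrow(reads$pairs), " read pairs")
}

stage_annotate <- function(config, outdir) {
  tr <- read_fasta(file.path(outdir, "transcripts.fasta"))
  cdsoff <- read_tsv(file.path(outdir, "transcripts_cds.tsv"))
  tr$cds_start <- cdsoff$cds_start[match(tr$id, cdsoff$id)]
  refs <- read_fasta(file.path(outdir, "reference_cds.fasta"))
  thr <- classifier_thresholds(config$active_min_aa,
                               config$active_min_fraction)
  out <- list()
  for (fam in c("B", "A")) {
    sel <- tr[startsWith(tr$id, fam), , drop = FALSE]
    if (nrow(sel) == 0L) next
    ref <- refs$seq[refs$id == paste0("ref", fam)]
    out[[fam]] <- assess_transcripts(sel, ref, thr)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  write_tsv(res, file.path(outdir, "assessments.tsv"))
  log_line(outdir, sum(res$status == "active"), " active / ",
           sum(res$status == "pseudogene"), " pseudogene calls")
}

stage_quantify <- function(config, outdir) {
  tr <- read_fasta(file.path(outdir, "transcripts.fasta"))
  truth <- read_tsv(file.path(outdir, "truth_loci.tsv"))
  pairs <- read_fastq_pairs(file.path(outdir, "reads_1.fastq"),
                            file.path(outdir, "reads_2.fastq"))
  tr <- tr[nchar(tr$seq) > config$insert_max, , drop = FALSE]
  fmap <- data.frame(locus_id = truth$locus_id, family = truth$family)
  qx <- quantify_expression(tr, pairs, fmap, config)
  counts <- merge(qx$refs[, c("ref_id", "copy_number", "length",
                              "unique_sites")],
                  qx$counts, by = "ref_id")
  write_tsv(counts, file.path(outdir, "counts.tsv"))
  write_tsv(qx$normalized, file.path(outdir, "normalized.tsv"))
  sm <- summarize_expression(qx$normalized, qx$ref_families)
  write_tsv(sm$per_family, file.path(outdir, "expression_summary.tsv"))
  write_tsv(sm$mean_ratio, file.path(outdir, "expression_family_ratio.tsv"))
  log_line(outdir, sum(qx$verdicts$verdict == "unique"), " unique pairs of ",
           nrow(pairs))
}

stage_evolve <- function(config, outdir, bootstrap_reps) {
  truth <- read_tsv(file.path(outdir, "truth_loci.tsv"))
  loci <- read_fasta(file.path(outdir, "loci.fasta"))
  feats <- read_features(file.path(outdir, "loci.gff3"), "gff3")
  refs <- read_fasta(file.path(outdir, "reference_cds.fasta"))
  ref_len <- nchar(refs$seq[refs$id == "refB"])
  cds <- feats[feats$type == "coding_region", , drop = FALSE]
  # full-length-CDS loci (no CDS indels) keep a gap-free codon alignment;
  # premature stops from substitutions do not perturb synonymous distances
  sel <- truth$locus_id[!truth$frameshift & truth$family == "B-like"]
  rows <- character(0)
  for (lid in sel) {
    f <- cds[cds$contig_id == lid, , drop = FALSE]
    if (nrow(f) != 1L || f$end - f$start != ref_len) next
    rows[lid] <- substr(loci$seq[loci$id == lid], f$start + 1L, f$end)
  }
  if (length(rows) < 3L) {
    log_line(outdir, "evolve: fewer than 3 usable active loci; skipped")
    return(invisible(NULL))
  }
  # outgroup lineage: same depth from the ancestral block as the family
  params <- family_params(seed = config$seed)
  og <- mutate_jc(refs$seq[refs$id == "refB"],
                  params$substitution_rate * params$total_time,
                  seed = config$seed + 3L)
  aln <- c(rows, outgroup = og)
  m <- ks_matrix(aln)
  write_tsv(data.frame(taxon = rownames(m), as.data.frame(m)),
            file.path(outdir, "ks_matrix.tsv"))
  fam_ix <- setdiff(rownames(m), "outgroup")
  intra <- m[fam_ix, fam_ix]
  inter_mean <- mean(m[fam_ix, "outgroup"], na.rm = TRUE)
  smry <- ks_summary(intra)
  age <- estimate_duplication_age(smry$max, inter_mean,
                                  config$calibration_time)
  write_tsv(data.frame(mean_intra_ks = smry$mean, max_intra_ks = smry$max,
                       most_distant = smry$most_distant,
                       interspecies_ks_mean = inter_mean,
                       calibration_mya = config$calibration_time,
                       est_duplication_age_mya = age),
            file.path(outdir, "dating.tsv"))
  bs <- bootstrap_support(aln, n_reps = bootstrap_reps,
                          seed = config$seed + 4L)
  ape::write.tree(bs$tree, file.path(outdir, "tree.nwk"))
  write_tsv(bs$support, file.path(outdir, "tree_support.tsv"))
  log_line(outdir, "evolve: ", length(rows), " loci, est age ",
           round(age, 2), " Mya, ", bs$n_skipped, " replicates skipped")
}

stage_repeats <- function(config, outdir) {
  loci <- read_fasta(file.path(outdir, "loci.fasta"))
  truth <- read_tsv(file.path(outdir, "truth_loci.tsv"))
  # repeat unit: one gene block (a B locus and its paired A locus)
  bid <- truth$locus_id[truth$family == "B-like"][1]
  aid <- sub("^B", "A", bid)
  unit <- paste0(loci$seq[loci$id == bid], random_dna(500, config$seed + 5L),
                 loci$seq[loci$id == aid])
  blocks <- data.frame(id = "U", seq = unit)
  plan <- amplicon_plan(c("U", "U", "U"), c("+", "+", "-"),
                        c(2000L, 2000L))
  lay <- layout_amplicon(blocks, plan, seed = config$seed + 6L)
  write_fasta(lay$contig, file.path(outdir, "amplicon.fasta"))
  write_features(lay$features, file.path(outdir, "amplicon.gff3"), "gff3")
  arms <- repeat_pairs(lay$contig$seq, w = config$dotplot_word,
                       min_arm = 2000L, max_gap = 500L)
  write_tsv(arms, file.path(outdir, "repeat_arms.tsv"))
  if (nrow(arms) > 0L)
    write_features(
      feature_table("amplicon",
                    c(arms$armA_start, arms$armB_start),
                    c(arms$armA_end, arms$armB_end),
                    strand = "+",
                    type = rep(arms$orientation, 2L),
                    name = paste0(rep(arms$orientation, 2L),
                                  rep(seq_len(nrow(arms)), 2L),
                                  rep(c("_armA", "_armB"),
                                      each = nrow(arms)))),
      file.path(outdir, "repeat_arms.bed"), "bed")
  # overlap assembly demo: exact tiling of a large synthetic contig
  big <- random_dna(300000L, seed = config$seed + 7L)
  tiles <- tile_sequence(big, 5L, 20000L)
  asm <- assemble_overlaps(tiles, min_overlap = config$relaxed_min_overlap,
                           min_identity = config$relaxed_min_identity)
  write_tsv(asm$layout, file.path(outdir, "assembly_layout.tsv"))
  write_fasta(asm$contigs, file.path(outdir, "assembled.fasta"))
  log_line(outdir, "repeats: ", nrow(arms), " arm pairs; assembly ",
           "reconstructed=", identical(asm$contigs$seq[1], big))
}
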