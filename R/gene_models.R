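# Splice-aware coding assessment: ORF prediction, GT-AG check, indel and
# frameshift detection against a reference CDS, premature-stop localization,
# and active/pseudogene classification.

#' Two-exon gene model
#'
#' 0-based half-open locus coordinates of the single 5'-UTR intron and the
#' CDS in exon 2.
#'
#' @param intron_start,intron_end,cds_start,cds_end locus coordinates.
#' @return a list of class `"gene_model"`.
#' @export
gene_model <- function(intron_start, intron_end, cds_start, cds_end) {
  m <- list(intron_start = as.integer(intron_start),
            intron_end = as.integer(intron_end),
            cds_start = as.integer(cds_start),
            cds_end = as.integer(cds_end))
  if (m$intron_start > m$intron_end || m$intron_end > m$cds_start ||
      m$cds_start > m$cds_end)
    stop("gene model coordinates must satisfy intron_start <= intron_end <= ",
         "cds_start <= cds_end (intron upstream of the start codon)",
         call. = FALSE)
  class(m) <- "gene_model"
  m
}

#' Splice a locus sequence under a gene model
#'
#' Removes the intron and reports whether the intron carries consensus GT-AG
#' dinucleotides.
#'
#' @param locus_sequence DNA string.
#' @param model a [gene_model()] (or compatible list with `intron_start`,
#'   `intron_end`).
#' @return list with `transcript` (exon concatenation) and `valid` (GT-AG
#'   flag; `TRUE` for a zero-length intron).
#' @export
splice_transcript <- function(locus_sequence, model) {
  n <- nchar(locus_sequence)
  i0 <- model$intron_start
  i1 <- model$intron_end
  if (i0 < 0L || i1 > n || i0 > i1)
    stop("intron interval [", i0, ", ", i1, ") out of bounds for a ", n,
         " bp locus", call. = FALSE)
  transcript <- paste0(substr(locus_sequence, 1L, i0),
                       substr(locus_sequence, i1 + 1L, n))
  valid <- if (i1 - i0 < 4L) TRUE else
    substr(locus_sequence, i0 + 1L, i0 + 2L) == "GT" &&
    substr(locus_sequence, i1 - 1L, i1) == "AG"
  list(transcript = transcript, valid = valid)
}

#' Find forward-strand ORFs
#'
#' Every ATG paired with its first downstream in-frame stop, in all three
#' forward frames; the peptide excludes the stop codon. Coordinates are
#' 0-based half-open over the coding bases (ATG through the last base before
#' the stop).
#'
#' @param transcript DNA string.
#' @param min_aa minimum peptide length (aa) to report.
#' @return data.frame with columns `start`, `end`, `frame`, `peptide_aa`,
#'   sorted by decreasing peptide length.
#' @export
find_orfs <- function(transcript, min_aa = 1L) {
  stopifnot(nchar(transcript) > 0L)
  out <- list()
  for (f in 0:2) {
    aa <- translate_codons(substr(transcript, f + 1L, nchar(transcript)))
    if (length(aa) == 0L) next
    atg <- which(aa == "M")
    stp <- which(aa == "*")
    if (length(atg) == 0L || length(stp) == 0L) next
    nxt <- stp[findInterval(atg, stp) + 1L]
    keep <- !is.na(nxt)
    atg <- atg[keep]; nxt <- nxt[keep]
    pep <- nxt - atg
    keep <- pep >= min_aa
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = f + 3L * (atg[keep] - 1L),
      end = f + 3L * (nxt[keep] - 1L),
      frame = f, peptide_aa = pep[keep])
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), peptide_aa = integer(0)))
  res <- do.call(rbind, out)
  res[order(-res$peptide_aa, res$start), , drop = FALSE]
}

#' Peptide length implied by a premature stop position
#'
#' The stop position is the 1-based CDS coordinate of the stop codon's first
#' base, so the encoded peptide is `(stop_start - 1) / 3` aa.
#'
#' @param stop_start 1-based CDS position of the stop codon's first base;
#'   must satisfy `stop_start %% 3 == 1`.
#' @return peptide length in aa.
#' @export
peptide_length_from_stop <- function(stop_start) {
  if (any((stop_start - 1) %% 3 != 0))
    stop("stop_start must be congruent to 1 (mod 3): got ",
         paste(stop_start, collapse = ", "), call. = FALSE)
  (stop_start - 1) %/% 3
}

validate_reference_cds <- function(reference_cds) {
  n <- nchar(reference_cds)
  if (n %% 3 != 0 || n < 6L)
    stop("reference CDS length must be a positive multiple of 3",
         call. = FALSE)
  if (substr(reference_cds, 1L, 3L) != "ATG")
    stop("reference CDS must begin with ATG", call. = FALSE)
  aa <- translate_codons(reference_cds)
  if (aa[length(aa)] != "*")
    stop("reference CDS must end with a stop codon", call. = FALSE)
  if (any(aa[-length(aa)] == "*"))
    stop("reference CDS contains an internal stop codon", call. = FALSE)
  invisible(TRUE)
}

# Extract indels from a gapped pairwise alignment (pattern = observed,
# subject = reference). Positions are 1-based reference coordinates of the
# first affected / first deleted reference base; size > 0 insertion,
# size < 0 deletion.
alignment_indels <- function(pat, sub) {
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  sc <- strsplit(sub, "", fixed = TRUE)[[1]]
  refpos <- cumsum(sc != "-")
  ev <- list()
  r <- rle(paste0(ifelse(sc == "-", "I", ifelse(pc == "-", "D", "M"))))
  idx <- cumsum(r$lengths) - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k] == "M") next
    i <- idx[k]
    if (r$values[k] == "I") {
      # gap in reference: insertion after reference base refpos[i]
      ev[[length(ev) + 1L]] <- data.frame(ref_pos = refpos[i] + 1L,
                                          size = r$lengths[k])
    } else {
      ev[[length(ev) + 1L]] <- data.frame(ref_pos = refpos[i],
                                          size = -r$lengths[k])
    }
  }
  if (length(ev) == 0L)
    return(data.frame(ref_pos = integer(0), size = integer(0)))
  do.call(rbind, ev)
}

#' Assess the coding state of a transcript against a reference CDS
#'
#' Globally aligns the transcript's CDS region to the reference (match +1,
#' mismatch -1, gap open -5, gap extend -1; reference aligned end-to-end,
#' trailing transcript sequence free), extracts indels with reference
#' coordinates, and translates the observed CDS from the reference start
#' through any shifted frame to the first stop.
#'
#' @param transcript spliced transcript DNA string.
#' @param reference_cds reference CDS (ATG..stop, length divisible by 3).
#' @param cds_start 0-based offset of the CDS start within the transcript.
#' @param locus_id optional id carried through to the result.
#' @return a list of class `"coding_assessment"`: `locus_id`, `indels`
#'   (data.frame `ref_pos`, `size`), `frameshift`, `premature_stop_start`
#'   (1-based CDS coordinate of the stop codon's first base, or `NA`),
#'   `peptide_aa`, `structural_type` (`"A-like"`, `"B-like"`, `"C-like"`,
#'   `"other"`), and `status` (`NA` until [classify_locus()]).
#' @export
assess_coding <- function(transcript, reference_cds, cds_start = 0L,
                          locus_id = NA_character_) {
  validate_reference_cds(reference_cds)
  obs <- substr(transcript, cds_start + 1L, nchar(transcript))
  if (nchar(obs) == 0L) stop("empty CDS region", call. = FALSE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = obs, subject = reference_cds, type = "local-global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  indels <- alignment_indels(pat, sub)
  frameshift <- nrow(indels) > 0L && any(indels$size %% 3L != 0L)
  obs_cds <- gsub("-", "", pat, fixed = TRUE)
  aa <- translate_codons(obs_cds)
  n_cod <- length(aa)
  stops <- which(aa == "*")
  ref_aa <- nchar(reference_cds) %/% 3L - 1L
  if (length(stops) > 0L && stops[1] < n_cod) {
    premature_stop_start <- 3L * (stops[1] - 1L) + 1L
    peptide_aa <- peptide_length_from_stop(premature_stop_start)
  } else {
    premature_stop_start <- NA_integer_
    peptide_aa <- if (length(stops) > 0L) stops[1] - 1L else n_cod
  }
  fs_sizes <- indels$size[indels$size %% 3L != 0L]
  structural_type <-
    if (nrow(indels) == 0L && peptide_aa == ref_aa) "A-like"
    else if (frameshift && all(fs_sizes > 0L)) "B-like"
    else if (frameshift && all(fs_sizes < 0L)) "C-like"
    else "other"
  structure(list(locus_id = locus_id, indels = indels,
                 frameshift = frameshift,
                 premature_stop_start = premature_stop_start,
                 peptide_aa = as.integer(peptide_aa),
                 structural_type = structural_type,
                 status = NA_character_),
            class = "coding_assessment")
}

#' Classifier thresholds for the active/pseudogene call
#'
#' @param min_aa absolute minimum predicted peptide length (aa).
#' @param min_fraction minimum peptide length as a fraction of the reference
#'   peptide.
#' @return a list of class `"classifier_thresholds"`.
#' @export
classifier_thresholds <- function(min_aa = 200L, min_fraction = 0.40) {
  stopifnot(min_aa >= 1, min_fraction > 0, min_fraction <= 1)
  structure(list(min_aa = as.integer(min_aa),
                 min_fraction = as.numeric(min_fraction)),
            class = "classifier_thresholds")
}

#' Classify a locus as active or pseudogene
#'
#' Active iff the predicted peptide reaches both the absolute and the
#' fractional length threshold:
#' `peptide_aa >= max(min_aa, ceiling(min_fraction * reference_aa))`.
#'
#' @param assessment a [assess_coding()] result.
#' @param reference_aa reference peptide length in aa (> 0).
#' @param thresholds a [classifier_thresholds()].
#' @return the assessment with `status` set to `"active"` or `"pseudogene"`.
#' @export
classify_locus <- function(assessment, reference_aa,
                           thresholds = classifier_thresholds()) {
  if (!is.numeric(reference_aa) || reference_aa <= 0)
    stop("reference_aa must be > 0", call. = FALSE)
  cut <- max(thresholds$min_aa,
             ceiling(thresholds$min_fraction * reference_aa))
  assessment$status <- if (assessment$peptide_aa >= cut) "active" else
    "pseudogene"
  assessment
}

#' Assess and classify a table of transcripts
#'
#' @param transcripts sequence table with `id`, `seq` and optionally
#'   `cds_start` (0-based CDS offset; default 0).
#' @param reference_cds reference CDS string.
#' @param thresholds a [classifier_thresholds()].
#' @return data.frame with one row per transcript: `locus_id`, `n_indels`,
#'   `indel_sizes` (comma-separated), `frameshift`, `premature_stop_start`,
#'   `peptide_aa`, `structural_type`, `status`.
#' @export
assess_transcripts <- function(transcripts, reference_cds,
                               thresholds = classifier_thresholds()) {
  ref_aa <- nchar(reference_cds) %/% 3L - 1L
  cds_start <- if ("cds_start" %in% names(transcripts))
    transcripts$cds_start else rep(0L, nrow(transcripts))
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    a <- assess_coding(transcripts$seq[i], reference_cds,
                       cds_start = cds_start[i],
                       locus_id = transcripts$id[i])
    a <- classify_locus(a, ref_aa, thresholds)
    data.frame(locus_id = a$locus_id, n_indels = nrow(a$indels),
               indel_sizes = paste(a$indels$size, collapse = ","),
               frameshift = a$frameshift,
               premature_stop_start = a$premature_stop_start,
               peptide_aa = a$peptide_aa,
               structural_type = a$structural_type,
               status = a$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Engineer a reference CDS and a frameshifted derivative
#'
#' Builds a random reference CDS of `n_aa` aa, then patches it so that
#' deleting `del_len` bp at reference position `del_pos` yields a derivative
#' whose first shifted-frame stop codon begins at CDS nucleotide `stop_at`
#' (1-based, `stop_at %% 3 == 1`). Both constraints are enforced by
#' construction and re-verified by direct translation.
#'
#' @param n_aa reference peptide length (aa).
#' @param del_pos 1-based reference position of the first deleted base.
#' @param del_len deletion length in bp (not divisible by 3).
#' @param stop_at required 1-based position of the premature stop's first
#'   base in the derived CDS.
#' @param seed integer seed.
#' @return list with `reference` (clean CDS), `mutated` (derivative carrying
#'   the deletion), `del_pos`, `del_len`, `stop_at`.
#' @export
engineer_premature_stop_cds <- function(n_aa = 543L, del_pos = 1218L,
                                        del_len = 8L, stop_at = 1273L,
                                        seed = 1L) {
  stopifnot(del_len %% 3L != 0L, (stop_at - 1L) %% 3L == 0L,
            stop_at > del_pos - del_len, 3L * (n_aa + 1L) > stop_at + del_len)
  local_seed(seed, {
    ref <- strsplit(random_cds(n_aa), "", fixed = TRUE)[[1]]
    map <- function(m) ifelse(m >= del_pos, m + del_len, m)  # mutated -> ref
    target_codon <- (stop_at - 1L) %/% 3L + 1L
    for (iter in 1:200) {
      mut <- ref[-seq.int(del_pos, del_pos + del_len - 1L)]
      aa_mut <- translate_codons(paste(mut, collapse = ""))
      aa_ref <- translate_codons(paste(ref, collapse = ""))
      early_ref <- which(aa_ref[-length(aa_ref)] == "*")
      stops_mut <- which(aa_mut == "*")
      bad_mut <- stops_mut[stops_mut < target_codon]
      if (length(early_ref) == 0L && length(bad_mut) == 0L &&
          length(stops_mut) > 0L && stops_mut[1] == target_codon) break
      if (!identical(ref[map(stop_at:(stop_at + 2L))], c("T", "A", "A"))) {
        ref[map(stop_at:(stop_at + 2L))] <- c("T", "A", "A")
      } else if (length(bad_mut) > 0L) {
        k <- bad_mut[1]
        pos <- map(3L * (k - 1L) + 1:3)
        ref[pos] <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
      } else if (length(early_ref) > 0L) {
        k <- early_ref[1]
        pos <- 3L * (k - 1L) + 1:3
        ref[pos] <- sample(c("A", "C", "G", "T"), 3L, replace = TRUE)
      }
    }
    reference <- paste(ref, collapse = "")
    mutated <- paste(ref[-seq.int(del_pos, del_pos + del_len - 1L)],
                     collapse = "")
    validate_reference_cds(reference)
    aa_mut <- translate_codons(mutated)
    first <- which(aa_mut == "*")[1]
    if (is.na(first) || 3L * (first - 1L) + 1L != stop_at)
      stop("fixture engineering failed to place the premature stop",
           call. = FALSE)
    list(reference = reference, mutated = mutated, del_pos = del_pos,
         del_len = del_len, stop_at = stop_at)
  })
}
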