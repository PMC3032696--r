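# File I/O: FASTA/FASTQ through Biostrings, GFF3/BED through rtracklayer,
# tabular outputs as plain TSV. Internal coordinates are 0-based half-open
# everywhere; GFF3 on disk is 1-based inclusive, BED 0-based half-open.

#' Read a FASTA file into a sequence table
#'
#' @param path FASTA file path.
#' @return a data.frame with columns `id`, `desc`, `seq` (uppercase DNA),
#'   one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_fasta_lines(path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L)
    return(data.frame(id = character(0), desc = character(0),
                      seq = character(0), stringsAsFactors = FALSE))
  hdr <- names(x)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (anyDuplicated(id))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  data.frame(id = id, desc = desc,
             seq = unname(toupper(as.character(x))),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Light structural scan so malformed input is reported with a line number
# (Biostrings' own errors do not carry one).
check_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">"))
    stop("FASTA parse error at line ", nonempty[1],
         ": expected '>' header", call. = FALSE)
  hdr_idx <- which(startsWith(lines, ">"))
  for (k in seq_along(hdr_idx)) {
    i <- hdr_idx[k]
    if (nchar(trimws(sub("^>", "", lines[i]))) == 0L)
      stop("FASTA parse error at line ", i, ": empty header", call. = FALSE)
    to <- if (k < length(hdr_idx)) hdr_idx[k + 1] - 1L else length(lines)
    body <- lines[seq.int(i + 1L, length.out = max(0L, to - i))]
    if (sum(nchar(trimws(body))) == 0L)
      stop("FASTA parse error at line ", i, ": record '",
           sub("^>", "", lines[i]), "' has an empty sequence", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a sequence table to FASTA
#'
#' @param seqs data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  x <- Biostrings::DNAStringSet(seqs$seq)
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  names(x) <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

strip_mate_suffix <- function(ids) sub("/[12]$", "", sub("\\s.*$", "", ids))

#' Read paired FASTQ files into a read-pair table
#'
#' Records are paired positionally; ids (after stripping any `/1`, `/2`
#' suffix) must match at every position.
#'
#' @param path1,path2 FASTQ paths for mate 1 and mate 2.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(path1, path2) {
  for (p in c(path1, path2))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                     with.qualities = TRUE)
  if (length(r1) != length(r2))
    stop("pairing error: mate files have ", length(r1), " and ", length(r2),
         " records", call. = FALSE)
  if (length(r1) == 0L)
    return(data.frame(id = character(0), seq1 = character(0),
                      qual1 = character(0), seq2 = character(0),
                      qual2 = character(0), stringsAsFactors = FALSE))
  id1 <- strip_mate_suffix(names(r1))
  id2 <- strip_mate_suffix(names(r2))
  bad <- which(id1 != id2)
  if (length(bad) > 0)
    stop("pairing error at record ", bad[1], ": '", id1[bad[1]], "' vs '",
         id2[bad[1]], "'", call. = FALSE)
  data.frame(id = unname(id1),
             seq1 = unname(toupper(as.character(r1))),
             qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
             seq2 = unname(toupper(as.character(r2))),
             qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a read-pair table to paired FASTQ files
#'
#' @param pairs data.frame as returned by [read_fastq_pairs()].
#' @param path1,path2 output FASTQ paths (mates 1 and 2).
#' @return c(path1, path2), invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_one <- function(seqs, quals, ids, suffix, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0(ids, suffix)
    q <- Biostrings::BStringSet(quals)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  if (nrow(pairs) == 0L) {
    file.create(path1); file.create(path2)
  } else {
    write_one(pairs$seq1, pairs$qual1, pairs$id, "/1", path1)
    write_one(pairs$seq2, pairs$qual2, pairs$id, "/2", path2)
  }
  invisible(c(path1, path2))
}

#' Feature table constructor
#'
#' Internal feature convention: 0-based half-open `[start, end)` on `contig_id`
#' with strand `+`/`-`.
#'
#' @param contig_id,start,end,strand,type,name vectors of equal length.
#' @return a validated feature data.frame.
#' @export
feature_table <- function(contig_id, start, end, strand = "+",
                          type = "region", name = NA_character_) {
  df <- data.frame(contig_id = contig_id, start = as.integer(start),
                   end = as.integer(end), strand = strand, type = type,
                   name = name, stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stop("feature start must be < end (0-based half-open)", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("feature strand must be '+' or '-'", call. = FALSE)
  df
}

#' Write features to GFF3 or BED
#'
#' GFF3 is written 1-based inclusive, BED 0-based half-open; the conversions
#' are mutually inverse with [read_features()].
#'
#' @param features a feature data.frame (see [feature_table()]).
#' @param path output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, format = c("gff3", "bed")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown feature format: ",
                                              format[1], call. = FALSE))
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  gr$type <- features$type
  gr$name <- as.character(features$name)
  if (format == "gff3") {
    gr$ID <- gr$name
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read features from GFF3 or BED into the internal convention
#'
#' @param path input path.
#' @param format `"gff3"` or `"bed"`.
#' @return a feature data.frame (0-based half-open coordinates).
#' @export
read_features <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- rtracklayer::import(path, format = format)
  nm <- if (format == "gff3" && "ID" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$ID)
  } else if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(gr$name)
  } else rep(NA_character_, length(gr))
  ty <- if ("type" %in% names(S4Vectors::mcols(gr))) as.character(gr$type)
        else rep("region", length(gr))
  data.frame(contig_id = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             type = ty, name = nm, stringsAsFactors = FALSE)
}

#' Plain TSV helpers
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
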