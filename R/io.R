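# File-format plumbing: FASTA/FASTQ via Biostrings, SAM emission.

#' Read a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#' @param path reads file; format inferred from extension (`.fq`/`.fastq`
#'   read as FASTQ, otherwise FASTA).
#' @return tibble with `name` and `seq`.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  tibble::tibble(name = sub("\\s.*$", "", names(x)), seq = unname(as.character(x)))
}

#' Write reads to FASTQ
#'
#' Emits constant base qualities (the aligner uses none).
#' @param reads tibble with `name`, `seq`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  reads <- normalize_reads(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$name))
  qual <- Biostrings::PhredQuality(
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1)))
  y <- Biostrings::QualityScaledDNAStringSet(x, qual)
  Biostrings::writeQualityScaledXStringSet(y, path)
  invisible(path)
}

#' Write alignment records as SAM
#'
#' Coordinates are emitted 1-based per the SAM convention. Quantized-domain
#' records are placed at their back-translated nucleotide position and carry
#' the quantized-domain interval in the private `qc:Z` tag (domain in
#' `qd:Z`); `NM` and `AS` hold the record's edit distance and score. `SEQ`
#' is omitted (`*`). Reads listed in `reads` but absent from `records` are
#' emitted unmapped.
#'
#' @param records alignment tibble from [run_hqalign()] (one domain).
#' @param path output SAM path.
#' @param target_lengths named integer vector of chromosome lengths (or a
#'   named character genome, from which lengths are taken).
#' @param reads optional reads tibble used to emit unmapped records.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, target_lengths, reads = NULL) {
  if (is.character(target_lengths) && !is.null(names(target_lengths)) &&
      !is.numeric(target_lengths)) {
    target_lengths <- stats::setNames(nchar(target_lengths), names(target_lengths))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(target_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(target_lengths[[nm]])), con)
  }
  writeLines("@PG\tID:hqalign\tPN:hqalign", con)
  if (nrow(records) > 0) {
    flag <- ifelse(records$strand == "-", 16L, 0L) +
      ifelse(records$is_supplementary, 2048L, 0L)
    pos1 <- if ("nt_tstart" %in% names(records)) {
      ifelse(records$domain == "quantized", records$nt_tstart, records$tstart) + 1L
    } else records$tstart + 1L
    lead <- ifelse(records$strand == "+", records$qstart,
                   records$query_length - records$qend)
    trail <- ifelse(records$strand == "+", records$query_length - records$qend,
                    records$qstart)
    cig <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""), records$cigar,
                  ifelse(trail > 0, paste0(trail, "S"), ""))
    qc <- paste0("qc:Z:", records$tstart, "-", records$tend)
    lines <- paste(records$query_name, flag, records$target_name, pos1,
                   records$mapq, cig, "*", 0L, 0L, "*", "*",
                   paste0("NM:i:", records$nm),
                   paste0("AS:i:", round(records$score)),
                   paste0("qd:Z:", records$domain), qc, sep = "\t")
    writeLines(lines, con)
  }
  if (!is.null(reads)) {
    reads <- normalize_reads(reads)
    missing <- setdiff(reads$name, unique(records$query_name))
    for (nm in missing) {
      writeLines(paste(nm, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, "*", "*",
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
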