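## seqio: FASTQ/FASTA input, quality filtering, rejection reporting.

#' Construct a table of sequence reads
#'
#' Reads are held in an ordinary data frame with one row per read:
#' `read_id` (character), `seq` (character, uppercase `A/C/G/T/N`), and
#' `qual` (list column of integer Phred scores, zero-length for FASTA
#' input). This is the container every downstream pipeline step consumes.
#'
#' @param read_id character vector of read identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param qual list of integer vectors of Phred quality scores, one per
#'   read, each the same length as its sequence (or zero-length).
#' @return a `sequence_reads` data frame.
#' @export
sequence_reads <- function(read_id, seq, qual = NULL) {
  seq <- toupper(seq)
  if (is.null(qual)) qual <- rep(list(integer(0)), length(seq))
  stopifnot(length(read_id) == length(seq), length(qual) == length(seq))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid nucleotide characters in read(s): ",
         paste(head(read_id[bad], 5), collapse = ", "))
  }
  ok <- vapply(seq_along(seq), function(i) {
    length(qual[[i]]) == 0L || length(qual[[i]]) == nchar(seq[i])
  }, logical(1))
  if (!all(ok)) {
    stop("quality length differs from sequence length for read(s): ",
         paste(head(read_id[!ok], 5), collapse = ", "))
  }
  out <- data.frame(read_id = as.character(read_id), seq = seq,
                    stringsAsFactors = FALSE)
  out$qual <- lapply(qual, as.integer)
  class(out) <- c("sequence_reads", "data.frame")
  out
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a [sequence_reads()] data frame in file order.
#' @details A record whose quality string length differs from its sequence
#'   length, or whose header/separator lines are malformed, raises an error
#'   naming the 1-based record index. An empty file yields zero reads.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) return(sequence_reads(character(0), character(0)))
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seq <- lines[seq(2L, by = 4L, length.out = n)]
  sep <- lines[seq(3L, by = 4L, length.out = n)]
  qstr <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) stop("malformed FASTQ header at record ", bad_hdr[1])
  bad_sep <- which(!startsWith(sep, "+"))
  if (length(bad_sep)) stop("malformed FASTQ separator at record ", bad_sep[1])
  bad_len <- which(nchar(seq) != nchar(qstr))
  if (length(bad_len)) {
    stop("sequence/quality length mismatch at record ", bad_len[1])
  }
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  qual <- lapply(qstr, function(q) utf8ToInt(q) - 33L)
  sequence_reads(ids, seq, qual)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads a [sequence_reads()] data frame with qualities present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qlen <- lengths(reads$qual)
  if (any(qlen != nchar(reads$seq))) {
    stop("cannot write FASTQ: reads without full-length qualities")
  }
  qstr <- vapply(reads$qual, function(q) intToUtf8(q + 33L), character(1))
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- qstr
  writeLines(out, path)
  invisible(path)
}

#' Read a FASTA file as reads without qualities
#' @param path path to an uncompressed FASTA file.
#' @return a [sequence_reads()] data frame (empty quality vectors).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  sequence_reads(names(x), as.character(x))
}

#' Write reads as FASTA
#' @param reads a [sequence_reads()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Quality-filter policy
#'
#' Thresholds applied per read by [quality_filter()]. Defaults follow
#' conventional amplicon QC: mean Phred at least 20, no ambiguous bases,
#' and a length window from the shortest anchor-compatible amplicon
#' (both anchors plus a 1-residue loop, 72 nt) up to twice a generous
#' amplicon length. The downstream anchor match supplies the real
#' specificity; these thresholds only remove junk.
#'
#' @param min_mean_quality minimum mean Phred score (units: Phred).
#' @param max_fraction_N maximum tolerated fraction of `N` bases, in `[0,1]`.
#' @param min_length,max_length inclusive read-length window in bases.
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_mean_quality = 20, max_fraction_N = 0,
                          min_length = 72, max_length = 600) {
  stopifnot(min_mean_quality >= 0, max_fraction_N >= 0, max_fraction_N <= 1,
            min_length >= 0, min_length <= max_length)
  structure(list(min_mean_quality = min_mean_quality,
                 max_fraction_N = max_fraction_N,
                 min_length = min_length, max_length = max_length),
            class = "filter_policy")
}

#' Filter reads by quality, ambiguity, and length
#'
#' A read is kept iff its mean Phred quality is at least
#' `min_mean_quality`, its fraction of `N` bases is at most
#' `max_fraction_N`, and its length lies within
#' `[min_length, max_length]`. Reads without qualities (FASTA input) pass
#' the quality criterion vacuously. Filtering never errors and the report
#' partitions the input: counts over all rejection reasons plus `passed`
#' sum to the number of input reads. Each rejected read is counted once,
#' under the first failing criterion in the order low_quality,
#' too_many_N, too_short, too_long.
#'
#' @param reads a [sequence_reads()] data frame.
#' @param policy a [filter_policy()].
#' @return a list with `kept` (the surviving reads, input order preserved)
#'   and `report` (data frame `reason`/`count`).
#' @export
quality_filter <- function(reads, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  n <- nrow(reads)
  len <- nchar(reads$seq)
  mean_q <- vapply(reads$qual, function(q) {
    if (length(q) == 0L) Inf else mean(q)
  }, numeric(1))
  frac_n <- ifelse(len == 0L, 0,
                   nchar(gsub("[^N]", "", reads$seq)) / pmax(len, 1L))
  reason <- rep("passed", n)
  reason[len > policy$max_length] <- "too_long"
  reason[len < policy$min_length] <- "too_short"
  reason[frac_n > policy$max_fraction_N] <- "too_many_N"
  reason[mean_q < policy$min_mean_quality] <- "low_quality"
  levels <- c("low_quality", "too_many_N", "too_short", "too_long", "passed")
  report <- data.frame(reason = levels,
                       count = as.integer(table(factor(reason, levels))),
                       stringsAsFactors = FALSE)
  kept <- reads[reason == "passed", , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- class(reads)
  list(kept = kept, report = report)
}

#' Write a rejection report as TSV
#' @param report the `report` element of [quality_filter()] output.
#' @param path output path; columns `reason` and `count`.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
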