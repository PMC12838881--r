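## cdrh3: six-frame translation, anchor-based loop localization, clone
## aggregation. The CDR-H3 loop is the substring strictly between the
## conserved framework anchors DTAVYYCAR and FDYWGQGTLVTVSS.

#' Anchor specification for CDR-H3 localization
#'
#' The loop is delimited by two framework motifs that are invariant across
#' the library: nine residues upstream (`DTAVYYCAR`) and fourteen residues
#' downstream (`FDYWGQGTLVTVSS`). Matching is Hamming-distance based
#' (no indels), leftmost match wins. Defaults tolerate no mismatch on the
#' short upstream motif and one on the long downstream motif, which
#' absorbs a single sequencing error without admitting spurious anchors.
#'
#' @param upstream,downstream amino-acid motifs (uppercase).
#' @param max_mismatches integer vector of length 2 (upstream, downstream):
#'   maximum Hamming mismatches tolerated per anchor.
#' @param min_loop_len,max_loop_len inclusive bounds on loop length in
#'   residues. The default ceiling of 25 comfortably exceeds any loop
#'   produced by the library design.
#' @return an `anchor_spec` list.
#' @export
anchor_spec <- function(upstream = UPSTREAM_ANCHOR,
                        downstream = DOWNSTREAM_ANCHOR,
                        max_mismatches = c(0L, 1L),
                        min_loop_len = 1L, max_loop_len = 25L) {
  stopifnot(nchar(upstream) > 0, nchar(downstream) > 0,
            !grepl("[^A-Z]", upstream), !grepl("[^A-Z]", downstream),
            length(max_mismatches) == 2L,
            all(max_mismatches >= 0L),
            max_mismatches[1] < nchar(upstream),
            max_mismatches[2] < nchar(downstream),
            min_loop_len >= 1L, min_loop_len <= max_loop_len)
  structure(list(upstream = upstream, downstream = downstream,
                 max_mismatches = as.integer(max_mismatches),
                 min_loop_len = as.integer(min_loop_len),
                 max_loop_len = as.integer(max_loop_len)),
            class = "anchor_spec")
}

FRAME_NAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

## Batch six-frame translation: one Biostrings call per frame for the
## whole read set (per-call S4 overhead dominates otherwise). Returns an
## n x 6 character matrix with columns in FRAME_NAMES order.
six_frame_matrix <- function(seqs) {
  n <- length(seqs)
  fwd <- Biostrings::DNAStringSet(toupper(seqs))
  rev <- Biostrings::reverseComplement(fwd)
  frame_of <- function(set, off) {
    w <- Biostrings::width(set) - off
    w <- pmax(w - (w %% 3L), 0L)
    s <- Biostrings::subseq(set, start = off + 1L, width = w)
    as.character(Biostrings::translate(s, if.fuzzy.codon = "X"))
  }
  out <- matrix("", nrow = n, ncol = 6L,
                dimnames = list(NULL, FRAME_NAMES))
  for (o in 0:2) {
    out[, o + 1L] <- frame_of(fwd, o)
    out[, o + 4L] <- frame_of(rev, o)
  }
  out
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Standard genetic code; trailing partial codons are dropped; any codon
#' containing `N` translates to `X`; stop codons translate to `*`.
#' Reverse frames translate the reverse complement with offsets 0-2.
#'
#' @param nucleotides a DNA string over `A/C/G/T/N`.
#' @return named character vector of six amino-acid sequences, names
#'   `+1`, `+2`, `+3`, `-1`, `-2`, `-3`.
#' @export
translate_six_frames <- function(nucleotides) {
  six_frame_matrix(nucleotides)[1L, ]
}

## Leftmost Hamming match of `motif` in `protein` with at most `mm`
## mismatches; NA if none. Thin wrapper over Biostrings::matchPattern.
leftmost_match <- function(motif, protein, mm, from = 1L) {
  if (nchar(protein) - from + 1L < nchar(motif)) return(NA_integer_)
  hit <- Biostrings::matchPattern(motif,
                                  Biostrings::AAString(protein),
                                  max.mismatch = mm, with.indels = FALSE)
  st <- Biostrings::start(hit)
  st <- st[st >= from]
  if (length(st) == 0L) NA_integer_ else min(st)
}

#' Locate the CDR-H3 loop in a protein sequence
#'
#' Finds the leftmost occurrence of the upstream anchor (within its
#' mismatch budget), then the leftmost occurrence of the downstream anchor
#' starting after it. The loop is the substring strictly between the two
#' anchors; it must contain no stop symbol and satisfy the length bounds.
#'
#' @param protein uppercase amino-acid sequence (may contain `*`/`X`).
#' @param anchors an [anchor_spec()].
#' @return a list with `status` (one of `extracted`, `no_frame`,
#'   `loop_out_of_bounds`, `internal_stop`) and `loop` (the loop sequence
#'   when extracted, otherwise `NA`).
#' @examples
#' v <- synab_variants()
#' locate_cdrh3(v$heavy_chain[v$variant == "A7"])$loop  # "KKEYYSR"
#' @export
locate_cdrh3 <- function(protein, anchors = anchor_spec()) {
  fail <- function(status) list(status = status, loop = NA_character_)
  up <- leftmost_match(anchors$upstream, protein, anchors$max_mismatches[1])
  if (is.na(up)) return(fail("no_frame"))
  up_end <- up + nchar(anchors$upstream) - 1L
  down <- leftmost_match(anchors$downstream, protein,
                         anchors$max_mismatches[2], from = up_end + 1L)
  if (is.na(down)) return(fail("no_frame"))
  loop <- substr(protein, up_end + 1L, down - 1L)
  if (grepl("*", loop, fixed = TRUE)) return(fail("internal_stop"))
  if (nchar(loop) < anchors$min_loop_len ||
      nchar(loop) > anchors$max_loop_len) {
    return(fail("loop_out_of_bounds"))
  }
  list(status = "extracted", loop = loop)
}

## Status priority when no frame yields a valid loop: a frame that found
## both anchors but failed loop validation is more informative than one
## that found no anchors at all.
STATUS_PRIORITY <- c("internal_stop", "loop_out_of_bounds", "no_frame")

#' Extract the CDR-H3 loop from a sequencing read
#'
#' Translates the read in all six frames and applies [locate_cdrh3()] to
#' each. The read is `extracted` iff exactly one frame yields a valid
#' loop; if several frames qualify the read is discarded as
#' `ambiguous_frame` rather than guessed, since silently wrong-frame loops
#' would contaminate enrichment statistics.
#'
#' @param read a single-row [sequence_reads()] data frame, or a list with
#'   elements `read_id` and `seq`.
#' @param anchors an [anchor_spec()].
#' @return a list with `status` (`extracted`, `no_frame`,
#'   `ambiguous_frame`, `loop_out_of_bounds`, `internal_stop`), `frame`
#'   (one of `+1..+3`, `-1..-3` when extracted) and `loop`.
#' @export
extract_from_read <- function(read, anchors = anchor_spec()) {
  seqs <- if (is.character(read)) read else read$seq
  out <- extract_from_reads(
    sequence_reads("r", seqs[1]), anchors)$log
  list(status = out$status[1], frame = out$frame[1], loop = out$loop[1])
}

#' Extract CDR-H3 loops from many reads at once
#'
#' Vectorized counterpart of [extract_from_read()]: one batch of six-frame
#' translations and two anchor scans (Biostrings `vmatchPattern`) for the
#' whole read set.
#'
#' @param reads a [sequence_reads()] data frame.
#' @param anchors an [anchor_spec()].
#' @return a list with `log`, a data frame of `read_id`, `status`,
#'   `frame`, `loop` (one row per read, input order).
#' @export
extract_from_reads <- function(reads, anchors = anchor_spec()) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(log = data.frame(read_id = character(0),
                                 status = character(0),
                                 frame = character(0),
                                 loop = character(0),
                                 stringsAsFactors = FALSE)))
  }
  prots <- six_frame_matrix(reads$seq)
  flat <- as.vector(prots)  # column-major: frame varies slowest
  aaset <- Biostrings::AAStringSet(flat)
  up_hits <- Biostrings::startIndex(Biostrings::vmatchPattern(
    anchors$upstream, aaset,
    max.mismatch = anchors$max_mismatches[1], with.indels = FALSE))
  down_hits <- Biostrings::startIndex(Biostrings::vmatchPattern(
    anchors$downstream, aaset,
    max.mismatch = anchors$max_mismatches[2], with.indels = FALSE))
  up_len <- nchar(anchors$upstream)
  status <- character(n); frame <- rep(NA_character_, n)
  loop <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    frame_status <- character(6L); frame_loop <- rep(NA_character_, 6L)
    for (f in 1:6) {
      k <- (f - 1L) * n + i
      ups <- up_hits[[k]]
      if (is.null(ups) || length(ups) == 0L) {
        frame_status[f] <- "no_frame"; next
      }
      up_end <- min(ups) + up_len - 1L
      downs <- down_hits[[k]]
      downs <- downs[downs > up_end]
      if (length(downs) == 0L) { frame_status[f] <- "no_frame"; next }
      lp <- substr(flat[k], up_end + 1L, min(downs) - 1L)
      if (grepl("*", lp, fixed = TRUE)) {
        frame_status[f] <- "internal_stop"
      } else if (nchar(lp) < anchors$min_loop_len ||
                 nchar(lp) > anchors$max_loop_len) {
        frame_status[f] <- "loop_out_of_bounds"
      } else {
        frame_status[f] <- "extracted"; frame_loop[f] <- lp
      }
    }
    hit <- which(frame_status == "extracted")
    if (length(hit) == 1L) {
      status[i] <- "extracted"; frame[i] <- FRAME_NAMES[hit]
      loop[i] <- frame_loop[hit]
    } else if (length(hit) > 1L) {
      status[i] <- "ambiguous_frame"
    } else {
      status[i] <- STATUS_PRIORITY[min(match(frame_status, STATUS_PRIORITY))]
    }
  }
  list(log = data.frame(read_id = reads$read_id, status = status,
                        frame = frame, loop = loop,
                        stringsAsFactors = FALSE))
}

#' Aggregate extraction outcomes into a clone table
#'
#' Counts identical loops among extracted outcomes. The result is sorted
#' by descending count with ties broken lexicographically by loop, so the
#' ordering is total and deterministic.
#'
#' @param outcomes the `log` data frame from [extract_from_reads()], or
#'   any data frame with `status` and `loop` columns.
#' @param library library label, one of `positive`, `negative`, `naive`.
#' @return a `clone_table` data frame with columns `loop`, `count`,
#'   `library`; counts sum to the number of extracted outcomes.
#' @export
aggregate_clones <- function(outcomes,
                             library = c("positive", "negative", "naive")) {
  library <- match.arg(library)
  loops <- outcomes$loop[outcomes$status == "extracted"]
  if (length(loops) == 0L) {
    out <- data.frame(loop = character(0), count = integer(0),
                      library = character(0), stringsAsFactors = FALSE)
  } else {
    tab <- table(loops)
    out <- data.frame(loop = names(tab), count = as.integer(tab),
                      library = library, stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$loop), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Build a clone table directly
#' @param loop character vector of loop sequences.
#' @param count integer vector of supporting read counts.
#' @param library library label.
#' @return a `clone_table` data frame (sorted as in [aggregate_clones()]).
#' @export
clone_table <- function(loop, count,
                        library = c("positive", "negative", "naive")) {
  library <- match.arg(library)
  stopifnot(length(loop) == length(count), all(count >= 1))
  out <- data.frame(loop = as.character(loop), count = as.integer(count),
                    library = rep(library, length(loop)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$loop), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("clone_table", "data.frame")
  out
}

#' Write / read clone tables as TSV
#' @param clones a `clone_table` data frame.
#' @param path file path; columns `loop`, `count`, `library`.
#' @return `path` (writer) or a `clone_table` (reader).
#' @export
write_clone_table <- function(clones, path) {
  write.table(clones, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clone_table
#' @export
read_clone_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  clone_table(x$loop, x$count, x$library[1])
}

#' Published scFv variant sequences
#'
#' The Sanger-sequenced heavy chains of the six isolated SynAb variants
#' (A2, A4, A6, A7, A9, A10), with their CDR-H3 loops, shipped as a
#' plain-text table. These serve as ground-truth worked examples for the
#' anchor-based extractor.
#'
#' @return data frame with columns `variant`, `heavy_chain`, `cdrh3`.
#' @export
synab_variants <- function() {
  read.delim(system.file("extdata", "synab_variants.tsv",
                         package = "cdrh3kit"),
             stringsAsFactors = FALSE)
}
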