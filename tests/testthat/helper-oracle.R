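# Brute-force extraction oracle, independent of the package's Biostrings
# path: seqinr translation, hand-rolled reverse complement, sliding-window
# Hamming anchor scan. Slow but transparent; used to cross-check
# extract_from_read(s) on synthetic reads.

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
        collapse = "")
}

oracle_translate <- function(seq) {
  # forward frame +1 only; seqinr handles the genetic code
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  codons <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  aa <- vapply(codons, function(cd) {
    if (grepl("N", cd)) "X"
    else seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1))
  paste(aa, collapse = "")
}

oracle_six_frames <- function(seq) {
  rc <- oracle_revcomp(seq)
  c("+1" = oracle_translate(seq),
    "+2" = oracle_translate(substring(seq, 2)),
    "+3" = oracle_translate(substring(seq, 3)),
    "-1" = oracle_translate(rc),
    "-2" = oracle_translate(substring(rc, 2)),
    "-3" = oracle_translate(substring(rc, 3)))
}

oracle_find_motif <- function(protein, motif, mm, from = 1) {
  np <- nchar(protein); nm <- nchar(motif)
  m_chars <- strsplit(motif, "")[[1]]
  if (np - from + 1 < nm) return(NA_integer_)
  for (i in from:(np - nm + 1)) {
    w <- strsplit(substr(protein, i, i + nm - 1), "")[[1]]
    if (sum(w != m_chars) <= mm) return(i)
  }
  NA_integer_
}

oracle_locate <- function(protein, anchors) {
  up <- oracle_find_motif(protein, anchors$upstream,
                          anchors$max_mismatches[1])
  if (is.na(up)) return(list(status = "no_frame", loop = NA_character_))
  up_end <- up + nchar(anchors$upstream) - 1
  down <- oracle_find_motif(protein, anchors$downstream,
                            anchors$max_mismatches[2], from = up_end + 1)
  if (is.na(down)) return(list(status = "no_frame", loop = NA_character_))
  loop <- substr(protein, up_end + 1, down - 1)
  if (grepl("*", loop, fixed = TRUE)) {
    return(list(status = "internal_stop", loop = NA_character_))
  }
  if (nchar(loop) < anchors$min_loop_len ||
      nchar(loop) > anchors$max_loop_len) {
    return(list(status = "loop_out_of_bounds", loop = NA_character_))
  }
  list(status = "extracted", loop = loop)
}

oracle_extract <- function(seq, anchors) {
  frames <- oracle_six_frames(seq)
  res <- lapply(frames, oracle_locate, anchors = anchors)
  st <- vapply(res, `[[`, character(1), "status")
  hit <- which(st == "extracted")
  if (length(hit) == 1) {
    list(status = "extracted", frame = names(frames)[hit],
         loop = res[[hit]]$loop)
  } else if (length(hit) > 1) {
    list(status = "ambiguous_frame", frame = NA_character_,
         loop = NA_character_)
  } else {
    pri <- c("internal_stop", "loop_out_of_bounds", "no_frame")
    list(status = pri[min(match(st, pri))], frame = NA_character_,
         loop = NA_character_)
  }
}
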