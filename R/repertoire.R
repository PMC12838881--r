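## repertoire_stats: loop-length distributions, position-specific
## amino-acid frequency matrices F(AA, p), enrichment ratios
## E(AA, p) = F_pos(AA, p) / F_neg(AA, p), and residue-class summaries.

#' Residue-class scheme for enrichment summaries
#'
#' Partition of the 20 amino acids into the classes used when summarising
#' enrichment: positively charged (K, R, H), negatively charged (D, E),
#' special/flexibility-modulating (G, S, P), hydrophobic
#' (A, V, L, I, M, F, W, Y, C), and the polar uncharged remainder
#' (N, Q, T).
#'
#' @return named list of character vectors partitioning [AA_ALPHABET].
#' @export
residue_classes <- function() {
  list(positive = c("K", "R", "H"),
       negative = c("D", "E"),
       special = c("G", "S", "P"),
       hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y", "C"),
       polar_uncharged = c("N", "Q", "T"))
}

clone_weights <- function(clones, weighting) {
  switch(weighting,
         read_weighted = clones$count,
         unique_clone = rep(1, nrow(clones)))
}

#' Loop-length distribution of a clone table
#'
#' @param clones a `clone_table` data frame.
#' @param weighting `read_weighted` (each read counts; default, since
#'   downstream sample weighting is also count-based) or `unique_clone`
#'   (each distinct loop counts once).
#' @return a `length_distribution` list: `probabilities` (named numeric,
#'   names are loop lengths, sums to 1), `mode` (argmax length; ties break
#'   toward the shorter length), `weighting`.
#' @export
length_distribution <- function(clones,
                                weighting = c("read_weighted",
                                              "unique_clone")) {
  weighting <- match.arg(weighting)
  if (nrow(clones) == 0L) stop("empty clone table")
  w <- clone_weights(clones, weighting)
  len <- nchar(clones$loop)
  tot <- tapply(w, len, sum)
  p <- as.numeric(tot) / sum(w)
  names(p) <- names(tot)
  lens <- as.integer(names(p))
  ord <- order(lens)
  p <- p[ord]; lens <- lens[ord]
  mode <- lens[which.max(p)]  # which.max takes the first (shortest) tie
  structure(list(probabilities = p, mode = mode, weighting = weighting),
            class = "length_distribution")
}

#' Position-specific amino-acid frequency matrix
#'
#' For clones of one fixed loop length, computes
#' `F(AA, p) = (weighted count of AA at position p + pseudocount) /
#' (weighted total at p + 20 * pseudocount)`. With `pseudocount = 0` this
#' is the plain positional frequency. Every column sums to 1.
#'
#' @param clones a `clone_table` data frame.
#' @param loop_length loop length (residues) to restrict to.
#' @param weighting as in [length_distribution()].
#' @param pseudocount non-negative smoothing constant added per cell.
#' @return a 20 x `loop_length` `freq_matrix` (rows: [AA_ALPHABET];
#'   columns: positions 1..L numbered from the residue after the upstream
#'   anchor), with attributes `loop_length`, `weighting`, `pseudocount`,
#'   `position_totals`, `library`.
#' @export
positional_frequencies <- function(clones, loop_length,
                                   weighting = c("read_weighted",
                                                 "unique_clone"),
                                   pseudocount = 0) {
  weighting <- match.arg(weighting)
  stopifnot(pseudocount >= 0)
  sel <- clones[nchar(clones$loop) == loop_length, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no clones of loop length ", loop_length)
  w <- clone_weights(sel, weighting)
  counts <- matrix(0, nrow = 20L, ncol = loop_length,
                   dimnames = list(AA_ALPHABET, seq_len(loop_length)))
  chars <- strsplit(sel$loop, "")
  for (i in seq_along(chars)) {
    idx <- match(chars[[i]], AA_ALPHABET)
    for (p in seq_len(loop_length)) {
      if (!is.na(idx[p])) counts[idx[p], p] <- counts[idx[p], p] + w[i]
    }
  }
  totals <- colSums(counts)
  f <- sweep(counts + pseudocount, 2, totals + 20 * pseudocount, "/")
  structure(f, class = c("freq_matrix", class(f)),
            loop_length = loop_length, weighting = weighting,
            pseudocount = pseudocount, position_totals = totals,
            library = sel$library[1])
}

#' Pooled amino-acid frequencies over all positions and lengths
#'
#' Collapses a clone table to a single frequency vector: the weighted
#' count of each amino acid over every loop position of every clone,
#' divided by the weighted total number of residues. This is the
#' whole-library composition used for all-lengths enrichment.
#'
#' @inheritParams positional_frequencies
#' @return named numeric vector over [AA_ALPHABET] summing to 1, with
#'   attributes `weighting`, `pseudocount`, `library`.
#' @export
pooled_frequencies <- function(clones,
                               weighting = c("read_weighted",
                                             "unique_clone"),
                               pseudocount = 0) {
  weighting <- match.arg(weighting)
  if (nrow(clones) == 0L) stop("empty clone table")
  w <- clone_weights(clones, weighting)
  chars <- strsplit(clones$loop, "")
  counts <- setNames(numeric(20L), AA_ALPHABET)
  for (i in seq_along(chars)) {
    idx <- match(chars[[i]], AA_ALPHABET)
    idx <- idx[!is.na(idx)]
    for (j in idx) counts[j] <- counts[j] + w[i]
  }
  f <- (counts + pseudocount) / (sum(counts) + 20 * pseudocount)
  structure(f, weighting = weighting, pseudocount = pseudocount,
            library = clones$library[1])
}

#' Enrichment ratios between two libraries
#'
#' Cell-wise ratio `E = F_num / F_den`. Cells where the denominator
#' frequency is 0 are flagged undefined (`NA`) rather than infinite.
#' In `pooled` mode positional matrices are first collapsed to one
#' frequency vector per library (positions averaged, weighted by their
#' construction totals) and then divided. Frequency vectors from
#' [pooled_frequencies()] may be supplied directly.
#'
#' @param numerator,denominator two `freq_matrix` objects of the same
#'   loop length, or two pooled frequency vectors.
#' @param mode `positional` (cell-wise, matrices only) or `pooled`.
#' @return an `enrichment_table`: matrix (positional) or named vector
#'   (pooled) of ratios with `NA` marking undefined cells; attributes
#'   `mode`, `numerator_library`, `denominator_library`.
#' @export
enrichment <- function(numerator, denominator,
                       mode = c("positional", "pooled")) {
  mode <- match.arg(mode)
  collapse <- function(f) {
    if (is.matrix(f)) {
      wts <- attr(f, "position_totals")
      if (is.null(wts) || sum(wts) == 0) wts <- rep(1, ncol(f))
      as.numeric(f %*% (wts / sum(wts))) |> setNames(rownames(f))
    } else f
  }
  if (mode == "positional") {
    if (!is.matrix(numerator) || !is.matrix(denominator) ||
        !identical(dim(numerator), dim(denominator))) {
      stop("positional enrichment needs two frequency matrices of ",
           "identical shape")
    }
    e <- unclass(numerator) / unclass(denominator)
    e[unclass(denominator) == 0] <- NA_real_
  } else {
    fn <- collapse(numerator); fd <- collapse(denominator)
    if (!identical(names(fn), names(fd))) stop("alphabet mismatch")
    e <- fn / fd
    e[fd == 0] <- NA_real_
  }
  structure(e, class = c("enrichment_table", class(e)), mode = mode,
            numerator_library = attr(numerator, "library"),
            denominator_library = attr(denominator, "library"))
}

#' Per-class mean enrichment by position
#'
#' Arithmetic mean of defined enrichment cells within each residue class
#' at each loop position; undefined (`NA`) cells are excluded from the
#' mean and counted.
#'
#' @param table a positional `enrichment_table`.
#' @param scheme a residue-class partition, see [residue_classes()].
#' @return data frame with `class`, `position`, `mean_enrichment`
#'   (`NaN` when every cell of the class is undefined at that position),
#'   `n_undefined`.
#' @export
class_summary <- function(table, scheme = residue_classes()) {
  if (!is.matrix(table)) stop("class_summary needs a positional table")
  out <- do.call(rbind, lapply(names(scheme), function(cl) {
    sub <- table[scheme[[cl]], , drop = FALSE]
    data.frame(class = cl, position = seq_len(ncol(table)),
               mean_enrichment = apply(sub, 2, mean, na.rm = TRUE),
               n_undefined = apply(sub, 2, function(x) sum(is.na(x))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write repertoire statistics as TSV
#'
#' Matrices are written with amino acids as rows (fixed alphabetical
#' order) and positions as columns; length distributions as
#' `length<TAB>fraction`.
#'
#' @param x a `freq_matrix`, `enrichment_table`, or `length_distribution`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(x, path) {
  if (inherits(x, "length_distribution")) {
    write.table(data.frame(length = names(x$probabilities),
                           fraction = as.numeric(x$probabilities)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (is.matrix(x)) {
    df <- data.frame(AA = rownames(x), unclass(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(data.frame(AA = names(x), value = as.numeric(x)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
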