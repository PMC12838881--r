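## synthetic_data: generators for every input the pipeline consumes, with
## planted ground truth recorded in a manifest. The defaults encode the
## study conditions the analysis targets: a negative (non-binder) library
## whose loop lengths peak at 6 residues with a uniform residue
## composition, and a positive (binder) library peaking at 7 residues
## whose composition plants a 3x lysine/arginine/histidine enrichment and
## a 0.5x aspartate/glutamate depletion relative to the negative library.

## Default length profiles (fractions over loop lengths 5..12). Only the
## modes (6 negative, 7 positive) are dictated by the study; the
## surrounding shape is a realistic unimodal profile: negative binders
## decay from their short-loop peak, positive binders are broader.
NEGATIVE_LENGTH_PMF <- c(`5` = 0.14, `6` = 0.30, `7` = 0.20, `8` = 0.13,
                         `9` = 0.09, `10` = 0.06, `11` = 0.05, `12` = 0.03)
POSITIVE_LENGTH_PMF <- c(`5` = 0.05, `6` = 0.16, `7` = 0.28, `8` = 0.17,
                         `9` = 0.13, `10` = 0.09, `11` = 0.08, `12` = 0.04)

## Class multipliers applied to a uniform base composition. The factor
## 7/12 on the 12 unconstrained residues makes the multipliers average to
## exactly 1 over the 20 amino acids, so normalization is a no-op and the
## REALIZED enrichment versus a uniform library equals the multiplier:
## K/R/H exactly 3, D/E exactly 0.5, G/S/P exactly 1, hydrophobic and
## polar residues mildly depleted (7/12), mirroring the qualitative
## depletion of hydrophobics seen in sorted binder repertoires.
POSITIVE_CLASS_BIAS <- list(positive = 3, negative = 0.5, special = 1,
                            hydrophobic = 7 / 12, polar_uncharged = 7 / 12)

class_bias_to_composition <- function(class_bias,
                                      scheme = residue_classes()) {
  mult <- setNames(rep(1, 20L), AA_ALPHABET)
  for (cl in names(class_bias)) {
    if (!cl %in% names(scheme)) stop("unknown residue class: ", cl)
    stopifnot(class_bias[[cl]] > 0)
    mult[scheme[[cl]]] <- class_bias[[cl]]
  }
  mult / sum(mult)
}

#' Library specification for loop sampling
#'
#' @param n_reads number of loops (reads) to draw.
#' @param length_pmf named numeric vector, loop length -> probability,
#'   summing to 1.
#' @param class_bias named list of multipliers (by residue class, see
#'   [residue_classes()]) applied to a uniform base composition and
#'   renormalized; `NULL` means uniform.
#' @param label library label.
#' @param seed integer seed; the draw is a pure function of the spec.
#' @return a `library_spec` list.
#' @export
library_spec <- function(n_reads, length_pmf, class_bias = NULL,
                         label = c("positive", "negative", "naive"),
                         seed = 1L) {
  label <- match.arg(label)
  stopifnot(n_reads >= 1, abs(sum(length_pmf) - 1) < 1e-9,
            all(length_pmf >= 0), !is.null(names(length_pmf)))
  comp <- if (is.null(class_bias)) {
    setNames(rep(1 / 20, 20L), AA_ALPHABET)
  } else {
    class_bias_to_composition(class_bias)
  }
  structure(list(n_reads = as.integer(n_reads), length_pmf = length_pmf,
                 composition = comp, class_bias = class_bias,
                 label = label, seed = as.integer(seed)),
            class = "library_spec")
}

#' Default positive / negative library specifications
#'
#' The positive (binder) library peaks at loop length 7 and plants the
#' K/R/H-enriched, D/E-depleted composition; the negative (non-binder)
#' library peaks at length 6 with a uniform composition. Default sizes
#' echo the scale of the sorted datasets (7789 positive, 9907 negative
#' unique fragments).
#'
#' @param n_reads library size in reads.
#' @param seed integer seed.
#' @return a [library_spec()].
#' @export
positive_library_spec <- function(n_reads = 7789, seed = 1L) {
  library_spec(n_reads, POSITIVE_LENGTH_PMF, POSITIVE_CLASS_BIAS,
               label = "positive", seed = seed)
}

#' @rdname positive_library_spec
#' @export
negative_library_spec <- function(n_reads = 9907, seed = 2L) {
  library_spec(n_reads, NEGATIVE_LENGTH_PMF, NULL,
               label = "negative", seed = seed)
}

#' Sample CDR-H3 loops from a library specification
#'
#' Loop lengths are i.i.d. from `length_pmf`; residues are i.i.d. per
#' position from the (biased) composition. Deterministic under the spec's
#' seed; the caller's RNG state is untouched.
#'
#' @param spec a [library_spec()].
#' @return list with `clones` (a `clone_table`) and `manifest`, a
#'   `truth_manifest` recording the planted length pmf, mode, per-residue
#'   composition, and enrichment of that composition relative to uniform
#'   - everything needed to predict downstream statistics without
#'   rerunning the generator.
#' @export
sample_loops <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  loops <- withr::with_seed(spec$seed, {
    len_values <- as.integer(names(spec$length_pmf))
    lens <- len_values[sample.int(length(len_values), spec$n_reads,
                                  replace = TRUE,
                                  prob = spec$length_pmf)]
    res <- sample(AA_ALPHABET, sum(lens), replace = TRUE,
                  prob = spec$composition)
    vapply(split(res, rep(seq_along(lens), lens)),
           paste, character(1), collapse = "")
  })
  tab <- table(loops)
  clones <- clone_table(names(tab), as.integer(tab), spec$label)
  manifest <- structure(list(
    kind = "library",
    label = spec$label,
    n_reads = spec$n_reads,
    length_pmf = spec$length_pmf,
    mode_length = as.integer(names(spec$length_pmf))[
      which.max(spec$length_pmf)],
    composition = spec$composition,
    enrichment_vs_uniform = spec$composition / (1 / 20),
    seed = spec$seed), class = "truth_manifest")
  list(clones = clones, manifest = manifest)
}

#' Read model for the amplicon simulator
#'
#' @param per_base_error substitution error probability per base.
#' @param quality_mean,quality_sd Phred quality model (Gaussian, rounded,
#'   clamped to `[2, 41]`); defaults emulate a modern Illumina run.
#' @param fraction_junk_reads fraction of additional anchor-free random
#'   reads appended to the output.
#' @return a `read_model` list.
#' @export
read_model <- function(per_base_error = 0.001, quality_mean = 35,
                       quality_sd = 3, fraction_junk_reads = 0.01) {
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            fraction_junk_reads >= 0, fraction_junk_reads <= 1,
            quality_mean >= 0, quality_sd >= 0)
  structure(list(per_base_error = per_base_error,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 fraction_junk_reads = fraction_junk_reads),
            class = "read_model")
}

## Synonymous codons of the standard genetic code, by amino acid.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

## Vectorized uniform synonymous-codon choice for many proteins at once.
## Codons are laid out in a (symbol x 6) matrix so one indexing operation
## picks a random synonymous codon for every residue of every protein.
reverse_translate_many <- function(proteins) {
  codons <- codon_table()
  syms <- names(codons)
  ncod <- lengths(codons)
  M <- matrix("", nrow = length(syms), ncol = max(ncod),
              dimnames = list(syms, NULL))
  for (i in seq_along(codons)) M[i, seq_len(ncod[i])] <- codons[[i]]
  chars <- strsplit(proteins, "")
  flat <- unlist(chars, use.names = FALSE)
  row <- match(flat, syms)
  if (anyNA(row)) stop("cannot reverse-translate symbol(s): ",
                       paste(unique(flat[is.na(row)]), collapse = ", "))
  pick <- 1L + floor(runif(length(flat)) * ncod[row])
  picked <- M[cbind(row, pick)]
  grp <- rep(seq_along(chars), lengths(chars))
  vapply(split(picked, grp), paste, character(1), collapse = "")
}

#' Reverse-translate a protein with uniform synonymous codons
#' @param protein amino-acid sequence over the 20-letter alphabet.
#' @return a DNA string encoding `protein` in frame +1.
#' @export
reverse_translate <- function(protein) {
  unname(reverse_translate_many(protein))
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
        collapse = "")
}

#' Embed clones in the heavy-chain framework and simulate sequencing
#'
#' Each loop is reverse-translated with uniform synonymous codons and
#' embedded as framework + upstream anchor + loop + downstream anchor +
#' framework (SynAb heavy-chain context). Each read is placed on the
#' reverse strand with probability 0.5 and offset by 0-2 leading random
#' bases so that all six reading frames occur. Substitution errors and
#' Gaussian-rounded qualities are then applied, and a fraction of
#' anchor-free random reads is appended.
#'
#' @param clones a `clone_table`.
#' @param model a [read_model()].
#' @param seed integer seed.
#' @return a [sequence_reads()] data frame (one read per clone count,
#'   plus junk reads).
#' @export
embed_and_sequence <- function(clones, model = read_model(), seed = 1L) {
  loops <- rep(clones$loop, clones$count)
  n <- length(loops)
  withr::with_seed(seed, {
    prots <- paste0(FRAMEWORK_5P_CONTEXT, UPSTREAM_ANCHOR, loops,
                    DOWNSTREAM_ANCHOR, FRAMEWORK_3P_CONTEXT)
    dna <- reverse_translate_many(prots)
    offsets <- sample(0:2, n, replace = TRUE)
    lead <- vapply(offsets, random_dna, character(1))
    lead[offsets == 0L] <- ""
    dna <- paste0(lead, dna)
    flip <- runif(n) < 0.5
    if (any(flip)) {
      dna[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(dna[flip])))
    }
    n_junk <- rbinom(1L, n, model$fraction_junk_reads)
    junk_len <- round(mean(nchar(dna)))
    dna <- c(dna, vapply(rep(junk_len, n_junk), random_dna, character(1)))
    ids <- c(sprintf("read%06d", seq_len(n)),
             if (n_junk > 0) sprintf("junk%06d", seq_len(n_junk)))
    ## substitution errors: flip each erroneous base to one of the other
    ## three, chosen uniformly, in one vectorized pass
    chars <- strsplit(dna, "")
    flat <- unlist(chars, use.names = FALSE)
    err <- which(runif(length(flat)) < model$per_base_error)
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(flat[err], bases)
      shift <- 1L + floor(runif(length(err)) * 3)  # 1..3 positions away
      flat[err] <- bases[1L + (cur - 1L + shift) %% 4L]
    }
    grp <- rep(seq_along(chars), lengths(chars))
    dna <- vapply(split(flat, grp), paste, character(1), collapse = "")
    qual <- lapply(nchar(dna), function(L) {
      pmin(pmax(as.integer(round(rnorm(L, model$quality_mean,
                                       model$quality_sd))), 2L), 41L)
    })
    sequence_reads(ids, dna, qual)
  })
}

#' Simulate fluorogenic inhibition progress curves
#'
#' Product fluorescence follows a single-exponential approach to the
#' substrate-depletion plateau, `F(t) = F_inf * (1 - exp(-v_I t / F_inf))`,
#' whose initial slope equals the Morrison velocity at each inhibitor
#' concentration. The plateau `F_inf` is set so that the uninhibited
#' reaction converts `conversion` of the substrate over `duration`
#' (default 10% over 120 min, a conventional initial-rate regime).
#' Multiplicative Gaussian noise is applied per point.
#'
#' @param cond an [assay_condition()].
#' @param Ki_pM planted inhibition constant (pM).
#' @param inhibitor_grid_nM inhibitor concentrations (nM); include 0 for
#'   an uninhibited control.
#' @param duration_min,interval_min sampling window and spacing (min).
#' @param noise_sd multiplicative noise standard deviation (fraction).
#' @param conversion fraction of substrate converted by the uninhibited
#'   reaction over `duration_min`.
#' @param seed integer seed.
#' @return list with `curves` (list of [progress_curve()]) and
#'   `manifest` (`truth_manifest` with planted Ki, v0, per-concentration
#'   initial velocities, plateau, seed).
#' @export
simulate_assay <- function(cond, Ki_pM,
                           inhibitor_grid_nM = c(0, 0.01, 0.03, 0.1,
                                                 0.3, 1, 3, 10),
                           duration_min = 120, interval_min = 1,
                           noise_sd = 0, conversion = 0.1, seed = 1L) {
  stopifnot(length(inhibitor_grid_nM) >= 1, duration_min > 0,
            interval_min > 0, interval_min <= duration_min,
            conversion > 0, conversion < 1)
  times <- seq(0, duration_min, by = interval_min)
  v_planted <- morrison_velocity(cond, inhibitor_grid_nM, Ki_pM)
  k0 <- -log(1 - conversion) / duration_min   # uninhibited decay rate
  F_inf <- cond$v0 / k0
  curves <- withr::with_seed(seed, {
    lapply(seq_along(inhibitor_grid_nM), function(i) {
      f <- F_inf * (1 - exp(-v_planted[i] * times / F_inf))
      if (noise_sd > 0) {
        f <- f * (1 + rnorm(length(f), 0, noise_sd))
      }
      progress_curve(inhibitor_grid_nM[i], times, f)
    })
  })
  manifest <- structure(list(
    kind = "assay", Ki_pM = Ki_pM, v0 = cond$v0,
    inhibitor_grid_nM = inhibitor_grid_nM,
    velocities = v_planted, F_inf = F_inf,
    noise_sd = noise_sd, seed = seed), class = "truth_manifest")
  list(curves = curves, manifest = manifest)
}

#' Write a truth manifest as JSON
#' @param manifest a `truth_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
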