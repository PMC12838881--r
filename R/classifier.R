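## classifier: desk-scale binder-classification scaffold. Sequence
## featurization (one-hot / k-mer counts / precomputed embeddings), PCA
## capped at a retained-variance fraction fitted on training rows only,
## and a count-weighted ridge-penalized logistic (linear) classifier
## evaluated by the binder-class F1 on a held-out split.

#' Label clone tables for classification
#'
#' Builds the labelled-sequence table the classifier consumes. Binder
#' weights are the clone count divided by the total positive count (so a
#' frequently observed fragment contributes proportionally more to the
#' training loss); non-binders receive uniform weight `1/n`.
#'
#' @param binders,non_binders `clone_table` data frames.
#' @param anchors an [anchor_spec()]; supplies the constant flanking
#'   motifs stored alongside each loop.
#' @return a `labeled_sequences` data frame with columns `loop`,
#'   `flanked`, `label` (`binder`/`non_binder`), `weight`.
#' @export
labeled_sequences <- function(binders, non_binders,
                              anchors = anchor_spec()) {
  flank <- function(x) paste0(anchors$upstream, x, anchors$downstream)
  pos <- data.frame(loop = binders$loop,
                    flanked = flank(binders$loop),
                    label = "binder",
                    weight = binders$count / sum(binders$count),
                    stringsAsFactors = FALSE)
  neg <- data.frame(loop = non_binders$loop,
                    flanked = flank(non_binders$loop),
                    label = "non_binder",
                    weight = 1 / nrow(non_binders),
                    stringsAsFactors = FALSE)
  out <- rbind(pos, neg)
  class(out) <- c("labeled_sequences", "data.frame")
  out
}

#' Feature configuration
#'
#' @param featurizer `one_hot_padded` (loops right-padded to the maximum
#'   length with a blank channel), `kmer_counts` (overlapping k-mer
#'   counts), or `external_embedding_file` (precomputed vectors, e.g.
#'   protein-language-model embeddings, loaded from a TSV keyed by
#'   sequence).
#' @param k k-mer size for `kmer_counts`.
#' @param include_flanks if `TRUE`, featurize the flanked sequence
#'   (constant anchors prepended/appended) instead of the bare loop.
#' @param variance_retained fraction of variance the PCA must retain,
#'   in `(0, 1]`.
#' @param embedding_file path to the embedding TSV
#'   (`sequence<TAB>v1..vd`, no header requirement beyond column count).
#' @return a `feature_config` list.
#' @export
feature_config <- function(featurizer = c("one_hot_padded", "kmer_counts",
                                          "external_embedding_file"),
                           k = 1L, include_flanks = FALSE,
                           variance_retained = 0.95,
                           embedding_file = NULL) {
  featurizer <- match.arg(featurizer)
  stopifnot(k >= 1L, variance_retained > 0, variance_retained <= 1)
  if (featurizer == "external_embedding_file" && is.null(embedding_file)) {
    stop("external_embedding_file featurizer needs an embedding_file")
  }
  structure(list(featurizer = featurizer, k = as.integer(k),
                 include_flanks = include_flanks,
                 variance_retained = variance_retained,
                 embedding_file = embedding_file),
            class = "feature_config")
}

one_hot_matrix <- function(seqs, pad_to) {
  alpha <- c(AA_ALPHABET, "-")  # 21st blank channel for padding
  n <- length(seqs)
  X <- matrix(0, nrow = n, ncol = pad_to * 21L)
  for (i in seq_len(n)) {
    aa <- strsplit(seqs[i], "")[[1]]
    if (length(aa) > pad_to) stop("sequence longer than pad length")
    aa <- c(aa, rep("-", pad_to - length(aa)))
    idx <- match(aa, alpha)
    if (anyNA(idx)) stop("unknown residue in sequence: ", seqs[i])
    X[i, (seq_len(pad_to) - 1L) * 21L + idx] <- 1
  }
  colnames(X) <- paste0("p", rep(seq_len(pad_to), each = 21L), "_",
                        rep(alpha, pad_to))
  X
}

kmer_matrix <- function(seqs, k) {
  kmers_of <- function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    substring(s, 1:(L - k + 1L), k:L)
  }
  per_seq <- lapply(seqs, kmers_of)
  vocab <- sort(unique(unlist(per_seq)))
  X <- matrix(0, nrow = length(seqs), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(per_seq)) {
    tab <- table(per_seq[[i]])
    X[i, names(tab)] <- as.numeric(tab)
  }
  X
}

read_embedding_file <- function(path, seqs) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  keys <- df[[1]]
  miss <- setdiff(unique(seqs), keys)
  if (length(miss)) {
    stop("embedding file missing sequence(s): ",
         paste(head(miss, 10), collapse = ", "))
  }
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  M[match(seqs, keys), , drop = FALSE]
}

#' Featurize labelled sequences
#'
#' @param seqs a `labeled_sequences` data frame (or character vector of
#'   sequences).
#' @param config a [feature_config()].
#' @return numeric matrix, one row per sequence. Identical sequences map
#'   to identical rows under every featurizer.
#' @export
featurize <- function(seqs, config = feature_config()) {
  s <- if (is.character(seqs)) {
    seqs
  } else if (config$include_flanks) {
    seqs$flanked
  } else {
    seqs$loop
  }
  if (length(s) == 0L) stop("no sequences to featurize")
  switch(config$featurizer,
         one_hot_padded = one_hot_matrix(s, max(nchar(s))),
         kmer_counts = kmer_matrix(s, config$k),
         external_embedding_file =
           read_embedding_file(config$embedding_file, s))
}

#' Variance-capped principal-component reduction
#'
#' Fits a PCA on the training rows only, keeps the smallest number of
#' components whose cumulative explained variance reaches
#' `variance_retained`, and applies the same centering and rotation to
#' the test rows; test rows never influence the fitted transform.
#'
#' @param X_train training feature matrix (more than one row).
#' @param X_test optional test feature matrix with matching columns.
#' @param variance_retained fraction in `(0, 1]`.
#' @return list with `train`, `test` (reduced matrices; `test` is `NULL`
#'   when not supplied), `n_components`, and `explained` (cumulative
#'   variance fractions).
#' @export
reduce_dimensions <- function(X_train, X_test = NULL,
                              variance_retained = 0.95) {
  stopifnot(nrow(X_train) > 1, variance_retained > 0,
            variance_retained <= 1)
  pca <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  vars <- pca$sdev^2
  if (sum(vars) == 0) stop("degenerate feature matrix: zero variance")
  cum <- cumsum(vars) / sum(vars)
  ncomp <- which(cum >= variance_retained - 1e-12)[1]
  keep <- seq_len(ncomp)
  project <- function(M) {
    sweep(M, 2, pca$center, "-") %*% pca$rotation[, keep, drop = FALSE]
  }
  list(train = pca$x[, keep, drop = FALSE],
       test = if (!is.null(X_test)) project(X_test),
       n_components = ncomp, explained = cum)
}

## F1 etc. from confusion counts; binder is the positive class.
confusion_metrics <- function(tp, fp, fn, tn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(f1_binder = f1, precision = precision, recall = recall,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Train and evaluate the binder classifier
#'
#' Stratified seeded 80/20 split by label, featurization, PCA fitted on
#' the training rows, then a ridge-penalized logistic regression (a
#' linear decision rule with a deterministic solver) trained with the
#' per-sample weights. Reports binder-class F1, precision, recall, and
#' confusion counts on the held-out split. Fully reproducible given the
#' seed and invariant to the row order of the input.
#'
#' @param seqs a `labeled_sequences` data frame.
#' @param config a [feature_config()].
#' @param split_fraction training fraction (default 0.8).
#' @param seed integer seed controlling the split.
#' @param lambda ridge penalty of the logistic fit.
#' @return a `classifier_report` list: `f1_binder`, `precision`,
#'   `recall`, `tp`, `fp`, `fn`, `tn`, `n_components`, `n_train`,
#'   `n_test`.
#' @export
train_evaluate <- function(seqs, config = feature_config(),
                           split_fraction = 0.8, seed = 1L,
                           lambda = 1e-3) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  ## canonical row order so shuffled inputs give the same split
  ord <- order(seqs$label, seqs$loop, seqs$weight)
  seqs <- seqs[ord, , drop = FALSE]
  y <- seqs$label
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(split(seq_along(y), y), function(ix) {
      sample(ix, floor(split_fraction * length(ix)))
    }), use.names = FALSE)
  })
  train <- seqs[idx_train, , drop = FALSE]
  test <- seqs[-idx_train, , drop = FALSE]
  if (length(unique(train$label)) < 2L ||
      length(unique(test$label)) < 2L) {
    stop("train/test split does not contain both classes")
  }
  X <- featurize(seqs, config)
  red <- reduce_dimensions(X[idx_train, , drop = FALSE],
                           X[-idx_train, , drop = FALSE],
                           config$variance_retained)
  Xtr <- red$train; Xte <- red$test
  if (ncol(Xtr) < 2L) {  # glmnet requires >= 2 predictors
    Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0)
  }
  fit <- glmnet::glmnet(Xtr, factor(train$label,
                                    levels = c("non_binder", "binder")),
                        family = "binomial", alpha = 0, lambda = lambda,
                        weights = train$weight, standardize = FALSE)
  prob <- predict(fit, Xte, type = "response")[, 1]
  pred <- ifelse(prob >= 0.5, "binder", "non_binder")
  tp <- sum(pred == "binder" & test$label == "binder")
  fp <- sum(pred == "binder" & test$label == "non_binder")
  fn <- sum(pred == "non_binder" & test$label == "binder")
  tn <- sum(pred == "non_binder" & test$label == "non_binder")
  m <- confusion_metrics(tp, fp, fn, tn)
  structure(c(m, list(n_components = red$n_components,
                      n_train = nrow(train), n_test = nrow(test))),
            class = "classifier_report")
}

#' Write a classifier report as JSON
#' @param report a `classifier_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_classifier_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
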