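test_that("one-hot featurization marks one channel per position", {
  X <- featurize(c("AC"), feature_config("one_hot_padded"))
  expect_equal(sum(X != 0), 2)
  # padded position uses the blank channel
  X2 <- featurize(c("AC", "ACD"), feature_config("one_hot_padded"))
  expect_equal(ncol(X2), 3 * 21)
  expect_equal(sum(X2[1, ] != 0), 3)  # two residues + one pad mark
  expect_equal(unname(X2[1, "p3_-"]), 1)
})

test_that("1-mer counts match hand counts for the published A7 loop", {
  X <- featurize(c("KKEYYSR"), feature_config("kmer_counts", k = 1))
  counts <- setNames(as.numeric(X[1, ]), colnames(X))
  expect_equal(counts[c("E", "K", "R", "S", "Y")],
               c(E = 1, K = 2, R = 1, S = 1, Y = 2))
})

test_that("identical sequences give identical feature rows", {
  for (cfg in list(feature_config("one_hot_padded"),
                   feature_config("kmer_counts", k = 2))) {
    X <- featurize(c("KAYSSRR", "GGSYAYD", "KAYSSRR"), cfg)
    expect_equal(X[1, ], X[3, ])
    expect_false(isTRUE(all.equal(X[1, ], X[2, ])))
  }
})

test_that("flanked featurization prepends and appends the anchors", {
  cl_p <- clone_table("KAYSSRR", 3L, "positive")
  cl_n <- clone_table("GGSYAYD", 2L, "negative")
  seqs <- labeled_sequences(cl_p, cl_n)
  expect_equal(seqs$flanked[seqs$label == "binder"],
               paste0("DTAVYYCAR", "KAYSSRR", "FDYWGQGTLVTVSS"))
  X <- featurize(seqs, feature_config("kmer_counts", k = 1,
                                      include_flanks = TRUE))
  # flanks add constant mass: one 'W' appears only via the flank
  expect_true(all(X[, "W"] >= 1))
})

test_that("external embeddings are loaded by key and missing keys error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("KAYSSRR\t0.5\t1.5", "GGSYAYD\t-1\t2"), path)
  cfg <- feature_config("external_embedding_file", embedding_file = path)
  X <- featurize(c("GGSYAYD", "KAYSSRR"), cfg)
  expect_equal(unname(X[1, ]), c(-1, 2))
  expect_equal(unname(X[2, ]), c(0.5, 1.5))
  expect_error(featurize(c("WWWWWWW"), cfg), "WWWWWWW")
})

test_that("sample weights are clone counts over total positive counts", {
  cl_p <- clone_table(c("KAYSSRR", "KKYSSRR"), c(3L, 1L), "positive")
  cl_n <- clone_table(c("GGSYAYD", "GGSYAYE"), c(5L, 5L), "negative")
  seqs <- labeled_sequences(cl_p, cl_n)
  expect_equal(sort(seqs$weight[seqs$label == "binder"]),
               c(0.25, 0.75))
  expect_equal(seqs$weight[seqs$label == "non_binder"], c(0.5, 0.5))
})

test_that("PCA keeps the smallest component count reaching the target", {
  # rank-1 data: a single component suffices
  withr::with_seed(3, {
    u <- rnorm(40)
    X1 <- outer(u, c(1, 2, 3))
    expect_equal(reduce_dimensions(X1, NULL, 0.95)$n_components, 1L)
  })
  # exactly isotropic data in d dimensions: ceil(0.95 d) components
  d <- 20
  Xiso <- rbind(diag(d), -diag(d))
  red <- reduce_dimensions(Xiso, NULL, 0.95)
  expect_equal(red$n_components, ceiling(0.95 * d))

  expect_error(reduce_dimensions(matrix(1, 10, 4), NULL, 0.95),
               "degenerate")
})

test_that("retaining all variance reconstructs the data", {
  withr::with_seed(4, {
    X <- matrix(rnorm(200), 20, 10)
    pca <- stats::prcomp(X, center = TRUE)
    red <- reduce_dimensions(X, NULL, 1.0)
    recon <- red$train %*% t(pca$rotation[, seq_len(red$n_components)])
    recon <- sweep(recon, 2, pca$center, "+")
    expect_lt(max(abs(recon - X)), 1e-8)
  })
})

test_that("the fitted transform ignores test rows entirely", {
  withr::with_seed(5, {
    Xtr <- matrix(rnorm(300), 30, 10)
    Xte1 <- matrix(rnorm(100), 10, 10)
    Xte2 <- matrix(rnorm(100, sd = 50), 10, 10)
    r1 <- reduce_dimensions(Xtr, Xte1, 0.9)
    r2 <- reduce_dimensions(Xtr, Xte2, 0.9)
    expect_identical(r1$train, r2$train)
    expect_identical(r1$n_components, r2$n_components)
  })
})

test_that("F1 follows its confusion-count definition", {
  m <- cdrh3kit:::confusion_metrics(tp = 3, fp = 1, fn = 1, tn = 10)
  expect_equal(m$f1_binder, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  edge <- cdrh3kit:::confusion_metrics(tp = 0, fp = 0, fn = 5, tn = 5)
  expect_equal(edge$f1_binder, 0)
})

make_separable_tables <- function(n = 60, seed = 9) {
  withr::with_seed(seed, {
    pos <- unique(vapply(1:n, function(i) {
      paste(sample(c("K", "R"), 7, TRUE), collapse = "")
    }, character(1)))
    neg <- unique(vapply(1:n, function(i) {
      paste(sample(c("D", "E"), 7, TRUE), collapse = "")
    }, character(1)))
  })
  list(pos = clone_table(pos, rep(1L, length(pos)), "positive"),
       neg = clone_table(neg, rep(1L, length(neg)), "negative"))
}

test_that("a separable library is classified perfectly", {
  tabs <- make_separable_tables()
  seqs <- labeled_sequences(tabs$pos, tabs$neg)
  rep <- train_evaluate(seqs, feature_config("one_hot_padded"), seed = 2)
  expect_equal(rep$f1_binder, 1)
  expect_equal(rep$fp + rep$fn, 0)
})

test_that("evaluation is invariant to input row order given the seed", {
  tabs <- make_separable_tables(seed = 10)
  seqs <- labeled_sequences(tabs$pos, tabs$neg)
  shuf <- seqs[withr::with_seed(2, sample(nrow(seqs))), ]
  r1 <- train_evaluate(seqs, feature_config("kmer_counts", k = 1),
                       seed = 7)
  r2 <- train_evaluate(shuf, feature_config("kmer_counts", k = 1),
                       seed = 7)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("duplicating a row equals adding its weight", {
  # weighting semantics of the linear fit: two copies at weights w1, w2
  # are one copy at w1 + w2
  tabs <- make_separable_tables(seed = 12)
  seqs <- labeled_sequences(tabs$pos, tabs$neg)
  X <- featurize(seqs, feature_config("kmer_counts", k = 1))
  y <- factor(seqs$label, levels = c("non_binder", "binder"))
  dup <- c(seq_len(nrow(X)), 1L)
  w_dup <- c(seqs$weight, seqs$weight[1])
  w_sum <- seqs$weight
  w_sum[1] <- w_sum[1] * 2
  f1 <- glmnet::glmnet(X[dup, ], y[dup], family = "binomial", alpha = 0,
                       lambda = 1e-3, weights = w_dup,
                       standardize = FALSE)
  f2 <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = 1e-3, weights = w_sum,
                       standardize = FALSE)
  expect_equal(as.numeric(coef(f1)), as.numeric(coef(f2)),
               tolerance = 1e-6)
})

test_that("shuffled labels give no better than baseline skill", {
  withr::with_seed(31, {
    loops <- unique(vapply(1:80, function(i) {
      paste(sample(AA_ALPHABET, 7, TRUE), collapse = "")
    }, character(1)))
  })
  n <- length(loops)
  f1s <- vapply(1:20, function(s) {
    lab <- withr::with_seed(s, sample(rep(c("positive", "negative"),
                                          length.out = n)))
    pos <- clone_table(loops[lab == "positive"],
                       rep(1L, sum(lab == "positive")), "positive")
    neg <- clone_table(loops[lab == "negative"],
                       rep(1L, sum(lab == "negative")), "negative")
    r <- train_evaluate(labeled_sequences(pos, neg),
                        feature_config("kmer_counts", k = 1), seed = s)
    r$f1_binder
  }, numeric(1))
  # binder prevalence is ~0.5; an uninformed classifier's binder F1
  # scatters around the always-binder baseline 2p/(1+p) ~ 0.67 and below
  expect_lt(mean(f1s), 0.8)
  expect_lt(sum(f1s > 0.95), 3)
})

test_that("single-class splits are rejected", {
  tabs <- make_separable_tables(seed = 14)
  few <- clone_table(tabs$neg$loop[1], 1L, "negative")
  seqs <- labeled_sequences(tabs$pos, few)
  expect_error(train_evaluate(seqs, feature_config("kmer_counts", k = 1),
                              seed = 1), "both classes")
})
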