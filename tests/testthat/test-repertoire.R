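test_that("length distribution weights reads or unique clones", {
  cl <- clone_table(c("ABCDEF", "ABCDEFG"), c(2L, 3L), "positive")
  # 6-letter loops are not amino acids here; lengths are what matters
  ld <- length_distribution(cl, "read_weighted")
  expect_equal(unname(ld$probabilities[c("6", "7")]), c(0.4, 0.6))
  expect_equal(ld$mode, 7L)

  ld_u <- length_distribution(cl, "unique_clone")
  expect_equal(unname(ld_u$probabilities[c("6", "7")]), c(0.5, 0.5))
  expect_equal(ld_u$mode, 6L)  # tie breaks toward the shorter length

  single <- clone_table("KAYSSRR", 4L, "positive")
  ld_s <- length_distribution(single)
  expect_equal(unname(ld_s$probabilities), 1)
  expect_equal(ld_s$mode, 7L)

  expect_error(length_distribution(clone_table(character(0), integer(0))),
               "empty")
})

test_that("length mode of a seeded synthetic library matches its manifest", {
  sim <- sample_loops(positive_library_spec(n_reads = 10000, seed = 303))
  ld <- length_distribution(sim$clones)
  expect_equal(ld$mode, sim$manifest$mode_length)
  expect_equal(sum(ld$probabilities), 1, tolerance = 1e-12)
})

test_that("positional frequencies reproduce hand-computed matrices", {
  # single clone: indicator matrix (published A7 loop)
  f <- positional_frequencies(clone_table("KKEYYSR", 1L, "positive"), 7)
  expect_equal(f["K", 1], 1)
  expect_equal(f["K", 2], 1)
  expect_equal(f["E", 3], 1)
  expect_equal(sum(f == 1), 7)
  expect_equal(sum(f), 7)

  f2 <- positional_frequencies(clone_table(c("AG", "AC"), c(1L, 1L),
                                           "positive"), 2)
  expect_equal(f2["A", 1], 1)
  expect_equal(f2["G", 2], 0.5)
  expect_equal(f2["C", 2], 0.5)

  expect_error(positional_frequencies(clone_table("AG", 1L, "positive"), 9),
               "no clones")
})

test_that("frequency matrix matches a nested-loop tally on multinomial draws", {
  loops <- withr::with_seed(17, {
    vapply(1:500, function(i) {
      paste(sample(AA_ALPHABET, 7, TRUE), collapse = "")
    }, character(1))
  })
  tab <- table(loops)
  cl <- clone_table(names(tab), as.integer(tab), "naive")
  f <- positional_frequencies(cl, 7)
  # independent tally straight over the read-level loop list
  for (p in 1:7) {
    counts <- setNames(numeric(20), AA_ALPHABET)
    for (lp in loops) {
      aa <- substr(lp, p, p)
      counts[aa] <- counts[aa] + 1
    }
    expect_equal(unname(f[, p]), unname(counts / 500))
  }
})

test_that("frequency columns sum to one for any pseudocount", {
  sim <- sample_loops(positive_library_spec(n_reads = 2000, seed = 7))
  for (pc in c(0, 0.5, 2)) {
    f <- positional_frequencies(sim$clones, 7, pseudocount = pc)
    expect_equal(unname(colSums(f)), rep(1, 7), tolerance = 1e-12)
  }
  pooled <- pooled_frequencies(sim$clones, pseudocount = 0.5)
  expect_equal(sum(pooled), 1, tolerance = 1e-12)
})

test_that("enrichment ratios divide frequencies and flag undefined cells", {
  f <- positional_frequencies(clone_table(c("KG", "KC"), c(1L, 1L),
                                          "positive"), 2)
  e_self <- enrichment(f, f)
  expect_equal(unname(e_self["K", 1]), 1)
  expect_true(all(e_self[!is.na(e_self)] == 1))
  # zero-denominator cells are NA, not Inf
  expect_true(is.na(e_self["A", 1]))

  num <- positional_frequencies(clone_table(c("KKK", "KGG", "GGK", "GGG",
                                              "KGK", "GKG", "KKG", "GKK",
                                              "KGG", "GGG"),
                                            rep(1L, 10), "positive"), 3)
  den <- positional_frequencies(clone_table(c("KGG", "GGG", "GGG", "GGG",
                                              "GGG", "GGG", "GGG", "GGG",
                                              "GKG", "GGK"),
                                            rep(1L, 10), "negative"), 3)
  e <- enrichment(num, den)
  # position 1: K frequency 0.5 vs 0.1
  expect_equal(unname(e["K", 1]), 5)
})

test_that("a 3x frequency ratio yields enrichment 3", {
  # K at 30% vs 10% in every position
  mk <- function(lib, nk) {
    loops <- c(rep("KKK", nk), rep("GGG", 10 - nk))
    tab <- table(loops)
    clone_table(names(tab), as.integer(tab), lib)
  }
  e <- enrichment(positional_frequencies(mk("positive", 3), 3),
                  positional_frequencies(mk("negative", 1), 3))
  expect_equal(unname(e["K", ]), rep(3, 3))
})

test_that("enrichment is reciprocal where both directions are defined", {
  sim_p <- sample_loops(positive_library_spec(n_reads = 1500, seed = 41))
  sim_n <- sample_loops(negative_library_spec(n_reads = 1500, seed = 42))
  fp <- positional_frequencies(sim_p$clones, 7)
  fn <- positional_frequencies(sim_n$clones, 7)
  ab <- enrichment(fp, fn)
  ba <- enrichment(fn, fp)
  both <- !is.na(ab) & !is.na(ba) & ab > 0 & ba > 0
  expect_gt(sum(both), 50)
  expect_equal(unname(ab[both] * ba[both]), rep(1, sum(both)),
               tolerance = 1e-12)
})

test_that("statistics are invariant under clone-table row permutation", {
  sim <- sample_loops(positive_library_spec(n_reads = 800, seed = 55))
  cl <- sim$clones
  shuf <- cl[withr::with_seed(1, sample(nrow(cl))), ]
  class(shuf) <- class(cl)
  expect_equal(length_distribution(shuf)$probabilities,
               length_distribution(cl)$probabilities)
  expect_equal(unclass(positional_frequencies(shuf, 7)),
               unclass(positional_frequencies(cl, 7)),
               ignore_attr = TRUE)
  expect_equal(as.numeric(pooled_frequencies(shuf)),
               as.numeric(pooled_frequencies(cl)))
})

test_that("empirical enrichment converges to the planted ratio with n", {
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    sp <- sample_loops(positive_library_spec(n_reads = n, seed = 71))
    sn <- sample_loops(negative_library_spec(n_reads = n, seed = 72))
    e <- enrichment(pooled_frequencies(sp$clones),
                    pooled_frequencies(sn$clones), mode = "pooled")
    planted <- sp$manifest$enrichment_vs_uniform["K"]
    abs(e["K"] - planted) / planted
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.02)
})

test_that("pooled enrichment recovers planted class composition at n = 1e4", {
  sp <- sample_loops(positive_library_spec(n_reads = 1e4, seed = 81))
  sn <- sample_loops(negative_library_spec(n_reads = 1e4, seed = 82))
  e <- enrichment(pooled_frequencies(sp$clones),
                  pooled_frequencies(sn$clones), mode = "pooled")
  planted <- sp$manifest$enrichment_vs_uniform
  for (aa in c("K", "R", "H", "D", "E", "G", "S")) {
    expect_equal(unname(e[aa]), unname(planted[aa]), tolerance = 0.15)
  }
})

test_that("class summary averages defined cells per class and position", {
  ones <- matrix(1, nrow = 20, ncol = 3,
                 dimnames = list(AA_ALPHABET, 1:3))
  cs <- class_summary(structure(ones, class = c("enrichment_table",
                                                "matrix")))
  expect_true(all(cs$mean_enrichment == 1))
  expect_true(all(cs$n_undefined == 0))

  m <- ones
  m["D", 1] <- 2; m["E", 1] <- 4
  cs2 <- class_summary(m)
  expect_equal(cs2$mean_enrichment[cs2$class == "negative" &
                                   cs2$position == 1], 3)

  m["K", 2] <- NA
  cs3 <- class_summary(m)
  pos2 <- cs3[cs3$class == "positive" & cs3$position == 2, ]
  expect_equal(pos2$n_undefined, 1)
  expect_equal(pos2$mean_enrichment, 1)  # mean over R, H only
})

test_that("planted class ordering is recovered: positive > special > negative", {
  sp <- sample_loops(positive_library_spec(n_reads = 1e4, seed = 91))
  sn <- sample_loops(negative_library_spec(n_reads = 1e4, seed = 92))
  e <- enrichment(positional_frequencies(sp$clones, 7),
                  positional_frequencies(sn$clones, 7))
  cs <- class_summary(e)
  mean_of <- function(cl) {
    mean(cs$mean_enrichment[cs$class == cl], na.rm = TRUE)
  }
  expect_gt(mean_of("positive"), mean_of("special"))
  expect_gt(mean_of("special"), mean_of("negative"))
})

test_that("residue classes partition the alphabet", {
  sc <- residue_classes()
  expect_setequal(unlist(sc), AA_ALPHABET)
  expect_equal(length(unlist(sc)), 20L)
})
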