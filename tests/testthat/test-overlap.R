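test_that("shared ratio normalises the intersection by the smaller set", {
  # worked example: |A| = 5, |B| = 10, 2 genes in common
  rec <- shared_ratio(paste0("a", 1:5),
                      c("a1", "a2", paste0("b", 1:8)))
  expect_equal(rec$ratio, 0.4)
  expect_equal(rec$intersection, 2L)

  # the focal-regulator geometry: 79 targets, 866 DEGs, 12 shared
  tg <- paste0("t", 1:79)
  deg <- c(tg[1:12], paste0("d", 1:854))
  expect_equal(shared_ratio(tg, deg)$ratio, 12 / 79)
  expect_equal(round(100 * shared_ratio(tg, deg)$ratio, 1), 15.2)

  s <- paste0("x", 1:7)
  expect_equal(shared_ratio(s, s)$ratio, 1)
  expect_equal(shared_ratio(paste0("x", 1:3), paste0("y", 1:3))$ratio, 0)
  # one empty set: ratio 0 with sizes recorded
  rec0 <- shared_ratio(character(0), s)
  expect_equal(rec0$ratio, 0)
  expect_equal(rec0$size_b, 7L)
  expect_error(shared_ratio(character(0), character(0)),
               class = "grn_degenerate_test_error")
})

test_that("shared ratio is symmetric, bounded, and monotone", {
  set.seed(3)
  for (i in 1:25) {
    a <- sample(paste0("g", 1:30), sample(1:15, 1))
    b <- sample(paste0("g", 1:30), sample(1:15, 1))
    r_ab <- shared_ratio(a, b)
    expect_equal(r_ab$ratio, shared_ratio(b, a)$ratio)
    expect_gte(r_ab$ratio, 0); expect_lte(r_ab$ratio, 1)
    expect_lte(r_ab$intersection, min(r_ab$size_a, r_ab$size_b))
    expect_equal(r_ab$ratio == 0, length(intersect(a, b)) == 0)

    # adding a common element never decreases the ratio
    new <- "new_common"
    expect_gte(shared_ratio(c(a, new), c(b, new))$ratio, r_ab$ratio)
    # adding an element only to the strictly larger set changes nothing
    if (length(a) < length(b)) {
      expect_equal(shared_ratio(a, c(b, "only_b"))$ratio, r_ab$ratio)
    }
  }
})

test_that("summarize_distribution matches a brute-force six-number oracle", {
  expect_equal(
    unlist(summarize_distribution(c(0, 0, 0, 0))),
    c(n = 4, minimum = 0, q1 = 0, median = 0, mean = 0, q3 = 0, maximum = 0))
  s <- summarize_distribution(c(0, 0.5, 1))
  expect_equal(s$median, 0.5); expect_equal(s$mean, 0.5)
  # 11 evenly spaced values under linear interpolation between order stats
  s11 <- summarize_distribution(seq(0, 1, by = 0.1))
  expect_equal(s11$q1, 0.25); expect_equal(s11$q3, 0.75)

  set.seed(8)
  for (i in 1:20) {
    x <- runif(sample(2:50, 1))
    expect_equal(unlist(summarize_distribution(x)), brute_six_number(x),
                 tolerance = 1e-12)
  }
  expect_error(summarize_distribution(numeric(0)),
               class = "grn_config_error")
})

test_that("six-number summaries are internally ordered", {
  set.seed(21)
  for (i in 1:20) {
    s <- summarize_distribution(rbeta(sample(1:40, 1), 0.4, 2))
    expect_true(s$minimum <= s$q1 && s$q1 <= s$median &&
                  s$median <= s$q3 && s$q3 <= s$maximum)
    expect_true(s$mean >= s$minimum && s$mean <= s$maximum)
  }
})

test_that("sign test reproduces exact binomial tails", {
  # 9 null samples below, 1 above: P(X <= 1 | n = 10, p = 1/2) = 11/1024
  null <- c(seq(0.01, 0.09, by = 0.01), 0.9)
  expect_equal(sign_test_exceeds(0.5, null, "greater"), 11 / 1024)
  # observed beyond every null sample
  expect_equal(sign_test_exceeds(1, runif(1000, 0, 0.5), "greater"), 0.5^1000)
  # observed at the centre of a symmetric sample, two-sided
  expect_equal(sign_test_exceeds(0.5, c(1:4, 6:9) / 10, "two_sided"), 1)
  # ties with the observed value are discarded before the binomial
  expect_equal(sign_test_exceeds(0.5, c(0.5, 0.5, null), "greater"),
               11 / 1024)
  expect_error(sign_test_exceeds(0.3, rep(0.3, 5)),
               class = "grn_degenerate_test_error")
})

test_that("sign test agrees with stats::binom.test on random draws", {
  set.seed(5)
  for (i in 1:20) {
    null <- runif(sample(3:60, 1))
    obs <- runif(1)
    n_above <- sum(null > obs)
    n <- length(null)
    expect_equal(sign_test_exceeds(obs, null, "greater"),
                 binom.test(n_above, n, alternative = "less")$p.value)
    expect_equal(sign_test_exceeds(obs, null, "less"),
                 binom.test(n_above, n, alternative = "greater")$p.value)
  }
})

test_that("sample_tf_pairs draws unique ordered non-self pairs with a cap", {
  # a 3-member family admits exactly 6 ordered pairs
  p3 <- sample_tf_pairs(c("x", "y", "z"), 1000, seed = 1)
  expect_equal(nrow(p3), 6L)
  expect_setequal(paste(p3$tf1, p3$tf2),
                  c("x y", "x z", "y x", "y z", "z x", "z y"))
  expect_equal(nrow(sample_tf_pairs(c("x", "y"), 1000, seed = 1)), 2L)

  p50 <- sample_tf_pairs(paste0("tf", 1:50), 1000, seed = 2)
  expect_equal(nrow(p50), 1000L)
  expect_false(any(p50$tf1 == p50$tf2))
  expect_false(anyDuplicated(paste(p50$tf1, p50$tf2)) > 0)
  # reproducible
  expect_identical(p50, sample_tf_pairs(paste0("tf", 1:50), 1000, seed = 2))
  expect_error(sample_tf_pairs("solo", 10, seed = 1),
               class = "grn_config_error")
})

test_that("null distribution at frame size equals exhaustive enumeration", {
  net <- toy3()
  ref <- c("g3", "g4", "g6")
  # oracle: compute each regulator's ratio by hand-enumerable brute force
  oracle <- vapply(c("TFa", "TFb", "TFc"), function(tf) {
    tg <- targets_of(net, tf)
    length(intersect(tg, ref)) / min(length(tg), length(ref))
  }, numeric(1))
  nd <- null_ratio_distribution(net, ref, n_samples = 3, seed = 7)
  expect_setequal(nd$records$ratio, unname(oracle))
  expect_equal(sort(nd$records$id_a), sort(names(oracle)))
  expect_equal(unlist(nd$summary), brute_six_number(unname(oracle)),
               tolerance = 1e-12)

  # identical draw sequence under the same seed
  nd2 <- null_ratio_distribution(net, ref, n_samples = 3, seed = 7)
  expect_identical(nd$records, nd2$records)

  # a reference disjoint from every target set gives an all-zero summary
  nd0 <- null_ratio_distribution(net, c("zz1", "zz2"), 3, seed = 1)
  expect_true(all(nd0$records$ratio == 0))
  expect_equal(nd0$summary$maximum, 0)

  expect_error(null_ratio_distribution(net, ref, n_samples = 10, seed = 1),
               class = "grn_config_error")  # exceeds frame without replacement
})

test_that("pairwise distribution matches brute force on all ordered pairs", {
  sets <- list(TF1 = paste0("g", 1:6), TF2 = paste0("g", 4:9),
               TF3 = paste0("h", 1:3), TF4 = paste0("g", 1:6))
  net <- net_from_targets(sets)
  frame <- names(sets)
  pairs <- expand.grid(tf1 = frame, tf2 = frame, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$tf1 != pairs$tf2, ]
  got <- pairwise_ratio_distribution(net, pairs)
  expect_equal(got$summary$n, 12L)
  oracle <- mapply(function(a, b) {
    length(intersect(sets[[a]], sets[[b]])) /
      min(length(sets[[a]]), length(sets[[b]]))
  }, pairs$tf1, pairs$tf2)
  expect_equal(got$records$ratio, unname(oracle))
  expect_equal(unlist(got$summary), brute_six_number(unname(oracle)),
               tolerance = 1e-12)
  # identical target sets give ratio 1, disjoint give 0
  expect_equal(got$records$ratio[got$records$id_a == "TF1" &
                                   got$records$id_b == "TF4"], 1)
  expect_equal(got$records$ratio[got$records$id_a == "TF1" &
                                   got$records$id_b == "TF3"], 0)
})
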