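test_that("scores match the brute-force binomial tail oracle", {
  for (seed in 1:15) {
    tab <- tabulate_bigrams(random_pairs(seed))
    res <- mdca(tab, all = TRUE)
    for (i in seq_len(nrow(res))) {
      k <- res$observed[i]; n <- res$trials[i]; p <- res$success_prob[i]
      if (res$direction[i] == "independent") {
        expect_identical(res$score[i], 0)
        next
      }
      tail_oracle <- if (res$direction[i] == "attraction") {
        oracle_tail_upper(k, n, p)
      } else {
        oracle_tail_lower(k, n, p)
      }
      tail_impl <- 10^(-abs(res$score[i]))
      expect_lt(abs(tail_impl - tail_oracle) / tail_oracle, 1e-12)
      expect_identical(res$direction[i] == "attraction", res$score[i] > 0)
    }
  }
})

test_that("the exclusive data sets reproduce the reference pbin columns", {
  se <- mdca(se_pairs())
  get <- function(res, a, b) res$score[res$first == a & res$second == b]
  expect_equal(round(get(se, "Huff", "Puff"), 1), 2.4)
  expect_equal(round(get(se, "Peep", "Howl"), 1), 2.5)
  expect_equal(round(get(se, "Howl", "Peep"), 1), 2.5)
  expect_true(all(se$direction == "attraction"))
  expect_true(all(se$band == "p<0.01"))

  le <- mdca(le_pairs())
  expect_equal(round(get(le, "Huff", "Puff"), 1), 24.1)
  expect_equal(round(get(le, "Peep", "Howl"), 1), 25.3)
  expect_equal(round(get(le, "Howl", "Peep"), 1), 25.1)
})

test_that("observed equal to expected is independent with score zero", {
  tab <- data.frame(first = c("A", "C", "A", "C"),
                    second = c("B", "B", "D", "D"))
  r <- mdca_score(tab, "A", "B")
  expect_identical(r$direction, "independent")
  expect_identical(r$score, 0)
  expect_identical(r$expected, 1)
  # saturated single bigram type: p = 1, k = n
  sat <- mdca_score(data.frame(first = rep("A", 5), second = rep("B", 5)),
                    "A", "B")
  expect_identical(sat$direction, "independent")
  expect_identical(sat$score, 0)
})

test_that("the matrix equals per-pair scoring and covers unobserved pairs", {
  tab <- tabulate_bigrams(random_pairs(99))
  res <- mdca(tab, all = TRUE)
  for (i in seq_len(nrow(res))) {
    one <- mdca_score(tab, res$first[i], res$second[i])
    expect_equal(one$score, res$score[i])
    expect_identical(one$direction, res$direction[i])
  }
  # unobserved pair with positive expectation is scored as repulsion
  zero <- res[res$observed == 0 & res$expected > 0, ]
  expect_true(nrow(zero) == 0 || all(zero$direction == "repulsion"))
  expect_true(nrow(zero) == 0 || all(zero$score < 0))
})

test_that("significance bands use strict thresholds on |score|", {
  expect_identical(significance_band(c(2.4, -2.4)), c("p<0.01", "p<0.01"))
  expect_identical(significance_band(0), "NS")
  expect_identical(significance_band(1.3), "NS")
  expect_identical(significance_band(1.31), "p<0.05")
  expect_identical(significance_band(2), "p<0.05")
  expect_identical(significance_band(3.2), "p<0.001")
  expect_error(significance_band(Inf), class = "colloc_bad_input")
})

test_that("Holm-adjusted bands are never more significant than raw bands", {
  lv <- c("NS" = 0, "p<0.05" = 1, "p<0.01" = 2, "p<0.001" = 3)
  res <- mdca(tabulate_bigrams(random_pairs(7)), all = TRUE)
  expect_true(all(lv[res$band_holm] <= lv[res$band]))
})

test_that("order asymmetry classifies linearisation", {
  # Huff-Puff occurs only in that order
  expect_identical(order_asymmetry(se_pairs(), "Huff", "Puff")$ordering,
                   "ordered")
  # Peep and Howl combine significantly in both orders
  expect_identical(order_asymmetry(se_pairs(), "Peep", "Howl")$ordering,
                   "bidirectional")
  # a pair never observed in either order
  big <- random_pairs(3, labels = c("A", "B", "C", "D"))
  big <- big[!(big$first %in% c("A", "B") & big$second %in% c("A", "B")), ]
  big <- rbind(big, data.frame(first = c("A", "B"), second = c("C", "C"),
                               count = c(1, 1)))
  expect_identical(order_asymmetry(big, "A", "B")$ordering, "none")
  expect_error(order_asymmetry(se_pairs(), "Huff", "Huff"),
               class = "colloc_bad_input")
})

test_that("scaling every count by c scales exclusive-pair scores by c", {
  base <- se_pairs()
  s1 <- mdca(base)$score
  for (c_mult in c(2L, 10L)) {
    scaled <- base
    scaled$count <- scaled$count * c_mult
    sc <- mdca(scaled)$score
    # planted pairs have k = n, where the tail is p^n and scaling is exact
    expect_equal(sort(sc), sort(s1) * c_mult, tolerance = 1e-12)
  }
})

test_that("background recombination strictly lowers a pair's score", {
  base <- se_pairs()
  score0 <- mdca_score(base, "Huff", "Puff")$score
  prev <- score0
  for (extra in c(2L, 6L, 12L)) {
    noisy <- rbind(base, data.frame(first = c("Huff", "Bark"),
                                    second = c("Bark", "Puff"),
                                    count = c(extra, extra)))
    cur <- mdca_score(noisy, "Huff", "Puff")$score
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("shuffled corpora rarely reach the p<0.05 band (type-I control)", {
  base <- artificial_corpus("SR", seed = 7)
  props <- vapply(1:200, function(s) {
    r <- mdca(shuffle_null(base, seed = s))
    mean(r$band != "NS")
  }, numeric(1))
  expect_lte(mean(props), 0.10)
})

test_that("an undefined binomial raises a labelled error", {
  expect_error(mdca_score(se_pairs(), "Puff", "Huff"),
               class = "colloc_no_trials")
  expect_error(mdca_score(se_pairs(), "Woof", "Huff"),
               class = "colloc_unknown_label")
})
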