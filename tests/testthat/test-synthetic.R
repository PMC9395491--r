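test_that("the exclusive artificial data sets are fully determined", {
  se <- artificial_corpus("SE")
  expect_identical(nrow(se), 16L)
  tab <- tabulate_bigrams(se)
  expect_identical(tab$n_calls, 32L)
  expect_identical(tab$counts["Huff", "Puff"], 4L)
  expect_identical(tab$counts["Peep", "Howl"], 5L)
  expect_identical(tab$counts["Howl", "Peep"], 7L)
  le <- tabulate_bigrams(artificial_corpus("LE"))
  expect_identical(le$n_pairs, 160L)
  expect_identical(le$n_calls, 320L)
  expect_identical(le$counts, tab$counts * 10L)
})

test_that("recombination data sets keep planted counts and add background", {
  sr <- artificial_corpus("SR", seed = 11)
  tab <- tabulate_bigrams(sr)
  expect_identical(tab$n_pairs, 49L)
  expect_identical(tab$n_calls, 98L)
  expect_identical(tab$counts["Huff", "Puff"], 4L)
  expect_identical(tab$counts["Peep", "Howl"], 5L)
  expect_identical(tab$counts["Howl", "Peep"], 7L)
  # background recombines over call types outside the planted bigrams
  planted_calls <- c("Huff", "Puff", "Peep", "Howl")
  bg_labels <- setdiff(tab$labels[tab$f_token > 0], planted_calls)
  expect_gte(length(bg_labels), 2)
  expect_true(all(diag(tab$counts) == 0))

  lr <- tabulate_bigrams(artificial_corpus("LR", seed = 11))
  expect_identical(lr$n_pairs, 490L)
  expect_identical(lr$n_calls, 980L)

  expect_identical(artificial_corpus("SR", seed = 11), sr)  # determinism
  expect_error(artificial_corpus("SR"), class = "colloc_bad_spec")
})

test_that("an explicit background table is used verbatim and validated", {
  bg <- data.frame(first = rep(c("Bark", "Cough", "Whistle"), c(20, 10, 3)),
                   second = rep(c("Grunt", "Chirp", "Twitter"), c(20, 10, 3)))
  sr <- tabulate_bigrams(artificial_corpus("SR", background_table = bg))
  expect_identical(sr$n_pairs, 49L)
  expect_identical(sr$counts["Bark", "Grunt"], 20L)
  expect_identical(sr$counts["Huff", "Puff"], 4L)
  expect_error(artificial_corpus("SR", background_table = bg[1:10, ]),
               regexp = "expected 33", class = "colloc_bad_spec")
})

test_that("simulate_corpus plants counts exactly and is deterministic", {
  sp <- synthetic_spec(repertoire(c("A", "B", "C")),
                       planted = data.frame(first = "A", second = "B",
                                            count = 4))
  corp <- simulate_corpus(sp)
  expect_identical(nrow(corp), 4L)
  expect_true(all(corp$first == "A" & corp$second == "B"))

  sp2 <- synthetic_spec(default_repertoire(),
                        planted = data.frame(first = "Huff", second = "Puff",
                                             count = 3),
                        background_pairs = 50,
                        background_policy = "recombine-uniform", seed = 5)
  expect_identical(simulate_corpus(sp2), simulate_corpus(sp2))
  tab <- tabulate_bigrams(simulate_corpus(sp2))
  expect_identical(tab$n_pairs, 53L)
  expect_identical(tab$counts["Huff", "Puff"], 3L)
})

test_that("spec validation rejects bad recipes", {
  expect_error(
    synthetic_spec(repertoire(c("A", "B")),
                   planted = data.frame(first = c("A", "A"),
                                        second = c("B", "B"),
                                        count = c(1, 2))),
    regexp = "duplicated", class = "colloc_bad_spec")
  expect_error(
    synthetic_spec(repertoire(c("A", "B")),
                   planted = data.frame(first = "A", second = "Z", count = 1)),
    class = "colloc_bad_spec")
  expect_error(
    synthetic_spec(repertoire(c("A", "B")),
                   planted = data.frame(first = "A", second = "B", count = 1),
                   background_pairs = 5, background_policy = "exclusive"),
    class = "colloc_bad_spec")
  expect_error(
    synthetic_spec(repertoire(c("A", "B")),
                   planted = data.frame(first = "A", second = "B", count = 1),
                   background_pairs = 5,
                   background_policy = "recombine-uniform"),
    class = "colloc_bad_spec")   # random background without a seed
})

test_that("uniform background is uniform over its candidate pairs", {
  labs <- default_repertoire()
  planted <- data.frame(first = "Huff", second = "Puff", count = 1)
  n_bg <- 1000L
  totals <- NULL
  for (seed in 1:50) {
    sp <- synthetic_spec(labs, planted, background_pairs = n_bg,
                         background_policy = "recombine-uniform", seed = seed)
    tab <- tabulate_bigrams(simulate_corpus(sp))
    cnt <- tab$counts
    cnt["Huff", "Puff"] <- 0L
    totals <- if (is.null(totals)) cnt else totals + cnt
  }
  # 89 candidate ordered pairs (90 heterotypic minus the planted one)
  expect_identical(sum(totals), 50L * n_bg)
  expect_true(all(diag(totals) == 0))
  p <- 1 / 89
  expected <- 50 * n_bg * p
  sd4 <- 4 * sqrt(50 * n_bg * p * (1 - p))
  mask <- row(totals) != col(totals)
  mask[rownames(totals) == "Huff", colnames(totals) == "Puff"] <- FALSE
  expect_true(all(abs(totals[mask] - expected) <= sd4))
})

test_that("excluding planted calls keeps planted bigrams exclusive", {
  sp <- synthetic_spec(default_repertoire(),
                       planted = data.frame(first = "Huff", second = "Puff",
                                            count = 5),
                       background_pairs = 200,
                       background_policy = "recombine-uniform",
                       background_exclude = "planted-calls", seed = 2)
  tab <- tabulate_bigrams(simulate_corpus(sp))
  expect_identical(unname(tab$f_token["Huff"]), 5)
  expect_identical(unname(tab$f_token["Puff"]), 5)
  expect_identical(tab$counts["Huff", "Puff"], 5L)
})

test_that("a planted exclusive bigram is recovered as the top MDCA score", {
  hits <- vapply(1:100, function(s) {
    sp <- synthetic_spec(default_repertoire(),
                         planted = data.frame(first = "Huff", second = "Puff",
                                              count = 5),
                         background_pairs = 200,
                         background_policy = "recombine-uniform",
                         background_exclude = "planted-calls", seed = s)
    res <- mdca(simulate_corpus(sp))
    top <- res[which.max(res$score), ]
    top$first == "Huff" && top$second == "Puff"
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("shuffle_null preserves token frequencies and destroys pairing", {
  for (seed in 1:10) {
    base <- simulate_corpus(synthetic_spec(
      default_repertoire(),
      planted = data.frame(first = "Huff", second = "Puff", count = 3),
      background_pairs = 40, background_policy = "recombine-uniform",
      seed = seed))
    sh <- shuffle_null(base, seed = seed + 1000)
    expect_identical(marginals(sh)$f_token, marginals(base)$f_token)
    expect_identical(nrow(sh), nrow(base))
  }
  one <- as_corpus(data.frame(first = "A", second = "B"))
  sh1 <- shuffle_null(one, seed = 1)
  expect_setequal(c(sh1$first, sh1$second), c("A", "B"))
  expect_identical(shuffle_null(one, seed = 3), shuffle_null(one, seed = 3))
  expect_error(shuffle_null(one[0, ], seed = 1), class = "colloc_bad_input")
})
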