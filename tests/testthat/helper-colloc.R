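# Shared fixtures and independent oracles. All fixtures are built in code.

# The small-exclusive pair list: three planted bigrams, counts 4/5/7.
se_pairs <- function() {
  data.frame(first  = c("Huff", "Peep", "Howl"),
             second = c("Puff", "Howl", "Peep"),
             count  = c(4L, 5L, 7L))
}

le_pairs <- function() {
  out <- se_pairs()
  out$count <- out$count * 10L
  out
}

# Independent binomial tail oracle: explicit term-by-term summation of
# choose(n, i) p^i (1-p)^(n-i). Deliberately naive; only valid for small n.
oracle_tail_upper <- function(k, n, p) {
  if (k > n) return(0)
  i <- seq(k, n)
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

oracle_tail_lower <- function(k, n, p) {
  i <- seq(0, k)
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# Random small count table as a pair-list data frame; row sums stay <= 25
# so the naive oracle remains numerically trustworthy.
random_pairs <- function(seed, labels = c("A", "B", "C", "D")) {
  withr::with_seed(seed, {
    grid <- expand.grid(first = labels, second = labels,
                        stringsAsFactors = FALSE)
    grid$count <- sample(0:5, nrow(grid), replace = TRUE)
    grid[grid$count > 0, ]
  })
}
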