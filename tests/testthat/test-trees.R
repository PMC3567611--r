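test_that("history labels match the published sets", {
  expect_identical(sequence_labels(0), "a")
  expect_identical(sequence_labels(1), c("aa", "ba"))
  expect_setequal(sequence_labels(2), c("aaa", "baa", "aba", "bba"))
  expect_setequal(sequence_labels(3),
                  c("aaaa", "baaa", "abaa", "aaba", "bbaa", "abba", "baba", "bbba"))
  expect_setequal(sequence_labels(1, "anchored"), c("aa", "ba", "bb", "ab"))
  expect_setequal(sequence_labels(2, "anchored"),
                  c("aaa", "baa", "aba", "bba", "bbb", "abb", "bab", "aab"))
  expect_length(sequence_labels(3, "anchored"), 16)
  expect_error(sequence_labels(4), "between 0 and 3")
})

test_that("trials are assigned to the correct history patterns", {
  s <- seq_from(c(1, 1, 2, 1))
  amp <- c(3, 3.2, 4.1, 3.9)
  t1 <- average_by_sequence(amp, s, order = 1)
  # trial 2 repeats (aa); trials 3 and 4 alternate (ba)
  expect_equal(t1$count[t1$pattern == "aa"], 1)
  expect_equal(t1$mean[t1$pattern == "aa"], 3.2)
  expect_equal(t1$count[t1$pattern == "ba"], 2)
  expect_equal(t1$mean[t1$pattern == "ba"], mean(c(4.1, 3.9)))

  # constant amplitudes give the constant in every non-empty cell
  tc <- average_by_sequence(rep(2.5, 4), s, order = 2)
  expect_true(all(tc$mean[tc$count > 0] == 2.5))
  # empty cells are reported as missing with count 0
  expect_true(any(tc$count == 0 & is.na(tc$mean)))

  # anchored mode keys symbols to the rare event
  s2 <- as_p3_sequence(c(1, 2, 2), K = 2, probs = c(0.3, 0.7))
  ta <- average_by_sequence(c(5, 2, 2.2), s2, order = 1, mode = "anchored")
  expect_equal(ta$count[ta$pattern == "ab"], 1)  # rare then frequent
  expect_equal(ta$count[ta$pattern == "bb"], 1)
})

test_that("pattern counts and means are conserved across orders", {
  sq <- generate_sequence(2, 192, c(0.5, 0.5), seed = 77)
  amp <- rnorm(192, 3.5, 1)
  for (m in 0:3) {
    tm <- average_by_sequence(amp, sq, order = m)
    expect_equal(sum(tm$count), 192 - m)
    # count-weighted mean equals the grand mean of eligible trials
    expect_equal(sum(tm$mean * tm$count, na.rm = TRUE) / sum(tm$count),
                 mean(amp[(m + 1):192]))
  }
  # refinement: a pattern aggregates its two children plus the boundary trial
  for (m in 0:2) {
    tm <- average_by_sequence(amp, sq, order = m)
    tc <- average_by_sequence(amp, sq, order = m + 1)
    for (p in tm$pattern) {
      kids <- tc[tc$pattern %in% paste0(c("a", "b"), p), ]
      kid_sum <- sum(kids$mean * kids$count, na.rm = TRUE)
      kid_n <- sum(kids$count)
      # the trial with exactly m predecessors sits in the parent only
      boundary <- m + 1
      window <- sq$event[max(1, boundary - m):boundary]
      blab <- paste(ifelse(window == sq$event[boundary], "a", "b"), collapse = "")
      extra <- if (blab == p) amp[boundary] else 0
      extra_n <- if (blab == p) 1 else 0
      row <- tm[tm$pattern == p, ]
      expect_equal(row$count, kid_n + extra_n)
      if (row$count > 0) {
        expect_equal(row$mean * row$count, kid_sum + extra)
      }
    }
  }
})

test_that("tree tables average across participants or pool trials", {
  sq <- generate_sequence(2, 60, c(0.5, 0.5), seed = 9)
  amp <- purrr::map_dfr(1:3, function(l) {
    tibble::tibble(participant = l, trial = 1:60, Y = rnorm(60, 3 + l, 0.5))
  })
  tt <- tree_table(amp, sq, orders = 0:1)
  expect_equal(nrow(tt), 1 + 2)
  # grand average of per-participant means at order 0
  per <- vapply(1:3, function(l) mean(amp$Y[amp$participant == l]), numeric(1))
  expect_equal(tt$mean[tt$order == 0], mean(per))

  tp <- tree_table(amp, sq, orders = 0, average = "pooled")
  expect_equal(tp$mean, mean(amp$Y))
  expect_equal(tp$count, 180)
})

test_that("alternation-sensitive observers separate ba from aa patterns", {
  # qualitative: with alpha_Delta > 0 the DIF surprise is higher after
  # alternations than after repetitions in the equiprobable category
  sq <- generate_sequence(2, 192, c(0.5, 0.5), seed = 15)
  tr <- dif_probability(sq, dif_params())
  t1 <- average_by_sequence(tr$I, sq, order = 1)
  expect_gt(t1$mean[t1$pattern == "ba"], t1$mean[t1$pattern == "aa"])
})
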