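test_that("MAR counting observer matches hand computation and the uniform prior", {
  s <- seq_from(c(1, 1, 2))
  tr <- mar_probability(s)
  expect_equal(unlist(tr[1, c("P_1", "P_2")], use.names = FALSE), c(0.5, 0.5))
  # after (1,1,2): P_1(4) = (2+1)/(3+2)
  s4 <- seq_from(c(1, 1, 2, 1))
  expect_equal(mar_probability(s4)$P_1[4], 0.6)

  # long-run convergence to the relative frequency, gap < K/(n-1+K)
  sq <- generate_sequence(2, 2000, c(0.3, 0.7), seed = 2)
  tr <- mar_probability(sq)
  n <- nrow(tr)
  rel_freq <- cumsum(sq$event == 1)[n - 1] / (n - 1)
  expect_lt(abs(tr$P_1[n] - rel_freq), 2 / (n - 1 + 2))

  # exact normalisation and the monotone update property
  P <- as.matrix(tr[, c("P_1", "P_2")])
  expect_equal(rowSums(P), rep(1, n))
  k_obs <- sq$event[-n]
  P_next <- P[cbind(2:n, k_obs)]
  P_curr <- P[cbind(1:(n - 1), k_obs)]
  expect_true(all(P_next > P_curr))
})

test_that("SQU short-term count is a truncated exponentially decaying sum", {
  prm <- squ_params(c(0.5, 0.5))
  expect_equal(prm$beta_S, -1 / log(0.6), tolerance = 1e-12)
  expect_equal(round(prm$beta_S, 2), 1.96)

  # no occurrence in the window
  s <- seq_from(c(2, 2, 2, 2, 2, 2, 2))
  expect_equal(squ_short_count(s, 1, prm)$value, rep(0, 7))
  # single match at lag 1
  s <- seq_from(c(1, 2))
  expect_equal(squ_short_count(s, 1, prm)$value[2], 0.6)
  # matches at lags 1 and 2
  s <- seq_from(c(1, 1, 2))
  expect_equal(squ_short_count(s, 1, prm)$value[3], 0.96)
  # events further back than N_depth are forgotten entirely
  s <- seq_from(c(1, 2, 2, 2, 2, 2, 2))
  expect_equal(squ_short_count(s, 1, prm)$value[7], 0)
})

test_that("SQU alternation count has the published codomain and sign rule", {
  # exhaustive enumeration of all binary histories up to length 6
  for (len in 2:6) {
    grids <- expand.grid(rep(list(1:2), len))
    for (i in seq_len(nrow(grids))) {
      ev <- as.integer(grids[i, ])
      s <- seq_from(ev)
      v <- squ_alternation_count(s, n = len)
      expect_true(v %in% c(-3L, -2L, 0L, 2L, 3L))
      if (v != 0) {
        expect_identical(v > 0, ev[len] != ev[len - 1])
      }
    }
  }
  # trial 1 has no predecessor
  expect_identical(squ_alternation_count(seq_from(c(1, 2)), n = 1), 0L)
  # fewer than two prior alternations give no expectation
  expect_identical(squ_alternation_count(seq_from(c(1, 1, 2)), n = 3), 0L)
  # an established alternation met / violated
  expect_identical(squ_alternation_count(seq_from(c(1, 2, 1, 2)), n = 4), 2L)
  expect_identical(squ_alternation_count(seq_from(c(1, 2, 1, 1)), n = 4), -2L)
  expect_identical(squ_alternation_count(seq_from(c(2, 1, 2, 1, 2)), n = 5), 3L)
  # the magnitude saturates at 3 within the 5-trial memory span
  expect_identical(squ_alternation_count(seq_from(c(1, 2, 1, 2, 1, 2)), n = 6), 3L)
})

test_that("SQU expectancy is the published affine combination", {
  prm <- squ_params(c(0.5, 0.5))
  s <- seq_from(c(1, 2, 1, 2, 1, 2, 2))
  tr <- squ_expectancy(s, prm)
  # empty window, no alternation: E = 0.505 * 0.5 - 0.027
  expect_equal(tr$E_1[1], 0.2255)
  # affine in the short-term count
  cs1 <- squ_short_count(s, 1, prm)$value
  cd1 <- squ_alternation_count(s, k = 1)
  expect_equal(tr$E_1, 0.505 * 0.5 + 0.235 * cs1 - 0.033 * cd1 - 0.027)
  # regressor picks the realised event's expectancy
  expect_equal(trace_regressor(tr)[2], tr$E_2[2])
  expect_error(squ_params(NULL), "made known")
})

test_that("DIF short filter matches the two-step hand recursion and its direct sum", {
  beta6 <- -1 / log(0.6)  # gamma_S = 0.6
  s <- seq_from(c(1, 2, 2))
  g <- input_signal_g(s, 1)
  cs <- dif_short_filter(g, beta6)
  expect_equal(cs$c[cs$n == 0], 0.5)
  expect_equal(cs$c[cs$n == 1], 0.5)   # uniform input keeps the prior
  expect_equal(cs$c[cs$n == 2], 0.7)   # 0.4 * 1 + 0.6 * 0.5

  # direct-sum oracle (materialised padding, C_S = gamma/(1-gamma))
  sq <- generate_sequence(2, 200, c(0.3, 0.7), seed = 13)
  for (beta in c(beta6, 1.82)) {
    gamma <- exp(-1 / beta)
    gpad <- input_signal_g(sq, 1, pad = 50)
    direct <- vapply(seq_len(200), function(n) {
      nu <- gpad$nu[gpad$nu <= n - 1]
      x <- gpad$value[gpad$nu <= n - 1]
      (1 - gamma) / gamma * sum(gamma^(n - nu) * x)
    }, numeric(1))
    rec <- dif_short_filter(input_signal_g(sq, 1), beta)$c[-1]
    expect_lt(max(abs(rec - direct)), 1e-10)
    expect_true(all(rec >= 0 & rec <= 1))
  }
})

test_that("long-term schedule reproduces the printed anchors and grows monotonically", {
  sch <- long_term_schedule(TAU1_STAR, TAU2_STAR, 192)
  expect_equal(round(sch$beta_L[1], 1), 40.3)
  expect_equal(round(sch$beta_L[192]), 11787)
  expect_true(all(diff(sch$beta_L) > 0))
  expect_true(all(sch$gamma_L > 0 & sch$gamma_L < 1))
  expect_true(all(diff(sch$gamma_L) > 0))
  expect_error(long_term_schedule(-1, 0.5, 10), "positive")
})

test_that("long filter reduces to the short filter and matches its unrolled sum", {
  sq <- generate_sequence(2, 200, c(0.5, 0.5), seed = 21)
  g <- input_signal_g(sq, 1)

  # constant schedule == short filter exactly
  gamma <- exp(-1 / 1.82)
  const_sched <- tibble::tibble(n = 1:200, beta_L = 1.82, gamma_L = gamma)
  expect_equal(dif_long_filter(g, const_sched)$c, dif_short_filter(g, 1.82)$c)

  # unrolled direct form: c(n) = prod gamma * c(0) + sum (1-gamma_nu) prod gamma
  sched <- long_term_schedule(TAU1_STAR, TAU2_STAR, 200)
  rec <- dif_long_filter(g, sched)$c[-1]
  x <- g$value
  direct <- vapply(seq_len(200), function(n) {
    if (n == 1) return(0.5)
    gam <- sched$gamma_L[1:(n - 1)]     # factors applied on steps 2..n
    total <- prod(gam) * 0.5
    for (nu in 1:(n - 1)) {
      w <- if (nu == 1) 1 - sched$gamma_L[1] else 1 - sched$gamma_L[nu]
      # remaining factors from step nu+1..n are gamma_L at trials nu..n-1
      rest <- if (nu < n - 1) prod(sched$gamma_L[(nu + 1):(n - 1)]) else 1
      total <- total + w * rest * x[nu]
    }
    total
  }, numeric(1))
  expect_lt(max(abs(rec - direct)), 1e-10)

  # partition of unity across events
  g2 <- input_signal_g(sq, 2)
  expect_equal(dif_long_filter(g, sched)$c + dif_long_filter(g2, sched)$c,
               rep(1, 201))
})

test_that("alternation FIR filter is local, linear and high-pass", {
  prm <- dif_params()
  sq <- seq_from(c(2, 2, 2, 2, 2, 2, 2, 2))
  g <- input_signal_g(sq, 1)
  cd <- dif_alternation_filter(g, prm$taps, prm$C_Delta)
  # event 1 never occurs and padding is out of reach from n >= 5
  expect_equal(cd$c[5:8], rep(0, 4))

  # output depends only on the last 4 inputs
  s_a <- seq_from(c(1, 2, 2, 2, 2, 1))
  s_b <- seq_from(c(2, 2, 2, 2, 2, 1))   # differs only at lag 5 from n = 6
  ca <- dif_alternation_filter(input_signal_g(s_a, 1), prm$taps, prm$C_Delta)
  cb <- dif_alternation_filter(input_signal_g(s_b, 1), prm$taps, prm$C_Delta)
  expect_equal(ca$c[6], cb$c[6])

  expect_error(dif_alternation_filter(g, taps = c(1, -1)), "4 FIR taps")
})

test_that("DIF probabilities start uniform, normalise, and degenerate correctly", {
  prm <- dif_params()
  for (sd in 1:3) {
    for (probs in list(c(0.5, 0.5), c(0.3, 0.7))) {
      sq <- generate_sequence(2, 96, probs, seed = 100 * sd + round(10 * probs[1]))
      tr <- dif_probability(sq, prm)
      P <- as.matrix(tr[, c("P_1", "P_2")])
      expect_equal(unname(P[1, ]), c(0.5, 0.5))
      expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
      expect_true(all(P >= 0 & P <= 1))
      expect_true(all(tr$I >= 0))
    }
  }

  # pure long-term observer equals the long filter output
  prm_L <- dif_params(alpha_L = 1, alpha_S = 0, alpha_Delta = 0)
  sq <- generate_sequence(2, 50, c(0.5, 0.5), seed = 5)
  tr <- dif_probability(sq, prm_L)
  sched <- long_term_schedule(prm_L$tau1, prm_L$tau2, 50)
  cL <- dif_long_filter(input_signal_g(sq, 1), sched)$c[-1]
  expect_equal(tr$P_1, cL)

  expect_error(dif_params(alpha_L = 0.9, alpha_S = 0.2, alpha_Delta = 0.05),
               "equal 1")
})

test_that("surprise maps probabilities to bits and is antitone", {
  s <- seq_from(c(1, 1, 1))
  tr <- mar_probability(s)
  expect_equal(tr$I[1], 1)          # P = 1/2
  tr$P_1 <- c(0.25, 0.5, 1); tr$P_2 <- 1 - tr$P_1
  tr2 <- surprise(tr, s)
  expect_equal(tr2$I, c(2, 1, 0))   # -log2 of 0.25, 0.5, 1
  p <- sort(runif(50, 0.01, 1))
  expect_true(all(diff(-log2(p)) <= 0))
  expect_error(surprise(squ_expectancy(seq_from(c(1, 2)), squ_params(c(0.5, 0.5))),
                        seq_from(c(1, 2))), "not defined")
})

test_that("filter amplitude responses have the declared characters", {
  prm <- dif_params()
  f <- seq(0, 1 / 3, length.out = 150)

  hs <- amplitude_response("short", f, params = prm)$magnitude
  expect_equal(hs[1], 1)                       # unity DC gain
  expect_true(all(diff(hs) <= 1e-12))          # low-pass

  # closed-form Nyquist magnitude for gamma = 0.6
  prm6 <- dif_params(beta_S = -1 / log(0.6))
  expect_equal(amplitude_response("short", 1 / 3, params = prm6)$magnitude,
               (1 - 0.6) / (1 + 0.6))
  expect_equal(amplitude_response("short", 1 / 3, params = prm6)$magnitude, 0.25)

  hl1 <- amplitude_response("long", f, params = prm, n = 1)$magnitude
  hl192 <- amplitude_response("long", f, params = prm, n = 192)$magnitude
  expect_true(all(diff(hl1) <= 1e-12))
  expect_true(all(diff(hl192) <= 1e-12))
  # the late-trial low-pass is much sharper at Nyquist
  expect_lt(hl192[150], hl1[150])

  hd <- amplitude_response("alternation", f, params = prm)$magnitude
  expect_true(all(diff(hd) >= -1e-12))         # high-pass
  expect_gt(hd[150], hd[1])

  expect_error(amplitude_response("short", 0.5, params = prm), "fs/2")
})
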