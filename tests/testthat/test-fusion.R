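test_that("Spearman correlation matches the average-rank brute-force oracle", {
  # monotone invariance and reversal
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_rho(x, x^2), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  # frozen tied-data value, hand-computed from average ranks: sqrt(0.1)
  expect_equal(spearman_rho(c(1, 1, 2, 3), c(2, 3, 1, 4)), 0.316227766,
               tolerance = 1e-8)
  set.seed(101)
  for (i in 1:100) {
    a <- sample(1:4, 8, replace = TRUE)  # plenty of ties
    b <- sample(1:4, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_lt(abs(spearman_rho(a, b) - oracle_spearman(a, b)), 1e-12)
  }
  expect_true(is.na(spearman_rho(rep(1, 6), 1:6)))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("partial Spearman matches the rank-regression residual oracle", {
  set.seed(102)
  for (i in 1:200) {
    x <- runif(6); y <- runif(6); z <- runif(6)
    if (abs(oracle_spearman(x, z)) > 1 - 1e-9 ||
        abs(oracle_spearman(y, z)) > 1 - 1e-9) next
    expect_lt(abs(partial_spearman(x, y, z) - oracle_partial_spearman(x, y, z)),
              1e-12)
  }
  # collapses to the raw correlation when z is rank-orthogonal to x and y
  # (a tie-free z admits no exactly orthogonal permutation of 1..6, so use
  # the binary model pattern, whose tied ranks do)
  z <- c(0.5, 1, 1, 1, 1, 0.5)
  x <- find_rank_orthogonal(z)
  y <- find_rank_orthogonal(z, skip = 1)
  expect_equal(partial_spearman(x, y, z), spearman_rho(x, y), tolerance = 1e-12)
  # self-correlation is 1 whenever defined
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  expect_equal(partial_spearman(x, x, m), 1)
  # degenerate denominator gives NA, never infinity
  expect_true(is.na(partial_spearman(runif(6), 1:6, 1:6)))
})

test_that("the commonality index equals raw minus residual-partial and handles degeneracy", {
  set.seed(103)
  for (i in 1:200) {
    f <- runif(6); g <- runif(6); m <- runif(6)
    if (abs(oracle_spearman(f, m)) > 1 - 1e-9 ||
        abs(oracle_spearman(g, m)) > 1 - 1e-9) next
    expect_lt(abs(as.numeric(commonality_index(f, g, m)) -
                    (spearman_rho(f, g) - oracle_partial_spearman(f, g, m))),
              1e-12)
  }
  # MEG RDV rank-identical to the model: undefined
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  r <- commonality_index(runif(6), m, m)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "rank-identical")
  expect_error(commonality_index(1:6, 1:6, 1:5), "same length")
})

test_that("a rank-orthogonal model yields exactly zero commonality", {
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  f <- find_rank_orthogonal(m)
  g <- find_rank_orthogonal(m, skip = 1)
  expect_equal(abs(oracle_spearman(f, m)), 0, tolerance = 1e-14)
  expect_equal(abs(oracle_spearman(g, m)), 0, tolerance = 1e-14)
  expect_equal(as.numeric(commonality_index(f, g, m)), 0, tolerance = 1e-12)
})

test_that("commonality is symmetric in the two neural RDVs and rank-invariant", {
  set.seed(104)
  for (i in 1:50) {
    f <- runif(6); g <- runif(6); m <- sample(c(0.5, 0.5, 1, 1, 1, 1))
    expect_equal(commonality_index(f, g, m), commonality_index(g, f, m),
                 tolerance = 1e-14)
    # strictly monotone transform of one RDV changes nothing
    expect_equal(commonality_index(exp(3 * f), g, m),
                 commonality_index(f, g, m), tolerance = 1e-12)
  }
})

test_that("the vectorised permutation path equals the elementwise index", {
  set.seed(105)
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  ms <- rsafusion:::rank_std(m)
  G <- matrix(runif(6 * 25), 6)
  G[, 7] <- 1  # constant column: undefined correlation
  gs <- apply(G, 2, function(v) {
    r <- rsafusion:::rank_std(v)
    if (is.null(r)) rep(NA_real_, 6) else r
  })
  gm <- as.vector(crossprod(ms, gs))
  for (i in 1:30) {
    f <- runif(6)
    fast <- rsafusion:::fast_commonality(f, gs, gm, ms)
    slow <- vapply(1:25, function(t) as.numeric(commonality_index(f, G[, t], m)),
                   numeric(1))
    expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-12)
    expect_identical(is.na(fast), is.na(slow))
  }
})

test_that("commonality time courses carry component correlations on the full grid", {
  set.seed(106)
  stack <- matrix(runif(6 * 541), 6)
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  tr <- commonality_timecourse(runif(6), stack, m, seq(-200, 2500, 5))
  expect_length(tr$commonality, 541)
  expect_length(tr$rho_fmri_meg, 541)
  expect_length(tr$rho_meg_model, 541)
  expect_length(tr$rho_fmri_model, 1)
  expect_error(commonality_timecourse(runif(6), stack, m, 1:10),
               "must match")
})

test_that("Storey q-values match hand computation and the step-up property", {
  expect_equal(storey_fdr(rep(1, 20)), rep(1, 20))
  # pi0 at lambda = 0.5 is capped at 1 here; the small p gets
  # q = pi0 * m * p / 1 = 100 * 0.001
  p <- c(0.001, rep(0.9, 99))
  q <- storey_fdr(p)
  expect_equal(q[1], 0.1)
  expect_true(all(q[-1] == 0.9))
  set.seed(107)
  pr <- runif(50)^2
  qr <- storey_fdr(pr)
  o <- order(pr)
  expect_true(all(diff(qr[o]) >= -1e-12))
  expect_true(all(qr >= 0 & qr <= 1))
  # sparse-alternative case: pi0 < 1 sharpens the q-values below BH
  p2 <- c(rep(0.002, 5), runif(45, 0.6, 1))
  expect_true(all(storey_fdr(p2)[1:5] <= p.adjust(p2, "BH")[1:5]))
  expect_warning(qq <- storey_fdr(c(0.01, 0.5)), "Benjamini-Hochberg")
  expect_equal(qq, p.adjust(c(0.01, 0.5), "BH"))
  expect_error(storey_fdr(c(rep(0.5, 10), 1.5)), "\\[0, 1\\]")
  expect_error(storey_fdr(runif(20), lambda = 2), "lambda")
})

test_that("permutation p-values obey the add-one count formula bounds", {
  tt <- fix_trials(4, 16, seed = 108)
  b <- fix_betas(tt, effect = 0, n_voxels = 8, seed = 109)
  set.seed(110)
  stack <- matrix(runif(6 * 12), 6)
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  tr <- commonality_timecourse(as.numeric(rdm_to_rdv(1 - pairwise_condition_decoding(b))),
                               stack, m, seq(0, 550, 50))
  # force extremes: below every null value -> p = 1; above every one -> 1/(n+1)
  tr$commonality[1] <- -10
  tr$commonality[2] <- 10
  out <- permutation_test_commonality(tr, b, stack, m, n_perm = 100, seed = 111)
  expect_equal(out$p_values[1], 1)
  expect_equal(out$p_values[2], 1 / 101)
  expect_true(all(out$p_values >= 1 / 101 & out$p_values <= 1, na.rm = TRUE))
  expect_false(any(out$sig_mask[!is.na(out$p_values) & tr$commonality < 0]))
  expect_error(permutation_test_commonality(tr, b, stack, m, n_perm = 10),
               "at least 100")
})

test_that("an all-missing trace yields an empty mask with a warning", {
  tt <- fix_trials(4, 16, seed = 112)
  b <- fix_betas(tt, effect = 0, n_voxels = 8, seed = 113)
  m <- c(0.5, 1, 1, 1, 1, 0.5)
  stack <- matrix(rep(m, 5), 6)  # every MEG RDV rank-identical to the model
  tr <- commonality_timecourse(runif(6), stack, m, seq(0, 200, 50))
  expect_true(all(is.na(tr$commonality)))
  expect_warning(out <- permutation_test_commonality(tr, b, stack, m, n_perm = 100),
                 "missing")
  expect_false(any(out$sig_mask))
})

test_that("temporal metrics read off onset, peak and peak-to-response times", {
  tms <- seq(0, 1000, 50)
  com <- exp(-((tms - 400) / 150)^2)
  tr <- structure(list(times_ms = tms, commonality = com,
                       sig_mask = tms >= 300 & tms <= 600,
                       alignment = "stimulus"),
                  class = "commonality_trace")
  m <- temporal_metrics(tr, response_ref_ms = 1500)
  expect_equal(m$time_to_first_sig_ms, 300)
  expect_equal(m$time_to_max_ms, 400)
  expect_equal(m$time_from_max_to_response_ms, 1100)
  expect_true(m$reliable)
  # never-significant trace: onset undefined, peak still reported, flagged
  tr$sig_mask[] <- FALSE
  m0 <- temporal_metrics(tr, response_ref_ms = 1500)
  expect_true(is.na(m0$time_to_first_sig_ms))
  expect_equal(m0$time_to_max_ms, 400)
  expect_false(m0$reliable)
  # response-aligned: time from max is minus the peak time
  tr2 <- structure(list(times_ms = seq(-1000, 0, 50),
                        commonality = exp(-((seq(-1000, 0, 50) + 300) / 100)^2),
                        sig_mask = rep(TRUE, 21), alignment = "response"),
                   class = "commonality_trace")
  m2 <- temporal_metrics(tr2)
  expect_equal(m2$time_to_max_ms, -300)
  expect_equal(m2$time_from_max_to_response_ms, 300)
})
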