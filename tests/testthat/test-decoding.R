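test_that("the lean libsvm call matches e1071::svm decisions exactly", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(c(8, 12, 24), 1); p <- sample(c(4, 10, 30), 1)
    y <- factor(rep(c("a", "b"), length.out = n))
    X <- matrix(rnorm(n * p), n, p) +
      outer(as.integer(y) == 1, rnorm(p) * runif(1, 0, 1.5))
    Xt <- matrix(rnorm(6 * p), 6, p)
    pred <- rsafusion:::svm_classify(X, y, Xt)
    st <- rsafusion:::scale_train_stats(X)
    Xs <- sweep(sweep(X, 2, st$mu), 2, st$s, "/")
    Xts <- sweep(sweep(Xt, 2, st$mu), 2, st$s, "/")
    o <- order(as.integer(y))
    m <- e1071::svm(Xs[o, , drop = FALSE], y[o], kernel = "linear", cost = 1,
                    scale = FALSE, fitted = FALSE)
    d <- as.vector(Xts %*% crossprod(m$SV, m$coefs)) - m$rho
    expect_equal(as.character(pred), ifelse(d >= 0, "a", "b"))
  }
})

test_that("strong planted signal is decoded perfectly, leave-one-block-out", {
  tt <- fix_trials(6, 16, seed = 62)
  b <- fix_betas(tt, effect = 10, n_voxels = 20, seed = 63)
  lev <- rsa_scheme("across")$factors$across
  r <- decode_fmri_lobo(b, lev)
  expect_equal(r$accuracy, 1.0)
  expect_equal(r$n_folds, 6)
  expect_equal(r$accuracy, mean(r$per_fold))
})

test_that("duplicating every voxel leaves the accuracy unchanged", {
  # duplicating features doubles the kernel, which for a soft-margin SVM is
  # the same model at doubled C; in the separable (hard-margin) regime the
  # solutions coincide, so accuracies agree exactly
  lev <- rsa_scheme("across")$factors$across
  for (s in 1:3) {
    tt <- fix_trials(6, 16, seed = 63 + s)
    b <- fix_betas(tt, effect = 6, n_voxels = 16, seed = 73 + s)
    a1 <- decode_fmri_lobo(b, lev)$accuracy
    b2 <- b
    b2$values <- array(c(b$values, b$values), dim = c(4, 6, 32))
    b2$n_voxels <- 32L
    a2 <- decode_fmri_lobo(b2, lev)$accuracy
    expect_equal(a1, a2, tolerance = 1e-6)
  }
})

test_that("a single-class training partition raises an error naming the block", {
  X <- matrix(rnorm(12 * 4), 12, 4)
  y <- c(1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  block <- rep(1:3, each = 4)
  expect_error(rsafusion:::lobo_core(X, y, block), "held-out block 1")
  tt <- fix_trials(2, 16, seed = 66)
  b <- fix_betas(tt, seed = 67)
  expect_error(decode_fmri_lobo(b, c("a", "b", "a", "b")), "at least 3 blocks")
  expect_error(decode_fmri_lobo(fix_betas(fix_trials(3, 16, seed = 1), seed = 2),
                                c("a", "a", "a", "a")), "exactly 2 classes")
})

test_that("zero-signal decoding is calibrated: mean accuracy within 1% of 50%", {
  tt <- fix_trials(6, 16, seed = 68)
  lev <- rsa_scheme("across")$factors$across
  set.seed(69)
  accs <- vapply(1:200, function(i) {
    b <- fix_betas(tt, effect = 0, n_voxels = 16, seed = 1000 + i)
    decode_fmri_lobo(b, lev)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.01)
})

test_that("accuracy is monotone in the planted effect size", {
  tt <- fix_trials(6, 16, seed = 70)
  lev <- rsa_scheme("across")$factors$across
  sizes <- c(0, 0.5, 1, 2, 5)
  means <- vapply(seq_along(sizes), function(si) {
    mean(vapply(1:50, function(i) {
      b <- fix_betas(tt, effect = sizes[si], n_voxels = 12,
                     seed = 3000 + si * 100 + i)
      decode_fmri_lobo(b, lev)$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
  expect_lt(means[1], 0.55)
  expect_gt(means[5], 0.9)
})

test_that("permutation nulls are centred on chance and reproducible", {
  # 12 training blocks keep the cross-validated null's anti-learning bias
  # well inside the +/- 2% band
  tt <- fix_trials(12, 16, seed = 71)
  b <- fix_betas(tt, effect = 0, n_voxels = 16, seed = 72)
  lev <- rsa_scheme("across")$factors$across
  null1 <- permutation_null_decoding(b, lev, n_perm = 100, seed = 73)
  null2 <- permutation_null_decoding(b, lev, n_perm = 100, seed = 73)
  expect_identical(null1, null2)
  expect_gt(mean(null1), 0.48)
  expect_lt(mean(null1), 0.52)
  expect_error(permutation_null_decoding(b, lev, n_perm = 50), "at least 100")
})

test_that("an observation above every null value gets the add-one count p-value", {
  tt <- fix_trials(6, 16, seed = 74)
  b <- fix_betas(tt, effect = 10, n_voxels = 12, seed = 75)
  lev <- rsa_scheme("across")$factors$across
  obs <- decode_fmri_lobo(b, lev)$accuracy
  null <- permutation_null_decoding(b, lev, n_perm = 100, seed = 76)
  expect_true(all(null < obs))
  p <- (1 + sum(null >= obs)) / (1 + length(null))
  expect_equal(p, 1 / 101)
})

test_that("the decoding permutation test has calibrated type-I error", {
  tt <- fix_trials(4, 16, seed = 77)
  lev <- rsa_scheme("across")$factors$across
  rejections <- vapply(1:200, function(i) {
    b <- fix_betas(tt, effect = 0, n_voxels = 12, seed = 5000 + i)
    obs <- decode_fmri_lobo(b, lev)$accuracy
    null <- permutation_null_decoding(b, lev, n_perm = 100, seed = 6000 + i)
    (1 + sum(null >= obs)) / (1 + length(null)) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.02)
  expect_lte(mean(rejections), 0.10)
})

test_that("MEG decoding reuses one fold partition across time points", {
  tt <- fix_trials(2, 16, seed = 78,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  ep <- fix_epochs(tt, effect = 1, window = c(100, 400), n_sensors = 6,
                   rate = 20, span = c(0, 500), seed = 79)
  ep$values[, , 5] <- ep$values[, , 2]  # identical data slices
  lab <- fix_meg_labels(ep, tt)
  r <- decode_meg_timecourse(ep, lab, k = 4, seed = 80)
  expect_identical(r$accuracy[5], r$accuracy[2])
  expect_identical(r$per_fold[, 5], r$per_fold[, 2])
})

test_that("MEG decoding rejects impossible stratification", {
  tt <- fix_trials(2, 16, seed = 81,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  ep <- fix_epochs(tt, n_sensors = 4, rate = 20, span = c(0, 200), seed = 82)
  lab <- fix_meg_labels(ep, tt)
  lab[lab == "left"][-(1:3)] <- NA  # only 3 left trials remain
  expect_error(decode_meg_timecourse(ep, lab, k = 5, seed = 83),
               "stratified")
  expect_error(decode_meg_timecourse(ep, fix_meg_labels(ep, tt), k = 1),
               "at least 2")
})

test_that("pairwise decoding gives a symmetric matrix with perfect cells for orthogonal strong patterns", {
  tt <- fix_trials(6, 16, seed = 84)
  b <- simulate_fmri_betas(tt, list(list(roi = "r", n_voxels = 20)),
                           list(effect_spec("across", 8), effect_spec("rule", 8)),
                           "across", seed = 85)$r
  acc <- pairwise_condition_decoding(b)
  expect_identical(acc, t(acc))
  expect_true(all(is.na(diag(acc))))
  expect_true(all(acc[lower.tri(acc)] > 0.95))
  # pure-noise pairwise cells hover around chance on average; run at the
  # paradigm's 12 blocks, where the known negative bias of cross-validated
  # null accuracies at small training sizes is modest
  tt12 <- fix_trials(12, 16, seed = 84)
  cell_means <- vapply(1:10, function(i) {
    z <- fix_betas(tt12, effect = 0, n_voxels = 20, seed = 85 + i)
    accz <- pairwise_condition_decoding(z)
    mean(accz[lower.tri(accz)])
  }, numeric(1))
  expect_lt(abs(mean(cell_means) - 0.5), 0.05)
})

test_that("pairwise MEG decoding requires all four condition levels", {
  tt <- fix_trials(2, 16, seed = 87,
                   behaviour_params = list(accuracy_rate = 1, omission_rate = 0))
  ep <- fix_epochs(tt, n_sensors = 4, rate = 20, span = c(0, 200), seed = 88)
  cond <- scheme_conditions(tt, "across")[match(ep$trial_ids, tt$trial_id)]
  cond[cond == "left-r1"] <- NA
  expect_error(pairwise_condition_decoding(ep, cond, k = 2), "missing")
})
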