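# --- internal linear-SVM machinery -----------------------------------------
# Linear SVM (libsvm via e1071), C = 1, no class weighting. Features are
# z-scored with training-fold statistics only. Training samples are ordered
# so the lower factor level is libsvm's positive class, making the decision
# sign convention deterministic; an exact-zero decision value is assigned to
# the lower level.

scale_train_stats <- function(Xtr) {
  n <- nrow(Xtr)
  mu <- colMeans(Xtr)
  s <- sqrt(pmax(colMeans(Xtr * Xtr) - mu * mu, 0) * n / max(1, n - 1))
  s[!is.finite(s) | s == 0] <- 1
  list(mu = mu, s = s)
}

# libsvm training entry point, called directly (the svm() wrapper spends
# most of its time on argument validation, which dominates at the call rates
# of the permutation tests). Arguments mirror e1071::svm(kernel = "linear",
# cost = 1, scale = FALSE); a test asserts identical decision values.
.svm_env <- new.env(parent = emptyenv())

svm_fit_linear <- function(X, yint) {
  if (is.null(.svm_env$sym)) {
    .svm_env$sym <- get("R_svmtrain", envir = asNamespace("e1071"))
    .svm_env$err0 <- paste(rep(" ", 255), collapse = "")
  }
  n <- nrow(X); p <- ncol(X)
  cret <- .C(.svm_env$sym, as.double(t(X)), as.integer(n), as.integer(p),
             as.double(yint), integer(1), integer(1),
             as.integer(0),  # C-classification
             as.integer(0),  # linear kernel
             as.integer(3), as.double(1 / p), as.double(0),
             as.double(1),   # cost
             as.double(0.5), integer(0), double(0), as.integer(0),
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1), as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(n),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(n), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1), error = .svm_env$err0)
  if (cret$error != .svm_env$err0) stop("libsvm: ", cret$error)
  sv <- X[cret$index[seq_len(cret$nr)], , drop = FALSE]
  list(w = crossprod(sv, cret$coefs[seq_len(cret$nr)]), rho = cret$rho,
       first_label = cret$labels[1])
}

# Integer-label classifier core: yi in {1, 2}, lower label = libsvm positive
# class; an exact-zero decision value goes to label 1. Returns integer
# predictions for Xte.
svm_predict_int <- function(Xtr, yi, Xte) {
  ntr <- nrow(Xtr); nte <- nrow(Xte)
  mu <- colMeans(Xtr)
  s <- sqrt(pmax(colMeans(Xtr * Xtr) - mu * mu, 0) * ntr / max(1, ntr - 1))
  s[!is.finite(s) | s == 0] <- 1
  Xtr <- (Xtr - rep(mu, each = ntr)) / rep(s, each = ntr)
  Xte <- (Xte - rep(mu, each = nte)) / rep(s, each = nte)
  o <- order(yi)
  fit <- svm_fit_linear(Xtr[o, , drop = FALSE], yi[o])
  d <- Xte %*% fit$w - fit$rho
  2L - (d >= 0)
}

svm_classify <- function(Xtr, ytr, Xte) {
  pred <- svm_predict_int(Xtr, as.integer(ytr), Xte)
  factor(levels(ytr)[pred], levels = levels(ytr))
}

# Leave-one-block-out CV over samples (rows of X) grouped into blocks.
lobo_core <- function(X, y, block) {
  yi <- as.integer(y)
  folds <- sort(unique(block))
  acc <- vapply(folds, function(b) {
    tr <- block != b
    if (min(yi[tr]) == max(yi[tr]))
      stop("training partition for held-out block ", b, " contains a single class")
    pred <- svm_predict_int(X[tr, , drop = FALSE], yi[tr], X[!tr, , drop = FALSE])
    mean(pred == yi[!tr])
  }, numeric(1))
  names(acc) <- folds
  acc
}

# All 6 pairwise leave-one-block-out accuracies from a sample matrix with
# integer condition codes 1..4; the layout is built once so permutation
# tests can relabel samples without copying data.
pairwise_lobo_acc <- function(X, cond, block, conditions) {
  acc <- matrix(NA_real_, 4, 4, dimnames = list(conditions, conditions))
  for (i in 1:3) for (j in (i + 1):4) {
    sel <- cond == i | cond == j
    yi <- (cond[sel] == j) + 1L
    acc[i, j] <- acc[j, i] <-
      mean(lobo_core(X[sel, , drop = FALSE], yi, block[sel]))
  }
  acc
}

# Flatten a beta_patterns array into (sample x voxel) rows with condition
# and block codes.
beta_sample_matrix <- function(betas) {
  nc <- length(betas$condition_labels)
  nb <- length(betas$block_ids)
  X <- matrix(aperm(betas$values, c(2, 1, 3)), nc * nb, betas$n_voxels)
  list(X = X, cond = rep(seq_len(nc), each = nb),
       block = rep(seq_len(nb), nc))
}

# Stratified k-fold assignment, fixed across time points; errors if a class
# has fewer members than folds.
stratified_folds <- function(y, k) {
  if (min(table(y)) < k)
    stop("class imbalance makes stratified ", k, "-fold assignment impossible")
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Subsample the majority class of a training index set to the minority count.
balance_train <- function(idx, y) {
  tab <- table(y[idx])
  if (length(unique(tab)) == 1L) return(idx)
  n_min <- min(tab)
  unlist(lapply(levels(y), function(lv) {
    w <- idx[y[idx] == lv]
    if (length(w) > n_min) sample(w, n_min) else w
  }))
}

new_decoding_result <- function(accuracy, per_fold, mode, ...) {
  structure(c(list(accuracy = accuracy, per_fold = per_fold,
                   n_folds = if (is.matrix(per_fold)) nrow(per_fold) else length(per_fold),
                   mode = mode), list(...)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  if (length(x$accuracy) == 1L) {
    cat(sprintf("Decoding (%s): accuracy %.3f over %d folds\n",
                x$mode, x$accuracy, x$n_folds))
  } else {
    cat(sprintf("Decoding (%s): %d time points, %d folds; peak accuracy %.3f at %g ms\n",
                x$mode, length(x$accuracy), x$n_folds, max(x$accuracy),
                x$times_ms[which.max(x$accuracy)]))
  }
  invisible(x)
}

# --- exported operations ----------------------------------------------------

#' Leave-one-block-out fMRI decoding
#'
#' Binary linear-SVM classification of condition beta patterns: one fold per
#' block, training on all remaining blocks (voxels as features), accuracy
#' averaged over folds.
#'
#' @param betas A `beta_patterns` object.
#' @param labels Binary labelling of the conditions: vector of length
#'   `length(betas$condition_labels)` (character/factor/numeric, NA =
#'   condition excluded).
#' @return A `decoding_result` with scalar `accuracy` and `per_fold` vector.
#' @export
decode_fmri_lobo <- function(betas, labels) {
  nc <- length(betas$condition_labels)
  nb <- length(betas$block_ids)
  if (nb < 3L) stop("leave-one-block-out decoding needs at least 3 blocks")
  if (length(labels) != nc)
    stop("labels must have one entry per condition (", nc, ")")
  lab <- factor(labels)
  if (nlevels(lab) != 2L) stop("labels must define exactly 2 classes")
  sm <- beta_sample_matrix(betas)
  ylab <- lab[sm$cond]
  keep <- !is.na(ylab)
  per_fold <- lobo_core(sm$X[keep, , drop = FALSE], ylab[keep], sm$block[keep])
  names(per_fold) <- betas$block_ids[as.integer(names(per_fold))]
  new_decoding_result(mean(per_fold), per_fold, "fmri_lobo", roi = betas$roi)
}

#' Time-resolved MEG decoding
#'
#' Binary linear-SVM classification of sensor patterns independently at every
#' time sample, with a single stratified k-fold partition of trials reused
#' across all time points so the accuracy trace is temporally comparable.
#'
#' @param epochs A `sensor_epochs` object.
#' @param labels Per-trial binary labels (NA trials are dropped).
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment (and balancing subsamples).
#' @param balance Subsample the majority class within each training fold to
#'   match the minority class (default TRUE).
#' @return A `decoding_result` with `accuracy` vector over time and
#'   `per_fold` (fold x time) matrix.
#' @export
decode_meg_timecourse <- function(epochs, labels, k = 10L, seed = NULL,
                                  balance = TRUE) {
  if (k < 2L) stop("k must be at least 2")
  if (length(labels) != dim(epochs$values)[1])
    stop("labels must have one entry per trial")
  if (!is.null(seed)) set.seed(seed)
  y <- factor(labels)
  keep <- which(!is.na(y))
  y <- droplevels(y[keep])
  if (nlevels(y) != 2L) stop("labels must define exactly 2 classes")
  V <- epochs$values[keep, , , drop = FALSE]
  nt <- dim(V)[3]
  fold <- stratified_folds(y, k)
  train_sets <- lapply(seq_len(k), function(f) {
    idx <- which(fold != f)
    if (balance) balance_train(idx, y) else idx
  })
  yi <- as.integer(y)
  per_fold <- matrix(NA_real_, k, nt)
  for (f in seq_len(k)) {
    tr <- train_sets[[f]]
    te <- which(fold == f)
    ytr <- yi[tr]; yte <- yi[te]
    for (t in seq_len(nt)) {
      pred <- svm_predict_int(V[tr, , t, drop = TRUE], ytr,
                              V[te, , t, drop = TRUE])
      per_fold[f, t] <- mean(pred == yte)
    }
  }
  new_decoding_result(colMeans(per_fold), per_fold, "meg_timeresolved",
                      alignment = epochs$alignment, times_ms = epochs$times_ms,
                      k = k)
}

#' Label-permutation null distribution of decoding accuracy
#'
#' Repeats the full cross-validated decoding with shuffled class labels.
#' Shuffling respects the unit of exchangeability: for fMRI beta patterns the
#' condition labels are permuted within each block; for MEG epochs the trial
#' labels are permuted across trials.
#'
#' @param data A `beta_patterns` or `sensor_epochs` object.
#' @param labels As in [decode_fmri_lobo()] / [decode_meg_timecourse()].
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param ... Passed to the underlying decoder (e.g. `k` for MEG). For MEG
#'   epochs a single time sample must be selected via `time_index`.
#' @param time_index For `sensor_epochs`: index of the time sample to decode.
#' @return Numeric vector of `n_perm` null accuracies.
#' @export
permutation_null_decoding <- function(data, labels, n_perm = 1000L, seed = NULL,
                                      time_index = NULL, ...) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  if (inherits(data, "beta_patterns")) {
    nc <- length(data$condition_labels)
    nb <- length(data$block_ids)
    lab <- factor(labels)
    keep <- which(!is.na(lab))
    X <- do.call(rbind, lapply(keep, function(ci) data$values[ci, , ]))
    y0 <- rep(lab[keep], each = nb)
    block <- rep(data$block_ids, length(keep))
    vapply(seq_len(n_perm), function(p) {
      y <- y0
      for (b in unique(block)) {
        w <- which(block == b)
        y[w] <- y[w][sample(length(w))]
      }
      mean(lobo_core(X, factor(y), block))
    }, numeric(1))
  } else if (inherits(data, "sensor_epochs")) {
    if (is.null(time_index))
      stop("give time_index: permutation nulls are computed per time sample")
    ep1 <- data
    ep1$values <- data$values[, , time_index, drop = FALSE]
    ep1$times_ms <- data$times_ms[time_index]
    vapply(seq_len(n_perm), function(p) {
      decode_meg_timecourse(ep1, sample(labels), seed = NULL, ...)$accuracy
    }, numeric(1))
  } else stop("data must be beta_patterns or sensor_epochs")
}

#' Pairwise-condition decoding accuracies
#'
#' Decodes every unordered pair of the four scheme conditions, feeding the
#' neural RDMs. For fMRI the leave-one-block-out scheme is reused; for MEG a
#' stratified k-fold (with majority-class subsampling) is run at every time
#' point with one fold partition per pair.
#'
#' @param data A `beta_patterns` object, or a `sensor_epochs` object together
#'   with per-trial `conditions`.
#' @param conditions For MEG: factor of length n-trials with the scheme's 4
#'   condition levels (NA = excluded trial).
#' @param k,seed,balance MEG cross-validation controls.
#' @return For fMRI: a symmetric 4x4 accuracy matrix (diagonal NA). For MEG:
#'   a 4 x 4 x time array, with `times_ms` attribute.
#' @export
pairwise_condition_decoding <- function(data, conditions = NULL, k = 10L,
                                        seed = NULL, balance = TRUE) {
  if (inherits(data, "beta_patterns")) {
    conds <- data$condition_labels
    if (length(conds) != 4L) stop("pairwise decoding expects 4 conditions")
    if (length(data$block_ids) < 3L)
      stop("leave-one-block-out decoding needs at least 3 blocks")
    sm <- beta_sample_matrix(data)
    pairwise_lobo_acc(sm$X, sm$cond, sm$block, conds)
  } else if (inherits(data, "sensor_epochs")) {
    if (is.null(conditions)) stop("conditions are required for MEG pairwise decoding")
    if (!is.null(seed)) set.seed(seed)
    conds <- levels(conditions)
    if (length(conds) != 4L) stop("pairwise decoding expects 4 condition levels")
    if (any(table(conditions) == 0))
      stop("condition level(s) missing from the data: ",
           paste(conds[table(conditions) == 0], collapse = ", "))
    nt <- dim(data$values)[3]
    acc <- array(NA_real_, c(4, 4, nt), dimnames = list(conds, conds, NULL))
    for (i in 1:3) for (j in (i + 1):4) {
      lab <- rep(NA_character_, length(conditions))
      lab[conditions == conds[i]] <- "a"
      lab[conditions == conds[j]] <- "b"
      r <- decode_meg_timecourse(data, lab, k = k, seed = NULL, balance = balance)
      acc[i, j, ] <- acc[j, i, ] <- r$accuracy
    }
    attr(acc, "times_ms") <- data$times_ms
    acc
  } else stop("data must be beta_patterns or sensor_epochs")
}
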