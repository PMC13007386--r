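#' Specify a planted multivariate effect
#'
#' Describes ground truth planted by the synthetic-data generator: which
#' information type carries signal, where (an fMRI ROI and/or an MEG time
#' window), and how strongly. Effect size is the Euclidean norm of the latent
#' multivariate pattern (over voxels / sensors) in units of the noise SD: a
#' multivariate effect amplitude comparable across ROI sizes.
#'
#' @param info_type One of `"across"`, `"within"`, `"rule"`, `"response"`.
#' @param effect_size Non-negative pattern amplitude in noise-SD units.
#' @param roi ROI id the effect lives in (NULL = every ROI).
#' @param window_ms Length-2 numeric MEG time window (ms) in which the effect
#'   is on; NULL for fMRI-only effects.
#' @param frame Frame the window is expressed in: `"stimulus"` (relative to
#'   stimulus onset) or `"response"` (relative to the button press).
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(info_type, effect_size, roi = NULL, window_ms = NULL,
                        frame = c("stimulus", "response")) {
  frame <- match.arg(frame)
  if (!info_type %in% INFO_TYPES)
    stop("info_type must be one of: ", paste(INFO_TYPES, collapse = ", "))
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be a non-negative number")
  if (!is.null(window_ms) && (length(window_ms) != 2L || window_ms[1] >= window_ms[2]))
    stop("window_ms must be c(start, end) with start < end")
  structure(list(info_type = info_type, effect_size = effect_size, roi = roi,
                 window_ms = window_ms, frame = frame),
            class = "effect_spec")
}

# Orthogonal unit-norm latent patterns, one per level of a feature.
# effect_size scales the whole pattern vector, so it is the Euclidean norm of
# the planted multivariate pattern in noise-SD units (a multivariate effect
# amplitude, comparable across ROI sizes).
latent_level_patterns <- function(levels, n_dim) {
  u <- unique(stats::na.omit(levels))
  p <- matrix(stats::rnorm(length(u) * n_dim), length(u), n_dim,
              dimnames = list(u, NULL))
  if (length(u) >= 2L) {
    # Gram-Schmidt so planted contrasts are unambiguous
    for (i in seq_len(nrow(p))[-1]) {
      for (j in seq_len(i - 1L)) {
        p[i, ] <- p[i, ] - sum(p[i, ] * p[j, ]) / sum(p[j, ]^2) * p[j, ]
      }
    }
  }
  p / sqrt(rowSums(p^2))
}

#' Simulate condition-wise fMRI beta patterns for a set of ROIs
#'
#' Generates block-wise condition beta patterns directly at the condition
#' level: each condition's expected pattern is a fixed latent voxel pattern
#' determined by the planted effects, and each (condition, block) estimate is
#' that pattern plus i.i.d. Gaussian noise. ROIs with no matching effect spec
#' carry pure noise for that contrast.
#'
#' @param trials A `trial_table` (defines the number of blocks).
#' @param roi_specs List of lists with `roi` and `n_voxels` (and optionally
#'   `hemisphere`).
#' @param effect_specs List of [effect_spec()] objects.
#' @param scheme RSA scheme name defining the 4 condition labels.
#' @param noise_sd Noise SD of the beta estimates (default 1).
#' @param seed Integer seed; same inputs + seed give bit-identical output.
#' @param colour_rule_map Cue-colour to rule map (rule scheme labels).
#' @return Named list of `beta_patterns` objects, one per ROI, each holding a
#'   (condition x block x voxel) array.
#' @export
simulate_fmri_betas <- function(trials, roi_specs, effect_specs = list(),
                                scheme, noise_sd = 1, seed = NULL,
                                colour_rule_map = default_colour_rule_map()) {
  sch <- rsa_scheme(scheme, colour_rule_map)
  if (!is.null(seed)) set.seed(seed)
  blocks <- sort(unique(trials$block))
  nb <- length(blocks)
  nc <- length(sch$conditions)
  if (inherits(effect_specs, "effect_spec")) effect_specs <- list(effect_specs)

  out <- lapply(roi_specs, function(rs) {
    v <- rs$n_voxels
    if (is.null(v) || v < 1) stop("each roi_spec needs a positive n_voxels")
    mu <- matrix(0, nc, v)
    for (es in effect_specs) {
      if (!is.null(es$roi) && !identical(es$roi, rs$roi)) next
      lev <- sch$factors[[es$info_type]]
      if (is.null(lev))
        stop("effect info_type '", es$info_type,
             "' does not match scheme '", scheme, "' labels")
      pat <- latent_level_patterns(lev, v)
      for (ci in seq_len(nc)) {
        if (!is.na(lev[ci]))
          mu[ci, ] <- mu[ci, ] + es$effect_size * pat[lev[ci], ]
      }
    }
    vals <- array(stats::rnorm(nc * nb * v, sd = noise_sd), dim = c(nc, nb, v))
    vals <- vals + aperm(array(mu, dim = c(nc, v, nb)), c(1, 3, 2))
    beta_patterns(rs$roi, vals, sch$conditions, blocks,
                  hemisphere = if (is.null(rs$hemisphere)) "bilateral" else rs$hemisphere,
                  scheme = scheme)
  })
  names(out) <- vapply(roi_specs, function(rs) rs$roi, character(1))
  out
}

#' Construct a beta_patterns container
#'
#' @param roi ROI id.
#' @param values Numeric array (condition x block x voxel), finite.
#' @param condition_labels Character vector matching dim 1.
#' @param block_ids Vector matching dim 2.
#' @param hemisphere `"left"`, `"right"` or `"bilateral"`.
#' @param scheme RSA scheme the condition labels come from.
#' @return A `beta_patterns` object.
#' @export
beta_patterns <- function(roi, values, condition_labels, block_ids,
                          hemisphere = "bilateral", scheme = NULL) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(condition_labels),
            dim(values)[2] == length(block_ids))
  if (!all(is.finite(values))) stop("beta values must be finite")
  structure(list(roi = roi, hemisphere = hemisphere,
                 condition_labels = condition_labels,
                 block_ids = block_ids, values = values,
                 n_voxels = dim(values)[3], scheme = scheme),
            class = "beta_patterns")
}

#' @export
print.beta_patterns <- function(x, ...) {
  cat(sprintf("Beta patterns: ROI %s (%s), %d conditions x %d blocks x %d voxels\n",
              x$roi, x$hemisphere, length(x$condition_labels),
              length(x$block_ids), x$n_voxels))
  invisible(x)
}

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response peak minus undershoot), the
#' standard first-order haemodynamic model: peak at 6 s, undershoot at 16 s,
#' peak-to-undershoot ratio 6.
#'
#' @param t Time in seconds (vector).
#' @param peak,undershoot Gamma shape parameters (rate 1) in seconds.
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    stats::dgamma(t, shape = undershoot, rate = 1) / ratio
  h[t < 0] <- 0
  h
}

#' Build a first-level design matrix for one RSA scheme
#'
#' Trials are modelled as epochs lasting from stimulus onset until the
#' response (duration = reaction time), convolved with the canonical
#' double-gamma HRF. One regressor per condition per block, plus one constant
#' column per block. Incorrect and omitted trials are excluded. Stimulus
#' onsets are laid out deterministically from the paradigm timing (500 ms
#' fixation, then the stimulus/response period of duration RT, or the full
#' 4.5 s response window on omissions).
#'
#' @param trials A `trial_table`.
#' @param scheme RSA scheme name.
#' @param tr_s Repetition time in seconds (default 2).
#' @param hrf_params List overriding `peak`, `undershoot`, `ratio`.
#' @param colour_rule_map,response_colours Passed to [scheme_conditions()].
#' @return Numeric design matrix (scans x columns) of class `fmri_design`,
#'   with attributes `condition` and `block` (per task column; NA for
#'   constants), `scan_block` (per row), and `empty_columns` flagging task
#'   regressors with no events in their block.
#' @export
build_design_matrix <- function(trials, scheme, tr_s = 2, hrf_params = list(),
                                colour_rule_map = default_colour_rule_map(),
                                response_colours = NULL) {
  hp <- utils::modifyList(list(peak = 6, undershoot = 16, ratio = 6), hrf_params)
  cond <- scheme_conditions(trials, scheme, colour_rule_map, response_colours)
  conditions <- levels(cond)
  rt_s <- trials$rt_ms / 1000
  if (any(!is.na(rt_s) & rt_s <= 0))
    stop("zero-duration epochs: all reaction times must be positive")
  dt <- 0.1
  blocks <- sort(unique(trials$block))

  X_blocks <- vector("list", length(blocks))
  scan_block <- integer(0)
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    tb <- trials[trials$block == b, , drop = FALSE]
    cb <- cond[trials$block == b]
    # deterministic onsets from the paradigm timing
    dur <- ifelse(is.na(tb$rt_ms), 4.5, tb$rt_ms / 1000)
    onset <- 0.5 + cumsum(c(0, utils::head(dur + 0.5, -1)))
    # pad past the HRF support so late regressors decay within the block
    t_end <- onset[length(onset)] + dur[length(dur)] + 28
    n_scan <- ceiling(t_end / tr_s)
    fine_t <- seq(0, n_scan * tr_s, by = dt)
    hrf <- hrf_double_gamma(seq(0, 32, by = dt), hp$peak, hp$undershoot, hp$ratio)
    Xb <- matrix(0, n_scan, length(conditions))
    for (ci in seq_along(conditions)) {
      sel <- which(!is.na(cb) & cb == conditions[ci])
      box <- numeric(length(fine_t))
      for (k in sel) {
        box[fine_t >= onset[k] & fine_t < onset[k] + tb$rt_ms[k] / 1000] <- 1
      }
      conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine_t)] * dt
      scan_t <- (seq_len(n_scan) - 1L) * tr_s
      Xb[, ci] <- conv[round(scan_t / dt) + 1L]
    }
    X_blocks[[bi]] <- Xb
    scan_block <- c(scan_block, rep(b, n_scan))
  }
  n_total <- length(scan_block)
  nc <- length(conditions)
  X <- matrix(0, n_total, nc * length(blocks) + length(blocks))
  col_cond <- rep(NA_character_, ncol(X))
  col_block <- rep(NA_integer_, ncol(X))
  for (bi in seq_along(blocks)) {
    rows <- scan_block == blocks[bi]
    cols <- (bi - 1L) * nc + seq_len(nc)
    X[rows, cols] <- X_blocks[[bi]]
    col_cond[cols] <- conditions
    col_block[cols] <- blocks[bi]
    ccol <- nc * length(blocks) + bi
    X[rows, ccol] <- 1
    col_block[ccol] <- blocks[bi]
  }
  colnames(X) <- ifelse(is.na(col_cond),
                        paste0("const:b", col_block),
                        paste0(col_cond, ":b", col_block))
  empty <- !is.na(col_cond) & colSums(abs(X)) == 0
  structure(X, condition = col_cond, block = col_block,
            scan_block = scan_block, scheme = scheme,
            empty_columns = colnames(X)[empty], class = c("fmri_design", "matrix"))
}

#' Fit the first-level GLM
#'
#' Ordinary least squares of a (time x voxel) BOLD matrix on an
#' [build_design_matrix()] design. Task-regressor estimates are reshaped into
#' a (condition x block x voxel) `beta_patterns` array; constants are
#' discarded. A rank-deficient design triggers a warning and the minimum-norm
#' (pseudo-inverse) solution.
#'
#' @param bold Numeric matrix, scans x voxels.
#' @param design An `fmri_design`.
#' @param roi ROI id recorded on the result.
#' @param hemisphere Hemisphere label.
#' @return A `beta_patterns` object.
#' @export
fit_glm <- function(bold, design, roi = "roi", hemisphere = "bilateral") {
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(design))
    stop("bold has ", nrow(bold), " rows but the design has ", nrow(design))
  X <- unclass(design)
  attributes(X) <- list(dim = dim(design), dimnames = dimnames(design))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("design is rank deficient (rank ", qrX$rank, " < ", ncol(X),
            "); returning the minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], bold) / sv$d[pos])
  } else {
    beta <- qr.coef(qrX, bold)
  }
  cond <- attr(design, "condition")
  blk <- attr(design, "block")
  conditions <- unique(cond[!is.na(cond)])
  blocks <- sort(unique(blk[!is.na(cond)]))
  vals <- array(NA_real_, c(length(conditions), length(blocks), ncol(bold)))
  for (ci in seq_along(conditions)) {
    for (bi in seq_along(blocks)) {
      j <- which(!is.na(cond) & cond == conditions[ci] & blk == blocks[bi])
      vals[ci, bi, ] <- beta[j, ]
    }
  }
  beta_patterns(roi, vals, conditions, blocks, hemisphere,
                scheme = attr(design, "scheme"))
}
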