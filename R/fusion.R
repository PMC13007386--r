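#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties get average ranks).
#' Returns NA (rather than an error) when either vector is constant, and
#' propagates that missingness downstream.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or NA if undefined.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Partial Spearman correlation of x and y given z
#'
#' Computed on the pairwise Spearman correlations:
#' \deqn{\rho_{xy.z} = \frac{\rho_{xy} - \rho_{xz}\rho_{yz}}
#'   {\sqrt{1-\rho_{xz}^2}\sqrt{1-\rho_{yz}^2}}}{
#'   (rxy - rxz * ryz) / (sqrt(1 - rxz^2) * sqrt(1 - ryz^2))}
#' Undefined (NA, never +/-Inf) when either denominator correlation is 1 in
#' magnitude within `eps`.
#'
#' @param x,y,z Numeric vectors of equal length.
#' @param eps Degeneracy tolerance (default 1e-10).
#' @return Partial correlation, or NA if degenerate.
#' @export
partial_spearman <- function(x, y, z, eps = 1e-10) {
  rxy <- spearman_rho(x, y)
  rxz <- spearman_rho(x, z)
  ryz <- spearman_rho(y, z)
  if (is.na(rxy) || is.na(rxz) || is.na(ryz)) return(NA_real_)
  if (abs(rxz) >= 1 - eps || abs(ryz) >= 1 - eps) return(NA_real_)
  (rxy - rxz * ryz) / (sqrt(1 - rxz^2) * sqrt(1 - ryz^2))
}

#' Three-way commonality index
#'
#' The variance shared simultaneously by an fMRI RDV, an MEG RDV, and a model
#' RDV: the raw Spearman correlation between the two neural RDVs minus their
#' partial Spearman correlation given the model,
#' \deqn{C = \rho_{fMRI,MEG} - \rho_{fMRI,MEG | Model}.}{C = rho(fMRI, MEG) - rho(fMRI, MEG | Model).}
#' A rank-orthogonal model leaves the partial equal to the raw correlation
#' and the index is zero; a model rank-identical to either neural RDV makes
#' the partial undefined and the index is NA with a `reason` attribute.
#'
#' @param fmri_rdv,meg_rdv,model_rdv Numeric RDVs of equal length.
#' @return The commonality index (scalar), NA when degenerate.
#' @export
commonality_index <- function(fmri_rdv, meg_rdv, model_rdv) {
  f <- as.numeric(fmri_rdv); g <- as.numeric(meg_rdv); m <- as.numeric(model_rdv)
  if (length(f) != length(g) || length(f) != length(m))
    stop("all three RDVs must have the same length")
  raw <- spearman_rho(f, g)
  if (is.na(raw))
    return(structure(NA_real_, reason = "constant neural RDV"))
  part <- partial_spearman(f, g, m)
  if (is.na(part))
    return(structure(NA_real_, reason = "model rank-identical to a neural RDV"))
  raw - part
}

#' Commonality time course for one ROI and one model
#'
#' Applies [commonality_index()] at every MEG time point, storing the
#' component correlations for audit.
#'
#' @param fmri_rdv Numeric 6-vector (the ROI's dissimilarities).
#' @param meg_rdv_stack 6 x T matrix of MEG RDVs over time.
#' @param model_rdv Numeric 6-vector (binary model dissimilarities).
#' @param times_ms Time grid of length T.
#' @param roi,info_type,alignment Metadata recorded on the trace.
#' @return A `commonality_trace` object (without inference fields until
#'   [permutation_test_commonality()] is applied).
#' @export
commonality_timecourse <- function(fmri_rdv, meg_rdv_stack, model_rdv,
                                   times_ms, roi = "roi", info_type = NA,
                                   alignment = "stimulus") {
  meg_rdv_stack <- as.matrix(meg_rdv_stack)
  nt <- ncol(meg_rdv_stack)
  if (length(times_ms) != nt)
    stop("times_ms length must match the stack's time dimension")
  f <- as.numeric(fmri_rdv); m <- as.numeric(model_rdv)
  rho_fm <- spearman_rho(f, m)
  rho_fg <- rho_gm <- com <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    g <- meg_rdv_stack[, t]
    rho_fg[t] <- spearman_rho(f, g)
    rho_gm[t] <- spearman_rho(g, m)
    com[t] <- as.numeric(commonality_index(f, g, m))
  }
  structure(list(roi = roi, info_type = info_type, alignment = alignment,
                 times_ms = times_ms, commonality = com,
                 rho_fmri_meg = rho_fg, rho_fmri_model = rho_fm,
                 rho_meg_model = rho_gm,
                 p_values = NULL, q_values = NULL, sig_mask = NULL,
                 n_perm = 0L, alpha = NA_real_),
            class = "commonality_trace")
}

#' Storey q-values
#'
#' Adaptive FDR control: the proportion of true nulls is estimated from the
#' upper tail of the p-value distribution, `pi0 = #{p > lambda} / (m (1 -
#' lambda))` (capped at 1), and q-values are the step-up minima `q(i) =
#' min_{j >= i} pi0 * m * p(j) / j` on the sorted p-values. With fewer than
#' 10 p-values the estimate of pi0 is hopeless and the function falls back to
#' Benjamini-Hochberg with a warning.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA allowed,
#'   propagated).
#' @param lambda Tuning parameter in (0, 1) for the pi0 estimate (default
#'   0.5). A vector of lambdas averages the per-lambda estimates (a simple
#'   smoother).
#' @return Vector of q-values, monotone in p, in `[0, 1]`.
#' @export
storey_fdr <- function(p_values, lambda = 0.5) {
  ok <- which(!is.na(p_values))
  p <- p_values[ok]
  q_all <- rep(NA_real_, length(p_values))
  if (length(p) == 0L) return(q_all)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (length(p) < 10L) {
    warning("fewer than 10 p-values; falling back to Benjamini-Hochberg")
    q_all[ok] <- stats::p.adjust(p, method = "BH")
    return(q_all)
  }
  if (any(lambda <= 0 | lambda >= 1)) stop("lambda must lie in (0, 1)")
  m <- length(p)
  pi0 <- mean(vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1)))
  pi0 <- min(1, max(pi0, 0))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q_all[ok] <- q
  q_all
}

# Standardised average ranks: crossprod of two such vectors is their
# Spearman correlation. NULL for constant vectors (undefined correlation).
rank_std <- function(v) {
  r <- rank(v)
  s <- stats::sd(r)
  if (s == 0) return(NULL)
  (r - mean(r)) / (s * sqrt(length(r) - 1))
}

# Vectorised commonality trace for a single fMRI RDV against a pre-ranked
# MEG stack; numerically identical to elementwise commonality_index().
# gs: 6 x T matrix of standardised MEG ranks (NA column = constant RDV);
# gm: length-T vector of Spearman(MEG_t, model); ms: standardised model ranks.
fast_commonality <- function(f, gs, gm, ms, eps = 1e-10) {
  nt <- ncol(gs)
  fs <- rank_std(f)
  if (is.null(fs)) return(rep(NA_real_, nt))
  rfg <- as.vector(crossprod(fs, gs))
  rfm <- sum(fs * ms)
  den2 <- (1 - rfm^2) * (1 - gm^2)
  part <- (rfg - rfm * gm) / sqrt(pmax(den2, 0))
  com <- rfg - part
  com[is.na(rfg) | is.na(gm) | abs(rfm) >= 1 - eps | abs(gm) >= 1 - eps] <- NA_real_
  com
}

#' Permutation test for a commonality time course
#'
#' The null distribution is built by shuffling the fMRI condition labels
#' (within each block), regenerating the fMRI RDM by rerunning the pairwise
#' leave-one-block-out decoding, and recomputing the full commonality time
#' course, `n_perm` times. MEG RDVs and the model are held fixed, so the null
#' breaks only the fMRI-side condition structure. One-tailed (positive)
#' p-values use the add-one count estimator `p = (1 + #{null >= obs}) / (1 +
#' n_perm)`; q-values are Storey-corrected across the time points of the
#' trace, and a time point is significant when `q < alpha` and its
#' commonality is positive.
#'
#' @param trace A `commonality_trace` (the observed time course).
#' @param fmri_betas The `beta_patterns` the trace's fMRI RDV came from; a
#'   list of them for group-level traces (each permutation then shuffles
#'   every participant and averages the regenerated RDVs).
#' @param meg_rdv_stack,model_rdv As used for the observed trace.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param alpha Significance level (default 0.05).
#' @param lambda Storey lambda (default 0.5).
#' @param seed Integer seed.
#' @return The trace with `p_values`, `q_values`, `sig_mask` filled in and
#'   the null 95th-percentile trace in `null_q95`.
#' @export
permutation_test_commonality <- function(trace, fmri_betas, meg_rdv_stack,
                                         model_rdv, n_perm = 1000L,
                                         alpha = 0.05, lambda = 0.5,
                                         seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  meg_rdv_stack <- as.matrix(meg_rdv_stack)
  nt <- ncol(meg_rdv_stack)
  m <- as.numeric(model_rdv)
  obs <- trace$commonality
  if (all(is.na(obs))) {
    warning("all commonality values are missing; empty significance mask")
    trace$p_values <- rep(NA_real_, nt)
    trace$q_values <- rep(NA_real_, nt)
    trace$sig_mask <- rep(FALSE, nt)
    return(trace)
  }
  ms <- rank_std(m)
  if (is.null(ms)) stop("the model RDV is constant; commonality is undefined")
  gs <- matrix(NA_real_, 6, nt)
  gm <- rep(NA_real_, nt)
  for (t in seq_len(nt)) {
    v <- rank_std(meg_rdv_stack[, t])
    if (!is.null(v)) {
      gs[, t] <- v
      gm[t] <- sum(v * ms)
    }
  }
  if (inherits(fmri_betas, "beta_patterns")) fmri_betas <- list(fmri_betas)
  sms <- lapply(fmri_betas, beta_sample_matrix)
  conds <- fmri_betas[[1]]$condition_labels
  lt <- lower.tri(matrix(0, 4, 4))
  null_mat <- matrix(NA_real_, n_perm, nt)
  for (pi in seq_len(n_perm)) {
    f_null <- rowMeans(vapply(sms, function(sm) {
      cond_perm <- sm$cond
      for (b in unique(sm$block)) {
        w <- which(sm$block == b)
        cond_perm[w] <- cond_perm[w][sample(length(w))]
      }
      (1 - pairwise_lobo_acc(sm$X, cond_perm, sm$block, conds))[lt]
    }, numeric(6)))
    null_mat[pi, ] <- fast_commonality(f_null, gs, gm, ms)
  }
  p <- vapply(seq_len(nt), function(t) {
    if (is.na(obs[t])) return(NA_real_)
    nv <- null_mat[, t]
    nv <- nv[!is.na(nv)]
    (1 + sum(nv >= obs[t])) / (1 + length(nv))
  }, numeric(1))
  q <- storey_fdr(p, lambda)
  trace$p_values <- p
  trace$q_values <- q
  trace$sig_mask <- !is.na(q) & q < alpha & !is.na(obs) & obs > 0
  trace$n_perm <- n_perm
  trace$alpha <- alpha
  trace$null_q95 <- apply(null_mat, 2, stats::quantile, probs = 0.95, na.rm = TRUE)
  trace
}

#' Temporal metrics of a commonality trace
#'
#' Three summary times extracted from a (tested) commonality time course:
#' time to the first significant commonality (earliest significant time point
#' at or after 0 for stimulus-aligned traces; earliest significant point for
#' response-aligned ones), time of the maximum commonality, and the time from
#' that maximum to the response (for stimulus-aligned traces, relative to
#' `response_ref_ms`; for response-aligned traces the maximum's own time
#' relative to the response at 0).
#'
#' @param trace A `commonality_trace` with a significance mask.
#' @param response_ref_ms Reference response time in ms after stimulus onset
#'   (stimulus-aligned traces only).
#' @return A `temporal_metrics` list with `time_to_first_sig_ms`,
#'   `time_to_max_ms`, `time_from_max_to_response_ms` and a `reliable` flag
#'   (FALSE when the trace never reaches significance).
#' @export
temporal_metrics <- function(trace, response_ref_ms = NULL) {
  tms <- trace$times_ms
  com <- trace$commonality
  sig <- trace$sig_mask
  if (is.null(sig)) stop("run permutation_test_commonality() first")
  cand <- if (trace$alignment == "stimulus") sig & tms >= 0 else sig
  first_sig <- if (any(cand, na.rm = TRUE)) min(tms[which(cand)]) else NA_real_
  t_max <- if (all(is.na(com))) NA_real_ else tms[which.max(com)]
  from_max <- if (is.na(t_max)) NA_real_
              else if (trace$alignment == "response") -t_max
              else if (!is.null(response_ref_ms)) response_ref_ms - t_max
              else NA_real_
  structure(list(time_to_first_sig_ms = first_sig,
                 time_to_max_ms = t_max,
                 time_from_max_to_response_ms = from_max,
                 reliable = any(cand, na.rm = TRUE)),
            class = "temporal_metrics")
}

#' @export
print.temporal_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "N/A" else sprintf("%g ms", v)
  cat("Temporal commonality metrics",
      if (!x$reliable) " (no significant time points; unreliable)" else "", ":\n",
      sep = "")
  cat("  time to first significant commonality:", fmt(x$time_to_first_sig_ms), "\n")
  cat("  time to maximum commonality:          ", fmt(x$time_to_max_ms), "\n")
  cat("  time from maximum to response:        ", fmt(x$time_from_max_to_response_ms), "\n")
  invisible(x)
}
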