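#' Model-based MEG-fMRI fusion for one ROI and one information type
#'
#' The package's central fitting function. From condition-wise fMRI beta
#' patterns (one ROI) and MEG sensor epochs it builds decoding-based
#' representational dissimilarity vectors (leave-one-block-out pairwise SVM
#' decoding for fMRI; time-resolved stratified k-fold pairwise decoding for
#' MEG), correlates them with the binary model RDV of the requested
#' information type, and returns the commonality time course
#' \deqn{C(t) = \rho_{fMRI,MEG(t)} - \rho_{fMRI,MEG(t) | Model}}{C(t) = rho(fMRI, MEG(t)) - rho(fMRI, MEG(t) | Model)}
#' together with permutation-based one-tailed significance (fMRI condition
#' labels shuffled within block, RDM regenerated, Storey FDR across time) and
#' the derived temporal metrics.
#'
#' Group-level fusion: all RDM inputs may be per-participant lists. The
#' neural RDMs are then averaged across participants before correlation
#' (fusion operates on group-averaged data), and each permutation reshuffles
#' every participant's fMRI condition labels and re-averages, so the null
#' respects the group structure.
#'
#' @param fmri_betas A `beta_patterns` object whose condition labels follow
#'   the scheme of `info_type` (see [rsa_scheme()]), or a list of them (one
#'   per participant).
#' @param meg_epochs A `sensor_epochs` object, or a list of them (one per
#'   participant, on identical time grids).
#' @param info_type `"across"`, `"within"`, `"rule"` or `"response"`.
#' @param trials The `trial_table` behind `meg_epochs` (used to derive the
#'   per-trial condition of each MEG trial, and the response reference time);
#'   a list when `meg_epochs` is a list.
#' @param meg_conditions Optional explicit per-trial condition factor(s)
#'   (overrides derivation from `trials`).
#' @param n_perm Permutations for inference (0 skips inference; default 1000).
#' @param alpha One-tailed significance level after FDR (default 0.05).
#' @param lambda Storey lambda (default 0.5).
#' @param k MEG cross-validation folds (default 10).
#' @param balance Balance MEG training folds by subsampling (default TRUE).
#' @param seed Integer seed driving every random element of the fit.
#' @param response_ref_ms Response reference for stimulus-aligned temporal
#'   metrics; defaults to the median correct RT in `trials`.
#' @param colour_rule_map,response_colours,cross_value Scheme and model
#'   options, see [scheme_conditions()] and [build_model_rdm()].
#' @return A `commonality_trace` object with components `commonality`,
#'   `rho_fmri_meg`, `rho_fmri_model`, `rho_meg_model`, `p_values`,
#'   `q_values`, `sig_mask`, `metrics`, plus the underlying `fmri_rdm`,
#'   `meg_rdv_stack` and `model_rdm`. Methods: `print`, `summary`, `plot`.
#' @export
commonality_fusion <- function(fmri_betas, meg_epochs, info_type,
                               trials = NULL, meg_conditions = NULL,
                               n_perm = 1000L, alpha = 0.05, lambda = 0.5,
                               k = 10L, balance = TRUE, seed = NULL,
                               response_ref_ms = NULL,
                               colour_rule_map = default_colour_rule_map(),
                               response_colours = NULL, cross_value = 0.5) {
  sch <- rsa_scheme(info_type, colour_rule_map)
  if (inherits(fmri_betas, "beta_patterns")) fmri_betas <- list(fmri_betas)
  if (inherits(meg_epochs, "sensor_epochs")) meg_epochs <- list(meg_epochs)
  if (inherits(trials, "trial_table")) trials <- list(trials)
  if (is.factor(meg_conditions)) meg_conditions <- list(meg_conditions)
  np <- length(meg_epochs)
  for (b in fmri_betas) {
    if (!identical(b$condition_labels, sch$conditions))
      stop("fmri_betas condition labels do not follow the '", info_type,
           "' scheme (expected ", paste(sch$conditions, collapse = ", "), ")")
  }
  if (is.null(meg_conditions)) {
    if (is.null(trials))
      stop("either trials or meg_conditions must be given")
    if (length(trials) != np)
      stop("trials must have one trial table per participant")
    meg_conditions <- lapply(seq_len(np), function(p) {
      cond_all <- scheme_conditions(trials[[p]], info_type, colour_rule_map,
                                    response_colours)
      cond_all[match(meg_epochs[[p]]$trial_ids, trials[[p]]$trial_id)]
    })
  }
  times_ms <- meg_epochs[[1]]$times_ms
  alignment <- meg_epochs[[1]]$alignment
  for (e in meg_epochs) {
    if (!isTRUE(all.equal(e$times_ms, times_ms)) || e$alignment != alignment)
      stop("all participants' epochs must share one time grid and alignment")
  }
  if (!is.null(seed)) set.seed(seed)

  fmri_rdms <- lapply(fmri_betas, function(b)
    build_neural_rdm(pairwise_condition_decoding(b), info_type,
                     source = "neural_fmri"))
  fmri_rdm <- if (length(fmri_rdms) > 1L)
    aggregate_rdms(fmri_rdms, "participant") else fmri_rdms[[1]]
  f_rdv <- as.numeric(rdm_to_rdv(fmri_rdm))

  stacks <- lapply(seq_len(np), function(p)
    rdv_stack_from_accuracy(
      pairwise_condition_decoding(meg_epochs[[p]], meg_conditions[[p]],
                                  k = k, balance = balance)))
  stack <- Reduce(`+`, stacks) / np

  model_rdm <- build_model_rdm(info_type, colour_rule_map, cross_value)
  m_rdv <- as.numeric(rdm_to_rdv(model_rdm))

  trace <- commonality_timecourse(f_rdv, stack, m_rdv, times_ms,
                                  roi = fmri_betas[[1]]$roi,
                                  info_type = info_type,
                                  alignment = alignment)
  trace$n_participants <- length(fmri_betas)
  if (n_perm > 0L) {
    trace <- permutation_test_commonality(trace, fmri_betas, stack, m_rdv,
                                          n_perm = n_perm, alpha = alpha,
                                          lambda = lambda)
  }
  if (is.null(response_ref_ms) && !is.null(trials)) {
    rts <- unlist(lapply(trials, function(tt) tt$rt_ms[tt$correct]))
    response_ref_ms <- stats::median(rts, na.rm = TRUE)
  }
  trace$metrics <- if (!is.null(trace$sig_mask))
    temporal_metrics(trace, response_ref_ms) else NULL
  trace$response_ref_ms <- response_ref_ms
  trace$fmri_rdm <- fmri_rdm
  trace$model_rdm <- model_rdm
  trace$meg_rdv_stack <- stack
  trace$k <- k
  trace$call <- match.call()
  trace
}

#' @export
print.commonality_trace <- function(x, ...) {
  cat(sprintf("Commonality trace: ROI %s, %s information, %s-aligned\n",
              x$roi, x$info_type, x$alignment))
  cat(sprintf("  %d time points (%g..%g ms)\n", length(x$times_ms),
              min(x$times_ms), max(x$times_ms)))
  if (all(is.na(x$commonality))) {
    cat("  all commonality values missing\n")
    return(invisible(x))
  }
  imax <- which.max(x$commonality)
  cat(sprintf("  peak commonality %.4f at %g ms\n",
              x$commonality[imax], x$times_ms[imax]))
  if (!is.null(x$sig_mask)) {
    ns <- sum(x$sig_mask, na.rm = TRUE)
    cat(sprintf("  %d significant time point%s (one-tailed, %d permutations, q < %g)\n",
                ns, if (ns == 1) "" else "s", x$n_perm, x$alpha))
  } else {
    cat("  no inference run (n_perm = 0)\n")
  }
  invisible(x)
}

#' @export
summary.commonality_trace <- function(object, ...) {
  x <- object
  print(x)
  gm <- x$rho_meg_model[!is.na(x$rho_meg_model)]
  cat(sprintf("  rho(fMRI, model) = %.3f; rho(MEG, model) extreme = %.3f\n",
              x$rho_fmri_model, gm[which.max(abs(gm))]))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Plot a commonality time course
#'
#' Base-graphics trace of the commonality index over time; significant time
#' points (if inference was run) are drawn with a thickened line, and the
#' permutation null's 95th percentile is shown dashed.
#'
#' @param x A `commonality_trace`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.commonality_trace <- function(x, ...) {
  graphics::plot(x$times_ms, x$commonality, type = "l",
                 xlab = sprintf("time relative to %s (ms)", x$alignment),
                 ylab = "commonality index",
                 main = sprintf("%s: %s information", x$roi, x$info_type), ...)
  graphics::abline(h = 0, lty = 3)
  graphics::abline(v = 0, lty = 3)
  if (!is.null(x$null_q95))
    graphics::lines(x$times_ms, x$null_q95, lty = 2, col = "grey50")
  if (!is.null(x$sig_mask) && any(x$sig_mask)) {
    y <- x$commonality
    y[!x$sig_mask] <- NA
    graphics::lines(x$times_ms, y, lwd = 3)
  }
  invisible(x)
}

#' Tidy data frame of a commonality trace
#'
#' @param x A `commonality_trace`.
#' @param ... Unused.
#' @return Data frame with one row per time point: roi, info_type, alignment,
#'   time_ms, commonality, component correlations, p, q, sig.
#' @export
as.data.frame.commonality_trace <- function(x, ...) {
  data.frame(roi = x$roi, info_type = x$info_type, alignment = x$alignment,
             time_ms = x$times_ms, commonality = x$commonality,
             rho_fmri_meg = x$rho_fmri_meg,
             rho_fmri_model = x$rho_fmri_model,
             rho_meg_model = x$rho_meg_model,
             p = if (is.null(x$p_values)) NA_real_ else x$p_values,
             q = if (is.null(x$q_values)) NA_real_ else x$q_values,
             sig = if (is.null(x$sig_mask)) NA else x$sig_mask)
}
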