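#' Build a neural RDM from pairwise decoding accuracies
#'
#' Dissimilarity = 1 - decoding accuracy (accuracy scaled 0..1), so chance
#' decoding maps to 0.5 and perfect separation to 0.
#'
#' @param pairwise_acc Symmetric 4x4 accuracy matrix (diagonal NA), as
#'   returned by [pairwise_condition_decoding()].
#' @param info_type Information type the RDM targets.
#' @param source Provenance tag, e.g. `"neural_fmri"` or `"neural_meg"`.
#' @return An `rdm` object.
#' @export
build_neural_rdm <- function(pairwise_acc, info_type, source = "neural_fmri") {
  m <- as.matrix(pairwise_acc)
  off <- m[row(m) != col(m)]
  if (any(!is.na(off) & (off < 0 | off > 1)))
    stop("decoding accuracies must lie in [0, 1]")
  if (any(abs(m - t(m)) > 1e-9, na.rm = TRUE))
    stop("pairwise accuracy matrix must be symmetric")
  d <- 1 - m
  diag(d) <- NA_real_
  new_rdm(info_type, colnames(m), d, source)
}

new_rdm <- function(info_type, condition_labels, matrix, source) {
  structure(list(info_type = info_type, condition_labels = condition_labels,
                 matrix = matrix, source = source),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM (%s, %s): conditions %s\n", x$info_type, x$source,
              paste(x$condition_labels, collapse = ", ")))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Build a binary model RDM for one information type
#'
#' Hypothesis matrix over the scheme's four conditions: 1 where the two
#' conditions differ on the coded feature, 0.5 where they do not. Conditions
#' with no level on the feature (the cue-colour conditions of the response
#' scheme) take `cross_value` against every other condition.
#'
#' @param info_type `"across"`, `"within"`, `"rule"` or `"response"`.
#' @param colour_rule_map Cue-colour to rule map (rule scheme).
#' @param cross_value Dissimilarity between a condition with a feature level
#'   and one without (response scheme only; default 0.5).
#' @return An `rdm` object with cells in `{0.5, 1}`.
#' @export
build_model_rdm <- function(info_type, colour_rule_map = default_colour_rule_map(),
                            cross_value = 0.5) {
  sch <- rsa_scheme(info_type, colour_rule_map)
  lev <- sch$factors[[info_type]]
  n <- length(sch$conditions)
  m <- matrix(cross_value, n, n, dimnames = list(sch$conditions, sch$conditions))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!is.na(lev[i]) && !is.na(lev[j]))
      m[i, j] <- if (lev[i] == lev[j]) 0.5 else 1
  }
  diag(m) <- NA_real_
  new_rdm(info_type, sch$conditions, m, "model")
}

#' Vectorise an RDM (lower triangle, column-major)
#'
#' The six below-diagonal cells of the 4x4 matrix in column-major order; the
#' element order is fixed and shared by every RDV in the package, so all
#' correlations between RDVs are consistent.
#'
#' @param rdm An `rdm` object or a symmetric numeric matrix.
#' @return An `rdv`: numeric vector of length p(p-1)/2 with a `labels`
#'   attribute naming the condition pairs.
#' @export
rdm_to_rdv <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else as.matrix(rdm)
  if (nrow(m) != ncol(m)) stop("RDM must be square")
  if (any(abs(m - t(m)) > 1e-9, na.rm = TRUE))
    stop("RDM must be symmetric (tolerance 1e-9)")
  lt <- lower.tri(m)
  v <- m[lt]
  labs <- outer(rownames(m), colnames(m), paste, sep = " vs ")[lt]
  structure(v, labels = labs, class = "rdv")
}

#' Rebuild a symmetric RDM matrix from an RDV
#'
#' @param v Numeric vector of length p(p-1)/2.
#' @param condition_labels Optional labels for the p conditions.
#' @return Symmetric matrix with NA diagonal.
#' @export
rdv_to_rdm <- function(v, condition_labels = NULL) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (p != round(p)) stop("length(v) is not p(p-1)/2 for integer p")
  m <- matrix(0, p, p)
  m[lower.tri(m)] <- as.numeric(v)
  m <- m + t(m)
  diag(m) <- NA_real_
  if (!is.null(condition_labels)) dimnames(m) <- list(condition_labels, condition_labels)
  m
}

#' Average RDMs cellwise
#'
#' Used to aggregate over hemispheres and over participants; aggregation is a
#' plain arithmetic mean, so the order of aggregation does not matter for
#' equal counts.
#'
#' @param rdms List of `rdm` objects with identical labels and info type.
#' @param over Annotation of what is averaged over (`"hemisphere"` or
#'   `"participant"`); recorded on the result.
#' @return An `rdm` object.
#' @export
aggregate_rdms <- function(rdms, over = c("hemisphere", "participant")) {
  over <- match.arg(over)
  ref <- rdms[[1]]
  for (r in rdms[-1]) {
    if (!identical(r$condition_labels, ref$condition_labels) ||
        !identical(r$info_type, ref$info_type))
      stop("all RDMs must share condition labels and info type")
  }
  mats <- lapply(rdms, function(r) r$matrix)
  avg <- Reduce(`+`, mats) / length(mats)
  new_rdm(ref$info_type, ref$condition_labels, avg,
          paste0("mean_over_", over))
}

# Dissimilarity RDV stack (6 x time) from a 4x4xT pairwise accuracy array.
rdv_stack_from_accuracy <- function(acc_array) {
  nt <- dim(acc_array)[3]
  out <- vapply(seq_len(nt), function(t) {
    as.numeric(rdm_to_rdv(1 - acc_array[, , t]))
  }, numeric(6))
  attr(out, "times_ms") <- attr(acc_array, "times_ms")
  out
}
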