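# -- IAP / leave-one-out validation ------------------------------------------

#' Invariant Accuracy of Prediction (AUC ROC)
#'
#' The probability that a randomly chosen active score exceeds a randomly
#' chosen inactive score, ties counted 1/2 — the Mann-Whitney form of the
#' area under the ROC curve. Computed from midranks, which is exactly the
#' all-pairs comparison sum. Invariant under any strictly increasing
#' transform of the scores, and `iap(A, B) + iap(B, A) = 1` always holds
#' under the half-tie convention.
#'
#' @param active_scores,inactive_scores nonempty numeric vectors.
#' @return a number in `[0, 1]`.
#' @examples
#' iap(c(3, 2), c(1, 0))  # 1: perfect separation
#' iap(1, 1)              # 0.5: a single tie
#' @export
iap <- function(active_scores, inactive_scores) {
  n1 <- length(active_scores)
  n0 <- length(inactive_scores)
  if (n1 == 0L || n0 == 0L)
    stop_posmna("IAP needs nonempty active and inactive score sets",
                class = "validation")
  r <- rank(c(active_scores, inactive_scores))  # midranks = half-tie counting
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validation report
#'
#' Per activity: the IAP of the analytic leave-one-out scores of pairs
#' labeled with the activity against all remaining pairs, plus the
#' unweighted mean across activities. The LOO unit is the pair (row);
#' molecules shared between pairs are not held out, which the accompanying
#' vignette discusses as a leakage caveat of pair-level validation.
#'
#' @param x a fitted [ddi_fit()] model, or a pair table (data frame with
#'   `id_a`, `id_b`, `activity`) to be fitted first.
#' @param molecules,level,k passed to [ddi_fit()] when `x` is a pair table.
#' @return data frame of class `ddi_validation` with columns `activity`,
#'   `n_active`, `n_inactive`, `iap`; the unweighted mean is available as
#'   `attr(, "average")` and shown by `print`.
#' @export
ddi_validate <- function(x, molecules = NULL, level = 2L, k = 1) {
  m <- if (inherits(x, "posmna_bayes")) x
       else ddi_fit(x, molecules, level = level, k = k)
  res <- data.frame(
    activity = m$activities,
    n_active = as.integer(m$N_a),
    n_inactive = as.integer(m$N - m$N_a),
    iap = vapply(m$activities, function(a)
      iap(m$calib[[a]]$active, m$calib[[a]]$inactive), numeric(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, average = mean(res$iap),
            class = c("ddi_validation", "data.frame"))
}

#' @export
print.ddi_validation <- function(x, digits = 3L, ...) {
  y <- as.data.frame(x)
  y$iap <- round(y$iap, digits)
  print(y, row.names = FALSE)
  cat(sprintf("Average %s\n", format(round(attr(x, "average"), digits))))
  invisible(x)
}
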