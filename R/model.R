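# -- naive Bayes activity-spectrum model over PoSMNA descriptors -------------
#
# Per activity a the model keeps one-vs-rest counts over training pairs:
#   N      total pairs          N_a    pairs labeled a
#   n_d    pairs containing descriptor d
#   n_ad   pairs containing d AND labeled a
# Smoothed conditional probability:
#   P(a|d) = (n_ad + k * p_a) / (n_d + k),  p_a = N_a / N
# (for a descriptor unseen in training the estimate falls back to p_a, so a
# prediction always averages over the full descriptor set of the pair).
# Raw score:
#   S_a(D) = mean over d in D of arcsin(2 * P(a|d) - 1)      in [-pi/2, pi/2]
# The arcsine-mean combiner is one of many strictly monotone choices; Pa, Pi
# and IAP depend on scores only through ranks, so any strictly increasing
# transform of the per-descriptor estimates yields identical calibrated
# output (a property the test suite asserts).
#
# Pa and Pi are tie-adjusted empirical ranks of a score against the
# leave-one-out score distributions of the training actives and inactives.
# That construction makes "IAP = AUC ROC" an exact identity rather than an
# approximation, and the LOO scores themselves are computed analytically by
# count exclusion, which equals retraining without the pair.

MODEL_FORMAT_VERSION <- "posmna/1"

#' Fit a pairwise interaction model
#'
#' Fits the naive Bayes activity model on a table of labeled molecule pairs.
#' Pair keys are unordered (`(A,B)` and `(B,A)` are the same pair) and
#' duplicate (pair, activity) rows collapse; a pair may carry several labels.
#' Negatives for an activity are all training pairs not labeled with it
#' (one-vs-rest). Leave-one-out calibration scores are computed at fit time
#' by analytic count exclusion.
#'
#' @param pairs data frame with columns `id_a`, `id_b`, `activity` (one row
#'   per label), e.g. from [read_pair_table()] or [synth_pair_table()].
#' @param molecules named list of [mol_graph()] objects (e.g. from
#'   [read_molecules()]), or a data frame with columns `id` and `smiles`.
#' @param level MNA descriptor depth (default 2, the modeling standard).
#' @param k additive smoothing strength `>= 0` (default 1).
#' @param activities label vocabulary; defaults to the sorted labels present.
#'   Every activity must have at least one positive and one negative pair.
#' @return An object of class `posmna_bayes` with `print`, `summary`,
#'   `predict` and `plot` methods. `summary` reports per-activity LOO IAP.
#' @seealso [predict.posmna_bayes()], [ddi_validate()], [write_model()]
#' @export
ddi_fit <- function(pairs, molecules, level = 2L, k = 1, activities = NULL) {
  stopifnot(k >= 0)
  pairs <- as.data.frame(pairs)
  need <- c("id_a", "id_b", "activity")
  if (!all(need %in% names(pairs)))
    stop_posmna("pair table must have columns id_a, id_b, activity",
                class = "schema")
  molecules <- as_molecule_list(molecules)

  lab_a <- as.character(pairs$id_a)
  lab_b <- as.character(pairs$id_b)
  act <- as.character(pairs$activity)
  missing_ids <- setdiff(unique(c(lab_a, lab_b)), names(molecules))
  if (length(missing_ids))
    stop_posmna("pair table references unknown molecule id(s): ",
                paste(utils::head(missing_ids, 5L), collapse = ", "),
                class = "schema")
  if (is.null(activities)) activities <- sort(unique(act))
  bad_act <- setdiff(unique(act), activities)
  if (length(bad_act))
    stop_posmna("unknown activity label(s): ", paste(bad_act, collapse = ", "),
                class = "schema")

  key <- pair_key(lab_a, lab_b)
  dedup <- !duplicated(paste0(key, "\r", act))
  key <- key[dedup]; act <- act[dedup]
  lab_a <- lab_a[dedup]; lab_b <- lab_b[dedup]
  ukey <- unique(key)
  n <- length(ukey)
  if (n < 2L)
    stop_posmna("need at least 2 distinct training pairs", class = "fit")
  first <- match(ukey, key)
  pair_ids <- data.frame(id_a = pmin(lab_a, lab_b)[first],
                         id_b = pmax(lab_a, lab_b)[first],
                         stringsAsFactors = FALSE)

  A <- length(activities)
  Y <- matrix(FALSE, n, A, dimnames = list(NULL, activities))
  Y[cbind(match(key, ukey), match(act, activities))] <- TRUE
  N_a <- colSums(Y)
  if (any(N_a == 0L) || any(N_a == n)) {
    off <- activities[N_a == 0L | N_a == n]
    stop_posmna("activity without both positives and negatives: ",
                paste(off, collapse = ", "), class = "fit")
  }

  mna_cache <- lapply(molecules[unique(c(pair_ids$id_a, pair_ids$id_b))],
                      mna_set, level = level)
  dsets <- lapply(seq_len(n), function(i)
    posmna_set(mna_cache[[pair_ids$id_a[[i]]]],
               mna_cache[[pair_ids$id_b[[i]]]]))

  vocab <- mna_sort(unique(unlist(dsets, use.names = FALSE)))
  idx <- lapply(dsets, match, vocab)
  V <- length(vocab)
  n_d <- tabulate(unlist(idx, use.names = FALSE), nbins = V)
  n_ad <- matrix(0L, V, A, dimnames = list(NULL, activities))
  for (a in seq_len(A))
    n_ad[, a] <- tabulate(unlist(idx[Y[, a]], use.names = FALSE), nbins = V)

  m <- structure(
    list(format_version = MODEL_FORMAT_VERSION, level = as.integer(level),
         k = k, activities = activities, N = n, N_a = N_a,
         vocab = vocab, n_d = n_d, n_ad = n_ad,
         calib = NULL, loo = NULL, Y = Y, pair_ids = pair_ids,
         pair_sets = idx, call = match.call()),
    class = "posmna_bayes")
  m$loo <- loo_scores(m)
  m$calib <- lapply(seq_len(A), function(a)
    list(active = sort(m$loo[Y[, a], a]),
         inactive = sort(m$loo[!Y[, a], a])))
  names(m$calib) <- activities
  m
}

as_molecule_list <- function(molecules) {
  if (is.data.frame(molecules)) {
    stopifnot(all(c("id", "smiles") %in% names(molecules)))
    parsed <- parse_smiles_batch(molecules$smiles, molecules$id)
    return(parsed)
  }
  if (!is.list(molecules) || is.null(names(molecules)))
    stop_posmna("molecules must be a named list of mol_graph objects or an ",
                "(id, smiles) data frame", class = "schema")
  molecules
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")

clamp1 <- function(x) {  # dim-preserving clamp to [-1, 1] for asin()
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

#' Smoothed conditional probability of an activity given a descriptor
#'
#' `(n_ad + k * p_a) / (n_d + k)` with `p_a = N_a / N`; a descriptor unseen
#' in training (`n_d = 0`) falls back to the prior `p_a`.
#'
#' @param m fitted [ddi_fit()] model.
#' @param activity one of `m$activities`.
#' @param descriptor PoSMNA descriptor string(s).
#' @return numeric vector of probabilities in `(0, 1)` (in `[0, 1]` at `k = 0`).
#' @export
cond_prob <- function(m, activity, descriptor) {
  a <- match_activity(m, activity)
  i <- match(descriptor, m$vocab)
  nd <- ifelse(is.na(i), 0L, m$n_d[i])
  nad <- ifelse(is.na(i), 0L, m$n_ad[i, a])
  p_a <- m$N_a[[a]] / m$N
  p <- (nad + m$k * p_a) / (nd + m$k)
  p[nd == 0L] <- p_a
  p
}

match_activity <- function(m, activity) {
  a <- match(activity, m$activities)
  if (is.na(a))
    stop_posmna("unknown activity '", activity, "'", class = "schema")
  a
}

# raw scores of one descriptor-index set against all activities;
# NA indices denote descriptors unseen in training
score_indices <- function(m, i) {
  nd <- ifelse(is.na(i), 0L, m$n_d[i])
  nad <- matrix(0, length(i), length(m$activities))
  seen <- !is.na(i)
  nad[seen, ] <- m$n_ad[i[seen], , drop = FALSE]
  p_a <- m$N_a / m$N
  p <- sweep(nad, 2L, m$k * p_a, `+`) / (nd + m$k)
  p[nd == 0L, ] <- rep(p_a, each = sum(nd == 0L))
  colMeans(asin(clamp1(2 * p - 1)))
}

#' Raw score of a descriptor set
#'
#' The mean arcsine-transformed conditional probability of the activity over
#' the pair's PoSMNA descriptors — strictly increasing in every
#' per-descriptor estimate, bounded in `[-pi/2, pi/2]`.
#'
#' @param m fitted model.
#' @param dset character vector of PoSMNA descriptors (see [posmna_set()]).
#' @param activity single activity label, or `NULL` for all.
#' @return named numeric vector of scores (radians).
#' @export
pair_score <- function(m, dset, activity = NULL) {
  if (!length(dset))
    stop_posmna("empty descriptor set", class = "descriptor")
  s <- score_indices(m, match(dset, m$vocab))
  names(s) <- m$activities
  if (is.null(activity)) s else s[[match_activity(m, activity)]]
}

#' Analytic leave-one-out scores of the training pairs
#'
#' Scores every training pair with its own contribution removed by count
#' arithmetic — `n_d - 1`, `n_ad - [pair labeled a]`, and the prior
#' recomputed on `N - 1` pairs — which is exactly equal to retraining
#' without the pair. Descriptors private to the left-out pair fall back to
#' the deflated prior.
#'
#' @param m fitted model (must retain its training pair sets).
#' @return numeric matrix, training pairs x activities.
#' @export
loo_scores <- function(m) {
  if (is.null(m$pair_sets))
    stop_posmna("model was loaded from disk without training pair sets; ",
                "LOO scores are only available on a freshly fitted model",
                class = "fit")
  n <- m$N
  A <- length(m$activities)
  S <- matrix(NA_real_, n, A, dimnames = list(NULL, m$activities))
  for (i in seq_len(n)) {
    d <- m$pair_sets[[i]]
    y <- m$Y[i, ]
    ndp <- m$n_d[d] - 1L
    nadp <- sweep(m$n_ad[d, , drop = FALSE], 2L, as.integer(y), `-`)
    pap <- (m$N_a - y) / (n - 1L)
    p <- sweep(nadp, 2L, m$k * pap, `+`) / (ndp + m$k)
    if (any(ndp == 0L))
      p[ndp == 0L, ] <- rep(pap, each = sum(ndp == 0L))
    S[i, ] <- colMeans(asin(clamp1(2 * p - 1)))
  }
  S
}

#' Calibrated activity probabilities from a raw score
#'
#' Tie-adjusted empirical ranks against the model's leave-one-out calibration
#' distributions: `Pa` is the fraction of training actives scoring below `s`
#' (ties weighted 1/2), `Pi` the fraction of training inactives scoring above
#' `s`. `Pa` is nondecreasing and `Pi` nonincreasing in `s`, and both depend
#' on scores only through ranks.
#'
#' @param m fitted model.
#' @param activity activity label.
#' @param s numeric vector of raw scores.
#' @return list with numeric components `pa` and `pi`, each parallel to `s`.
#' @export
pa_pi <- function(m, activity, s) {
  a <- match_activity(m, activity)
  cal <- m$calib[[a]]
  list(pa = rank_below(cal$active, s),
       pi = 1 - rank_below(cal$inactive, s))
}

# fraction of sorted calibration scores strictly below s, ties counted half
rank_below <- function(sorted, s) {
  n_le <- findInterval(s, sorted)
  n_lt <- findInterval(s, sorted, left.open = TRUE)
  (n_lt + 0.5 * (n_le - n_lt)) / length(sorted)
}

#' Predict interaction activities for molecule pairs
#'
#' Computes the PoSMNA descriptor set of each pair and, per activity, the raw
#' score `S`, calibrated `Pa` and `Pi`, and `dP = Pa - Pi`; within each pair
#' the activities are ranked by decreasing `dP`, the presentation order of an
#' activity-spectrum prediction. A positive `dP` reads as a predicted
#' interaction at that isoform; negative `dP` means the isoform is predicted
#' uninvolved.
#'
#' @param object fitted `posmna_bayes` model.
#' @param pairs either a character vector of two molecule ids, a list of two
#'   [mol_graph()] objects, or a data frame with columns `id_a`, `id_b`.
#' @param molecules named list of [mol_graph()] (or `(id, smiles)` data
#'   frame) resolving any ids in `pairs`.
#' @param ... unused.
#' @return A data frame of class `ddi_prediction` with columns `pair_id`,
#'   `activity`, `S`, `Pa`, `Pi`, `dP`, sorted by `dP` descending within pair.
#' @export
predict.posmna_bayes <- function(object, pairs, molecules = NULL, ...) {
  m <- object
  if (is.list(pairs) && !is.data.frame(pairs) &&
      length(pairs) == 2L && inherits(pairs[[1L]], "mol_graph")) {
    graphs <- pairs
    tab <- data.frame(id_a = graphs[[1L]]$id, id_b = graphs[[2L]]$id,
                      stringsAsFactors = FALSE)
    molecules <- stats::setNames(graphs, c(graphs[[1L]]$id, graphs[[2L]]$id))
  } else if (is.character(pairs) && length(pairs) == 2L) {
    tab <- data.frame(id_a = pairs[[1L]], id_b = pairs[[2L]],
                      stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(pairs)
    stopifnot(all(c("id_a", "id_b") %in% names(tab)))
  }
  if (is.null(molecules))
    stop_posmna("molecules must be supplied to resolve pair ids",
                class = "schema")
  molecules <- as_molecule_list(molecules)
  ids <- unique(c(tab$id_a, tab$id_b))
  missing_ids <- setdiff(ids, names(molecules))
  if (length(missing_ids))
    stop_posmna("unknown molecule id(s): ",
                paste(missing_ids, collapse = ", "), class = "schema")
  cache <- lapply(molecules[ids], mna_set, level = m$level)

  out <- lapply(seq_len(nrow(tab)), function(r) {
    dset <- posmna_set(cache[[tab$id_a[[r]]]], cache[[tab$id_b[[r]]]])
    s <- pair_score(m, dset)
    pp <- vapply(m$activities, function(a) {
      v <- pa_pi(m, a, s[[a]])
      c(v$pa, v$pi)
    }, numeric(2L))
    rec <- data.frame(
      pair_id = paste0(tab$id_a[[r]], "+", tab$id_b[[r]]),
      activity = m$activities,
      S = unname(s), Pa = pp[1L, ], Pi = pp[2L, ],
      dP = pp[1L, ] - pp[2L, ],
      stringsAsFactors = FALSE, row.names = NULL)
    rec[order(-rec$dP, rec$activity), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ddi_prediction", "data.frame")
  res
}

#' @export
print.ddi_prediction <- function(x, digits = 3L, ...) {
  y <- as.data.frame(x)
  for (col in c("S", "Pa", "Pi", "dP")) y[[col]] <- round(y[[col]], digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Qualitative interaction call
#'
#' Activities whose `dP = Pa - Pi` exceeds the threshold are called "YES";
#' an empty result means no interaction is predicted for the pair at any of
#' the modeled isoforms.
#'
#' @param prediction a `ddi_prediction` (one pair, or several).
#' @param threshold decision threshold on `dP` (default 0).
#' @return character vector of predicted activities (for several pairs, a
#'   named list keyed by `pair_id`).
#' @export
ddi_classify <- function(prediction, threshold = 0) {
  byp <- split(prediction, prediction$pair_id)
  res <- lapply(byp, function(p) p$activity[p$dP > threshold])
  if (length(res) == 1L) res[[1L]] else res
}

#' @export
print.posmna_bayes <- function(x, ...) {
  cat("PoSMNA naive Bayes interaction model\n")
  cat(sprintf("  %d training pairs, %d descriptors, MNA level %d, k = %g\n",
              x$N, length(x$vocab), x$level, x$k))
  cat("  activities (positives/negatives):\n")
  for (a in seq_along(x$activities))
    cat(sprintf("    %-10s %4d / %4d\n", x$activities[[a]], x$N_a[[a]],
                x$N - x$N_a[[a]]))
  invisible(x)
}

#' Summarize a fitted model by its leave-one-out accuracy
#'
#' @param object fitted model.
#' @param ... unused.
#' @return a [ddi_validate()] report (per-activity IAP and unweighted mean).
#' @export
summary.posmna_bayes <- function(object, ...) ddi_validate(object)

#' Plot leave-one-out calibration score distributions
#'
#' One panel per activity: boxplots of the LOO scores of training actives vs
#' inactives — the distributions against which `Pa` and `Pi` are ranked.
#'
#' @param x fitted model.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.posmna_bayes <- function(x, ...) {
  A <- length(x$activities)
  old <- graphics::par(mfrow = grDevices::n2mfrow(A), mar = c(2.5, 4, 2, 0.5))
  on.exit(graphics::par(old))
  for (a in seq_len(A)) {
    cal <- x$calib[[a]]
    graphics::boxplot(list(active = cal$active, inactive = cal$inactive),
                      main = x$activities[[a]], ylab = "LOO score", ...)
  }
  invisible(x)
}
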