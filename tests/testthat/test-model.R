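# direct construction of a model object with hand-set counts, for testing
# the estimator arithmetic in isolation
fake_model <- function(vocab, n_d, n_ad, N, N_a, k = 1, calib = NULL) {
  acts <- names(N_a)
  structure(
    list(format_version = "posmna/1", level = 2L, k = k, activities = acts,
         N = N, N_a = N_a, vocab = vocab, n_d = n_d,
         n_ad = matrix(n_ad, ncol = length(acts),
                       dimnames = list(NULL, acts)),
         calib = calib, loo = NULL, Y = NULL, pair_ids = NULL,
         pair_sets = NULL, call = NULL),
    class = "posmna_bayes")
}

test_that("conditional probabilities follow the smoothed count estimate", {
  m <- fake_model("d", n_d = 2L, n_ad = 1L, N = 4L, N_a = c(a = 2L), k = 1)
  expect_equal(cond_prob(m, "a", "d"), 0.5)  # (1 + 1*0.5) / (2 + 1)
  expect_equal(cond_prob(m, "a", "unseen"), 0.5)  # prior fallback

  m2 <- fake_model("d", n_d = 2L, n_ad = 1L, N = 8L, N_a = c(a = 2L), k = 1)
  expect_equal(cond_prob(m2, "a", "unseen"), 0.25)

  m0 <- fake_model("d", n_d = 5L, n_ad = 5L, N = 10L, N_a = c(a = 5L), k = 0)
  expect_equal(cond_prob(m0, "a", "d"), 1.0)  # unsmoothed limit
})

test_that("raw scores are the arcsine mean and match brute-force summation", {
  # all cond_prob = 0.5 -> score 0; all = 1 (k = 0) -> pi/2
  m <- fake_model("d", n_d = 2L, n_ad = 1L, N = 4L, N_a = c(a = 2L), k = 1)
  expect_equal(pair_score(m, "d", "a"), 0)
  m0 <- fake_model("d", n_d = 5L, n_ad = 5L, N = 10L, N_a = c(a = 5L), k = 0)
  expect_equal(pair_score(m0, "d", "a"), pi / 2)

  # random 10-descriptor case against direct re-summation
  withr::with_seed(42, {
    vocab <- paste0("d", 1:10)
    n_d <- sample(1:20, 10L, replace = TRUE)
    n_ad <- vapply(n_d, function(nd) sample.int(nd, 1L) - 1L, integer(1L))
    m <- fake_model(vocab, n_d, n_ad, N = 25L, N_a = c(a = 9L), k = 1)
    brute <- mean(vapply(vocab, function(d)
      asin(2 * cond_prob(m, "a", d) - 1), numeric(1L)))
    expect_equal(pair_score(m, vocab, "a"), brute, tolerance = 1e-15)
  })
})

test_that("fitted counts match a direct recount of descriptor incidence", {
  tab <- fx_small_table(n = 30L)
  m <- ddi_fit(tab$pairs, fx_mols())
  # class sizes match the generated labels
  expect_equal(as.integer(m$N_a),
               as.integer(table(factor(tab$pairs$activity,
                                       levels = m$activities))))
  # recount n_d / n_ad from scratch through the public descriptor interface
  sets <- fx_sets()
  key <- unique(paste(pmin(tab$pairs$id_a, tab$pairs$id_b),
                      pmax(tab$pairs$id_a, tab$pairs$id_b)))
  dsets <- lapply(strsplit(key, " "), function(p)
    posmna_set(sets[[p[[1L]]]], sets[[p[[2L]]]]))
  probe <- sample(m$vocab, 25L)
  for (d in probe) {
    holds <- vapply(dsets, function(s) d %in% s, logical(1L))
    expect_equal(m$n_d[[match(d, m$vocab)]], sum(holds))
  }
})

test_that("degenerate training tables are rejected with named activities", {
  mols <- list(a = fx_mol("benzene"), b = fx_mol("methane"),
               c = fx_mol("ethanol"))
  all_lab <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                        activity = c("CYP3A4", "CYP3A4"))
  expect_error(ddi_fit(all_lab, mols), class = "posmna_fit_error")
  expect_error(ddi_fit(all_lab, mols), "CYP3A4")
  one_pair <- data.frame(id_a = "a", id_b = "b", activity = "CYP3A4")
  expect_error(ddi_fit(one_pair, mols), class = "posmna_fit_error")
})

test_that("analytic LOO equals brute-force retraining without each pair", {
  tab <- fx_small_table(n = 30L, eps = 0.1, seed = 1L)
  counts <- table(tab$pairs$activity)
  stopifnot(all(counts >= 2L))  # fixture sanity: every LOO refit is fittable
  m <- ddi_fit(tab$pairs, fx_mols())
  S <- loo_scores(m)
  key <- paste(pmin(tab$pairs$id_a, tab$pairs$id_b),
               pmax(tab$pairs$id_a, tab$pairs$id_b))
  ukey <- unique(key)
  sets <- fx_sets()
  for (i in seq_along(ukey)) {
    keep <- key != ukey[[i]]
    m_i <- ddi_fit(tab$pairs[keep, ], fx_mols(), activities = m$activities)
    p <- strsplit(ukey[[i]], " ")[[1L]]
    dset <- posmna_set(sets[[p[[1L]]]], sets[[p[[2L]]]])
    expect_equal(unname(S[i, ]), unname(pair_score(m_i, dset)),
                 tolerance = 1e-12)
  }
})

test_that("LOO of a 2-pair table reduces to the single-remaining-pair model", {
  mols <- list(a = fx_mol("benzene"), b = fx_mol("methane"),
               c = fx_mol("ethanol"), d = fx_mol("propane"))
  tab <- data.frame(id_a = c("a", "c"), id_b = c("b", "d"),
                    activity = c("X", "Y"))
  m <- ddi_fit(tab, mols, activities = c("X", "Y"))
  S <- loo_scores(m)
  # pair 1 holds benzene+methane descriptors; after exclusion every one is
  # unseen, so each activity reduces to its deflated prior:
  # X: (1-1)/1 = 0 -> arcsin(-1); Y: (1-0)/1 = 1 -> arcsin(+1)
  expect_equal(unname(S[1L, "X"]), -pi / 2)
  expect_equal(unname(S[1L, "Y"]), pi / 2)
  expect_equal(unname(S[2L, "Y"]), -pi / 2)
  expect_equal(unname(S[2L, "X"]), pi / 2)
})

test_that("Pa/Pi are tie-adjusted ranks against the calibration arrays", {
  cal <- list(a = list(active = c(1, 2, 3), inactive = c(0, 1)))
  m <- fake_model("d", 1L, 1L, N = 5L, N_a = c(a = 3L), calib = cal)
  r <- pa_pi(m, "a", 2.5)
  expect_equal(r$pa, 2 / 3)
  expect_equal(r$pi, 0)
  r <- pa_pi(m, "a", -10)
  expect_equal(r$pa, 0)
  expect_equal(r$pi, 1)
  cal1 <- list(a = list(active = 1, inactive = c(0, 2)))
  m1 <- fake_model("d", 1L, 1L, N = 3L, N_a = c(a = 1L), calib = cal1)
  expect_equal(pa_pi(m1, "a", 1)$pa, 0.5)  # tie convention
  # monotonicity: Pa nondecreasing, Pi nonincreasing in s
  s_grid <- seq(-2, 4, by = 0.25)
  r <- pa_pi(m, "a", s_grid)
  expect_true(all(diff(r$pa) >= 0))
  expect_true(all(diff(r$pi) <= 0))
})

test_that("Pa, Pi and IAP are invariant under increasing score transforms", {
  withr::with_seed(9, {
    act <- round(rnorm(15), 1)  # rounding forces ties
    inact <- round(rnorm(40), 1)
  })
  tr <- function(x) exp(2 * x) + x  # strictly increasing
  cal <- list(a = list(active = sort(act), inactive = sort(inact)))
  cal_t <- list(a = list(active = sort(tr(act)), inactive = sort(tr(inact))))
  m <- fake_model("d", 1L, 1L, N = 55L, N_a = c(a = 15L), calib = cal)
  m_t <- fake_model("d", 1L, 1L, N = 55L, N_a = c(a = 15L), calib = cal_t)
  s <- c(act[3L], inact[5L], 0.17)
  expect_equal(pa_pi(m, "a", s), pa_pi(m_t, "a", tr(s)))
  expect_equal(iap(act, inact), iap(tr(act), tr(inact)))
})

test_that("predictions carry all activities ranked by dP with bounds", {
  tab <- synth_pair_table(2, fx_library(), n_pairs = 120L, eps = 0,
                          mna_sets = fx_sets())
  m <- ddi_fit(tab$pairs, fx_mols())
  pred <- predict(m, c("warfarin", "naproxen"), molecules = fx_mols())
  expect_s3_class(pred, "ddi_prediction")
  expect_equal(nrow(pred), length(m$activities))
  expect_true(all(pred$Pa >= 0 & pred$Pa <= 1))
  expect_true(all(pred$Pi >= 0 & pred$Pi <= 1))
  expect_equal(pred$dP, pred$Pa - pred$Pi)
  expect_true(all(diff(pred$dP) <= 0))  # sorted descending

  # a pair matching a planted rule ranks its own activity first
  fam <- fx_library()$id[fx_library()$family %in% "CYP2C9"]
  p2 <- predict(m, fam[1:2], molecules = fx_mols())
  expect_equal(p2$activity[[1L]], "CYP2C9")
})

test_that("qualitative calls respect the dP threshold", {
  pred <- structure(
    data.frame(pair_id = "x+y",
               activity = c("CYP2C9", "CYP1A2", "CYP3A4"),
               S = c(0.5, -0.2, -0.9), Pa = c(0.4, 0.1, 0.01),
               Pi = c(0.03, 0.3, 0.7),
               dP = c(0.37, -0.2, -0.69)),
    class = c("ddi_prediction", "data.frame"))
  expect_equal(ddi_classify(pred), "CYP2C9")
  expect_equal(ddi_classify(pred, threshold = 0.5), character(0))
  pred$dP <- -abs(pred$dP)
  expect_equal(ddi_classify(pred), character(0))
})

test_that("model serialization round-trips to bit-identical predictions", {
  tab <- fx_small_table(n = 24L)
  m <- ddi_fit(tab$pairs, fx_mols())
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  pred1 <- predict(m, c("warfarin", "naproxen"), molecules = fx_mols())
  pred2 <- predict(m2, c("warfarin", "naproxen"), molecules = fx_mols())
  expect_identical(pred1, pred2)
  lib <- fx_library()
  ids <- lib$id[3:4]
  expect_identical(predict(m, ids, molecules = fx_mols()),
                   predict(m2, ids, molecules = fx_mols()))

  # version gate
  txt <- readLines(path, warn = FALSE)
  writeLines(sub("posmna/1", "posmna/999", txt), path)
  expect_error(read_model(path), class = "posmna_io_error")
})
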