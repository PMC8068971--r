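# -- synthetic molecule library and labeled pair tables ----------------------
#
# Stand-in for a non-redistributable interaction training set. The library is
# built by decorating seven small heteroaromatic scaffolds — one chemical
# family per CYP isoform — at enumerated ring positions, which guarantees
# chemical validity without any valence-repair pass. Every family carries at
# least one "core" MNA/2 descriptor that is present in all its members
# (substitution sites sit at graph distance >= 2 from a core atom, so the
# core atom's two-shell neighborhood never changes) and absent from every
# other family: these core descriptors are the planted rule features, and
# their disjointness is what makes the planted labels recoverable. Labels
# are assigned by the rules and then flipped with probability `eps`
# (symmetric label noise — a simple, analyzable null).
#
# The class profile defaults to the documented composition of a curated
# CYP-mediated interaction training set, in which the dominant isoform
# (CYP3A4) accounts for ~69% of all pairs.

WARFARIN_SMILES <- "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O"
NAPROXEN_SMILES <- "COc1ccc2cc(C(C)C(=O)O)ccc2c1"

.base_decorations <- c("", "C", "N", "O", "F", "Cl", "Br")

.synth_families <- list(
  list(activity = "CYP1A2", tag = "pyr", template = "c1cc({R1})c({R2})nc1",
       decorations = .base_decorations),                        # pyridine
  list(activity = "CYP2B6", tag = "fur", template = "c1cc({R1})c({R2})o1",
       decorations = .base_decorations),                        # furan
  list(activity = "CYP2C19", tag = "thi", template = "c1cc({R1})c({R2})s1",
       decorations = .base_decorations),                        # thiophene
  list(activity = "CYP2C8", tag = "prl", template = "CCn1cc({R1})cc1{R2}",
       decorations = .base_decorations),                        # N-Et-pyrrole
  list(activity = "CYP2C9", tag = "pyz", template = "c1cc({R1})c({R2})nn1",
       decorations = .base_decorations),                        # pyridazine
  list(activity = "CYP2D6", tag = "isx", template = "c1c({R1})c({R2})on1",
       decorations = .base_decorations),                        # isoxazole
  list(activity = "CYP3A4", tag = "imz", template = "Cn1cc({R1})nc1{R2}",
       decorations = c(.base_decorations, "I"))                 # N-Me-imidazole
)

#' Class-imbalance profile of the default training composition
#'
#' Relative pair counts per isoform (132, 27, 80, 55, 204, 231, 1616 over a
#' 2345-pair set); CYP3A4 dominates with ~69% of pairs, reflecting its real
#' preponderance in drug metabolism.
#'
#' @return named numeric vector of weights over [CYP_ACTIVITIES].
#' @export
cyp_imbalance_profile <- function() {
  stats::setNames(c(132, 27, 80, 55, 204, 231, 1616), CYP_ACTIVITIES)
}

# proportional allocation by largest remainder; every class gets >= 1
allocate_counts <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    take <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[take] <- counts[take] + 1
  }
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1
    counts[which(counts == 0)[1L]] <- 1
  }
  stats::setNames(as.integer(counts), names(weights))
}

instantiate_template <- function(template, decs) {
  s <- template
  for (i in seq_along(decs)) {
    ph_paren <- paste0("({R", i, "})")
    ph_bare <- paste0("{R", i, "}")
    if (grepl(ph_paren, s, fixed = TRUE)) {
      s <- sub(ph_paren,
               if (nzchar(decs[[i]])) paste0("(", decs[[i]], ")") else "",
               s, fixed = TRUE)
    } else {
      s <- sub(ph_bare, decs[[i]], s, fixed = TRUE)
    }
  }
  s
}

#' Generate a seeded synthetic molecule library
#'
#' Draws `n` single-component drug-like molecules: the pinned reference
#' compounds warfarin and naproxen, plus scaffold-decorated members of the
#' seven chemical families (allocated roughly by the square root of the
#' class weights so that pair demand can be met). The same seed always
#' yields the same library, byte for byte when written with [write_smiles()].
#'
#' @param seed integer RNG seed; the generator uses one seeded stream.
#' @param n library size, `>= 10` (at most 2 + the number of distinct
#'   decorated scaffolds, 360). The default of 80 gives a pair table of the
#'   default size about five pairs per molecule, the dense molecule reuse
#'   characteristic of curated interaction sets, where a few hundred drugs
#'   generate thousands of pairs.
#' @return data frame with columns `id`, `smiles`, `family` (the associated
#'   activity label; `NA` for the pinned compounds).
#' @export
synth_library <- function(seed, n = 80L) {
  stopifnot(n >= 10L)
  weights <- cyp_imbalance_profile()
  n_fam <- n - 2L
  max_per <- vapply(.synth_families, function(f)
    length(f$decorations)^2, numeric(1L))
  if (n_fam > sum(max_per))
    stop_posmna("library size ", n, " exceeds the ", sum(max_per) + 2L,
                " distinct decorated scaffolds available", class = "synth")
  alloc <- allocate_counts(n_fam, sqrt(weights))
  # cap by family capacity, spilling the excess into families with room
  alloc <- pmin(alloc, max_per)
  short <- n_fam - sum(alloc)
  while (short > 0L) {
    room <- which(alloc < max_per)
    alloc[room[which.max(max_per[room] - alloc[room])]] <-
      alloc[room[which.max(max_per[room] - alloc[room])]] + 1L
    short <- short - 1L
  }
  rows <- withr::with_seed(seed, {
    out <- lapply(seq_along(.synth_families), function(f) {
      fam <- .synth_families[[f]]
      decs <- fam$decorations
      combos <- expand.grid(r1 = decs, r2 = decs, stringsAsFactors = FALSE)
      pick <- sort(sample.int(nrow(combos), alloc[[f]]))
      data.frame(
        id = sprintf("%s%03d", fam$tag, seq_len(alloc[[f]])),
        smiles = vapply(pick, function(j)
          instantiate_template(fam$template,
                               c(combos$r1[[j]], combos$r2[[j]])),
          character(1L)),
        family = fam$activity, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  res <- rbind(
    data.frame(id = c("warfarin", "naproxen"),
               smiles = c(WARFARIN_SMILES, NAPROXEN_SMILES),
               family = NA_character_, stringsAsFactors = FALSE),
    rows)
  rownames(res) <- NULL
  res
}

# MNA/2 sets of every library molecule, via one batched parse
library_mna_sets <- function(library, level = 2L) {
  mols <- parse_smiles_batch(library$smiles, library$id)
  errs <- attr(mols, "errors")
  if (length(errs))
    stop_posmna("synthetic library contains unparseable structures: ",
                paste(utils::head(errs, 3L), collapse = "; "), class = "synth")
  lapply(mols[library$id], mna_set, level = level)
}

#' Derive the planted family rules from a library
#'
#' For every chemical family present, the rule feature is the
#' collation-smallest MNA/2 descriptor shared by all family members and
#' absent from every molecule outside the family. The rule requires the
#' feature in both molecules of a pair (symmetric, so the unordered-pair
#' model can recover it); an empty candidate set is an error, since such a
#' rule would be unsatisfiable.
#'
#' @param library a [synth_library()] data frame.
#' @param level MNA level (default 2).
#' @param mna_sets optional precomputed list of MNA sets keyed by id.
#' @return data frame with columns `activity`, `feature_a`, `feature_b`.
#' @export
synth_rules <- function(library, level = 2L, mna_sets = NULL) {
  if (is.null(mna_sets)) mna_sets <- library_mna_sets(library, level)
  fams <- unique(stats::na.omit(library$family))
  rules <- lapply(fams, function(a) {
    inside <- library$id[!is.na(library$family) & library$family == a]
    outside <- setdiff(library$id, inside)
    shared <- Reduce(intersect, mna_sets[inside])
    feat <- setdiff(shared, unique(unlist(mna_sets[outside], use.names = FALSE)))
    if (!length(feat))
      stop_posmna("unsatisfiable rule for ", a,
                  ": no descriptor is common to the family and private to it",
                  class = "synth")
    data.frame(activity = a, feature_a = mna_sort(feat)[[1L]],
               feature_b = mna_sort(feat)[[1L]], stringsAsFactors = FALSE)
  })
  do.call(rbind, rules)
}

#' Generate a seeded labeled pair table with planted structure
#'
#' Samples unordered molecule pairs whose members both carry a family's rule
#' feature, labels them with the family's activity, then flips each label
#' with probability `eps` to a uniformly drawn other activity of the
#' profile. The returned truth manifest records intended and final labels.
#'
#' @param seed integer RNG seed (one stream for sampling and noise).
#' @param library a [synth_library()] data frame.
#' @param n_pairs number of labeled pairs (default 200).
#' @param eps symmetric label-flip rate in `[0, 0.5)`; default 0.1, a
#'   moderate level of curation noise.
#' @param profile named weight vector over activities (default
#'   [cyp_imbalance_profile()]); allocation is proportional with largest-remainder
#'   rounding and a floor of one pair per class.
#' @param rules planted rules (default [synth_rules()] on `library`).
#' @param exclude optional pair table whose (unordered) pairs must not be
#'   re-drawn — used to sample fresh evaluation pairs disjoint from a
#'   training table.
#' @param mna_sets optional precomputed MNA sets keyed by id.
#' @return list with components `pairs` (data frame `id_a`, `id_b`,
#'   `activity`), `truth` (adds `activity_true` and `flipped`), `rules`, and
#'   `counts` (intended per-activity totals).
#' @export
synth_pair_table <- function(seed, library, n_pairs = 200L, eps = 0.1,
                             profile = cyp_imbalance_profile(), rules = NULL,
                             exclude = NULL, mna_sets = NULL) {
  stopifnot(eps >= 0, eps < 0.5, n_pairs >= 1L)
  if (is.null(mna_sets)) mna_sets <- library_mna_sets(library)
  if (is.null(rules)) rules <- synth_rules(library, mna_sets = mna_sets)
  acts <- names(profile)
  missing_rules <- setdiff(acts, rules$activity)
  if (length(missing_rules))
    stop_posmna("no planted rule for: ",
                paste(missing_rules, collapse = ", "), class = "synth")
  counts <- allocate_counts(n_pairs, profile)
  excl_keys <- if (!is.null(exclude))
    pair_key(exclude$id_a, exclude$id_b) else character()

  withr::with_seed(seed, {
    drawn <- lapply(acts, function(a) {
      feat <- rules$feature_a[rules$activity == a][[1L]]
      members <- library$id[vapply(mna_sets[library$id], function(s)
        feat %in% s, logical(1L))]
      if (length(members) < 2L)
        stop_posmna("rule for ", a, " matches fewer than 2 molecules",
                    class = "synth")
      combos <- utils::combn(sort(members), 2L)
      keys <- pair_key(combos[1L, ], combos[2L, ])
      ok <- which(!keys %in% excl_keys)
      if (length(ok) < counts[[a]])
        stop_posmna("cannot draw ", counts[[a]], " distinct ", a,
                    " pairs: only ", length(ok), " available", class = "synth")
      pick <- sort(sample(ok, counts[[a]]))
      data.frame(id_a = combos[1L, pick], id_b = combos[2L, pick],
                 activity_true = a, stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, drawn)
    n <- nrow(truth)
    truth$flipped <- stats::runif(n) < eps
    truth$activity <- truth$activity_true
    if (any(truth$flipped) && length(acts) > 1L) {
      # reassignment is prevalence-weighted so that label noise preserves the
      # class marginals of the profile (uniform reassignment would drain the
      # dominant class and multiply the effective noise rate of rare classes);
      # a flip is suppressed if it would leave its class with no correctly
      # labeled pair, so every activity stays fittable at any noise level
      cur <- table(factor(truth$activity, levels = acts))
      for (i in which(truth$flipped)) {
        a0 <- truth$activity_true[[i]]
        if (cur[[a0]] <= 1L) {
          truth$flipped[[i]] <- FALSE
          next
        }
        others <- setdiff(acts, a0)
        w <- profile[others]
        a1 <- sample(others, 1L, prob = w / sum(w))
        truth$activity[[i]] <- a1
        cur[[a0]] <- cur[[a0]] - 1L
        cur[[a1]] <- cur[[a1]] + 1L
      }
    }
    rownames(truth) <- NULL
    list(pairs = truth[, c("id_a", "id_b", "activity")],
         truth = truth[, c("id_a", "id_b", "activity_true", "activity",
                           "flipped")],
         rules = rules, counts = counts)
  })
}
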