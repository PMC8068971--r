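test_that("library generation is deterministic with pinned reference drugs", {
  lib <- synth_library(11, 40)
  expect_identical(lib, synth_library(11, 40))
  expect_equal(lib$smiles[match("warfarin", lib$id)],
               "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O")
  expect_equal(lib$smiles[match("naproxen", lib$id)],
               "COc1ccc2cc(C(C)C(=O)O)ccc2c1")
  expect_equal(nrow(lib), 40L)
  expect_false(anyDuplicated(lib$id) > 0L)

  # every generated structure parses as a single-component molecule
  mols <- posmna:::parse_smiles_batch(lib$smiles, lib$id)
  expect_length(mols, 40L)
  expect_length(attr(mols, "errors"), 0L)

  path1 <- withr::local_tempfile(fileext = ".smi")
  path2 <- withr::local_tempfile(fileext = ".smi")
  write_smiles(lib, path1)
  write_smiles(synth_library(11, 40), path2)
  expect_identical(readLines(path1), readLines(path2))

  expect_equal(nrow(synth_library(1, 10)), 10L)
  expect_error(synth_library(1, 10000), class = "posmna_synth_error")
})

test_that("class allocation follows the imbalance profile proportionally", {
  counts <- posmna:::allocate_counts(235, cyp_imbalance_profile())
  expect_equal(counts[["CYP3A4"]], 162L)  # dominant ~69% of pairs
  expect_equal(sum(counts), 235L)
  expect_true(all(counts >= 1L))
})

test_that("planted rules are satisfiable, symmetric, and family-private", {
  lib <- fx_library()
  sets <- fx_sets()
  rules <- synth_rules(lib, mna_sets = sets)
  expect_setequal(rules$activity, CYP_ACTIVITIES)
  expect_identical(rules$feature_a, rules$feature_b)
  expect_false(anyDuplicated(rules$feature_a) > 0L)
  for (r in seq_len(nrow(rules))) {
    fam <- rules$activity[[r]]
    inside <- lib$id[lib$family %in% fam]
    outside <- setdiff(lib$id, inside)
    expect_true(all(vapply(sets[inside], function(s)
      rules$feature_a[[r]] %in% s, logical(1L))))
    expect_false(any(vapply(sets[outside], function(s)
      rules$feature_a[[r]] %in% s, logical(1L))))
  }
})

test_that("pair tables are deterministic, rule-consistent, and excludable", {
  lib <- fx_library()
  tab <- synth_pair_table(5, lib, n_pairs = 60L, eps = 0.2,
                          mna_sets = fx_sets())
  expect_identical(tab, synth_pair_table(5, lib, n_pairs = 60L, eps = 0.2,
                                         mna_sets = fx_sets()))
  expect_equal(nrow(tab$pairs), 60L)
  # intended labels respect the planted family membership
  fam_of <- setNames(lib$family, lib$id)
  expect_identical(unname(fam_of[tab$truth$id_a]), tab$truth$activity_true)
  expect_identical(unname(fam_of[tab$truth$id_b]), tab$truth$activity_true)
  # unflipped labels match the intent; flips moved to another class
  expect_identical(tab$truth$activity[!tab$truth$flipped],
                   tab$truth$activity_true[!tab$truth$flipped])
  expect_true(all(tab$truth$activity[tab$truth$flipped] !=
                  tab$truth$activity_true[tab$truth$flipped]))
  # per-class intended counts equal the allocation
  expect_equal(as.integer(table(factor(tab$truth$activity_true,
                                       levels = names(tab$counts)))),
               as.integer(tab$counts))

  fresh <- synth_pair_table(6, lib, n_pairs = 60L, eps = 0,
                            exclude = tab$pairs, mna_sets = fx_sets())
  k1 <- paste(pmin(tab$pairs$id_a, tab$pairs$id_b),
              pmax(tab$pairs$id_a, tab$pairs$id_b))
  k2 <- paste(pmin(fresh$pairs$id_a, fresh$pairs$id_b),
              pmax(fresh$pairs$id_a, fresh$pairs$id_b))
  expect_length(intersect(k1, k2), 0L)

  # a rule that no molecule satisfies is rejected
  bad <- data.frame(activity = CYP_ACTIVITIES,
                    feature_a = "Zz(Zz)", feature_b = "Zz(Zz)")
  expect_error(synth_pair_table(1, lib, n_pairs = 10L, rules = bad,
                                mna_sets = fx_sets()),
               class = "posmna_synth_error")
})

test_that("label noise degrades accuracy between separable and chance", {
  lib <- fx_library()
  noisy <- synth_pair_table(7, lib, n_pairs = 200L, eps = 0.3,
                            mna_sets = fx_sets())
  avg_noisy <- attr(ddi_validate(noisy$pairs, fx_mols()), "average")

  permuted <- noisy$pairs
  permuted$activity <- withr::with_seed(7, sample(permuted$activity))
  avg_null <- attr(ddi_validate(permuted, fx_mols()), "average")

  expect_lt(avg_noisy, 1)
  expect_gt(avg_noisy, avg_null)
})
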