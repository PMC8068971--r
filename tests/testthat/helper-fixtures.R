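# Shared fixtures, built in code and cached per test run.

PINNED <- c(
  warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  naproxen = "COc1ccc2cc(C(C)C(=O)O)ccc2c1",
  benzene  = "c1ccccc1",
  methane  = "C",
  ethanol  = "CCO",
  propane  = "CCC"
)

.fx <- new.env(parent = emptyenv())

fx_mol <- function(name) {
  key <- paste0("mol_", name)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- parse_structure(PINNED[[name]], id = name)
  .fx[[key]]
}

fx_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- synth_library(1, 80)
  .fx$lib
}

fx_mols <- function() {
  if (is.null(.fx$mols)) {
    lib <- fx_library()
    .fx$mols <- posmna:::parse_smiles_batch(lib$smiles, lib$id)
  }
  .fx$mols
}

fx_sets <- function() {
  if (is.null(.fx$sets)) .fx$sets <- lapply(fx_mols(), mna_set)
  .fx$sets
}

# small 3-activity training fixture for LOO-identity checks
fx_small_table <- function(n = 30L, eps = 0.1, seed = 1L) {
  profile <- cyp_imbalance_profile()[c("CYP2C9", "CYP2D6", "CYP3A4")]
  synth_pair_table(seed, fx_library(), n_pairs = n, eps = eps,
                   profile = profile, mna_sets = fx_sets())
}

# -- random chemically-shaped graphs (for descriptor property tests) ---------
# Random connected heavy-atom trees plus a few cycle-closing edges and
# hydrogen leaves; valence realism is irrelevant to the descriptor grammar.
random_mol_graph <- function(seed, max_atoms = 20L) {
  withr::with_seed(seed, {
    n_heavy <- sample(3:10, 1L)
    elements <- sample(c("C", "N", "O", "S"), n_heavy, replace = TRUE)
    edges <- if (n_heavy > 1L)
      cbind(2:n_heavy, vapply(2:n_heavy, function(i)
        sample.int(i - 1L, 1L), integer(1L)))
    else matrix(integer(), ncol = 2L)
    extra <- sample(0:2, 1L)
    if (extra > 0L && n_heavy >= 4L) {
      for (z in seq_len(extra)) {
        uv <- sample.int(n_heavy, 2L)
        if (!any(edges[, 1L] == max(uv) & edges[, 2L] == min(uv)))
          edges <- rbind(edges, c(max(uv), min(uv)))
      }
    }
    n_h <- min(sample(0:4, 1L), max_atoms - n_heavy)
    if (n_h > 0L) {
      hosts <- sample.int(n_heavy, n_h, replace = TRUE)
      edges <- rbind(edges, cbind(n_heavy + seq_len(n_h), hosts))
      elements <- c(elements, rep("H", n_h))
    }
    mol_graph(elements, edges, id = paste0("rand", seed))
  })
}

# permute atom order of a graph (relabeled isomorph)
permute_graph <- function(g, seed) {
  withr::with_seed(seed, {
    n <- length(g$element)
    p <- sample.int(n)  # p[old] = new index
    mol_graph(g$element[order(p)],
              cbind(p[g$edges[, 1L]], p[g$edges[, 2L]]),
              id = g$id, bond_order = g$bond_order,
              charge = g$charge[order(p)])
  })
}

# -- independent naive reference for the MNA grammar -------------------------
# Written against the grammar definition only; shares no code with the
# package implementation (scalar recursion, explicit comparator, O(n^2) sort).
ref_alphabet <- c("(", ")", LETTERS, letters, "-")

ref_cmp <- function(a, b) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  for (j in seq_len(min(length(ca), length(cb)))) {
    ra <- match(ca[[j]], ref_alphabet)
    rb <- match(cb[[j]], ref_alphabet)
    if (ra != rb) return(sign(ra - rb))
  }
  sign(length(ca) - length(cb))
}

ref_sort <- function(xs) {
  # selection sort with the scalar comparator
  out <- character(0L)
  while (length(xs)) {
    best <- 1L
    for (j in seq_along(xs)) if (ref_cmp(xs[[j]], xs[[best]]) < 0L) best <- j
    out <- c(out, xs[[best]])
    xs <- xs[-best]
  }
  out
}

ref_mna <- function(g, i, level) {
  lab <- if (g$in_ring[[i]]) g$element[[i]] else paste0("-", g$element[[i]])
  if (level == 0L) return(lab)
  subs <- vapply(g$adjacency[[i]], function(j) ref_mna(g, j, level - 1L),
                 character(1L))
  paste0(lab, "(", paste(ref_sort(subs), collapse = ""), ")")
}

ref_mna_set <- function(g, level = 2L) {
  heavy <- which(!g$is_hydrogen)
  unique(vapply(heavy, function(i) ref_mna(g, i, level), character(1L)))
}
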