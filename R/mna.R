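# -- MNA / PoSMNA descriptors ------------------------------------------------
#
# An MNA descriptor of level k is a canonical string built recursively:
#   D0(atom)  = label(atom)
#   Dk(atom)  = label(atom) "(" <Dk-1 of every neighbor, collation-sorted> ")"
# where label = element symbol, prefixed with '-' iff the atom is acyclic.
# Hydrogens participate as neighbors (so "-H(...)" appears inside strings)
# but only heavy atoms contribute centers to a molecule's descriptor set.
#
# The collation is NOT plain ASCII: '(' < ')' < letters (ASCII order) < '-',
# i.e. the acyclic mark ranks after every letter. This is the unique order
# consistent with the reference example orderings, which place "C(CCC)"
# before "C(CC-H)" and run from a "C(...)" string down to a "-O(...)" string.

.mna_alphabet <- c("(", ")", LETTERS, letters, "-")
.mna_from <- paste(.mna_alphabet, collapse = "")
# monotone remap onto contiguous ASCII bytes so that C-locale (radix) string
# order on the keys realizes the descriptor collation
.mna_to <- rawToChar(as.raw(48L + seq_along(.mna_alphabet) - 1L))

mna_key <- function(x) chartr(.mna_from, .mna_to, x)

#' Compare descriptor strings under the MNA collation
#'
#' Character-wise comparison under a fixed translation table in which
#' `(` < `)` < uppercase and lowercase letters (ASCII order) < `-`: the
#' acyclic mark ranks after all letters. All descriptor ordering in the
#' package (neighbor sub-descriptors, descriptor sets, pair canonicalization,
#' output files) uses this collation, independently of the session locale.
#'
#' @param s1,s2 character vectors (recycled to a common length).
#' @return integer vector: `-1` where `s1` sorts first, `0` where equal,
#'   `1` where `s2` sorts first.
#' @examples
#' mna_collate("C(CCC)", "C(CC-H)")   # -1: ring carbon before the -H variant
#' mna_collate("C(C)", "-O(C)")       # -1: any letter before the '-' mark
#' @export
mna_collate <- function(s1, s2) {
  k1 <- mna_key(s1)
  k2 <- mna_key(s2)
  u <- sort(unique(c(k1, k2)), method = "radix")
  as.integer(sign(match(k1, u) - match(k2, u)))
}

#' Sort strings under the MNA collation
#' @param x character vector.
#' @return `x` sorted by [mna_collate()] order.
#' @export
mna_sort <- function(x) x[order(mna_key(x), method = "radix")]

# all-atom descriptors of one level, computed bottom-up over the recursion
mna_all_atoms <- function(g, level) {
  lab <- ifelse(g$in_ring, g$element, paste0("-", g$element))
  d <- lab
  for (k in seq_len(level)) {
    prev <- d
    d <- vapply(seq_along(lab), function(i) {
      nb <- g$adjacency[[i]]
      paste0(lab[[i]], "(", paste(mna_sort(prev[nb]), collapse = ""), ")")
    }, character(1L))
  }
  d
}

#' MNA descriptor of one atom
#'
#' @param g a hydrogen-complete, ring-flagged [mol_graph()].
#' @param center atom index (any atom, including hydrogens).
#' @param level neighborhood depth `>= 0`; level 2 (MNA/2) is what the pair
#'   model consumes.
#' @return the canonical descriptor string.
#' @examples
#' methane <- mol_graph(c("C", "H", "H", "H", "H"), cbind(1L, 2:5))
#' mna_descriptor(methane, 1, 2)  # "-C(-H(-C)-H(-C)-H(-C)-H(-C))"
#' @export
mna_descriptor <- function(g, center, level = 2L) {
  stopifnot(level >= 0L, center >= 1L, center <= length(g$element))
  mna_all_atoms(g, level)[[center]]
}

#' MNA descriptor set of a molecule
#'
#' One descriptor per heavy-atom center, collapsed to a unique set and
#' returned in collation order. Descriptor multiplicity is discarded:
#' the model's semantics are presence/absence.
#'
#' @inheritParams mna_descriptor
#' @return character vector of unique MNA strings, collation-sorted.
#' @export
mna_set <- function(g, level = 2L) {
  heavy <- !g$is_hydrogen
  if (!any(heavy))
    stop_posmna("molecule '", g$id, "' has no heavy atoms", class = "descriptor")
  mna_sort(unique(mna_all_atoms(g, level)[heavy]))
}

#' PoSMNA descriptor set of a molecule pair
#'
#' The direct product of the two molecules' MNA sets:
#' `{a,b,...} x {d,e,...} = {"a d", "a e", ..., "b d", ...}`, with the two
#' components of every product string ordered by [mna_collate()] (smaller
#' first, single-space separator) so the pair is unordered —
#' `posmna_set(a, b)` and `posmna_set(b, a)` are identical. Self-products
#' `"x x"` are kept when a descriptor occurs in both molecules.
#'
#' @param a,b character vectors: MNA descriptor sets of the two molecules at
#'   a common level (see [mna_set()]).
#' @return character vector of unique PoSMNA strings, collation-sorted; its
#'   length is at most `length(a) * length(b)`.
#' @export
posmna_set <- function(a, b) {
  if (!length(a) || !length(b))
    stop_posmna("PoSMNA product of an empty descriptor set", class = "descriptor")
  x <- rep(a, each = length(b))
  y <- rep(b, times = length(a))
  kx <- mna_key(x)
  ky <- mna_key(y)
  u <- sort(unique(c(kx, ky)), method = "radix")
  swap <- match(kx, u) > match(ky, u)
  lo <- ifelse(swap, y, x)
  hi <- ifelse(swap, x, y)
  mna_sort(unique(paste(lo, hi)))
}
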