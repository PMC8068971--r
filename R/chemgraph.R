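#' @keywords internal
"_PACKAGE"

# -- molecular graph ---------------------------------------------------------
#
# The descriptor substrate is deliberately thin: element symbol, ring flag and
# adjacency. Bond orders and formal charges are parsed and kept only so that a
# graph can be written back out as a chemically valid molblock; they take no
# part in descriptor generation, and stereochemistry is discarded entirely.

#' Construct a molecular graph
#'
#' Low-level constructor for the hydrogen-complete molecular graph consumed by
#' [mna_set()]. Ring membership and connected components are computed on
#' construction; `in_ring` is `TRUE` exactly for atoms lying on at least one
#' cycle (any cycle, not an SSSR), which is what the `-` acyclic mark in MNA
#' strings encodes.
#'
#' Most users will not call this directly: [parse_structure()] builds graphs
#' from SMILES or SDF records with hydrogens completed by a valence model.
#' The constructor exists so that graphs can also be assembled directly, e.g.
#' for synthetic test structures.
#'
#' @param element character vector of element symbols (`"H"` marks hydrogens).
#' @param bonds two-column integer matrix of atom indices (undirected edges),
#'   or `NULL` for a bond-less molecule.
#' @param id molecule identifier.
#' @param bond_order integer vector of bond orders, parallel to the rows of
#'   `bonds` (kept for serialization only; defaults to single bonds).
#' @param charge integer vector of formal charges per atom (default zero).
#' @return An object of class `mol_graph`: a list with fields `id`, `element`,
#'   `is_hydrogen`, `in_ring`, `edges`, `bond_order`, `charge`, `adjacency`
#'   (list of neighbor index vectors) and `component` (component id per atom).
#' @examples
#' g <- mol_graph(c("C", "H", "H", "H", "H"),
#'                cbind(1L, 2:5), id = "methane")
#' g$in_ring
#' @export
mol_graph <- function(element, bonds = NULL, id = "mol",
                      bond_order = NULL, charge = NULL) {
  element <- as.character(element)
  n <- length(element)
  if (n == 0L)
    stop_posmna("empty molecule '", id, "': no atoms", class = "parse")
  if (is.null(bonds)) bonds <- matrix(integer(), ncol = 2L)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L &&
      (any(bonds < 1L) || any(bonds > n) || any(bonds[, 1L] == bonds[, 2L])))
    stop_posmna("molecule '", id, "': bond endpoints out of range or reflexive",
                class = "parse")
  if (is.null(bond_order)) bond_order <- rep(1L, nrow(bonds))
  if (is.null(charge)) charge <- integer(n)

  adjacency <- rep(list(integer()), n)
  if (nrow(bonds) > 0L) {
    ends <- c(bonds[, 1L], bonds[, 2L])
    nbrs <- c(bonds[, 2L], bonds[, 1L])
    split_adj <- split(nbrs, ends)
    adjacency[as.integer(names(split_adj))] <-
      lapply(split_adj, function(v) sort(unique(as.integer(v))))
  }
  is_h <- element == "H"
  bad_h <- which(is_h & lengths(adjacency) != 1L & n > 1L)
  if (length(bad_h))
    stop_posmna("molecule '", id, "': hydrogen atom(s) ",
                paste(bad_h, collapse = ", "),
                " must have exactly one neighbor", class = "parse")

  g <- structure(
    list(id = id, element = element, is_hydrogen = is_h,
         in_ring = logical(n), edges = bonds, bond_order = as.integer(bond_order),
         charge = as.integer(charge), adjacency = adjacency,
         component = integer(n)),
    class = "mol_graph")
  g <- flag_ring_atoms(g)
  g$component <- graph_components(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  nh <- sum(!x$is_hydrogen)
  cat(sprintf("<mol_graph '%s': %d atoms (%d heavy, %d H), %d bonds, %d ring atoms, %d component%s>\n",
              x$id, length(x$element), nh, sum(x$is_hydrogen), nrow(x$edges),
              sum(x$in_ring), max(x$component),
              if (max(x$component) == 1L) "" else "s"))
  invisible(x)
}

#' Number of heavy (non-hydrogen) atoms
#' @param g a `mol_graph`.
#' @return integer count.
#' @export
n_heavy <- function(g) sum(!g$is_hydrogen)

# structured package errors: class posmna_<class>_error
stop_posmna <- function(..., class) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("posmna_", class, "_error"),
                                "posmna_error")))
}

graph_components <- function(g) {
  n <- length(g$element)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in g$adjacency[[v]]) if (comp[u] == 0L) {
        comp[u] <- cur
        queue <- c(queue, u)
      }
    }
  }
  comp
}

#' Flag ring atoms
#'
#' Sets `in_ring` to `TRUE` exactly for atoms lying on at least one cycle —
#' any cycle, not an SSSR — which is the condition the binary `-` acyclic
#' mark of MNA strings encodes. An atom is on a cycle iff it has an incident
#' non-bridge edge; degree-1 vertices are pruned first and the remaining 2-core
#' edges are tested by endpoint reachability with the edge removed (leaf
#' pruning alone is not enough: atoms on bridges *between* ring systems also
#' survive it). Hydrogens always end up acyclic.
#'
#' @param g a `mol_graph`.
#' @return `g` with its `in_ring` field recomputed.
#' @export
flag_ring_atoms <- function(g) {
  n <- length(g$element)
  deg <- lengths(g$adjacency)
  alive <- rep(TRUE, n)
  repeat {
    leaves <- which(alive & deg == 1L)
    if (!length(leaves)) break
    alive[leaves] <- FALSE
    for (v in leaves)
      for (u in g$adjacency[[v]])
        if (alive[u]) deg[u] <- deg[u] - 1L
  }
  core <- alive & deg >= 2L
  in_ring <- logical(n)
  if (nrow(g$edges) > 0L) {
    sel <- which(core[g$edges[, 1L]] & core[g$edges[, 2L]])
    for (e in sel) {
      u <- g$edges[e, 1L]
      v <- g$edges[e, 2L]
      if (in_ring[u] && in_ring[v]) next
      # is v reachable from u in the 2-core without edge (u,v)?
      seen <- logical(n)
      seen[u] <- TRUE
      queue <- u
      found <- FALSE
      while (length(queue) && !found) {
        w <- queue[[1L]]; queue <- queue[-1L]
        for (x in g$adjacency[[w]]) {
          if (!core[x] || seen[x]) next
          if (w == u && x == v) next       # skip the tested edge itself
          if (x == v) { found <- TRUE; break }
          seen[x] <- TRUE
          queue <- c(queue, x)
        }
      }
      if (found) in_ring[u] <- in_ring[v] <- TRUE
    }
  }
  g$in_ring <- in_ring
  g
}

# -- Open Babel bridge -------------------------------------------------------

# One conversion backend for every structure input: Open Babel resolves
# aromaticity, valence-model implicit hydrogens ('h' option makes them
# explicit atoms) and formal charges, and emits kekulized V2000 molblocks.
ob_to_sdf <- function(source, from = c("SMI", "SDF")) {
  from <- match.arg(from)
  ChemmineOB::convertFormat(
    from, "SDF", source,
    options = data.frame(names = "h", args = "", stringsAsFactors = FALSE))
}

split_sdf_records <- function(text) {
  recs <- strsplit(text, "$$$$\n", fixed = TRUE)[[1L]]
  recs[nzchar(trimws(recs))]
}

# Parse one V2000 molblock (as emitted by Open Babel) into a mol_graph.
parse_molblock <- function(lines, id = NULL) {
  if (is.null(id)) {
    id <- trimws(lines[[1L]])
    if (!nzchar(id)) id <- "mol"
  }
  counts <- lines[[4L]]
  n_at <- as.integer(substr(counts, 1L, 3L))
  n_bo <- as.integer(substr(counts, 4L, 6L))
  if (is.na(n_at) || is.na(n_bo))
    stop_posmna("record '", id, "': malformed V2000 counts line", class = "parse")
  atom_lines <- lines[4L + seq_len(n_at)]
  element <- trimws(substr(atom_lines, 32L, 34L))
  bond_lines <- lines[4L + n_at + seq_len(n_bo)]
  bonds <- cbind(as.integer(substr(bond_lines, 1L, 3L)),
                 as.integer(substr(bond_lines, 4L, 6L)))
  if (n_bo == 0L) bonds <- matrix(integer(), ncol = 2L)
  bond_order <- if (n_bo > 0L) as.integer(substr(bond_lines, 7L, 9L)) else integer()
  charge <- integer(n_at)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)), " +")[[1L]])
    if (length(f) >= 2L) {
      idx <- f[seq(1L, length(f), by = 2L)]
      val <- f[seq(2L, length(f), by = 2L)]
      charge[idx] <- val
    }
  }
  mol_graph(element, bonds, id = id, bond_order = bond_order, charge = charge)
}

#' Parse a structure record into a molecular graph
#'
#' Accepts a SMILES string or a single SDF (V2000) record. Aromatic perception
#' and implicit-hydrogen completion are delegated to Open Babel; the returned
#' graph is hydrogen-complete with ring membership flagged. Stereochemical
#' annotations are read but discarded: atom identity for descriptor purposes
#' is element symbol plus ring flag only.
#'
#' @param text SMILES string, or the full text of one SDF record.
#' @param id molecule identifier; for SDF input, defaults to the title line.
#' @param format `"smiles"`, `"sdf"`, or `"auto"` (detects a molblock by its
#'   `V2000` counts line).
#' @param strip_salts if `TRUE`, multi-component inputs are reduced to the
#'   component with the most heavy atoms (a tie is an error); if `FALSE`
#'   (default) multi-component inputs are rejected, mirroring a training set
#'   restricted to single-component organic compounds.
#' @return A [mol_graph()].
#' @examples
#' \donttest{
#' benzene <- parse_structure("c1ccccc1", id = "benzene")
#' sum(benzene$in_ring)  # 6
#' }
#' @export
parse_structure <- function(text, id = NULL,
                            format = c("auto", "smiles", "sdf"),
                            strip_salts = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    lns <- strsplit(text, "\n")[[1L]]
    format <- if (length(lns) >= 4L && grepl("V2000", lns[[4L]], fixed = TRUE))
      "sdf" else "smiles"
  }
  if (format == "smiles") {
    smiles <- trimws(text)
    if (!nzchar(smiles))
      stop_posmna("empty SMILES for record '", id %||% "?", "'", class = "parse")
    if (is.null(id)) id <- "mol"
    out <- ob_to_sdf(paste0(smiles, "\t", id, "\n"), "SMI")
  } else {
    out <- ob_to_sdf(text, "SDF")
  }
  recs <- split_sdf_records(out)
  if (!length(recs))
    stop_posmna("could not parse record '", id %||% "?",
                "': structure rejected by the SMILES/SDF reader",
                class = "parse")
  g <- parse_molblock(strsplit(recs[[1L]], "\n")[[1L]], id = id)
  require_single_component(g, strip_salts = strip_salts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enforce single-component structures
#'
#' Pairwise interaction models are trained on single-component organic
#' compounds, so multi-component records (salts, mixtures) are rejected by
#' default. With `strip_salts = TRUE` the largest component (by heavy-atom
#' count) is retained; ties are an error rather than an arbitrary choice.
#'
#' @param g a `mol_graph`.
#' @inheritParams parse_structure
#' @return a single-component `mol_graph`.
#' @export
require_single_component <- function(g, strip_salts = FALSE) {
  k <- max(g$component)
  if (k == 1L) return(g)
  sizes <- vapply(seq_len(k), function(i)
    sum(g$component == i & !g$is_hydrogen), integer(1L))
  if (!strip_salts)
    stop_posmna("molecule '", g$id, "' has ", k,
                " components (heavy-atom sizes: ",
                paste(sizes, collapse = ", "),
                "); pass strip_salts = TRUE to keep the largest",
                class = "multicomponent")
  best <- which(sizes == max(sizes))
  if (length(best) > 1L)
    stop_posmna("molecule '", g$id, "': cannot strip salts, ",
                length(best), " components tie at ", max(sizes),
                " heavy atoms", class = "multicomponent")
  keep <- which(g$component == best)
  remap <- match(seq_along(g$element), keep)
  sel <- g$edges[, 1L] %in% keep
  mol_graph(g$element[keep],
            cbind(remap[g$edges[sel, 1L]], remap[g$edges[sel, 2L]]),
            id = g$id, bond_order = g$bond_order[sel],
            charge = g$charge[keep])
}

#' Complete explicit hydrogens
#'
#' Graphs produced by [parse_structure()] are already hydrogen-complete; this
#' operation routes an arbitrary graph back through the valence model so that
#' every implicit hydrogen becomes an explicit atom (`is_hydrogen = TRUE`,
#' never in a ring). It is idempotent on complete graphs.
#'
#' @param g a `mol_graph`.
#' @return a hydrogen-complete `mol_graph`.
#' @export
add_explicit_hydrogens <- function(g) {
  out <- ob_to_sdf(write_molblock(g), "SDF")
  recs <- split_sdf_records(out)
  if (!length(recs))
    stop_posmna("hydrogen completion failed for molecule '", g$id,
                "': valence model rejected the structure", class = "valence")
  parse_molblock(strsplit(recs[[1L]], "\n")[[1L]], id = g$id)
}

#' Write a molecular graph as an SDF (V2000) record
#'
#' Emits a coordinate-free molblock carrying elements, bonds with their
#' parsed orders, and formal charges — enough for a lossless structural round
#' trip through [parse_structure()].
#'
#' @param g a `mol_graph`.
#' @return a single string, one SDF record terminated by `$$$$`.
#' @export
write_molblock <- function(g) {
  n <- length(g$element)
  nb <- nrow(g$edges)
  lines <- c(
    g$id, " posmna", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            g$element),
    if (nb > 0L) sprintf("%3d%3d%3d  0  0  0  0",
                         g$edges[, 1L], g$edges[, 2L], g$bond_order))
  chg <- which(g$charge != 0L)
  if (length(chg))
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, g$charge[chg]),
                                    collapse = "")))
  paste0(paste(c(lines, "M  END", "$$$$"), collapse = "\n"), "\n")
}
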