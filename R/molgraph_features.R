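## Fixed-width numeric featurization of molecular graphs: 63 binary atom
## features and 8 binary bond features, the encoding consumed by the graph
## rank predictors.

## 43 named symbols + 1 "other" slot = 44-way atom-symbol block
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

one_hot_capped <- function(value, n_slots) {
  v <- integer(n_slots)
  v[min(value, n_slots - 1L) + 1L] <- 1L
  v
}

#' Featurize a molecule as numeric graph tensors
#'
#' Atom features (63 binary): symbol one-hot over 43 common elements plus
#' an "other" slot (44), heavy-atom degree 0-5 (6), implicit hydrogen count
#' 0-4 (5), total valence 0-5 (6), aromaticity (2).  Bond features (8
#' binary): type one-hot single/double/triple/aromatic (4), conjugation
#' (2), ring membership (2).  The graph is hydrogen-suppressed; the edge
#' list is symmetric (each bond appears once, undirected).
#'
#' @param smiles A single SMILES string.
#' @return Object of class `mol_graph_features`: list with `atom_features`
#'   (n_atoms x 63), `bond_features` (n_bonds x 8), `edges` (n_bonds x 2).
#' @export
featurize_graph <- function(smiles) {
  g <- mol_graph(smiles)
  a <- g$atoms
  atom_features <- t(vapply(seq_len(nrow(a)), function(i) {
    sym_slot <- match(a$symbol[i], ATOM_SYMBOLS)
    sym <- integer(44L)
    sym[if (is.na(sym_slot)) 44L else sym_slot] <- 1L
    c(sym,
      one_hot_capped(a$degree[i], 6L),
      one_hot_capped(a$n_h[i], 5L),
      one_hot_capped(a$valence[i], 6L),
      if (a$aromatic[i]) c(0L, 1L) else c(1L, 0L))
  }, integer(63L)))
  b <- g$bonds
  bond_features <- if (nrow(b)) {
    t(vapply(seq_len(nrow(b)), function(k) {
      type <- integer(4L)
      type[if (b$aromatic[k]) 4L else min(b$order[k], 3L)] <- 1L
      c(type,
        if (b$conjugated[k]) c(0L, 1L) else c(1L, 0L),
        if (b$in_ring[k]) c(0L, 1L) else c(1L, 0L))
    }, integer(8L)))
  } else {
    matrix(integer(0), nrow = 0L, ncol = 8L)
  }
  structure(
    list(atom_features = atom_features,
         bond_features = bond_features,
         edges = cbind(a1 = b$a1, a2 = b$a2),
         smiles = g$smiles),
    class = "mol_graph_features"
  )
}

#' @export
print.mol_graph_features <- function(x, ...) {
  cat("Graph features:", nrow(x$atom_features), "atoms x 63,",
      nrow(x$bond_features), "bonds x 8\n")
  invisible(x)
}
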