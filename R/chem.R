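## Chemistry layer: SMILES parsing/canonicalization, molecular properties
## and hydrogen-suppressed molecular graphs, via ChemmineR/ChemmineOB
## (OpenBabel).  All downstream featurizers build on these helpers.

## Default valences used to infer implicit hydrogen counts from the
## kekulized connection table OpenBabel emits.
DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Se = 2, As = 3, H = 1
)

ob_quiet <- function(expr) {
  # OpenBabel prints parse warnings on stderr; keep package output clean.
  msgs <- utils::capture.output(res <- suppressWarnings(expr), type = "message")
  res
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to OpenBabel canonical form.  Unparseable strings
#' map to `NA`, which doubles as the validity check used by the profile
#' filter.
#'
#' @param smiles Character vector.
#' @return Character vector of canonical SMILES with `NA` for invalid input.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  # one conversion per molecule: a hard parse failure must not take the
  # rest of the batch down with it
  vapply(smiles, function(s) {
    res <- tryCatch(
      ob_quiet(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) ""
    )
    res <- trimws(res)
    if (!nzchar(res)) NA_character_ else res
  }, character(1), USE.NAMES = FALSE)
}

#' Parse SMILES into an SDF container
#'
#' @param smiles Character vector of SMILES.
#' @return A list with `sdf` (ChemmineR `SDFset` of the valid molecules,
#'   cids `m<i>`), `valid` (logical per input), `canonical` (canonical
#'   SMILES or `NA`).
#' @export
parse_smiles <- function(smiles) {
  canonical <- canonicalize_smiles(smiles)
  valid <- !is.na(canonical)
  sdf <- NULL
  if (any(valid)) {
    v <- smiles[valid]
    names(v) <- paste0("m", which(valid))
    sdf <- ob_quiet(ChemmineR::smiles2sdf(v))
  }
  list(sdf = sdf, valid = valid, canonical = canonical)
}

count_matches_ob <- function(sdf, smarts) {
  n <- ob_quiet(ChemmineR::smartsSearchOB(sdf, smarts, uniqueMatches = FALSE))
  as.numeric(n)
}

#' Molecular property panel
#'
#' Computes, per molecule: molecular weight, LogP, hydrogen-bond donors and
#' acceptors, rotatable bonds, aromatic rings, heteroatom and carbon counts.
#' These are the eight quantities the Muegge drug-likeness filter inspects.
#'
#' @param smiles Character vector of SMILES.
#' @return data.frame with one row per input (NA rows for unparseable
#'   SMILES) and a logical `valid` column.
#' @export
mol_properties <- function(smiles) {
  p <- parse_smiles(smiles)
  out <- data.frame(
    smiles = smiles, valid = p$valid, mw = NA_real_, logp = NA_real_,
    h_donors = NA_real_, h_acceptors = NA_real_, rot_bonds = NA_real_,
    aromatic_rings = NA_real_, heteroatoms = NA_real_, carbons = NA_real_,
    stringsAsFactors = FALSE
  )
  if (is.null(p$sdf)) return(out)
  idx <- as.integer(sub("^m", "", ChemmineR::cid(p$sdf)))
  props <- ob_quiet(ChemmineR::propOB(p$sdf))
  out$mw[idx] <- props$MW
  out$logp[idx] <- props$logP
  out$h_donors[idx] <- props$HBD
  # HBA1 is OpenBabel's standard acceptor count
  out$h_acceptors[idx] <- props$HBA1
  # rotatable bonds: directional SMARTS matches, two per bond
  out$rot_bonds[idx] <-
    count_matches_ob(p$sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]") / 2
  for (j in seq_along(idx)) {
    i <- idx[j]
    syms <- atom_symbols(p$sdf[[j]])
    out$carbons[i] <- sum(syms == "C")
    out$heteroatoms[i] <- sum(!(syms %in% c("C", "H")))
    ri <- ring_info(p$sdf[[j]])
    out$aromatic_rings[i] <- sum(ri$aromatic)
  }
  out
}

atom_symbols <- function(sdf_single) {
  ab <- ChemmineR::atomblock(sdf_single)
  sub("_.*$", "", rownames(ab))
}

## Ring perception for a single molecule: list of integer atom-index rings
## plus a logical aromatic flag per ring.
ring_info <- function(sdf_single) {
  r <- tryCatch(
    ob_quiet(ChemmineR::rings(sdf_single, type = "all", arom = TRUE)),
    error = function(e) list(RINGS = list(), AROMATIC = logical(0))
  )
  ring_atoms <- lapply(r$RINGS, function(a) as.integer(sub("^.*_", "", a)))
  list(rings = ring_atoms, aromatic = as.logical(r$AROMATIC))
}

#' Hydrogen-suppressed molecular graph
#'
#' Returns the atom and bond tables the graph featurizer consumes: atom
#' symbol, heavy-atom degree, implicit hydrogen count, total valence and
#' aromaticity; bond order (1/2/3 with an aromatic flag), conjugation and
#' ring membership.  Aromaticity comes from OpenBabel ring perception; a
#' bond is flagged conjugated when it is aromatic or adjacent to a
#' double/triple/aromatic bond.
#'
#' @param smiles A single SMILES string.
#' @return List of class `mol_graph` with `atoms` and `bonds` data.frames
#'   and the canonical SMILES.
#' @export
mol_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  p <- parse_smiles(smiles)
  if (!p$valid[1]) {
    stop_digera("cannot featurize unparseable SMILES: ", smiles,
                class = "digera_featurization_error")
  }
  mol <- p$sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  if (ncol(ab) < 3L) {
    # single-heavy-atom molecule (no bonds): the SDF connection table is
    # degenerate, so build the one-node graph from the canonical SMILES
    sym <- sub("^\\[?([A-Z][a-z]?).*$", "\\1", p$canonical[1])
    n_h <- unname(DEFAULT_VALENCE[sym])
    if (is.na(n_h)) n_h <- 0
    return(structure(
      list(
        atoms = data.frame(symbol = sym, degree = 0L, n_h = n_h,
                           valence = n_h, aromatic = FALSE,
                           stringsAsFactors = FALSE),
        bonds = data.frame(a1 = integer(0), a2 = integer(0),
                           order = integer(0), aromatic = logical(0),
                           conjugated = logical(0), in_ring = logical(0)),
        smiles = p$canonical[1]
      ),
      class = "mol_graph"
    ))
  }
  syms <- atom_symbols(mol)
  n_atoms <- length(syms)
  bb <- ChemmineR::bondblock(mol)
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = as.integer(length(bb) > 0), byrow = TRUE,
                                     dimnames = list(NULL, names(bb)))
  n_bonds <- if (is.null(bb)) 0L else nrow(bb)
  a1 <- if (n_bonds) as.integer(bb[, 1]) else integer(0)
  a2 <- if (n_bonds) as.integer(bb[, 2]) else integer(0)
  order <- if (n_bonds) as.integer(bb[, 3]) else integer(0)

  ri <- ring_info(mol)
  atom_aromatic <- rep(FALSE, n_atoms)
  bond_in_ring <- rep(FALSE, n_bonds)
  bond_aromatic <- rep(FALSE, n_bonds)
  if (length(ri$rings)) {
    for (ring_i in seq_along(ri$rings)) {
      atoms <- ri$rings[[ring_i]]
      arom <- isTRUE(ri$aromatic[ring_i])
      if (arom) atom_aromatic[atoms] <- TRUE
      m <- length(atoms)
      pairs <- cbind(atoms, atoms[c(2:m, 1)])
      for (b in seq_len(n_bonds)) {
        hit <- any((a1[b] == pairs[, 1] & a2[b] == pairs[, 2]) |
                   (a1[b] == pairs[, 2] & a2[b] == pairs[, 1]))
        if (hit) {
          bond_in_ring[b] <- TRUE
          if (arom) bond_aromatic[b] <- TRUE
        }
      }
    }
  }

  degree <- tabulate(c(a1, a2), nbins = n_atoms)
  bond_order_sum <- rep(0, n_atoms)
  for (b in seq_len(n_bonds)) {
    bond_order_sum[a1[b]] <- bond_order_sum[a1[b]] + order[b]
    bond_order_sum[a2[b]] <- bond_order_sum[a2[b]] + order[b]
  }
  default_val <- unname(DEFAULT_VALENCE[syms])
  default_val[is.na(default_val)] <- 0
  n_h <- pmax(0, default_val - bond_order_sum)
  valence <- degree + n_h

  # atom carries pi density if aromatic or incident to a multiple bond
  atom_pi <- atom_aromatic
  if (n_bonds) {
    multi <- which(order >= 2L | bond_aromatic)
    atom_pi[c(a1[multi], a2[multi])] <- TRUE
  }
  conjugated <- vapply(seq_len(n_bonds), function(b) {
    if (bond_aromatic[b]) return(TRUE)
    neigh <- setdiff(which(a1 %in% c(a1[b], a2[b]) | a2 %in% c(a1[b], a2[b])), b)
    any(order[neigh] >= 2L | bond_aromatic[neigh])
  }, logical(1))

  structure(
    list(
      atoms = data.frame(symbol = syms, degree = degree, n_h = n_h,
                         valence = valence, aromatic = atom_aromatic,
                         stringsAsFactors = FALSE),
      bonds = data.frame(a1 = a1, a2 = a2, order = order,
                         aromatic = bond_aromatic, conjugated = conjugated,
                         in_ring = bond_in_ring),
      smiles = p$canonical[1]
    ),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("Molecular graph:", nrow(x$atoms), "atoms,", nrow(x$bonds), "bonds (",
      x$smiles, ")\n")
  invisible(x)
}
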