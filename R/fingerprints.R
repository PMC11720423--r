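## Molecular fingerprints: 166-bit MACCS keys (OpenBabel), Morgan-style
## hashed circular fingerprints (ECFP6 / FCFP4, 1024 bits), an 881-bit
## hashed structural fingerprint at PubChem width, and a pluggable
## embedding provider slot for pretrained models such as MFBERT.

FP_WIDTHS <- c(maccs = 166L, ecfp6 = 1024L, fcfp4 = 1024L, pcfp = 881L)
FP_ORDER <- c("maccs", "ecfp6", "fcfp4", "pcfp", "mfbert")

#' MACCS keys (166 bits)
#'
#' Computed by OpenBabel's MACCS pattern set; the 166 keys occupy the first
#' 166 positions of the block OpenBabel returns.
#'
#' @param smiles Character vector of SMILES (all must parse).
#' @return Binary matrix, one row per molecule, 166 columns.
#' @export
maccs_fingerprint <- function(smiles) {
  p <- parse_smiles(smiles)
  if (!all(p$valid)) {
    stop_digera("unparseable SMILES: ",
                paste(smiles[!p$valid], collapse = ", "),
                class = "digera_featurization_error")
  }
  fp <- ob_quiet(ChemmineR::fingerprintOB(p$sdf, "MACCS"))
  m <- ChemmineR::as.matrix(fp)[, seq_len(166L), drop = FALSE]
  rownames(m) <- smiles
  colnames(m) <- paste0("maccs_", seq_len(166L))
  storage.mode(m) <- "integer"
  m
}

## Initial atom invariants for the Morgan iteration.
## type = "connectivity" (ECFP): element, degree, H count, valence, ring,
## aromatic.  type = "functional" (FCFP): pharmacophoric role bits --
## donor, acceptor, aromatic, halogen.
atom_invariants <- function(graph, type = c("connectivity", "functional")) {
  type <- match.arg(type)
  a <- graph$atoms
  in_ring <- rep(FALSE, nrow(a))
  if (nrow(graph$bonds)) {
    ring_bonds <- graph$bonds[graph$bonds$in_ring, , drop = FALSE]
    in_ring[unique(c(ring_bonds$a1, ring_bonds$a2))] <- TRUE
  }
  if (type == "connectivity") {
    vapply(seq_len(nrow(a)), function(i) {
      hash_ints(c(match(a$symbol[i], names(DEFAULT_VALENCE), nomatch = 99L),
                  a$degree[i], a$n_h[i], a$valence[i],
                  as.integer(in_ring[i]), as.integer(a$aromatic[i])))
    }, numeric(1))
  } else {
    donor <- a$symbol %in% c("N", "O") & a$n_h > 0
    acceptor <- a$symbol %in% c("N", "O")
    halogen <- a$symbol %in% c("F", "Cl", "Br", "I")
    vapply(seq_len(nrow(a)), function(i) {
      hash_ints(c(as.integer(donor[i]), as.integer(acceptor[i]),
                  as.integer(a$aromatic[i]), as.integer(halogen[i])))
    }, numeric(1))
  }
}

## One molecule's Morgan-style circular fingerprint identifiers: iterative
## neighbourhood hashing up to `radius`, duplicate environments dropped.
morgan_ids <- function(graph, radius, type) {
  ids <- atom_invariants(graph, type)
  all_ids <- ids
  b <- graph$bonds
  n_atoms <- nrow(graph$atoms)
  if (n_atoms == 0L) return(numeric(0))
  nbrs <- vector("list", n_atoms)
  if (nrow(b)) {
    bond_code <- ifelse(b$aromatic, 4L, b$order)
    for (k in seq_len(nrow(b))) {
      nbrs[[b$a1[k]]] <- rbind(nbrs[[b$a1[k]]], c(bond_code[k], b$a2[k]))
      nbrs[[b$a2[k]]] <- rbind(nbrs[[b$a2[k]]], c(bond_code[k], b$a1[k]))
    }
  }
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(n_atoms)) {
      if (is.null(nbrs[[i]])) next
      env <- cbind(nbrs[[i]][, 1], ids[nbrs[[i]][, 2]])
      env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
      new_ids[i] <- hash_ints(c(r, ids[i], t(env)))
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  unique(all_ids)
}

fold_bits <- function(ids, n_bits) {
  v <- integer(n_bits)
  v[(ids %% n_bits) + 1L] <- 1L
  v
}

#' Morgan-style hashed circular fingerprint
#'
#' Iterative neighbourhood hashing of atom environments up to
#' `diameter / 2`, folded into `n_bits` positions.  `type = "connectivity"`
#' uses ECFP-style atom invariants (element, degree, hydrogens, valence,
#' ring, aromaticity); `type = "functional"` uses FCFP-style pharmacophoric
#' roles (donor, acceptor, aromatic, halogen).
#'
#' @param smiles Character vector of SMILES.
#' @param diameter Environment diameter (6 for ECFP6, 4 for FCFP4).
#' @param n_bits Folded width (default 1024).
#' @param type Invariant family.
#' @return Binary matrix, one row per molecule.
#' @export
morgan_fingerprint <- function(smiles, diameter = 6L, n_bits = 1024L,
                               type = c("connectivity", "functional")) {
  type <- match.arg(type)
  radius <- as.integer(diameter) %/% 2L
  m <- t(vapply(smiles, function(s) {
    g <- mol_graph(s)
    fold_bits(morgan_ids(g, radius, type), n_bits)
  }, integer(n_bits)))
  rownames(m) <- smiles
  colnames(m) <- paste0(if (type == "connectivity") "ecfp_" else "fcfp_",
                        seq_len(n_bits))
  m
}

#' 881-bit hashed structural fingerprint (PubChem width)
#'
#' A hashed substructure fingerprint folded to the 881-bit width of the
#' PubChem structural-key system: radius-2 connectivity environments plus
#' element counts.  The key semantics are this package's own hashing, not
#' the PubChem key dictionary.
#'
#' @param smiles Character vector of SMILES.
#' @return Binary matrix with 881 columns.
#' @export
pubchem_width_fingerprint <- function(smiles) {
  n_bits <- 881L
  m <- t(vapply(smiles, function(s) {
    g <- mol_graph(s)
    ids <- morgan_ids(g, 2L, "connectivity")
    counts <- table(g$atoms$symbol)
    count_ids <- vapply(seq_along(counts), function(i) {
      hash_ints(c(1e6, utf8ToInt(names(counts)[i]), min(counts[[i]], 8L)))
    }, numeric(1))
    fold_bits(c(ids, count_ids), n_bits)
  }, integer(n_bits)))
  rownames(m) <- smiles
  colnames(m) <- paste0("pcfp_", seq_len(n_bits))
  m
}

#' Tanimoto similarity between two binary fingerprints
#'
#' @param a,b Binary vectors of equal length.
#' @return Similarity in \[0, 1\] (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(1)
  inter / uni
}

## ---- Embedding providers (MFBERT slot) --------------------------------

provider_registry <- new.env(parent = emptyenv())

#' Register an embedding provider
#'
#' Pretrained molecular embeddings (e.g. MFBERT) enter the pipeline through
#' this contract: a name, an output dimension, and a batch `embed` function
#' mapping SMILES to a numeric matrix.
#'
#' @param name Provider name (the `"mfbert"` slot is used by
#'   [fingerprint_concat()]).
#' @param dimension Output width.
#' @param embed `function(smiles)` returning an `n x dimension` matrix.
#' @export
register_embedding_provider <- function(name, dimension, embed) {
  stopifnot(is.character(name), is.function(embed))
  assign(name, list(name = name, dimension = as.integer(dimension),
                    embed = embed),
         envir = provider_registry)
  invisible(name)
}

#' @rdname register_embedding_provider
#' @export
get_embedding_provider <- function(name) {
  if (!exists(name, envir = provider_registry, inherits = FALSE)) {
    stop_digera("no embedding provider registered under '", name, "'",
                class = "digera_configuration_error")
  }
  get(name, envir = provider_registry, inherits = FALSE)
}

#' Deterministic hash-based embedding provider
#'
#' A stand-in provider for tests and offline runs: embeds a molecule by
#' hashing its canonical SMILES into `dimension` pseudo-random but fully
#' deterministic values in \[-1, 1\].  Carries no chemical information
#' beyond molecule identity.
#'
#' @param dimension Embedding width (default 64).
#' @return The provider list (also registered under `"mfbert"`).
#' @export
hash_embedding_provider <- function(dimension = 64L) {
  dimension <- as.integer(dimension)
  embed <- function(smiles) {
    canon <- canonicalize_smiles(smiles)
    m <- t(vapply(canon, function(s) {
      if (is.na(s)) {
        stop_digera("unparseable SMILES in embedding request",
                    class = "digera_featurization_error")
      }
      h <- hash_string(s)
      vapply(seq_len(dimension), function(j) {
        (hash_ints(c(h, j)) / HASH_MOD) * 2 - 1
      }, numeric(1))
    }, numeric(dimension)))
    rownames(m) <- smiles
    m
  }
  register_embedding_provider("mfbert", dimension, embed)
  get_embedding_provider("mfbert")
}

#' Concatenated fingerprint blocks
#'
#' Blocks are concatenated in the canonical order MACCS (166), ECFP6
#' (1024), FCFP4 (1024), PCFP (881), MFBERT (provider dimension); the
#' `layout` attribute records each block's name and width.
#'
#' @param smiles Character vector of SMILES.
#' @param blocks Subset of `c("maccs", "ecfp6", "fcfp4", "pcfp", "mfbert")`.
#' @return Numeric matrix with a `layout` attribute (named widths).
#' @export
fingerprint_concat <- function(smiles,
                               blocks = c("maccs", "ecfp6", "fcfp4", "pcfp")) {
  blocks <- match.arg(blocks, FP_ORDER, several.ok = TRUE)
  blocks <- FP_ORDER[FP_ORDER %in% blocks]
  parts <- lapply(blocks, function(b) {
    switch(b,
      maccs = maccs_fingerprint(smiles),
      ecfp6 = morgan_fingerprint(smiles, 6L, 1024L, "connectivity"),
      fcfp4 = morgan_fingerprint(smiles, 4L, 1024L, "functional"),
      pcfp = pubchem_width_fingerprint(smiles),
      mfbert = get_embedding_provider("mfbert")$embed(smiles)
    )
  })
  out <- do.call(cbind, parts)
  layout <- vapply(parts, ncol, integer(1))
  names(layout) <- blocks
  attr(out, "layout") <- layout
  out
}
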