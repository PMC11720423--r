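## Synthetic data with planted ground truth: drug-like SMILES, Z-score
## profile sets with a linear chemistry -> expression signal, low-rank
## gene-effect matrices, and separable activity classes.  Every generator
## is fully determined by its seed.

## Scaffold/substituent library for drug-like SMILES enumeration.  The
## fragments are written so that plain string substitution yields valid
## SMILES; generated molecules span both sides of the 200 and 600 g/mol
## filter boundaries.
SYN_SCAFFOLDS <- c(
  "%sc1ccc(%s)cc1",                 # benzene
  "%sc1ccc(%s)cn1",                 # pyridine
  "%sc1ccc2ccccc2c1",               # naphthalene (single slot via %s%s trick)
  "%sc1ccc(-c2ccc(%s)cc2)cc1",      # biphenyl
  "%sc1ccc(C(=O)N%s)cc1",           # benzamide
  "%sc1nc2ccccc2s1",                # benzothiazole
  "%sC1CCN(%s)CC1",                 # piperidine
  "%sc1ccc(S(=O)(=O)N%s)cc1"        # sulfonamide
)
SYN_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "CCCCCCCC", "CCCCCCCCCCCCCCCC",
  strrep("C", 40L),
  "OC", "OCC", "N", "NC", "Cl", "F", "Br", "C(F)(F)F",
  "C(=O)O", "C(=O)OC", "C(=O)N", "C(C)C", "OCCOCCOCC", "CCN(CC)CC"
)

#' Generate valid drug-like SMILES
#'
#' Samples scaffold/substituent combinations from an internal library;
#' every output parses, and the molecular-weight distribution spans both
#' sides of the 200 and 600 g/mol boundaries so downstream filters are
#' exercised.
#'
#' @param n Number of molecules (>= 1); duplicates allowed once the
#'   library is exhausted.
#' @param seed RNG seed.
#' @return Character vector of `n` SMILES.
#' @export
gen_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  combos <- expand.grid(scaffold = SYN_SCAFFOLDS, a = SYN_SUBSTITUENTS,
                        b = SYN_SUBSTITUENTS, stringsAsFactors = FALSE)
  with_seed(seed, {
    pick <- sample(nrow(combos), n, replace = n > nrow(combos))
    vapply(pick, function(i) {
      sc <- combos$scaffold[i]
      n_slots <- lengths(regmatches(sc, gregexpr("%s", sc, fixed = TRUE)))
      if (n_slots == 2L) sprintf(sc, combos$a[i], combos$b[i])
      else sprintf(sc, combos$a[i])
    }, character(1))
  })
}

#' Specification for a synthetic profile set
#'
#' The planted model is `Z = mu + MACCS(chem) %*% W + noise`: a gene-wise
#' baseline response `mu` shared by every profile (the consensus structure
#' real signature collections exhibit), plus each molecule's 166-bit MACCS
#' fingerprint mapped linearly to gene expression through a Gaussian
#' weight matrix `W`.  Replicate experiments are independent noise draws;
#' an optional outlier fraction of chemicals has all its replicates
#' rank-permuted by one shared permutation (an aberrant experimental
#' group).
#'
#' @param n_chems Number of distinct molecules.
#' @param n_genes Genes per profile (default 100 for tests; use 978 for
#'   integration scale).
#' @param n_dupes Replicate experiments per condition (default 1).
#' @param noise_sd Gaussian noise SD on Z (default 0.1; the planted signal
#'   has roughly unit scale).
#' @param baseline_sd SD of the shared gene-wise baseline `mu` (default
#'   1).
#' @param outlier_frac Fraction of profiles receiving the shared aberrant
#'   permutation (default 0).
#' @param cell_lines,doses,times Condition vocabularies sampled uniformly.
#' @param seed RNG seed.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_profile_spec <- function(n_chems = 30L, n_genes = 100L,
                                   n_dupes = 1L, noise_sd = 0.1,
                                   baseline_sd = 1, outlier_frac = 0,
                                   cell_lines = c("MCF7", "PC3", "VCAP"),
                                   doses = c(5, 10), times = c(6, 24),
                                   seed = 1L) {
  structure(
    list(n_chems = as.integer(n_chems), n_genes = as.integer(n_genes),
         n_dupes = as.integer(n_dupes), noise_sd = noise_sd,
         baseline_sd = baseline_sd,
         outlier_frac = outlier_frac, cell_lines = cell_lines,
         doses = doses, times = times, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic profile set with ground truth
#'
#' @param spec A [synthetic_profile_spec()].
#' @return List with `profiles` (a `profile_set`), `truth` (the weight
#'   matrix `W`, per-chem clean Z and rank matrices, fingerprints, and the
#'   outlier profile ids).
#' @export
gen_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  smiles <- gen_molecules(spec$n_chems, seed = spec$seed)
  fp <- maccs_fingerprint(smiles)
  with_seed(spec$seed + 1L, {
    W <- matrix(stats::rnorm(166L * spec$n_genes, sd = 1 / sqrt(166)),
                166L, spec$n_genes)
    mu <- stats::rnorm(spec$n_genes, sd = spec$baseline_sd)
    clean_z <- sweep(fp %*% W, 2, mu, "+")
    colnames(clean_z) <- paste0("g", seq_len(spec$n_genes))
    clean_rank <- t(apply(clean_z, 1, zscore_to_ranks))
    cell <- sample(spec$cell_lines, spec$n_chems, replace = TRUE)
    dose <- sample(spec$doses, spec$n_chems, replace = TRUE)
    time <- sample(spec$times, spec$n_chems, replace = TRUE)
    rows <- list()
    meta <- list()
    pid <- 0L
    for (i in seq_len(spec$n_chems)) {
      for (d in seq_len(spec$n_dupes)) {
        pid <- pid + 1L
        z <- clean_z[i, ] +
          stats::rnorm(spec$n_genes, sd = spec$noise_sd)
        rows[[pid]] <- z
        meta[[pid]] <- data.frame(
          profile_id = sprintf("p%04d", pid), smiles = smiles[i],
          cell_line = cell[i], dose_um = dose[i], time_h = time[i],
          chem_index = i, stringsAsFactors = FALSE
        )
      }
    }
    z <- do.call(rbind, rows)
    colnames(z) <- colnames(clean_z)
    meta <- do.call(rbind, meta)
    n_total <- nrow(meta)
    outlier_ids <- character(0)
    if (spec$outlier_frac > 0) {
      # corrupt whole chemicals: every replicate of the selected chems
      # receives one shared rank permutation, forming a coherent aberrant
      # experimental group (what the k-means screen is meant to catch)
      n_out_chems <- max(1L, round(spec$outlier_frac * spec$n_chems))
      out_chems <- sample(spec$n_chems, n_out_chems)
      out_idx <- which(meta$chem_index %in% out_chems)
      perm <- sample(spec$n_genes)
      z[out_idx, ] <- z[out_idx, perm, drop = FALSE]
      outlier_ids <- meta$profile_id[out_idx]
    }
    ps <- profile_set(meta[, c("profile_id", "smiles", "cell_line",
                               "dose_um", "time_h")], z)
    list(
      profiles = ps,
      truth = list(W = W, mu = mu, smiles = smiles, fingerprints = fp,
                   clean_z = clean_z, clean_rank = clean_rank,
                   chem_index = meta$chem_index,
                   outlier_ids = outlier_ids)
    )
  })
}

#' Generate a low-rank synthetic gene-effect matrix
#'
#' `effects = scores %*% t(loadings) + noise` with `rank` planted factors;
#' used to exercise the cell-line PCA featurizer.
#'
#' @param n_cell_lines,n_genes Matrix dimensions.
#' @param rank Number of planted factors.
#' @param noise_sd Residual noise SD.
#' @param factor_sd SD of the planted factor scores (default 1).
#' @param missing_frac Fraction of entries set to NA (default 0).
#' @param seed RNG seed.
#' @return List with `effects` (matrix with dimnames) and `truth`.
#' @export
gen_gene_effects <- function(n_cell_lines = 100L, n_genes = 500L,
                             rank = 10L, noise_sd = 0.05, factor_sd = 1,
                             missing_frac = 0, seed = 1L) {
  with_seed(seed, {
    scores <- matrix(stats::rnorm(n_cell_lines * rank, sd = factor_sd),
                     n_cell_lines, rank)
    loadings <- matrix(stats::rnorm(n_genes * rank), n_genes, rank)
    effects <- scores %*% t(loadings) +
      matrix(stats::rnorm(n_cell_lines * n_genes, sd = noise_sd),
             n_cell_lines, n_genes)
    dimnames(effects) <- list(paste0("CL", seq_len(n_cell_lines)),
                              paste0("g", seq_len(n_genes)))
    if (missing_frac > 0) {
      miss <- sample(length(effects), round(missing_frac * length(effects)))
      effects[miss] <- NA
    }
    list(effects = effects,
         truth = list(scores = scores, loadings = loadings, rank = rank))
  })
}

#' Generate a separable synthetic activity set
#'
#' Synthetic fingerprint classes: active and inactive/decoy compounds draw
#' their bits from Bernoulli profiles that differ on a fraction
#' `separation` of the bit positions (0 = indistinguishable classes,
#' 1 = fully separated).  Potency values follow the 1 uM rule: actives
#' draw Ki/Kd/IC50 below 1 uM, inactives at or above 1 uM or undetermined,
#' decoys carry no measurement.
#'
#' @param n_active,n_inactive,n_decoy Class counts.
#' @param separation Fraction of discriminative bits in \[0, 1\].
#' @param n_bits Fingerprint width (default 256).
#' @param seed RNG seed.
#' @return List with `records` (activity data.frame, labeled) and
#'   `fingerprints` (binary matrix).
#' @export
gen_activity_set <- function(n_active, n_inactive, n_decoy, separation,
                             n_bits = 256L, seed = 1L) {
  stopifnot(separation >= 0)
  with_seed(seed, {
    p_base <- stats::runif(n_bits, 0.15, 0.45)
    p_active <- p_base
    n_disc <- round(min(separation, 1) * n_bits)
    if (n_disc > 0) {
      disc <- sample(n_bits, n_disc)
      p_active[disc] <- 1 - p_base[disc]
    }
    draw <- function(n, p) {
      m <- matrix(stats::rbinom(n * n_bits, 1L, rep(p, each = n)), n, n_bits)
      colnames(m) <- paste0("b", seq_len(n_bits))
      m
    }
    fp <- rbind(draw(n_active, p_active), draw(n_inactive, p_base),
                draw(n_decoy, p_base))
    measure <- sample(c("Ki", "Kd", "IC50"), n_active + n_inactive,
                      replace = TRUE)
    records <- data.frame(
      smiles = sprintf("SYN%05d", seq_len(n_active + n_inactive + n_decoy)),
      measure_type = c(measure, rep(NA_character_, n_decoy)),
      value_um = c(stats::runif(n_active, 0.001, 0.999),
                   ifelse(stats::runif(n_inactive) < 0.8,
                          stats::runif(n_inactive, 1, 100), NA_real_),
                   rep(NA_real_, n_decoy)),
      label = c(rep(NA_character_, n_active + n_inactive),
                rep("decoy", n_decoy)),
      stringsAsFactors = FALSE
    )
    records <- label_activity(records)
    list(records = records, fingerprints = fp)
  })
}
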