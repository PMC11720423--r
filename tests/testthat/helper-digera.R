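# Shared fixtures: everything is generated in code at test time.

random_rank_vector <- function(n, ties = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n)
  if (ties) z <- round(z, 1)  # coarse rounding plants tie groups
  zscore_to_ranks(z)
}

tiny_profile_set <- function(n = 6L, n_genes = 20L, seed = 1L) {
  set.seed(seed)
  smiles <- gen_molecules(n, seed = seed)
  meta <- data.frame(
    profile_id = sprintf("p%02d", seq_len(n)), smiles = smiles,
    cell_line = rep(c("MCF7", "PC3"), length.out = n),
    dose_um = rep(c(5, 10), length.out = n),
    time_h = rep(c(6, 24), length.out = n), stringsAsFactors = FALSE
  )
  z <- matrix(stats::rnorm(n * n_genes), n, n_genes,
              dimnames = list(NULL, paste0("g", seq_len(n_genes))))
  profile_set(meta, z)
}
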