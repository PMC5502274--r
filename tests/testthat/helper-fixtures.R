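# Shared fixtures, built in code.

# Three planted 5-stage response patterns: mutually near-orthogonal (so the
# unsigned network separates them) with all-distinct stage values (so the
# 5-point permutation distribution has no exact ties).
planted_patterns <- function() {
  list(
    up_late = c(0.0, 0.3, 1.2, 2.0, 2.5),
    u_shape = c(2.4, 0.1, 1.3, 0.3, 2.1),
    early_late = c(0.2, 2.4, 1.1, 0.4, 2.2)
  )
}

# Small two-module study used across tests.
small_study_config <- function(seed = 11, ...) {
  pats <- planted_patterns()
  simulation_config(
    n_genes = 300, n_metabolites = 8, seed = seed,
    modules = list(
      list(module_id = "M1", size = 60, response_pattern = pats$up_late),
      list(module_id = "M2", size = 60, response_pattern = pats$u_shape)
    ),
    metabolite_links = list(
      list(metabolite_id = "anthoA", module_id = "M1", link_strength = 0.95)
    ),
    motif_plants = list(
      list(motif = "ACGTGKC", module_id = "M1", carrier_fraction = 0.6,
           background_fraction = 0.05)
    ),
    extra_motifs = c("CACGTG", "RYCGAC"),
    ...
  )
}

# Minimal sample metadata: S stages x 2 treatments x n_reps replicates.
toy_samples <- function(stages = c(26, 53), n_reps = 3) {
  grid <- expand.grid(replicate = seq_len(n_reps), treatment = c("CT", "WD"),
                      stage_daa = stages, stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = sprintf("%s_%d_r%d", grid$treatment, grid$stage_daa,
                        grid$replicate),
    stage_daa = as.integer(grid$stage_daa),
    treatment = grid$treatment,
    replicate = as.integer(grid$replicate)
  )
}

# Expression tibble from a features x samples matrix.
toy_values <- function(mat, samples, id = "feature_id") {
  stopifnot(ncol(mat) == nrow(samples))
  colnames(mat) <- samples$sample_id
  out <- tibble::as_tibble(mat)
  out <- dplyr::bind_cols(tibble::tibble(!!id := rownames(mat) %||%
                                           paste0("f", seq_len(nrow(mat)))),
                          out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force motif counting oracle: expand the IUPAC motif to all concrete
# words, then count every (overlapping) window equal to one of them.
oracle_motif_count <- function(sequence, motif) {
  words <- expand_iupac(motif)
  k <- nchar(motif)
  sequence <- toupper(sequence)
  n <- nchar(sequence) - k + 1
  if (n < 1) return(0L)
  windows <- substring(sequence, seq_len(n), seq_len(n) + k - 1)
  sum(windows %in% words)
}

# Exhaustive permutation distribution of the correlation of x with permuted y.
all_perm_correlations <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  vapply(perms(seq_along(y)), function(idx) stats::cor(x, y[idx]), numeric(1))
}
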