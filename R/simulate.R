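#' Configuration for a synthetic water-deficit study
#'
#' Builds and validates the configuration object consumed by the simulators.
#' The defaults emulate the design of a two-treatment (control vs water
#' deficit), five-stage, three-replicate berry field study: negative-binomial
#' counts with planted co-response modules, metabolite profiles tied to
#' chosen modules, and promoters carrying planted degenerate motifs.
#'
#' @param n_genes,n_metabolites Number of features to simulate.
#' @param n_stages Number of developmental stages (default 5).
#' @param n_reps Biological replicates per treatment and stage (default 3).
#' @param stage_daa Integer stage labels in days after anthesis; defaults to
#'   `c(26, 53, 67, 81, 106)` when `n_stages == 5`, else `1:n_stages`.
#' @param modules List of planted modules, each a list with `module_id`,
#'   `size`, `response_pattern` (numeric vector of `n_stages` log2FC means)
#'   and optional `noise_sd` (gene-level scatter around the pattern, default
#'   0.2). Genes not covered by any module are null genes with zero planted
#'   response.
#' @param metabolite_links List of planted module-metabolite links, each a
#'   list with `metabolite_id`, `module_id` and `link_strength` in \[0, 1\].
#' @param motif_plants List of planted promoter motifs, each a list with
#'   `motif` (IUPAC 6-8-mer), `module_id`, `carrier_fraction` and
#'   `background_fraction` (both in \[0, 1\], carrier >= background).
#' @param extra_motifs Additional catalog motifs scanned but not planted.
#' @param promoter_length Promoter length in bp (default 1000, i.e. the 1 kb
#'   upstream convention).
#' @param gc_content Expected GC fraction of the promoter background.
#' @param nb_dispersion Global negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param baseline_log2_mean_range Range of per-gene baseline log2 mean
#'   counts, sampled uniformly.
#' @param metab_rep_noise_sd Replicate-level log-scale noise of metabolite
#'   concentrations.
#' @param seed Integer seed; identical configurations give byte-identical
#'   outputs.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_genes,
                              n_metabolites = 0,
                              n_stages = 5,
                              n_reps = 3,
                              stage_daa = NULL,
                              modules = list(),
                              metabolite_links = list(),
                              motif_plants = list(),
                              extra_motifs = character(),
                              promoter_length = 1000,
                              gc_content = 0.5,
                              nb_dispersion = 0.1,
                              baseline_log2_mean_range = c(4, 10),
                              metab_rep_noise_sd = 0.1,
                              seed = 1L) {
  stop_cfg <- function(...) {
    stop("Invalid simulation config: ", ..., call. = FALSE)
  }
  if (n_genes < 1) stop_cfg("`n_genes` must be a positive integer.")
  if (n_stages < 1) stop_cfg("`n_stages` must be a positive integer.")
  if (n_reps < 1) stop_cfg("`n_reps` must be a positive integer.")
  if (is.null(stage_daa)) {
    stage_daa <- if (n_stages == 5) c(26L, 53L, 67L, 81L, 106L) else seq_len(n_stages)
  }
  if (length(stage_daa) != n_stages) {
    stop_cfg("`stage_daa` must have length `n_stages`.")
  }
  modules <- lapply(modules, function(m) {
    if (is.null(m$noise_sd)) m$noise_sd <- 0.2
    if (is.null(m$module_id) || is.null(m$size) || is.null(m$response_pattern)) {
      stop_cfg("each module needs `module_id`, `size`, `response_pattern`.")
    }
    if (length(m$response_pattern) != n_stages) {
      stop_cfg("module '", m$module_id, "': `response_pattern` must have length ",
               n_stages, " (one mean log2FC per stage).")
    }
    if (m$noise_sd < 0) stop_cfg("module '", m$module_id, "': `noise_sd` must be >= 0.")
    m
  })
  if (length(modules) > 0) {
    sizes <- vapply(modules, function(m) as.numeric(m$size), numeric(1))
    if (sum(sizes) > n_genes) {
      stop_cfg("sum of module sizes (", sum(sizes),
               ") exceeds `n_genes` (", n_genes, ").")
    }
    ids <- vapply(modules, function(m) m$module_id, character(1))
    if (anyDuplicated(ids)) stop_cfg("duplicate module ids.")
  }
  module_ids <- vapply(modules, function(m) m$module_id, character(1))
  for (l in metabolite_links) {
    if (is.null(l$metabolite_id) || is.null(l$module_id) || is.null(l$link_strength)) {
      stop_cfg("each metabolite link needs `metabolite_id`, `module_id`, `link_strength`.")
    }
    if (!l$module_id %in% module_ids) {
      stop_cfg("metabolite link '", l$metabolite_id,
               "' references unknown module '", l$module_id, "'.")
    }
    if (l$link_strength < 0 || l$link_strength > 1) {
      stop_cfg("link_strength must lie in [0, 1].")
    }
  }
  if (length(metabolite_links) > n_metabolites) {
    stop_cfg("more metabolite links than metabolites.")
  }
  for (mp in motif_plants) {
    if (is.null(mp$motif) || is.null(mp$module_id) ||
        is.null(mp$carrier_fraction) || is.null(mp$background_fraction)) {
      stop_cfg("each motif plant needs `motif`, `module_id`, ",
               "`carrier_fraction`, `background_fraction`.")
    }
    validate_iupac(mp$motif)
    if (!mp$module_id %in% module_ids) {
      stop_cfg("motif plant '", mp$motif, "' references unknown module '",
               mp$module_id, "'.")
    }
    if (mp$carrier_fraction < mp$background_fraction) {
      stop_cfg("motif '", mp$motif, "': carrier_fraction (",
               mp$carrier_fraction, ") must be >= background_fraction (",
               mp$background_fraction, "); depletion plants are rejected.")
    }
    if (nchar(mp$motif) > promoter_length) {
      stop_cfg("motif '", mp$motif, "' (", nchar(mp$motif),
               " bp) cannot fit in promoters of length ", promoter_length, ".")
    }
  }
  for (m in extra_motifs) validate_iupac(m)
  if (gc_content <= 0 || gc_content >= 1) stop_cfg("`gc_content` must be in (0, 1).")
  if (nb_dispersion <= 0) stop_cfg("`nb_dispersion` must be positive.")
  if (promoter_length < 1) stop_cfg("`promoter_length` must be positive.")
  if (length(baseline_log2_mean_range) != 2 ||
      diff(baseline_log2_mean_range) < 0) {
    stop_cfg("`baseline_log2_mean_range` must be an increasing interval.")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_metabolites = as.integer(n_metabolites),
      n_stages = as.integer(n_stages),
      n_reps = as.integer(n_reps),
      stage_daa = as.integer(stage_daa),
      modules = modules,
      metabolite_links = metabolite_links,
      motif_plants = motif_plants,
      extra_motifs = extra_motifs,
      promoter_length = as.integer(promoter_length),
      gc_content = gc_content,
      nb_dispersion = nb_dispersion,
      baseline_log2_mean_range = baseline_log2_mean_range,
      metab_rep_noise_sd = metab_rep_noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

sim_sample_meta <- function(cfg) {
  grid <- expand.grid(
    replicate = seq_len(cfg$n_reps),
    treatment = c("CT", "WD"),
    stage_daa = cfg$stage_daa,
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample_id = sprintf("%s_%03d_r%d", grid$treatment, grid$stage_daa, grid$replicate),
    stage_daa = as.integer(grid$stage_daa),
    treatment = grid$treatment,
    replicate = as.integer(grid$replicate)
  )
}

#' Simulate a replicated two-treatment expression experiment
#'
#' Draws negative-binomial counts for `n_genes` across all
#' stage x treatment x replicate samples. Control means are constant across
#' stages; water-deficit means are the control means scaled by
#' `2^planted_log2fc`, where the planted per-gene log2FC is the module's
#' response pattern plus gene-level Gaussian scatter (`noise_sd`). Genes not
#' in any module have zero planted response. A log2-normalized table
#' (`log2(count / size_factor + 1)`, median-of-ratios size factors) is
#' returned alongside the raw counts as a variance-stabilization stand-in.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `counts` and `vst` (tibbles, `feature_id` + one column
#'   per sample), `samples` (sample metadata tibble) and `truth` (a list with
#'   `gene_module` and `planted_log2fc` tibbles).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  withr::with_seed(cfg$seed, {
    gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))
    gene_module <- rep("null", cfg$n_genes)
    planted <- matrix(0, cfg$n_genes, cfg$n_stages,
                      dimnames = list(gene_ids, paste0("s", cfg$stage_daa)))
    at <- 1L
    for (m in cfg$modules) {
      idx <- seq.int(at, length.out = m$size)
      gene_module[idx] <- m$module_id
      noise <- matrix(stats::rnorm(m$size * cfg$n_stages, 0, m$noise_sd),
                      m$size, cfg$n_stages)
      planted[idx, ] <- matrix(m$response_pattern, m$size, cfg$n_stages,
                               byrow = TRUE) + noise
      at <- at + m$size
    }
    samples <- sim_sample_meta(cfg)
    base_mu <- 2^stats::runif(cfg$n_genes,
                              cfg$baseline_log2_mean_range[1],
                              cfg$baseline_log2_mean_range[2])
    size_param <- 1 / cfg$nb_dispersion
    counts <- matrix(0L, cfg$n_genes, nrow(samples),
                     dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      s_idx <- match(samples$stage_daa[j], cfg$stage_daa)
      mu <- if (samples$treatment[j] == "WD") {
        base_mu * 2^planted[, s_idx]
      } else {
        base_mu
      }
      counts[, j] <- stats::rnbinom(cfg$n_genes, mu = mu, size = size_param)
    }
    sf <- median_of_ratios(counts)
    vst <- log2(sweep(counts, 2, sf, "/") + 1)
    truth <- list(
      gene_module = tibble::tibble(feature_id = gene_ids, module_id = gene_module),
      planted_log2fc = tibble::as_tibble(planted, rownames = "feature_id")
    )
    list(
      counts = tibble::as_tibble(counts, rownames = "feature_id"),
      vst = tibble::as_tibble(vst, rownames = "feature_id"),
      samples = samples,
      truth = truth
    )
  })
}

# Median-of-ratios size factors; genes with any zero count are excluded from
# the geometric-mean reference (their log geomean is -Inf).
median_of_ratios <- function(counts) {
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    warning("No gene has all-positive counts; size factors set to 1.")
    return(rep(1, ncol(counts)))
  }
  apply(counts[usable, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[usable]))
  })
}

#' Simulate metabolite concentrations linked to planted modules
#'
#' Each linked metabolite's stage-wise log2FC(WD/CT) profile is a convex
#' blend `link_strength * module_profile + (1 - link_strength) * noise`,
#' where the module profile defaults to the mean planted response of the
#' module's genes. Unlinked metabolites are pure noise. Replicate-level
#' concentrations are positive: a log-normal baseline per metabolite, scaled
#' by `2^profile` under water deficit, with log-scale replicate scatter.
#'
#' @param cfg A [simulation_config()].
#' @param truth Ground-truth list from [simulate_expression()].
#' @param module_profiles Optional named list of module response profiles
#'   (numeric vectors over stages) overriding the truth-derived means.
#' @return A list with `metabolites` (tibble: `metabolite_id`, `class`, one
#'   column per sample) and `truth` (tibble `metabolite_module`).
#' @export
simulate_metabolites <- function(cfg, truth, module_profiles = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(module_profiles)) {
    planted <- as.matrix(truth$planted_log2fc[, -1])
    module_profiles <- lapply(
      stats::setNames(nm = unique(truth$gene_module$module_id)),
      function(mid) {
        colMeans(planted[truth$gene_module$module_id == mid, , drop = FALSE])
      }
    )
  }
  for (l in cfg$metabolite_links) {
    if (!l$module_id %in% names(module_profiles)) {
      stop("Metabolite link references unknown module '", l$module_id, "'.",
           call. = FALSE)
    }
  }
  link_ids <- vapply(cfg$metabolite_links, function(l) l$metabolite_id, character(1))
  n_fill <- cfg$n_metabolites - length(link_ids)
  met_ids <- c(link_ids, sprintf("met%03d", seq_len(cfg$n_metabolites))[
    !sprintf("met%03d", seq_len(cfg$n_metabolites)) %in% link_ids
  ][seq_len(max(n_fill, 0))])
  classes <- rep(c("anthocyanin", "amino_acid", "phenolic", "voc"),
                 length.out = cfg$n_metabolites)
  samples <- sim_sample_meta(cfg)
  withr::with_seed(derive_seed(cfg$seed, 1L), {
    conc <- matrix(0, cfg$n_metabolites, nrow(samples),
                   dimnames = list(met_ids, samples$sample_id))
    met_module <- rep("null", cfg$n_metabolites)
    for (i in seq_len(cfg$n_metabolites)) {
      link <- if (i <= length(cfg$metabolite_links)) cfg$metabolite_links[[i]] else NULL
      noise <- stats::rnorm(cfg$n_stages)
      profile <- if (!is.null(link)) {
        met_module[i] <- link$module_id
        link$link_strength * module_profiles[[link$module_id]] +
          (1 - link$link_strength) * noise
      } else {
        noise
      }
      base <- stats::rlnorm(1, meanlog = log(100), sdlog = 1)
      for (j in seq_len(nrow(samples))) {
        s_idx <- match(samples$stage_daa[j], cfg$stage_daa)
        mu <- base * if (samples$treatment[j] == "WD") 2^profile[s_idx] else 1
        conc[i, j] <- mu * exp(stats::rnorm(1, 0, cfg$metab_rep_noise_sd))
      }
    }
    list(
      metabolites = dplyr::bind_cols(
        tibble::tibble(metabolite_id = met_ids, class = classes),
        tibble::as_tibble(conc)
      ),
      truth = tibble::tibble(metabolite_id = met_ids, module_id = met_module)
    )
  })
}

#' Simulate promoter sequences with planted degenerate motifs
#'
#' Every gene receives a random sequence of `promoter_length` bases with
#' expected GC content `gc_content`. For each motif plant, one concrete
#' expansion of the IUPAC motif (sampled uniformly per insertion) is written
#' at a random position, forward strand, in `carrier_fraction` of the target
#' module's genes and `background_fraction` of all other genes.
#'
#' @param cfg A [simulation_config()].
#' @param truth Ground-truth list from [simulate_expression()].
#' @return A list with `promoters` (tibble: `gene_id`, `sequence`), `motifs`
#'   (tibble: `motif`, `label`) and `truth` (tibble `motif_module`).
#' @export
simulate_promoters <- function(cfg, truth) {
  stopifnot(inherits(cfg, "simulation_config"))
  gene_ids <- truth$gene_module$feature_id
  gene_module <- truth$gene_module$module_id
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
             cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  withr::with_seed(derive_seed(cfg$seed, 2L), {
    seqs <- vapply(seq_along(gene_ids), function(i) {
      paste(sample(bases, cfg$promoter_length, replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(seqs) <- gene_ids
    for (mp in cfg$motif_plants) {
      k <- nchar(mp$motif)
      in_mod <- which(gene_module == mp$module_id)
      out_mod <- which(gene_module != mp$module_id)
      carriers <- c(
        sample(in_mod, round(mp$carrier_fraction * length(in_mod))),
        if (length(out_mod) > 0) {
          sample(out_mod, round(mp$background_fraction * length(out_mod)))
        }
      )
      for (g in carriers) {
        instance <- sample_iupac_expansion(mp$motif)
        pos <- sample.int(cfg$promoter_length - k + 1, 1)
        substr(seqs[g], pos, pos + k - 1) <- instance
      }
    }
    planted_motifs <- vapply(cfg$motif_plants, function(mp) mp$motif, character(1))
    motif_module <- vapply(cfg$motif_plants, function(mp) mp$module_id, character(1))
    motifs <- unique(c(planted_motifs, cfg$extra_motifs))
    list(
      promoters = tibble::tibble(gene_id = gene_ids, sequence = unname(seqs)),
      motifs = tibble::tibble(motif = motifs, label = motifs),
      truth = tibble::tibble(
        motif = planted_motifs,
        module_id = motif_module
      )
    )
  })
}

#' Synthetic per-stage differential-expression table
#'
#' Produces the DE-table input that, for real data, an upstream count-based
#' differential-expression analysis would supply. Per stage, a moderated
#' t-test (limma on the log2-normalized values, mean-variance trend) compares
#' treatments per gene; p-values are BH-adjusted within each stage and rows
#' with `padj < alpha` are reported with their log2FC (difference of log2
#' means) and direction. The moderated test gives realistic power at the
#' three-replicate design the generator emulates.
#'
#' @param vst Log2-normalized expression tibble from [simulate_expression()].
#' @param samples Sample metadata tibble.
#' @param alpha Adjusted-p cutoff for calling a gene DE (default 0.05).
#' @return A DE-table tibble: `gene_id`, `stage_daa`, `log2fc`, `padj`,
#'   `direction`.
#' @export
simulate_de_table <- function(vst, samples, alpha = 0.05) {
  mat <- as.matrix(vst[, -1])
  rownames(mat) <- vst[[1]]
  out <- list()
  for (s in sort(unique(samples$stage_daa))) {
    cols <- samples$sample_id[samples$stage_daa == s]
    trt <- factor(samples$treatment[match(cols, samples$sample_id)],
                  levels = c("CT", "WD"))
    design <- stats::model.matrix(~trt)
    fit <- limma::lmFit(mat[, cols, drop = FALSE], design)
    fit <- tryCatch(limma::eBayes(fit, trend = TRUE),
                    error = function(e) limma::eBayes(fit))
    tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
    lfc <- tt$logFC
    padj <- tt$adj.P.Val
    keep <- which(padj < alpha & lfc != 0)
    if (length(keep) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        gene_id = rownames(mat)[keep],
        stage_daa = as.integer(s),
        log2fc = unname(lfc[keep]),
        padj = unname(padj[keep]),
        direction = ifelse(lfc[keep] > 0, "up", "down")
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(gene_id = character(), stage_daa = integer(),
                          log2fc = numeric(), padj = numeric(),
                          direction = character()))
  }
  dplyr::bind_rows(out)
}

# Welch t-test p-value robust to zero-variance groups.
safe_two_group_p <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Simulate the full input stack of a water-deficit study
#'
#' Convenience wrapper running [simulate_expression()],
#' [simulate_de_table()], [simulate_metabolites()] and
#' [simulate_promoters()] under one configuration, assembling the combined
#' ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return A `berry_sim` list: `counts`, `vst`, `samples`, `de`,
#'   `metabolites`, `promoters`, `motifs`, `truth` (with `gene_module`,
#'   `metabolite_module`, `motif_module`, `planted_log2fc`).
#' @export
simulate_study <- function(cfg) {
  expr <- simulate_expression(cfg)
  de <- simulate_de_table(expr$vst, expr$samples)
  met <- simulate_metabolites(cfg, expr$truth)
  prom <- simulate_promoters(cfg, expr$truth)
  structure(
    list(
      counts = expr$counts,
      vst = expr$vst,
      samples = expr$samples,
      de = de,
      metabolites = met$metabolites,
      promoters = prom$promoters,
      motifs = prom$motifs,
      truth = list(
        gene_module = expr$truth$gene_module,
        metabolite_module = met$truth,
        motif_module = prom$truth,
        planted_log2fc = expr$truth$planted_log2fc
      )
    ),
    class = "berry_sim"
  )
}

#' Write a simulated study to disk
#'
#' Writes `counts.tsv`, `vst.tsv`, `samples.tsv`, `de_table.tsv`,
#' `metabolites.tsv`, `promoters.fasta`, `motifs.txt` and `truth/*.tsv`
#' under `outdir`, in the formats the readers in this package consume.
#'
#' @param sim A `berry_sim` from [simulate_study()].
#' @param outdir Output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "berry_sim"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  write_tsv_plain(sim$counts, file.path(outdir, "counts.tsv"))
  write_tsv_plain(sim$vst, file.path(outdir, "vst.tsv"))
  write_tsv_plain(sim$samples, file.path(outdir, "samples.tsv"))
  write_tsv_plain(sim$de, file.path(outdir, "de_table.tsv"))
  write_tsv_plain(sim$metabolites, file.path(outdir, "metabolites.tsv"))
  write_fasta(sim$promoters, file.path(outdir, "promoters.fasta"))
  writeLines(paste(sim$motifs$motif, sim$motifs$label, sep = "\t"),
             file.path(outdir, "motifs.txt"))
  write_tsv_plain(sim$truth$gene_module, file.path(outdir, "truth", "gene_module.tsv"))
  write_tsv_plain(sim$truth$metabolite_module,
                  file.path(outdir, "truth", "metabolite_module.tsv"))
  write_tsv_plain(sim$truth$motif_module, file.path(outdir, "truth", "motif_module.tsv"))
  write_tsv_plain(sim$truth$planted_log2fc,
                  file.path(outdir, "truth", "planted_log2fc.tsv"))
  invisible(outdir)
}

# Small deterministic seed derivation kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}
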