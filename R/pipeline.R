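# End-to-end orchestration: simulate/read -> response profiles -> modules
# (co-response + developmental) -> CRE enrichment -> module-metabolite screen
# -> subnetwork -> export, with a manifest and run log.

pipeline_known_keys <- list(
  top = c("simulation", "inputs", "response", "modules", "cre", "policy",
          "network", "outdir", "seed"),
  inputs = c("counts", "vst", "samples", "de_table", "metabolites",
             "promoters", "motifs"),
  response = c("pseudocount_counts", "pseudocount_metabolites"),
  modules = c("coresponse", "development"),
  module_params = c("power", "network_type", "min_module_size", "cut_height",
                    "merge_cut", "label_prefix"),
  cre = c("strands", "fdr_threshold"),
  policy = c("pcc_min", "p_emp_max", "n_perm", "use_abs_for_edges",
             "representative"),
  network = c("tf_genes", "max_genes")
)

validate_pipeline_config <- function(config) {
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0) {
      stop("Unknown configuration key '", unknown[1], "' in ", where, ".",
           call. = FALSE)
    }
  }
  check_keys(config, pipeline_known_keys$top, "config")
  if (is.null(config$simulation) && is.null(config$inputs)) {
    stop("Config needs either a `simulation` block or an `inputs` block.",
         call. = FALSE)
  }
  if (!is.null(config$inputs)) {
    check_keys(config$inputs, pipeline_known_keys$inputs, "inputs")
  }
  if (!is.null(config$response)) {
    check_keys(config$response, pipeline_known_keys$response, "response")
  }
  if (!is.null(config$modules)) {
    check_keys(config$modules, pipeline_known_keys$modules, "modules")
    for (m in names(config$modules)) {
      check_keys(config$modules[[m]], pipeline_known_keys$module_params,
                 paste0("modules$", m))
    }
  }
  if (!is.null(config$cre)) check_keys(config$cre, pipeline_known_keys$cre, "cre")
  if (!is.null(config$policy)) {
    check_keys(config$policy, pipeline_known_keys$policy, "policy")
  }
  if (!is.null(config$network)) {
    check_keys(config$network, pipeline_known_keys$network, "network")
  }
  if (is.null(config$outdir)) stop("Config needs `outdir`.", call. = FALSE)
  invisible(config)
}

pipeline_stage <- function(stage, log_con, expr) {
  writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] start"),
             log_con)
  tryCatch(expr, error = function(e) {
    writeLines(paste0("[", stage, "] FAILED: ", conditionMessage(e)), log_con)
    stop("Pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the integrated analysis pipeline
#'
#' Executes the full analysis: input simulation (or loading from disk),
#' stage-wise response profiles and per-stage metabolite ANOVA, co-response
#' and developmental module detection on the differentially expressed gene
#' universe, promoter motif enrichment per module, the module-metabolite
#' co-response screen, subnetwork construction, and export (TSV tables, SIF
#' and GraphML networks, a JSON manifest and a run log). Re-running with the
#' same configuration reproduces every numeric output.
#'
#' @param config Path to a YAML configuration file or an equivalent named
#'   list. Unknown keys are rejected before any computation. See the bundled
#'   `demo_config.yaml` under `inst/extdata` for the full schema.
#' @return Invisibly, a list with the in-memory results (`sim` or inputs,
#'   `profiles`, `modules`, `enrichment`, `coresponse`, `network`,
#'   `outdir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_pipeline_config(config)
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- pipeline_stage("simulate", log_con, {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(simulation_config, sim_args)
      simulate_study(cfg)
    })
    counts <- sim$counts; vst <- sim$vst; samples <- sim$samples
    de <- sim$de; metab <- sim$metabolites
    promoters <- sim$promoters; motifs <- sim$motifs
  } else {
    sim <- NULL
    inp <- config$inputs
    loaded <- pipeline_stage("load", log_con, {
      cx <- read_expression(inp$counts, inp$samples, mode = "counts")
      vx <- read_expression(inp$vst, inp$samples, mode = "vst")
      mx <- read_metabolites(inp$metabolites, inp$samples)
      list(counts = cx$values, vst = vx$values, samples = cx$samples,
           de = read_de_table(inp$de_table),
           metab = mx$values,
           promoters = read_promoters(inp$promoters),
           motifs = read_motifs(inp$motifs))
    })
    counts <- loaded$counts; vst <- loaded$vst; samples <- loaded$samples
    de <- loaded$de; metab <- loaded$metab
    promoters <- loaded$promoters; motifs <- loaded$motifs
  }

  # --- response profiles ----------------------------------------------------
  resp_cfg <- config$response %||% list()
  profiles <- pipeline_stage("respond", log_con, {
    gene_lfc <- log2_fold_change(counts, samples,
                                 pseudocount = resp_cfg$pseudocount_counts %||% 1)
    met_vals <- metab[, setdiff(names(metab), "class")]
    met_lfc <- log2_fold_change(met_vals, samples,
                                pseudocount = resp_cfg$pseudocount_metabolites)
    anova <- stagewise_anova(met_vals, samples)
    clust <- cluster_response_profiles(met_lfc)
    pca <- pca_scores(t(profiles_to_matrix_wide(vst)), center = TRUE,
                      scale = FALSE)
    list(gene_lfc = gene_lfc, met_lfc = met_lfc, anova = anova,
         clust = clust, pca = pca)
  })

  # --- modules --------------------------------------------------------------
  de_genes <- sort(unique(de$gene_id))
  mods <- pipeline_stage("modules", log_con, {
    ds1 <- profiles$gene_lfc[profiles$gene_lfc$feature_id %in% de_genes, ]
    co_params <- do.call(network_params, utils::modifyList(
      list(min_module_size = 20, label_prefix = "WD"),
      config$modules$coresponse %||% list()
    ))
    dev_params <- do.call(network_params, utils::modifyList(
      list(min_module_size = 30, label_prefix = "DEV"),
      config$modules$development %||% list()
    ))
    if (length(de_genes) < max(2, co_params$min_module_size)) {
      # a (near-)null dataset: too few DE genes to support any module
      co <- empty_module_set(de_genes, co_params)
      dev <- empty_module_set(de_genes, dev_params)
    } else {
      co <- detect_coresponse_modules(ds1, co_params)
      ds2 <- vst[vst$feature_id %in% de_genes, ]
      dev <- detect_coresponse_modules(ds2, dev_params)
    }
    list(coresponse = co, development = dev, ds1 = ds1)
  })

  # --- CRE enrichment -------------------------------------------------------
  cre_cfg <- config$cre %||% list()
  enrichment <- pipeline_stage("cre-enrich", log_con, {
    background <- intersect(de_genes, promoters$gene_id)
    assign_bg <- mods$coresponse$assignment[
      mods$coresponse$assignment$feature_id %in% background, ]
    if (length(background) == 0 || nrow(motifs) == 0 ||
        all(assign_bg$module == "unassigned")) {
      empty_enrichment()
    } else {
      matches <- scan_promoters(promoters[promoters$gene_id %in% background, ],
                                motifs, strands = cre_cfg$strands %||% "both")
      module_cre_enrichment(matches, assign_bg, background = background,
                            fdr_threshold = cre_cfg$fdr_threshold %||% 0.01)
    }
  })

  # --- module-metabolite co-response ---------------------------------------
  pol_cfg <- config$policy %||% list()
  policy <- threshold_policy(
    pcc_min = pol_cfg$pcc_min %||% 0.8,
    p_emp_max = pol_cfg$p_emp_max %||% 0.01,
    n_perm = pol_cfg$n_perm %||% 1000,
    use_abs_for_edges = pol_cfg$use_abs_for_edges %||% FALSE
  )
  coresp <- pipeline_stage("coresponse", log_con, {
    if (is.null(mods$coresponse$eigengenes)) {
      tibble::tibble(module = character(), metabolite_id = character(),
                     pcc = numeric(), p_emp = numeric(), passes = logical())
    } else {
      reps <- module_representatives(mods$coresponse, mods$ds1,
                                     mode = pol_cfg$representative %||% "eigengene")
      module_metabolite_coresponse(reps, profiles$met_lfc, policy, seed = seed)
    }
  })

  # --- subnetwork -----------------------------------------------------------
  net <- pipeline_stage("network", log_con, {
    assign <- mods$coresponse$assignment
    genes <- assign$feature_id[assign$module != "unassigned"]
    max_genes <- config$network$max_genes %||% 400L
    if (length(genes) > max_genes) genes <- sort(genes)[seq_len(max_genes)]
    mets <- unique(coresp$metabolite_id[coresp$passes])
    tf_genes <- unlist(config$network$tf_genes) %||% character()
    kinds <- dplyr::bind_rows(
      tibble::tibble(
        id = genes,
        kind = as.character(ifelse(genes %in% tf_genes, "TF", "structural_gene")),
        module_id = assign$module[match(genes, assign$feature_id)],
        annotation = ""
      ),
      tibble::tibble(id = mets, kind = "metabolite",
                     module_id = "", annotation = "")
    )
    all_profiles <- dplyr::bind_rows(
      profiles$gene_lfc[profiles$gene_lfc$feature_id %in% genes, ],
      profiles$met_lfc[profiles$met_lfc$feature_id %in% mets, ]
    )
    build_subnetwork(all_profiles, kinds, policy, seed = seed)
  })

  # --- export ---------------------------------------------------------------
  pipeline_stage("export", log_con, {
    write_tsv_plain(profiles$gene_lfc, file.path(outdir, "log2fc_genes.tsv"))
    write_tsv_plain(profiles$met_lfc, file.path(outdir, "log2fc_metabolites.tsv"))
    write_tsv_plain(profiles$anova, file.path(outdir, "anova.tsv"))
    write_tsv_plain(profiles$clust$order, file.path(outdir, "cluster_order.tsv"))
    write_tsv_plain(profiles$pca$scores, file.path(outdir, "pca_scores.tsv"))
    write_tsv_plain(mods$coresponse$assignment,
                    file.path(outdir, "assignment_coresponse.tsv"))
    write_tsv_plain(mods$development$assignment,
                    file.path(outdir, "assignment_development.tsv"))
    if (!is.null(mods$coresponse$eigengenes)) {
      write_tsv_plain(mods$coresponse$eigengenes,
                      file.path(outdir, "eigengenes_coresponse.tsv"))
    }
    write_tsv_plain(enrichment, file.path(outdir, "enrichment.tsv"))
    write_tsv_plain(coresp, file.path(outdir, "module_metabolite.tsv"))
    write_network(net, "sif", file.path(outdir, "network.sif"))
    write_network(net, "graphml", file.path(outdir, "network.graphml"))
    manifest <- list(
      package = "berrynet",
      version = as.character(utils::packageVersion("berrynet")),
      seed = seed,
      config = config,
      soft_power = list(coresponse = mods$coresponse$power,
                        development = mods$development$power),
      policy = unclass(policy),
      n_de_genes = length(de_genes),
      outputs = list.files(outdir)
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  writeLines("done", log_con)
  invisible(list(sim = sim, profiles = profiles, modules = mods,
                 enrichment = enrichment, coresponse = coresp, network = net,
                 outdir = outdir))
}

empty_module_set <- function(feature_ids, params) {
  structure(
    list(
      assignment = tibble::tibble(feature_id = feature_ids,
                                  module = rep("unassigned", length(feature_ids))),
      eigengenes = NULL,
      var_explained = tibble::tibble(module = character(),
                                     var_explained = numeric(),
                                     size = integer()),
      power = NA_real_,
      params = params,
      excluded = character()
    ),
    class = "module_set"
  )
}

empty_enrichment <- function() {
  tibble::tibble(module = character(), motif = character(), k = integer(),
                 n = integer(), K = integer(), N = integer(), p = numeric(),
                 fdr = numeric(), score = numeric(), enriched = logical())
}

# wide tibble (feature_id + sample columns) -> features x samples matrix
profiles_to_matrix_wide <- function(values) {
  mat <- as.matrix(values[, -1])
  rownames(mat) <- values[[1]]
  mat
}
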