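long_profiles <- function(mat, stages = c(26L, 53L, 67L, 81L, 106L)) {
  tibble::tibble(
    feature_id = rep(rownames(mat), each = ncol(mat)),
    stage_daa = rep(stages[seq_len(ncol(mat))], nrow(mat)),
    log2fc = as.vector(t(mat)))
}

test_that("threshold policy validates its ranges", {
  expect_error(threshold_policy(pcc_min = 1.2), "pcc_min")
  expect_error(threshold_policy(p_emp_max = 0), "p_emp_max")
  expect_error(threshold_policy(n_perm = 0), "n_perm")
  pol <- threshold_policy()
  expect_equal(pol$pcc_min, 0.8)
  expect_equal(pol$p_emp_max, 0.01)
  expect_equal(pol$n_perm, 1000L)
})

test_that("network container enforces canonical form and referential integrity", {
  nodes <- tibble::tibble(id = c("b", "a"), kind = c("TF", "metabolite"))
  edges <- tibble::tibble(source = "b", target = "a", pcc = 0.9, p_emp = 0.005,
                          edge_kind = "gene-metabolite")
  net <- coresponse_network(nodes, edges)
  expect_equal(net$edges$source, "a")   # canonical order
  expect_equal(net$edges$target, "b")
  expect_equal(net$nodes$id, c("a", "b"))
  expect_error(coresponse_network(nodes, dplyr::mutate(edges, target = "b")),
               "Self-edges")
  expect_error(coresponse_network(nodes, dplyr::mutate(edges, target = "zz")),
               "unknown node")
  expect_error(coresponse_network(dplyr::mutate(nodes, kind = "gene"), edges),
               "Unknown node kind")
})

test_that("module-metabolite screen flags a perfect planted link", {
  pats <- planted_patterns()
  mod_profile <- tibble::tibble(module = "WD1",
                                s26 = pats$up_late[1], s53 = pats$up_late[2],
                                s67 = pats$up_late[3], s81 = pats$up_late[4],
                                s106 = pats$up_late[5])
  met <- long_profiles(rbind(linked = pats$up_late))
  # n_perm large enough to resolve p below the 0.01 threshold
  res <- module_metabolite_coresponse(mod_profile, met,
                                      threshold_policy(n_perm = 20000),
                                      seed = 1)
  expect_equal(res$pcc, 1, tolerance = 1e-12)
  expect_lt(res$p_emp, 0.01)
  expect_true(res$passes)
  # threshold semantics: an impossibly high cutoff blocks the same pair
  strict <- threshold_policy(pcc_min = 0.999999, n_perm = 200)
  res2 <- module_metabolite_coresponse(mod_profile,
                                       long_profiles(rbind(x = pats$u_shape)),
                                       strict, seed = 1)
  expect_false(res2$passes)
  # misaligned stage axes are an error
  met3 <- long_profiles(rbind(linked = pats$up_late[1:4]),
                        stages = c(26L, 53L, 67L, 81L))
  expect_error(module_metabolite_coresponse(mod_profile, met3, seed = 1),
               "misaligned")
})

test_that("unlinked metabolites pass the screen in at most 5% of seeds", {
  pats <- planted_patterns()
  mod_profile <- tibble::tibble(module = "WD1",
                                s26 = pats$up_late[1], s53 = pats$up_late[2],
                                s67 = pats$up_late[3], s81 = pats$up_late[4],
                                s106 = pats$up_late[5])
  passes <- vapply(1:100, function(s) {
    withr::with_seed(7000 + s, {
      met <- long_profiles(matrix(rnorm(5), 1,
                                  dimnames = list("m1", NULL)))
    })
    module_metabolite_coresponse(mod_profile, met,
                                 threshold_policy(n_perm = 1000),
                                 seed = s)$passes
  }, logical(1))
  expect_lte(sum(passes), 5)
})

test_that("subnetwork contains exactly the policy-passing pairs", {
  pats <- planted_patterns()
  withr::with_seed(60, {
    mat <- rbind(
      tf1 = pats$up_late + rnorm(5, sd = 0.05),
      g1 = pats$up_late + rnorm(5, sd = 0.05),
      g2 = pats$up_late + rnorm(5, sd = 0.05),
      g3 = pats$u_shape + rnorm(5, sd = 0.05),
      met1 = pats$up_late + rnorm(5, sd = 0.05),
      met2 = rnorm(5))
  })
  kinds <- tibble::tibble(
    id = rownames(mat),
    kind = c("TF", rep("structural_gene", 3), "metabolite", "metabolite"))
  profiles <- long_profiles(mat)
  policy <- threshold_policy(pcc_min = 0.8, p_emp_max = 0.2, n_perm = 499)
  net <- build_subnetwork(profiles, kinds, policy, seed = 3)
  # no metabolite-metabolite edges ever
  met_ids <- kinds$id[kinds$kind == "metabolite"]
  expect_false(any(net$edges$source %in% met_ids &
                     net$edges$target %in% met_ids))
  # every edge satisfies the policy
  expect_true(all(net$edges$pcc > policy$pcc_min))
  expect_true(all(net$edges$p_emp < policy$p_emp_max))
  # idempotence: re-deriving the screen from profiles reproduces the edges
  redo <- build_subnetwork(profiles, kinds, policy, seed = 3)
  expect_identical(net$edges, redo$edges)
  # edges found between the co-responding cluster, none to the stray gene
  expect_false("g3" %in% c(net$edges$source, net$edges$target))
  expect_gt(sum(net$edges$edge_kind == "gene-gene"), 0)
  # empty metabolite set: gene-gene edges only
  net2 <- build_subnetwork(profiles[profiles$feature_id %in% kinds$id[1:4], ],
                           kinds[1:4, ], policy, seed = 3)
  expect_true(all(net2$edges$edge_kind == "gene-gene"))
  # missing profile is an error naming the id
  expect_error(build_subnetwork(profiles, dplyr::bind_rows(
    kinds, tibble::tibble(id = "ghost", kind = "TF")), policy), "ghost")
})

test_that("identical gene profiles are fully connected at pcc 1", {
  pats <- planted_patterns()
  mat <- rbind(g1 = pats$up_late, g2 = pats$up_late, g3 = pats$up_late)
  kinds <- tibble::tibble(id = rownames(mat), kind = "structural_gene")
  net <- build_subnetwork(long_profiles(mat), kinds,
                          threshold_policy(n_perm = 20000), seed = 2)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$pcc, rep(1, 3), tolerance = 1e-12)
})

test_that("planted links are recovered and unplanted ones stay absent", {
  pats <- planted_patterns()
  cfg <- simulation_config(
    n_genes = 150, n_metabolites = 3, seed = 71, metab_rep_noise_sd = 0.02,
    modules = list(list(module_id = "M1", size = 50,
                        response_pattern = pats$up_late, noise_sd = 0.1)),
    metabolite_links = list(
      list(metabolite_id = "linked", module_id = "M1", link_strength = 1)))
  ex <- simulate_expression(cfg)
  met <- simulate_metabolites(cfg, ex$truth)
  mlfc <- log2_fold_change(met$metabolites[, setdiff(names(met$metabolites),
                                                     "class")],
                           ex$samples, pseudocount = NULL)
  gene_ids <- ex$truth$gene_module$feature_id[
    ex$truth$gene_module$module_id == "M1"][1:10]
  glfc <- log2_fold_change(ex$counts, ex$samples)
  kinds <- dplyr::bind_rows(
    tibble::tibble(id = gene_ids[1], kind = "TF"),
    tibble::tibble(id = gene_ids[-1], kind = "structural_gene"),
    tibble::tibble(id = met$metabolites$metabolite_id, kind = "metabolite"))
  profiles <- dplyr::bind_rows(glfc[glfc$feature_id %in% gene_ids, ], mlfc)
  net <- build_subnetwork(profiles, kinds,
                          threshold_policy(n_perm = 20000), seed = 5)
  linked_edges <- net$edges[net$edges$edge_kind == "gene-metabolite", ]
  touched <- unique(c(linked_edges$source, linked_edges$target))
  expect_true("linked" %in% touched)
  expect_false(any(c("met001", "met002") %in% touched))
})

test_that("the pipeline runs end to end, rejects unknown keys, and handles nulls", {
  outdir <- file.path(withr::local_tempdir(), "run")
  config <- list(
    simulation = list(
      n_genes = 150, n_metabolites = 4, seed = 19,
      modules = list(
        list(module_id = "M1", size = 50,
             response_pattern = planted_patterns()$up_late)),
      motif_plants = list(
        list(motif = "ACGTGKC", module_id = "M1", carrier_fraction = 0.8,
             background_fraction = 0.05))),
    policy = list(n_perm = 199),
    network = list(max_genes = 40),
    outdir = outdir, seed = 19)
  res <- suppressWarnings(run_pipeline(config))
  expect_true(all(file.exists(file.path(outdir, c(
    "log2fc_genes.tsv", "anova.tsv", "assignment_coresponse.tsv",
    "enrichment.tsv", "module_metabolite.tsv", "network.sif",
    "network.graphml", "manifest.json", "run.log")))))
  expect_s3_class(res$network, "coresponse_network")
  enr <- readr::read_tsv(file.path(outdir, "enrichment.tsv"),
                         show_col_types = FALSE)
  expect_true(any(enr$motif == "ACGTGKC" & enr$enriched))

  bad <- config; bad$typo <- 1
  expect_error(run_pipeline(bad), "Unknown configuration key 'typo'")
  bad2 <- config; bad2$policy$nonsense <- 1
  expect_error(run_pipeline(bad2), "Unknown configuration key 'nonsense'")

  # null data: no planted structure -> no modules, no edges, no enrichment
  null_out <- file.path(withr::local_tempdir(), "null")
  null_cfg <- list(simulation = list(n_genes = 120, n_metabolites = 3,
                                     seed = 23),
                   policy = list(n_perm = 199),
                   outdir = null_out, seed = 23)
  res0 <- suppressWarnings(run_pipeline(null_cfg))
  expect_equal(nrow(res0$network$edges), 0)
  expect_false(any(res0$enrichment$enriched))
  expect_false(any(res0$coresponse$passes))
})

test_that("pipeline outputs can be read from a YAML configuration", {
  outdir <- file.path(withr::local_tempdir(), "yamlrun")
  cfg_path <- file.path(withr::local_tempdir(), "cfg.yaml")
  yaml::write_yaml(list(
    simulation = list(n_genes = 100, n_metabolites = 2, seed = 9,
                      modules = list(list(module_id = "M1", size = 40,
                                          response_pattern = c(0, 0.3, 1.2, 2.0, 2.5)))),
    policy = list(n_perm = 99),
    outdir = outdir, seed = 9), cfg_path)
  res <- suppressWarnings(run_pipeline(cfg_path))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_equal(manifest$seed, 9)
})
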