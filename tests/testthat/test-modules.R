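# Simulated profile matrix with block structure: each block shares a latent
# vector, mixed with independent noise to reach roughly the target
# correlation. Optionally adds independent singleton features.
block_profiles <- function(n_per_block, n_blocks, n_obs, within_r, seed,
                           n_singletons = 0) {
  withr::with_seed(seed, {
    sizes <- rep_len(n_per_block, n_blocks)
    lat <- matrix(rnorm(n_blocks * n_obs), n_blocks)
    w <- sqrt(within_r)
    mat <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      t(vapply(seq_len(sizes[b]), function(i) {
        w * lat[b, ] + sqrt(1 - w^2) * rnorm(n_obs)
      }, numeric(n_obs)))
    }))
    rownames(mat) <- sprintf("b%d_%02d",
                             rep(seq_len(n_blocks), times = sizes),
                             unlist(lapply(sizes, seq_len)))
    if (n_singletons > 0) {
      noise <- matrix(rnorm(n_singletons * n_obs), n_singletons)
      rownames(noise) <- sprintf("s%02d", seq_len(n_singletons))
      mat <- rbind(mat, noise)
    }
    mat
  })
}

test_that("TOM formula matches hand evaluation and basic limits", {
  # two perfectly correlated features: a = 1, TOM = 1
  m <- rbind(f1 = c(1, 2, 3, 4), f2 = c(2, 4, 6, 8))
  tom <- adjacency_tom(m, power = 6)
  expect_equal(tom[1, 2], 1)
  # two uncorrelated features with no shared neighbors: TOM = 0
  m0 <- rbind(f1 = c(1, -1, 1, -1), f2 = c(1, 1, -1, -1))
  expect_equal(adjacency_tom(m0, power = 6)[1, 2], 0)
  # random profiles vs direct triple-loop evaluation
  withr::with_seed(20, { mr <- matrix(rnorm(6 * 8), nrow = 6) })
  rownames(mr) <- paste0("g", 1:6)
  beta <- 5
  tom2 <- adjacency_tom(mr, power = beta)
  a <- abs(stats::cor(t(mr)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  for (i in 1:5) for (j in (i + 1):6) {
    l_ij <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    oracle <- (l_ij + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    expect_equal(tom2[i, j], oracle, tolerance = 1e-12)
  }
})

test_that("TOM is symmetric with unit diagonal and entries in [0, 1]", {
  withr::with_seed(21, { m <- matrix(rnorm(30 * 6), nrow = 30) })
  rownames(m) <- paste0("g", 1:30)
  tom <- adjacency_tom(m, power = 9)
  expect_equal(tom, t(tom))
  expect_equal(unname(diag(tom)), rep(1, 30))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # unsigned adjacency is monotone decreasing in beta for |r| < 1
  r <- abs(stats::cor(t(m)))
  off <- upper.tri(r)
  expect_true(all(r[off]^9 <= r[off]^6 + 1e-15))
  expect_error(adjacency_tom(rbind(m, flat = rep(2, 6)), power = 6),
               "Zero-variance")
})

test_that("soft power selection prefers block-structured data and falls back sanely", {
  # degenerate: all pairwise |r| = 1 -> undefined fit, smallest candidate
  m <- rbind(a = 1:10, b = 2 * (1:10), c = 3 * (1:10) + 1,
             d = -2 * (1:10), e = 0.5 * (1:10))
  w <- testthat::capture_warnings(
    sel <- select_soft_power(m, candidate_powers = c(3, 6, 9)))
  expect_true(any(grepl("undefined", w)))
  expect_equal(sel$power, 3)
  # single candidate is returned regardless of fit
  withr::with_seed(22, { mr <- matrix(rnorm(25 * 10), nrow = 25) })
  rownames(mr) <- paste0("g", 1:25)
  sel1 <- suppressWarnings(select_soft_power(mr, candidate_powers = 6))
  expect_equal(sel1$power, 6)
  # planted 3-block data (blocks 20/15/10 plus independent genes):
  # selected power >= 4 in the majority of seeds
  picks <- vapply(1:20, function(s) {
    m <- block_profiles(c(20, 15, 10), 3, 30, within_r = 0.81,
                        seed = 1000 + s, n_singletons = 15)
    suppressWarnings(select_soft_power(m)$power)
  }, numeric(1))
  expect_gte(mean(picks >= 4), 0.5)
})

test_that("module detection recovers planted blocks and rejects noise", {
  m <- block_profiles(50, 2, 20, within_r = 0.95, seed = 30)
  tom <- adjacency_tom(m, power = 6)
  asg <- detect_modules(tom, network_params(min_module_size = 10))
  truth <- sub("_.*", "", rownames(m))
  expect_equal(length(setdiff(unique(asg$module), "unassigned")), 2)
  expect_equal(module_recovery_ari(asg$module, truth), 1.0)
  # all features identical: one module containing everything
  ident <- matrix(rep(1:6, each = 12), nrow = 12) +
    matrix(rnorm(72, sd = 1e-8), nrow = 12)
  rownames(ident) <- paste0("g", 1:12)
  asg2 <- detect_modules(adjacency_tom(ident, power = 6),
                         network_params(min_module_size = 5))
  expect_equal(unique(asg2$module), "WD1")
  # independent features: everything unassigned in >= 18/20 seeds
  all_un <- vapply(1:20, function(s) {
    withr::with_seed(3000 + s, {
      mi <- matrix(rnorm(10 * 12), nrow = 10)
    })
    rownames(mi) <- paste0("g", 1:10)
    asg <- detect_modules(adjacency_tom(mi, power = 9),
                          network_params(min_module_size = 5))
    all(asg$module == "unassigned")
  }, logical(1))
  expect_gte(sum(all_un), 18)
})

test_that("module eigengene matches an eigendecomposition oracle", {
  # identical members: eigengene proportional to the shared profile
  shared <- c(1, 3, 2, 5, 4)
  m <- rbind(g1 = shared, g2 = shared, g3 = shared)
  res <- module_eigengene(m)
  expect_equal(res$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(stats::cor(res$eigengene, shared)), 1, tolerance = 1e-12)
  expect_equal(sum(res$eigengene^2), 1, tolerance = 1e-12)
  # eigengene is oriented along the mean member profile
  expect_gt(stats::cor(res$eigengene, shared), 0)
  # two orthogonal equal-variance members split the variance
  m2 <- rbind(g1 = c(1, -1, 1, -1), g2 = c(1, 1, -1, -1))
  expect_equal(module_eigengene(m2)$var_explained, 0.5, tolerance = 1e-12)
  # random module vs eigen() on the standardized cross-product
  withr::with_seed(31, { mr <- matrix(rnorm(20 * 5), nrow = 20) })
  rownames(mr) <- paste0("g", 1:20)
  res3 <- module_eigengene(mr)
  z <- t(scale(t(mr)))
  eig <- eigen(crossprod(z))
  expect_equal(abs(res3$eigengene), abs(eig$vectors[, 1]), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res3$var_explained, eig$values[1] / sum(eig$values),
               tolerance = 1e-10)
  expect_error(module_eigengene(mr[1, , drop = FALSE]), ">= 2 members")
})

test_that("eigengene-based merging joins split modules and respects cuts", {
  m <- block_profiles(30, 1, 15, within_r = 0.9, seed = 32)
  asg <- tibble::tibble(feature_id = rownames(m),
                        module = rep(c("A", "B"), 15))
  merged <- merge_close_modules(asg, m, merge_cut = 0.25)
  expect_equal(length(unique(merged$module)), 1)
  expect_equal(merge_close_modules(asg, m, merge_cut = 0), asg)
  # three orthogonal modules stay apart
  m3 <- rbind(
    a1 = c(1, -1, 1, -1, 1, -1), a2 = c(1, -1, 1, -1, 1, -1) + 1e-6,
    b1 = c(1, 1, -1, -1, 1, 1), b2 = c(1, 1, -1, -1, 1, 1) + 1e-6,
    c1 = c(1, 1, 1, -1, -1, -1), c2 = c(1, 1, 1, -1, -1, -1) + 1e-6)
  asg3 <- tibble::tibble(feature_id = rownames(m3),
                         module = rep(c("A", "B", "C"), each = 2))
  expect_equal(merge_close_modules(asg3, m3, 0.25), asg3)
})

test_that("end-to-end detection recovers planted co-response modules", {
  pats <- planted_patterns()
  cfg <- simulation_config(
    n_genes = 400, seed = 41,
    modules = list(
      list(module_id = "M1", size = 80, response_pattern = pats$up_late),
      list(module_id = "M2", size = 80, response_pattern = pats$u_shape)))
  ex <- simulate_expression(cfg)
  lfc <- log2_fold_change(ex$counts, ex$samples)
  ms <- suppressWarnings(detect_coresponse_modules(lfc))
  expect_s3_class(ms, "module_set")
  merged <- dplyr::inner_join(ms$assignment, ex$truth$gene_module,
                              by = "feature_id")
  planted <- merged[merged$module_id != "null", ]
  expect_gte(module_recovery_ari(planted$module, planted$module_id), 0.8)
  expect_true(all(ms$var_explained$var_explained >= 0 &
                    ms$var_explained$var_explained <= 1))
  expect_true(all(ms$var_explained$size >= ms$params$min_module_size))
  # tidy/glance surface
  expect_equal(nrow(tidy(ms)), 400)
  expect_gte(glance(ms)$n_modules, 2)
})
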