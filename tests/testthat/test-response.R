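test_that("log2 fold change follows the replicate-mean ratio definition", {
  samples <- toy_samples(stages = 26)
  vals <- toy_values(matrix(c(2, 2, 2, 8, 8, 8,
                              5, 5, 5, 5, 5, 5,
                              0, 0, 0, 3, 3, 3), nrow = 3, byrow = TRUE,
                            dimnames = list(c("g1", "g2", "g3"), NULL)),
                     samples)
  lfc0 <- log2_fold_change(vals[1:2, ], samples, pseudocount = 0)
  expect_equal(lfc0$log2fc[lfc0$feature_id == "g1"], 2)   # log2(8/2)
  expect_equal(lfc0$log2fc[lfc0$feature_id == "g2"], 0)
  lfc1 <- log2_fold_change(vals, samples, pseudocount = 1)
  expect_equal(lfc1$log2fc[lfc1$feature_id == "g3"], 2)   # log2(4/1)
})

test_that("log2 fold change is antisymmetric under treatment swap", {
  samples <- toy_samples()
  withr::with_seed(4, {
    mat <- matrix(rpois(8 * nrow(samples), 40), nrow = 8,
                  dimnames = list(paste0("g", 1:8), NULL))
  })
  vals <- toy_values(mat, samples)
  swapped <- samples
  swapped$treatment <- ifelse(samples$treatment == "CT", "WD", "CT")
  a <- log2_fold_change(vals, samples, pseudocount = 1)
  b <- log2_fold_change(vals, swapped, pseudocount = 1)
  expect_equal(a$log2fc, -b$log2fc)
})

test_that("missing treatment at a stage is an error", {
  samples <- toy_samples(stages = 26)
  samples <- samples[samples$treatment == "CT", ]
  vals <- toy_values(matrix(1:6, nrow = 2), samples)
  expect_error(log2_fold_change(vals, samples), "lacks replicates")
})

test_that("stagewise ANOVA matches the explicit F computation", {
  samples <- toy_samples(stages = 26)
  # identical groups: F = 0, p = 1
  vals <- toy_values(matrix(c(1, 2, 3, 1, 2, 3), nrow = 1,
                            dimnames = list("m1", NULL)), samples)
  res <- stagewise_anova(vals, samples)
  expect_equal(res$p_value, 1)
  # oracle: CT (1,2,3) vs WD (11,12,13): SSB = 150, MSW = 1, F = 150, df (1,4)
  vals2 <- toy_values(matrix(c(1, 2, 3, 11, 12, 13), nrow = 1,
                             dimnames = list("m1", NULL)), samples)
  res2 <- stagewise_anova(vals2, samples)
  expect_equal(res2$p_value, stats::pf(150, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(res2$p_value, 0.001)
  # degenerate variance convention
  s2 <- toy_samples(stages = 26, n_reps = 2)
  res3 <- stagewise_anova(toy_values(matrix(c(5, 5, 5, 5), nrow = 1,
                                            dimnames = list("m1", NULL)), s2), s2)
  expect_equal(res3$p_value, 1)
  res4 <- stagewise_anova(toy_values(matrix(c(5, 5, 7, 7), nrow = 1,
                                            dimnames = list("m1", NULL)), s2), s2)
  expect_equal(res4$p_value, 0)
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  withr::with_seed(10, {
    for (i in 1:5) {
      a <- rnorm(4); b <- rnorm(4, mean = 1)
      p_anova <- berrynet:::anova_two_group_p(a, b)
      p_t <- stats::t.test(a, b, var.equal = TRUE)$p.value
      expect_equal(p_anova, p_t, tolerance = 1e-12)
    }
  })
})

test_that("ANOVA p-values are uniform under the null", {
  withr::with_seed(77, {
    p <- vapply(1:1000, function(i) {
      berrynet:::anova_two_group_p(rnorm(3), rnorm(3))
    }, numeric(1))
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("profile clustering uses 1 - PCC with complete linkage", {
  profiles <- tibble::tibble(
    feature_id = rep(c("a", "b", "c"), each = 4),
    stage_daa = rep(c(26L, 53L, 67L, 81L), 3),
    log2fc = c(1, 2, 3, 4,   1, 2, 3, 4,   4, 3, 2, 1))
  cl <- cluster_response_profiles(profiles)
  # identical profiles a,b merge first at height 0
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  # anticorrelated profile joins last at height 2
  expect_equal(cl$hclust$height[2], 2, tolerance = 1e-12)
})

test_that("clustering matches a brute-force complete-linkage oracle", {
  withr::with_seed(12, {
    mat <- matrix(rnorm(4 * 6), nrow = 4,
                  dimnames = list(c("p1", "p2", "p3", "p4"), NULL))
  })
  profiles <- tibble::tibble(
    feature_id = rep(rownames(mat), each = 6),
    stage_daa = rep(1:6, 4),
    log2fc = as.vector(t(mat)))
  cl <- cluster_response_profiles(profiles)
  # naive agglomeration: repeatedly join the pair of clusters with the
  # smallest maximum pairwise distance
  d <- 1 - stats::cor(t(mat))
  clusters <- as.list(rownames(mat))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  expect_equal(sort(cl$hclust$height), sort(heights), tolerance = 1e-12)
})

test_that("clustering is invariant to input row order and sets aside flats", {
  withr::with_seed(13, {
    mat <- matrix(rnorm(5 * 4), nrow = 5,
                  dimnames = list(paste0("f", 1:5), NULL))
  })
  profiles <- tibble::tibble(
    feature_id = rep(rownames(mat), each = 4),
    stage_daa = rep(1:4, 5),
    log2fc = as.vector(t(mat)))
  shuffled <- profiles[rev(seq_len(nrow(profiles))), ]
  expect_equal(cluster_response_profiles(profiles)$order,
               cluster_response_profiles(shuffled)$order)
  flat <- dplyr::bind_rows(profiles, tibble::tibble(
    feature_id = "flat", stage_daa = 1:4, log2fc = rep(1, 4)))
  expect_warning(cl <- cluster_response_profiles(flat), "set aside")
  expect_equal(cl$order$feature_id[6], "flat")
  allflat <- tibble::tibble(feature_id = rep(c("x", "y"), each = 3),
                            stage_daa = rep(1:3, 2), log2fc = rep(0, 6))
  expect_error(suppressWarnings(cluster_response_profiles(allflat)),
               "zero variance")
})

test_that("PCA scores match an eigendecomposition oracle", {
  # collinear points: PC1 carries all the variance
  line <- cbind(1:6, 2 * (1:6))
  p <- pca_scores(line)
  expect_equal(p$variance_explained_pct[1], 100)
  # fixed 5 x 4 matrix vs explicit covariance eigendecomposition
  withr::with_seed(14, { x <- matrix(rnorm(20), nrow = 5) })
  p2 <- pca_scores(x, center = TRUE, scale = FALSE)
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(xc))
  oracle_scores <- xc %*% eig$vectors
  got <- as.matrix(p2$scores[, -1])
  for (j in 1:4) {
    expect_equal(abs(got[, j]), abs(oracle_scores[, j]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  expect_equal(p2$variance_explained_pct,
               100 * eig$values / sum(eig$values), tolerance = 1e-10)
  expect_true(all(diff(p2$variance_explained_pct) <= 1e-10))
  expect_equal(sum(p2$variance_explained_pct), 100, tolerance = 1e-8)
})

test_that("PCA of an isotropic cloud splits variance evenly", {
  withr::with_seed(15, { x <- matrix(rnorm(2000), ncol = 2) })
  p <- pca_scores(x)
  expect_lt(abs(p$variance_explained_pct[1] - 50), 3)
  expect_lt(abs(p$variance_explained_pct[2] - 50), 3)
})

test_that("DE overlap performs exact set algebra", {
  de <- tibble::tibble(
    gene_id = c("g1", "g2", "g2"),
    stage_daa = c(26L, 26L, 53L),
    log2fc = c(1, -1, 2), padj = rep(0.01, 3),
    direction = c("up", "down", "up"))
  ov <- de_overlap(de)
  expect_equal(ov$stage_counts$total, c(2L, 1L))
  expect_equal(ov$stage_counts$up, c(1L, 1L))
  unique_a <- ov$regions$count[ov$regions$stages == "26"]
  common <- ov$regions$count[ov$regions$stages == "26+53"]
  expect_equal(unique_a, 1L)
  expect_equal(common, 1L)
  expect_false("53" %in% ov$regions$stages)  # no gene unique to 53
})

test_that("overlap regions partition the union across five random sets", {
  withr::with_seed(16, {
    pool <- paste0("g", 1:300)
    de <- purrr::map_dfr(1:5, function(s) {
      tibble::tibble(gene_id = sample(pool, 100), stage_daa = s,
                     log2fc = 1, padj = 0.01, direction = "up")
    })
  })
  ov <- de_overlap(de)
  expect_equal(sum(ov$regions$count), length(unique(de$gene_id)))
  expect_lte(nrow(ov$regions), 31)
  # cross-check one region against brute force
  sets <- split(de$gene_id, de$stage_daa)
  only12 <- setdiff(intersect(sets[["1"]], sets[["2"]]),
                    Reduce(union, sets[c("3", "4", "5")]))
  got <- ov$regions$count[ov$regions$stages == "1+2"]
  expect_equal(if (length(got)) got else 0L, length(only12))
})
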