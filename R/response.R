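#' Stage-wise log2(WD/CT) response profiles
#'
#' For every feature and stage, computes
#' `log2((mean_WD + pseudocount) / (mean_CT + pseudocount))` from the
#' replicate arithmetic means. This is the per-feature water-deficit
#' response profile that feeds co-response module detection and the
#' metabolite heatmaps.
#'
#' The default pseudocount is 1 for count-like data; for metabolite
#' concentrations pass `pseudocount = NULL` to use half the smallest
#' positive observed value (zeros are rare but possible in concentration
#' tables and the ratio must stay finite).
#'
#' @param values Tibble whose first column is the feature id and whose
#'   remaining (numeric) columns are samples.
#' @param samples Sample metadata tibble (`sample_id`, `stage_daa`,
#'   `treatment`, `replicate`).
#' @param pseudocount Positive offset added to both means, or `NULL` for the
#'   metabolite default described above.
#' @return A long tibble: `feature_id`, `stage_daa`, `log2fc`.
#' @export
log2_fold_change <- function(values, samples, pseudocount = 1) {
  id_col <- names(values)[1]
  num_cols <- intersect(names(values), samples$sample_id)
  if (length(num_cols) == 0) {
    stop("No data column matches a sample id in the metadata.", call. = FALSE)
  }
  mat <- as.matrix(values[, num_cols])
  rownames(mat) <- values[[1]]
  if (is.null(pseudocount)) {
    pos <- mat[mat > 0]
    if (length(pos) == 0) stop("All values are zero; cannot derive a pseudocount.",
                               call. = FALSE)
    pseudocount <- min(pos) / 2
  }
  if (pseudocount < 0) stop("`pseudocount` must be nonnegative.", call. = FALSE)
  meta <- samples[match(num_cols, samples$sample_id), ]
  stages <- sort(unique(meta$stage_daa))
  out <- purrr::map_dfr(stages, function(s) {
    wd_cols <- meta$sample_id[meta$stage_daa == s & meta$treatment == "WD"]
    ct_cols <- meta$sample_id[meta$stage_daa == s & meta$treatment == "CT"]
    if (length(wd_cols) == 0 || length(ct_cols) == 0) {
      stop("Stage ", s, " lacks replicates for ",
           if (length(wd_cols) == 0) "WD" else "CT", ".", call. = FALSE)
    }
    m_wd <- rowMeans(mat[, wd_cols, drop = FALSE])
    m_ct <- rowMeans(mat[, ct_cols, drop = FALSE])
    if (pseudocount == 0 && any(m_ct == 0 | m_wd == 0)) {
      stop("Zero mean with pseudocount 0 would give an infinite log ratio; ",
           "use a positive pseudocount.", call. = FALSE)
    }
    tibble::tibble(
      feature_id = rownames(mat),
      stage_daa = as.integer(s),
      log2fc = unname(log2((m_wd + pseudocount) / (m_ct + pseudocount)))
    )
  })
  out
}

# Long profile tibble -> features x stages matrix (stage-ordered columns).
profiles_to_matrix <- function(profiles) {
  wide <- tidyr::pivot_wider(profiles[, c("feature_id", "stage_daa", "log2fc")],
                             names_from = "stage_daa", values_from = "log2fc",
                             names_sort = TRUE)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$feature_id
  mat
}

#' Per-stage one-way ANOVA between treatments
#'
#' Fixed-effects one-way ANOVA (CT vs WD) per feature and stage, the test
#' used to flag metabolites responding to water deficit at a sampling date.
#' With two groups the F statistic equals the square of the pooled-variance
#' t statistic. Degenerate stages where both groups have zero within-group
#' variance are reported as p = 1 (equal means) or p = 0 (unequal means) by
#' convention.
#'
#' @param values Tibble, first column feature ids, other numeric columns
#'   samples (a `class` column, if present, is ignored).
#' @param samples Sample metadata tibble.
#' @return Long tibble: `feature_id`, `stage_daa`, `p_value`.
#' @export
stagewise_anova <- function(values, samples) {
  num_cols <- intersect(names(values), samples$sample_id)
  mat <- as.matrix(values[, num_cols])
  rownames(mat) <- values[[1]]
  meta <- samples[match(num_cols, samples$sample_id), ]
  stages <- sort(unique(meta$stage_daa))
  purrr::map_dfr(stages, function(s) {
    wd_cols <- meta$sample_id[meta$stage_daa == s & meta$treatment == "WD"]
    ct_cols <- meta$sample_id[meta$stage_daa == s & meta$treatment == "CT"]
    if (length(wd_cols) < 2 || length(ct_cols) < 2) {
      stop("Stage ", s, " needs >= 2 replicates per treatment for ANOVA.",
           call. = FALSE)
    }
    p <- apply(mat, 1, function(v) {
      anova_two_group_p(v[ct_cols], v[wd_cols])
    })
    tibble::tibble(feature_id = rownames(mat), stage_daa = as.integer(s),
                   p_value = unname(p))
  })
}

anova_two_group_p <- function(a, b) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  grp <- factor(rep(c("CT", "WD"), c(length(a), length(b))))
  stats::anova(stats::lm(c(a, b) ~ grp))[["Pr(>F)"]][1]
}

#' Cluster response profiles by correlation distance
#'
#' Agglomerative clustering of feature profiles with distance
#' `1 - PCC` and complete linkage -- the ordering used for response
#' heatmaps. Features are sorted lexicographically by id before clustering
#' so ties break deterministically and the result is invariant to input row
#' order. Zero-variance profiles cannot be correlated; they are set aside
#' with a warning and appended after the ordered leaves.
#'
#' @param profiles Long tibble (`feature_id`, `stage_daa`, `log2fc`) as from
#'   [log2_fold_change()].
#' @return A `profile_clustering` list: `order` (tibble `feature_id`,
#'   `position`), `hclust` (the merge tree), `set_aside` (zero-variance
#'   ids).
#' @export
cluster_response_profiles <- function(profiles) {
  mat <- profiles_to_matrix(profiles)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) < 2) stop("Need at least 2 profiles to cluster.", call. = FALSE)
  vars <- apply(mat, 1, stats::var)
  aside <- rownames(mat)[vars == 0]
  keep <- rownames(mat)[vars > 0]
  if (length(keep) == 0) {
    stop("All profiles have zero variance; nothing to cluster.", call. = FALSE)
  }
  if (length(aside) > 0) {
    warning(length(aside), " zero-variance profile(s) set aside and appended ",
            "after the ordered leaves.")
  }
  m <- mat[keep, , drop = FALSE]
  if (length(keep) == 1) {
    ord <- keep
    hc <- NULL
  } else {
    d <- stats::as.dist(1 - stats::cor(t(m)))
    hc <- stats::hclust(d, method = "complete")
    ord <- keep[hc$order]
  }
  leaves <- c(ord, aside)
  structure(
    list(
      order = tibble::tibble(feature_id = leaves,
                             position = seq_along(leaves)),
      hclust = hc,
      set_aside = aside
    ),
    class = "profile_clustering"
  )
}

#' Principal component scores
#'
#' PCA of a samples x features matrix via singular value decomposition
#' (centered by default; scaling to unit variance is appropriate for
#' metabolite tables with heterogeneous units, and off for log-scale
#' expression). Zero-variance features are dropped with a warning when
#' scaling. Each component's sign is fixed so that its largest-magnitude
#' loading is positive, making scores reproducible across platforms.
#'
#' @param x Numeric matrix (samples in rows) or a tibble whose first column
#'   is the sample id.
#' @param center,scale Passed to the decomposition (defaults `TRUE`,
#'   `FALSE`).
#' @return A `pca_result`: `scores` (tibble `sample_id` + `PC1..`),
#'   `variance_explained_pct`, `loadings`.
#' @export
pca_scores <- function(x, center = TRUE, scale = FALSE) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    x <- as.matrix(x[, -1])
    rownames(x) <- ids
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample", seq_len(nrow(x)))
  if (nrow(x) < 2) stop("PCA needs >= 2 samples.", call. = FALSE)
  if (scale) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      warning(sum(v == 0), " zero-variance feature(s) dropped before scaling.")
      x <- x[, v > 0, drop = FALSE]
    }
  }
  if (ncol(x) < 2) stop("PCA needs >= 2 usable features.", call. = FALSE)
  pc <- stats::prcomp(x, center = center, scale. = scale)
  # orient: largest-|loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = dplyr::bind_cols(
        tibble::tibble(sample_id = rownames(x)),
        tibble::as_tibble(pc$x)
      ),
      variance_explained_pct = var_pct,
      loadings = pc$rotation
    ),
    class = "pca_result"
  )
}

#' Per-stage DE counts and cross-stage overlap regions
#'
#' Exact set algebra over the per-stage differentially-expressed gene sets:
#' per-stage totals with up/down splits, and the cardinality of every
#' exclusive Venn region across stages (a gene's region is the exact set of
#' stages at which it is DE).
#'
#' @param de DE table tibble (`gene_id`, `stage_daa`, `log2fc`, `padj`,
#'   `direction`), typically from [read_de_table()].
#' @return A `de_overlap` list: `stage_counts` (tibble `stage_daa`, `total`,
#'   `up`, `down`) and `regions` (tibble `stages` (label like "26+53"),
#'   `n_stages`, `count`).
#' @export
de_overlap <- function(de) {
  stage_counts <- de |>
    dplyr::group_by(.data$stage_daa) |>
    dplyr::summarise(
      total = dplyr::n(),
      up = sum(.data$direction == "up"),
      down = sum(.data$direction == "down"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$stage_daa)
  membership <- de |>
    dplyr::distinct(.data$gene_id, .data$stage_daa) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      stages = paste(sort(unique(.data$stage_daa)), collapse = "+"),
      n_stages = dplyr::n_distinct(.data$stage_daa),
      .groups = "drop"
    )
  regions <- membership |>
    dplyr::count(.data$stages, .data$n_stages, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$n_stages), .data$stages)
  structure(list(stage_counts = stage_counts, regions = regions),
            class = "de_overlap")
}

#' Heatmap of response profiles in clustering order
#'
#' @param profiles Long tibble from [log2_fold_change()].
#' @param clustering Optional [cluster_response_profiles()] result supplying
#'   the row order (computed if missing).
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(profiles, clustering = NULL) {
  if (is.null(clustering)) clustering <- cluster_response_profiles(profiles)
  df <- dplyr::left_join(profiles, clustering$order, by = "feature_id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage_daa),
                                   y = stats::reorder(.data$feature_id, .data$position))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log2fc)) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  name = expression(log[2] * "FC (WD/CT)")) +
    ggplot2::labs(x = "stage (DAA)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
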