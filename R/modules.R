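#' Network construction parameters
#'
#' Parameter bundle for weighted co-expression network construction. The
#' defaults follow the canonical recommendations of the weighted-network
#' method: unsigned adjacency, soft power chosen by the scale-free fit,
#' static tree cut near the top of the dendrogram, and eigengene-based
#' module merging at dissimilarity 0.25.
#'
#' @param power Soft-threshold exponent `beta` (`NULL` to select via
#'   [select_soft_power()]).
#' @param network_type `"unsigned"` (`|r|^beta`) or `"signed"`
#'   (`((1 + r)/2)^beta`).
#' @param min_module_size Smallest cluster kept as a module; smaller
#'   clusters go to `"unassigned"`. 20 suits stage-wise response profiles,
#'   30 suits full expression trajectories.
#' @param cut_height Dendrogram cut height in (0, 1\] on the `1 - TOM`
#'   scale.
#' @param merge_cut Eigengene dissimilarity below which modules merge.
#' @param label_prefix Prefix for module labels (`"WD"` for co-response,
#'   `"DEV"` for developmental modules).
#' @return A `network_params` list.
#' @export
network_params <- function(power = NULL,
                           network_type = c("unsigned", "signed"),
                           min_module_size = 20,
                           cut_height = 0.95,
                           merge_cut = 0.25,
                           label_prefix = "WD") {
  network_type <- match.arg(network_type)
  if (!is.null(power) && power <= 0) stop("`power` must be positive.", call. = FALSE)
  if (min_module_size < 1) stop("`min_module_size` must be positive.", call. = FALSE)
  if (cut_height <= 0 || cut_height > 1) {
    stop("`cut_height` must lie in (0, 1].", call. = FALSE)
  }
  if (merge_cut < 0 || merge_cut > 1) stop("`merge_cut` must lie in [0, 1].",
                                           call. = FALSE)
  structure(
    list(power = power, network_type = network_type,
         min_module_size = as.integer(min_module_size),
         cut_height = cut_height, merge_cut = merge_cut,
         label_prefix = label_prefix),
    class = "network_params"
  )
}

as_feature_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (is.data.frame(profiles)) {
    if (all(c("feature_id", "stage_daa", "log2fc") %in% names(profiles))) {
      return(profiles_to_matrix(profiles))
    }
    mat <- as.matrix(profiles[, -1])
    rownames(mat) <- as.character(profiles[[1]])
    return(mat)
  }
  stop("`profiles` must be a matrix or a data frame with feature ids in ",
       "the first column.", call. = FALSE)
}

check_feature_variance <- function(mat) {
  vars <- apply(mat, 1, stats::var)
  if (any(vars == 0)) {
    stop("Zero-variance feature(s): ",
         paste(utils::head(rownames(mat)[vars == 0], 5), collapse = ", "),
         if (sum(vars == 0) > 5) ", ...",
         ". Remove constant profiles before network construction.",
         call. = FALSE)
  }
  invisible(mat)
}

#' Select the soft-threshold power by scale-free fit
#'
#' For each candidate power, builds the adjacency, computes node
#' connectivity `k`, bins `k` into `n_bins` equal-width bins, and fits
#' `log10 p(k) ~ log10 k` by least squares. The fit index is the signed
#' R-squared (negated when the slope is positive, since scale-free topology
#' requires a decaying `p(k)`). Returns the smallest power whose index
#' reaches `target_r2`; if none does, the power with the best index is
#' returned with a warning. If the binned fit is undefined for every
#' candidate (e.g. all connectivities identical), the smallest candidate is
#' returned with a warning.
#'
#' @param profiles Feature profiles: long tibble, wide data frame or
#'   features x variables matrix.
#' @param candidate_powers Powers to try (default 1:20).
#' @param target_r2 Scale-free fit threshold (default 0.8).
#' @param network_type See [network_params()].
#' @param n_bins Number of connectivity bins (>= 5).
#' @return A list: `power`, `fit` (tibble `power`, `r2`, `mean_k`).
#' @export
select_soft_power <- function(profiles, candidate_powers = 1:20,
                              target_r2 = 0.8,
                              network_type = c("unsigned", "signed"),
                              n_bins = 10) {
  network_type <- match.arg(network_type)
  if (length(candidate_powers) == 0) {
    stop("`candidate_powers` must be nonempty.", call. = FALSE)
  }
  if (n_bins < 5) stop("Need >= 5 connectivity bins.", call. = FALSE)
  mat <- as_feature_matrix(profiles)
  check_feature_variance(mat)
  if (nrow(mat) < 20) {
    warning("Scale-free fitting on fewer than 20 features is unreliable.")
  }
  r <- stats::cor(t(mat))
  if (all(!is.finite(r))) stop("All correlations undefined.", call. = FALSE)
  base <- if (network_type == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- 0
  fits <- purrr::map_dfr(candidate_powers, function(beta) {
    k <- rowSums(base^beta)
    tibble::tibble(power = beta, r2 = scale_free_r2(k, n_bins), mean_k = mean(k))
  })
  ok <- fits$power[!is.na(fits$r2) & fits$r2 >= target_r2]
  reached <- length(ok) > 0
  if (reached) {
    power <- min(ok)
  } else if (all(is.na(fits$r2))) {
    warning("Scale-free fit undefined for every candidate power; ",
            "returning the smallest candidate.")
    power <- min(candidate_powers)
  } else {
    power <- fits$power[which.max(fits$r2)]
    warning("No candidate power reaches target R^2 = ", target_r2,
            "; returning the best fit (power ", power, ", R^2 = ",
            round(max(fits$r2, na.rm = TRUE), 3), ").")
  }
  list(power = power, fit = fits, reached_target = reached)
}

# Canonical sample-size-based default power, used when the scale-free
# criterion cannot be satisfied (few observations per profile make the
# connectivity distribution uninformative).
default_power_for <- function(n_obs, network_type) {
  p <- if (n_obs < 20) 9 else if (n_obs < 30) 8 else if (n_obs < 40) 7 else 6
  if (network_type == "signed") 2 * p else p
}

# Signed scale-free fit index: R^2 of the log-log regression of the binned
# connectivity density, with sign flipped when the slope is positive (a
# scale-free topology requires p(k) to *decay* in k). Equal-width bins.
scale_free_r2 <- function(k, n_bins) {
  if (length(unique(k)) < n_bins || any(k <= 0)) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  pk <- tapply(k, bins, length) / length(k)
  kk <- tapply(k, bins, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 5) return(NA_real_)
  fit <- stats::lm(log10(pk[keep]) ~ log10(kk[keep]))
  -sign(stats::coef(fit)[2]) * summary(fit)$r.squared
}

#' Adjacency and topological overlap matrix
#'
#' Builds the soft-thresholded adjacency (`|r|^beta` unsigned or
#' `((1 + r)/2)^beta` signed) and the topological overlap similarity
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`. Entries lie in \[0, 1\] and the matrix is symmetric.
#' Zero-variance features are rejected.
#'
#' @param profiles Feature profiles (see [select_soft_power()]).
#' @param power Soft-threshold exponent.
#' @param network_type `"unsigned"` or `"signed"`.
#' @return The TOM similarity matrix with feature ids as dimnames.
#' @export
adjacency_tom <- function(profiles, power = 6,
                          network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  mat <- as_feature_matrix(profiles)
  check_feature_variance(mat)
  r <- stats::cor(t(mat))
  a <- if (network_type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 0
  tom_from_adjacency(a)
}

tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  l <- a %*% a
  min_k <- outer(k, k, pmin)
  tom <- (l + a) / (min_k + 1 - a)
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2  # enforce exact symmetry against FP noise
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`,
#' cut at `cut_height` (the simplified recursive variant of dynamic cutting:
#' subtrees taller than the cut height are split until all merges fall below
#' it, which for a monotone dendrogram is the static cut at that height).
#' Clusters smaller than `min_module_size` become `"unassigned"`. Module
#' labels are `<prefix>1, <prefix>2, ...` in decreasing size order.
#'
#' @param tom TOM similarity matrix from [adjacency_tom()].
#' @param params A [network_params()].
#' @return Assignment tibble: `feature_id`, `module`.
#' @export
detect_modules <- function(tom, params = network_params()) {
  if (is.null(rownames(tom))) {
    rownames(tom) <- colnames(tom) <- paste0("f", seq_len(nrow(tom)))
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= params$min_module_size]
  labels <- rep("unassigned", nrow(tom))
  if (length(keep) > 0) {
    keep <- keep[order(-sizes[keep], as.numeric(keep))]
    new_names <- paste0(params$label_prefix, seq_along(keep))
    for (i in seq_along(keep)) {
      labels[cl == as.numeric(keep[i])] <- new_names[i]
    }
  }
  tibble::tibble(feature_id = rownames(tom), module = labels)
}

#' Module eigengene and explained variance
#'
#' First right-singular direction of the feature-standardized module
#' submatrix: the unit-norm sample-space profile summarizing the module,
#' oriented so its correlation with the mean standardized member profile is
#' nonnegative. `var_explained` is the leading squared singular value over
#' the total.
#'
#' @param mat Features x samples numeric matrix restricted to one module
#'   (>= 2 rows).
#' @return List with `eigengene` (named numeric over samples) and
#'   `var_explained`.
#' @export
module_eigengene <- function(mat) {
  mat <- as_feature_matrix(mat)
  if (nrow(mat) < 2) stop("A module needs >= 2 members for an eigengene.",
                          call. = FALSE)
  check_feature_variance(mat)
  z <- t(scale(t(mat)))  # standardize each feature profile
  sv <- svd(z)
  eig <- sv$v[, 1]
  mean_profile <- colMeans(z)
  if (sum(eig * mean_profile) < 0) eig <- -eig
  names(eig) <- colnames(mat)
  list(eigengene = eig, var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the closest pair of modules whose eigengene
#' dissimilarity `1 - PCC` falls below `merge_cut`, recomputing eigengenes
#' after every merge, until no pair qualifies. Ties break on the
#' lexicographically first label pair. The merged module keeps the label of
#' the larger member.
#'
#' @param assignment Tibble `feature_id`, `module` (from [detect_modules()]).
#' @param mat Features x samples matrix covering all assigned features.
#' @param merge_cut Dissimilarity threshold (0 leaves the assignment
#'   unchanged).
#' @return Updated assignment tibble.
#' @export
merge_close_modules <- function(assignment, mat, merge_cut = 0.25) {
  mat <- as_feature_matrix(mat)
  if (merge_cut <= 0) return(assignment)
  labels <- stats::setNames(assignment$module, assignment$feature_id)
  repeat {
    mods <- sort(setdiff(unique(labels), "unassigned"))
    if (length(mods) < 2) break
    eigs <- lapply(mods, function(m) {
      module_eigengene(mat[names(labels)[labels == m], , drop = FALSE])$eigengene
    })
    names(eigs) <- mods
    best <- NULL
    best_d <- Inf
    for (i in seq_len(length(mods) - 1)) {
      for (j in seq(i + 1, length(mods))) {
        d <- 1 - stats::cor(eigs[[i]], eigs[[j]])
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(mods[i], mods[j])
        }
      }
    }
    if (is.null(best) || best_d >= merge_cut) break
    sizes <- table(labels)
    winner <- if (sizes[best[1]] >= sizes[best[2]]) best[1] else best[2]
    loser <- setdiff(best, winner)
    labels[labels == loser] <- winner
  }
  tibble::tibble(feature_id = names(labels), module = unname(labels))
}

#' Detect co-response or developmental modules end to end
#'
#' Convenience pipeline: (optional) soft-power selection, adjacency and
#' topological overlap, tree cutting, eigengene-based merging, and final
#' eigengene computation. Zero-variance features are excluded beforehand and
#' reported in the result.
#'
#' @param profiles Long profile tibble (`feature_id`, `stage_daa`,
#'   `log2fc`), wide data frame, or features x variables matrix. For
#'   co-response modules pass stage-wise log2FC profiles; for developmental
#'   modules pass expression values across all samples.
#' @param params A [network_params()].
#' @return A `module_set`: `assignment` (tibble `feature_id`, `module`),
#'   `eigengenes` (tibble `module`, one column per variable),
#'   `var_explained` (tibble), `power`, `params`, `excluded` (zero-variance
#'   ids).
#' @export
detect_coresponse_modules <- function(profiles, params = network_params()) {
  mat <- as_feature_matrix(profiles)
  vars <- apply(mat, 1, stats::var)
  excluded <- rownames(mat)[vars == 0]
  if (length(excluded) > 0) {
    warning(length(excluded), " zero-variance feature(s) excluded from ",
            "network construction.")
    mat <- mat[vars > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("Too few variable features for module detection.",
                          call. = FALSE)
  power <- params$power
  if (is.null(power)) {
    sel <- suppressWarnings(
      select_soft_power(mat, network_type = params$network_type)
    )
    power <- if (sel$reached_target) {
      sel$power
    } else {
      # scale-free fit unattainable (typical for short stage-axis profiles):
      # fall back to the method's sample-size-based default
      default_power_for(ncol(mat), params$network_type)
    }
  }
  tom <- adjacency_tom(mat, power = power, network_type = params$network_type)
  assignment <- detect_modules(tom, params)
  assignment <- merge_close_modules(assignment, mat, params$merge_cut)
  # relabel by size after merging
  mods <- setdiff(unique(assignment$module), "unassigned")
  if (length(mods) > 0) {
    sizes <- table(assignment$module)[mods]
    relabel <- stats::setNames(
      paste0(params$label_prefix, seq_along(mods)),
      names(sort(sizes, decreasing = TRUE))
    )
    assignment$module <- ifelse(assignment$module == "unassigned",
                                "unassigned", relabel[assignment$module])
  }
  if (length(excluded) > 0) {
    assignment <- dplyr::bind_rows(
      assignment,
      tibble::tibble(feature_id = excluded, module = "unassigned")
    )
  }
  eig_rows <- list()
  ve <- list()
  for (m in sort(setdiff(unique(assignment$module), "unassigned"))) {
    members <- assignment$feature_id[assignment$module == m]
    res <- module_eigengene(mat[members, , drop = FALSE])
    eig_rows[[m]] <- tibble::tibble(module = m, !!!as.list(res$eigengene))
    ve[[m]] <- tibble::tibble(module = m, var_explained = res$var_explained,
                              size = length(members))
  }
  structure(
    list(
      assignment = assignment,
      eigengenes = if (length(eig_rows)) dplyr::bind_rows(eig_rows) else NULL,
      var_explained = if (length(ve)) dplyr::bind_rows(ve) else
        tibble::tibble(module = character(), var_explained = numeric(),
                       size = integer()),
      power = power,
      params = params,
      excluded = excluded
    ),
    class = "module_set"
  )
}
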