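#' Edge-screening threshold policy
#'
#' Thresholds applied to every candidate association: edges require
#' `pcc > pcc_min` (on the signed coefficient by default; set
#' `use_abs_for_edges` to screen on `|pcc|` and admit negative regulators)
#' together with a permutation p-value `p_emp < p_emp_max` estimated from
#' `n_perm` permutations. Defaults are PCC > 0.8 with empirical p < 0.01
#' from 1,000 permutations.
#'
#' @param pcc_min Correlation threshold in (0, 1).
#' @param p_emp_max Empirical p-value threshold in (0, 1\].
#' @param n_perm Number of permutations.
#' @param use_abs_for_edges Screen on `|pcc|` instead of signed pcc.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(pcc_min = 0.8, p_emp_max = 0.01,
                             n_perm = 1000, use_abs_for_edges = FALSE) {
  if (pcc_min <= 0 || pcc_min >= 1) stop("`pcc_min` must lie in (0, 1).",
                                         call. = FALSE)
  if (p_emp_max <= 0 || p_emp_max > 1) stop("`p_emp_max` must lie in (0, 1].",
                                            call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1.", call. = FALSE)
  structure(
    list(pcc_min = pcc_min, p_emp_max = p_emp_max,
         n_perm = as.integer(n_perm),
         use_abs_for_edges = isTRUE(use_abs_for_edges)),
    class = "threshold_policy"
  )
}

#' Construct and validate a co-response network
#'
#' Container for typed gene/TF/metabolite nodes and correlation-screened
#' undirected edges. Edges are stored in canonical order (source < target,
#' sorted), self-edges and dangling references are rejected.
#'
#' @param nodes Tibble with `id`, `kind` (`structural_gene`, `TF`,
#'   `metabolite`), and optional `module_id`, `annotation`.
#' @param edges Tibble with `source`, `target`, `pcc`, `p_emp`, `edge_kind`
#'   (`gene-gene` or `gene-metabolite`).
#' @return A `coresponse_network` list.
#' @export
coresponse_network <- function(nodes, edges) {
  nodes <- tibble::as_tibble(nodes)
  edges <- tibble::as_tibble(edges)
  if (!"module_id" %in% names(nodes)) nodes$module_id <- NA_character_
  if (!"annotation" %in% names(nodes)) nodes$annotation <- NA_character_
  nodes$module_id[is.na(nodes$module_id)] <- ""
  nodes$annotation[is.na(nodes$annotation)] <- ""
  net <- structure(
    list(
      nodes = dplyr::arrange(nodes[, c("id", "kind", "module_id", "annotation")],
                             .data$id),
      edges = canonicalize_edges(edges)
    ),
    class = "coresponse_network"
  )
  validate_network(net)
  net
}

canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          pcc = numeric(), p_emp = numeric(),
                          edge_kind = character()))
  }
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  out <- tibble::tibble(source = a, target = b, pcc = edges$pcc,
                        p_emp = edges$p_emp, edge_kind = edges$edge_kind)
  dplyr::arrange(out, .data$source, .data$target)
}

validate_network <- function(net) {
  stopifnot(inherits(net, "coresponse_network"))
  if (anyDuplicated(net$nodes$id)) {
    stop("Duplicate node id '",
         net$nodes$id[duplicated(net$nodes$id)][1], "'.", call. = FALSE)
  }
  bad_kind <- setdiff(net$nodes$kind, c("structural_gene", "TF", "metabolite"))
  if (length(bad_kind) > 0) {
    stop("Unknown node kind '", bad_kind[1], "'.", call. = FALSE)
  }
  if (nrow(net$edges) > 0) {
    if (any(net$edges$source == net$edges$target)) {
      stop("Self-edges are not allowed.", call. = FALSE)
    }
    dangling <- setdiff(c(net$edges$source, net$edges$target), net$nodes$id)
    if (length(dangling) > 0) {
      stop("Edge references unknown node '", dangling[1], "'.", call. = FALSE)
    }
    if (any(abs(net$edges$pcc) > 1)) stop("pcc outside [-1, 1].", call. = FALSE)
    if (any(net$edges$p_emp <= 0 | net$edges$p_emp > 1)) {
      stop("p_emp outside (0, 1].", call. = FALSE)
    }
    if (any(!net$edges$edge_kind %in% c("gene-gene", "gene-metabolite"))) {
      stop("Unknown edge kind.", call. = FALSE)
    }
  }
  invisible(net)
}

#' Module representative profiles
#'
#' Stage-space profile summarizing each module, either its eigengene
#' (default) or the mean member profile. Used for the module-metabolite
#' screen.
#'
#' @param module_set A `module_set` from [detect_coresponse_modules()].
#' @param profiles The feature profiles the modules were detected on (long
#'   tibble, wide data frame or matrix).
#' @param mode `"eigengene"` or `"mean"`.
#' @return Tibble: `module` plus one numeric column per stage/variable.
#' @export
module_representatives <- function(module_set, profiles,
                                   mode = c("eigengene", "mean")) {
  mode <- match.arg(mode)
  if (mode == "eigengene") {
    if (is.null(module_set$eigengenes)) {
      stop("Module set has no eigengenes (no assigned modules).", call. = FALSE)
    }
    return(module_set$eigengenes)
  }
  mat <- as_feature_matrix(profiles)
  assign <- module_set$assignment
  mods <- sort(setdiff(unique(assign$module), "unassigned"))
  purrr::map_dfr(mods, function(m) {
    members <- intersect(assign$feature_id[assign$module == m], rownames(mat))
    tibble::tibble(module = m,
                   !!!as.list(colMeans(mat[members, , drop = FALSE])))
  })
}

#' Module-metabolite co-response screen
#'
#' Correlates every module representative with every metabolite response
#' profile over the shared stages, attaching permutation p-values. A pair
#' passes when `pcc > pcc_min` (or `|pcc|` under the absolute policy) and
#' `p_emp < p_emp_max`.
#'
#' @param module_profiles Tibble from [module_representatives()] (`module` +
#'   stage columns).
#' @param metabolite_profiles Long tibble (`feature_id`, `stage_daa`,
#'   `log2fc`) from [log2_fold_change()] on the metabolite table.
#' @param policy A [threshold_policy()].
#' @param seed Base seed; each pair uses its own derived stream, so results
#'   do not depend on evaluation order.
#' @return Tibble: `module`, `metabolite_id`, `pcc`, `p_emp`, `passes`.
#' @export
module_metabolite_coresponse <- function(module_profiles, metabolite_profiles,
                                         policy = threshold_policy(),
                                         seed = 1L) {
  met_mat <- profiles_to_matrix(metabolite_profiles)
  mod_mat <- as.matrix(module_profiles[, -1])
  rownames(mod_mat) <- module_profiles$module
  if (ncol(mod_mat) != ncol(met_mat)) {
    stop("Stage axes misaligned: modules have ", ncol(mod_mat),
         " stages, metabolites ", ncol(met_mat), ".", call. = FALSE)
  }
  pairs <- expand.grid(module = rownames(mod_mat),
                       metabolite_id = rownames(met_mat),
                       stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(pairs, function(module, metabolite_id) {
    x <- mod_mat[module, ]
    y <- met_mat[metabolite_id, ]
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      return(tibble::tibble(module = module, metabolite_id = metabolite_id,
                            pcc = NA_real_, p_emp = NA_real_, passes = FALSE))
    }
    res <- empirical_pcc_pvalue(x, y, n_perm = policy$n_perm,
                                seed = pair_seed(seed, module, metabolite_id))
    stat <- if (policy$use_abs_for_edges) abs(res$pcc) else res$pcc
    tibble::tibble(module = module, metabolite_id = metabolite_id,
                   pcc = res$pcc, p_emp = res$p_emp,
                   passes = stat > policy$pcc_min & res$p_emp < policy$p_emp_max)
  })
  dplyr::arrange(out, .data$module, .data$metabolite_id)
}

#' Build a gene/TF-metabolite co-response subnetwork
#'
#' Screens every gene-gene and gene-metabolite pair (metabolite-metabolite
#' pairs are excluded) against the threshold policy and assembles the
#' passing edges into a typed network. The correlation filter is applied
#' first; permutation p-values are then computed only for pairs that clear
#' it (a pair failing the PCC threshold can never pass the conjunctive
#' policy), with a per-pair seeded stream so the result is independent of
#' evaluation order.
#'
#' @param profiles Long tibble (`feature_id`, `stage_daa`, `log2fc`)
#'   covering every node id.
#' @param kinds Tibble with `id`, `kind` (`structural_gene`, `TF`,
#'   `metabolite`) and optional `module_id`, `annotation`.
#' @param policy A [threshold_policy()].
#' @param seed Base seed for the permutation streams.
#' @return A `coresponse_network`.
#' @export
build_subnetwork <- function(profiles, kinds, policy = threshold_policy(),
                             seed = 1L) {
  mat <- profiles_to_matrix(profiles)
  missing <- setdiff(kinds$id, rownames(mat))
  if (length(missing) > 0) {
    stop("No profile for node(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  ids <- sort(kinds$id)
  kind_of <- stats::setNames(kinds$kind, kinds$id)
  is_gene <- kind_of[ids] %in% c("structural_gene", "TF")
  sub <- mat[ids, , drop = FALSE]
  vars <- apply(sub, 1, stats::var)
  usable <- vars > 0
  edges <- list()
  if (sum(usable) >= 2) {
    cm <- stats::cor(t(sub[usable, , drop = FALSE]))
    uid <- rownames(cm)
    ugene <- is_gene[match(uid, ids)]
    for (i in seq_len(nrow(cm) - 1)) {
      for (j in seq(i + 1, nrow(cm))) {
        if (!ugene[i] && !ugene[j]) next  # no metabolite-metabolite edges
        stat <- if (policy$use_abs_for_edges) abs(cm[i, j]) else cm[i, j]
        if (!is.finite(stat) || stat <= policy$pcc_min) next
        res <- empirical_pcc_pvalue(
          sub[uid[i], ], sub[uid[j], ], n_perm = policy$n_perm,
          seed = pair_seed(seed, uid[i], uid[j])
        )
        if (res$p_emp < policy$p_emp_max) {
          edges[[length(edges) + 1]] <- tibble::tibble(
            source = uid[i], target = uid[j],
            pcc = res$pcc, p_emp = res$p_emp,
            edge_kind = if (ugene[i] && ugene[j]) "gene-gene" else "gene-metabolite"
          )
        }
      }
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(source = character(), target = character(),
                   pcc = numeric(), p_emp = numeric(), edge_kind = character())
  coresponse_network(kinds, edges)
}
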