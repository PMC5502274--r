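#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @method tidy module_set
#' @export
tidy.module_set <- function(x, ...) x$assignment

#' @method glance module_set
#' @export
glance.module_set <- function(x, ...) {
  assigned <- x$assignment$module != "unassigned"
  tibble::tibble(
    n_modules = length(unique(x$assignment$module[assigned])),
    n_assigned = sum(assigned),
    n_unassigned = sum(!assigned),
    power = x$power,
    median_var_explained = stats::median(x$var_explained$var_explained)
  )
}

#' @method autoplot module_set
#' @export
autoplot.module_set <- function(object, ...) {
  if (is.null(object$eigengenes)) {
    stop("No modules to plot.", call. = FALSE)
  }
  df <- tidyr::pivot_longer(object$eigengenes, -"module",
                            names_to = "variable", values_to = "value")
  df$variable <- factor(df$variable, levels = unique(df$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$value,
                                   group = .data$module,
                                   colour = .data$module)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "eigengene", colour = "module") +
    ggplot2::theme_minimal()
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_explained_pct)),
    variance_explained_pct = x$variance_explained_pct
  )
}

#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, colour = NULL, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$variance_explained_pct[1]),
      y = sprintf("PC2 (%.1f%%)", object$variance_explained_pct[2])
    ) +
    ggplot2::theme_minimal()
  p
}

#' @method tidy coresponse_network
#' @export
tidy.coresponse_network <- function(x, ...) x$edges

#' @method glance coresponse_network
#' @export
glance.coresponse_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_gene_gene = sum(x$edges$edge_kind == "gene-gene"),
    n_gene_metabolite = sum(x$edges$edge_kind == "gene-metabolite")
  )
}

#' @method autoplot coresponse_network
#' @export
autoplot.coresponse_network <- function(object, ...) {
  if (nrow(object$edges) == 0) {
    stop("Network has no edges to plot.", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = object$nodes)
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(id = igraph::V(g)$name, x = lay[, 1], y = lay[, 2],
                          kind = igraph::V(g)$kind)
  edges <- dplyr::left_join(object$edges,
                            stats::setNames(nodes[, c("id", "x", "y")],
                                            c("source", "x0", "y0")),
                            by = "source")
  edges <- dplyr::left_join(edges,
                            stats::setNames(nodes[, c("id", "x", "y")],
                                            c("target", "x1", "y1")),
                            by = "target")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = .data$edge_kind),
                          colour = "grey60") +
    ggplot2::scale_linewidth_manual(values = c("gene-gene" = 0.8,
                                               "gene-metabolite" = 0.4)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$kind,
                                     colour = .data$kind), size = 3) +
    ggplot2::scale_shape_manual(values = c(structural_gene = 16, TF = 15,
                                           metabolite = 17)) +
    ggplot2::theme_void()
}

#' @method tidy de_overlap
#' @export
tidy.de_overlap <- function(x, ...) x$stage_counts

#' @method glance de_overlap
#' @export
glance.de_overlap <- function(x, ...) {
  tibble::tibble(
    n_stages = nrow(x$stage_counts),
    total_de_calls = sum(x$stage_counts$total),
    n_unique_genes = sum(x$regions$count)
  )
}

#' @method print module_set
#' @export
print.module_set <- function(x, ...) {
  g <- glance(x)
  cat("Module set:", g$n_modules, "modules,", g$n_assigned, "assigned /",
      g$n_unassigned, "unassigned features (power", x$power, ")\n")
  print(x$var_explained)
  invisible(x)
}

#' @method print coresponse_network
#' @export
print.coresponse_network <- function(x, ...) {
  g <- glance(x)
  cat("Co-response network:", g$n_nodes, "nodes,", g$n_edges, "edges (",
      g$n_gene_gene, "gene-gene,", g$n_gene_metabolite, "gene-metabolite)\n")
  invisible(x)
}
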