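# All tabular I/O is tab-separated with '.' decimals -- one dialect, bit-exact
# round trips. Readers validate at the boundary and reject rather than repair.

write_tsv_plain <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

parse_numeric_cells <- function(df, path, integer_only = FALSE) {
  id_col <- names(df)[1]
  out <- matrix(NA_real_, nrow(df), ncol(df) - 1,
                dimnames = list(df[[1]], names(df)[-1]))
  for (j in seq(2, ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0) {
      stop("Parse error in ", path, ": non-numeric or non-finite value '",
           df[[j]][bad[1]], "' at row ", bad[1], " (", id_col, " = '",
           df[[1]][bad[1]], "'), column '", names(df)[j], "'.", call. = FALSE)
    }
    if (integer_only) {
      frac <- which(v != round(v) | v < 0)
      if (length(frac) > 0) {
        stop("Parse error in ", path, ": counts mode requires nonnegative ",
             "integers, got '", df[[j]][frac[1]], "' at row ", frac[1],
             " (", id_col, " = '", df[[1]][frac[1]], "'), column '",
             names(df)[j], "'.", call. = FALSE)
      }
    }
    out[, j - 1] <- v
  }
  out
}

validate_sample_meta <- function(meta, path = "<samples>") {
  need <- c("sample_id", "stage_daa", "treatment", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("Sample metadata ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("Duplicate sample id in ", path, ": '",
         meta$sample_id[duplicated(meta$sample_id)][1], "'.", call. = FALSE)
  }
  if (!all(meta$treatment %in% c("CT", "WD"))) {
    stop("Sample metadata ", path, ": treatment must be 'CT' or 'WD'.",
         call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(meta$sample_id),
    stage_daa = as.integer(meta$stage_daa),
    treatment = as.character(meta$treatment),
    replicate = as.integer(meta$replicate)
  )
}

#' Read an expression matrix with sample metadata
#'
#' The data file is a TSV whose first column holds feature ids and whose
#' remaining columns are samples; the metadata TSV has columns `sample_id`,
#' `stage_daa`, `treatment` (CT/WD), `replicate`. In `"counts"` mode all
#' values must be nonnegative integers. Malformed input is rejected with an
#' error naming the offending cell; samples present in the data but absent
#' from the metadata are an error.
#'
#' @param path Expression TSV.
#' @param meta_path Sample metadata TSV.
#' @param mode `"vst"` (any finite numeric) or `"counts"`.
#' @return A list with `values` (tibble, `feature_id` + sample columns) and
#'   `samples` (metadata tibble, restricted and ordered to the data columns).
#' @export
read_expression <- function(path, meta_path, mode = c("vst", "counts")) {
  mode <- match.arg(mode)
  df <- read_tsv_plain(path)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("Parse error in ", path, ": no features.", call. = FALSE)
  }
  if (anyDuplicated(df[[1]])) {
    stop("Parse error in ", path, ": duplicate feature id '",
         df[[1]][duplicated(df[[1]])][1], "'.", call. = FALSE)
  }
  if (anyDuplicated(names(df)[-1])) {
    stop("Parse error in ", path, ": duplicate sample id '",
         names(df)[-1][duplicated(names(df)[-1])][1], "'.", call. = FALSE)
  }
  mat <- parse_numeric_cells(df, path, integer_only = (mode == "counts"))
  meta <- validate_sample_meta(read_tsv_plain(meta_path), meta_path)
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing) > 0) {
    stop("Samples present in ", path, " but absent from ", meta_path, ": ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  values <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(mat)),
    tibble::as_tibble(mat)
  )
  list(values = values, samples = meta)
}

#' Read metabolite concentrations
#'
#' Same layout as [read_expression()] except for an optional second `class`
#' column; concentrations must be nonnegative.
#'
#' @param path Metabolite TSV (`metabolite_id`, optional `class`, samples).
#' @param meta_path Sample metadata TSV.
#' @return List with `values` (tibble `metabolite_id`, `class`, samples) and
#'   `samples`.
#' @export
read_metabolites <- function(path, meta_path) {
  df <- read_tsv_plain(path)
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("Parse error in ", path, ": no metabolites.", call. = FALSE)
  }
  has_class <- "class" %in% names(df)
  class_col <- if (has_class) df$class else rep(NA_character_, nrow(df))
  data_df <- df[, setdiff(names(df), "class")]
  if (anyDuplicated(data_df[[1]])) {
    stop("Parse error in ", path, ": duplicate metabolite id '",
         data_df[[1]][duplicated(data_df[[1]])][1], "'.", call. = FALSE)
  }
  mat <- parse_numeric_cells(data_df, path)
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop("Parse error in ", path, ": negative concentration at metabolite '",
         rownames(mat)[bad[1]], "', sample '", colnames(mat)[bad[2]], "'.",
         call. = FALSE)
  }
  meta <- validate_sample_meta(read_tsv_plain(meta_path), meta_path)
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing) > 0) {
    stop("Samples present in ", path, " but absent from ", meta_path, ": ",
         paste(missing, collapse = ", "), ".", call. = FALSE)
  }
  meta <- meta[match(colnames(mat), meta$sample_id), ]
  values <- dplyr::bind_cols(
    tibble::tibble(metabolite_id = rownames(mat), class = class_col),
    tibble::as_tibble(mat)
  )
  list(values = values, samples = meta)
}

#' Read promoter sequences from FASTA
#'
#' Multi-line records are concatenated; the record id is the first
#' whitespace-delimited token of the header; lowercase bases are mapped to
#' uppercase. Characters outside \{A,C,G,T,N\} and duplicate ids are
#' rejected. Promoters shorter than `nominal_length` are accepted with a
#' warning (real annotations contain truncated upstream regions).
#'
#' @param path FASTA file.
#' @param nominal_length Expected promoter length (default 1000 bp).
#' @return Tibble with `gene_id` and `sequence`.
#' @export
read_promoters <- function(path, nominal_length = 1000) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("Parse error in ", path, ": no records.", call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("Parse error in ", path, ": duplicate FASTA id '",
         ids[duplicated(ids)][1], "'.", call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) {
      stop("Parse error in ", path, ": empty sequence for '", ids[i], "'.",
           call. = FALSE)
    }
    bad <- regmatches(seqs[i], regexpr("[^ACGTN]", seqs[i]))
    if (length(bad) > 0) {
      stop("Validation error in ", path, ": invalid character '", bad,
           "' in record '", ids[i], "'.", call. = FALSE)
    }
  }
  short <- nchar(seqs) < nominal_length
  if (any(short)) {
    warning(sum(short), " promoter(s) shorter than the nominal ",
            nominal_length, " bp (e.g. '", ids[which(short)[1]], "').")
  }
  tibble::tibble(gene_id = ids, sequence = unname(seqs))
}

write_fasta <- function(promoters, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(promoters))) {
    writeLines(paste0(">", promoters$gene_id[i]), con)
    s <- promoters$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read a degenerate-motif catalog
#'
#' One motif per line, optionally followed by a tab-separated label; `#`
#' starts a comment; blank lines are skipped. Motifs must be IUPAC strings
#' of length 6-8; duplicates are rejected.
#'
#' @param path Motif list file.
#' @return Tibble with `motif` and `label` columns.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("Parse error in ", path, ": no motifs.", call. = FALSE)
  parts <- strsplit(lines, "\t")
  motifs <- vapply(parts, `[`, character(1), 1)
  labels <- vapply(parts, function(p) if (length(p) > 1) p[2] else p[1], character(1))
  motifs <- vapply(motifs, validate_iupac, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(motifs)) {
    stop("Validation error in ", path, ": duplicate motif '",
         motifs[duplicated(motifs)][1], "'.", call. = FALSE)
  }
  tibble::tibble(motif = motifs, label = labels)
}

#' Read a per-stage differential-expression table
#'
#' TSV with columns `gene_id`, `stage_daa`, `log2fc`, `padj` and optional
#' `direction`. `padj` must lie in \[0, 1\], `(gene, stage)` pairs must be
#' unique, and any supplied `direction` must be consistent with the sign of
#' `log2fc` (it is derived when absent).
#'
#' @param path DE table TSV.
#' @return Tibble with `gene_id`, `stage_daa`, `log2fc`, `padj`, `direction`.
#' @export
read_de_table <- function(path) {
  df <- read_tsv_plain(path)
  need <- c("gene_id", "stage_daa", "log2fc", "padj")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("Parse error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), ".", call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = df$gene_id,
    stage_daa = as.integer(df$stage_daa),
    log2fc = suppressWarnings(as.numeric(df$log2fc)),
    padj = suppressWarnings(as.numeric(df$padj))
  )
  bad <- which(is.na(out$log2fc) | is.na(out$padj) | is.na(out$stage_daa))
  if (length(bad) > 0) {
    stop("Parse error in ", path, ": non-numeric value at row ", bad[1], ".",
         call. = FALSE)
  }
  oor <- which(out$padj < 0 | out$padj > 1)
  if (length(oor) > 0) {
    stop("Validation error in ", path, ": padj outside [0, 1] at row ",
         oor[1], " (gene '", out$gene_id[oor[1]], "').", call. = FALSE)
  }
  key <- paste(out$gene_id, out$stage_daa)
  if (anyDuplicated(key)) {
    stop("Validation error in ", path, ": duplicate (gene, stage) pair '",
         key[duplicated(key)][1], "'.", call. = FALSE)
  }
  derived <- ifelse(out$log2fc > 0, "up", "down")
  if ("direction" %in% names(df)) {
    mism <- which(df$direction != derived)
    if (length(mism) > 0) {
      stop("Validation error in ", path, ": direction '",
           df$direction[mism[1]], "' inconsistent with sign of log2fc at row ",
           mism[1], " (gene '", out$gene_id[mism[1]], "').", call. = FALSE)
    }
  }
  out$direction <- derived
  out
}

#' Export a co-response network
#'
#' `"sif"` writes a Cytoscape SIF file (one line per edge,
#' `source<TAB>edge_kind<TAB>target`) plus sidecar `<path>.nodes.tsv` and
#' `<path>.edges.tsv` attribute tables. `"graphml"` embeds all node and edge
#' attributes in a single GraphML file (doubles at 17 significant digits, so
#' a round trip through [read_network()] reproduces `pcc` and `p_emp`
#' exactly).
#'
#' @param net A `coresponse_network` (see [build_subnetwork()]).
#' @param format `"sif"` or `"graphml"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, format = c("sif", "graphml"), path) {
  format <- match.arg(format)
  validate_network(net)
  if (format == "sif") {
    lines <- if (nrow(net$edges) > 0) {
      paste(net$edges$source, net$edges$edge_kind, net$edges$target, sep = "\t")
    } else {
      character()
    }
    writeLines(lines, path)
    write_tsv_plain(net$nodes, paste0(path, ".nodes.tsv"))
    write_tsv_plain(net$edges, paste0(path, ".edges.tsv"))
  } else {
    write_graphml(net, path)
  }
  invisible(path)
}

num17 <- function(x) sprintf("%.17g", x)

write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keydefs <- list(
    c("d_kind", "node", "kind", "string"),
    c("d_module", "node", "module_id", "string"),
    c("d_annot", "node", "annotation", "string"),
    c("d_pcc", "edge", "pcc", "double"),
    c("d_pemp", "edge", "p_emp", "double"),
    c("d_ekind", "edge", "edge_kind", "string")
  )
  for (kd in keydefs) {
    xml2::xml_add_child(doc, "key", id = kd[1], "for" = kd[2],
                        attr.name = kd[3], attr.type = kd[4])
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(net$nodes))) {
    node <- xml2::xml_add_child(graph, "node", id = net$nodes$id[i])
    xml2::xml_add_child(node, "data", key = "d_kind", net$nodes$kind[i])
    xml2::xml_add_child(node, "data", key = "d_module", net$nodes$module_id[i])
    xml2::xml_add_child(node, "data", key = "d_annot", net$nodes$annotation[i])
  }
  for (i in seq_len(nrow(net$edges))) {
    edge <- xml2::xml_add_child(graph, "edge",
                                source = net$edges$source[i],
                                target = net$edges$target[i])
    xml2::xml_add_child(edge, "data", key = "d_pcc", num17(net$edges$pcc[i]))
    xml2::xml_add_child(edge, "data", key = "d_pemp", num17(net$edges$p_emp[i]))
    xml2::xml_add_child(edge, "data", key = "d_ekind", net$edges$edge_kind[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a co-response network from GraphML
#'
#' Inverse of [write_network()] with `format = "graphml"`; node and edge
#' attributes (kind, module, annotation, pcc, p_emp, edge kind) are
#' restored and the canonical edge ordering reapplied.
#'
#' @param path GraphML file.
#' @return A `coresponse_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- igraph::vertex_attr(g, "id")
  if (is.null(ids)) ids <- igraph::vertex_attr(g, "name")
  nodes <- tibble::tibble(
    id = ids,
    kind = igraph::vertex_attr(g, "kind"),
    module_id = igraph::vertex_attr(g, "module_id"),
    annotation = igraph::vertex_attr(g, "annotation")
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble::tibble(
    source = if (nrow(el)) ids[el[, 1]] else character(),
    target = if (nrow(el)) ids[el[, 2]] else character(),
    pcc = igraph::edge_attr(g, "pcc") %||% numeric(),
    p_emp = igraph::edge_attr(g, "p_emp") %||% numeric(),
    edge_kind = igraph::edge_attr(g, "edge_kind") %||% character()
  )
  coresponse_network(nodes, edges)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
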